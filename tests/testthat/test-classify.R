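cv_default <- function() make_clinvar(
  gene = c("CHEK2", "BRCA2", "TP53"),
  transcript = c("NM_007194", "NM_000059", "NM_000546"),
  cdna_change = c("c.1100delC", "c.A3396G", "c.G1010A"),
  label = c("pathogenic", "benign", "pathogenic"))

test_that("ClinVar labels take precedence and the rule engine is bypassed", {
  v <- make_variants(1, gene = "CHEK2", transcript = "NM_007194",
                     cdna_change = "c.1100delC", exon = 10L)
  out <- classify_variant(v, cv_default())
  expect_equal(out$verdict, "pathogenic")
  expect_equal(out$source, "clinvar")
  expect_true(is.na(out$rule_applied))

  # a truncating variant labelled benign in ClinVar stays benign
  v2 <- make_variants(1, gene = "BRCA2", cdna_change = "c.A3396G",
                      functional_class = "frameshift_indel")
  out2 <- classify_variant(v2, cv_default())
  expect_equal(out2$verdict, "benign")
  expect_equal(out2$source, "clinvar")

  # a ClinVar-pathogenic missense is pathogenic despite the rule fallback
  v3 <- make_variants(1, gene = "TP53", transcript = "NM_000546",
                      cdna_change = "c.G1010A", functional_class = "missense")
  expect_equal(classify_variant(v3, cv_default())$verdict, "pathogenic")
})

test_that("novel variants follow the truncation / splice / missense rules", {
  cv <- cv_default()
  fs <- classify_variant(make_variants(1, cdna_change = "c.5754dupT"), cv)
  expect_equal(fs$verdict, "pathogenic")
  expect_equal(fs$source, "rule")
  expect_equal(fs$rule_applied, "truncation")

  sg <- classify_variant(make_variants(1, gene = "TP53",
    transcript = "NM_000546", cdna_change = "c.G272A",
    protein_change = "p.W91X", functional_class = "stopgain", exon = 4L), cv)
  expect_equal(sg$verdict, "pathogenic")

  ms <- classify_variant(make_variants(1, gene = "TP53",
    transcript = "NM_000546", cdna_change = "c.G1054T",
    protein_change = "p.D352Y", functional_class = "missense", exon = 10L), cv)
  expect_equal(ms$verdict, "vus")
  expect_equal(ms$rule_applied, "missense_or_inframe")

  inf <- classify_variant(make_variants(1, cdna_change = "c.1_3del",
    functional_class = "inframe_indel"), cv)
  expect_equal(inf$verdict, "vus")
})

test_that("the splice rule cuts off at two base pairs from the junction", {
  splice <- function(d) classify_variant(make_variants(1,
    functional_class = "intronic", splice_distance = d,
    cdna_change = sprintf("c.516+%dG>A", abs(d)), exon = NA_integer_,
    protein_change = NA_character_), cv_default())
  expect_equal(splice(1L)$verdict, "pathogenic")
  expect_equal(splice(2L)$verdict, "pathogenic")
  expect_equal(splice(2L)$rule_applied, "splice_2bp")
  expect_equal(splice(-2L)$verdict, "pathogenic")  # donor/acceptor agnostic
  expect_equal(splice(3L)$verdict, "not_counted")
  expect_equal(splice(15L)$verdict, "not_counted")
})

test_that("a last-exon truncating variant is not downgraded", {
  v <- make_variants(1, exon = 27L, cdna_change = "c.9925dupA",
                     is_last_exon = TRUE)
  expect_equal(classify_variant(v, cv_default())$verdict, "pathogenic")
})

test_that("synonymous and other classes are retained as not_counted", {
  syn <- classify_variant(make_variants(1, cdna_change = "c.A7242G",
    functional_class = "synonymous"), cv_default())
  expect_equal(syn$verdict, "not_counted")
  expect_equal(syn$rule_applied, "noncoding_or_synonymous")
  oth <- classify_variant(make_variants(1, cdna_change = "c.100G>A",
    functional_class = "other"), cv_default())
  expect_equal(oth$verdict, "not_counted")
})

test_that("every functional class reaches exactly one verdict branch", {
  cv <- empty_clinvar()
  for (fc in functional_classes()) {
    v <- make_variants(1, functional_class = fc,
      cdna_change = "c.1A>G",
      splice_distance = if (fc == "intronic") 1L else NA_integer_)
    out <- classify_variant(v, cv)
    expect_true(out$verdict %in% c("pathogenic", "vus", "not_counted"),
                info = fc)
    expect_equal(out$source, "rule", info = fc)
    expect_false(is.na(out$rule_applied), info = fc)
  }
})

test_that("an intronic call without splice distance is a classification error", {
  v <- make_variants(1, functional_class = "intronic")
  v$splice_distance <- NA_integer_  # bypasses reader validation on purpose
  expect_error(classify_variants(v, empty_clinvar()), "classification error")
})

test_that("verdict tallies are stable under input reordering", {
  set.seed(3)
  v <- rbind(
    make_variants(5, cdna_change = "c.5754dupT"),
    make_variants(3, gene = "TP53", transcript = "NM_000546",
                  functional_class = "missense", cdna_change = "c.G1054T"),
    make_variants(2, functional_class = "synonymous",
                  cdna_change = "c.A7242G"))
  cv <- empty_clinvar()
  t1 <- verdict_tally(classify_variants(v, cv))
  t2 <- verdict_tally(classify_variants(v[sample.int(nrow(v)), ], cv))
  expect_identical(t1, t2)
  expect_equal(unname(t1["BRCA2", "pathogenic"]), 5)
  expect_equal(unname(t1["TP53", "vus"]), 3)
  expect_equal(nrow(verdict_tally(classify_variants(v[0, ], cv))), 0)
})
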