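test_that("library molarity follows the 649 g/mol bp formula", {
  expect_equal(library_molarity(649, 1e6), 1.0)
  # hand evaluation: 2.6 * 1e6 / (649 * 400)
  expect_equal(library_molarity(2.6, 400), 10.0154083204931, tolerance = 1e-12)
  expect_error(library_molarity(0, 400), "domain error")
  expect_error(library_molarity(2.6, -1), "domain error")
})

test_that("age groups split at 40 and 50", {
  expect_identical(age_group(c(39, 40, 49, 50, NA)),
                   c("under40", "40to49", "40to49", "other", "other"))
})

test_that("variant table validation rejects malformed rows loudly", {
  v <- make_variants(3)
  ok <- validate_variants(v)
  expect_equal(nrow(ok), 3)

  bad <- make_variants(1, allelic_ratio = 1.2)
  expect_error(validate_variants(bad), "allelic_ratio outside")

  bad2 <- make_variants(1); bad2$read_depth <- "12x"
  expect_error(validate_variants(bad2), "unparseable numeric.*read_depth")

  # splice distance must be present exactly for intronic calls
  expect_error(validate_variants(make_variants(1,
    functional_class = "intronic", splice_distance = NA_integer_)),
    "missing splice_distance")
  expect_error(validate_variants(make_variants(1, splice_distance = 5L)),
    "splice_distance given for non-intronic")

  miss <- make_variants(1); miss$gene <- NULL
  expect_error(validate_variants(miss), "missing required column.*gene")
})

test_that("off-panel genes are rejected and counted, not silently dropped", {
  v <- rbind(make_variants(2),
             make_variants(1, gene = "ATM", transcript = "NM_000051"))
  expect_message(ok <- validate_variants(v), "1 row")
  expect_equal(nrow(ok), 2)
  rej <- attr(ok, "rejected")
  expect_equal(nrow(rej), 1)
  expect_equal(rej$gene, "ATM")
  expect_equal(attr(ok, "n_read"), nrow(ok) + nrow(rej))
})

test_that("subject validation enforces enums and family-history consistency", {
  s <- data.frame(subject_id = "x1", status = "case", age = 39,
                  er_status = "positive", grade = "high",
                  fh_first_degree = "yes", fh_any = "no",
                  stringsAsFactors = FALSE)
  expect_error(validate_subjects(s), "fh_first_degree")
  s$fh_any <- "yes"
  ok <- validate_subjects(s)
  expect_equal(ok$age_group, "under40")
  s$age <- 40
  expect_equal(validate_subjects(s)$age_group, "40to49")
  s$status <- "patient"
  expect_error(validate_subjects(s), "invalid value")
})

test_that("variant keys normalize case, whitespace and the c. prefix", {
  k1 <- normalize_variant_key("chek2", " NM_007194 ", "C.1100DELC")
  k2 <- normalize_variant_key("CHEK2", "NM_007194", "c.1100delC")
  k3 <- normalize_variant_key("CHEK2", "NM_007194", "1100delC")
  expect_identical(k1, k2)
  expect_identical(k2, k3)
  expect_false(k1 == normalize_variant_key("CHEK2", "NM_007194", "c.1100delA"))
})

test_that("clinvar tables reject duplicate keys and bad labels", {
  expect_error(make_clinvar(gene = c("CHEK2", "chek2"),
                            transcript = "NM_007194",
                            cdna_change = c("c.1100delC", "C.1100DELC"),
                            label = c("pathogenic", "benign")),
               "duplicate ClinVar key")
  expect_error(make_clinvar("CHEK2", "NM_007194", "c.1100delC", "probably_bad"),
               "invalid value")
})

test_that("external control table supports the gnomAD-style comparison", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cohort_name\tn_total\tgene\tcarrier_count",
               "gnomAD_NFE\t21384\tBRCA2\t76",
               "gnomAD_NFE\t21384\tCHEK2\t144"), tmp)
  ex <- read_external_controls(tmp)
  expect_s3_class(ex, "external_controls")
  expect_equal(ex$n_total, 21384L)
  expect_equal(unname(ex$carriers["BRCA2"]), 76L)
  res <- external_burden(22, 655, ex, "BRCA2")
  expect_equal(res$c, 76)
  expect_equal(res$d, 21308)

  writeLines(c("cohort_name\tn_total\tgene\tcarrier_count",
               "gnomAD_NFE\t100\tBRCA2\t176"), tmp)
  expect_error(read_external_controls(tmp), "exceeds n_total")
})

test_that("every table format round-trips through write and read", {
  sim <- simulate_cohort(simulation_config(
    n_cases = 80, n_controls = 160,
    control_carrier_freq = c(BRCA2 = 0.05, CHEK2 = 0.05, PALB2 = 0.05,
                             BRCA1 = 0.05, TP53 = 0.05),
    odds_ratio = c(BRCA2 = 3, CHEK2 = 3, PALB2 = 3, BRCA1 = 3, TP53 = 3),
    artifact_rate = 0.1, seed = 7L))
  dir <- withr::local_tempdir()

  vp <- file.path(dir, "v.tsv")
  write_variant_table(sim$variants, vp)
  back <- read_variant_table(vp, burden_config())
  expect_equal(nrow(back), nrow(sim$variants))
  for (col in names(sim$variants))
    expect_equal(back[[col]], sim$variants[[col]], info = col)

  sp <- file.path(dir, "s.csv")
  write_subjects(sim$subjects, sp)
  sback <- read_subjects(sp)
  expect_equal(sback, sim$subjects, ignore_attr = TRUE)

  cp <- file.path(dir, "c.tsv")
  write_clinvar(sim$clinvar, cp)
  cback <- read_clinvar(cp)
  expect_equal(as.data.frame(cback), as.data.frame(sim$clinvar),
               ignore_attr = TRUE)

  ep <- file.path(dir, "e.tsv")
  ex <- validate_external_controls(data.frame(
    cohort_name = "gnomAD_NFE", n_total = 21384,
    gene = c("BRCA2", "CHEK2"), carrier_count = c(76, 144)))
  write_external_controls(ex, ep)
  expect_equal(read_external_controls(ep), ex, ignore_attr = TRUE)
})

test_that("config files round-trip and reject unknown keys", {
  dir <- withr::local_tempdir()
  cfg <- burden_config(depth_min = 15, alpha = 0.01)
  p <- file.path(dir, "cfg.yaml")
  write_config(cfg, p)
  back <- read_config(p)
  expect_equal(back, cfg)
  writeLines("depth_minimum: 15", p)
  expect_error(read_config(p), "unknown key")
  expect_error(burden_config(alpha = 1.2), "alpha")
})
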