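test_that("one-sided Fisher p equals the hypergeometric tail sum", {
  expect_equal(fisher_one_sided(0, 10, 0, 10), 1.0)
  expect_equal(fisher_one_sided(22, 633, 2, 1609),
               brute_fisher_tail(22, 633, 2, 1609))
  expect_equal(fisher_one_sided(3, 652, 0, 1611),
               brute_fisher_tail(3, 652, 0, 1611))
  expect_error(fisher_one_sided(-1, 5, 2, 3), "domain error")
  expect_error(fisher_one_sided(1.5, 5, 2, 3), "domain error")
})

test_that("fisher agrees with stats::fisher.test's greater alternative", {
  set.seed(21)
  for (i in 1:50) {
    cells <- rmultinom(1, sample(10:80, 1), c(0.1, 0.3, 0.2, 0.4))[, 1]
    a <- cells[1]; b <- cells[2]; c_ <- cells[3]; d <- cells[4]
    ref <- stats::fisher.test(matrix(c(a, c_, b, d), 2),
                              alternative = "greater")$p.value
    expect_equal(fisher_one_sided(a, b, c_, d), ref, tolerance = 1e-12)
  }
})

test_that("the tail probability is non-increasing in the observed count", {
  # fixed margins: shift one carrier from controls to cases
  n1 <- 30; n2 <- 60; K <- 12
  p <- vapply(0:K, function(a)
    fisher_one_sided(a, n1 - a, K - a, n2 - (K - a)), numeric(1))
  expect_true(all(diff(p) <= 1e-12))
})

test_that("odds ratios and Woolf intervals match the published tables", {
  # internal controls
  r <- odds_ratio_ci(22, 633, 2, 1609)
  expect_equal(round(r$odds_ratio, 2), 27.96)
  expect_equal(round(r$ci_low, 2), 6.56)
  expect_equal(round(r$ci_high, 1), 119.3)
  r <- odds_ratio_ci(16, 639, 5, 1606)
  expect_equal(round(c(r$odds_ratio, r$ci_low, r$ci_high), 2),
               c(8.04, 2.93, 22.05))
  r <- odds_ratio_ci(6, 649, 1, 1610)
  expect_equal(round(c(r$odds_ratio, r$ci_low, r$ci_high), 2),
               c(14.88, 1.79, 123.88))
  # gnomAD replication
  r <- odds_ratio_ci(22, 633, 76, 21308)
  expect_equal(round(c(r$odds_ratio, r$ci_low, r$ci_high), 2),
               c(9.74, 6.02, 15.76))
  r <- odds_ratio_ci(3, 652, 16, 21368)
  expect_equal(round(c(r$odds_ratio, r$ci_low, r$ci_high), 2),
               c(6.14, 1.79, 21.14))
})

test_that("degenerate tables use the documented sentinel conventions", {
  r <- odds_ratio_ci(4, 651, 0, 1611)
  expect_identical(r$odds_ratio, Inf)
  expect_true(is.na(r$ci_low) && is.na(r$ci_high))
  r0 <- odds_ratio_ci(0, 655, 3, 1608)
  expect_identical(r0$odds_ratio, 0)
  expect_true(is.na(odds_ratio_ci(0, 655, 0, 1611)$odds_ratio))
})

test_that("the Woolf interval is log-symmetric, covers the point estimate and tightens", {
  r <- odds_ratio_ci(1, 1, 1, 1)
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$ci_low * r$ci_high, 1, tolerance = 1e-12)
  set.seed(22)
  for (i in 1:30) {
    cells <- sample(1:50, 4, TRUE)
    r <- do.call(odds_ratio_ci, as.list(cells))
    expect_true(r$ci_low <= r$odds_ratio && r$odds_ratio <= r$ci_high)
    r10 <- do.call(odds_ratio_ci, as.list(cells * 10))
    expect_equal(r10$odds_ratio, r$odds_ratio)
    expect_true(log(r10$ci_high / r10$ci_low) <
                  log(r$ci_high / r$ci_low))
  }
})

test_that("carrier sets use woman-level semantics across genes", {
  subjects <- make_subjects(3, 1)
  # case_001 has two BRCA2 variants; case_002 has BRCA2 + CHEK2
  calls <- rbind(
    make_variants(1, sample_id = "case_001", cdna_change = "c.1delA"),
    make_variants(1, sample_id = "case_001", cdna_change = "c.2delA"),
    make_variants(1, sample_id = "case_002"),
    make_variants(1, sample_id = "case_002", gene = "CHEK2",
                  transcript = "NM_007194", cdna_change = "c.401_402del"))
  classified <- classify_variants(calls, empty_clinvar())
  carr <- carriers_by_gene(classified, subjects)
  expect_equal(carr$BRCA2, c("case_001", "case_002"))
  expect_equal(carr$CHEK2, "case_002")
  expect_equal(carriers_by_gene(classified[0, ], subjects),
               stats::setNames(list(), character(0)))
  mg <- multi_gene_carriers(carr)
  expect_equal(mg$subject_id, "case_002")
  expect_equal(mg$genes, "BRCA2,CHEK2")
})

test_that("multi-gene carriers equal a pairwise-intersection oracle", {
  set.seed(23)
  for (i in 1:20) {
    sets <- lapply(1:4, function(j)
      sample(sprintf("s%02d", 1:30), sample(0:12, 1)))
    names(sets) <- c("G1", "G2", "G3", "G4")
    oracle <- sort(unique(unlist(lapply(combn(4, 2, simplify = FALSE),
      function(p) intersect(sets[[p[1]]], sets[[p[2]]])))))
    expect_equal(multi_gene_carriers(sets)$subject_id, oracle)
  }
  expect_equal(nrow(multi_gene_carriers(list(A = "x", B = "y"))), 0)
})

test_that("overall carrier rate is the woman-level union over genes", {
  subjects <- make_subjects(10, 5)
  carr <- list(BRCA2 = c("case_001", "case_002"),
               CHEK2 = c("case_002", "case_003"))
  r <- overall_carrier_rate(subjects, carr)
  expect_equal(as.numeric(r), 3 / 10)
  expect_equal(attr(r, "n_carriers"), 3)
  expect_equal(as.numeric(overall_carrier_rate(subjects, list())), 0)
  # brute-force union scan oracle on random sets
  set.seed(24)
  ids <- subjects$subject_id[subjects$status == "case"]
  for (i in 1:20) {
    sets <- lapply(1:3, function(j) sample(ids, sample(0:8, 1)))
    brute <- sum(vapply(ids, function(s)
      any(vapply(sets, function(g) s %in% g, logical(1))), logical(1)))
    expect_equal(attr(overall_carrier_rate(subjects, sets), "n_carriers"),
                 brute)
  }
})

test_that("case-only tables stratify cases, drop unknowns and orient exposure", {
  s <- validate_subjects(data.frame(
    subject_id = sprintf("c%02d", 1:10),
    status = "case",
    age = c(35, 36, 37, 45, 46, 47, 48, 55, NA, 44),
    er_status = "unknown", grade = "unknown",
    fh_first_degree = c(rep("no", 8), "unknown", "no"),
    fh_any = c(rep(c("yes", "no"), 4), "unknown", "no"),
    stringsAsFactors = FALSE))
  carr <- list(BRCA2 = c("c01", "c04"))
  expect_message(
    r <- case_only_burden(s, carr, "age_group", "BRCA2"),
    "2 case")                       # ages 55 and NA fall outside both strata
  expect_equal(c(r$a, r$b, r$c, r$d), c(1, 2, 1, 4))
  expect_equal(r$n_excluded, 2)
  r2 <- suppressMessages(case_only_burden(s, carr, "fh_any", "BRCA2"))
  expect_equal(r2$a + r2$b, sum(s$fh_any == "yes"))
  # identical carrier fractions in both strata give OR 1
  s3 <- make_subjects(8, 0, age = c(35, 35, 35, 35, 45, 45, 45, 45))
  r3 <- case_only_burden(s3, list(G = c("case_001", "case_005")),
                         "age_group", "G")
  expect_equal(r3$odds_ratio, 1)
})

test_that("gene_burden composes counts, OR and p against internal controls", {
  fx <- fixture_paper_counts()
  carr <- carriers_by_gene(fx$classified, fx$subjects)
  r <- gene_burden(fx$subjects, carr, "BRCA2")
  expect_equal(c(r$a, r$b, r$c, r$d), c(22, 633, 2, 1609))
  expect_equal(r$p_one_sided, brute_fisher_tail(22, 633, 2, 1609))
  expect_error(gene_burden(fx$subjects, carr, "ATM"), "no carrier set")
})

test_that("burden_scan covers every panel gene and both control arms", {
  fx <- fixture_paper_counts()
  ex <- validate_external_controls(data.frame(
    cohort_name = "gnomAD_NFE", n_total = 21384,
    gene = c("BRCA2", "CHEK2", "PALB2", "BRCA1", "TP53"),
    carrier_count = c(76, 144, 22, 81, 16)))
  scan <- burden_scan(fx$classified, fx$subjects, external = ex)
  expect_equal(nrow(scan), 10)
  ext <- scan[scan$comparison == "gnomAD_NFE", ]
  expect_equal(round(ext$odds_ratio[ext$gene == "CHEK2"], 2), 3.69)
  expect_equal(round(ext$odds_ratio[ext$gene == "BRCA1"], 2), 1.62)
})
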