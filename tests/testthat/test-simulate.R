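flat_config <- function(freq = 0.05, or = 3, n_cases = 120, n_controls = 240,
                        ...) {
  genes <- c("BRCA2", "CHEK2", "PALB2", "BRCA1", "TP53")
  simulation_config(
    n_cases = n_cases, n_controls = n_controls,
    control_carrier_freq = stats::setNames(rep(freq, 5), genes),
    odds_ratio = stats::setNames(rep(or, 5), genes), ...)
}

test_that("identical seeds give byte-identical output files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- flat_config(artifact_rate = 0.1, seed = 17L)
  simulate_cohort(cfg, dir = d1)
  simulate_cohort(cfg, dir = d2)
  for (f in c("subjects.csv", "variants.tsv", "clinvar.tsv", "truth.tsv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  d3 <- withr::local_tempdir()
  cfg2 <- flat_config(artifact_rate = 0.1, seed = 18L)
  simulate_cohort(cfg2, dir = d3)
  expect_false(identical(readLines(file.path(d1, "variants.tsv")),
                         readLines(file.path(d3, "variants.tsv"))))
})

test_that("zero carrier frequencies and zero planting rates give an empty table", {
  genes <- c("BRCA2", "CHEK2", "PALB2", "BRCA1", "TP53")
  cfg <- simulation_config(
    n_cases = 50, n_controls = 50,
    control_carrier_freq = stats::setNames(rep(0, 5), genes),
    odds_ratio = stats::setNames(rep(1, 5), genes),
    artifact_rate = 0, vus_rate = 0, benign_rate = 0, synonymous_rate = 0,
    seed = 2L)
  sim <- simulate_cohort(cfg)
  expect_equal(nrow(sim$variants), 0)
  expect_equal(nrow(sim$subjects), 100)
})

test_that("the generator's files round-trip into identical records", {
  cfg <- flat_config(artifact_rate = 0.05, seed = 19L, n_cases = 300,
                     n_controls = 300)
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(cfg, dir = dir)
  expect_gte(nrow(sim$variants), 100)
  back <- read_variant_table(sim$paths$variants)
  expect_equal(nrow(back), nrow(sim$variants))
  for (col in names(sim$variants))
    expect_equal(back[[col]], sim$variants[[col]], info = col)
})

test_that("classification recovers every planted class when nothing fails QC", {
  cfg <- flat_config(artifact_rate = 0, seed = 23L, n_cases = 200,
                     n_controls = 200, vus_rate = 0.05, benign_rate = 0.05,
                     synonymous_rate = 0.05)
  sim <- simulate_cohort(cfg)
  qc <- apply_qc(sim$variants)
  expect_true(all(qc$passed))
  classified <- classify_variants(sim$variants, sim$clinvar)
  expect_identical(classified$verdict, sim$truth$variant_truth$true_class)
  # and the per-gene pathogenic tallies equal the planted carrier counts
  carr <- carriers_by_gene(classified, sim$subjects)
  cm <- sim$truth$carrier_matrix
  for (g in cfg$genes)
    expect_equal(length(carr[[g]]), sum(cm[[g]]), info = g)
})

test_that("planted artifact calls and only those fail QC, near the configured rate", {
  cfg <- flat_config(artifact_rate = 0.1, seed = 29L, n_cases = 400,
                     n_controls = 800)
  sim <- simulate_cohort(cfg)
  qc <- apply_qc(sim$variants)
  expect_identical(!qc$passed, sim$truth$variant_truth$is_artifact)
  n <- nrow(qc)
  frac <- mean(!qc$passed)
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / n))
})

test_that("case carrier frequencies follow the odds transform", {
  cfg <- flat_config(freq = 0.1, or = 4)
  odds1 <- 4 * 0.1 / 0.9
  expect_equal(unname(cfg$case_carrier_freq["BRCA2"]), odds1 / (1 + odds1))
  # realized control frequency within binomial error of the configured one
  big <- flat_config(freq = 0.1, or = 4, n_cases = 200, n_controls = 2000,
                     seed = 37L)
  sim <- simulate_cohort(big)
  cm <- sim$truth$carrier_matrix
  ctrl <- cm[cm$status == "control", ]
  for (g in big$genes) {
    p_hat <- mean(ctrl[[g]])
    expect_lt(abs(p_hat - 0.1), 4 * sqrt(0.1 * 0.9 / nrow(ctrl)))
  }
})

test_that("inconsistent simulation configs are refused", {
  genes <- c("BRCA2", "CHEK2", "PALB2", "BRCA1", "TP53")
  expect_error(simulation_config(
    control_carrier_freq = stats::setNames(rep(1.2, 5), genes)),
    "config error")
  expect_error(simulation_config(
    control_carrier_freq = c(BRCA2 = 0.01)), "missing gene")
  expect_error(simulation_config(vus_rate = -0.1), "probabilities")
})
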