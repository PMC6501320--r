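#' Configuration of a synthetic DCIS case-control cohort
#'
#' Full parameterization of the generator: arm sizes, per-gene control
#' carrier frequencies and carrier odds ratios (case carrier probabilities
#' follow through the odds transform), the fraction of planted pathogenic
#' variants that are "known" (present in the emitted ClinVar fixture), a
#' conditional-probability covariate model (age mixture, ER and grade
#' marginals, family-history rates, and carrier-covariate associations:
#' carriers skew ER-positive and high/intermediate grade, one designated
#' gene's carriers skew under 40), an artifact model (each emitted call is a
#' QC-failing artifact with probability `artifact_rate`, split evenly over
#' failure modes), and planting rates for non-pathogenic variants.
#'
#' Defaults mirror the study conditions: 655 cases / 1611 controls; BRCA2,
#' CHEK2 and PALB2 at their internal control carrier frequencies (2/1611,
#' 5/1611, 1/1611) with internal odds ratios (27.96, 8.04, 14.88); BRCA1 and
#' TP53 — for which the internal control arm had no carriers, so a Bernoulli
#' model cannot be parameterized from it — at their gnomAD control
#' frequencies (81/21384, 16/21384) with the external-replication odds ratios
#' (1.62, 6.14), which reproduce the observed case counts (4 and 3 of 655) in
#' expectation. Case age is drawn as integer years in 25-49 with under-40
#' mass 100/655.
#'
#' @param n_cases,n_controls Arm sizes.
#' @param genes Panel gene symbols.
#' @param control_carrier_freq Named per-gene control carrier probability.
#' @param odds_ratio Named per-gene carrier odds ratio (cases vs controls).
#' @param known_fraction Named per-gene probability that a planted pathogenic
#'   variant is in the ClinVar fixture.
#' @param p_under40 Probability a case is under 40.
#' @param er_case,grade_case Baseline case ER / grade marginals (named,
#'   summing to 1).
#' @param er_carrier,grade_carrier ER / grade distributions for carriers.
#' @param young_gene Gene whose carriers skew young.
#' @param p_under40_young_gene P(under 40) for carriers of `young_gene`.
#' @param fh_any_case,fh_any_carrier P(family history, any relative) for
#'   non-carrier and carrier cases; controls have none by study design.
#' @param fh_first_given_any P(first-degree history | any history).
#' @param artifact_rate Probability an emitted call is a QC-failing artifact.
#' @param vus_rate,benign_rate,synonymous_rate Per-subject planting rates for
#'   a novel missense/in-frame VUS, a ClinVar benign/conflicting variant, and
#'   a novel synonymous (not-counted) variant.
#' @param ar_beta Two shape parameters of the Beta allelic-ratio model for
#'   clean heterozygous calls.
#' @param seed Integer RNG seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(
    n_cases = 655, n_controls = 1611,
    genes = c("BRCA2", "CHEK2", "PALB2", "BRCA1", "TP53"),
    control_carrier_freq = c(BRCA2 = 2 / 1611, CHEK2 = 5 / 1611,
                             PALB2 = 1 / 1611, BRCA1 = 81 / 21384,
                             TP53 = 16 / 21384),
    odds_ratio = c(BRCA2 = 27.96, CHEK2 = 8.04, PALB2 = 14.88,
                   BRCA1 = 1.62, TP53 = 6.14),
    known_fraction = c(BRCA2 = 21 / 22, CHEK2 = 13 / 16, PALB2 = 3 / 6,
                       BRCA1 = 1 / 4, TP53 = 2 / 3),
    p_under40 = 100 / 655,
    er_case = c(positive = 397 / 655, negative = 89 / 655,
                unknown = 169 / 655),
    grade_case = c(high = 417 / 655, intermediate = 168 / 655,
                   low = 54 / 655, unknown = 16 / 655),
    er_carrier = c(positive = 0.80, negative = 0.08, unknown = 0.12),
    grade_carrier = c(high = 0.70, intermediate = 0.25, low = 0.03,
                      unknown = 0.02),
    young_gene = "BRCA2",
    p_under40_young_gene = 9 / 22,
    fh_any_case = 0.42, fh_any_carrier = 0.65,
    fh_first_given_any = 0.5,
    artifact_rate = 0.05,
    vus_rate = 0.02, benign_rate = 0.01, synonymous_rate = 0.02,
    ar_beta = c(20, 20),
    seed = 1L) {
  stopifnot(n_cases >= 1, n_controls >= 1, length(genes) >= 1)
  genes <- toupper(genes)
  pick <- function(x, nm) {
    if (is.null(names(x))) names(x) <- genes
    miss <- setdiff(genes, names(x))
    if (length(miss))
      stop("config error: '", nm, "' missing gene(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    x[genes]
  }
  control_carrier_freq <- pick(control_carrier_freq, "control_carrier_freq")
  odds_ratio <- pick(odds_ratio, "odds_ratio")
  known_fraction <- pick(known_fraction, "known_fraction")
  probs <- c(control_carrier_freq, known_fraction, p_under40,
             p_under40_young_gene, fh_any_case, fh_any_carrier,
             fh_first_given_any, artifact_rate, vus_rate, benign_rate,
             synonymous_rate, er_case, grade_case, er_carrier, grade_carrier)
  if (any(probs < 0 | probs > 1))
    stop("config error: all probabilities must lie in [0, 1]", call. = FALSE)
  if (any(control_carrier_freq >= 1))
    stop("config error: control carrier frequency must be < 1", call. = FALSE)
  odds1 <- odds_ratio * control_carrier_freq / (1 - control_carrier_freq)
  p1 <- odds1 / (1 + odds1)
  if (any(p1 >= 1))
    stop("config error: case carrier probability >= 1 under the odds ",
         "transform", call. = FALSE)
  structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    genes = genes, control_carrier_freq = control_carrier_freq,
    odds_ratio = odds_ratio, case_carrier_freq = p1,
    known_fraction = known_fraction,
    p_under40 = p_under40, er_case = er_case, grade_case = grade_case,
    er_carrier = er_carrier, grade_carrier = grade_carrier,
    young_gene = young_gene, p_under40_young_gene = p_under40_young_gene,
    fh_any_case = fh_any_case, fh_any_carrier = fh_any_carrier,
    fh_first_given_any = fh_first_given_any,
    artifact_rate = artifact_rate, vus_rate = vus_rate,
    benign_rate = benign_rate, synonymous_rate = synonymous_rate,
    ar_beta = ar_beta, seed = as.integer(seed)
  ), class = "simulation_config")
}

# Variant template library. Each planted variant is drawn from here; "known"
# roles appear in the emitted ClinVar fixture with the stated label.
.variant_templates <- function() {
  tx <- c(BRCA2 = "NM_000059", BRCA1 = "NM_007294", CHEK2 = "NM_007194",
          PALB2 = "NM_024675", TP53 = "NM_000546")
  row <- function(gene, exon, cdna, prot, fc, sd = NA_integer_,
                  last = FALSE, role, label = NA_character_) {
    data.frame(gene = gene, transcript = tx[[gene]], exon = exon,
               cdna_change = cdna, protein_change = prot,
               functional_class = fc, splice_distance = sd,
               is_last_exon = last, role = role, clinvar_label = label,
               stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    # known pathogenic (ClinVar: pathogenic)
    row("BRCA2", 20L, "c.8575delC", "p.Q2859fs", "frameshift_indel",
        role = "known_pathogenic", label = "pathogenic"),
    row("BRCA2", 25L, "c.C9382T", "p.R3128X", "stopgain",
        role = "known_pathogenic", label = "pathogenic"),
    row("BRCA2", 11L, "c.6275_6276del", "p.L2092fs", "frameshift_indel",
        role = "known_pathogenic", label = "pathogenic"),
    row("CHEK2", 10L, "c.1100delC", "p.T367fs", "frameshift_indel",
        role = "known_pathogenic", label = "pathogenic"),
    row("PALB2", 10L, "c.3113G>A", "p.W1038X", "stopgain",
        role = "known_pathogenic", label = "pathogenic"),
    row("PALB2", 4L, "c.1592delT", "p.L531fs", "frameshift_indel",
        role = "known_pathogenic", label = "pathogenic"),
    row("BRCA1", 12L, "c.C4327T", "p.R1443X", "stopgain",
        role = "known_pathogenic", label = "pathogenic"),
    row("TP53", 6L, "c.C637T", "p.R213X", "stopgain",
        role = "known_pathogenic", label = "pathogenic"),
    # known pathogenic missense: exercises ClinVar precedence over the rule
    row("TP53", 10L, "c.G1010A", "p.R337H", "missense",
        role = "known_pathogenic", label = "pathogenic"),
    # novel pathogenic (absent from the fixture)
    row("BRCA2", 11L, "c.5754dupT", "p.H1918fs", "frameshift_indel",
        role = "novel_pathogenic"),
    row("BRCA2", 27L, "c.9925dupA", "p.T3309fs", "frameshift_indel",
        last = TRUE, role = "novel_pathogenic"),
    row("CHEK2", 3L, "c.401_402del", "p.E134fs", "frameshift_indel",
        role = "novel_pathogenic"),
    row("CHEK2", NA_integer_, "c.592+2T>C", NA_character_, "intronic",
        sd = 2L, role = "novel_pathogenic"),
    row("PALB2", NA_integer_, "c.2834+1G>A", NA_character_, "intronic",
        sd = 1L, role = "novel_pathogenic"),
    row("PALB2", 5L, "c.1685delA", "p.K562fs", "frameshift_indel",
        role = "novel_pathogenic"),
    row("BRCA1", 11L, "c.2338delC", "p.L780fs", "frameshift_indel",
        role = "novel_pathogenic"),
    row("TP53", 4L, "c.G272A", "p.W91X", "stopgain",
        role = "novel_pathogenic"),
    # novel VUS
    row("BRCA2", 11L, "c.G5000A", "p.R1667Q", "missense", role = "vus"),
    row("CHEK2", 11L, "c.1240_1242del", "p.E414del", "inframe_indel",
        role = "vus"),
    row("PALB2", 6L, "c.G2120A", "p.S707N", "missense", role = "vus"),
    row("BRCA1", 10L, "c.G3119A", "p.S1040N", "missense", role = "vus"),
    row("TP53", 10L, "c.G1054T", "p.D352Y", "missense", role = "vus"),
    # known benign / conflicting
    row("BRCA2", 11L, "c.A3396G", "p.K1132K", "synonymous",
        role = "known_other", label = "benign"),
    row("BRCA1", 13L, "c.T4308C", "p.S1436S", "synonymous",
        role = "known_other", label = "benign"),
    row("CHEK2", 4L, "c.T470C", "p.I157T", "missense",
        role = "known_other", label = "conflicting"),
    # novel not-counted
    row("BRCA2", 14L, "c.A7242G", "p.S2414S", "synonymous",
        role = "synonymous"),
    row("CHEK2", NA_integer_, "c.846+15C>T", NA_character_, "intronic",
        sd = 15L, role = "synonymous"),
    row("PALB2", 13L, "c.C3300T", "p.T1100T", "synonymous",
        role = "synonymous"),
    row("BRCA1", 9L, "c.A2082G", "p.S694S", "synonymous",
        role = "synonymous"),
    row("TP53", 3L, "c.C216T", "p.V72V", "synonymous", role = "synonymous")
  ))
}

.sample_cat <- function(n, probs) {
  names(probs)[1L + findInterval(stats::runif(n), cumsum(probs) / sum(probs))]
}

# Clean QC metrics: clamped away from the filter thresholds so that planted
# biology is never removed by QC.
.clean_metrics <- function(n, ar_beta) {
  data.frame(
    read_depth = 50 + stats::rnbinom(n, size = 10, mu = 250),
    variant_quality = round(stats::runif(n, 100, 3000), 1),
    genotype_quality = round(stats::runif(n, 40, 99)),
    allelic_ratio = round(pmin(0.97, pmax(0.30,
      stats::rbeta(n, ar_beta[1], ar_beta[2]))), 3)
  )
}

.artifact_metrics <- function(n, config_qc = burden_config()) {
  m <- .clean_metrics(n, c(20, 20))
  mode <- sample(qc_reasons(), n, replace = TRUE)
  dp <- m$read_depth; vq <- m$variant_quality
  gq <- m$genotype_quality; ar <- m$allelic_ratio
  dp[mode == "low_depth"] <- sample(0:9, sum(mode == "low_depth"), TRUE)
  vq[mode == "low_quality"] <- round(stats::runif(sum(mode == "low_quality"),
                                                  0, 19.9), 1)
  gq[mode == "low_gq"] <- sample(0:19, sum(mode == "low_gq"), TRUE)
  i <- mode == "low_ar_absolute"
  ar[i] <- round(stats::runif(sum(i), 0, 0.19), 3)
  i <- mode == "low_ar_conditional"
  ar[i] <- round(stats::runif(sum(i), 0.20, 0.29), 3)
  dp[i] <- sample(10:49, sum(i), TRUE)
  data.frame(read_depth = dp, variant_quality = vq, genotype_quality = gq,
             allelic_ratio = ar, artifact_mode = mode)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws per-subject carrier status per gene (Bernoulli at the control
#' frequency for controls and at the odds-transformed case frequency for
#' cases), covariates from the conditional-probability model, planted variant
#' calls from the template library (known pathogenic templates appear in the
#' emitted ClinVar fixture), planted VUS / benign / synonymous calls, and
#' injected QC-failing artifact calls. Everything is reproducible from
#' `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param dir Optional directory; when given, `subjects.csv`, `variants.tsv`,
#'   `clinvar.tsv` and `truth.tsv` are written there.
#' @return An object of class `synthetic_cohort`: list with `subjects`,
#'   `variants`, `clinvar`, `truth` (list of `carrier_matrix` and
#'   `variant_truth`), `config`, and `paths` when `dir` was given.
#' @export
simulate_cohort <- function(config = simulation_config(), dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  genes <- config$genes
  n_cases <- config$n_cases; n_controls <- config$n_controls
  n <- n_cases + n_controls
  ids <- c(sprintf("case_%04d", seq_len(n_cases)),
           sprintf("control_%04d", seq_len(n_controls)))
  status <- rep(c("case", "control"), c(n_cases, n_controls))

  # carrier status per gene
  carrier <- sapply(genes, function(g) {
    p <- ifelse(status == "case", config$case_carrier_freq[[g]],
                config$control_carrier_freq[[g]])
    stats::runif(n) < p
  })
  carrier <- matrix(carrier, nrow = n, dimnames = list(NULL, genes))
  any_carrier <- rowSums(carrier) > 0

  # covariates
  is_case <- status == "case"
  p_young <- ifelse(is_case,
                    ifelse(config$young_gene %in% genes &
                             carrier[, config$young_gene],
                           config$p_under40_young_gene, config$p_under40),
                    0)
  young <- stats::runif(n) < p_young
  age <- integer(n)
  age[is_case & young] <- sample(25:39, sum(is_case & young), TRUE)
  age[is_case & !young] <- sample(40:49, sum(is_case & !young), TRUE)
  age[!is_case] <- pmin(85L, pmax(30L,
    as.integer(round(stats::rnorm(sum(!is_case), 52, 9)))))

  er <- rep("unknown", n)
  grade <- rep("unknown", n)
  er[is_case & any_carrier] <- .sample_cat(sum(is_case & any_carrier),
                                           config$er_carrier)
  er[is_case & !any_carrier] <- .sample_cat(sum(is_case & !any_carrier),
                                            config$er_case)
  grade[is_case & any_carrier] <- .sample_cat(sum(is_case & any_carrier),
                                              config$grade_carrier)
  grade[is_case & !any_carrier] <- .sample_cat(sum(is_case & !any_carrier),
                                               config$grade_case)

  # family history: controls are screened to have none by study design
  p_fh <- ifelse(is_case,
                 ifelse(any_carrier, config$fh_any_carrier,
                        config$fh_any_case), 0)
  fh_any <- ifelse(stats::runif(n) < p_fh, "yes", "no")
  fh_first <- ifelse(fh_any == "yes" &
                       stats::runif(n) < config$fh_first_given_any,
                     "yes", "no")

  subjects <- data.frame(
    subject_id = ids, status = status, age = age, er_status = er,
    grade = grade, fh_first_degree = fh_first, fh_any = fh_any,
    stringsAsFactors = FALSE)
  subjects$age_group <- age_group(subjects$age)

  # planted variant calls
  tpl <- .variant_templates()
  tpl <- tpl[tpl$gene %in% genes, , drop = FALSE]
  take <- function(role_set, g, n_draw) {
    pool <- which(tpl$role %in% role_set & tpl$gene == g)
    if (!length(pool)) stop("no template for ", g, " role ",
                            paste(role_set, collapse = "/"), call. = FALSE)
    pool[sample.int(length(pool), n_draw, replace = TRUE)]
  }
  calls <- list()
  add_call <- function(sample_id, tpl_idx, true_class, artifact = FALSE) {
    t <- tpl[tpl_idx, , drop = FALSE]
    t$sample_id <- sample_id
    t$true_class <- true_class
    t$is_artifact <- artifact
    calls[[length(calls) + 1L]] <<- t
  }

  for (g in genes) {
    idx <- which(carrier[, g])
    if (!length(idx)) next
    known <- stats::runif(length(idx)) < config$known_fraction[[g]]
    if (any(known))
      add_call(ids[idx[known]], take("known_pathogenic", g, sum(known)),
               "pathogenic")
    if (any(!known))
      add_call(ids[idx[!known]], take("novel_pathogenic", g, sum(!known)),
               "pathogenic")
  }

  plant_extra <- function(rate, role, true_class) {
    hit <- which(stats::runif(n) < rate)
    if (!length(hit)) return(invisible())
    pool <- which(tpl$role == role)
    pick <- pool[sample.int(length(pool), length(hit), replace = TRUE)]
    cls <- if (is.null(true_class)) tpl$clinvar_label[pick] else true_class
    add_call(ids[hit], pick, cls)
  }
  plant_extra(config$vus_rate, "vus", "vus")
  plant_extra(config$benign_rate, "known_other", NULL)
  plant_extra(config$synonymous_rate, "synonymous", "not_counted")

  if (length(calls)) {
    variants <- do.call(rbind, calls)
    metrics <- .clean_metrics(nrow(variants), config$ar_beta)
    variants <- cbind(variants, metrics)
    variants$artifact_mode <- NA_character_
  } else {
    variants <- cbind(tpl[0, , drop = FALSE],
                      data.frame(sample_id = character(0),
                                 true_class = character(0),
                                 is_artifact = logical(0),
                                 read_depth = numeric(0),
                                 variant_quality = numeric(0),
                                 genotype_quality = numeric(0),
                                 allelic_ratio = numeric(0),
                                 artifact_mode = character(0)))
  }
  n_real <- nrow(variants)

  # artifacts: each emitted call is an artifact with prob artifact_rate
  if (config$artifact_rate > 0 && n_real > 0) {
    n_art <- stats::rnbinom(1, size = n_real, prob = 1 - config$artifact_rate)
    if (n_art > 0) {
      pool <- which(tpl$role %in% c("vus", "synonymous"))
      pick <- pool[sample.int(length(pool), n_art, replace = TRUE)]
      art <- tpl[pick, , drop = FALSE]
      art$sample_id <- sample(ids, n_art, replace = TRUE)
      art$true_class <- "artifact"
      art$is_artifact <- TRUE
      art <- cbind(art, .artifact_metrics(n_art))
      variants <- rbind(variants, art)
    }
  }

  if (nrow(variants)) {
    variants <- variants[sample.int(nrow(variants)), , drop = FALSE]
    rownames(variants) <- NULL
  }
  variant_truth <- variants[, intersect(
    c("sample_id", "gene", "cdna_change", "true_class", "is_artifact",
      "artifact_mode"), names(variants)), drop = FALSE]
  variants <- variants[, .variant_cols, drop = FALSE]

  known_tpl <- tpl[!is.na(tpl$clinvar_label), , drop = FALSE]
  clinvar <- validate_clinvar(data.frame(
    gene = known_tpl$gene, transcript = known_tpl$transcript,
    cdna_change = known_tpl$cdna_change, label = known_tpl$clinvar_label,
    stringsAsFactors = FALSE))

  truth <- list(
    carrier_matrix = data.frame(subject_id = ids, status = status,
                                carrier, stringsAsFactors = FALSE),
    variant_truth = variant_truth)

  out <- list(subjects = subjects, variants = variants, clinvar = clinvar,
              truth = truth, config = config)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      subjects = file.path(dir, "subjects.csv"),
      variants = file.path(dir, "variants.tsv"),
      clinvar = file.path(dir, "clinvar.tsv"),
      truth = file.path(dir, "truth.tsv"))
    write_subjects(subjects, paths$subjects)
    write_variant_table(variants, paths$variants)
    write_clinvar(clinvar, paths$clinvar)
    utils::write.table(variant_truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    out$paths <- paths
  }
  structure(out, class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d cases / %d controls, %d variant calls\n",
              x$config$n_cases, x$config$n_controls, nrow(x$variants)))
  cm <- x$truth$carrier_matrix
  for (g in x$config$genes)
    cat(sprintf("  %-6s true carriers: %d cases, %d controls\n", g,
                sum(cm[[g]] & cm$status == "case"),
                sum(cm[[g]] & cm$status == "control")))
  cat("  artifact calls:", sum(x$truth$variant_truth$is_artifact), "\n")
  invisible(x)
}
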