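#' Run the full burden pipeline
#'
#' Orchestrates the stages in their analysis order — read/validate, QC
#' filter, classify, burden testing and report tables — with a machine-
#' readable run manifest. Equivalent to invoking [apply_qc()],
#' [classify_variants()], [burden_scan()], [case_only_burden()] and
#' [frequency_tables()] by hand in that order.
#'
#' Inputs may be file paths (variant TSV, subject CSV, ClinVar TSV, external
#' control TSV) or the corresponding validated in-memory objects. When
#' `out_dir` is given, every stage output is written there as TSV together
#' with `manifest.json` and a plain-text log; on a stage failure the manifest
#' is still written, with the failed stage named, before the error
#' propagates.
#'
#' @param variants Variant table path or `data.frame`.
#' @param subjects Subject table path or `data.frame`.
#' @param clinvar ClinVar table path or `clinvar_table`.
#' @param external Optional external-control table path or
#'   `external_controls`.
#' @param config A [burden_config()].
#' @param out_dir Optional output directory.
#' @return An object of class `burden_pipeline`: list with `qc` (all QC
#'   outcomes), `qc_summary`, `classified` (QC-passing calls with verdicts),
#'   `burden` (a `burden_scan`), `case_only` (data.frame over stratifiers x
#'   genes), `frequency` (a `frequency_table`), `overall_rate`,
#'   `multi_gene`, and `manifest`.
#' @export
run_pipeline <- function(variants, subjects, clinvar, external = NULL,
                         config = burden_config(), out_dir = NULL) {
  t0 <- Sys.time()
  log_lines <- character(0)
  note <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  digest_of <- function(x) {
    if (is.character(x) && length(x) == 1 && file.exists(x))
      unname(tools::md5sum(x)) else "in-memory"
  }
  manifest <- list(
    tool = "dcisburden",
    version = as.character(utils::packageVersion("dcisburden")),
    config = unclass(config),
    seed = config$seed,
    inputs = list(variants = digest_of(variants),
                  subjects = digest_of(subjects),
                  clinvar = digest_of(clinvar),
                  external = if (is.null(external)) NULL
                             else digest_of(external)),
    counts = list(), completed_stage = "none", failed_stage = NULL)
  finish_manifest <- function() {
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA,
                           null = "null")
      writeLines(log_lines, file.path(out_dir, "log.txt"))
    }
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$failed_stage <<- name
      finish_manifest()
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  # -- read ------------------------------------------------------------------
  res <- stage("read", {
    v <- if (is.character(variants)) read_variant_table(variants, config)
         else validate_variants(variants, config)
    s <- if (is.character(subjects)) read_subjects(subjects)
         else validate_subjects(subjects)
    cv <- if (is.character(clinvar)) read_clinvar(clinvar)
          else if (inherits(clinvar, "clinvar_table")) clinvar
          else validate_clinvar(clinvar)
    ex <- if (is.null(external)) NULL
          else if (is.character(external)) read_external_controls(external)
          else if (inherits(external, "external_controls")) external
          else validate_external_controls(external)
    list(v = v, s = s, cv = cv, ex = ex)
  })
  n_rejected <- nrow(attr(res$v, "rejected") %||% data.frame())
  manifest$counts$variants_read <- attr(res$v, "n_read") %||% nrow(res$v)
  manifest$counts$variants_rejected <- n_rejected
  manifest$counts$variants_accepted <- nrow(res$v)
  manifest$counts$subjects <- nrow(res$s)
  manifest$counts$n_cases <- sum(res$s$status == "case")
  manifest$counts$n_controls <- sum(res$s$status == "control")
  manifest$completed_stage <- "read"
  note("read: ", nrow(res$v), " variant calls accepted (",
       n_rejected, " rejected), ", nrow(res$s), " subjects")

  # -- qc --------------------------------------------------------------------
  qc <- stage("qc", apply_qc(res$v, config))
  qcs <- qc_summary(qc)
  passing <- qc[qc$passed, , drop = FALSE]
  manifest$counts$qc_passed <- qcs$n_passed
  manifest$counts$qc_failed <- qcs$n_failed
  manifest$counts$qc_by_reason <- as.list(qcs$by_reason)
  manifest$completed_stage <- "qc"
  note("qc: ", qcs$n_passed, " passed, ", qcs$n_failed, " failed")

  # -- classify --------------------------------------------------------------
  classified <- stage("classify", classify_variants(passing, res$cv))
  vt <- table(factor(classified$verdict,
                     levels = c("pathogenic", "vus", "benign", "conflicting",
                                "not_counted")))
  manifest$counts$verdicts <- as.list(vt)
  manifest$completed_stage <- "classify"
  note("classify: ", paste(names(vt), as.integer(vt), sep = "=",
                           collapse = ", "))

  # -- burden ----------------------------------------------------------------
  results <- stage("burden", {
    scan <- burden_scan(classified, res$s, external = res$ex,
                        config = config)
    carriers <- attr(scan, "carriers")
    co <- list()
    for (strat in c("age_group", "fh_first_degree", "fh_any"))
      for (g in config$panel_genes)
        co[[length(co) + 1L]] <- as.data.frame(suppressMessages(
          case_only_burden(res$s, carriers, strat, g, config$ci_level)))
    case_only <- do.call(rbind, co)
    freq <- frequency_tables(res$s, classified, genes = config$panel_genes)
    list(scan = scan, carriers = carriers, case_only = case_only,
         freq = freq,
         overall = overall_carrier_rate(res$s, carriers),
         multi = multi_gene_carriers(carriers))
  })
  manifest$counts$carriers_per_gene <- lapply(results$carriers, length)
  manifest$counts$overall_case_carriers <-
    attr(results$overall, "n_carriers")
  manifest$completed_stage <- "burden"
  note("burden: overall case carrier rate ",
       sprintf("%.1f%%", 100 * as.numeric(results$overall)))
  manifest$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.table(passing[, .variant_cols], file.path(out_dir, "filtered.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    utils::write.table(classified, file.path(out_dir, "classified.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    utils::write.table(as.data.frame(qcs), file.path(out_dir, "qc_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(results$scan),
                       file.path(out_dir, "burden.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    utils::write.table(results$case_only, file.path(out_dir, "case_only.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    utils::write.table(as.data.frame(results$freq),
                       file.path(out_dir, "frequency.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  }
  finish_manifest()

  structure(list(
    qc = qc, qc_summary = qcs, classified = classified,
    burden = results$scan, case_only = results$case_only,
    frequency = results$freq, overall_rate = results$overall,
    multi_gene = results$multi, manifest = manifest,
    config = config), class = "burden_pipeline")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.burden_pipeline <- function(x, ...) {
  cat("Burden pipeline run (", x$manifest$tool, " ",
      x$manifest$version, ")\n", sep = "")
  cat(sprintf("  %d/%d calls passed QC; %d cases, %d controls\n",
              x$manifest$counts$qc_passed, x$manifest$counts$variants_accepted,
              x$manifest$counts$n_cases, x$manifest$counts$n_controls))
  cat(sprintf("  overall case carrier rate: %.1f%% (%d/%d)\n",
              100 * as.numeric(x$overall_rate),
              attr(x$overall_rate, "n_carriers"),
              attr(x$overall_rate, "n_cases")))
  cat("\n")
  print(x$burden)
  invisible(x)
}
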