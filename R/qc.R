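#' Apply the variant quality filters
#'
#' Applies the five exclusion clauses to every call: read depth below
#' `depth_min`, variant quality below `quality_min`, genotype quality below
#' `gq_min`, allelic ratio below `ar_min_absolute` at any depth, and allelic
#' ratio below `ar_min_conditional` when read depth is below
#' `depth_conditional`. All comparisons are strict, so a value exactly at a
#' threshold passes. A missing depth/quality/GQ/allelic-ratio value fails with
#' the corresponding reason, since such a call cannot be assessed.
#'
#' @param calls A validated variant `data.frame` (see [read_variant_table()]).
#' @param config A [burden_config()] supplying the thresholds.
#' @return `calls` with five logical reason columns (`low_depth`,
#'   `low_quality`, `low_gq`, `low_ar_absolute`, `low_ar_conditional`), a
#'   collapsed `reasons` string and a logical `passed` column (`TRUE` iff no
#'   reason fired). Input order is preserved.
#' @examples
#' v <- data.frame(read_depth = c(9, 60), variant_quality = 50,
#'                 genotype_quality = 50, allelic_ratio = c(0.5, 0.25))
#' apply_qc(v)[, c("passed", "reasons")]
#' @export
apply_qc <- function(calls, config = burden_config()) {
  stopifnot(is.data.frame(calls))
  need <- c("read_depth", "variant_quality", "genotype_quality",
            "allelic_ratio")
  .check_header(calls, need, "apply_qc input")
  dp <- calls$read_depth
  vq <- calls$variant_quality
  gq <- calls$genotype_quality
  ar <- calls$allelic_ratio

  out <- calls
  out$low_depth <- is.na(dp) | dp < config$depth_min
  out$low_quality <- is.na(vq) | vq < config$quality_min
  out$low_gq <- is.na(gq) | gq < config$gq_min
  out$low_ar_absolute <- is.na(ar) | ar < config$ar_min_absolute
  out$low_ar_conditional <- !is.na(ar) & !is.na(dp) &
    ar < config$ar_min_conditional & dp < config$depth_conditional
  reason_mat <- as.matrix(out[, qc_reasons()])
  if (nrow(out)) {
    out$reasons <- apply(reason_mat, 1, function(r)
      paste(qc_reasons()[r], collapse = ";"))
    out$passed <- rowSums(reason_mat) == 0
  } else {
    out$reasons <- character(0)
    out$passed <- logical(0)
  }
  rownames(out) <- NULL
  out
}

#' @rdname apply_qc
#' @export
qc_reasons <- function() {
  c("low_depth", "low_quality", "low_gq", "low_ar_absolute",
    "low_ar_conditional")
}

#' Summarise QC outcomes
#'
#' Tabulates [apply_qc()] output: how many calls passed, how many failed each
#' clause (a call failing several clauses is attributed to each of them), and
#' how many failed more than one clause.
#'
#' @param outcomes Output of [apply_qc()].
#' @return An object of class `qc_summary`: a list with `n_total`, `n_passed`,
#'   `n_failed`, per-reason counts (`by_reason`) and `n_multiple`.
#' @export
qc_summary <- function(outcomes) {
  stopifnot(is.data.frame(outcomes), all(qc_reasons() %in% names(outcomes)),
            "passed" %in% names(outcomes))
  reason_mat <- as.matrix(outcomes[, qc_reasons(), drop = FALSE])
  n_fired <- rowSums(reason_mat)
  structure(list(
    n_total = nrow(outcomes),
    n_passed = sum(outcomes$passed),
    n_failed = sum(!outcomes$passed),
    by_reason = colSums(reason_mat),
    n_multiple = sum(n_fired > 1)
  ), class = "qc_summary")
}

#' @export
print.qc_summary <- function(x, ...) {
  cat(sprintf("QC summary: %d calls, %d passed, %d failed\n",
              x$n_total, x$n_passed, x$n_failed))
  for (r in names(x$by_reason))
    cat(sprintf("  %-18s %d\n", r, x$by_reason[[r]]))
  cat(sprintf("  %-18s %d\n", "multiple reasons", x$n_multiple))
  invisible(x)
}

#' @export
as.data.frame.qc_summary <- function(x, ...) {
  data.frame(metric = c("total", "passed", "failed", names(x$by_reason),
                        "multiple"),
             count = c(x$n_total, x$n_passed, x$n_failed,
                       unname(x$by_reason), x$n_multiple))
}
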