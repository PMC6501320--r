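#' One-sided Fisher's exact test for carrier enrichment
#'
#' Exact one-sided p-value for a 2x2 carrier-status x group table
#' \code{(a, b; c, d)} with `a` carriers among the first group (cases) and `c`
#' among the second (controls). Conditional on the margins, the carrier count
#' in the first group is hypergeometric; the p-value is the upper tail
#' P(X >= a), i.e. the probability of at least the observed enrichment of
#' carriers in the first group. The direction is fixed to enrichment because
#' the alternative of interest is an excess, not a deficit, of carriers in
#' cases.
#'
#' @param a,b,c,d Non-negative integer cell counts: first-group carriers,
#'   first-group non-carriers, second-group carriers, second-group
#'   non-carriers. Vectorized.
#' @return The one-sided p-value(s) in (0, 1].
#' @examples
#' fisher_one_sided(22, 633, 2, 1609)   # ~ 2e-10
#' fisher_one_sided(0, 10, 0, 10)       # 1: no carriers anywhere
#' @export
fisher_one_sided <- function(a, b, c, d) {
  cells <- cbind(a, b, c, d)
  if (!is.numeric(cells) || anyNA(cells) || any(cells < 0) ||
      any(cells != floor(cells)))
    stop("domain error: cells must be non-negative integers", call. = FALSE)
  # X ~ Hypergeometric(white = a + c carriers, black = b + d non-carriers,
  # drawn = a + b first-group subjects); upper tail at the observed a.
  stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

#' Odds ratio with Woolf (logit) confidence interval
#'
#' Point estimate \eqn{(a d)/(b c)} with the asymptotic log-scale interval
#' \eqn{\exp(\log OR \pm z \sqrt{1/a + 1/b + 1/c + 1/d})} (no continuity
#' correction). Degenerate tables use fixed conventions: the odds ratio is
#' `Inf` when there are first-group carriers but no second-group carriers
#' (c = 0, a > 0), `0` in the mirrored case, and `NA` (undefined) when there
#' are no carriers in either group; the interval is reported only when all
#' four cells are positive.
#'
#' @inheritParams fisher_one_sided
#' @param ci_level Confidence level (default 0.95).
#' @return A list with `odds_ratio`, `ci_low`, `ci_high` (the bounds are `NA`
#'   for any zero cell).
#' @examples
#' odds_ratio_ci(22, 633, 2, 1609)  # OR 27.96, CI 6.56-119.26
#' odds_ratio_ci(4, 651, 0, 1611)   # OR Inf, no CI
#' @export
odds_ratio_ci <- function(a, b, c, d, ci_level = 0.95) {
  cells <- c(a, b, c, d)
  if (!is.numeric(cells) || length(cells) != 4 || anyNA(cells) ||
      any(cells < 0))
    stop("domain error: cells must be four non-negative numbers",
         call. = FALSE)
  or <- if (a == 0 && c == 0) NA_real_
        else if (c == 0 || b == 0) Inf
        else if (a == 0 || d == 0) 0
        else (a * d) / (b * c)
  if (all(cells > 0)) {
    z <- stats::qnorm(1 - (1 - ci_level) / 2)
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    lo <- exp(log(or) - z * se)
    hi <- exp(log(or) + z * se)
  } else {
    lo <- NA_real_
    hi <- NA_real_
  }
  list(odds_ratio = or, ci_low = lo, ci_high = hi)
}

#' Per-gene carrier sets
#'
#' Collapses classified variant calls to the subject level: for each gene, the
#' set of subjects carrying at least one variant with a qualifying verdict.
#' A subject with several qualifying variants in one gene appears once in
#' that gene's set; a subject with variants in two genes appears in both
#' sets. Calls from sample ids absent from the subject table are dropped with
#' a message.
#'
#' @param classified Output of [classify_variants()] (QC-passing calls).
#' @param subjects A validated subject `data.frame`.
#' @param verdict_filter Verdicts that qualify (default `"pathogenic"`).
#' @param genes Genes to report (default: panel genes observed in
#'   `classified`, plus any in `genes`).
#' @return Named list of character vectors of subject ids, one per gene.
#' @export
carriers_by_gene <- function(classified, subjects,
                             verdict_filter = "pathogenic",
                             genes = NULL) {
  stopifnot(is.data.frame(classified), is.data.frame(subjects))
  if (is.null(genes))
    genes <- sort(unique(classified$gene))
  qual <- classified[classified$verdict %in% verdict_filter, , drop = FALSE]
  unknown <- !(qual$sample_id %in% subjects$subject_id)
  if (any(unknown)) {
    message(sum(unknown),
            " qualifying call(s) dropped: sample_id not in subject table")
    qual <- qual[!unknown, , drop = FALSE]
  }
  out <- lapply(genes, function(g)
    sort(unique(qual$sample_id[qual$gene == g])))
  names(out) <- genes
  out
}

.burden_result <- function(gene, a, b, c, d, ci_level, comparison_label,
                           n_excluded = 0L) {
  ci <- odds_ratio_ci(a, b, c, d, ci_level)
  structure(list(
    gene = gene, a = a, b = b, c = c, d = d,
    odds_ratio = ci$odds_ratio, ci_low = ci$ci_low, ci_high = ci$ci_high,
    p_one_sided = fisher_one_sided(a, b, c, d),
    ci_level = ci_level, comparison_label = comparison_label,
    n_excluded = n_excluded
  ), class = "burden_result")
}

#' @export
print.burden_result <- function(x, ...) {
  or_txt <- if (is.na(x$odds_ratio)) "undefined"
            else if (is.infinite(x$odds_ratio)) "inf"
            else sprintf("%.2f", x$odds_ratio)
  ci_txt <- if (is.na(x$ci_low)) ""
            else sprintf(" (%.2f-%.2f)", x$ci_low, x$ci_high)
  cat(sprintf("%s [%s]: %d/%d vs %d/%d carriers, OR = %s%s, one-sided p = %.3g\n",
              x$gene, x$comparison_label, x$a, x$a + x$b, x$c, x$c + x$d,
              or_txt, ci_txt, x$p_one_sided))
  invisible(x)
}

#' @export
as.data.frame.burden_result <- function(x, ...) {
  data.frame(gene = x$gene, comparison = x$comparison_label,
             a = x$a, b = x$b, c = x$c, d = x$d,
             odds_ratio = x$odds_ratio, ci_low = x$ci_low,
             ci_high = x$ci_high, p_one_sided = x$p_one_sided,
             stringsAsFactors = FALSE)
}

#' Per-gene burden test against internal controls
#'
#' Builds the carrier-status x case-control 2x2 table for one gene from the
#' carrier sets and the subject table and computes the odds ratio, Woolf
#' interval and one-sided exact p-value. The counting unit is the individual
#' (carrier), not the variant or allele.
#'
#' @param subjects A validated subject `data.frame` (cases and controls).
#' @param carriers Output of [carriers_by_gene()].
#' @param gene Gene symbol.
#' @param ci_level Confidence level for the odds-ratio interval.
#' @return A `burden_result`.
#' @export
gene_burden <- function(subjects, carriers, gene, ci_level = 0.95) {
  if (!gene %in% names(carriers))
    stop("no carrier set for gene ", gene, call. = FALSE)
  cases <- subjects$subject_id[subjects$status == "case"]
  controls <- subjects$subject_id[subjects$status == "control"]
  a <- sum(cases %in% carriers[[gene]])
  c_ <- sum(controls %in% carriers[[gene]])
  .burden_result(gene, a, length(cases) - a, c_, length(controls) - c_,
                 ci_level, "internal controls")
}

#' Per-gene burden test against an external control cohort
#'
#' Same mathematics as [gene_burden()] with the control arm replaced by
#' published per-gene carrier counts from an external reference cohort.
#'
#' @param case_carriers Number of case carriers for the gene.
#' @param n_cases Total number of cases.
#' @param external An `external_controls` object.
#' @param gene Gene symbol (must be present in `external$carriers`).
#' @param ci_level Confidence level.
#' @return A `burden_result` labelled with the external cohort name.
#' @export
external_burden <- function(case_carriers, n_cases, external, gene,
                            ci_level = 0.95) {
  stopifnot(inherits(external, "external_controls"))
  if (!gene %in% names(external$carriers))
    stop("gene ", gene, " not in external-control table", call. = FALSE)
  c_ <- unname(external$carriers[[gene]])
  .burden_result(gene, case_carriers, n_cases - case_carriers,
                 c_, external$n_total - c_, ci_level, external$cohort_name)
}

#' Case-only stratified burden test
#'
#' Compares carrier frequency between strata of cases, without controls: age
#' at diagnosis (under 40 vs 40-49), first-degree family history (yes vs no),
#' or any-relative family history (yes vs no). The exposed stratum (younger /
#' family-history-positive) forms the first row of the 2x2 table. Cases whose
#' stratum is unknown are excluded from the table; their number is recorded
#' in the result (`n_excluded`) and reported via a message.
#'
#' @param subjects A validated subject `data.frame`; only cases are used.
#' @param carriers Output of [carriers_by_gene()].
#' @param stratifier One of `"age_group"`, `"fh_first_degree"`, `"fh_any"`.
#' @param gene Gene symbol.
#' @param ci_level Confidence level.
#' @return A `burden_result` with `comparison_label` naming the stratifier.
#' @export
case_only_burden <- function(subjects, carriers,
                             stratifier = c("age_group", "fh_first_degree",
                                            "fh_any"),
                             gene, ci_level = 0.95) {
  stratifier <- match.arg(stratifier)
  cases <- subjects[subjects$status == "case", , drop = FALSE]
  if (stratifier == "age_group") {
    exposed <- cases$age_group == "under40"
    unexposed <- cases$age_group == "40to49"
    label <- "case-only: under40 vs 40to49"
  } else {
    exposed <- cases[[stratifier]] == "yes"
    unexposed <- cases[[stratifier]] == "no"
    label <- paste0("case-only: ", stratifier, " yes vs no")
  }
  known <- exposed | unexposed
  n_excl <- sum(!known)
  if (n_excl > 0)
    message(n_excl, " case(s) with unknown ", stratifier,
            " excluded from case-only table")
  carrier <- cases$subject_id %in% carriers[[gene]]
  a <- sum(exposed & carrier)
  b <- sum(exposed & !carrier)
  c_ <- sum(unexposed & carrier)
  d <- sum(unexposed & !carrier)
  .burden_result(gene, a, b, c_, d, ci_level, label, n_excluded = n_excl)
}

#' Burden scan over the whole panel
#'
#' Runs [gene_burden()] for every panel gene against internal controls and,
#' when an external cohort is supplied, [external_burden()] as replication.
#' This is the table-shaped summary of the case-control analysis.
#'
#' @param classified Output of [classify_variants()] (QC-passing calls).
#' @param subjects A validated subject `data.frame`.
#' @param external Optional `external_controls` object.
#' @param genes Genes to test (default: panel genes of `config`).
#' @param config A [burden_config()]; supplies gene panel and `ci_level`.
#' @param verdict_filter Qualifying verdicts (default `"pathogenic"`).
#' @return A `data.frame` of class `burden_scan`, one row per gene x
#'   comparison, with cells, odds ratio, interval and one-sided p-value.
#' @export
burden_scan <- function(classified, subjects, external = NULL,
                        genes = NULL, config = burden_config(),
                        verdict_filter = "pathogenic") {
  if (is.null(genes)) genes <- config$panel_genes
  carriers <- carriers_by_gene(classified, subjects, verdict_filter, genes)
  n_cases <- sum(subjects$status == "case")
  rows <- list()
  for (g in genes) {
    internal <- gene_burden(subjects, carriers, g, config$ci_level)
    rows[[length(rows) + 1L]] <- as.data.frame(internal)
    if (!is.null(external) && g %in% names(external$carriers)) {
      rows[[length(rows) + 1L]] <- as.data.frame(
        external_burden(internal$a, n_cases, external, g, config$ci_level))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "carriers") <- carriers
  attr(out, "ci_level") <- config$ci_level
  class(out) <- c("burden_scan", "data.frame")
  out
}

#' @export
print.burden_scan <- function(x, digits = 3, ...) {
  cat("Per-gene carrier burden (one-sided Fisher's exact test)\n\n")
  df <- as.data.frame(x)
  df$OR <- ifelse(is.na(df$odds_ratio), "undef",
                  ifelse(is.infinite(df$odds_ratio), "inf",
                         sprintf("%.2f", df$odds_ratio)))
  df$CI95 <- ifelse(is.na(df$ci_low), "-",
                    sprintf("%.2f-%.2f", df$ci_low, df$ci_high))
  df$p <- signif(df$p_one_sided, digits)
  print(df[, c("gene", "comparison", "a", "b", "c", "d", "OR", "CI95", "p")],
        row.names = FALSE)
  invisible(x)
}

#' @export
summary.burden_scan <- function(object, alpha = 0.05, ...) {
  df <- as.data.frame(object)
  sig <- df[df$p_one_sided < alpha, , drop = FALSE]
  cat(sprintf("%d gene x comparison tests; %d with one-sided p < %g\n",
              nrow(df), nrow(sig), alpha))
  cat("(raw p-values; no multiple-testing adjustment by design)\n")
  if (nrow(sig)) print(sig[, c("gene", "comparison", "p_one_sided")],
                       row.names = FALSE)
  invisible(df)
}

#' Forest plot of a burden scan
#'
#' Log-scale forest plot of the per-gene odds ratios and Woolf intervals.
#' Genes with infinite or undefined odds ratios are omitted (annotated in the
#' margin).
#'
#' @param x A `burden_scan`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.burden_scan <- function(x, ...) {
  df <- as.data.frame(x)
  ok <- is.finite(df$odds_ratio) & df$odds_ratio > 0 & !is.na(df$ci_low)
  skipped <- df[!ok, , drop = FALSE]
  df <- df[ok, , drop = FALSE]
  if (!nrow(df)) {
    warning("no finite odds ratios to plot")
    return(invisible(x))
  }
  lab <- paste(df$gene, df$comparison, sep = " / ")
  y <- rev(seq_len(nrow(df)))
  xlim <- range(c(df$ci_low, df$ci_high, 1))
  old <- graphics::par(mar = c(4, 12, 2, 2))
  on.exit(graphics::par(old))
  graphics::plot(df$odds_ratio, y, log = "x", xlim = xlim, pch = 19,
                 yaxt = "n", ylab = "", xlab = "odds ratio (log scale)",
                 ylim = c(0.5, nrow(df) + 0.5), ...)
  graphics::segments(df$ci_low, y, df$ci_high, y)
  graphics::abline(v = 1, lty = 2, col = "grey50")
  graphics::axis(2, at = y, labels = lab, las = 1, cex.axis = 0.7)
  if (nrow(skipped))
    graphics::mtext(paste("omitted (inf/undefined OR):",
                          paste(unique(skipped$gene), collapse = ", ")),
                    side = 1, line = 3, cex = 0.7)
  invisible(x)
}

#' Overall carrier rate among cases
#'
#' Fraction of cases carrying at least one qualifying variant in any panel
#' gene; multi-gene carriers are counted once (woman-level union).
#'
#' @param subjects A validated subject `data.frame`.
#' @param carriers Output of [carriers_by_gene()].
#' @return The carrier fraction, with attributes `n_carriers` and `n_cases`.
#' @export
overall_carrier_rate <- function(subjects, carriers) {
  cases <- subjects$subject_id[subjects$status == "case"]
  union_ids <- unique(unlist(carriers, use.names = FALSE))
  n_carr <- sum(cases %in% union_ids)
  structure(n_carr / length(cases), n_carriers = n_carr,
            n_cases = length(cases))
}

#' Subjects carrying pathogenic variants in two or more genes
#'
#' @param carriers Output of [carriers_by_gene()].
#' @return A `data.frame` with `subject_id`, `genes` (comma-collapsed) and
#'   `n_genes`, one row per multi-gene carrier (possibly zero rows).
#' @export
multi_gene_carriers <- function(carriers) {
  ids <- unlist(carriers, use.names = FALSE)
  gene_of <- rep(names(carriers), lengths(carriers))
  if (!length(ids))
    return(data.frame(subject_id = character(0), genes = character(0),
                      n_genes = integer(0), stringsAsFactors = FALSE))
  by_id <- split(gene_of, ids)
  multi <- by_id[vapply(by_id, function(g) length(unique(g)) >= 2L, logical(1))]
  out <- data.frame(
    subject_id = names(multi),
    genes = vapply(multi, function(g) paste(sort(unique(g)), collapse = ","),
                   character(1)),
    n_genes = vapply(multi, function(g) length(unique(g)), integer(1)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
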