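#' Stratified carrier-frequency tables
#'
#' Builds the ER-status x age x family-history frequency tables for cases:
#' for each ER stratum (negative, positive), age scope (under 40; under 50 =
#' all cases in this under-50 design) and family-history restriction (all
#' women; women with a family history of breast cancer in any relative), the
#' per-gene count of qualifying variants, the stratum denominator and the
#' percentage. Totals are reported at both the variant level and the woman
#' level: the two differ when an individual carries two qualifying variants.
#' Cases with unknown ER status are excluded from both ER strata; their count
#' is attached as attribute `"n_er_unknown"`.
#'
#' @param subjects A validated subject `data.frame`; only cases are used.
#' @param classified Output of [classify_variants()] (QC-passing calls).
#' @param genes Genes to report.
#' @param verdict_filter Qualifying verdicts (default `"pathogenic"`).
#' @return A `data.frame` of class `frequency_table` with columns
#'   `er_status`, `age_scope`, `fh_restricted`, `gene` (gene symbol,
#'   `"total_variants"` or `"total_women"`), `count`, `denominator`,
#'   `percent`.
#' @export
frequency_tables <- function(subjects, classified,
                             genes = sort(unique(classified$gene)),
                             verdict_filter = "pathogenic") {
  cases <- subjects[subjects$status == "case", , drop = FALSE]
  qual <- classified[classified$verdict %in% verdict_filter &
                       classified$sample_id %in% cases$subject_id, ,
                     drop = FALSE]
  er_of <- cases$er_status[match(qual$sample_id, cases$subject_id)]
  agegrp_of <- cases$age_group[match(qual$sample_id, cases$subject_id)]
  fh_of <- cases$fh_any[match(qual$sample_id, cases$subject_id)]

  rows <- list()
  for (er in c("negative", "positive")) {
    for (scope in c("under40", "under50")) {
      for (fh in c(FALSE, TRUE)) {
        in_scope_case <- cases$er_status == er &
          (if (scope == "under40") cases$age_group == "under40"
           else cases$age_group %in% c("under40", "40to49")) &
          (!fh | cases$fh_any == "yes")
        denom <- sum(in_scope_case)
        in_scope_var <- er_of == er &
          (if (scope == "under40") agegrp_of == "under40"
           else agegrp_of %in% c("under40", "40to49")) &
          (!fh | fh_of == "yes")
        for (g in genes) {
          cnt <- sum(in_scope_var & qual$gene == g)
          rows[[length(rows) + 1L]] <- data.frame(
            er_status = er, age_scope = scope, fh_restricted = fh,
            gene = g, count = cnt, denominator = denom,
            percent = if (denom > 0) 100 * cnt / denom else NA_real_,
            stringsAsFactors = FALSE)
        }
        n_var <- sum(in_scope_var)
        n_wom <- length(unique(qual$sample_id[in_scope_var]))
        for (tot in c("total_variants", "total_women")) {
          cnt <- if (tot == "total_variants") n_var else n_wom
          rows[[length(rows) + 1L]] <- data.frame(
            er_status = er, age_scope = scope, fh_restricted = fh,
            gene = tot, count = cnt, denominator = denom,
            percent = if (denom > 0) 100 * cnt / denom else NA_real_,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_er_unknown") <- sum(cases$er_status == "unknown")
  class(out) <- c("frequency_table", "data.frame")
  out
}

#' @export
print.frequency_table <- function(x, ...) {
  df <- as.data.frame(x)
  df$percent <- ifelse(df$gene %in% c("total_variants", "total_women"),
                       sprintf("%.0f%%", df$percent),
                       sprintf("%.1f%%", df$percent))
  cat("Stratified frequency of qualifying variants among cases\n")
  cat("(ER-unknown cases excluded:", attr(x, "n_er_unknown"), ")\n\n")
  print(df, row.names = FALSE)
  invisible(x)
}

#' Look up one cell of a frequency table
#'
#' @param ft A `frequency_table`.
#' @param er_status `"negative"` or `"positive"`.
#' @param age_scope `"under40"` or `"under50"`.
#' @param gene Gene symbol, `"total_variants"` or `"total_women"`.
#' @param fh_restricted Restrict to women with a family history?
#' @return The matching one-row `data.frame`.
#' @export
frequency_cell <- function(ft, er_status, age_scope, gene,
                           fh_restricted = FALSE) {
  row <- ft[ft$er_status == er_status & ft$age_scope == age_scope &
              ft$gene == gene & ft$fh_restricted == fh_restricted, ,
            drop = FALSE]
  as.data.frame(row)
}
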