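#' Classify QC-passing variants
#'
#' Assigns each variant a clinical verdict. A variant whose normalized key
#' (gene + transcript + cDNA change) is present in the ClinVar-style lookup
#' takes the ClinVar label unconditionally (source `"clinvar"`); the rule
#' engine is never consulted for such variants, even when the label
#' contradicts the functional class. Variants absent from the lookup are
#' classified by predicted protein impact:
#'
#' * frameshift indel, stop-gain or stop-loss: `pathogenic` (rule
#'   `truncation`);
#' * intronic within two base pairs of the exon-intron junction:
#'   `pathogenic` (rule `splice_2bp`);
#' * missense substitution or in-frame indel: `vus` (rule
#'   `missense_or_inframe`);
#' * everything else (synonymous, deeper intronic, other): `not_counted`
#'   (rule `noncoding_or_synonymous`), retained and flagged rather than
#'   dropped.
#'
#' A truncating variant in the last exon of its gene is still called
#' pathogenic: escape from nonsense-mediated decay does not downgrade the
#' verdict.
#'
#' @param calls A validated variant `data.frame` (QC-passing rows).
#' @param clinvar A `clinvar_table` from [read_clinvar()].
#' @return `calls` with added columns `verdict` (pathogenic / vus / benign /
#'   conflicting / not_counted), `source` (`"clinvar"` or `"rule"`) and
#'   `rule_applied` (NA when source is clinvar).
#' @export
classify_variants <- function(calls, clinvar) {
  stopifnot(is.data.frame(calls), inherits(clinvar, "clinvar_table"))
  n <- nrow(calls)
  verdict <- character(n)
  source <- character(n)
  rule <- rep(NA_character_, n)

  if (n > 0) {
    key <- normalize_variant_key(calls$gene, calls$transcript,
                                 calls$cdna_change)
    hit <- match(key, clinvar$key)
    known <- !is.na(hit)
    verdict[known] <- clinvar$label[hit[known]]
    source[known] <- "clinvar"

    fc <- calls$functional_class
    intr_missing <- !known & fc == "intronic" & is.na(calls$splice_distance)
    if (any(intr_missing))
      stop("classification error: intronic variant lacking splice_distance (",
           calls$gene[which(intr_missing)[1]], " ",
           calls$cdna_change[which(intr_missing)[1]], ")", call. = FALSE)

    novel <- !known
    trunc <- novel & fc %in% c("frameshift_indel", "stopgain", "stoploss")
    splice <- novel & fc == "intronic" & abs(calls$splice_distance) <= 2
    vus <- novel & fc %in% c("missense", "inframe_indel")
    rest <- novel & !trunc & !splice & !vus

    verdict[trunc] <- "pathogenic"; rule[trunc] <- "truncation"
    verdict[splice] <- "pathogenic"; rule[splice] <- "splice_2bp"
    verdict[vus] <- "vus"; rule[vus] <- "missense_or_inframe"
    verdict[rest] <- "not_counted"; rule[rest] <- "noncoding_or_synonymous"
    source[novel] <- "rule"
  }

  out <- calls
  out$verdict <- verdict
  out$source <- source
  out$rule_applied <- rule
  rownames(out) <- NULL
  out
}

#' Classify a single variant call
#'
#' Convenience wrapper around [classify_variants()] for one call.
#'
#' @param call A one-row variant `data.frame`.
#' @param clinvar A `clinvar_table`.
#' @return The classified one-row `data.frame`.
#' @export
classify_variant <- function(call, clinvar) {
  stopifnot(is.data.frame(call), nrow(call) == 1)
  classify_variants(call, clinvar)
}

#' Per-gene verdict tallies
#'
#' Cross-tabulates classified calls by gene and verdict, with all five
#' verdict levels always present. The tally is invariant under reordering of
#' the input rows.
#'
#' @param classified Output of [classify_variants()].
#' @param genes Genes to report (default: those observed).
#' @return A gene x verdict integer matrix.
#' @export
verdict_tally <- function(classified, genes = sort(unique(classified$gene))) {
  levels_v <- c("pathogenic", "vus", "benign", "conflicting", "not_counted")
  tab <- table(factor(classified$gene, levels = genes),
               factor(classified$verdict, levels = levels_v))
  matrix(as.integer(tab), nrow = length(genes), ncol = length(levels_v),
         dimnames = list(gene = genes, verdict = levels_v))
}
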