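#' Run configuration for the burden pipeline
#'
#' Holds the gene panel and every tunable threshold used downstream: the QC
#' filter cutoffs, the test significance level and the confidence level for
#' odds-ratio intervals. Defaults are the analysis values used throughout the
#' package documentation: variants are excluded when read depth < 10, variant
#' quality < 20 or genotype quality < 20; allelic-ratio calls below 0.2 are
#' excluded at any depth, and calls below 0.3 are additionally excluded when
#' read depth is under 50.
#'
#' @param panel_genes Character vector of gene symbols on the panel.
#' @param depth_min Minimum read depth (reads); calls below fail QC.
#' @param quality_min Minimum phred-scaled variant quality.
#' @param gq_min Minimum phred-scaled genotype quality.
#' @param ar_min_absolute Allelic-ratio floor applied at any read depth.
#' @param ar_min_conditional Allelic-ratio floor applied when depth is below
#'   `depth_conditional`.
#' @param depth_conditional Read depth below which `ar_min_conditional`
#'   applies.
#' @param alpha Significance level for the one-sided burden test.
#' @param ci_level Confidence level for odds-ratio intervals.
#' @param seed Integer seed recorded in run manifests.
#' @return An object of class `burden_config` (a validated list).
#' @examples
#' cfg <- burden_config()
#' cfg$depth_min
#' @export
burden_config <- function(panel_genes = c("BRCA2", "CHEK2", "PALB2", "BRCA1", "TP53"),
                          depth_min = 10,
                          quality_min = 20,
                          gq_min = 20,
                          ar_min_absolute = 0.2,
                          ar_min_conditional = 0.3,
                          depth_conditional = 50,
                          alpha = 0.05,
                          ci_level = 0.95,
                          seed = 1L) {
  stopifnot(is.character(panel_genes), length(panel_genes) >= 1,
            !anyDuplicated(panel_genes))
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0)
      stop("config error: '", nm, "' must be a single non-negative number",
           call. = FALSE)
    x
  }
  cfg <- list(
    panel_genes = toupper(panel_genes),
    depth_min = num1(depth_min, "depth_min"),
    quality_min = num1(quality_min, "quality_min"),
    gq_min = num1(gq_min, "gq_min"),
    ar_min_absolute = num1(ar_min_absolute, "ar_min_absolute"),
    ar_min_conditional = num1(ar_min_conditional, "ar_min_conditional"),
    depth_conditional = num1(depth_conditional, "depth_conditional"),
    alpha = num1(alpha, "alpha"),
    ci_level = num1(ci_level, "ci_level"),
    seed = as.integer(seed)
  )
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("config error: 'alpha' must lie in (0, 1)", call. = FALSE)
  if (cfg$ci_level <= 0 || cfg$ci_level >= 1)
    stop("config error: 'ci_level' must lie in (0, 1)", call. = FALSE)
  if (cfg$ar_min_absolute > 1 || cfg$ar_min_conditional > 1)
    stop("config error: allelic-ratio thresholds must lie in [0, 1]",
         call. = FALSE)
  structure(cfg, class = "burden_config")
}

#' @export
print.burden_config <- function(x, ...) {
  cat("Burden pipeline configuration\n")
  cat("  panel genes :", paste(x$panel_genes, collapse = ", "), "\n")
  cat(sprintf("  QC          : depth >= %g, quality >= %g, GQ >= %g\n",
              x$depth_min, x$quality_min, x$gq_min))
  cat(sprintf("  allelic     : AR >= %g always; AR >= %g when depth < %g\n",
              x$ar_min_absolute, x$ar_min_conditional, x$depth_conditional))
  cat(sprintf("  inference   : alpha = %g, CI level = %g\n", x$alpha, x$ci_level))
  cat("  seed        :", x$seed, "\n")
  invisible(x)
}

#' Read / write a run configuration file
#'
#' The configuration is stored as a flat YAML document whose keys mirror the
#' arguments of [burden_config()]. Unknown keys are rejected so that typos in
#' threshold names cannot silently fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @return `read_config()` returns a `burden_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop("config error: file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- names(formals(burden_config))
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("config error: unknown key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  do.call(burden_config, raw)
}

#' @rdname read_config
#' @param config A `burden_config` object.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "burden_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Sequencing-library molar concentration
#'
#' Converts a measured library mass concentration and mean fragment length to
#' molarity using the standard average molecular weight of a DNA base pair
#' (649 g/mol):
#' \deqn{nM = \mathrm{conc}\ (ng/\mu L) \times 10^6 / (649 \times \mathrm{size}\ (bp))}
#'
#' @param concentration Library concentration in ng/uL; must be positive.
#' @param average_size Mean library fragment length in base pairs; positive.
#' @return Molar concentration in nanomolar (nM).
#' @examples
#' library_molarity(649, 1e6)   # 1 nM by construction
#' library_molarity(2.6, 400)
#' @export
library_molarity <- function(concentration, average_size) {
  if (!is.numeric(concentration) || !is.numeric(average_size))
    stop("domain error: inputs must be numeric", call. = FALSE)
  if (any(is.na(concentration)) || any(is.na(average_size)) ||
      any(concentration <= 0) || any(average_size <= 0))
    stop("domain error: concentration and average_size must be > 0",
         call. = FALSE)
  concentration * 1e6 / (649 * average_size)
}

# Functional-class vocabulary shared by the reader, classifier and simulator.
functional_classes <- function() {
  c("frameshift_indel", "stopgain", "stoploss", "intronic",
    "missense", "inframe_indel", "synonymous", "other")
}

clinvar_labels <- function() c("benign", "vus", "conflicting", "pathogenic")
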