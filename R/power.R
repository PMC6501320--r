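#' Configuration for the Monte-Carlo power estimate
#'
#' Parameterizes the design calculation for the one-sided Fisher burden test.
#' `caf` is the combined allele frequency of the qualifying variant class in
#' the population; under the rare-variant Hardy-Weinberg approximation the
#' control carrier probability is `2 * caf`. The case carrier probability is
#' derived through the odds transform: odds(p1) = odds_ratio_alt * odds(p0).
#'
#' @param n_cases,n_controls Arm sizes (positive integers).
#' @param caf Combined allele frequency, in (0, 0.5).
#' @param odds_ratio_alt Effect size under the alternative (carrier odds
#'   ratio).
#' @param alpha One-sided significance level.
#' @param replicates Number of Monte-Carlo replicates (>= 1).
#' @param seed Integer RNG seed.
#' @return An object of class `power_config`.
#' @export
power_config <- function(n_cases = 655, n_controls = 1611, caf = 0.001,
                         odds_ratio_alt = 5, alpha = 0.05,
                         replicates = 2000, seed = 1L) {
  stopifnot(n_cases >= 1, n_controls >= 1, replicates >= 1,
            odds_ratio_alt > 0, alpha > 0, alpha < 1)
  if (!is.numeric(caf) || caf <= 0 || caf >= 0.5)
    stop("domain error: caf must lie in (0, 0.5)", call. = FALSE)
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 caf = caf, odds_ratio_alt = odds_ratio_alt, alpha = alpha,
                 replicates = as.integer(replicates), seed = as.integer(seed)),
            class = "power_config")
}

#' Monte-Carlo power of the one-sided Fisher burden test
#'
#' Estimates the power to detect a qualifying variant class of combined
#' allele frequency `caf` at carrier odds ratio `odds_ratio_alt`. Per
#' replicate, control carriers are drawn Binomial(n_controls, p0) with
#' p0 = 2 * caf (rare-variant Hardy-Weinberg carrier probability) and case
#' carriers Binomial(n_cases, p1) with odds(p1) = odds_ratio_alt * odds(p0);
#' the replicate rejects when the one-sided Fisher p-value is below `alpha`.
#' Power is the rejection fraction, reported with its Monte-Carlo standard
#' error. Reproducible from `seed`.
#'
#' @param config A [power_config()].
#' @return An object of class `power_estimate`: list with `power`, `se`
#'   (Monte-Carlo standard error), `replicates`, `p0`, `p1` and the config.
#' @examples
#' estimate_power(power_config(replicates = 500))
#' @export
estimate_power <- function(config = power_config()) {
  stopifnot(inherits(config, "power_config"))
  p0 <- 2 * config$caf
  odds1 <- config$odds_ratio_alt * p0 / (1 - p0)
  p1 <- odds1 / (1 + odds1)
  if (!is.finite(p1) || p1 >= 1)
    stop("domain error: case carrier probability >= 1 under the odds ",
         "transform", call. = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)
  R <- config$replicates
  a <- stats::rbinom(R, config$n_cases, p1)
  c_ <- stats::rbinom(R, config$n_controls, p0)
  p <- fisher_one_sided(a, config$n_cases - a, c_, config$n_controls - c_)
  pow <- mean(p < config$alpha)
  structure(list(power = pow, se = sqrt(pow * (1 - pow) / R),
                 replicates = R, p0 = p0, p1 = p1, config = config),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf(
    "Monte-Carlo power: %.3f +/- %.3f (MC s.e., %d replicates)\n",
    x$power, x$se, x$replicates))
  cat(sprintf(
    "  design: %d cases / %d controls, carrier p0 = %.4g, p1 = %.4g, one-sided alpha = %g\n",
    x$config$n_cases, x$config$n_controls, x$p0, x$p1, x$config$alpha))
  invisible(x)
}
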