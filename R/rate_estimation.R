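# Per-division event rates and Luria-Delbruck fluctuation-rate estimation
# by the Lea-Coulson method of the median.

#' Lea-Coulson method-of-the-median fluctuation rate
#'
#' Given per-culture mutant counts, the median count r solves the
#' Lea-Coulson relation r/m - ln(m) - 1.24 = 0 for the expected number of
#' mutations per culture m; the per-division rate is m / N_t. A median of
#' zero is reported as rate 0 with a below-resolution flag.
#'
#' @param experiment a `fluctuation_experiment` (fields `counts`, `N_t`), or
#'   a numeric vector of counts with `N_t` supplied separately.
#' @param N_t final cells per culture (taken from the experiment if absent).
#' @return list with `rate` (per cell division), `m`, `median_r`,
#'   `below_resolution`.
#' @export
lea_coulson_median_rate <- function(experiment, N_t = NULL) {
  if (inherits(experiment, "fluctuation_experiment")) {
    counts <- experiment$counts
    N_t <- experiment$N_t
  } else {
    counts <- experiment
    if (is.null(N_t)) stopf("supply N_t when passing raw counts")
  }
  if (!length(counts)) stopf("need at least one culture")
  if (any(counts < 0)) stopf("mutant counts must be nonnegative")
  r_med <- stats::median(counts)
  if (r_med == 0) {
    return(list(rate = 0, m = 0, median_r = 0, below_resolution = TRUE))
  }
  f <- function(m) r_med / m - log(m) - 1.24
  # f is strictly decreasing in m; bracket the root
  lo <- 1e-12; hi <- max(2, r_med)
  while (f(hi) > 0) hi <- hi * 2
  m <- stats::uniroot(f, c(lo, hi), tol = 1e-9)$root
  list(rate = m / N_t, m = m, median_r = r_med, below_resolution = FALSE)
}

#' Per-division event rate from an isolate tally
#'
#' Events arising during a single induced cell division: rate is simply the
#' number of events divided by the number of isolates examined.
#'
#' @param n_events events observed.
#' @param n_isolates isolates examined.
#' @return rate per cell division.
#' @export
per_division_rate <- function(n_events, n_isolates) {
  if (n_isolates <= 0) stopf("n_isolates must be > 0")
  if (n_events < 0) stopf("n_events must be >= 0")
  n_events / n_isolates
}

#' Fold change over a reference rate
#'
#' Reported to `sigfigs` significant figures with halves rounded away from
#' zero (matching how published fold values such as 22.5 -> 23 are printed).
#'
#' @param rate numeric rate.
#' @param reference reference rate (> 0).
#' @param sigfigs significant figures (default 2).
#' @return rounded fold change.
#' @export
fold_change <- function(rate, reference, sigfigs = 2) {
  if (reference <= 0) stopf("reference rate must be > 0")
  signif_half_up(rate / reference, sigfigs)
}

#' Per-base-pair mutation rate from a mutation tally
#'
#' @param n_mutations mutations observed across the cohort.
#' @param n_isolates isolates examined.
#' @param genome_bp genome size in bp over which mutations were ascertained
#'   (diploid bp for a diploid cohort).
#' @return mutations per bp per cell division.
#' @export
mutation_rate_per_bp <- function(n_mutations, n_isolates, genome_bp) {
  per_division_rate(n_mutations, n_isolates) / genome_bp
}
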