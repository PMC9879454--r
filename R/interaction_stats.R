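# Cohort-level statistics: expected intra/interchromosomal proportions from
# Ty1-pair enumeration, goodness-of-fit chi-square, Fisher's exact test,
# a Yates-corrected 1-df region chi-square, and exact binomial bias tests.
# The exact tests are implemented by direct enumeration of the hypergeometric
# / binomial support rather than by delegating to stats::fisher.test /
# binom.test, so that the test suite can check them against those oracles.

#' Enumerate detectable Ty1-Ty1 pairs
#'
#' Iterates over all unordered pairs of full Ty1 elements. A pair is
#' intrachromosomal-detectable when both elements lie on the same homolog of
#' the same chromosome and a recombination event between them changes SNP
#' dosage: for same-arm pairs at least one heterozygous SNP must lie between
#' the elements (unequal crossover deletes/duplicates the interval); for
#' opposite-arm pairs at least one SNP must lie distal to either element
#' (circle or isochromosome formation). A pair on non-homologous chromosomes
#' is interchromosomal-detectable (an unbalanced translocation always
#' changes dosage over the distal spans). Pairs on homologs of the same
#' chromosome are allelic and excluded.
#'
#' @param genome a `diploid_genome` with >= 2 Ty1 elements.
#' @return list with `n_intra`, `n_inter`, `prop_intra`, `prop_inter`.
#' @export
enumerate_pairs <- function(genome) {
  ty <- genome$ty_elements
  ty <- ty[ty$family == "Ty1", , drop = FALSE]
  if (nrow(ty) < 2) stopf("genome must contain >= 2 Ty1 elements")
  sn <- genome$snps
  n_intra <- 0L; n_inter <- 0L
  arm <- vapply(seq_len(nrow(ty)), function(i) {
    position_arm(genome, ty$chromosome[i], ty$start[i])
  }, character(1))
  for (i in seq_len(nrow(ty) - 1L)) {
    for (j in seq(i + 1L, nrow(ty))) {
      if (ty$chromosome[i] != ty$chromosome[j]) {
        n_inter <- n_inter + 1L
        next
      }
      if (ty$homolog[i] != ty$homolog[j]) next   # allelic: excluded
      a <- if (ty$start[i] <= ty$start[j]) i else j
      b <- if (a == i) j else i
      chrom <- ty$chromosome[i]
      snc <- sn[sn$chromosome == chrom, ]
      if (arm[i] == arm[j]) {
        detectable <- any(snc$position > ty$end[a] &
                            snc$position < ty$start[b])
      } else {
        len <- chrom_lookup(genome, chrom)$length
        detectable <- any(snc$position < ty$start[a]) ||
          any(snc$position > ty$start[b])
      }
      if (detectable) n_intra <- n_intra + 1L
    }
  }
  total <- n_intra + n_inter
  if (total == 0) stopf("no detectable Ty1 pairs in genome")
  list(
    n_intra = n_intra, n_inter = n_inter,
    prop_intra = n_intra / total, prop_inter = n_inter / total
  )
}

#' Pearson goodness-of-fit chi-square
#'
#' @param observed integer counts.
#' @param expected_proportions expected proportions (rescaled to sum to 1,
#'   so the statistic is invariant to scaling).
#' @return list with `statistic`, `df`, `p`.
#' @export
gof_chisq <- function(observed, expected_proportions) {
  if (length(observed) != length(expected_proportions)) {
    stopf("observed and expected lengths differ")
  }
  p <- expected_proportions / sum(expected_proportions)
  e <- sum(observed) * p
  stat <- sum((observed - e)^2 / e)
  df <- length(observed) - 1L
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric test, two-sided by the probability-mass convention:
#' the p-value sums the probabilities of all tables (with the observed
#' margins) whose point probability does not exceed that of the observed
#' table.
#'
#' @param table a 2x2 matrix (or something coercible to one) of counts.
#' @return two-sided p-value.
#' @export
fisher_2x2 <- function(table) {
  m <- matrix(as.numeric(unlist(table)), 2, 2,
              byrow = is.list(table))
  if (any(m < 0) || any(m != floor(m))) stopf("counts must be nonnegative integers")
  a <- m[1, 1]
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  support <- lo:hi
  logp <- stats::dhyper(support, c1, n - c1, r1, log = TRUE)
  p_obs <- logp[support == a]
  # tolerance guards against ties broken by floating-point noise
  sum(exp(logp[logp <= p_obs + 1e-7]))
}

#' 1-df chi-square of a region tally against an expected fraction
#'
#' Tests whether `n_in` of `n_in + n_out` observations falling in a region
#' that makes up `expected_fraction` of the genome is compatible with
#' uniform placement. Yates' continuity correction is applied by default
#' (|O - E| reduced by 0.5 before squaring).
#'
#' @param n_in,n_out observed counts inside/outside the region.
#' @param expected_fraction fraction of the genome in the region.
#' @param continuity apply Yates' correction (default TRUE).
#' @return list with `statistic`, `p`.
#' @export
region_chisq <- function(n_in, n_out, expected_fraction, continuity = TRUE) {
  n <- n_in + n_out
  e <- c(n * expected_fraction, n * (1 - expected_fraction))
  o <- c(n_in, n_out)
  d <- abs(o - e)
  if (continuity) d <- pmax(0, d - 0.5)
  stat <- sum(d^2 / e)
  list(statistic = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

#' Exact two-sided binomial test for a direction bias
#'
#' Exact binomial test of `a` successes in `a + b` trials against success
#' probability `p0`, two-sided by the probability-mass convention (summing
#' P(X = k) over all k whose point probability does not exceed the observed
#' one).
#'
#' @param a,b counts in the two directions.
#' @param p0 null success probability (default 0.5).
#' @return two-sided p-value.
#' @export
binomial_bias <- function(a, b, p0 = 0.5) {
  if (a < 0 || b < 0) stopf("counts must be nonnegative")
  n <- a + b
  logp <- stats::dbinom(0:n, n, p0, log = TRUE)
  p_obs <- logp[a + 1]
  min(1, sum(exp(logp[logp <= p_obs + 1e-7])))
}
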