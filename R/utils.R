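# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` on exit so that seeded operations do
#' not perturb the global RNG stream. A `NULL` seed evaluates the code with
#' the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible sub-seed (< 2^31) from a root seed and an index, so
# that per-isolate streams are independent of the order in which they run.
derive_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + index * 16807) %% 2147483647)
}

#' Round to significant figures, halves away from zero
#'
#' Unlike [signif()], which rounds half to even (so `signif(22.5, 2)` is 22),
#' this rounds exact halves away from zero, matching how published fold
#' changes such as 22.5 -> 23 are reported. A small relative guard absorbs
#' floating-point representation error in ratios.
#'
#' @param x numeric vector.
#' @param digits significant digits (default 2).
#' @return rounded numeric vector.
#' @export
signif_half_up <- function(x, digits = 2) {
  stopifnot(digits >= 1)
  out <- x
  nz <- is.finite(x) & x != 0
  a <- abs(x[nz])
  e <- floor(log10(a)) - digits + 1
  f <- a / 10^e
  out[nz] <- sign(x[nz]) * floor(f + 0.5 + 1e-9) * 10^e
  out
}

roman_chromosomes <- function(n = 16) as.character(utils::as.roman(seq_len(n)))

# largest odd integer <= n (at least 1); used to clip smoothing windows
odd_at_most <- function(n) {
  n <- max(1L, as.integer(n))
  if (n %% 2L == 0L) n - 1L else n
}
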