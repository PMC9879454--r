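# Association of called breakpoints with Ty/delta annotations, partner
# family tallies, and per-element hotspot enrichment tests.

#' Associate breakpoint intervals with Ty annotations
#'
#' Each breakpoint interval of each call is intersected (closed intervals,
#' >= 1 bp overlap) with the Ty/delta element spans of the genome, on either
#' homolog.
#'
#' @param calls a call data.frame from [call_events()].
#' @param genome a `diploid_genome`.
#' @return data.frame with one row per call and breakpoint interval:
#'   `id`, `class`, `chromosome`, `bp_start`, `bp_end`, `overlapping_ids`
#'   (comma-separated), `overlapping_families`, `has_ty_flag`.
#' @export
associate <- function(calls, genome) {
  ty <- genome$ty_elements
  rows <- list()
  add <- function(call, lo, hi) {
    hit <- which(ty$chromosome == call$chromosome &
                   ty$start <= hi & ty$end >= lo)
    rows[[length(rows) + 1L]] <<- data.frame(
      id = call$id, class = call$class, chromosome = call$chromosome,
      bp_start = lo, bp_end = hi,
      overlapping_ids = paste(ty$id[hit], collapse = ","),
      overlapping_families = paste(unique(ty$family[hit]), collapse = ","),
      has_ty_flag = length(hit) > 0,
      stringsAsFactors = FALSE
    )
  }
  for (i in seq_len(nrow(calls))) {
    call <- calls[i, ]
    add(call, call$bp1_start, call$bp1_end)
    if (!is.na(call$bp2_start)) add(call, call$bp2_start, call$bp2_end)
  }
  if (!length(rows)) {
    return(data.frame(
      id = character(), class = character(), chromosome = character(),
      bp_start = numeric(), bp_end = numeric(),
      overlapping_ids = character(), overlapping_families = character(),
      has_ty_flag = logical(), stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fraction of breakpoints with a Ty element, by event class group
#'
#' @param annotation output of [associate()].
#' @return data.frame with `group` (`dosage` for DEL/DUP/CIRCLE/ISO classes,
#'   `loh` for I-LOH/T-LOH), `n_breakpoints`, `n_with_ty`, `fraction`.
#' @export
ty_fraction_by_group <- function(annotation) {
  grp <- ifelse(annotation$class %in% c("I-LOH", "T-LOH"), "loh", "dosage")
  agg <- function(g) {
    sub <- annotation[grp == g, , drop = FALSE]
    data.frame(
      group = g, n_breakpoints = nrow(sub),
      n_with_ty = sum(sub$has_ty_flag),
      fraction = if (nrow(sub)) mean(sub$has_ty_flag) else NA_real_
    )
  }
  rbind(agg("dosage"), agg("loh"))
}

#' Tally recombination partner families
#'
#' Symmetric tally over {Ty1, Ty2, delta} of the family pair of each
#' recombination event (truncated Ty1 counts as Ty1).
#'
#' @param pairs data.frame with columns `family_a`, `family_b` (or a
#'   character matrix/list of 2-vectors).
#' @return a named count vector over `Ty1-Ty1`, `Ty1-Ty2`, `Ty1-delta`,
#'   `Ty2-Ty2`, `Ty2-delta`, `delta-delta`.
#' @export
partner_tally <- function(pairs) {
  lev <- c("Ty1", "Ty2", "delta")
  keys <- c("Ty1-Ty1", "Ty1-Ty2", "Ty1-delta",
            "Ty2-Ty2", "Ty2-delta", "delta-delta")
  out <- stats::setNames(integer(length(keys)), keys)
  if (is.null(pairs) || !nrow(as.data.frame(pairs))) return(out)
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  norm <- function(x) {
    x[x == "truncated_Ty1"] <- "Ty1"
    x[x == "solo_delta"] <- "delta"
    x
  }
  a <- norm(pairs$family_a); b <- norm(pairs$family_b)
  bad <- !(a %in% lev) | !(b %in% lev)
  if (any(bad)) stopf("unknown family in partner pair: %s/%s",
                      a[bad][1], b[bad][1])
  lo <- pmin(match(a, lev), match(b, lev))
  hi <- pmax(match(a, lev), match(b, lev))
  key <- paste(lev[lo], lev[hi], sep = "-")
  tab <- table(key)
  out[names(tab)] <- as.integer(tab)
  out
}

#' Per-element hotspot enrichment test
#'
#' Under the null that each of `total_events` element involvements picks one
#' of `n_elements` elements uniformly, the count at one element is binomial
#' with success probability `1/n_elements`. The one-sided upper tail
#' P(X >= k) is reported per element, optionally Bonferroni-multiplied
#' (capped at 1).
#'
#' @param counts named integer vector of event counts per element.
#' @param n_elements number of elements in the null (default
#'   `length(counts)`).
#' @param total_events total element involvements (default `sum(counts)`).
#' @param correction `"bonferroni"` or `"none"`.
#' @return data.frame with `element`, `count`, `p`, `p_adj`.
#' @export
hotspot_test <- function(counts, n_elements = length(counts),
                         total_events = sum(counts),
                         correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  if (any(counts > total_events)) {
    stopf("element count exceeds total_events")
  }
  p <- stats::pbinom(counts - 1, total_events, 1 / n_elements,
                     lower.tail = FALSE)
  p_adj <- if (correction == "bonferroni") pmin(1, p * n_elements) else p
  data.frame(
    element = if (!is.null(names(counts))) names(counts)
      else as.character(seq_along(counts)),
    count = as.integer(counts), p = p, p_adj = p_adj,
    stringsAsFactors = FALSE, row.names = NULL
  )
}
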