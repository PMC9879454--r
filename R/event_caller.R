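# Event calling from per-SNP allele read depth. The signal is the ratio of
# coverage (RC): each allele's read count divided by the genome-wide mean
# total site coverage, so an unaltered heterozygous allele sits near 0.5, a
# lost allele near 0, and a duplicated single allele near 1.0. Per homolog
# and chromosome the RC series is median-smoothed, thresholded into dosage
# states {0, 1, 2}, segmented, and the joint (W, Y) state pattern is mapped
# onto the event taxonomy: reciprocal 0/2 regions are LOH (terminal or
# interstitial by telomere contact), non-reciprocal regions are deletions or
# duplications, whole-chromosome patterns are monosomy/trisomy/UPD, double
# terminal deletions on one homolog indicate a centric circle, and a coupled
# terminal deletion/duplication on opposite arms an isochromosome.

#' Caller parameters
#'
#' @param smoothing_window running-median window (SNP count, odd).
#' @param t_low,t_high RC thresholds separating dosage states 0/1/2; the
#'   defaults 0.25 and 0.75 are the midpoints between the ideal levels
#'   0, 0.5 and 1.0.
#' @param min_support_snps,min_support_bp minimum segment support: state
#'   runs with fewer SNPs or a shorter span are absorbed into a neighbor.
#' @param terminal_margin_bp distance from a chromosome end within which a
#'   segment boundary is treated as reaching the telomere.
#' @param breakpoint_window breakpoint window width in bp (default 20000):
#'   event edges are reported as a window of this width centered at the
#'   midpoint between the last unaltered and first altered SNP.
#' @return a list of class `caller_params`.
#' @export
caller_params <- function(smoothing_window = 11,
                          t_low = 0.25, t_high = 0.75,
                          min_support_snps = 5,
                          min_support_bp = 10000,
                          terminal_margin_bp = 30000,
                          breakpoint_window = 20000) {
  if (!(t_low > 0 && t_low < t_high && t_high < 1.25)) {
    stopf("need 0 < t_low < t_high < 1.25")
  }
  smoothing_window <- as.integer(smoothing_window)
  if (smoothing_window < 1 || smoothing_window %% 2 == 0) {
    stopf("smoothing_window must be odd and >= 1")
  }
  structure(
    list(
      smoothing_window = smoothing_window, t_low = t_low, t_high = t_high,
      min_support_snps = as.integer(min_support_snps),
      min_support_bp = as.integer(min_support_bp),
      terminal_margin_bp = as.integer(terminal_margin_bp),
      breakpoint_window = as.integer(breakpoint_window)
    ),
    class = "caller_params"
  )
}

#' Compute the ratio of coverage (RC) for a dosage table
#'
#' RC(row) = read_count / D-bar, where D-bar is the mean over SNP sites of
#' the total (W + Y) coverage. With this denominator an unaltered
#' heterozygous allele has RC near 0.5 and a duplicated single allele near
#' 1.0. The statistic is invariant under global depth rescaling.
#'
#' @param table a `snp_dosage` data.frame (long format, one row per SNP and
#'   parental class) as produced by [synthesize_snp_counts()].
#' @return the table with an `rc` column; mean site coverage is attached as
#'   attribute `mean_site_coverage`.
#' @export
compute_rc <- function(table) {
  if (!nrow(table)) stopf("empty dosage table")
  site <- paste(table$chromosome, table$position)
  totals <- tapply(table$read_count, site, sum)
  d_bar <- mean(totals)
  if (d_bar == 0) stopf("mean site coverage is zero")
  table$rc <- table$read_count / d_bar
  attr(table, "mean_site_coverage") <- d_bar
  table
}

#' Segment a per-homolog RC series into dosage states
#'
#' The RC series (SNPs sorted by position) is median-smoothed, mapped to
#' states by thresholds (state 0 below `t_low`, 1 between, 2 at or above
#' `t_high`), and adjacent same-state runs are merged. Runs below the
#' minimum support (SNP count or bp span) are absorbed into the larger
#' neighbor. A chromosome with fewer SNPs than the smoothing window is
#' returned as a single majority-state segment.
#'
#' @param rc numeric RC values.
#' @param positions SNP positions (bp), same length, sorted increasing.
#' @param params a [caller_params()].
#' @return data.frame of runs: `state`, `start_idx`, `end_idx`,
#'   `start_pos`, `end_pos`, `n_snps`.
#' @export
segment_profile <- function(rc, positions, params = caller_params()) {
  n <- length(rc)
  stopifnot(n == length(positions), !is.unsorted(positions))
  if (n == 0) return(NULL)
  state_of <- function(x) {
    ifelse(x < params$t_low, 0L, ifelse(x < params$t_high, 1L, 2L))
  }
  k <- odd_at_most(min(params$smoothing_window, n))
  sm <- if (k >= 3) stats::runmed(rc, k, endrule = "median") else rc
  states <- state_of(sm)
  if (n < params$smoothing_window) {
    maj <- as.integer(names(which.max(table(states))))
    return(data.frame(
      state = maj, start_idx = 1L, end_idx = n,
      start_pos = positions[1], end_pos = positions[n], n_snps = n
    ))
  }
  runs_from <- function(states) {
    r <- rle(states)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    data.frame(state = r$values, start_idx = starts, end_idx = ends,
               start_pos = positions[starts], end_pos = positions[ends],
               n_snps = r$lengths)
  }
  runs <- runs_from(states)
  repeat {
    if (nrow(runs) <= 1) break
    weak <- which(runs$n_snps < params$min_support_snps |
                    (runs$end_pos - runs$start_pos) < params$min_support_bp)
    if (!length(weak)) break
    w <- weak[which.min(runs$n_snps[weak])]
    nbrs <- c(if (w > 1) w - 1L, if (w < nrow(runs)) w + 1L)
    tgt <- nbrs[which.max(runs$n_snps[nbrs])]
    states[runs$start_idx[w]:runs$end_idx[w]] <- runs$state[tgt]
    runs <- runs_from(states)
  }
  runs
}

# joint (W, Y) state regions for one chromosome
.joint_regions <- function(runs_w, runs_y, positions, params) {
  n <- length(positions)
  w_state <- integer(n); y_state <- integer(n)
  for (r in seq_len(nrow(runs_w))) {
    w_state[runs_w$start_idx[r]:runs_w$end_idx[r]] <- runs_w$state[r]
  }
  for (r in seq_len(nrow(runs_y))) {
    y_state[runs_y$start_idx[r]:runs_y$end_idx[r]] <- runs_y$state[r]
  }
  key <- paste(w_state, y_state)
  r <- rle(key)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  reg <- data.frame(
    w = w_state[starts], y = y_state[starts],
    start_idx = starts, end_idx = ends, n_snps = r$lengths
  )
  # absorb boundary slivers produced by mismatched W/Y segmentation edges
  repeat {
    if (nrow(reg) <= 1) break
    weak <- which(reg$n_snps < params$min_support_snps)
    if (!length(weak)) break
    w <- weak[which.min(reg$n_snps[weak])]
    nbrs <- c(if (w > 1) w - 1L, if (w < nrow(reg)) w + 1L)
    tgt <- nbrs[which.max(reg$n_snps[nbrs])]
    idx <- reg$start_idx[w]:reg$end_idx[w]
    w_state[idx] <- reg$w[tgt]; y_state[idx] <- reg$y[tgt]
    key <- paste(w_state, y_state)
    r <- rle(key)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    reg <- data.frame(
      w = w_state[starts], y = y_state[starts],
      start_idx = starts, end_idx = ends, n_snps = r$lengths
    )
  }
  reg
}

.new_call <- function(class, chromosome, homolog, start_idx, end_idx,
                      start_pos, end_pos, reciprocal,
                      start_idx2 = NA, end_idx2 = NA,
                      start_pos2 = NA, end_pos2 = NA) {
  data.frame(
    class = class, chromosome = chromosome, homolog = homolog,
    start_idx = start_idx, end_idx = end_idx,
    start_pos = start_pos, end_pos = end_pos,
    start_idx2 = start_idx2, end_idx2 = end_idx2,
    start_pos2 = start_pos2, end_pos2 = end_pos2,
    reciprocal = reciprocal,
    paired_with = NA_character_, stringsAsFactors = FALSE
  )
}

#' Classify the joint dosage pattern of one chromosome
#'
#' Decision rules: reciprocal (0,2) regions are LOH, terminal or interstitial
#' by telomere contact; non-reciprocal regions (one homolog at 0 or 2 with
#' the other at 1) are deletions/duplications; a single whole-chromosome
#' region is monosomy (0,1), trisomy (2,1) or UPD (0,2); terminal deletions
#' on both arms of one homolog merge into a CIRCLE call; a terminal deletion
#' on one arm coupled with a terminal duplication on the other arm of the
#' same homolog merges into an ISO call. Whole-chromosome calls take
#' precedence over segment-level calls on the same span.
#'
#' @param runs_w,runs_y per-homolog segmentations from [segment_profile()].
#' @param positions SNP positions of the chromosome.
#' @param chromosome chromosome name.
#' @param params a [caller_params()].
#' @return data.frame of event calls (possibly empty).
#' @export
classify_chromosome <- function(runs_w, runs_y, positions, chromosome,
                                params = caller_params()) {
  reg <- .joint_regions(runs_w, runs_y, positions, params)
  n <- length(positions)
  calls <- list()
  emit <- function(...) calls[[length(calls) + 1L]] <<- .new_call(...)
  if (nrow(reg) == 1) {
    w <- reg$w[1]; y <- reg$y[1]
    cls <- NULL; hom <- NULL
    if (w == 0 && y == 1) { cls <- "MONOSOMY"; hom <- "W" }
    if (w == 1 && y == 0) { cls <- "MONOSOMY"; hom <- "Y" }
    if (w == 2 && y == 1) { cls <- "TRISOMY"; hom <- "W" }
    if (w == 1 && y == 2) { cls <- "TRISOMY"; hom <- "Y" }
    if (w == 0 && y == 2) { cls <- "UPD"; hom <- "W" }
    if (w == 2 && y == 0) { cls <- "UPD"; hom <- "Y" }
    if (!is.null(cls)) {
      emit(cls, chromosome, hom, 1L, n, positions[1], positions[n],
           reciprocal = cls == "UPD")
    }
    return(.bind_calls(calls))
  }
  for (r in seq_len(nrow(reg))) {
    w <- reg$w[r]; y <- reg$y[r]
    if (w == 1 && y == 1) next
    terminal <- reg$start_idx[r] == 1L || reg$end_idx[r] == n
    span <- c(positions[reg$start_idx[r]], positions[reg$end_idx[r]])
    if ((w == 0 && y == 2) || (w == 2 && y == 0)) {
      emit(if (terminal) "T-LOH" else "I-LOH", chromosome,
           if (w == 0) "W" else "Y",
           reg$start_idx[r], reg$end_idx[r], span[1], span[2],
           reciprocal = TRUE)
    } else {
      if (w != 1) {
        emit(paste0(if (terminal) "T-" else "I-", if (w == 0) "DEL" else "DUP"),
             chromosome, "W", reg$start_idx[r], reg$end_idx[r],
             span[1], span[2], reciprocal = FALSE)
      }
      if (y != 1) {
        emit(paste0(if (terminal) "T-" else "I-", if (y == 0) "DEL" else "DUP"),
             chromosome, "Y", reg$start_idx[r], reg$end_idx[r],
             span[1], span[2], reciprocal = FALSE)
      }
    }
  }
  out <- .bind_calls(calls)
  .merge_arm_patterns(out, n)
}

.bind_calls <- function(calls) {
  if (!length(calls)) {
    return(data.frame(
      class = character(0), chromosome = character(0),
      homolog = character(0), start_idx = integer(0), end_idx = integer(0),
      start_pos = numeric(0), end_pos = numeric(0),
      start_idx2 = integer(0), end_idx2 = integer(0),
      start_pos2 = numeric(0), end_pos2 = numeric(0),
      reciprocal = logical(0), paired_with = character(0),
      stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

# merge double terminal deletions (CIRCLE) and coupled terminal
# deletion/duplication on opposite arms (ISO) of one homolog
.merge_arm_patterns <- function(calls, n) {
  if (nrow(calls) < 2) return(calls)
  for (hom in c("W", "Y")) {
    left <- which(calls$homolog == hom & calls$start_idx == 1L &
                    calls$class %in% c("T-DEL", "T-DUP"))
    right <- which(calls$homolog == hom & calls$end_idx == n &
                     calls$class %in% c("T-DEL", "T-DUP"))
    if (length(left) == 1 && length(right) == 1 && left != right) {
      l <- calls[left, ]; r <- calls[right, ]
      merged <- if (l$class == "T-DEL" && r$class == "T-DEL") "CIRCLE"
        else if (l$class != r$class) "ISO" else NA
      if (!is.na(merged)) {
        calls[left, c("start_idx2", "end_idx2", "start_pos2", "end_pos2")] <-
          r[, c("start_idx", "end_idx", "start_pos", "end_pos")]
        calls$class[left] <- merged
        # ISO records the duplicated arm first by convention
        if (merged == "ISO" && l$class == "T-DEL") {
          tmp <- calls[left, c("start_idx", "end_idx", "start_pos", "end_pos")]
          calls[left, c("start_idx", "end_idx", "start_pos", "end_pos")] <-
            calls[left, c("start_idx2", "end_idx2", "start_pos2", "end_pos2")]
          calls[left, c("start_idx2", "end_idx2", "start_pos2", "end_pos2")] <-
            tmp
        }
        calls <- calls[-right, , drop = FALSE]
      }
    }
  }
  rownames(calls) <- NULL
  calls
}

#' Greedily pair terminal deletions with terminal duplications
#'
#' Within one isolate's call set, each unpaired T-DEL is paired with the
#' first unpaired T-DUP on a different chromosome (ties broken by chromosome
#' order, then coordinate), reflecting the interpretation of coupled
#' T-DEL/T-DUP patterns as unbalanced translocations. Leftovers stay
#' unpaired. A T-DEL/T-DUP pair on the same chromosome is an isochromosome
#' and is merged by the classifier before pairing.
#'
#' @param calls a call data.frame across one isolate, with an `id` column
#'   (added if absent).
#' @return the calls with `paired_with` filled where a partner was found.
#' @export
pair_translocations <- function(calls) {
  if (!nrow(calls)) return(calls)
  if (is.null(calls$id)) {
    calls$id <- sprintf("%s_%s_%d", calls$chromosome, calls$class,
                        seq_len(nrow(calls)))
  }
  chrom_rank <- match(calls$chromosome, roman_chromosomes())
  ord <- order(chrom_rank, calls$start_pos)
  dels <- intersect(ord, which(calls$class == "T-DEL"))
  dups <- intersect(ord, which(calls$class == "T-DUP"))
  used <- logical(nrow(calls))
  for (d in dels) {
    cand <- dups[!used[dups] & calls$chromosome[dups] != calls$chromosome[d]]
    if (!length(cand)) next
    p <- cand[1]
    calls$paired_with[d] <- calls$id[p]
    calls$paired_with[p] <- calls$id[d]
    used[p] <- TRUE
  }
  calls
}

#' Breakpoint interval(s) for a call
#'
#' For I-LOH calls the breakpoint is the region between flanking heterozygous
#' SNPs: the interval from the last heterozygous SNP before the tract to the
#' first heterozygous SNP after it. For terminal LOH and all deletion /
#' duplication edges, a window of width `params$breakpoint_window` (default
#' 20 kb) centered at the midpoint between the last unaltered SNP and the
#' first altered SNP. Windows are clipped at coordinate 1 and at the
#' chromosome end.
#'
#' @param call one row of a call data.frame.
#' @param positions SNP positions of the call's chromosome.
#' @param chrom_length chromosome length (bp).
#' @param params a [caller_params()].
#' @return data.frame of 1 or 2 intervals with columns `start`, `end`.
#' @export
breakpoint_interval <- function(call, positions, chrom_length,
                                params = caller_params()) {
  n <- length(positions)
  win <- params$breakpoint_window
  edge_window <- function(inside_idx, outside_idx) {
    if (outside_idx < 1 || outside_idx > n) {
      # altered region reaches the chromosome end: clip at the boundary
      center <- positions[inside_idx]
    } else {
      center <- (positions[inside_idx] + positions[outside_idx]) / 2
    }
    c(max(1, round(center - win / 2)), min(chrom_length, round(center + win / 2)))
  }
  ivals <- list()
  if (call$class == "I-LOH") {
    lo <- if (call$start_idx > 1) positions[call$start_idx - 1L] else 1
    hi <- if (call$end_idx < n) positions[call$end_idx + 1L] else chrom_length
    ivals[[1]] <- c(lo, hi)
  } else if (call$class %in% c("T-LOH", "T-DEL", "T-DUP", "MONOSOMY",
                               "TRISOMY", "UPD")) {
    if (call$start_idx > 1) {
      ivals[[1]] <- edge_window(call$start_idx, call$start_idx - 1L)
    } else if (call$end_idx < n) {
      ivals[[1]] <- edge_window(call$end_idx, call$end_idx + 1L)
    } else {
      ivals[[1]] <- c(1, chrom_length)   # whole chromosome
    }
  } else if (call$class %in% c("I-DEL", "I-DUP")) {
    ivals[[1]] <- edge_window(call$start_idx, call$start_idx - 1L)
    ivals[[2]] <- edge_window(call$end_idx, call$end_idx + 1L)
  } else if (call$class %in% c("CIRCLE", "ISO")) {
    e1 <- if (call$start_idx == 1) call$end_idx else call$start_idx
    o1 <- if (call$start_idx == 1) call$end_idx + 1L else call$start_idx - 1L
    ivals[[1]] <- edge_window(e1, o1)
    e2 <- if (call$start_idx2 == 1) call$end_idx2 else call$start_idx2
    o2 <- if (call$start_idx2 == 1) call$end_idx2 + 1L else call$start_idx2 - 1L
    ivals[[2]] <- edge_window(e2, o2)
  }
  out <- do.call(rbind, lapply(ivals, function(v) {
    data.frame(start = v[1], end = v[2])
  }))
  out
}

# Target joint (W, Y) state pattern of a call's interval(s); NULL when the
# call has no local edge to refine (whole-chromosome classes).
.call_patterns <- function(call) {
  lost0 <- function(hom) if (hom == "W") c(0L, 1L) else c(1L, 0L)
  gain2 <- function(hom) if (hom == "W") c(2L, 1L) else c(1L, 2L)
  # for LOH the lost allele's exact zero is the sharp edge signal; the
  # duplicated side is left unconstrained (NA matches any raw state)
  loh <- function(hom) if (hom == "W") c(0L, NA) else c(NA, 0L)
  switch(call$class,
    "T-LOH" = , "I-LOH" = list(loh(call$homolog)),
    "T-DEL" = , "I-DEL" = list(lost0(call$homolog)),
    "T-DUP" = , "I-DUP" = list(gain2(call$homolog)),
    "CIRCLE" = list(lost0(call$homolog), lost0(call$homolog)),
    "ISO" = list(gain2(call$homolog), lost0(call$homolog)),
    NULL
  )
}

# Median smoothing biases segment edges inward by about one SNP when the
# minimum of the high-state values in the half-window dips below threshold;
# refine each call edge outward (up to half the smoothing window) while the
# raw per-SNP joint state still matches the call's pattern.
.refine_calls <- function(calls, raw_w, raw_y, positions, params) {
  if (!nrow(calls)) return(calls)
  max_step <- (params$smoothing_window - 1L) %/% 2L
  n <- length(positions)
  for (i in seq_len(nrow(calls))) {
    pats <- .call_patterns(calls[i, ])
    if (is.null(pats)) next
    refine <- function(lo, hi, pat) {
      match_at <- function(j) {
        (is.na(pat[1]) || raw_w[j] == pat[1]) &&
          (is.na(pat[2]) || raw_y[j] == pat[2])
      }
      step <- 0L
      while (lo > 1L && step < max_step && match_at(lo - 1L)) {
        lo <- lo - 1L; step <- step + 1L
      }
      step <- 0L
      while (hi < n && step < max_step && match_at(hi + 1L)) {
        hi <- hi + 1L; step <- step + 1L
      }
      c(lo, hi)
    }
    r1 <- refine(calls$start_idx[i], calls$end_idx[i], pats[[1]])
    calls$start_idx[i] <- r1[1]; calls$end_idx[i] <- r1[2]
    calls$start_pos[i] <- positions[r1[1]]; calls$end_pos[i] <- positions[r1[2]]
    if (length(pats) > 1 && !is.na(calls$start_idx2[i])) {
      r2 <- refine(calls$start_idx2[i], calls$end_idx2[i], pats[[2]])
      calls$start_idx2[i] <- r2[1]; calls$end_idx2[i] <- r2[2]
      calls$start_pos2[i] <- positions[r2[1]]
      calls$end_pos2[i] <- positions[r2[2]]
    }
  }
  calls
}

#' Call events from a dosage table
#'
#' End-to-end caller: computes RC, segments each homolog of each chromosome,
#' classifies joint patterns, attaches breakpoint intervals, and pairs
#' terminal deletions with duplications across chromosomes.
#'
#' @param table a `snp_dosage` table.
#' @param genome the `diploid_genome` the table refers to.
#' @param params a [caller_params()].
#' @return data.frame of calls with breakpoint columns `bp1_start`,
#'   `bp1_end`, `bp2_start`, `bp2_end` (1-based inclusive).
#' @export
call_events <- function(table, genome, params = caller_params()) {
  table <- compute_rc(table)
  all_calls <- list()
  for (chrom in unique(table$chromosome)) {
    sub <- table[table$chromosome == chrom, ]
    w <- sub[sub$parental_class == "W", ]
    y <- sub[sub$parental_class == "Y", ]
    ordw <- order(w$position); ordy <- order(y$position)
    w <- w[ordw, ]; y <- y[ordy, ]
    positions <- w$position
    if (!identical(positions, y$position)) {
      stopf("chromosome %s: W and Y rows do not share SNP positions", chrom)
    }
    runs_w <- segment_profile(w$rc, positions, params)
    runs_y <- segment_profile(y$rc, positions, params)
    calls <- classify_chromosome(runs_w, runs_y, positions, chrom, params)
    if (!nrow(calls)) next
    state_of <- function(x) {
      ifelse(x < params$t_low, 0L, ifelse(x < params$t_high, 1L, 2L))
    }
    calls <- .refine_calls(calls, state_of(w$rc), state_of(y$rc),
                           positions, params)
    len <- chrom_lookup(genome, chrom)$length
    bp <- lapply(seq_len(nrow(calls)), function(i) {
      iv <- breakpoint_interval(calls[i, ], positions, len, params)
      c(iv$start[1], iv$end[1],
        if (nrow(iv) > 1) iv$start[2] else NA,
        if (nrow(iv) > 1) iv$end[2] else NA)
    })
    bp <- do.call(rbind, bp)
    calls$bp1_start <- bp[, 1]; calls$bp1_end <- bp[, 2]
    calls$bp2_start <- bp[, 3]; calls$bp2_end <- bp[, 4]
    all_calls[[length(all_calls) + 1L]] <- calls
  }
  if (!length(all_calls)) {
    out <- .bind_calls(list())
    out$bp1_start <- out$bp1_end <- out$bp2_start <- out$bp2_end <- numeric(0)
    out$id <- character(0)
    return(out)
  }
  out <- do.call(rbind, all_calls)
  rownames(out) <- NULL
  out$id <- sprintf("%s_%s_%d", out$chromosome, out$class, seq_len(nrow(out)))
  pair_translocations(out)
}

#' Classify a haploid 5-FOA-resistant isolate from its diagnostic PCR pattern
#'
#' Four diagnostic products are scored: the left and right Ty-flank junction
#' products, the across-element product, and a product internal to the URA3
#' insertion. Classes: 1 = all products parental size (URA3 point change);
#' 2 = across-element product shortened to solo-delta size (pop-out);
#' 3 = junctions and across-element parental but URA3-internal absent
#' (conversion removing the insertion, element retained); 4 = both junction
#' products present but no across-element product (conversion associated
#' with a crossover rearranging the flanks). Anything else is
#' `"unclassified"`.
#'
#' @param pattern named list or vector with entries `left_junction`,
#'   `right_junction`, `across_element`, `ura3_internal`, each one of
#'   `"absent"`, `"present_parental_size"`, `"present_shorter"`.
#' @return integer class 1-4, or the string `"unclassified"`.
#' @export
classify_haploid_isolate <- function(pattern) {
  p <- as.list(pattern)
  need <- c("left_junction", "right_junction", "across_element",
            "ura3_internal")
  if (!all(need %in% names(p))) {
    stopf("pattern must name %s", paste(need, collapse = ", "))
  }
  ok <- c("absent", "present_parental_size", "present_shorter")
  for (f in need) {
    if (!p[[f]] %in% ok) stopf("invalid value '%s' for %s", p[[f]], f)
  }
  junctions_par <- p$left_junction == "present_parental_size" &&
    p$right_junction == "present_parental_size"
  if (p$across_element == "present_shorter" && junctions_par) return(2L)
  if (junctions_par && p$across_element == "absent") return(4L)
  if (junctions_par && p$across_element == "present_parental_size") {
    if (p$ura3_internal == "absent") return(3L)
    if (p$ura3_internal == "present_parental_size") return(1L)
  }
  "unclassified"
}
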