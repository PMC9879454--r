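# Composition of mechanisms into simulated isolates, plus the synthetic
# signals the downstream callers consume: per-SNP allele read counts,
# long-read diagnostic-SNP matrices over hybrid Ty elements, and
# Luria-Delbruck fluctuation assays.

#' Simulation parameters
#'
#' Default mechanism weights are proportional to the event tallies observed
#' across the combined long-term and transient induction cohorts (large
#' deletions 17, duplications 5, circles 2, isochromosomes 3, simple
#' translocations 23 split into unbalanced/BIR/balanced, I-LOH 28, T-LOH 29
#' split crossover/BIR, monosomy 17, trisomy 1, UPD 4, plus one pop-out,
#' one Ty-Ty conversion and three inversions detected by long reads).
#'
#' @param weights named nonnegative mechanism weights (sum > 0).
#' @param tract_mean_allelic mean allelic gene-conversion tract length (bp,
#'   geometric); governs I-LOH tract sizes.
#' @param tract_mean_ty mean Ty-internal conversion tract length (bp,
#'   geometric); governs hybrid-element tracts seen by long reads.
#' @param mean_depth mean total sequencing depth per SNP site.
#' @param depth_model `"poisson"` (default) or `"nbinom"`; allele counts for
#'   copy number c are drawn with mean `mean_depth/2 * c`.
#' @param nb_dispersion negative-binomial size parameter (only for
#'   `depth_model = "nbinom"`).
#' @param miscall probability a long read reports the wrong parent at a
#'   diagnostic SNP (0 <= miscall < 0.5).
#' @param missing_rate probability a long read has no call at a SNP.
#' @param ty2_partner_prob probability a Ty-Ty mechanism picks a Ty2 partner
#'   (default 5/124, the observed Ty1-Ty2 fraction of breakpoint pairs).
#' @param delta_partner_prob probability of a solo-delta partner (1/124).
#' @param tloh_w_loss_prob probability a terminal-LOH event loses the W
#'   (W303-1A-like) haplotype; default 24/25, the observed 24:1 bias.
#' @param seed integer seed.
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(weights = NULL,
                       tract_mean_allelic = 30000,
                       tract_mean_ty = 2000,
                       mean_depth = 40,
                       depth_model = c("poisson", "nbinom"),
                       nb_dispersion = 20,
                       miscall = 0.05,
                       missing_rate = 0.05,
                       ty2_partner_prob = 5 / 124,
                       delta_partner_prob = 1 / 124,
                       tloh_w_loss_prob = 24 / 25,
                       seed = NULL) {
  depth_model <- match.arg(depth_model)
  default_w <- c(
    SSA_popout = 1, conversion_noncrossover = 1,
    unequal_xover_del = 17, unequal_xover_dup = 5,
    intrachromatid_circle = 2, isochromosome = 3, inversion = 3,
    reciprocal_translocation_unbalanced = 18, BIR_translocation = 4,
    reciprocal_translocation_balanced = 1,
    allelic_crossover = 20, allelic_BIR = 9, allelic_conversion = 28,
    monosomy = 17, trisomy = 1, UPD = 4,
    sister_dicentric = 0
  )
  if (is.null(weights)) {
    weights <- default_w
  } else {
    w <- default_w * 0
    unknown <- setdiff(names(weights), names(w))
    if (length(unknown)) stopf("unknown mechanism '%s'", unknown[1])
    w[names(weights)] <- weights
    weights <- w
  }
  if (any(weights < 0) || sum(weights) <= 0) {
    stopf("mechanism weights must be nonnegative with positive sum")
  }
  if (mean_depth <= 0) stopf("mean_depth must be > 0")
  if (miscall < 0 || miscall >= 0.5) stopf("miscall must be in [0, 0.5)")
  structure(
    list(
      weights = weights,
      tract_mean_allelic = tract_mean_allelic,
      tract_mean_ty = tract_mean_ty,
      mean_depth = mean_depth, depth_model = depth_model,
      nb_dispersion = nb_dispersion,
      miscall = miscall, missing_rate = missing_rate,
      ty2_partner_prob = ty2_partner_prob,
      delta_partner_prob = delta_partner_prob,
      tloh_w_loss_prob = tloh_w_loss_prob,
      seed = seed
    ),
    class = "sim_params"
  )
}

# --- participant selection ---------------------------------------------------

# all Ty pairs eligible for a mechanism, as a data.frame of index pairs into
# genome$ty_elements (first element always carries the Cas9 target)
.eligible_pairs <- function(genome, mechanism, used_chroms) {
  ty <- genome$ty_elements
  arm <- vapply(seq_len(nrow(ty)), function(i) {
    position_arm(genome, ty$chromosome[i], ty$start[i])
  }, character(1))
  targets <- which(ty$has_cas9_target & !ty$chromosome %in% used_chroms)
  if (!length(targets)) return(NULL)
  out <- list()
  for (i in targets) {
    js <- switch(mechanism,
      unequal_xover_del = ,
      unequal_xover_dup = which(
        ty$homolog == ty$homolog[i] & ty$chromosome == ty$chromosome[i] &
          ty$orientation == ty$orientation[i] & arm == arm[i] &
          (ty$end < ty$start[i] | ty$start > ty$end[i])
      ),
      intrachromatid_circle = ,
      sister_dicentric = which(
        ty$homolog == ty$homolog[i] & ty$chromosome == ty$chromosome[i] &
          ty$orientation == ty$orientation[i] & arm != arm[i]
      ),
      isochromosome = which(
        ty$homolog == ty$homolog[i] & ty$chromosome == ty$chromosome[i] &
          ty$orientation != ty$orientation[i] & arm != arm[i]
      ),
      inversion = which(
        ty$homolog == ty$homolog[i] & ty$chromosome == ty$chromosome[i] &
          ty$orientation != ty$orientation[i] & arm == arm[i] &
          (ty$end < ty$start[i] | ty$start > ty$end[i])
      ),
      reciprocal_translocation_unbalanced = ,
      reciprocal_translocation_balanced = ,
      BIR_translocation = which(
        ty$chromosome != ty$chromosome[i] & arm == arm[i] &
          !ty$chromosome %in% used_chroms
      ),
      conversion_noncrossover = which(ty$id != ty$id[i])
    )
    js <- setdiff(js, i)
    if (length(js)) {
      out[[length(out) + 1L]] <- data.frame(i = i, j = js)
    }
  }
  if (!length(out)) NULL else do.call(rbind, out)
}

# choose one pair: partner family drawn per configured probabilities
.sample_pair <- function(genome, pairs, params) {
  ty <- genome$ty_elements
  fam <- ty$family[pairs$j]
  fam[fam == "truncated_Ty1"] <- "Ty1"
  probs <- c(
    Ty1 = 1 - params$ty2_partner_prob - params$delta_partner_prob,
    Ty2 = params$ty2_partner_prob,
    solo_delta = params$delta_partner_prob
  )
  avail <- intersect(names(probs), unique(fam))
  p <- probs[avail] / sum(probs[avail])
  cls <- sample(avail, 1L, prob = p)
  cand <- which(fam == cls)
  r <- pairs[cand[sample.int(length(cand), 1L)], ]
  list(a = ty$id[r$i], b = ty$id[r$j])
}

#' Simulate one isolate: a random composition of recombination mechanisms
#'
#' Draws `n_events` mechanisms by weight and applies each to the karyotype
#' with uniformly chosen eligible participants. Ty-Ty mechanisms pick a
#' Cas9-target-bearing Ty1 as the broken element and a partner whose family
#' follows the configured Ty1/Ty2/delta probabilities. Each event is placed
#' on chromosomes untouched by earlier events in the same isolate, so that
#' the expected dosage class of every truth record is well defined; if no
#' eligible participants remain after a bounded number of redraws the draw
#' is skipped (logged via `message()`).
#'
#' @param genome a `diploid_genome`.
#' @param params a [sim_params()] object.
#' @param n_events number of events to attempt (>= 0).
#' @param seed overrides `params$seed` when given.
#' @return `list(karyotype =, truth =)`; `truth` has one row per applied
#'   event (zero rows when `n_events = 0`).
#' @export
simulate_isolate <- function(genome, params = sim_params(), n_events = 3,
                             seed = params$seed) {
  if (n_events < 0) stopf("n_events must be >= 0")
  with_seed(seed, {
    k <- baseline_karyotype(genome)
    truth <- list()
    used <- character()
    mechs <- names(params$weights)
    for (ev in seq_len(n_events)) {
      placed <- FALSE
      for (try in 1:20) {
        mech <- sample(mechs, 1L, prob = params$weights)
        res <- tryCatch(
          .apply_mechanism(k, genome, mech, params, used),
          error = function(e) NULL
        )
        if (!is.null(res)) {
          k <- res$karyotype
          truth[[length(truth) + 1L]] <- res$truth
          used <- union(used, stats::na.omit(c(res$truth$chrom_a,
                                               res$truth$chrom_b)))
          placed <- TRUE
          break
        }
      }
      if (!placed) message("simulate_isolate: no eligible participants; ",
                           "event draw skipped")
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      truth_event("x", "x", "x")[0, ]
    list(karyotype = k, truth = truth)
  })
}

.apply_mechanism <- function(k, genome, mech, params, used) {
  free_chroms <- setdiff(genome$chromosomes$name, used)
  if (!length(free_chroms)) return(NULL)
  pick_chrom <- function() sample(free_chroms, 1L)
  if (mech %in% c("allelic_crossover", "allelic_BIR", "allelic_conversion")) {
    chrom <- pick_chrom()
    sn <- genome$snps[genome$snps$chromosome == chrom, ]
    if (!nrow(sn)) return(NULL)
    pos <- sn$position[sample.int(nrow(sn), 1L)] + 1L
    if (mech == "allelic_conversion") {
      lose <- sample(c("W", "Y"), 1L)
      tract <- stats::rgeom(1, 1 / params$tract_mean_allelic) + 1L
      return(apply_allelic_event(k, chrom, pos, "conversion",
                                 tract_len = tract, lose = lose))
    }
    lose <- sample(c("W", "Y"), 1L,
                   prob = c(params$tloh_w_loss_prob,
                            1 - params$tloh_w_loss_prob))
    kind <- if (mech == "allelic_BIR") "BIR" else "crossover"
    return(apply_allelic_event(k, chrom, pos, kind, lose = lose))
  }
  if (mech %in% c("monosomy", "trisomy", "UPD")) {
    chrom <- pick_chrom()
    return(apply_aneuploidy(k, chrom, kind = mech,
                            homolog = sample(c("W", "Y"), 1L)))
  }
  if (mech == "SSA_popout") {
    ty <- genome$ty_elements
    cand <- which(ty$has_cas9_target & ty$family %in% c("Ty1", "Ty2") &
                    !ty$chromosome %in% used)
    if (!length(cand)) return(NULL)
    return(apply_ssa_popout(k, ty$id[cand[sample.int(length(cand), 1L)]]))
  }
  pairs <- .eligible_pairs(genome, mech, used)
  if (is.null(pairs)) return(NULL)
  pr <- .sample_pair(genome, pairs, params)
  switch(mech,
    unequal_xover_del = apply_unequal_xover(k, pr$a, pr$b, "del"),
    unequal_xover_dup = apply_unequal_xover(k, pr$a, pr$b, "dup"),
    intrachromatid_circle = apply_intrachromatid_circle(k, pr$a, pr$b),
    isochromosome = apply_isochromosome(
      k, pr$a, pr$b, keep = sample(c("left", "right"), 1L)),
    inversion = apply_inversion(k, pr$a, pr$b),
    reciprocal_translocation_unbalanced = apply_translocation(
      k, pr$a, pr$b, "unbalanced",
      keep = sample(c("ab", "ba"), 1L)),
    reciprocal_translocation_balanced = apply_translocation(
      k, pr$a, pr$b, "balanced"),
    BIR_translocation = apply_bir_translocation(k, pr$a, pr$b),
    conversion_noncrossover = apply_ty_conversion(k, pr$a, pr$b),
    sister_dicentric = apply_sister_dicentric(k, pr$a, pr$b),
    stopf("unimplemented mechanism '%s'", mech)
  )
}

# --- read-depth signal -------------------------------------------------------

#' Synthesize per-SNP allele read counts from a copy-number profile
#'
#' For an allele at copy number `c`, the read count is Poisson with mean
#' `mean_depth/2 * c` (or negative binomial with that mean when
#' `depth_model = "nbinom"`), so an unaltered heterozygous site has expected
#' total coverage `mean_depth` and ratio-of-coverage 0.5 per allele.
#'
#' @param profile output of [copy_number_profile()] (or a karyotype, which
#'   is profiled first after checking all molecules are monocentric).
#' @param params a [sim_params()].
#' @param seed optional seed.
#' @return a `snp_dosage` data.frame with columns `chromosome`, `position`,
#'   `parental_class`, `read_count` (two rows per SNP site).
#' @export
synthesize_snp_counts <- function(profile, params = sim_params(),
                                  seed = params$seed) {
  if (inherits(profile, "karyotype")) {
    assert_monocentric(profile)
    profile <- copy_number_profile(profile)
  }
  with_seed(seed, {
    n <- nrow(profile)
    per_copy <- params$mean_depth / 2
    draw <- function(copies) {
      mu <- per_copy * copies
      cnt <- if (params$depth_model == "poisson") {
        stats::rpois(n, mu)
      } else {
        stats::rnbinom(n, size = params$nb_dispersion, mu = mu)
      }
      cnt[copies == 0] <- 0L
      cnt
    }
    out <- rbind(
      data.frame(
        chromosome = profile$chromosome, position = profile$position,
        parental_class = "W", read_count = draw(profile$w_copies),
        stringsAsFactors = FALSE
      ),
      data.frame(
        chromosome = profile$chromosome, position = profile$position,
        parental_class = "Y", read_count = draw(profile$y_copies),
        stringsAsFactors = FALSE
      )
    )
    out <- out[order(match(out$chromosome, unique(profile$chromosome)),
                     out$position, out$parental_class), ]
    rownames(out) <- NULL
    class(out) <- c("snp_dosage", "data.frame")
    out
  })
}

# --- long-read Ty matrices ---------------------------------------------------

#' Synthesize a long-read by diagnostic-SNP call matrix over a hybrid Ty
#'
#' The truth assigns every diagnostic SNP offset inside `true_tract` to the
#' donor parent `B` and the rest to recipient parent `A`. Each read reports
#' each SNP as the truth parent with probability `1 - miscall`, the other
#' parent otherwise, and is missing with probability `missing_rate`
#' (regenerated if a read would carry no calls at all).
#'
#' @param positions increasing diagnostic SNP offsets (bp within the
#'   element alignment).
#' @param true_tract `c(lo, hi)` donor-derived interval (bp), or `NULL` for
#'   no conversion tract.
#' @param dsb_offset Cas9 cut offset within the element.
#' @param n_reads number of reads.
#' @param miscall per-call error probability.
#' @param missing_rate per-call missing probability.
#' @param seed optional seed.
#' @param parents labels for the two parental elements.
#' @return an object of class `ty_read_matrix`.
#' @export
synthesize_ty_reads <- function(positions, true_tract, dsb_offset,
                                n_reads = 15, miscall = 0.05,
                                missing_rate = 0.05, seed = NULL,
                                parents = c("A", "B")) {
  if (is.unsorted(positions, strictly = TRUE)) {
    stopf("diagnostic SNP positions must be strictly increasing")
  }
  truth <- rep("A", length(positions))
  if (!is.null(true_tract)) {
    truth[positions >= true_tract[1] & positions <= true_tract[2]] <- "B"
  }
  with_seed(seed, {
    m <- matrix(NA_character_, nrow = n_reads, ncol = length(positions))
    for (r in seq_len(n_reads)) {
      repeat {
        flip <- stats::runif(length(positions)) < miscall
        call <- ifelse(flip, ifelse(truth == "A", "B", "A"), truth)
        call[stats::runif(length(positions)) < missing_rate] <- NA
        if (any(!is.na(call)) || length(positions) == 0) break
      }
      m[r, ] <- call
    }
    structure(
      list(positions = as.integer(positions), calls = m,
           dsb_offset = as.integer(dsb_offset), parents = parents,
           truth = truth),
      class = "ty_read_matrix"
    )
  })
}

#' @export
print.ty_read_matrix <- function(x, ...) {
  cat(sprintf("<ty_read_matrix> %d reads x %d diagnostic SNPs, DSB at %d bp\n",
              nrow(x$calls), length(x$positions), x$dsb_offset))
  invisible(x)
}

# --- fluctuation assays ------------------------------------------------------

#' Simulate a Luria-Delbruck fluctuation experiment
#'
#' Each culture grows from one cell to `N_t` cells by synchronous doublings.
#' At generation g, each of the `2^(g-1)` dividing cells acquires a mutation
#' with probability `rate_per_division`; a mutant arising at generation g
#' expands clonally to `2^(G-g)` cells by the end (mutation of already-mutant
#' lineages is ignored; `rate_per_division` is assumed small).
#'
#' @param rate_per_division mutation probability per cell division.
#' @param N_t final cells per culture; rounded up to the next power of two
#'   (with a message) if not already one.
#' @param n_cultures number of parallel cultures.
#' @param seed optional seed.
#' @return an object of class `fluctuation_experiment` with fields `counts`
#'   (per-culture mutant counts) and `N_t`.
#' @export
simulate_fluctuation <- function(rate_per_division, N_t, n_cultures,
                                 seed = NULL) {
  if (rate_per_division < 0) stopf("rate must be >= 0")
  if (N_t <= 0) stopf("N_t must be > 0")
  G <- ceiling(log2(N_t))
  if (2^G != N_t) {
    message(sprintf("N_t = %s is not a power of 2; using 2^%d", N_t, G))
  }
  with_seed(seed, {
    counts <- integer(n_cultures)
    for (g in seq_len(G)) {
      muts <- stats::rbinom(n_cultures, 2^(g - 1), rate_per_division)
      counts <- counts + muts * 2^(G - g)
    }
    structure(
      list(counts = counts, N_t = 2^G,
           rate_true = rate_per_division),
      class = "fluctuation_experiment"
    )
  })
}

#' @export
print.fluctuation_experiment <- function(x, ...) {
  cat(sprintf(
    "<fluctuation_experiment> %d cultures, N_t = %s; median r = %s, mean = %.2f\n",
    length(x$counts), format(x$N_t, big.mark = ","),
    stats::median(x$counts), mean(x$counts)
  ))
  invisible(x)
}
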