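# Hybrid diploid genome model: chromosomes, heterozygous SNP map, and
# per-homolog Ty/delta annotations. All internal coordinates are 1-based
# inclusive; BED output is converted at the I/O boundary.

# S. cerevisiae reference chromosome lengths (sacCer3) and centromere spans.
# Used as the length profile for the simulated genome; Ty and SNP positions
# are synthetic and do not reproduce any real annotation.
.SC_CHROM_LENGTHS <- c(
  I = 230218L, II = 813184L, III = 316620L, IV = 1531933L,
  V = 576874L, VI = 270161L, VII = 1090940L, VIII = 562643L,
  IX = 439888L, X = 745751L, XI = 666816L, XII = 1078177L,
  XIII = 924431L, XIV = 784333L, XV = 1091291L, XVI = 948066L
)

.SC_CEN_START <- c(
  I = 151465L, II = 238207L, III = 114385L, IV = 449711L,
  V = 151987L, VI = 148510L, VII = 496920L, VIII = 105586L,
  IX = 355629L, X = 436307L, XI = 440129L, XII = 150828L,
  XIII = 268031L, XIV = 628758L, XV = 326584L, XVI = 555957L
)

.SC_CEN_END <- c(
  I = 151582L, II = 238323L, III = 114501L, IV = 449821L,
  V = 152104L, VI = 148627L, VII = 497038L, VIII = 105703L,
  IX = 355745L, X = 436425L, XI = 440246L, XII = 150947L,
  XIII = 268149L, XIV = 628875L, XV = 326702L, XVI = 556073L
)

# Ty element span limits (bp): full Ty1/Ty2 elements, LTR-inclusive, fall in
# roughly 5.9-6.3 kb; a solo delta (long terminal repeat) is 330 bp.
.TY_SPAN_MIN <- 5900L
.TY_SPAN_MAX <- 6300L
.DELTA_SPAN <- 330L

#' Chromosome definitions for a genome profile
#'
#' @param profile `"full"` uses the 16 S. cerevisiae reference chromosome
#'   lengths (about 12 Mb per haploid set); `"mini"` scales every chromosome
#'   into the 100-500 kb range for fast tests.
#' @return data.frame with columns `name`, `length`, `cen_start`, `cen_end`.
#' @export
chromosome_table <- function(profile = c("full", "mini")) {
  profile <- match.arg(profile)
  len <- .SC_CHROM_LENGTHS
  cs <- .SC_CEN_START
  ce <- .SC_CEN_END
  if (profile == "mini") {
    scaled <- pmin(500000, pmax(100000, round(len / 3)))
    f <- scaled / len
    cs <- pmax(2L, as.integer(round(cs * f)))
    ce <- cs + 120L
    len <- as.integer(scaled)
  }
  data.frame(
    name = names(.SC_CHROM_LENGTHS),
    length = as.integer(len),
    cen_start = as.integer(cs),
    cen_end = as.integer(ce),
    stringsAsFactors = FALSE
  )
}

ty_id <- function(homolog, chrom, arm, orientation, family, index) {
  fam <- switch(family,
    Ty1 = "Ty1", Ty2 = "Ty2",
    solo_delta = "D", truncated_Ty1 = "tTy1"
  )
  sprintf(
    "%s-%s%s-%s%s-%d", homolog, chrom, arm,
    if (orientation == "Watson") "W" else "C", fam, index
  )
}

# place `n` non-overlapping elements of given spans on one homolog set,
# avoiding centromeres and chromosome ends.  Returns a data.frame of spans.
.place_elements <- function(chroms, n, span_fun, homolog, family,
                            occupied, margin = 5000L) {
  out <- vector("list", n)
  k <- 0L
  guard <- 0L
  while (k < n) {
    guard <- guard + 1L
    if (guard > 50000L) stopf("could not place %d %s elements", n, family)
    ci <- sample.int(nrow(chroms), 1L, prob = chroms$length)
    cd <- chroms[ci, ]
    span <- span_fun()
    lo <- margin
    hi <- cd$length - margin - span
    if (hi <= lo) next
    start <- as.integer(floor(stats::runif(1, lo, hi)))
    end <- start + span - 1L
    # keep clear of the centromere
    if (start <= cd$cen_end + 1000L && end >= cd$cen_start - 1000L) next
    prev <- occupied[[cd$name]]
    if (!is.null(prev) &&
        any(start <= prev$end + 100L & end >= prev$start - 100L)) {
      next
    }
    k <- k + 1L
    row <- data.frame(
      chromosome = cd$name, start = start, end = end,
      stringsAsFactors = FALSE
    )
    occupied[[cd$name]] <- rbind(prev, row)
    out[[k]] <- row
  }
  list(spans = do.call(rbind, out), occupied = occupied)
}

#' Build the default hybrid diploid genome
#'
#' Emulates a W303-1A x YJM789-like hybrid diploid: one parental set of
#' homologs (class `W`) carries 37 full Ty1 and 15 Ty2 elements, the other
#' (class `Y`) 17 Ty1 and 9 Ty2, placed uniformly at random outside
#' centromeres so that most positions are non-allelic between the two sets.
#' Heterozygous SNPs are placed quasi-uniformly (jittered grid, so the
#' largest inter-SNP gap is bounded) outside Ty spans. All full Ty1 elements
#' carry the Cas9 target; Ty2 and solo delta elements do not.
#'
#' @param seed integer seed; the genome is deterministic given the seed.
#' @param n_snps number of heterozygous SNPs (default 55000 for the full
#'   profile; the mini profile defaults to 2000).
#' @param profile `"full"` (about 12 Mb per haploid set) or `"mini"`
#'   (100-500 kb chromosomes, for fast tests).
#' @param n_ty1,n_ty2 named counts of full elements per homolog class,
#'   e.g. `c(W = 37, Y = 17)`.
#' @param n_solo_delta named counts of solo delta (330 bp LTR) elements.
#' @param dsb_offset bp from the 5' end of the element to the Cas9 cut site
#'   (default 2180).
#' @return an object of class `diploid_genome`: a list with `chromosomes`,
#'   `snps`, `ty_elements`, `dsb_offset`, `profile`.
#' @export
default_hybrid_genome <- function(seed, n_snps = NULL,
                                  profile = c("full", "mini"),
                                  n_ty1 = c(W = 37, Y = 17),
                                  n_ty2 = c(W = 15, Y = 9),
                                  n_solo_delta = c(W = 40, Y = 40),
                                  dsb_offset = 2180L) {
  profile <- match.arg(profile)
  if (is.null(n_snps)) n_snps <- if (profile == "full") 55000L else 2000L
  if (n_snps < 0) stopf("n_snps must be >= 0, got %s", n_snps)
  chroms <- chromosome_table(profile)
  with_seed(seed, {
    ty <- list()
    for (homolog in c("W", "Y")) {
      occupied <- list()
      specs <- list(
        list(family = "Ty1", n = n_ty1[[homolog]],
             span = function() sample(.TY_SPAN_MIN:.TY_SPAN_MAX, 1L)),
        list(family = "Ty2", n = n_ty2[[homolog]],
             span = function() sample(.TY_SPAN_MIN:.TY_SPAN_MAX, 1L)),
        list(family = "solo_delta", n = n_solo_delta[[homolog]],
             span = function() .DELTA_SPAN)
      )
      for (sp in specs) {
        if (sp$n == 0) next
        placed <- .place_elements(chroms, sp$n, sp$span, homolog, sp$family,
                                  occupied)
        occupied <- placed$occupied
        spans <- placed$spans
        ori <- sample(c("Watson", "Crick"), nrow(spans), replace = TRUE)
        cen_mid <- (chroms$cen_start + chroms$cen_end) / 2
        arm <- ifelse(
          spans$start < cen_mid[match(spans$chromosome, chroms$name)],
          "L", "R"
        )
        key <- paste(spans$chromosome, arm)
        idx <- stats::ave(seq_len(nrow(spans)), key, FUN = seq_along)
        ids <- mapply(ty_id, homolog, spans$chromosome, arm, ori,
                      sp$family, idx)
        ty[[length(ty) + 1L]] <- data.frame(
          id = unname(ids), family = sp$family, orientation = ori,
          homolog = homolog, chromosome = spans$chromosome,
          start = spans$start, end = spans$end,
          has_cas9_target = sp$family == "Ty1",
          stringsAsFactors = FALSE
        )
      }
    }
    ty <- do.call(rbind, ty)
    rownames(ty) <- NULL

    snps <- .place_snps(chroms, ty, n_snps)

    genome <- structure(
      list(
        chromosomes = chroms, snps = snps, ty_elements = ty,
        dsb_offset = as.integer(dsb_offset), profile = profile
      ),
      class = "diploid_genome"
    )
    validate_genome(genome)
    genome
  })
}

# quasi-uniform SNP placement: per-chromosome allocation proportional to
# length, one SNP jittered inside each grid cell, nudged out of Ty spans.
.place_snps <- function(chroms, ty, n_snps) {
  if (n_snps == 0) {
    return(data.frame(
      chromosome = character(), position = integer(),
      w_allele = character(), y_allele = character(),
      stringsAsFactors = FALSE
    ))
  }
  alloc <- floor(n_snps * as.numeric(chroms$length) /
                   sum(as.numeric(chroms$length)))
  rem <- n_snps - sum(alloc)
  if (rem > 0) {
    extra <- order(chroms$length, decreasing = TRUE)[seq_len(rem)]
    alloc[extra] <- alloc[extra] + 1L
  }
  bases <- c("A", "C", "G", "T")
  res <- vector("list", nrow(chroms))
  for (i in seq_len(nrow(chroms))) {
    n <- alloc[i]
    if (n == 0) next
    len <- chroms$length[i]
    cell <- len / n
    pos <- as.integer(floor((seq_len(n) - stats::runif(n)) * cell)) + 1L
    spans <- ty[ty$chromosome == chroms$name[i], , drop = FALSE]
    if (nrow(spans) > 0) {
      for (tries in 1:5) {
        inside <- rep(FALSE, n)
        hit_end <- integer(n)
        for (j in seq_len(nrow(spans))) {
          in_j <- pos >= spans$start[j] & pos <= spans$end[j]
          inside <- inside | in_j
          hit_end[in_j] <- spans$end[j]
        }
        if (!any(inside)) break
        pos[inside] <- hit_end[inside] + 1L +
          as.integer(floor(stats::runif(sum(inside), 0, 200)))
      }
    }
    pos <- pmin(pmax(pos, 1L), len)
    pos <- sort(pos)
    while (any(dup <- duplicated(pos))) pos[dup] <- pos[dup] + 1L
    pos <- sort(pmin(pos, len))
    w <- sample(bases, n, replace = TRUE)
    y <- vapply(w, function(b) sample(setdiff(bases, b), 1L), character(1))
    res[[i]] <- data.frame(
      chromosome = chroms$name[i], position = pos,
      w_allele = w, y_allele = unname(y), stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Validate a diploid genome object
#'
#' Checks the structural invariants: unique chromosome names, centromeres
#' inside chromosomes, elements and SNPs within bounds and on defined
#' chromosomes, SNPs outside Ty spans, element spans consistent with family,
#' and no overlapping elements on the same homolog.
#'
#' @param genome a `diploid_genome`.
#' @return the genome, invisibly; errors describe the first violation.
#' @export
validate_genome <- function(genome) {
  ch <- genome$chromosomes
  if (anyDuplicated(ch$name)) stopf("duplicated chromosome names")
  bad <- which(!(ch$cen_start > 0 & ch$cen_start < ch$cen_end &
                   ch$cen_end <= ch$length))
  if (length(bad)) {
    stopf("chromosome %s: centromere outside 0 < start < end <= length",
          ch$name[bad[1]])
  }
  ty <- genome$ty_elements
  if (nrow(ty)) {
    m <- match(ty$chromosome, ch$name)
    if (anyNA(m)) {
      stopf("Ty element %s references unknown chromosome %s",
            ty$id[which(is.na(m))[1]], ty$chromosome[which(is.na(m))[1]])
    }
    bad <- which(!(ty$end > ty$start & ty$start >= 1 &
                     ty$end <= ch$length[m]))
    if (length(bad)) stopf("Ty element %s outside chromosome bounds",
                           ty$id[bad[1]])
    span <- ty$end - ty$start + 1L
    full <- ty$family %in% c("Ty1", "Ty2")
    bad <- which(full & (span < .TY_SPAN_MIN - 100 | span > .TY_SPAN_MAX + 100))
    if (length(bad)) stopf("element %s: full Ty span %d bp out of range",
                           ty$id[bad[1]], span[bad[1]])
    bad <- which(ty$family == "solo_delta" & span != .DELTA_SPAN)
    if (length(bad)) stopf("element %s: solo delta must span %d bp",
                           ty$id[bad[1]], .DELTA_SPAN)
    bad <- which(ty$has_cas9_target &
                   !ty$family %in% c("Ty1", "truncated_Ty1"))
    if (length(bad)) stopf("element %s: Cas9 target only on (truncated) Ty1",
                           ty$id[bad[1]])
    for (key in unique(paste(ty$homolog, ty$chromosome))) {
      sub <- ty[paste(ty$homolog, ty$chromosome) == key, , drop = FALSE]
      sub <- sub[order(sub$start), , drop = FALSE]
      if (nrow(sub) > 1 &&
          any(sub$start[-1] <= sub$end[-nrow(sub)])) {
        stopf("overlapping Ty elements on homolog %s", key)
      }
    }
  }
  sn <- genome$snps
  if (nrow(sn)) {
    m <- match(sn$chromosome, ch$name)
    if (anyNA(m)) stopf("SNP references unknown chromosome %s",
                        sn$chromosome[which(is.na(m))[1]])
    bad <- which(sn$position < 1 | sn$position > ch$length[m])
    if (length(bad)) stopf("SNP %s:%d outside chromosome",
                           sn$chromosome[bad[1]], sn$position[bad[1]])
    if (anyDuplicated(paste(sn$chromosome, sn$position))) {
      stopf("duplicated SNP positions")
    }
    if (any(sn$w_allele == sn$y_allele)) stopf("SNP with identical alleles")
    for (i in seq_len(nrow(ty))) {
      hit <- sn$chromosome == ty$chromosome[i] &
        sn$position >= ty$start[i] & sn$position <= ty$end[i]
      if (any(hit)) {
        stopf("SNP %s:%d falls inside Ty element %s",
              sn$chromosome[hit][1], sn$position[hit][1], ty$id[i])
      }
    }
  }
  invisible(genome)
}

#' @export
print.diploid_genome <- function(x, ...) {
  fam <- table(x$ty_elements$homolog, x$ty_elements$family)
  cat(sprintf(
    "<diploid_genome> %s profile: %d chromosomes (%.2f Mb), %d het SNPs\n",
    x$profile, nrow(x$chromosomes), sum(x$chromosomes$length) / 1e6,
    nrow(x$snps)
  ))
  cat("Ty elements per homolog class:\n")
  print(fam)
  invisible(x)
}

ty_lookup <- function(genome, id) {
  i <- match(id, genome$ty_elements$id)
  if (is.na(i)) stopf("unknown Ty element id '%s'", id)
  genome$ty_elements[i, ]
}

chrom_lookup <- function(genome, name) {
  i <- match(name, genome$chromosomes$name)
  if (is.na(i)) stopf("unknown chromosome '%s'", name)
  genome$chromosomes[i, ]
}

# arm of a position relative to the centromere midpoint: "L" or "R"
position_arm <- function(genome, chrom, pos) {
  cd <- chrom_lookup(genome, chrom)
  if (pos < (cd$cen_start + cd$cen_end) / 2) "L" else "R"
}
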