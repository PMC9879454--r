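# Mechanism operations on karyotypes. Every operation returns
# list(karyotype =, truth =) where `truth` is a one-row truth-event record
# describing the mechanism, its participants, the dosage class the event is
# expected to produce (or "silent"), the affected spans in parental
# coordinates, and the true breakpoint position(s).
#
# NAHR junctions are modeled at the element 5' boundary: because the
# heterozygous SNP map excludes Ty-internal positions, any junction placed
# inside the recombining elements yields the same SNP dosage profile.

truth_event <- function(mechanism, participants, expected_call_class,
                        chrom_a = NA, homolog_a = NA, class_a = NA,
                        span_a = c(NA, NA), bp_a = NA,
                        chrom_b = NA, homolog_b = NA, class_b = NA,
                        span_b = c(NA, NA), bp_b = NA) {
  data.frame(
    mechanism = mechanism,
    participants = paste(participants, collapse = ","),
    expected_call_class = expected_call_class,
    chrom_a = chrom_a, homolog_a = homolog_a, class_a = class_a,
    span_a_start = as.integer(span_a[1]), span_a_end = as.integer(span_a[2]),
    bp_a = as.integer(bp_a),
    chrom_b = chrom_b, homolog_b = homolog_b, class_b = class_b,
    span_b_start = as.integer(span_b[1]), span_b_end = as.integer(span_b[2]),
    bp_b = as.integer(bp_b),
    stringsAsFactors = FALSE
  )
}

.snps_in <- function(genome, chrom, lo, hi) {
  sn <- genome$snps
  sum(sn$chromosome == chrom & sn$position >= lo & sn$position <= hi)
}

.require_pair <- function(a, b) {
  if (a$id == b$id) stopf("the two Ty elements must be distinct")
}

.get_ty <- function(genome, ty) {
  if (is.character(ty)) ty_lookup(genome, ty) else ty
}

#' Replace a full Ty element by a solo delta (SSA pop-out)
#'
#' Single-strand annealing between the two flanking 330-bp LTRs excises the
#' element body, leaving one solo delta. The SNP dosage profile is unchanged
#' (dosage-silent) because heterozygous SNPs never fall inside Ty spans.
#'
#' @param k a `karyotype`.
#' @param ty a Ty element id (or row of `genome$ty_elements`); must be a full
#'   Ty1/Ty2 still present on a molecule of `k`.
#' @return `list(karyotype, truth)`.
#' @export
apply_ssa_popout <- function(k, ty) {
  ty <- .get_ty(k$genome, ty)
  if (ty$family == "solo_delta") {
    stopf("element %s is already a solo delta", ty$id)
  }
  if (!ty$family %in% c("Ty1", "Ty2")) {
    stopf("SSA pop-out requires a full Ty element, got %s", ty$family)
  }
  body_start <- ty$start + 330L     # keep one LTR
  mi <- find_molecule(k, ty$homolog, ty$chromosome, body_start)
  if (is.na(mi)) {
    stopf("element %s: internal span not present (already popped out?)",
          ty$id)
  }
  mol <- k$molecules[[mi]]
  s1 <- split_molecule(mol, ty$homolog, ty$chromosome, body_start)
  rest <- new_molecule("tmp", s1$post)
  s2 <- split_molecule(rest, ty$homolog, ty$chromosome, ty$end + 1L)
  if (is.null(s2)) stopf("element %s: 3' flank not present", ty$id)
  mol$segments <- rbind(s1$pre, s2$post)
  rownames(mol$segments) <- NULL
  k$molecules[[mi]] <- mol
  list(
    karyotype = k,
    truth = truth_event("SSA_popout", ty$id, "silent",
                        chrom_a = ty$chromosome, homolog_a = ty$homolog,
                        bp_a = ty$start)
  )
}

#' Unequal crossover between direct-repeat Ty elements on one homolog
#'
#' Both elements must lie on the same homolog, same chromosome, in the same
#' orientation. `keep = "del"` removes the inter-element interval
#' (interstitial deletion); `keep = "dup"` duplicates it in tandem
#' (interstitial duplication). The event is recorded as `"silent"` when no
#' heterozygous SNP falls in the interval.
#'
#' @param k a `karyotype`.
#' @param ty_a,ty_b element ids or annotation rows.
#' @param keep `"del"` or `"dup"`.
#' @return `list(karyotype, truth)`.
#' @export
apply_unequal_xover <- function(k, ty_a, ty_b, keep = c("del", "dup")) {
  keep <- match.arg(keep)
  a <- .get_ty(k$genome, ty_a); b <- .get_ty(k$genome, ty_b)
  .require_pair(a, b)
  if (a$homolog != b$homolog || a$chromosome != b$chromosome) {
    stopf("unequal crossover requires elements on one homolog molecule")
  }
  if (a$orientation != b$orientation) {
    stopf("elements in opposite orientation: use apply_inversion()")
  }
  if (a$start > b$start) { tmp <- a; a <- b; b <- tmp }
  if (a$end >= b$start) stopf("elements overlap")
  cd <- chrom_lookup(k$genome, a$chromosome)
  if (a$start <= cd$cen_end && b$start >= cd$cen_start) {
    stopf(paste("inter-element interval contains the centromere:",
                "use apply_intrachromatid_circle()"))
  }
  cut_a <- a$start; cut_b <- b$start
  mi <- find_molecule(k, a$homolog, a$chromosome, cut_a)
  if (is.na(mi)) stopf("element %s not present in karyotype", a$id)
  mol <- k$molecules[[mi]]
  if (keep == "del") {
    s1 <- split_molecule(mol, a$homolog, a$chromosome, cut_a)
    s2 <- split_molecule(new_molecule("tmp", s1$post),
                         a$homolog, a$chromosome, cut_b)
    if (is.null(s2)) stopf("element %s not on the same molecule", b$id)
    mol$segments <- rbind(s1$pre, s2$post)
    cls <- "I-DEL"
  } else {
    s1 <- split_molecule(mol, a$homolog, a$chromosome, cut_b)
    s2 <- split_molecule(mol, a$homolog, a$chromosome, cut_a)
    mol$segments <- rbind(s1$pre, s2$post)
    cls <- "I-DUP"
  }
  rownames(mol$segments) <- NULL
  k$molecules[[mi]] <- mol
  n_snp <- .snps_in(k$genome, a$chromosome, cut_a, cut_b - 1L)
  list(
    karyotype = k,
    truth = truth_event(
      if (keep == "del") "unequal_xover_del" else "unequal_xover_dup",
      c(a$id, b$id),
      if (n_snp > 0) cls else "silent",
      chrom_a = a$chromosome, homolog_a = a$homolog, class_a = cls,
      span_a = c(cut_a, cut_b - 1L), bp_a = cut_a, bp_b = cut_b,
      chrom_b = a$chromosome
    )
  )
}

#' Intrachromatid crossover producing a centric circle (double T-DEL)
#'
#' Requires two directly-oriented elements on opposite arms of one homolog.
#' The centromere-containing circular molecule is retained; both acentric
#' linear arms are lost, producing terminal zero-copy regions on both arms
#' of that homolog.
#'
#' @inheritParams apply_unequal_xover
#' @return `list(karyotype, truth)`.
#' @export
apply_intrachromatid_circle <- function(k, ty_a, ty_b) {
  a <- .get_ty(k$genome, ty_a); b <- .get_ty(k$genome, ty_b)
  .require_pair(a, b)
  if (a$homolog != b$homolog || a$chromosome != b$chromosome) {
    stopf("circle formation requires elements on one homolog molecule")
  }
  cd <- chrom_lookup(k$genome, a$chromosome)
  arm_a <- position_arm(k$genome, a$chromosome, a$start)
  arm_b <- position_arm(k$genome, b$chromosome, b$start)
  if (arm_a == arm_b) stopf("elements on the same arm cannot form a circle")
  if (a$orientation != b$orientation) {
    stopf("circle formation requires directly-oriented elements")
  }
  if (a$start > b$start) { tmp <- a; a <- b; b <- tmp }
  cut_l <- a$start; cut_r <- b$start
  mi <- find_molecule(k, a$homolog, a$chromosome, cut_l)
  if (is.na(mi)) stopf("element %s not present in karyotype", a$id)
  mol <- k$molecules[[mi]]
  s1 <- split_molecule(mol, a$homolog, a$chromosome, cut_l)
  s2 <- split_molecule(new_molecule("tmp", s1$post),
                       a$homolog, a$chromosome, cut_r)
  if (is.null(s2)) stopf("element %s not on the same molecule", b$id)
  mol$segments <- s2$pre
  rownames(mol$segments) <- NULL
  mol$circular <- TRUE
  k$molecules[[mi]] <- mol
  if (molecule_cen_count(mol, k$genome) != 1L) {
    stopf("circle junction does not retain exactly one centromere")
  }
  n_snp <- .snps_in(k$genome, a$chromosome, 1L, cut_l - 1L) +
    .snps_in(k$genome, a$chromosome, cut_r, cd$length)
  list(
    karyotype = k,
    truth = truth_event(
      "intrachromatid_circle", c(a$id, b$id),
      if (n_snp > 0) "CIRCLE" else "silent",
      chrom_a = a$chromosome, homolog_a = a$homolog, class_a = "CIRCLE",
      span_a = c(1L, cut_l - 1L), bp_a = cut_l,
      chrom_b = a$chromosome, homolog_b = a$homolog,
      span_b = c(cut_r, cd$length), bp_b = cut_r
    )
  )
}

#' Isochromosome formation from inverted elements on opposite arms
#'
#' A crossover between inverted-orientation Ty elements on opposite arms of
#' one homolog yields two monocentric isochromosomes; one is retained. The
#' kept product mirrors one arm's distal material (terminal duplication) and
#' loses the other arm's (terminal deletion) on the same chromosome.
#'
#' @inheritParams apply_unequal_xover
#' @param keep `"left"` duplicates the left-arm distal material and deletes
#'   the right arm's; `"right"` the converse.
#' @return `list(karyotype, truth)`.
#' @export
apply_isochromosome <- function(k, ty_a, ty_b, keep = c("left", "right")) {
  keep <- match.arg(keep)
  a <- .get_ty(k$genome, ty_a); b <- .get_ty(k$genome, ty_b)
  .require_pair(a, b)
  if (a$homolog != b$homolog || a$chromosome != b$chromosome) {
    stopf("isochromosome formation requires elements on one homolog")
  }
  arm_a <- position_arm(k$genome, a$chromosome, a$start)
  arm_b <- position_arm(k$genome, b$chromosome, b$start)
  if (arm_a == arm_b) stopf("elements on the same arm cannot form an isochromosome")
  if (a$orientation == b$orientation) {
    stopf("isochromosome formation requires inverted-orientation elements")
  }
  if (a$start > b$start) { tmp <- a; a <- b; b <- tmp }
  cd <- chrom_lookup(k$genome, a$chromosome)
  cut_l <- a$start; cut_r <- b$start
  mi <- find_molecule(k, a$homolog, a$chromosome, cut_l)
  if (is.na(mi)) stopf("element %s not present in karyotype", a$id)
  mol <- k$molecules[[mi]]
  sl <- split_molecule(mol, a$homolog, a$chromosome, cut_l)
  sr <- split_molecule(mol, a$homolog, a$chromosome, cut_r)
  if (is.null(sr)) stopf("element %s not on the same molecule", b$id)
  if (keep == "left") {
    # prefix to left cut + mirrored prefix to right cut (carries centromere)
    segs <- rbind(sl$pre, rev_segments(sr$pre))
    dup_span <- c(1L, cut_l - 1L); del_span <- c(cut_r, cd$length)
  } else {
    segs <- rbind(rev_segments(sr$post), sl$post)
    dup_span <- c(cut_r, cd$length); del_span <- c(1L, cut_l - 1L)
  }
  mol$segments <- segs
  rownames(mol$segments) <- NULL
  k$molecules[[mi]] <- mol
  if (molecule_cen_count(mol, k$genome) != 1L) {
    stopf("isochromosome product is not monocentric")
  }
  n_vis <- .snps_in(k$genome, a$chromosome, dup_span[1], dup_span[2]) +
    .snps_in(k$genome, a$chromosome, del_span[1], del_span[2])
  list(
    karyotype = k,
    truth = truth_event(
      "isochromosome", c(a$id, b$id),
      if (n_vis > 0) "ISO" else "silent",
      chrom_a = a$chromosome, homolog_a = a$homolog, class_a = "T-DUP",
      span_a = dup_span, bp_a = if (keep == "left") cut_l else cut_r,
      chrom_b = a$chromosome, homolog_b = a$homolog, class_b = "T-DEL",
      span_b = del_span, bp_b = if (keep == "left") cut_r else cut_l
    )
  )
}

#' Inversion between inverted-repeat elements on one arm
#'
#' Reverses the segment between the two elements. Dosage-silent: sequence
#' coverage of every SNP is unchanged, only adjacencies change (two novel
#' junctions). Applying the operation twice restores the original order.
#'
#' @inheritParams apply_unequal_xover
#' @return `list(karyotype, truth)`.
#' @export
apply_inversion <- function(k, ty_a, ty_b) {
  a <- .get_ty(k$genome, ty_a); b <- .get_ty(k$genome, ty_b)
  .require_pair(a, b)
  if (a$homolog != b$homolog || a$chromosome != b$chromosome) {
    stopf("inversion requires elements on one homolog molecule")
  }
  if (a$orientation == b$orientation) {
    stopf("direct-orientation elements: use apply_unequal_xover()")
  }
  arm_a <- position_arm(k$genome, a$chromosome, a$start)
  arm_b <- position_arm(k$genome, b$chromosome, b$start)
  if (arm_a != arm_b) stopf("inversion requires elements on the same arm")
  if (a$start > b$start) { tmp <- a; a <- b; b <- tmp }
  cut_a <- a$start; cut_b <- b$start
  mi <- find_molecule(k, a$homolog, a$chromosome, cut_a)
  if (is.na(mi)) stopf("element %s not present in karyotype", a$id)
  mol <- k$molecules[[mi]]
  blk <- extract_block(mol, a$homolog, a$chromosome, cut_a, cut_b - 1L)
  mol$segments <- normalize_segments(
    rbind(blk$pre, rev_segments(blk$block), blk$post)
  )
  k$molecules[[mi]] <- mol
  list(
    karyotype = k,
    truth = truth_event("inversion", c(a$id, b$id), "silent",
                        chrom_a = a$chromosome, homolog_a = a$homolog,
                        span_a = c(cut_a, cut_b - 1L),
                        bp_a = cut_a, bp_b = cut_b)
  )
}

# centromere count of a bare segment list
.segs_cen_count <- function(segs, genome) {
  molecule_cen_count(list(segments = segs), genome)
}

#' Reciprocal translocation between Ty elements on non-homologous chromosomes
#'
#' `segregation = "balanced"`: both recombinant molecules replace the two
#' participating molecules (dosage-silent). `"unbalanced"`: one monocentric
#' recombinant is retained together with an intact copy of the chromosome
#' donating its distal (suffix) part, while the molecule donating the
#' centromere-proximal (prefix) part is lost; this yields a terminal deletion
#' on the prefix donor and a terminal duplication on the suffix donor.
#' Junction orientation within the elements is abstracted; eligibility
#' requires the two cut sites to lie on the same arm type so that both
#' recombinants are monocentric.
#'
#' @inheritParams apply_unequal_xover
#' @param segregation `"balanced"` or `"unbalanced"`.
#' @param keep for unbalanced events, which recombinant is retained:
#'   `"ab"` (prefix of `ty_a`'s chromosome + suffix of `ty_b`'s) or `"ba"`.
#' @return `list(karyotype, truth)`.
#' @export
apply_translocation <- function(k, ty_a, ty_b,
                                segregation = c("unbalanced", "balanced"),
                                keep = c("ab", "ba")) {
  segregation <- match.arg(segregation)
  keep <- match.arg(keep)
  a <- .get_ty(k$genome, ty_a); b <- .get_ty(k$genome, ty_b)
  .require_pair(a, b)
  if (a$chromosome == b$chromosome) {
    stopf(paste("elements on (homologs of) the same chromosome:",
                "use the allelic or intrachromosomal operations"))
  }
  cut_a <- a$start; cut_b <- b$start
  mia <- find_molecule(k, a$homolog, a$chromosome, cut_a)
  mib <- find_molecule(k, b$homolog, b$chromosome, cut_b)
  if (is.na(mia)) stopf("element %s not present in karyotype", a$id)
  if (is.na(mib)) stopf("element %s not present in karyotype", b$id)
  if (mia == mib) stopf("elements already on the same molecule")
  sa <- split_molecule(k$molecules[[mia]], a$homolog, a$chromosome, cut_a)
  sb <- split_molecule(k$molecules[[mib]], b$homolog, b$chromosome, cut_b)
  r_ab <- rbind(sa$pre, sb$post)   # prefix A + suffix B
  r_ba <- rbind(sb$pre, sa$post)
  cen_ab <- .segs_cen_count(r_ab, k$genome)
  cen_ba <- .segs_cen_count(r_ba, k$genome)
  genome <- k$genome
  if (segregation == "balanced") {
    if (cen_ab != 1L || cen_ba != 1L) {
      stopf("balanced translocation would create dicentric/acentric products")
    }
    k$molecules[[mia]] <- new_molecule(
      sprintf("t(%s;%s)", a$chromosome, b$chromosome), r_ab)
    k$molecules[[mib]] <- new_molecule(
      sprintf("t(%s;%s)", b$chromosome, a$chromosome), r_ba)
    return(list(
      karyotype = k,
      truth = truth_event("reciprocal_translocation_balanced",
                          c(a$id, b$id), "silent",
                          chrom_a = a$chromosome, homolog_a = a$homolog,
                          bp_a = cut_a,
                          chrom_b = b$chromosome, homolog_b = b$homolog,
                          bp_b = cut_b)
    ))
  }
  rec <- if (keep == "ab") r_ab else r_ba
  if (.segs_cen_count(rec, genome) != 1L) {
    stopf("kept recombinant is not monocentric; choose the other product")
  }
  if (keep == "ab") {
    # retain recombinant + intact suffix donor (B); prefix donor (A) lost
    k$molecules[[mia]] <- new_molecule(
      sprintf("t(%s;%s)", a$chromosome, b$chromosome), r_ab)
    del <- a; dup <- b; cut_del <- cut_a; cut_dup <- cut_b
  } else {
    k$molecules[[mib]] <- new_molecule(
      sprintf("t(%s;%s)", b$chromosome, a$chromosome), r_ba)
    del <- b; dup <- a; cut_del <- cut_b; cut_dup <- cut_a
  }
  len_del <- chrom_lookup(genome, del$chromosome)$length
  len_dup <- chrom_lookup(genome, dup$chromosome)$length
  list(
    karyotype = k,
    truth = truth_event(
      "reciprocal_translocation_unbalanced", c(a$id, b$id), "T-DEL+T-DUP",
      chrom_a = del$chromosome, homolog_a = del$homolog, class_a = "T-DEL",
      span_a = c(cut_del, len_del), bp_a = cut_del,
      chrom_b = dup$chromosome, homolog_b = dup$homolog, class_b = "T-DUP",
      span_b = c(cut_dup, len_dup), bp_b = cut_dup
    )
  )
}

#' Break-induced replication across non-homologous chromosomes
#'
#' The molecule broken at `ty_a` copies the molecule carrying `ty_b` from the
#' cut to the telomere; `ty_b`'s molecule is unchanged. Dosage signature:
#' terminal deletion distal to `ty_a`, terminal duplication distal to `ty_b`
#' (the same coupled pattern as an unbalanced reciprocal translocation).
#'
#' @inheritParams apply_unequal_xover
#' @return `list(karyotype, truth)`.
#' @export
apply_bir_translocation <- function(k, ty_a, ty_b) {
  a <- .get_ty(k$genome, ty_a); b <- .get_ty(k$genome, ty_b)
  .require_pair(a, b)
  if (a$chromosome == b$chromosome) {
    stopf("BIR translocation requires non-homologous chromosomes")
  }
  cut_a <- a$start; cut_b <- b$start
  mia <- find_molecule(k, a$homolog, a$chromosome, cut_a)
  mib <- find_molecule(k, b$homolog, b$chromosome, cut_b)
  if (is.na(mia) || is.na(mib)) stopf("participating element not present")
  sa <- split_molecule(k$molecules[[mia]], a$homolog, a$chromosome, cut_a)
  sb <- split_molecule(k$molecules[[mib]], b$homolog, b$chromosome, cut_b)
  rec <- rbind(sa$pre, sb$post)
  if (.segs_cen_count(rec, k$genome) != 1L) {
    stopf("BIR product is not monocentric for this element pair")
  }
  k$molecules[[mia]] <- new_molecule(
    sprintf("bir(%s;%s)", a$chromosome, b$chromosome), rec)
  len_a <- chrom_lookup(k$genome, a$chromosome)$length
  len_b <- chrom_lookup(k$genome, b$chromosome)$length
  list(
    karyotype = k,
    truth = truth_event(
      "BIR_translocation", c(a$id, b$id), "T-DEL+T-DUP",
      chrom_a = a$chromosome, homolog_a = a$homolog, class_a = "T-DEL",
      span_a = c(cut_a, len_a), bp_a = cut_a,
      chrom_b = b$chromosome, homolog_b = b$homolog, class_b = "T-DUP",
      span_b = c(cut_b, len_b), bp_b = cut_b
    )
  )
}

#' Ty-Ty gene conversion without crossover (dosage-silent)
#'
#' Conversion of part of one element by a non-allelic donor changes no
#' flanking SNP dosage; the karyotype is unchanged and the event is recorded
#' as silent (detectable only by long-read evidence).
#'
#' @inheritParams apply_unequal_xover
#' @return `list(karyotype, truth)`.
#' @export
apply_ty_conversion <- function(k, ty_a, ty_b) {
  a <- .get_ty(k$genome, ty_a); b <- .get_ty(k$genome, ty_b)
  .require_pair(a, b)
  list(
    karyotype = k,
    truth = truth_event("conversion_noncrossover", c(a$id, b$id), "silent",
                        chrom_a = a$chromosome, homolog_a = a$homolog,
                        bp_a = a$start)
  )
}

#' Allelic recombination: crossover/BIR (T-LOH) or gene conversion (I-LOH)
#'
#' `kind = "crossover"` or `"BIR"`: from `position` to the right telomere the
#' lost parental class drops to 0 copies and the other rises to 2 (terminal
#' LOH; total dosage conserved). `kind = "conversion"`: an interstitial tract
#' of length `tract_len` starting at `position` is homozygosed (I-LOH). A
#' conversion tract running past the telomere is clipped and relabeled T-LOH
#' with a warning.
#'
#' @param k a `karyotype`.
#' @param chromosome chromosome name.
#' @param position breakpoint (bp).
#' @param kind `"crossover"`, `"BIR"` or `"conversion"`.
#' @param tract_len conversion tract length in bp (conversion only).
#' @param lose which parental class loses material (`"W"` or `"Y"`).
#' @return `list(karyotype, truth)`.
#' @export
apply_allelic_event <- function(k, chromosome, position,
                                kind = c("crossover", "BIR", "conversion"),
                                tract_len = NULL, lose = "W") {
  kind <- match.arg(kind)
  gain <- if (lose == "W") "Y" else "W"
  cd <- chrom_lookup(k$genome, chromosome)
  if (position < 1 || position > cd$length) stopf("position outside chromosome")
  mi_l <- find_molecule(k, lose, chromosome, position)
  mi_g <- find_molecule(k, gain, chromosome, position)
  if (is.na(mi_l) || is.na(mi_g)) {
    stopf("both homologs must cover position %s:%d", chromosome, position)
  }
  sl <- split_molecule(k$molecules[[mi_l]], lose, chromosome, position)
  mech <- switch(kind, crossover = "allelic_crossover",
                 BIR = "allelic_BIR", conversion = "allelic_conversion")
  if (kind == "conversion") {
    if (is.null(tract_len) || tract_len <= 0) {
      stopf("conversion requires tract_len > 0")
    }
    tract_end <- position + as.integer(tract_len) - 1L
    if (tract_end >= cd$length) {
      warnf("conversion tract extends past the telomere; relabeled T-LOH")
      kind <- "crossover"   # falls through to the terminal branch below
    } else {
      sg <- split_molecule(k$molecules[[mi_g]], gain, chromosome, position)
      sg2 <- split_molecule(new_molecule("tmp", sg$post),
                            gain, chromosome, tract_end + 1L)
      sl2 <- split_molecule(new_molecule("tmp", sl$post),
                            lose, chromosome, tract_end + 1L)
      mol <- k$molecules[[mi_l]]
      mol$segments <- rbind(sl$pre, sg2$pre, sl2$post)
      rownames(mol$segments) <- NULL
      k$molecules[[mi_l]] <- mol
      n_snp <- .snps_in(k$genome, chromosome, position, tract_end)
      return(list(
        karyotype = k,
        truth = truth_event(
          mech, sprintf("%s:%d", chromosome, position),
          if (n_snp > 0) "I-LOH" else "silent",
          chrom_a = chromosome, homolog_a = lose, class_a = "I-LOH",
          span_a = c(position, tract_end), bp_a = position, bp_b = tract_end
        )
      ))
    }
  }
  # terminal branch: crossover or BIR (or clipped conversion)
  sg <- split_molecule(k$molecules[[mi_g]], gain, chromosome, position)
  mol <- k$molecules[[mi_l]]
  mol$segments <- rbind(sl$pre, sg$post)
  rownames(mol$segments) <- NULL
  k$molecules[[mi_l]] <- mol
  n_snp <- .snps_in(k$genome, chromosome, position, cd$length)
  list(
    karyotype = k,
    truth = truth_event(
      mech, sprintf("%s:%d", chromosome, position),
      if (n_snp > 0) "T-LOH" else "silent",
      chrom_a = chromosome, homolog_a = lose, class_a = "T-LOH",
      span_a = c(position, cd$length), bp_a = position
    )
  )
}

# molecule index whose centromere derives from (chromosome, homolog)
.find_centric_molecule <- function(k, chromosome, homolog) {
  cd <- chrom_lookup(k$genome, chromosome)
  for (i in seq_along(k$molecules)) {
    segs <- k$molecules[[i]]$segments
    hit <- segs$homolog == homolog & segs$chromosome == chromosome &
      segs$start <= cd$cen_start & segs$end >= cd$cen_end
    if (any(hit)) return(i)
  }
  NA_integer_
}

#' Whole-chromosome events: monosomy, trisomy, uniparental disomy
#'
#' Monosomy drops the molecule whose centromere derives from the given
#' homolog; trisomy duplicates it; UPD replaces it with a copy of the other
#' homolog's molecule (dosage-balanced whole-chromosome LOH).
#'
#' @param k a `karyotype`.
#' @param chromosome chromosome name.
#' @param kind `"monosomy"`, `"trisomy"` or `"UPD"`.
#' @param homolog for monosomy/trisomy, the affected parental class; for
#'   UPD, the class that is LOST (the other is duplicated).
#' @return `list(karyotype, truth)`.
#' @export
apply_aneuploidy <- function(k, chromosome,
                             kind = c("monosomy", "trisomy", "UPD"),
                             homolog = "W") {
  kind <- match.arg(kind)
  other <- if (homolog == "W") "Y" else "W"
  cd <- chrom_lookup(k$genome, chromosome)
  mi <- .find_centric_molecule(k, chromosome, homolog)
  if (is.na(mi)) {
    stopf("no %s-centric molecule of chromosome %s present (already %s?)",
          homolog, chromosome, "lost")
  }
  span <- c(1L, cd$length)
  if (kind == "monosomy") {
    k$molecules[[mi]] <- NULL
    cls <- "MONOSOMY"
  } else if (kind == "trisomy") {
    dup <- k$molecules[[mi]]
    dup$name <- paste0(dup$name, "+")
    k$molecules[[length(k$molecules) + 1L]] <- dup
    cls <- "TRISOMY"
  } else {
    mo <- .find_centric_molecule(k, chromosome, other)
    if (is.na(mo)) stopf("no %s homolog of %s to duplicate", other, chromosome)
    dup <- k$molecules[[mo]]
    dup$name <- paste0(dup$name, "+")
    k$molecules[[mi]] <- dup
    cls <- "UPD"
  }
  list(
    karyotype = k,
    truth = truth_event(
      switch(kind, monosomy = "monosomy", trisomy = "trisomy", UPD = "UPD"),
      sprintf("%s_%s", chromosome, homolog), cls,
      chrom_a = chromosome, homolog_a = homolog, class_a = cls,
      span_a = span
    )
  )
}

#' Sister-chromatid crossover producing a dicentric (flagged, unresolved)
#'
#' A crossover between directly-oriented elements on opposite arms of sister
#' chromatids fuses them into a dicentric molecule. The product is flagged
#' rather than resolved; read-depth synthesis refuses karyotypes containing
#' unresolved dicentrics (such products are selected against in vivo).
#'
#' @inheritParams apply_unequal_xover
#' @return `list(karyotype, truth)`.
#' @export
apply_sister_dicentric <- function(k, ty_a, ty_b) {
  a <- .get_ty(k$genome, ty_a); b <- .get_ty(k$genome, ty_b)
  .require_pair(a, b)
  if (a$homolog != b$homolog || a$chromosome != b$chromosome) {
    stopf("sister-chromatid fusion requires elements on one homolog")
  }
  arm_a <- position_arm(k$genome, a$chromosome, a$start)
  arm_b <- position_arm(k$genome, b$chromosome, b$start)
  if (arm_a == arm_b) stopf("elements must be on opposite arms")
  if (a$start > b$start) { tmp <- a; a <- b; b <- tmp }
  mi <- find_molecule(k, a$homolog, a$chromosome, a$start)
  if (is.na(mi)) stopf("element %s not present in karyotype", a$id)
  mol <- k$molecules[[mi]]
  s_r <- split_molecule(mol, a$homolog, a$chromosome, b$start)
  # sister fusion: prefix to right cut + mirrored prefix (two centromeres)
  mol$segments <- rbind(s_r$pre, rev_segments(s_r$pre))
  rownames(mol$segments) <- NULL
  mol$name <- paste0("dic(", mol$name, ")")
  k$molecules[[mi]] <- mol
  list(
    karyotype = k,
    truth = truth_event("sister_dicentric", c(a$id, b$id), "silent",
                        chrom_a = a$chromosome, homolog_a = a$homolog,
                        bp_a = a$start, bp_b = b$start)
  )
}
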