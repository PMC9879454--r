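# Per-mechanism contracts, each checked against the interval-arithmetic
# oracle (oracle_profile) on the mini genome. Pair pickers below find the
# first annotation pair satisfying each mechanism's eligibility rule.

find_pair <- function(g, same_arm = NULL, same_orientation = TRUE,
                      same_chrom = TRUE, family = "Ty1") {
  ty <- g$ty_elements
  arm <- vapply(seq_len(nrow(ty)), function(i) {
    tyshuffle:::position_arm(g, ty$chromosome[i], ty$start[i])
  }, character(1))
  for (i in which(ty$family == family & ty$has_cas9_target)) {
    for (j in seq_len(nrow(ty))) {
      if (i == j || ty$family[j] != family) next
      if (same_chrom &&
          !(ty$chromosome[j] == ty$chromosome[i] &&
              ty$homolog[j] == ty$homolog[i])) next
      if (!same_chrom && ty$chromosome[j] == ty$chromosome[i]) next
      ori_ok <- (ty$orientation[j] == ty$orientation[i]) == same_orientation
      if (!ori_ok) next
      if (!is.null(same_arm) && (arm[j] == arm[i]) != same_arm) next
      if (same_chrom && !is.null(same_arm) && isTRUE(same_arm)) {
        lo <- min(ty$start[c(i, j)]); hi <- max(ty$start[c(i, j)])
        cd <- g$chromosomes[g$chromosomes$name == ty$chromosome[i], ]
        if (lo <= cd$cen_end && hi >= cd$cen_start) next
        if (ty$end[min(i, j)] >= ty$start[max(i, j)]) next
      }
      return(ty[c(i, j), ])
    }
  }
  NULL
}

test_that("SSA pop-out shortens the molecule, keeps dosage, and refuses repeats", {
  g <- mini_genome()
  k <- baseline_karyotype(g)
  ty <- g$ty_elements[g$ty_elements$family == "Ty1", ][1, ]
  before <- copy_number_profile(k)
  res <- apply_ssa_popout(k, ty$id)
  expect_equal(res$truth$expected_call_class, "silent")
  mi <- which(vapply(res$karyotype$molecules, function(m) {
    m$name == sprintf("%s_%s", ty$chromosome, ty$homolog)
  }, logical(1)))
  segs <- res$karyotype$molecules[[mi]]$segments
  expect_equal(sum(segs$end - segs$start + 1),
               g$chromosomes$length[g$chromosomes$name == ty$chromosome] -
                 (ty$end - ty$start + 1) + 330)
  expect_equal(oracle_profile(res$karyotype), before)
  expect_error(apply_ssa_popout(res$karyotype, ty$id), "popped")

  delta <- g$ty_elements[g$ty_elements$family == "solo_delta", ][1, ]
  expect_error(apply_ssa_popout(k, delta$id), "solo delta")
})

test_that("unequal crossover deletes or duplicates the inter-element interval", {
  g <- mini_genome()
  k <- baseline_karyotype(g)
  pair <- find_pair(g, same_arm = TRUE, same_orientation = TRUE)
  expect_false(is.null(pair))
  a <- pair[1, ]; b <- pair[2, ]
  lo <- min(a$start, b$start); hi <- max(a$start, b$start)
  in_interval <- function(p) {
    p$chromosome == a$chromosome & p$position >= lo & p$position < hi
  }
  del <- apply_unequal_xover(k, a$id, b$id, "del")
  pd <- oracle_profile(del$karyotype)
  sel <- in_interval(pd)
  col <- if (a$homolog == "W") "w_copies" else "y_copies"
  expect_true(all(pd[[col]][sel] == 0))
  expect_true(all(pd[[col]][!sel] == 1))

  dup <- apply_unequal_xover(k, a$id, b$id, "dup")
  pu <- oracle_profile(dup$karyotype)
  expect_true(all(pu[[col]][sel] == 2))
  expect_true(all(pu[[col]][!sel] == 1))
  # dosage change is exactly 1 copy over the span, 0 elsewhere (conservation)
  other <- if (col == "w_copies") "y_copies" else "w_copies"
  expect_true(all(pd[[other]] == 1) && all(pu[[other]] == 1))

  inv_pair <- find_pair(g, same_arm = TRUE, same_orientation = FALSE)
  expect_error(apply_unequal_xover(k, inv_pair$id[1], inv_pair$id[2], "del"),
               "apply_inversion")
})

test_that("a zero-SNP interval records a dosage-silent unequal crossover", {
  ty <- rbind(
    toy_ty("W-IL-WTy1-1", "I", 20000),
    toy_ty("W-IL-WTy1-2", "I", 27000)   # adjacent: no SNP in between
  )
  g <- toy_genome(ty)
  k <- baseline_karyotype(g)
  res <- apply_unequal_xover(k, "W-IL-WTy1-1", "W-IL-WTy1-2", "del")
  expect_equal(res$truth$expected_call_class, "silent")
})

test_that("intrachromatid circle keeps one centromere and drops distal SNPs", {
  g <- mini_genome()
  k <- baseline_karyotype(g)
  pair <- find_pair(g, same_arm = FALSE, same_orientation = TRUE)
  expect_false(is.null(pair))
  a <- pair[1, ]; b <- pair[2, ]
  res <- apply_intrachromatid_circle(k, a$id, b$id)
  expect_equal(res$truth$expected_call_class, "CIRCLE")
  mols <- res$karyotype$molecules
  circ <- mols[[which(vapply(mols, function(m) isTRUE(m$circular),
                             logical(1)))]]
  expect_equal(molecule_cen_count(circ, g), 1)
  prof <- oracle_profile(res$karyotype)
  col <- if (a$homolog == "W") "w_copies" else "y_copies"
  lo <- min(a$start, b$start); hi <- max(a$start, b$start)
  distal <- prof$chromosome == a$chromosome &
    (prof$position < lo | prof$position >= hi)
  expect_true(all(prof[[col]][distal] == 0))
  expect_true(all(prof[[col]][!distal] == 1))
  # total SNP dosage lost equals the SNPs distal to the two elements
  expect_equal(sum(prof[[col]] == 0), sum(distal))

  same_arm <- find_pair(g, same_arm = TRUE, same_orientation = TRUE)
  expect_error(apply_intrachromatid_circle(k, same_arm$id[1], same_arm$id[2]),
               "same arm")
})

test_that("isochromosome mirrors one arm and deletes the other", {
  g <- mini_genome()
  k <- baseline_karyotype(g)
  pair <- find_pair(g, same_arm = FALSE, same_orientation = FALSE)
  expect_false(is.null(pair))
  a <- pair[1, ]; b <- pair[2, ]
  res <- apply_isochromosome(k, a$id, b$id, keep = "left")
  expect_equal(res$truth$expected_call_class, "ISO")
  t <- res$truth
  mols <- res$karyotype$molecules
  iso <- mols[[tyshuffle:::find_molecule(res$karyotype, t$homolog_a,
                                         t$chrom_a, t$span_a_start)]]
  expect_equal(molecule_cen_count(iso, g), 1)
  prof <- oracle_profile(res$karyotype)
  col <- if (t$homolog_a == "W") "w_copies" else "y_copies"
  on_chr <- prof$chromosome == t$chrom_a
  dup <- on_chr & prof$position >= t$span_a_start &
    prof$position <= t$span_a_end
  del <- on_chr & prof$position >= t$span_b_start &
    prof$position <= t$span_b_end
  expect_true(all(prof[[col]][dup] == 2))
  expect_true(all(prof[[col]][del] == 0))
  expect_true(all(prof[[col]][on_chr & !dup & !del] == 1))
})

test_that("inversion is dosage-silent, involutive, with two novel junctions", {
  g <- mini_genome()
  k <- baseline_karyotype(g)
  pair <- find_pair(g, same_arm = TRUE, same_orientation = FALSE)
  expect_false(is.null(pair))
  a <- pair[1, ]; b <- pair[2, ]
  before <- copy_number_profile(k)
  res <- apply_inversion(k, a$id, b$id)
  expect_equal(res$truth$expected_call_class, "silent")
  expect_equal(oracle_profile(res$karyotype), before)
  mi <- tyshuffle:::find_molecule(res$karyotype, a$homolog, a$chromosome,
                                  a$start)
  j <- tyshuffle:::molecule_junctions(res$karyotype$molecules[[mi]])
  expect_equal(nrow(j), 2)
  twice <- apply_inversion(res$karyotype, a$id, b$id)
  mseg <- function(kk) kk$molecules[[mi]]$segments
  expect_equal(mseg(twice$karyotype), mseg(k))
  expect_error(
    apply_inversion(k, find_pair(g, TRUE, TRUE)$id[1],
                    find_pair(g, TRUE, TRUE)$id[2]),
    "apply_unequal_xover"
  )
})

test_that("translocations: balanced silent, unbalanced couples T-DEL and T-DUP", {
  g <- mini_genome()
  k <- baseline_karyotype(g)
  pair <- find_pair(g, same_chrom = FALSE)
  # restrict to a same-arm-type pair so products are monocentric
  ty <- g$ty_elements
  arm <- vapply(seq_len(nrow(ty)), function(i) {
    tyshuffle:::position_arm(g, ty$chromosome[i], ty$start[i])
  }, character(1))
  names(arm) <- ty$id
  ids <- which(ty$has_cas9_target)
  found <- NULL
  for (i in ids) for (j in seq_len(nrow(ty))) {
    if (ty$chromosome[j] != ty$chromosome[i] && ty$family[j] == "Ty1" &&
        arm[j] == arm[i]) { found <- c(i, j); break }
  }
  a <- ty[found[1], ]; b <- ty[found[2], ]
  before <- copy_number_profile(k)

  bal <- apply_translocation(k, a$id, b$id, "balanced")
  expect_equal(bal$truth$expected_call_class, "silent")
  expect_equal(oracle_profile(bal$karyotype), before)
  expect_silent(assert_monocentric(bal$karyotype))

  unb <- apply_translocation(k, a$id, b$id, "unbalanced", keep = "ab")
  t <- unb$truth
  expect_equal(t$expected_call_class, "T-DEL+T-DUP")
  prof <- oracle_profile(unb$karyotype)
  col <- function(h) if (h == "W") "w_copies" else "y_copies"
  del_sel <- prof$chromosome == t$chrom_a & prof$position >= t$span_a_start
  dup_sel <- prof$chromosome == t$chrom_b & prof$position >= t$span_b_start
  expect_true(all(prof[[col(t$homolog_a)]][del_sel] == 0))
  expect_true(all(prof[[col(t$homolog_b)]][dup_sel] == 2))

  # recombinant size equals prefix of A plus suffix of B
  rec_i <- which(vapply(unb$karyotype$molecules,
                        function(m) startsWith(m$name, "t("), logical(1)))
  rec <- unb$karyotype$molecules[[rec_i]]
  len_b <- g$chromosomes$length[g$chromosomes$name == t$chrom_b]
  expected_size <- (a$start - 1) + (len_b - b$start + 1)
  expect_equal(sum(rec$segments$end - rec$segments$start + 1), expected_size)

  same <- find_pair(g, same_arm = TRUE, same_orientation = TRUE)
  expect_error(apply_translocation(k, same$id[1], same$id[2]),
               "allelic|intrachromosomal")
})

test_that("allelic events conserve total dosage at every SNP", {
  g <- mini_genome()
  k <- baseline_karyotype(g)
  # crossover: distal reciprocal 0/2
  res <- apply_allelic_event(k, "IV", 300000, "crossover", lose = "W")
  prof <- oracle_profile(res$karyotype)
  distal <- prof$chromosome == "IV" & prof$position >= 300000
  expect_true(all(prof$w_copies[distal] == 0))
  expect_true(all(prof$y_copies[distal] == 2))
  expect_true(all(prof$w_copies + prof$y_copies == 2))

  # conversion: interstitial tract only
  res2 <- apply_allelic_event(k, "V", 50000, "conversion",
                              tract_len = 30000, lose = "Y")
  p2 <- oracle_profile(res2$karyotype)
  tract <- p2$chromosome == "V" & p2$position >= 50000 & p2$position < 80000
  expect_true(all(p2$y_copies[tract] == 0))
  expect_true(all(p2$w_copies[tract] == 2))
  expect_true(all(p2$y_copies[!tract] == 1))
  expect_true(all(p2$w_copies + p2$y_copies == 2))
  expect_equal(res2$truth$expected_call_class, "I-LOH")

  # tract past the telomere: clipped, relabeled, warned
  len <- g$chromosomes$length[g$chromosomes$name == "V"]
  expect_warning(
    res3 <- apply_allelic_event(k, "V", len - 5000, "conversion",
                                tract_len = 20000, lose = "W"),
    "telomere"
  )
  expect_equal(res3$truth$class_a, "T-LOH")
})

test_that("aneuploidies behave as whole-chromosome dosage changes", {
  g <- mini_genome()
  k <- baseline_karyotype(g)
  mono <- apply_aneuploidy(k, "III", "monosomy", homolog = "W")
  p <- oracle_profile(mono$karyotype)
  on3 <- p$chromosome == "III"
  expect_true(all(p$w_copies[on3] == 0) && all(p$y_copies[on3] == 1))
  expect_error(apply_aneuploidy(mono$karyotype, "III", "monosomy",
                                homolog = "W"), "already")

  upd <- apply_aneuploidy(k, "V", "UPD", homolog = "W")
  p <- oracle_profile(upd$karyotype)
  on5 <- p$chromosome == "V"
  expect_true(all(p$w_copies[on5] == 0) && all(p$y_copies[on5] == 2))
  expect_true(all(p$w_copies + p$y_copies == 2))

  # trisomy then monosomy of the same homolog restores baseline
  tri <- apply_aneuploidy(k, "VII", "trisomy", homolog = "Y")
  p <- oracle_profile(tri$karyotype)
  expect_true(all(p$y_copies[p$chromosome == "VII"] == 2))
  back <- apply_aneuploidy(tri$karyotype, "VII", "monosomy", homolog = "Y")
  expect_equal(oracle_profile(back$karyotype), oracle_profile(k))
})
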