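mk_call <- function(id, class, chrom, bp1, bp2 = c(NA, NA)) {
  data.frame(id = id, class = class, chromosome = chrom, homolog = "W",
             bp1_start = bp1[1], bp1_end = bp1[2],
             bp2_start = bp2[1], bp2_end = bp2[2],
             stringsAsFactors = FALSE)
}

test_that("breakpoint windows overlapping Ty spans are flagged", {
  g <- full_genome()   # large Ty-free gaps only exist at full genome scale
  ty <- g$ty_elements[g$ty_elements$family == "Ty1", ][1, ]
  near <- mk_call("e1", "T-DEL", ty$chromosome,
                  c(ty$start - 10000, ty$start + 10000))
  ann <- associate(near, g)
  expect_true(ann$has_ty_flag)
  expect_match(ann$overlapping_ids, ty$id, fixed = TRUE)

  # a window >= 50 kb from any element (search every chromosome for a gap)
  far_chrom <- NULL; far_pos <- NULL
  for (ch in g$chromosomes$name) {
    sub <- g$ty_elements[g$ty_elements$chromosome == ch, ]
    gaps <- sort(c(1, sub$start, sub$end,
                   g$chromosomes$length[g$chromosomes$name == ch]))
    for (i in seq_len(length(gaps) - 1)) {
      if (gaps[i + 1] - gaps[i] > 120000) {
        far_chrom <- ch
        far_pos <- (gaps[i] + gaps[i + 1]) / 2
        break
      }
    }
    if (!is.null(far_pos)) break
  }
  expect_false(is.null(far_pos))
  far <- mk_call("e2", "T-LOH", far_chrom,
                 c(far_pos - 10000, far_pos + 10000))
  ann <- associate(far, g)
  expect_false(ann$has_ty_flag)
  # flag is true exactly when the overlap list is nonempty
  both <- associate(rbind(near, far), g)
  expect_equal(both$has_ty_flag, both$overlapping_ids != "")

  # association is invariant to event order
  rev_ann <- associate(rbind(far, near), g)
  expect_equal(rev_ann[order(rev_ann$id), ]$has_ty_flag,
               both[order(both$id), ]$has_ty_flag)
})

test_that("a simulated cohort separates Ty-rich dosage breakpoints from LOH", {
  # run at full genome scale: Ty density (not breakpoint accuracy) sets the
  # chance-overlap floor for LOH breakpoints, and the mini profile is 3x
  # denser in Ty elements than the genome it mimics
  g <- full_genome()
  anns <- list()
  for (seed in 1:8) {
    sim <- suppressWarnings(suppressMessages(
      simulate_isolate(g, sim_params(), 3, seed = 300 + seed)))
    counts <- synthesize_snp_counts(sim$karyotype,
                                    sim_params(mean_depth = 40),
                                    seed = 400 + seed)
    calls <- call_events(counts, g)
    if (nrow(calls)) anns[[length(anns) + 1L]] <- associate(calls, g)
  }
  frac <- ty_fraction_by_group(do.call(rbind, anns))
  dosage <- frac$fraction[frac$group == "dosage"]
  loh <- frac$fraction[frac$group == "loh"]
  expect_gt(frac$n_breakpoints[frac$group == "dosage"], 5)
  expect_gt(dosage, 0.8)   # Ty-mediated events carry Ty at breakpoints
  expect_lt(loh, 0.5)      # allelic LOH placed at random SNPs mostly does not
})

test_that("partner tallies are symmetric with correct Ty2 sampling rate", {
  expect_equal(sum(partner_tally(NULL)), 0)
  t1 <- partner_tally(data.frame(family_a = c("Ty1", "Ty2"),
                                 family_b = c("Ty2", "Ty1")))
  expect_equal(unname(t1["Ty1-Ty2"]), 2)
  all_ty1 <- partner_tally(data.frame(family_a = rep("Ty1", 5),
                                      family_b = rep("Ty1", 5)))
  expect_equal(unname(all_ty1["Ty1-Ty1"]), 5)
  expect_equal(sum(all_ty1 > 0), 1)

  # mechanism partner sampling respects the configured Ty2 probability
  g <- mini_genome()
  params <- sim_params()
  pairs <- tyshuffle:::.eligible_pairs(g, "reciprocal_translocation_unbalanced",
                                       character(0))
  set.seed(1)
  fams <- replicate(1000, {
    pr <- tyshuffle:::.sample_pair(g, pairs, params)
    tyshuffle:::ty_lookup(g, pr$b)$family
  })
  p_ty2 <- mean(fams == "Ty2")
  se <- sqrt(params$ty2_partner_prob * (1 - params$ty2_partner_prob) / 1000)
  expect_lt(abs(p_ty2 - params$ty2_partner_prob), 4 * se)
})

test_that("hotspot p-values equal the exact binomial tail", {
  # direct summation oracle
  tail_oracle <- function(k, n, p) sum(stats::dbinom(k:n, n, p))
  res <- hotspot_test(c(e1 = 12), n_elements = 54, total_events = 124,
                      correction = "none")
  expect_equal(res$p, tail_oracle(12, 124, 1 / 54), tolerance = 1e-12)

  counts <- c(a = 0, b = 3, c = 12, d = 5)
  res <- hotspot_test(counts, n_elements = 54, total_events = 124)
  for (i in seq_along(counts)) {
    expect_equal(res$p[i], tail_oracle(counts[i], 124, 1 / 54),
                 tolerance = 1e-12)
  }
  expect_equal(res$p_adj, pmin(1, res$p * 54))
  expect_equal(res$p[res$element == "a"], 1)        # k = 0 -> p = 1

  # central value: k at expectation is not enriched
  n <- 54; tot <- 108
  central <- hotspot_test(c(x = 2), n_elements = n, total_events = tot,
                          correction = "none")
  expect_gt(central$p, 0.3)

  expect_error(hotspot_test(c(x = 5), n_elements = 10, total_events = 3),
               "exceeds")
})
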