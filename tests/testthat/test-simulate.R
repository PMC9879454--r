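test_that("simulate_isolate is deterministic with a total class mapping", {
  g <- mini_genome()
  s1 <- suppressWarnings(suppressMessages(
    simulate_isolate(g, sim_params(), n_events = 3, seed = 4)))
  s2 <- suppressWarnings(suppressMessages(
    simulate_isolate(g, sim_params(), n_events = 3, seed = 4)))
  expect_identical(s1$truth, s2$truth)
  expect_equal(nrow(s1$truth), 3)
  # every mechanism maps to exactly one call class (or silent)
  known <- c("silent", "I-DEL", "I-DUP", "I-LOH", "T-LOH", "CIRCLE", "ISO",
             "T-DEL+T-DUP", "MONOSOMY", "TRISOMY", "UPD")
  for (seed in 1:10) {
    tr <- suppressWarnings(suppressMessages(
      simulate_isolate(g, sim_params(), 3, seed = seed)))$truth
    expect_true(all(tr$expected_call_class %in% known))
  }

  s0 <- simulate_isolate(g, sim_params(), n_events = 0, seed = 1)
  expect_equal(nrow(s0$truth), 0)
  expect_equal(copy_number_profile(s0$karyotype)$w_copies,
               rep(1L, nrow(g$snps)))
})

test_that("allelic and whole-chromosome events conserve dosage; del/dup shift by one", {
  g <- mini_genome()
  conserving <- c("allelic_crossover", "allelic_BIR", "allelic_conversion",
                  "UPD")
  for (mech in conserving) {
    sim <- suppressWarnings(suppressMessages(simulate_isolate(
      g, sim_params(weights = stats::setNames(1, mech)), 1, seed = 3)))
    prof <- copy_number_profile(sim$karyotype)
    expect_true(all(prof$w_copies + prof$y_copies == 2), label = mech)
  }
  for (mech in c("unequal_xover_del", "unequal_xover_dup")) {
    sim <- suppressMessages(simulate_isolate(
      g, sim_params(weights = stats::setNames(1, mech)), 1, seed = 5))
    t <- sim$truth
    prof <- copy_number_profile(sim$karyotype)
    sel <- prof$chromosome == t$chrom_a & prof$position >= t$span_a_start &
      prof$position <= t$span_a_end
    tot <- prof$w_copies + prof$y_copies
    shift <- if (mech == "unequal_xover_del") 1L else 3L
    expect_true(all(tot[sel] == shift), label = mech)
    expect_true(all(tot[!sel] == 2L), label = mech)
  }
})

test_that("synthesized counts track copy number with Poisson statistics", {
  g <- default_hybrid_genome(1)   # full profile: 55,000 SNPs
  k <- baseline_karyotype(g)
  counts <- synthesize_snp_counts(k, sim_params(mean_depth = 40), seed = 2)
  counts <- compute_rc(counts)
  expect_gt(mean(counts$rc), 0.48)
  expect_lt(mean(counts$rc), 0.52)

  # copy 0 -> identically zero counts
  gm <- mini_genome()
  km <- baseline_karyotype(gm)
  res <- apply_aneuploidy(km, "III", "monosomy", homolog = "W")
  c2 <- synthesize_snp_counts(res$karyotype, sim_params(mean_depth = 40),
                              seed = 3)
  zero <- c2$chromosome == "III" & c2$parental_class == "W"
  expect_true(all(c2$read_count[zero] == 0))

  # doubling depth halves the coefficient of variation of RC (+-10%)
  cv <- function(depth) {
    cc <- compute_rc(synthesize_snp_counts(
      k, sim_params(mean_depth = depth), seed = 7))
    stats::sd(cc$rc) / mean(cc$rc)
  }
  ratio <- cv(40) / cv(160)   # 4x depth -> CV halves (Poisson scaling)
  expect_gt(ratio, 2 * 0.9)
  expect_lt(ratio, 2 * 1.1)
})

test_that("negative-binomial depth model produces overdispersed counts", {
  g <- mini_genome()
  k <- baseline_karyotype(g)
  pois <- synthesize_snp_counts(k, sim_params(mean_depth = 40), seed = 1)
  nb <- synthesize_snp_counts(
    k, sim_params(mean_depth = 40, depth_model = "nbinom",
                  nb_dispersion = 5), seed = 1)
  expect_gt(stats::var(nb$read_count), stats::var(pois$read_count))
  expect_equal(mean(nb$read_count), mean(pois$read_count), tolerance = 0.05)
})

test_that("synthetic Ty read matrices match their closed-form column statistics", {
  pos <- seq(100, 5900, by = 100)
  m0 <- synthesize_ty_reads(pos, c(1500, 3000), dsb_offset = 2180,
                            n_reads = 15, miscall = 0, missing_rate = 0,
                            seed = 1)
  # miscall 0 -> every column unanimous and equal to truth
  for (j in seq_along(pos)) {
    expect_equal(length(unique(m0$calls[, j])), 1)
  }
  expect_equal(unname(m0$calls[1, ]), m0$truth)

  # expected fraction of unanimous columns ~ 0.9^15 + 0.1^15 per column
  set.seed(10)
  n_cols <- 0; n_unan <- 0
  for (s in 1:40) {
    m <- synthesize_ty_reads(pos, NULL, 2180, n_reads = 15, miscall = 0.1,
                             missing_rate = 0, seed = s)
    unan <- apply(m$calls, 2, function(col) length(unique(col)) == 1)
    n_cols <- n_cols + length(unan); n_unan <- n_unan + sum(unan)
  }
  p_expect <- 0.9^15 + 0.1^15
  se <- sqrt(p_expect * (1 - p_expect) / n_cols)
  expect_lt(abs(n_unan / n_cols - p_expect), 4 * se + 1e-9)

  # a tract covering no diagnostic SNP yields no B columns
  m_empty <- synthesize_ty_reads(pos, c(101, 150), 2180, n_reads = 10,
                                 miscall = 0, missing_rate = 0, seed = 2)
  expect_false(any(m_empty$calls == "B"))

  expect_error(synthesize_ty_reads(c(5, 3, 9), NULL, 100, 5, 0, 0),
               "increasing")
})

test_that("fluctuation simulator shows Luria-Delbruck behavior", {
  e0 <- simulate_fluctuation(0, 2^20, 50, seed = 1)
  expect_true(all(e0$counts == 0))

  e1 <- simulate_fluctuation(1e-5, 2^20, 1000, seed = 2)
  e2 <- simulate_fluctuation(1e-5, 2^20, 1000, seed = 2)
  expect_identical(e1$counts, e2$counts)
  # jackpot cultures drag the mean far above the median
  expect_gt(mean(e1$counts), stats::median(e1$counts))

  expect_message(simulate_fluctuation(1e-4, 1000, 10, seed = 1),
                 "power of 2")
})

test_that("doubling model agrees with an explicit per-lineage oracle", {
  # oracle: simulate every cell division explicitly at tiny N_t
  lineage_sim <- function(rate, G) {
    n_wt <- 1; n_mut <- 0
    for (g in seq_len(G)) {
      muts <- stats::rbinom(1, n_wt, rate)
      n_wt <- 2 * n_wt - muts
      n_mut <- 2 * n_mut + muts
    }
    n_mut
  }
  set.seed(99)
  G <- 10; rate <- 5e-3
  oracle <- replicate(4000, lineage_sim(rate, G))
  model <- simulate_fluctuation(rate, 2^G, 4000, seed = 100)$counts
  # same expected mutant count m*E[clone size]; compare means within 15%
  expect_lt(abs(mean(model) - mean(oracle)) / mean(oracle), 0.15)
  expect_gt(mean(model), stats::median(model))
  expect_gt(mean(oracle), stats::median(oracle))
})
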