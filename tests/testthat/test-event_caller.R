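test_that("compute_rc matches the ratio-of-coverage definition", {
  tab <- data.frame(
    chromosome = rep("I", 8), position = rep(c(10, 20, 30, 40), 2),
    parental_class = rep(c("W", "Y"), each = 4),
    read_count = rep(20L, 8)
  )
  class(tab) <- c("snp_dosage", "data.frame")
  rc <- compute_rc(tab)
  expect_true(all(rc$rc == 0.5))
  expect_equal(attr(rc, "mean_site_coverage"), 40)

  # a 40/0 site in an otherwise heterozygous genome: RC ~ 1.0 and 0
  tab$read_count[tab$position == 30 & tab$parental_class == "W"] <- 40L
  tab$read_count[tab$position == 30 & tab$parental_class == "Y"] <- 0L
  rc <- compute_rc(tab)
  d_bar <- attr(rc, "mean_site_coverage")
  expect_equal(rc$rc[rc$position == 30 & rc$parental_class == "W"], 40 / d_bar)
  expect_equal(rc$rc[rc$position == 30 & rc$parental_class == "Y"], 0)

  # invariance under global rescaling
  tab2 <- tab
  tab2$read_count <- tab2$read_count * 3L
  expect_equal(compute_rc(tab2)$rc, rc$rc)

  tab$read_count <- 0L
  expect_error(compute_rc(tab), "zero")
  expect_error(compute_rc(tab[0, ]), "empty")
})

test_that("segment_profile finds clean segments and absorbs outliers", {
  params <- caller_params()
  pos <- seq(1000, by = 2000, length.out = 100)
  # noise-free heterozygous baseline: a single state-1 segment
  runs <- segment_profile(rep(0.5, 100), pos, params)
  expect_equal(nrow(runs), 1)
  expect_equal(runs$state, 1L)

  # isolated single-SNP outlier does not create a segment
  rc <- rep(0.5, 100); rc[50] <- 0
  runs <- segment_profile(rc, pos, params)
  expect_equal(nrow(runs), 1)

  # clean step at SNP 60: boundary within one SNP of truth
  rc <- c(rep(0.5, 59), rep(0, 41))
  runs <- segment_profile(rc, pos, params)
  expect_equal(nrow(runs), 2)
  expect_equal(runs$state, c(1L, 0L))
  expect_lte(abs(runs$start_idx[2] - 60), 1)

  # fewer SNPs than the window: single majority-state segment
  runs <- segment_profile(c(0.5, 0.5, 0.4), c(1, 2, 3), params)
  expect_equal(nrow(runs), 1)
  expect_equal(runs$state, 1L)
})

test_that("the caller recovers a noisy T-LOH with a covering 20-kb window", {
  g <- mini_genome()
  k <- baseline_karyotype(g)
  res <- apply_allelic_event(k, "IV", 300000, "crossover", lose = "W")
  counts <- synthesize_snp_counts(res$karyotype, sim_params(mean_depth = 40),
                                  seed = 5)
  calls <- call_events(counts, g)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$class, "T-LOH")
  expect_equal(calls$chromosome, "IV")
  expect_equal(calls$homolog, "W")
  expect_true(calls$bp1_start <= 300000 && 300000 <= calls$bp1_end)
  expect_equal(calls$bp1_end - calls$bp1_start, 20000, tolerance = 0.01)
  # LOH calls carry reciprocal dosage; DEL/DUP never do
  expect_true(calls$reciprocal)
})

test_that("whole-chromosome precedence: UPD yields one call, not LOH", {
  g <- mini_genome()
  k <- baseline_karyotype(g)
  res <- apply_aneuploidy(k, "V", "UPD", homolog = "W")
  counts <- synthesize_snp_counts(res$karyotype, sim_params(mean_depth = 40),
                                  seed = 6)
  calls <- call_events(counts, g)
  expect_equal(calls$class, "UPD")
  expect_false(any(calls$class %in% c("T-LOH", "I-LOH")))
})

test_that("unbalanced translocations call a paired T-DEL and T-DUP", {
  g <- mini_genome()
  sim <- suppressMessages(simulate_isolate(
    g, sim_params(weights = c(reciprocal_translocation_unbalanced = 1)),
    1, seed = 2))
  t <- sim$truth
  counts <- synthesize_snp_counts(sim$karyotype, sim_params(mean_depth = 40),
                                  seed = 11)
  calls <- call_events(counts, g)
  expect_setequal(calls$class, c("T-DEL", "T-DUP"))
  del <- calls[calls$class == "T-DEL", ]
  dup <- calls[calls$class == "T-DUP", ]
  expect_equal(del$chromosome, t$chrom_a)
  expect_equal(dup$chromosome, t$chrom_b)
  expect_equal(del$paired_with, dup$id)
  expect_equal(dup$paired_with, del$id)
  expect_false(any(calls$reciprocal))
})

test_that("dosage-silent events produce no calls", {
  g <- mini_genome()
  for (mech in c("inversion", "reciprocal_translocation_balanced",
                 "SSA_popout")) {
    sim <- suppressMessages(simulate_isolate(
      g, sim_params(weights = stats::setNames(1, mech)), 1, seed = 9))
    expect_equal(sim$truth$expected_call_class, "silent")
    counts <- synthesize_snp_counts(sim$karyotype,
                                    sim_params(mean_depth = 40), seed = 12)
    calls <- call_events(counts, g)
    expect_equal(nrow(calls), 0, label = mech)
  }
})

test_that("noise-free classification is exact for every visible event", {
  g <- mini_genome()
  n_checked <- 0
  for (seed in 1:15) {
    sim <- suppressWarnings(suppressMessages(
      simulate_isolate(g, sim_params(), 3, seed = seed)))
    calls <- call_events(exact_counts(sim$karyotype), g)
    sc <- score_calls(sim$truth, calls, g)
    vis <- sc[sc$visible, , drop = FALSE]
    n_checked <- n_checked + nrow(vis)
    expect_true(all(vis$class_ok), label = sprintf("seed %d", seed))
    expect_true(all(is.na(vis$bp_ok) | vis$bp_ok),
                label = sprintf("seed %d bp", seed))
  }
  expect_gt(n_checked, 20)
})

test_that("breakpoint windows follow the 20-kb midpoint rule", {
  params <- caller_params()
  # last unaltered SNP at 301,000, first altered at 305,000:
  # midpoint 303,000, window [293,000, 313,000]
  positions <- c(100000, 301000, 305000, 320000, 340000, 360000)
  call <- data.frame(
    class = "T-LOH", chromosome = "I", homolog = "W",
    start_idx = 3L, end_idx = 6L, start_pos = 305000, end_pos = 360000,
    start_idx2 = NA, end_idx2 = NA, start_pos2 = NA, end_pos2 = NA,
    reciprocal = TRUE, paired_with = NA
  )
  iv <- breakpoint_interval(call, positions, 400000, params)
  expect_equal(iv$start, 293000)
  expect_equal(iv$end, 313000)

  # I-LOH: span bounded by the flanking heterozygous SNPs
  call$class <- "I-LOH"; call$end_idx <- 4L; call$end_pos <- 320000
  iv <- breakpoint_interval(call, positions, 400000, params)
  expect_equal(iv$start, 301000)
  expect_equal(iv$end, 340000)

  # window clipped at coordinate 1 when the event starts at the first SNP
  call$class <- "T-DEL"; call$start_idx <- 1L; call$end_idx <- 2L
  iv <- breakpoint_interval(call, positions, 400000, params)
  expect_gte(iv$start, 1)
})

test_that("haploid PCR patterns map onto the four 5-FOA-resistant classes", {
  pat <- function(left = "present_parental_size",
                  right = "present_parental_size",
                  across = "present_parental_size",
                  ura3 = "present_parental_size") {
    list(left_junction = left, right_junction = right,
         across_element = across, ura3_internal = ura3)
  }
  expect_equal(classify_haploid_isolate(pat()), 1L)
  expect_equal(classify_haploid_isolate(
    pat(across = "present_shorter", ura3 = "absent")), 2L)
  expect_equal(classify_haploid_isolate(pat(ura3 = "absent")), 3L)
  expect_equal(classify_haploid_isolate(
    pat(across = "absent", ura3 = "absent")), 4L)
  expect_equal(classify_haploid_isolate(
    pat(left = "absent", across = "absent")), "unclassified")
  expect_error(classify_haploid_isolate(list(left_junction = "absent")),
               "pattern")
})

test_that("translocation pairing is greedy with leftovers unpaired", {
  mk <- function(class, chrom, pos = 1) {
    data.frame(class = class, chromosome = chrom, homolog = "W",
               start_idx = 1L, end_idx = 10L, start_pos = pos,
               end_pos = pos + 1000, start_idx2 = NA, end_idx2 = NA,
               start_pos2 = NA, end_pos2 = NA, reciprocal = FALSE,
               paired_with = NA_character_)
  }
  calls <- rbind(mk("T-DEL", "II"), mk("T-DUP", "V"))
  out <- pair_translocations(calls)
  expect_equal(out$paired_with[1], out$id[2])

  # two T-DELs and no T-DUP stay unpaired
  calls <- rbind(mk("T-DEL", "II"), mk("T-DEL", "V"))
  out <- pair_translocations(calls)
  expect_true(all(is.na(out$paired_with)))

  # a T-DUP on the same chromosome is not an eligible partner
  calls <- rbind(mk("T-DEL", "II"), mk("T-DUP", "II"))
  out <- pair_translocations(calls)
  expect_true(all(is.na(out$paired_with)))
})
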