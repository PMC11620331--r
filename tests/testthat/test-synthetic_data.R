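test_that("printed single-molecule tallies give the expected percentages", {
  expect_equal(tally_outcome_proportion(50, 58)$display, 86)
  expect_equal(tally_outcome_proportion(57, 59)$display, 97)
  expect_equal(tally_outcome_proportion(0, 10)$percent, 0)
  expect_equal(tally_outcome_proportion(50, 58)$percent, 100 * 50 / 58)
  expect_error(tally_outcome_proportion(1, 0), "n_total")
})

test_that("pure leading-strand collapse is fully one-ended", {
  gs <- small_genome()
  nk <- nick_sites("chr1", 100000, "+", "n1")
  p <- collision_sim_params(fork_directionality = 1, events = 1000,
                            background_rate = 0, convert_prob = 0)
  tr <- simulate_collision_track(nk, p, gs, seed = 5)
  expect_equal(track_window_sum(tr, "chr1", 100000, 200000), 0)
  expect_equal(peak_asymmetry(tr, nk)$asymmetry, 0.5)
})

test_that("pure lagging-strand collapse is balanced within sampling error", {
  gs <- small_genome()
  nk <- nick_sites("chr1", 100000, "-", "n1")
  p <- collision_sim_params(fork_directionality = 1, events = 2000,
                            background_rate = 0)
  tr <- simulate_collision_track(nk, p, gs, seed = 5)
  a <- peak_asymmetry(tr, nk)
  # L and R are both Binomial(2000, 0.6); |asym| stays within ~4 sd
  expect_lt(abs(a$asymmetry), 4 * sqrt(0.25 / (a$L + a$R)) + 0.02)
})

test_that("orientation rule maps strand and fork direction to class", {
  expect_equal(collision_class("-", rightward = TRUE), "lagging")
  expect_equal(collision_class("-", rightward = FALSE), "leading")
  expect_equal(collision_class("+", rightward = TRUE), "leading")
  expect_equal(collision_class("+", rightward = FALSE), "lagging")
})

test_that("read bookkeeping is exact and seeds reproduce byte-identically", {
  gs <- small_genome()
  nk <- nick_sites("chr1", 100000, "+", "n1")
  p <- collision_sim_params(fork_directionality = 0.8, events = 500,
                            background_rate = 1e-4, convert_prob = 0.3)
  a <- simulate_collision_track(nk, p, gs, seed = 99)
  b <- simulate_collision_track(nk, p, gs, seed = 99)
  expect_identical(a$plus, b$plus)
  expect_identical(a$minus, b$minus)
  info <- attr(a, "sim_info")
  total <- sum(track_window_values(a, "chr1", 0, 200000, "+")) +
    sum(track_window_values(a, "chr1", 0, 200000, "-"))
  expect_equal(total, info$n_signal_ends + info$n_background)
  expect_equal(a$total_reads, total)

  c_ <- simulate_collision_track(nk, p, gs, seed = 100)
  expect_false(identical(a$plus, c_$plus))
})

test_that("event class frequencies converge to the fork directionality", {
  gs <- small_genome()
  nk <- nick_sites("chr1", 100000, "+", "n1")
  f <- 0.7
  p <- collision_sim_params(fork_directionality = f, events = 10000,
                            background_rate = 0)
  tr <- simulate_collision_track(nk, p, gs, seed = 21)
  info <- attr(tr, "sim_info")
  n <- info$n_leading + info$n_lagging
  # for a Watson nick, leading events are the rightward-fork draws
  ci <- f + c(-1, 1) * 4 * sqrt(f * (1 - f) / n)
  expect_gt(info$n_leading / n, ci[1])
  expect_lt(info$n_leading / n, ci[2])
})

test_that("converging-fork conversion adds far-side ends at the set distance", {
  gs <- small_genome()
  nk <- nick_sites("chr1", 100000, "+", "n1")
  p <- collision_sim_params(fork_directionality = 1, events = 2000,
                            background_rate = 0, convert_prob = 0.4,
                            convert_distance = 30000)
  tr <- simulate_collision_track(nk, p, gs, seed = 3)
  right <- track_window_sum(tr, "chr1", 100000, 200000)
  at_conv <- track_window_sum(tr, "chr1", 129999, 130001)
  expect_equal(right, at_conv)  # all far-side ends sit at the distance
  expect_gt(right / 2000, 0.3)
  expect_lt(right / 2000, 0.5)
})

test_that("RFD field follows origins with sign change at midpoints", {
  gs <- small_genome(100000L)
  one <- simulate_rfd_field(50000, gs, bin_size = 1000)
  expect_equal(rfd_at(one, "chr1", 80000), 1)
  expect_equal(rfd_at(one, "chr1", 20000), -1)
  expect_true(all(abs(one$rfd) <= 1, na.rm = TRUE))

  two <- simulate_rfd_field(c(20000, 80000), gs, bin_size = 1000)
  expect_equal(rfd_at(two, "chr1", 30000), 1)   # right of first origin
  expect_equal(rfd_at(two, "chr1", 70000), -1)  # left of second origin
  expect_equal(rfd_at(two, "chr1", 10000), -1)
  # hard step exactly at the 50 kb midpoint with smoothing width 0
  expect_equal(rfd_at(two, "chr1", 49999), 1)
  expect_equal(rfd_at(two, "chr1", 50001), -1)

  sm <- simulate_rfd_field(c(20000, 80000), gs, bin_size = 1000,
                           smoothing_width = 10000)
  mid_vals <- sm$rfd[sm$start >= 45000 & sm$end <= 55000]
  expect_true(all(diff(mid_vals) < 0))  # linear ramp across termination
  expect_true(all(abs(mid_vals) < 1))
  expect_error(simulate_rfd_field(numeric(0), gs), "origin")
})

test_that("spike-in read counts track the configured cell fraction", {
  gs <- small_genome(1000L, spike_len = 5000L)
  cfg <- spikein_config("spike1", 1000, 2000, fraction = 0.2)
  base <- stranded_track(gs, total_reads = 1)
  tr <- simulate_spikein(base, cfg, depth = 10000, seed = 8)
  n <- tr$spikein_reads
  expect_gt(n, 2000 - 4 * sqrt(10000 * 0.2 * 0.8))
  expect_lt(n, 2000 + 4 * sqrt(10000 * 0.2 * 0.8))
  expect_equal(count_spikein_reads(tr, cfg), n)

  tr2 <- simulate_spikein(base, cfg, depth = 10000, seed = 9)
  expect_false(identical(tr$spikein_reads, tr2$spikein_reads) &&
                 identical(tr$plus, tr2$plus))
  expect_error(spikein_config("spike1", 0, 10, fraction = 0), "fraction")
  expect_error(spikein_config("spike1", 0, 10, fraction = 1), "fraction")
})

test_that("RPA polarity reports single- versus double-ended resection", {
  gs <- small_genome()
  nk <- nick_sites("chr1", 100000, "+", "n1")
  p <- collision_sim_params(events = 200, max_length = 3000)
  se <- simulate_rpa_track(nk, p, gs, mode = "single_ended", seed = 2)
  r_se <- rpa_asymmetry(se, "chr1", 95000, 105000)
  expect_true(r_se$censored || r_se$ratio > 10)

  de <- simulate_rpa_track(nk, p, gs, mode = "double_ended", seed = 2)
  r_de <- rpa_asymmetry(de, "chr1", 95000, 105000)
  expect_gt(r_de$ratio, 0.8)
  expect_lt(r_de$ratio, 1.25)

  inv <- simulate_rpa_track(nk, p, gs, mode = "single_ended",
                            invasion_signal = TRUE, seed = 2)
  expect_gt(track_window_sum(inv, "chr1", 100000, 103000, strand = "-"), 0)
  expect_equal(track_window_sum(se, "chr1", 100000, 103000, strand = "-"), 0)
})

test_that("amplicon simulation honours p_del and fixed deletions", {
  ref <- random_dna(120)
  all_ref <- simulate_amplicon_reads(ref, 60, p_del = 0, n_reads = 20,
                                     seed = 1)
  expect_true(all(as.character(all_ref) == ref))

  fixed <- simulate_amplicon_reads(ref, 60, p_del = 1,
                                   fixed_deletion = c(55, 65),
                                   n_reads = 10, seed = 1)
  expected <- paste0(substr(ref, 1, 55), substr(ref, 66, 120))
  expect_true(all(as.character(fixed) == expected))

  a <- simulate_amplicon_reads(ref, 60, n_reads = 30, seed = 4)
  b <- simulate_amplicon_reads(ref, 60, n_reads = 30, seed = 4)
  expect_identical(as.character(a), as.character(b))
})
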