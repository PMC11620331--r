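norm_rect <- function(len, blocks, h = 10) {
  # blocks: list of c(from, to); returns an RPM-state track
  v <- numeric(len)
  for (b in blocks) v[(b[1] + 1):b[2]] <- h
  tr <- vec_track(v, total_reads = 1e6)
  compute_rpm(tr)  # factor 1, values unchanged
}

test_that("thresholding finds rectangular blocks and rejects flat tracks", {
  expect_length(call_peaks(norm_rect(1000, list()), min_signal = 3), 0)

  one <- call_peaks(norm_rect(1000, list(c(100, 200))), min_signal = 3,
                    background_rate = 0.01)
  expect_length(one, 1)
  expect_equal(GenomicRanges::start(one), 101)  # GRanges is 1-based
  expect_equal(GenomicRanges::end(one), 200)
  expect_equal(S4Vectors::mcols(one)$signal, 10)
  expect_equal(S4Vectors::mcols(one)$summit, 100)
  expect_error(call_peaks(norm_rect(1000, list()), min_signal = 0), "min_signal")
  expect_error(call_peaks(vec_track(numeric(10), total_reads = 1)),
               "normalized")
})

test_that("nearby blocks merge only within the merge gap", {
  blocks <- list(c(100, 200), c(230, 300))
  merged <- call_peaks(norm_rect(1000, blocks), merge_gap = 50)
  expect_length(merged, 1)
  expect_equal(GenomicRanges::width(merged), 200)
  split <- call_peaks(norm_rect(1000, blocks), merge_gap = 20)
  expect_length(split, 2)
})

test_that("peaks are disjoint, sorted, and deterministically reproducible", {
  set.seed(31)
  v <- rpois(5000, 0.5) + rep(c(0, 8, 0, 8, 0), each = 1000)
  tr <- compute_rpm(vec_track(v, total_reads = 1e6))
  a <- call_peaks(tr, min_signal = 3, background_rate = 0.5)
  b <- call_peaks(tr, min_signal = 3, background_rate = 0.5)
  expect_identical(as.data.frame(a), as.data.frame(b))
  if (length(a) > 1) {
    expect_true(all(diff(GenomicRanges::start(a)) > 0))
    expect_true(all(GenomicRanges::start(a)[-1] >
                      GenomicRanges::end(a)[-length(a)]))
  }
})

test_that("qualification keeps only isolated single-site peaks", {
  pk <- call_peaks(norm_rect(40000, list(c(1000, 2000), c(10000, 11000),
                                         c(30000, 31000))))
  # peak 1 holds two sites; peak 2 one site 8,001 bp from a neighbour;
  # peak 3 no site
  sites <- nick_sites(rep("chr1", 3), c(1500, 1600, 10500 - 1 + 1),
                      c("+", "-", "+"), c("a", "b", "c"))
  # adjust: site c at 10500; nearest other site (b at 1600) is 8900 bp away
  q <- qualify_peaks(pk, sites, min_separation = 8000)
  expect_length(q, 1)
  expect_equal(unlist(S4Vectors::mcols(q)$site_labels), "c")
  info <- attr(q, "qualification")
  expect_equal(unname(info["discarded_multi_site"]), 1)
  expect_equal(unname(info["discarded_no_site"]), 1)

  # boundary of the separation rule: 7,999 bp discarded, 8,001 bp kept
  pk2 <- call_peaks(norm_rect(40000, list(c(10000, 11000))))
  close_site <- nick_sites(c("chr1", "chr1"), c(10500, 10500 + 7999),
                           c("+", "+"), c("x", "y"))
  expect_length(qualify_peaks(pk2, close_site), 0)
  far_site <- nick_sites(c("chr1", "chr1"), c(10500, 10500 + 8001),
                         c("+", "+"), c("x", "y"))
  kept <- qualify_peaks(pk2, far_site)
  expect_length(kept, 1)
  expect_equal(S4Vectors::mcols(kept)$site_distance, 8001)

  # idempotent
  expect_equal(as.data.frame(qualify_peaks(kept, far_site)),
               as.data.frame(kept))
})

test_that("every retained peak contains its generating nick", {
  gs <- small_genome(400000L)
  positions <- c(50000, 150000, 250000, 350000)
  plus <- list(); minus <- list()
  v_p <- numeric(400000); v_m <- numeric(400000)
  tracks <- lapply(seq_along(positions), function(i) {
    nk <- nick_sites("chr1", positions[i], "+", paste0("n", i))
    simulate_collision_track(nk, collision_sim_params(
      events = 500, background_rate = 0, fork_directionality = 0.85), gs,
      seed = 100 + i)
  })
  for (tr in tracks) {
    v_p <- v_p + track_window_values(tr, "chr1", 0, 400000, "+")
    v_m <- v_m + track_window_values(tr, "chr1", 0, 400000, "-")
  }
  total <- sum(v_p) + sum(v_m)
  comb <- compute_rpm(stranded_track(gs, plus = list(chr1 = v_p),
                                     minus = list(chr1 = v_m),
                                     total_reads = total))
  sites <- nick_sites(rep("chr1", 4), positions, "+", paste0("n", 1:4))
  pk <- call_peaks(comb, min_signal = 3, merge_gap = 500,
                   background_rate = 1e-3)
  q <- qualify_peaks(pk, sites)
  expect_gt(length(q), 0)
  covered <- vapply(seq_along(q), function(i)
    any(GenomicRanges::start(q)[i] <= positions + 1 &
          positions + 1 <= GenomicRanges::end(q)[i]), logical(1))
  expect_true(all(covered))  # recall 1 with no background
})

test_that("intensity sums both strands over the +/-30 kb window only", {
  gs <- small_genome(100000L)
  nk <- nick_sites("chr1", 50000, "+", "n1")
  zero <- stranded_track(gs, total_reads = 1)
  expect_equal(peak_intensity(zero, nk), 0)

  v_p <- numeric(100000); v_m <- numeric(100000)
  v_p[(50000 - 29999):(50000)] <- 0.001  # 30 reads spread left
  v_m[(50001):(50000 + 30000)] <- 0.001
  tr <- stranded_track(gs, plus = list(chr1 = v_p),
                       minus = list(chr1 = v_m), total_reads = 60)
  expect_equal(peak_intensity(tr, nk), 0.001 * 60000)

  # reads just beyond the boundary are excluded
  v2 <- numeric(100000)
  v2[50000 - 30001 + 1] <- 5  # position 50000-30001 < window start
  v2[50000 + 30000 + 1] <- 7  # position 80000 = window end (half-open)
  tr2 <- stranded_track(gs, plus = list(chr1 = v2), total_reads = 12)
  expect_equal(peak_intensity(tr2, nk), 0)
})
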