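test_that("bedGraph intervals expand to per-base counts and sum overlaps", {
  gs <- small_genome(100L)
  p <- withr::local_tempfile(fileext = ".bedGraph")
  m <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("chr1\t10\t12\t3", "chr1\t11\t13\t2"), p)
  writeLines(character(0), m)
  tr <- read_stranded_bedgraph(p, m, gs, total_reads = 10)
  v <- track_window_values(tr, "chr1", 0, 100, strand = "+")
  expect_equal(v[11:14], c(3, 5, 2, 0))
  expect_equal(sum(v), 10)
  expect_equal(sum(track_window_values(tr, "chr1", 0, 100, strand = "-")), 0)
})

test_that("bedGraph reader rejects malformed and out-of-genome input", {
  gs <- small_genome(100L)
  m <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(character(0), m)
  bad <- withr::local_tempfile(fileext = ".bedGraph")

  writeLines("chr1\t12\t10\t3", bad)
  expect_error(read_stranded_bedgraph(bad, m, gs), "line 1")

  writeLines("chr1\t5\t8\t-2", bad)
  expect_error(read_stranded_bedgraph(bad, m, gs), "negative")

  writeLines("chrUnknown\t5\t8\t2", bad)
  expect_error(read_stranded_bedgraph(bad, m, gs), "chrUnknown")

  writeLines(c("chr1\t5\t8\t2", "chr1\t90\t120\t1"), bad)
  expect_error(read_stranded_bedgraph(bad, m, gs), "line 2")
})

test_that("RPM scaling follows 1e6 / total reads and sums correctly", {
  v <- numeric(1000); v[101] <- 2
  tr <- vec_track(v, total_reads = 2e6)
  rpm <- compute_rpm(tr)
  expect_equal(track_window_values(rpm, "chr1", 100, 101, "+"), 1.0)
  expect_equal(rpm$normalization, "RPM")

  # genome-wide RPM sum = 1e6 * in-track reads / total reads
  set.seed(41)
  v2 <- rpois(500, 0.2)
  tr2 <- vec_track(v2, rpois(500, 0.2), total_reads = 12345)
  rpm2 <- compute_rpm(tr2)
  got <- sum(track_window_values(rpm2, "chr1", 0, 500, "+")) +
    sum(track_window_values(rpm2, "chr1", 0, 500, "-"))
  in_track <- sum(v2) + sum(tr2$minus$chr1)
  expect_equal(got, 1e6 * in_track / 12345, tolerance = 1e-12)
})

test_that("spike-in normalization divides RPM by locus/total factor", {
  v <- numeric(200); v[11:20] <- 10
  tr <- vec_track(v, total_reads = 1e6, spikein_reads = 1e4)
  out <- spikein_normalize(compute_rpm(tr), spikein_config("spike1", 0, 10))
  # RPM value 10 * (1e6/1e6) = 10; factor 0.01 -> 1000
  expect_equal(track_window_values(out, "chr1", 10, 11, "+"), 1000)
  expect_equal(out$normalization, "spike_normalized")

  # doubling spike-in reads halves the normalized signal
  tr2 <- vec_track(v, total_reads = 1e6, spikein_reads = 2e4)
  out2 <- spikein_normalize(compute_rpm(tr2), spikein_config("spike1", 0, 10))
  expect_equal(track_window_values(out2, "chr1", 10, 11, "+"),
               1000 / 2)
})

test_that("normalization is invariant under uniform depth scaling", {
  set.seed(7)
  v <- rpois(300, 1)
  for (c_scale in c(3, 10)) {
    a <- spikein_normalize(
      compute_rpm(vec_track(v, total_reads = 5e5, spikein_reads = 500)),
      spikein_config("spike1", 0, 10))
    b <- spikein_normalize(
      compute_rpm(vec_track(v * c_scale, total_reads = 5e5 * c_scale,
                            spikein_reads = 500 * c_scale)),
      spikein_config("spike1", 0, 10))
    expect_equal(track_window_values(a, "chr1", 0, 300, "+"),
                 track_window_values(b, "chr1", 0, 300, "+"),
                 tolerance = 1e-12)
  }
})

test_that("normalization state machine rejects out-of-order transitions", {
  tr <- vec_track(rep(1, 10), total_reads = 100, spikein_reads = 5)
  expect_error(spikein_normalize(tr, spikein_config("s", 0, 1)), "RPM")
  rpm <- compute_rpm(tr)
  expect_error(compute_rpm(rpm), "raw")
  zero_spike <- vec_track(rep(1, 10), total_reads = 100)
  expect_error(spikein_normalize(compute_rpm(zero_spike),
                                 spikein_config("s", 0, 1)), "spike-in")
  expect_error(compute_rpm(vec_track(rep(0, 10), total_reads = 0)),
               "total mapped reads")
})

test_that("stranded bedGraph and nick BED round-trip identically", {
  set.seed(13)
  for (i in 1:5) {
    plus <- rpois(400, 0.3) * sample(c(1, 2.5), 400, replace = TRUE)
    minus <- rpois(400, 0.3)
    tr <- vec_track(plus, minus, total_reads = 999)
    p <- withr::local_tempfile(); m <- withr::local_tempfile()
    write_track_bedgraph(tr, p, m)
    back <- read_stranded_bedgraph(p, m, tr$genome, total_reads = 999)
    expect_equal(track_window_values(back, "chr1", 0, 400, "+"), plus)
    expect_equal(track_window_values(back, "chr1", 0, 400, "-"), minus)
  }

  sites <- nick_sites(c("chr1", "chr1"), c(120, 4000), c("+", "-"),
                      c("a", "b"))
  f <- withr::local_tempfile(fileext = ".bed")
  write_nicks_bed(sites, f)
  back <- read_nicks_bed(f)
  expect_equal(as.data.frame(back), as.data.frame(sites))
})

test_that("peak files round-trip through the BED6+4 layout", {
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(101, 501), c(200, 700)))
  S4Vectors::mcols(gr)$name <- c("peak_1", "peak_2")
  S4Vectors::mcols(gr)$signal <- c(12.5, 0)
  S4Vectors::mcols(gr)$qsurrogate <- c(1e-8, 0.5)
  S4Vectors::mcols(gr)$summit <- c(150, 600)
  S4Vectors::mcols(gr)$site_labels <- I(list(c("a", "b"), character(0)))
  S4Vectors::mcols(gr)$site_distance <- c(9000, -1)
  f <- withr::local_tempfile(fileext = ".bed")
  write_peaks_bed(gr, f)
  back <- read_peaks_bed(f)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(gr))
  expect_equal(S4Vectors::mcols(back)$signal, S4Vectors::mcols(gr)$signal)
  expect_equal(S4Vectors::mcols(back)$qsurrogate,
               S4Vectors::mcols(gr)$qsurrogate)
  expect_equal(S4Vectors::mcols(back)$summit, S4Vectors::mcols(gr)$summit)
  expect_equal(unclass(S4Vectors::mcols(back)$site_labels),
               unclass(S4Vectors::mcols(gr)$site_labels))
  expect_equal(S4Vectors::mcols(back)$site_distance,
               S4Vectors::mcols(gr)$site_distance)
  # zero-signal peak keeps a literal 0 score
  lines <- readLines(f)
  expect_match(lines[3], "\t0\t", fixed = FALSE)
})

test_that("coordinates resolve against exactly one namespace", {
  expect_error(genome_spec(c(chr1 = 100), spikein = c(chr1 = 50)),
               "both namespaces")
  gs <- small_genome(100L, spike_len = 50L)
  expect_equal(chrom_namespace(gs, "spike1"), "spikein")
  expect_error(chrom_length(gs, "nope"), "unknown chromosome")
  expect_error(nick_sites("chr1", 101, "+", genome = gs), "beyond")
})
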