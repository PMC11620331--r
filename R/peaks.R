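#' Threshold-based peak calling on combined-strand coverage
#'
#' Calls peaks as maximal runs of combined (plus + minus) per-base signal
#' strictly greater than `min_signal`, merging runs separated by at most
#' `merge_gap` bp. Each peak is annotated with its summit (position of the
#' maximum; leftmost on ties), its signal (the maximum value), and a Poisson
#' upper-tail probability of the summit count under a uniform background of
#' `background_rate` reads per bp, used as the significance surrogate
#' (`qsurrogate`). Peaks are filtered to `qsurrogate < max_q`, mirroring the
#' standard signal > 3 / q < 0.001 filter applied to broad-peak callers'
#' output in this assay.
#'
#' @param track A normalized (`RPM` or `spike_normalized`)
#'   [stranded_track()].
#' @param min_signal Minimum combined per-base signal; default 3.
#' @param merge_gap Maximum sub-threshold gap (bp) merged into one peak.
#' @param background_rate Expected background signal per bp for the Poisson
#'   surrogate.
#' @param max_q Significance filter threshold; default 0.001. Use `1` to
#'   disable.
#' @return A sorted, disjoint `GRanges` (1-based, as GRanges convention)
#'   with metadata columns `name`, `signal`, `qsurrogate`, `summit`
#'   (0-based absolute position), `site_labels` (filled by
#'   [qualify_peaks()]), `site_distance`.
#' @export
call_peaks <- function(track, min_signal = 3, merge_gap = 100,
                       background_rate = 0.01, max_q = 0.001) {
  stopifnot(inherits(track, "stranded_track"))
  if (min_signal <= 0) stop("min_signal must be > 0")
  if (track$normalization == "raw")
    stop("call_peaks requires a normalized track (RPM or spike_normalized)")
  out <- list()
  for (ch in names(track$plus)) {
    comb <- track$plus[[ch]] + track$minus[[ch]]
    above <- comb > min_signal
    ir <- methods::as(above, "IRanges")  # TRUE runs, 1-based
    if (length(ir) == 0L) next
    if (merge_gap > 0)
      ir <- IRanges::reduce(ir, min.gapwidth = merge_gap + 1L)
    v <- IRanges::Views(comb, ir)
    summit1 <- IRanges::viewWhichMaxs(v)  # 1-based, leftmost on ties
    sig <- IRanges::viewMaxs(v)
    # P(X > floor(signal)) under Poisson(background_rate)
    q <- stats::ppois(floor(sig), lambda = background_rate,
                      lower.tail = FALSE)
    gr <- GenomicRanges::GRanges(ch, ir)
    S4Vectors::mcols(gr)$signal <- sig
    S4Vectors::mcols(gr)$qsurrogate <- q
    S4Vectors::mcols(gr)$summit <- summit1 - 1
    out[[ch]] <- gr[q < max_q]
  }
  if (length(out) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      name = character(0), signal = numeric(0), qsurrogate = numeric(0),
      summit = numeric(0), site_labels = I(list()),
      site_distance = numeric(0))
    return(gr)
  }
  gr <- sort(do.call(c, unname(out)))
  S4Vectors::mcols(gr)$name <- sprintf("peak_%d", seq_along(gr))
  S4Vectors::mcols(gr)$site_labels <- I(rep(list(character(0)),
                                            length(gr)))
  S4Vectors::mcols(gr)$site_distance <- rep(-1, length(gr))
  S4Vectors::mcols(gr) <- S4Vectors::mcols(gr)[
    , c("name", "signal", "qsurrogate", "summit", "site_labels",
        "site_distance")]
  gr
}

#' Qualify peaks for asymmetry analysis
#'
#' Retains only peaks suitable for single-nick asymmetry scoring: a peak must
#' contain exactly one target site, and that site must be more than
#' `min_separation` bp away (site-to-site distance) from every other target
#' site, removing multi-nicking composites and near-neighbour interference.
#' Retained peaks get `site_labels` (the contained site) and `site_distance`
#' (distance to the nearest other site, -1 when there is no other site).
#' The counts discarded per rule are attached as attribute `"qualification"`.
#'
#' @param peaks `GRanges` from [call_peaks()].
#' @param target_sites A [nick_sites()] table.
#' @param min_separation Minimum distance to other target sites (bp);
#'   default 8000.
#' @return The qualified subset of `peaks`. Idempotent.
#' @export
qualify_peaks <- function(peaks, target_sites, min_separation = 8000) {
  if (length(peaks) == 0L) return(peaks)
  sites <- GenomicRanges::GRanges(
    target_sites$chrom,
    IRanges::IRanges(start = target_sites$position + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(peaks, sites, ignore.strand = TRUE)
  n_in <- S4Vectors::countQueryHits(hits)

  # site-to-site distance to the nearest OTHER target site
  site_dist <- rep(Inf, nrow(target_sites))
  for (ch in unique(target_sites$chrom)) {
    idx <- which(target_sites$chrom == ch)
    if (length(idx) < 2L) next
    p <- sort(target_sites$position[idx], index.return = TRUE)
    gaps <- diff(p$x)
    d <- pmin(c(Inf, gaps), c(gaps, Inf))
    site_dist[idx[p$ix]] <- d
  }

  keep <- rep(FALSE, length(peaks))
  labels <- rep(list(character(0)), length(peaks))
  dists <- rep(-1, length(peaks))
  single <- which(n_in == 1L)
  for (i in single) {
    s <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
    labels[[i]] <- target_sites$label[s]
    dists[i] <- if (is.finite(site_dist[s])) site_dist[s] else -1
    keep[i] <- is.infinite(site_dist[s]) || site_dist[s] > min_separation
  }
  out <- peaks[keep]
  S4Vectors::mcols(out)$site_labels <- I(labels[keep])
  S4Vectors::mcols(out)$site_distance <- dists[keep]
  attr(out, "qualification") <- c(
    n_input = length(peaks),
    discarded_no_site = sum(n_in == 0L),
    discarded_multi_site = sum(n_in > 1L),
    discarded_too_close = length(single) - sum(keep[single]),
    n_kept = sum(keep))
  out
}

#' Total break-end signal around a nick
#'
#' Sums both strand channels over `[nick - halfwidth, nick + halfwidth)`,
#' clamped to the chromosome with a warning.
#'
#' @param track A [stranded_track()].
#' @param nick Single-row [nick_sites()] table.
#' @param halfwidth Window half-width (bp); default 30000 (the +/-30 kb
#'   intensity window).
#' @export
peak_intensity <- function(track, nick, halfwidth = 30000) {
  chrom <- nick$chrom[1]; pos <- nick$position[1]
  len <- length(track$plus[[chrom]])
  if (pos - halfwidth < 0 || pos + halfwidth > len)
    warning("intensity window clamped to the ends of ", chrom)
  track_window_sum(track, chrom, pos - halfwidth, pos + halfwidth)
}
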