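#' Resection length at a uniquely targeted site (boundary method)
#'
#' Estimates the resection tract length on one side of a nick as the
#' distance from the nick to the far edge of the break-end signal peak. The
#' background threshold is `tau = mean + k_sigma * sd` of the combined
#' per-base signal over a flank background region well outside the peak;
#' scanning outward from the nick, the boundary is the farthest position
#' with signal `>= tau` reachable without crossing a sub-threshold gap
#' longer than `max_gap` bp (dips inside a peak are tolerated up to that
#' gap).
#'
#' @param track A [stranded_track()].
#' @param nick Single-row [nick_sites()] table.
#' @param side `"left"` or `"right"` of the nick.
#' @param flank_bg_region `c(from, to)`: distances (bp) from the nick, on
#'   the scanned side, delimiting the background region; default
#'   `c(20000, 30000)`, disjoint from any plausible peak.
#' @param k_sigma Threshold stringency; default 3.
#' @param max_gap Longest sub-threshold gap (bp) tolerated inside the peak;
#'   default 200.
#' @param tau_floor Threshold floor used when the background region is
#'   exactly flat zero (then mean = sd = 0 and any signal would qualify);
#'   default 1e-9, logged via a message.
#' @return Resection length in bp (0 when no signal clears the threshold).
#' @export
resection_length_unique <- function(track, nick, side = c("left", "right"),
                                    flank_bg_region = c(20000, 30000),
                                    k_sigma = 3, max_gap = 200,
                                    tau_floor = 1e-9) {
  side <- match.arg(side)
  chrom <- nick$chrom[1]; pos <- nick$position[1]
  dirn <- if (side == "left") -1 else 1
  bg_from <- pos + dirn * flank_bg_region[2]
  bg_to <- pos + dirn * flank_bg_region[1]
  bg <- track_window_values(track, chrom, min(bg_from, bg_to),
                            max(bg_from, bg_to))
  if (length(bg) == 0L) stop("flank background region is empty")
  tau <- mean(bg) + k_sigma * stats::sd(bg)
  if (!is.finite(tau) || tau <= 0) {
    message("flat zero background; using threshold floor ", tau_floor)
    tau <- tau_floor
  }
  scan_to <- flank_bg_region[1]
  vals <- if (side == "left")
    rev(track_window_values(track, chrom, pos - scan_to, pos))
  else
    track_window_values(track, chrom, pos, pos + scan_to)
  # outward scan: farthest above-threshold position with no gap > max_gap
  boundary <- 0L
  gap <- 0L
  for (i in seq_along(vals)) {
    if (vals[i] >= tau) {
      boundary <- i
      gap <- 0L
    } else {
      gap <- gap + 1L
      if (gap > max_gap) break
    }
  }
  as.numeric(boundary)
}

#' Resection length by the twelve-bin sliding-window method
#'
#' The estimator used at degenerate (multi-site) nicks: the scanned side is
#' cut into `bin`-bp bins outward from the nick; the background `B` is the
#' mean bin signal over bins fully inside `bg_range` (default 7-9 kb from
#' the nick); a window of `win_bins` bins slides outward one bin at a time;
#' at the first window in which strictly more than `trigger_below` bins have
#' signal strictly below `B`, the endpoint is the outer (far-from-nick) edge
#' of the farthest bin in that window with signal strictly above `B`. Ties
#' with `B` count as neither below nor above. If no window triggers before
#' `search_limit`, the limit itself is returned with `at_limit = TRUE`
#' (the hyper-resection regime); if the triggering window holds no
#' above-background bin, the endpoint falls back to the outer edge of the
#' last above-background bin seen before the window (0 if none).
#'
#' @param track A [stranded_track()].
#' @param nick Single-row [nick_sites()] table.
#' @param side `"left"` or `"right"`.
#' @param bin Bin width (bp); default 50.
#' @param win_bins Bins per sliding window; default 12.
#' @param bg_range `c(from, to)` distances (bp) from the nick delimiting the
#'   background bins; default `c(7000, 9000)`.
#' @param trigger_below The window triggers when more than this many bins
#'   are below background; default 8 (i.e. >= 9 of 12).
#' @param search_limit Farthest distance scanned (bp); default 50000.
#' @param bg_floor Substitute background when the background bins average
#'   exactly 0 (strict comparisons would otherwise never trigger); default
#'   1e-9.
#' @return List with `length` (bp, a multiple of `bin`), `at_limit`,
#'   `background`.
#' @export
resection_length_sliding <- function(track, nick, side = c("left", "right"),
                                     bin = 50, win_bins = 12,
                                     bg_range = c(7000, 9000),
                                     trigger_below = 8,
                                     search_limit = 50000,
                                     bg_floor = 1e-9) {
  side <- match.arg(side)
  if (search_limit < win_bins * bin)
    stop("search_limit must cover at least one window")
  chrom <- nick$chrom[1]; pos <- nick$position[1]
  n_bins <- floor(search_limit / bin)
  vals <- side_values(track, chrom, pos, side, n_bins * bin)
  bins <- bin_sums(vals, bin)            # signal per bin, outward order

  bg_lo <- ceiling(bg_range[1] / bin)    # bins fully inside bg_range
  bg_hi <- floor(bg_range[2] / bin)
  bg_vals <- side_values(track, chrom, pos, side, bg_hi * bin)
  bg_bins <- bin_sums(bg_vals, bin)[(bg_lo + 1):bg_hi]
  if (length(bg_bins) == 0L) stop("background region holds no full bin")
  B <- mean(bg_bins)
  if (B <= 0) B <- bg_floor

  sliding_scan(bins, B, bin, win_bins, trigger_below)
}

# per-base values on one side of pos, ordered outward from the nick
side_values <- function(track, chrom, pos, side, extent) {
  if (side == "left")
    rev(track_window_values(track, chrom, pos - extent, pos))
  else
    track_window_values(track, chrom, pos, pos + extent)
}

bin_sums <- function(vals, bin) {
  n <- floor(length(vals) / bin)
  if (n == 0L) return(numeric(0))
  colSums(matrix(vals[seq_len(n * bin)], nrow = bin))
}

# core sliding-window decision; bins are outward-ordered bin sums
sliding_scan <- function(bins, B, bin, win_bins, trigger_below) {
  n <- length(bins)
  above <- bins > B
  below <- bins < B
  last_above_before <- 0L  # outer edge (bin index) of last above bin seen
  for (w in seq_len(n - win_bins + 1L)) {
    idx <- w:(w + win_bins - 1L)
    if (sum(below[idx]) > trigger_below) {
      in_win_above <- idx[above[idx]]
      endpoint_bin <- if (length(in_win_above) > 0L)
        max(in_win_above)
      else
        last_above_before
      return(list(length = endpoint_bin * bin, at_limit = FALSE,
                  background = B))
    }
    if (above[w]) last_above_before <- w
  }
  list(length = n * bin, at_limit = TRUE, background = B)
}

#' Order statistics of a set of resection lengths
#'
#' @param lengths Numeric vector of per-site (or per-side) resection
#'   lengths.
#' @return List with `max`, `median`, `n`.
#' @export
summarize_resection <- function(lengths) {
  lengths <- lengths[is.finite(lengths)]
  if (length(lengths) == 0L)
    stop("no finite resection lengths to summarize")
  list(max = max(lengths), median = stats::median(lengths),
       n = length(lengths))
}
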