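#' Peak asymmetry around a nick
#'
#' Counts break-end reads (both strand channels) in the windows
#' `[nick - window, nick)` (left, `L`) and `[nick, nick + window)` (right,
#' `R`; the nick base itself belongs to the right window under the half-open
#' convention) and returns
#' \deqn{asymmetry = 0.5 - R / (L + R)}
#' which ranges over \[-0.5, 0.5\]: 0.5 when all reads are left of the nick
#' (fully single-ended), 0 when reads are balanced (double-ended), negative
#' when the dominant end lies to the right. The magnitude is what
#' discriminates seDSBs from deDSBs; the sign records which side dominates,
#' which flips with fork direction.
#'
#' @param track A [stranded_track()].
#' @param nick Single-row [nick_sites()] table.
#' @param window Window width per side (bp); default 3000.
#' @return List with `asymmetry` (signed), `L`, `R`. When `L + R == 0` the
#'   asymmetry is `NA` (undefined; such sites are excluded from downstream
#'   correlation).
#' @examples
#' gs <- genome_spec(c(chr1 = 1000))
#' tr <- stranded_track(gs, plus = list(chr1 = rep(c(0, 150, 0), c(400, 1, 599))),
#'                      minus = list(chr1 = rep(c(0, 50, 0), c(600, 1, 399))),
#'                      total_reads = 200)
#' peak_asymmetry(tr, nick_sites("chr1", 500, "+"), window = 300)$asymmetry
#' # 0.5 - 50/200 = 0.25
#' @export
peak_asymmetry <- function(track, nick, window = 3000) {
  chrom <- nick$chrom[1]; pos <- nick$position[1]
  L <- track_window_sum(track, chrom, pos - window, pos)
  R <- track_window_sum(track, chrom, pos, pos + window)
  asym <- if (L + R > 0) 0.5 - R / (L + R) else NA_real_
  list(asymmetry = asym, L = L, R = R)
}

#' RPA strand asymmetry over a region
#'
#' Ratio of plus-strand to minus-strand RPA (ssDNA) reads over a region:
#' values far above 1 indicate resected DNA on one side only (single-ended
#' pattern), values near 1 a double-ended pattern.
#'
#' @param track A [stranded_track()] of RPA coverage.
#' @param chrom,start,end Region (0-based half-open).
#' @return List with `ratio`, `plus`, `minus`, and `censored` (`TRUE` when
#'   the minus-strand count is zero, in which case `ratio` is `Inf`).
#' @export
rpa_asymmetry <- function(track, chrom, start, end) {
  p <- track_window_sum(track, chrom, start, end, strand = "+")
  m <- track_window_sum(track, chrom, start, end, strand = "-")
  if (m == 0)
    return(list(ratio = Inf, plus = p, minus = m, censored = TRUE))
  list(ratio = p / m, plus = p, minus = m, censored = FALSE)
}

#' Classify a break's end structure from its asymmetry
#'
#' Magnitude thresholds follow the observed ranges: strongly asymmetric
#' breaks (|asymmetry| around 0.3-0.4) are single-ended, near-symmetric
#' breaks (|asymmetry| around 0-0.1) double-ended; the gap between the
#' defaults is reported as ambiguous.
#'
#' @param asymmetry Signed or unsigned asymmetry value(s).
#' @param se_threshold |asymmetry| at or above which the call is `"seDSB"`;
#'   default 0.25.
#' @param de_threshold |asymmetry| at or below which the call is `"deDSB"`;
#'   default 0.10.
#' @return Character vector in `{"seDSB", "deDSB", "ambiguous"}` (`NA` in,
#'   `NA` out).
#' @export
classify_end_structure <- function(asymmetry, se_threshold = 0.25,
                                   de_threshold = 0.10) {
  if (de_threshold >= se_threshold)
    stop("de_threshold must be below se_threshold")
  a <- abs(asymmetry)
  out <- ifelse(is.na(a), NA_character_,
                ifelse(a >= se_threshold, "seDSB",
                       ifelse(a <= de_threshold, "deDSB", "ambiguous")))
  out
}

#' Per-nick asymmetry table
#'
#' Convenience wrapper applying [peak_asymmetry()] and
#' [classify_end_structure()] to every nick site.
#'
#' @param track A [stranded_track()].
#' @param sites A [nick_sites()] table.
#' @param window Window width per side (bp).
#' @param ... Passed to [classify_end_structure()].
#' @return `data.frame` with columns label, chrom, position, target_strand,
#'   L, R, asymmetry, class.
#' @export
asymmetry_table <- function(track, sites, window = 3000, ...) {
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    a <- peak_asymmetry(track, sites[i, , drop = FALSE], window = window)
    data.frame(label = sites$label[i], chrom = sites$chrom[i],
               position = sites$position[i],
               target_strand = sites$target_strand[i],
               L = a$L, R = a$R, asymmetry = a$asymmetry,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$class <- classify_end_structure(out$asymmetry, ...)
  out
}
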