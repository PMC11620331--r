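#' Strand-specific per-base break-end coverage
#'
#' A `stranded_track` holds per-base, non-negative read-end counts on the
#' plus and minus strands of every chromosome of a [genome_spec()], stored as
#' run-length encoded vectors ([S4Vectors::Rle]). It carries the library-level
#' metadata the normalization formulas need: the total number of reads mapped
#' to the main genome, the number of reads mapped to the spike-in locus, and a
#' normalization state that may only advance `raw -> RPM -> spike_normalized`.
#'
#' `total_reads` is library size, deliberately carried as metadata rather
#' than inferred from in-track counts: reads mapped outside any region of
#' interest still count toward reads-per-million scaling.
#'
#' @param genome A [genome_spec()].
#' @param plus,minus Optional named lists (chromosome -> numeric vector or
#'   `Rle` of per-base counts). Missing chromosomes start at zero coverage.
#' @param total_reads Total main-genome mapped reads (library size).
#' @param spikein_reads Reads mapped to the spike-in locus.
#' @param normalization One of `"raw"`, `"RPM"`, `"spike_normalized"`.
#' @return An object of class `stranded_track`.
#' @examples
#' gs <- genome_spec(c(chr1 = 1000))
#' tr <- stranded_track(gs, plus = list(chr1 = rep(c(0, 2, 0), c(10, 5, 985))),
#'                      total_reads = 10)
#' track_window_sum(tr, "chr1", 0, 20)
#' @export
stranded_track <- function(genome, plus = NULL, minus = NULL,
                           total_reads = 0, spikein_reads = 0,
                           normalization = "raw") {
  stopifnot(inherits(genome, "genome_spec"))
  normalization <- match.arg(normalization,
                             c("raw", "RPM", "spike_normalized"))
  chroms <- all_chroms(genome)
  mk <- function(given) {
    out <- vector("list", length(chroms))
    names(out) <- chroms
    for (ch in chroms) {
      len <- chrom_length(genome, ch)
      v <- given[[ch]]
      if (is.null(v)) {
        out[[ch]] <- S4Vectors::Rle(0, len)
      } else {
        if (!methods::is(v, "Rle")) v <- S4Vectors::Rle(as.numeric(v))
        if (length(v) != len)
          stop("coverage on ", ch, " has length ", length(v),
               ", expected ", len)
        if (any(S4Vectors::runValue(v) < 0))
          stop("negative coverage on ", ch)
        out[[ch]] <- v
      }
    }
    out
  }
  structure(list(genome = genome, plus = mk(plus), minus = mk(minus),
                 total_reads = as.numeric(total_reads),
                 spikein_reads = as.numeric(spikein_reads),
                 normalization = normalization),
            class = "stranded_track")
}

#' @export
print.stranded_track <- function(x, ...) {
  cat("stranded_track [", x$normalization, "]: ",
      length(x$plus), " chromosome(s), total_reads = ", x$total_reads,
      ", spikein_reads = ", x$spikein_reads, "\n", sep = "")
  invisible(x)
}

strand_cov <- function(track, chrom, strand = c("both", "+", "-")) {
  strand <- match.arg(strand)
  p <- track$plus[[chrom]]
  m <- track$minus[[chrom]]
  if (is.null(p)) stop("unknown chromosome: ", chrom)
  switch(strand, "+" = p, "-" = m, both = p + m)
}

#' Sum of coverage over a window
#'
#' Sums per-base counts over the 0-based half-open interval
#' `[start, end)`, clamped to the chromosome.
#'
#' @param track A [stranded_track()].
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open bounds.
#' @param strand `"both"` (default), `"+"` or `"-"`.
#' @export
track_window_sum <- function(track, chrom, start, end,
                             strand = c("both", "+", "-")) {
  strand <- match.arg(strand)
  cov <- strand_cov(track, chrom, strand)
  len <- length(cov)
  s <- max(0, floor(start)); e <- min(len, ceiling(end))
  if (e <= s) return(0)
  sum(S4Vectors::window(cov, s + 1L, e))
}

#' Per-base coverage of a window as a plain numeric vector
#'
#' @inheritParams track_window_sum
#' @return Numeric vector of length `end - start` (clamped regions padded
#'   implicitly by clamping, so the returned length can be shorter at
#'   chromosome edges).
#' @export
track_window_values <- function(track, chrom, start, end,
                                strand = c("both", "+", "-")) {
  strand <- match.arg(strand)
  cov <- strand_cov(track, chrom, strand)
  len <- length(cov)
  s <- max(0, floor(start)); e <- min(len, ceiling(end))
  if (e <= s) return(numeric(0))
  as.numeric(S4Vectors::window(cov, s + 1L, e))
}

scale_track <- function(track, factor) {
  for (ch in names(track$plus)) {
    track$plus[[ch]] <- track$plus[[ch]] * factor
    track$minus[[ch]] <- track$minus[[ch]] * factor
  }
  track
}

#' Reads-per-million normalization
#'
#' Converts raw counts to normalized read density (reads per million, RPM):
#' every per-base count is multiplied by `1e6 / total_reads`, where
#' `total_reads` is the library size carried in the track metadata.
#'
#' @param track A raw-state [stranded_track()] with `total_reads > 0`.
#' @return The track with state `"RPM"`.
#' @export
compute_rpm <- function(track) {
  stopifnot(inherits(track, "stranded_track"))
  if (track$normalization != "raw")
    stop("compute_rpm requires a raw-state track (got ",
         track$normalization, ")")
  if (track$total_reads <= 0)
    stop("total mapped reads must be > 0 for RPM normalization")
  track <- scale_track(track, 1e6 / track$total_reads)
  track$normalization <- "RPM"
  track
}

#' Spike-in configuration
#'
#' @param locus_chrom,locus_start,locus_end The spike-in locus interval
#'   (0-based half-open) on a spike-in-namespace chromosome; a single
#'   fixed interval per experiment.
#' @param fraction Nominal cell fraction of spike-in material, in (0, 1);
#'   default 0.20.
#' @return A `spikein_config` list.
#' @export
spikein_config <- function(locus_chrom, locus_start, locus_end,
                           fraction = 0.20) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("spike-in fraction must lie strictly inside (0, 1)")
  if (locus_start >= locus_end) stop("empty spike-in locus")
  structure(list(locus_chrom = locus_chrom,
                 locus_start = as.numeric(locus_start),
                 locus_end = as.numeric(locus_end),
                 fraction = fraction),
            class = "spikein_config")
}

#' Spike-in normalization
#'
#' Scales an RPM track by the spike-in factor: the scaling factor is the
#' number of reads mapped to the spike-in locus divided by the total number
#' of reads mapped to the main genome, and every RPM value is divided by it.
#' More spike-in signal therefore yields smaller normalized values, which is
#' the behaviour that makes independently sequenced samples comparable when
#' the spike-in material was mixed in at a fixed cell fraction.
#'
#' @param track An RPM-state [stranded_track()] with `spikein_reads > 0`.
#' @param config A [spikein_config()] (kept for provenance; the counts used
#'   live in the track metadata).
#' @return The track with state `"spike_normalized"`.
#' @export
spikein_normalize <- function(track, config) {
  stopifnot(inherits(track, "stranded_track"),
            inherits(config, "spikein_config"))
  if (track$normalization != "RPM")
    stop("spikein_normalize requires an RPM-state track (got ",
         track$normalization, ")")
  if (track$spikein_reads <= 0)
    stop("no reads mapped to the spike-in locus; normalization impossible")
  if (track$total_reads <= 0)
    stop("total mapped reads must be > 0")
  factor <- track$spikein_reads / track$total_reads
  track <- scale_track(track, 1 / factor)
  track$normalization <- "spike_normalized"
  track
}

#' Count reads overlapping the spike-in locus
#'
#' Sums both strand channels over the configured locus interval; spike-in
#' locus reads are counted without strand resolution.
#'
#' @inheritParams spikein_normalize
#' @export
count_spikein_reads <- function(track, config) {
  track_window_sum(track, config$locus_chrom, config$locus_start,
                   config$locus_end)
}
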