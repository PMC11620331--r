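#' Binned replication fork directionality (RFD)
#'
#' RFD per bin is `(C - W) / (C + W)` with `C` the Crick-strand and `W` the
#' Watson-strand fragment count, so RFD lies in \[-1, 1\] and positive
#' values mean predominantly rightward-moving forks. This polarity is fixed
#' at the API; stranded inputs from chemistries with the opposite labelling
#' convention (e.g. some nascent-strand protocols) must be sign-flipped by
#' the caller. Bins with `C + W == 0` carry `NA` (undefined).
#'
#' @param counts Either a `data.frame` with columns `chrom`, `start`,
#'   `crick`, `watson` (binned stranded fragment counts; `end` optional) or
#'   a [stranded_track()], in which case the minus channel is taken as Crick
#'   and the plus channel as Watson and counts are binned here.
#' @param bin_size Bin width in bp (required for a track input; for a
#'   data.frame it must match the bin grid).
#' @return An `rfd_profile`: a `data.frame` (chrom, start, end, crick,
#'   watson, rfd) with attribute `bin_size`.
#' @export
compute_rfd <- function(counts, bin_size = 1000) {
  if (bin_size <= 0) stop("bin_size must be > 0")
  if (inherits(counts, "stranded_track")) {
    rows <- list()
    for (ch in names(counts$plus)) {
      len <- length(counts$plus[[ch]])
      starts <- seq(0, len - 1, by = bin_size)
      ends <- pmin(starts + bin_size, len)
      W <- vapply(seq_along(starts), function(i)
        track_window_sum(counts, ch, starts[i], ends[i], strand = "+"),
        numeric(1))
      C <- vapply(seq_along(starts), function(i)
        track_window_sum(counts, ch, starts[i], ends[i], strand = "-"),
        numeric(1))
      rows[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                               crick = C, watson = W,
                               stringsAsFactors = FALSE)
    }
    counts <- do.call(rbind, rows)
  } else {
    counts <- as.data.frame(counts)
    if (!all(c("chrom", "start", "crick", "watson") %in% names(counts)))
      stop("binned counts need columns chrom, start, crick, watson")
    if (is.null(counts$end)) counts$end <- counts$start + bin_size
  }
  if (any(counts$crick < 0 | counts$watson < 0))
    stop("fragment counts must be non-negative")
  rfd_profile(counts, bin_size = bin_size)
}

rfd_profile <- function(df, bin_size) {
  tot <- df$crick + df$watson
  df$rfd <- ifelse(tot > 0, (df$crick - df$watson) / tot, NA_real_)
  attr(df, "bin_size") <- bin_size
  class(df) <- c("rfd_profile", "data.frame")
  df
}

#' RFD value at a position
#'
#' Returns the RFD of the bin containing the position (no interpolation);
#' `NA` when the position falls in no bin or in an undefined (empty) bin.
#'
#' @param profile An `rfd_profile` from [compute_rfd()].
#' @param chrom,position Query point (0-based).
#' @export
rfd_at <- function(profile, chrom, position) {
  i <- which(profile$chrom == chrom & profile$start <= position &
               position < profile$end)
  if (length(i) == 0L) return(NA_real_)
  profile$rfd[i[1]]
}

#' Leading/lagging designation of a nick from local RFD
#'
#' A nick targeted to the Crick strand in a region of positive RFD
#' (rightward forks) is a lagging-strand nick, and with negative RFD a
#' leading-strand nick; a Watson-strand nick mirrors the rule. RFD exactly 0
#' or undefined yields `"unclassified"`.
#'
#' @param nick Single-row [nick_sites()] table (or list with
#'   `target_strand`).
#' @param rfd_at_nick RFD value of the bin containing the nick.
#' @return `"leading"`, `"lagging"` or `"unclassified"`.
#' @export
classify_nick <- function(nick, rfd_at_nick) {
  strand <- nick$target_strand[1]
  stopifnot(strand %in% c("+", "-"))
  if (is.na(rfd_at_nick) || rfd_at_nick == 0) return("unclassified")
  if (strand == "-") {
    if (rfd_at_nick > 0) "lagging" else "leading"
  } else {
    if (rfd_at_nick > 0) "leading" else "lagging"
  }
}

#' Correlate peak asymmetry with RFD within a nick class
#'
#' Spearman rank correlation (average-rank tie handling) between asymmetry
#' and RFD across the nicks of one designated class. For leading-strand
#' sites the magnitudes |asymmetry| and |RFD| are paired (their signs both
#' flip with fork direction, so magnitude carries the dose-response);
#' lagging-strand sites are paired the same way for comparability. Records
#' with non-finite asymmetry or RFD are dropped.
#'
#' @param records `data.frame` with columns `asymmetry`, `rfd`, `class`.
#' @param class Which designated class to correlate (`"leading"` or
#'   `"lagging"`).
#' @return List with `r` (Spearman; `NA` when an input vector is constant),
#'   `n`.
#' @export
correlate_asymmetry_rfd <- function(records, class) {
  sub <- records[records$class == class & is.finite(records$asymmetry) &
                   is.finite(records$rfd), , drop = FALSE]
  if (nrow(sub) < 3L)
    stop("need at least 3 finite records in class ", class)
  x <- abs(sub$asymmetry); y <- abs(sub$rfd)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, n = nrow(sub)))
  list(r = stats::cor(x, y, method = "spearman"), n = nrow(sub))
}
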