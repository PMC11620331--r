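#' Call a single deletion from an amplicon read
#'
#' Explains a read as the reference minus one contiguous deletion: the
#' longest read prefix matching the reference prefix and the longest read
#' suffix matching the reference suffix are found; when together they cover
#' the whole read and the reference is longer, the read is a single-deletion
#' product and the call is canonicalized by left-alignment (the smallest
#' deletion start compatible with the read, the VCF convention), which makes
#' microhomology length well defined and coordinates stable. A read equal to
#' the reference yields no call; a read not explicable by one deletion is
#' `"unclassified"`.
#'
#' @param read,ref Character (or `DNAString`) sequences; `read` no longer
#'   than `ref`.
#' @return `NULL` for an intact read; the string `"unclassified"` when one
#'   deletion cannot explain the read; otherwise a `data.frame` row with
#'   `del_start`, `del_end` (0-based half-open on the reference),
#'   `del_length`, `microhomology`.
#' @examples
#' call_deletion("ACGTAA", "ACGTACGTAA")  # 4-bp deletion, left-aligned
#' @export
call_deletion <- function(read, ref) {
  read <- as.character(read); ref <- as.character(ref)
  if (nchar(read) == 0L) stop("empty read")
  if (read == ref) return(NULL)
  n <- nchar(read); L <- nchar(ref)
  if (n > L) return("unclassified")
  rd <- strsplit(read, "")[[1]]
  rf <- strsplit(ref, "")[[1]]
  p <- 0L
  while (p < n && rd[p + 1L] == rf[p + 1L]) p <- p + 1L
  s <- 0L
  while (s < n && rd[n - s] == rf[L - s]) s <- s + 1L
  if (p + s < n) return("unclassified")
  d <- L - n
  if (d == 0L) return("unclassified")  # same length but mismatched
  del_start <- max(0L, n - s)          # leftmost compatible start (<= p)
  del_end <- del_start + d
  data.frame(del_start = del_start, del_end = del_end, del_length = d,
             microhomology = microhomology_length(ref, del_start, del_end))
}

#' Junctional microhomology length of a deletion
#'
#' The largest `m` such that the `m` bases starting at the deletion start
#' equal the `m` bases starting at the deletion end
#' (`ref[del_start, del_start + m) == ref[del_end, del_end + m)`), bounded
#' by the remaining reference length. This is the length of identical
#' sequence shared by the two junction flanks — the signature of
#' microhomology-mediated end joining.
#'
#' @param ref Reference sequence.
#' @param del_start,del_end Deletion bounds, 0-based half-open.
#' @return Integer microhomology length.
#' @export
microhomology_length <- function(ref, del_start, del_end) {
  ref <- as.character(ref)
  L <- nchar(ref)
  stopifnot(del_start >= 0, del_start < del_end, del_end <= L)
  m <- 0L
  while (del_end + m < L &&
         substr(ref, del_start + m + 1L, del_start + m + 1L) ==
         substr(ref, del_end + m + 1L, del_end + m + 1L))
    m <- m + 1L
  m
}

#' Call deletions across a read set
#'
#' Applies [call_deletion()] to every read and aggregates identical
#' `(del_start, del_end)` calls.
#'
#' @param reads `DNAStringSet` or character vector of reads.
#' @param ref Reference sequence.
#' @return List with `calls` (one row per distinct deletion, with
#'   `n_reads` support), `n_reads`, `n_intact`, `n_deletion`,
#'   `n_unclassified`.
#' @export
call_deletions <- function(reads, ref) {
  reads <- as.character(reads)
  intact <- 0L; unclass <- 0L
  rows <- list()
  for (rd in reads) {
    res <- call_deletion(rd, ref)
    if (is.null(res)) intact <- intact + 1L
    else if (identical(res, "unclassified")) unclass <- unclass + 1L
    else rows[[length(rows) + 1L]] <- res
  }
  if (length(rows) > 0L) {
    calls <- do.call(rbind, rows)
    agg <- stats::aggregate(list(n_reads = rep(1L, nrow(calls))),
                            by = calls[c("del_start", "del_end",
                                         "del_length", "microhomology")],
                            FUN = sum)
    agg <- agg[order(agg$del_start, agg$del_end), , drop = FALSE]
    rownames(agg) <- NULL
  } else {
    agg <- data.frame(del_start = integer(0), del_end = integer(0),
                      del_length = integer(0), microhomology = integer(0),
                      n_reads = integer(0))
  }
  list(calls = agg, n_reads = length(reads), n_intact = intact,
       n_deletion = length(rows), n_unclassified = unclass)
}

#' Summarize deletion junctions
#'
#' @param callset Result of [call_deletions()].
#' @param length_breaks Deletion-length bin edges for the frequency table.
#' @return List with `table` (deletion-length bin x microhomology length
#'   read counts), `fraction_deleted` (reads with a deletion among
#'   classified reads), `fraction_mh_ge2` (deletion reads with
#'   microhomology >= 2), `modal_microhomology` (`NA` when no deletions).
#' @export
summarize_junctions <- function(callset,
                                length_breaks = c(0, 10, 25, 50, 100, Inf)) {
  calls <- callset$calls
  if (nrow(calls) == 0L) {
    return(list(table = table(factor(levels = "none"), factor(levels = "0")),
                fraction_deleted = 0, fraction_mh_ge2 = 0,
                modal_microhomology = NA_real_))
  }
  len_bin <- cut(calls$del_length, breaks = length_breaks, right = FALSE,
                 include.lowest = TRUE)
  tab <- stats::xtabs(n_reads ~ len_bin + microhomology, data =
                        data.frame(len_bin = len_bin,
                                   microhomology = calls$microhomology,
                                   n_reads = calls$n_reads))
  n_del_reads <- sum(calls$n_reads)
  mh_per_read <- rep(calls$microhomology, calls$n_reads)
  mh_counts <- table(mh_per_read)
  list(table = tab,
       fraction_deleted = n_del_reads /
         (n_del_reads + callset$n_intact),
       fraction_mh_ge2 = sum(calls$n_reads[calls$microhomology >= 2]) /
         n_del_reads,
       modal_microhomology =
         as.numeric(names(mh_counts)[which.max(mh_counts)]))
}
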