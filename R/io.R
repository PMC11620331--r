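#' Read a pair of strand-specific bedGraph files into a track
#'
#' Reads 4-column bedGraph (chrom, start, end, value; 0-based half-open,
#' UCSC dialect) for each strand and expands intervals to per-base counts.
#' Overlapping intervals are summed. Lines beginning with `#`, `track` or
#' `browser` are skipped. An empty (or absent-strand) file yields an all-zero
#' channel.
#'
#' @param path_plus,path_minus bedGraph paths for plus- and minus-strand
#'   read ends.
#' @param genome A [genome_spec()]; every chromosome in the files must
#'   resolve in it.
#' @param total_reads,spikein_reads Library metadata to attach (see
#'   [stranded_track()]).
#' @return A raw-state [stranded_track()].
#' @export
read_stranded_bedgraph <- function(path_plus, path_minus, genome,
                                   total_reads = 0, spikein_reads = 0) {
  plus <- bedgraph_to_cov(path_plus, genome)
  minus <- bedgraph_to_cov(path_minus, genome)
  stranded_track(genome, plus = plus, minus = minus,
                 total_reads = total_reads, spikein_reads = spikein_reads)
}

read_bedgraph_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]; lineno <- lineno[keep]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), value = numeric(),
                      lineno = integer()))
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 4L))
    stop("malformed bedGraph line ", lineno[which(nf < 4L)[1]],
         " in ", path, ": fewer than 4 fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  value <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  bad <- which(!is.finite(start) | !is.finite(end) | !is.finite(value))
  if (length(bad) > 0L)
    stop("malformed bedGraph line ", lineno[bad[1]], " in ", path,
         ": non-numeric field")
  bad <- which(start >= end | start < 0)
  if (length(bad) > 0L)
    stop("malformed bedGraph line ", lineno[bad[1]], " in ", path,
         ": start must satisfy 0 <= start < end")
  bad <- which(value < 0)
  if (length(bad) > 0L)
    stop("negative value on bedGraph line ", lineno[bad[1]], " in ", path)
  data.frame(chrom = chrom, start = start, end = end, value = value,
             lineno = lineno, stringsAsFactors = FALSE)
}

bedgraph_to_cov <- function(path, genome) {
  tab <- read_bedgraph_table(path)
  cov <- list()
  if (nrow(tab) == 0L) return(cov)
  for (ch in unique(tab$chrom)) {
    len <- chrom_length(genome, ch)  # errors on unknown chromosome
    sub <- tab[tab$chrom == ch, , drop = FALSE]
    if (any(sub$end > len))
      stop("bedGraph line ", sub$lineno[which(sub$end > len)[1]], " in ",
           path, ": interval beyond end of ", ch)
    cov[[ch]] <- IRanges::coverage(
      IRanges::IRanges(start = sub$start + 1L, end = sub$end),
      weight = sub$value, width = len)
  }
  cov
}

#' Write a track as a pair of strand-specific bedGraph files
#'
#' Emits one 4-column bedGraph per strand with zero runs omitted, preceded
#' by a `#` header comment recording the normalization state so a reader can
#' tell raw counts from normalized density. Round-trips losslessly through
#' [read_stranded_bedgraph()].
#'
#' @param track A [stranded_track()].
#' @param path_plus,path_minus Output paths.
#' @export
write_track_bedgraph <- function(track, path_plus, path_minus) {
  write_one <- function(covs, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# forkcollapse bedGraph; normalization=",
                      track$normalization), con)
    for (ch in names(covs)) {
      rle <- covs[[ch]]
      ends <- cumsum(S4Vectors::runLength(rle))
      starts <- c(0, ends[-length(ends)])
      vals <- S4Vectors::runValue(rle)
      keep <- vals != 0
      if (!any(keep)) next
      writeLines(sprintf("%s\t%s\t%s\t%s", ch,
                         format(starts[keep], scientific = FALSE, trim = TRUE),
                         format(ends[keep], scientific = FALSE, trim = TRUE),
                         format(vals[keep], digits = 15, scientific = FALSE,
                                trim = TRUE)), con)
    }
  }
  write_one(track$plus, path_plus)
  write_one(track$minus, path_minus)
  invisible(c(path_plus, path_minus))
}

#' Write and read nick sites as BED6
#'
#' Nick sites are written as width-1 BED6 features (`start = position`,
#' `end = position + 1`), name = label, score = 0, strand = target strand.
#'
#' @param sites A [nick_sites()] table.
#' @param path File path.
#' @export
write_nicks_bed <- function(sites, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# forkcollapse nick sites (BED6; nick at interval start)", con)
  if (nrow(sites) > 0L)
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", sites$chrom,
                       as.integer(sites$position),
                       as.integer(sites$position) + 1L,
                       sites$label, sites$target_strand), con)
  invisible(path)
}

#' @rdname write_nicks_bed
#' @param genome Optional [genome_spec()] for range checking.
#' @export
read_nicks_bed <- function(path, genome = NULL) {
  tab <- read_bed_table(path, min_fields = 6L)
  nick_sites(chrom = tab$V1, position = as.numeric(tab$V2),
             target_strand = tab$V6, label = tab$V4, genome = genome)
}

read_bed_table <- function(path, min_fields) {
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]; lineno <- lineno[keep]
  if (length(lines) == 0L) {
    out <- as.data.frame(matrix(character(), 0, min_fields))
    names(out) <- paste0("V", seq_len(min_fields))
    return(out)
  }
  fields <- strsplit(lines, "\t")
  nf <- lengths(fields)
  if (any(nf < min_fields))
    stop("malformed BED line ", lineno[which(nf < min_fields)[1]], " in ",
         path, ": fewer than ", min_fields, " fields")
  out <- as.data.frame(do.call(rbind, lapply(fields, `[`, seq_len(min_fields))),
                       stringsAsFactors = FALSE)
  names(out) <- paste0("V", seq_len(min_fields))
  out
}

#' Write and read called peaks
#'
#' Peaks are serialized in a narrowPeak-flavoured BED6+4 layout:
#' chrom, start, end, name, score (= signal, as BED convention), strand (.),
#' then signal, the Poisson-tail significance surrogate, the summit position
#' (absolute, 0-based), and two annotation columns (contained site labels,
#' comma-separated, and distance to the nearest other target site, -1 when
#' undefined). Round-trips losslessly through [read_peaks_bed()].
#'
#' @param peaks A `GRanges` as returned by [call_peaks()].
#' @param path File path.
#' @export
write_peaks_bed <- function(peaks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# forkcollapse peaks (BED6+4: signal, qsurrogate, summit, site_labels, site_distance)", con)
  if (length(peaks) > 0L) {
    mc <- S4Vectors::mcols(peaks)
    labels <- vapply(mc$site_labels, function(x)
      if (length(x) == 0L) "." else paste(x, collapse = ","), "")
    fmt <- function(x) vapply(x, format, "", digits = 15, trim = TRUE)
    writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t.\t%s\t%s\t%d\t%s\t%s",
                       as.character(GenomicRanges::seqnames(peaks)),
                       GenomicRanges::start(peaks) - 1L,
                       GenomicRanges::end(peaks),
                       mc$name,
                       fmt(mc$signal),
                       fmt(mc$signal),
                       fmt(mc$qsurrogate),
                       as.integer(mc$summit),
                       labels,
                       fmt(mc$site_distance)),
               con)
  }
  invisible(path)
}

#' @rdname write_peaks_bed
#' @export
read_peaks_bed <- function(path) {
  tab <- read_bed_table(path, min_fields = 11L)
  gr <- GenomicRanges::GRanges(
    seqnames = tab$V1,
    ranges = IRanges::IRanges(start = as.numeric(tab$V2) + 1L,
                              end = as.numeric(tab$V3)))
  S4Vectors::mcols(gr)$name <- tab$V4
  S4Vectors::mcols(gr)$signal <- as.numeric(tab$V7)
  S4Vectors::mcols(gr)$qsurrogate <- as.numeric(tab$V8)
  S4Vectors::mcols(gr)$summit <- as.numeric(tab$V9)
  S4Vectors::mcols(gr)$site_labels <- I(lapply(tab$V10, function(x)
    if (identical(x, ".")) character(0) else strsplit(x, ",")[[1]]))
  S4Vectors::mcols(gr)$site_distance <- as.numeric(tab$V11)
  gr
}
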