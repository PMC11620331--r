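#' Define a genome with an optional spike-in namespace
#'
#' A `genome_spec` names the chromosomes of the main (sample) genome and,
#' optionally, of an exogenous spike-in genome mixed into the library for
#' cross-sample normalization. Every coordinate used elsewhere in the package
#' resolves against exactly one of the two namespaces, so a chromosome name
#' may not appear in both.
#'
#' @param main Named integer/numeric vector: chromosome name -> length in bp.
#' @param spikein Optional named vector for the spike-in genome, same form.
#' @return An object of class `genome_spec`.
#' @examples
#' gs <- genome_spec(c(chr1 = 2e5), spikein = c(spike1 = 5e4))
#' chrom_length(gs, "chr1")
#' @export
genome_spec <- function(main, spikein = NULL) {
  check_chrom_table(main, "main")
  if (!is.null(spikein)) {
    check_chrom_table(spikein, "spikein")
    dup <- intersect(names(main), names(spikein))
    if (length(dup) > 0L)
      stop("chromosome name(s) present in both namespaces: ",
           paste(dup, collapse = ", "))
  }
  structure(list(main = as_len_vec(main),
                 spikein = if (is.null(spikein)) NULL else as_len_vec(spikein)),
            class = "genome_spec")
}

as_len_vec <- function(x) {
  out <- as.numeric(x)
  names(out) <- names(x)
  out
}

check_chrom_table <- function(x, what) {
  if (length(x) == 0L || is.null(names(x)) || any(!nzchar(names(x))))
    stop(what, " genome must be a non-empty named vector of lengths")
  if (anyDuplicated(names(x)))
    stop("duplicate chromosome names in ", what, " namespace")
  if (any(!is.finite(x)) || any(x <= 0))
    stop("chromosome lengths in ", what, " namespace must be positive")
  invisible(x)
}

#' @rdname genome_spec
#' @param genome A `genome_spec`.
#' @param chrom Chromosome name.
#' @export
chrom_length <- function(genome, chrom) {
  ns <- chrom_namespace(genome, chrom)
  unname(genome[[ns]][[chrom]])
}

#' Which namespace a chromosome belongs to
#'
#' @inheritParams chrom_length
#' @return `"main"` or `"spikein"`.
#' @export
chrom_namespace <- function(genome, chrom) {
  stopifnot(inherits(genome, "genome_spec"), is.character(chrom),
            length(chrom) == 1L)
  if (chrom %in% names(genome$main)) return("main")
  if (!is.null(genome$spikein) && chrom %in% names(genome$spikein))
    return("spikein")
  stop("unknown chromosome: ", chrom)
}

all_chroms <- function(genome) {
  c(names(genome$main),
    if (!is.null(genome$spikein)) names(genome$spikein))
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("genome_spec:", length(x$main), "main chromosome(s)")
  if (!is.null(x$spikein))
    cat(",", length(x$spikein), "spike-in chromosome(s)")
  cat("\n")
  invisible(x)
}

#' Nick-site table
#'
#' Nick sites are points, not intervals: `position` is the 0-based offset of
#' the broken phosphodiester bond, i.e. the nick lies between `position - 1`
#' and `position`. `target_strand` records which strand carries the nick
#' (`"+"` = Watson/top, `"-"` = Crick/bottom); together with the local
#' replication fork direction it determines whether a collision is a
#' leading-strand (run-off, single-ended) or lagging-strand (bypass,
#' double-ended) event.
#'
#' @param chrom Character vector of chromosome names.
#' @param position Integer vector, 0-based nick offsets.
#' @param target_strand `"+"` or `"-"` per site.
#' @param label Unique site labels; autogenerated when missing.
#' @param genome Optional `genome_spec` used to range-check positions.
#' @return A `data.frame` of class `nick_sites`.
#' @examples
#' nick_sites("chr1", 1e5, "-", "sg1")
#' @export
nick_sites <- function(chrom, position, target_strand, label = NULL,
                       genome = NULL) {
  n <- length(position)
  chrom <- rep_len(as.character(chrom), n)
  target_strand <- rep_len(as.character(target_strand), n)
  if (!all(target_strand %in% c("+", "-")))
    stop("target_strand must be '+' or '-'")
  if (any(position < 0))
    stop("nick positions must be non-negative")
  if (is.null(label))
    label <- sprintf("nick_%d", seq_len(n))
  if (anyDuplicated(label))
    stop("nick labels must be unique")
  if (!is.null(genome)) {
    for (i in seq_len(n)) {
      len <- chrom_length(genome, chrom[i])
      if (position[i] > len)
        stop("nick position ", position[i], " beyond end of ", chrom[i])
    }
  }
  out <- data.frame(chrom = chrom, position = as.numeric(position),
                    target_strand = target_strand,
                    label = as.character(label),
                    stringsAsFactors = FALSE)
  class(out) <- c("nick_sites", "data.frame")
  out
}
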