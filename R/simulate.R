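#' Parameters for the fork-collision simulator
#'
#' The simulator encodes the collision model relating nick strand and fork
#' direction to DSB end structure: when the replisome's leading-strand
#' template is broken, the replisome runs off and leaves a single DNA end on
#' the side the fork came from (seDSB); when the nick sits on the
#' lagging-strand template, the helicase bypasses it and a double-ended break
#' (deDSB) with one end on each side results. An unrepaired single end can
#' later gain a second end when a converging fork arrives from the other
#' side.
#'
#' @param fork_directionality Fraction `f` of rightward-moving forks at the
#'   nick, in \[0, 1\]. `f = (1 + RFD) / 2` for a given local RFD value.
#' @param cut_efficiency Fraction of simulated cells actually nicked.
#' @param convert_prob Probability that an unrepaired single-ended break is
#'   converted to double-ended by a converging fork.
#' @param convert_distance Distance (bp) from the nick at which the
#'   converging fork supplies the second end.
#' @param resection One of `"uniform"` (lengths uniform on `(0, max_length]`)
#'   or `"truncexp"` (truncated exponential with the given mean).
#' @param max_length Maximum resection tract length (bp).
#' @param resection_mean Mean for the truncated-exponential family.
#' @param background_rate Expected uniform background reads per bp
#'   (Poisson).
#' @param events Number of simulated cells per nick.
#' @return A `collision_sim_params` list.
#' @export
collision_sim_params <- function(fork_directionality = 0.85,
                                 cut_efficiency = 1,
                                 convert_prob = 0,
                                 convert_distance = 10000,
                                 resection = c("uniform", "truncexp"),
                                 max_length = 5000,
                                 resection_mean = 2000,
                                 background_rate = 0,
                                 events = 1000) {
  resection <- match.arg(resection)
  for (p in c(fork_directionality, cut_efficiency, convert_prob))
    if (!is.numeric(p) || p < 0 || p > 1)
      stop("probabilities must lie in [0, 1]")
  if (max_length <= 0) stop("max_length must be > 0")
  if (background_rate < 0) stop("background_rate must be >= 0")
  if (events < 1) stop("events must be >= 1")
  structure(list(fork_directionality = fork_directionality,
                 cut_efficiency = cut_efficiency,
                 convert_prob = convert_prob,
                 convert_distance = convert_distance,
                 resection = resection, max_length = max_length,
                 resection_mean = resection_mean,
                 background_rate = background_rate,
                 events = as.integer(events)),
            class = "collision_sim_params")
}

draw_resection <- function(params, n) {
  if (params$resection == "uniform") {
    # uniform on (0, max]: never exactly 0
    params$max_length * stats::runif(n)
  } else {
    q <- stats::runif(n) * stats::pexp(params$max_length,
                                       1 / params$resection_mean)
    stats::qexp(q, 1 / params$resection_mean)
  }
}

#' Background rate matching a target background read fraction
#'
#' Returns the per-bp Poisson rate at which uniform background contributes
#' the requested fraction of the expected signal-end count for the given
#' collision parameters on a chromosome of length `chrom_len`.
#'
#' @param params A [collision_sim_params()].
#' @param chrom_len Chromosome length in bp.
#' @param fraction Desired expected background reads as a fraction of
#'   expected signal-end reads (e.g. 0.05 for 5%).
#' @param target_strand Nick target strand (decides which fork direction is
#'   the leading-strand collision).
#' @export
background_rate_for_fraction <- function(params, chrom_len, fraction,
                                         target_strand = "+") {
  f <- params$fork_directionality
  leading_frac <- if (target_strand == "+") f else 1 - f
  # leading emits 1 end (+convert_prob for the converging-fork second end),
  # lagging emits 2
  ends <- leading_frac * (1 + params$convert_prob) + (1 - leading_frac) * 2
  expected <- params$events * params$cut_efficiency * ends
  fraction * expected / chrom_len
}

#' Which collision class a nick produces for a given fork direction
#'
#' A rightward fork replicating through a Crick-strand (`-`) nick meets a
#' broken lagging-strand template (bypass, double-ended); through a
#' Watson-strand (`+`) nick it meets a broken leading-strand template
#' (run-off, single-ended). Leftward forks mirror the rule.
#'
#' @param target_strand `"+"` or `"-"`.
#' @param rightward Logical, fork moving rightward?
#' @return `"leading"` or `"lagging"`.
#' @export
collision_class <- function(target_strand, rightward) {
  stopifnot(target_strand %in% c("+", "-"))
  if (rightward) {
    if (target_strand == "+") "leading" else "lagging"
  } else {
    if (target_strand == "+") "lagging" else "leading"
  }
}

#' Simulate break-end coverage at a nick-induced fork collapse
#'
#' Per simulated cell: draw the fork direction `Bernoulli(f)`; resolve the
#' collision class from fork direction and nick target strand
#' ([collision_class()]); a leading-strand collision emits one break end at
#' `nick - r` (rightward fork) or `nick + r` (leftward fork), where `r` is a
#' resection draw; a lagging-strand collision emits two ends at `nick - r1`
#' and `nick + r2` with independent draws. With probability `convert_prob`
#' an unrepaired single end gains a second end at the converging-fork
#' distance on the far side. Left-side ends are recorded on the plus-strand
#' channel and right-side ends on the minus-strand channel (a fixed package
#' convention; the asymmetry statistic is positional, not strand-based).
#' Uniform Poisson background is added to both channels. Positions falling
#' outside the chromosome are clamped to its ends with a warning.
#'
#' `total_reads` of the returned track is set to the number of emitted reads
#' so RPM normalization is immediately possible; event bookkeeping
#' (`n_signal_ends`, `n_background`, per-class event counts) is attached as
#' attribute `"sim_info"`.
#'
#' @param nick A single-row [nick_sites()] table (or a list with `chrom`,
#'   `position`, `target_strand`).
#' @param params A [collision_sim_params()].
#' @param genome A [genome_spec()].
#' @param seed Optional integer seed for reproducibility.
#' @return A raw-state [stranded_track()].
#' @export
simulate_collision_track <- function(nick, params, genome, seed = NULL) {
  stopifnot(inherits(params, "collision_sim_params"),
            inherits(genome, "genome_spec"))
  if (!is.null(seed)) set.seed(seed)
  chrom <- nick$chrom[1]; pos <- nick$position[1]
  strand <- nick$target_strand[1]
  len <- chrom_length(genome, chrom)

  n <- params$events
  nicked <- stats::runif(n) < params$cut_efficiency
  rightward <- stats::runif(n) < params$fork_directionality
  classes <- ifelse(rightward,
                    ifelse(strand == "+", "leading", "lagging"),
                    ifelse(strand == "+", "lagging", "leading"))
  classes[!nicked] <- "uncut"

  left_ends <- numeric(0)   # plus channel
  right_ends <- numeric(0)  # minus channel

  lead <- which(classes == "leading")
  if (length(lead) > 0L) {
    r <- draw_resection(params, length(lead))
    from_right_fork <- rightward[lead]
    # end lies on the side the incoming fork came from
    left_ends <- c(left_ends, pos - r[from_right_fork])
    right_ends <- c(right_ends, pos + r[!from_right_fork])
    # converging fork arrives from the side opposite the single end
    conv <- stats::runif(length(lead)) < params$convert_prob
    d <- params$convert_distance
    left_ends <- c(left_ends, rep(pos - d, sum(conv & !from_right_fork)))
    right_ends <- c(right_ends, rep(pos + d, sum(conv & from_right_fork)))
  }
  lag <- which(classes == "lagging")
  if (length(lag) > 0L) {
    r1 <- draw_resection(params, length(lag))
    r2 <- draw_resection(params, length(lag))
    left_ends <- c(left_ends, pos - r1)
    right_ends <- c(right_ends, pos + r2)
  }

  clamp <- function(x) {
    out <- pmin(pmax(x, 0), len - 1)
    if (any(out != x))
      warning("clamped ", sum(out != x),
              " break end(s) falling outside ", chrom)
    out
  }
  left_ends <- clamp(left_ends)
  right_ends <- clamp(right_ends)
  n_signal <- length(left_ends) + length(right_ends)

  n_bg <- stats::rpois(2L, params$background_rate * len)
  bg_plus <- floor(stats::runif(n_bg[1]) * len)
  bg_minus <- floor(stats::runif(n_bg[2]) * len)

  mk_cov <- function(ends) {
    counts <- tabulate(as.integer(floor(ends)) + 1L, nbins = len)
    S4Vectors::Rle(counts)
  }
  track <- stranded_track(
    genome,
    plus = stats::setNames(list(mk_cov(c(left_ends, bg_plus))), chrom),
    minus = stats::setNames(list(mk_cov(c(right_ends, bg_minus))), chrom),
    total_reads = n_signal + sum(n_bg))
  attr(track, "sim_info") <- list(
    n_signal_ends = n_signal, n_background = sum(n_bg),
    n_leading = length(lead), n_lagging = length(lag),
    n_uncut = sum(classes == "uncut"),
    left_ends = left_ends, right_ends = right_ends)
  track
}

#' Deterministic replication-fork-directionality field from origins
#'
#' Every position is replicated by a fork travelling away from its nearest
#' origin, so RFD is +1 (all rightward) to the right of an origin and -1 to
#' its left; between two adjacent origins the sign flips at their midpoint
#' (the termination zone). A linear blend of the given smoothing width is
#' applied across each midpoint; width 0 gives a hard step. Binned Crick and
#' Watson fragment counts consistent with the field are synthesized at the
#' stated depth so the profile can exercise [compute_rfd()]-style consumers.
#'
#' @param origin_positions Numeric vector of origin coordinates (bp).
#' @param genome A [genome_spec()]; the field is built on `chrom`.
#' @param chrom Chromosome name (default: first main chromosome).
#' @param bin_size Bin width in bp.
#' @param smoothing_width Width (bp) of the linear blend across termination
#'   midpoints.
#' @param depth Fragment count per bin used to synthesize Crick/Watson
#'   counts.
#' @return An `rfd_profile` (see [compute_rfd()]).
#' @export
simulate_rfd_field <- function(origin_positions, genome,
                               chrom = names(genome$main)[1],
                               bin_size = 1000, smoothing_width = 0,
                               depth = 100) {
  if (length(origin_positions) == 0L)
    stop("at least one origin is required")
  len <- chrom_length(genome, chrom)
  if (any(origin_positions < 0 | origin_positions > len))
    stop("origins must lie within ", chrom)
  origins <- sort(as.numeric(origin_positions))
  starts <- seq(0, len - 1, by = bin_size)
  ends <- pmin(starts + bin_size, len)
  centers <- (starts + ends) / 2

  rfd <- vapply(centers, function(x) {
    i <- findInterval(x, origins)
    if (i == 0L) return(-1)              # nearest origin to the right
    if (i == length(origins)) return(1)  # nearest origin to the left
    mid <- (origins[i] + origins[i + 1]) / 2
    if (smoothing_width > 0) {
      # linear ramp +1 -> -1 across the termination midpoint
      v <- 1 - 2 * (x - (mid - smoothing_width / 2)) / smoothing_width
      max(-1, min(1, v))
    } else if (x < mid) 1 else -1
  }, numeric(1))

  crick <- round(depth * (1 + rfd) / 2)
  watson <- depth - crick
  rfd_profile(data.frame(chrom = chrom, start = starts, end = ends,
                         crick = crick, watson = watson,
                         stringsAsFactors = FALSE),
              bin_size = bin_size)
}

#' Add spike-in locus reads to a track
#'
#' Draws the number of spike-in reads as `Binomial(depth, fraction)` —
#' modelling spike-in cells mixed at a fixed cell fraction, each contributing
#' break-end reads at a single fixed locus — places them uniformly over the
#' configured locus on both strand channels, and updates the track's
#' `spikein_reads` metadata.
#'
#' @param track A raw-state [stranded_track()] whose genome has a spike-in
#'   namespace containing the configured locus.
#' @param config A [spikein_config()].
#' @param depth Number of cells/fragments sampled.
#' @param seed Optional integer seed.
#' @return The track with spike-in coverage and metadata set.
#' @export
simulate_spikein <- function(track, config, depth, seed = NULL) {
  stopifnot(inherits(track, "stranded_track"),
            inherits(config, "spikein_config"))
  if (!is.null(seed)) set.seed(seed)
  ns <- chrom_namespace(track$genome, config$locus_chrom)
  if (ns != "spikein")
    stop("spike-in locus chromosome ", config$locus_chrom,
         " is not in the spikein namespace")
  n <- stats::rbinom(1L, size = as.integer(depth), prob = config$fraction)
  width <- config$locus_end - config$locus_start
  pos <- config$locus_start + floor(stats::runif(n) * width)
  on_plus <- stats::runif(n) < 0.5
  len <- chrom_length(track$genome, config$locus_chrom)
  add <- function(cov, p) {
    cov + S4Vectors::Rle(tabulate(as.integer(p) + 1L, nbins = len))
  }
  ch <- config$locus_chrom
  track$plus[[ch]] <- add(track$plus[[ch]], pos[on_plus])
  track$minus[[ch]] <- add(track$minus[[ch]], pos[!on_plus])
  track$spikein_reads <- track$spikein_reads + n
  track
}

#' Simulate strand-polarized RPA ssDNA coverage around a nick
#'
#' End resection leaves RPA-coated single-stranded DNA whose strand polarity
#' reports which side(s) of the break were resected. In single-ended mode the
#' signal covers the resected tract on the fork-proximal side of the nick
#' (plus channel, left of the nick for a rightward-fork leading collapse);
#' with `invasion_signal = TRUE` a minor signal is added beyond the nick on
#' the far side, emulating ssDNA exposed in a migrating D-loop. In
#' double-ended mode (`mode = "double_ended"`) opposite-polarity signal of
#' equal weight covers the right side as well.
#'
#' @param nick A single-row [nick_sites()] table.
#' @param params A [collision_sim_params()] (resection draws reuse it).
#' @param genome A [genome_spec()].
#' @param mode `"single_ended"` or `"double_ended"`.
#' @param invasion_signal Add D-loop ssDNA signal beyond the nick?
#' @param invasion_fraction Fraction of events contributing invasion signal.
#' @param invasion_extent Length (bp) of the D-loop tract.
#' @param seed Optional integer seed.
#' @return A raw-state [stranded_track()].
#' @export
simulate_rpa_track <- function(nick, params, genome,
                               mode = c("single_ended", "double_ended"),
                               invasion_signal = FALSE,
                               invasion_fraction = 0.2,
                               invasion_extent = 2000, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  chrom <- nick$chrom[1]; pos <- nick$position[1]
  len <- chrom_length(genome, chrom)
  n <- params$events
  plus <- numeric(len); minus <- numeric(len)
  add_interval <- function(v, s, e) {
    s <- max(0, floor(s)); e <- min(len, ceiling(e))
    if (e > s) v[(s + 1):e] <- v[(s + 1):e] + 1
    v
  }
  r_left <- draw_resection(params, n)
  for (i in seq_len(n))
    plus <- add_interval(plus, pos - r_left[i], pos)
  if (mode == "double_ended") {
    r_right <- draw_resection(params, n)
    for (i in seq_len(n))
      minus <- add_interval(minus, pos, pos + r_right[i])
  }
  if (invasion_signal) {
    k <- as.integer(round(invasion_fraction * n))
    if (k > 0) for (i in seq_len(k))
      minus <- add_interval(minus, pos, pos + invasion_extent)
  }
  stranded_track(genome,
                 plus = stats::setNames(list(plus), chrom),
                 minus = stats::setNames(list(minus), chrom),
                 total_reads = sum(plus) + sum(minus))
}

#' Simulate amplicon reads carrying deletions around a nick
#'
#' Each read is the reference sequence, or, with probability `p_del`, the
#' reference with a single deletion spanning the nick. Deletion endpoints are
#' drawn uniformly within `flank` bp on each side of the nick; when
#' `microhomology_bias = TRUE`, several candidate junctions are drawn per
#' read and the one with the longest junctional microhomology is kept,
#' emulating end-joining that favours annealing at short flanking repeats.
#'
#' @param ref_seq Reference sequence (character or `DNAString`), length >= 50.
#' @param nick_offset 0-based offset of the nick; must be interior.
#' @param p_del Per-read deletion probability.
#' @param flank Maximum distance (bp) of each deletion endpoint from the nick.
#' @param fixed_deletion Optional `c(start, end)` (0-based half-open): every
#'   deletion read carries exactly this deletion.
#' @param microhomology_bias Bias junctions toward microhomology?
#' @param bias_weight Junction sampling weight base: a junction with
#'   microhomology `m` is drawn with probability proportional to
#'   `bias_weight^m` (1 = no bias); default 8.
#' @param n_reads Number of reads.
#' @param seed Optional integer seed.
#' @return A [Biostrings::DNAStringSet] of reads, with attribute
#'   `"truth"` (a data.frame of the planted deletion per read; -1s for
#'   no deletion).
#' @export
simulate_amplicon_reads <- function(ref_seq, nick_offset, p_del = 0.5,
                                    flank = 20, fixed_deletion = NULL,
                                    microhomology_bias = FALSE,
                                    bias_weight = 8, n_reads = 100,
                                    seed = NULL) {
  ref <- as.character(ref_seq)
  L <- nchar(ref)
  if (L < 50) stop("reference must be at least 50 bp")
  if (nick_offset <= 0 || nick_offset >= L)
    stop("nick_offset must be interior to the reference")
  if (!is.null(seed)) set.seed(seed)

  # candidate junctions span the nick; endpoints may coincide with it so a
  # repeat copy abutting the nick can be deleted cleanly
  s_range <- seq(max(0L, nick_offset - flank), nick_offset)
  e_range <- seq(nick_offset, min(L, nick_offset + flank))
  grid <- expand.grid(s = s_range, e = e_range)
  grid <- grid[grid$s < grid$e, , drop = FALSE]
  grid$mh <- mapply(function(s, e) microhomology_length(ref, s, e),
                    grid$s, grid$e)
  w <- if (microhomology_bias) bias_weight^grid$mh else rep(1, nrow(grid))
  reads <- character(n_reads)
  truth <- matrix(-1L, n_reads, 2L,
                  dimnames = list(NULL, c("del_start", "del_end")))
  for (i in seq_len(n_reads)) {
    if (stats::runif(1) < p_del) {
      if (!is.null(fixed_deletion)) {
        j <- fixed_deletion
      } else {
        k <- sample.int(nrow(grid), 1L, prob = w)
        j <- c(grid$s[k], grid$e[k])
      }
      read <- paste0(substr(ref, 1, j[1]), substr(ref, j[2] + 1, L))
      if (!nzchar(read))
        stop("deletion model produced an empty read")
      reads[i] <- read
      truth[i, ] <- as.integer(j)
    } else {
      reads[i] <- ref
    }
  }
  out <- Biostrings::DNAStringSet(reads)
  names(out) <- sprintf("read_%d", seq_len(n_reads))
  attr(out, "truth") <- as.data.frame(truth)
  out
}

#' Outcome proportion from single-molecule event counts
#'
#' @param n_event,n_total Event and total molecule counts.
#' @return List with `percent` (exact, 100 * n_event / n_total) and
#'   `display` (nearest-integer percentage).
#' @examples
#' tally_outcome_proportion(50, 58)$display  # 86
#' @export
tally_outcome_proportion <- function(n_event, n_total) {
  if (!is.numeric(n_total) || n_total <= 0)
    stop("n_total must be > 0")
  if (n_event < 0 || n_event > n_total)
    stop("n_event must lie in [0, n_total]")
  pct <- 100 * n_event / n_total
  list(percent = pct, display = round(pct))
}
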