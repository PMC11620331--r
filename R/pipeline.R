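#' Built-in simulation scenarios
#'
#' Deterministic small datasets covering the qualitatively distinct repair
#' regimes: `leading_seDSB` (strongly rightward forks over a Watson-strand
#' nick: run-off, asymmetric single-ended signal), `lagging_deDSB` (the same
#' forks over a Crick-strand nick: bypass, symmetric double-ended signal),
#' `rad51_like_hyperresection` (unrepaired single ends converted by
#' converging forks; resection tracts beyond 40 kb, probed with a 50-kb
#' search limit), and `brca1_like` (hyper-resection plus
#' microhomology-biased deletion junctions in amplicon reads).
#'
#' @param scenario Scenario name.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, a list with the generated objects and file paths
#'   (stranded bedGraph pair, nick BED, and for `brca1_like` a reads/ref
#'   FASTA pair).
#' @export
make_fixtures <- function(scenario = c("leading_seDSB", "lagging_deDSB",
                                       "rad51_like_hyperresection",
                                       "brca1_like"),
                          dir = tempfile("fixtures_"), seed = 1L) {
  scenario <- tryCatch(match.arg(scenario), error = function(e)
    stop("unknown scenario; choices: leading_seDSB, lagging_deDSB, ",
         "rad51_like_hyperresection, brca1_like"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gs <- genome_spec(c(chr1 = 200000L))
  nick <- switch(scenario,
                 lagging_deDSB = nick_sites("chr1", 100000, "-", "nick1"),
                 nick_sites("chr1", 100000, "+", "nick1"))
  params <- switch(
    scenario,
    leading_seDSB = collision_sim_params(fork_directionality = 0.85,
                                         max_length = 5000, events = 1000),
    lagging_deDSB = collision_sim_params(fork_directionality = 0.85,
                                         max_length = 5000, events = 1000),
    rad51_like_hyperresection = collision_sim_params(
      fork_directionality = 0.95, max_length = 45000, events = 3000,
      convert_prob = 0.5, convert_distance = 45500),
    brca1_like = collision_sim_params(fork_directionality = 0.95,
                                      max_length = 45000, events = 3000))
  params$background_rate <- background_rate_for_fraction(
    params, 200000, 0.05, nick$target_strand[1])
  track <- simulate_collision_track(nick, params, gs, seed = seed)
  paths <- list(
    plus = file.path(dir, "track_plus.bedGraph"),
    minus = file.path(dir, "track_minus.bedGraph"),
    nicks = file.path(dir, "nicks.bed"))
  write_track_bedgraph(track, paths$plus, paths$minus)
  write_nicks_bed(nick, paths$nicks)
  # the sliding estimator's background window must lie beyond the resection
  # tract; in the hyper-resection regimes the 7-9 kb default sits inside the
  # signal, so these scenarios carry a window past the 45-kb tract maximum
  sliding_args <- if (scenario %in% c("rad51_like_hyperresection",
                                      "brca1_like"))
    list(search_limit = 50000, bg_range = c(47000, 50000))
  else
    list(search_limit = 50000, bg_range = c(7000, 9000))
  out <- list(scenario = scenario, genome = gs, nick = nick,
              params = params, track = track, paths = paths,
              sliding_args = sliding_args)
  if (scenario == "brca1_like") {
    ref <- paste0(
      strrep("ACGT", 20),            # 80 bp left arm
      "GGCCGGCC",                    # planted direct repeat around the nick
      strrep("TGCA", 20))            # 80 bp right arm
    reads <- simulate_amplicon_reads(ref, nick_offset = 84, p_del = 0.6,
                                     flank = 15, microhomology_bias = TRUE,
                                     n_reads = 200, seed = seed + 1L)
    paths$reads <- file.path(dir, "amplicon_reads.fasta")
    paths$ref <- file.path(dir, "amplicon_ref.fasta")
    Biostrings::writeXStringSet(reads, paths$reads)
    Biostrings::writeXStringSet(
      stats::setNames(Biostrings::DNAStringSet(ref), "ref"), paths$ref)
    out$reads <- reads
    out$ref <- ref
    out$paths <- paths
  }
  invisible(out)
}

validation_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("fc_validation_error",
                                             "fc_error")))
}

runtime_error <- function(stage, parent) {
  stop(errorCondition(
    paste0("pipeline stage '", stage, "' failed: ",
           conditionMessage(parent)),
    class = c("fc_runtime_error", "fc_error")))
}

# deterministic per-stage substream of a global seed (kept < 2^31)
stage_seed <- function(seed, stage_index) {
  as.integer((as.numeric(seed) * 1000003 + 7919 * stage_index) %% 2147483647)
}

#' Run the full simulate-and-score pipeline
#'
#' Executes simulate -> normalize -> peaks -> asymmetry -> resection ->
#' RFD classification on a simulated dataset described by a config (a YAML
#' file path or an equivalent named list), writing per-stage artifacts
#' (stranded bedGraph pair, nick BED, peak BED, per-nick TSV report) and a
#' machine-readable JSON manifest (package version, seed, parameters) into
#' `out_dir`. One global seed is expanded into per-stage substreams so any
#' stage can be re-run in isolation reproducibly. Config validation failures
#' signal a condition of class `fc_validation_error` before any work; stage
#' failures signal `fc_runtime_error` naming the stage, after writing a
#' `FAILED` marker file alongside any partial outputs.
#'
#' Config fields (defaults in parentheses): `seed` (required),
#' `chrom_length` (200000), `nick_position` (100000), `target_strand`
#' ("+"), `fork_directionality` (0.85), `events` (1000), `max_length`
#' (5000), `convert_prob` (0), `background_fraction` (0.05),
#' `asymmetry_window` (3000), `min_signal` (3), `min_separation` (8000),
#' `rfd_bin` (1000), `origins` (c(20000)), `search_limit` (50000).
#'
#' @param config Path to a YAML file or a named list.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the per-nick `report` data.frame, the
#'   manifest, and artifact paths.
#' @export
run_pipeline <- function(config, out_dir = tempfile("fc_run_")) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) validation_error("config must be a list or a path")
  defaults <- list(chrom_length = 200000, nick_position = 100000,
                   target_strand = "+", fork_directionality = 0.85,
                   events = 1000, max_length = 5000, convert_prob = 0,
                   background_fraction = 0.05, asymmetry_window = 3000,
                   min_signal = 3, min_separation = 8000, rfd_bin = 1000,
                   origins = 20000, search_limit = 50000)
  unknown <- setdiff(names(config), c(names(defaults), "seed"))
  if (length(unknown) > 0L)
    validation_error("unknown config field(s): ",
                     paste(unknown, collapse = ", "))
  if (is.null(config$seed))
    validation_error("config must provide a seed: the simulation stage ",
                     "is stochastic")
  cfg <- utils::modifyList(defaults, config)
  if (!cfg$target_strand %in% c("+", "-"))
    validation_error("target_strand must be '+' or '-'")
  if (cfg$nick_position <= 0 || cfg$nick_position >= cfg$chrom_length)
    validation_error("nick_position must be interior to the chromosome")

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      if (inherits(e, "fc_error")) stop(e)
      writeLines(paste("FAILED at stage:", name),
                 file.path(out_dir, "FAILED"))
      runtime_error(name, e)
    })
  }

  gs <- genome_spec(stats::setNames(cfg$chrom_length, "chr1"))
  nick <- nick_sites("chr1", cfg$nick_position, cfg$target_strand, "nick1")
  params <- collision_sim_params(
    fork_directionality = cfg$fork_directionality, events = cfg$events,
    max_length = cfg$max_length, convert_prob = cfg$convert_prob)
  params$background_rate <- background_rate_for_fraction(
    params, cfg$chrom_length, cfg$background_fraction, cfg$target_strand)

  track <- run_stage("simulate", function()
    simulate_collision_track(nick, params, gs,
                             seed = stage_seed(cfg$seed, 1L)))
  paths <- list(plus = file.path(out_dir, "track_plus.bedGraph"),
                minus = file.path(out_dir, "track_minus.bedGraph"),
                nicks = file.path(out_dir, "nicks.bed"),
                peaks = file.path(out_dir, "peaks.bed"),
                report = file.path(out_dir, "report.tsv"),
                manifest = file.path(out_dir, "manifest.json"))
  run_stage("write_tracks", function() {
    write_track_bedgraph(track, paths$plus, paths$minus)
    write_nicks_bed(nick, paths$nicks)
  })

  norm <- run_stage("normalize", function() compute_rpm(track))
  rpm_factor <- 1e6 / track$total_reads
  peaks <- run_stage("peaks", function() {
    p <- call_peaks(norm, min_signal = cfg$min_signal,
                    background_rate = params$background_rate * rpm_factor)
    qualify_peaks(p, nick, min_separation = cfg$min_separation)
  })
  run_stage("write_peaks", function() write_peaks_bed(peaks, paths$peaks))

  report <- run_stage("score", function() {
    tab <- asymmetry_table(norm, nick, window = cfg$asymmetry_window)
    res <- resection_length_sliding(norm, nick, side = "left",
                                    search_limit = cfg$search_limit)
    rfd <- simulate_rfd_field(cfg$origins, gs, bin_size = cfg$rfd_bin)
    r_at <- rfd_at(rfd, "chr1", cfg$nick_position)
    tab$resection_left_bp <- res$length
    tab$resection_at_limit <- res$at_limit
    tab$rfd <- r_at
    tab$fork_class <- classify_nick(nick, r_at)
    tab$intensity_30kb <- peak_intensity(norm, nick)
    tab
  })
  run_stage("report", function()
    utils::write.table(report, paths$report, sep = "\t", row.names = FALSE,
                       quote = FALSE))

  manifest <- list(
    package = "forkcollapse",
    version = as.character(utils::packageVersion("forkcollapse")),
    seed = cfg$seed, config = cfg,
    n_signal_ends = attr(track, "sim_info")$n_signal_ends,
    n_background = attr(track, "sim_info")$n_background,
    total_reads = track$total_reads,
    n_peaks = length(peaks))
  run_stage("manifest", function()
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE))
  invisible(list(report = report, manifest = manifest, paths = paths,
                 peaks = peaks))
}
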