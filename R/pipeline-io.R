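## Shared readers/writers, run configuration and the stage runner that
## chains the analyses (simulate, coloc, repletion, cohesion, chip).
## TSV is the interchange format between stages; standard genomic
## formats (bedGraph/BED/FASTA, all 0-based half-open on disk) and TIFF
## sit at the domain boundaries.

#' Default run configuration
#'
#' Collects every tunable parameter of the pipeline with its default:
#' pixel size 129 nm (2 px = 258 nm), colocalization threshold 258 nm,
#' 5-min frame interval, persistence length 3 frames, 7-min cohesion
#' offset, 50-bp coverage bins, 2-kb smoothing window, top 26 peaks.
#' Locus labels describe the fluorescent marker arrays (ori1: lacO array
#' 15 kb counter-clockwise of oriC; ter3: tetO array 50 kb clockwise of
#' dif) and are metadata only. The motif consensus is configuration, not
#' code: the default is the 13-bp matS consensus, and the synthetic
#' generator plants whatever consensus the configuration provides.
#'
#' @param ... overrides of the defaults.
#' @return object of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    pixel_size_nm = 129,
    coloc_threshold_nm = 258,
    coloc_fraction = 0.86,
    coloc_jitter_sd_nm = 40,
    null_draws_per_cell = 10,
    n_cells = 2000,
    frame_interval_min = 5,
    persistence_K = 3,
    cohesion_offset_min = 7,
    n_tracks = 50,
    chip_bin_bp = 50,
    chip_window_bp = 2000,
    chip_top_n = 26,
    chip_pseudocount = 0.5,
    chip_genome_length_bp = 4641652,
    motif_consensus = "GTGACRNYGTCAC",
    motif_max_mismatch = 1,
    loci = list(ori1 = "lacO array 15 kb CCW of oriC",
                ter3 = "tetO array 50 kb CW of dif"),
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop_config("unknown config field(s): %s",
                paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  for (f in c("pixel_size_nm", "coloc_threshold_nm", "frame_interval_min",
              "chip_bin_bp", "chip_window_bp", "chip_genome_length_bp"))
    assert_scalar_number(cfg[[f]], f, lower = 0, strict_lower = TRUE)
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration (YAML)
#'
#' Serialization is lossless: `read_run_config(write_run_config(cfg))`
#' reproduces the configuration.
#'
#' @param config a [run_config()].
#' @param path file path.
#' @return `write_run_config` returns `path` invisibly;
#'   `read_run_config` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

## ---- TSV tables ---------------------------------------------------------

write_tsv_exact <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop_input("%s file not found: %s", what, path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_parse("%s file %s lacks column(s): %s", what, path,
               paste(missing, collapse = ", "))
  df
}

#' Write / read a focus table (TSV)
#'
#' @param foci focus table as produced by [detect_foci()].
#' @param path file path.
#' @return the table (readers) or the path, invisibly (writers).
#' @export
write_focus_table <- function(foci, path) write_tsv_exact(foci, path)

#' @rdname write_focus_table
#' @export
read_focus_table <- function(path) {
  read_tsv_checked(path, c("cell_id", "channel", "row", "col"),
                   "focus table")
}

#' Write / read time-lapse tracks (TSV)
#'
#' @param tracks long track table (`cell_id`, `frame`, `time_min`,
#'   `replisome_count`, `locus_count`).
#' @param path file path.
#' @return the table (reader) or the path, invisibly (writer).
#' @export
write_tracks <- function(tracks, path) write_tsv_exact(tracks, path)

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  read_tsv_checked(path, c("cell_id", "frame", "time_min",
                           "replisome_count", "locus_count"), "track")
}

## ---- genomic formats ----------------------------------------------------

#' Write / read binned coverage as bedGraph
#'
#' bedGraph is 0-based, half-open. Reading validates every data line
#' (4 fields, integer interval, numeric score) and reports the first
#' offending line by number before handing the file to the standard
#' importer.
#'
#' @param track a [coverage_track()] or `enrichment_track`.
#' @param path file path.
#' @param sample_id,role,replicate metadata to attach on read.
#' @return the track (reader) or the path, invisibly (writer).
#' @export
write_bedgraph <- function(track, path) {
  vals <- if (inherits(track, "enrichment_track")) track$ratio else track$counts
  n <- length(vals)
  starts <- (seq_len(n) - 1L) * track$bin_bp
  ends <- pmin(starts + track$bin_bp, track$genome_length_bp)
  df <- data.frame(chrom = track$reference,
                   start = format(starts, scientific = FALSE, trim = TRUE),
                   end = format(ends, scientific = FALSE, trim = TRUE),
                   score = vals)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

validate_bedgraph_lines <- function(path) {
  lines <- readLines(path)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^(track|browser|#)", ln) || !nzchar(trimws(ln))) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    ok <- length(f) == 4L &&
      !is.na(suppressWarnings(as.integer(f[2L]))) &&
      !is.na(suppressWarnings(as.integer(f[3L]))) &&
      !is.na(suppressWarnings(as.numeric(f[4L])))
    if (!ok)
      stop_parse("malformed bedGraph line %d in %s: '%s'", i, path, ln)
  }
  invisible(TRUE)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path, sample_id = basename(path),
                          role = c("IP", "mock"), replicate = 1L) {
  role <- match.arg(role)
  if (!file.exists(path)) stop_input("bedGraph file not found: %s", path)
  validate_bedgraph_lines(path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  w <- GenomicRanges::width(gr)
  bin_bp <- as.numeric(stats::median(w))
  genome_length <- max(GenomicRanges::end(gr))
  counts <- numeric(ceiling(genome_length / bin_bp))
  ## GRanges starts are 1-based; convert to 0-based bin index
  idx <- floor((GenomicRanges::start(gr) - 1L) / bin_bp) + 1L
  counts[idx] <- GenomicRanges::mcols(gr)$score
  coverage_track(counts, bin_bp, genome_length, sample_id = sample_id,
                 role = role, replicate = replicate,
                 reference = as.character(
                   GenomicRanges::seqnames(gr)[1L]))
}

#' Write / read site positions as BED
#'
#' @param positions_bp 0-based positions (starts).
#' @param path file path.
#' @param width_bp feature width (default 1).
#' @param reference reference sequence name.
#' @param names feature names.
#' @return positions (reader, 0-based starts with names) or the path
#'   (writer, invisibly).
#' @export
write_bed_sites <- function(positions_bp, path, width_bp = 1,
                            reference = "chr",
                            names = seq_along(positions_bp)) {
  df <- data.frame(chrom = reference,
                   start = format(as.integer(positions_bp),
                                  scientific = FALSE, trim = TRUE),
                   end = format(as.integer(positions_bp + width_bp),
                                scientific = FALSE, trim = TRUE),
                   name = names)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed_sites
#' @export
read_bed_sites <- function(path) {
  if (!file.exists(path)) stop_input("BED file not found: %s", path)
  gr <- rtracklayer::import(path, format = "BED")
  out <- GenomicRanges::start(gr) - 1L   # back to 0-based starts
  nm <- GenomicRanges::mcols(gr)$name
  if (!is.null(nm)) names(out) <- nm
  out
}

#' Write frames or label masks as TIFF
#'
#' Images are written as 16-bit TIFF; intensities are stored as
#' `value / 65535` and recovered on read, so integer data up to 65535
#' round-trips exactly.
#'
#' @param frames named list of numeric matrices (a `sim_frames` object)
#'   or a single matrix (e.g. a label mask).
#' @param path file path.
#' @return the matrix/list (reader) or the path (writer, invisibly).
#' @export
write_frames_tiff <- function(frames, path) {
  if (is.matrix(frames)) frames <- list(frames)
  tiff::writeTIFF(lapply(frames, function(m) pmin(m, 65535) / 65535),
                  path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_frames_tiff
#' @export
read_frames_tiff <- function(path) {
  if (!file.exists(path)) stop_input("TIFF file not found: %s", path)
  planes <- tiff::readTIFF(path, all = TRUE)
  lapply(planes, function(m) round(m * 65535))
}

## ---- stage runner -------------------------------------------------------

#' Run one pipeline stage into an artifact directory
#'
#' Each stage reads its inputs from `dir` (or generates them, for
#' `"simulate"`), writes its outputs, a JSON summary and the exact
#' resolved configuration next to them. Identical config and seed give
#' byte-identical outputs.
#'
#' Stages: `"simulate"` writes focus tables, cell masks, time-lapse
#' tracks and ChIP coverage with ground truth; `"coloc"`, `"repletion"`,
#' `"cohesion"` and `"chip"` each consume the corresponding fixtures and
#' write their results.
#'
#' @param config a [run_config()].
#' @param stage one of `"simulate"`, `"coloc"`, `"repletion"`,
#'   `"cohesion"`, `"chip"`.
#' @param dir artifact directory (created if missing).
#' @return the summary list of the stage, invisibly.
#' @export
run_pipeline <- function(config = run_config(),
                         stage = c("simulate", "coloc", "repletion",
                                   "cohesion", "chip"),
                         dir = ".") {
  stage <- match.arg(stage)
  if (!inherits(config, "run_config"))
    stop_config("'config' must be a run_config object")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_run_config(config, file.path(dir, paste0(stage, "_config.yaml")))
  summary <- switch(stage,
    simulate = stage_simulate(config, dir),
    coloc = stage_coloc(config, dir),
    repletion = stage_repletion(config, dir),
    cohesion = stage_cohesion(config, dir),
    chip = stage_chip(config, dir))
  jsonlite::write_json(summary,
                       file.path(dir, paste0(stage, "_summary.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

stage_simulate <- function(config, dir) {
  ispec <- sim_imaging_spec(n_cells = config$n_cells,
                            pixel_size_nm = config$pixel_size_nm,
                            coloc_fraction = config$coloc_fraction,
                            coloc_jitter_sd_nm = config$coloc_jitter_sd_nm,
                            seed = config$seed)
  sim <- generate_cells(ispec)
  write_focus_table(truth_focus_table(sim$truth),
                    file.path(dir, "foci.tsv"))
  write_tsv_exact(sim$truth, file.path(dir, "cells_truth.tsv"))
  write_frames_tiff(sim$labels, file.path(dir, "cell_masks.tif"))

  tspec <- sim_timelapse_spec(n_cells = config$n_tracks,
                              frame_interval_min = config$frame_interval_min,
                              K = config$persistence_K,
                              seed = config$seed + 1L)
  tl <- generate_timelapse(tspec)
  write_tracks(tl$tracks, file.path(dir, "tracks.tsv"))
  write_tsv_exact(tl$truth, file.path(dir, "tracks_truth.tsv"))

  meas <- sim_repletion(seed = config$seed + 2L)
  write_tsv_exact(meas, file.path(dir, "repletion.tsv"))

  n_sites <- 23L
  gap <- config$chip_genome_length_bp / (n_sites + 1L)
  sites <- round(gap * seq_len(n_sites))
  cspec <- sim_chip_spec(genome_length_bp = config$chip_genome_length_bp,
                         bin_bp = config$chip_bin_bp,
                         site_positions = sites,
                         seed = config$seed + 3L)
  chip <- generate_chipseq(cspec)
  for (tr in c(chip$ip, chip$mock))
    write_bedgraph(tr, file.path(dir, paste0(tr$sample_id, ".bedgraph")))
  write_bed_sites(sites, file.path(dir, "planted_sites.bed"),
                  width_bp = nchar(config$motif_consensus))
  genome <- plant_motif_genome(
    min(config$chip_genome_length_bp, 200000L),
    config$motif_consensus,
    site_positions = numeric(), seed = config$seed + 4L)
  gs <- Biostrings::DNAStringSet(genome)
  names(gs) <- "chr"
  Biostrings::writeXStringSet(gs, file.path(dir, "genome.fasta"))
  list(stage = "simulate", n_cells = config$n_cells,
       n_tracks = config$n_tracks, n_sites = n_sites)
}

stage_coloc <- function(config, dir) {
  foci <- read_focus_table(file.path(dir, "foci.tsv"))
  labels <- read_frames_tiff(file.path(dir, "cell_masks.tif"))[[1L]]
  res <- colocalization_fraction(foci,
                                 threshold_nm = config$coloc_threshold_nm,
                                 pixel_size_nm = config$pixel_size_nm)
  cells <- regions_from_labels(labels, config$pixel_size_nm)
  null <- random_pixel_null(cells, foci,
                            n_draws_per_cell = config$null_draws_per_cell,
                            threshold_nm = config$coloc_threshold_nm,
                            pixel_size_nm = config$pixel_size_nm,
                            seed = config$seed)
  write_tsv_exact(data.frame(cell_id = names(res$distances_nm),
                             distance_nm = unname(res$distances_nm)),
                  file.path(dir, "coloc_distances.tsv"))
  list(stage = "coloc",
       percent_colocalized = res$percent_colocalized,
       null_percent = null$null_percent,
       n_cells_used = res$n_cells_used,
       threshold_nm = config$coloc_threshold_nm)
}

stage_repletion <- function(config, dir) {
  meas <- read_tsv_checked(file.path(dir, "repletion.tsv"),
                           c("replicate_id", "time_min",
                             "brightest_intensity", "has_focus"),
                           "repletion")
  tc <- build_timecourse(meas)
  write_tsv_exact(as.data.frame(tc), file.path(dir, "timecourse.tsv"))
  rate <- fit_initial_rate(tc)
  list(stage = "repletion", initial_rate_per_min = rate$slope,
       rate_se = rate$se, window_min = rate$window_min)
}

stage_cohesion <- function(config, dir) {
  tracks <- read_tracks(file.path(dir, "tracks.tsv"))
  params <- cohesion_params(K = config$persistence_K,
                            offset_min = config$cohesion_offset_min)
  calls <- cohesion_calls(tracks, params)
  write_tsv_exact(calls, file.path(dir, "cohesion_calls.tsv"))
  pop <- population_segregation(calls)
  write_tsv_exact(pop$curve, file.path(dir, "segregation_curve.tsv"))
  list(stage = "cohesion", t50_min = pop$t50_min, n_used = pop$n_used,
       n_censored = pop$n_censored)
}

stage_chip <- function(config, dir) {
  ip_files <- sort(list.files(dir, "^ip_rep.*\\.bedgraph$",
                              full.names = TRUE))
  mock_files <- sort(list.files(dir, "^mock_rep.*\\.bedgraph$",
                                full.names = TRUE))
  if (length(ip_files) == 0L || length(mock_files) == 0L)
    stop_input("no IP/mock bedGraph files found in %s", dir)
  ip <- mapply(read_bedgraph, ip_files, role = "IP",
               replicate = seq_along(ip_files), SIMPLIFY = FALSE)
  mock <- mapply(read_bedgraph, mock_files, role = "mock",
                 replicate = seq_along(mock_files), SIMPLIFY = FALSE)
  enr <- median_ratio_track(ip, mock,
                            pseudocount = config$chip_pseudocount)
  sm <- smooth_track(enr, config$chip_window_bp)
  peaks <- call_top_peaks(sm, N = config$chip_top_n,
                          min_separation_bp = config$chip_window_bp)
  write_bedgraph(sm, file.path(dir, "enrichment.bedgraph"))
  write_bed_sites(round(peaks$position_bp),
                  file.path(dir, "peaks.bed"),
                  width_bp = config$chip_bin_bp, names = peaks$rank)
  prof <- anchored_profile(list(ip_vs_mock = enr), peaks$position_bp,
                           half_window_bp = config$chip_window_bp / 2)
  write_tsv_exact(prof$profiles, file.path(dir, "anchored_profile.tsv"))
  list(stage = "chip",
       genome_median_ratio = stats::median(enr$ratio),
       n_peaks = nrow(peaks),
       profile_peak_height = prof$summary$peak_height[1L],
       profile_flatness = prof$summary$flatness[1L])
}
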