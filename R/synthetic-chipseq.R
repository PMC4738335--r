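## Replicated IP/mock coverage with peaks planted at motif positions and
## highly-transcribed-region (HTR) artifacts shared by both roles, plus a
## genome generator that plants concrete motif instances.

#' Specify a synthetic ChIP experiment
#'
#' Per-bin read counts are drawn from a negative binomial whose mean is a
#' depth-proportional baseline times a local fold: `site_enrichment`
#' within +/-2 bins of each planted site (IP samples only), and the HTR
#' artifact folds applied to IP and mock alike (these mimic the spurious
#' formaldehyde reactivity of highly transcribed regions, which cancels
#' in the IP/mock ratio). Library sizes differ across replicates by a
#' sampled log-normal factor.
#'
#' @param genome_length_bp reference length (default the E. coli K-12
#'   chromosome size).
#' @param bin_bp bin width (default 50).
#' @param site_positions planted site positions, bp (0-based).
#' @param site_enrichment fold enrichment (>= 1) per site; recycled.
#' @param n_replicates replicates per role (default 3).
#' @param read_depth expected reads per sample (default 2e7, a typical
#'   Illumina lane share).
#' @param dispersion negative-binomial overdispersion (default 0.02).
#' @param libsize_log_sd sd of the log-normal library-size factor.
#' @param htr_artifacts data frame (`start`, `end`, `fold`) of intervals
#'   elevated in both IP and mock, or `NULL`.
#' @param reference reference sequence name used in exported tracks.
#' @param circular circular chromosome? Default `TRUE`.
#' @param seed integer seed.
#' @return object of class `sim_chip_spec`.
#' @export
sim_chip_spec <- function(genome_length_bp = 4641652, bin_bp = 50,
                          site_positions = numeric(),
                          site_enrichment = 8,
                          n_replicates = 3, read_depth = 2e7,
                          dispersion = 0.02, libsize_log_sd = 0.15,
                          htr_artifacts = NULL, reference = "chr",
                          circular = TRUE, seed = 1L) {
  assert_scalar_number(genome_length_bp, "genome_length_bp", lower = 1)
  assert_scalar_number(bin_bp, "bin_bp", lower = 1)
  assert_scalar_number(n_replicates, "n_replicates", lower = 1)
  assert_scalar_number(read_depth, "read_depth", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(dispersion, "dispersion", lower = 0)
  if (any(site_positions < 0 | site_positions >= genome_length_bp))
    stop_config("site positions must lie in [0, genome_length_bp)")
  site_enrichment <- rep_len(site_enrichment, length(site_positions))
  if (any(site_enrichment < 1))
    stop_config("site enrichment folds must be >= 1")
  if (length(site_positions) > 1L) {
    bins <- floor(site_positions / bin_bp)
    if (min(diff(sort(bins))) < 2)
      stop_config("planted sites closer than 2 bins overlap")
  }
  if (!is.null(htr_artifacts) &&
      !all(c("start", "end", "fold") %in% names(htr_artifacts)))
    stop_config("'htr_artifacts' needs columns start, end, fold")
  structure(list(genome_length_bp = genome_length_bp, bin_bp = bin_bp,
                 site_positions = site_positions,
                 site_enrichment = site_enrichment,
                 n_replicates = as.integer(n_replicates),
                 read_depth = read_depth, dispersion = dispersion,
                 libsize_log_sd = libsize_log_sd,
                 htr_artifacts = htr_artifacts, reference = reference,
                 circular = circular, seed = as.integer(seed)),
            class = "sim_chip_spec")
}

#' A binned coverage track
#'
#' @param counts per-bin read counts.
#' @param bin_bp bin width.
#' @param genome_length_bp reference length.
#' @param sample_id sample identifier.
#' @param role `"IP"` or `"mock"`.
#' @param replicate replicate index.
#' @param reference reference sequence name.
#' @param circular circular chromosome flag.
#' @return object of class `coverage_track`.
#' @export
coverage_track <- function(counts, bin_bp, genome_length_bp,
                           sample_id = "sample", role = c("IP", "mock"),
                           replicate = 1L, reference = "chr",
                           circular = TRUE) {
  role <- match.arg(role)
  n_bins <- ceiling(genome_length_bp / bin_bp)
  if (length(counts) != n_bins)
    stop_input("expected %d bins for %g bp at %g bp/bin, got %d",
               n_bins, genome_length_bp, bin_bp, length(counts))
  if (any(counts < 0)) stop_input("negative counts in coverage track")
  structure(list(counts = as.numeric(counts), bin_bp = bin_bp,
                 genome_length_bp = genome_length_bp,
                 sample_id = sample_id, role = role,
                 replicate = as.integer(replicate),
                 reference = reference, circular = circular,
                 normalized = FALSE),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf(
    "coverage_track '%s' (%s rep %d): %d bins x %g bp%s, total %.3g\n",
    x$sample_id, x$role, x$replicate, length(x$counts), x$bin_bp,
    if (x$normalized) " (CPM)" else "", sum(x$counts)))
  invisible(x)
}

## Per-bin fold vector for one role.
chip_fold_vector <- function(spec, role) {
  n_bins <- ceiling(spec$genome_length_bp / spec$bin_bp)
  fold <- rep(1, n_bins)
  if (role == "IP" && length(spec$site_positions) > 0L) {
    for (i in seq_along(spec$site_positions)) {
      b <- floor(spec$site_positions[i] / spec$bin_bp) + 1L
      idx <- (b - 2L):(b + 2L)
      if (spec$circular) idx <- ((idx - 1L) %% n_bins) + 1L
      idx <- idx[idx >= 1L & idx <= n_bins]
      fold[idx] <- pmax(fold[idx], spec$site_enrichment[i])
    }
  }
  if (!is.null(spec$htr_artifacts)) {
    for (i in seq_len(nrow(spec$htr_artifacts))) {
      b1 <- floor(spec$htr_artifacts$start[i] / spec$bin_bp) + 1L
      b2 <- min(n_bins, floor((spec$htr_artifacts$end[i] - 1) /
                                spec$bin_bp) + 1L)
      fold[b1:b2] <- pmax(fold[b1:b2], spec$htr_artifacts$fold[i])
    }
  }
  fold
}

#' Generate replicated IP and mock coverage tracks
#'
#' @param spec a [sim_chip_spec()].
#' @return list of class `sim_chip` with `ip` and `mock` (lists of
#'   [coverage_track()]s), `truth_sites` (data frame `position_bp`,
#'   `fold`) and the `spec`.
#' @export
generate_chipseq <- function(spec) {
  stopifnot(inherits(spec, "sim_chip_spec"))
  n_bins <- ceiling(spec$genome_length_bp / spec$bin_bp)
  base_mu <- spec$read_depth / n_bins
  size <- if (spec$dispersion > 0) 1 / spec$dispersion else Inf
  withr::with_seed(spec$seed, {
    make_role <- function(role) {
      fold <- chip_fold_vector(spec, role)
      lapply(seq_len(spec$n_replicates), function(r) {
        lib <- exp(stats::rnorm(1, 0, spec$libsize_log_sd))
        mu <- base_mu * lib * fold
        counts <- if (is.finite(size))
          stats::rnbinom(n_bins, mu = mu, size = size)
        else stats::rpois(n_bins, mu)
        coverage_track(counts, spec$bin_bp, spec$genome_length_bp,
                       sample_id = sprintf("%s_rep%d", tolower(role), r),
                       role = role, replicate = r,
                       reference = spec$reference,
                       circular = spec$circular)
      })
    }
    ip <- make_role("IP")
    mock <- make_role("mock")
    structure(list(ip = ip, mock = mock,
                   truth_sites = data.frame(
                     position_bp = spec$site_positions,
                     fold = spec$site_enrichment),
                   spec = spec), class = "sim_chip")
  })
}

#' Random genome with planted motif instances
#'
#' Draws a uniform-random ACGT sequence and writes one concrete instance
#' of the (possibly degenerate IUPAC) consensus at each planted position,
#' sampling a concrete base for each degenerate code.
#'
#' @param genome_length_bp sequence length.
#' @param consensus IUPAC consensus string.
#' @param site_positions 0-based start positions of planted instances.
#' @param seed integer seed.
#' @return a [Biostrings::DNAString] with attribute `"planted_starts"`
#'   (0-based).
#' @export
plant_motif_genome <- function(genome_length_bp, consensus,
                               site_positions = numeric(), seed = 1L) {
  codes <- iupac_code_list()
  letters_cons <- strsplit(toupper(consensus), "")[[1L]]
  if (!all(letters_cons %in% names(codes)))
    stop_config("consensus contains non-IUPAC characters")
  if (any(site_positions < 0 |
          site_positions + nchar(consensus) > genome_length_bp))
    stop_config("planted motif instances must fit inside the genome")
  withr::with_seed(seed, {
    seq <- sample(c("A", "C", "G", "T"), genome_length_bp, replace = TRUE)
    for (p in site_positions) {
      inst <- vapply(letters_cons, function(l) {
        opts <- codes[[l]]
        opts[sample.int(length(opts), 1L)]
      }, character(1))
      seq[(p + 1L):(p + length(inst))] <- inst
    }
    g <- Biostrings::DNAString(paste(seq, collapse = ""))
    attr(g, "planted_starts") <- site_positions
    g
  })
}

iupac_code_list <- function() {
  list(A = "A", C = "C", G = "G", T = "T",
       R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
       W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
       B = c("C", "G", "T"), D = c("A", "G", "T"),
       H = c("A", "C", "T"), V = c("A", "C", "G"),
       N = c("A", "C", "G", "T"))
}
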