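## IP/mock ratio-of-medians enrichment, smoothing, top-N peak calling,
## degenerate motif scanning, peak-motif annotation and anchor-centred
## (metagene) profiles.

#' Normalize coverage tracks to counts per million
#'
#' Scales each track so its library total is one million, making
#' replicates with different sequencing depths comparable.
#'
#' @param tracks a [coverage_track()] or list of them.
#' @return the tracks, normalized; each carries its scaling factor in
#'   attribute `"cpm_factor"`.
#' @export
normalize_coverage <- function(tracks) {
  single <- inherits(tracks, "coverage_track")
  if (single) tracks <- list(tracks)
  out <- lapply(tracks, function(tr) {
    tot <- sum(tr$counts)
    if (tot <= 0) stop_input("track '%s' has zero total counts",
                             tr$sample_id)
    f <- 1e6 / tot
    tr$counts <- tr$counts * f
    tr$normalized <- TRUE
    attr(tr, "cpm_factor") <- f
    tr
  })
  if (single) out[[1L]] else out
}

#' IP/mock ratio-of-medians enrichment track
#'
#' Per bin: (median across IP replicates + pseudocount) / (median across
#' mock replicates + pseudocount), computed on depth-normalized (CPM)
#' counts. The median is taken across replicates first and the ratio
#' second, so a single aberrant replicate cannot dominate any bin.
#'
#' @param ip_tracks,mock_tracks lists of [coverage_track()]s (>= 1 each).
#' @param pseudocount stabilizer added to both medians (default 0.5
#'   normalized units).
#' @param normalize CPM-normalize the inputs first? Default `TRUE`.
#' @return object of class `enrichment_track`: per-bin `ratio` plus
#'   binning metadata (`bin_bp`, `genome_length_bp`, `reference`,
#'   `circular`, `pseudocount`, `smoothing_window_bp`).
#' @export
median_ratio_track <- function(ip_tracks, mock_tracks, pseudocount = 0.5,
                               normalize = TRUE) {
  if (inherits(ip_tracks, "coverage_track")) ip_tracks <- list(ip_tracks)
  if (inherits(mock_tracks, "coverage_track")) mock_tracks <- list(mock_tracks)
  if (length(ip_tracks) < 1L || length(mock_tracks) < 1L)
    stop_input("need at least one track per role")
  all_tr <- c(ip_tracks, mock_tracks)
  nb <- vapply(all_tr, function(t) length(t$counts), integer(1))
  bb <- vapply(all_tr, function(t) t$bin_bp, numeric(1))
  if (length(unique(nb)) != 1L || length(unique(bb)) != 1L)
    stop_input("IP and mock tracks disagree in bin count or bin width")
  if (normalize) {
    ip_tracks <- normalize_coverage(ip_tracks)
    mock_tracks <- normalize_coverage(mock_tracks)
  }
  med_ip <- row_medians(do.call(cbind, lapply(ip_tracks, `[[`, "counts")))
  med_mock <- row_medians(do.call(cbind, lapply(mock_tracks, `[[`, "counts")))
  ref <- ip_tracks[[1L]]
  structure(list(ratio = (med_ip + pseudocount) / (med_mock + pseudocount),
                 bin_bp = ref$bin_bp,
                 genome_length_bp = ref$genome_length_bp,
                 reference = ref$reference, circular = ref$circular,
                 pseudocount = pseudocount,
                 smoothing_window_bp = NA_real_,
                 n_ip = length(ip_tracks), n_mock = length(mock_tracks)),
            class = "enrichment_track")
}

#' @export
print.enrichment_track <- function(x, ...) {
  cat(sprintf(
    "enrichment_track: %d bins x %g bp, median ratio %.3f%s (eps = %g)\n",
    length(x$ratio), x$bin_bp, stats::median(x$ratio),
    if (!is.na(x$smoothing_window_bp))
      sprintf(", smoothed %g bp", x$smoothing_window_bp) else "",
    x$pseudocount))
  invisible(x)
}

#' Smooth an enrichment track with a centred moving average
#'
#' @param track an `enrichment_track`.
#' @param window_bp window width in bp (default 2000); must be at least
#'   one bin. On a circular reference the window wraps across the origin,
#'   so the genome-wide sum is conserved exactly.
#' @return the smoothed track, with `smoothing_window_bp` set.
#' @export
smooth_track <- function(track, window_bp = 2000) {
  stopifnot(inherits(track, "enrichment_track"))
  if (window_bp < track$bin_bp)
    stop_input("smoothing window (%g bp) below bin width (%g bp)",
               window_bp, track$bin_bp)
  w <- max(1L, round(window_bp / track$bin_bp))
  x <- track$ratio
  if (track$circular) {
    sm <- stats::filter(x, rep(1 / w, w), sides = 2, circular = TRUE)
  } else {
    ## linear reference: partial windows at the edges
    cs <- cumsum(c(0, x))
    n <- length(x)
    lo <- pmax(0L, seq_len(n) - 1L - ((w - 1L) %/% 2L))
    hi <- pmin(n, seq_len(n) + (w %/% 2L))
    sm <- (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
  }
  if (is.null(track$raw_ratio)) track$raw_ratio <- x
  track$ratio <- as.numeric(sm)
  track$smoothing_window_bp <- window_bp
  track
}

#' Call the top-N enrichment peaks
#'
#' Local maxima of the (smoothed) enrichment track are selected greedily
#' by descending score, each accepted peak excluding further peaks within
#' `min_separation_bp` (circular distance on circular references).
#' Returns at most `N` peaks; fewer when the track has fewer maxima.
#'
#' Smoothing a narrow site with a wide window produces a flat-topped
#' plateau on which the argmax is set by noise, so when the track was
#' produced by [smooth_track()] each selected peak's position is refined
#' to the summit (argmax) of the unsmoothed ratio within half a
#' smoothing window of the smoothed maximum.
#'
#' @param track an `enrichment_track` (typically after [smooth_track()]).
#' @param N number of peaks to return (default 26).
#' @param min_separation_bp exclusion-zone radius (default 2000).
#' @return data frame of class `peak_table`: `position_bp` (bin centre,
#'   0-based), `score`, `rank`.
#' @export
call_top_peaks <- function(track, N = 26, min_separation_bp = 2000) {
  stopifnot(inherits(track, "enrichment_track"))
  s <- track$ratio
  n <- length(s)
  if (track$circular) {
    left <- s[c(n, seq_len(n - 1L))]
    right <- s[c(seq_len(n - 1L) + 1L, 1L)]
  } else {
    left <- c(-Inf, s[-n]); right <- c(s[-1L], -Inf)
  }
  ## plateau-safe: strictly above right neighbour, at or above left
  cand <- which(s >= left & s > right)
  cand <- cand[order(s[cand], decreasing = TRUE)]
  pos <- (cand - 1L) * track$bin_bp + track$bin_bp / 2
  L <- track$genome_length_bp
  sel <- integer()
  for (i in seq_along(cand)) {
    if (length(sel) == length(cand)) break
    d <- abs(pos[i] - pos[sel])
    if (track$circular && length(sel)) d <- pmin(d, L - d)
    if (length(sel) == 0L || all(d >= min_separation_bp)) {
      sel <- c(sel, i)
      if (length(sel) == N) break
    }
  }
  pos_sel <- pos[sel]
  if (!is.null(track$raw_ratio) && !is.na(track$smoothing_window_bp)) {
    half <- max(1L, round(track$smoothing_window_bp / 2 / track$bin_bp))
    pos_sel <- vapply(cand[sel], function(b) {
      idx <- (b - half):(b + half)
      if (track$circular) idx <- ((idx - 1L) %% n) + 1L
      else idx <- idx[idx >= 1L & idx <= n]
      summit <- idx[which.max(track$raw_ratio[idx])]
      (summit - 1L) * track$bin_bp + track$bin_bp / 2
    }, numeric(1))
  }
  out <- data.frame(position_bp = pos_sel, score = s[cand[sel]],
                    rank = seq_along(sel))
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Scan a genome for a degenerate consensus motif
#'
#' Scans both strands for matches to an IUPAC consensus with at most
#' `max_mismatch` mismatches. Hits are reported by their forward-strand
#' start; positions where the forward and reverse strand both match
#' (e.g. for a palindromic consensus) are collapsed to a single hit.
#'
#' @param genome a [Biostrings::DNAString] or character string
#'   (uppercase ACGT; other letters never match a concrete consensus
#'   base).
#' @param consensus IUPAC consensus string.
#' @param max_mismatch maximum mismatches (default 1).
#' @return data frame of class `motif_hits`: `start` (0-based), `strand`
#'   (`"+"`/`"-"`), `mismatches`, `match` (the genomic sequence).
#' @export
scan_motif <- function(genome, consensus, max_mismatch = 1) {
  if (is.character(genome)) genome <- Biostrings::DNAString(genome)
  consensus <- toupper(consensus)
  if (!all(strsplit(consensus, "")[[1L]] %in% names(iupac_code_list())))
    stop_config("consensus contains non-IUPAC characters")
  pat_f <- Biostrings::DNAString(consensus)
  pat_r <- Biostrings::reverseComplement(pat_f)
  fixed <- c(pattern = FALSE, subject = TRUE)
  hits_for <- function(pat, strand) {
    m <- Biostrings::matchPattern(pat, genome,
                                  max.mismatch = max_mismatch,
                                  fixed = fixed)
    if (length(m) == 0L)
      return(data.frame(start = integer(), strand = character(),
                        mismatches = integer(), match = character()))
    st <- Biostrings::start(m)
    mm <- Biostrings::neditStartingAt(pat, genome, starting.at = st,
                                      fixed = fixed)
    data.frame(start = st - 1L, strand = strand, mismatches = mm,
               match = as.character(m))
  }
  out <- rbind(hits_for(pat_f, "+"), hits_for(pat_r, "-"))
  out <- out[order(out$start, match(out$strand, c("+", "-"))), ,
             drop = FALSE]
  ## collapse double reports at one position (palindromic consensus)
  out <- out[!duplicated(out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("motif_hits", "data.frame")
  out
}

#' Annotate peaks with the nearest motif hit
#'
#' Labels each peak with the nearest motif hit within `tolerance_bp` of
#' the peak position (or none), and counts peaks at a motif. Hits can be
#' excluded from consideration by position (e.g. a known site that shows
#' no enrichment and is left out of downstream profile analyses).
#'
#' @param peaks a `peak_table` from [call_top_peaks()].
#' @param motif_hits a `motif_hits` table from [scan_motif()].
#' @param tolerance_bp maximum peak-to-motif distance (default 500).
#' @param exclude_bp motif positions (0-based starts) to drop before
#'   annotation, or `NULL`.
#' @param motif_length used to convert hit starts to centres; defaults
#'   to the `match` width.
#' @return the peak table with columns `motif_start`, `motif_distance_bp`
#'   and `at_motif` added; the number of motif-annotated peaks is in
#'   attribute `"n_at_motif"`.
#' @export
annotate_peaks <- function(peaks, motif_hits, tolerance_bp = 500,
                           exclude_bp = NULL, motif_length = NULL) {
  hits <- motif_hits
  if (!is.null(exclude_bp))
    hits <- hits[!(hits$start %in% exclude_bp), , drop = FALSE]
  if (is.null(motif_length))
    motif_length <- if (nrow(hits)) nchar(hits$match[1L]) else 0L
  centres <- hits$start + motif_length / 2
  ann <- lapply(peaks$position_bp, function(p) {
    if (length(centres) == 0L)
      return(data.frame(motif_start = NA_integer_,
                        motif_distance_bp = NA_real_, at_motif = FALSE))
    d <- abs(centres - p)
    j <- which.min(d)
    data.frame(motif_start = hits$start[j], motif_distance_bp = d[j],
               at_motif = d[j] <= tolerance_bp)
  })
  out <- cbind(as.data.frame(peaks), do.call(rbind, ann))
  out$motif_start[!out$at_motif] <- NA_integer_
  attr(out, "n_at_motif") <- sum(out$at_motif)
  out
}

## Circular-safe bin extraction around an anchor, offsets in bins.
extract_window <- function(track, anchor_bp, offsets) {
  n <- length(track$ratio)
  b0 <- floor(anchor_bp / track$bin_bp) + 1L
  idx <- b0 + offsets
  if (track$circular) {
    idx <- ((idx - 1L) %% n) + 1L
    track$ratio[idx]
  } else {
    ok <- idx >= 1L & idx <= n
    out <- rep(NA_real_, length(idx))
    out[ok] <- track$ratio[idx[ok]]
    out
  }
}

#' Anchor-centred enrichment profiles across conditions
#'
#' Extracts enrichment windows centred on a common set of anchor
#' positions (typically the top peaks of a reference condition), aligns
#' them by anchor, and takes the across-anchor median at each offset.
#' Per condition it reports the profile peak height (maximum of the
#' median profile) and a flatness statistic (max / median over the
#' window; ~1 for a featureless profile). The fold change between two
#' conditions is the ratio of their profile maxima.
#'
#' @param tracks_by_condition named list of `enrichment_track`s, one per
#'   condition, sharing binning.
#' @param anchors_bp anchor positions in bp (non-empty).
#' @param half_window_bp half-width of the extracted window (default
#'   1000, i.e. a 2-kb window centred on each anchor).
#' @return list of class `anchored_profile`: `profiles` (data frame,
#'   `offset_bp` plus one column per condition), `summary` (per
#'   condition: `peak_height`, `flatness`), `anchors_bp`.
#' @export
anchored_profile <- function(tracks_by_condition, anchors_bp,
                             half_window_bp = 1000) {
  if (length(anchors_bp) == 0L) stop_input("no anchors supplied")
  if (is.null(names(tracks_by_condition)))
    names(tracks_by_condition) <- paste0("cond", seq_along(tracks_by_condition))
  bb <- vapply(tracks_by_condition, `[[`, numeric(1), "bin_bp")
  if (length(unique(bb)) != 1L)
    stop_input("conditions disagree in bin width")
  bin <- bb[[1L]]
  k <- floor(half_window_bp / bin)
  offsets <- -k:k
  prof <- lapply(tracks_by_condition, function(tr) {
    m <- vapply(anchors_bp, function(a) extract_window(tr, a, offsets),
                numeric(length(offsets)))
    apply(m, 1L, stats::median, na.rm = TRUE)
  })
  profiles <- data.frame(offset_bp = offsets * bin)
  for (nm in names(prof)) profiles[[nm]] <- prof[[nm]]
  summary <- data.frame(
    condition = names(prof),
    peak_height = vapply(prof, max, numeric(1)),
    flatness = vapply(prof, function(p) max(p) / stats::median(p),
                      numeric(1)),
    row.names = NULL)
  structure(list(profiles = profiles, summary = summary,
                 anchors_bp = anchors_bp,
                 half_window_bp = half_window_bp),
            class = "anchored_profile")
}

#' Fold change between two conditions of an anchored profile
#'
#' @param profile an `anchored_profile`.
#' @param numerator,denominator condition names.
#' @return ratio of the two profile maxima.
#' @export
profile_fold_change <- function(profile, numerator, denominator) {
  s <- profile$summary
  a <- s$peak_height[s$condition == numerator]
  b <- s$peak_height[s$condition == denominator]
  if (length(a) != 1L || length(b) != 1L)
    stop_input("conditions '%s' and '%s' not both present",
               numerator, denominator)
  a / b
}
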