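## Independent oracles and small fixture builders shared across tests.

## Exhaustive-run oracle for the persistence rule: scan every start
## index for K consecutive separated frames, take the first.
oracle_segregation <- function(sep_flags, time_min, K) {
  n <- length(sep_flags)
  for (i in seq_len(n - K + 1L)) {
    if (all(sep_flags[i:(i + K - 1L)])) return(time_min[i])
  }
  NA_real_
}

## Terminal-absence oracle for replisome disappearance: first index j
## such that the focus is absent from j through the end of the track.
oracle_replisome_end <- function(counts, time_min) {
  n <- length(counts)
  for (j in seq_len(n)) {
    if (all(counts[j:n] == 0)) return(time_min[j])
  }
  NA_real_
}

## Position-by-position brute-force motif scan with IUPAC degeneracy.
## Independent of Biostrings: pure character comparison.
oracle_scan <- function(genome_chr, consensus, max_mismatch) {
  codes <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
            S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
            D = "H", H = "D", N = "N")
  g <- strsplit(genome_chr, "")[[1L]]
  scan_one <- function(cons_letters, strand) {
    L <- length(cons_letters)
    n <- length(g)
    if (n < L) return(NULL)
    mm <- integer(n - L + 1L)
    for (j in seq_len(L)) {
      ok <- g[j:(n - L + j)] %in% codes[[cons_letters[j]]]
      mm <- mm + !ok
    }
    hit <- which(mm <= max_mismatch)
    if (length(hit) == 0L) return(NULL)
    data.frame(start = hit - 1L, strand = strand, mismatches = mm[hit])
  }
  cons <- strsplit(toupper(consensus), "")[[1L]]
  rc <- rev(unname(comp[cons]))
  out <- rbind(scan_one(cons, "+"), scan_one(rc, "-"))
  if (is.null(out))
    return(data.frame(start = integer(), strand = character(),
                      mismatches = integer()))
  out <- out[order(out$start, match(out$strand, c("+", "-"))), ,
             drop = FALSE]
  out <- out[!duplicated(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## One-cell track builder for cohesion tests.
make_track <- function(replisome_count, locus_count, dt = 5, cell_id = 1L) {
  n <- length(replisome_count)
  data.frame(cell_id = cell_id, frame = seq_len(n),
             time_min = (seq_len(n) - 1L) * dt,
             replisome_count = replisome_count,
             locus_count = locus_count)
}

## Disc-shaped cell region (pixel centres within radius of the centre).
make_disc_cell <- function(radius_px, cell_id = 1L, pixel_size_nm = 129) {
  n <- 2L * ceiling(radius_px) + 3L
  ctr <- (n + 1) / 2
  idx <- expand.grid(row = seq_len(n), col = seq_len(n))
  keep <- (idx$row - ctr)^2 + (idx$col - ctr)^2 <= radius_px^2
  structure(list(cell_id = cell_id, rows = idx$row[keep],
                 cols = idx$col[keep], center_row = ctr, center_col = ctr,
                 pixel_size_nm = pixel_size_nm),
            class = "cell_region")
}

## Noise-free Gaussian spot window for fitting tests.
gauss_window <- function(n = 11, row0 = 6, col0 = 6, amplitude = 200,
                         sigma = 1.5, offset = 100) {
  offset + amplitude *
    exp(-(outer((seq_len(n) - row0)^2, (seq_len(n) - col0)^2, "+")) /
          (2 * sigma^2))
}

## Minimal focus table from explicit per-cell centroids.
focus_table <- function(cell_id, channel, row, col) {
  data.frame(cell_id = cell_id, frame_id = 1L, channel = channel,
             row = row, col = col, amplitude = NA_real_,
             sd_px = NA_real_, qc = "ok")
}

## Enrichment track built directly from a ratio vector.
ratio_track <- function(ratio, bin_bp = 50, circular = TRUE) {
  structure(list(ratio = ratio, bin_bp = bin_bp,
                 genome_length_bp = length(ratio) * bin_bp,
                 reference = "chr", circular = circular,
                 pseudocount = 0, smoothing_window_bp = NA_real_,
                 n_ip = 1L, n_mock = 1L),
            class = "enrichment_track")
}
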