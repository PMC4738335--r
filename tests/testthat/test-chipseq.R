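test_that("CPM normalization rescales libraries and logs factors", {
  counts <- rep(200, 10000); counts[1] <- 2e6 - sum(counts[-1])
  tr <- coverage_track(counts, 100, 1e6, role = "IP")
  norm <- normalize_coverage(tr)
  expect_equal(norm$counts[2], 100)  # 200 reads in a 2e6 library -> 100 CPM
  expect_equal(attr(norm, "cpm_factor"), 0.5)

  t1 <- coverage_track(rpois(1000, 50) + 1, 100, 1e5, role = "IP")
  t2 <- t1; t2$counts <- t1$counts * 2
  n <- normalize_coverage(list(t1, t2))
  expect_equal(n[[1]]$counts, n[[2]]$counts)

  bad <- coverage_track(rep(0, 1000), 100, 1e5)
  expect_error(normalize_coverage(bad), class = "mukcoloc_input_error")
})

test_that("library-size factors vanish after normalization", {
  sp <- sim_chip_spec(genome_length_bp = 2e5, bin_bp = 50,
                      read_depth = 2e6, libsize_log_sd = 0.3, seed = 50)
  ch <- generate_chipseq(sp)
  norm <- normalize_coverage(ch$ip)
  means <- vapply(norm, function(t) mean(t$counts), numeric(1))
  expect_lt(diff(range(means)) / mean(means), 0.02)
})

test_that("ratio track takes medians before the ratio", {
  mk <- function(v, role, rep) coverage_track(v, 100, 300, role = role,
                                              replicate = rep)
  ip <- lapply(1:3, function(i) mk(c(10, 12, 14)[i] * c(1, 1, 1), "IP", i))
  mock <- lapply(1:3, function(i) mk(c(5, 6, 7)[i] * c(1, 1, 1),
                                     "mock", i))
  enr <- median_ratio_track(ip, mock, pseudocount = 0, normalize = FALSE)
  expect_equal(enr$ratio, rep(12 / 6, 3))
  ## identical IP and mock give exactly 1 (the pseudocount cancels)
  enr2 <- median_ratio_track(ip, ip, pseudocount = 0.5, normalize = FALSE)
  expect_equal(enr2$ratio, rep(1, 3))
  ## bin mismatch is an error
  expect_error(median_ratio_track(ip, list(mk(c(1, 2), "mock", 1))),
               class = "mukcoloc_input_error")
})

test_that("IP counts at a planted site scale with the planted fold", {
  ## analytic mean check across seeds: site bins should average 8x the
  ## per-bin baseline while background bins stay at baseline
  depth <- 2e5; L <- 1e5; bin <- 50
  n_bins <- L / bin; base <- depth / n_bins
  site <- 50000
  site_bin <- floor(site / bin) + 1
  m_site <- m_bg <- 0
  for (s in 1:30) {
    ch <- generate_chipseq(sim_chip_spec(
      genome_length_bp = L, bin_bp = bin, site_positions = site,
      site_enrichment = 8, read_depth = depth, libsize_log_sd = 0,
      n_replicates = 1, seed = s))
    m_site <- m_site + ch$ip[[1]]$counts[site_bin] / 30
    m_bg <- m_bg + mean(ch$ip[[1]]$counts[1:500]) / 30
  }
  expect_equal(m_site / base, 8, tolerance = 0.15)
  expect_equal(m_bg / base, 1, tolerance = 0.05)
})

test_that("shared highly-transcribed artifacts cancel in the ratio", {
  htr <- data.frame(start = 40000, end = 45000, fold = 10)
  ch <- generate_chipseq(sim_chip_spec(
    genome_length_bp = 1e5, bin_bp = 50, read_depth = 2e6,
    htr_artifacts = htr, seed = 51))
  enr <- median_ratio_track(ch$ip, ch$mock)
  bins <- (40000 / 50 + 1):(45000 / 50)
  expect_gt(median(enr$ratio[bins]), 0.9)
  expect_lt(median(enr$ratio[bins]), 1.1)
  sm <- smooth_track(enr, 2000)
  expect_true(all(sm$ratio[bins] > 0.8 & sm$ratio[bins] < 1.25))
  ## both roles are elevated in the interval
  expect_gt(mean(ch$ip[[1]]$counts[bins]),
            5 * mean(ch$ip[[1]]$counts[1:500]))
  expect_gt(mean(ch$mock[[1]]$counts[bins]),
            5 * mean(ch$mock[[1]]$counts[1:500]))
})

test_that("overlapping planted sites are rejected", {
  expect_error(sim_chip_spec(site_positions = c(1000, 1040)),
               class = "mukcoloc_config_error")
})

test_that("chip generation is deterministic under the seed", {
  sp <- sim_chip_spec(genome_length_bp = 5e4, site_positions = 2e4,
                      read_depth = 1e5, seed = 52)
  a <- generate_chipseq(sp); b <- generate_chipseq(sp)
  expect_identical(a$ip[[1]]$counts, b$ip[[1]]$counts)
  expect_identical(a$mock[[3]]$counts, b$mock[[3]]$counts)
})

test_that("smoothing averages an impulse over the window and conserves mass", {
  x <- rep(0, 100); x[30] <- 1
  tr <- ratio_track(x, bin_bp = 50)           # 5-kb circular genome
  sm <- smooth_track(tr, 2000)                # 40-bin window
  expect_equal(sum(sm$ratio > 0), 40)
  expect_equal(max(sm$ratio), 1 / 40)
  expect_equal(sum(sm$ratio), sum(x), tolerance = 1e-9)
  ## constant track unchanged
  cst <- smooth_track(ratio_track(rep(2, 100)), 2000)
  expect_equal(cst$ratio, rep(2, 100))
  ## circular wrap: an impulse at bin 1 reaches the last bins
  x2 <- rep(0, 100); x2[1] <- 1
  sm2 <- smooth_track(ratio_track(x2), 2000)
  expect_gt(sm2$ratio[100], 0)
  expect_error(smooth_track(ratio_track(x2), 10),
               class = "mukcoloc_input_error")
})

test_that("top-peak calling enforces exclusion zones and never pads", {
  x <- rep(1, 200)
  x[50] <- 5; x[60] <- 4                      # 500 bp apart at 50 bp/bin
  x[150] <- 3
  pk <- call_top_peaks(ratio_track(x), N = 26, min_separation_bp = 2000)
  expect_equal(nrow(pk), 2L)                  # the 4 is excluded by the 5
  expect_equal(pk$position_bp, c(49 * 50 + 25, 149 * 50 + 25))
  expect_equal(pk$rank, 1:2)
  ## a flat track has no local maxima: empty result, no padding
  expect_equal(nrow(call_top_peaks(ratio_track(rep(1, 200)))), 0L)
})

test_that("motif scanning handles degenerate consensus on both strands", {
  cons <- "GTGACRNYGTCAC"
  expect_equal(scan_motif(cons, cons, max_mismatch = 0)$start, 0L)
  g <- plant_motif_genome(5e4, cons, c(1000, 30000), seed = 53)
  h <- scan_motif(g, cons, max_mismatch = 0)
  expect_true(all(c(1000, 30000) %in% h$start))
  expect_true(all(h$mismatches == 0))
  ## scanning with the reverse complement finds the same positions
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(cons)))
  expect_equal(scan_motif(g, rc, max_mismatch = 0)$start, h$start)
  expect_error(scan_motif(g, "GTXAC"), class = "mukcoloc_config_error")
})

test_that("motif scan equals the brute-force oracle on random sequence", {
  cons <- "GTGACRNYGTCAC"
  for (s in 1:3) {
    g <- plant_motif_genome(2e4, cons, c(5000, 12000), seed = s)
    got <- scan_motif(g, cons, max_mismatch = 1)
    want <- oracle_scan(as.character(g), cons, 1)
    expect_equal(got$start, want$start)
    expect_equal(got$mismatches, want$mismatches)
  }
})

test_that("peak annotation respects tolerance and exclusions", {
  pk <- structure(data.frame(position_bp = c(1006, 5600, 9000),
                             score = c(5, 4, 3), rank = 1:3),
                  class = c("peak_table", "data.frame"))
  hits <- data.frame(start = c(1000, 5000, 9000), strand = "+",
                     mismatches = 0L,
                     match = "GTGACANNGTCAC")
  ann <- annotate_peaks(pk, hits, tolerance_bp = 500)
  expect_equal(ann$at_motif, c(TRUE, FALSE, TRUE))  # 5600 is 600-ish away
  expect_equal(attr(ann, "n_at_motif"), 2L)
  expect_equal(ann$motif_distance_bp[1], abs(1000 + 6.5 - 1006))
  ## excluding the motif near the first peak removes its annotation
  ann2 <- annotate_peaks(pk, hits, tolerance_bp = 500, exclude_bp = 1000)
  expect_false(ann2$at_motif[1])
})

test_that("anchored profiles are symmetric for symmetric planted peaks", {
  x <- rep(1, 400)
  centre_bin <- 200
  bump <- dnorm(-10:10, sd = 3); bump <- 3 * bump / max(bump)
  x[centre_bin + (-10:10)] <- 1 + bump
  ap <- anchored_profile(list(cond = ratio_track(x)),
                         anchors_bp = (centre_bin - 1) * 50 + 25,
                         half_window_bp = 1000)
  prof <- ap$profiles$cond
  expect_equal(prof, rev(prof), tolerance = 1e-9)
  expect_equal(max(prof), 4, tolerance = 1e-6)
  ## the window median sits on the Gaussian tail 10 bins out
  expect_equal(ap$summary$flatness, 4 / (1 + 3 * exp(-100 / 18)),
               tolerance = 1e-3)
})

test_that("profile fold change is the ratio of profile maxima", {
  x1 <- rep(1, 400); x2 <- rep(1, 400)
  anchors <- c(100, 300) * 50 - 25
  for (b in c(100, 300)) {
    x1[b] <- 3.0; x2[b] <- 4.5
  }
  ap <- anchored_profile(list(a = ratio_track(x1), b = ratio_track(x2)),
                         anchors_bp = anchors, half_window_bp = 500)
  expect_equal(profile_fold_change(ap, "b", "a"), 1.5)
  expect_error(profile_fold_change(ap, "b", "zz"),
               class = "mukcoloc_input_error")
})
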