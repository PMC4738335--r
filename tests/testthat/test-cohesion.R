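test_that("replisome end is the start of the terminal absence run", {
  t5 <- (0:5) * 5
  expect_equal(call_replisome_end(c(1, 1, 1, 0, 0, 0), t5), 15)
  ## a single-frame dropout followed by reappearance is not terminal
  expect_equal(call_replisome_end(c(1, 0, 1, 0, 0, 0), t5), 15)
  expect_true(is.na(call_replisome_end(rep(1, 6), t5)))
  expect_error(call_replisome_end(rep(0, 6), t5),
               class = "mukcoloc_input_error")
})

test_that("segregation requires K consecutive separated frames", {
  p <- cohesion_params(K = 3)
  t9 <- (0:8) * 5
  ## the 2-run at frames 3-4 is transient; frame 6 starts the first 3-run
  expect_equal(call_segregation(1 + c(0, 0, 1, 1, 0, 1, 1, 1, 1), t9, p),
               25)
  expect_equal(call_segregation(rep(2, 9), t9, p), 0)
  expect_true(is.na(call_segregation(
    1 + c(1, 1, 0, 1, 1, 0, 1, 1, 0), t9, p)))
})

test_that("persistence calls match exhaustive run enumeration on all flag patterns", {
  p <- cohesion_params(K = 3)
  times <- (0:9) * 5
  for (code in 0:1023) {
    flags <- as.integer(intToBits(code)[1:10])
    got <- call_segregation(1 + flags, times, p)
    want <- oracle_segregation(flags == 1, times, 3)
    expect_identical(got, want)
  }
})

test_that("replisome calls match the terminal-run oracle on random tracks", {
  set.seed(40)
  times <- (0:11) * 5
  for (i in 1:200) {
    counts <- rbinom(12, 1, 0.6)
    if (all(counts == 0)) counts[1] <- 1
    expect_identical(call_replisome_end(counts, times),
                     oracle_replisome_end(counts, times))
  }
})

test_that("cohesion time is the measured interval plus the 7-min offset", {
  ## 1-min frames so off-grid intervals can be planted exactly
  mk <- function(end_min, split_min, n = 30) {
    make_track(as.integer((0:(n - 1)) < end_min),
               ifelse(0:(n - 1) >= split_min, 2L, 1L), dt = 1)
  }
  expect_equal(cohesion_time(mk(10, 12))$cohesion_time_min, 9)
  expect_equal(cohesion_time(mk(10, 10))$cohesion_time_min, 7)
  ## segregation may precede replisome disappearance
  cc <- cohesion_time(mk(10, 5))
  expect_equal(cc$measured_interval_min, -5)
  expect_equal(cc$cohesion_time_min, 2)
  ## censoring propagates
  tr <- mk(10, 12)
  tr$replisome_count <- 1L
  expect_true(cohesion_time(tr)$censored)
  expect_true(is.na(cohesion_time(tr)$cohesion_time_min))
})

test_that("t50 is the first time at which half the cells have segregated", {
  calls <- data.frame(cell_id = 1:4, cohesion_time_min = c(7, 7, 12, 12),
                      censored = FALSE)
  expect_equal(population_segregation(calls)$t50_min, 7)
  calls2 <- data.frame(cell_id = 1:3, cohesion_time_min = rep(9, 3),
                       censored = FALSE)
  expect_equal(population_segregation(calls2)$t50_min, 9)
  calls3 <- data.frame(cell_id = 1, cohesion_time_min = NA_real_,
                       censored = TRUE)
  expect_error(population_segregation(calls3),
               class = "mukcoloc_input_error")
})

test_that("transient separations shorter than K never change the call", {
  spec <- sim_timelapse_spec(n_cells = 20, transient_split_prob = 0,
                             transient_merge_prob = 0, delay_min = 10,
                             seed = 41)
  tl <- generate_timelapse(spec)
  p <- cohesion_params()
  base <- cohesion_calls(tl$tracks, p)
  set.seed(42)
  perturbed <- do.call(rbind, lapply(split(tl$tracks, tl$tracks$cell_id),
    function(tr) {
      split_idx <- match(2L, tr$locus_count)
      if (split_idx > 4) {
        at <- sample(seq_len(split_idx - 3), 1)
        tr$locus_count[at:(at + 1)] <- 2L   # 2-frame run, gap before split
      }
      tr
    }))
  expect_equal(cohesion_calls(perturbed, p)$segregation_min,
               base$segregation_min)
})

test_that("raising K never makes a segregation call earlier", {
  set.seed(43)
  times <- (0:14) * 5
  for (i in 1:100) {
    flags <- rbinom(15, 1, 0.5)
    s3 <- call_segregation(1 + flags, times, cohesion_params(K = 3))
    s4 <- call_segregation(1 + flags, times, cohesion_params(K = 4))
    expect_true(is.na(s4) || (!is.na(s3) && s4 >= s3))
  }
})

test_that("generated tracks yield cohesion times on the offset grid", {
  tl <- generate_timelapse(sim_timelapse_spec(n_cells = 40, delay_min = 9,
                                              seed = 44))
  calls <- cohesion_calls(tl$tracks)
  ok <- !calls$censored
  expect_true(any(ok))
  ## cohesion = (multiple of the 5-min frame interval) + 7-min offset
  expect_true(all((calls$cohesion_time_min[ok] - 7) %% 5 == 0))
})

test_that("centroid distances can veto a separation call", {
  p <- cohesion_params(K = 2, min_separation_px = 2)
  times <- (0:3) * 5
  close_pair <- rbind(c(5, 5), c(5, 6))     # 1 px apart
  far_pair <- rbind(c(5, 5), c(5, 8))       # 3 px apart
  cents <- list(close_pair, close_pair, far_pair, far_pair)
  got <- call_segregation(c(2, 2, 2, 2), times, p, centroids = cents)
  expect_equal(got, 10)  # the close frames do not count as separated
})
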