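test_that("registration leaves an aligned series untouched", {
  ph <- generate_phantom(small_spec())
  reg <- register_frames(ph$rest)
  expect_true(all(reg$shifts == 0L))
  expect_identical(reg$series$data, ph$rest$data)
})

test_that("registration recovers known integer motion exactly without noise", {
  ph <- generate_phantom(small_spec(motion_amplitude = 3L, seed = 21L))
  reg <- register_frames(ph$stress)
  expect_identical(unname(reg$shifts), unname(-ph$truth$shifts_stress))
  # and the corrected series matches the motionless render
  still <- generate_phantom(small_spec(motion_amplitude = 0L, seed = 21L))
  expect_equal(reg$series$data, still$stress$data, tolerance = 1e-12)
})

test_that("an oversized search window is rejected", {
  ph <- generate_phantom(small_spec())
  expect_error(register_frames(ph$rest, max_shift = 30L), "window")
})

test_that("TSI extraction reduces masks to mean curves", {
  arr <- array(7, dim = c(8, 8, 1, 5))
  series <- perfusion_series(arr, dt = 1, n_baseline = 2)
  labels <- matrix(0L, 8, 8); labels[3:4, 3:4] <- 1L
  bp <- matrix(FALSE, 8, 8); bp[6, 6] <- TRUE
  masks <- list(list(level = "mid", labels = labels, blood_pool = bp))
  tsi <- extract_tsi(series, masks)
  expect_equal(unname(tsi$segments[, "1"]), rep(7, 5))
  expect_equal(tsi$blood_pool, rep(7, 5))

  # single-pixel mask returns that pixel's time course
  arr[6, 6, 1, ] <- 1:5
  tsi2 <- extract_tsi(perfusion_series(arr, 1, n_baseline = 2), masks)
  expect_equal(tsi2$blood_pool, as.numeric(1:5))
})

test_that("noise-free phantom TSI curves equal their generating tissue curves", {
  spec <- small_spec()
  ph <- generate_phantom(spec)
  masks <- lapply(ph$contours, segment_aha16, grid = dim(ph$rest$data)[1:2])
  tsi <- extract_tsi(ph$rest, masks)
  t <- ph$rest$times
  aif <- aif_gamma_variate(t, spec$aif_rest)
  for (seg in c(1, 7, 16)) {
    want <- tissue_curve(aif, spec$f_rest[seg], spec$dt, spec$s0_myo,
                         spec$aif_rest$s0)
    expect_equal(unname(tsi$segments[, as.character(seg)]), want,
                 tolerance = 1e-12)
  }
  expect_equal(tsi$blood_pool, aif, tolerance = 1e-12)
})

test_that("baseline detection follows the 3-SD rule with a 1-au floor", {
  got <- detect_baseline(c(10, 10, 10, 10, 11, 50, 80), n_baseline = 3)
  expect_equal(got$baseline, 10)
  expect_equal(got$onset, 6L)   # the 11 is within the 1-au absolute floor
  expect_error(detect_baseline(rep(5, 10), 3), "no enhancement")
  expect_error(detect_baseline(1:3, 5), "shorter")
})

test_that("phantom blood-pool onset lands within one frame of bolus arrival", {
  spec <- small_spec()
  ph <- generate_phantom(spec)
  masks <- lapply(ph$contours, segment_aha16, grid = dim(ph$rest$data)[1:2])
  tsi <- extract_tsi(ph$rest, masks)
  got <- detect_baseline(tsi$blood_pool, spec$n_baseline)
  true_frame <- spec$aif_rest$t0 / spec$dt + 1
  expect_lte(abs(got$onset - true_frame), 1 + 1e-9)
})

test_that("maximum upslope is exact on a ramp and zero on a plateau", {
  t <- 0:19
  up <- max_upslope(c(rep(0, 5), 2 * (1:15)), t, k = 3, n_baseline = 4)
  expect_equal(up$slope, 2)
  up4 <- max_upslope(c(rep(0, 5), 2 * (1:15)), t, k = 5, n_baseline = 4)
  expect_equal(up4$slope, 2)
  # forced plateau after a step: the only admissible window is flat
  flat <- c(rep(0, 4), rep(10, 10))
  up0 <- max_upslope(flat, seq_along(flat) - 1, k = 2, n_baseline = 3)
  expect_equal(up0$slope, 0)
})

test_that("maximum upslope equals exhaustive window enumeration", {
  p <- aif_params(amplitude = 100, t0 = 4, alpha = 3, beta = 2, s0 = 10)
  t <- seq(0, 25, by = 0.5)
  curve <- aif_gamma_variate(t, p)
  got <- max_upslope(curve, t, k = 3, n_baseline = 5)
  expect_equal(got$slope, oracle_max_upslope(curve, t, 3, 5),
               tolerance = 1e-9)

  set.seed(14)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    n <- sample(20:40, 1)
    tt <- (seq_len(n) - 1) * runif(1, 0.4, 1.5)
    cc <- c(rep(0, 5), cumsum(runif(n - 5, 0, 4))) + rnorm(n, 0, 0.3)
    res <- try(max_upslope(cc, tt, k, 5), silent = TRUE)
    if (inherits(res, "try-error")) next
    expect_equal(res$slope, oracle_max_upslope(cc, tt, k, 5),
                 tolerance = 1e-9)
  }
})

test_that("window preconditions are enforced", {
  expect_error(max_upslope(c(0, 0, 0, 5, 6), 0:4, k = 1, n_baseline = 3),
               "k")
  # peak right after onset: no room for a 5-frame window
  expect_error(max_upslope(c(0, 0, 0, 10, 0, 0, 0, 0), 0:7, k = 5,
                           n_baseline = 3), "admissible")
})

test_that("relative upslope is the plain ratio with a degenerate-AIF guard", {
  expect_equal(relative_upslope(0.5, 2), 0.25)
  expect_equal(relative_upslope(2, 2), 1)
  expect_error(relative_upslope(1, 0), "blood-pool")
})

test_that("identical states give unit MPRI everywhere", {
  ph <- generate_phantom(small_spec(f_stress = rep(0.1, 16)))
  m <- phantom_mpri(ph)
  expect_equal(m$segments$mpri, rep(1, 16), tolerance = 1e-9)
  expect_equal(m$global_mpri, 1, tolerance = 1e-9)
  expect_equal(unname(m$level_means), rep(1, 3), tolerance = 1e-9)
})

test_that("a stress-only flow reduction halves that segment's MPRI", {
  f_s <- rep(0.2, 16); f_s[8] <- 0.1
  ph <- generate_phantom(small_spec(f_stress = f_s))
  m <- phantom_mpri(ph)
  others <- m$segments$mpri[m$segments$segment != 8]
  expect_equal(m$segments$mpri[m$segments$segment == 8],
               mean(others) / 2, tolerance = 1e-6)
})

test_that("relative upslopes and MPRI are invariant to global signal scaling", {
  ph <- generate_phantom(small_spec(noise_sigma = 0.5, seed = 2L))
  m1 <- phantom_mpri(ph)
  ph$rest$data <- ph$rest$data * 3.7
  ph$stress$data <- ph$stress$data * 3.7
  m2 <- phantom_mpri(ph)
  expect_equal(m2$segments$relupslope_rest, m1$segments$relupslope_rest,
               tolerance = 1e-12)
  expect_equal(m2$segments$mpri, m1$segments$mpri, tolerance = 1e-12)
})

test_that("defect classification implements the full decision table", {
  expect_equal(classify_defect(TRUE, FALSE, FALSE), "reversible")
  expect_equal(classify_defect(TRUE, TRUE, TRUE), "fixed")
  expect_equal(classify_defect(TRUE, TRUE, FALSE), "artifact")
  expect_equal(classify_defect(FALSE, FALSE, FALSE), "normal")
  expect_equal(classify_defect(FALSE, FALSE, TRUE), "normal")
  expect_equal(classify_defect(TRUE, FALSE, TRUE), "reversible")
  expect_equal(classify_defect(FALSE, TRUE, FALSE), "artifact")
  expect_equal(classify_defect(FALSE, TRUE, TRUE), "artifact")
})

test_that("deficit flagging is median-relative and end-to-end calls match", {
  expect_false(any(flag_deficit_segments(rep(1, 16))))
  v <- rep(1, 16); v[5] <- 0.5
  expect_identical(which(flag_deficit_segments(v)), 5L)

  # stress-only 40% flow reduction in segment 8 -> reversible there only
  f_s <- rep(0.2, 16); f_s[8] <- 0.12
  ph <- generate_phantom(small_spec(f_stress = f_s))
  m <- phantom_mpri(ph)
  sd_flags <- flag_deficit_segments(m$segments$relupslope_stress)
  rd_flags <- flag_deficit_segments(m$segments$relupslope_rest)
  calls <- classify_defect(sd_flags, rd_flags, rep(FALSE, 16))
  expect_equal(calls[m$segments$segment == 8], "reversible")
  expect_true(all(calls[m$segments$segment != 8] == "normal"))
  expect_error(flag_deficit_segments(v, threshold = 1.2), "threshold")
})

test_that("noise at 2% of peak signal keeps global MPRI within 5% of truth", {
  spec0 <- small_spec()
  masks <- lapply(generate_phantom(spec0)$contours, segment_aha16,
                  grid = c(spec0$nrow, spec0$ncol))
  sigma <- 0.02 * (spec0$aif_rest$s0 + spec0$aif_rest$amplitude)
  for (seed in 1:20) {
    ph <- generate_phantom(small_spec(noise_sigma = sigma, seed = seed))
    m <- compute_mpri(extract_tsi(ph$rest, masks, state = "rest"),
                      extract_tsi(ph$stress, masks, state = "stress"))
    expect_lt(abs(m$global_mpri - 2) / 2, 0.05)
  }
})

test_that("registration brings the motion-corrupted MPRI closer to truth", {
  spec0 <- small_spec()
  masks <- lapply(generate_phantom(spec0)$contours, segment_aha16,
                  grid = c(spec0$nrow, spec0$ncol))
  improved <- vapply(1:20, function(seed) {
    ph <- generate_phantom(small_spec(motion_amplitude = 3L, seed = seed))
    mpri_of <- function(rest, stress) {
      compute_mpri(extract_tsi(rest, masks, state = "rest"),
                   extract_tsi(stress, masks, state = "stress"))$global_mpri
    }
    before <- abs(mpri_of(ph$rest, ph$stress) - 2)
    after <- abs(mpri_of(register_frames(ph$rest)$series,
                         register_frames(ph$stress)$series) - 2)
    after < before
  }, logical(1))
  expect_gte(mean(improved), 0.9)
})
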