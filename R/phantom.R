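#' Gamma-variate arterial input function parameters
#'
#' Parameters of the amplitude-normalised gamma-variate bolus model used as
#' the synthetic blood-pool (arterial input) curve. The normalisation is such
#' that the curve peaks exactly at `s0 + amplitude` at time `t0 + alpha*beta`.
#'
#' @param amplitude Peak enhancement above baseline (au), >= 0.
#' @param t0 Bolus arrival time (s), >= 0.
#' @param alpha Shape parameter (dimensionless), > 0.
#' @param beta Timescale parameter (s), > 0.
#' @param s0 Pre-contrast baseline signal of the blood pool (au).
#' @return An object of class `aif_params`.
#' @export
#' @examples
#' p <- aif_params(amplitude = 100, t0 = 8, alpha = 3, beta = 2, s0 = 50)
#' aif_gamma_variate(c(0, 14), p)  # baseline and peak
aif_params <- function(amplitude = 100, t0 = 8, alpha = 3, beta = 2, s0 = 50) {
  if (!is.numeric(alpha) || alpha <= 0) stop("aif_params: 'alpha' must be > 0")
  if (!is.numeric(beta) || beta <= 0) stop("aif_params: 'beta' must be > 0")
  if (t0 < 0) stop("aif_params: 't0' must be >= 0")
  if (amplitude < 0) stop("aif_params: 'amplitude' must be >= 0")
  structure(list(amplitude = amplitude, t0 = t0, alpha = alpha,
                 beta = beta, s0 = s0), class = "aif_params")
}

#' Evaluate a gamma-variate arterial input function
#'
#' Amplitude-normalised gamma-variate bolus curve:
#' `s0 + A * ((t - t0)/(alpha*beta))^alpha * exp(alpha - (t - t0)/beta)` for
#' `t > t0`, and `s0` before bolus arrival. The peak value `s0 + A` occurs at
#' `t = t0 + alpha*beta`.
#'
#' @param t Numeric vector of sample times (s), non-decreasing.
#' @param p An [aif_params()] object.
#' @return Numeric vector of signal intensities (au), same length as `t`.
#' @export
aif_gamma_variate <- function(t, p) {
  stopifnot(inherits(p, "aif_params"))
  if (is.unsorted(t)) stop("aif_gamma_variate: 't' must be non-decreasing")
  s <- rep(p$s0, length(t))
  post <- t > p$t0
  if (any(post)) {
    tau <- t[post] - p$t0
    s[post] <- p$s0 + p$amplitude *
      (tau / (p$alpha * p$beta))^p$alpha * exp(p$alpha - tau / p$beta)
  }
  s
}

#' Simulated myocardial tissue enhancement curve
#'
#' Pure-uptake (no washout) compartment model for the first-pass window: the
#' tissue signal is the baseline plus the flow-scaled running integral of the
#' arterial input above its baseline,
#' `S(t_m) = s0_myo + F * dt * sum_{j<=m} (aif_j - s0_blood)`.
#' Its steepest frame-to-frame slope is `F * max(aif - s0_blood)`, so the
#' relative upslope is proportional to the uptake rate `F` and, with the same
#' AIF shape at rest and stress, the true MPRI equals `F_stress / F_rest`.
#'
#' @param aif Numeric vector, blood-pool signal per frame (au).
#' @param flow Uptake-rate scalar `F` (dimensionless), > 0.
#' @param dt Frame interval (s).
#' @param s0_myo Myocardial baseline signal (au).
#' @param s0_blood Blood-pool baseline subtracted from `aif` (au).
#' @return Numeric vector of tissue signal per frame (au).
#' @export
tissue_curve <- function(aif, flow, dt, s0_myo, s0_blood) {
  if (flow <= 0) stop("tissue_curve: 'flow' must be > 0")
  s0_myo + flow * dt * cumsum(aif - s0_blood)
}

#' Specification of a synthetic first-pass perfusion phantom
#'
#' Bundles every parameter of the rest/stress phantom pair: image grid,
#' annulus geometry at the three short-axis levels (base, mid, apex), frame
#' timing, rest and stress arterial input functions, per-segment uptake rates
#' (16 AHA segments), noise, rigid in-plane motion, and the random seed.
#'
#' Perfusion deficits are expressed through the flow vectors: a reversible
#' deficit is a reduced `f_stress` entry only; a fixed deficit reduces the
#' segment's flow in both states.
#'
#' @param nrow,ncol Grid size in pixels.
#' @param spacing In-plane pixel spacing (mm).
#' @param dt Frame interval (s).
#' @param n_frames Number of dynamic frames.
#' @param n_baseline Number of pre-contrast baseline frames (< `n_frames`).
#' @param center LV centre in 0-based pixel coordinates `c(x, y)`.
#' @param endo_radius,epi_radius Endocardial / epicardial radius (mm) at the
#'   basal and mid levels; the apical annulus is scaled by `apex_scale`.
#' @param apex_scale Apical radius scale factor (default 0.7).
#' @param rv_angle Angle (degrees) from the LV centre to the RV-insertion
#'   landmark, in the x-right / y-down pixel frame.
#' @param aif_rest,aif_stress [aif_params()] for each state.
#' @param f_rest,f_stress Length-16 vectors of per-segment uptake rates, > 0.
#' @param s0_myo Myocardial baseline signal (au).
#' @param noise_sigma Additive Gaussian noise SD (au).
#' @param motion_amplitude Maximum in-plane random-walk shift (pixels,
#'   integer); 0 disables motion.
#' @param dark_rim If `TRUE`, inject a one-pixel subendocardial dark-rim
#'   artifact (80% of tissue enhancement during bolus transit, both states).
#' @param lge_flags Length-16 logical vector of late-gadolinium-enhancement
#'   flags carried through to defect classification.
#' @param seed Integer seed driving noise and motion.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(nrow = 64, ncol = 64, spacing = 1, dt = 1,
                         n_frames = 60, n_baseline = 5,
                         center = c(31.5, 31.5),
                         endo_radius = 10, epi_radius = 16, apex_scale = 0.7,
                         rv_angle = 120,
                         aif_rest = aif_params(),
                         aif_stress = aif_params(),
                         f_rest = rep(0.1, 16), f_stress = rep(0.2, 16),
                         s0_myo = 20, noise_sigma = 1,
                         motion_amplitude = 0L, dark_rim = FALSE,
                         lge_flags = rep(FALSE, 16), seed = 1L) {
  if (n_baseline >= n_frames)
    stop("phantom_spec: 'n_baseline' must be < 'n_frames'")
  if (length(f_rest) != 16L || length(f_stress) != 16L)
    stop("phantom_spec: flow vectors must have length 16")
  if (any(f_rest <= 0) || any(f_stress <= 0))
    stop("phantom_spec: all uptake rates must be > 0")
  if (endo_radius >= epi_radius)
    stop("phantom_spec: 'endo_radius' must be < 'epi_radius'")
  if (length(lge_flags) != 16L)
    stop("phantom_spec: 'lge_flags' must have length 16")
  structure(list(nrow = nrow, ncol = ncol, spacing = spacing, dt = dt,
                 n_frames = as.integer(n_frames),
                 n_baseline = as.integer(n_baseline),
                 center = center, endo_radius = endo_radius,
                 epi_radius = epi_radius, apex_scale = apex_scale,
                 rv_angle = rv_angle, aif_rest = aif_rest,
                 aif_stress = aif_stress, f_rest = f_rest,
                 f_stress = f_stress, s0_myo = s0_myo,
                 noise_sigma = noise_sigma,
                 motion_amplitude = as.integer(motion_amplitude),
                 dark_rim = isTRUE(dark_rim), lge_flags = lge_flags,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# circle polygon in 0-based pixel coordinates, closed implicitly
.circle_polygon <- function(center, radius_px, n_vertices = 128L) {
  th <- 2 * pi * seq(0L, n_vertices - 1L) / n_vertices
  cbind(x = center[1] + radius_px * cos(th),
        y = center[2] + radius_px * sin(th))
}

.phantom_contours <- function(spec) {
  levels <- c("base", "mid", "apex")
  scale <- c(base = 1, mid = 1, apex = spec$apex_scale)
  rv_rad <- spec$rv_angle * pi / 180
  lapply(levels, function(lv) {
    endo_px <- spec$endo_radius * scale[[lv]] / spec$spacing
    epi_px <- spec$epi_radius * scale[[lv]] / spec$spacing
    rv_r <- spec$epi_radius / spec$spacing + 3
    slice_contours(
      level = lv,
      endo = .circle_polygon(spec$center, endo_px),
      epi = .circle_polygon(spec$center, epi_px),
      rv_insertion = c(spec$center[1] + rv_r * cos(rv_rad),
                       spec$center[2] + rv_r * sin(rv_rad)))
  })
}

# integer random-walk shifts clipped to +/- amplitude; first frame unshifted
.random_walk_shifts <- function(n_frames, amplitude) {
  s <- matrix(0L, nrow = n_frames, ncol = 2,
              dimnames = list(NULL, c("dx", "dy")))
  if (amplitude > 0L) {
    for (f in 2:n_frames) {
      step <- sample(c(-1L, 0L, 1L), 2, replace = TRUE)
      s[f, ] <- pmin(pmax(s[f - 1, ] + step, -amplitude), amplitude)
    }
  }
  s
}

# one state's clean 4D stack from per-slice label masks and per-label curves
.render_state <- function(spec, masks, aif, flows) {
  nt <- spec$n_frames
  arr <- array(0, dim = c(spec$nrow, spec$ncol, length(masks), nt))
  for (s in seq_along(masks)) {
    m <- masks[[s]]
    labs <- sort(unique(m$labels[m$labels > 0L]))
    npix <- spec$nrow * spec$ncol
    sl <- matrix(0, nrow = npix, ncol = nt)
    for (lab in labs) {
      idx <- which(m$labels == lab)
      sl[idx, ] <- rep(tissue_curve(aif, flows[lab], spec$dt,
                                    spec$s0_myo, spec$aif_rest$s0),
                       each = length(idx))
    }
    lum <- which(m$lumen)
    sl[lum, ] <- rep(aif, each = length(lum))
    if (spec$dark_rim && any(m$rim)) {
      transit <- aif - aif[1] > 0.05 * max(aif - aif[1])
      rim_idx <- which(m$rim)
      for (f in which(transit)) {
        v <- sl[rim_idx, f]
        sl[rim_idx, f] <- spec$s0_myo + 0.8 * (v - spec$s0_myo)
      }
    }
    arr[, , s, ] <- sl
  }
  arr
}

.apply_shifts <- function(arr, shifts) {
  out <- array(0, dim = dim(arr))
  for (f in seq_len(dim(arr)[4])) {
    for (s in seq_len(dim(arr)[3])) {
      out[, , s, f] <- shift_image(arr[, , s, f], shifts[f, 1], shifts[f, 2])
    }
  }
  out
}

#' Generate a synthetic rest/stress first-pass perfusion phantom
#'
#' Builds a pair of 4D dynamic series (frames of three short-axis slices) in
#' which each AHA segment's annulus sector follows its [tissue_curve()] with
#' the segment's uptake rate, the LV lumen follows the state's gamma-variate
#' AIF, and the background is zero. Gaussian noise and an integer random-walk
#' in-plane translation are optionally applied; both are driven by
#' `spec$seed` so output is fully reproducible. Contours are returned in the
#' unshifted geometry.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `perfusion_phantom`:
#'   \describe{
#'     \item{rest, stress}{[perfusion_series()] objects.}
#'     \item{contours}{List of three [slice_contours()] (base, mid, apex).}
#'     \item{truth}{Ground truth: the spec, per-segment `flow_ratio`
#'       (`f_stress / f_rest`), and applied per-frame `shifts_rest` /
#'       `shifts_stress` (pixels).}
#'   }
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(noise_sigma = 0))
#' dim(ph$rest$data)
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$epi_radius / spec$spacing + abs(spec$motion_amplitude) >
      min(spec$center[1], spec$center[2],
          spec$nrow - 1 - spec$center[1], spec$ncol - 1 - spec$center[2]))
    stop("generate_phantom: annulus (plus motion) exceeds the image grid")

  contours <- .phantom_contours(spec)
  grid <- c(spec$nrow, spec$ncol)
  masks <- lapply(contours, function(cs) {
    sm <- segment_aha16(cs, grid)
    lumen <- rasterize_polygon(cs$endo, grid)
    ann <- sm$labels > 0L
    # subendocardial one-pixel rim: annulus pixels adjacent to the lumen
    rim <- ann & .dilate_disk(lumen, 1.5)
    list(labels = sm$labels, lumen = lumen, rim = rim)
  })

  t <- (seq_len(spec$n_frames) - 1L) * spec$dt
  aif_r <- aif_gamma_variate(t, spec$aif_rest)
  aif_s <- aif_gamma_variate(t, spec$aif_stress)
  clean_rest <- .render_state(spec, masks, aif_r, spec$f_rest)
  clean_stress <- .render_state(spec, masks, aif_s, spec$f_stress)

  set.seed(spec$seed)
  shifts_rest <- .random_walk_shifts(spec$n_frames, spec$motion_amplitude)
  shifts_stress <- .random_walk_shifts(spec$n_frames, spec$motion_amplitude)
  rest <- .apply_shifts(clean_rest, shifts_rest)
  stress <- .apply_shifts(clean_stress, shifts_stress)
  if (spec$noise_sigma > 0) {
    rest <- rest + array(stats::rnorm(length(rest), 0, spec$noise_sigma),
                         dim = dim(rest))
    stress <- stress + array(stats::rnorm(length(stress), 0, spec$noise_sigma),
                             dim = dim(stress))
  }

  mk <- function(a) perfusion_series(a, dt = spec$dt,
                                     spacing = rep(spec$spacing, 2),
                                     n_baseline = spec$n_baseline)
  structure(list(
    rest = mk(rest), stress = mk(stress), contours = contours,
    truth = list(spec = spec,
                 flow_ratio = spec$f_stress / spec$f_rest,
                 shifts_rest = shifts_rest,
                 shifts_stress = shifts_stress)),
    class = "perfusion_phantom")
}

#' Write a phantom bundle to disk
#'
#' Writes one 4D NIfTI per state (dimension order x, y, slice, time; pixel
#' spacing and frame interval in the header), one contour JSON per slice,
#' and the ground truth as JSON.
#'
#' @param phantom A [generate_phantom()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "perfusion_phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    rest = write_perfusion_nifti(phantom$rest, file.path(dir, "rest.nii.gz")),
    stress = write_perfusion_nifti(phantom$stress,
                                   file.path(dir, "stress.nii.gz")))
  for (cs in phantom$contours) {
    p <- file.path(dir, paste0("contours_", cs$level, ".json"))
    write_contours_json(cs, p)
    paths[paste0("contours_", cs$level)] <- p
  }
  tr <- phantom$truth
  truth <- list(
    flow_ratio = tr$flow_ratio,
    f_rest = tr$spec$f_rest, f_stress = tr$spec$f_stress,
    noise_sigma = tr$spec$noise_sigma,
    motion_amplitude = tr$spec$motion_amplitude,
    seed = tr$spec$seed,
    lge_flags = tr$spec$lge_flags,
    shifts_rest = tr$shifts_rest, shifts_stress = tr$shifts_stress)
  tp <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, tp, auto_unbox = TRUE, digits = NA)
  paths["truth"] <- tp
  invisible(paths)
}
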