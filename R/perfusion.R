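#' Translate an image by an integer pixel shift
#'
#' Content moves by `(dx, dy)`; pixels shifted in from outside are zero.
#'
#' @param img Numeric matrix indexed `[x + 1, y + 1]`.
#' @param dx,dy Integer shift in pixels (x right, y down).
#' @return Shifted matrix of the same dimension.
#' @export
shift_image <- function(img, dx, dy) {
  out <- matrix(0, nrow(img), ncol(img))
  src_x <- seq_len(nrow(img)) - dx
  src_y <- seq_len(ncol(img)) - dy
  ok_x <- src_x >= 1 & src_x <= nrow(img)
  ok_y <- src_y >= 1 & src_y <= ncol(img)
  out[ok_x, ok_y] <- img[src_x[ok_x], src_y[ok_y]]
  out
}

#' Rigid integer-shift registration of a dynamic series
#'
#' Emulates the effect of motion-corrected reconstruction on the dynamic
#' stack: every frame is translated by the integer in-plane shift that
#' maximises its cross-correlation (sum of products over all slices) with a
#' reference frame, searching a bounded window. Candidate shifts are ranked
#' by increasing magnitude so that, on ties, the smallest correction wins
#' and an already-aligned frame is left untouched.
#'
#' @param series A [perfusion_series()].
#' @param reference Reference frame index (default 1, a baseline frame).
#' @param max_shift Search half-width in pixels (default 5).
#' @return List with `series` (corrected copy) and `shifts`, an
#'   `n_frames x 2` integer matrix of applied corrections `(dx, dy)`.
#' @export
register_frames <- function(series, reference = 1L, max_shift = 5L) {
  stopifnot(inherits(series, "perfusion_series"))
  d <- dim(series$data)
  nt <- d[4]
  if (reference < 1L || reference > nt)
    stop("register_frames: reference frame index out of range")
  if (2L * max_shift + 1L > min(d[1], d[2]))
    stop("register_frames: search window larger than the image")

  cand <- expand.grid(dx = -max_shift:max_shift, dy = -max_shift:max_shift)
  cand <- cand[order(abs(cand$dx) + abs(cand$dy), cand$dx, cand$dy), ]
  ref <- series$data[, , , reference, drop = FALSE]
  dim(ref) <- d[1:3]

  out <- series$data
  shifts <- matrix(0L, nt, 2, dimnames = list(NULL, c("dx", "dy")))
  for (f in seq_len(nt)) {
    frame <- series$data[, , , f, drop = FALSE]
    dim(frame) <- d[1:3]
    best <- -Inf; best_k <- 1L
    for (k in seq_len(nrow(cand))) {
      dx <- cand$dx[k]; dy <- cand$dy[k]
      # overlap of frame shifted by (dx, dy) with the reference
      sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
      sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
      score <- sum(frame[sx - dx, sy - dy, ] * ref[sx, sy, ])
      if (score > best) { best <- score; best_k <- k }
    }
    dx <- cand$dx[best_k]; dy <- cand$dy[best_k]
    shifts[f, ] <- c(dx, dy)
    if (dx != 0L || dy != 0L)
      for (s in seq_len(d[3]))
        out[, , s, f] <- shift_image(series$data[, , s, f], dx, dy)
  }
  corrected <- series
  corrected$data <- out
  list(series = corrected, shifts = shifts)
}

#' Extract time-signal-intensity curves
#'
#' For every frame, the mean signal over each AHA segment label and over the
#' blood-pool ROI of the designated slice, yielding the per-state curve set
#' that upslope analysis consumes.
#'
#' @param series A [perfusion_series()].
#' @param masks List of [segment_aha16()] results, one per slice, in slice
#'   order.
#' @param blood_slice Index of the slice whose blood-pool ROI supplies the
#'   arterial curve (default: the `"mid"` slice if present, else 1).
#' @param state `"rest"` or `"stress"` (metadata only).
#' @return An object of class `tsi_curves`: `times` (s), `segments` (matrix
#'   `n_frames x n_segments`, columns named by AHA label), `blood_pool`
#'   (vector), `state`, `n_baseline`.
#' @export
extract_tsi <- function(series, masks, blood_slice = NULL, state = "rest") {
  stopifnot(inherits(series, "perfusion_series"))
  d <- dim(series$data)
  if (length(masks) != d[3])
    stop("extract_tsi: need one segment mask per slice")
  if (is.null(blood_slice)) {
    lv <- vapply(masks, function(m) m$level, character(1))
    blood_slice <- if ("mid" %in% lv) match("mid", lv) else 1L
  }
  nt <- d[4]
  flat <- series$data
  dim(flat) <- c(d[1] * d[2], d[3], nt)
  mean_curve <- function(idx, s) {
    m <- flat[idx, s, , drop = FALSE]
    dim(m) <- c(length(idx), nt)
    colMeans(m)
  }

  seg_curves <- list()
  for (s in seq_along(masks)) {
    m <- masks[[s]]
    if (any(dim(m$labels) != d[1:2]))
      stop("extract_tsi: mask grid does not match the image grid")
    for (lab in sort(unique(m$labels[m$labels > 0L]))) {
      idx <- which(m$labels == lab)
      if (length(idx) == 0L)
        stop("extract_tsi: empty mask for segment ", lab)
      seg_curves[[as.character(lab)]] <- mean_curve(idx, s)
    }
  }
  labs <- as.integer(names(seg_curves))
  bp_idx <- which(masks[[blood_slice]]$blood_pool)
  if (length(bp_idx) == 0L)
    stop("extract_tsi: empty blood-pool mask on slice ", blood_slice)
  bp <- mean_curve(bp_idx, blood_slice)

  segs <- do.call(cbind, seg_curves[order(labs)])
  colnames(segs) <- sort(labs)
  structure(list(state = state, times = series$times, segments = segs,
                 blood_pool = bp, n_baseline = series$n_baseline),
            class = "tsi_curves")
}

#' Baseline level and bolus-arrival detection
#'
#' Baseline is the mean of the first `n_baseline` frames; enhancement starts
#' at the first frame whose signal exceeds baseline plus three baseline SDs.
#' A zero-SD (noise-free) baseline falls back to an absolute tolerance of
#' 1 au.
#'
#' @param curve Numeric signal vector.
#' @param n_baseline Number of baseline frames (< length of curve).
#' @return List with `baseline` (au) and `onset` (frame index, 1-based).
#' @export
detect_baseline <- function(curve, n_baseline) {
  if (n_baseline >= length(curve))
    stop("detect_baseline: curve shorter than the baseline window")
  base <- curve[seq_len(n_baseline)]
  level <- mean(base)
  tol <- 3 * stats::sd(base)
  if (!is.finite(tol) || tol == 0) tol <- 1
  onset <- which(curve > level + tol)[1]
  if (is.na(onset))
    stop("detect_baseline: no enhancement above baseline (no bolus)")
  list(baseline = level, onset = onset)
}

#' Maximum upslope of a time-signal-intensity curve
#'
#' The steepest rate of signal increase (au/s): over every contiguous window
#' of `k` frames starting at or after the bolus-arrival frame and ending no
#' later than one frame past the curve's global peak, an ordinary
#' least-squares line is fitted to signal versus time; the maximum fitted
#' slope is returned (ties go to the earliest window).
#'
#' @param curve Numeric signal vector (au).
#' @param times Numeric frame times (s), same length.
#' @param k Window length in frames, >= 2 (default 3).
#' @param n_baseline Baseline frames for [detect_baseline()] (default 5).
#' @return An object of class `upslope_result`: `slope` (au/s), `window_start`
#'   (index), `k`, `baseline` (au), `onset` (index).
#' @export
max_upslope <- function(curve, times, k = 3L, n_baseline = 5L) {
  if (k < 2L) stop("max_upslope: window 'k' must be >= 2")
  if (length(curve) != length(times))
    stop("max_upslope: 'curve' and 'times' lengths differ")
  bl <- detect_baseline(curve, n_baseline)
  peak <- which.max(curve)
  last_end <- min(peak + 1L, length(curve))
  if (last_end - k + 1L < bl$onset)
    stop("max_upslope: fewer than ", k, " admissible frames for the window")
  starts <- seq.int(bl$onset, last_end - k + 1L)
  best <- -Inf; best_start <- starts[1]
  for (i in starts) {
    idx <- i:(i + k - 1L)
    tt <- times[idx]; ss <- curve[idx]
    slope <- sum((tt - mean(tt)) * (ss - mean(ss))) / sum((tt - mean(tt))^2)
    if (slope > best + 1e-12) { best <- slope; best_start <- i }
  }
  structure(list(slope = best, window_start = best_start, k = as.integer(k),
                 baseline = bl$baseline, onset = bl$onset),
            class = "upslope_result")
}

#' Relative upslope
#'
#' Segment maximum upslope divided by the blood-pool maximum upslope; the
#' normalisation removes the dependence on bolus amplitude and shape.
#'
#' @param segment,blood_pool [max_upslope()] results (or bare slopes).
#' @return Dimensionless ratio.
#' @export
relative_upslope <- function(segment, blood_pool) {
  s <- if (inherits(segment, "upslope_result")) segment$slope else segment
  b <- if (inherits(blood_pool, "upslope_result")) blood_pool$slope else blood_pool
  if (b <= 0)
    stop("relative_upslope: blood-pool upslope must be > 0 (degenerate AIF)")
  s / b
}

.aha_level <- function(seg) {
  ifelse(seg <= 6, "basal", ifelse(seg <= 12, "mid", "apical"))
}

#' Myocardial perfusion reserve index (MPRI)
#'
#' Per segment, MPRI is the ratio of the stress to the rest relative
#' upslope. Level means are taken over basal (1-6), mid (7-12) and apical
#' (13-16) segments; the global MPRI is the arithmetic mean over all
#' available segments.
#'
#' @param rest,stress [extract_tsi()] curve sets for the two states, with
#'   identical segment sets.
#' @param k Upslope window length in frames (default 3).
#' @return An object of class `mpri_result`: `segments` (data.frame with
#'   columns segment, level, relupslope_rest, relupslope_stress, mpri),
#'   `level_means` (named numeric: basal, mid, apical), `global_mpri`,
#'   `n_segments`.
#' @export
compute_mpri <- function(rest, stress, k = 3L) {
  stopifnot(inherits(rest, "tsi_curves"), inherits(stress, "tsi_curves"))
  segs <- colnames(rest$segments)
  if (!identical(segs, colnames(stress$segments)))
    stop("compute_mpri: rest and stress segment sets differ")

  rel_state <- function(tsi) {
    bp <- max_upslope(tsi$blood_pool, tsi$times, k, tsi$n_baseline)
    vapply(segs, function(s) {
      up <- max_upslope(tsi$segments[, s], tsi$times, k, tsi$n_baseline)
      relative_upslope(up, bp)
    }, numeric(1))
  }
  rel_rest <- rel_state(rest)
  rel_stress <- rel_state(stress)
  if (any(rel_rest <= 0))
    stop("compute_mpri: non-positive rest relative upslope in segment ",
         paste(segs[rel_rest <= 0], collapse = ", "))
  mpri <- rel_stress / rel_rest

  seg_id <- as.integer(segs)
  lev <- .aha_level(seg_id)
  df <- data.frame(segment = seg_id, level = lev,
                   relupslope_rest = unname(rel_rest),
                   relupslope_stress = unname(rel_stress),
                   mpri = unname(mpri))
  level_means <- vapply(c("basal", "mid", "apical"),
                        function(l) mean(df$mpri[df$level == l]), numeric(1))
  structure(list(segments = df, level_means = level_means,
                 global_mpri = mean(df$mpri), n_segments = nrow(df)),
            class = "mpri_result")
}

#' @export
print.mpri_result <- function(x, ...) {
  cat("MPRI result over", x$n_segments, "AHA segments\n")
  cat(sprintf("  global MPRI: %.3f\n", x$global_mpri))
  cat(sprintf("  level means: basal %.3f  mid %.3f  apical %.3f\n",
              x$level_means["basal"], x$level_means["mid"],
              x$level_means["apical"]))
  invisible(x)
}

#' Classify a perfusion defect
#'
#' Decision table combining the stress and rest deficit calls with late
#' gadolinium enhancement (LGE): a deficit at stress only is a reversible
#' (inducible) defect; at both states it is a fixed defect when LGE is
#' present in the territory and an artifact when it is not; no deficit at
#' stress with none at rest is normal. A rest-only deficit has no defined
#' physiological reading and is reported as an artifact.
#'
#' @param stress_deficit,rest_deficit,lge Logical vectors (recycled).
#' @return Character vector: `"normal"`, `"artifact"`, `"fixed"` or
#'   `"reversible"`.
#' @export
classify_defect <- function(stress_deficit, rest_deficit, lge) {
  n <- max(length(stress_deficit), length(rest_deficit), length(lge))
  s <- rep_len(as.logical(stress_deficit), n)
  r <- rep_len(as.logical(rest_deficit), n)
  g <- rep_len(as.logical(lge), n)
  out <- character(n)
  out[s & r & g] <- "fixed"
  out[s & r & !g] <- "artifact"
  out[s & !r] <- "reversible"
  out[!s & !r] <- "normal"
  out[!s & r] <- "artifact"
  out
}

#' Flag hypoperfused segments within one state
#'
#' Automated surrogate for the visual deficit call: a segment is flagged
#' when its relative upslope falls below `threshold` times the median
#' relative upslope of all segments in that state.
#'
#' @param rel_upslopes Named numeric vector of per-segment relative upslopes.
#' @param threshold Fraction of the median (default 0.75), in (0, 1).
#' @return Logical vector parallel to `rel_upslopes`.
#' @export
flag_deficit_segments <- function(rel_upslopes, threshold = 0.75) {
  if (threshold <= 0 || threshold >= 1)
    stop("flag_deficit_segments: 'threshold' must be in (0, 1)")
  rel_upslopes < threshold * stats::median(rel_upslopes)
}
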