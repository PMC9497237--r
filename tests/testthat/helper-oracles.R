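# Independent oracles used across the suite; deliberately written as plain
# loops / calls to reference implementations, not via the package's own code.

# point-in-polygon oracle via mgcv::in.out on a closed boundary loop
oracle_inside <- function(px, py, poly) {
  bnd <- rbind(poly, poly[1, , drop = FALSE])
  mgcv::in.out(bnd, cbind(px, py))
}

# OLS slope oracle via lm()
oracle_slope <- function(t, s) unname(stats::coef(stats::lm(s ~ t))[2])

# exhaustive window enumeration oracle for the maximum upslope: replicates
# the admissible-window definition directly, fitting each window with lm()
oracle_max_upslope <- function(curve, times, k, n_baseline) {
  base <- curve[seq_len(n_baseline)]
  tol <- 3 * stats::sd(base)
  if (!is.finite(tol) || tol == 0) tol <- 1
  onset <- which(curve > mean(base) + tol)[1]
  last_end <- min(which.max(curve) + 1L, length(curve))
  slopes <- sapply(onset:(last_end - k + 1L), function(i) {
    idx <- i:(i + k - 1L)
    oracle_slope(times[idx], curve[idx])
  })
  max(slopes)
}

# two-sided permutation p-value oracle for the rank-sum statistic
oracle_wilcoxon_p <- function(x, y) {
  nx <- length(x)
  rk <- rank(c(x, y))
  w_obs <- sum(rk[seq_len(nx)])
  mu <- nx * (length(rk) + 1) / 2
  combos <- utils::combn(length(rk), nx)
  w_all <- apply(combos, 2, function(i) sum(rk[i]))
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# random star-shaped endo/epi contour pair with an RV-insertion landmark;
# guaranteed valid (endo strictly inside epi) on a 64x64 grid
random_contours <- function(level = "mid", n_vertices = 72) {
  ctr <- c(runif(1, 28, 36), runif(1, 28, 36))
  th <- 2 * pi * seq(0, n_vertices - 1) / n_vertices
  r_endo <- runif(1, 6, 9)
  wob <- runif(1, 0, 0.12)
  ph <- runif(1, 0, 2 * pi)
  re <- r_endo * (1 + wob * sin(2 * th + ph))
  ring <- runif(1, 4, 7)
  rp <- re + ring
  rv_ang <- runif(1, 0, 2 * pi)
  slice_contours(
    level = level,
    endo = cbind(ctr[1] + re * cos(th), ctr[2] + re * sin(th)),
    epi = cbind(ctr[1] + rp * cos(th), ctr[2] + rp * sin(th)),
    rv_insertion = c(ctr[1] + (max(rp) + 3) * cos(rv_ang),
                     ctr[2] + (max(rp) + 3) * sin(rv_ang)))
}

# smaller, faster phantom for unit tests (defaults still 3 slices, 16 segs)
small_spec <- function(...) {
  args <- list(nrow = 48, ncol = 48, center = c(23.5, 23.5),
               endo_radius = 8, epi_radius = 13, n_frames = 40,
               noise_sigma = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(phantom_spec, args)
}

phantom_mpri <- function(ph, k = 3L) {
  masks <- lapply(ph$contours, segment_aha16, grid = dim(ph$rest$data)[1:2])
  compute_mpri(extract_tsi(ph$rest, masks, state = "rest"),
               extract_tsi(ph$stress, masks, state = "stress"), k = k)
}
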