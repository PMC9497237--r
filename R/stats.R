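#' Descriptive summary of one group
#'
#' @param x Numeric vector.
#' @param label Group label.
#' @return List with `label`, `n`, `mean`, `sd`, `median`, `iqr`
#'   (`c(q1, q3)`, type-7 quantiles).
#' @export
group_summary <- function(x, label = "") {
  x <- x[!is.na(x)]
  if (length(x) < 1L) stop("group_summary: need at least one observation")
  q <- unname(stats::quantile(x, c(0.25, 0.75)))
  list(label = label, n = length(x), mean = mean(x), sd = stats::sd(x),
       median = stats::median(x), iqr = q)
}

#' Welch two-sample t-test from raw samples or summaries
#'
#' Unpaired t-test with the Welch-Satterthwaite degrees of freedom, computed
#' from group means, SDs and sizes; raw samples are reduced to those
#' summaries first. Two-sided p-value.
#'
#' @param x,y Raw samples (ignored when summaries are given).
#' @param summary_x,summary_y Optional named vectors/lists with elements
#'   `mean`, `sd`, `n`.
#' @return List with `t`, `df`, `p`, and the two summaries used.
#' @export
#' @examples
#' welch_ttest(summary_x = c(mean = 0.75, sd = 0.22, n = 16),
#'             summary_y = c(mean = 0.92, sd = 0.23, n = 18))
welch_ttest <- function(x = NULL, y = NULL,
                        summary_x = NULL, summary_y = NULL) {
  reduce <- function(v, s, who) {
    if (!is.null(s)) {
      s <- as.list(s)
      c(mean = as.numeric(s$mean), sd = as.numeric(s$sd), n = as.numeric(s$n))
    } else {
      if (length(v) < 2L)
        stop("welch_ttest: group ", who, " needs n >= 2")
      c(mean = mean(v), sd = stats::sd(v), n = length(v))
    }
  }
  a <- reduce(x, summary_x, "x")
  b <- reduce(y, summary_y, "y")
  if (a["n"] < 2 || b["n"] < 2)
    stop("welch_ttest: both groups need n >= 2")
  if (a["sd"] <= 0 && b["sd"] <= 0)
    stop("welch_ttest: at least one group must have positive SD")
  se2 <- a["sd"]^2 / a["n"] + b["sd"]^2 / b["n"]
  t_stat <- (a["mean"] - b["mean"]) / sqrt(se2)
  df <- se2^2 / (a["sd"]^4 / (a["n"]^2 * (a["n"] - 1)) +
                 b["sd"]^4 / (b["n"]^2 * (b["n"] - 1)))
  p <- 2 * stats::pt(-abs(t_stat), df)
  list(t = unname(t_stat), df = unname(df), p = unname(p),
       summary_x = a, summary_y = b)
}

# distribution of doubled-midrank subset sums over all size-m subsets,
# by dynamic programming: counts[j+1, s+1] = #subsets of size j summing to s
.ranksum_counts <- function(r2, m) {
  smax <- sum(r2)
  counts <- matrix(0, nrow = m + 1L, ncol = smax + 1L)
  counts[1, 1] <- 1
  for (r in r2) {
    jmax <- m
    for (j in jmax:1) {
      nz <- which(counts[j, ] > 0)
      if (length(nz))
        counts[j + 1L, nz + r] <- counts[j + 1L, nz + r] + counts[j, nz]
    }
  }
  counts[m + 1L, ]
}

#' Wilcoxon rank-sum test
#'
#' Rank-sum statistic with midrank ties. For total n <= `exact_limit` the
#' two-sided p-value is exact over the full permutation distribution of the
#' rank sum (computed by a subset-sum recursion over doubled midranks, so
#' ties are handled exactly); larger samples use the normal approximation
#' with the usual tie-corrected variance (no continuity correction).
#'
#' @param x,y Numeric samples, each non-empty.
#' @param exact_limit Largest `n_x + n_y` for the exact branch (default 20).
#' @return List with `W` (rank sum of `x`), `U`, `p`, `method`
#'   (`"exact"` or `"normal"`).
#' @export
wilcoxon_rank_sum <- function(x, y, exact_limit = 20L) {
  nx <- length(x); ny <- length(y); n <- nx + ny
  if (nx < 1L || ny < 1L)
    stop("wilcoxon_rank_sum: both samples must be non-empty")
  all_v <- c(x, y)
  if (length(unique(all_v)) == 1L)
    stop("wilcoxon_rank_sum: all values identical in both groups (degenerate)")
  rk <- rank(all_v)
  w <- sum(rk[seq_len(nx)])
  u <- w - nx * (nx + 1) / 2
  mu <- nx * (n + 1) / 2

  if (n <= exact_limit) {
    r2 <- as.integer(round(2 * rk))
    counts <- .ranksum_counts(r2, nx)
    s_vals <- seq_along(counts) - 1L
    dev_obs <- abs(round(2 * w) - round(2 * mu))
    p <- sum(counts[abs(s_vals - 2 * mu) >= dev_obs]) / choose(n, nx)
    method <- "exact"
  } else {
    ties <- table(all_v)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (w - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(W = w, U = u, p = min(p, 1), method = method)
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = x - y`: bias is their mean, limits of agreement are
#' `bias +/- 1.96 * SD(d)` (sample SD), and the coefficient of variation is
#' the within-subject SD, `SD(d)/sqrt(2)`, expressed as a percentage of the
#' grand mean of all measurements.
#'
#' @param x,y Paired measurements (e.g. two observers), equal length.
#' @return An object of class `bland_altman`: `n`, `bias`, `sd_diff`,
#'   `loa` (`c(lower, upper)`), `cov_pct`, plus `means` and `diffs` for
#'   plotting.
#' @export
bland_altman <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L)
    stop("bland_altman: need at least 2 complete pairs")
  d <- x - y
  bias <- mean(d)
  sdd <- stats::sd(d)
  loa <- bias + c(-1, 1) * 1.96 * sdd
  grand <- mean(c(x, y))
  cov_pct <- 100 * (sdd / sqrt(2)) / grand
  structure(list(n = length(x), bias = bias, sd_diff = sdd, loa = loa,
                 cov_pct = cov_pct, means = (x + y) / 2, diffs = d),
            class = "bland_altman")
}

#' Bland-Altman plot
#'
#' @param x A [bland_altman()] result.
#' @param main Plot title.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot_bland_altman <- function(x, main = "Bland-Altman", ...) {
  stopifnot(inherits(x, "bland_altman"))
  graphics::plot(x$means, x$diffs, xlab = "Mean of pair",
                 ylab = "Difference", main = main, ...)
  graphics::abline(h = x$bias, lty = 1)
  graphics::abline(h = x$loa, lty = 2)
  invisible(x)
}

#' Intraclass correlation ICC(2,1): two-way random, absolute agreement
#'
#' Single-measurement ICC from the mean squares of the subjects-by-raters
#' two-way ANOVA, with the standard F-based 95% confidence interval.
#'
#' @param ratings Numeric matrix, subjects in rows, raters in columns, no
#'   missing cells.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `icc`, `ci` (`c(lower, upper)`), `n_subjects`,
#'   `n_raters`, and the ANOVA mean squares `msr`, `msc`, `mse`.
#' @export
icc_absolute <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 5L) stop("icc_absolute: need at least 5 subjects")
  if (k < 2L) stop("icc_absolute: need at least 2 raters")
  if (anyNA(ratings)) stop("icc_absolute: missing cells are not supported")

  df <- data.frame(value = as.vector(ratings),
                   subject = factor(rep(seq_len(n), times = k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(value ~ subject + rater, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]

  if (stats::var(rowMeans(ratings)) < .Machine$double.eps^0.75) {
    warning("icc_absolute: no between-subject variance; ICC set to 0")
    return(list(icc = 0, ci = c(NA_real_, NA_real_), n_subjects = n,
                n_raters = k, msr = msr, msc = msc, mse = mse))
  }

  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  # F-based CI (Shrout-Fleiss form for the two-way random, agreement ICC)
  alpha <- 1 - conf_level
  fj <- msc / mse
  vn <- (k - 1) * (n - 1) *
    (k * icc * fj + n * (1 + (k - 1) * icc) - k * icc)^2
  vd <- (n - 1) * k^2 * icc^2 * fj^2 +
    (n * (1 + (k - 1) * icc) - k * icc)^2
  v <- vn / vd
  f_u <- stats::qf(1 - alpha / 2, n - 1, v)
  f_l <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_u * mse) /
    (f_u * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_l * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_l * msr)
  list(icc = icc, ci = c(lower, upper), n_subjects = n, n_raters = k,
       msr = msr, msc = msc, mse = mse)
}

#' Percent change from baseline
#'
#' Per-subject percent rise `100 * (peak - baseline) / baseline`; summarise
#' a cohort with [group_summary()] (mean +/- SD convention).
#'
#' @param baseline,peak Numeric vectors (recycled), baseline > 0.
#' @return Numeric vector of percent changes.
#' @export
#' @examples
#' percent_change(100, 150)  # 50
percent_change <- function(baseline, peak) {
  if (any(baseline <= 0))
    stop("percent_change: 'baseline' must be > 0")
  100 * (peak - baseline) / baseline
}
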