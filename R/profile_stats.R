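#' Moments of a lag profile treated as a density over lags
#'
#' Normalises the profile rates to weights `w_k = rr_k / sum(rr)` and
#' computes weighted moments of the lag (in seconds): mean, dispersion
#' (weighted standard deviation), skewness and non-excess kurtosis
#' (`kurtosis = 3` for a Gaussian, `1.8` for a continuous uniform). Under
#' this reading, higher kurtosis and lower dispersion indicate recurrence
#' concentrated in a narrow band of lags — more punctual coordination. A
#' right-skewed profile (positive skewness, bulk of the mass at negative
#' lags with a tail toward positive ones) corresponds to a
#' participant-leading interaction; a left-skewed one to assistant leading.
#'
#' Moments are invariant to rescaling all rates by a positive constant.
#'
#' @param profile a [lag_profile()] (raw rates; normalisation for display
#'   does not change the moments).
#' @return An object of class `profile_shape` with fields `mean_lag`,
#'   `dispersion` (s), `skewness`, `kurtosis`, `peak_lag` (s), `peak_rr`.
#' @export
profile_moments <- function(profile) {
  stopifnot(inherits(profile, "lag_profile"))
  rr <- profile$rr
  if (any(rr < 0)) stop("profile rates must be non-negative")
  total <- sum(rr)
  if (total <= 0) stop("undefined shape: profile has zero total mass")
  w <- rr / total
  lag <- profile$lags_s
  mu <- sum(w * lag)
  v <- sum(w * (lag - mu)^2)
  sigma <- sqrt(v)
  if (sigma == 0) {
    skew <- kurt <- NA_real_
  } else {
    skew <- sum(w * (lag - mu)^3) / sigma^3
    kurt <- sum(w * (lag - mu)^4) / sigma^4
  }
  structure(list(mean_lag = mu, dispersion = sigma, skewness = skew,
                 kurtosis = kurt, peak_lag = peak_lag(profile),
                 peak_rr = max(rr)),
            class = "profile_shape")
}

#' @export
print.profile_shape <- function(x, ...) {
  cat("<profile_shape> peak ", signif(x$peak_rr, 4), " at ",
      signif(x$peak_lag, 4), " s; dispersion ", signif(x$dispersion, 4),
      " s, skewness ", signif(x$skewness, 4), ", kurtosis ",
      signif(x$kurtosis, 4), "\n", sep = "")
  invisible(x)
}

#' Lag of the profile maximum
#'
#' Returns the lag (seconds) at which the recurrence rate peaks. Ties are
#' broken toward the smallest absolute lag, and between `-l` and `+l` toward
#' the negative (participant-leading) lag; in particular a flat profile
#' yields 0 s.
#'
#' @param profile a [lag_profile()].
#' @return Peak lag in seconds.
#' @export
peak_lag <- function(profile) {
  stopifnot(inherits(profile, "lag_profile"))
  cand <- profile$lags_s[profile$rr == max(profile$rr)]
  cand[order(abs(cand), cand)][1]
}

#' Block means of a distance series or lag profile
#'
#' Averages consecutive non-overlapping blocks: a distance series is blocked
#' over time (e.g. 15-s blocks of the interaction) and a lag profile over
#' lags (e.g. 0.5-s lag bands). A trailing partial block is kept when it is
#' at least half full and dropped otherwise.
#'
#' @param x a `distance_series` or [lag_profile()].
#' @param block_s block length in seconds.
#' @param ... unused.
#' @return A data.frame with one row per block: `block_id`, `start_s`,
#'   `end_s` (half-open block extent), `n` (samples) and `mean`.
#' @export
block_means <- function(x, block_s, ...) UseMethod("block_means")

block_means_core <- function(values, positions_s, step_s, block_s) {
  if (block_s <= 0) stop("`block_s` must be positive")
  len <- as.integer(round(block_s / step_s))
  n <- length(values)
  if (len > n) {
    stop("block of ", block_s, " s (", len, " samples) is longer than the series (",
         n, " samples)")
  }
  n_full <- n %/% len
  rem <- n - n_full * len
  n_blocks <- n_full + (rem >= len / 2)
  idx <- lapply(seq_len(n_blocks), function(b) ((b - 1L) * len + 1L):min(n, b * len))
  data.frame(
    block_id = seq_len(n_blocks),
    start_s = vapply(idx, function(i) positions_s[i[1]], numeric(1)),
    end_s = vapply(idx, function(i) positions_s[i[length(i)]] + step_s, numeric(1)),
    n = lengths(idx),
    mean = vapply(idx, function(i) mean(values[i]), numeric(1))
  )
}

#' @rdname block_means
#' @export
block_means.distance_series <- function(x, block_s, ...) {
  block_means_core(x$values, (seq_along(x$values) - 1) / x$fps, 1 / x$fps, block_s)
}

#' @rdname block_means
#' @export
block_means.lag_profile <- function(x, block_s, ...) {
  block_means_core(x$rr, x$lags_s, 1 / x$fps, block_s)
}

#' @rdname block_means
#' @export
block_means.surrogate_profile <- function(x, block_s, ...) {
  block_means_core(x$mean_rr, x$lags_s, 1 / x$fps, block_s)
}

significance_flag <- function(p) {
  ifelse(p < 0.05, "significant", ifelse(p < 0.1, "trend", "ns"))
}

new_group_comparison <- function(statistic_name, statistic, p_value, extra) {
  structure(c(list(statistic_name = statistic_name, statistic = statistic,
                   p_value = p_value,
                   significance_flag = significance_flag(p_value)),
              extra),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> ", x$statistic_name, " = ", signif(x$statistic, 4),
      ", p = ", signif(x$p_value, 3), " (", x$significance_flag, ")\n", sep = "")
  invisible(x)
}

#' Mann-Whitney rank-sum test between two independent groups
#'
#' Rank-sum test with midranks for ties. Reports the U statistic of each
#' group (`u_a`, `u_b`; `statistic` is the smaller of the two, by
#' convention), per-group mean ranks, and a two-sided p-value: exact (via
#' the null rank-sum distribution) when `n1 * n2 <= 400` and the pooled
#' values have no ties, otherwise a normal approximation with tie
#' correction.
#'
#' @param group_a,group_b numeric vectors of per-dyad values.
#' @return A `group_comparison` with `statistic_name = "mann_whitney_u"`.
#' @export
mann_whitney <- function(group_a, group_b) {
  group_a <- as.numeric(group_a); group_b <- as.numeric(group_b)
  n1 <- length(group_a); n2 <- length(group_b)
  if (n1 < 1L || n2 < 1L) stop("both groups must be non-empty")
  pooled <- c(group_a, group_b)
  r <- rank(pooled)
  r1 <- sum(r[seq_len(n1)])
  u_a <- r1 - n1 * (n1 + 1) / 2
  u_b <- n1 * n2 - u_a
  ties <- table(pooled)
  has_ties <- any(ties > 1)
  u_min <- min(u_a, u_b)
  if (!has_ties && n1 * n2 <= 400) {
    p <- min(1, 2 * stats::pwilcox(u_min, n1, n2))
    z <- NA_real_
  } else {
    N <- n1 + n2
    tie_term <- sum(ties^3 - ties)
    sigma2 <- n1 * n2 / 12 * ((N^3 - N - tie_term) / (N * (N - 1)))
    if (sigma2 <= 0) stop("degenerate input: all pooled values identical")
    z <- (u_a - n1 * n2 / 2) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  new_group_comparison("mann_whitney_u", u_min, p, list(
    u_a = u_a, u_b = u_b, z = z, n1 = n1, n2 = n2,
    mean_rank_a = r1 / n1, mean_rank_b = (sum(r) - r1) / n2
  ))
}

#' Recover a group's U statistic from its rank sum
#'
#' For a two-group rank test with group size `n_group`, the Mann-Whitney
#' statistic of that group is its rank sum minus `n_group * (n_group + 1) / 2`.
#' Useful for reconstructing U from reported mean ranks.
#'
#' @param n_group size of the group.
#' @param mean_rank the group's mean rank over the pooled ranking.
#' @return The group's U statistic.
#' @export
u_from_mean_rank <- function(n_group, mean_rank) {
  n_group * mean_rank - n_group * (n_group + 1) / 2
}

#' Wilcoxon signed-rank test for paired values
#'
#' Paired test on `x - y`: zero differences are removed, absolute
#' differences are midranked, and the positive-rank sum is standardised with
#' the tie-corrected null variance to a Z statistic (positive Z means `x`
#' tends to exceed `y`); the p-value is two-sided via the normal
#' approximation.
#'
#' @param x,y equal-length numeric vectors of paired observations.
#' @return A `group_comparison` with
#'   `statistic_name = "wilcoxon_signed_rank_z"` and fields `w_plus`,
#'   `n_pairs` (after zero removal).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  d <- x - y
  d <- d[d != 0]
  m <- length(d)
  if (m < 2L) stop("degenerate input: fewer than 2 non-zero differences")
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  mu <- m * (m + 1) / 4
  ties <- table(abs(d))
  sigma2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
  if (sigma2 <= 0) stop("degenerate input: null variance is zero")
  z <- (w_plus - mu) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  new_group_comparison("wilcoxon_signed_rank_z", z, p,
                       list(w_plus = w_plus, n_pairs = m))
}

#' Blockwise rank tests across dyads
#'
#' Runs one nonparametric test per block (column) of a dyads-by-blocks value
#' matrix, flagging each at `p < 0.05` (significant) and `p < 0.1` (trend).
#' Two comparisons are supported:
#'
#' * `comparison = "group"`: unpaired high-vs-low rank-sum test
#'   ([mann_whitney()]) per block.
#' * `comparison = "surrogate"`: paired original-vs-surrogate signed-rank
#'   test ([wilcoxon_signed_rank()]) per block, within each group level
#'   (or across all dyads when `groups` is `NULL`).
#'
#' No multiple-testing correction is applied by default; an optional
#' Benjamini-Hochberg adjustment is available via `p_adjust = "BH"` (the
#' flags then use the adjusted p-values).
#'
#' @param block_values numeric matrix, one row per dyad, one column per
#'   block (e.g. from stacking [block_means()] output).
#' @param groups factor/character of group labels per dyad (two levels for
#'   `comparison = "group"`).
#' @param surrogate_values matrix of the same shape as `block_values` with
#'   the paired surrogate values (required for `comparison = "surrogate"`).
#' @param comparison `"group"` or `"surrogate"`.
#' @param block_ids optional block labels (defaults to column names or
#'   indices).
#' @param p_adjust `"none"` (default, mirroring the original reporting) or
#'   `"BH"`.
#' @return A data.frame with one row per test: `block_id`, `group` (for the
#'   surrogate comparison), `statistic_name`, `statistic`, `p_value`,
#'   `significance_flag`, and sample sizes.
#' @export
blockwise_group_test <- function(block_values, groups = NULL,
                                 surrogate_values = NULL,
                                 comparison = c("group", "surrogate"),
                                 block_ids = NULL,
                                 p_adjust = c("none", "BH")) {
  comparison <- match.arg(comparison)
  p_adjust <- match.arg(p_adjust)
  block_values <- as.matrix(block_values)
  if (is.null(block_ids)) {
    block_ids <- colnames(block_values)
    if (is.null(block_ids)) block_ids <- as.character(seq_len(ncol(block_values)))
  }
  rows <- list()
  if (comparison == "group") {
    if (is.null(groups)) stop("`groups` is required for the group comparison")
    groups <- factor(groups)
    if (nlevels(groups) != 2L) stop("`groups` must have exactly 2 levels")
    if (length(groups) != nrow(block_values)) {
      stop("`groups` length must match the number of dyads (rows)")
    }
    if (any(table(groups) < 2L)) stop("each group needs at least 2 dyads")
    lv <- levels(groups)
    for (b in seq_len(ncol(block_values))) {
      cmp <- mann_whitney(block_values[groups == lv[1], b],
                          block_values[groups == lv[2], b])
      rows[[length(rows) + 1L]] <- data.frame(
        block_id = block_ids[b], group = NA_character_,
        statistic_name = cmp$statistic_name, statistic = cmp$statistic,
        p_value = cmp$p_value, significance_flag = cmp$significance_flag,
        n1 = cmp$n1, n2 = cmp$n2)
    }
  } else {
    if (is.null(surrogate_values)) {
      stop("`surrogate_values` is required for the surrogate comparison")
    }
    surrogate_values <- as.matrix(surrogate_values)
    if (!identical(dim(surrogate_values), dim(block_values))) {
      stop("`surrogate_values` must match the shape of `block_values`")
    }
    grp <- if (is.null(groups)) factor(rep("all", nrow(block_values))) else factor(groups)
    if (length(grp) != nrow(block_values)) {
      stop("`groups` length must match the number of dyads (rows)")
    }
    if (any(table(grp) < 2L)) stop("each group needs at least 2 dyads")
    for (g in levels(grp)) {
      sel <- grp == g
      for (b in seq_len(ncol(block_values))) {
        cmp <- wilcoxon_signed_rank(block_values[sel, b],
                                    surrogate_values[sel, b])
        rows[[length(rows) + 1L]] <- data.frame(
          block_id = block_ids[b], group = g,
          statistic_name = cmp$statistic_name, statistic = cmp$statistic,
          p_value = cmp$p_value, significance_flag = cmp$significance_flag,
          n1 = cmp$n_pairs, n2 = cmp$n_pairs)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (p_adjust == "BH") {
    out$p_value <- stats::p.adjust(out$p_value, method = "BH")
    out$significance_flag <- significance_flag(out$p_value)
  }
  rownames(out) <- NULL
  out
}
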