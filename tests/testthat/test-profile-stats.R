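profile_of <- function(rr, fps = 30) {
  L <- (length(rr) - 1) / 2
  structure(list(lags_frames = (-L):L, lags_s = ((-L):L) / fps, rr = rr,
                 fps = fps, n = NA, normalized = FALSE),
            class = "lag_profile")
}

test_that("profile moments treat the profile as a density over lags", {
  # equal mass at -1 s and +1 s only
  rr <- numeric(61); rr[c(1, 61)] <- 0.5
  shape <- profile_moments(profile_of(rr))
  expect_equal(shape$mean_lag, 0)
  expect_equal(shape$dispersion, 1)
  expect_equal(shape$skewness, 0)
  expect_equal(shape$kurtosis, 1)

  # point mass: zero dispersion, shape undefined
  rr <- numeric(61); rr[10] <- 1
  shape <- profile_moments(profile_of(rr))
  expect_equal(shape$dispersion, 0)
  expect_true(is.na(shape$skewness) && is.na(shape$kurtosis))

  expect_error(profile_moments(profile_of(numeric(61))), "zero total mass")

  # continuous-uniform limit on [-3, 3]: non-excess kurtosis 9/5
  fine <- profile_of(rep(1, 2401), fps = 400)
  expect_lt(abs(profile_moments(fine)$kurtosis - 1.8), 0.018)
})

test_that("symmetric profiles have vanishing skewness", {
  set.seed(19)
  for (rep in 1:10) {
    half <- runif(30)
    rr <- c(half, runif(1), rev(half))
    expect_lt(abs(profile_moments(profile_of(rr))$skewness), 1e-12)
  }
})

test_that("moments are invariant to rescaling the rates", {
  set.seed(13)
  rr <- runif(181)
  a <- profile_moments(profile_of(rr))
  b <- profile_moments(profile_of(rr * 7.3))
  expect_equal(a$kurtosis, b$kurtosis)
  expect_equal(a$dispersion, b$dispersion)
  expect_equal(a$skewness, b$skewness)
})

test_that("peak lag uses the argmax with centre-preferring tie-breaks", {
  # argmax at a -360 ms bin (-11 frames at 30 fps)
  prof <- profile_of(rep(0.1, 181))
  prof$rr[prof$lags_frames == -11] <- 0.4
  expect_equal(peak_lag(prof), -11 / 30)

  flat <- profile_of(rep(0.3, 181))
  expect_equal(peak_lag(flat), 0)

  two <- profile_of(rep(0, 181))
  two$rr[two$lags_frames %in% c(-15, 15)] <- 1
  expect_equal(peak_lag(two), -0.5)

  # mirrored profile has the negated peak lag
  set.seed(2)
  sim <- simulate_dyad_categorical(sim_config(n_frames = 2000, lead_lag = 9,
                                              fidelity = 0.95, seed = 31))
  f <- lag_profile(sim$participant, sim$assistant)
  b <- lag_profile(sim$assistant, sim$participant)
  expect_equal(peak_lag(b), -peak_lag(f))
})

test_that("block means partition distance series and lag profiles", {
  d <- structure(list(values = rep(5, 900), fps = 30), class = "distance_series")
  bm <- block_means(d, 15)
  expect_equal(bm$mean, c(5, 5))
  expect_equal(bm$start_s, c(0, 15))
  expect_equal(bm$end_s, c(15, 30))

  # +/-3 s profile at 30 fps: 181 lags -> 12 full 0.5-s blocks; the single
  # trailing lag is under half a block and is dropped
  prof <- profile_of(seq(0, 1, length.out = 181))
  bp <- block_means(prof, 0.5)
  expect_equal(nrow(bp), 12)
  expect_equal(bp$n, rep(15, 12))
  expect_equal(bp$start_s[1], -3)
  expect_equal(bp$mean[1], mean(prof$rr[1:15]))

  short <- structure(list(values = rep(1, 100), fps = 30), class = "distance_series")
  expect_error(block_means(short, 15), "longer than the series")

  # trailing block kept when at least half full
  d2 <- structure(list(values = c(rep(1, 450), rep(3, 300)), fps = 30),
                  class = "distance_series")
  expect_equal(block_means(d2, 15)$mean, c(1, 3))
  d3 <- structure(list(values = c(rep(1, 450), rep(3, 100)), fps = 30),
                  class = "distance_series")
  expect_equal(block_means(d3, 15)$mean, 1)
})

test_that("rank-sum test reports U, mean ranks and a calibrated p-value", {
  sep <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$u_a, 0)       # complete separation
  expect_equal(sep$u_b, 9)
  expect_equal(sep$statistic, 0)
  expect_equal(sep$p_value, 0.1) # exact two-sided 2/20

  same <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$u_a, 4 * 4 / 2)
  expect_gt(same$p_value, 0.9)

  # U recovered from printed mean ranks: groups of 16 and 12 with pooled
  # mean ranks 11.50 and 18.50 give U = 144 for the smaller group
  expect_equal(u_from_mean_rank(12, 18.50), 144)
  expect_equal(u_from_mean_rank(16, 11.50), 16 * 12 - 144)

  set.seed(43)
  a <- rnorm(8); b <- rnorm(9)
  got <- mann_whitney(a, b)
  ref <- wilcox.test(a, b, exact = TRUE)
  expect_equal(got$statistic, min(ref$statistic, 72 - ref$statistic),
               ignore_attr = TRUE)
  expect_equal(got$p_value, ref$p.value)

  # tie-corrected normal approximation against the reference implementation
  a <- c(rep(1, 10), rep(2, 12), rnorm(8))
  b <- c(rep(1, 9), rep(2, 7), rnorm(9))
  got <- mann_whitney(a, b)
  ref <- wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(got$p_value, ref$p.value)

  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("rank-sum test invariances hold", {
  set.seed(47)
  for (rep in 1:10) {
    a <- rnorm(7); b <- rnorm(11)
    got <- mann_whitney(a, b)
    expect_equal(got$u_a + got$u_b, 7 * 11)
    mono <- mann_whitney(exp(a), exp(b))  # strictly monotone transform
    expect_equal(mono$u_a, got$u_a)
    expect_equal(mono$p_value, got$p_value)
  }
})

test_that("signed-rank test standardises the positive-rank sum", {
  a <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3)
  got <- wilcoxon_signed_rank(a + (1:10) / 10, a)
  # all 10 differences positive and distinct: W+ = 55, null mean 27.5,
  # null sd sqrt(n(n+1)(2n+1)/24) = sqrt(96.25)
  expect_equal(got$w_plus, 55)
  expect_equal(got$statistic, (55 - 27.5) / sqrt(10 * 11 * 21 / 24))
  expect_equal(got$n_pairs, 10)
  # with every |difference| tied, the tie-corrected null sd shrinks
  tied <- wilcoxon_signed_rank(a + 1, a)
  expect_equal(tied$statistic, 27.5 / sqrt(96.25 - (10^3 - 10) / 48))

  expect_error(wilcoxon_signed_rank(a, a), "degenerate")
  expect_error(wilcoxon_signed_rank(1:3, 1:4), "equal length")

  set.seed(53)
  x <- rnorm(20); y <- rnorm(20)
  got <- wilcoxon_signed_rank(x, y)
  ref <- wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = FALSE)
  expect_equal(got$p_value, ref$p.value)
})

test_that("signed-rank test holds its nominal size under the null", {
  set.seed(59)
  reps <- 2000
  rej <- mean(replicate(reps, {
    x <- rnorm(15); y <- rnorm(15)
    wilcoxon_signed_rank(x, y)$p_value < 0.05
  }))
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / reps) + 0.005)
})

test_that("blockwise tests flag planted separations and reject degenerate input", {
  set.seed(61)
  high <- matrix(rnorm(5 * 4, 100, 5), 5, 4)
  low <- matrix(rnorm(4 * 4, 200, 5), 4, 4)
  res <- blockwise_group_test(rbind(high, low),
                              groups = rep(c("high", "low"), c(5, 4)))
  expect_equal(nrow(res), 4)
  expect_true(all(res$significance_flag == "significant"))
  expect_true(all(res$p_value < 0.05))

  expect_error(blockwise_group_test(rbind(high[1, , drop = FALSE],
                                          low[1, , drop = FALSE]),
                                    groups = c("high", "low")),
               "at least 2 dyads")

  # paired original-vs-surrogate comparison
  orig <- matrix(rnorm(8 * 3, 0.5, 0.01), 8, 3)
  surr <- orig - 0.2
  res <- blockwise_group_test(orig, surrogate_values = surr,
                              comparison = "surrogate")
  expect_equal(nrow(res), 3)
  expect_true(all(res$statistic > 0))
  expect_true(all(res$p_value < 0.05))

  # flags are consistent with p-values
  expect_true(all((res$p_value < 0.05) == (res$significance_flag == "significant")))
})
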