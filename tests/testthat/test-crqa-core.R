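test_that("lag profile recovers identity and lagged copying", {
  set.seed(2)
  p <- rand_series(300)
  prof <- lag_profile(p, p, max_lag = 1)
  expect_equal(prof$rr[prof$lags_frames == 0], 1)

  # assistant mimics 5 frames later: a[t] = p[t - 5] => peak at lag -5
  sym <- as.character(p$symbols)
  a <- series_of(c(sample(c("LEFT", "RIGHT", "NONE"), 5, TRUE),
                   sym[1:295]))
  prof <- lag_profile(p, a, max_lag = 1)
  expect_equal(prof$lags_frames[which.max(prof$rr)], -5)
  expect_equal(max(prof$rr), 1)  # every valid comparison on that diagonal matches
  # and the whole profile equals the brute-force matrix enumeration
  naive <- naive_lag_profile(sym, as.character(a$symbols), 30)
  expect_equal(prof$rr, naive$rr)
})

test_that("independent series stay at the chance matching rate at every lag", {
  set.seed(8)
  p <- rand_series(9000)
  a <- rand_series(9000)
  prof <- lag_profile(p, a, max_lag = 3)
  tol <- 4 * sqrt((1 / 3) * (2 / 3) / 9000)
  expect_true(all(abs(prof$rr - 1 / 3) < tol))
})

test_that("lag profile validates its arguments", {
  p <- rand_series(50)
  expect_error(lag_profile(p, rand_series(49)), "length mismatch")
  expect_error(lag_profile(p, rand_series(50), max_lag = 2), "below the series length")
})

test_that("crqa measures match hand-enumerated small plots", {
  p <- series_of(c("LEFT", "RIGHT", "LEFT"))
  a <- series_of(c("LEFT", "LEFT", "RIGHT"))
  m <- crqa_measures(p, a)
  expect_equal(m$rr, 5 / 9)  # matches at (1,1),(1,2),(2,3),(3,1),(3,2)

  const <- series_of(rep("NONE", 3))
  m2 <- crqa_measures(const, const, lmin = 2)
  expect_equal(m2$rr, 1)
  # all-recurrent 3x3 plot: diagonals of length 1,2,3,2,1; those >= 2 average 7/3
  expect_equal(m2$mean_line, 7 / 3)
  expect_equal(m2$tt_v, 3)
  expect_equal(m2$cat_ent, 0)  # single 3x3 block

  # no two equal symbols anywhere: empty plot, measures 0 and flagged undefined
  m3 <- crqa_measures(series_of(c("LEFT", "LEFT")), series_of(c("RIGHT", "RIGHT")))
  expect_equal(m3$rr, 0)
  expect_equal(m3$mean_line, 0)
  expect_false(m3$lines_defined$mean_line)
  expect_false(m3$lines_defined$tt_v)
})

test_that("categorical entropy counts block areas", {
  # blocks (L:2)x(L:1)=2 and (R:1)x(R:2)=2: a single distinct area
  expect_equal(cat_entropy(series_of(c("LEFT", "LEFT", "RIGHT")),
                           series_of(c("LEFT", "RIGHT", "RIGHT"))), 0)
  # blocks of areas 4 and 1 with equal frequency
  expect_equal(cat_entropy(series_of(c("LEFT", "LEFT", "RIGHT")),
                           series_of(c("RIGHT", "LEFT", "LEFT"))), log(2))
  expect_equal(cat_entropy(series_of(rep("NONE", 5)), series_of(rep("NONE", 5))), 0)
  # min_area filters small blocks
  expect_equal(cat_entropy(series_of(c("LEFT", "LEFT", "RIGHT")),
                           series_of(c("RIGHT", "LEFT", "LEFT")), min_area = 2), 0)
})

test_that("production measures agree exactly with the full-matrix oracle", {
  set.seed(17)
  for (rep in 1:40) {
    n <- sample(5:50, 1)
    p <- rand_series(n)
    a <- rand_series(n)
    lmin <- sample(2:3, 1)
    got <- crqa_measures(p, a, lmin = lmin)
    want <- naive_crqa_measures(as.character(p$symbols), as.character(a$symbols),
                                lmin = lmin)
    expect_equal(got$rr, want$rr)
    expect_equal(got$mean_line, want$mean_line)
    expect_equal(got$tt_v, want$tt_v)
    expect_equal(got$tt_h, want$tt_h)
    expect_equal(got$cat_ent, want$cat_ent)
    L <- sample(1:(n - 1), 1)
    expect_equal(lag_profile(p, a, max_lag = L / p$fps)$rr,
                 naive_lag_profile(as.character(p$symbols),
                                   as.character(a$symbols), L)$rr)
  }
})

test_that("rr is the diagonal-count-weighted average of the lag profile", {
  set.seed(23)
  p <- rand_series(40)
  a <- rand_series(40)
  prof <- lag_profile(p, a, max_lag = 39 / 30)
  weights <- 40 - abs(prof$lags_frames)
  expect_equal(sum(weights * prof$rr) / 40^2, crqa_measures(p, a)$rr)
})

test_that("swapping the two series transposes the recurrence structure", {
  set.seed(29)
  p <- rand_series(60)
  a <- rand_series(60)
  f <- lag_profile(p, a, max_lag = 1)
  b <- lag_profile(a, p, max_lag = 1)
  expect_equal(f$rr, rev(b$rr))
  mf <- crqa_measures(p, a)
  mb <- crqa_measures(a, p)
  expect_equal(mf$rr, mb$rr)
  expect_equal(mf$cat_ent, mb$cat_ent)
  expect_equal(mf$mean_line, mb$mean_line)
  expect_equal(mf$tt_v, mb$tt_h)
  expect_equal(mf$tt_h, mb$tt_v)
})

test_that("shuffled surrogates behave as a chance baseline", {
  set.seed(31)
  p <- rand_series(400)
  # permutation-invariant input: constant assistant series
  const <- series_of(rep("NONE", 400))
  sur <- shuffle_baseline(p, const, max_lag = 0.5, n_shuffles = 5, seed = 1)
  expect_equal(sur$mean_rr, lag_profile(p, const, max_lag = 0.5)$rr)
  expect_equal(sur$sd_rr, rep(0, length(sur$sd_rr)))

  # determinism under a fixed seed, independence from the caller's RNG state
  sim <- simulate_dyad_categorical(sim_config(n_frames = 500, lead_lag = 5,
                                              fidelity = 0.9, seed = 4))
  s1 <- shuffle_baseline(sim$participant, sim$assistant, n_shuffles = 7, seed = 99)
  runif(3)
  s2 <- shuffle_baseline(sim$participant, sim$assistant, n_shuffles = 7, seed = 99)
  expect_identical(s1, s2)

  # coupling is destroyed by permutation
  sim <- simulate_dyad_categorical(sim_config(n_frames = 3000, lead_lag = 5,
                                              fidelity = 0.9, seed = 6))
  orig <- lag_profile(sim$participant, sim$assistant)
  sur <- shuffle_baseline(sim$participant, sim$assistant, n_shuffles = 20, seed = 2)
  expect_lt(max(sur$mean_rr), max(orig$rr))

  expect_error(shuffle_baseline(p, const, n_shuffles = 0), "at least 1")
})

test_that("surrogate mean profile of an independent pair is flat", {
  set.seed(37)
  p <- rand_series(2000)
  a <- rand_series(2000)
  sur <- shuffle_baseline(p, a, max_lag = 1, n_shuffles = 30, seed = 3)
  chance <- mean(lag_profile(p, a, max_lag = 1)$rr)
  # binomial sampling error at each lag, averaged over 30 shuffles
  tol <- 4 * sqrt((1 / 3) * (2 / 3) / 2000 / 30) + 0.01
  expect_true(all(abs(sur$mean_rr - chance) < tol))
})

test_that("profile normalisation is for display only", {
  set.seed(41)
  sim <- simulate_dyad_categorical(sim_config(n_frames = 600, seed = 9))
  prof <- lag_profile(sim$participant, sim$assistant)
  norm <- normalize_profile(prof)
  expect_true(norm$normalized)
  expect_equal(range(norm$rr), c(0, 1))
  expect_equal(which.max(norm$rr), which.max(prof$rr))
})
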