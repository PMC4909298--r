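test_that("intercept-only penalized estimate equals (y+1/2)/(n+1) exactly", {
  for (n in c(1, 2, 5, 10, 25, 50)) {
    for (y in unique(c(0, 1, floor(n / 2), n))) {
      f <- firth_logistic_fit(rep(0, n), c(rep(1, y), rep(0, n - y)))
      expect_identical(f$intercept_only, TRUE)
      expect_equal(plogis(f$beta0), (y + 0.5) / (n + 1), tolerance = 1e-14)
      expect_equal(f$beta1, 0)
      expect_equal(f$vcov[2, 2], 0)
      p <- (y + 0.5) / (n + 1)
      expect_equal(f$vcov[1, 1], 1 / (n * p * (1 - p)), tolerance = 1e-14)
    }
  }
  # symmetry: y = n/2 gives beta0 = 0
  expect_equal(firth_logistic_fit(rep(0, 10), c(rep(1, 5), rep(0, 5)))$beta0, 0)
})

test_that("penalized fit stays finite under separation and matches the grid oracle", {
  f <- firth_logistic_fit(c(-2, -1, 0, 1, 2), c(0, 0, 0, 1, 1))
  expect_true(f$converged)
  expect_true(all(is.finite(c(f$beta0, f$beta1))))
  g <- firth_grid_oracle(c(-2, -1, 0, 1, 2), c(0, 0, 0, 1, 1))
  expect_equal(f$beta0, unname(g[1]), tolerance = 2e-3)
  expect_equal(f$beta1, unname(g[2]), tolerance = 2e-3)
})

test_that("Newton solution matches dense grid search on random small windows", {
  set.seed(7)
  for (rep in 1:12) {
    n <- sample(5:21, 1)
    dt <- (1:n) - sample(n, 1)
    y <- rbinom(n, 1, runif(1, 0.1, 0.9))
    f <- firth_logistic_fit(dt, y)
    g <- firth_grid_oracle(dt, y)
    expect_lt(max(abs(c(f$beta0 - g[1], f$beta1 - g[2]))), 1e-3)
  }
})

test_that("estimates stay finite on degenerate 0/1 inputs", {
  set.seed(8)
  cases <- list(rep(0, 9), rep(1, 9), c(rep(0, 4), rep(1, 5)),
                rbinom(3, 1, 0.5), c(0, 1), c(1))
  for (y in cases) {
    n <- length(y)
    f <- firth_logistic_fit(seq_len(n) - (n + 1) / 2, y)
    expect_true(all(is.finite(c(f$beta0, f$beta1))))
    expect_true(all(diag(f$vcov) >= 0))
  }
  expect_error(firth_logistic_fit(1:3, c(0, 1)), "equal length")
  expect_error(firth_logistic_fit(numeric(0), numeric(0)), "empty")
})

test_that("fitted probabilities are equivariant to offset shifts", {
  set.seed(9)
  dt <- -5:5
  y <- rbinom(11, 1, 0.5)
  f <- firth_logistic_fit(dt, y)
  fs <- firth_logistic_fit(dt + 3, y)
  # same slope; intercept compensates the shift; same fitted values
  # (eta at offset d+3 under the shifted fit equals eta at d under the original)
  expect_equal(fs$beta1, f$beta1, tolerance = 1e-6)
  expect_equal(fs$beta0 + 3 * fs$beta1, f$beta0, tolerance = 1e-6)
})

test_that("glm_curve centers each fit so p_hat is the window-center estimate", {
  # response pattern symmetric under time reversal around the center: the
  # slope term vanishes by symmetry of the penalized likelihood. (The center
  # estimate differs slightly from the one-parameter fit because the
  # two-parameter Jeffreys penalty is not the one-parameter penalty.)
  y <- c(1, 0, 1, 0, 1)
  f <- firth_logistic_fit(-2:2, y)
  expect_equal(f$beta1, 0, tolerance = 1e-7)
  g0 <- firth_grid_oracle(-2:2, y)
  expect_equal(f$beta0, unname(g0[1]), tolerance = 1e-3)

  # all-1 window, full linear model: finite, < 1, above the intercept-only value
  f19 <- firth_logistic_fit(-9:9, rep(1, 19))
  expect_lt(plogis(f19$beta0), 1)
  g <- firth_grid_oracle(-9:9, rep(1, 19))
  expect_equal(f19$beta0, unname(g[1]), tolerance = 2e-3)

  # invariance to session relabeling: glm_curve uses centered offsets, so a
  # pure index shift of the same responses gives identical estimates
  set.seed(10)
  r <- rbinom(60, 1, 0.5)
  c1 <- glm_curve(make_series(r), window = 11)
  c2 <- glm_curve(trial_series("x", rep(2L, 60), 1:60, r), window = 11)
  expect_equal(c1$p_hat, c2$p_hat)
})

test_that("glm_curve recovers a linear logit trend and beats the constant
           model in a steep region", {
  # noiseless check: slope recovery on a logistic truth with matching window
  set.seed(11)
  eta <- -2 + 0.12 * (1:60)
  reps <- 300
  b1 <- numeric(reps)
  for (r in seq_len(reps)) {
    y <- rbinom(60, 1, plogis(eta))
    b1[r] <- firth_logistic_fit(-7:7, y[23:37])$beta1
  }
  se <- sd(b1) / sqrt(reps)
  expect_lt(abs(mean(b1) - 0.12), 4 * se + 0.01)

  # fast session-start transient (warm-up shape): truncated windows at the
  # border are asymmetric, so the constant model is badly biased there while
  # the glm tracks the trend
  p_true <- plogis(1.5 - 2.5 * exp(-(0:59) / 4))
  early <- 1:8
  err_glm <- err_const <- numeric(200)
  set.seed(12)
  for (r in 1:200) {
    s <- make_series(rbinom(60, 1, p_true))
    err_glm[r] <- mean(abs(glm_curve(s, 19)$p_hat[early] - p_true[early]))
    err_const[r] <- mean(abs(constant_model_curve(s, 19)$p_hat[early] - p_true[early]))
  }
  expect_lt(mean(err_glm), mean(err_const))
})

test_that("degenerate windows fall back to intercept-only", {
  s <- make_series(c(1, 0, 1, 1), trials_per_session = 2)
  cv <- glm_curve(s, window = 3)  # sep windows of size <= 2
  expect_equal(cv$p_hat[1], (1 + 0.5) / (2 + 1))
  expect_true(all(is.finite(cv$eta_hat)))
  # window size 1
  s1 <- make_series(c(1, 0), trials_per_session = 1)
  cv1 <- glm_curve(s1, window = 1)
  expect_equal(cv1$p_hat, c(1.5 / 2, 0.5 / 2))
})
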