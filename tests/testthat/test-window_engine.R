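test_that("build_window truncates at borders (sep) and spans breaks (conv)", {
  set.seed(1)
  one <- make_series(rbinom(60, 1, 0.5))
  expect_equal(build_window(30, 9, one, "sep")$members, 21:39)
  expect_equal(build_window(1, 9, one, "sep")$members, 1:10)
  expect_equal(build_window(60, 9, one, "sep")$members, 51:60)

  two <- make_series(rbinom(120, 1, 0.5), trials_per_session = 60)
  expect_equal(build_window(60, 9, two, "conv")$members, 51:69)
  expect_equal(build_window(60, 9, two, "sep")$members, 51:60)
  expect_equal(build_window(61, 9, two, "sep")$members, 61:70)

  expect_error(build_window(0, 9, one), "out of range")
  expect_error(build_window(61, 9, one), "out of range")

  # member count bounded by 2h+1, window always contains the center
  for (i in c(1, 5, 30, 58, 60)) for (h in c(0, 3, 9)) {
    w <- build_window(i, h, two, "sep")
    expect_lte(length(w$members), 2 * h + 1)
    expect_true(i %in% w$members)
    expect_equal(w$members, min(w$members):max(w$members))
  }
})

test_that("binomial_proportion computes x/n and the Agresti-Coull center", {
  expect_equal(binomial_proportion(c(1, 0, 1, 1, 0))$p_hat, 0.6)
  expect_equal(binomial_proportion(c(1, 1, 1))$p_hat, 1)
  est <- binomial_proportion(c(rep(1, 13), rep(0, 6)))
  expect_equal(est$p_hat, 13 / 19)
  k2 <- qnorm(0.975)^2
  expect_equal(est$p_tilde, (13 + k2 / 2) / (19 + k2))
  expect_error(binomial_proportion(integer(0)), "empty")
})

test_that("wald_ci matches the closed form and degenerates at x in {0, n}", {
  est <- binomial_proportion(c(rep(1, 5), rep(0, 5)))
  expect_equal(wald_ci(est), c(0.19010, 0.80990), tolerance = 1e-4)
  expect_equal(wald_ci(binomial_proportion(rep(0, 10))), c(0, 0))
  # kappa = 0 (alpha -> 1) collapses to p_hat; use alpha close to 1
  est2 <- binomial_proportion(c(1, 0, 1), alpha = 1 - 1e-12)
  ci <- wald_ci(est2)
  expect_equal(ci[1], ci[2], tolerance = 1e-5)
})

test_that("agresti_coull_ci matches the closed form and never degenerates", {
  est <- binomial_proportion(c(rep(1, 3), rep(0, 7)))
  expect_equal(est$p_tilde, 0.35551, tolerance = 1e-4)
  expect_equal(agresti_coull_ci(est), c(0.10333, 0.60769), tolerance = 1e-3)
  est0 <- binomial_proportion(rep(0, 10))
  ci0 <- agresti_coull_ci(est0)
  expect_equal(est0$p_tilde, 0.13877, tolerance = 1e-4)
  expect_equal(ci0, c(0, 0.32089), tolerance = 1e-4)
  # strictly positive width at the boundary counts, unlike Wald
  for (n in c(5, 11, 19)) for (x in c(0, n)) {
    ci <- agresti_coull_ci(binomial_proportion(c(rep(1, x), rep(0, n - x))))
    expect_gt(ci[2] - ci[1], 0)
  }
})

test_that("interval width is non-increasing in n at fixed p_hat", {
  for (p in c(0.2, 0.5, 0.8)) {
    widths <- sapply(c(5, 10, 20, 40), function(n) {
      x <- round(n * p)
      est <- binomial_proportion(c(rep(1, x), rep(0, n - x)))
      w1 <- diff(wald_ci(est)); w2 <- diff(agresti_coull_ci(est))
      c(w1, w2)
    })
    expect_true(all(diff(widths[1, ]) <= 1e-12))
    expect_true(all(diff(widths[2, ]) <= 1e-12))
  }
})

test_that("constant_model_curve matches brute-force window counts", {
  # step series: direct enumeration oracle at every trial
  s <- make_series(c(rep(0, 30), rep(1, 30)))
  cv <- constant_model_curve(s, window = 11, mode = "sep")
  for (i in seq_len(60)) {
    j <- max(1, i - 5):min(60, i + 5)
    expect_equal(cv$p_hat[i], mean(s$response[j]))
  }
  # all-1 series
  cv1 <- constant_model_curve(make_series(rep(1, 20)), window = 5)
  expect_true(all(cv1$p_hat == 1))
  expect_true(all(cv1$ci_high == 1))
  # single session: conv and sep coincide
  set.seed(2)
  r <- make_series(rbinom(50, 1, 0.4))
  expect_equal(constant_model_curve(r, 9, "conv")$p_hat,
               constant_model_curve(r, 9, "sep")$p_hat)
})

test_that("reversing a session's responses reverses the sep-mode curve", {
  set.seed(3)
  s <- make_series(rbinom(40, 1, 0.3))
  rs <- make_series(rev(s$response))
  for (w in c(7, 19)) {
    expect_equal(rev(constant_model_curve(rs, w, "sep")$p_hat),
                 constant_model_curve(s, w, "sep")$p_hat)
    expect_equal(rev(constant_model_curve(rs, w, "sep")$ci_low),
                 constant_model_curve(s, w, "sep")$ci_low)
  }
})

test_that("adjusted logit stays finite and consistent at extreme windows", {
  cv <- constant_model_curve(make_series(rep(1, 15)), window = 7)
  expect_true(all(is.finite(cv$eta_hat)))
  expect_true(all(is.finite(cv$v_eta)))
  # interior window: n = 7, x = 7 -> eta = log(7.5/0.5), v = 1/(7 p*(1-p*))
  pstar <- 7.5 / 8
  expect_equal(cv$eta_hat[8], log(7.5 / 0.5))
  expect_equal(cv$v_eta[8], 1 / (7 * pstar * (1 - pstar)))
})

test_that("empirical Agresti-Coull coverage tracks the exact coverage", {
  # exact coverage (binomial enumeration) is never undersized on the grid,
  # and lies inside +/- 3 pp of nominal for n >= 19; empirical coverage at
  # 1e4 replicates agrees with the exact value. At n = 11 and extreme p the
  # interval is conservative (exact coverage up to 98.15%), a documented
  # property of the Agresti-Coull construction.
  set.seed(99)
  for (n in c(11, 19, 31, 51)) {
    for (p in seq(0.1, 0.9, by = 0.2)) {
      exact <- ac_exact_coverage(p, n)
      expect_gte(exact, 0.92)
      if (n >= 19) expect_lte(exact, 0.98)
      x <- rbinom(1e4, n, p)
      kappa <- qnorm(0.975)
      pt <- (x + kappa^2 / 2) / (n + kappa^2)
      hw <- kappa * sqrt(pt * (1 - pt) / (n + kappa^2))
      emp <- mean(pmax(0, pt - hw) <= p & p <= pmin(1, pt + hw))
      expect_lt(abs(emp - exact), 0.01)
    }
  }
})
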