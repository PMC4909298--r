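# shared fixture builders (all data generated in code)

# one-subject series from a response vector, split into equal sessions
make_series <- function(responses, trials_per_session = length(responses),
                        subject_id = "s1") {
  n <- length(responses)
  stopifnot(n %% trials_per_session == 0)
  sess <- rep(seq_len(n / trials_per_session), each = trials_per_session)
  trial_series(subject_id, sess, rep(seq_len(trials_per_session), n / trials_per_session),
               responses)
}

# small random multi-subject dataset with a shared layout
make_dataset <- function(n_subjects = 3, trials_per_session = 30, n_sessions = 1,
                         p = 0.5, seed = 1) {
  set.seed(seed)
  study_dataset(lapply(seq_len(n_subjects), function(k) {
    make_series(rbinom(trials_per_session * n_sessions, 1, p),
                trials_per_session, subject_id = sprintf("s%02d", k))
  }))
}

# independent penalized-likelihood oracle: two-stage dense grid search
# (coarse grid, then a fine grid around the coarse optimum); shares no code
# with the Newton solver
firth_grid_oracle <- function(dt, y, lim = 8) {
  pll_grid <- function(b0s, b1s) {
    G <- as.matrix(expand.grid(b0 = b0s, b1 = b1s))
    ETA <- G[, 1] %o% rep(1, length(dt)) + G[, 2] %o% dt
    P <- plogis(ETA)
    W <- P * (1 - P)
    a <- rowSums(W); b <- rowSums(sweep(W, 2, dt, "*"))
    cc <- rowSums(sweep(W, 2, dt^2, "*"))
    det <- a * cc - b^2
    ll <- ETA %*% y + rowSums(plogis(-ETA, log.p = TRUE))
    val <- ifelse(det > 0, ll + 0.5 * log(det), -Inf)
    G[which.max(val), ]
  }
  # four refinement stages; each box is wide enough to cover the diagonal
  # likelihood ridge induced by uncentered offsets (shift ~ step * max|dt|)
  g <- pll_grid(seq(-lim, lim, by = 0.1), seq(-lim, lim, by = 0.1))
  shift <- 1 + max(abs(dt))
  g <- pll_grid(seq(g[1] - 0.1 * shift, g[1] + 0.1 * shift, by = 0.005),
                seq(g[2] - 0.2, g[2] + 0.2, by = 0.005))
  g <- pll_grid(seq(g[1] - 0.005 * shift, g[1] + 0.005 * shift, by = 5e-4),
                seq(g[2] - 0.01, g[2] + 0.01, by = 5e-4))
  pll_grid(seq(g[1] - 5e-4 * shift, g[1] + 5e-4 * shift, by = 5e-5),
           seq(g[2] - 1e-3, g[2] + 1e-3, by = 5e-5))
}

# exact coverage of the Agresti-Coull interval by binomial enumeration
ac_exact_coverage <- function(p, n, alpha = 0.05) {
  kappa <- qnorm(1 - alpha / 2)
  x <- 0:n
  pt <- (x + kappa^2 / 2) / (n + kappa^2)
  hw <- kappa * sqrt(pt * (1 - pt) / (n + kappa^2))
  lo <- pmax(0, pt - hw); hi <- pmin(1, pt + hw)
  sum(dbinom(x, n, p) * (lo <= p & p <= hi))
}
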