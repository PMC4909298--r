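#' Build a moving estimation window around a center trial
#'
#' The window around center trial `i` contains the up to `h` preceding and
#' `h` succeeding trials, truncated at the series borders. In `sep` mode the
#' window is truncated at the session boundaries of the center trial's
#' session; in `conv` mode it is built on the concatenated global trial
#' sequence, ignoring session breaks.
#'
#' @param i center trial, as a global trial index into the series.
#' @param h bandwidth (non-negative integer); window size is at most `2h+1`.
#' @param series a [trial_series()].
#' @param mode `"sep"` (within-session) or `"conv"` (across sessions).
#' @return An object of class `estimation_window`: list with `center`,
#'   `bandwidth`, `members` (global trial indices), `mode`.
#' @examples
#' s <- trial_series("a", rep(1, 60), 1:60, rbinom(60, 1, 0.5))
#' build_window(30, h = 9, s, mode = "sep")$members  # 21..39
#' @export
build_window <- function(i, h, series, mode = c("sep", "conv")) {
  mode <- match.arg(mode)
  n <- n_trials(series)
  if (!is.numeric(i) || length(i) != 1L || i < 1 || i > n)
    stop(sprintf("center trial index %s out of range 1..%d", format(i), n),
         call. = FALSE)
  if (h < 0) stop("'h' must be a non-negative integer", call. = FALSE)
  i <- as.integer(i); h <- as.integer(h)
  if (mode == "conv") {
    members <- max(1L, i - h):min(n, i + h)
  } else {
    sess <- series$session[i]
    in_sess <- which(series$session == sess)
    lo <- in_sess[1L]; hi <- in_sess[length(in_sess)]
    members <- max(lo, i - h):min(hi, i + h)
  }
  structure(list(center = i, bandwidth = h, members = members, mode = mode),
            class = "estimation_window")
}

#' Binomial proportion estimate for one window
#'
#' Summarizes the 0/1 responses of a window into the raw proportion and the
#' Agresti-Coull shrunken center used for interval construction.
#'
#' @param responses 0/1 response vector of the window members.
#' @param alpha nominal error level of the associated intervals.
#' @return An object of class `binomial_estimate`: list with `x` (successes),
#'   `n` (window size), `p_hat = x/n`, `p_tilde` (Agresti-Coull center),
#'   `alpha`, `kappa` (the `(1-alpha/2)` normal quantile).
#' @export
binomial_proportion <- function(responses, alpha = 0.05) {
  check_alpha(alpha)
  if (!length(responses)) stop("empty window", call. = FALSE)
  if (!all(responses %in% c(0, 1))) stop("responses must be 0 or 1", call. = FALSE)
  x <- sum(responses); n <- length(responses)
  kappa <- norm_quantile(alpha)
  structure(list(x = x, n = n, p_hat = x / n,
                 p_tilde = (x + kappa^2 / 2) / (n + kappa^2),
                 alpha = alpha, kappa = kappa),
            class = "binomial_estimate")
}

#' Wald confidence interval for a binomial proportion
#'
#' The textbook normal-approximation interval
#' \eqn{\hat p \pm \kappa \sqrt{\hat p (1-\hat p)/n}}, clipped to \[0, 1\].
#' It degenerates to zero width when all responses agree (x = 0 or x = n),
#' which is the failure mode motivating the Agresti-Coull interval; it is
#' kept for comparison and diagnostics only.
#'
#' @param est a [binomial_proportion()] estimate.
#' @return Numeric vector `c(ci_low, ci_high)`.
#' @export
wald_ci <- function(est) {
  stopifnot(inherits(est, "binomial_estimate"))
  half <- est$kappa * sqrt(est$p_hat * (1 - est$p_hat) / est$n)
  c(clip01(est$p_hat - half), clip01(est$p_hat + half))
}

#' Agresti-Coull confidence interval for a binomial proportion
#'
#' Interval centered at \eqn{\tilde p = (x + \kappa^2/2)/(n + \kappa^2)} with
#' half-width \eqn{\kappa \sqrt{\tilde p (1-\tilde p)/(n + \kappa^2)}},
#' clipped to \[0, 1\]. Equivalent to a Wald interval after adding
#' \eqn{\kappa^2/2} pseudo-successes and pseudo-failures; its width stays
#' strictly positive even when x = 0 or x = n.
#'
#' @inheritParams wald_ci
#' @return Numeric vector `c(ci_low, ci_high)`.
#' @export
agresti_coull_ci <- function(est) {
  stopifnot(inherits(est, "binomial_estimate"))
  half <- est$kappa * sqrt(est$p_tilde * (1 - est$p_tilde) / (est$n + est$kappa^2))
  c(clip01(est$p_tilde - half), clip01(est$p_tilde + half))
}

# vectorized Agresti-Coull bounds from success/size vectors
#' @keywords internal
ac_bounds <- function(x, n, kappa) {
  pt <- (x + kappa^2 / 2) / (n + kappa^2)
  half <- kappa * sqrt(pt * (1 - pt) / (n + kappa^2))
  list(low = clip01(pt - half), high = clip01(pt + half))
}

# adjusted logit and its variance for the constant model, finite at x in {0, n}:
# eta = log((x+1/2)/(n-x+1/2)), v = 1/(n p* (1-p*)) with p* = (x+1/2)/(n+1)
#' @keywords internal
adjusted_logit <- function(x, n) {
  pstar <- (x + 0.5) / (n + 1)
  list(eta = log((x + 0.5) / (n - x + 0.5)),
       v = 1 / (n * pstar * (1 - pstar)))
}

# per-trial window bounds (global indices) for every trial at once;
# works for any object carrying a per-trial 'session' vector
#' @keywords internal
window_bounds <- function(series, h, mode) {
  n <- length(series$session)
  i <- seq_len(n)
  if (mode == "conv") {
    lo <- pmax(1L, i - h); hi <- pmin(n, i + h)
  } else {
    first <- stats::ave(i, series$session, FUN = min)
    last <- stats::ave(i, series$session, FUN = max)
    lo <- pmax(first, i - h); hi <- pmin(last, i + h)
  }
  list(lo = as.integer(lo), hi = as.integer(hi))
}

#' Constant-model (moving-proportion) learning curve
#'
#' Estimates the per-trial success probability as the binomial proportion of
#' correct responses in a moving window of size `window` (= 2h+1), with
#' Agresti-Coull pointwise confidence intervals. `mode = "conv"` reproduces
#' the conventional analysis in which windows run across session breaks;
#' `mode = "sep"` truncates windows at session boundaries so that step-like
#' performance changes between sessions are preserved.
#'
#' For population use the curve also carries an adjusted logit
#' \eqn{\hat\eta = \log((x + 1/2)/(n - x + 1/2))} with variance
#' \eqn{v = 1/(n p^* (1-p^*))}, \eqn{p^* = (x + 1/2)/(n + 1)}, which stays
#' finite for all-correct and all-incorrect windows and coincides with the
#' intercept-only penalized-likelihood adjustment.
#'
#' @param series a [trial_series()].
#' @param window odd window size `s = 2h+1` (number of trials).
#' @param mode `"sep"` or `"conv"`.
#' @param alpha nominal error level for the pointwise intervals.
#' @return A `learning_curve` data frame with one row per trial: `p_hat`,
#'   `ci_low`, `ci_high`, `eta_hat`, `v_eta`.
#' @export
constant_model_curve <- function(series, window = 19, mode = c("sep", "conv"),
                                 alpha = 0.05) {
  mode <- match.arg(mode)
  check_alpha(alpha)
  h <- size_to_bandwidth(window)
  b <- window_bounds(series, h, mode)
  cs <- c(0L, cumsum(series$response))
  x <- cs[b$hi + 1L] - cs[b$lo]
  nW <- b$hi - b$lo + 1L
  kappa <- norm_quantile(alpha)
  ci <- ac_bounds(x, nW, kappa)
  al <- adjusted_logit(x, nW)
  new_learning_curve(series, p_hat = x / nW, ci_low = ci$low, ci_high = ci$high,
                     eta_hat = al$eta, v_eta = al$v,
                     model = paste0("const-", mode), window = window, alpha = alpha)
}
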