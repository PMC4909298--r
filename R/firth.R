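#' Firth-penalized local logistic regression for one window
#'
#' Fits the two-parameter logistic model
#' \eqn{\mathrm{logit}(p_j) = \beta_0 + \beta_1 (t_j - t_i)} to the 0/1
#' responses of one moving window by maximizing the Firth-penalized
#' log-likelihood \eqn{l(\beta) + \frac12 \log \det I(\beta)}, where
#' \eqn{I(\beta) = X^\top W X} is the Fisher information with
#' \eqn{W = \mathrm{diag}(p_j(1-p_j))}. The Jeffreys-prior penalty removes
#' the first-order bias of maximum likelihood and guarantees finite
#' estimates even under complete separation or all-equal responses, where
#' ordinary logistic regression diverges.
#'
#' The penalized score equations
#' \eqn{U^*_r(\beta) = \sum_j (Y_j - p_j + h_j(\tfrac12 - p_j)) x_{jr} = 0}
#' (with \eqn{h_j} the hat-matrix diagonal) are solved by Newton-Raphson
#' with step-halving. When all offsets are equal the model degenerates to
#' intercept-only, which has the closed-form solution
#' \eqn{\hat p = (y + 1/2)/(n + 1)}; this path is computed exactly.
#'
#' @param offsets numeric vector of centered trial times \eqn{t_j - t_i}.
#' @param responses 0/1 vector, same length as `offsets`.
#' @param max_iter maximum Newton iterations.
#' @param tol convergence tolerance on the maximum absolute penalized score.
#' @return An object of class `firth_fit`: list with `beta0`, `beta1`,
#'   `vcov` (2x2, from the unpenalized Fisher information at the penalized
#'   estimate), `converged`, `iterations`, `penalized_loglik`, `n`,
#'   `intercept_only`.
#' @examples
#' # complete separation: ordinary ML diverges, the penalized fit is finite
#' f <- firth_logistic_fit(c(-2, -1, 0, 1, 2), c(0, 0, 0, 1, 1))
#' c(f$beta0, f$beta1)
#' @export
firth_logistic_fit <- function(offsets, responses, max_iter = 50L, tol = 1e-8) {
  if (length(offsets) != length(responses))
    stop("'offsets' and 'responses' must have equal length", call. = FALSE)
  n <- length(responses)
  if (n < 1L) stop("empty window", call. = FALSE)
  if (!all(responses %in% c(0, 1))) stop("responses must be 0 or 1", call. = FALSE)
  fit <- firth_fit_core(as.numeric(offsets), as.numeric(responses),
                        max_iter = max_iter, tol = tol)
  structure(fit, class = "firth_fit")
}

#' @export
print.firth_fit <- function(x, ...) {
  cat(sprintf("<firth_fit> n = %d: beta0 = %.5f, beta1 = %.5f (%s, %d iter)\n",
              x$n, x$beta0, x$beta1,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

# intercept-only penalized solution, exact: p = (y + 1/2)/(n + 1)
#' @keywords internal
firth_intercept_only <- function(y, n) {
  p <- (y + 0.5) / (n + 1)
  eta <- log(p / (1 - p))
  w <- n * p * (1 - p)
  # penalized loglik of the intercept-only model at the optimum
  pll <- y * log(p) + (n - y) * log(1 - p) + 0.5 * log(w)
  list(beta0 = eta, beta1 = 0,
       vcov = matrix(c(1 / w, 0, 0, 0), 2L, 2L),
       converged = TRUE, iterations = 0L,
       penalized_loglik = pll, n = as.integer(n), intercept_only = TRUE)
}

# penalized log-likelihood at (b0, b1); stable via log(1+e^eta) = -log plogis(-eta)
#' @keywords internal
firth_pll2 <- function(dt, y, b0, b1) {
  eta <- b0 + b1 * dt
  p <- stats::plogis(eta)
  w <- p * (1 - p)
  a <- sum(w); b <- sum(w * dt); cc <- sum(w * dt * dt)
  d <- a * cc - b * b
  if (!is.finite(d) || d <= 0) return(-Inf)
  sum(y * eta) + sum(stats::plogis(-eta, log.p = TRUE)) + 0.5 * log(d)
}

# lean Newton solver used in the hot loops (2x2 algebra written out)
#' @keywords internal
firth_fit_core <- function(dt, y, max_iter = 50L, tol = 1e-8) {
  n <- length(y)
  if (n < 1L || length(unique(dt)) == 1L)
    return(firth_intercept_only(sum(y), n))
  # start at the Agresti-Coull-shrunken proportion (finite, near the optimum)
  k2 <- 3.841459  # qnorm(0.975)^2
  p0 <- (sum(y) + k2 / 2) / (n + k2)
  b0 <- log(p0 / (1 - p0)); b1 <- 0
  pll <- firth_pll2(dt, y, b0, b1)
  converged <- FALSE
  iter <- 0L
  a <- bb <- cc <- det <- NA_real_
  repeat {
    eta <- b0 + b1 * dt
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    wdt <- w * dt
    a <- sum(w); bb <- sum(wdt); cc <- sum(wdt * dt)
    det <- a * cc - bb * bb
    if (!is.finite(det) || det <= 0) break
    # inverse information and hat-matrix diagonal
    i11 <- cc / det; i12 <- -bb / det; i22 <- a / det
    hat <- w * (i11 + 2 * i12 * dt + i22 * dt * dt)
    z <- y - p + hat * (0.5 - p)
    s1 <- sum(z); s2 <- sum(z * dt)
    if (max(abs(s1), abs(s2)) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    iter <- iter + 1L
    d0 <- i11 * s1 + i12 * s2
    d1 <- i12 * s1 + i22 * s2
    # step-halving on the penalized likelihood
    step <- 1
    pll_new <- firth_pll2(dt, y, b0 + d0, b1 + d1)
    for (half in 1:12) {
      if (is.finite(pll_new) && pll_new >= pll - 1e-12) break
      step <- step / 2
      pll_new <- firth_pll2(dt, y, b0 + step * d0, b1 + step * d1)
    }
    b0 <- b0 + step * d0; b1 <- b1 + step * d1
    pll <- pll_new
  }
  vcov <- if (is.finite(det) && det > 0)
    matrix(c(cc, -bb, -bb, a) / det, 2L, 2L)
  else matrix(NA_real_, 2L, 2L)
  list(beta0 = b0, beta1 = b1, vcov = vcov,
       converged = converged, iterations = iter,
       penalized_loglik = pll, n = as.integer(n), intercept_only = FALSE)
}

#' Local-GLM learning curve via Firth-penalized logistic regression
#'
#' For every trial `i`, fits [firth_logistic_fit()] to the moving window
#' around `i` with offsets \eqn{t_j - t_i}, so that the fitted intercept is
#' the linear predictor at the center trial:
#' \eqn{\hat p_i = \mu(\hat\beta_0)}. Pointwise confidence intervals are
#' \eqn{[\mu(\hat\beta_0 - \kappa s_i),\ \mu(\hat\beta_0 + \kappa s_i)]}
#' with \eqn{s_i} the asymptotic standard deviation of the intercept, taken
#' from the inverse (unpenalized) Fisher information evaluated at the
#' penalized estimate. Windows are built session-wise (`sep`) by default so
#' that fast transients at session starts are resolved rather than smoothed
#' across the break; a `conv` switch exists for comparison.
#'
#' Degenerate windows (size < 3 or zero spread in offsets) fall back to the
#' exact intercept-only penalized solution with `beta1 = 0`, since the
#' linear term is unidentifiable there.
#'
#' @inheritParams constant_model_curve
#' @return A `learning_curve` data frame with one row per trial.
#' @export
glm_curve <- function(series, window = 19, mode = c("sep", "conv"), alpha = 0.05) {
  mode <- match.arg(mode)
  check_alpha(alpha)
  h <- size_to_bandwidth(window)
  b <- window_bounds(series, h, mode)
  n <- n_trials(series)
  kappa <- norm_quantile(alpha)
  p_hat <- ci_low <- ci_high <- eta_hat <- v_eta <- numeric(n)
  y_all <- as.numeric(series$response)
  for (i in seq_len(n)) {
    j <- b$lo[i]:b$hi[i]
    y <- y_all[j]
    nW <- length(j)
    if (nW < 3L) {
      fit <- firth_intercept_only(sum(y), nW)
    } else {
      fit <- firth_fit_core(as.numeric(j - i), y)
    }
    s2 <- fit$vcov[1L, 1L]
    eta_hat[i] <- fit$beta0
    v_eta[i] <- s2
    p_hat[i] <- stats::plogis(fit$beta0)
    half <- kappa * sqrt(s2)
    ci_low[i] <- stats::plogis(fit$beta0 - half)
    ci_high[i] <- stats::plogis(fit$beta0 + half)
  }
  new_learning_curve(series, p_hat, ci_low, ci_high, eta_hat, v_eta,
                     model = "glm", window = window, alpha = alpha)
}
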