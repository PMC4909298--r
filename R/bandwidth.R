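#' Leave-one-out prediction of a single trial
#'
#' Builds the moving window for trial `i` (Eq-1 truncation rule), removes
#' trial `i` from it, and returns the model's estimate for trial `i` from
#' the remaining responses. For the constant models this is the proportion
#' of the remaining window; for the GLM it is the penalized-likelihood fit
#' on the remaining trials with offsets still centered at `t_i`.
#'
#' @param series a [trial_series()].
#' @param model `"const-conv"`, `"const-sep"` or `"glm"`.
#' @param window odd window size `s = 2h+1`.
#' @param i global trial index to predict.
#' @return Predicted success probability, or `NA_real_` when the deleted
#'   window is empty (e.g. a session of size 1).
#' @export
loo_predict <- function(series, model = c("const-sep", "const-conv", "glm"),
                        window = 19, i) {
  model <- match.arg(model)
  h <- size_to_bandwidth(window)
  mode <- if (model == "const-conv") "conv" else "sep"
  w <- build_window(i, h, series, mode = mode)
  j <- setdiff(w$members, i)
  if (!length(j)) return(NA_real_)
  y <- as.numeric(series$response[j])
  if (model == "glm") {
    nW <- length(j)
    if (nW < 3L || length(unique(j)) == 1L) {
      fit <- firth_intercept_only(sum(y), nW)
    } else {
      fit <- firth_fit_core(as.numeric(j - i), y)
    }
    stats::plogis(fit$beta0)
  } else {
    mean(y)
  }
}

# vectorized constant-model LOO predictions for one subject at one bandwidth
#' @keywords internal
loo_const_all <- function(series, h, mode) {
  b <- window_bounds(series, h, mode)
  cs <- c(0L, cumsum(series$response))
  x <- cs[b$hi + 1L] - cs[b$lo]
  nW <- b$hi - b$lo + 1L
  pred <- (x - series$response) / (nW - 1L)
  pred[nW == 1L] <- NA_real_
  pred
}

# GLM LOO predictions for one subject at one bandwidth (sep windows)
#' @keywords internal
loo_glm_all <- function(series, h, mode = "sep") {
  b <- window_bounds(series, h, mode)
  n <- n_trials(series)
  y_all <- as.numeric(series$response)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    j <- setdiff(b$lo[i]:b$hi[i], i)
    if (!length(j)) { pred[i] <- NA_real_; next }
    y <- y_all[j]
    if (length(j) < 3L) {
      fit <- firth_intercept_only(sum(y), length(j))
    } else {
      fit <- firth_fit_core(as.numeric(j - i), y)
    }
    pred[i] <- stats::plogis(fit$beta0)
  }
  pred
}

#' Cross-validated mean squared error of prediction over a window-size grid
#'
#' Estimates, for every window size in `grid`, the mean squared error of
#' prediction \eqn{\widehat{MSEP} = \sum_i (Y_i - \hat p_i^{(-i)})^2} by
#' leave-one-out cross-validation, summed across all trials of all subjects.
#' Both the raw sum and the per-trial mean over contributing trials are
#' reported; trials whose deleted window is empty are excluded and counted.
#'
#' @param dataset a [study_dataset()].
#' @param model `"const-conv"`, `"const-sep"` or `"glm"`.
#' @param grid odd window sizes to evaluate (default 5 to 61 in steps of 2).
#' @param tolerance tolerance passed to [select_bandwidth()].
#' @return An object of class `msep_curve`: data frame with columns `window`,
#'   `msep_sum`, `msep_mean`, `n_contrib`, `n_skipped`; attributes
#'   `per_subject` (matrix of per-subject sums), `argmin` (grid size with the
#'   smallest per-trial mean), `selected` (see [select_bandwidth()]),
#'   `model`.
#' @export
msep <- function(dataset, model = c("const-sep", "const-conv", "glm"),
                 grid = seq(5L, 61L, by = 2L), tolerance = 0.01) {
  model <- match.arg(model)
  stopifnot(inherits(dataset, "study_dataset"))
  if (!length(grid)) stop("'grid' must be non-empty", call. = FALSE)
  if (any(grid %% 2 != 1)) stop("all grid window sizes must be odd", call. = FALSE)
  grid <- as.integer(sort(grid))
  mode <- if (model == "const-conv") "conv" else "sep"
  K <- length(dataset$series)
  per_subject <- matrix(NA_real_, nrow = length(grid), ncol = K,
                        dimnames = list(NULL, names(dataset$series)))
  msum <- mmean <- numeric(length(grid))
  ncontrib <- nskip <- integer(length(grid))
  for (g in seq_along(grid)) {
    h <- size_to_bandwidth(grid[g])
    tot <- 0; ntot <- 0L; nsk <- 0L
    for (k in seq_len(K)) {
      ser <- dataset$series[[k]]
      pred <- if (model == "glm") loo_glm_all(ser, h, mode)
              else loo_const_all(ser, h, mode)
      err <- (ser$response - pred)^2
      ok <- !is.na(err)
      per_subject[g, k] <- sum(err[ok])
      tot <- tot + sum(err[ok]); ntot <- ntot + sum(ok); nsk <- nsk + sum(!ok)
    }
    msum[g] <- tot; mmean[g] <- tot / ntot
    ncontrib[g] <- ntot; nskip[g] <- nsk
  }
  if (any(nskip > 0L))
    warning(sprintf("%d leave-one-out prediction(s) skipped (empty deleted window)",
                    max(nskip)), call. = FALSE)
  out <- data.frame(window = grid, msep_sum = msum, msep_mean = mmean,
                    n_contrib = ncontrib, n_skipped = nskip)
  out <- structure(out, class = c("msep_curve", "data.frame"),
                   per_subject = per_subject, model = model,
                   argmin = grid[which.min(mmean)])
  attr(out, "selected") <- select_bandwidth(out, tolerance = tolerance)
  out
}

#' @export
print.msep_curve <- function(x, ...) {
  cat(sprintf("<msep_curve> model %s, %d window sizes; argmin %d, selected %d\n",
              attr(x, "model"), nrow(x), attr(x, "argmin"), attr(x, "selected")))
  print.data.frame(as.data.frame(x), ...)
  invisible(x)
}

#' Select the operating window size from an MSEP curve
#'
#' Returns the largest grid size whose per-trial-mean MSEP lies within
#' `tolerance` (a fraction of the overall MSEP range across the grid) of the
#' global minimum. Among near-minimal sizes the largest is preferred because
#' the variance of the estimate decreases with window size.
#'
#' @param curve an [msep()] result.
#' @param tolerance fraction of the MSEP range (default 0.01, i.e. 1%).
#' @return The selected window size (integer).
#' @export
select_bandwidth <- function(curve, tolerance = 0.01) {
  stopifnot(inherits(curve, "msep_curve"))
  m <- curve$msep_mean
  thr <- min(m) + tolerance * (max(m) - min(m))
  max(curve$window[m <= thr])
}
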