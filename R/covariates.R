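#' Construct a continuous per-trial covariate series
#'
#' Holds one subject's continuous per-trial covariate (reaction time in
#' seconds, z-scored evoked-potential SNR, ...) on the same session/trial
#' grid as the binary responses.
#'
#' @param value numeric vector of per-trial values (finite).
#' @param session integer vector of session indices (1-based).
#' @param trial integer vector of within-session trial indices (1-based,
#'   unit-spaced). Defaults to 1..m within each session in input order.
#' @param subject_id optional subject label.
#' @return An object of class `covariate_series`.
#' @export
covariate_series <- function(value, session = rep(1L, length(value)),
                             trial = NULL, subject_id = "subject") {
  value <- as.numeric(value)
  session <- as.integer(session)
  if (length(session) != length(value))
    stop("'session' must match 'value' in length", call. = FALSE)
  if (is.null(trial)) {
    trial <- stats::ave(seq_along(value), session, FUN = seq_along)
  }
  trial <- as.integer(trial)
  if (any(!is.finite(value)))
    stop("covariate values must be finite", call. = FALSE)
  ord <- order(session, trial)
  out <- structure(list(subject_id = as.character(subject_id)[1L],
                        session = session[ord], trial = trial[ord],
                        value = value[ord]),
                   class = "covariate_series")
  for (s in unique(out$session)) {
    tt <- out$trial[out$session == s]
    if (any(diff(tt) <= 0))
      stop(sprintf("trial times must be strictly increasing within session %d", s),
           call. = FALSE)
  }
  out
}

#' @export
print.covariate_series <- function(x, ...) {
  cat(sprintf("<covariate_series> subject %s: %d trials, mean %.4g\n",
              x$subject_id, length(x$value), mean(x$value)))
  invisible(x)
}

# one local (weighted) linear fit: returns intercept estimate and its SE
#' @keywords internal
local_linear_one <- function(dt, x) {
  n <- length(x)
  if (n >= 2L && length(unique(dt)) >= 2L) {
    X <- cbind(1, dt)
    XtX <- crossprod(X)
    inv <- solve(XtX)
    beta <- drop(inv %*% crossprod(X, x))
    resid <- x - drop(X %*% beta)
    s2 <- if (n > 2L) sum(resid^2) / (n - 2L) else 0
    c(fit = beta[1L], se = sqrt(s2 * inv[1L, 1L]))
  } else {
    # local-constant fallback: singular design or a single point
    m <- mean(x)
    se <- if (n > 1L) stats::sd(x) / sqrt(n) else 0
    c(fit = m, se = se)
  }
}

#' Local linear smoothing of a covariate series
#'
#' Per trial `i`, fits a weighted least-squares line of the covariate on the
#' centered trial time \eqn{t - t_i} over the moving window (uniform kernel
#' on the window, matching the discrete window semantics used for the
#' learning curves). The fitted value at `i` is the local intercept; its
#' standard error comes from the local residual variance, and pointwise
#' confidence intervals are Gaussian, \eqn{\mathrm{fit} \pm \kappa\,
#' \mathrm{SE}}. Windows with a singular local design fall back to a local
#' constant fit.
#'
#' @param series a [covariate_series()].
#' @param window odd window size.
#' @param alpha nominal error level.
#' @param mode `"sep"` (windows truncated at session breaks) or `"conv"`.
#' @return An object of class `smoothed_curve`: data frame with per-trial
#'   `fit`, `se`, `ci_low`, `ci_high`.
#' @export
local_linear_smooth <- function(series, window = 19, alpha = 0.05,
                                mode = c("sep", "conv")) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "covariate_series"))
  check_alpha(alpha)
  h <- size_to_bandwidth(window)
  b <- window_bounds(series, h, mode)
  n <- length(series$value)
  kappa <- norm_quantile(alpha)
  fit <- se <- numeric(n)
  for (i in seq_len(n)) {
    j <- b$lo[i]:b$hi[i]
    r <- local_linear_one(as.numeric(j - i), series$value[j])
    fit[i] <- r[["fit"]]; se[i] <- r[["se"]]
  }
  out <- data.frame(trial_global = seq_len(n), session = series$session,
                    trial = series$trial, fit = fit, se = se,
                    ci_low = fit - kappa * se, ci_high = fit + kappa * se)
  structure(out, class = c("smoothed_curve", "data.frame"),
            subject_id = series$subject_id, window = window, alpha = alpha,
            mode = mode, kernel = "uniform")
}

#' @export
print.smoothed_curve <- function(x, ...) {
  cat(sprintf("<smoothed_curve> subject %s, window %d, %d trials (uniform kernel)\n",
              attr(x, "subject_id"), attr(x, "window"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat(sprintf("... %d more trials\n", nrow(x) - 6L))
  invisible(x)
}

#' Per-trial evoked-potential signal-to-noise ratio
#'
#' For each trial epoch, computes the root-mean-square (RMS) amplitude of
#' the signal over the 0.5 s following stimulus onset and over the 0.5 s
#' baseline preceding it, takes the log-scale ratio
#' \eqn{\log(\mathrm{RMS}_{post}/\mathrm{RMS}_{base})}, and z-standardizes
#' the resulting values across the subject's trials (mean 0, SD 1). The
#' natural log is used; after z-scoring the base is immaterial.
#'
#' @param trial_epochs numeric matrix, one row per trial, columns = samples
#'   of the recorded epoch. Each epoch must cover at least 0.5 s before and
#'   0.5 s after onset at the stated sampling rate.
#' @param sampling_rate sampling rate in Hz.
#' @param onset_index 1-based sample index of stimulus onset within the epoch.
#' @param session optional session labels (one per trial).
#' @param subject_id optional subject label.
#' @return A [covariate_series()] of z-standardized SNR values.
#' @export
compute_snr <- function(trial_epochs, sampling_rate, onset_index,
                        session = rep(1L, nrow(trial_epochs)),
                        subject_id = "subject") {
  trial_epochs <- as.matrix(trial_epochs)
  nb <- round(0.5 * sampling_rate)
  if (onset_index - nb < 1L || onset_index + nb - 1L > ncol(trial_epochs))
    stop("epochs too short: need 0.5 s before and after onset", call. = FALSE)
  base <- trial_epochs[, (onset_index - nb):(onset_index - 1L), drop = FALSE]
  post <- trial_epochs[, onset_index:(onset_index + nb - 1L), drop = FALSE]
  rms <- function(m) sqrt(rowMeans(m^2))
  raw <- log(rms(post) / rms(base))
  z <- (raw - mean(raw)) / stats::sd(raw)
  covariate_series(z, session = session, subject_id = subject_id)
}

#' Grand-mean smoothed covariate curve across subjects
#'
#' Smooths each subject's covariate series with [local_linear_smooth()] and
#' averages the per-subject fitted values per trial; confidence bands are
#' \eqn{\bar x \pm \kappa\,\mathrm{SEM}} with the standard error of the mean
#' taken across subjects.
#'
#' @param series_list list of [covariate_series()] with a shared layout.
#' @inheritParams local_linear_smooth
#' @return A `smoothed_curve` data frame (population level).
#' @export
grand_mean_covariate <- function(series_list, window = 19, alpha = 0.05,
                                 mode = c("sep", "conv")) {
  mode <- match.arg(mode)
  K <- length(series_list)
  if (K < 2L) stop("need at least 2 subjects", call. = FALSE)
  layouts <- lapply(series_list, function(s) paste(s$session, s$trial))
  if (!all(vapply(layouts, identical, logical(1), layouts[[1L]])))
    stop("all subjects must share the same session/trial layout", call. = FALSE)
  sm <- lapply(series_list, local_linear_smooth, window = window,
               alpha = alpha, mode = mode)
  fits <- vapply(sm, function(s) s$fit, numeric(nrow(sm[[1L]])))
  m <- rowMeans(fits)
  sem <- apply(fits, 1L, stats::sd) / sqrt(K)
  kappa <- norm_quantile(alpha)
  ref <- series_list[[1L]]
  out <- data.frame(trial_global = seq_along(ref$value), session = ref$session,
                    trial = ref$trial, fit = m, se = sem,
                    ci_low = m - kappa * sem, ci_high = m + kappa * sem)
  structure(out, class = c("smoothed_curve", "data.frame"),
            subject_id = sprintf("grand mean (n=%d)", K), window = window,
            alpha = alpha, mode = mode, kernel = "uniform")
}
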