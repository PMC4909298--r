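#' Construct a true (reference) learning curve
#'
#' A `true_curve` holds the per-trial Bernoulli success probabilities used
#' to generate simulated response sequences, together with the session
#' layout.
#'
#' @param p numeric vector of success probabilities, all strictly in (0, 1).
#' @param session integer session index per trial (default: one session).
#' @param trial within-session trial index (default 1..m per session).
#' @return An object of class `true_curve`.
#' @export
true_curve <- function(p, session = rep(1L, length(p)), trial = NULL) {
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("true success probabilities must lie strictly in (0, 1)", call. = FALSE)
  session <- as.integer(session)
  if (length(session) != length(p))
    stop("'session' must match 'p' in length", call. = FALSE)
  if (is.null(trial)) trial <- stats::ave(seq_along(p), session, FUN = seq_along)
  structure(list(p = p, session = session, trial = as.integer(trial)),
            class = "true_curve")
}

#' @export
print.true_curve <- function(x, ...) {
  cat(sprintf("<true_curve> %d trials in %d session(s), p in [%.3f, %.3f]\n",
              length(x$p), length(unique(x$session)), min(x$p), max(x$p)))
  invisible(x)
}

#' Read a true curve from CSV (columns p, session[, trial])
#'
#' Allows replicating the error study with any externally estimated
#' reference curve (e.g. a population curve estimated from real data).
#'
#' @param path CSV path with columns `p`, `session` and optionally `trial`.
#' @return A [true_curve()].
#' @export
read_true_curve <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("p", "session") %in% names(df)))
    stop("true-curve CSV needs columns 'p' and 'session'", call. = FALSE)
  true_curve(df$p, df$session, if ("trial" %in% names(df)) df$trial else NULL)
}

#' Write a true curve to CSV
#' @param curve a [true_curve()].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_true_curve <- function(curve, path) {
  stopifnot(inherits(curve, "true_curve"))
  utils::write.csv(
    format(data.frame(trial_global = seq_along(curve$p), session = curve$session,
                      trial = curve$trial, p = curve$p),
           digits = 15, scientific = FALSE, trim = TRUE),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Specification of a synthetic learning population
#'
#' Parametrizes the per-subject true learning curves on the logit scale as a
#' sigmoid acquisition plus session-level steps, a fast warm-up transient at
#' the start of post-acquisition sessions, and a slow within-session
#' decline:
#' \deqn{\eta_k(t) = \beta_{base} + o_k + A\,\sigma((t - m_k)/\lambda)
#'   + \Delta (s-1) - W e^{-(j-1)/\tau}\,[s \ge 2] - D\,(j-1)/(m-1)}
#' with global trial \eqn{t}, session \eqn{s}, within-session trial \eqn{j},
#' subject logit offset \eqn{o_k \sim N(0, \sigma_o^2)} and subject
#' acquisition midpoint \eqn{m_k = m + \delta_k},
#' \eqn{\delta_k \sim N(0, \sigma_m^2)}.
#'
#' The defaults emulate a 20-subject, 3-session, 60-trials-per-session
#' avoidance-learning study: chance-level start (p about 0.2), a sigmoid
#' acquisition crossing mid-study, step-wise level increases across session
#' breaks, fast transients in the first 5-10 trials of sessions 2 and 3,
#' and a mild performance decline towards session ends.
#'
#' @param n_subjects number of subjects.
#' @param n_sessions number of sessions.
#' @param trials_per_session trials in each session.
#' @param baseline baseline logit at study start.
#' @param amplitude acquisition amplitude on the logit scale.
#' @param midpoint acquisition midpoint, in global trials.
#' @param slope acquisition time constant, in trials.
#' @param session_step logit level step added per session after the first.
#' @param warmup_amplitude size (logit) of the start-of-session depression
#'   that decays during warm-up (sessions 2+).
#' @param warmup_decay warm-up decay length, in trials.
#' @param decline within-session logit decline from first to last trial.
#' @param sd_midpoint between-subject SD of the acquisition midpoint (trials).
#' @param sd_offset between-subject SD of the subject logit offset.
#' @return An object of class `synth_spec`.
#' @export
synth_population_spec <- function(n_subjects = 20L, n_sessions = 3L,
                                  trials_per_session = 60L,
                                  baseline = -1.4, amplitude = 2.2,
                                  midpoint = 45, slope = 4,
                                  session_step = 0.5,
                                  warmup_amplitude = 1.2, warmup_decay = 3,
                                  decline = 0.3,
                                  sd_midpoint = 10, sd_offset = 0.5) {
  spec <- structure(as.list(environment()), class = "synth_spec")
  if (spec$n_subjects < 1L || spec$n_sessions < 1L || spec$trials_per_session < 1L)
    stop("subject, session and trial counts must be positive", call. = FALSE)
  if (spec$warmup_decay <= 0 || spec$slope <= 0)
    stop("'warmup_decay' and 'slope' must be positive", call. = FALSE)
  spec
}

#' @export
print.synth_spec <- function(x, ...) {
  cat(sprintf(paste0("<synth_spec> %d subjects x %d sessions x %d trials; ",
                     "baseline %.2f, amplitude %.2f @ trial %g (slope %g)\n"),
              x$n_subjects, x$n_sessions, x$trials_per_session,
              x$baseline, x$amplitude, x$midpoint, x$slope))
  invisible(x)
}

# logit curve for one subject given its midpoint shift and offset
#' @keywords internal
synth_logit <- function(spec, midpoint_shift = 0, offset = 0) {
  m <- spec$trials_per_session
  sess <- rep(seq_len(spec$n_sessions), each = m)
  j <- rep(seq_len(m), times = spec$n_sessions)
  t <- seq_along(sess)
  eta <- spec$baseline + offset +
    spec$amplitude * stats::plogis((t - (spec$midpoint + midpoint_shift)) / spec$slope) +
    spec$session_step * (sess - 1L) -
    spec$warmup_amplitude * exp(-(j - 1) / spec$warmup_decay) * (sess >= 2L) -
    spec$decline * (if (m > 1L) (j - 1) / (m - 1) else 0)
  list(eta = eta, session = sess, trial = j)
}

#' Draw the per-subject true curves of a synthetic population
#'
#' Samples the subject-level midpoint shifts and logit offsets of `spec` and
#' returns the implied per-subject [true_curve()]s plus the population
#' reference curve (inverse logit of the subject-mean logit, the estimand of
#' the fixed-effects grand mean).
#'
#' @param spec a [synth_population_spec()].
#' @param seed integer seed for the subject-level draws.
#' @return List with `subject_truths` (list of `true_curve`) and
#'   `population_truth` (a `true_curve`).
#' @export
population_truth <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(seed)
  shifts <- stats::rnorm(spec$n_subjects, 0, spec$sd_midpoint)
  offsets <- stats::rnorm(spec$n_subjects, 0, spec$sd_offset)
  truths <- vector("list", spec$n_subjects)
  etas <- NULL
  for (k in seq_len(spec$n_subjects)) {
    g <- synth_logit(spec, shifts[k], offsets[k])
    truths[[k]] <- true_curve(expit(g$eta), g$session, g$trial)
    etas <- cbind(etas, g$eta)
  }
  names(truths) <- sprintf("S%02d", seq_len(spec$n_subjects))
  g0 <- synth_logit(spec)
  list(subject_truths = truths,
       population_truth = true_curve(expit(rowMeans(etas)), g0$session, g0$trial))
}

#' Simulate Bernoulli response sequences from a true curve
#'
#' Draws `R` independent response sequences, each trial an independent
#' Bernoulli draw from the curve's success probability. Reproducible given
#' the seed.
#'
#' @param curve a [true_curve()].
#' @param R number of replicate sequences.
#' @param seed integer seed.
#' @return Integer matrix with `R` rows (replicates) and one column per trial.
#' @export
simulate_responses <- function(curve, R, seed = 1L) {
  stopifnot(inherits(curve, "true_curve"))
  if (R < 1L) stop("'R' must be >= 1", call. = FALSE)
  set.seed(seed)
  n <- length(curve$p)
  matrix(stats::rbinom(R * n, 1L, rep(curve$p, each = R)), nrow = R, ncol = n)
}

#' Generate a synthetic study dataset with known ground truth
#'
#' Draws the per-subject true curves from `spec` (see [population_truth()])
#' and one Bernoulli response sequence per subject, returning both the
#' [study_dataset()] and the ground truth for parameter-recovery checks.
#'
#' @param spec a [synth_population_spec()].
#' @param seed integer seed controlling both subject effects and responses.
#' @return List with `dataset` (a `study_dataset`), `subject_truths`, and
#'   `population_truth`.
#' @export
generate_population <- function(spec = synth_population_spec(), seed = 1L) {
  tr <- population_truth(spec, seed = seed)
  sers <- vector("list", spec$n_subjects)
  for (k in seq_len(spec$n_subjects)) {
    tc <- tr$subject_truths[[k]]
    y <- stats::rbinom(length(tc$p), 1L, tc$p)
    sers[[k]] <- trial_series(names(tr$subject_truths)[k], tc$session, tc$trial, y)
  }
  list(dataset = study_dataset(sers),
       subject_truths = tr$subject_truths,
       population_truth = tr$population_truth)
}

# constant-model estimates + AC bounds for a whole replicate matrix at once
#' @keywords internal
const_curves_matrix <- function(Y, bounds, kappa) {
  cs <- cbind(0L, t(apply(Y, 1L, cumsum)))
  x <- cs[, bounds$hi + 1L, drop = FALSE] - cs[, bounds$lo, drop = FALSE]
  nW <- matrix(bounds$hi - bounds$lo + 1L, nrow = nrow(Y), ncol = ncol(Y), byrow = TRUE)
  ci <- ac_bounds(x, nW, kappa)
  list(p = x / nW, low = ci$low, high = ci$high)
}

#' Monte-Carlo error study of the learning-curve estimators
#'
#' Replicates the simulation design used to quantify random and systematic
#' estimation errors: `R` response sequences are drawn from `curve`, every
#' sequence is analyzed with each model at each window size (the same
#' sequences are reused across estimators, so comparisons are paired), and
#' per trial the study reports
#' \itemize{
#'   \item bias: mean estimated minus true success probability,
#'   \item sd: standard deviation of the estimates across replicates,
#'   \item mae: mean absolute error (normalized by `R`),
#'   \item coverage: fraction of replicates whose confidence interval
#'     contains the true value (closed interval, clipped bounds included).
#' }
#'
#' @param curve a [true_curve()].
#' @param R number of replicate sequences.
#' @param models character vector from `"const-conv"`, `"const-sep"`, `"glm"`.
#' @param windows odd window sizes to evaluate.
#' @param alpha nominal error level of the intervals.
#' @param seed integer seed.
#' @return An object of class `sim_study`: long data frame with columns
#'   `trial`, `session`, `model`, `window`, `true_p`, `bias`, `sd`, `mae`,
#'   `coverage`; attributes `R`, `seed`, `alpha`.
#' @export
error_study <- function(curve, R = 1000L,
                        models = c("const-conv", "const-sep", "glm"),
                        windows = c(11L, 19L, 31L, 51L),
                        alpha = 0.05, seed = 1L) {
  stopifnot(inherits(curve, "true_curve"))
  models <- match.arg(models, c("const-conv", "const-sep", "glm"),
                      several.ok = TRUE)
  if (any(windows %% 2 != 1)) stop("window sizes must be odd", call. = FALSE)
  Y <- simulate_responses(curve, R, seed = seed)
  n <- length(curve$p)
  kappa <- norm_quantile(alpha)
  dummy <- trial_series("truth", curve$session, curve$trial, rep(0L, n))
  res <- list()
  for (w in as.integer(windows)) {
    h <- size_to_bandwidth(w)
    for (model in models) {
      mode <- if (model == "const-conv") "conv" else "sep"
      bounds <- window_bounds(dummy, h, mode)
      if (model == "glm") {
        P <- LO <- HI <- matrix(NA_real_, R, n)
        for (r in seq_len(R)) {
          y <- as.numeric(Y[r, ])
          for (i in seq_len(n)) {
            j <- bounds$lo[i]:bounds$hi[i]
            if (length(j) < 3L) fit <- firth_intercept_only(sum(y[j]), length(j))
            else fit <- firth_fit_core(as.numeric(j - i), y[j])
            half <- kappa * sqrt(fit$vcov[1L, 1L])
            P[r, i] <- stats::plogis(fit$beta0)
            LO[r, i] <- stats::plogis(fit$beta0 - half)
            HI[r, i] <- stats::plogis(fit$beta0 + half)
          }
        }
        est <- list(p = P, low = LO, high = HI)
      } else {
        est <- const_curves_matrix(Y, bounds, kappa)
      }
      tp <- matrix(curve$p, R, n, byrow = TRUE)
      res[[length(res) + 1L]] <- data.frame(
        trial = seq_len(n), session = curve$session,
        model = model, window = w, true_p = curve$p,
        bias = colMeans(est$p) - curve$p,
        sd = apply(est$p, 2L, stats::sd),
        mae = colMeans(abs(est$p - tp)),
        coverage = colMeans(est$low <= tp & tp <= est$high))
    }
  }
  structure(do.call(rbind, res), class = c("sim_study", "data.frame"),
            R = as.integer(R), seed = as.integer(seed), alpha = alpha)
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("<sim_study> R = %d replicates, models %s, windows %s\n",
              attr(x, "R"), paste(unique(x$model), collapse = "/"),
              paste(unique(x$window), collapse = "/")))
  invisible(x)
}
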