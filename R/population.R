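#' Fixed-effects population (grand-mean) learning curve
#'
#' Computes the population learning curve on the logit scale: per trial, the
#' grand-mean logit is the average over subjects of the per-subject local
#' estimates \eqn{\hat\eta_i(k)} — the intercept of the sum-to-zero-coded
#' fixed-effects model — and the grand-mean probability is its inverse logit.
#' Per-subject components come either from the session-wise constant model
#' (adjusted logit, see [constant_model_curve()]) or from the Firth-penalized
#' local GLM ([glm_curve()]). Subjects are modelled as fixed rather than
#' random effects: learning populations are typically heterogeneous, and the
#' subject deviations are of interest in themselves.
#'
#' Two variance rules for the grand-mean logit are available:
#' `"printed"` uses \eqn{v^{GM} = \frac{1}{K}\sum_k v_i(k)} (the rule the
#' fixed-effects formulation states, which retains between-subject scale),
#' while `"mean"` uses \eqn{v^{GM} = \frac{1}{K^2}\sum_k v_i(k)}, the
#' variance of a mean of independent estimates. Confidence intervals are
#' \eqn{[\mu(\hat\eta^{GM} - \kappa\sqrt{v^{GM}}),\
#' \mu(\hat\eta^{GM} + \kappa\sqrt{v^{GM}})]}.
#'
#' @param dataset a [study_dataset()] with at least 2 subjects sharing one
#'   session layout.
#' @param model per-subject component model, `"const-sep"` or `"glm"`.
#' @param window odd window size.
#' @param alpha nominal error level.
#' @param variance_rule `"printed"` or `"mean"` (see Details).
#' @return An object of class `population_curve`: data frame with per-trial
#'   `eta_gm`, `p_gm`, `v_gm`, `ci_low`, `ci_high`; attributes `eta` and `v`
#'   (trial x subject matrices of the per-subject components), `model`,
#'   `window`, `alpha`, `variance_rule`.
#' @export
fixed_effects_grand_mean <- function(dataset, model = c("glm", "const-sep"),
                                     window = 19, alpha = 0.05,
                                     variance_rule = c("printed", "mean")) {
  model <- match.arg(model)
  variance_rule <- match.arg(variance_rule)
  stopifnot(inherits(dataset, "study_dataset"))
  K <- length(dataset$series)
  if (K < 2L) stop("the population model requires at least 2 subjects", call. = FALSE)
  curves <- lapply(dataset$series, function(s) {
    if (model == "glm") glm_curve(s, window = window, alpha = alpha)
    else constant_model_curve(s, window = window, mode = "sep", alpha = alpha)
  })
  eta <- vapply(curves, function(cv) cv$eta_hat, numeric(nrow(curves[[1L]])))
  v <- vapply(curves, function(cv) cv$v_eta, numeric(nrow(curves[[1L]])))
  eta_gm <- rowMeans(eta)
  v_gm <- rowMeans(v)
  if (variance_rule == "mean") v_gm <- v_gm / K
  kappa <- norm_quantile(alpha)
  ref <- dataset$series[[1L]]
  out <- data.frame(trial_global = seq_along(ref$response),
                    session = ref$session, trial = ref$trial,
                    eta_gm = eta_gm, p_gm = expit(eta_gm), v_gm = v_gm,
                    ci_low = expit(eta_gm - kappa * sqrt(v_gm)),
                    ci_high = expit(eta_gm + kappa * sqrt(v_gm)))
  structure(out, class = c("population_curve", "data.frame"),
            eta = eta, v = v, model = model, window = window, alpha = alpha,
            variance_rule = variance_rule, n_subjects = K)
}

#' Arithmetic grand-mean learning curve (conventional analysis)
#'
#' The conventional population analysis: per trial, the arithmetic mean over
#' subjects of the conventional moving-proportion estimates (constant model,
#' windows run across session breaks), with standard-error-of-the-mean
#' confidence bands \eqn{\bar p \pm \kappa\, s/\sqrt{K}}, clipped to
#' \[0, 1\]. Provided for comparison with [fixed_effects_grand_mean()]; it
#' implicitly treats per-trial success probabilities as Gaussian across
#' subjects, which bounded Bernoulli proportions are not.
#'
#' @inheritParams fixed_effects_grand_mean
#' @return A `population_curve` data frame with per-trial `p_gm`, `ci_low`,
#'   `ci_high`, `sd_subjects`.
#' @export
arithmetic_grand_mean <- function(dataset, window = 19, alpha = 0.05) {
  stopifnot(inherits(dataset, "study_dataset"))
  K <- length(dataset$series)
  if (K < 2L) stop("the population model requires at least 2 subjects", call. = FALSE)
  curves <- lapply(dataset$series, function(s)
    constant_model_curve(s, window = window, mode = "conv", alpha = alpha))
  p <- vapply(curves, function(cv) cv$p_hat, numeric(nrow(curves[[1L]])))
  pbar <- rowMeans(p)
  sdp <- apply(p, 1L, stats::sd)
  kappa <- norm_quantile(alpha)
  half <- kappa * sdp / sqrt(K)
  ref <- dataset$series[[1L]]
  out <- data.frame(trial_global = seq_along(ref$response),
                    session = ref$session, trial = ref$trial,
                    p_gm = pbar, sd_subjects = sdp,
                    ci_low = clip01(pbar - half),
                    ci_high = clip01(pbar + half))
  structure(out, class = c("population_curve", "data.frame"),
            p = p, model = "const-conv-arithmetic", window = window,
            alpha = alpha, n_subjects = K)
}

#' @export
print.population_curve <- function(x, ...) {
  cat(sprintf("<population_curve> model %s, window %d, %d subjects, %d trials\n",
              attr(x, "model"), attr(x, "window"), attr(x, "n_subjects"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat(sprintf("... %d more trials\n", nrow(x) - 6L))
  invisible(x)
}

#' Write a population curve to a delimited text file
#'
#' @param curve a `population_curve`.
#' @param path output file path.
#' @return Invisibly, the path written.
#' @export
write_population_curve <- function(curve, path) {
  stopifnot(inherits(curve, "population_curve"))
  utils::write.csv(format(as.data.frame(curve), digits = 15,
                          scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
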