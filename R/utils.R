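#' @keywords internal
logit <- function(p) log(p / (1 - p))

#' @keywords internal
expit <- function(eta) stats::plogis(eta)

# (1 - alpha/2) standard-normal quantile, the half-width multiplier kappa
#' @keywords internal
norm_quantile <- function(alpha) stats::qnorm(1 - alpha / 2)

#' @keywords internal
clip01 <- function(x) pmin(1, pmax(0, x))

#' @keywords internal
check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be a single number in (0, 1)", call. = FALSE)
  alpha
}

# window SIZE s = 2h+1 (odd) -> bandwidth h
#' @keywords internal
size_to_bandwidth <- function(window) {
  if (!is.numeric(window) || length(window) != 1L || window < 1 || window %% 2 != 1)
    stop("'window' must be a single odd integer >= 1", call. = FALSE)
  as.integer((window - 1L) / 2L)
}

#' @keywords internal
check_mode <- function(mode) match.arg(mode, c("sep", "conv"))
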