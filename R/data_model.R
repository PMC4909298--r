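#' Construct a per-subject trial response series
#'
#' A `trial_series` holds one subject's binary (correct/incorrect) responses,
#' organized into training sessions with 1-based, unit-spaced trial indices
#' within each session. Optional continuous per-trial covariates (e.g.
#' reaction time in seconds, a per-trial physiological scalar) ride along.
#'
#' @param subject_id character scalar identifying the subject.
#' @param session integer vector, session index (1-based) of every trial.
#' @param trial integer vector, trial index within its session (1-based,
#'   unit-spaced, starting at 1).
#' @param response integer/numeric vector of responses, each exactly 0 or 1.
#' @param covariates optional data frame of per-trial covariates with one row
#'   per trial (e.g. a `reaction_time` column).
#' @return An object of class `trial_series`.
#' @examples
#' s <- trial_series("R01", session = c(1, 1, 1), trial = 1:3,
#'                   response = c(1, 0, 1))
#' n_trials(s)
#' @export
trial_series <- function(subject_id, session, trial, response, covariates = NULL) {
  session <- as.integer(session)
  trial <- as.integer(trial)
  n <- length(session)
  if (length(trial) != n || length(response) != n)
    stop("'session', 'trial' and 'response' must have equal length", call. = FALSE)
  ord <- order(session, trial)
  session <- session[ord]; trial <- trial[ord]; response <- response[ord]
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n)
      stop("'covariates' must have one row per trial", call. = FALSE)
    covariates <- covariates[ord, , drop = FALSE]
    rownames(covariates) <- NULL
  }
  out <- structure(
    list(subject_id = as.character(subject_id)[1L],
         session = session, trial = trial,
         response = as.integer(response),
         covariates = covariates),
    class = "trial_series")
  validate_trial_series(out)
  out
}

#' @keywords internal
validate_trial_series <- function(x) {
  if (length(x$response) < 1L)
    stop("a trial series must contain at least one trial", call. = FALSE)
  bad <- which(!(x$response %in% c(0L, 1L)) | is.na(x$response))
  if (length(bad))
    stop(sprintf("response values must be 0 or 1; offending trial row(s): %s",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  for (s in unique(x$session)) {
    tt <- x$trial[x$session == s]
    if (length(tt) < 1L)
      stop(sprintf("session %d contains no trials", s), call. = FALSE)
    if (!identical(tt, seq_len(length(tt))))
      stop(sprintf(
        "trial indices in session %d must be 1, 2, ... (strictly increasing, unit-spaced)", s),
        call. = FALSE)
  }
  invisible(x)
}

#' @rdname trial_series
#' @param x a `trial_series`.
#' @export
n_trials <- function(x) UseMethod("n_trials")

#' @export
n_trials.trial_series <- function(x) length(x$response)

#' @export
print.trial_series <- function(x, ...) {
  cat(sprintf("<trial_series> subject %s: %d trials in %d session(s); %d correct\n",
              x$subject_id, n_trials(x), length(unique(x$session)),
              sum(x$response)))
  invisible(x)
}

# per-session trial counts, in session order
#' @keywords internal
session_lengths <- function(series) {
  as.integer(table(factor(series$session, levels = sort(unique(series$session)))))
}

#' Construct a multi-subject study dataset
#'
#' Bundles the per-subject series of one study. The population (grand-mean)
#' model requires a shared session layout: every subject must have the same
#' number of sessions with the same number of trials per session.
#'
#' @param series a list of [trial_series()] objects with distinct subject ids.
#' @return An object of class `study_dataset` with elements `series` (named
#'   list) and `layout` (list with `n_sessions`, `trials_per_session`).
#' @export
study_dataset <- function(series) {
  if (!length(series)) stop("'series' must contain at least one subject", call. = FALSE)
  ids <- vapply(series, function(s) s$subject_id, character(1))
  if (anyDuplicated(ids))
    stop("subject ids must be distinct", call. = FALSE)
  names(series) <- ids
  layouts <- lapply(series, session_lengths)
  ref <- layouts[[1L]]
  for (k in seq_along(layouts)) {
    if (!identical(layouts[[k]], ref))
      stop(sprintf("subject %s has a different session layout than subject %s",
                   ids[k], ids[1L]), call. = FALSE)
  }
  structure(list(series = series,
                 layout = list(n_sessions = length(ref), trials_per_session = ref)),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("<study_dataset> %d subject(s), %d session(s) x trials (%s)\n",
              length(x$series), x$layout$n_sessions,
              paste(x$layout$trials_per_session, collapse = ", ")))
  invisible(x)
}

#' Read per-trial records from a delimited text file
#'
#' Canonical format: comma-separated, UTF-8, header row, required columns
#' `subject`, `session`, `trial`, `response`; any further numeric columns
#' (e.g. `reaction_time`) are carried as per-trial covariates. Rows may be in
#' any order; they are sorted by (subject, session, trial).
#'
#' @param path path to the CSV file.
#' @param sep field separator (default `","`).
#' @return A [study_dataset()].
#' @export
read_trials <- function(path, sep = ",") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
  required <- c("subject", "session", "trial", "response")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("missing required column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  bad <- which(!(df$response %in% c(0, 1)) | is.na(df$response))
  if (length(bad))
    stop(sprintf("response outside {0,1} in data row(s): %s",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  key <- paste(df$subject, df$session, df$trial, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop(sprintf("duplicated (subject, session, trial) in data row(s): %s",
                 paste(utils::head(dup, 5L), collapse = ", ")), call. = FALSE)
  covcols <- setdiff(names(df), required)
  sers <- lapply(split(df, df$subject), function(d) {
    trial_series(d$subject[1L], d$session, d$trial, d$response,
                 covariates = if (length(covcols)) d[covcols] else NULL)
  })
  study_dataset(sers[order(names(sers))])
}

#' Write a study dataset to the canonical delimited format
#'
#' @param dataset a [study_dataset()].
#' @param path output file path.
#' @return Invisibly, the path written.
#' @export
write_trials <- function(dataset, path) {
  stopifnot(inherits(dataset, "study_dataset"))
  rows <- lapply(dataset$series, function(s) {
    d <- data.frame(subject = s$subject_id, session = s$session,
                    trial = s$trial, response = s$response,
                    stringsAsFactors = FALSE)
    if (!is.null(s$covariates)) d <- cbind(d, s$covariates)
    d
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# assemble the learning_curve data frame shared by the estimators
#' @keywords internal
new_learning_curve <- function(series, p_hat, ci_low, ci_high, eta_hat, v_eta,
                               model, window, alpha) {
  out <- data.frame(
    trial_global = seq_along(series$response),
    session = series$session,
    trial = series$trial,
    p_hat = p_hat, ci_low = ci_low, ci_high = ci_high,
    eta_hat = eta_hat, v_eta = v_eta)
  structure(out,
            class = c("learning_curve", "data.frame"),
            subject_id = series$subject_id,
            model = model, window = window, alpha = alpha)
}

#' @export
print.learning_curve <- function(x, ...) {
  cat(sprintf("<learning_curve> subject %s, model %s, window %d, alpha %g, %d trials\n",
              attr(x, "subject_id"), attr(x, "model"), attr(x, "window"),
              attr(x, "alpha"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat(sprintf("... %d more trials\n", nrow(x) - 6L))
  invisible(x)
}

#' Write a learning curve to a delimited text file
#'
#' Columns: `trial` (global index), `session`, `trial_in_session`, `p_hat`,
#' `ci_low`, `ci_high`, `eta_hat`, `v_eta`, `model`, `window`. Values are
#' written with full double precision (15 significant digits).
#'
#' @param curve a `learning_curve` as returned by [constant_model_curve()] or
#'   [glm_curve()].
#' @param path output file path.
#' @return Invisibly, the path written.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "learning_curve"))
  df <- data.frame(trial = curve$trial_global, session = curve$session,
                   trial_in_session = curve$trial,
                   p_hat = curve$p_hat, ci_low = curve$ci_low,
                   ci_high = curve$ci_high, eta_hat = curve$eta_hat,
                   v_eta = curve$v_eta,
                   model = rep(attr(curve, "model"), nrow(curve)),
                   window = rep(attr(curve, "window"), nrow(curve)))
  utils::write.csv(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a learning curve written by [write_curve()]
#'
#' @param path path to the curve CSV.
#' @return A data frame with the curve columns (numeric columns restored).
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
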