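#' Weights of the composite negative-symptom proxy
#'
#' The imaging proxy for negative symptoms is a weighted sum of the
#' cortical change (BOLD readout) and the ventral-striatal change
#' (population activity), with the published 40/60 weighting as the
#' default.
#'
#' @param w_cortical,w_striatal Non-negative weights (sum > 0).
#' @return An object of class `readout_weights`.
#' @export
readout_weights <- function(w_cortical = 0.4, w_striatal = 0.6) {
  if (w_cortical < 0 || w_striatal < 0) stop("weights must be >= 0")
  if (w_cortical + w_striatal <= 0) stop("weights must sum to > 0")
  structure(list(w_cortical = w_cortical, w_striatal = w_striatal),
            class = "readout_weights")
}

#' Composite negative-symptom proxy
#'
#' `w_cortical * cortical_change + w_striatal * striatal_change`:
#' linear in both arguments.
#'
#' @param cortical_change Change in the cortical BOLD readout.
#' @param striatal_change Change in ventral-striatal activity.
#' @param w A [readout_weights] object.
#' @return The proxy value (vectorised).
#' @export
composite_readout <- function(cortical_change, striatal_change,
                              w = readout_weights()) {
  stopifnot(inherits(w, "readout_weights"))
  if (any(!is.finite(cortical_change)) || any(!is.finite(striatal_change))) {
    stop("inputs must be finite")
  }
  w$w_cortical * cortical_change + w$w_striatal * striatal_change
}

#' Pool replicate trials of one drug-dose combination
#'
#' When the same drug-dose is reported by several trials, the pooled
#' outcome is the patient-count-weighted mean and the counts sum.
#'
#' @param dpanss Observed PANSS-negative changes (points).
#' @param n Patient counts (>= 1), same length.
#' @return A list with `dpanss` (pooled change) and `n` (total
#'   patients).
#' @export
pool_replicates <- function(dpanss, n) {
  if (length(dpanss) == 0L) stop("no records to pool")
  if (length(n) != length(dpanss)) stop("'n' must match 'dpanss'")
  if (any(n < 1)) stop("patient counts must be >= 1")
  list(dpanss = sum(dpanss * n) / sum(n), n = sum(n))
}

#' Calibrate the proxy against clinical PANSS-negative outcomes
#'
#' Least-squares linear fit of observed PANSS-negative change on the
#' model proxy (optionally weighted by patient count), with the Pearson
#' correlation as the headline diagnostic. A linear map is used because
#' the published calibration is presented as a scatter of model outcome
#' against clinical change.
#'
#' @param proxies Model proxy per trial.
#' @param outcomes Observed PANSS-negative change per trial (points).
#' @param n Optional patient counts for a weighted fit.
#' @param weighted Use `n` as least-squares weights?
#' @return An object of class `calibration_map`: a list with `slope`,
#'   `intercept`, `r` (Pearson), `n_trials`, `residuals` and `fitted`.
#' @export
calibrate <- function(proxies, outcomes, n = NULL, weighted = FALSE) {
  if (length(proxies) < 3L) stop("need at least 3 trials to calibrate")
  if (length(outcomes) != length(proxies)) {
    stop("'outcomes' must match 'proxies'")
  }
  if (stats::sd(proxies) == 0) {
    stop("zero variance in proxies: cannot fit")
  }
  w <- if (weighted) {
    if (is.null(n)) stop("'n' required for a weighted fit")
    n
  } else {
    NULL
  }
  fit <- stats::lm(outcomes ~ proxies, weights = w)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = stats::cor(proxies, outcomes),
                 n_trials = length(proxies),
                 # a noise-free fit triggers summary.lm's perfect-fit
                 # warning; the zero SE itself is meaningful here
                 slope_se = suppressWarnings(
                   summary(fit)$coefficients[2, 2]),
                 residuals = unname(stats::residuals(fit)),
                 fitted = unname(stats::fitted(fit))),
            class = "calibration_map")
}

#' @export
print.calibration_map <- function(x, ...) {
  cat(sprintf(
    "PANSS-negative calibration: slope %.4g, intercept %.4g, r = %.3f (n = %d)\n",
    x$slope, x$intercept, x$r, x$n_trials))
  invisible(x)
}

#' Predict PANSS-negative change from a model proxy
#'
#' @param proxy Model proxy value(s).
#' @param map A [calibration_map] from [calibrate].
#' @return Predicted PANSS-negative change (points).
#' @export
predict_panss_change <- function(proxy, map) {
  if (!inherits(map, "calibration_map")) {
    stop("'map' must be a calibration_map from calibrate()")
  }
  map$slope * proxy + map$intercept
}

#' Write a calibration report as JSON
#'
#' @param map A [calibration_map].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration_report <- function(map, path) {
  jsonlite::write_json(unclass(map), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a trial database from delimited text
#'
#' Columns: `drug`, `dose`, `d2_occupancy` (fraction, may be NA),
#' `dpanss_neg` (points), `n` (patients).
#'
#' @param path Path to a tab-delimited file.
#' @return A data frame of class `trial_database`.
#' @export
read_trial_database <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("drug", "dose", "dpanss_neg", "n")
  if (!all(need %in% names(x))) {
    stop("trial database needs columns: ", paste(need, collapse = ", "))
  }
  if (any(x$n < 1)) stop("patient counts must be >= 1")
  if (any(x$dose <= 0)) stop("doses must be > 0")
  class(x) <- unique(c("trial_database", class(x)))
  x
}

#' Write a trial database as delimited text
#'
#' @param x A trial database data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_database <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
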