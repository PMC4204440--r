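#' Published sensitivity rows for the calibrated model
#'
#' The bundled transcription of the published range-based sensitivity
#' analysis: for each parameter, the fractional sweep range and the
#' extreme relative changes (%) of the model outcome, plus the reported
#' effect size. One row (GABA reduction) does not satisfy the stated
#' effect-size formula; it is shipped as printed, not corrected.
#'
#' @return A data frame with columns `group`, `parameter`, `lo_frac`,
#'   `hi_frac`, `min_effect_pct`, `max_effect_pct`,
#'   `reported_effect_size`.
#' @export
sensitivity_reference_rows <- function() {
  utils::read.delim(system.file("extdata",
                                "pathology_sensitivity_rows.tsv",
                                package = "glyqsp", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' Range-based sensitivity effect size
#'
#' The difference between the maximum and minimum relative outcome
#' changes (as fractions) divided by the fractional parameter range:
#' `((max_pct - min_pct)/100) / (hi_frac - lo_frac)`.
#'
#' @param min_pct,max_pct Extreme relative outcome changes (%).
#' @param lo_frac,hi_frac Fractional parameter excursions
#'   (e.g. -0.2 and +0.2 for a +/-20% sweep); `hi_frac > lo_frac`.
#' @return Dimensionless effect size.
#' @examples
#' effect_size(-37.7, 18.2, -0.20, 0.20)  # 1.398
#' @export
effect_size <- function(min_pct, max_pct, lo_frac, hi_frac) {
  if (hi_frac <= lo_frac) stop("'hi_frac' must exceed 'lo_frac'")
  ((max_pct - min_pct) / 100) / (hi_frac - lo_frac)
}

#' Specification of one parameter sweep
#'
#' @param parameter Dot-addressed configuration key
#'   (e.g. `"pd.ee.ec50"` or `"network.g_gaba_ie"`).
#' @param lo_frac,hi_frac Fractional excursions around the calibrated
#'   value; `lo_frac < hi_frac`.
#' @param n Number of evenly spaced settings (>= 2).
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(parameter, lo_frac, hi_frac, n = 5) {
  if (lo_frac >= hi_frac) stop("'lo_frac' must be < 'hi_frac'")
  if (n < 2) stop("'n' must be >= 2")
  structure(list(parameter = parameter, lo_frac = lo_frac,
                 hi_frac = hi_frac, n = as.integer(n)),
            class = "sweep_spec")
}

# resolve/assign a dot-addressed key in a nested list
.get_path <- function(x, path) {
  for (k in strsplit(path, ".", fixed = TRUE)[[1]]) {
    if (is.null(x[[k]])) stop("config error: cannot resolve '", path, "'")
    x <- x[[k]]
  }
  x
}

.set_path <- function(x, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(keys) == 1L) {
    if (is.null(x[[keys]])) stop("config error: cannot resolve '", path, "'")
    x[[keys]] <- value
    return(x)
  }
  head <- keys[1]
  if (is.null(x[[head]])) stop("config error: cannot resolve '", path, "'")
  x[[head]] <- .set_path(x[[head]], paste(keys[-1], collapse = "."),
                         value)
  x
}

#' Sweep one model parameter and summarise its effect
#'
#' Evaluates a scalar model outcome at `n` settings of one parameter,
#' fractionally displaced around its calibrated value, and reports the
#' extreme relative changes and the range-based [effect_size]. The
#' model bundle decouples the sweep machinery from any particular
#' outcome: `bundle$config` is a nested configuration list and
#' `bundle$outcome` a function mapping a configuration to a scalar
#' (e.g. the calibrated PANSS proxy at the dose-response optimum, or a
#' raw cortical readout).
#'
#' @param bundle A list with elements `config` (nested list) and
#'   `outcome` (function of the config returning a scalar).
#' @param spec A [sweep_spec].
#' @return A one-row data frame of class `sensitivity_row` with the
#'   parameter, sweep range, `min_effect_pct`, `max_effect_pct` and
#'   `effect_size`, plus attribute `grid` holding the per-setting
#'   outcomes.
#' @export
run_sweep <- function(bundle, spec) {
  stopifnot(inherits(spec, "sweep_spec"), is.function(bundle$outcome))
  base_val <- .get_path(bundle$config, spec$parameter)
  if (!is.numeric(base_val) || length(base_val) != 1L) {
    stop("config error: '", spec$parameter,
         "' does not address a scalar numeric parameter")
  }
  base_out <- bundle$outcome(bundle$config)
  if (base_out == 0) stop("calibrated outcome is 0: relative changes undefined")
  fracs <- seq(spec$lo_frac, spec$hi_frac, length.out = spec$n)
  outs <- vapply(fracs, function(fr) {
    cfg <- .set_path(bundle$config, spec$parameter,
                     base_val * (1 + fr))
    bundle$outcome(cfg)
  }, numeric(1))
  pct <- 100 * (outs - base_out) / abs(base_out)
  row <- data.frame(parameter = spec$parameter,
                    lo_frac = spec$lo_frac, hi_frac = spec$hi_frac,
                    min_effect_pct = min(pct),
                    max_effect_pct = max(pct),
                    effect_size = effect_size(min(pct), max(pct),
                                              spec$lo_frac,
                                              spec$hi_frac))
  attr(row, "grid") <- data.frame(frac = fracs, outcome = outs,
                                  pct_change = pct)
  class(row) <- c("sensitivity_row", class(row))
  row
}

#' Write sensitivity rows as delimited text plus JSON
#'
#' @param rows A data frame of sensitivity rows (rbind of [run_sweep]
#'   results).
#' @param path Output path for the tab-delimited table; a `.json`
#'   twin is written alongside.
#' @return `path`, invisibly.
#' @export
write_sensitivity_table <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(rows, paste0(path, ".json"), digits = NA)
  invisible(path)
}
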