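#' Hill parameters for glycine potentiation of one NMDA synapse class
#'
#' Glycine potentiation of the NMDA current through a given NR2 subunit
#' class is saturable and well described by a Hill relation
#' \eqn{g = g_{max} \, [Gly]^n / ([Gly]^n + EC_{50}^n)}. A `hill_params`
#' object holds the concentration of half-maximal potentiation and the
#' Hill coefficient for one synapse class.
#'
#' @param ec50 Glycine concentration of half-maximal potentiation (uM), > 0.
#' @param slope Hill coefficient (dimensionless), > 0.
#' @return An object of class `hill_params`.
#' @examples
#' hill_params(ec50 = 0.35, slope = 1.84)
#' @export
hill_params <- function(ec50, slope) {
  stopifnot(is.numeric(ec50), length(ec50) == 1L, is.finite(ec50),
            is.numeric(slope), length(slope) == 1L, is.finite(slope))
  if (ec50 <= 0) stop("'ec50' must be > 0")
  if (slope <= 0) stop("'slope' must be > 0")
  structure(list(ec50 = ec50, slope = slope), class = "hill_params")
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf("Hill parameters: EC50 = %g uM, slope = %g\n", x$ec50, x$slope))
  invisible(x)
}

as_hill_params <- function(x) {
  if (inherits(x, "hill_params")) return(x)
  if (is.list(x) || is.numeric(x)) return(hill_params(x[["ec50"]], x[["slope"]]))
  stop("cannot interpret as hill_params")
}

#' Fractional Hill activation of the glycine co-agonist site
#'
#' Evaluates \eqn{[Gly]^n / ([Gly]^n + EC_{50}^n)}: the fraction of maximal
#' NMDA potentiation at extracellular glycine concentration `gly`. Zero at
#' zero glycine, exactly 0.5 at `ec50`, strictly increasing, and bounded
#' below 1.
#'
#' @param gly Extracellular glycine (uM), >= 0. Vectorised.
#' @param p A [hill_params] object.
#' @return Activation fraction in `[0, 1)`, same length as `gly`.
#' @examples
#' hill_activation(1.1, hill_params(0.25, 1.1))
#' @export
hill_activation <- function(gly, p) {
  p <- as_hill_params(p)
  stopifnot(is.numeric(gly))
  if (any(!is.finite(gly)) || any(gly < 0)) {
    stop("'gly' must be finite and >= 0")
  }
  # evaluate on the log scale to keep large powers finite
  gn <- gly^p$slope
  gn / (gn + p$ec50^p$slope)
}

#' Pharmacodynamics of the two cortical NMDA synapse classes
#'
#' Bundles the glycine Hill parameters of the pyramidal-pyramidal (e-e,
#' NR2A/B-dominated) and pyramidal-interneuron (e-i, NR2C/D-dominated)
#' synapse classes, their relative maximal conductances, and optional
#' Hill parameters for high-glycine receptor internalization (surface
#' expression loss with an EC50 around 40 uM).
#'
#' The two NR2 subunits within each class are lumped into a single Hill
#' pair, as in the reported simulations; the internalization slope
#' defaults to 1 when only an EC50 is supplied.
#'
#' @param ee,ei [hill_params] for the e-e and e-i classes.
#' @param gmax_ee,gmax_ei Relative maximal conductances, > 0.
#' @param internalization_ee,internalization_ei Optional [hill_params]
#'   (or a bare EC50, slope taken as 1) describing surface-expression
#'   loss at high glycine. `NULL` disables internalization.
#' @return An object of class `synapse_class_pd`.
#' @examples
#' pd <- synapse_class_pd(ee = hill_params(0.35, 1.84),
#'                        ei = hill_params(0.25, 1.1))
#' @export
synapse_class_pd <- function(ee, ei, gmax_ee = 1, gmax_ei = 1,
                             internalization_ee = NULL,
                             internalization_ei = NULL) {
  norm_int <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.numeric(x) && length(x) == 1L) return(hill_params(x, 1))
    as_hill_params(x)
  }
  stopifnot(gmax_ee > 0, gmax_ei > 0)
  structure(list(ee = as_hill_params(ee), ei = as_hill_params(ei),
                 gmax_ee = gmax_ee, gmax_ei = gmax_ei,
                 internalization_ee = norm_int(internalization_ee),
                 internalization_ei = norm_int(internalization_ei)),
            class = "synapse_class_pd")
}

#' @export
print.synapse_class_pd <- function(x, ...) {
  cat("NMDA synapse-class pharmacodynamics\n")
  cat(sprintf("  e-e: EC50 %g uM, slope %g, gmax %g\n",
              x$ee$ec50, x$ee$slope, x$gmax_ee))
  cat(sprintf("  e-i: EC50 %g uM, slope %g, gmax %g\n",
              x$ei$ec50, x$ei$slope, x$gmax_ei))
  if (!is.null(x$internalization_ee))
    cat(sprintf("  internalization e-e: EC50 %g uM, slope %g\n",
                x$internalization_ee$ec50, x$internalization_ee$slope))
  if (!is.null(x$internalization_ei))
    cat(sprintf("  internalization e-i: EC50 %g uM, slope %g\n",
                x$internalization_ei$ec50, x$internalization_ei$slope))
  invisible(x)
}

#' Effective relative NMDA conductance at a glycine concentration
#'
#' Glycine potentiation times (when configured) the surviving surface
#' fraction under high-glycine internalization:
#' `gmax * hill(gly) * (1 - hill_int(gly))`.
#'
#' @param gly Extracellular glycine (uM), >= 0. Vectorised.
#' @param class `"ee"` (pyramidal-pyramidal) or `"ei"`
#'   (pyramidal-interneuron).
#' @param pd A [synapse_class_pd] object.
#' @return Relative conductance (dimensionless), same length as `gly`.
#' @export
effective_conductance <- function(gly, class = c("ee", "ei"), pd) {
  class <- match.arg(class)
  stopifnot(inherits(pd, "synapse_class_pd"))
  gmax <- if (class == "ee") pd$gmax_ee else pd$gmax_ei
  act <- hill_activation(gly, pd[[class]])
  int <- pd[[paste0("internalization_", class)]]
  surv <- if (is.null(int)) 1 else 1 - hill_activation(gly, int)
  gmax * act * surv
}

#' Ratio of e-i over e-e NMDA potentiation
#'
#' The central mediator of the glycine dose-response: the ratio of the
#' fractional potentiation on pyramidal-interneuron synapses (NR2C/D)
#' over pyramidal-pyramidal synapses (NR2A/B). When the e-e class has a
#' steeper Hill slope the ratio passes through a minimum below 1 before
#' returning to 1 at saturating glycine, transiently tipping the circuit
#' towards excitation. Internalization factors are applied when
#' configured; relative `gmax` values are not (the ratio compares
#' fractional potentiation, not absolute conductance).
#'
#' @param gly Extracellular glycine (uM), strictly > 0 (the ratio is
#'   0/0 at zero glycine and the small-glycine limit can diverge).
#' @param pd A [synapse_class_pd] object.
#' @return Positive ratio, same length as `gly`.
#' @export
ei_over_ee_ratio <- function(gly, pd) {
  stopifnot(inherits(pd, "synapse_class_pd"))
  if (any(!is.finite(gly)) || any(gly <= 0)) {
    stop("'gly' must be finite and > 0 (ratio undefined at gly = 0)")
  }
  num <- hill_activation(gly, pd$ei)
  den <- hill_activation(gly, pd$ee)
  if (!is.null(pd$internalization_ei))
    num <- num * (1 - hill_activation(gly, pd$internalization_ei))
  if (!is.null(pd$internalization_ee))
    den <- den * (1 - hill_activation(gly, pd$internalization_ee))
  num / den
}

#' Locate the extremum of the e-i/e-e potentiation ratio
#'
#' Scans [ei_over_ee_ratio] on a log-spaced grid over `window` and
#' refines the bracketed minimum by golden-section search. The curves
#' are smooth and either monotone or unimodal over physiological
#' windows, so a moderately dense grid plus local refinement recovers
#' the minimum reliably; ties are broken towards the lowest glycine.
#'
#' @param pd A [synapse_class_pd] object.
#' @param window Length-2 window `c(lo, hi)` in uM, `0 < lo < hi`.
#' @param n_grid Number of log-spaced scan points (default 1000).
#' @param tol Relative bracket tolerance for the refinement.
#' @return A list with `gly_star` (uM), `ratio_star`, and
#'   `is_interior_minimum` (TRUE when the minimum lies strictly inside
#'   the window rather than on its boundary, and the curve is not flat).
#' @export
find_ratio_extremum <- function(pd, window = c(0.01, 100), n_grid = 1000,
                                tol = 1e-10) {
  stopifnot(length(window) == 2L, window[1] > 0, window[1] < window[2])
  grid <- exp(seq(log(window[1]), log(window[2]), length.out = n_grid))
  vals <- ei_over_ee_ratio(grid, pd)
  if (any(!is.finite(vals))) stop("non-finite ratio on the scan grid")
  i <- which.min(vals)  # which.min takes the first index: ties -> lowest gly
  interior <- i > 1L && i < n_grid
  if (!interior) {
    return(list(gly_star = grid[i], ratio_star = vals[i],
                is_interior_minimum = FALSE))
  }
  # golden-section refinement on log-concentration within the bracket
  f <- function(lg) ei_over_ee_ratio(exp(lg), pd)
  opt <- stats::optimize(f, lower = log(grid[i - 1L]),
                         upper = log(grid[i + 1L]), tol = tol)
  gly_star <- exp(opt$minimum)
  ratio_star <- opt$objective
  if (ratio_star > vals[i]) {  # guard: never worse than the grid point
    gly_star <- grid[i]
    ratio_star <- vals[i]
  }
  # a flat curve (identical classes) has no meaningful interior minimum
  flat <- (max(vals) - min(vals)) <= 1e-12 * max(abs(vals))
  dip <- min(vals[1], vals[n_grid]) - ratio_star > 1e-9 * abs(ratio_star)
  list(gly_star = gly_star, ratio_star = ratio_star,
       is_interior_minimum = !flat && dip)
}

#' Classify the shape of the glycine dose-response
#'
#' A parameter set is `beneficial_U` when the e-i/e-e ratio has an
#' interior minimum below 1 at a physiologically reachable glycine
#' concentration (0.5-10 uM by default), predicting an inverse U-shaped
#' clinical dose-response with an optimum there; it is
#' `subphysiological_minimum` when the minimum falls below the
#' reachable band; otherwise the ratio is monotone over the window.
#'
#' @param pd A [synapse_class_pd] object.
#' @param window Search window in uM (see [find_ratio_extremum]).
#' @param beneficial_band Glycine band (uM) within which an interior
#'   minimum counts as clinically reachable.
#' @param n_grid Scan density passed to [find_ratio_extremum].
#' @return One of `"beneficial_U"`, `"monotonic"`,
#'   `"subphysiological_minimum"`.
#' @export
classify_dose_response <- function(pd, window = c(0.01, 100),
                                   beneficial_band = c(0.5, 10),
                                   n_grid = 1000) {
  ext <- find_ratio_extremum(pd, window = window, n_grid = n_grid)
  if (!ext$is_interior_minimum) return("monotonic")
  if (ext$gly_star < beneficial_band[1]) return("subphysiological_minimum")
  if (ext$gly_star <= beneficial_band[2] && ext$ratio_star < 1) {
    return("beneficial_U")
  }
  "monotonic"
}

#' Count beneficial parameter combinations across EC50 grids
#'
#' Classifies every combination of e-i and e-e EC50 values at a series
#' of Hill-slope ratios (e-e slope / e-i slope) and tabulates the
#' classes. Used to map the region of parameter space predicting an
#' inverse U-shaped dose-response, which grows with the slope ratio.
#'
#' @param ec50_ei,ec50_ee Numeric grids of EC50 values (uM).
#' @param slope_ratios e-e over e-i Hill-slope ratios to evaluate.
#' @param slope_ei The (fixed) e-i Hill slope.
#' @param ... Passed to [classify_dose_response].
#' @return A data frame with one row per slope ratio and columns
#'   `slope_ratio`, `beneficial_U`, `monotonic`,
#'   `subphysiological_minimum`.
#' @export
classification_map <- function(ec50_ei, ec50_ee, slope_ratios,
                               slope_ei = 1, ...) {
  out <- lapply(slope_ratios, function(r) {
    cls <- vapply(ec50_ei, function(ci) {
      vapply(ec50_ee, function(ce) {
        pd <- synapse_class_pd(ee = hill_params(ce, slope_ei * r),
                               ei = hill_params(ci, slope_ei))
        classify_dose_response(pd, ...)
      }, character(1))
    }, character(length(ec50_ee)))
    data.frame(slope_ratio = r,
               beneficial_U = sum(cls == "beneficial_U"),
               monotonic = sum(cls == "monotonic"),
               subphysiological_minimum =
                 sum(cls == "subphysiological_minimum"))
  })
  do.call(rbind, out)
}
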