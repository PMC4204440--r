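#' Synaptic context for steady-state receptor competition
#'
#' Describes the endogenous neurotransmitter side of one receptor
#' population: its free concentration and affinity at the postsynaptic
#' receptor, and an optional presynaptic autoreceptor feedback. When
#' `feedback_gain` is non-zero, release is scaled down as autoreceptor
#' activation rises above its drug-free baseline (negative-feedback
#' autoreceptors), solved by fixed-point iteration.
#'
#' Neurotransmitter baselines and feedback gains are synapse-specific
#' user data, not shipped constants.
#'
#' @param nt_conc Free neurotransmitter concentration (nM), > 0.
#' @param nt_ki Neurotransmitter affinity at the receptor (nM), > 0.
#' @param feedback_gain Fractional release change per unit change in
#'   autoreceptor activation (>= 0; 0 disables feedback).
#' @param autoreceptor_ki Neurotransmitter affinity at the presynaptic
#'   autoreceptor (nM); defaults to `nt_ki`.
#' @return An object of class `synapse_context`.
#' @export
synapse_context <- function(nt_conc, nt_ki, feedback_gain = 0,
                            autoreceptor_ki = nt_ki) {
  stopifnot(nt_conc > 0, nt_ki > 0, autoreceptor_ki > 0,
            feedback_gain >= 0)
  structure(list(nt_conc = nt_conc, nt_ki = nt_ki,
                 feedback_gain = feedback_gain,
                 autoreceptor_ki = autoreceptor_ki),
            class = "synapse_context")
}

# mass-action competitive occupancies for a set of ligands
# conc, ki vectors -> list(occ (per ligand), free)
.competitive_occupancy <- function(conc, ki) {
  ratio <- conc / ki
  denom <- 1 + sum(ratio)
  list(occ = ratio / denom, free = 1 / denom)
}

#' Steady-state receptor activation under competitive binding
#'
#' Mass-action competition between the endogenous neurotransmitter
#' (intrinsic activity 1) and up to four agents at one receptor:
#' each ligand occupies `(C/Ki) / (1 + sum C_j/Ki_j)` of the receptor
#' pool and contributes occupancy times intrinsic activity to the
#' activation. With a non-zero autoreceptor feedback gain the release
#' (hence free neurotransmitter) is iterated to a fixed point
#' (tolerance 1e-8).
#'
#' @param ctx A [synapse_context].
#' @param drugs A data frame (or list of lists) with columns
#'   `concentration` (nM), `ki` (nM) and `intrinsic_activity`
#'   (0 = neutral antagonist, 1 = full agonist); at most 4 rows.
#' @return A list with `activation` (fraction), `occupancy` (named
#'   vector: neurotransmitter, each drug, free receptor) and
#'   `release_scale` (1 without feedback).
#' @examples
#' ctx <- synapse_context(nt_conc = 10, nt_ki = 10)
#' steady_state_activation(ctx, data.frame(concentration = 100, ki = 10,
#'                                         intrinsic_activity = 0))
#' @export
steady_state_activation <- function(ctx, drugs = NULL) {
  stopifnot(inherits(ctx, "synapse_context"))
  if (is.null(drugs) || NROW(drugs) == 0L) {
    drugs <- data.frame(concentration = numeric(0), ki = numeric(0),
                        intrinsic_activity = numeric(0))
  }
  drugs <- as.data.frame(drugs)
  if (nrow(drugs) > 4L) stop("at most 4 competing agents are supported")
  if (any(drugs$ki <= 0)) stop("drug ki must be > 0")
  if (any(drugs$concentration < 0)) stop("drug concentrations must be >= 0")
  if (any(drugs$intrinsic_activity < 0 | drugs$intrinsic_activity > 1)) {
    stop("intrinsic_activity must be in [0, 1]")
  }

  eval_at <- function(release) {
    nt <- ctx$nt_conc * release
    occ <- .competitive_occupancy(c(nt, drugs$concentration),
                                  c(ctx$nt_ki, drugs$ki))
    act <- occ$occ[1] * 1 +
      sum(occ$occ[-1] * drugs$intrinsic_activity)
    list(occ = occ, activation = act, nt = nt)
  }
  auto_act <- function(release) {
    nt <- ctx$nt_conc * release
    occ <- .competitive_occupancy(c(nt, drugs$concentration),
                                  c(ctx$autoreceptor_ki, drugs$ki))
    occ$occ[1] + sum(occ$occ[-1] * drugs$intrinsic_activity)
  }

  release <- 1
  if (ctx$feedback_gain > 0) {
    baseline <- {
      occ0 <- .competitive_occupancy(ctx$nt_conc, ctx$autoreceptor_ki)
      occ0$occ[1]
    }
    for (iter in seq_len(500L)) {
      new <- max(0, 1 - ctx$feedback_gain * (auto_act(release) - baseline))
      if (abs(new - release) < 1e-8) { release <- new; break }
      release <- (release + new) / 2  # damped update
      if (iter == 500L) stop("autoreceptor feedback did not converge")
    }
  }

  res <- eval_at(release)
  occ <- c(res$occ$occ, res$occ$free)
  names(occ) <- c("neurotransmitter",
                  if (nrow(drugs)) paste0("drug", seq_len(nrow(drugs))),
                  "free")
  list(activation = res$activation, occupancy = occ,
       release_scale = release)
}

#' Relative activation of a receptor under treatment
#'
#' The normalised change `(activated - control) / control`: the
#' dimensionless interface between the pharmacology layer and the
#' circuit models (a value of -0.3 means the receptor runs at 70% of
#' its untreated activation).
#'
#' @param activated Activation under treatment, finite.
#' @param control Untreated (placebo) activation, > 0.
#' @return The relative activation (dimensionless, > -1 whenever
#'   `activated` > 0).
#' @export
relative_effect <- function(activated, control) {
  if (any(control <= 0)) stop("'control' must be > 0")
  (activated - control) / control
}

#' Free drug concentration producing a target receptor occupancy
#'
#' Inverts the competitive-binding relation for a single drug at a
#' receptor, given neurotransmitter competition, so that PET-style
#' occupancy measurements (e.g. D2 occupancy from raclopride
#' displacement) can be converted into the functional intrasynaptic
#' drug concentration. Without autoreceptor feedback the closed form is
#' `C = ki * occ * (1 + NT/KiNT) / (1 - occ)`; with feedback the
#' inversion is solved numerically against the forward model so the
#' round trip holds to 1e-6.
#'
#' @param target_occupancy Desired drug occupancy, in (0, 1).
#' @param ki Drug affinity at the receptor (nM).
#' @param ctx A [synapse_context]; use a very large `nt_ki` (or tiny
#'   `nt_conc`) for a competition-free inversion.
#' @param intrinsic_activity Drug intrinsic activity (affects feedback
#'   only).
#' @return Free drug concentration (nM).
#' @export
occupancy_to_concentration <- function(target_occupancy, ki, ctx,
                                       intrinsic_activity = 0) {
  stopifnot(inherits(ctx, "synapse_context"), ki > 0)
  if (target_occupancy <= 0 || target_occupancy >= 1) {
    stop("'target_occupancy' must be in (0, 1)")
  }
  closed <- ki * target_occupancy *
    (1 + ctx$nt_conc / ctx$nt_ki) / (1 - target_occupancy)
  if (ctx$feedback_gain == 0) return(closed)
  f <- function(logc) {
    d <- data.frame(concentration = exp(logc), ki = ki,
                    intrinsic_activity = intrinsic_activity)
    steady_state_activation(ctx, d)$occupancy[["drug1"]] -
      target_occupancy
  }
  root <- stats::uniroot(f, lower = log(closed) - 20,
                         upper = log(closed) + 20, tol = 1e-12)
  exp(root$root)
}

#' Read a drug-receptor affinity table
#'
#' Delimited text with header `drug,receptor,ki_nM,intrinsic_activity`
#' (PDSP-style binding affinities; intrinsic activity defaults to 0,
#' i.e. neutral antagonism, when the column is absent).
#'
#' @param path Path to a comma-delimited file.
#' @return A data frame of class `affinity_profile`.
#' @export
read_affinity_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("drug", "receptor", "ki_nM")
  if (!all(need %in% names(x))) {
    stop("affinity table needs columns: ", paste(need, collapse = ", "))
  }
  if (is.null(x$intrinsic_activity)) x$intrinsic_activity <- 0
  if (any(x$ki_nM <= 0)) stop("ki_nM must be > 0")
  class(x) <- unique(c("affinity_profile", class(x)))
  x
}

#' Write a drug-receptor affinity table
#'
#' @param x An affinity table (see [read_affinity_table]).
#' @param path Output path (comma-delimited).
#' @return `path`, invisibly.
#' @export
write_affinity_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
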