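#' Inward-rectifier (Kir2) channel parameters
#'
#' Boltzmann-gated K+ conductance of the medium spiny neuron with the
#' printed sign convention: with sensitivity `v_c = -11` mV the
#' conductance decreases with depolarisation (inward rectification) and
#' equals half its maximum exactly at `v_h`.
#'
#' @param g_bar Maximal conductance (mS/cm2), default 1.2.
#' @param e_k K+ reversal potential (mV), default -90.
#' @param v_h Half-activation potential (mV), default -111.
#' @param v_c Sensitivity (mV), default -11; must be non-zero.
#' @return An object of class `kir_params`.
#' @export
kir_params <- function(g_bar = 1.2, e_k = -90, v_h = -111, v_c = -11) {
  if (g_bar <= 0) stop("'g_bar' must be > 0")
  if (v_c == 0) stop("'v_c' must be non-zero")
  structure(list(g_bar = g_bar, e_k = e_k, v_h = v_h, v_c = v_c),
            class = "kir_params")
}

#' Dopamine-modulated inward-rectifier current
#'
#' `I = u * g(v) * (v - e_k)` with
#' `g(v) = g_bar / (1 + exp(-(v - v_h)/v_c))`. The D1 activation scale
#' `u` multiplies the whole current: D1 signalling up-regulates Kir2 in
#' the substance-P (direct pathway) cells, stabilising the
#' hyperpolarised down-state.
#'
#' @param v Membrane potential (mV). Vectorised.
#' @param u D1 activation scale, >= 0.
#' @param p A [kir_params] object.
#' @return Current (uA/cm2), same length as `v`.
#' @examples
#' kir2_current(-111, u = 1)  # half-activated: 0.6 * (-21) = -12.6
#' @export
kir2_current <- function(v, u = 1, p = kir_params()) {
  stopifnot(inherits(p, "kir_params"))
  if (u < 0) stop("'u' must be >= 0")
  g <- p$g_bar / (1 + exp(-(v - p$v_h) / p$v_c))
  u * g * (v - p$e_k)
}

#' Medium spiny neuron parameters
#'
#' Channel set of Eq-style MSN membrane dynamics: inward rectifier
#' (Kir2), A-type K+, slow K+, Cl-, and L-type Ca++ currents on top of
#' standard spike-generating Na+/K+ currents, driven by cortical
#' glutamatergic afferents gated by hippocampal/amygdala input. Channel
#' kinetics other than Kir2 are standard textbook formulations
#' (documented assumptions); densities below are the recorded package
#' defaults.
#'
#' The three striatal cell classes differ in their neuromodulatory
#' couplings: `SP_D1` (substance-P+, direct pathway) carries D1
#' couplings on Kir2 and L-type Ca++; `Enk_D2` (enkephalin+, indirect
#' pathway) carries D2 couplings on the A-type K+ current and on
#' presynaptic glutamate release; `dual` carries both.
#'
#' @param cell_class `"SP_D1"`, `"Enk_D2"`, or `"dual"`.
#' @param c_m Membrane capacitance (uF/cm2), > 0.
#' @param kir A [kir_params] object.
#' @param g_na,g_kdr Spike-current densities (mS/cm2).
#' @param g_ka A-type K+ density (mS/cm2).
#' @param g_ksi Slow K+ density (mS/cm2).
#' @param g_cl,e_cl Cl- conductance (mS/cm2) and reversal (mV).
#' @param g_ca,e_ca L-type Ca++ conductance (mS/cm2) and reversal (mV).
#' @param drive_gain Synaptic gain on the cortical drive.
#' @param modulation_gains Named list of linear modulation gains
#'   (defaults 0.5 each); these are calibration targets, not constants.
#' @return An object of class `msn_params`.
#' @export
msn_params <- function(cell_class = c("SP_D1", "Enk_D2", "dual"),
                       c_m = 1, kir = kir_params(),
                       g_na = 35, g_kdr = 9,
                       g_ka = 2.5, g_ksi = 0.3,
                       g_cl = 0.08, e_cl = -60,
                       g_ca = 0.06, e_ca = 120,
                       drive_gain = 1,
                       modulation_gains = list(d1_ca = 0.5, d2_ka = 0.5,
                                               d2_glu = 0.5, m1_cl = 0.5,
                                               m2_drive = 0.5,
                                               alpha1a_gate = 0.5)) {
  cell_class <- match.arg(cell_class)
  if (c_m <= 0) stop("'c_m' must be > 0")
  structure(list(cell_class = cell_class, c_m = c_m, kir = kir,
                 g_na = g_na, g_kdr = g_kdr, g_ka = g_ka, g_ksi = g_ksi,
                 g_cl = g_cl, e_cl = e_cl, g_ca = g_ca, e_ca = e_ca,
                 drive_gain = drive_gain,
                 modulation_gains = modulation_gains),
            class = "msn_params")
}

#' Neuromodulatory state driving the striatal model
#'
#' Relative activations (fractional change vs untreated control, see
#' [relative_effect]) of the receptors that modulate the medium spiny
#' neuron and its afferents. All values default to 0 (no change).
#'
#' @param D1,D2,M1,M2,`5HT2C`,`5HT3`,alpha1A Relative activations,
#'   each > -1.
#' @return An object of class `modulation_state`.
#' @export
modulation_state <- function(D1 = 0, D2 = 0, M1 = 0, M2 = 0,
                             `5HT2C` = 0, `5HT3` = 0, alpha1A = 0) {
  vals <- c(D1 = D1, D2 = D2, M1 = M1, M2 = M2, `5HT2C` = `5HT2C`,
            `5HT3` = `5HT3`, alpha1A = alpha1A)
  if (any(vals <= -1)) stop("relative activations must be > -1")
  structure(as.list(vals), class = "modulation_state")
}

#' Dopamine release scale from serotonergic modulation
#'
#' Striatal dopamine release rises linearly as 5-HT2C activation falls
#' (5-HT2C inhibition disinhibits release) and falls as 5-HT3
#' activation falls (5-HT3 antagonism decreases release):
#' `1 - k_2c * d5HT2C + k_3 * d5HT3`, clipped at 0.
#'
#' @param m A [modulation_state].
#' @param k_2c,k_3 Linear gains (defaults 0.5; calibration targets).
#' @return Dopamine release scale factor (>= 0).
#' @examples
#' dopamine_release_scale(modulation_state(`5HT2C` = -0.2))  # 1.10
#' @export
dopamine_release_scale <- function(m, k_2c = 0.5, k_3 = 0.5) {
  stopifnot(inherits(m, "modulation_state"))
  max(0, 1 + k_2c * (-m$`5HT2C`) + k_3 * m$`5HT3`)
}

#' Simulate one medium spiny neuron
#'
#' Integrates the MSN membrane equation with the class-appropriate
#' neuromodulation: in `SP_D1` cells D1 activation scales the Kir2
#' current (`u = 1 + D1`) and the L-type Ca++ conductance; in `Enk_D2`
#' cells D2 activation scales the A-type K+ current and reduces
#' presynaptic glutamate release; `dual` cells carry both. M1 scales
#' the Cl- conductance; M2 reduces the afferent drive; alpha1A scales
#' the hippocampal/amygdala gating drive. Deterministic given `seed`.
#'
#' @param p An [msn_params] object.
#' @param cortical_drive Cortical glutamatergic drive (relative
#'   conductance), sampled at `dt`.
#' @param gating_drive Hippocampal/amygdala gate multiplying the drive
#'   efficacy; defaults to an always-open gate of 1.
#' @param m A [modulation_state].
#' @param dt Integration step (ms), <= 0.05.
#' @param duration Simulated time (ms).
#' @param seed Integer seed for the background noise.
#' @param noise_rate,noise_amp Background Poisson conductance noise.
#' @param record_stride Keep every `record_stride`-th voltage sample.
#' @return A list with `trace` (data frame `time_ms`, `v_mV`),
#'   `spike_times`, `spike_count`, `rate_hz` and `excitability`
#'   (spike rate in Hz).
#' @export
simulate_msn <- function(p, cortical_drive, gating_drive = NULL,
                         m = modulation_state(), dt = 0.025,
                         duration = NULL, seed = 1L,
                         noise_rate = 0, noise_amp = 0.02,
                         record_stride = 40L) {
  stopifnot(inherits(p, "msn_params"), inherits(m, "modulation_state"))
  if (dt <= 0 || dt > 0.05) stop("'dt' must be in (0, 0.05] ms")
  n <- length(cortical_drive)
  if (is.null(duration)) duration <- n * dt
  if (is.null(gating_drive)) gating_drive <- rep(1, n)
  if (length(gating_drive) != n) {
    stop("'gating_drive' must match 'cortical_drive' in length")
  }
  g <- p$modulation_gains
  kir_u <- 1
  g_ka <- p$g_ka
  g_ca <- p$g_ca
  presyn <- 1
  if (p$cell_class %in% c("SP_D1", "dual")) {
    kir_u <- max(0, 1 + m$D1)
    g_ca <- g_ca * max(0, 1 + g$d1_ca * m$D1)
  }
  if (p$cell_class %in% c("Enk_D2", "dual")) {
    g_ka <- g_ka * max(0, 1 + g$d2_ka * m$D2)
    presyn <- presyn * max(0, 1 - g$d2_glu * m$D2)
  }
  g_cl <- p$g_cl * max(0, 1 + g$m1_cl * m$M1)
  drive_scale <- presyn * max(0, 1 - g$m2_drive * m$M2)
  gate_scale <- max(0, 1 + g$alpha1a_gate * m$alpha1A)

  set.seed(seed)
  res <- .sim_msn_cpp(dt, duration,
                      drive_scale * cortical_drive,
                      gate_scale * gating_drive,
                      p$c_m, p$g_na, p$g_kdr,
                      p$kir$g_bar, kir_u, p$kir$e_k, p$kir$v_h,
                      p$kir$v_c, g_ka, p$g_ksi, g_cl, p$e_cl,
                      g_ca, p$e_ca, p$drive_gain,
                      noise_rate, noise_amp, as.integer(record_stride))
  rate <- res$n_spikes / (duration / 1000)
  list(trace = data.frame(time_ms = res$trace_time, v_mV = res$trace_v),
       spike_times = res$spike_times, spike_count = res$n_spikes,
       rate_hz = rate, mean_v = res$mean_v, excitability = rate)
}

#' Population readout of the ventral striatum
#'
#' Weighted mean of a firing measure across the three MSN classes. The
#' combination rule is a documented package choice (the composite
#' striatal activity entering the negative-symptom proxy); weights
#' default to equal.
#'
#' @param cells A list of [simulate_msn] results.
#' @param classes Character vector of cell classes, one per cell.
#' @param weights Named class weights (default equal).
#' @param measure Which field of each cell result to average
#'   (default `"excitability"`).
#' @return Scalar population activity.
#' @export
striatal_population_readout <- function(cells, classes,
                                        weights = NULL,
                                        measure = "excitability") {
  if (length(cells) == 0L) stop("empty MSN population")
  if (length(classes) != length(cells)) {
    stop("'classes' must name one class per cell")
  }
  lev <- unique(classes)
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(lev)), lev)
  if (!all(lev %in% names(weights))) stop("missing class weight(s)")
  vals <- vapply(cells, function(x) x[[measure]], numeric(1))
  per_class <- vapply(lev, function(cl) mean(vals[classes == cl]),
                      numeric(1))
  w <- weights[lev]
  sum(w * per_class) / sum(w)
}
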