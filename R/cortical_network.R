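#' Default receptor-to-channel coupling table
#'
#' Couplings map a receptor's relative activation onto intrinsic
#' conductances of the cortical neurons. Dopamine D1 activation is
#' coupled to the slow K+ conductance (negative gain: D1 reduces the
#' slowly inactivating K+ current) and the high-voltage-activated Ca++
#' conductance (positive gain). The other receptors handled by the
#' pharmacology layer are accepted in the table but ship with zero
#' gain: coupling magnitudes are calibration data, not package
#' constants.
#'
#' @return A data frame with columns `receptor`, `target`, `gain`.
#' @export
default_receptor_couplings <- function() {
  zero <- c("D2", "5HT1A", "5HT2A", "5HT2C", "5HT3", "M1", "M2",
            "alpha1A", "alpha2A")
  rbind(
    data.frame(receptor = "D1", target = c("g_ks_exc", "g_hva_exc"),
               gain = c(-0.5, 0.5)),
    data.frame(receptor = zero, target = "g_ks_exc", gain = 0)
  )
}

#' Configuration of the cortical excitatory-inhibitory network
#'
#' A conductance-based circuit of 20 pyramidal cells and 10 fast-spiking
#' interneurons. Recurrent AMPA and NMDA synapses drive both
#' populations; the NMDA conductance is split by synapse class (e-e vs
#' e-i) because glycine potentiates the two classes differently;
#' interneurons inhibit through GABA-A. A transient current injected
#' into a subset of pyramidal cells at `stim_onset` initiates
#' synchronised firing that is then degraded by background noise and by
#' independently driven distractor neurons.
#'
#' Synaptic conductances are per-class totals, normalised inside the
#' simulator by presynaptic count. Baseline NMDA conductances are the
#' fully glycine-potentiated values; [simulate_network] scales them
#' down by the fractional potentiation at the simulated glycine level.
#'
#' @param n_exc,n_inh Population sizes.
#' @param p_ee,p_ei,p_ie,p_ii Connection probabilities per synapse
#'   class.
#' @param g_ampa_ee,g_ampa_ei AMPA class conductances (mS/cm2).
#' @param g_nmda_ee,g_nmda_ei NMDA class conductances at full glycine
#'   potentiation (mS/cm2).
#' @param g_gaba_ie,g_gaba_ii GABA-A class conductances (mS/cm2).
#' @param g_ks_exc,g_hva_exc Slow K+ and HVA Ca++ conductances of the
#'   pyramidal cells (neuromodulation targets, mS/cm2).
#' @param i_dc_exc,i_dc_inh Constant depolarising currents (uA/cm2).
#' @param noise_rate,noise_amp Background Poisson event rate (Hz) and
#'   conductance increment per event.
#' @param stim_onset,stim_duration,stim_amplitude Stimulus timing (ms)
#'   and current (uA/cm2).
#' @param stim_targets Indices (within the excitatory population) of
#'   stimulated cells.
#' @param distractor_targets Excitatory cells receiving independent
#'   distractor drive after stimulus onset.
#' @param distractor_rate,distractor_amp Distractor Poisson drive.
#' @param tau_ampa,tau_nmda,tau_gaba Synaptic decay constants (ms).
#' @param duration,dt Simulated time and integration step (ms);
#'   `dt` must be <= 0.05 ms.
#' @param baseline_skip Initial transient excluded from baseline
#'   normalisation (ms).
#' @param receptor_couplings Coupling table, see
#'   [default_receptor_couplings].
#' @param seed Integer seed controlling connectivity and noise.
#' @return An object of class `network_config` (a validated list).
#' @export
network_config <- function(n_exc = 20, n_inh = 10,
                           p_ee = 1, p_ei = 1, p_ie = 1, p_ii = 1,
                           g_ampa_ee = 0.03, g_ampa_ei = 0.02,
                           g_nmda_ee = 0.80, g_nmda_ei = 0.70,
                           g_gaba_ie = 0.45, g_gaba_ii = 0.05,
                           g_ks_exc = 0.25, g_hva_exc = 0.03,
                           i_dc_exc = 0.2, i_dc_inh = -0.2,
                           noise_rate = 600, noise_amp = 0.04,
                           stim_onset = 2000, stim_duration = 500,
                           stim_amplitude = 1.0,
                           stim_targets = 1:10,
                           distractor_targets = 16:20,
                           distractor_rate = 200, distractor_amp = 0.04,
                           tau_ampa = 2, tau_nmda = 100, tau_gaba = 8,
                           duration = 5000, dt = 0.025,
                           baseline_skip = 500,
                           receptor_couplings = default_receptor_couplings(),
                           seed = 1L) {
  cfg <- as.list(environment())
  validate_network_config(cfg)
}

validate_network_config <- function(cfg) {
  if (cfg$n_exc <= 0 || cfg$n_inh <= 0) stop("population counts must be > 0")
  probs <- c(cfg$p_ee, cfg$p_ei, cfg$p_ie, cfg$p_ii)
  if (any(probs < 0 | probs > 1)) {
    stop("connection probabilities must be in [0, 1]")
  }
  if (cfg$dt <= 0 || cfg$dt > 0.05) stop("'dt' must be in (0, 0.05] ms")
  if (cfg$duration <= cfg$stim_onset) {
    stop("'duration' must exceed 'stim_onset'")
  }
  gs <- c(cfg$g_ampa_ee, cfg$g_ampa_ei, cfg$g_nmda_ee, cfg$g_nmda_ei,
          cfg$g_gaba_ie, cfg$g_gaba_ii, cfg$g_ks_exc, cfg$g_hva_exc)
  if (any(gs < 0)) stop("conductances must be >= 0")
  rc <- cfg$receptor_couplings
  if (!all(c("receptor", "target", "gain") %in% names(rc))) {
    stop("receptor_couplings needs columns receptor, target, gain")
  }
  known_targets <- c("g_ks_exc", "g_hva_exc", "g_ampa_ee", "g_ampa_ei",
                     "g_nmda_ee", "g_nmda_ei", "g_gaba_ie", "g_gaba_ii",
                     "noise_amp", "i_dc_exc", "i_dc_inh")
  bad <- setdiff(rc$target, known_targets)
  if (length(bad)) {
    stop("unknown coupling target(s): ", paste(bad, collapse = ", "))
  }
  structure(cfg, class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf("Cortical E/I network: %d excitatory + %d inhibitory\n",
              x$n_exc, x$n_inh))
  cat(sprintf("  duration %g ms (dt %g ms), stimulus at %g ms\n",
              x$duration, x$dt, x$stim_onset))
  cat(sprintf("  NMDA (full potentiation): e-e %g, e-i %g mS/cm2\n",
              x$g_nmda_ee, x$g_nmda_ei))
  invisible(x)
}

#' Schizophrenia pathology of the cortical circuit
#'
#' Fractional lesions applied to the healthy network: reduced glutamate
#' (NMDA) tone, reduced GABA release (lower GAD67 activity), reduced
#' cortical dopamine coupling, and increased background noise. The
#' shipped defaults of 0.3 each are placeholders inside the published
#' sensitivity sweep ranges, not calibrated constants.
#'
#' @param nmda_reduction,gaba_reduction,da_deficit Fractions in
#'   `[0, 1)`.
#' @param noise_increase Fractional noise increase, >= 0.
#' @return An object of class `pathology_config`.
#' @export
pathology_config <- function(nmda_reduction = 0.3, gaba_reduction = 0.3,
                             da_deficit = 0.3, noise_increase = 0.3) {
  red <- c(nmda_reduction, gaba_reduction, da_deficit)
  if (any(red < 0 | red >= 1)) stop("reductions must be in [0, 1)")
  if (noise_increase < 0) stop("'noise_increase' must be >= 0")
  structure(list(nmda_reduction = nmda_reduction,
                 gaba_reduction = gaba_reduction,
                 da_deficit = da_deficit,
                 noise_increase = noise_increase),
            class = "pathology_config")
}

#' Apply schizophrenia pathology to a network configuration
#'
#' Returns a modified copy: NMDA conductances scaled by
#' `1 - nmda_reduction`, GABA-A conductances by `1 - gaba_reduction`,
#' dopamine-receptor coupling gains by `1 - da_deficit`, and noise
#' amplitude by `1 + noise_increase`. Successive applications compose
#' multiplicatively.
#'
#' @param cfg A [network_config].
#' @param path A [pathology_config].
#' @return A new `network_config`.
#' @export
apply_pathology <- function(cfg, path) {
  stopifnot(inherits(cfg, "network_config"),
            inherits(path, "pathology_config"))
  out <- unclass(cfg)
  out$g_nmda_ee <- out$g_nmda_ee * (1 - path$nmda_reduction)
  out$g_nmda_ei <- out$g_nmda_ei * (1 - path$nmda_reduction)
  out$g_gaba_ie <- out$g_gaba_ie * (1 - path$gaba_reduction)
  out$g_gaba_ii <- out$g_gaba_ii * (1 - path$gaba_reduction)
  da <- out$receptor_couplings$receptor %in% c("D1", "D2", "D3", "D4",
                                               "D5")
  out$receptor_couplings$gain[da] <-
    out$receptor_couplings$gain[da] * (1 - path$da_deficit)
  out$noise_amp <- out$noise_amp * (1 + path$noise_increase)
  validate_network_config(out)
}

#' Apply receptor relative activations to a network configuration
#'
#' Each coupling row scales its target conductance by
#' `max(0, 1 + gain * relative_activation)`; multiple receptors
#' converging on one target stack multiplicatively.
#'
#' @param cfg A [network_config].
#' @param effects Named numeric vector of relative activations (names
#'   are receptors present in the coupling table).
#' @param table Coupling table; defaults to the one inside `cfg`.
#' @return A new `network_config`.
#' @export
apply_receptor_effects <- function(cfg, effects,
                                   table = cfg$receptor_couplings) {
  stopifnot(inherits(cfg, "network_config"), is.numeric(effects))
  known <- unique(table$receptor)
  unknown <- setdiff(names(effects), known)
  if (length(unknown)) {
    stop("unknown receptor(s): ", paste(unknown, collapse = ", "),
         "; known receptors: ", paste(known, collapse = ", "))
  }
  out <- unclass(cfg)
  for (r in names(effects)) {
    rows <- table[table$receptor == r, , drop = FALSE]
    for (k in seq_len(nrow(rows))) {
      tgt <- rows$target[k]
      out[[tgt]] <- out[[tgt]] * max(0, 1 + rows$gain[k] * effects[[r]])
    }
  }
  validate_network_config(out)
}

# Bernoulli connectivity scaled to per-class totals; no autapses.
# Weight from presynaptic j to postsynaptic i is g_class / n_pre.
.build_weights <- function(cfg) {
  n <- cfg$n_exc + cfg$n_inh
  exc <- seq_len(cfg$n_exc)
  inh <- cfg$n_exc + seq_len(cfg$n_inh)
  wa <- matrix(0, n, n)
  wn <- matrix(0, n, n)
  wg <- matrix(0, n, n)
  draw <- function(ni, nj, p) matrix(stats::runif(ni * nj) < p, ni, nj)
  m_ee <- draw(cfg$n_exc, cfg$n_exc, cfg$p_ee); diag(m_ee) <- FALSE
  m_ei <- draw(cfg$n_inh, cfg$n_exc, cfg$p_ei)
  m_ie <- draw(cfg$n_exc, cfg$n_inh, cfg$p_ie)
  m_ii <- draw(cfg$n_inh, cfg$n_inh, cfg$p_ii); diag(m_ii) <- FALSE
  wa[exc, exc] <- m_ee * cfg$g_ampa_ee / cfg$n_exc
  wa[inh, exc] <- m_ei * cfg$g_ampa_ei / cfg$n_exc
  wn[exc, exc] <- m_ee * cfg$g_nmda_ee / cfg$n_exc
  wn[inh, exc] <- m_ei * cfg$g_nmda_ei / cfg$n_exc
  wg[exc, inh] <- m_ie * cfg$g_gaba_ie / cfg$n_inh
  wg[inh, inh] <- m_ii * cfg$g_gaba_ii / cfg$n_inh
  list(ampa = wa, nmda = wn, gaba = wg)
}

# normalised population activity from a spike table
.population_activity <- function(times, t_max, baseline_window, n_cells,
                                 bin = 20, smooth_bins = 5,
                                 floor_hz = 0.1) {
  edges <- seq(0, t_max, by = bin)
  counts <- graphics::hist(times, breaks = edges, plot = FALSE)$counts
  rate <- counts / (n_cells * bin / 1000)  # Hz per cell
  kern <- rep(1 / smooth_bins, smooth_bins)
  sm <- as.numeric(stats::filter(rate, kern, sides = 2))
  sm[is.na(sm)] <- rate[is.na(sm)]  # unsmoothed values at the edges
  rate <- sm + floor_hz
  mid <- edges[-1] - bin / 2
  base <- mid >= baseline_window[1] & mid <= baseline_window[2]
  data.frame(time = mid, value = rate / mean(rate[base]))
}

#' Simulate the cortical network at a glycine concentration
#'
#' Applies pathology (if any), scales the e-e and e-i NMDA conductances
#' by their fractional glycine potentiation (see
#' [effective_conductance]; omitted when `gly` is `NULL`), draws the
#' connectivity and background noise from `cfg$seed`, and integrates
#' the circuit. Identical configurations and seeds give identical spike
#' trains.
#'
#' @param cfg A [network_config].
#' @param path Optional [pathology_config].
#' @param gly Extracellular glycine (uM) or `NULL` for fully
#'   potentiated NMDA conductances.
#' @param pd A [synapse_class_pd]; required when `gly` is given.
#' @return An object of class `network_output`: a list with `spikes`
#'   (data frame `neuron`, `time_ms`, `population`), `rate_exc` and
#'   `rate_inh` (Hz per cell over the analysis window, stimulus onset
#'   to end), `u_e` and `u_i` (population activities normalised to a
#'   pre-stimulus baseline of 1), and the realised `config`.
#' @export
simulate_network <- function(cfg, path = NULL, gly = NULL, pd = NULL) {
  stopifnot(inherits(cfg, "network_config"))
  if (!is.null(path)) cfg <- apply_pathology(cfg, path)
  if (!is.null(gly)) {
    if (is.null(pd)) stop("'pd' is required when 'gly' is given")
    out <- unclass(cfg)
    out$g_nmda_ee <- out$g_nmda_ee * effective_conductance(gly, "ee", pd)
    out$g_nmda_ei <- out$g_nmda_ei * effective_conductance(gly, "ei", pd)
    cfg <- validate_network_config(out)
  }
  set.seed(cfg$seed)
  w <- .build_weights(cfg)
  res <- .sim_ei_network_cpp(
    cfg$n_exc, cfg$n_inh, cfg$dt, cfg$duration, w$ampa, w$nmda, w$gaba,
    cfg$stim_onset, cfg$stim_duration, cfg$stim_amplitude,
    as.integer(cfg$stim_targets), as.integer(cfg$distractor_targets),
    cfg$distractor_rate, cfg$distractor_amp, cfg$noise_rate,
    cfg$noise_amp, cfg$g_ks_exc, cfg$g_hva_exc, cfg$i_dc_exc,
    cfg$i_dc_inh, cfg$tau_ampa, cfg$tau_nmda, cfg$tau_gaba)
  spikes <- data.frame(neuron = res$neuron, time_ms = res$spike_time)
  spikes$population <- ifelse(spikes$neuron <= cfg$n_exc,
                              "exc", "inh")
  win <- c(cfg$stim_onset, cfg$duration)
  win_s <- (win[2] - win[1]) / 1000
  in_win <- spikes$time_ms >= win[1]
  rate_exc <- sum(in_win & spikes$population == "exc") /
    (cfg$n_exc * win_s)
  rate_inh <- sum(in_win & spikes$population == "inh") /
    (cfg$n_inh * win_s)
  basewin <- c(cfg$baseline_skip, cfg$stim_onset)
  u_e <- .population_activity(
    spikes$time_ms[spikes$population == "exc"], cfg$duration, basewin,
    cfg$n_exc)
  u_i <- .population_activity(
    spikes$time_ms[spikes$population == "inh"], cfg$duration, basewin,
    cfg$n_inh)
  structure(list(spikes = spikes, rate_exc = rate_exc,
                 rate_inh = rate_inh, u_e = u_e, u_i = u_i,
                 config = cfg),
            class = "network_output")
}

#' @export
print.network_output <- function(x, ...) {
  cat(sprintf(
    "Network output: %d spikes; exc %.2f Hz, inh %.2f Hz (window %g-%g ms)\n",
    nrow(x$spikes), x$rate_exc, x$rate_inh, x$config$stim_onset,
    x$config$duration))
  invisible(x)
}

#' Write spike trains as delimited text
#'
#' @param out A `network_output`.
#' @param path Output path (tab-delimited `neuron`, `time_ms`,
#'   `population`).
#' @return `path`, invisibly.
#' @export
write_spikes <- function(out, path) {
  utils::write.table(out$spikes, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
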