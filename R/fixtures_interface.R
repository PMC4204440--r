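`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-stage seed from a global seed
#'
#' One global seed fans out to reproducible per-stage seeds through a
#' counter-based mix, so any stage can be re-run in isolation with the
#' same stream. Results stay within the 32-bit integer range.
#'
#' @param master Global integer seed.
#' @param stage Stage name (character).
#' @param index Optional counter within the stage.
#' @return A positive integer seed below 2^31.
#' @export
derive_seed <- function(master, stage, index = 0L) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  val <- (as.numeric(master) * 69069 + h * 1000003 + index) %%
    2147483629
  as.integer(val + 1)
}

#' Specification of a synthetic clinical-trial database
#'
#' The retrospective clinical database behind the published calibration
#' (34 drug-dose combinations with PANSS-negative outcomes) is not
#' distributed; this generator emulates its schema so the calibration
#' machinery can be exercised and recovery-tested. Defaults produce
#' 17 drugs at 2 dose levels each (34 rows), log-uniform receptor
#' affinities, and outcomes placed on a known linear map of the model
#' proxy plus Gaussian noise.
#'
#' Noise can be specified directly (`noise_sd`, points) or tuned so the
#' realised in-sample proxy-outcome correlation equals `target_r`
#' (the drawn noise is residualised against the proxy and rescaled),
#' mirroring the published calibration quality on data whose ground
#' truth is known.
#'
#' @param n_drugs Number of synthetic drugs.
#' @param doses_per_drug Dose levels per drug.
#' @param receptors Receptor set for the affinity tables.
#' @param ki_range Log-uniform sampling range for Ki (nM).
#' @param slope,intercept Ground-truth linear map proxy -> PANSS
#'   change.
#' @param noise_sd Outcome noise standard deviation (points); used
#'   when `target_r` is `NULL`.
#' @param target_r When non-`NULL`, tune the noise so the realised
#'   proxy-outcome Pearson correlation equals this value.
#' @param n_range Patient-count range per trial.
#' @param seed Master seed.
#' @return An object of class `synthetic_trial_spec`.
#' @export
synthetic_trial_spec <- function(n_drugs = 17, doses_per_drug = 2,
                                 receptors = c("D2", "D1", "5HT2A",
                                               "5HT2C", "5HT3", "M1",
                                               "alpha1A"),
                                 ki_range = c(1, 1000),
                                 slope = -8, intercept = -1,
                                 noise_sd = 1, target_r = 0.65,
                                 n_range = c(20, 200), seed = 1L) {
  if (n_drugs < 1 || doses_per_drug < 1) stop("counts must be >= 1")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (!is.null(target_r) && (target_r <= 0 || target_r >= 1)) {
    stop("'target_r' must be in (0, 1)")
  }
  structure(list(n_drugs = n_drugs, doses_per_drug = doses_per_drug,
                 receptors = receptors, ki_range = ki_range,
                 slope = slope, intercept = intercept,
                 noise_sd = noise_sd, target_r = target_r,
                 n_range = n_range, seed = as.integer(seed)),
            class = "synthetic_trial_spec")
}

# receptor weights of the desk-scale proxy surrogate: how strongly a
# relative activation change at each receptor moves the cortical and
# striatal readouts (documented surrogate for the full circuit path)
.proxy_weights <- function(receptors) {
  w_cort <- c(D1 = 0.6, D2 = -0.2, `5HT2A` = -0.3, `5HT2C` = -0.2,
              `5HT3` = -0.1, M1 = 0.2, alpha1A = 0.1)
  w_str <- c(D1 = 0.3, D2 = -0.8, `5HT2A` = -0.1, `5HT2C` = -0.4,
             `5HT3` = -0.2, M1 = 0.3, alpha1A = 0.2)
  keep <- function(w) {
    out <- w[receptors]
    out[is.na(out)] <- 0.1
    names(out) <- receptors
    out
  }
  list(cortical = keep(w_cort), striatal = keep(w_str))
}

#' Generate a synthetic clinical-trial database
#'
#' Samples per-drug receptor affinity profiles, converts doses into
#' synaptic concentrations, runs the steady-state receptor-competition
#' model forward for every trial to obtain D2 occupancy and per-receptor
#' relative activations, maps those onto a composite negative-symptom
#' proxy through fixed surrogate weights, and places observed
#' PANSS-negative changes on the ground-truth linear map plus noise.
#' Deterministic per master seed; the truth record is returned
#' separately for recovery testing.
#'
#' @param spec A [synthetic_trial_spec].
#' @return A list with `trials` (a `trial_database` data frame),
#'   `affinities` (an `affinity_profile` data frame), and `truth`
#'   (slope, intercept, per-trial proxies, realised correlation).
#' @export
generate_synthetic_trials <- function(spec = synthetic_trial_spec()) {
  stopifnot(inherits(spec, "synthetic_trial_spec"))
  set.seed(spec$seed)
  nr <- length(spec$receptors)
  drugs <- sprintf("drug%02d", seq_len(spec$n_drugs))
  aff <- expand.grid(drug = drugs, receptor = spec$receptors,
                     stringsAsFactors = FALSE)
  aff <- aff[order(aff$drug), ]
  lo <- log(spec$ki_range[1]); hi <- log(spec$ki_range[2])
  aff$ki_nM <- exp(stats::runif(nrow(aff), lo, hi))
  aff$intrinsic_activity <- 0
  rownames(aff) <- NULL
  class(aff) <- unique(c("affinity_profile", class(aff)))

  # per-receptor synaptic contexts: a fixed neurotransmitter tone
  ctx <- synapse_context(nt_conc = 100, nt_ki = 50)
  w <- .proxy_weights(spec$receptors)
  control <- steady_state_activation(ctx)$activation

  rows <- list()
  proxies <- numeric(0)
  for (d in drugs) {
    doses <- sort(exp(stats::runif(spec$doses_per_drug, log(2),
                                   log(30))))
    prof <- aff[aff$drug == d, ]
    for (dose in doses) {
      conc <- dose * 10  # dose units -> free synaptic nM
      x_eff <- vapply(spec$receptors, function(r) {
        ki <- prof$ki_nM[prof$receptor == r]
        act <- steady_state_activation(
          ctx, data.frame(concentration = conc, ki = ki,
                          intrinsic_activity = 0))$activation
        relative_effect(act, control)
      }, numeric(1))
      ki_d2 <- prof$ki_nM[prof$receptor == "D2"]
      occ_d2 <- if (length(ki_d2)) {
        steady_state_activation(
          ctx, data.frame(concentration = conc, ki = ki_d2,
                          intrinsic_activity = 0))$occupancy[["drug1"]]
      } else {
        NA_real_
      }
      proxy <- composite_readout(sum(w$cortical * x_eff),
                                 sum(w$striatal * x_eff))
      proxies <- c(proxies, proxy)
      rows[[length(rows) + 1L]] <-
        data.frame(drug = d, dose = dose, d2_occupancy = occ_d2,
                   dpanss_neg = NA_real_,
                   n = sample(seq(spec$n_range[1], spec$n_range[2]),
                              1L))
    }
  }
  trials <- do.call(rbind, rows)

  truth_line <- spec$slope * proxies + spec$intercept
  eps <- stats::rnorm(length(proxies), 0, 1)
  if (!is.null(spec$target_r) && stats::sd(proxies) > 0) {
    # residualise the noise against the proxy, then scale it so the
    # realised correlation matches the target exactly
    eps <- stats::residuals(stats::lm(eps ~ proxies))
    sig_sd <- stats::sd(truth_line)
    eps <- eps / stats::sd(eps) *
      sig_sd * sqrt(1 / spec$target_r^2 - 1)
    trials$dpanss_neg <- truth_line + eps  # |r| = target_r by construction
  } else {
    trials$dpanss_neg <- truth_line + spec$noise_sd * eps
  }
  rownames(trials) <- NULL
  class(trials) <- unique(c("trial_database", class(trials)))
  realised_r <- stats::cor(proxies, trials$dpanss_neg)
  list(trials = trials, affinities = aff,
       truth = list(slope = spec$slope, intercept = spec$intercept,
                    proxies = proxies, realised_r = realised_r))
}

#' Write a synthetic-trial fixture set to a directory
#'
#' Emits `affinities.csv`, `trials.tsv` and `truth.json` (the ground
#' truth is kept separate from the database so recovery tests cannot
#' leak it).
#'
#' @param fix Result of [generate_synthetic_trials].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial_fixtures <- function(fix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_affinity_table(fix$affinities, file.path(dir, "affinities.csv"))
  write_trial_database(fix$trials, file.path(dir, "trials.tsv"))
  jsonlite::write_json(fix$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Default nested run configuration
#'
#' The full-pipeline configuration consumed by [run_dose_response] and
#' the command-line interface: pharmacodynamics, pathology, cortical
#' network, Balloon hemodynamics, striatal population and readout
#' weights, with a global seed. Values are plain nested lists so they
#' can round-trip through YAML.
#'
#' @param seed Global seed.
#' @return A nested configuration list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    pd = list(ee = list(ec50 = 0.35, slope = 2),
              ei = list(ec50 = 0.2, slope = 1),
              gmax_ee = 1, gmax_ei = 1,
              internalization_ee = NULL, internalization_ei = NULL),
    pathology = list(nmda_reduction = 0.3, gaba_reduction = 0.3,
                     da_deficit = 0.3, noise_increase = 0.3),
    network = list(duration = 5000, dt = 0.025, n_seeds = 5),
    balloon = list(dt = 0.005, playout = 10),
    striatum = list(n_sp_d1 = 2, n_enk_d2 = 2, n_dual = 1,
                    drive_scale = 0.06),
    weights = list(w_cortical = 0.4, w_striatal = 0.6),
    outcome = "composite"
  ), class = c("run_config", "list"))
}

#' Read / write a run configuration as YAML
#'
#' @param path Path to a YAML file.
#' @return For `read_run_config`, a `run_config` list; the writer
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  cfg <- utils::modifyList(unclass(default_run_config()),
                           yaml::read_yaml(path))
  structure(cfg, class = c("run_config", "list"))
}

#' @rdname read_run_config
#' @param cfg A `run_config` list.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# build the pieces of the pipeline from a run_config
.config_pd <- function(cfg) {
  synapse_class_pd(
    ee = hill_params(cfg$pd$ee$ec50, cfg$pd$ee$slope),
    ei = hill_params(cfg$pd$ei$ec50, cfg$pd$ei$slope),
    gmax_ee = cfg$pd$gmax_ee, gmax_ei = cfg$pd$gmax_ei,
    internalization_ee = cfg$pd$internalization_ee,
    internalization_ei = cfg$pd$internalization_ei)
}

.config_pathology <- function(cfg) {
  do.call(pathology_config, cfg$pathology)
}

#' Run the full glycine dose-response pipeline
#'
#' For each glycine concentration: scale the NMDA synapse classes by
#' their fractional potentiation, simulate the pathological cortical
#' network (averaging over `cfg$network$n_seeds` seeds), convert the
#' normalised population activities into a BOLD summary, drive a small
#' mixed population of medium spiny neurons with the excitatory
#' cortical activity, and combine the cortical and striatal readouts
#' into the composite negative-symptom proxy.
#'
#' @param cfg A `run_config` (see [default_run_config]).
#' @param glycine_uM Strictly increasing glycine grid (uM).
#' @param outcome One of `"composite"`, `"rate"` (mean excitatory
#'   firing), `"bold"`, `"striatal"`.
#' @return A [dose_response_curve] with attribute `details` (a data
#'   frame of the per-point readouts).
#' @export
run_dose_response <- function(cfg = default_run_config(),
                              glycine_uM = 10^seq(-1, 2, length.out = 7),
                              outcome = cfg$outcome) {
  pd <- .config_pd(cfg)
  path <- .config_pathology(cfg)
  n_seeds <- cfg$network$n_seeds
  rows <- lapply(seq_along(glycine_uM), function(i) {
    gly <- glycine_uM[i]
    per_seed <- lapply(seq_len(n_seeds), function(s) {
      net_cfg <- network_config(
        duration = cfg$network$duration, dt = cfg$network$dt,
        stim_onset = cfg$network$stim_onset %||% 2000,
        seed = derive_seed(cfg$seed, "network", s))
      net <- simulate_network(net_cfg, path = path, gly = gly, pd = pd)
      # resample population activities onto the hemodynamic grid; the
      # hemodynamic response evolves over ~15 s, much longer than the
      # spiking simulation, so the post-stimulus drive level is held
      # for a playout period to let the main BOLD peak develop
      dt_s <- cfg$balloon$dt
      playout_s <- cfg$balloon$playout %||% 10
      t_net <- seq(0, cfg$network$duration / 1000, by = dt_s)
      ue <- stats::approx(net$u_e$time / 1000, net$u_e$value, t_net,
                          rule = 2)$y
      ui <- stats::approx(net$u_i$time / 1000, net$u_i$value, t_net,
                          rule = 2)$y
      post <- t_net >= net_cfg$stim_onset / 1000
      n_pad <- round(playout_s / dt_s)
      ue <- c(ue, rep(mean(ue[post]), n_pad))
      ui <- c(ui, rep(mean(ui[post]), n_pad))
      bold <- simulate_bold(ue, ui, dt = dt_s)
      bsum <- bold_summary(bold,
                           window = c(net_cfg$stim_onset / 1000,
                                      max(bold$time)))
      # striatal population driven by the excitatory cortical activity
      msn_dt <- 0.05
      n_msn <- ceiling(cfg$network$duration / msn_dt)
      drive <- stats::approx(net$u_e$time, net$u_e$value,
                             (seq_len(n_msn) - 1) * msn_dt,
                             rule = 2)$y * cfg$striatum$drive_scale
      classes <- rep(c("SP_D1", "Enk_D2", "dual"),
                     c(cfg$striatum$n_sp_d1, cfg$striatum$n_enk_d2,
                       cfg$striatum$n_dual))
      cells <- lapply(seq_along(classes), function(k) {
        simulate_msn(msn_params(cell_class = classes[k]), drive,
                     dt = msn_dt,
                     seed = derive_seed(cfg$seed, "msn", s * 100 + k))
      })
      striatal <- striatal_population_readout(cells, classes)
      c(rate = net$rate_exc, bold = as.numeric(bsum),
        striatal = striatal)
    })
    avg <- colMeans(do.call(rbind, per_seed))
    w <- readout_weights(cfg$weights$w_cortical, cfg$weights$w_striatal)
    data.frame(glycine_uM = gly, rate = avg[["rate"]],
               bold = avg[["bold"]], striatal = avg[["striatal"]],
               composite = composite_readout(avg[["bold"]],
                                             avg[["striatal"]], w))
  })
  details <- do.call(rbind, rows)
  curve <- dose_response_curve(details$glycine_uM, details[[outcome]],
                               what = "network_outcome")
  attr(curve, "details") <- details
  curve
}

#' Write a reproducibility manifest for a pipeline run
#'
#' Records the configuration (and its MD5 hash), the global seed and
#' the package version, sufficient to re-run the deterministic stages
#' bit-for-bit.
#'
#' @param cfg The `run_config` used.
#' @param seed The global seed used.
#' @param outdir Output directory.
#' @return Path of the manifest, invisibly.
#' @export
write_run_manifest <- function(cfg, seed, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(outdir, "config.yaml")
  write_run_config(cfg, cfg_path)
  manifest <- list(
    config_file = "config.yaml",
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = seed,
    package_version = as.character(utils::packageVersion("glyqsp")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"))
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Fast analytic surrogate of the glycine dose-response outcome
#'
#' The network outcome tracks the inverse of the e-i/e-e potentiation
#' ratio (excitatory dominance); this surrogate evaluates that
#' relationship directly, without spiking simulations, and is the
#' default outcome for desk-scale sensitivity sweeps. The scalar
#' returned is the maximum over the glycine grid of
#' `1 / ei_over_ee_ratio`, i.e. the peak excitatory dominance the
#' dose-response can reach.
#'
#' @param cfg A `run_config` (only the `pd` block is used).
#' @param glycine_uM Evaluation grid (uM).
#' @return Scalar surrogate outcome.
#' @export
surrogate_outcome <- function(cfg,
                              glycine_uM = 10^seq(-2, 2,
                                                  length.out = 200)) {
  pd <- .config_pd(cfg)
  max(1 / ei_over_ee_ratio(glycine_uM, pd))
}
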