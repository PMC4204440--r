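#' Balloon-model hemodynamic parameters
#'
#' Parameters of the metabolic-hemodynamic cascade that converts
#' normalised excitatory and inhibitory neural drives into a BOLD
#' signal: glucose-consumption responses for each population, an
#' oxygen-consumption mixing weight, a flow response, and the Balloon
#' venous compartment.
#'
#' Defaults keep the printed model constants (`a_e = 1.2`,
#' sigmoid steepness `c = 2.5` and threshold `d = 1.6`,
#' volume time constant `tau = 10` s, deoxyhemoglobin weight
#' `a1 = 3.4`); `a2` defaults to 1. The flow gain `epsilon = 10`
#' places the model in the standard positive-BOLD regime where the
#' flow response exceeds the metabolic response for a sustained step;
#' see the methods vignette.
#'
#' @param v0 Resting venous blood volume fraction.
#' @param a1,a2 Deoxyhemoglobin and blood-volume weights of the BOLD
#'   equation.
#' @param t0 Mean venous transit time (s).
#' @param tau Viscoelastic time constant of the venous balloon (s).
#' @param alpha Grubb outflow exponent; outflow is `v^(1/alpha)`.
#' @param gamma Excitatory/inhibitory metabolic mixing weight.
#' @param a_e,a_i Efficacies of the glucose-consumption response to
#'   excitation and inhibition.
#' @param tau_e,tau_i Glucose-response time constants (s).
#' @param delta_e,delta_f Neural-to-metabolic and neural-to-flow delays
#'   (s).
#' @param epsilon Flow-response gain.
#' @param tau_s,tau_f Flow-signal decay and feedback time constants (s).
#' @param c,d Steepness and threshold of the sigmoid applied to neural
#'   drives on the metabolic path.
#' @param x0 Baseline oxygen-glucose index (must differ from 2).
#' @param sigmoid Apply the sigmoid transform to the metabolic drives?
#' @return An object of class `balloon_params`.
#' @export
balloon_params <- function(v0 = 0.02, a1 = 3.4, a2 = 1.0,
                           t0 = 2, tau = 10, alpha = 0.4,
                           gamma = 1, a_e = 1.2, a_i = 0.7,
                           tau_e = 1, tau_i = 1,
                           delta_e = 0.3, delta_f = 0.5,
                           epsilon = 10, tau_s = 0.8, tau_f = 0.4,
                           c = 2.5, d = 1.6, x0 = 1,
                           sigmoid = TRUE) {
  pos <- c(v0 = v0, t0 = t0, tau = tau, alpha = alpha, tau_e = tau_e,
           tau_i = tau_i, tau_s = tau_s, tau_f = tau_f)
  if (any(pos <= 0)) stop("v0, t0, tau, alpha and time constants must be > 0")
  if (delta_e < 0 || delta_f < 0) stop("delays must be >= 0")
  if (x0 == 2) stop("'x0' must differ from 2")
  structure(list(v0 = v0, a1 = a1, a2 = a2, t0 = t0, tau = tau,
                 alpha = alpha, gamma = gamma, a_e = a_e, a_i = a_i,
                 tau_e = tau_e, tau_i = tau_i, delta_e = delta_e,
                 delta_f = delta_f, epsilon = epsilon, tau_s = tau_s,
                 tau_f = tau_f, c = c, d = d, x0 = x0,
                 sigmoid = sigmoid),
            class = "balloon_params")
}

# sigmoid transform for the metabolic drive, rescaled so baseline
# activity 1 maps to 1
.metabolic_drive <- function(u, p) {
  if (!isTRUE(p$sigmoid)) return(u)
  s <- function(z) 1 / (1 + exp(-p$c * (z - p$d)))
  s(u) / s(1)
}

#' Venous outflow and volume derivative of the Balloon compartment
#'
#' The outflow `f_out = v^(1/alpha) + tau * dv/dt` is coupled to the
#' volume equation `dv/dt = (f - f_out)/t0`; solving the pair
#' algebraically gives `dv/dt = (f - v^(1/alpha)) / (t0 + tau)`.
#' At baseline (`v = 1`, `f = 1`) the outflow is exactly 1.
#'
#' @param v Normalised venous volume.
#' @param f Normalised inflow.
#' @param p A [balloon_params] object.
#' @return A list with `f_out` and `dvdt`.
#' @export
balloon_outflow <- function(v, f, p = balloon_params()) {
  dvdt <- (f - v^(1 / p$alpha)) / (p$t0 + p$tau)
  list(f_out = v^(1 / p$alpha) + p$tau * dvdt, dvdt = dvdt)
}

#' Combined metabolic rate of oxygen consumption
#'
#' `m_i = g_i`, `m_e = g_e (2 - x) / (2 - x0)`, combined as
#' `m = (gamma * m_e + m_i) / (gamma + 1)`. As `gamma` grows the
#' combined rate approaches the excitatory rate.
#'
#' @param g_e,g_i Normalised glucose consumption of the excitatory and
#'   inhibitory populations, > 0.
#' @param x Oxygen-glucose index (defaults to the baseline `x0`,
#'   i.e. no uncoupling).
#' @param p A [balloon_params] object.
#' @return The combined normalised oxygen consumption.
#' @export
metabolic_rate <- function(g_e, g_i, x = p$x0, p = balloon_params()) {
  if (any(g_e <= 0) || any(g_i <= 0)) stop("glucose rates must be > 0")
  if (p$x0 == 2) stop("'x0' must differ from 2")
  m_i <- g_i
  m_e <- g_e * (2 - x) / (2 - p$x0)
  (p$gamma * m_e + m_i) / (p$gamma + 1)
}

#' Simulate the BOLD response to excitatory and inhibitory drives
#'
#' Integrates the metabolic-hemodynamic cascade from its baseline fixed
#' point: delayed, sigmoid-transformed neural drives feed second-order
#' glucose responses for each population; glucose sets oxygen
#' consumption through the oxygen-glucose index; the delayed excitatory
#' drive also feeds a flow-inducing signal; and flow, volume and
#' deoxyhemoglobin evolve in the venous balloon. The BOLD signal is
#' `y = v0 * (a1 (1 - q) - a2 (1 - v))`, identically zero for constant
#' unit drives.
#'
#' Integration is fixed-step RK4 (via deSolve) so that step-halving
#' convergence can be checked directly.
#'
#' @param u_e,u_i Excitatory and inhibitory population activities
#'   sampled at `dt`, normalised so pre-stimulus baseline is 1.
#' @param p A [balloon_params] object.
#' @param dt Sampling/integration step (s), <= 0.01.
#' @param x_fun Optional function of time returning the oxygen-glucose
#'   index `x(t)`; defaults to the constant baseline `x0`.
#' @return A data frame with columns `time`, `y` (BOLD) and the state
#'   variables `v`, `q`, `f`, `s`, `g_e`, `g_i`, `s_e`, `s_i`.
#' @export
simulate_bold <- function(u_e, u_i, p = balloon_params(), dt = 0.005,
                          x_fun = NULL) {
  stopifnot(inherits(p, "balloon_params"), length(u_e) == length(u_i))
  if (dt > 0.01) stop("'dt' must be <= 0.01 s")
  n <- length(u_e)
  times <- (seq_len(n) - 1L) * dt
  # rule = 2: clamp to the first/last sample outside the series, so
  # delayed lookups before t = 0 see the baseline value
  ue_f <- stats::approxfun(times, u_e, rule = 2)
  ui_f <- stats::approxfun(times, u_i, rule = 2)
  xf <- if (is.null(x_fun)) function(t) p$x0 else x_fun

  deriv <- function(t, y, parms) {
    v <- y[1]; q <- y[2]; f <- y[3]; s <- y[4]
    g_e <- y[5]; g_i <- y[6]; s_e <- y[7]; s_i <- y[8]
    if (v <= 0 || q <= 0) stop("integration error: non-positive v or q")
    ofl <- balloon_outflow(v, f, p)
    m <- metabolic_rate(g_e, g_i, xf(t), p)
    ue_m <- .metabolic_drive(ue_f(t - p$delta_e), p)
    ui_m <- .metabolic_drive(ui_f(t - p$delta_e), p)
    dv <- ofl$dvdt
    dq <- (m - ofl$f_out * q / v) / p$t0
    df <- s
    ds <- p$epsilon * (ue_f(t - p$delta_f) - 1) - s / p$tau_s -
      (f - 1) / p$tau_f
    dge <- s_e
    dgi <- s_i
    dse <- p$a_e * (ue_m - 1) / p$tau_e - 2 * s_e / p$tau_e -
      (g_e - 1) / p$tau_e^2
    dsi <- p$a_i * (ui_m - 1) / p$tau_i - 2 * s_i / p$tau_i -
      (g_i - 1) / p$tau_i^2
    list(c(dv, dq, df, ds, dge, dgi, dse, dsi))
  }

  y0 <- c(v = 1, q = 1, f = 1, s = 0, g_e = 1, g_i = 1, s_e = 0,
          s_i = 0)
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "rk4")
  if (any(!is.finite(sol))) stop("integration error: non-finite state")
  sol <- as.data.frame(sol)
  y <- p$v0 * (p$a1 * (1 - sol$q) - p$a2 * (1 - sol$v))
  data.frame(time = sol$time, y = y, v = sol$v, q = sol$q, f = sol$f,
             s = sol$s, g_e = sol$g_e, g_i = sol$g_i, s_e = sol$s_e,
             s_i = sol$s_i)
}

#' Scalar summary of a BOLD time series
#'
#' Either the peak signal within a window (default) or the
#' time-integral over the window; the choice is recorded in the result
#' attributes so downstream calibration reports what it used.
#'
#' @param y BOLD samples, or the data frame returned by
#'   [simulate_bold].
#' @param time Sample times (taken from the data frame when omitted).
#' @param window Length-2 time window (defaults to the full series).
#' @param method `"peak"` or `"integral"`.
#' @return A scalar with attribute `method`.
#' @export
bold_summary <- function(y, time = NULL, window = NULL,
                         method = c("peak", "integral")) {
  method <- match.arg(method)
  if (is.data.frame(y)) {
    time <- y$time
    y <- y$y
  }
  if (is.null(time)) time <- seq_along(y) - 1
  if (is.null(window)) window <- range(time)
  keep <- time >= window[1] & time <= window[2]
  if (!any(keep)) stop("empty summary window")
  val <- if (method == "peak") {
    max(y[keep])
  } else {
    sum(diff(time[keep]) * (y[keep][-1] + y[keep][-sum(keep)]) / 2)
  }
  structure(val, method = method)
}
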