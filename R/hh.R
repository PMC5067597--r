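#' @useDynLib presynaptic, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx approxfun splinefun rpois runif rexp density
#'   setNames dnorm dpois ppois
#' @importFrom graphics hist
#' @importFrom utils write.csv head tail
NULL

# Elementary charge in coulomb
.e_charge <- 1.602176634e-19

#' Parameters of the simplified Hodgkin-Huxley membrane model
#'
#' Bundles the electrical parameters of the reduced excitable-membrane model
#' used to generate the action-potential-evoked calcium current.  The model
#' carries a classical sodium/potassium spike generator (sodium activation
#' `p` instantaneous at its voltage-dependent steady state, sodium
#' inactivation slaved to the potassium gate as `0.89 - 1.1 n`, potassium
#' gate `n` with the classical voltage-dependent rate functions) plus a
#' high-threshold calcium current
#' \deqn{I_{Ca} = g_{Ca}\, m^3 h\, (V - E_{Ca})}
#' whose activation gate `m` opens only near the spike peak
#' (Boltzmann steady state centred at `theta_m`) and whose inactivation
#' gate `h` closes slowly above `theta_h`.
#'
#' Units: capacitance in uF/cm^2, conductances in mS/cm^2, potentials in mV,
#' time constants in ms.  `g_Ca` is the single-terminal calcium conductance;
#' with the default value the calcium current is reported on the nA display
#' scale used throughout (see [simulate_hh()] for the charge convention).
#' `tau_p` and `tau_n` are retained as part of the published parameter set;
#' the classical rate functions (whose prefactors are `eta_p`, `eta_n` and
#' slopes `sigma_p`, `sigma_n`) govern the kinetics of `p` and `n`.
#'
#' @param C membrane capacitance (uF/cm^2)
#' @param g_Na,g_K,g_L,g_Ca maximal conductances (mS/cm^2)
#' @param E_Na,E_K,E_L,E_Ca reversal potentials (mV)
#' @param tau_p,theta_p,eta_p,sigma_p sodium-activation gating parameters
#' @param tau_n,theta_n,eta_n,sigma_n potassium gating parameters
#' @param tau_h,theta_h,sigma_h calcium inactivation gate (ms, mV, mV)
#' @param tau_m,theta_m,sigma_m calcium activation gate (ms, mV, mV)
#' @param V0,n0,m0,h0 initial values; the defaults are the equilibrium
#'   solution of the model, so the membrane rests until stimulated
#' @return an object of class `hh_params`
#' @export
hh_params <- function(C = 1,
                      g_Na = 120, E_Na = 50,
                      g_K = 36, E_K = -77,
                      g_L = 0.3, E_L = -54.4,
                      g_Ca = 14.5e-9, E_Ca = 140,
                      tau_p = 10, theta_p = -40, eta_p = 4, sigma_p = 18,
                      tau_n = 10, theta_n = -55, eta_n = 0.125, sigma_n = 80,
                      tau_h = 10, theta_h = -41, sigma_h = -0.5,
                      tau_m = 1.3, theta_m = 37, sigma_m = 1,
                      V0 = -65.0974, n0 = 0.3162, m0 = 4.5649e-45, h0 = 1) {
  p <- as.list(environment())
  if (p$C <= 0) stop("capacitance must be positive")
  for (g in c("g_Na", "g_K", "g_L", "g_Ca"))
    if (p[[g]] < 0) stop(g, " must be non-negative")
  for (tau in c("tau_m", "tau_h"))
    if (p[[tau]] <= 0) stop(tau, " must be positive")
  structure(p, class = "hh_params")
}

#' Depolarizing stimulus protocol
#'
#' The action potential is evoked by a rectangular forcing term added to the
#' voltage equation: `amplitude` (in mV/ms, i.e. current over capacitance)
#' applied from `onset` for `duration` milliseconds.
#'
#' @param amplitude forcing amplitude (default 50)
#' @param onset stimulus onset (ms)
#' @param duration stimulus duration (ms); must be positive
#' @return an object of class `stimulus_protocol`
#' @export
stimulus_protocol <- function(amplitude = 50, onset = 1, duration = 1) {
  if (duration <= 0) stop("stimulus duration must be positive")
  if (onset < 0) stop("stimulus onset must be non-negative")
  structure(list(amplitude = amplitude, onset = onset, duration = duration),
            class = "stimulus_protocol")
}

# classical voltage-dependent rate functions (limits taken at removable
# singularities)
.hh_alpha_p <- function(V, theta = -40) {
  x <- V - theta
  ifelse(abs(x) < 1e-7, 1, 0.1 * x / (1 - exp(-x / 10)))
}
.hh_beta_p <- function(V, eta = 4, sigma = 18) eta * exp(-(V + 65) / sigma)
.hh_alpha_n <- function(V, theta = -55) {
  x <- V - theta
  ifelse(abs(x) < 1e-7, 0.1, 0.01 * x / (1 - exp(-x / 10)))
}
.hh_beta_n <- function(V, eta = 0.125, sigma = 80) eta * exp(-(V + 65) / sigma)

.hh_p_inf <- function(V, par) {
  a <- .hh_alpha_p(V, par$theta_p)
  a / (a + .hh_beta_p(V, par$eta_p, par$sigma_p))
}
.hh_n_inf <- function(V, par) {
  a <- .hh_alpha_n(V, par$theta_n)
  a / (a + .hh_beta_n(V, par$eta_n, par$sigma_n))
}
.boltzmann <- function(V, theta, sigma) 1 / (1 + exp(-(V - theta) / sigma))

# calcium current on the display (nA) scale: g_Ca[mS] * mV gives uA;
# the 1e9 factor moves the numeric value onto the printed nA axis
# (physically the single-channel current is of fA magnitude, see vignette)
.hh_ica <- function(V, m, h, par) 1e9 * par$g_Ca * m^3 * h * (V - par$E_Ca)

#' Simulate the calcium current evoked by an action potential
#'
#' Integrates the reduced excitable-membrane model from its resting state,
#' applies the depolarizing stimulus, and returns the voltage, gating
#' variables, calcium current, cumulative charge and per-channel ion influx
#' on a regular output grid.
#'
#' Charge convention: the current column is on the nA display scale; the
#' cumulative charge is `Q_fC = 1e-3 * integral |I_Ca| dt`, the scaling under
#' which the default conductance yields the literature count of roughly 80
#' calcium ions per channel per action potential (one display nA equals one
#' femtoampere of physical single-channel current).
#'
#' @param params an [hh_params()] object
#' @param stimulus a [stimulus_protocol()] object
#' @param t_end end of the simulation (ms); must cover the stimulus plus a
#'   10 ms tail
#' @param dt_out output grid spacing (ms)
#' @param rtol,atol integrator tolerances
#' @return a data frame of class `current_trace` with columns `t_ms`, `V_mV`,
#'   `n`, `m`, `h`, `I_Ca_nA`, `Q_fC`
#' @export
simulate_hh <- function(params = hh_params(), stimulus = stimulus_protocol(),
                        t_end = 40, dt_out = 0.01,
                        rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "hh_params"), inherits(stimulus, "stimulus_protocol"))
  if (t_end < stimulus$onset + stimulus$duration + 10)
    stop("t_end must cover the stimulus onset plus a tail of at least 10 ms")
  par <- params
  rhs <- function(t, y, iapp) {
    V <- y[1]; n <- y[2]; m <- y[3]; h <- y[4]
    p <- .hh_p_inf(V, par)
    hNa <- 0.89 - 1.1 * n
    ica_den <- par$g_Ca * m^3 * h * (V - par$E_Ca) # mS/cm2 scale, negligible
    dV <- (iapp -
             par$g_Na * p^3 * hNa * (V - par$E_Na) -
             par$g_K * n^4 * (V - par$E_K) -
             par$g_L * (V - par$E_L) - ica_den) / par$C
    dn <- .hh_alpha_n(V, par$theta_n) * (1 - n) -
      .hh_beta_n(V, par$eta_n, par$sigma_n) * n
    dm <- (.boltzmann(V, par$theta_m, par$sigma_m) - m) / par$tau_m
    dh <- (.boltzmann(V, par$theta_h, par$sigma_h) - h) / par$tau_h
    list(c(dV, dn, dm, dh))
  }
  # integrate piecewise so the stimulus discontinuities fall on segment ends
  brk <- sort(unique(pmin(pmax(c(0, stimulus$onset,
                                 stimulus$onset + stimulus$duration, t_end),
                               0), t_end)))
  brk <- brk[!duplicated(signif(brk, 12))]
  y <- c(par$V0, par$n0, par$m0, par$h0)
  segs <- list()
  for (i in seq_len(length(brk) - 1)) {
    tt <- seq(brk[i], brk[i + 1], by = dt_out)
    if (tail(tt, 1) < brk[i + 1]) tt <- c(tt, brk[i + 1])
    iapp <- if (brk[i] >= stimulus$onset &&
                brk[i] < stimulus$onset + stimulus$duration)
      stimulus$amplitude else 0
    out <- deSolve::lsoda(y, tt, rhs, iapp, rtol = rtol, atol = atol)
    if (any(!is.finite(out)))
      stop(sprintf("integration failure: non-finite state near t = %.4g ms",
                   out[which(!is.finite(out), arr.ind = TRUE)[1, 1], 1]))
    y <- as.numeric(out[nrow(out), -1])
    segs[[i]] <- out[if (i > 1) -1 else TRUE, , drop = FALSE]
  }
  out <- do.call(rbind, segs)
  V <- out[, 2]; n <- out[, 3]; m <- out[, 4]; h <- out[, 5]
  ica <- .hh_ica(V, m, h, par)
  tms <- out[, 1]
  aI <- abs(ica)
  # running trapezoidal integral of |I_Ca|, converted to fC
  Q <- 1e-3 * c(0, cumsum((aI[-1] + aI[-length(aI)]) / 2 * diff(tms)))
  trace <- data.frame(t_ms = tms, V_mV = V, n = n, m = m, h = h,
                      I_Ca_nA = ica, Q_fC = Q)
  class(trace) <- c("current_trace", "data.frame")
  attr(trace, "params") <- params
  attr(trace, "stimulus") <- stimulus
  trace
}

#' Peak magnitude of the calcium current
#' @param trace a `current_trace`
#' @return peak of `|I_Ca|` (nA display scale)
#' @export
peak_current <- function(trace) max(abs(trace$I_Ca_nA))

#' Duration of the calcium transient
#'
#' Width of the interval over which `|I_Ca|` exceeds `frac` of its peak,
#' with the crossing times linearly interpolated.
#'
#' @param trace a `current_trace`
#' @param frac detection threshold as a fraction of the peak (default 1\%)
#' @return transient width in ms
#' @export
transient_width <- function(trace, frac = 0.01) {
  aI <- abs(trace$I_Ca_nA)
  thr <- frac * max(aI)
  ix <- which(aI > thr)
  if (!length(ix)) return(0)
  i1 <- min(ix); i2 <- max(ix)
  t1 <- if (i1 > 1)
    approx(aI[(i1 - 1):i1], trace$t_ms[(i1 - 1):i1], thr)$y else trace$t_ms[i1]
  t2 <- if (i2 < nrow(trace))
    approx(aI[i2:(i2 + 1)], trace$t_ms[i2:(i2 + 1)], thr)$y else trace$t_ms[i2]
  t2 - t1
}

#' Convert a charge to an ion count
#'
#' @param Q_fC charge in femtocoulomb; must be non-negative
#' @param valence ion valence (2 for calcium)
#' @return integer number of ions, `round(Q / (valence * e))`
#' @export
ions_from_charge <- function(Q_fC, valence = 2) {
  if (any(Q_fC < 0)) stop("charge must be non-negative")
  if (valence < 1) stop("valence must be at least 1")
  round(Q_fC * 1e-15 / (valence * .e_charge))
}

#' Per-channel ion influx profile
#'
#' Converts the simulated calcium current into a time-dependent ion influx
#' rate J(t) (ions per ms per channel), `J = |I_Ca| / (valence e)` under the
#' charge convention of [simulate_hh()].  The returned object carries the
#' grid, the total (unrounded) ion count and an interpolator that is clamped
#' to zero outside the simulated window.
#'
#' @param trace a `current_trace`
#' @param valence ion valence (default 2, calcium)
#' @return an object of class `influx_profile` with elements `t`, `J`,
#'   `total_ions`, `fun` (vectorized interpolator), `valence`
#' @export
influx_profile <- function(trace, valence = 2) {
  stopifnot(inherits(trace, "current_trace"))
  # dQ/dt in fC/ms is 1e-3 |I|; ions/ms = (fC/ms) * 1e-15 / (valence e)
  J <- abs(trace$I_Ca_nA) * 1e-18 / (valence * .e_charge)
  tt <- trace$t_ms
  total <- sum((J[-1] + J[-length(J)]) / 2 * diff(tt))
  sf <- stats::splinefun(tt, J, method = "monoH.FC")
  lo <- min(tt); hi <- max(tt)
  fun <- function(t) {
    out <- numeric(length(t))
    inside <- t >= lo & t <= hi
    out[inside] <- pmax(0, sf(t[inside]))
    out
  }
  structure(list(t = tt, J = J, total_ions = total, fun = fun,
                 valence = valence),
            class = "influx_profile")
}

#' Write a current trace (with influx) to CSV
#'
#' @param trace a `current_trace`
#' @param path output file
#' @param valence ion valence used for the influx column
#' @return the path, invisibly
#' @export
write_current_trace <- function(trace, path, valence = 2) {
  inf <- influx_profile(trace, valence)
  df <- cbind(trace, J_ions_per_ms = inf$J)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf(paste0(
    "Calcium current trace: %d points over %.4g ms\n",
    "  peak |I_Ca| %.4g nA, 1%%-width %.4g ms, total charge %.4g fC\n"),
    nrow(x), max(x$t_ms), peak_current(x), transient_width(x),
    max(x$Q_fC)))
  invisible(x)
}
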