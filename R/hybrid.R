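#' Pure-birth Markov derivative for the target occupancy probabilities
#'
#' Time-derivative of the per-target occupancy distribution
#' `Pr[i, k+1] = Pr{k ions bound at target i}` under the pure-birth chain
#' with per-target arrival rate `lambda[i]`: probability flows from `k - 1`
#' to `k` at rate lambda, the last column (`k = T`) is absorbing, and there
#' is no unbinding.
#'
#' @param Pr matrix `n_targets x (T + 1)` of occupancy probabilities
#' @param lambda per-target arrival rates (non-negative; same time unit as
#'   the returned derivative)
#' @return matrix of time-derivatives, rows summing to zero
#' @export
markov_rhs <- function(Pr, lambda) {
  if (any(lambda < 0)) stop("negative arrival rate")
  if (length(lambda) != nrow(Pr)) stop("one rate per target required")
  K <- ncol(Pr)
  dPr <- matrix(0, nrow(Pr), K)
  dPr[, 1] <- -lambda * Pr[, 1]
  if (K > 2)
    for (k in 2:(K - 1)) dPr[, k] <- lambda * (Pr[, k - 1] - Pr[, k])
  dPr[, K] <- lambda * Pr[, K - 1]
  dPr
}

#' Mass-action derivative for the bulk ion pool
#'
#' Derivatives of the free (`N_f`) and buffer-bound (`N_b`) ion counts:
#' reversible buffering, the bulk share of the channel influx, loss by neck
#' escape and by binding to free targets, and the re-injection jump of `T`
#' ions whenever a target activates (evaluated analytically as
#' `T * sum(lambda * Pr[, T])`).
#'
#' @param N_f,N_b free and buffer-bound ion counts
#' @param Pr occupancy matrix as in [markov_rhs()]
#' @param lambda per-target arrival rates (1/ms)
#' @param influx_bulk bulk share of the influx (ions/ms)
#' @param rates a [rate_set()] (rates in 1/s; converted internally)
#' @param S_tot total number of buffer sites
#' @param free_target_sum if `TRUE` (default) the target sink counts each
#'   target by its probability of still being free, `1 - Pr{T}`; otherwise
#'   all targets are counted
#' @return `c(dN_f, dN_b)` in ions/ms
#' @export
bulk_rhs <- function(N_f, N_b, Pr, lambda, influx_bulk, rates, S_tot,
                     free_target_sum = TRUE) {
  if (S_tot - N_b < -1e-9) stop("buffer occupancy exceeds S_tot")
  k0 <- rates$k_0 / 1000; km1 <- rates$k_minus_1 / 1000
  kes <- rates$k_es / 1000; kT <- rates$k_T / 1000
  K <- ncol(Pr)
  free_sum <- if (free_target_sum) sum(1 - Pr[, K]) else nrow(Pr)
  jump <- (K - 1) * sum(lambda * Pr[, K - 1])
  dNf <- km1 * N_b - k0 * N_f * (S_tot - N_b) + influx_bulk -
    (kes + kT * free_sum) * N_f + jump
  dNb <- k0 * N_f * (S_tot - N_b) - km1 * N_b
  c(dNf, dNb)
}

#' Solve the coupled hybrid Markov-mass-action system
#'
#' Integrates, from `Pr{0, 0} = 1` and an empty bulk, the coupled system of
#' per-target pure-birth chains driven by the direct channel flux plus bulk
#' arrivals (`lambda_i(t) = J(t) w_i + k_T N_f(t)`), and the mass-action
#' equations for the free and buffered bulk ions.
#'
#' @param geom a [synapse_geometry()]
#' @param params a [transport_params()]
#' @param rates a [rate_set()]
#' @param channels a [place_channels()] matrix
#' @param influx an [influx_profile()] (or `current_trace`)
#' @param table an [estimate_q()] splitting table
#' @param t_end end time (ms)
#' @param free_target_sum see [bulk_rhs()]
#' @param rtol,atol integrator tolerances
#' @param times optional explicit output grid (ms); the default is 0.1 ms
#'   resolution up to 20 ms and 1 ms beyond
#' @return an object of class `hybrid_solution`: output times `t`, occupancy
#'   array `Pr` (`time x target x (T+1)`), bulk counts `N_f`, `N_b`, arrival
#'   rates `lambda`, per-target activation densities `f` (1/ms), cumulative
#'   activation probabilities `F`, and the direct-flux weights used
#' @export
solve_hybrid <- function(geom, params, rates, channels, influx, table,
                         t_end = 1000, free_target_sum = TRUE,
                         rtol = 1e-8, atol = 1e-10, times = NULL) {
  if (inherits(influx, "current_trace")) influx <- influx_profile(influx)
  stopifnot(inherits(influx, "influx_profile"), inherits(rates, "rate_set"))
  nT <- geom$n_targets
  Tthr <- params$threshold
  K <- Tthr + 1
  cw <- channel_weights(channels, geom, table)
  Jfun <- influx$fun
  kT <- rates$k_T / 1000
  k0 <- rates$k_0 / 1000
  km1 <- rates$k_minus_1 / 1000
  kes <- rates$k_es / 1000
  S <- params$S_tot
  w <- cw$w
  bulk_w <- cw$bulk_share
  npr <- nT * K
  rhs <- function(t, y, parms) {
    Pr <- matrix(y[seq_len(npr)], nT, K)
    Nf <- y[npr + 1]; Nb <- y[npr + 2]
    J <- Jfun(t)
    lam <- J * w + kT * max(Nf, 0)
    dPr <- matrix(0, nT, K)
    dPr[, 1] <- -lam * Pr[, 1]
    if (K > 2)
      for (k in 2:(K - 1)) dPr[, k] <- lam * (Pr[, k - 1] - Pr[, k])
    dPr[, K] <- lam * Pr[, K - 1]
    free_sum <- if (free_target_sum) sum(1 - Pr[, K]) else nT
    jump <- Tthr * sum(lam * Pr[, K - 1])
    # direct flux aimed at an already-released target joins the bulk
    diverted <- J * sum(w * Pr[, K])
    dNf <- km1 * Nb - k0 * Nf * (S - Nb) + J * bulk_w + diverted -
      (kes + kT * free_sum) * Nf + jump
    dNb <- k0 * Nf * (S - Nb) - km1 * Nb
    list(c(as.vector(dPr), dNf, dNb))
  }
  if (is.null(times))
    times <- unique(c(seq(0, min(20, t_end), by = 0.1),
                      if (t_end > 20) seq(21, t_end, by = 1), t_end))
  y0 <- c(as.vector(cbind(rep(1, nT), matrix(0, nT, K - 1))), 0, 0)
  out <- deSolve::lsoda(y0, times, rhs, NULL, rtol = rtol, atol = atol)
  if (any(!is.finite(out))) stop("hybrid solver failure: non-finite state")
  tt <- out[, 1]
  Pr <- array(out[, 1 + seq_len(npr)], dim = c(length(tt), nT, K))
  norm_err <- max(abs(apply(Pr, c(1, 2), sum) - 1))
  if (norm_err > 1e-4)
    stop(sprintf("occupancy normalization violated (max error %.3g)",
                 norm_err))
  Nf <- out[, npr + 2]; Nb <- out[, npr + 3]
  J <- Jfun(tt)
  lambda <- outer(J, w) + kT * pmax(Nf, 0) # time x target, 1/ms
  f <- lambda * Pr[, , K - 1]
  Fcum <- Pr[, , K]
  # cumulative influx per channel on the (fine) influx grid, sampled at the
  # output times; used by the cascade reconstruction
  cJ <- c(0, cumsum((influx$J[-1] + influx$J[-length(influx$J)]) / 2 *
                      diff(influx$t)))
  cum_J <- approx(influx$t, cJ, pmin(pmax(tt, min(influx$t)),
                                     max(influx$t)), rule = 2)$y
  structure(list(t = tt, Pr = Pr, N_f = Nf, N_b = Nb, lambda = lambda,
                 f = f, F = Fcum, release_prob = Fcum[length(tt), ],
                 cum_J = cum_J, k_T_ms = kT,
                 weights = w, bulk_share = bulk_w, threshold = Tthr,
                 norm_error = norm_err, free_target_sum = free_target_sum,
                 rates = rates, S_tot = S),
            class = "hybrid_solution")
}

#' Closed-form cascade reconstruction of the occupancy probabilities
#'
#' Given a solved trajectory, re-derives the occupancy probabilities by
#' direct integration of the cascade: with cumulative intensity
#' `Lambda_i(t)`, the pure-birth chain gives the truncated-Poisson solution
#' `Pr{k, t} = Lambda^k e^(-Lambda)/k!` for `k < T` and
#' `Pr{T, t} = P(N >= T)`.  Agreement with the ODE solution (to solver
#' tolerance) is a consistency check of the coupled integration.
#'
#' @param sol a [solve_hybrid()] solution
#' @return array matching `sol$Pr`
#' @export
cascade_probabilities <- function(sol) {
  tt <- sol$t
  nT <- dim(sol$Pr)[2]; K <- dim(sol$Pr)[3]
  Pr <- array(0, dim(sol$Pr))
  # bulk part of the cumulative intensity (N_f is smooth on the output grid;
  # the direct part uses the exact cumulative influx)
  nf <- pmax(sol$N_f, 0)
  Lam_bulk <- sol$k_T_ms *
    c(0, cumsum((nf[-1] + nf[-length(nf)]) / 2 * diff(tt)))
  for (i in seq_len(nT)) {
    Lam <- sol$weights[i] * sol$cum_J + Lam_bulk
    for (k in 0:(K - 2)) Pr[, i, k + 1] <- stats::dpois(k, Lam)
    Pr[, i, K] <- stats::ppois(K - 2, Lam, lower.tail = FALSE)
  }
  Pr
}

.trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))

#' Release-time densities of a hybrid solution
#'
#' Per-target activation densities `f_i(t) = lambda_i(t) Pr_i{T-1, t}` and
#' the aggregate density (sum over targets normalized by the total expected
#' number of releases, so it integrates to 1 over the solved window).
#'
#' @param sol a [solve_hybrid()] solution
#' @return data frame with `t`, one `f_<i>` column per target, and
#'   `aggregate`; attribute `total_release` holds the expected number of
#'   releases by `t_end`
#' @export
release_pdf <- function(sol) {
  total <- sum(sol$release_prob)
  agg <- rowSums(sol$f)
  df <- data.frame(t = sol$t, sol$f,
                   aggregate = if (total > 0) agg / total else agg * 0)
  names(df)[1 + seq_len(ncol(sol$f))] <- paste0("f_", seq_len(ncol(sol$f)))
  attr(df, "total_release") <- total
  df
}

#' Mean release time per target
#'
#' `integral t f_i(t) dt` over the solved window.  If a target's cumulative
#' activation probability has not reached `complete_tol` by the end of the
#' window the conditional mean (normalized by the achieved probability) is
#' reported and flagged.
#'
#' @param sol a [solve_hybrid()] solution
#' @param complete_tol completeness threshold (default 0.999)
#' @return data frame with `target`, `mean_ms`, `release_prob`,
#'   `conditional`
#' @export
mean_release_time <- function(sol, complete_tol = 0.999) {
  nT <- ncol(sol$f)
  m <- numeric(nT); cond <- logical(nT)
  for (i in seq_len(nT)) {
    raw <- .trapz(sol$t, sol$t * sol$f[, i])
    p <- sol$release_prob[i]
    cond[i] <- p < complete_tol
    m[i] <- if (cond[i] && p > 0) raw / p else raw
  }
  data.frame(target = seq_len(nT), mean_ms = m,
             release_prob = sol$release_prob, conditional = cond)
}

#' Average the release density over random channel placements
#'
#' Draws `n_realizations` independent uniform channel placements, solves the
#' hybrid system for each, and averages the aggregate release intensity.
#' The returned density is the placement-averaged intensity normalized by
#' the average expected number of releases.
#'
#' @param geom,params,rates,influx,table as in [solve_hybrid()]
#' @param n_realizations number of placements (default 150)
#' @param seed master seed; per-realization seeds are derived
#'   deterministically from it
#' @param t_end,free_target_sum,times passed to [solve_hybrid()]
#' @param placements optional list of pre-drawn placements (overrides
#'   `n_realizations` and `seed`)
#' @return an object of class `release_density`: grid `t`, normalized
#'   `density`, mean release `intensity` (releases/ms), expected releases
#'   per realization (`mean_releases`), per-realization expected release
#'   counts, the placements and their seeds
#' @export
monte_carlo_release <- function(geom, params, rates, influx, table,
                                n_realizations = 150, seed = 1,
                                t_end = 1000, free_target_sum = TRUE,
                                times = NULL, placements = NULL) {
  if (inherits(influx, "current_trace")) influx <- influx_profile(influx)
  if (n_realizations < 1) stop("need at least one realization")
  seeds <- .child_seeds(seed, n_realizations)
  if (is.null(placements))
    placements <- lapply(seeds, function(s)
      place_channels(geom, params$n_channels, s))
  n <- length(placements)
  intensity <- NULL
  cum <- NULL
  per_real <- numeric(n)
  tt <- NULL
  for (j in seq_len(n)) {
    sol <- tryCatch(
      solve_hybrid(geom, params, rates, placements[[j]], influx, table,
                   t_end = t_end, free_target_sum = free_target_sum,
                   times = times),
      error = function(e) stop(sprintf(
        "realization %d (seed %d) failed: %s", j, seeds[j],
        conditionMessage(e))))
    agg <- rowSums(sol$f)
    cm <- rowSums(sol$F) # exact cumulative: absorbing-state occupancy
    if (is.null(intensity)) { intensity <- agg; cum <- cm; tt <- sol$t }
    else { intensity <- intensity + agg; cum <- cum + cm }
    per_real[j] <- sum(sol$release_prob)
  }
  intensity <- intensity / n
  cum <- cum / n
  mean_rel <- mean(per_real)
  structure(list(t = tt, density = if (mean_rel > 0) intensity / mean_rel
                 else intensity, intensity = intensity, cum_releases = cum,
                 mean_releases = mean_rel, per_realization = per_real,
                 placements = placements, seeds = seeds,
                 n_realizations = n),
            class = "release_density")
}

# deterministic positive child seeds below 2^31
.child_seeds <- function(seed, n) {
  vapply(seq_len(n), function(i)
    as.integer((as.double(seed) * 1009 + 7919 * i) %% 2147483647L) + 1L,
    integer(1))
}

#' @export
print.hybrid_solution <- function(x, ...) {
  cat(sprintf(paste0(
    "Hybrid Markov-mass-action solution: %d targets, threshold %d, ",
    "t_end %.4g ms\n  expected releases %.3f, max normalization error ",
    "%.2g\n"),
    dim(x$Pr)[2], x$threshold, max(x$t), sum(x$release_prob),
    x$norm_error))
  invisible(x)
}

#' @export
print.release_density <- function(x, ...) {
  cat(sprintf(paste0(
    "Placement-averaged release density: %d realizations, t_end %.4g ms\n",
    "  mean expected releases per realization %.3f\n"),
    x$n_realizations, max(x$t), x$mean_releases))
  invisible(x)
}
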