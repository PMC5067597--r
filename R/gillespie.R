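#' Reaction propensities of the stochastic bulk model
#'
#' @param N_f,N_b free and buffer-bound ion counts
#' @param released logical vector, which targets have already released
#' @param rates a [rate_set()]
#' @param S_tot total buffer sites
#' @return named vector of propensities (1/s): `buffer_bind`,
#'   `buffer_release`, `escape`, then `target_<i>` (zero for released
#'   targets)
#' @export
propensities <- function(N_f, N_b, released, rates, S_tot) {
  if (N_f < 0 || N_b < 0) stop("negative counts")
  if (N_b > S_tot) stop("buffer occupancy exceeds S_tot")
  a <- c(buffer_bind = rates$k_0 * N_f * (S_tot - N_b),
         buffer_release = rates$k_minus_1 * N_b,
         escape = rates$k_es * N_f,
         setNames(rates$k_T * N_f * as.numeric(!released),
                  paste0("target_", seq_along(released))))
  a
}

# inverse-CDF sampler of the influx: returns a function u in [0, total] -> t
.influx_invcdf <- function(influx) {
  tt <- influx$t; J <- influx$J
  cum <- c(0, cumsum((J[-1] + J[-length(J)]) / 2 * diff(tt)))
  keep <- !duplicated(cum)
  if (sum(keep) < 2) return(function(u) rep(tt[1], length(u)))
  stats::approxfun(cum[keep], tt[keep], rule = 2)
}

#' Sample ion injection times for one realization
#'
#' The arrival of ions through each channel is an inhomogeneous Poisson
#' process with intensity `J(t)`: the count is Poisson with mean
#' `integral J dt` and the times are drawn by inverting the cumulative
#' intensity (exact for a tabulated rate).
#'
#' @param influx an [influx_profile()]
#' @param n_channels number of channels
#' @param seed optional seed
#' @return data frame with `t` (ms, sorted) and `channel`
#' @export
sample_injections <- function(influx, n_channels, seed = NULL) {
  inv <- .influx_invcdf(influx)
  total <- influx$total_ions
  .with_seed(seed, {
    k <- rpois(n_channels, total)
    df <- data.frame(t = inv(runif(sum(k)) * total),
                     channel = rep(seq_len(n_channels), k))
    df[order(df$t), , drop = FALSE]
  })
}

#' Configuration for a single stochastic realization
#'
#' @param geom,params,rates,influx,table as in [solve_hybrid()]
#' @param channels a [place_channels()] matrix
#' @param t_max simulation horizon (ms)
#' @param seed integer seed (recorded in the output)
#' @return an object of class `ssa_config`
#' @export
ssa_config <- function(geom, params, rates, channels, influx, table,
                       t_max = 1000, seed = 1) {
  if (inherits(influx, "current_trace")) influx <- influx_profile(influx)
  cw <- channel_weights(channels, geom, table)
  structure(list(geom = geom, params = params, rates = rates,
                 channels = channels, influx = influx, alloc = cw$alloc,
                 t_max = t_max, seed = as.integer(seed)),
            class = "ssa_config")
}

#' Run one exact stochastic realization (with event log)
#'
#' Performs an exact Gillespie simulation of the bulk network with the
#' scheduled channel injections: each injected ion goes straight to target
#' `i` with probability `p_s q_i` or to the bulk with probability
#' `1 - p_s`, evaluated at its channel's position.  A target that
#' accumulates `T` ions releases: the time is recorded, the `T` ions return
#' to the bulk and the target is retired.  Reaching `t_max` with targets
#' unreleased is normal termination.
#'
#' @param config an [ssa_config()]
#' @return an object of class `ssa_result`: event `log` (time, type code,
#'   index, running counts), `release_time`, `release_target`, final
#'   `ledger`, the injection schedule and the seed.  Event type codes:
#'   1 arrival to bulk, 2 direct arrival to a target, 3 buffer binding,
#'   4 buffer release, 5 escape, 6 target binding from the bulk, 7 release.
#' @export
ssa_run <- function(config) {
  stopifnot(inherits(config, "ssa_config"))
  nT <- config$geom$n_targets
  inj <- sample_injections(config$influx, nrow(config$channels),
                           seed = config$seed)
  dest <- integer(nrow(inj))
  .with_seed(config$seed + 1L, {
    for (i in seq_len(nrow(inj))) {
      d <- sample.int(nT + 1, 1, prob = config$alloc[inj$channel[i], ])
      dest[i] <- if (d > nT) 0L else d
    }
  })
  res <- ssa_single_cpp(inj$t, dest,
                        config$rates$k_0 / 1000,
                        config$rates$k_minus_1 / 1000,
                        config$rates$k_es / 1000, config$rates$k_T / 1000,
                        as.integer(config$params$S_tot),
                        as.integer(config$params$threshold),
                        as.integer(nT), config$t_max, config$seed + 2L)
  structure(list(log = res$log, release_time = res$release_time,
                 release_target = res$release_target,
                 bound_end = res$bound_end, released_end = res$released_end,
                 ledger = res$ledger, injections = cbind(inj, dest = dest),
                 seed = config$seed),
            class = "ssa_result")
}

#' Ensemble of stochastic realizations
#'
#' Runs `n_runs` exact realizations, cycling through the supplied channel
#' placements (so the placement ensemble matches a hybrid Monte-Carlo
#' average computed on the same placements).  All sampling is vectorized;
#' the event loops run in compiled code.
#'
#' @param geom,params,rates,influx,table as in [solve_hybrid()]
#' @param placements a list of [place_channels()] matrices (or a single
#'   matrix)
#' @param n_runs number of realizations
#' @param t_max horizon (ms)
#' @param seed master seed
#' @return an object of class `ssa_ensemble`: pooled `release_time`,
#'   `release_run`, `release_target`, the per-run integer `ledger`
#'   (entered / escaped / free / buffer-bound / target-bound / released /
#'   events / redirected) and bookkeeping fields
#' @export
ssa_release <- function(geom, params, rates, influx, table, placements,
                        n_runs = 1000, t_max = 1000, seed = 1) {
  if (inherits(influx, "current_trace")) influx <- influx_profile(influx)
  if (is.matrix(placements)) placements <- list(placements)
  m <- length(placements)
  nT <- geom$n_targets
  nc <- nrow(placements[[1]])
  allocs <- lapply(placements, function(p)
    channel_weights(p, geom, table)$alloc)
  inv <- .influx_invcdf(influx)
  total <- influx$total_ions
  samp <- .with_seed(seed, {
    K <- matrix(rpois(n_runs * nc, total), n_runs, nc, byrow = TRUE)
    kvec <- as.vector(t(K))
    ion_run <- rep(rep(seq_len(n_runs), each = nc), kvec)
    ion_ch <- rep(rep(seq_len(nc), n_runs), kvec)
    tarr <- inv(runif(sum(K)) * total)
    dest <- integer(length(tarr))
    pl_of_run <- (ion_run - 1L) %% m + 1L
    for (p in seq_len(m)) for (cch in seq_len(nc)) {
      idx <- which(pl_of_run == p & ion_ch == cch)
      if (length(idx)) {
        d <- sample.int(nT + 1, length(idx), replace = TRUE,
                        prob = allocs[[p]][cch, ])
        dest[idx] <- ifelse(d > nT, 0L, d)
      }
    }
    o <- order(ion_run, tarr)
    list(run = ion_run[o], t = tarr[o], dest = dest[o])
  })
  res <- ssa_batch_cpp(as.integer(samp$run - 1L), samp$t,
                       as.integer(samp$dest), as.integer(n_runs),
                       rates$k_0 / 1000, rates$k_minus_1 / 1000,
                       rates$k_es / 1000, rates$k_T / 1000,
                       as.integer(params$S_tot),
                       as.integer(params$threshold), as.integer(nT),
                       t_max, as.integer(seed) + 1L)
  structure(list(release_time = res$release_time,
                 release_run = res$release_run,
                 release_target = res$release_target,
                 ledger = res$ledger, n_runs = n_runs, t_max = t_max,
                 seed = seed, n_placements = m),
            class = "ssa_ensemble")
}

#' Empirical release-time histogram
#'
#' @param result an `ssa_ensemble` (or any list with `release_time`,
#'   `release_run`, `n_runs`)
#' @param breaks bin edges in ms (default 2 ms bins on 0..300)
#' @param events `"all"` pools every release (total mass = mean releases per
#'   run); `"first"` keeps only each run's first release (total mass =
#'   fraction of runs with at least one release)
#' @return data frame with bin `mid`, `density` (per ms) and `count`;
#'   attributes `breaks`, `mass` and `frac_beyond` (releases after the last
#'   break, excluded)
#' @export
release_histogram <- function(result, breaks = seq(0, 300, by = 2),
                              events = c("all", "first")) {
  events <- match.arg(events)
  rt <- result$release_time
  if (events == "first" && length(rt)) {
    keep <- !duplicated(result$release_run)
    ord <- order(result$release_run, rt)
    keep <- ord[!duplicated(result$release_run[ord])]
    rt <- rt[keep]
  }
  if (!length(rt)) {
    h <- data.frame(mid = head(breaks, -1) + diff(breaks) / 2,
                    density = 0, count = 0L)
    attr(h, "empty") <- TRUE
    attr(h, "breaks") <- breaks
    attr(h, "mass") <- 0
    attr(h, "frac_beyond") <- 0
    return(h)
  }
  inside <- rt >= breaks[1] & rt <= tail(breaks, 1)
  cnt <- hist(rt[inside], breaks = breaks, plot = FALSE)$counts
  dens <- cnt / (result$n_runs * diff(breaks))
  h <- data.frame(mid = head(breaks, -1) + diff(breaks) / 2,
                  density = dens, count = cnt)
  attr(h, "empty") <- FALSE
  attr(h, "breaks") <- breaks
  attr(h, "mass") <- sum(cnt) / result$n_runs
  attr(h, "frac_beyond") <- mean(!inside)
  h
}

#' @export
print.ssa_ensemble <- function(x, ...) {
  cat(sprintf(paste0(
    "Gillespie ensemble: %d runs to %.4g ms (%d placements cycled)\n",
    "  %d releases (%.2f per run), %.3g events total\n"),
    x$n_runs, x$t_max, x$n_placements, length(x$release_time),
    length(x$release_time) / x$n_runs, sum(as.numeric(x$ledger[, "events"]))))
  invisible(x)
}
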