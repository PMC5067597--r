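#' Detect modes of a release-time density
#'
#' Smooths the density with a Gaussian kernel (bandwidth `bw` ms) on a
#' uniform grid over `window` and reports local maxima whose topographic
#' prominence is at least `prominence_frac` of the global maximum.  The
#' mass of each mode is the integral of the smoothed density over its basin
#' (between the flanking minima).
#'
#' @param t,y density sampled at times `t` (ms)
#' @param bw Gaussian smoothing bandwidth (ms)
#' @param window analysis window (ms)
#' @param dt grid resolution (ms)
#' @param prominence_frac prominence threshold as a fraction of the global
#'   maximum
#' @return data frame with one row per detected mode: `location`, `height`,
#'   `prominence`, `mass`, ordered by location
#' @export
detect_modes <- function(t, y, bw = 2, window = c(0, 500), dt = 0.5,
                         prominence_frac = 0.05) {
  grid <- seq(window[1], window[2], by = dt)
  yg <- approx(t, y, grid, rule = 2)$y
  if (bw > 0) {
    kh <- dnorm(seq(-4 * bw, 4 * bw, by = dt), sd = bw)
    kh <- kh / sum(kh)
    # reflect-pad so boundary modes are not attenuated
    npad <- (length(kh) - 1) / 2
    ypad <- c(rev(yg[seq_len(npad) + 1]), yg,
              rev(yg[length(yg) - seq_len(npad)]))
    yg <- stats::filter(ypad, kh, sides = 2)[npad + seq_along(grid)]
  }
  n <- length(yg)
  locmax <- which(diff(sign(diff(yg))) < 0) + 1L
  if (yg[1] > yg[2]) locmax <- c(1L, locmax)
  if (yg[n] > yg[n - 1]) locmax <- c(locmax, n)
  if (!length(locmax))
    return(data.frame(location = numeric(0), height = numeric(0),
                      prominence = numeric(0), mass = numeric(0)))
  h <- yg[locmax]
  prom <- numeric(length(locmax))
  for (j in seq_along(locmax)) {
    i <- locmax[j]
    # walk to the nearest higher peak on each side; prominence is the drop
    # to the highest saddle on the way
    saddle <- -Inf
    for (dir in c(-1, 1)) {
      k <- i
      low <- yg[i]
      repeat {
        k <- k + dir
        if (k < 1 || k > n) { low <- min(yg[max(1, min(k, n))], low); break }
        if (yg[k] > yg[i]) break
        low <- min(low, yg[k])
      }
      if (k >= 1 && k <= n && yg[k] > yg[i]) saddle <- max(saddle, low)
    }
    prom[j] <- if (is.finite(saddle)) yg[i] - saddle else yg[i]
  }
  keep <- prom >= prominence_frac * max(yg)
  locmax <- locmax[keep]; h <- h[keep]; prom <- prom[keep]
  mass <- numeric(length(locmax))
  if (length(locmax)) {
    # basin boundaries: minima between consecutive kept modes
    cuts <- c(1L, vapply(seq_len(length(locmax) - 1), function(j) {
      seg <- locmax[j]:locmax[j + 1]
      seg[which.min(yg[seg])]
    }, integer(1)), n)
    for (j in seq_along(locmax)) {
      seg <- cuts[j]:cuts[j + 1]
      mass[j] <- .trapz(grid[seg], yg[seg])
    }
  }
  data.frame(location = grid[locmax], height = h, prominence = prom,
             mass = mass)
}

#' Compare a hybrid release density with stochastic release samples
#'
#' Computes the Kolmogorov-Smirnov distance between the hybrid release-time
#' CDF and the empirical CDF of the stochastic release times (both
#' conditioned on release within the common window), along with mode
#' structure on both sides.
#'
#' @param density a [monte_carlo_release()] result, a [release_pdf()] data
#'   frame, or a list with `t` and `density`
#' @param samples numeric vector of release times (ms), or an
#'   `ssa_ensemble`
#' @param window comparison window (ms); defaults to the density grid range
#' @param bw,prominence_frac mode-detection settings (see [detect_modes()])
#' @param alpha significance level for the KS critical value (default 1\%)
#' @return list with `ks` (distance), `ks_critical`, `n_samples`,
#'   `modes_hybrid`, `modes_samples` and a `low_power` flag (fewer than 100
#'   samples)
#' @export
compare_distributions <- function(density, samples, window = NULL,
                                  bw = 2, prominence_frac = 0.05,
                                  alpha = 0.01) {
  cum <- NULL
  if (inherits(density, "hybrid_solution"))
    density <- list(t = density$t, density = release_pdf(density)$aggregate,
                    cum_releases = rowSums(density$F))
  if (inherits(density, "release_density") || is.list(density))
    cum <- density$cum_releases
  if (is.data.frame(density))
    density <- list(t = density$t, density = density$aggregate)
  if (inherits(samples, "ssa_ensemble")) samples <- samples$release_time
  if (is.null(window)) window <- range(density$t)
  samples <- samples[samples >= window[1] & samples <= window[2]]
  n <- length(samples)
  if (n == 0) stop("no release samples in the comparison window")
  keep <- density$t >= window[1] & density$t <= window[2]
  tt <- density$t[keep]; dd <- density$density[keep]
  if (!is.null(cum)) {
    # use the exact cumulative (absorbing-state occupancy) when available:
    # it avoids quadrature error on the steep early rise
    Fh <- cum[keep] - cum[keep][1]
  } else {
    Fh <- c(0, cumsum((dd[-1] + dd[-length(dd)]) / 2 * diff(tt)))
  }
  Fh <- Fh / Fh[length(Fh)] # conditional on release inside the window
  Ffun <- stats::approxfun(tt, Fh, rule = 2)
  s <- sort(samples)
  Fs <- Ffun(s)
  ks <- max(pmax(abs(seq_len(n) / n - Fs), abs((seq_len(n) - 1) / n - Fs)))
  kcrit <- sqrt(-log(alpha / 2) / 2) / sqrt(n) # asymptotic one-sample value
  list(ks = ks, ks_critical = kcrit, n_samples = n,
       modes_hybrid = detect_modes(tt, dd, bw = bw, window = window,
                                   prominence_frac = prominence_frac),
       modes_samples = detect_modes_samples(samples, bw = bw,
                                            window = window,
                                            prominence_frac = prominence_frac),
       low_power = n < 100)
}

#' Mode detection for empirical release samples
#'
#' Gaussian kernel density estimate of the samples (bandwidth `bw`) followed
#' by [detect_modes()].
#'
#' @param samples release times (ms)
#' @param bw kernel bandwidth (ms)
#' @param window analysis window (ms)
#' @param prominence_frac prominence threshold
#' @return as [detect_modes()]
#' @export
detect_modes_samples <- function(samples, bw = 2, window = c(0, 500),
                                 prominence_frac = 0.05) {
  d <- density(samples, bw = bw, from = window[1], to = window[2], n = 1024)
  detect_modes(d$x, d$y, bw = 0, window = window, dt = diff(d$x[1:2]),
               prominence_frac = prominence_frac)
}

#' Experiment configuration
#'
#' Bundles everything needed to reproduce the buffer-sweep release
#' experiments end to end (influx simulation, transport rates, allocation
#' table, hybrid Monte-Carlo average and stochastic validation).
#'
#' @param buffer_sweep buffer-site counts to sweep (default 0, 100, 400)
#' @param n_realizations hybrid channel placements per sweep point
#' @param n_ssa stochastic runs per sweep point
#' @param seed master seed; stage seeds are derived from it
#' @param t_end horizon (ms)
#' @param use_printed_rates use the tabulated one-digit rates (default
#'   `TRUE`, the values used by the reference release simulations)
#' @param k_minus_1 buffer unbinding rate (1/s)
#' @param free_target_sum see [bulk_rhs()]
#' @param runs_per_block,n_rho,n_theta allocation-table settings
#'   (see [estimate_q()])
#' @param threshold activation threshold T
#' @param n_channels channels per placement
#' @param histogram_breaks bin edges for the stochastic histograms
#' @return an object of class `experiment_config`
#' @export
experiment_config <- function(buffer_sweep = c(0, 100, 400),
                              n_realizations = 150, n_ssa = 10000,
                              seed = 1, t_end = 1000,
                              use_printed_rates = TRUE, k_minus_1 = 0.5,
                              free_target_sum = TRUE,
                              runs_per_block = 200, n_rho = 10, n_theta = 5,
                              threshold = 5, n_channels = 3,
                              histogram_breaks = seq(0, 300, 2)) {
  if (any(buffer_sweep < 0)) stop("buffer counts must be non-negative")
  structure(as.list(environment()), class = "experiment_config")
}

#' Read an experiment configuration from YAML
#' @param path YAML file whose keys match the [experiment_config()]
#'   arguments
#' @return an `experiment_config`
#' @export
read_experiment_config <- function(path) {
  do.call(experiment_config, yaml::read_yaml(path))
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config[order(names(config))],
                              auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

#' Run the buffer-sweep release experiment end to end
#'
#' Pipeline: simulate the action-potential calcium influx, build the
#' transport rates and the Brownian allocation table, then for every buffer
#' count in the sweep compute the placement-averaged hybrid release density
#' and a matched Gillespie ensemble (cycling the same placements), and
#' compare the two.  All stages derive their seeds from the master seed, so
#' the result (including the summary) is fully reproducible.
#'
#' @param config an [experiment_config()]
#' @param outdir optional output directory; when given, densities and
#'   histograms are written as CSV and the summary as JSON
#' @param quiet suppress progress messages
#' @return a list of class `experiment_result` with the influx trace, rates,
#'   splitting table, per-buffer results (`hybrid`, `ssa`, `histogram`,
#'   `comparison`) and a machine-readable `summary`
#' @export
run_experiment <- function(config = experiment_config(), outdir = NULL,
                           quiet = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  hash <- .config_hash(config)
  seed <- config$seed
  geom <- synapse_geometry()
  say("simulating calcium influx")
  trace <- simulate_hh()
  influx <- influx_profile(trace)
  say("building allocation table (seed %d)", seed + 1)
  table <- estimate_q(geom, runs_per_block = config$runs_per_block,
                      n_rho = config$n_rho, n_theta = config$n_theta,
                      seed = seed + 1)
  results <- list()
  summary <- list(config_hash = hash, seed = seed,
                  peak_current_nA = peak_current(trace),
                  transient_width_ms = transient_width(trace),
                  ions_per_channel = influx$total_ions,
                  sweep = list())
  for (S in config$buffer_sweep) {
    params <- transport_params(S_tot = S, k_minus_1 = config$k_minus_1,
                               threshold = config$threshold,
                               n_channels = config$n_channels)
    rates <- rate_set(geom, params,
                      use_printed_rates = config$use_printed_rates)
    say("buffer sites: %d -- hybrid (%d placements)", S,
        config$n_realizations)
    hyb <- monte_carlo_release(geom, params, rates, influx, table,
                               n_realizations = config$n_realizations,
                               seed = seed + 2, t_end = config$t_end,
                               free_target_sum = config$free_target_sum)
    # round the run count up to a multiple of the placement count so the
    # stochastic ensemble weights every placement equally
    n_ssa <- ceiling(config$n_ssa / config$n_realizations) *
      config$n_realizations
    say("buffer sites: %d -- Gillespie (%d runs)", S, n_ssa)
    ssa <- ssa_release(geom, params, rates, influx, table,
                       placements = hyb$placements, n_runs = n_ssa,
                       t_max = config$t_end, seed = seed + 3)
    hist <- release_histogram(ssa, breaks = config$histogram_breaks)
    cmp <- compare_distributions(hyb, ssa, window = c(0, config$t_end))
    key <- paste0("buffers_", S)
    results[[key]] <- list(S_tot = S, rates = rates, hybrid = hyb,
                           ssa = ssa, histogram = hist, comparison = cmp)
    summary$sweep[[key]] <- list(
      S_tot = S,
      hybrid_mean_releases = hyb$mean_releases,
      ssa_mean_releases = length(ssa$release_time) / ssa$n_runs,
      ks = cmp$ks, ks_critical = cmp$ks_critical,
      n_modes = nrow(cmp$modes_hybrid),
      mode_locations_ms = cmp$modes_hybrid$location,
      mode_masses = cmp$modes_hybrid$mass)
  }
  out <- structure(list(config = config, trace = trace, influx = influx,
                        table = table, results = results,
                        summary = summary),
                   class = "experiment_result")
  if (!is.null(outdir)) write_experiment(out, outdir)
  out
}

#' Write experiment outputs to a directory
#'
#' @param result an `experiment_result`
#' @param outdir output directory (created if needed)
#' @return the directory, invisibly
#' @export
write_experiment <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_current_trace(result$trace, file.path(outdir, "current_trace.csv"))
  write_splitting_table(result$table, file.path(outdir, "qtable.csv"))
  for (key in names(result$results)) {
    r <- result$results[[key]]
    write.csv(data.frame(t = r$hybrid$t, density = r$hybrid$density,
                         intensity = r$hybrid$intensity),
              file.path(outdir, paste0("hybrid_density_", key, ".csv")),
              row.names = FALSE)
    write.csv(r$histogram,
              file.path(outdir, paste0("ssa_histogram_", key, ".csv")),
              row.names = FALSE)
  }
  jsonlite::write_json(result$summary,
                       file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("Buffer-sweep experiment (hash %s)\n",
              x$summary$config_hash))
  for (s in x$summary$sweep)
    cat(sprintf(
      "  S_tot=%4d: %d mode(s) at [%s] ms, KS=%.4f (crit %.4f)\n",
      s$S_tot, s$n_modes,
      paste(sprintf("%.1f", s$mode_locations_ms), collapse = ", "),
      s$ks, s$ks_critical))
  invisible(x)
}
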