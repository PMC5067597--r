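#' Splitting probability between ribbon targets and bulk
#'
#' Probability that an ion entering at membrane position `x` reaches a
#' ribbon target before being lost to the undifferentiated bulk.  The
#' implemented closed form is an interpolation formula in the distance
#' `rho(x)` to the nearest vesicle centre,
#' \deqn{p_s(\rho) = \frac{1}{1 + \rho^2 / (A\,\epsilon^{3/2}\sqrt{r})},}
#' with shape constant `A = 9.8`; it matches Brownian-dynamics estimates of
#' the splitting in the lattice-cell geometry to within Monte-Carlo error
#' for `rho` between about `3 epsilon` and the cell diagonal (see the
#' package vignette for the calibration and its near-field limitation).
#'
#' @param x membrane position `c(x, y)` or a two-column matrix; must lie in
#'   the tiled active zone.  Alternatively supply `rho` directly.
#' @param geom a [synapse_geometry()]
#' @param rho distance to the nearest target centre (um), bypassing `x`
#' @param A shape constant of the interpolation formula
#' @return splitting probability in (0, 1]
#' @export
splitting_probability <- function(x = NULL, geom, rho = NULL, A = 9.8) {
  stopifnot(inherits(geom, "synapse_geometry"))
  if (is.null(rho)) {
    if (is.null(x)) stop("supply either x or rho")
    if (!all(in_tiled_region(x, geom)))
      stop("position outside the tiled active zone")
    rho <- .nearest_target(x, geom)$rho
  }
  if (any(rho < 0)) stop("rho must be non-negative")
  eps <- geom$ribbon_height
  r <- geom$vesicle_radius
  1 / (1 + rho^2 / (A * eps^1.5 * sqrt(r)))
}

#' Estimate target-allocation probabilities by Brownian dynamics
#'
#' Launches Brownian trajectories from a polar grid of blocks covering the
#' fundamental sub-triangle of a lattice square (angles 0..pi/4 from a
#' reference vesicle; the 8-fold dihedral symmetry of the square extends the
#' table to all of it).  Trajectories reflect on the membrane, the vesicle
#' spheres and the lateral walls, and are absorbed on any ribbon or on the
#' plane `z = 2r` (entry into the bulk).  Conditional on ribbon absorption
#' the hit target's rank among the four nearest targets of the launch point
#' is tallied; hits beyond the 4th-nearest target are truncated and the
#' remainder renormalized.
#'
#' @param geom a [synapse_geometry()]
#' @param runs_per_block Brownian runs per block (default 200)
#' @param n_rho,n_theta radial and angular block counts
#' @param seed integer seed for the trajectory generator
#' @param max_steps per-trajectory step budget; exceeding it censors the
#'   trajectory, and more than 1\% censored aborts
#' @return a data frame of class `splitting_table` with one row per block:
#'   polar coordinates (`rho`, `theta`), normalized radius `u`, allocation
#'   probabilities `q1`..`q4` with standard errors, the Brownian splitting
#'   estimate `ps_hat`, and run/hit counts
#' @export
estimate_q <- function(geom, runs_per_block = 200, n_rho = 10, n_theta = 5,
                       seed = 1, max_steps = 2e6) {
  stopifnot(inherits(geom, "synapse_geometry"))
  if (runs_per_block < 1) stop("runs_per_block must be at least 1")
  H <- geom$half_spacing
  ref <- which.min(colSums((t(geom$centers) -
                              colMeans(geom$centers))^2))
  cref <- geom$centers[ref, ]
  th <- (seq_len(n_theta) - 0.5) / n_theta * (pi / 4)
  u <- (seq_len(n_rho) - 0.5) / n_rho
  grid <- expand.grid(u = u, theta = th)
  grid$rho <- grid$u * H / cos(grid$theta)
  xs <- cref[1] + grid$rho * cos(grid$theta)
  ys <- cref[2] + grid$rho * sin(grid$theta)
  counts <- brw_outcome_counts(xs, ys, as.integer(runs_per_block),
                               geom$centers, geom$vesicle_radius,
                               geom$ribbon_height, geom$z_top,
                               as.numeric(geom$bounds),
                               smin = geom$ribbon_height / 5, smax = 0.01,
                               max_steps = as.integer(max_steps),
                               seed = as.integer(seed))
  nT <- geom$n_targets
  censored <- sum(counts[, nT + 2])
  if (censored > 0.01 * length(xs) * runs_per_block)
    stop(sprintf("%d of %d trajectories censored (step budget exhausted)",
                 censored, length(xs) * runs_per_block))
  qmat <- matrix(NA_real_, nrow(grid), 4)
  semat <- matrix(NA_real_, nrow(grid), 4)
  nhit <- integer(nrow(grid))
  for (b in seq_len(nrow(grid))) {
    ranks <- order(.nearest_target(c(xs[b], ys[b]), geom)$d2[1, ])
    hits <- counts[b, 1 + ranks[1:4]] # rank-ordered ribbon hits
    tot4 <- sum(hits)
    nhit[b] <- sum(counts[b, 2:(nT + 1)])
    if (tot4 > 0) {
      qmat[b, ] <- hits / tot4
      semat[b, ] <- sqrt(qmat[b, ] * (1 - qmat[b, ]) / tot4)
    }
  }
  # blocks with no ribbon hit inherit the allocation of the previous radial
  # block at the same angle (their direct flux is negligible anyway)
  for (j in seq_len(n_theta)) for (k in seq_len(n_rho)) {
    b <- (j - 1) * n_rho + k
    if (is.na(qmat[b, 1])) {
      if (k == 1) {
        qmat[b, ] <- c(1, 0, 0, 0); semat[b, ] <- 0
      } else {
        qmat[b, ] <- qmat[b - 1, ]; semat[b, ] <- semat[b - 1, ]
      }
    }
  }
  tab <- data.frame(rho = grid$rho, theta = grid$theta, u = grid$u,
                    q1 = qmat[, 1], q2 = qmat[, 2], q3 = qmat[, 3],
                    q4 = qmat[, 4],
                    se1 = semat[, 1], se2 = semat[, 2], se3 = semat[, 3],
                    se4 = semat[, 4],
                    ps_hat = nhit / runs_per_block,
                    n_runs = runs_per_block, n_hits = nhit)
  class(tab) <- c("splitting_table", "data.frame")
  attr(tab, "seed") <- seed
  attr(tab, "grid") <- c(n_rho = n_rho, n_theta = n_theta)
  attr(tab, "reference_target") <- ref
  attr(tab, "geometry") <- list(H = H, r = geom$vesicle_radius,
                                eps = geom$ribbon_height,
                                n_targets = geom$n_targets,
                                lattice_dims = geom$lattice_dims)
  tab
}

# bilinear interpolation of q1..q4 over the (u, theta) block grid, with the
# query angle folded into [0, pi/4] by lattice symmetry
.q_interp <- function(table, u, theta) {
  g <- attr(table, "grid")
  n_rho <- g["n_rho"]; n_theta <- g["n_theta"]
  ug <- (seq_len(n_rho) - 0.5) / n_rho
  tg <- (seq_len(n_theta) - 0.5) / n_theta * (pi / 4)
  bi <- function(grid_vals, xg, x) {
    # index and weight of the lower grid point, clamped to the grid
    if (x <= xg[1]) return(list(i = 1L, w = 1))
    n <- length(xg)
    if (x >= xg[n]) return(list(i = n - if (n > 1) 1L else 0L,
                                w = if (n > 1) 0 else 1))
    i <- findInterval(x, xg)
    list(i = i, w = (xg[i + 1] - x) / (xg[i + 1] - xg[i]))
  }
  au <- bi(NULL, ug, u); at <- bi(NULL, tg, theta)
  q <- numeric(4)
  for (k in 1:4) {
    col <- matrix(table[[paste0("q", k)]], n_rho, n_theta)
    ui2 <- min(au$i + 1L, n_rho); ti2 <- min(at$i + 1L, n_theta)
    q[k] <- at$w * (au$w * col[au$i, at$i] + (1 - au$w) * col[ui2, at$i]) +
      (1 - at$w) * (au$w * col[au$i, ti2] + (1 - au$w) * col[ui2, ti2])
  }
  q / sum(q)
}

#' Allocation of an entering ion among the four nearest targets
#'
#' Looks up, for a membrane position, the conditional probabilities that an
#' ion reaching a ribbon reaches each of the four nearest targets, by
#' bilinear interpolation of an [estimate_q()] table.
#'
#' @param table a `splitting_table`
#' @param x membrane position `c(x, y)`
#' @param geom the [synapse_geometry()] the table was built for
#' @return list with `q` (length-4 probabilities summing to 1) and
#'   `targets` (the matching target indices, nearest first)
#' @export
q_lookup <- function(table, x, geom) {
  stopifnot(inherits(table, "splitting_table"))
  nt <- .nearest_target(x, geom)
  cc <- geom$centers[nt$index, ]
  dx <- abs(x[1] - cc[1]); dy <- abs(x[2] - cc[2])
  theta <- atan2(dy, dx)
  if (theta > pi / 4) theta <- pi / 2 - theta
  u <- nt$rho * cos(theta) / geom$half_spacing
  ranks <- order(nt$d2[1, ])[1:4]
  list(q = .q_interp(table, min(u, 1), theta), targets = ranks)
}

#' Direct-flux weights of a channel placement
#'
#' For each channel, combines the splitting probability and the allocation
#' table into per-target weights: channel `x` sends a fraction
#' `p_s(x) q(x, i)` of its influx straight to target `i` and `1 - p_s(x)`
#' to the bulk.
#'
#' @param channels a [place_channels()] matrix
#' @param geom a [synapse_geometry()]
#' @param table an [estimate_q()] table
#' @param A shape constant passed to [splitting_probability()]
#' @return list with `w` (per-target summed weights), `bulk_share`
#'   (summed bulk fractions), `ps` (per-channel splitting probabilities) and
#'   `alloc` (matrix `n_channels x (n_targets + 1)`, last column = bulk)
#' @export
channel_weights <- function(channels, geom, table, A = 9.8) {
  nT <- geom$n_targets
  nc <- nrow(channels)
  alloc <- matrix(0, nc, nT + 1)
  ps <- numeric(nc)
  for (i in seq_len(nc)) {
    xi <- as.numeric(channels[i, ])
    ps[i] <- splitting_probability(xi, geom, A = A)
    ql <- q_lookup(table, xi, geom)
    alloc[i, ql$targets] <- ps[i] * ql$q
    alloc[i, nT + 1] <- 1 - ps[i]
  }
  list(w = colSums(alloc[, seq_len(nT), drop = FALSE]),
       bulk_share = sum(alloc[, nT + 1]), ps = ps, alloc = alloc)
}

#' Direct ion flux arriving at one target
#'
#' Sum over channels of `J(t) p_s(x) q(x, i)`: the rate (ions/ms) at which
#' ions entering through the channels reach target `i` without passing
#' through the bulk.  Zero outside the influx transient.
#'
#' @param i target index
#' @param t time or vector of times (ms)
#' @param channels a [place_channels()] matrix
#' @param influx an [influx_profile()] (or a `current_trace`, converted with
#'   valence 2)
#' @param table an [estimate_q()] table
#' @param geom a [synapse_geometry()]
#' @return flux in ions/ms, vectorized over `t`
#' @export
target_flux <- function(i, t, channels, influx, table, geom) {
  if (inherits(influx, "current_trace")) influx <- influx_profile(influx)
  if (i < 1 || i > geom$n_targets) stop("target index out of range")
  cw <- channel_weights(channels, geom, table)
  cw$w[i] * influx$fun(t)
}

#' Write a splitting table to CSV (with a JSON sidecar header)
#'
#' @param table a `splitting_table`
#' @param path CSV output path; a `.json` sidecar with seed and geometry is
#'   written next to it
#' @return the path, invisibly
#' @export
write_splitting_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  meta <- list(seed = attr(table, "seed"), grid = as.list(attr(table, "grid")),
               geometry = attr(table, "geometry"),
               reference_target = attr(table, "reference_target"))
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
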