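#' Presynaptic terminal geometry
#'
#' Describes the terminal head (a ball), the vesicle lattice and the neck.
#' Vesicles (the release targets) are spheres of radius `vesicle_radius`
#' resting on the active-zone membrane on a square lattice of spacing
#' `2 * half_spacing`; the ribbon sensor of each vesicle is the band of its
#' surface within `ribbon_height` of the membrane.  The head volume defaults
#' to that of a ball of radius `ball_radius` (0.905 um^3 for the default
#' 0.6 um), the value that underlies the transport rates reported by
#' [rate_set()].
#'
#' @param ball_radius radius of the terminal head (um)
#' @param volume head volume (um^3); defaults to the ball volume
#' @param vesicle_radius vesicle radius r (um)
#' @param ribbon_height ribbon height epsilon (um); must satisfy
#'   `ribbon_height < vesicle_radius < half_spacing`
#' @param half_spacing half the lattice spacing H (um)
#' @param n_targets number of vesicles
#' @param lattice_dims columns x rows of the vesicle lattice; the product
#'   must equal `n_targets`
#' @param neck_radius,neck_length neck dimensions (um)
#' @return an object of class `synapse_geometry` with the vesicle centre
#'   coordinates (`centers`), the lateral bounds of the tiled active zone
#'   (`bounds`) and the absorbing bulk-entry height (`z_top = 2 r`)
#' @export
synapse_geometry <- function(ball_radius = 0.6, volume = NULL,
                             vesicle_radius = 0.02, ribbon_height = 0.001,
                             half_spacing = 0.07, n_targets = 8,
                             lattice_dims = c(4, 2),
                             neck_radius = 0.1, neck_length = 0.15) {
  if (is.null(volume)) volume <- 4 / 3 * pi * ball_radius^3
  if (volume <= 0) stop("volume must be positive")
  if (!(ribbon_height < vesicle_radius && vesicle_radius < half_spacing))
    stop("geometry must satisfy ribbon_height < vesicle_radius < half_spacing")
  if (n_targets < 1) stop("need at least one target")
  if (prod(lattice_dims) != n_targets)
    stop("lattice_dims must multiply to n_targets")
  H <- half_spacing
  cx <- rep((seq_len(lattice_dims[1]) - 1) * 2 * H, lattice_dims[2])
  cy <- rep((seq_len(lattice_dims[2]) - 1) * 2 * H, each = lattice_dims[1])
  centers <- cbind(x = cx, y = cy)
  structure(list(ball_radius = ball_radius, volume = volume,
                 vesicle_radius = vesicle_radius,
                 ribbon_height = ribbon_height,
                 half_spacing = H, n_targets = n_targets,
                 lattice_dims = lattice_dims,
                 neck_radius = neck_radius, neck_length = neck_length,
                 centers = centers,
                 bounds = c(xlo = -H, xhi = max(cx) + H,
                            ylo = -H, yhi = max(cy) + H),
                 z_top = 2 * vesicle_radius),
            class = "synapse_geometry")
}

#' Transport and activation parameters
#'
#' @param D calcium diffusion coefficient (um^2/s)
#' @param D_B buffer diffusion coefficient (um^2/s)
#' @param r_B radius of a buffer binding site (um)
#' @param S_tot number of buffer sites in the bulk
#' @param k_minus_1 buffer unbinding rate (1/s)
#' @param threshold number of ions that must accumulate on one ribbon to
#'   trigger release (T)
#' @param n_channels number of calcium channels
#' @return an object of class `transport_params`
#' @export
transport_params <- function(D = 20, D_B = 20, r_B = 0.001, S_tot = 0,
                             k_minus_1 = 0.5, threshold = 5, n_channels = 3) {
  if (D <= 0 || D_B <= 0) stop("diffusion coefficients must be positive")
  if (threshold < 1) stop("threshold must be at least 1")
  if (S_tot < 0) stop("S_tot must be non-negative")
  if (n_channels < 1) stop("need at least one channel")
  structure(list(D = D, D_B = D_B, r_B = r_B, S_tot = S_tot,
                 k_minus_1 = k_minus_1, threshold = threshold,
                 n_channels = n_channels),
            class = "transport_params")
}

# run code with a locally seeded RNG, restoring the caller's state
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

#' Place calcium channels uniformly on the active zone
#'
#' Channels are drawn uniformly over the union of the lattice squares (side
#' `2 H`, one per vesicle), which tile the rectangular active zone.
#'
#' @param geom a [synapse_geometry()]
#' @param n_channels number of channels
#' @param seed optional integer seed (placement is reproducible under it and
#'   the caller's RNG state is untouched)
#' @return matrix with columns `x`, `y` and attribute `seed`, of class
#'   `channel_placement`
#' @export
place_channels <- function(geom, n_channels = 3, seed = NULL) {
  stopifnot(inherits(geom, "synapse_geometry"))
  if (n_channels < 1) stop("need at least one channel")
  b <- geom$bounds
  xy <- .with_seed(seed, cbind(x = runif(n_channels, b["xlo"], b["xhi"]),
                               y = runif(n_channels, b["ylo"], b["yhi"])))
  rownames(xy) <- NULL
  structure(xy, seed = seed, class = c("channel_placement", class(xy)))
}

# distance to, and index of, the nearest vesicle centre for rows of x
.nearest_target <- function(x, geom) {
  x <- matrix(x, ncol = 2)
  cc <- geom$centers
  d2 <- outer(x[, 1], cc[, 1], "-")^2 + outer(x[, 2], cc[, 2], "-")^2
  idx <- max.col(-d2)
  list(rho = sqrt(d2[cbind(seq_len(nrow(x)), idx)]), index = idx,
       d2 = d2)
}

#' Is a position inside the tiled active zone?
#' @param x numeric vector `c(x, y)` or a two-column matrix
#' @param geom a [synapse_geometry()]
#' @return logical vector
#' @export
in_tiled_region <- function(x, geom) {
  x <- matrix(x, ncol = 2)
  b <- geom$bounds
  x[, 1] >= b["xlo"] & x[, 1] <= b["xhi"] &
    x[, 2] >= b["ylo"] & x[, 2] <= b["yhi"]
}

#' @export
print.synapse_geometry <- function(x, ...) {
  cat(sprintf(paste0(
    "Presynaptic geometry: %d vesicles (%dx%d lattice, spacing %.3g um)\n",
    "  head volume %.4g um^3, vesicle radius %.3g um, ribbon %.3g um\n",
    "  neck: radius %.3g um, length %.3g um\n"),
    x$n_targets, x$lattice_dims[1], x$lattice_dims[2], 2 * x$half_spacing,
    x$volume, x$vesicle_radius, x$ribbon_height, x$neck_radius,
    x$neck_length))
  invisible(x)
}
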