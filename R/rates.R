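#' Mean time for a free ion to bind one buffer site
#'
#' First-arrival time of a Brownian particle to a small mobile spherical
#' site of radius `r_B` in a domain of volume `|Omega|`, when both the
#' particle (D) and the site (D_B) diffuse:
#' \deqn{\tau_B = |\Omega| / (4\pi (D + D_B) r_B).}
#' With the default geometry and transport parameters this evaluates to
#' 1.80 s.
#'
#' @param geom a [synapse_geometry()]
#' @param params a [transport_params()]
#' @return mean binding time in seconds
#' @export
buffer_binding_time <- function(geom, params = transport_params()) {
  if (params$r_B <= 0) stop("buffer site radius must be positive")
  geom$volume / (4 * pi * (params$D + params$D_B) * params$r_B)
}

#' Mean time for a bulk ion to reach one ribbon target
#'
#' Narrow-escape arrival time to the thin ribbon (height epsilon) under one
#' vesicle, \deqn{\tau_T = |\Omega| / (4\pi D \epsilon),} i.e. the ribbon
#' has the capture capacitance of a sphere of radius epsilon.  Default
#' geometry: 3.60 s.
#'
#' @param geom a [synapse_geometry()]
#' @param D ion diffusion coefficient (um^2/s)
#' @return mean arrival time in seconds
#' @export
target_arrival_time <- function(geom, D = 20) {
  if (geom$ribbon_height <= 0) stop("ribbon height must be positive")
  geom$volume / (4 * pi * D * geom$ribbon_height)
}

#' Mean time to escape through the terminal neck
#'
#' Escape from the head through a cylindrical neck of radius `r_neck` and
#' length `l_neck`, dominated by the flux through the neck cross-section:
#' \deqn{\tau_{es} = |\Omega|\, l_{neck} / (r_{neck}^2 D) + l_{neck}^2/(2D).}
#' Default geometry: 0.68 s.
#'
#' @param geom a [synapse_geometry()]
#' @param D ion diffusion coefficient (um^2/s)
#' @return mean escape time in seconds
#' @export
escape_time <- function(geom, D = 20) {
  if (geom$neck_radius <= 0 || geom$neck_length <= 0)
    stop("neck dimensions must be positive")
  geom$volume * geom$neck_length / (geom$neck_radius^2 * D) +
    geom$neck_length^2 / (2 * D)
}

#' Poissonian transport rates of the bulk model
#'
#' Builds the rate set used by both the hybrid solver and the Gillespie
#' simulator.  By default the rates are the exact reciprocals of the
#' formula-derived mean times ([buffer_binding_time()],
#' [target_arrival_time()], [escape_time()]); with
#' `use_printed_rates = TRUE` the conventional one-digit values
#' (k_0 = 0.6, k_T = 0.3, k_es = 1.5 1/s) used in the reference release
#' simulations are substituted, with the mean times kept as their exact
#' reciprocals so that `rate * mean_time = 1` always holds.
#'
#' @param geom a [synapse_geometry()]
#' @param params a [transport_params()]
#' @param use_printed_rates use the rounded tabulated rates instead of the
#'   formula reciprocals
#' @return an object of class `rate_set` with rates `k_0`, `k_T`, `k_es`,
#'   `k_minus_1` (1/s) and mean times `tau_B`, `tau_T`, `tau_es` (s)
#' @export
rate_set <- function(geom, params = transport_params(),
                     use_printed_rates = FALSE) {
  tb <- buffer_binding_time(geom, params)
  tt <- target_arrival_time(geom, params$D)
  te <- escape_time(geom, params$D)
  if (use_printed_rates) {
    k0 <- 0.6; kT <- 0.3; kes <- 1.5
    tb <- 1 / k0; tt <- 1 / kT; te <- 1 / kes
  } else {
    k0 <- 1 / tb; kT <- 1 / tt; kes <- 1 / te
  }
  structure(list(k_0 = k0, k_T = kT, k_es = kes,
                 k_minus_1 = params$k_minus_1,
                 tau_B = tb, tau_T = tt, tau_es = te,
                 use_printed_rates = use_printed_rates),
            class = "rate_set")
}

#' @export
print.rate_set <- function(x, ...) {
  cat(sprintf(paste0(
    "Transport rates (%s):\n",
    "  buffer binding  k_0  = %.4g /s  (tau_B  = %.4g s, per site)\n",
    "  target arrival  k_T  = %.4g /s  (tau_T  = %.4g s, per ribbon)\n",
    "  neck escape     k_es = %.4g /s  (tau_es = %.4g s)\n",
    "  buffer release  k_-1 = %.4g /s\n"),
    if (x$use_printed_rates) "tabulated values" else "formula reciprocals",
    x$k_0, x$tau_B, x$k_T, x$tau_T, x$k_es, x$tau_es, x$k_minus_1))
  invisible(x)
}
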