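# Shared fixtures, built once per test run and cached.  Everything is
# generated in code; seeds are fixed so the suite is deterministic.

.fixtures <- new.env(parent = emptyenv())

fx <- function(name) {
  if (!exists(name, envir = .fixtures)) {
    val <- switch(name,
      trace = simulate_hh(),
      influx = influx_profile(fx("trace")),
      geom = synapse_geometry(),
      qtable = estimate_q(fx("geom"), runs_per_block = 200, seed = 11),
      stop("unknown fixture: ", name))
    assign(name, val, envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# a zero-current trace (no stimulus ever opens the calcium channel)
zero_trace <- function() {
  tr <- fx("trace")
  tr$I_Ca_nA[] <- 0
  tr$Q_fC[] <- 0
  tr
}

# rate set with selected rates overridden (the object is a plain list)
rates_with <- function(..., base = NULL) {
  r <- if (is.null(base)) rate_set(fx("geom"), transport_params(),
                                   use_printed_rates = TRUE) else base
  over <- list(...)
  for (nm in names(over)) r[[nm]] <- over[[nm]]
  r
}

# trapezoidal integral
trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))
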