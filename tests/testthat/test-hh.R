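test_that("the membrane rests at its equilibrium without a stimulus", {
  quiet <- simulate_hh(stimulus = stimulus_protocol(amplitude = 0),
                       t_end = 100, dt_out = 0.1)
  p <- hh_params()
  expect_lt(max(abs(quiet$V_mV - p$V0)), 0.01)
  expect_lt(max(abs(quiet$n - p$n0)), 1e-4)
  expect_lt(max(abs(quiet$h - p$h0)), 1e-6)
  expect_lt(max(abs(quiet$I_Ca_nA)), 1e-6)
})

test_that("the stimulated trace is internally consistent", {
  tr <- fx("trace")
  # cumulative charge equals the trapezoidal integral of |I_Ca|
  aI <- abs(tr$I_Ca_nA)
  Q <- 1e-3 * trapz(tr$t_ms, aI)
  expect_lt(abs(Q - max(tr$Q_fC)) / Q, 1e-6)
  expect_true(all(diff(tr$Q_fC) >= 0))
  # the spike is a single transient: current returns to (near) zero
  expect_lt(abs(tr$I_Ca_nA[nrow(tr)]), 1e-4 * peak_current(tr))
})

test_that("calcium current is linear in its conductance at fixed voltage", {
  tr1 <- fx("trace")
  tr2 <- simulate_hh(hh_params(g_Ca = 2 * 14.5e-9))
  # the conductance feeds back into dV/dt only at the 1e-8 mS/cm2 scale, so
  # the voltage waveform is unchanged and the current doubles pointwise
  big <- abs(tr1$I_Ca_nA) > 1e-3 * peak_current(tr1)
  expect_lt(max(abs(tr2$I_Ca_nA[big] / tr1$I_Ca_nA[big] - 2)), 1e-4)
})

test_that("integration failure is reported with the blow-up time", {
  expect_error(simulate_hh(t_end = 5), "tail")
})

test_that("charge-to-ion conversion follows Faraday counting", {
  expect_identical(ions_from_charge(0), 0)
  expect_equal(ions_from_charge(2.563e-2, valence = 2), 80)
  expect_error(ions_from_charge(-1), "non-negative")
  expect_error(ions_from_charge(1, valence = 0), "valence")
})

test_that("a rectangular test current integrates to the brute-force count", {
  tt <- seq(0, 3, by = 1e-3)
  amp <- 1 # display nA
  I <- ifelse(tt >= 0.5 & tt < 1.5, amp, 0)
  tr <- data.frame(t_ms = tt, V_mV = 0, n = 0, m = 0, h = 0, I_Ca_nA = I,
                   Q_fC = 1e-3 * c(0, cumsum((I[-1] + I[-length(I)]) / 2 *
                                               diff(tt))))
  class(tr) <- c("current_trace", "data.frame")
  inf <- influx_profile(tr, valence = 2)
  # brute-force quadrature oracle: 1 display nA = 1 fA physical, so a 1 ms
  # rectangle carries 1e-18 C, i.e. 1e-18 / (2 * 1.602176634e-19) ions
  oracle <- trapz(tt, I) * 1e-18 / (2 * 1.602176634e-19)
  expect_equal(inf$total_ions, oracle, tolerance = 1e-6)
  expect_equal(oracle, 3.1209, tolerance = 1e-4)
})

test_that("the influx profile integrates to the charge-derived ion count", {
  tr <- fx("trace")
  inf <- fx("influx")
  expect_true(all(inf$J >= 0))
  expect_equal(inf$total_ions,
               max(tr$Q_fC) * 1e-15 / (2 * 1.602176634e-19),
               tolerance = 1e-6)
  # interpolator is clamped to zero outside the simulated window
  expect_identical(inf$fun(c(-5, max(tr$t_ms) + 5)), c(0, 0))
  # and reproduces the grid values
  expect_equal(inf$fun(tr$t_ms[c(100, 200, 400)]),
               inf$J[c(100, 200, 400)], tolerance = 1e-8)
})

test_that("zero current means zero influx", {
  inf <- influx_profile(zero_trace())
  expect_identical(max(inf$J), 0)
  expect_identical(inf$total_ions, 0)
})

test_that("current traces round-trip through CSV", {
  path <- tempfile(fileext = ".csv")
  write_current_trace(fx("trace"), path)
  df <- read.csv(path)
  expect_named(df, c("t_ms", "V_mV", "n", "m", "h", "I_Ca_nA", "Q_fC",
                     "J_ions_per_ms"))
  expect_equal(df$I_Ca_nA, fx("trace")$I_Ca_nA, tolerance = 1e-8)
  unlink(path)
})
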