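test_that("propensities mirror the hybrid rate terms", {
  rts <- rates_with()
  released <- c(FALSE, TRUE, FALSE)
  a <- propensities(N_f = 12, N_b = 30, released, rts, S_tot = 100)
  expect_equal(unname(a["buffer_bind"]), rts$k_0 * 12 * 70)
  expect_equal(unname(a["buffer_release"]), rts$k_minus_1 * 30)
  expect_equal(unname(a["escape"]), rts$k_es * 12)
  expect_equal(unname(a["target_2"]), 0)
  # with N_f independent particles the first-binding rate is linear in N_f
  a2 <- propensities(24, 30, released, rts, S_tot = 100)
  expect_equal(unname(a2[c("target_1", "target_3")]),
               2 * unname(a[c("target_1", "target_3")]))
  expect_error(propensities(-1, 0, released, rts, 100), "negative")
})

test_that("zero influx produces an empty event log", {
  geom <- fx("geom")
  cfg <- ssa_config(geom, transport_params(S_tot = 100), rates_with(),
                    place_channels(geom, 3, seed = 4),
                    influx_profile(zero_trace()), fx("qtable"), seed = 8)
  res <- ssa_run(cfg)
  expect_identical(nrow(res$log), 0L)
  expect_length(res$release_time, 0)
  expect_identical(unname(res$ledger["entered"]), 0L)
})

test_that("identical seed and configuration reproduce the event log", {
  geom <- fx("geom")
  cfg <- ssa_config(geom, transport_params(S_tot = 50), rates_with(),
                    place_channels(geom, 3, seed = 4), fx("influx"),
                    fx("qtable"), t_max = 200, seed = 12)
  r1 <- ssa_run(cfg); r2 <- ssa_run(cfg)
  expect_identical(r1$log, r2$log)
  expect_identical(r1$release_time, r2$release_time)
})

test_that("the integer ledger balances exactly at every event", {
  geom <- fx("geom")
  cfg <- ssa_config(geom, transport_params(S_tot = 100), rates_with(),
                    place_channels(geom, 3, seed = 4), fx("influx"),
                    fx("qtable"), t_max = 500, seed = 13)
  res <- ssa_run(cfg)
  lg <- res$log
  expect_gt(nrow(lg), 100)
  # entered = free + buffered + bound-on-active-targets + escaped, at every
  # event (released ions are re-counted in the free pool)
  expect_true(all(lg$entered ==
                    lg$N_f + lg$N_b + lg$target_bound + lg$escaped))
  expect_identical(unname(res$ledger["entered"]),
                   unname(res$ledger["free"] + res$ledger["buffer_bound"] +
                            res$ledger["target_bound"] +
                            res$ledger["escaped"]))
})

test_that("escape-only dynamics decay at the analytic rate", {
  n_runs <- 1000; N0 <- 100; t_obs <- 300
  kes <- 1.5e-3 # per ms
  res <- presynaptic:::ssa_batch_cpp(
    rep(0:(n_runs - 1), each = N0), rep(0, n_runs * N0),
    rep(0L, n_runs * N0), n_runs, 0, 0, kes, 0, 0L, 5L, 1L, t_obs, 99L)
  nf <- res$ledger[, "free"]
  expected <- N0 * exp(-kes * t_obs)
  se <- sqrt(N0 * exp(-kes * t_obs) * (1 - exp(-kes * t_obs)) / n_runs)
  expect_lt(abs(mean(nf) - expected), 3 * se)
})

test_that("single-target release times follow the Erlang law", {
  # a large, nearly constant free pool feeding one target with threshold 5
  n_runs <- 2000; N0 <- 5000; kT <- 2e-4 / N0
  res <- presynaptic:::ssa_batch_cpp(
    rep(0:(n_runs - 1), each = N0), rep(0, n_runs * N0),
    rep(0L, n_runs * N0), n_runs, 0, 0, 0, kT, 0L, 5L, 1L, 1e6, 42L)
  expect_length(res$release_time, n_runs)
  ks <- suppressWarnings(
    ks.test(res$release_time, pgamma, shape = 5, rate = kT * N0))
  expect_gt(ks$p.value, 0.01)
})

test_that("pre-sampled injection times reproduce the influx profile", {
  inf <- fx("influx")
  inj <- do.call(rbind, lapply(1:50, function(s)
    sample_injections(inf, n_channels = 3, seed = 300 + s)))
  # counts: Poisson with mean total_ions per channel
  expect_equal(nrow(inj) / (3 * 50), inf$total_ions, tolerance = 0.05)
  # shape: chi-square against the integrated intensity on 20 bins
  supp <- range(inf$t[inf$J > 1e-9 * max(inf$J)])
  br <- seq(supp[1], supp[2], length.out = 21)
  obs <- hist(inj$t[inj$t >= supp[1] & inj$t <= supp[2]], breaks = br,
              plot = FALSE)$counts
  Jcum <- approx(inf$t, c(0, cumsum((inf$J[-1] + inf$J[-length(inf$J)]) / 2 *
                                      diff(inf$t))), br)$y
  expected <- diff(Jcum) / diff(range(Jcum)) * sum(obs)
  p <- suppressWarnings(chisq.test(obs, p = expected / sum(expected)))$p.value
  expect_gt(p, 0.01)
})

test_that("release histograms normalize as stated", {
  geom <- fx("geom")
  pars <- transport_params(S_tot = 0)
  rts <- rate_set(geom, pars, use_printed_rates = TRUE)
  ssa <- ssa_release(geom, pars, rts, fx("influx"), fx("qtable"),
                     place_channels(geom, 3, seed = 5), n_runs = 200,
                     t_max = 400, seed = 31)
  br <- seq(0, 400, 2)
  h_all <- release_histogram(ssa, breaks = br, events = "all")
  expect_equal(attr(h_all, "mass"), length(ssa$release_time) / ssa$n_runs)
  expect_equal(sum(h_all$density * diff(br)), attr(h_all, "mass"),
               tolerance = 1e-12)
  h_first <- release_histogram(ssa, breaks = br, events = "first")
  expect_equal(attr(h_first, "mass"),
               length(unique(ssa$release_run)) / ssa$n_runs)
  # empty input flags an empty distribution rather than failing
  h0 <- release_histogram(list(release_time = numeric(0),
                               release_run = integer(0), n_runs = 10))
  expect_true(attr(h0, "empty"))
})
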