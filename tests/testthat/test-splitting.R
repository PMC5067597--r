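test_that("splitting probability is monotone and vanishes with the ribbon", {
  geom <- fx("geom")
  r <- geom$vesicle_radius; H <- geom$half_spacing
  rho <- seq(r, H * sqrt(2), length.out = 80)
  ps <- splitting_probability(geom = geom, rho = rho)
  expect_true(all(diff(ps) <= 0))
  expect_true(all(ps > 0 & ps < 1))
  # vanishing ribbon height
  eps_seq <- c(1e-3, 1e-4, 1e-5, 1e-6)
  pseq <- vapply(eps_seq, function(e)
    splitting_probability(geom = synapse_geometry(ribbon_height = e),
                          rho = r), numeric(1))
  expect_true(all(diff(pseq) < 0))
  expect_lt(pseq[length(pseq)], 1e-3)
  # positions outside the tiled region are rejected
  expect_error(splitting_probability(c(10, 10), geom), "outside")
})

test_that("the closed form matches a Brownian splitting estimate at rho = r", {
  geom <- fx("geom")
  ref <- attr(fx("qtable"), "reference_target")
  x0 <- geom$centers[ref, 1] + geom$vesicle_radius
  y0 <- geom$centers[ref, 2]
  out <- presynaptic:::brw_trajectories(
    x0, y0, geom$centers, geom$vesicle_radius, geom$ribbon_height,
    geom$z_top, as.numeric(geom$bounds), 10000L,
    geom$ribbon_height / 5, 0.01, 2000000L, seed = 101L)
  expect_identical(sum(out < 0), 0L) # nothing censored
  ps_hat <- mean(out > 0)
  se <- sqrt(ps_hat * (1 - ps_hat) / length(out))
  ps <- splitting_probability(c(x0, y0), geom)
  expect_lt(abs(ps - ps_hat), 2 * se)
})

test_that("allocation probabilities are normalized and nearest-dominated", {
  qt <- fx("qtable")
  qsum <- qt$q1 + qt$q2 + qt$q3 + qt$q4
  expect_equal(qsum, rep(1, nrow(qt)), tolerance = 1e-12)
  expect_true(all(qt[, c("q1", "q2", "q3", "q4")] >= 0))
  # the nearest target dominates close to the vesicle
  close <- qt$rho < fx("geom")$half_spacing / 2
  expect_true(all(qt$q1[close] == pmax(qt$q1, qt$q2, qt$q3, qt$q4)[close]))
})

test_that("the two second-nearest targets are symmetric on the diagonal", {
  geom <- fx("geom")
  ref <- attr(fx("qtable"), "reference_target")
  rho <- 0.3 * geom$half_spacing * sqrt(2)
  x0 <- geom$centers[ref, 1] + rho / sqrt(2)
  y0 <- geom$centers[ref, 2] + rho / sqrt(2)
  out <- presynaptic:::brw_trajectories(
    x0, y0, geom$centers, geom$vesicle_radius, geom$ribbon_height,
    geom$z_top, as.numeric(geom$bounds), 4000L,
    geom$ribbon_height / 5, 0.01, 2000000L, seed = 103L)
  d2 <- presynaptic:::.nearest_target(c(x0, y0), geom)$d2[1, ]
  ranks <- order(d2)
  n2 <- sum(out == ranks[2]); n3 <- sum(out == ranks[3])
  # the launch point is equidistant from targets of rank 2 and 3
  expect_equal(d2[ranks[2]], d2[ranks[3]], tolerance = 1e-9)
  ntot <- n2 + n3
  se <- sqrt(ntot) / 2
  expect_lt(abs(n2 - n3) / 2, 2 * se + 1)
})

test_that("the Brownian estimator converges like one over root runs", {
  geom <- fx("geom")
  ref <- attr(fx("qtable"), "reference_target")
  x0 <- geom$centers[ref, 1] + 0.5 * geom$half_spacing
  y0 <- geom$centers[ref, 2] + 0.1 * geom$half_spacing
  est <- function(n, seed) {
    out <- presynaptic:::brw_trajectories(
      x0, y0, geom$centers, geom$vesicle_radius, geom$ribbon_height,
      geom$z_top, as.numeric(geom$bounds), as.integer(n),
      geom$ribbon_height / 5, 0.01, 2000000L, as.integer(seed))
    mean(out > 0)
  }
  s1 <- vapply(1:24, function(s) est(150, 1000 + s), numeric(1))
  s2 <- vapply(1:24, function(s) est(600, 2000 + s), numeric(1))
  ratio <- sd(s1) / sd(s2)
  # quadrupling the runs should halve the spread (generous band: 24 reps)
  expect_gt(ratio, 1.2)
  expect_lt(ratio, 3.5)
})

test_that("table lookup interpolates, normalizes and ranks targets", {
  geom <- fx("geom"); qt <- fx("qtable")
  set.seed(5)
  for (i in 1:20) {
    x <- c(runif(1, geom$bounds["xlo"], geom$bounds["xhi"]),
           runif(1, geom$bounds["ylo"], geom$bounds["yhi"]))
    ql <- q_lookup(qt, x, geom)
    expect_equal(sum(ql$q), 1, tolerance = 1e-12)
    expect_true(all(ql$q >= 0))
    d <- sqrt(colSums((t(geom$centers) - x)^2))
    expect_identical(ql$targets, order(d)[1:4])
  }
})

test_that("direct target flux sums channels and conserves the influx", {
  geom <- fx("geom"); qt <- fx("qtable"); inf <- fx("influx")
  ch <- place_channels(geom, 3, seed = 9)
  cw <- channel_weights(ch, geom, qt)
  # per channel, target shares plus the bulk share account for all ions
  expect_equal(rowSums(cw$alloc), rep(1, nrow(ch)), tolerance = 1e-12)
  expect_equal(sum(cw$w) + cw$bulk_share, nrow(ch), tolerance = 1e-12)
  tq <- c(1, 2, 3, 5)
  tot <- Reduce(`+`, lapply(seq_len(geom$n_targets), function(i)
    target_flux(i, tq, ch, inf, qt, geom)))
  expect_equal(tot + cw$bulk_share * inf$fun(tq),
               nrow(ch) * inf$fun(tq), tolerance = 1e-10)
  # zero influx, zero flux
  expect_identical(target_flux(1, tq, ch, influx_profile(zero_trace()),
                               qt, geom), rep(0, 4))
  expect_error(target_flux(99, 1, ch, inf, qt, geom), "out of range")
  # single channel straight above a vesicle edge
  ch1 <- matrix(c(geom$centers[2, 1] + geom$vesicle_radius,
                  geom$centers[2, 2]), 1)
  ps <- splitting_probability(ch1[1, ], geom)
  ql <- q_lookup(qt, ch1[1, ], geom)
  expect_equal(target_flux(ql$targets[1], 2, ch1, inf, qt, geom),
               inf$fun(2) * ps * ql$q[1], tolerance = 1e-10)
})

test_that("splitting tables round-trip to CSV with a JSON header", {
  path <- tempfile(fileext = ".csv")
  write_splitting_table(fx("qtable"), path)
  df <- read.csv(path)
  expect_equal(nrow(df), nrow(fx("qtable")))
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", path))
  expect_equal(meta$seed, 11)
  unlink(c(path, sub("\\.csv$", ".json", path)))
})
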