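# a fast single-placement hybrid solve shared by several tests
hyb_fixture <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      geom <- fx("geom")
      pars <- transport_params(S_tot = 0)
      rts <- rate_set(geom, pars, use_printed_rates = TRUE)
      ch <- place_channels(geom, 3, seed = 5)
      val <<- solve_hybrid(geom, pars, rts, ch, fx("influx"), fx("qtable"),
                           t_end = 1000)
    }
    val
  }
})

test_that("the pure-birth derivative conserves probability", {
  Pr <- matrix(c(0.2, 0.5, 0.1, 0.1, 0.05, 0.05,
                 1, 0, 0, 0, 0, 0), 2, 6, byrow = TRUE)
  lam <- c(0.3, 1.2)
  d <- markov_rhs(Pr, lam)
  expect_equal(rowSums(d), c(0, 0), tolerance = 1e-15)
  expect_equal(markov_rhs(Pr, c(0, 0)), matrix(0, 2, 6))
  expect_error(markov_rhs(Pr, c(-1, 1)), "negative")
})

test_that("constant-rate occupancy matches the Erlang closed form", {
  lam <- 0.8; Tthr <- 5
  rhs <- function(t, y, p) list(as.vector(markov_rhs(matrix(y, 1), lam)))
  tt <- seq(0, 12, by = 0.05)
  out <- deSolve::lsoda(c(1, rep(0, Tthr)), tt, rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  # absorbing state follows the Erlang CDF, the transient states a Poisson
  expect_equal(out[, Tthr + 2], pgamma(tt, Tthr, rate = lam),
               tolerance = 1e-8)
  for (k in 0:(Tthr - 1))
    expect_equal(out[, k + 2], dpois(k, lam * tt), tolerance = 1e-8)
  # independent oracle: matrix exponential of the generator
  Q <- matrix(0, Tthr + 1, Tthr + 1)
  for (k in 1:Tthr) { Q[k, k] <- -lam; Q[k, k + 1] <- lam }
  for (tcheck in c(1, 4, 9)) {
    me <- as.numeric(Matrix::expm(Q * tcheck)[1, ])
    expect_equal(as.numeric(out[which.min(abs(tt - tcheck)), -1]), me,
                 tolerance = 1e-7)
  }
})

test_that("bulk derivatives vanish for an empty quiescent terminal", {
  rts <- rates_with()
  Pr <- cbind(1, matrix(0, 8, 5))
  d <- bulk_rhs(0, 0, Pr, rep(0, 8), 0, rts, S_tot = 100)
  expect_identical(d, c(0, 0))
  expect_error(bulk_rhs(1, 200, Pr, rep(0, 8), 0, rts, S_tot = 100),
               "exceeds")
})

test_that("escape-only bulk dynamics decay exponentially", {
  rts <- rates_with(k_T = 0, k_0 = 0, k_minus_1 = 0)
  Pr <- cbind(1, matrix(0, 8, 5))
  rhs <- function(t, y, p)
    list(bulk_rhs(y[1], y[2], Pr, rep(0, 8), 0, rts, S_tot = 0))
  tt <- seq(0, 2000, by = 5)
  out <- deSolve::lsoda(c(100, 0), tt, rhs, NULL, rtol = 1e-10, atol = 1e-12)
  expect_equal(out[, 2], 100 * exp(-rts$k_es / 1000 * tt), tolerance = 1e-6)
})

test_that("buffering without escape conserves ions and reaches balance", {
  rts <- rates_with(k_T = 0, k_es = 0)
  Pr <- cbind(1, matrix(0, 8, 5))
  S <- 50
  rhs <- function(t, y, p)
    list(bulk_rhs(y[1], y[2], Pr, rep(0, 8), 0, rts, S_tot = S))
  tt <- seq(0, 60000, by = 100)
  out <- deSolve::lsoda(c(200, 0), tt, rhs, NULL, rtol = 1e-10, atol = 1e-12)
  expect_equal(out[, 2] + out[, 3], rep(200, length(tt)), tolerance = 1e-6)
  nf <- unname(out[nrow(out), 2]); nb <- unname(out[nrow(out), 3])
  # detailed balance at the fixed point
  expect_equal(rts$k_0 * nf * (S - nb), rts$k_minus_1 * nb,
               tolerance = 1e-6)
})

test_that("the coupled solution keeps its probabilistic invariants", {
  sol <- hyb_fixture()
  expect_lt(sol$norm_error, 1e-6)
  expect_true(all(sol$Pr > -1e-9 & sol$Pr < 1 + 1e-9))
  # absorbing state is non-decreasing for every target
  expect_true(all(apply(sol$F, 2, function(x) all(diff(x) >= -1e-9))))
  expect_true(all(sol$N_f > -1e-9) && all(sol$N_b > -1e-9))
})

test_that("coupled integration agrees with the cascade reconstruction", {
  sol <- hyb_fixture()
  casc <- cascade_probabilities(sol)
  # the cascade uses trapezoidal cumulative intensities on the output grid,
  # so agreement is limited by that quadrature, not the ODE tolerance
  expect_lt(max(abs(casc - sol$Pr)), 5e-3)
})

test_that("release densities integrate to the release probability", {
  sol <- hyb_fixture()
  pdf_ <- release_pdf(sol)
  for (i in seq_len(8))
    expect_equal(trapz(pdf_$t, pdf_[[paste0("f_", i)]]),
                 sol$release_prob[i], tolerance = 2e-3)
  expect_equal(trapz(pdf_$t, pdf_$aggregate), 1, tolerance = 2e-3)
  expect_true(all(pdf_$aggregate >= 0))
})

test_that("mean release time matches the Erlang mean at constant rate", {
  lam <- 0.05; Tthr <- 5
  tt <- seq(0, 2000, by = 0.25)
  erlang_sol <- function(rate) {
    f <- matrix(dgamma(tt, Tthr, rate = rate), ncol = 1)
    structure(list(t = tt, f = f,
                   F = matrix(pgamma(tt, Tthr, rate = rate), ncol = 1),
                   release_prob = pgamma(max(tt), Tthr, rate = rate)),
              class = "hybrid_solution")
  }
  m1 <- mean_release_time(erlang_sol(lam))
  expect_false(m1$conditional)
  expect_equal(m1$mean_ms, Tthr / lam, tolerance = 1e-3)
  # doubling the rate halves the mean (time rescaling)
  m2 <- mean_release_time(erlang_sol(2 * lam))
  expect_equal(m2$mean_ms / m1$mean_ms, 0.5, tolerance = 1e-3)
  # incomplete release is flagged and reported conditionally
  m3 <- mean_release_time(erlang_sol(lam / 20))
  expect_true(m3$conditional)
})

test_that("a one-realization Monte Carlo equals the single solve", {
  geom <- fx("geom")
  pars <- transport_params(S_tot = 0)
  rts <- rate_set(geom, pars, use_printed_rates = TRUE)
  ch <- place_channels(geom, 3, seed = 5)
  mc <- monte_carlo_release(geom, pars, rts, fx("influx"), fx("qtable"),
                            placements = list(ch), t_end = 1000)
  sol <- hyb_fixture()
  expect_equal(mc$intensity, rowSums(sol$f), tolerance = 1e-10)
  expect_equal(mc$mean_releases, sum(sol$release_prob), tolerance = 1e-10)
  # the averaged density integrates to one (it is normalized by the mean
  # expected release count)
  expect_equal(trapz(mc$t, mc$density), 1, tolerance = 2e-3)
})
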