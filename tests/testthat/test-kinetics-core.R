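# Closed-form relaxations, generator matrices and exact trace simulation.

test_that("cs_relaxations matches the eigenvalue oracle and its limits", {
  m <- mechanism_cs(2, 8, 1, 5)

  r <- cs_relaxations(m, 10)
  expect_equal(sort(c(r$alpha1, r$alpha2), decreasing = TRUE),
               relax_rates_eigen(m, 10), tolerance = 1e-12)

  # L = 0: the square root collapses to |koff - k12 - k21|
  r0 <- cs_relaxations(m, 0)
  expect_equal(sort(c(r0$alpha1, r0$alpha2)),
               sort(c(m$k12 + m$k21, m$koff)))

  # k21 = 0 decouples the exchange: alpha1 = kon L + koff, alpha2 = k12
  md <- mechanism_cs(2, 0, 1, 5)
  rd <- cs_relaxations(md, 10)   # kon*L + koff = 15 > k12
  expect_equal(rd$alpha1, 15)
  expect_equal(rd$alpha2, 2)

  # saturation: alpha2 -> k12 as L -> infinity; alpha1/L -> kon
  Lbig <- 1e6 * m$koff / m$kon
  rb <- cs_relaxations(m, Lbig)
  expect_equal(rb$alpha2, m$k12, tolerance = 1e-4)
  expect_equal(rb$alpha1 / Lbig, m$kon, tolerance = 1e-4)

  # k12 = k21 = 0 reduces to the lock-and-key law plus a zero root
  mz <- mechanism_cs(0, 0, 1, 5)
  rz <- cs_relaxations(mz, 10)
  expect_equal(rz$alpha1, lk_relaxation(mechanism_lk(1, 5), 10))
  expect_equal(rz$alpha2, 0)

  expect_error(cs_relaxations(m, -1), "ligand")
  expect_error(mechanism_cs(-1, 8, 1, 5), ">= 0")
  expect_error(mechanism_cs(2, 8, 0, 5), "binding-competent")
})

test_that("closed forms agree with rate-matrix eigenvalues on random sets", {
  set.seed(42)
  for (i in 1:300) {
    m <- random_cs()
    L <- 10^stats::runif(1, -1, 2)
    r <- cs_relaxations(m, L)
    expect_equal(sort(c(r$alpha1, r$alpha2), decreasing = TRUE),
                 relax_rates_eigen(m, L), tolerance = 1e-9)
    ml <- mechanism_lk(m$kon, m$koff)
    expect_equal(lk_relaxation(ml, L), relax_rates_eigen(ml, L),
                 tolerance = 1e-9)
  }
})

test_that("lk_relaxation is linear in L with intercept koff", {
  m <- mechanism_lk(1.6, 7.8)
  expect_equal(lk_relaxation(m, 20), 39.8)
  expect_equal(lk_relaxation(m, 0), 7.8)
  m0 <- mechanism_lk(1e-12, 7.8)   # kon -> 0: rate independent of L
  expect_equal(lk_relaxation(m0, 1e6), 7.8, tolerance = 1e-5)
  expect_error(lk_relaxation(m, -3), "ligand")
})

test_that("rate_matrix is a proper generator", {
  set.seed(7)
  for (i in 1:50) {
    m <- random_cs()
    K <- rate_matrix(m, 10^stats::runif(1, -1, 2))
    expect_lt(max(abs(colSums(K))), 1e-13 * max(abs(K)))
    offdiag <- K[row(K) != col(K)]
    expect_true(all(offdiag >= 0))
  }
  # LK at L = 0: single nonzero eigenvalue -koff
  K0 <- rate_matrix(mechanism_lk(1, 3), 0)
  expect_equal(sort(eigen(K0, only.values = TRUE)$values), c(-3, 0))
})

test_that("equilibrium_populations is the null vector with k21/k12 partition", {
  expect_equal(equilibrium_populations(mechanism_cs(3, 3, 1, 5), 0),
               c(Estar = 0.5, E = 0.5, EL = 0))
  expect_equal(unname(equilibrium_populations(mechanism_cs(2, 8, 1, 5), 0)),
               c(0.8, 0.2, 0))
  m <- mechanism_cs(2, 8, 1, 5)
  p <- equilibrium_populations(m, 10)
  expect_equal(sum(p), 1)
  expect_equal(as.numeric(rate_matrix(m, 10) %*% p), rep(0, 3),
               tolerance = 1e-12)
  # fractions at L = 0 obey the E*:E = k21:k12 partition
  p0 <- equilibrium_populations(m, 0)
  expect_equal(p0[["Estar"]] / p0[["E"]], m$k21 / m$k12)
  expect_error(equilibrium_populations(mechanism_cs(0, 0, 1, 5), 0),
               "degenerate")
})

test_that("simulate_trace propagates populations exactly", {
  m <- mechanism_cs(2, 8, 1, 5)
  tt <- log_grid(1e-3, 6, 120)

  # stationarity: starting at equilibrium gives a constant signal
  peq <- equilibrium_populations(m, 10)
  obs <- observable_model(p0 = peq)
  tr <- simulate_trace(m, obs, 10, tt)
  expect_lt(diff(range(tr$signal)), 1e-12)

  # populations stay a distribution at every time point
  tr2 <- simulate_trace(m, NULL, 10, tt)
  P <- attr(tr2, "populations")
  expect_true(all(P > -1e-12))
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-10)

  # long-time limit approaches the equilibrium projection
  co <- c(Estar = 1, E = 1, EL = 0.7)
  expect_equal(tr2$signal[length(tt)], sum(co * peq), tolerance = 1e-6)

  # LK trace minus its asymptote is a single exponential at the
  # closed-form rate
  ml <- mechanism_lk(1.6, 7.8)
  trl <- simulate_trace(ml, NULL, 20, log_grid(1e-3, 0.5, 150))
  f <- fit_exponentials(trl, 1L)
  expect_equal(f$rates[1], lk_relaxation(ml, 20), tolerance = 1e-8)

  # CS residual is a sum of two exponentials at the closed-form rates
  f2 <- fit_exponentials(simulate_trace(m, NULL, 10, tt), 2L)
  r <- cs_relaxations(m, 10)
  expect_equal(f2$rates, c(r$alpha1, r$alpha2), tolerance = 1e-6)
})

test_that("dead-time censoring drops early points and can exhaust a grid", {
  m <- mechanism_lk(1, 5)
  tt <- seq(1e-4, 0.5, length.out = 100)
  tr <- simulate_trace(m, NULL, 10, tt, dead_time_s = 5e-3)
  expect_true(all(tr$time >= 5e-3))
  expect_lt(length(tr$time), 100)
  expect_error(simulate_trace(m, NULL, 10, tt, dead_time_s = 1),
               "censoring")
})

test_that("trace and observable validation catch bad inputs", {
  expect_error(sf_trace(1:5, 1:5, 1, 288), "length >= 10")
  expect_error(sf_trace(c(1:9, 9), 1:10, 1, 288), "increasing")
  expect_error(sf_trace(1:10, 1:10, -1, 288), "metadata")
  expect_error(observable_model(p0 = c(0.6, 0.6)), "sum to 1")
  expect_error(observable_model(coefficients = c(E = 1, EL = 1)),
               "distinct")
})
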