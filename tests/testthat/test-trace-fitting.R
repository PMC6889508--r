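# Per-trace exponential fitting and residual-based model-count selection.

test_that("noiseless fits recover closed-form rates", {
  ml <- mechanism_at(lk_d194a(), 288.15)
  tr <- simulate_trace(ml, NULL, 20, log_grid(1e-3, 0.5, 200))
  f <- fit_exponentials(tr, 1L)
  expect_true(f$converged)
  expect_equal(f$rates[1], 39.8, tolerance = 1e-6)
  expect_gt(f$dof, 0)

  m <- mechanism_cs(2, 8, 1, 5)
  f2 <- fit_exponentials(simulate_trace(m, NULL, 10, log_grid(1e-3, 6, 250)), 2L)
  r <- cs_relaxations(m, 10)
  expect_equal(f2$rates, c(r$alpha1, r$alpha2), tolerance = 1e-4)
  expect_true(all(diff(f2$rates) < 0))   # descending
})

test_that("degenerate traces are flagged, not raised", {
  flat <- sf_trace(seq(0.001, 1, length.out = 50), rep(2, 50), 10, 288.15)
  f <- fit_exponentials(flat, 1L)
  expect_false(f$converged)
  expect_equal(f$amplitudes, 0)
  expect_warning(sel <- choose_exponential_count(flat), "degenerate")
  expect_identical(sel$n, 1L)
})

test_that("model-count selection separates one from two phases", {
  ml <- mechanism_at(lk_d194a(), 288.15)
  tr1 <- simulate_trace(ml, NULL, 20, log_grid(1e-3, 0.5, 200))
  expect_identical(choose_exponential_count(tr1)$n, 1L)

  m <- mechanism_cs(2, 8, 1, 5)
  tr2 <- simulate_trace(m, NULL, 10, log_grid(1e-3, 6, 250))
  expect_identical(choose_exponential_count(tr2)$n, 2L)

  # with 1% noise and 5-fold separated rates the second phase is found
  set.seed(99)
  sig <- tr2$signal + rnorm(length(tr2$signal),
                            0, 0.01 * diff(range(tr2$signal)))
  trn <- sf_trace(tr2$time, sig, 10, 288.15)
  expect_identical(choose_exponential_count(trn)$n, 2L)
})

test_that("single-exponential rates are unbiased under 2% noise", {
  ml <- mechanism_at(lk_d194a(), 288.15)
  tt <- log_grid(1e-3, 0.5, 500)
  clean <- simulate_trace(ml, NULL, 20, tt)
  span <- diff(range(clean$signal))
  set.seed(1234)
  rates <- replicate(200, {
    tr <- sf_trace(tt, clean$signal + rnorm(500, 0, 0.02 * span),
                   20, 288.15)
    fit_exponentials(tr, 1L)$rates[1]
  })
  expect_lt(abs(mean(rates) - 39.8) / 39.8, 0.01)
})

test_that("the F-test keeps its type-I error near the nominal level", {
  ml <- mechanism_at(lk_d194a(), 288.15)
  tt <- log_grid(1e-3, 0.5, 200)
  clean <- simulate_trace(ml, NULL, 20, tt)
  span <- diff(range(clean$signal))
  set.seed(5678)
  n2 <- sum(replicate(200, {
    tr <- sf_trace(tt, clean$signal + rnorm(200, 0, 0.02 * span),
                   20, 288.15)
    choose_exponential_count(tr, alpha_level = 0.01)$n == 2L
  }))
  # nominal 1% plus binomial slack over 200 replicates
  expect_lte(n2 / 200, 0.03)
})

test_that("extract_relaxation_profile tabulates and sorts conditions", {
  expect_identical(nrow(extract_relaxation_profile(list())), 0L)

  des <- experiment_design(ligand_uM = c(10, 30), temp_K = c(278.15, 298.15),
                           points = 120)
  prof <- extract_relaxation_profile(
    gen_stopped_flow_dataset(lk_d194a(), NULL, des, noise_model(0, 2)))
  expect_identical(nrow(prof), 4L)
  expect_true(all(prof$n_exp == 1L))
  expect_true(!is.unsorted(prof$temp_K))

  csdes <- experiment_design(ligand_uM = c(5, 20, 60),
                             temp_K = c(283.15, 293.15),
                             points = 200, duration_s = 8)
  profc <- extract_relaxation_profile(
    gen_stopped_flow_dataset(cs_example(), NULL, csdes, noise_model(0, 2)))
  expect_true(all(profc$n_exp == 2L))
  expect_true(all(profc$alpha1_s > profc$alpha2_s))
})
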