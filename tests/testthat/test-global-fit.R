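# Arrhenius laws, global fitting, thermodynamics and mechanism
# discrimination.

test_that("arrhenius_eval matches direct arithmetic and is monotone", {
  law <- arrhenius_law(7.8, 13)
  expect_equal(arrhenius_eval(law, 288.15), 7.8)
  expect_equal(arrhenius_eval(law, 303.15), 23.98619, tolerance = 1e-6)
  expect_equal(arrhenius_eval(arrhenius_law(3, 0), c(278, 300)), c(3, 3))

  Ts <- seq(275, 310, by = 5)
  expect_true(all(diff(arrhenius_eval(arrhenius_law(2, 10), Ts)) > 0))
  expect_true(all(diff(arrhenius_eval(arrhenius_law(2, -10), Ts)) < 0))
  expect_error(arrhenius_law(-1, 5), "k0")
  expect_error(arrhenius_eval(law, -3), "temperature")
})

test_that("global_kinetic_model validates its laws", {
  expect_error(global_kinetic_model("cs", list(kon = arrhenius_law(1, 1))),
               "must be named")
  expect_error(global_kinetic_model("lk", list(
    kon = arrhenius_law(1, 1, 288.15), koff = arrhenius_law(1, 1, 298.15))),
    "same reference temperature")
  m <- mechanism_at(lk_d194a(), 288.15)
  expect_s3_class(m, "mechanism_lk")
  expect_equal(m$koff, 7.8)
})

test_that("noiseless LK profiles are recovered to 1e-4", {
  prof <- extract_relaxation_profile(
    gen_stopped_flow_dataset(lk_d194a(), NULL,
                             experiment_design(points = 150),
                             noise_model(0, 7)))
  fit <- fit_global(prof, "lk")
  expect_true(fit$diagnostics$converged)
  expect_equal(fit$laws$kon$k0, 1.6, tolerance = 1e-4)
  expect_equal(fit$laws$koff$k0, 7.8, tolerance = 1e-4)
  expect_equal(fit$laws$kon$E, 8.9, tolerance = 1e-4)
  expect_equal(fit$laws$koff$E, 13, tolerance = 1e-4)
  expect_true(all(is.finite(fit$diagnostics$se)))
})

test_that("noiseless CS profiles are recovered to 1e-4", {
  des <- experiment_design(points = 200, duration_s = 8)
  prof <- extract_relaxation_profile(
    gen_stopped_flow_dataset(cs_example(), NULL, des, noise_model(0, 7)))
  fit <- fit_global(prof, "cs")
  truth <- cs_example()
  for (nm in names(truth$laws)) {
    expect_equal(fit$laws[[nm]]$k0, truth$laws[[nm]]$k0, tolerance = 1e-4)
    expect_equal(fit$laws[[nm]]$E, truth$laws[[nm]]$E, tolerance = 1e-4)
  }
})

test_that("a single-temperature profile is rejected", {
  des <- experiment_design(temp_K = 288.15, points = 120)
  prof <- extract_relaxation_profile(
    gen_stopped_flow_dataset(lk_d194a(), NULL, des, noise_model(0, 1)))
  expect_error(fit_global(prof, "lk"), "unidentifiable")
})

test_that("derive_thermo reproduces the published derived columns", {
  # prethrombin-2: Kd = 100 uM, dG = -5.3, dH = -8.4, dS = -11
  th <- derive_thermo(variant_lk_model("prethrombin2"))
  expect_equal(th$Kd_uM, 100)
  expect_equal(th$dG_kcal, -5.27, tolerance = 0.01)
  expect_equal(th$dH_kcal, -8.4)
  expect_equal(th$dS_cal, -10.85, tolerance = 0.01)

  # D194A: Kd = 4.875 uM, dG ~ -7.0, dH = -4.1, dS ~ +10
  th2 <- derive_thermo(lk_d194a())
  expect_equal(th2$Kd_uM, 4.875)
  expect_equal(th2$dG_kcal, -7.0, tolerance = 0.01)
  expect_equal(th2$dH_kcal, -4.1)
  expect_equal(th2$dS_cal, 10.08, tolerance = 0.01)

  # identities: dG = dH - T dS and the 1 M standard state
  expect_equal(th2$dG_kcal, th2$dH_kcal - th2$T * th2$dS_cal / 1000,
               tolerance = 1e-9)
  m1 <- global_kinetic_model("lk", list(kon = arrhenius_law(1, 2),
                                        koff = arrhenius_law(1e6, 3)))
  expect_equal(derive_thermo(m1)$dG_kcal, 0)   # Kd = 1 M
})

test_that("thermodynamic identity holds over random models", {
  set.seed(11)
  for (i in 1:50) {
    m <- global_kinetic_model("lk", list(
      kon = arrhenius_law(10^runif(1, -2, 1), runif(1, -5, 25)),
      koff = arrhenius_law(10^runif(1, -1, 2), runif(1, -5, 25))))
    th <- derive_thermo(m, runif(1, 275, 310))
    expect_equal(th$dG_kcal, th$dH_kcal - th$T * th$dS_cal / 1000,
                 tolerance = 1e-9)
    expect_equal(th$dG_kcal, R_KCAL * th$T * log(th$Kd_uM * 1e-6),
                 tolerance = 1e-9)
  }
})

test_that("discriminate_mechanism reads the saturation evidence", {
  des <- experiment_design(points = 150)
  prof_lk <- extract_relaxation_profile(
    gen_stopped_flow_dataset(lk_d194a(), NULL, des, noise_model(0.02, 31)))
  d1 <- discriminate_mechanism(prof_lk)
  expect_identical(d1$kind, "lk")
  expect_identical(d1$confidence, "high")

  des_cs <- experiment_design(points = 150, duration_s = 8)
  prof_cs <- extract_relaxation_profile(
    gen_stopped_flow_dataset(cs_example(), NULL, des_cs,
                             noise_model(0.02, 32)))
  d2 <- discriminate_mechanism(prof_cs)
  expect_identical(d2$kind, "cs")
  expect_gt(d2$evidence$frac_double, 0.5)

  d3 <- discriminate_mechanism(prof_lk[1, , drop = FALSE])
  expect_identical(d3$kind, "lk")
  expect_identical(d3$confidence, "low")
})
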