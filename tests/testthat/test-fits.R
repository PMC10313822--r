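# i-V, Hill inhibition, and Langmuir binding fits.

test_that("exact i-V points are recovered to machine precision", {
  truth <- linear_iv(39.9, 56.8)
  v <- c(-60, -30, 0, 30, 60, 90)
  d <- data.frame(voltage = v, amplitude = linear_iv_current(truth, v))
  f <- suppressWarnings(fit_iv(d))  # lm warns on a perfect fit
  expect_equal(f$parameters[["g"]], 39.9, tolerance = 1e-12)
  expect_equal(f$parameters[["E_rev"]], 56.8, tolerance = 1e-12)
  expect_identical(f$units[["g"]], "pS")
  expect_identical(f$units[["E_rev"]], "mV")
})

test_that("two points determine the line: (0, -2.27), (90, +1.32)", {
  d <- data.frame(voltage = c(0, 90), amplitude = c(-2.26632, 1.32468))
  f <- suppressWarnings(fit_iv(d))
  expect_equal(f$parameters[["g"]], 39.9, tolerance = 1e-9)
  expect_equal(f$parameters[["E_rev"]], 56.8, tolerance = 1e-9)
})

test_that("i-V estimator is unbiased on symmetric noise", {
  truth <- linear_iv(39.9, 56.8)
  v <- seq(-90, 90, 30)
  res <- t(vapply(1:200, function(s) {
    set.seed(s)
    d <- data.frame(voltage = v,
                    amplitude = linear_iv_current(truth, v) + rnorm(7, 0, 0.1))
    fit_iv(d)$parameters
  }, c(g = 0, E_rev = 0)))
  expect_lt(abs(mean(res[, "E_rev"]) - 56.8), 1)
  expect_lt(abs(mean(res[, "g"]) / 39.9 - 1), 0.005)
})

test_that("i-V fit honours uncertainty weights and rejects degenerate data", {
  expect_error(fit_iv(data.frame(voltage = c(0, 0), amplitude = c(1, 2))),
               "distinct voltages")
  d <- data.frame(voltage = c(-60, 0, 60), amplitude = c(-4.66, -2.27, 0.13),
                  uncertainty = c(0.1, 0.1, 0.1))
  f <- fit_iv(d)
  expect_true(f$converged)
  expect_true(all(is.finite(f$se)))
})

test_that("relative Po is the post/pre ratio", {
  expect_equal(relative_po(0.4, 0.2), 0.5)
  expect_equal(relative_po(0.37, 0.37), 1)
  expect_equal(relative_po(0.5, 0), 0)
  expect_error(relative_po(0, 0.5), "positive")
})

test_that("noiseless Hill tables recover the generating IC50 exactly", {
  for (ic in c(1.09, 19.20)) {
    tab <- generate_dose_response(ic, 1, noise_sd = 0)
    f <- fit_hill_inhibition(tab)
    expect_equal(f$parameters[["ic50"]], ic, tolerance = 1e-6)
    expect_equal(f$parameters[["hill"]], 1, tolerance = 1e-4)
    # fitted model passes through 0.5 at the fitted IC50 by construction
    h <- f$parameters[["hill"]]
    expect_equal(1 / (1 + (f$parameters[["ic50"]] / f$parameters[["ic50"]])^h),
                 0.5)
  }
})

test_that("fix_hill mode is honoured and recorded", {
  tab <- generate_dose_response(6.08, 1, noise_sd = 0.05, seed = 3)
  f_free <- fit_hill_inhibition(tab)
  f_fix <- fit_hill_inhibition(tab, fix_hill = 1)
  expect_false(f_free$details$hill_fixed)
  expect_true(f_fix$details$hill_fixed)
  expect_identical(f_fix$parameters[["hill"]], 1)
  expect_identical(f_fix$se[["hill"]], 0)
})

test_that("one-plateau dose tables are flagged as non-identifiable", {
  lo <- generate_dose_response(1000, 1, doses = c(0.1, 0.3, 1), noise_sd = 0)
  expect_error(fit_hill_inhibition(lo), "plateau")
  hi <- generate_dose_response(0.001, 1, doses = c(10, 30, 100), noise_sd = 0)
  expect_error(fit_hill_inhibition(hi), "plateau")
  expect_error(
    fit_hill_inhibition(data.frame(dose = c(1, 2), relative_po = c(0.9, 0.1))),
    ">= 3 distinct doses"
  )
})

test_that("steady-state Langmuir fit recovers K_D on the 12-point series", {
  conc <- spr_conc_series()
  for (kd in c(7.99, 22.94)) {
    series <- data.frame(conc = conc, response = conc * 100 / (conc + kd))
    # the 22.94 mM truth exceeds the 20 mM series top, so the fit correctly
    # flags weak saturation; the estimate itself is still exact
    f <- suppressWarnings(fit_langmuir_steady(series))
    expect_equal(f$parameters[["K_D"]], kd, tolerance = 1e-4)
    expect_equal(f$parameters[["R_max"]], 100, tolerance = 1e-4)
    # half-saturation at C = K_D under the fitted model
    kd_hat <- f$parameters[["K_D"]]
    rmax_hat <- f$parameters[["R_max"]]
    expect_equal(kd_hat * rmax_hat / (kd_hat + kd_hat), rmax_hat / 2)
  }
})

test_that("non-saturating binding series raises a warning", {
  conc <- c(0.01, 0.03, 0.1, 0.3)
  series <- data.frame(conc = conc, response = conc * 100 / (conc + 50))
  expect_warning(fit_langmuir_steady(series), "non-saturating")
  expect_error(fit_langmuir_steady(data.frame(conc = c(1, 2),
                                              response = c(1, 2))),
               "distinct concentrations")
})

test_that("global kinetic fit recovers (ka, kd) and agrees with steady state", {
  kd_true <- 0.1
  ka_true <- kd_true / 7.99
  sgs <- lapply(spr_conc_series(), function(C) {
    simulate_sensorgram(ka_true, kd_true, 100, C)
  })
  fk <- fit_langmuir_kinetic(sgs)
  expect_equal(fk$parameters[["ka"]], ka_true, tolerance = 1e-3)
  expect_equal(fk$parameters[["kd"]], kd_true, tolerance = 1e-3)
  expect_equal(fk$parameters[["K_D"]], 7.99, tolerance = 1e-3)
  fs <- fit_langmuir_steady(binding_series(sgs))
  expect_equal(fs$parameters[["K_D"]], fk$parameters[["K_D"]],
               tolerance = 0.02)
  # dissociation phase is log-linear with slope -kd
  sg <- sgs[[12]]
  sel <- sg$time > sg$t_assoc + 1
  slope <- coef(lm(log(sg$response[sel]) ~ sg$time[sel]))[[2]]
  expect_equal(slope, -kd_true, tolerance = 1e-6)
})

test_that("kinetic fit demands concentration contrast", {
  sg <- simulate_sensorgram(0.0125, 0.1, 100, 5)
  expect_error(fit_langmuir_kinetic(list(sg, sg)), "identical")
  expect_error(fit_langmuir_kinetic(list(sg)), "length")
})

test_that("fits are deterministic given identical inputs", {
  tab <- generate_dose_response(8.51, 1, noise_sd = 0.1, seed = 9)
  f1 <- fit_hill_inhibition(tab)
  f2 <- fit_hill_inhibition(tab)
  expect_identical(f1$parameters, f2$parameters)
  sgs <- lapply(c(2, 8, 20), function(C) {
    simulate_sensorgram(0.0125, 0.1, 100, C, noise_sd = 1, seed = C)
  })
  expect_identical(fit_langmuir_kinetic(sgs)$parameters,
                   fit_langmuir_kinetic(sgs)$parameters)
})

test_that("fit_result withholds standard errors when not converged", {
  f <- fit_result(c(a = 1), se = c(a = 0.1), converged = FALSE)
  expect_null(f$se)
})
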