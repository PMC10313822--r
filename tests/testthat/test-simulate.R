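# Trace, dose-response and sensorgram generators.

test_that("identical seeds and parameters reproduce traces bit-identically", {
  m <- wt_channel_model()
  a <- quick_acq(duration = 0.5, seed = 11)
  t1 <- simulate_trace(m, a, voltage = 0)
  t2 <- simulate_trace(m, a, voltage = 0)
  expect_identical(t1$current, t2$current)
  t3 <- simulate_trace(m, quick_acq(duration = 0.5, seed = 12), voltage = 0)
  expect_false(identical(t1$current, t3$current))
})

test_that("a channel that never opens yields a flat zero-mean record", {
  m <- channel_model(linear_iv(39.9, 56.8), gating_params(0, 50))
  tr <- simulate_trace(m, quick_acq(duration = 2, seed = 3), voltage = 0,
                       return_states = TRUE)
  expect_true(all(attr(tr, "n_open") == 0L))
  # mean within 3 SE of 0 (noise only)
  se <- sd(tr$current) / sqrt(length(tr$current))
  # filtered noise is autocorrelated: inflate SE by the ~fs/(2 fc) factor
  se <- se * sqrt(10000 / (2 * 1000))
  expect_lt(abs(mean(tr$current)), 3 * se)
})

test_that("occupancy converges to the stationary open probability", {
  m <- channel_model(linear_iv(39.9, 56.8), gating_params(50, 50))
  tr <- simulate_trace(m, quick_acq(duration = 60, seed = 5, noise_sd = 0),
                       return_states = TRUE, voltage = 0)
  frac <- mean(attr(tr, "n_open"))
  # SE of a time-averaged two-state process: sqrt(2 p (1-p) tau / T)
  tau <- 1 / (50 + 50)
  se <- sqrt(2 * 0.5 * 0.5 * tau / 60)
  expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("open-level amplitude equals the linear i-V unit current", {
  m <- wt_channel_model()
  tr <- simulate_trace(m, quick_acq(duration = 5, seed = 7, noise_sd = 0),
                       voltage = 0, return_states = TRUE)
  n_open <- attr(tr, "n_open")
  skip_if(sum(n_open) == 0)
  # noiseless levels: run interiors sit at 0 and i1 = -2.27 pA; medians are
  # insensitive to the filter-smeared transition samples
  open_lvl <- median(tr$current[n_open == 1L])
  closed_lvl <- median(tr$current[n_open == 0L])
  expect_equal(open_lvl - closed_lvl, -2.26632, tolerance = 0.05 / 2.27)
  expect_equal(tr$metadata$unit_current, -2.26632, tolerance = 1e-9)
})

test_that("luminal Ca2+ scales the opening rate by the Hill factor", {
  m <- wt_channel_model()  # ic50 1.09 mM, hill 1
  tr <- simulate_trace(m, quick_acq(duration = 0.1, seed = 1), voltage = 0,
                       luminal_ca = 1.09)
  expect_equal(tr$metadata$k_open, 25, tolerance = 1e-12)
  expect_equal(tr$metadata$stationary_po, 25 / 75, tolerance = 1e-12)
  tr10 <- simulate_trace(m, quick_acq(duration = 0.1, seed = 1), voltage = 0,
                         luminal_ca = 10.9)
  expect_equal(tr10$metadata$k_open, 50 / 11, tolerance = 1e-12)
})

test_that("PIP2 preset swaps conductance and gating", {
  m <- wt_channel_model()
  tr <- simulate_trace(m, quick_acq(duration = 0.1, seed = 1), voltage = 0,
                       use_pip2 = TRUE)
  expect_equal(tr$metadata$conductance, 80.1)
  no_preset <- channel_model(linear_iv(39.9, 56.8), gating_params(50, 50))
  expect_error(simulate_trace(no_preset, quick_acq(duration = 0.1, seed = 1),
                              voltage = 0, use_pip2 = TRUE), "pip2")
})

test_that("multichannel superposition has the binomial level structure", {
  m <- channel_model(linear_iv(39.9, 56.8), gating_params(50, 50),
                     n_channels = 3L)
  tr <- simulate_multichannel_steps(m, quick_acq(duration = 10, seed = 9,
                                                 noise_sd = 0),
                                    voltage = 0, return_states = TRUE)
  n_open <- attr(tr, "n_open")
  expect_true(all(n_open %in% 0:3))
  # noiseless level set is {k * i1 : k = 0..3}; check run interiors, where
  # the filter has settled
  i1 <- tr$metadata$unit_current
  settled <- rep(TRUE, length(n_open))
  for (lag in c(-15:-1, 1:15)) {
    shifted <- data.table::shift(n_open, lag, fill = -1L)
    settled <- settled & shifted == n_open
  }
  expect_gt(mean(settled), 0.5)
  expect_lt(max(abs(tr$current[settled] - i1 * n_open[settled])), 0.05)
  expect_error(
    simulate_multichannel_steps(wt_channel_model(), quick_acq(), 0),
    "n_channels >= 2"
  )
})

test_that("open-count distribution is Binomial(N, Po)", {
  m <- channel_model(linear_iv(39.9, 56.8), gating_params(50, 50),
                     n_channels = 5L)
  tr <- simulate_multichannel_steps(m, quick_acq(duration = 60, seed = 13,
                                                 noise_sd = 0),
                                    voltage = 0, return_states = TRUE)
  n_open <- attr(tr, "n_open")
  # decorrelate: keep one sample per 100 ms (~10 correlation times)
  sub <- n_open[seq(1, length(n_open), by = 1000)]
  obs <- tabulate(sub + 1L, nbins = 6L)
  expected <- dbinom(0:5, 5, 0.5) * length(sub)
  chi2 <- sum((obs - expected)^2 / expected)
  expect_lt(chi2, qchisq(0.99, df = 5))
})

test_that("simulated open dwells are exponential with mean 1/k_close", {
  # Kolmogorov-Smirnov against Exponential(rate = k_close) on ~1e4 events
  m <- channel_model(linear_iv(39.9, 56.8), gating_params(50, 50))
  tr <- simulate_trace(m, acquisition_params(duration = 400, seed = 17,
                                             noise_sd = 0),
                       voltage = 0, return_states = TRUE)
  r <- rle(attr(tr, "n_open"))
  keep <- r$values == 1L
  keep[1] <- FALSE
  keep[length(keep)] <- FALSE  # drop truncated boundary dwells
  open_ms <- r$lengths[keep] / 10  # 10 kHz -> 0.1 ms per sample
  expect_gt(length(open_ms), 8000)
  d <- suppressWarnings(
    ks.test(open_ms / 1000, "pexp", rate = 50)$statistic
  )
  expect_lt(d, 1.628 / sqrt(length(open_ms)))  # alpha = 0.01
  expect_equal(mean(open_ms), 20, tolerance = 3 * 20 / sqrt(length(open_ms)))
})

test_that("dose-response generator matches the Hill mean", {
  noiseless <- generate_dose_response(1.09, 1, doses = c(0, 1.09, 5),
                                      replicates = 2, noise_sd = 0)
  byd <- tapply(noiseless$relative_po, noiseless$dose, mean)
  expect_equal(unname(byd[["0"]]), 1)
  expect_equal(unname(byd[["1.09"]]), 0.5)
  tab <- generate_dose_response(1.09, 1, seed = 4)
  means <- tapply(tab$relative_po, tab$dose, mean)
  # monotone non-increasing in expectation; allow small noise wiggle
  expect_true(all(diff(means) < 0.15))
  expect_true(all(tab$relative_po >= 0))
  expect_error(generate_dose_response(1.09, 1, doses = numeric(0)),
               "non-empty")
  expect_error(generate_dose_response(-1, 1), "positive")
  expect_error(generate_dose_response(1, 0), "positive")
})

test_that("sensorgram follows the closed-form 1:1 Langmuir kinetics", {
  # plateau at C = K_D is rmax/2
  sg <- simulate_sensorgram(ka = 0.0125, kd = 0.1, rmax = 100, conc = 8,
                            t_assoc = 600, t_dissoc = 10)
  expect_equal(max(sg$response), 50, tolerance = 1e-4)
  # zero analyte: identically zero
  sg0 <- simulate_sensorgram(0.0125, 0.1, 100, conc = 0)
  expect_true(all(sg0$response == 0))
  # association half-time ln(2)/(ka C + kd)
  sg2 <- simulate_sensorgram(ka = 0.01, kd = 0.05, rmax = 100, conc = 5)
  rate <- 0.01 * 5 + 0.05  # 0.1 s^-1
  req <- 5 * 100 / (5 + 0.05 / 0.01)
  t_half <- sg2$time[min(which(sg2$response >= req / 2))]
  expect_equal(t_half, log(2) / rate, tolerance = 0.1 / 6.93)
  expect_error(simulate_sensorgram(0, 0.1, 100, 1), "positive")
})

test_that("steady-state endpoint matches the binding isotherm exactly", {
  conc <- spr_conc_series()
  resp <- vapply(conc, function(C) {
    sg <- simulate_sensorgram(0.0125, 0.1, 100, C, t_assoc = 400)
    steady_state_response(sg, frac = 0.05)
  }, numeric(1))
  expect_equal(resp, conc * 100 / (conc + 8), tolerance = 1e-4)
})

test_that("acquisition and model constructors enforce their invariants", {
  expect_error(acquisition_params(sampling_rate = 1500, filter_cutoff = 1000),
               "twice the filter cutoff")
  expect_error(acquisition_params(duration = 0), "duration")
  expect_error(acquisition_params(noise_sd = -1), "noise_sd")
  expect_error(gating_params(-1, 10), "non-negative")
  expect_error(channel_model(linear_iv(39.9, 56.8), gating_params(1, 1),
                             n_channels = 0), "positive integer")
  expect_error(channel_model(linear_iv(39.9, 56.8), gating_params(1, 1),
                             ca_inhibition = list(ic50 = -1, hill = 1)),
               "positive")
  expect_equal(stationary_po(gating_params(50, 50)), 0.5)
  expect_equal(stationary_po(gating_params(0, 0)), 0)
})
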