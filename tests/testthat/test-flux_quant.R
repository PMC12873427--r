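params <- assay_params(6.02e11, volume_L = 6e-4,
                       buffering_capacity_M_per_pH = 0.01)

test_that("noiseless traces give exact slopes; windows before valinomycin error", {
  fx <- make_flux_trace(2000, 1000, params, noise_cl_mM = 0, noise_pH = 0,
                        seed = 1)
  cl <- initial_slope(fx$trace, "chloride", params)
  h <- initial_slope(fx$trace, "proton", params)
  r <- turnover_rates(cl, h, params)
  expect_equal(r$cl_rate, 2000, tolerance = 1e-6)
  expect_equal(r$h_rate, 1000, tolerance = 1e-6)
  expect_error(initial_slope(fx$trace, "chloride", params, start_s = 0),
               "precedes valinomycin")
  short <- flux_trace(seq(0, 100, by = 5), rep(1, 21), rep(4.5, 21), 50)
  expect_error(initial_slope(short, "chloride", params, window_s = 10),
               "fewer than 5")
})

test_that("noisy slope estimates fall within 3 standard errors of the program", {
  fx <- make_flux_trace(2300, 1100, params, seed = 42)
  cl <- initial_slope(fx$trace, "chloride", params)
  r <- turnover_rates(cl, initial_slope(fx$trace, "proton", params), params)
  # analytic SE of the regression slope under the generator's noise
  t <- seq(30, 40, by = 0.2)
  se_cl <- 2e-4 / sqrt(sum((t - mean(t))^2)) * 1e-3 * params$volume_L *
    6.02214076e23 / params$n_transporters
  expect_lt(abs(r$cl_rate - 2300), 3 * se_cl)
})

test_that("turnover arithmetic and proportionality", {
  r <- turnover_rates(1e-9, 0.5e-9, assay_params(6.02e11))
  expect_equal(r$cl_rate, 1000, tolerance = 1e-3)
  half <- turnover_rates(1e-9, 0.5e-9, assay_params(2 * 6.02e11))
  expect_equal(half$cl_rate, r$cl_rate / 2, tolerance = 1e-9)
  expect_error(assay_params(0), "n_transporters > 0")
})

test_that("stoichiometry: ratio semantics and the uncoupled signal", {
  expect_equal(as.numeric(stoichiometry(list(cl_rate = 2000,
                                             h_rate = 1000))), 2)
  un <- stoichiometry(list(cl_rate = 470, h_rate = 0))
  expect_true(is.na(un))
  expect_true(attr(un, "uncoupled"))
  # a transporter with no proton pathway (gating-glutamate-to-alanine
  # analogue) flows through the pipeline as uncoupled, not as a number
  fx <- make_flux_trace(470, 0, params, seed = 7)
  res <- analyze_flux_trace(fx$trace, params)
  expect_true(is.na(res$stoichiometry))
  expect_true(attr(res$stoichiometry, "uncoupled"))
})

test_that("negative post-valinomycin proton slopes are leak, never transport", {
  fx <- make_flux_trace(1000, 0, params, noise_pH = 0, seed = 1)
  # impose an outward proton drift (extravesicular acidification)
  fx$trace$pH <- fx$trace$pH -
    0.001 * pmax(fx$trace$time_s - fx$trace$valinomycin_time_s, 0)
  res <- analyze_flux_trace(fx$trace, params)
  expect_true(res$leak)
  expect_equal(res$h_rate, 0)
})

test_that("replicate aggregation uses mean of ratios with SEM", {
  reps <- lapply(c(1.9, 2.0, 2.1), function(s)
    list(cl_rate = 1000 * s, h_rate = 1000, stoichiometry = s))
  agg <- aggregate_replicates(reps)
  expect_equal(agg$stoichiometry, 2.0)
  expect_equal(agg$stoichiometry_sem, sd(c(1.9, 2, 2.1)) / sqrt(3),
               tolerance = 1e-9)
  expect_equal(agg$stoichiometry_sem, 0.0577, tolerance = 1e-3)
  same <- aggregate_replicates(rep(list(list(cl_rate = 2000, h_rate = 1000,
                                             stoichiometry = 2)), 4))
  expect_equal(same$stoichiometry_sem, 0)
  one <- aggregate_replicates(list(list(cl_rate = 1, h_rate = 1,
                                        stoichiometry = 1)))
  expect_true(is.na(one$cl_sem))
  expect_true(isTRUE(attr(one, "single_replicate")))
  # mean of ratios differs from ratio of means on heterogeneous replicates
  het <- lapply(list(c(3000, 1000), c(1000, 800)), function(x)
    list(cl_rate = x[1], h_rate = x[2], stoichiometry = x[1] / x[2]))
  ha <- aggregate_replicates(het)
  expect_false(isTRUE(all.equal(ha$stoichiometry, ha$cl_rate / ha$h_rate)))
})

test_that("2:1 programmed traces recover stoichiometry within 0.15 over 6 replicates", {
  reps <- lapply(1:6, function(r) {
    fx <- make_flux_trace(2200, 1100, params, seed = 100 + r)
    analyze_flux_trace(fx$trace, params)
  })
  agg <- aggregate_replicates(reps)
  expect_lt(abs(agg$stoichiometry - 2.0), 0.15)
})

test_that("rate and stoichiometry estimators are unbiased across 100 seeded runs", {
  st <- vapply(1:100, function(r) {
    fx <- make_flux_trace(2000, 1000, params, seed = 1000 + r)
    res <- analyze_flux_trace(fx$trace, params)
    c(res$cl_rate, res$h_rate, as.numeric(res$stoichiometry))
  }, numeric(3))
  expect_lt(abs(mean(st[1, ]) - 2000) / 2000, 0.02)
  expect_lt(abs(mean(st[2, ]) - 1000) / 1000, 0.02)
  expect_lt(abs(mean(st[3, ]) - 2.0), 0.05)
})

test_that("stoichiometry is invariant to simultaneous electrode recalibration", {
  fx <- make_flux_trace(2000, 1000, params, seed = 9)
  res <- analyze_flux_trace(fx$trace, params)
  # rescale both channels by the same calibration factor
  tr2 <- fx$trace
  tr2$chloride_mM <- tr2$chloride_mM * 1.7
  p2 <- params
  p2$volume_L <- params$volume_L / 1.7
  cl2 <- initial_slope(tr2, "chloride", p2)
  # proton conversion scales with buffering x volume: compensate buffering
  p2$buffering_capacity <- params$buffering_capacity * 1.7
  h2 <- initial_slope(tr2, "proton", p2)
  r2 <- turnover_rates(cl2, h2, p2)
  expect_equal(as.numeric(stoichiometry(r2)),
               as.numeric(res$stoichiometry), tolerance = 1e-9)
})

test_that("robust Theil-Sen slopes tolerate a spiky electrode artifact", {
  fx <- make_flux_trace(2000, 1000, params, noise_cl_mM = 0, noise_pH = 0,
                        seed = 2)
  tr <- fx$trace
  spike_at <- which(tr$time_s > 32 & tr$time_s < 32.4)
  tr$chloride_mM[spike_at] <- tr$chloride_mM[spike_at] + 0.5
  cl_ls <- initial_slope(tr, "chloride", params)
  cl_ts <- initial_slope(tr, "chloride", params, robust = TRUE)
  truth <- fx$truth$cl_slope_mM_s * 1e-3 * params$volume_L
  expect_lt(abs(as.numeric(cl_ts) - truth) / truth, 0.05)
  expect_gt(abs(as.numeric(cl_ls) - truth) / truth,
            abs(as.numeric(cl_ts) - truth) / truth)
})
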