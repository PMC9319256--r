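# BLI kinetics: phase fits, F-test model selection, pseudo-first-order
# extraction.

test_that("association fit recovers exact single-exponential parameters", {
  t <- seq(0, 480, by = 0.5)
  r <- ifelse(t >= 180 & t < 300, 0.8 * (1 - exp(-0.08 * (t - 180))), 0)
  r[t >= 300] <- (0.8 * (1 - exp(-0.08 * 120))) * exp(-0.0685 * (t[t >= 300] - 300))
  sg <- sensorgram(t, r, 3)
  fit <- fit_association(sg, "single")
  expect_equal(fit$kobs, 0.08, tolerance = 1e-6)
  expect_equal(fit$req, 0.8, tolerance = 1e-6)
})

test_that("association fit resolves a 5% minor phase from noiseless data", {
  sim <- gen_bli(noise_frac = 0, minor_frac = 0.05, seed = 1)
  sg <- sim$sensorgrams[[3]]
  kobs_true <- 0.0037 * 3 + 0.0685
  fit <- fit_association(sg, "double")
  expect_equal(fit$kobs, kobs_true, tolerance = 1e-4)
  expect_equal(fit$kobs2, 0.005, tolerance = 1e-4)
  expect_equal(fit$minor_fraction, 0.05 / 1.05, tolerance = 1e-4)
  # the larger-amplitude exponential is primary
  expect_gt(abs(fit$req), abs(fit$req2))
})

test_that("flat sensorgrams are rejected", {
  t <- seq(0, 480, by = 1)
  sg <- sensorgram(t, rep(0, length(t)), 3)
  expect_error(fit_association(sg, "single"), "no association signal")
})

test_that("kobs is invariant to a uniform time shift", {
  sim <- gen_bli(noise_frac = 0.02, seed = 8)
  sg <- sim$sensorgrams[[4]]
  fit1 <- fit_association(sg, "single")
  shifted <- sensorgram(sg$time_s + 100, sg$response_RU, sg$analyte_uM,
                        t0_assoc = sg$t0_assoc + 100,
                        t0_dissoc = sg$t0_dissoc + 100)
  fit2 <- fit_association(shifted, "single")
  expect_equal(fit1$kobs, fit2$kobs, tolerance = 1e-10)
})

test_that("double fit is nested within single (never worse residuals)", {
  for (i in 1:10) {
    sim <- gen_bli(seed = i)
    sg <- sim$sensorgrams[[(i %% 5) + 1]]
    fs <- fit_association(sg, "single")
    fd <- fit_association(sg, "double")
    expect_lte(fd$rss, fs$rss + 1e-12)
  }
})

test_that("F-test keeps the single model for single-exponential truth", {
  picks <- vapply(1:30, function(i) {
    sim <- gen_bli(minor_frac = 0, seed = i)
    sg <- sim$sensorgrams[[5]]
    select_model(fit_association(sg, "single"),
                 fit_association(sg, "double"))$model
  }, character(1))
  expect_gte(mean(picks == "single"), 0.9)
})

test_that("F-test detects a genuine 5% second phase at high SNR", {
  sim <- gen_bli(minor_frac = 0.05, kobs2 = 0.005, noise_frac = 0.002,
                 seed = 2)
  sg <- sim$sensorgrams[[5]]
  sel <- select_model(fit_association(sg, "single"),
                      fit_association(sg, "double"))
  expect_equal(sel$model, "double")
  expect_lt(sel$p_value, 0.05)
})

test_that("identical residuals give F = 0 and the single model", {
  f1 <- bindlab:::.phase_fit(req = 1, kobs = 0.1, model = "single",
                             rss = 2, n_points = 100, n_par = 2)
  f2 <- bindlab:::.phase_fit(req = 1, kobs = 0.1, req2 = 0, kobs2 = 0.01,
                             model = "double", rss = 2, n_points = 100,
                             n_par = 4)
  sel <- select_model(f1, f2)
  expect_equal(sel$fstat, 0)
  expect_equal(sel$model, "single")
  expect_error(select_model(f1, f2, n_points = 4), "fewer points")
})

test_that("dissociation fit recovers the off-rate exactly and flags flat decays", {
  t <- seq(0, 480, by = 0.5)
  r <- numeric(length(t))
  r[t >= 180 & t < 300] <- 0.9 * (1 - exp(-0.09 * (t[t >= 180 & t < 300] - 180)))
  r1 <- 0.9 * (1 - exp(-0.09 * 120))
  r[t >= 300] <- r1 * exp(-0.0685 * (t[t >= 300] - 300))
  fit <- fit_dissociation(sensorgram(t, r, 3))
  expect_equal(fit$koff_local, 0.0685, tolerance = 1e-6)
  expect_equal(fit$r1, r1, tolerance = 1e-6)
  # koff = 0: flat at R1, flagged
  r[t >= 300] <- r1
  flat <- fit_dissociation(sensorgram(t, r, 3))
  expect_equal(flat$koff_local, 0)
  expect_true(any(grepl("no dissociation", flat$flags)))
})

test_that("pseudo-first-order line reproduces printed rate pairs exactly", {
  concs <- c(1, 2, 3, 5, 7)
  d1 <- data.frame(conc_uM = concs, kobs = 0.0037 * concs + 0.0685)
  k1 <- pseudo_first_order(d1)
  expect_equal(k1$kon, 0.0037, tolerance = 1e-12)
  expect_equal(k1$koff, 0.0685, tolerance = 1e-12)
  expect_equal(k1$kd_uM, 18.5, tolerance = 1e-3)
  d2 <- data.frame(conc_uM = concs, kobs = 0.011 * concs + 0.046)
  expect_equal(pseudo_first_order(d2)$kd_uM, 4.2, tolerance = 5e-3)
  expect_error(pseudo_first_order(d1[1:2, ]), "at least 3")
  d3 <- data.frame(conc_uM = concs, kobs = -0.001 * concs + 0.05)
  expect_error(pseudo_first_order(d3), "no concentration dependence")
})

test_that("kd_from_rates reproduces the printed dissociation constants", {
  expect_equal(kd_from_rates(0.0685, 0.0037), 18.5, tolerance = 1e-3)
  expect_equal(kd_from_rates(0, 0.01), 0)
  expect_equal(kd_from_rates(0.23, 0.020), 11.5, tolerance = 1e-9)
  expect_error(kd_from_rates(0.1, 0), "> 0")
  expect_error(kd_from_rates(-0.1, 0.01), ">= 0")
})

test_that("end-to-end kinetic recovery stays within 25% of truth", {
  kd_true <- 0.0685 / 0.0037
  for (i in 1:5) {
    sim <- gen_bli(seed = i)
    tab <- do.call(rbind, lapply(sim$sensorgrams, function(s) {
      fs <- fit_association(s, "single")
      fd <- fit_association(s, "double")
      sel <- select_model(fs, fd)
      fit <- if (sel$model == "double") fd else fs
      data.frame(conc_uM = s$analyte_uM, kobs = fit$kobs)
    }))
    k <- pseudo_first_order(tab)
    expect_lt(abs(k$kd_uM - kd_true) / kd_true, 0.25)
  }
})
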