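test_that("Welch PSD locates tones, scales quadratically, and is flat for white noise", {
  t <- seq(0.001, 1, by = 0.001)
  x <- sin(2 * pi * 40 * t)
  p <- welch_psd(x, fs = 1000)
  expect_equal(p$freq[which.max(p$power)], 40)
  expect_true(all(diff(p$freq) > 0))
  p2 <- welch_psd(2 * x, fs = 1000)
  expect_close(p2$power / p$power, rep(4, nrow(p)), 1e-8)
  expect_error(welch_psd(x[1:100], fs = 1000), "shorter")
  set.seed(6)
  slopes <- sapply(1:100, function(r) {
    pw <- welch_psd(rnorm(500), fs = 1000)
    keep <- pw$freq >= 10 & pw$freq <= 200
    coef(lm(log10(pw$power[keep]) ~ log10(pw$freq[keep])))[[2]]
  })
  expect_lt(abs(mean(slopes)), 0.2)
})

test_that("evoked-response removal projects out the condition mean", {
  set.seed(8)
  erp <- sin(2 * pi * 4 * seq(0.001, 1, by = 0.001))
  trials <- outer(runif(12, 0.5, 1.5), erp) + matrix(rnorm(12000, 0, 0.05), 12)
  res <- remove_erp(trials)
  expect_lt(max(abs(colMeans(res))), 0.05)
  # identical trials -> near-zero residuals
  same <- matrix(rep(erp, 5), 5, byrow = TRUE)
  expect_lt(max(abs(remove_erp(same))), 1e-12)
  # a trial orthogonal to the mean is unchanged (up to the projection of
  # its own contribution to the mean): test with explicit orthogonal series
  # and idempotence up to numerical tolerance
  res2 <- remove_erp(res)
  expect_close(res2, res, 0.03)
  expect_warning(remove_erp(trials[1, , drop = FALSE]), "single trial")
})

# Oracle for the spectral decomposition: spectra synthesised exactly from
# the model equation log10 P = bb - n*x + w * G(x | mu, sigma).
model_psd <- function(freq, bb, n, w = 0, mu = log10(55),
                      sigma = log10(1.1)) {
  x <- log10(freq)
  data.frame(freq = freq,
             power = 10^(bb - n * x + w * exp(-(x - mu)^2 / (2 * sigma^2))))
}

test_that("spectral model fit recovers parameters from model-generated spectra", {
  freq <- 1:200
  base <- model_psd(freq, bb = -1, n = 2)
  stim <- model_psd(freq, bb = -0.55, n = 2)
  f <- fit_spectral_model(stim, base)
  expect_lt(abs(f$broadband - 0.45), 1e-3)
  expect_lt(abs(f$gamma), 1e-3)
  expect_lt(abs(f$slope_n - 2), 1e-3)
  # add a bump of known weight at 55 Hz
  stim2 <- model_psd(freq, bb = -0.55, n = 2, w = 0.8)
  f2 <- fit_spectral_model(stim2, base)
  expect_lt(abs(f2$gamma - 0.8), 0.008)
  expect_lt(abs(10^f2$stim$mu - 55), 1)
  expect_lt(abs(f2$broadband - 0.45), 0.008)
  # identical spectra give identically zero components
  f0 <- fit_spectral_model(base, base)
  expect_equal(f0$broadband, 0)
  expect_equal(f0$gamma, 0)
  # stimulus-mode gamma reports the raw stimulus bump weight
  f3 <- fit_spectral_model(stim2, base, gamma_mode = "stimulus")
  expect_lt(abs(f3$gamma - 0.8), 0.008)
  expect_error(fit_spectral_model(stim2, base[1:100, ]), "grids")
})

test_that("alpha component is the band-mean log-power change", {
  freq <- 1:200
  base <- model_psd(freq, bb = -1, n = 2)
  expect_equal(alpha_component(base, base), 0)
  stim <- base
  sel <- stim$freq >= 8 & stim$freq <= 13
  stim$power[sel] <- stim$power[sel] * 0.1
  expect_equal(alpha_component(stim, base), -1, tolerance = 1e-12)
})

test_that("bootstrap component intervals behave like resampling intervals", {
  set.seed(10)
  mk <- function(k) t(sapply(1:k, function(i) {
    leaky_integrate(matrix(rnorm(1000, 0, 1), 1), 0.01, 0.001)$currents[1, ]
  }))
  stim <- mk(12); base <- mk(12)
  one <- bootstrap_components(stim, base, fs = 1000, n_boot = 1, seed = 2)
  expect_equal(one$broadband_low, one$broadband_high)  # single resample
  ci <- bootstrap_components(stim, base, fs = 1000, n_boot = 60, seed = 2)
  # point estimates inside their own intervals
  expect_gte(ci$broadband, ci$broadband_low)
  expect_lte(ci$broadband, ci$broadband_high)
  expect_gte(ci$alpha, ci$alpha_low)
  expect_lte(ci$alpha, ci$alpha_high)
  # intervals shrink with more trials (averaged over replications)
  w_many <- mean(replicate(4, {
    s <- mk(40)
    b <- bootstrap_components(s, base, fs = 1000, n_boot = 40, seed = 3)
    b$broadband_high - b$broadband_low
  }))
  w_few <- mean(replicate(4, {
    s <- mk(6)
    b <- bootstrap_components(s, base, fs = 1000, n_boot = 40, seed = 4)
    b$broadband_high - b$broadband_low
  }))
  expect_lt(w_many, w_few)
})

test_that("experiment summaries move the right component for the right input", {
  pcfg <- population_config(trial = trial_config(n_neurons = 60, rng_seed = 2))
  conds <- list(baseline_condition(),
                input_condition(c1_sigma = 0.6, c3_amplitude = 1, label = "hi_bb"),
                input_condition(c2_coherence = 0.5, c3_amplitude = 1,
                                label = "hi_gamma"))
  exp <- simulate_experiment(pcfg, conds, n_repeats = 8, seed = 31)
  s <- summarize_experiment(exp, n_boot = 0)
  blank <- s[s$condition == "blank", ]
  expect_equal(blank$broadband, 0)
  expect_equal(blank$gamma, 0)
  expect_equal(blank$alpha, 0)
  hb <- s[s$condition == "hi_bb", ]
  expect_gt(hb$broadband, 0.3)
  hg <- s[s$condition == "hi_gamma", ]
  expect_gt(hg$gamma, 0.5)
  expect_lt(abs(hg$broadband), 0.15)
  # long-format spectra cover all conditions on a 1 Hz grid
  sp <- experiment_spectra(exp)
  expect_setequal(unique(sp$condition), c("blank", "hi_bb", "hi_gamma"))
  expect_true(all(sp$power > 0))
})
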