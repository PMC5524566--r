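test_that("variant specs enumerate the eight level/correlation combinations", {
  modes <- all_variant_modes()
  expect_length(modes, 8)
  expect_length(unique(names(modes)), 8)
  dflt <- variant_spec()
  expect_equal(as.character(dflt), c("level", "correlation", "level"))
  # default combination targets the standard knobs
  base <- baseline_condition()
  c1 <- lfpbold:::condition_with_strength(base, "broadband", 0.7, dflt)
  expect_equal(c1$c1_sigma, 0.7)
  c2 <- lfpbold:::condition_with_strength(base, "gamma", 0.4, dflt)
  expect_equal(c2$c2_coherence, 0.4)
  c3 <- lfpbold:::condition_with_strength(base, "alpha", 0.2, dflt)
  expect_equal(c3$c3_amplitude, 0.2)
  # correlation-variant broadband moves the coherence knob instead
  alt <- variant_spec(broadband = "correlation")
  c4 <- lfpbold:::condition_with_strength(base, "broadband", 0.02, alt)
  expect_equal(c4$c1_coherence, 0.02)
  expect_equal(c4$c1_sigma, base$c1_sigma)
})

# Synthetic calibration table generated exactly from the broadband family,
# bypassing any simulation: the curve fit must recover it.
synthetic_calib <- function(a = 1.05, v = 0.006, r0 = 0.4, cc = 160,
                            qa = 18, pa = 0.9, ea = 0.5, aa = 2.2) {
  base <- baseline_condition()
  bbfun <- function(s) a * log10((s^2 + v) / (0.3^2 + v))
  sb <- seq(0.3, 0.8, length.out = 10)
  rows <- data.frame(component = "broadband", strength = sb,
                     bb_strength = sb, broadband = bbfun(sb),
                     gamma = 0, alpha = 0)
  for (bs in c(0.3, 0.45, 0.62)) {
    bb <- bbfun(bs)
    sg <- c(0, 0.01, 0.02, 0.035, 0.06, 0.1, 0.16, 0.25, 0.4)
    rows <- rbind(rows, data.frame(component = "gamma", strength = sg,
      bb_strength = bs, broadband = bb,
      gamma = log10(1 + r0 * (1 + cc * sg) * 10^(-bb)) - log10(1 + r0),
      alpha = 0))
    sa <- c(0, 0.4, 0.6, 0.75, 0.9, 1.1, 1.35)
    rows <- rbind(rows, data.frame(component = "alpha", strength = sa,
      bb_strength = bs, broadband = bb, gamma = 0,
      alpha = aa * (log10(qa * sa^pa + 10^(ea * bb)) - log10(qa + 1))))
  }
  attr(rows, "baseline") <- base
  attr(rows, "variant") <- variant_spec()
  rows
}

test_that("curve fitting recovers parameters from noise-free calibration data", {
  calib <- synthetic_calib()
  curves <- fit_calibration_curves(calib)
  expect_lt(abs(curves$broadband$params$a / 1.05 - 1), 0.01)
  expect_lt(abs(curves$broadband$params$v / 0.006 - 1), 0.05)
  expect_lt(curves$broadband$fit_residual, 1e-4)
  expect_lt(curves$gamma$fit_residual, 1e-3)
  expect_lt(curves$alpha$fit_residual, 1e-3)
  expect_true(all(sapply(curves, `[[`, "monotone")))
  # zero change maps to the baseline strength
  expect_equal(curves$broadband$fun(0.3), 0)
  expect_equal(curves$gamma$fun(0), 0)
  expect_equal(curves$alpha$fun(1), 0, tolerance = 1e-12)
})

test_that("inversion undoes the forward curves and flags unreachable targets", {
  curves <- fit_calibration_curves(synthetic_calib())
  # noise-free round trip through the monotone inverse
  for (s in c(0.35, 0.5, 0.75)) {
    tgt <- curves$broadband$fun(s)
    inv <- lfpbold:::invert_curve(curves$broadband, tgt)
    expect_false(inv$clipped)
    expect_lt(abs(inv$strength - s), 1e-3)
  }
  targets <- data.frame(condition = c("a", "blank"),
                        broadband = c(curves$broadband$fun(0.5), 0),
                        gamma = c(0.3, 0), alpha = c(-0.4, 0))
  out <- invert_components(targets, curves)
  expect_lt(abs(out$broadband_strength[out$condition == "a"] - 0.5), 1e-3)
  expect_lt(abs(out$broadband_strength[out$condition == "blank"] - 0.3), 1e-3)
  expect_lt(abs(out$alpha_strength[out$condition == "blank"] - 1), 1e-3)
  expect_false(any(out$clipped_broadband))
  # impossible targets are clipped to the range edge, never silent
  bad <- data.frame(condition = "x", broadband = 10, gamma = -5, alpha = 10)
  expect_message(outb <- invert_components(bad, curves), "clipped")
  expect_true(outb$clipped_broadband)
  expect_true(outb$clipped_gamma)
  expect_true(outb$clipped_alpha)
  expect_equal(outb$broadband_strength, 0.8)   # upper edge of the grid
  # fitted_conditions maps strengths onto the right condition fields
  conds <- fitted_conditions(out)
  expect_equal(conds$a$c1_sigma, out$broadband_strength[out$condition == "a"])
  expect_equal(conds$blank$c3_amplitude,
               out$alpha_strength[out$condition == "blank"])
})

test_that("gamma masking falls out of the fitted family", {
  curves <- fit_calibration_curves(synthetic_calib())
  g <- curves$gamma$fun
  # same input strength produces a smaller component over a raised floor
  expect_gt(g(0.1, 0), g(0.1, 0.5))
  # and a target needs more coherence when broadband is high
  t0 <- lfpbold:::invert_curve(curves$gamma, 0.3, bb = 0)$strength
  t1 <- lfpbold:::invert_curve(curves$gamma, 0.3, bb = 0.5)$strength
  expect_gt(t1, t0)
})
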