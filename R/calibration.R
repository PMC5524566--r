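#' Variant specification: which knob drives each spectral component
#'
#' Each spectral component can be driven either by the per-neuron level of
#' its input or by the across-neuron correlation.  The default model varies
#' the broadband level, the gamma correlation, and the alpha level; the
#' other seven combinations are alternative models that can be calibrated
#' and inverted with the same machinery.
#'
#' @param broadband,gamma,alpha `"level"` or `"correlation"`.
#' @return named character vector of class `variant_spec`.
#' @export
variant_spec <- function(broadband = "level", gamma = "correlation",
                         alpha = "level") {
  v <- c(broadband = match.arg(broadband, c("level", "correlation")),
         gamma = match.arg(gamma, c("level", "correlation")),
         alpha = match.arg(alpha, c("level", "correlation")))
  structure(v, class = "variant_spec")
}

#' All eight level/correlation variant combinations
#' @return list of eight [variant_spec()]s, named e.g. `"level.correlation.level"`.
#' @export
all_variant_modes <- function() {
  g <- expand.grid(broadband = c("level", "correlation"),
                   gamma = c("level", "correlation"),
                   alpha = c("level", "correlation"),
                   stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(g)), function(i)
    variant_spec(g$broadband[i], g$gamma[i], g$alpha[i]))
  names(out) <- apply(g, 1, paste, collapse = ".")
  out
}

# Apply a component strength to the appropriate knob of a condition.
condition_with_strength <- function(base, component, strength,
                                    variant = variant_spec(),
                                    label = NULL) {
  cond <- unclass(base)
  mode <- variant[[component]]
  field <- switch(component,
    broadband = if (mode == "level") "c1_sigma" else "c1_coherence",
    gamma     = if (mode == "correlation") "c2_coherence" else "c2_sigma",
    alpha     = if (mode == "level") "c3_amplitude" else "c3_coherence")
  cond[[field]] <- strength
  if (!is.null(label)) cond$label <- label
  do.call(input_condition, cond)
}

# Default calibration strength grids per component and mode.  Level grids
# start at the baseline value (zero component change); correlation grids
# start at the baseline correlation.
default_strength_grid <- function(component, mode, base) {
  switch(component,
    broadband = if (mode == "level")
      seq(base$c1_sigma, 0.8, length.out = 10)
    else seq(0, 0.03, length.out = 10),
    gamma = if (mode == "correlation")
      c(0, 0.01, 0.02, 0.035, 0.06, 0.1, 0.16, 0.25, 0.4)
    else seq(base$c2_sigma, 1.0, length.out = 7),
    alpha = if (mode == "level")
      c(0, 0.4, 0.6, 0.75, 0.9, 1.1, 1.35) * base$c3_amplitude
    else seq(0, 0.95, length.out = 7))
}

#' Simulate the calibration grid
#'
#' Systematically varies one input strength at a time (the other inputs at
#' their baseline settings), simulates `n_trials` trials per grid point,
#' and measures the three spectral components against the baseline
#' condition.  Because a broadband elevation masks narrowband bumps in the
#' spectrum, the gamma and alpha grids are additionally crossed with a
#' small set of broadband levels, so that the masking can be fitted.
#'
#' @param pcfg a [population_config()].
#' @param base the baseline [input_condition()] (see
#'   [baseline_condition()]).
#' @param variant a [variant_spec()].
#' @param strengths named list of strength grids per component; defaults
#'   are chosen per component and mode.
#' @param bb_levels broadband strengths at which the gamma and alpha grids
#'   are repeated (first entry should be the baseline).
#' @param n_trials simulated trials per grid point; either one number or a
#'   named vector per component.  The broadband default is higher because
#'   the broadband component is measured much more precisely than the
#'   narrowband ones, so curve error shows up sooner.
#' @param n_trials_baseline trials for the shared baseline estimate.
#' @param seed master seed.
#' @return data frame with columns `component`, `strength`, `bb_strength`,
#'   `broadband`, `gamma`, `alpha`; attribute `baseline` carries `base`.
#' @export
run_calibration_grid <- function(pcfg, base = baseline_condition(),
                                 variant = variant_spec(),
                                 strengths = NULL,
                                 bb_levels = NULL,
                                 n_trials = c(broadband = 25, gamma = 15,
                                              alpha = 15),
                                 n_trials_baseline = 60,
                                 seed = 1) {
  if (is.null(bb_levels)) {
    bb_levels <- if (variant[["broadband"]] == "level")
      c(base$c1_sigma, 0.45, 0.62) else c(base$c1_coherence, 0.01, 0.02)
  }
  grids <- lapply(c(broadband = "broadband", gamma = "gamma",
                    alpha = "alpha"), function(comp) {
    if (!is.null(strengths[[comp]])) strengths[[comp]]
    else default_strength_grid(comp, variant[[comp]], base)
  })
  if (length(n_trials) == 1)
    n_trials <- c(broadband = n_trials, gamma = n_trials, alpha = n_trials)
  fs <- pcfg$trial$fs
  base_trials <- simulate_condition(pcfg, base, n_trials_baseline,
                                    seed = substream_seed(seed, "calib-base"))
  base_mat <- lfp_trial_matrix(base_trials)
  pb <- trial_psd_matrices(base_mat, fs)
  keep <- fit_freq_mask(pb$freq)
  x <- log10(pb$freq[keep])
  slope_n <- -coef(lm(log10(colMeans(pb$stim))[keep] ~ x))[[2]]
  measure_point <- function(cond, sd, k) {
    tr <- simulate_condition(pcfg, cond, k, seed = sd)
    m <- trial_psd_matrices(lfp_trial_matrix(tr), fs)
    sf <- fit_spectral_model(mean_psd(m$stim, m$freq),
                             mean_psd(pb$stim, pb$freq), slope_n = slope_n)
    c(broadband = sf$broadband, gamma = sf$gamma,
      alpha = alpha_component(mean_psd(m$alpha, m$freq),
                              mean_psd(pb$alpha, pb$freq)))
  }
  rows <- list()
  for (s in grids$broadband) {
    cond <- condition_with_strength(base, "broadband", s, variant,
                                    label = paste0("cal-bb-", signif(s, 4)))
    v <- measure_point(cond, substream_seed(seed, "cal", "broadband", s),
                       n_trials[["broadband"]])
    rows[[length(rows) + 1]] <- data.frame(component = "broadband",
      strength = s, bb_strength = s, t(v))
  }
  for (comp in c("gamma", "alpha")) {
    for (bs in bb_levels) {
      for (s in grids[[comp]]) {
        cond <- condition_with_strength(base, "broadband", bs, variant)
        cond <- condition_with_strength(cond, comp, s, variant,
          label = paste0("cal-", comp, "-", signif(s, 4), "-", signif(bs, 4)))
        v <- measure_point(cond, substream_seed(seed, "cal", comp, s, bs),
                           n_trials[[comp]])
        rows[[length(rows) + 1]] <- data.frame(component = comp,
          strength = s, bb_strength = bs, t(v))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "baseline") <- base
  attr(out, "variant") <- variant
  attr(out, "slope_n") <- slope_n
  out
}

# Baseline strength of a component under a variant (the value at which its
# component change is zero).
baseline_strength <- function(component, variant, base) {
  switch(component,
    broadband = if (variant[["broadband"]] == "level") base$c1_sigma
                else base$c1_coherence,
    gamma     = if (variant[["gamma"]] == "correlation") base$c2_coherence
                else base$c2_sigma,
    alpha     = if (variant[["alpha"]] == "level") base$c3_amplitude
                else base$c3_coherence)
}

#' Fit the forward calibration curves
#'
#' Fits one monotone parametric curve per component to the calibration
#' grid.  The families follow the structure of the simulated spectra.
#' Broadband: the fitted intercept change is the log ratio of per-neuron
#' input power plus a constant floor contributed by the other inputs,
#' `bb(s) = a * log10((s^2 + v) / (s0^2 + v))`.
#' Gamma: a narrowband bump of input strength `s` rides on a spectral
#' floor that is multiplied by `10^bb` when broadband rises, so the fitted
#' log-bump height is
#' `g(s, bb) = a * (log10(1 + r0*(1 + c*s) * 10^(-bb)) - log10(1 + r0))`
#' with `r0` the baseline bump-to-floor ratio — masking of a fixed bump by
#' a raised floor falls out of the form rather than being bolted on.
#' Alpha: band-averaged log power of an oscillation of strength `s` over
#' the same rising floor,
#' `al(s, bb) = a * (log10(q*s^p + 10^(e*bb)) - log10(q*s0^p + 1))`.
#' All three are monotone nondecreasing in their own strength.
#'
#' @param calib a [run_calibration_grid()] result.
#' @return named list of three `calibration_curve` objects
#'   (`broadband`, `gamma`, `alpha`), each with the fitted parameters, the
#'   valid strength range, the fit RMSE, and a forward function
#'   `fun(s, bb = 0)`.
#' @export
fit_calibration_curves <- function(calib) {
  base <- attr(calib, "baseline")
  variant <- attr(calib, "variant")
  if (is.null(variant)) variant <- variant_spec()
  ctl <- minpack.lm::nls.lm.control(maxiter = 500)
  curves <- list()
  for (comp in c("broadband", "gamma", "alpha")) {
    d <- calib[calib$component == comp, ]
    s0 <- baseline_strength(comp, variant, base)
    y <- d[[comp]]
    if (comp == "broadband") {
      fit <- minpack.lm::nlsLM(
        y ~ a * log10((s^2 + v) / (s0^2 + v)),
        data = data.frame(s = d$strength, y = y),
        start = list(a = 1, v = 0.01),
        lower = c(a = 1e-3, v = 1e-6), control = ctl)
      p <- as.list(coef(fit))
      fun <- local({
        a <- p$a; v <- p$v; s0 <- s0
        function(s, bb = 0) a * log10((s^2 + v) / (s0^2 + v))
      })
    } else if (comp == "gamma") {
      bb <- vapply(d$bb_strength, curves$broadband$fun, numeric(1))
      fit <- minpack.lm::nlsLM(
        y ~ a * (log10(1 + r0 * (1 + cc * s) * 10^(-bb)) - log10(1 + r0)),
        data = data.frame(s = d$strength, y = y, bb = bb),
        start = list(a = 1, r0 = 0.4, cc = 150),
        lower = c(a = 1e-3, r0 = 1e-4, cc = 1),
        upper = c(a = 10, r0 = 100, cc = 5000), control = ctl)
      p <- as.list(coef(fit))
      fun <- local({
        a <- p$a; r0 <- p$r0; cc <- p$cc
        function(s, bb = 0)
          a * (log10(1 + r0 * (1 + cc * s) * 10^(-bb)) - log10(1 + r0))
      })
    } else {
      bb <- vapply(d$bb_strength, curves$broadband$fun, numeric(1))
      fit <- minpack.lm::nlsLM(
        y ~ a * (log10(q * s^p + 10^(e * bb)) - log10(q * s0^p + 1)),
        data = data.frame(s = d$strength, y = y, bb = bb),
        start = list(a = 1, q = 300, p = 2, e = 1),
        lower = c(a = 1e-3, q = 1e-2, p = 0.5, e = 0.05),
        upper = c(a = 10, q = 1e6, p = 4, e = 3), control = ctl)
      p <- as.list(coef(fit))
      fun <- local({
        a <- p$a; q <- p$q; pp <- p$p; e <- p$e; s0 <- s0
        function(s, bb = 0)
          a * (log10(q * s^pp + 10^(e * bb)) - log10(q * s0^pp + 1))
      })
    }
    rng <- range(d$strength)
    fitted_vals <- if (comp == "broadband") fun(d$strength)
                   else fun(d$strength, vapply(d$bb_strength,
                                               curves$broadband$fun,
                                               numeric(1)))
    grid_check <- seq(rng[1], rng[2], length.out = 50)
    mono <- all(diff(fun(grid_check)) >= -1e-9)
    if (!mono)
      warning("fitted ", comp, " curve is not monotone over its range")
    curves[[comp]] <- structure(list(
      component = comp, params = p, s0 = s0, valid_range = rng,
      fit_residual = sqrt(mean((y - fitted_vals)^2)),
      monotone = mono, fun = fun), class = "calibration_curve")
  }
  attr(curves, "baseline") <- base
  attr(curves, "variant") <- variant
  curves
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("Calibration curve [", x$component, "]: strengths ",
      signif(x$valid_range[1], 3), "-", signif(x$valid_range[2], 3),
      ", RMSE ", signif(x$fit_residual, 3), "\n", sep = "")
  invisible(x)
}

# Invert one monotone forward curve by bisection-backed root finding.
invert_curve <- function(curve, target, bb = 0, tol = 1e-6) {
  f <- function(s) curve$fun(s, bb) - target
  lo <- curve$valid_range[1]; hi <- curve$valid_range[2]
  flo <- f(lo); fhi <- f(hi)
  if (flo > 0) return(list(strength = lo, clipped = TRUE))
  if (fhi < 0) return(list(strength = hi, clipped = TRUE))
  r <- uniroot(f, c(lo, hi), tol = tol)
  list(strength = r$root, clipped = FALSE)
}

#' Invert a component table into input strengths
#'
#' Converts per-condition target components (e.g. measured from real
#' recordings or generated fixtures) into the input strengths that the
#' forward calibration curves predict will reproduce them.  The broadband
#' target is inverted first; the implied broadband change then enters the
#' gamma and alpha inversions through the masking term.  Targets outside
#' the achievable range are clipped to the range boundary and flagged.
#'
#' @param targets data frame with columns `condition`, `broadband`,
#'   `gamma`, `alpha`.
#' @param curves a [fit_calibration_curves()] result.
#' @return data frame with the inverted strengths
#'   (`broadband_strength`, `gamma_strength`, `alpha_strength`), clip
#'   flags, and the original targets; attribute `variant`/`baseline`
#'   forwarded from the curves.
#' @export
invert_components <- function(targets, curves) {
  stopifnot(all(c("condition", "broadband", "gamma", "alpha") %in%
                  names(targets)))
  rows <- lapply(seq_len(nrow(targets)), function(i) {
    ib <- invert_curve(curves$broadband, targets$broadband[i])
    bb_hat <- curves$broadband$fun(ib$strength)
    ig <- invert_curve(curves$gamma, targets$gamma[i], bb = bb_hat)
    ia <- invert_curve(curves$alpha, targets$alpha[i], bb = bb_hat)
    data.frame(condition = targets$condition[i],
               broadband_strength = ib$strength,
               gamma_strength = ig$strength,
               alpha_strength = ia$strength,
               clipped_broadband = ib$clipped,
               clipped_gamma = ig$clipped,
               clipped_alpha = ia$clipped)
  })
  out <- do.call(rbind, rows)
  if (any(out$clipped_broadband | out$clipped_gamma | out$clipped_alpha))
    message("some targets fell outside the achievable range and were clipped")
  out <- merge(out, targets, by = "condition", sort = FALSE)
  attr(out, "variant") <- attr(curves, "variant")
  attr(out, "baseline") <- attr(curves, "baseline")
  out
}

#' Conditions implied by inverted strengths
#'
#' @param inverted an [invert_components()] result.
#' @param base baseline condition (defaults to the one attached to
#'   `inverted`).
#' @param variant [variant_spec()] (defaults likewise).
#' @return named list of [input_condition()]s.
#' @export
fitted_conditions <- function(inverted, base = attr(inverted, "baseline"),
                              variant = attr(inverted, "variant")) {
  if (is.null(variant)) variant <- variant_spec()
  conds <- lapply(seq_len(nrow(inverted)), function(i) {
    cond <- condition_with_strength(base, "broadband",
                                    inverted$broadband_strength[i], variant)
    cond <- condition_with_strength(cond, "gamma",
                                    inverted$gamma_strength[i], variant)
    condition_with_strength(cond, "alpha", inverted$alpha_strength[i],
                            variant, label = as.character(inverted$condition[i]))
  })
  names(conds) <- inverted$condition
  conds
}

#' Simulate a site from a target component table
#'
#' The full forward pipeline for one recording site: invert the targets
#' into input strengths, simulate every condition, and return both the
#' re-summarised spectral components and the per-condition BOLD proxy, with
#' split-half (even/odd trial) versions for cross-validated analyses.
#'
#' @param targets per-condition component table (must contain the baseline
#'   condition with zero components).
#' @param curves [fit_calibration_curves()] result.
#' @param pcfg a [population_config()].
#' @param n_repeats trials per condition.
#' @param seed master seed.
#' @param n_boot bootstrap resamples for the component summary CIs.
#' @param baseline label of the baseline condition in `targets`.
#' @param bold_noise_sd Gaussian noise added to the per-half BOLD means
#'   (measurement noise on the response side; 0 for none).
#' @param bold_noise_frac response noise expressed as a fraction of the
#'   across-condition standard deviation of the mean BOLD — the natural way
#'   to match a target split-half reliability.  For split-half reliability
#'   R2 of the response (normalized vectors), noise/signal =
#'   sqrt((1-r)/r) with r = (1 + R2)/2.  Added on top of `bold_noise_sd`.
#' @return list with `inverted`, `components`, `components_half`
#'   (two-row-per-condition data frame with a `half` column), `bold`
#'   (condition, bold, CI bounds), `bold_half`, and `spectra` (the
#'   per-condition trial-averaged stimulus-window spectra).  Conditions are
#'   simulated one at a time and only field-potential-level data are kept,
#'   so memory stays bounded for large populations.
#' @export
simulate_site <- function(targets, curves, pcfg, n_repeats = 30, seed = 1,
                          n_boot = 100, baseline = "blank",
                          bold_noise_sd = 0, bold_noise_frac = 0) {
  inverted <- invert_components(targets, curves)
  conds <- fitted_conditions(inverted)
  fs <- pcfg$trial$fs
  mats <- list(); bold_trials <- list()
  for (lab in names(conds)) {
    tr <- simulate_condition(pcfg, conds[[lab]], n_repeats, seed = seed)
    mats[[lab]] <- lfp_trial_matrix(tr)
    bold_trials[[lab]] <- vapply(tr, bold_proxy, numeric(1))
    rm(tr)
  }
  comps <- summarize_lfp_mats(mats, fs, baseline = baseline, n_boot = n_boot,
                              seed = substream_seed(seed, "summary"))
  halves <- list(seq(1, n_repeats, by = 2), seq(2, n_repeats, by = 2))
  comp_half <- do.call(rbind, lapply(1:2, function(h) {
    cbind(summarize_lfp_mats(mats, fs, baseline = baseline, n_boot = 0,
                             trial_subset = halves[[h]]), half = h)
  }))
  bold <- do.call(rbind, lapply(names(bold_trials), function(lab) {
    b <- bold_trials[[lab]]
    ci <- with_substream(substream_seed(seed, "boldboot", lab), {
      reps <- vapply(seq_len(max(n_boot, 1)), function(i)
        mean(sample(b, replace = TRUE)), numeric(1))
      quantile(reps, c(0.16, 0.84), names = FALSE)
    })
    data.frame(condition = lab, bold = mean(b),
               bold_low = ci[1], bold_high = ci[2])
  }))
  # Response-side replicates use the trials *not* used by the same-numbered
  # component half, so predictor and response measurement noise are
  # independent — the simulation analogue of measuring BOLD in different
  # subjects than the field potentials.
  noise_sd <- bold_noise_sd +
    bold_noise_frac * sd(vapply(bold_trials, mean, numeric(1)))
  bold_half <- do.call(rbind, lapply(1:2, function(h) {
    noise <- with_substream(substream_seed(seed, "boldnoise", h),
                            rnorm(length(bold_trials), 0, noise_sd))
    data.frame(condition = names(bold_trials),
               bold = vapply(bold_trials, function(b)
                 mean(b[halves[[3 - h]]]), numeric(1)) + noise,
               half = h)
  }))
  list(inverted = inverted, components = comps, components_half = comp_half,
       bold = bold, bold_half = bold_half,
       spectra = spectra_from_mats(mats, fs))
}

#' Predicted BOLD for a target component table
#'
#' Inverts the targets, simulates each condition, and reports the
#' per-condition mean BOLD proxy with bootstrap confidence intervals.
#'
#' @inheritParams simulate_site
#' @param n_boot bootstrap resamples over trials for the 68% CIs.
#' @return data frame `condition`, `bold`, `bold_low`, `bold_high`.
#' @export
predict_bold_for_targets <- function(targets, curves, pcfg, n_repeats = 30,
                                     seed = 1, n_boot = 100) {
  inverted <- invert_components(targets, curves)
  conds <- fitted_conditions(inverted)
  rows <- lapply(names(conds), function(lab) {
    tr <- simulate_condition(pcfg, conds[[lab]], n_repeats,
                             seed = substream_seed(seed, "predict", lab))
    b <- vapply(tr, bold_proxy, numeric(1))
    ci <- with_substream(substream_seed(seed, "predboot", lab), {
      reps <- vapply(seq_len(n_boot), function(i)
        mean(sample(b, replace = TRUE)), numeric(1))
      quantile(reps, c(0.16, 0.84), names = FALSE)
    })
    data.frame(condition = lab, bold = mean(b),
               bold_low = ci[1], bold_high = ci[2])
  })
  do.call(rbind, rows)
}
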