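#' Welch power spectral density
#'
#' Averaged modified periodograms with a Hann window.  Defaults give the
#' spectral pipeline used throughout the package: 250 ms windows with 50%
#' overlap, zero-padded to a 1 Hz frequency grid.  Each segment is demeaned
#' before windowing so that the DC offset of the summed population current
#' does not leak into the low-frequency bins.
#'
#' @param x numeric time series.
#' @param fs sampling rate in Hz.
#' @param window_s Hann window length in seconds.
#' @param overlap fractional overlap between segments.
#' @param nfft FFT length (zero-padding); defaults to `fs`, i.e. a 1 Hz
#'   grid.
#' @param fmax highest frequency retained, Hz.
#' @return data frame of class `psd` with columns `freq` (1 Hz steps) and
#'   `power` (one-sided density), and attributes `fs`, `n_segments`.
#' @export
welch_psd <- function(x, fs, window_s = 0.25, overlap = 0.5, nfft = fs,
                      fmax = fs / 2) {
  nwin <- round(window_s * fs)
  if (length(x) < nwin)
    stop("series shorter than one analysis window")
  step <- max(1, round(nwin * (1 - overlap)))
  starts <- seq(1, length(x) - nwin + 1, by = step)
  w <- signal::hanning(nwin)
  U <- sum(w^2)
  acc <- numeric(nfft)
  for (s in starts) {
    seg <- x[s:(s + nwin - 1)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(fft(c(seg, numeric(nfft - nwin))))^2
  }
  pxx <- acc / (length(starts) * fs * U)
  half <- 2:(floor(nfft / 2))          # positive frequencies below Nyquist
  pxx <- 2 * pxx[half]
  freq <- (half - 1) * fs / nfft
  keep <- freq <= fmax
  structure(data.frame(freq = freq[keep], power = pxx[keep]),
            fs = fs, n_segments = length(starts),
            class = c("psd", "data.frame"))
}

#' Regress the condition-mean evoked response out of each trial
#'
#' Computes the mean time series across trials of one condition (the
#' evoked response) and removes its per-trial scalar projection from each
#' trial, leaving the induced (non-phase-locked) activity.
#'
#' @param trials trials x time numeric matrix for one condition.
#' @return residual matrix of the same shape.  With a single trial the
#'   removal is skipped with a warning.
#' @export
remove_erp <- function(trials) {
  trials <- as.matrix(trials)
  if (nrow(trials) < 2) {
    warning("single trial: evoked-response removal skipped")
    return(trials)
  }
  erp <- colMeans(trials)
  denom <- sum(erp^2)
  if (denom == 0) return(trials)
  coefs <- as.vector(trials %*% erp) / denom
  trials - outer(coefs, erp)
}

# Profile fit of log10 P = bb - n*x + w * G(x | mu, sigma) with n fixed:
# for a candidate mu the model is linear in (bb, w); w is constrained >= 0.
# mu is profiled over a grid plus a local refinement.
fit_bump <- function(logp, x, slope_n, sigma_log10,
                     mu_range = log10(c(35, 80))) {
  y <- logp + slope_n * x
  fit_at_mu <- function(mu) {
    g <- exp(-(x - mu)^2 / (2 * sigma_log10^2))
    gc <- g - mean(g)
    w <- sum(gc * (y - mean(y))) / sum(gc^2)
    if (!is.finite(w) || w < 0) w <- 0
    bb <- mean(y) - w * mean(g)
    rss <- sum((y - bb - w * g)^2)
    list(bb = bb, w = w, mu = mu, rss = rss)
  }
  grid <- seq(mu_range[1] + 1e-3, mu_range[2] - 1e-3, length.out = 25)
  fits <- lapply(grid, fit_at_mu)
  best <- which.min(vapply(fits, `[[`, numeric(1), "rss"))
  lo <- grid[max(1, best - 1)]; hi <- grid[min(length(grid), best + 1)]
  opt <- optimize(function(mu) fit_at_mu(mu)$rss, c(lo, hi))
  out <- fit_at_mu(opt$minimum)
  if (!all(is.finite(c(out$bb, out$w, out$mu))))
    stop("spectral model fit failed: non-finite parameters")
  out
}

# Frequencies used for the power-law + bump fit: 35-200 Hz minus the
# line-noise bands (60, 120, 180 Hz +/- 5 Hz), kept for pipeline parity
# with recorded data even though simulations have no line noise.
fit_freq_mask <- function(freq, fit_range = c(35, 200),
                          exclude_line_noise = TRUE) {
  keep <- freq >= fit_range[1] & freq <= fit_range[2]
  if (exclude_line_noise) {
    for (f0 in c(60, 120, 180)) keep <- keep & abs(freq - f0) > 5
  }
  keep
}

#' Fit the spectral model and extract broadband and gamma components
#'
#' Fits `log10 P(f) = beta_bb - n*x + beta_nb * G(x | mu, sigma)` with
#' `x = log10 f` over 35–200 Hz (line-noise bands excluded).  The power-law
#' exponent `n` is first fixed by a least-squares line on the baseline
#' spectrum; with `n` held, the intercept, a nonnegative log-Gaussian bump
#' weight and the bump centre (`10^mu` bounded to 35–80 Hz; `sigma` fixed at
#' `log10(1.1)`) are fitted to both spectra.  The broadband component is the
#' change in power-law intercept from baseline; the gamma component is by
#' default the change in bump weight from baseline (set
#' `gamma_mode = "stimulus"` for the raw stimulus-fit weight).
#'
#' @param psd_stim,psd_base [welch_psd()] outputs on the same grid.
#' @param sigma_log10 bump width on the log10-frequency axis.
#' @param fit_range frequency range for the fit, Hz.
#' @param exclude_line_noise drop 60/120/180 +/- 5 Hz from the fit.
#' @param gamma_mode `"difference"` (default) or `"stimulus"`.
#' @param slope_n optionally supply a precomputed baseline exponent.
#' @return list of class `spectral_fit` with `broadband`, `gamma`,
#'   `slope_n`, and the stimulus/baseline fits (`bb`, `w`, `mu`, `rss`).
#' @export
fit_spectral_model <- function(psd_stim, psd_base,
                               sigma_log10 = log10(1.1),
                               fit_range = c(35, 200),
                               exclude_line_noise = TRUE,
                               gamma_mode = c("difference", "stimulus"),
                               slope_n = NULL) {
  gamma_mode <- match.arg(gamma_mode)
  if (!isTRUE(all.equal(psd_stim$freq, psd_base$freq)))
    stop("stimulus and baseline spectra are on different frequency grids")
  keep <- fit_freq_mask(psd_stim$freq, fit_range, exclude_line_noise)
  x <- log10(psd_stim$freq[keep])
  if (is.null(slope_n)) {
    lb <- log10(psd_base$power[keep])
    slope_n <- -coef(lm(lb ~ x))[[2]]
  }
  fs <- fit_bump(log10(psd_stim$power[keep]), x, slope_n, sigma_log10)
  fb <- fit_bump(log10(psd_base$power[keep]), x, slope_n, sigma_log10)
  structure(list(
    broadband = fs$bb - fb$bb,
    gamma = if (gamma_mode == "difference") fs$w - fb$w else fs$w,
    slope_n = slope_n, stim = fs, base = fb, gamma_mode = gamma_mode),
    class = "spectral_fit")
}

#' Alpha component: band-averaged log-power change from baseline
#'
#' Mean of `log10` power over the alpha band of the stimulus spectrum minus
#' the same quantity for the baseline spectrum.
#'
#' @param psd_stim,psd_base [welch_psd()] outputs on the same grid
#'   (conventionally computed over the late, 250–500 ms, part of the trial
#'   where alpha changes are not masked by onset transients).
#' @param band alpha band in Hz.
#' @return scalar, log10 units.
#' @export
alpha_component <- function(psd_stim, psd_base, band = c(8, 13)) {
  sel <- psd_stim$freq >= band[1] & psd_stim$freq <= band[2]
  mean(log10(psd_stim$power[sel])) - mean(log10(psd_base$power[sel]))
}

# Per-trial PSD matrices for one condition's LFP trials.
# lfp_mat: trials x time.  Returns list(stim = trials x nfreq matrix,
# alpha = same, freq).
trial_psd_matrices <- function(lfp_mat, fs, stim_window = c(0, 0.5),
                               alpha_window = c(0.25, 0.5)) {
  idx <- function(w) (round(w[1] * fs) + 1):round(w[2] * fs)
  i_stim <- idx(stim_window); i_alpha <- idx(alpha_window)
  one <- function(i, sel) welch_psd(lfp_mat[i, sel], fs)$power
  ex <- welch_psd(lfp_mat[1, i_stim], fs)
  stim <- t(vapply(seq_len(nrow(lfp_mat)), one, ex$power, sel = i_stim))
  alpha <- t(vapply(seq_len(nrow(lfp_mat)), one, ex$power, sel = i_alpha))
  list(stim = stim, alpha = alpha, freq = ex$freq)
}

mean_psd <- function(mat, freq, idx = seq_len(nrow(mat))) {
  structure(data.frame(freq = freq, power = colMeans(mat[idx, , drop = FALSE])),
            class = c("psd", "data.frame"))
}

#' Bootstrap spectral components across trials
#'
#' Resamples trials with replacement (independently for the stimulus and
#' baseline conditions), recomputes trial-averaged spectra and the three
#' component estimates, and reports percentile confidence intervals.
#'
#' @param stim_lfp,base_lfp trials x time matrices of field-potential
#'   series for the stimulus and baseline conditions.
#' @param fs sampling rate, Hz.
#' @param n_boot number of bootstrap resamples.
#' @param prob tail coverage of the interval (0.68 gives a 68% CI).
#' @param seed RNG substream seed for the resampling.
#' @param slope_n optional fixed baseline power-law exponent.
#' @param ... passed to [fit_spectral_model()].
#' @return one-row data frame: point estimates `broadband`, `gamma`,
#'   `alpha` and `*_low`, `*_high` interval bounds.
#' @export
bootstrap_components <- function(stim_lfp, base_lfp, fs, n_boot = 100,
                                 prob = 0.68, seed = 1, slope_n = NULL, ...) {
  ps <- trial_psd_matrices(stim_lfp, fs)
  pb <- trial_psd_matrices(base_lfp, fs)
  comp <- function(is, ib) {
    sf <- fit_spectral_model(mean_psd(ps$stim, ps$freq, is),
                             mean_psd(pb$stim, pb$freq, ib),
                             slope_n = slope_n, ...)
    c(broadband = sf$broadband, gamma = sf$gamma,
      alpha = alpha_component(mean_psd(ps$alpha, ps$freq, is),
                              mean_psd(pb$alpha, pb$freq, ib)))
  }
  point <- comp(seq_len(nrow(ps$stim)), seq_len(nrow(pb$stim)))
  boots <- with_substream(seed, {
    t(vapply(seq_len(n_boot), function(b) {
      comp(sample.int(nrow(ps$stim), replace = TRUE),
           sample.int(nrow(pb$stim), replace = TRUE))
    }, point))
  })
  lo <- (1 - prob) / 2
  ci <- apply(boots, 2, quantile, probs = c(lo, 1 - lo), names = FALSE)
  data.frame(broadband = point[["broadband"]], gamma = point[["gamma"]],
             alpha = point[["alpha"]],
             broadband_low = ci[1, 1], broadband_high = ci[2, 1],
             gamma_low = ci[1, 2], gamma_high = ci[2, 2],
             alpha_low = ci[1, 3], alpha_high = ci[2, 3])
}

# Stack a condition's trials into a trials x time LFP matrix.
lfp_trial_matrix <- function(trials, mc = measure_config()) {
  t(vapply(trials, lfp_timeseries, numeric(ncol(trials[[1]]$currents)),
           mc = mc))
}

#' Spectral component summary of a simulated experiment
#'
#' Runs the full spectral pipeline on each condition of an experiment:
#' field-potential series per trial, optional evoked-response removal,
#' Welch spectra per trial, trial averaging, and the broadband / gamma /
#' alpha component fits against the designated baseline condition, with
#' bootstrap confidence intervals.  The baseline power-law exponent is
#' fitted once on the baseline condition's average spectrum and reused for
#' every condition.
#'
#' @param exp an [simulate_experiment()] result.
#' @param baseline label of the baseline (blank) condition.
#' @param mc a [measure_config()].
#' @param erp_removal regress out the condition-mean evoked response before
#'   spectral analysis (off by default: simulated trials have no evoked
#'   component).
#' @param n_boot bootstrap resamples per condition (0 skips the CIs).
#' @param trial_subset optional indices restricting which repeats are used
#'   (e.g. even trials only, for split-half analyses).
#' @param seed RNG substream seed for the bootstraps.
#' @param ... passed to [fit_spectral_model()].
#' @return data frame with one row per condition: `condition`,
#'   `broadband`, `gamma`, `alpha`, and `_low`/`_high` bounds when
#'   `n_boot > 0`.
#' @export
summarize_experiment <- function(exp, baseline = "blank",
                                 mc = measure_config(),
                                 erp_removal = FALSE, n_boot = 100,
                                 trial_subset = NULL, seed = 1, ...) {
  stopifnot(inherits(exp, "experiment"))
  fs <- exp$pcfg$trial$fs
  mats <- lapply(exp$trials, function(tr) {
    if (!is.null(trial_subset)) tr <- tr[trial_subset]
    m <- lfp_trial_matrix(tr, mc)
    if (erp_removal) m <- remove_erp(m)
    m
  })
  summarize_lfp_mats(mats, fs, baseline = baseline, n_boot = n_boot,
                     seed = seed, ...)
}

# Core of the component summary, operating on per-condition trials x time
# field-potential matrices (so callers can discard the full current
# matrices as soon as the LFP is extracted).
summarize_lfp_mats <- function(mats, fs, baseline = "blank", n_boot = 100,
                               trial_subset = NULL, seed = 1, ...) {
  if (!baseline %in% names(mats))
    stop("baseline condition '", baseline, "' not in experiment")
  if (!is.null(trial_subset))
    mats <- lapply(mats, function(m) m[trial_subset, , drop = FALSE])
  base_mat <- mats[[baseline]]
  # baseline exponent, fixed for the whole experiment
  pb <- trial_psd_matrices(base_mat, fs)
  keep <- fit_freq_mask(pb$freq)
  x <- log10(pb$freq[keep])
  slope_n <- -coef(lm(log10(colMeans(pb$stim))[keep] ~ x))[[2]]
  rows <- lapply(names(mats), function(lab) {
    if (n_boot > 0) {
      out <- bootstrap_components(mats[[lab]], base_mat, fs, n_boot = n_boot,
                                  seed = substream_seed(seed, lab, "boot"),
                                  slope_n = slope_n, ...)
    } else {
      psc <- trial_psd_matrices(mats[[lab]], fs)
      sf <- fit_spectral_model(mean_psd(psc$stim, psc$freq),
                               mean_psd(pb$stim, pb$freq),
                               slope_n = slope_n, ...)
      out <- data.frame(
        broadband = sf$broadband, gamma = sf$gamma,
        alpha = alpha_component(mean_psd(psc$alpha, psc$freq),
                                mean_psd(pb$alpha, pb$freq)))
    }
    cbind(condition = lab, out)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "slope_n") <- slope_n
  attr(res, "baseline") <- baseline
  res
}

#' Per-condition average spectra of an experiment
#'
#' Trial-averaged stimulus-window spectra for every condition, in long
#' format — the input for per-frequency correlation analyses.
#'
#' @inheritParams summarize_experiment
#' @return data frame with columns `condition`, `freq`, `power`.
#' @export
experiment_spectra <- function(exp, mc = measure_config(),
                               trial_subset = NULL) {
  fs <- exp$pcfg$trial$fs
  rows <- lapply(names(exp$trials), function(lab) {
    tr <- exp$trials[[lab]]
    if (!is.null(trial_subset)) tr <- tr[trial_subset]
    m <- trial_psd_matrices(lfp_trial_matrix(tr, mc), fs)
    data.frame(condition = lab, freq = m$freq, power = colMeans(m$stim))
  })
  do.call(rbind, rows)
}

# experiment_spectra on per-condition LFP matrices.
spectra_from_mats <- function(mats, fs) {
  rows <- lapply(names(mats), function(lab) {
    m <- trial_psd_matrices(mats[[lab]], fs)
    data.frame(condition = lab, freq = m$freq, power = colMeans(m$stim))
  })
  do.call(rbind, rows)
}
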