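#' Trial configuration
#'
#' Dimensions and sampling of one simulated trial.  The defaults — 200
#' neurons, 1 s of data at millisecond sampling — are the population and
#' trial structure used throughout the package.
#'
#' @param n_neurons number of neurons in the population.
#' @param duration trial duration in seconds.
#' @param dt sample interval in seconds; `duration/dt` must be a whole
#'   number of samples.
#' @param rng_seed master seed for all randomness in this trial's inputs.
#' @return an object of class `trial_config`.
#' @export
trial_config <- function(n_neurons = 200, duration = 1, dt = 0.001,
                         rng_seed = 1) {
  stopifnot(n_neurons >= 1, duration > 0, dt > 0)
  n_samples <- duration / dt
  if (abs(n_samples - round(n_samples)) > 1e-8)
    stop("duration/dt must be an integer number of samples")
  structure(list(n_neurons = as.integer(n_neurons), duration = duration,
                 dt = dt, n_samples = as.integer(round(n_samples)),
                 fs = 1 / dt, rng_seed = rng_seed),
            class = "trial_config")
}

#' Stimulus condition: strengths of the three neuronal inputs
#'
#' A condition is defined by the settings of the three input classes of the
#' population model: the per-neuron standard deviation of the asynchronous
#' broadband input, the across-neuron coherence of the narrowband gamma
#' input, and the amplitude of the inhibitory alpha input.  The remaining
#' knobs (broadband coherence, gamma level, alpha coherence) are fixed by
#' default but exposed so that alternative model variants — driving a
#' component by level instead of correlation or vice versa — can be run.
#'
#' @param c1_sigma standard deviation of the broadband input (baseline 0.3).
#' @param c2_coherence pairwise correlation of the gamma input, in `[0, 1]`.
#' @param c3_amplitude nonnegative scale of the alpha input.
#' @param label condition name.
#' @param c1_mean mean of the broadband input (excitatory offset, 0.25).
#' @param c1_coherence pairwise correlation of the broadband input
#'   (0 in the default model).
#' @param c2_sigma standard deviation of the gamma input before filtering
#'   (fixed at 0.2 in the default model).
#' @param c3_coherence pairwise correlation of the alpha input (fixed 0.75).
#' @return an object of class `input_condition`.
#' @export
input_condition <- function(c1_sigma = 0.3, c2_coherence = 0,
                            c3_amplitude = 0, label = "condition",
                            c1_mean = 0.25, c1_coherence = 0,
                            c2_sigma = 0.2, c3_coherence = 0.75) {
  if (c1_sigma < 0) stop("c1_sigma must be nonnegative")
  if (c2_coherence < 0 || c2_coherence > 1)
    stop("c2_coherence must lie in [0, 1]")
  if (c3_amplitude < 0) stop("c3_amplitude must be nonnegative")
  if (c1_coherence < 0 || c1_coherence > 1 ||
      c3_coherence < 0 || c3_coherence > 1)
    stop("coherences must lie in [0, 1]")
  if (c2_sigma < 0) stop("c2_sigma must be nonnegative")
  structure(list(c1_sigma = c1_sigma, c2_coherence = c2_coherence,
                 c3_amplitude = c3_amplitude, label = label,
                 c1_mean = c1_mean, c1_coherence = c1_coherence,
                 c2_sigma = c2_sigma, c3_coherence = c3_coherence),
            class = "input_condition")
}

#' Baseline (blank-stimulus) condition
#'
#' The condition against which spectral components are measured: broadband
#' input at its baseline standard deviation, no gamma coherence, and a
#' nonzero resting alpha amplitude (alpha oscillations are large during
#' blank viewing, so stimuli can only be represented as alpha *decreases*
#' if the baseline amplitude is positive).
#'
#' @param c3_amplitude resting alpha amplitude.
#' @param label condition label.
#' @param ... further arguments passed to [input_condition()].
#' @export
baseline_condition <- function(c3_amplitude = 1, label = "blank", ...) {
  input_condition(c1_sigma = 0.3, c2_coherence = 0,
                  c3_amplitude = c3_amplitude, label = label, ...)
}

# Equicorrelated standard-normal draws via the shared-factor construction
# x_i = sqrt(rho) z_common + sqrt(1-rho) z_i, which realises an exact
# equicorrelation matrix without forming (or factoring) an n x n covariance.
# Returns an n x T matrix with unit marginal variance.
equicorr_normal <- function(n, T, rho) {
  z <- matrix(rnorm(n * T), n, T)
  if (rho <= 0) return(z)
  common <- rnorm(T)
  sqrt(rho) * matrix(common, n, T, byrow = TRUE) + sqrt(1 - rho) * z
}

#' Broadband input (asynchronous noise, input class 1)
#'
#' I.i.d. Gaussian draws with a small positive mean, approximating
#' Poisson-like spike arrivals: more arrivals correspond to a larger
#' standard deviation.  Independent across neurons and time in the default
#' model; `coherence` admits the across-neuron-correlation model variant.
#'
#' @param cfg a [trial_config()].
#' @param c1_sigma standard deviation of the draws.
#' @param c1_mean mean of the draws (excitatory offset).
#' @param coherence pairwise correlation across neurons (0 in the default
#'   model).
#' @param seed substream seed; defaults to one derived from
#'   `cfg$rng_seed`.
#' @return a neurons x time matrix.
#' @export
gen_broadband_input <- function(cfg, c1_sigma = 0.3, c1_mean = 0.25,
                                coherence = 0,
                                seed = substream_seed(cfg$rng_seed, "c1")) {
  if (c1_sigma < 0) stop("c1_sigma must be nonnegative")
  with_substream(seed, {
    z <- equicorr_normal(cfg$n_neurons, cfg$n_samples, coherence)
    c1_mean + c1_sigma * z
  })
}

#' Narrowband gamma input (input class 2)
#'
#' Equicorrelated Gaussian noise (sd `c2_sigma`, pairwise correlation
#' `c2_coherence`) band-pass filtered in the gamma band with a 10th-order
#' Butterworth applied forward and backward over zero-padded series.
#' Band-pass filtering is linear, so the across-neuron equicorrelation of
#' the generating noise is preserved in the filtered series.
#'
#' @inheritParams gen_broadband_input
#' @param c2_coherence pairwise correlation in `[0, 1]`.
#' @param c2_sigma standard deviation of the generating noise.
#' @param band band edges in Hz.  The default 50–60 Hz places the
#'   oscillation inside the conventional 30–80 Hz gamma range.
#' @return a neurons x time matrix.
#' @export
gen_gamma_input <- function(cfg, c2_coherence, c2_sigma = 0.2,
                            band = c(50, 60),
                            seed = substream_seed(cfg$rng_seed, "c2")) {
  if (c2_coherence < 0 || c2_coherence > 1)
    stop("c2_coherence must lie in [0, 1]")
  sos <- butter_bandpass_sos(10, band[1], band[2], cfg$fs)
  with_substream(seed, {
    z <- c2_sigma * equicorr_normal(cfg$n_neurons, cfg$n_samples, c2_coherence)
    filtfilt_padded(z, sos, cfg$fs, pad_s = 1)
  })
}

#' Inhibitory alpha input (input class 3)
#'
#' Equicorrelated Gaussian noise (unit sd, pairwise correlation 0.75)
#' band-pass filtered in the alpha band; the Hilbert envelope of the
#' filtered series is added to it, the result is negated — so that larger
#' alpha power drags the mean *down*, modelling pulsed inhibition — and
#' scaled by `c3_amplitude`.  Every sample is nonpositive because the
#' envelope bounds the signal magnitude.
#'
#' @inheritParams gen_broadband_input
#' @param c3_amplitude nonnegative output scale.
#' @param c3_coherence pairwise correlation of the generating noise.
#' @param band band edges in Hz.
#' @return a neurons x time matrix.
#' @export
gen_alpha_input <- function(cfg, c3_amplitude, c3_coherence = 0.75,
                            band = c(9, 12),
                            seed = substream_seed(cfg$rng_seed, "c3")) {
  if (c3_amplitude < 0) stop("c3_amplitude must be nonnegative")
  if (c3_amplitude == 0)
    return(matrix(0, cfg$n_neurons, cfg$n_samples))
  sos <- butter_bandpass_sos(10, band[1], band[2], cfg$fs)
  with_substream(seed, {
    z <- equicorr_normal(cfg$n_neurons, cfg$n_samples, c3_coherence)
    npad <- cfg$fs  # pad 1 s so both the filter and the envelope are clean
    zp <- cbind(matrix(0, cfg$n_neurons, npad), z,
                matrix(0, cfg$n_neurons, npad))
    filt <- t(sos_filtfilt_cols(sos, t(zp)))
    env <- hilbert_envelope(filt)
    keep <- npad + seq_len(cfg$n_samples)
    -c3_amplitude * (filt[, keep, drop = FALSE] + env[, keep, drop = FALSE])
  })
}

#' Build the full input set for one trial
#'
#' Generates the three input classes from independent, deterministically
#' derived RNG substreams and returns them together with their elementwise
#' sum, which is the total input delivered to each neuron.
#'
#' @param cfg a [trial_config()].
#' @param cond an [input_condition()].
#' @param trial_index index used to derive per-trial substreams.
#' @return an object of class `input_set`: list with matrices `c1`, `c2`,
#'   `c3`, `total` (all neurons x time) and the generating `cond`.
#' @export
build_input_set <- function(cfg, cond, trial_index = 1) {
  stopifnot(inherits(cfg, "trial_config"), inherits(cond, "input_condition"))
  sub <- function(comp) substream_seed(cfg$rng_seed, cond$label,
                                       trial_index, comp)
  c1 <- gen_broadband_input(cfg, cond$c1_sigma, cond$c1_mean,
                            coherence = cond$c1_coherence, seed = sub("c1"))
  c2 <- gen_gamma_input(cfg, cond$c2_coherence, c2_sigma = cond$c2_sigma,
                        seed = sub("c2"))
  c3 <- gen_alpha_input(cfg, cond$c3_amplitude,
                        c3_coherence = cond$c3_coherence, seed = sub("c3"))
  structure(list(c1 = c1, c2 = c2, c3 = c3, total = c1 + c2 + c3,
                 cond = cond, trial_index = trial_index),
            class = "input_set")
}
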