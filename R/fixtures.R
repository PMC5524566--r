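#' Scenario profiles for synthetic component tables
#'
#' Component ranges per stimulus class for the two site profiles.  Both
#' emulate an experiment with four grating stimuli, three noise patterns
#' and one blank: gratings elevate broadband and narrowband gamma, noise
#' patterns elevate broadband with essentially no gamma, and both stimulus
#' classes suppress alpha.  The `"V1"` profile makes broadband the
#' dominant varying component with only a narrow range of alpha changes;
#' the `"V2V3"` profile has weaker broadband modulation and a wide range
#' of alpha suppression that is strongest for the noise patterns.
#' All values are log10-power changes from the blank baseline.
#'
#' @param profile `"V1"` or `"V2V3"`.
#' @return nested list of `c(min, max)` ranges per class and component.
#' @export
scenario_profile <- function(profile = c("V1", "V2V3")) {
  profile <- match.arg(profile)
  if (profile == "V1") {
    list(grating = list(broadband = c(0.20, 0.55), gamma = c(0.05, 0.35),
                        alpha = c(-0.30, -0.15)),
         noise   = list(broadband = c(0.30, 0.60), gamma = c(0.00, 0.03),
                        alpha = c(-0.35, -0.20)),
         bold_noise_frac = 0.27)
  } else {
    list(grating = list(broadband = c(0.10, 0.30), gamma = c(0.05, 0.35),
                        alpha = c(-0.25, -0.10)),
         noise   = list(broadband = c(0.10, 0.35), gamma = c(0.00, 0.03),
                        alpha = c(-0.55, -0.35)),
         bold_noise_frac = 0.48)
  }
}

#' Generate a synthetic per-condition component table
#'
#' Draws broadband / gamma / alpha values for four gratings, three noise
#' patterns and one blank condition from the ranges of the chosen profile.
#' The blank row is exactly zero (components are changes from the blank's
#' own baseline).
#'
#' Each profile also carries `bold_noise_frac`, the response-side
#' measurement noise as a fraction of the across-condition BOLD signal sd;
#' the defaults correspond to split-half BOLD reliabilities of about 0.86
#' (primary-cortex-like sites) and 0.63 (extrastriate-like sites).
#'
#' @param profile `"V1"` or `"V2V3"` (see [scenario_profile()]), or a
#'   ranges list of the same shape for a custom scenario.
#' @param n_gratings,n_noise number of conditions per stimulus class.
#' @param seed RNG substream seed.
#' @return data frame `condition`, `class`, `broadband`, `gamma`, `alpha`.
#' @export
make_component_table <- function(profile = "V1", n_gratings = 4,
                                 n_noise = 3, seed = 1) {
  rng <- if (is.character(profile)) scenario_profile(profile) else profile
  draw <- function(cls, k) {
    r <- rng[[cls]]
    data.frame(condition = paste0(cls, seq_len(k)), class = cls,
               broadband = runif(k, r$broadband[1], r$broadband[2]),
               gamma = runif(k, r$gamma[1], r$gamma[2]),
               alpha = runif(k, r$alpha[1], r$alpha[2]))
  }
  out <- with_substream(seed, rbind(draw("grating", n_gratings),
                                    draw("noise", n_noise)))
  out <- rbind(out, data.frame(condition = "blank", class = "blank",
                               broadband = 0, gamma = 0, alpha = 0))
  rownames(out) <- NULL
  if (!is.null(rng$bold_noise_frac))
    attr(out, "bold_noise_frac") <- rng$bold_noise_frac
  out
}

#' Generate a per-condition BOLD table for a component table
#'
#' In `"model-consistent"` mode the BOLD values are produced by the full
#' forward model: the component table is inverted through the calibration
#' curves, the population is simulated, and the BOLD proxy is averaged over
#' the even/odd trial halves (plus optional Gaussian measurement noise).
#' In `"decoupled"` mode BOLD is drawn independently of the components — a
#' negative control for the regression analyses.
#'
#' @param components a [make_component_table()] result (or any table with
#'   `condition`, `broadband`, `gamma`, `alpha`).
#' @param mode `"model-consistent"` or `"decoupled"`.
#' @param curves,pcfg calibration curves and population configuration
#'   (required in model-consistent mode).
#' @param noise_sd sd of additive noise on each half's BOLD value
#'   (model-consistent), or of the independent draws (decoupled).
#' @param seed RNG substream seed.
#' @param n_repeats simulated trials per condition (model-consistent).
#' @return data frame `condition`, `bold`, `half`.
#' @export
make_bold_table <- function(components,
                            mode = c("model-consistent", "decoupled"),
                            curves = NULL, pcfg = NULL, noise_sd = 0,
                            seed = 1, n_repeats = 30) {
  mode <- match.arg(mode)
  if (mode == "decoupled") {
    sdd <- if (noise_sd > 0) noise_sd else 1
    return(with_substream(seed, do.call(rbind, lapply(1:2, function(h)
      data.frame(condition = components$condition,
                 bold = rnorm(nrow(components), 0, sdd), half = h)))))
  }
  if (is.null(curves) || is.null(pcfg))
    stop("model-consistent mode needs calibration curves and a pcfg")
  frac <- attr(components, "bold_noise_frac")
  site <- simulate_site(components, curves, pcfg, n_repeats = n_repeats,
                        seed = seed, n_boot = 0, bold_noise_sd = noise_sd,
                        bold_noise_frac = if (is.null(frac)) 0 else frac)
  site$bold_half
}
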