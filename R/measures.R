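#' Instrument measure configuration
#'
#' Gain constants and the power convention shared by the field-potential
#' and BOLD-proxy measures.  Power is the time-mean of squared samples by
#' default, so summary values do not depend on trial duration; `"sum"`
#' gives the raw sum of squares instead.
#'
#' @param alpha_scale electrode gain applied to the summed current before
#'   squaring (so the field-potential power scales with `alpha_scale^2`).
#' @param beta_scale neurovascular gain applied linearly to the summed
#'   per-neuron power.
#' @param power_convention `"mean"` or `"sum"`.
#' @return an object of class `measure_config`.
#' @export
measure_config <- function(alpha_scale = 1, beta_scale = 1,
                           power_convention = c("mean", "sum")) {
  stopifnot(alpha_scale > 0, beta_scale > 0)
  structure(list(alpha_scale = alpha_scale, beta_scale = beta_scale,
                 power_convention = match.arg(power_convention)),
            class = "measure_config")
}

pow_fun <- function(mc) {
  if (mc$power_convention == "mean") function(x) mean(x^2)
  else function(x) sum(x^2)
}

#' Field-potential time series: the summed population current
#'
#' @param pc `population_currents` (or a neurons x time matrix).
#' @param mc a [measure_config()].
#' @return numeric vector, one value per time sample.
#' @export
lfp_timeseries <- function(pc, mc = measure_config()) {
  mc$alpha_scale * colSums(current_matrix(pc))
}

#' Field-potential power: power of the sum
#'
#' The summed current is squared and averaged over the trial window (the
#' "power of the sum" order of operations).
#'
#' @inheritParams lfp_timeseries
#' @return scalar power.
#' @export
lfp_power <- function(pc, mc = measure_config()) {
  pow_fun(mc)(lfp_timeseries(pc, mc))
}

#' BOLD proxy: sum of the power
#'
#' Each neuron's current is squared and averaged over time, and these
#' per-neuron powers are summed (the "sum of the power" order of
#' operations).  The measure is blind to across-neuron synchrony: any
#' per-neuron permutation of time points, sign flip, or phase shift leaves
#' it unchanged.
#'
#' @inheritParams lfp_timeseries
#' @return scalar.
#' @export
bold_proxy <- function(pc, mc = measure_config()) {
  I <- current_matrix(pc)
  p <- pow_fun(mc)
  mc$beta_scale * sum(apply(I, 1, p))
}

#' Total cross-power between distinct neurons
#'
#' The sum over ordered pairs `i != j` of the time-averaged product of the
#' two neurons' currents, computed directly from the Gram matrix of the
#' population (not as a difference of the other two measures).  With unit
#' gains, `lfp_power = bold_proxy + cross_power` exactly.
#'
#' @inheritParams lfp_timeseries
#' @return scalar.
#' @export
cross_power <- function(pc, mc = measure_config()) {
  I <- current_matrix(pc)
  norm <- if (mc$power_convention == "mean") ncol(I) else 1
  G <- tcrossprod(I) / norm
  mc$alpha_scale^2 * (sum(G) - sum(diag(G)))
}

#' Equicorrelated Gaussian population specification
#'
#' The parameters of a population whose time series are multivariate
#' Gaussian with common mean `m`, common variance `sigma2`, and common
#' pairwise correlation `rho` — the setting in which both instrument
#' measures have closed forms.
#'
#' @param n number of neurons.
#' @param m common mean.
#' @param sigma2 common variance.
#' @param rho common pairwise correlation; must keep the equicorrelation
#'   matrix positive semidefinite, i.e. `rho >= -1/(n-1)`.
#' @return an object of class `gaussian_population_spec`.
#' @export
gaussian_population_spec <- function(n, m = 0, sigma2 = 1, rho = 0) {
  stopifnot(n >= 1, sigma2 >= 0)
  if (rho > 1 || (n > 1 && rho < -1 / (n - 1)))
    stop("rho outside [-1/(n-1), 1]: equicorrelation not positive semidefinite")
  structure(list(n = n, m = m, sigma2 = sigma2, rho = rho),
            class = "gaussian_population_spec")
}

#' Closed-form BOLD proxy for an equicorrelated Gaussian population
#'
#' Expected sum of per-neuron power: `beta * n * (m^2 + sigma2)`.  The
#' expression does not involve `rho` — the BOLD proxy is blind to
#' across-neuron correlation.
#'
#' @param spec a [gaussian_population_spec()].
#' @param beta linear gain on the summed power.
#' @return scalar.
#' @export
analytic_bold <- function(spec, beta = 1) {
  beta * spec$n * (spec$m^2 + spec$sigma2)
}

#' Closed-form field-potential power for an equicorrelated Gaussian
#' population
#'
#' Expected power of the summed series:
#' `alpha * (n*(m^2 + sigma2) + (n^2 - n)*(m^2 + sigma2*rho))`.
#' The first term is the summed per-neuron power, the second the expected
#' cross-power, which grows with both the mean offset and the correlation.
#' Here `alpha` is a linear gain on the power (the closed forms are stated
#' at the power level); the time-domain measures apply the electrode gain
#' to the voltage instead, i.e. quadratically — set both to 1 to compare
#' the two routes.
#'
#' @inheritParams analytic_bold
#' @param alpha linear gain on the power of the summed series.
#' @return scalar.
#' @export
analytic_lfp_power <- function(spec, alpha = 1) {
  alpha * (spec$n * (spec$m^2 + spec$sigma2) +
             (spec$n^2 - spec$n) * (spec$m^2 + spec$sigma2 * spec$rho))
}

#' Closed-form cross-power for an equicorrelated Gaussian population
#'
#' @inheritParams analytic_lfp_power
#' @return scalar `alpha * (n^2 - n) * (m^2 + sigma2 * rho)`.
#' @export
analytic_cross_power <- function(spec, alpha = 1) {
  alpha * (spec$n^2 - spec$n) * (spec$m^2 + spec$sigma2 * spec$rho)
}

#' Tabulate the closed forms over a parameter grid
#'
#' Evaluates the analytic BOLD proxy, field-potential power and cross-power
#' over the grid of (mean, standard deviation, correlation) values — a
#' numerical rendering of how the three quantities depend on the population
#' parameters.
#'
#' @param m_grid,sigma_grid,rho_grid numeric vectors (sigma values are
#'   standard deviations).
#' @param n number of neurons.
#' @param alpha,beta gains passed to the analytic forms.
#' @return data frame with columns `m`, `sigma`, `rho`, `bold`,
#'   `lfp_power`, `cross_power`.
#' @export
sweep_gaussian_surfaces <- function(m_grid = seq(0, 1, by = 0.25),
                                    sigma_grid = seq(0, 1, by = 0.25),
                                    rho_grid = seq(0, 1, by = 0.25),
                                    n = 5, alpha = 1, beta = 1) {
  grid <- expand.grid(m = m_grid, sigma = sigma_grid, rho = rho_grid,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    spec <- gaussian_population_spec(n, grid$m[i], grid$sigma[i]^2,
                                     grid$rho[i])
    data.frame(bold = analytic_bold(spec, beta),
               lfp_power = analytic_lfp_power(spec, alpha),
               cross_power = analytic_cross_power(spec, alpha))
  })
  cbind(grid, do.call(rbind, rows))
}
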