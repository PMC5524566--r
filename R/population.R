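#' Population configuration
#'
#' Couples a trial configuration with the dendritic membrane time constant
#' of the leaky integrator.
#'
#' @param tau membrane time constant in seconds (default 10 ms).
#' @param trial a [trial_config()].
#' @return an object of class `population_config`.
#' @export
population_config <- function(tau = 0.010, trial = trial_config()) {
  stopifnot(tau > 0, inherits(trial, "trial_config"))
  if (tau < 5 * trial$dt)
    warning("tau is less than 5*dt; the discretised integrator is coarse")
  structure(list(tau = tau, trial = trial), class = "population_config")
}

#' Leaky integration of summed inputs into dendritic currents
#'
#' Integrates `tau * dI/dt = -I + C` per neuron with `I(0) = 0` using the
#' exponential-Euler update `I[k] = I[k-1] * exp(-dt/tau) +
#' C[k] * (1 - exp(-dt/tau))`, which is exact for piecewise-constant input
#' and unconditionally stable.  The integrator acts as a first-order
#' low-pass filter with unit DC gain and cutoff near `1/(2*pi*tau)` Hz;
#' white-noise input therefore comes out with an approximately `1/f^2`
#' ("brown") spectrum above the cutoff.
#'
#' @param total_input neurons x time matrix of summed inputs (or an
#'   `input_set`, whose `total` is used).
#' @param tau membrane time constant in seconds.
#' @param dt sample interval in seconds.
#' @param condition_label,trial_index provenance carried into the result.
#' @return an object of class `population_currents`: list with `currents`
#'   (neurons x time), `dt`, `condition_label`, `trial_index`.
#' @export
leaky_integrate <- function(total_input, tau, dt,
                            condition_label = NA_character_,
                            trial_index = NA_integer_) {
  if (inherits(total_input, "input_set")) {
    if (is.na(condition_label)) condition_label <- total_input$cond$label
    if (is.na(trial_index)) trial_index <- total_input$trial_index
    total_input <- total_input$total
  }
  stopifnot(tau > 0, dt > 0)
  if (!all(is.finite(total_input))) stop("non-finite values in input")
  decay <- exp(-dt / tau)
  I <- t(leaky_integrate_cols(t(total_input), decay))
  structure(list(currents = I, dt = dt, condition_label = condition_label,
                 trial_index = trial_index),
            class = "population_currents")
}

# Accept either a population_currents object or a bare matrix.
current_matrix <- function(pc) {
  if (inherits(pc, "population_currents")) pc$currents
  else as.matrix(pc)
}

#' Simulate all trials of one condition
#'
#' Runs `n_repeats` independent trials of [build_input_set()] followed by
#' [leaky_integrate()].  Trial substreams are derived from the master seed,
#' the condition label and the trial index, so a condition's trials do not
#' depend on which other conditions are simulated alongside it.
#'
#' @param pcfg a [population_config()].
#' @param cond an [input_condition()].
#' @param n_repeats number of trials.
#' @param seed master seed; overrides the seed in `pcfg$trial` if given.
#' @return list of `population_currents`, one per trial.
#' @export
simulate_condition <- function(pcfg, cond, n_repeats = 30, seed = NULL) {
  stopifnot(n_repeats >= 1)
  cfg <- pcfg$trial
  if (!is.null(seed)) cfg$rng_seed <- seed
  lapply(seq_len(n_repeats), function(k) {
    leaky_integrate(build_input_set(cfg, cond, trial_index = k),
                    tau = pcfg$tau, dt = cfg$dt)
  })
}

#' Simulate a multi-condition experiment
#'
#' @param pcfg a [population_config()].
#' @param conditions list of [input_condition()]s with unique labels.
#' @param n_repeats trials per condition.
#' @param seed master seed for the whole experiment.
#' @return an object of class `experiment`: list with `trials` (a named
#'   list, one entry of `n_repeats` `population_currents` per condition),
#'   `conditions`, `n_repeats`, `seed` and the `pcfg` used.
#' @export
simulate_experiment <- function(pcfg, conditions, n_repeats = 30, seed = 1) {
  labels <- vapply(conditions, function(x) x$label, character(1))
  if (anyDuplicated(labels)) stop("duplicate condition labels")
  trials <- lapply(conditions, function(cond)
    simulate_condition(pcfg, cond, n_repeats, seed = seed))
  names(trials) <- labels
  structure(list(trials = trials, conditions = setNames(conditions, labels),
                 n_repeats = n_repeats, seed = seed, pcfg = pcfg),
            class = "experiment")
}

#' @export
print.experiment <- function(x, ...) {
  cat("Simulated experiment:", length(x$conditions), "conditions x",
      x$n_repeats, "repeats (", x$pcfg$trial$n_neurons, "neurons,",
      x$pcfg$trial$duration, "s trials, seed", x$seed, ")\n")
  invisible(x)
}
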