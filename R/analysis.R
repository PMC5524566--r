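#' Coefficient of determination for (possibly cross-validated) predictions
#'
#' `R^2 = 1 - SS_residuals / SS_data`.  Because predictions may come from
#' a model fitted on held-out data, the residual sum of squares can exceed
#' the data variance and `R^2` spans `(-Inf, 1]`; for unrelated
#' equal-variance data and predictions it tends to -1.  With
#' `normalize = TRUE`, data and predictions are each mean-subtracted and
#' divided by their vector length first — the convention for predictions
#' in arbitrary units.
#'
#' @param data observed values.
#' @param pred predicted values.
#' @param normalize normalise both vectors before comparing.
#' @return scalar in `(-Inf, 1]`.
#' @export
r_squared <- function(data, pred, normalize = FALSE) {
  stopifnot(length(data) == length(pred))
  if (normalize) {
    nz <- function(v) {
      v <- v - mean(v)
      len <- sqrt(sum(v^2))
      if (len > 0) v / len else v
    }
    data <- nz(data); pred <- nz(pred)
  }
  ss_res <- sum((data - pred)^2)
  ss_dat <- sum((data - mean(data))^2)
  1 - ss_res / ss_dat
}

# Solve bold ~ components by OLS for the given predictors; returns lm fit.
fit_half <- function(comp, bold, predictors) {
  d <- merge(comp, bold, by = "condition")
  form <- stats::as.formula(paste("bold ~", paste(predictors, collapse = "+")))
  stats::lm(form, data = d)
}

#' Cross-validated regression of BOLD on field-potential components
#'
#' Fits `bold ~ components` by ordinary least squares on one half of the
#' replicates (component half 1 with BOLD half 1), predicts the held-out
#' half, repeats with the halves swapped, and computes a single coefficient
#' of determination over the concatenated held-out predictions.  Reported
#' betas come from a fit to the half-averaged data (cross-validation is
#' used only for `r2_cv`).
#'
#' @param components data frame with columns `condition`, `half` (1/2) and
#'   the component columns.
#' @param bold data frame with columns `condition`, `half`, `bold`.
#' @param predictors character subset of
#'   `c("broadband", "gamma", "alpha")`.
#' @param baseline label of the blank condition; its absence biases the
#'   intercept and triggers a warning.
#' @return list of class `lfpbold_regression`: `betas` (named),
#'   `intercept`, `r2_cv`, `predictors`, `n_conditions`.
#' @export
fit_cv_regression <- function(components, bold,
                              predictors = c("broadband", "gamma", "alpha"),
                              baseline = "blank") {
  stopifnot(all(predictors %in% c("broadband", "gamma", "alpha")),
            length(predictors) >= 1)
  if (!baseline %in% components$condition)
    warning("no '", baseline, "' condition: mean-response sign may be lost")
  conds <- intersect(unique(components$condition), unique(bold$condition))
  if (length(conds) < length(predictors) + 2)
    stop("need at least ", length(predictors) + 2,
         " shared conditions for ", length(predictors), " predictor(s)")
  ch <- split(components, components$half)
  bh <- split(bold, bold$half)
  if (length(ch) != 2 || length(bh) != 2)
    stop("components and bold must both have halves 1 and 2")
  preds <- obs <- NULL
  for (tr in 1:2) {
    te <- 3 - tr
    fit <- fit_half(ch[[tr]], bh[[tr]], predictors)
    test <- merge(ch[[te]], bh[[te]], by = "condition")
    preds <- c(preds, predict(fit, newdata = test))
    obs <- c(obs, test$bold)
  }
  r2 <- r_squared(obs, preds)
  # interpretation fit on half-averaged tables
  avg <- function(d, vcols) stats::aggregate(d[vcols],
                                             by = list(condition = d$condition),
                                             FUN = mean)
  full <- fit_half(avg(components, setdiff(names(components),
                                           c("condition", "half"))),
                   avg(bold, "bold"), predictors)
  cf <- coef(full)
  structure(list(betas = cf[predictors], intercept = cf[["(Intercept)"]],
                 r2_cv = r2, predictors = predictors,
                 n_conditions = length(conds)),
            class = "lfpbold_regression")
}

#' @export
print.lfpbold_regression <- function(x, ...) {
  cat("BOLD ~", paste(x$predictors, collapse = " + "),
      " | cross-validated R^2 =", round(x$r2_cv, 3), "\n")
  print(round(c(x$betas, intercept = x$intercept), 4))
  invisible(x)
}

#' The seven component regression models (plus a shuffled noise floor)
#'
#' Runs [fit_cv_regression()] for every nonempty subset of the three
#' components, and for each model a label-shuffled control in which the
#' BOLD values in the training half are randomly reassigned across
#' conditions — the noise floor for the cross-validated `R^2`.
#'
#' @inheritParams fit_cv_regression
#' @param n_shuffle number of shuffles averaged into the noise floor.
#' @param seed RNG substream seed for the shuffles.
#' @return data frame with one row per model: `model`, `r2_cv`,
#'   `r2_shuffled`, `beta_broadband`, `beta_gamma`, `beta_alpha` (NA for
#'   predictors not in the model).
#' @export
model_menu <- function(components, bold, baseline = "blank",
                       n_shuffle = 20, seed = 1) {
  sets <- list("broadband", "gamma", "alpha",
               c("broadband", "gamma"), c("broadband", "alpha"),
               c("gamma", "alpha"), c("broadband", "gamma", "alpha"))
  shuffle_bold <- function(b, s) with_substream(s, {
    do.call(rbind, lapply(split(b, b$half), function(d) {
      d$bold <- d$bold[sample.int(nrow(d))]
      d
    }))
  })
  rows <- lapply(sets, function(ps) {
    fit <- fit_cv_regression(components, bold, ps, baseline)
    shuf <- vapply(seq_len(n_shuffle), function(i) {
      fit_cv_regression(components,
                        shuffle_bold(bold, substream_seed(seed, "shuf", i)),
                        ps, baseline)$r2_cv
    }, numeric(1))
    b <- setNames(rep(NA_real_, 3), c("broadband", "gamma", "alpha"))
    b[ps] <- fit$betas
    data.frame(model = paste(ps, collapse = "+"), r2_cv = fit$r2_cv,
               r2_shuffled = mean(shuf),
               beta_broadband = b[["broadband"]], beta_gamma = b[["gamma"]],
               beta_alpha = b[["alpha"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bootstrap sign test on regression coefficients across sites
#'
#' Resamples sites with replacement, recomputes the median beta per
#' predictor, and flags a predictor as a significantly positive (negative)
#' contributor when fewer than 2.5% of resampled medians fall at or below
#' (at or above) zero.
#'
#' @param betas matrix or data frame, sites x predictors.
#' @param n_boot number of resamples.
#' @param seed RNG substream seed.
#' @return data frame: `predictor`, `median`, `frac_le0`, `frac_ge0`,
#'   `significance` (`"positive"`, `"negative"` or `"ns"`).
#' @export
bootstrap_beta_test <- function(betas, n_boot = 10000, seed = 1) {
  betas <- as.matrix(betas)
  n <- nrow(betas)
  meds <- with_substream(seed, {
    vapply(seq_len(n_boot), function(i) {
      apply(betas[sample.int(n, replace = TRUE), , drop = FALSE], 2, median)
    }, numeric(ncol(betas)))
  })
  dim(meds) <- c(ncol(betas), n_boot)   # predictors x resamples, always
  out <- data.frame(predictor = colnames(betas),
                    median = apply(betas, 2, median),
                    frac_le0 = rowMeans(meds <= 0),
                    frac_ge0 = rowMeans(meds >= 0))
  out$significance <- ifelse(out$frac_le0 < 0.025, "positive",
                       ifelse(out$frac_ge0 < 0.025, "negative", "ns"))
  rownames(out) <- NULL
  out
}

#' Correlation between BOLD and spectral power at every frequency
#'
#' For each frequency bin, the Pearson correlation across (non-baseline)
#' conditions between the log-power change from baseline and the BOLD
#' change from baseline.
#'
#' @param spectra long data frame `condition`, `freq`, `power` of
#'   trial-averaged spectra (see [experiment_spectra()]), including the
#'   baseline condition.
#' @param bold data frame `condition`, `bold` (halves, if present, are
#'   averaged).
#' @param baseline label of the baseline condition.
#' @param freq_range frequencies retained, Hz.
#' @return data frame `freq`, `correlation`; the correlation is `NA` with
#'   attribute `constant_bold = TRUE` when BOLD does not vary.
#' @export
per_frequency_correlation <- function(spectra, bold, baseline = "blank",
                                      freq_range = c(1, 200)) {
  if ("half" %in% names(bold))
    bold <- stats::aggregate(bold["bold"],
                             by = list(condition = bold$condition), FUN = mean)
  if (!baseline %in% spectra$condition || !baseline %in% bold$condition)
    stop("baseline condition missing from spectra or bold table")
  sp <- spectra[spectra$freq >= freq_range[1] & spectra$freq <= freq_range[2], ]
  base_sp <- sp[sp$condition == baseline, ]
  sp <- sp[sp$condition != baseline, ]
  dbold <- bold$bold - bold$bold[bold$condition == baseline]
  names(dbold) <- bold$condition
  dbold <- dbold[names(dbold) != baseline]
  constant <- isTRUE(all.equal(var(dbold), 0)) || var(dbold) == 0
  freqs <- sort(unique(sp$freq))
  cors <- vapply(freqs, function(f) {
    d <- sp[sp$freq == f, ]
    dp <- log10(d$power) - log10(base_sp$power[base_sp$freq == f])
    if (constant || var(dp) == 0) return(NA_real_)
    cor(dp, dbold[as.character(d$condition)])
  }, numeric(1))
  structure(data.frame(freq = freqs, correlation = cors),
            constant_bold = constant)
}
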