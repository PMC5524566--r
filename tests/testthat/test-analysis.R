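test_that("coefficient of determination has the documented limit behaviour", {
  y <- c(1, 2, 3, 4.5)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, y + 10, normalize = TRUE), 1)  # offset removed
  expect_lt(r_squared(y, y + 10), 0)
  # unrelated equal-variance normalized vectors tend to R^2 = -1 at n = 8
  set.seed(1)
  r2s <- replicate(10000, {
    r_squared(rnorm(8), rnorm(8), normalize = TRUE)
  })
  expect_lt(abs(mean(r2s) + 1), 0.05)
})

# Split-half tables with a known generative rule: condition-level truth is
# drawn once, each half observes it with independent measurement noise.
make_tables <- function(n_cond = 8, beta_bb = 2, noise = 0.01, seed = 2) {
  set.seed(seed)
  truth <- data.frame(condition = c(paste0("s", 1:(n_cond - 1)), "blank"),
                      broadband = c(runif(n_cond - 1, 0, 0.6), 0),
                      gamma = c(runif(n_cond - 1, 0, 0.4), 0),
                      alpha = c(runif(n_cond - 1, -0.5, 0), 0))
  comps <- do.call(rbind, lapply(1:2, function(h) {
    out <- truth
    for (v in c("broadband", "gamma", "alpha"))
      out[[v]] <- out[[v]] + rnorm(n_cond, 0, noise)
    out$half <- h
    out
  }))
  bold <- do.call(rbind, lapply(1:2, function(h) {
    data.frame(condition = truth$condition,
               bold = beta_bb * truth$broadband + 1 +
                      rnorm(n_cond, 0, noise), half = h)
  }))
  list(components = comps, bold = bold)
}

test_that("cross-validated regression recovers a known generating model", {
  tb <- make_tables()
  fit <- fit_cv_regression(tb$components, tb$bold, "broadband")
  expect_gt(fit$r2_cv, 0.95)
  expect_lt(abs(fit$betas[["broadband"]] - 2), 0.2)
  # unrelated BOLD: negative cross-validated R^2 on average (the fitted
  # betas shrink toward zero, so the penalty is milder than the -1 limit
  # of the equal-variance normalized-vector case)
  set.seed(9)
  r2s <- replicate(40, {
    tb2 <- make_tables(seed = sample.int(1e6, 1))
    tb2$bold$bold <- rnorm(nrow(tb2$bold))
    fit_cv_regression(tb2$components, tb2$bold, "broadband")$r2_cv
  })
  expect_lt(mean(r2s), -0.1)
  # an irrelevant predictor does not help under cross-validation (average)
  set.seed(10)
  diffs <- replicate(60, {
    tb3 <- make_tables(noise = 0.05, seed = sample.int(1e6, 1))
    fit_cv_regression(tb3$components, tb3$bold, c("broadband", "gamma"))$r2_cv -
      fit_cv_regression(tb3$components, tb3$bold, "broadband")$r2_cv
  })
  expect_lte(mean(diffs), 0.01)
  # guard rails
  tb4 <- make_tables()
  tb4$components <- tb4$components[tb4$components$condition != "blank", ]
  tb4$bold <- tb4$bold[tb4$bold$condition != "blank", ]
  expect_warning(fit_cv_regression(tb4$components, tb4$bold, "broadband"),
                 "blank")
  few <- lapply(tb4, function(d) d[d$condition %in% c("s1", "s2", "s3"), ])
  suppressWarnings(
    expect_error(fit_cv_regression(few$components, few$bold,
                                   c("broadband", "gamma", "alpha")),
                 "at least"))
})

test_that("the model menu returns all seven models with a shuffled floor", {
  tb <- make_tables(noise = 0.02)
  mm <- model_menu(tb$components, tb$bold, n_shuffle = 10, seed = 4)
  expect_equal(nrow(mm), 7)
  expect_setequal(mm$model,
    c("broadband", "gamma", "alpha", "broadband+gamma", "broadband+alpha",
      "gamma+alpha", "broadband+gamma+alpha"))
  bb_row <- mm[mm$model == "broadband", ]
  expect_gt(bb_row$r2_cv, bb_row$r2_shuffled)    # informative data beat noise
  expect_true(is.na(bb_row$beta_gamma))
  expect_false(is.na(mm$beta_gamma[mm$model == "broadband+gamma+alpha"]))
})

test_that("bootstrap sign test flags coherent betas and spares symmetric ones", {
  pos <- matrix(1.2, 6, 1, dimnames = list(NULL, "broadband"))
  res <- bootstrap_beta_test(pos, n_boot = 500, seed = 1)
  expect_equal(res$significance, "positive")
  sym <- matrix(c(-2, -1, -0.5, 0.5, 1, 2), 6, 1,
                dimnames = list(NULL, "alpha"))
  expect_equal(bootstrap_beta_test(sym, n_boot = 500, seed = 1)$significance,
               "ns")
  # power: betas ~ N(0.5, 0.1) across 9 sites detected in >= 95% of draws
  set.seed(5)
  hits <- mean(replicate(60, {
    b <- matrix(rnorm(9, 0.5, 0.1), 9, 1, dimnames = list(NULL, "bb"))
    bootstrap_beta_test(b, n_boot = 300, seed = 7)$significance == "positive"
  }))
  expect_gte(hits, 0.95)
})

test_that("per-frequency correlation relates band power changes to BOLD", {
  set.seed(12)
  conds <- c("a", "b", "c", "d", "blank")
  freq <- 1:200
  base_pow <- 10^(-2 * log10(freq))
  sp <- do.call(rbind, lapply(conds, function(cl) {
    lift <- if (cl == "blank") 0 else runif(1, 0, 0.5)
    data.frame(condition = cl, freq = freq,
               power = base_pow * 10^(lift * (freq >= 90 & freq <= 110)))
  }))
  # BOLD cloned from the 100 Hz log-power change
  p100 <- sapply(conds, function(cl)
    log10(sp$power[sp$condition == cl & sp$freq == 100] / base_pow[100]))
  bold <- data.frame(condition = conds, bold = p100)
  pf <- per_frequency_correlation(sp, bold)
  expect_equal(pf$correlation[pf$freq == 100], 1, tolerance = 1e-9)
  expect_true(is.na(pf$correlation[pf$freq == 10]))  # no power variation there
  # constant BOLD: undefined correlation, flagged
  bold0 <- data.frame(condition = conds, bold = 1)
  pf0 <- per_frequency_correlation(sp, bold0)
  expect_true(attr(pf0, "constant_bold"))
  expect_true(all(is.na(pf0$correlation)))
  # condition order does not matter
  pf2 <- per_frequency_correlation(sp[order(sp$condition, decreasing = TRUE), ],
                                   bold[rev(seq_len(nrow(bold))), ])
  expect_equal(pf$correlation[pf$freq == 100], pf2$correlation[pf2$freq == 100])
})
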