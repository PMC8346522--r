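# LASSO-Cox risk model, threshold training, KM/log-rank, Cox tables,
# rank-sum comparison and Odx categories.

fit_toy_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      coh <- generate_survival_cohort(cohort_spec(n_patients = 78,
                                                  seed = 81))
      cache <<- list(coh = coh, fit = cfod_cox(coh$features, coh$survival))
    }
    cache
  }
})

test_that("the 10% feature budget retains round(0.1 n) features", {
  tm <- fit_toy_model()
  expect_identical(tm$fit$k_requested, 8)   # round(0.10 * 78)
  expect_identical(length(tm$fit$selected), 8L)
  expect_identical(length(coef(tm$fit)), 8L)
  # budget rounding at other sizes
  coh <- generate_survival_cohort(cohort_spec(n_patients = 40, seed = 82))
  fit40 <- cfod_cox(coh$features, coh$survival)
  expect_identical(length(fit40$selected), 4L)
})

test_that("a dominant predictor is selected under a tight budget", {
  beta <- setNames(rep(0, 18), cfod_feature_names())
  beta["CFOD_whole_150"] <- -1
  hits <- vapply(1:20, function(s) {
    coh <- generate_survival_cohort(
      cohort_spec(n_patients = 500, beta = beta, seed = 200 + s))
    fit <- suppressWarnings(cfod_cox(coh$features, coh$survival, k = 2))
    "CFOD_whole_150" %in% fit$selected
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("null cohorts give coefficients shrunk toward zero", {
  beta0 <- setNames(rep(0, 18), cfod_feature_names())
  mean_abs <- vapply(1:30, function(s) {
    coh <- generate_survival_cohort(
      cohort_spec(n_patients = 100, beta = beta0, seed = 300 + s))
    fit <- suppressWarnings(cfod_cox(coh$features, coh$survival))
    mean(abs(coef(fit)))
  }, 0)
  expect_lt(mean(mean_abs), 0.1)
})

test_that("risk scores are the stated linear functional", {
  tm <- fit_toy_model()
  fit <- tm$fit
  # feature vector at the stored means standardizes to zero -> score 0
  base <- as.data.frame(as.list(fit$impute_means))
  names(base) <- names(fit$impute_means)
  expect_equal(unname(predict(fit, base)), 0, tolerance = 1e-12)
  # moving one selected feature by +1 sd changes the score by its beta
  for (f in fit$selected[1:3]) {
    shifted <- base
    shifted[[f]] <- shifted[[f]] + fit$scale[f]
    expect_equal(unname(predict(fit, shifted)), unname(fit$beta[f]),
                 tolerance = 1e-12)
  }
  # additivity on the standardized scale
  f1 <- fit$selected[1]; f2 <- fit$selected[2]
  s1 <- base; s1[[f1]] <- s1[[f1]] + fit$scale[f1]
  s2 <- base; s2[[f2]] <- s2[[f2]] + fit$scale[f2]
  s12 <- base; s12[[f1]] <- s1[[f1]]; s12[[f2]] <- s2[[f2]]
  expect_equal(predict(fit, s12), predict(fit, s1) + predict(fit, s2),
               tolerance = 1e-12)
  # unknown features rejected
  expect_error(predict(fit, base[, -1, drop = FALSE]), "lacks")
})

test_that("threshold training scans percentiles for the best log-rank split", {
  set.seed(83)
  n <- 30
  scores <- rnorm(n)
  time <- rexp(n, 1 / 500) * exp(-scores)
  event <- rbinom(n, 1, 0.8)
  got <- select_risk_threshold(scores, time, event)
  # brute-force oracle over the same candidate set
  cand <- unique(quantile(scores, seq(0.10, 0.90, 0.01), names = FALSE))
  ps <- vapply(cand, function(t) {
    hi <- scores > t
    if (!any(hi) || all(hi)) return(NA_real_)
    logrank_bruteforce(time, event, hi)$p
  }, 0)
  expect_equal(got$p, min(ps, na.rm = TRUE), tolerance = 1e-9)
  expect_equal(min(abs(got$threshold - cand[which(ps <= min(ps, na.rm = TRUE)
                                                  + 1e-15)])), 0)

  # two separated clusters with separated outcomes: threshold in the gap
  sc <- c(rnorm(15, -4, 0.2), rnorm(15, 4, 0.2))
  tt <- c(rexp(15, 1 / 2000), rexp(15, 1 / 100))
  thr <- select_risk_threshold(sc, tt, rep(1, 30))
  expect_gt(thr$threshold, -3)
  expect_lt(thr$threshold, 3)

  expect_error(select_risk_threshold(rep(1, 10), 1:10, rep(1, 10)),
               "identical")
})

test_that("KM and log-rank match the from-scratch counting oracle", {
  set.seed(84)
  n <- 50
  time <- round(rexp(n, 1 / 300)) + 1
  event <- rbinom(n, 1, 0.7)
  grp <- factor(ifelse(rbinom(n, 1, 0.5) == 1, "high", "low"),
                levels = c("low", "high"))
  res <- km_logrank(grp, time, event)
  oracle <- logrank_bruteforce(time, event, grp)
  expect_lt(abs(res$logrank_p - oracle$p), 1e-10)
  # product-limit estimates per group
  sf <- summary(res$km)
  for (g in c("low", "high")) {
    km_o <- km_bruteforce(time[grp == g], event[grp == g])
    sel <- sf$strata == paste0("group=", g) & sf$n.event > 0
    expect_equal(sf$surv[sel], km_o$surv[km_o$time %in% sf$time[sel]],
                 tolerance = 1e-10)
  }
  # survival starts at 1
  expect_true(all(summary(res$km, times = 0)$surv == 1))
})

test_that("identical groups give a null stratification", {
  time <- c(100, 200, 300, 400, 150, 250)
  event <- c(1, 0, 1, 1, 0, 1)
  grp <- factor(rep(c("low", "high"), each = 6), levels = c("low", "high"))
  res <- km_logrank(grp, rep(time, 2), rep(event, 2))
  expect_equal(res$hr, 1, tolerance = 1e-8)
  expect_gt(res$logrank_p, 0.99)
})

test_that("a group without events is flagged as unstable", {
  grp <- factor(rep(c("low", "high"), each = 10), levels = c("low", "high"))
  time <- c(rexp(10, 1 / 100) + 1, rep(500, 10))
  event <- c(rep(1, 10), rep(0, 10))
  w <- capture_warnings(res <- km_logrank(grp, time, event))
  expect_true(any(grepl("zero events", w)))
  expect_true(res$diverged)
})

test_that("Cox tables recover known hazard ratios and apply the
           missingness rule", {
  set.seed(85)
  n <- 1000
  xbin <- rbinom(n, 1, 0.5)
  time <- rexp(n, 1 / 1000 * exp(log(2) * xbin))
  surv <- data.frame(time_days = time, event = rep(1, n))
  tab <- cox_fit(surv, data.frame(arm = xbin), mode = "univariate")
  expect_gt(tab$hr, 1.7)
  expect_lt(tab$hr, 2.35)

  # identical arms -> HR 1
  tab0 <- cox_fit(data.frame(time_days = rep(time[1:100], 2),
                             event = 1),
                  data.frame(arm = rep(0:1, each = 100)),
                  mode = "univariate")
  expect_equal(tab0$hr, 1, tolerance = 1e-6)

  # covariate with 50% missingness is excluded from the multivariate fit
  covs <- data.frame(arm = xbin,
                     sparse = ifelse(runif(n) < 0.5, NA, rnorm(n)))
  expect_message(tabm <- cox_fit(surv, covs, mode = "multivariate"),
                 "sparse")
  expect_false(any(grepl("sparse", tabm$term)))
})

test_that("short- vs long-DFS comparison uses the five-year rule", {
  vals <- c(1, 2, 3, 10, 11, 12, 5)
  time <- c(400, 500, 600, 2000, 2200, 1826.25, 1000)
  event <- c(1, 1, 1, 0, 1, 0, 0)   # last patient censored early: excluded
  res <- compare_feature_by_dfs_group(vals, time, event)
  expect_identical(res$n_short, 3L)
  expect_identical(res$n_long, 3L)
  expect_identical(res$direction, "lower in short DFS")

  # power at a 1-sd shift
  set.seed(86)
  sig <- vapply(1:60, function(s) {
    v <- c(rnorm(50, 0), rnorm(50, 1))
    tt <- c(rexp(50, 1 / 800) + 1, rep(2000, 50))
    ev <- c(rep(1, 50), rep(0, 50))
    tt[1:50] <- pmin(tt[1:50], 1800)
    compare_feature_by_dfs_group(v, tt, ev)$p < 0.05
  }, TRUE)
  expect_gte(mean(sig), 0.8)

  expect_error(compare_feature_by_dfs_group(1:3, c(10, 20, 30), c(1, 1, 1)),
               "non-empty")
})

test_that("Odx categorization follows the TAILORx cuts", {
  expect_identical(as.character(odx_category(c(0, 10, 11, 25, 26, 40))),
                   c("low", "low", "intermediate", "intermediate",
                     "high", "high"))
  expect_error(odx_category(-1), "negative")
})
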