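# LASSO-regularized Cox model on the 18 CFOD-TS features, with a fixed
# feature budget (about 10% of the training cohort size), a trained
# dichotomization threshold, and the downstream reporting tools
# (Kaplan-Meier / log-rank, uni/multivariate Cox, rank-sum comparison,
# Oncotype DX categorization).

FIVE_YEARS_DAYS <- 1826.25

#' Fit the CFOD-TS risk model
#'
#' Fits a LASSO-penalized Cox proportional hazards model of disease-free
#' survival on the (internally z-scored) patient features, with the feature
#' budget fixed at \code{k = round(k_frac * n)} retained features rather
#' than a cross-validated penalty: the penalty chosen is the largest value
#' on the path yielding exactly \code{k} nonzero coefficients. The
#' continuous risk score is the linear combination of the selected
#' standardized features weighted by their coefficients, and the
#' dichotomization threshold is trained by scanning score percentiles for
#' the most significant log-rank split (see
#' \code{\link{select_risk_threshold}}).
#'
#' Missing feature slots are imputed by the training-set column mean; the
#' imputation means, standardization parameters and threshold are stored so
#' that validation applies the identical transform with no refitting.
#'
#' @param features data.frame with an \code{id} column and one column per
#'   feature (default: the 18 columns of \code{\link{cfod_feature_names}}).
#' @param survival data.frame with columns \code{id}, \code{time_days},
#'   \code{event}.
#' @param k number of features to retain; overrides \code{k_frac}.
#' @param k_frac feature budget as a fraction of the cohort size
#'   (default 0.10).
#' @param feature_cols names of the feature columns; defaults to every
#'   non-\code{id} numeric column.
#' @param nlambda,lambda.min.ratio penalty-path resolution passed to
#'   \code{glmnet}.
#' @return An object of class \code{cfod_cox}: selected feature names,
#'   coefficients on the standardized scale, standardization and imputation
#'   parameters, the trained threshold and training log-rank p.
#' @seealso \code{\link{predict.cfod_cox}}, \code{\link{km_logrank}}
#' @export
cfod_cox <- function(features, survival, k = NULL, k_frac = 0.1,
                     feature_cols = NULL, nlambda = 200,
                     lambda.min.ratio = 1e-4) {
  tab <- merge(features, survival, by = "id")
  n <- nrow(tab)
  if (n < 20) stop("need at least 20 patients to fit", call. = FALSE)
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(names(features), "id")
    feature_cols <- feature_cols[vapply(features[feature_cols], is.numeric,
                                        TRUE)]
  }
  if (is.null(k)) k <- max(1L, round(k_frac * n))
  if (k >= n) stop("feature budget k must be smaller than n", call. = FALSE)
  k <- min(k, length(feature_cols))

  x <- as.matrix(tab[, feature_cols, drop = FALSE])
  impute_means <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- impute_means[j]
  center <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  z <- sweep(sweep(x, 2, center), 2, scl, "/")

  y <- survival::Surv(tab$time_days, tab$event)
  fit <- glmnet::glmnet(z, y, family = "cox", standardize = FALSE,
                        nlambda = nlambda,
                        lambda.min.ratio = lambda.min.ratio)
  # largest penalty with exactly k nonzero coefficients; when the path grid
  # jumps over k, refine the grid between the bracketing penalties
  find_exact <- function(f) {
    hit <- which(f$df == k)
    if (length(hit)) f$lambda[hit[1]] else NA_real_
  }
  lambda <- find_exact(fit)
  path <- fit
  tries <- 0L
  while (is.na(lambda) && tries < 4L) {
    tries <- tries + 1L
    below <- which(path$df < k)
    above <- which(path$df > k)
    if (!length(below) || !length(above)) break
    lam_hi <- path$lambda[max(below)]          # last grid point under budget
    lam_lo <- path$lambda[min(above)]
    grid <- exp(seq(log(lam_hi), log(lam_lo), length.out = 60))
    path <- glmnet::glmnet(z, y, family = "cox", standardize = FALSE,
                           lambda = grid)
    lambda <- find_exact(path)
  }
  if (is.na(lambda)) {
    below <- which(path$df < k)
    if (!length(below)) below <- which.min(path$df)
    got <- max(path$df[below])
    warning(sprintf(
      "no penalty retains exactly %d features; using %d (nearest below)",
      k, got))
    lambda <- path$lambda[below[path$df[below] == got][1]]
  }
  beta_all <- as.numeric(coef(path, s = lambda, exact = FALSE))
  names(beta_all) <- feature_cols
  selected <- feature_cols[beta_all != 0]
  beta <- beta_all[selected]

  scores <- drop(z[, selected, drop = FALSE] %*% beta)
  thr <- select_risk_threshold(scores, tab$time_days, tab$event)

  structure(list(
    selected = selected, beta = beta, k = length(selected),
    k_requested = k, lambda = lambda,
    center = center[selected], scale = scl[selected],
    impute_means = impute_means, feature_cols = feature_cols,
    threshold = thr$threshold, train_logrank_p = thr$p,
    threshold_note = paste(
      "threshold optimized on the training scan;",
      "its training log-rank p is anti-conservative"),
    n_train = n, train_scores = scores,
    train_survival = tab[, c("id", "time_days", "event")]),
    class = "cfod_cox")
}

#' @export
print.cfod_cox <- function(x, ...) {
  cat(sprintf(
    "CFOD-TS LASSO-Cox risk model: %d of %d features (n = %d)\n",
    x$k, length(x$feature_cols), x$n_train))
  print(round(x$beta, 4))
  cat(sprintf("risk threshold %.4f (training log-rank p = %.3g)\n",
              x$threshold, x$train_logrank_p))
  invisible(x)
}

#' @export
summary.cfod_cox <- function(object, ...) {
  cat("CFOD-TS LASSO-Cox risk model\n")
  cat(sprintf("  training cohort: n = %d, feature budget k = %d\n",
              object$n_train, object$k_requested))
  cat(sprintf("  penalty lambda = %.5g, retained %d features\n",
              object$lambda, object$k))
  tab <- data.frame(feature = object$selected,
                    beta = round(object$beta, 4),
                    center = round(object$center, 3),
                    scale = round(object$scale, 3), row.names = NULL)
  print(tab)
  cat(sprintf("  dichotomization threshold = %.4f (train log-rank p %.3g)\n",
              object$threshold, object$train_logrank_p))
  cat("  note:", object$threshold_note, "\n")
  invisible(object)
}

#' @export
coef.cfod_cox <- function(object, ...) object$beta

#' Risk scores and risk groups for new patients
#'
#' Applies the stored imputation, standardization and coefficients — a
#' purely deterministic linear functional of the features, with no
#' refitting — and optionally dichotomizes at the trained threshold into
#' the high-risk (\code{score > threshold}) and low-risk groups.
#'
#' @param object a fitted \code{\link{cfod_cox}} model.
#' @param newdata data.frame with the selected feature columns (an
#'   \code{id} column is carried through if present).
#' @param type \code{"risk"} for continuous scores, \code{"group"} for the
#'   \code{"low"}/\code{"high"} factor.
#' @param ... unused.
#' @return numeric vector of scores or a factor of risk groups.
#' @export
predict.cfod_cox <- function(object, newdata,
                             type = c("risk", "group"), ...) {
  type <- match.arg(type)
  missing_cols <- setdiff(object$selected, names(newdata))
  if (length(missing_cols)) {
    stop("newdata lacks selected features: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(newdata[, object$selected, drop = FALSE])
  for (j in seq_len(ncol(x))) {
    x[is.na(x[, j]), j] <- object$impute_means[object$selected[j]]
  }
  z <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  scores <- drop(z %*% object$beta)
  if (type == "risk") return(scores)
  factor(ifelse(scores > object$threshold, "high", "low"),
         levels = c("low", "high"))
}

#' Kaplan-Meier plot of the model's training risk groups
#'
#' @param x a fitted \code{cfod_cox} model.
#' @param ... passed to \code{plot.survfit}.
#' @export
plot.cfod_cox <- function(x, ...) {
  grp <- factor(ifelse(x$train_scores > x$threshold, "high", "low"),
                levels = c("low", "high"))
  sf <- survival::survfit(
    survival::Surv(x$train_survival$time_days, x$train_survival$event) ~ grp)
  graphics::plot(sf, col = c("#2166ac", "#b2182b"), lwd = 2,
                 xlab = "days", ylab = "disease-free survival", ...)
  graphics::legend("bottomleft", c("low risk", "high risk"),
                   col = c("#2166ac", "#b2182b"), lwd = 2, bty = "n")
  invisible(x)
}

#' Train the risk-score dichotomization threshold
#'
#' Scans candidate thresholds at the 10th to 90th score percentiles in steps
#' of one percentile and returns the threshold giving the most significant
#' log-rank separation between \code{score > t} and \code{score <= t} on the
#' training cohort; ties go to the threshold nearest the median score. The
#' restriction to inner percentiles avoids degenerate tiny groups. Because
#' the threshold is optimized on the same data, its training p-value is
#' anti-conservative; it is reported as metadata, not inference.
#'
#' @param scores numeric training risk scores.
#' @param time_days,event training survival outcome.
#' @return list with \code{threshold}, \code{p} (log-rank at the chosen
#'   threshold) and the full \code{scan} data.frame.
#' @export
select_risk_threshold <- function(scores, time_days, event) {
  if (length(unique(scores)) < 2) {
    stop("all risk scores identical; threshold undefined", call. = FALSE)
  }
  cand <- unique(quantile(scores, probs = seq(0.10, 0.90, by = 0.01),
                          names = FALSE, type = 7))
  med <- median(scores)
  y <- survival::Surv(time_days, event)
  ps <- vapply(cand, function(t) {
    hi <- scores > t
    if (!any(hi) || all(hi)) return(NA_real_)
    sd <- survival::survdiff(y ~ hi)
    1 - pchisq(sd$chisq, 1)
  }, 0)
  ok <- which(!is.na(ps))
  if (!length(ok)) stop("no candidate threshold splits the cohort",
                        call. = FALSE)
  pmin_val <- min(ps[ok])
  best <- ok[ps[ok] <= pmin_val + 1e-15]
  best <- best[which.min(abs(cand[best] - med))]
  list(threshold = cand[best], p = ps[best],
       scan = data.frame(threshold = cand, p = ps))
}

#' Kaplan-Meier curves, log-rank test and hazard ratio for two risk groups
#'
#' Product-limit survival estimates per group with at-risk counts, a
#' two-sided log-rank test, and the hazard ratio of the high-risk group with
#' the low-risk group as reference, from a univariate Cox fit on the group
#' indicator (Wald 95% CI).
#'
#' @param group factor with levels \code{c("low", "high")} (low =
#'   reference), or anything coercible to it.
#' @param time_days,event survival outcome vectors.
#' @return An object of class \code{StratificationResult}: list with
#'   \code{hr}, \code{ci} (length 2), \code{logrank_p}, \code{n},
#'   \code{events}, \code{km} (a \code{survfit} object) and a
#'   \code{diverged} flag set when a group has no events (monotone
#'   likelihood).
#' @export
km_logrank <- function(group, time_days, event) {
  group <- factor(group, levels = c("low", "high"))
  if (any(table(group) == 0)) stop("both groups must be non-empty",
                                   call. = FALSE)
  y <- survival::Surv(time_days, event)
  sf <- survival::survfit(y ~ group)
  sd <- survival::survdiff(y ~ group)
  p <- 1 - pchisq(sd$chisq, length(sd$n) - 1)
  cx <- survival::coxph(y ~ group)
  hr <- exp(coef(cx)[1])
  se <- sqrt(diag(cx$var))[1]
  ci <- exp(coef(cx)[1] + c(-1, 1) * 1.96 * se)
  ev <- tapply(event, group, sum)
  diverged <- any(ev == 0)
  if (diverged) {
    warning("a risk group has zero events; hazard ratio is unstable")
  }
  structure(list(hr = unname(hr), ci = unname(ci), logrank_p = p,
                 n = as.vector(table(group)), events = as.vector(ev),
                 km = sf, diverged = diverged),
            class = "StratificationResult")
}

#' @export
print.StratificationResult <- function(x, ...) {
  cat(sprintf(
    "Risk stratification: HR = %.2f (95%% CI %.2f-%.2f), log-rank p = %.3g\n",
    x$hr, x$ci[1], x$ci[2], x$logrank_p))
  cat(sprintf("  low risk: n = %d (%d events); high risk: n = %d (%d events)\n",
              x$n[1], x$events[1], x$n[2], x$events[2]))
  if (x$diverged) cat("  warning: monotone likelihood (a group had 0 events)\n")
  invisible(x)
}

#' Univariate or multivariate Cox proportional hazards table
#'
#' Univariate mode fits one Cox model per covariate; multivariate mode fits
#' a joint model after dropping covariates missing in more than one third of
#' patients and restricting to complete cases. Factor covariates should be
#' coded with the reference as their first level. Monotone-likelihood
#' non-convergence is flagged per covariate rather than failing.
#'
#' @param survival data.frame with \code{time_days} and \code{event}.
#' @param covariates data.frame of covariates, same row order.
#' @param mode \code{"univariate"} or \code{"multivariate"}.
#' @return data.frame with columns \code{term}, \code{hr}, \code{ci_lo},
#'   \code{ci_hi}, \code{p}, \code{n}, \code{diverged}.
#' @export
cox_fit <- function(survival, covariates,
                    mode = c("univariate", "multivariate")) {
  mode <- match.arg(mode)
  y <- survival::Surv(survival$time_days, survival$event)
  row_of <- function(cx, n_used) {
    b <- coef(cx)
    se <- sqrt(diag(cx$var))
    data.frame(term = names(b), hr = exp(b),
               ci_lo = exp(b - 1.96 * se), ci_hi = exp(b + 1.96 * se),
               p = 2 * stats::pnorm(-abs(b / se)), n = n_used,
               diverged = abs(b) > 10 | se > 100, row.names = NULL)
  }
  if (mode == "univariate") {
    out <- lapply(names(covariates), function(v) {
      keep <- !is.na(covariates[[v]])
      cx <- survival::coxph(y[keep] ~ covariates[[v]][keep])
      r <- row_of(cx, sum(keep))
      r$term <- sub("^covariates\\[\\[v\\]\\]\\[keep\\]", v, r$term)
      r
    })
    return(do.call(rbind, out))
  }
  miss <- vapply(covariates, function(v) mean(is.na(v)), 0)
  dropped <- names(covariates)[miss > 1 / 3]
  if (length(dropped)) {
    message("dropped from multivariate model (>1/3 missing): ",
            paste(dropped, collapse = ", "))
  }
  use <- covariates[, miss <= 1 / 3, drop = FALSE]
  cc <- complete.cases(use)
  cx <- survival::coxph(y[cc] ~ ., data = use[cc, , drop = FALSE])
  row_of(cx, sum(cc))
}

#' Compare a feature between short- and long-DFS patients
#'
#' Short DFS: an event before five years (1826.25 days); long DFS: follow-up
#' (event or censoring) of at least five years. Patients censored before
#' five years are excluded. Two-sided Wilcoxon rank-sum test with normal
#' approximation and tie correction.
#'
#' @param values numeric feature values, one per patient.
#' @param time_days,event survival outcome vectors.
#' @return list with \code{p}, \code{median_short}, \code{median_long},
#'   \code{direction} (\code{"lower in short DFS"} or
#'   \code{"higher in short DFS"}), \code{n_short}, \code{n_long}.
#' @export
compare_feature_by_dfs_group <- function(values, time_days, event) {
  short <- event == 1 & time_days < FIVE_YEARS_DAYS
  long <- time_days >= FIVE_YEARS_DAYS
  if (!any(short) || !any(long)) {
    stop("both DFS groups must be non-empty", call. = FALSE)
  }
  vs <- values[short]; vl <- values[long]
  wt <- wilcox.test(vs, vl, exact = FALSE)
  list(p = wt$p.value, median_short = median(vs, na.rm = TRUE),
       median_long = median(vl, na.rm = TRUE),
       direction = if (median(vs, na.rm = TRUE) <= median(vl, na.rm = TRUE))
         "lower in short DFS" else "higher in short DFS",
       n_short = sum(short), n_long = sum(long))
}

#' TAILORx Oncotype DX risk categorization
#'
#' Low: score below 11; intermediate: 11 to 25 inclusive; high: above 25.
#'
#' @param score numeric recurrence score(s), non-negative.
#' @return factor with levels \code{low}, \code{intermediate}, \code{high}.
#' @export
odx_category <- function(score) {
  if (any(score < 0, na.rm = TRUE)) {
    stop("recurrence score cannot be negative", call. = FALSE)
  }
  out <- ifelse(score < 11, "low", ifelse(score <= 25, "intermediate", "high"))
  factor(out, levels = c("low", "intermediate", "high"))
}
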