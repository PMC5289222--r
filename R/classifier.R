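#' Logistic-regression cell-fate model
#'
#' Binomial logistic regression of cell fate (spore = 1, vegetative = 0) on
#' a single predictor, optionally with one covariate:
#' `logit(p) = b0 + b1*x1 (+ b2*x2)`. Fitting is maximum likelihood by
#' iteratively reweighted least squares; standard errors come from the
#' observed information at the optimum. Complete separation is flagged
#' rather than silently returning divergent coefficients.
#'
#' @param records data frame with a `fate` column (`"spore"`/`"vegetative"`
#'   or 0/1) and the predictor/covariate columns.
#' @param predictor name of the predictor column (e.g. `"mean_mu"`,
#'   `"peak_pulse"`).
#' @param covariate optional covariate column name (e.g. inducer level or a
#'   strain indicator).
#' @return object of class `logistic_fit`: coefficients, standard errors,
#'   log-likelihood, `n`, the underlying `glm`, and a `separation` flag.
#' @export
fit_logistic <- function(records, predictor, covariate = NULL) {
  y <- records$fate
  if (!is.numeric(y)) y <- as.integer(y == "spore")
  if (length(unique(y)) < 2)
    stop("both fate classes must be present")
  x1 <- records[[predictor]]
  if (any(!is.finite(x1))) stop("predictor must be finite")
  df <- data.frame(y = y, x1 = x1)
  form <- y ~ x1
  if (!is.null(covariate)) {
    x2 <- records[[covariate]]
    if (length(unique(x2)) < 2) stop("covariate is constant")
    if (isTRUE(all.equal(stats::cor(x1, x2), 1)) ||
        isTRUE(all.equal(stats::cor(x1, x2), -1)))
      stop("covariate is collinear with the predictor")
    df$x2 <- x2
    form <- y ~ x1 + x2
  }
  fit <- suppressWarnings(stats::glm(form, family = stats::binomial(), data = df))
  separation <- !fit$converged || any(abs(stats::coef(fit)) > 1e3) ||
    max(fit$fitted.values) > 1 - 1e-10 && min(fit$fitted.values) < 1e-10
  sm <- summary(fit)
  structure(list(
    coefficients = stats::coef(fit),
    standard_errors = sm$coefficients[, "Std. Error"],
    z_values = sm$coefficients[, "z value"],
    p_values = sm$coefficients[, "Pr(>|z|)"],
    log_likelihood = as.numeric(stats::logLik(fit)),
    n = nrow(df), predictor = predictor, covariate = covariate,
    separation = separation, glm = fit),
    class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fate model on %s (n = %d)%s\n", x$predictor, x$n,
              if (x$separation) " [complete separation flagged]" else ""))
  co <- cbind(estimate = x$coefficients, se = x$standard_errors,
              p = x$p_values)
  print(round(co, 4))
  invisible(x)
}

#' Sporulation threshold from a logistic fit
#'
#' The predictor value at which the fitted probability of sporulation is
#' 0.5: `-b0/b1`, with a delta-method standard error. The direction records
#' whether cells sporulate below the threshold (negative slope, as for
#' growth rate) or above it (positive slope, as for promoter activity or
#' KinA level).
#'
#' @param fit a [fit_logistic()] result (no covariate term).
#' @return list of class `threshold_result`: `threshold`,
#'   `standard_error`, `direction`.
#' @export
threshold_from_fit <- function(fit) {
  if (fit$separation)
    stop("threshold undefined under complete separation")
  b <- fit$coefficients
  if (length(b) != 2) stop("threshold requires a single-predictor fit")
  if (abs(b[2]) < 1e-12) stop("slope ~ 0: threshold undefined")
  thr <- -b[1] / b[2]
  V <- stats::vcov(fit$glm)
  grad <- c(-1 / b[2], b[1] / b[2]^2)
  se <- sqrt(drop(t(grad) %*% V %*% grad))
  structure(list(threshold = unname(thr), standard_error = unname(se),
                 direction = if (b[2] < 0) "sporulate-below"
                             else "sporulate-above"),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("Threshold %.4g +/- %.3g (%s)\n", x$threshold,
              x$standard_error, x$direction))
  invisible(x)
}

#' Receiver operating characteristic curve
#'
#' Sweeps every distinct score value as a classification threshold (ties
#' grouped), computing the false-positive rate (vegetative cells called
#' spores) and true-positive rate (spores called spores); AUC by the
#' trapezoid rule. `direction = "below"` means low scores predict
#' sporulation (growth rate); `"above"` means high scores do (promoter
#' activity, KinA level).
#'
#' @param labels fate labels (`"spore"`/`"vegetative"` or 1/0).
#' @param score numeric score per record.
#' @param direction `"below"` or `"above"`.
#' @return object of class `roc_curve`: data frame `sweep` with
#'   `threshold`, `fpr`, `tpr`; scalar `auc`; and `n_pos`, `n_neg`.
#' @export
roc_curve <- function(labels, score, direction = c("below", "above")) {
  direction <- match.arg(direction)
  y <- if (is.numeric(labels)) labels > 0 else labels == "spore"
  if (all(y) || !any(y)) stop("both classes required for a ROC curve")
  s <- if (direction == "below") -score else score
  ord <- order(s, decreasing = TRUE)
  sy <- y[ord]; ss <- s[ord]
  # cumulative counts at the end of each tie block (one sweep point per
  # distinct threshold), plus the call-nothing endpoint
  last_of_block <- c(diff(ss) != 0, TRUE)
  cum_tp <- cumsum(sy)[last_of_block]
  cum_fp <- cumsum(!sy)[last_of_block]
  tpr <- c(0, cum_tp / sum(y))
  fpr <- c(0, cum_fp / sum(!y))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  thr_vals <- c(Inf, ss[last_of_block])
  if (direction == "below") thr_vals <- -thr_vals
  structure(list(sweep = data.frame(threshold = thr_vals,
                                    fpr = fpr, tpr = tpr),
                 auc = auc, n_pos = sum(y), n_neg = sum(!y)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d spores / %d vegetative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, y, ...) {
  graphics::plot(x$sweep$fpr, x$sweep$tpr, type = "l",
                 xlab = "false-positive rate", ylab = "true-positive rate",
                 ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Classification rates at a fixed threshold
#'
#' False-positive rate (fraction of vegetative cells incorrectly predicted
#' to sporulate), true-positive rate (fraction of sporulating cells
#' correctly predicted), and total error rate at one threshold.
#'
#' @param labels fate labels.
#' @param score numeric score.
#' @param threshold threshold value, or a [threshold_from_fit()] result.
#' @param direction `"below"` or `"above"`; taken from a threshold object
#'   when one is supplied.
#' @return named vector `fpr`, `tpr`, `total_error`.
#' @export
classify_at <- function(labels, score, threshold,
                        direction = c("below", "above")) {
  if (inherits(threshold, "threshold_result")) {
    direction <- if (threshold$direction == "sporulate-below") "below"
                 else "above"
    threshold <- threshold$threshold
  } else direction <- match.arg(direction)
  if (!is.finite(threshold)) stop("threshold must be finite")
  y <- if (is.numeric(labels)) labels > 0 else labels == "spore"
  call_spore <- if (direction == "below") score <= threshold
                else score >= threshold
  c(fpr = sum(call_spore & !y) / max(sum(!y), 1),
    tpr = sum(call_spore & y) / max(sum(y), 1),
    total_error = mean(call_spore != y))
}

#' Wald test for a covariate effect on the sporulation threshold
#'
#' Fits the pooled two-predictor logistic model and tests the covariate
#' coefficient against zero (Wald t/z statistic, two-sided p).
#'
#' @inheritParams fit_logistic
#' @return list with `t`, `p`, `estimate`, `se`, and the full fit.
#' @export
covariate_test <- function(records, predictor, covariate) {
  fit <- fit_logistic(records, predictor, covariate)
  est <- fit$coefficients[["x2"]]
  se <- fit$standard_errors[["x2"]]
  t <- est / se
  list(t = t, p = 2 * stats::pnorm(-abs(t)), estimate = est, se = se,
       fit = fit)
}

#' Spearman rank correlation with a Fisher-z test
#'
#' Spearman's rho with a two-sided test based on the Fisher
#' z-transformation, `z = atanh(rho) * sqrt((n - 3) / 1.06)` (the 1.06
#' variance inflation is the standard Spearman correction). A permutation
#' option is available for small n.
#'
#' @param x,y numeric vectors.
#' @param method `"fisher"` (default) or `"permutation"`.
#' @param n_perm permutations when `method = "permutation"`.
#' @return list of class `correlation_result`: `rho`, `p`, `n`.
#' @export
spearman_test <- function(x, y, method = c("fisher", "permutation"),
                          n_perm = 2000) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must match in length")
  n <- length(x)
  if (n < 4) stop("need n >= 4")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("inputs must not be constant")
  rho <- stats::cor(x, y, method = "spearman")
  if (method == "fisher") {
    z <- atanh(min(max(rho, -1 + 1e-12), 1 - 1e-12)) * sqrt((n - 3) / 1.06)
    p <- 2 * stats::pnorm(-abs(z))
  } else {
    null_rho <- vapply(seq_len(n_perm), function(i)
      stats::cor(x, sample(y), method = "spearman"), numeric(1))
    p <- (1 + sum(abs(null_rho) >= abs(rho))) / (n_perm + 1)
  }
  structure(list(rho = rho, p = p, n = n), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f, p = %.3g, n = %d\n", x$rho, x$p, x$n))
  invisible(x)
}

#' Sample size needed to detect a rank correlation
#'
#' Fisher-z power formula for the Spearman test:
#' `n = 1.06 * ((z_alpha/2 + z_beta) / atanh(rho0))^2 + 3`, rounded up.
#'
#' @param rho0 correlation to detect.
#' @param power target power.
#' @param alpha two-sided significance level.
#' @return required sample size (integer).
#' @export
required_n <- function(rho0, power = 0.9, alpha = 0.05) {
  if (abs(rho0) <= 0 || abs(rho0) >= 1) stop("rho0 must be in (0, 1)")
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  ceiling(1.06 * ((za + zb) / atanh(abs(rho0)))^2 + 3)
}
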