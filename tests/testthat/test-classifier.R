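logistic_sample <- function(n, b0, b1, seed) {
  set.seed(seed)
  x <- rnorm(n)
  p <- plogis(b0 + b1 * x)
  data.frame(fate = rbinom(n, 1, p), x = x)
}

test_that("logistic fit recovers known coefficients", {
  d <- logistic_sample(5000, 0, 2, seed = 1)
  fit <- fit_logistic(d, "x")
  expect_false(fit$separation)
  expect_lt(abs(fit$coefficients[["(Intercept)"]] - 0) /
              fit$standard_errors[["(Intercept)"]], 2)
  expect_lt(abs(fit$coefficients[["x1"]] - 2) /
              fit$standard_errors[["x1"]], 2)
  expect_error(fit_logistic(data.frame(fate = rep(1, 10), x = rnorm(10)),
                            "x"), "both")
})

test_that("a predictor independent of fate is rarely called significant", {
  set.seed(2)
  rejections <- 0L
  for (r in 1:20) {
    d <- data.frame(fate = rbinom(400, 1, 0.5), x = rnorm(400))
    fit <- fit_logistic(d, "x")
    if (fit$p_values[["x1"]] < 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections, 3)  # ~binomial(20, 0.05)
})

test_that("complete separation is flagged, not silently reported", {
  d <- data.frame(fate = c(rep(0, 50), rep(1, 50)),
                  x = c(rnorm(50, -3), rnorm(50, 3)))
  fit <- fit_logistic(d, "x")
  expect_true(fit$separation)
  expect_error(threshold_from_fit(fit), "separation")
})

test_that("threshold algebra and the delta-method standard error", {
  d <- logistic_sample(4000, 2, -4, seed = 3)
  names(d)[2] <- "score"
  fit <- fit_logistic(d, "score")
  thr <- threshold_from_fit(fit)
  expect_equal(thr$threshold, -fit$coefficients[[1]] / fit$coefficients[[2]])
  expect_lt(abs(thr$threshold - 0.5) / thr$standard_error, 3)
  expect_identical(thr$direction, "sporulate-below")
  expect_gt(thr$standard_error, 0)
})

test_that("generator fate threshold is recovered within 2 SE", {
  fit <- fit_logistic(colony_records, "mean_mu")
  thr <- threshold_from_fit(fit)
  mu_star <- attr(colony_tree, "config")$mu_star
  expect_lt(abs(thr$threshold - mu_star), 2 * thr$standard_error)
  expect_identical(thr$direction, "sporulate-below")
})

test_that("ROC endpoints: random scores give 0.5, separators give 1 and 0", {
  set.seed(4)
  n <- 1e5
  y <- rbinom(n, 1, 0.4)
  s <- rnorm(n)
  r <- roc_curve(y, s, direction = "above")
  expect_lt(abs(r$auc - 0.5), 0.01)
  perfect <- roc_curve(y, y + 0.01 * runif(n), direction = "above")
  expect_equal(perfect$auc, 1)
  reversed <- roc_curve(1 - y, y + 0.01 * runif(n), direction = "above")
  expect_equal(reversed$auc, 0)
  expect_error(roc_curve(rep(1, 5), rnorm(5)), "both classes")
})

test_that("AUC is invariant under monotone score transforms and matches pROC", {
  rec <- colony_records
  r1 <- roc_curve(rec$fate, rec$mean_mu, "below")
  r2 <- roc_curve(rec$fate, exp(3 * rec$mean_mu) + 1, "below")
  expect_equal(r1$auc, r2$auc, tolerance = 1e-12)
  skip_if_not_installed("pROC")
  ref <- pROC::auc(pROC::roc(rec$fate == "spore", rec$mean_mu,
                             direction = ">", quiet = TRUE))
  expect_equal(r1$auc, as.numeric(ref), tolerance = 1e-9)
})

test_that("classify_at is consistent with the ROC sweep", {
  rec <- colony_records
  r <- roc_curve(rec$fate, rec$mean_mu, "below")
  # rebuild the curve from classify_at over the same thresholds
  thr <- sort(unique(rec$mean_mu))
  pts <- t(vapply(thr, function(th)
    classify_at(rec$fate, rec$mean_mu, th, "below"), numeric(3)))
  ord <- order(pts[, "fpr"], pts[, "tpr"])
  fpr <- c(0, pts[ord, "fpr"]); tpr <- c(0, pts[ord, "tpr"])
  auc2 <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  expect_equal(r$auc, auc2, tolerance = 1e-9)
  # a threshold below every score calls nothing a spore
  low <- classify_at(rec$fate, rec$mean_mu, min(rec$mean_mu) - 1, "below")
  expect_equal(unname(low[c("fpr", "tpr")]), c(0, 0))
  # fate-threshold agreement: logistic threshold is near the error-optimal one
  err <- pts[, "total_error"]
  opt <- thr[which.min(err)]
  fit_thr <- threshold_from_fit(fit_logistic(rec, "mean_mu"))$threshold
  expect_lt(abs(fit_thr - opt), 0.05)
})

test_that("covariate Wald test: calibrated null, powered alternative, collinearity", {
  set.seed(6)
  rejections <- 0L
  for (r in 1:20) {
    d <- logistic_sample(400, 0, 1.5, seed = 100 + r)
    d$z <- rnorm(400)  # no effect
    ct <- covariate_test(d, "x", "z")
    if (ct$p < 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections, 4)  # Binomial(20, 0.05): P(>4) < 0.003
  # strong covariate effect is detected
  set.seed(7)
  x <- rnorm(2000); z <- rbinom(2000, 1, 0.5)
  p <- plogis(0.5 + 1.5 * x - 2 * z)
  d2 <- data.frame(fate = rbinom(2000, 1, p), x = x, z = z)
  expect_lt(covariate_test(d2, "x", "z")$p, 1e-3)
  d2$x2 <- d2$x
  expect_error(covariate_test(d2, "x", "x2"), "collinear")
})

test_that("Spearman test: exact monotone, calibrated null, permutation option", {
  expect_equal(spearman_test(1:20, (1:20)^3)$rho, 1)
  set.seed(8)
  rej <- 0L
  for (r in 1:100) {
    x <- runif(2000); y <- runif(2000)
    if (spearman_test(x, y)$p < 0.05) rej <- rej + 1L
  }
  expect_gte(rej, 1); expect_lte(rej, 12)  # ~ Binomial(100, 0.05)
  expect_error(spearman_test(rep(1, 10), rnorm(10)), "constant")
  p_perm <- spearman_test(rnorm(30), rnorm(30), method = "permutation")$p
  expect_gte(p_perm, 0); expect_lte(p_perm, 1)
})

test_that("required sample size for rho = 0.2 is ~260-280 and delivers ~90% power", {
  n_req <- required_n(0.2, power = 0.9, alpha = 0.05)
  expect_gte(n_req, 250); expect_lte(n_req, 290)
  # Monte-Carlo power at the computed n (bivariate normal with the Pearson
  # rho that induces Spearman rho = 0.2)
  r_pearson <- 2 * sin(pi * 0.2 / 6)
  set.seed(9)
  hits <- 0L; n_rep <- 200L
  for (r in seq_len(n_rep)) {
    x <- rnorm(n_req)
    y <- r_pearson * x + sqrt(1 - r_pearson^2) * rnorm(n_req)
    if (spearman_test(x, y)$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.85)
  expect_lte(hits / n_rep, 0.97)
})

test_that("growth-rate and activity classifiers reach AUC 0.85 on default colonies", {
  rec <- colony_records
  auc_mu <- roc_curve(rec$fate, rec$mean_mu, "below")$auc
  auc_act <- roc_curve(rec$fate, rec$peak_pulse, "above")$auc
  expect_gte(auc_mu, 0.85)
  expect_gte(auc_act, 0.85)
})
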