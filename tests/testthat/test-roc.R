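test_that("empirical ROC matches exhaustive threshold enumeration", {
  set.seed(31)
  for (i in 1:20) {
    inst <- random_instance(n = 30 + i)
    for (dir in c("above", "below")) {
      rc <- empirical_roc(inst$values, inst$labels, dir)
      expect_equal(unname(as.matrix(rc[, c("fpr", "tpr")])),
                   unname(oracle_roc_vertices(inst$values, inst$labels, dir)))
    }
  }
})

test_that("perfect separation and all-ties give the boundary curves", {
  rc <- empirical_roc(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE), "below")
  expect_true(any(rc$fpr == 0 & rc$tpr == 1))
  expect_equal(trapezoid_auc(rc), 1)
  rc2 <- empirical_roc(rep(2, 10), rep(c(TRUE, FALSE), 5), "above")
  expect_equal(nrow(rc2), 2L)  # (0,0) -> (1,1) diagonal
  expect_equal(trapezoid_auc(rc2), 0.5)
  expect_error(empirical_roc(1:4, rep(TRUE, 4), "above"), "both classes")
})

test_that("trapezoidal AUC equals the pairwise Mann-Whitney estimator", {
  set.seed(52)
  for (i in 1:50) {
    inst <- random_instance(n = 25 + (i %% 20), ties = i %% 2 == 0)
    dir <- if (i %% 3 == 0) "below" else "above"
    auc <- trapezoid_auc(empirical_roc(inst$values, inst$labels, dir))
    expect_equal(auc, oracle_mw_auc(inst$values, inst$labels, dir),
                 tolerance = 1e-12)
  }
})

test_that("operating-point AUC reproduces a discrete score's trapezoid AUC", {
  set.seed(63)
  for (i in 1:10) {
    scores <- sample(0:4, 120, replace = TRUE)
    labels <- rbinom(120, 1, plogis(scores - 2)) == 1
    ev_rows <- t(vapply(1:4, function(t) {
      pos <- scores >= t
      c(sensitivity = 100 * sum(pos & labels) / sum(labels),
        specificity = 100 * sum(!pos & !labels) / sum(!labels))
    }, numeric(2)))
    expect_equal(auc_from_operating_points(as.data.frame(ev_rows)),
                 trapezoid_auc(empirical_roc(scores, labels, "above")),
                 tolerance = 1e-12)
  }
  expect_equal(auc_from_operating_points(data.frame(sensitivity = 100,
                                                    specificity = 100)), 1)
  expect_error(auc_from_operating_points(data.frame(sensitivity = 104,
                                                    specificity = 50)),
               "\\[0, 100\\]")
})

test_that("Youden search equals exhaustive cutoff enumeration", {
  set.seed(74)
  for (i in 1:30) {
    inst <- random_instance(n = 35, ties = TRUE)
    dir <- if (i %% 2 == 0) "below" else "above"
    rule <- youden_cutoff(inst$values, inst$labels, dir)
    expect_equal(rule$youden_j,
                 oracle_youden_j(inst$values, inst$labels, dir),
                 tolerance = 1e-12)
    expect_equal(rule$youden_j,
                 rule$sensitivity / 100 + rule$specificity / 100 - 1)
  }
})

test_that("Youden cutoff separates perfectly separable classes", {
  rule <- youden_cutoff(c(1, 2, 3, 4, 5, 6), rep(c(TRUE, FALSE), each = 3),
                        direction = "below")
  expect_equal(rule$youden_j, 1)
  expect_gt(rule$cutoff, 3)
  expect_lt(rule$cutoff, 4)
  expect_equal(rule$sensitivity, 100)
  expect_equal(rule$specificity, 100)
})

test_that("Youden ties break toward the most specific cutoff", {
  # interleaved classes: J = 0.5 is attained by both "< 1.5" (one
  # positive call) and "< 3.5" (three); the more specific rule must win
  v <- c(1, 3, 2, 4)
  y <- c(TRUE, TRUE, FALSE, FALSE)
  rule <- youden_cutoff(v, y, "below")
  expect_equal(rule$youden_j, 0.5)
  expect_lt(rule$cutoff, 2)
  expect_equal(rule$specificity, 100)
})

test_that("Youden classification is invariant to monotone transforms", {
  set.seed(85)
  for (i in 1:10) {
    inst <- random_instance(n = 40, ties = FALSE)
    r1 <- youden_cutoff(inst$values, inst$labels, "above")
    r2 <- youden_cutoff(exp(inst$values), inst$labels, "above")
    expect_equal(r2$youden_j, r1$youden_j, tolerance = 1e-12)
    expect_identical(apply_rule(r2, exp(inst$values)),
                     apply_rule(r1, inst$values))
  }
})

test_that("DeLong AUC, SE and CI agree with the pROC implementation", {
  set.seed(96)
  for (i in 1:5) {
    v <- c(rnorm(60, 0.8), rnorm(90))
    y <- rep(c(TRUE, FALSE), c(60, 90))
    mine <- delong_auc_ci(v, y)
    ref <- pROC::roc(response = y, predictor = v, direction = "<",
                     quiet = TRUE)
    ci <- pROC::ci.auc(ref, method = "delong")
    expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
    expect_equal(mine$standard_error, sqrt(pROC::var(ref, method = "delong")),
                 tolerance = 1e-10)
    expect_equal(c(mine$ci_low, mine$ci_high), as.numeric(ci[c(1, 3)]),
                 tolerance = 1e-9)
  }
})

test_that("perfect separation yields AUC 1 with zero standard error", {
  res <- delong_auc_ci(c(5, 6, 7, 1, 2, 3), rep(c(TRUE, FALSE), each = 3))
  expect_equal(res$auc, 1)
  expect_equal(res$standard_error, 0)
  expect_equal(c(res$ci_low, res$ci_high), c(1, 1))
})

test_that("the logit-scale CI stays inside (0,1) and covers the AUC", {
  set.seed(7)
  v <- c(rnorm(40, 2), rnorm(40))
  y <- rep(c(TRUE, FALSE), each = 40)
  res <- delong_auc_ci(v, y, ci_method = "logit")
  expect_true(res$ci_low > 0 && res$ci_high < 1)
  expect_true(res$ci_low <= res$auc && res$auc <= res$ci_high)
})

test_that("DeLong Wald CI attains nominal coverage on binormal data", {
  true_auc <- binormal_auc(1, 1, 0, 1)
  set.seed(123)
  hits <- logical(1000)
  for (i in 1:1000) {
    v <- c(rnorm(500, 1), rnorm(500))
    y <- rep(c(TRUE, FALSE), each = 500)
    res <- delong_auc_ci(v, y)
    hits[i] <- res$ci_low <= true_auc && true_auc <= res$ci_high
  }
  expect_gt(mean(hits), 0.93)
  expect_lt(mean(hits), 0.97)
})

test_that("DeLong variance agrees with a bootstrap at cohort scale", {
  set.seed(134)
  v <- c(rnorm(92, 0.7), rnorm(198))
  y <- rep(c(TRUE, FALSE), c(92, 198))
  res <- delong_auc_ci(v, y)
  boot <- replicate(2000, {
    i1 <- sample(which(y), replace = TRUE)
    i0 <- sample(which(!y), replace = TRUE)
    idx <- c(i1, i0)
    trapezoid_auc(empirical_roc(v[idx], y[idx], "above"))
  })
  expect_lt(abs(var(boot) - res$standard_error^2) / var(boot), 0.15)
})

test_that("identical markers give a null paired DeLong test", {
  v <- c(rnorm(30, 1), rnorm(30))
  y <- rep(c(TRUE, FALSE), each = 30)
  res <- delong_paired_test(v, v, y)
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p.value, 1)
  expect_equal(unname(diff(res$estimate)), 0)
})

test_that("paired DeLong agrees with the pROC paired test", {
  set.seed(145)
  for (i in 1:5) {
    y <- rep(c(TRUE, FALSE), c(45, 80))
    z <- rnorm(125)
    a <- z + rnorm(125) + as.numeric(y)
    b <- z + rnorm(125) + 0.5 * as.numeric(y)
    mine <- delong_paired_test(a, b, y)
    ref <- pROC::roc.test(
      pROC::roc(y, a, direction = "<", quiet = TRUE),
      pROC::roc(y, b, direction = "<", quiet = TRUE),
      method = "delong", paired = TRUE)
    expect_equal(unname(mine$statistic), unname(ref$statistic),
                 tolerance = 1e-9)
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("paired DeLong p-value matches a permutation oracle", {
  set.seed(156)
  y <- rep(c(TRUE, FALSE), c(12, 18))
  z <- rnorm(30)
  a <- z + rnorm(30, sd = 0.8) + 0.8 * as.numeric(y)
  b <- z + rnorm(30, sd = 0.8) + 0.4 * as.numeric(y)
  obs <- delong_paired_test(a, b, y)
  d_obs <- abs(diff(unname(obs$estimate)))
  # label-preserving marker swap: exchange a_i and b_i at random
  perm <- replicate(5000, {
    swap <- runif(30) < 0.5
    aa <- ifelse(swap, b, a)
    bb <- ifelse(swap, a, b)
    abs(oracle_mw_auc(aa, y) - oracle_mw_auc(bb, y))
  })
  p_perm <- mean(perm >= d_obs - 1e-12)
  expect_lt(abs(obs$p.value - p_perm), 0.02)
})

test_that("mismatched record sets are rejected", {
  expect_error(delong_paired_test(1:5, 1:4, c(TRUE, FALSE, TRUE, FALSE)),
               "same records")
})

test_that("binormal AUC matches Monte-Carlo integration", {
  expect_equal(binormal_auc(1, 1, 1, 2), 0.5)
  set.seed(167)
  mc <- mean(rnorm(1e6, 7.96, 1.26) < rnorm(1e6, 8.82, 1.11))
  expect_equal(binormal_auc(7.96, 1.26, 8.82, 1.11, "below"), mc,
               tolerance = 2e-3)
  expect_error(binormal_auc(1, 0, 0, 1), "positive")
})

test_that("binary-marker AUC matches simulated Bernoulli draws", {
  expect_equal(binary_marker_auc(0.4, 0.4), 0.5)
  expect_equal(binary_marker_auc(0.696, 0.298), 0.699)
  set.seed(178)
  x <- c(rbinom(1e5, 1, 0.696), rbinom(1e5, 1, 0.298))
  y <- rep(c(TRUE, FALSE), each = 1e5)
  expect_equal(binary_marker_auc(0.696, 0.298),
               trapezoid_auc(empirical_roc(x, y, "above")),
               tolerance = 5e-3)
  expect_error(binary_marker_auc(1.2, 0.5), "\\[0, 1\\]")
})

test_that("predictive values follow Bayes' rule and are monotone in prevalence", {
  res <- ppv_npv(100, 100, 0.3)
  expect_equal(c(res$ppv, res$npv), c(100, 100))
  prev <- seq(0.05, 0.95, by = 0.05)
  pv <- ppv_npv(80, 70, prev)
  expect_true(all(diff(pv$ppv) > 0))
  expect_true(all(diff(pv$npv) < 0))
  expect_error(ppv_npv(80, 70, 1), "prevalence")
  expect_warning(ppv_npv(0, 100, 0.5), "degenerate")
})
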