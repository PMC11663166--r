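# Diagnostic-accuracy numerics: empirical ROC curves, trapezoidal and
# analytic AUCs, Youden-optimal cutoffs, DeLong variance/CI/paired test,
# and prevalence-adjusted predictive values.

# Orient marker values so that higher transformed score = more positive.
orient <- function(values, direction) {
  if (check_direction(direction) == "below") -values else values
}

check_two_classes <- function(labels, min_each = 1L) {
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 < min_each || n0 < min_each)
    stop(sprintf(
      "both classes must be present with at least %d member(s) (got %d positive, %d negative)",
      min_each, n1, n0), call. = FALSE)
  invisible(c(n0 = n0, n1 = n1))
}

drop_incomplete <- function(values, labels) {
  keep <- is.finite(values) & !is.na(labels)
  list(values = values[keep], labels = labels[keep])
}

#' Empirical ROC curve
#'
#' Builds the empirical receiver operating characteristic curve of a
#' continuous or ordinal marker against a binary reference label.  Ties
#' collapse to a single vertex, producing diagonal segments.  The
#' orientation is set by `direction`: `"below"` means lower marker
#' values indicate positivity (volumes, cognitive scores, CSF ratio),
#' `"above"` the opposite (atrophy rating scales).
#'
#' @param values numeric marker vector.
#' @param labels binary reference (logical, or 0/1) — `TRUE` = positive.
#' @param direction `"above"` or `"below"` (which side is positive).
#' @return Object of class `roc_curve`: a data.frame of vertices
#'   `(fpr, tpr)` sorted by FPR, beginning at (0,0) and ending at (1,1),
#'   with the marker cutoff attached to each interior vertex (the vertex
#'   collects all records at least as extreme as that cutoff).
#' @examples
#' rc <- empirical_roc(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE), "below")
#' trapezoid_auc(rc) # 1: perfect separation
#' @export
empirical_roc <- function(values, labels, direction = c("above", "below")) {
  direction <- match.arg(direction)
  labels <- as_binary_labels(labels)
  cc <- drop_incomplete(values, labels)
  values <- cc$values; labels <- cc$labels
  n <- check_two_classes(labels)
  s <- orient(values, direction)
  o <- order(s, decreasing = TRUE)
  s <- s[o]; y <- labels[o]; v <- values[o]
  last_of_run <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last_of_run]
  fp <- cumsum(!y)[last_of_run]
  vertices <- data.frame(
    fpr = c(0, fp / n[["n0"]]),
    tpr = c(0, tp / n[["n1"]]),
    cutoff = c(NA_real_, v[last_of_run]))
  structure(vertices, class = c("roc_curve", "data.frame"),
            direction = direction,
            n_pos = n[["n1"]], n_neg = n[["n0"]])
}

#' @export
plot.roc_curve <- function(x, add = FALSE, col = 1, lwd = 2,
                           main = "ROC curve", ...) {
  if (!add) {
    plot(x$fpr, x$tpr, type = "n", xlim = c(0, 1), ylim = c(0, 1),
         xlab = "1 - specificity", ylab = "sensitivity", main = main, ...)
    abline(0, 1, col = "grey", lty = 3)
  }
  lines(x$fpr, x$tpr, col = col, lwd = lwd)
  invisible(x)
}

#' Area under an ROC curve by trapezoidal integration
#'
#' Sums trapezoid areas over consecutive vertices.  On the empirical
#' curve this equals the Mann-Whitney estimator
#' P(score_pos > score_neg) + 0.5 P(score_pos = score_neg).
#'
#' @param curve an [empirical_roc()] object (or any data.frame with
#'   `fpr`/`tpr` columns sorted by `fpr`).
#' @return AUC in \[0, 1\].
#' @export
trapezoid_auc <- function(curve) {
  f <- curve$fpr; t <- curve$tpr
  sum(diff(f) * (t[-1] + t[-length(t)]) / 2)
}

#' AUC of a discrete score from its printed operating points
#'
#' Reconstructs the ROC polygon of a discrete score from per-threshold
#' (sensitivity, specificity) pairs in percent — the form in which
#' threshold tables are reported — and trapezoid-integrates it.  Each
#' point maps to `(FPR, TPR) = (1 - spec/100, sens/100)`; anchors (0,0)
#' and (1,1) are added and the vertices sorted by FPR.  For the full
#' threshold table of a discrete score this is exactly the trapezoidal
#' AUC of that score's empirical ROC.
#'
#' @param points a data.frame or matrix with columns `sensitivity` and
#'   `specificity` (percent), one row per threshold; or a list of
#'   `c(sens, spec)` pairs.
#' @return AUC in \[0, 1\].
#' @examples
#' # volumetric score thresholds >=1 and >=2
#' auc_from_operating_points(data.frame(sensitivity = c(86.9, 38.0),
#'                                      specificity = c(50.5, 86.3)))
#' @export
auc_from_operating_points <- function(points) {
  if (is.list(points) && !is.data.frame(points))
    points <- do.call(rbind, points)
  points <- as.matrix(as.data.frame(points))
  if (ncol(points) < 2) stop("need sensitivity and specificity columns",
                             call. = FALSE)
  cn <- colnames(points)
  sens <- if ("sensitivity" %in% cn) points[, "sensitivity"] else points[, 1]
  spec <- if ("specificity" %in% cn) points[, "specificity"] else points[, 2]
  if (any(sens < 0 | sens > 100 | spec < 0 | spec > 100))
    stop("operating points must lie in [0, 100] percent", call. = FALSE)
  fpr <- c(0, 1 - spec / 100, 1)
  tpr <- c(0, sens / 100, 1)
  o <- order(fpr, tpr)
  trapezoid_auc(data.frame(fpr = fpr[o], tpr = tpr[o]))
}

# Sensitivity/specificity (percent) of the rule "transformed score >= t".
sens_spec_at <- function(s, labels, t) {
  pos <- s >= t
  c(sens = 100 * sum(pos & labels) / sum(labels),
    spec = 100 * sum(!pos & !labels) / sum(!labels))
}

#' Youden-optimal dichotomization of a marker
#'
#' Exhaustive search over candidate cutoffs — midpoints between
#' consecutive distinct observed values, plus the all-positive and
#' all-negative extremes — for the cutoff maximizing the Youden index
#' J = sensitivity + specificity - 1.  Ties are broken toward the cutoff
#' classifying fewer records as positive (the most specific rule),
#' deterministically.
#'
#' @inheritParams empirical_roc
#' @param marker marker name stored in the returned rule.
#' @return Object of class `dichot_rule`: list with `marker`,
#'   `direction`, `cutoff` (positive iff value < cutoff for
#'   `direction = "below"`, value > cutoff for `"above"`), `youden_j`,
#'   `sensitivity` and `specificity` (percent) at the cutoff.
#' @examples
#' yr <- youden_cutoff(c(1, 2, 3, 4, 5, 6), rep(c(TRUE, FALSE), each = 3),
#'                     direction = "below")
#' yr$youden_j # 1: perfect separation
#' @export
youden_cutoff <- function(values, labels, direction = c("above", "below"),
                          marker = deparse(substitute(values))) {
  direction <- match.arg(direction)
  labels <- as_binary_labels(labels)
  cc <- drop_incomplete(values, labels)
  values <- cc$values; labels <- cc$labels
  check_two_classes(labels)
  s <- orient(values, direction)
  u <- sort(unique(s))
  cand <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  stats <- vapply(cand, function(t) sens_spec_at(s, labels, t), numeric(2))
  j <- (stats["sens", ] + stats["spec", ]) / 100 - 1
  n_pos_pred <- vapply(cand, function(t) sum(s >= t), integer(1))
  best <- which(j > max(j) - 1e-12)
  best <- best[order(n_pos_pred[best], best)][1]
  cutoff <- if (direction == "below") -cand[best] else cand[best]
  structure(list(marker = marker, direction = direction, cutoff = cutoff,
                 youden_j = unname(j[best]),
                 sensitivity = unname(stats["sens", best]),
                 specificity = unname(stats["spec", best])),
            class = "dichot_rule")
}

#' Construct a dichotomization rule with a fixed cutoff
#'
#' @param marker marker/column name.
#' @param direction `"below"` (value < cutoff scores positive) or
#'   `"above"` (value > cutoff scores positive); strict inequalities.
#' @param cutoff numeric cutoff in marker units.
#' @return A `dichot_rule` object (without Youden statistics).
#' @export
dichot_rule <- function(marker, direction = c("above", "below"), cutoff) {
  direction <- match.arg(direction)
  stop_if_not_scalar_number(cutoff, "cutoff")
  structure(list(marker = marker, direction = direction, cutoff = cutoff,
                 youden_j = NA_real_, sensitivity = NA_real_,
                 specificity = NA_real_),
            class = "dichot_rule")
}

#' Apply a dichotomization rule to marker values
#'
#' @param rule a `dichot_rule`.
#' @param values numeric vector.
#' @return Logical vector (strict inequality; `NA` propagates).
#' @export
apply_rule <- function(rule, values) {
  if (rule$direction == "below") values < rule$cutoff else values > rule$cutoff
}

#' @export
print.dichot_rule <- function(x, ...) {
  op <- if (x$direction == "below") "<" else ">"
  cat(sprintf("Dichotomization rule: %s %s %.4g\n", x$marker, op, x$cutoff))
  if (!is.na(x$youden_j))
    cat(sprintf("  Youden J = %.3f (sensitivity %.1f%%, specificity %.1f%%)\n",
                x$youden_j, x$sensitivity, x$specificity))
  invisible(x)
}

# DeLong placement values via midranks (O(n log n)).
# V10[i] = P-hat(neg < pos_i) + 0.5 P-hat(neg = pos_i); analogously V01.
delong_placements <- function(s, labels) {
  n1 <- sum(labels); n0 <- sum(!labels)
  r_all <- rank(s, ties.method = "average")
  r1 <- rank(s[labels], ties.method = "average")
  r0 <- rank(s[!labels], ties.method = "average")
  v10 <- (r_all[labels] - r1) / n0
  v01 <- 1 - (r_all[!labels] - r0) / n1
  auc <- (sum(r_all[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(v10 = v10, v01 = v01, auc = auc, n1 = n1, n0 = n0)
}

#' AUC with DeLong standard error and confidence interval
#'
#' Computes the Mann-Whitney AUC of a marker and its variance by
#' DeLong's placement-value (structural components) estimator, with a
#' Wald confidence interval on the AUC scale truncated to \[0, 1\]
#' (or on the logit scale behind a flag).
#'
#' @inheritParams empirical_roc
#' @param conf_level confidence level (default 0.95).
#' @param ci_method `"wald"` (default) or `"logit"`.
#' @return Object of class `auc_ci`: list with `auc`, `standard_error`,
#'   `ci_low`, `ci_high`, `conf_level`, `n_pos`, `n_neg`.
#' @examples
#' set.seed(1)
#' v <- c(rnorm(50, 1), rnorm(50))
#' delong_auc_ci(v, rep(c(TRUE, FALSE), each = 50))
#' @export
delong_auc_ci <- function(values, labels, direction = c("above", "below"),
                          conf_level = 0.95,
                          ci_method = c("wald", "logit")) {
  direction <- match.arg(direction)
  ci_method <- match.arg(ci_method)
  labels <- as_binary_labels(labels)
  cc <- drop_incomplete(values, labels)
  values <- cc$values; labels <- cc$labels
  check_two_classes(labels, min_each = 2L)
  p <- delong_placements(orient(values, direction), labels)
  v <- var(p$v10) / p$n1 + var(p$v01) / p$n0
  se <- sqrt(max(v, 0))
  z <- qnorm(1 - (1 - conf_level) / 2)
  if (ci_method == "wald" || se == 0 || p$auc %in% c(0, 1)) {
    ci <- c(p$auc - z * se, p$auc + z * se)
  } else {
    lo <- qlogis(p$auc)
    se_lo <- se / (p$auc * (1 - p$auc))
    ci <- plogis(c(lo - z * se_lo, lo + z * se_lo))
  }
  ci <- pmin(pmax(ci, 0), 1)
  structure(list(auc = p$auc, standard_error = se,
                 ci_low = ci[1], ci_high = ci[2],
                 conf_level = conf_level, ci_method = ci_method,
                 n_pos = p$n1, n_neg = p$n0),
            class = "auc_ci")
}

#' @export
print.auc_ci <- function(x, ...) {
  cat(sprintf("AUC %.3f (%.0f%% CI %.3f-%.3f), DeLong SE %.4f, n = %d/%d pos/neg\n",
              x$auc, 100 * x$conf_level, x$ci_low, x$ci_high,
              x$standard_error, x$n_pos, x$n_neg))
  invisible(x)
}

#' DeLong's test for two correlated AUCs
#'
#' Paired comparison of the AUCs of two markers measured on the same
#' records, using the covariance of their DeLong placement values and a
#' two-sided normal reference for the AUC difference.
#'
#' @param values_a,values_b marker vectors over the same records.
#' @param labels shared binary reference labels.
#' @param directions length-2 character: orientation of each marker.
#' @return An object of class `htest` with the z statistic, two-sided
#'   p-value, and the two AUC estimates.
#' @examples
#' set.seed(1)
#' y <- rep(c(TRUE, FALSE), each = 40)
#' a <- rnorm(80, y); b <- rnorm(80, 0.5 * y)
#' delong_paired_test(a, b, y)
#' @export
delong_paired_test <- function(values_a, values_b, labels,
                               directions = c("above", "above")) {
  if (length(values_a) != length(values_b) ||
      length(values_a) != length(labels))
    stop("both markers and the labels must cover the same records",
         call. = FALSE)
  labels <- as_binary_labels(labels)
  keep <- is.finite(values_a) & is.finite(values_b) & !is.na(labels)
  values_a <- values_a[keep]; values_b <- values_b[keep]
  labels <- labels[keep]
  check_two_classes(labels, min_each = 2L)
  pa <- delong_placements(orient(values_a, directions[1]), labels)
  pb <- delong_placements(orient(values_b, directions[2]), labels)
  s10 <- cov(cbind(pa$v10, pb$v10))
  s01 <- cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / pa$n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / pa$n0
  d <- pa$auc - pb$auc
  z <- if (v <= 0) { if (abs(d) < 1e-12) 0 else sign(d) * Inf } else d / sqrt(v)
  p <- 2 * pnorm(-abs(z))
  structure(list(
    statistic = c(z = z), p.value = p,
    estimate = c("AUC marker A" = pa$auc, "AUC marker B" = pb$auc),
    alternative = "two.sided",
    method = "DeLong's test for two correlated ROC curves",
    data.name = sprintf("%d records (%d positive)",
                        length(labels), pa$n1)),
    class = "htest")
}

#' @importFrom stats cov
NULL

#' Analytic AUC of a Gaussian marker (binormal model)
#'
#' Closed-form AUC when both classes are Gaussian:
#' `pnorm(|mu_pos - mu_neg| / sqrt(sd_pos^2 + sd_neg^2))`, oriented by
#' `direction` (an AUC below 0.5 results if the marker discriminates in
#' the direction opposite to the one given).
#'
#' @param mu_pos,sd_pos,mu_neg,sd_neg class means and SDs (`sd > 0`).
#' @param direction `"above"` or `"below"` (which side is positive).
#' @return AUC in \[0, 1\].
#' @examples
#' binormal_auc(7.96, 1.26, 8.82, 1.11, direction = "below") # about 0.70
#' @export
binormal_auc <- function(mu_pos, sd_pos, mu_neg, sd_neg,
                         direction = c("above", "below")) {
  direction <- match.arg(direction)
  if (sd_pos <= 0 || sd_neg <= 0) stop("sds must be positive", call. = FALSE)
  effect <- if (direction == "below") mu_neg - mu_pos else mu_pos - mu_neg
  pnorm(effect / sqrt(sd_pos^2 + sd_neg^2))
}

#' Analytic AUC of a binary marker
#'
#' The AUC of a Bernoulli marker with carrier rates `rate_pos` and
#' `rate_neg` in the two classes is
#' `(rate_pos + (1 - rate_neg)) / 2` (ties counted half).
#'
#' @param rate_pos,rate_neg marker-positive rates in each class, in
#'   \[0, 1\].
#' @return AUC in \[0, 1\].
#' @examples
#' binary_marker_auc(0.696, 0.298) # 0.699
#' @export
binary_marker_auc <- function(rate_pos, rate_neg) {
  if (any(c(rate_pos, rate_neg) < 0 | c(rate_pos, rate_neg) > 1))
    stop("rates must lie in [0, 1]", call. = FALSE)
  (rate_pos + (1 - rate_neg)) / 2
}

#' Predictive values from sensitivity, specificity, and prevalence
#'
#' Bayes' rule:
#' `PPV = se p / (se p + (1 - sp)(1 - p))` and
#' `NPV = sp (1 - p) / ((1 - se) p + sp (1 - p))`, reported in percent.
#' Degenerate inputs with a zero denominator return `NaN` with a
#' warning.
#'
#' @param sensitivity,specificity percent, in \[0, 100\]; vectors recycle.
#' @param prevalence disease prevalence as a proportion in (0, 1).
#' @return A data.frame with columns `ppv` and `npv` (percent).
#' @examples
#' ppv_npv(86.9, 50.5, 92 / 290) # PPV 44.9, NPV 89.2
#' @export
ppv_npv <- function(sensitivity, specificity, prevalence) {
  if (any(sensitivity < 0 | sensitivity > 100) ||
      any(specificity < 0 | specificity > 100))
    stop("sensitivity and specificity must be percentages in [0, 100]",
         call. = FALSE)
  if (any(prevalence <= 0 | prevalence >= 1))
    stop("prevalence must lie strictly inside (0, 1)", call. = FALSE)
  se <- sensitivity / 100; sp <- specificity / 100; p <- prevalence
  d_ppv <- se * p + (1 - sp) * (1 - p)
  d_npv <- (1 - se) * p + sp * (1 - p)
  if (any(d_ppv == 0) || any(d_npv == 0))
    warning("degenerate operating point: a predictive value is undefined (0/0); returning NaN")
  data.frame(ppv = 100 * se * p / d_ppv,
             npv = 100 * sp * (1 - p) / d_npv)
}
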