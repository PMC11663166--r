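# Composite point scores: the two-region volumetric score (0-2) and the
# four-item score adding RAVLT immediate recall and APOE4 carriage (0-4).

#' Composite score specification
#'
#' A composite score sums one point per satisfied item.  Items are either
#' dichotomization rules on continuous markers (strict inequality at the
#' cutoff) or binary columns scoring one point when `TRUE`.
#'
#' @param rules list of [dichot_rule()] objects.
#' @param binary_items character vector of logical column names, each
#'   worth one point when `TRUE`.
#' @param name score name.
#' @return Object of class `score_spec`.
#' @seealso [volumetric_score_spec()], [four_item_score_spec()],
#'   [composite_score()]
#' @export
score_spec <- function(rules = list(), binary_items = character(),
                       name = "composite") {
  if (length(rules) && !all(vapply(rules, inherits, logical(1), "dichot_rule")))
    stop("'rules' must be a list of dichot_rule objects", call. = FALSE)
  markers <- c(vapply(rules, `[[`, character(1), "marker"), binary_items)
  k <- length(markers)
  if (k < 1 || k > 8) stop("a score must have between 1 and 8 items",
                           call. = FALSE)
  if (anyDuplicated(markers))
    stop("each marker may appear at most once", call. = FALSE)
  structure(list(rules = rules, binary_items = binary_items,
                 name = name, max_score = k),
            class = "score_spec")
}

#' Default two-region volumetric score (0-2)
#'
#' One point each for hippocampal volume < 6.94 ml and angular gyrus
#' volume < 7.80 ml (normalized volumes; the Youden-optimal reference
#' cutoffs of the source cohort).
#'
#' @return A `score_spec` with two items.
#' @export
volumetric_score_spec <- function() {
  score_spec(rules = list(
    dichot_rule("hippocampus_ml", "below", 6.94),
    dichot_rule("angular_gyrus_ml", "below", 7.80)),
    name = "volumetric")
}

#' Default four-item predictive score (0-4)
#'
#' The volumetric items plus one point for RAVLT immediate recall
#' < 42 points and one point for APOE4 carriage.
#'
#' @return A `score_spec` with four items.
#' @export
four_item_score_spec <- function() {
  score_spec(rules = list(
    dichot_rule("hippocampus_ml", "below", 6.94),
    dichot_rule("angular_gyrus_ml", "below", 7.80),
    dichot_rule("ravlt_immediate", "below", 42)),
    binary_items = "apoe4_carrier",
    name = "four_item")
}

#' Re-derive a score's cutoffs on a cohort
#'
#' Replaces each rule's cutoff with the Youden-optimal cutoff computed on
#' the given cohort (binary items are unchanged).  This is the
#' alternative to the frozen default cutoffs.
#'
#' @param spec a `score_spec`.
#' @param cohort cohort data.frame.
#' @param labels binary labels (default the cohort's `amyloid_positive`).
#' @return A `score_spec` with refitted cutoffs.
#' @export
refit_score_cutoffs <- function(spec, cohort,
                                labels = cohort$amyloid_positive) {
  spec$rules <- lapply(spec$rules, function(r) {
    youden_cutoff(cohort[[r$marker]], labels, direction = r$direction,
                  marker = r$marker)
  })
  spec
}

#' @export
print.score_spec <- function(x, ...) {
  cat(sprintf("Composite score '%s' (0-%d points):\n", x$name, x$max_score))
  for (r in x$rules) {
    op <- if (r$direction == "below") "<" else ">"
    cat(sprintf("  +1 if %s %s %.4g\n", r$marker, op, r$cutoff))
  }
  for (b in x$binary_items) cat(sprintf("  +1 if %s\n", b))
  invisible(x)
}

#' Compute a composite score per record
#'
#' Sums the satisfied items of a [score_spec()] for each cohort row,
#' with strict inequalities at the cutoffs.  Records missing any item
#' value score `NA` (complete-case policy: each downstream evaluation
#' drops them and uses its own subset's prevalence).
#'
#' @param cohort cohort data.frame.
#' @param spec a `score_spec`.
#' @return Integer vector of scores in `0..max_score`, `NA` where any
#'   item is missing.
#' @examples
#' cohort <- data.frame(hippocampus_ml = c(6.5, 6.94),
#'                      angular_gyrus_ml = c(7.5, 9),
#'                      ravlt_immediate = c(38, 50),
#'                      apoe4_carrier = c(TRUE, FALSE))
#' composite_score(cohort, four_item_score_spec()) # 4, 0
#' @export
composite_score <- function(cohort, spec) {
  needed <- c(vapply(spec$rules, `[[`, character(1), "marker"),
              spec$binary_items)
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols))
    stop(sprintf("cohort lacks score item column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  pts <- matrix(NA, nrow = nrow(cohort),
                ncol = length(spec$rules) + length(spec$binary_items))
  j <- 0L
  for (r in spec$rules) {
    j <- j + 1L
    pts[, j] <- apply_rule(r, cohort[[r$marker]])
  }
  for (b in spec$binary_items) {
    j <- j + 1L
    pts[, j] <- as.logical(cohort[[b]])
  }
  as.integer(rowSums(pts))
}

#' Select the most discriminative region per anatomical group
#'
#' For each candidate region the empirical Mann-Whitney AUC against
#' amyloid status is computed (lower volume = more positive), averaging
#' left/right variants per record first when a base column is absent but
#' `<region>_left`/`<region>_right` columns exist.  The candidate with
#' the highest AUC is returned from each group; ties break
#' alphabetically by region name.
#'
#' @param cohort cohort data.frame with an `amyloid_positive` column.
#' @param medial_temporal_candidates,cortical_candidates character
#'   vectors of volume column names.
#' @return List with elements `medial_temporal`, `cortical` (selected
#'   names) and `auc` (named vector of all candidate AUCs).
#' @export
select_regions <- function(cohort, medial_temporal_candidates,
                           cortical_candidates) {
  if (!length(medial_temporal_candidates) || !length(cortical_candidates))
    stop("both candidate sets must be non-empty", call. = FALSE)
  region_values <- function(r) {
    if (r %in% names(cohort)) return(cohort[[r]])
    lr <- paste0(r, c("_left", "_right"))
    if (all(lr %in% names(cohort)))
      return(rowMeans(cohort[, lr]))
    stop(sprintf("candidate region '%s' not found in cohort", r),
         call. = FALSE)
  }
  all_cand <- sort(unique(c(medial_temporal_candidates, cortical_candidates)))
  aucs <- vapply(all_cand, function(r)
    delong_auc_ci(region_values(r), cohort$amyloid_positive,
                  direction = "below")$auc, numeric(1))
  pick <- function(cands) {
    cands <- sort(cands)
    cands[which.max(aucs[cands])]
  }
  list(medial_temporal = pick(medial_temporal_candidates),
       cortical = pick(cortical_candidates),
       auc = aucs)
}

#' Evaluate a discrete score over all its thresholds
#'
#' For each threshold t in 1..k the rule "score >= t is test-positive"
#' is evaluated: sensitivity and specificity from the observed counts,
#' PPV/NPV via Bayes' rule at the analysis subset's prevalence (or a
#' supplied one), and the score's AUC (Mann-Whitney on the ordinal
#' score) with a DeLong confidence interval.  Records with missing
#' scores or labels are dropped first (complete-case).
#'
#' @param scores integer scores in 0..k (`NA` allowed, dropped).
#' @param labels binary reference labels.
#' @param k maximum score (default: observed maximum).
#' @param prevalence prevalence used for PPV/NPV; defaults to the
#'   analysis subset's own positive fraction.
#' @param conf_level confidence level for the AUC CI.
#' @param name evaluation label.
#' @return Object of class `score_evaluation`: list with `table`
#'   (data.frame threshold/sensitivity/specificity/ppv/npv, percent),
#'   `auc` (an `auc_ci`), `n`, `n_pos`, `prevalence`, `name`.
#'   Sensitivity is non-increasing and specificity non-decreasing down
#'   the rows (asserted).
#' @examples
#' set.seed(1)
#' sc <- rbinom(100, 4, 0.5); y <- sc + rbinom(100, 2, 0.5) >= 4
#' evaluate_thresholds(sc, y)
#' @export
evaluate_thresholds <- function(scores, labels, k = NULL, prevalence = NULL,
                                conf_level = 0.95, name = "score") {
  labels <- as_binary_labels(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (any(scores != round(scores)))
    stop("scores must be integers", call. = FALSE)
  check_two_classes(labels, min_each = 2L)
  k <- k %||% max(scores)
  if (k < 1) stop("maximum score must be at least 1", call. = FALSE)
  prev <- prevalence %||% mean(labels)
  rows <- t(vapply(seq_len(k), function(t)
    sens_spec_at(scores, labels, t), numeric(2)))
  pv <- ppv_npv(rows[, "sens"], rows[, "spec"], prev)
  tab <- data.frame(threshold = seq_len(k),
                    sensitivity = rows[, "sens"],
                    specificity = rows[, "spec"],
                    ppv = pv$ppv, npv = pv$npv)
  stopifnot(all(diff(tab$sensitivity) <= 1e-9),
            all(diff(tab$specificity) >= -1e-9))
  auc <- delong_auc_ci(scores, labels, direction = "above",
                       conf_level = conf_level)
  structure(list(table = tab, auc = auc, n = length(scores),
                 n_pos = sum(labels), prevalence = prev, name = name),
            class = "score_evaluation")
}

#' @export
print.score_evaluation <- function(x, ...) {
  cat(sprintf("Evaluation of score '%s' (n = %d, %d positive, prevalence %.1f%%)\n",
              x$name, x$n, x$n_pos, 100 * x$prevalence))
  tab <- x$table
  out <- data.frame(threshold = paste0(">= ", tab$threshold),
                    sensitivity = sprintf("%.1f", tab$sensitivity),
                    specificity = sprintf("%.1f", tab$specificity),
                    ppv = sprintf("%.1f", tab$ppv),
                    npv = sprintf("%.1f", tab$npv))
  print(out, row.names = FALSE)
  cat(sprintf("AUC %.3f (%.0f%% CI %.3f-%.3f)\n", x$auc$auc,
              100 * x$auc$conf_level, x$auc$ci_low, x$auc$ci_high))
  invisible(x)
}

#' @export
as.data.frame.score_evaluation <- function(x, ...) {
  tab <- x$table
  tab$auc <- x$auc$auc
  tab$ci_low <- x$auc$ci_low
  tab$ci_high <- x$auc$ci_high
  tab
}

#' @export
plot.score_evaluation <- function(x, ...) {
  pts <- data.frame(fpr = c(0, 1 - x$table$specificity / 100, 1),
                    tpr = c(0, x$table$sensitivity / 100, 1))
  pts <- pts[order(pts$fpr, pts$tpr), ]
  plot(pts$fpr, pts$tpr, type = "b", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("Score '%s' (AUC %.3f)", x$name, x$auc$auc), ...)
  abline(0, 1, col = "grey", lty = 3)
  invisible(x)
}

#' Write a threshold evaluation as CSV
#'
#' Columns: threshold, sensitivity, specificity, PPV, NPV, AUC, CI low,
#' CI high (the AUC columns repeat on every row).
#'
#' @param evaluation a `score_evaluation`.
#' @param path file path.
#' @export
write_evaluation <- function(evaluation, path) {
  write.csv(as.data.frame(evaluation), path, row.names = FALSE)
  invisible(path)
}
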