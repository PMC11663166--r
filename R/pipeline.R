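# End-to-end orchestration: simulate (optional) -> cutoffs -> score ->
# evaluate -> eligibility -> report tables, deterministic under one seed.

#' Read a pipeline configuration from JSON or YAML
#'
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return A named list.
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs",
           call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

# md5 of the canonical JSON serialization of the effective config.
config_digest <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Cohort summary table (demographics and cognition by amyloid group)
#'
#' Per-variable observed N, per-group mean (± SD) or percentage, and a
#' group-difference p-value: rank-based (Kruskal-Wallis) for continuous
#' variables, chi-squared for binary/categorical ones.
#'
#' @param cohort cohort data.frame with `amyloid_positive`.
#' @return data.frame with columns `variable`, `n`, `negative`,
#'   `positive`, `p_value`.
#' @export
cohort_summary <- function(cohort) {
  g <- cohort$amyloid_positive
  cont <- c("age", "education", "moca", "mmse", "ravlt_immediate")
  rows <- list()
  for (v in intersect(cont, names(cohort))) {
    x <- cohort[[v]]
    ok <- !is.na(x)
    p <- kruskal.test(x[ok], factor(g[ok]))$p.value
    rows[[v]] <- data.frame(
      variable = v, n = sum(ok),
      negative = fmt_mean_sd(mean(x[!g], na.rm = TRUE), sd(x[!g], na.rm = TRUE), 1),
      positive = fmt_mean_sd(mean(x[g], na.rm = TRUE), sd(x[g], na.rm = TRUE), 1),
      p_value = p)
  }
  if ("sex" %in% names(cohort)) {
    ok <- !is.na(cohort$sex)
    p <- suppressWarnings(
      chisq.test(table(cohort$sex[ok], g[ok]))$p.value)
    rows$sex <- data.frame(
      variable = "sex (% female)", n = sum(ok),
      negative = sprintf("%.1f%%", 100 * mean(cohort$sex[!g] == "female",
                                              na.rm = TRUE)),
      positive = sprintf("%.1f%%", 100 * mean(cohort$sex[g] == "female",
                                              na.rm = TRUE)),
      p_value = p)
  }
  if ("apoe4_carrier" %in% names(cohort)) {
    x <- cohort$apoe4_carrier
    ok <- !is.na(x)
    p <- suppressWarnings(chisq.test(table(x[ok], g[ok]))$p.value)
    rows$apoe4 <- data.frame(
      variable = "apoe4_carrier (%)", n = sum(ok),
      negative = sprintf("%.1f%%", 100 * mean(x[!g], na.rm = TRUE)),
      positive = sprintf("%.1f%%", 100 * mean(x[g], na.rm = TRUE)),
      p_value = p)
  }
  if ("diagnosis" %in% names(cohort)) {
    ok <- !is.na(cohort$diagnosis)
    p <- suppressWarnings(
      chisq.test(table(cohort$diagnosis[ok], g[ok]))$p.value)
    pct <- function(grp) {
      tb <- prop.table(table(factor(cohort$diagnosis[grp],
                                    c("SCI", "MCI", "dementia"))))
      sprintf("%.1f%% SCI, %.1f%% MCI, %.1f%% dementia",
              100 * tb[1], 100 * tb[2], 100 * tb[3])
    }
    rows$diagnosis <- data.frame(
      variable = "diagnosis", n = sum(ok),
      negative = pct(!g & ok), positive = pct(g & ok), p_value = p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group comparison of imaging markers with optional covariate adjustment
#'
#' Per-marker group means/SDs and a group-difference p-value.  With
#' `method = "ancova"` (the default for continuous imaging markers) the
#' p-value comes from a covariate-adjusted linear model
#' `marker ~ group + covariates`; an empty adjustment set reduces this
#' to the unadjusted two-group comparison.  `method = "rank"` uses the
#' Kruskal-Wallis test and ignores covariates.
#'
#' @param cohort cohort data.frame with `amyloid_positive`.
#' @param markers character vector of marker columns.
#' @param adjust_for covariate columns (default age and sex, which
#'   differ between the groups).
#' @param method `"ancova"` or `"rank"`.
#' @return data.frame with per-group formatted means, raw means/SDs and
#'   p-values.
#' @export
group_comparison <- function(cohort, markers,
                             adjust_for = c("age", "sex"),
                             method = c("ancova", "rank")) {
  method <- match.arg(method)
  adjust_for <- intersect(adjust_for, names(cohort))
  g <- cohort$amyloid_positive
  rows <- lapply(markers, function(v) {
    x <- cohort[[v]]
    if (is.null(x)) stop(sprintf("marker '%s' not in cohort", v),
                         call. = FALSE)
    if (var(x, na.rm = TRUE) == 0)
      stop(sprintf("marker '%s' is constant", v), call. = FALSE)
    if (method == "rank") {
      ok <- !is.na(x)
      p <- kruskal.test(x[ok], factor(g[ok]))$p.value
    } else {
      dat <- data.frame(.y = x, .g = g,
                        cohort[, adjust_for, drop = FALSE])
      fml <- as.formula(paste(".y ~ .g",
                              if (length(adjust_for))
                                paste("+", paste(adjust_for, collapse = " + "))
                              else ""))
      fit <- lm(fml, data = dat)
      p <- summary(fit)$coefficients[".gTRUE", "Pr(>|t|)"]
    }
    data.frame(marker = v,
               mean_neg = mean(x[!g], na.rm = TRUE),
               sd_neg = sd(x[!g], na.rm = TRUE),
               mean_pos = mean(x[g], na.rm = TRUE),
               sd_pos = sd(x[g], na.rm = TRUE),
               negative = fmt_mean_sd(mean(x[!g], na.rm = TRUE),
                                      sd(x[!g], na.rm = TRUE)),
               positive = fmt_mean_sd(mean(x[g], na.rm = TRUE),
                                      sd(x[g], na.rm = TRUE)),
               p_value = p, method = method)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Visual scale vs computed counterpart: AUC each with CI, paired DeLong p.
default_rating_pairs <- function() {
  list(c("visual_mta", "computed_mta"),
       c("visual_pa", "computed_pa"),
       c("visual_gca", "computed_gca_frontal"),
       c("visual_fazekas", "computed_fazekas"))
}

#' Compare visual and computed rating scale AUCs
#'
#' For each (visual, computed) scale pair the per-marker AUC with DeLong
#' CI is computed (higher rating = more positive) and the two correlated
#' AUCs are compared with the paired DeLong test on the records scored
#' by both.
#'
#' @param cohort cohort data.frame with `amyloid_positive`.
#' @param pairs list of length-2 character vectors (visual, computed).
#' @return data.frame with one row per marker and the pairwise p-value
#'   attached to each pair's rows.
#' @export
auc_comparison <- function(cohort, pairs = default_rating_pairs()) {
  labels <- cohort$amyloid_positive
  rows <- list()
  for (pr in pairs) {
    pr <- intersect(pr, names(cohort))
    if (length(pr) < 2) next
    both <- complete.cases(cohort[, pr]) & !is.na(labels)
    tst <- delong_paired_test(cohort[[pr[1]]][both], cohort[[pr[2]]][both],
                              labels[both])
    for (m in pr) {
      ac <- delong_auc_ci(cohort[[m]][both], labels[both])
      rows[[m]] <- data.frame(marker = m, auc = ac$auc,
                              ci_low = ac$ci_low, ci_high = ac$ci_high,
                              pair = paste(pr, collapse = " vs "),
                              delong_p = tst$p.value)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full amyloid-prediction pipeline
#'
#' Executes simulate (optional) -> GMM cutoffs -> composite scores ->
#' threshold evaluation -> eligibility -> report tables.  Deterministic
#' given the seed; each stage logs its record count to stderr.
#'
#' The configuration is a named list (or a path readable by
#' [read_pipeline_config()]) with optional entries:
#' \describe{
#'   \item{cohort_csv}{path to an existing cohort CSV; when absent a
#'     synthetic cohort is simulated from [cohort_config()].}
#'   \item{seed}{root seed (can also be given as the `seed` argument,
#'     which wins); stage seeds are split deterministically from it.}
#'   \item{n_negative, n_positive}{synthetic group sizes.}
#'   \item{cutoff_mode}{`"frozen"` (default: published score cutoffs) or
#'     `"youden"` (re-derived on the input cohort).}
#'   \item{conf_level}{confidence level for AUC CIs (default 0.95).}
#' }
#'
#' @param config named list or config file path.
#' @param seed root seed overriding the config's.
#' @param quiet suppress stage logging.
#' @return Object of class `report_bundle` with the cohort, per-assay
#'   GMM fits and derived cutoffs, the score specs used, evaluations for
#'   amyloid status and eligibility, and the four report tables
#'   (`summary`, `group_comparison`, `auc_comparison`, plus the
#'   evaluations), and a provenance block (config digest, seed, package
#'   version).
#' @examples
#' \donttest{
#' bundle <- run_pipeline(list(seed = 11), quiet = TRUE)
#' bundle
#' }
#' @export
run_pipeline <- function(config = list(), seed = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  seed <- seed %||% config$seed %||% 1L
  config$seed <- seed
  log_stage <- function(fmt, ...) {
    if (!quiet) message(sprintf(paste0("[amyloidscreen] ", fmt), ...))
  }
  t0 <- proc.time()[["elapsed"]]

  # stage 1: cohort
  if (!is.null(config$cohort_csv)) {
    cohort <- read_cohort(config$cohort_csv)
    required <- c("abeta_ratio", "csf_assay")
    miss <- setdiff(required, names(cohort))
    if (length(miss))
      stop(sprintf("input cohort lacks required column(s): %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    ccfg <- NULL
  } else {
    ccfg <- cohort_config(
      n_negative = config$n_negative %||% 198L,
      n_positive = config$n_positive %||% 92L)
    cohort <- simulate_cohort(ccfg, seed = derive_seed(seed, 0L))
  }
  log_stage("cohort: %d records", nrow(cohort))

  # stage 2: data-driven CSF cutoffs per assay
  gmm_fits <- list()
  derived <- list()
  for (a in unique(cohort$csf_assay[!is.na(cohort$csf_assay)])) {
    vals <- cohort$abeta_ratio[cohort$csf_assay == a]
    fit <- fit_csf_gmm(vals[is.finite(vals)], k = 2,
                       seed = derive_seed(seed, 2L))
    gmm_fits[[a]] <- fit
    derived[[a]] <- as.numeric(derive_cutoff(fit))
  }
  log_stage("cutoffs: %s",
            paste(sprintf("%s %.3f", names(derived), unlist(derived)),
                  collapse = ", "))
  if (is.null(cohort$amyloid_positive) || all(is.na(cohort$amyloid_positive))) {
    dcut <- assay_cutoffs(innotest = derived$Innotest %||% 0.60,
                          lumipulse = derived$Lumipulse %||% 0.86)
    cohort$amyloid_positive <- classify_amyloid(cohort$abeta_ratio,
                                                cohort$csf_assay, dcut)
  }

  # stage 3: composite scores
  vol_spec <- volumetric_score_spec()
  four_spec <- four_item_score_spec()
  if (identical(config$cutoff_mode, "youden")) {
    vol_spec <- refit_score_cutoffs(vol_spec, cohort)
    four_spec <- refit_score_cutoffs(four_spec, cohort)
  }
  score_vol <- composite_score(cohort, vol_spec)
  score_four <- composite_score(cohort, four_spec)
  log_stage("scores: volumetric complete-case n = %d, four-item n = %d",
            sum(!is.na(score_vol)), sum(!is.na(score_four)))

  # stage 4: evaluation against amyloid status
  conf_level <- config$conf_level %||% 0.95
  eval_vol <- evaluate_thresholds(score_vol, cohort$amyloid_positive,
                                  k = vol_spec$max_score,
                                  conf_level = conf_level,
                                  name = "volumetric vs amyloid")
  eval_four <- evaluate_thresholds(score_four, cohort$amyloid_positive,
                                   k = four_spec$max_score,
                                   conf_level = conf_level,
                                   name = "four_item vs amyloid")

  # stage 5: eligibility
  criteria <- eligibility_criteria()
  elig <- assess_eligibility(cohort, criteria)
  log_stage("eligibility: %d of %d records eligible",
            sum(elig$eligible), nrow(cohort))
  elig_vol <- eligibility_evaluation(cohort, criteria, vol_spec,
                                     conf_level = conf_level)
  elig_four <- eligibility_evaluation(cohort, criteria, four_spec,
                                      conf_level = conf_level)

  # stage 6: report tables
  t_summary <- cohort_summary(cohort)
  t_groups <- group_comparison(cohort,
                               markers = intersect(
                                 c("visual_mta", "computed_mta", "visual_pa",
                                   "computed_pa", "visual_gca",
                                   "computed_gca_frontal",
                                   "computed_gca_occipital", "visual_fazekas",
                                   "computed_fazekas", "hippocampus_ml",
                                   "angular_gyrus_ml"),
                                 names(cohort)))
  t_auc <- auc_comparison(cohort)
  log_stage("report: done in %.1f s", proc.time()[["elapsed"]] - t0)

  structure(list(
    cohort = cohort, cohort_config = ccfg,
    gmm_fits = gmm_fits, derived_cutoffs = derived,
    score_specs = list(volumetric = vol_spec, four_item = four_spec),
    scores = data.frame(id = cohort$id, volumetric = score_vol,
                        four_item = score_four),
    eligibility = elig, criteria = criteria,
    evaluations = list(amyloid_volumetric = eval_vol,
                       amyloid_four_item = eval_four,
                       eligibility_volumetric = elig_vol,
                       eligibility_four_item = elig_four),
    tables = list(summary = t_summary, group_comparison = t_groups,
                  auc_comparison = t_auc),
    provenance = list(seed = seed, config_digest = config_digest(config),
                      package_version = as.character(
                        packageVersion("amyloidscreen")))),
    class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Amyloid-prediction report bundle\n")
  cat(sprintf("  cohort: %d records, %d amyloid-positive, %d treatment-eligible\n",
              nrow(x$cohort), sum(x$cohort$amyloid_positive, na.rm = TRUE),
              sum(x$eligibility$eligible)))
  if (length(x$derived_cutoffs))
    cat(sprintf("  GMM cutoffs: %s\n",
                paste(sprintf("%s %.3f", names(x$derived_cutoffs),
                              unlist(x$derived_cutoffs)), collapse = ", ")))
  for (nm in names(x$evaluations)) {
    e <- x$evaluations[[nm]]
    cat(sprintf("  %-25s AUC %.3f (%.3f-%.3f)\n", nm, e$auc$auc,
                e$auc$ci_low, e$auc$ci_high))
  }
  cat(sprintf("  provenance: seed %s, config %s, version %s\n",
              x$provenance$seed,
              substr(x$provenance$config_digest, 1, 8),
              x$provenance$package_version))
  invisible(x)
}

#' Write a report bundle to a directory of CSV/JSON files
#'
#' Writes `cohort.csv`, `scores.csv`, `eligibility.csv`, the report
#' tables (`table_summary.csv`, `table_group_comparison.csv`,
#' `table_auc_comparison.csv`, and one `table_evaluation_<name>.csv` per
#' evaluation), `cutoffs.json`, and `provenance.json`.  Reruns with the
#' same config and seed produce byte-identical files.
#'
#' @param bundle a `report_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(bundle$cohort, file.path(dir, "cohort.csv"))
  write.csv(bundle$scores, file.path(dir, "scores.csv"), row.names = FALSE,
            na = "")
  write.csv(cbind(id = bundle$cohort$id, bundle$eligibility),
            file.path(dir, "eligibility.csv"), row.names = FALSE)
  for (nm in names(bundle$tables))
    write.csv(bundle$tables[[nm]], file.path(dir, paste0("table_", nm, ".csv")),
              row.names = FALSE)
  for (nm in names(bundle$evaluations))
    write_evaluation(bundle$evaluations[[nm]],
                     file.path(dir, paste0("table_evaluation_", nm, ".csv")))
  jsonlite::write_json(bundle$derived_cutoffs,
                       file.path(dir, "cutoffs.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(bundle$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
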