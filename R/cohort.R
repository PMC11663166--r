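#' Default synthetic memory-clinic cohort configuration
#'
#' Returns the configuration of the synthetic cohort generator.  The
#' defaults encode the published group-level structure of a real-world
#' memory clinic population of 290 patients referred for diagnostic
#' work-up of cognitive complaints: 198 CSF-amyloid-negative and 92
#' amyloid-positive participants, per-group Gaussian marker distributions
#' (normalized brain volumes in ml, cognitive test scores, visual and
#' computed atrophy rating scales), per-group binary rates (APOE4
#' carriage, anticoagulant use, MRI availability), clinical diagnosis
#' proportions, a per-assay two-component CSF Abeta42/Abeta40 ratio
#' mixture, and per-variable missingness counts.
#'
#' Markers are generated conditionally independent given amyloid group:
#' only per-group marginals are encoded, so any real-world correlation
#' between, say, hippocampal volume and memory performance is absent by
#' construction.  Continuous scores are clipped to their valid ranges and
#' integer scales rounded; clipping bounds live in the config so the
#' unclipped Gaussian case remains testable.
#'
#' @param n_negative,n_positive fixed group sizes (not sampled).
#' @param seed optional default seed stored with the config.
#' @return An object of class `cohort_config`: a list with elements
#'   `n_negative`, `n_positive`, `markers` (per-marker list of per-group
#'   `mean`/`sd`, `bounds`, `integer` flag), `binary` (per-variable
#'   per-group rates), `diagnosis` (per-group proportions over
#'   SCI/MCI/dementia), `etiology_negative` (proportions of etiology tags
#'   in the amyloid-negative group), `assay_innotest_prop`, `csf`
#'   (per-assay mixture component means/sds; component 1 is the
#'   amyloid-positive, low-ratio component), `cutoffs` (an
#'   [assay_cutoffs()] object), and `missing_n` (observed N per variable
#'   at the reference cohort size of 290).
#' @examples
#' cfg <- cohort_config()
#' cfg$n_positive
#' cfg$markers$hippocampus_ml
#' @seealso [generate_cohort()], [apply_missingness()], [simulate_cohort()]
#' @export
cohort_config <- function(n_negative = 198L, n_positive = 92L, seed = NULL) {
  marker <- function(m_neg, s_neg, m_pos, s_pos, lower, upper, integer = FALSE)
    list(negative = c(mean = m_neg, sd = s_neg),
         positive = c(mean = m_pos, sd = s_pos),
         bounds = c(lower = lower, upper = upper), integer = integer)
  cfg <- list(
    n_negative = as.integer(n_negative),
    n_positive = as.integer(n_positive),
    markers = list(
      age                   = marker(58.4, 7.1, 62.8, 5.8, 18, 100),
      education             = marker(13.7, 3.4, 13.6, 3.0, 0, 30, TRUE),
      moca                  = marker(23.4, 4.6, 20.3, 5.7, 0, 30, TRUE),
      mmse                  = marker(26.5, 3.9, 24.8, 4.5, 0, 30, TRUE),
      ravlt_immediate       = marker(44.6, 12.7, 35.8, 13.4, 0, 75, TRUE),
      hippocampus_ml        = marker(6.88, 0.95, 6.33, 0.92, 0.5, Inf),
      angular_gyrus_ml      = marker(8.82, 1.11, 7.96, 1.26, 0.5, Inf),
      visual_mta            = marker(0.74, 0.71, 0.97, 0.71, 0, 4, TRUE),
      visual_pa             = marker(0.62, 0.70, 0.80, 0.70, 0, 3, TRUE),
      visual_gca            = marker(0.86, 0.63, 1.17, 0.68, 0, 3, TRUE),
      visual_fazekas        = marker(1.00, 0.70, 1.07, 0.63, 0, 3, TRUE),
      computed_mta          = marker(0.45, 0.73, 0.82, 0.86, 0, 4),
      computed_pa           = marker(0.58, 0.78, 1.09, 0.90, 0, 3),
      computed_gca_frontal  = marker(0.68, 0.86, 1.17, 1.01, 0, 3),
      computed_gca_occipital = marker(0.55, 0.73, 0.94, 0.82, 0, 3),
      computed_fazekas      = marker(0.68, 0.91, 0.68, 0.91, 0, 3)
    ),
    binary = list(
      female        = c(negative = 0.585, positive = 0.554),
      apoe4_carrier = c(negative = 0.298, positive = 0.696),
      anticoagulant = c(negative = 0.08, positive = 0.10),
      mri_available = c(negative = 1.0, positive = 1.0)
    ),
    diagnosis = list(
      negative = c(SCI = 0.671, MCI = 0.191, dementia = 0.136) / 0.998,
      positive = c(SCI = 0.228, MCI = 0.250, dementia = 0.521) / 0.999
    ),
    etiology_negative = c(unspecified = 142, psychiatric = 20, vascular = 7,
                          alcohol = 6, FTD = 5, other = 18) / 198,
    assay_innotest_prop = 0.45,
    csf = list(
      Innotest  = list(means = c(0.44, 0.96), sds = c(0.075, 0.16)),
      Lumipulse = list(means = c(0.65, 1.28), sds = c(0.10, 0.20))
    ),
    cutoffs = assay_cutoffs(),
    missing_n = c(education = 267, moca = 282, mmse = 232,
                  apoe4_carrier = 280, ravlt_immediate = 254),
    missing_reference_n = 290L,
    seed = seed
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_negative <= 0 || cfg$n_positive <= 0)
    stop("group sizes must be positive", call. = FALSE)
  for (nm in names(cfg$markers)) {
    m <- cfg$markers[[nm]]
    if (m$negative["sd"] <= 0 || m$positive["sd"] <= 0)
      stop(sprintf("marker '%s' has non-positive sd", nm), call. = FALSE)
  }
  for (nm in names(cfg$binary)) {
    r <- cfg$binary[[nm]]
    if (any(r < 0 | r > 1))
      stop(sprintf("binary rate '%s' outside [0,1]", nm), call. = FALSE)
  }
  for (g in names(cfg$diagnosis)) {
    p <- cfg$diagnosis[[g]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop(sprintf("diagnosis proportions for group '%s' must sum to 1", g),
           call. = FALSE)
  }
  for (a in names(cfg$csf)) {
    if (any(cfg$csf[[a]]$sds <= 0))
      stop("CSF mixture sds must be positive", call. = FALSE)
  }
  if (cfg$assay_innotest_prop < 0 || cfg$assay_innotest_prop > 1)
    stop("assay mixture proportion outside [0,1]", call. = FALSE)
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic memory-clinic cohort configuration\n")
  cat(sprintf("  groups: %d amyloid-negative, %d amyloid-positive (prevalence %.1f%%)\n",
              x$n_negative, x$n_positive,
              100 * x$n_positive / (x$n_negative + x$n_positive)))
  cat(sprintf("  markers: %d Gaussian, %d binary; assays: %s\n",
              length(x$markers), length(x$binary),
              paste(names(x$csf), collapse = ", ")))
  cat(sprintf("  missingness configured for: %s\n",
              paste(names(x$missing_n), collapse = ", ")))
  invisible(x)
}

# Fixed column order of the cohort table / CSV serialization.
cohort_columns <- function() {
  c("id", "age", "sex", "education", "diagnosis", "etiology_tag",
    "moca", "mmse", "ravlt_immediate", "apoe4_carrier",
    "csf_assay", "abeta_ratio", "amyloid_positive",
    "hippocampus_ml", "angular_gyrus_ml",
    "visual_mta", "visual_gca", "visual_pa", "visual_fazekas",
    "computed_mta", "computed_pa", "computed_gca_frontal",
    "computed_gca_occipital", "computed_fazekas",
    "anticoagulant", "mri_available")
}

# Draw one group's Gaussian marker: clip to bounds, round integer scales.
draw_marker <- function(n, par, group) {
  g <- par[[group]]
  x <- rnorm(n, g["mean"], g["sd"])
  x <- pmin(pmax(x, par$bounds["lower"]), par$bounds["upper"])
  if (isTRUE(par$integer)) x <- round(x)
  unname(x)
}

# CSF ratio for one record: the mixture component matching the record's
# group, rejection-sampled onto the correct side of the assay cutoff so
# the group label and the ratio never contradict.
draw_ratio <- function(n, mix, comp, cutoff, positive) {
  out <- numeric(n)
  need <- rep(TRUE, n)
  while (any(need)) {
    k <- sum(need)
    x <- rnorm(k, mix$means[comp], mix$sds[comp])
    ok <- if (positive) x > 0 & x < cutoff else x >= cutoff
    out[need][ok] <- x[ok]
    need[need] <- !ok
  }
  out
}

#' Generate a synthetic memory-clinic cohort
#'
#' Draws exactly `n_negative + n_positive` participant records with fixed
#' group sizes.  Continuous markers are per-group Gaussian draws clipped
#' to their valid ranges (integer scales rounded); binary variables are
#' per-group Bernoulli draws; the CSF Abeta42/Abeta40 ratio is drawn from
#' the assay-specific mixture component matching the record's amyloid
#' group, rejection-sampled so it falls on the correct side of the assay
#' cutoff.  The same `(config, seed)` pair always yields an identical
#' table.  No values are masked; see [apply_missingness()].
#'
#' @param config a [cohort_config()] object.
#' @param seed integer seed; defaults to the seed stored in `config`.
#' @return A `data.frame` with one row per participant and the columns
#'   documented in [write_cohort()], in fixed order.
#' @examples
#' cohort <- generate_cohort(cohort_config(), seed = 7)
#' nrow(cohort)                 # 290
#' sum(cohort$amyloid_positive) # 92
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  validate_cohort_config(config)
  if (is.null(seed)) stop("a seed is required for reproducible generation",
                          call. = FALSE)
  with_seed(seed, {
    n0 <- config$n_negative
    n1 <- config$n_positive
    n <- n0 + n1
    group <- rep(c(FALSE, TRUE), c(n0, n1))
    tab <- data.frame(id = sprintf("P%04d", seq_len(n)),
                      stringsAsFactors = FALSE)
    for (nm in names(config$markers)) {
      par <- config$markers[[nm]]
      tab[[nm]] <- c(draw_marker(n0, par, "negative"),
                     draw_marker(n1, par, "positive"))
    }
    for (nm in names(config$binary)) {
      r <- config$binary[[nm]]
      tab[[nm]] <- c(rbinom(n0, 1, r["negative"]),
                     rbinom(n1, 1, r["positive"])) == 1
    }
    tab$sex <- ifelse(tab$female, "female", "male")
    tab$female <- NULL
    tab$diagnosis <- c(
      sample(names(config$diagnosis$negative), n0, TRUE,
             prob = config$diagnosis$negative),
      sample(names(config$diagnosis$positive), n1, TRUE,
             prob = config$diagnosis$positive))
    # Amyloid-positive MCI/dementia present as typical amnestic AD;
    # negative-group etiologies follow the clinic's reported case mix.
    etio_neg <- sample(names(config$etiology_negative), n0, TRUE,
                       prob = config$etiology_negative)
    etio_pos <- ifelse(tab$diagnosis[group] == "SCI",
                       "unspecified", "AD-typical")
    tab$etiology_tag <- c(etio_neg, etio_pos)
    tab$csf_assay <- ifelse(runif(n) < config$assay_innotest_prop,
                            "Innotest", "Lumipulse")
    tab$amyloid_positive <- group
    cuts <- c(Innotest = config$cutoffs$innotest,
              Lumipulse = config$cutoffs$lumipulse)
    tab$abeta_ratio <- NA_real_
    for (a in names(config$csf)) {
      for (pos in c(FALSE, TRUE)) {
        i <- tab$csf_assay == a & group == pos
        if (!any(i)) next
        tab$abeta_ratio[i] <- draw_ratio(sum(i), config$csf[[a]],
                                         comp = if (pos) 1L else 2L,
                                         cutoff = cuts[[a]], positive = pos)
      }
    }
    tab[, cohort_columns()]
  })
}

#' Mask values completely at random to match configured observed counts
#'
#' Reproduces the per-variable missingness of the reference cohort:
#' for each configured variable the observed N (out of the reference size
#' of 290) is scaled proportionally to the actual cohort size and values
#' are masked uniformly at random until the observed count matches.
#' `id` and `amyloid_positive` are never masked; masking is independent
#' of amyloid status (missing completely at random).
#'
#' @param table cohort table from [generate_cohort()].
#' @param config a [cohort_config()] whose `missing_n` entry gives the
#'   observed N per variable.
#' @param seed integer seed.
#' @return The table with `NA`s inserted.
#' @examples
#' cohort <- generate_cohort(cohort_config(), seed = 7)
#' cohort <- apply_missingness(cohort, cohort_config(), seed = 8)
#' sum(!is.na(cohort$ravlt_immediate)) # 254
#' @export
apply_missingness <- function(table, config, seed) {
  n <- nrow(table)
  ref <- config$missing_reference_n %||% 290L
  with_seed(seed, {
    for (nm in names(config$missing_n)) {
      if (nm %in% c("id", "amyloid_positive")) next
      if (!nm %in% names(table)) next
      observed <- round(config$missing_n[[nm]] * n / ref)
      if (observed > n)
        stop(sprintf("configured observed N for '%s' exceeds cohort size", nm),
             call. = FALSE)
      n_miss <- n - observed
      if (n_miss <= 0) next
      table[[nm]][sample.int(n, n_miss)] <- NA
    }
    table
  })
}

#' Generate a cohort and apply its configured missingness
#'
#' Convenience wrapper composing [generate_cohort()] and
#' [apply_missingness()] with deterministically split seeds.
#'
#' @inheritParams generate_cohort
#' @return A cohort `data.frame`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = config$seed) {
  tab <- generate_cohort(config, seed)
  apply_missingness(tab, config, derive_seed(seed, 1L))
}

#' Write / read a cohort table as CSV
#'
#' The CSV has a fixed, documented column order with literal header names
#' matching the participant-record fields: `id`, `age`, `sex`,
#' `education`, `diagnosis`, `etiology_tag`, `moca`, `mmse`,
#' `ravlt_immediate`, `apoe4_carrier`, `csf_assay`, `abeta_ratio`,
#' `amyloid_positive`, `hippocampus_ml`, `angular_gyrus_ml`,
#' `visual_mta`, `visual_gca`, `visual_pa`, `visual_fazekas`,
#' `computed_mta`, `computed_pa`, `computed_gca_frontal`,
#' `computed_gca_occipital`, `computed_fazekas`, `anticoagulant`,
#' `mri_available`.  Missing values are written as empty cells.
#'
#' @param table cohort table.
#' @param path file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns
#'   the cohort `data.frame` with logical flag columns restored.
#' @export
write_cohort <- function(table, path) {
  cols <- intersect(cohort_columns(), names(table))
  extra <- setdiff(names(table), cols)
  write.csv(table[, c(cols, extra)], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE,
                  na.strings = c("", "NA"))
  for (nm in c("apoe4_carrier", "amyloid_positive", "anticoagulant",
               "mri_available")) {
    if (nm %in% names(tab)) tab[[nm]] <- as.logical(tab[[nm]])
  }
  tab
}
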