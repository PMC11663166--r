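test_that("default config encodes the published cohort structure", {
  cfg <- cohort_config()
  expect_equal(cfg$n_negative, 198L)
  expect_equal(cfg$n_positive, 92L)
  expect_equal(unname(cfg$markers$hippocampus_ml$negative), c(6.88, 0.95))
  expect_equal(unname(cfg$markers$hippocampus_ml$positive), c(6.33, 0.92))
  expect_equal(unname(cfg$markers$angular_gyrus_ml$negative), c(8.82, 1.11))
  expect_equal(unname(cfg$markers$angular_gyrus_ml$positive), c(7.96, 1.26))
  expect_equal(unname(cfg$markers$ravlt_immediate$negative), c(44.6, 12.7))
  expect_equal(unname(cfg$markers$ravlt_immediate$positive), c(35.8, 13.4))
  expect_equal(unname(cfg$binary$apoe4_carrier), c(0.298, 0.696))
  expect_equal(unname(cfg$markers$computed_mta$negative), c(0.45, 0.73))
  expect_equal(unname(cfg$markers$computed_mta$positive), c(0.82, 0.86))
  # diagnosis proportions normalized from the printed percentages
  expect_equal(unname(cfg$diagnosis$negative),
               c(0.671, 0.191, 0.136) / 0.998)
  expect_equal(unname(cfg$diagnosis$positive),
               c(0.228, 0.250, 0.521) / 0.999)
  expect_equal(sum(cfg$diagnosis$negative), 1)
  expect_equal(sum(cfg$diagnosis$positive), 1)
})

test_that("config validation rejects impossible parameters", {
  cfg <- cohort_config()
  cfg$markers$age$negative["sd"] <- -1
  expect_error(generate_cohort(cfg, seed = 1), "non-positive sd")
  expect_error(cohort_config(n_negative = 0), "positive")
  cfg2 <- cohort_config()
  cfg2$binary$apoe4_carrier["negative"] <- 1.4
  expect_error(generate_cohort(cfg2, seed = 1), "outside")
})

test_that("generated cohorts have fixed group sizes and exact prevalence", {
  cohort <- generate_cohort(cohort_config(), seed = 7)
  expect_equal(nrow(cohort), 290L)
  expect_equal(sum(cohort$amyloid_positive), 92L)
  small <- generate_cohort(cohort_config(n_negative = 30, n_positive = 10),
                           seed = 3)
  expect_equal(sum(small$amyloid_positive), 10L)
  expect_equal(nrow(small), 40L)
})

test_that("the same config and seed reproduce an identical table", {
  cfg <- cohort_config()
  expect_identical(generate_cohort(cfg, seed = 42),
                   generate_cohort(cfg, seed = 42))
  expect_identical(simulate_cohort(cfg, seed = 42),
                   simulate_cohort(cfg, seed = 42))
  expect_false(identical(generate_cohort(cfg, seed = 42),
                         generate_cohort(cfg, seed = 43)))
})

test_that("records respect scale ranges and positivity constraints", {
  cohort <- generate_cohort(cohort_config(), seed = 11)
  expect_true(all(cohort$visual_mta %in% 0:4))
  expect_true(all(cohort$visual_gca %in% 0:3))
  expect_true(all(cohort$visual_pa %in% 0:3))
  expect_true(all(cohort$visual_fazekas %in% 0:3))
  expect_true(all(cohort$moca >= 0 & cohort$moca <= 30))
  expect_true(all(cohort$mmse >= 0 & cohort$mmse <= 30))
  expect_true(all(cohort$moca == round(cohort$moca)))
  expect_true(all(cohort$hippocampus_ml > 0))
  expect_true(all(cohort$angular_gyrus_ml > 0))
  expect_true(all(cohort$abeta_ratio > 0))
  expect_true(all(cohort$computed_mta >= 0 & cohort$computed_mta <= 4))
})

test_that("amyloid labels agree with the ratio side of the assay cutoff", {
  cohort <- generate_cohort(cohort_config(), seed = 19)
  derived <- classify_amyloid(cohort$abeta_ratio, cohort$csf_assay)
  expect_identical(derived, cohort$amyloid_positive)
})

test_that("group marker means match the configuration within CLT bounds", {
  cohort <- generate_cohort(cohort_config(), seed = 7)
  hip_pos <- cohort$hippocampus_ml[cohort$amyloid_positive]
  expect_lt(abs(mean(hip_pos) - 6.33), 3 * 0.92 / sqrt(92))
  hip_neg <- cohort$hippocampus_ml[!cohort$amyloid_positive]
  expect_lt(abs(mean(hip_neg) - 6.88), 3 * 0.95 / sqrt(198))
})

test_that("marginals recover configured means, sds and rates across seeds", {
  cfg <- cohort_config()
  stats <- vapply(1:200, function(s) {
    co <- generate_cohort(cfg, seed = s)
    pos <- co$amyloid_positive
    c(m_hip = mean(co$hippocampus_ml[pos]),
      s_hip = sd(co$hippocampus_ml[pos]),
      m_ang = mean(co$angular_gyrus_ml[!pos]),
      apoe = mean(co$apoe4_carrier[pos]))
  }, numeric(4))
  m <- rowMeans(stats)
  # mean of 200 per-seed estimates: SE shrinks by sqrt(200)
  expect_lt(abs(m["m_hip"] - 6.33), 3 * 0.92 / sqrt(92 * 200))
  expect_lt(abs(m["m_ang"] - 8.82), 3 * 1.11 / sqrt(198 * 200))
  expect_lt(abs(m["s_hip"] - 0.92), 0.02)
  expect_lt(abs(m["apoe"] - 0.696),
            3 * sqrt(0.696 * 0.304 / (92 * 200)))
})

test_that("missingness reproduces the published per-variable observed N", {
  cfg <- cohort_config()
  cohort <- apply_missingness(generate_cohort(cfg, seed = 5), cfg, seed = 6)
  expect_equal(sum(!is.na(cohort$education)), 267L)
  expect_equal(sum(!is.na(cohort$moca)), 282L)
  expect_equal(sum(!is.na(cohort$mmse)), 232L)
  expect_equal(sum(!is.na(cohort$apoe4_carrier)), 280L)
  expect_equal(sum(!is.na(cohort$ravlt_immediate)), 254L)
  expect_false(anyNA(cohort$id))
  expect_false(anyNA(cohort$amyloid_positive))
  # proportional scaling for non-default sizes
  cfg2 <- cohort_config(n_negative = 100, n_positive = 45)
  co2 <- apply_missingness(generate_cohort(cfg2, seed = 5), cfg2, seed = 6)
  expect_equal(sum(!is.na(co2$ravlt_immediate)), round(254 * 145 / 290))
})

test_that("zero-missingness config leaves the table unchanged", {
  cfg <- cohort_config()
  cohort <- generate_cohort(cfg, seed = 5)
  cfg$missing_n <- cfg$missing_n[0]
  expect_identical(apply_missingness(cohort, cfg, seed = 6), cohort)
})

test_that("missingness cannot exceed the cohort size", {
  cfg <- cohort_config(n_negative = 10, n_positive = 5)
  cfg$missing_reference_n <- 10L
  cohort <- generate_cohort(cfg, seed = 1)
  expect_error(apply_missingness(cohort, cfg, seed = 2), "exceeds cohort size")
})

test_that("masking is independent of amyloid status (MCAR)", {
  cfg <- cohort_config()
  base <- generate_cohort(cfg, seed = 100)
  # pool masked-vs-group counts over 100 seeds and chi-square the total
  counts <- matrix(0, 2, 2)
  for (s in 1:100) {
    m <- apply_missingness(base, cfg, seed = s)
    masked <- is.na(m$ravlt_immediate)
    counts <- counts + table(masked, base$amyloid_positive)
  }
  expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("cohort CSV round-trips with fixed header order and empty NAs", {
  cfg <- cohort_config()
  cohort <- simulate_cohort(cfg, seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  expect_identical(gsub('"', "", header)[1:5],
                   c("id", "age", "sex", "education", "diagnosis"))
  back <- read_cohort(path)
  expect_equal(back$abeta_ratio, cohort$abeta_ratio)
  expect_identical(back$amyloid_positive, cohort$amyloid_positive)
  expect_identical(is.na(back$ravlt_immediate), is.na(cohort$ravlt_immediate))
})
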