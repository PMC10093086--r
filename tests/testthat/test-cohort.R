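test_that("label allocation is exact-count and lateralities are recorded", {
  co <- sample_cohort(cohort_spec(n_cases = 100, prevalence = 0.5, seed = 7))
  cases <- dplyr::distinct(co, case_id, label, affected_laterality)
  expect_equal(nrow(cases), 100)
  expect_equal(sum(cases$label == "malignant"), 50)
  expect_true(all(cases$affected_laterality %in% c("left", "right")))
  # 99-case default matches the 49/50 structure
  co2 <- sample_cohort(cohort_spec(seed = 2))
  expect_equal(sum(dplyr::distinct(co2, case_id, label)$label == "malignant"),
               49)
})

test_that("sequence lengths and exam dates respect the cohort structure", {
  co <- sample_cohort(cohort_spec(n_cases = 1000, seed = 1))
  per_case <- co |>
    dplyr::filter(laterality == "left") |>
    dplyr::group_by(case_id) |>
    dplyr::summarise(n = dplyr::n(),
                     increasing = all(diff(time_years) > 0),
                     gaps = list(diff(time_years)), .groups = "drop")
  expect_true(all(per_case$n >= 2 & per_case$n <= 9))
  expect_true(all(per_case$increasing))
  gaps <- unlist(per_case$gaps)
  expect_true(all(gaps >= 0.5))
  expect_lt(abs(mean(gaps) - 1.27), 0.05)
})

test_that("cohorts are deterministic given the spec and validate inputs", {
  spec <- cohort_spec(n_cases = 30, seed = 5)
  expect_identical(sample_cohort(spec), sample_cohort(spec))
  expect_error(cohort_spec(prevalence = 1.2), "prevalence")
  expect_error(cohort_spec(seq_len_range = c(9, 2)), "seq_len_range")
})

test_that("the field effect puts the same drift in both breasts", {
  spec <- cohort_spec(n_cases = 60, drift_per_year = 0.4, field_effect = TRUE,
                      seed = 4)
  co <- sample_cohort(spec)
  # within a breast, beta(t) - beta(last exam) is pure drift (baseline and
  # asymmetry are constant per breast), so the two breasts must match exactly
  # for malignant cases and be zero for benign cases
  rel <- co |>
    dplyr::group_by(case_id, laterality) |>
    dplyr::arrange(exam_index, .by_group = TRUE) |>
    dplyr::mutate(dbeta = beta - beta[dplyr::n()]) |>
    dplyr::ungroup() |>
    dplyr::select(case_id, label, laterality, exam_index, years_before_last,
                  dbeta) |>
    tidyr::pivot_wider(names_from = laterality, values_from = dbeta)
  mal <- dplyr::filter(rel, label == "malignant")
  ben <- dplyr::filter(rel, label == "benign")
  expect_equal(mal$left, mal$right, tolerance = 1e-12)
  expect_equal(mal$left, -0.4 * 0.25 * mal$years_before_last,
               tolerance = 1e-12)
  expect_true(all(abs(ben$left) < 1e-12 & abs(ben$right) < 1e-12))

  # without the field effect only the affected breast drifts
  co2 <- sample_cohort(cohort_spec(n_cases = 60, drift_per_year = 0.4,
                                   field_effect = FALSE, seed = 4))
  contra <- co2 |>
    dplyr::filter(label == "malignant", !is_affected) |>
    dplyr::group_by(case_id) |>
    dplyr::summarise(drift = max(abs(beta - beta[dplyr::n()])),
                     .groups = "drop")
  expect_true(all(contra$drift < 1e-12))
})

test_that("feature sequences carry temporal but not single-timepoint signal", {
  spec <- cohort_spec(n_cases = 200, prevalence = 0.5, drift_per_year = 0.4,
                      seed = 3)
  df <- generate_feature_sequences(spec, dim = 50)
  expect_equal(length(feature_columns(df)), 50)
  aff <- dplyr::filter(df, is_affected)
  last <- select_last_prior(aff)
  y <- as.numeric(last$label == "malignant")
  expect_lt(oracle_auc(last$f01, y), 0.6)
  slopes <- aff |>
    dplyr::group_by(case_id, label) |>
    dplyr::summarise(sl = coef(lm(f01 ~ time_years))[[2]], .groups = "drop")
  expect_gt(oracle_auc(slopes$sl, as.numeric(slopes$label == "malignant")),
            0.75)
})

test_that("with zero drift the features are independent of the label", {
  spec <- cohort_spec(n_cases = 150, prevalence = 0.5, drift_per_year = 0,
                      seed = 6)
  df <- generate_feature_sequences(spec, dim = 5)
  last <- select_last_prior(dplyr::filter(df, is_affected))
  y <- as.numeric(last$label == "malignant")
  a <- oracle_auc(last$f01, y)
  # chance-level discrimination: within ~3 SE of 0.5 for n = 75 + 75
  expect_lt(abs(a - 0.5), 3 * sqrt(0.0833 * (1 / 75 + 1 / 75)))
  # sequence lengths delegated from the shared skeleton
  lens <- dplyr::count(dplyr::filter(df, is_affected), case_id)
  expect_true(all(lens$n >= 2 & lens$n <= 9))
})
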