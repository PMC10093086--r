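rank_auc <- function(score, y) {
  r <- rank(score)
  np <- sum(y == 1); nn <- sum(y == 0)
  (sum(r[y == 1]) - np * (np + 1) / 2) / (np * nn)
}

test_that("fold assignment is stratified, grouped, and deterministic", {
  cases <- tibble::tibble(
    case_id = sprintf("c%02d", 1:99),
    label = rep(c("malignant", "benign"), c(49, 50))
  )
  f <- assign_folds(cases, k = 5, seed = 1)
  expect_setequal(f$case_id, cases$case_id)
  expect_equal(anyDuplicated(f$case_id), 0)
  sizes <- table(f$fold)
  expect_true(all(sizes >= 19 & sizes <= 20))
  mal <- table(f$fold[f$label == "malignant"])
  expect_true(all(mal >= 9 & mal <= 10))
  expect_identical(assign_folds(cases, k = 5, seed = 1)$fold, f$fold)
  expect_false(identical(assign_folds(cases, k = 5, seed = 2)$fold, f$fold))
  small <- cases[c(1:3, 50:99), ]
  expect_error(assign_folds(small, k = 5, seed = 1), "at least")
})

test_that("AUC matches the exhaustive pair-counting oracle", {
  perfect <- tibble::tibble(score = c(0.9, 0.8, 0.2, 0.1),
                            label = c(1, 1, 0, 0))
  expect_equal(roc_result(perfect)$auc, 1.0)
  ties <- tibble::tibble(score = rep(0.3, 12), label = rep(c(0, 1), 6))
  expect_equal(roc_result(ties)$auc, 0.5)
  set.seed(10)
  for (i in 1:20) {
    n <- sample(6:25, 1)
    sc <- tibble::tibble(
      score = round(rnorm(n), 1),       # rounding forces ties
      label = c(0, 1, sample(0:1, n - 2, replace = TRUE))
    )
    expect_equal(roc_result(sc)$auc, oracle_auc(sc$score, sc$label),
                 tolerance = 1e-12)
  }
  expect_error(roc_result(tibble::tibble(score = 1:3, label = c(1, 1, 1))),
               "both classes")
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(11)
  sc <- tibble::tibble(score = rnorm(40), label = rep(c(0, 1), 20))
  r1 <- roc_result(sc)
  sc2 <- dplyr::mutate(sc, score = exp(3 * score) + 2)
  expect_equal(roc_result(sc2)$auc, r1$auc, tolerance = 1e-12)
  # label flip complements the AUC and the CI covers the estimate
  sc3 <- dplyr::mutate(sc, label = 1 - label)
  expect_equal(roc_result(sc3)$auc, 1 - r1$auc, tolerance = 1e-12)
  expect_true(r1$ci95[1] <= r1$auc && r1$auc <= r1$ci95[2])
})

test_that("DeLong variance matches the empirical AUC variance under the null", {
  set.seed(12)
  n <- 100
  reps <- 300
  aucs <- numeric(reps); vars <- numeric(reps)
  for (i in seq_len(reps)) {
    sc <- tibble::tibble(score = rnorm(2 * n), label = rep(c(0, 1), n))
    r <- roc_result(sc)
    aucs[i] <- r$auc; vars[i] <- r$se^2
  }
  expect_lt(abs(mean(vars) / var(aucs) - 1), 0.25)
})

test_that("paired comparison handles identity, flips, and matches bootstrap", {
  set.seed(13)
  n <- 60
  y <- rep(c(0, 1), n / 2)
  a <- tibble::tibble(case_id = sprintf("c%02d", 1:n),
                      score = rnorm(n) + 0.55 * y, label = y)
  same <- compare_paired(a, a)
  expect_equal(same$delta, 0)
  expect_equal(same$p, 1)
  flipped <- dplyr::mutate(a, score = 1 - score)
  cmpf <- compare_paired(a, flipped)
  expect_equal(cmpf$delta, 2 * cmpf$auc_a - 1, tolerance = 1e-12)
  # bootstrap oracle for the p-value of a genuinely different pair
  b <- dplyr::mutate(a, score = score + rnorm(n, sd = 1.2))
  cmp <- compare_paired(a, b)
  deltas <- vapply(1:10000, function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(y[idx])) < 2) return(NA_real_)
    rank_auc(a$score[idx], y[idx]) - rank_auc(b$score[idx], y[idx])
  }, numeric(1))
  deltas <- deltas[is.finite(deltas)]
  p_boot <- 2 * pnorm(-abs(cmp$delta) / sd(deltas))
  expect_lt(abs(cmp$p - p_boot), 0.02)
  expect_error(compare_paired(a, b[1:10, ]), "same cases")
})

test_that("Holm-Bonferroni applies the sequential rejection rule", {
  hb <- holm_bonferroni(c(0.01, 0.03, 0.04), alpha = 0.05)
  expect_equal(hb$reject, c(TRUE, FALSE, FALSE))
  expect_equal(hb$p_adj, p.adjust(c(0.01, 0.03, 0.04), "holm"))
  one <- holm_bonferroni(0.04)
  expect_true(one$reject)
  all1 <- holm_bonferroni(rep(1, 4))
  expect_false(any(all1$reject))
  expect_equal(all1$p_adj, rep(1, 4))
  expect_error(holm_bonferroni(numeric(0)), "empty")
  expect_error(holm_bonferroni(c(0.5, 1.2)), "0, 1")
})

test_that("merging averages per-case scores and preserves structure", {
  a <- tibble::tibble(case_id = c("x", "y"), score = c(0.2, 0.6),
                      label = c(0, 1), fold = c(0, 1))
  b <- tibble::tibble(case_id = c("x", "y"), score = c(0.4, 0.8),
                      label = c(0, 1), fold = c(0, 1))
  m <- merge_scores(a, b)
  expect_equal(m$score, c(0.3, 0.7))
  expect_equal(m$label, c(0, 1))
  self <- merge_scores(a, a)
  expect_equal(self$score, a$score)
  expect_error(merge_scores(a, b[1, ]), "same cases")
})

test_that("cross-validation scores every case exactly once, reproducibly", {
  spec <- cohort_spec(n_cases = 40, prevalence = 0.5, seed = 14)
  df <- dplyr::filter(generate_feature_sequences(spec, dim = 4), is_affected)
  folds <- assign_folds(df, k = 5, seed = 3)
  trainer <- list(
    fit = function(train) colMeans(as.matrix(train[, feature_columns(train)])),
    score = function(model, test) {
      last <- select_last_prior(test)
      tibble::tibble(case_id = last$case_id,
                     score = as.matrix(last[, names(model)]) %*% model |>
                       as.numeric())
    }
  )
  s1 <- cross_validate(trainer, df, folds)
  s2 <- cross_validate(trainer, df, folds)
  expect_identical(s1, s2)
  expect_setequal(s1$case_id, unique(df$case_id))
  expect_equal(anyDuplicated(s1$case_id), 0)
  expect_equal(sort(unique(s1$fold)), 0:4)
})
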