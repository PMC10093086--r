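# Evaluation machinery: stratified grouped 5-fold cross-validation shared by
# all classifiers, ROC/AUC with DeLong variance, tests against chance,
# paired AUC comparison, Holm-Bonferroni correction, and classifier merging
# by per-case score averaging.

#' Stratified case-level fold assignment
#'
#' Cases are stratified by label: within each class the case ids are shuffled
#' by a seeded RNG and dealt round-robin over the folds, so per-fold class
#' proportions match the global ratio to within one case. All exams and both
#' breasts of a case share its fold; one assignment is reused by every
#' classifier so pairwise comparisons see identical splits.
#'
#' @param df per-case or per-exam tibble with `case_id` and `label`.
#' @param k number of folds.
#' @param seed shuffle seed.
#' @return A tibble `case_id, label, fold` (fold in `0..k-1`) of class
#'   `mt_folds`.
#' @export
assign_folds <- function(df, k = 5L, seed = 1L) {
  k <- assert_count(k, "k", lower = 2L)
  cases <- dplyr::distinct(df, .data$case_id, .data$label)
  counts <- table(cases$label)
  if (any(counts < k)) {
    abort(sprintf("every class needs at least k = %d cases", k))
  }
  out <- withr::with_seed(seed, {
    dplyr::bind_rows(lapply(split(cases, cases$label), function(cl) {
      cl <- cl[sample.int(nrow(cl)), ]
      cl$fold <- (seq_len(nrow(cl)) - 1L) %% k
      cl
    }))
  })
  out <- dplyr::arrange(out, .data$case_id)
  class(out) <- c("mt_folds", class(out))
  attr(out, "k") <- k
  out
}

#' ROC analysis of a score set
#'
#' AUC by the Mann--Whitney statistic (ties count 1/2), standard error and
#' 95% CI by DeLong's method, and a two-sided normal test of AUC = 0.5.
#'
#' @param scores tibble with `score`, `label` (0/1 or benign/malignant) and
#'   optionally `case_id`.
#' @return An `mt_roc`: `auc`, `se`, `ci95`, `p_vs_chance`, `n_pos`, `n_neg`
#'   plus the underlying `pROC::roc` object.
#' @export
roc_result <- function(scores) {
  y <- score_labels(scores)
  if (length(unique(y)) < 2L) abort("both classes are required for ROC")
  r <- pROC::roc(response = y, predictor = scores$score,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  v <- suppressWarnings(pROC::var(r, method = "delong"))
  se <- sqrt(max(v, 0))
  ci <- auc + c(-1, 1) * qnorm(0.975) * se
  p <- if (se > .EPS) 2 * pnorm(-abs(auc - 0.5) / se) else
    as.numeric(abs(auc - 0.5) < .EPS)
  structure(list(auc = auc, se = se, ci95 = pmin(pmax(ci, 0), 1),
                 p_vs_chance = p, n_pos = sum(y == 1), n_neg = sum(y == 0),
                 roc = r),
            class = "mt_roc")
}

score_labels <- function(scores) {
  y <- scores$label
  if (!is.numeric(y)) y <- as.numeric(y == "malignant")
  y
}

#' @export
print.mt_roc <- function(x, ...) {
  cat(sprintf("<mt_roc> AUC = %.3f +/- %.3f [%.3f, %.3f], p vs chance = %.4f\n",
              x$auc, x$se, x$ci95[1], x$ci95[2], x$p_vs_chance))
  invisible(x)
}

#' Paired comparison of two classifiers' AUCs
#'
#' Paired DeLong test on the same cases: `delta = AUC_a - AUC_b` with
#' covariance-aware variance, two-sided p-value and 95% CI. (This is the
#' nonparametric stand-in for binormal ROC comparison software; the variance
#' accounts for the correlation induced by scoring identical cases.)
#'
#' @param a,b score tibbles (`case_id, score, label`) over the same cases.
#' @return A one-row tibble: `auc_a, auc_b, delta, se, ci_lo, ci_hi, z, p`.
#' @export
compare_paired <- function(a, b) {
  m <- dplyr::inner_join(a, b, by = "case_id", suffix = c("_a", "_b"))
  if (nrow(m) != nrow(a) || nrow(m) != nrow(b)) {
    abort("score sets must cover the same cases")
  }
  y <- m$label_a
  if (!is.numeric(y)) y <- as.numeric(y == "malignant")
  ra <- pROC::roc(y, m$score_a, levels = c(0, 1), direction = "<",
                  quiet = TRUE)
  rb <- pROC::roc(y, m$score_b, levels = c(0, 1), direction = "<",
                  quiet = TRUE)
  va <- pROC::var(ra, method = "delong")
  vb <- pROC::var(rb, method = "delong")
  cab <- pROC::cov(ra, rb, method = "delong")
  delta <- as.numeric(pROC::auc(ra)) - as.numeric(pROC::auc(rb))
  se <- sqrt(max(va + vb - 2 * cab, 0))
  z <- if (se > .EPS) delta / se else 0
  p <- if (se > .EPS) 2 * pnorm(-abs(z)) else 1
  tibble::tibble(auc_a = as.numeric(pROC::auc(ra)),
                 auc_b = as.numeric(pROC::auc(rb)),
                 delta = delta, se = se,
                 ci_lo = delta - qnorm(0.975) * se,
                 ci_hi = delta + qnorm(0.975) * se,
                 z = z, p = p)
}

#' Holm--Bonferroni step-down correction
#'
#' @param pvals p-values in `[0, 1]`.
#' @param alpha family-wise error rate.
#' @return A tibble `p, p_adj, reject` in the input order.
#' @export
holm_bonferroni <- function(pvals, alpha = 0.05) {
  if (length(pvals) == 0L) abort("empty p-value vector")
  if (any(pvals < 0 | pvals > 1)) abort("p-values must lie in [0, 1]")
  adj <- p.adjust(pvals, method = "holm")
  tibble::tibble(p = pvals, p_adj = adj, reject = adj <= alpha)
}

#' Merge two classifiers by averaging per-case scores
#'
#' @param a,b score tibbles over the same cases.
#' @return A score tibble with the per-case arithmetic mean of the scores.
#' @export
merge_scores <- function(a, b) {
  m <- dplyr::inner_join(a, b, by = "case_id", suffix = c("_a", "_b"))
  if (nrow(m) != nrow(a) || nrow(m) != nrow(b)) {
    abort("score sets must cover the same cases")
  }
  out <- tibble::tibble(case_id = m$case_id,
                        score = (m$score_a + m$score_b) / 2)
  if ("label_a" %in% names(m)) out$label <- m$label_a
  if ("fold_a" %in% names(m)) out$fold <- m$fold_a
  out
}

#' Leakage-safe cross-validation of a trainer
#'
#' For each fold: fit the trainer on the out-of-fold cases (all
#' preprocessing, standardization and PCA included in the trainer's `fit`),
#' score the held-out cases, and concatenate. Every case is scored exactly
#' once, by a model that never saw it.
#'
#' @param trainer list with `fit(df) -> model` and
#'   `score(model, df) -> tibble(case_id, score)` (see [lstm_trainer()],
#'   [svm_trainer()]).
#' @param df flat per-exam feature table (one breast per case).
#' @param folds an [assign_folds()] table.
#' @return Score tibble `case_id, label, fold, score`.
#' @export
cross_validate <- function(trainer, df, folds) {
  df <- dplyr::inner_join(df, folds[, c("case_id", "fold")], by = "case_id")
  purrr::map_dfr(sort(unique(folds$fold)), function(f) {
    train <- dplyr::filter(df, .data$fold != f)
    test <- dplyr::filter(df, .data$fold == f)
    if (length(unique(train$label)) < 2L) {
      abort(sprintf("training portion of fold %d has a single class", f))
    }
    model <- trainer$fit(train)
    sc <- trainer$score(model, test)
    lab <- dplyr::distinct(test, .data$case_id, .data$label)
    out <- dplyr::inner_join(sc, lab, by = "case_id")
    out$fold <- f
    out
  })
}

#' LSTM trainer for [cross_validate()]
#'
#' @param config an [lstm_config()].
#' @param feature_cols feature columns (default: detect per fold).
#' @return A trainer list.
#' @export
lstm_trainer <- function(config = lstm_config(), feature_cols = NULL) {
  list(
    fit = function(df) lstm_train(df, config,
                                  feature_cols %||% feature_columns(df)),
    score = function(model, df) predict(model, df)
  )
}

#' Single-timepoint PCA+SVM trainer for [cross_validate()]
#'
#' @param config an [svm_config()].
#' @param feature_cols feature columns (default: detect per fold).
#' @return A trainer list.
#' @export
svm_trainer <- function(config = svm_config(), feature_cols = NULL) {
  list(
    fit = function(df) stp_train(df, config,
                                 feature_cols %||% feature_columns(df)),
    score = function(model, df) predict(model, df)
  )
}
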