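# Single-timepoint comparator: features from the last antecedent exam only
# (the exam closest to diagnosis), z-scored, reduced to 25 principal
# components, classified with an SVM whose continuous decision score feeds
# the ROC analysis directly.

#' SVM baseline configuration
#'
#' @param n_components number of principal components kept (default 25;
#'   capped at the training rank at fit time).
#' @param kernel `"radial"` or `"linear"`.
#' @param cost SVM cost parameter C.
#' @param seed seed (the fit is deterministic; kept for provenance).
#' @return An `mt_svm_config`.
#' @export
svm_config <- function(n_components = 25L, kernel = c("radial", "linear"),
                       cost = 1, seed = 1L) {
  structure(list(n_components = assert_count(n_components, "n_components"),
                 kernel = match.arg(kernel),
                 cost = assert_number(cost, "cost", lower = .EPS),
                 seed = assert_count(seed, "seed", lower = 0L)),
            class = "mt_svm_config")
}

#' Select the last antecedent exam of each case
#'
#' Keeps, per case (and per breast when several lateralities are present),
#' the chronologically last exam -- the one closest to the future diagnosis.
#' Rows are sorted by `exam_index` first, so manifest order does not matter.
#'
#' @param df flat per-exam feature table.
#' @return Tibble with one row per (case, laterality).
#' @export
select_last_prior <- function(df) {
  if (nrow(df) == 0L) abort("empty exam table")
  grp <- if ("laterality" %in% names(df)) {
    dplyr::group_by(df, .data$case_id, .data$laterality)
  } else {
    dplyr::group_by(df, .data$case_id)
  }
  dplyr::ungroup(dplyr::slice_max(grp, .data$exam_index, n = 1L,
                                  with_ties = FALSE))
}

#' Fit a PCA transform on training-fold rows
#'
#' Features are z-scored (zero-variance features left unscaled with a
#' warning), centered, and rotated onto the leading principal components.
#' Components use a deterministic sign convention: the largest-magnitude
#' loading of each component is positive.
#'
#' @param x training feature matrix (rows = cases).
#' @param n_components number of components; must not exceed the rank bound
#'   `min(nrow(x) - 1, ncol(x))`.
#' @return An `mt_pca` transform.
#' @export
fit_pca <- function(x, n_components = 25L) {
  x <- as.matrix(x)
  r <- min(nrow(x) - 1L, ncol(x))
  if (n_components > r) {
    abort(sprintf("n_components (%d) exceeds the rank bound %d",
                  n_components, r))
  }
  mu <- colMeans(x)
  sdv <- apply(x, 2L, sd)
  zero <- !is.finite(sdv) | sdv < .EPS
  if (any(zero)) {
    warn(sprintf("%d zero-variance feature(s); left unscaled", sum(zero)))
    sdv[zero] <- 1
  }
  z <- sweep(sweep(x, 2L, mu), 2L, sdv, `/`)
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  flip <- apply(rot, 2L, function(col) sign(col[which.max(abs(col))]))
  rot <- sweep(rot, 2L, flip, `*`)
  structure(list(mean = mu, sd = sdv, rotation = rot,
                 sdev = pc$sdev[seq_len(n_components)]),
            class = "mt_pca")
}

#' @export
predict.mt_pca <- function(object, newdata, ...) {
  z <- sweep(sweep(as.matrix(newdata), 2L, object$mean), 2L, object$sd, `/`)
  z %*% object$rotation
}

#' Train the single-timepoint PCA+SVM baseline
#'
#' Selects the last antecedent exam per case, fits the z-score + PCA
#' transform on the training rows only, and trains an SVM on the component
#' scores. Scoring returns the continuous SVM decision value oriented so
#' that larger means more likely malignant (rank-equivalent to a
#' probability, which is all ROC analysis needs).
#'
#' @param df flat per-exam feature table (one breast per case).
#' @param config an [svm_config()].
#' @param feature_cols feature columns.
#' @return An `mt_stp` model.
#' @export
stp_train <- function(df, config = svm_config(),
                      feature_cols = feature_columns(df)) {
  last <- select_last_prior(df)
  x <- as.matrix(last[, feature_cols, drop = FALSE])
  y <- factor(ifelse(last$label == "malignant", "malignant", "benign"),
              levels = c("benign", "malignant"))
  if (length(unique(y)) < 2L) abort("training data must contain both classes")
  ncomp <- min(config$n_components, nrow(x) - 1L, ncol(x))
  pca <- fit_pca(x, ncomp)
  scores <- predict(pca, x)
  fit <- e1071::svm(scores, y, kernel = config$kernel, cost = config$cost,
                    scale = FALSE)
  # orientation of the decision value relative to the positive class
  dv <- attr(predict(fit, scores, decision.values = TRUE), "decision.values")
  flip <- if (grepl("^malignant", colnames(dv)[1])) 1 else -1
  structure(list(pca = pca, svm = fit, flip = flip, config = config,
                 feature_cols = feature_cols, n_components = ncomp),
            class = "mt_stp")
}

#' @export
print.mt_stp <- function(x, ...) {
  cat(sprintf("<mt_stp> PCA(%d) + %s SVM (C = %g)\n", x$n_components,
              x$svm$kernel, x$config$cost))
  invisible(x)
}

#' Score cases with the single-timepoint baseline
#'
#' @param object an `mt_stp`.
#' @param newdata flat per-exam feature table.
#' @param ... unused.
#' @return A tibble `case_id, score` (continuous decision values).
#' @export
predict.mt_stp <- function(object, newdata, ...) {
  last <- select_last_prior(newdata)
  x <- as.matrix(last[, object$feature_cols, drop = FALSE])
  comp <- predict(object$pca, x)
  dv <- attr(predict(object$svm, comp, decision.values = TRUE),
             "decision.values")
  tibble::tibble(case_id = last$case_id,
                 score = object$flip * as.numeric(dv))
}
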