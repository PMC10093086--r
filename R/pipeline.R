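# End-to-end experiment: simulate a cohort, derive two feature sets ("cnn"
# pooled backbone features and "radiomics"), train the LSTM sequence
# classifier and the single-timepoint PCA+SVM baseline on the affected and
# contralateral breasts with one shared fold assignment, merge lateralities
# (and feature sets) by score averaging, and report the seven-classifier
# AUC table plus the pre-registered pairwise comparisons.

#' Run the full temporal-classification experiment
#'
#' Two modes. `"direct"` (fast path) draws feature-level sequences from the
#' cohort generator for both nominal feature sets, skipping image rendering.
#' `"rendered"` renders every exam's texture patch, then extracts the
#' 50-feature radiomic bank and the pooled backbone features from the
#' images. Either way the downstream classifiers, cross-validation and ROC
#' report are identical.
#'
#' @param cohort an [cohort_spec()].
#' @param mode `"direct"` or `"rendered"`.
#' @param lstm an [lstm_config()].
#' @param svm an [svm_config()].
#' @param cv_k,cv_seed fold count and fold-shuffle seed (one assignment
#'   shared by all classifiers).
#' @param direct_dims named integer vector: feature dimension per feature set
#'   in direct mode.
#' @param roi_size patch side for rendered mode.
#' @param backbone backbone layout name for rendered mode.
#' @param input_size backbone input resize for rendered mode (`NULL` =
#'   native).
#' @param dir scratch directory for rendered images (tempdir by default).
#' @return An `mt_experiment`: `report` (one row per classifier x feature
#'   type x laterality), `comparisons` (paired DeLong tests with
#'   Holm-Bonferroni flags), `scores` (all out-of-fold score sets), `folds`,
#'   and the configs.
#' @export
run_experiment <- function(cohort = cohort_spec(n_cases = 120L, prevalence = 0.5),
                           mode = c("direct", "rendered"),
                           lstm = lstm_config(),
                           svm = svm_config(),
                           cv_k = 5L, cv_seed = 1L,
                           direct_dims = c(cnn = 24L, radiomics = 50L),
                           roi_size = 512L,
                           backbone = "tiny-test",
                           input_size = NULL,
                           dir = NULL) {
  mode <- match.arg(mode)
  if (is.null(names(direct_dims)) || any(names(direct_dims) == "")) {
    abort("`direct_dims` must be a named vector of feature-set dimensions")
  }

  feats <- if (mode == "direct") {
    purrr::map(direct_dims, function(d) {
      generate_feature_sequences(cohort, dim = d)
    })
  } else {
    dir <- dir %||% file.path(tempdir(), "mt_experiment")
    manifest <- render_cohort(sample_cohort(cohort), dir, roi_size = roi_size)
    manifest <- dplyr::mutate(manifest, exam_date = as.Date(.data$exam_date))
    layout <- backbone_layout(backbone)
    list(
      cnn = extract_deep_batch(manifest, dir, layout = layout,
                               seed = cohort$seed, input_size = input_size),
      radiomics = extract_radiomics_batch(manifest, dir)
    )
  }

  folds <- assign_folds(feats[[1]], k = cv_k, seed = cv_seed)
  lat_filter <- list(affected = TRUE, contralateral = FALSE)

  scores <- list()
  for (fs in names(feats)) {
    df_all <- feats[[fs]]
    for (lat in names(lat_filter)) {
      df <- dplyr::filter(df_all, .data$is_affected == lat_filter[[lat]])
      for (cl in c("lstm", "svm")) {
        trainer <- if (cl == "lstm") lstm_trainer(lstm) else svm_trainer(svm)
        scores[[fs]][[lat]][[cl]] <- cross_validate(trainer, df, folds)
      }
    }
    for (cl in c("lstm", "svm")) {
      scores[[fs]][["both"]][[cl]] <-
        merge_scores(scores[[fs]][["affected"]][[cl]],
                     scores[[fs]][["contralateral"]][[cl]])
    }
  }
  fs2 <- names(feats)[1:2]
  for (cl in c("lstm", "svm")) {
    scores[["combined"]][["both"]][[cl]] <-
      merge_scores(scores[[fs2[1]]][["both"]][[cl]],
                   scores[[fs2[2]]][["both"]][[cl]])
  }

  rows <- list()
  for (fs in names(scores)) for (lat in names(scores[[fs]])) {
    for (cl in names(scores[[fs]][[lat]])) {
      r <- roc_result(scores[[fs]][[lat]][[cl]])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        feature_type = fs, laterality = lat, classifier = cl,
        auc = r$auc, se = r$se, ci_lo = r$ci95[1], ci_hi = r$ci95[2],
        p_vs_chance = r$p_vs_chance)
    }
  }
  report <- dplyr::bind_rows(rows)

  # pre-registered comparisons only; merged classifiers are reported without
  # tests to preserve statistical power
  cmp <- dplyr::bind_rows(
    dplyr::mutate(compare_paired(scores[[fs2[1]]]$affected$lstm,
                                 scores[[fs2[2]]]$affected$lstm),
                  comparison = sprintf("%s vs %s LSTM (affected)",
                                       fs2[1], fs2[2])),
    dplyr::mutate(compare_paired(scores[[fs2[1]]]$contralateral$lstm,
                                 scores[[fs2[2]]]$contralateral$lstm),
                  comparison = sprintf("%s vs %s LSTM (contralateral)",
                                       fs2[1], fs2[2])),
    dplyr::mutate(compare_paired(scores[[fs2[1]]]$affected$lstm,
                                 scores[[fs2[1]]]$contralateral$lstm),
                  comparison = sprintf("%s LSTM affected vs contralateral",
                                       fs2[1])),
    dplyr::mutate(compare_paired(scores[[fs2[2]]]$affected$lstm,
                                 scores[[fs2[2]]]$contralateral$lstm),
                  comparison = sprintf("%s LSTM affected vs contralateral",
                                       fs2[2]))
  )
  hb <- holm_bonferroni(cmp$p)
  cmp$p_adj <- hb$p_adj
  cmp$reject <- hb$reject

  structure(list(report = report, comparisons = cmp, scores = scores,
                 folds = folds, cohort = cohort, lstm = lstm, svm = svm,
                 mode = mode),
            class = "mt_experiment")
}

#' @export
print.mt_experiment <- function(x, ...) {
  cat(sprintf("<mt_experiment> mode %s, %d cases\n", x$mode,
              x$cohort$n_cases))
  print(as.data.frame(x$report), digits = 3)
  invisible(x)
}

#' Serialize an experiment report to JSON
#'
#' @param x an `mt_experiment`.
#' @param path output path.
#' @export
write_report <- function(x, path) {
  jsonlite::write_json(
    list(schema = "mt_experiment_report/1",
         mode = x$mode,
         cohort = unclass(x$cohort),
         report = x$report,
         comparisons = x$comparisons,
         auc_inference = "delong"),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
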