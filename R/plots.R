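#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_abline geom_point
#'   geom_errorbar geom_histogram labs facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' ROC curve of a score set
#'
#' @param object an `mt_roc`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot mt_roc
#' @export
autoplot.mt_roc <- function(object, ...) {
  co <- pROC::coords(object$roc, x = "all", transpose = FALSE)
  df <- tibble::tibble(fpr = 1 - co$specificity, tpr = co$sensitivity)
  ggplot(df, aes(x = .data$fpr, y = .data$tpr)) +
    geom_line(linewidth = 0.8) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey50") +
    labs(x = "False positive rate", y = "True positive rate",
         title = sprintf("AUC = %.3f ± %.3f", object$auc, object$se)) +
    theme_minimal()
}

#' AUC summary plot of an experiment
#'
#' One point (with 95% CI error bars) per classifier, faceted by classifier
#' family, with the chance line at AUC 0.5.
#'
#' @param object an `mt_experiment`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot mt_experiment
#' @export
autoplot.mt_experiment <- function(object, ...) {
  df <- dplyr::mutate(object$report,
                      name = paste(.data$feature_type, .data$laterality))
  ggplot(df, aes(x = .data$name, y = .data$auc)) +
    geom_point() +
    geom_errorbar(aes(ymin = .data$ci_lo, ymax = .data$ci_hi), width = 0.2) +
    geom_abline(slope = 0, intercept = 0.5, linetype = "dashed",
                colour = "grey50") +
    facet_wrap(~classifier) +
    labs(x = NULL, y = "AUC (95% CI)") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Histogram of exams per case in a cohort
#'
#' @param cohort output of [sample_cohort()] or
#'   [generate_feature_sequences()].
#' @return A ggplot.
#' @export
plot_sequence_lengths <- function(cohort) {
  lens <- dplyr::summarise(dplyr::group_by(cohort, .data$case_id,
                                           .data$label),
                           n_exams = max(.data$exam_index), .groups = "drop")
  ggplot(lens, aes(x = .data$n_exams, fill = .data$label)) +
    geom_histogram(binwidth = 1, position = "dodge", colour = "white") +
    labs(x = "Prior exams per case", y = "Cases", fill = NULL) +
    theme_minimal()
}
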