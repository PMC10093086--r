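#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @method tidy mt_roc
#' @export
tidy.mt_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, se = x$se, ci_lo = x$ci95[1], ci_hi = x$ci95[2],
                 p_vs_chance = x$p_vs_chance)
}

#' @method glance mt_roc
#' @export
glance.mt_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, se = x$se, p_vs_chance = x$p_vs_chance,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @method tidy mt_lstm
#' @export
tidy.mt_lstm <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_history),
                 training_loss = x$loss_history)
}

#' @method glance mt_lstm
#' @export
glance.mt_lstm <- function(x, ...) {
  tibble::tibble(hidden_dim = x$config$hidden_dim,
                 learning_rate = x$config$learning_rate,
                 epochs = x$config$epochs,
                 batch_size = x$config$batch_size,
                 loss_mode = x$config$loss,
                 initial_loss = x$loss_history[1],
                 final_loss = tail(x$loss_history, 1))
}

#' @method glance mt_stp
#' @export
glance.mt_stp <- function(x, ...) {
  tibble::tibble(n_components = x$n_components,
                 kernel = x$svm$kernel,
                 cost = x$config$cost,
                 n_support_vectors = nrow(x$svm$SV))
}

#' @method tidy mt_experiment
#' @export
tidy.mt_experiment <- function(x, ...) x$report

#' @method glance mt_experiment
#' @export
glance.mt_experiment <- function(x, ...) {
  tibble::tibble(mode = x$mode, n_cases = x$cohort$n_cases,
                 prevalence = x$cohort$prevalence,
                 drift_per_year = x$cohort$drift_per_year,
                 field_effect = x$cohort$field_effect,
                 n_classifiers = nrow(x$report))
}
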