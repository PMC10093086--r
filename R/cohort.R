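# Sequence-length distribution for the number of screening exams per case.
# Support 2..9 with most mass at 2-4; probabilities chosen so that the
# expected number of exams per case is ~3.21 (318 exams over 99 cases).
.SEQ_LEN_SUPPORT <- 2:9
.SEQ_LEN_PROBS <- c(0.45, 0.25, 0.13, 0.07, 0.045, 0.03, 0.015, 0.01)

# Nominal texture-parameter baselines and their between-woman spreads
# (spread scaled by `baseline_jitter`). Drift acts in units of `sd`.
.TEXTURE_NOMINAL <- list(
  beta           = list(mean = 2.8,  sd = 0.25),
  lump_density   = list(mean = 2e-4, sd = 4e-5),
  lump_amplitude = list(mean = 1.0,  sd = 0.10),
  lump_radius_px = list(mean = 6.0,  sd = 0.60),
  noise_sd       = list(mean = 0.15, sd = 0.015)
)
# texture parameters that carry the malignant temporal drift
.DRIFTED_PARAMS <- c("beta", "lump_density")

#' Specify a synthetic longitudinal screening cohort
#'
#' A cohort of women each contributes a date-ordered series of 2--9 screening
#' exams (two breasts per exam). Cases labelled `malignant` carry a slow
#' temporal drift of their parenchymal texture parameters towards the date of
#' the (future) diagnosis; the drift is anchored so the *last* antecedent exam
#' matches the case's own baseline, which keeps single-timepoint marginals
#' label-uninformative while sequences remain informative. With
#' `field_effect = TRUE` the drift is applied to the contralateral breast as
#' well as the affected one.
#'
#' @param n_cases number of women in the cohort.
#' @param prevalence fraction of malignant cases in `[0, 1]`; label counts use
#'   exact-count allocation (`round(prevalence * n_cases)` malignant).
#' @param seq_len_range integer pair; admissible number of exams per case.
#' @param interval_mean_years,interval_sd_years mean and SD of the between-exam
#'   interval (truncated normal, floored at `interval_min_years`).
#' @param interval_min_years minimum allowed interval between exams, in years.
#' @param drift_per_year malignant drift rate, in units of the between-woman SD
#'   of each drifted quantity per year.
#' @param field_effect should the contralateral breast drift too?
#' @param baseline_jitter multiplier on the between-woman spread of baseline
#'   texture parameters (and on feature baselines for the feature-level path).
#' @param seed integer seed; the generator is fully deterministic given the
#'   spec.
#' @return An object of class `mt_cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 99L,
                        prevalence = 49 / 99,
                        seq_len_range = c(2L, 9L),
                        interval_mean_years = 1.27,
                        interval_sd_years = 0.3,
                        interval_min_years = 0.5,
                        drift_per_year = 0.4,
                        field_effect = TRUE,
                        baseline_jitter = 1,
                        seed = 1L) {
  n_cases <- assert_count(n_cases, "n_cases")
  assert_number(prevalence, "prevalence", 0, 1)
  if (length(seq_len_range) != 2L || seq_len_range[1] > seq_len_range[2] ||
      seq_len_range[1] < 1L) {
    abort("`seq_len_range` must be an ordered pair of positive integers")
  }
  seq_len_range <- as.integer(seq_len_range)
  assert_number(interval_mean_years, "interval_mean_years", lower = .EPS)
  assert_number(interval_sd_years, "interval_sd_years", lower = 0)
  assert_number(interval_min_years, "interval_min_years", lower = 0)
  assert_number(drift_per_year, "drift_per_year")
  assert_flag(field_effect, "field_effect")
  assert_number(baseline_jitter, "baseline_jitter", lower = 0)
  seed <- assert_count(seed, "seed", lower = 0L)
  structure(
    list(
      n_cases = n_cases, prevalence = prevalence,
      seq_len_range = seq_len_range,
      interval_mean_years = interval_mean_years,
      interval_sd_years = interval_sd_years,
      interval_min_years = interval_min_years,
      drift_per_year = drift_per_year,
      field_effect = field_effect,
      baseline_jitter = baseline_jitter,
      seed = seed
    ),
    class = "mt_cohort_spec"
  )
}

#' @export
print.mt_cohort_spec <- function(x, ...) {
  cat("<mt_cohort_spec>\n")
  cat(sprintf("  n_cases: %d (prevalence %.3f), exams/case in [%d, %d]\n",
              x$n_cases, x$prevalence, x$seq_len_range[1], x$seq_len_range[2]))
  cat(sprintf("  intervals: %.2f +/- %.2f y (min %.2f)\n",
              x$interval_mean_years, x$interval_sd_years, x$interval_min_years))
  cat(sprintf("  drift/year: %.3f, field effect: %s, jitter: %.2f, seed: %d\n",
              x$drift_per_year, x$field_effect, x$baseline_jitter, x$seed))
  invisible(x)
}

# truncated-normal intervals (redraw below the floor)
draw_intervals <- function(n, mean, sd, min) {
  if (n == 0L) return(numeric(0))
  out <- rnorm(n, mean, sd)
  bad <- which(out < min)
  while (length(bad) > 0L) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out < min)
  }
  out
}

# case-level skeleton: labels, lateralities, exam counts, dates, times.
# Exact-count label allocation: round(prevalence * n) malignant, assigned to a
# randomly chosen subset of case ids.
sample_case_skeletons <- function(spec) {
  n <- spec$n_cases
  n_pos <- round(spec$prevalence * n)
  lab <- rep("benign", n)
  lab[sample.int(n, n_pos)] <- "malignant"
  affected <- sample(c("left", "right"), n, replace = TRUE)

  lens <- .SEQ_LEN_SUPPORT
  keep <- lens >= spec$seq_len_range[1] & lens <= spec$seq_len_range[2]
  if (!any(keep)) abort("`seq_len_range` excludes the whole length support")
  support <- lens[keep]
  probs <- .SEQ_LEN_PROBS[keep] / sum(.SEQ_LEN_PROBS[keep])
  n_exams <- sample(support, n, replace = TRUE, prob = probs)

  # last antecedent exam date; diagnosis follows ~1 year later
  last_dates <- as.Date("2015-01-01") + round(runif(n, 0, 4 * 365.25))

  purrr::map_dfr(seq_len(n), function(i) {
    L <- n_exams[i]
    gaps <- draw_intervals(L - 1L, spec$interval_mean_years,
                           spec$interval_sd_years, spec$interval_min_years)
    t_from_first <- c(0, cumsum(gaps))
    span <- t_from_first[L]
    tibble::tibble(
      case_id = sprintf("case%04d", i),
      label = lab[i],
      affected_laterality = affected[i],
      exam_index = seq_len(L),
      time_years = t_from_first,
      years_before_last = span - t_from_first,
      exam_date = last_dates[i] - round((span - t_from_first) * 365.25)
    )
  })
}

#' Generate a synthetic screening cohort at the texture-parameter level
#'
#' Draws the full cohort structure (labels, exam counts, irregular exam dates)
#' and per-exam, per-breast texture parameters for the lumpy power-law texture
#' model rendered by [render_texture()]. Malignant cases drift in `beta`
#' (spectral slope) and `lump_density` at `drift_per_year` between-woman SDs
#' per year, anchored at the last exam, in the affected breast and -- if
#' `field_effect` -- equally in the contralateral breast.
#'
#' @param spec an [cohort_spec()] object.
#' @return A tibble with one row per (case, exam, breast) carrying the texture
#'   parameters, with the spec attached as attribute `"spec"`.
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "mt_cohort_spec"))
  withr::with_seed(spec$seed, {
    skel <- sample_case_skeletons(spec)
    cases <- unique(skel$case_id)

    # per-case baseline texture parameters, shared between breasts up to a
    # small within-woman asymmetry (30% of the between-woman spread)
    base <- purrr::map(.TEXTURE_NOMINAL, function(p) {
      p$mean + spec$baseline_jitter * p$sd * rnorm(length(cases))
    })
    asym <- purrr::map(.TEXTURE_NOMINAL, function(p) {
      0.3 * spec$baseline_jitter * p$sd *
        matrix(rnorm(2L * length(cases)), ncol = 2L)
    })

    out <- tidyr::crossing(skel, laterality = c("left", "right")) |>
      dplyr::arrange(.data$case_id, .data$exam_index, .data$laterality)
    ci <- match(out$case_id, cases)
    li <- ifelse(out$laterality == "left", 1L, 2L)
    out$is_affected <- out$laterality == out$affected_laterality
    drifted <- out$label == "malignant" &
      (out$is_affected | spec$field_effect)
    # anchored drift: zero at the last antecedent exam, negative earlier
    dt <- -out$years_before_last

    for (nm in names(.TEXTURE_NOMINAL)) {
      p <- .TEXTURE_NOMINAL[[nm]]
      v <- base[[nm]][ci] + asym[[nm]][cbind(ci, li)]
      if (nm %in% .DRIFTED_PARAMS) {
        v <- v + ifelse(drifted, spec$drift_per_year * p$sd * dt, 0)
      }
      out[[nm]] <- v
    }
    out$beta <- pmin(pmax(out$beta, 0.5), 4)
    out$lump_density <- pmax(out$lump_density, 0)
    out$lump_amplitude <- pmax(out$lump_amplitude, 0)
    out$lump_radius_px <- pmax(out$lump_radius_px, 0.5)
    out$noise_sd <- pmax(out$noise_sd, 0)

    attr(out, "spec") <- spec
    out
  })
}

#' Generate labelled feature sequences directly (fast path)
#'
#' Bypasses image rendering and emits per-exam feature vectors with the same
#' cohort skeleton as [sample_cohort()]. Each feature follows an AR(1) process
#' around a per-case, per-breast baseline drawn with spread `baseline_jitter`;
#' the first `n_informative` features additionally carry the anchored
#' malignant drift (`drift_per_year` feature units per year towards the last
#' exam), in the affected breast and, if `field_effect`, the contralateral
#' breast. Because the drift is anchored at the last exam and baselines are
#' jittered, the marginal distribution at any single exam is essentially
#' label-uninformative; the *change* over the sequence is the only signal.
#'
#' @param spec an [cohort_spec()] object.
#' @param dim number of features per exam.
#' @param n_informative how many features carry the drift (capped at `dim`).
#' @param ar AR(1) coefficient of the within-sequence noise.
#' @param noise_sd stationary SD of the within-sequence noise.
#' @return A tibble with one row per (case, exam, breast) and feature columns
#'   `f01 ...`; attributes `"spec"` and `"informative"` (feature names).
#' @export
generate_feature_sequences <- function(spec, dim = 50L, n_informative = 5L,
                                       ar = 0.6, noise_sd = 0.3) {
  stopifnot(inherits(spec, "mt_cohort_spec"))
  dim <- assert_count(dim, "dim")
  n_informative <- min(assert_count(n_informative, "n_informative", 0L), dim)
  assert_number(ar, "ar", -0.999, 0.999)
  assert_number(noise_sd, "noise_sd", lower = 0)

  withr::with_seed(spec$seed + 1L, {
    skel <- sample_case_skeletons(spec)
    out <- tidyr::crossing(skel, laterality = c("left", "right")) |>
      dplyr::arrange(.data$case_id, .data$laterality, .data$exam_index)
    out$is_affected <- out$laterality == out$affected_laterality
    drifted <- out$label == "malignant" &
      (out$is_affected | spec$field_effect)
    dt <- -out$years_before_last

    # one AR(1) trajectory per (case, breast, feature); rows of `out` are
    # grouped by (case, breast) with exams in chronological order
    grp <- paste(out$case_id, out$laterality)
    first <- !duplicated(grp)
    n_row <- nrow(out)
    feat <- matrix(0, n_row, dim)
    innov <- matrix(rnorm(n_row * dim), n_row, dim)
    e <- matrix(0, n_row, dim)
    for (r in seq_len(n_row)) {
      e[r, ] <- if (first[r]) noise_sd * innov[r, ]
      else ar * e[r - 1L, ] + noise_sd * sqrt(1 - ar^2) * innov[r, ]
    }
    # per-group baselines
    n_grp <- sum(first)
    b <- spec$baseline_jitter * matrix(rnorm(n_grp * dim), n_grp, dim)
    gi <- cumsum(first)
    feat <- b[gi, , drop = FALSE] + e
    if (n_informative > 0L) {
      drift_block <- outer(ifelse(drifted, spec$drift_per_year, 0) * dt,
                           rep(1, n_informative))
      feat[, seq_len(n_informative)] <-
        feat[, seq_len(n_informative)] + drift_block
    }
    colnames(feat) <- sprintf("f%02d", seq_len(dim))
    out <- dplyr::bind_cols(out, tibble::as_tibble(feat))
    attr(out, "spec") <- spec
    attr(out, "informative") <- colnames(feat)[seq_len(n_informative)]
    out
  })
}

#' Names of the feature columns of a feature/score table
#'
#' @param df a tibble produced by [generate_feature_sequences()] or a batch
#'   feature extractor.
#' @return Character vector of columns matching `^f\\d` or known radiomic /
#'   deep-feature prefixes.
#' @export
feature_columns <- function(df) {
  grep("^(f\\d|bc_|eg_|hist_|fft_|ngtdm_|mink_|pl_|glcm_|deep_)",
       names(df), value = TRUE)
}
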