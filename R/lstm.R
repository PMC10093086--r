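# Variable-length sequence classifier: a single-layer LSTM with logistic
# gates and tanh cell activation, a per-step sigmoid read-out, zero
# post-padding with a validity mask, masked binary cross-entropy, and plain
# minibatch SGD. Gradients are computed by backpropagation through time.

.CLIP <- 1e-7

#' LSTM training configuration
#'
#' Defaults follow the selected operating point of the study design this
#' package implements: hidden dimension 512, learning rate 1e-4, 100 epochs
#' of plain SGD with minibatches of 8. Scaled-down experiments (smaller
#' hidden dimension, higher learning rate) are configured explicitly.
#'
#' @param hidden_dim LSTM state size.
#' @param learning_rate SGD step size (no momentum, no weight decay).
#' @param epochs number of passes over the training cases.
#' @param batch_size minibatch size.
#' @param seed seed for weight initialization and minibatch shuffling.
#' @param loss `"step"` (sum of per-step BCE over valid steps divided by the
#'   total valid-step count) or `"sequence"` (per-case mean over valid steps,
#'   then mean over cases).
#' @return An `mt_lstm_config`.
#' @export
lstm_config <- function(hidden_dim = 512L, learning_rate = 1e-4,
                        epochs = 100L, batch_size = 8L, seed = 1L,
                        loss = c("step", "sequence")) {
  structure(list(
    hidden_dim = assert_count(hidden_dim, "hidden_dim"),
    learning_rate = assert_number(learning_rate, "learning_rate", lower = .EPS),
    epochs = assert_count(epochs, "epochs"),
    batch_size = assert_count(batch_size, "batch_size"),
    seed = assert_count(seed, "seed", lower = 0L),
    loss = match.arg(loss)
  ), class = "mt_lstm_config")
}

#' Zero-pad feature sequences and build the validity mask
#'
#' Post-padding: every sequence is padded with all-zero steps up to the
#' length of the longest sequence; `mask[i, t] = 1` for the first
#' `lengths[i]` steps and 0 after.
#'
#' @param sequences list of `T_i x d` matrices (chronological order).
#' @param labels numeric 0/1 per sequence (1 = future malignant).
#' @param case_ids optional identifiers carried through to scoring.
#' @return An `mt_batch`: `features` (`n x max_len x d` array), `mask`
#'   (`n x max_len`), `labels`, `lengths`, `case_ids`.
#' @export
pad_and_mask <- function(sequences, labels, case_ids = NULL) {
  if (length(sequences) == 0L) abort("no sequences")
  d <- unique(vapply(sequences, ncol, integer(1)))
  if (length(d) != 1L) abort("sequences have inconsistent feature dimensions")
  lengths <- vapply(sequences, nrow, integer(1))
  n <- length(sequences); maxT <- max(lengths)
  X <- array(0, dim = c(n, maxT, d))
  mask <- matrix(0, n, maxT)
  for (i in seq_len(n)) {
    X[i, seq_len(lengths[i]), ] <- sequences[[i]]
    mask[i, seq_len(lengths[i])] <- 1
  }
  structure(list(features = X, mask = mask, labels = as.numeric(labels),
                 lengths = lengths,
                 case_ids = case_ids %||% sprintf("seq%04d", seq_len(n))),
            class = "mt_batch")
}

#' Build a padded batch from a flat per-exam feature table
#'
#' Groups rows by `case_id` (the table is assumed to hold a single breast per
#' case, e.g. after filtering on `laterality` or `is_affected`), orders exams
#' chronologically by `exam_index`, and pads.
#'
#' @param df tibble with `case_id`, `label`, `exam_index` and feature columns.
#' @param feature_cols feature column names (default [feature_columns()]).
#' @return An `mt_batch`.
#' @export
seq_batch <- function(df, feature_cols = feature_columns(df)) {
  df <- dplyr::arrange(df, .data$case_id, .data$exam_index)
  split_idx <- split(seq_len(nrow(df)), df$case_id)
  sequences <- purrr::map(split_idx, function(ii) {
    as.matrix(df[ii, feature_cols, drop = FALSE])
  })
  labels <- vapply(split_idx, function(ii) {
    as.numeric(df$label[ii[1]] == "malignant")
  }, numeric(1))
  pad_and_mask(unname(sequences), unname(labels), names(split_idx))
}

#' Standardize batch features using training-fold statistics
#'
#' Z-scores each feature using the mean and SD over *valid* (unmasked) steps
#' of the batch the statistics were fitted on; padded entries are re-zeroed
#' after scaling so they remain exactly 0. Zero-variance features get scale 1
#' with a warning.
#'
#' @param batch an `mt_batch`.
#' @param stats `NULL` to fit on `batch` itself (training fold) or the
#'   `"stats"` attribute of a previously standardized batch.
#' @return The standardized `mt_batch` with attribute `"stats"`.
#' @export
standardize_batch <- function(batch, stats = NULL) {
  X <- batch$features
  d <- dim(X)[3]
  valid <- batch$mask == 1
  if (is.null(stats)) {
    flat <- matrix(X, prod(dim(X)[1:2]), d)[as.vector(valid), , drop = FALSE]
    mu <- colMeans(flat)
    sdv <- apply(flat, 2L, sd)
    zero <- !is.finite(sdv) | sdv < .EPS
    if (any(zero)) {
      warn(sprintf("%d zero-variance feature(s); left unscaled", sum(zero)))
      sdv[zero] <- 1
    }
    stats <- list(mean = mu, sd = sdv)
  }
  for (j in seq_len(d)) {
    X[, , j] <- (X[, , j] - stats$mean[j]) / stats$sd[j]
    X[, , j][!valid] <- 0
  }
  batch$features <- X
  attr(batch, "stats") <- stats
  batch
}

#' Initialize LSTM parameters
#'
#' Gate pre-activations are `h_prev %*% W + x_t %*% U + b` with the gate
#' blocks ordered (input, forget, candidate, output); the forget-gate bias
#' starts at 1. The read-out is `sigmoid(h_t %*% v + c0)`.
#'
#' @param input_dim feature dimension.
#' @param hidden_dim state size.
#' @param seed integer seed.
#' @return Parameter list `W, U, b, v, c0`.
#' @export
lstm_init <- function(input_dim, hidden_dim, seed = 1L) {
  withr::with_seed(seed, {
    H <- hidden_dim
    params <- list(
      W = matrix(rnorm(H * 4L * H, sd = 1 / sqrt(H)), H, 4L * H),
      U = matrix(rnorm(input_dim * 4L * H, sd = 1 / sqrt(input_dim)),
                 input_dim, 4L * H),
      b = c(rep(0, H), rep(1, H), rep(0, 2L * H)),
      v = rnorm(H, sd = 1 / sqrt(H)),
      c0 = 0
    )
    params
  })
}

#' LSTM forward pass
#'
#' Runs the recurrence over all padded steps and reads out
#' `P(malignant)` at every step; the per-case score is the read-out at the
#' last *valid* step of each sequence, so extra padding never changes it.
#'
#' @param batch an `mt_batch`.
#' @param params from [lstm_init()] (or a trained model's `$params`).
#' @param cache keep intermediate activations for backpropagation?
#' @return List with `probs` (`n x max_len`), `scores` (per-case, at the last
#'   valid step), and optionally `cache`.
#' @export
lstm_forward <- function(batch, params, cache = FALSE) {
  X <- batch$features
  n <- dim(X)[1]; Tmax <- dim(X)[2]; d <- dim(X)[3]
  H <- length(params$v)
  if (nrow(params$U) != d) abort("feature dimension does not match parameters")
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  probs <- matrix(0, n, Tmax)
  store <- if (cache) vector("list", Tmax) else NULL
  idx <- list(i = seq_len(H), f = H + seq_len(H),
              g = 2L * H + seq_len(H), o = 3L * H + seq_len(H))
  for (t in seq_len(Tmax)) {
    xt <- matrix(X[, t, ], n, d)
    A <- h %*% params$W + xt %*% params$U +
      matrix(params$b, n, 4L * H, byrow = TRUE)
    gi <- sigmoid(A[, idx$i, drop = FALSE])
    gf <- sigmoid(A[, idx$f, drop = FALSE])
    gg <- tanh(A[, idx$g, drop = FALSE])
    go <- sigmoid(A[, idx$o, drop = FALSE])
    c_prev <- cc; h_prev <- h
    cc <- gf * cc + gi * gg
    tc <- tanh(cc)
    h <- go * tc
    probs[, t] <- sigmoid(h %*% params$v + params$c0)
    if (cache) {
      store[[t]] <- list(x = xt, h_prev = h_prev, c_prev = c_prev,
                         i = gi, f = gf, g = gg, o = go, c = cc, tc = tc,
                         h = h)
    }
  }
  scores <- probs[cbind(seq_len(n), batch$lengths)]
  out <- list(probs = probs, scores = scores)
  if (cache) out$cache <- store
  out
}

#' Masked binary cross-entropy
#'
#' Per-step BCE of each read-out against the case label, restricted to valid
#' steps. With `per = "step"` the sum over valid steps is divided by the
#' total valid-step count of the batch; with `per = "sequence"` each case is
#' averaged over its own valid steps first. Outputs are clipped to
#' `[1e-7, 1 - 1e-7]`.
#'
#' @param probs `n x max_len` matrix of read-outs.
#' @param labels per-case 0/1 labels.
#' @param mask `n x max_len` validity mask.
#' @param per `"step"` or `"sequence"`.
#' @return Scalar loss (natural log).
#' @export
masked_bce <- function(probs, labels, mask, per = c("step", "sequence")) {
  per <- match.arg(per)
  p <- pmin(pmax(probs, .CLIP), 1 - .CLIP)
  y <- matrix(labels, nrow(p), ncol(p))
  ll <- -(y * log(p) + (1 - y) * log(1 - p)) * mask
  if (per == "step") sum(ll) / sum(mask)
  else mean(rowSums(ll) / pmax(rowSums(mask), 1))
}

# per-step weight on d(loss)/d(logit): the mask normalized per the loss mode
bce_step_weights <- function(mask, per) {
  if (per == "step") mask / sum(mask)
  else mask / (rowSums(mask) * nrow(mask))
}

# full BPTT gradient of the masked BCE w.r.t. all parameters
lstm_backward <- function(batch, params, fwd, per = "step") {
  X <- batch$features
  n <- dim(X)[1]; Tmax <- dim(X)[2]
  H <- length(params$v)
  wts <- bce_step_weights(batch$mask, per)
  y <- batch$labels
  grads <- list(W = params$W * 0, U = params$U * 0, b = params$b * 0,
                v = params$v * 0, c0 = 0)
  dh_next <- matrix(0, n, H)
  dc_next <- matrix(0, n, H)
  for (t in rev(seq_len(Tmax))) {
    st <- fwd$cache[[t]]
    dlogit <- wts[, t] * (fwd$probs[, t] - y)      # n-vector
    grads$v <- grads$v + as.vector(crossprod(st$h, dlogit))
    grads$c0 <- grads$c0 + sum(dlogit)
    dh <- dh_next + outer(dlogit, params$v)
    dc <- dc_next + dh * st$o * (1 - st$tc^2)
    do <- dh * st$tc
    di <- dc * st$g
    dg <- dc * st$i
    df <- dc * st$c_prev
    da <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                dg * (1 - st$g^2),
                do * st$o * (1 - st$o))
    grads$W <- grads$W + crossprod(st$h_prev, da)
    grads$U <- grads$U + crossprod(st$x, da)
    grads$b <- grads$b + colSums(da)
    dh_next <- da %*% t(params$W)
    dc_next <- dc * st$f
  }
  grads
}

#' Train the LSTM sequence classifier
#'
#' Standardizes the training batch (statistics are stored for scoring),
#' then runs plain minibatch SGD on the masked BCE for a fixed number of
#' epochs. Fully deterministic given the config seed.
#'
#' @param df flat per-exam feature table (one breast per case) with
#'   `case_id`, `label`, `exam_index` and feature columns; alternatively an
#'   `mt_batch` built by [pad_and_mask()].
#' @param config an [lstm_config()].
#' @param feature_cols feature columns (ignored for `mt_batch` input).
#' @return An `mt_lstm` model: parameters, config, feature columns,
#'   standardization stats, per-epoch training-loss history.
#' @export
lstm_train <- function(df, config = lstm_config(),
                       feature_cols = NULL) {
  if (inherits(df, "mt_batch")) {
    batch <- df
  } else {
    feature_cols <- feature_cols %||% feature_columns(df)
    batch <- seq_batch(df, feature_cols)
  }
  if (length(unique(batch$labels)) < 2L) {
    abort("training data must contain both classes")
  }
  batch <- standardize_batch(batch)
  stats <- attr(batch, "stats")
  d <- dim(batch$features)[3]
  params <- lstm_init(d, config$hidden_dim, config$seed)
  n <- dim(batch$features)[1]
  history <- numeric(config$epochs)
  withr::with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      for (s0 in starts) {
        ii <- ord[s0:min(s0 + config$batch_size - 1L, n)]
        sub <- list(features = batch$features[ii, , , drop = FALSE],
                    mask = batch$mask[ii, , drop = FALSE],
                    labels = batch$labels[ii],
                    lengths = batch$lengths[ii])
        class(sub) <- "mt_batch"
        fwd <- lstm_forward(sub, params, cache = TRUE)
        gr <- lstm_backward(sub, params, fwd, per = config$loss)
        for (nm in names(params)) {
          params[[nm]] <- params[[nm]] - config$learning_rate * gr[[nm]]
        }
      }
      fwd <- lstm_forward(batch, params)
      history[epoch] <- masked_bce(fwd$probs, batch$labels, batch$mask,
                                   per = config$loss)
    }
  })
  structure(list(params = params, config = config,
                 feature_cols = if (inherits(df, "mt_batch")) NULL
                 else feature_cols,
                 stats = stats, loss_history = history),
            class = "mt_lstm")
}

#' @export
print.mt_lstm <- function(x, ...) {
  cat(sprintf(
    "<mt_lstm> hidden %d, %d epochs (lr %.2g), final training loss %.4f\n",
    x$config$hidden_dim, x$config$epochs, x$config$learning_rate,
    tail(x$loss_history, 1)))
  invisible(x)
}

#' Score cases with a trained LSTM
#'
#' @param object an `mt_lstm`.
#' @param newdata flat per-exam feature table or `mt_batch`.
#' @param ... unused.
#' @return A tibble `case_id, score` where `score` is the read-out
#'   `P(malignant)` at the last valid step of each sequence.
#' @export
predict.mt_lstm <- function(object, newdata, ...) {
  batch <- if (inherits(newdata, "mt_batch")) newdata
  else seq_batch(newdata, object$feature_cols)
  batch <- standardize_batch(batch, stats = object$stats)
  fwd <- lstm_forward(batch, object$params)
  tibble::tibble(case_id = batch$case_ids, score = fwd$scores)
}
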