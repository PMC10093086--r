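make_batch <- function(lens = c(2, 4, 3), d = 3, seed = 42) {
  set.seed(seed)
  seqs <- lapply(lens, function(Ti) matrix(rnorm(Ti * d), Ti, d))
  pad_and_mask(seqs, labels = rep_len(c(1, 0), length(lens)))
}

add_padding <- function(batch, extra) {
  d <- dim(batch$features)
  X <- array(0, dim = d + c(0, extra, 0))
  X[, seq_len(d[2]), ] <- batch$features
  batch$features <- X
  batch$mask <- cbind(batch$mask, matrix(0, d[1], extra))
  batch
}

test_that("padding and masks follow the post-padding convention", {
  b <- make_batch(lens = c(2, 4))
  expect_equal(dim(b$features), c(2L, 4L, 3L))
  expect_equal(b$mask, rbind(c(1, 1, 0, 0), c(1, 1, 1, 1)))
  expect_true(all(b$features[1, 3:4, ] == 0))
  expect_equal(b$lengths, c(2L, 4L))
  b2 <- make_batch(lens = c(3, 3, 3))
  expect_true(all(b2$mask == 1))
  expect_error(pad_and_mask(list(matrix(0, 2, 3), matrix(0, 2, 4)), c(0, 1)),
               "inconsistent")
})

test_that("standardization uses valid steps only and keeps pads at zero", {
  b <- make_batch(lens = c(2, 5, 3))
  s <- standardize_batch(b)
  X <- s$features
  valid <- which(b$mask == 1)
  for (j in 1:3) {
    xj <- X[, , j][b$mask == 1]
    expect_lt(abs(mean(xj)), 1e-9)
    expect_true(all(X[, , j][b$mask == 0] == 0))
  }
  # training stats reapplied to new data reproduce the transform
  s2 <- standardize_batch(b, stats = attr(s, "stats"))
  expect_identical(s$features, s2$features)
  # zero-variance feature warns and is left unscaled
  bz <- make_batch()
  bz$features[, , 2] <- bz$mask * 5
  expect_warning(standardize_batch(bz), "zero-variance")
})

test_that("an untrained all-zero model outputs 0.5 everywhere", {
  b <- make_batch()
  p0 <- lapply(lstm_init(3, 4, seed = 1), function(x) x * 0)
  f <- lstm_forward(b, p0)
  expect_true(all(abs(f$probs - 0.5) < 1e-12))
  expect_equal(masked_bce(f$probs, b$labels, b$mask), log(2),
               tolerance = 1e-12)
})

test_that("predictions and loss are exactly invariant to extra padding", {
  b <- make_batch(lens = c(2, 6, 4, 3))
  params <- lstm_init(3, 5, seed = 3)
  f1 <- lstm_forward(b, params)
  b2 <- add_padding(b, 4)
  f2 <- lstm_forward(b2, params)
  expect_identical(f1$scores, f2$scores)
  l1 <- masked_bce(f1$probs, b$labels, b$mask)
  l2 <- masked_bce(f2$probs, b2$labels, b2$mask)
  expect_lt(abs(l1 - l2), 1e-12)
  l1s <- masked_bce(f1$probs, b$labels, b$mask, per = "sequence")
  l2s <- masked_bce(f2$probs, b2$labels, b2$mask, per = "sequence")
  expect_lt(abs(l1s - l2s), 1e-12)
})

test_that("a one-cell LSTM matches hand-composed gate formulas", {
  # scalar hidden state, single-step sequence: compose the cell by hand
  d <- 2
  params <- lstm_init(d, 1, seed = 5)
  x <- c(0.3, -1.2)
  b <- pad_and_mask(list(matrix(x, 1, d)), labels = 1)
  f <- lstm_forward(b, params)
  sig <- function(z) 1 / (1 + exp(-z))
  a <- as.vector(x %*% params$U) + params$b      # h_prev = 0
  i <- sig(a[1]); fg <- sig(a[2]); g <- tanh(a[3]); o <- sig(a[4])
  cc <- i * g                                    # c_prev = 0
  h <- o * tanh(cc)
  expect_equal(f$scores, sig(h * params$v + params$c0), tolerance = 1e-12)
})

test_that("masked BCE clips extreme outputs", {
  probs <- matrix(c(1, 0), 1, 2)
  m <- matrix(1, 1, 2)
  l <- masked_bce(probs, labels = 1, mask = m)
  expect_true(is.finite(l))
  expect_equal(l, (0 - log(1e-7) - log(1 - 1e-7)) / 2, tolerance = 1e-6)
})

test_that("analytic gradients match central finite differences", {
  set.seed(8)
  b <- make_batch(lens = c(3, 2, 4), d = 3, seed = 13)
  for (per in c("step", "sequence")) {
    params <- lstm_init(3, 4, seed = 21)
    fwd <- lstm_forward(b, params, cache = TRUE)
    gr <- mammotrend:::lstm_backward(b, params, fwd, per = per)
    eps <- 1e-5
    worst <- 0
    for (nm in c("W", "U", "b", "v", "c0")) {
      n_el <- length(params[[nm]])
      idxs <- if (n_el > 12) sample.int(n_el, 12) else seq_len(n_el)
      for (i in idxs) {
        pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
        pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
        lp <- masked_bce(lstm_forward(b, pp)$probs, b$labels, b$mask, per)
        lm_ <- masked_bce(lstm_forward(b, pm)$probs, b$labels, b$mask, per)
        ng <- (lp - lm_) / (2 * eps)
        rel <- abs(ng - gr[[nm]][i]) / max(abs(ng), abs(gr[[nm]][i]), 1e-5)
        worst <- max(worst, rel)
      }
    }
    expect_lt(worst, 1e-5)
  }
})

test_that("training reduces the loss, learns the drift, and is reproducible", {
  spec <- cohort_spec(n_cases = 160, prevalence = 0.5, drift_per_year = 0.4,
                      seed = 3)
  df <- dplyr::filter(generate_feature_sequences(spec, dim = 20), is_affected)
  cfg <- lstm_config(hidden_dim = 16, learning_rate = 0.05, epochs = 60,
                     batch_size = 8, seed = 1)
  m1 <- lstm_train(df, cfg)
  expect_lt(tail(m1$loss_history, 1), m1$loss_history[1])
  sc <- dplyr::inner_join(predict(m1, df),
                          dplyr::distinct(df, case_id, label), by = "case_id")
  expect_gte(roc_result(sc)$auc, 0.85)
  m2 <- lstm_train(df, cfg)
  expect_equal(m1$params, m2$params, tolerance = 1e-10)
  # single-class training errors out
  one <- dplyr::filter(df, label == "benign")
  expect_error(lstm_train(one, cfg), "both classes")
})
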