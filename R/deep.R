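# Multi-stage pooled convolutional features: a VGG-style stack of 3x3
# convolutions with ReLU and 2x2 max pooling, where the output of every
# pooling stage is globally average-pooled to one value per channel and the
# stage vectors are concatenated. For the VGG-19 layout the stage channel
# counts (64, 128, 256, 512, 512) give 1472 features per image.

#' Describe a convolutional backbone layout
#'
#' @param name `"vgg19"` (stages of 2, 2, 4, 4, 4 convolutions with
#'   64/128/256/512/512 channels; 1472 pooled features) or `"tiny-test"`
#'   (two stages of one convolution with 8 and 16 channels; 24 features,
#'   intended for fast seeded-random-weight tests).
#' @return An `mt_backbone` with `stage_channels`, `conv_per_stage`, and
#'   `total_features`.
#' @export
backbone_layout <- function(name = c("vgg19", "tiny-test")) {
  if (!name[1] %in% c("vgg19", "tiny-test")) {
    abort(sprintf("unknown backbone '%s'", name[1]))
  }
  name <- name[1]
  layout <- switch(name,
    vgg19 = list(stage_channels = c(64L, 128L, 256L, 512L, 512L),
                 conv_per_stage = c(2L, 2L, 4L, 4L, 4L)),
    `tiny-test` = list(stage_channels = c(8L, 16L),
                       conv_per_stage = c(1L, 1L))
  )
  structure(c(list(name = name, in_channels = 3L), layout,
              list(total_features = sum(layout$stage_channels))),
            class = "mt_backbone")
}

#' @export
print.mt_backbone <- function(x, ...) {
  cat(sprintf("<mt_backbone> %s: stages (%s), %d pooled features\n", x$name,
              paste(x$stage_channels, collapse = ", "), x$total_features))
  invisible(x)
}

#' Initialize backbone weights
#'
#' He-normal 3x3 kernels, zero biases, deterministic given `seed`. Weights
#' for each convolution are stored as a `(9 * c_in) x c_out` matrix ready for
#' the im2col forward pass.
#'
#' @param layout an [backbone_layout()].
#' @param seed integer seed.
#' @return List of per-convolution `list(W, b, c_in, c_out)`.
#' @export
init_backbone_weights <- function(layout, seed = 1L) {
  withr::with_seed(seed, {
    weights <- list()
    c_in <- layout$in_channels
    for (s in seq_along(layout$stage_channels)) {
      c_out <- layout$stage_channels[s]
      for (k in seq_len(layout$conv_per_stage[s])) {
        W <- matrix(rnorm(9L * c_in * c_out, sd = sqrt(2 / (9 * c_in))),
                    9L * c_in, c_out)
        weights[[length(weights) + 1L]] <-
          list(W = W, b = numeric(c_out), c_in = c_in, c_out = c_out)
        c_in <- c_out
      }
    }
    weights
  })
}

#' Preprocess an ROI for the backbone
#'
#' Min--max rescales the patch to `[0, 1]` (a constant patch becomes all
#' zeros, with a warning) and replicates it to 3 identical channels;
#' optionally resizes to `out_size` (bilinear).
#'
#' @param roi an `mt_roi` or numeric matrix.
#' @param out_size optional output side in pixels; `NULL` keeps the native
#'   resolution (fully convolutional use).
#' @return A `H x W x 3` array.
#' @export
preprocess_roi <- function(roi, out_size = NULL) {
  v <- as_intensity_matrix(roi)
  rng <- range(v)
  if (rng[2] > rng[1]) {
    v <- (v - rng[1]) / (rng[2] - rng[1])
  } else {
    warn("constant ROI: preprocessed input is all zeros")
    v <- v * 0
  }
  if (!is.null(out_size)) {
    v <- EBImage::imageData(EBImage::resize(EBImage::as.Image(v),
                                            w = out_size, h = out_size))
  }
  array(v, dim = c(dim(v), 3L))
}

# im2col 3x3 same-padding convolution: input H x W x Cin -> H x W x Cout
conv3x3 <- function(x, W, b) {
  h <- dim(x)[1]; w <- dim(x)[2]; cin <- dim(x)[3]
  pad <- array(0, dim = c(h + 2L, w + 2L, cin))
  pad[2:(h + 1L), 2:(w + 1L), ] <- x
  cols <- matrix(0, h * w, 9L * cin)
  k <- 0L
  for (dc in 0:2) for (dr in 0:2) {
    block <- pad[dr + seq_len(h), dc + seq_len(w), , drop = FALSE]
    cols[, k * cin + seq_len(cin)] <- matrix(block, h * w, cin)
    k <- k + 1L
  }
  out <- cols %*% W
  out <- sweep(out, 2L, b, `+`)
  array(out, dim = c(h, w, ncol(W)))
}

relu <- function(x) { x[x < 0] <- 0; x }

maxpool2 <- function(x) {
  h <- (dim(x)[1] %/% 2L) * 2L; w <- (dim(x)[2] %/% 2L) * 2L
  x <- x[seq_len(h), seq_len(w), , drop = FALSE]
  a <- x[seq(1L, h, 2L), , , drop = FALSE]
  b <- x[seq(2L, h, 2L), , , drop = FALSE]
  m <- pmax(a, b)
  pmax(m[, seq(1L, w, 2L), , drop = FALSE],
       m[, seq(2L, w, 2L), , drop = FALSE])
}

#' Extract multi-stage globally pooled CNN features
#'
#' Runs the backbone forward; after each max-pooling stage the feature maps
#' are globally average-pooled to one value per channel, and the per-stage
#' vectors are concatenated in stage order. Output length equals
#' `sum(stage_channels)` (1472 for the VGG-19 layout). Deterministic given
#' the weights.
#'
#' @param roi an `mt_roi` or numeric matrix.
#' @param layout an [backbone_layout()].
#' @param weights from [init_backbone_weights()]; generated with `seed` if
#'   `NULL`.
#' @param seed seed for random weights when `weights` is `NULL`.
#' @param input_size optional resize side before the forward pass (the
#'   spatial size must survive one halving per stage, so at least
#'   `2^n_stages`); `NULL` runs fully convolutionally at native resolution.
#' @return A one-row tibble with `total_features` columns `deep_s<stage>_c<channel>`.
#' @export
extract_deep <- function(roi, layout = backbone_layout("vgg19"),
                         weights = NULL, seed = 1L, input_size = NULL) {
  if (is.null(weights)) weights <- init_backbone_weights(layout, seed)
  n_conv <- sum(layout$conv_per_stage)
  if (length(weights) != n_conv ||
      weights[[1]]$c_in != layout$in_channels) {
    abort("weights do not match the backbone layout")
  }
  x <- preprocess_roi(roi, out_size = input_size)
  min_side <- 2L^length(layout$stage_channels)
  if (min(dim(x)[1:2]) < min_side) {
    abort(sprintf("input side must be at least %d for this backbone", min_side))
  }
  feats <- list()
  wi <- 0L
  for (s in seq_along(layout$stage_channels)) {
    for (k in seq_len(layout$conv_per_stage[s])) {
      wi <- wi + 1L
      x <- relu(conv3x3(x, weights[[wi]]$W, weights[[wi]]$b))
    }
    x <- maxpool2(x)
    pooled <- apply(x, 3L, mean)
    feats[[s]] <- setNames(pooled, sprintf("deep_s%d_c%03d", s,
                                           seq_along(pooled)))
  }
  tibble::as_tibble(as.list(unlist(feats)))
}

#' Batch deep-feature extraction over a manifest
#'
#' @inheritParams extract_radiomics_batch
#' @param layout,weights,seed,input_size forwarded to [extract_deep()]; a
#'   single weight set is generated once and reused for every image.
#' @return A tibble of provenance + pooled feature columns.
#' @export
extract_deep_batch <- function(manifest, dir = ".",
                               layout = backbone_layout("tiny-test"),
                               weights = NULL, seed = 1L, input_size = NULL) {
  if (is.null(weights)) weights <- init_backbone_weights(layout, seed)
  purrr::map_dfr(seq_len(nrow(manifest)), function(r) {
    img <- read_image(file.path(dir, manifest$image_path[r]),
                      spacing_mm = c(0.07, 0.07))
    dplyr::bind_cols(
      manifest[r, intersect(c("case_id", "label", "affected_laterality",
                              "laterality", "is_affected", "exam_index",
                              "exam_date", "time_years", "years_before_last"),
                            names(manifest))],
      extract_deep(img$intensities, layout, weights, input_size = input_size)
    )
  })
}
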