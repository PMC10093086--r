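rand_grid <- function(n, levels = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(sample.int(levels, n * n, replace = TRUE) - 1L, n, n)
}

test_that("quantization bins the patch's own range with a closed top bin", {
  v <- matrix(0:255, 16, 16)
  q <- quantize_gray(v, 16)
  expect_equal(as.vector(q), as.vector(floor(v / 16)))
  expect_true(all(quantize_gray(matrix(3.7, 5, 5), 16) == 0L))
  expect_identical(quantize_gray(v + 1000, 16), q)   # shift invariance
  expect_error(quantize_gray(v, 1), "n_levels")
})

test_that("GLCMs match hand-enumerated pair counts", {
  checker <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  g <- compute_glcm(checker, n_levels = 2, angles = 0, symmetric = TRUE)
  expect_equal(g$probs, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  cst <- compute_glcm(matrix(0L, 4, 4), n_levels = 2)
  expect_equal(cst$probs[1, 1], 1)
  expect_equal(sum(cst$probs), 1)
  rnd <- compute_glcm(rand_grid(12, 5, seed = 1), n_levels = 5)
  expect_equal(sum(rnd$probs), 1, tolerance = 1e-12)
  expect_equal(rnd$probs, t(rnd$probs))
})

test_that("Haralick features agree with the brute-force oracle", {
  # degenerate single-cell matrix
  h0 <- haralick14(compute_glcm(matrix(0L, 4, 4), n_levels = 2))
  expect_equal(unname(h0[c("glcm_energy", "glcm_contrast", "glcm_entropy")]),
               c(1, 0, 0))
  # checkerboard: contrast 1, energy 0.5
  hc <- haralick14(matrix(c(0, 0.5, 0.5, 0), 2, 2))
  expect_equal(unname(hc[["glcm_contrast"]]), 1)
  expect_equal(unname(hc[["glcm_energy"]]), 0.5)
  # random grids vs oracle
  for (s in 1:10) {
    g <- compute_glcm(rand_grid(8, 8, seed = s), n_levels = 8)
    expect_equal(unname(haralick14(g)), oracle_haralick(g$probs),
                 tolerance = 1e-10)
  }
})

test_that("NGTDM features agree with per-pixel computation", {
  cst <- ngtdm5(matrix(2L, 6, 6))
  expect_equal(unname(cst[["ngtdm_coarseness"]]), 1e12)
  expect_equal(unname(cst[c("ngtdm_contrast", "ngtdm_busyness",
                            "ngtdm_complexity", "ngtdm_strength")]),
               rep(0, 4))
  two <- matrix(c(0L, 1L), 4, 4)
  expect_equal(unname(ngtdm5(two)), oracle_ngtdm(two), tolerance = 1e-10)
  expect_length(ngtdm5(rand_grid(10, 4, seed = 2)), 5)
  expect_error(ngtdm5(matrix(0L, 2, 2)), "smaller")
  expect_error(ngtdm5(rand_grid(6), neighborhood = 4), "odd")
})

test_that("histogram features match moments of known distributions", {
  cst <- histogram10(matrix(4, 8, 8))
  expect_equal(unname(cst[c("hist_sd", "hist_skewness", "hist_entropy")]),
               c(0, 0, 0))
  expect_equal(unname(cst[["hist_uniformity"]]), 1)
  bim <- histogram10(matrix(c(0, 1), 10, 10))
  expect_equal(unname(bim[["hist_mean"]]), 0.5)
  expect_equal(unname(bim[["hist_skewness"]]), 0)
  set.seed(11)
  z <- matrix(rnorm(512^2), 512, 512)
  hz <- histogram10(z)
  expect_lt(abs(hz[["hist_mean"]]), 0.02)
  expect_lt(abs(hz[["hist_kurtosis"]]), 0.05)
})

test_that("edge-gradient features respond to edges and only edges", {
  cst <- edge_gradient4(matrix(1, 16, 16))
  expect_equal(unname(cst), rep(0, 4))
  step <- cbind(matrix(0, 16, 8), matrix(100, 16, 8))
  mag <- mammotrend:::sobel_magnitude(step)
  nonzero_cols <- which(colSums(mag) > 1e-6 * max(mag))
  expect_equal(nonzero_cols, 8:9)        # 2-px band at the step
  ef <- edge_gradient4(step)
  expect_equal(unname(ef[["eg_edge_fraction"]]), 2 * 16 / (16 * 16))
  rot <- edge_gradient4(t(step))
  expect_equal(unname(ef[["eg_mean"]]), unname(rot[["eg_mean"]]),
               tolerance = 1e-12)
})

test_that("the radial PSD is Parseval-consistent and localizes sinusoids", {
  set.seed(5)
  v <- matrix(rnorm(64 * 64), 64, 64)
  psd <- radial_psd(v, window = "none")
  x <- v - mean(v)
  expect_equal(psd$total_power, 64^2 * sum(x^2), tolerance = 1e-6)
  # pure sinusoid concentrates in its own annulus
  f0 <- 8 / 64
  s <- outer(rep(1, 64), sin(2 * pi * 8 * (0:63) / 64))
  ps <- radial_psd(s, window = "none")
  k <- round(ps$freq * 64)
  expect_gt(ps$power[k == 8] / sum(ps$power), 0.99)
  expect_error(radial_psd(matrix(0, 4, 6)), "square")
})

test_that("Fourier summary features follow their defining sums", {
  z <- fourier2(radial_psd(matrix(0, 64, 64), window = "none"))
  expect_equal(unname(z), c(0, 0))
  s <- outer(rep(1, 64), sin(2 * pi * 8 * (0:63) / 64))
  fs <- fourier2(radial_psd(s, window = "none"))
  expect_equal(unname(fs[["fft_first_moment"]]), 8 / 64, tolerance = 1e-3)
  set.seed(6)
  psd <- radial_psd(matrix(rnorm(64^2), 64, 64), window = "hann")
  ff <- fourier2(psd)
  idx <- which(round(psd$freq * psd$n) >= 3)
  expect_equal(unname(ff[["fft_rms_variation"]]),
               sqrt(sum(psd$power[idx])), tolerance = 1e-12)
  expect_equal(unname(ff[["fft_first_moment"]]),
               sum(psd$freq[idx] * psd$power[idx]) / sum(psd$power[idx]),
               tolerance = 1e-12)
})

test_that("box-counting features behave on smooth and fractal surfaces", {
  ramp <- outer(seq(0, 1, length.out = 256), rep(1, 256))
  fd <- boxcount6(ramp)
  expect_length(fd, 6)
  expect_lt(abs(fd[["bc_fd_all"]] - 2), 0.1)
  expect_error(boxcount6(matrix(0, 64, 64)), "128")
  fbm <- fbm_surface(0.5, size = 256, seed = 1)
  expect_lt(abs(boxcount6(fbm)[["bc_fd_all"]] - 2.5), 0.2)
})

test_that("the blanket dimension is exact on flats and tracks box counting", {
  expect_equal(unname(minkowski1(matrix(3, 64, 64))), 2, tolerance = 1e-6)
  fbm <- fbm_surface(0.3, size = 256, seed = 2)
  mk <- minkowski1(fbm)
  expect_lt(abs(mk - 2.7), 0.25)
  expect_lt(abs(mk - boxcount6(fbm)[["bc_fd_all"]]), 0.25)
})

test_that("the full bank has 50 features with the registry structure", {
  reg <- radiomic_registry()
  expect_equal(nrow(reg), 50)
  expect_equal(unname(table(factor(reg$category, levels = unique(reg$category)))),
               expected = c(6L, 4L, 10L, 2L, 5L, 1L, 8L, 14L),
               ignore_attr = TRUE)
  roi <- render_texture(texture_params(), size = 128, seed = 3)
  fv <- extract_radiomics(roi)
  expect_equal(names(fv), reg$name)
  expect_true(all(is.finite(unlist(fv))))
  expect_identical(fv, extract_radiomics(roi))
})

test_that("features have the documented intensity-shift behaviour", {
  roi <- render_texture(texture_params(), size = 128, seed = 4)$intensities
  a <- extract_radiomics(roi)
  b <- extract_radiomics(roi + 250)
  reg <- radiomic_registry()
  unchanged <- reg$name[reg$category %in% c("glcm", "ngtdm")]
  for (nm in unchanged) expect_equal(a[[nm]], b[[nm]], tolerance = 1e-9)
  expect_equal(a[["hist_entropy"]], b[["hist_entropy"]], tolerance = 1e-12)
  for (nm in c("hist_mean", "hist_median", "hist_p05", "hist_p95")) {
    expect_equal(b[[nm]] - a[[nm]], 250, tolerance = 1e-9)
  }
  expect_equal(a[["hist_sd"]], b[["hist_sd"]], tolerance = 1e-9)
})
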