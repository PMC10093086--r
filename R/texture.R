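#' Texture parameters for the lumpy power-law parenchyma surrogate
#'
#' The surrogate texture is an isotropic Gaussian random field whose radially
#' averaged power spectrum falls as `f^-beta`, plus Poisson-placed Gaussian
#' blobs ("lumps") mimicking focal fibroglandular densities, plus white
#' detector noise.
#'
#' @param beta spectral slope of the background field, in `[0, 4]`
#'   (`beta = 0` is white noise; mammographic parenchyma is typically ~2.8).
#' @param lump_density expected blobs per pixel^2.
#' @param lump_amplitude blob peak amplitude, relative to unit field SD.
#' @param lump_radius_px Gaussian radius of a blob, pixels.
#' @param noise_sd additive white-noise SD, relative to unit field SD.
#' @return An object of class `mt_texture_params`.
#' @export
texture_params <- function(beta = 2.8, lump_density = 2e-4,
                           lump_amplitude = 1, lump_radius_px = 6,
                           noise_sd = 0.15) {
  assert_number(beta, "beta", 0, 4)
  assert_number(lump_density, "lump_density", lower = 0)
  assert_number(lump_amplitude, "lump_amplitude", lower = 0)
  assert_number(lump_radius_px, "lump_radius_px", lower = .EPS)
  assert_number(noise_sd, "noise_sd", lower = 0)
  structure(list(beta = beta, lump_density = lump_density,
                 lump_amplitude = lump_amplitude,
                 lump_radius_px = lump_radius_px, noise_sd = noise_sd),
            class = "mt_texture_params")
}

# FFT sample frequencies in cycles/pixel for length n (like a radix-ordered
# frequency axis: 0, 1/n, ..., then negative frequencies)
fft_freqs <- function(n) {
  k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
  k / n
}

# zero-mean, unit-SD Gaussian field with radially averaged power spectrum
# proportional to f^-beta (spectral synthesis: shape white noise in Fourier
# space; conjugate symmetry is inherited from the real input field)
power_law_field <- function(nr, nc, beta) {
  w <- matrix(rnorm(nr * nc), nr, nc)
  if (beta == 0) {
    f <- w
  } else {
    W <- fft(w)
    rho <- sqrt(outer(fft_freqs(nr)^2, fft_freqs(nc)^2, `+`))
    amp <- rho
    amp[1, 1] <- Inf          # kill DC
    amp <- amp^(-beta / 2)
    amp[1, 1] <- 0
    f <- Re(fft(W * amp, inverse = TRUE)) / (nr * nc)
  }
  s <- sd(as.vector(f))
  if (s > 0) f <- (f - mean(f)) / s
  f
}

#' Render a synthetic parenchyma-like texture patch
#'
#' Deterministic given `seed`: a power-law Gaussian field plus Poisson-placed
#' Gaussian lumps plus white noise, min--max rescaled to the 12-bit range
#' `[0, 4095]`.
#'
#' @param params an [texture_params()] object (plain lists with the same
#'   fields, e.g. a row of [sample_cohort()] output, also work).
#' @param size integer pair, patch size in pixels (default `c(512, 512)`).
#' @param seed integer seed for this patch.
#' @return An `mt_roi` object whose `$intensities` is a `size` matrix.
#' @export
render_texture <- function(params, size = c(512L, 512L), seed = 1L) {
  if (length(size) == 1L) size <- c(size, size)
  if (any(size < 1)) abort("`size` must be positive")
  nr <- as.integer(size[1]); nc <- as.integer(size[2])
  p <- unclass(params)
  withr::with_seed(seed, {
    f <- power_law_field(nr, nc, p$beta)
    n_lumps <- rpois(1L, p$lump_density * nr * nc)
    if (n_lumps > 0 && p$lump_amplitude > 0) {
      cy <- runif(n_lumps, 1, nr)
      cx <- runif(n_lumps, 1, nc)
      r <- p$lump_radius_px
      half <- ceiling(4 * r)
      for (i in seq_len(n_lumps)) {
        rows <- max(1L, floor(cy[i] - half)):min(nr, ceiling(cy[i] + half))
        cols <- max(1L, floor(cx[i] - half)):min(nc, ceiling(cx[i] + half))
        d2 <- outer((rows - cy[i])^2, (cols - cx[i])^2, `+`)
        f[rows, cols] <- f[rows, cols] +
          p$lump_amplitude * exp(-d2 / (2 * r^2))
      }
    }
    if (p$noise_sd > 0) f <- f + p$noise_sd * matrix(rnorm(nr * nc), nr, nc)
    rng <- range(f)
    if (rng[2] > rng[1]) f <- (f - rng[1]) / (rng[2] - rng[1]) * 4095
    else f[] <- 0
    new_roi(f, origin = c(0L, 0L))
  })
}

#' Fractional-Brownian-motion calibration surface
#'
#' A self-similar Gaussian surface with Hurst exponent `H` (fractal
#' dimension `3 - H`), used as a phantom for the fractal-dimension
#' estimators. Synthesized spectrally with power spectrum `f^-(2H+2)` on an
#' `oversample`-times finer grid and then point-decimated: decimation aliases
#' super-Nyquist power into the sampled grid, giving the surface genuine
#' roughness at pixel scale (a directly synthesized band-limited field is
#' smooth at lag 1 and does not behave like sampled fBm there).
#'
#' @param H Hurst exponent in `(0, 1)`.
#' @param size output side in pixels.
#' @param seed integer seed.
#' @param oversample synthesis refinement factor.
#' @return A numeric matrix.
#' @export
fbm_surface <- function(H, size = 256L, seed = 1L, oversample = 4L) {
  assert_number(H, "H", 0.01, 0.99)
  big <- render_texture(texture_params(beta = 2 * H + 2, lump_density = 0,
                                       noise_sd = 0),
                        size = size * oversample, seed = seed)$intensities
  big[seq(1, size * oversample, by = oversample),
      seq(1, size * oversample, by = oversample)]
}

#' Render a sampled cohort to image files plus a manifest
#'
#' Writes one 16-bit TIFF patch per (case, exam, breast) row of a
#' [sample_cohort()] table, together with a manifest CSV
#' (`case_id, label, affected_laterality, laterality, exam_index, exam_date,
#' image_path, ...`) and the generating spec as JSON.
#'
#' @param cohort output of [sample_cohort()].
#' @param dir output directory (created if needed).
#' @param roi_size patch side in pixels.
#' @return The manifest tibble (invisibly written to `dir/manifest.csv`).
#' @export
render_cohort <- function(cohort, dir, roi_size = 512L) {
  spec <- attr(cohort, "spec")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- cohort
  manifest$image_path <- sprintf("%s_e%d_%s.tif", manifest$case_id,
                                 manifest$exam_index, manifest$laterality)
  for (r in seq_len(nrow(manifest))) {
    roi <- render_texture(
      manifest[r, c("beta", "lump_density", "lump_amplitude",
                    "lump_radius_px", "noise_sd")],
      size = roi_size,
      seed = (spec$seed * 1000003L + r) %% .Machine$integer.max
    )
    write_image(roi, file.path(dir, manifest$image_path[r]))
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
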