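# The 50-feature parenchymal texture bank. Category sizes are fixed:
# box-counting fractal 6, edge gradient 4, histogram 10, Fourier 2, NGTDM 5,
# Minkowski fractal 1, power-law beta 8, GLCM 14. All logarithms are base 2
# with 0*log(0) == 0; denominators are guarded by .EPS; degenerate inputs
# (constant patches) take the documented values rather than NaN.

.GLCM_LEVELS <- 16L      # gray levels for GLCM / NGTDM / histogram entropy
.GLCM_DISTANCE <- 1L
.PSD_MIN_INDEX <- 3L     # lowest annulus index used in spectral fits

#' Quantize an ROI to discrete gray levels
#'
#' Linear min--max binning of the patch's own intensity range into levels
#' `0 .. n_levels - 1` (the top bin is closed). A constant patch maps to
#' level 0 everywhere. Because binning uses the patch's own range, the result
#' is invariant to adding a constant offset.
#'
#' @param roi an `mt_roi` or numeric matrix.
#' @param n_levels number of gray levels (>= 2).
#' @return Integer matrix of levels.
#' @export
quantize_gray <- function(roi, n_levels = .GLCM_LEVELS) {
  n_levels <- assert_count(n_levels, "n_levels", lower = 2L)
  v <- as_intensity_matrix(roi)
  rng <- range(v)
  if (rng[2] <= rng[1]) {
    q <- v; q[] <- 0L; storage.mode(q) <- "integer"
    return(q)
  }
  q <- floor((v - rng[1]) / (rng[2] - rng[1]) * n_levels)
  q[q == n_levels] <- n_levels - 1L
  storage.mode(q) <- "integer"
  q
}

#' Gray-level co-occurrence matrix
#'
#' Counts co-occurring level pairs at pixel distance `distance_px` over the
#' requested angles (degrees, subset of 0/45/90/135), accumulated over angles,
#' optionally symmetrized, and normalized to sum 1.
#'
#' @param q integer matrix of quantized levels (see [quantize_gray()]).
#' @param n_levels number of levels `L`; the matrix is `L x L`.
#' @param distance_px offset length in pixels.
#' @param angles angles in degrees.
#' @param symmetric count each pair in both directions.
#' @return An `mt_glcm`: list with `probs`, `n_levels`, `distance_px`,
#'   `symmetric`.
#' @export
compute_glcm <- function(q, n_levels = max(q) + 1L, distance_px = .GLCM_DISTANCE,
                         angles = c(0, 45, 90, 135), symmetric = TRUE) {
  if (length(q) == 0L) abort("empty grid")
  if (!all(angles %in% c(0, 45, 90, 135))) {
    abort("angles must be a subset of {0, 45, 90, 135}")
  }
  d <- as.integer(distance_px)
  offsets <- list(`0` = c(0L, d), `45` = c(-d, d),
                  `90` = c(-d, 0L), `135` = c(-d, -d))
  L <- as.integer(n_levels)
  counts <- matrix(0, L, L)
  nr <- nrow(q); nc <- ncol(q)
  for (a in as.character(angles)) {
    off <- offsets[[a]]
    r1 <- max(1L, 1L - off[1]):min(nr, nr - off[1])
    c1 <- max(1L, 1L - off[2]):min(nc, nc - off[2])
    if (length(r1) == 0L || length(c1) == 0L) next
    from <- q[r1, c1, drop = FALSE]
    to <- q[r1 + off[1], c1 + off[2], drop = FALSE]
    idx <- cbind(as.vector(from) + 1L, as.vector(to) + 1L)
    tab <- table(factor(idx[, 1], levels = 1:L),
                 factor(idx[, 2], levels = 1:L))
    counts <- counts + as.matrix(tab)
  }
  if (symmetric) counts <- counts + t(counts)
  total <- sum(counts)
  probs <- if (total > 0) counts / total else counts
  structure(list(probs = unname(probs), n_levels = L, distance_px = d,
                 symmetric = symmetric), class = "mt_glcm")
}

#' Haralick's 14 GLCM statistics
#'
#' Computed on a normalized GLCM in the fixed order: energy, contrast,
#' correlation, sum-of-squares variance, inverse difference moment,
#' sum average, sum variance, sum entropy, entropy, difference variance,
#' difference entropy, information measure of correlation 1 and 2, and the
#' maximal correlation coefficient (square root of the second-largest
#' eigenvalue of the Q matrix; 0 when Q is degenerate). Gray levels are
#' indexed 0-based; logs are base 2; correlation is defined as 0 when a
#' marginal variance vanishes.
#'
#' @param glcm an `mt_glcm` (or a normalized probability matrix).
#' @return Named numeric vector of length 14 (names prefixed `glcm_`).
#' @export
haralick14 <- function(glcm) {
  P <- if (inherits(glcm, "mt_glcm")) glcm$probs else unname(as.matrix(glcm))
  L <- nrow(P)
  lev <- 0:(L - 1)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(lev * px); muy <- sum(lev * py)
  sx <- sqrt(sum((lev - mux)^2 * px)); sy <- sqrt(sum((lev - muy)^2 * py))
  I <- matrix(lev, L, L); J <- t(I)

  # distributions of i + j (support 0 .. 2L-2) and |i - j| (0 .. L-1)
  psum <- vapply(0:(2 * L - 2), function(k) sum(P[I + J == k]), numeric(1))
  pdif <- vapply(0:(L - 1), function(k) sum(P[abs(I - J) == k]), numeric(1))
  ks <- 0:(2 * L - 2); kd <- 0:(L - 1)

  energy <- sum(P^2)
  contrast <- sum((I - J)^2 * P)
  correlation <- if (sx > .EPS && sy > .EPS) {
    (sum(I * J * P) - mux * muy) / (sx * sy)
  } else 0
  variance <- sum((I - mux)^2 * P)
  idm <- sum(P / (1 + (I - J)^2))
  sum_avg <- sum(ks * psum)
  sum_var <- sum((ks - sum_avg)^2 * psum)
  sum_ent <- entropy2(psum)
  ent <- entropy2(as.vector(P))
  dif_avg <- sum(kd * pdif)
  dif_var <- sum((kd - dif_avg)^2 * pdif)
  dif_ent <- entropy2(pdif)

  pxy <- outer(px, py)
  pos <- P > 0 & pxy > 0
  hxy1 <- -sum(P[pos] * log2(pxy[pos]))
  posm <- pxy > 0
  hxy2 <- -sum(pxy[posm] * log2(pxy[posm]))
  hx <- entropy2(px); hy <- entropy2(py)
  imc1 <- if (max(hx, hy) > .EPS) (ent - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - ent))))

  mcc <- {
    nz <- which(px > .EPS & py > .EPS)
    if (length(nz) < 2L) 0 else {
      Ps <- P[nz, nz, drop = FALSE]
      # Q[i, j] = sum_k P(i,k) P(j,k) / (px(i) py(k))
      Q <- (Ps / px[nz]) %*% t(sweep(Ps, 2L, py[nz], `/`))
      ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
      sqrt(max(0, ev[2]))
    }
  }

  setNames(
    c(energy, contrast, correlation, variance, idm, sum_avg, sum_var,
      sum_ent, ent, dif_var, dif_ent, imc1, imc2, mcc),
    paste0("glcm_", c("energy", "contrast", "correlation", "variance", "idm",
                      "sum_average", "sum_variance", "sum_entropy", "entropy",
                      "difference_variance", "difference_entropy",
                      "imc1", "imc2", "mcc")))
}

#' Amadasun--King NGTDM features
#'
#' Coarseness, contrast, busyness, complexity and strength computed from the
#' neighborhood gray-tone difference matrix over interior pixels, with
#' `.EPS = 1e-12` guarding zero denominators (a constant patch therefore has
#' coarseness `1e12`).
#'
#' @param q integer matrix of quantized levels.
#' @param neighborhood odd window side (default 3).
#' @return Named numeric vector of length 5 (names prefixed `ngtdm_`).
#' @export
ngtdm5 <- function(q, neighborhood = 3L) {
  neighborhood <- assert_count(neighborhood, "neighborhood", lower = 3L)
  if (neighborhood %% 2L == 0L) abort("`neighborhood` must be odd")
  d <- neighborhood %/% 2L
  nr <- nrow(q); nc <- ncol(q)
  if (nr < neighborhood || nc < neighborhood) {
    abort("grid smaller than the NGTDM neighborhood")
  }
  # neighborhood mean excluding the center, via a box sum
  w <- neighborhood^2
  box <- matrix(0, nr - 2L * d, nc - 2L * d)
  for (dr in -d:d) for (dc in -d:d) {
    box <- box + q[(1L + d + dr):(nr - d + dr), (1L + d + dc):(nc - d + dc)]
  }
  center <- q[(1L + d):(nr - d), (1L + d):(nc - d)]
  A <- (box - center) / (w - 1)
  diffs <- abs(center - A)

  levels_present <- sort(unique(as.vector(center)))
  Npix <- length(center)
  s <- vapply(levels_present, function(k) sum(diffs[center == k]), numeric(1))
  n_i <- vapply(levels_present, function(k) sum(center == k), numeric(1))
  p <- n_i / Npix
  i <- levels_present
  Ng <- length(i)

  coarseness <- 1 / (.EPS + sum(p * s))
  contrast <- if (Ng > 1L) {
    (sum(outer(p, p) * outer(i, i, function(a, b) (a - b)^2)) /
       (Ng * (Ng - 1))) * (sum(s) / Npix)
  } else 0
  busyness <- if (Ng > 1L) {
    sum(p * s) / (.EPS + sum(abs(outer(i * p, i * p, `-`))))
  } else 0
  complexity <- if (Ng > 1L) {
    ps <- p * s
    sum(abs(outer(i, i, `-`)) * outer(ps, ps, `+`) /
          (Npix * outer(p, p, `+`)))
  } else 0
  strength <- sum(outer(p, p, `+`) * outer(i, i, function(a, b) (a - b)^2)) /
    (.EPS + sum(s))

  setNames(c(coarseness, contrast, busyness, complexity, strength),
           paste0("ngtdm_", c("coarseness", "contrast", "busyness",
                              "complexity", "strength")))
}

#' First-order histogram features
#'
#' Mean, SD, skewness, excess kurtosis, median, 5th and 95th percentiles,
#' gray-level entropy (on the 16-level quantized patch, base 2), uniformity
#' (sum of squared level probabilities) and balance
#' `(p95 - median) / (median - p5)` with an epsilon-guarded denominator.
#' Skewness and kurtosis are defined as 0 for a constant patch.
#'
#' @param roi an `mt_roi` or numeric matrix.
#' @return Named numeric vector of length 10 (names prefixed `hist_`).
#' @export
histogram10 <- function(roi) {
  v <- as.vector(as_intensity_matrix(roi))
  m <- mean(v)
  m2 <- mean((v - m)^2)
  s <- sqrt(m2)
  skew <- if (s > .EPS) mean((v - m)^3) / m2^1.5 else 0
  kurt <- if (s > .EPS) mean((v - m)^4) / m2^2 - 3 else 0
  qs <- unname(quantile(v, c(0.05, 0.5, 0.95)))
  q <- quantize_gray(as_intensity_matrix(roi), .GLCM_LEVELS)
  p <- tabulate(as.vector(q) + 1L, nbins = .GLCM_LEVELS) / length(q)
  ent <- entropy2(p)
  unif <- sum(p^2)
  num <- qs[3] - qs[2]; den <- qs[2] - qs[1]
  balance <- if (abs(den) > .EPS) num / den else if (abs(num) > .EPS) num / .EPS else 0
  setNames(c(m, s, skew, kurt, qs[2], qs[1], qs[3], ent, unif, balance),
           paste0("hist_", c("mean", "sd", "skewness", "kurtosis", "median",
                             "p05", "p95", "entropy", "uniformity", "balance")))
}

sobel_magnitude <- function(v) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)   # column gradient
  ky <- t(kx)                                           # row gradient
  img <- EBImage::as.Image(v)
  gx <- EBImage::filter2(img, kx, boundary = "replicate")
  gy <- EBImage::filter2(img, ky, boundary = "replicate")
  sqrt(EBImage::imageData(gx)^2 + EBImage::imageData(gy)^2)
}

#' Edge-gradient features
#'
#' Sobel gradient magnitude summarized by mean, SD, skewness, and the edge
#' fraction (share of pixels whose magnitude exceeds the Otsu threshold of
#' the magnitude image). A constant patch yields all zeros.
#'
#' @param roi an `mt_roi` or numeric matrix.
#' @return Named numeric vector of length 4 (names prefixed `eg_`).
#' @export
edge_gradient4 <- function(roi) {
  v <- as_intensity_matrix(roi)
  mag <- sobel_magnitude(v)
  m <- mean(mag); m2 <- mean((mag - m)^2); s <- sqrt(m2)
  skew <- if (s > .EPS) mean((mag - m)^3) / m2^1.5 else 0
  frac <- if (max(mag) > .EPS) {
    th <- EBImage::otsu(EBImage::as.Image(mag / max(mag)))
    mean(mag / max(mag) > th)
  } else 0
  setNames(c(m, s, skew, frac),
           paste0("eg_", c("mean", "sd", "skewness", "edge_fraction")))
}

#' Radially averaged power spectral density
#'
#' Mean-subtracts the patch, optionally applies a 2D Hann window, takes the
#' 2D FFT power, and averages it over annuli of width one frequency sample
#' (1/N cycles/pixel). The DC bin is excluded.
#'
#' @param roi an `mt_roi` or square numeric matrix.
#' @param window `"hann"` or `"none"`.
#' @return An `mt_psd`: list with `freq` (annulus center frequencies,
#'   cycles/pixel), `power` (mean power per annulus), `window`, `n`, and
#'   `total_power` (sum of the 2D power over all non-DC bins).
#' @export
radial_psd <- function(roi, window = c("hann", "none")) {
  window <- match.arg(window)
  v <- as_intensity_matrix(roi)
  n <- nrow(v)
  if (ncol(v) != n) abort("radial_psd expects a square patch")
  v <- v - mean(v)
  if (window == "hann") {
    h <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
    v <- v * outer(h, h)
  }
  P <- Mod(fft(v))^2
  fr <- fft_freqs(n)
  rho <- sqrt(outer(fr^2, fr^2, `+`))
  # annulus k collects bins with rho in ((k-0.5)/n, (k+0.5)/n]
  k <- as.integer(round(rho * n))
  kmax <- n %/% 2L
  keep <- k >= 1L & k <= kmax
  pow <- vapply(split(P[keep], k[keep]), mean, numeric(1))
  kk <- as.integer(names(pow))
  structure(list(freq = kk / n, power = unname(pow), window = window, n = n,
                 total_power = sum(P) - P[1, 1]),
            class = "mt_psd")
}

psd_band_indices <- function(psd) {
  which(round(psd$freq * psd$n) >= .PSD_MIN_INDEX)
}

#' Fourier summary features
#'
#' RMS spectral variation `sqrt(sum(P))` and the first moment of the power
#' spectrum `sum(f P) / sum(P)`, both over the fitted frequency band (annuli
#' at least 3 frequency samples from DC, avoiding DC leakage). An all-zero
#' spectrum yields `(0, 0)`.
#'
#' @param psd an `mt_psd` from [radial_psd()].
#' @return Named numeric vector of length 2 (names prefixed `fft_`).
#' @export
fourier2 <- function(psd) {
  idx <- psd_band_indices(psd)
  p <- psd$power[idx]; f <- psd$freq[idx]
  tot <- sum(p)
  out <- if (tot <= .EPS) c(0, 0) else c(sqrt(tot), sum(f * p) / tot)
  setNames(out, c("fft_rms_variation", "fft_first_moment"))
}

fit_loglog_slope <- function(freq, power) {
  pos <- power > 0
  if (sum(pos) < 2L) return(0)
  coef(lm(log2(power[pos]) ~ log2(freq[pos])))[[2]]
}

#' Power-law spectral slope features
#'
#' `beta = -slope` of the least-squares fit of log2 power vs log2 frequency
#' of the radially averaged spectrum, for 8 variants: {Hann window, no
#' window} x {full band, low/middle/high third of the usable frequency
#' range}. The usable band starts 3 frequency samples above DC to avoid DC
#' leakage; each fitted band must contain at least 8 annuli.
#'
#' @param roi an `mt_roi` or square numeric matrix (or a precomputed list of
#'   two `mt_psd`s named `hann` and `none`).
#' @return Named numeric vector of length 8 (names prefixed `pl_`).
#' @export
powerlaw8 <- function(roi) {
  psds <- if (is.list(roi) && !is.null(roi$hann) && inherits(roi$hann, "mt_psd")) {
    roi
  } else {
    list(hann = radial_psd(roi, "hann"), none = radial_psd(roi, "none"))
  }
  out <- c()
  for (w in c("hann", "none")) {
    psd <- psds[[w]]
    idx <- psd_band_indices(psd)
    f <- psd$freq[idx]
    cuts <- min(f) + (max(f) - min(f)) * c(1, 2) / 3
    bands <- list(
      full = idx,
      low = idx[f <= cuts[1]],
      mid = idx[f > cuts[1] & f <= cuts[2]],
      high = idx[f > cuts[2]]
    )
    for (b in names(bands)) {
      ii <- bands[[b]]
      if (length(ii) < 8L) abort("fewer than 8 annuli in a fitted band")
      beta <- -fit_loglog_slope(psd$freq[ii], psd$power[ii])
      out[sprintf("pl_%s_%s", w, b)] <- beta
    }
  }
  out
}

# 4-neighbour (cross) grayscale dilation/erosion with replicated edges
cross_extremum <- function(z, fun) {
  nr <- nrow(z); nc <- ncol(z)
  up <- z[c(1L, seq_len(nr - 1L)), ]
  down <- z[c(seq_len(nr - 1L) + 1L, nr), ]
  left <- z[, c(1L, seq_len(nc - 1L))]
  right <- z[, c(seq_len(nc - 1L) + 1L, nc)]
  if (identical(fun, max)) pmax(z, up, down, left, right)
  else pmin(z, up, down, left, right)
}

# local-mean subtraction used by the detrended box-counting variants
local_mean_subtract <- function(v, side = 65L) {
  k <- matrix(1 / side^2, side, side)
  mu <- EBImage::imageData(
    EBImage::filter2(EBImage::as.Image(v), k, boundary = "replicate"))
  v - mu
}

# vertical exaggeration applied before box/blanket counting: keeps box
# occupancy well above the +1 floor at coarse scales
.FD_AMPLITUDE <- 4

# differential box counting at one scale on an amplitude-scaled surface
dbc_count <- function(z, s) {
  M <- nrow(z)
  nb <- M %/% s
  zc <- z[seq_len(nb * s), seq_len(nb * s)]
  bi <- (row(zc) - 1L) %/% s + 1L
  bj <- (col(zc) - 1L) %/% s + 1L
  g <- (bj - 1L) * nb + bi
  zmax <- tapply(as.vector(zc), as.vector(g), max)
  zmin <- tapply(as.vector(zc), as.vector(g), min)
  sum(pmax(ceiling((zmax - zmin) / s), 1))
}

#' Box-counting fractal dimension features
#'
#' Differential box counting on the intensity surface with box sizes
#' `2, 4, ..., 128` and boxes of height equal to their side. The surface is
#' rescaled to `[0, 4 * (side - 1)]` (a fixed vertical exaggeration that
#' keeps coarse-scale box occupancy above the one-box floor), and the box
#' count per block is `max(ceil(range / s), 1)`. Six features: the fractal
#' dimension fitted over the headline band `s >= 8` (the two finest scales
#' are excluded because 2x2 and 4x4 block ranges are dominated by
#' finite-sample extremes rather than the scaling law), the fine half
#' (`s = 2..16`) and the coarse half (`s = 16..128`), each for the raw patch
#' and for a local-mean-subtracted (65-px boxcar) patch.
#'
#' @param roi an `mt_roi` or square numeric matrix with side >= 128.
#' @return Named numeric vector of length 6 (names prefixed `bc_`).
#' @export
boxcount6 <- function(roi) {
  v <- as_intensity_matrix(roi)
  M <- min(dim(v))
  if (M < 128L) abort("box counting needs a patch of at least 128 px")
  v <- v[seq_len(M), seq_len(M)]
  scales <- 2L^(1:7)
  fd_for <- function(z) {
    rng <- range(z)
    z <- if (rng[2] > rng[1]) {
      (z - rng[1]) / (rng[2] - rng[1]) * .FD_AMPLITUDE * (M - 1)
    } else z * 0
    N <- vapply(scales, function(s) dbc_count(z, s), numeric(1))
    ls <- log2(scales); lN <- log2(N)
    slope <- function(ii) -coef(lm(lN[ii] ~ ls[ii]))[[2]]
    c(all = slope(3:7), fine = slope(1:4), coarse = slope(4:7))
  }
  raw <- fd_for(v)
  det <- fd_for(local_mean_subtract(v))
  setNames(c(raw, det),
           paste0("bc_", c("fd_all", "fd_fine", "fd_coarse",
                           "fd_all_detrended", "fd_fine_detrended",
                           "fd_coarse_detrended")))
}

#' Minkowski (blanket) fractal dimension
#'
#' Morphological blanket estimate: upper and lower surfaces grown by
#' iterated grayscale dilation/erosion (cross structuring element) with unit
#' vertical growth, surface area `A(e) = sum(u_e - l_e) / (2e)` for
#' `e = 1..16`, and `FD = 2 - slope(log A ~ log e)` fitted over `e = 8..16`
#' (small blanket widths are dominated by the unit growth and local extremes,
#' so the fit uses the scaling regime). Intensities are rescaled to
#' `[0, 4 * (side - 1)]` as in [boxcount6()]; a constant patch gives
#' exactly 2.
#'
#' @param roi an `mt_roi` or square numeric matrix.
#' @return Named numeric vector of length 1 (`mink_fd`).
#' @export
minkowski1 <- function(roi) {
  v <- as_intensity_matrix(roi)
  M <- min(dim(v))
  v <- v[seq_len(M), seq_len(M)]
  rng <- range(v)
  z <- if (rng[2] > rng[1]) {
    (v - rng[1]) / (rng[2] - rng[1]) * .FD_AMPLITUDE * (M - 1)
  } else v * 0
  u <- z; l <- z
  emax <- 16L
  A <- numeric(emax)
  for (e in seq_len(emax)) {
    u <- pmax(u + 1, cross_extremum(u, max))
    l <- pmin(l - 1, cross_extremum(l, min))
    A[e] <- sum(u - l) / (2 * e)
  }
  band <- 8:16
  fd <- 2 - coef(lm(log2(A[band]) ~ log2(band)))[[2]]
  c(mink_fd = fd)
}

#' The radiomic feature registry
#'
#' @return A tibble with columns `name` and `category` listing the 50
#'   features in extraction order; per-category counts are
#'   (6, 4, 10, 2, 5, 1, 8, 14).
#' @export
radiomic_registry <- function() {
  tibble::tibble(
    name = c(
      paste0("bc_", c("fd_all", "fd_fine", "fd_coarse", "fd_all_detrended",
                      "fd_fine_detrended", "fd_coarse_detrended")),
      paste0("eg_", c("mean", "sd", "skewness", "edge_fraction")),
      paste0("hist_", c("mean", "sd", "skewness", "kurtosis", "median",
                        "p05", "p95", "entropy", "uniformity", "balance")),
      c("fft_rms_variation", "fft_first_moment"),
      paste0("ngtdm_", c("coarseness", "contrast", "busyness", "complexity",
                         "strength")),
      "mink_fd",
      c(t(outer(c("pl_hann_", "pl_none_"), c("full", "low", "mid", "high"),
                paste0))),
      paste0("glcm_", c("energy", "contrast", "correlation", "variance",
                        "idm", "sum_average", "sum_variance", "sum_entropy",
                        "entropy", "difference_variance", "difference_entropy",
                        "imc1", "imc2", "mcc"))
    ),
    category = rep(c("boxcount_fd", "edge_gradient", "histogram", "fourier",
                     "ngtdm", "minkowski_fd", "powerlaw_beta", "glcm"),
                   times = c(6, 4, 10, 2, 5, 1, 8, 14))
  )
}

#' Extract the full 50-feature radiomic bank from one ROI
#'
#' Concatenates the eight feature families in registry order (box-counting 6,
#' edge gradient 4, histogram 10, Fourier 2, NGTDM 5, Minkowski 1, power-law
#' 8, GLCM 14). Deterministic: the same patch always yields the same vector.
#'
#' @param roi an `mt_roi` or square numeric matrix (side >= 128).
#' @return A one-row tibble with 50 named feature columns.
#' @export
extract_radiomics <- function(roi) {
  v <- as_intensity_matrix(roi)
  q <- quantize_gray(v, .GLCM_LEVELS)
  psds <- list(hann = radial_psd(v, "hann"), none = radial_psd(v, "none"))
  vals <- c(
    boxcount6(v),
    edge_gradient4(v),
    histogram10(v),
    fourier2(psds$hann),
    ngtdm5(q),
    minkowski1(v),
    powerlaw8(psds),
    haralick14(compute_glcm(q, n_levels = .GLCM_LEVELS))
  )
  reg <- radiomic_registry()
  stopifnot(identical(names(vals), reg$name))
  tibble::as_tibble(as.list(vals))
}

#' Batch radiomic extraction over a manifest
#'
#' Reads each manifest image, extracts the 50-feature bank, and returns one
#' row per (case, exam, laterality) with provenance columns followed by the
#' feature columns.
#'
#' @param manifest tibble from [read_manifest()] (an `image_path` column,
#'   resolved relative to `dir`).
#' @param dir directory containing the images.
#' @return A tibble of provenance + 50 feature columns.
#' @export
extract_radiomics_batch <- function(manifest, dir = ".") {
  purrr::map_dfr(seq_len(nrow(manifest)), function(r) {
    img <- read_image(file.path(dir, manifest$image_path[r]),
                      spacing_mm = c(0.07, 0.07))
    dplyr::bind_cols(
      manifest[r, intersect(c("case_id", "label", "affected_laterality",
                              "laterality", "is_affected", "exam_index",
                              "exam_date", "time_years", "years_before_last"),
                            names(manifest))],
      extract_radiomics(img$intensities)
    )
  })
}
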