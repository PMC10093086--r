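# Independent brute-force oracles used to validate the package's vectorized
# implementations. These are deliberately written as plain loops over the
# defining formulas and share no code with the package internals.

# Haralick statistics from a normalized co-occurrence matrix, 0-based levels,
# base-2 logs, 0*log0 == 0, sum variance centered at the sum average,
# variance centered at the x-marginal mean.
oracle_haralick <- function(P) {
  L <- nrow(P)
  lg2 <- function(x) ifelse(x > 0, log2(x), 0)
  px <- rowSums(P); py <- colSums(P)
  mux <- 0; muy <- 0
  for (i in 1:L) { mux <- mux + (i - 1) * px[i]; muy <- muy + (i - 1) * py[i] }
  sx2 <- 0; sy2 <- 0
  for (i in 1:L) { sx2 <- sx2 + ((i - 1) - mux)^2 * px[i]
                   sy2 <- sy2 + ((i - 1) - muy)^2 * py[i] }
  psum <- numeric(2 * L - 1)   # index k+1 = i+j (0-based sum)
  pdif <- numeric(L)           # index k+1 = |i-j|
  for (i in 1:L) for (j in 1:L) {
    psum[(i - 1) + (j - 1) + 1] <- psum[(i - 1) + (j - 1) + 1] + P[i, j]
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + P[i, j]
  }
  f1 <- sum(P^2)
  f2 <- 0; f3n <- 0; f4 <- 0; f5 <- 0; f9 <- 0
  for (i in 1:L) for (j in 1:L) {
    f2 <- f2 + ((i - 1) - (j - 1))^2 * P[i, j]
    f3n <- f3n + (i - 1) * (j - 1) * P[i, j]
    f4 <- f4 + ((i - 1) - mux)^2 * P[i, j]
    f5 <- f5 + P[i, j] / (1 + ((i - 1) - (j - 1))^2)
    f9 <- f9 - P[i, j] * lg2(P[i, j])
  }
  f3 <- if (sx2 > 1e-12 && sy2 > 1e-12) {
    (f3n - mux * muy) / sqrt(sx2 * sy2)
  } else 0
  f6 <- 0
  for (k in seq_along(psum)) f6 <- f6 + (k - 1) * psum[k]
  f7 <- 0; f8 <- 0
  for (k in seq_along(psum)) {
    f7 <- f7 + ((k - 1) - f6)^2 * psum[k]
    f8 <- f8 - psum[k] * lg2(psum[k])
  }
  dmu <- 0
  for (k in seq_along(pdif)) dmu <- dmu + (k - 1) * pdif[k]
  f10 <- 0; f11 <- 0
  for (k in seq_along(pdif)) {
    f10 <- f10 + ((k - 1) - dmu)^2 * pdif[k]
    f11 <- f11 - pdif[k] * lg2(pdif[k])
  }
  hx <- -sum(ifelse(px > 0, px * lg2(px), 0))
  hy <- -sum(ifelse(py > 0, py * lg2(py), 0))
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:L) for (j in 1:L) {
    pp <- px[i] * py[j]
    if (pp > 0) {
      if (P[i, j] > 0) hxy1 <- hxy1 - P[i, j] * lg2(pp)
      hxy2 <- hxy2 - pp * lg2(pp)
    }
  }
  f12 <- if (max(hx, hy) > 1e-12) (f9 - hxy1) / max(hx, hy) else 0
  f13 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - f9))))
  nz <- which(px > 1e-12 & py > 1e-12)
  f14 <- if (length(nz) < 2) 0 else {
    Q <- matrix(0, length(nz), length(nz))
    for (a in seq_along(nz)) for (b in seq_along(nz)) {
      s <- 0
      for (k in nz) {
        s <- s + P[nz[a], k] * P[nz[b], k] / (px[nz[a]] * py[k])
      }
      Q[a, b] <- s
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, ev[2]))
  }
  c(f1, f2, f3, f4, f5, f6, f7, f8, f9, f10, f11, f12, f13, f14)
}

# Amadasun-King NGTDM features by direct per-pixel neighborhood computation
oracle_ngtdm <- function(q, eps = 1e-12) {
  nr <- nrow(q); nc <- ncol(q)
  centers <- c(); avgs <- c()
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
    nb <- q[(i - 1):(i + 1), (j - 1):(j + 1)]
    centers <- c(centers, q[i, j])
    avgs <- c(avgs, (sum(nb) - q[i, j]) / 8)
  }
  Np <- length(centers)
  lv <- sort(unique(centers))
  s <- sapply(lv, function(k) sum(abs(centers[centers == k] -
                                        avgs[centers == k])))
  p <- sapply(lv, function(k) mean(centers == k))
  Ng <- length(lv)
  coar <- 1 / (eps + sum(p * s))
  con <- 0; bus_d <- 0; comp <- 0; str_ <- 0
  if (Ng > 1) {
    for (a in 1:Ng) for (b in 1:Ng) {
      con <- con + p[a] * p[b] * (lv[a] - lv[b])^2
      bus_d <- bus_d + abs(lv[a] * p[a] - lv[b] * p[b])
      comp <- comp + abs(lv[a] - lv[b]) * (p[a] * s[a] + p[b] * s[b]) /
        (Np * (p[a] + p[b]))
      str_ <- str_ + (p[a] + p[b]) * (lv[a] - lv[b])^2
    }
    con <- con / (Ng * (Ng - 1)) * sum(s) / Np
    bus <- sum(p * s) / (eps + bus_d)
    strength <- str_ / (eps + sum(s))
  } else { con <- 0; bus <- 0; comp <- 0; strength <- 0 }
  c(coar, con, bus, comp, strength)
}

# first-order statistics computed directly from definitions
oracle_histogram <- function(v, n_levels = 16) {
  v <- as.vector(v)
  m <- mean(v); s2 <- mean((v - m)^2); s <- sqrt(s2)
  sk <- if (s > 1e-12) mean((v - m)^3) / s2^1.5 else 0
  ku <- if (s > 1e-12) mean((v - m)^4) / s2^2 - 3 else 0
  qs <- unname(quantile(v, c(0.05, 0.5, 0.95)))
  rng <- range(v)
  if (rng[2] > rng[1]) {
    lev <- floor((v - rng[1]) / (rng[2] - rng[1]) * n_levels)
    lev[lev == n_levels] <- n_levels - 1
  } else lev <- rep(0, length(v))
  p <- as.vector(table(factor(lev, levels = 0:(n_levels - 1)))) / length(v)
  ent <- -sum(ifelse(p > 0, p * log2(p), 0))
  unif <- sum(p^2)
  num <- qs[3] - qs[2]; den <- qs[2] - qs[1]
  bal <- if (abs(den) > 1e-12) num / den else if (abs(num) > 1e-12) num / 1e-12 else 0
  c(m, s, sk, ku, qs[2], qs[1], qs[3], ent, unif, bal)
}

# AUC by exhaustive enumeration of positive-negative pairs, ties count 1/2
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# minimal explicit-VR little-endian DICOM writer for test fixtures
write_test_dicom <- function(path, mat, spacing = c(0.07, 0.07),
                             transfer_syntax = "1.2.840.10008.1.2.1") {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, eos = NULL)
  put_u16 <- function(x) writeBin(as.integer(x), con, size = 2L,
                                  endian = "little")
  elem <- function(group, element, vr, value_raw) {
    put_u16(group); put_u16(element)
    writeChar(vr, con, eos = NULL)
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      writeBin(raw(2), con)
      writeBin(length(value_raw), con, size = 4L, endian = "little")
    } else {
      put_u16(length(value_raw))
    }
    writeBin(value_raw, con)
  }
  pad_even <- function(s, pad = as.raw(0L)) {
    r <- charToRaw(s)
    if (length(r) %% 2 == 1) r <- c(r, pad)
    r
  }
  u16_raw <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                                  endian = "little")
  elem(0x0002, 0x0010, "UI", pad_even(transfer_syntax))
  elem(0x0028, 0x0010, "US", u16_raw(nrow(mat)))
  elem(0x0028, 0x0011, "US", u16_raw(ncol(mat)))
  elem(0x0028, 0x0100, "US", u16_raw(16L))
  elem(0x0028, 0x0030, "DS",
       pad_even(sprintf("%g\\%g", spacing[1], spacing[2]), charToRaw(" ")))
  px <- as.integer(t(mat))          # row-major
  elem(0x7FE0, 0x0010, "OW", writeBin(px, raw(), size = 2L,
                                      endian = "little"))
  invisible(path)
}
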