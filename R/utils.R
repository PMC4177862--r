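# Internal numerical helpers shared across modules.

#' @importFrom stats filter
NULL

# 1-D Gaussian kernel, truncated at 3 sigma, normalised.
gaussianKernel1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian smoothing with replicate-edge padding. Border handling
# matters for displacement fields: circular or zero padding would drag the
# field toward zero at the image edge.
smooth2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gaussianKernel1d(sigma)
  r <- (length(k) - 1L) / 2L
  nr <- nrow(m); nc <- ncol(m)
  mp <- m[c(rep(1L, r), seq_len(nr), rep(nr, r)),
          c(rep(1L, r), seq_len(nc), rep(nc, r)), drop = FALSE]
  f1 <- stats::filter(mp, k, sides = 2)
  f2 <- t(stats::filter(t(f1), k, sides = 2))
  out <- as.matrix(f2)[r + seq_len(nr), r + seq_len(nc), drop = FALSE]
  dimnames(out) <- NULL
  out
}

# Bilinear interpolation of img at fractional (row, col) index positions;
# zero outside the image domain.
bilinearSample <- function(img, ri, ci) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(ri); c0 <- floor(ci)
  fr <- ri - r0; fc <- ci - c0
  pick <- function(r, c) {
    v <- numeric(length(r))
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    v[ok] <- img[cbind(r[ok], c[ok])]
    v
  }
  (1 - fr) * (1 - fc) * pick(r0, c0) +
    fr * (1 - fc) * pick(r0 + 1, c0) +
    (1 - fr) * fc * pick(r0, c0 + 1) +
    fr * fc * pick(r0 + 1, c0 + 1)
}

# Partial derivative of a matrix field along rows (margin = 1, physical step
# spacing) or columns (margin = 2): central differences inside, one-sided at
# the borders.
finiteDiff <- function(m, margin, step) {
  n <- dim(m)[margin]
  if (n < 2) stop("finiteDiff needs at least 2 samples along the margin")
  idx <- seq_len(n)
  up <- pmin(idx + 1L, n)
  dn <- pmax(idx - 1L, 1L)
  denom <- (up - dn) * step
  if (margin == 1L) {
    (m[up, , drop = FALSE] - m[dn, , drop = FALSE]) / denom
  } else {
    sweep(m[, up, drop = FALSE] - m[, dn, drop = FALSE], 2L, denom, "/")
  }
}

# 4-connected component count of a binary matrix (BFS over a pixel queue).
# Used only for validity diagnostics, so clarity beats speed.
connectedComponents4 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  comp <- 0L
  fg <- which(mask > 0)
  for (p in fg) {
    if (lab[p] != 0L) next
    comp <- comp + 1L
    queue <- p
    lab[p] <- comp
    while (length(queue)) {
      q <- queue[[1]]
      queue <- queue[-1]
      r <- ((q - 1L) %% nr) + 1L
      cc <- ((q - 1L) %/% nr) + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1]; cci <- cc + d[2]
        if (rr >= 1L && rr <= nr && cci >= 1L && cci <= nc) {
          qq <- (cci - 1L) * nr + rr
          if (mask[qq] > 0 && lab[qq] == 0L) {
            lab[qq] <- comp
            queue <- c(queue, qq)
          }
        }
      }
    }
  }
  list(labels = lab, n = comp)
}

# Deterministic fan-out of a master seed into per-subject / per-stage seeds,
# kept below 2^31 so they remain valid R integer seeds.
fanSeed <- function(master, index) {
  as.integer((as.double(master) * 48271 + as.double(index) * 1000003) %%
               2147483647)
}

# Draw from N(mean, sd) truncated at +/- 3 sd by rejection.
rnormTrunc3 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- abs(x - mean) <= 3 * sd
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

ccStop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "ccmorphError")))
}
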