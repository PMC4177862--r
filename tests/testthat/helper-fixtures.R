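# Fixtures built in code: filled rectangles, arch shapes on canvases, and
# tiny cohorts shared across test files.

filledRectMask <- function(nrow = 35, ncol = 100, spacing = c(1, 1)) {
  midsagittalMask(matrix(1L, nrow, ncol), spacing = spacing, subjectID = "rect")
}

# an arch mask centred on a larger canvas (common grid for registration)
archOnCanvas <- function(base = 80, height = 28,
                         areas = c(200, 80, 90, 60, 170),
                         canvas = c(60, 110), shift = c(0, 0),
                         id = "arch") {
  m <- makeCCShape(base, height, areas, subjectID = id)
  px <- maskPixels(m)
  cv <- matrix(0L, canvas[1], canvas[2])
  r0 <- floor((canvas[1] - nrow(px)) / 2) + shift[1]
  c0 <- floor((canvas[2] - ncol(px)) / 2) + shift[2]
  cv[r0 + seq_len(nrow(px)), c0 + seq_len(ncol(px))] <- px
  midsagittalMask(cv, spacing = pixelSpacing(m), subjectID = id)
}

# random 4-connected blob grown from a seed pixel (for rectangle oracles)
randomBlob <- function(npix = 50, dim = c(30, 30)) {
  px <- matrix(0L, dim[1], dim[2])
  r <- sample(5:(dim[1] - 5), 1); c <- sample(5:(dim[2] - 5), 1)
  px[r, c] <- 1L
  frontier <- matrix(c(r, c), 1, 2)
  while (sum(px) < npix) {
    i <- sample(nrow(frontier), 1)
    d <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))[sample(4, 1), ]
    nr <- frontier[i, 1] + d[1]; nc <- frontier[i, 2] + d[2]
    if (nr >= 2 && nr <= dim[1] - 1 && nc >= 2 && nc <= dim[2] - 1 &&
        px[nr, nc] == 0L) {
      px[nr, nc] <- 1L
      frontier <- rbind(frontier, c(nr, nc))
    }
  }
  # keep the long axis along columns so "+col" is a valid anterior direction
  idx <- which(px > 0, arr.ind = TRUE)
  if (diff(range(idx[, 1])) > diff(range(idx[, 2]))) px <- t(px)
  midsagittalMask(px, spacing = c(1, 1), subjectID = "blob")
}

# brute-force minimum-area rectangle over rotations (oracle for min_area
# mode): rotate pixel centers over a grid of angles, take axis bounds
bruteForceMinRectArea <- function(mask, stepDeg = 0.1,
                                  convention = "pixel_center") {
  pts <- cbind((which(maskPixels(mask) > 0, arr.ind = TRUE)[, 2] - 0.5),
               (which(maskPixels(mask) > 0, arr.ind = TRUE)[, 1] - 0.5))
  best <- Inf
  for (th in seq(0, 90 - stepDeg, by = stepDeg) * pi / 180) {
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
    q <- pts %*% R
    w <- diff(range(q[, 1])); h <- diff(range(q[, 2]))
    if (convention == "pixel_extent") {
      w <- w + abs(R[1, 1]) + abs(R[2, 1])
      h <- h + abs(R[1, 2]) + abs(R[2, 2])
    }
    best <- min(best, w * h)
  }
  best
}

# samples with exact first and second moments (mean, sd hit exactly),
# for deterministic reproduction of printed cell statistics
exactMomentSample <- function(n, mean, sd) {
  x <- stats::qnorm(seq_len(n) / (n + 1))
  x <- (x - mean(x)) / stats::sd(x)
  mean + sd * x
}

# area table with the four printed isthmus cells at their exact moments
exactIsthmusCellTable <- function(cells, nScale = 1) {
  rows <- NULL; idx <- 0
  for (nm in names(cells)) {
    cl <- cells[[nm]]
    parts <- strsplit(nm, "_")[[1]]
    y <- exactMomentSample(cl$n * nScale, cl$mean, cl$sd)
    y <- y[(seq_along(y) * 5L) %% length(y) + 1L]  # decorrelate from age order
    age <- seq(20, 60, length.out = cl$n * nScale)
    idx <- idx + 1
    rows <- rbind(rows, data.frame(
      subject_id = sprintf("%s%03d", nm, seq_along(y)), group = parts[1],
      sex = parts[2], age = age, site = "site1", linear_scale = 1,
      region = "isthmus", stereotaxic_area_mm2 = y, native_area_mm2 = y,
      stringsAsFactors = FALSE))
  }
  rows
}
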