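# Five-region proportional subdivision: four cuts perpendicular to the long
# side of the minimum rectangle, at cumulative 33/50/67/80% of its length
# measured from the anterior end.

#' Subdivide a CC mask into five proportional sub-regions
#'
#' Cuts the mask with four lines perpendicular to the rectangle's long side,
#' at cumulative fractions of the base length measured from the anterior
#' end (0.33, 0.50, 0.67 and 0.80 by default). A pixel belongs to slab k if
#' its center's coordinate along the base axis falls in the half-open
#' interval `[start_k, end_k)`; the last slab is closed. The image
#' handedness is never assumed: `anteriorDirection` declares whether the
#' anterior end lies toward increasing (`"+col"`) or decreasing (`"-col"`)
#' column index.
#'
#' @param mask a [MidsagittalMask-class].
#' @param rect its [BoundingRect-class] (any mode); for `min_area`
#'   rectangles the base axis is the rectangle's long-edge direction.
#' @param anteriorDirection `"+col"` or `"-col"`.
#' @param fractions five length fractions summing to 1, anterior to
#'   posterior (default [ccRegionFractions()]).
#' @return A [SubregionLabelMap-class]; label 1 is the anterior third,
#'   label 5 the splenium.
#' @export
subdivide <- function(mask, rect, anteriorDirection = c("+col", "-col"),
                      fractions = ccRegionFractions()) {
  anteriorDirection <- match.arg(anteriorDirection)
  stopifnot(is(mask, "MidsagittalMask"), is(rect, "BoundingRect"))
  if (length(fractions) != 5 || abs(sum(fractions) - 1) > 1e-9)
    ccStop("ccmorphBadFractions",
           "fractions must be five values summing to 1 (got sum %.6f)",
           sum(fractions))
  pts <- foregroundCenters(mask)
  corners <- rectCorners(rect)
  b <- baseLength(rect)
  u <- (corners[2, ] - corners[1, ]) / b
  origin <- corners[1, ]
  avec <- if (anteriorDirection == "+col") c(1, 0) else c(-1, 0)
  d <- sum(u * avec)
  if (abs(d) < 1e-9)
    ccStop("ccmorphBadOrientation",
           "anteriorDirection has no component along the rectangle base axis")
  if (d < 0) {                 # walk the base from the anterior end
    origin <- corners[2, ]
    u <- -u
  }
  t <- (pts[, "x"] - origin[1]) * u[1] + (pts[, "y"] - origin[2]) * u[2]
  if (any(t < -1e-6 * b) || any(t > b * (1 + 1e-6)))
    ccStop("ccmorphRectMismatch",
           "rectangle does not cover the mask foreground")
  t <- pmin(pmax(t, 0), b)
  cuts <- b * cumsum(fractions)[1:4]
  lab <- findInterval(t, cuts) + 1L   # half-open; t == cut joins next slab
  labels <- matrix(0L, nrow(maskPixels(mask)), ncol(maskPixels(mask)))
  idx <- which(maskPixels(mask) > 0, arr.ind = TRUE)  # same order as pts
  labels[idx] <- lab
  new("SubregionLabelMap", labels = labels, spacing = pixelSpacing(mask),
      proportions = as.numeric(fractions))
}

#' Pixel-count areas of the five sub-regions
#'
#' `area_k = count(label == k) * row_mm * col_mm`. This is the native-space
#' area oracle against which Jacobian-integrated areas are checked.
#'
#' @param labelmap a [SubregionLabelMap-class].
#' @param spacing optional spacing override, `c(row_mm, col_mm)`.
#' @return Named numeric vector of five areas (mm^2), anterior to posterior.
#' @export
regionPixelAreas <- function(labelmap, spacing = NULL) {
  sp <- if (is.null(spacing)) pixelSpacing(labelmap) else as.numeric(spacing)
  lab <- labelMatrix(labelmap)
  counts <- tabulate(lab[lab > 0], nbins = 5)
  if (any(counts == 0))
    warning("empty sub-region(s): ",
            paste(ccRegionNames()[counts == 0], collapse = ", "))
  stats::setNames(counts * sp[1] * sp[2], ccRegionNames())
}
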