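# Minimum rectangle covering a CC mask and the bending-angle statistic.

# Physical (x, y) mm coordinates of foreground pixel centers; x runs along
# columns, y along rows.
foregroundCenters <- function(mask) {
  idx <- which(maskPixels(mask) > 0, arr.ind = TRUE)
  sp <- pixelSpacing(mask)
  cbind(x = (idx[, 2] - 0.5) * sp[2], y = (idx[, 1] - 0.5) * sp[1])
}

#' Minimum rectangle covering a mask
#'
#' Constructs the rectangle circumscribing the mask foreground, the basis of
#' both the bending-angle statistic and the five-region subdivision. Two
#' modes: `"axis_aligned"` takes tight bounds along the image axes (the
#' default: masks are assumed AC-PC aligned, so the rectangle is axis-aligned
#' in practice); `"min_area"` computes the minimum-area rotated rectangle of
#' the foreground convex hull by rotating calipers over hull edges.
#'
#' Two pixel conventions are supported. `"pixel_extent"` (default) measures
#' between outer pixel boundaries, so a filled run of n pixels at 1 mm
#' spacing has length n; this is self-consistent with pixel-count areas.
#' `"pixel_center"` measures between pixel centers (n - 1 for the same run).
#' For rotated rectangles the extent convention pads each side by the pixel
#' footprint projected onto that side's direction.
#'
#' @param mask a [MidsagittalMask-class] with non-empty foreground.
#' @param mode `"axis_aligned"` or `"min_area"`.
#' @param convention `"pixel_extent"` or `"pixel_center"`.
#' @return A [BoundingRect-class]; the base is always the longer side.
#' @export
boundingRectangle <- function(mask, mode = c("axis_aligned", "min_area"),
                              convention = c("pixel_extent", "pixel_center")) {
  mode <- match.arg(mode)
  convention <- match.arg(convention)
  if (sum(maskPixels(mask)) == 0)
    ccStop("ccmorphEmptyMask", "cannot bound an empty mask")
  pts <- foregroundCenters(mask)
  sp <- pixelSpacing(mask)
  # a mask spanning a single row or column has no height: the bending angle
  # and subdivision are undefined regardless of the pixel convention
  if (diff(range(pts[, "x"])) == 0 || diff(range(pts[, "y"])) == 0)
    ccStop("ccmorphDegenerateRect", "zero-extent rectangle")

  if (mode == "axis_aligned") {
    xr <- range(pts[, "x"]); yr <- range(pts[, "y"])
    if (convention == "pixel_extent") {
      xr <- xr + c(-0.5, 0.5) * sp[2]
      yr <- yr + c(-0.5, 0.5) * sp[1]
    }
    wx <- diff(xr); wy <- diff(yr)
    if (min(wx, wy) <= 0)
      ccStop("ccmorphDegenerateRect", "zero-extent rectangle")
    if (wx >= wy) {
      corners <- rbind(c(xr[1], yr[1]), c(xr[2], yr[1]),
                       c(xr[2], yr[2]), c(xr[1], yr[2]))
      base <- wx; height <- wy
    } else {
      corners <- rbind(c(xr[1], yr[1]), c(xr[1], yr[2]),
                       c(xr[2], yr[2]), c(xr[2], yr[1]))
      base <- wy; height <- wx
    }
  } else {
    hull <- grDevices::chull(pts[, "x"], pts[, "y"])
    hp <- pts[hull, , drop = FALSE]
    if (nrow(hp) < 3)
      ccStop("ccmorphDegenerateRect", "zero-extent rectangle")
    best <- NULL
    nh <- nrow(hp)
    for (i in seq_len(nh)) {
      e <- hp[i %% nh + 1, ] - hp[i, ]
      len <- sqrt(sum(e^2))
      if (len < 1e-12) next
      u <- e / len            # edge direction
      v <- c(-u[2], u[1])     # perpendicular
      pu <- hp %*% u; pv <- hp %*% v
      du <- diff(range(pu)); dv <- diff(range(pv))
      if (convention == "pixel_extent") {
        du <- du + abs(u[1]) * sp[2] + abs(u[2]) * sp[1]
        dv <- dv + abs(v[1]) * sp[2] + abs(v[2]) * sp[1]
      }
      area <- du * dv
      if (is.null(best) || area < best$area - 1e-12) {
        best <- list(area = area, u = u, v = v,
                     ur = range(pu), vr = range(pv), du = du, dv = dv)
      }
    }
    if (is.null(best) || min(best$du, best$dv) <= 0)
      ccStop("ccmorphDegenerateRect", "zero-extent rectangle")
    padu <- (best$du - diff(best$ur)) / 2
    padv <- (best$dv - diff(best$vr)) / 2
    u <- best$u; v <- best$v
    o <- (best$ur[1] - padu) * u + (best$vr[1] - padv) * v
    if (best$du >= best$dv) {
      corners <- rbind(o, o + best$du * u, o + best$du * u + best$dv * v,
                       o + best$dv * v)
      base <- best$du; height <- best$dv
    } else {
      corners <- rbind(o, o + best$dv * v, o + best$dv * v + best$du * u,
                       o + best$du * u)
      base <- best$dv; height <- best$du
    }
  }
  dimnames(corners) <- NULL
  new("BoundingRect", baseMM = unname(base), heightMM = unname(height),
      corners = unname(as.matrix(corners)), mode = mode,
      convention = convention)
}

#' Bending angle of the corpus callosum
#'
#' Vertex angle (degrees) of the isosceles triangle sharing the base and
#' height of the minimum rectangle circumscribing the CC:
#' `2 * arctan(base / (2 * height))`. A flatter arch has a larger angle; a
#' more convex (more arched) CC has a smaller one.
#'
#' @param rect a [BoundingRect-class], or the base length in mm.
#' @param height rectangle height in mm (only when `rect` is numeric).
#' @return Angle in degrees, in (0, 180).
#' @export
bendingAngle <- function(rect, height = NULL) {
  if (is(rect, "BoundingRect")) {
    b <- baseLength(rect); h <- rectHeight(rect)
  } else {
    stopifnot(is.numeric(rect), is.numeric(height))
    b <- rect; h <- height
  }
  if (b <= 0 || h <= 0)
    ccStop("ccmorphDegenerateRect", "base and height must be positive")
  deg <- 2 * atan(b / (2 * h)) * 180 / pi
  stopifnot(deg > 0, deg < 180)
  deg
}

#' Rectangle height implied by a bending angle
#'
#' Inverse of [bendingAngle()] at fixed base:
#' `height = base / (2 * tan(degrees / 2))`. Used by the synthetic cohort
#' generator to convert sampled angles into rectangle geometry.
#'
#' @param base base length (mm).
#' @param degrees bending angle in (0, 180).
#' @return Height in mm.
#' @export
heightForAngle <- function(base, degrees) {
  stopifnot(base > 0, degrees > 0, degrees < 180)
  base / (2 * tan(degrees * pi / 360))
}
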