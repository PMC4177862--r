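#' @import methods
NULL

#' Canonical corpus-callosum sub-region names
#'
#' The five rostro-caudal sub-regions used throughout the package, ordered
#' anterior to posterior: the anterior third (rostrum + genu + rostral body,
#' kept as one region), the anterior mid-body, the posterior mid-body, the
#' isthmus and the splenium.
#'
#' @return Character vector of length five.
#' @export
ccRegionNames <- function() {
  c("anterior_third", "anterior_midbody", "posterior_midbody",
    "isthmus", "splenium")
}

#' Default sub-region length fractions
#'
#' Length fractions of the five sub-regions along the long side of the
#' minimum rectangle, anterior to posterior: 33, 17, 17, 13 and 20 percent.
#'
#' @return Numeric vector of length five summing to 1.
#' @export
ccRegionFractions <- function() c(0.33, 0.17, 0.17, 0.13, 0.20)

# ---------------------------------------------------------------- classes --

#' MidsagittalMask: a subject's binary CC mask
#'
#' A 2-D binary pixel grid holding one subject's corpus-callosum region of
#' interest on the midsagittal plane, together with the physical pixel
#' spacing in mm. Rows are the dorso-ventral axis, columns the
#' anterior-posterior axis; which column direction is anterior is *not*
#' assumed and must be declared wherever it matters (see
#' [subdivide()]).
#'
#' @slot pixels integer matrix of 0/1 values (rows x cols).
#' @slot spacing numeric length-2, physical size of one pixel in mm as
#'   `c(row_mm, col_mm)`; strictly positive.
#' @slot subjectID character scalar identifier.
#'
#' @export
setClass("MidsagittalMask",
  representation(pixels = "matrix", spacing = "numeric",
                 subjectID = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@spacing) != 2 || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be two strictly positive values (mm)")
    if (!all(object@pixels %in% c(0L, 1L)))
      msg <- c(msg, "pixels must be binary (0/1)")
    if (length(msg)) msg else TRUE
  })

#' Construct a MidsagittalMask
#'
#' Binarizes `pixels` (non-zero is foreground), validates the spacing and
#' warns if the foreground is empty or not a single 4-connected component
#' (a plausible hand-segmentation slip, not necessarily fatal).
#'
#' @param pixels numeric or integer matrix; non-zero entries are foreground.
#' @param spacing numeric length-2 pixel size in mm, `c(row_mm, col_mm)`.
#' @param subjectID character scalar.
#' @param check if `TRUE` (default) warn on empty or fragmented foreground.
#' @return A [MidsagittalMask-class] object.
#' @export
midsagittalMask <- function(pixels, spacing = c(1, 1), subjectID = "subject",
                            check = TRUE) {
  stopifnot(is.matrix(pixels))
  px <- matrix(as.integer(pixels != 0), nrow(pixels), ncol(pixels))
  obj <- new("MidsagittalMask", pixels = px, spacing = as.numeric(spacing),
             subjectID = as.character(subjectID))
  if (check) {
    if (sum(px) == 0L) {
      warning("mask '", subjectID, "' has no foreground pixels")
    } else {
      ncomp <- connectedComponents4(px)$n
      if (ncomp > 1L)
        warning("mask '", subjectID, "' has ", ncomp,
                " 4-connected components; expected a single CC blob")
    }
  }
  obj
}

#' BoundingRect: minimum rectangle covering a mask
#'
#' The rectangle circumscribing a CC mask, either axis-aligned or the
#' minimum-area rotated rectangle of the foreground convex hull. The base is
#' always the longer side. Corners are in physical mm coordinates
#' (x = column axis, y = row axis), ordered so that the edge from corner 1
#' to corner 2 runs along the base.
#'
#' @slot baseMM length of the longer side (mm).
#' @slot heightMM length of the shorter side (mm).
#' @slot corners 4 x 2 numeric matrix of (x, y) vertices in mm.
#' @slot mode `"axis_aligned"` or `"min_area"`.
#' @slot convention `"pixel_extent"` or `"pixel_center"` (see
#'   [boundingRectangle()]).
#' @export
setClass("BoundingRect",
  representation(baseMM = "numeric", heightMM = "numeric",
                 corners = "matrix", mode = "character",
                 convention = "character"),
  validity = function(object) {
    msg <- character()
    if (!(object@baseMM >= object@heightMM && object@heightMM > 0))
      msg <- c(msg, "need baseMM >= heightMM > 0")
    if (!identical(dim(object@corners), c(4L, 2L)))
      msg <- c(msg, "corners must be a 4 x 2 matrix")
    else {
      e1 <- object@corners[2, ] - object@corners[1, ]
      e2 <- object@corners[4, ] - object@corners[1, ]
      tol <- 1e-6 * max(object@baseMM, 1)
      if (abs(sum(e1 * e2)) > tol)
        msg <- c(msg, "corner edges are not orthogonal")
      if (abs(sqrt(sum(e1^2)) - object@baseMM) > tol)
        msg <- c(msg, "corner base edge does not match baseMM")
      if (abs(sqrt(sum(e2^2)) - object@heightMM) > tol)
        msg <- c(msg, "corner height edge does not match heightMM")
    }
    if (length(msg)) msg else TRUE
  })

#' SubregionLabelMap: five-region CC labelling
#'
#' Per-pixel labels aligned with the source mask: 0 background, then 1-5 for
#' the anterior third, anterior mid-body, posterior mid-body, isthmus and
#' splenium.
#'
#' @slot labels integer matrix of values 0-5.
#' @slot spacing numeric length-2 pixel size (mm).
#' @slot proportions the five length fractions used for the cuts.
#' @export
setClass("SubregionLabelMap",
  representation(labels = "matrix", spacing = "numeric",
                 proportions = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!all(object@labels %in% 0:5))
      msg <- c(msg, "labels must be integers in 0..5")
    if (length(object@proportions) != 5 ||
        abs(sum(object@proportions) - 1) > 1e-9)
      msg <- c(msg, "proportions must be five fractions summing to 1")
    if (length(object@spacing) != 2 || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be two positive values")
    if (length(msg)) msg else TRUE
  })

#' DeformationField: template-to-subject displacement field
#'
#' Per-pixel 2-D displacements (mm) on the template grid, mapping template
#' coordinates to subject coordinates; the convention is fixed so that
#' integrating the Jacobian determinant over template-space labels yields
#' subject areas directly.
#'
#' @slot displacements numeric array `c(nrow, ncol, 2)`; component 1 is the
#'   row (y) displacement, component 2 the column (x) displacement, in mm.
#' @slot spacing numeric length-2 grid spacing (mm).
#' @slot subjectID character scalar.
#' @slot converged logical; `FALSE` if the matcher hit its iteration cap.
#' @export
setClass("DeformationField",
  representation(displacements = "array", spacing = "numeric",
                 subjectID = "character", converged = "logical"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@displacements)
    if (length(d) != 3 || d[3] != 2)
      msg <- c(msg, "displacements must be an (nrow, ncol, 2) array")
    if (any(!is.finite(object@displacements)))
      msg <- c(msg, "displacements must be finite everywhere")
    if (length(object@spacing) != 2 || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be two positive values")
    if (length(msg)) msg else TRUE
  })

#' CCTemplate: unbiased group-average template
#'
#' Result of [buildTemplate()]: the continuous (soft-edged) template image,
#' the per-subject template-to-subject deformation fields from the final
#' registration pass, the centred subject masks on the common grid, and the
#' per-iteration mean displacement history.
#'
#' @slot image numeric matrix, template intensities in `[0, 1]`.
#' @slot spacing numeric length-2 grid spacing (mm).
#' @slot fields named list of [DeformationField-class], one per subject.
#' @slot masks named list of [MidsagittalMask-class] on the template grid.
#' @slot history data.frame of per-iteration diagnostics.
#' @export
setClass("CCTemplate",
  representation(image = "matrix", spacing = "numeric", fields = "list",
                 masks = "list", history = "data.frame"))

#' AncovaResult: one tested effect from a linear model
#'
#' @slot effect character, the tested term (e.g. `"group"`, `"group:sex"`).
#' @slot F numeric F value.
#' @slot df1,df2 numerator and denominator degrees of freedom.
#' @slot p numeric p value.
#' @slot adjustedMeans named numeric vector of covariate-adjusted cell means.
#' @slot table full per-effect data.frame (effect, F, df1, df2, p).
#' @export
setClass("AncovaResult",
  representation(effect = "character", F = "numeric", df1 = "numeric",
                 df2 = "numeric", p = "numeric", adjustedMeans = "numeric",
                 table = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (object@F < 0) msg <- c(msg, "F must be non-negative")
    if (object@p < 0 || object@p > 1) msg <- c(msg, "p must be in [0, 1]")
    if (object@df1 <= 0 || object@df2 <= 0)
      msg <- c(msg, "degrees of freedom must be positive")
    if (length(msg)) msg else TRUE
  })

#' PosthocResult: Scheffe pairwise contrasts
#'
#' @slot contrasts data.frame with columns cell1, cell2, estimate, se,
#'   F, p (Scheffe-adjusted), p_unadjusted, significant (at 0.05).
#' @slot alpha significance level used for the flag.
#' @export
setClass("PosthocResult",
  representation(contrasts = "data.frame", alpha = "numeric"))

# ------------------------------------------------------------------- show --

setMethod("show", "MidsagittalMask", function(object) {
  cat(sprintf("MidsagittalMask '%s': %d x %d px, spacing %.3g x %.3g mm, %d foreground px\n",
              object@subjectID, nrow(object@pixels), ncol(object@pixels),
              object@spacing[1], object@spacing[2], sum(object@pixels)))
})

setMethod("show", "BoundingRect", function(object) {
  cat(sprintf("BoundingRect (%s, %s): base %.2f mm, height %.2f mm\n",
              object@mode, object@convention, object@baseMM, object@heightMM))
})

setMethod("show", "SubregionLabelMap", function(object) {
  counts <- tabulate(object@labels[object@labels > 0], 5)
  cat("SubregionLabelMap:", paste(ccRegionNames(), counts, sep = "=",
                                  collapse = ", "), "px\n")
})

setMethod("show", "DeformationField", function(object) {
  mag <- sqrt(object@displacements[, , 1]^2 + object@displacements[, , 2]^2)
  cat(sprintf("DeformationField '%s': %d x %d, mean |u| %.3f mm, %s\n",
              object@subjectID, dim(object@displacements)[1],
              dim(object@displacements)[2], mean(mag),
              if (object@converged) "converged" else "NOT converged"))
})

setMethod("show", "CCTemplate", function(object) {
  cat(sprintf("CCTemplate: %d x %d grid, %d subjects, %d iterations\n",
              nrow(object@image), ncol(object@image), length(object@fields),
              nrow(object@history)))
})

setMethod("show", "AncovaResult", function(object) {
  cat(sprintf("ANCOVA effect '%s': F(%g,%g) = %.3f, p = %.4g\n",
              object@effect, object@df1, object@df2, object@F, object@p))
})

setMethod("show", "PosthocResult", function(object) {
  cat("Scheffe post-hoc contrasts (alpha =", object@alpha, "):\n")
  print(object@contrasts, digits = 4)
})
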