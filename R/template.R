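# Unbiased group-average template construction and Jacobian-based area
# measurement.

# Place each mask centered (by foreground bounding box) on a common canvas.
# Stands in for the linear stereotaxic alignment that precedes template
# building; pixel counts (areas) are unchanged by the integer shift.
commonGrid <- function(masks, padPx = 8L) {
  sps <- t(vapply(masks, pixelSpacing, numeric(2)))
  if (any(abs(sweep(sps, 2, sps[1, ])) > 1e-9))
    ccStop("ccmorphDimMismatch", "all masks must share one pixel spacing")
  boxes <- lapply(masks, function(m) {
    idx <- which(maskPixels(m) > 0, arr.ind = TRUE)
    if (nrow(idx) == 0) ccStop("ccmorphEmptyMask", "empty mask in cohort")
    apply(idx, 2, range)
  })
  hs <- vapply(boxes, function(b) diff(b[, 1]) + 1L, numeric(1))
  ws <- vapply(boxes, function(b) diff(b[, 2]) + 1L, numeric(1))
  nr <- as.integer(max(hs)) + 2L * padPx
  nc <- as.integer(max(ws)) + 2L * padPx
  out <- lapply(seq_along(masks), function(i) {
    b <- boxes[[i]]
    px <- maskPixels(masks[[i]])[b[1, 1]:b[2, 1], b[1, 2]:b[2, 2], drop = FALSE]
    canvas <- matrix(0L, nr, nc)
    r0 <- as.integer(floor((nr - nrow(px)) / 2))
    c0 <- as.integer(floor((nc - ncol(px)) / 2))
    canvas[r0 + seq_len(nrow(px)), c0 + seq_len(ncol(px))] <- px
    midsagittalMask(canvas, spacing = pixelSpacing(masks[[i]]),
                    subjectID = subjectID(masks[[i]]), check = FALSE)
  })
  names(out) <- vapply(masks, subjectID, character(1))
  out
}

warpImage <- function(img, u, spacing) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- matrix(seq_len(nr), nr, nc) + u[, , 1] / spacing[1]
  ci <- matrix(seq_len(nc), nr, nc, byrow = TRUE) + u[, , 2] / spacing[2]
  matrix(bilinearSample(img, as.vector(ri), as.vector(ci)), nr, nc)
}

#' Build an unbiased group-average template
#'
#' Iterative template construction: an initial template is the voxel-wise
#' average of the (softened, grid-centred) masks; each iteration
#' (1) estimates the nonlinear mapping between every subject and the current
#' template, (2) resamples each subject into template space, (3) averages
#' them into a temporary template, and (4) applies the inverse of the
#' average deformation to the temporary template, removing net deformation
#' bias. Early iterations use only the coarse end of the registration
#' schedule; each successive iteration admits finer scales. A final
#' registration pass against the finished template returns the per-subject
#' template-to-subject fields used for area measurement.
#'
#' @param masks list of [MidsagittalMask-class] on a common spacing.
#' @param nIterations number of template refinement iterations.
#' @param settings see [registrationSettings()].
#' @param padPx canvas padding around the largest mask.
#' @return A [CCTemplate-class].
#' @export
buildTemplate <- function(masks, nIterations = 4L,
                          settings = registrationSettings(), padPx = 8L) {
  if (length(masks) < 2)
    ccStop("ccmorphEmptyCohort", "need at least 2 masks to build a template")
  placed <- commonGrid(masks, padPx = padPx)
  spacing <- pixelSpacing(placed[[1]])
  images <- lapply(placed, softMask, sigmaPx = settings$imageSigmaPx)
  tmpl <- Reduce(`+`, images) / length(images)
  sched <- settings$schedulePx
  hist <- NULL
  prevMag <- Inf; prevMag2 <- Inf
  for (it in seq_len(nIterations)) {
    itSettings <- settings
    itSettings$schedulePx <- sched[seq_len(min(it, length(sched)))]
    fields <- lapply(names(images), function(id)
      suppressWarnings(registerPair(images[[id]], tmpl, spacing = spacing,
                                    settings = itSettings, subjectID = id)))
    warped <- Map(function(img, f) warpImage(img, displacements(f), spacing),
                  images, fields)
    tmp <- Reduce(`+`, warped) / length(warped)
    ubar <- Reduce(`+`, lapply(fields, displacements)) / length(fields)
    # inverse of the average deformation: sample at x - ubar(x)
    tmpl <- warpImage(tmp, -ubar, spacing)
    mag <- mean(sqrt(Reduce(`+`, lapply(fields, function(f) {
      u <- displacements(f); u[, , 1]^2 + u[, , 2]^2
    })) / length(fields)))
    hist <- rbind(hist, data.frame(iteration = it,
                                   finest_scale_px = min(itSettings$schedulePx),
                                   mean_disp_mm = mag))
    # admitting finer scales legitimately grows |u| a little per iteration;
    # only sustained substantial growth is divergence
    if (mag > 1.05 * prevMag && prevMag > 1.05 * prevMag2)
      ccStop("ccmorphDiverged",
             "template construction diverging: mean displacement %.3f > %.3f > %.3f mm over three iterations",
             mag, prevMag, prevMag2)
    prevMag2 <- prevMag; prevMag <- mag
  }
  fields <- lapply(names(images), function(id)
    registerPair(images[[id]], tmpl, spacing = spacing, settings = settings,
                 subjectID = id))
  names(fields) <- names(images)
  new("CCTemplate", image = tmpl, spacing = spacing, fields = fields,
      masks = placed, history = hist)
}

#' Threshold the template into a mask
#'
#' The soft template image thresholded at 0.5, as a
#' [MidsagittalMask-class] ready for [boundingRectangle()] and
#' [subdivide()]; this automatic labelling of the template stands in for
#' expert manual labelling.
#'
#' @param template a [CCTemplate-class].
#' @param threshold intensity threshold (default 0.5).
#' @return A [MidsagittalMask-class].
#' @export
templateMask <- function(template, threshold = 0.5) {
  midsagittalMask((templateImage(template) > threshold) * 1L,
                  spacing = pixelSpacing(template), subjectID = "template",
                  check = FALSE)
}

#' Sub-regional areas of one subject by Jacobian integration
#'
#' With labels drawn once on the template and the subject's
#' template-to-subject deformation field, the stereotaxic-space area of
#' region k is the integral of the Jacobian determinant over the labelled
#' template pixels: `sum(detJ[label == k]) * pixel_area`. The native
#' (absolute) area divides by the squared linear native-to-stereotaxic
#' scaling factor.
#'
#' @param templateLabels a [SubregionLabelMap-class] on the template grid.
#' @param field the subject's [DeformationField-class] (template grid).
#' @param record one-row data.frame with at least `subject_id` and
#'   `linear_scale` (see [readDemographics()]); optional.
#' @return data.frame with one row per region: subject_id, region,
#'   stereotaxic_area_mm2, native_area_mm2.
#' @export
regionAreas <- function(templateLabels, field, record = NULL) {
  lab <- labelMatrix(templateLabels)
  if (!identical(dim(lab), dim(displacements(field))[1:2]))
    ccStop("ccmorphDimMismatch", "label map and field grids differ")
  J <- suppressWarnings(jacobianMap(field))
  sp <- pixelSpacing(field)
  pxArea <- sp[1] * sp[2]
  stereo <- vapply(1:5, function(k) sum(J[lab == k]) * pxArea, numeric(1))
  ls <- if (!is.null(record) && "linear_scale" %in% names(record))
    record$linear_scale else 1
  id <- if (!is.null(record) && "subject_id" %in% names(record))
    record$subject_id else subjectID(field)
  data.frame(subject_id = id, region = ccRegionNames(),
             stereotaxic_area_mm2 = stereo,
             native_area_mm2 = stereo / ls^2,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Dice overlap of two binary masks
#'
#' @param a,b [MidsagittalMask-class] objects or binary matrices on one grid.
#' @return Dice coefficient in `[0, 1]`.
#' @export
diceOverlap <- function(a, b) {
  pa <- if (is(a, "MidsagittalMask")) maskPixels(a) else (a > 0) * 1L
  pb <- if (is(b, "MidsagittalMask")) maskPixels(b) else (b > 0) * 1L
  2 * sum(pa & pb) / (sum(pa) + sum(pb))
}
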