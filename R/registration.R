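# Pairwise nonlinear 2-D registration: demons-style sum-of-squared-difference
# forces with Gaussian (diffusion-like) regularisation of the displacement
# field, run coarse-to-fine over a schedule of regularisation scales. The
# field is stored template-to-subject so that Jacobian integration over
# template-space labels yields subject areas directly. Fully deterministic:
# no stochastic initialisation.

#' Registration settings
#'
#' @param schedulePx coarse-to-fine schedule of regularisation scales in
#'   pixels; the displacement field is smoothed with sigma = scale / 2 at
#'   each level. The default 16, 8, 4, 2 halves the scale per level.
#' @param iterations maximum demons iterations per level.
#' @param stepMaxPx per-iteration update cap, in pixels.
#' @param imageSigmaPx Gaussian smoothing applied to binary masks to obtain
#'   soft-edged images before matching (binary SSD has flat gradients).
#' @param tol convergence threshold on the mean update magnitude (pixels).
#' @return Settings list for [registerPair()] and [buildTemplate()].
#' @export
registrationSettings <- function(schedulePx = c(16, 8, 4, 2),
                                 iterations = 150L, stepMaxPx = 2,
                                 imageSigmaPx = 0.8, tol = 5e-3) {
  stopifnot(all(schedulePx > 0), iterations >= 1)
  list(schedulePx = schedulePx, iterations = as.integer(iterations),
       stepMaxPx = stepMaxPx, imageSigmaPx = imageSigmaPx, tol = tol)
}

#' Soften a binary mask into a matchable image
#'
#' Gaussian-smooths the 0/1 pixel grid (sigma in pixels) into a continuous
#' image in `[0, 1]`.
#'
#' @param mask a [MidsagittalMask-class] or numeric matrix.
#' @param sigmaPx smoothing sigma in pixels.
#' @return Numeric matrix.
#' @export
softMask <- function(mask, sigmaPx = 1) {
  m <- if (is(mask, "MidsagittalMask")) maskPixels(mask) + 0 else mask
  smooth2d(m, sigmaPx)
}

# One demons level: iterate force + field smoothing at a fixed scale.
demonsLevel <- function(u, moving, fixed, spacing, sigmaPx, iters, stepMaxPx,
                        tol) {
  nr <- nrow(fixed); nc <- ncol(fixed)
  ri <- matrix(seq_len(nr), nr, nc)
  ci <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ms <- mean(spacing)
  stepMax <- stepMaxPx * ms
  converged <- FALSE
  gfr <- finiteDiff(fixed, 1L, spacing[1])
  gfc <- finiteDiff(fixed, 2L, spacing[2])
  for (it in seq_len(iters)) {
    wr <- ri + u[, , 1] / spacing[1]
    wc <- ci + u[, , 2] / spacing[2]
    mw <- matrix(bilinearSample(moving, as.vector(wr), as.vector(wc)), nr, nc)
    diffim <- mw - fixed
    gr <- (finiteDiff(mw, 1L, spacing[1]) + gfr) / 2
    gc <- (finiteDiff(mw, 2L, spacing[2]) + gfc) / 2
    denom <- gr^2 + gc^2 + (diffim / ms)^2
    ok <- denom > 1e-12
    vr <- matrix(0, nr, nc); vc <- matrix(0, nr, nc)
    vr[ok] <- -diffim[ok] * gr[ok] / denom[ok]
    vc[ok] <- -diffim[ok] * gc[ok] / denom[ok]
    vmag <- sqrt(vr^2 + vc^2)
    over <- vmag > stepMax
    if (any(over)) {
      scale <- stepMax / vmag[over]
      vr[over] <- vr[over] * scale
      vc[over] <- vc[over] * scale
    }
    u[, , 1] <- smooth2d(u[, , 1] + vr, sigmaPx)
    u[, , 2] <- smooth2d(u[, , 2] + vc, sigmaPx)
    if (mean(vmag) < tol * ms) { converged <- TRUE; break }
  }
  list(u = u, converged = converged)
}

#' Register a moving image to a fixed image
#'
#' Estimates the displacement field `u` such that
#' `moving(x + u(x)) ~ fixed(x)`: with `fixed` a template and `moving` a
#' subject, `u` maps template coordinates to subject coordinates.
#' Minimises sum-of-squared differences with diffusion-style regularisation
#' (Gaussian smoothing of the field each iteration), coarse-to-fine over
#' `settings$schedulePx`.
#'
#' @param moving a [MidsagittalMask-class] (softened internally) or a
#'   numeric matrix image.
#' @param fixed same, on the same grid.
#' @param spacing grid spacing `c(row_mm, col_mm)`; taken from the masks
#'   when they carry one.
#' @param settings see [registrationSettings()].
#' @param subjectID identifier stored in the returned field.
#' @param init optional initial displacement array.
#' @return A [DeformationField-class]; `converged` is `FALSE` (with a
#'   warning) if the final level hit its iteration cap.
#' @export
registerPair <- function(moving, fixed, spacing = NULL,
                         settings = registrationSettings(),
                         subjectID = "subject", init = NULL) {
  if (is(moving, "MidsagittalMask")) {
    if (is.null(spacing)) spacing <- pixelSpacing(moving)
    moving <- softMask(moving, settings$imageSigmaPx)
  }
  if (is(fixed, "MidsagittalMask")) {
    if (is.null(spacing)) spacing <- pixelSpacing(fixed)
    fixed <- softMask(fixed, settings$imageSigmaPx)
  }
  if (is.null(spacing)) spacing <- c(1, 1)
  if (!identical(dim(moving), dim(fixed)))
    ccStop("ccmorphDimMismatch",
           "moving (%s) and fixed (%s) grids differ; resample first",
           paste(dim(moving), collapse = "x"),
           paste(dim(fixed), collapse = "x"))
  u <- if (is.null(init)) array(0, c(dim(fixed), 2)) else init
  converged <- TRUE
  for (g in settings$schedulePx) {
    res <- demonsLevel(u, moving, fixed, spacing, sigmaPx = g / 2,
                       iters = settings$iterations,
                       stepMaxPx = settings$stepMaxPx, tol = settings$tol)
    u <- res$u
    converged <- res$converged
  }
  if (!converged)
    warning("registration for '", subjectID,
            "' hit the iteration cap at the finest level")
  new("DeformationField", displacements = u, spacing = as.numeric(spacing),
      subjectID = subjectID, converged = converged)
}

#' Jacobian determinant map of a deformation field
#'
#' Per-pixel determinant of the spatial derivative of the mapping
#' `x -> x + u(x)`, i.e. `det(I + grad u)`, by central finite differences
#' (one-sided at the borders). The determinant is the local area ratio:
#' 1 everywhere for a zero field, `s^2` for uniform scaling by `s`, 1 for a
#' rigid rotation. Non-positive determinants (folding) are never clamped;
#' they are counted and reported as an attribute and a warning.
#'
#' @param field a [DeformationField-class].
#' @return Numeric matrix of determinants with attribute `nNonPositive`.
#' @export
jacobianMap <- function(field) {
  u <- displacements(field)
  sp <- pixelSpacing(field)
  dudy <- finiteDiff(u[, , 1], 1L, sp[1])
  dudx <- finiteDiff(u[, , 1], 2L, sp[2])
  dvdy <- finiteDiff(u[, , 2], 1L, sp[1])
  dvdx <- finiteDiff(u[, , 2], 2L, sp[2])
  J <- (1 + dudy) * (1 + dvdx) - dudx * dvdy
  npos <- sum(J <= 0)
  if (npos > 0)
    warning("deformation field '", subjectID(field), "' has ", npos,
            " non-positive Jacobian determinant(s)")
  attr(J, "nNonPositive") <- npos
  J
}
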