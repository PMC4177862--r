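# Synthetic CC cohorts: arch-shaped masks with planted bending angle and
# sub-regional areas, and purely numeric area cohorts drawn from group
# distributions, so every downstream stage is testable without MRI data.

#' Default cohort specification
#'
#' Study conditions for a congenitally blind (CB) versus sighted control
#' (NC) cohort: 28 subjects per group (16 male, 12 female), group bending
#' angles 109.6 +/- 4.9 (CB) and 113.4 +/- 5.7 (NC) degrees, and the five
#' sub-regional area distributions (mm^2), including the group x sex cell
#' distributions of the isthmus used for interaction simulations. Shipped as
#' a YAML file in `inst/extdata/cb_cohort.yaml`; this function reads it.
#'
#' @return A validated cohort spec list (see [readCohortSpec()]).
#' @export
defaultCohortSpec <- function() {
  readCohortSpec(system.file("extdata", "cb_cohort.yaml", package = "ccmorph",
                             mustWork = TRUE))
}

#' Read and validate a cohort specification
#'
#' The YAML layout has a `groups` block (per group: `n`, `males`, `females`,
#' `age_range`, `bending_angle` mean/sd, `base_mm` mean/sd and per-region
#' area mean/sd) and an optional `isthmus_cells` block with the four
#' group x sex cell distributions.
#'
#' @param path YAML file path.
#' @return The validated spec as a nested list.
#' @export
readCohortSpec <- function(path) {
  spec <- yaml::read_yaml(path)
  validateCohortSpec(spec)
  spec
}

validateCohortSpec <- function(spec) {
  if (is.null(spec$groups) || !length(spec$groups))
    ccStop("ccmorphBadSpec", "cohort spec has no groups")
  for (g in names(spec$groups)) {
    gs <- spec$groups[[g]]
    for (f in c("n", "males", "females", "age_range", "bending_angle",
                "base_mm", "regions"))
      if (is.null(gs[[f]]))
        ccStop("ccmorphBadSpec", "group %s lacks field %s", g, f)
    if (gs$n < 2)
      ccStop("ccmorphBadSpec", "group %s needs n >= 2", g)
    if (gs$males + gs$females != gs$n)
      ccStop("ccmorphBadSpec", "group %s: males + females != n", g)
    missing <- setdiff(ccRegionNames(), names(gs$regions))
    if (length(missing))
      ccStop("ccmorphBadSpec", "group %s lacks region(s) %s", g,
             paste(missing, collapse = ", "))
    for (r in ccRegionNames()) {
      ms <- gs$regions[[r]]
      if (ms$sd < 0 || ms$mean <= 0)
        ccStop("ccmorphBadSpec", "group %s region %s: need mean > 0, sd >= 0",
               g, r)
    }
    if (gs$bending_angle$sd < 0 || gs$base_mm$sd < 0)
      ccStop("ccmorphBadSpec", "group %s: SDs must be >= 0", g)
  }
  invisible(TRUE)
}

#' Generate one arch-shaped CC mask with planted geometry
#'
#' Builds a synthetic corpus-callosum-like mask: a half-ellipse arch
#' centerline spanning the base, thickened by a per-slab thickness profile
#' (piecewise constant with short cosine tapers at the slab joins) chosen so
#' that the pixel-counted area inside each proportional slab equals the
#' planted area. The bounding rectangle of the output reproduces
#' `baseMM` x `heightMM` to within one pixel, so the bending angle is
#' controlled analytically. Not an anatomical contour; a geometry with
#' exactly known ground truth.
#'
#' @param baseMM rectangle base length (mm).
#' @param heightMM rectangle height (mm).
#' @param regionAreasMM2 five planted areas (mm^2), anterior to posterior.
#' @param spacing pixel size `c(row_mm, col_mm)` (default 1 mm isotropic).
#' @param fractions slab length fractions (default [ccRegionFractions()]).
#' @param taperMM half-width of the cosine taper at slab joins.
#' @param marginPx background margin around the shape.
#' @param subjectID identifier for the returned mask.
#' @return A [MidsagittalMask-class].
#' @export
makeCCShape <- function(baseMM, heightMM, regionAreasMM2,
                        spacing = c(1, 1), fractions = ccRegionFractions(),
                        taperMM = 1.5, marginPx = 2L, subjectID = "synthetic") {
  stopifnot(length(regionAreasMM2) == 5)
  if (baseMM <= 2 * max(spacing) || heightMM <= 2 * max(spacing))
    ccStop("ccmorphDegenerateShape",
           "base and height must exceed two pixels")
  if (any(regionAreasMM2 <= 0))
    ccStop("ccmorphInfeasibleShape", "planted areas must be positive")
  rs <- spacing[1]; cs <- spacing[2]
  nc <- round(baseMM / cs)
  b <- nc * cs                         # effective base = whole pixels
  # target the nearest whole-pixel row extent, mirroring the base treatment,
  # so the rasterized bounding rectangle lands within half a pixel per axis
  nrTarget <- as.integer(round(heightMM / rs))
  heightMM <- nrTarget * rs
  w <- fractions * b
  tk <- regionAreasMM2 / w             # per-slab thickness
  bad <- which(tk > heightMM / 2)
  if (length(bad))
    ccStop("ccmorphInfeasibleShape",
           "planted area for %s needs thickness %.1f mm > height/2 = %.1f mm",
           paste(ccRegionNames()[bad], collapse = ", "), max(tk[bad]),
           heightMM / 2)

  cuts <- cumsum(w)[1:4]
  tau <- min(taperMM, 0.4 * min(w))
  thickAt <- function(x) {
    k <- findInterval(x, cuts) + 1L
    t <- tk[k]
    for (j in 1:4) {
      inJoin <- abs(x - cuts[j]) < tau
      if (any(inJoin)) {
        s <- (1 - cos(pi * (x[inJoin] - (cuts[j] - tau)) / (2 * tau))) / 2
        t[inJoin] <- tk[j] + (tk[j + 1] - tk[j]) * s
      }
    }
    t
  }

  xs <- (seq_len(nc) - 0.5) * cs       # column centers
  tx <- thickAt(xs)
  # Plant areas over the same half-open pixel-column groups the subdivision
  # will measure, not over continuous intervals: renormalise the (tapered)
  # thickness within each slab's columns so each slab's column integral is
  # exactly the planted area.
  slabOfCol <- findInterval(xs, cuts) + 1L
  for (k in 1:5) {
    idx <- slabOfCol == k
    tx[idx] <- tx[idx] * regionAreasMM2[k] / (sum(tx[idx]) * cs)
  }
  if (max(tx) > heightMM / 2)
    ccStop("ccmorphInfeasibleShape",
           "planted area for %s needs thickness %.1f mm > height/2 = %.1f mm",
           ccRegionNames()[slabOfCol[which.max(tx)]], max(tx), heightMM / 2)
  shape <- sqrt(pmax(0, 1 - (2 * xs / b - 1)^2))
  # Solve the arch apex a and foot offset c0 jointly so that the band top
  # peaks at exactly heightMM and the band bottom touches 0 at one end
  # column (centerline y = c0 + (a - c0) * shape).
  a <- heightMM - thickAt(b / 2) / 2
  c0 <- 0
  for (i in 1:30) {
    c0 <- max((tx[1] / 2 - a * shape[1]) / (1 - shape[1]),
              (tx[nc] / 2 - a * shape[nc]) / (1 - shape[nc]))
    yc <- c0 + (a - c0) * shape
    overshoot <- max(yc + tx / 2) - heightMM
    if (abs(overshoot) < 1e-9) break
    a <- a - overshoot
  }
  yc <- c0 + (a - c0) * shape
  if (a <= c0 || a <= 0)
    ccStop("ccmorphInfeasibleShape",
           "height too small for the planted thickness profile")
  if (min(yc - tx / 2) < -1e-6)
    ccStop("ccmorphInfeasibleShape",
           "planted areas too thick for the arch height")

  # Rasterize column by column; Bresenham-style error diffusion per slab so
  # that pixel-counted slab areas track the planted areas to sub-pixel error.
  nr <- nrTarget + 2L * marginPx
  px <- matrix(0L, nr, nc + 2L * marginPx)
  err <- 0; prevSlab <- 1L
  r0 <- integer(nc); njs <- integer(nc)
  for (j in seq_len(nc)) {
    if (slabOfCol[j] != prevSlab) { err <- 0; prevSlab <- slabOfCol[j] }
    ideal <- tx[j] / rs
    nj <- min(nrTarget, max(1L, as.integer(round(ideal + err))))
    err <- err + ideal - nj
    ic <- yc[j] / rs + 0.5             # fractional center row (y up)
    njs[j] <- nj
    r0[j] <- as.integer(round(ic - nj / 2)) + 1L
  }
  # bridge adjacent columns so the shape stays 4-connected where the arch
  # shoulders are steeper than the band is thick (shifts, never resizes)
  for (j in 2:nc) {
    if (r0[j] > r0[j - 1L] + njs[j - 1L] - 1L)
      r0[j] <- r0[j - 1L] + njs[j - 1L] - 1L
    else if (r0[j] + njs[j] - 1L < r0[j - 1L])
      r0[j] <- r0[j - 1L] - njs[j] + 1L
  }
  # pin the apex and foot columns so the row extent is exactly nrTarget,
  # and keep every block inside it (shifting never changes pixel counts)
  jTop <- which.max(yc + tx / 2)
  jBot <- which.min(yc - tx / 2)
  r0[jTop] <- nrTarget - njs[jTop] + 1L
  r0[jBot] <- 1L
  r0 <- pmax(1L, pmin(r0, nrTarget - njs + 1L))
  for (j in seq_len(nc))
    px[marginPx + (r0[j]:(r0[j] + njs[j] - 1L)), j + marginPx] <- 1L
  midsagittalMask(px, spacing = spacing, subjectID = subjectID)
}

drawFeasible <- function(n, mean, sd, lower = -Inf, upper = Inf, what = "value",
                         maxReject = 100L) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (tries in seq_len(maxReject)) {
      x <- rnormTrunc3(1, mean, sd)
      if (x > lower && x < upper) { out[i] <- x; ok <- TRUE; break }
    }
    if (!ok)
      ccStop("ccmorphInfeasibleDraw",
             "could not draw a feasible %s from N(%.3g, %.3g^2) in %d tries",
             what, mean, sd, maxReject)
  }
  out
}

#' Sample a cohort of synthetic CC masks
#'
#' Per subject, draws the five sub-regional areas and a bending angle from
#' the group's normal distributions (truncated at 3 SD and rejected if
#' geometrically infeasible), converts the angle to a base/height ratio by
#' inverting the bending-angle formula, and calls [makeCCShape()].
#' Demographics (sex per the spec's composition, age uniform in the group
#' range, site round-robin over `sites`) are emitted alongside.
#'
#' @param spec a cohort spec (see [defaultCohortSpec()]).
#' @param seed integer master seed; fanned out per subject so subsets are
#'   reproducible in isolation.
#' @param n optional per-group size override (e.g. for small demo cohorts);
#'   sex composition is scaled proportionally.
#' @param spacing pixel size for the generated masks.
#' @param sites character vector of site labels to cycle over.
#' @return `list(masks = <list of MidsagittalMask>, demographics = <data.frame>,
#'   truth = <data.frame of planted areas and angles>)`.
#' @export
sampleMaskCohort <- function(spec, seed, n = NULL, spacing = c(1, 1),
                             sites = "site1") {
  validateCohortSpec(spec)
  masks <- list(); demo <- NULL; truth <- NULL
  subjIdx <- 0L
  for (g in names(spec$groups)) {
    gs <- spec$groups[[g]]
    ng <- if (is.null(n)) gs$n else n
    nM <- round(ng * gs$males / gs$n)
    sexes <- rep(c("M", "F"), c(nM, ng - nM))
    for (i in seq_len(ng)) {
      subjIdx <- subjIdx + 1L
      set.seed(fanSeed(seed, subjIdx))
      id <- sprintf("%s%02d", tolower(g), i)
      mask <- NULL
      for (tries in seq_len(100L)) {
        areas <- vapply(ccRegionNames(), function(r)
          drawFeasible(1, gs$regions[[r]]$mean, gs$regions[[r]]$sd,
                       lower = 0, what = paste0(g, " ", r)), numeric(1))
        ang <- drawFeasible(1, gs$bending_angle$mean, gs$bending_angle$sd,
                            lower = 1, upper = 179,
                            what = paste0(g, " bending angle"))
        base <- drawFeasible(1, gs$base_mm$mean, gs$base_mm$sd, lower = 1,
                             what = paste0(g, " base length"))
        height <- heightForAngle(base, ang)
        mask <- tryCatch(
          makeCCShape(base, height, areas, spacing = spacing, subjectID = id),
          ccmorphInfeasibleShape = function(e) NULL,
          ccmorphDegenerateShape = function(e) NULL)
        if (!is.null(mask)) break
      }
      if (is.null(mask))
        ccStop("ccmorphInfeasibleDraw",
               "group %s: no feasible geometry in 100 draws (areas vs bending angle)",
               g)
      masks[[id]] <- mask
      age <- stats::runif(1, gs$age_range[1], gs$age_range[2])
      demo <- rbind(demo, data.frame(
        subject_id = id, group = g, sex = sexes[i], age = age,
        site = sites[(subjIdx - 1L) %% length(sites) + 1L],
        linear_scale = 1, stringsAsFactors = FALSE))
      truth <- rbind(truth, data.frame(
        subject_id = id, region = ccRegionNames(), planted_area_mm2 = areas,
        planted_angle_deg = ang, planted_base_mm = base,
        stringsAsFactors = FALSE, row.names = NULL))
    }
  }
  list(masks = masks, demographics = demo, truth = truth)
}

#' Simulate a numeric area table (no masks)
#'
#' Draws per-subject sub-regional areas straight from the group normal
#' distributions (untruncated) and a bending angle per subject; ages are
#' uniform within the group range. Native and stereotaxic areas coincide
#' (`linear_scale = 1`). This bypasses imaging entirely and feeds the
#' statistics module directly.
#'
#' @param spec cohort spec (see [defaultCohortSpec()]).
#' @param seed integer seed.
#' @param n optional per-group size override.
#' @param sites site labels cycled over subjects.
#' @return data.frame with one row per subject x region: subject_id, group,
#'   sex, age, site, linear_scale, region, stereotaxic_area_mm2,
#'   native_area_mm2, bending_deg, base_mm, height_mm.
#' @export
simulateAreaTable <- function(spec, seed, n = NULL, sites = "site1") {
  validateCohortSpec(spec)
  set.seed(seed)
  rows <- NULL
  subjIdx <- 0L
  for (g in names(spec$groups)) {
    gs <- spec$groups[[g]]
    ng <- if (is.null(n)) gs$n else n
    nM <- round(ng * gs$males / gs$n)
    sexes <- rep(c("M", "F"), c(nM, ng - nM))
    ages <- stats::runif(ng, gs$age_range[1], gs$age_range[2])
    angs <- stats::rnorm(ng, gs$bending_angle$mean, gs$bending_angle$sd)
    bases <- stats::rnorm(ng, gs$base_mm$mean, gs$base_mm$sd)
    areas <- vapply(ccRegionNames(), function(r)
      stats::rnorm(ng, gs$regions[[r]]$mean, gs$regions[[r]]$sd),
      numeric(ng))
    if (ng == 1) areas <- matrix(areas, nrow = 1)
    rep5 <- rep(seq_len(ng), each = 5L)
    flat <- as.vector(t(areas))
    rows <- rbind(rows, data.frame(
      subject_id = sprintf("%s%0*d", tolower(g), max(2L, nchar(ng)), rep5),
      group = g, sex = sexes[rep5], age = ages[rep5],
      site = sites[(subjIdx + rep5 - 1L) %% length(sites) + 1L],
      linear_scale = 1, region = rep(ccRegionNames(), ng),
      stereotaxic_area_mm2 = flat, native_area_mm2 = flat,
      bending_deg = angs[rep5], base_mm = bases[rep5],
      height_mm = heightForAngle(bases[rep5],
                                 pmin(pmax(angs[rep5], 1), 179)),
      stringsAsFactors = FALSE, row.names = NULL))
    subjIdx <- subjIdx + ng
  }
  rows
}

#' Simulate the four group x sex cells of one region
#'
#' Draws a single-region area table from explicit cell distributions (as
#' used for interaction-F simulations on the isthmus), with independent
#' uniform ages.
#'
#' @param cells named list of `list(mean=, sd=, n=)`, names like `"CB_M"`.
#' @param region region name for the output rows.
#' @param ageRange ages drawn uniformly in this range.
#' @return Single-region area table data.frame.
#' @export
simulateCellTable <- function(cells, region = "isthmus",
                              ageRange = c(19, 63)) {
  ns <- vapply(cells, function(cl) as.integer(cl$n), integer(1))
  parts <- strsplit(names(cells), "_")
  y <- unlist(lapply(cells, function(cl) stats::rnorm(cl$n, cl$mean, cl$sd)),
              use.names = FALSE)
  n <- sum(ns)
  data.frame(
    subject_id = sprintf("s%03d", seq_len(n)),
    group = rep(vapply(parts, `[`, "", 1), ns),
    sex = rep(vapply(parts, `[`, "", 2), ns),
    age = stats::runif(n, ageRange[1], ageRange[2]),
    site = "site1", linear_scale = 1, region = region,
    stereotaxic_area_mm2 = y, native_area_mm2 = y,
    stringsAsFactors = FALSE)
}
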