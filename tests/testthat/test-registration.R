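# Registration and Jacobian-based area measurement. Small canvases keep the
# demons iterations cheap; settings mirror the pipeline's coarse profile.

coarse <- registrationSettings(schedulePx = c(8, 4, 2), iterations = 100)

test_that("registering an image to itself yields a (near-)zero field", {
  A <- archOnCanvas()
  f <- registerPair(A, A)
  expect_lt(max(abs(displacements(f))), 0.1)
})

test_that("a known translation is recovered", {
  A <- archOnCanvas()
  B <- archOnCanvas(shift = c(0, 3))
  f <- suppressWarnings(registerPair(B, A))   # field maps A-space -> B-space
  u <- displacements(f)
  w <- softMask(A, 0.8) > 0.2
  expect_lt(abs(mean(u[, , 2][w]) - 3), 0.5)
  expect_lt(abs(mean(u[, , 1][w])), 0.5)
})

test_that("uniform scaling is recovered as a quadratic area ratio", {
  A <- archOnCanvas()
  px <- maskPixels(A)
  ctr <- colMeans(which(px > 0, arr.ind = TRUE))
  ri <- matrix(seq_len(nrow(px)), nrow(px), ncol(px))
  ci <- matrix(seq_len(ncol(px)), nrow(px), ncol(px), byrow = TRUE)
  warp <- matrix(ccmorph:::bilinearSample(px + 0,
                                          ctr[1] + (ri - ctr[1]) / 1.1,
                                          ctr[2] + (ci - ctr[2]) / 1.1),
                 nrow(px), ncol(px))
  S <- midsagittalMask((warp > 0.5) * 1L, c(1, 1), "scaled")
  f <- suppressWarnings(registerPair(S, A))
  J <- suppressWarnings(jacobianMap(f))
  w <- softMask(A, 0.8) > 0.2
  expect_equal(mean(J[w]), 1.21, tolerance = 0.05)
})

test_that("grid mismatches are rejected", {
  A <- archOnCanvas()
  B <- archOnCanvas(canvas = c(50, 100))
  expect_error(registerPair(B, A), class = "ccmorphDimMismatch")
})

test_that("Jacobian maps obey the closed forms", {
  mkField <- function(u) new("DeformationField", displacements = u,
                             spacing = c(1, 1), subjectID = "f",
                             converged = TRUE)
  # zero field -> 1 everywhere
  u0 <- array(0, c(20, 25, 2))
  expect_true(all(jacobianMap(mkField(u0)) == 1))
  # affine u(x) = (s-1) x -> determinant s^2
  s <- 1.2
  u <- array(0, c(20, 25, 2))
  u[, , 1] <- (s - 1) * matrix(seq_len(20), 20, 25)
  u[, , 2] <- (s - 1) * matrix(seq_len(25), 20, 25, byrow = TRUE)
  expect_equal(max(abs(jacobianMap(mkField(u)) - s^2)), 0, tolerance = 1e-9)
  # rigid rotation -> determinant 1
  th <- 10 * pi / 180
  ri <- matrix(seq_len(20), 20, 25); ci <- matrix(seq_len(25), 20, 25,
                                                  byrow = TRUE)
  ur <- (cos(th) - 1) * ri - sin(th) * ci
  uc <- sin(th) * ri + (cos(th) - 1) * ci
  ur2 <- array(c(ur, uc), c(20, 25, 2))
  expect_equal(max(abs(jacobianMap(mkField(ur2)) - 1)), 0, tolerance = 1e-3)
})

test_that("non-positive determinants are reported, not clamped", {
  u <- array(0, c(10, 10, 2))
  u[, , 1] <- -2 * matrix(seq_len(10), 10, 10)   # folds rows over
  f <- new("DeformationField", displacements = u, spacing = c(1, 1),
           subjectID = "fold", converged = TRUE)
  expect_warning(J <- jacobianMap(f), "non-positive")
  expect_gt(attr(J, "nNonPositive"), 0)
  expect_lt(min(J), 0)
})

test_that("region areas integrate identity and affine fields exactly", {
  m <- filledRectMask(35, 100)
  lab <- subdivide(m, boundingRectangle(m), "+col")
  u0 <- array(0, c(35, 100, 2))
  f0 <- new("DeformationField", displacements = u0, spacing = c(1, 1),
            subjectID = "id", converged = TRUE)
  a0 <- regionAreas(lab, f0)
  expect_equal(a0$stereotaxic_area_mm2, c(1155, 595, 595, 455, 700))
  expect_equal(a0$native_area_mm2, a0$stereotaxic_area_mm2)

  s <- 1.1
  u <- array(0, c(35, 100, 2))
  u[, , 1] <- (s - 1) * matrix(seq_len(35), 35, 100)
  u[, , 2] <- (s - 1) * matrix(seq_len(100), 35, 100, byrow = TRUE)
  f1 <- new("DeformationField", displacements = u, spacing = c(1, 1),
            subjectID = "aff", converged = TRUE)
  a1 <- regionAreas(lab, f1)
  expect_equal(a1$stereotaxic_area_mm2, a0$stereotaxic_area_mm2 * s^2,
               tolerance = 1e-9)
})

test_that("linear scale converts stereotaxic to native quadratically", {
  m <- filledRectMask(20, 60)
  lab <- subdivide(m, boundingRectangle(m), "+col")
  f <- new("DeformationField", displacements = array(0, c(20, 60, 2)),
           spacing = c(1, 1), subjectID = "s1", converged = TRUE)
  rec <- data.frame(subject_id = "s1", linear_scale = 2)
  a <- regionAreas(lab, f, rec)
  expect_equal(a$native_area_mm2, a$stereotaxic_area_mm2 / 4)
})

test_that("a cohort of identical masks is its own template with zero fields", {
  m <- makeCCShape(80, 28, c(200, 80, 90, 60, 170))
  masks <- lapply(1:4, function(i)
    midsagittalMask(maskPixels(m), c(1, 1), paste0("s", i)))
  tm <- buildTemplate(masks, nIterations = 2, settings = coarse)
  expect_gt(diceOverlap(templateMask(tm), tm@masks[[1]]), 0.99)
  expect_lt(max(abs(displacements(templateFields(tm)[[1]]))), 0.1)
})

test_that("the unbiased template of two translated masks sits at the midpoint", {
  A <- archOnCanvas(shift = c(0, -2), id = "a")
  B <- archOnCanvas(shift = c(0, 2), id = "b")
  masks <- list(
    midsagittalMask(maskPixels(A), c(1, 1), "a"),
    midsagittalMask(maskPixels(B), c(1, 1), "b"))
  # bypass the centring of commonGrid: register the placed masks directly
  tm <- buildTemplate(masks, nIterations = 3,
                      settings = registrationSettings(schedulePx = c(16, 8, 4, 2),
                                                      iterations = 100),
                      padPx = 8L)
  ctm <- colMeans(which(maskPixels(templateMask(tm)) > 0, arr.ind = TRUE))
  c1 <- colMeans(which(maskPixels(tm@masks[["a"]]) > 0, arr.ind = TRUE))
  c2 <- colMeans(which(maskPixels(tm@masks[["b"]]) > 0, arr.ind = TRUE))
  mid <- (c1 + c2) / 2
  expect_lt(sqrt(sum((ctm - mid)^2)), 0.75)
  # after unbiasing, the average deformation is (near) zero
  ub <- Reduce(`+`, lapply(templateFields(tm), displacements)) / 2
  expect_lt(mean(sqrt(ub[, , 1]^2 + ub[, , 2]^2)), 0.2)
})

test_that("template construction is invariant to cohort order", {
  spec <- defaultCohortSpec()
  coh <- sampleMaskCohort(spec, seed = 13, n = 2)
  tm1 <- buildTemplate(coh$masks, nIterations = 2, settings = coarse)
  tm2 <- buildTemplate(rev(coh$masks), nIterations = 2, settings = coarse)
  expect_gt(diceOverlap(templateMask(tm1), templateMask(tm2)), 0.98)
})

test_that("empty cohorts are rejected", {
  expect_error(buildTemplate(list()), class = "ccmorphEmptyCohort")
  expect_error(buildTemplate(list(archOnCanvas())),
               class = "ccmorphEmptyCohort")
})

test_that("Jacobian integration conserves whole-CC area over sub-regions", {
  spec <- defaultCohortSpec()
  coh <- sampleMaskCohort(spec, seed = 19, n = 3)
  tm <- buildTemplate(coh$masks, nIterations = 2, settings = coarse)
  tmask <- templateMask(tm)
  lab <- subdivide(tmask, boundingRectangle(tmask), "+col")
  for (id in names(templateFields(tm))[1:2]) {
    f <- templateFields(tm)[[id]]
    a <- regionAreas(lab, f)
    J <- suppressWarnings(jacobianMap(f))
    whole <- sum(J[labelMatrix(lab) > 0])
    expect_equal(sum(a$stereotaxic_area_mm2), whole, tolerance = 1e-9)
  }
})
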