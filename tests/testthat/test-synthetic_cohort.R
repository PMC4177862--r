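test_that("planted bounding rectangle is reproduced within one pixel", {
  m <- makeCCShape(100, 35.27, rep(100, 5))
  r <- boundingRectangle(m)
  expect_true(abs(baseLength(r) - 100) <= 1)
  expect_true(abs(rectHeight(r) - 35.27) <= 1)
})

test_that("planted slab areas are recovered by pixel counting", {
  planted <- c(150, 80, 100, 70, 220)
  m <- makeCCShape(100, 35.27, planted)
  meas <- regionPixelAreas(subdivide(m, boundingRectangle(m), "+col"))
  tol <- pmax(0.02 * planted, 4)
  expect_true(all(abs(meas - planted) <= tol))
})

test_that("planted-area recovery holds over randomised feasible params", {
  set.seed(11)
  tested <- 0
  while (tested < 12) {
    b <- runif(1, 80, 110); h <- runif(1, 25, 40)
    planted <- c(runif(1, 200, 350), runif(1, 70, 130), runif(1, 70, 130),
                 runif(1, 50, 100), runif(1, 150, 260))
    m <- tryCatch(makeCCShape(b, h, planted),
                  ccmorphInfeasibleShape = function(e) NULL)
    if (is.null(m)) next
    tested <- tested + 1
    meas <- regionPixelAreas(subdivide(m, boundingRectangle(m), "+col"))
    expect_true(all(abs(meas - planted) <= pmax(0.02 * planted, 4)),
                info = sprintf("base %.1f height %.1f", b, h))
  }
})

test_that("bending angle of the generated shape matches the planted angle", {
  set.seed(12)
  tested <- 0
  while (tested < 8) {
    b <- runif(1, 80, 110); ang <- runif(1, 100, 125)
    h <- heightForAngle(b, ang)
    planted <- c(runif(1, 200, 300), runif(1, 80, 110), runif(1, 80, 110),
                 runif(1, 55, 80), runif(1, 150, 230))
    # half-pixel quantisation at 1 mm costs up to ~1 degree; generate at
    # 0.5 mm where the 1-degree recovery contract is meaningful
    m <- tryCatch(makeCCShape(b, h, planted, spacing = c(0.5, 0.5)),
                  ccmorphInfeasibleShape = function(e) NULL)
    if (is.null(m)) next
    tested <- tested + 1
    expect_lt(abs(bendingAngle(boundingRectangle(m)) - ang), 1)
  }
})

test_that("halving the pixel size preserves physical areas", {
  planted <- c(150, 80, 100, 70, 220)
  m1 <- makeCCShape(100, 35.27, planted)
  m2 <- makeCCShape(100, 35.27, planted, spacing = c(0.5, 0.5))
  n1 <- sum(maskPixels(m1)); n2 <- sum(maskPixels(m2))
  expect_equal(n2 / n1, 4, tolerance = 0.02)   # pixel counts x4
  expect_equal(n2 * 0.25, n1, tolerance = 0.02 * n1) # physical area equal
})

test_that("infeasible or degenerate demands are rejected", {
  expect_error(makeCCShape(100, 10, c(300, 100, 107, 79, 226)),
               class = "ccmorphInfeasibleShape")
  expect_error(makeCCShape(1, 1, rep(10, 5)),
               class = "ccmorphDegenerateShape")
  expect_error(makeCCShape(100, 30, c(-5, 10, 10, 10, 10)),
               class = "ccmorphInfeasibleShape")
})

test_that("mask cohorts are reproducible and match the demographics design", {
  spec <- defaultCohortSpec()
  coh <- sampleMaskCohort(spec, seed = 11, n = 4)
  expect_length(coh$masks, 8)
  expect_equal(nrow(coh$demographics), 8)
  coh2 <- sampleMaskCohort(spec, seed = 11, n = 4)
  expect_identical(lapply(coh$masks, maskPixels),
                   lapply(coh2$masks, maskPixels))
  expect_identical(coh$demographics, coh2$demographics)
  full <- sampleMaskCohort(spec, seed = 3)
  tab <- table(full$demographics$group, full$demographics$sex)
  expect_equal(unname(tab["CB", "M"]), 16)
  expect_equal(unname(tab["CB", "F"]), 12)
})

test_that("cohort subsets regenerate identically under the per-subject seed fanout", {
  spec <- defaultCohortSpec()
  full <- sampleMaskCohort(spec, seed = 21, n = 5)
  part <- sampleMaskCohort(spec, seed = 21, n = 5)
  expect_identical(maskPixels(full$masks[["cb03"]]),
                   maskPixels(part$masks[["cb03"]]))
})

test_that("zero-SD spec collapses each group onto one shape", {
  spec <- defaultCohortSpec()
  for (g in names(spec$groups)) {
    spec$groups[[g]]$bending_angle$sd <- 0
    spec$groups[[g]]$base_mm$sd <- 0
    for (r in ccRegionNames()) spec$groups[[g]]$regions[[r]]$sd <- 0
  }
  coh <- sampleMaskCohort(spec, seed = 9, n = 3)
  cb <- lapply(coh$masks[grep("^cb", names(coh$masks))], maskPixels)
  expect_identical(cb[[1]], cb[[2]])
  expect_identical(cb[[1]], cb[[3]])
})

test_that("planted cohort means track the spec distributions", {
  spec <- defaultCohortSpec()
  coh <- sampleMaskCohort(spec, seed = 17)
  spl <- coh$truth[coh$truth$region == "splenium" &
                     grepl("^cb", coh$truth$subject_id), ]
  se <- spec$groups$CB$regions$splenium$sd / sqrt(28)
  expect_lt(abs(mean(spl$planted_area_mm2) - 225.64), 2 * se)
})

test_that("numeric area tables follow the law of large numbers", {
  spec <- defaultCohortSpec()
  big <- simulateAreaTable(spec, seed = 6, n = 1e6 / 2)
  s <- big[big$region == "splenium" & big$group == "CB", "stereotaxic_area_mm2"]
  expect_lt(abs(mean(s) - 225.64), 0.2)
  expect_lt(abs(sd(s) - 31.7), 0.2)
})

test_that("zero-SD numeric tables equal their means and identical groups give null F", {
  spec <- defaultCohortSpec()
  for (g in names(spec$groups)) {
    spec$groups[[g]]$bending_angle$sd <- 0
    spec$groups[[g]]$base_mm$sd <- 0
    for (r in ccRegionNames()) spec$groups[[g]]$regions[[r]]$sd <- 0
  }
  tb <- simulateAreaTable(spec, seed = 3, n = 6)
  spl <- tb[tb$region == "splenium" & tb$group == "NC", ]
  expect_true(all(spl$stereotaxic_area_mm2 == 260.84))

  # two groups drawn from one distribution: one-way F has mean ~ 1
  spec2 <- defaultCohortSpec()
  spec2$groups$CB <- spec2$groups$NC
  set.seed(31)
  fs <- replicate(300, {
    tb2 <- simulateAreaTable(spec2, seed = sample.int(2^30, 1), n = 14)
    d <- tb2[tb2$region == "splenium", ]
    summary(stats::aov(stereotaxic_area_mm2 ~ group, d))[[1]]$`F value`[1]
  })
  expect_lt(abs(mean(fs) - 1), 0.25)
})

test_that("cohort spec validation catches malformed specs", {
  spec <- defaultCohortSpec()
  bad <- spec; bad$groups$CB$males <- 20
  expect_error(sampleMaskCohort(bad, seed = 1), class = "ccmorphBadSpec")
  bad2 <- spec; bad2$groups$CB$regions$splenium <- NULL
  expect_error(simulateAreaTable(bad2, seed = 1), class = "ccmorphBadSpec")
  bad3 <- spec; bad3$groups$NC[["n"]] <- 1
  expect_error(simulateAreaTable(bad3, seed = 1), class = "ccmorphBadSpec")
})

test_that("repeatedly infeasible draws name the offending parameter", {
  spec <- defaultCohortSpec()
  spec$groups$CB$bending_angle$mean <- 176   # arch nearly flat: infeasible
  spec$groups$CB$bending_angle$sd <- 0.1
  expect_error(sampleMaskCohort(spec, seed = 2, n = 2),
               class = "ccmorphInfeasibleDraw")
})
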