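spec <- defaultCohortSpec()

test_that("identical groups give a null group F and p near 1 at zero noise", {
  nullSpec <- spec
  nullSpec$groups$CB <- nullSpec$groups$NC
  for (g in names(nullSpec$groups))
    for (r in ccRegionNames()) nullSpec$groups[[g]]$regions[[r]]$sd <- 0
  # small independent jitter so the fit is numerically well-posed
  tb <- simulateAreaTable(nullSpec, seed = 2, n = 10)
  set.seed(5)
  tb$stereotaxic_area_mm2 <- tb$stereotaxic_area_mm2 + rnorm(nrow(tb), 0, 1)
  res <- ancovaGroup(tb, "splenium")
  expect_lt(res@F, 5)           # no systematic effect
  expect_equal(res@df1, 1)
})

test_that("adding a constant to every area leaves the group F unchanged", {
  tb <- simulateAreaTable(spec, seed = 14, n = 14)
  r1 <- ancovaGroup(tb, "splenium")
  tb2 <- tb
  tb2$stereotaxic_area_mm2 <- tb2$stereotaxic_area_mm2 + 500
  r2 <- ancovaGroup(tb2, "splenium")
  expect_equal(r1@F, r2@F)
  expect_equal(r1@p, r2@p)
})

test_that("centering the age covariate does not change F values", {
  tb <- simulateAreaTable(spec, seed = 15, n = 14)
  r1 <- ancovaGroup(tb, "isthmus", factors = c("group", "sex"))
  tb2 <- tb; tb2$age <- tb2$age - mean(tb2$age)
  r2 <- ancovaGroup(tb2, "isthmus", factors = c("group", "sex"))
  expect_equal(r1@table$F, r2@table$F, tolerance = 1e-10)
})

test_that("denominator df bookkeeping matches the fitted models", {
  tb <- simulateAreaTable(spec, seed = 16)   # n = 28 + 28
  one <- ancovaGroup(tb, "splenium")                      # group + age
  expect_equal(one@df2, 56 - 3)
  two <- interactionF(tb, "isthmus")                      # group*sex + age
  expect_equal(two@df2, 56 - 5)
  expect_equal(two@effect, "group:sex")
})

test_that("parallel group effects across sexes give a null interaction", {
  cells <- list(CB_M = list(mean = 90, sd = 0, n = 10),
                CB_F = list(mean = 80, sd = 0, n = 10),
                NC_M = list(mean = 70, sd = 0, n = 10),
                NC_F = list(mean = 60, sd = 0, n = 10))
  set.seed(6)
  tb <- simulateCellTable(cells)
  tb$stereotaxic_area_mm2 <- tb$stereotaxic_area_mm2 + rnorm(nrow(tb), 0, 1)
  res <- interactionF(tb, "isthmus")
  expect_lt(res@F, 5)
})

test_that("swapping the sex labels wholesale leaves the interaction F unchanged", {
  set.seed(7)
  tb <- simulateCellTable(spec$isthmus_cells)
  r1 <- interactionF(tb, "isthmus")
  tb2 <- tb; tb2$sex <- ifelse(tb2$sex == "M", "F", "M")
  r2 <- interactionF(tb2, "isthmus")
  expect_equal(r1@F, r2@F, tolerance = 1e-10)
})

test_that("empty cells are rejected with the cell named", {
  set.seed(8)
  tb <- simulateCellTable(spec$isthmus_cells)
  tb <- tb[!(tb$group == "CB" & tb$sex == "F"), ]
  expect_error(interactionF(tb, "isthmus"), class = "ccmorphEmptyCell")
})

test_that("Scheffe contrasts reproduce the isthmus cell pattern at exact moments", {
  tb <- exactIsthmusCellTable(spec$isthmus_cells)
  ph <- scheffePosthoc(tb, "isthmus")
  ct <- ph@contrasts
  involvesCBM <- ct$cell1 == "CB:M" | ct$cell2 == "CB:M"
  # the blind-male cell exceeds every other cell; nothing else separates
  expect_true(all(ct$significant[involvesCBM]))
  expect_false(any(ct$significant[!involvesCBM]))
  means <- tapply(tb$stereotaxic_area_mm2, paste(tb$group, tb$sex, sep = ":"),
                  mean)
  expect_true(all(means["CB:M"] > means[names(means) != "CB:M"]))
})

test_that("Scheffe p values are conservative and symmetric in pair order", {
  set.seed(9)
  tb <- simulateCellTable(spec$isthmus_cells)
  ph <- scheffePosthoc(tb, "isthmus")
  expect_true(all(ph@contrasts$p >= ph@contrasts$p_unadjusted - 1e-12))
  expect_true(all(ph@contrasts$p >= 0 & ph@contrasts$p <= 1))
})

test_that("equal cells give no significant Scheffe contrasts", {
  cells <- list(CB_M = list(mean = 70, sd = 0, n = 8),
                CB_F = list(mean = 70, sd = 0, n = 8),
                NC_M = list(mean = 70, sd = 0, n = 8),
                NC_F = list(mean = 70, sd = 0, n = 8))
  set.seed(10)
  tb <- simulateCellTable(cells)
  tb$stereotaxic_area_mm2 <- tb$stereotaxic_area_mm2 + rnorm(nrow(tb), 0, 2)
  ph <- scheffePosthoc(tb, "isthmus")
  expect_false(any(ph@contrasts$significant))
})

test_that("site ANOVA calibrates under the null and detects a shifted site", {
  # null: three sites from one distribution; p approximately uniform
  set.seed(20)
  ps <- replicate(400, {
    tb <- simulateAreaTable(spec, seed = sample.int(2^30, 1), n = 9,
                            sites = c("s1", "s2", "s3"))
    siteAnova(tb)@p
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  # power: one site shifted far out
  tb <- simulateAreaTable(spec, seed = 30, n = 9, sites = c("s1", "s2", "s3"))
  shift <- tb$site == "s3"
  tb$native_area_mm2[shift] <- tb$native_area_mm2[shift] + 150
  res <- siteAnova(tb)
  expect_lt(res@p, 0.001)
  expect_equal(res@df1, 2)
  # two sites only: df1 = 1
  tb2 <- simulateAreaTable(spec, seed = 31, n = 9, sites = c("s1", "s2"))
  expect_equal(siteAnova(tb2)@df1, 1)
  # single site rejected
  tb3 <- simulateAreaTable(spec, seed = 32, n = 4)
  expect_error(siteAnova(tb3), class = "ccmorphSingleSite")
})

test_that("the Bonferroni gate is inclusive at its threshold", {
  p <- c(anterior_third = 0.010, anterior_midbody = 0.011,
         posterior_midbody = 0.5, isthmus = 0.001, splenium = 0.2)
  flags <- bonferroniGate(p)
  expect_true(flags[["anterior_third"]])    # p = 0.010 counts
  expect_false(flags[["anterior_midbody"]]) # p = 0.011 does not
  expect_true(flags[["isthmus"]])
  expect_equal(sum(bonferroniGate(rep(0.5, 5))), 0)
  expect_error(bonferroniGate(rep(0.005, 4)), class = "ccmorphBadCount")
})
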