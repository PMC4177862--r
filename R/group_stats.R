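# Group statistics on an area table: age-covaried ANCOVA (Type III sums of
# squares, sum-to-zero factor coding), group x sex interaction, Scheffe
# post-hoc contrasts, Bonferroni gating across the five sub-regions, and a
# one-way scanner-site check on native areas.

areaColumn <- function(space = c("stereotaxic", "native")) {
  space <- match.arg(space)
  paste0(space, "_area_mm2")
}

subsetRegion <- function(table, region, space) {
  col <- areaColumn(space)
  if (!region %in% table$region)
    ccStop("ccmorphBadRegion", "region '%s' not present in the table", region)
  d <- table[table$region == region, , drop = FALSE]
  if (any(is.na(d$age)))
    ccStop("ccmorphBadAge", "missing ages in region '%s'", region)
  d$group <- factor(d$group)
  d$sex <- factor(d$sex)
  d$area <- d[[col]]
  d
}

checkCells <- function(d, factors, minPerCell = 2L) {
  cells <- interaction(d[factors], drop = FALSE, sep = ":")
  counts <- table(cells)
  empty <- names(counts)[counts < minPerCell]
  if (length(empty))
    ccStop("ccmorphEmptyCell", "cell(s) with fewer than %d subjects: %s",
           minPerCell, paste(empty, collapse = ", "))
  invisible(TRUE)
}

ancovaFit <- function(d, factors, covariate = "age") {
  rhs <- if (length(factors) == 2)
    paste(factors[1], "*", factors[2]) else factors
  fml <- stats::as.formula(paste("area ~", rhs, "+", covariate))
  contr <- stats::setNames(replicate(length(factors), "contr.sum",
                                     simplify = FALSE), factors)
  mod <- stats::lm(fml, data = d, contrasts = contr)
  if (any(is.na(stats::coef(mod))))
    ccStop("ccmorphRankDeficient", "rank-deficient design for this region")
  mod
}

effectTable <- function(mod) {
  a3 <- car::Anova(mod, type = 3)
  keep <- !rownames(a3) %in% c("(Intercept)", "Residuals")
  data.frame(effect = rownames(a3)[keep], F = a3[keep, "F value"],
             df1 = a3[keep, "Df"],
             df2 = a3["Residuals", "Df"], p = a3[keep, "Pr(>F)"],
             stringsAsFactors = FALSE, row.names = NULL)
}

adjustedCellMeans <- function(mod, d, factors, covariate = "age") {
  grid <- unique(d[factors])
  grid[[covariate]] <- mean(d[[covariate]])
  mu <- stats::predict(mod, newdata = grid)
  stats::setNames(mu, apply(grid[factors], 1, paste, collapse = ":"))
}

ancovaResultFor <- function(mod, d, factors, effect, covariate = "age") {
  tab <- effectTable(mod)
  row <- tab[tab$effect == effect, ]
  if (nrow(row) != 1)
    ccStop("ccmorphBadEffect", "effect '%s' not in the fitted model", effect)
  new("AncovaResult", effect = effect, F = row$F, df1 = row$df1,
      df2 = row$df2, p = row$p,
      adjustedMeans = adjustedCellMeans(mod, d, factors, covariate),
      table = tab)
}

#' Group ANCOVA for one sub-region
#'
#' Linear model `area ~ group (+ sex + group:sex) + age` with sum-to-zero
#' factor coding and Type III sums of squares; returns the group effect.
#' Areas default to stereotaxic space (the brain-size-normalised areas the
#' group comparison is defined on).
#'
#' @param table area table (see [simulateAreaTable()]).
#' @param region one of [ccRegionNames()] (or any region present).
#' @param factors `"group"` or `c("group", "sex")`; with two factors the
#'   interaction is included.
#' @param covariate covariate column name (default `"age"`).
#' @param space `"stereotaxic"` (default) or `"native"`.
#' @return An [AncovaResult-class] for the group effect; slot `table` holds
#'   all effects.
#' @export
ancovaGroup <- function(table, region, factors = "group", covariate = "age",
                        space = "stereotaxic") {
  d <- subsetRegion(table, region, space)
  checkCells(d, factors)
  mod <- ancovaFit(d, factors, covariate)
  ancovaResultFor(mod, d, factors, "group", covariate)
}

#' Group x sex interaction F for one sub-region
#'
#' The interaction term of the two-factor age-covaried model
#' `area ~ group * sex + age` (Type III, sum-to-zero coding).
#'
#' @inheritParams ancovaGroup
#' @return An [AncovaResult-class] for the `group:sex` effect.
#' @export
interactionF <- function(table, region, covariate = "age",
                         space = "stereotaxic") {
  d <- subsetRegion(table, region, space)
  checkCells(d, c("group", "sex"))
  mod <- ancovaFit(d, c("group", "sex"), covariate)
  ancovaResultFor(mod, d, c("group", "sex"), "group:sex", covariate)
}

#' Scheffe post-hoc contrasts among the group x sex cells
#'
#' All six pairwise contrasts among the four group x sex cell means, from
#' the cell-means model (with the age covariate retained when present).
#' The Scheffe criterion compares each contrast F to the distribution of
#' `(k - 1) * F(k - 1, df_error)`; the adjusted p is
#' `P(F(k-1, df_e) > F_contrast / (k-1))`, valid simultaneously over all
#' linear contrasts, hence conservative for pairwise ones.
#'
#' @inheritParams ancovaGroup
#' @param alpha significance level for the flag (default 0.05).
#' @return A [PosthocResult-class].
#' @export
scheffePosthoc <- function(table, region, covariate = "age", alpha = 0.05,
                           space = "stereotaxic") {
  d <- subsetRegion(table, region, space)
  d$cell <- factor(paste(d$group, d$sex, sep = ":"))
  k <- nlevels(d$cell)
  if (k < 2)
    ccStop("ccmorphEmptyCell", "need at least 2 group x sex cells")
  fml <- if (covariate %in% names(d))
    stats::as.formula(paste("area ~ 0 + cell +", covariate))
  else area ~ 0 + cell
  mod <- stats::lm(fml, data = d)
  V <- stats::vcov(mod)
  cf <- stats::coef(mod)
  cellIdx <- grep("^cell", names(cf))
  cellNames <- sub("^cell", "", names(cf)[cellIdx])
  dfe <- mod$df.residual
  pairs <- utils::combn(seq_along(cellIdx), 2)
  res <- apply(pairs, 2, function(pr) {
    i <- cellIdx[pr[1]]; j <- cellIdx[pr[2]]
    est <- unname(cf[i] - cf[j])
    se <- sqrt(V[i, i] + V[j, j] - 2 * V[i, j])
    Fc <- (est / se)^2
    c(est = est, se = se, F = Fc,
      p = stats::pf(Fc / (k - 1), k - 1, dfe, lower.tail = FALSE),
      p_unadj = 2 * stats::pt(-abs(est / se), dfe))
  })
  out <- data.frame(cell1 = cellNames[pairs[1, ]],
                    cell2 = cellNames[pairs[2, ]],
                    estimate = res["est", ], se = res["se", ],
                    F = res["F", ], p = res["p", ],
                    p_unadjusted = res["p_unadj", ],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$significant <- out$p < alpha
  new("PosthocResult", contrasts = out, alpha = alpha)
}

#' One-way site ANOVA on native whole-CC area
#'
#' Checks for acquisition-site differences with a one-way ANOVA across
#' sites on the native-space total CC area (sum of the five sub-regions per
#' subject). Always uses native areas: site effects act on raw anatomy,
#' before brain-size normalisation.
#'
#' @param table area table.
#' @return An [AncovaResult-class] for the site effect.
#' @export
siteAnova <- function(table) {
  tot <- stats::aggregate(native_area_mm2 ~ subject_id + site, data = table,
                          FUN = sum)
  tot$site <- factor(tot$site)
  if (nlevels(tot$site) < 2)
    ccStop("ccmorphSingleSite", "site ANOVA needs at least 2 sites")
  mod <- stats::lm(native_area_mm2 ~ site, data = tot)
  a <- stats::anova(mod)
  new("AncovaResult", effect = "site", F = a["site", "F value"],
      df1 = a["site", "Df"], df2 = a["Residuals", "Df"],
      p = a["site", "Pr(>F)"],
      adjustedMeans = c(tapply(tot$native_area_mm2, tot$site, mean)),
      table = data.frame(effect = "site", F = a["site", "F value"],
                         df1 = a["site", "Df"], df2 = a["Residuals", "Df"],
                         p = a["site", "Pr(>F)"], stringsAsFactors = FALSE))
}

#' Bonferroni gate over the five sub-region tests
#'
#' Multiple-comparison gate across the five sub-regions at the fixed
#' threshold p <= 0.01 (0.05 over five regions, applied inclusively).
#'
#' @param results list of exactly five [AncovaResult-class] objects, or a
#'   numeric vector of five p values, named by region.
#' @param threshold significance threshold (default 0.01, inclusive).
#' @return Named logical vector of significance flags.
#' @export
bonferroniGate <- function(results, threshold = 0.01) {
  p <- if (is.numeric(results)) results
  else vapply(results, function(r) r@p, numeric(1))
  if (length(p) != 5)
    ccStop("ccmorphBadCount", "expected exactly five region results, got %d",
           length(p))
  if (is.null(names(p)) || !any(nzchar(names(p)))) names(p) <- ccRegionNames()
  p <= threshold
}
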