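#' Default livestock body masses (kg)
#'
#' Configuration for [livestockBiomass()]; literature-style averages for the
#' four common livestock types. Override by passing a named vector.
#' @export
DEFAULT_BODY_MASS <- c(cow = 250, buffalo = 350, sheep = 30, goat = 25)

#' Village livestock biomass
#'
#' Head counts times mean body mass, split into small-bodied (sheep + goat)
#' and large-bodied (cow + buffalo) stock.
#'
#' @param counts named numeric vector with elements `cow`, `buffalo`,
#'   `sheep`, `goat` (head counts).
#' @param masses named numeric vector of mean body masses in kg; defaults to
#'   [DEFAULT_BODY_MASS].
#' @return named numeric `c(small =, large =)` in kg.
#' @examples
#' livestockBiomass(c(cow = 0, buffalo = 0, sheep = 100, goat = 50))
#' @export
livestockBiomass <- function(counts, masses = DEFAULT_BODY_MASS) {
  need <- c("cow", "buffalo", "sheep", "goat")
  if (!all(need %in% names(masses)) || any(!is.finite(masses[need])) ||
      any(masses[need] <= 0))
    stop("body-mass configuration must give a positive mass for ",
         paste(need, collapse = ", "))
  counts <- counts[need]
  counts[is.na(counts)] <- 0
  if (any(counts < 0)) stop("head counts must be non-negative")
  c(small = sum(counts[c("sheep", "goat")] * masses[c("sheep", "goat")]),
    large = sum(counts[c("cow", "buffalo")] * masses[c("cow", "buffalo")]))
}

#' Apportion a village quantity to overlapping grids
#'
#' Villages spread over several grid cells contribute in proportion to the
#' village area falling in each cell; contributions conserve the village
#' total exactly.
#'
#' @param amount scalar quantity (e.g. biomass in kg).
#' @param overlap named numeric vector of grid overlap fractions, summing
#'   to 1.
#' @return named numeric vector of per-grid contributions.
#' @export
apportionToGrids <- function(amount, overlap) {
  if (any(overlap < 0 | overlap > 1))
    stop("overlap fractions must lie in [0,1]")
  if (abs(sum(overlap) - 1) > 1e-9)
    stop("overlap fractions must sum to 1")
  amount * overlap
}

#' Grid-level livestock biomass from a village table
#'
#' @param villages data.frame with columns `village_id`, `cow`, `buffalo`,
#'   `sheep`, `goat`.
#' @param overlaps data.frame with columns `village_id`, `grid_id`,
#'   `fraction` (fractions sum to 1 within village).
#' @param masses body-mass configuration, see [livestockBiomass()].
#' @return data.frame `grid_id`, `biomass_small`, `biomass_large` in kg.
#' @export
gridLivestockBiomass <- function(villages, overlaps,
                                 masses = DEFAULT_BODY_MASS) {
  grids <- unique(overlaps$grid_id)
  small <- large <- setNames(numeric(length(grids)), grids)
  for (i in seq_len(nrow(villages))) {
    v <- villages[i, ]
    bm <- livestockBiomass(
      c(cow = v$cow, buffalo = v$buffalo, sheep = v$sheep, goat = v$goat),
      masses)
    ov <- overlaps[overlaps$village_id == v$village_id, ]
    if (!nrow(ov)) next
    fr <- setNames(ov$fraction, ov$grid_id)
    small[names(fr)] <- small[names(fr)] + apportionToGrids(bm["small"], fr)
    large[names(fr)] <- large[names(fr)] + apportionToGrids(bm["large"], fr)
  }
  data.frame(grid_id = grids, biomass_small = unname(small[grids]),
             biomass_large = unname(large[grids]))
}

#' Open-natural-ecosystem area from a pixel probability field
#'
#' Pixels with probability strictly above 0.5 count as ONE; area is the pixel
#' count times the pixel area.
#'
#' @param pixel_probs numeric vector or matrix of per-pixel probabilities in
#'   `[0, 1]`.
#' @param pixel_area area of one pixel in km^2.
#' @return area in km^2.
#' @examples
#' oneArea(c(0.4, 0.5, 0.6), 1)  # 1: only the strict exceedance counts
#' @export
oneArea <- function(pixel_probs, pixel_area) {
  p <- as.numeric(pixel_probs)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("pixel probabilities must lie in [0,1]")
  sum(p > 0.5, na.rm = TRUE) * pixel_area
}

#' Z-score columns against a standardization population
#'
#' Standardizes `(x - mean) / sd` with the sample (n-1) standard deviation,
#' computing the moments over `population` — by default the table itself, but
#' for district-wide prediction the full grid set (sampled and unsampled) so
#' that fitted coefficients and predictions share one scale.
#'
#' @param table data.frame of numeric columns to standardize.
#' @param population data.frame holding the same columns over the
#'   standardization population.
#' @param columns which columns to standardize (default: all numeric).
#' @return `table` with the named columns replaced by z-scores; the moments
#'   are attached as attributes `zscore_mean` / `zscore_sd`.
#' @export
zscoreColumns <- function(table, population = table, columns = NULL) {
  if (is.null(columns))
    columns <- names(table)[vapply(table, is.numeric, TRUE)]
  mu <- sdv <- setNames(numeric(length(columns)), columns)
  for (cl in columns) {
    x <- population[[cl]]
    if (is.null(x)) stop("population lacks column '", cl, "'")
    mu[cl] <- mean(x)
    sdv[cl] <- sd(x)
    if (!is.finite(sdv[cl]) || sdv[cl] == 0)
      stop("zero-variance column cannot be z-scored: '", cl, "'")
    table[[cl]] <- (table[[cl]] - mu[cl]) / sdv[cl]
  }
  attr(table, "zscore_mean") <- mu
  attr(table, "zscore_sd") <- sdv
  table
}

#' Pearson collinearity screen
#'
#' Flags every covariate pair with `|r| >= threshold` (inclusive, default
#' 0.6). Flagged pairs may never co-occur in one model specification; the
#' candidate-set builder enforces this.
#'
#' @param table data.frame of numeric covariate columns (>= 3 rows).
#' @param threshold inclusive absolute-correlation cutoff.
#' @param columns columns to screen (default all numeric).
#' @return data.frame `u`, `v`, `r` of flagged pairs (zero rows if none).
#' @export
correlationScreen <- function(table, threshold = 0.6, columns = NULL) {
  if (is.null(columns))
    columns <- names(table)[vapply(table, is.numeric, TRUE)]
  if (nrow(table) < 3) stop("need at least 3 rows to screen correlations")
  cm <- cor(table[columns])
  out <- data.frame(u = character(), v = character(), r = numeric())
  if (length(columns) < 2) return(out)
  prs <- combn(columns, 2)
  for (k in seq_len(ncol(prs))) {
    r <- cm[prs[1, k], prs[2, k]]
    if (abs(r) >= threshold)
      out <- rbind(out, data.frame(u = prs[1, k], v = prs[2, k], r = r))
  }
  out
}

# TRUE when covariates a and b are jointly barred by the screen
isIncompatible <- function(a, b, flagged) {
  if (!nrow(flagged)) return(FALSE)
  any((flagged$u == a & flagged$v == b) | (flagged$u == b & flagged$v == a))
}

#' Assemble and standardize the site-covariate table
#'
#' Joins land-cover areas, road length and apportioned livestock biomass into
#' one table keyed by `grid_id`, z-scores the covariate columns against the
#' full district population, and runs the collinearity screen on the sampled
#' subset.
#'
#' @param landcover data.frame with `grid_id`, `area_kharif`,
#'   `area_double_triple`, `area_one`, `road_length`, `water_fraction`,
#'   `sampled` (logical).
#' @param biomass data.frame from [gridLivestockBiomass()] (optional; absent
#'   biomass columns are filled with 0).
#' @param threshold correlation-screen cutoff.
#' @return list with `covariates` (z-scored, all grids), `raw`, `flagged`
#'   (screen report), `moments`.
#' @export
buildCovariateTable <- function(landcover, biomass = NULL, threshold = 0.6) {
  df <- landcover
  if (!is.null(biomass)) {
    df <- merge(df, biomass, by = "grid_id", all.x = TRUE)
    df$biomass_small[is.na(df$biomass_small)] <- 0
    df$biomass_large[is.na(df$biomass_large)] <- 0
  } else {
    df$biomass_small <- df$biomass_large <- 0
  }
  df$biomass_all <- df$biomass_small + df$biomass_large
  covcols <- intersect(
    c("area_kharif", "area_double_triple", "area_one", "road_length",
      "biomass_small", "biomass_large", "biomass_all"),
    names(df))
  covcols <- covcols[vapply(covcols, function(cl) sd(df[[cl]]) > 0, TRUE)]
  z <- zscoreColumns(df, population = df, columns = covcols)
  sampled <- if ("sampled" %in% names(df)) df$sampled else rep(TRUE, nrow(df))
  flagged <- correlationScreen(z[sampled, , drop = FALSE],
                               threshold = threshold, columns = covcols)
  list(covariates = z, raw = df, flagged = flagged,
       moments = list(mean = attr(z, "zscore_mean"),
                      sd = attr(z, "zscore_sd")))
}
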