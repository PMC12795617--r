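#' Default covariate menus per species
#'
#' Which covariates are eligible for occupancy (psi) and detection (p) for
#' each focal species, with the expected sign of the relationship (used for
#' reporting only, never to constrain fits). Column names refer to the
#' covariate table: `area_one` (open natural ecosystem), `area_kharif`
#' (monsoon cropping), `area_double_triple` (irrigated cropping),
#' `road_length`, `biomass_all` / `biomass_small` (livestock), plus the
#' replicate-level `grid_covered` and `years_experience`.
#'
#' @return named list per species with elements `psi`, `p`, `expected_sign`.
#' @export
speciesMenus <- function() {
  list(
    leopard = list(
      psi = c("biomass_all", "road_length", "area_double_triple", "area_one"),
      p = c("area_double_triple", "area_one", "grid_covered",
            "years_experience"),
      expected_sign = c(biomass_all = "+", road_length = "-",
                        area_double_triple = "+", area_one = "+")),
    wolf = list(
      psi = c("biomass_small", "road_length", "area_kharif", "area_one"),
      p = c("area_kharif", "area_one", "grid_covered", "years_experience"),
      expected_sign = c(biomass_small = "+", road_length = "-",
                        area_kharif = "+", area_one = "+")),
    hyena = list(
      psi = c("biomass_all", "road_length", "area_double_triple", "area_one"),
      p = c("area_double_triple", "area_one", "grid_covered",
            "years_experience"),
      expected_sign = c(biomass_all = "+", road_length = "-",
                        area_double_triple = "+", area_one = "+")),
    sloth_bear = list(
      psi = c("road_length", "area_kharif", "area_one"),
      p = c("area_kharif", "area_one", "grid_covered", "years_experience"),
      expected_sign = c(road_length = "-", area_kharif = "+",
                        area_one = "+")),
    blackbuck = list(
      psi = c("road_length", "area_kharif", "area_one"),
      p = c("area_kharif", "area_one", "grid_covered", "years_experience"),
      expected_sign = c(road_length = "-", area_kharif = "+",
                        area_one = "+"))
  )
}

#' Pipeline configuration
#'
#' Consolidates the thresholds of the analysis: correlation screen cutoff,
#' delta-QAICc retention bound, the strict 0.5 pixel-probability cutoff for
#' ONE area, the 3/4 waterbody exclusion, bootstrap size and seeds.
#'
#' @param correlation_threshold collinearity cutoff (inclusive).
#' @param delta_retain delta-QAICc retention bound (inclusive).
#' @param water_threshold waterbody exclusion fraction.
#' @param bootstrap_B parametric-bootstrap replicates for c-hat.
#' @param chat `"bootstrap"` or `"none"`.
#' @param seed master seed.
#' @param starts optimisation starts per fit.
#' @param model_species species receiving the covariate-model treatment;
#'   the others get naive/detection-rate summaries and a null fit only.
#' @return a `pipelineConfig` list.
#' @export
pipelineConfig <- function(correlation_threshold = 0.6, delta_retain = 2.0,
                           water_threshold = 0.75, bootstrap_B = 100,
                           chat = "bootstrap", seed = 1, starts = 5,
                           model_species = c("hyena", "sloth_bear",
                                             "blackbuck")) {
  stopifnot(correlation_threshold > 0, delta_retain > 0, water_threshold > 0)
  structure(list(
    correlation_threshold = correlation_threshold,
    delta_retain = delta_retain, water_threshold = water_threshold,
    bootstrap_B = bootstrap_B, chat = chat, seed = as.integer(seed),
    starts = starts, model_species = model_species
  ), class = "pipelineConfig")
}

#' Run the full interview-to-surface pipeline
#'
#' Ingests interview records, builds per-species detection histories and
#' naive-occupancy summaries, and for the modelled species runs the two-step
#' QAICc selection and the model-averaged district surface. Species whose
#' data cannot support covariate models still get their detection matrix and
#' null fit. Each stage failure aborts with a stage-tagged error.
#'
#' @param records list of [interviewRecord()]s (e.g. from [readInterviews()]
#'   or [simulateSurvey()]).
#' @param covariates result of [buildCovariateTable()] or
#'   [simulateLandscape()].
#' @param config a [pipelineConfig()].
#' @param species which focal species to process (default: those present).
#' @param outDir optional directory for delimited-text exports.
#' @return named list per species: `detections`, `naive`, `nullFit`, and for
#'   modelled species `selection`, `surface`; plus `manifest`.
#' @export
runPipeline <- function(records, covariates, config = pipelineConfig(),
                        species = NULL, outDir = NULL) {
  stageError <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
  }
  cov <- covariates$covariates
  flagged <- covariates$flagged
  menus <- speciesMenus()
  if (is.null(species)) {
    present <- unique(unlist(lapply(records, function(r) names(r$responses))))
    species <- intersect(FOCAL_SPECIES, present)
  }
  out <- list()
  for (sp in species) {
    res <- list()
    dm <- stageError("ingest", standardizeDetCovariates(suppressWarnings(
      buildDetectionMatrix(records, sp))))
    res$detections <- dm
    res$naive <- round(naiveOccupancy(dm), 2)
    res$nullFit <- stageError("fit",
      fitOccupancy(dm, cov, occuModelSpec(), starts = config$starts,
                   seed = config$seed))
    if (sp %in% config$model_species) {
      menu <- menus[[sp]]
      missingCov <- setdiff(menu$psi, names(cov))
      if (length(missingCov))
        stop(sprintf("[config] species '%s' menu names unknown covariates: %s",
                     sp, paste(missingCov, collapse = ", ")), call. = FALSE)
      res$selection <- stageError("select",
        twoStepSelect(dm, cov, pMenu = intersect(menu$p, c(names(cov),
                        "grid_covered", "years_experience")),
                      psiMenu = menu$psi, flagged = flagged,
                      B = config$bootstrap_B, seed = config$seed,
                      chat = config$chat, starts = config$starts))
      res$surface <- stageError("average",
        modelAverage(res$selection$psiLadder, cov,
                     waterThreshold = config$water_threshold))
    }
    out[[sp]] <- res
  }
  out$manifest <- list(
    seed = config$seed, thresholds = config[c(
      "correlation_threshold", "delta_retain", "water_threshold",
      "bootstrap_B", "chat")],
    n_records = length(records), species = species,
    package_version = as.character(utils::packageVersion("occuInterview")))
  if (!is.null(outDir)) exportPipeline(out, outDir)
  invisible(out)
}

#' Render a ladder in the printed-table column layout
#'
#' Columns: model label, K, QAICc, delta-QAICc, weight, cumulative weight,
#' quasi-log-likelihood, all rounded to two decimals.
#'
#' @param ladder a [ModelLadder-class].
#' @return data.frame of character columns.
#' @export
renderLadder <- function(ladder) {
  tb <- ladderTable(ladder)
  if (!nrow(tb)) return(data.frame(note = "no models within delta <= 2"))
  data.frame(
    model = tb$model, K = tb$K,
    QAICc = sprintf("%.2f", tb$QAICc),
    dQAICc = sprintf("%.2f", tb$dQAICc),
    weight = sprintf("%.2f", tb$weight),
    cumWeight = sprintf("%.2f", tb$cumWeight),
    quasiLogLik = sprintf("%.2f", tb$quasiLogLik))
}

#' Coefficient summary table across a candidate set
#'
#' One row per covariate, reporting `estimate (SE)` from the top-ranked
#' model in which the covariate first appears, plus the null-model row.
#'
#' @param ladder a [ModelLadder-class] (occupancy stage).
#' @param covariates covariate names to report (default: all seen).
#' @return data.frame `covariate`, `estimate`, `se`, `model`.
#' @export
betaSummary <- function(ladder, covariates = NULL) {
  fits <- ladder@fits
  seen <- unique(unlist(lapply(fits, function(f) f@spec@psiCovariates)))
  if (is.null(covariates)) covariates <- seen
  rows <- list()
  nullIdx <- which(vapply(fits, function(f)
    length(f@spec@psiCovariates) == 0, TRUE))[1]
  if (!is.na(nullIdx))
    rows[["(null)"]] <- data.frame(
      covariate = "(null)",
      estimate = fits[[nullIdx]]@betaPsi[[1]],
      se = fits[[nullIdx]]@sePsi[[1]],
      model = modelLabel(fits[[nullIdx]]))
  for (cv in covariates) {
    idx <- which(vapply(fits, function(f)
      cv %in% f@spec@psiCovariates, TRUE))[1]
    if (is.na(idx)) next
    f <- fits[[idx]]
    k <- which(f@spec@psiCovariates == cv) + 1
    rows[[cv]] <- data.frame(covariate = cv, estimate = f@betaPsi[[k]],
                             se = f@sePsi[[k]], model = modelLabel(f))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# write the pipeline bundle as delimited text + manifest
exportPipeline <- function(result, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  species <- setdiff(names(result), "manifest")
  for (sp in species) {
    res <- result[[sp]]
    writeDetectionHistory(res$detections,
                          file.path(outDir, paste0(sp, "_history.csv")))
    write.csv(siteSummary(res$detections),
              file.path(outDir, paste0(sp, "_sites.csv")), row.names = FALSE)
    if (!is.null(res$selection)) {
      write.csv(renderLadder(res$selection$pLadder),
                file.path(outDir, paste0(sp, "_ladder_p.csv")),
                row.names = FALSE)
      write.csv(renderLadder(res$selection$psiLadder),
                file.path(outDir, paste0(sp, "_ladder_psi.csv")),
                row.names = FALSE)
      write.csv(res$surface@surface,
                file.path(outDir, paste0(sp, "_surface.csv")),
                row.names = FALSE)
    }
  }
  mf <- result$manifest
  lines <- c(
    sprintf("seed: %d", mf$seed),
    sprintf("n_records: %d", mf$n_records),
    sprintf("species: %s", paste(mf$species, collapse = ", ")),
    sprintf("package_version: %s", mf$package_version),
    vapply(names(mf$thresholds), function(nm)
      sprintf("%s: %s", nm, mf$thresholds[[nm]]), ""))
  writeLines(lines, file.path(outDir, "manifest.txt"))
  invisible(outDir)
}

#' Export a surface as GeoJSON
#'
#' Joins per-grid occupancy to square cell polygons. Geometry is supplied as
#' a data.frame of cell centres plus the cell size; requires the jsonlite
#' package.
#'
#' @param surface an [AveragedSurface-class].
#' @param centres data.frame `grid_id`, `x`, `y` (cell-centre coordinates).
#' @param cellSize cell edge length in the coordinate units.
#' @param path output file.
#' @export
writeSurfaceGeoJSON <- function(surface, centres, cellSize, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required for GeoJSON export")
  df <- merge(surface@surface, centres, by = "grid_id")
  h <- cellSize / 2
  features <- lapply(seq_len(nrow(df)), function(i) {
    x <- df$x[i]; y <- df$y[i]
    ring <- list(c(x - h, y - h), c(x + h, y - h), c(x + h, y + h),
                 c(x - h, y + h), c(x - h, y - h))
    list(type = "Feature",
         properties = list(grid_id = df$grid_id[i], psi = df$psi[i],
                           se = df$se[i], excluded = df$excluded[i]),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = 6)
  invisible(path)
}
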