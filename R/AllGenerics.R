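#' Accessors and show methods
#'
#' Small accessor layer over the S4 containers so downstream code never
#' touches slots directly.
#' @name accessors
NULL

#' @describeIn accessors species of a detection matrix
#' @param object an S4 object from this package
#' @export
setGeneric("speciesName", function(object) standardGeneric("speciesName"))

#' @describeIn accessors site identifiers
#' @export
setGeneric("siteIDs", function(object) standardGeneric("siteIDs"))

#' @describeIn accessors three-state site x replicate matrix
#' @export
setGeneric("detectionStates", function(object) standardGeneric("detectionStates"))

#' @describeIn accessors binary (certain-only) site x replicate matrix
#' @export
setGeneric("detectionBinary", function(object) standardGeneric("detectionBinary"))

#' @describeIn accessors replicate-level detection covariate matrices
#' @export
setGeneric("detectionCovariates", function(object) standardGeneric("detectionCovariates"))

#' @describeIn accessors number of sites
#' @export
setGeneric("nSites", function(object) standardGeneric("nSites"))

#' Naive occupancy: fraction of sites with at least one certain detection
#'
#' Ignores imperfect detection; under the null occupancy model the estimated
#' occupancy can only be at or above this value.
#' @param object a [DetectionMatrix-class]
#' @return proportion in `[0, 1]`
#' @export
setGeneric("naiveOccupancy", function(object) standardGeneric("naiveOccupancy"))

#' @describeIn accessors ladder table (data.frame)
#' @export
setGeneric("ladderTable", function(object) standardGeneric("ladderTable"))

#' @describeIn accessors retained (dQAICc <= 2) fits of a ladder
#' @export
setGeneric("retainedFits", function(object) standardGeneric("retainedFits"))

setMethod("speciesName", "DetectionMatrix", function(object) object@species)
setMethod("siteIDs", "DetectionMatrix", function(object) object@siteIDs)
setMethod("detectionStates", "DetectionMatrix", function(object) object@states)
setMethod("detectionBinary", "DetectionMatrix", function(object) object@binary)
setMethod("detectionCovariates", "DetectionMatrix",
          function(object) object@detCovariates)
setMethod("nSites", "DetectionMatrix", function(object) nrow(object@states))

setMethod("naiveOccupancy", "DetectionMatrix", function(object) {
  if (nrow(object@binary) == 0L) stop("empty detection matrix")
  detected <- rowSums(object@binary == 1L, na.rm = TRUE) > 0
  mean(detected)
})

setMethod("ladderTable", "ModelLadder", function(object) object@table)
setMethod("retainedFits", "ModelLadder",
          function(object) object@fits[object@retained])

#' @describeIn accessors model label like `"psi(one), p(.)"`
#' @export
setGeneric("modelLabel", function(object) standardGeneric("modelLabel"))

setMethod("modelLabel", "OccuModelSpec", function(object) {
  lab <- function(x) if (length(x)) paste(x, collapse = ", ") else "."
  sprintf("psi(%s), p(%s)", lab(object@psiCovariates), lab(object@pCovariates))
})
setMethod("modelLabel", "OccupancyFit", function(object) modelLabel(object@spec))

setMethod("show", "DetectionMatrix", function(object) {
  nrep <- rowSums(!is.na(object@states))
  cat(sprintf("DetectionMatrix: %s, %d sites, %d-%d replicates/site\n",
              object@species, nrow(object@states), min(nrep), max(nrep)))
  cat(sprintf("  naive occupancy: %.2f\n", naiveOccupancy(object)))
})

setMethod("show", "OccuModelSpec", function(object) {
  cat("OccuModelSpec:", modelLabel(object), "\n")
})

setMethod("show", "OccupancyFit", function(object) {
  cat(sprintf("OccupancyFit %s  [%s]\n", modelLabel(object),
              if (object@converged) "converged" else "NOT converged"))
  cat(sprintf("  logLik %.3f  K %d  n %d\n",
              object@logLik, object@K, object@nSites))
  est <- c(object@betaPsi, object@betaP)
  se <- c(object@sePsi, object@seP)
  for (i in seq_along(est))
    cat(sprintf("  %-28s %8.3f (%s)\n", names(est)[i], est[i],
                ifelse(is.na(se[i]), "NA", sprintf("%.3f", se[i]))))
})

setMethod("show", "FalsePositiveFit", function(object) {
  cat(sprintf("FalsePositiveFit  [%s]\n",
              if (object@converged) "converged" else "NOT converged"))
  cat(sprintf("  psi %.3f  p11 %.3f  p10 %.4f  b %.3f\n",
              object@psi, object@p11, object@p10, object@b))
  bf <- names(object@boundaryFlags)[object@boundaryFlags]
  if (length(bf)) cat("  boundary:", paste(bf, collapse = ", "), "\n")
})

setMethod("show", "ModelLadder", function(object) {
  cat(sprintf("ModelLadder: %d models, c-hat %.3f, n %d, %d retained (d<=2)\n",
              nrow(object@table), object@cHat, object@nSites,
              length(object@retained)))
  print(format(object@table, digits = 4), row.names = FALSE)
})

setMethod("show", "AveragedSurface", function(object) {
  inc <- !object@surface$excluded
  cat(sprintf("AveragedSurface: %d grids (%d excluded), district mean psi %.2f (SE %.2f)\n",
              nrow(object@surface), sum(!inc),
              object@districtMean, object@districtSE))
})
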