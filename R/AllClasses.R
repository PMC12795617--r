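#' @import methods
#' @importFrom stats cor sd optim optimHess plogis qlogis rbinom rnorm runif
#'   rgamma quantile setNames complete.cases qnorm pnorm
#' @importFrom utils read.csv write.csv combn
NULL

#' Focal species recognised by the pipeline
#'
#' Five large mammals surveyed through key-informant interviews. Leopard and
#' wolf carry a paired look-alike image (tiger and jackal respectively) in the
#' identification protocol; the other three do not.
#' @export
FOCAL_SPECIES <- c("leopard", "wolf", "hyena", "sloth_bear", "blackbuck")

#' Detection-history matrix for one species
#'
#' Holds the site-by-replicate detection states for one focal species over a
#' grid of 5 x 5 km cells, together with the conservative binary collapse and
#' the replicate-level detection covariates. States are coded 0 (non-detection),
#' 1 (uncertain detection), 2 (certain detection); replicates a respondent
#' failed the identification test for are `NA` (missing). The binary layer
#' recodes state 2 as 1 and states 0/1 as 0, so that only certain detections
#' survive into the single-season occupancy likelihood.
#'
#' @slot species character scalar, one of [FOCAL_SPECIES].
#' @slot states integer matrix, sites x max replicates, values in
#'   `{0, 1, 2, NA}`; trailing `NA`s pad ragged replicate counts.
#' @slot binary integer matrix of the same shape over `{0, 1, NA}`.
#' @slot siteIDs character vector of grid-cell identifiers (rownames).
#' @slot detCovariates named list of numeric matrices (same shape as
#'   `states`) with per-replicate detection covariates, at least
#'   `grid_covered` (1 if the respondent covered all four sub-grids, else 0)
#'   and `years_experience`.
#' @export
setClass("DetectionMatrix",
  representation(
    species = "character",
    states = "matrix",
    binary = "matrix",
    siteIDs = "character",
    detCovariates = "list"
  )
)

setValidity("DetectionMatrix", function(object) {
  msgs <- character()
  if (length(object@species) != 1L)
    msgs <- c(msgs, "species must be a single string")
  st <- object@states
  bn <- object@binary
  if (!identical(dim(st), dim(bn)))
    msgs <- c(msgs, "states and binary must have identical dimensions")
  if (nrow(st) != length(object@siteIDs))
    msgs <- c(msgs, "siteIDs length must equal number of rows")
  ok <- st %in% c(0L, 1L, 2L, NA)
  if (!all(ok)) msgs <- c(msgs, "states must lie in {0,1,2,NA}")
  # collapse rule: binary 1 iff state 2; 0 iff state in {0,1}; NA propagates
  exp_bin <- ifelse(is.na(st), NA_integer_, ifelse(st == 2L, 1L, 0L))
  if (!identical(as.integer(bn), as.integer(exp_bin)))
    msgs <- c(msgs, "binary layer inconsistent with the collapse rule")
  if (any(rowSums(!is.na(st)) < 1L))
    msgs <- c(msgs, "every site needs at least one usable replicate")
  for (nm in names(object@detCovariates)) {
    if (!identical(dim(object@detCovariates[[nm]]), dim(st)))
      msgs <- c(msgs, sprintf("detection covariate '%s' has wrong shape", nm))
  }
  if (length(msgs)) msgs else TRUE
})

#' Model specification: covariate lists for occupancy and detection
#'
#' Names the z-scored site covariates entering the occupancy (psi) linear
#' predictor and the covariates (site- or replicate-level) entering the
#' detection (p) linear predictor, both on the logit link. Empty lists give
#' the intercept-only structures written `psi(.)` and `p(.)`.
#'
#' @slot psiCovariates character vector (possibly empty).
#' @slot pCovariates character vector (possibly empty).
#' @export
setClass("OccuModelSpec",
  representation(psiCovariates = "character", pCovariates = "character")
)

#' Construct an [OccuModelSpec-class]
#'
#' @param psi character vector of occupancy covariate names (default none).
#' @param p character vector of detection covariate names (default none).
#' @return An [OccuModelSpec-class] object.
#' @examples
#' occuModelSpec(psi = "one", p = "double_triple")
#' @export
occuModelSpec <- function(psi = character(), p = character()) {
  new("OccuModelSpec",
      psiCovariates = as.character(psi), pCovariates = as.character(p))
}

#' Fitted single-season occupancy model
#'
#' Result of [fitOccupancy()]: maximum-likelihood estimates of the logit-scale
#' coefficients for occupancy and detection, their standard errors from the
#' inverse observed information, and convergence diagnostics. `K` is the
#' parameter count used in information-criterion ladders: the number of
#' estimated coefficients plus one slot for the variance-inflation factor
#' c-hat, matching the convention of overdispersion-adjusted QAICc tables
#' (a null model with two coefficients has K = 3).
#'
#' @slot spec the [OccuModelSpec-class] fitted.
#' @slot betaPsi,betaP named numeric vectors of estimates (intercept first).
#' @slot sePsi,seP standard errors (NA when the Hessian is not
#'   positive-definite).
#' @slot vcov full variance-covariance matrix of `c(betaPsi, betaP)`.
#' @slot logLik maximised log-likelihood.
#' @slot nParams number of estimated coefficients.
#' @slot K `nParams + 1` (variance-inflation slot).
#' @slot nSites number of sites contributing to the likelihood.
#' @slot converged logical.
#' @slot hessianPD logical, observed information positive-definite.
#' @slot maxGradNorm max-norm of the numerical gradient at the optimum.
#' @slot cHat overdispersion factor applied downstream (NA until set).
#' @export
setClass("OccupancyFit",
  representation(
    spec = "OccuModelSpec",
    betaPsi = "numeric", betaP = "numeric",
    sePsi = "numeric", seP = "numeric",
    vcov = "matrix",
    logLik = "numeric", nParams = "integer", K = "integer",
    nSites = "integer", converged = "logical", hessianPD = "logical",
    maxGradNorm = "numeric", cHat = "numeric"
  )
)

setValidity("OccupancyFit", function(object) {
  msgs <- character()
  if (object@K != object@nParams + 1L)
    msgs <- c(msgs, "K must equal nParams + 1")
  if (isTRUE(object@hessianPD) && any(!is.na(object@sePsi) & object@sePsi <= 0))
    msgs <- c(msgs, "SEs must be positive when the Hessian is PD")
  if (length(msgs)) msgs else TRUE
})

#' Fitted multi-state false-positive occupancy model
#'
#' Diagnostic three-state model in which occupied sites yield certain
#' detections (state 2) with probability `p11 * b` and uncertain detections
#' (state 1) with probability `p11 * (1 - b)`, while unoccupied sites yield
#' uncertain false positives with probability `p10` and never a certain
#' detection. Boundary flags mark estimates within tolerance of 0 or 1 —
#' the typical failure mode when uncertain detections are sparse.
#'
#' @slot psi,p11,p10,b point estimates (probability scale, intercept-only
#'   psi/p11 reported at covariate means when covariates are present).
#' @slot betaPsi,betaP11 logit-scale coefficient vectors.
#' @slot se named numeric vector of logit-scale standard errors.
#' @slot logLik,nParams,nSites,converged as in [OccupancyFit-class].
#' @slot boundaryFlags named logical vector over `c("psi","p11","p10","b")`.
#' @slot hessianCondition condition number of the observed information.
#' @export
setClass("FalsePositiveFit",
  representation(
    psi = "numeric", p11 = "numeric", p10 = "numeric", b = "numeric",
    betaPsi = "numeric", betaP11 = "numeric",
    se = "numeric", logLik = "numeric", nParams = "integer",
    nSites = "integer", converged = "logical",
    boundaryFlags = "logical", hessianCondition = "numeric"
  )
)

setValidity("FalsePositiveFit", function(object) {
  pr <- c(object@psi, object@p11, object@p10, object@b)
  if (any(pr < 0 | pr > 1)) "probabilities must lie in [0,1]" else TRUE
})

#' QAICc model ladder
#'
#' A ranked candidate set: each entry carries the model label, K, QAICc,
#' delta-QAICc from the top model, Akaike weight, cumulative weight and
#' quasi-log-likelihood (logLik / c-hat). Models with delta <= 2 form the
#' retained set used for model averaging.
#'
#' @slot table data.frame with columns `model`, `K`, `QAICc`, `dQAICc`,
#'   `weight`, `cumWeight`, `quasiLogLik`, sorted ascending by QAICc.
#' @slot fits list of the corresponding [OccupancyFit-class] objects, in
#'   ladder order.
#' @slot cHat overdispersion factor used.
#' @slot nSites effective sample size used in the small-sample correction.
#' @slot retained integer indices (into ladder order) with dQAICc <= 2.
#' @export
setClass("ModelLadder",
  representation(
    table = "data.frame", fits = "list", cHat = "numeric",
    nSites = "integer", retained = "integer"
  )
)

setValidity("ModelLadder", function(object) {
  msgs <- character()
  tb <- object@table
  if (nrow(tb)) {
    if (abs(sum(tb$weight) - 1) > 1e-9)
      msgs <- c(msgs, "weights must sum to 1")
    if (is.unsorted(tb$QAICc)) msgs <- c(msgs, "table must be sorted by QAICc")
    if (abs(tb$dQAICc[1]) > 1e-12)
      msgs <- c(msgs, "top entry must have dQAICc = 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' Model-averaged occupancy surface
#'
#' Per-grid model-averaged occupancy probabilities over the retained
#' (delta-QAICc <= 2) model set, with unconditional standard errors, the grids
#' excluded by the waterbody rule (more than 3/4 of the cell under water), and
#' the district-wide mean.
#'
#' @slot surface data.frame with columns `grid_id`, `psi`, `se`, `excluded`,
#'   `reason`.
#' @slot districtMean mean of per-grid psi over included grids.
#' @slot districtSE delta-method SE of that mean (beta covariance propagated
#'   through the average of inverse-logits, model-averaged).
#' @slot meanOfSEs mean of the per-grid SEs (reported alongside, see the
#'   methods vignette).
#' @slot weights renormalised weights of the retained models.
#' @export
setClass("AveragedSurface",
  representation(
    surface = "data.frame", districtMean = "numeric", districtSE = "numeric",
    meanOfSEs = "numeric", weights = "numeric"
  )
)

setValidity("AveragedSurface", function(object) {
  ps <- object@surface$psi[!object@surface$excluded]
  if (any(ps < 0 | ps > 1, na.rm = TRUE)) "psi must lie in [0,1]" else TRUE
})
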