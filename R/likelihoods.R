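#' Design matrices for an occupancy model
#'
#' Resolves a model specification against a site-covariate table and the
#' replicate-level covariate matrices of a detection matrix. Detection
#' covariates are looked up first among the replicate-level matrices
#' (`grid_covered`, `years_experience`, ...), then among the site covariates
#' (habitat covariates acting on detection are constant across replicates).
#'
#' @param dm [DetectionMatrix-class].
#' @param siteCov data.frame keyed by `grid_id` with z-scored site covariates.
#' @param spec [OccuModelSpec-class].
#' @return list `Xpsi` (n x (1+k_psi)), `pCovs` (list of n x J matrices, no
#'   intercept), `parNames`.
#' @keywords internal
occuDesign <- function(dm, siteCov, spec) {
  ids <- siteIDs(dm)
  idx <- match(ids, siteCov$grid_id)
  if (anyNA(idx)) stop("site covariates missing for grids: ",
                       paste(ids[is.na(idx)], collapse = ", "))
  n <- length(ids)
  J <- ncol(detectionStates(dm))
  Xpsi <- matrix(1, n, 1 + length(spec@psiCovariates))
  if (length(spec@psiCovariates)) {
    for (k in seq_along(spec@psiCovariates)) {
      nm <- spec@psiCovariates[k]
      if (is.null(siteCov[[nm]])) stop("unknown psi covariate '", nm, "'")
      v <- siteCov[[nm]][idx]
      if (any(!is.finite(v))) stop("non-finite values in psi covariate '", nm, "'")
      Xpsi[, k + 1] <- v
    }
  }
  dcv <- detectionCovariates(dm)
  pCovs <- list()
  for (nm in spec@pCovariates) {
    if (!is.null(dcv[[nm]])) {
      pCovs[[nm]] <- dcv[[nm]]
    } else if (!is.null(siteCov[[nm]])) {
      v <- siteCov[[nm]][idx]
      if (any(!is.finite(v))) stop("non-finite values in p covariate '", nm, "'")
      pCovs[[nm]] <- matrix(v, n, J)
    } else stop("unknown p covariate '", nm, "'")
  }
  parNames <- c("psi_(Intercept)",
                if (length(spec@psiCovariates))
                  paste0("psi_", spec@psiCovariates),
                "p_(Intercept)",
                if (length(spec@pCovariates)) paste0("p_", spec@pCovariates))
  list(Xpsi = Xpsi, pCovs = pCovs, parNames = parNames)
}

# logit-scale linear predictor for detection as an n x J matrix
pLinpred <- function(par, kpsi, pCovs, n, J) {
  eta <- matrix(par[kpsi + 1], n, J)
  if (length(pCovs))
    for (k in seq_along(pCovs))
      eta <- eta + par[kpsi + 1 + k] * pCovs[[k]]
  eta
}

#' Negative log-likelihood of the single-season occupancy model
#'
#' Binary detection data over `{0,1,NA}`. For site i with detections the
#' contribution is `psi_i * prod_j p_ij^y (1-p_ij)^(1-y)`; with an all-zero
#' history the unoccupied state is added: `psi_i * prod_j (1-p_ij) +
#' (1-psi_i)`. Missing replicates contribute factor 1 (skipped, never
#' imputed). Both parameters are inverse-logits of linear predictors.
#'
#' @param par numeric vector: psi intercept, psi slopes, p intercept,
#'   p slopes (in `spec` order).
#' @param dm [DetectionMatrix-class] (the binary layer is used).
#' @param siteCov site-covariate data.frame.
#' @param spec [OccuModelSpec-class].
#' @param design optional precomputed [occuDesign()] (internal fast path).
#' @return scalar negative log-likelihood.
#' @examples
#' # psi = p = 0.5, single site with history (1, 0): L = 0.125
#' @export
occNegLogLik <- function(par, dm, siteCov, spec, design = NULL) {
  if (is.null(design)) design <- occuDesign(dm, siteCov, spec)
  Y <- detectionBinary(dm)
  kpsi <- ncol(design$Xpsi)
  stopifnot(length(par) == kpsi + 1 + length(design$pCovs))
  psi <- plogis(drop(design$Xpsi %*% par[seq_len(kpsi)]))
  eta <- pLinpred(par, kpsi, design$pCovs, nrow(Y), ncol(Y))
  p <- plogis(eta)
  obs <- !is.na(Y)
  lp <- matrix(0, nrow(Y), ncol(Y))
  lp[obs] <- ifelse(Y[obs] == 1L, log(p[obs]), log1p(-p[obs]))
  condLog <- rowSums(lp)
  anyDet <- rowSums(Y == 1L, na.rm = TRUE) > 0
  L <- psi * exp(condLog) + (1 - psi) * as.numeric(!anyDet)
  L <- pmax(L, .Machine$double.xmin)
  -sum(log(L))
}

#' Negative log-likelihood of the multi-state false-positive model
#'
#' Three-state data over `{0,1,2,NA}`. Occupied sites emit state 2 with
#' probability `p11 * b`, state 1 with `p11 * (1-b)`, state 0 with
#' `1 - p11`; unoccupied sites emit state 1 with probability `p10`, state 0
#' with `1 - p10` and never state 2, so a certain detection forces the
#' occupied branch. `psi` and `p11` are logit-linear in covariates; `p10`
#' and `b` are scalar logits.
#'
#' @param par vector: psi block, p11 block (as in [occNegLogLik()]), then
#'   `logit(p10)`, `logit(b)`.
#' @param dm [DetectionMatrix-class] (three-state layer).
#' @param siteCov,spec,design as in [occNegLogLik()].
#' @return scalar negative log-likelihood.
#' @export
fpNegLogLik <- function(par, dm, siteCov, spec, design = NULL) {
  if (is.null(design)) design <- occuDesign(dm, siteCov, spec)
  S <- detectionStates(dm)
  kpsi <- ncol(design$Xpsi)
  kp <- 1 + length(design$pCovs)
  stopifnot(length(par) == kpsi + kp + 2)
  psi <- plogis(drop(design$Xpsi %*% par[seq_len(kpsi)]))
  p11 <- plogis(pLinpred(par, kpsi, design$pCovs, nrow(S), ncol(S)))
  p10 <- plogis(par[kpsi + kp + 1])
  b <- plogis(par[kpsi + kp + 2])
  obs <- !is.na(S)
  locc <- lunocc <- matrix(0, nrow(S), ncol(S))
  nobs <- sum(obs)
  po <- cbind(1 - p11[obs], p11[obs] * (1 - b), p11[obs] * b)
  pu <- cbind(rep(1 - p10, nobs), rep(p10, nobs), rep(0, nobs))
  sel <- cbind(seq_len(nobs), S[obs] + 1L)
  locc[obs] <- log(pmax(po[sel], .Machine$double.xmin))
  lunocc[obs] <- log(pmax(pu[sel], .Machine$double.xmin))
  # a state-2 record zeroes the unoccupied branch
  hasCertain <- rowSums(S == 2L, na.rm = TRUE) > 0
  Lun <- exp(rowSums(lunocc))
  Lun[hasCertain] <- 0
  L <- psi * exp(rowSums(locc)) + (1 - psi) * Lun
  L <- pmax(L, .Machine$double.xmin)
  -sum(log(L))
}
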