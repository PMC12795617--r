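# central-difference numerical gradient
numGrad <- function(fn, par, eps = 1e-6) {
  g <- numeric(length(par))
  for (i in seq_along(par)) {
    h <- eps * max(1, abs(par[i]))
    up <- par; up[i] <- up[i] + h
    dn <- par; dn[i] <- dn[i] - h
    g[i] <- (fn(up) - fn(dn)) / (2 * h)
  }
  g
}

# quasi-Newton minimisation from several jittered starts; returns the best
# finite optimum with Hessian-based diagnostics
multiStartOptim <- function(fn, npar, starts, seed, gradTol) {
  set.seed(seed)
  start_list <- c(list(rep(0, npar)),
                  lapply(seq_len(max(0, starts - 1)),
                         function(i) rnorm(npar, 0, 1)))
  best <- NULL
  for (s in start_list) {
    res <- tryCatch(
      optim(s, fn, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) next
    if (is.null(best) || res$value < best$value - 1e-10) best <- res
  }
  if (is.null(best))
    return(list(ok = FALSE, par = rep(NA_real_, npar), value = NA_real_,
                se = rep(NA_real_, npar), vcov = matrix(NA_real_, npar, npar),
                hessianPD = FALSE, maxGrad = Inf, condition = Inf))
  # Newton polish: BFGS stops on relative likelihood change, which can leave
  # the gradient above tolerance on badly scaled covariates
  for (it in 1:5) {
    g <- numGrad(fn, best$par)
    if (max(abs(g)) <= gradTol / 10) break
    Hp <- tryCatch(optimHess(best$par, fn), error = function(e) NULL)
    if (is.null(Hp)) break
    step <- tryCatch(solve(Hp, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    moved <- FALSE
    for (sc in c(1, 0.5, 0.25, 0.1)) {
      cand <- best$par - sc * step
      v <- fn(cand)
      if (is.finite(v) && v <= best$value + 1e-12) {
        best$par <- cand; best$value <- v; moved <- TRUE; break
      }
    }
    if (!moved) break
  }
  H <- tryCatch(optimHess(best$par, fn), error = function(e) NULL)
  se <- rep(NA_real_, npar)
  vc <- matrix(NA_real_, npar, npar)
  pd <- FALSE
  cond <- Inf
  if (!is.null(H) && all(is.finite(H))) {
    ch <- tryCatch(chol(H), error = function(e) NULL)
    if (!is.null(ch)) {
      pd <- TRUE
      vc <- chol2inv(ch)
      se <- sqrt(pmax(diag(vc), 0))
      ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
      cond <- max(ev) / max(min(ev), .Machine$double.xmin)
    }
  }
  g <- numGrad(fn, best$par)
  list(ok = TRUE, par = best$par, value = best$value, se = se, vcov = vc,
       hessianPD = pd, maxGrad = max(abs(g)),
       converged = pd && max(abs(g)) <= gradTol, condition = cond)
}

#' Fit a single-season occupancy model by maximum likelihood
#'
#' Minimises [occNegLogLik()] with BFGS from multiple jittered starts
#' (deterministic given `seed`); standard errors come from the inverse
#' observed information. A fit is flagged non-converged — never an error —
#' when every start fails, the Hessian is not positive-definite, or the
#' gradient max-norm exceeds `gradTol`; downstream model selection excludes
#' such fits, mirroring the practice of dropping models with convergence
#' issues.
#'
#' @param dm [DetectionMatrix-class] (binary layer used).
#' @param siteCov z-scored site-covariate data.frame keyed by `grid_id`.
#' @param spec [OccuModelSpec-class] (default intercept-only).
#' @param starts number of optimisation starts (first is the origin).
#' @param seed integer seed for start jitter.
#' @param gradTol gradient max-norm convergence tolerance (finite-difference
#'   gradients; see the methods vignette for the choice).
#' @return an [OccupancyFit-class].
#' @export
fitOccupancy <- function(dm, siteCov = data.frame(grid_id = siteIDs(dm)),
                         spec = occuModelSpec(), starts = 10, seed = 1,
                         gradTol = 1e-4) {
  design <- occuDesign(dm, siteCov, spec)
  Y <- detectionBinary(dm)
  anyDet <- rowSums(Y == 1L, na.rm = TRUE) > 0
  if (all(anyDet) || !any(anyDet))
    warning("no contrast between detected and undetected sites; ",
            "estimates will sit on the boundary")
  fn <- function(p) occNegLogLik(p, dm, siteCov, spec, design = design)
  npar <- ncol(design$Xpsi) + 1 + length(design$pCovs)
  opt <- multiStartOptim(fn, npar, starts, seed, gradTol)
  kpsi <- ncol(design$Xpsi)
  nm <- design$parNames
  new("OccupancyFit",
      spec = spec,
      betaPsi = setNames(opt$par[seq_len(kpsi)], nm[seq_len(kpsi)]),
      betaP = setNames(opt$par[(kpsi + 1):npar], nm[(kpsi + 1):npar]),
      sePsi = setNames(opt$se[seq_len(kpsi)], nm[seq_len(kpsi)]),
      seP = setNames(opt$se[(kpsi + 1):npar], nm[(kpsi + 1):npar]),
      vcov = opt$vcov,
      logLik = if (opt$ok) -opt$value else NA_real_,
      nParams = as.integer(npar), K = as.integer(npar + 1L),
      nSites = nrow(Y),
      converged = isTRUE(opt$converged), hessianPD = opt$hessianPD,
      maxGradNorm = opt$maxGrad, cHat = NA_real_)
}

#' Fit the multi-state false-positive model
#'
#' Diagnostic estimator for the three-state data; reports boundary flags
#' (estimates within `boundaryTol` of 0 or 1 on the probability scale, where
#' SEs blow up) and the condition number of the observed information — the
#' signature of the practical non-identifiability that arises when uncertain
#' detections are rare.
#'
#' @inheritParams fitOccupancy
#' @param boundaryTol probability-scale distance to 0/1 that triggers a
#'   boundary flag.
#' @return a [FalsePositiveFit-class].
#' @export
fitFalsePositive <- function(dm, siteCov = data.frame(grid_id = siteIDs(dm)),
                             spec = occuModelSpec(), starts = 10, seed = 1,
                             gradTol = 1e-4, boundaryTol = 0.01) {
  design <- occuDesign(dm, siteCov, spec)
  fn <- function(p) fpNegLogLik(p, dm, siteCov, spec, design = design)
  kpsi <- ncol(design$Xpsi)
  kp <- 1 + length(design$pCovs)
  npar <- kpsi + kp + 2
  opt <- multiStartOptim(fn, npar, starts, seed, gradTol)
  par <- opt$par
  probs <- c(psi = unname(plogis(par[1])),
             p11 = unname(plogis(par[kpsi + 1])),
             p10 = unname(plogis(par[kpsi + kp + 1])),
             b = unname(plogis(par[kpsi + kp + 2])))
  flags <- probs < boundaryTol | probs > 1 - boundaryTol
  flags[is.na(flags)] <- TRUE
  nm <- c(design$parNames, "logit_p10", "logit_b")
  new("FalsePositiveFit",
      psi = probs[["psi"]], p11 = probs[["p11"]], p10 = probs[["p10"]],
      b = probs[["b"]],
      betaPsi = setNames(par[seq_len(kpsi)], nm[seq_len(kpsi)]),
      betaP11 = setNames(par[(kpsi + 1):(kpsi + kp)], nm[(kpsi + 1):(kpsi + kp)]),
      se = setNames(opt$se, nm),
      logLik = if (opt$ok) -opt$value else NA_real_,
      nParams = as.integer(npar), nSites = nSites(dm),
      converged = isTRUE(opt$converged),
      boundaryFlags = flags, hessianCondition = opt$condition)
}

#' Predict occupancy over grid cells
#'
#' Inverse-logit of the fitted linear predictor with delta-method standard
#' errors from the coefficient covariance. Covariates must be on the same
#' (z-scored) scale as at fitting time; values outside the training range
#' trigger an extrapolation warning, not an error.
#'
#' @param fit converged [OccupancyFit-class].
#' @param newdata data.frame with `grid_id` and the fit's psi covariates.
#' @param trainRange optional named list of `c(min, max)` per covariate used
#'   for the extrapolation warning.
#' @return data.frame `grid_id`, `psi`, `se`.
#' @export
predictPsi <- function(fit, newdata, trainRange = NULL) {
  if (!fit@converged)
    warning("predicting from a non-converged fit")
  covs <- fit@spec@psiCovariates
  X <- matrix(1, nrow(newdata), 1 + length(covs))
  for (k in seq_along(covs)) {
    v <- newdata[[covs[k]]]
    if (is.null(v)) stop("newdata lacks covariate '", covs[k], "'")
    X[, k + 1] <- v
    if (!is.null(trainRange[[covs[k]]])) {
      rg <- trainRange[[covs[k]]]
      if (any(v < rg[1] | v > rg[2]))
        warning("extrapolating beyond the training range of '", covs[k], "'")
    }
  }
  eta <- drop(X %*% fit@betaPsi)
  psi <- plogis(eta)
  kpsi <- length(fit@betaPsi)
  Vpsi <- fit@vcov[seq_len(kpsi), seq_len(kpsi), drop = FALSE]
  se <- rep(NA_real_, length(psi))
  if (all(is.finite(Vpsi))) {
    varEta <- rowSums((X %*% Vpsi) * X)
    se <- sqrt(pmax(varEta, 0)) * psi * (1 - psi)  # d plogis / d eta
  }
  data.frame(grid_id = newdata$grid_id, psi = psi, se = se)
}
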