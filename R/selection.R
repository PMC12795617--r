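#' Simplify a global model by the SE-versus-estimate rule
#'
#' Drops every covariate whose standard error is greater than or equal to the
#' absolute value of its estimate; intercepts are always kept. Applied to the
#' global additive model on one side (detection or occupancy) before building
#' the candidate set. When the global fit did not converge the step is
#' skipped with a warning and the full list is returned.
#'
#' @param fit [OccupancyFit-class] of the global model.
#' @param side `"psi"` or `"p"`.
#' @return character vector of retained covariate names.
#' @export
simplifyGlobal <- function(fit, side = c("psi", "p")) {
  side <- match.arg(side)
  covs <- if (side == "psi") fit@spec@psiCovariates else fit@spec@pCovariates
  if (!length(covs)) return(covs)
  if (!fit@converged) {
    warning("global model did not converge; simplification skipped")
    return(covs)
  }
  est <- if (side == "psi") fit@betaPsi else fit@betaP
  se <- if (side == "psi") fit@sePsi else fit@seP
  keep <- logical(length(covs))
  for (k in seq_along(covs)) {
    i <- k + 1  # skip intercept
    keep[k] <- is.finite(se[i]) && se[i] < abs(est[i])
  }
  covs[keep]
}

# simulate a binary detection matrix from a fitted model, preserving the
# design (missingness pattern and detection covariates)
simulateFromFit <- function(fit, dm, siteCov) {
  design <- occuDesign(dm, siteCov, fit@spec)
  Y <- detectionBinary(dm)
  n <- nrow(Y); J <- ncol(Y)
  par <- c(fit@betaPsi, fit@betaP)
  psi <- plogis(drop(design$Xpsi %*% par[seq_len(ncol(design$Xpsi))]))
  p <- plogis(pLinpred(par, ncol(design$Xpsi), design$pCovs, n, J))
  z <- rbinom(n, 1, psi)
  p[is.na(p)] <- 0  # padded cells beyond a site's replicates
  newY <- matrix(rbinom(n * J, 1, p * z), n, J)
  newY[is.na(Y)] <- NA_integer_
  st <- ifelse(is.na(newY), NA_integer_, newY * 2L)  # certain when detected
  new("DetectionMatrix", species = speciesName(dm),
      states = matrix(as.integer(st), n, J),
      binary = matrix(as.integer(newY), n, J),
      siteIDs = siteIDs(dm), detCovariates = detectionCovariates(dm))
}

# Pearson chi-square over detection-history cohorts (sites grouped by number
# of observed replicates); expected counts are summed site-level history
# probabilities under the fit
historyChiSq <- function(fit, dm, siteCov) {
  design <- occuDesign(dm, siteCov, fit@spec)
  Y <- detectionBinary(dm)
  par <- c(fit@betaPsi, fit@betaP)
  kpsi <- ncol(design$Xpsi)
  psi <- plogis(drop(design$Xpsi %*% par[seq_len(kpsi)]))
  p <- plogis(pLinpred(par, kpsi, design$pCovs, nrow(Y), ncol(Y)))
  nrep <- rowSums(!is.na(Y))
  chi2 <- 0
  for (k in sort(unique(nrep))) {
    idx <- which(nrep == k)
    obsKey <- apply(Y[idx, seq_len(k), drop = FALSE], 1, paste, collapse = "")
    pm <- p[idx, seq_len(k), drop = FALSE]
    usedE <- 0
    for (key in unique(obsKey)) {
      hh <- as.integer(strsplit(key, "")[[1]])
      O <- sum(obsKey == key)
      # P(h | site i) = psi * prod p^y (1-p)^(1-y) + (1-psi) * [h all zero]
      condP <- apply(pm, 1, function(pr)
        prod(ifelse(hh == 1, pr, 1 - pr)))
      E <- sum(psi[idx] * condP + (1 - psi[idx]) * as.numeric(all(hh == 0)))
      usedE <- usedE + E
      if (E > 1e-12) chi2 <- chi2 + (O - E)^2 / E
    }
    # pooled cell for the histories never observed in this cohort:
    # O = 0, E = n_k - sum(E over observed cells)
    chi2 <- chi2 + max(length(idx) - usedE, 0)
  }
  chi2
}

#' Parametric-bootstrap overdispersion factor (c-hat)
#'
#' Goodness-of-fit in the style of the detection-history Pearson chi-square
#' bootstrap: the observed statistic over history cohorts is compared with
#' its distribution under data simulated from the fitted model (each
#' bootstrap set is refit before evaluating the statistic). The ratio
#' `chi2_obs / mean(chi2_boot)` estimates the variance inflation; values
#' below 1 are floored at 1 (underdispersion is not credited). Deterministic
#' given `seed`.
#'
#' @param fit converged [OccupancyFit-class] (the simplified global model).
#' @param dm,siteCov data the fit was estimated on.
#' @param B number of bootstrap replicates (must be >= 1; 1000 by default,
#'   reduce for desk-scale runs).
#' @param seed integer seed.
#' @return list `cHat` (floored), `cHatRaw`, `chi2Obs`, `chi2Boot`.
#' @export
gofChat <- function(fit, dm, siteCov = data.frame(grid_id = siteIDs(dm)),
                    B = 1000, seed = 1) {
  if (B < 1) stop("B must be at least 1")
  Y <- detectionBinary(dm)
  keys <- apply(Y, 1, paste, collapse = "/")
  if (length(unique(keys)) < 2)
    stop("degenerate data: a single unique detection history")
  chi2Obs <- historyChiSq(fit, dm, siteCov)
  design <- occuDesign(dm, siteCov, fit@spec)
  startPar <- c(fit@betaPsi, fit@betaP)
  set.seed(seed)
  chi2Boot <- vapply(seq_len(B), function(b) {
    dmb <- simulateFromFit(fit, dm, siteCov)
    fn <- function(par) occNegLogLik(par, dmb, siteCov, fit@spec,
                                     design = design)
    res <- tryCatch(
      optim(startPar, fn, method = "BFGS",
            control = list(maxit = 300, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(res)) return(NA_real_)
    fb <- fit
    np <- length(fit@betaPsi)
    fb@betaPsi <- setNames(res$par[seq_len(np)], names(fit@betaPsi))
    fb@betaP <- setNames(res$par[-seq_len(np)], names(fit@betaP))
    historyChiSq(fb, dmb, siteCov)
  }, 0)
  chi2Boot <- chi2Boot[is.finite(chi2Boot)]
  if (!length(chi2Boot)) stop("all bootstrap refits failed")
  raw <- chi2Obs / mean(chi2Boot)
  list(cHat = max(1, raw), cHatRaw = raw, chi2Obs = chi2Obs,
       chi2Boot = chi2Boot)
}

#' Small-sample quasi-AIC
#'
#' `-2 * quasiLogLik + 2K + 2K(K+1)/(n - K - 1)` with the quasi-log-likelihood
#' `logLik / cHat`, K the number of estimated coefficients plus one slot for
#' the variance-inflation factor, and n the number of sites.
#'
#' @param quasiLogLik quasi-log-likelihood.
#' @param K parameter count including the c-hat slot.
#' @param n effective sample size (sites).
#' @return QAICc value.
#' @examples
#' qaicc(-31.59, 4, 119)  # 71.53
#' @export
qaicc <- function(quasiLogLik, K, n) {
  if (n <= K + 1) stop("effective sample size too small: n <= K + 1")
  -2 * quasiLogLik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Rank candidate fits into a QAICc ladder
#'
#' Excludes non-converged fits, computes QAICc under the shared c-hat, ranks,
#' and derives delta-QAICc, Akaike weights `exp(-d/2) / sum(exp(-d/2))`,
#' cumulative weights and the retained set (delta <= 2, inclusive).
#'
#' @param fits list of [OccupancyFit-class].
#' @param cHat overdispersion factor (>= 1).
#' @param n effective sample size (defaults to the fits' site count).
#' @return a [ModelLadder-class].
#' @export
buildLadder <- function(fits, cHat = 1, n = NULL) {
  conv <- vapply(fits, function(f) isTRUE(f@converged), TRUE)
  fits <- fits[conv]
  if (!length(fits)) stop("no converged fits to rank")
  if (is.null(n)) n <- fits[[1]]@nSites
  qll <- vapply(fits, function(f) f@logLik / cHat, 0)
  K <- vapply(fits, function(f) f@K, 0L)
  q <- mapply(qaicc, qll, K, MoreArgs = list(n = n))
  ord <- order(q)
  fits <- fits[ord]; q <- q[ord]; qll <- qll[ord]; K <- K[ord]
  d <- q - q[1]
  w <- exp(-d / 2); w <- w / sum(w)
  tb <- data.frame(
    model = vapply(fits, modelLabel, ""),
    K = K, QAICc = q, dQAICc = d, weight = w, cumWeight = cumsum(w),
    quasiLogLik = qll)
  fits <- lapply(fits, function(f) { f@cHat <- cHat; f })
  new("ModelLadder", table = tb, fits = fits, cHat = cHat,
      nSites = as.integer(n), retained = which(d <= 2.0))
}

#' Akaike weights from a delta column
#'
#' Reconstructs weights from delta-QAICc values alone, e.g. to check a
#' printed ladder.
#' @param delta numeric vector of delta-QAICc values.
#' @return weights summing to 1.
#' @export
akaikeWeights <- function(delta) {
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Enumerate the candidate model set
#'
#' All subsets of the eligible covariates (the null model included), minus
#' every subset containing a pair flagged by the collinearity screen.
#'
#' @param eligible character vector of covariate names.
#' @param flagged screen report from [correlationScreen()] (data.frame with
#'   columns `u`, `v`).
#' @return list of character vectors (first element: the empty/null set).
#' @export
candidateSet <- function(eligible, flagged = data.frame(u = character(),
                                                        v = character())) {
  subsets <- list(character())
  for (k in seq_along(eligible))
    subsets <- c(subsets, combn(eligible, k, simplify = FALSE))
  ok <- vapply(subsets, function(s) {
    if (length(s) < 2) return(TRUE)
    prs <- combn(s, 2)
    !any(vapply(seq_len(ncol(prs)), function(i)
      isIncompatible(prs[1, i], prs[2, i], flagged), TRUE))
  }, TRUE)
  subsets[ok]
}

# resolve a covariate menu against the screen: walk the priority order (menu
# order by default) and drop any covariate incompatible with one already kept
resolveMenu <- function(menu, flagged, priority = menu) {
  kept <- character()
  for (nm in priority) {
    if (!nm %in% menu) next
    clash <- any(vapply(kept, function(k) isIncompatible(nm, k, flagged), TRUE))
    if (!clash) kept <- c(kept, nm)
  }
  kept
}

#' Two-step model selection for detection then occupancy
#'
#' Stage 1 selects the detection structure with occupancy held at the null:
#' a global additive detection model is fitted, simplified by the
#' SE-versus-estimate rule, refitted, its bootstrap c-hat estimated, and all
#' covariate subsets ranked by QAICc. Stage 2 fixes the best detection
#' structure and repeats the procedure for occupancy. Collinear pairs never
#' enter one model; clashes inside the global model are resolved by a
#' priority order (menu order by default).
#'
#' @param dm [DetectionMatrix-class].
#' @param siteCov z-scored site covariates keyed by `grid_id`.
#' @param pMenu,psiMenu eligible covariate names for detection / occupancy.
#' @param flagged collinearity screen report.
#' @param B bootstrap replicates for c-hat (set `chat = "none"` to skip).
#' @param seed integer seed (fits and bootstrap).
#' @param chat `"bootstrap"` (default) or `"none"` (c-hat fixed at 1,
#'   i.e. AICc ranking).
#' @param priorityP,priorityPsi priority orders for collinearity resolution.
#' @param starts optimisation starts per fit.
#' @return list with `pLadder`, `psiLadder` ([ModelLadder-class]), `bestPSpec`,
#'   `cHat` (named, both stages), `eligibleP`, `eligiblePsi`.
#' @export
twoStepSelect <- function(dm, siteCov, pMenu, psiMenu,
                          flagged = data.frame(u = character(), v = character()),
                          B = 1000, seed = 1, chat = c("bootstrap", "none"),
                          priorityP = pMenu, priorityPsi = psiMenu,
                          starts = 5) {
  chat <- match.arg(chat)
  stage <- function(psiFixed, menu, priority, side, stageSeed) {
    menu <- resolveMenu(menu, flagged, priority)
    mkspec <- function(covs) {
      if (side == "p") occuModelSpec(psi = psiFixed$psi, p = covs)
      else occuModelSpec(psi = covs, p = psiFixed$p)
    }
    global <- fitOccupancy(dm, siteCov, mkspec(menu), starts = starts,
                           seed = stageSeed)
    eligible <- if (length(menu)) simplifyGlobal(global, side) else character()
    simpl <- if (identical(sort(eligible), sort(menu))) global
             else fitOccupancy(dm, siteCov, mkspec(eligible), starts = starts,
                               seed = stageSeed)
    ch <- 1
    if (chat == "bootstrap" && simpl@converged && length(eligible) >= 0) {
      ch <- tryCatch(
        gofChat(simpl, dm, siteCov, B = B, seed = stageSeed)$cHat,
        error = function(e) { warning("c-hat estimation failed: ",
                                      conditionMessage(e)); 1 })
    }
    cands <- candidateSet(eligible, flagged)
    fits <- lapply(cands, function(cv)
      fitOccupancy(dm, siteCov, mkspec(cv), starts = starts, seed = stageSeed))
    ladder <- buildLadder(fits, cHat = ch, n = nSites(dm))
    list(ladder = ladder, cHat = ch, eligible = eligible)
  }
  s1 <- stage(list(psi = character()), pMenu, priorityP, "p", seed)
  bestP <- s1$ladder@fits[[1]]@spec@pCovariates
  s2 <- stage(list(p = bestP), psiMenu, priorityPsi, "psi", seed + 1L)
  list(pLadder = s1$ladder, psiLadder = s2$ladder,
       bestPSpec = bestP,
       cHat = c(p = s1$cHat, psi = s2$cHat),
       eligibleP = s1$eligible, eligiblePsi = s2$eligible)
}

#' Model-averaged occupancy surface
#'
#' Averages per-grid occupancy predictions over the retained (delta-QAICc
#' <= 2) models with weights renormalised to sum to one. Grids with more
#' than three quarters of their area under water are excluded. Per-grid
#' standard errors are unconditional (within-model delta-method variance
#' plus between-model spread); the district mean is reported with a
#' delta-method SE propagated through the spatial average, alongside the
#' mean of per-grid SEs.
#'
#' @param ladder [ModelLadder-class].
#' @param covRows data.frame of all district grids with `grid_id`, the psi
#'   covariates (z-scored on the fitting scale) and optionally
#'   `water_fraction`.
#' @param waterThreshold exclusion threshold on `water_fraction`.
#' @return an [AveragedSurface-class].
#' @export
modelAverage <- function(ladder, covRows, waterThreshold = 0.75) {
  idx <- ladder@retained
  if (!length(idx)) stop("retained model set is empty")
  fits <- ladder@fits[idx]
  w <- ladder@table$weight[idx]
  w <- w / sum(w)
  preds <- lapply(fits, predictPsi, newdata = covRows)
  psiMat <- vapply(preds, function(p) p$psi, numeric(nrow(covRows)))
  seMat <- vapply(preds, function(p) p$se, numeric(nrow(covRows)))
  psiMat <- matrix(psiMat, nrow(covRows)); seMat <- matrix(seMat, nrow(covRows))
  psiBar <- drop(psiMat %*% w)
  seBar <- vapply(seq_len(nrow(covRows)), function(i)
    sum(w * sqrt(seMat[i, ]^2 + (psiMat[i, ] - psiBar[i])^2)), 0)
  wf <- covRows$water_fraction
  excluded <- if (is.null(wf)) rep(FALSE, nrow(covRows)) else wf > waterThreshold
  reason <- ifelse(excluded, "waterbody", "")
  inc <- !excluded
  districtMean <- mean(psiBar[inc])
  # delta-method variance of the spatial mean, per model, then combined
  meansPerModel <- colMeans(psiMat[inc, , drop = FALSE])
  varPerModel <- vapply(seq_along(fits), function(m) {
    fit <- fits[[m]]
    covs <- fit@spec@psiCovariates
    X <- matrix(1, sum(inc), 1 + length(covs))
    for (k in seq_along(covs)) X[, k + 1] <- covRows[[covs[k]]][inc]
    psi <- psiMat[inc, m]
    g <- colMeans(X * (psi * (1 - psi)))
    kp <- length(fit@betaPsi)
    V <- fit@vcov[seq_len(kp), seq_len(kp), drop = FALSE]
    if (all(is.finite(V))) drop(t(g) %*% V %*% g) else NA_real_
  }, 0)
  districtSE <- sum(w * sqrt(varPerModel + (meansPerModel - districtMean)^2))
  new("AveragedSurface",
      surface = data.frame(grid_id = covRows$grid_id, psi = psiBar,
                           se = seBar, excluded = excluded, reason = reason),
      districtMean = districtMean, districtSE = districtSE,
      meanOfSEs = mean(seBar[inc]), weights = w)
}
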