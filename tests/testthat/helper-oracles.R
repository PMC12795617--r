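# Test helpers: detection-matrix constructors and independent likelihood
# oracles. The oracles marginalise the latent occupancy state by explicit
# per-site enumeration and share no code with the package implementation.

makeDM <- function(Y, states = NULL, species = "hyena",
                   covered = NULL, exper = NULL) {
  Y <- matrix(as.integer(Y), nrow(Y), ncol(Y))
  if (is.null(states)) states <- ifelse(is.na(Y), NA_integer_, Y * 2L)
  states <- matrix(as.integer(states), nrow(Y), ncol(Y))
  n <- nrow(Y); J <- ncol(Y)
  if (is.null(covered)) covered <- matrix(1, n, J)
  if (is.null(exper)) exper <- matrix(0, n, J)
  new("DetectionMatrix", species = species, states = states,
      binary = Y, siteIDs = sprintf("S%04d", seq_len(n)),
      detCovariates = list(grid_covered = covered, years_experience = exper))
}

# explicit sum over z in {0,1} for the binary model
oracleOccNll <- function(psi, p, Y) {
  total <- 0
  for (i in seq_len(nrow(Y))) {
    Lz1 <- psi[i]
    Lz0 <- 1 - psi[i]
    for (j in seq_len(ncol(Y))) {
      y <- Y[i, j]
      if (is.na(y)) next
      Lz1 <- Lz1 * (if (y == 1) p[i, j] else 1 - p[i, j])
      Lz0 <- Lz0 * (if (y == 1) 0 else 1)
    }
    total <- total - log(Lz1 + Lz0)
  }
  total
}

# explicit sum over z in {0,1} for the three-state model
oracleFpNll <- function(psi, p11, p10, b, S) {
  total <- 0
  for (i in seq_len(nrow(S))) {
    Lz1 <- psi[i]
    Lz0 <- 1 - psi[i]
    for (j in seq_len(ncol(S))) {
      s <- S[i, j]
      if (is.na(s)) next
      Lz1 <- Lz1 * switch(as.character(s),
                          "0" = 1 - p11[i, j],
                          "1" = p11[i, j] * (1 - b),
                          "2" = p11[i, j] * b)
      Lz0 <- Lz0 * switch(as.character(s),
                          "0" = 1 - p10, "1" = p10, "2" = 0)
    }
    total <- total - log(Lz1 + Lz0)
  }
  total
}

# random small binary instance with intercept-only parameters
randomOccInstance <- function(seed) {
  set.seed(seed)
  n <- sample(3:8, 1)
  J <- sample(2:5, 1)
  Y <- matrix(rbinom(n * J, 1, 0.4), n, J)
  if (runif(1) < 0.5) Y[sample(length(Y), sample(1:3, 1))] <- NA
  Y[rowSums(!is.na(Y)) == 0, 1] <- 0L  # keep at least one usable replicate
  list(Y = Y, b0psi = rnorm(1), b0p = rnorm(1))
}

# build a minimal converged OccupancyFit by hand (for rule-level tests)
syntheticFit <- function(psiCovs = character(), pCovs = character(),
                         betaPsi = 0, betaP = 0, sePsi = 1, seP = 1,
                         logLik = -50, nSites = 119L, converged = TRUE) {
  spec <- occuModelSpec(psi = psiCovs, p = pCovs)
  np <- length(betaPsi) + length(betaP)
  nm <- c(paste0("psi_", c("(Intercept)", psiCovs)),
          paste0("p_", c("(Intercept)", pCovs)))
  new("OccupancyFit", spec = spec,
      betaPsi = setNames(betaPsi, nm[seq_along(betaPsi)]),
      betaP = setNames(betaP, nm[length(betaPsi) + seq_along(betaP)]),
      sePsi = setNames(sePsi, nm[seq_along(betaPsi)]),
      seP = setNames(seP, nm[length(betaPsi) + seq_along(betaP)]),
      vcov = diag(np) * 0.01,
      logLik = logLik, nParams = as.integer(np), K = as.integer(np + 1),
      nSites = nSites, converged = converged, hessianPD = TRUE,
      maxGradNorm = 0, cHat = NA_real_)
}

# species response constructed from first principles (independent of the
# generator's own response builder)
makeResponse <- function(species, state) {
  paired <- if (species %in% c("leopard", "wolf")) TRUE else logical()
  if (state == "FAILED")
    return(speciesResponse(species, paired_set_correct = paired,
                           hint_used = TRUE, focal_identified = FALSE))
  if (state == "0")
    return(speciesResponse(species, paired_set_correct = paired))
  speciesResponse(species, paired_set_correct = paired,
                  hint_used = (state == "1"), focal_identified = TRUE,
                  sighting_reported = TRUE, sighting_in_focal_grid = TRUE,
                  sighting_within_past_year = TRUE)
}

makeRecord <- function(id, grid, states, exper = 10, subs = 1:3) {
  responses <- lapply(names(states), function(sp) makeResponse(sp, states[[sp]]))
  names(responses) <- names(states)
  interviewRecord(id, grid, subs, exper, responses = responses)
}
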