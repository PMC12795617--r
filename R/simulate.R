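#' Simulation configuration
#'
#' Defaults mirror the study's scale: a district of 230 grid cells of
#' 5 x 5 km with 119 sampled in a checkerboard, 1-6 interview replicates per
#' sampled site, occupancy near 0.5 and per-replicate detection near 0.3 on
#' the logit scale, a high certainty probability and a rare uncertain
#' false-positive rate. Covariate fields are truncated Gaussians bounded by
#' the 25 km^2 cell area with a configurable pairwise correlation to exercise
#' the collinearity screen.
#'
#' @param n_district total grid cells in the district.
#' @param n_sampled sampled cells.
#' @param replicate_probs probability vector over 1..7 replicates per site.
#' @param beta_psi named numeric: `intercept` plus z-scored covariate effects
#'   on logit occupancy (names must match covariate columns).
#' @param alpha_p same for logit detection (replicate- or site-level names).
#' @param certainty P(recorded certain | true detection).
#' @param false_positive_rate per-replicate P(uncertain detection |
#'   unoccupied).
#' @param failure_rate per-response P(respondent fails the identification).
#' @param cov_correlation target Pearson correlation between `area_one` and
#'   `area_kharif` (must be in (-1, 1)).
#' @param seed integer seed.
#' @return a `simConfig` list.
#' @export
simConfig <- function(n_district = 230, n_sampled = 119,
                      replicate_probs = c(0.10, 0.20, 0.30, 0.25, 0.10, 0.05, 0),
                      beta_psi = c(intercept = 0, area_one = 1),
                      alpha_p = c(intercept = -0.85, years_experience = 0.5),
                      certainty = 0.9, false_positive_rate = 0.02,
                      failure_rate = 0.03, cov_correlation = 0.2,
                      seed = 1) {
  stopifnot(n_sampled >= 2, n_sampled <= n_district,
            length(replicate_probs) == 7,
            abs(sum(replicate_probs) - 1) < 1e-9,
            certainty >= 0, certainty <= 1,
            false_positive_rate >= 0, false_positive_rate <= 1,
            failure_rate >= 0, failure_rate <= 1)
  if (abs(cov_correlation) >= 1) stop("infeasible correlation target")
  structure(list(
    n_district = n_district, n_sampled = n_sampled,
    replicate_probs = replicate_probs, beta_psi = beta_psi,
    alpha_p = alpha_p, certainty = certainty,
    false_positive_rate = false_positive_rate, failure_rate = failure_rate,
    cov_correlation = cov_correlation, seed = seed
  ), class = "simConfig")
}

# bounded Gaussian field in [0, 25] km^2
boundedArea <- function(z, mu, sdv) pmin(pmax(mu + sdv * z, 0), 25)

#' Simulate the district landscape
#'
#' Generates per-grid land-cover areas (kharif, double/triple, open natural
#' ecosystem), road length, livestock biomass and water fractions for the
#' whole district, marks the sampled subset, z-scores against the full
#' district and runs the collinearity screen — the same objects the
#' covariate engine produces from real tables. `area_one` and `area_kharif`
#' share the configured correlation (Gaussian copula with mild truncation).
#'
#' @param cfg a [simConfig()].
#' @return list as from [buildCovariateTable()], plus `landcover` (raw).
#' @export
simulateLandscape <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_district
  r <- cfg$cov_correlation
  z1 <- rnorm(n)
  z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)
  landcover <- data.frame(
    grid_id = sprintf("G%03d", seq_len(n)),
    area_one = boundedArea(z1, 8, 3),
    area_kharif = boundedArea(z2, 10, 3),
    area_double_triple = boundedArea(rnorm(n), 6, 2.5),
    road_length = pmax(rnorm(n, 10, 4), 0),
    water_fraction = ifelse(runif(n) < 0.03, runif(n, 0.5, 1),
                            runif(n, 0, 0.2)),
    sampled = FALSE
  )
  odd <- seq(1, n, by = 2)  # alternate-grid (checkerboard) sampling
  sel <- odd[seq_len(min(length(odd), cfg$n_sampled))]
  landcover$sampled[sel] <- TRUE
  if (sum(landcover$sampled) < cfg$n_sampled) {
    need <- cfg$n_sampled - sum(landcover$sampled)
    landcover$sampled[which(!landcover$sampled)[seq_len(need)]] <- TRUE
  }
  villages <- data.frame(
    village_id = sprintf("V%03d", seq_len(n)),
    cow = rpoisLike(n, 120), buffalo = rpoisLike(n, 40),
    sheep = rpoisLike(n, 400), goat = rpoisLike(n, 250)
  )
  # each village overlaps its own grid and, half the time, the next one
  split <- runif(n) < 0.5
  frac <- ifelse(split, runif(n, 0.5, 0.9), 1)
  nxt <- c(seq_len(n)[-1], 1)
  overlaps <- rbind(
    data.frame(village_id = villages$village_id,
               grid_id = landcover$grid_id, fraction = frac),
    data.frame(village_id = villages$village_id[split],
               grid_id = landcover$grid_id[nxt[split]],
               fraction = 1 - frac[split])
  )
  biomass <- gridLivestockBiomass(villages, overlaps)
  out <- buildCovariateTable(landcover, biomass)
  out$landcover <- landcover
  out$villages <- villages
  out$overlaps <- overlaps
  out
}

# rounded overdispersed counts (negative-binomial-ish via gamma mixing)
rpoisLike <- function(n, mu) round(rgamma(n, shape = 4, rate = 4 / mu))

#' Simulate a key-informant interview survey
#'
#' Draws true occupancy states from the logit-linear model on the z-scored
#' landscape, then per replicate: a true detection with probability p
#' (occupied sites only), recorded certain with probability `certainty` and
#' uncertain otherwise; unoccupied sites yield an uncertain false positive
#' with the configured rate — never a certain one. Respondent covariates
#' (sub-grid coverage, herding experience) and identification failures are
#' generated per interview, and the interviews are emitted as
#' [interviewRecord()]s so the ingest path is exercised end to end.
#'
#' @param cfg a [simConfig()].
#' @param landscape result of [simulateLandscape()] (regenerated from `cfg`
#'   when omitted).
#' @param species focal species to label the records with.
#' @return list: `records` (interview records), `truth` (per-site psi, z,
#'   per-replicate p and states), `landscape`.
#' @export
simulateSurvey <- function(cfg, landscape = simulateLandscape(cfg),
                           species = "hyena") {
  set.seed(cfg$seed + 1L)
  cov <- landscape$covariates
  sampled <- cov[cov$sampled, , drop = FALSE]
  n <- nrow(sampled)
  bp <- cfg$beta_psi
  eta <- rep(bp[["intercept"]], n)
  for (nm in setdiff(names(bp), "intercept"))
    eta <- eta + bp[[nm]] * sampled[[nm]]
  psi <- plogis(eta)
  z <- rbinom(n, 1, psi)
  nreps <- sample(1:7, n, replace = TRUE, prob = cfg$replicate_probs)
  records <- list()
  truth <- list()
  rid <- 0
  for (i in seq_len(n)) {
    stateRow <- pRow <- numeric(nreps[i])
    for (j in seq_len(nreps[i])) {
      rid <- rid + 1
      exper <- round(runif(1, 2, 40))
      allFour <- runif(1) < 0.5
      subs <- if (allFour) 1:4 else sort(sample(1:4, 3))
      ap <- cfg$alpha_p
      etaP <- ap[["intercept"]]
      for (nm in setdiff(names(ap), "intercept")) {
        val <- switch(nm,
          years_experience = (exper - 20) / 12,  # roughly centred/scaled
          grid_covered = as.numeric(allFour),
          sampled[[nm]][i])
        etaP <- etaP + ap[[nm]] * val
      }
      p <- plogis(etaP)
      pRow[j] <- p
      failed <- runif(1) < cfg$failure_rate
      state <- if (z[i] == 1 && runif(1) < p) {
        if (runif(1) < cfg$certainty) 2L else 1L
      } else if (z[i] == 0 && runif(1) < cfg$false_positive_rate) 1L else 0L
      stateRow[j] <- if (failed) NA_integer_ else state
      resp <- stateToResponse(species, if (failed) "FAILED"
                              else as.character(state))
      responses <- list()
      responses[[species]] <- resp
      records[[rid]] <- interviewRecord(
        respondent_id = sprintf("R%05d", rid),
        focal_grid_id = sampled$grid_id[i],
        subgrids_covered = subs,
        years_experience = exper,
        responses = responses)
    }
    truth[[i]] <- list(grid_id = sampled$grid_id[i], psi = psi[i], z = z[i],
                       p = pRow, states = stateRow)
  }
  list(records = records, truth = truth, landscape = landscape,
       species = species)
}

# construct a response whose classification equals the requested state
stateToResponse <- function(species, state) {
  paired <- if (species %in% c("leopard", "wolf")) TRUE else logical()
  switch(state,
    "2" = speciesResponse(species, paired_set_correct = paired,
                          hint_used = FALSE, focal_identified = TRUE,
                          sighting_reported = TRUE,
                          sighting_in_focal_grid = TRUE,
                          sighting_within_past_year = TRUE),
    "1" = speciesResponse(species, paired_set_correct = paired,
                          hint_used = TRUE, focal_identified = TRUE,
                          sighting_reported = TRUE,
                          sighting_in_focal_grid = TRUE,
                          sighting_within_past_year = TRUE),
    "0" = speciesResponse(species, paired_set_correct = paired,
                          hint_used = FALSE, focal_identified = TRUE,
                          sighting_reported = FALSE),
    "FAILED" = speciesResponse(species, paired_set_correct = paired,
                               hint_used = TRUE, focal_identified = FALSE,
                               sighting_reported = FALSE))
}

#' Write simulated interviews to the standard interview file format
#'
#' @param survey result of [simulateSurvey()].
#' @param path output CSV path.
#' @export
writeInterviewFile <- function(survey, path) {
  rows <- lapply(survey$records, function(r) {
    base <- data.frame(
      respondent_id = r$respondent_id, focal_grid_id = r$focal_grid_id,
      subgrids_covered = paste(r$subgrids_covered, collapse = ";"),
      years_experience = r$years_experience, merged_pair = r$merged_pair)
    for (sp in names(r$responses)) {
      resp <- r$responses[[sp]]
      base[[paste0(sp, "_paired_correct")]] <-
        if (length(resp$paired_set_correct)) all(resp$paired_set_correct)
        else NA
      base[[paste0(sp, "_hint_used")]] <- resp$hint_used
      base[[paste0(sp, "_focal_identified")]] <- resp$focal_identified
      base[[paste0(sp, "_sighting_reported")]] <- resp$sighting_reported
      base[[paste0(sp, "_sighting_in_grid")]] <- resp$sighting_in_focal_grid
      base[[paste0(sp, "_sighting_past_year")]] <-
        resp$sighting_within_past_year
    }
    base
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Parameter-recovery experiment
#'
#' Repeatedly simulates a survey, builds the detection matrix through the
#' ingest path, fits the intercept-only occupancy model, and (optionally)
#' runs the two-step selection to measure how often the generating
#' covariates enter the retained sets. Reports bias, RMSE and Wald 95% CI
#' coverage for occupancy and detection.
#'
#' @param cfg a [simConfig()] template (its seed is replaced per replicate).
#' @param n_reps number of simulation replicates.
#' @param seed master seed.
#' @param select run [twoStepSelect()] per replicate (slower).
#' @param pMenu,psiMenu menus for the selection step.
#' @param B bootstrap replicates for c-hat when selecting.
#' @param chat c-hat mode passed to [twoStepSelect()].
#' @return list with `psi` / `p` summaries (truth, mean estimate, bias,
#'   rmse, coverage) and, when selecting, `selectionHits` (fraction of
#'   replicates whose retained occupancy set contains the generating
#'   covariates).
#' @export
recoveryExperiment <- function(cfg, n_reps = 200, seed = 1, select = FALSE,
                               pMenu = character(), psiMenu = character(),
                               B = 20, chat = "none") {
  psiHat <- pHat <- psiCov <- pCov <- psiTrue <- pTrue <-
    rep(NA_real_, n_reps)
  hits <- rep(NA, n_reps)
  for (r in seq_len(n_reps)) {
    cfg_r <- cfg
    cfg_r$seed <- seed + 7919L * r
    sv <- simulateSurvey(cfg_r)
    dm <- standardizeDetCovariates(
      suppressWarnings(buildDetectionMatrix(sv$records, sv$species)))
    cov <- sv$landscape$covariates
    # recovery target: mean occupancy and mean conditional detection prob.
    psiTrue[r] <- mean(vapply(sv$truth, function(t) t$psi, 0))
    pTrue[r] <- mean(unlist(lapply(sv$truth, function(t) t$p))) *
      cfg$certainty
    fit <- fitOccupancy(dm, cov, occuModelSpec(), starts = 3,
                        seed = cfg_r$seed)
    if (fit@converged) {
      psiHat[r] <- plogis(fit@betaPsi[[1]])
      pHat[r] <- plogis(fit@betaP[[1]])
      ciPsi <- plogis(fit@betaPsi[[1]] + c(-1.96, 1.96) * fit@sePsi[[1]])
      ciP <- plogis(fit@betaP[[1]] + c(-1.96, 1.96) * fit@seP[[1]])
      psiCov[r] <- psiTrue[r] >= ciPsi[1] && psiTrue[r] <= ciPsi[2]
      pCov[r] <- pTrue[r] >= ciP[1] && pTrue[r] <= ciP[2]
    }
    if (select) {
      sel <- tryCatch(
        twoStepSelect(dm, cov, pMenu, psiMenu,
                      flagged = sv$landscape$flagged, B = B,
                      seed = cfg_r$seed, chat = chat, starts = 3),
        error = function(e) NULL)
      genPsi <- setdiff(names(cfg$beta_psi), "intercept")
      genP <- intersect(setdiff(names(cfg$alpha_p), "intercept"), pMenu)
      hits[r] <- if (is.null(sel)) NA else {
        inRetained <- function(ladder, side, gen) {
          sets <- lapply(retainedFits(ladder), function(f)
            if (side == "psi") f@spec@psiCovariates else f@spec@pCovariates)
          all(vapply(gen, function(g)
            any(vapply(sets, function(s) g %in% s, TRUE)), TRUE))
        }
        inRetained(sel$psiLadder, "psi", genPsi) &&
          inRetained(sel$pLadder, "p", genP)
      }
    }
  }
  summ <- function(est, tru, cov) list(
    truth = mean(tru, na.rm = TRUE), estimate = mean(est, na.rm = TRUE),
    bias = mean(est - tru, na.rm = TRUE),
    rmse = sqrt(mean((est - tru)^2, na.rm = TRUE)),
    coverage = mean(cov, na.rm = TRUE),
    n_converged = sum(!is.na(est)))
  out <- list(psi = summ(psiHat, psiTrue, psiCov),
              p = summ(pHat, pTrue, pCov))
  if (select) out$selectionHits <- mean(hits, na.rm = TRUE)
  out
}
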