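test_that("global-model simplification drops covariates with SE >= |estimate|", {
  fit <- syntheticFit(psiCovs = c("one", "road", "kharif"),
                      betaPsi = c(0.5, 1.66, 0.85, 0.20),
                      sePsi = c(0.2, 1.58, 0.41, 0.50),
                      betaP = 0, seP = 0.1)
  # 1.66 (1.58) and 0.85 (0.41) retained; 0.20 (0.50) dropped
  expect_identical(simplifyGlobal(fit, "psi"), c("one", "road"))
  # negative estimates compare on absolute value
  fitn <- syntheticFit(psiCovs = "road", betaPsi = c(0, -1.20),
                       sePsi = c(0.1, 0.40), betaP = 0, seP = 0.1)
  expect_identical(simplifyGlobal(fitn, "psi"), "road")
  # exact tie SE == |beta| is dropped (inclusive rule)
  fitt <- syntheticFit(psiCovs = "x", betaPsi = c(0, 0.5),
                       sePsi = c(0.1, 0.5), betaP = 0, seP = 0.1)
  expect_identical(simplifyGlobal(fitt, "psi"), character(0))
  # non-converged global: skipped with a warning
  fitu <- syntheticFit(psiCovs = "x", betaPsi = c(0, 0.5),
                       sePsi = c(0.1, 0.2), betaP = 0, seP = 0.1,
                       converged = FALSE)
  expect_warning(out <- simplifyGlobal(fitu, "psi"), "skipped")
  expect_identical(out, "x")
})

test_that("small-sample QAICc formula and guards", {
  expect_equal(qaicc(-31.59, 4, 119), 71.53, tolerance = 1e-3)
  expect_equal(qaicc(-107.98, 6, 119), 228.71, tolerance = 1e-3)
  expect_equal(qaicc(0, 0, 100), 0)
  expect_error(qaicc(-10, 99, 100), "too small")
})

test_that("ladders rank, weight, and retain inclusively at delta = 2", {
  # three synthetic fits with controlled log-likelihoods
  mk <- function(ll, psiCovs = character()) {
    f <- syntheticFit(psiCovs = psiCovs,
                      betaPsi = rep(0, 1 + length(psiCovs)),
                      sePsi = rep(0.1, 1 + length(psiCovs)),
                      betaP = 0, seP = 0.1, logLik = ll, nSites = 119L)
    f
  }
  f0 <- mk(-50)                          # K = 3
  # choose logLik so the K=4 model lands exactly delta = 2 above f0
  q0 <- qaicc(-50, 3, 119)
  ll1 <- -(q0 + 2 - 2 * 4 - 2 * 4 * 5 / (119 - 5)) / 2
  f1 <- mk(ll1, "one")
  f2 <- mk(-60, "road")
  lad <- buildLadder(list(f2, f1, f0), cHat = 1)
  tb <- ladderTable(lad)
  expect_equal(tb$dQAICc[1], 0)
  expect_equal(sum(tb$weight), 1, tolerance = 1e-12)
  expect_false(is.unsorted(tb$QAICc))
  expect_equal(tb$cumWeight, cumsum(tb$weight))
  # delta exactly 2.0 is retained
  expect_equal(tb$dQAICc[2], 2, tolerance = 1e-9)
  expect_equal(lad@retained, 1:2)
  # single-model ladder has weight 1
  single <- buildLadder(list(f0), cHat = 1)
  expect_equal(ladderTable(single)$weight, 1)
  # non-converged fits are excluded before ranking
  bad <- mk(-10); bad@converged <- FALSE
  lad2 <- buildLadder(list(f0, bad), cHat = 1)
  expect_equal(nrow(ladderTable(lad2)), 1)
  expect_error(buildLadder(list(bad), cHat = 1), "no converged")
  # quasi-log-likelihood scales by c-hat
  ladc <- buildLadder(list(f0), cHat = 2)
  expect_equal(ladderTable(ladc)$quasiLogLik, -25)
})

test_that("weight reconstruction matches printed two-decimal ladders", {
  # deltas derived from the printed QAICc columns (the printed delta column
  # is rounded independently and can be off by 0.01)
  expect_equal(round(akaikeWeights(c(142.59, 144.05) - 142.59), 2),
               c(0.67, 0.33))
  expect_equal(round(akaikeWeights(c(143.47, 143.55, 147.18) - 143.47), 2),
               c(0.47, 0.45, 0.07))
  # removing a model and renormalising preserves weight ratios
  w <- akaikeWeights(c(0, 0.4, 1.3, 2.2))
  w2 <- akaikeWeights(c(0, 0.4, 1.3))
  expect_equal(w2[1] / w2[2], w[1] / w[2], tolerance = 1e-12)
})

test_that("candidate sets enumerate subsets and honour incompatibilities", {
  none <- data.frame(u = character(), v = character())
  expect_length(candidateSet(c("a", "b"), none), 4)
  flagAB <- data.frame(u = "a", v = "b")
  expect_length(candidateSet(c("a", "b"), flagAB), 3)
  cands <- candidateSet(c("a", "b", "c", "d"), flagAB)
  expect_length(cands, 12)
  # oracle: brute-force subset filter
  all16 <- unlist(lapply(0:4, function(k)
    combn(c("a", "b", "c", "d"), k, simplify = FALSE)), recursive = FALSE)
  keep <- Filter(function(s) !all(c("a", "b") %in% s), all16)
  expect_length(keep, 12)
  expect_setequal(vapply(cands, paste, "", collapse = "+"),
                  vapply(keep, paste, "", collapse = "+"))
})

test_that("bootstrap goodness-of-fit is calibrated under the model and detects clustering", {
  # self-consistency: raw c-hat centred near 1 when the model is true
  raws <- vapply(1:6, function(t) {
    set.seed(400 + t)
    n <- 119; J <- 4
    z <- rbinom(n, 1, 0.55)
    Y <- matrix(rbinom(n * J, 1, 0.4 * rep(z, J)), n, J)
    dm <- makeDM(Y)
    fit <- fitOccupancy(dm, data.frame(grid_id = siteIDs(dm)),
                        starts = 3, seed = 1)
    g <- gofChat(fit, dm, B = 40, seed = t)
    expect_gte(g$cHat, 1)        # floored
    g$cHatRaw
  }, 0)
  expect_gt(mean(raws), 0.7)
  expect_lt(mean(raws), 1.3)
  # within-site correlated replicates inflate c-hat
  infl <- vapply(1:6, function(t) {
    set.seed(500 + t)
    n <- 119; J <- 5
    z <- rbinom(n, 1, 0.55)
    first <- rbinom(n, 1, 0.45 * z)
    Y <- vapply(1:J, function(j)
      ifelse(runif(n) < 0.6, first, rbinom(n, 1, 0.45 * z)), numeric(n))
    dm <- makeDM(Y)
    fit <- fitOccupancy(dm, data.frame(grid_id = siteIDs(dm)),
                        starts = 3, seed = 1)
    gofChat(fit, dm, B = 40, seed = t)$cHatRaw
  }, 0)
  expect_gte(mean(infl > 1), 0.9)
  # guards
  dm1 <- makeDM(matrix(0L, 10, 2))
  fit1 <- suppressWarnings(fitOccupancy(dm1, data.frame(grid_id = siteIDs(dm1))))
  expect_error(gofChat(fit1, dm1, B = 0), "at least 1")
  expect_error(gofChat(fit1, dm1, B = 10), "degenerate")
})

test_that("model averaging is a convex combination with the waterbody rule", {
  fitA <- syntheticFit(betaPsi = qlogis(0.4), sePsi = 0.2, betaP = 0,
                       seP = 0.1, logLik = -50)
  fitB <- syntheticFit(betaPsi = qlogis(0.6), sePsi = 0.2, betaP = 0,
                       seP = 0.1, logLik = -50)
  lad <- buildLadder(list(fitA, fitB), cHat = 1)
  cov <- data.frame(grid_id = paste0("G", 1:6),
                    water_fraction = c(0, 0.2, 0.8, 0.74, 0.76, 1))
  avg <- modelAverage(lad, cov)
  # equal weights (identical QAICc): 0.5 * 0.4 + 0.5 * 0.6 = 0.5
  expect_equal(avg@surface$psi, rep(0.5, 6), tolerance = 1e-12)
  expect_identical(avg@surface$excluded, c(F, F, T, F, T, T))
  expect_equal(avg@districtMean, 0.5, tolerance = 1e-12)
  # single retained model: surface equals that model's predictions
  lad1 <- buildLadder(list(fitA), cHat = 1)
  avg1 <- modelAverage(lad1, cov)
  expect_equal(avg1@surface$psi, rep(0.4, 6), tolerance = 1e-12)
  # convexity against a direct recomputation
  fitC <- syntheticFit(psiCovs = "one", betaPsi = c(0, 1),
                       sePsi = c(0.1, 0.1), betaP = 0, seP = 0.1,
                       logLik = -49)
  cov$one <- seq(-2, 2, length.out = 6)
  lad2 <- buildLadder(list(fitA, fitC), cHat = 1)
  avg2 <- modelAverage(lad2, cov)
  w <- avg2@weights
  direct <- w[1] * predictPsi(lad2@fits[[1]], cov)$psi +
    w[2] * predictPsi(lad2@fits[[2]], cov)$psi
  expect_equal(avg2@surface$psi, direct, tolerance = 1e-12)
  lo <- pmin(0.4, plogis(cov$one)); hi <- pmax(0.4, plogis(cov$one))
  expect_true(all(avg2@surface$psi >= lo - 1e-12 &
                  avg2@surface$psi <= hi + 1e-12))
})

test_that("two-step selection with empty menus yields null-only ladders", {
  set.seed(9)
  n <- 40; J <- 3
  z <- rbinom(n, 1, 0.5)
  Y <- matrix(rbinom(n * J, 1, 0.5 * rep(z, J)), n, J)
  dm <- makeDM(Y)
  cov <- data.frame(grid_id = siteIDs(dm))
  sel <- twoStepSelect(dm, cov, pMenu = character(), psiMenu = character(),
                       chat = "none", starts = 2, seed = 1)
  expect_equal(nrow(ladderTable(sel$pLadder)), 1)
  expect_equal(nrow(ladderTable(sel$psiLadder)), 1)
  expect_identical(ladderTable(sel$psiLadder)$model, "psi(.), p(.)")
  expect_identical(sel$bestPSpec, character(0))
})
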