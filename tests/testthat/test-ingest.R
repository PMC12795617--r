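test_that("classification covers the full flag lattice with one outcome each", {
  # enumerate every consistent flag combination and check against a literal
  # restatement of the flowchart
  grid <- expand.grid(paired = c(TRUE, FALSE, NA), hint = c(TRUE, FALSE),
                      focal = c(TRUE, FALSE), rep = c(TRUE, FALSE),
                      ingrid = c(TRUE, FALSE), pastyr = c(TRUE, FALSE))
  # NA paired means "no paired set" (hyena-like species)
  grid <- grid[grid$rep | (!grid$ingrid & !grid$pastyr), ]
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    sp <- if (is.na(g$paired)) "sloth_bear" else "leopard"
    resp <- speciesResponse(
      sp, paired_set_correct = if (is.na(g$paired)) logical() else g$paired,
      hint_used = g$hint, focal_identified = g$focal,
      sighting_reported = g$rep, sighting_in_focal_grid = g$ingrid,
      sighting_within_past_year = g$pastyr)
    got <- classifyDetection(resp)
    expected <- if (!g$focal) "FAILED"
      else if (!(g$rep && g$ingrid && g$pastyr)) "0"
      else if ((is.na(g$paired) || g$paired) && !g$hint) "2"
      else "1"
    expect_identical(got, expected, info = paste(unlist(g), collapse = "/"))
  }
})

test_that("named flowchart cases classify as expected", {
  certain <- speciesResponse("leopard", paired_set_correct = TRUE,
    sighting_reported = TRUE, sighting_in_focal_grid = TRUE,
    sighting_within_past_year = TRUE)
  expect_identical(classifyDetection(certain), "2")
  hinted <- speciesResponse("leopard", paired_set_correct = TRUE,
    hint_used = TRUE, sighting_reported = TRUE,
    sighting_in_focal_grid = TRUE, sighting_within_past_year = TRUE)
  expect_identical(classifyDetection(hinted), "1")
  failed <- speciesResponse("leopard", paired_set_correct = TRUE,
    hint_used = TRUE, focal_identified = FALSE)
  expect_identical(classifyDetection(failed), "FAILED")
  # border sighting: reported but not inside the focal grid -> conservative 0
  border <- speciesResponse("leopard", paired_set_correct = TRUE,
    sighting_reported = TRUE, sighting_in_focal_grid = FALSE,
    sighting_within_past_year = TRUE)
  expect_identical(classifyDetection(border), "0")
  expect_identical(classifyDetection(speciesResponse("leopard",
    paired_set_correct = TRUE)), "0")
  # inconsistent flags are rejected at construction
  expect_error(speciesResponse("wolf", sighting_reported = FALSE,
                               sighting_in_focal_grid = TRUE),
               "inconsistent")
})

test_that("replicate validity follows the sub-grid coverage rule", {
  expect_identical(validateReplicate(c(1, 2, 3)), "independent")
  expect_identical(validateReplicate(1:4), "independent")
  expect_identical(validateReplicate(c(1, 2)), "needs_pairing")
  expect_identical(validateReplicate(3), "invalid")
  expect_identical(validateReplicate(integer()), "invalid")
})

test_that("merging paired interviews keeps max experience and max state, FAILED dominating", {
  a <- makeRecord("a", "G1", list(hyena = "0"), exper = 12, subs = c(1, 2))
  b <- makeRecord("b", "G1", list(hyena = "2"), exper = 30, subs = c(3, 4))
  m <- mergePaired(a, b)
  expect_equal(m$years_experience, 30)
  expect_true(m$merged_pair)
  expect_identical(classifyDetection(m$responses$hyena), "2")
  # full 4x4 state-pair enumeration against the rule table
  states <- c("0", "1", "2", "FAILED")
  for (s1 in states) for (s2 in states) {
    r1 <- makeRecord("x", "G9", list(hyena = s1), subs = c(1, 2))
    r2 <- makeRecord("y", "G9", list(hyena = s2), subs = c(3, 4))
    got <- classifyDetection(mergePaired(r1, r2)$responses$hyena)
    want <- if (s1 == "FAILED" || s2 == "FAILED") "FAILED"
      else as.character(max(as.integer(s1), as.integer(s2)))
    expect_identical(got, want, info = paste(s1, s2))
  }
  expect_error(mergePaired(a, makeRecord("c", "G2", list(hyena = "0"),
                                         subs = c(3, 4))), "different focal")
  expect_error(mergePaired(a, makeRecord("d", "G1", list(hyena = "0"),
                                         subs = c(1, 2))), "below three")
})

test_that("detection matrix assembly collapses, drops FAILED and failed sites", {
  recs <- list(
    makeRecord("r1", "G1", list(hyena = "2", wolf = "0")),
    makeRecord("r2", "G1", list(hyena = "1", wolf = "FAILED")),
    makeRecord("r3", "G1", list(hyena = "0", wolf = "0")),
    makeRecord("r4", "G2", list(hyena = "FAILED", wolf = "2")))
  dm <- suppressWarnings(buildDetectionMatrix(recs, "hyena"))
  expect_identical(unname(detectionStates(dm)["G1", ]), c(2L, 1L, 0L))
  expect_identical(unname(detectionBinary(dm)["G1", ]), c(1L, 0L, 0L))
  # G2: the only hyena replicate FAILED -> site dropped, with a warning
  expect_warning(buildDetectionMatrix(recs, "hyena"), "dropping 1 site")
  expect_identical(siteIDs(dm), "G1")
  # the same interviews still serve wolf at G2
  dmw <- buildDetectionMatrix(recs, "wolf")
  expect_setequal(siteIDs(dmw), c("G1", "G2"))
  expect_identical(unname(detectionBinary(dmw)["G2", 1]), 1L)
  # duplicate keys
  expect_error(buildDetectionMatrix(c(recs, recs[1]), "hyena"), "duplicate")
})

test_that("collapse rule: binary ones equal state twos; naive occupancy is permutation-invariant", {
  set.seed(31)
  for (t in 1:20) {
    n <- sample(5:15, 1); J <- sample(2:5, 1)
    st <- matrix(sample(c(0:2, NA), n * J, replace = TRUE,
                        prob = c(0.5, 0.15, 0.25, 0.1)), n, J)
    st[rowSums(!is.na(st)) == 0, 1] <- 0L
    bn <- ifelse(is.na(st), NA_integer_, as.integer(st == 2))
    dm <- makeDM(bn, states = st)
    expect_equal(sum(detectionBinary(dm) == 1, na.rm = TRUE),
                 sum(detectionStates(dm) == 2, na.rm = TRUE))
    # collapsing an already binary matrix changes nothing (idempotence)
    dm2 <- makeDM(detectionBinary(dm), states = detectionBinary(dm) * 2L)
    expect_identical(detectionBinary(dm2), detectionBinary(dm))
    # permute replicates within each site
    perm <- t(apply(cbind(st), 1, sample))
    bnp <- ifelse(is.na(perm), NA_integer_, as.integer(perm == 2))
    expect_equal(naiveOccupancy(makeDM(bnp, states = perm)),
                 naiveOccupancy(dm))
  }
  expect_equal(naiveOccupancy(makeDM(matrix(0L, 4, 2))), 0)
  expect_error(naiveOccupancy(makeDM(matrix(integer(), 0, 0))), "empty")
})

test_that("interview files round-trip through the ingest reader", {
  cfg <- simConfig(n_district = 30, n_sampled = 12, seed = 77)
  sv <- simulateSurvey(cfg, species = "wolf")
  path <- withr::local_tempfile(fileext = ".csv")
  writeInterviewFile(sv, path)
  recs <- readInterviews(path)
  expect_length(recs, length(sv$records))
  dmA <- suppressWarnings(buildDetectionMatrix(sv$records, "wolf"))
  dmB <- suppressWarnings(buildDetectionMatrix(recs, "wolf"))
  expect_identical(detectionStates(dmA), detectionStates(dmB))
  expect_identical(detectionCovariates(dmA), detectionCovariates(dmB))
})

test_that("generator truth log and matrix bookkeeping agree exactly", {
  cfg <- simConfig(n_district = 60, n_sampled = 25, seed = 5)
  sv <- simulateSurvey(cfg)
  dm <- suppressWarnings(buildDetectionMatrix(sv$records, "hyena"))
  for (t in sv$truth) {
    want <- t$states[!is.na(t$states)]
    if (!length(want)) {
      expect_false(t$grid_id %in% siteIDs(dm))
      next
    }
    got <- detectionStates(dm)[t$grid_id, ]
    expect_identical(unname(got[!is.na(got)]), as.integer(want),
                     info = t$grid_id)
  }
})

test_that("site summary reports replicate counts and rounded naive occupancy", {
  dm <- makeDM(rbind(c(1L, 0L, NA), c(0L, 0L, 0L), c(1L, 1L, 0L)))
  s <- siteSummary(dm)
  expect_equal(s$n_replicates, c(2, 3, 3))
  expect_equal(s$n_detections, c(1, 0, 2))
  expect_equal(attr(s, "naive_occupancy"), 0.67)
})
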