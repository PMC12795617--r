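test_that("livestock biomass is the configured mass-weighted head count", {
  bm <- livestockBiomass(c(cow = 0, buffalo = 0, sheep = 100, goat = 50),
                         masses = c(cow = 250, buffalo = 350, sheep = 30,
                                    goat = 25))
  expect_equal(unname(bm["small"]), 4250)
  expect_equal(unname(bm["large"]), 0)
  expect_equal(unname(livestockBiomass(c(cow = 0, buffalo = 0, sheep = 0,
                                         goat = 0))), c(0, 0))
  expect_error(livestockBiomass(c(cow = 1, buffalo = 1, sheep = 1, goat = 1),
                                masses = c(cow = 250)), "mass")
  # randomized counts match an independent dot-product recomputation
  set.seed(11)
  for (t in 1:20) {
    cnt <- setNames(sample(0:500, 4), c("cow", "buffalo", "sheep", "goat"))
    m <- setNames(runif(4, 20, 400), c("cow", "buffalo", "sheep", "goat"))
    bm <- livestockBiomass(cnt, m)
    expect_equal(unname(bm["small"]),
                 cnt[["sheep"]] * m[["sheep"]] + cnt[["goat"]] * m[["goat"]])
    expect_equal(unname(bm["large"]),
                 cnt[["cow"]] * m[["cow"]] + cnt[["buffalo"]] * m[["buffalo"]])
  }
})

test_that("apportionment is proportional and conserves the village total", {
  got <- apportionToGrids(4250, c(A = 0.4, B = 0.6))
  expect_equal(unname(got), c(1700, 2550))
  expect_equal(unname(apportionToGrids(99, c(G = 1))), 99)
  expect_error(apportionToGrids(1, c(A = 0.5, B = 0.6)), "sum to 1")
  expect_error(apportionToGrids(1, c(A = -0.1, B = 1.1)), "\\[0,1\\]")
})

test_that("grid biomass equals a brute-force village-by-grid double loop", {
  set.seed(21)
  nv <- 50; ng <- 12
  villages <- data.frame(village_id = paste0("V", 1:nv),
                         cow = sample(0:200, nv, TRUE),
                         buffalo = sample(0:80, nv, TRUE),
                         sheep = sample(0:600, nv, TRUE),
                         goat = sample(0:400, nv, TRUE))
  overlaps <- do.call(rbind, lapply(1:nv, function(v) {
    k <- sample(1:3, 1)
    g <- sample(ng, k)
    w <- runif(k); w <- w / sum(w)
    data.frame(village_id = paste0("V", v), grid_id = paste0("G", g),
               fraction = w)
  }))
  got <- gridLivestockBiomass(villages, overlaps)
  small <- large <- setNames(numeric(ng), paste0("G", 1:ng))
  for (i in seq_len(nrow(overlaps))) {
    v <- villages[villages$village_id == overlaps$village_id[i], ]
    small[overlaps$grid_id[i]] <- small[overlaps$grid_id[i]] +
      (v$sheep * 30 + v$goat * 25) * overlaps$fraction[i]
    large[overlaps$grid_id[i]] <- large[overlaps$grid_id[i]] +
      (v$cow * 250 + v$buffalo * 350) * overlaps$fraction[i]
  }
  expect_equal(setNames(got$biomass_small, got$grid_id),
               small[got$grid_id])
  expect_equal(setNames(got$biomass_large, got$grid_id),
               large[got$grid_id])
  # conservation of the district total
  tot <- sum(villages$sheep * 30 + villages$goat * 25 +
             villages$cow * 250 + villages$buffalo * 350)
  expect_equal(sum(got$biomass_small) + sum(got$biomass_large), tot)
})

test_that("ONE area counts strict exceedance of 0.5 and is monotone", {
  expect_equal(oneArea(c(0.4, 0.5, 0.6), 1), 1)   # 0.5 itself is excluded
  expect_equal(oneArea(rep(0, 10), 2), 0)
  expect_error(oneArea(c(0.2, 1.3), 1), "\\[0,1\\]")
  set.seed(4)
  for (t in 1:10) {
    probs <- runif(200)
    expect_equal(oneArea(probs, 0.09), sum(probs > 0.5) * 0.09)
    bumped <- pmin(probs + runif(200, 0, 0.2), 1)
    expect_gte(oneArea(bumped, 0.09), oneArea(probs, 0.09))
  }
})

test_that("z-scoring uses the sample sd, is idempotent, and rejects constants", {
  df <- data.frame(x = c(1, 2, 3))
  z <- zscoreColumns(df)
  expect_equal(z$x, c(-1, 0, 1))
  z2 <- zscoreColumns(z)
  expect_equal(z2$x, z$x)
  expect_error(zscoreColumns(data.frame(x = rep(2, 5))), "zero-variance.*x")
  # moments taken from the full population, applied to a subset
  pop <- data.frame(x = rnorm(100, 5, 2))
  sub <- pop[1:30, , drop = FALSE]
  zs <- zscoreColumns(sub, population = pop)
  expect_equal(zs$x, (sub$x - mean(pop$x)) / sd(pop$x))
  zp <- zscoreColumns(pop)
  expect_equal(mean(zp$x), 0, tolerance = 1e-9)
  expect_equal(sd(zp$x), 1, tolerance = 1e-9)
})

test_that("correlation screen is inclusive at the threshold and symmetric", {
  set.seed(8)
  u <- rnorm(40)
  df <- data.frame(u = u, dup = u, w = rnorm(40))
  fl <- correlationScreen(df)
  expect_true(any(fl$u == "u" & fl$v == "dup"))
  # construct a pair with empirical correlation exactly 0.6
  x <- as.numeric(scale(rnorm(50)))
  e <- as.numeric(scale(residuals(lm(rnorm(50) ~ x))))
  y <- 0.6 * x + sqrt(1 - 0.36) * e
  expect_equal(cor(x, y), 0.6, tolerance = 1e-12)
  fl2 <- correlationScreen(data.frame(x = x, y = y))
  expect_equal(nrow(fl2), 1)  # inclusive >=
  # symmetry of the incompatibility relation
  expect_true(occuInterview:::isIncompatible("x", "y", fl2))
  expect_true(occuInterview:::isIncompatible("y", "x", fl2))
  # independent noise at n = 500 is essentially never flagged
  noise <- as.data.frame(matrix(rnorm(500 * 4), 500, 4))
  expect_equal(nrow(correlationScreen(noise)), 0)
  expect_error(correlationScreen(df[1:2, ]), "3 rows")
})

test_that("covariate table build joins biomass, z-scores district-wide and screens", {
  cfg <- simConfig(n_district = 80, n_sampled = 40, seed = 13)
  ls <- simulateLandscape(cfg)
  cov <- ls$covariates
  for (cl in c("area_one", "area_kharif", "road_length", "biomass_small")) {
    expect_equal(mean(cov[[cl]]), 0, tolerance = 1e-9)
    expect_equal(sd(cov[[cl]]), 1, tolerance = 1e-9)
  }
  expect_true(all(ls$raw$area_one >= 0 & ls$raw$area_one <= 25))
  expect_equal(sum(cov$sampled), 40)
})
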