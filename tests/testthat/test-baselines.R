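test_that("sequence features reproduce Henderson-Hasselbalch charges", {
  f <- sharmaFeatures("KK", "DD", pH = 7)
  expect_equal(f$qVL, 2 / (1 + 10^(7 - 10.53)), tolerance = 1e-9)
  expect_equal(f$qVH, -2 / (1 + 10^(3.65 - 7)), tolerance = 1e-9)
  expect_equal(f$qVL, 2, tolerance = 1e-2)
  expect_equal(f$qVH, -2, tolerance = 1e-2)
  expect_equal(f$csp, f$qVL * f$qVH, tolerance = 1e-12)
  expect_equal(f$csp, -4, tolerance = 0.05)
  # identical chains: the charge-symmetry product is a square
  fi <- sharmaFeatures("KDR", "KDR", pH = 6)
  expect_gte(fi$csp, 0)
  expect_equal(fi$csp, fi$qVL^2, tolerance = 1e-12)
  # swapping chains leaves net charge and csp unchanged
  fs <- sharmaFeatures("DD", "KK", pH = 7)
  expect_equal(fs$qNet, f$qNet, tolerance = 1e-12)
  expect_equal(fs$csp, f$csp, tolerance = 1e-12)
  # all-Gly: no ionizable residues, hydrophobicity falls back
  fg <- sharmaFeatures("GGG", "GGG", pH = 7, hiFallback = 0)
  expect_equal(fg$qNet, 0)
  expect_equal(fg$hi, 0)
  expect_error(sharmaFeatures("KBZ", "DD"), "invalid amino-acid")
})

test_that("the linear viscosity model recovers exact and noisy coefficients", {
  set.seed(10)
  feats <- data.frame(qNet = rnorm(40, 0, 3), csp = rnorm(40, 0, 4),
                      hi = runif(40, 0.5, 2))
  beta <- c(1.2, 0.15, -0.08, 0.5)
  y <- beta[1] + beta[2] * feats$qNet + beta[3] * feats$csp + beta[4] * feats$hi
  m <- fitSharma(feats, 10^y)
  expect_lt(sqrt(sum(stats::residuals(m$fit)^2)), 1e-8)
  expect_equal(unname(m$coefficients), beta, tolerance = 1e-8)
  expect_equal(predict(m, feats), 10^y, tolerance = 1e-6)
  # duplicating the data leaves the fit unchanged
  m2 <- fitSharma(rbind(feats, feats), rep(10^y, 2))
  expect_equal(m2$coefficients, m$coefficients, tolerance = 1e-9)
  # noisy labels: coefficients recovered within 3 standard errors
  yn <- y + rnorm(40, 0, 0.05)
  mn <- fitSharma(feats, 10^yn)
  se <- summary(mn$fit)$coefficients[, "Std. Error"]
  expect_true(all(abs(unname(mn$coefficients) - beta) < 3 * se + 1e-12))
  expect_error(fitSharma(feats[1:3, ], 10^y[1:3]), "at least 4")
  degen <- feats; degen$csp <- 2 * degen$qNet
  expect_error(fitSharma(degen, 10^y), "rank-deficient")
})

test_that("clustered-negative-charge score matches a hand-computed double loop", {
  spec <- gridSpec(9, 0.75, 32L)
  xyz <- rbind(c(0, 0, 0), c(3, 0, 0), c(-3, 0, 0), c(0, 3, 0), c(0, 0, 14))
  chg <- c(-0.6, -0.4, 0.5, 0, 0.8)
  s <- barStructure(xyz[1:4, , drop = FALSE], charges = chg[1:4], radii = 1.7)
  occ <- computeSES(s, spec)
  sc <- scmScore(s, occ, exposureThreshold = 0.1, radius = 5)
  # every atom of this tiny cluster is exposed; neighborhood sums by hand
  nb <- vapply(1:4, function(i) {
    d2 <- colSums((t(xyz[1:4, ]) - xyz[i, ])^2)
    sum(chg[1:4][d2 <= 25])
  }, 1.0)
  expect_equal(as.numeric(sc), abs(sum(pmin(0, nb))), tolerance = 1e-12)
  # no negative charges: score 0
  sPos <- barStructure(xyz[1:4, , drop = FALSE], charges = abs(chg[1:4]))
  expect_equal(as.numeric(scmScore(sPos, computeSES(sPos, spec), radius = 5)), 0)
})

test_that("the negative-charge score is local and charge-monotone", {
  spec <- gridSpec(12, 0.75, 64L)
  base <- canonicalize(assignParameters(makeToyStructure(nResidues = 14L,
                                                         coreRadius = 4.5,
                                                         seed = 21L)))
  occ <- computeSES(base, spec)
  s0 <- as.numeric(scmScore(base, occ))
  # adding one exposed Asp patch strictly increases the score
  withAsp <- canonicalize(assignParameters(
    makeToyStructure(nResidues = 14L, coreRadius = 4.5, seed = 21L,
                     patches = list(list(center = c(0, 0, 1),
                                         angularRadius = 45,
                                         resname = "ASP")))))
  expect_gt(withAsp@provenance$nPatchResidues, 0)
  s1 <- as.numeric(scmScore(withAsp, computeSES(withAsp, spec)))
  expect_gt(s1, s0)
  # a positive charge beyond the neighborhood radius leaves the score unchanged
  far <- base
  a <- far@atoms
  extra <- a[1, ]
  extra$serial <- max(a$serial) + 1L
  extra$name <- "NZ"; extra$element <- "N"; extra$resname <- "LYS"
  extra$resno <- max(a$resno) + 1L
  extra$x <- 0; extra$y <- 0; extra$z <- 25
  extra$charge <- 1; extra$radius <- 1.7
  # place it outside the occupancy grid region entirely: score must only use
  # atoms within the neighborhood radius of exposed atoms
  farAtoms <- rbind(a, extra)
  sFar <- new("FvStructure", atoms = farAtoms, chains = base@chains,
              provenance = list())
  s2 <- as.numeric(scmScore(sFar, occ, radius = 10))
  expect_equal(s2, s0, tolerance = 1e-9)
})
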