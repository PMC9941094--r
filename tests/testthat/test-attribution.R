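test_that("integrated gradients are exact for a single-region linear model", {
  net <- linearishNet()
  x <- inputGridFromArray(c(0.9, 0.3, 0.5, 0.1, 0.7, 0.2, 0.6, 0.4))
  a <- integratedGradients(net, x, steps = 16L)
  wEff <- sum(c(1, 2, -1, 0.5) * c(0.5, 0.25, 1, 2))
  expected <- numeric(8)
  expected[1] <- 0.9 * wEff          # argmax voxel of the single pool region
  expect_equal(as.vector(a@scores), expected, tolerance = 1e-12)
  # completeness holds exactly here
  expect_equal(sum(a@scores),
               a@source$prediction - a@source$baselinePrediction,
               tolerance = 1e-10)
  # zero path: x == baseline gives all-zero scores
  a0 <- integratedGradients(net, x, baseline = x@data, steps = 16L)
  expect_equal(max(abs(a0@scores)), 0)
  expect_error(integratedGradients(net, x, steps = 4L), "at least 8")
  expect_error(integratedGradients(net, x, baseline = numeric(3)), "shape")
})

test_that("completeness gap is small and shrinks with more steps", {
  spec <- testSpec()
  tr <- lapply(1:4, function(i) dummyGrid(spec, paste0("s", i),
                                          target = i / 4, seed = i))
  fit <- trainFold(tr, tr, testNetConfig(epochs = 10L, window = 3L),
                   seed = 5L, allowOverlap = TRUE)
  x <- dummyGrid(spec, "q", target = 0.5, seed = 99)
  gap <- function(steps) {
    a <- integratedGradients(fit$net, x, steps = steps)
    abs(sum(a@scores) - (a@source$prediction - a@source$baselinePrediction)) /
      abs(a@source$prediction - a@source$baselinePrediction)
  }
  g16 <- gap(16L); g128 <- gap(128L); g256 <- gap(256L)
  expect_lt(g128, 0.01)
  expect_lte(g256, g16 + 1e-9)
  # masked-input zeroing: zero voxels get exactly zero attribution
  a <- integratedGradients(fit$net, x, steps = 16L)
  expect_true(all(a@scores[!x@mask] == 0))
})

test_that("pooled significance is the population sd of nonzero scores", {
  spec <- tinySpec()
  mk <- function(vals) new("AttributionGrid", spec = spec,
                           scores = array(vals, dim = c(2, 2, 2, 1)),
                           source = list())
  two <- mk(c(1, -1, 0, 0, 0, 0, 0, 0))
  expect_equal(as.numeric(poolSignificance(list(two))), 1)
  expect_equal(as.numeric(poolSignificance(list(two, two))),
               as.numeric(poolSignificance(list(two))))
  set.seed(4)
  rnd <- lapply(1:3, function(i) mk(rnorm(8) * rbinom(8, 1, 0.7)))
  pooled <- unlist(lapply(rnd, function(a) {
    v <- as.numeric(a@scores); v[v != 0]
  }))
  expect_equal(as.numeric(poolSignificance(rnd)),
               sqrt(mean((pooled - mean(pooled))^2)), tolerance = 1e-12)
  expect_error(poolSignificance(list(mk(rep(0, 8)))), "zero")
})

test_that("patch finding matches an independent graph-components oracle", {
  spec <- patchSpec()
  for (seed in 1:10) {
    a <- randomAttribution(spec, seed)
    patches <- findPatches(a, 1, linkDist = 1.5)
    oracle <- igraphComponents(a, 1, 1.5)
    got <- lapply(patches, function(p) sort(p$voxels))
    expect_setequal(lapply(got, paste, collapse = ","),
                    lapply(oracle, paste, collapse = ","))
    # patches partition the significant voxels, per sign
    sc <- a@scores[, , , 1]
    expect_setequal(unlist(got), which(abs(sc) > 1))
    # sorted by size descending
    sizes <- vapply(patches, `[[`, 1L, "size")
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("patch finding degenerate cases", {
  spec <- patchSpec()
  a0 <- new("AttributionGrid", spec = spec,
            scores = array(0.5, dim = c(20, 20, 20, 1)), source = list())
  expect_length(findPatches(a0, 1), 0)
  v <- array(0, dim = c(20, 20, 20, 1))
  v[3, 3, 3, 1] <- 2; v[4, 3, 3, 1] <- 2     # one cluster
  v[17, 17, 17, 1] <- 2                       # far away
  a2 <- new("AttributionGrid", spec = spec, scores = v, source = list())
  ps <- findPatches(a2, 1)
  expect_length(ps, 2)
  expect_equal(vapply(ps, `[[`, 1L, "size"), c(2L, 1L))
  expect_error(findPatches(a2, 1, linkDist = 0.5), "at least the grid spacing")
})

test_that("patch points classify by nearest heavy atom with priority order", {
  spec <- gridSpec(6, 1.5, 16L)
  off <- espvisc:::padOffset(spec)
  # voxel index helper for physical coordinates
  vox <- function(x, y, z) {
    i <- round((c(x, y, z) + spec@extent) / spec@spacing) + off + 1
    i[1] + 16 * (i[2] - 1) + 256 * (i[3] - 1)
  }
  s <- barStructure(rbind(c(-4, 0, 0), c(-4, 1.2, 0),   # Asp CG/OD1
                          c(4, 0, 0),                   # Tyr ring carbon
                          c(0, 4, 0),                   # backbone O
                          c(0, -4, 0)),                 # plain C
                    names = c("CG", "OD1", "CZ", "O", "CB"),
                    resnames = c("ASP", "ASP", "TYR", "GLY", "GLY"),
                    resnos = c(1, 1, 2, 3, 4))
  pAsp <- list(voxels = c(vox(-4.5, 0, 0), vox(-4.5, 1.5, 0)),
               sign = "positive", size = 2L)
  compAsp <- classifyPatchPoints(pAsp, s, spec)
  expect_equal(unname(compAsp$fractions["asp_glu"]), 1)
  expect_equal(sum(compAsp$fractions), 1, tolerance = 1e-9)
  pTyr <- list(voxels = vox(4.5, 0, 0), sign = "positive", size = 1L)
  expect_equal(unname(classifyPatchPoints(pTyr, s, spec)$fractions["aromatic"]), 1)
  pMix <- list(voxels = c(vox(-4.5, 0, 0), vox(0, 4.5, 0), vox(0, -4.5, 0),
                          vox(0, -4.5, 1.5)), sign = "positive", size = 4L)
  comp <- classifyPatchPoints(pMix, s, spec)
  expect_equal(unname(comp$fractions[c("asp_glu", "acceptor", "lipophilic")]),
               c(0.25, 0.25, 0.5))
  expect_equal(comp$acceptorMainchainFraction, 1)
  expect_error(classifyPatchPoints(list(voxels = integer(0)), s, spec), "empty")
})

test_that("segment composition assigns voxels to nearest residues", {
  spec <- gridSpec(6, 1.5, 16L)
  off <- espvisc:::padOffset(spec)
  vox <- function(x, y, z) {
    i <- round((c(x, y, z) + spec@extent) / spec@spacing) + off + 1
    i[1] + 16 * (i[2] - 1) + 256 * (i[3] - 1)
  }
  s <- barStructure(rbind(c(-4, 0, 0), c(4, 0, 0)), names = c("CA", "CA"),
                    resnames = "ALA", resnos = c(10, 50),
                    chains = c("H", "H"), roles = c(H = "heavy"))
  seg <- new("SegmentMap",
             table = data.frame(chain = "H", resno = c(10, 50), insert = "",
                                segment = c("framework", "CDR-H3")))
  pFw <- list(voxels = c(vox(-4.5, 0, 0), vox(-4.5, 1.5, 0)), sign = "positive",
              size = 2L)
  expect_equal(unname(segmentComposition(pFw, seg, s, spec)["framework"]), 1)
  pBoth <- list(voxels = c(vox(-4.5, 0, 0), vox(4.5, 0, 0)), sign = "positive",
                size = 2L)
  fr <- segmentComposition(pBoth, seg, s, spec)
  expect_equal(unname(fr[c("CDR-H3", "framework")]), c(0.5, 0.5))
  segU <- new("SegmentMap",
              table = data.frame(chain = "H", resno = c(10, 50), insert = "",
                                 segment = "unknown"))
  expect_warning(segmentComposition(pFw, segU, s, spec), "unknown")
})

test_that("carboxylates split into proximal and distal by cation distance", {
  spec <- gridSpec(12, 1.5, 32L)
  off <- espvisc:::padOffset(spec)
  p <- spec@paddedDim
  vox <- function(x, y, z) {
    i <- round((c(x, y, z) + spec@extent) / spec@spacing) + off + 1
    i[1] + p * (i[2] - 1) + p * p * (i[3] - 1)
  }
  # proximal Asp: carboxyl 3.0 A from Lys NZ; distal Glu 12 A from any cation;
  # a second Asp at 4.2 A falls in the excluded gap
  s <- barStructure(rbind(c(-6, 0, 0), c(-6, 1.2, 0), c(-6, -1.2, 0),  # ASP 1
                          c(-3, 0, 0),                                  # LYS NZ
                          c(6, 0, 0), c(6, 1.2, 0), c(6, -1.2, 0),      # GLU
                          c(-3, 4.2, 0)),                               # ASP 2
                    names = c("CG", "OD1", "OD2", "NZ", "CD", "OE1", "OE2", "OD1"),
                    resnames = c("ASP", "ASP", "ASP", "LYS", "GLU", "GLU",
                                 "GLU", "ASP"),
                    resnos = c(1, 1, 1, 2, 3, 3, 3, 4))
  sc <- array(0, dim = c(p, p, p, 1))
  sc[vox(-7.5, 0, 0)] <- -1   # near proximal Asp carboxyl
  sc[vox(7.5, 0, 0)] <- 1     # near distal Glu carboxyl
  sc[vox(-3, 5.4, 0)] <- 5    # near the gap-zone Asp: must be ignored
  a <- new("AttributionGrid", spec = spec, scores = sc, source = list())
  res <- carboxylateAttribution(a, s)
  expect_equal(res$proximal, -1)
  expect_equal(res$distal, 1)
  expect_gt(res$distal, res$proximal)
  noAcid <- barStructure(rbind(c(0, 0, 0)), names = "CA", resnames = "ALA")
  expect_error(carboxylateAttribution(a, noAcid), "no Asp/Glu")
})
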