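uniformOcc <- function(spec) {
  n <- nPhysical(spec)
  new("OccupancyGrid", spec = spec, interior = array(FALSE, dim = c(n, n, n)),
      surfaceDistance = array(Inf, dim = c(n, n, n)))
}

test_that("screened-Coulomb field matches Coulomb, screens, and superposes", {
  spec <- gridSpec(9, 0.75, 32L)
  q1 <- barStructure(rbind(c(0, 0, 0)), charges = 1)
  phi <- solveDebye(q1, spec, epsOut = 80, ionicStrength = 0)
  ax <- axisCoords(spec)
  g <- expand.grid(x = ax, y = ax, z = ax)
  r <- pmax(sqrt(g$x^2 + g$y^2 + g$z^2), 0.5 * spec@spacing)
  expect_equal(as.vector(phi@values), 7046.20 / (4 * pi * 80 * r),
               tolerance = 1e-6)
  # strong screening: the far field collapses relative to the Coulomb case
  phiS <- solveDebye(q1, spec, epsOut = 80, ionicStrength = 10)
  far <- sqrt(g$x^2 + g$y^2 + g$z^2) > 6
  expect_lt(max(abs(phiS@values[far])), 0.01 * max(abs(phi@values[far])))
  # linearity
  q2 <- barStructure(rbind(c(2, 1, 0)), charges = -0.5)
  both <- barStructure(rbind(c(0, 0, 0), c(2, 1, 0)), charges = c(1, -0.5))
  expect_equal(solveDebye(both, spec)@values,
               phi@values + solveDebye(q2, spec)@values, tolerance = 1e-9)
})

test_that("PB solver: zero charge gives zero field, dipole is antisymmetric", {
  spec <- gridSpec(9, 0.75, 32L)
  s0 <- barStructure(rbind(c(0, 0, 0)), charges = 0)
  expect_equal(max(abs(solveESP(s0, spec, uniformOcc(spec))@values)), 0)
  # +1/-1 mirror pair in uniform dielectric: phi(x) = -phi(mirror(x))
  dip <- barStructure(rbind(c(-2.25, 0, 0), c(2.25, 0, 0)), charges = c(1, -1))
  phi <- solveESP(dip, spec, uniformOcc(spec), epsIn = 80, epsOut = 80)
  v <- phi@values
  mirrored <- v[rev(seq_len(dim(v)[1])), , ]
  expect_equal(v, -mirrored, tolerance = 1e-3 * max(abs(v)))
})

test_that("PB and screened-Coulomb agree in uniform dielectric", {
  spec <- gridSpec(12, 0.75, 64L)
  s <- barStructure(rbind(c(0.375, 0, 0)), charges = 1)
  pb <- solveESP(s, spec, uniformOcc(spec), epsIn = 80, epsOut = 80)
  db <- solveDebye(s, spec, epsOut = 80)
  ax <- axisCoords(spec)
  g <- expand.grid(x = ax, y = ax, z = ax)
  r <- sqrt((g$x - 0.375)^2 + g$y^2 + g$z^2)
  sel <- r > 3
  relerr <- abs(pb@values[sel] - db@values[sel]) / abs(db@values[sel])
  expect_lt(max(relerr), 0.05)
  expect_error(solveESP(s, spec, uniformOcc(spec), epsIn = -1), "positive")
})

test_that("masked input grid zeroes everything outside the shell", {
  spec <- gridSpec(6, 1.5, 16L)
  n <- nPhysical(spec)
  phi <- new("ScalarField", spec = spec,
             values = array(rnorm(n^3), dim = c(n, n, n)), kind = "esp")
  offShell <- new("ShellMask", spec = spec,
                  active = array(FALSE, dim = c(n, n, n)))
  g0 <- buildESPInput(phi, offShell)
  expect_equal(sum(g0@data != 0), 0)

  act <- array(FALSE, dim = c(n, n, n))
  act[3, 4, 5] <- TRUE
  phi1 <- phi; phi1@values[3, 4, 5] <- 2.5
  g1 <- buildESPInput(phi1, new("ShellMask", spec = spec, active = act))
  expect_equal(sum(g1@data != 0), 1)
  off <- espvisc:::padOffset(spec)
  expect_equal(g1@data[off + 3, off + 4, off + 5, 1], 2.5)

  # nonzero voxel set equals the active shell voxel set on a real structure
  s <- canonicalize(assignParameters(makeToyStructure(seed = 12L)))
  cfg <- deskPreset()
  occ <- computeSES(s, cfg$grid, cfg$probe)
  shell <- computeShell(occ, cfg$shellThickness)
  phi2 <- solveESP(s, cfg$grid, occ)
  gin <- buildESPInput(phi2, shell)
  inner <- gin@data[, , , 1]
  expect_equal(sum(inner != 0), sum(shell@active))
  expect_identical(unname(which(gin@mask)), unname(which(inner != 0)))
})

test_that("Eisenberg channels: class selection, decay, and linearity", {
  spec <- gridSpec(6, 1.5, 16L)
  n <- nPhysical(spec)
  allShell <- new("ShellMask", spec = spec,
                  active = array(TRUE, dim = c(n, n, n)))
  philicOnly <- barStructure(rbind(c(0, 0, 0), c(2, 0, 0)),
                             names = c("CB", "OG"), resnames = "SER")
  g <- buildEisenbergInput(philicOnly, allShell)
  expect_equal(max(abs(g@data[, , , 1])), 0)   # no hydrophobic atoms
  expect_gt(max(g@data[, , , 2]), 0)

  phobe <- barStructure(rbind(c(0, 0, 0)), names = "CB", resnames = "ILE")
  g1 <- buildEisenbergInput(phobe, allShell)
  off <- espvisc:::padOffset(spec)
  c0 <- off + (n + 1) / 2
  ray <- g1@data[c0:(c0 + 4), c0, c0, 1]
  expect_true(all(diff(ray) <= 1e-12))
  # two-atom field is the sum of the single-atom fields
  phobe2 <- barStructure(rbind(c(3, 0, 0)), names = "CB", resnames = "ILE")
  both <- barStructure(rbind(c(0, 0, 0), c(3, 0, 0)), names = "CB",
                       resnames = "ILE")
  gb <- buildEisenbergInput(both, allShell)
  g2 <- buildEisenbergInput(phobe2, allShell)
  expect_equal(gb@data[, , , 1], g1@data[, , , 1] + g2@data[, , , 1],
               tolerance = 1e-9)
  expect_error(
    buildEisenbergInput(barStructure(rbind(c(0, 0, 0)), resnames = "XXX"),
                        allShell), "Eisenberg")
})

test_that("combined representation stacks the ESP and Eisenberg channels", {
  s <- canonicalize(assignParameters(makeToyStructure(seed = 31L)))
  cfg <- deskPreset()
  cfg$representation <- "combined"
  g <- featurizeStructure(s, cfg)
  expect_equal(dim(g@data)[4], 3)
  expect_equal(g@channels, c("esp", "eisenberg_phobic", "eisenberg_philic"))
  cfgE <- deskPreset(); cfgE$representation <- "esp"
  ge <- featurizeStructure(s, cfgE)
  expect_equal(g@data[, , , 1], ge@data[, , , 1])
})

test_that("random rotations are rigid, seeded, and count correctly", {
  s <- canonicalize(assignParameters(makeToyStructure(nResidues = 10L, seed = 2L)))
  rots <- randomRotations(s, 10, seed = 7L)
  expect_length(rots, 10)
  d0 <- dist(coords(s))
  for (r in rots[1:3]) expect_equal(as.vector(dist(coords(r))),
                                    as.vector(d0), tolerance = 1e-9)
  rots2 <- randomRotations(s, 10, seed = 7L)
  expect_identical(coords(rots[[5]]), coords(rots2[[5]]))
  rots3 <- randomRotations(s, 10, seed = 8L)
  expect_false(isTRUE(all.equal(coords(rots[[1]]), coords(rots3[[1]]))))
  expect_error(randomRotations(s, 0), "at least 1")
})
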