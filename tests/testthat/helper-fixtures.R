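# Shared fixture builders: bare structures from coordinate tables, a tiny
# hand-written PDB, and small dummy input grids for network tests.

barStructure <- function(xyz, radii = 1.7, charges = 0, names = "C",
                         elements = NULL, resnames = "ALA", resnos = NULL,
                         chains = "A", roles = NULL) {
  n <- nrow(xyz)
  names <- rep_len(names, n)
  if (is.null(elements)) elements <- substr(names, 1, 1)
  if (is.null(resnos)) resnos <- seq_len(n)
  a <- data.frame(serial = seq_len(n), name = names,
                  element = rep_len(elements, n),
                  resname = rep_len(resnames, n), resno = rep_len(resnos, n),
                  insert = "", chain = rep_len(chains, n),
                  x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                  charge = rep_len(charges, n), radius = rep_len(radii, n),
                  mass = unname(espvisc:::elementMasses[rep_len(elements, n)]),
                  stringsAsFactors = FALSE)
  a$mass[is.na(a$mass)] <- 12.011
  if (is.null(roles)) roles <- stats::setNames(rep("other", length(unique(a$chain))),
                                               unique(a$chain))
  new("FvStructure", atoms = a, chains = roles, provenance = list())
}

writeTinyPDB <- function(path, lines) {
  writeLines(lines, path)
  path
}

# three protein atoms plus an END record, fixed-width PDB fields
tinyPDBLines <- c(
  "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1       2.500   2.000   3.000  1.00  0.00           C",
  "ATOM      3  C   ALA A   1       3.800   2.700   3.500  1.00  0.00           C",
  "END")

watersPDBLines <- c(
  "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  GLY A   1       1.450   0.000   0.000  1.00  0.00           C",
  "ATOM      3  C   GLY A   1       2.000   1.400   0.000  1.00  0.00           C",
  "ATOM      4  O   GLY A   1       3.200   1.600   0.000  1.00  0.00           O",
  "ATOM      5  CB  GLY A   1       2.000  -1.400   0.000  1.00  0.00           C",
  "HETATM    6  O   HOH A 101      10.000  10.000  10.000  1.00  0.00           O",
  "HETATM    7  O   HOH A 102      12.000  10.000  10.000  1.00  0.00           O",
  "END")

# minimal InputGrid carrying arbitrary data, for network-level tests
dummyGrid <- function(spec, id, target, seed = 1L, density = 0.05) {
  p <- spec@paddedDim
  dat <- espvisc:::withSeed(seed, {
    v <- numeric(p^3)
    k <- max(1L, round(density * p^3))
    idx <- sample(p^3, k)
    v[idx] <- stats::rnorm(k)
    v
  })
  new("InputGrid", spec = spec, data = array(dat, dim = c(p, p, p, 1)),
      mask = array(dat != 0, dim = c(p, p, p)), channels = "esp",
      label = 10^target, target = target,
      provenance = list(structureId = id, targetTransform = "log10"))
}

# small grid + config presets for fast network tests
testSpec <- function() gridSpec(6, 1.5, 16L)   # 9^3 physical, padded 16^3

testNetConfig <- function(epochs = 20L, window = 5L, lr = 1e-3)
  netConfig(nBlocks = 4L, firstFilters = 4L, dropout = 0.05,
            learningRate = lr, epochs = epochs, selectionWindow = window)

# micro pipeline configuration for end-to-end smoke tests
microPreset <- function(epochs = 3L, k = 2L) {
  cfg <- deskPreset()
  cfg$net <- netConfig(nBlocks = 5L, learningRate = 1e-3, epochs = epochs,
                       selectionWindow = min(epochs, 50L))
  cfg$k <- as.integer(k)
  cfg$nRotationsTrain <- 1L
  cfg$nRotationsPredict <- 1L
  cfg
}
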