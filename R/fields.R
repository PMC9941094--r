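# Electrostatic potential on the grid (finite-difference linearized
# Poisson-Boltzmann with a screened-Coulomb fallback), masked input-grid
# assembly, Eisenberg hydrophobicity channels, and rotation augmentation.

# kappa^2 [1/A^2] = 8.4862 * I[M] / eps  (Debye screening at 298 K; I = 0.15 M,
# eps = 80 gives the familiar ~8 A Debye length)
debyeKappa <- function(ionicStrength, epsOut) {
  if (ionicStrength <= 0) return(0)
  sqrt(8.4862 * ionicStrength / epsOut)
}

#' Solve the linearized Poisson-Boltzmann equation by finite differences
#'
#' 7-point stencil with harmonic-mean face dielectrics from the
#' interior/exterior map, trilinear charge spreading, Debye-Hueckel Dirichlet
#' boundary values, SOR iteration to a relative residual tolerance.  The
#' potential is returned in kT/e at 298 K.
#'
#' @param s an \linkS4class{FvStructure} with charges assigned
#' @param spec a \linkS4class{GridSpec}
#' @param occ \linkS4class{OccupancyGrid} defining the dielectric map
#' @param epsIn,epsOut inner/outer dielectric constants (default 1 and 80)
#' @param ionicStrength molar ionic strength (default 0, no screening)
#' @param tol relative residual tolerance
#' @param maxit maximum SOR sweeps
#' @return a \linkS4class{ScalarField} of kind \code{"esp"}
#' @export
solveESP <- function(s, spec, occ, epsIn = 1, epsOut = 80, ionicStrength = 0,
                     tol = 1e-5, maxit = 10000L) {
  if (epsIn <= 0 || epsOut <= 0) stop("dielectric constants must be positive")
  a <- s@atoms
  if (any(is.na(a$charge))) stop("charges not assigned; run assignParameters() first")
  n <- nPhysical(spec)
  kappa <- debyeKappa(ionicStrength, epsOut)
  res <- cpp_pb_solve(as.matrix(a[, c("x", "y", "z")]), a$charge,
                      as.logical(occ@interior), n, spec@spacing, -spec@extent,
                      epsIn, epsOut, kappa, tol, as.integer(maxit))
  if (!res$converged)
    stop(sprintf("PB solver did not converge in %d sweeps (relative residual %.3g)",
                 res$iterations, res$residual))
  new("ScalarField", spec = spec, values = array(res$phi, dim = c(n, n, n)),
      kind = "esp")
}

#' Screened-Coulomb (Debye-Hueckel) potential
#'
#' Direct superposition phi(x) = sum_i q_i exp(-kappa r_i) / (4 pi eps0
#' eps_out r_i) in kT/e, with the singularity clamped at half a voxel.
#' Fast uniform-dielectric fallback; also supplies the PB boundary condition.
#'
#' @inheritParams solveESP
#' @return a \linkS4class{ScalarField} of kind \code{"esp"}
#' @export
solveDebye <- function(s, spec, epsOut = 80, ionicStrength = 0) {
  a <- s@atoms
  if (any(is.na(a$charge))) stop("charges not assigned; run assignParameters() first")
  n <- nPhysical(spec)
  phi <- cpp_debye(as.matrix(a[, c("x", "y", "z")]), a$charge, n, spec@spacing,
                   -spec@extent, epsOut, debyeKappa(ionicStrength, epsOut),
                   0.5 * spec@spacing)
  new("ScalarField", spec = spec, values = array(phi, dim = c(n, n, n)),
      kind = "esp")
}

padField <- function(values, spec) {
  p <- spec@paddedDim
  n <- nPhysical(spec)
  off <- padOffset(spec)
  out <- array(0, dim = c(p, p, p))
  out[off + seq_len(n), off + seq_len(n), off + seq_len(n)] <- values
  out
}

#' Assemble the masked electrostatic input grid
#'
#' Keeps the potential only on active shell voxels, zeroes everything else,
#' and centers the physical block inside the padded cube.
#'
#' @param phi \linkS4class{ScalarField} (kind "esp")
#' @param shell \linkS4class{ShellMask} on the same grid
#' @param label optional viscosity in cP
#' @param targetTransform \code{"log10"} or \code{"raw"} training target
#' @param clip optional symmetric clip (kT/e) applied to the potential
#' @param provenance list carried into the grid
#' @return an \linkS4class{InputGrid} with one channel
#' @export
buildESPInput <- function(phi, shell, label = numeric(0),
                          targetTransform = "log10", clip = NULL,
                          provenance = list()) {
  if (!identical(phi@spec, shell@spec)) stop("field and shell grids do not match")
  v <- phi@values
  if (!is.null(clip)) v <- pmin(pmax(v, -clip), clip)
  v[!shell@active] <- 0
  spec <- phi@spec
  dat <- array(padField(v, spec), dim = c(spec@paddedDim, spec@paddedDim,
                                          spec@paddedDim, 1))
  target <- if (length(label)) applyTransform(label, targetTransform) else numeric(0)
  new("InputGrid", spec = spec, data = dat,
      mask = array(padField(shell@active, spec) > 0,
                   dim = rep(spec@paddedDim, 3)),
      channels = "esp", label = label, target = target,
      provenance = c(provenance, list(targetTransform = targetTransform)))
}

applyTransform <- function(x, transform) {
  switch(transform, log10 = log10(x), raw = x,
         stop("unknown target transform: ", transform))
}

invertTransform <- function(x, transform) {
  switch(transform, log10 = 10^x, raw = x,
         stop("unknown target transform: ", transform))
}

#' Two-channel Eisenberg hydrophobicity representation
#'
#' Residues are classed hydrophobic/hydrophilic by the sign of their Eisenberg
#' scale value; per channel, atoms of the opposite class are dropped, each
#' remaining atom gets a Gaussian of unit height whose width is 3 x |scale| of
#' its parent residue (the density falls to exp(-1) at that radius), densities
#' are summed at voxel centers, and the same shell masking as the
#' electrostatic channel is applied.
#'
#' @param s an \linkS4class{FvStructure}
#' @param shell \linkS4class{ShellMask}
#' @param label,targetTransform,provenance as in \code{\link{buildESPInput}}
#' @return an \linkS4class{InputGrid} with channels
#'   \code{eisenberg_phobic}, \code{eisenberg_philic}
#' @export
buildEisenbergInput <- function(s, shell, label = numeric(0),
                                targetTransform = "log10", provenance = list()) {
  spec <- shell@spec
  eis <- readTable("eisenberg")
  a <- s@atoms
  sc <- eis$scale[match(a$resname, eis$resname)]
  if (any(is.na(sc)))
    stop("residue(s) without an Eisenberg scale entry: ",
         paste(unique(a$resname[is.na(sc)]), collapse = ", "))
  n <- nPhysical(spec)
  chan <- function(keep) {
    if (!any(keep)) return(array(0, dim = c(n, n, n)))
    d <- cpp_gaussian_density(as.matrix(a[keep, c("x", "y", "z")]),
                              3 * abs(sc[keep]), n, spec@spacing, -spec@extent)
    array(d, dim = c(n, n, n))
  }
  phobic <- chan(sc > 0)
  philic <- chan(sc < 0)
  phobic[!shell@active] <- 0
  philic[!shell@active] <- 0
  p <- spec@paddedDim
  dat <- array(0, dim = c(p, p, p, 2))
  dat[, , , 1] <- padField(phobic, spec)
  dat[, , , 2] <- padField(philic, spec)
  target <- if (length(label)) applyTransform(label, targetTransform) else numeric(0)
  new("InputGrid", spec = spec, data = dat,
      mask = array(padField(shell@active, spec) > 0, dim = rep(p, 3)),
      channels = c("eisenberg_phobic", "eisenberg_philic"),
      label = label, target = target,
      provenance = c(provenance, list(targetTransform = targetTransform)))
}

#' Concatenate input grids channel-wise
#'
#' @param ... \linkS4class{InputGrid} objects on the same grid (e.g. the
#'   electrostatic channel plus the two Eisenberg channels)
#' @return an \linkS4class{InputGrid} with the channels stacked
#' @export
combineInputs <- function(...) {
  gs <- list(...)
  spec <- gs[[1]]@spec
  for (g in gs) if (!identical(g@spec, spec)) stop("input grids do not match")
  p <- spec@paddedDim
  nch <- sum(vapply(gs, function(g) length(g@channels), 1L))
  dat <- array(0, dim = c(p, p, p, nch))
  k <- 0
  for (g in gs) for (c in seq_along(g@channels)) {
    k <- k + 1
    dat[, , , k] <- g@data[, , , c]
  }
  new("InputGrid", spec = spec, data = dat, mask = gs[[1]]@mask,
      channels = unlist(lapply(gs, function(g) g@channels)),
      label = gs[[1]]@label, target = gs[[1]]@target,
      provenance = gs[[1]]@provenance)
}

quaternionToMatrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Uniform random rotation matrices
#' @keywords internal
randomRotationMatrices <- function(n, seed) {
  withSeed(seed, {
    lapply(seq_len(n), function(i) {
      u <- stats::runif(3)
      q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
             sqrt(1 - u[1]) * cos(2 * pi * u[2]),
             sqrt(u[1]) * sin(2 * pi * u[3]),
             sqrt(u[1]) * cos(2 * pi * u[3]))
      quaternionToMatrix(q)
    })
  })
}

#' Randomly rotated copies of a structure
#'
#' Draws \code{n} independent uniform rotations (quaternion sampling) about
#' the center of mass and applies them to the canonicalized structure;
#' deterministic given the seed.  The production protocol uses 10 rotated
#' samples per training structure and a 10-structure inference ensemble.
#'
#' @param s a canonicalized \linkS4class{FvStructure}
#' @param n number of rotated copies
#' @param seed RNG seed
#' @return list of \code{n} rotated structures
#' @export
randomRotations <- function(s, n, seed = 1L) {
  if (n < 1) stop("n must be at least 1")
  mats <- randomRotationMatrices(n, seed)
  lapply(seq_len(n), function(i) rotateStructure(s, mats[[i]], rotationId = i))
}

#' Apply a rotation matrix to a structure
#' @keywords internal
rotateStructure <- function(s, R, rotationId = NA) {
  a <- s@atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  prov <- s@provenance
  prov$transforms <- c(prov$transforms, list(list(type = "rotate", matrix = R)))
  prov$rotation <- R
  prov$rotationId <- rotationId
  initialize(s, atoms = a, provenance = prov)
}

#' Featurize one structure under a run configuration
#'
#' Surface, shell, potential and masked input grid for the structure as
#' given (no rotation applied here).
#'
#' @param s parameterized, canonicalized \linkS4class{FvStructure}
#' @param cfg run configuration (see \code{\link{deskPreset}})
#' @param label optional viscosity label in cP
#' @return an \linkS4class{InputGrid}
#' @export
featurizeStructure <- function(s, cfg, label = numeric(0)) {
  occ <- computeSES(s, cfg$grid, cfg$probe)
  shell <- computeShell(occ, cfg$shellThickness)
  prov <- list(structureId = s@provenance$structureId,
               rotationId = s@provenance$rotationId)
  esp <- NULL
  if (cfg$representation %in% c("esp", "combined")) {
    phi <- if (identical(cfg$solver, "debye"))
      solveDebye(s, cfg$grid, cfg$epsOut, cfg$ionicStrength)
    else
      solveESP(s, cfg$grid, occ, cfg$epsIn, cfg$epsOut, cfg$ionicStrength,
               cfg$tol, cfg$maxit)
    esp <- buildESPInput(phi, shell, label, cfg$targetTransform, cfg$clipEsp, prov)
  }
  if (cfg$representation == "esp") return(esp)
  eis <- buildEisenbergInput(s, shell, label, cfg$targetTransform, prov)
  if (cfg$representation == "eisenberg") return(eis)
  combineInputs(esp, eis)
}

#' Featurize rotated copies of a structure
#'
#' @param s parameterized, canonicalized structure
#' @param n number of random rotations
#' @param seed RNG seed for the rotations
#' @inheritParams featurizeStructure
#' @return list of \linkS4class{InputGrid}, one per rotation
#' @export
featurizeRotations <- function(s, n, seed, cfg, label = numeric(0)) {
  lapply(randomRotations(s, n, seed), featurizeStructure, cfg = cfg, label = label)
}
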