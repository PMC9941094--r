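# Synthetic toy structures with controllable negative surface patches, and
# labelled datasets whose log-viscosity is a known function of the
# negative-patch electrostatic area plus noise.  Exercises the identical
# code paths as real antibody structures at a fraction of the size.

residueTemplate <- function(resname) {
  # radial offsets (u = outward unit vector, t1/t2 tangents); names chosen so
  # parameter assignment and the nearest-atom categories work unchanged
  switch(resname,
    ALA = list(N = c(0, -1.4, 0), CA = c(0, 0, 0), C = c(0, 1.4, 0),
               O = c(0.6, 1.9, 0.9), CB = c(1.5, 0, 0)),
    SER = list(N = c(0, -1.4, 0), CA = c(0, 0, 0), C = c(0, 1.4, 0),
               O = c(0.6, 1.9, 0.9), CB = c(1.5, 0, 0), OG = c(2.9, 0, 0)),
    ASP = list(N = c(0, -1.4, 0), CA = c(0, 0, 0), C = c(0, 1.4, 0),
               O = c(0.6, 1.9, 0.9), CB = c(1.5, 0, 0), CG = c(2.8, 0, 0),
               OD1 = c(3.7, 0.7, 0), OD2 = c(3.7, -0.7, 0)),
    GLU = list(N = c(0, -1.4, 0), CA = c(0, 0, 0), C = c(0, 1.4, 0),
               O = c(0.6, 1.9, 0.9), CB = c(1.5, 0, 0), CD = c(2.8, 0, 0),
               OE1 = c(3.7, 0.7, 0), OE2 = c(3.7, -0.7, 0)),
    LYS = list(N = c(0, -1.4, 0), CA = c(0, 0, 0), C = c(0, 1.4, 0),
               O = c(0.6, 1.9, 0.9), CB = c(1.5, 0, 0), NZ = c(3.7, 0, 0)),
    ARG = list(N = c(0, -1.4, 0), CA = c(0, 0, 0), C = c(0, 1.4, 0),
               O = c(0.6, 1.9, 0.9), CB = c(1.5, 0, 0), CZ = c(3.0, 0, 0),
               NH1 = c(3.8, 0.7, 0), NH2 = c(3.8, -0.7, 0)),
    stop("no template for residue ", resname))
}

#' Build a synthetic pseudo-protein with surface charge patches
#'
#' Residues are placed on a Fibonacci sphere of the given core radius,
#' alternating neutral Ala/Ser scaffold residues; residues whose direction
#' falls within a patch's angular radius of its center direction are replaced
#' by the patch residue type (Asp/Glu for negative patches, Lys/Arg for
#' positive).  Sidechains point radially outward so charged groups sit on the
#' surface.  Deterministic given the seed.
#'
#' @param nResidues residues on the sphere
#' @param coreRadius sphere radius in Angstrom (default 6, keeping all atoms well inside the desk-scale grid)
#' @param patches list of \code{list(center = unit 3-vector or NULL for a
#'   seeded random direction, angularRadius = degrees, resname = "ASP" etc.)}
#' @param seed RNG seed (jitter and random patch centers)
#' @param jitter coordinate jitter standard deviation, Angstrom
#' @return an \linkS4class{FvStructure} (parameters unassigned); the number
#'   of patch residues is recorded in provenance
#' @export
makeToyStructure <- function(nResidues = 40L, coreRadius = 6.0,
                             patches = list(), seed = 1L, jitter = 0.15) {
  dirs <- fibonacciSphere(nResidues)
  resnames <- rep(c("ALA", "SER"), length.out = nResidues)
  withSeed(seed, {
    for (p in patches) {
      center <- p$center %||% {
        v <- stats::rnorm(3)
        v / sqrt(sum(v^2))
      }
      cosang <- dirs %*% center
      hit <- cosang >= cos(p$angularRadius * pi / 180)
      resnames[hit] <- p$resname
    }
    nPatch <- sum(!resnames %in% c("ALA", "SER"))
    rows <- list()
    serial <- 0L
    half <- ceiling(nResidues / 2)
    for (i in seq_len(nResidues)) {
      u <- dirs[i, ]
      ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      t1 <- ref - sum(ref * u) * u
      t1 <- t1 / sqrt(sum(t1^2))
      t2 <- c(u[2] * t1[3] - u[3] * t1[2], u[3] * t1[1] - u[1] * t1[3],
              u[1] * t1[2] - u[2] * t1[1])
      tmpl <- residueTemplate(resnames[i])
      chain <- if (i <= half) "L" else "H"
      resno <- if (i <= half) i else i - half
      for (nm in names(tmpl)) {
        off <- tmpl[[nm]]
        pos <- (coreRadius + off[1]) * u + off[2] * t1 + off[3] * t2 +
          stats::rnorm(3, 0, jitter)
        serial <- serial + 1L
        rows[[serial]] <- data.frame(
          serial = serial, name = nm,
          element = substr(nm, 1, 1), resname = resnames[i], resno = resno,
          insert = "", chain = chain, x = pos[1], y = pos[2], z = pos[3],
          charge = NA_real_, radius = NA_real_,
          mass = unname(elementMasses[substr(nm, 1, 1)]),
          stringsAsFactors = FALSE)
      }
    }
    atoms <- do.call(rbind, rows)
    new("FvStructure", atoms = atoms,
        chains = c(L = "light", H = "heavy"),
        provenance = list(source = "synthetic", seed = seed,
                          nPatchResidues = nPatch, transforms = list()))
  })
}

#' Label-generating model for synthetic datasets
#'
#' log10(viscosity in cP) = intercept + slope * driver + Normal(0, noiseSd),
#' where the driver is computed by the package's own pipeline: the number of
#' surface-shell voxels whose electrostatic potential is below
#' \code{negEspThreshold} (negative-patch electrostatic area, in voxels), or
#' the clustered-negative-charge score.
#'
#' @param slope log10-cP per driver unit
#' @param intercept log10-cP
#' @param noiseSd log10-cP noise standard deviation
#' @param driver \code{"negative_patch_area"} or \code{"scm_score"}
#' @param negEspThreshold kT/e threshold defining a negative shell voxel
#' @return a \code{labelModel} list
#' @export
labelModel <- function(slope = 0.0025, intercept = 0.3, noiseSd = 0.1,
                       driver = "negative_patch_area", negEspThreshold = -0.5) {
  stopifnot(noiseSd >= 0)
  structure(list(slope = slope, intercept = intercept, noiseSd = noiseSd,
                 driver = driver, negEspThreshold = negEspThreshold),
            class = "labelModel")
}

#' Negative-patch electrostatic surface area (voxels)
#'
#' Featurizes the structure under the configuration and counts active shell
#' voxels with potential below the threshold.
#' @keywords internal
negativePatchArea <- function(s, cfg, threshold = -0.5) {
  occ <- computeSES(s, cfg$grid, cfg$probe)
  shell <- computeShell(occ, cfg$shellThickness)
  phi <- if (identical(cfg$solver, "debye"))
    solveDebye(s, cfg$grid, cfg$epsOut, cfg$ionicStrength)
  else
    solveESP(s, cfg$grid, occ, cfg$epsIn, cfg$epsOut, cfg$ionicStrength,
             cfg$tol, cfg$maxit)
  sum(shell@active & phi@values < threshold)
}

#' Generate a labelled synthetic dataset
#'
#' Structures with graded negative-patch sizes (patch angular radius swept
#' over \code{angularRange}, patch direction random per structure); labels in
#' cP from the \code{\link{labelModel}} applied to the driver value computed
#' with the package's own surface/electrostatics pipeline.
#'
#' @param n structures (at least 4)
#' @param model a \code{\link{labelModel}}
#' @param seed RNG seed
#' @param cfg run configuration used to compute the driver (default
#'   \code{\link{deskPreset}()})
#' @param angularRange degrees, smallest to largest patch
#' @return named list of records \code{list(structure, viscosity, driver,
#'   id)}; the label model is attached as an attribute
#' @export
makeLabeledDataset <- function(n = 24L, model = labelModel(), seed = 1L,
                               cfg = deskPreset(), angularRange = c(0, 75)) {
  if (n < 4) stop("n must be at least 4")
  radii <- seq(angularRange[1], angularRange[2], length.out = n)
  noise <- withSeed(seed, stats::rnorm(n, 0, model$noiseSd))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("syn%02d", i)
    patches <- if (radii[i] > 0)
      list(list(center = NULL, angularRadius = radii[i], resname = "ASP"))
    else list()
    s <- makeToyStructure(patches = patches, seed = as.integer(seed) + i * 97L)
    s <- canonicalize(assignParameters(s))
    s@provenance$structureId <- id
    driver <- if (model$driver == "negative_patch_area")
      negativePatchArea(s, cfg, model$negEspThreshold)
    else as.numeric(scmScore(s, computeSES(s, cfg$grid, cfg$probe)))
    eta <- 10^(model$intercept + model$slope * driver + noise[i])
    out[[i]] <- list(structure = s, viscosity = eta, driver = driver, id = id)
  }
  names(out) <- vapply(out, `[[`, "", "id")
  attr(out, "labelModel") <- model
  out
}

#' Featurize a synthetic dataset for training
#'
#' Rotation-augmented input grids per structure, labels and targets attached.
#'
#' @param dataset result of \code{\link{makeLabeledDataset}}
#' @param cfg run configuration
#' @param nRotations rotated samples per structure
#' @param seed RNG seed
#' @return named list: structure id -> list of \linkS4class{InputGrid}
#' @export
datasetGrids <- function(dataset, cfg, nRotations = 2L, seed = 1L) {
  out <- lapply(seq_along(dataset), function(i) {
    rec <- dataset[[i]]
    featurizeRotations(rec$structure, nRotations,
                       seed = as.integer(seed) + i * 131L, cfg = cfg,
                       label = rec$viscosity)
  })
  names(out) <- names(dataset)
  out
}
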