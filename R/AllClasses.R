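#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib espvisc, .registration = TRUE
NULL

#' Cubic grid geometry
#'
#' Describes the cubic voxel grid onto which surfaces and fields are sampled:
#' a physical region from \code{-extent} to \code{+extent} Angstrom along each
#' Cartesian axis with uniform \code{spacing}, giving
#' \code{2 * extent / spacing + 1} points per axis, embedded (zero padded,
#' centered) in a \code{paddedDim}^3 cube so the spatial size halves cleanly
#' through the network's pooling stages.
#'
#' @slot extent half-width of the physical region, Angstrom
#' @slot spacing voxel spacing, Angstrom
#' @slot paddedDim padded points per axis
#' @export
setClass("GridSpec", representation(extent = "numeric", spacing = "numeric",
                                    paddedDim = "integer"))

setValidity("GridSpec", function(object) {
  n <- 2 * object@extent / object@spacing + 1
  if (object@spacing <= 0) return("spacing must be positive")
  if (abs(n - round(n)) > 1e-9) return("2*extent/spacing must be an integer")
  if (object@paddedDim < round(n)) return("paddedDim smaller than physical grid")
  TRUE
})

#' Construct a GridSpec
#'
#' Defaults give the production grid: -36..+36 Angstrom at 0.75 Angstrom
#' spacing (97 physical points per axis) padded to 128^3 so that six pooling
#' halvings leave a 2^3 spatial map and a 1024-long flattened feature vector.
#'
#' @param extent half-width in Angstrom
#' @param spacing grid spacing in Angstrom
#' @param paddedDim padded cube dimension (voxels per axis)
#' @return a \linkS4class{GridSpec}
#' @export
gridSpec <- function(extent = 36, spacing = 0.75, paddedDim = 128L) {
  new("GridSpec", extent = extent, spacing = spacing,
      paddedDim = as.integer(paddedDim))
}

#' Number of physical grid points per axis
#' @param spec a \linkS4class{GridSpec}
#' @export
nPhysical <- function(spec) as.integer(round(2 * spec@extent / spec@spacing + 1))

#' Axis coordinates of the physical grid points
#' @param spec a \linkS4class{GridSpec}
#' @export
axisCoords <- function(spec) seq(-spec@extent, spec@extent, by = spec@spacing)

padOffset <- function(spec) as.integer((spec@paddedDim - nPhysical(spec)) %/% 2)

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: +/-%g A, spacing %g A (%d^3 physical, padded to %d^3)\n",
              object@extent, object@spacing, nPhysical(object), object@paddedDim))
})

#' Protein structure with per-atom parameters
#'
#' Atoms are held in a data frame (columns serial, name, element, resname,
#' resno, insert, chain, x, y, z, charge, radius, mass); \code{chains} maps
#' chain identifiers to their role (\code{heavy}, \code{light} or
#' \code{other}); \code{provenance} records the source and any rigid
#' transforms applied.
#'
#' @slot atoms data.frame of atoms
#' @slot chains named character vector of chain roles
#' @slot provenance list
#' @export
setClass("FvStructure", representation(atoms = "data.frame",
                                       chains = "character",
                                       provenance = "list"))

setValidity("FvStructure", function(object) {
  a <- object@atoms
  need <- c("serial", "name", "element", "resname", "resno", "insert",
            "chain", "x", "y", "z", "charge", "radius", "mass")
  if (!all(need %in% names(a))) return("atoms is missing required columns")
  if (nrow(a) == 0) return("structure has no atoms")
  if (!all(is.finite(as.matrix(a[, c("x", "y", "z")])))) return("non-finite coordinates")
  ok <- is.na(a$radius) | a$radius > 0
  if (!all(ok)) return("non-positive atomic radius")
  TRUE
})

setMethod("show", "FvStructure", function(object) {
  a <- object@atoms
  cat(sprintf("FvStructure: %d atoms, %d residues, chains: %s\n",
              nrow(a), nrow(unique(a[, c("chain", "resno", "insert")])),
              paste(sprintf("%s(%s)", names(object@chains), object@chains),
                    collapse = ", ")))
  if (!all(is.na(a$charge)))
    cat(sprintf("  net charge %+.3f e\n", sum(a$charge, na.rm = TRUE)))
})

#' Atom table accessor
#' @param x an \linkS4class{FvStructure}
#' @return data.frame of atoms
#' @export
atoms <- function(x) x@atoms

#' Chain role accessor
#' @param x an \linkS4class{FvStructure}
#' @export
chainRoles <- function(x) x@chains

#' Atom coordinates as a matrix
#' @param x an \linkS4class{FvStructure}
#' @export
coords <- function(x) as.matrix(x@atoms[, c("x", "y", "z")])

#' Per-residue Fv segment labels
#'
#' One row per residue with its segment label: \code{framework},
#' \code{CDR-L1..L3}, \code{CDR-H1..H3} or \code{unknown}.
#' @slot table data.frame with columns chain, resno, insert, segment
#' @export
setClass("SegmentMap", representation(table = "data.frame"))

setMethod("show", "SegmentMap", function(object) {
  cat("SegmentMap:\n")
  print(table(object@table$segment))
})

#' Solvent-excluded occupancy on a grid
#'
#' @slot spec the \linkS4class{GridSpec} (physical grid only)
#' @slot interior logical array, TRUE inside the solvent-excluded volume
#' @slot surfaceDistance numeric array, Angstrom distance of each exterior
#'   voxel center to the nearest interior voxel center (0 inside)
#' @export
setClass("OccupancyGrid", representation(spec = "GridSpec", interior = "array",
                                         surfaceDistance = "array"))

#' Exterior surface-shell mask
#' @slot spec the \linkS4class{GridSpec}
#' @slot active logical array, TRUE for exterior voxels within the shell
#' @export
setClass("ShellMask", representation(spec = "GridSpec", active = "array"))

setValidity("ShellMask", function(object) {
  if (!is.logical(object@active)) return("active must be logical")
  TRUE
})

#' Scalar field on the physical grid
#' @slot spec the \linkS4class{GridSpec}
#' @slot values numeric array (potential in kT/e for kind "esp")
#' @slot kind one of "esp", "eisenberg_phobic", "eisenberg_philic"
#' @export
setClass("ScalarField", representation(spec = "GridSpec", values = "array",
                                       kind = "character"))

setValidity("ScalarField", function(object) {
  if (!all(is.finite(object@values))) return("field contains non-finite values")
  TRUE
})

#' Masked, padded network input grid
#'
#' Channels of the padded cube; every voxel outside the surface-shell mask is
#' exactly zero.  Optionally carries the viscosity label (cP) and the
#' transformed training target.
#'
#' @slot spec the \linkS4class{GridSpec}
#' @slot data 4-d numeric array (paddedDim^3 x channels)
#' @slot mask padded logical array of shell membership
#' @slot channels channel names
#' @slot label viscosity in cP (length 0 or 1)
#' @slot target transformed training value (length 0 or 1)
#' @slot provenance list (structure id, rotation, featurization settings)
#' @export
setClass("InputGrid", representation(spec = "GridSpec", data = "array",
                                     mask = "array", channels = "character",
                                     label = "numeric", target = "numeric",
                                     provenance = "list"))

setValidity("InputGrid", function(object) {
  d <- dim(object@data)
  p <- object@spec@paddedDim
  if (length(d) != 4 || any(d[1:3] != p)) return("data must be paddedDim^3 x channels")
  if (d[4] != length(object@channels)) return("channel count mismatch")
  TRUE
})

setMethod("show", "InputGrid", function(object) {
  cat(sprintf("InputGrid: %d^3 x %d channel(s) [%s], %d nonzero voxels%s\n",
              object@spec@paddedDim, length(object@channels),
              paste(object@channels, collapse = ", "),
              sum(object@data != 0),
              if (length(object@label)) sprintf(", label %.3g cP", object@label) else ""))
})

#' Integrated-gradients attribution scores on the input grid
#' @slot spec the \linkS4class{GridSpec}
#' @slot scores numeric array, same shape as the input it explains
#' @slot source list (model/structure/rotation identifiers, prediction)
#' @export
setClass("AttributionGrid", representation(spec = "GridSpec", scores = "array",
                                           source = "list"))

setMethod("show", "AttributionGrid", function(object) {
  cat(sprintf("AttributionGrid: %d nonzero scores, range [%.3g, %.3g]\n",
              sum(object@scores != 0), min(object@scores), max(object@scores)))
})
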