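# Grid-based solvent-excluded (Connolly-style) surface and the exterior
# surface-shell mask.

#' Compute the solvent-excluded volume on the grid
#'
#' Two-pass morphological construction: voxels within (atom radius + probe)
#' of any atom center form the probe-inflated volume; voxels of that volume
#' that a probe sphere centered on any non-inflated voxel can reach are then
#' eroded away, leaving the solvent-excluded interior.  The exact Euclidean
#' distance transform used for the erosion also provides, for every exterior
#' voxel, the distance to the nearest interior voxel center.
#'
#' @param s an \linkS4class{FvStructure} with radii assigned
#' @param spec a \linkS4class{GridSpec}
#' @param probe probe sphere radius in Angstrom (default 1.4, water)
#' @return an \linkS4class{OccupancyGrid}
#' @export
computeSES <- function(s, spec = gridSpec(), probe = 1.4) {
  a <- s@atoms
  if (any(is.na(a$radius))) stop("radii not assigned; run assignParameters() first")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  out <- which(apply(abs(xyz), 1, max) > spec@extent - spec@spacing)
  if (length(out))
    stop(sprintf("atom(s) outside the +/-%g A grid extent: %s", spec@extent,
                 paste(a$serial[utils::head(out, 5)], collapse = ", ")))
  n <- nPhysical(spec)
  res <- cpp_ses(xyz, a$radius, n, spec@spacing, -spec@extent, probe)
  interior <- array(res$interior, dim = c(n, n, n))
  sdist <- array(cpp_edt(res$interior, n, spec@spacing), dim = c(n, n, n))
  sdist[interior] <- 0
  new("OccupancyGrid", spec = spec, interior = interior, surfaceDistance = sdist)
}

#' Exterior shell mask around the molecular surface
#'
#' Marks exterior voxels whose center lies within \code{thickness} of the
#' surface (measured as distance to the nearest interior voxel center);
#' interior voxels, where the potential is ill-defined, are never active.
#'
#' @param occ an \linkS4class{OccupancyGrid}
#' @param thickness shell thickness in Angstrom (default 2)
#' @return a \linkS4class{ShellMask}
#' @export
computeShell <- function(occ, thickness = 2) {
  active <- !occ@interior & occ@surfaceDistance <= thickness &
    is.finite(occ@surfaceDistance)
  new("ShellMask", spec = occ@spec, active = active)
}

#' Brute-force solvent-excluded volume (reference implementation)
#'
#' Tests every voxel against every admissible probe placement (probe centers
#' at voxel positions outside the probe-inflated volume).  Quadratic in voxel
#' count; intended only for small grids as an independent check of
#' \code{\link{computeSES}}.
#'
#' @inheritParams computeSES
#' @return logical array of the interior
#' @export
bruteForceSES <- function(s, spec, probe = 1.4) {
  a <- s@atoms
  n <- nPhysical(spec)
  ax <- axisCoords(spec)
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  xyz <- as.matrix(a[, c("x", "y", "z")])
  inflated <- rep(FALSE, nrow(g))
  for (i in seq_len(nrow(xyz))) {
    d2 <- (g[, 1] - xyz[i, 1])^2 + (g[, 2] - xyz[i, 2])^2 + (g[, 3] - xyz[i, 3])^2
    inflated <- inflated | d2 <= (a$radius[i] + probe)^2
  }
  probeCenters <- g[!inflated, , drop = FALSE]
  interior <- inflated
  idx <- which(inflated)
  p2 <- probe^2
  for (chunk in split(idx, ceiling(seq_along(idx) / 512))) {
    sub <- g[chunk, , drop = FALSE]
    d2 <- outer(sub[, 1], probeCenters[, 1], "-")^2 +
      outer(sub[, 2], probeCenters[, 2], "-")^2 +
      outer(sub[, 3], probeCenters[, 3], "-")^2
    reach <- apply(d2 <= p2, 1, any)
    interior[chunk[reach]] <- FALSE
  }
  array(interior, dim = c(n, n, n))
}
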