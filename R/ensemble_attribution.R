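# Averaging attribution maps over the (model x rotation) inference ensemble
# on a common unrotated frame.

#' Map an attribution grid back to the unrotated frame
#'
#' For every voxel of the unrotated frame, looks up the score at the nearest
#' voxel of the rotated frame (the voxel whose center is closest to the
#' rotated image of the query center).
#'
#' @param a an \linkS4class{AttributionGrid} computed on a rotated copy
#' @param R the rotation matrix that produced the rotated copy
#' @return an \linkS4class{AttributionGrid} in the unrotated frame
#' @export
alignAttribution <- function(a, R) {
  spec <- a@spec
  sc <- a@scores
  if (length(dim(sc)) == 4) sc <- sc[, , , 1]
  p <- spec@paddedDim
  nz <- which(sc != 0)
  out <- array(0, dim = dim(sc))
  if (length(nz)) {
    # score at rotated-frame voxel v describes the point R^-1 x_v of the
    # original structure; deposit it at the nearest unrotated voxel
    pts <- voxelCoords(spec, nz) %*% R  # R^-1 = t(R), applied as x %*% R
    off <- padOffset(spec)
    vi <- round((pts + spec@extent) / spec@spacing) + off + 1
    ok <- vi[, 1] >= 1 & vi[, 1] <= p & vi[, 2] >= 1 & vi[, 2] <= p &
      vi[, 3] >= 1 & vi[, 3] <= p
    idx <- vi[ok, 1] + p * (vi[ok, 2] - 1) + p * p * (vi[ok, 3] - 1)
    vals <- sc[nz[ok]]
    for (i in seq_along(idx)) out[idx[i]] <- out[idx[i]] + vals[i]
  }
  new("AttributionGrid", spec = spec,
      scores = array(out, dim = dim(a@scores)), source = a@source)
}

#' Ensemble-averaged integrated-gradients attribution
#'
#' Featurizes rotated copies of the structure, computes integrated gradients
#' per (model, rotation), maps each map back to the unrotated frame by the
#' inverse rotation with nearest-voxel resampling, and averages.
#'
#' @param ens a trained \code{viscEnsemble} with featurization metadata
#' @param s parameterized, canonicalized \linkS4class{FvStructure}
#' @param nRotations rotated copies
#' @param seed RNG seed for the rotations
#' @param steps integrated-gradients Riemann steps
#' @return an \linkS4class{AttributionGrid} (mean over models x rotations)
#' @export
ensembleAttribution <- function(ens, s, nRotations = 10L, seed = 1L,
                                steps = 128L) {
  cfg <- ens$meta
  if (is.null(cfg)) stop("ensemble has no featurization metadata")
  mats <- randomRotationMatrices(nRotations, seed)
  total <- NULL
  count <- 0L
  for (r in seq_len(nRotations)) {
    sr <- rotateStructure(s, mats[[r]], rotationId = r)
    g <- featurizeStructure(sr, cfg)
    for (m in seq_along(ens$models)) {
      a <- integratedGradients(ens$models[[m]]$net, g, steps = steps,
                               source = list(model = m, rotation = r))
      al <- alignAttribution(a, mats[[r]])
      total <- if (is.null(total)) al@scores else total + al@scores
      count <- count + 1L
    }
  }
  new("AttributionGrid", spec = cfg$grid, scores = total / count,
      source = list(structureId = s@provenance$structureId,
                    nModels = length(ens$models), nRotations = nRotations,
                    steps = steps))
}
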