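# Integrated-gradients attribution, significance thresholding, contiguous
# surface patch extraction and biophysical / segment / carboxylate analyses.

#' Integrated gradients attribution
#'
#' Path-integrated gradient of the prediction with respect to each input
#' voxel along the straight line from the baseline (all-zero grid by
#' default), using a midpoint Riemann sum:
#' scores_i = (x_i - b_i) / steps * sum_k dF/dx_i at b + (k - 1/2)/steps (x - b).
#' Scores satisfy completeness (they sum to F(x) - F(b) as steps grows) and
#' are exactly zero at zero-masked voxels.
#'
#' @param net a \code{viscNet} (or \code{viscNetFit})
#' @param x an \linkS4class{InputGrid}
#' @param baseline optional baseline grid/array (default all zeros)
#' @param steps Riemann steps (at least 8; default 128)
#' @param source identifier list stored on the result
#' @return an \linkS4class{AttributionGrid}
#' @export
integratedGradients <- function(net, x, baseline = NULL, steps = 128L,
                                source = list()) {
  if (inherits(net, "viscNetFit")) net <- net$net
  if (steps < 8) stop("steps must be at least 8")
  xv <- gridVector(x)
  bv <- if (is.null(baseline)) numeric(length(xv)) else gridVector(baseline)
  if (length(bv) != length(xv)) stop("baseline shape does not match input")
  diff <- xv - bv
  acc <- numeric(length(xv))
  for (k in seq_len(steps)) {
    alpha <- (k - 0.5) / steps
    g <- cpp_net_input_grad(net$weights, net$channels, net$dims,
                            bv + alpha * diff)
    if (!all(is.finite(g$gradient))) stop("non-finite gradients")
    acc <- acc + g$gradient
  }
  scores <- diff * acc / steps
  pred <- forwardNet(net, x)
  predBase <- cpp_net_forward(net$weights, net$channels, net$dims, bv)
  new("AttributionGrid", spec = x@spec,
      scores = array(scores, dim = dim(x@data)),
      source = c(source, list(prediction = pred, baselinePrediction = predBase,
                              steps = steps)))
}

#' Pooled significance threshold
#'
#' Pools the nonzero attribution scores of all grids (the test-set molecules
#' of one model) and returns the population standard deviation of that
#' distribution as the significance threshold.
#'
#' @param attrs list of \linkS4class{AttributionGrid}
#' @return the threshold sigma (numeric, attribute \code{n} = pooled count)
#' @export
poolSignificance <- function(attrs) {
  if (!length(attrs)) stop("empty attribution list")
  pooled <- unlist(lapply(attrs, function(a) {
    v <- as.numeric(a@scores)
    v[v != 0]
  }))
  if (!length(pooled)) stop("all attribution scores are zero")
  sigma <- sqrt(mean((pooled - mean(pooled))^2))
  if (sigma == 0) stop("degenerate attribution distribution")
  structure(sigma, n = length(pooled))
}

neighborOffsets <- function(spacing, linkDist) {
  r <- floor(linkDist / spacing)
  off <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  keep <- (off$dx^2 + off$dy^2 + off$dz^2) * spacing^2 <= linkDist^2 &
    !(off$dx == 0 & off$dy == 0 & off$dz == 0)
  as.matrix(off[keep, , drop = FALSE])
}

#' Extract contiguous significant-attribution patches
#'
#' Voxels with |score| above the threshold are grouped, separately by sign,
#' into connected components in which two voxels are linked when their
#' centers are within \code{linkDist} (default 1.5 Angstrom, twice the
#' production grid spacing).  Patches are sorted by size (descending), ties
#' broken by sign then smallest voxel index.
#'
#' @param a an \linkS4class{AttributionGrid} (single channel)
#' @param thr threshold from \code{\link{poolSignificance}} (or a number)
#' @param linkDist linkage distance in Angstrom
#' @return list of patches: \code{list(voxels, sign, size)}
#' @export
findPatches <- function(a, thr, linkDist = 1.5) {
  spacing <- a@spec@spacing
  if (linkDist < spacing) stop("linkDist must be at least the grid spacing")
  sc <- a@scores
  if (length(dim(sc)) == 4) sc <- sc[, , , 1]
  d <- dim(sc)[1]
  sigma <- as.numeric(thr)
  patches <- list()
  off <- neighborOffsets(spacing, linkDist)
  for (sgn in c(1, -1)) {
    idx <- which(if (sgn > 0) sc > sigma else sc < -sigma)
    if (!length(idx)) next
    inSet <- new.env(hash = TRUE, parent = emptyenv())
    for (i in idx) assign(as.character(i), TRUE, envir = inSet)
    visited <- new.env(hash = TRUE, parent = emptyenv())
    for (start in idx) {
      if (!is.null(visited[[as.character(start)]])) next
      comp <- integer(0)
      queue <- start
      visited[[as.character(start)]] <- TRUE
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        comp <- c(comp, v)
        v0 <- v - 1L
        x <- v0 %% d; y <- (v0 %/% d) %% d; z <- v0 %/% (d * d)
        nx <- x + off[, 1]; ny <- y + off[, 2]; nz <- z + off[, 3]
        ok <- nx >= 0 & nx < d & ny >= 0 & ny < d & nz >= 0 & nz < d
        nb <- 1L + nx[ok] + d * (ny[ok] + d * nz[ok])
        for (w in nb) {
          kw <- as.character(w)
          if (!is.null(inSet[[kw]]) && is.null(visited[[kw]])) {
            visited[[kw]] <- TRUE
            queue <- c(queue, w)
          }
        }
      }
      patches[[length(patches) + 1]] <-
        list(voxels = sort(comp), sign = if (sgn > 0) "positive" else "negative",
             size = length(comp))
    }
  }
  if (!length(patches)) return(list())
  ord <- order(-vapply(patches, `[[`, 1L, "size"),
               vapply(patches, `[[`, "", "sign"),
               vapply(patches, function(p) min(p$voxels), 1L))
  patches[ord]
}

#' Physical coordinates of padded-grid voxel indices
#' @keywords internal
voxelCoords <- function(spec, idx) {
  p <- spec@paddedDim
  off <- padOffset(spec)
  v0 <- idx - 1L
  i <- v0 %% p; j <- (v0 %/% p) %% p; k <- v0 %/% (p * p)
  cbind(x = -spec@extent + (i - off) * spec@spacing,
        y = -spec@extent + (j - off) * spec@spacing,
        z = -spec@extent + (k - off) * spec@spacing)
}

nearestHeavyAtom <- function(pts, s) {
  a <- s@atoms[s@atoms$element != "H", , drop = FALSE]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  idx <- vapply(seq_len(nrow(pts)), function(i) {
    d2 <- (xyz[, 1] - pts[i, 1])^2 + (xyz[, 2] - pts[i, 2])^2 +
      (xyz[, 3] - pts[i, 3])^2
    which.min(d2)
  }, 1L)
  a[idx, , drop = FALSE]
}

backboneNames <- c("N", "CA", "C", "O", "OXT")
aromaticResidues <- c("HIS", "PHE", "TYR", "TRP")
carboxylAtoms <- list(ASP = c("CG", "OD1", "OD2"), GLU = c("CD", "OE1", "OE2"))

atomCategory <- function(atom) {
  resname <- atom$resname; name <- atom$name; element <- atom$element
  sidechain <- !(name %in% backboneNames)
  if (resname %in% c("ASP", "GLU") && sidechain) return("asp_glu")
  if (element == "O") {
    carbox <- resname %in% c("ASP", "GLU") &&
      name %in% carboxylAtoms[[resname]]
    if (!carbox) return("acceptor")
  }
  if (resname %in% aromaticResidues && sidechain) return("aromatic")
  if (element == "N") return("donor")
  if (resname == "LYS" && name %in% c("NZ")) return("donor")
  if (resname == "ARG" && name %in% c("NE", "CZ", "NH1", "NH2")) return("donor")
  if (element == "C") return("lipophilic")
  "lipophilic"
}

#' Biophysical composition of a patch
#'
#' Assigns each patch voxel the category of its nearest protein heavy atom
#' with the priority: Asp/Glu sidechain > hydrogen-bond acceptor (any oxygen
#' except the Asp/Glu carboxylate) > aromatic sidechain (His/Phe/Tyr/Trp) >
#' hydrogen-bond donor (nitrogens, the Lys amine, the Arg guanidine group) >
#' lipophilic (remaining carbons).  Also reports the mainchain-carbonyl
#' sub-fraction of the acceptor category.
#'
#' @param patch a patch from \code{\link{findPatches}}
#' @param s the \linkS4class{FvStructure} the attribution grid was computed on
#' @param spec the \linkS4class{GridSpec} of the attribution grid
#' @return list with \code{fractions} (named, summing to 1) and
#'   \code{acceptorMainchainFraction}
#' @export
classifyPatchPoints <- function(patch, s, spec) {
  if (!length(patch$voxels)) stop("empty patch")
  pts <- voxelCoords(spec, patch$voxels)
  near <- nearestHeavyAtom(pts, s)
  cats <- vapply(seq_len(nrow(near)), function(i) atomCategory(near[i, ]), "")
  lev <- c("asp_glu", "acceptor", "aromatic", "donor", "lipophilic")
  fr <- table(factor(cats, levels = lev)) / length(cats)
  accIdx <- which(cats == "acceptor")
  accMain <- if (length(accIdx))
    mean(near$name[accIdx] %in% c("O", "OXT")) else NA_real_
  list(fractions = stats::setNames(as.numeric(fr), lev),
       acceptorMainchainFraction = accMain)
}

#' Fv-segment composition of a patch
#'
#' Assigns each patch voxel the segment (framework / CDR loop) of the residue
#' owning its nearest heavy atom and returns the fractional composition.
#'
#' @param patch a patch from \code{\link{findPatches}}
#' @param seg a \linkS4class{SegmentMap} covering the structure
#' @param s the \linkS4class{FvStructure}
#' @param spec the \linkS4class{GridSpec}
#' @return named numeric vector of fractions (sums to 1)
#' @export
segmentComposition <- function(patch, seg, s, spec) {
  if (!length(patch$voxels)) stop("empty patch")
  pts <- voxelCoords(spec, patch$voxels)
  near <- nearestHeavyAtom(pts, s)
  key <- paste(near$chain, near$resno, near$insert, sep = "|")
  segKey <- paste(seg@table$chain, seg@table$resno, seg@table$insert, sep = "|")
  labels <- seg@table$segment[match(key, segKey)]
  labels[is.na(labels)] <- "unknown"
  if (all(labels == "unknown"))
    warning("segment map labels every residue unknown")
  fr <- table(labels) / length(labels)
  stats::setNames(as.numeric(fr), names(fr))
}

#' Proximal vs. distal carboxylate attribution
#'
#' Asp/Glu residues are split by the minimum distance from their carboxyl
#' atoms to the nearest cation center (Lys NZ or an Arg guanidine heavy
#' atom): proximal when at most \code{proximalMax} (3.5 Angstrom), distal
#' when at least \code{distalMin} (5 Angstrom); residues in between are
#' excluded.  A grid point is associated with a carboxylate when its nearest
#' protein heavy atom belongs to the carboxyl motif and it lies within
#' \code{assocMax} (4 Angstrom) of one of the three carboxyl atoms.  The mean
#' attribution score of each set is returned.
#'
#' @param a an \linkS4class{AttributionGrid}
#' @param s the \linkS4class{FvStructure}
#' @param proximalMax,distalMin,assocMax distance thresholds in Angstrom
#' @return list(proximal, distal) mean scores (NA with a \code{missing} flag
#'   when a set is empty)
#' @export
carboxylateAttribution <- function(a, s, proximalMax = 3.5, distalMin = 5,
                                   assocMax = 4.0) {
  at <- s@atoms
  acidic <- at[at$resname %in% c("ASP", "GLU"), , drop = FALSE]
  if (!nrow(acidic)) stop("structure contains no Asp/Glu residues")
  acidKey <- paste(acidic$chain, acidic$resno, acidic$insert, sep = "|")
  resKey <- unique(acidKey)
  cations <- at[(at$resname == "LYS" & at$name == "NZ") |
                  (at$resname == "ARG" & at$name %in% c("NE", "CZ", "NH1", "NH2")),
                , drop = FALSE]
  classOf <- function(key) {
    sub <- acidic[acidKey == key, , drop = FALSE]
    carb <- sub[sub$name %in% carboxylAtoms[[sub$resname[1]]], , drop = FALSE]
    if (!nrow(carb)) return(list(class = "excluded", carb = carb))
    dmin <- if (nrow(cations)) {
      min(vapply(seq_len(nrow(carb)), function(i)
        min(sqrt((cations$x - carb$x[i])^2 + (cations$y - carb$y[i])^2 +
                   (cations$z - carb$z[i])^2)), 1.0))
    } else Inf
    cls <- if (dmin <= proximalMax) "proximal"
           else if (dmin >= distalMin) "distal" else "excluded"
    list(class = cls, carb = carb)
  }
  info <- lapply(resKey, classOf)
  names(info) <- resKey

  sc <- a@scores
  if (length(dim(sc)) == 4) sc <- sc[, , , 1]
  nz <- which(sc != 0)
  pts <- voxelCoords(a@spec, nz)
  near <- nearestHeavyAtom(pts, s)
  nearKey <- paste(near$chain, near$resno, near$insert, sep = "|")
  nearIsCarb <- vapply(seq_len(nrow(near)), function(i) {
    rn <- near$resname[i]
    rn %in% c("ASP", "GLU") && near$name[i] %in% carboxylAtoms[[rn]]
  }, TRUE)

  meanFor <- function(cls) {
    keys <- resKey[vapply(info, `[[`, "", "class") == cls]
    if (!length(keys)) return(structure(NA_real_, missing = TRUE))
    vals <- numeric(0)
    for (key in keys) {
      carb <- info[[key]]$carb
      cand <- which(nearIsCarb & nearKey == key)
      if (!length(cand)) next
      d <- vapply(cand, function(ci) {
        min(sqrt((carb$x - pts[ci, 1])^2 + (carb$y - pts[ci, 2])^2 +
                   (carb$z - pts[ci, 3])^2))
      }, 1.0)
      sel <- cand[d < assocMax]
      vals <- c(vals, sc[nz[sel]])
    }
    if (!length(vals)) return(structure(NA_real_, missing = TRUE))
    mean(vals)
  }
  list(proximal = meanFor("proximal"), distal = meanFor("distal"))
}
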