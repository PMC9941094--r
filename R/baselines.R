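# Comparison baselines: the re-trainable three-feature sequence model
# (net charge, charge-symmetry product, hydrophobicity index) and a
# structure-based clustered-negative-charge score.

henderson <- function(seq, pH, pka, termini = FALSE) {
  aa <- strsplit(seq, "")[[1]]
  if (!all(aa %in% readTable("eisenberg")$aa))
    stop("invalid amino-acid letter(s): ",
         paste(unique(aa[!aa %in% readTable("eisenberg")$aa]), collapse = ", "))
  q <- 0
  for (site in c("D", "E")) {
    n <- sum(aa == site)
    pk <- pka$pka[pka$site == site]
    q <- q - n / (1 + 10^(pk - pH))
  }
  for (site in c("H", "K", "R")) {
    n <- sum(aa == site)
    pk <- pka$pka[pka$site == site]
    q <- q + n / (1 + 10^(pH - pk))
  }
  if (termini) {
    q <- q + 1 / (1 + 10^(pH - pka$pka[pka$site == "nterm"]))
    q <- q - 1 / (1 + 10^(pka$pka[pka$site == "cterm"] - pH))
  }
  q
}

#' Sequence-derived viscosity features
#'
#' Henderson-Hasselbalch fractional charges (bundled pKa table over D, E, H,
#' K, R, optionally the termini) give per-chain net charges; returns the Fv
#' net charge, the VL x VH charge-symmetry product, and a hydrophobicity
#' index (sum of positive Eisenberg values over |sum of negative values|).
#'
#' @param vlSeq,vhSeq one-letter light/heavy chain sequences
#' @param pH solution pH
#' @param termini include charged termini
#' @param hiFallback hydrophobicity index when a chain pair has no
#'   hydrophilic residues (denominator zero)
#' @return list(qNet, csp, hi, qVL, qVH)
#' @export
sharmaFeatures <- function(vlSeq, vhSeq, pH = 5.8, termini = FALSE,
                           hiFallback = NA_real_) {
  pka <- readTable("pka")
  qVL <- henderson(vlSeq, pH, pka, termini)
  qVH <- henderson(vhSeq, pH, pka, termini)
  eis <- readTable("eisenberg")
  aa <- strsplit(paste0(vlSeq, vhSeq), "")[[1]]
  sc <- eis$scale[match(aa, eis$aa)]
  phob <- sum(sc[sc > 0])
  phil <- abs(sum(sc[sc < 0]))
  hi <- if (phil > 0) phob / phil else hiFallback
  list(qNet = qVL + qVH, csp = qVL * qVH, hi = hi, qVL = qVL, qVH = qVH)
}

#' Fit the three-feature linear viscosity model
#'
#' Ordinary least squares of the (optionally log10-transformed) viscosity on
#' net charge, charge-symmetry product and hydrophobicity index.
#'
#' @param features data.frame (or list of feature lists) with columns
#'   qNet, csp, hi
#' @param labels viscosity in cP
#' @param transform \code{"log10"} or \code{"raw"}
#' @return a \code{sharmaModel} with coefficients and a predict method
#' @export
fitSharma <- function(features, labels, transform = "log10") {
  if (!is.data.frame(features))
    features <- do.call(rbind, lapply(features, function(f)
      data.frame(qNet = f$qNet, csp = f$csp, hi = f$hi)))
  if (nrow(features) < 4) stop("at least 4 samples required")
  y <- applyTransform(labels, transform)
  fit <- stats::lm(y ~ qNet + csp + hi, data = features)
  if (any(is.na(stats::coef(fit)))) stop("rank-deficient design")
  structure(list(coefficients = stats::coef(fit), transform = transform,
                 fit = fit), class = "sharmaModel")
}

#' @export
predict.sharmaModel <- function(object, newdata, ...) {
  if (!is.data.frame(newdata))
    newdata <- do.call(rbind, lapply(newdata, function(f)
      data.frame(qNet = f$qNet, csp = f$csp, hi = f$hi)))
  unname(invertTransform(stats::predict(object$fit, newdata = newdata),
                         object$transform))
}

#' @export
print.sharmaModel <- function(x, ...) {
  cat("sharmaModel:", x$transform, "scale\n")
  print(x$coefficients)
  invisible(x)
}

fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Clustered negative surface charge score
#'
#' For every solvent-exposed heavy atom (exposure = fraction of probe points
#' on a sphere of radius atom-radius + probe that fall outside the
#' solvent-excluded volume, above a threshold), sums the partial charges of
#' all atoms within the neighborhood radius; the score is the magnitude of
#' the total of the negative neighborhood sums.  Larger scores indicate
#' larger or denser negative surface charge clusters.
#'
#' @param s a parameterized \linkS4class{FvStructure}
#' @param occ \linkS4class{OccupancyGrid} for the exposure test
#' @param exposureThreshold minimum exposed-point fraction (default 0.1)
#' @param radius neighborhood radius in Angstrom (default 10)
#' @param probe probe radius used for the exposure sphere
#' @param nSpherePoints probe points per atom
#' @return the score (numeric, attributes \code{nExposed})
#' @export
scmScore <- function(s, occ, exposureThreshold = 0.1, radius = 10,
                     probe = 1.4, nSpherePoints = 92L) {
  a <- s@atoms
  if (any(is.na(a$charge))) stop("charges not assigned")
  heavy <- which(a$element != "H")
  spec <- occ@spec
  n <- nPhysical(spec)
  sph <- fibonacciSphere(nSpherePoints)
  interior <- occ@interior
  exposedFrac <- vapply(heavy, function(i) {
    pts <- sph * (a$radius[i] + probe)
    pts[, 1] <- pts[, 1] + a$x[i]
    pts[, 2] <- pts[, 2] + a$y[i]
    pts[, 3] <- pts[, 3] + a$z[i]
    vi <- round((pts + spec@extent) / spec@spacing) + 1
    inside <- vi[, 1] >= 1 & vi[, 1] <= n & vi[, 2] >= 1 & vi[, 2] <= n &
      vi[, 3] >= 1 & vi[, 3] <= n
    ext <- !inside
    if (any(inside))
      ext[inside] <- !interior[cbind(vi[inside, 1], vi[inside, 2], vi[inside, 3])]
    mean(ext)
  }, 1.0)
  exposed <- heavy[exposedFrac > exposureThreshold]
  if (!length(exposed)) stop("no solvent-exposed atoms")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  score <- 0
  for (i in exposed) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- sum(a$charge[d2 <= radius^2])
    score <- score + min(0, nb)
  }
  structure(abs(score), nExposed = length(exposed))
}
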