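# The 3D convolutional regression network: architecture, training protocol
# (batch size 1, Adam, Huber loss, last-window checkpoint selection),
# cross-validation ensembling, leave-one-out protocol and ensemble inference.

#' Network and training configuration
#'
#' Defaults are the production settings: 6 convolution blocks (3x3x3 kernels,
#' ReLU, max pooling that halves the spatial size) starting at 4 filters and
#' doubling per block, a 0.05-dropout flattened feature vector into a single
#' linear output node, Glorot initialization, Huber loss, Adam with default
#' moments, learning rate 1e-5, batch size 1, 2000 epochs, and checkpoint
#' selection as the best validation loss within the last 50 epochs.
#'
#' @param nBlocks convolution blocks
#' @param firstFilters filters in the first block (doubled per block)
#' @param dropout dropout rate on the flattened feature vector
#' @param learningRate fixed Adam learning rate
#' @param epochs training epochs
#' @param selectionWindow final epochs eligible for checkpoint selection
#' @param huberDelta Huber loss transition point
#' @param targetTransform \code{"log10"} (default) or \code{"raw"} cP target
#' @param adamBeta1,adamBeta2,adamEps Adam moment parameters
#' @return a \code{netConfig} list
#' @export
netConfig <- function(nBlocks = 6L, firstFilters = 4L, dropout = 0.05,
                      learningRate = 1e-5, epochs = 2000L,
                      selectionWindow = 50L, huberDelta = 1,
                      targetTransform = "log10", adamBeta1 = 0.9,
                      adamBeta2 = 0.999, adamEps = 1e-8) {
  stopifnot(nBlocks >= 1, firstFilters >= 1, dropout >= 0, dropout < 1,
            learningRate > 0, epochs >= 1, selectionWindow >= 1, huberDelta > 0)
  structure(list(nBlocks = as.integer(nBlocks),
                 firstFilters = as.integer(firstFilters), dropout = dropout,
                 learningRate = learningRate, epochs = as.integer(epochs),
                 batchSize = 1L, selectionWindow = as.integer(selectionWindow),
                 huberDelta = huberDelta, targetTransform = targetTransform,
                 adamBeta1 = adamBeta1, adamBeta2 = adamBeta2,
                 adamEps = adamEps),
            class = "netConfig")
}

#' Build an untrained network
#'
#' Filter counts double per block; each pooling halves the spatial size, so
#' the input dimension must be divisible by 2^nBlocks.  With the default 6
#' blocks and a 128^3 single-channel input the final convolution output
#' flattens to a 1024-long feature vector.  Weights are Glorot-uniform
#' initialized from the current RNG state.
#'
#' @param cfg a \code{\link{netConfig}}
#' @param inChannels input channels (1 electrostatic, 2 Eisenberg, 3 combined)
#' @param inDim padded input voxels per axis
#' @return a \code{viscNet} object
#' @export
buildNet <- function(cfg, inChannels = 1L, inDim = 128L) {
  if (inDim %% 2^cfg$nBlocks != 0)
    stop(sprintf("input dimension %d is not divisible by 2^%d", inDim, cfg$nBlocks))
  channels <- c(inChannels, cfg$firstFilters * 2^(0:(cfg$nBlocks - 1)))
  dims <- as.integer(inDim / 2^(0:cfg$nBlocks))
  fcLen <- channels[length(channels)] * dims[length(dims)]^3
  glorot <- function(nin, nout, count) {
    lim <- sqrt(6 / (nin + nout))
    stats::runif(count, -lim, lim)
  }
  weights <- list()
  for (b in seq_len(cfg$nBlocks)) {
    cin <- channels[b]; cout <- channels[b + 1]
    weights[[2 * b - 1]] <- glorot(27 * cin, 27 * cout, 27 * cin * cout)
    weights[[2 * b]] <- rep(0, cout)
  }
  weights[[2 * cfg$nBlocks + 1]] <- glorot(fcLen, 1, fcLen)
  weights[[2 * cfg$nBlocks + 2]] <- 0
  structure(list(weights = weights, channels = as.integer(channels),
                 dims = dims, fcLen = as.integer(fcLen), cfg = cfg,
                 inChannels = as.integer(inChannels), inDim = as.integer(inDim)),
            class = "viscNet")
}

#' Number of trainable parameters
#' @param net a \code{viscNet}
#' @export
nParams <- function(net) sum(vapply(net$weights, length, 1L))

#' @export
print.viscNet <- function(x, ...) {
  cat(sprintf("viscNet: %d blocks, filters %s, input %d^3 x %d, flatten %d, %d parameters\n",
              x$cfg$nBlocks, paste(x$channels[-1], collapse = "-"), x$inDim,
              x$inChannels, x$fcLen, nParams(x)))
  invisible(x)
}

gridVector <- function(g) {
  if (is(g, "InputGrid")) as.double(g@data) else as.double(g)
}

#' Forward pass (target scale)
#'
#' Runs the network in inference mode (dropout off) on one input grid and
#' returns the prediction on the training-target scale.
#'
#' @param net a \code{viscNet}
#' @param x an \linkS4class{InputGrid} or numeric array of matching shape
#' @export
forwardNet <- function(net, x) {
  cpp_net_forward(net$weights, net$channels, net$dims, gridVector(x))
}

gridStructureId <- function(g) {
  id <- g@provenance$structureId
  if (is.null(id) || is.na(id)) "unknown" else as.character(id)
}

#' Train one cross-validation fold
#'
#' Trains for the configured number of epochs with batch size 1, evaluating
#' the validation loss every epoch, and restores the checkpoint with the
#' minimum validation loss among the final selection window (ties broken by
#' the later epoch).  Deterministic given the seed.
#'
#' @param train,val lists of \linkS4class{InputGrid} with targets set; the two
#'   lists must be disjoint by structure id (all rotations of a structure stay
#'   on one side)
#' @param cfg a \code{\link{netConfig}}
#' @param seed RNG seed (weight init and training loop)
#' @param foldId integer tag stored on the result
#' @param allowOverlap permit overlapping train/validation sets (sanity runs
#'   only; cross-validation splits must stay disjoint by structure)
#' @return a \code{viscNetFit}: the trained \code{net} plus training log,
#'   \code{selectedEpoch} and fold metadata
#' @export
trainFold <- function(train, val, cfg, seed = 1L, foldId = NA_integer_,
                      allowOverlap = FALSE) {
  if (!length(train) || !length(val)) stop("empty training or validation split")
  idsT <- vapply(train, gridStructureId, "")
  idsV <- vapply(val, gridStructureId, "")
  if (!allowOverlap && length(intersect(idsT, idsV)) && !all(idsT == "unknown"))
    stop("structure id(s) present in both train and validation: ",
         paste(intersect(idsT, idsV), collapse = ", "))
  tr <- vapply(train, function(g) {
    if (!length(g@target)) stop("training grid without target")
    g@target
  }, 1.0)
  tv <- vapply(val, function(g) {
    if (!length(g@target)) stop("validation grid without target")
    g@target
  }, 1.0)
  dimIn <- dim(train[[1]]@data)
  net <- withSeed(seed, buildNet(cfg, inChannels = dimIn[4], inDim = dimIn[1]))
  fit <- cpp_net_train(net$weights, net$channels, net$dims,
                       lapply(train, gridVector), tr,
                       lapply(val, gridVector), tv,
                       cfg$epochs, cfg$learningRate, cfg$dropout,
                       cfg$huberDelta, cfg$selectionWindow, as.integer(seed),
                       cfg$adamBeta1, cfg$adamBeta2, cfg$adamEps)
  net$weights <- fit$weights
  structure(list(net = net, trainLoss = fit$train_loss, valLoss = fit$val_loss,
                 selectedEpoch = fit$selected_epoch, bestVal = fit$best_val,
                 foldId = foldId, seed = seed,
                 trainIds = unique(idsT), valIds = unique(idsV)),
            class = "viscNetFit")
}

#' @export
print.viscNetFit <- function(x, ...) {
  cat(sprintf("viscNetFit (fold %s): selected epoch %d, val loss %.4g\n",
              x$foldId, x$selectedEpoch, x$bestVal))
  invisible(x)
}

#' Assign structures to cross-validation folds
#' @keywords internal
cvFolds <- function(ids, k, seed) {
  if (k > length(ids)) stop("more folds than structures")
  withSeed(seed, {
    fold <- rep(seq_len(k), length.out = length(ids))
    stats::setNames(sample(fold), ids)
  })
}

#' Train a cross-validation ensemble
#'
#' Splits the structures into \code{k} folds (by structure id, so all
#' rotations of one structure stay together), trains one network per fold
#' with the remaining folds as training data, and returns the ensemble.  The
#' production protocol uses a 10-fold split giving an ensemble of 10 models.
#'
#' @param gridsByStructure named list: structure id -> list of
#'   \linkS4class{InputGrid} (its rotated samples), targets set
#' @param k number of folds
#' @param cfg a \code{\link{netConfig}}
#' @param seed RNG seed (fold assignment; per-fold seeds derived)
#' @param meta featurization metadata stored for inference (a run
#'   configuration, see \code{\link{deskPreset}})
#' @return a \code{viscEnsemble}
#' @export
trainCVEnsemble <- function(gridsByStructure, k = 10L, cfg = netConfig(),
                            seed = 1L, meta = NULL) {
  ids <- names(gridsByStructure)
  if (is.null(ids)) stop("gridsByStructure must be a named list")
  folds <- cvFolds(ids, k, seed)
  models <- vector("list", k)
  for (f in seq_len(k)) {
    trIds <- ids[folds[ids] != f]
    vaIds <- ids[folds[ids] == f]
    train <- unlist(lapply(gridsByStructure[trIds], identity), recursive = FALSE)
    val <- unlist(lapply(gridsByStructure[vaIds], identity), recursive = FALSE)
    models[[f]] <- trainFold(train, val, cfg, seed = as.integer(seed) + f,
                             foldId = f)
  }
  structure(list(models = models, folds = folds, cfg = cfg, meta = meta,
                 seed = seed), class = "viscEnsemble")
}

#' @export
print.viscEnsemble <- function(x, ...) {
  cat(sprintf("viscEnsemble: %d cross-validation models over %d structures\n",
              length(x$models), length(x$folds)))
  invisible(x)
}

#' Wrap pre-built networks as an ensemble
#'
#' Useful for protocol audits and attribution tooling when trained weights
#' are not needed.
#' @param nets list of \code{viscNet}
#' @param meta featurization metadata (run configuration)
#' @export
asEnsemble <- function(nets, meta = NULL) {
  models <- lapply(seq_along(nets), function(i)
    structure(list(net = nets[[i]], foldId = i), class = "viscNetFit"))
  structure(list(models = models, folds = integer(0),
                 cfg = nets[[1]]$cfg, meta = meta, seed = NA),
            class = "viscEnsemble")
}

#' Leave-one-out split audit
#'
#' For two disjoint id sets A and B, each fold leaves one member of A out as
#' the test case and trains on the remaining members of A plus all of B (with
#' |A| = 21 and |B| = 38 every fold trains on 58 structures).
#'
#' @param idsA,idsB character vectors of structure ids
#' @return list of folds, each \code{list(test, train)}
#' @export
loocvSplits <- function(idsA, idsB) {
  if (length(intersect(idsA, idsB))) stop("the two sets overlap")
  lapply(idsA, function(a) list(test = a, train = c(setdiff(idsA, a), idsB)))
}

#' Leave-one-out cross-validation protocol
#'
#' Runs the full protocol: for every structure in set A, a cross-validation
#' ensemble is trained on (A minus that structure) union B and used to
#' predict the left-out structure.
#'
#' @param gridsA,gridsB named lists of per-structure \linkS4class{InputGrid}
#'   lists (disjoint names)
#' @param k folds for each inner ensemble
#' @param cfg a \code{\link{netConfig}}
#' @param seed RNG seed
#' @return list of \code{viscPrediction} records, one per member of A
#' @export
loocvProtocol <- function(gridsA, gridsB, k = 10L, cfg = netConfig(), seed = 1L) {
  if (length(intersect(names(gridsA), names(gridsB))))
    stop("the two sets overlap")
  out <- vector("list", length(gridsA))
  names(out) <- names(gridsA)
  for (i in seq_along(gridsA)) {
    id <- names(gridsA)[i]
    trainSet <- c(gridsA[setdiff(names(gridsA), id)], gridsB)
    ens <- trainCVEnsemble(trainSet, k = k, cfg = cfg,
                           seed = as.integer(seed) + i * 100L)
    out[[i]] <- predictFromGrids(ens, gridsA[[id]], id = id)
  }
  out
}

#' Predict from already-featurized grids
#'
#' Runs every model of the ensemble on every supplied grid (rotated samples
#' of one structure), inverse-transforms each prediction to cP and averages.
#'
#' @param ens a \code{viscEnsemble}
#' @param grids list of \linkS4class{InputGrid} for one structure
#' @param id structure identifier for the record
#' @return a \code{viscPrediction}
#' @export
predictFromGrids <- function(ens, grids, id = "structure") {
  transform <- ens$cfg$targetTransform
  preds <- numeric(0)
  for (m in ens$models)
    for (g in grids)
      preds <- c(preds, invertTransform(forwardNet(m$net, g), transform))
  structure(list(id = id, predictions = preds, final = mean(preds),
                 nPredictions = length(preds),
                 nModels = length(ens$models), nRotations = length(grids)),
            class = "viscPrediction")
}

#' Ensemble viscosity prediction for a structure
#'
#' Featurizes \code{nRotations} randomly rotated copies of the structure with
#' the ensemble's stored featurization settings, runs each through every
#' cross-validation model (dropout off), inverse-transforms to cP and
#' averages.  The production protocol (10 rotations x 10 models) yields 100
#' predictions per molecule.
#'
#' @param ens a \code{viscEnsemble} with featurization metadata
#' @param s a parameterized, canonicalized \linkS4class{FvStructure}
#' @param nRotations rotated copies for the inference ensemble
#' @param seed RNG seed for the rotations
#' @param id structure identifier
#' @return a \code{viscPrediction}
#' @export
predictViscosity <- function(ens, s, nRotations = 10L, seed = 1L,
                             id = "structure") {
  cfg <- ens$meta
  if (is.null(cfg)) stop("ensemble has no featurization metadata")
  expectCh <- ens$models[[1]]$net$inChannels
  grids <- featurizeRotations(s, nRotations, seed, cfg)
  if (dim(grids[[1]]@data)[4] != expectCh)
    stop("representation mismatch: ensemble expects ", expectCh, " channel(s)")
  predictFromGrids(ens, grids, id = id)
}

#' @export
print.viscPrediction <- function(x, ...) {
  cat(sprintf("viscPrediction %s: %.3g cP (mean of %d = %d models x %d rotations)\n",
              x$id, x$final, x$nPredictions, x$nModels, x$nRotations))
  invisible(x)
}

#' Out-of-fold cross-validation predictions
#'
#' For each structure, predicts with the model of the fold that held it out,
#' averaging over the structure's rotated grids; the standard held-out
#' generalization estimate for a CV ensemble.
#'
#' @param ens a \code{viscEnsemble} trained by \code{\link{trainCVEnsemble}}
#' @param gridsByStructure the same named list used for training
#' @return data.frame with columns id, predicted (cP)
#' @export
cvHeldOutPredictions <- function(ens, gridsByStructure) {
  transform <- ens$cfg$targetTransform
  ids <- names(gridsByStructure)
  pred <- vapply(ids, function(id) {
    f <- ens$folds[[id]]
    net <- ens$models[[f]]$net
    mean(vapply(gridsByStructure[[id]],
                function(g) invertTransform(forwardNet(net, g), transform), 1.0))
  }, 1.0)
  data.frame(id = ids, predicted = unname(pred), stringsAsFactors = FALSE)
}
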