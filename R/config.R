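# Run configurations, presets, validation, serialization, and the staged
# pipeline driver used by the command-line script.

#' Production run configuration
#'
#' The full-scale settings: 97^3 physical grid (+/-36 Angstrom, 0.75 Angstrom
#' spacing) padded to 128^3, probe 1.4 Angstrom, 2 Angstrom shell, dielectrics
#' 1/80 with no ionic screening, finite-difference Poisson-Boltzmann solver,
#' 6-block network trained 2000 epochs at learning rate 1e-5 in 10-fold
#' cross-validation with 10 rotated samples per structure and a 10-rotation
#' inference ensemble.
#'
#' @return a run configuration list
#' @export
paperPreset <- function() {
  list(name = "paper-full", representation = "esp",
       grid = gridSpec(36, 0.75, 128L), probe = 1.4, shellThickness = 2,
       epsIn = 1, epsOut = 80, ionicStrength = 0, solver = "pb", tol = 1e-5,
       maxit = 10000L, clipEsp = NULL, targetTransform = "log10",
       net = netConfig(), k = 10L, nRotationsTrain = 10L,
       nRotationsPredict = 10L)
}

#' Desk-scale test configuration
#'
#' A scaled-down profile exercising the identical code paths in minutes on
#' one CPU: 17^3 physical grid (+/-12 Angstrom, 1.5 Angstrom spacing) padded
#' to 32^3, a 5-block network (32 is not divisible by 2^6), learning rate
#' 1e-3 over 200 epochs (the shorter schedule on a far smaller problem needs
#' a proportionally larger step), 3-fold cross-validation and 2 rotations per
#' structure.
#'
#' @return a run configuration list
#' @export
deskPreset <- function() {
  list(name = "desk-test", representation = "esp",
       grid = gridSpec(12, 1.5, 32L), probe = 1.4, shellThickness = 2,
       epsIn = 1, epsOut = 80, ionicStrength = 0, solver = "pb", tol = 1e-5,
       maxit = 10000L, clipEsp = NULL, targetTransform = "log10",
       net = netConfig(nBlocks = 5L, learningRate = 1e-3, epochs = 200L),
       k = 3L, nRotationsTrain = 2L, nRotationsPredict = 2L)
}

#' Validate a run configuration
#'
#' Checks field presence, types and grid/network compatibility before any
#' stage runs.
#' @param cfg a run configuration list
#' @return the configuration, invisibly; errors on violation
#' @export
validateConfig <- function(cfg) {
  need <- c("representation", "grid", "probe", "shellThickness", "epsIn",
            "epsOut", "ionicStrength", "solver", "tol", "maxit",
            "targetTransform", "net", "k", "nRotationsTrain",
            "nRotationsPredict")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("configuration missing field(s): ",
                         paste(miss, collapse = ", "))
  if (!cfg$representation %in% c("esp", "eisenberg", "combined"))
    stop("unknown representation: ", cfg$representation)
  if (!cfg$solver %in% c("pb", "debye")) stop("unknown solver: ", cfg$solver)
  if (!is(cfg$grid, "GridSpec")) stop("grid must be a GridSpec")
  validObject(cfg$grid)
  if (cfg$grid@paddedDim %% 2^cfg$net$nBlocks != 0)
    stop("padded grid dimension not divisible by 2^nBlocks")
  if (cfg$epsIn <= 0 || cfg$epsOut <= 0) stop("dielectrics must be positive")
  invisible(cfg)
}

cfgToList <- function(cfg) {
  out <- cfg
  out$grid <- list(extent = cfg$grid@extent, spacing = cfg$grid@spacing,
                   paddedDim = cfg$grid@paddedDim)
  out$net <- unclass(cfg$net)
  out
}

cfgFromList <- function(lst) {
  lst$grid <- gridSpec(lst$grid$extent, lst$grid$spacing, lst$grid$paddedDim)
  lst$net <- do.call(netConfig, lst$net[setdiff(names(lst$net), "batchSize")])
  lst
}

#' Read / write a run configuration as YAML
#' @param path file path
#' @param cfg configuration to write
#' @export
writeConfig <- function(cfg, path) {
  yaml::write_yaml(cfgToList(cfg), path)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) validateConfig(cfgFromList(yaml::read_yaml(path)))

readLabelsCSV <- function(path) {
  labels <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "path", "viscosity_cP")
  if (!all(need %in% names(labels)))
    stop("label file must have columns id, path, viscosity_cP")
  labels
}

loadStructure <- function(path, cfg) {
  canonicalize(assignParameters(readPDB(path)))
}

#' Run one pipeline stage
#'
#' Staged driver behind the command-line script.  Every stage writes its
#' outputs plus a copy of the exact configuration and seed into \code{out},
#' so identical configurations reproduce identical artifacts.
#'
#' Commands: \code{synth} (toy PDBs + labels CSV), \code{featurize} (labels
#' CSV -> rotation-augmented grids), \code{train} (grids -> cross-validation
#' ensemble), \code{predict} (ensemble + PDBs -> predictions CSV),
#' \code{attribute} (ensemble + PDB -> patch table CSV), \code{evaluate}
#' (predictions + labels -> metrics JSON).
#'
#' @param command stage name
#' @param cfg run configuration (see \code{\link{deskPreset}})
#' @param inputs named list of stage inputs (paths or counts; see details)
#' @param out output directory
#' @param seed integer seed for all stochastic steps
#' @return invisibly, a list of produced artifact paths
#' @export
runPipeline <- function(command = c("synth", "featurize", "train", "predict",
                                    "attribute", "evaluate"),
                        cfg = deskPreset(), inputs = list(), out = ".",
                        seed = 1L) {
  command <- match.arg(command)
  validateConfig(cfg)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  writeConfig(cfg, file.path(out, "config.yaml"))
  writeLines(as.character(seed), file.path(out, "seed.txt"))
  artifacts <- list()

  if (command == "synth") {
    n <- inputs$n %||% 24L
    ds <- makeLabeledDataset(n = n, model = inputs$model %||% labelModel(),
                             seed = seed, cfg = cfg)
    pdbDir <- file.path(out, "pdb")
    dir.create(pdbDir, showWarnings = FALSE)
    rows <- lapply(ds, function(rec) {
      p <- file.path(pdbDir, paste0(rec$id, ".pdb"))
      writePDB(rec$structure, p)
      data.frame(id = rec$id, path = p, viscosity_cP = rec$viscosity,
                 set_name = "synthetic", driver = rec$driver)
    })
    labPath <- file.path(out, "labels.csv")
    utils::write.csv(do.call(rbind, rows), labPath, row.names = FALSE)
    artifacts$labels <- labPath
  } else if (command == "featurize") {
    labels <- readLabelsCSV(inputs$labels)
    gridDir <- file.path(out, "grids")
    dir.create(gridDir, showWarnings = FALSE)
    for (i in seq_len(nrow(labels))) {
      s <- loadStructure(labels$path[i], cfg)
      s@provenance$structureId <- labels$id[i]
      grids <- featurizeRotations(s, cfg$nRotationsTrain,
                                  seed = seed + i * 131L, cfg = cfg,
                                  label = labels$viscosity_cP[i])
      saveRDS(grids, file.path(gridDir, paste0(labels$id[i], ".rds")))
    }
    artifacts$grids <- gridDir
  } else if (command == "train") {
    files <- list.files(inputs$grids, pattern = "\\.rds$", full.names = TRUE)
    if (!length(files)) stop("no featurized grids found in ", inputs$grids)
    gridsByStructure <- lapply(files, readRDS)
    names(gridsByStructure) <- sub("\\.rds$", "", basename(files))
    ens <- trainCVEnsemble(gridsByStructure, k = cfg$k, cfg = cfg$net,
                           seed = seed, meta = cfg)
    ensPath <- file.path(out, "ensemble.rds")
    saveRDS(ens, ensPath)
    artifacts$ensemble <- ensPath
  } else if (command == "predict") {
    ens <- readRDS(inputs$ensemble)
    pdbs <- inputs$pdbs
    rows <- lapply(seq_along(pdbs), function(i) {
      s <- loadStructure(pdbs[i], cfg)
      rec <- predictViscosity(ens, s, cfg$nRotationsPredict,
                              seed = seed + i, id = basename(pdbs[i]))
      data.frame(id = rec$id, predicted_cP = rec$final,
                 n_predictions = rec$nPredictions)
    })
    predPath <- file.path(out, "predictions.csv")
    utils::write.csv(do.call(rbind, rows), predPath, row.names = FALSE)
    artifacts$predictions <- predPath
  } else if (command == "attribute") {
    ens <- readRDS(inputs$ensemble)
    s <- loadStructure(inputs$pdb, cfg)
    res <- ensembleAttribution(ens, s, nRotations = cfg$nRotationsPredict,
                               seed = seed, steps = inputs$steps %||% 64L)
    sigma <- poolSignificance(list(res))
    patches <- findPatches(res, sigma, linkDist = 2 * cfg$grid@spacing)
    rows <- lapply(seq_along(patches), function(i) {
      p <- patches[[i]]
      comp <- classifyPatchPoints(p, s, cfg$grid)
      data.frame(patch = i, sign = p$sign, size = p$size,
                 t(comp$fractions))
    })
    patchPath <- file.path(out, "patches.csv")
    utils::write.csv(if (length(rows)) do.call(rbind, rows) else
      data.frame(patch = integer(0)), patchPath, row.names = FALSE)
    artifacts$patches <- patchPath
  } else if (command == "evaluate") {
    preds <- utils::read.csv(inputs$predictions, stringsAsFactors = FALSE)
    labels <- readLabelsCSV(inputs$labels)
    m <- match(preds$id, labels$id)
    rep <- metricsReport(preds$predicted_cP, labels$viscosity_cP[m],
                         seed = seed)
    rep$confusion <- as.list(as.data.frame(rep$confusion))
    metPath <- file.path(out, "metrics.json")
    jsonlite::write_json(rep, metPath, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    artifacts$metrics <- metPath
  }
  invisible(artifacts)
}
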