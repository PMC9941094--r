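test_that("architecture arithmetic: flatten length and parameter count", {
  net128 <- buildNet(netConfig(), 1L, 128L)
  expect_equal(net128$fcLen, 1024L)
  expect_equal(net128$channels, c(1L, 4L, 8L, 16L, 32L, 64L, 128L))
  net64 <- buildNet(netConfig(), 1L, 64L)
  expect_equal(net64$fcLen, 128L)
  # parameter count is fixed and reproducible
  expect_equal(nParams(net128), 296009L)
  expect_equal(nParams(buildNet(netConfig(), 1L, 128L)), nParams(net128))
  expect_error(buildNet(netConfig(), 1L, 96L), "divisible")
})

test_that("forward pass with a zeroed linear head returns zero", {
  spec <- testSpec()
  net <- withr::with_seed(1, buildNet(testNetConfig(), 1L, spec@paddedDim))
  net$weights[[length(net$weights) - 1]][] <- 0
  net$weights[[length(net$weights)]][] <- 0
  x <- array(0, dim = c(16, 16, 16, 1))
  expect_equal(forwardNet(net, x), 0)
})

test_that("fold training selects the best checkpoint in the final window", {
  spec <- testSpec()
  tr <- lapply(1:4, function(i) dummyGrid(spec, paste0("s", i),
                                          target = i / 4, seed = i))
  va <- lapply(5:6, function(i) dummyGrid(spec, paste0("s", i),
                                          target = i / 4, seed = i))
  fit <- trainFold(tr, va, testNetConfig(epochs = 20L, window = 5L), seed = 3L)
  expect_gte(fit$selectedEpoch, 16)
  expect_lte(fit$selectedEpoch, 20)
  expect_equal(fit$bestVal, min(fit$valLoss[16:20]))
  # training loss decreases in trend on a learnable problem
  expect_lt(mean(tail(fit$trainLoss, 5)), mean(head(fit$trainLoss, 5)))
  # val == train sanity run: selected window minimum beats the window start
  fit2 <- trainFold(tr, tr, testNetConfig(epochs = 20L, window = 5L),
                    seed = 3L, allowOverlap = TRUE)
  expect_lte(fit2$bestVal, fit2$valLoss[16])
  expect_error(trainFold(tr, va[0], testNetConfig()), "empty")
  expect_error(trainFold(tr, tr, testNetConfig()), "both train and validation")
})

test_that("training is deterministic given the seed", {
  spec <- testSpec()
  tr <- lapply(1:3, function(i) dummyGrid(spec, paste0("s", i),
                                          target = i / 3, seed = i))
  va <- list(dummyGrid(spec, "s9", target = 0.5, seed = 9))
  cfg <- testNetConfig(epochs = 5L, window = 2L)
  f1 <- trainFold(tr, va, cfg, seed = 11L)
  f2 <- trainFold(tr, va, cfg, seed = 11L)
  expect_identical(f1$net$weights, f2$net$weights)
  expect_identical(f1$valLoss, f2$valLoss)
})

test_that("cross-validation splits keep structures together and cover folds", {
  spec <- testSpec()
  grids <- lapply(1:10, function(i)
    lapply(1:2, function(r) dummyGrid(spec, paste0("s", i), target = i / 10,
                                      seed = 10 * i + r)))
  names(grids) <- paste0("s", 1:10)
  cfg <- testNetConfig(epochs = 2L, window = 1L)
  ens <- trainCVEnsemble(grids, k = 10L, cfg = cfg, seed = 5L)
  expect_length(ens$models, 10)
  # leave-one-out limit: each validation fold holds exactly one structure
  for (m in ens$models) {
    expect_length(m$valIds, 1)
    expect_length(m$trainIds, 9)
    expect_false(m$valIds %in% m$trainIds)
  }
  expect_setequal(unlist(lapply(ens$models, `[[`, "valIds")), names(grids))
  expect_error(trainCVEnsemble(grids, k = 11L, cfg = cfg), "more folds")
})

test_that("leave-one-out splits have the prescribed training sizes", {
  splits <- loocvSplits(paste0("a", 1:21), paste0("b", 1:38))
  expect_length(splits, 21)
  expect_true(all(vapply(splits, function(f) length(f$train), 1L) == 58))
  for (f in splits) expect_false(f$test %in% f$train)
  small <- loocvSplits(paste0("a", 1:3), paste0("b", 1:5))
  expect_length(small, 3)
  expect_true(all(vapply(small, function(f) length(f$train), 1L) == 7))
  expect_error(loocvSplits(c("x", "y"), c("y", "z")), "overlap")
})

test_that("the leave-one-out protocol trains on everything but the test case", {
  spec <- testSpec()
  mk <- function(id, i) list(dummyGrid(spec, id, target = i / 8, seed = i))
  gridsA <- setNames(lapply(1:3, function(i) mk(paste0("a", i), i)),
                     paste0("a", 1:3))
  gridsB <- setNames(lapply(4:8, function(i) mk(paste0("b", i), i)),
                     paste0("b", 4:8))
  recs <- loocvProtocol(gridsA, gridsB, k = 2L,
                        cfg = testNetConfig(epochs = 2L, window = 1L),
                        seed = 2L)
  expect_length(recs, 3)
  expect_true(all(vapply(recs, function(r) is.finite(r$final), TRUE)))
})

test_that("ensemble inference averages rotations x models predictions", {
  spec <- testSpec()
  grids <- lapply(1:4, function(i)
    list(dummyGrid(spec, paste0("s", i), target = i / 4, seed = i)))
  names(grids) <- paste0("s", 1:4)
  cfg <- testNetConfig(epochs = 2L, window = 1L)
  ens <- trainCVEnsemble(grids, k = 2L, cfg = cfg, seed = 1L)
  g <- grids[[1]]
  rec1 <- predictFromGrids(ens, g[1], id = "s1")
  expect_equal(rec1$nPredictions, 2)  # 1 rotation x 2 models
  expect_equal(rec1$final, mean(rec1$predictions), tolerance = 1e-9)
  one <- ens; one$models <- one$models[1]
  recSingle <- predictFromGrids(one, g[1])
  expect_equal(recSingle$final, recSingle$predictions[1])
  # held-out predictions reuse each structure's holding-out fold model
  held <- cvHeldOutPredictions(ens, grids)
  expect_setequal(held$id, names(grids))
  expect_true(all(is.finite(held$predicted)))
})

test_that("end-to-end prediction is reproducible and counts 100 predictions", {
  cfg <- microPreset()
  nets <- withr::with_seed(2, lapply(1:10, function(i)
    buildNet(cfg$net, 1L, cfg$grid@paddedDim)))
  ens <- asEnsemble(nets, meta = cfg)
  s <- canonicalize(assignParameters(makeToyStructure(seed = 77L)))
  rec <- predictViscosity(ens, s, nRotations = 10L, seed = 9L)
  expect_equal(rec$nPredictions, 100)
  expect_equal(rec$final, mean(rec$predictions), tolerance = 1e-12)
  rec2 <- predictViscosity(ens, s, nRotations = 10L, seed = 9L)
  expect_identical(rec$predictions, rec2$predictions)
})
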