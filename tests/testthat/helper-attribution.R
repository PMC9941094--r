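# Shared attribution fixtures: a tiny unpadded grid, a single-region
# piecewise-linear network, random sparse attribution grids, and an
# igraph-based connected-components oracle.

tinySpec <- function() gridSpec(0.5, 1, 2L)  # 2^3 grid, no padding

# one conv block whose kernels have only a center tap, so the model is linear
# on the region where the pooling argmax is fixed
linearishNet <- function(centerTaps = c(0.5, 0.25, 1, 2), bias = 10,
                         fcw = c(1, 2, -1, 0.5)) {
  net <- withr::with_seed(1, buildNet(netConfig(nBlocks = 1L), 1L, 2L))
  W <- rep(0, 27 * 1 * 4)
  for (o in seq_len(4)) W[(o - 1) * 27 + 14] <- centerTaps[o]
  net$weights[[1]] <- W
  net$weights[[2]] <- rep(bias, 4)
  net$weights[[3]] <- fcw
  net$weights[[4]] <- 0
  net
}

inputGridFromArray <- function(vals, spec = tinySpec()) {
  p <- spec@paddedDim
  new("InputGrid", spec = spec, data = array(vals, dim = c(p, p, p, 1)),
      mask = array(vals != 0, dim = c(p, p, p)), channels = "esp",
      label = numeric(0), target = numeric(0), provenance = list())
}

patchSpec <- function() gridSpec(6.75, 0.75, 20L)  # 19^3 physical in 20^3

randomAttribution <- function(spec, seed, density = 0.01) {
  p <- spec@paddedDim
  withr::with_seed(seed, {
    v <- numeric(p^3)
    idx <- sample(p^3, round(density * p^3))
    v[idx] <- sample(c(-1, 1), length(idx), replace = TRUE) * runif(length(idx), 1.5, 3)
    new("AttributionGrid", spec = spec, scores = array(v, dim = c(p, p, p, 1)),
        source = list())
  })
}

igraphComponents <- function(a, sigma, linkDist) {
  sc <- a@scores[, , , 1]
  d <- dim(sc)[1]
  comps <- list()
  for (sgn in c(1, -1)) {
    idx <- which(if (sgn > 0) sc > sigma else sc < -sigma)
    if (!length(idx)) next
    v0 <- idx - 1L
    pts <- cbind(v0 %% d, (v0 %/% d) %% d, v0 %/% (d * d)) * a@spec@spacing
    dm <- as.matrix(dist(pts))
    adj <- dm <= linkDist + 1e-12
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    mem <- igraph::components(g)$membership
    comps <- c(comps, lapply(split(idx, mem), sort))
  }
  comps
}
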