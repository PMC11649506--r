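test_that("libsize normalization: equal depths give unit size factors, zeros stay zero", {
  m <- matrix(rpois(200, 5), 20, 10)
  m[1, ] <- 0
  cm <- count_matrix(m)
  norm <- lognormalize(cm, method = "libsize")
  # not exactly equal depths here, so force them:
  m2 <- matrix(2L, 20, 10)
  sf <- attr(lognormalize(count_matrix(m2)), "size_factors")
  expect_equal(unname(sf), rep(1, 10))
  expect_true(all(as.matrix(norm)[m == 0] == 0))
  expect_error(lognormalize(count_matrix(cbind(m, 0))), "zero total")
})

test_that("pooled size factors recover planted depth ratio within 5%", {
  skip_if_not_installed("scran")
  set.seed(42)
  g <- 400
  base <- rlnorm(g, 0, 1)
  mu1 <- 800 * base / sum(base)
  counts <- cbind(
    matrix(rnbinom(g * 60, mu = rep(mu1, 60), size = 3), g),
    matrix(rnbinom(g * 60, mu = rep(2 * mu1, 60), size = 3), g))
  norm <- lognormalize(count_matrix(counts), method = "pooled",
                       ward_preclusters = 2)
  sf <- attr(norm, "size_factors")
  r <- mean(sf[61:120]) / mean(sf[1:60])
  expect_lt(abs(r - 2) / 2, 0.05)
  expect_equal(mean(sf), 1)
})

test_that("pooled reduces to libsize-like factors for homogeneous cells", {
  skip_if_not_installed("scran")
  set.seed(7)
  g <- 300
  base <- rlnorm(g, 0, 1)
  depth <- runif(80, 0.5, 2)
  counts <- vapply(depth, function(d)
    rnbinom(g, mu = d * 600 * base / sum(base), size = 5), numeric(g))
  pooled <- attr(lognormalize(count_matrix(counts), method = "pooled",
                              ward_preclusters = 2), "size_factors")
  lib <- attr(lognormalize(count_matrix(counts), method = "libsize"),
              "size_factors")
  expect_gt(cor(pooled, lib), 0.98)
})

test_that("PCA agrees with a dense SVD oracle and handles rank deficiency", {
  set.seed(11)
  x <- matrix(rnorm(200 * 500), 200, 500)     # features x observations
  emb <- run_pca(x, n = 50)
  xc <- x - rowMeans(x)
  sv <- svd(xc)
  oracle <- sv$v[, 1:50] %*% diag(sv$d[1:50])
  # align component signs before comparing
  sgn <- sign(colSums(oracle * emb$coords))
  expect_lt(max(abs(oracle %*% diag(sgn) - emb$coords)), 1e-6)
  expect_true(all(diff(emb$variance) <= 1e-9))

  # rank-2 matrix: trailing components carry (essentially) zero variance
  r2 <- outer(rnorm(100), rnorm(60)) + outer(rnorm(100), rnorm(60))
  expect_warning(e2 <- run_pca(r2, n = 50), "rank")
  expect_lt(max(e2$variance[3:50]), 1e-8)

  # translation invariance: shifting a feature leaves centered scores alone
  x2 <- x; x2[5, ] <- x2[5, ] + 100
  e3 <- run_pca(x2, n = 20)
  e1 <- run_pca(x, n = 20)
  sgn <- sign(colSums(e1$coords * e3$coords))
  expect_lt(max(abs(e3$coords %*% diag(sgn) - e1$coords)), 1e-6)
})

test_that("single-batch integration is the identity; planted offsets are removed", {
  set.seed(9)
  n <- 400
  type <- sample(3, n, TRUE)
  X <- matrix(rnorm(n * 10, sd = 0.3), n, 10) +
    outer(type == 1, c(5, rep(0, 9))) + outer(type == 2, c(0, 5, rep(0, 8)))
  e <- structure(list(coords = X, variance = rep(1, 10), corrected = FALSE),
                 class = "Embedding")
  e1 <- integrate_batches(e, rep("a", n))
  expect_identical(e1$coords, X)

  batch <- rep(c("a", "b"), each = n / 2)
  Xb <- X; Xb[batch == "b", 5] <- Xb[batch == "b", 5] + 3
  eb <- structure(list(coords = Xb, variance = rep(1, 10), corrected = FALSE),
                  class = "Embedding")
  pre <- sqrt(sum((colMeans(Xb[batch == "a", ]) -
                     colMeans(Xb[batch == "b", ]))^2))
  ec <- integrate_batches(eb, batch, seed = 3)
  post <- sqrt(sum((colMeans(ec$coords[batch == "a", ]) -
                      colMeans(ec$coords[batch == "b", ]))^2))
  expect_lt(post / pre, 0.05)
  expect_equal(dim(ec$coords), dim(Xb))
})

test_that("integration preserves planted cluster structure (ARI shift < 0.05)", {
  set.seed(21)
  n <- 600
  ty <- sample(4, n, TRUE)
  ctrs <- matrix(rnorm(4 * 10, sd = 3), 4, 10)
  Y <- ctrs[ty, ] + matrix(rnorm(n * 10, sd = 0.5), n, 10)
  b <- sample(c("s1", "s2", "s3"), n, TRUE)
  offs <- matrix(rnorm(3 * 10, sd = 1), 3, 10)
  Y <- Y + offs[match(b, c("s1", "s2", "s3")), ]
  e <- structure(list(coords = Y, variance = rep(1, 10), corrected = FALSE),
                 class = "Embedding")
  cl_pre <- louvain_cluster(e, k_neighbors = 50, resolution = 0.5, seed = 5)
  ec <- integrate_batches(e, b, seed = 3)
  cl_post <- louvain_cluster(ec, k_neighbors = 50, resolution = 0.5, seed = 5)
  a_pre <- ari(cl_pre, ty); a_post <- ari(cl_post, ty)
  expect_gte(a_post - a_pre, -0.05)
})

test_that("two disjoint cliques resolve into exactly two clusters", {
  adj <- matrix(0, 100, 100)
  adj[1:50, 1:50] <- 1; adj[51:100, 51:100] <- 1
  diag(adj) <- 0
  cl <- louvain_graph(adj, resolution = 1, seed = 2)
  expect_equal(length(unique(cl)), 2)
  expect_equal(length(unique(cl[1:50])), 1)
  expect_equal(length(unique(cl[51:100])), 1)
})

test_that("Louvain attains the exhaustive-enumeration modularity optimum on a toy graph", {
  # two 4-cliques joined by a single edge
  adj <- matrix(0, 8, 8)
  adj[1:4, 1:4] <- 1; adj[5:8, 5:8] <- 1; adj[4, 5] <- adj[5, 4] <- 1
  diag(adj) <- 0
  best <- -Inf
  for (p in set_partitions(8)) {
    m <- partition_membership(p, 8)
    q <- graph_modularity(adj, m)
    if (q > best) best <- q
  }
  cl <- louvain_graph(adj, resolution = 1, seed = 3)
  expect_equal(graph_modularity(adj, cl), best, tolerance = 1e-12)
  # returned partition beats the trivial partitions
  expect_gte(graph_modularity(adj, cl),
             graph_modularity(adj, seq_len(8)))
  expect_gte(graph_modularity(adj, cl),
             graph_modularity(adj, rep(1, 8)))
})

test_that("Louvain at default settings recovers planted 5-type structure (ARI >= 0.9)", {
  cfg <- sim_config(seed = 11, n_genes = 800, cohorts = "HS",
                    donors_per_cohort = c(HS = 4), cells_per_donor = 500,
                    celltype_props = list(HS = c(`B naive` = .2, `CD4 TCM` = .2,
                                                 `CD8 TEM` = .2, NK = .2,
                                                 MAIT = .2)),
                    n_empty = 0, doublet_rate = 0, n_marker_genes = 20)
  sim <- simulate_cohort(cfg)
  emb <- run_pca(lognormalize(sim$counts), n = 50)
  cl <- louvain_cluster(emb, k_neighbors = 100, resolution = 0.1, seed = 4)
  expect_gte(ari(cl, sim$truth$cells$true_type), 0.9)
  # deterministic under a fixed seed
  cl2 <- louvain_cluster(emb, k_neighbors = 100, resolution = 0.1, seed = 4)
  expect_identical(cl, cl2)
})

test_that("clustering input contracts", {
  expect_error(snn_graph(matrix(0, 0, 2), 10), "empty")
  expect_error(snn_graph(matrix(rnorm(20), 10, 2), k_neighbors = 15),
               "k_neighbors")
})
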