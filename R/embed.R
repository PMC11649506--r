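#' Log-normalize a count matrix
#'
#' Library-size normalization (default) or pool-based deconvolution size
#' factors with Ward-linkage pre-clustering (scran-style). Size factors are
#' rescaled to mean 1 and counts are transformed as
#' `log1p(count / sf * scale / median(libsize))`.
#'
#' @param m a [count_matrix()] (total layer used) or a sparse/dense counts
#'   matrix, genes x cells.
#' @param method "libsize" or "pooled".
#' @param scale target count scale before log1p (default 1e4).
#' @param ward_preclusters number of Ward pre-clusters for pooled factors.
#' @return sparse genes x cells matrix of log-normalized values, with the
#'   size factors in attribute "size_factors". Zeros map to zeros.
#' @export
lognormalize <- function(m, method = c("libsize", "pooled"), scale = 1e4,
                         ward_preclusters = 5) {
  method <- match.arg(method)
  counts <- if (inherits(m, "CountMatrix")) m$layers$total else
    as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  cs <- Matrix::colSums(counts)
  if (any(cs == 0)) stop("cell(s) with zero total counts must be filtered upstream")
  sf <- switch(method,
    libsize = cs / mean(cs),
    pooled = pooled_size_factors(counts, ward_preclusters))
  sf <- sf / mean(sf)
  fac <- scale / stats::median(cs)
  out <- counts
  out@x <- log1p(counts@x / rep.int(sf, diff(counts@p)) * fac)
  attr(out, "size_factors") <- sf
  out
}

# scran pool-based deconvolution size factors behind Ward pre-clustering
pooled_size_factors <- function(counts, k) {
  if (!requireNamespace("scran", quietly = TRUE))
    stop("method 'pooled' requires the scran package")
  n <- ncol(counts)
  cl <- if (k > 1 && n > 2 * k) {
    cs <- Matrix::colSums(counts)
    logx <- counts
    logx@x <- log1p(counts@x / rep.int(cs, diff(counts@p)) * 1e4)
    pcs <- run_pca(logx, n = min(10, n - 1))$coords
    stats::cutree(stats::hclust(stats::dist(pcs), method = "ward.D2"), k = k)
  } else rep(1L, n)
  sizes <- seq(21, min(101, max(21, floor(min(table(cl)) / 2))), 5)
  scran::calculateSumFactors(counts, clusters = cl, sizes = sizes,
                             min.mean = 0.1)
}

#' Principal component embedding via (randomized) SVD
#'
#' Computes the first `n` principal component scores of the observations.
#' Uses exact thin SVD when `n` is a substantial share of the smaller
#' dimension, otherwise randomized SVD with 10 power iterations; both agree
#' with the dense SVD up to component sign.
#'
#' @param x features x observations matrix (genes x cells), dense or
#'   sparse; observations are embedded.
#' @param n number of components (default 50; capped at rank with a
#'   warning).
#' @param center center each feature before decomposition (default TRUE).
#' @param seed seed for the randomized projection.
#' @return an `Embedding`: list(coords = obs x n score matrix, variance =
#'   non-increasing explained variances, rotation, center, corrected =
#'   FALSE).
#' @export
run_pca <- function(x, n = 50, center = TRUE, seed = 1L) {
  d <- dim(x)
  if (is.null(d) || any(d == 0)) stop("empty matrix")
  nobs <- d[2]
  n <- min(n, d[1], nobs)
  mu <- if (center) Matrix::rowMeans(x) else rep(0, d[1])

  if (n >= 0.25 * min(d)) {
    xc <- as.matrix(x) - mu
    sv <- svd(xc, nu = 0, nv = n)
    dvals <- sv$d[seq_len(n)]
    scores <- sv$v %*% diag(dvals, n, n)
    rot <- as.matrix(xc %*% sv$v) %*% diag(ifelse(dvals > 1e-12, 1 / dvals, 0), n, n)
  } else {
    set.seed(seed)
    k <- min(n + 10, min(d))
    omega <- matrix(stats::rnorm(nobs * k), nobs, k)
    # work with A = centered x (features x obs) without densifying x:
    # A %*% v = x %*% v - mu * sum(v)
    Amul <- function(v) as.matrix(x %*% v) - outer(mu, colSums(v))
    Atmul <- function(v) as.matrix(Matrix::crossprod(x, v)) -
      outer(rep(1, nobs), as.numeric(crossprod(mu, v))) * 1
    Y <- Amul(omega)
    for (i in 1:10) {
      Y <- qr.Q(qr(Y))
      Y <- Amul(Atmul(Y))
    }
    Q <- qr.Q(qr(Y))
    B <- t(Atmul(Q))            # k x nobs
    sv <- svd(B)
    dvals <- sv$d[seq_len(n)]
    scores <- sv$v[, seq_len(n), drop = FALSE] %*% diag(dvals, n, n)
    rot <- Q %*% sv$u[, seq_len(n), drop = FALSE]
  }
  variance <- dvals^2 / max(1, nobs - 1)
  rank_tol <- max(dvals) * 1e-10
  if (any(dvals <= rank_tol) && n > sum(dvals > rank_tol))
    warning("requested more components than the matrix rank")
  colnames(scores) <- paste0("PC", seq_len(n))
  rownames(scores) <- colnames(x)
  structure(list(coords = scores, variance = variance, rotation = rot,
                 center = mu, corrected = FALSE, batch_key = NULL),
            class = "Embedding")
}

#' @export
print.Embedding <- function(x, ...) {
  cat(sprintf("Embedding: %d cells x %d components%s\n",
              nrow(x$coords), ncol(x$coords),
              if (isTRUE(x$corrected)) " (batch-corrected)" else ""))
  invisible(x)
}

#' Batch integration by diversity-penalized soft clustering
#'
#' Simplified linear batch correction in the embedding: iterate soft
#' k-means with an entropy-over-batches diversity penalty, then subtract
#' per-cluster, per-batch centroid offsets, until assignments stabilize.
#' With a single batch the transform is the identity.
#'
#' @param e an `Embedding`.
#' @param batch factor/character batch label per cell.
#' @param n_soft_clusters soft cluster count.
#' @param diversity_weight penalty strength (theta); 0 disables mixing
#'   pressure.
#' @param max_iter,tol iteration cap and mean-assignment-change tolerance.
#' @param seed RNG seed for centroid initialization.
#' @return the corrected `Embedding` (same cells and components).
#' @export
integrate_batches <- function(e, batch, n_soft_clusters = 20,
                              diversity_weight = 1, max_iter = 20,
                              tol = 1e-4, seed = 1L) {
  stopifnot(inherits(e, "Embedding"))
  Z <- e$coords
  batch <- as.character(batch)
  stopifnot(length(batch) == nrow(Z))
  ub <- unique(batch)
  if (length(ub) < 2) {
    e$corrected <- TRUE
    e$batch_key <- ub
    return(e)
  }
  n <- nrow(Z)
  K <- min(n_soft_clusters, max(2L, floor(n / 10)))
  bfrac <- table(factor(batch, ub)) / n

  for (attempt in 1:2) {
    ctr <- with_stage_seed(seed + attempt - 1L, "integrate",
      stats::kmeans(Z, centers = K, nstart = 3, iter.max = 50)$centers)
    # deliberately soft kernel: broad assignments let the linear correction
    # act across batch-pure subclusters instead of freezing them in place
    sigma2 <- 10 * mean(apply(pairwise_sqdist(Z, ctr), 1, min)) + 1e-8
    Rprev <- NULL
    Zc <- Z
    ok <- TRUE
    for (it in seq_len(max_iter)) {
      D2 <- pairwise_sqdist(Zc, ctr)
      base <- -D2 / (2 * sigma2)
      base <- base - apply(base, 1, max)
      R <- exp(base); R <- R / rowSums(R)
      if (diversity_weight > 0) {
        # fixed-point rounds so the diversity penalty shapes this round's
        # assignments, not the previous one's
        for (j in 1:5) {
          O <- rowsum(R, batch)                         # batch x K
          E <- outer(as.numeric(bfrac), colSums(R))
          pen <- diversity_weight * log((E + 1) / (O + 1))
          logR <- base + pen[match(batch, rownames(O)), ]
          logR <- logR - apply(logR, 1, max)
          R <- exp(logR); R <- R / rowSums(R)
        }
      }
      if (it == 1 && any(rowsum(R, batch) %*% rep(1, K) == 0)) {
        ok <- FALSE; break                              # batch lost: re-seed
      }
      # per-cluster linear correction: remove batch-specific centroid offset
      corr <- matrix(0, n, ncol(Z))
      ck <- crossprod(R, Zc) / pmax(colSums(R), 1e-12)  # K x d global
      for (b in ub) {
        ib <- which(batch == b)
        Rb <- R[ib, , drop = FALSE]
        wb <- colSums(Rb)
        ckb <- crossprod(Rb, Zc[ib, , drop = FALSE]) / pmax(wb, 1e-12)
        off <- ckb - ck                                 # K x d
        use <- wb > 1e-6
        if (any(use))
          corr[ib, ] <- Rb[, use, drop = FALSE] %*% off[use, , drop = FALSE]
      }
      Zc <- Zc - corr
      ctr <- crossprod(R, Zc) / pmax(colSums(R), 1e-12)
      # stop when both assignments and the applied correction have settled
      corr_rel <- mean(sqrt(rowSums(corr^2))) /
        (mean(sqrt(rowSums(Zc^2))) + 1e-12)
      if (!is.null(Rprev) && mean(abs(R - Rprev)) < tol &&
          corr_rel < tol) break
      Rprev <- R
    }
    if (ok) {
      e$coords <- Zc
      e$corrected <- TRUE
      return(e)
    }
  }
  stop("a batch was entirely absent from every cluster after initialization")
}

pairwise_sqdist <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  d2
}

# brute-force kNN (Euclidean), chunked; query rows search all rows of X
knn_index <- function(X, k, query = seq_len(nrow(X)), include_self = FALSE) {
  n <- nrow(X)
  stopifnot(k < n)
  out <- matrix(0L, length(query), k)
  chunk <- max(1L, floor(2e7 / n))
  for (s in seq(1, length(query), by = chunk)) {
    idx <- query[s:min(s + chunk - 1, length(query))]
    d2 <- pairwise_sqdist(X[idx, , drop = FALSE], X)
    if (!include_self) d2[cbind(seq_along(idx), idx)] <- Inf
    ord <- apply(d2, 1, function(r) order(r)[seq_len(k)])
    out[s:(s + length(idx) - 1), ] <- t(ord)
  }
  out
}

#' Shared-nearest-neighbor graph of an embedding
#'
#' kNN by Euclidean distance in the embedding, edges weighted by the
#' Jaccard similarity of the two cells' neighbor sets (self included);
#' edges with weight below `prune` are dropped.
#'
#' @param e an `Embedding` or a cells x components matrix.
#' @param k_neighbors neighbors per cell.
#' @param prune minimum Jaccard weight kept (default 1/15).
#' @return an igraph undirected weighted graph.
#' @export
snn_graph <- function(e, k_neighbors = 100, prune = 1 / 15) {
  X <- if (inherits(e, "Embedding")) e$coords else as.matrix(e)
  n <- nrow(X)
  if (n == 0) stop("empty embedding")
  if (n < k_neighbors + 1) stop("need at least k_neighbors + 1 cells")
  nn <- knn_index(X, k_neighbors)
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k_neighbors),
                            j = as.vector(t(nn)), x = 1, dims = c(n, n))
  diag(A) <- 1
  shared <- Matrix::tcrossprod(A)                     # |N(i) n N(j)|
  ksz <- k_neighbors + 1
  jac <- as(as(shared, "generalMatrix"), "CsparseMatrix")
  jac@x <- jac@x / (2 * ksz - jac@x)
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  diag(jac) <- 0
  igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Louvain clustering of cells in an embedding
#'
#' Builds the shared-nearest-neighbor graph and maximizes
#' resolution-scaled modularity by Louvain passes; deterministic under a
#' fixed seed.
#'
#' @param e an `Embedding` (or matrix of coordinates).
#' @param k_neighbors evaluated nearest neighbors (default 100).
#' @param resolution modularity resolution (default 0.1).
#' @param seed RNG seed.
#' @return integer cluster labels (1-based) per cell.
#' @export
louvain_cluster <- function(e, k_neighbors = 100, resolution = 0.1,
                            seed = 1L) {
  g <- snn_graph(e, k_neighbors)
  louvain_graph(g, resolution = resolution, seed = seed)
}

#' Louvain clustering of an explicit graph
#'
#' @param g an igraph graph or a (sparse) adjacency matrix.
#' @param resolution modularity resolution.
#' @param seed RNG seed.
#' @return integer membership vector.
#' @export
louvain_graph <- function(g, resolution = 1, seed = 1L) {
  if (!igraph::is_igraph(g))
    g <- igraph::graph_from_adjacency_matrix(
      Matrix::Matrix(g, sparse = TRUE), mode = "undirected",
      weighted = TRUE, diag = FALSE)
  cl <- with_stage_seed(seed, "louvain",
    igraph::cluster_louvain(g, resolution = resolution))
  as.integer(igraph::membership(cl))
}

#' Modularity of a partition
#'
#' @param g igraph graph or adjacency matrix.
#' @param membership integer membership vector.
#' @param resolution modularity resolution.
#' @return numeric modularity.
#' @export
graph_modularity <- function(g, membership, resolution = 1) {
  if (!igraph::is_igraph(g))
    g <- igraph::graph_from_adjacency_matrix(
      Matrix::Matrix(g, sparse = TRUE), mode = "undirected",
      weighted = TRUE, diag = FALSE)
  igraph::modularity(g, membership, resolution = resolution,
                     weights = igraph::E(g)$weight)
}
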