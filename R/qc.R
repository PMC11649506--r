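#' Droplet cell calling against an ambient RNA null
#'
#' Estimates the ambient (cell-free) expression profile from low-count
#' barcodes and tests every higher-count barcode for deviation from it with
#' a Monte-Carlo multinomial goodness-of-fit test at the barcode's own
#' total count. P-values are Benjamini-Hochberg adjusted and barcodes with
#' FDR below `fdr_threshold` are called as cells; barcodes above the
#' automatically detected knee of the ranked total-count curve are always
#' called.
#'
#' @param raw a [count_matrix()] including low-count background barcodes.
#' @param ambient_count_max barcodes with totals at or below this form the
#'   ambient pool and are never called.
#' @param n_mc Monte-Carlo iterations (>= 100); the attainable p-value
#'   lower bound is 1/(n_mc+1).
#' @param fdr_threshold call cells at BH FDR below this (strict).
#' @param seed RNG seed for the Monte-Carlo draws.
#' @return data.frame with barcode, total_count, ambient_pvalue,
#'   ambient_fdr, knee flag and called_cell flag (NA p-values for barcodes
#'   inside the ambient pool).
#' @export
call_cells <- function(raw, ambient_count_max = 100, n_mc = 10000,
                       fdr_threshold = 0.01, seed = 1L) {
  stopifnot(inherits(raw, "CountMatrix"))
  if (n_mc < 100) stop("n_mc must be >= 100")
  m <- raw$layers$total
  totals <- Matrix::colSums(m)
  pool <- which(totals > 0 & totals <= ambient_count_max)
  if (!length(pool)) stop("no ambient pool: no barcodes at or below ambient_count_max")
  ambient <- Matrix::rowSums(m[, pool, drop = FALSE]) + 0.5
  ambient <- as.numeric(ambient / sum(ambient))

  test_idx <- which(totals > ambient_count_max)
  p <- rep(NA_real_, length(totals))
  if (length(test_idx)) {
    logp <- log(ambient)
    stat <- vapply(test_idx, function(j) {
      x <- m[, j]
      nz <- which(x > 0)
      sum(x[nz] * log(x[nz])) - sum(x[nz] * logp[nz]) -
        totals[j] * log(totals[j])
    }, numeric(1))
    ord <- order(totals[test_idx])
    pv <- with_stage_seed(seed, "callcells",
      ambient_null_pvalues(ambient, as.integer(totals[test_idx][ord]),
                           stat[ord], as.integer(n_mc)))
    p[test_idx[ord]] <- pv
  }
  fdr <- rep(NA_real_, length(totals))
  fdr[test_idx] <- bh_adjust(p[test_idx])
  called <- !is.na(fdr) & fdr < fdr_threshold

  knee <- rep(FALSE, length(totals))
  if (length(test_idx) >= 10) {
    kt <- knee_total(totals[test_idx])
    knee[test_idx] <- totals[test_idx] >= kt
    called <- called | knee
  }
  data.frame(barcode = raw$barcodes, total_count = totals,
             ambient_pvalue = p, ambient_fdr = fdr,
             knee = knee, called_cell = called, row.names = NULL)
}

# knee of the log-rank vs log-total curve: point of maximum negative second
# difference after running-mean smoothing
knee_total <- function(totals) {
  tt <- sort(totals, decreasing = TRUE)
  y <- log10(tt + 1)
  x <- log10(seq_along(tt))
  w <- max(3L, round(length(tt) * 0.02))
  ys <- stats::filter(y, rep(1 / w, w), sides = 2)
  keep <- which(!is.na(ys))
  if (length(keep) < 5) return(Inf)
  d2 <- diff(diff(ys[keep]))
  i <- keep[which.min(d2) + 1L]
  tt[i]
}

#' Score and flag doublets with artificial-doublet nearest neighbors
#'
#' Simulates artificial doublets as sums of random cell pairs, embeds real
#' and artificial barcodes jointly by PCA of log-normalized counts, and
#' scores each real cell by the fraction of its k nearest neighbors that
#' are artificial, rescaled by the simulated:real ratio so a score of 1
#' means neighborhoods as doublet-dense as expected by chance.
#'
#' @param called a [count_matrix()] of called cells (>= 2 * k_neighbors).
#' @param n_sim_doublets artificial doublets to simulate (default: one per
#'   real cell; must be >= k_neighbors).
#' @param k_neighbors neighbors evaluated per cell.
#' @param score_threshold flag cells with score above this; default flags
#'   the top `expected_rate` fraction of scores.
#' @param expected_rate expected doublet rate used for the default
#'   threshold.
#' @param n_pcs principal components of the joint embedding.
#' @param seed RNG seed.
#' @return data.frame(barcode, doublet_score, doublet_flag).
#' @export
flag_doublets <- function(called, n_sim_doublets = NULL, k_neighbors = 25,
                          score_threshold = NULL, expected_rate = 0.05,
                          n_pcs = 30, seed = 1L) {
  stopifnot(inherits(called, "CountMatrix"))
  n <- length(called$barcodes)
  if (n < 2 * k_neighbors) stop("need at least 2 * k_neighbors called cells")
  if (is.null(n_sim_doublets)) n_sim_doublets <- n
  if (n_sim_doublets < k_neighbors) stop("n_sim_doublets must be >= k_neighbors")
  m <- called$layers$total
  with_stage_seed(seed, "doublets", {
    i1 <- sample.int(n, n_sim_doublets, replace = TRUE)
    i2 <- sample.int(n, n_sim_doublets, replace = TRUE)
    art <- m[, i1, drop = FALSE] + m[, i2, drop = FALSE]
    joint <- cbind(m, art)
    # log1p of raw counts: keeps depth as a feature, so homotypic doublets
    # (indistinguishable after depth normalization) remain separable
    logx <- joint
    logx@x <- log1p(joint@x)
    emb <- run_pca(logx, n = min(n_pcs, n - 1), seed = stage_seed(seed, "dblpca"))
    nn <- knn_index(emb$coords, k = k_neighbors, query = seq_len(n))
    frac <- rowMeans(matrix(nn > n, nrow = nrow(nn)))
    score <- frac * n / n_sim_doublets
    thr <- score_threshold %||%
      stats::quantile(score, 1 - expected_rate, names = FALSE)
    data.frame(barcode = called$barcodes, doublet_score = score,
               doublet_flag = score > thr, row.names = NULL)
  })
}

#' Mitochondrial filter on the spliced layer
#'
#' Computes the fraction of spliced counts from mitochondrial genes per
#' cell; cells with strictly less than `threshold` are kept (a cell at
#' exactly 5 of 100 spliced counts is removed under the default).
#'
#' @param m a [count_matrix()] with a spliced layer.
#' @param mito_gene_ids mitochondrial gene ids (subset of the matrix genes).
#' @param threshold keep cells with mito fraction strictly below this.
#' @return data.frame(barcode, mito_fraction, kept); cells with zero
#'   spliced counts get NA fraction and are removed with a warning.
#' @export
mito_filter <- function(m, mito_gene_ids, threshold = 0.05) {
  stopifnot(inherits(m, "CountMatrix"), "spliced" %in% names(m$layers))
  if (!all(mito_gene_ids %in% m$gene_ids))
    stop("mito_gene_ids must be a subset of gene_ids")
  sp <- m$layers$spliced
  tot <- Matrix::colSums(sp)
  mito <- if (length(mito_gene_ids))
    Matrix::colSums(sp[mito_gene_ids, , drop = FALSE]) else rep(0, ncol(sp))
  frac <- ifelse(tot > 0, mito / tot, NA_real_)
  if (anyNA(frac))
    warning(sum(is.na(frac)), " cell(s) with zero spliced counts removed")
  kept <- !is.na(frac) & frac < threshold
  data.frame(barcode = m$barcodes, mito_fraction = frac, kept = kept,
             row.names = NULL)
}

#' Run the full droplet QC pipeline
#'
#' Cell calling, doublet flagging among called cells, then mitochondrial
#' filtering, in that order. Stage counts telescope:
#' kept = called - doublets_removed - mito_removed.
#'
#' @param raw a [count_matrix()] with background barcodes.
#' @param mito_gene_ids mitochondrial gene ids.
#' @param ambient_count_max,n_mc,fdr_threshold see [call_cells()].
#' @param k_neighbors,expected_doublet_rate see [flag_doublets()].
#' @param mito_threshold see [mito_filter()].
#' @param seed RNG seed.
#' @return list with `report` (per-barcode QC table), `summary` (stage
#'   counts) and `filtered` (the kept CountMatrix).
#' @export
run_qc <- function(raw, mito_gene_ids = grep("^MT-", raw$gene_ids, value = TRUE),
                   ambient_count_max = 100, n_mc = 10000,
                   fdr_threshold = 0.01, k_neighbors = 25,
                   expected_doublet_rate = 0.05, mito_threshold = 0.05,
                   seed = 1L) {
  calls <- call_cells(raw, ambient_count_max, n_mc, fdr_threshold, seed)
  called_cm <- subset_counts(raw, barcodes = which(calls$called_cell),
                             note = "qc:called")
  dbl <- flag_doublets(called_cm, k_neighbors = k_neighbors,
                       expected_rate = expected_doublet_rate, seed = seed)
  singlet_cm <- subset_counts(called_cm, barcodes = which(!dbl$doublet_flag),
                              note = "qc:singlets")
  mf <- mito_filter(singlet_cm, intersect(mito_gene_ids, singlet_cm$gene_ids),
                    mito_threshold)
  kept_cm <- subset_counts(singlet_cm, barcodes = which(mf$kept),
                           note = "qc:mito")

  report <- calls
  report$doublet_score <- NA_real_
  report$doublet_flag <- NA
  report[match(dbl$barcode, report$barcode), c("doublet_score", "doublet_flag")] <-
    dbl[, c("doublet_score", "doublet_flag")]
  report$mito_fraction <- NA_real_
  report$mito_kept <- NA
  report[match(mf$barcode, report$barcode), c("mito_fraction", "mito_kept")] <-
    mf[, c("mito_fraction", "kept")]
  report$kept <- report$barcode %in% kept_cm$barcodes

  summary <- c(barcodes = nrow(report),
               called = sum(calls$called_cell),
               doublets_removed = sum(dbl$doublet_flag),
               mito_removed = sum(!mf$kept),
               kept = length(kept_cm$barcodes))
  list(report = report, summary = summary, filtered = kept_cm)
}
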