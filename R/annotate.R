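#' Reference-based annotation by rank correlation
#'
#' Scores each cell against every reference label by Spearman correlation
#' over discriminative marker genes (union of the top `n_markers` genes by
#' profile difference for every ordered label pair). The label score is the
#' `quantile` of the cell's correlations with that label's sample profiles
#' (the mean profile when no samples ship). Labels scoring within 0.05 of
#' the top are re-scored in fine-tuning rounds using markers recomputed on
#' that label subset.
#'
#' @param cells log-normalized genes x cells matrix (dense or sparse).
#' @param ref a `ReferencePanel` (see [build_reference_panels()]).
#' @param quantile quantile of per-sample correlations used as label score.
#' @param fine_tune_rounds re-scoring rounds among near-top labels.
#' @param n_markers top genes per ordered label pair.
#' @return data.frame(barcode, label, harmonized, score).
#' @export
annotate_correlation <- function(cells, ref, quantile = 0.8,
                                 fine_tune_rounds = 2, n_markers = 30) {
  stopifnot(inherits(ref, "ReferencePanel"))
  genes <- intersect(rownames(cells), colnames(ref$profiles))
  if (length(genes) < 50) stop("insufficient feature overlap")
  prof <- ref$profiles[, genes, drop = FALSE]
  labels <- rownames(prof)
  if (length(labels) < 2) stop("need at least 2 reference labels")
  X <- as.matrix(cells[genes, , drop = FALSE])

  samples <- lapply(labels, function(l) {
    s <- ref$samples[[l]]
    if (is.null(s)) matrix(prof[l, ], ncol = 1,
                           dimnames = list(colnames(prof), NULL))
    else s[genes, , drop = FALSE]
  })
  names(samples) <- labels

  score_subset <- function(cell_mat, labs) {
    mk <- marker_union(prof[labs, , drop = FALSE], n_markers)
    ranked_c <- col_std_ranks(cell_mat[mk, , drop = FALSE])
    sc <- matrix(NA_real_, ncol(cell_mat), length(labs),
                 dimnames = list(NULL, labs))
    for (l in labs) {
      ranked_s <- col_std_ranks(samples[[l]][mk, , drop = FALSE])
      rho <- crossprod(ranked_c, ranked_s)      # cells x samples
      sc[, l] <- apply(rho, 1, stats::quantile, probs = quantile,
                       names = FALSE)
    }
    sc
  }

  sc <- score_subset(X, labels)
  best <- labels[max.col(sc, ties.method = "first")]
  best_score <- sc[cbind(seq_len(nrow(sc)), match(best, labels))]

  for (round in seq_len(fine_tune_rounds)) {
    changed <- FALSE
    cand <- lapply(seq_len(nrow(sc)), function(i) {
      labels[sc[i, ] >= max(sc[i, ]) - 0.05]
    })
    sig <- vapply(cand, paste, character(1), collapse = "|")
    for (s in unique(sig)) {
      labs <- cand[[match(s, sig)]]
      if (length(labs) < 2 || length(labs) == length(labels)) next
      idx <- which(sig == s)
      sc2 <- score_subset(X[, idx, drop = FALSE], labs)
      nb <- labs[max.col(sc2, ties.method = "first")]
      if (any(nb != best[idx])) changed <- TRUE
      best[idx] <- nb
      best_score[idx] <- sc2[cbind(seq_along(idx), match(nb, labs))]
    }
    if (!changed) break
  }
  data.frame(barcode = colnames(cells) %||% seq_len(ncol(cells)),
             label = best,
             harmonized = unname(ref$harmonization[best]),
             score = best_score, row.names = NULL)
}

# union of top-n discriminative genes over ordered label pairs
marker_union <- function(prof, n) {
  labs <- rownames(prof)
  mk <- character(0)
  for (a in labs) for (b in labs) {
    if (a == b) next
    d <- prof[a, ] - prof[b, ]
    mk <- c(mk, colnames(prof)[order(d, decreasing = TRUE)[seq_len(min(n, ncol(prof)))]])
  }
  unique(mk)
}

# column-wise rank transform then standardize to unit-norm centered columns
col_std_ranks <- function(m) {
  r <- apply(as.matrix(m), 2, rank, ties.method = "average")
  r <- sweep(r, 2, colMeans(r))
  nrm <- sqrt(colSums(r^2))
  nrm[nrm == 0] <- 1
  sweep(r, 2, nrm, "/")
}

#' Label transfer by embedded nearest neighbors
#'
#' Majority label among the k nearest labeled anchors in a shared
#' embedding; the score is the winning vote fraction.
#'
#' @param cells cells x components coordinate matrix (or `Embedding`).
#' @param anchors anchors x components coordinate matrix in the same space.
#' @param anchor_labels label per anchor.
#' @param harmonization optional named map anchor label -> common
#'   vocabulary (identity by default).
#' @param k neighbors (must not exceed the number of anchors).
#' @return data.frame(barcode, label, harmonized, score).
#' @export
annotate_knn <- function(cells, anchors, anchor_labels, harmonization = NULL,
                         k = 15) {
  Xq <- if (inherits(cells, "Embedding")) cells$coords else as.matrix(cells)
  Xa <- as.matrix(anchors)
  if (!nrow(Xa)) stop("anchors must be nonempty")
  if (k > nrow(Xa)) stop("k exceeds the number of anchors")
  stopifnot(length(anchor_labels) == nrow(Xa))
  d2 <- pairwise_sqdist(Xq, Xa)
  lab <- character(nrow(Xq)); sc <- numeric(nrow(Xq))
  for (i in seq_len(nrow(Xq))) {
    nn <- order(d2[i, ])[seq_len(k)]
    tab <- sort(table(anchor_labels[nn]), decreasing = TRUE)
    lab[i] <- names(tab)[1]
    sc[i] <- tab[1] / k
  }
  harm <- if (is.null(harmonization)) lab else unname(harmonization[lab])
  data.frame(barcode = rownames(Xq) %||% seq_len(nrow(Xq)),
             label = lab, harmonized = harm, score = sc, row.names = NULL)
}

#' Consensus cell annotation across annotators
#'
#' The consensus label is the modal harmonized label when its vote
#' fraction strictly exceeds `threshold` (so 5 of 6 annotators agreeing,
#' 0.833, is assigned, while 4 of 6 or 4 of 5 are not); ties and weaker
#' majorities yield "unassigned".
#'
#' @param labels cells x annotators matrix or data.frame of harmonized
#'   labels (NA = no call by that annotator).
#' @param threshold strict vote-fraction threshold (default 0.80).
#' @return data.frame(consensus, agreement): agreement is the modal vote
#'   fraction among annotators that made a call.
#' @export
consensus_annotation <- function(labels, threshold = 0.80) {
  labels <- as.matrix(labels)
  out_lab <- character(nrow(labels))
  agree <- numeric(nrow(labels))
  for (i in seq_len(nrow(labels))) {
    v <- labels[i, ]
    v <- v[!is.na(v)]
    if (!length(v)) { out_lab[i] <- "unassigned"; agree[i] <- 0; next }
    tab <- table(v)
    top <- max(tab)
    agree[i] <- top / length(v)
    winners <- names(tab)[tab == top]
    out_lab[i] <- if (length(winners) == 1 && agree[i] > threshold)
      winners else "unassigned"
  }
  data.frame(consensus = out_lab, agreement = agree, row.names = NULL)
}

#' Retain lymphoid cells
#'
#' Keeps cells whose consensus label belongs to the lymphoid lineages
#' (B cells, CD4 T, CD8 T, other T, NK). Unassigned cells are dropped;
#' known non-lymphoid labels (monocytes, DC, platelets, ...) are dropped;
#' an unrecognized label is an error naming it. Idempotent.
#'
#' @param meta cell metadata with a consensus label column.
#' @param label_col name of the consensus column.
#' @return the filtered metadata with a `lineage` column; per-lineage
#'   counts in attribute "lineage_counts".
#' @export
subset_lymphoid <- function(meta, label_col = "consensus") {
  labs <- meta[[label_col]]
  nonlymph <- c("Monocyte", "CD14 Mono", "CD16 Mono", "DC", "cDC", "pDC",
                "Platelet", "Eryth", "HSPC", "unassigned")
  lymph_lineages <- c("B cells", "CD4 T", "CD8 T", "other T", "NK")
  known <- labs %in% c(subtype_vocabulary(), lymph_lineages, nonlymph)
  if (any(!known))
    stop("unknown label lineage for: ",
         paste(unique(labs[!known]), collapse = ", "))
  keep <- !(labs %in% nonlymph)
  out <- meta[keep, , drop = FALSE]
  out$lineage <- lymphoid_lineage(out[[label_col]])
  counts <- table(factor(out$lineage, lymph_lineages))
  attr(out, "lineage_counts") <- counts
  out
}
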