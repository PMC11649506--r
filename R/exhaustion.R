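#' Module score with expression-bin-matched control genes
#'
#' Per-cell signature score: genes are binned into `nbin` equal-size bins
#' by mean expression across cells; each panel gene contributes `nctrl`
#' control genes sampled uniformly without replacement from its bin; the
#' score of a gene set is mean(panel genes) - mean(control multiset) per
#' cell. In signed mode (default) the reported score is
#' score(plus genes) - score(minus genes), so loss of effector genes and
#' gain of inhibitory receptors move the score the same way; `signed =
#' FALSE` scores all members as one set for parity with the unsigned
#' convention.
#'
#' @param X log-normalized genes x cells matrix.
#' @param panel a [gene_panel()].
#' @param nbin number of expression bins (default 24).
#' @param nctrl control genes sampled per panel gene (capped at bin size).
#' @param seed RNG seed for control sampling.
#' @param signed use the panel signs (default TRUE).
#' @return data.frame(barcode, score) with attributes nbin, nctrl, seed,
#'   panel name. Panel genes missing from X are dropped with a warning;
#'   an entirely absent panel is an error.
#' @export
module_score <- function(X, panel, nbin = 24, nctrl = 100, seed = 1L,
                         signed = TRUE) {
  stopifnot(inherits(panel, "GenePanel"))
  if (nrow(X) < nbin) stop("need at least nbin genes")
  members <- panel$members
  present <- names(members)[names(members) %in% rownames(X)]
  if (!length(present)) stop("panel entirely absent from the matrix")
  if (length(present) < length(members))
    warning("panel genes missing from matrix: ",
            paste(setdiff(names(members), present), collapse = ", "))
  members <- members[present]

  gmean <- Matrix::rowMeans(X)
  bin <- ceiling(rank(gmean, ties.method = "first") / (length(gmean) / nbin))
  bin_members <- split(rownames(X), bin)

  ctrl <- with_stage_seed(seed, "modulescore", {
    out <- list()
    for (g in present) {
      pool <- bin_members[[as.character(bin[match(g, rownames(X))])]]
      out[[g]] <- sample(pool, min(nctrl, length(pool)))
    }
    out
  })

  cellsum <- function(genes) {
    if (!length(genes)) return(rep(0, ncol(X)))
    Matrix::colMeans(X[genes, , drop = FALSE])
  }
  set_score <- function(gs) {
    if (!length(gs)) return(rep(0, ncol(X)))
    panel_mean <- cellsum(gs)
    # control multiset: mean over panel genes of their control-set means
    ctrl_mean <- rowMeans(vapply(gs, function(g) cellsum(ctrl[[g]]),
                                 numeric(ncol(X))))
    panel_mean - ctrl_mean
  }

  score <- if (signed) {
    set_score(names(members)[members > 0]) -
      set_score(names(members)[members < 0])
  } else {
    set_score(names(members))
  }
  out <- data.frame(barcode = colnames(X) %||% seq_len(ncol(X)),
                    score = score, row.names = NULL)
  attr(out, "nbin") <- nbin
  attr(out, "nctrl") <- nctrl
  attr(out, "seed") <- seed
  attr(out, "panel") <- panel$name
  attr(out, "signed") <- signed
  out
}

#' Donor-aware cohort comparison of exhaustion module scores
#'
#' Uses the module score as the response in the random-intercept model,
#' with patient condition as fixed effect and donor as random effect;
#' optionally per cell type (stratified) and jointly with cell-type fixed
#' effects.
#'
#' @param scores output of [module_score()] (barcode, score).
#' @param meta per-cell metadata with donor, cohort and cell-type columns.
#' @param contrast length-2 cohort vector (reference, comparison).
#' @param cell_types cell types to test separately (default: the panel's
#'   targets present in the data; NULL = all in meta).
#' @param celltype_col metadata cell-type column.
#' @param df_method see [fit_lmm()].
#' @return data.frame of per-stratum results (cell_type "joint" for the
#'   pooled model with cell-type fixed effects): estimate, se, df, p,
#'   tau2, sigma2, n_cells, n_donors.
#' @export
exhaustion_test <- function(scores, meta, contrast = c("RAP", "CCI"),
                            cell_types = NULL, celltype_col = "consensus",
                            df_method = "satterthwaite") {
  stopifnot(length(contrast) == 2)
  d <- merge(scores, meta, by = "barcode")
  d <- d[d$cohort %in% contrast, , drop = FALSE]
  if (is.null(cell_types)) cell_types <- unique(d[[celltype_col]])
  cond <- as.integer(d$cohort == contrast[2])

  one <- function(sel, label, covariates = NULL) {
    fit <- fit_lmm(d$score[sel], cond[sel], d$donor[sel],
                   covariates = if (is.null(covariates)) NULL
                                else covariates[sel, , drop = FALSE],
                   df_method = df_method)
    data.frame(cell_type = label, contrast = paste(contrast[2], "vs", contrast[1]),
               estimate = fit$beta1, se = fit$se[2], df = fit$df,
               p = fit$p, tau2 = fit$tau2, sigma2 = fit$sigma2,
               n_cells = fit$n_cells, n_donors = fit$n_donors)
  }
  res <- lapply(cell_types, function(ct)
    one(d[[celltype_col]] == ct, ct))
  if (length(cell_types) > 1) {
    ctf <- factor(d[[celltype_col]])
    mm <- stats::model.matrix(~ ctf)[, -1, drop = FALSE]
    res <- c(res, list(one(rep(TRUE, nrow(d)), "joint", covariates = mm)))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
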