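#' Default end-to-end run configuration
#'
#' Stage toggles and per-stage parameter blocks mirroring each module's
#' defaults. Stages run in fixed order: simulate, qc, cluster, annotate,
#' compose, de, score, enrich.
#'
#' @param seed global seed (each stage derives a named substream).
#' @param outdir output directory (NULL = keep results in memory only).
#' @param ... named overrides merged into the nested defaults, e.g.
#'   `simulate = list(cells_per_donor = 100)`.
#' @return a `RunConfig` list.
#' @export
default_run_config <- function(seed = 1L, outdir = NULL, ...) {
  cfg <- list(
    seed = as.integer(seed),
    outdir = outdir,
    stages = list(simulate = TRUE, qc = TRUE, cluster = TRUE,
                  annotate = TRUE, compose = TRUE, de = TRUE,
                  score = TRUE, enrich = FALSE),
    simulate = list(cells_per_donor = 150L, n_genes = 1200L,
                    donors_per_cohort = c(HS = 4L, D4 = 3L, RAP = 4L, CCI = 4L),
                    n_empty = 1500L),
    qc = list(ambient_count_max = 100, n_mc = 2000, fdr_threshold = 0.01,
              mito_threshold = 0.05, expected_doublet_rate = 0.05,
              k_neighbors = 25),
    cluster = list(norm = "libsize", n_pcs = 50, k_neighbors = 100,
                   resolution = 0.1, batch_key = "sample"),
    annotate = list(n_panels = 6L, consensus_threshold = 0.80, knn_k = 15),
    de = list(reference = "RAP", comparison = "CCI",
              min_expressing_frac = 0.05, min_cells_per_donor = 5),
    score = list(nbin = 24, nctrl = 100),
    enrich = list(gmt = NULL, p_adj_threshold = 0.05))
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]])
  class(cfg) <- "RunConfig"
  cfg
}

#' Read a run configuration from YAML
#' @param path YAML file with fields as in [default_run_config()].
#' @return a `RunConfig`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(default_run_config,
          c(list(seed = y$seed %||% 1L, outdir = y$outdir),
            y[setdiff(names(y), c("seed", "outdir"))]))
}

#' Run the full pipeline
#'
#' Executes the enabled stages in fixed order on a simulated cohort (or a
#' 10x triplet given in `config$input`), each stage consuming the previous
#' stage's outputs. Returns all stage outputs plus a manifest recording
#' the seed, package version and per-stage cell/gene counts; with an
#' `outdir`, stage tables are also written as CSV.
#'
#' @param config a `RunConfig` from [default_run_config()].
#' @return named list of stage outputs with `manifest`.
#' @export
run_pipeline <- function(config = default_run_config()) {
  seed <- config$seed
  st <- config$stages
  state <- list()
  manifest <- list(seed = seed,
                   version = as.character(utils::packageVersion("lymphtraj")),
                   counts = list())
  need <- function(what, stage, from) {
    if (is.null(state[[what]]))
      stop("stage '", stage, "' requires output of stage '", from, "'")
  }

  if (isTRUE(st$simulate)) {
    simcfg <- do.call(sim_config, c(list(seed = stage_seed(seed, "sim")),
                                    config$simulate))
    state$sim <- simulate_cohort(simcfg)
    state$simcfg <- simcfg
    manifest$counts$simulate <- dim(state$sim$counts)
  } else if (!is.null(config$input)) {
    state$sim <- list(counts = read_tenx(config$input$counts),
                      meta = utils::read.csv(config$input$sample_sheet))
    manifest$counts$input <- dim(state$sim$counts)
  }

  if (isTRUE(st$qc)) {
    need("sim", "qc", "simulate")
    q <- config$qc
    state$qc <- run_qc(state$sim$counts,
                       ambient_count_max = q$ambient_count_max,
                       n_mc = q$n_mc, fdr_threshold = q$fdr_threshold,
                       k_neighbors = q$k_neighbors,
                       expected_doublet_rate = q$expected_doublet_rate,
                       mito_threshold = q$mito_threshold,
                       seed = stage_seed(seed, "qc"))
    manifest$counts$qc <- state$qc$summary
  }

  if (isTRUE(st$cluster)) {
    need("qc", "cluster", "qc")
    cl <- config$cluster
    kept <- state$qc$filtered
    norm <- lognormalize(kept, method = cl$norm)
    emb <- run_pca(norm, n = min(cl$n_pcs, length(kept$barcodes) - 1),
                   seed = stage_seed(seed, "pca"))
    meta <- state$sim$meta[match(kept$barcodes, state$sim$meta$barcode), ]
    batch <- meta[[cl$batch_key]] %||% meta$sample
    emb <- integrate_batches(emb, batch, seed = stage_seed(seed, "integrate"))
    k <- min(cl$k_neighbors, length(kept$barcodes) - 1)
    clusters <- louvain_cluster(emb, k_neighbors = k,
                                resolution = cl$resolution,
                                seed = stage_seed(seed, "louvain"))
    state$cluster <- list(norm = norm, embedding = emb, clusters = clusters,
                          meta = meta)
    manifest$counts$cluster <- c(cells = nrow(emb$coords),
                                 clusters = length(unique(clusters)))
  }

  if (isTRUE(st$annotate)) {
    need("cluster", "annotate", "cluster")
    an <- config$annotate
    panels <- build_reference_panels(state$simcfg, n_panels = an$n_panels)
    norm <- state$cluster$norm
    votes <- list()
    for (p in seq_len(length(panels) - 1)) {
      votes[[paste0("panel", p)]] <-
        annotate_correlation(norm, panels[[p]])$harmonized
    }
    anchor <- panels[[length(panels)]]
    emb <- state$cluster$embedding
    anc_coords <- t(anchor$cells[names(emb$center), , drop = FALSE] - emb$center) %*%
      emb$rotation
    votes$knn <- annotate_knn(emb$coords, anc_coords, anchor$cell_labels,
                              k = an$knn_k)$harmonized
    vmat <- do.call(cbind, votes)
    cons <- consensus_annotation(vmat, threshold = an$consensus_threshold)
    meta <- state$cluster$meta
    meta$consensus <- cons$consensus
    meta$agreement <- cons$agreement
    meta$cluster <- state$cluster$clusters
    lymph <- subset_lymphoid(meta)
    state$annotate <- list(votes = vmat, meta = meta, lymphoid = lymph)
    manifest$counts$annotate <- c(
      assigned = sum(cons$consensus != "unassigned"),
      lymphoid = nrow(lymph))
  }

  if (isTRUE(st$compose)) {
    need("annotate", "compose", "annotate")
    lymph <- state$annotate$lymphoid
    ct <- composition_crosstab(lymph)
    props <- subject_proportions(lymph)
    state$compose <- list(crosstab = ct, proportions = props,
                          tests = tryCatch(composition_tests(props),
                                           error = function(e) NULL))
    manifest$counts$compose <- c(cells = ct$grand_total)
  }

  if (isTRUE(st$de)) {
    need("annotate", "de", "annotate")
    decfg <- config$de
    lymph <- state$annotate$lymphoid
    norm <- state$cluster$norm
    types <- intersect(
      unique(lymph$consensus[lymph$cohort == decfg$comparison]),
      unique(lymph$consensus[lymph$cohort == decfg$reference]))
    de <- list()
    for (ct in types) {
      de[[ct]] <- tryCatch(
        de_celltype(norm, lymph, ct,
                    reference = decfg$reference,
                    comparison = decfg$comparison,
                    min_cells_per_donor = decfg$min_cells_per_donor,
                    min_expressing_frac = decfg$min_expressing_frac),
        error = function(e) NULL)
    }
    state$de <- de
    manifest$counts$de <- vapply(de, function(d)
      if (is.null(d)) 0L else sum(d$significant), integer(1))
  }

  if (isTRUE(st$score)) {
    need("annotate", "score", "annotate")
    sc <- config$score
    lymph <- state$annotate$lymphoid
    norm <- state$cluster$norm
    res <- list()
    for (panel in list(nk_exhaustion_panel(), cd8tem_exhaustion_panel())) {
      ms <- module_score(norm[, match(lymph$barcode, colnames(norm))],
                         panel, nbin = sc$nbin, nctrl = sc$nctrl,
                         seed = stage_seed(seed, paste0("score_", panel$name)))
      tst <- tryCatch(
        exhaustion_test(ms, lymph,
                        cell_types = intersect(panel$target_types,
                                               lymph$consensus)),
        error = function(e) NULL)
      res[[panel$name]] <- list(scores = ms, test = tst)
    }
    state$score <- res
  }

  if (isTRUE(st$enrich)) {
    need("de", "enrich", "de")
    if (is.null(config$enrich$gmt))
      stop("stage 'enrich' requires a GMT path in config$enrich$gmt")
    coll <- read_gmt(config$enrich$gmt)
    state$enrich <- lapply(state$de, function(d) {
      if (is.null(d) || !any(d$significant)) NULL
      else enrich_directional(d, coll, config$enrich$p_adj_threshold)
    })
  }

  state$manifest <- manifest
  if (!is.null(config$outdir)) write_pipeline_outputs(state, config$outdir)
  state
}

write_pipeline_outputs <- function(state, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(x, nm) if (!is.null(x))
    utils::write.csv(x, file.path(outdir, nm), row.names = FALSE)
  if (!is.null(state$qc)) wcsv(state$qc$report, "qc_report.csv")
  if (!is.null(state$annotate))
    wcsv(state$annotate$meta, "annotations.csv")
  if (!is.null(state$compose))
    write_composition(state$compose$crosstab, file.path(outdir, "composition.csv"))
  if (!is.null(state$de))
    wcsv(do.call(rbind, state$de), "de_results.csv")
  if (!is.null(state$score))
    for (nm in names(state$score))
      wcsv(state$score[[nm]]$test, paste0("exhaustion_", nm, ".csv"))
  yaml::write_yaml(state$manifest, file.path(outdir, "manifest.yaml"))
  invisible(outdir)
}

#' Composition report in the published table layout
#'
#' The cohort x subtype cross-tab in the published row order with
#' per-lineage totals appended.
#'
#' @param meta consensus-annotated lymphoid cell metadata, or a
#'   pre-tabulated counts data.frame (e.g. [table2_counts()]).
#' @param ... passed to [composition_crosstab()].
#' @return list(crosstab = `CompositionTable`, lineage_totals, grand_total).
#' @export
table2_report <- function(meta, ...) {
  ct <- composition_crosstab(meta, ...)
  lin <- ct$lineage %||% stats::setNames(lymphoid_lineage(ct$subtypes),
                                         ct$subtypes)
  lt <- rowsum(ct$counts, lin[rownames(ct$counts)])
  list(crosstab = ct,
       lineage_totals = rowSums(lt),
       grand_total = ct$grand_total)
}
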