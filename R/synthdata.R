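#' Configuration for the hierarchical droplet simulator
#'
#' Defines the generative model used for benchmarking: donors nested in
#' clinical cohorts (HS healthy, D4 acute sepsis day 4, RAP rapid recovery,
#' CCI chronic critical illness), per-cell-type negative-binomial expression
#' programs with marker enrichment, a donor random intercept shared across a
#' designated donor-variable gene subset, cohort-specific cell-type
#' composition (defaulting to the packaged composition-table proportions),
#' mitochondrial content, ambient empty droplets, doublets and a signed
#' exhaustion-panel shift in CCI cells of designated types.
#'
#' Per cell c of donor d and type t, gene g has NB mean
#' \code{mu_gc = L_c * share_g(d,t,c)} with
#' \code{share ~ w_g * exp(marker_gt + beta_gt * I(CCI) + u_d * I(g donor-variable)
#' + s_g * delta * I(CCI, t in exhaustion targets))}, normalized over genes,
#' where \code{w_g} is a log-normal baseline, \code{u_d ~ N(0, tau^2)} and
#' \code{L_c} is a log-normal library size. Counts are
#' \code{NB(mu, size = theta)}; layers are a fixed (0.75, 0.20, 0.05)
#' multinomial split of the total.
#'
#' @param seed master seed; all stages derive named substreams from it.
#' @param n_genes total genes (must cover markers, mito and panel genes).
#' @param cohorts cohort ids, a subset of HS, D4, RAP, CCI.
#' @param donors_per_cohort named (or scalar) donor counts per cohort;
#'   default mirrors the study design (12/4/4/5).
#' @param cells_per_donor cells per donor (droplet target scaled to desk
#'   size; 5000 in the study, 300 by default here).
#' @param celltype_props named list cohort -> named probability vector over
#'   cell types; default derives from the packaged composition counts for
#'   eight simulated subtypes.
#' @param n_marker_genes,marker_logfc markers per type and their log-fold
#'   enrichment (natural-log units) when `marker_program` is NULL.
#' @param marker_program optional named list type -> named numeric
#'   (gene -> log-fold enrichment).
#' @param condition_effects data.frame(cell_type, gene, beta): natural-log
#'   fold effects of CCI vs RAP. Default plants beta = 1 on 30 CD8 TEM and
#'   20 NK genes.
#' @param donor_sd tau, SD of the donor random intercept (log-units).
#' @param donor_gene_frac fraction of genes carrying the donor intercept.
#' @param nb_dispersion theta, NB size parameter (> 0).
#' @param libsize_lognormal c(meanlog, sdlog) of per-cell library size.
#' @param n_mito_genes mitochondrial genes (0 disables mito simulation).
#' @param mito_fraction_beta c(a, b) Beta parameters of per-cell mito share.
#' @param doublet_rate fraction of droplets that are doublets.
#' @param n_empty,empty_count_range ambient droplets and their total-count
#'   range (uniform integer).
#' @param exhaustion_shift delta, log-units added (signed) to exhaustion
#'   panel genes in CCI cells of `exhaustion_types`.
#' @param exhaustion_types cell types receiving the exhaustion shift.
#' @return a validated `SimConfig` object.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       cohorts = c("HS", "D4", "RAP", "CCI"),
                       donors_per_cohort = c(HS = 12L, D4 = 4L, RAP = 4L, CCI = 5L),
                       cells_per_donor = 300L,
                       celltype_props = NULL,
                       n_marker_genes = 25L,
                       marker_logfc = 2,
                       marker_program = NULL,
                       condition_effects = NULL,
                       donor_sd = 0.5,
                       donor_gene_frac = 0.3,
                       nb_dispersion = 2,
                       libsize_lognormal = c(log(2500), 0.3),
                       n_mito_genes = 10L,
                       mito_fraction_beta = c(1.5, 48.5),
                       doublet_rate = 0.05,
                       n_empty = 2000L,
                       empty_count_range = c(20L, 80L),
                       exhaustion_shift = 1,
                       exhaustion_types = c("CD8 TEM", "NK")) {
  stopifnot(all(cohorts %in% c("HS", "D4", "RAP", "CCI")))
  if (length(donors_per_cohort) == 1L && is.null(names(donors_per_cohort)))
    donors_per_cohort <- stats::setNames(rep(donors_per_cohort, length(cohorts)), cohorts)
  donors_per_cohort <- donors_per_cohort[cohorts]
  if (is.null(celltype_props)) celltype_props <- default_celltype_props(cohorts)
  types <- names(celltype_props[[1]])

  panel_genes <- unique(c(names(nk_exhaustion_panel()$members),
                          names(cd8tem_exhaustion_panel()$members)))
  mito_ids <- if (n_mito_genes > 0)
    paste0("MT-", sprintf("%02d", seq_len(n_mito_genes))) else character()

  if (is.null(marker_program)) {
    n_named <- length(panel_genes) + length(mito_ids)
    need <- n_named + length(types) * n_marker_genes
    if (n_genes < need)
      stop("n_genes smaller than union of marker/mito/panel genes (need >= ",
           need, ")")
    reg <- paste0("G", sprintf("%04d", seq_len(n_genes - n_named)))
    marker_program <- list()
    for (i in seq_along(types)) {
      idx <- ((i - 1) * n_marker_genes + 1):(i * n_marker_genes)
      marker_program[[types[i]]] <-
        stats::setNames(rep(marker_logfc, n_marker_genes), reg[idx])
    }
    gene_ids <- c(panel_genes, mito_ids, reg)
  } else {
    named <- unique(c(panel_genes, mito_ids, unlist(lapply(marker_program, names))))
    if (n_genes < length(named))
      stop("n_genes smaller than union of marker/mito/panel genes")
    reg <- paste0("G", sprintf("%04d", seq_len(n_genes - length(named))))
    gene_ids <- c(named, reg)
  }

  if (is.null(condition_effects)) {
    free <- setdiff(gene_ids, c(panel_genes, mito_ids,
                                unlist(lapply(marker_program, names))))
    condition_effects <- data.frame(
      cell_type = rep(c("CD8 TEM", "NK"), c(30L, 20L)),
      gene = free[seq_len(50L)],
      beta = 1)
    condition_effects <-
      condition_effects[condition_effects$cell_type %in% types, , drop = FALSE]
  }

  cfg <- structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    gene_ids = gene_ids, cohorts = cohorts,
    donors_per_cohort = donors_per_cohort,
    cells_per_donor = as.integer(cells_per_donor),
    celltype_props = celltype_props, cell_types = types,
    marker_program = marker_program,
    condition_effects = condition_effects,
    donor_sd = donor_sd, donor_gene_frac = donor_gene_frac,
    nb_dispersion = nb_dispersion,
    libsize_lognormal = libsize_lognormal,
    mito_genes = mito_ids, mito_fraction_beta = mito_fraction_beta,
    doublet_rate = doublet_rate,
    n_empty = as.integer(n_empty),
    empty_count_range = as.integer(empty_count_range),
    exhaustion_shift = exhaustion_shift,
    exhaustion_types = exhaustion_types,
    layer_split = c(spliced = 0.75, unspliced = 0.20, ambiguous = 0.05)),
    class = "SimConfig")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  for (co in cfg$cohorts) {
    p <- cfg$celltype_props[[co]]
    if (is.null(p)) stop("missing celltype_props for cohort ", co)
    if (abs(sum(p) - 1) > 1e-9)
      stop("celltype_props for ", co, " must sum to 1")
    if (any(p < 0 | p > 1)) stop("probabilities must lie in [0,1]")
  }
  stopifnot(cfg$nb_dispersion > 0, cfg$donor_sd >= 0,
            cfg$doublet_rate >= 0, cfg$doublet_rate <= 1,
            cfg$donor_gene_frac >= 0, cfg$donor_gene_frac <= 1)
  if (cfg$cells_per_donor < 1L) stop("cells_per_donor must be >= 1")
  invisible(cfg)
}

#' Default cohort cell-type composition for the simulator
#'
#' Proportions of eight simulated lymphoid subtypes per cohort, derived
#' from the packaged composition-table counts (renormalized over the
#' simulated subtypes), so the generator's composition shifts mirror the
#' study's cohort structure.
#'
#' @param cohorts cohorts to include.
#' @return named list cohort -> named probability vector.
#' @export
default_celltype_props <- function(cohorts = c("HS", "D4", "RAP", "CCI")) {
  tab <- table2_counts()
  types <- c("B naive", "Plasmablast", "CD4 T naive", "CD4 TCM",
             "CD8 T naive", "CD8 TEM", "NK", "MAIT")
  tab <- tab[match(types, tab$subtype), ]
  out <- lapply(cohorts, function(co) {
    p <- tab[[co]] / sum(tab[[co]])
    stats::setNames(p, types)
  })
  names(out) <- cohorts
  out
}

#' Simulate a cohort-structured droplet dataset with ground truth
#'
#' Draws donors, cells, doublets and ambient empty droplets under the
#' generative model described in [sim_config()]. Identical seeds give
#' bit-identical outputs.
#'
#' @param config a `SimConfig`.
#' @return list with `counts` (a [count_matrix()] with spliced, unspliced,
#'   ambiguous and total layers), `meta` (per-barcode data.frame: barcode,
#'   donor, cohort, sample), and `truth` (list: `cells` per-barcode truth
#'   including doublet/empty flags and parents, `effects` the beta table,
#'   `genes` realized baseline weights and flags, `donors` realized random
#'   intercepts, `ambient` the ambient gene profile used for empties).
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  with_stage_seed(config$seed, "simulate", simulate_cohort_impl(config))
}

# shared gene baseline: the "biology" common to the cohort data and every
# reference panel, drawn from its own named substream of the master seed
gene_baseline <- function(cfg) {
  with_stage_seed(cfg$seed, "genebaseline", {
    w <- stats::rlnorm(cfg$n_genes, meanlog = 0, sdlog = 1)
    names(w) <- cfg$gene_ids
    panel_all <- unique(c(names(nk_exhaustion_panel()$members),
                          names(cd8tem_exhaustion_panel()$members)))
    w[intersect(panel_all, cfg$gene_ids)] <-
      w[intersect(panel_all, cfg$gene_ids)] * 8
    marker_genes <- unlist(lapply(cfg$marker_program, names))
    w[intersect(marker_genes, cfg$gene_ids)] <-
      w[intersect(marker_genes, cfg$gene_ids)] * 2
    w
  })
}

simulate_cohort_impl <- function(cfg) {
  G <- cfg$n_genes
  gid <- cfg$gene_ids
  types <- cfg$cell_types

  # realized gene-level parameters
  w <- gene_baseline(cfg)
  panel_plus <- c(names(which(nk_exhaustion_panel()$members > 0)),
                  names(which(cd8tem_exhaustion_panel()$members > 0)))
  panel_minus <- c(names(which(nk_exhaustion_panel()$members < 0)),
                   names(which(cd8tem_exhaustion_panel()$members < 0)))
  donor_variable <- rep(FALSE, G)
  donor_variable[sample.int(G, round(cfg$donor_gene_frac * G))] <- TRUE
  is_mito <- gid %in% cfg$mito_genes

  # per-type log-enrichment vectors
  type_lfc <- matrix(0, G, length(types), dimnames = list(gid, types))
  for (t in names(cfg$marker_program)) {
    mk <- cfg$marker_program[[t]]
    type_lfc[names(mk), t] <- type_lfc[names(mk), t] + mk
  }
  beta_mat <- matrix(0, G, length(types), dimnames = list(gid, types))
  ce <- cfg$condition_effects
  if (!is.null(ce) && nrow(ce)) {
    keep <- ce$gene %in% gid & ce$cell_type %in% types
    ce <- ce[keep, , drop = FALSE]
    beta_mat[cbind(match(ce$gene, gid), match(ce$cell_type, types))] <- ce$beta
  }
  # signed exhaustion shift for CCI cells of designated types
  exh_mat <- matrix(0, G, length(types), dimnames = list(gid, types))
  sgn <- numeric(G); names(sgn) <- gid
  sgn[intersect(panel_plus, gid)] <- 1
  sgn[intersect(panel_minus, gid)] <- -1
  for (t in intersect(cfg$exhaustion_types, types))
    exh_mat[, t] <- sgn * cfg$exhaustion_shift

  # donors
  donors <- data.frame(
    donor = character(), cohort = character(), u = numeric())
  for (co in cfg$cohorts) {
    nd <- cfg$donors_per_cohort[[co]]
    donors <- rbind(donors, data.frame(
      donor = sprintf("%s_d%02d", co, seq_len(nd)),
      cohort = co,
      u = stats::rnorm(nd, 0, cfg$donor_sd)))
  }

  n_cells <- nrow(donors) * cfg$cells_per_donor
  counts <- Matrix::Matrix(0, G, 0, sparse = TRUE)
  blocks <- vector("list", nrow(donors))
  cell_type <- character(n_cells)
  cell_donor <- character(n_cells)
  cell_cohort <- character(n_cells)
  cell_lib <- numeric(n_cells)
  cell_mito <- numeric(n_cells)
  pos <- 0L
  for (di in seq_len(nrow(donors))) {
    d <- donors$donor[di]; co <- donors$cohort[di]; u <- donors$u[di]
    nc <- cfg$cells_per_donor
    tt <- sample(types, nc, replace = TRUE, prob = cfg$celltype_props[[co]])
    L <- stats::rlnorm(nc, cfg$libsize_lognormal[1], cfg$libsize_lognormal[2])
    mfrac <- if (length(cfg$mito_genes))
      stats::rbeta(nc, cfg$mito_fraction_beta[1], cfg$mito_fraction_beta[2])
    else rep(0, nc)
    mu <- matrix(0, G, nc)
    # donor intercept multiplies the donor-variable genes after share
    # normalization, so it is a genuine relative shift (a global intercept
    # applied before normalization would cancel out of the multinomial)
    dmul <- exp(u * donor_variable)
    for (t in unique(tt)) {
      sel <- which(tt == t)
      lw <- log(w) + type_lfc[, t] +
        (if (co == "CCI") beta_mat[, t] + exh_mat[, t] else 0)
      r <- exp(lw)
      r_n <- r; r_n[is_mito] <- 0
      share_n <- r_n / sum(r_n)
      if (any(is_mito)) {
        share_m <- r[is_mito] / sum(r[is_mito])
        for (j in sel) {
          mu[!is_mito, j] <- L[j] * (1 - mfrac[j]) * share_n[!is_mito] *
            dmul[!is_mito]
          mu[is_mito, j] <- L[j] * mfrac[j] * share_m * dmul[is_mito]
        }
      } else {
        mu[, sel] <- outer(share_n * dmul, L[sel])
      }
    }
    x <- stats::rnbinom(G * nc, mu = as.vector(mu), size = cfg$nb_dispersion)
    m <- Matrix::Matrix(matrix(x, G, nc), sparse = TRUE)
    blocks[[di]] <- m
    idx <- pos + seq_len(nc)
    cell_type[idx] <- tt; cell_donor[idx] <- d; cell_cohort[idx] <- co
    cell_lib[idx] <- L; cell_mito[idx] <- mfrac
    pos <- pos + nc
  }
  counts <- do.call(cbind, blocks)

  # doublets: elementwise sums of two cells sampled within a donor
  n_doub <- round(cfg$doublet_rate * n_cells)
  doub <- NULL
  p1 <- p2 <- integer(0)
  if (n_doub > 0) {
    p1 <- sample.int(n_cells, n_doub, replace = TRUE)
    p2 <- vapply(p1, function(i) {
      same <- which(cell_donor == cell_donor[i])
      same[sample.int(length(same), 1L)]
    }, integer(1))
    doub <- counts[, p1, drop = FALSE] + counts[, p2, drop = FALSE]
  }

  # ambient profile: library-size-weighted average of expected cell profiles
  ambient <- Matrix::rowSums(counts) + 0.5
  ambient <- as.numeric(ambient / sum(ambient))
  emp <- NULL
  if (cfg$n_empty > 0) {
    etot <- sample(seq(cfg$empty_count_range[1], cfg$empty_count_range[2]),
                   cfg$n_empty, replace = TRUE)
    emp <- Matrix::Matrix(
      vapply(etot, function(tt)
        as.numeric(stats::rmultinom(1, tt, ambient)), numeric(G)),
      sparse = TRUE)
  }

  total <- do.call(cbind, Filter(Negate(is.null), list(counts, doub, emp)))
  n_all <- ncol(total)
  barcodes <- sprintf("bc%06d", seq_len(n_all))
  dimnames(total) <- list(gid, barcodes)

  # splicing layers: fixed multinomial split of each total count
  sp <- cfg$layer_split
  tot_t <- methods::as(total, "CsparseMatrix")
  x <- tot_t@x
  xs <- stats::rbinom(length(x), size = x, prob = sp["spliced"])
  xu <- stats::rbinom(length(x), size = x - xs,
                      prob = sp["unspliced"] / (1 - sp["spliced"]))
  xa <- x - xs - xu
  mk_layer <- function(vals) {
    m <- tot_t; m@x <- as.double(vals); Matrix::drop0(m)
  }
  layers <- list(spliced = mk_layer(xs), unspliced = mk_layer(xu),
                 ambiguous = mk_layer(xa), total = tot_t)

  kind <- rep(c("cell", "doublet", "empty"),
              c(n_cells, n_doub, cfg$n_empty))
  truth_cells <- data.frame(
    barcode = barcodes,
    true_type = c(cell_type, ifelse(cell_type[p1] == cell_type[p2],
                                    cell_type[p1], "mixed"),
                  rep(NA, cfg$n_empty)),
    donor = c(cell_donor, cell_donor[p1], rep(NA, cfg$n_empty)),
    cohort = c(cell_cohort, cell_cohort[p1], rep(NA, cfg$n_empty)),
    is_doublet = kind == "doublet",
    is_empty = kind == "empty",
    parent1 = c(rep(NA, n_cells), cell_type[p1], rep(NA, cfg$n_empty)),
    parent2 = c(rep(NA, n_cells), cell_type[p2], rep(NA, cfg$n_empty)),
    libsize = c(cell_lib, cell_lib[p1] + cell_lib[p2], rep(NA, cfg$n_empty)),
    mito_fraction = c(cell_mito, (cell_mito[p1] + cell_mito[p2]) / 2,
                      rep(NA, cfg$n_empty)))
  meta <- data.frame(barcode = barcodes,
                     donor = truth_cells$donor,
                     cohort = truth_cells$cohort,
                     sample = truth_cells$donor)

  list(counts = count_matrix(layers, provenance = "simulate_cohort"),
       meta = meta,
       truth = list(cells = truth_cells,
                    effects = ce,
                    genes = data.frame(gene = gid, base_weight = w,
                                       donor_variable = donor_variable,
                                       is_mito = is_mito),
                    donors = donors,
                    type_lfc = type_lfc, beta_mat = beta_mat,
                    exh_mat = exh_mat,
                    ambient = ambient))
}

#' Build synthetic reference panels of varying granularity
#'
#' Emulates a set of independent reference datasets: each panel simulates
#' pure cells of every simulated subtype under the config's expression
#' programs with panel-specific measurement noise, pseudobulks them into
#' per-label mean profiles (log-normalized units) and per-label sample
#' profiles, and ships a total harmonization map into the common subtype
#' vocabulary. Panel `n_panels - 1` is coarse (lineage-level labels); the
#' last panel doubles as the anchor set for the kNN annotator.
#'
#' @param config a `SimConfig`.
#' @param n_panels number of panels (default 6).
#' @param cells_per_label pure cells simulated per label per panel.
#' @param samples_per_label pseudobulk sample profiles kept per label.
#' @return list of `ReferencePanel` objects (fields: name, labels,
#'   profiles, samples, harmonization, cells/cell_labels for the anchor
#'   panel).
#' @export
build_reference_panels <- function(config, n_panels = 6L,
                                   cells_per_label = 240L,
                                   samples_per_label = 10L) {
  validate_sim_config(config)
  types <- config$cell_types
  panels <- vector("list", n_panels)
  for (p in seq_len(n_panels)) {
    coarse <- (p == n_panels - 1L)
    panels[[p]] <- with_stage_seed(
      config$seed, paste0("refpanel", p),
      build_one_panel(config, sprintf("panel%d", p), coarse,
                      cells_per_label, samples_per_label,
                      keep_cells = (p == n_panels)))
  }
  panels
}

build_one_panel <- function(cfg, name, coarse, cells_per_label,
                            samples_per_label, keep_cells = FALSE) {
  G <- cfg$n_genes; gid <- cfg$gene_ids; types <- cfg$cell_types
  # same biology as simulate_cohort (shared baseline substream), measured
  # by an independent lab: mild gene-wise distortion plus sampling noise,
  # no donor effects and no condition effects
  w <- gene_baseline(cfg) * stats::rlnorm(G, 0, 0.1)

  type_lfc <- matrix(0, G, length(types), dimnames = list(gid, types))
  for (t in names(cfg$marker_program)) {
    mm <- cfg$marker_program[[t]]
    type_lfc[names(mm), t] <- mm
  }
  L <- exp(cfg$libsize_lognormal[1])
  cells <- matrix(0, G, 0)
  labels <- character(0)
  for (t in types) {
    share <- exp(log(w) + type_lfc[, t])
    share <- share / sum(share)
    x <- stats::rnbinom(G * cells_per_label, mu = rep(L * share, cells_per_label),
                        size = cfg$nb_dispersion)
    cells <- cbind(cells, matrix(x, G))
    labels <- c(labels, rep(t, cells_per_label))
  }
  # log-normalize (library size, scale 1e4)
  sf <- colSums(cells); sf[sf == 0] <- 1
  logx <- log1p(sweep(cells, 2, sf, "/") * 1e4)
  rownames(logx) <- gid
  grp_lab <- if (coarse) lymphoid_lineage(labels) else labels
  ulab <- unique(grp_lab)
  profiles <- vapply(ulab, function(l)
    rowMeans(logx[, grp_lab == l, drop = FALSE]), numeric(G))
  profiles <- t(profiles)            # label x gene
  colnames(profiles) <- gid
  samples <- lapply(ulab, function(l) {
    idx <- which(grp_lab == l)
    spl <- split(idx, cut(seq_along(idx), samples_per_label, labels = FALSE))
    out <- vapply(spl, function(ii)
      rowMeans(logx[, ii, drop = FALSE]), numeric(G))
    rownames(out) <- gid
    out
  })
  names(samples) <- ulab
  harmonization <- stats::setNames(ulab, ulab)  # already in common vocab
  structure(list(name = name, labels = ulab, profiles = profiles,
                 samples = samples, harmonization = harmonization,
                 cells = if (keep_cells) logx else NULL,
                 cell_labels = if (keep_cells) grp_lab else NULL),
            class = "ReferencePanel")
}

#' @export
print.ReferencePanel <- function(x, ...) {
  cat(sprintf("ReferencePanel '%s': %d labels x %d genes\n",
              x$name, nrow(x$profiles), ncol(x$profiles)))
  invisible(x)
}

#' Write a simulated dataset to disk in interchange formats
#'
#' 10x-style triplet for the counts, CSV for sample sheet and ground
#' truth, YAML for the config.
#'
#' @param sim output of [simulate_cohort()].
#' @param config the `SimConfig` used.
#' @param dir output directory.
#' @export
write_simulation <- function(sim, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tenx(sim$counts, file.path(dir, "counts"))
  utils::write.csv(sim$meta, file.path(dir, "sample_sheet.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$truth$cells, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  cfg <- config
  cfg$condition_effects <- as.list(cfg$condition_effects)
  yaml::write_yaml(unclass(cfg), file.path(dir, "sim_config.yaml"))
  invisible(dir)
}
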