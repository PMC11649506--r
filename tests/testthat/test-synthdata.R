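test_that("splicing layers sum exactly to the total layer", {
  fx <- fx_droplet_sim()
  ly <- fx$sim$counts$layers
  expect_equal(max(abs(ly$spliced + ly$unspliced + ly$ambiguous - ly$total)), 0)
})

test_that("identical seeds give bit-identical count matrices", {
  fx <- fx_droplet_sim()
  sim2 <- simulate_cohort(fx$cfg)
  expect_identical(as.matrix(fx$sim$counts$layers$total),
                   as.matrix(sim2$counts$layers$total))
  expect_identical(fx$sim$truth$cells, sim2$truth$cells)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(celltype_props = list(
    HS = c(`CD4 TCM` = 0.5, NK = 0.4)), cohorts = "HS"), "sum to 1")
  expect_error(sim_config(nb_dispersion = -1))
  expect_error(sim_config(cells_per_donor = 0), "cells_per_donor")
  expect_error(sim_config(n_genes = 30), "smaller than union")
})

test_that("degenerate null: near-Poisson single-type counts match the closed-form mean", {
  # tau = 0, no effects, theta large, fixed library size, one donor/type
  cfg <- sim_config(seed = 21, n_genes = 400, cohorts = "HS",
                    donors_per_cohort = c(HS = 1), cells_per_donor = 800,
                    celltype_props = list(HS = c(`CD4 TCM` = 1)),
                    donor_sd = 0, nb_dispersion = 1e6,
                    libsize_lognormal = c(log(1500), 0),
                    n_mito_genes = 0, doublet_rate = 0, n_empty = 0,
                    condition_effects = data.frame(cell_type = character(),
                                                   gene = character(),
                                                   beta = numeric()),
                    n_marker_genes = 5)
  sim <- simulate_cohort(cfg)
  w <- sim$truth$genes$base_weight
  lfc <- sim$truth$type_lfc[, "CD4 TCM"]
  share <- w * exp(lfc) / sum(w * exp(lfc))
  mu <- 1500 * share
  obs <- Matrix::rowMeans(sim$counts$layers$total)
  se <- sqrt(mu / 800)              # Poisson-limit Monte-Carlo SE
  frac_within <- mean(abs(obs - mu) <= 3 * pmax(se, 1e-9))
  expect_gt(frac_within, 0.98)
})

test_that("NB moment oracle: empirical variance matches mu + mu^2/theta", {
  cfg <- sim_config(seed = 22, n_genes = 300, cohorts = "HS",
                    donors_per_cohort = c(HS = 1), cells_per_donor = 5000,
                    celltype_props = list(HS = c(NK = 1)),
                    donor_sd = 0, nb_dispersion = 2,
                    libsize_lognormal = c(log(1200), 0),
                    n_mito_genes = 0, doublet_rate = 0, n_empty = 0,
                    n_marker_genes = 5)
  sim <- simulate_cohort(cfg)
  m <- sim$counts$layers$total
  mu_hat <- Matrix::rowMeans(m)
  v_hat <- Matrix::rowMeans(m^2) - mu_hat^2
  v_theory <- mu_hat + mu_hat^2 / 2
  keep <- mu_hat > 0.5
  rel <- abs(v_hat[keep] - v_theory[keep]) / v_theory[keep]
  # variance of a variance estimate is noisy; check the bulk agrees
  expect_lt(median(rel), 0.10)
  expect_gt(mean(rel < 0.25), 0.95)
})

test_that("pseudobulk donor-intercept variance recovers tau^2 without attenuation", {
  tau <- 0.5
  cfg <- sim_config(seed = 23, n_genes = 300, cohorts = "HS",
                    donors_per_cohort = c(HS = 150), cells_per_donor = 100,
                    celltype_props = list(HS = c(`CD4 TCM` = 1)),
                    donor_sd = tau, donor_gene_frac = 1,
                    libsize_lognormal = c(log(1500), 0),
                    n_mito_genes = 0, doublet_rate = 0, n_empty = 0,
                    n_marker_genes = 5)
  sim <- simulate_cohort(cfg)
  m <- sim$counts$layers$total
  donor <- sim$truth$cells$donor
  # per-donor mean log expression of high-expression genes carries u_d
  hi <- order(Matrix::rowMeans(m), decreasing = TRUE)[1:50]
  pb <- sapply(unique(donor), function(d)
    log(Matrix::rowMeans(m[hi, donor == d, drop = FALSE]) + 0.5))
  u_hat <- colMeans(pb)
  u_true <- sim$truth$donors$u[match(unique(donor), sim$truth$donors$donor)]
  # estimates track the realized intercepts one-for-one (no attenuation)
  expect_gt(cor(u_hat, u_true), 0.98)
  expect_lt(abs(unname(coef(lm(u_hat ~ u_true))[2]) - 1), 0.1)
  # and their spread recovers the nominal tau^2
  expect_lt(abs(var(u_hat) - tau^2) / tau^2, 0.25)
})

test_that("doublet barcodes average twice the singlet library size", {
  cfg <- sim_config(seed = 24, n_genes = 300, cohorts = "HS",
                    donors_per_cohort = c(HS = 4), cells_per_donor = 300,
                    celltype_props = list(HS = c(NK = 0.5, `B naive` = 0.5)),
                    doublet_rate = 0.1, n_empty = 0, n_marker_genes = 5)
  sim <- simulate_cohort(cfg)
  tr <- sim$truth$cells
  tot <- Matrix::colSums(sim$counts$layers$total)
  expect_gte(sum(tr$is_doublet), 100)
  ratio <- mean(tot[tr$is_doublet]) / mean(tot[!tr$is_doublet & !tr$is_empty])
  expect_lt(abs(ratio - 2), 0.2)
})

test_that("reference panels: count, granularity and profile fidelity", {
  fx <- fx_clean_sim()
  panels <- build_reference_panels(fx$cfg, n_panels = 6)
  expect_length(panels, 6)
  # distinct substreams: panel profiles differ
  expect_false(identical(panels[[1]]$profiles, panels[[2]]$profiles))
  # coarse panel maps onto the lineage parents of the fine labels
  coarse <- panels[[5]]
  fine <- panels[[1]]
  expect_setequal(coarse$labels, unique(lymphoid_lineage(fine$labels)))
  # harmonization is total
  expect_true(all(fine$labels %in% names(fine$harmonization)))
  # profiles built from pure cells track the true expression program
  w <- fx$sim$truth$genes$base_weight
  for (lab in c("NK", "CD8 TEM")) {
    lfc <- fx$sim$truth$type_lfc[, lab]
    share <- w * exp(lfc) / sum(w * exp(lfc))
    true_prog <- log1p(exp(fx$cfg$libsize_lognormal[1]) * share *
                         1e4 / exp(fx$cfg$libsize_lognormal[1]))
    prof <- fine$profiles[lab, ]
    cosine <- sum(prof * true_prog) /
      sqrt(sum(prof^2) * sum(true_prog^2))
    expect_gt(cosine, 0.95)
  }
})

test_that("ground truth covers exactly the configured condition effects", {
  fx <- fx_clean_sim()
  expect_setequal(fx$sim$truth$effects$gene, fx$cfg$condition_effects$gene)
  bm <- fx$sim$truth$beta_mat
  expect_equal(sum(bm != 0), nrow(fx$cfg$condition_effects))
})

test_that("simulation round-trips through the 10x triplet format", {
  fx <- fx_clean_sim()
  dir <- withr::local_tempdir()
  write_simulation(fx$sim, fx$cfg, dir)
  cm <- read_tenx(file.path(dir, "counts"))
  expect_equal(as.matrix(cm$layers$total),
               as.matrix(fx$sim$counts$layers$total))
  expect_setequal(names(cm$layers),
                  c("spliced", "unspliced", "ambiguous", "total"))
  sheet <- read.csv(file.path(dir, "sample_sheet.csv"))
  expect_equal(sheet$barcode, fx$sim$meta$barcode)
})
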