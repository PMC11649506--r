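test_that("with no donor variance the fit collapses to OLS", {
  set.seed(1)
  # exchangeable cells, balanced: beta1 = difference of condition means
  cond <- rep(0:1, each = 60)
  donor <- rep(1:6, each = 20)       # donors nested in condition
  y <- 0.7 * cond + rnorm(120, 0, 1) # tau = 0
  fit <- fit_lmm(y, cond, donor)
  ols <- coef(lm(y ~ cond))
  expect_lt(abs(fit$beta1 - unname(ols[2])), 1e-6)
  expect_lt(abs(fit$beta0 - unname(ols[1])), 1e-6)
})

test_that("estimates match the lme4 REML oracle within 1e-4", {
  skip_if_not_installed("lme4")
  sim <- simulate_lmm_dataset(50, donors_per_group = 3, cells_per_donor = 40,
                              beta1 = 0.5, tau = 0.5, sigma = 1, seed = 2)
  for (g in seq_len(50)) {
    y <- sim$y[g, ]
    fit <- fit_lmm(y, sim$condition, sim$donor)
    m <- lme4::lmer(y ~ cond + (1 | donor), REML = TRUE,
                    data = data.frame(y = y, cond = sim$condition,
                                      donor = sim$donor))
    vc <- as.data.frame(lme4::VarCorr(m))
    expect_lt(abs(fit$beta1 - unname(lme4::fixef(m)[2])), 1e-4)
    expect_lt(abs(fit$tau2 - vc$vcov[1]), 1e-4)
    expect_lt(abs(fit$sigma2 - vc$vcov[2]), 1e-4)
  }
})

test_that("Satterthwaite df matches lmerTest on a balanced design", {
  skip_if_not_installed("lmerTest")
  sim <- simulate_lmm_dataset(5, donors_per_group = 4, cells_per_donor = 30,
                              beta1 = 0.3, tau = 0.5, sigma = 1, seed = 3)
  for (g in 1:5) {
    y <- sim$y[g, ]
    fit <- fit_lmm(y, sim$condition, sim$donor)
    m <- lmerTest::lmer(y ~ cond + (1 | donor), REML = TRUE,
                        data = data.frame(y = y, cond = sim$condition,
                                          donor = sim$donor))
    co <- coef(summary(m))
    expect_lt(abs(fit$df - co[2, "df"]), 1e-3)
    expect_lt(abs(fit$p - co[2, "Pr(>|t|)"]), 1e-6)
  }
})

test_that("translation equivariance and REML local optimality", {
  sim <- simulate_lmm_dataset(1, 4, 30, beta1 = 0.4, tau = 0.5, seed = 5)
  y <- sim$y[1, ]
  f0 <- fit_lmm(y, sim$condition, sim$donor)
  f1 <- fit_lmm(y + 3, sim$condition, sim$donor)
  expect_equal(f1$beta0 - f0$beta0, 3, tolerance = 1e-10)
  expect_lt(abs(f1$beta1 - f0$beta1), 1e-10)

  # REML objective at lambda-hat beats lambda/2 and 2*lambda
  obj <- function(lam) {
    d <- as.integer(sim$donor); D <- max(d); nd <- tabulate(d, D)
    X <- cbind(1, sim$condition)
    a <- lam / (1 + nd * lam)
    S <- rowsum(X, d); td <- rowsum(y, d)[, 1]
    XtVX <- crossprod(X) - crossprod(S * a, S)
    XtVy <- crossprod(X, y) - crossprod(S * a, td)
    beta <- solve(XtVX, XtVy)
    rss <- sum(y^2) - sum(a * td^2) - sum(beta * XtVy)
    (length(y) - 2) * log(rss / (length(y) - 2)) +
      sum(log1p(nd * lam)) + determinant(XtVX)$modulus[1]
  }
  lam_hat <- f0$lambda
  expect_lte(obj(lam_hat), obj(lam_hat / 2) + 1e-6)
  expect_lte(obj(lam_hat), obj(lam_hat * 2) + 1e-6)
})

test_that("degenerate and error inputs are handled", {
  expect_error(fit_lmm(rnorm(10), rep(0:1, 5), rep(1, 10)), "single donor")
  f <- fit_lmm(rep(2, 40), rep(0:1, each = 20), rep(1:4, each = 10))
  expect_true(f$degenerate)
  expect_equal(f$p, 1)
  expect_error(fit_lmm(c(1, NA, 3), c(0, 1, 1), c(1, 2, 2)))
})

test_that("null calibration: donor-aware Wald holds its level, pooled t-test does not", {
  sim <- simulate_lmm_dataset(300, donors_per_group = 4, cells_per_donor = 40,
                              beta1 = 0, tau = 0.5, sigma = 1, seed = 11)
  p_lmm <- p_pool <- numeric(300)
  for (g in seq_len(300)) {
    p_lmm[g] <- fit_lmm(sim$y[g, ], sim$condition, sim$donor)$p
    p_pool[g] <- pooled_t_test(sim$y[g, ], sim$condition)$p
  }
  expect_gte(mean(p_lmm < 0.05), 0.02)
  expect_lte(mean(p_lmm < 0.05), 0.08)
  expect_gt(mean(p_pool < 0.05), 0.10)
})

test_that("parameter recovery: mean beta1 unbiased, tau2 in range across genes", {
  sim <- simulate_lmm_dataset(200, donors_per_group = 5, cells_per_donor = 30,
                              beta1 = 1, tau = 0.5, sigma = 1, seed = 13)
  est <- t(vapply(seq_len(200), function(g) {
    f <- fit_lmm(sim$y[g, ], sim$condition, sim$donor)
    c(f$beta1, f$tau2)
  }, numeric(2)))
  mc_se <- sd(est[, 1]) / sqrt(200)
  expect_lt(abs(mean(est[, 1]) - 1), 2 * mc_se + 0.02)
  expect_lt(abs(median(est[, 2]) - 0.25) / 0.25, 0.25)
})

test_that("BH adjustment: hand-computed example, permutation invariance, NaN error", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bh_adjust(p[perm])[order(perm)], bh_adjust(p))
  expect_error(bh_adjust(c(0.1, NaN)), "finite")
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("de_celltype applies lineage thresholds and recovers planted effects", {
  expect_equal(de_threshold("B naive"), 0.5)
  expect_equal(de_threshold("CD8 TEM"), 0.1)
  expect_equal(de_threshold("NK"), 0.01)
  expect_equal(de_threshold("CD4 TCM"), 0.01)

  cfg <- sim_config(seed = 17, n_genes = 400, cohorts = c("RAP", "CCI"),
                    donors_per_cohort = c(RAP = 5, CCI = 5),
                    cells_per_donor = 150,
                    celltype_props = list(RAP = c(`CD8 TEM` = 0.6, NK = 0.4),
                                          CCI = c(`CD8 TEM` = 0.6, NK = 0.4)),
                    donor_sd = 0.3, n_empty = 0, doublet_rate = 0,
                    n_marker_genes = 10, exhaustion_shift = 0)
  sim <- simulate_cohort(cfg)
  norm <- lognormalize(sim$counts)
  meta <- data.frame(barcode = sim$truth$cells$barcode,
                     donor = sim$truth$cells$donor,
                     cohort = sim$truth$cells$cohort,
                     consensus = sim$truth$cells$true_type)
  de <- de_celltype(norm, meta, "CD8 TEM")
  planted <- sim$truth$effects$gene[sim$truth$effects$cell_type == "CD8 TEM"]
  sig <- de$gene[de$significant]
  # planted positive effects are found with the right sign
  expect_gte(mean(planted %in% sig), 0.5)
  expect_true(all(de$direction[de$gene %in% planted] == "up"))
  # significance monotone as the threshold tightens
  n_sig <- vapply(c(0.5, 0.1, 0.01), function(th)
    sum(de$p_adj < th), numeric(1))
  expect_true(all(diff(n_sig) <= 0))
  # p_adj >= p always
  expect_true(all(de$p_adj >= de$p - 1e-15))
  expect_error(de_celltype(norm, meta[meta$cohort == "RAP", ], "CD8 TEM"),
               "absent in condition")
})
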