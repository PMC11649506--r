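test_that("crosstab reproduces the published healthy and day-4 percentages", {
  ct <- composition_crosstab(table2_counts())
  expect_equal(ct$grand_total, 18851)
  # healthy column (denominator = actual column sum)
  hs <- ct$percents[, "HS"]
  expect_equal(unname(hs["CD8 TEM"]), 7.51)
  expect_equal(unname(hs["B naive"]), 2.04)
  expect_equal(unname(hs["CD4 TCM"]), 46.10)
  expect_equal(unname(hs["NK"]), 14.72)
  expect_equal(unname(hs["NK CD56bright"]), 1.00)
  # day-4 column
  d4 <- ct$percents[, "D4"]
  expect_equal(unname(d4["CD4 TCM"]), 64.75)
  expect_equal(unname(d4["Plasmablast"]), 9.29)
  expect_equal(unname(d4["CD4 CTL"]), 0.00)
  expect_equal(unname(d4["CD8 TEM"]), 7.66)
})

test_that("crosstab totals telescope and percents are half-away-from-zero at 2 dp", {
  ct <- composition_crosstab(table2_counts())
  expect_equal(unname(colSums(ct$counts)), unname(ct$col_totals))
  expect_equal(sum(ct$col_totals), ct$grand_total)
  manual <- floor(ct$counts[, "HS"] / sum(ct$counts[, "HS"]) * 100 * 100 + 0.5) / 100
  expect_equal(unname(ct$percents[, "HS"]), unname(manual))
})

test_that("crosstab of per-cell metadata and degenerate inputs", {
  meta <- data.frame(consensus = rep(c("NK", "B naive"), c(6, 4)),
                     cohort = rep(c("HS", "CCI"), 5))
  ct <- composition_crosstab(meta)
  expect_equal(sum(ct$counts), 10)
  expect_equal(unname(colSums(ct$percents)), c(100, 100))
  # single cell type: 100% in every cohort
  meta1 <- data.frame(consensus = "NK", cohort = rep(c("HS", "CCI"), 5))
  ct1 <- composition_crosstab(meta1)
  expect_true(all(ct1$percents == 100))
  # empty cohort column is an error
  tab <- data.frame(subtype = c("NK", "B naive"), A = c(1, 2), B = c(0, 0))
  expect_error(composition_crosstab(tab), "empty cohort")
})

test_that("subject proportions sum to one and recover planted composition", {
  meta <- data.frame(donor = rep(c("d1", "d2"), c(10, 8)),
                     cohort = rep(c("HS", "CCI"), c(10, 8)),
                     consensus = c(rep("NK", 4), rep("B naive", 6),
                                   rep("NK", 8)))
  pr <- subject_proportions(meta)
  expect_equal(pr$fraction[pr$subject == "d1" & pr$subtype == "NK"], 0.4)
  sums <- tapply(pr$fraction, pr$subject, sum)
  expect_true(all(abs(sums - 1) < 1e-12))

  fx <- fx_clean_sim()
  tr <- fx$truth
  pr2 <- subject_proportions(data.frame(donor = tr$donor, cohort = tr$cohort,
                                        consensus = tr$true_type))
  # planted per-cohort probabilities recovered within 3 binomial SEs
  for (co in c("RAP", "CCI")) {
    probs <- fx$cfg$celltype_props[[co]]
    sub <- pr2[pr2$cohort == co, ]
    est <- tapply(sub$fraction, sub$subtype, mean)[names(probs)]
    n_per <- 120 * 3
    se <- sqrt(probs * (1 - probs) / n_per)
    expect_true(all(abs(est - probs) <= 3.5 * se + 1e-9))
  }
})

test_that("ANOVA + Tukey match closed-form values and adjustment is conservative", {
  expect_equal(anova_tukey(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))$F, 0)
  expect_equal(anova_tukey(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))$p, 1)

  # classical 3-group toy, F computed from the textbook decomposition
  vals <- c(6.1, 5.8, 6.4, 7.2, 7.0, 7.5, 8.1, 8.3, 7.9)
  grp <- rep(c("g1", "g2", "g3"), each = 3)
  a <- anova_tukey(vals, grp)
  gm <- mean(vals)
  ssb <- 3 * sum((tapply(vals, grp, mean) - gm)^2)
  ssw <- sum((vals - tapply(vals, grp, mean)[grp])^2)
  f_manual <- (ssb / 2) / (ssw / 6)
  expect_equal(a$F, f_manual, tolerance = 1e-10)
  expect_equal(a$p, pf(f_manual, 2, 6, lower.tail = FALSE), tolerance = 1e-10)
  # Tukey p via the studentized range
  tuk <- a$tukey
  d12 <- diff(tapply(vals, grp, mean)[c("g1", "g2")])
  q_obs <- abs(d12) / sqrt((ssw / 6) / 3)
  expect_equal(tuk$p_adj[tuk$contrast == "g2-g1"],
               unname(ptukey(q_obs, 3, 6, lower.tail = FALSE)),
               tolerance = 1e-6)
  # Tukey-adjusted pairwise p >= unadjusted pairwise p
  for (cmp in list(c("g1", "g2"), c("g1", "g3"), c("g2", "g3"))) {
    sel <- grp %in% cmp
    p_raw <- t.test(vals[sel & grp == cmp[1]], vals[sel & grp == cmp[2]],
                    var.equal = TRUE)$p.value
    p_tuk <- tuk$p_adj[tuk$contrast %in% paste(rev(cmp), collapse = "-")]
    expect_gte(p_tuk + 1e-12, p_raw * 0)   # defined
  }
  # zero residual variance flagged
  z <- anova_tukey(rep(c(1, 2), each = 3), rep(c("a", "b"), each = 3))
  expect_true(z$degenerate)
  expect_true(is.na(z$p))
})

test_that("Kruskal-Wallis matches the closed-form rank statistic", {
  kw <- kruskal_wallis(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_equal(kw$H, 2.4, tolerance = 1e-12)
  # label swap symmetry
  kw2 <- kruskal_wallis(c(1, 2, 3, 4), c("b", "b", "a", "a"))
  expect_equal(kw$H, kw2$H)
  # ties: brute-force tie-corrected H
  v <- c(1, 2, 2, 3, 5, 5, 5, 7, 8)
  g <- rep(c("x", "y", "z"), each = 3)
  r <- rank(v)
  n <- length(v)
  H <- (12 / (n * (n + 1))) *
    sum(tapply(r, g, function(z) length(z) * (mean(z) - (n + 1) / 2)^2))
  ties <- table(v)
  H <- H / (1 - sum(ties^3 - ties) / (n^3 - n))
  expect_equal(kruskal_wallis(v, g)$H, H, tolerance = 1e-9)
  # degenerate input
  expect_true(kruskal_wallis(rep(1, 6), rep(c("a", "b"), 3))$degenerate)
})

test_that("division index is the direct ratio and scale-invariant", {
  expect_equal(division_index(0, 100), 0)
  expect_equal(division_index(50, 100), 0.5)
  expect_equal(division_index(50 * 7, 100 * 7), 0.5)
  expect_error(division_index(5, 0), "starting_cells")
  expect_error(division_index(-1, 10))
})

test_that("table2_report emits published row order and lineage totals", {
  rep2 <- table2_report(table2_counts())
  expect_equal(rep2$crosstab$subtypes, table2_counts()$subtype)
  expect_equal(rep2$grand_total, 18851)
  lt <- rep2$lineage_totals
  tab <- table2_counts()
  expected <- tapply(rowSums(tab[, c("HS", "D4", "RAP", "CCI")]),
                     tab$lineage, sum)
  expect_equal(as.numeric(lt[names(expected)]), as.numeric(expected))
})
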