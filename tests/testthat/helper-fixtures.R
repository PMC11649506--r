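# shared fixtures (built once per test run) and independent oracles

.fx <- new.env()

`%||%` <- function(a, b) if (is.null(a)) b else a

# clean two-cohort simulation: no empties/doublets, used for annotation,
# composition and scoring tests
fx_clean_sim <- function() {
  if (is.null(.fx$clean)) {
    cfg <- sim_config(seed = 5, n_genes = 700, cohorts = c("RAP", "CCI"),
                      donors_per_cohort = c(RAP = 3, CCI = 3),
                      cells_per_donor = 120, n_empty = 0, doublet_rate = 0,
                      n_marker_genes = 20)
    sim <- simulate_cohort(cfg)
    .fx$clean <- list(cfg = cfg, sim = sim,
                      norm = lognormalize(sim$counts),
                      truth = sim$truth$cells)
  }
  .fx$clean
}

fx_panels <- function() {
  if (is.null(.fx$panels)) .fx$panels <-
    build_reference_panels(fx_clean_sim()$cfg, n_panels = 6)
  .fx$panels
}

# droplet-structured simulation with empties and doublets for QC tests
fx_droplet_sim <- function() {
  if (is.null(.fx$droplet)) {
    cfg <- sim_config(seed = 3, n_genes = 600, cohorts = c("RAP", "CCI"),
                      donors_per_cohort = c(RAP = 3, CCI = 3),
                      cells_per_donor = 100, n_empty = 2000,
                      n_marker_genes = 15)
    .fx$droplet <- list(cfg = cfg, sim = simulate_cohort(cfg))
  }
  .fx$droplet
}

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  sa <- sum(choose(tab, 2))
  sr <- sum(choose(rowSums(tab), 2))
  sc <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  e <- sr * sc / choose(n, 2)
  (sa - e) / ((sr + sc) / 2 - e)
}

# brute-force one-sided hypergeometric enrichment tail:
# P(X >= q) with X ~ Hypergeom(N, m, k), by direct combinatorial sum
hyper_tail_bruteforce <- function(q, m, N, k) {
  j <- q:min(m, k)
  if (q > min(m, k)) return(0)
  sum(exp(lchoose(m, j) + lchoose(N - m, k - j) - lchoose(N, k)))
}

# enumerate all set partitions of 1..n (Bell number growth; n <= 8)
set_partitions <- function(n) {
  parts <- list(list(1L))
  for (i in 2:n) {
    nxt <- list()
    for (p in parts) {
      for (b in seq_along(p)) {
        q <- p; q[[b]] <- c(q[[b]], i)
        nxt[[length(nxt) + 1]] <- q
      }
      nxt[[length(nxt) + 1]] <- c(p, list(i))
    }
    parts <- nxt
  }
  parts
}

partition_membership <- function(p, n) {
  m <- integer(n)
  for (b in seq_along(p)) m[p[[b]]] <- b
  m
}

# independent direct-formula re-computation of the module score
module_score_oracle <- function(X, panel, nbin, nctrl, seed, signed = TRUE) {
  X <- as.matrix(X)
  members <- panel$members[names(panel$members) %in% rownames(X)]
  gmean <- rowMeans(X)
  bin <- ceiling(rank(gmean, ties.method = "first") /
                   (length(gmean) / nbin))
  bins <- split(rownames(X), bin)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(lymphtraj::stage_seed(seed, "modulescore"))
  ctrl <- list()
  for (g in names(members)) {
    pool <- bins[[as.character(bin[match(g, rownames(X))])]]
    ctrl[[g]] <- sample(pool, min(nctrl, length(pool)))
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  one <- function(gs) {
    if (!length(gs)) return(rep(0, ncol(X)))
    pm <- colMeans(X[gs, , drop = FALSE])
    cm <- rowMeans(sapply(gs, function(g)
      colMeans(X[ctrl[[g]], , drop = FALSE])))
    pm - cm
  }
  if (signed) one(names(members)[members > 0]) - one(names(members)[members < 0])
  else one(names(members))
}

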