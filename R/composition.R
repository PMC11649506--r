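#' Packaged cohort composition counts
#'
#' The published cohort x subtype lymphoid cell counts (20 subtypes by
#' four cohorts) shipped as a plain-text fixture.
#'
#' @return data.frame(subtype, lineage, HS, D4, RAP, CCI).
#' @export
table2_counts <- function() {
  utils::read.csv(system.file("extdata", "table2_counts.csv",
                              package = "lymphtraj", mustWork = TRUE),
                  check.names = FALSE)
}

# round half away from zero (the convention of the printed table)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Cohort x subtype composition table
#'
#' Cross-tabulates consensus-annotated cells into absolute counts and
#' percent-of-cohort (rounded half-away-from-zero to 2 decimals, computed
#' from the actual column sums).
#'
#' @param meta cell metadata (one row per cell) with subtype and cohort
#'   columns, or a pre-tabulated counts data.frame with a `subtype` column
#'   and one column per cohort (optionally a `lineage` column).
#' @param subtype_col,cohort_col column names when `meta` is per-cell.
#' @param subtypes optional row order (defaults to observed order, or the
#'   common vocabulary order when all labels belong to it).
#' @return a `CompositionTable`: list(counts, percents, col_totals,
#'   grand_total, subtypes, lineage).
#' @export
composition_crosstab <- function(meta, subtype_col = "consensus",
                                 cohort_col = "cohort", subtypes = NULL) {
  if (all(c("subtype") %in% names(meta)) && !subtype_col %in% names(meta)) {
    cohorts <- setdiff(names(meta), c("subtype", "lineage"))
    counts <- as.matrix(meta[, cohorts, drop = FALSE])
    rownames(counts) <- meta$subtype
    lineage <- if ("lineage" %in% names(meta))
      stats::setNames(meta$lineage, meta$subtype) else NULL
  } else {
    tab <- table(meta[[subtype_col]], meta[[cohort_col]])
    counts <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                     dimnames = dimnames(tab))
    lineage <- NULL
  }
  if (is.null(subtypes)) {
    subtypes <- if (all(rownames(counts) %in% subtype_vocabulary()))
      intersect(subtype_vocabulary(), rownames(counts)) else rownames(counts)
  }
  counts <- counts[subtypes, , drop = FALSE]
  col_totals <- colSums(counts)
  if (any(col_totals == 0))
    stop("empty cohort column(s): ",
         paste(colnames(counts)[col_totals == 0], collapse = ", "))
  percents <- round_half_up(sweep(counts, 2, col_totals, "/") * 100, 2)
  structure(list(counts = counts, percents = percents,
                 col_totals = col_totals, grand_total = sum(counts),
                 subtypes = subtypes,
                 lineage = lineage %||%
                   tryCatch(stats::setNames(lymphoid_lineage(subtypes), subtypes),
                            error = function(e) NULL)),
            class = "CompositionTable")
}

#' @export
print.CompositionTable <- function(x, ...) {
  cat(sprintf("CompositionTable: %d subtypes x %d cohorts, %d cells\n",
              nrow(x$counts), ncol(x$counts), x$grand_total))
  print(utils::head(format_composition(x)))
  invisible(x)
}

#' Format a composition table as "count (percent)" text
#' @param x a `CompositionTable`.
#' @return data.frame in the published layout, with a Total row.
#' @export
format_composition <- function(x) {
  stopifnot(inherits(x, "CompositionTable"))
  body <- matrix(sprintf("%d (%.2f)", x$counts, x$percents),
                 nrow(x$counts), dimnames = dimnames(x$counts))
  out <- data.frame(subtype = rownames(body), body, check.names = FALSE,
                    row.names = NULL)
  total <- c("Total", sprintf("%d (100.00)", x$col_totals))
  rbind(out, stats::setNames(as.list(total), names(out)))
}

#' Write a composition table to CSV
#' @param x a `CompositionTable`.
#' @param path output file.
#' @export
write_composition <- function(x, path) {
  utils::write.csv(format_composition(x), path, row.names = FALSE)
  invisible(path)
}

#' Per-subject subtype proportions
#'
#' Fraction of each subject's lymphoid cells in each subtype (the
#' denominator is the subject's total); fractions sum to 1 per subject.
#' Subjects with zero cells are excluded with a warning.
#'
#' @param meta per-cell metadata.
#' @param subject_col,subtype_col,cohort_col column names.
#' @return data.frame(subject, cohort, subtype, fraction), complete over
#'   subject x subtype with zero fractions.
#' @export
subject_proportions <- function(meta, subject_col = "donor",
                                subtype_col = "consensus",
                                cohort_col = "cohort") {
  subj <- meta[[subject_col]]
  keep <- !is.na(subj)
  if (any(!keep)) meta <- meta[keep, , drop = FALSE]
  subj <- meta[[subject_col]]
  tab <- table(subj, meta[[subtype_col]])
  tot <- rowSums(tab)
  if (any(tot == 0)) {
    warning("subject(s) with 0 lymphoid cells excluded: ",
            paste(rownames(tab)[tot == 0], collapse = ", "))
    tab <- tab[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  frac <- sweep(tab, 1, tot, "/")
  cohort_of <- tapply(as.character(meta[[cohort_col]]), subj,
                      function(z) z[1])
  out <- as.data.frame(as.table(frac), stringsAsFactors = FALSE)
  names(out) <- c("subject", "subtype", "fraction")
  out$cohort <- unname(cohort_of[out$subject])
  out[, c("subject", "cohort", "subtype", "fraction")]
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Classical decomposition via [stats::aov()]; pairwise Tukey-adjusted
#' p-values via the studentized range ([stats::TukeyHSD()]).
#'
#' @param values numeric response (e.g. per-subject subtype fractions).
#' @param groups group factor (>= 2 groups with >= 2 observations each).
#' @return list(F, p, df, tukey = data.frame(contrast, diff, p_adj),
#'   degenerate flag). Zero residual variance gives NA p with
#'   degenerate = TRUE.
#' @export
anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  rownames(an) <- trimws(rownames(an))
  ss_res <- an["Residuals", "Sum Sq"]
  if (ss_res <= 1e-12 * max(sum(an[, "Sum Sq"]), 1e-300)) {
    return(list(F = NA_real_, p = NA_real_, df = an[, "Df"],
                tukey = NULL, degenerate = TRUE))
  }
  tk <- stats::TukeyHSD(fit)$groups
  list(F = an["groups", "F value"], p = an["groups", "Pr(>F)"],
       df = an[, "Df"],
       tukey = data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                          p_adj = tk[, "p adj"], row.names = NULL),
       degenerate = FALSE)
}

#' Per-subtype cohort comparisons of subject proportions
#'
#' Runs [anova_tukey()] on each subtype's per-subject fractions across
#' cohorts.
#'
#' @param props output of [subject_proportions()].
#' @return data.frame(subtype, F, p) with the Tukey tables in attribute
#'   "tukey".
#' @export
composition_tests <- function(props) {
  sts <- unique(props$subtype)
  tuk <- list()
  res <- do.call(rbind, lapply(sts, function(st) {
    d <- props[props$subtype == st, ]
    a <- anova_tukey(d$fraction, d$cohort)
    tuk[[st]] <<- a$tukey
    data.frame(subtype = st, F = a$F, p = a$p)
  }))
  attr(res, "tukey") <- tuk
  res
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with chi-square reference on g - 1 degrees of
#' freedom (via [stats::kruskal.test()]). All-identical values give NA
#' with a degeneracy flag.
#'
#' @param values numeric observations.
#' @param groups group labels (>= 2 groups).
#' @return list(H, p, df, degenerate).
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups), length(values) >= 2,
            nlevels(groups) >= 2)
  if (length(unique(values)) == 1)
    return(list(H = NA_real_, p = NA_real_, df = nlevels(groups) - 1,
                degenerate = TRUE))
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter), degenerate = FALSE)
}

#' Division index of a proliferation assay
#'
#' Total number of divisions divided by the number of cells at the start
#' of the culture.
#'
#' @param total_divisions non-negative division count(s).
#' @param starting_cells positive starting cell count(s).
#' @return numeric index, vectorized.
#' @export
division_index <- function(total_divisions, starting_cells) {
  if (any(starting_cells <= 0)) stop("starting_cells must be > 0")
  if (any(total_divisions < 0)) stop("total_divisions must be >= 0")
  total_divisions / starting_cells
}
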