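#' Read a GMT gene-set file
#'
#' Tab-delimited: set name, description, then member genes. Genes are
#' whitespace-trimmed, upper-cased and deduplicated; set order is
#' preserved.
#'
#' @param path GMT file.
#' @param source collection name (defaults to the file name).
#' @return a `GeneSetCollection`: list(source, sets, descriptions).
#' @export
read_gmt <- function(path, source = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    f <- trimws(f)
    if (length(f) < 3)
      stop("malformed GMT at line ", i, ": expected at least 3 tab-delimited fields")
    genes <- unique(toupper(f[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (!length(genes))
      stop("malformed GMT at line ", i, ": empty gene list")
    sets[[f[1]]] <- genes
    desc[f[1]] <- f[2]
  }
  structure(list(source = source, sets = sets, descriptions = desc),
            class = "GeneSetCollection")
}

#' Write a GeneSetCollection to GMT
#' @param collection a `GeneSetCollection`.
#' @param path output file.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]] %||% "", collection$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection '%s': %d sets\n", x$source, length(x$sets)))
  invisible(x)
}

#' Gene-set over-representation by Fisher's exact test
#'
#' For each set, forms the 2x2 table of DE membership vs set membership
#' within the universe and computes the one-sided hypergeometric
#' enrichment p-value (optionally depletion); BH adjustment across sets
#' within the collection. The recommended universe is the genes actually
#' tested in the DE stratum, not the whole genome.
#'
#' @param de_genes character vector of DE genes (must lie in universe).
#' @param universe background gene universe.
#' @param collection a `GeneSetCollection`; sets are intersected with the
#'   universe.
#' @param p_adj_threshold keep sets below this BH-adjusted p.
#' @param alternative "enrichment" (default) or "depletion".
#' @return data.frame(set, overlap, set_size, odds_ratio, p, p_adj, kept).
#' @export
fisher_enrich <- function(de_genes, universe, collection,
                          p_adj_threshold = 0.05,
                          alternative = c("enrichment", "depletion")) {
  alternative <- match.arg(alternative)
  universe <- unique(toupper(universe))
  de_genes <- unique(toupper(de_genes))
  if (!length(universe)) stop("empty universe")
  if (!length(de_genes)) stop("empty DE gene list")
  if (!all(de_genes %in% universe))
    stop("de_genes must be a subset of the universe")
  N <- length(universe); k <- length(de_genes)
  res <- lapply(names(collection$sets), function(nm) {
    set <- intersect(unique(toupper(collection$sets[[nm]])), universe)
    m <- length(set)
    q <- length(intersect(de_genes, set))
    p <- if (m == 0) 1 else if (alternative == "enrichment")
      stats::phyper(q - 1, m, N - m, k, lower.tail = FALSE)
    else stats::phyper(q, m, N - m, k, lower.tail = TRUE)
    a <- q; b <- k - q; cc <- m - q; dd <- N - m - b
    or <- if (b * cc == 0) Inf else (a * dd) / (b * cc)
    data.frame(set = nm, overlap = q, set_size = m, odds_ratio = or, p = p)
  })
  out <- do.call(rbind, res)
  out$p_adj <- bh_adjust(out$p)
  out$kept <- out$p_adj < p_adj_threshold
  out
}

#' Direction-split over-representation of a DE table
#'
#' Runs [fisher_enrich()] separately on up- and down-regulated significant
#' genes, with the tested genes as universe.
#'
#' @param de a `DEResult` table from [de_celltype()].
#' @param collection a `GeneSetCollection`.
#' @param p_adj_threshold see [fisher_enrich()].
#' @return data.frame with a `direction` column ("up"/"down"); directions
#'   with no significant genes are omitted.
#' @export
enrich_directional <- function(de, collection, p_adj_threshold = 0.05) {
  universe <- de$gene
  parts <- lapply(c("up", "down"), function(dir) {
    g <- de$gene[de$significant & de$direction == dir]
    if (!length(g)) return(NULL)
    r <- fisher_enrich(g, universe, collection, p_adj_threshold)
    r$direction <- dir
    r
  })
  do.call(rbind, parts)
}
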