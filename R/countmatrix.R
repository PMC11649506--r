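#' Sparse layered count matrix for droplet scRNA-seq
#'
#' A genes x barcodes container holding named sparse integer layers
#' (spliced, unspliced, ambiguous and their elementwise total). Total mRNA
#' counts are defined as the elementwise sum of the three splicing layers,
#' and downstream analysis consumes the total layer unless a step says
#' otherwise (the mitochondrial filter uses the spliced layer).
#'
#' @param layers named list of sparse (or dense) non-negative integer
#'   matrices with identical dimensions. If "total" is absent and the three
#'   component layers are present it is computed as their sum; a single
#'   matrix may be supplied directly and becomes the total layer.
#' @param gene_ids,barcodes character identifiers; default to dimnames.
#' @param provenance optional character vector recording source paths and
#'   filter history.
#' @return an object of class `CountMatrix`.
#' @export
count_matrix <- function(layers, gene_ids = NULL, barcodes = NULL,
                         provenance = character()) {
  if (is(layers, "Matrix") || is.matrix(layers)) layers <- list(total = layers)
  stopifnot(is.list(layers), length(layers) > 0, !is.null(names(layers)))
  layers <- lapply(layers, function(m) {
    if (is.matrix(m)) m <- Matrix::Matrix(m, sparse = TRUE)
    m <- as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
    if (any(m@x < 0) || any(m@x != round(m@x)))
      stop("count layers must be non-negative integers")
    m
  })
  d <- dim(layers[[1]])
  for (m in layers) if (!identical(dim(m), d)) stop("layer shapes differ")
  comp <- c("spliced", "unspliced", "ambiguous")
  if (all(comp %in% names(layers))) {
    tot <- layers$spliced + layers$unspliced + layers$ambiguous
    if (is.null(layers$total)) {
      layers$total <- tot
    } else if (max(abs(layers$total - tot)) > 0) {
      stop("total layer does not equal spliced + unspliced + ambiguous")
    }
  }
  if (is.null(layers$total)) stop("need a total layer or all three components")
  if (is.null(gene_ids)) gene_ids <- rownames(layers$total)
  if (is.null(barcodes)) barcodes <- colnames(layers$total)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(d[1]))
  if (is.null(barcodes)) barcodes <- paste0("bc", seq_len(d[2]))
  stopifnot(length(gene_ids) == d[1], length(barcodes) == d[2])
  layers <- lapply(layers, function(m) {
    dimnames(m) <- list(gene_ids, barcodes); m
  })
  structure(list(layers = layers, gene_ids = gene_ids, barcodes = barcodes,
                 provenance = provenance),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d barcodes; layers: %s\n",
              length(x$gene_ids), length(x$barcodes),
              paste(names(x$layers), collapse = ", ")))
  if (length(x$provenance)) cat("provenance:", paste(x$provenance, collapse = " | "), "\n")
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$layers$total)

#' Subset a CountMatrix by barcodes and/or genes
#'
#' @param cm a CountMatrix.
#' @param barcodes,genes index vectors (logical, integer or character).
#' @param note provenance note appended to the filter history.
#' @return the subsetted CountMatrix.
#' @export
subset_counts <- function(cm, barcodes = NULL, genes = NULL, note = NULL) {
  stopifnot(inherits(cm, "CountMatrix"))
  gi <- if (is.null(genes)) seq_along(cm$gene_ids) else genes
  bi <- if (is.null(barcodes)) seq_along(cm$barcodes) else barcodes
  layers <- lapply(cm$layers, function(m) m[gi, bi, drop = FALSE])
  count_matrix(layers,
               provenance = c(cm$provenance, note %||% character()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-barcode total counts of a layer
#' @param cm a CountMatrix.
#' @param layer layer name, default "total".
#' @return named numeric vector over barcodes.
#' @export
barcode_totals <- function(cm, layer = "total") {
  Matrix::colSums(cm$layers[[layer]])
}

#' Read a 10x-style triplet directory
#'
#' Expects `matrix.mtx` (genes x barcodes MatrixMarket), `features.tsv`
#' (id, symbol, type) and `barcodes.tsv`. Layered exports written by
#' [write_tenx()] use `<layer>.mtx` files.
#'
#' @param dir directory containing the triplet.
#' @return a CountMatrix.
#' @export
read_tenx <- function(dir) {
  feats <- utils::read.delim(file.path(dir, "features.tsv"), header = FALSE)
  bcs <- utils::read.delim(file.path(dir, "barcodes.tsv"), header = FALSE)[[1]]
  mtx_files <- list.files(dir, pattern = "\\.mtx$", full.names = TRUE)
  layers <- lapply(mtx_files, Matrix::readMM)
  names(layers) <- sub("^matrix$", "total",
                       sub("\\.mtx$", "", basename(mtx_files)))
  layers <- lapply(layers, function(m) {
    dimnames(m) <- list(feats[[1]], bcs); m
  })
  count_matrix(layers, provenance = paste0("read_tenx:", dir))
}

#' Write a CountMatrix as a 10x-style triplet
#'
#' @param cm a CountMatrix.
#' @param dir output directory (created if missing).
#' @param symbols optional gene symbols (defaults to gene ids).
#' @export
write_tenx <- function(cm, dir, symbols = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(cm$layers)) {
    fn <- if (nm == "total") "matrix.mtx" else paste0(nm, ".mtx")
    Matrix::writeMM(cm$layers[[nm]], file.path(dir, fn))
  }
  feats <- data.frame(id = cm$gene_ids,
                      symbol = symbols %||% cm$gene_ids,
                      type = "Gene Expression")
  utils::write.table(feats, file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(cm$barcodes, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}
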