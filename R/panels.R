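#' Signed exhaustion gene panels
#'
#' Curated lymphocyte-exhaustion panels with signed membership: +1 genes are
#' up-regulated in exhausted cells (inhibitory receptors and exhaustion
#' transcription factors), -1 genes are effector/stemness molecules whose
#' loss is exhaustion-consistent. The NK panel carries the effector
#' molecules CD226 (DNAM-1) and KLRK1 as negative members and the negative
#' regulators TIGIT, TOX, CD96 (TACTILE), LAG3 and LAMP1 as positive
#' members; FCGR3A (CD16) is deliberately excluded from the default panel.
#' The CD8 TEM panel carries TCF7 as the sole negative (stemness) member.
#'
#' @param name panel name.
#' @param members named numeric vector of +1/-1 weights keyed by gene symbol.
#' @param target_types cell types the panel is scored in by default.
#' @return a `GenePanel` object.
#' @export
gene_panel <- function(name, members, target_types = character()) {
  stopifnot(length(members) > 0, !is.null(names(members)),
            all(members %in% c(-1, 1)))
  structure(list(name = name, members = members,
                 target_types = target_types),
            class = "GenePanel")
}

#' @rdname gene_panel
#' @export
nk_exhaustion_panel <- function() {
  gene_panel("nk_exhaustion",
             c(CD226 = -1, KLRK1 = -1, TIGIT = 1, TOX = 1, CD96 = 1,
               LAG3 = 1, LAMP1 = 1),
             target_types = "NK")
}

#' @rdname gene_panel
#' @export
cd8tem_exhaustion_panel <- function() {
  gene_panel("cd8tem_exhaustion",
             c(KLRG1 = 1, TCF7 = -1, TNFSF4 = 1, CTLA4 = 1, TIGIT = 1,
               EOMES = 1, TOX = 1, LAG3 = 1, PDCD1 = 1, HAVCR2 = 1),
             target_types = "CD8 TEM")
}

#' @export
print.GenePanel <- function(x, ...) {
  cat(sprintf("GenePanel '%s': %d genes (+%d/-%d), targets: %s\n",
              x$name, length(x$members), sum(x$members > 0),
              sum(x$members < 0),
              paste(x$target_types, collapse = ", ")))
  invisible(x)
}

# common 20-subtype vocabulary (cohort composition table row order)
.subtype_vocabulary <- c(
  "B naive", "B intermediate", "B memory", "Plasmablast",
  "CD4 T naive", "CD4 T proliferating", "CD4 TEM", "CD4 TCM", "CD4 CTL",
  "Treg",
  "CD8 T naive", "CD8 T proliferating", "CD8 TEM", "CD8 TCM",
  "dnT", "gdT", "MAIT",
  "NK", "NK Proliferating", "NK CD56bright")

.lineage_map <- c(
  "B naive" = "B cells", "B intermediate" = "B cells",
  "B memory" = "B cells", "Plasmablast" = "B cells",
  "CD4 T naive" = "CD4 T", "CD4 T proliferating" = "CD4 T",
  "CD4 TEM" = "CD4 T", "CD4 TCM" = "CD4 T", "CD4 CTL" = "CD4 T",
  "Treg" = "CD4 T",
  "CD8 T naive" = "CD8 T", "CD8 T proliferating" = "CD8 T",
  "CD8 TEM" = "CD8 T", "CD8 TCM" = "CD8 T",
  "dnT" = "other T", "gdT" = "other T", "MAIT" = "other T",
  "NK" = "NK", "NK Proliferating" = "NK", "NK CD56bright" = "NK")

#' Lymphoid lineage of a subtype label
#'
#' Maps the common subtype vocabulary (and the lineage parents themselves)
#' to the five lymphoid lineages: B cells, CD4 T, CD8 T, other T, NK.
#'
#' @param labels character vector of subtype or lineage labels.
#' @return character vector of lineage labels.
#' @export
lymphoid_lineage <- function(labels) {
  lineages <- unique(unname(.lineage_map))
  out <- ifelse(labels %in% lineages, labels,
                unname(.lineage_map[labels]))
  bad <- unique(labels[is.na(out)])
  if (length(bad))
    stop("unknown label lineage for: ", paste(bad, collapse = ", "))
  out
}

#' The common subtype vocabulary
#' @return character vector of the 20 subtype labels in table row order.
#' @export
subtype_vocabulary <- function() .subtype_vocabulary
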