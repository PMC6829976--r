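# Cross-species ortholog projection into the human identifier namespace.

#' Construct an ortholog map
#'
#' Wraps a many-to-many (species gene -> human gene) table. Species gene
#' identifiers are matched case-insensitively (they are normalized the same
#' way set members are); human targets are normalized symbols.
#'
#' @param table data.frame with columns `species`, `species_gene`,
#'   `human_gene`.
#' @return an object of class `ortholog_map`.
#' @export
ortholog_map <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("species", "species_gene", "human_gene") %in% names(table)))
  table$species <- tolower(trimws(table$species))
  unknown <- setdiff(unique(table$species), GENESET_SPECIES)
  if (length(unknown))
    stop("unknown species label(s): ", paste(unknown, collapse = ", "),
         "; allowed: ", paste(GENESET_SPECIES, collapse = ", "))
  table$species_gene <- toupper(gsub("[[:space:]]+", "", table$species_gene))
  table$human_gene <- toupper(gsub("[[:space:]]+", "", table$human_gene))
  table <- unique(table[nzchar(table$species_gene) & nzchar(table$human_gene),
                        c("species", "species_gene", "human_gene")])
  rownames(table) <- NULL
  structure(list(table = table, species_list = sort(unique(table$species))),
            class = "ortholog_map")
}

#' @export
print.ortholog_map <- function(x, ...) {
  cat(sprintf("<ortholog_map> %d pair(s) covering species: %s\n",
              nrow(x$table),
              if (length(x$species_list)) paste(x$species_list, collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' Look up human orthologs of a species gene
#'
#' @param m an [ortholog_map].
#' @param species species label.
#' @param genes character vector of species gene identifiers.
#' @return named list: per input gene, the character vector of human symbols
#'   (possibly empty).
#' @export
orthologs_of <- function(m, species, genes) {
  stopifnot(inherits(m, "ortholog_map"))
  species <- tolower(species)
  genes_n <- toupper(gsub("[[:space:]]+", "", genes))
  sub <- m$table[m$table$species == species, , drop = FALSE]
  out <- lapply(genes_n, function(g)
    sort(unique(sub$human_gene[sub$species_gene == g])))
  names(out) <- genes
  out
}

#' Reverse index: species genes mapping to a human gene
#'
#' @param m an [ortholog_map].
#' @param human_genes character vector of human symbols.
#' @return named list of data.frames (`species`, `species_gene`).
#' @export
orthologs_reverse <- function(m, human_genes) {
  stopifnot(inherits(m, "ortholog_map"))
  hg <- toupper(gsub("[[:space:]]+", "", human_genes))
  out <- lapply(hg, function(h) {
    sub <- m$table[m$table$human_gene == h, c("species", "species_gene")]
    rownames(sub) <- NULL
    sub
  })
  names(out) <- human_genes
  out
}

#' Project a gene set into the human namespace
#'
#' Each member contributes the union of all of its human orthologs
#' (many-to-many union semantics: conservation asks whether any homolog
#' carries the association). Members without a mapping are dropped and
#' counted in the attached projection report, mirroring the drop rule for
#' identifiers that cannot be assigned. Human sets pass through unchanged.
#'
#' @param gs a [gene_set].
#' @param m an [ortholog_map] covering `gs$species` (unless human).
#' @return a human [gene_set]; attribute `"projection_report"` holds
#'   `n_input`, `n_mapped`, `n_dropped` and the dropped symbols.
#' @export
project_to_human <- function(gs, m) {
  stopifnot(is_gene_set(gs))
  if (identical(gs$species, "human")) {
    out <- gs
    attr(out, "projection_report") <- list(
      n_input = length(gs$members), n_mapped = length(gs$members),
      n_dropped = 0L, dropped = character())
    return(out)
  }
  stopifnot(inherits(m, "ortholog_map"))
  if (!gs$species %in% m$species_list)
    stop(sprintf("species '%s' is not covered by the ortholog map (has: %s)",
                 gs$species, paste(m$species_list, collapse = ", ")))
  hits <- orthologs_of(m, gs$species, gs$members)
  dropped <- names(hits)[lengths(hits) == 0L]
  out <- gene_set(paste0(gs$set_id, "_human"),
                  unlist(hits, use.names = FALSE),
                  label = if (nzchar(gs$label))
                    paste0(gs$label, " (human orthologs)") else "",
                  species = "human")
  attr(out, "projection_report") <- list(
    n_input = length(gs$members),
    n_mapped = length(gs$members) - length(dropped),
    n_dropped = length(dropped),
    dropped = sort(dropped))
  out
}
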