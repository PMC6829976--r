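# Loaders for the packaged study fixtures: the gene-set catalogue, the
# 20-gene regulation table with signature and cell-death flags, the 13-gene
# signature directions, and the six supplemental MeSH-derived conserved
# genes.

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "cisplatinsig")
  if (!nzchar(p)) stop("packaged fixture not found: ", file)
  p
}

#' Load the gene-set catalogue fixture
#'
#' Set ids and sizes for the per-species chemical-associated sets, their
#' conserved overlaps, the supplemental MeSH set and the per-subtype up/down
#' differential-expression sets. Memberships of the external sets are not
#' recoverable; only sizes are catalogued.
#'
#' @return data.frame with columns `gs_id`, `n_genes`, `species`, `kind`,
#'   `subtype`, `direction`, `description`.
#' @export
load_table1_fixture <- function() {
  tab <- utils::read.delim(fixture_path("table1_gene_sets.tsv"),
                           comment.char = "#", stringsAsFactors = FALSE,
                           na.strings = "NA")
  stopifnot(all(c("gs_id", "n_genes", "species", "kind", "subtype",
                  "direction", "description") %in% names(tab)))
  if (anyDuplicated(tab$gs_id))
    stop("fixture violates constraint: gene-set ids must be unique")
  if (any(tab$n_genes < 0))
    stop("fixture violates constraint: negative set size")
  tab
}

#' Load the 20-gene regulation fixture
#'
#' The regulation of the 20 conserved cisplatin-associated genes across the
#' four tumor-cell TNBC subtypes (BL1, BL2, M, LAR), with a per-gene
#' cell-death annotation flag and the resistant-signature membership flag.
#' The loader re-validates the fixture's internal consistency: status
#' vocabulary, completeness of the flags, and agreement of the `resistant`
#' column with the signature rule applied to the statuses.
#'
#' @return object of class `regulation_fixture`: list with `genes`,
#'   `subtypes`, `status` (a `regulation_matrix`), `death_flag` and
#'   `resistant_flag` (named logical vectors).
#' @export
load_table2_fixture <- function() {
  tab <- utils::read.csv(fixture_path("table2_regulation.csv"),
                         comment.char = "#", stringsAsFactors = FALSE)
  subtypes <- c("BL1", "BL2", "M", "LAR")
  need <- c("gene", subtypes, "resistant", "death")
  if (!all(need %in% names(tab)))
    stop("regulation fixture violates constraint: missing column(s) ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  genes <- normalize_gene_symbols(tab$gene)
  if (anyDuplicated(genes))
    stop("regulation fixture violates constraint: duplicate gene rows")
  m <- as.matrix(tab[, subtypes])
  rownames(m) <- genes
  if (!all(m %in% c("UP", "DOWN", "NONE")))
    stop("regulation fixture violates constraint: status outside {UP, DOWN, NONE}")
  if (any(rowSums(m != "NONE") == 0L))
    stop("regulation fixture violates constraint: gene with no differential status")
  death <- stats::setNames(as.logical(tab$death), genes)
  resistant <- stats::setNames(as.logical(tab$resistant), genes)
  if (anyNA(death) || anyNA(resistant))
    stop("regulation fixture violates constraint: death/resistant flag undefined for some gene")
  status <- new_regulation_matrix(m)
  sig <- resistant_signature(status, resistant = c("LAR", "M"),
                             sensitive = c("BL1", "BL2"))
  if (!setequal(sig$signature_genes, genes[resistant]))
    stop("regulation fixture violates constraint: 'resistant' column disagrees with the signature rule")
  structure(list(genes = genes, subtypes = subtypes, status = status,
                 death_flag = death, resistant_flag = resistant),
            class = "regulation_fixture")
}

#' @export
print.regulation_fixture <- function(x, ...) {
  cat(sprintf("<regulation_fixture> %d gene(s) x %d subtype(s); %d signature, %d cell-death\n",
              length(x$genes), length(x$subtypes),
              sum(x$resistant_flag), sum(x$death_flag)))
  invisible(x)
}

#' Load the 13-gene signature-direction fixture
#'
#' Directions of differential expression in the resistant subtypes for the
#' 13 signature genes.
#'
#' @return data.frame with columns `gene`, `M`, `LAR`.
#' @export
load_table3_fixture <- function() {
  tab <- utils::read.csv(fixture_path("table3_signature.csv"),
                         comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "M", "LAR") %in% names(tab)))
  tab$gene <- normalize_gene_symbols(tab$gene)
  if (!all(unlist(tab[, c("M", "LAR")]) %in% c("UP", "DOWN", "NONE")))
    stop("signature fixture violates constraint: status outside {UP, DOWN, NONE}")
  tab
}

#' The six supplemental MeSH-derived conserved genes
#'
#' Conserved cisplatin-associated genes contributed by the supplemental MeSH
#' set beyond the three-species CTD intersection.
#'
#' @return a human [gene_set] of 6 genes.
#' @export
mesh_conserved_genes <- function() {
  lines <- readLines(fixture_path("mesh_conserved_genes.txt"), warn = FALSE)
  lines <- trimws(lines[nzchar(trimws(lines)) & !startsWith(lines, "#")])
  gene_set("mesh_conserved", lines,
           label = "Conserved genes added by the supplemental MeSH cisplatin set",
           species = "human")
}

#' Derive per-subtype up/down gene sets from a regulation fixture
#'
#' Inverts the fixture's status matrix into the 8 up/down gene sets the
#' matrix-building step consumes (restricted to the fixture genes; the full
#' published DE sets are not recoverable).
#'
#' @param fx a `regulation_fixture`.
#' @return list with `up_sets` and `down_sets`, each a named list of
#'   [gene_set]s keyed by subtype.
#' @export
fixture_de_sets <- function(fx) {
  stopifnot(inherits(fx, "regulation_fixture"))
  m <- fx$status
  up_sets <- lapply(fx$subtypes, function(s)
    gene_set(paste0("up_", s), rownames(m)[m[, s] %in% c("UP", "BOTH")],
             label = paste("Up-regulated in", s)))
  down_sets <- lapply(fx$subtypes, function(s)
    gene_set(paste0("down_", s), rownames(m)[m[, s] %in% c("DOWN", "BOTH")],
             label = paste("Down-regulated in", s)))
  names(up_sets) <- names(down_sets) <- fx$subtypes
  list(up_sets = up_sets, down_sets = down_sets)
}
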