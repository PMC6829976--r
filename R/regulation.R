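# The gene x subtype regulation matrix and the resistant-subtype signature
# rule -- the core inference of the pipeline.

REG_STATUSES <- c("UP", "DOWN", "BOTH", "NONE")

new_regulation_matrix <- function(m) {
  stopifnot(is.matrix(m), is.character(m))
  bad <- !m %in% REG_STATUSES
  if (any(bad))
    stop("invalid regulation status value(s): ",
         paste(unique(m[bad]), collapse = ", "))
  if ((nrow(m) > 0L && is.null(rownames(m))) || is.null(colnames(m)))
    stop("regulation matrix needs gene rownames and subtype colnames")
  class(m) <- c("regulation_matrix", class(m))
  m
}

#' Build a gene-by-subtype regulation matrix
#'
#' Crosses a focus gene set (the conserved chemical-associated genes) with
#' per-subtype up- and down-regulated differential-expression sets. A focus
#' gene that appears in both the up and the down set of one subtype receives
#' status `BOTH` with a warning (this does occur in published DE lists).
#' Only focus genes with at least one non-`NONE` status are retained.
#'
#' @param up_sets named list of [gene_set]s: subtype -> up-regulated genes.
#' @param down_sets named list of [gene_set]s, same subtype names.
#' @param focus a [gene_set]; rows are restricted to its members.
#' @return a `regulation_matrix`: character matrix (genes x subtypes, values
#'   `UP`/`DOWN`/`BOTH`/`NONE`), rows sorted lexicographically.
#' @export
build_regulation_matrix <- function(up_sets, down_sets, focus) {
  stopifnot(is_gene_set(focus))
  assert_gene_sets(up_sets); assert_gene_sets(down_sets)
  subtypes <- names(up_sets)
  if (is.null(subtypes) || any(!nzchar(subtypes)))
    stop("up_sets and down_sets must be named by subtype")
  if (!setequal(subtypes, names(down_sets)))
    stop("subtype labels differ between up_sets and down_sets: ",
         paste(union(setdiff(subtypes, names(down_sets)),
                     setdiff(names(down_sets), subtypes)), collapse = ", "))
  down_sets <- down_sets[subtypes]
  genes <- sort(focus$members)
  m <- matrix("NONE", nrow = length(genes), ncol = length(subtypes),
              dimnames = list(genes, subtypes))
  for (s in subtypes) {
    up <- genes %in% up_sets[[s]]$members
    dn <- genes %in% down_sets[[s]]$members
    m[up & !dn, s] <- "UP"
    m[dn & !up, s] <- "DOWN"
    if (any(up & dn)) {
      m[up & dn, s] <- "BOTH"
      warning(sprintf("gene(s) %s in both the up and down set of subtype %s; status set to BOTH",
                      paste(genes[up & dn], collapse = ", "), s))
    }
  }
  keep <- rowSums(m != "NONE") > 0L
  new_regulation_matrix(m[keep, , drop = FALSE])
}

#' @export
print.regulation_matrix <- function(x, ...) {
  cat(sprintf("<regulation_matrix> %d gene(s) x %d subtype(s)\n",
              nrow(x), ncol(x)))
  print(unclass(x), quote = FALSE)
  invisible(x)
}

#' Summarize a regulation matrix
#'
#' Per-subtype counts of `UP`, `DOWN` and `BOTH` statuses (`BOTH` is counted
#' separately, in neither the up nor the down tally), plus the number of
#' genes up-regulated in at least one subtype and down-regulated in at least
#' one subtype (`BOTH` contributes to each).
#'
#' @param m a `regulation_matrix`.
#' @return list with `per_subtype` (data.frame `subtype`, `up`, `down`,
#'   `both`), `up_in_any`, `down_in_any`, `both_in_any`, `n_genes`.
#' @export
summarize_counts <- function(m) {
  stopifnot(inherits(m, "regulation_matrix"))
  subtypes <- colnames(m)
  per <- data.frame(
    subtype = subtypes,
    up = vapply(subtypes, function(s) sum(m[, s] == "UP"), integer(1)),
    down = vapply(subtypes, function(s) sum(m[, s] == "DOWN"), integer(1)),
    both = vapply(subtypes, function(s) sum(m[, s] == "BOTH"), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(
    per_subtype = per,
    up_in_any = sum(rowSums(m == "UP" | m == "BOTH") > 0L),
    down_in_any = sum(rowSums(m == "DOWN" | m == "BOTH") > 0L),
    both_in_any = sum(rowSums(m == "BOTH") > 0L),
    n_genes = nrow(m))
}

#' @export
summary.regulation_matrix <- function(object, ...) summarize_counts(object)

# a resistant status "matches" a sensitive status only when both are the same
# plain direction; BOTH is differential in both directions and matches neither
status_matches <- function(a, b) a == b & a %in% c("UP", "DOWN")

#' Extract the resistant-subtype signature
#'
#' A gene belongs to the signature when some resistant subtype shows a
#' differential status (`UP`, `DOWN` or `BOTH`) that differs from its status
#' in *every* sensitive subtype. `BOTH` counts as differential and matches
#' neither plain direction, so it always contributes. The exclusivity
#' partition groups signature genes by which resistant subtypes contributed
#' (e.g. genes exclusive to LAR, exclusive to M, or differential in both).
#'
#' @param m a `regulation_matrix`.
#' @param resistant character vector of resistant subtype labels.
#' @param sensitive character vector of sensitive subtype labels; disjoint
#'   from `resistant`, both drawn from `colnames(m)`.
#' @return object of class `signature_result`: list with `signature_genes`
#'   (sorted), `per_gene_basis` (per gene, data.frame `subtype`, `status` of
#'   the contributing resistant subtypes), `exclusivity` (named list of gene
#'   vectors, keyed by the contributing subtype combination such as
#'   `"LAR"`, `"M"`, `"LAR+M"`), `resistant`, `sensitive`.
#' @export
resistant_signature <- function(m, resistant, sensitive) {
  stopifnot(inherits(m, "regulation_matrix"))
  if (!length(resistant) || !length(sensitive))
    stop("resistant and sensitive subtype groups must be non-empty")
  if (length(intersect(resistant, sensitive)))
    stop("resistant and sensitive groups overlap: ",
         paste(intersect(resistant, sensitive), collapse = ", "))
  missing <- setdiff(c(resistant, sensitive), colnames(m))
  if (length(missing))
    stop("subtype(s) not in the matrix: ", paste(missing, collapse = ", "))
  basis <- list()
  for (g in rownames(m)) {
    contrib <- character()
    for (r in resistant) {
      st <- m[g, r]
      if (st == "NONE") next
      if (!any(status_matches(st, m[g, sensitive])))
        contrib <- c(contrib, r)
    }
    if (length(contrib))
      basis[[g]] <- data.frame(subtype = contrib, status = m[g, contrib],
                               row.names = NULL, stringsAsFactors = FALSE)
  }
  sig <- as.character(sort(names(basis)))
  basis <- basis[sig]
  combo <- vapply(basis, function(b)
    paste(resistant[resistant %in% b$subtype], collapse = "+"), character(1))
  combo_levels <- unlist(lapply(seq_along(resistant), function(k)
    utils::combn(resistant, k, function(s) paste(s, collapse = "+"))))
  exclusivity <- split(sig, factor(combo, levels = combo_levels))
  exclusivity <- lapply(exclusivity, unname)
  structure(list(signature_genes = sig, per_gene_basis = basis,
                 exclusivity = exclusivity,
                 resistant = resistant, sensitive = sensitive),
            class = "signature_result")
}

#' @export
print.signature_result <- function(x, ...) {
  cat(sprintf("<signature_result> %d gene(s) differentially regulated in {%s} vs {%s}\n",
              length(x$signature_genes),
              paste(x$resistant, collapse = ", "),
              paste(x$sensitive, collapse = ", ")))
  for (cls in names(x$exclusivity))
    cat(sprintf("  %s: %s\n", cls, paste(x$exclusivity[[cls]], collapse = ", ")))
  invisible(x)
}

#' Export a signature result as JSON
#'
#' @param sig a `signature_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
signature_to_json <- function(sig, path) {
  stopifnot(inherits(sig, "signature_result"))
  obj <- list(
    resistant = sig$resistant, sensitive = sig$sensitive,
    signature_genes = sig$signature_genes,
    per_gene_basis = sig$per_gene_basis,
    exclusivity = sig$exclusivity)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       dataframe = "rows")
  invisible(path)
}
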