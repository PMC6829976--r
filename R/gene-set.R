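#' Normalize gene symbols
#'
#' Gene identifiers across sources differ in case and stray whitespace.
#' Normalization strips all whitespace and uppercases, yielding HGNC-style
#' symbols; it is idempotent. Symbols that are empty after normalization are
#' dropped with a warning, mirroring the practice of discarding identifiers
#' that cannot be unambiguously assigned.
#'
#' @param x character vector of raw gene identifiers.
#' @return character vector of normalized symbols (empties removed).
#' @examples
#' normalize_gene_symbols(c(" tp53", "BRCA1 ", "Trp 53"))
#' @export
normalize_gene_symbols <- function(x) {
  if (length(x) == 0L) return(character())
  x <- toupper(gsub("[[:space:]]+", "", as.character(x)))
  empty <- !nzchar(x) | is.na(x)
  if (any(empty)) {
    warning(sprintf("dropped %d empty gene identifier(s) during normalization",
                    sum(empty)))
    x <- x[!empty]
  }
  x
}

#' Species labels recognised by the package
#' @export
GENESET_SPECIES <- c("human", "mouse", "rat", "other")

#' Construct a gene set
#'
#' A `gene_set` is a named, unordered collection of normalized gene symbols
#' with a species label and free-text description. Duplicate members (after
#' normalization) are collapsed.
#'
#' @param set_id unique identifier string.
#' @param members character vector of gene identifiers (normalized on entry).
#' @param label free-text description.
#' @param species one of `r paste(GENESET_SPECIES, collapse = ", ")`.
#' @param warn_duplicates warn when duplicate members are collapsed.
#' @return an object of class `gene_set` with elements `set_id`, `label`,
#'   `species` and `members` (sorted, unique).
#' @examples
#' gene_set("S1", c("tp53", "TP53", "BRCA1"))
#' @export
gene_set <- function(set_id, members = character(), label = "",
                     species = "human", warn_duplicates = FALSE) {
  stopifnot(is.character(set_id), length(set_id) == 1L, nzchar(set_id))
  species <- match.arg(species, GENESET_SPECIES)
  members <- normalize_gene_symbols(members)
  if (anyDuplicated(members)) {
    n_dup <- length(members) - length(unique(members))
    if (warn_duplicates)
      warning(sprintf("gene set '%s': collapsed %d duplicate member(s)",
                      set_id, n_dup))
    members <- unique(members)
  }
  structure(
    list(set_id = set_id, label = as.character(label), species = species,
         members = sort(members)),
    class = "gene_set"
  )
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s (%s): %d gene(s)\n", x$set_id, x$species,
              length(x$members)))
  if (nzchar(x$label)) cat("  ", x$label, "\n", sep = "")
  shown <- utils::head(x$members, 10L)
  if (length(shown))
    cat("  ", paste(shown, collapse = ", "),
        if (length(x$members) > 10L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$members)

#' @export
as.character.gene_set <- function(x, ...) x$members

is_gene_set <- function(x) inherits(x, "gene_set")

assert_gene_sets <- function(sets) {
  if (!length(sets)) stop("at least one gene set is required")
  ok <- vapply(sets, is_gene_set, logical(1))
  if (!all(ok)) stop("all inputs must be gene_set objects")
  invisible(sets)
}
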