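# Flat-file readers/writers: GMT gene sets, TSV ortholog tables,
# CSV regulation matrices, OBO-subset ontologies, GAF-like annotations.

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `set_id<TAB>description<TAB>member1<TAB>member2...`. A missing description
#' field is tolerated only when the line still has two fields; member symbols
#' are normalized and duplicates collapsed with a warning.
#'
#' @param path path to a GMT file.
#' @param species species label applied to every set in the file.
#' @return a named list of [gene_set] objects (names are set ids).
#' @seealso [write_gmt()]
#' @export
read_gmt <- function(path, species = "human") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2L)
      stop(sprintf("malformed GMT line %d: expected at least 2 tab-separated fields, got %d",
                   line_no[i], length(fields)))
    members <- fields[-(1:2)]
    members <- members[nzchar(trimws(members))]
    sets[[i]] <- gene_set(fields[[1]], members, label = fields[[2]],
                          species = species, warn_duplicates = TRUE)
  }
  ids <- vapply(sets, function(s) s$set_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate set ids in GMT file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(sets) <- ids
  sets
}

#' Write gene sets to a GMT file
#'
#' Members are written in lexicographic order so output is byte-stable and
#' `read_gmt(write_gmt(x))` is the identity on the data model.
#'
#' @param sets a list of [gene_set] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  assert_gene_sets(sets)
  lines <- vapply(sets, function(s) {
    paste(c(s$set_id, s$label, sort(s$members)), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an ortholog mapping table
#'
#' Tab-separated rows `species<TAB>species_gene<TAB>human_gene`; a header row
#' with those column names is tolerated. The mapping is many-to-many: a
#' species gene may map to several human genes and vice versa.
#'
#' @param path path to the TSV file.
#' @return an [ortholog_map] object.
#' @export
read_ortholog_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(ortholog_map(data.frame(species = character(),
                                   species_gene = character(),
                                   human_gene = character())))
  rows <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(rows) < 3L)
  if (length(bad))
    stop(sprintf("malformed ortholog row %d: expected 3 tab-separated fields",
                 bad[[1]]))
  tab <- data.frame(
    species = vapply(rows, `[[`, character(1), 1L),
    species_gene = vapply(rows, `[[`, character(1), 2L),
    human_gene = vapply(rows, `[[`, character(1), 3L),
    stringsAsFactors = FALSE
  )
  if (identical(tolower(unlist(tab[1, ])),
                c("species", "species_gene", "human_gene")))
    tab <- tab[-1, , drop = FALSE]
  ortholog_map(tab)
}

#' Read a regulation matrix from CSV
#'
#' Expects columns `gene` then one column per subtype holding
#' `UP`/`DOWN`/`BOTH`/`NONE`. Lines starting with `#` are comments.
#'
#' @param path CSV path.
#' @return a `regulation_matrix` (see [build_regulation_matrix()]).
#' @export
read_regulation_csv <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (!"gene" %in% names(tab)) stop("regulation CSV needs a 'gene' column")
  subtypes <- setdiff(names(tab), "gene")
  m <- as.matrix(tab[, subtypes, drop = FALSE])
  rownames(m) <- normalize_gene_symbols(tab$gene)
  new_regulation_matrix(m)
}

#' Write a regulation matrix to CSV
#'
#' @param m a `regulation_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regulation_csv <- function(m, path) {
  stopifnot(inherits(m, "regulation_matrix"))
  tab <- data.frame(gene = rownames(m), unclass(m), check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an OBO-format ontology subset
#'
#' Parses `[Term]` stanzas for `id`, `name`, `namespace`, `is_a` and
#' `relationship: part_of` lines; obsolete terms are skipped. This covers the
#' OBO subset needed for true-path annotation propagation; other relationship
#' types are ignored (conventional closure uses is_a and part_of only).
#'
#' @param path path to the OBO file.
#' @return an [ontology_dag].
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  term_starts <- which(lines == "[Term]")
  if (!length(term_starts)) stop("no [Term] stanzas found in ", path)
  block_ends <- c(term_starts[-1] - 1L, length(lines))
  ids <- character(); nms <- character(); nss <- character()
  e_child <- character(); e_parent <- character(); e_rel <- character()
  for (b in seq_along(term_starts)) {
    block <- lines[term_starts[b]:block_ends[b]]
    stanza_end <- grep("^\\[", block[-1])
    if (length(stanza_end)) block <- block[seq_len(stanza_end[1])]
    get1 <- function(key) {
      hit <- grep(paste0("^", key, ":"), block, value = TRUE)
      if (!length(hit)) return(NA_character_)
      sub("!.*$", "", sub(paste0("^", key, ":\\s*"), "", hit[[1]]))
    }
    if (!is.na(get1("is_obsolete"))) next
    id <- trimws(get1("id"))
    if (is.na(id) || !nzchar(id)) next
    ids <- c(ids, id)
    nm <- get1("name"); nms <- c(nms, if (is.na(nm)) id else trimws(nm))
    ns <- get1("namespace")
    nss <- c(nss, if (is.na(ns)) "default" else trimws(ns))
    for (ln in grep("^is_a:", block, value = TRUE)) {
      parent <- trimws(sub("!.*$", "", sub("^is_a:\\s*", "", ln)))
      e_child <- c(e_child, id); e_parent <- c(e_parent, parent)
      e_rel <- c(e_rel, "is_a")
    }
    for (ln in grep("^relationship:\\s*part_of", block, value = TRUE)) {
      parent <- trimws(sub("!.*$", "",
                           sub("^relationship:\\s*part_of\\s+", "", ln)))
      e_child <- c(e_child, id); e_parent <- c(e_parent, parent)
      e_rel <- c(e_rel, "part_of")
    }
  }
  ontology_dag(
    terms = data.frame(id = ids, name = nms, namespace = nss,
                       stringsAsFactors = FALSE),
    edges = data.frame(child = e_child, parent = e_parent, relation = e_rel,
                       stringsAsFactors = FALSE)
  )
}

#' Read gene-to-term annotations from a GAF-like TSV
#'
#' Minimal three-column dialect `gene<TAB>term<TAB>evidence` (evidence
#' optional); `!`-prefixed lines are comments as in GAF.
#'
#' @param path path to the TSV file.
#' @return an [annotation_set] of direct annotations.
#' @export
read_gaf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "!")]
  if (!length(lines)) return(annotation_set(list()))
  rows <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(rows) < 2L)
  if (length(bad))
    stop(sprintf("malformed annotation row %d: expected gene<TAB>term", bad[[1]]))
  genes <- normalize_gene_symbols(vapply(rows, `[[`, character(1), 1L))
  terms <- vapply(rows, `[[`, character(1), 2L)
  annotation_set(split(terms, genes))
}
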