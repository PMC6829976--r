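# Ontology-aware term enrichment: DAG container, true-path annotation
# propagation, hypergeometric enrichment, and cell-death flagging.

#' Construct an ontology DAG
#'
#' Terms plus child-to-parent edges restricted to `is_a` and `part_of`
#' relations (the conventional closure relations; regulates-type edges are
#' excluded upstream). The graph is validated to be acyclic with all edge
#' endpoints known.
#'
#' @param terms data.frame with columns `id`, `name`, `namespace`.
#' @param edges data.frame with columns `child`, `parent`, `relation`
#'   (relation in `is_a`, `part_of`).
#' @return object of class `ontology_dag` with elements `terms`, `edges`,
#'   and `parents` (named list: term -> character vector of parent ids).
#' @export
ontology_dag <- function(terms, edges) {
  stopifnot(is.data.frame(terms), all(c("id", "name", "namespace") %in% names(terms)),
            is.data.frame(edges))
  if (!nrow(edges))
    edges <- data.frame(child = character(), parent = character(),
                        relation = character(), stringsAsFactors = FALSE)
  stopifnot(all(c("child", "parent", "relation") %in% names(edges)))
  if (anyDuplicated(terms$id))
    stop("duplicate term ids: ",
         paste(unique(terms$id[duplicated(terms$id)]), collapse = ", "))
  bad_rel <- setdiff(unique(edges$relation), c("is_a", "part_of"))
  if (length(bad_rel))
    stop("unsupported relation(s): ", paste(bad_rel, collapse = ", "))
  unknown <- setdiff(unique(c(edges$child, edges$parent)), terms$id)
  if (length(unknown))
    stop("edge endpoint(s) not in term table: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  parents <- split(edges$parent, factor(edges$child, levels = terms$id))
  parents <- lapply(parents, function(p) sort(unique(p)))
  dag <- structure(list(terms = terms, edges = edges, parents = parents),
                   class = "ontology_dag")
  topo_order(dag)  # errors on cycles
  dag
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("<ontology_dag> %d term(s), %d edge(s), namespace(s): %s\n",
              nrow(x$terms), nrow(x$edges),
              paste(unique(x$terms$namespace), collapse = ", ")))
  invisible(x)
}

# Kahn topological sort, children before parents; errors on a cycle.
topo_order <- function(dag) {
  ids <- dag$terms$id
  # emit a term once all its children are emitted
  child_of <- split(dag$edges$child, factor(dag$edges$parent, levels = ids))
  n_unmet <- lengths(child_of)
  queue <- ids[n_unmet == 0L]
  out <- character(0)
  n_unmet <- stats::setNames(n_unmet, ids)
  while (length(queue)) {
    t <- queue[[1]]; queue <- queue[-1]
    out <- c(out, t)
    for (p in dag$parents[[t]]) {
      n_unmet[[p]] <- n_unmet[[p]] - 1L
      if (n_unmet[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (length(out) != length(ids))
    stop("ontology graph contains a cycle involving: ",
         paste(utils::head(setdiff(ids, out), 5L), collapse = ", "))
  out
}

#' All ancestors of each ontology term
#'
#' @param dag an [ontology_dag].
#' @return named list: term id -> sorted character vector of ancestor ids
#'   (excluding the term itself).
#' @export
term_ancestors <- function(dag) {
  stopifnot(inherits(dag, "ontology_dag"))
  anc <- stats::setNames(vector("list", nrow(dag$terms)), dag$terms$id)
  for (t in rev(topo_order(dag))) {  # roots first, so parents are complete
    ps <- dag$parents[[t]]
    anc[[t]] <- sort(unique(c(ps, unlist(anc[ps], use.names = FALSE))))
  }
  anc
}

#' All descendants of a collection of terms
#'
#' @param dag an [ontology_dag].
#' @param roots character vector of term ids.
#' @return sorted character vector of descendant ids (excluding the roots).
#' @export
term_descendants <- function(dag, roots) {
  stopifnot(inherits(dag, "ontology_dag"))
  missing <- setdiff(roots, dag$terms$id)
  if (length(missing))
    stop("unknown term(s): ", paste(missing, collapse = ", "))
  anc <- term_ancestors(dag)
  hits <- names(anc)[vapply(anc, function(a) any(roots %in% a), logical(1))]
  sort(setdiff(hits, roots))
}

#' Construct an annotation set
#'
#' @param direct named list: gene symbol -> character vector of term ids.
#' @param closed optional named list of propagated annotations (filled by
#'   [propagate_annotations()]).
#' @return object of class `annotation_set`.
#' @export
annotation_set <- function(direct, closed = NULL) {
  stopifnot(is.list(direct))
  if (length(direct) && is.null(names(direct)))
    stop("direct annotations must be named by gene")
  direct <- lapply(direct, function(x) sort(unique(as.character(x))))
  structure(list(direct = direct, closed = closed), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d gene(s), %s\n", length(x$direct),
              if (is.null(x$closed)) "not propagated" else "propagated"))
  invisible(x)
}

#' Propagate annotations up the ontology (true-path rule)
#'
#' Annotates every gene to all ancestors (via `is_a`/`part_of`) of each of
#' its direct terms. Idempotent: propagating an already propagated set leaves
#' it unchanged.
#'
#' @param dag an [ontology_dag].
#' @param ann an [annotation_set]; every annotated term must exist in `dag`.
#' @return the annotation set with `closed` filled in.
#' @export
propagate_annotations <- function(dag, ann) {
  stopifnot(inherits(dag, "ontology_dag"), inherits(ann, "annotation_set"))
  used <- unique(unlist(ann$direct, use.names = FALSE))
  unknown <- setdiff(used, dag$terms$id)
  if (length(unknown))
    stop("annotation(s) to unknown term(s): ",
         paste(unknown, collapse = ", "))
  anc <- term_ancestors(dag)
  ann$closed <- lapply(ann$direct, function(ts)
    sort(unique(c(ts, unlist(anc[ts], use.names = FALSE)))))
  ann
}

#' Hypergeometric term enrichment over propagated annotations
#'
#' For every term annotating at least one background gene (after true-path
#' propagation), tests whether the study set is enriched for the term with
#' the upper-tail hypergeometric probability, then applies
#' Benjamini-Hochberg adjustment within each ontology namespace. A term is
#' flagged `most_specific` when its p-value is no larger than that of every
#' annotated ancestor -- the heuristic used to report the most specific
#' enriched terms.
#'
#' @param study a [gene_set]; must be contained in `background`.
#' @param background a [gene_set] giving the annotation universe.
#' @param dag an [ontology_dag].
#' @param ann an [annotation_set] (propagated automatically if needed).
#' @return data.frame of class `enrichment_result`, sorted by p-value then
#'   term id, with columns `term`, `name`, `namespace`, `k`, `K`, `n`, `N`,
#'   `p_value`, `q_value`, `most_specific`.
#' @export
enrich <- function(study, background, dag, ann) {
  stopifnot(is_gene_set(study), is_gene_set(background),
            inherits(dag, "ontology_dag"), inherits(ann, "annotation_set"))
  outside <- setdiff(study$members, background$members)
  if (length(outside))
    stop("study set is not a subset of the background: ",
         paste(utils::head(outside, 5L), collapse = ", "))
  if (is.null(ann$closed)) ann <- propagate_annotations(dag, ann)
  closed <- ann$closed[names(ann$closed) %in% background$members]
  N <- length(background$members)
  n <- length(study$members)
  if (!length(closed)) {
    out <- data.frame(term = character(), name = character(),
                      namespace = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p_value = numeric(),
                      q_value = numeric(), most_specific = logical())
    class(out) <- c("enrichment_result", "data.frame")
    return(out)
  }
  gene <- rep(names(closed), lengths(closed))
  term <- unlist(closed, use.names = FALSE)
  K_tab <- table(term)
  in_study <- gene %in% study$members
  k_tab <- table(term[in_study])
  terms <- sort(names(K_tab))
  K <- as.integer(K_tab[terms])
  k <- as.integer(ifelse(is.na(k_tab[terms]), 0L, k_tab[terms]))
  idx <- match(terms, dag$terms$id)
  out <- data.frame(
    term = terms, name = dag$terms$name[idx],
    namespace = dag$terms$namespace[idx],
    k = k, K = K, n = n, N = N,
    p_value = hypergeom_overlap_p(k, K, n, N),
    stringsAsFactors = FALSE)
  out$q_value <- stats::ave(out$p_value, out$namespace,
                            FUN = function(p) stats::p.adjust(p, "BH"))
  anc <- term_ancestors(dag)
  p_of <- stats::setNames(out$p_value, out$term)
  out$most_specific <- vapply(seq_len(nrow(out)), function(i) {
    a <- intersect(anc[[out$term[i]]], out$term)
    !length(a) || all(out$p_value[i] <= p_of[a])
  }, logical(1))
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' @export
print.enrichment_result <- function(x, digits = 4, max_rows = 15L, ...) {
  cat(sprintf("<enrichment_result> %d term(s) tested (study n=%d, background N=%d)\n",
              nrow(x), if (nrow(x)) x$n[1] else 0L, if (nrow(x)) x$N[1] else 0L))
  print.data.frame(utils::head(x, max_rows), digits = digits,
                   row.names = FALSE)
  if (nrow(x) > max_rows) cat("  ...\n")
  invisible(x)
}

#' Write enrichment results as TSV
#'
#' @param res an `enrichment_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(res, path) {
  stopifnot(inherits(res, "enrichment_result"))
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Flag genes annotated under given ontology branches
#'
#' A gene is flagged when its propagated annotations intersect the given
#' root terms or any of their descendants. Used to mark genes associated
#' with cell-death processes.
#'
#' @param genes a [gene_set].
#' @param dag an [ontology_dag].
#' @param ann an [annotation_set] (propagated automatically if needed).
#' @param root_terms character vector of term ids that root the branches.
#' @return named logical vector over `genes$members`.
#' @export
flag_cell_death <- function(genes, dag, ann, root_terms) {
  stopifnot(is_gene_set(genes), inherits(dag, "ontology_dag"),
            inherits(ann, "annotation_set"))
  missing <- setdiff(root_terms, dag$terms$id)
  if (length(missing))
    stop("unknown root term(s): ", paste(missing, collapse = ", "))
  if (is.null(ann$closed)) ann <- propagate_annotations(dag, ann)
  branch <- union(root_terms, term_descendants(dag, root_terms))
  flags <- vapply(genes$members, function(g) {
    ts <- ann$closed[[g]]
    !is.null(ts) && length(intersect(ts, branch)) > 0L
  }, logical(1))
  stats::setNames(flags, genes$members)
}
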