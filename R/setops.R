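# Boolean set algebra, the hierarchical-similarity intersection lattice,
# and Jaccard / hypergeometric overlap statistics.

#' Combine gene sets with Boolean set algebra
#'
#' `UNION` and `INTERSECT` fold over all inputs; `DIFFERENCE` is the first
#' set minus the union of the rest (and therefore needs at least two sets).
#' The result records its provenance (operation and input ids) as an
#' attribute.
#'
#' @param op one of `"UNION"`, `"INTERSECT"`, `"DIFFERENCE"`
#'   (case-insensitive).
#' @param sets list of [gene_set] objects (all the same species).
#' @param set_id id for the result (default derived from `op`).
#' @return a [gene_set] with attribute `"provenance"`.
#' @examples
#' a <- gene_set("A", c("TP53", "BRCA1", "FAS"))
#' b <- gene_set("B", c("BRCA1", "FAS", "VIM"))
#' boolean_combine("INTERSECT", list(a, b))$members
#' @export
boolean_combine <- function(op, sets, set_id = NULL) {
  op <- match.arg(toupper(op), c("UNION", "INTERSECT", "DIFFERENCE"))
  assert_gene_sets(sets)
  if (op == "DIFFERENCE" && length(sets) < 2L)
    stop("DIFFERENCE requires at least two sets (first minus union of rest)")
  species <- unique(vapply(sets, function(s) s$species, character(1)))
  if (length(species) > 1L)
    stop("cannot combine sets from different species: ",
         paste(species, collapse = ", "),
         " (project to human first)")
  memb <- lapply(sets, function(s) s$members)
  res <- switch(op,
    UNION = Reduce(union, memb),
    INTERSECT = Reduce(intersect, memb),
    DIFFERENCE = setdiff(memb[[1]], Reduce(union, memb[-1]))
  )
  ids <- vapply(sets, function(s) s$set_id, character(1))
  if (is.null(set_id))
    set_id <- paste0(tolower(op), "(", paste(ids, collapse = ","), ")")
  out <- gene_set(set_id, res, species = species)
  attr(out, "provenance") <- list(op = op, inputs = ids)
  out
}

#' Upper-tail hypergeometric overlap probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing at
#' least `k` marked genes when `n` genes are drawn without replacement from a
#' universe of `N` genes of which `K` are marked. This is the significance
#' backing for gene-set overlaps. Computed through the survival function for
#' numerical stability. All arguments are recycled to a common length.
#'
#' @param k observed overlap count.
#' @param K size of set A (marked genes).
#' @param n size of set B (draws).
#' @param N universe size.
#' @return probability in `[0, 1]`.
#' @examples
#' hypergeom_overlap_p(5, 5, 5, 10)  # 1 / choose(10, 5)
#' @export
hypergeom_overlap_p <- function(k, K, n, N) {
  len <- max(length(k), length(K), length(n), length(N))
  k <- rep_len(as.numeric(k), len); K <- rep_len(as.numeric(K), len)
  n <- rep_len(as.numeric(n), len); N <- rep_len(as.numeric(N), len)
  bad <- k < 0 | K < 0 | n < 0 | K > N | n > N | k > pmin(K, n)
  if (any(bad))
    stop("hypergeometric bounds violated: need 0 <= k <= min(K, n) <= N")
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Pairwise Jaccard similarity with overlap significance
#'
#' One row per unordered pair of sets: intersection and union sizes, the
#' Jaccard index |A∩B| / |A∪B| (0 when both sets are empty), the upper-tail
#' hypergeometric p-value of the overlap against the universe, and its
#' Benjamini-Hochberg adjustment across all pairs.
#'
#' @param sets list of at least two [gene_set] objects.
#' @param universe a [gene_set] giving the background, or `NULL` (default)
#'   for the union of the inputs. Every input must be contained in it.
#' @return data.frame of class `overlap_stats` with columns `set_a`, `set_b`,
#'   `size_a`, `size_b`, `intersection_size`, `union_size`, `jaccard`,
#'   `universe_size`, `p_value`, `p_adjust`.
#' @export
jaccard_matrix <- function(sets, universe = NULL) {
  assert_gene_sets(sets)
  if (length(sets) < 2L) stop("need at least two sets")
  ids <- vapply(sets, function(s) s$set_id, character(1))
  memb <- lapply(sets, function(s) s$members)
  if (is.null(universe)) {
    uni <- Reduce(union, memb)
  } else {
    stopifnot(is_gene_set(universe))
    uni <- universe$members
    outside <- lapply(memb, setdiff, uni)
    if (any(lengths(outside) > 0L))
      stop("universe is smaller than the inputs: ",
           sum(lengths(outside)), " member(s) fall outside it")
  }
  N <- length(uni)
  pairs <- utils::combn(seq_along(sets), 2L)
  rows <- apply(pairs, 2L, function(ij) {
    a <- memb[[ij[1]]]; b <- memb[[ij[2]]]
    inter <- length(intersect(a, b)); uni_ab <- length(union(a, b))
    data.frame(
      set_a = ids[ij[1]], set_b = ids[ij[2]],
      size_a = length(a), size_b = length(b),
      intersection_size = inter, union_size = uni_ab,
      jaccard = if (uni_ab > 0L) inter / uni_ab else 0,
      universe_size = N,
      p_value = hypergeom_overlap_p(inter, length(a), length(b), N),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  class(out) <- c("overlap_stats", "data.frame")
  out
}

#' @export
print.overlap_stats <- function(x, digits = 4, ...) {
  cat(sprintf("<overlap_stats> %d pair(s), universe %d genes\n",
              nrow(x), x$universe_size[1]))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

# ---- intersection lattice (hierarchical-similarity graph) -------------------

#' Build the subset-intersection lattice of a gene-set family
#'
#' The hierarchical-similarity construct: leaves are the input sets and each
#' internal node holds, for a subset S of the inputs, either the genes present
#' in *at least* the sets of S (`AT_LEAST` mode: the plain intersection) or
#' the genes present in *exactly* the sets of S (`EXACT` mode: the
#' intersection minus every other input, so node contents partition the union
#' of the inputs). Only non-empty nodes are kept. Edges link each node to the
#' retained nodes immediately below it by subset inclusion of set ids. Nodes
#' are ordered by the number of contributing sets, then lexicographically by
#' id, so the structure is deterministic.
#'
#' @param sets list of [gene_set] objects (unique ids).
#' @param mode `"AT_LEAST"` (default) or `"EXACT"`.
#' @param max_sets combinatorial guard on the family size (default 12);
#'   raise explicitly for larger families.
#' @return object of class `intersection_lattice`: list with `nodes` (each a
#'   list of `child_set_ids` and `genes`), `edges` (data.frame `from`, `to`
#'   of node indices, parent above child), `set_ids` and `mode`.
#' @examples
#' l <- build_lattice(list(gene_set("S1", c("A", "B")),
#'                         gene_set("S2", c("B", "C"))))
#' length(l$nodes)
#' @export
build_lattice <- function(sets, mode = c("AT_LEAST", "EXACT"),
                          max_sets = 12L) {
  assert_gene_sets(sets)
  mode <- match.arg(toupper(mode[1]), c("AT_LEAST", "EXACT"))
  ids <- vapply(sets, function(s) s$set_id, character(1))
  if (anyDuplicated(ids)) stop("gene set ids must be unique")
  p <- length(sets)
  if (p > max_sets)
    stop(sprintf("%d sets exceeds the combinatorial guard (max_sets = %d); pass a larger max_sets to override",
                 p, max_sets))
  genes <- sort(unique(unlist(lapply(sets, function(s) s$members))))
  # bitmask per gene: which input sets contain it
  gmask <- integer(length(genes))
  for (j in seq_len(p)) {
    hit <- genes %in% sets[[j]]$members
    gmask[hit] <- bitwOr(gmask[hit], bitwShiftL(1L, j - 1L))
  }
  subsets <- seq_len(bitwShiftL(1L, p) - 1L)
  node_ids <- list(); node_genes <- list()
  for (m in subsets) {
    member_genes <- if (mode == "AT_LEAST")
      genes[bitwAnd(gmask, m) == m]
    else
      genes[gmask == m]
    if (!length(member_genes)) next
    in_subset <- bitwAnd(bitwShiftR(m, seq_len(p) - 1L), 1L) == 1L
    node_ids[[length(node_ids) + 1L]] <- sort(ids[in_subset])
    node_genes[[length(node_genes) + 1L]] <- member_genes
  }
  ord <- order(lengths(node_ids),
               vapply(node_ids, paste, character(1), collapse = "\t"))
  node_ids <- node_ids[ord]; node_genes <- node_genes[ord]
  nodes <- Map(function(i, g) list(child_set_ids = i, genes = g),
               node_ids, node_genes)
  # edges: parent -> child where child's id set is a proper subset of the
  # parent's and no retained node lies strictly between them
  n <- length(nodes)
  from <- integer(); to <- integer()
  if (n > 1L) {
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (a == b) next
      ia <- node_ids[[a]]; ib <- node_ids[[b]]
      if (length(ib) >= length(ia) || !all(ib %in% ia)) next
      between <- FALSE
      for (c in seq_len(n)) {
        if (c == a || c == b) next
        ic <- node_ids[[c]]
        if (length(ic) > length(ib) && length(ic) < length(ia) &&
            all(ib %in% ic) && all(ic %in% ia)) { between <- TRUE; break }
      }
      if (!between) { from <- c(from, a); to <- c(to, b) }
    }
  }
  structure(list(nodes = nodes,
                 edges = data.frame(from = from, to = to),
                 set_ids = sort(ids), mode = mode),
            class = "intersection_lattice")
}

#' @export
print.intersection_lattice <- function(x, ...) {
  cat(sprintf("<intersection_lattice> mode %s: %d input set(s), %d node(s), %d edge(s)\n",
              x$mode, length(x$set_ids), length(x$nodes), nrow(x$edges)))
  for (nd in utils::head(x$nodes, 12L))
    cat(sprintf("  {%s}: %d gene(s)\n",
                paste(nd$child_set_ids, collapse = ","), length(nd$genes)))
  if (length(x$nodes) > 12L) cat("  ...\n")
  invisible(x)
}

#' Export an intersection lattice as JSON
#'
#' @param lattice an `intersection_lattice`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
lattice_to_json <- function(lattice, path) {
  stopifnot(inherits(lattice, "intersection_lattice"))
  obj <- list(
    mode = lattice$mode,
    set_ids = lattice$set_ids,
    nodes = lapply(lattice$nodes, function(nd)
      list(child_set_ids = nd$child_set_ids, genes = nd$genes,
           n_genes = length(nd$genes))),
    edges = lattice$edges
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Export an intersection lattice as Graphviz DOT
#'
#' @param lattice an `intersection_lattice`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
lattice_to_dot <- function(lattice, path) {
  stopifnot(inherits(lattice, "intersection_lattice"))
  lab <- vapply(lattice$nodes, function(nd)
    sprintf("%s\\n%d genes", paste(nd$child_set_ids, collapse = " & "),
            length(nd$genes)), character(1))
  lines <- c("digraph lattice {", "  rankdir=BT;",
             sprintf('  n%d [label="%s", shape=box];',
                     seq_along(lattice$nodes), lab))
  if (nrow(lattice$edges))
    lines <- c(lines, sprintf("  n%d -> n%d;", lattice$edges$to,
                              lattice$edges$from))
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
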