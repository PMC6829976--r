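# Independent brute-force oracles used to check the package's primitives.
# These deliberately avoid the code paths they verify.

# Upper-tail hypergeometric probability by direct combinatorial arithmetic:
# sum of point masses C(K,i) C(N-K, n-i) / C(N, n) for i = k .. min(K, n).
oracle_hyper_upper <- function(k, K, n, N) {
  if (k <= 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# All non-empty subset intersections of a list of member vectors, keyed by
# the sorted set ids of the subset; exact = genes in exactly those sets.
oracle_subset_intersections <- function(members, ids, exact = FALSE) {
  p <- length(members)
  out <- list()
  for (size in seq_len(p)) {
    combos <- utils::combn(p, size, simplify = FALSE)
    for (idx in combos) {
      genes <- Reduce(intersect, members[idx])
      if (exact && length(idx) < p) {
        others <- Reduce(union, members[-idx])
        genes <- setdiff(genes, others)
      }
      if (length(genes))
        out[[paste(sort(ids[idx]), collapse = "|")]] <- sort(genes)
    }
  }
  out
}

lattice_as_oracle_keys <- function(lat) {
  out <- lapply(lat$nodes, function(nd) sort(nd$genes))
  names(out) <- vapply(lat$nodes, function(nd)
    paste(sort(nd$child_set_ids), collapse = "|"), character(1))
  out
}

# Random acyclic ontology: term i > 1 links to parents among earlier terms.
random_test_dag <- function(n_terms) {
  ids <- sprintf("R%02d", seq_len(n_terms))
  children <- character(); parents <- character()
  for (i in 2:n_terms) {
    ps <- sample(ids[seq_len(i - 1L)], sample(1:min(2L, i - 1L), 1L))
    children <- c(children, rep(ids[i], length(ps)))
    parents <- c(parents, ps)
  }
  ontology_dag(
    terms = data.frame(id = ids, name = ids, namespace = "bp",
                       stringsAsFactors = FALSE),
    edges = data.frame(child = children, parent = parents, relation = "is_a",
                       stringsAsFactors = FALSE))
}

# Transitive reachability upward from a term, by plain BFS over the edge list.
oracle_reachable_up <- function(dag, from) {
  seen <- character(); frontier <- from
  while (length(frontier)) {
    nxt <- unique(dag$edges$parent[dag$edges$child %in% frontier])
    nxt <- setdiff(nxt, seen)
    seen <- union(seen, nxt)
    frontier <- nxt
  }
  sort(seen)
}

# Benjamini-Hochberg by the direct sort-based formula.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Small random gene-set family over a fixed universe.
random_set_family <- function(n_sets, universe_size = 50L) {
  universe <- sprintf("U%03d", seq_len(universe_size))
  lapply(seq_len(n_sets), function(i)
    gene_set(sprintf("S%d", i),
             sample(universe, sample(3:universe_size, 1L))))
}
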