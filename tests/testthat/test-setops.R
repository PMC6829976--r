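test_that("Boolean combinations are exact set algebra with provenance", {
  a <- gene_set("A", c("A", "B", "C"))
  b <- gene_set("B", c("B", "C", "D"))
  c3 <- gene_set("C", "C")
  expect_identical(boolean_combine("INTERSECT", list(a, b, c3))$members, "C")
  expect_identical(boolean_combine("UNION", list(a, a))$members, a$members)
  expect_identical(boolean_combine("DIFFERENCE", list(a, b))$members, "A")
  prov <- attr(boolean_combine("union", list(a, b)), "provenance")
  expect_identical(prov$op, "UNION")
  expect_identical(prov$inputs, c("A", "B"))
  expect_error(boolean_combine("UNION", list()), "at least one")
  expect_error(boolean_combine("DIFFERENCE", list(a)), "at least two")
})

test_that("the hypergeometric upper tail matches combinatorial arithmetic", {
  expect_identical(hypergeom_overlap_p(0, 5, 5, 10), 1)
  expect_equal(hypergeom_overlap_p(5, 5, 5, 10), 1 / 252, tolerance = 1e-12)
  for (N in c(6L, 9L, 12L)) {
    for (K in 0:N) for (n in 0:N) for (k in 0:min(K, n)) {
      expect_equal(hypergeom_overlap_p(k, K, n, N),
                   oracle_hyper_upper(k, K, n, N), tolerance = 1e-12)
    }
  }
  expect_error(hypergeom_overlap_p(6, 5, 5, 10), "bounds")
  expect_error(hypergeom_overlap_p(2, 5, 11, 10), "bounds")
})

test_that("hypergeometric p is non-increasing in the overlap count", {
  for (k in 1:8)
    expect_lte(hypergeom_overlap_p(k, 10, 8, 40),
               hypergeom_overlap_p(k - 1, 10, 8, 40))
})

test_that("Jaccard statistics cover the degenerate and published-count cases", {
  a <- gene_set("A", c("X", "Y", "Z"))
  b <- gene_set("B", c("X", "Y", "Z"))
  d <- gene_set("D", c("P", "Q"))
  js <- jaccard_matrix(list(a, b, d))
  row_ab <- js[js$set_a == "A" & js$set_b == "B", ]
  expect_identical(row_ab$jaccard, 1)
  row_ad <- js[js$set_a == "A" & js$set_b == "D", ]
  expect_identical(row_ad$jaccard, 0)
  expect_identical(row_ad$p_value, 1)
  # overlap counts of the published mouse-human comparison
  uni <- sprintf("G%04d", 1:4000)
  set_a <- gene_set("hs", uni[1:2386])
  set_b <- gene_set("mm", uni[c(1:378, 2387:2891)])
  js2 <- jaccard_matrix(list(set_a, set_b))
  expect_identical(js2$intersection_size, 378L)
  expect_equal(js2$jaccard, 378 / 2891, tolerance = 1e-12)
})

test_that("jaccard_matrix validates the universe and symmetry", {
  a <- gene_set("A", c("X", "Y"))
  b <- gene_set("B", c("Y", "Z"))
  expect_error(jaccard_matrix(list(a, b), universe = gene_set("U", c("X", "Y"))),
               "universe")
  js <- jaccard_matrix(list(a, b))
  js_swapped <- jaccard_matrix(list(b, a))
  expect_identical(js$jaccard, js_swapped$jaccard)
  expect_identical(js$p_value, js_swapped$p_value)
})

test_that("BH adjustment matches the sort-based formula", {
  set.seed(3)
  for (i in 1:5) {
    p <- runif(sample(5:100, 1))
    expect_equal(stats::p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("hand-checkable lattices come out exactly", {
  s <- gene_set("S", c("A", "B"))
  lat1 <- build_lattice(list(s))
  expect_length(lat1$nodes, 1L)
  expect_identical(lat1$nodes[[1]]$genes, c("A", "B"))

  fam <- list(gene_set("S1", c("A", "B")), gene_set("S2", c("B", "C")))
  at_least <- build_lattice(fam, mode = "AT_LEAST")
  keys <- lattice_as_oracle_keys(at_least)
  expect_identical(keys[["S1"]], c("A", "B"))
  expect_identical(keys[["S2"]], c("B", "C"))
  expect_identical(keys[["S1|S2"]], "B")
  exact <- build_lattice(fam, mode = "EXACT")
  keys_e <- lattice_as_oracle_keys(exact)
  expect_identical(keys_e[["S1"]], "A")
  expect_identical(keys_e[["S2"]], "C")
  expect_identical(keys_e[["S1|S2"]], "B")
  # the pairwise node sits below both leaves
  pair_idx <- which(names(keys) == "S1|S2")
  expect_setequal(at_least$edges$to[at_least$edges$from == pair_idx],
                  which(names(keys) %in% c("S1", "S2")))
})

test_that("random lattices match brute-force subset enumeration in both modes", {
  set.seed(42)
  for (rep_i in 1:30) {
    fam <- random_set_family(sample(2:6, 1))
    ids <- vapply(fam, function(s) s$set_id, character(1))
    members <- lapply(fam, function(s) s$members)
    for (mode in c("AT_LEAST", "EXACT")) {
      lat <- build_lattice(fam, mode = mode)
      keys <- lattice_as_oracle_keys(lat)
      oracle <- oracle_subset_intersections(members, ids,
                                            exact = (mode == "EXACT"))
      expect_identical(keys[order(names(keys))], oracle[order(names(oracle))])
    }
    # EXACT-mode node contents partition the union of the inputs
    exact <- build_lattice(fam, mode = "EXACT")
    all_genes <- unlist(lapply(exact$nodes, `[[`, "genes"))
    expect_identical(sort(all_genes), sort(Reduce(union, members)))
    expect_false(anyDuplicated(all_genes) > 0)
  }
})

test_that("the set-count guard triggers and can be overridden", {
  fam <- lapply(1:13, function(i) gene_set(sprintf("S%d", i), "A"))
  expect_error(build_lattice(fam), "max_sets")
  lat <- build_lattice(fam[1:3], max_sets = 3L)
  expect_length(lat$nodes, 7L)  # every subset non-empty: all share gene A
})

test_that("lattice exports are well-formed JSON and DOT", {
  fam <- list(gene_set("S1", c("A", "B")), gene_set("S2", c("B", "C")))
  lat <- build_lattice(fam)
  jpath <- withr::local_tempfile(fileext = ".json")
  lattice_to_json(lat, jpath)
  parsed <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  expect_identical(parsed$mode, "AT_LEAST")
  expect_identical(length(parsed$nodes$n_genes), 3L)
  dpath <- withr::local_tempfile(fileext = ".dot")
  lattice_to_dot(lat, dpath)
  expect_match(readLines(dpath)[1], "digraph")
})
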