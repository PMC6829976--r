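chain_dag <- function() {
  ontology_dag(
    terms = data.frame(id = c("A", "B", "C"), name = c("a", "b", "c"),
                       namespace = "bp", stringsAsFactors = FALSE),
    edges = data.frame(child = c("A", "B"), parent = c("B", "C"),
                       relation = "is_a", stringsAsFactors = FALSE))
}

test_that("true-path propagation climbs is_a/part_of chains and is idempotent", {
  dag <- chain_dag()
  ann <- annotation_set(list(G1 = "A"))
  closed <- propagate_annotations(dag, ann)
  expect_setequal(closed$closed$G1, c("A", "B", "C"))
  again <- propagate_annotations(dag, closed)
  expect_identical(again$closed, closed$closed)
})

test_that("annotations to unknown terms are rejected with the offenders", {
  dag <- chain_dag()
  expect_error(propagate_annotations(dag, annotation_set(list(G1 = "ZZZ"))),
               "ZZZ")
})

test_that("cyclic ontologies are rejected", {
  expect_error(ontology_dag(
    terms = data.frame(id = c("A", "B"), name = c("a", "b"), namespace = "bp"),
    edges = data.frame(child = c("A", "B"), parent = c("B", "A"),
                       relation = "is_a")), "cycle")
})

test_that("propagation matches the transitive-reachability oracle on random DAGs", {
  set.seed(5)
  for (rep_i in 1:20) {
    dag <- random_test_dag(sample(5:20, 1))
    ids <- dag$terms$id
    genes <- sprintf("G%d", 1:6)
    direct <- lapply(genes, function(g) sample(ids, sample(1:3, 1)))
    names(direct) <- genes
    closed <- propagate_annotations(dag, annotation_set(direct))
    for (g in genes) {
      want <- sort(unique(c(direct[[g]],
                            unlist(lapply(direct[[g]],
                                          function(t) oracle_reachable_up(dag, t))))))
      expect_identical(closed$closed[[g]], want)
    }
  }
})

test_that("degenerate enrichments give p = 1", {
  dag <- chain_dag()
  genes <- sprintf("G%d", 1:6)
  ann <- annotation_set(stats::setNames(replicate(6, "A", simplify = FALSE),
                                        genes))
  bg <- gene_set("bg", genes)
  res_full <- enrich(bg, bg, dag, ann)  # study = background
  expect_true(all(res_full$p_value == 1))
  study <- gene_set("st", genes[1:2])
  res <- enrich(study, bg, dag, ann)
  # root term C annotates every background gene
  expect_identical(res$p_value[res$term == "C"], 1)
})

test_that("a perfectly concentrated term gets the enumerated p-value", {
  dag <- ontology_dag(
    terms = data.frame(id = c("ROOT", "T1", "T2"), name = c("r", "1", "2"),
                       namespace = "bp", stringsAsFactors = FALSE),
    edges = data.frame(child = c("T1", "T2"), parent = "ROOT",
                       relation = "is_a", stringsAsFactors = FALSE))
  genes <- sprintf("G%02d", 1:10)
  study_genes <- genes[1:4]
  direct <- stats::setNames(as.list(rep("T2", 10)), genes)
  for (g in study_genes) direct[[g]] <- "T1"
  ann <- annotation_set(direct)
  res <- enrich(gene_set("st", study_genes), gene_set("bg", genes), dag, ann)
  expect_equal(res$p_value[res$term == "T1"], 1 / choose(10, 4),
               tolerance = 1e-12)
  expect_identical(res$term[1], "T1")  # sorted by p
  expect_true(res$most_specific[res$term == "T1"])
})

test_that("study sets outside the background are rejected", {
  dag <- chain_dag()
  ann <- annotation_set(list(G1 = "A"))
  expect_error(enrich(gene_set("st", c("G1", "GX")), gene_set("bg", "G1"),
                      dag, ann), "subset")
})

test_that("adding an unannotated study gene never decreases a term's p", {
  toy <- gen_toy_ontology(synthetic_scenario(seed = 2))
  res1 <- enrich(toy$study, toy$background, toy$dag, toy$ann)
  extra <- setdiff(toy$background$members, toy$study$members)[1]
  ann2 <- toy$ann
  ann2$direct[[extra]] <- NULL  # make it unannotated
  bigger <- gene_set("st2", c(toy$study$members, extra))
  res2 <- enrich(bigger, toy$background, toy$dag, ann2)
  shared <- intersect(res1$term, res2$term)
  p1 <- stats::setNames(res1$p_value, res1$term)[shared]
  p2 <- stats::setNames(res2$p_value, res2$term)[shared]
  expect_true(all(p2 >= p1 - 1e-15))
})

test_that("branch flagging follows descendants of the root terms", {
  dag <- ontology_dag(
    terms = data.frame(id = c("DEATH", "APOP", "OTHER"),
                       name = c("cell death", "apoptosis", "other"),
                       namespace = "bp", stringsAsFactors = FALSE),
    edges = data.frame(child = "APOP", parent = "DEATH", relation = "is_a",
                       stringsAsFactors = FALSE))
  ann <- annotation_set(list(G1 = "APOP", G2 = "OTHER"))
  flags <- flag_cell_death(gene_set("g", c("G1", "G2", "G3")), dag, ann,
                           root_terms = "DEATH")
  expect_true(flags[["G1"]])    # hits a descendant only
  expect_false(flags[["G2"]])
  expect_false(flags[["G3"]])   # no annotations at all
  expect_error(flag_cell_death(gene_set("g", "G1"), dag, ann, "NOPE"),
               "unknown root")
})

test_that("enrichment q-values respect the BH oracle within a namespace", {
  toy <- gen_toy_ontology(synthetic_scenario(seed = 4))
  res <- enrich(toy$study, toy$background, toy$dag, toy$ann)
  expect_equal(res$q_value, oracle_bh(res$p_value), tolerance = 1e-12)
})
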