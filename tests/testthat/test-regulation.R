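toy_de <- function() {
  list(
    up = list(BL1 = gene_set("up_BL1", c("G1", "G2")),
              M = gene_set("up_M", c("G2", "G3"))),
    down = list(BL1 = gene_set("down_BL1", "G4"),
                M = gene_set("down_M", c("G3", "G5")))
  )
}

test_that("the regulation matrix restricts to focus genes with a status", {
  de <- toy_de()
  focus <- gene_set("focus", c("G1", "G2", "G3", "G4", "G9"))
  m <- suppressWarnings(build_regulation_matrix(de$up, de$down, focus))
  expect_setequal(rownames(m), c("G1", "G2", "G3", "G4"))  # G9 has no status
  expect_identical(m["G1", "BL1"], "UP")
  expect_identical(m["G4", "BL1"], "DOWN")
  expect_identical(m["G1", "M"], "NONE")
})

test_that("a gene in both up and down of one subtype becomes BOTH with a warning", {
  de <- toy_de()
  focus <- gene_set("focus", c("G3"))
  expect_warning(m <- build_regulation_matrix(de$up, de$down, focus), "BOTH")
  expect_identical(m["G3", "M"], "BOTH")
})

test_that("mismatched subtype labels are rejected", {
  de <- toy_de()
  names(de$down) <- c("BL1", "LAR")
  expect_error(build_regulation_matrix(de$up, de$down, gene_set("f", "G1")),
               "subtype labels differ")
})

test_that("summary counts handle the empty matrix", {
  de <- toy_de()
  m <- build_regulation_matrix(de$up, de$down, gene_set("f", "ABSENT"))
  expect_identical(nrow(m), 0L)
  counts <- summarize_counts(m)
  expect_identical(counts$up_in_any, 0L)
  expect_identical(counts$down_in_any, 0L)
  expect_true(all(counts$per_subtype$up == 0L))
  sig <- resistant_signature(m, "M", "BL1")
  expect_length(sig$signature_genes, 0L)
})

test_that("fixture reconstruction reproduces every published count", {
  fx <- load_table2_fixture()
  de <- fixture_de_sets(fx)
  m <- build_regulation_matrix(de$up_sets, de$down_sets,
                               focus = gene_set("focus", fx$genes))
  expect_identical(nrow(m), 20L)
  counts <- summarize_counts(m)
  expect_identical(counts$up_in_any, 16L)
  expect_identical(counts$down_in_any, 11L)
  per <- counts$per_subtype
  expect_identical(per$up[per$subtype == "BL1"], 2L)
  expect_identical(per$down[per$subtype == "BL1"], 5L)
  expect_identical(per$up[per$subtype == "BL2"], 4L)
  expect_identical(per$down[per$subtype == "BL2"], 0L)
  expect_identical(per$up[per$subtype == "M"], 5L)
  expect_identical(per$down[per$subtype == "M"], 3L)
  expect_identical(per$up[per$subtype == "LAR"], 8L)
  expect_identical(per$down[per$subtype == "LAR"], 3L)
})

test_that("the signature rule recovers the 13 published genes and their partition", {
  fx <- load_table2_fixture()
  sig <- resistant_signature(fx$status, c("LAR", "M"), c("BL1", "BL2"))
  expect_length(sig$signature_genes, 13L)
  expect_setequal(sig$signature_genes, fx$genes[fx$resistant_flag])
  expect_length(sig$exclusivity$LAR, 7L)
  expect_length(sig$exclusivity$M, 3L)
  expect_length(sig$exclusivity$`LAR+M`, 3L)
  expect_setequal(sig$exclusivity$`LAR+M`, c("CASP8", "TUBA1A", "VIM"))
  expect_setequal(sig$exclusivity$M, c("FAS", "NOX4", "VCAM1"))
})

test_that("a resistant status matched by any sensitive status is excluded", {
  m <- cisplatinsig:::new_regulation_matrix(matrix(
    c("UP", "NONE", "UP", "NONE",     # matches BL1 -> excluded
      "UP", "NONE", "DOWN", "NONE",   # differs everywhere -> included
      "NONE", "NONE", "NONE", "UP",   # sensitive all NONE -> included
      "UP", "UP", "UP", "UP"),        # matched in both sensitives -> excluded
    nrow = 4, byrow = TRUE,
    dimnames = list(c("GA", "GB", "GC", "GD"), c("BL1", "BL2", "M", "LAR"))))
  sig <- resistant_signature(m, c("LAR", "M"), c("BL1", "BL2"))
  expect_setequal(sig$signature_genes, c("GB", "GC"))
  expect_identical(sig$per_gene_basis$GB$subtype, "M")
})

test_that("BOTH in a resistant subtype counts as differential and matches nothing", {
  m <- cisplatinsig:::new_regulation_matrix(matrix(
    c("UP", "NONE", "BOTH", "NONE",
      "BOTH", "NONE", "BOTH", "NONE"),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("GA", "GB"), c("BL1", "BL2", "M", "LAR"))))
  sig <- resistant_signature(m, c("LAR", "M"), c("BL1", "BL2"))
  expect_setequal(sig$signature_genes, c("GA", "GB"))
})

test_that("overlapping subtype groups are rejected", {
  fx <- load_table2_fixture()
  expect_error(resistant_signature(fx$status, c("LAR", "M"), c("M", "BL1")),
               "overlap")
  expect_error(resistant_signature(fx$status, character(), "BL1"), "non-empty")
})

test_that("the signature is invariant to gene and label-order permutations", {
  fx <- load_table2_fixture()
  base <- resistant_signature(fx$status, c("LAR", "M"), c("BL1", "BL2"))
  perm <- fx$status[sample(nrow(fx$status)), , drop = FALSE]
  class(perm) <- class(fx$status)
  sig_perm <- resistant_signature(perm, c("M", "LAR"), c("BL2", "BL1"))
  expect_identical(sig_perm$signature_genes, base$signature_genes)
  expect_setequal(sig_perm$exclusivity$`M+LAR`, base$exclusivity$`LAR+M`)
})

test_that("with all sensitive statuses NONE the signature is every resistant DE gene", {
  m <- cisplatinsig:::new_regulation_matrix(matrix(
    c("NONE", "NONE", "UP", "NONE",
      "NONE", "NONE", "NONE", "DOWN",
      "NONE", "NONE", "UP", "UP"),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("GA", "GB", "GC"), c("BL1", "BL2", "M", "LAR"))))
  sig <- resistant_signature(m, c("LAR", "M"), c("BL1", "BL2"))
  expect_setequal(sig$signature_genes, c("GA", "GB", "GC"))
  # every signature gene is differentially expressed in >= 1 resistant subtype
  for (g in sig$signature_genes)
    expect_true(any(m[g, c("LAR", "M")] != "NONE"))
})
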