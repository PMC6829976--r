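# Planted-truth synthetic data: emulates the statistical structure of the
# pipeline's inputs (three species chemical-associated sets sharing a
# conserved core, per-subtype up/down DE sets realizing a planted
# resistance signature, and a toy ontology with one planted enriched term)
# so every stage is testable without external downloads.

# run expr under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}

#' Default planted regulation patterns
#'
#' Twenty regulation patterns mirroring the structure of the packaged
#' regulation fixture: 13 patterns that satisfy the resistant-signature rule
#' (7 exclusive to LAR, 3 exclusive to M, 3 differential in both) and 7
#' distractor patterns excluded by the rule. Used as the default
#' `planted_signature` of a [synthetic_scenario()].
#'
#' @return named list; each element has `status` (named character vector
#'   over subtypes) and `signature` (logical: does the pattern satisfy the
#'   rule).
#' @export
default_planted_signature <- function() {
  fx <- load_table2_fixture()
  out <- lapply(seq_along(fx$genes), function(i) {
    list(status = fx$status[i, ], signature = unname(fx$resistant_flag[i]))
  })
  names(out) <- sprintf("pattern_%02d", seq_along(fx$genes))
  out
}

#' Define a synthetic scenario
#'
#' Bundles every parameter of the synthetic generators; all randomness flows
#' from `seed`. The defaults reproduce the study conditions: a 96-gene
#' conserved core inside species sets of 2386 (human), 883 (mouse) and 616
#' (rat) genes; per-subtype DE set sizes BL1 215/251, BL2 154/127, M
#' 247/446, LAR 805/382 (up/down); and the 20 planted regulation patterns of
#' [default_planted_signature()], 13 of which satisfy the signature rule.
#'
#' @param seed integer seed.
#' @param universe_size number of genes in the synthetic genome.
#' @param core_size size of the planted conserved core.
#' @param species_extra named integer vector `human`, `mouse`, `rat`: number
#'   of non-core genes per species set.
#' @param fanout_prob probability a mouse/rat gene maps to a second human
#'   gene (extra targets are drawn inside the core so the planted triple
#'   intersection is preserved).
#' @param collision_mode if `TRUE`, species extras are sampled independently
#'   (they may collide across species); default samples them disjointly so
#'   the triple intersection is exactly the core.
#' @param subtype_spec named list: subtype -> c(up =, down =) set sizes.
#' @param planted_signature named list of regulation patterns (see
#'   [default_planted_signature()]); planted genes are taken from the core.
#' @param noise_rate probability that a planted set membership is dropped.
#' @param flip_rate probability that a surviving planted status flips
#'   direction (up <-> down).
#' @return object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(seed = 1L,
                               universe_size = 20000L,
                               core_size = 96L,
                               species_extra = c(human = 2290L, mouse = 787L,
                                                 rat = 520L),
                               fanout_prob = 0,
                               collision_mode = FALSE,
                               subtype_spec = list(
                                 BL1 = c(up = 215L, down = 251L),
                                 BL2 = c(up = 154L, down = 127L),
                                 M   = c(up = 247L, down = 446L),
                                 LAR = c(up = 805L, down = 382L)),
                               planted_signature = default_planted_signature(),
                               noise_rate = 0,
                               flip_rate = 0) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (core_size > universe_size)
    stop("core_size exceeds universe_size")
  stopifnot(all(c("human", "mouse", "rat") %in% names(species_extra)),
            all(species_extra >= 0))
  if (!collision_mode &&
      core_size + sum(species_extra) > universe_size)
    stop("universe too small for disjoint core and species extras")
  stopifnot(is.list(subtype_spec), length(subtype_spec) >= 1L,
            !is.null(names(subtype_spec)))
  for (s in names(subtype_spec))
    stopifnot(all(c("up", "down") %in% names(subtype_spec[[s]])))
  if (length(planted_signature) > core_size)
    stop("more planted patterns than core genes")
  for (p in planted_signature) {
    unknown <- setdiff(names(p$status), names(subtype_spec))
    if (length(unknown))
      stop("planted pattern references unknown subtype(s): ",
           paste(unknown, collapse = ", "))
    if (!all(p$status %in% c("UP", "DOWN", "BOTH", "NONE")))
      stop("planted pattern has invalid status value")
  }
  stopifnot(noise_rate >= 0, noise_rate <= 1, flip_rate >= 0, flip_rate <= 1,
            fanout_prob >= 0, fanout_prob <= 1)
  structure(list(seed = as.integer(seed), universe_size = universe_size,
                 core_size = core_size, species_extra = species_extra,
                 fanout_prob = fanout_prob, collision_mode = collision_mode,
                 subtype_spec = subtype_spec,
                 planted_signature = planted_signature,
                 noise_rate = noise_rate, flip_rate = flip_rate),
            class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf("<synthetic_scenario> seed %d: universe %d, core %d, noise %.2f\n",
              x$seed, x$universe_size, x$core_size, x$noise_rate))
  invisible(x)
}

# deterministic base layout shared by the generators: gene universe, core,
# per-species extras, planted-gene assignment
scenario_layout <- function(sc) {
  with_seed(sc$seed, {
    universe <- sprintf("G%05d", seq_len(sc$universe_size))
    core <- sample(universe, sc$core_size)
    pool <- setdiff(universe, core)
    extras <- list()
    if (sc$collision_mode) {
      for (sp in c("human", "mouse", "rat"))
        extras[[sp]] <- sample(pool, sc$species_extra[[sp]])
    } else {
      remaining <- pool
      for (sp in c("human", "mouse", "rat")) {
        extras[[sp]] <- sample(remaining, sc$species_extra[[sp]])
        remaining <- setdiff(remaining, extras[[sp]])
      }
    }
    planted <- if (length(sc$planted_signature))
      stats::setNames(core[seq_along(sc$planted_signature)],
                      names(sc$planted_signature))
    else character()
    list(universe = universe, core = core, extras = extras,
         planted = planted)
  })
}

#' Generate three species gene sets sharing a planted conserved core
#'
#' Produces human, mouse and rat chemical-associated gene sets together with
#' the ortholog map that projects the rodent sets into the human namespace.
#' In the default (disjoint) mode the human projections of the three sets
#' intersect in exactly the planted core.
#'
#' @param sc a [synthetic_scenario()].
#' @return list with `sets` (named list of three [gene_set]s), `map` (an
#'   [ortholog_map]) and `truth` (list with the planted `core`).
#' @export
gen_species_sets <- function(sc) {
  stopifnot(inherits(sc, "synthetic_scenario"))
  lay <- scenario_layout(sc)
  with_seed(sc$seed + 1L, {
    human <- gene_set("human_chem", c(lay$core, lay$extras$human),
                      label = "Synthetic human chemical-associated set",
                      species = "human")
    rows <- list()
    sets <- list(human = human)
    for (sp in c("mouse", "rat")) {
      prefix <- c(mouse = "MM-", rat = "RN-")[[sp]]
      human_targets <- c(lay$core, lay$extras[[sp]])
      species_genes <- paste0(prefix, human_targets)
      rows[[sp]] <- data.frame(species = sp, species_gene = species_genes,
                               human_gene = human_targets,
                               stringsAsFactors = FALSE)
      if (sc$fanout_prob > 0) {
        fan <- stats::runif(length(species_genes)) < sc$fanout_prob
        if (any(fan)) {
          # extra targets stay inside the core so the planted triple
          # intersection is unchanged
          extra <- data.frame(
            species = sp,
            species_gene = species_genes[fan],
            human_gene = sample(lay$core, sum(fan), replace = TRUE),
            stringsAsFactors = FALSE)
          rows[[sp]] <- rbind(rows[[sp]], extra)
        }
      }
      sets[[sp]] <- gene_set(paste0(sp, "_chem"), species_genes,
                             label = sprintf("Synthetic %s chemical-associated set", sp),
                             species = sp)
    }
    list(sets = sets,
         map = ortholog_map(do.call(rbind, rows)),
         truth = list(core = sort(lay$core)))
  })
}

# apply drop/flip noise to the planted membership of one set
apply_noise <- function(members, sc) {
  if (!length(members)) return(list(keep = character(), flipped = character()))
  drop <- stats::runif(length(members)) < sc$noise_rate
  kept <- members[!drop]
  flip <- if (sc$flip_rate > 0)
    stats::runif(length(kept)) < sc$flip_rate else rep(FALSE, length(kept))
  list(keep = kept[!flip], flipped = kept[flip])
}

#' Generate per-subtype up/down DE sets realizing a planted signature
#'
#' Planted genes (drawn from the conserved core) enter the up/down sets of
#' each subtype according to their planted regulation pattern, subject to
#' drop/flip noise; the sets are then filled to the scenario's per-subtype
#' sizes with background genes sampled outside the core.
#'
#' @param sc a [synthetic_scenario()].
#' @return list with `up_sets`, `down_sets` (named lists of [gene_set]s) and
#'   `truth` (planted gene assignment, the planted status matrix, and
#'   `signature_genes`, the planted genes whose pattern satisfies the
#'   signature rule).
#' @export
gen_subtype_sets <- function(sc) {
  stopifnot(inherits(sc, "synthetic_scenario"))
  lay <- scenario_layout(sc)
  subtypes <- names(sc$subtype_spec)
  patterns <- sc$planted_signature
  status <- matrix("NONE", nrow = length(patterns), ncol = length(subtypes),
                   dimnames = list(unname(lay$planted), subtypes))
  for (i in seq_along(patterns)) {
    st <- patterns[[i]]$status
    status[i, names(st)] <- unname(st)
  }
  bg_pool <- setdiff(lay$universe, lay$core)
  with_seed(sc$seed + 2L, {
    up_sets <- list(); down_sets <- list()
    for (s in subtypes) {
      planted_up <- rownames(status)[status[, s] %in% c("UP", "BOTH")]
      planted_dn <- rownames(status)[status[, s] %in% c("DOWN", "BOTH")]
      up_n <- apply_noise(planted_up, sc)
      dn_n <- apply_noise(planted_dn, sc)
      up_members <- c(up_n$keep, dn_n$flipped)
      dn_members <- c(dn_n$keep, up_n$flipped)
      want_up <- sc$subtype_spec[[s]][["up"]]
      want_dn <- sc$subtype_spec[[s]][["down"]]
      fill_n <- max(0L, want_up - length(up_members)) +
        max(0L, want_dn - length(dn_members))
      fill <- sample(bg_pool, min(fill_n, length(bg_pool)))
      n_up_fill <- max(0L, want_up - length(up_members))
      up_sets[[s]] <- gene_set(paste0("up_", s),
                               c(up_members, utils::head(fill, n_up_fill)),
                               label = paste("Synthetic up-regulated set,", s))
      down_sets[[s]] <- gene_set(paste0("down_", s),
                                 c(dn_members, utils::tail(fill, length(fill) - n_up_fill)),
                                 label = paste("Synthetic down-regulated set,", s))
    }
    sig_flag <- vapply(patterns, function(p) isTRUE(p$signature), logical(1))
    list(up_sets = up_sets, down_sets = down_sets,
         truth = list(planted = data.frame(label = names(patterns),
                                           gene = unname(lay$planted),
                                           stringsAsFactors = FALSE),
                      status = status,
                      signature_genes = sort(unname(lay$planted[sig_flag]))))
  })
}

#' Generate a toy ontology with one planted enriched term
#'
#' Builds a small random acyclic DAG (children choose parents among earlier
#' terms, so the last term is a leaf), a background gene universe with
#' random annotations, and a designated study set whose genes are all
#' directly annotated to the planted leaf term. The truth record carries the
#' exact upper-tail hypergeometric probability of the planted overlap,
#' computed by direct combinatorial arithmetic.
#'
#' @param sc a [synthetic_scenario()].
#' @param n_terms number of ontology terms (<= 50).
#' @param n_genes background universe size.
#' @param study_size study-set size.
#' @param extra_annotated background-only genes also annotated to the
#'   planted term.
#' @return list with `dag`, `ann` (direct annotations), `study`,
#'   `background` ([gene_set]s) and `truth` (planted `term`, counts `k`,
#'   `K`, `n`, `N`, and `p_exact`).
#' @export
gen_toy_ontology <- function(sc, n_terms = 25L, n_genes = 40L,
                             study_size = 8L, extra_annotated = 2L) {
  stopifnot(inherits(sc, "synthetic_scenario"), n_terms >= 3L, n_terms <= 50L,
            study_size + extra_annotated <= n_genes)
  with_seed(sc$seed + 3L, {
    ids <- sprintf("T%02d", seq_len(n_terms))
    children <- character(); parents <- character()
    for (i in 2:n_terms) {
      np <- sample(1:min(2L, i - 1L), 1L)
      ps <- sample(ids[seq_len(i - 1L)], np)
      children <- c(children, rep(ids[i], np)); parents <- c(parents, ps)
    }
    dag <- ontology_dag(
      terms = data.frame(id = ids, name = paste("term", ids),
                         namespace = "biological_process",
                         stringsAsFactors = FALSE),
      edges = data.frame(child = children, parent = parents,
                         relation = "is_a", stringsAsFactors = FALSE))
    genes <- sprintf("SYNGENE%03d", seq_len(n_genes))
    study_genes <- sample(genes, study_size)
    planted_term <- ids[n_terms]  # leaf: nothing propagates into it
    extra_genes <- sample(setdiff(genes, study_genes), extra_annotated)
    direct <- stats::setNames(vector("list", n_genes), genes)
    random_pool <- ids[-n_terms]
    for (g in genes)
      direct[[g]] <- sample(random_pool, sample(1:3, 1L))
    for (g in c(study_genes, extra_genes))
      direct[[g]] <- unique(c(direct[[g]], planted_term))
    k <- study_size; K <- study_size + extra_annotated
    n <- study_size; N <- n_genes
    i <- k:min(K, n)
    p_exact <- sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
    list(dag = dag, ann = annotation_set(direct),
         study = gene_set("toy_study", study_genes),
         background = gene_set("toy_background", genes),
         truth = list(term = planted_term, k = k, K = K, n = n, N = N,
                      p_exact = p_exact))
  })
}
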