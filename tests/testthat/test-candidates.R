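# toy screen: 1 large clone, 1 small clone, 3 tissues with the third excluded
toy_setup <- function() {
  m <- generate_library(3, 6, 4, seed = 41)
  design <- screen_design(n_small = 1, n_large = 1, n_tissue = 3,
                          excluded_tissues = 3)
  comparisons <- comparisons_from_design(design)
  expression <- data.frame(
    gene = c("gene0001", "gene0002", "gene0003"),
    basal_expression = c(10, 10, 5),
    luminal_expression = c(2, 2, 5))
  list(m = m, design = design, comparisons = comparisons,
       expression = expression)
}

# build an enriched-set list giving gene G the stated per-comparison counts
sets_for <- function(m, comparisons, counts_by_label) {
  sets <- stats::setNames(vector("list", nrow(comparisons)),
                          comparisons$comparison_id)
  for (i in seq_len(nrow(comparisons))) {
    key <- comparisons$comparison_id[i]
    k <- counts_by_label[[key]] %||% 0L
    sets[[key]] <- if (k > 0) m$sgrna_id[m$gene == "gene0001"][seq_len(k)] else character(0)
  }
  sets
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("hand-enumerated filter configurations reproduce exactly", {
  fx <- toy_setup()
  ids <- fx$comparisons$comparison_id
  lib_cmp <- ids[fx$comparisons$label == "clone_vs_library"]
  small_cmp <- ids[fx$comparisons$label == "clone_vs_smallclone"]
  tis_cmp <- ids[fx$comparisons$label == "tissue_vs_library"]

  # clone vs lib 2, clone vs small 2, tissueA 2, tissueB 3, tissueC excluded 0
  counts <- stats::setNames(list(2L, 2L, 2L, 3L, 0L),
                            c(lib_cmp, small_cmp, tis_cmp))
  sets <- sets_for(fx$m, fx$comparisons, counts)
  cmap <- gene_guide_counts(sets, fx$m)
  rep <- select_candidates(cmap, fx$comparisons, fx$design, fx$expression)
  g1 <- rep[rep$gene == "gene0001", ]
  expect_true(all(g1$passes_c1, g1$passes_c2, g1$passes_c3, g1$passes_c4,
                  g1$final_candidate))
  expect_equal(g1$min_tissue_vs_library, 2L)   # excluded tissue skipped
  expect_false(any(rep$final_candidate[rep$gene != "gene0001"]))

  # dropping one included tissue to a single guide breaks criterion 3
  counts[[tis_cmp[2]]] <- 1L
  rep2 <- select_candidates(gene_guide_counts(sets_for(fx$m, fx$comparisons, counts), fx$m),
                            fx$comparisons, fx$design, fx$expression)
  g1 <- rep2[rep2$gene == "gene0001", ]
  expect_false(g1$passes_c3)
  expect_false(g1$final_candidate)
  expect_true(g1$passes_c1 && g1$passes_c2 && g1$passes_c4)

  # basal == luminal fails criterion 4 at any ratio threshold above 1
  expr2 <- fx$expression; expr2$luminal_expression[1] <- 10
  counts[[tis_cmp[2]]] <- 3L
  rep3 <- select_candidates(gene_guide_counts(sets_for(fx$m, fx$comparisons, counts), fx$m),
                            fx$comparisons, fx$design, expr2)
  expect_false(rep3$passes_c4[rep3$gene == "gene0001"])
  expect_false(rep3$final_candidate[rep3$gene == "gene0001"])
})

test_that("toggling a tissue's exclusion changes only criterion 3 through it", {
  fx <- toy_setup()
  ids <- fx$comparisons$comparison_id
  tis_cmp <- ids[fx$comparisons$label == "tissue_vs_library"]
  counts <- stats::setNames(
    list(2L, 2L, 2L, 2L, 0L),
    c(ids[fx$comparisons$label == "clone_vs_library"],
      ids[fx$comparisons$label == "clone_vs_smallclone"], tis_cmp))
  sets <- sets_for(fx$m, fx$comparisons, counts)
  cmap <- gene_guide_counts(sets, fx$m)

  rep_excl <- select_candidates(cmap, fx$comparisons, fx$design, fx$expression)
  expect_true(rep_excl$final_candidate[rep_excl$gene == "gene0001"])

  incl <- fx$design; incl$excluded[] <- FALSE
  rep_incl <- select_candidates(cmap, fx$comparisons, incl, fx$expression)
  g1 <- rep_incl[rep_incl$gene == "gene0001", ]
  expect_false(g1$passes_c3)          # tissue3 now counts, with 0 guides
  expect_true(g1$passes_c1 && g1$passes_c2 && g1$passes_c4)
})

test_that("guide tallies are exact and reject unknown guides", {
  fx <- toy_setup()
  cid <- fx$comparisons$comparison_id[1]
  empty <- stats::setNames(list(character(0)), cid)
  cmap <- gene_guide_counts(empty, fx$m)
  expect_true(all(cmap$n_enriched == 0))
  expect_equal(nrow(cmap), 3)          # comparisons x non-control genes

  three <- stats::setNames(list(fx$m$sgrna_id[fx$m$gene == "gene0002"][1:3]), cid)
  cmap <- gene_guide_counts(three, fx$m)
  expect_equal(cmap$n_enriched[cmap$gene == "gene0002"], 3L)

  # brute-force recount over random sets
  set.seed(5)
  for (rep_i in 1:20) {
    ids <- sample(fx$m$sgrna_id, sample.int(nrow(fx$m), 1))
    sets <- stats::setNames(list(ids), cid)
    cmap <- gene_guide_counts(sets, fx$m)
    for (g in unique(fx$m$gene[!fx$m$is_control])) {
      manual <- sum(fx$m$gene[match(ids, fx$m$sgrna_id)] == g)
      expect_equal(cmap$n_enriched[cmap$gene == g], manual)
    }
  }
  expect_error(gene_guide_counts(stats::setNames(list("nope"), cid), fx$m),
               "unknown sgrna_id")
})

test_that("adding an enriched guide never turns a candidate into a non-candidate", {
  fx <- toy_setup()
  set.seed(6)
  for (rep_i in 1:25) {
    sets <- lapply(stats::setNames(fx$comparisons$comparison_id,
                                   fx$comparisons$comparison_id),
                   function(cid) sample(fx$m$sgrna_id, sample.int(10, 1) - 1))
    before <- select_candidates(gene_guide_counts(sets, fx$m),
                                fx$comparisons, fx$design, fx$expression)
    cid <- sample(fx$comparisons$comparison_id, 1)
    extra <- sample(setdiff(fx$m$sgrna_id, sets[[cid]]), 1)
    sets[[cid]] <- c(sets[[cid]], extra)
    after <- select_candidates(gene_guide_counts(sets, fx$m),
                               fx$comparisons, fx$design, fx$expression)
    expect_true(all(after$final_candidate[before$final_candidate]))
  }
})

test_that("genes missing from the expression table fail criterion 4 with a warning", {
  fx <- toy_setup()
  ids <- fx$comparisons$comparison_id
  counts <- stats::setNames(as.list(rep(2L, length(ids))), ids)
  cmap <- gene_guide_counts(sets_for(fx$m, fx$comparisons, counts), fx$m)
  expr <- fx$expression[fx$expression$gene != "gene0001", ]
  expect_warning(
    rep <- select_candidates(cmap, fx$comparisons, fx$design, expr),
    "criterion 4")
  expect_false(rep$passes_c4[rep$gene == "gene0001"])
  expect_false(rep$final_candidate[rep$gene == "gene0001"])
})

test_that("the enrichment summary partitions genes and reports proportions", {
  m <- generate_library(5, 6, 0, seed = 42)
  cmap <- data.frame(
    comparison_id = rep(c("a", "b"), each = 5),
    gene = rep(sprintf("gene%04d", 1:5), 2),
    n_enriched = c(1L, 2L, 5L, 0L, 0L, 0L, 2L, 1L, 0L, 3L))
  s <- enrichment_summary(cmap)
  a <- s$per_comparison[s$per_comparison$comparison_id == "a", ]
  expect_equal(c(a$genes_1_sgrna, a$genes_2_sgrnas, a$genes_3plus_sgrnas),
               c(1, 1, 1))
  # bins partition genes with >= 1 enriched guide
  for (cid in c("a", "b")) {
    row <- s$per_comparison[s$per_comparison$comparison_id == cid, ]
    expect_equal(row$genes_1_sgrna + row$genes_2_sgrnas + row$genes_3plus_sgrnas,
                 sum(cmap$n_enriched[cmap$comparison_id == cid] >= 1))
  }
  pg <- s$per_gene
  expect_equal(pg$prop_comparisons_enriched[pg$gene == "gene0002"], 1)
  expect_equal(pg$prop_comparisons_enriched[pg$gene == "gene0001"], 0.5)
  expect_true(all(pg$prop_comparisons_enriched >= 0 & pg$prop_comparisons_enriched <= 1))
})
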