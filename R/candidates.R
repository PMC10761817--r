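#' Tally enriched guides per gene and comparison
#'
#' @param sets named list (comparison_id -> character vector of enriched
#'   sgrna ids), as produced by [enriched_sets()].
#' @param manifest library manifest; every listed guide must be known.
#' @return data.frame `comparison_id`, `gene`, `n_enriched` covering every
#'   (comparison, non-control gene) pair, zeros included.
#' @export
gene_guide_counts <- function(sets, manifest) {
  genes <- unique(manifest$gene[!manifest$is_control])
  out <- expand.grid(comparison_id = names(sets), gene = genes,
                     stringsAsFactors = FALSE)
  out$n_enriched <- 0L
  for (cmp in names(sets)) {
    ids <- sets[[cmp]]
    unknown <- setdiff(ids, manifest$sgrna_id)
    if (length(unknown)) {
      stop("enriched set '", cmp, "' references unknown sgrna_id: ", unknown[1L])
    }
    g <- manifest$gene[match(ids, manifest$sgrna_id)]
    g <- g[g != CONTROL_GENE]
    if (!length(g)) next
    tab <- table(g)
    sel <- out$comparison_id == cmp & out$gene %in% names(tab)
    out$n_enriched[sel] <- as.integer(tab[out$gene[sel]])
  }
  out
}

#' Select candidate genes by the four screen criteria
#'
#' A gene is a final candidate iff
#' \enumerate{
#'   \item at least `min_guides` of its guides are enriched in some large
#'     clone versus the cell library;
#'   \item at least `min_guides` are enriched in some large clone versus a
#'     small clone;
#'   \item at least `min_guides` are enriched in every included regenerated
#'     tissue versus the cell library (tissues flagged excluded in the
#'     design are skipped);
#'   \item the gene is expressed higher in basal than in luminal cells,
#'     operationalised as `basal >= expression_ratio * luminal`.
#' }
#' Criteria 1-2 are existential over clone samples, criterion 3 universal
#' over included tissues. A gene absent from the expression table fails
#' criterion 4 with a warning rather than an error.
#'
#' @param counts_map output of [gene_guide_counts()].
#' @param comparisons data.frame from [comparisons_from_design()] (must cover
#'   every comparison_id of `counts_map`).
#' @param design `screen_design` (supplies tissue exclusion flags).
#' @param expression table with `gene`, `basal_expression`,
#'   `luminal_expression`.
#' @param min_guides minimum enriched guides per comparison (default 2).
#' @param expression_ratio minimal basal/luminal ratio (default 1.5).
#' @return data.frame of class `candidate_report`: per gene the four
#'   criterion booleans, supporting counts (`max_clone_vs_library`,
#'   `max_clone_vs_smallclone`, `min_tissue_vs_library` over included
#'   tissues) and `final_candidate`.
#' @export
select_candidates <- function(counts_map, comparisons, design, expression,
                              min_guides = 2L, expression_ratio = 1.5) {
  validate_design(design)
  unknown <- setdiff(counts_map$comparison_id, comparisons$comparison_id)
  if (length(unknown)) stop("counts reference unknown comparison: ", unknown[1L])
  cm <- merge(counts_map, comparisons, by = "comparison_id")
  excluded_samples <- design$sample_id[design$excluded]
  cm$included <- !(cm$treatment %in% excluded_samples)

  genes <- sort(unique(cm$gene))
  sup <- function(label, fun, default) {
    vapply(genes, function(g) {
      v <- cm$n_enriched[cm$gene == g & cm$label == label & cm$included]
      if (!length(v)) default else fun(v)
    }, numeric(1))
  }
  max_cvl <- sup("clone_vs_library", max, 0)
  max_cvs <- sup("clone_vs_smallclone", max, 0)
  min_tvl <- sup("tissue_vs_library", min, 0)
  has_tissue <- vapply(genes, function(g) {
    any(cm$gene == g & cm$label == "tissue_vs_library" & cm$included)
  }, logical(1))

  ex_idx <- match(genes, expression$gene)
  if (anyNA(ex_idx)) {
    warning("genes absent from the expression table fail criterion 4: ",
            paste(utils::head(genes[is.na(ex_idx)], 5L), collapse = ", "),
            if (sum(is.na(ex_idx)) > 5L) ", ..." else "")
  }
  basal <- expression$basal_expression[ex_idx]
  luminal <- expression$luminal_expression[ex_idx]
  c4 <- !is.na(ex_idx) & basal >= expression_ratio * luminal

  report <- data.frame(
    gene = genes,
    passes_c1 = max_cvl >= min_guides,
    passes_c2 = max_cvs >= min_guides,
    passes_c3 = has_tissue & min_tvl >= min_guides,
    passes_c4 = c4,
    max_clone_vs_library = as.integer(max_cvl),
    max_clone_vs_smallclone = as.integer(max_cvs),
    min_tissue_vs_library = as.integer(min_tvl),
    stringsAsFactors = FALSE
  )
  report$final_candidate <- report$passes_c1 & report$passes_c2 &
    report$passes_c3 & report$passes_c4
  class(report) <- c("candidate_report", "data.frame")
  report
}

#' @export
print.candidate_report <- function(x, ...) {
  cat("candidate report: ", sum(x$final_candidate), " of ", nrow(x),
      " genes pass all four criteria\n", sep = "")
  if (any(x$final_candidate)) print(as.data.frame(x[x$final_candidate, ]))
  invisible(x)
}

#' Enrichment summary across comparisons
#'
#' For each comparison, the number of genes with exactly 1, exactly 2, and 3
#' or more enriched guides (disjoint, exhaustive over genes with at least
#' one enriched guide); plus, per gene, the proportion of comparisons in
#' which it has at least one enriched guide.
#'
#' @param counts_map output of [gene_guide_counts()].
#' @return list with `per_comparison` and `per_gene` data.frames.
#' @export
enrichment_summary <- function(counts_map) {
  per_comparison <- do.call(rbind, lapply(split(counts_map, counts_map$comparison_id),
    function(d) {
      data.frame(comparison_id = d$comparison_id[1L],
                 genes_1_sgrna = sum(d$n_enriched == 1L),
                 genes_2_sgrnas = sum(d$n_enriched == 2L),
                 genes_3plus_sgrnas = sum(d$n_enriched >= 3L),
                 stringsAsFactors = FALSE)
    }))
  rownames(per_comparison) <- NULL
  n_cmp <- length(unique(counts_map$comparison_id))
  per_gene <- do.call(rbind, lapply(split(counts_map, counts_map$gene),
    function(d) {
      data.frame(gene = d$gene[1L],
                 prop_comparisons_enriched = sum(d$n_enriched >= 1L) / n_cmp,
                 stringsAsFactors = FALSE)
    }))
  rownames(per_gene) <- NULL
  list(per_comparison = per_comparison, per_gene = per_gene)
}
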