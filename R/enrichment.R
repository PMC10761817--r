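#' Per-sample size factors
#'
#' `median_ratio` is the median-of-ratios estimator computed over guides
#' nonzero in every sample (delegated to DESeq2); `control_guides` restricts
#' the reference set to non-targeting controls; `total` scales by column
#' sums. Factors are positive and, for the ratio methods, centred so their
#' log-mean is zero.
#'
#' @param counts guide x sample integer matrix (or `sgrna_counts`).
#' @param method one of `"median_ratio"`, `"control_guides"`, `"total"`.
#' @param manifest required for `"control_guides"`.
#' @return named numeric vector of size factors.
#' @export
normalize <- function(counts, method = c("median_ratio", "control_guides", "total"),
                      manifest = NULL) {
  if (inherits(counts, "sgrna_counts")) counts <- counts$counts
  method <- match.arg(method)
  sf <- switch(method,
    median_ratio = tryCatch(
      DESeq2::estimateSizeFactorsForMatrix(counts),
      error = function(e) stop("median_ratio needs at least one guide with ",
                               "nonzero counts in every sample (", conditionMessage(e), ")")
    ),
    control_guides = {
      if (is.null(manifest)) stop("control_guides normalization needs the manifest")
      ctrl <- which(manifest$is_control)
      if (!length(ctrl)) stop("no control guides in the manifest")
      tryCatch(
        DESeq2::estimateSizeFactorsForMatrix(counts, controlGenes = ctrl),
        error = function(e) stop("control_guides normalization failed: no control ",
                                 "guide is nonzero in every sample")
      )
    },
    total = {
      cs <- colSums(counts)
      if (any(cs == 0)) stop("total normalization: a sample has zero counts")
      cs / exp(mean(log(cs)))
    }
  )
  stopifnot(all(sf > 0))
  sf
}

#' Specify a treatment-vs-control comparison
#'
#' @param comparison_id short unique label.
#' @param treatment,control sample ids (must differ and exist in the design).
#' @param label comparison class: `"clone_vs_library"`,
#'   `"clone_vs_smallclone"` or `"tissue_vs_library"`.
#' @return one-row data.frame.
#' @export
comparison_spec <- function(comparison_id, treatment, control,
                            label = c("clone_vs_library", "clone_vs_smallclone",
                                      "tissue_vs_library")) {
  label <- match.arg(label)
  if (identical(treatment, control)) stop("treatment and control must differ")
  data.frame(comparison_id = comparison_id, treatment = treatment,
             control = control, label = label, stringsAsFactors = FALSE)
}

#' Enumerate the standard comparisons of a screen design
#'
#' Each large clone is compared to the cell library and to a paired small
#' clone (pairing by order, recycled if the counts differ); each tissue is
#' compared to the cell library. Excluded tissues keep their comparison —
#' exclusion is applied by the candidate filter, not here.
#'
#' @param design `screen_design`.
#' @return data.frame of comparison specs.
#' @export
comparisons_from_design <- function(design) {
  validate_design(design)
  lib <- design$sample_id[design$role == "cell_library"]
  large <- design$sample_id[design$role == "large_clone"]
  small <- design$sample_id[design$role == "small_clone"]
  tissue <- design$sample_id[design$role == "tissue"]
  out <- list()
  for (i in seq_along(large)) {
    out[[length(out) + 1L]] <- comparison_spec(
      paste0(large[i], "_vs_lib"), large[i], lib, "clone_vs_library")
    if (length(small)) {
      s <- small[(i - 1L) %% length(small) + 1L]
      out[[length(out) + 1L]] <- comparison_spec(
        paste0(large[i], "_vs_", s), large[i], s, "clone_vs_smallclone")
    }
  }
  for (t in tissue) {
    out[[length(out) + 1L]] <- comparison_spec(
      paste0(t, "_vs_lib"), t, lib, "tissue_vs_library")
  }
  do.call(rbind, out)
}

#' Per-guide enrichment test for one comparison
#'
#' For each guide the statistic is the natural-log ratio of
#' pseudocount-stabilised, size-factor-normalised counts, centred at the
#' all-guide median and standardised by
#' `sqrt(1/(t + pc) + 1/(c + pc) + 2 * phi)`, where `phi` is a pooled
#' method-of-moments overdispersion (upper-trimmed mean over all guides of
#' the excess of squared residual over the Poisson-level variance; the trim
#' keeps a minority of true hits from inflating it). One-sided p-values
#' (enrichment only) come from the standard normal reference by default, or
#' from the empirical null of control-guide scores — linearly interpolated
#' survival with Gaussian tail extension beyond its range — with
#' `null_method = "control_empirical"` (falling back to the all-guide null
#' below `min_controls`). FDR is Benjamini-Hochberg within the comparison;
#' a guide is `enriched` iff `fdr < fdr_threshold` and its log2 fold change
#' is positive.
#'
#' @param counts `sgrna_counts` or guide x sample matrix.
#' @param comparison one-row data.frame from [comparison_spec()].
#' @param manifest library manifest.
#' @param norm_method passed to [normalize()].
#' @param pseudocount added to normalised counts before ratios.
#' @param fdr_threshold BH-FDR cutoff for the `enriched` flag.
#' @param null_method `"normal"` or `"control_empirical"`.
#' @param min_controls minimum control guides for the control-empirical null.
#' @return data.frame of per-guide statistics (`sgrna_id`, `treatment_norm`,
#'   `control_norm`, `log2_fold_change`, `score`, `p_value`, `fdr`,
#'   `enriched`) with the comparison attached as attribute `comparison`.
#' @export
sgrna_test <- function(counts, comparison, manifest,
                       norm_method = "median_ratio", pseudocount = 1,
                       fdr_threshold = 0.05,
                       null_method = c("normal", "control_empirical"),
                       min_controls = 20L) {
  null_method <- match.arg(null_method)
  if (inherits(counts, "sgrna_counts")) counts <- counts$counts
  for (s in c(comparison$treatment, comparison$control)) {
    if (!s %in% colnames(counts)) stop("sample absent from count matrix: ", s)
  }
  pair <- counts[, c(comparison$treatment, comparison$control), drop = FALSE]
  sf <- normalize(pair, method = norm_method, manifest = manifest)
  t_raw <- pair[, 1L]
  c_raw <- pair[, 2L]
  t_norm <- t_raw / sf[1L]
  c_norm <- c_raw / sf[2L]
  d <- log((t_norm + pseudocount) / (c_norm + pseudocount))
  # Poisson-level variance of the log ratio, evaluated at the pooled null
  # mean rather than the observed counts (observed-count variances shrink
  # exactly when the ratio fluctuates up, inflating the upper tail)
  mu <- (t_norm + c_norm) / 2
  v <- 1 / (sf[1L] * mu + pseudocount) + 1 / (sf[2L] * mu + pseudocount)
  m0 <- median(d)
  excess <- (d - m0)^2 - v
  keep <- excess <= stats::quantile(excess, 0.9)  # upper trim against true hits
  phi <- max(0, mean(excess[keep]) / 2)
  score <- (d - m0) / sqrt(v + 2 * phi)

  is_ctrl <- manifest$is_control[match(rownames(pair), manifest$sgrna_id)]
  p <- switch(null_method,
    normal = pnorm(score, lower.tail = FALSE),
    control_empirical = {
      null_scores <- score[which(is_ctrl)]
      if (length(null_scores) < min_controls) null_scores <- score
      if (length(unique(null_scores)) < 2L) {
        stop("degenerate empirical null (all null scores identical); ",
             "use null_method = 'normal' or the all-guides null")
      }
      empirical_null_p(score, null_scores)
    })
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  fdr <- p.adjust(p, method = "BH")
  lfc <- log2((t_norm + pseudocount) / (c_norm + pseudocount))
  res <- data.frame(
    sgrna_id = rownames(pair),
    treatment_norm = t_norm, control_norm = c_norm,
    log2_fold_change = lfc, score = score,
    p_value = p, fdr = fdr,
    enriched = fdr < fdr_threshold & lfc > 0,
    stringsAsFactors = FALSE
  )
  attr(res, "comparison") <- comparison
  attr(res, "size_factors") <- sf
  attr(res, "phi") <- phi
  res
}

# One-sided upper-tail p from an empirical null: survival function linearly
# interpolated through the plotting positions (M+1-j)/(M+1) at the sorted
# null scores (the continuous analogue of a mid-p), with a Gaussian tail
# fitted to the null's mean/sd extending beyond its observed range.
empirical_null_p <- function(score, null_scores) {
  M <- length(null_scores)
  s_sorted <- sort(null_scores)
  surv_at <- (M:1) / (M + 1)
  mu <- mean(null_scores)
  sd0 <- stats::sd(null_scores)
  p <- numeric(length(score))
  inside <- score >= s_sorted[1L] & score <= s_sorted[M]
  if (any(inside)) {
    p[inside] <- stats::approx(s_sorted, surv_at, xout = score[inside],
                               ties = "ordered")$y
  }
  above <- score > s_sorted[M]
  if (any(above)) {
    tail_p <- pnorm(score[above], mean = mu, sd = sd0, lower.tail = FALSE)
    p[above] <- pmin(tail_p, 1 / (M + 1))
  }
  below <- score < s_sorted[1L]
  if (any(below)) {
    tail_p <- pnorm(score[below], mean = mu, sd = sd0, lower.tail = FALSE)
    p[below] <- pmax(tail_p, M / (M + 1))
  }
  pmin(p, 1)
}

#' Gene-level alpha-RRA aggregation with permutation p-values
#'
#' Guides are ranked by p-value over the whole library (average ranks for
#' ties; controls stay in the ranking universe), giving normalised ranks
#' `r = rank/N`. For a gene with `n` guides, only guides with `p < alpha`
#' are retained; with its retained normalised ranks sorted ascending, the
#' gene score is `min_k P(Beta(k, n-k+1) <= r_(k))` (1 if no guide passes
#' alpha). Significance comes from permuting the guide-to-gene labels:
#' the reported p-value is the exact smoothed permutation p
#' `(#{perm < obs} + U * (1 + #{perm = obs})) / (B + 1)` (uniform on (0,1]
#' under the null, floored at `1/(B+1)`), deterministic given `seed`.
#'
#' @param stats per-guide statistics from [sgrna_test()].
#' @param manifest library manifest.
#' @param alpha guide p-value threshold for rank retention.
#' @param n_permutations number of label permutations (>= 100).
#' @param seed integer seed.
#' @return data.frame per non-control gene: `gene`, `n_guides`,
#'   `n_enriched_sgrnas`, `rra_score`, `p_value`.
#' @export
gene_aggregate <- function(stats, manifest, alpha = 0.25,
                           n_permutations = 1000L, seed = 1L) {
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (n_permutations < 100L) stop("n_permutations below 100 gives unusable resolution")
  ord <- match(manifest$sgrna_id, stats$sgrna_id)
  if (any(is.na(ord))) stop("stats do not cover the manifest's guides")
  p <- stats$p_value[ord]
  enr <- stats$enriched[ord]
  genes <- manifest$gene
  N <- length(p)
  r <- rank(p, ties.method = "average") / N
  keep <- p < alpha

  gene_n <- table(genes)
  obs <- rra_gene_scores(genes, r, keep, gene_n)

  with_seed(seed, {
    B <- as.integer(n_permutations)
    perm_gene <- vector("list", B)
    for (b in seq_len(B)) perm_gene[[b]] <- genes[sample.int(N)]
    big <- data.table::data.table(
      perm = rep(seq_len(B), each = N),
      gene = unlist(perm_gene),
      r = rep(r, B), keep = rep(keep, B)
    )
    perm_scores <- rra_gene_scores_dt(big, gene_n)

    target <- names(obs)[names(obs) != CONTROL_GENE]
    u <- runif(length(target))
    pvals <- numeric(length(target))
    for (gi in seq_along(target)) {
      g <- target[gi]
      ps <- perm_scores[[g]]
      n_less <- sum(ps < obs[[g]])
      n_eq <- sum(ps == obs[[g]])
      pvals[gi] <- (n_less + u[gi] * (1 + n_eq)) / (B + 1)
    }
    pvals <- pmin(pmax(pvals, 1 / (B + 1)), 1)

    n_enr <- tapply(enr, genes, sum)[target]
    data.frame(gene = target,
               n_guides = as.integer(gene_n[target]),
               n_enriched_sgrnas = as.integer(n_enr),
               rra_score = as.numeric(obs[target]),
               p_value = pvals,
               stringsAsFactors = FALSE)
  })
}

# observed alpha-RRA scores, one pass
rra_gene_scores <- function(genes, r, keep, gene_n) {
  out <- stats::setNames(rep(1, length(gene_n)), names(gene_n))
  if (!any(keep)) return(out)
  dt <- data.table::data.table(gene = genes[keep], r = r[keep])
  data.table::setorder(dt, gene, r)
  dt[, k := seq_len(.N), by = gene]
  dt[, n := as.integer(gene_n[gene])]
  dt[, pb := pbeta(r, k, n - k + 1L)]
  sc <- dt[, list(score = min(pb)), by = gene]
  out[sc$gene] <- sc$score
  out
}

# permutation scores: list gene -> numeric vector over permutations
# (a permutation where no guide of the gene passes alpha scores 1)
rra_gene_scores_dt <- function(big, gene_n) {
  B <- max(big$perm)
  kept <- big[keep == TRUE]
  data.table::setorder(kept, perm, gene, r)
  kept[, k := seq_len(.N), by = list(perm, gene)]
  kept[, n := as.integer(gene_n[gene])]
  kept[, pb := pbeta(r, k, n - k + 1L)]
  sc <- kept[, list(score = min(pb)), by = list(perm, gene)]
  out <- lapply(stats::setNames(names(gene_n), names(gene_n)), function(g) {
    v <- rep(1, B)
    rows <- sc[gene == g]
    v[rows$perm] <- rows$score
    v
  })
  out
}

#' Project enriched flags into per-comparison guide sets
#'
#' @param stats_list named list (comparison_id -> [sgrna_test()] result).
#' @return named list of character vectors of enriched sgrna ids.
#' @export
enriched_sets <- function(stats_list) {
  lapply(stats_list, function(st) st$sgrna_id[st$enriched])
}
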