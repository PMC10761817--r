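#' Generate a synthetic GeCKO-style sgRNA library
#'
#' Draws random 20-nt guide sequences for `n_genes` genes with
#' `sgrnas_per_gene` guides each, plus `n_controls` non-targeting control
#' guides under the reserved pseudo-gene label `"NTC"`. Sequences are sampled
#' with a minimum pairwise Hamming distance of `min_hamming` (default 3) so
#' that one-mismatch read assignment is unambiguous by construction; genome-
#' scale libraries do not guarantee this, and ambiguity handling is exercised
#' separately with planted near-duplicate guides.
#'
#' @param n_genes number of protein-coding genes targeted.
#' @param sgrnas_per_gene guides per gene (uniform by construction).
#' @param n_controls number of non-targeting control guides.
#' @param seed integer seed; the manifest is deterministic given the seed.
#' @param min_hamming minimum pairwise Hamming distance between any two
#'   guide sequences.
#' @param max_attempts rejection-sampling budget per accepted sequence.
#' @return a `data.frame` of class `sgrna_manifest` with columns
#'   `sgrna_id`, `gene`, `sequence`, `is_control` and attribute
#'   `sgrnas_per_gene`.
#' @export
generate_library <- function(n_genes, sgrnas_per_gene, n_controls = 0L,
                             seed = 1L, min_hamming = 3L, max_attempts = 200L) {
  stopifnot(n_genes >= 1L, sgrnas_per_gene >= 1L, n_controls >= 0L)
  n_total <- n_genes * sgrnas_per_gene + n_controls
  width <- 20L
  with_seed(seed, {
    acc <- matrix(0L, nrow = n_total, ncol = width)
    n_acc <- 0L
    attempts <- 0L
    while (n_acc < n_total) {
      cand <- sample.int(4L, width, replace = TRUE)
      ok <- TRUE
      if (n_acc > 0L && min_hamming > 1L) {
        d <- rowSums(acc[seq_len(n_acc), , drop = FALSE] !=
                       matrix(cand, n_acc, width, byrow = TRUE))
        ok <- all(d >= min_hamming)
      }
      if (ok) {
        n_acc <- n_acc + 1L
        acc[n_acc, ] <- cand
        attempts <- 0L
      } else {
        attempts <- attempts + 1L
        if (attempts > max_attempts) {
          stop("could not sample ", n_total, " sequences at pairwise Hamming >= ",
               min_hamming, " within the attempt budget; request fewer guides")
        }
      }
    }
    seqs <- apply(acc, 1L, function(row) paste(DNA_BASES[row], collapse = ""))
    genes <- c(rep(sprintf("gene%04d", seq_len(n_genes)), each = sgrnas_per_gene),
               rep(CONTROL_GENE, n_controls))
    within_gene <- c(rep(seq_len(sgrnas_per_gene), times = n_genes),
                     seq_len(max(n_controls, 1L))[seq_len(n_controls)])
    ids <- ifelse(genes == CONTROL_GENE,
                  sprintf("%s_sg%04d", genes, within_gene),
                  sprintf("%s_sg%d", genes, within_gene))
    manifest <- data.frame(
      sgrna_id = ids, gene = genes, sequence = seqs,
      is_control = genes == CONTROL_GENE,
      stringsAsFactors = FALSE
    )
    attr(manifest, "sgrnas_per_gene") <- as.integer(sgrnas_per_gene)
    class(manifest) <- c("sgrna_manifest", "data.frame")
    validate_manifest(manifest)
    manifest
  })
}

#' Validate an sgRNA library manifest
#'
#' Checks the structural invariants: 20-nt ACGT sequences, unique guide ids,
#' and consistency between `is_control` and the reserved control label.
#' Duplicate sequences are allowed (real libraries contain them) and only
#' warned about.
#' @param manifest manifest data frame.
#' @return the manifest, invisibly; errors describe the first violation.
#' @export
validate_manifest <- function(manifest) {
  need <- c("sgrna_id", "gene", "sequence", "is_control")
  missing <- setdiff(need, names(manifest))
  if (length(missing)) stop("manifest lacks columns: ", paste(missing, collapse = ", "))
  bad_len <- which(nchar(manifest$sequence) != 20L)
  if (length(bad_len)) {
    stop("manifest sequences must be exactly 20 nt; offending sgrna_id: ",
         manifest$sgrna_id[bad_len[1L]])
  }
  if (any(grepl("[^ACGT]", manifest$sequence))) {
    stop("manifest sequences must be over {A,C,G,T}")
  }
  if (anyDuplicated(manifest$sgrna_id)) {
    stop("duplicate sgrna_id in manifest: ",
         manifest$sgrna_id[duplicated(manifest$sgrna_id)][1L])
  }
  if (!all(manifest$is_control == (manifest$gene == CONTROL_GENE))) {
    stop("is_control must hold exactly for guides with gene == '", CONTROL_GENE, "'")
  }
  if (anyDuplicated(manifest$sequence)) {
    warning("manifest contains duplicated guide sequences; reads matching them ",
            "will be discarded as ambiguous")
  }
  invisible(manifest)
}

#' @export
print.sgrna_manifest <- function(x, ...) {
  cat("sgRNA library manifest: ", nrow(x), " guides (",
      sum(!x$is_control), " targeting ", length(unique(x$gene[!x$is_control])),
      " genes, ", sum(x$is_control), " controls)\n", sep = "")
  print(utils::head(as.data.frame(x), 4L))
  invisible(x)
}

#' Write / read a library manifest (CSV)
#'
#' Columns: `sgrna_id,gene,sequence,is_control`.
#' @param manifest manifest to write.
#' @param path file path.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  utils::write.csv(as.data.frame(manifest)[, c("sgrna_id", "gene", "sequence", "is_control")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$is_control <- as.logical(df$is_control)
  class(df) <- c("sgrna_manifest", "data.frame")
  validate_manifest(df)
  spg <- table(df$gene[!df$is_control])
  attr(df, "sgrnas_per_gene") <- if (length(spg) && length(unique(spg)) == 1L)
    as.integer(spg[1L]) else NA_integer_
  df
}

#' Construct a screen design table
#'
#' The sample hierarchy of a clone-assay + transplantation screen: one
#' sequenced plasmid pool, one transduced cell library, small and large
#' mammosphere clones, and regenerated tissues. Tissues can be flagged
#' excluded (poor library quality) and are then skipped by the universal
#' tissue criterion of the candidate filter.
#'
#' @param n_small,n_large,n_tissue numbers of small-clone, large-clone and
#'   regenerated-tissue samples.
#' @param excluded_tissues integer indices (into the tissue samples) or
#'   character sample ids flagged as excluded.
#' @return data.frame of class `screen_design` with columns
#'   `sample_id`, `role`, `excluded`.
#' @export
screen_design <- function(n_small = 3L, n_large = 3L, n_tissue = 3L,
                          excluded_tissues = integer(0)) {
  stopifnot(n_large >= 1L, n_tissue >= 1L)
  tissue_ids <- sprintf("tissue%d", seq_len(n_tissue))
  excl <- if (is.character(excluded_tissues)) tissue_ids %in% excluded_tissues
          else seq_len(n_tissue) %in% excluded_tissues
  design <- data.frame(
    sample_id = c("plasmid", "cell_library",
                  sprintf("small_clone%d", seq_len(n_small)),
                  sprintf("large_clone%d", seq_len(n_large)),
                  tissue_ids),
    role = c("plasmid", "cell_library",
             rep("small_clone", n_small), rep("large_clone", n_large),
             rep("tissue", n_tissue)),
    excluded = c(rep(FALSE, 2L + n_small + n_large), excl),
    stringsAsFactors = FALSE
  )
  class(design) <- c("screen_design", "data.frame")
  validate_design(design)
  design
}

#' @rdname screen_design
#' @param design design data frame to validate.
#' @export
validate_design <- function(design) {
  need <- c("sample_id", "role", "excluded")
  if (!all(need %in% names(design))) stop("design needs columns sample_id, role, excluded")
  roles <- c("plasmid", "cell_library", "small_clone", "large_clone", "tissue")
  if (!all(design$role %in% roles)) {
    stop("unknown role: ", setdiff(design$role, roles)[1L])
  }
  if (sum(design$role == "plasmid") != 1L) stop("design must have exactly one plasmid sample")
  if (sum(design$role == "cell_library") != 1L) stop("design must have exactly one cell_library sample")
  if (sum(design$role == "large_clone") < 1L) stop("design must have at least one large_clone sample")
  if (sum(design$role == "tissue") < 1L) stop("design must have at least one tissue sample")
  if (anyDuplicated(design$sample_id)) stop("duplicate sample_id in design")
  if (any(design$excluded & design$role != "tissue")) {
    stop("excluded flag is only meaningful for tissue samples")
  }
  invisible(design)
}

#' @export
write_design <- function(design, path) {
  validate_design(design)
  utils::write.table(as.data.frame(design), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @param path file path of a design TSV.
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$excluded <- as.logical(df$excluded)
  class(df) <- c("screen_design", "data.frame")
  validate_design(df)
  df
}

#' Ground-truth fitness and guide efficiency for a simulated screen
#'
#' Knockout of a hit gene confers a per-passage log-growth advantage
#' (`hit_fitness`); all other genes are neutral. Each guide has an efficiency
#' in `[0,1]`: the probability that its lineage actually carries the
#' knockout. Control guides have efficiency 0 by definition.
#'
#' @param manifest library manifest.
#' @param hit_genes character vector of gene symbols spiked as hits (or an
#'   integer count, in which case the first genes of the manifest are used).
#' @param hit_fitness per-passage log growth advantage of a functional hit
#'   knockout; `log(2)` doubles the lineage's relative weight each passage.
#' @param hit_efficiency_range guide efficiencies for hit genes are drawn
#'   uniformly from this interval.
#' @param neutral_efficiency_range efficiencies for neutral targeting guides
#'   (inconsequential for counts, kept for realism of the truth table).
#' @param seed integer seed.
#' @return list of class `simulation_truth` with `gene_fitness` (named
#'   numeric) and `sgrna_efficiency` (named numeric).
#' @export
simulation_truth <- function(manifest, hit_genes = character(0),
                             hit_fitness = log(2),
                             hit_efficiency_range = c(0.8, 1),
                             neutral_efficiency_range = c(0.5, 1),
                             seed = 1L) {
  genes <- unique(manifest$gene[!manifest$is_control])
  if (is.numeric(hit_genes) && length(hit_genes) == 1L) {
    hit_genes <- genes[seq_len(hit_genes)]
  }
  if (!all(hit_genes %in% genes)) {
    stop("hit genes absent from manifest: ",
         paste(setdiff(hit_genes, genes), collapse = ", "))
  }
  with_seed(seed, {
    fitness <- stats::setNames(rep(0, length(genes)), genes)
    fitness[hit_genes] <- hit_fitness
    eff <- stats::setNames(numeric(nrow(manifest)), manifest$sgrna_id)
    hit_guide <- manifest$gene %in% hit_genes
    eff[hit_guide] <- runif(sum(hit_guide), hit_efficiency_range[1L], hit_efficiency_range[2L])
    neutral_guide <- !manifest$is_control & !hit_guide
    eff[neutral_guide] <- runif(sum(neutral_guide),
                                neutral_efficiency_range[1L], neutral_efficiency_range[2L])
    eff[manifest$is_control] <- 0
    stopifnot(all(is.finite(fitness)), all(eff >= 0 & eff <= 1))
    structure(list(gene_fitness = fitness, sgrna_efficiency = eff,
                   hit_genes = hit_genes),
              class = "simulation_truth")
  })
}

#' Synthetic basal/luminal expression table
#'
#' Emulates the gene-by-lineage expression input of the candidate filter:
#' log-normal expression levels for the two mammary epithelial lineages.
#' Genes listed in `basal_high_genes` are guaranteed basal-biased (ratio
#' at least `min_hit_ratio`); other genes get a random basal/luminal ratio
#' spanning both directions.
#'
#' @param genes character vector of gene symbols (controls are not expressed
#'   genes and should not be passed).
#' @param basal_high_genes genes forced to basal-high expression.
#' @param min_hit_ratio minimum basal/luminal ratio for `basal_high_genes`.
#' @param seed integer seed.
#' @return data.frame with columns `gene`, `basal_expression`,
#'   `luminal_expression`.
#' @export
synth_expression <- function(genes, basal_high_genes = character(0),
                             min_hit_ratio = 2, seed = 1L) {
  stopifnot(all(basal_high_genes %in% genes))
  with_seed(seed, {
    n <- length(genes)
    basal <- stats::rlnorm(n, meanlog = 3, sdlog = 1)
    ratio <- exp(runif(n, log(1 / 4), log(4)))
    hit <- genes %in% basal_high_genes
    ratio[hit] <- exp(runif(sum(hit), log(min_hit_ratio), log(4 * min_hit_ratio)))
    data.frame(gene = genes,
               basal_expression = basal,
               luminal_expression = basal / ratio,
               stringsAsFactors = FALSE)
  })
}

#' @export
write_expression <- function(expression, path) {
  utils::write.csv(expression, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @param expression expression table; `path` file path.
#' @param path file path.
#' @export
read_expression <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "basal_expression", "luminal_expression") %in% names(df)))
  if (anyDuplicated(df$gene)) stop("duplicate gene in expression table")
  if (any(!is.finite(df$basal_expression)) || any(!is.finite(df$luminal_expression)) ||
      any(df$basal_expression < 0) || any(df$luminal_expression < 0)) {
    stop("expression values must be finite and non-negative")
  }
  df
}
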