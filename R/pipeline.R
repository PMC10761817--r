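#' Default configuration for a simulated demonstration screen
#'
#' A scaled-down screen: 100 genes x 6 guides + 50 non-targeting controls,
#' 5 spiked hit genes with per-passage fitness log(2) and guide efficiency
#' in [0.8, 1], a design of one plasmid, one cell library, 3 small clones,
#' 3 large clones and 3 regenerated tissues (the third excluded for poor
#' library quality), sequenced at 2e5 reads per sample. All thresholds are
#' the package defaults. Returned as a plain nested list; write it with
#' [yaml::write_yaml()] to use from the command line.
#'
#' @param seed master seed; all stage streams derive from it.
#' @return nested configuration list (see [run_all()]).
#' @export
demo_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(
      n_genes = 100L, sgrnas_per_gene = 6L, n_controls = 50L,
      n_hits = 5L, hit_fitness = log(2),
      hit_efficiency = c(0.8, 1),
      n_small = 3L, n_large = 3L, n_tissue = 3L, excluded_tissues = 3L,
      plasmid_dispersion = 5, coverage = 100L, passages = 3,
      depth_per_sample = 2e5, expression_min_hit_ratio = 2,
      emit_fastq = FALSE
    ),
    paths = list(manifest = NULL, fastq_dir = NULL, design = NULL,
                 expression = NULL),
    window = list(start = 15L, end = 50L, max_mismatches = 1L),
    normalization = "median_ratio",
    test = list(pseudocount = 1, fdr_threshold = 0.05,
                null_method = "normal"),
    aggregate = list(alpha = 0.25, n_permutations = 1000L),
    filter = list(min_guides = 2L, expression_ratio = 1.5)
  )
}

#' Read and schema-check a run configuration (YAML)
#'
#' Unknown keys are rejected; a seed is mandatory.
#' @param path YAML file.
#' @return validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' @keywords internal
validate_config <- function(cfg) {
  template <- demo_config()
  check_keys <- function(x, ref, prefix = "") {
    extra <- setdiff(names(x), names(ref))
    if (length(extra)) {
      stop("unknown configuration key: ", prefix, extra[1L])
    }
    for (k in names(x)) {
      if (is.list(ref[[k]]) && !is.null(names(ref[[k]])) && is.list(x[[k]])) {
        check_keys(x[[k]], ref[[k]], paste0(prefix, k, "."))
      }
    }
  }
  check_keys(cfg, template)
  if (is.null(cfg$seed)) stop("configuration must set a seed")
  utils::modifyList(template, cfg)
}

#' Validate the inputs of a configuration
#'
#' Checks referenced files for existence and schema (20-nt manifest
#' sequences, design roles and exclusion flags, per-sample FASTQ presence,
#' expression coverage of the manifest's genes) without running anything.
#'
#' @param config configuration list (as from [read_run_config()] or
#'   [demo_config()]).
#' @return data.frame of problems (`severity`, `item`, `message`);
#'   zero rows means the configuration is runnable. The worst severity is
#'   attached as attribute `status` (0 ok, 1 warning, 2 error).
#' @export
validate_inputs <- function(config) {
  config <- validate_config(config)
  probs <- list()
  note <- function(severity, item, message) {
    probs[[length(probs) + 1L]] <<- data.frame(
      severity = severity, item = item, message = message,
      stringsAsFactors = FALSE)
  }
  p <- config$paths
  simulated <- !is.null(config$simulate) && is.null(p$manifest)
  manifest <- NULL
  if (!simulated) {
    if (is.null(p$manifest) || !file.exists(p$manifest)) {
      note("error", "manifest", paste0("manifest file not found: ",
                                       p$manifest %||% "<unset>"))
    } else {
      manifest <- tryCatch(read_manifest(p$manifest), error = function(e) {
        note("error", "manifest", conditionMessage(e)); NULL
      }, warning = function(w) suppressWarnings(read_manifest(p$manifest)))
    }
    design <- NULL
    if (is.null(p$design) || !file.exists(p$design)) {
      note("error", "design", paste0("design file not found: ",
                                     p$design %||% "<unset>"))
    } else {
      design <- tryCatch(read_design(p$design), error = function(e) {
        note("error", "design", conditionMessage(e)); NULL
      })
    }
    if (!is.null(design) && !is.null(p$fastq_dir)) {
      for (s in design$sample_id) {
        fq <- fastq_for_sample(p$fastq_dir, s)
        if (is.na(fq)) {
          note("error", s, paste0("no FASTQ for sample '", s, "' in ", p$fastq_dir))
        }
      }
    }
    if (is.null(p$expression) || !file.exists(p$expression)) {
      note("error", "expression", paste0("expression file not found: ",
                                         p$expression %||% "<unset>"))
    } else if (!is.null(manifest)) {
      expr <- tryCatch(read_expression(p$expression), error = function(e) {
        note("error", "expression", conditionMessage(e)); NULL
      })
      if (!is.null(expr)) {
        miss <- setdiff(unique(manifest$gene[!manifest$is_control]), expr$gene)
        if (length(miss)) {
          note("warning", "expression",
               paste0(length(miss), " manifest genes missing from the ",
                      "expression table (they will fail criterion 4)"))
        }
      }
    }
  }
  out <- if (length(probs)) do.call(rbind, probs) else
    data.frame(severity = character(0), item = character(0),
               message = character(0), stringsAsFactors = FALSE)
  attr(out, "status") <- if (any(out$severity == "error")) 2L else
    if (any(out$severity == "warning")) 1L else 0L
  out
}

fastq_for_sample <- function(dir, sample_id) {
  for (ext in c(".fastq", ".fastq.gz", ".fq", ".fq.gz")) {
    f <- file.path(dir, paste0(sample_id, ext))
    if (file.exists(f)) return(f)
  }
  NA_character_
}

#' Run the full pipeline: simulate/load, count, test, aggregate, select
#'
#' Executes the screen analysis end to end and writes every artifact to
#' `out_dir`: the library manifest, design, expression table, count matrix
#' (+ per-sample assignment tallies), per-comparison sgRNA statistics,
#' gene-level aggregation for the first tissue-vs-library comparison,
#' enriched-set JSON, candidate report (TSV + JSON), enrichment summary,
#' a resolved-config snapshot with input hashes, and a stage log.
#' Re-running with an identical configuration reproduces identical outputs.
#'
#' With a `simulate` block the screen is generated; setting
#' `simulate$emit_fastq: true` routes counts through FASTQ emission and the
#' shift-tolerant quantifier, otherwise the simulator's sampled abundances
#' are used directly. With `paths` set, the manifest/design/FASTQ/expression
#' inputs are loaded instead.
#'
#' @param config configuration list (see [demo_config()]).
#' @param out_dir output directory (created if missing).
#' @param quiet suppress stage messages.
#' @return the candidate report, invisibly; all artifacts on disk.
#' @export
run_all <- function(config, out_dir, quiet = FALSE) {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  logf <- function(...) {
    line <- paste0(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    if (!quiet) message(line)
  }
  unlink(log_path)
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  # ---- inputs: simulate or load -------------------------------------------
  sim <- config$simulate
  if (!is.null(sim) && is.null(config$paths$manifest)) {
    manifest <- stage("simulate", generate_library(
      sim$n_genes, sim$sgrnas_per_gene, sim$n_controls,
      seed = stage_seed(seed, "library")))
    truth <- simulation_truth(
      manifest, hit_genes = sim$n_hits, hit_fitness = sim$hit_fitness,
      hit_efficiency_range = sim$hit_efficiency,
      seed = stage_seed(seed, "truth"))
    design <- screen_design(sim$n_small, sim$n_large, sim$n_tissue,
                            excluded_tissues = sim$excluded_tissues)
    expression <- synth_expression(
      unique(manifest$gene[!manifest$is_control]),
      basal_high_genes = truth$hit_genes,
      min_hit_ratio = sim$expression_min_hit_ratio,
      seed = stage_seed(seed, "expression"))
    scr <- stage("simulate", simulate_screen(
      manifest, truth, design,
      params = list(plasmid_dispersion = sim$plasmid_dispersion,
                    bottleneck_cells = sim$coverage * nrow(manifest),
                    passages = sim$passages,
                    depth_per_sample = sim$depth_per_sample),
      seed = stage_seed(seed, "screen")))
    logf("simulate: ", nrow(manifest), " guides, ", nrow(design), " samples, ",
         "depth ", sim$depth_per_sample)
    write_manifest(manifest, file.path(out_dir, "manifest.csv"))
    write_design(design, file.path(out_dir, "design.tsv"))
    write_expression(expression, file.path(out_dir, "expression.csv"))
    saveRDS_free_truth(truth, file.path(out_dir, "truth.tsv"), manifest)

    if (isTRUE(sim$emit_fastq)) {
      fq_dir <- file.path(out_dir, "fastq")
      dir.create(fq_dir, showWarnings = FALSE)
      cfg <- read_emission_config()
      index <- build_index(manifest, match_window(
        config$window$start, config$window$end,
        max_mismatches = config$window$max_mismatches))
      cols <- list()
      for (s in design$sample_id) {
        fq <- file.path(fq_dir, paste0(s, ".fastq.gz"))
        emit_reads(scr$counts[, s], manifest, cfg, fastq_path = fq,
                   sidecar_path = file.path(fq_dir, paste0(s, ".truth.tsv")),
                   seed = stage_seed(seed, paste0("emit_", s)),
                   read_prefix = s)
        cols[[s]] <- stage("count", count_sample(fq, index))
        logf("count ", s, ": ", cols[[s]]$tally$n_assigned, "/",
             cols[[s]]$tally$n_reads, " reads assigned")
      }
      counts <- build_count_matrix(cols, design, manifest)
    } else {
      cols <- lapply(stats::setNames(design$sample_id, design$sample_id),
                     function(s) scr$counts[, s])
      counts <- build_count_matrix(cols, design, manifest)
      logf("counts taken from simulated abundances (emit_fastq: false)")
    }
  } else {
    probs <- validate_inputs(config)
    if (attr(probs, "status") >= 2L) {
      stop("stage 'inputs' failed: ", probs$message[probs$severity == "error"][1L])
    }
    manifest <- read_manifest(config$paths$manifest)
    design <- read_design(config$paths$design)
    expression <- read_expression(config$paths$expression)
    index <- build_index(manifest, match_window(
      config$window$start, config$window$end,
      max_mismatches = config$window$max_mismatches))
    cols <- list()
    for (s in design$sample_id) {
      fq <- fastq_for_sample(config$paths$fastq_dir, s)
      cols[[s]] <- stage("count", count_sample(fq, index))
      logf("count ", s, ": ", cols[[s]]$tally$n_assigned, "/",
           cols[[s]]$tally$n_reads, " reads assigned")
    }
    counts <- build_count_matrix(cols, design, manifest)
  }
  write_count_matrix(counts, file.path(out_dir, "counts.tsv"),
                     file.path(out_dir, "tallies.tsv"))

  # ---- enrichment ----------------------------------------------------------
  comparisons <- comparisons_from_design(design)
  stats_list <- list()
  for (i in seq_len(nrow(comparisons))) {
    cmp <- comparisons[i, ]
    stats_list[[cmp$comparison_id]] <- stage("test", sgrna_test(
      counts, cmp, manifest,
      norm_method = config$normalization,
      pseudocount = config$test$pseudocount,
      fdr_threshold = config$test$fdr_threshold,
      null_method = config$test$null_method))
  }
  all_stats <- do.call(rbind, lapply(names(stats_list), function(id) {
    cbind(comparison_id = id, stats_list[[id]], stringsAsFactors = FALSE)
  }))
  utils::write.table(all_stats, file.path(out_dir, "sgrna_stats.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  logf("test: ", sum(all_stats$enriched), " enriched guide calls over ",
       nrow(comparisons), " comparisons")

  first_tissue <- comparisons$comparison_id[comparisons$label == "tissue_vs_library"][1L]
  gene_stats <- stage("aggregate", gene_aggregate(
    stats_list[[first_tissue]], manifest,
    alpha = config$aggregate$alpha,
    n_permutations = config$aggregate$n_permutations,
    seed = stage_seed(seed, "aggregate")))
  utils::write.table(gene_stats, file.path(out_dir, "gene_stats.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  sets <- enriched_sets(stats_list)
  jsonlite::write_json(sets, file.path(out_dir, "enriched_sets.json"))

  # ---- candidates ----------------------------------------------------------
  counts_map <- gene_guide_counts(sets, manifest)
  report <- stage("candidates", select_candidates(
    counts_map, comparisons, design, expression,
    min_guides = config$filter$min_guides,
    expression_ratio = config$filter$expression_ratio))
  utils::write.table(as.data.frame(report), file.path(out_dir, "candidates.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(as.data.frame(report), file.path(out_dir, "candidates.json"))
  summ <- enrichment_summary(counts_map)
  utils::write.table(summ$per_comparison, file.path(out_dir, "summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  logf("candidates: ", sum(report$final_candidate), " final candidate genes")

  # ---- provenance ----------------------------------------------------------
  snapshot <- config
  inputs <- list.files(out_dir, pattern = "\\.(csv|tsv)$", full.names = TRUE)
  snapshot$input_hashes <- as.list(tools::md5sum(inputs))
  yaml::write_yaml(snapshot, file.path(out_dir, "config_resolved.yaml"))
  invisible(report)
}

# truth written as plain TSV (gene fitness + guide efficiency/knockout)
saveRDS_free_truth <- function(truth, path, manifest) {
  df <- data.frame(
    sgrna_id = manifest$sgrna_id,
    gene = manifest$gene,
    gene_fitness = ifelse(manifest$is_control, 0,
                          truth$gene_fitness[manifest$gene]),
    sgrna_efficiency = truth$sgrna_efficiency[manifest$sgrna_id],
    knockout = if (!is.null(truth$knockout))
      truth$knockout[manifest$sgrna_id] else NA,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
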