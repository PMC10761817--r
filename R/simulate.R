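#' Simulate a pooled knockout screen through its sample hierarchy
#'
#' Generative chain mirroring a clone-assay + transplantation screen:
#' \enumerate{
#'   \item plasmid guide frequencies are drawn from a symmetric
#'     Dirichlet(`plasmid_dispersion`) — the uneven representation of a
#'     pooled plasmid library;
#'   \item the transduced cell library is a multinomial bottleneck of the
#'     plasmid pool (`bottleneck_cells` infected cells, default 100x
#'     coverage);
#'   \item each guide's lineage carries the knockout with probability equal
#'     to its efficiency (one Bernoulli draw per guide per screen); a
#'     functional knockout of gene g grows with per-passage log advantage
#'     `gene_fitness[g]`;
#'   \item selected samples (large clones, regenerated tissues) reweight the
#'     cell-library frequencies by `exp(fitness * passages)` and renormalize;
#'     small clones are neutral passages (no reweighting); the plasmid sample
#'     is sequenced from the plasmid pool itself;
#'   \item every sample is an independent multinomial draw of
#'     `depth_per_sample` reads.
#' }
#' Selection is deterministic exponential reweighting rather than a branching
#' birth–death process: the downstream pipeline consumes count ratios only,
#' and reweighting keeps the ground-truth expectation analytic
#' (a gene with fitness log(2), efficiency 1 and 3 passages has exactly an
#' 8-fold pre-normalisation frequency ratio between tissue and cell library).
#'
#' @param manifest library manifest.
#' @param truth `simulation_truth` object.
#' @param design `screen_design` table.
#' @param params list overriding any of `plasmid_dispersion` (Dirichlet
#'   concentration, default 5), `bottleneck_cells` (default 100x the library
#'   size), `passages` (default 3), `clone_threshold` (bookkeeping label for
#'   the small/large clone size cut, default 100), `depth_per_sample`
#'   (default 2e5 reads).
#' @param seed integer seed; the whole chain is deterministic given it.
#' @return list of class `screen_sim`: `counts` (guide x sample integer
#'   matrix), `design`, `truth` (echo, with the realized per-guide knockout
#'   indicator attached as `knockout`), `params`, `frequencies` (list of the
#'   latent per-sample frequency vectors).
#' @export
simulate_screen <- function(manifest, truth, design, params = list(), seed = 1L) {
  validate_manifest(manifest)
  validate_design(design)
  n_guides <- nrow(manifest)
  if (n_guides == 0L) stop("empty manifest")
  p <- utils::modifyList(list(
    plasmid_dispersion = 5,
    bottleneck_cells = 100L * n_guides,
    passages = 3,
    clone_threshold = 100,
    depth_per_sample = 2e5
  ), params)
  if (p$depth_per_sample <= 0) stop("depth_per_sample must be positive")

  fit_gene <- truth$gene_fitness[manifest$gene]
  fit_gene[is.na(fit_gene)] <- 0            # control pseudo-gene: neutral
  eff <- truth$sgrna_efficiency[manifest$sgrna_id]
  if (any(is.na(eff))) stop("truth lacks efficiencies for some manifest guides")

  with_seed(seed, {
    g <- rgamma(n_guides, shape = p$plasmid_dispersion, rate = 1)
    plasmid_freq <- g / sum(g)
    cells <- as.vector(rmultinom(1L, size = p$bottleneck_cells, prob = plasmid_freq))
    cell_freq <- cells / sum(cells)
    knockout <- runif(n_guides) < eff
    f_guide <- ifelse(knockout, fit_gene, 0)

    sel_w <- cell_freq * exp(f_guide * p$passages)
    sel_freq <- if (sum(sel_w) > 0) sel_w / sum(sel_w) else cell_freq

    freqs <- list(plasmid = plasmid_freq, cell_library = cell_freq,
                  small_clone = cell_freq, large_clone = sel_freq,
                  tissue = sel_freq)
    counts <- matrix(0L, nrow = n_guides, ncol = nrow(design),
                     dimnames = list(manifest$sgrna_id, design$sample_id))
    for (j in seq_len(nrow(design))) {
      fr <- freqs[[design$role[j]]]
      counts[, j] <- as.vector(rmultinom(1L, size = p$depth_per_sample, prob = fr))
    }
    structure(list(counts = counts, design = design,
                   truth = within_truth_knockout(truth, manifest$sgrna_id, knockout),
                   params = p, frequencies = freqs),
              class = "screen_sim")
  })
}

within_truth_knockout <- function(truth, ids, knockout) {
  truth$knockout <- stats::setNames(knockout, ids)
  truth
}

#' Read-emission configuration
#'
#' Describes how amplicon reads are synthesised around a guide. The guide
#' canonically starts at base 23 of the read (1-based) but drifts by up to
#' `jitter_range` bases in either direction — the positional shift the
#' quantifier must tolerate. The 5' flank defaults to the outer PCR primer
#' followed by U6-promoter-style vector context ending in the `ACCG` guide
#' cloning scar; the 3' flank is the invariant sgRNA scaffold.
#'
#' @param canonical_start 1-based read position where the guide starts when
#'   the jitter is 0.
#' @param jitter_range integer pair; per-read shift is uniform on
#'   `jitter_range[1]:jitter_range[2]` and clipped so the guide stays within
#'   the read.
#' @param substitution_rate independent per-base substitution probability.
#' @param indel_read_fraction fraction of reads receiving a single 1-base
#'   insertion or deletion inside the guide region.
#' @param junk_read_fraction fraction of reads replaced by random sequence
#'   (primer artefacts, contamination).
#' @param read_length read length in bases (>= 50).
#' @param flank_5p,flank_3p vector context placed before/after the guide.
#' @return list of class `read_emission_config`.
#' @export
read_emission_config <- function(canonical_start = 23L,
                                 jitter_range = c(-10L, 10L),
                                 substitution_rate = 0.002,
                                 indel_read_fraction = 0.005,
                                 junk_read_fraction = 0.05,
                                 read_length = 60L,
                                 flank_5p = paste0("GAAAGTAATAATTTCTTGGGTAGTTT",
                                                   "TCTTGTGGAAAGGACGAAACACCG"),
                                 flank_3p = paste0("GTTTTAGAGCTAGAAATAGCAAGTTAAAATAA",
                                                   "GGCTAGTCCGTTATCAACTTGAAAAAGTGGCACCGAGTCGGTGC")) {
  cfg <- list(canonical_start = as.integer(canonical_start),
              jitter_range = as.integer(jitter_range),
              substitution_rate = substitution_rate,
              indel_read_fraction = indel_read_fraction,
              junk_read_fraction = junk_read_fraction,
              read_length = as.integer(read_length),
              flank_5p = flank_5p, flank_3p = flank_3p)
  rates <- c(cfg$substitution_rate, cfg$indel_read_fraction, cfg$junk_read_fraction)
  if (any(rates < 0 | rates > 1)) stop("emission rates must lie in [0,1]")
  if (cfg$read_length < 50L) stop("read_length must be >= 50")
  if (cfg$canonical_start + 19L > cfg$read_length) {
    stop("canonical_start + 19 must not exceed read_length")
  }
  if (diff(cfg$jitter_range) < 0L) stop("jitter_range must be ordered")
  class(cfg) <- "read_emission_config"
  cfg
}

#' Emit FASTQ reads for one sample of a simulated screen
#'
#' Writes one read per count unit: a 5'-flank prefix trimmed so the guide
#' begins at `canonical_start + jitter`, the guide, then the 3' flank,
#' truncated to `read_length`. Per-base substitutions, a fraction of reads
#' with a 1-base indel inside the guide, and a fraction of junk reads are
#' applied on top. A truth sidecar table records, per read, the source
#' guide, jitter, substitution count, indel and junk flags — the oracle
#' against which quantification is scored. Quality strings are constant
#' high quality; the matching rules ignore quality.
#'
#' @param counts integer vector of per-guide read counts (one count-matrix
#'   column), aligned with `manifest`.
#' @param manifest library manifest.
#' @param config `read_emission_config`.
#' @param fastq_path output FASTQ path (`.gz` writes gzip).
#' @param sidecar_path optional path for the truth sidecar TSV.
#' @param seed integer seed; output is byte-deterministic given it.
#' @param read_prefix prefix for read ids.
#' @return invisibly, the sidecar `data.frame` (`read_id`, `sgrna_id`,
#'   `jitter`, `n_substitutions`, `has_indel`, `is_junk`).
#' @export
emit_reads <- function(counts, manifest, config = read_emission_config(),
                       fastq_path, sidecar_path = NULL, seed = 1L,
                       read_prefix = "read") {
  if (length(counts) != nrow(manifest)) {
    stop("counts must align with the manifest (one entry per guide)")
  }
  counts <- as.integer(counts)
  n <- sum(counts)
  L <- config$read_length
  gl <- 20L
  min_start <- 1L
  max_start <- L - gl + 1L
  lo <- config$canonical_start + config$jitter_range[1L]
  hi <- config$canonical_start + config$jitter_range[2L]
  if (hi < min_start || lo > max_start) {
    stop("jitter range would push the guide outside the read")
  }

  with_seed(seed, {
    guide_idx <- rep.int(seq_along(counts), counts)
    guide_idx <- guide_idx[sample.int(n)]          # interleave guides
    jitter <- sample(seq.int(config$jitter_range[1L], config$jitter_range[2L]),
                     n, replace = TRUE)
    start <- pmin(pmax(config$canonical_start + jitter, min_start), max_start)
    jitter <- start - config$canonical_start       # record post-clip shift

    L5 <- nchar(config$flank_5p)
    if (L5 < max(start) - 1L) {
      stop("flank_5p shorter than the largest required prefix (",
           max(start) - 1L, " nt)")
    }
    prefix <- substring(config$flank_5p, L5 - (start - 1L) + 1L, L5)
    body <- paste0(prefix, manifest$sequence[guide_idx], config$flank_3p)
    reads <- substr(body, 1L, L)

    # independent per-base substitutions
    nsub <- rbinom(n, L, config$substitution_rate)
    for (i in which(nsub > 0L)) {
      pos <- sample.int(L, nsub[i])
      ch <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
      ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(DNA_BASES, b), 1L), "")
      reads[i] <- paste(ch, collapse = "")
    }

    # 1-base insertion or deletion inside the guide region
    has_indel <- runif(n) < config$indel_read_fraction
    for (i in which(has_indel)) {
      pos <- start[i] + sample.int(gl, 1L) - 1L
      if (runif(1L) < 0.5) {                        # deletion, refill from flank
        reads[i] <- substr(paste0(substr(reads[i], 1L, pos - 1L),
                                  substr(reads[i], pos + 1L, L),
                                  config$flank_3p), 1L, L)
      } else {                                      # insertion, truncate
        reads[i] <- substr(paste0(substr(reads[i], 1L, pos - 1L),
                                  sample(DNA_BASES, 1L),
                                  substr(reads[i], pos, L)), 1L, L)
      }
    }

    is_junk <- runif(n) < config$junk_read_fraction
    if (any(is_junk)) reads[is_junk] <- random_dna(sum(is_junk), L)

    read_id <- sprintf("%s_%07d", read_prefix, seq_len(max(n, 1L))[seq_len(n)])
    sidecar <- data.frame(
      read_id = read_id,
      sgrna_id = ifelse(is_junk, NA_character_, manifest$sgrna_id[guide_idx]),
      jitter = ifelse(is_junk, NA_integer_, jitter),
      n_substitutions = ifelse(is_junk, NA_integer_, nsub),
      has_indel = ifelse(is_junk, NA, has_indel),
      is_junk = is_junk,
      stringsAsFactors = FALSE
    )

    con <- if (grepl("\\.gz$", fastq_path)) gzfile(fastq_path, "w") else file(fastq_path, "w")
    on.exit(close(con))
    qual <- strrep("I", L)
    if (n > 0L) {
      writeLines(as.vector(rbind(paste0("@", read_id), reads, "+", qual)), con)
    }
    if (!is.null(sidecar_path)) {
      utils::write.table(sidecar, sidecar_path, sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
    invisible(sidecar)
  })
}
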