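#' Legal matching window for guide placement in a read
#'
#' A guide is accepted only if its 20-mer aligns, unpaired and ungapped,
#' entirely within read positions `window_start`..`window_end` (1-based,
#' inclusive; defaults 15-50), i.e. legal guide start positions are
#' `window_start` .. `window_end - guide_length + 1` (defaults 15..31), with
#' at most `max_mismatches` substitutions and no indels. The canonical guide
#' start is 23 and the observed drift reaches +/-10, so the window is the
#' operative acceptance rule: a guide starting at 13, 14, 32 or 33 is
#' rejected even though such shifts occur.
#'
#' @param window_start,window_end 1-based inclusive window bounds.
#' @param guide_length guide width (20 for GeCKO-style libraries).
#' @param max_mismatches 0 or 1 tolerated substitutions.
#' @return list of class `match_window` (adds `start_min`/`start_max`).
#' @export
match_window <- function(window_start = 15L, window_end = 50L,
                         guide_length = 20L, max_mismatches = 1L) {
  w <- list(window_start = as.integer(window_start),
            window_end = as.integer(window_end),
            guide_length = as.integer(guide_length),
            max_mismatches = as.integer(max_mismatches))
  if (w$window_end - w$window_start + 1L < w$guide_length) {
    stop("window shorter than the guide")
  }
  if (!w$max_mismatches %in% c(0L, 1L)) stop("max_mismatches must be 0 or 1")
  w$start_min <- w$window_start
  w$start_max <- w$window_end - w$guide_length + 1L
  class(w) <- "match_window"
  w
}

#' Build a shift-tolerant matching index over a library
#'
#' Exact lookups use the full 20-mer; one-mismatch lookups use the
#' pigeonhole split of each guide into two 10-mer halves (a single
#' substitution leaves at least one half intact), each half verified against
#' the full guide. Lookup results are exactly those of a brute-force Hamming
#' scan over every guide. Duplicate sequences are indexed with all their
#' owners; reads matching them resolve downstream as ambiguous.
#'
#' @param manifest library manifest.
#' @param window `match_window`.
#' @return object of class `sgrna_index`.
#' @export
build_index <- function(manifest, window = match_window()) {
  validate_manifest_for_index(manifest)
  gl <- window$guide_length
  half <- gl %/% 2L
  seqs <- manifest$sequence
  idx <- list(
    manifest = manifest,
    window = window,
    seqs = seqs,
    half = half,
    left_dt = data.table::data.table(half_seq = substr(seqs, 1L, half),
                                     guide = seq_along(seqs), key = "half_seq"),
    right_dt = data.table::data.table(half_seq = substr(seqs, half + 1L, gl),
                                      guide = seq_along(seqs), key = "half_seq")
  )
  class(idx) <- "sgrna_index"
  idx
}

validate_manifest_for_index <- function(manifest) {
  if (nrow(manifest) == 0L) stop("cannot index an empty manifest")
  if (any(nchar(manifest$sequence) != 20L)) stop("guide sequences must be 20 nt")
  invisible(manifest)
}

#' Assign reads to library guides under the shift/mismatch rules
#'
#' Every legal start position of every read is evaluated; a candidate is a
#' (guide, start, mismatches) triple with mismatches at or below the window's
#' cap, under ungapped comparison (indels are never considered — a read whose
#' guide carries an indel has no in-window match and falls out as
#' unassigned). Exact (0-mismatch) candidates strictly dominate 1-mismatch
#' candidates; among the surviving best-level candidates, a single named
#' guide yields `assigned` (earliest start recorded), two or more distinct
#' guides yield `ambiguous`, none yields `unassigned`. Each read therefore
#' increments at most one guide.
#'
#' @param reads character vector of read sequences.
#' @param index `sgrna_index`.
#' @param read_ids optional read identifiers.
#' @return data.frame with one row per read: `read_id`, `status`
#'   (`assigned`/`ambiguous`/`unassigned`), `sgrna_id`, `start`,
#'   `n_mismatches` (the latter three NA unless assigned).
#' @export
assign_reads <- function(reads, index, read_ids = NULL) {
  window <- index$window
  gl <- window$guide_length
  half <- index$half
  n <- length(reads)
  if (is.null(read_ids)) read_ids <- sprintf("read_%d", seq_len(n))
  out <- data.frame(read_id = read_ids,
                    status = rep("unassigned", n),
                    sgrna_id = rep(NA_character_, n),
                    start = rep(NA_integer_, n),
                    n_mismatches = rep(NA_integer_, n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  len <- nchar(reads)
  starts <- seq.int(window$start_min, window$start_max)
  pieces <- vector("list", length(starts))
  for (si in seq_along(starts)) {
    s <- starts[si]
    ok <- which(len >= s + gl - 1L)
    if (!length(ok)) next
    kmer <- substr(reads[ok], s, s + gl - 1L)
    q <- data.table::data.table(half_seq = substr(kmer, 1L, half),
                                read = ok, kpos = seq_along(ok))
    hitL <- index$left_dt[q, on = "half_seq", nomatch = NULL, allow.cartesian = TRUE]
    q[, half_seq := substr(kmer, half + 1L, gl)]
    hitR <- index$right_dt[q, on = "half_seq", nomatch = NULL, allow.cartesian = TRUE]
    pairs <- unique(rbind(hitL[, list(read, kpos, guide)],
                          hitR[, list(read, kpos, guide)]))
    if (!nrow(pairs)) next
    mm <- hamming_vec(kmer[pairs$kpos], index$seqs[pairs$guide], width = gl)
    keep <- mm <= window$max_mismatches
    if (!any(keep)) next
    pieces[[si]] <- data.table::data.table(read = pairs$read[keep],
                                           guide = pairs$guide[keep],
                                           start = s, mm = mm[keep])
  }
  cand <- data.table::rbindlist(pieces)
  if (!nrow(cand)) return(out)
  data.table::setorder(cand, read, mm, start)
  cand[, minmm := min(mm), by = read]
  best <- cand[mm == minmm]
  ngu <- best[, list(k = data.table::uniqueN(guide)), by = read]
  first <- best[!duplicated(read)]
  stopifnot(identical(first$read, ngu$read))
  assigned <- ngu$k == 1L
  rows <- first$read
  out$status[rows] <- ifelse(assigned, "assigned", "ambiguous")
  out$sgrna_id[rows[assigned]] <- index$manifest$sgrna_id[first$guide[assigned]]
  out$start[rows[assigned]] <- first$start[assigned]
  out$n_mismatches[rows[assigned]] <- first$mm[assigned]
  out
}

#' @rdname assign_reads
#' @param read single read sequence.
#' @export
assign_read <- function(read, index) {
  if (is.na(read) || !nzchar(read)) {
    return(data.frame(read_id = "read_1", status = "unassigned",
                      sgrna_id = NA_character_, start = NA_integer_,
                      n_mismatches = NA_integer_, stringsAsFactors = FALSE))
  }
  assign_reads(read, index)
}

# Minimal 4-line FASTQ reader (gz transparent through readLines).
# Errors name the malformed record's index, which downstream contracts need.
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) {
    return(data.frame(read_id = character(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  }
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ '", path, "': truncated record ",
         length(lines) %/% 4L + 1L)
  }
  ix <- seq(1L, length(lines), by = 4L)
  headers <- lines[ix]
  plus <- lines[ix + 2L]
  bad <- which(!startsWith(headers, "@") | !startsWith(plus, "+"))
  if (length(bad)) {
    stop("malformed FASTQ '", path, "': record ", bad[1L],
         " lacks '@' header or '+' separator")
  }
  seqs <- lines[ix + 1L]
  if (any(nchar(lines[ix + 3L]) != nchar(seqs))) {
    bad <- which(nchar(lines[ix + 3L]) != nchar(seqs))[1L]
    stop("malformed FASTQ '", path, "': record ", bad,
         " quality length differs from sequence length")
  }
  data.frame(read_id = sub("\\s.*$", "", sub("^@", "", headers)),
             sequence = seqs, stringsAsFactors = FALSE)
}

#' Count one sample's FASTQ against the library
#'
#' Applies [assign_reads()] to every record and tallies assigned reads per
#' guide; each read contributes to at most one guide, so the column sum
#' equals the assigned-read tally and
#' `n_assigned + n_ambiguous + n_unassigned = n_reads`.
#'
#' @param fastq_path FASTQ (optionally gzipped) path.
#' @param index `sgrna_index`.
#' @return list: `counts` (named integer vector in manifest order), `tally`
#'   (one-row data.frame: `n_reads`, `n_assigned`, `n_ambiguous`,
#'   `n_unassigned`), `assignments` (per-read table).
#' @export
count_sample <- function(fastq_path, index) {
  fq <- read_fastq(fastq_path)
  asg <- assign_reads(fq$sequence, index, read_ids = fq$read_id)
  hit <- asg$sgrna_id[asg$status == "assigned"]
  counts <- tabulate(match(hit, index$manifest$sgrna_id),
                     nbins = nrow(index$manifest))
  names(counts) <- index$manifest$sgrna_id
  tally <- data.frame(n_reads = nrow(asg),
                      n_assigned = sum(asg$status == "assigned"),
                      n_ambiguous = sum(asg$status == "ambiguous"),
                      n_unassigned = sum(asg$status == "unassigned"))
  stopifnot(sum(counts) == tally$n_assigned,
            tally$n_assigned + tally$n_ambiguous + tally$n_unassigned == tally$n_reads)
  list(counts = counts, tally = tally, assignments = asg)
}

#' Assemble per-sample columns into a count matrix
#'
#' @param columns named list mapping sample_id to the result of
#'   [count_sample()] (or to a bare named count vector, in which case the
#'   tallies are derived from the column sums).
#' @param design `screen_design`; every design sample must be present.
#' @param manifest library manifest fixing the guide order.
#' @return object of class `sgrna_counts`: `counts` matrix, `stats`
#'   per-sample tally table, `design`.
#' @export
build_count_matrix <- function(columns, design, manifest) {
  validate_design(design)
  missing <- setdiff(design$sample_id, names(columns))
  if (length(missing)) {
    stop("no counts for design samples: ", paste(missing, collapse = ", "))
  }
  counts <- matrix(0L, nrow = nrow(manifest), ncol = nrow(design),
                   dimnames = list(manifest$sgrna_id, design$sample_id))
  stats <- data.frame(sample_id = design$sample_id, n_reads = 0L,
                      n_assigned = 0L, n_ambiguous = 0L, n_unassigned = 0L,
                      stringsAsFactors = FALSE)
  for (j in seq_len(nrow(design))) {
    col <- columns[[design$sample_id[j]]]
    if (is.list(col) && !is.null(col$counts)) {
      v <- col$counts
      tl <- col$tally
    } else {
      v <- col
      tl <- data.frame(n_reads = sum(v), n_assigned = sum(v),
                       n_ambiguous = 0L, n_unassigned = 0L)
    }
    if (length(v) != nrow(manifest)) {
      stop("column '", design$sample_id[j], "' does not align with the manifest")
    }
    if (!is.null(names(v)) && !identical(names(v), manifest$sgrna_id)) {
      v <- v[manifest$sgrna_id]
    }
    counts[, j] <- as.integer(v)
    stats[j, c("n_reads", "n_assigned", "n_ambiguous", "n_unassigned")] <-
      tl[1L, c("n_reads", "n_assigned", "n_ambiguous", "n_unassigned")]
  }
  structure(list(counts = counts, stats = stats, design = design),
            class = "sgrna_counts")
}

#' @export
print.sgrna_counts <- function(x, ...) {
  cat("sgRNA count matrix: ", nrow(x$counts), " guides x ",
      ncol(x$counts), " samples\n", sep = "")
  print(x$stats)
  invisible(x)
}

#' Write / read an sgRNA count matrix (TSV + tally TSV)
#'
#' The matrix TSV has `sgrna_id` first, then one column per sample; the
#' per-sample tallies go to `paste0(path, ".tally")` unless given.
#' The pair round-trips losslessly through [read_count_matrix()].
#' @param x `sgrna_counts` object.
#' @param path output TSV path.
#' @param tally_path tally TSV path.
#' @export
write_count_matrix <- function(x, path, tally_path = paste0(path, ".tally")) {
  df <- data.frame(sgrna_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  tl <- merge(x$stats, x$design, by = "sample_id", sort = FALSE)
  utils::write.table(tl, tally_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path, tally_path = paste0(path, ".tally")) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$sgrna_id
  tl <- utils::read.delim(tally_path, stringsAsFactors = FALSE)
  design <- tl[, c("sample_id", "role", "excluded")]
  design$excluded <- as.logical(design$excluded)
  class(design) <- c("screen_design", "data.frame")
  structure(list(counts = counts,
                 stats = tl[, c("sample_id", "n_reads", "n_assigned",
                                "n_ambiguous", "n_unassigned")],
                 design = design),
            class = "sgrna_counts")
}
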