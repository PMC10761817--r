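# Independent brute-force matcher: every guide x every legal offset,
# Hamming distance by integer comparison over a padded read matrix.
# Deliberately shares no code with the package's pigeonhole index.
oracle_assign <- function(reads, manifest, window_start = 15L, window_end = 50L,
                          max_mm = 1L) {
  gl <- 20L
  starts <- window_start:(window_end - gl + 1L)
  n <- length(reads)
  maxlen <- max(nchar(reads), window_end, 1L)
  M <- matrix(0L, n, maxlen)
  for (i in seq_len(n)) {
    v <- utf8ToInt(reads[i])
    if (length(v)) M[i, seq_along(v)] <- v
  }
  G <- t(vapply(manifest$sequence, utf8ToInt, integer(gl), USE.NAMES = FALSE))
  bm <- rep(Inf, n)
  bguide <- integer(n)
  bstart <- integer(n)
  multi <- logical(n)
  lens <- nchar(reads)
  for (s in starts) {
    if (s + gl - 1L > maxlen) break
    fits <- lens >= s + gl - 1L   # the whole guide must lie inside the read
    tW <- t(M[, s:(s + gl - 1L), drop = FALSE])
    for (g in seq_len(nrow(G))) {
      mm <- colSums(tW != G[g, ])
      mm[!fits] <- gl
      better <- mm <= max_mm & mm < bm
      tie <- mm <= max_mm & mm == bm & bguide != g
      if (any(better)) {
        bm[better] <- mm[better]
        bguide[better] <- g
        bstart[better] <- s
        multi[better] <- FALSE
      }
      if (any(tie)) multi[tie] <- TRUE
    }
  }
  status <- ifelse(is.infinite(bm), "unassigned",
                   ifelse(multi, "ambiguous", "assigned"))
  data.frame(
    status = status,
    sgrna_id = ifelse(status == "assigned", manifest$sgrna_id[pmax(bguide, 1L)],
                      NA_character_),
    start = ifelse(status == "assigned", bstart, NA_integer_),
    n_mismatches = ifelse(status == "assigned", bm, NA_integer_),
    stringsAsFactors = FALSE
  )
}

FLANK5 <- "GAAAGTAATAATTTCTTGGGTAGTTTTCTTGTGGAAAGGACGAAACACCG"
FLANK3 <- "GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCGTTATCAACTTGAAAAAGTGGCACCGAGTCGGTGC"

# place a guide at a 1-based start inside a read of the given length
mk_read <- function(guide, start, len = 60L, flank5 = FLANK5, flank3 = FLANK3) {
  need <- start - 1L
  prefix <- if (need == 0L) "" else {
    pad <- if (need > nchar(flank5)) strrep("A", need - nchar(flank5)) else ""
    paste0(pad, substring(flank5, max(1L, nchar(flank5) - need + 1L), nchar(flank5)))
  }
  substr(paste0(prefix, guide, flank3, strrep("A", len)), 1L, len)
}

mutate_base <- function(seq, pos, shift = 1L) {
  bases <- c("A", "C", "G", "T")
  old <- substr(seq, pos, pos)
  new <- bases[(match(old, bases) + shift - 1L) %% 4L + 1L]
  substr(seq, pos, pos) <- new
  seq
}

rand_seq <- function(n, len) {
  vapply(seq_len(n),
         function(i) paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""),
         "")
}

# library with planted near-duplicate guide pairs (Hamming 1 and Hamming 2);
# the generated backbone itself guarantees pairwise Hamming >= 3
near_dup_manifest <- function(seed = 7L) {
  m <- generate_library(40, 3, 12, seed = seed)
  set.seed(seed + 1000L)
  dupA1 <- rand_seq(1, 20)
  dupA2 <- mutate_base(mutate_base(dupA1, 5L), 12L)   # Hamming 2 pair
  dupB1 <- rand_seq(1, 20)
  dupB2 <- mutate_base(dupB1, 7L)                     # Hamming 1 pair
  extra <- data.frame(
    sgrna_id = c("dupA_sg1", "dupA_sg2", "dupB_sg1", "dupB_sg2"),
    gene = c("dupA", "dupA", "dupB", "dupB"),
    sequence = c(dupA1, dupA2, dupB1, dupB2),
    is_control = FALSE, stringsAsFactors = FALSE
  )
  out <- rbind(as.data.frame(m), extra)
  class(out) <- c("sgrna_manifest", "data.frame")
  out
}

# adversarial read set spanning jitter -12..12, 0-2 substitutions, indels,
# junk, short reads and near-duplicate probes; returns reads only (the
# oracle defines the expected assignments)
adversarial_reads <- function(manifest, n, seed = 1L) {
  set.seed(seed)
  reads <- character(n)
  ng <- nrow(manifest)
  kind <- sample(c("plain", "subs", "indel", "junk", "short", "dup"), n,
                 replace = TRUE, prob = c(0.35, 0.3, 0.1, 0.1, 0.1, 0.05))
  dupA_mid <- mutate_base(manifest$sequence[manifest$sgrna_id == "dupA_sg1"], 5L)
  dupB_exact <- manifest$sequence[manifest$sgrna_id == "dupB_sg1"]
  for (i in seq_len(n)) {
    g <- manifest$sequence[sample.int(ng, 1L)]
    start <- max(1L, min(41L, 23L + sample(-12:12, 1L)))
    r <- switch(kind[i],
      plain = mk_read(g, start),
      subs = {
        r0 <- mk_read(g, start)
        for (p in sample.int(60L, sample(1:2, 1L))) r0 <- mutate_base(r0, p, sample(1:3, 1L))
        r0
      },
      indel = {
        p <- start + sample.int(20L, 1L) - 1L
        r0 <- mk_read(g, start)
        if (runif(1) < 0.5) {
          substr(paste0(substr(r0, 1, p - 1), substr(r0, p + 1, 60), "A"), 1, 60)
        } else {
          substr(paste0(substr(r0, 1, p - 1), sample(c("A","C","G","T"), 1),
                        substr(r0, p, 60)), 1, 60)
        }
      },
      junk = rand_seq(1, 60L),
      short = substr(mk_read(g, min(start, 25L)), 1L, sample(15:45, 1L)),
      dup = mk_read(if (runif(1) < 0.5) dupA_mid else dupB_exact,
                    sample(13:33, 1L))
    )
    reads[i] <- r
  }
  reads
}

# elementwise equality treating NA==NA as TRUE
identical_na <- function(a, b) (is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b)
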