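test_that("canonical and shifted placements assign with the right coordinates", {
  m <- generate_library(25, 3, 10, seed = 21)
  idx <- build_index(m)
  g <- m$sequence[7]

  a <- assign_read(mk_read(g, 23), idx)
  expect_equal(a$status, "assigned")
  expect_equal(a$sgrna_id, m$sgrna_id[7])
  expect_equal(a$start, 23)
  expect_equal(a$n_mismatches, 0)

  a <- assign_read(mutate_base(mk_read(g, 31), 31 + 4), idx)
  expect_equal(a$status, "assigned")
  expect_equal(a$start, 31)
  expect_equal(a$n_mismatches, 1)
})

test_that("window boundaries are exact: starts 15 and 31 in, 14 and 32 out", {
  m <- generate_library(25, 3, 10, seed = 21)
  idx <- build_index(m)
  g <- m$sequence[3]
  for (s in c(15, 31)) {
    expect_equal(assign_read(mk_read(g, s), idx)$status, "assigned", info = s)
    expect_equal(assign_read(mk_read(g, s), idx)$start, s)
  }
  for (s in c(13, 14, 32, 33)) {
    expect_equal(assign_read(mk_read(g, s), idx)$status, "unassigned", info = s)
  }
})

test_that("mismatch boundary: one substitution assigned, two not; indels never", {
  m <- generate_library(25, 3, 10, seed = 21)
  idx <- build_index(m)
  g <- m$sequence[10]
  r1 <- mutate_base(mk_read(g, 23), 23 + 2)
  expect_equal(assign_read(r1, idx)$n_mismatches, 1)
  r2 <- mutate_base(r1, 23 + 11)
  expect_equal(assign_read(r2, idx)$status, "unassigned")

  # 1-base deletion inside the guide
  r0 <- mk_read(g, 23)
  rdel <- substr(paste0(substr(r0, 1, 27), substr(r0, 29, 60), "A"), 1, 60)
  expect_equal(assign_read(rdel, idx)$status, "unassigned")
  # 1-base insertion inside the guide
  rins <- substr(paste0(substr(r0, 1, 29), "A", substr(r0, 30, 60)), 1, 60)
  expect_equal(assign_read(rins, idx)$status, "unassigned")

  # zero-tolerance window rejects single substitutions
  idx0 <- build_index(m, match_window(max_mismatches = 0))
  expect_equal(assign_read(r1, idx0)$status, "unassigned")
  expect_equal(assign_read(mk_read(g, 23), idx0)$status, "assigned")
})

test_that("near-duplicate guides resolve by maximum identity, then ambiguity", {
  m <- near_dup_manifest(seed = 7)
  idx <- build_index(m)
  dupA1 <- m$sequence[m$sgrna_id == "dupA_sg1"]
  dupB1 <- m$sequence[m$sgrna_id == "dupB_sg1"]

  # read halfway between the Hamming-2 pair: 1 mismatch to each -> ambiguous
  a <- assign_read(mk_read(mutate_base(dupA1, 5), 23), idx)
  expect_equal(a$status, "ambiguous")
  expect_true(is.na(a$sgrna_id))

  # exact match to one of a Hamming-1 pair: the exact hit dominates
  a <- assign_read(mk_read(dupB1, 23), idx)
  expect_equal(a$status, "assigned")
  expect_equal(a$sgrna_id, "dupB_sg1")
  expect_equal(a$n_mismatches, 0)

  # identical duplicated sequences always collide
  dup <- as.data.frame(m)
  dup$sequence[dup$sgrna_id == "dupB_sg2"] <- dupB1
  class(dup) <- class(m)
  idx2 <- build_index(dup)
  expect_equal(assign_read(mk_read(dupB1, 23), idx2)$status, "ambiguous")
})

test_that("empty and short reads fall out as unassigned", {
  m <- generate_library(10, 2, 4, seed = 2)
  idx <- build_index(m)
  expect_equal(assign_read("", idx)$status, "unassigned")
  g <- m$sequence[1]
  # window shrinks with the read: a start-15 guide in a 34-base read fits
  expect_equal(assign_read(substr(mk_read(g, 15), 1, 34), idx)$status, "assigned")
  # a start-25 guide truncated mid-guide does not
  expect_equal(assign_read(substr(mk_read(g, 25), 1, 40), idx)$status, "unassigned")
})

test_that("assignment equals the brute-force oracle on adversarial reads", {
  m <- near_dup_manifest(seed = 7)
  idx <- build_index(m)
  reads <- adversarial_reads(m, 2000, seed = 99)
  mine <- assign_reads(reads, idx)
  oracle <- oracle_assign(reads, m)
  expect_identical(mine$status, oracle$status)
  expect_identical(mine$sgrna_id, oracle$sgrna_id)
  expect_identical(mine$start, oracle$start)
  expect_identical(as.integer(mine$n_mismatches), as.integer(oracle$n_mismatches))
})

test_that("count_sample matches the emission sidecar and conserves reads", {
  m <- generate_library(20, 3, 8, seed = 13)
  idx <- build_index(m)
  counts <- rep(15L, nrow(m))

  # error-free reads with jitter inside the window: every read assigned and
  # the column equals the sidecar histogram exactly
  cfg <- read_emission_config(jitter_range = c(-8, 8), substitution_rate = 0,
                              indel_read_fraction = 0, junk_read_fraction = 0)
  fq <- withr::local_tempfile(fileext = ".fastq")
  side <- emit_reads(counts, m, cfg, fq, seed = 5)
  cs <- count_sample(fq, idx)
  expect_equal(cs$tally$n_assigned, cs$tally$n_reads)
  expect_equal(unname(cs$counts), unname(table(factor(side$sgrna_id, m$sgrna_id)))[seq_len(nrow(m))],
               ignore_attr = TRUE)

  # junk reads fall out as unassigned, in the sidecar's exact number
  cfg2 <- read_emission_config(jitter_range = c(0, 0), substitution_rate = 0,
                               indel_read_fraction = 0, junk_read_fraction = 0.1)
  fq2 <- withr::local_tempfile(fileext = ".fastq")
  side2 <- emit_reads(counts, m, cfg2, fq2, seed = 6)
  cs2 <- count_sample(fq2, idx)
  expect_equal(cs2$tally$n_unassigned, sum(side2$is_junk))
  expect_equal(cs2$tally$n_assigned + cs2$tally$n_ambiguous + cs2$tally$n_unassigned,
               cs2$tally$n_reads)
})

test_that("empty and malformed FASTQ inputs are handled per contract", {
  m <- generate_library(5, 2, 2, seed = 1)
  idx <- build_index(m)
  fq <- withr::local_tempfile(fileext = ".fastq")
  writeLines(character(0), fq)
  cs <- count_sample(fq, idx)
  expect_equal(cs$tally$n_reads, 0)
  expect_true(all(cs$counts == 0))

  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), fq)
  expect_error(count_sample(fq, idx), "record 2")
  writeLines(c("r1", "ACGT", "+", "IIII"), fq)
  expect_error(count_sample(fq, idx), "record 1")
})

test_that("count matrices assemble, satisfy tallies, and round-trip", {
  m <- generate_library(12, 2, 6, seed = 4)
  d <- screen_design(1, 1, 1)
  idx <- build_index(m)
  cfg <- read_emission_config(jitter_range = c(-5, 5))
  cols <- list()
  for (s in d$sample_id) {
    fq <- withr::local_tempfile(fileext = ".fastq")
    emit_reads(rep(8L, nrow(m)), m, cfg, fq, seed = match(s, d$sample_id))
    cols[[s]] <- count_sample(fq, idx)
  }
  cm <- build_count_matrix(cols, d, m)
  expect_equal(unname(colSums(cm$counts)), cm$stats$n_assigned)
  expect_equal(cm$stats$n_assigned + cm$stats$n_ambiguous + cm$stats$n_unassigned,
               cm$stats$n_reads)

  # identical input columns give identical matrix columns
  cols2 <- cols; cols2[["cell_library"]] <- cols[["plasmid"]]
  cm2 <- build_count_matrix(cols2, d, m)
  expect_identical(cm2$counts[, "plasmid"], unname(cm2$counts[, "cell_library"]) |>
                     stats::setNames(rownames(cm2$counts)))

  f <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(cm, f)
  cm3 <- read_count_matrix(f)
  expect_identical(cm$counts, cm3$counts)
  expect_equal(cm$stats, cm3$stats)

  expect_error(build_count_matrix(cols[1:2], d, m), "no counts for design samples")
})
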