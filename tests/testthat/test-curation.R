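test_that("the internal aligner handles identical sequences and clean indels", {
  s <- rand_dna(300, seed = 1)
  m <- align_set(c(a = s, b = s, c = s))
  expect_equal(ncol(m), 300)
  expect_false(any(m == "-"))
  expect_identical(attr(m, "backend"), "internal")

  ## a 3-bp deletion yields exactly one 3-column gap run
  del <- paste0(substring(s, 1, 150), substring(s, 154, 300))
  m2 <- align_set(c(a = s, b = del))
  expect_equal(ncol(m2), 300)
  gaps <- which(m2["b", ] == "-")
  expect_length(gaps, 3)
  expect_equal(diff(gaps), c(1, 1))
  expect_false(any(m2["a", ] == "-"))
})

test_that("internal and external aligners agree on low-divergence sets", {
  ## mafft is part of the pipeline's standard toolchain; downstream
  ## matrices from the two backends should differ in few columns
  set.seed(12)
  diffs <- vapply(1:10, function(i) {
    root <- rand_dna(450)
    seqs <- c(a = mutate_seq(root, 0.05), b = mutate_seq(root, 0.05),
              c = mutate_seq(root, 0.05), d = mutate_seq(root, 0.05))
    mi <- align_set(seqs, backend = "internal")
    mm <- align_set(seqs, backend = "mafft")
    if (ncol(mi) != ncol(mm)) return(1)
    mean(mi[rownames(mm), ] != mm)
  }, numeric(1))
  expect_lt(mean(diffs), 0.05)
})

test_that("missing-species filter applies the boundary and re-check rules", {
  expected <- sprintf("t%02d", 1:29)
  m27 <- aln_matrix(setNames(replicate(27, rand_dna(100)), expected[1:27]))
  expect_true(filter_missing_species(m27, expected))
  m26 <- m27[1:26, ]
  expect_false(filter_missing_species(m26, expected))
  ## removing a flagged taxon from a 27-present alignment fails the re-check
  expect_false(filter_missing_species(m27[-1, ], expected))
  ## an all-gap row does not count as present
  m_gap <- m27
  m_gap[1, ] <- "-"
  expect_false(filter_missing_species(m_gap, expected))
})

test_that("end trimming follows the trigger/stop fractions and leaves interiors alone", {
  base <- aln_matrix(setNames(replicate(10, rand_dna(60)), letters[1:10]))
  expect_equal(ncol(trim_ends(base)), 60)

  ## 30 leading columns missing in 6/10 taxa are removed entirely
  m <- base
  m[1:6, 1:30] <- "-"
  tm <- trim_ends(m)
  expect_equal(attr(tm, "trimmed"), c(left = 30L, right = 0L))
  expect_equal(ncol(tm), 30)

  ## fractions 0.6, 0.45, 0.2 at the left flank: exactly one column trimmed
  m2 <- aln_matrix(setNames(replicate(20, rand_dna(40)), letters[1:20]))
  m2[1:12, 1] <- "-"   # 0.60 >= stop
  m2[1:9, 2] <- "-"    # 0.45 < stop, > trigger
  m2[1:4, 3] <- "-"    # 0.20
  tm2 <- trim_ends(m2)
  expect_equal(attr(tm2, "trimmed"), c(left = 1L, right = 0L))

  ## terminal fraction below the trigger never starts trimming
  m3 <- base
  m3[1:3, 1] <- "-"    # 0.30 < 1/3
  expect_equal(ncol(trim_ends(m3)), 60)
})

test_that("length filter enforces the 450/150 boundaries exactly", {
  mk <- function(len, short_ungapped) {
    m <- aln_matrix(setNames(replicate(5, rand_dna(len)), letters[1:5]))
    if (short_ungapped < len) m[1, (short_ungapped + 1):len] <- "-"
    m
  }
  expect_true(filter_length(mk(450, 150)))
  expect_false(filter_length(mk(449, 149)))
  expect_false(filter_length(mk(449, 449)))
  expect_false(filter_length(mk(1605, 149)))
  expect_true(filter_length(mk(1605, 150)))
})

test_that("divergence flagging spots planted paralogs and rarely fires on clean sets", {
  ## exactly equal pairwise distances (disjoint mutated blocks): no flags
  s <- rand_dna(400, seed = 3)
  flip <- function(x, pos) {
    v <- strsplit(x, "")[[1]]
    v[pos] <- chartr("ACGT", "GTAC", v[pos])
    paste(v, collapse = "")
  }
  m_eq <- aln_matrix(c(a = flip(s, 1:4), b = flip(s, 5:8),
                       c = flip(s, 9:12), d = flip(s, 13:16),
                       e = flip(s, 17:20)))
  rep_eq <- flag_divergent_taxa(m_eq, 3.5)
  expect_length(rep_eq$flagged, 0)
  expect_true(isSymmetric(rep_eq$distances))
  expect_true(all(diag(rep_eq$distances) == 0))

  ## planted intruder at ~3x the ortholog divergence among 10 taxa
  set.seed(44)
  hits <- vapply(1:25, function(i) {
    root <- rand_dna(400)
    seqs <- setNames(lapply(1:9, function(j) mutate_seq(root, 0.03)),
                     paste0("t", 1:9))
    seqs$intruder <- mutate_seq(root, 0.20)
    "intruder" %in% flag_divergent_taxa(aln_matrix(unlist(seqs)),
                                        3.5)$flagged
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  ## null false-flag rate on clean ortholog sets stays low
  set.seed(45)
  false_flags <- vapply(1:100, function(i) {
    root <- rand_dna(300)
    seqs <- setNames(vapply(1:8, function(j) mutate_seq(root, 0.04),
                            character(1)), paste0("t", 1:8))
    length(flag_divergent_taxa(aln_matrix(seqs), 3.5)$flagged) > 0
  }, logical(1))
  expect_lte(mean(false_flags), 0.05)

  ## disabled below five taxa
  expect_length(flag_divergent_taxa(m_eq[1:4, ], 3.5)$flagged, 0)
})

test_that("long-branch flagging uses the terminal-branch ratio rule", {
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1,e:1);")
  expect_length(flag_long_branch_taxa(star, 5), 0)

  long <- ape::read.tree(text = "(a:1,b:1,c:1,d:1,e:10);")
  expect_equal(flag_long_branch_taxa(long, 5), "e")

  nolen <- ape::read.tree(text = "(a,b,(c,d));")
  expect_error(flag_long_branch_taxa(nolen, 5), "branch lengths")
})

test_that("reading-frame enforcement finds the frame and flags non-coding data", {
  ## a clean ORF in frame 0
  set.seed(8)
  codons <- replicate(150, {
    repeat {
      c3 <- rand_dna(3)
      if (!c3 %in% c("TAA", "TAG", "TGA")) break
    }
    c3
  })
  orf <- paste(codons, collapse = "")
  m <- aln_matrix(c(a = orf, b = orf, c = orf))
  fr <- enforce_reading_frame(m)
  expect_equal(attr(fr, "frame_offset"), 0L)
  expect_equal(attr(fr, "stop_counts")[["0"]], 0L)
  expect_false(attr(fr, "noncoding"))
  expect_equal(ncol(fr) %% 3, 0)

  ## one leading column shifts the frame to offset 1
  m1 <- cbind(matrix("G", 3, 1), m)
  rownames(m1) <- rownames(m)
  fr1 <- enforce_reading_frame(m1)
  expect_equal(attr(fr1, "frame_offset"), 1L)

  ## random sequence: flagged non-coding with ~3/64 stops per codon per frame
  set.seed(9)
  rnd <- aln_matrix(setNames(replicate(6, rand_dna(900)), letters[1:6]))
  frr <- enforce_reading_frame(rnd)
  expect_true(attr(frr, "noncoding"))
  rate <- attr(frr, "stop_counts") / (6 * 299)
  expect_lt(max(abs(rate - 3 / 64)), 3 * sqrt((3 / 64) * (61 / 64) / (6 * 299)))
})

test_that("curation is idempotent and its provenance log replays exactly", {
  ## build a raw alignment with trimmable flanks and one divergent intruder
  set.seed(21)
  root <- rand_dna(520)
  seqs <- setNames(vapply(1:8, function(i) mutate_seq(root, 0.03),
                          character(1)), paste0("t", 1:8))
  seqs["intruder"] <- mutate_seq(root, 0.25)
  m <- aln_matrix(seqs)
  m[1:5, 1:12] <- "-"   # ragged 5' end (5/9 missing)
  expected <- rownames(m)

  res <- curate_alignment(m, expected, curation_config(max_missing_species = 2))
  expect_true(res$kept)
  expect_false("intruder" %in% rownames(res$alignment))
  expect_equal(ncol(res$alignment) %% 3, 0)

  ## replaying the log on the raw alignment reproduces the curated matrix
  strip <- function(x) { a <- attributes(x)
    attributes(x) <- a[names(a) %in% c("dim", "dimnames")]; x }
  expect_identical(strip(replay_provenance(m, res$provenance)),
                   strip(res$alignment))

  ## running curation on its own output changes nothing
  res2 <- curate_alignment(res$alignment, expected,
                           curation_config(max_missing_species = 2))
  expect_true(res2$kept)
  expect_identical(res2$alignment, res$alignment)
  expect_length(res2$provenance, 0)

  ## discard reasons propagate
  short <- aln_matrix(setNames(replicate(9, rand_dna(300)), expected))
  res3 <- curate_alignment(short, expected)
  expect_false(res3$kept)
  expect_equal(res3$reason, "length")
})
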