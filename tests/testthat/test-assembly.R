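test_that("spaced k-mer index maps identical windows and rejects short references", {
  ref <- rand_dna(300, seed = 1)
  idx <- spaced_kmer_index(ref)
  expect_equal(length(unlist(idx)), 300 - 24 + 1)

  expect_length(spaced_kmer_index(rand_dna(10, seed = 2)), 0)

  ## a read copied verbatim from the reference maps with identity 1
  read <- data.frame(id = "r1", bases = substring(ref, 51, 150),
                     stringsAsFactors = FALSE)
  m <- map_reads_to_references(read, c(L1 = ref))
  expect_equal(nrow(m), 1)
  expect_equal(m$offset, 51)
  expect_equal(m$identity, 1)
  expect_equal(m$strand, "+")

  ## reverse-complemented reads map on the minus strand at the same spot
  read_rc <- data.frame(id = "r2",
                        bases = ahepipe:::revcomp(substring(ref, 51, 150)),
                        stringsAsFactors = FALSE)
  m2 <- map_reads_to_references(read_rc, c(L1 = ref))
  expect_equal(m2$strand, "-")
  expect_equal(m2$offset, 51)
})

test_that("spaced seeds map at least as often as contiguous seeds under heavy divergence", {
  set.seed(202)
  n_rep <- 200
  spaced <- assembly_config(mask = spaced_mask(8, 24))
  contig <- assembly_config(mask = spaced_mask(8, 8))  # contiguous 8-mer
  hit_s <- hit_c <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    ref <- rand_dna(300)
    read <- mutate_seq(substring(ref, 101, 200), 0.45)
    rd <- data.frame(id = "r", bases = read, stringsAsFactors = FALSE)
    hit_s[i] <- nrow(map_reads_to_references(rd, c(L = ref), spaced)) > 0
    hit_c[i] <- nrow(map_reads_to_references(rd, c(L = ref), contig)) > 0
  }
  expect_gte(mean(hit_s), mean(hit_c))

  ## unrelated random reads map at most rarely
  hits_rand <- vapply(seq_len(n_rep), function(i) {
    rd <- data.frame(id = "r", bases = rand_dna(100),
                     stringsAsFactors = FALSE)
    nrow(map_reads_to_references(rd, c(L = rand_dna(600)), spaced)) > 0
  }, logical(1))
  expect_lte(mean(hits_rand), 0.05)
})

test_that("anchor choice maximises identity with length and id tie-breaks", {
  reads <- data.frame(id = c("a", "b"), bases = c(strrep("A", 100),
                                                  strrep("A", 80)),
                      stringsAsFactors = FALSE)
  one <- data.frame(read_id = "a", identity = 0.99)
  expect_equal(choose_anchor_read(one, reads), "a")

  two <- data.frame(read_id = c("a", "b"), identity = c(0.90, 0.99))
  expect_equal(choose_anchor_read(two, reads), "b")

  tie <- data.frame(read_id = c("b", "a"), identity = c(0.95, 0.95))
  expect_equal(choose_anchor_read(tie, reads), "a")  # longer read wins

  reads_eq <- data.frame(id = c("z", "y"), bases = rep(strrep("A", 90), 2),
                         stringsAsFactors = FALSE)
  tie2 <- data.frame(read_id = c("z", "y"), identity = c(0.95, 0.95))
  expect_equal(choose_anchor_read(tie2, reads_eq), "y")  # lexicographic
})

test_that("stacking takes a strict-majority consensus with the 2x depth rule", {
  truth <- rand_dna(120, seed = 9)
  ## tiled identical reads; with min_depth 1 the consensus is their union
  reads <- data.frame(id = c("r1", "r2", "r3"),
                      bases = c(substring(truth, 1, 60),
                                substring(truth, 31, 90),
                                substring(truth, 61, 120)),
                      stringsAsFactors = FALSE)
  offs <- c(r1 = 1L, r2 = 31L, r3 = 61L)
  res1 <- stack_and_consense("r1", reads, offsets = offs,
                             config = assembly_config(min_depth = 1))
  expect_identical(res1$consensus, truth)
  expect_false(grepl("N", res1$consensus))

  ## with the default 2x rule, single-coverage tips are trimmed
  res2 <- stack_and_consense("r1", reads, offsets = offs)
  expect_identical(res2$consensus, substring(truth, 31, 90))

  ## majority column {A,A,G} -> A
  base <- strrep("C", 30)
  v <- strsplit(base, "")[[1]]
  vA <- v; vA[15] <- "A"
  vG <- v; vG[15] <- "G"
  rr <- data.frame(id = c("x1", "x2", "x3"),
                   bases = c(paste(vA, collapse = ""),
                             paste(vA, collapse = ""),
                             paste(vG, collapse = "")),
                   stringsAsFactors = FALSE)
  res3 <- stack_and_consense("x1", rr, offsets = c(x1 = 1L, x2 = 1L, x3 = 1L))
  expect_equal(substring(res3$consensus, 15, 15), "A")
})

test_that("extension grows a seed across the read pool and ignores foreign reads", {
  truth <- rand_dna(120, seed = 10)
  mk <- function(id, from, to)
    data.frame(id = id, bases = substring(truth, from, to),
               stringsAsFactors = FALSE)
  ## duplicated reads give 2x depth over the whole span; the second pair
  ## overlaps the seed by exactly the 20 bp minimum
  pool <- rbind(mk("a1", 1, 60), mk("a2", 1, 60),
                mk("b1", 41, 120), mk("b2", 41, 120))
  offs <- c(a1 = 1L, a2 = 1L, b1 = 41L, b2 = 41L)
  seed <- stack_and_consense("a1", pool[1:2, ], offsets = offs[1:2])
  seed$read_bases <- pool$bases[1:2]
  out <- extend_assembly(seed, pool, offsets = offs)
  expect_identical(out$consensus, truth)
  expect_setequal(out$reads, pool$id)

  ## an unrelated pool leaves the seed unchanged (k-mer search path)
  foreign <- data.frame(id = sprintf("f%d", 1:5),
                        bases = vapply(1:5, function(i) rand_dna(100),
                                       character(1)),
                        stringsAsFactors = FALSE)
  out2 <- extend_assembly(seed, foreign)
  expect_identical(out2$consensus, substring(truth, 1, 60))
  expect_length(setdiff(out2$reads, seed$reads), 0)
})

test_that("whole-locus assembly recovers truth sequences from clean reads", {
  st <- small_clean_study()
  asm <- assemble_all(st$reads_by_individual, st$references)
  expect_gt(length(asm$contigs), 0)
  for (ct in asm$contigs) {
    ## contigs only arise for individuals that truly carry the locus
    expect_true(ct$individual %in%
                  names(st$sequences[[ct$locus_id]]$copies[[1]]))
    truth <- st$sequences[[ct$locus_id]]$copies[[1]][[ct$individual]]
    tc <- strsplit(truth, "")[[1]]
    cc <- strsplit(ct$bases, "")[[1]]
    pos <- ct$start:(ct$start + ct$length - 1)
    ok <- pos >= 1 & pos <= length(tc)
    expect_gt(mean(cc[ok] == tc[pos[ok]]), 0.985)
  }
  ## capture bookkeeping is consistent
  expect_true(all(asm$capture$captured == (asm$capture$contig_length > 350)))
  expect_equal(sum(asm$summary$reads_in_contigs),
               sum(asm$capture$n_reads))
})

test_that("short loci are not captured and empty inputs do not error", {
  cfg <- simulation_config(n_taxa = 4, n_loci = 1, seed = 17,
                           duplicate_fraction = 0, locus_length = 300,
                           tree_height = 0.02, flank_decay = 0,
                           error_rate = 0)
  st <- simulate_capture_study(cfg)
  asm <- assemble_all(st$reads_by_individual, st$references)
  expect_true(all(!asm$capture$captured))

  empty <- list(sp01 = data.frame(id = character(0), bases = character(0),
                                  stringsAsFactors = FALSE))
  asm0 <- assemble_all(empty, st$references)
  expect_equal(length(asm0$contigs), 0)
  expect_equal(asm0$summary$total_reads, 0)
})

test_that("duplicated loci assemble into one contig per copy", {
  cfg <- simulation_config(n_taxa = 5, n_loci = 3, seed = 23,
                           duplicate_fraction = 1, loss_prob = 0,
                           locus_length = 600, tree_height = 0.015,
                           paralog_depth = 0.18, flank_decay = 0,
                           error_rate = 0.01)
  st <- simulate_capture_study(cfg)
  asm <- assemble_all(st$reads_by_individual, st$references)
  tab <- table(vapply(asm$contigs, function(ct)
    paste(ct$locus_id, ct$individual), character(1)))
  expect_gte(mean(tab == 2), 0.9)

  ## each contig matches one truth copy much better than the other
  for (ct in asm$contigs) {
    if (ct$length < 400) next
    ids <- vapply(1:2, function(k) {
      truth <- st$sequences[[ct$locus_id]]$copies[[k]][[ct$individual]]
      tc <- strsplit(truth, "")[[1]]
      cc <- strsplit(ct$bases, "")[[1]]
      pos <- ct$start:(ct$start + ct$length - 1)
      ok <- pos >= 1 & pos <= length(tc)
      mean(cc[ok] == tc[pos[ok]])
    }, numeric(1))
    expect_gt(max(ids), 0.985)
    expect_lt(min(ids), 0.95)
  }

  ## pool-reduction invariant: within an individual no read is reused
  for (ind in unique(vapply(asm$contigs, `[[`, character(1), "individual"))) {
    used <- unlist(lapply(asm$contigs,
                          function(ct) if (ct$individual == ind) ct$reads))
    expect_equal(anyDuplicated(used), 0)
  }
})

test_that("raising coverage does not shrink contigs in expectation", {
  lens <- sapply(c(5, 12), function(cov) {
    cfg <- simulation_config(n_taxa = 4, n_loci = 10, seed = 41,
                             duplicate_fraction = 0, locus_length = 501,
                             tree_height = 0.02, flank_decay = 0,
                             error_rate = 0.01, target_coverage = cov)
    st <- simulate_capture_study(cfg)
    asm <- assemble_all(st$reads_by_individual, st$references)
    mean(vapply(asm$contigs, `[[`, integer(1), "length"))
  })
  expect_gte(lens[2], lens[1])
})
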