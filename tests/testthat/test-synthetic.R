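test_that("species tree simulation yields rooted binary trees, deterministically", {
  t4 <- simulate_species_tree(4, seed = 1)
  expect_s3_class(t4, "phylo")
  expect_equal(ape::Ntip(t4), 4)
  expect_equal(nrow(t4$edge), 6)          # 2n - 2 edges in a rooted binary tree
  expect_true(ape::is.rooted(t4))
  expect_true(ape::is.binary(t4))

  t29 <- simulate_species_tree(29, seed = 7)
  expect_equal(ape::Ntip(t29), 29)
  expect_equal(nrow(t29$edge), 2 * 29 - 2)
  expect_equal(sum(t29$edge[, 2] > 29), 27)  # internal edges

  expect_identical(ape::write.tree(simulate_species_tree(12, seed = 5)),
                   ape::write.tree(simulate_species_tree(12, seed = 5)))
  expect_false(identical(ape::write.tree(simulate_species_tree(12, seed = 5)),
                         ape::write.tree(simulate_species_tree(12, seed = 6))))

  expect_error(simulate_species_tree(3, seed = 1), "n_taxa")

  th <- simulate_species_tree(10, seed = 2, height = 0.07)
  expect_equal(max(ape::node.depth.edgelength(th)), 0.07, tolerance = 1e-12)
})

test_that("gene family copy counts follow the duplication settings", {
  tree <- simulate_species_tree(10, seed = 11)
  cfg0 <- simulation_config(n_taxa = 10, n_loci = 30, duplicate_fraction = 0,
                            seed = 2)
  fams0 <- simulate_gene_families(tree, cfg0)
  expect_true(all(vapply(fams0, `[[`, integer(1), "n_copies") == 1L))

  cfg2 <- simulation_config(n_taxa = 10, n_loci = 30, duplicate_fraction = 1,
                            loss_prob = 0, seed = 3)
  fams2 <- simulate_gene_families(tree, cfg2)
  expect_true(all(vapply(fams2, `[[`, integer(1), "n_copies") == 2L))
  expect_true(all(vapply(fams2, function(f)
    all(vapply(f$copies, ape::Ntip, integer(1)) == 10), logical(1))))

  ## locus lengths are codon multiples within the configured range
  lens <- vapply(fams2, `[[`, integer(1), "locus_length")
  expect_true(all(lens %% 3 == 0))
  expect_true(all(lens >= 448 & lens <= 1605))
})

test_that("observed duplicated fraction matches a loss-process oracle", {
  tree <- simulate_species_tree(12, seed = 21)
  dup <- 0.4; loss <- 0.05; n_loci <- 500

  ## Independent Monte-Carlo oracle for the loss process: probability that
  ## a copy retains >= 4 taxa, and that a duplicated family (conditioned on
  ## at least one surviving copy, as the generator rejects otherwise)
  ## presents both copies.
  tr <- stats::reorder(tree, "cladewise")
  nt <- ape::Ntip(tr)
  copy_survives <- function() {
    lost_edge <- runif(nrow(tr$edge)) < loss
    node_lost <- logical(nt + tr$Nnode)
    for (i in seq_len(nrow(tr$edge))) {
      node_lost[tr$edge[i, 2]] <- node_lost[tr$edge[i, 1]] || lost_edge[i]
    }
    sum(!node_lost[seq_len(nt)]) >= 4
  }
  set.seed(99)
  reps <- 4000
  s1 <- replicate(reps, copy_survives())
  s2 <- replicate(reps, copy_survives())
  p_both <- mean(s1 & s2)
  p_any <- mean(s1 | s2)
  p_two_given_kept <- p_both / p_any
  expected <- dup * p_two_given_kept

  cfg <- simulation_config(n_taxa = 12, n_loci = n_loci,
                           duplicate_fraction = dup, loss_prob = loss,
                           seed = 31)
  fams <- simulate_gene_families(tree, cfg)
  observed <- mean(vapply(fams, `[[`, integer(1), "n_copies") >= 2)
  se <- sqrt(expected * (1 - expected) / n_loci)
  expect_lt(abs(observed - expected), 3 * se + 0.02)
})

test_that("sequence evolution matches closed-form divergence expectations", {
  ## zero branch lengths: every tip identical
  tree <- simulate_species_tree(4, seed = 1)
  tree$edge.length[] <- 0
  fam <- manual_family(tree, locus_length = 300)
  cfg <- simulation_config(n_taxa = 4, n_loci = 1, seed = 5)
  ls <- evolve_sequences(fam, cfg)
  seqs <- ls$copies[[1]]
  expect_length(unique(unname(seqs)), 1)

  ## two taxa at distance d under equal rates: p =~ (3/4)(1 - exp(-4d/3))
  d <- 0.2
  two <- ape::read.tree(text = sprintf("(a:%g,b:%g);", d / 2, d / 2))
  fam2 <- manual_family(two, locus_length = 3000)
  cfg2 <- simulation_config(
    n_taxa = 4, n_loci = 1, seed = 8,
    subst_model = list(rates = rep(1, 6),
                       base_freq = c(A = .25, C = .25, G = .25, T = .25),
                       codon_rates = c(1, 1, 1)))
  sq <- evolve_sequences(fam2, cfg2)$copies[[1]]
  p_obs <- mean(strsplit(sq[["a"]], "")[[1]] != strsplit(sq[["b"]], "")[[1]])
  p_exp <- 0.75 * (1 - exp(-4 * d / 3))
  se <- sqrt(p_exp * (1 - p_exp) / 3000)
  expect_lt(abs(p_obs - p_exp), 3 * se + 0.01)  # stop repair perturbs slightly

  ## codon-position rate multipliers: third positions carry the largest
  ## share of variable sites
  tr6 <- simulate_species_tree(6, seed = 3, height = 0.05)
  var_by_pos <- c(0, 0, 0)
  for (i in 1:10) {
    fam_i <- manual_family(tr6, locus_length = 1200, locus_id = paste0("L", i))
    cfg_i <- simulation_config(n_taxa = 6, n_loci = 1, seed = 100 + i)
    m <- aln_matrix(evolve_sequences(fam_i, cfg_i)$copies[[1]])
    varcol <- apply(m, 2, function(col) length(unique(col)) > 1)
    for (p in 1:3) var_by_pos[p] <- var_by_pos[p] +
        sum(varcol[seq(p, ncol(m), by = 3)])
  }
  expect_true(var_by_pos[3] > var_by_pos[1])
  expect_true(var_by_pos[3] > var_by_pos[2])

  ## in-frame: no internal stop codons in frame 0
  s <- evolve_sequences(manual_family(tr6, locus_length = 900), cfg)$copies[[1]]
  for (x in s) {
    v <- strsplit(x, "")[[1]]
    codons <- paste0(v[seq(1, 898, 3)], v[seq(2, 899, 3)], v[seq(3, 900, 3)])
    expect_false(any(codons %in% c("TAA", "TAG", "TGA")))
  }

  expect_error(evolve_sequences(manual_family(tr6, locus_length = 0), cfg),
               "zero-length")
})

test_that("read shearing follows the coverage model and records full truth", {
  src <- rand_dna(600, seed = 42)
  cfg <- simulation_config(n_taxa = 4, n_loci = 1, flank_decay = 0,
                           error_rate = 0, target_coverage = 10, seed = 1)

  rs <- shear_reads(src, "sp01", cfg, "L001", 1, seed = 77)
  depth <- integer(600)
  for (i in seq_len(nrow(rs$truth))) {
    idx <- rs$truth$start[i] + 1:cfg$read_length
    depth[idx] <- depth[idx] + 1
  }
  expect_lt(abs(mean(depth[150:450]) - 10) / 10, 0.10)

  ## error-free reads are exact substrings of the source
  for (i in seq_len(nrow(rs$reads))) {
    b <- rs$reads$bases[i]
    if (rs$truth$strand[i] == "-") b <- ahepipe:::revcomp(b)
    expect_identical(substring(src, rs$truth$start[i] + 1,
                               rs$truth$start[i] + nchar(b)), b)
  }

  ## truth completeness: one truth row per read, ids unique
  expect_setequal(rs$reads$id, rs$truth$read_id)
  expect_false(anyDuplicated(rs$reads$id) > 0)

  ## efficiency scales the expected read count linearly
  cfg_low <- cfg; cfg_low$per_species_efficiency <- 0.1
  n_hi <- vapply(1:20, function(s)
    nrow(shear_reads(src, "sp01", cfg, "L001", 1, seed = s)$reads),
    numeric(1))
  n_lo <- vapply(1:20, function(s)
    nrow(shear_reads(src, "sp01", cfg_low, "L001", 1, seed = 1000 + s)$reads),
    numeric(1))
  lambda <- mean(n_hi)
  expect_lt(abs(mean(n_lo) - lambda * 0.1),
            3 * sqrt(lambda * 0.1 / 20))

  ## flank decay lowers depth at the ends relative to the core
  cfg_dec <- cfg; cfg_dec$flank_decay <- 0.01
  rs2 <- shear_reads(src, "sp01", cfg_dec, "L001", 1, seed = 5)
  depth2 <- integer(600)
  for (i in seq_len(nrow(rs2$truth))) {
    idx <- rs2$truth$start[i] + 1:cfg$read_length
    depth2[idx] <- depth2[idx] + 1
  }
  expect_gt(mean(depth2[280:320]), mean(depth2[c(1:40, 561:600)]))

  ## byte-identical outputs for identical config and seed
  expect_identical(shear_reads(src, "sp01", cfg, "L001", 1, seed = 9),
                   shear_reads(src, "sp01", cfg, "L001", 1, seed = 9))
})

test_that("whole-study simulation is deterministic and truth-complete", {
  st <- small_clean_study()
  cfg <- st$config
  st2 <- simulate_capture_study(cfg)
  expect_identical(st$truth, st2$truth)
  expect_identical(st$references, st2$references)
  all_ids <- unlist(lapply(st$reads_by_individual, `[[`, "id"))
  expect_setequal(all_ids, st$truth$read_id)
  expect_equal(anyDuplicated(st$truth$read_id), 0)
  ## every truth coordinate lies inside its source sequence
  for (i in seq_len(nrow(st$truth))) {
    tr <- st$truth[i, ]
    src <- st$sequences[[tr$locus_id]]$copies[[tr$copy_index]][[tr$individual]]
    expect_true(tr$start >= 0 &&
                  tr$start + cfg$read_length <= nchar(src))
  }
})
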