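## Synthetic-data module: species trees, duplication/loss gene families,
## in-frame sequence evolution and probe-centred capture reads with a full
## truth map.  Everything downstream of the wet lab can be exercised on data
## where the correct answer is known.

#' Simulation configuration for synthetic capture data
#'
#' Bundles every knob of the generator.  Defaults emulate a first-generation
#' anchored-enrichment experiment on a percomorph-scale radiation: a 29-taxon
#' species tree, loci of 450-1605 bp, a fraction of loci carrying an ancient
#' root-level duplication (the teleost whole-genome duplication predates all
#' sampled taxa), probe-centred read coverage with linear flank decay, and
#' independent substitution sequencing errors.
#'
#' @param n_taxa Number of species on the simulated tree.
#' @param n_loci Number of loci.
#' @param duplicate_fraction Probability that a locus carries the root-level
#'   duplication (two gene copies).
#' @param secondary_duplicate_fraction Probability, per opportunity (up to
#'   three), that an already-duplicated locus gains a further copy; copy count
#'   is capped at 5.
#' @param loss_prob Per-branch, per-copy probability that a gene copy is lost
#'   on that branch (all descendant taxa lose the copy).
#' @param locus_length Either a single length in bp or a `c(min, max)` range
#'   to draw from uniformly; lengths are rounded down to a codon multiple.
#' @param tree_height Root-to-tip height of the species tree in expected
#'   substitutions/site (controls intra-ortholog divergence).
#' @param paralog_depth Stem branch length added to each copy at the
#'   duplication, in expected substitutions/site; inter-copy divergence is
#'   roughly `2 * paralog_depth + 2 * tree_height`.
#' @param subst_model List with `rates` (six GTR exchangeabilities in the
#'   order AC, AG, AT, CG, CT, GT), `base_freq` (A, C, G, T) and
#'   `codon_rates` (relative rate multipliers for codon positions 1, 2, 3).
#' @param read_length Read length in bp.
#' @param target_coverage Expected read depth at the probe-centred core.
#' @param probe_length Width of the flat coverage core, bp.
#' @param flank_decay Linear decay of relative coverage per bp outside the
#'   core (0 = flat coverage across the locus).
#' @param per_species_efficiency Capture-efficiency multiplier in (0, 1]:
#'   a single value, or a named vector per species (unnamed species get 1).
#'   Emulates, e.g., one poorly-capturing species in an otherwise uniform
#'   experiment.
#' @param error_rate Per-base substitution sequencing-error probability.
#' @param seed Master integer seed; all per-locus streams are derived from it
#'   with [derive_seed()] so adding loci never perturbs earlier ones.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_taxa = 29,
                              n_loci = 100,
                              duplicate_fraction = 0.4,
                              secondary_duplicate_fraction = 0,
                              loss_prob = 0.05,
                              locus_length = c(450, 1605),
                              tree_height = 0.05,
                              paralog_depth = 0.09,
                              subst_model = list(
                                rates = c(1, 4, 1, 1, 4, 1),
                                base_freq = c(A = 0.23, C = 0.23,
                                              G = 0.24, T = 0.30),
                                codon_rates = c(0.3, 0.2, 1.0)
                              ),
                              read_length = 100,
                              target_coverage = 10,
                              probe_length = 120,
                              flank_decay = 0.005,
                              per_species_efficiency = 1,
                              error_rate = 0.01,
                              seed = 1L) {
  stopifnot(
    n_taxa >= 4, n_loci >= 1,
    duplicate_fraction >= 0, duplicate_fraction <= 1,
    secondary_duplicate_fraction >= 0, secondary_duplicate_fraction <= 1,
    loss_prob >= 0, loss_prob <= 1,
    all(locus_length > 0), length(locus_length) %in% c(1, 2),
    tree_height > 0, paralog_depth >= 0,
    length(subst_model$rates) == 6, all(subst_model$rates > 0),
    length(subst_model$base_freq) == 4,
    abs(sum(subst_model$base_freq) - 1) < 1e-8,
    length(subst_model$codon_rates) == 3, all(subst_model$codon_rates > 0),
    read_length >= 20, target_coverage > 0, probe_length > 0,
    flank_decay >= 0,
    all(per_species_efficiency > 0), all(per_species_efficiency <= 1),
    error_rate >= 0, error_rate <= 1
  )
  cfg <- list(n_taxa = as.integer(n_taxa), n_loci = as.integer(n_loci),
              duplicate_fraction = duplicate_fraction,
              secondary_duplicate_fraction = secondary_duplicate_fraction,
              loss_prob = loss_prob, locus_length = locus_length,
              tree_height = tree_height, paralog_depth = paralog_depth,
              subst_model = subst_model, read_length = as.integer(read_length),
              target_coverage = target_coverage,
              probe_length = as.integer(probe_length),
              flank_decay = flank_decay,
              per_species_efficiency = per_species_efficiency,
              error_rate = error_rate, seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate a rooted binary species tree
#'
#' Draws a pure-birth (Yule) tree with `ape::rphylo` and rescales it to the
#' requested root-to-tip height.
#'
#' @param n_taxa Number of tips (>= 4).
#' @param seed Integer seed.
#' @param height Root-to-tip height in expected substitutions/site.
#' @return An `ape::phylo` object with tips `sp01`, `sp02`, ...
#' @export
simulate_species_tree <- function(n_taxa, seed, height = 0.05) {
  if (n_taxa < 4)
    stop("n_taxa must be >= 4 (downstream capture rule needs >= 4 species)")
  set.seed(seed)
  tree <- ape::rphylo(n_taxa, birth = 1, death = 0)
  tree$tip.label <- sprintf("sp%02d", seq_len(n_taxa))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth * height
  tree
}

## Apply the per-branch loss process to one copy: each edge is lost with
## probability loss_prob; a lost edge removes all its descendant taxa.
## Returns list(tree = pruned phylo or NULL, lost = character()).
apply_losses <- function(tree, loss_prob) {
  if (loss_prob <= 0) return(list(tree = tree, lost = character(0)))
  tr <- stats::reorder(tree, "cladewise")  # parents precede children
  n_edge <- nrow(tr$edge)
  lost_edge <- stats::runif(n_edge) < loss_prob
  n_node <- ape::Ntip(tr) + tr$Nnode
  node_lost <- logical(n_node)
  for (i in seq_len(n_edge)) {
    parent <- tr$edge[i, 1]; child <- tr$edge[i, 2]
    node_lost[child] <- node_lost[parent] || lost_edge[i]
  }
  lost_tips <- tr$tip.label[node_lost[seq_len(ape::Ntip(tr))]]
  if (length(lost_tips) > ape::Ntip(tr) - 2)
    return(list(tree = NULL, lost = lost_tips))
  pruned <- if (length(lost_tips)) ape::drop.tip(tr, lost_tips) else tr
  list(tree = pruned, lost = lost_tips)
}

## Newick of a phylo without the trailing ";".
newick_core <- function(tree) sub(";\\s*$", "", ape::write.tree(tree))

#' Simulate gene families under root duplication and lineage-specific loss
#'
#' A fraction `duplicate_fraction` of loci receive a duplication at the root
#' of the species tree; each copy then loses taxa independently (one loss
#' event per branch with probability `loss_prob` removes all descendants).
#' Copies retaining fewer than 4 taxa are dropped.  Loss draws are rejected
#' (and redrawn from the same stream) until at least one copy retains >= 4
#' taxa, so every family is capturable.
#'
#' @param tree Species tree (`phylo`).
#' @param config A [simulation_config()].
#' @return A list of `gene_family` objects, each with the per-copy pruned
#'   trees, the lost taxa, the combined family tree used for sequence
#'   evolution (tips labelled `taxon@cK`), the copy origins, and the locus
#'   length.
#' @export
simulate_gene_families <- function(tree, config) {
  lapply(seq_len(config$n_loci), function(i) {
    locus_id <- sprintf("L%03d", i)
    set.seed(derive_seed(config$seed, locus_id, "family"))
    lr <- config$locus_length
    len <- if (length(lr) == 2) round(stats::runif(1, lr[1], lr[2])) else lr
    len <- max(3L, as.integer(len) - as.integer(len) %% 3L)

    duplicated <- stats::runif(1) < config$duplicate_fraction
    n_copies_drawn <- if (!duplicated) 1L else {
      extra <- sum(stats::runif(3) < config$secondary_duplicate_fraction)
      min(5L, 2L + extra)
    }

    ## Rejection-sample the loss process until one copy keeps >= 4 taxa.
    for (attempt in 1:50) {
      copies <- vector("list", n_copies_drawn)
      lost <- vector("list", n_copies_drawn)
      for (k in seq_len(n_copies_drawn)) {
        res <- apply_losses(tree, config$loss_prob)
        ok <- !is.null(res$tree) && ape::Ntip(res$tree) >= 4
        copies[[k]] <- if (ok) res$tree else NULL
        lost[[k]] <- res$lost
      }
      keep <- !vapply(copies, is.null, logical(1))
      if (any(keep)) break
    }
    if (!any(keep)) {  # pathological loss_prob; fall back to a full copy
      copies <- list(tree); lost <- list(character(0)); keep <- TRUE
    }
    copies <- copies[keep]; lost <- lost[keep]
    n_copies <- length(copies)
    origin <- if (n_copies_drawn == 1L) "single" else
      c("wgd", "wgd", rep("secondary", max(0, n_copies_drawn - 2)))[keep]

    ## Family tree: copies hang off a common root with stem branches.
    suffixed <- lapply(seq_len(n_copies), function(k) {
      tr <- copies[[k]]
      tr$tip.label <- paste0(tr$tip.label, "@c", k)
      tr
    })
    if (n_copies == 1) {
      family_tree <- suffixed[[1]]
    } else {
      stems <- rep(config$paralog_depth, n_copies)
      ## secondary copies sit closer to their sister copy
      stems[origin == "secondary"] <- config$paralog_depth * 0.5
      cores <- vapply(suffixed, newick_core, character(1))
      nwk <- sprintf("(%s);",
                     paste(sprintf("%s:%g", cores, stems), collapse = ","))
      family_tree <- ape::read.tree(text = nwk)
    }

    structure(list(locus_id = locus_id, n_copies = n_copies,
                   copies = copies, losses = lost, copy_origin = origin,
                   family_tree = family_tree, locus_length = len),
              class = "gene_family")
  })
}

## Random in-frame root sequence without stop codons (frame 0).
random_root_sequence <- function(len, base_freq) {
  x <- sample(DNA_BASES, len, replace = TRUE, prob = base_freq)
  repair_stops(x)
}

## Replace in-frame stop codons (TAA, TAG, TGA) deterministically: third
## position -> C (TAC/TGC are sense codons).  Operates on a char vector whose
## frame-0 codons start at position 1.
repair_stops <- function(x) {
  n_codon <- length(x) %/% 3
  if (n_codon == 0) return(x)
  idx <- 3 * (seq_len(n_codon) - 1)
  first <- x[idx + 1]; second <- x[idx + 2]; third <- x[idx + 3]
  stop_codon <- first == "T" &
    ((second == "A" & third %in% c("A", "G")) | (second == "G" & third == "A"))
  x[idx[stop_codon] + 3] <- "C"
  x
}

#' Evolve in-frame sequences for one gene family
#'
#' Simulates sequences along the family tree under a GTR model
#' (via `phangorn::simSeq`), with per-codon-position rate multipliers applied
#' by simulating the three position classes separately and interleaving.
#' In-frame stop codons that arise along branches are repaired
#' deterministically (third codon position set to C), a minimal stand-in for
#' purifying selection; the curation stage expects open reading frames.
#'
#' @param family A `gene_family`.
#' @param config A [simulation_config()].
#' @return A `locus_sequences` list: `reference` (the ancestral/root sequence,
#'   used as the probe reference), `copies` (per copy, a named vector
#'   taxon -> sequence), plus the family.
#' @export
evolve_sequences <- function(family, config) {
  len <- family$locus_length
  if (len <= 0) stop("zero-length locus")
  sm <- config$subst_model
  set.seed(derive_seed(config$seed, family$locus_id, "root"))
  root <- random_root_sequence(len, sm$base_freq)

  tips <- family$family_tree$tip.label
  out <- matrix("", nrow = length(tips), ncol = len, dimnames = list(tips))
  for (p in 1:3) {
    pos <- seq(p, len, by = 3)
    tr <- family$family_tree
    tr$edge.length <- tr$edge.length * sm$codon_rates[p]
    set.seed(derive_seed(config$seed, family$locus_id, "evolve", p))
    sim <- phangorn::simSeq(tr, l = length(pos), Q = sm$rates,
                            bf = sm$base_freq, type = "DNA",
                            rootseq = tolower(root[pos]))
    m <- toupper(as.character(sim))
    out[rownames(m), pos] <- m
  }
  copies <- vector("list", family$n_copies)
  for (k in seq_len(family$n_copies)) {
    suffix <- paste0("@c", k)
    ktips <- tips[endsWith(tips, suffix)]
    seqs <- vapply(ktips, function(t) chars_seq(repair_stops(out[t, ])),
                   character(1))
    names(seqs) <- sub("@c\\d+$", "", ktips)
    copies[[k]] <- seqs
  }
  structure(list(locus_id = family$locus_id, reference = chars_seq(root),
                 copies = copies, family = family),
            class = "locus_sequences")
}

## Per-species capture-efficiency lookup.
species_efficiency <- function(config, individual) {
  eff <- config$per_species_efficiency
  if (is.null(names(eff))) return(eff[1])
  if (individual %in% names(eff)) unname(eff[individual]) else 1
}

#' Shear a source sequence into probe-centred capture reads
#'
#' Read start positions are drawn from a trapezoid intensity: flat over the
#' central probe window, decaying linearly at `flank_decay` per bp outside
#' it.  The intensity is scaled so expected depth at the locus centre equals
#' `target_coverage * efficiency`; the total read count is Poisson.
#' Per-base substitution errors are applied at `error_rate`.
#'
#' @param sequence Source sequence (single string), length >= `read_length`.
#' @param individual Species/individual label (used for ids, truth and the
#'   per-species efficiency lookup).
#' @param config A [simulation_config()].
#' @param locus_id,copy_index Truth annotations.
#' @param seed Integer seed (default derived from the config master seed).
#' @return A `read_set`: `reads` data frame (id, bases) and `truth` data
#'   frame (read_id, locus_id, copy_index, individual, start, strand);
#'   `start` is the 0-based position of the read in the source sequence.
#' @export
shear_reads <- function(sequence, individual, config,
                        locus_id = "locus", copy_index = 1L,
                        seed = derive_seed(config$seed, locus_id, copy_index,
                                           individual, "reads")) {
  L <- nchar(sequence)
  rl <- config$read_length
  if (L < rl) stop("sequence shorter than read_length")
  set.seed(seed)
  eff <- species_efficiency(config, individual)

  starts0 <- 0:(L - rl)                     # 0-based candidate starts
  mid <- starts0 + rl / 2
  core_lo <- (L - config$probe_length) / 2
  core_hi <- (L + config$probe_length) / 2
  dist <- pmax(0, core_lo - mid, mid - core_hi)
  w <- pmax(0, 1 - config$flank_decay * dist)
  centre <- L / 2
  covering <- starts0 <= centre & centre < starts0 + rl
  s_centre <- sum(w[covering])
  if (s_centre <= 0) s_centre <- max(w) * rl
  scale <- config$target_coverage * eff / s_centre
  n_reads <- stats::rpois(1, scale * sum(w))
  if (n_reads == 0) {
    return(structure(list(
      reads = data.frame(id = character(0), bases = character(0),
                         stringsAsFactors = FALSE),
      truth = data.frame(read_id = character(0), locus_id = character(0),
                         copy_index = integer(0), individual = character(0),
                         start = integer(0), strand = character(0),
                         stringsAsFactors = FALSE)), class = "read_set"))
  }
  starts <- sample(starts0, n_reads, replace = TRUE, prob = w)
  bases <- substring(sequence, starts + 1, starts + rl)
  ## substitution errors
  if (config$error_rate > 0) {
    n_err <- stats::rbinom(n_reads, rl, config$error_rate)
    for (i in which(n_err > 0)) {
      v <- seq_chars(bases[i])
      pos <- sample.int(rl, n_err[i])
      for (p in pos) v[p] <- sample(setdiff(DNA_BASES, v[p]), 1)
      bases[i] <- chars_seq(v)
    }
  }
  strand <- ifelse(stats::runif(n_reads) < 0.5, "+", "-")
  bases[strand == "-"] <- revcomp(bases[strand == "-"])
  ids <- sprintf("%s_%s_c%d_%05d", individual, locus_id, copy_index,
                 seq_len(n_reads))
  structure(list(
    reads = data.frame(id = ids, bases = bases, stringsAsFactors = FALSE),
    truth = data.frame(read_id = ids, locus_id = locus_id,
                       copy_index = as.integer(copy_index),
                       individual = individual, start = as.integer(starts),
                       strand = strand, stringsAsFactors = FALSE)),
    class = "read_set")
}

#' Simulate a complete capture study with known truth
#'
#' Convenience orchestrator: species tree, gene families, sequences, and
#' reads for every individual and gene copy.  Every downstream module can be
#' run on the result and scored against `truth` and `sequences`.
#'
#' @param config A [simulation_config()].
#' @return A `capture_study` list: `tree`, `families`, `sequences` (per-locus
#'   `locus_sequences`), `references` (named vector locus -> ancestral
#'   sequence, the mapping reference), `reads_by_individual` (list of data
#'   frames id/bases), `truth` (combined truth map) and `config`.
#' @export
simulate_capture_study <- function(config) {
  tree <- simulate_species_tree(config$n_taxa,
                                derive_seed(config$seed, "tree"),
                                height = config$tree_height)
  families <- simulate_gene_families(tree, config)
  sequences <- lapply(families, evolve_sequences, config = config)
  names(sequences) <- vapply(families, `[[`, character(1), "locus_id")
  references <- vapply(sequences, `[[`, character(1), "reference")

  reads <- list(); truth <- list()
  for (ls in sequences) {
    for (k in seq_along(ls$copies)) {
      for (ind in names(ls$copies[[k]])) {
        rs <- shear_reads(ls$copies[[k]][[ind]], ind, config,
                          locus_id = ls$locus_id, copy_index = k)
        reads[[length(reads) + 1L]] <- rs$reads
        truth[[length(truth) + 1L]] <- rs$truth
      }
    }
  }
  reads <- do.call(rbind, reads)
  truth <- do.call(rbind, truth)
  reads_by_individual <- split(reads, truth$individual)
  structure(list(tree = tree, families = families, sequences = sequences,
                 references = references,
                 reads_by_individual = reads_by_individual,
                 truth = truth, config = config),
            class = "capture_study")
}

#' @export
print.capture_study <- function(x, ...) {
  cat("Synthetic capture study:", x$config$n_taxa, "taxa,",
      x$config$n_loci, "loci,", nrow(x$truth), "reads\n")
  nc <- vapply(x$families, `[[`, integer(1), "n_copies")
  cat("Copy-count distribution:\n")
  print(table(nc))
  invisible(x)
}
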