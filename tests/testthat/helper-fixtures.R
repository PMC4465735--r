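## Shared fixture builders.  Everything is generated in code at test time.

## Random DNA string.
rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Mutate a fraction of positions to a (uniformly) different base.
mutate_seq <- function(s, rate, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- strsplit(s, "")[[1]]
  idx <- which(runif(length(v)) < rate)
  for (i in idx) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}

## A gene family object built by hand (bypassing the loss process), used to
## drive evolve_sequences() under controlled branch lengths.
manual_family <- function(tree, locus_length = 300, locus_id = "LX") {
  t1 <- tree
  t1$tip.label <- paste0(t1$tip.label, "@c1")
  structure(list(locus_id = locus_id, n_copies = 1L, copies = list(tree),
                 losses = list(character(0)), copy_origin = "single",
                 family_tree = t1, locus_length = locus_length),
            class = "gene_family")
}

## Character alignment matrix from a vector of strings.
aln_matrix <- function(seqs) {
  m <- do.call(rbind, strsplit(unname(seqs), ""))
  rownames(m) <- names(seqs)
  m
}

## Small clean study used by several files (memoised per session).
small_clean_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(n_taxa = 6, n_loci = 4, seed = 303,
                               duplicate_fraction = 0, locus_length = 600,
                               tree_height = 0.03, flank_decay = 0,
                               error_rate = 0.01)
      cache <<- simulate_capture_study(cfg)
    }
    cache
  }
})
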