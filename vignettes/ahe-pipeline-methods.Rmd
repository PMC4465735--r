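---
title: "Methods: anchored-enrichment locus processing, orthology assignment and support rarefaction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anchored-enrichment locus processing, orthology assignment and support rarefaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ahepipe)
```

# The problem

Anchored hybrid enrichment (AHE) captures a few hundred conserved nuclear
loci plus their flanks with hybridisation probes. In teleost fishes an
ancient whole-genome duplication predates every sampled species, so a
capture experiment routinely pulls down *both* surviving copies of a locus.
Mixing paralogs into one alignment distorts species-tree inference, so the
processing chain must (i) assemble reads into per-copy consensus sequences
without collapsing copies, (ii) sort the per-individual sequences into
putatively orthologous "homolog sets", (iii) curate the resulting
alignments, and (iv) quantify how node support in the concatenated analysis
responds to the number of loci sampled (rarefaction). `ahepipe` implements
this chain as testable components, together with a synthetic-data generator
that provides ground truth for every stage.

# Synthetic data: what it emulates

`simulation_config()` fixes the generator's conditions. The defaults model
a first-generation AHE experiment on a percomorph-scale radiation:

* a pure-birth species tree (default 29 taxa), rescaled to a root-to-tip
  height in expected substitutions/site (`tree_height`, default 0.05 —
  intra-ortholog divergences of a few percent, typical of AHE exons);
* loci of 450–1605 bp (the range of curated AHE alignments), rounded to
  codon multiples;
* a root-level duplication in a fraction of loci (`duplicate_fraction`,
  default 0.4, echoing the observed preponderance of one- and two-copy
  loci), with per-branch, per-copy loss (`loss_prob` 0.05). Losses apply to
  every copy; draws are rejected until at least one copy retains four taxa,
  since an uncapturable locus would never enter the dataset. Copies add a
  stem branch (`paralog_depth`) on each side of the duplication, so
  inter-copy divergence is roughly `2*paralog_depth + 2*tree_height`;
* GTR sequence evolution (via `phangorn::simSeq`) with per-codon-position
  rate multipliers (default 0.3/0.2/1.0, giving third positions the bulk of
  the variable sites, as observed in coding AHE data). Note the realized
  divergence is the branch length times the mean codon multiplier (0.5 with
  the defaults). Stop codons arising along branches are repaired
  deterministically (third position set to C) — a minimal stand-in for
  purifying selection, since downstream curation expects open reading
  frames;
* probe-centred coverage: a trapezoid with a flat core (`probe_length`,
  default 120 bp) and linear decay (`flank_decay`) into the flanks, scaled
  so depth at the locus centre equals `target_coverage` times a per-species
  capture efficiency. One low-efficiency species can be configured to mimic
  a poorly-capturing taxon. Reads carry independent substitution errors
  only — no indels, no quality model — because the assembler's contract is
  substitution-tolerant ungapped stacking.

Seeding: one master seed; every per-locus, per-stage stream is derived by
hashing `(seed, locus, stage)` (`derive_seed()`), so adding loci or draws
never perturbs earlier ones and all outputs are byte-reproducible.

What the generator does *not* emulate: indels, selection, recombination,
contamination, base-quality artefacts, and genuinely heterogeneous
gene-tree histories (incomplete lineage sorting). Passing tests therefore
demonstrate the pipeline's correctness on idealised capture data, not its
robustness to every pathology of real libraries.

# Assembly

`assemble_all()` mirrors the classic in-house AHE assembler contract:

1. **Mapping.** Reads (both strands) are matched to per-locus references
   with spaced k-mers (weight 8 over a 24 bp span; the care positions are
   spread so don't-care columns absorb mismatches). A shared key only
   *maps* a read when the ungapped identity on that key's diagonal is at
   least `1 - max_map_divergence` (default 0.45) over at least 40 bp.
   The identity check is essential: a bare weight-8 key match against a
   600 bp reference has an expected ~1.4 random collisions per read, so
   "shares a key" alone cannot bound false mapping. The divergence bound is
   what the spaced seed is advertised to tolerate; the seed itself is only
   the lookup device.
2. **Seeding.** The best-matching read (highest reference identity; ties:
   longer read, then smaller id) anchors a stack. Each mapped read joins
   only if it overlaps the current working consensus by ≥ 20 comparable bp
   at ≥ 95 % identity — this is the rule that keeps paralogous copies
   (> 5 % divergent) in separate stacks.
3. **Extension.** The majority-rule consensus seeds repeated passes over
   the remaining pool; the consensus is re-taken after each pass until no
   read is added.
4. **Reporting.** Consensus columns need ≥ 2 reads; lower-depth columns
   become `N` and are trimmed from the ends. A locus is "captured" when a
   round produces a contig > 350 bp.
5. **Rounds.** Consumed reads leave the pool and the next round seeds a new
   consensus per locus (the second gene copy, typically), up to 5 rounds or
   until no contig of ≥ 20 bp arises. Five matches the maximum number of
   homolog sets per locus ever observed.

Majority ties keep the previous consensus base when it is among the tied
set, else an IUPAC ambiguity code is emitted. At 10× Poisson coverage,
occasional interior columns fall below 2× and are reported as `N`
(no-calls); contig-to-truth identity is therefore assessed over called
bases.

# The paralog picker

`pick_paralogs()` implements the six-step homolog-set procedure: choose the
reference individual (most loci captured; ties by total contig length, then
label); iterate over its sequences in assembly-round order; homolog set *k*
is reference sequence *k* plus, from every other individual, the
best-aligning not-yet-assigned sequence; assigned sequences are removed and
the procedure repeats until the reference sequences are used up.

"Best aligned" is scored as the identical-position count of the best local
alignment (match +1, mismatch −1, gap −4/−1) divided by the length of the
shorter sequence. Normalising by the alignment's own span instead would let
a 30 bp perfect segment between unrelated sequences score 1.0; with length
normalisation, unrelated pairs score clearly below orthology-level
identities while overlapping contigs score near their true identity. Sequences
scoring < 0.5 against every remaining reference are reported unassigned
rather than forced into a set (a guard, not part of the original
procedure); surplus copies beyond the reference's count likewise remain
unassigned. The greedy per-individual choice is the literal reading of the
procedure; an exhaustive per-individual best-total-score mode
(`method = "optimal"`, feasible because copy counts never exceed 5) is
provided for comparison. When inter-paralog divergence approaches zero the
assignment becomes arbitrary — by construction, no scorer can distinguish
copies that are not diverged.

# Alignment curation

Filter order is fixed: align → missing-species → end trim → length →
divergence/long-branch flags → missing-species re-check → reading frame.
The source procedure lists these rules without fully ordering them; the
order above applies cheap structural filters before expensive outlier
screens and re-checks species counts after any taxon removal.

* **Aligner.** The default backend is an internal centre-star progressive
  aligner (ends-free affine-gap pairwise alignments against the longest
  sequence, insertions merged into shared columns), so the pipeline needs
  no external binary; `backend = "mafft"` delegates to MAFFT when
  available. On low-divergence AHE sets the two agree in almost all
  columns; the internal aligner is not meant for deep or indel-rich
  alignments.
* **Missing species.** More than 2 missing species (absent or all-gap)
  discards the locus, and the check is re-applied after outlier removal.
* **End trimming.** The two fractions in the rule ("more than a third …
  until less than half") are read as: trimming *triggers* when the terminal
  column's missing fraction exceeds 1/3 and *strips* consecutive terminal
  columns while the fraction is ≥ 1/2. Interior columns are never touched.
  Gaps count as missing by default (`count_gaps_as_missing`), since the
  trimming exists to reduce ragged ends regardless of whether raggedness is
  written as `-` or `N`.
* **Length.** Keep iff ≥ 450 columns and the shortest sequence has ≥ 150
  ungapped bp.
* **Divergence outliers.** A taxon is flagged when its median pairwise
  p-distance exceeds the across-taxa median by > 3.5 MAD-based robust SDs
  *and* by ≥ 50 % relatively. The relative guard is needed because the MAD
  of tightly clustered distances collapses, turning noise into huge
  z-scores; 3.5 is the conventional robust-outlier threshold for an
  "unusually high" divergence that the source leaves unquantified.
* **Long branches.** Terminal branches > 5× the median terminal branch in
  the locus NJ tree flag the taxon. Gene trees come from the internal
  distance backend — Bayesian per-locus inference is out of scope.
* **Reading frame.** The offset (0/1/2) minimising in-frame stops is
  chosen and partial codons trimmed; if every frame averages more than one
  stop per sequence the locus is flagged non-coding and passed through with
  the offset recorded as undetermined (random DNA averages 3/64 stops per
  codon in every frame, so genuinely coding loci are far from this bound).

Every edit is logged; `replay_provenance()` re-applies the log to the raw
alignment and must reproduce the curated matrix exactly. Curation is
idempotent: running it on its own output changes nothing.

# Supermatrix statistics

`concatenate()` pads absent taxa with `N`, records 0-based half-open locus
spans and a cycling codon map. A column is *variable* iff ≥ 2 distinct
unambiguous bases occur among non-missing states; ambiguity codes alone
never make a column variable (conservative, since an ambiguity is a
half-call). Three completeness definitions are computed: trailing-gap+
missing-locus; additionally counting interior gaps; and per-species locus
presence. GC% is reported ignoring ambiguities or with fractional IUPAC
counting; G−C skew always uses unambiguous counts. Partition schemes:
by gene, by codon position, third positions removed, third positions only,
and a standard-code amino-acid translation in which any codon containing a
gap, `N` or an in-frame stop is missing. Exported partition files use
1-based inclusive coordinates (the de facto convention); internal
coordinates stay 0-based half-open.

# Tree support backend

The backend is distance-based — p, JC69 or K2P distances with pairwise
deletion (pairs sharing < 100 comparable columns get a flagged large
distance), neighbour joining with label-sorted input for deterministic tie
breaking, and a nonparametric bootstrap that resamples columns (or codon
triplets) and maps bipartition frequencies onto the full-data tree.
Re-implementing ML or Bayesian inference is explicitly out of scope; the
rarefaction machinery only needs replicate trees and bipartition
frequencies, and `tree_fun` is pluggable so an external inference wrapper
can be swapped in. Consequently, support values produced here are
methodologically parallel to, but not numerically comparable with,
published ML bootstrap values. "Node support" means internal-edge
(bipartition) support; threshold counts use strict `>`.

# Rarefaction

`run_rarefaction()` draws locus pools in increments of 5 with 20 draws per
size (the study design; both are configuration), concatenates each draw,
bootstraps it, and records average node support, tracked-clade supports
(monophyly or MRCA-defined) and node counts above 50/70/90 %. Average
support is taken over all internal edges of each draw's tree. Draws are
seeded from the master seed, pool size and draw index; the bootstrap seed
is derived from the *content* of the drawn subset (in canonical locus
order), so identical subsets give identical results — in particular the
full pool, where every draw is the same set, has zero across-draw spread.
`plateau_detect()` (an added convenience) returns the smallest pool size
from which every later mean stays strictly within a tolerance (default 2
support points) of its trailing-window (default 3 sizes) running mean.

# Problem sizes used in tests and the acceptance script

The shipped checks run the generator at deliberately modest scale, chosen
once as representative: 4 individuals for the assembly and paralog studies
(50 loci of 600 bp at 10× coverage and 1 % error; duplicated loci with
stems giving ≥ 15 % realized inter-copy and ≤ 5 % intra-ortholog
divergence), and a 12-taxon, 40-locus, 450 bp-per-locus study for the
rarefaction curve with 50 bootstrap replicates per draw. The published
29-species matrix statistics are recomputed from the shipped per-table
summary files, not from raw reads, which the original study did not
deposit in re-runnable form.

# Known limitations

* The internal aligner assumes modest divergence and sparse indels.
* NJ bootstrap supports underestimate what a partitioned ML analysis would
  give on the same data; rarefaction *shapes* are meaningful, absolute
  levels are backend-dependent.
* The paralog picker is greedy per individual; pathological score ties can
  order-depend (ties essentially never occur with continuous scores).
* The "fractional IUPAC" GC mode is one reading of "accounting for
  ambiguities"; with few ambiguity codes the two modes differ negligibly,
  and no published value is asserted for it.
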