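## Alignment curation: align each homolog set, then apply the filtering,
## trimming, frame-enforcement and outlier-removal rules that turn raw
## per-set alignments into curated locus alignments fit for concatenation.
## Fixed filter order: align -> missing-species -> end trim -> length ->
## divergence/long-branch flags -> missing-species re-check -> reading frame.
## Every edit is logged; replaying the log on the raw alignment reproduces
## the curated matrix exactly.

#' Curation configuration
#'
#' @param min_length Minimum alignment length (bp) to keep a locus.
#' @param min_ungapped Minimum ungapped length of the shortest sequence.
#' @param max_missing_species Maximum missing species before discarding.
#' @param trim_trigger End trimming starts when the missing fraction in the
#'   terminal column exceeds this (default 1/3).
#' @param trim_stop Columns are stripped while their missing fraction is at
#'   least this (default 1/2); trimming never touches interior columns.
#' @param divergence_z Robust (MAD-based) z-score above which a taxon's
#'   median pairwise distance flags it as divergent.
#' @param long_branch_ratio Terminal branches longer than this multiple of
#'   the median terminal branch flag the taxon.
#' @param count_gaps_as_missing Treat '-' as missing state in trimming and
#'   missing-species accounting (as well as 'N'/'?').
#' @param min_taxa_for_flagging Distance/branch flagging is disabled below
#'   this many taxa.
#' @return List of class `curation_config`.
#' @export
curation_config <- function(min_length = 450, min_ungapped = 150,
                            max_missing_species = 2,
                            trim_trigger = 1 / 3, trim_stop = 1 / 2,
                            divergence_z = 3.5, long_branch_ratio = 5,
                            count_gaps_as_missing = TRUE,
                            min_taxa_for_flagging = 5) {
  structure(list(min_length = min_length, min_ungapped = min_ungapped,
                 max_missing_species = max_missing_species,
                 trim_trigger = trim_trigger, trim_stop = trim_stop,
                 divergence_z = divergence_z,
                 long_branch_ratio = long_branch_ratio,
                 count_gaps_as_missing = count_gaps_as_missing,
                 min_taxa_for_flagging = min_taxa_for_flagging),
            class = "curation_config")
}

#' Align a homolog set
#'
#' Default backend is an internal centre-star progressive aligner (each
#' sequence is aligned to the longest sequence with an ends-free affine-gap
#' pairwise alignment; insertions relative to the centre are merged into
#' shared columns), so the pipeline runs with no external binary.  `mafft`
#' can be selected when the binary is on the PATH.
#'
#' @param sequences Named character vector (>= 2 sequences).
#' @param backend `"internal"` or `"mafft"`.
#' @return Character matrix (taxa x columns, gap `-`) with attribute
#'   `backend` recording which aligner ran.
#' @export
align_set <- function(sequences, backend = c("internal", "mafft")) {
  backend <- match.arg(backend)
  stopifnot(length(sequences) >= 2, !is.null(names(sequences)))
  if (backend == "mafft") {
    if (Sys.which("mafft") == "")
      stop("mafft not found on PATH")
    tmp_in <- tempfile(fileext = ".fasta")
    tmp_out <- tempfile(fileext = ".fasta")
    on.exit(unlink(c(tmp_in, tmp_out)), add = TRUE)
    writeLines(paste0(">", names(sequences), "\n", sequences), tmp_in)
    status <- system2("mafft", c("--auto", "--quiet", tmp_in),
                      stdout = tmp_out, stderr = FALSE)
    if (status != 0) stop("mafft failed with status ", status)
    ss <- Biostrings::readDNAStringSet(tmp_out)
    m <- seqs_to_matrix(stats::setNames(toupper(as.character(ss)),
                                        names(ss)))
    m <- m[names(sequences), , drop = FALSE]
  } else {
    m <- center_star_align(sequences)
  }
  attr(m, "backend") <- backend
  m
}

## Centre-star progressive alignment.  The longest sequence is the centre;
## every other sequence is aligned to it ends-free; insertions relative to
## the centre are merged (left-aligned within their slot).
center_star_align <- function(seqs) {
  seqs <- toupper(seqs)
  if (length(seqs) == 1) return(seqs_to_matrix(seqs))
  ci <- which.max(nchar(seqs))
  center <- seqs[[ci]]
  Lc <- nchar(center)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                 baseOnly = FALSE)
  ins <- integer(Lc + 1)  # ins[g + 1]: max insertion length after centre pos g
  parsed <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    if (i == ci) next
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(seqs[[i]]), Biostrings::DNAString(center),
      type = "overlap", substitutionMatrix = sm,
      gapOpening = 6, gapExtension = 1)
    p <- seq_chars(as.character(Biostrings::alignedPattern(pa)))
    s <- seq_chars(as.character(Biostrings::alignedSubject(pa)))
    ps <- Biostrings::start(Biostrings::pattern(pa))
    pe <- Biostrings::end(Biostrings::pattern(pa))
    ss <- Biostrings::start(Biostrings::subject(pa))
    se <- Biostrings::end(Biostrings::subject(pa))
    chars_at <- rep(NA_character_, Lc)
    ins_i <- vector("list", Lc + 1)
    spos <- ss - 1L
    for (col in seq_along(s)) {
      if (s[col] == "-") {
        ins_i[[spos + 1L]] <- c(ins_i[[spos + 1L]], p[col])
      } else {
        spos <- spos + 1L
        if (p[col] != "-") chars_at[spos] <- p[col] else chars_at[spos] <- "-"
      }
    }
    ## unaligned flanks: backfill centre positions ungapped, overflow becomes
    ## terminal insertions
    if (ps > 1) {
      left <- seq_chars(substr(seqs[[i]], 1, ps - 1))
      npre <- min(length(left), ss - 1L)
      if (npre > 0)
        chars_at[(ss - npre):(ss - 1L)] <-
          left[(length(left) - npre + 1L):length(left)]
      if (length(left) > npre)
        ins_i[[1L]] <- c(left[seq_len(length(left) - npre)], ins_i[[1L]])
    }
    if (pe < nchar(seqs[[i]])) {
      right <- seq_chars(substr(seqs[[i]], pe + 1, nchar(seqs[[i]])))
      npost <- min(length(right), Lc - se)
      if (npost > 0) chars_at[(se + 1L):(se + npost)] <- right[seq_len(npost)]
      if (length(right) > npost)
        ins_i[[Lc + 1L]] <- c(ins_i[[Lc + 1L]],
                              right[(npost + 1L):length(right)])
    }
    parsed[[i]] <- list(chars_at = chars_at, ins = ins_i)
    ins <- pmax(ins, vapply(ins_i, length, integer(1)))
  }
  csl <- cumsum(ins)  # csl[p]: insertion columns in slots 0..p-1
  col_of_center <- seq_len(Lc) + csl[seq_len(Lc)]
  width <- Lc + csl[Lc + 1L]
  out <- matrix("-", nrow = length(seqs), ncol = width,
                dimnames = list(names(seqs), NULL))
  out[ci, col_of_center] <- seq_chars(center)
  slot_start <- c(1L, col_of_center + 1L)  # first column of slot g (g=0..Lc)
  for (i in seq_along(seqs)) {
    if (i == ci) next
    pp <- parsed[[i]]
    filled <- !is.na(pp$chars_at)
    out[i, col_of_center[filled]] <- pp$chars_at[filled]
    for (g in which(lengths(pp$ins) > 0)) {
      v <- pp$ins[[g]]
      out[i, slot_start[g] + seq_along(v) - 1L] <- v
    }
  }
  out
}

## Missing fraction per column.
column_missing_fraction <- function(m, count_gaps = TRUE) {
  colMeans(matrix(is_missing_char(m, count_gaps), nrow = nrow(m)))
}

#' Missing-species filter
#'
#' @param alignment Character matrix (taxa x columns).
#' @param expected_taxa Character vector of taxa expected in the study.
#' @param max_missing Maximum missing species tolerated.
#' @return `TRUE` (keep) or `FALSE` (discard).  A species counts missing if
#'   it is absent from the alignment or entirely gap/N.
#' @export
filter_missing_species <- function(alignment, expected_taxa,
                                   max_missing = 2) {
  present <- rownames(alignment)
  all_missing <- rowMeans(matrix(is_missing_char(alignment, TRUE),
                                 nrow = nrow(alignment))) >= 1
  present <- present[!all_missing]
  length(setdiff(expected_taxa, present)) <= max_missing
}

#' Trim alignment ends with high missing-data fractions
#'
#' Scanning inward from each end: if the terminal column's missing fraction
#' exceeds `start_fraction`, consecutive terminal columns with missing
#' fraction at least `stop_fraction` are removed; trimming stops at the
#' first column below `stop_fraction`.  Interior columns are never touched.
#'
#' @param alignment Character matrix.
#' @param start_fraction Trigger fraction (default 1/3).
#' @param stop_fraction Stop fraction (default 1/2).
#' @param count_gaps Count '-' as missing.
#' @return The trimmed matrix with attribute `trimmed = c(left, right)`
#'   giving the number of columns removed at each end.
#' @export
trim_ends <- function(alignment, start_fraction = 1 / 3,
                      stop_fraction = 1 / 2, count_gaps = TRUE) {
  frac <- column_missing_fraction(alignment, count_gaps)
  n <- length(frac)
  left <- 0L
  if (n > 0 && frac[1] > start_fraction)
    while (left < n && frac[left + 1L] >= stop_fraction) left <- left + 1L
  right <- 0L
  if (n - left > 0 && frac[n] > start_fraction)
    while (right < n - left && frac[n - right] >= stop_fraction)
      right <- right + 1L
  out <- alignment[, if (left + right >= n) integer(0) else
    (left + 1L):(n - right), drop = FALSE]
  attr(out, "trimmed") <- c(left = left, right = right)
  out
}

#' Length filter
#'
#' @param alignment Character matrix.
#' @param min_length Minimum number of columns (default 450).
#' @param min_ungapped Minimum ungapped length of the shortest sequence
#'   (default 150).
#' @return `TRUE` (keep) or `FALSE` (discard).
#' @export
filter_length <- function(alignment, min_length = 450, min_ungapped = 150) {
  if (ncol(alignment) < min_length) return(FALSE)
  ungapped <- rowSums(matrix(!is_missing_char(alignment, TRUE),
                             nrow = nrow(alignment)))
  min(ungapped) >= min_ungapped
}

#' Flag taxa with unusually high pairwise divergence
#'
#' A taxon is flagged when its median pairwise p-distance exceeds the
#' across-taxa median of those medians by more than `z_threshold` robust
#' standard deviations (MAD-based) *and* by at least 50 % in relative terms.
#' The relative guard keeps the MAD criterion from firing on tightly
#' clustered distances, where the robust scale estimate collapses and tiny
#' fluctuations otherwise produce huge z-scores.  Flagging is disabled
#' below 5 taxa.
#'
#' @param alignment Character matrix.
#' @param z_threshold Robust z threshold (default 3.5).
#' @return A `distance_report` list: `distances` (p-distance matrix),
#'   `median_distance` (per taxon), `z` (robust z-scores), `flagged`
#'   (taxon labels), `alignment` (with flagged rows removed).
#' @export
flag_divergent_taxa <- function(alignment, z_threshold = 3.5) {
  n <- nrow(alignment)
  if (n < 5) {
    return(structure(list(distances = NULL, median_distance = NULL,
                          z = NULL, flagged = character(0),
                          alignment = alignment),
                     class = "distance_report"))
  }
  d <- distance_matrix(alignment, model = "p")
  med <- apply(d + diag(NA_real_, n), 1, stats::median, na.rm = TRUE)
  centre <- stats::median(med)
  s <- stats::mad(med)
  z <- if (s > 0) (med - centre) / s else rep(0, n)
  flagged <- rownames(alignment)[z > z_threshold & med > 1.5 * centre]
  structure(list(distances = d, median_distance = med, z = z,
                 flagged = flagged,
                 alignment = alignment[setdiff(rownames(alignment), flagged),
                                       , drop = FALSE]),
            class = "distance_report")
}

#' Flag taxa with very long terminal branches in a gene tree
#'
#' @param gene_tree `phylo` with branch lengths.
#' @param ratio_threshold Flag terminal branches longer than this multiple
#'   of the median terminal branch length.
#' @return Character vector of flagged taxon labels.
#' @export
flag_long_branch_taxa <- function(gene_tree, ratio_threshold = 5) {
  if (is.null(gene_tree$edge.length))
    stop("gene tree has no branch lengths")
  tip_edges <- match(seq_len(ape::Ntip(gene_tree)), gene_tree$edge[, 2])
  tl <- gene_tree$edge.length[tip_edges]
  med <- stats::median(tl)
  if (med <= 0) return(character(0))
  gene_tree$tip.label[tl > ratio_threshold * med]
}

#' Enforce an open reading frame on an alignment
#'
#' Chooses the frame offset (0/1/2) minimising in-frame stop codons summed
#' over taxa, then trims partial codons at both ends so the length is
#' divisible by 3.  If every frame averages more than one stop per taxon the
#' locus is flagged non-coding and passed through (frame offset
#' undetermined, length still trimmed to a codon multiple).
#'
#' @param alignment Character matrix.
#' @return The trimmed matrix with attributes `frame_offset` (0/1/2 or NA),
#'   `noncoding` (logical) and `stop_counts` (stops per frame).
#' @export
enforce_reading_frame <- function(alignment) {
  n_col <- ncol(alignment)
  stops_in_frame <- function(off) {
    usable <- n_col - off
    n_codon <- usable %/% 3
    if (n_codon == 0) return(0L)
    idx1 <- off + 3 * (seq_len(n_codon) - 1) + 1
    total <- 0L
    for (r in seq_len(nrow(alignment))) {
      c1 <- alignment[r, idx1]; c2 <- alignment[r, idx1 + 1]
      c3 <- alignment[r, idx1 + 2]
      ok <- c1 %in% DNA_BASES & c2 %in% DNA_BASES & c3 %in% DNA_BASES
      total <- total + sum(ok & c1 == "T" &
                             ((c2 == "A" & c3 %in% c("A", "G")) |
                                (c2 == "G" & c3 == "A")))
    }
    total
  }
  stops <- vapply(0:2, stops_in_frame, integer(1))
  names(stops) <- 0:2
  noncoding <- all(stops > nrow(alignment))
  off <- if (noncoding) NA_integer_ else as.integer(which.min(stops) - 1L)
  use_off <- if (noncoding) 0L else off
  usable <- ncol(alignment) - use_off
  keep <- use_off + seq_len(usable - usable %% 3)
  out <- alignment[, keep, drop = FALSE]
  attr(out, "frame_offset") <- off
  attr(out, "noncoding") <- noncoding
  attr(out, "stop_counts") <- stops
  out
}

#' Curate one homolog-set alignment
#'
#' Applies the full rule chain in fixed order (missing-species filter, end
#' trimming, length filter, divergence and long-branch flagging,
#' missing-species re-check, reading-frame enforcement), logging every edit.
#'
#' @param alignment Character matrix (from [align_set()]) or named character
#'   vector of equal-length sequences.
#' @param expected_taxa All taxa expected in the study.
#' @param config A [curation_config()].
#' @param locus_id,homolog_index Labels carried into the result.
#' @return A `curation_result`: `kept` (logical), `reason` (when discarded),
#'   `alignment` (curated matrix or NULL) and `provenance` (list of logged
#'   edits; see [replay_provenance()]).
#' @export
curate_alignment <- function(alignment, expected_taxa,
                             config = curation_config(),
                             locus_id = "locus", homolog_index = 1L) {
  if (!is.matrix(alignment)) alignment <- seqs_to_matrix(alignment)
  prov <- list()
  log_edit <- function(op, ...) prov[[length(prov) + 1L]] <<-
    c(list(op = op), list(...))
  discard <- function(reason) {
    structure(list(kept = FALSE, reason = reason, alignment = NULL,
                   locus_id = locus_id, homolog_index = homolog_index,
                   provenance = prov), class = "curation_result")
  }

  if (!filter_missing_species(alignment, expected_taxa,
                              config$max_missing_species))
    return(discard("missing_species"))

  trimmed <- trim_ends(alignment, config$trim_trigger, config$trim_stop,
                       config$count_gaps_as_missing)
  tr <- attr(trimmed, "trimmed")
  if (any(tr > 0)) log_edit("trim_ends", left = unname(tr["left"]),
                            right = unname(tr["right"]))
  alignment <- trimmed

  if (!filter_length(alignment, config$min_length, config$min_ungapped))
    return(discard("length"))

  if (nrow(alignment) >= config$min_taxa_for_flagging) {
    rep_d <- flag_divergent_taxa(alignment, config$divergence_z)
    flagged <- rep_d$flagged
    gt <- tryCatch(nj_tree(distance_matrix(alignment, model = "JC69")),
                   error = function(e) NULL)
    if (!is.null(gt))
      flagged <- union(flagged,
                       flag_long_branch_taxa(gt, config$long_branch_ratio))
    if (length(flagged)) {
      log_edit("remove_taxa", taxa = flagged)
      alignment <- alignment[setdiff(rownames(alignment), flagged), ,
                             drop = FALSE]
      if (!filter_missing_species(alignment, expected_taxa,
                                  config$max_missing_species))
        return(discard("missing_species_after_editing"))
    }
  }

  framed <- enforce_reading_frame(alignment)
  off <- attr(framed, "frame_offset")
  cut <- ncol(alignment) - ncol(framed)
  if (cut > 0 || isTRUE(off > 0))
    log_edit("frame_trim",
             offset = ifelse(is.na(off), 0L, off),
             length = ncol(framed))
  structure(list(kept = TRUE, reason = NA_character_, alignment = framed,
                 locus_id = locus_id, homolog_index = homolog_index,
                 frame_offset = off,
                 noncoding = attr(framed, "noncoding"),
                 provenance = prov), class = "curation_result")
}

#' Replay a curation provenance log on the raw alignment
#'
#' @param alignment The raw (pre-curation) matrix.
#' @param provenance A provenance list from [curate_alignment()].
#' @return The matrix with all logged edits re-applied.
#' @export
replay_provenance <- function(alignment, provenance) {
  for (ed in provenance) {
    alignment <- switch(ed$op,
      trim_ends = {
        n <- ncol(alignment)
        alignment[, (ed$left + 1L):(n - ed$right), drop = FALSE]
      },
      remove_taxa = alignment[setdiff(rownames(alignment), ed$taxa), ,
                              drop = FALSE],
      frame_trim = alignment[, ed$offset + seq_len(ed$length),
                             drop = FALSE],
      stop("unknown provenance op: ", ed$op))
  }
  alignment
}

#' Curate all homolog sets from a paralog picking
#'
#' @param picking A `paralog_picking` from [pick_paralogs()], or a plain
#'   list of `homolog_set` objects.
#' @param expected_taxa All study taxa.
#' @param config A [curation_config()].
#' @param backend Aligner backend for [align_set()].
#' @return List with `curated` (kept `curation_result`s, named
#'   `{locus}_h{set}`) and `discarded` (data frame locus/set/reason).
#' @export
curate_all <- function(picking, expected_taxa, config = curation_config(),
                       backend = "internal") {
  sets <- if (inherits(picking, "paralog_picking")) picking$sets else picking
  curated <- list(); discarded <- list()
  for (hs in sets) {
    if (length(hs$members) < 2) next
    raw <- tryCatch(align_set(hs$members, backend = backend),
                    error = function(e) NULL)
    if (is.null(raw)) {
      discarded[[length(discarded) + 1L]] <-
        data.frame(locus = hs$locus_id, set = hs$set_index,
                   reason = "alignment_failed", stringsAsFactors = FALSE)
      next
    }
    res <- curate_alignment(raw, expected_taxa, config,
                            locus_id = hs$locus_id,
                            homolog_index = hs$set_index)
    if (res$kept) {
      curated[[sprintf("%s_h%d", hs$locus_id, hs$set_index)]] <- res
    } else {
      discarded[[length(discarded) + 1L]] <-
        data.frame(locus = hs$locus_id, set = hs$set_index,
                   reason = res$reason, stringsAsFactors = FALSE)
    }
  }
  list(curated = curated, discarded = do.call(rbind, discarded))
}
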