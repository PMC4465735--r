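## Seed-and-extend majority-rule consensus assembly of capture reads.
##
## Contract (mirroring the original in-house assembler): reads are mapped to
## per-locus references with divergence-tolerant spaced k-mers; the
## best-matching read anchors a stack; other reads join only with >= 20 bp
## overlap at >= 95 % identity, which keeps paralogous copies in separate
## stacks; the majority-rule consensus (2x minimum depth) seeds an extension
## phase with multiple passes over the read pool; rounds on the reduced pool
## produce one additional consensus per locus while new seeds arise.

#' Assembly configuration
#'
#' @param min_overlap Minimum read/stack overlap in bp (comparable columns).
#' @param min_identity Minimum identity in the overlap for a read to join.
#' @param min_depth Minimum per-column depth for the reported consensus.
#' @param capture_min_length A locus counts as captured when some round's
#'   contig is strictly longer than this (bp).
#' @param max_rounds Cap on assembly rounds per locus (the observed number of
#'   homolog sets per locus never exceeds five).
#' @param min_new_contig Rounds stop when no new contig of at least this many
#'   bp arises.
#' @param mask Spaced-seed care/don't-care mask (see [spaced_mask()]).
#' @param max_map_divergence Maximum read-to-reference divergence tolerated
#'   at mapping: a shared spaced key only maps a read when the ungapped
#'   identity on that diagonal is at least `1 - max_map_divergence`.
#' @param min_map_overlap Minimum read/reference overlap (bp) for the
#'   mapping identity check (clipped to the read length).
#' @return A list of class `assembly_config`.
#' @export
assembly_config <- function(min_overlap = 20, min_identity = 0.95,
                            min_depth = 2, capture_min_length = 350,
                            max_rounds = 5, min_new_contig = 20,
                            mask = spaced_mask(), max_map_divergence = 0.45,
                            min_map_overlap = 40) {
  structure(list(min_overlap = min_overlap, min_identity = min_identity,
                 min_depth = min_depth,
                 capture_min_length = capture_min_length,
                 max_rounds = max_rounds, min_new_contig = min_new_contig,
                 mask = mask, max_map_divergence = max_map_divergence,
                 min_map_overlap = min_map_overlap),
            class = "assembly_config")
}

#' Spaced-seed mask
#'
#' Weight-8 care positions spread over a 24 bp span; don't-care positions
#' between them absorb mismatches, so a single key tolerates substantial
#' sequence divergence between read and reference.
#'
#' @param weight Number of care positions.
#' @param span Total mask span in bp.
#' @return Logical vector of length `span`, `TRUE` at care positions.
#' @export
spaced_mask <- function(weight = 8, span = 24) {
  stopifnot(weight >= 2, span >= weight)
  m <- rep(FALSE, span)
  m[round(seq(1, span, length.out = weight))] <- TRUE
  m
}

## Extract spaced keys from a char vector: keys[i] is the key of the window
## starting at pos[i] (1-based).
spaced_keys <- function(chars, mask) {
  span <- length(mask)
  L <- length(chars)
  if (L < span) return(list(keys = character(0), pos = integer(0)))
  starts <- seq_len(L - span + 1L)
  care <- which(mask) - 1L
  km <- matrix(chars[outer(starts, care, "+")], nrow = length(starts))
  list(keys = do.call(paste0, as.data.frame(km, stringsAsFactors = FALSE)),
       pos = starts)
}

#' Spaced k-mer index of a reference sequence
#'
#' @param reference Reference sequence (single string).
#' @param pattern Logical care/don't-care mask (default [spaced_mask()]).
#' @return A named list mapping each spaced key to the 1-based window start
#'   positions at which it occurs; empty when the reference is shorter than
#'   the mask span.
#' @export
spaced_kmer_index <- function(reference, pattern = spaced_mask()) {
  sk <- spaced_keys(seq_chars(reference), pattern)
  split(sk$pos, sk$keys)
}

#' Map reads to locus references with spaced seeds
#'
#' A read maps to a locus when, on either strand, it shares at least one
#' spaced key with the reference and the ungapped identity on that key's
#' diagonal is at least `1 - max_map_divergence` over an overlap of at least
#' `min_map_overlap` bp (clipped to the read length).  The identity check
#' is what bounds the tolerated divergence; the spaced key is only the
#' divergence-tolerant lookup.  For each mapped (read, locus) pair the best
#' diagonal is reported: `offset` is the 1-based reference position of the
#' read's first base and `identity` the ungapped identity over the overlap.
#'
#' @param reads Data frame with columns `id`, `bases`.
#' @param references Named character vector, locus -> reference sequence.
#' @param config An [assembly_config()].
#' @return Data frame: read_id, locus, strand, offset, identity, overlap,
#'   hits.  Reads may map to several loci; unmapped reads are absent.
#' @export
map_reads_to_references <- function(reads, references,
                                    config = assembly_config()) {
  mask <- config$mask
  ref_chars <- lapply(references, seq_chars)
  refk <- lapply(ref_chars, spaced_keys, mask = mask)
  nk <- vapply(refk, function(x) length(x$keys), integer(1))
  all_keys <- unlist(lapply(refk, `[[`, "keys"), use.names = FALSE)
  all_pos <- unlist(lapply(refk, `[[`, "pos"), use.names = FALSE)
  all_loc <- rep(seq_along(refk), nk)
  uk <- unique(all_keys)
  kid <- match(all_keys, uk)
  by_key <- split(seq_along(all_keys), factor(kid, levels = seq_along(uk)))

  out <- vector("list", nrow(reads) * 2L)
  n_out <- 0L
  for (i in seq_len(nrow(reads))) {
    for (strand in c("+", "-")) {
      b <- if (strand == "+") reads$bases[i] else revcomp(reads$bases[i])
      rc <- seq_chars(b)
      rk <- spaced_keys(rc, mask)
      ids <- match(rk$keys, uk)
      keep <- which(!is.na(ids))
      if (!length(keep)) next
      hit_lists <- by_key[ids[keep]]
      rows <- unlist(hit_lists, use.names = FALSE)
      readpos <- rep(rk$pos[keep], lengths(hit_lists))
      loc <- all_loc[rows]
      dg <- all_pos[rows] - readpos
      key <- paste0(loc, ":", dg)
      tab <- table(key)
      parts <- strsplit(names(tab), ":", fixed = TRUE)
      locs <- vapply(parts, function(p) as.integer(p[1]), integer(1))
      dgs <- vapply(parts, function(p) as.integer(p[2]), integer(1))
      min_ov <- min(config$min_map_overlap, length(rc))
      min_id <- 1 - config$max_map_divergence
      for (l in unique(locs)) {
        sel <- which(locs == l)
        ## evaluate candidate diagonals, best-supported first
        sel <- sel[order(-tab[sel])]
        best <- NULL
        for (s in sel[seq_len(min(5L, length(sel)))]) {
          off <- dgs[s] + 1L  # ref position of read base 1
          idov <- ungapped_identity(rc, off, ref_chars[[l]])
          if (idov[1] >= min_ov && idov[2] >= min_id &&
              (is.null(best) || idov[2] > best$identity))
            best <- list(offset = off, identity = idov[2],
                         overlap = idov[1], hits = as.integer(tab[s]))
        }
        if (is.null(best)) next
        n_out <- n_out + 1L
        out[[n_out]] <- data.frame(
          read_id = reads$id[i], locus = names(references)[l],
          strand = strand, offset = best$offset, identity = best$identity,
          overlap = as.integer(best$overlap), hits = best$hits,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (n_out == 0L)
    return(data.frame(read_id = character(0), locus = character(0),
                      strand = character(0), offset = integer(0),
                      identity = numeric(0), overlap = integer(0),
                      hits = integer(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out[seq_len(n_out)])
  ## keep the best strand per (read, locus)
  o <- order(res$read_id, res$locus, -res$hits, -res$identity)
  res <- res[o, , drop = FALSE]
  res[!duplicated(res[c("read_id", "locus")]), , drop = FALSE]
}

## Ungapped identity of read placed at ref position `off` (1-based position
## of read base 1).  Returns c(overlap, identity) over comparable columns.
ungapped_identity <- function(read_chars, off, ref_chars) {
  a <- max(1L, off)
  b <- min(length(ref_chars), off + length(read_chars) - 1L)
  if (a > b) return(c(0, 0))
  rr <- ref_chars[a:b]
  qq <- read_chars[(a - off + 1L):(b - off + 1L)]
  cmp <- rr %in% DNA_BASES & qq %in% DNA_BASES
  n <- sum(cmp)
  if (n == 0) return(c(0, 0))
  c(n, sum(rr[cmp] == qq[cmp]) / n)
}

#' Choose the anchor (best-matching) read for a locus
#'
#' @param mapped Data frame of mapping rows for one locus (as produced by
#'   [map_reads_to_references()]).
#' @param reads Data frame with `id`, `bases` (for the length tie-break).
#' @return The anchor `read_id`: highest identity to the reference, ties
#'   broken by longer read, then lexicographically smaller id.
#' @export
choose_anchor_read <- function(mapped, reads) {
  if (nrow(mapped) == 0) stop("no mapped reads")
  len <- nchar(reads$bases)[match(mapped$read_id, reads$id)]
  o <- order(-mapped$identity, -len, mapped$read_id)
  mapped$read_id[o[1]]
}

## ---- stack machinery ------------------------------------------------------
## A stack lives on a global coordinate axis (the reference frame when
## offsets come from mapping).  State: base counts (4 x width matrix starting
## at `origin`), working consensus (majority over all reads, depth >= 1,
## ties resolved towards the previous consensus else IUPAC).

new_stack <- function(origin, width) {
  counts <- matrix(0L, nrow = 4, ncol = width,
                   dimnames = list(DNA_BASES, NULL))
  list(counts = counts, origin = origin, reads = character(0),
       offsets = integer(0), cons = rep("", width))
}

stack_add_read <- function(stack, read_chars, off, read_id) {
  idx <- (off - stack$origin + 1L):(off - stack$origin + length(read_chars))
  ok <- read_chars %in% DNA_BASES & idx >= 1 & idx <= ncol(stack$counts)
  j <- idx[ok]
  stack$counts[cbind(match(read_chars[ok], DNA_BASES), j)] <-
    stack$counts[cbind(match(read_chars[ok], DNA_BASES), j)] + 1L
  stack$reads <- c(stack$reads, read_id)
  stack$offsets <- c(stack$offsets, off)
  stack
}

## Majority call per column over all reads (depth >= 1); tie -> previous
## consensus base when among the tied set, else IUPAC ambiguity.
stack_consense <- function(stack) {
  counts <- stack$counts
  depth <- colSums(counts)
  mx <- apply(counts, 2, max)
  cons <- character(ncol(counts))
  for (j in which(depth > 0)) {
    top <- DNA_BASES[counts[, j] == mx[j]]
    cons[j] <- if (length(top) == 1L) top
    else if (stack$cons[j] %in% top) stack$cons[j]
    else iupac_code(top)
  }
  stack$cons <- cons
  stack
}

#' Stack reads on an anchor and take the majority-rule consensus
#'
#' Each read is tried once against the growing stack (anchor first): it is
#' placed at its mapping offset, or located by exact k-mer diagonal voting
#' when no offset is supplied, and joins only if it overlaps the current
#' working consensus by at least `min_overlap` comparable bp at
#' `min_identity` or better.  The reported consensus applies the minimum
#' depth rule: columns below `min_depth` become N, and such columns are
#' trimmed from the contig ends.
#'
#' @param anchor Anchor read id.
#' @param reads Data frame `id`, `bases` (oriented; see
#'   [map_reads_to_references()] for strand handling).
#' @param offsets Optional named integer vector read_id -> global offset of
#'   the read's first base (e.g. reference-frame offsets from mapping).
#' @param config An [assembly_config()].
#' @return A list: `consensus` (reported contig string, 2x rule applied),
#'   `working` (depth >= 1 consensus chars), `origin` (global coordinate of
#'   `working[1]`), `depth`, `reads` (ids placed), `offsets`.
#' @export
stack_and_consense <- function(anchor, reads, offsets = NULL,
                               config = assembly_config()) {
  stopifnot(anchor %in% reads$id)
  chars <- lapply(reads$bases, seq_chars)
  names(chars) <- reads$id
  have_off <- !is.null(offsets)
  a_off <- if (have_off) offsets[[anchor]] else 1L
  lens <- nchar(reads$bases)
  if (have_off) {
    origin <- min(offsets); width <- max(offsets + lens[match(names(offsets),
                                                              reads$id)]) -
      origin
  } else {
    origin <- 1L - max(lens); width <- 3L * max(lens)
  }
  stack <- new_stack(as.integer(origin), as.integer(width))
  stack <- stack_add_read(stack, chars[[anchor]], as.integer(a_off), anchor)
  stack <- stack_consense(stack)

  others <- setdiff(reads$id, anchor)
  for (rid in others) {
    rc <- chars[[rid]]
    off <- if (have_off && rid %in% names(offsets)) offsets[[rid]]
    else find_offset(rc, stack$cons, stack$origin)
    if (is.na(off)) next
    ov <- consensus_identity(rc, off, stack)
    if (ov[1] >= config$min_overlap && ov[2] >= config$min_identity) {
      stack <- stack_add_read(stack, rc, as.integer(off), rid)
      stack <- stack_consense(stack)
    }
  }
  finish_stack(stack, config)
}

## Identity of a read against the current working consensus.
consensus_identity <- function(read_chars, off, stack) {
  rel <- off - stack$origin + 1L
  a <- max(1L, rel)
  b <- min(ncol(stack$counts), rel + length(read_chars) - 1L)
  if (a > b) return(c(0, 0))
  cc <- stack$cons[a:b]
  qq <- read_chars[(a - rel + 1L):(b - rel + 1L)]
  cmp <- cc %in% DNA_BASES & qq %in% DNA_BASES
  n <- sum(cmp)
  if (n == 0) return(c(0, 0))
  c(n, sum(cc[cmp] == qq[cmp]) / n)
}

## Locate a read against a consensus by exact k-mer diagonal voting.
## Returns the global offset of read base 1, or NA.
find_offset <- function(read_chars, cons_chars, origin, k = 12L) {
  cons_chars[cons_chars == ""] <- "?"
  L <- length(cons_chars)
  if (L < k || length(read_chars) < k) return(NA_integer_)
  cs <- substring(chars_seq(cons_chars), seq_len(L - k + 1L),
                  seq_len(L - k + 1L) + k - 1L)
  rs <- substring(chars_seq(read_chars), seq_len(length(read_chars) - k + 1L),
                  seq_len(length(read_chars) - k + 1L) + k - 1L)
  m <- match(rs, cs)
  hit <- which(!is.na(m))
  if (!length(hit)) return(NA_integer_)
  dg <- m[hit] - hit  # consensus index minus read index
  best <- as.integer(names(sort(table(dg), decreasing = TRUE))[1])
  origin + best
}

## Apply the min-depth rule and end trimming; returns the public fields.
finish_stack <- function(stack, config) {
  depth <- colSums(stack$counts)
  good <- which(depth >= config$min_depth)
  if (!length(good)) {
    return(list(consensus = "", working = stack$cons, origin = stack$origin,
                depth = depth, reads = stack$reads, offsets = stack$offsets))
  }
  span <- good[1]:good[length(good)]
  calls <- stack$cons[span]
  calls[depth[span] < config$min_depth] <- "N"
  list(consensus = chars_seq(calls), working = stack$cons,
       origin = stack$origin, depth = depth, reads = stack$reads,
       offsets = stack$offsets,
       contig_start = stack$origin + span[1] - 1L)
}

#' Grow a seed consensus outward over a read pool
#'
#' Repeated passes over the pool: any unused read overlapping the current
#' working consensus by `min_overlap` comparable bp at `min_identity` or
#' better is added; after each pass the consensus is re-taken.  Iteration
#' stops when a pass adds nothing.  Reads consumed are reported so the
#' caller can reduce the pool.
#'
#' @param seed A stack result from [stack_and_consense()] (or a list with at
#'   least `working`, `origin`, `reads`, `offsets`).
#' @param pool Data frame `id`, `bases` of candidate reads (oriented).
#' @param offsets Optional named global offsets for pool reads (reference
#'   frame); reads without an offset are located by k-mer voting.
#' @param config An [assembly_config()].
#' @return Same shape as [stack_and_consense()]'s return value.
#' @export
extend_assembly <- function(seed, pool, offsets = NULL,
                            config = assembly_config()) {
  ## rebuild stack state from the seed
  lens <- nchar(pool$bases)
  lo <- min(seed$origin,
            if (!is.null(offsets) && length(offsets)) min(offsets) else
              seed$origin)
  hi <- max(seed$origin + length(seed$working),
            if (!is.null(offsets) && length(offsets))
              max(offsets + lens[match(names(offsets), pool$id)]) else
                seed$origin + length(seed$working)) + max(lens, 0)
  stack <- new_stack(as.integer(lo - max(lens, 0)),
                     as.integer(hi - lo + 2L * max(lens, 0)))
  ## replay seed reads if available, else seat the seed consensus itself
  if (length(seed$reads) && !is.null(seed$offsets) &&
      length(seed$offsets) == length(seed$reads) &&
      !is.null(seed$read_bases)) {
    for (i in seq_along(seed$reads))
      stack <- stack_add_read(stack, seq_chars(seed$read_bases[i]),
                              seed$offsets[i], seed$reads[i])
  } else {
    ## seat the working consensus with weight 2 so it satisfies min_depth
    sc <- seed$working
    for (w in 1:2)
      stack <- stack_add_read(stack, sc, as.integer(seed$origin),
                              paste0("__seed", w))
    stack$reads <- character(0); stack$offsets <- integer(0)
  }
  stack <- stack_consense(stack)

  chars <- lapply(pool$bases, seq_chars)
  names(chars) <- pool$id
  unused <- setdiff(pool$id, seed$reads)
  repeat {
    added <- FALSE
    placed <- character(0)
    for (rid in unused) {
      rc <- chars[[rid]]
      off <- if (!is.null(offsets) && rid %in% names(offsets))
        offsets[[rid]] else find_offset(rc, stack$cons, stack$origin)
      if (is.na(off)) next
      ov <- consensus_identity(rc, off, stack)
      if (ov[1] >= config$min_overlap && ov[2] >= config$min_identity) {
        stack <- stack_add_read(stack, rc, as.integer(off), rid)
        placed <- c(placed, rid)
        added <- TRUE
      }
    }
    unused <- setdiff(unused, placed)
    stack <- stack_consense(stack)
    if (!added) break
  }
  out <- finish_stack(stack, config)
  out$reads <- union(seed$reads, out$reads)
  out
}

#' Assemble all loci for all individuals
#'
#' One seed/alignment per locus per round; after each round the read pool is
#' reduced by the reads already consumed, so further rounds recover
#' additional gene copies (paralogs) whose reads failed the 95 % stacking
#' rule against the first consensus.  Rounds stop when no new contig of at
#' least `min_new_contig` bp arises, or after `max_rounds`.
#'
#' @param reads_by_individual Named list of data frames `id`, `bases`.
#' @param references Named character vector locus -> reference sequence.
#' @param config An [assembly_config()].
#' @param verbose Print per-individual progress.
#' @return An `assembly_result`: `contigs` (list of per-round contigs with
#'   locus, individual, round, bases, length, n_reads, reads), `capture`
#'   (per individual x locus: captured flag, best contig length, reads in
#'   contigs) and `summary` (per-individual capture-efficiency table: loci
#'   captured, average captured-locus length, % reads in assembly, reads per
#'   locus).
#' @export
assemble_all <- function(reads_by_individual, references,
                         config = assembly_config(), verbose = FALSE) {
  contigs <- list()
  capture_rows <- list()
  summary_rows <- list()
  loci <- sort(names(references))

  for (ind in names(reads_by_individual)) {
    reads <- reads_by_individual[[ind]]
    if (is.null(reads) || nrow(reads) == 0) {
      summary_rows[[ind]] <- data.frame(
        individual = ind, total_reads = 0L, n_contigs = 0L,
        reads_in_contigs = 0L, loci_captured = 0L, avg_locus_length = NA_real_,
        pct_reads_in_assembly = 0, reads_per_locus = NA_real_,
        stringsAsFactors = FALSE)
      next
    }
    mapped <- map_reads_to_references(reads, references, config)
    consumed <- character(0)
    reads_in_contigs <- 0L
    n_contigs_ind <- 0L
    best_len <- stats::setNames(rep(0L, length(loci)), loci)
    locus_reads <- stats::setNames(rep(0L, length(loci)), loci)

    for (round in seq_len(config$max_rounds)) {
      new_contig <- FALSE
      for (locus in loci) {
        rows <- mapped[mapped$locus == locus &
                         !(mapped$read_id %in% consumed), , drop = FALSE]
        if (nrow(rows) == 0) next
        oriented <- data.frame(
          id = rows$read_id,
          bases = ifelse(rows$strand == "+",
                         reads$bases[match(rows$read_id, reads$id)],
                         revcomp(reads$bases[match(rows$read_id,
                                                   reads$id)])),
          stringsAsFactors = FALSE)
        offs <- stats::setNames(rows$offset, rows$read_id)
        anchor <- choose_anchor_read(rows, oriented)
        seed <- stack_and_consense(anchor, oriented, offsets = offs,
                                   config = config)
        seed$read_bases <- oriented$bases[match(seed$reads, oriented$id)]
        contig <- extend_assembly(seed, oriented, offsets = offs,
                                  config = config)
        used <- contig$reads
        clen <- nchar(contig$consensus)
        if (clen >= config$min_new_contig) {
          n_contigs_ind <- n_contigs_ind + 1L
          contigs[[length(contigs) + 1L]] <- list(
            locus_id = locus, individual = ind, round_index = round,
            bases = contig$consensus, length = clen,
            n_reads = length(used), reads = used,
            start = contig$contig_start)
          reads_in_contigs <- reads_in_contigs + length(used)
          locus_reads[locus] <- locus_reads[locus] + length(used)
          if (clen > best_len[locus]) best_len[locus] <- clen
          new_contig <- TRUE
        }
        consumed <- c(consumed, used)
      }
      if (!new_contig) break
    }
    captured <- best_len > config$capture_min_length
    capture_rows[[ind]] <- data.frame(
      individual = ind, locus = loci, captured = unname(captured),
      contig_length = unname(best_len), n_reads = unname(locus_reads),
      stringsAsFactors = FALSE)
    n_cap <- sum(captured)
    summary_rows[[ind]] <- data.frame(
      individual = ind, total_reads = nrow(reads),
      n_contigs = n_contigs_ind, reads_in_contigs = reads_in_contigs,
      loci_captured = n_cap,
      avg_locus_length = if (n_cap) mean(best_len[captured]) else NA_real_,
      pct_reads_in_assembly = 100 * reads_in_contigs / nrow(reads),
      reads_per_locus = if (n_cap) reads_in_contigs / n_cap else NA_real_,
      stringsAsFactors = FALSE)
    if (verbose)
      message(sprintf("%s: %d contigs, %d/%d loci captured", ind,
                      n_contigs_ind, n_cap, length(loci)))
  }
  structure(list(contigs = contigs,
                 capture = do.call(rbind, capture_rows),
                 summary = do.call(rbind, summary_rows)),
            class = "assembly_result")
}

#' @export
print.assembly_result <- function(x, ...) {
  cat("Assembly:", length(x$contigs), "contigs,",
      length(unique(x$capture$individual)), "individuals\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Contigs of an assembly as per-individual, per-locus sequence lists
#'
#' Round order is preserved (round 1 consensus first), which downstream
#' defines the reference-sequence order of the paralog picker.
#'
#' @param assembly An `assembly_result`.
#' @param captured_only Keep only contigs longer than the capture threshold.
#' @param config An [assembly_config()] (for the threshold).
#' @return Nested list: `[[locus]][[individual]]` -> character vector of
#'   contig sequences named `{locus}_{individual}_{round}`.
#' @export
contig_sequences <- function(assembly, captured_only = FALSE,
                             config = assembly_config()) {
  out <- list()
  for (ct in assembly$contigs) {
    if (captured_only && ct$length <= config$capture_min_length) next
    nm <- sprintf("%s_%s_%d", ct$locus_id, ct$individual, ct$round_index)
    out[[ct$locus_id]][[ct$individual]] <-
      c(out[[ct$locus_id]][[ct$individual]],
        stats::setNames(ct$bases, nm))
  }
  out
}
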