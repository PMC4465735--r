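## The "paralog picker": partitions per-individual consensus sequences into
## putatively orthologous homolog sets against a reference individual.
## Six-step procedure: (1) choose the reference individual (best capture
## efficiency); (2) align every individual's consensus sequences to the
## reference individual's sequences; (3) homolog set 1 = reference sequence
## 1 plus, per individual, the best-aligning sequence; (4) remove assigned
## sequences; (5)-(6) repeat with reference sequence 2, and so on until the
## reference sequences are used up.

#' Choose the reference individual from a capture table
#'
#' The reference individual is the one with the best capture efficiency:
#' most loci captured, ties broken by larger total contig length, then
#' lexicographically.
#'
#' @param capture_table Per individual x locus data frame with columns
#'   `individual`, `captured`, `contig_length` (as produced by
#'   [assemble_all()]).
#' @return The reference individual's label.
#' @export
choose_reference_individual <- function(capture_table) {
  if (is.null(capture_table) || nrow(capture_table) == 0)
    stop("empty capture table")
  agg <- stats::aggregate(cbind(n_captured = captured,
                                total_length = contig_length) ~ individual,
                          data = capture_table, FUN = sum)
  o <- order(-agg$n_captured, -agg$total_length, agg$individual)
  agg$individual[o[1]]
}

#' Best local-alignment identity between two sequences
#'
#' The best local pairwise alignment is found with match +1, mismatch -1,
#' gap open -4, gap extend -1; the score is the number of identical aligned
#' positions divided by the length of the shorter sequence.  Normalising by
#' sequence length (rather than by the local alignment's own span) keeps
#' short spurious high-identity segments between unrelated sequences from
#' scoring like orthologs, while a partial contig overlapping the reference
#' well still scores near its true identity (up to clipped divergent ends).
#'
#' @param query,reference_seq DNA sequences (strings; IUPAC codes allowed).
#' @return Identity fraction in `[0, 1]`.
#' @export
best_alignment_score <- function(query, reference_seq) {
  stopifnot(nchar(query) > 0, nchar(reference_seq) > 0)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(reference_seq),
    type = "local", substitutionMatrix = sm,
    gapOpening = 4, gapExtension = 1)
  min(1, Biostrings::nmatch(aln) / min(nchar(query), nchar(reference_seq)))
}

## All-pairs score cache: rows = sequences (flat), cols = reference seqs.
score_matrix <- function(seqs, refs) {
  m <- matrix(0, nrow = length(seqs), ncol = length(refs))
  for (i in seq_along(seqs))
    for (j in seq_along(refs))
      m[i, j] <- best_alignment_score(seqs[[i]], refs[[j]])
  m
}

#' Assign sequences to homolog sets against reference sequences
#'
#' Iterates over the reference sequences in their extraction order; homolog
#' set k contains reference sequence k and, for each other individual, its
#' not-yet-assigned sequence scoring highest against reference k (greedy,
#' per-individual independent choice).  Assigned sequences are removed
#' before the next set.  Sequences scoring below `min_score` against every
#' remaining reference are reported unassigned rather than forced into a
#' set.
#'
#' @param sequences_by_individual Named list: individual -> named character
#'   vector of consensus sequences (multiple entries = multiple gene
#'   copies).  The reference individual may be included; its sequences are
#'   matched to the references by identity of names when present.
#' @param reference_sequences Named character vector of the reference
#'   individual's sequences, in extraction (assembly round) order.
#' @param locus_id Locus label carried through to the output.
#' @param min_score Minimum acceptance identity to join any set.
#' @param method `"greedy"` (the literal six-step reading, default) or
#'   `"optimal"` (per-individual best total-score assignment over all
#'   reference sequences, for comparison).
#' @return A list with `sets` (list of `homolog_set`: locus_id, set_index,
#'   reference_name, reference_sequence, members, member_names) and
#'   `unassigned` (data frame individual/name of leftover sequences).
#' @export
assign_homolog_sets <- function(sequences_by_individual, reference_sequences,
                                locus_id = "locus", min_score = 0.5,
                                method = c("greedy", "optimal")) {
  method <- match.arg(method)
  K <- length(reference_sequences)
  if (K == 0) {
    warning("no reference sequences for locus ", locus_id, "; skipped")
    return(list(sets = list(), unassigned = NULL))
  }
  inds <- names(sequences_by_individual)
  scores <- lapply(sequences_by_individual, function(seqs)
    score_matrix(seqs, reference_sequences))

  ## chosen[[ind]][k] = index of the sequence assigned to set k (NA = none)
  chosen <- lapply(inds, function(ind) rep(NA_integer_, K))
  names(chosen) <- inds
  for (ind in inds) {
    sc <- scores[[ind]]
    n <- nrow(sc)
    if (n == 0) next
    if (method == "greedy") {
      avail <- rep(TRUE, n)
      for (k in seq_len(K)) {
        if (!any(avail)) break
        cand <- which(avail)
        best <- cand[which.max(sc[cand, k])]
        if (sc[best, k] >= min_score) {
          chosen[[ind]][k] <- best
          avail[best] <- FALSE
        }
      }
    } else {
      ## exhaustive best assignment (copy counts are <= 5)
      slots <- seq_len(K)
      cands <- seq_len(n)
      m <- min(n, K)
      best_val <- -Inf; best_asn <- rep(NA_integer_, K)
      seq_perms <- function(v, m) {
        if (m == 0) return(list(integer(0)))
        out <- list()
        for (i in seq_along(v))
          for (rest in seq_perms(v[-i], m - 1))
            out[[length(out) + 1L]] <- c(v[i], rest)
        out
      }
      for (ks in utils::combn(slots, m, simplify = FALSE)) {
        for (perm in seq_perms(cands, m)) {
          val <- sum(sc[cbind(perm, ks)])
          if (val > best_val) {
            asn <- rep(NA_integer_, K); asn[ks] <- perm
            best_val <- val; best_asn <- asn
          }
        }
      }
      for (k in seq_len(K))
        if (!is.na(best_asn[k]) && sc[best_asn[k], k] >= min_score)
          chosen[[ind]][k] <- best_asn[k]
    }
  }

  sets <- lapply(seq_len(K), function(k) {
    members <- character(0); member_names <- character(0)
    for (ind in inds) {
      idx <- chosen[[ind]][k]
      if (!is.na(idx)) {
        members[ind] <- sequences_by_individual[[ind]][[idx]]
        member_names[ind] <- names(sequences_by_individual[[ind]])[idx]
      }
    }
    structure(list(locus_id = locus_id, set_index = k,
                   reference_name = names(reference_sequences)[k],
                   reference_sequence = unname(reference_sequences[[k]]),
                   members = members, member_names = member_names),
              class = "homolog_set")
  })
  un <- do.call(rbind, lapply(inds, function(ind) {
    n <- length(sequences_by_individual[[ind]])
    left <- setdiff(seq_len(n), stats::na.omit(chosen[[ind]]))
    if (!length(left)) return(NULL)
    data.frame(individual = ind,
               name = names(sequences_by_individual[[ind]])[left],
               stringsAsFactors = FALSE)
  }))
  list(sets = sets, unassigned = un)
}

#' Run the paralog picker over all loci of an assembly
#'
#' @param assembly An `assembly_result` from [assemble_all()].
#' @param reference_individual Reference individual; default chosen with
#'   [choose_reference_individual()].
#' @param captured_only Use only contigs above the capture length threshold.
#' @param min_score,method Passed to [assign_homolog_sets()].
#' @param config An [assembly_config()].
#' @return A `paralog_picking` list: `sets` (flat list of homolog sets over
#'   all loci), `unassigned`, `reference_individual`, `tally`
#'   (see [tally_homolog_sets()]).
#' @export
pick_paralogs <- function(assembly, reference_individual = NULL,
                          captured_only = TRUE, min_score = 0.5,
                          method = "greedy", config = assembly_config()) {
  if (is.null(reference_individual))
    reference_individual <- choose_reference_individual(assembly$capture)
  byloc <- contig_sequences(assembly, captured_only = captured_only,
                            config = config)
  sets <- list(); unassigned <- list()
  for (locus in sort(names(byloc))) {
    seqs <- byloc[[locus]]
    refs <- seqs[[reference_individual]]
    if (is.null(refs) || !length(refs)) {
      warning("locus ", locus, ": reference individual has no sequence; ",
              "skipped")
      next
    }
    others <- seqs[setdiff(names(seqs), reference_individual)]
    res <- assign_homolog_sets(others, refs, locus_id = locus,
                               min_score = min_score, method = method)
    ## the reference individual belongs to each of its own sets
    for (k in seq_along(res$sets)) {
      res$sets[[k]]$members[reference_individual] <- unname(refs[[k]])
      res$sets[[k]]$member_names[reference_individual] <- names(refs)[k]
    }
    sets <- c(sets, res$sets)
    if (!is.null(res$unassigned))
      unassigned[[locus]] <- res$unassigned
  }
  structure(list(sets = sets,
                 unassigned = do.call(rbind, unassigned),
                 reference_individual = reference_individual,
                 tally = tally_homolog_sets(sets)),
            class = "paralog_picking")
}

#' Tally homolog sets per locus
#'
#' @param sets A list of `homolog_set` objects (possibly over many loci).
#' @return A `homolog_tally` list: `per_locus` (data frame locus /
#'   n_sets), `n_loci`, `n_sets`, `distribution` (named counts over set
#'   counts present, 1 upward) and `single_set_fraction`.
#' @export
tally_homolog_sets <- function(sets) {
  if (!length(sets)) {
    return(structure(list(per_locus = data.frame(locus = character(0),
                                                 n_sets = integer(0)),
                          n_loci = 0L, n_sets = 0L,
                          distribution = integer(0),
                          single_set_fraction = NA_real_),
                     class = "homolog_tally"))
  }
  loci <- vapply(sets, `[[`, character(1), "locus_id")
  per <- as.data.frame(table(locus = loci), stringsAsFactors = FALSE)
  names(per) <- c("locus", "n_sets")
  structure(list(per_locus = per, n_loci = nrow(per),
                 n_sets = length(sets),
                 distribution = table(per$n_sets),
                 single_set_fraction = mean(per$n_sets == 1)),
            class = "homolog_tally")
}

#' @export
print.homolog_tally <- function(x, ...) {
  cat(x$n_sets, "homolog sets over", x$n_loci, "loci;",
      sprintf("%.1f%% single-set loci\n", 100 * x$single_set_fraction))
  print(x$distribution)
  invisible(x)
}
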