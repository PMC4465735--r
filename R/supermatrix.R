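## Supermatrix construction and matrix-level statistics: concatenation with
## per-locus spans and a codon map, site-variability accounting per codon
## position, three matrix-completeness definitions, GC statistics, the four
## partition schemes, and taxon subsampling.
## Internal coordinates are 0-based half-open; exported partition files use
## the de facto 1-based inclusive convention.

#' Concatenate curated alignments into a supermatrix
#'
#' @param curated_alignments Named list of character matrices, or of
#'   `curation_result` objects (their `alignment` is used).  Every alignment
#'   must be in frame with length divisible by 3.
#' @param taxon_universe Taxa forming the matrix rows; default the union of
#'   taxa over loci.  Taxa absent from a locus are padded with `N` across
#'   its span.
#' @return A `supermatrix`: `matrix` (taxa x columns), `spans` (data frame
#'   locus/start/end, 0-based half-open) and `codon_map` (1/2/3 per
#'   column).
#' @export
concatenate <- function(curated_alignments, taxon_universe = NULL) {
  mats <- lapply(curated_alignments, function(x)
    if (inherits(x, "curation_result")) x$alignment else x)
  if (is.null(names(mats)) || any(!nzchar(names(mats))))
    names(mats) <- sprintf("locus%03d", seq_along(mats))
  bad <- vapply(mats, function(m) ncol(m) %% 3 != 0, logical(1))
  if (any(bad))
    stop("alignment length not divisible by 3: ",
         paste(names(mats)[bad], collapse = ", "))
  taxa <- taxon_universe
  if (is.null(taxa)) taxa <- sort(unique(unlist(lapply(mats, rownames))))
  if (anyDuplicated(taxa)) stop("duplicate taxon labels")
  widths <- vapply(mats, ncol, integer(1))
  total <- sum(widths)
  out <- matrix("N", nrow = length(taxa), ncol = total,
                dimnames = list(taxa, NULL))
  start <- cumsum(c(0L, widths[-length(widths)]))
  for (i in seq_along(mats)) {
    m <- mats[[i]]
    rows <- intersect(taxa, rownames(m))
    out[rows, (start[i] + 1L):(start[i] + widths[i])] <-
      m[rows, , drop = FALSE]
  }
  spans <- data.frame(locus = names(mats), start = unname(start),
                      end = unname(start + widths),
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(matrix = out, spans = spans,
                 codon_map = rep_len(1:3, total)),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("Supermatrix:", nrow(x$matrix), "taxa x", ncol(x$matrix), "columns,",
      nrow(x$spans), "loci\n")
  invisible(x)
}

sm_matrix <- function(x) if (inherits(x, "supermatrix")) x$matrix else x

#' Site-variability accounting
#'
#' A column is variable iff at least two distinct unambiguous bases occur
#' among its non-missing, non-gap states; otherwise constant (all-missing
#' columns count as constant).  Reported for the whole matrix and per codon
#' position.
#'
#' @param x A `supermatrix` (or a character matrix, treated as starting at
#'   codon position 1).
#' @return Data frame with rows `whole_matrix`, `pos1`, `pos2`, `pos3` and
#'   columns `partition`, `total`, `constant`, `variable`.
#' @export
site_variability <- function(x) {
  m <- sm_matrix(x)
  cmap <- if (inherits(x, "supermatrix")) x$codon_map
  else rep_len(1:3, ncol(m))
  codes <- matrix(match(m, DNA_BASES, nomatch = 0L), nrow = nrow(m))
  n_distinct <- apply(codes, 2, function(col)
    length(unique(col[col > 0L])))
  variable <- n_distinct >= 2
  row <- function(name, sel) data.frame(
    partition = name, total = sum(sel), constant = sum(sel & !variable),
    variable = sum(sel & variable), stringsAsFactors = FALSE)
  rbind(row("whole_matrix", rep(TRUE, ncol(m))),
        row("pos1", cmap == 1), row("pos2", cmap == 2),
        row("pos3", cmap == 3))
}

#' Summarise a site-variability table
#'
#' Works on any table in the [site_variability()] layout, including
#' published site counts, and checks internal consistency (constant +
#' variable = total in every row; position totals sum to the whole-matrix
#' row).
#'
#' @param tbl Data frame with columns `partition`, `total`, `constant`,
#'   `variable`; the whole-matrix row is the one named `whole_matrix` (or
#'   the first row).
#' @return List: `percent_variable` (whole matrix, %),
#'   `third_position_share` (% of variable sites at position 3),
#'   `consistent` (logical).
#' @export
summarize_site_variability <- function(tbl) {
  stopifnot(all(c("partition", "total", "constant", "variable") %in%
                  names(tbl)))
  wi <- match("whole_matrix", tbl$partition, nomatch = 1L)
  whole <- tbl[wi, ]
  pos <- tbl[-wi, ]
  consistent <- all(tbl$constant + tbl$variable == tbl$total) &&
    sum(pos$total) == whole$total && sum(pos$variable) == whole$variable
  p3 <- pos[grepl("3", pos$partition), ]
  list(percent_variable = 100 * whole$variable / whole$total,
       third_position_share = 100 * sum(p3$variable) / whole$variable,
       consistent = consistent)
}

## Missing cells per row/span under the two completeness definitions.
missing_cells_row_span <- function(row_chars, with_indels) {
  L <- length(row_chars)
  miss <- !(row_chars %in% DNA_BASES)
  if (all(miss)) return(L)
  if (with_indels) return(sum(miss))
  lead <- match(FALSE, miss) - 1L
  trail <- L - max(which(!miss))
  lead + trail
}

#' Matrix completeness
#'
#' Three definitions: `trailing_and_missing` counts missing-locus cells plus
#' leading/trailing gap runs per species per locus span; `with_indels`
#' additionally counts interior gaps and Ns; `locus_presence` is the mean
#' over species of the percentage of loci present.
#'
#' @param x A `supermatrix`.
#' @param mode One of `"trailing_and_missing"`, `"with_indels"`,
#'   `"locus_presence"`.
#' @return Completeness percentage in `[0, 100]`.
#' @export
completeness <- function(x, mode = c("trailing_and_missing", "with_indels",
                                     "locus_presence")) {
  mode <- match.arg(mode)
  m <- sm_matrix(x)
  spans <- x$spans
  if (mode == "locus_presence") {
    pres <- presence_matrix(x)
    return(mean(100 * rowMeans(pres)))
  }
  miss <- 0
  for (i in seq_len(nrow(spans))) {
    cols <- (spans$start[i] + 1L):spans$end[i]
    for (r in seq_len(nrow(m)))
      miss <- miss + missing_cells_row_span(m[r, cols],
                                            mode == "with_indels")
  }
  100 * (1 - miss / length(m))
}

## Logical taxa x loci presence matrix (a locus is present for a species
## when its span is not entirely missing).
presence_matrix <- function(x) {
  m <- x$matrix; spans <- x$spans
  out <- matrix(FALSE, nrow(m), nrow(spans),
                dimnames = list(rownames(m), spans$locus))
  for (i in seq_len(nrow(spans))) {
    cols <- (spans$start[i] + 1L):spans$end[i]
    out[, i] <- rowSums(matrix(m[, cols] %in% DNA_BASES, nrow = nrow(m))) > 0
  }
  out
}

#' Per-species completeness table
#'
#' One row per species: percent missing data (including trailing ends and
#' indels), loci present, percent presence, ungapped alignment length and
#' mean ungapped locus length.
#'
#' @param x A `supermatrix`.
#' @return Data frame in the layout of [summarize_species_completeness()].
#' @export
species_completeness <- function(x) {
  m <- x$matrix; spans <- x$spans
  pres <- presence_matrix(x)
  ungapped <- rowSums(matrix(m %in% DNA_BASES, nrow = nrow(m)))
  pct_missing <- 100 * (1 - ungapped / ncol(m))
  n_loci <- rowSums(pres)
  data.frame(species = rownames(m),
             pct_missing = pct_missing,
             n_loci = as.integer(n_loci),
             pct_presence = 100 * n_loci / nrow(spans),
             ungapped_length = as.integer(ungapped),
             ungapped_locus_length = ungapped / pmax(n_loci, 1),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarise a per-species completeness table
#'
#' Works on any table with per-species `pct_missing` and
#' `ungapped_locus_length` columns, including published per-species
#' missing-data accountings.
#'
#' @param tbl Data frame with columns `pct_missing` and
#'   `ungapped_locus_length`.
#' @return List: `overall_completeness` (100 minus the mean percent
#'   missing) and `mean_locus_length` (mean per-species ungapped locus
#'   length, bp).
#' @export
summarize_species_completeness <- function(tbl) {
  stopifnot(all(c("pct_missing", "ungapped_locus_length") %in% names(tbl)))
  list(overall_completeness = 100 - mean(tbl$pct_missing),
       mean_locus_length = mean(tbl$ungapped_locus_length))
}

#' GC content and G-C skew
#'
#' @param x A `supermatrix` or character matrix.
#' @param ambiguity_mode `"ignore"` (GC over unambiguous A/C/G/T counts) or
#'   `"fractional"` (IUPAC codes contribute fractionally to each compatible
#'   base before the same ratio).  The skew `(G - C)/(G + C)` always uses
#'   unambiguous counts.
#' @return List: `gc_percent`, `gc_skew`, and `third_position_gc` (per
#'   species, %) when a codon map is available.
#' @export
gc_stats <- function(x, ambiguity_mode = c("ignore", "fractional")) {
  ambiguity_mode <- match.arg(ambiguity_mode)
  m <- sm_matrix(x)
  if (length(m) == 0 || all(!m %in% rownames(IUPAC_FRACTIONS)))
    stop("empty matrix")
  base_counts <- function(chars) {
    if (ambiguity_mode == "ignore") {
      cnt <- vapply(DNA_BASES, function(b) sum(chars == b), numeric(1))
    } else {
      idx <- match(chars, rownames(IUPAC_FRACTIONS), nomatch = 0L)
      cnt <- colSums(IUPAC_FRACTIONS[idx[idx > 0L], , drop = FALSE])
    }
    cnt
  }
  cnt <- base_counts(as.vector(m))
  gc <- 100 * (cnt["G"] + cnt["C"]) / sum(cnt)
  ## skew on unambiguous counts
  g <- sum(m == "G"); c <- sum(m == "C")
  skew <- if (g + c > 0) (g - c) / (g + c) else NA_real_
  out <- list(gc_percent = unname(gc), gc_skew = skew)
  if (inherits(x, "supermatrix")) {
    third <- x$codon_map == 3
    out$third_position_gc <- vapply(rownames(m), function(sp) {
      cnt <- base_counts(m[sp, third])
      s <- sum(cnt)
      if (s > 0) 100 * unname(cnt["G"] + cnt["C"]) / s else NA_real_
    }, numeric(1))
  }
  out
}

#' Build a partition scheme on a supermatrix
#'
#' @param x A `supermatrix`.
#' @param scheme_name `"by_gene"` (one block per locus), `"by_codon"`
#'   (three positional blocks), `"third_removed"` (positions 1-2 only),
#'   `"third_only"` (position 3), or `"amino_acid"` (standard-code
#'   translation; codons containing a gap, N or an in-frame stop translate
#'   to missing `X`).
#' @return A `partition_scheme`: `name`, `blocks` (named list of 1-based
#'   column indices into the supermatrix), and for `amino_acid` also
#'   `translation` (character matrix of residues).
#' @export
build_partitions <- function(x, scheme_name = c("by_gene", "by_codon",
                                                "third_removed",
                                                "third_only",
                                                "amino_acid")) {
  scheme_name <- match.arg(scheme_name)
  cmap <- x$codon_map
  blocks <- switch(scheme_name,
    by_gene = {
      b <- lapply(seq_len(nrow(x$spans)), function(i)
        (x$spans$start[i] + 1L):x$spans$end[i])
      names(b) <- x$spans$locus
      b
    },
    by_codon = list(pos1 = which(cmap == 1), pos2 = which(cmap == 2),
                    pos3 = which(cmap == 3)),
    third_removed = list(pos12 = which(cmap != 3)),
    third_only = list(pos3 = which(cmap == 3)),
    amino_acid = list(aa = seq_len(ncol(x$matrix) %/% 3))
  )
  out <- structure(list(name = scheme_name, blocks = blocks),
                   class = "partition_scheme")
  if (scheme_name == "amino_acid")
    out$translation <- translate_matrix(x$matrix)
  out
}

## Standard-code translation; any codon containing a non-ACGT char or coding
## for a stop becomes missing 'X'.
translate_matrix <- function(m) {
  gc <- Biostrings::GENETIC_CODE
  n_codon <- ncol(m) %/% 3
  idx1 <- 3 * (seq_len(n_codon) - 1) + 1
  out <- matrix("X", nrow = nrow(m), ncol = n_codon,
                dimnames = list(rownames(m), NULL))
  for (r in seq_len(nrow(m))) {
    c1 <- m[r, idx1]; c2 <- m[r, idx1 + 1]; c3 <- m[r, idx1 + 2]
    ok <- c1 %in% DNA_BASES & c2 %in% DNA_BASES & c3 %in% DNA_BASES
    aa <- rep("X", n_codon)
    aa[ok] <- unname(gc[paste0(c1[ok], c2[ok], c3[ok])])
    aa[aa == "*"] <- "X"
    out[r, ] <- aa
  }
  out
}

#' Drop taxa from a supermatrix
#'
#' Rows are removed; columns are untouched (no re-alignment), matching the
#' reduced-taxon-sampling analyses where closely related species are removed
#' to test the effect of taxon sampling on node support.
#'
#' @param x A `supermatrix`.
#' @param keep_list Taxa to keep (subset of the matrix taxa).
#' @return A `supermatrix` over the kept taxa.
#' @export
reduce_taxa <- function(x, keep_list) {
  if (length(keep_list) == 0) stop("empty keep_list")
  if (!all(keep_list %in% rownames(x$matrix)))
    stop("keep_list contains unknown taxa")
  keep <- rownames(x$matrix)[rownames(x$matrix) %in% keep_list]
  structure(list(matrix = x$matrix[keep, , drop = FALSE], spans = x$spans,
                 codon_map = x$codon_map),
            class = "supermatrix")
}
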