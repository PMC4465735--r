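## File-format interfaces: FASTA/FASTQ reads, truth maps, gene trees,
## declarative simulation configs, homolog-set FASTA, supermatrix +
## partition files (relaxed PHYLIP / FASTA / RAxML / NEXUS), and
## tab-separated summary tables.

#' Write reads as FASTA or FASTQ
#'
#' FASTQ qualities are dummy (`I` = Q40) since the generator does not model
#' base quality.
#'
#' @param reads Data frame `id`, `bases` (or a `read_set`).
#' @param file Output path.
#' @param format `"fasta"` or `"fastq"`.
#' @export
write_reads <- function(reads, file, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (inherits(reads, "read_set")) reads <- reads$reads
  x <- Biostrings::DNAStringSet(reads$bases)
  names(x) <- reads$id
  if (format == "fastq") {
    q <- Biostrings::BStringSet(strrep("I", nchar(reads$bases)))
    Biostrings::writeXStringSet(x, file, format = "fastq", qualities = q)
  } else {
    Biostrings::writeXStringSet(x, file, format = "fasta")
  }
  invisible(file)
}

#' Read reads from FASTA or FASTQ
#'
#' @param file Input path (format detected from the extension).
#' @return Data frame `id`, `bases`.
#' @export
read_reads <- function(file) {
  fastq <- grepl("\\.f(ast)?q$", file, ignore.case = TRUE)
  x <- Biostrings::readDNAStringSet(file,
                                    format = if (fastq) "fastq" else "fasta")
  data.frame(id = sub("\\s.*$", "", names(x)),
             bases = toupper(as.character(x)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param file Output path.
#' @export
write_fasta <- function(seqs, file) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, file, format = "fasta")
  invisible(file)
}

#' Read a FASTA file as a named character vector
#'
#' @param file Input path.
#' @export
read_fasta <- function(file) {
  x <- Biostrings::readDNAStringSet(file)
  stats::setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Write/read the truth map of a simulated read set
#'
#' Tab-separated columns: read_id, locus, copy, individual, start (0-based),
#' strand.
#'
#' @param truth Truth data frame (from [shear_reads()] or
#'   [simulate_capture_study()]).
#' @param file Path.
#' @export
write_truth_map <- function(truth, file) {
  utils::write.table(truth, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_truth_map
#' @export
read_truth_map <- function(file) {
  utils::read.table(file, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write per-family gene trees as newick
#'
#' @param families List of `gene_family` objects.
#' @param file Output path (one tree per line, tips `taxon@cK`).
#' @export
write_gene_trees <- function(families, file) {
  trees <- lapply(families, `[[`, "family_tree")
  class(trees) <- "multiPhylo"
  ape::write.tree(trees, file = file)
  invisible(file)
}

#' Write/read a simulation configuration as a declarative YAML file
#'
#' @param config A [simulation_config()].
#' @param file Path.
#' @export
write_simulation_config <- function(config, file) {
  vals <- unclass(config)
  ## named vectors become YAML maps (plain vectors lose their names)
  vals$subst_model$base_freq <- as.list(vals$subst_model$base_freq)
  if (!is.null(names(vals$per_species_efficiency)))
    vals$per_species_efficiency <- as.list(vals$per_species_efficiency)
  yaml::write_yaml(vals, file)
  invisible(file)
}

#' @rdname write_simulation_config
#' @export
read_simulation_config <- function(file) {
  vals <- yaml::read_yaml(file)
  vals$subst_model$base_freq <- unlist(vals$subst_model$base_freq)
  vals$per_species_efficiency <- unlist(vals$per_species_efficiency)
  do.call(simulation_config, vals)
}

#' Write homolog sets as one FASTA per set
#'
#' Files are named `{locus}_h{set_index}.fasta`; a tab-separated tally table
#' and an unassigned-sequence report accompany them.
#'
#' @param picking A `paralog_picking` from [pick_paralogs()].
#' @param dir Output directory (created if needed).
#' @export
write_homolog_sets <- function(picking, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (hs in picking$sets) {
    f <- file.path(dir, sprintf("%s_h%d.fasta", hs$locus_id, hs$set_index))
    write_fasta(hs$members, f)
  }
  utils::write.table(picking$tally$per_locus,
                     file.path(dir, "homolog_tally.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(picking$unassigned))
    utils::write.table(picking$unassigned,
                       file.path(dir, "unassigned.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write a supermatrix with its partition files
#'
#' Writes the matrix as FASTA and relaxed PHYLIP, the per-locus spans as a
#' RAxML-style partition file (1-based inclusive coordinates) and as NEXUS
#' character sets.
#'
#' @param x A `supermatrix`.
#' @param prefix Output path prefix; files `<prefix>.fasta`,
#'   `<prefix>.phy`, `<prefix>.partitions`, `<prefix>.nex` are written.
#' @export
write_supermatrix <- function(x, prefix) {
  seqs <- matrix_to_seqs(x$matrix)
  write_fasta(seqs, paste0(prefix, ".fasta"))
  con <- file(paste0(prefix, ".phy"), "w")
  writeLines(sprintf(" %d %d", nrow(x$matrix), ncol(x$matrix)), con)
  writeLines(sprintf("%s  %s", names(seqs), seqs), con)
  close(con)
  part <- sprintf("DNA, %s = %d-%d", x$spans$locus, x$spans$start + 1L,
                  x$spans$end)
  writeLines(part, paste0(prefix, ".partitions"))
  nex <- c("#NEXUS", "begin sets;",
           sprintf("  charset %s = %d-%d;", x$spans$locus,
                   x$spans$start + 1L, x$spans$end),
           "end;")
  writeLines(nex, paste0(prefix, ".nex"))
  invisible(prefix)
}

#' Read a supermatrix written by [write_supermatrix()]
#'
#' @param prefix Path prefix used at write time.
#' @return A `supermatrix` (codon map reconstructed as cycling 1/2/3).
#' @export
read_supermatrix <- function(prefix) {
  seqs <- read_fasta(paste0(prefix, ".fasta"))
  m <- seqs_to_matrix(seqs)
  part <- readLines(paste0(prefix, ".partitions"))
  mt <- regmatches(part,
                   regexec("DNA, (\\S+) = (\\d+)-(\\d+)", part))
  spans <- data.frame(
    locus = vapply(mt, `[`, character(1), 2),
    start = as.integer(vapply(mt, `[`, character(1), 3)) - 1L,
    end = as.integer(vapply(mt, `[`, character(1), 4)),
    stringsAsFactors = FALSE)
  structure(list(matrix = m, spans = spans,
                 codon_map = rep_len(1:3, ncol(m))),
            class = "supermatrix")
}

#' Write a rarefaction curve as tidy tab-separated tables
#'
#' @param curve A `rarefaction_curve`.
#' @param prefix Path prefix; `<prefix>_draws.tsv` and
#'   `<prefix>_summary.tsv` are written.
#' @export
write_rarefaction <- function(curve, prefix) {
  utils::write.table(curve$draws, paste0(prefix, "_draws.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(curve$summary, paste0(prefix, "_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Read clade definitions from a plain-text file
#'
#' One clade per line: `name: taxon1, taxon2, ...`; prefix the name with
#' `mrca:` for an MRCA-defined clade (default is taxon-set monophyly).
#'
#' @param file Path.
#' @return List of [clade_definition()]s.
#' @export
read_clade_definitions <- function(file) {
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, function(ln) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    kind <- "monophyly"
    if (length(parts) == 3 && trimws(parts[1]) == "mrca") {
      kind <- "mrca"; parts <- parts[-1]
    }
    taxa <- trimws(strsplit(parts[2], ",", fixed = TRUE)[[1]])
    clade_definition(trimws(parts[1]), taxa, kind)
  })
}
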