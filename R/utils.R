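## Small shared helpers: sequence/char conversions, IUPAC codes, seed streams.

DNA_BASES <- c("A", "C", "G", "T")

## IUPAC code for a set of bases (sorted, unique). Single base returns itself.
IUPAC_FROM_SET <- c(
  "A" = "A", "C" = "C", "G" = "G", "T" = "T",
  "AC" = "M", "AG" = "R", "AT" = "W", "CG" = "S", "CT" = "Y", "GT" = "K",
  "ACG" = "V", "ACT" = "H", "AGT" = "D", "CGT" = "B", "ACGT" = "N"
)

## Fractional base composition of IUPAC codes, used by gc_stats().
IUPAC_FRACTIONS <- local({
  sets <- list(
    A = "A", C = "C", G = "G", T = "T",
    M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
    S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
    V = c("A", "C", "G"), H = c("A", "C", "T"),
    D = c("A", "G", "T"), B = c("C", "G", "T"),
    N = c("A", "C", "G", "T")
  )
  m <- matrix(0, nrow = length(sets), ncol = 4,
              dimnames = list(names(sets), DNA_BASES))
  for (code in names(sets)) m[code, sets[[code]]] <- 1 / length(sets[[code]])
  m
})

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

chars_seq <- function(v) paste(v, collapse = "")

revcomp <- function(s) {
  chartr("ACGTNMRWSYKVHDB", "TGCANKYWSRMBDHV",
         vapply(s, function(x) chars_seq(rev(seq_chars(x))), character(1),
                USE.NAMES = FALSE))
}

iupac_code <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  code <- IUPAC_FROM_SET[key]
  if (is.na(code)) "N" else unname(code)
}

#' Derive a reproducible integer seed from a master seed and a key
#'
#' Per-locus and per-stage random streams are derived by hashing
#' `(master_seed, ...)` so that adding loci or draws never perturbs streams
#' already consumed.  The result is always in `[0, 2^31 - 2]`.
#'
#' @param master_seed Integer master seed.
#' @param ... Additional key components (coerced to character).
#' @return A single integer seed.
#' @export
derive_seed <- function(master_seed, ...) {
  key <- paste(c(as.character(master_seed), vapply(list(...), as.character,
                                                  character(1))),
               collapse = "/")
  h <- 17
  for (v in utf8ToInt(key)) h <- (h * 31 + v) %% 2147483629
  as.integer(h)
}

## Missing/gap predicate used throughout curation and supermatrix code.
is_missing_char <- function(x, count_gaps = TRUE) {
  if (count_gaps) !(x %in% DNA_BASES) else x == "N" | x == "?"
}

## Alignment rows (named character vector of equal-length strings) to a
## character matrix, taxa as rows.
seqs_to_matrix <- function(seqs) {
  stopifnot(length(unique(nchar(seqs))) == 1)
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}

matrix_to_seqs <- function(m) {
  out <- apply(m, 1, paste, collapse = "")
  names(out) <- rownames(m)
  out
}
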