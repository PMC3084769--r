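#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
NULL

DNA_BASES <- c("A", "C", "G", "T")

# transition partner of each base; everything else is a transversion
TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

is_transition <- function(from, to) {
  TRANSITION[from] == to
}

#' Reverse complement of a nucleotide string
#'
#' @param x Character vector of IUPAC nucleotide strings.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# uppercase + validity check; rejects characters outside the IUPAC alphabet
normalize_seq <- function(x, what = "sequence") {
  x <- toupper(x)
  bad <- grepl("[^ACGTRYSWKMBDHVN-]", x)
  if (any(bad)) {
    abort(sprintf("%s contains non-IUPAC characters", what),
          class = "hervclone_bad_sequence")
  }
  x
}

frac_ambiguous <- function(x) {
  n <- nchar(x)
  if (n == 0L) return(0)
  (n - nchar(gsub("[^ACGT]", "", x))) / n
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# per-site substitution at `rate`, transitions twice as likely as
# transversions (P(ts) = 2/3); positions in `shield` are never touched
mutate_seq <- function(seq, rate, shield = integer()) {
  if (rate <= 0) return(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(bases)) < rate)
  hit <- setdiff(hit, shield)
  for (i in hit) {
    b <- bases[i]
    if (!b %in% DNA_BASES) next
    if (stats::runif(1) < 2 / 3) {
      bases[i] <- TRANSITION[[b]]
    } else {
      tv <- setdiff(DNA_BASES, c(b, TRANSITION[[b]]))
      bases[i] <- sample(tv, 1)
    }
  }
  paste(bases, collapse = "")
}

# ungapped identity between equal-length strings over ACGT columns
hamming_identity <- function(a, b) {
  va <- strsplit(a, "", fixed = TRUE)[[1]]
  vb <- strsplit(b, "", fixed = TRUE)[[1]]
  stopifnot(length(va) == length(vb))
  ok <- va %in% DNA_BASES & vb %in% DNA_BASES
  sum(va[ok] == vb[ok]) / sum(ok)
}

#' Read a FASTA file into a tibble
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (full header line) and `sequence`
#'   (uppercase).
#' @export
read_fasta_tbl <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("FASTA file not found: %s", path),
          class = "hervclone_io_error")
  }
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) {
    abort(sprintf("FASTA file is empty: %s", path),
          class = "hervclone_parse_error")
  }
  tibble(id = names(ss), sequence = unname(toupper(as.character(ss))))
}

#' Write sequences from a tibble to FASTA
#'
#' @param x A data frame with an id column and a `sequence` column.
#' @param path Output path.
#' @param id Name of the column holding record ids.
#' @return `path`, invisibly.
#' @export
write_fasta_tbl <- function(x, path, id = "id") {
  ss <- Biostrings::DNAStringSet(x$sequence)
  names(ss) <- x[[id]]
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

# seed helper: all exported generators route randomness through this so a
# fixed seed gives byte-identical output and the caller's RNG is untouched
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# derive a sub-seed for stage `k` without risking integer overflow
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(k) %% 1000L
}
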