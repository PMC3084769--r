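# shared nucleotide scoring: match +1, mismatch -1 (approximates
# megablast-like behaviour); IUPAC ambiguity codes get fractional scores
sub_matrix <- function(match = 1, mismatch = -1) {
  Biostrings::nucleotideSubstitutionMatrix(match = match,
                                           mismatch = mismatch,
                                           baseOnly = FALSE)
}

#' Pairwise identity of a query against a subject
#'
#' Semi-global alignment (free end gaps, Biostrings "overlap" type)
#' under fixed scoring (match +1, mismatch -1, gap open 5, gap extend
#' 2). Identity is matches divided by aligned columns, with internal gap
#' columns counted as mismatches and end gaps excluded -- the closest
#' deterministic analogue of a BLAST "Max identity" over the local hit.
#'
#' @param query,subject Nucleotide strings (IUPAC). Sequences with more
#'   than 10% ambiguous (non-ACGT) bases are rejected.
#' @param gap_opening,gap_extension Gap penalties (positive numbers).
#' @return One-row tibble: `aligned_length` (columns compared,
#'   including internal gaps), `n_matches`, `identity`, `score`.
#' @export
#' @examples
#' align_identity("ACGTACGT", "ACGTACGT")$identity
align_identity <- function(query, subject, gap_opening = 5,
                           gap_extension = 2) {
  query <- normalize_seq(query, "query")
  subject <- normalize_seq(subject, "subject")
  if (!nzchar(query) || !nzchar(subject)) {
    abort("sequences must be nonempty", class = "hervclone_validation_error")
  }
  for (s in list(query = query, subject = subject)) {
    if (frac_ambiguous(s) > 0.10) {
      abort("sequence has more than 10% ambiguous bases",
            class = "hervclone_validation_error")
    }
  }
  aln <- Biostrings::pairwiseAlignment(
    pattern = query, subject = subject, type = "overlap",
    substitutionMatrix = sub_matrix(), gapOpening = gap_opening,
    gapExtension = gap_extension)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  cols <- length(p)
  matches <- sum(p == s & p != "-")
  tibble(aligned_length = cols, n_matches = matches,
         identity = if (cols > 0) matches / cols else 0,
         score = Biostrings::score(aln))
}
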