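#' Kimura two-parameter distance between two aligned sequences
#'
#' d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q)), with P and Q the
#' transition and transversion fractions over comparable (ACGT in both)
#' columns. Saturated pairs (log argument <= 0) raise an error.
#'
#' @param seq1,seq2 Aligned nucleotide strings of equal length.
#' @return The K2P distance (substitutions per site).
#' @export
#' @examples
#' k2p_distance("AAAA", "AAAG")
k2p_distance <- function(seq1, seq2) {
  a <- strsplit(normalize_seq(seq1, "seq1"), "")[[1]]
  b <- strsplit(normalize_seq(seq2, "seq2"), "")[[1]]
  if (length(a) != length(b)) {
    abort("sequences must be aligned to equal length",
          class = "hervclone_validation_error")
  }
  ok <- a %in% DNA_BASES & b %in% DNA_BASES
  n <- sum(ok)
  if (n == 0L) {
    abort("no comparable columns", class = "hervclone_validation_error")
  }
  diff <- ok & a != b
  ts <- sum(diff & is_transition(a, b))
  tv <- sum(diff) - ts
  P <- ts / n
  Q <- tv / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    abort("K2P distance saturated (log argument <= 0)",
          class = "hervclone_saturation_error")
  }
  -0.5 * log(w1 * sqrt(w2))
}

#' K2P distance matrix for a set of aligned sequences
#'
#' @param seqs Named character vector (or tibble with id and `sequence`
#'   columns) of aligned, equal-length sequences.
#' @param id Column holding labels when `seqs` is a data frame.
#' @return Symmetric numeric matrix with zero diagonal and the sequence
#'   labels as dimnames.
#' @export
k2p_matrix <- function(seqs, id = 1L) {
  if (is.data.frame(seqs)) {
    seqs <- stats::setNames(seqs$sequence, seqs[[id]])
  }
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      d[i, j] <- d[j, i] <- k2p_distance(seqs[[i]], seqs[[j]])
    }
  }
  d
}
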