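#' Nested PCR primer set for the HERV-W env SU-TM amplicon
#'
#' The default primers are the published outer/inner pairs used to
#' amplify the ~650 bp fragment spanning the surface-unit/transmembrane
#' junction of the env gene. The 5' BamHI/XhoI linker bases are part of
#' the printed sequences and are kept in the footprint; [trim_to_region()]
#' removes the full footprints.
#'
#' @param outer_sense,outer_antisense,inner_sense,inner_antisense Primer
#'   sequences, written 5' to 3'.
#' @param max_mismatches Maximum mismatches tolerated when annealing a
#'   primer (default 2).
#' @param three_prime_exact Number of 3'-terminal bases that must match
#'   exactly (default 3); mimics the 3'-end sensitivity of polymerase
#'   extension.
#' @return An object of class `primer_set`.
#' @export
#' @examples
#' primer_set()
primer_set <- function(outer_sense = "GATGGATCCAAAACTACATGAAACCT",
                       outer_antisense = "CGTGACTCGAGCTGCTTCCTGC",
                       inner_sense = "GATGGATCCAGCCTATTTAATACCAC",
                       inner_antisense = "CGTGACTCGAGAGTTAAGTTGATCTTGCAA",
                       max_mismatches = 2L,
                       three_prime_exact = 3L) {
  ps <- list(
    outer_sense = normalize_seq(outer_sense, "outer_sense"),
    outer_antisense = normalize_seq(outer_antisense, "outer_antisense"),
    inner_sense = normalize_seq(inner_sense, "inner_sense"),
    inner_antisense = normalize_seq(inner_antisense, "inner_antisense"),
    max_mismatches = as.integer(max_mismatches),
    three_prime_exact = as.integer(three_prime_exact)
  )
  if (any(!nzchar(unlist(ps[1:4])))) {
    abort("all four primers must be nonempty", class = "hervclone_config_error")
  }
  structure(ps, class = "primer_set")
}

#' @export
print.primer_set <- function(x, ...) {
  cat("<primer_set>\n")
  cat("  outer: ", x$outer_sense, " / ", x$outer_antisense, "\n", sep = "")
  cat("  inner: ", x$inner_sense, " / ", x$inner_antisense, "\n", sep = "")
  cat(sprintf("  max_mismatches %d, three_prime_exact %d\n",
              x$max_mismatches, x$three_prime_exact))
  invisible(x)
}
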