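#' Load a paralog reference panel from FASTA
#'
#' Headers are parsed as `locus_id [prototype]`: the first whitespace
#' token is the locus id (a chromosome-band label such as `7q21.2`, `14`
#' or `X`) and an optional `prototype` token flags the ERVWE1 prototype.
#' Exactly one record must carry the flag.
#'
#' @param path Path to a FASTA file.
#' @return A validated panel tibble: `locus_id`, `sequence` (uppercase),
#'   `is_prototype`.
#' @export
#' @examples
#' # a simulated 12-locus panel shipped with the package
#' fa <- system.file("extdata", "synthetic_panel.fa", package = "hervclone")
#' load_panel(fa)
load_panel <- function(path) {
  x <- read_fasta_tbl(path)
  toks <- strsplit(x$id, "\\s+")
  panel <- tibble(
    locus_id = vapply(toks, `[[`, character(1), 1L),
    sequence = normalize_seq(x$sequence, "panel sequence"),
    is_prototype = vapply(toks, function(t) "prototype" %in% t[-1], logical(1))
  )
  validate_panel(panel)
}

validate_panel <- function(panel) {
  dup <- unique(panel$locus_id[duplicated(panel$locus_id)])
  if (length(dup) > 0L) {
    abort(sprintf("duplicate locus_id in panel: %s",
                  paste(dup, collapse = ", ")),
          class = "hervclone_validation_error")
  }
  if (any(!nzchar(panel$sequence))) {
    abort("panel contains an empty sequence",
          class = "hervclone_validation_error")
  }
  np <- sum(panel$is_prototype)
  if (np != 1L) {
    abort(sprintf("panel must flag exactly one prototype (found %d)", np),
          class = "hervclone_validation_error")
  }
  panel
}

#' Write a panel tibble to FASTA
#'
#' The prototype record gets a `prototype` header token so the file
#' round-trips through [load_panel()].
#'
#' @param panel Panel tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  ids <- ifelse(panel$is_prototype, paste(panel$locus_id, "prototype"),
                panel$locus_id)
  write_fasta_tbl(tibble(id = ids, sequence = panel$sequence), path)
}

prototype_of <- function(panel) {
  validate_panel(panel)
  panel[panel$is_prototype, , drop = FALSE]
}
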