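# primer annealing site search: returns 1-based start positions on the
# template (+ strand for sense primers, matching revcomp(primer) for
# antisense primers), honouring the mismatch budget and the 3'-exact rule
find_primer_sites <- function(template, primer, orientation,
                              max_mismatches, three_prime_exact) {
  subj <- Biostrings::DNAString(template)
  patt <- if (orientation == "sense") primer else revcomp(primer)
  hits <- Biostrings::matchPattern(Biostrings::DNAString(patt), subj,
                                   max.mismatch = max_mismatches,
                                   with.indels = FALSE)
  starts <- Biostrings::start(hits)
  if (length(starts) == 0L || three_prime_exact == 0L) return(starts)
  plen <- nchar(patt)
  k <- min(three_prime_exact, plen)
  # the primer's 3' end is the right end of a sense footprint and the
  # left end of an antisense footprint on the template
  keep <- vapply(starts, function(s) {
    frag <- substr(template, s, s + plen - 1L)
    if (orientation == "sense") {
      substr(frag, plen - k + 1L, plen) == substr(patt, plen - k + 1L, plen)
    } else {
      substr(frag, 1L, k) == substr(patt, 1L, k)
    }
  }, logical(1))
  starts[keep]
}

# all products of one sense/antisense primer pair on a + strand template
pcr_products <- function(template, template_id, sense, antisense,
                         max_mismatches, three_prime_exact,
                         max_product_length) {
  s_sites <- find_primer_sites(template, sense, "sense",
                               max_mismatches, three_prime_exact)
  a_sites <- find_primer_sites(template, antisense, "antisense",
                               max_mismatches, three_prime_exact)
  ls <- nchar(sense); la <- nchar(antisense)
  out <- list()
  for (s in s_sites) {
    for (a in a_sites) {
      prod_end <- a + la - 1L
      len <- prod_end - s + 1L
      if (a >= s + ls && len <= max_product_length) {
        out[[length(out) + 1L]] <- tibble(
          template_id = template_id, start = s, end = prod_end,
          length = len, strand = "+",
          sequence = substr(template, s, prod_end),
          fwd_footprint = ls, rev_footprint = la)
      }
    }
  }
  res <- if (length(out) == 0L) empty_amplicon_tbl() else bind_rows(out)
  arrange(res, .data$start, .data$end)
}

empty_amplicon_tbl <- function() {
  tibble(template_id = character(), start = integer(), end = integer(),
         length = integer(), strand = character(), sequence = character(),
         fwd_footprint = integer(), rev_footprint = integer())
}

#' In-silico PCR on a template sequence
#'
#' Finds every product in which the sense primer anneals on the plus
#' strand and the reverse complement of the antisense primer anneals
#' downstream, each with at most `max_mismatches` mismatches and the
#' 3'-terminal `three_prime_exact` bases matching exactly. For
#' `stage = "nested"` the outer pair is applied first and the inner pair
#' is then searched within each outer product (coordinates reported on
#' the original template); when the outer pair finds no site, the inner
#' pair is applied directly to the template (covering re-amplification
#' of material that is already an outer product). Absence of sites is
#' not an error: an empty table is the "none detected" (ND) outcome.
#'
#' @param template Template sequence (string), or a one-row panel tibble.
#' @param primers A [primer_set()].
#' @param stage `"outer"` or `"nested"`.
#' @param template_id Label used in the output (defaults to the panel
#'   `locus_id` or `"template"`).
#' @param max_product_length Products longer than this are discarded as
#'   implausible (default 2000 bp; the target amplicon is ~650 bp).
#' @return Amplicon tibble sorted by start: `template_id`, `start`,
#'   `end` (1-based, inclusive), `length`, `strand`, `sequence`,
#'   `fwd_footprint`, `rev_footprint` (primer footprint lengths).
#' @export
#' @examples
#' ps <- primer_set()
#' tmpl <- paste0(strrep("A", 20), ps$inner_sense, strrep("ACGT", 150),
#'                revcomp(ps$inner_antisense), strrep("T", 20))
#' in_silico_pcr(tmpl, ps, stage = "nested")
in_silico_pcr <- function(template, primers = primer_set(),
                          stage = c("nested", "outer"),
                          template_id = NULL, max_product_length = 2000L) {
  stage <- match.arg(stage)
  if (is.data.frame(template)) {
    template_id <- template_id %||% template$locus_id[1]
    template <- template$sequence[1]
  }
  template_id <- template_id %||% "template"
  template <- normalize_seq(template, "template")
  if (stage == "outer") {
    return(pcr_products(template, template_id, primers$outer_sense,
                        primers$outer_antisense, primers$max_mismatches,
                        primers$three_prime_exact, max_product_length))
  }
  outer <- pcr_products(template, template_id, primers$outer_sense,
                        primers$outer_antisense, primers$max_mismatches,
                        primers$three_prime_exact, max_product_length)
  if (nrow(outer) == 0L) {
    # no outer sites: anneal the inner pair directly
    return(pcr_products(template, template_id, primers$inner_sense,
                        primers$inner_antisense, primers$max_mismatches,
                        primers$three_prime_exact, max_product_length))
  }
  inner <- lapply(seq_len(nrow(outer)), function(i) {
    prod <- pcr_products(outer$sequence[i], template_id,
                         primers$inner_sense, primers$inner_antisense,
                         primers$max_mismatches, primers$three_prime_exact,
                         max_product_length)
    prod$start <- prod$start + outer$start[i] - 1L
    prod$end <- prod$end + outer$start[i] - 1L
    prod
  })
  res <- bind_rows(inner)
  res <- res[!duplicated(res[, c("start", "end")]), , drop = FALSE]
  arrange(res, .data$start, .data$end)
}

#' Nested amplicon of a panel's prototype locus
#'
#' Convenience wrapper: runs [in_silico_pcr()] on the flagged prototype
#' and returns its first (leftmost) nested product.
#'
#' @param panel Panel tibble.
#' @param primers A [primer_set()].
#' @return One-row amplicon tibble.
#' @export
prototype_amplicon <- function(panel, primers = primer_set()) {
  proto <- prototype_of(panel)
  amp <- in_silico_pcr(proto, primers, stage = "nested")
  if (nrow(amp) == 0L) {
    abort("no nested PCR product on the prototype locus",
          class = "hervclone_pcr_error")
  }
  amp[1, , drop = FALSE]
}

#' Insert sequence of an amplicon (primer footprints removed)
#'
#' @param amplicon One-row amplicon tibble from [in_silico_pcr()].
#' @return The insert string.
#' @export
amplicon_insert <- function(amplicon) {
  substr(amplicon$sequence[1], amplicon$fwd_footprint[1] + 1L,
         amplicon$length[1] - amplicon$rev_footprint[1])
}

#' Trim a cloned sequence to the amplicon region of interest
#'
#' Aligns the clone to the prototype amplicon (semi-global, free end
#' gaps) and returns the clone bases that fall within the amplicon's
#' insert, i.e. with both primer footprints and any flanking vector
#' sequence removed. Clones covering less than `min_coverage` of the
#' amplicon fail with a diagnostic and should be excluded downstream.
#' Trimming is idempotent: a trimmed clone trims to itself.
#'
#' @param clone Clone sequence (string).
#' @param amplicon One-row amplicon tibble (see [prototype_amplicon()]).
#' @param min_coverage Minimum fraction of the amplicon that the
#'   alignment must span (default 0.5).
#' @return Trimmed clone sequence (string).
#' @export
trim_to_region <- function(clone, amplicon, min_coverage = 0.5) {
  clone <- normalize_seq(clone, "clone")
  amp_seq <- amplicon$sequence[1]
  ins_start <- amplicon$fwd_footprint[1] + 1L
  ins_end <- amplicon$length[1] - amplicon$rev_footprint[1]
  aln <- Biostrings::pairwiseAlignment(
    pattern = clone, subject = amp_seq, type = "overlap",
    substitutionMatrix = sub_matrix(), gapOpening = 5, gapExtension = 2)
  subj_range <- Biostrings::subject(aln)
  cov <- (Biostrings::end(subj_range) - Biostrings::start(subj_range) + 1L) /
    nchar(amp_seq)
  # a clone that is already the bare insert still covers insert/amplicon
  cov_insert <- (min(Biostrings::end(subj_range), ins_end) -
                   max(Biostrings::start(subj_range), ins_start) + 1L) /
    (ins_end - ins_start + 1L)
  if (max(cov, cov_insert) < min_coverage) {
    abort(sprintf(
      "clone covers only %.1f%% of the prototype amplicon (need %.0f%%)",
      100 * cov, 100 * min_coverage),
      class = "hervclone_trim_error")
  }
  p_chars <- strsplit(as.character(Biostrings::alignedPattern(aln)),
                      "")[[1]]
  s_chars <- strsplit(as.character(Biostrings::alignedSubject(aln)),
                      "")[[1]]
  s_pos <- Biostrings::start(subj_range) - 1L
  keep <- character(0)
  for (i in seq_along(s_chars)) {
    if (s_chars[i] != "-") s_pos <- s_pos + 1L
    if (p_chars[i] != "-" && s_chars[i] != "-" &&
        s_pos >= ins_start && s_pos <= ins_end) {
      keep <- c(keep, p_chars[i])
    }
  }
  if (length(keep) == 0L) {
    abort("no clone bases fall within the amplicon insert",
          class = "hervclone_trim_error")
  }
  paste(keep, collapse = "")
}

#' Trim a table of clones to the amplicon region
#'
#' Vectorised [trim_to_region()] over a clone tibble; failures are
#' reported, not fatal, so one bad clone does not sink a sample.
#'
#' @param clones Tibble with `clone_id` and `sequence` columns (a
#'   `sample_id` column is carried through if present).
#' @param amplicon One-row amplicon tibble.
#' @param min_coverage Passed to [trim_to_region()].
#' @return The input tibble with `sequence` replaced by the trimmed
#'   sequence and a logical `trimmed` column; untrimmable clones keep
#'   their sequence and get `trimmed = FALSE`.
#' @export
trim_clones <- function(clones, amplicon, min_coverage = 0.5) {
  res <- purrr::map(clones$sequence, function(s) {
    tryCatch(list(seq = trim_to_region(s, amplicon, min_coverage), ok = TRUE),
             hervclone_trim_error = function(e) list(seq = s, ok = FALSE))
  })
  out <- clones
  out$sequence <- vapply(res, `[[`, character(1), "seq")
  out$trimmed <- vapply(res, `[[`, logical(1), "ok")
  n_bad <- sum(!out$trimmed)
  if (n_bad > 0L) {
    warn(sprintf("%d clone(s) could not be trimmed and are flagged", n_bad))
  }
  out
}
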