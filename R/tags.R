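as_reference_tbl <- function(references) {
  if (is.data.frame(references)) {
    stopifnot(all(c("feature", "sequence") %in% names(references)))
    refs <- tibble(feature = references$feature,
                   sequence = normalize_seq(references$sequence, "reference"))
  } else if (is.character(references) && length(references) == 1L &&
             file.exists(references)) {
    x <- read_fasta_tbl(references)
    refs <- tibble(feature = sub("\\s.*$", "", x$id), sequence = x$sequence)
  } else {
    refs <- tibble(feature = names(references),
                   sequence = normalize_seq(unname(references), "reference"))
  }
  if (nrow(refs) == 0L) {
    abort("reference set is empty", class = "hervclone_config_error")
  }
  refs
}

as_read_tbl <- function(reads) {
  if (is.data.frame(reads)) {
    stopifnot(all(c("read_id", "sequence") %in% names(reads)))
    return(tibble(read_id = reads$read_id,
                  sequence = toupper(reads$sequence)))
  }
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    fq <- grepl("\\.(fastq|fq)(\\.gz)?$", reads, ignore.case = TRUE)
    ss <- if (fq) Biostrings::readDNAStringSet(reads, format = "fastq")
          else Biostrings::readDNAStringSet(reads)
    return(tibble(read_id = names(ss) %||% sprintf("r%06d", seq_along(ss)),
                  sequence = toupper(as.character(ss))))
  }
  tibble(read_id = names(reads) %||% sprintf("r%06d", seq_along(reads)),
         sequence = toupper(unname(reads)))
}

# minimal mismatch count of each read against one reference (both
# strands, ungapped, full read length), capped at max_mismatch + 1
min_mismatch_vs_ref <- function(reads, ref_seq, max_mismatch) {
  width <- nchar(reads[1])
  best <- rep(max_mismatch + 1L, length(reads))
  if (width > nchar(ref_seq)) return(best)
  ss <- Biostrings::DNAStringSet(reads)
  subjects <- list(Biostrings::DNAString(ref_seq),
                   Biostrings::reverseComplement(Biostrings::DNAString(ref_seq)))
  for (k in 0:max_mismatch) {
    # one PDict per mismatch budget: preprocessing is budget-specific
    pd <- Biostrings::PDict(ss, max.mismatch = if (k == 0L) NA else k)
    for (subj in subjects) {
      n <- Biostrings::countPDict(pd, subj, max.mismatch = k)
      best <- pmin(best, ifelse(n > 0L, k, max_mismatch + 1L))
    }
  }
  best
}

#' Count short-read tags against reference features
#'
#' Each read is matched ungapped over its full length against both
#' strands of every reference, tolerating at most `max_mismatch`
#' substitutions. A read is credited to the unique feature achieving
#' its minimal mismatch count; reads tying across two or more features
#' go to the `ambiguous` bucket and reads matching nothing (or longer
#' than every reference, which additionally triggers a warning) are
#' `unmatched`. Per sample, `counted + ambiguous + unmatched = total`
#' always holds.
#'
#' @param reads Read set: tibble (`read_id`, `sequence`), named
#'   character vector, or FASTA/FASTQ path.
#' @param references Reference features: tibble (`feature`,
#'   `sequence`), named character vector, or FASTA path.
#' @param max_mismatch Maximum substitutions tolerated (default 1).
#' @return An object of class `tag_counts`: list with `counts` (tibble
#'   `feature`, `count`, in reference order), `ambiguous`, `unmatched`,
#'   `total`.
#' @export
count_tags <- function(reads, references, max_mismatch = 1L) {
  refs <- as_reference_tbl(references)
  rd <- as_read_tbl(reads)
  n_total <- nrow(rd)
  counts <- stats::setNames(rep(0L, nrow(refs)), refs$feature)
  ambiguous <- 0L
  unmatched <- 0L
  if (n_total > 0L) {
    usable <- !grepl("[^ACGT]", rd$sequence) & nzchar(rd$sequence)
    unmatched <- unmatched + sum(!usable)
    too_long <- nchar(rd$sequence) > max(nchar(refs$sequence))
    if (any(too_long & usable)) {
      warn(sprintf("%d read(s) longer than every reference were skipped",
                   sum(too_long & usable)))
    }
    rdu <- rd[usable, , drop = FALSE]
    if (nrow(rdu) > 0L) {
      # group by read width: PDict requires constant width
      for (w in unique(nchar(rdu$sequence))) {
        sel <- nchar(rdu$sequence) == w
        seqs <- rdu$sequence[sel]
        mm <- sapply(refs$sequence, function(rs) {
          min_mismatch_vs_ref(seqs, rs, max_mismatch)
        })
        mm <- matrix(mm, nrow = length(seqs))
        best <- apply(mm, 1L, min)
        hit <- best <= max_mismatch
        unmatched <- unmatched + sum(!hit)
        n_best <- rowSums(mm == best)
        amb <- hit & n_best > 1L
        ambiguous <- ambiguous + sum(amb)
        uniq <- which(hit & !amb)
        if (length(uniq) > 0L) {
          feat <- refs$feature[apply(mm[uniq, , drop = FALSE], 1L,
                                     which.min)]
          tb <- table(feat)
          counts[names(tb)] <- counts[names(tb)] + as.integer(tb)
        }
      }
    }
  }
  structure(list(
    counts = tibble(feature = refs$feature, count = unname(counts)),
    ambiguous = ambiguous, unmatched = unmatched, total = n_total
  ), class = "tag_counts")
}

#' @export
print.tag_counts <- function(x, ...) {
  cat(sprintf("<tag_counts> %d reads: %d counted, %d ambiguous, %d unmatched\n",
              x$total, sum(x$counts$count), x$ambiguous, x$unmatched))
  print(x$counts)
  invisible(x)
}

#' Multi-sample tag-count table
#'
#' Runs [count_tags()] per sample and stacks the results into one long
#' tibble; per-sample ambiguous/unmatched tallies are kept in the
#' `tallies` attribute.
#'
#' @param read_sets Named list of read sets (see [count_tags()]).
#' @param references Reference features.
#' @param max_mismatch Maximum substitutions tolerated.
#' @return Long tibble `sample_id`, `feature`, `count` with a `tallies`
#'   attribute (tibble `sample_id`, `ambiguous`, `unmatched`, `total`).
#' @export
tag_count_table <- function(read_sets, references, max_mismatch = 1L) {
  stopifnot(is.list(read_sets), !is.null(names(read_sets)))
  per <- purrr::imap(read_sets, function(rd, sid) {
    tc <- count_tags(rd, references, max_mismatch)
    list(counts = dplyr::bind_cols(tibble(sample_id = sid), tc$counts),
         tally = tibble(sample_id = sid, ambiguous = tc$ambiguous,
                        unmatched = tc$unmatched, total = tc$total))
  })
  out <- bind_rows(purrr::map(per, "counts"))
  attr(out, "tallies") <- bind_rows(purrr::map(per, "tally"))
  out
}

#' Filter features by a minimum tag count
#'
#' Retains features with at least `min_tags` in every sample (the
#' default reading of "at least 2 tags detected per sample") or, with
#' `scope = "any"`, in at least one sample.
#'
#' @param counts Long count tibble (`sample_id`, `feature`, `count`).
#' @param min_tags Minimum tags (default 2).
#' @param scope `"every"` (default) or `"any"`.
#' @return Filtered tibble; dropped feature names are kept in the
#'   `dropped_features` attribute.
#' @export
filter_min_tags <- function(counts, min_tags = 2L,
                            scope = c("every", "any")) {
  scope <- match.arg(scope)
  keep <- counts |>
    group_by(.data$feature) |>
    summarise(ok = if (scope == "every") all(.data$count >= min_tags)
              else any(.data$count >= min_tags), .groups = "drop")
  dropped <- keep$feature[!keep$ok]
  if (length(dropped) > 0L) {
    inform(sprintf("dropping %d feature(s) below the %d-tag filter: %s",
                   length(dropped), min_tags,
                   paste(dropped, collapse = ", ")))
  }
  out <- counts[counts$feature %in% keep$feature[keep$ok], , drop = FALSE]
  attr(out, "dropped_features") <- dropped
  out
}

#' Normalise tag counts to a housekeeping feature
#'
#' abundance(sample, feature) = count(sample, feature) /
#' count(sample, housekeeping); the housekeeping feature itself
#' normalises to 1 in every sample.
#'
#' @param counts Long count tibble (`sample_id`, `feature`, `count`).
#' @param housekeeping Housekeeping feature label (default `"GAPDH"`).
#' @return Long tibble `sample_id`, `feature`, `abundance`.
#' @export
normalize_to_housekeeping <- function(counts, housekeeping = "GAPDH") {
  hk <- counts[counts$feature == housekeeping, ]
  missing <- setdiff(unique(counts$sample_id), hk$sample_id)
  if (length(missing) > 0L) {
    abort(sprintf("housekeeping feature '%s' absent in sample(s): %s",
                  housekeeping, paste(missing, collapse = ", ")),
          class = "hervclone_validation_error")
  }
  zero <- hk$sample_id[hk$count == 0]
  if (length(zero) > 0L) {
    abort(sprintf("housekeeping count is zero in sample(s): %s",
                  paste(zero, collapse = ", ")),
          class = "hervclone_validation_error")
  }
  counts |>
    left_join(dplyr::rename(hk, hk_count = "count")[, c("sample_id",
                                                        "hk_count")],
              by = "sample_id") |>
    mutate(abundance = .data$count / .data$hk_count) |>
    select("sample_id", "feature", "abundance")
}
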