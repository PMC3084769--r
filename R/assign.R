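#' Assignment thresholds
#'
#' The locus match rule: a clone is assigned to its best panel locus only
#' if identity is strictly greater than `min_identity` ("greater than
#' 97% similarity") over at least `min_aligned_length` aligned bp ("a
#' query length of 580 or higher bps", inclusive). Two passing hits
#' closer than `tie_margin` in identity yield an `AMBIGUOUS` call.
#'
#' @param min_identity Identity threshold, exclusive (default 0.97).
#' @param min_aligned_length Aligned-length threshold in bp, inclusive
#'   (default 580).
#' @param tie_margin Identity difference under which two passing hits
#'   are considered tied (default 0.002).
#' @param identity_over Denominator of the identity fraction:
#'   `"alignment"` (default; aligned columns of the local hit, the
#'   BLAST "Max identity" reading) or `"query"` (full query length, the
#'   stricter alternative reading).
#' @return An object of class `assignment_thresholds`.
#' @export
assignment_thresholds <- function(min_identity = 0.97,
                                  min_aligned_length = 580L,
                                  tie_margin = 0.002,
                                  identity_over = c("alignment", "query")) {
  identity_over <- match.arg(identity_over)
  if (min_identity <= 0 || min_identity > 1) {
    abort("min_identity must be in (0, 1]", class = "hervclone_config_error")
  }
  if (min_aligned_length <= 0) {
    abort("min_aligned_length must be > 0", class = "hervclone_config_error")
  }
  structure(list(min_identity = min_identity,
                 min_aligned_length = as.integer(min_aligned_length),
                 tie_margin = tie_margin,
                 identity_over = identity_over),
            class = "assignment_thresholds")
}

#' Assign one clone to its chromosomal encoding locus
#'
#' Aligns the clone against every panel locus with [align_identity()],
#' ranks hits by identity (ties broken by alignment score, then by
#' lexicographic locus id, so panel order never matters), and applies
#' the match rule in `thresholds`. Clones whose best hit fails either
#' threshold are called `ND` (none detected); two passing hits within
#' `tie_margin` give `AMBIGUOUS`.
#'
#' @param clone Clone sequence (string), trimmed to the region of
#'   interest.
#' @param panel Panel tibble.
#' @param thresholds An [assignment_thresholds()].
#' @param clone_id Optional label for the output row.
#' @return One-row tibble: `clone_id`, `call`, `best_locus`, `identity`,
#'   `aligned_length`, `n_matches`, `score`, `runner_up_locus`,
#'   `runner_up_identity`, `margin`.
#' @export
assign_locus <- function(clone, panel, thresholds = assignment_thresholds(),
                         clone_id = "clone") {
  if (nrow(panel) == 0L) {
    abort("panel is empty", class = "hervclone_config_error")
  }
  hits <- purrr::map_dfr(seq_len(nrow(panel)), function(i) {
    h <- align_identity(clone, panel$sequence[i])
    if (thresholds$identity_over == "query") {
      h$identity <- h$n_matches / nchar(clone)
    }
    h$locus_id <- panel$locus_id[i]
    h
  })
  hits <- arrange(hits, dplyr::desc(.data$identity), dplyr::desc(.data$score),
                  .data$locus_id)
  passes <- hits$identity > thresholds$min_identity &
    hits$aligned_length >= thresholds$min_aligned_length
  best <- hits[1, ]
  ru <- if (nrow(hits) >= 2L) hits[2, ] else NULL
  call <- if (!passes[1]) {
    "ND"
  } else if (sum(passes) >= 2L &&
             hits$identity[1] - hits$identity[which(passes)[2]] <
               thresholds$tie_margin) {
    "AMBIGUOUS"
  } else {
    best$locus_id
  }
  tibble(clone_id = clone_id, call = call, best_locus = best$locus_id,
         identity = best$identity, aligned_length = best$aligned_length,
         n_matches = best$n_matches, score = best$score,
         runner_up_locus = if (is.null(ru)) NA_character_ else ru$locus_id,
         runner_up_identity = if (is.null(ru)) NA_real_ else ru$identity,
         margin = if (is.null(ru)) NA_real_ else best$identity - ru$identity)
}

#' Assign a table of clones to panel loci
#'
#' @param clones Tibble with `clone_id` and `sequence` (a `sample_id`
#'   column is carried through if present).
#' @param panel Panel tibble.
#' @param thresholds An [assignment_thresholds()].
#' @return Assignment tibble, one row per clone (see [assign_locus()]).
#' @export
assign_clones <- function(clones, panel,
                          thresholds = assignment_thresholds()) {
  out <- purrr::map_dfr(seq_len(nrow(clones)), function(i) {
    assign_locus(clones$sequence[i], panel, thresholds,
                 clone_id = clones$clone_id[i])
  })
  if ("sample_id" %in% names(clones)) {
    out <- dplyr::bind_cols(tibble(sample_id = clones$sample_id), out)
  }
  out
}

#' Per-sample locus frequency table
#'
#' Counts and fractions of calls per sample. Fractions are over called
#' plus ND clones (the denominator the clone-frequency figures use);
#' AMBIGUOUS clones are tabulated but excluded from that denominator,
#' so their `fraction` is `NA`.
#'
#' @param assignments Assignment tibble from [assign_clones()]; must
#'   have a `sample_id` column (a constant one is added if absent).
#' @return Tibble: `sample_id`, `call`, `n`, `fraction`.
#' @export
summarize_assignments <- function(assignments) {
  if (nrow(assignments) == 0L) {
    abort("no assignments to summarise", class = "hervclone_validation_error")
  }
  if (!"sample_id" %in% names(assignments)) {
    assignments$sample_id <- "sample"
  }
  assignments |>
    group_by(.data$sample_id, .data$call) |>
    summarise(n = dplyr::n(), .groups = "drop_last") |>
    mutate(fraction = ifelse(.data$call == "AMBIGUOUS", NA_real_,
                             .data$n / sum(.data$n[.data$call != "AMBIGUOUS"]))) |>
    ungroup() |>
    arrange(.data$sample_id, dplyr::desc(.data$n), .data$call)
}

#' Chi-square comparison of locus distributions between groups
#'
#' Pearson chi-square (no continuity correction) on the group-by-locus
#' contingency table of called clones (ND/AMBIGUOUS excluded). Rows or
#' columns whose total is zero are dropped with a warning.
#'
#' @param assignments Assignment tibble with a `sample_id` column.
#' @param groups Named vector or two-column data frame mapping
#'   `sample_id` to a group label.
#' @return One-row tibble: `statistic`, `df`, `p.value`, `n_clones`,
#'   `method`.
#' @export
compare_group_diversity <- function(assignments, groups) {
  if (is.data.frame(groups)) {
    groups <- stats::setNames(groups[[2]], groups[[1]])
  }
  called <- assignments[!assignments$call %in% c("ND", "AMBIGUOUS"), ]
  if (nrow(called) == 0L) {
    abort("no called clones", class = "hervclone_validation_error")
  }
  grp <- groups[called$sample_id]
  if (anyNA(grp)) {
    abort("every sample_id needs a group label",
          class = "hervclone_config_error")
  }
  tab <- table(group = grp, locus = called$call)
  keep_r <- rowSums(tab) > 0
  keep_c <- colSums(tab) > 0
  if (any(!keep_r) || any(!keep_c)) {
    warn("dropping empty rows/columns from the contingency table")
    tab <- tab[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    abort("need at least 2 groups and 2 loci with called clones",
          class = "hervclone_validation_error")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p.value = ct$p.value, n_clones = sum(tab),
         method = "Pearson chi-square (uncorrected)")
}
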