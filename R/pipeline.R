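prepare_out_dir <- function(out_dir, force) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0L && !force) {
    abort(sprintf(
      "output directory '%s' is not empty; use force = TRUE to overwrite",
      out_dir), class = "hervclone_io_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out_dir
}

write_tsv_out <- function(x, out_dir, name) {
  path <- file.path(out_dir, name)
  readr::write_tsv(x, path)
  path
}

#' Run the clone pipeline: amplify, trim, assign, diversity, tree
#'
#' End-to-end embodiment of the clonal analysis: excises the prototype
#' amplicon by in-silico nested PCR, trims every clone to the insert,
#' assigns clones to panel loci by the identity/length rule, tabulates
#' per-sample locus frequencies, summarises molecular diversity per
#' sample, and builds a K2P + neighbor-joining tree of the panel locus
#' inserts (rooted to the outgroup when one is given). Per-sample
#' failures are isolated: a sample whose diversity cannot be computed
#' is flagged in the status table and the rest of the run completes.
#' Rerunning with the same inputs reproduces byte-identical outputs.
#'
#' @param panel Panel tibble (see [load_panel()]).
#' @param clones Clone tibble (`sample_id`, `clone_id`, `sequence`).
#' @param out_dir Output directory for TSV/Newick/JSON files.
#' @param thresholds An [assignment_thresholds()].
#' @param primers A [primer_set()].
#' @param outgroup Optional one-row tibble (`locus_id`, `sequence`)
#'   used to root the tree (e.g. the MSRV prototype env sequence).
#' @param force Overwrite a non-empty `out_dir`.
#' @return An object of class `clone_run`: list with `assignments`,
#'   `locus_frequencies`, `diversity`, `tree`, `sample_status`,
#'   `files`, `config`.
#' @export
run_clone_pipeline <- function(panel, clones, out_dir,
                               thresholds = assignment_thresholds(),
                               primers = primer_set(),
                               outgroup = NULL, force = FALSE) {
  validate_panel(panel)
  if (nrow(clones) == 0L) {
    abort("no clones supplied", class = "hervclone_config_error")
  }
  prepare_out_dir(out_dir, force)
  proto_amp <- prototype_amplicon(panel, primers)
  proto_insert <- amplicon_insert(proto_amp)
  trimmed <- suppressWarnings(trim_clones(clones, proto_amp))
  ok <- trimmed[trimmed$trimmed, , drop = FALSE]
  # assignment runs against the panel locus inserts so aligned lengths
  # reflect the region of interest, not vector/primer sequence
  locus_inserts <- panel
  locus_inserts$sequence <- vapply(seq_len(nrow(panel)), function(i) {
    amp <- in_silico_pcr(panel[i, ], primers, stage = "nested")
    if (nrow(amp) == 0L) panel$sequence[i] else amplicon_insert(amp[1, ])
  }, character(1))
  assignments <- assign_clones(ok, locus_inserts, thresholds)
  freqs <- summarize_assignments(assignments)
  status <- list()
  div <- list()
  for (sid in unique(clones$sample_id)) {
    d <- ok[ok$sample_id == sid, , drop = FALSE]
    res <- tryCatch({
      div[[sid]] <- diversity_summary(d, proto_insert)
      "ok"
    }, error = function(e) paste("failed:", conditionMessage(e)))
    status[[sid]] <- tibble(
      sample_id = sid,
      n_clones = sum(clones$sample_id == sid),
      n_trimmed = nrow(d),
      diversity = res)
  }
  diversity <- bind_rows(div)
  tree_tbl <- locus_inserts[, c("locus_id", "sequence")]
  og_label <- NULL
  if (!is.null(outgroup)) {
    og_amp <- in_silico_pcr(outgroup$sequence[1], primers,
                            stage = "nested",
                            template_id = outgroup$locus_id[1])
    og_seq <- if (nrow(og_amp) > 0L) amplicon_insert(og_amp[1, ]) else
      outgroup$sequence[1]
    tree_tbl <- bind_rows(tree_tbl,
                          tibble(locus_id = outgroup$locus_id[1],
                                 sequence = og_seq))
    og_label <- outgroup$locus_id[1]
  }
  tree <- nj_tree(k2p_matrix(tree_tbl, id = "locus_id"), outgroup = og_label)
  files <- c(
    assignments = write_tsv_out(assignments, out_dir, "assignments.tsv"),
    locus_frequencies = write_tsv_out(freqs, out_dir,
                                      "locus_frequencies.tsv"),
    diversity = write_tsv_out(diversity, out_dir, "diversity.tsv"),
    sample_status = write_tsv_out(bind_rows(status), out_dir,
                                  "sample_status.tsv"),
    tree = write_newick(tree, file.path(out_dir, "panel_tree.nwk"))
  )
  config <- list(
    version = as.character(utils::packageVersion("hervclone")),
    thresholds = unclass(thresholds),
    primers = unclass(primers),
    outgroup = og_label,
    n_loci = nrow(panel), n_clones = nrow(clones))
  jsonlite::write_json(config, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  files["report"] <- file.path(out_dir, "report.json")
  structure(list(assignments = assignments, locus_frequencies = freqs,
                 diversity = diversity, tree = tree,
                 sample_status = bind_rows(status), files = files,
                 config = config),
            class = "clone_run")
}

#' Run the tag pipeline: count, filter, normalise, correlate
#'
#' Counts reads per sample against the reference features (or accepts a
#' precomputed long count table), applies the minimum-tag filter,
#' normalises to the housekeeping feature, ranks the HERV features by
#' abundance, and selects host genes whose expression tracks the target
#' feature at the r-squared cutoff. The housekeeping and target
#' features are exempt from the tag filter (they are the analysis
#' scaffold, not candidates). Samples with zero reads are flagged and
#' excluded; the rest complete.
#'
#' @param read_sets Named list of per-sample read sets, or `NULL` when
#'   `counts` is given.
#' @param references Reference features (required with `read_sets`).
#' @param out_dir Output directory.
#' @param counts Optional precomputed long count tibble (`sample_id`,
#'   `feature`, `count`).
#' @param housekeeping Housekeeping feature (default `"GAPDH"`).
#' @param target Target feature (default `"HERV-W_env"`).
#' @param cutoff r-squared selection cutoff (default 0.75).
#' @param min_tags Minimum tags per sample for the filter (default 2).
#' @param scope Filter scope, `"every"` or `"any"`.
#' @param max_mismatch Mismatch tolerance for counting (default 1).
#' @param force Overwrite a non-empty `out_dir`.
#' @return An object of class `tag_run`: list with `counts`,
#'   `filtered`, `expression`, `herv_ranking`, `herv_family` (per-family
#'   rollup of the HERV region features), `correlation`,
#'   `excluded_samples`, `files`, `config`.
#' @export
run_tag_pipeline <- function(read_sets = NULL, references = NULL, out_dir,
                             counts = NULL, housekeeping = "GAPDH",
                             target = "HERV-W_env", cutoff = 0.75,
                             min_tags = 2L, scope = "every",
                             max_mismatch = 1L, force = FALSE) {
  if (is.null(counts)) {
    if (is.null(read_sets) || is.null(references)) {
      abort("supply either counts or read_sets + references",
            class = "hervclone_config_error")
    }
    refs <- as_reference_tbl(references)
    if (!housekeeping %in% refs$feature) {
      abort(sprintf("housekeeping feature '%s' absent from references",
                    housekeeping), class = "hervclone_config_error")
    }
    counts <- tag_count_table(read_sets, references, max_mismatch)
  }
  if (!housekeeping %in% counts$feature) {
    abort(sprintf("housekeeping feature '%s' absent from counts",
                  housekeeping), class = "hervclone_config_error")
  }
  prepare_out_dir(out_dir, force)
  totals <- counts |>
    group_by(.data$sample_id) |>
    summarise(total = sum(.data$count), .groups = "drop")
  excluded <- totals$sample_id[totals$total == 0]
  if (length(excluded) > 0L) {
    warn(sprintf("excluding sample(s) with zero tags: %s",
                 paste(excluded, collapse = ", ")))
  }
  live <- counts[!counts$sample_id %in% excluded, , drop = FALSE]
  keep_always <- live$feature %in% c(housekeeping, target)
  filtered <- bind_rows(
    suppressMessages(filter_min_tags(live[!keep_always, , drop = FALSE],
                                     min_tags, scope)),
    live[keep_always, , drop = FALSE])
  expr <- normalize_to_housekeeping(filtered, housekeeping)
  herv <- expr[grepl("^HERV", expr$feature), , drop = FALSE]
  herv_ranking <- herv |>
    group_by(.data$sample_id) |>
    arrange(dplyr::desc(.data$abundance), .by_group = TRUE) |>
    mutate(rank = dplyr::row_number()) |>
    ungroup()
  # per-family rollup alongside the region-specific features
  herv_family <- live[grepl("^HERV", live$feature), , drop = FALSE] |>
    group_by(.data$sample_id) |>
    summarise(family = "HERV-W", count = sum(.data$count),
              .groups = "drop")
  correlation <- tryCatch(
    select_correlated_genes(expr, target, cutoff),
    error = function(e) {
      warn(sprintf("correlation stage skipped: %s", conditionMessage(e)))
      NULL
    })
  files <- c(
    counts = write_tsv_out(counts, out_dir, "tag_counts.tsv"),
    filtered = write_tsv_out(filtered, out_dir, "filtered_counts.tsv"),
    expression = write_tsv_out(expr, out_dir, "expression.tsv"),
    herv_ranking = write_tsv_out(herv_ranking, out_dir,
                                 "herv_ranking.tsv"),
    herv_family = write_tsv_out(herv_family, out_dir,
                                "herv_family_counts.tsv")
  )
  if (!is.null(correlation)) {
    files["correlation"] <- write_tsv_out(as_tibble(correlation), out_dir,
                                          "correlation.tsv")
  }
  selected <- if (is.null(correlation)) character(0) else
    correlation$feature[correlation$selected]
  config <- list(
    version = as.character(utils::packageVersion("hervclone")),
    housekeeping = housekeeping, target = target, cutoff = cutoff,
    min_tags = min_tags, scope = scope, max_mismatch = max_mismatch,
    excluded_samples = excluded)
  jsonlite::write_json(list(config = config, selected_genes = selected),
                       file.path(out_dir, "selected_genes.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  files["selected_genes"] <- file.path(out_dir, "selected_genes.json")
  structure(list(counts = counts, filtered = filtered, expression = expr,
                 herv_ranking = herv_ranking, herv_family = herv_family,
                 correlation = correlation, excluded_samples = excluded,
                 files = files, config = config),
            class = "tag_run")
}

#' @export
print.clone_run <- function(x, ...) {
  cat("<clone_run>\n")
  cat(sprintf("  %d clones assigned across %d sample(s)\n",
              nrow(x$assignments),
              length(unique(x$assignments$sample_id))))
  print(x$locus_frequencies, n = 10)
  invisible(x)
}

#' @export
print.tag_run <- function(x, ...) {
  cat("<tag_run>\n")
  sel <- x$correlation$feature[x$correlation$selected]
  cat(sprintf("  %d feature(s) counted, %d selected at r^2 >= %.2f\n",
              length(unique(x$counts$feature)), length(sel),
              attr(x$correlation, "cutoff")))
  invisible(x)
}
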