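#' @importFrom dplyr bind_rows mutate filter group_by summarise ungroup
#'   arrange left_join select n
NULL

LOCUS_NAME_POOL <- c("7q21.2", "14", "15", "X", "3q23", "5p12", "6q21",
                     "2q13", "12q13", "20q11", "17p11", "1q32", "9p22",
                     "4q21", "11q13", "8p21")

locus_names <- function(n) {
  if (n <= length(LOCUS_NAME_POOL)) return(LOCUS_NAME_POOL[seq_len(n)])
  c(LOCUS_NAME_POOL, sprintf("loc%02d", seq_len(n - length(LOCUS_NAME_POOL))))
}

# fixed layout of the simulated ancestral locus:
#   pad - outer_sense - spacer - inner_sense - core - rc(inner_anti) -
#   spacer - rc(outer_anti) - pad
# primer footprints are shielded from mutation so in-silico PCR always
# finds its sites on simulated panels
ancestor_layout <- function(ancestor_length, primers) {
  lens <- c(pad_l = 50L,
            outer_s = nchar(primers$outer_sense),
            spacer1 = 20L,
            inner_s = nchar(primers$inner_sense),
            core = 0L,
            inner_a = nchar(primers$inner_antisense),
            spacer2 = 20L,
            outer_a = nchar(primers$outer_antisense),
            pad_r = 50L)
  core <- ancestor_length - sum(lens)
  if (core < 350L) {
    abort("ancestor_length too short for the primer layout",
          class = "hervclone_config_error")
  }
  lens["core"] <- core
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  layout <- tibble(part = names(lens), start = as.integer(starts),
                   end = as.integer(ends))
  shield <- unlist(lapply(c("outer_s", "inner_s", "inner_a", "outer_a"),
                          function(p) {
                            i <- which(layout$part == p)
                            seq(layout$start[i], layout$end[i])
                          }))
  list(layout = layout, shield = as.integer(shield))
}

build_ancestor <- function(ancestor_length, primers) {
  lay <- ancestor_layout(ancestor_length, primers)
  parts <- lay$layout
  piece <- character(nrow(parts))
  fill <- c(outer_s = primers$outer_sense,
            inner_s = primers$inner_sense,
            inner_a = revcomp(primers$inner_antisense),
            outer_a = revcomp(primers$outer_antisense))
  for (i in seq_len(nrow(parts))) {
    p <- parts$part[i]
    piece[i] <- if (p %in% names(fill)) fill[[p]] else
      random_dna(parts$end[i] - parts$start[i] + 1L)
  }
  list(sequence = paste(piece, collapse = ""), shield = lay$shield)
}

#' Simulate a HERV-W env paralog reference panel
#'
#' Builds a random ancestral locus containing intact nested-PCR primer
#' sites, then derives each panel locus as an independently mutated copy
#' (substitutions only, transition:transversion 2:1; primer footprints
#' shielded). Locus 1 is labelled `7q21.2` and flagged as the ERVWE1
#' prototype. A diverged `MSRV` outgroup copy is generated alongside for
#' tree rooting.
#'
#' @param config A [sim_config()].
#' @return A list of class `panel_sim` with elements `panel` (tibble:
#'   `locus_id`, `sequence`, `is_prototype`), `outgroup` (one-row
#'   tibble), `ancestor` (string) and `truth` (list with the shielded
#'   primer positions and per-locus substitution counts).
#' @export
#' @examples
#' sim <- simulate_panel(sim_config(seed = 1, n_loci = 4))
#' sim$panel
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  primers <- primer_set()
  with_seed(derive_seed(config$seed, 1L), {
    anc <- build_ancestor(config$ancestor_length, primers)
    ids <- locus_names(config$n_loci)
    seqs <- vapply(seq_len(config$n_loci), function(i) {
      mutate_seq(anc$sequence, config$per_locus_divergence, anc$shield)
    }, character(1))
    outgroup_seq <- mutate_seq(anc$sequence, config$outgroup_divergence,
                               anc$shield)
  })
  panel <- tibble(locus_id = ids, sequence = seqs,
                  is_prototype = seq_along(ids) == 1L)
  # fail loudly if divergence pushed identities under the configured floor
  if (config$n_loci >= 2L && config$per_locus_divergence > 0) {
    pw <- utils::combn(config$n_loci, 2L)
    idents <- vapply(seq_len(ncol(pw)), function(k) {
      hamming_identity(seqs[pw[1, k]], seqs[pw[2, k]])
    }, numeric(1))
    if (min(idents) < config$min_pairwise_identity) {
      abort(sprintf(
        "realized pairwise identity %.4f fell below the configured floor %.2f; lower per_locus_divergence",
        min(idents), config$min_pairwise_identity),
        class = "hervclone_sim_error")
    }
  }
  n_sub <- vapply(seqs, function(s) {
    round((1 - hamming_identity(anc$sequence, s)) * nchar(s))
  }, numeric(1))
  structure(list(
    panel = panel,
    outgroup = tibble(locus_id = "MSRV", sequence = outgroup_seq,
                      is_prototype = FALSE),
    ancestor = anc$sequence,
    truth = list(shielded_positions = anc$shield,
                 substitutions_per_locus = unname(n_sub))
  ), class = "panel_sim")
}

#' Simulate per-sample clone libraries from a panel
#'
#' Each clone is the nested-PCR amplicon of its origin locus with
#' independent per-base substitution errors at `clone_error_rate`
#' (emulating polymerase and sequencing error; a rate of 2e-4 reproduces
#' the ~0.02% diversity seen in plasmid PCR controls). Origin loci are
#' drawn from the per-sample mixture weights; clone counts are uniform
#' on `clones_per_sample`.
#'
#' @param panel Panel tibble (`locus_id`, `sequence`, `is_prototype`), as
#'   produced by [simulate_panel()] or [load_panel()].
#' @param config A [sim_config()].
#' @param primers A [primer_set()] used to excise the amplicon.
#' @return A list of class `clone_sim`: `clones` (tibble `sample_id`,
#'   `clone_id`, `sequence`) and `truth` (tibble `sample_id`, `clone_id`,
#'   `origin_locus`, `n_errors`, `error_positions` list-column).
#' @export
simulate_clones <- function(panel, config, primers = primer_set()) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(panel) == 0L) {
    abort("panel is empty", class = "hervclone_config_error")
  }
  w <- config$mixture_weights
  if (is.null(w)) w <- rep(1 / nrow(panel), nrow(panel))
  if (!is.list(w)) w <- rep(list(w), config$n_samples)
  if (length(w) != config$n_samples) {
    abort("need one mixture weight vector per sample",
          class = "hervclone_config_error")
  }
  for (wi in w) {
    if (length(wi) != nrow(panel)) {
      abort(sprintf("mixture weight vector length %d != %d loci",
                    length(wi), nrow(panel)),
            class = "hervclone_config_error")
    }
  }
  # amplicon of every locus once, up front
  amps <- vapply(panel$sequence, function(s) {
    pr <- in_silico_pcr(s, primers, stage = "nested")
    if (nrow(pr) == 0L) {
      abort("a panel locus yielded no nested PCR product",
            class = "hervclone_sim_error")
    }
    pr$sequence[1]
  }, character(1))
  rows <- vector("list", config$n_samples)
  with_seed(derive_seed(config$seed, 2L), {
    for (s in seq_len(config$n_samples)) {
      rng <- config$clones_per_sample[1]:config$clones_per_sample[2]
      n_clones <- rng[sample.int(length(rng), 1L)]
      origin <- sample(panel$locus_id, n_clones, replace = TRUE, prob = w[[s]])
      tmpl <- amps[match(origin, panel$locus_id)]
      mutated <- vapply(tmpl, mutate_seq, character(1),
                        rate = config$clone_error_rate)
      errs <- mapply(function(a, b) {
        which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
      }, tmpl, mutated, SIMPLIFY = FALSE)
      rows[[s]] <- tibble(
        sample_id = sprintf("S%02d", s),
        clone_id = sprintf("S%02d_c%02d", s, seq_len(n_clones)),
        origin_locus = origin,
        sequence = unname(mutated),
        n_errors = lengths(errs),
        error_positions = unname(errs)
      )
    }
  })
  all <- bind_rows(rows)
  structure(list(
    clones = all[, c("sample_id", "clone_id", "sequence")],
    truth = all[, c("sample_id", "clone_id", "origin_locus", "n_errors",
                    "error_positions")]
  ), class = "clone_sim")
}

#' Simulate a sample-by-feature tag-count table
#'
#' Emulates transcript-tag profiling of brain specimens: HERV-W features
#' (env, pol, LTR, gag, with env the most abundant), a GAPDH
#' housekeeping feature, "tracking" host genes whose expected counts are
#' affine in env abundance, and "independent" host genes with no
#' relation to env. Counts are negative binomial with the configured
#' dispersion.
#'
#' @param config A [sim_config()].
#' @param exact_tracking If `TRUE`, tracking genes are emitted without
#'   noise as proportional functions of the observed env counts
#'   (rounded), so their Pearson r^2 with env stays ~1 even after
#'   housekeeping normalisation (a shared noisy denominator preserves
#'   proportionality but not a nonzero intercept).
#' @return A list of class `tag_sim`: `counts` (tibble `sample_id`,
#'   `feature`, `count`), `truth` (tibble `feature`, `class`, `slope`,
#'   `intercept`) and `env_mean` (per-sample expected env counts).
#' @export
simulate_tag_counts <- function(config, exact_tracking = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_samples < 3L) {
    abort("n_samples must be >= 3 for tag simulation",
          class = "hervclone_config_error")
  }
  if (config$nb_dispersion <= 0) {
    abort("nb_dispersion must be > 0", class = "hervclone_config_error")
  }
  size <- 1 / config$nb_dispersion
  herv <- c("HERV-W_env" = 1, "HERV-W_pol" = 0.3, "HERV-W_LTR" = 0.2,
            "HERV-W_gag" = 0.1)
  trk <- sprintf("TRK%02d", seq_len(config$n_tracking_genes))
  ind <- sprintf("IND%02d", seq_len(config$n_independent_genes))
  samples <- sprintf("S%02d", seq_len(config$n_samples))
  with_seed(derive_seed(config$seed, 3L), {
    env_mean <- exp(stats::runif(config$n_samples, log(200), log(2000)))
    rows <- list()
    env_counts <- stats::rnbinom(config$n_samples, mu = env_mean,
                                 size = size)
    rows[["HERV-W_env"]] <- tibble(sample_id = samples,
                                   feature = "HERV-W_env",
                                   count = env_counts)
    for (f in setdiff(names(herv), "HERV-W_env")) {
      mu <- env_mean * herv[[f]]
      rows[[f]] <- tibble(sample_id = samples, feature = f,
                          count = stats::rnbinom(config$n_samples,
                                                 mu = mu, size = size))
    }
    rows[["GAPDH"]] <- tibble(sample_id = samples, feature = "GAPDH",
                              count = stats::rnbinom(config$n_samples,
                                                     mu = 1000, size = size))
    slope <- stats::runif(config$n_tracking_genes, 0.05, 0.5)
    intercept <- if (exact_tracking) rep(0, config$n_tracking_genes) else
      stats::runif(config$n_tracking_genes, 0, 50)
    for (i in seq_along(trk)) {
      cnt <- if (exact_tracking) round(slope[i] * env_counts) else
        stats::rnbinom(config$n_samples,
                       mu = intercept[i] + slope[i] * env_mean,
                       size = size)
      rows[[trk[i]]] <- tibble(sample_id = samples, feature = trk[i],
                               count = cnt)
    }
    ind_mu <- stats::runif(config$n_independent_genes, 50, 500)
    for (i in seq_along(ind)) {
      rows[[ind[i]]] <- tibble(sample_id = samples, feature = ind[i],
                               count = stats::rnbinom(config$n_samples,
                                                      mu = ind_mu[i],
                                                      size = size))
    }
  })
  counts <- bind_rows(rows)
  counts$count <- as.integer(counts$count)
  truth <- tibble(
    feature = c(names(herv), "GAPDH", trk, ind),
    class = c(rep("herv", length(herv)), "housekeeping",
              rep("tracking", length(trk)), rep("independent", length(ind))),
    slope = c(rep(NA_real_, length(herv) + 1L), slope,
              rep(NA_real_, length(ind))),
    intercept = c(rep(NA_real_, length(herv) + 1L), intercept,
                  rep(NA_real_, length(ind)))
  )
  structure(list(counts = counts, truth = truth,
                 env_mean = stats::setNames(env_mean, samples)),
            class = "tag_sim")
}

#' Simulate short-read tags from reference features
#'
#' Draws fixed-length reads uniformly from a set of reference sequences
#' (feature chosen by `proportions`, position uniform, strand uniform),
#' optionally with per-base substitution errors. Used to exercise and
#' calibrate [count_tags()].
#'
#' @param references Tibble with `feature` and `sequence` columns (or a
#'   named character vector).
#' @param n_reads Number of reads.
#' @param proportions Sampling weights over features (default uniform).
#' @param read_length Read length in bp (default 36).
#' @param error_rate Per-base substitution probability (default 0).
#' @param seed Integer seed.
#' @return List: `reads` (tibble `read_id`, `sequence`) and `truth`
#'   (tibble `read_id`, `feature`, `strand`, `start`).
#' @export
simulate_reads <- function(references, n_reads, proportions = NULL,
                           read_length = 36L, error_rate = 0, seed = 1L) {
  refs <- as_reference_tbl(references)
  if (any(nchar(refs$sequence) < read_length)) {
    abort("all references must be at least read_length long",
          class = "hervclone_config_error")
  }
  if (is.null(proportions)) proportions <- rep(1, nrow(refs))
  with_seed(derive_seed(seed, 4L), {
    feat_i <- sample(nrow(refs), n_reads, replace = TRUE, prob = proportions)
    starts <- vapply(feat_i, function(i) {
      sample.int(nchar(refs$sequence[i]) - read_length + 1L, 1L)
    }, integer(1))
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    seqs <- substring(refs$sequence[feat_i], starts, starts + read_length - 1L)
    seqs[strand == "-"] <- revcomp(seqs[strand == "-"])
    if (error_rate > 0) {
      seqs <- vapply(seqs, mutate_seq, character(1), rate = error_rate)
    }
  })
  list(
    reads = tibble(read_id = sprintf("r%06d", seq_len(n_reads)),
                   sequence = unname(seqs)),
    truth = tibble(read_id = sprintf("r%06d", seq_len(n_reads)),
                   feature = refs$feature[feat_i], strand = strand,
                   start = starts)
  )
}

#' Simulate a small reference feature set for tag counting
#'
#' Random, mutually unrelated reference sequences, one per feature name.
#'
#' @param features Character vector of feature names.
#' @param length Reference length in bp.
#' @param seed Integer seed.
#' @return Tibble with `feature` and `sequence`.
#' @export
simulate_tag_references <- function(features = c("HERV-W_env", "HERV-W_pol",
                                                 "HERV-W_LTR", "HERV-W_gag",
                                                 "GAPDH"),
                                    length = 150L, seed = 1L) {
  with_seed(derive_seed(seed, 5L), {
    tibble(feature = features,
           sequence = vapply(features, function(f) random_dna(length),
                             character(1)))
  })
}
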