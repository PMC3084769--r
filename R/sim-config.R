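#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators into one validated
#' object. The defaults emulate the study design the package targets: a
#' 12-locus HERV-W env paralog panel whose members stay above 90% mutual
#' identity, per-sample clone libraries of 6 to 27 sequences, a low
#' per-base clone error floor (the 0.02% level seen in plasmid PCR
#' controls corresponds to `clone_error_rate = 2e-4`), and overdispersed
#' tag counts in which a subset of host genes tracks env abundance.
#'
#' @param seed Integer seed; a fixed seed makes every generator
#'   byte-identical across runs.
#' @param n_loci Number of paralog loci in the panel (>= 2).
#' @param ancestor_length Length of the simulated ancestral locus in bp
#'   (>= 700). The default 838 makes the nested PCR product exactly
#'   650 bp.
#' @param per_locus_divergence Per-site substitution probability applied
#'   independently to each locus copy of the ancestor, in `[0, 1]`.
#' @param clone_error_rate Per-base substitution probability applied to
#'   each clone of its origin-locus amplicon, in `[0, 1]`.
#' @param clones_per_sample Integer range `c(low, high)`; clone counts per
#'   sample are drawn uniformly from it. Default `c(6, 27)`.
#' @param mixture_weights Either one nonnegative vector over loci summing
#'   to 1 (recycled across samples) or a list of such vectors, one per
#'   sample.
#' @param n_samples Number of samples.
#' @param tag_length Short-read tag length in bp (default 36).
#' @param nb_dispersion Positive negative-binomial dispersion for tag
#'   counts (variance = mu + dispersion * mu^2).
#' @param n_tracking_genes,n_independent_genes Number of host genes whose
#'   abundance tracks env (affine + noise) or is independent of it.
#' @param min_pairwise_identity Floor on realized pairwise locus identity;
#'   `simulate_panel()` fails loudly if any pair falls below it.
#' @param outgroup_divergence Per-site divergence of the simulated MSRV
#'   outgroup sequence from the ancestor.
#' @return An object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$n_loci
sim_config <- function(seed = 1L,
                       n_loci = 12L,
                       ancestor_length = 838L,
                       per_locus_divergence = 0.03,
                       clone_error_rate = 0.003,
                       clones_per_sample = c(6L, 27L),
                       mixture_weights = NULL,
                       n_samples = 5L,
                       tag_length = 36L,
                       nb_dispersion = 0.1,
                       n_tracking_genes = 10L,
                       n_independent_genes = 10L,
                       min_pairwise_identity = 0.90,
                       outgroup_divergence = 0.15) {
  cfg <- list(
    seed = as.integer(seed),
    n_loci = as.integer(n_loci),
    ancestor_length = as.integer(ancestor_length),
    per_locus_divergence = per_locus_divergence,
    clone_error_rate = clone_error_rate,
    clones_per_sample = as.integer(clones_per_sample),
    mixture_weights = mixture_weights,
    n_samples = as.integer(n_samples),
    tag_length = as.integer(tag_length),
    nb_dispersion = nb_dispersion,
    n_tracking_genes = as.integer(n_tracking_genes),
    n_independent_genes = as.integer(n_independent_genes),
    min_pairwise_identity = min_pairwise_identity,
    outgroup_divergence = outgroup_divergence
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stop_cfg <- function(msg) abort(msg, class = "hervclone_config_error")
  if (cfg$n_loci < 2L) stop_cfg("n_loci must be >= 2")
  if (cfg$ancestor_length < 700L) stop_cfg("ancestor_length must be >= 700")
  for (r in c("per_locus_divergence", "clone_error_rate")) {
    if (cfg[[r]] < 0 || cfg[[r]] > 1) {
      stop_cfg(sprintf("%s must be in [0, 1]", r))
    }
  }
  if (length(cfg$clones_per_sample) != 2L ||
      cfg$clones_per_sample[1] > cfg$clones_per_sample[2] ||
      cfg$clones_per_sample[1] < 1L) {
    stop_cfg("clones_per_sample must be c(low, high) with 1 <= low <= high")
  }
  if (cfg$nb_dispersion <= 0) stop_cfg("nb_dispersion must be > 0")
  if (cfg$n_samples < 1L) stop_cfg("n_samples must be >= 1")
  if (!is.null(cfg$mixture_weights)) {
    w <- cfg$mixture_weights
    if (!is.list(w)) w <- list(w)
    for (wi in w) {
      if (length(wi) != cfg$n_loci) {
        stop_cfg(sprintf(
          "mixture weight vector has length %d but panel has %d loci",
          length(wi), cfg$n_loci))
      }
      if (any(wi < 0)) stop_cfg("mixture weights must be nonnegative")
      if (abs(sum(wi) - 1) > 1e-9) {
        stop_cfg("mixture weights must sum to 1 (within 1e-9)")
      }
    }
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  seed %d | %d loci x %d bp ancestor | divergence %.3g\n",
              x$seed, x$n_loci, x$ancestor_length, x$per_locus_divergence))
  cat(sprintf("  %d samples, %d-%d clones each, clone error %.3g\n",
              x$n_samples, x$clones_per_sample[1], x$clones_per_sample[2],
              x$clone_error_rate))
  cat(sprintf("  tags: %d bp, NB dispersion %.3g, %d tracking + %d independent genes\n",
              x$tag_length, x$nb_dispersion, x$n_tracking_genes,
              x$n_independent_genes))
  invisible(x)
}
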