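# character matrix of equal-length aligned sequences, rows = sequences
seq_matrix <- function(seqs) {
  lens <- unique(nchar(seqs))
  if (length(lens) != 1L) {
    abort("sequences differ in length; align/trim them first",
          class = "hervclone_validation_error")
  }
  matrix(unlist(strsplit(seqs, "", fixed = TRUE)), nrow = length(seqs),
         byrow = TRUE)
}

#' Count variant (segregating) sites among aligned clones
#'
#' A site is variant when more than one base occurs among the clones at
#' that alignment column. Columns where any clone (or the reference,
#' when given) carries a gap or ambiguity character are excluded from
#' both the variant-site count `S` and the compared length `L`.
#'
#' @param clones Character vector of aligned, equal-length clone
#'   sequences (>= 2 for among-clone S).
#' @param reference Optional reference sequence of the same length;
#'   per-clone difference counts against it are reported.
#' @return List: `S`, `L`, `sites` (tibble `position`, `variant`),
#'   `vs_reference` (tibble `clone`, `differences`, `compared`; `NULL`
#'   without a reference).
#' @export
#' @examples
#' count_variant_sites(c("ACGT", "ACGA", "ACGT"))$S
count_variant_sites <- function(clones, reference = NULL) {
  if (length(clones) < 2L) {
    abort("need >= 2 clones for among-clone variant sites",
          class = "hervclone_validation_error")
  }
  m <- seq_matrix(c(clones, reference))
  cm <- m[seq_along(clones), , drop = FALSE]
  valid <- apply(m, 2L, function(col) all(col %in% DNA_BASES))
  poly <- apply(cm, 2L, function(col) length(unique(col)) > 1L)
  S <- sum(poly & valid)
  L <- sum(valid)
  vs_ref <- NULL
  if (!is.null(reference)) {
    ref <- m[nrow(m), ]
    vs_ref <- tibble(
      clone = seq_along(clones),
      differences = apply(cm[, valid, drop = FALSE], 1L,
                          function(r) sum(r != ref[valid])),
      compared = L)
  }
  list(S = S, L = L,
       sites = tibble(position = which(valid), variant = poly[valid]),
       vs_reference = vs_ref)
}

#' Watterson-normalised number of variant sites (theta)
#'
#' theta = S / (L * a), where a is the harmonic correction for sample
#' size, a = sum(1/i) for i = 1..(n-1). This is the standard
#' per-site normalisation of the observed number of nucleotide changes
#' by sequence length and sample size. `correction = "n"` divides by n
#' instead of the harmonic sum, for comparison.
#'
#' @param S Number of variant sites.
#' @param L Compared length in bp.
#' @param n Number of clones (>= 2).
#' @param correction `"watterson"` (default) or `"n"`.
#' @return Per-site theta (numeric scalar).
#' @export
#' @examples
#' theta_watterson(S = 3, L = 600, n = 6)
theta_watterson <- function(S, L, n, correction = c("watterson", "n")) {
  correction <- match.arg(correction)
  if (n < 2L) {
    abort("theta is undefined for n < 2", class = "hervclone_validation_error")
  }
  if (L <= 0 || S < 0 || S > L) {
    abort("need L > 0 and 0 <= S <= L", class = "hervclone_validation_error")
  }
  a <- switch(correction,
              watterson = sum(1 / seq_len(n - 1L)),
              n = n)
  S / (L * a)
}

#' Percent diversity of clones relative to a reference
#'
#' The mean over clones of 100 * (mismatched columns / compared
#' columns) against the reference (prototype) sequence, with
#' gap/ambiguity columns excluded pairwise-complete. `method =
#' "pooled"` instead pools mismatches and compared columns over all
#' clones before taking the ratio; both are reported by
#' [diversity_summary()] since either reading of a per-patient percent
#' is defensible.
#'
#' @param clones Character vector of aligned clone sequences.
#' @param reference Reference sequence of the same length.
#' @param method `"per_clone"` (default) or `"pooled"`.
#' @return Percent diversity in `[0, 100]`.
#' @export
#' @examples
#' percent_diversity(c("AAAAAA", "AAAAAT"), "AAAAAA")
percent_diversity <- function(clones, reference,
                              method = c("per_clone", "pooled")) {
  method <- match.arg(method)
  ref <- strsplit(normalize_seq(reference, "reference"), "")[[1]]
  per <- vapply(clones, function(cl) {
    v <- strsplit(cl, "", fixed = TRUE)[[1]]
    if (length(v) != length(ref)) {
      abort("clone and reference lengths differ; trim/align first",
            class = "hervclone_validation_error")
    }
    ok <- v %in% DNA_BASES & ref %in% DNA_BASES
    if (!any(ok)) {
      abort("zero comparable columns between clone and reference",
            class = "hervclone_validation_error")
    }
    c(mm = sum(v[ok] != ref[ok]), comp = sum(ok))
  }, numeric(2))
  if (method == "per_clone") {
    mean(100 * per["mm", ] / per["comp", ])
  } else {
    100 * sum(per["mm", ]) / sum(per["comp", ])
  }
}

#' Per-sample molecular diversity summary
#'
#' For each sample: clone count `n`, compared length `L`, variant sites
#' `S`, Watterson-normalised `theta`, and percent divergence of the
#' clones from the prototype (per-clone mean and pooled).
#'
#' @param clones Tibble with `sample_id`, `clone_id`, `sequence`
#'   (aligned/trimmed to common coordinates within each sample).
#' @param reference Prototype insert sequence (same length as the
#'   clones).
#' @return Tibble: `sample_id`, `n`, `L`, `S`, `theta`,
#'   `pct_div_vs_prototype`, `pct_div_pooled`.
#' @export
diversity_summary <- function(clones, reference) {
  clones |>
    group_by(.data$sample_id) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 2L) {
        return(tibble(n = nrow(d), L = NA_integer_, S = NA_integer_,
                      theta = NA_real_,
                      pct_div_vs_prototype =
                        percent_diversity(d$sequence, reference),
                      pct_div_pooled =
                        percent_diversity(d$sequence, reference, "pooled")))
      }
      vs <- count_variant_sites(d$sequence, reference)
      tibble(n = nrow(d), L = vs$L, S = vs$S,
             theta = theta_watterson(vs$S, vs$L, nrow(d)),
             pct_div_vs_prototype = percent_diversity(d$sequence, reference),
             pct_div_pooled = percent_diversity(d$sequence, reference,
                                                "pooled"))
    }) |>
    ungroup()
}

#' Spearman correlation of per-sample diversity with env abundance
#'
#' Rank correlation between intra-sample clone diversity (percent
#' divergence from the prototype) and HERV-W env transcript abundance,
#' with exact p-values for n <= 10 (no ties) and the t approximation
#' otherwise.
#'
#' @param diversity Numeric vector of per-sample percent diversities.
#' @param abundance Numeric vector of per-sample env abundances (same
#'   order, >= 4 pairs).
#' @return One-row tibble: `rho`, `p.value`, `n`, `undefined`.
#' @export
correlate_diversity_abundance <- function(diversity, abundance) {
  if (length(diversity) != length(abundance) || length(diversity) < 4L) {
    abort("need >= 4 paired samples", class = "hervclone_validation_error")
  }
  if (stats::sd(diversity) == 0 || stats::sd(abundance) == 0) {
    return(tibble(rho = NA_real_, p.value = NA_real_,
                  n = length(diversity), undefined = TRUE))
  }
  exact <- length(diversity) <= 10L && !anyDuplicated(diversity) &&
    !anyDuplicated(abundance)
  ct <- suppressWarnings(
    stats::cor.test(diversity, abundance, method = "spearman",
                    exact = exact))
  tibble(rho = unname(ct$estimate), p.value = ct$p.value,
         n = length(diversity), undefined = FALSE)
}
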