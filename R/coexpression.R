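expr_wide <- function(expr, value = "abundance") {
  tidyr::pivot_wider(expr[, c("sample_id", "feature", value)],
                     names_from = "feature",
                     values_from = dplyr::all_of(value))
}

#' Select host genes co-expressed with a target feature
#'
#' Pearson correlation of every feature's normalised abundance with the
#' target feature across samples; features with `r^2 >= cutoff` are
#' selected. Zero-variance features are flagged undefined and excluded
#' from selection. Pearson r is invariant to affine rescaling, so
#' selection is unchanged by per-gene scaling.
#'
#' @param expr Long expression tibble (`sample_id`, `feature`,
#'   `abundance`), e.g. from [normalize_to_housekeeping()].
#' @param target Target feature label (default `"HERV-W_env"`).
#' @param cutoff r-squared selection cutoff, inclusive (default 0.75).
#' @return A `correlation_report`: tibble `feature`, `r`, `r_squared`,
#'   `undefined`, `selected`, sorted by `r_squared`; attributes
#'   `target`, `cutoff`, `n_samples`.
#' @export
select_correlated_genes <- function(expr, target = "HERV-W_env",
                                    cutoff = 0.75) {
  wide <- expr_wide(expr)
  if (!target %in% names(wide)) {
    abort(sprintf("target feature '%s' not present", target),
          class = "hervclone_config_error")
  }
  if (nrow(wide) < 3L) {
    abort("need >= 3 samples", class = "hervclone_validation_error")
  }
  tv <- wide[[target]]
  if (stats::sd(tv) == 0) {
    abort("target feature is constant across samples",
          class = "hervclone_validation_error")
  }
  genes <- setdiff(names(wide), c("sample_id", target))
  rep <- purrr::map_dfr(genes, function(g) {
    v <- wide[[g]]
    if (stats::sd(v) == 0) {
      tibble(feature = g, r = NA_real_, r_squared = NA_real_,
             undefined = TRUE, selected = FALSE)
    } else {
      r <- stats::cor(v, tv)
      tibble(feature = g, r = r, r_squared = r^2, undefined = FALSE,
             selected = r^2 >= cutoff)
    }
  })
  rep <- arrange(rep, dplyr::desc(.data$r_squared))
  structure(rep, class = c("correlation_report", class(rep)),
            target = target, cutoff = cutoff, n_samples = nrow(wide))
}

#' Mann-Whitney U comparison of a feature between two groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test; the exact null
#' distribution is used when `min(n1, n2) <= 8` and there are no ties,
#' otherwise the normal approximation with tie correction. When every
#' value is tied across both groups the result is degenerate with
#' p = 1.
#'
#' @param x,y Numeric vectors for the two groups (each n >= 3).
#' @return An object of class `group_comparison` wrapping the test;
#'   use [generics::tidy()] for a tibble.
#' @export
#' @examples
#' tidy(group_compare(c(1, 2, 3), c(4, 5, 6)))
group_compare <- function(x, y) {
  if (length(x) < 3L || length(y) < 3L) {
    abort("each group needs n >= 3", class = "hervclone_validation_error")
  }
  all_tied <- length(unique(c(x, y))) == 1L
  if (all_tied) {
    res <- list(statistic = c(W = length(x) * length(y) / 2),
                p.value = 1, method = "degenerate (all values tied)")
  } else {
    ties <- anyDuplicated(c(x, y)) > 0L
    exact <- min(length(x), length(y)) <= 8L && !ties
    res <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = !exact))
  }
  structure(list(
    U = unname(res$statistic), p.value = res$p.value,
    median_x = stats::median(x), median_y = stats::median(y),
    n1 = length(x), n2 = length(y),
    direction = if (stats::median(x) > stats::median(y)) "up"
                else if (stats::median(x) < stats::median(y)) "down"
                else "none",
    degenerate = all_tied, method = res$method
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> U = %.1f, p = %.4g (medians %.3g vs %.3g, %s)\n",
              x$U, x$p.value, x$median_x, x$median_y, x$direction))
  invisible(x)
}

#' Per-gene Spearman correlation with a target feature
#'
#' Spearman rho and p-value of each gene against the target, exact p
#' for n <= 10 without ties and the t approximation otherwise;
#' constant genes are flagged undefined. The report is sorted by
#' absolute rho.
#'
#' @param expr Long expression tibble (`sample_id`, `feature`,
#'   `abundance`).
#' @param target Target feature label.
#' @param genes Optional subset of features to test (default all but
#'   the target).
#' @param adjust Multiple-testing adjustment for the reported
#'   `p.adjusted` column: `"none"` (default; the screen reports
#'   unadjusted thresholds) or `"BH"` (Benjamini-Hochberg).
#' @return Tibble: `feature`, `rho`, `p.value`, `p.adjusted`, `n`,
#'   `undefined`.
#' @export
spearman_env_immune <- function(expr, target = "HERV-W_env", genes = NULL,
                                adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  wide <- expr_wide(expr)
  if (!target %in% names(wide)) {
    abort(sprintf("target feature '%s' not present", target),
          class = "hervclone_config_error")
  }
  if (nrow(wide) < 4L) {
    abort("need >= 4 paired samples", class = "hervclone_validation_error")
  }
  tv <- wide[[target]]
  genes <- genes %||% setdiff(names(wide), c("sample_id", target))
  out <- purrr::map_dfr(genes, function(g) {
    v <- wide[[g]]
    if (stats::sd(v) == 0 || stats::sd(tv) == 0) {
      return(tibble(feature = g, rho = NA_real_, p.value = NA_real_,
                    n = length(v), undefined = TRUE))
    }
    exact <- length(v) <= 10L && !anyDuplicated(v) && !anyDuplicated(tv)
    ct <- suppressWarnings(stats::cor.test(v, tv, method = "spearman",
                                           exact = exact))
    tibble(feature = g, rho = unname(ct$estimate), p.value = ct$p.value,
           n = length(v), undefined = FALSE)
  })
  out$p.adjusted <- stats::p.adjust(out$p.value,
                                    method = if (adjust == "BH") "BH"
                                             else "none")
  arrange(out, dplyr::desc(abs(.data$rho)))
}

#' Row-standardised expression matrix for heatmap display
#'
#' Per-gene z-scores across samples using the sample (n - 1) standard
#' deviation; zero-variance rows are emitted as zeros and listed in the
#' `constant_features` attribute.
#'
#' @param expr Long expression tibble (`sample_id`, `feature`,
#'   `abundance`).
#' @param genes Optional subset of features (default all).
#' @return Numeric matrix, genes in rows, samples in columns.
#' @export
#' @examples
#' expr <- tibble::tibble(sample_id = rep(c("a", "b", "c"), 2),
#'                        feature = rep(c("g1", "g2"), each = 3),
#'                        abundance = c(1, 2, 3, 5, 5, 5))
#' expression_matrix_for_heatmap(expr)
expression_matrix_for_heatmap <- function(expr, genes = NULL) {
  wide <- expr_wide(expr)
  if (nrow(wide) < 2L) {
    abort("need >= 2 samples", class = "hervclone_validation_error")
  }
  genes <- genes %||% setdiff(names(wide), "sample_id")
  m <- t(as.matrix(wide[, genes, drop = FALSE]))
  colnames(m) <- wide$sample_id
  sds <- apply(m, 1L, stats::sd)
  const <- rownames(m)[sds == 0]
  z <- (m - rowMeans(m)) / ifelse(sds == 0, 1, sds)
  z[sds == 0, ] <- 0
  attr(z, "constant_features") <- const
  z
}
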