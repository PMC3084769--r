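#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a group comparison
#'
#' @param x A `group_comparison` from [group_compare()].
#' @param ... Ignored.
#' @return One-row tibble: `U`, `p.value`, `median_x`, `median_y`,
#'   `n1`, `n2`, `direction`, `degenerate`, `method`.
#' @export
tidy.group_comparison <- function(x, ...) {
  tibble(U = x$U, p.value = x$p.value, median_x = x$median_x,
         median_y = x$median_y, n1 = x$n1, n2 = x$n2,
         direction = x$direction, degenerate = x$degenerate,
         method = x$method)
}

#' Tidy a correlation report
#'
#' @param x A `correlation_report` from [select_correlated_genes()].
#' @param ... Ignored.
#' @return The per-gene tibble (`feature`, `r`, `r_squared`,
#'   `undefined`, `selected`).
#' @export
tidy.correlation_report <- function(x, ...) {
  as_tibble(x)
}

#' Glance at a correlation report
#'
#' @param x A `correlation_report`.
#' @param ... Ignored.
#' @return One-row tibble: `target`, `cutoff`, `n_samples`, `n_genes`,
#'   `n_selected`, `n_undefined`.
#' @export
glance.correlation_report <- function(x, ...) {
  tibble(target = attr(x, "target"), cutoff = attr(x, "cutoff"),
         n_samples = attr(x, "n_samples"), n_genes = nrow(x),
         n_selected = sum(x$selected, na.rm = TRUE),
         n_undefined = sum(x$undefined))
}

#' Tidy a tag-count result
#'
#' @param x A `tag_counts` from [count_tags()].
#' @param ... Ignored.
#' @return The per-feature count tibble.
#' @export
tidy.tag_counts <- function(x, ...) {
  x$counts
}

#' Glance at a tag-count result
#'
#' @param x A `tag_counts`.
#' @param ... Ignored.
#' @return One-row tibble: `total`, `counted`, `ambiguous`,
#'   `unmatched`.
#' @export
glance.tag_counts <- function(x, ...) {
  tibble(total = x$total, counted = sum(x$counts$count),
         ambiguous = x$ambiguous, unmatched = x$unmatched)
}

#' Glance at a clone pipeline run
#'
#' @param x A `clone_run` from [run_clone_pipeline()].
#' @param ... Ignored.
#' @return One-row tibble with clone, call and sample tallies.
#' @export
glance.clone_run <- function(x, ...) {
  tibble(n_clones = nrow(x$assignments),
         n_called = sum(!x$assignments$call %in% c("ND", "AMBIGUOUS")),
         n_nd = sum(x$assignments$call == "ND"),
         n_ambiguous = sum(x$assignments$call == "AMBIGUOUS"),
         n_samples = length(unique(x$assignments$sample_id)))
}
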