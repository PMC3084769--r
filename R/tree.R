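#' Neighbor-joining tree with optional outgroup rooting
#'
#' Saitou-Nei neighbor joining (Studier-Keppler Q-criterion, as
#' implemented in \pkg{ape}) on a distance matrix. When an outgroup is
#' given, the root is placed at the midpoint of the outgroup's pendant
#' edge. Negative branch lengths, which NJ can produce, are retained
#' and flagged via the `negative_lengths` attribute rather than
#' clamped, so additivity checks stay exact.
#'
#' @param dm Symmetric distance matrix with labelled dimnames (or a
#'   `dist` object), at least 3 taxa.
#' @param outgroup Optional taxon label to root on.
#' @return An [ape::phylo] tree; rooted iff `outgroup` was given.
#' @export
#' @examples
#' d <- matrix(c(0, 3, 5, 6, 3, 0, 6, 7, 5, 6, 0, 7, 6, 7, 7, 0), 4, 4,
#'             dimnames = list(LETTERS[1:4], LETTERS[1:4]))
#' nj_tree(d, outgroup = "D")
nj_tree <- function(dm, outgroup = NULL) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  if (!isSymmetric(unname(dm), tol = 1e-8)) {
    abort("distance matrix must be symmetric",
          class = "hervclone_validation_error")
  }
  if (nrow(dm) < 3L) {
    abort("neighbor joining needs >= 3 taxa",
          class = "hervclone_validation_error")
  }
  if (is.null(rownames(dm))) {
    rownames(dm) <- colnames(dm) <- paste0("t", seq_len(nrow(dm)))
  }
  tr <- ape::nj(stats::as.dist(dm))
  if (!is.null(outgroup)) {
    if (!outgroup %in% tr$tip.label) {
      abort(sprintf("outgroup '%s' is not among the taxa", outgroup),
            class = "hervclone_config_error")
    }
    tr <- root_on_outgroup_edge(tr, outgroup)
  }
  attr(tr, "negative_lengths") <- any(tr$edge.length < 0)
  tr
}

# root at the midpoint of the outgroup's pendant edge: after ape::root()
# the outgroup hangs off the root with its whole pendant length and its
# sibling edge has length 0; split the pendant length between the two
root_on_outgroup_edge <- function(tr, outgroup) {
  tip <- which(tr$tip.label == outgroup)
  pend <- tr$edge.length[tr$edge[, 2] == tip]
  rooted <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  root_node <- ape::Ntip(rooted) + 1L
  kids <- which(rooted$edge[, 1] == root_node)
  tip2 <- which(rooted$tip.label == outgroup)
  for (k in kids) {
    rooted$edge.length[k] <- pend / 2
  }
  # guard: both root children must sum to the original pendant length
  stopifnot(length(kids) == 2L, any(rooted$edge[kids, 2] == tip2))
  rooted
}

#' Write / read trees in Newick format
#'
#' Thin wrappers over [ape::write.tree()] and [ape::read.tree()] kept
#' for a uniform IO surface; round-trips preserve topology and branch
#' lengths.
#'
#' @param tree An `phylo` object.
#' @param path File path.
#' @return `write_newick` returns `path` invisibly; `read_newick`
#'   returns a `phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
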