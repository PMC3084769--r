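# --- genetic-code machinery -------------------------------------------------

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- gsub("U", "T", names(gc))
  gc
}

# degeneracy class of each position of each codon: number of the three
# possible substitutions that are synonymous, mapped 0 -> 0-fold,
# 1 or 2 -> 2-fold, 3 -> 4-fold (the usual convention: third positions of
# three-codon families count as twofold). Stop codons get NA.
codon_degeneracy <- function() {
  gc <- codon_table()
  codons <- names(gc)
  deg <- matrix(NA_integer_, nrow = length(codons), ncol = 3L,
                dimnames = list(codons, NULL))
  for (cd in codons) {
    aa <- gc[[cd]]
    if (aa == "*") next
    for (pos in 1:3) {
      alts <- vapply(setdiff(DNA_BASES, substr(cd, pos, pos)), function(b) {
        alt <- cd
        substr(alt, pos, pos) <- b
        gc[[alt]] == aa
      }, logical(1))
      nsyn <- sum(alts)
      deg[cd, pos] <- if (nsyn == 0L) 0L else if (nsyn == 3L) 4L else 2L
    }
  }
  deg
}

# cached at first use
the <- new.env(parent = emptyenv())
get_degeneracy <- function() {
  if (is.null(the$deg)) the$deg <- codon_degeneracy()
  the$deg
}

split_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1, n, 3L), seq(3, n, 3L))
}

# all minimal mutational pathways between two codons, as lists of
# (from_codon, to_codon, position) steps; pathways through stop codons
# are dropped unless every pathway passes through a stop
codon_pathways <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0L) return(list())
  gc <- codon_table()
  perms <- permutations_of(pos)
  paths <- lapply(perms, function(order) {
    cur <- c1
    steps <- vector("list", length(order))
    via_stop <- FALSE
    for (k in seq_along(order)) {
      p <- order[k]
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      steps[[k]] <- list(from = cur, to = nxt, pos = p)
      if (k < length(order) && gc[[nxt]] == "*") via_stop <- TRUE
      cur <- nxt
    }
    list(steps = steps, via_stop = via_stop)
  })
  ok <- !vapply(paths, `[[`, logical(1), "via_stop")
  if (any(ok)) paths <- paths[ok]
  lapply(paths, `[[`, "steps")
}

permutations_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}

class_index <- function(cl) match(cl, c(0L, 2L, 4L))

# --- the estimator ----------------------------------------------------------

#' Ka/Ks by the Li-Wu-Luo (1985) counting method
#'
#' Sites are classified by codon-position degeneracy (nondegenerate,
#' twofold, fourfold; standard genetic code) and the class counts L0,
#' L2, L4 averaged over the two sequences. Nucleotide differences are
#' resolved by enumerating all minimal mutational pathways between the
#' two codons (pathways through stop codons are excluded when any
#' stop-free pathway exists), averaging the per-class transition (S_i)
#' and transversion (V_i) counts over pathways; at each step the changed
#' position contributes half to its class in the "from" codon and half
#' to its class in the "to" codon. Per-class K2P corrections give A_i
#' (transition) and B_i (transversion) distances, and
#' \deqn{Ks = (L2 A2 + L4 (A4 + B4)) / (L2/3 + L4)}
#' \deqn{Ka = (L2 B2 + L0 (A0 + B0)) / (2 L2/3 + L0)}
#' `weighting = "mlwl"` replaces the 1/3 : 2/3 split of twofold sites by
#' kappa/(kappa+2) : 2/(kappa+2) with kappa estimated from the fourfold
#' class (a kappa-aware variant of the estimator).
#'
#' @param seq1,seq2 Coding sequences of equal length, a multiple of 3,
#'   with no stop codons.
#' @param weighting `"lwl"` (default) or `"mlwl"`.
#' @return One-row tibble: `Ka`, `Ks`, `ka_ks` (NaN with `ks_zero =
#'   TRUE` when Ks = 0), site counts `L0`, `L2`, `L4`, per-class `A0`,
#'   `A2`, `A4`, `B0`, `B2`, `B4`, and flags `saturated`, `ks_zero`.
#' @export
#' @examples
#' kaks_lwl("ATGAAA", "ATGAAG")
kaks_lwl <- function(seq1, seq2, weighting = c("lwl", "mlwl")) {
  weighting <- match.arg(weighting)
  seq1 <- normalize_seq(seq1, "seq1")
  seq2 <- normalize_seq(seq2, "seq2")
  if (nchar(seq1) != nchar(seq2)) {
    abort("sequences must have equal length",
          class = "hervclone_validation_error")
  }
  if (nchar(seq1) %% 3L != 0L || nchar(seq1) == 0L) {
    abort("length must be a positive multiple of 3",
          class = "hervclone_validation_error")
  }
  if (grepl("[^ACGT]", seq1) || grepl("[^ACGT]", seq2)) {
    abort("coding sequences must be unambiguous ACGT",
          class = "hervclone_validation_error")
  }
  gc <- codon_table()
  deg <- get_degeneracy()
  cod1 <- split_codons(seq1)
  cod2 <- split_codons(seq2)
  if (any(gc[cod1] == "*") || any(gc[cod2] == "*")) {
    abort("stop codon present; trim coding sequences first",
          class = "hervclone_validation_error")
  }
  L <- c(0, 0, 0)   # 0-, 2-, 4-fold site counts, averaged over the pair
  S <- c(0, 0, 0)   # transitions per class
  V <- c(0, 0, 0)   # transversions per class
  for (i in seq_along(cod1)) {
    d1 <- deg[cod1[i], ]
    d2 <- deg[cod2[i], ]
    for (p in 1:3) {
      L[class_index(d1[p])] <- L[class_index(d1[p])] + 0.5
      L[class_index(d2[p])] <- L[class_index(d2[p])] + 0.5
    }
    paths <- codon_pathways(cod1[i], cod2[i])
    if (length(paths) == 0L) next
    w <- 1 / length(paths)
    for (path in paths) {
      for (st in path) {
        b1 <- substr(st$from, st$pos, st$pos)
        b2 <- substr(st$to, st$pos, st$pos)
        ts <- is_transition(b1, b2)
        for (cl in c(deg[st$from, st$pos], deg[st$to, st$pos])) {
          k <- class_index(cl)
          if (ts) S[k] <- S[k] + 0.5 * w else V[k] <- V[k] + 0.5 * w
        }
      }
    }
  }
  P <- ifelse(L > 0, S / L, 0)
  Q <- ifelse(L > 0, V / L, 0)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  saturated <- any(L > 0 & (w1 <= 0 | w2 <= 0))
  A <- B <- rep(NA_real_, 3)
  okc <- L > 0 & w1 > 0 & w2 > 0
  A[okc] <- 0.5 * log(1 / w1[okc]) - 0.25 * log(1 / w2[okc])
  B[okc] <- 0.5 * log(1 / w2[okc])
  A0 <- A[1]; A2 <- A[2]; A4 <- A[3]
  B0 <- B[1]; B2 <- B[2]; B4 <- B[3]
  term <- function(x, l) if (l > 0) x * l else 0
  if (weighting == "lwl") {
    syn2 <- 1 / 3
  } else {
    # kappa from the fourfold class; falls back to 2 when inestimable
    kappa <- if (!is.na(A4) && !is.na(B4) && B4 > 0) {
      max(2 * A4 / B4, 0)
    } else 2
    syn2 <- kappa / (kappa + 2)
  }
  Ks_num <- term(A2, L[2]) + term(A4 + B4, L[3])
  Ks_den <- syn2 * L[2] + L[3]
  Ka_num <- term(B2, L[2]) + term(A0 + B0, L[1])
  Ka_den <- (1 - syn2) * L[2] + L[1]
  # counting noise can push a per-class K2P component slightly negative
  # (e.g. transversions without transitions); estimates are floored at 0
  Ks <- if (saturated) NA_real_ else if (Ks_den > 0)
    max(Ks_num / Ks_den, 0) else NA_real_
  Ka <- if (saturated) NA_real_ else if (Ka_den > 0)
    max(Ka_num / Ka_den, 0) else NA_real_
  ks_zero <- !is.na(Ks) && Ks == 0
  ratio <- if (is.na(Ka) || is.na(Ks)) NA_real_ else if (ks_zero) NaN else
    Ka / Ks
  tibble(Ka = Ka, Ks = Ks, ka_ks = ratio,
         L0 = L[1], L2 = L[2], L4 = L[3],
         A0 = A0, A2 = A2, A4 = A4, B0 = B0, B2 = B2, B4 = B4,
         saturated = saturated, ks_zero = ks_zero)
}

#' Pairwise Ka/Ks over a table of coding sequences
#'
#' @param seqs Tibble with id and `sequence` columns (equal-length
#'   coding sequences).
#' @param id Column holding the labels.
#' @param weighting Passed to [kaks_lwl()].
#' @return Tibble with one row per unordered pair: `id1`, `id2` and the
#'   [kaks_lwl()] columns.
#' @export
kaks_pairwise <- function(seqs, id = 1L, weighting = "lwl") {
  labs <- seqs[[id]]
  pairs <- utils::combn(nrow(seqs), 2L)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    res <- kaks_lwl(seqs$sequence[i], seqs$sequence[j], weighting)
    dplyr::bind_cols(tibble(id1 = labs[i], id2 = labs[j]), res)
  })
}
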