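# Independent brute-force oracles used to validate the package's
# implementations. Each is written from first principles against the
# documented conventions, not by calling the code under test.

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# mutate exactly k distinct positions (substitutions only)
mutate_k <- function(seq, k) {
  v <- strsplit(seq, "")[[1]]
  pos <- sample(length(v), k)
  for (i in pos) {
    v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  }
  paste(v, collapse = "")
}

# ---- affine-gap overlap alignment oracle (Gotoh, free end gaps) -----------
# returns the optimal score under match +1 / mismatch -1 / gap open 5 /
# gap extend 2 with end gaps free on both sequences, as a plain dynamic
# program (quadratic time, no traceback)
overlap_align_score <- function(a, b, match = 1, mismatch = -1,
                                gap_open = 5, gap_ext = 2) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  n <- length(va); m <- length(vb)
  NEG <- -1e9
  # M: end in match/mismatch; X: gap in b (consume a); Y: gap in a
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, ] <- 0  # free leading gaps: any prefix of either sequence skipped
  M[, 1] <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (va[i - 1] == vb[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_ext,
                     X[i - 1, j] - gap_ext)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_ext,
                     Y[i, j - 1] - gap_ext)
    }
  }
  # free trailing gaps: best cell on the last row or column
  best <- NEG
  for (i in 1:(n + 1)) best <- max(best, M[i, m + 1], X[i, m + 1], Y[i, m + 1])
  for (j in 1:(m + 1)) best <- max(best, M[n + 1, j], X[n + 1, j], Y[n + 1, j])
  max(best, 0)
}

# ---- LWL85 Ka/Ks oracle ----------------------------------------------------
# completely separate implementation: its own genetic code table, its
# own degeneracy computation, recursive pathway enumeration

oracle_code <- local({
  b1 <- rep(c("T", "C", "A", "G"), each = 16)
  b2 <- rep(rep(c("T", "C", "A", "G"), each = 4), 4)
  b3 <- rep(c("T", "C", "A", "G"), 16)
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aa, paste0(b1, b2, b3))
})

oracle_deg <- function(codon, pos) {
  aa <- oracle_code[[codon]]
  nsyn <- 0L
  for (b in setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))) {
    alt <- codon
    substr(alt, pos, pos) <- b
    if (oracle_code[[alt]] == aa) nsyn <- nsyn + 1L
  }
  if (nsyn == 0L) 0L else if (nsyn == 3L) 4L else 2L
}

oracle_is_ts <- function(x, y) {
  paste0(x, y) %in% c("AG", "GA", "CT", "TC")
}

# enumerate all orderings of the differing positions recursively
oracle_paths <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0) return(list())
  recurse <- function(cur, remaining, steps) {
    if (length(remaining) == 0) return(list(steps))
    out <- list()
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      out <- c(out, recurse(nxt, setdiff(remaining, p),
                            c(steps, list(list(from = cur, to = nxt,
                                               pos = p)))))
    }
    out
  }
  paths <- recurse(c1, pos, list())
  # drop pathways via stop codons at intermediate states when possible
  via_stop <- vapply(paths, function(path) {
    if (length(path) < 2) return(FALSE)
    any(vapply(path[-length(path)], function(st) {
      oracle_code[[st$to]] == "*"
    }, logical(1)))
  }, logical(1))
  if (any(!via_stop)) paths <- paths[!via_stop]
  paths
}

oracle_kaks <- function(s1, s2) {
  cods1 <- substring(s1, seq(1, nchar(s1), 3), seq(3, nchar(s1), 3))
  cods2 <- substring(s2, seq(1, nchar(s2), 3), seq(3, nchar(s2), 3))
  L <- c("0" = 0, "2" = 0, "4" = 0)
  S <- c("0" = 0, "2" = 0, "4" = 0)
  V <- c("0" = 0, "2" = 0, "4" = 0)
  for (i in seq_along(cods1)) {
    for (p in 1:3) {
      L[as.character(oracle_deg(cods1[i], p))] <-
        L[as.character(oracle_deg(cods1[i], p))] + 0.5
      L[as.character(oracle_deg(cods2[i], p))] <-
        L[as.character(oracle_deg(cods2[i], p))] + 0.5
    }
    paths <- oracle_paths(cods1[i], cods2[i])
    if (length(paths) == 0) next
    for (path in paths) {
      for (st in path) {
        bfrom <- substr(st$from, st$pos, st$pos)
        bto <- substr(st$to, st$pos, st$pos)
        for (cl in c(oracle_deg(st$from, st$pos),
                     oracle_deg(st$to, st$pos))) {
          key <- as.character(cl)
          add <- 0.5 / length(paths)
          if (oracle_is_ts(bfrom, bto)) S[key] <- S[key] + add
          else V[key] <- V[key] + add
        }
      }
    }
  }
  kd <- function(P, Q) {
    w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
    if (w1 <= 0 || w2 <= 0) return(c(A = NA, B = NA))
    c(A = 0.5 * log(1 / w1) - 0.25 * log(1 / w2), B = 0.5 * log(1 / w2))
  }
  AB <- sapply(c("0", "2", "4"), function(k) {
    if (L[k] > 0) kd(unname(S[k] / L[k]), unname(V[k] / L[k]))
    else c(A = NA, B = NA)
  })
  tA <- function(k) if (L[k] > 0 && !is.na(AB["A", k])) AB["A", k] * L[k] else 0
  tB <- function(k) if (L[k] > 0 && !is.na(AB["B", k])) AB["B", k] * L[k] else 0
  Ks_den <- L["2"] / 3 + L["4"]
  Ka_den <- 2 * L["2"] / 3 + L["0"]
  # same zero floor as the estimator under test
  list(
    Ka = if (Ka_den > 0)
      max(unname((tB("2") + tA("0") + tB("0")) / Ka_den), 0) else NA,
    Ks = if (Ks_den > 0)
      max(unname((tA("2") + tA("4") + tB("4")) / Ks_den), 0) else NA,
    L = unname(L))
}

# random stop-free coding sequence of n codons
rand_cds <- function(n_codons) {
  ok <- names(oracle_code)[oracle_code != "*"]
  paste(sample(ok, n_codons, replace = TRUE), collapse = "")
}

# mutate a CDS avoiding stop codons in the result
mutate_cds <- function(cds, k) {
  repeat {
    out <- mutate_k(cds, k)
    cods <- substring(out, seq(1, nchar(out), 3), seq(3, nchar(out), 3))
    if (!any(oracle_code[cods] == "*")) return(out)
  }
}

# ---- naive Hamming tag-count oracle ---------------------------------------
# all-pairs scan: every read against every window of every reference on
# both strands; minimal mismatch per feature, unique-best crediting.
# Window matrices are precomputed per read width, but each read is still
# compared against every window position (a genuine quadratic scan).
oracle_count_tags <- function(reads, refs, max_mismatch) {
  rc <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  feat_names <- refs$feature
  counts <- stats::setNames(rep(0L, length(feat_names)), feat_names)
  ambiguous <- 0L; unmatched <- 0L
  windows_for_width <- function(w) {
    win <- list(); feat <- integer(0)
    for (fi in seq_along(feat_names)) {
      for (s in c(refs$sequence[fi], rc(refs$sequence[fi]))) {
        if (w > nchar(s)) next
        sv <- strsplit(s, "")[[1]]
        for (start in 1:(nchar(s) - w + 1)) {
          win[[length(win) + 1L]] <- sv[start:(start + w - 1)]
          feat <- c(feat, fi)
        }
      }
    }
    if (length(win) == 0L) return(NULL)
    list(mat = do.call(rbind, win), feat = feat)
  }
  cache <- list()
  for (r in reads) {
    w <- nchar(r)
    key <- as.character(w)
    if (is.null(cache[[key]])) cache[[key]] <- list(windows_for_width(w))
    win <- cache[[key]][[1]]
    best_per_feat <- rep(max_mismatch + 1L, length(feat_names))
    if (!is.null(win)) {
      rv <- strsplit(r, "")[[1]]
      mm <- rowSums(win$mat != matrix(rv, nrow(win$mat), w, byrow = TRUE))
      for (fi in unique(win$feat)) {
        best_per_feat[fi] <- min(mm[win$feat == fi], max_mismatch + 1L)
      }
    }
    b <- min(best_per_feat)
    if (b > max_mismatch) {
      unmatched <- unmatched + 1L
    } else if (sum(best_per_feat == b) > 1L) {
      ambiguous <- ambiguous + 1L
    } else {
      counts[which.min(best_per_feat)] <- counts[which.min(best_per_feat)] + 1L
    }
  }
  list(counts = counts, ambiguous = ambiguous, unmatched = unmatched)
}

# ---- misc ------------------------------------------------------------------

# exact permutation probability of r^2 >= cutoff for a fixed pair of
# vectors, enumerating all pairings of y against x
perm_r2_prob <- function(x, y, cutoff) {
  perms <- all_perms(seq_along(y))
  hits <- vapply(perms, function(p) {
    r <- suppressWarnings(stats::cor(x, y[p]))
    !is.na(r) && r^2 >= cutoff
  }, logical(1))
  mean(hits)
}

all_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_perms(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
  }
  out
}

# coalescent simulation of the number of segregating sites for a sample
# of n lineages at per-site theta0 over L sites (infinite sites)
sim_segregating_sites <- function(n, theta_locus) {
  total_time <- 0
  for (k in n:2) {
    rate <- k * (k - 1) / 2
    total_time <- total_time + k * stats::rexp(1, rate)
  }
  stats::rpois(1, theta_locus * total_time / 2)
}

# random additive distance matrix from a random tree with positive
# branch lengths; returns the matrix and the generating tree
rand_additive_matrix <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, br = function(k) stats::runif(k, 0.05, 1))
  tr <- ape::unroot(tr)
  d <- ape::cophenetic.phylo(tr)
  ord <- sort(rownames(d))
  list(d = d[ord, ord], tree = tr)
}
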