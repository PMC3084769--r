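test_that("K2P distance matches closed forms and an established implementation", {
  expect_equal(k2p_distance("ACGT", "ACGT"), 0)
  # 10 transitions out of 100: d = -1/2 ln(0.8)
  s1 <- strrep("A", 100)
  s2 <- paste0(strrep("G", 10), strrep("A", 90))
  expect_equal(k2p_distance(s1, s2), -0.5 * log(0.8), tolerance = 1e-9)

  # cross-check against ape's K80 on random pairs
  withr::with_seed(90, {
    for (rep in 1:10) {
      a <- rand_seq(300)
      b <- mutate_k(a, sample(5:40, 1))
      bin <- ape::as.DNAbin(list(a = strsplit(tolower(a), "")[[1]],
                                 b = strsplit(tolower(b), "")[[1]]))
      expect_equal(k2p_distance(a, b),
                   as.numeric(ape::dist.dna(bin, model = "K80")),
                   tolerance = 1e-9)
    }
  })

  # saturation raises an explicit error
  expect_error(k2p_distance("AAAA", "GGGG"),
               class = "hervclone_saturation_error")

  # consistency: estimated distance approaches the truth for long
  # sequences, simulating under the exact K2P transition probabilities
  # at distance d0 (kappa = 2: alpha = 2 beta, d = (alpha + 2 beta) t)
  withr::with_seed(91, {
    L <- 1e5
    d0 <- 0.1
    bt <- d0 / 4; at <- d0 / 2
    P <- 1 / 4 + exp(-4 * bt) / 4 - exp(-2 * (at + bt)) / 2
    Q <- 1 / 2 - exp(-4 * bt) / 2
    base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    ts_map <- c(A = "G", G = "A", C = "T", T = "C")
    u <- stats::runif(L)
    out <- base
    ts_hit <- u < P
    tv_hit <- u >= P & u < P + Q
    out[ts_hit] <- ts_map[base[ts_hit]]
    tv_pick <- stats::runif(sum(tv_hit)) < 0.5
    tv_opts <- cbind(c(A = "C", C = "A", G = "C", T = "A")[base[tv_hit]],
                     c(A = "T", C = "G", G = "T", T = "G")[base[tv_hit]])
    out[tv_hit] <- ifelse(tv_pick, tv_opts[, 1], tv_opts[, 2])
    d_hat <- k2p_distance(paste(base, collapse = ""),
                          paste(out, collapse = ""))
  })
  expect_lt(abs(d_hat - d0) / d0, 0.05)
})

test_that("NJ recovers the worked additive example exactly", {
  # tree ((A:1,B:2):1,(C:3,D:4)): AB=3 AC=5 AD=6 BC=6 BD=7 CD=7
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(d)
  cp <- ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(cp, d, tolerance = 1e-12)
  # A+B vs C+D split present
  splits <- ape::prop.part(tr)
  expect_equal(sort(ape::cophenetic.phylo(tr)["A", ]),
               sort(d["A", ]), tolerance = 1e-12)
})

test_that("NJ reconstructs random additive matrices and outgroup rooting splits the pendant edge", {
  withr::with_seed(92, {
    for (rep in 1:40) {
      n <- sample(6:10, 1)
      ref <- rand_additive_matrix(n)
      tr <- nj_tree(ref$d)
      cp <- ape::cophenetic.phylo(tr)
      cp <- cp[rownames(ref$d), colnames(ref$d)]
      expect_lt(max(abs(cp - ref$d)), 1e-9)
      expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ref$tree)),
                   structure(0, names = "PH85"), ignore_attr = TRUE)

      # outgroup rooting: root children are the outgroup and the rest,
      # each carrying half the original pendant edge
      og <- rownames(ref$d)[1]
      pend <- tr$edge.length[tr$edge[, 2] == which(tr$tip.label == og)]
      rooted <- nj_tree(ref$d, outgroup = og)
      expect_true(ape::is.rooted(rooted))
      root_node <- ape::Ntip(rooted) + 1L
      kids <- which(rooted$edge[, 1] == root_node)
      expect_equal(sort(rooted$edge.length[kids]), rep(pend / 2, 2),
                   tolerance = 1e-12)
      og_tip <- which(rooted$tip.label == og)
      expect_true(og_tip %in% rooted$edge[kids, 2])
      # rooting preserves all pairwise path lengths
      cpr <- ape::cophenetic.phylo(rooted)[rownames(ref$d), colnames(ref$d)]
      expect_lt(max(abs(cpr - ref$d)), 1e-9)
    }
  })
})

test_that("nj_tree validates its inputs", {
  d <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_tree(d), class = "hervclone_validation_error")
  d3 <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(d3, outgroup = "zz"), class = "hervclone_config_error")
  asym <- d3; asym[1, 2] <- 5
  expect_error(nj_tree(asym), class = "hervclone_validation_error")
})

test_that("Newick IO round-trips topology and branch lengths", {
  ref <- withr::with_seed(93, rand_additive_matrix(8))
  tr <- nj_tree(ref$d, outgroup = rownames(ref$d)[2])
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  rt <- read_newick(f)
  expect_identical(sort(rt$tip.label), sort(tr$tip.label))
  cp1 <- ape::cophenetic.phylo(tr)
  cp2 <- ape::cophenetic.phylo(rt)[rownames(cp1), colnames(cp1)]
  expect_lt(max(abs(cp1 - cp2)), 1e-8)
})

test_that("three-taxon NJ solves the closed-form pendant system", {
  d <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.6,
                0.5, 0.6, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- nj_tree(d)
  # pendant lengths: a = (dxy + dxz - dyz)/2 etc.
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl["x"]), (0.3 + 0.5 - 0.6) / 2, tolerance = 1e-12)
  expect_equal(unname(bl["y"]), (0.3 + 0.6 - 0.5) / 2, tolerance = 1e-12)
  expect_equal(unname(bl["z"]), (0.5 + 0.6 - 0.3) / 2, tolerance = 1e-12)
})
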