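# shared fixture: a simulated panel reduced to its amplicon inserts
panel_inserts <- local({
  sim <- simulate_panel(sim_config(seed = 1, n_loci = 12,
                                   per_locus_divergence = 0.03))
  panel <- sim$panel
  panel$sequence <- vapply(seq_len(nrow(panel)), function(i) {
    amplicon_insert(in_silico_pcr(panel[i, ], primer_set())[1, ])
  }, character(1))
  panel
})

test_that("align_identity matches arithmetic on constructed inputs and the DP oracle", {
  s <- withr::with_seed(10, rand_seq(650))
  expect_equal(align_identity(s, s)$identity, 1)
  expect_equal(align_identity(s, s)$aligned_length, 650L)

  # exactly 20 substitutions: identity = 630/650
  q <- withr::with_seed(11, mutate_k(s, 20))
  hit <- align_identity(q, s)
  expect_equal(hit$identity, 630 / 650)
  expect_equal(hit$aligned_length, 650L)

  # internal deletion: gap columns count as mismatches
  del <- paste0(substr(s, 1, 300), substr(s, 304, 650))
  hit_del <- align_identity(del, s)
  expect_equal(hit_del$aligned_length, 650L)
  expect_equal(hit_del$identity, 647 / 650)

  # optimal score agrees with an independent quadratic-time DP oracle
  withr::with_seed(12, {
    for (rep in 1:8) {
      a <- rand_seq(120)
      b <- if (rep %% 2 == 0) mutate_k(a, sample(1:20, 1)) else rand_seq(110)
      expect_equal(align_identity(a, b)$score, overlap_align_score(a, b),
                   tolerance = 1e-9)
    }
  })

  # heavily ambiguous sequences are rejected
  expect_error(align_identity(paste0(strrep("N", 100), strrep("A", 100)), s),
               class = "hervclone_validation_error")
})

test_that("assign_locus applies the 97% / 580 bp rule literally", {
  th <- assignment_thresholds()
  insert <- panel_inserts$sequence[panel_inserts$locus_id == "14"]

  # a panel member's own insert assigns to itself at identity 1
  a <- assign_locus(insert, panel_inserts, th)
  expect_identical(a$call, "14")
  expect_equal(a$identity, 1)

  # identity just below the threshold: ND (96.92% < 97%)
  L <- nchar(insert)
  k_below <- ceiling((1 - 0.97) * L) + 1L
  withr::with_seed(20, below <- mutate_k(insert, k_below))
  a2 <- assign_locus(below, panel_inserts, th)
  expect_lt(a2$identity, 0.97)
  expect_identical(a2$call, "ND")

  # 99% identity but aligned length < 580: ND by the length rule
  short <- substr(insert, 1, 500)
  withr::with_seed(21, short <- mutate_k(short, 5))
  a3 <- assign_locus(short, panel_inserts, th)
  expect_lt(a3$aligned_length, 580L)
  expect_identical(a3$call, "ND")

  # "greater than 97%" is strict: identity exactly at threshold fails
  expect_identical(
    assign_locus(insert, panel_inserts,
                 assignment_thresholds(min_identity = 1))$call, "ND")

  expect_error(assign_locus(insert, panel_inserts[0, ], th),
               class = "hervclone_config_error")
})

test_that("identity can alternatively be taken over the full query length", {
  insert <- panel_inserts$sequence[panel_inserts$locus_id == "15"]
  # pad the clone with vector tail: alignment identity stays 1, but
  # query-length identity drops below threshold
  padded <- paste0(insert, strrep("G", 30))
  th_q <- assignment_thresholds(identity_over = "query")
  a_aln <- assign_locus(padded, panel_inserts)
  a_q <- assign_locus(padded, panel_inserts, th_q)
  expect_identical(a_aln$call, "15")
  expect_lt(a_q$identity, a_aln$identity)
})

test_that("simulated clones with 0.3% error are recovered against a >=3% divergent panel", {
  sim <- simulate_panel(sim_config(seed = 1, n_loci = 12,
                                   per_locus_divergence = 0.03))
  cfg <- sim_config(seed = 17, n_loci = 12, clone_error_rate = 0.003,
                    n_samples = 3)
  cl <- simulate_clones(sim$panel, cfg)
  amp <- prototype_amplicon(sim$panel)
  trimmed <- trim_clones(cl$clones, amp)
  asg <- assign_clones(trimmed, panel_inserts)
  joined <- merge(asg, cl$truth, by = "clone_id")
  called <- joined[!joined$call %in% c("ND", "AMBIGUOUS"), ]
  expect_gt(nrow(called) / nrow(joined), 0.95)
  expect_true(all(called$call == called$origin_locus))
})

test_that("assignment is invariant to panel row order", {
  insert <- panel_inserts$sequence[3]
  withr::with_seed(30, q <- mutate_k(insert, 4))
  a1 <- assign_locus(q, panel_inserts)
  perm <- withr::with_seed(31, sample(nrow(panel_inserts)))
  a2 <- assign_locus(q, panel_inserts[perm, ])
  expect_identical(a1$call, a2$call)
  expect_identical(a1$best_locus, a2$best_locus)
})

test_that("raising min_identity never increases the number of called clones", {
  withr::with_seed(40, {
    queries <- vapply(1:12, function(i) {
      mutate_k(panel_inserts$sequence[i], sample(0:30, 1))
    }, character(1))
  })
  clones <- tibble::tibble(clone_id = paste0("c", 1:12), sequence = queries)
  n_called <- vapply(c(0.90, 0.95, 0.97, 0.99), function(mi) {
    asg <- assign_clones(clones, panel_inserts,
                         assignment_thresholds(min_identity = mi))
    sum(!asg$call %in% c("ND", "AMBIGUOUS"))
  }, numeric(1))
  expect_true(all(diff(n_called) <= 0))
})

test_that("summarize_assignments fractions behave over called + ND", {
  asg <- tibble::tibble(
    sample_id = rep("s1", 10),
    clone_id = paste0("c", 1:10),
    call = rep("7q21.2", 10))
  s1 <- summarize_assignments(asg)
  expect_equal(s1$fraction, 1)

  asg2 <- tibble::tibble(
    sample_id = rep("s1", 10), clone_id = paste0("c", 1:10),
    call = c(rep("7q21.2", 5), rep("14", 5)))
  s2 <- summarize_assignments(asg2)
  expect_equal(sort(s2$fraction), c(0.5, 0.5))

  # AMBIGUOUS excluded from the denominator; fractions sum to 1
  asg3 <- tibble::tibble(
    sample_id = rep("s1", 10), clone_id = paste0("c", 1:10),
    call = c(rep("7q21.2", 4), rep("ND", 4), rep("AMBIGUOUS", 2)))
  s3 <- summarize_assignments(asg3)
  expect_equal(sum(s3$fraction, na.rm = TRUE), 1, tolerance = 1e-9)
  expect_true(is.na(s3$fraction[s3$call == "AMBIGUOUS"]))
})

test_that("mixture frequencies recover the weights within the multinomial 99% CI", {
  sim <- simulate_panel(sim_config(seed = 2, n_loci = 4))
  w <- c(0.4, 0.3, 0.2, 0.1)
  cfg <- sim_config(seed = 23, n_loci = 4, clone_error_rate = 0.002,
                    n_samples = 1, mixture_weights = w,
                    clones_per_sample = c(200L, 200L))
  cl <- simulate_clones(sim$panel, cfg)
  amp <- prototype_amplicon(sim$panel)
  inserts <- sim$panel
  inserts$sequence <- vapply(seq_len(4), function(i) {
    amplicon_insert(in_silico_pcr(sim$panel[i, ], primer_set())[1, ])
  }, character(1))
  asg <- assign_clones(trim_clones(cl$clones, amp), inserts)
  s <- summarize_assignments(asg)
  called <- s[!s$call %in% c("ND", "AMBIGUOUS"), ]
  # exact binomial 99% acceptance region per locus
  for (i in seq_along(w)) {
    cnt <- called$n[called$call == sim$panel$locus_id[i]]
    if (length(cnt) == 0) cnt <- 0L
    expect_gte(cnt, stats::qbinom(0.005, 200, w[i]))
    expect_lte(cnt, stats::qbinom(0.995, 200, w[i]))
  }
})

test_that("chi-square group comparison matches closed forms", {
  # identical distributions: statistic 0, p = 1
  asg <- tibble::tibble(
    sample_id = rep(c("a", "b"), each = 10),
    clone_id = paste0("c", 1:20),
    call = rep(c(rep("7q21.2", 5), rep("14", 5)), 2))
  res <- compare_group_diversity(asg, c(a = "g1", b = "g2"))
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)

  # [[10,0],[0,10]]: n(ad-bc)^2/((a+b)(c+d)(a+c)(b+d)) = 20
  asg2 <- tibble::tibble(
    sample_id = rep(c("a", "b"), each = 10),
    clone_id = paste0("c", 1:20),
    call = c(rep("7q21.2", 10), rep("14", 10)))
  res2 <- compare_group_diversity(asg2, c(a = "g1", b = "g2"))
  expect_equal(res2$statistic, 20)
  expect_equal(res2$df, 1L)
})

test_that("chi-square type-I error is near nominal under a shared multinomial", {
  withr::with_seed(99, {
    alpha <- 0.05
    n_rep <- 400
    rejects <- 0
    for (r in seq_len(n_rep)) {
      calls <- sample(c("7q21.2", "14", "15"), 90, replace = TRUE,
                      prob = c(0.5, 0.3, 0.2))
      asg <- tibble::tibble(sample_id = rep(c("a", "b", "c"), each = 30),
                            clone_id = paste0("c", 1:90), call = calls)
      p <- compare_group_diversity(asg, c(a = "g1", b = "g2", c = "g3"))$p.value
      if (p < alpha) rejects <- rejects + 1
    }
    se <- sqrt(alpha * (1 - alpha) / n_rep)
    expect_lt(abs(rejects / n_rep - alpha), 4 * se)
  })
})
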