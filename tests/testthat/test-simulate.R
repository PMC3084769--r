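test_that("panel simulation respects the zero-divergence and determinism contracts", {
  cfg0 <- sim_config(seed = 7, n_loci = 4, per_locus_divergence = 0)
  sim0 <- simulate_panel(cfg0)
  expect_true(all(sim0$panel$sequence == sim0$ancestor))
  expect_identical(sim0$panel$locus_id[sim0$panel$is_prototype], "7q21.2")

  sim_a <- simulate_panel(sim_config(seed = 7))
  sim_b <- simulate_panel(sim_config(seed = 7))
  expect_identical(sim_a$panel, sim_b$panel)
  expect_identical(sim_a$outgroup, sim_b$outgroup)
  # FASTA bytes identical too
  fa <- withr::local_tempfile(fileext = ".fa")
  fb <- withr::local_tempfile(fileext = ".fa")
  write_panel(sim_a$panel, fa)
  write_panel(sim_b$panel, fb)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
})

test_that("12-locus panel at 3% divergence keeps all pairwise identities in [0.90, 1]", {
  sim <- simulate_panel(sim_config(seed = 1, n_loci = 12,
                                   per_locus_divergence = 0.03))
  pairs <- combn(12, 2)
  idents <- vapply(seq_len(ncol(pairs)), function(k) {
    a <- strsplit(sim$panel$sequence[pairs[1, k]], "")[[1]]
    b <- strsplit(sim$panel$sequence[pairs[2, k]], "")[[1]]
    mean(a == b)
  }, numeric(1))
  expect_true(all(idents >= 0.90 & idents <= 1))
  # excess divergence is an explicit failure, not a silent emission
  expect_error(simulate_panel(sim_config(seed = 1, per_locus_divergence = 0.2,
                                         outgroup_divergence = 0.2)),
               class = "hervclone_sim_error")
})

test_that("panel primer sites survive mutation so PCR always succeeds", {
  sim <- simulate_panel(sim_config(seed = 42, per_locus_divergence = 0.05,
                                   min_pairwise_identity = 0.85))
  for (i in seq_len(nrow(sim$panel))) {
    amp <- in_silico_pcr(sim$panel[i, ], primer_set(), stage = "nested")
    expect_gte(nrow(amp), 1L)
    expect_equal(amp$length[1], 650L)
  }
})

test_that("clone simulation conserves truth and honours zero error / single-locus weights", {
  sim <- simulate_panel(sim_config(seed = 5, n_loci = 3))
  cfg <- sim_config(seed = 5, n_loci = 3, clone_error_rate = 0,
                    n_samples = 2, mixture_weights = c(1, 0, 0))
  cl <- simulate_clones(sim$panel, cfg)
  amp <- prototype_amplicon(sim$panel)
  expect_true(all(cl$clones$sequence == amp$sequence))
  expect_true(all(cl$truth$origin_locus == "7q21.2"))
  expect_identical(cl$clones$clone_id, cl$truth$clone_id)
  expect_true(all(cl$truth$n_errors == 0))
  # per-sample clone counts within the configured range and conserved
  tab <- table(cl$clones$sample_id)
  expect_true(all(tab >= 6 & tab <= 27))
  expect_identical(table(cl$truth$sample_id), tab)

  # 50/50 mixture over two loci: truth counts sum to the clone total
  cfg2 <- sim_config(seed = 3, n_loci = 3, n_samples = 1,
                     mixture_weights = c(0.5, 0.5, 0),
                     clones_per_sample = c(20L, 20L))
  cl2 <- simulate_clones(sim$panel, cfg2)
  expect_equal(sum(table(cl2$truth$origin_locus)), 20L)
  expect_true(all(cl2$truth$origin_locus %in% c("7q21.2", "14")))

  # wrong weight-vector length is a configuration error
  expect_error(
    simulate_clones(sim$panel, sim_config(seed = 1, n_loci = 3,
                                          mixture_weights = c(0.5, 0.5))),
    class = "hervclone_config_error")
})

test_that("clone error calibration matches the analytic expectation (plasmid control regime)", {
  # 0.02% artifactual diversity: error rate 2e-4, 14 clones per sample,
  # single template; realized per-base substitution rate converges to
  # the configured rate within 3 binomial standard errors
  sim <- simulate_panel(sim_config(seed = 2, n_loci = 2,
                                   per_locus_divergence = 0.01))
  rate <- 2e-4
  n_bases <- 0
  n_subs <- 0
  for (seed in 1:30) {
    cfg <- sim_config(seed = seed, n_loci = 2, clone_error_rate = rate,
                      n_samples = 1, mixture_weights = c(1, 0),
                      clones_per_sample = c(14L, 14L))
    cl <- simulate_clones(sim$panel, cfg)
    n_subs <- n_subs + sum(cl$truth$n_errors)
    n_bases <- n_bases + sum(nchar(cl$clones$sequence))
  }
  se <- sqrt(rate * (1 - rate) / n_bases)
  expect_lt(abs(n_subs / n_bases - rate), 3 * se)
})

test_that("tag-count simulation is deterministic, nonnegative-integer, and validated", {
  a <- simulate_tag_counts(sim_config(seed = 11))
  b <- simulate_tag_counts(sim_config(seed = 11))
  expect_identical(a$counts, b$counts)
  expect_true(all(a$counts$count >= 0))
  expect_type(a$counts$count, "integer")
  expect_setequal(unique(a$truth$class),
                  c("herv", "housekeeping", "tracking", "independent"))
  expect_error(simulate_tag_counts(sim_config(seed = 1, n_samples = 2)),
               class = "hervclone_config_error")
  expect_error(sim_config(seed = 1, nb_dispersion = 0),
               class = "hervclone_config_error")
})

test_that("read simulation produces reads traceable to their source feature", {
  refs <- simulate_tag_references(seed = 9, length = 120)
  rd <- simulate_reads(refs, n_reads = 200, seed = 9)
  expect_equal(nrow(rd$reads), 200L)
  expect_true(all(nchar(rd$reads$sequence) == 36L))
  # each error-free read occurs in its truth reference (either strand)
  for (i in sample(200, 20)) {
    ref <- refs$sequence[refs$feature == rd$truth$feature[i]]
    found <- grepl(rd$reads$sequence[i], ref, fixed = TRUE) ||
      grepl(revcomp(rd$reads$sequence[i]), ref, fixed = TRUE)
    expect_true(found)
  }
})
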