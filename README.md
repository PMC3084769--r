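# hervclone

Locus assignment, molecular diversity and tag profiling for HERV-W
*env* amplicon clones.

## The problem

The human genome contains envelope (*env*) sequences of the endogenous
retrovirus family HERV-W at many chromosomal loci, all more than 90%
identical to the prototype provirus ERVWE1 at 7q21.2 — the only copy
with a complete Syncytin-1 open reading frame. When *env* transcripts
are amplified from tissue (the ~650 bp SU-TM amplicon), cloned and
sequenced, each clone must be traced back to its chromosomal encoding
locus before anything can be said about which loci are
transcriptionally active, how diverse the transcripts are, or how
*env* abundance relates to host gene expression. `hervclone` is an R
package for that analysis chain, aimed at researchers studying
endogenous retrovirus expression in brain and placental tissue.

At its core are:

* **the locus match rule** — a clone is assigned to the panel locus of
  its best semi-global alignment iff identity > 97% over ≥ 580 aligned
  bp (ND otherwise; near-ties are AMBIGUOUS);
* **diversity statistics** — segregating sites *S*, the
  Watterson-normalised variant-site estimate
  θ̂ = S / (L · Σᵢ₌₁ⁿ⁻¹ 1/i), and percent divergence of clones from
  the ERVWE1 prototype;
* **LWL85 Ka/Ks** — nonsynonymous and synonymous substitutions per
  site by degeneracy-class counting with per-class K2P correction;
* **K2P + neighbor-joining trees** rooted to an outgroup (MSRV);
* **tag profiling** — mismatch-tolerant, strand-aware counting of
  short sequence tags against HERV and host gene references,
  GAPDH normalisation, and the ≥ 2-tags-per-sample filter;
* **co-expression selection** of host genes with Pearson r² ≥ 0.75
  against HERV-W *env*, plus Mann–Whitney and Spearman group
  statistics;
* **synthetic-data generators** with recorded ground truth (paralog
  panels, clone libraries, tag-count matrices), so the entire pipeline
  is testable without any external data.

## Worked example

Simulate a 12-locus paralog panel, draw three samples of clones from a
mixture concentrated on 7q21.2, and run the clone pipeline:

```r
library(hervclone)

cfg <- sim_config(seed = 42, n_loci = 12, n_samples = 3,
                  mixture_weights = c(0.5, 0.2, 0.2, 0.1, rep(0, 8)))
sim <- simulate_panel(cfg)
cl  <- simulate_clones(sim$panel, cfg)
run <- run_clone_pipeline(sim$panel, cl$clones, "clone_run",
                          outgroup = sim$outgroup)
run$locus_frequencies
#> # A tibble: 11 × 4
#>    sample_id call       n fraction
#>    <chr>     <chr>  <int>    <dbl>
#>  1 S01       7q21.2     8   0.471
#>  2 S01       14         5   0.294
#>  3 S01       15         2   0.118
#>  4 S01       X          2   0.118
#>  5 S02       7q21.2     8   0.727
#>  6 S02       15         2   0.182
#>  7 S02       X          1   0.0909
#>  8 S03       7q21.2     8   0.667
#>  9 S03       15         2   0.167
#> 10 S03       14         1   0.0833
#> 11 S03       X          1   0.0833
```

Every clone was called, and the per-sample clonal frequencies recover
the simulated mixture (7q21.2 dominant, minority contributions from
loci 14, 15 and X — the pattern expected of healthy, multi-locus
transcription). Per-sample diversity:

```r
run$diversity
#> # A tibble: 3 × 7
#>   sample_id     n     L     S  theta pct_div_vs_prototype pct_div_pooled
#>   <chr>     <int> <int> <int>  <dbl>                <dbl>          <dbl>
#> 1 S01          17   594   102 0.0508                 3.98           3.98
#> 2 S02          11   594    64 0.0368                 1.82           1.82
#> 3 S03          12   594    89 0.0496                 2.30           2.30
```

Mixed-locus samples show percent divergence from the prototype in the
single-digit percent range, driven by the inter-locus differences; a
sample drawing only 7q21.2 clones would sit near the clone error floor
(~0.3% here, 0.02% in a plasmid-control regime). The NJ tree of the
panel inserts, rooted on the simulated MSRV outgroup, is written to
`clone_run/panel_tree.nwk`; `plot_locus_frequencies(run$locus_frequencies)`
draws the clonal-frequency bars.

For expression work: `simulate_tag_counts()` (or `count_tags()` /
`tag_count_table()` on reads) feeds `run_tag_pipeline()`, which
filters (≥ 2 tags per sample), normalises to GAPDH, ranks the HERV
features (env first in expectation), and reports the genes with
r² ≥ 0.75 against HERV-W env — see `glance(run_tag$correlation)` and
`autoplot()` on the correlation report.

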