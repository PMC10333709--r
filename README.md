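# celldemux

Dual-modality donor demultiplexing and cluster abundance testing for pooled
single-cell runs.

## The problem

Nasal biopsies (or any scarce clinical samples) yield too few cells to run one
10x lane per donor, so samples are barcoded with hashtag oligos (HTOs, e.g.
anti-B2M antibody–oligo conjugates), pooled — here 15 donors per run — and
encapsulated together. Two questions then have to be answered computationally:

1. **Which donor does each cell come from?** Hashtag counts answer this, but
   hashtags can fail or be ambient; the cells' own SNP alleles give an
   independent answer. `celldemux` implements both and keeps only cells the
   two modalities agree on.
2. **Do immune-cell cluster frequencies change after allergen challenge?**
   Per-sample cluster counts are proportions of highly variable biopsy
   yields, overdispersed relative to a binomial, and repeatedly measured per
   volunteer — which calls for a binomial generalized linear mixed model with
   donor- and sample-level random effects.

## The methods

**Hashtag demultiplexing.** For each hashtag, the distribution of
`log10(count + 1)` over all cells of a run is bimodal: an ambient noise peak
and a signal peak from that hashtag's own donor. A two-component Gaussian
mixture is fitted by EM, and a cell is called positive for hashtag *h* when

```
pi_h N(x; mu_hi, sigma_hi) / [(1 - pi_h) N(x; mu_lo, sigma_lo)] >= 3
```

i.e. when the cell is at least three times more likely under the signal peak
than under the noise peak. Cells positive for exactly one hashtag are
assigned to that donor; cells with zero or two or more positives are excluded
(negatives / multiplets).

**Genotype demultiplexing.** At SNPs that are polymorphic in the pooled
pileup, each cell's reference/alternative transcript counts are scored
against every donor's genotype `g in {0, 1, 2}` with a three-state binomial
likelihood (`P(alt) = eps, 0.5, 1 - eps`). Per-sample genotypes are called
from cumulated counts of provisionally assigned cells, validated across runs
by all-pairs genotype concordance (same-donor pairs must separate completely
from different-donor pairs), pooled per donor, and finally each cell is
assigned to its maximum-likelihood donor subject to a log-likelihood margin.

**Consensus.** Only cells assigned to the same donor by both routes are kept;
the full hashtag-by-genotype cross-tabulation is reported.

**Abundance testing.** Per cluster and group, with sample *s* of volunteer
*v*:

```
count_s ~ Binomial(total_s, logit^-1(b0 + b1 * after_s + u_v + e_s))
u_v ~ N(0, sigma_u^2),  e_s ~ N(0, sigma_e^2)
```

`b1` is the challenge effect (log-odds); the sample-level `e_s` absorbs
overdispersion. The after−before contrast is taken via estimated marginal
means (equal to `b1` for this design), tested with a Wald z, and
Benjamini–Hochberg corrected across clusters at adjusted p < 0.1. Exact
Wilcoxon signed-rank and Mann–Whitney tests are included for the
nonparametric comparisons.

A synthetic-data generator (`sim_config()`, `simulate_experiment()`,
`simulate_cluster_counts()`) reproduces all of this structure with emitted
ground truth, so every stage is scored against known labels.

## Worked example

```r
library(celldemux)

cfg <- sim_config(n_runs = 1, donors_per_run = 15, cells_per_donor = 500,
                  doublet_rate = 0.05, seed = 1)
e   <- simulate_experiment(cfg)
r   <- e$runs$run1

ht  <- assign_by_hashtag(r$counts, fit_hashtag_mixtures(r$counts))
gt  <- assign_by_genotype(r$allele_counts, e$genotypes)
out <- consensus_assign(ht[, c("cell_id", "donor_call")],
                        gt[, c("cell_id", "donor_call")])
table(out$status)
#>    consistent genotype_only    unassigned
#>          7118           377             5
```

7,118 of 7,500 cells are consistently assigned by both modalities (the
consensus set); 5 are called by neither, and 377 — essentially the simulated
doublets plus the hashtag negatives — are called only by the genotype route
and are excluded from the final set. Scoring against the generator's truth:

```r
scored <- dplyr::inner_join(out, r$truth, by = "cell_id")
mean(scored$final_donor[scored$status == "consistent"] ==
     scored$donor[scored$status == "consistent"])
#> [1] 1
```

Abundance testing on a simulated before/after design:

```r
design <- tidyr::expand_grid(donor_id = sprintf("d%02d", 1:10),
                             timepoint = c("before", "after")) |>
  dplyr::mutate(group = "allergic")
params <- tibble::tibble(cluster_id = c("cDC2", "MDSC"),
                         beta0 = c(-2, -3), beta1 = c(0.8, 0),
                         sigma_u = 0.5, sigma_e = 0.3)
sim <- simulate_cluster_counts(design, params, total_sampler = 2000, seed = 2)
test_cluster_abundance(sim$table)
#> # A tibble: 2 × 13
#>   group    cluster_id beta0  beta1    se     z sigma_u sigma_e    p_raw
#>   <chr>    <chr>      <dbl>  <dbl> <dbl> <dbl>   <dbl>   <dbl>    <dbl>
#> 1 allergic MDSC       -2.71 -0.122 0.139 -0.88   0.351   0.294 3.79e- 1
#> 2 allergic cDC2       -2.03  0.709 0.112  6.31   0.637   0.242 2.83e-10
#> # plus: converged, boundary, p_adj, significant
```

The cluster simulated with a challenge effect of 0.8 log-odds is recovered
(estimate 0.71 ± 0.11, BH-significant at adjusted p = 5.7e-10); the null
cluster is not (adjusted p = 0.38).

## Command line

A thin CLI over the same functions ships in `inst/cli/celldemux.R`
(subcommands `simulate`, `qc`, `demux-hashtag`, `demux-genotype`,
`consensus`, `abundance`, `run`).

## Scope

The package starts from count tables (hashtag counts, per-cell allele counts,
per-sample cluster counts): alignment, pileup extraction, expression
normalization, clustering and annotation are upstream and out of scope, as
are gene-expression simulation and probabilistic fusion of the two
demultiplexing modalities. See `vignettes/methods.Rmd` for the model
details, parameter choices, and limitations.
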