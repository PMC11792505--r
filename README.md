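# assemproc

Attribution of microbial community assembly processes to taxa and sampling
units.

## What it does, and for whom

Microbial community ecologists routinely ask whether turnover between
communities is driven by deterministic selection or by stochastic
processes. The established two-step null-model framework answers this per
*pair of communities*: the standardized effect size of the
abundance-weighted beta mean nearest taxon distance,

    βMNTD(k,m) = ½ [ Σ_i f_ik · min_{j∈m} d_ij  +  Σ_i f_im · min_{j∈k} d_ij ]
    SES = (βMNTD_obs − mean(null)) / sd(null),   null = tip-label shuffling

classifies SES > 2 as heterogeneous (variable) selection and SES < −2 as
homogeneous selection; the remaining pairs are classified by the Raup–Crick
metric on Bray–Curtis dissimilarity under a fixed-richness,
occupancy/abundance-proportional null (RC > 0.95 dispersal limitation,
RC < −0.95 homogenizing dispersal, otherwise drift).

`assemproc` implements that framework and extends it with two attribution
analyses:

* **DTU attribution** (`attribute_taxa()`): each taxon or taxonomic group
  is removed from the community, both metrics are recomputed *under the
  identical randomizations*, and five decision rules attribute each pair's
  process to the target; the output is, per target, the fraction of pairs
  attributed to each of the five processes.
* **DSU attribution** (`attribute_sites()`, `group_summary()`): each
  sampling unit's (or group's) contribution is the process profile over
  the classified pairs that involve it — with 4 sites A–D there are 6
  pairs, and the group {A, B} is involved in 5 of them (AB, AC, AD, BC,
  BD).

A Mantel-correlogram gate (`phylo_signal()`) checks for phylogenetic signal
in niche differences before βMNTD is interpreted, and a simulator
(`simulate_assembly()`) generates communities under known assembly regimes
for validation. Inputs are a TSV abundance table (taxa-by-samples by
default), a newick phylogeny covering the table's taxa, and optional
taxonomy and sample-metadata TSVs.

## Worked example

```r
library(assemproc)

sim   <- simulate_assembly("heterogeneous_selection", seed = 101,
                           divergent_taxon = TRUE)
cfg   <- null_config(seed = 202, n_reps = 500)
pairs <- classify_communities(sim$community, sim$tree, cfg)
print(pairs)
#> Pairwise assembly classification: 66 site pairs, 80 taxa
#>   heterogeneous_selection  42
#>   homogeneous_selection    0
#>   dispersal_limitation     4
#>   homogenizing_dispersal   2
#>   drift                    18
```

42 of 66 site pairs are classified as heterogeneous selection — the regime
the simulator implanted (sites filter taxa through narrow niches along a
wide environmental gradient). Removal attribution over all 80 taxa ranks
the implanted divergent-trait taxon first:

```r
att <- attribute_taxa(sim$community, sim$tree,
                      taxon_targets(sim$community), cfg, pairs = pairs)
a <- att$attribution
head(a[order(-a$heterogeneous_selection),
       c("target_id", "n_evaluable", "heterogeneous_selection", "drift")])
#>  target_id n_evaluable heterogeneous_selection     drift
#>        T54          66              0.12121212 0.8636364
#>        T29          66              0.04545455 0.9545455
#>         T1          66              0.03030303 0.9696970
#>        T17          66              0.03030303 0.9696970
#>        T18          66              0.03030303 0.9696970
#>        T19          66              0.03030303 0.9696970
sim$divergent_taxon
#> [1] "T54"
```

T54's row reads: removing T54 flips the heterogeneous-selection verdict for
12% of the pairs (no other taxon flips more than 4.5%), while for 86% of
pairs no rule fires (drift attribution). Sampling-unit attribution along
the gradient bands:

```r
group_summary(pairs, sim$metadata, "band")[
  , c("target_id", "n_involved", "significant_fraction", "stochasticity")]
#>  target_id n_involved significant_fraction stochasticity
#>       high         38            0.7368421     0.3684211
#>        low         38            0.7631579     0.2631579
#>     medium         38            0.7894737     0.3421053
```

Each band of 4 sites is involved in 38 of the 66 pairs; roughly three
quarters of them show a significant SES or RC result, and the stochasticity
column is the fraction attributed to dispersal limitation, homogenizing
dispersal or drift.

Result tables are written as plain TSV (deterministic column order:
`pair_id, site_a, site_b, beta_mntd, null_mean, null_sd, ses, rc, process,
status` for pair metrics; `target_id, n_taxa/n_sites, n_evaluable`, the
five process fractions, and diagnostics for attribution tables) with the
seed recorded in a `#` header. A command-line front end wrapping the same
functions ships in `inst/scripts/assemproc.R` with subcommands `simulate`,
`signal`, `classify`, `attribute-taxa`, `attribute-sites`, `run-full`.

## Further reading

The methods vignette (`vignettes/assembly-attribution.Rmd`) documents the
model, the null models and their shared randomization streams, the five
decision rules and their labeling conventions, degenerate and boundary
cases, the simulator's regimes, and known limitations.
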