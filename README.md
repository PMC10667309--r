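# phagehic

Inference of phage-host infections from proximity-ligation (Hi-C)
metagenome link tables, for soil (and other) microbiome studies that pair
shotgun metagenomes, metatranscriptomes and Hi-C libraries across replicated
conditions.

Hi-C read pairs that join a viral contig to a MAG are physical evidence that
the phage was inside that host cell at sampling time — but raw link tables
are dominated by spurious contacts. `phagehic` implements the quantitative
model that extracts infections from them:

* **Viral copies per host (VPH)** for a candidate pair with link count `L`,
  phage link total `ΣL(v)`, and normalized abundances `V` (phage), `H`
  (host):

  `VPH = (V / H) × (L / ΣL(v))`

* **Connectivity ratio** comparing the pair's link density
  `D_VH = L / (kb_v · kb_h)` with the host's internal density
  `D_H = intra / kb_h²`:

  `R' = (D_VH / D_H) × (H ΣL(v)) / (V L)`, with the identity
  `R' × VPH = D_VH / D_H`.

* A **two-round filter**: round 1 keeps pairs with `L ≥ 2`, `R' ≥ 0.1` and
  intra-MAG connectivity ≥ 10; round 2 picks, per Hi-C library, the score
  threshold maximizing (phages retaining ≥ 1 host) + (fraction of links
  removed); then a within-phage 80%-of-maximum count rule, a promiscuity
  flag, and collapse to replicate-supported (vOTU × dereplicated host
  population) pairs.

Around the core sit the supporting analyses: multi-tool viral contig voting,
greedy-centroid vOTU clustering (95% ANI / 85% AF) and MAG dereplication
(99%), CRISPR spacer matching (≤ 1 mismatch and ≥ 95% identity, best hit
per spacer), coverage-based presence (breadth > 50%) and activity calls,
infection networks, three co-occurrence network methods (Pearson, CLR,
random-forest importance) with betweenness/degree centrality, and the
pre/post statistical layer (Welch t-tests, log-log VPH-abundance
regression). A fully specified synthetic soil-community simulator with
recorded ground truth makes the whole pipeline testable without external
data; see `vignette("phage-host-inference")` for the model and every
documented design choice.

## Worked example

```r
library(phagehic)

sim <- simulate_community(sim_config(seed = 1))   # 100 MAGs, 150 phages, 3+3 libraries
report <- run_pipeline(sim, seed = 1)
report
#> <hic_report>
#>   14234 candidate links -> 324 survivors -> 175 infection pairs (79 supported)
#>   vs ground truth: precision 0.975, recall 0.786, Spearman(vph) 0.892
```

14,234 phage-MAG link rows survive to candidacy; filtering leaves 324
contig-level links, which collapse to 175 infection pairs, 79 of them seen
in at least two replicate libraries. Because the simulator records its
ground truth, the report can score itself:

```r
report$evaluation
#> # A tibble: 3 × 7
#>   condition n_detected n_truth    tp precision recall spearman_vph
#>   <chr>          <int>   <int> <int>     <dbl>  <dbl>        <dbl>
#> 1 pre               44      52    43     0.977  0.827        0.782
#> 2 post              35      46    34     0.971  0.739        0.879
#> 3 overall           79      98    77     0.975  0.786        0.892
```

97.5% of reported pairs are true infections, 78.6% of true infections are
recovered, and the estimated VPH tracks the generative VPH (Spearman 0.89).
The per-host VPH comparison shows the planted post-drying lysogeny shift:

```r
tidy(report$vph_comparison)[, c("metric", "mean_pre", "mean_post", "t", "p")]
#> # A tibble: 1 × 5
#>   metric                   mean_pre mean_post     t        p
#>   <chr>                       <dbl>     <dbl> <dbl>    <dbl>
#> 1 total_vph_per_population     2.38      5.17  4.00 0.000367
```

Mean per-population VPH rises from 2.4 to 5.2 after drying (Welch two-sided
p = 4e-4) — the simulator plants a 1.6× VPH multiplier post-drying, and the
detected shift is larger because post-condition detection favours heavier
infections. `autoplot(report$infection_network)`,
`plot_vph_comparison(report$vph_table)` and
`autoplot(report$regressions$pre)` draw the corresponding figures; every
table in the bundle can be written as TSV with
`write_report(report, "outdir")`.

Real data enter through the same tabular contracts:
`aggregate_read_pairs()` for mapped Hi-C read pairs,
`read_sim_dataset()`-shaped TSV directories for link/coverage/transcript
tables, and cluster tables from `greedy_centroid_cluster()`.

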