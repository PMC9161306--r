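# concordr

Co-expression analysis across a small number of experimental conditions is
brittle: with only four condition means per molecule, rank correlations are
dominated by within-condition noise, and Euclidean distances on z-scores
cannot tell a flat profile from a structured one. `concordr` implements a
pattern-based alternative for integrating **metabolite concentrations** with
**phosphopeptide LFQ intensities** measured across four tissue-by-time
conditions — end-of-day root (DR), end-of-day shoot (DS), end-of-night root
(NR), end-of-night shoot (NS) — in several plant genotypes. It is aimed at
proteomics/metabolomics groups who have replicate-level log2 tables after
quantification and imputation and want calibrated, pattern-level
metabolite–phosphopeptide networks.

## The concordance index

For each molecule, every ordered condition pair (j | i) yields a *condition
deviation*

    d_k = (x̄_j − x̄_i) / sd(x)_i ,   k = 1, …, 12

the difference of condition means in multiples of the reference condition's
sample standard deviation. For a metabolite M and phosphopeptide P the
*combined condition deviation* keeps the weaker of the two signals and their
sign agreement:

    z_k(M, P) = sign(d_k(M)) · sign(d_k(P)) · min(|d_k(M)|, |d_k(P)|)

Each z_k is discretized into a component z̃_k by magnitude class —
|z| ∈ [1,2) → 0.25, [2,3) → 1, [3,5) → 1.5, [5,10) → 1.75, ≥ 10 → 2, with
the sign of z_k — and the components are summed separately into
I_C(−) ≤ 0 and I_C(+) ≥ 0, giving the **concordance index**

    I_C = I_C(−) + I_C(+)  ∈  [−24, 24]  (quarter-integer valued).

Large positive I_C means concordant patterns, large negative I_C discordant
ones. Pairs are co-filtered by a Spearman rank correlation on
replicate-paired values (α = 0.05) and by a Kruskal–Wallis "flatness" test on
each partner; false-positive rates are calibrated against null datasets in
which condition means are redrawn from per-molecule three-parameter Gamma
fits and replicates from normal distributions. Connections with I_C at or
above threshold (screening 6, networks 7) are aggregated into bipartite
metabolite ↔ functional-bin networks with mean-I_C edge weights.

The package also provides MAD-based outlier masking, k-means/hierarchical
pattern clustering with a between-genotype distance d_GT, Fisher
over-representation profiles along ranked lists (weighted scores x_k,
scaled ranks ρ_SC), and a synthetic-data generator with planted pattern
archetypes and known pair-level ground truth.

## Worked example

```r
library(concordr)

ds        <- generate_dataset(n_metabolites = 8, n_phospho = 60,
                              genotypes = 1, effect_size = 2,
                              noise_sd = 0.5, seed = 42)
data      <- mask_outliers(ds$data)              # modified z-score, MAD
summaries <- summarize_conditions(data)          # means, sd, KW flatness
pairs     <- concordance_table(data, summaries, genotype = "gt1")
dplyr::arrange(pairs, dplyr::desc(ic))[1:3, c(1:2, 4:9)]
#>   metabolite_id phosphopeptide_id ic_neg ic_pos    ic   rho     rho_p
#> 1 met_005       pep_0042               0   15.5  15.5 0.790 0.0000208
#> 2 met_001       pep_0036               0   15    15   0.670 0.00169
#> 3 met_001       pep_0057               0   15    15   0.8   0.0000392

conn <- filter_connections(pairs, ic_min = 7)    # + Spearman + non-flat
nrow(conn)
#> [1] 45

rec <- evaluate_recovery(filter_connections(pairs, ic_min = 6), ds$truth)
sprintf("recall %.2f precision %.2f", rec$recall, rec$precision)
#> [1] "recall 1.00 precision 0.98"
```

The top pairs share a planted archetype: eight of their twelve combined
deviations fall in the strongest classes (components 1.75–2, summing to
I_C ≈ 15), the Spearman co-filter confirms the rank agreement, and at the
screening threshold every planted concordant pair is recovered with 98%
precision. From `conn`, `aggregate_bins()` + `build_network()` produce the
GraphML network; `run_pipeline()` chains all stages and writes every table
plus a JSON manifest.

A thin command-line front end over the same functions lives at
`inst/cli/concordr.R`:

```sh
Rscript inst/cli/concordr.R simulate --seed 1 --out data/
Rscript inst/cli/concordr.R run --measurements data/measurements.tsv --out results/
```

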