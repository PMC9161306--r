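Package: concordr
Title: Concordance-Index Networks Linking Metabolites and Phosphopeptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects concordant and discordant abundance patterns between
    metabolites and phosphopeptides measured across four tissue-by-time
    conditions in multiple genotypes. Implements the concordance index I_C, a
    quarter-integer pattern-similarity score built from discretized pairwise
    condition deviations, together with a Spearman rank-correlation co-filter,
    MAD-based outlier removal, Kruskal-Wallis flatness classification,
    Gamma/normal null simulation for false-positive calibration, Fisher
    over-representation profiles with weighted scores and scaled ranks,
    k-means and hierarchical pattern clustering with a between-genotype
    distance, and bipartite metabolite-to-functional-bin network construction
    with mean-I_C edge weights. Includes a synthetic-data generator with
    planted pattern archetypes and known pair-level ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
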