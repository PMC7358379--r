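# tmtbridge

Quantitative analysis of multi-plex, isobaric-label (TMT) proteome
experiments that are bridged by pooled internal-reference channels, aimed at
treatment-versus-control screens with few biological replicates — the
motivating case being a human cardiomyocyte (AC16) screen of five
mitochondrial toxicants (FCCP, dinoterb, picoxystrobin, pinacyanol,
triclocarban) against a DMSO control, 18 samples split over two 11-plexes.

It is written for proteomics analysts who receive protein-level reporter-ion
intensity exports (Proteome-Discoverer-style TSVs) and need a tested,
scriptable route from those tables to differential proteins and dysregulated
pathways.

## What it computes

**Quantification.** Per protein and plex, relative abundance is the ratio of
a sample's summed reporter intensity to the pooled-reference abundance
(arithmetic mean of the plex's pooled channels):
`r = y_sample / mean(y_pooled)`. Plex-wide batch factors cancel in `r`, so
plexes merge on their commonly detected proteins. Pooled-channel CVs
(sd/mean, %) monitor reproducibility.

**Differential expression.** Per protein and treatment: ratio of group means
against the control, two-sided pooled-variance Student t-test, and post-hoc
power at the observed Cohen's d via the noncentral t distribution,
`power = P(|T(df, d·sqrt(n1·n2/(n1+n2)))| > t_crit)`. Three gates — power >
0.8, p < 0.05, and a fold-change filter (ratio > 1.15 or < 0.85; an
asymmetric < 0.8 mode is available) — are combined per analysis stage.

**Pathways.** The treatment-specific dysregulation statistic compares, per
pathway, `percent_change(t) = 100·n_changed(t)/n_detected` against
`percent_coverage = 100·n_detected/n_annotated`, flagging treatment `t` when
change meets or exceeds coverage; plus right-tailed Fisher (hypergeometric)
enrichment with a selectable background (full annotation universe vs the
detected-protein "user dataset"), and a functional-class breakdown of
changed mitochondrial proteins.

**Synthetic data.** A ground-truthed generator (`simulate_fixture()`)
reproduces the two-plex, six-group design with log-normal channel noise,
plex batch factors, dropout and planted pathway signals, so the whole
pipeline is testable without any download.

## Worked example

```r
library(tmtbridge)

fx <- simulate_fixture("paper", seed = 2026, out_dir = "demo")
cfg <- run_config(design = "demo/design.tsv",
                  tables = c("demo/intensities_set1.tsv",
                             "demo/intensities_set2.tsv"),
                  gmt = "demo/pathways.gmt",
                  localization = "demo/localization.tsv",
                  classes = "demo/classes.tsv",
                  out_dir = "demo_out", control = "DMSO")
s <- run_pipeline(cfg)

s$counts
#> $n_total_detected            [1] 4996
#> $n_overlap                   [1] 4706
#> $n_mitochondrial_detected    [1] 556
#> $n_changed_union             [1] 1921
#> $n_mitochondrial_changed     [1] 236
#> $n_non_mitochondrial_changed [1] 1685

round(unlist(s$changed_fraction_power), 3)
#>      dinoterb          FCCP picoxystrobin    pinacyanol  triclocarban
#>         0.173         0.171         0.171         0.113         0.120

round(unlist(s$cv[c("median_cv_percent", "frac_cv_lt5")]), 4)
#> median_cv_percent       frac_cv_lt5
#>            1.3683            1.0000

length(s$flagged_pathways)
#> [1] 5
s$top_enrichment$user_dataset$FCCP[[1]]
#> pathway_001, p = 6.88e-14 (k = 23 of K = 28)
```

Reading the output: of 4,996 simulated proteins, 4,706 are quantified in
every sample of both plexes and form the analysis universe; pooled-channel
CVs (median 1.4%, all below 5%) confirm the two plexes bridged cleanly. The
power gate flags 11–17% of proteins per treatment (the generator perturbs
10%; treatments measured in the opposite plex from the control carry extra
reference noise and sit higher — see the methods vignette). The
coverage-vs-change statistic flags 5 (pathway, treatment) pairs — exactly
the five planted pathways — and each planted pathway is also its
treatment's top Fisher-enrichment hit, here `pathway_001` for FCCP with 23
of its 28 detected members changed.

Every stage also lands as a TSV (`merged.tsv`, `cv_report.tsv`,
`differential.tsv`, `correlations.tsv`, `pathway_dysregulation.tsv`,
`enrichment.tsv`, `functional_classes.tsv`) plus `summary.json` and a
`run.log` recording the thresholds and tie rule used.

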