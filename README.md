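# enhancerlink

Identify the **active enhancer network** of a ligand-activated
transcription factor by integrating strand-specific nascent-transcription
coverage (GRO-seq-style), ChIP peak sets, gene models and
chromosome-conformation read pairs.

A nuclear receptor may occupy thousands of genomic sites while its ligand
changes the transcription of only a few hundred genes. `enhancerlink` is
for genomics analysts who need to separate the functional enhancers from
silent binding sites and link them to their target genes when proximity
alone cannot: it filters bound sites by divergent eRNA production, calls
ligand-induced changes in nascent transcription, assigns changing
enhancers to the closest changing gene, places the resulting regulatory
units into CTCF/cohesin-delimited functional domains, and compares 3C
interaction frequencies across genome compartments. A synthetic-genome
generator with planted ground truth makes the entire pipeline testable
offline.

## The core statistics

* **Divergent site**: a minus-strand/plus-strand transcript-unit pair with
  5' ends in outward orientation, 5'-distance < 300 bp, and expression of
  the better partner > 0.2 RPKM, where
  RPKM = C / ((L/10³)(N/10⁶)) for summed coverage C, length L, library N.
  Units are maximal nonzero-coverage runs (gaps ≤ 50 bp bridged, ≥ 0.006
  RPKM genome-wide floor).
* **Change call**: two-sided binomial test of the ligand count against the
  two-library total with success probability N_ligand/(N_vehicle+N_ligand),
  BH-adjusted; changing means q < 0.1 and fold change strictly > 2
  (median-of-ratios effective library sizes by default).
* **Enhancer vs silencer**: a GRO-positive, changing bound region assigned
  to the closest changing gene; sign-concordant = enhancer, discordant =
  silencer.
* **Boundary / domain**: overlapping CTCF/RAD21 peaks with both scores > 15
  and ratio < 3; nearest similar-score boundaries pair into domains;
  domains separated by < 100 kb merge into active domains.
* **Interaction frequency**: reads per fixed bin normalized to 1000 total;
  Welch two-tailed t-tests between inactive / active / target bins.

## Worked example

```r
library(enhancerlink)
demo <- run_demo(seed = 1)   # simulate the 10-Mb reference genome + run everything
demo$network
#> <enhancer_network>
#>   peaks: 300 ( 180 GRO+, 120 GRO- )
#>   divergent sites: 300 | changing: 42
#>   assigned regions: 24 = 22 enhancers + 2 silencers -> 15 genes
#>   domains: 24 (median 225 kb ) merged: 12
#>   transcribed fraction: 0.200 | active-enhancer fraction: 0.073
```

Reading the output: of 300 binding sites, 180 overlap divergent
eRNA-producing sites (GRO-positive) and 120 are silent. 42 divergent sites
change upon ligand; 24 bound regions both change and can be assigned to a
changing gene — 22 concordant enhancers and 2 discordant silencers for 15
regulated genes, i.e. an active-enhancer fraction of 7.3% of all binding
sites. The planted 20% transcribed genome is recovered exactly, as are the
24 planted CTCF/RAD21 domains (median 225 kb, merging to 12 active
domains).

```r
print(demo$network$contacts$comparison)
#>  bin_class  n     mean       sd
#>   inactive  4  6.25000 1.031899
#>     active 14 12.04762 2.864033
#>     target  7 19.95238 3.346798
#>    group1 group2          t        df      p_value
#>  inactive active  -6.280611 14.513671 1.713351e-05
#>    active target  -5.346358 10.545747 2.714870e-04
#>  inactive target -10.029954  7.734285 1.055249e-05
```

The bait enhancer contacts active domains about twice as often as inactive
genome, and regions containing other regulated genes/enhancers three times
as often — the planted interaction enrichment, recovered with
interchromosomal Welch tests.

Broom-style accessors (`tidy()` for the assignment table, `glance()` for
the one-row summary) and ggplot helpers (`plot_summit_profile()`,
`plot_tss_distances()`, `plot_enhancers_per_gene()`,
`plot_contact_classes()`) cover the result types. See the vignette
(`vignettes/enhancer-network-analysis.Rmd`) for the model, parameter and
design discussion.

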