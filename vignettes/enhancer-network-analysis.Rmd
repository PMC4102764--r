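---
title: "Identifying a ligand-activated enhancer network from nascent transcription and chromatin architecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying a ligand-activated enhancer network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhancerlink)
library(dplyr)
```

## The problem

A signal-dependent transcription factor such as a ligand-activated nuclear
receptor typically occupies thousands of genomic sites in a differentiated
cell, yet ligand treatment changes the transcription of only a few hundred
genes. Chromatin immunoprecipitation alone therefore cannot say which bound
sites are *functional* enhancers and which are silent ("parking") sites, and
because enhancers act over tens to hundreds of kilobases, naive
nearest-gene assignment of all peaks is mostly wrong — the large majority of
binding sites sit nowhere near a regulated promoter.

`enhancerlink` implements an integrative strategy that resolves both
problems with nascent-transcription (GRO-seq-style) data:

1. Active regulatory elements — promoters and enhancers alike — produce
   short **divergent transcripts**: two opposite-strand RNAs whose 5' ends
   lie close together and point away from each other. Detecting these
   divergent initiation sites from strand-specific coverage identifies the
   transcriptionally engaged fraction of the genome.
2. A binding site overlapping a divergent site is *active*
   (**GRO-positive**); one overlapping no nascent transcription is *silent*
   (**GRO-negative**).
3. Ligand-induced changes in eRNA output at a bound site, matched in sign
   with a change in a gene's nascent transcription, link the enhancer to
   its target: the **closest gene with changing expression**.
4. CTCF/cohesin co-bound positions delimit **functional domains** within
   which enhancer–promoter communication is expected to be confined, and
   chromosome-conformation (3C-seq-style) read counts quantify how often a
   bait enhancer touches other genomic regions.

Every stage is exercised end-to-end on a synthetic genome with planted
ground truth, so the whole pipeline is testable without any external
sequencing data.

## Models, parameters and their defaults

### Transcript units and the transcribed fraction

Stranded per-base coverage is segmented per strand into maximal runs of
nonzero signal; runs separated by at most `tx_max_gap_bp` (default 50 bp)
of zero coverage are bridged, and units shorter than `tx_min_length_bp`
(100 bp) or below `tx_min_rpkm` are discarded. Expression is measured in
RPKM,

$$\mathrm{RPKM} = \frac{C}{(L/10^3)\,(N/10^6)},$$

with \(C\) the summed per-base coverage in the unit, \(L\) its length and
\(N\) the library size. The genome-wide expression floor used for the
transcribed-fraction statistic is **0.006 RPKM**; the transcribed fraction
is the length of the across-strand union of all units divided by the genome
length. The run-bridging segmentation is the package's own choice of a
simple, fully specified algorithm; the gap parameter is exposed because no
single value suits every read depth.

### Divergent initiation sites

A site pairs a minus-strand unit (5' end \(m\), transcribing leftward) with
a plus-strand unit (5' end \(p\), transcribing rightward) such that
\(p \ge m\) (outward orientation; convergent overlap is elongation, not
initiation) and \(p - m < 300\) bp (strict). The better-expressed partner
must exceed **0.2 RPKM** (strictly); a `strict_both` switch demands both
partners pass, since it is ambiguous whether one or both transcripts must
clear the floor. Pairing is a greedy matching by smallest 5'-gap with
leftmost tie-break: each unit joins at most one site and the result is
independent of input order.

### Active versus silent binding sites

A peak is GRO-positive iff it overlaps a divergent site by at least one
base (half-open interval semantics; abutting intervals do not overlap). The
classification is an exhaustive, exclusive partition, asserted at run time.

### Ligand-induced changes

Change calling uses a per-region two-sided exact binomial test of the
ligand count against the vehicle + ligand total, with success probability
\(N_\ell/(N_v+N_\ell)\) — the conditional form of the two-library Poisson
comparison. P-values are Benjamini–Hochberg adjusted across all tested
regions, and a region is called changing when \(q < 0.1\) **and** the
normalized fold change strictly exceeds 2 ("more than twofold"). A
pseudocount of one read per condition enters the fold change only, never
the test; regions with zero total count get \(p = 1\) by convention.

Two normalization modes exist. `library_size` uses the raw totals. The
pipeline default, `median_ratio`, rescales the ligand library by the median
per-region cpm ratio before testing. The reason is composition bias: when a
substantial mass of the transcriptome is strongly induced, the ligand
library is systematically deeper, which compresses cpm fold changes of the
truly changed regions toward 1. Anchoring the scale on the unchanged
majority (the median-of-ratios idea familiar from count-based differential
expression) restores the fold scale as long as fewer than half of the
regions change — the standard assumption of that estimator.

For divergent sites, differential counting uses the window from the start
of the minus-strand member unit to the end of the plus-strand member unit,
on both strands. The site interval itself spans only the two 5' ends and
contains almost no signal (the transcripts point outward), so the member
units, which carry the eRNA signal, are the meaningful quantification
window.

Time-course designs are supported by testing each timepoint against the
baseline; a region is changing if any timepoint passes, signed by its most
significant timepoint.

### Enhancer-to-gene annotation

Eligible regions are GRO-positive peaks whose divergent site is changing.
Each is assigned to the closest changing gene on its chromosome by
\(|\text{peak midpoint} - \mathrm{TSS}|\). No distance cap is applied by
default — functional enhancers can act from hundreds of kilobases away, so
a cap would discard exactly the interesting cases — but an optional
`max_distance_bp` drops and counts remote regions. Sign-concordant
(site and gene changing in the same direction) assignments are
**enhancers**; discordant ones are **silencers**. Concordance is the
package's operationalization of the enhancer/silencer distinction; it is
recorded per assignment so downstream consumers can apply their own rule.
Distance ties go to the more significant gene (smaller \(q\), then \(p\)),
then to the lexicographically smaller gene id, making annotation
deterministic and permutation-invariant.

### Boundaries, functional domains, active domains

A boundary is an overlapping CTCF/RAD21 peak pair with both caller scores
**> 15** (strict) and score ratio **< 3** (strict) — similar occupancy of
the two factors. The boundary interval is the intersection of the two
peaks and its combined score the smaller of the two. Domains are built by
a left-to-right greedy scan that pairs each boundary with the nearest
unconsumed boundary to its right whose combined-score ratio is < 3
(reusing the same similarity constant for want of a separately specified
one); domain coordinates run between the two boundary midpoints, a
symmetric and deterministic convention. When a pairing skips dissimilar
boundaries, those stay unpaired permanently — pairing them later would
create overlapping domains — and they are reported via an attribute.
Neighbouring domains separated by strictly less than **100 kb** are merged
transitively into active domains; merging is idempotent. A regulated gene
"resides" in the domain structure when its TSS and *all* of its assigned
regions fall inside one and the same merged domain.

### Interaction frequencies

Prey positions of one bait are mapped onto fixed windows (default
**1 Mb**; the last window of a chromosome is truncated) and converted to
frequencies \(f_i = 1000\, c_i / \sum_j c_j\) — reads per bin normalized to
1000 total reads — so frequencies always sum to 1000 when any read exists.
Bins are classified with the precedence **target** (overlaps a regulated
gene or assigned region) > **active** (overlaps a merged domain) >
**inactive**; a bin containing a regulated region is unambiguously a
target, hence the precedence. Classes are compared with unpaired
two-tailed t-tests, Welch's unequal-variance form by default (the robust
reading of "unpaired two-tailed t-test"; the pooled form is available via
`var_equal`). Bins on the bait's own chromosome are excluded by default to
isolate interchromosomal signal. Restriction-fragment identity is not
modelled: at megabase resolution, preys are adequately represented as
points.

## The synthetic genome

`synthetic_spec()` / `simulate_genome()` build a deterministic (per seed)
toy genome in which every downstream answer is known:

* **Scale**: 2 chromosomes x 5 Mb. Gene density (120 genes / 10 Mb) is
  close to the mammalian average of roughly one gene per 100 kb; 180
  enhancers and 120 silent binding sites give the binding-site compartment
  realistic active/silent proportions.
* **Transcripts**: each gene has a body transcript on its strand plus a
  short (400 bp) opposite-strand promoter transcript whose 5' end lies
  `divergent_gap_bp` (150 bp) upstream; each enhancer emits two
  outward-pointing eRNAs of 300–500 bp with the same 150-bp 5' gap. eRNA
  lengths are a free parameter of the generator, not a biological claim.
  Planted transcripts cover 20% of the genome.
* **Read model**: coverage is per-base Poisson (`noise = "none"` gives the
  exact expectation) at depth \(\lambda = r \cdot N / 10^9\) for a region
  of RPKM \(r\) and library size \(N\). The default basal RPKM is derived
  as \(10^9 / \text{transcribed bp}\), the unique flat value under which
  the expected vehicle read total equals the library size; on this 10-Mb
  genome with a 1e6-read library that is RPKM 500 at mean depth 0.5. This
  is the desk-scale consequence of the RPKM definition: tiny denominators
  make every well-covered region sit far above thresholds (0.006, 0.2)
  calibrated for ~70-million-read mammalian libraries. Running a
  mammalian-scale RPKM (say, 1) through a 1e6-read library would put less
  than one expected read on a 400-bp eRNA, so nothing could be detected;
  the derived value is the self-consistent choice, and the thresholds
  remain in place as permissive floors.
* **Ligand response**: 15% of genes respond (close to the few-percent
  scale seen for a selective ligand, enlarged enough to keep desk-scale
  counts usable), 15% of those downward, at 4-fold; their enhancers' eRNAs
  change 4-fold concordantly except a 7% silencer fraction planted
  discordant. Library composition consequently differs between conditions,
  which is exactly what the median-ratio normalization handles.
* **Architecture**: 24 domains delimited by CTCF/RAD21 co-peaks whose
  score pairs stay within 2.2-fold (safely inside the 3-fold filter), plus
  20 decoy co-peaks violating the score floor or the ratio. Inter-domain
  gaps alternate between short (20–90 kb, below the 100-kb merge rule) and
  long (250–450 kb) domain-free tracts, so merging and the
  inactive-genome compartment are both exercised. Genes live in
  non-overlapping slots inside domains and each gene's enhancers are
  placed 3–11 kb upstream — always nearer their own TSS than any other
  gene's, so the planted target is also the nearest changing gene.
* **Interactions**: one active enhancer serves as bait;
  interchromosomal reads are distributed over bins at relative rates
  1 : 1.8 : 3 for inactive : active : target, plus a cis block near the
  bait that the analysis excludes. The demonstration bins at 200 kb, the
  desk-scale analogue of 1-Mb windows on a gigabase genome (about 25
  trans-chromosomal bins, comparable to what a sparse genome offers per
  comparison).

What the generator does **not** emulate: mappability artefacts, GC or
fragment-length bias, replicate variability and overdispersion (noise is
pure Poisson), convergent or overlapping gene pairs, enhancers inside gene
bodies or beyond their own gene's territory, and sequence-level motif
realism (a FASTA, if requested, is random sequence with literal DR1
consensus strings planted at enhancer centres). Passing tests therefore
demonstrate algorithmic correctness and parameter recovery under the
stated generative model — not robustness to the full messiness of real
nascent-transcription data, where segmentation gaps, fuzzy 5' ends and
dispersed counts will erode precision and sensitivity.

## Numerical conventions and degenerate inputs

* All coordinates are 0-based half-open; GTF is converted at the boundary.
  Strand `.` is allowed on peaks only, never on transcripts.
* Overlapping bedGraph records are summed with a warning (tolerant of
  replicate-merged tracks); records beyond the chromosome end are errors.
* Thresholds quoted as "more than" / "less than" are strict inequalities
  throughout (fold > 2, gap < 300, score > 15, ratio < 3, merge gap
  < 100 kb), and the tests pin the boundary cases.
* Zero-count regions: \(p = 1\), status unchanged. Identical constant
  groups in the contact comparison: \(t = 0\), \(p = 1\). Classes with
  fewer than two bins skip their comparison with a warning.
* Ties are always broken deterministically (leftmost coordinate, smaller
  gene id, more significant record), so every stage is
  permutation-invariant.

## Problem sizes used by the test-suite

The unit tests run on miniature genomes (2 x 1 Mb, 24 genes) so the whole
suite stays fast; the acceptance checks use the full reference conditions
(10 Mb, 1e6 reads) for site recovery and the transcribed fraction, 200
simulation replicates for false-discovery control, and 100 seeded
replicates for the contact-class comparison. These sizes are the package's
reference conditions; all recovery statistics quoted by
`scripts/acceptance.R` are recomputed from scratch at run time.

## Known limitations

* The change-calling model is a two-library binomial test; it cannot use
  replicate dispersion. Replicates, where available, are pooled by the
  caller.
* Median-ratio normalization assumes a majority of unchanged regions.
* Domain pairing is greedy; a dynamic-programming matching could pair
  boundaries globally but would need an objective the procedure never
  states.
* The motif scanner is a consensus-plus-mismatch matcher by design — the
  targeted-scan counterpart of pattern tools like fuzznuc — not a PWM
  scorer.

## A short session

```{r demo, eval = FALSE}
demo <- run_demo(seed = 1)
demo$network            # funnel counts of the whole analysis
glance(demo$network)    # one-row summary
tidy(demo$network)      # one row per enhancer/silencer assignment
plot_contact_classes(demo$network$contacts$bins,
                     bait_chrom = demo$network$contacts$bins$chrom[1])
```
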