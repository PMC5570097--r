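---
title: "Profiling fermentation communities on two platforms: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling fermentation communities on two platforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermentome)
```

## The problem

Uninoculated ("wild") wine fermentations are driven by a succession of
fungal species — apiculate yeasts such as *Hanseniaspora* and
*Metschnikowia* early on, *Saccharomyces cerevisiae* towards dryness. Two
sequencing strategies are commonly used to follow that succession:

* **ITS meta-barcoding**: PCR amplification of the ribosomal internal
  transcribed spacer with fungal-specific primers (BITS/B58S3), followed by
  amplicon sequencing. Cheap and sensitive, but the read count of a taxon is
  proportional not to its cells but to
  `cells x ITS copy number x amplification efficiency` — ribosomal repeat
  copy number varies widely between species, and primer efficiency varies
  with template sequence, so per-taxon abundances can be systematically
  biased.
* **Shotgun metagenomics**: total DNA is sequenced directly and mapped to a
  reference genome collection. No PCR of a marker locus is involved, so read
  counts scale with `cells x genome length`; expressing abundance *per
  genomic window* cancels genome length, making this the (approximately)
  unbiased yardstick.

`fermentome` implements both branches plus the comparison between them, and
ships a synthetic mock-community generator so the whole workflow — including
the detection of a deliberately injected amplicon bias — runs at desk scale
with known ground truth.

## The central statistic: internally normalised observed/expected ratios

For a mock community with known input cells, each platform yields observed
abundances $o_t$ per taxon with expected cells $e_t$ (conspecific strains
pooled). The raw ratio $r_t = o_t / e_t$ has arbitrary units (fragments per
cell, windows per cell), so ratios are normalised internally by anchoring on
*S. cerevisiae*:

$$ R_t = \frac{o_t / e_t}{o_a / e_a}, \qquad a = \textit{S. cerevisiae}, $$

making $R_a \equiv 1$ by construction and cancelling any global rescaling of
the observed table (`mock_ratios()`). A taxon is flagged as biased when
$R_t$ falls outside $[1/f, f]$ (`flag_bias()`; $f = 2$ for routine
reporting, $f = 5$ for headline flags). The fold bias of the ITS channel
relative to shotgun is

$$ B_t = R_t^{\mathrm{ITS}} / R_t^{\mathrm{shotgun}} $$

(`estimate_bias_factor()`), interpretable as the factor by which to divide
ITS abundances of taxon $t$ to correct them. On the published seven-strain
control mixes this statistic exposes an 18.6- and 10.5-fold
over-representation of *Metschnikowia pulcherrima* in the ITS channel while
the shotgun ratios for the same taxon sit near 0.9 and 0.7:

```{r table2}
obs <- control_mix_observed()
d1 <- control_mix_design(1)
o1 <- obs[obs$mix == 1, ]
its <- mock_ratios(setNames(o1$its_observed, o1$species), d1)
sh  <- mock_ratios(setNames(o1$shotgun_observed, o1$species), d1)
round(estimate_bias_factor(its, sh, "Metschnikowia pulcherrima"), 1)
```

## The ITS branch

`run_its_pipeline()` chains the read-preparation and OTU operations with
the defaults used throughout:

| step | operation | defaults | notes |
|---|---|---|---|
| quality trim | `quality_trim()` | `TRAILING` Q20, `MINLEN` 50 | 3' bases below Q20 removed, short reads rejected |
| merge | `merge_pairs()` | overlap >= 10, mismatch <= 0.25 | best ungapped overlap incl. "outies" (insert shorter than the read); disagreements resolved to the higher-quality base |
| adapter trim | `trim_residual_adapters()` | `-e 0.1`, overlap >= 6 | residual Illumina adapters at either end |
| demultiplex | `demultiplex()` | 1 mismatch per 8-bp barcode | dual inline barcodes; both ends stripped through the primer |
| dereplicate | `dereplicate()` | — | md5-keyed, per-sample counts kept |
| cluster | `cluster_otus()` | d = 1, min size 10 | connected components of the <=1-edit graph |
| classify | `assign_taxonomy()` | id >= 0.98, 10 accepts, consensus >= 0.4 | rank-wise consensus, unique mode required |

Design choices that were genuinely open:

* **Clustering is exact single linkage.** The greedy seeded growth and
  second-pass "fastidious" refinement of amplicon swarm clustering are
  implementation details of a particular tool; the testable core is the
  partition itself, which for linking radius *d* is exactly the connected
  components of the <= *d*-edit-distance graph. We compute those components
  exactly (verified against a brute-force oracle), with an optional
  `fastidious = TRUE` flag that grafts clusters of fewer than 3 reads onto a
  large cluster within edit distance 2 (off by default). For d = 1 the
  candidate search uses hashes of all single-deletion variants, so
  clustering stays near-linear in the number of unique sequences.
* **md5 keys** are computed on the uppercased sequence with no surrounding
  whitespace — the point of the keying is cross-experiment stability.
* **Tie-breaks are deterministic everywhere**: higher abundance first, then
  lexicographically smallest key.
* **Consensus taxonomy requires a unique mode**: the consensus-fraction
  parameter alone leaves ties undefined; we truncate to the parent rank on
  any tie.
* **Orientation**: after merging, a two-sided inline-barcoded read is
  orientation-ambiguous, so reads failing the forward-orientation barcode
  test are retried reverse-complemented; when a sample's barcode pair is
  itself symmetric (e.g. N701/N701) the primer sequences decide, ties going
  to the forward orientation.

## The shotgun branch

`run_shotgun_pipeline()`: host filtering (a pair is kept only when
*neither* mate aligns to the grapevine-like host), per-mate mapping,
exclusion of reads whose best placement is tied across locations (the
uniqueness reading of a `-q 10` mapping-quality filter), an optional
pair-concordance filter (same target, opposite strands, insert <= 1500),
then 10-kb windowing. Per window we report the read count (a read counts in
*every* window it overlaps by >= 1 bp, so boundary-spanning reads count
twice — the counting convention of `bedtools coverage -counts`) and the
`id_factor`, the mean over reads of `1 - mismatches / read length`, a proxy
for the evolutionary distance between sample and reference.

Species abundance is the mean read count over all windows of the species'
genome(s), with the **adjusted mean** rule: the mean is zeroed when fewer
than 20% of the windows contain any read. This breadth filter prevents a
handful of high-count windows — mis-mapping, or small horizontally
transferred segments shared with a truly abundant species — from fabricating
abundance for an absent genome. Normalisation is
`adjusted_mean * 1e6 / total reads` where the denominator is counted
*before* host filtering and includes unaligned reads.

Open points resolved as follows: window statistics use read counts (not
per-base depth), matching the cited counting tool; each aligned mate counts
as one read; organelle-like references with variable copy number can be
dropped via `exclude =`. The built-in mapper is a minimal ungapped
seed-and-extend aligner (k = 21 seeds, both strands, <= 10% mismatches) —
entirely adequate for high-complexity synthetic genomes, while real-data
users can ingest externally produced SAM via `read_sam_alignments()`.

## The synthetic mock community

`mock_design()` fixes the ground truth; `build_references()` and the two
simulators realise it:

* Genomes and ITS templates are i.i.d. uniform DNA. This is deliberately
  simple: uniform sequences have essentially unique k-mers, so exact
  seed-and-extend mapping is a faithful stand-in for a production aligner,
  and random ITS templates are mutually dissimilar (verified < 0.9 pairwise
  identity), so classification is unambiguous.
* Conspecific strains share one genome and one ITS template, because the
  assays cannot separate strains of a species; the two *S. cerevisiae*
  strains of the control mixes therefore map onto a single pooled anchor.
* ITS reads: per-strain counts are multinomial with weights
  `cells x its_copy_number x amp_bias`; each amplicon is
  `barcode|spacer|primer|ITS|rc(primer)|rc(spacer)|rc(barcode)` with
  degenerate primer positions instantiated per molecule.
* Shotgun reads: multinomial weights `cells x genome_length` (no bias —
  this is what makes the channel the yardstick), uniform fragment starts,
  normal insert sizes, plus a `host_fraction` of pairs from a generated
  host genome.
* Errors are substitution-only at a uniform per-base rate; the downstream
  identity factor counts mismatches, so indels would only complicate the
  bookkeeping without changing what is being tested. Quality strings are
  constant Q40 with an optional decaying tail for exercising the trimmer.

**Default parameter scale.** The generator is desk-scale by design:
genome length 100 kb (about 1% of a real wine-yeast genome), ITS template
160 nt (the ITS1-fragment scale of the BITS/B58S3 primer pair), 4 ITS
copies per genome (keeping the ribosomal repeat near its real ~0.5-1% share
of the genome), 2 x 150 nt ITS reads, 2 x 100 nt shotgun reads with 350 bp
inserts, host fraction 1% (grapevine contamination is below 1% per sample
in practice), and a 1% per-base error rate in the standard experiments.
These values were chosen once, from the experimental setting being
emulated, and are not tuned per analysis.

**What the simulator does not emulate** — and hence what passing tests do
not show about real data: chimera formation and PCR duplicates, indel and
platform-specific error profiles, sequence-dependent amplification
chemistry (bias is injected as an abstract multiplicative factor, since the
true copy numbers and primer efficiencies behind the *Metschnikowia* bias
are unknown), shared homology between community genomes and between
community and host, and real reference-database incompleteness.

## Community structure

`bray_curtis()` implements
$1 - 2\sum_i \min(u_i, v_i) / (\sum_i u_i + \sum_i v_i)$; ordination is
classical scaling (`pcoa()`): double-centre $-d^2/2$, eigendecompose, scale
eigenvectors by the square roots of their eigenvalues. Bray-Curtis matrices
are generally non-Euclidean, so negative eigenvalues occur; they are
reported but excluded from coordinates, with no Lingoes/Cailliez correction
by default — the simplest defensible convention. Axis signs follow the
first-nonzero-loading-positive rule. Analyses follow the conventions of
this application area: the 30 most abundant taxa (`top_n_taxa()`, ties
lexicographic), abundances taken as given (no rarefaction), and taxon
weightings computed as the covariance between taxon abundance and axis
coordinates scaled to unit maximum. "Weightings" overlaid on a PCoA plot
have no single standard definition (PCA-style loadings do not directly
exist for PCoA), so this covariance definition is a documented choice.

`platform_agreement()` computes ordinary least squares on log10 abundances
over taxa positive on both platforms, zeros excluded and reported
separately. On the printed control-mix table this log-scale convention
yields an R^2 near 0.90 — the *Metschnikowia* outlier is exactly what drags
it down — while the squared correlation of the linear values (dominated by
the most abundant taxa) is above 0.99; both are asserted in the test suite.

## Numerical and degenerate-input conventions

* Edit distances are banded Levenshtein, capped at d+1; hash-generated
  candidate pairs are always verified, so hash collisions cannot create
  false cluster links.
* Merging scores overlaps by matches minus mismatches; ties prefer the
  longer overlap, then the smaller offset. Outie merges report only the
  overlapping fragment.
* `mock_ratios()` reports ratio 0 for expected-but-unobserved taxa;
  observed-but-undesigned taxa are set aside rather than silently ratioed.
* Degenerate inputs fail loudly: empty dereplicated sets, all-zero
  Bray-Curtis profiles, a missing or zero anchor, zero-width windows,
  zero total reads in normalisation.

## Problem sizes used in the standard experiments

The packaged experiments simulate 50,000 read pairs per platform for the
two control-mix designs (five seeds each) for the unbiased-accuracy
analysis, and 20,000 pairs per platform across ten seeds for the
bias-recovery analysis on a balanced four-species design with a 10-fold
bias on one taxon. The balanced design is used for recovery because under
the control-mix cell counts *Metschnikowia* draws only a handful of
expected shotgun reads at this depth — no estimator could recover a fold
factor from five reads; the balanced design tests the estimator, not the
sampler. At these sizes a full dual-platform experiment runs in about a
minute on one core.

## Known limitations

* The built-in mapper is ungapped and k-mer seeded; it is not suitable for
  real, repetitive, indel-bearing genomes (ingest external SAM instead).
* Single-linkage at d = 1 fragments very low-abundance taxa whose 2-error
  reads lack a 1-error bridge; with the minimum OTU size of 10 this
  depresses rare-taxon abundances somewhat — visible in the simulations as
  ratios drifting below 1 for taxa with a few hundred reads, still well
  within the 2-fold window the analysis targets.
* `assign_taxonomy()` performs full global alignments of each query against
  every reference; fine for curated ITS databases of moderate size, not for
  hundreds of thousands of references.
* PCoA loadings are a covariance heuristic for display, not a statistical
  test; no PERMANOVA or similar inference is provided.
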