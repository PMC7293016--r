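---
title: "Methods: winscore peak calling, tissue specificity and the evolution of m6A sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: winscore peak calling, tissue specificity and the evolution of m6A sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6adyn)
```

m6adyn reimplements, as a tested pipeline, the computational analyses used to
characterize N6-methyladenosine (m6A) methylomes across tissues from
MeRIP-seq data: enrichment-based peak calling, single-nucleotide RRACH site
inference, metagene and genic-region profiling, tissue-specificity scoring,
sub-motif statistics, association with poly(A) cleavage sites, cross-species
constraint estimation with matched controls, and population-genetic selection
scans. This vignette documents the models, the tunable parameters and the
numerical choices, and states precisely what the synthetic-data experiments
can and cannot show.

## The winscore model of MeRIP enrichment

MeRIP-seq pairs an antibody-enriched (IP) library with a fragmented input
library of the same sample. Methylated fragments are over-represented in the
IP library, so methylation shows up as local IP coverage exceeding what the
input predicts. Scanning each transcript with 100-nt sliding windows, the
enrichment of a window is

$$\mathrm{winscore} \;=\; \log_2\!\frac{\mathrm{MeanWinIP}/\mathrm{MedianGeneIP}}
{\mathrm{MeanWinControl}/\mathrm{MedianGeneControl}},$$

where the window means are normalized by the gene median coverages of the
respective tracks, cancelling expression level and library depth. Windows
with winscore ≥ 2 (a four-fold normalized ratio), IP window RPKM ≥ 10 and
input gene RPKM ≥ 1 are enriched; all thresholds are inclusive. Enriched
windows overlapping within a sample merge into candidate peaks, and a
candidate becomes a peak when it reaches winscore ≥ 2 in at least two samples
of a tissue, with coordinates the union over supporting samples. m6A sites
are then the central A of every RRACH motif (R = A/G, H = A/C/U) inside a
peak, scanned on the transcript strand and deduplicated genome-wide.

Choices the window definition leaves open, and how this package fixes them:

* **Sliding step, 50 nt.** Half-window granularity; the window count stays
  linear in transcript length and every position is covered by two windows.
  The step is configurable.
* **Pseudocount, 1.** Added to all four terms of the ratio so zero-coverage
  windows and genes are defined. The pseudocount makes the statistic only
  approximately invariant to jointly rescaling IP and input coverage of a
  gene; with `pseudocount = 0` the invariance is exact, and the property
  suite tests both regimes.
* **Transcript coordinates.** Windows tile the spliced transcript of the
  (longest) isoform and are mapped back to genomic coordinates for output;
  poly(A)-selected libraries carry no intron signal.
* **Gene medians** are computed over all transcript bases, zeros included.
* **Per-sample peak winscore** is the maximum member-window winscore, and a
  site inherits the winscore of its best covering window.

To control for differences in RIP efficiency between samples, winscores can
be rescaled per sample so that the mean winscore of its top-50 peaks matches
the cross-sample average of those means (`normalize_winscores_top50()`).

## Metagene profiling

Transcripts are divided into 10 / 50 / 40 equal-length bins for 5'UTR, CDS
and 3'UTR, matching the relative segment lengths of the human transcriptome,
so bin 60 is the first 3'UTR bin and the stop codon sits at the 59/60
boundary. A site's bin is `floor(relative_position × n_bins)` with the
region-local relative position in [0, 1), clamped to the region's last bin.
Raw per-bin fractions are the canonical output; the least-squares polynomial
fit (default degree 5) is presentation-only and never feeds downstream
statistics. Noncoding-gene sites have no UTR/CDS structure and are excluded
from the 100-bin profile; genic-region annotation labels every site exactly
once with precedence CDS > UTR > ncRNA across conflicting isoforms.

## Tissue specificity

For each site the average winscore per tissue, taken at the site's best
covering window in every sample — including tissues without a called peak,
because the index needs a complete profile — forms the vector
$x = (x_1, \dots, x_n)$. Negative averages are floored at zero so $x$ behaves
like a nonnegative expression profile. The tissue-specificity index is

$$\tau \;=\; \frac{\sum_{i=1}^{n}\bigl(1 - x_i/\max_i x_i\bigr)}{n - 1},$$

which is 0 for a uniform profile, 1 for a one-tissue profile, scale-invariant
and bounded in [0, 1]. Sites with τ < 0.15 are shared, τ > 0.6
tissue-specific (strict inequalities), the rest intermediate. An all-zero
profile has no defined τ and is excluded with a logged reason. Independently
of τ, the tissue-sharing spectrum counts, per site, the tissues in whose
consensus peaks it lies; a ubiquitous-expression filter (expression > 3 in
every tissue, strict) removes gene-expression specificity from that
comparison.

## Sub-motif statistics

RRACH resolves into four sub-motifs by its two R positions — GGACH, AGACH,
GAACH, AAACH — with the H position ignored for classing. Per-sample
proportions, and their cross-tissue means and variances, summarize motif
preference. Whether GGACH and AAACH segregate into different peaks is tested
by permutation: motif class labels are shuffled uniformly over all motif
occurrence slots across a sample's peaks (positions fixed, so per-peak slot
counts and per-class totals are both conserved), and the number of peaks
containing both classes is recomputed 10,000 times. Observed and expected
counts are mean-centred by dividing by the mean expected count, and the
left-tail empirical p-value uses the (b+1)/(m+1) correction so it is never
exactly zero — with 10,000 shuffles its floor is just below 1e-4. The
wording "sub-motif sequences were shuffled within peaks" is ambiguous
between shuffling sequences and shuffling class labels; the label
permutation is adopted here as the minimal null that randomizes
class-to-peak assignment, which is exactly what the co-occurrence statistic
probes.

Because the statistic is integer-valued, the reported p-value is
conservative by construction. The calibration suite therefore checks two
things: exact KS-uniformity of the *randomized* p-value (the standard
device for discrete tests) and validity of the reported p
(P(p ≤ α) ≤ α under the null).

## Cleavage sites and poly(A) signals

Distances between m6A sites and cleavage positions are signed in transcript
orientation (downstream positive) and aggregated over cleavage sites within
±200 nt. The poly(A) signal of a cleavage site is classified from the 40 nt
upstream on the sense strand — wide enough to cover the canonical 15–30 nt
PAS-to-cleavage geometry with margin — with precedence AAUAAA, then AUUAAA,
then any of ten common single-base AAUAAA variants ("other"); sites with
none form the noncanonical class. The exact membership of the "other" group
is configurable, since poly(A) databases differ slightly. Composition
profiles report per-position base frequencies within ±50 nt per class, plus
the 5-mer context of the cut.

## Cross-species constraint with matched controls

A site is conserved when its aligned base in the target species is A; a
substitution or gap is not conserved, because the methylated base is the A
itself (an aligned purine is not enough). Since conservation varies with
gene-level selection pressure, position in the CDS, and codon position,
control A sites (non-m6A RRACH motifs) are matched by stratum: dN/dS decile
of the host gene × 20-bin CDS location × codon position (3'UTR location bin
for 3'UTR sites). dN/dS deciles balance stratum occupancy against matching
fidelity where the matching requirement is only "similar" values. For each
m6A site one control is drawn uniformly without replacement from its
stratum; 10,000 such sets give the null distribution of the conserved
fraction, and the right-tail (count ≥ observed + 1)/(10,001) is the
empirical p. Within a stratum the number of conserved controls in a set is
exactly hypergeometric, so the null is drawn per-stratum from `rhyper` —
mathematically identical to explicit index resampling (the test suite
checks this equivalence against an explicit resampling loop) and orders of
magnitude faster. When a stratum has no (or too few) controls the functions
error, listing the strata; the pipeline then coarsens bins stepwise
(10×20 → 5×10 → 3×5 → 1×5 → 1×1) until matching is feasible, recording the
resolution used.

The proportion of sites under constraint is the relative rate deficit
$\bigl((1-f_{\mathrm{m6A}}) - (1-f_{\mathrm{ctrl}})\bigr)/(1-f_{\mathrm{ctrl}})$,
reported as an unsigned percentage with the direction kept as metadata. The
phylostratigraphic age of a site is the rank of the most distantly related
species (in a divergence-ordered panel) whose aligned base is A — read
literally, conservation in intermediate species is not required; this is
configurable because the alternative (requiring a contiguous block) is also
defensible. Nucleotide-level constraint scores (rejected-substitution style)
are consumed as an input column; computing them is out of scope, and the
synthetic generator emits a correlated surrogate instead.

## Population-genetic scans

SNPs are annotated against RRACH motifs on the host gene's sense strand:
their motif-relative position (R1/R2/A/C/H), the m6A allele (the allele that
completes the motif; SNPs where both alleles do are flagged ambiguous and
excluded from ratio tests), and whether the derived allele creates an RRAC
motif that the ancestral allele does not (`creates_motif`), using the
ancestral-allele tag (INFO/AA; records without it are excluded and counted).
Allele-specific methylation compares the m6A-allele read ratio between IP
and input compartments per motif position with a two-sample
Kolmogorov–Smirnov test; derived-allele-frequency spectra of gain-of-motif
SNPs are compared with control groups (non-m6A RRACH in 3'UTRs; intergenic
RRACH) by a one-sided Mann–Whitney U test (normal approximation with tie
correction, alternative: m6A right-shifted). Per-SNP Fst is the
Weir–Cockerham (1984) variance-components estimator θ = a/(a+b+c) computed
from genotypes — the same estimator standard VCF tooling reports — with raw
(possibly negative) values kept and monomorphic SNPs undefined; SNPs with
Fst > 0.15 (strict) form the highly differentiated set, retaining both
derived-m6A-allele and ancestral-m6A-allele SNPs. Heterozygote calling from
read pileups defaults to ≥ 10 reads and minor-allele fraction ≥ 0.2 — no
published thresholds exist for this step, so both are explicit arguments. No
multiple-testing correction is applied by default (raw p-values are
reported, as is conventional for these scans); BH adjustment is available
via `p.adjust` on the returned tables.

## The synthetic study and what it shows

`simulate_study()` emits a complete miniature study with machine-readable
ground truth; every artifact draws from its own RNG stream derived from the
master seed, so runs are bit-reproducible and adding artifacts never
perturbs earlier ones. Defaults define the reference study conditions:

* **Geometry.** 200 intronless protein-coding genes (5'UTR/CDS/3'UTR =
  240/1200/960 nt, the canonical 10:50:40 proportions) plus 10% noncoding
  genes, separated by 2-kb intergenic gaps; one isoform per gene.
* **Sites.** Planted at 2/kb; 70% of coding-gene sites drawn from a normal
  distribution centred on the stop codon (sd 150 nt), the rest uniform,
  reproducing the stop-codon concentration seen in real methylomes. Each
  site is written into the reference as an RRACH 5-mer and carries a
  lognormal methylation-level multiplier (sd 0.25 on the log scale).
* **Methylation structure.** A site is tissue-specific (methylated in
  exactly one of three tissues, three replicates each) with probability 0.4
  — near the one-tissue fraction observed in real adult-tissue panels —
  otherwise methylated in all tissues.
* **Coverage.** Per-base negative-binomial counts (size 10) around depth 30,
  scaled by lognormal gene×tissue expression (sd 0.5) and per-sample RIP
  efficiency (sd 0.2); IP means are multiplied by 8 × the site level within
  ±50 nt of a methylated site. Coverage is simulated directly (not as
  reads): peak calling consumes coverage, and read mapping is out of scope.
  Enrichment 8 is a free parameter chosen so a fully enriched window clears
  the four-fold winscore threshold with margin; 1 is the null.
* **Conservation.** Aligned bases per species are independent Bernoulli
  draws: P(A) = 0.9 at m6A sites vs 0.6 at controls, per-gene dN/dS ~
  Gamma(2, 10) shared by m6A and control sites of a gene.
* **Population genetics.** Two populations × 120 haplotypes; neutral SNPs
  follow a 1/i site-frequency spectrum; 30% of gain-of-motif SNPs are
  "selected": derived frequency shifted +0.3 and split ±0.25 between
  populations (high Fst). Ancestral alleles are tagged in INFO/AA;
  5% of records omit the tag to exercise the exclusion path.

What passing tests on this generator do show: the estimators recover exactly
the structure planted under their own model assumptions — winscore peaks
find the enrichment boxes, τ separates planted specific from broad sites,
the matched-control test detects a 0.9 vs 0.6 conservation gap with power
near 1 at 200 sites, the DAF test detects a +0.3 shift, Fst separates
selected from neutral SNPs. What they do not show: robustness to features of
real data the generator omits — autocorrelated and fragment-length-shaped
coverage, smooth (not box-shaped) enrichment decay, isoform diversity and
introns, mapping artifacts, batch structure, linkage disequilibrium between
SNPs, and phylogenetically correlated (non-independent) substitution
patterns across species.

One structural property of the box-enrichment geometry is worth knowing
when interpreting recovery numbers: with 8-fold enrichment a 100-nt window
passes the four-fold threshold once ≳ 3/7 of it overlaps the ±50 nt box, so
consensus peaks legitimately extend up to ~57 nt beyond the box, and
background RRACH motifs in that flank band (all of them 51–110 nt from a
planted site, in practice ~17% of called sites) are called as sites. At
50-nt tolerance the caller therefore plateaus near 83% precision at ~97%
sensitivity on these defaults; within-box tolerance would count those flank
calls differently, but the 50-nt criterion is kept as the stricter reading.

## Problem sizes and numerical conventions

Internal coordinates are 0-based half-open everywhere (BED-native); GTF and
VCF are converted at the boundary. All thresholds are inclusive (≥) except
where a strict inequality is printed (τ classes, FPKM > 3, Fst > 0.15).
Permutation tests use 10,000 draws at analysis scale; the test suite runs
reduced sizes (199–2,000 draws, 200+ replicate runs for calibration) and the
end-to-end demo uses the default 200-gene study, which completes in a few
minutes on one CPU. Quartile splits use nearest-rank boundaries with
disjoint groups; ties in classification thresholds go to the intermediate
class by the strict inequalities above.

```{r demo, eval = FALSE}
cfg <- sim_config(seed = 1)
run <- run_pipeline(cfg, outdir = "m6adyn_demo")
print(run)
```
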