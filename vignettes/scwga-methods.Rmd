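---
title: "Models and methods in scwga"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in scwga}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scwga)
```

# Scope

`scwga` evaluates single-cell whole-genome amplification (WGA)
experiments. It bundles four analysis tracks — coverage uniformity,
bulk-referenced variant evaluation, kindred-cell somatic-rate
estimation, mutagen-exposure analysis — plus CRISPR off-target
attribution, and a set of synthetic-data generators that produce every
input the analyses need, with recorded ground truth. The generators are
first-class, tested code: all statements the test suite makes about the
analyses are statements about their behaviour on these synthetic
conditions, not about any particular sequencing run.

# The amplification simulator

Quasilinear, terminator-limited amplification (PTA-like chemistry) and
exponential isothermal amplification (MDA-like) are both modelled as a
discrete-round branching process over *amplicons*:

* Each round, every template receives a Poisson number of primers,
  `priming_rate` per kb of *effective* template length.
* An extension copies the template rightward from a uniform start until
  it incorporates a chain terminator (per-base probability `alpha`) or
  reaches the template end.
* A terminated daughter re-enters the template pool with its length
  down-weighted by `rho` (`reprime_weight`); un-terminated daughters and
  the two primary haplotypes keep full weight.
* Copies inherit the template's copying errors that fall inside the
  copied interval and add fresh errors at `error_rate` per base.

The defaults are mode presets chosen once, as the package's
characterisation of the two chemistries, and validated by qualitative
ordering properties only (no kinetic constants are available for a
quantitative fit):

| parameter | quasilinear | exponential | why |
|---|---|---|---|
| `alpha` (per base) | 2e-3 | 5e-5 | mean amplicon ~500 b vs tens of kb |
| `rho` | 0.05 | 1.0 | terminated products re-prime poorly vs fully |
| `priming_rate` (/kb/round) | 2 | 0.05 | see below |
| `error_rate` (per base) | 1e-4 | 1e-4 | inflated so error statistics are measurable on toy (100 kb) genomes |
| `rounds` | 6 | 6 | enough for compounding bias to express |

The two priming presets keep total product mass on the same order
between modes: exponential re-amplification compounds per round, so a
single shared priming rate either starves the quasilinear pool (no
overlapping product, so every error sits on the only molecule at its
locus) or detonates the exponential one. Treating primer economy as
part of the chemistry preset — rather than `rho` alone — was the one
deviation from a pure single-knob design; both knobs are still
user-settable.

Three ordering properties characterise the modes and are asserted over
paired seeds in the test suite:

1. mean amplicon length: quasilinear < exponential;
2. coverage inequality (Gini of binned sampled reads): quasilinear <
   exponential in at least 95% of paired replicates;
3. allele fractions of *callable* copying errors (molecule-share VAF at
   least 0.1, the kind of discordant variant a caller could emit):
   quasilinear medians below exponential medians in at least 95% of
   paired replicates. The 0.1 floor matters: the bulk of exponential
   errors are fresh last-round copies at vanishing VAF, which no caller
   would see; the comparison mirrors distributions of *called*
   discordant variants.

`error_vaf()` reports exact molecule-share allele fractions (carriers
over covering amplicons) rather than sampled read counts; the expected
read-level VAF equals this share, and the exact value removes one
source of Monte-Carlo noise from mode comparisons.

# Coverage uniformity statistics

`cv()` is the coefficient of variation of binned counts with the
*sample* (n−1) standard deviation — pinned so golden values are stable
on small bin counts. `mapd()` is the median absolute difference of
log2-transformed counts of consecutive bins, pooled across maximal runs
of unmasked bins (runs never span chromosome boundaries or masked
bins); zeros are handled with a +1 pseudocount, a choice that
deliberately *preserves* the known artifact where profiles dominated by
zero bins report a lower MAPD than their informative bins alone — the
suite asserts that inequality rather than hiding it. The Lorenz curve
sorts bins ascending by count (stable sort, so ties keep input order)
and `gini()` is one minus twice its trapezoidal area; a brute-force
mean-absolute-difference Gini serves as the independent oracle at 1/n
discretisation tolerance. Reads with mapping quality below 40 are
dropped at binning, and bins overlapping assembly gaps or segmental
duplication masks are excluded from every statistic. Default profile
bin width is 100 kb; `metric_vs_scale()` re-bins at multiples of the
native width and/or thins counts binomially for metric-versus-scale
sweeps.

# Variant evaluation

Variant identity everywhere is `(chrom, pos, alt)`; a genotype
disagreement (0/1 vs 1/1) still counts as detection, because the
evaluated quantity is "variants identified". Allele fraction is always
recomputed as `alt / (ref + alt)` from allele depths; AF tags are never
trusted. Missing genotypes are "not called" in all set logic.
Sensitivity is the detected fraction of bulk calls; discordant calls
are cell-not-bulk. Allelic dropout at bulk-heterozygous sites is a VAF
outside `[0.1, 0.9]` at cell depth ≥ 10, or an uncalled site with
adequate coverage; the bounds are pinned here, since the underlying
distributions are usually shown without a numeric cutoff.

Mutation spectra use the pyrimidine convention (purine-reference
variants are reverse-complemented, alleles and context alike) over 6
classes and 96 trinucleotide channels; variants at sequence edges or
with `N` context are skipped and counted. Spectrum reconstruction
solves non-negative least squares against a user-supplied
reference-signature matrix (96 × k, columns summing to 1) via
`pracma::lsqnonneg`, reporting the cosine similarity between observed
and reconstructed spectra. No signature catalogue is bundled; tests use
synthetic matrices, with an exhaustive exposure-lattice search as the
oracle for k ≤ 3.

# Kindred-cell analysis

Kindred cells — single cells re-isolated from a clone grown out of one
founder — make classification against the donor bulk possible:

* **callable sites**: bulk depth ≥ 15 and ≥ `ceiling(0.5 × n_cells)`
  cells at depth ≥ 5 (the ceiling convention is pinned here);
* **germline**: called in the bulk;
* **somatic**: absent from the bulk, called in ≥ 2 cells (recurrence
  rule; founder somatic variants are shared by the clone);
* **false positive**: absent from the bulk, private to one cell.

The recurrence rule is this package's concrete reading of the
bulk/one-cell/multi-cell comparison scheme; since private high-quality
calls may contain genuine somatic variants, `include_private = TRUE`
optionally admits them (the default recurrence-only estimate is the
conservative one).

High-quality (HQ) calls satisfy DP ≥ 10, GQ ≥ 20, VAF ≥ 0.35. The
per-cell somatic rate corrects observed HQ somatic counts for
incomplete detection:

```
rate = HQ somatic carried / (HQ germline sensitivity × callable Mb)
```

with sensitivity estimated as the fraction of bulk-HQ germline variants
the cell detected with an HQ call — the same filters on numerator and
denominator, so the correction is internally consistent. By default
only bulk-*heterozygous* germline variants enter this estimate:
somatic variants are heterozygous, and homozygous variants pass the
VAF filter almost surely, so including them would overstate
sensitivity and bias the corrected rate downward by a few percent.
Genome-wide burdens extrapolate with `genome_mb = 3088` (GRCh38
primary assembly).

At genome scale the per-cell germline carrier rows (millions per cell)
are aggregated during classification rather than materialised
(`germline_carriers = FALSE`); the summaries are identical either way.

# The kindred generator and what the recovery tests show

`simulate_kindred_dataset()` plants germline variants (default 1,000
per Mb, two-thirds heterozygous), founder somatic variants (default
0.33 per Mb, the burden reported for single hematopoietic stem cells),
and per-cell private false positives (Poisson, default mean 2,785 — a
PTA-like burden) with Beta(2, 6) allele fractions mimicking the
low-VAF skew of amplification artifacts. Depth is negative binomial
(mean 30, dispersion 0.3; bulk mean 45), allele depths are binomial
splits, and GQ is a deterministic phred-like function of depth and VAF
— over-dispersion without read-level modelling. One root seed feeds
labelled child streams per cell and stage, so adding a cell leaves the
others' draws untouched. Positions live on 100-Mb pseudo-chromosomes;
site collisions from the birthday effect are dropped or resolved
first-wins.

The acceptance-level checks run 10 seeds of the default 5-cell,
3,088-Mb configuration with detection probability 0.85 and require the
mean estimated rate to sit within 3 Monte-Carlo standard errors of the
planted 0.33/Mb, and a 3,200-Mb two-cell configuration whose per-cell
germline precision, averaged over 10 seeds, rounds to 99.9%. What
passing shows: the classification logic and the sensitivity correction
are unbiased *under this generator's assumptions* — detection
independent across variants and cells, depth independent of position,
no shared artifact hotspots. Real amplification artifacts cluster and
recur; the generator deliberately omits recurrent FPs (they would be
misclassified as somatic by any recurrence rule, which is exactly the
overestimation caveat the somatic-rate method carries).

# Mutagen-exposure analysis

A variant is mutagen-attributed when called in exactly one cell, absent
from the bulk call set, at a site with bulk depth ≥ 15 (absence must be
verifiable; under-covered sites are excluded outright). Per-cell sets
are disjoint by construction. Dose–response tables aggregate per-cell
counts by compound and dose. DNase-hypersensitive-site enrichment
extends DHS intervals by 340 b (two nucleosomes) on each side, merges
them, and compares the proportion of a cell's variants inside
covered (≥ 10×) DHS against the proportion of the ≥ 10× genome in DHS;
a variant occupies its single base position, half-open containment.

# CRISPR off-target attribution

Candidate sites are all genomic 23-mers (both strands, windows with `N`
skipped) whose first 20 bases are within 5 mismatches of the
protospacer and whose PAM positions 2–3 read `GG` (the N is free). The
canonical cleavage coordinate is the blunt cut between protospacer
positions 17 and 18, 3 bp 5′ of the PAM — standard SpCas9 geometry,
pinned here because "canonical cleavage site" needs a number. The
implementation scans with `Biostrings::matchPattern`; a pure character
brute-force scan is the test oracle (200 random genome/protospacer
cases).

Indels are attributed when their leftmost coordinate falls within 50 bp
of a cleavage site of the gRNA their cell received (an any-overlap mode
is available for long deletions, since "overlap within 50 bp" is
ambiguous for them; leftmost is the default), excluding indels present
in the bulk or in any cell that received a different gRNA; control-cell
hits are reported separately as presumed false positives.
Non-recurrent single-base insertions — the classic amplification
artifact — are removed. Structural variants require both breakpoints
within 200 bp of (possibly different) cleavage sites and must not recur
in control or other-gRNA cells. Chromosome scope is a configurable
include-list defaulting to every sequence in the genome.

# Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; VCF (1-based) and
  GRanges (1-based closed) are converted exactly at I/O boundaries.
* Even-count medians use the mean of the central pair.
* Nearest-cleavage-site ties resolve to the lower coordinate.
* Empty pools produce all-zero coverage, not an error; zero-mean
  profiles, empty bulks, and all-zero spectra are rejected with
  explicit messages.
* `derive_seed()` folds a labelled stream name into the root seed with
  a small polynomial hash; all derived seeds stay below 2^31.
* Multiallelic VCF records are split into biallelic records keeping
  `(AD[1], AD[k+1])`; alleles absent from the genotype are dropped as
  uncalled.

# Problem sizes

The test suite and the acceptance script run entirely on synthetic
data: toy genomes of 10–100 kb for amplification, spectra and
off-target work (with brute-force oracles on genomes up to a few kb),
and site-sparse kindred simulations at the full 3,088-Mb coordinate
space with ~3.1 M germline sites per run, 10 seeds per estimate. These
sizes were chosen so each property is measured at the scale its claim
is about, while a complete run stays in the minutes range on one core.

# Known limitations

* The branching-process parameterisation is a stand-in validated by
  ordering properties, not a kinetic model; absolute coverage or VAF
  levels are not calibrated to any platform.
* No read-level simulation (FASTQ), sequencing-error model, chimera
  formation, or GC bias.
* The kindred generator has no positional structure in false positives,
  no copy-number variation, and no ploidy changes, so CNV-aware
  corrections are out of scope.
* CNV segmentation, SV calling and de novo signature extraction are
  consumed as inputs or replaced by reconstruction against supplied
  reference signatures; they are not reimplemented.
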