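---
title: "Predicting and validating restriction-based centromere enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting and validating restriction-based centromere enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cenrich)
```

## The model

Human centromeres are long tandem arrays of AT-rich ~171-bp alpha-satellite
monomers, frequently organised into chromosome-specific Higher Order Repeat
(HOR) units, flanked by pericentromeric satellite families (HSat1–5, of
which HSATII is the most prominent). These arrays are strongly depleted of
many restriction sites that occur every few hundred bp elsewhere in the
genome. Digesting genomic DNA with a combination of such enzymes therefore
shatters the bulk of the genome into small fragments while leaving
satellite arrays as rare, very long fragments; selecting high-molecular-
weight material (in practice >20 kb, by sucrose-gradient fractionation)
yields a sample in which centromeric DNA — ~2.8% of the reference genome —
can exceed half of all base pairs, a >20-fold enrichment.

This package models the computational side of that strategy end to end:
predicting the enrichment achievable with a given enzyme combination on a
given genome, screening enzyme panels for good combinations, and
quantifying realised enrichment and methylation effects from
sequencing-derived count tables.

## In silico digestion

An enzyme is a name plus an IUPAC recognition sequence; `CCNGG` (ScrFI)
describes four concrete 5-mers. Matching uses `Biostrings` with the
pattern's ambiguity codes interpreted and the genome taken literally, so an
assembly `N` never matches anything. For non-palindromic recognition
sequences both orientations are scanned and reported in forward
coordinates; the six shipped enzymes (ScrFI `CCNGG`, NlaIV `GGNNCC`,
EcoO109I `RGGNCCY`, BstUI `CGCG`, MscI `TGGCCA`, AseI `ATTAAT`) are all
palindromic, so for them single-strand scanning already finds every
double-strand site.

Digestion replaces each retained recognition site by a break and takes the
lengths of the remaining strings as the fragment sizes (`site_removal`,
the default). This deletes site bases from the fragments — a deliberate
simplification that makes fragment lengths slightly conservative; a
`site_retained` mode that cuts at the site start and conserves every base
is available for mass-balance work.

Three numerical choices deserve a note:

* **Multi-enzyme resolution.** When several enzymes' candidate sites
  overlap, the pooled candidates are resolved to a non-overlapping set by
  greedy leftmost selection, with ties at equal start broken toward the
  longer recognition sequence and then by enzyme-name order. A joint pool
  was chosen over sequential per-enzyme substitution because it is
  order-independent; the two differ only on rare overlapping-site
  configurations.
* **Assembly gaps.** Runs of `N` at least as long as the plan's shortest
  recognition sequence are treated as hard fragment breaks in both modes,
  so unresolved gaps cannot masquerade as long intact fragments.
* **Case.** Sequences are uppercased on input; soft-masking never alters
  digestion.

The implementation is continuously cross-checked against a naive
window-by-window scanner written directly from the IUPAC table, and obeys
exact mass conservation (fragments + retained sites = sequence length).

## Enrichment prediction

```{r toy, eval = FALSE}
toy <- make_toy_genome(toy_genome_spec(seed = 1))
plan <- digestion_plan(c("ScrFI", "NlaIV", "EcoO109I"))
tbl <- predict_enrichment(toy$genome, toy$regions, plan)
enrichment_above(tbl, min_length = 20000)
```

`predict_enrichment()` digests the target partition (regions labeled
`cen_region` by default) and the rest of the genome separately, bins all
fragments by length, and reports per bin the percentage of fragments and of
base pairs that are of target origin, plus the fold enrichment in target bp
over the undigested baseline (the genome-wide target bp fraction). Bins
default to 5-kb steps up to 55 kb with an open-ended top bin; the exact
edges are a parameter and every result table records its own.

Digesting partitions separately means fragments never straddle a
target/non-target boundary; this reproduces the per-region convention of
reference in silico digestions but slightly idealises boundary behaviour.
A `whole_chromosome` mode digests chromosomes intact and labels each
fragment target when at least half of its length overlaps target regions —
closer to a real digest, at the cost of boundary fragments of mixed origin.

`screen_combinations()` evaluates all enzyme combinations up to a size
limit, reusing per-enzyme site positions across combinations. The default
objective is the maximum fold enrichment over bins starting at >= 15 kb,
reflecting the fragment range that survives high-molecular-weight size
selection; screening output is verified in the test suite against
brute-force per-combination prediction.

## Sequencing-based validation

Downstream of external aligners, realised enrichment is quantified from
simple count inputs:

* `count_kmer_positive_reads()` classifies reads as satellite when at least
  two of their k-mer windows (default k = 18) belong to a reference k-mer
  set. K-mers are canonicalized (lexicographic minimum of k-mer and reverse
  complement) so read orientation is irrelevant. "At least two" is read as
  two matching *windows* — in tandem-repeat DNA a recurring k-mer is
  informative each time it occurs; a `distinct = TRUE` flag provides the
  distinct-k-mer variant.
* `binned_log2_profile()` scales sample and reference binned counts (2-kb
  bins by default) to a common total and reports per-bin log2 ratios with a
  pseudocount of 1 scaled count; `call_domains()` extracts enrichment
  domains as maximal runs of bins with fold strictly above 5, by default
  with no gap bridging and no minimum run length (the strict reading of the
  5-fold rule; both are parameters).
* `uncut_site_fraction()` counts recognition-site occurrences inside reads
  — overlapping occurrences allowed, since reads are observations rather
  than digestion substrates — and expresses the digested sample's count as
  a percentage of an unfractionated reference at equal base totals.
* `length_change()` turns depth-normalized per-region read counts into
  percent variation between conditions, the usual proxy for relative
  satellite array length; `coverage_threshold_table()` summarises what
  fraction of 2-kb bins reach each minimum coverage.

## Methylation comparison

Per-CpG methylation frequency is the percentage of reads calling the site
methylated among reads with any valid call. `classify_changes()` joins two
condition tables on position and applies the donut-chart rule with strict
inequalities exactly as conventionally stated: sites enter only with WT
frequency > 40% and coverage > 10 in both samples; a retained site is
increased/decreased when the KO−WT difference exceeds ±10 percentage
points, otherwise unchanged — so boundary values (Δ = ±10, coverage = 10,
WT = 40%) fall on the conservative side. Frequencies are carried as
percentages throughout because the band arithmetic is in percentage
points. `aggregate_by_family()` reports unweighted per-site means per
repeat family. `find_dip_regions()` is a small sliding-window utility for
locally hypomethylated subdomains (centromere dip regions): windows of
10 kb stepped by a quarter window, dips are runs of windows whose mean
frequency is below threshold, at least 20 kb long, and flanked on both
sides by informative above-threshold windows — a uniformly hypomethylated
array is therefore not a dip.

## The synthetic-data generator

`make_toy_genome()` emulates the features of real (peri)centromeres that
the pipeline's correctness depends on: tandem arrays of a single monomer
(default 171 bp, AT-rich), rejection-sampled so that the *doubled* monomer
— hence every junction window of the tandem array — is free of the chosen
enzymes' sites; and background DNA carrying exact recognition-site
instances at controllable spacing (default 500 bp, jittered ±20% so
fragment sizes are controlled without being degenerate). Defaults build a
34,200-bp array (200 monomers) in a 342,000-bp chromosome: target fraction
exactly 0.10, so designed-recovery checks have exact expectations
(top-bin target fragment percentage 100, selected fold exactly 10).

What the generator does *not* emulate: real alpha-satellite sequence
divergence between monomers (a `divergence_rate` exists but defaults to
0), chromosome-scale genomes, nanopore error models (the read simulator is
error-free by default, with an optional uniform substitution rate), and
biased coverage. Passing tests therefore demonstrate algorithmic
correctness under controlled conditions, not robustness to every artifact
of real sequencing data.

`simulate_methylation()` draws per-site WT methylation probabilities from
a beta distribution around a family mean (concentration 50, i.e. a ~6-7
percentage-point site-level spread), sets the KO probability to the WT
probability scaled by one minus the family's relative drop, and draws
binomial calls at Poisson coverage (mean 30). The default family effects —
a 73% relative drop at HSATII versus 9.8% at alpha-satellite — mirror the
observed behaviour of DNMT1/DNMT3B double-knockout cells, where
pericentromeric methylation collapses while centromeric methylation is
largely maintained. Family WT means default to 65% (alpha-satellite) and
75% (HSATII): high-methylation satellite values chosen so that the >40%
WT inclusion filter retains most sites, which is the regime in which the
classification rule is informative. Note that with coverage ~30, binomial
noise on a frequency difference is ~13 percentage points, so the
alpha-satellite family ends up with "unchanged" as its largest class but
not an overwhelming majority — an inherent property of the rule at that
coverage, visible in the simulation exactly as in real data.

## Problem sizes and determinism

All generators are deterministic given their seed, and every synthetic
dataset carries a truth record recomputable from its own FASTA/BED output.
The shipped tests run on desk-scale problems — a few hundred kb of toy
genome, 200 oracle-comparison sequences up to 5 kb, 1,000 conservation
cases, 10,000 simulated reads, 5,000 simulated CpGs — chosen so the whole
suite completes in a few minutes on one CPU while leaving the statistical
checks (binomial confidence intervals, 2-standard-error recovery bands)
well-powered. Full-scale reproduction on a real reference genome is a
matter of supplying the genome FASTA and region BED to the same functions;
nothing in the implementation is specific to toy sizes.

## Known limitations

* Enzyme methylation sensitivity is not modeled; on CpG-methylated genomes
  predicted digestion overestimates cutting for methylation-blocked
  enzymes (observable downstream as elevated uncut-site fractions).
* Partial digestion and star activity are out of scope; digestion is
  all-or-none at every retained site.
* `site_removal` deletes recognition-site bases, so fragment lengths are
  a few bp shorter than a physical digest would give; use `site_retained`
  when exact mass matters.
* The published satellite 18-mer catalogue is consumed as a plain text
  file; it is not redistributed with the package. `kmer_set()` can build a
  set de novo from user monomer sequences instead.
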