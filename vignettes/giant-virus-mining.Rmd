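---
title: "Mining giant-virus scaffolds from soil metagenomes: methods and design"
author: "gvmine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining giant-virus scaffolds from soil metagenomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gvmine)
```

## The problem

Giant viruses (phylum *Nucleocytoviricota*, the nucleocytoplasmic large DNA
viruses) are routinely detected in metagenome assemblies by baiting with a
handful of core genes, most often the major capsid protein. That bait fails
for non-icosahedral families — *Pandoraviridae* lack the capsid protein
entirely and *Pithoviridae* carry only a divergent form — which matters in
soil and permafrost, where exactly these families are expected. gvmine
implements an alternative detection scheme that does not privilege any single
gene: every scaffold is summarised by two counts, and a calibrated straight
line in that plane separates viral from cellular sequences. Around this core
the package provides the supporting stages such a survey needs: assembly
chimera assessment against references, marker-gene extraction with a paralog
filter for phylogeny, coverage-based abundance and virus–eukaryote
co-occurrence statistics, and a synthetic-data generator that reproduces the
statistical structure of a control database so the whole analysis can be
exercised and tested offline.

## The classification model

Each scaffold is reduced to an evidence pair $(c, v)$:

* $v$ — the number of distinct ORFs on the scaffold matching a
  *Nucleocytoviricota*-specific HMM profile at E-value $\le 10^{-10}$;
* $c$ — the number of qualifying cellular protein matches (identity
  $\ge 35\%$, E-value $\le 10^{-5}$, subject in Bacteria, Archaea or
  Eukaryota).

The decision rule is a strict linear discriminant:

$$\text{viral} \iff v > a\,c + b$$

with points *on* the line excluded. The published operating point is
$a = 0.1$, $b = 1$. Calibration (`calibrate_boundary()`) is an exhaustive
grid search: every $(a, b)$ pair on a configurable grid (default slope 0–0.5
by 0.01, intercept 0–10 by 0.5) is scored on a labeled control set, pairs
whose *eukaryotic* false-positive rate is not strictly below 1% are discarded,
and the most sensitive surviving pair wins. Eukaryotes get the hard
constraint because they are the host compartment: a eukaryotic contig
mistaken for a virus is the contamination mode that matters most downstream
(endogenized viral regions aside, which are handled by annotation flags, not
by the boundary). Two choices here are deliberate and configurable:

* *Strictness.* "Less than 1%" is read strictly, so 1 misclassified
  eukaryote among 100 fails. Likewise "better than the stringent threshold"
  (markers, below) means strictly smaller E-value, and a scaffold exactly on
  the decision line is non-viral.
* *Tie-breaking.* Among equally sensitive feasible grid points the higher
  intercept, then the higher slope, is preferred — the most conservative
  boundary that costs no sensitivity.

A proportions mode (both counts divided by the scaffold's ORF count) is
provided but not the default; on count data the raw-count rule performs at
least as well, and proportions are unstable on short scaffolds with few ORFs.

Two conventions behind the evidence pair deserve a note. Viral evidence
counts *ORFs* (an ORF hitting three profiles counts once); cellular evidence
counts *hit rows*, because that is what large similarity searches report —
but row counts inherit the upstream tool's per-query reporting limit, so each
ORF's contribution is capped (default 25 rows) and a distinct-ORF mode is
available. The built-in ORF caller (`extract_orfs()`) is deliberately minimal
plumbing: six-frame stop-to-stop extraction, standard code, no start-codon
requirement, minimum 50 aa. Ambiguous codons (translated `X`, e.g. over `N`
runs) break ORFs the same way stops do, so scaffolding gaps never produce
phantom ORFs; externally predicted genes can be supplied instead and are
expected for real analyses.

## Chimera assessment

Assemblies are validated by aligning contigs to reference genomes (mock
communities, or the generator's truth). `trim_overlaps()` implements the
match-trimming rule: matches below 99.99% identity are discarded, the rest
are processed best-first (descending score; ties by ascending E-value, then
start, then reference id — the ordering is documented because it makes the
result permutation-invariant), each match is cut wherever it overlaps
previously retained segments, and every resulting fragment is kept only if it
is at least 500 nt. A query whose retained segments name two or more distinct
genomes is chimeric; a query with no retained segment is *unassessed* and
excluded from proportion denominators (no alignable evidence either way) —
though the all-queries denominator is also reported, since published chimera
rates do not always state which convention they use. At bin level a bin is
chimeric when its contigs' segments jointly span two genomes, and
single-contig bins are excluded from the denominator.

## Marker genes and the paralog filter

Phylogenetic placement uses seven marker genes: family B DNA polymerase, the
two largest RNA polymerase subunits, VLTF3, the major capsid protein, the A32
packaging ATPase and the D5 primase (`default_marker_set()`). TFIIS is
excluded by default because its phylogeny conflicts with well-established
clades; D5 is retained even though it shows an anomalous placement in
Cedratviruses — the anomaly is a property of that gene's history, not of the
selection logic.

Marker hits start at a permissive E-value of $10^{-5}$. Because giant-virus
genomes duplicate genes freely, a second, *stringent* threshold is derived
per marker from the paralogs themselves: collect the E-values of every
scaffold's second-best copy, sort ascending, and take the first quartile.
The quartile convention is nearest-rank (the order statistic at index
$\lceil n/4 \rceil$): E-values span dozens of orders of magnitude, and
interpolating on the raw scale would be dominated by the largest values. An
interpolated quartile on $\log_{10} E$ is available as an option. When a
marker has no multi-copy scaffolds the threshold falls back to the initial
cutoff — no paralog evidence, no extra stringency — with a warning. Only the
best copy per scaffold survives, and only if strictly below the threshold.
Scaffolds then partition into a high-confidence set (≥ 3 of the 7 markers,
safe to place in a tree without split-genome artifacts) and an extended set
(≥ 1 marker) for the broader census; the first is provably a subset of the
second. Profiles for completeness checking are restricted to low-copy
families (mean ≤ 1.1 copies per genome, inclusive).

## Abundance and co-occurrence

Relative abundance is coverage-based: per sample, a group's abundance is the
sum of mean scaffold coverages of its scaffolds divided by the summed
coverage of *all* scaffolds — both restricted to sequences ≥ 10 kb, the
scale at which scaffold statistics are trustworthy here. Scaffolds without a
taxonomy label pool into `unclassified`, so rows sum to 1 over exhaustive
groups. Coverage comes either from precomputed tables or from SAM files via
`coverage_from_sam()`, which drops alignments under MAPQ 3 and reads of at
most 30 nt (the abundance workflow), or MAPQ 30 for cross-sample presence
calls, where a scaffold counts as present only when strictly more than 10 kb
of it is covered.

Virus–eukaryote co-occurrence uses the Spearman rank correlation. A pair is
tested when both members are non-zero in at least 2 samples; the correlation
is then computed over *all* samples, zeros included — excluding zeros would
silently change $n$ from pair to pair. P-values come from the t
approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ with midrank ties for
$n \ge 10$, and from the exact tie-aware permutation distribution (all $n!$
arrangements) below that; a typical 11-sample design sits just inside the
approximation, and both routes are exposed. All tested pairs in a run form a
single Benjamini–Hochberg family. Pairs with a constant abundance vector have
no defined correlation; they are emitted flagged and excluded from the
family rather than dropped silently. The virus:eukaryote coverage ratio uses
the unbiased $n-1$ standard deviation, with zero-denominator samples flagged
and excluded.

## The synthetic-data generator

The generator produces every input the pipeline consumes, with known truth:

* **Contigs** (`shred_genomes()`) are cut as consecutive non-overlapping
  fragments from source genomes, mimicking control-database construction by
  shredding references into contig-sized pieces. Lengths default to a
  lognormal with log-mean 9.8 and log-sd 0.6 truncated to [10, 200] kb —
  median ≈ 18 kb, chosen once as a realistic scaffold-size profile for a
  soil assembly analysed at the ≥ 10 kb scale — and are fully configurable,
  including an empirical resampling family.
* **Chimeras** (`plant_chimeras()`) replace an expected fraction of contigs
  with two-genome junctions. The junction point is uniform over
  $[\ell_{min}/2,\; L - \ell_{min}/2]$ so both halves stay long enough to be
  retained by the 500-nt trimming rule — planted chimeras are detectable by
  the stated rules, which is the point of planting them.
* **Evidence counts** (`simulate_hit_counts()`) are negative binomial with
  per-class rates per kb and mean proportional to contig length
  (`dispersion = Inf` gives Poisson). Defaults encode well-separated
  populations — viral contigs at 5 viral-ORF and 1 cellular match per 10 kb,
  cellular contigs at 0.05 and 20 — the two-cloud structure the classifier
  assumes. Overdispersion is the norm in real hit data, hence the NB family.
* **Abundance matrices** (`simulate_abundance_matrix()`) use a Gaussian
  copula with lognormal marginals; planted (virus, eukaryote) pairs get a
  latent correlation of the stated strength, so strength 1 yields identical
  sample ranks and strength 0 yields independence. The default design has 11
  samples, matching the scale of study this emulates.

Every stochastic operation takes an explicit seed and is bit-reproducible;
a run-level seed fans out to stages through a counter scheme (`fan_seed()`),
so no stage's draws depend on another's consumption of the stream.

What the generator does *not* emulate: read-level error, assembly graphs,
upstream tool idiosyncrasies, genome composition (shredded sequences are
uniform-random when sequences are requested at all), or realistic taxon
correlation structure beyond the planted pairs. Passing tests on synthetic
data therefore demonstrates that the *rules* are implemented exactly and
recover planted truth under the stated noise model — not that the operating
point (0.1, 1) is optimal for any particular real assembly, which depends on
the control database used for calibration.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; 1-based inclusive at file
  boundaries that conventionally use them (SAM, alignment tabular).
* Threshold comparisons at stated cutoffs are inclusive (`evalue <= 1e-10`,
  `identity >= 35`, copy mean `<= 1.1`), except where the rule is explicitly
  strict (the decision line, the `< 1%` constraint, `> 10 kb` covered,
  stringent-threshold selection).
* Genomes shorter than the minimum contig length shred to nothing, with a
  warning. Contigs too short to split detectably are skipped by the chimera
  planter. An empty second-match set falls back to the initial cutoff.
  A sample with zero total coverage among ≥ 10 kb scaffolds is an error, not
  a silent NaN row.
* Ranking ties (equal E-values) break by descending bit score then ORF id;
  all orderings are total, so every result is permutation-invariant.

## Problem sizes used in the test suite

The packaged checks run the classifier grid exactly (the full
$1001 \times 1001$ integer evidence grid), calibrate 50 random 500-record
control sets against a brute-force search, recover a 5% chimera rate planted
in 1000 contigs, compare the interval trimmer against a per-base oracle on
1000 random instances, and validate the quartile, Spearman and BH routines
against independent oracles on 1000 random inputs each. These sizes were
chosen as the smallest at which the checks are statistically meaningful
(binomial confidence intervals, law-of-large-numbers tolerances at
3 standard errors) while keeping the suite quick to run.

## Known limitations

* The package classifies and bookkeeps; it does not run assemblers, mappers,
  gene callers, profile or similarity searches, and it stops at exporting
  per-marker FASTA — alignment and tree inference are external.
* Taxonomy of cellular scaffolds and contamination flags (rRNA detection,
  endogenization scores, manual curation) are inputs, not computations.
* The cellular-match count depends on the upstream search tool's reporting
  limit; the per-ORF cap makes that dependence explicit but cannot remove it.
* With 11 samples, co-occurrence has limited power and monotone-association
  tests cannot distinguish direct virus–host interaction from shared
  environmental drivers; treat significant pairs as hypotheses.
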