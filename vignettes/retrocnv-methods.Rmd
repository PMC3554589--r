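---
title: "Detecting and testing retroCNVs: models, thresholds, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and testing retroCNVs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrocnv)
```

## The problem

Gene retrotransposition copies a spliced mRNA back into the genome,
creating an intron-less duplicate (a retrocopy) far from the parental
locus. Segregating retrocopies — retroCNVs — are a class of gene
copy-number polymorphism that read-depth CNV callers largely miss,
because the duplicated sequence is identical to the parental exons and
the insertion is typically short relative to array or depth windows.
This package detects retroCNVs from the mate-pair and split-evidence
signatures they leave in short-read data, genotypes them across
population cohorts, and asks whether individual insertions show
population-genetic evidence of positive selection.

## Detection model

Three evidence classes are implemented, each with the thresholds exposed
as arguments and defaulting to the published operating points.

**Reference-present retroCNVs** (deletion signature). For each
catalogued reference retrocopy, read pairs within 5 kb are scanned for
pairs that map further apart than the library concordance limit and
bracket the retrocopy without overlapping it. A call requires more than
five non-redundant pairs (`min_support = 6`), where non-redundancy is
keyed on `(start1, start2)` per sample — duplicate fragments from PCR or
optical artifacts collapse to one observation.

The concordance limit is `mean + 3·SD` of the fragment length fitted
from concordant pairs, not the bare mean: half of all concordant pairs
exceed the mean by construction, so the literal "greater than the
average insert size" rule would misclassify them. The multiplier `k = 3`
is configurable.

**Reference-absent retroCNVs** (insertion sites). Pairs with one read
entirely inside exonic sequence and the mate in a distinct region
(another chromosome, or beyond the concordance limit) are grouped by
their parental gene, and mate-side clusters (joining distance = the
concordance limit) become candidate insertion sites. The insertion point
is the midpoint between the innermost plus- and minus-strand mate edges.
Candidates are excluded when (a) within 2 kb of a known retrocopy, (b)
overlapping a repeat interval, (c) supported by five or fewer
non-redundant pairs, or (d) when clusters from two or more parental
genes coincide at one locus.

Per-gene clustering before exclusion is a deliberate design point. Reads
originating inside an inserted retrocopy map back to the parental exons,
so a pair wholly inside the insert appears as a discordant pair between
two exons of the parental gene — these artifact clusters sit at the
parental locus itself. They are removed first (reported as
`parental_locus` in the curation report), because a gene can never be
its own insertion site; only then is the two-gene ambiguity rule
applied, so an artifact cluster cannot shadow a genuine intronic
insertion in a neighbouring gene. All exclusions are machine-readable
curation-report rows rather than silent drops, replacing the manual
curation a human analyst would perform.

**Junction reads.** Reads that failed genomic mapping are aligned to
spliced transcript sequences (both orientations, mismatch-tolerant
full-length matching). A hit crossing an exon–exon junction records `l`
and `r`, the bases left and right of the junction, and is kept only if
its mismatch count is at most 4% of the read length *and* at most
`0.2·min(l, r)` — the second cap guards against short overhangs aligning
by chance. A gene is called retrotransposed when one read crosses a
junction by ≥ 10 bp, or two reads with distinct sequences each cross by
≥ 5 bp. Junctions whose 40-bp context matches the reference genome at
≥ 90% identity with ≥ 10 bp on both sides are disqualified (a genomic
read could mimic a junction read); a partial match spanning the junction
by `s < 10` bp raises both cutoffs by `s`, so a 7-bp spill yields 17 bp
(one read) and 12 bp (two reads). Hit discovery is pluggable: a
precomputed hit table can stand in for the built-in local aligner, which
requires a hit to cover at least half the context before it counts.

**Ascertainment control.** Because reference-present and
reference-absent retroCNVs are discovered in different sample sets,
frequency-sensitive contrasts can use `apply_discovery_ascertainment()`,
which re-imposes a single scheme: more than five supporting pairs in at
least one discovery genome, ignoring junction evidence entirely.

## Genotyping and allele frequencies

One supporting read or pair per evidence class suffices for a genotype:
presence and absence evidence together give a heterozygote, presence
alone a homozygote carrier, absence alone homozygous absent. When the
only presence evidence is junction reads the state is
`present_unknown_zygosity` — a first-class state rather than a logged
caveat, because junction reads cannot reveal the second chromosome; it
counts as a carrier wherever carrier status is all that matters, which
makes the zygosity-blind path produce exactly the same frequencies as
the standard path.

Low coverage undercalls heterozygotes, so frequencies are not taken from
genotype counts. Instead the carrier fraction `f` (any presence evidence
over any evidence) is converted assuming Hardy–Weinberg equilibrium:
`1 − f = q²`, hence `q = √(1 − f)` and `p = 1 − q`. Loci where every
genotyped individual is a carrier are flagged: their estimate `p = 1` is
a censoring artifact of a frequency merely approaching 1. The expected
number of copy-number differences between two random individuals is
`Σ 2pq` over loci. Before external phasing, junction evidence upgrades
pair-based homozygous-absent calls to heterozygous and fills
pair-less individuals with "present on one chromosome, other unknown".

## Selection tests

**π_der/π_anc.** At a located insertion with phased flanking SNPs
(±100 kb), haplotypes are split by the retroCNV allele and per-site
nucleotide diversity π is computed within each class over all non-focal
sites. A sweeping allele rises too fast to accumulate diversity on its
background, depressing the ratio. Because young alleles always carry
less diversity, the observed ratio is compared with frequency-matched
polymorphisms in neutral coalescent replicates with the same number of
chromosomes, the same number of segregating sites, a single flat
recombination rate, and the population's size history (a bottleneck
`(t = 0.05, x = 0.5), (t = 0.15, x = 1.5)` for the European/Asian
samples; a constant relative size of 1.5 for the African sample, in
units of 4N₀ generations). Every polymorphism in the medial 25% of each
replicate with the observed derived count contributes one null ratio;
the p-value is the fraction of pooled null ratios at or below the
observed one. Matching is exact derived-count equality by default, with
a ±`match_tol` relaxation for sparse counts. Null polymorphisms whose
ancestral class is monomorphic have no defined ratio; they are excluded
and counted.

The coalescent core (C++) simulates the ancestral recombination graph
under the piecewise size history with a fixed number of segregating
sites placed uniformly, one mutation per site dropped on that site's
marginal genealogy in proportion to branch length. Its site-frequency
spectrum was checked against per-tree-normalised branch-length spectra
from an independent coalescent implementation during development, and
the suite asserts the closed forms E[π per site] = 1/a_{n−1} and the
1/i spectrum shape.

Two numerical properties matter for interpretation. First, the null
ratio distribution has an atom at zero for rare alleles (a derived class
of two chromosomes is often monomorphic across the window), so p-values
are discrete there and the test is conservative for very rare focal
alleles. The calibration experiment in the test suite therefore draws
focal alleles at intermediate derived counts (between 10% and 90% of
chromosomes), the regime in which the test is actually applied — the
candidates worth testing are common enough to have at least two carriers
and two non-carriers, and the published candidates were at intermediate
to high frequency. Second, pooling matched polymorphisms across
replicates (rather than one indicator per replicate) uses all the null
information and is the package's reading of the published procedure; a
precomputed null table (`coalescent_null_ratios()`) can be shared across
many tests of the same configuration, which the calibration tests
exploit.

**Empirical percentile.** The observed ratio is also ranked against
ratios at comparison SNPs from non-overlapping 200-kb windows: at most
one SNP per window within 10 kb of the window centre and in the same 5%
derived-frequency bin, ties broken by position.

**iHS density.** Given a genome-wide table of per-SNP integrated
haplotype scores (scores are inputs, not computed here), the region
±50 kb is scored by the fraction of SNPs in the upper or lower 2.5%
tails, a two-cell χ² against the 5% expectation, and the fraction of
10,000 random length-matched regions (each required to contain a scored
SNP) with a larger χ². The two-cell χ² also grows under a *deficit* of
extreme scores, so the report carries the extreme fraction alongside the
statistic to disambiguate direction.

**Sweep generator.** The positive control conditions a structured
coalescent on a deterministic logistic trajectory for the focal allele
(strength `α = 2Ns`), with allelic classes as demes of sizes
proportional to `p(t)` and `1 − p(t)`; when the trajectory reaches the
origin the derived lineages coalesce and join the ancestral background.
Recombination is not modelled within the sweep genealogy — the generator
is a qualitative positive control, not an inference tool — and `α = 0`
delegates to the neutral simulator with a frequency-matched focal site
so the null reduction is exact.

## The synthetic-data generator

`simulate_reference_with_retrocopies()` builds a toy genome: two 40-kb
chromosomes, six five-exon genes (150-bp exons, 350-bp introns), two
fixed retrocopies, and three retroCNV events — one present in the
reference at allele frequency 0.5, two absent at frequency 0.3, one of
those inserted into an intron of another gene. The cohort is 20 diploid
individuals at 20× coverage with 100-bp reads and a 400 ± 50 bp fragment
library; each haplotype carries each event independently with
probability equal to the allele frequency, so truth genotypes are
Hardy–Weinberg draws. These sizes keep the full pipeline and test suite
desk-scale while leaving every threshold binding (the retrocopy length
of 750 bp exceeds the 550-bp concordance limit; exons exceed the read
length so junction crossings are frequent).

`simulate_cohort_reads()` emits reads the way a mapper would see them:
reads inside an inserted retrocopy map to the parental exons, reads
crossing an exon–exon junction or an insertion breakpoint become
unmapped FASTQ records, and reads spanning a deleted reference retrocopy
map with inflated separation. Mapped pairs are emitted as already-aligned
SAM records rather than raw reads needing an aligner, which keeps the
test suite free of mapper dependencies; junction reads are emitted
unmapped, matching how the detection path consumes them.

What the generator does *not* emulate: sequencing errors (mismatch
filters are exercised with explicitly mutated reads instead; a uniform
error flag is out of scope), multi-mapping ambiguity, target-site
duplications and polyA tails, chimeric library artifacts, and
chromosome-scale variation in recombination or repeat content. Passing
tests therefore demonstrate the correctness of the calling logic under
idealised mapping, not robustness to real-data artifacts; thresholds
inherited from the published method carry that robustness burden.

## Coordinates, formats, and other design decisions

- Internal coordinates are 1-based closed throughout, carried by
  `GRanges`; BED (0-based half-open) and GFF3 (1-based closed) are
  converted at the boundary by rtracklayer, and round-trip tests pin the
  conventions. This trades the spec-style half-open arithmetic for the
  native convention of the container library actually used.
- Exact contingency statistics use the standard implementations
  (`fisher.test`, `chisq.test`, `p.adjust`); the two-sided Fisher
  convention — summing point probabilities at or below the observed
  table's — reproduces all printed contrasts. The test suite verifies
  the implementation against an independent hypergeometric enumeration
  for every table with total count up to 30.
- The false-negative estimator converts a per-chromosome detection
  probability `d` (measured by re-detecting fixed retrocopies at a
  doubled support threshold, i.e. 12 pairs when discovery used 6) into
  `1 − (1 − d)^i` for `i` carrier chromosomes.
- "Mapped adjacently without gaps" in catalog construction is
  operationalised as consecutive aligned blocks separated by at most 20
  bp on the genome; candidate loci flagged by a pluggable
  genomic-duplication predicate (default: flank identity ≥ 90% over
  ±2 kb) are dropped. Minimum alignment identity defaults to 95%.
  Whether a partially aligned terminal exon "counts" is resolved as: an
  exon counts when at least one aligned base covers it.
- Reference-present discovery counts support per individual by default
  (a deletion genotype is an individual-level property); a pooled mode
  is available and is always used when attaching insertion sites to
  junction-only calls, where the paper's low-coverage genomes are merged.
- `ρ` scaling assumes N₀ = 10⁴ when converting genetic-map rates; the
  calibration experiments use ρ = 40 over the 200-kb window (1 cM/Mb
  scale), exposed as an argument everywhere.
- The chromosome-movement contrast treats `{chrX, X}` as the X class;
  Y never appears in the contrasts.

## Problem sizes in the tests

The suite runs the complete cohort analysis at the generator's default
scale (20 individuals, 20×), the coalescent calibration at n = 80
chromosomes and S = 200 sites with 500 replicates per demography against
a 500-replicate null pool, sweep power at n = 60 with 40 draws per arm,
the π oracle on 1,000 random 6×30 matrices, and the Fisher enumeration
on all ~45,000 tables with totals up to 30.

## Known limitations

- Junction-read alignment is exhaustive over transcripts and
  orientations; it is comfortable at toy scale but would need a seeded
  index for genome-scale transcript sets.
- The genotyper does not model mapping quality or base quality; with
  error-free simulated reads a single supporting pair is decisive, while
  real data would motivate the optional support thresholds.
- The coalescent p-value is conservative for very rare focal alleles
  (the zero atom discussed above); results for alleles with fewer than
  ~8 derived copies should be read as bounds.
- Outgroup polarisation (which allele is derived) is an input; the
  package trusts the supplied presence-is-derived flag rather than
  recomputing synteny.
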