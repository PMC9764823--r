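---
title: "RH-seq screen analysis with rhemiseq: model, parameters, and verification"
author: "rhemiseq maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RH-seq screen analysis with rhemiseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhemiseq)
```

## The experiment this package analyses

A reciprocal hemizygosity (RH) test asks whether the two parental alleles
of one gene differ in their phenotypic effect, on a controlled hybrid
background: two F1 hybrids are compared that are each hemizygous at the
gene, differing only in *which* parent's allele remains functional.
RH-seq scales this test genome-wide. Mos1 transposon mutagenesis of each
parental strain (here the *C. elegans* reference strain N2 and the wild
isolate ED3077), followed by crossing to the other wild-type parent,
yields pools of F1 hemizygotes in which each clone carries one disrupted
allele marked by its transposon insertion site. The pools develop with
and without a stressor (tunicamycin, an ER-stress-inducing
N-glycosylation inhibitor), and insertion-site sequencing reads out each
clone's abundance. For each gene, clones disrupted in the N2 allele
(leaving only the ED3077 copy functional) are compared with clones
disrupted in the ED3077 allele: a systematic abundance difference after
selection means the two alleles confer different fitness under the drug.

`rhemiseq` implements the computational side of such a screen: from raw
junction-sequencing FASTQ to per-gene statistics, plus a generative
simulator of the whole experiment used for verification.

## Read model and processing

Each single-end read is expected to follow the amplification-primer
architecture

```
[6 random nt][6-nt sample barcode][Mos1 3' tail][genomic flank][3' adapter...]
```

Processing (`processLibrary()`) is a deterministic chain:

1. **Adapter clipping** (`clipAdapter()`): if the 3' adapter occurs in the
   read it is truncated at the adapter's first occurrence; otherwise a
   read suffix equal to an adapter prefix of at least
   `adapterMinOverlap = 8` nt is removed. Matching is exact; the minimum
   overlap guards against chance 3'-end matches (an 8-mer matches by
   chance at rate 4^-8 per position).
2. **Prefix trim and demultiplexing** (`trimPrefixAndDemux()`): the first
   6 nt (PCR diversity bases) are discarded, not used for duplicate
   removal; the next 6 nt are matched against the sample sheet. Matching
   is exact by default (`barcodeMaxMismatch = 0`); Hamming-distance-1
   rescue is available but off, since with short barcodes a 1-mismatch
   rescue can silently cross-assign samples.
3. **Transposon-tag filter and flank excision** (`extractFlank()`): only
   reads containing the configured transposon tag exactly (zero
   mismatches) are kept, and everything 3' of the tag's first occurrence
   becomes the genomic flank. The default tag is the 26-nt Mos1 3'-tail
   segment of the amplification primer
   (`GATTTAAAAAAAACGACATTTCATAC`); `tagMatchLen` restricts matching to
   the tag's terminal bases for protocols that screen a different
   transposon-suffix length. A flank that itself still contains the tag
   indicates a tandem/chimeric amplification artifact and is rejected as
   `contaminated` rather than risking a wrong junction.
4. **Length filter** (`lengthFilter()`): flanks shorter than
   `minFlankLen = 30` nt are eliminated (a 30-nt flank is kept). Below
   ~30 nt, exact unique placement in a 100-Mb genome is not reliable.

Every input read lands in exactly one accounting category
(`kept`, `no_barcode`, `too_short`, `no_tag`, `contaminated`,
`short_flank`); the category totals always sum to the input count, which
the tests assert.

Base qualities are read and carried but never used: the decisive filter
is exact transposon-tag identity, and any sequencing error in tag or
flank makes the read fail the exact filters rather than mislead them.

## Genomes, mapping, and gene assignment

Reads from hemizygotes mutagenized in the reference parent map against
the reference genome; reads from the other parent map against a
**pseudogenome** (`buildPseudogenome()`): the reference with the
alternate allele substituted at every inter-strain SNP. Substitution
preserves chromosome names, lengths and coordinates (SNPs only, no
indels), so one gene annotation applies to both genomes and positions
from the two pools are directly comparable. SNPs are read from a VCF
(`readVcfSnps()`) keeping biallelic single-nucleotide rows with
`QUAL > 20` and combined depth strictly between 5 and 71 — the lower
bound removes poorly supported calls, the upper bound removes
repeat-inflated ones. Whether "combined depth" is INFO `DP` or the sum
of per-sample `DP` varies by caller, so the source is configurable
(`depthSource`, default: INFO if present).

The built-in mapper (`mapFlanks()`) places each flank by exact
full-length substring search over both strands and keeps it only if
there is exactly one hit genome-wide; zero hits is `unmapped`, two or
more is `multimapped` and discarded. Exact full-length matching mirrors
a 100%-identity alignment policy and is what makes "unique" a sharp
criterion; externally produced BLAT alignments can be imported instead
(`readPsl()` + `pslUniqueHits()`, with the same 100%-identity and
uniqueness rules). The **junction coordinate** is the genomic position
of the flank's first base in read orientation — alignment start on the
`+` strand, alignment end on the `-` strand. No universal convention
exists for which side of the insertion to name; this one is applied
consistently, and since insertion sites are compared only through the
100-bp collapsing window, only relative positions matter.

An insertion is **genic** when its junction lies inside a gene body
(`[start, end]` including introns; `assignGene()`). Insertions inside
several overlapping genes count for each of them by default (dropping
them would silently discard signal; `multi = FALSE` restricts to
unambiguous positions). A configurable exclusion list handles genes with
known annotation ambiguity.

## Collapsing and quantification

Reads mapping within `window = 100` bp of each other in one library are
taken to come from one transposon clone: `collapsePositions()` performs
single-linkage clustering on sorted positions — the only
order-independent reading of "within 100 bp of each other", so a chain
at 0/90/180 merges even though its ends are 180 bp apart. Each cluster
is reported at its **modal position** (the member position with the most
reads; ties break to the lowest coordinate, a deterministic and
documented choice) with the summed read count, conserving totals.

Clusters from different libraries of the same allele are unified into
one insertion when their modal positions fall within the same window
(`buildInsertionSet()`); reusing the clone-identity window for
cross-library matching is the minimal assumption. The result is an
`InsertionSet` (a `RangedSummarizedExperiment`): rows are insertions,
columns are libraries, with `counts` (absent observations recorded as 0)
and `abundance` assays. Abundances are counts divided by the library's
total uniquely mapped reads ("total reads in the sample" could also mean
all sequenced or all tag-passing reads; uniquely mapped is the default
because it is the denominator actually available to every downstream
quantity, and `libraryTotals` overrides it), times a `scale` factor
(default 1, a pure fraction; `1e6` gives counts-per-million).

## Per-insertion effects and the per-gene test

For each insertion and mutagenesis round in which it was detected, the
**tunicamycin effect** is

\[ e = \log_2\left(\frac{a_\mathrm{control}}{a_\mathrm{treatment}}\right) \]

with normalized abundances \(a\); positive values mean depletion under
the drug. When the raw count on either side is zero the corresponding
abundance is replaced by `pseudoAbundance` (default 1) before the ratio,
keeping it finite. A pseudo-abundance of 1 on a fractional abundance
scale is deliberately extreme — it pins never-detected observations to a
large sentinel value rather than interpolating them — and both the
pseudo-abundance and the normalization `scale` are exposed so users can
match them (e.g. `scale = 1e6` with pseudo-abundance 1 treats a zero as
"below one read per million"). Effects are averaged across the rounds in
which the insertion was observed (`averageAcrossRounds()`).

Per gene, the round-averaged effects of all insertions disrupting the A
allele are compared with those disrupting the B allele by a two-sample
two-tailed Mann-Whitney test (`mannWhitneyTest()`): U from rank sums
with midranks for ties; an exact p by exhaustive enumeration of all
`choose(n+m, n)` assignments when `n + m <= 10` without ties (exactness
is cheap exactly where insertion counts are small), otherwise a normal
approximation with tie correction and continuity correction. A gene is
tested only when **both** alleles have at least `minPerAllele = 2`
insertions — one insertion per side cannot support a rank test, and the
threshold is reported in the output metadata so the tested-gene universe
is explicit. Benjamini-Hochberg adjustment (`bhAdjust()`, delegating to
`stats::p.adjust`) is applied across all tested genes. The reported
`direction` names the allele whose disruption causes the stronger
depletion: hemizygotes left with only the other allele fare worse under
the drug, so the named allele is the resistance-promoting one. The
effect sign convention (control over treatment) is stated in the column
documentation to avoid orientation confusion with displays that plot the
inverse ratio.

## The simulator: what it emulates, and what it does not

`SimulationConfig()` + `simulateExperiment()` generate a complete
synthetic screen: a uniform-random genome split into equal chromosomes;
SNPs at `snpRate` per bp (default 1e-3, a realistic inter-strain SNP
density for *C. elegans* wild isolates); non-overlapping gene models
with random gaps; per-round, per-allele pools of planted insertions; and
raw FASTQ in the exact read architecture above, one multiplexed FASTQ
per parental allele with per-(round, condition) barcodes.

The abundance model: each insertion gets a log-normal clone-size factor
(`cloneSdLog = 0.5`; selfed mutant clones enter pools at unequal sizes,
and log-normal is the standard heavy-tailed choice — data-free, hence a
modeling decision), an expected control read count
`readsPerInsertion * factor`, and an expected treatment count multiplied
by the selection fold-change of the disrupted gene's allele (1 for
neutral genes and intergenic insertions). Observed counts are Poisson
(default) or negative binomial. Reads are emitted error-free by default
because the pipeline's tag and mapping filters are exact; decoy reads
(no tag / unknown barcode / sub-minimum flank) can be mixed in at
configured rates to exercise the accounting.

Default screen shape follows the study design this emulates: 12
mutagenesis rounds for the A-allele pools and 11 for the B-allele pools,
~500 insertions per round, ~100 reads per insertion. The default genome
is 5 Mb: planted junctions of one allele keep a minimum separation of
`2 * window + 1 = 201` bp so that distinct planted clones remain
distinguishable after 100-bp collapsing, and at the default insertion
density a smaller desk genome cannot host that separation. For
count-level statistical studies that never emit reads (no collapsing
involved), `minSeparation = 0` disables the constraint and the genome is
purely abstract.

What the simulator does **not** emulate: the wet-lab genetics (mating
efficiency, transposition kinetics, sorting), PCR duplicates and
amplification bias, sequencing errors (unless enabled as decoys),
structural variation between the parents (the pseudogenome is SNP-only),
and maternal or parent-of-origin effects. Passing the verification suite
therefore demonstrates correctness of the computation under the stated
generative model — not robustness to every artifact of real libraries.

## Verification studies and problem sizes

The test suite runs, among others, these end-to-end studies (sizes
chosen to keep a full run on one CPU in minutes):

* **Oracle equivalence** — the Mann-Whitney p agrees with independent
  exhaustive enumeration for every no-tie design with `n + m <= 10`; BH
  agrees with an independent step-up implementation on 1000 random
  vectors (lengths 1–500); collapsing agrees with a brute-force
  transitive-closure oracle on 1000 random position sets; the mapper
  agrees with a naive all-offsets both-strands scan on 1000 random
  flanks against a 100-kb two-chromosome genome with a planted duplicate
  block.
* **Pseudogenome** — after k random SNPs, the position-wise diff equals
  exactly the SNP set, and reverse substitution restores the reference
  byte-exactly.
* **End-to-end recovery** — on a 1-Mb, 2+2-round scenario with 250
  insertions/round, 250 reads/insertion and 30 genes under 2–4-fold
  allele-specific selection, the pipeline recovers 100% of planted
  junction positions exactly, with no spurious insertions, and the
  per-insertion measured effects regress on the planted log2
  fold-changes with slope within [0.9, 1.1].
* **Statistical calibration** — at count level on an abstract 20-Mb
  genome with 1000 equal 6-kb genes and the full 12+11 rounds (~15
  insertions per gene and allele), the fraction of null genes with
  p < 0.05 lies within [0.03, 0.07]; with 10 genes under 4-fold
  allele-specific selection, all 10 rank in the top 20 by p-value with
  the planted direction recovered.
* **Determinism** — identical configs and seeds give byte-identical
  result files.

`scripts/acceptance.R` re-runs the end-to-end and calibration studies
from scratch with a caller-supplied seed and writes the measured
quantities as JSON.

## Known limitations

* The exact mapper requires perfect full-length matches; reads spanning
  unannotated variants between the strains (or sequencing errors) are
  lost rather than placed approximately. The PSL import path exists for
  users who prefer a heuristic aligner's placements.
* Insertions are point junctions; the package does not model local
  realignment, strand-split calling, or PCR-duplicate structure.
* Round is treated as a replicate to average over, not as a random
  effect; with few rounds per insertion this is the conservative choice,
  and it matches the averaging the screen design implies.
* With the default fractional abundance scale, the pseudo-abundance
  sentinel of 1 dominates the effect of any zero observation; see the
  discussion above for how to choose compatible `scale` /
  `pseudoAbundance` pairs.
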