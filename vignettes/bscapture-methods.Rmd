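---
title: "Methods: bisulfite capture design, calling and allelic analysis"
author: "bscapture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bisulfite capture design, calling and allelic analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bscapture)
```

## The problem

In a convert-then-capture bisulfite assay, genomic DNA is bisulfite
converted *before* hybridization capture. Conversion deaminates
unmethylated cytosine to uracil (sequenced as T) while 5-methylcytosine
(5mC) and 5-hydroxymethylcytosine (5hmC) resist, so a fragment with $n$
potentially methylated cytosines can appear as any of $2^n$ converted
alleles per strand. Capture probes must therefore be designed against the
converted sequence space, not the reference. `bscapture` implements the
computational workflow around such an assay: probe design against the
converted genome, per-cytosine CG/CHG/CHH methylation calling with capture
QC metrics, bisulfite-informative SNP handling with parent-of-origin read
assignment in hybrids, TAB-seq 5hmC quantification, and methylation-based
classification of target regions between two genotypes — plus a
deterministic simulator supplying ground truth for all of it.

## In-silico conversion and cytosine contexts

`bs_convert()` applies the conversion rule to a strand's own 5'→3'
sequence: every C becomes T, except that under the "all CGs methylated"
assumption Cs immediately followed by G are preserved. CG dinucleotides
are strand-symmetric, so one canonical rule serves both strands; a
bottom-strand window is converted by reverse-complementing first
(`generate_candidates()` does this for bottom-strand probes). The rule is
idempotent, and under the no-methylation assumption the output contains no
C — both properties are exercised in the test suite.

Contexts follow the standard plant-genomics definitions (H = A, T or C):
CG if the next strand-aware base is G, CHG if the base after next is G,
CHH otherwise. Two situations the definitions leave open are handled
explicitly: sites whose context window runs off the contig end are
labelled `"edge"`, and windows containing N yield no call. Both are
excluded from summaries — an ambiguous context cannot be resolved, and
silently defaulting it to CHH would bias non-CG statistics. A single
downstream base suffices for CG.

For allele enumeration (`enumerate_alleles()`), "potentially methylated
cytosines" counts **all** strand cytosines by default, because non-CG
methylation is prevalent in the genomes this assay targets; a
`cg_only` mode is exposed for the mammalian-style reading since the choice
is genuinely open.

## Probe design

Probes of variable length (50–100 nt) are tiled every 5 bp across each
target, in four panels: top/bottom strand × all/no CG methylation.

* **Length policy.** The only stated probe property that length can tune
  is the melting temperature, so each candidate grows from its tiled start
  in 1 bp steps until the Tm of its *converted* sequence enters a band
  (default 68–73 °C), falling back to the length closest to the band
  center. The default Tm method is the GC-content formula
  $T_m = 64.9 + 41\,(n_{GC} - 16.4)/L$; a Wallace-rule alternative is
  selectable. Candidates stay inside their target, so targets shorter
  than the minimum length yield none (with a warning).
* **Repetitiveness.** A 15-mer frequency table is built from both strands
  of the fully converted genome (no CGs methylated). A probe's repeat
  score is the mean table count over its 15-mers; probes averaging above
  10 000 are removed (the cutoff is inclusive: exactly 10 000 survives).
  On desk-scale synthetic genomes this default can never fire, so tests
  scale the cutoff while pinning the default value itself.
* **Uniqueness.** Mapping locations are counted under bisulfite-asymmetric
  matching — probe T matches genome C or T, retained probe Cs must match
  C — implemented by turning probe Ts into the IUPAC code Y and scanning
  both orientations of every contig with `Biostrings::countPattern()`.
  Matching is exact by default with a configurable mismatch budget, which
  is appropriate at desk scale. Probes mapping to more than three
  locations are discarded.
* **Ranking and selection.** The rank score is a weighted sum (default
  unit weights) of min–max normalized components, all oriented
  lower-is-better: |Tm − 70.5|, repeat score, uniqueness, homopolymer
  score (the longest single-base run). Windows of 15 bp are placed
  left-to-right with 20 bp gaps, restarting at each target boundary; the
  best-ranked candidate per window wins, ties breaking to the lowest
  start, then the longest probe, so selection is fully deterministic.
  With 5 bp tiling each window evaluates exactly three candidate starts.

## Methylation calling and capture metrics

Reads enter in a tabular SAM-like dialect with true alignment coordinates
(alignment itself is out of scope; the simulator emits aligned reads). At
each covered strand-aware cytosine, read C (OT strand) or G (OB strand,
reference-forward) counts as methylated and T/A as unmethylated. Three
conventions matter:

* the first 2 sequenced bases of each mate are ignored (end-repair
  artifacts), honoring read orientation;
* positions covered by both mates of a pair are counted once;
* read bases other than the converted/unconverted pair (sequencing
  errors, SNPs) are ignored rather than counted unmethylated, which
  avoids SNP-induced deflation of levels.

PCR duplicates are defined by identity of coordinates, mate, bisulfite
strand *and* the within-read methylation pattern (pattern mode is the
default; coordinate-only mode reproduces the conventional definition).
Coverage statistics are computed over the union of target bases from
fragment-level intervals (mate overlaps clipped), including zero-depth
bases by default — the convention is exposed as a flag since either
reading is defensible. Fold enrichment uses the simplified base-ratio
definition (on-target aligned bases / target size) ÷ (total aligned bases
/ genome size) rather than the full hybrid-selection metric family.

The mixture-bias check mirrors mixing an untreated and a fully
CpG-methylated sample 50:50: per common site the expected mixture level is
the count-pooled level of the two pure samples, the expected histogram is
built analytically by propagating each pooled level through a binomial at
the mixture's observed depth (so both histograms carry the same sampling
spread), and the total variation distance between expected and observed
histograms is reported. The per-site expectations and depths are returned
so a caller can calibrate "within resampling error" by parametric
bootstrap, which is exactly what the tests do.

## SNPs and parent-of-origin assignment

De novo SNP candidates are retained at quality ≥ 20 and coverage ≤ 120;
SNPs within 20 bp of another retained SNP are then removed (inclusive
distance, both members of a close pair). The proximity step runs on the
quality/coverage-retained set, matching the stated order of operations.
Consensus SNPs are the intersection of a catalog list and the de novo
calls with order-insensitive allele agreement; conflicts are dropped with
a warning.

Conversion destroys some SNPs' information content: on OT reads a C/T SNP
collapses (C reads as C or T), on OB reads a G/A SNP does; all other
pairs remain informative, which the tests verify by enumerating converted
readouts of all 12 ordered allele pairs. A read is assigned to a parent
when strictly more than 60% of its informative SNPs agree — 60% exactly is
ambiguous; a single-SNP read is assigned directly (special handling is
described only for 0 and >1 SNPs); a SNP-free read adopts its mate's
parental verdict (`via_mate`), ambiguous mates do not propagate, and mates
with conflicting parental verdicts are both downgraded to ambiguous (a
case the source conventions leave open). Support is counted over
informative SNPs whose read base matches exactly one parent's readout;
bases matching neither (errors) are excluded.

## TAB-seq 5hmC

TAB-seq glucosylates 5hmC (protecting it) and Tet-oxidizes 5mC (removing
its protection), so the unconverted fraction of TAB-seq estimates 5hmC
directly and 5mC follows by subtraction from the standard-bisulfite
unconverted fraction. `hmc_quantify()` reports sites inside the targets
with TAB depth ≥ 10 (the filter is applied per cytosine, with the
per-region reading available by pre-aggregating, since the coarser
filter is ambiguous in the source conventions); negative 5mC estimates —
pure sampling noise — are clamped to 0 and flagged rather than dropped, so
downstream averages remain computable while the clamping stays visible.
Context is restricted to CG by default. Spike-in control contigs of known
state yield the conversion rate (unmethylated control), oxidation-plus-
conversion rate (5mC control) and protection rate (5hmC control).

## Region classification

Per-region, per-context levels are count-weighted
(Σ methylated / Σ total over the region's sites), and the coverage
fraction is the share of the region's reference context-cytosines seen by
at least one read — the source conventions say "read coverage of at least
85%" without defining the denominator, so this is pinned here. Two
genotypes' summaries are classified as:

| class | rule |
|---|---|
| `all_high` | Σ levels over 3 contexts × 2 genotypes ≥ 4.2 (0–6 scale), coverage ≥ 0.85 in both |
| `all_low` | every context < 0.05 in both (the "unmethylated" bound is unstated; 0.05 is configurable), coverage ≥ 0.90 |
| `context_dependent_X` | X above its threshold (CG > 0.95, CHG > 0.2, CHH > 0.75) in both, other contexts < 0.2 in both, coverage ≥ 0.80 |
| `dmr_X` | \|level difference\| ≥ 0.4 in context X (no numeric threshold is stated; 0.4 is configurable); labels may co-occur |

"At least" thresholds are inclusive and context thresholds strict, exactly
as stated. Inclusive comparisons on computed sums carry a 10⁻⁹ numeric
slack so that levels constructed to sit exactly on a boundary are not
misclassified by floating-point rounding. A pure-CHH class is permitted:
that none was observed in the motivating data is treated as an
observation, not a rule. Classification is symmetric in genotype order,
and `all_high`/`all_low` are mutually exclusive by construction.

## The simulator: what it emulates, and what it does not

The generator reproduces the study conditions end-to-end: fragments of
180–220 bp, 100 bp paired-end mates, bisulfite conversion efficiency
0.998 (unmethylated Cs fail to convert with probability 0.002), a mean
target depth of 30 by default, an unmethylated control contig standing in
for the chloroplast/lambda conversion control, bimodal CG and CHG
methylomes with low CHH levels (two-component Beta mixtures; CHH from a
single low-mean Beta), a diploid F1 with SNPs drawn per-bp (a
configurable fraction constrained to A/T pairs so informative SNPs exist
on both strands), TAB-seq chemistry with 5hmC protection and 5mC
oxidation plus the three spike-in control contigs, literal-copy PCR
duplicates at a configurable fraction, and an off-target fragment
fraction so on-target rate and fold enrichment are exercisable. All
randomness flows from a single seed and outputs are byte-identical across
runs.

On-target fragments are placed fully inside a target whenever the target
is at least one fragment long (otherwise they span it); this makes "reads
generated only from targets have on-target rate exactly 1" hold at the
read level, where a merely-overlapping fragment could leave one mate
entirely off-target.

What the simulator does **not** model: capture hybridization
thermodynamics and probe-affinity bias, PCR amplification bias beyond
literal duplicates, bisulfite degradation and fragment-length bias,
base-quality structure, alignment error (reads carry true coordinates),
and sequencing error by default (a substitution rate is available but off,
since no error model is stated). Passing parameter-recovery tests
therefore demonstrates the correctness of the calling arithmetic and its
statistical calibration under clean alignments — not robustness to
mapping artifacts or coverage bias in real libraries.

## Numerical and scale choices

Test and example problem sizes are chosen so the whole suite runs in
about a minute on one core: genomes of 5–50 kb, targets of 1–40 kb,
depths 10–100, around 10 000 reads for the assignment accuracy check.
These sizes leave every statistical check with comfortable power (site
counts in the hundreds to thousands) while keeping brute-force oracles —
full enumeration of conversion alleles, sliding-window mapping scans,
k-mer recounts — affordable. Recovery tests compare observed RMSE against
the binomial expectation at the realized per-site depths (factor-2 band
plus a small allowance for the 0.002 conversion-failure bias), and the
mixture check calibrates its distance against a parametric bootstrap of
its own null rather than a fixed magic number.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(genome_length = 20000, depth = 30, seed = 7)
genome <- make_genome(cfg)
methylome <- make_methylome(genome, seed = 7)
targets <- data.frame(contig = "chr1", start = c(2000, 8000),
                      end = c(5000, 11000))

sim <- simulate_bs_reads(genome, methylome, targets, cfg)
reads <- mark_duplicates(sim$reads, genome)
calls <- call_methylation(reads, genome)
capture_metrics(reads, targets, genome)

panel <- design_probes(genome, targets)
summarize_regions(calls, targets, genome)
```

## Known limitations

The uniqueness scan is exact-match by default (a mismatch budget exists
but is slow at genome scale); the Tm model is a composition formula, not
nearest-neighbor thermodynamics; duplicate marking operates per read row,
so a pair whose mates disagree in pattern can be flagged asymmetrically;
statistical DMR testing is deliberately absent (no test is defined for
the region taxonomy — the thresholds *are* the definition); and the
assignment of reads whose mates disagree is a pinned interpretation, not
a stated rule.
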