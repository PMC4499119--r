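# bscapture

Toolkit for **convert-then-capture bisulfite sequencing**: targeted DNA
methylation assays in which the library is bisulfite-converted *before*
hybridization capture. Conversion turns unmethylated cytosine into T
while 5mC/5hmC resist, so each fragment strand with *n* potentially
methylated cytosines can appear as any of 2ⁿ converted alleles — probe
design, alignment-downstream analysis and QC all have to work in that
converted sequence space. The package is aimed at epigenomics
methods developers and analysts who need the full computational workflow
of such an assay on controllable synthetic data.

What it implements:

* **Bisulfite-aware probe design** — variable-length (50–100 nt) probes
  tiled every 5 bp in four panels (top/bottom strand × all/no CG
  methylation), scored by melting temperature, repetitiveness against a
  15-mer table of the fully converted genome (mean frequency > 10 000
  removed), bisulfite-asymmetric mapping uniqueness (> 3 locations
  discarded) and homopolymer runs, then selected per 15 bp window at
  20 bp spacing by a composite rank score.
* **Methylation calling** — per-cytosine CG/CHG/CHH counts from aligned
  bisulfite reads with 5'-trim and mate-overlap conventions, duplicate
  marking by coordinates *plus* within-read methylation pattern, and
  capture QC: on-target rate (≥ 1 bp overlap, no padding), mean/median
  target coverage, fold enrichment, and a mixture-bias check.
* **Allelic analysis** — SNP filtering (quality ≥ 20, coverage ≤ 120,
  20 bp proximity), catalog∩de-novo consensus, bisulfite informativeness
  (C/T SNPs collapse on OT reads, G/A on OB), parent-of-origin read
  assignment under the strict > 60 % support rule with mate rescue, and
  per-parent methylation calling.
* **TAB-seq 5hmC** — 5hmC = TAB unconverted fraction, 5mC = BS − TAB,
  per-cytosine depth ≥ 10 inside targets, spike-in efficiency estimation.
* **Region classification** — the two-genotype taxonomy: `all_high`
  (summed level across contexts and genotypes ≥ 4.2, coverage ≥ 85 %),
  `all_low` (coverage ≥ 90 %), `context_dependent_{CG,CHG,CHH}`
  (CG > 0.95 / CHG > 0.2 / CHH > 0.75, others < 0.2, coverage ≥ 80 %),
  and per-context DMR labels.
* **A deterministic simulator** — diploid genomes with SNPs, bimodal
  CG/CHG methylomes, 180–220 bp fragments, 100 bp paired-end reads at
  99.8 % conversion efficiency, unmethylated control contig, TAB-seq
  chemistry with spike-ins, PCR duplicates and off-target fractions —
  all with recorded ground truth.

See `vignettes/bscapture-methods.Rmd` for the models, conventions and
design decisions.

## Worked example

```r
library(bscapture)

cfg       <- sim_config(genome_length = 20000, depth = 30, seed = 7)
genome    <- make_genome(cfg)
methylome <- make_methylome(genome, seed = 7)
targets   <- data.frame(contig = "chr1", start = c(2000, 8000),
                        end = c(5000, 11000))

sim   <- simulate_bs_reads(genome, methylome, targets, cfg)
reads <- mark_duplicates(sim$reads, genome)
calls <- call_methylation(reads, genome)

capture_metrics(reads, targets, genome)
#> $duplicate_rate : 0.000541   # chance coordinate+pattern collisions only
#> $on_target_rate : 1          # all fragments were placed inside targets
#> $mean_coverage  : 30.8       # matches the configured depth 30
#> $median_coverage: 32
#> $fold_enrichment: 4          # targets are 6 kb of a 24 kb genome + control

head(calls, 3)
#>   contig  pos strand context methylated unmethylated level
#> 1   chr1 2010      -     CHH          0            1   0.0
#> 2   chr1 2018      +     CHH          0            2   0.0
#> 3   chr1 2019      +     CHH          1            1   0.5

summarize_regions(calls, targets, genome)[, c("start", "end", "level_CG",
                                              "level_CHG", "level_CHH")]
#>   start   end  level_CG level_CHG  level_CHH
#> 1  2000  5000 0.6626720 0.4722935 0.09913966
#> 2  8000 11000 0.6477096 0.4577282 0.10437259
```

The region levels show the simulated methylome's signature: bimodal CG
(region average ≈ 0.66), intermediate CHG, low CHH (≈ 0.10). Per-cytosine
`level` is methylated/(methylated+unmethylated) over non-duplicate,
trimmed, overlap-clipped read bases.

Probe design on the same genome:

```r
panel <- design_probes(genome["chr1"], targets[1, ])
head(panel[, c("start", "end", "state", "length", "tm", "rank_score")], 2)
#>   start  end state length       tm rank_score
#> 1  2010 2091 top_M     81 68.24074  1.3812123
#> 2  2035 2098 top_M     63 68.54444  0.8896215
```

Probe lengths vary because each candidate grows until its converted-
sequence Tm enters the 68–73 °C band; starts advance 35 bp at a time
(15 bp selection window + 20 bp gap).

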