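# bindscape

Exhaustive relative binding-energy landscapes for transcription factors from
paired-end sequencing of a randomized-core dsDNA library.

## The problem

How strongly does a transcription factor (TF) bind *every possible* short DNA
sequence — not just its best sites? One answer: incubate the TF's DNA-binding
domain with a dsDNA pool whose central `n` bases (4–7) are fully randomized
between fixed flanks, separate the bound fraction, and sequence both the
input pool and the bound pool paired-end. Enrichment of a core sequence in
the bound pool measures its affinity, including moderate- and low-affinity
sites that motif-discovery assays miss.

`bindscape` is the analysis side of that assay, for bench scientists and
computational biologists alike: it turns the two FASTQ libraries into counts
over all 4^n core sequence types, relative binding energies, landscape
figures on a K-mer grid, and PWM sequence logos — plus a simulation module
for planning sequencing depth.

## The statistic

For core sequence type S_i with R_i reads in the input pool and B_i reads in
the bound pool,

    P(S_i)        = R_i / Σ_j R_j          (input proportion)
    P(S_i|bound)  = B_i / Σ_j B_j          (bound proportion)
    ΔΔG_i         = −log2( P(S_i|bound) / P(S_i) )

Lower ΔΔG = stronger binding; the scale is log2 (one unit = two-fold
enrichment, ≈ 0.411 kcal/mol at 298 K) and is defined up to an additive
constant set by pool composition. Before counting, read pairs must pass a
reverse-complement consistency filter: the core extracted from mate 2 must be
the exact reverse complement of the core from mate 1, which suppresses
sequencing errors.

## Worked example

Simulate an assay with a planted GAC core motif, then analyze it exactly as
real FASTQ libraries would be:

```r
library(bindscape)

design <- library_design("TTGGA", "CCAAT", n = 4)
truth  <- make_truth(design, motif_spec = list(core = "GAC"), seed = 1)
synth_fastq(truth, "input_R1.fastq", "input_R2.fastq",
            n_pairs = 2e5, pool = "input", seed = 2)
synth_fastq(truth, "bound_R1.fastq", "bound_R2.fastq",
            n_pairs = 2e5, pool = "bound", seed = 3)

input <- count_pool(design = design, pool = "input",
                    fastq1 = "input_R1.fastq", fastq2 = "input_R2.fastq")
bound <- count_pool(design = design, pool = "bound",
                    fastq1 = "bound_R1.fastq", fastq2 = "bound_R2.fastq")
input
#> count_table (input pool): n = 4, 256 types, 200000 kept / 200000 pairs

land <- relative_binding_energy(input, bound)
head(sort(land$ddg), 4)
#>       GACC       GACT       GACG       GGAC
#> -1.9280536 -1.4579682 -0.7088086 -0.4016755

select_high_affinity(land, cutoff = -1)
#> [1] "GACC" "GACT"

build_pwm(select_high_affinity(land, -1))
#> pwm: 4 columns from 2 sequences (uniform weights)
#>   consensus: GACC
#>   info (bits): 2.00 2.00 2.00 1.00

query_value(land, "GACC")
#>   sequence row col input_count bound_count  ddg_log2 minus_ddg
#> 1     GACC   8   3         591        2249 -1.928054  1.928054
```

The strongest binders are GACC and GACT (the planted preference order after
the core is C < T < G < A), only those two clear the −1 selection cutoff, and
the resulting logo reads GAC with a C/T split at the fourth position —
2 bits per fully determined column, 1 bit for the 50/50 column. At this depth
the estimated landscape correlates with the planted truth at Pearson
r = 0.915 (`compare_landscapes(land$ddg, truth$true_ddg)`); energies for
core-free sequences sit near 0.

`run_pipeline()` chains the same steps from a config (YAML or list) and also
writes landscape heatmaps/3-D bars on the K-mer grid with core highlighting,
a QC report and a run manifest. `inst/cli/bindscape.R` exposes each step as a
shell subcommand (`extract`, `energy`, `marginalize`, `logo`, `render`,
`simulate`, `depth`, `downsample`, `compare`, `query`).

## Depth planning

```r
tr <- make_truth(design, seed = 1, energy_range_kcal = c(0.5, 5))
depth_curve(tr, depths = c(1e3, 1e4, 1e5, 1e6), replicates = 5, seed = 9)
```

returns mean Pearson correlation between estimated and true energies per
depth; for n = 4 it approaches 1 by 1e6 read pairs per pool.
`sequencing_bases(1e5)` converts a read-pair budget into sequenced bases
(30 Mb for 100,000 PE150 pairs).

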