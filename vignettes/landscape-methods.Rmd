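---
title: "Methods: relative binding-energy landscapes from randomized-library sequencing"
author: "bindscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: relative binding-energy landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindscape)
```

## The assay and its model

A transcription factor's specificity can be profiled exhaustively by letting
the protein's DNA-binding domain select binders from a double-stranded DNA
pool in which `n` central bases (typically 4–7) are fully randomized between
fixed flanking sequences. Both the input pool and the protein-bound fraction
are sequenced paired-end; each fragment is read twice, once from each strand,
so the two mates of a clean pair carry reverse-complementary copies of the
same core.

For every core sequence type $S_i$ (there are $4^n$ of them), with $R_{S_i}$
reads in the input pool and $B_{S_i}$ reads in the bound pool, the proportions
are

$$P(S_i) = \frac{R_{S_i}}{\sum_j R_{S_j}}, \qquad
  P(S_i \mid \mathrm{bound}) = \frac{B_{S_i}}{\sum_j B_{S_j}},$$

and the **relative binding energy** is

$$\Delta\Delta G_{S_i} = -\log_2 \frac{P(S_i \mid \mathrm{bound})}{P(S_i)}.$$

Lower values mean stronger binding. Because both proportions are normalized
within their pool, the landscape is defined only up to an additive constant
set by overall pool composition; all comparisons the package makes (Pearson
correlation between replicates or proteins, selection relative to a cutoff)
are either offset-invariant or explicitly documented as cutoff-based. Under
equilibrium binding with the protein far from saturation, the enrichment
ratio is proportional to a Boltzmann factor, so $\Delta\Delta G$ in $\log_2$
units is an affinity scale: one unit is a two-fold enrichment change,
corresponding to $RT\ln 2 \approx 0.411$ kcal/mol at 298 K
(`kcal_to_log2()` / `log2_to_kcal()` convert, using RT = 0.593 kcal/mol). The
package deliberately estimates no absolute $K_d$ or $\Delta G$: concentrations
of free protein and free DNA are not observable from the two pools.

## Read processing

Cores are extracted by exact flank matching: the first occurrence of the left
flank, then the first occurrence of the right flank after it (mate 2 is
matched against the mirrored design, i.e. the reverse-complemented flanks in
swapped roles). A pair is kept only if both cores extract with the designed
length and plain A/C/G/T, and the mate-2 core is the reverse complement of
the mate-1 core. This pair-consistency filter is the assay's main guard
against sequencing error: a substitution in either mate almost surely breaks
the agreement. Discards are tallied by reason (`flank_not_found`,
`wrong_region_length`, `ambiguous_base`, `not_reverse_complement`) and the
invariant *kept + discarded = processed* holds on every input.

Decisions where the procedure is genuinely open, made once and fixed:

* **Exact flank matching by default.** A Hamming-tolerant option
  (`max_mismatch`) exists but is off: tolerant matching trades a small gain in
  yield for core-position ambiguity, and with ~30 nt constructs the flanks are
  long enough that exact matching keeps the vast majority of clean reads.
* **Cores containing N are discarded** (`ambiguous_base`) rather than
  imputed — the conservative choice for a counting estimator.
* **Types are counted in mate-1 orientation** and not collapsed with reverse
  complements, preserving all $4^n$ strand-oriented types; `collapse_rc`
  offers the collapsed view.
* **Base qualities are ignored**: the reverse-complement filter dominates any
  per-base quality filter for this construct, and no quality rule is part of
  the method. Qualities are retained in the FASTQ I/O layer for future use.

## Zero counts and the pseudocount policy

With finite depth some types can drop to zero in one pool. The default
(pseudocount 0) leaves $\Delta\Delta G$ **undefined (NA)** for such types:
the output never fabricates an energy for a type that was not observed.
An opt-in pseudocount (1 is a reasonable choice) replaces counts $c$ by
$c + \epsilon$ in both pools before normalization, defining every type at the
cost of shrinkage toward the flat landscape. All downstream operations
(selection, correlation, logos) work on the defined subset.

## The K-mer grid

To display all $4^k$ values at once, every length-$k$ sequence is mapped to a
unique cell of a $2^k \times 2^k$ grid by a recursive quadrant (chaos-game
style) rule: writing $s = s_1 \dots s_k$, base $s_i$ contributes its quadrant
bits scaled by $2^{k-i}$,

$$\mathrm{row}(s) = \sum_i \mathrm{rowbit}(s_i)\,2^{k-i}, \qquad
  \mathrm{col}(s) = \sum_i \mathrm{colbit}(s_i)\,2^{k-i},$$

with the default corner assignment A = (0,0), C = (0,1), G = (1,0),
T = (1,1). The map is a bijection, and all sequences sharing a length-$p$
prefix occupy one contiguous $2^{k-p} \times 2^{k-p}$ block — which is what
makes motif structure visible: every GAC-prefixed sequence falls in a single
corner block of the grid. The corner assignment and the 0-based,
row-0-at-top orientation are rendering conventions, stated so exports are
reproducible; `kmer_layout()` accepts any bijective base-to-corner map.
Figures (ggplot2 heatmaps or lattice 3-D bars) are always accompanied by a
sidecar TSV that is the bit-exact record of what was drawn; the figure is
never the source of truth.

## Motif summaries

Sequences with $\Delta\Delta G$ below a cutoff (default −1, i.e. at least
two-fold enriched over the pool) feed a position weight matrix: column
probabilities are base frequencies of the selected set (uniform weighting by
default — each selected sequence votes once; bound-count weighting is an
option), and the information content of column $j$ against the uniform
background is $2 + \sum_b p_{bj}\log_2 p_{bj}$ bits. `trim_logo()` drops
poorly informative positions by keeping the maximal contiguous run of columns
with at least `min_info` bits (default 0.2 bits, chosen to remove
near-background flanks while keeping weak but real preferences); the full
matrix is always retained alongside. The PWM is a summary of the selected
set, not the model — the landscape itself is the model-free object.

## The synthetic-data generator

The simulation module is first-class: it defines the conditions under which
the estimator is validated.

* **Input pool**: independent per-position base probabilities, default
  A = 0.27, C = 0.23, G = 0.20, T = 0.30 — a mild synthesis bias honoring the
  usage ordering T > A > C > G seen in randomized oligo pools; the exact
  values are configurable defaults, not measurements.
* **Bound pool**: Boltzmann-type reweighting
  $b_i \propto q_i\,2^{-\Delta\Delta G_i}$ of the input probabilities
  $q_i$, sampled multinomially at the requested depth. This is equilibrium
  selection only: wash kinetics, bead capture and PCR bias are deliberately
  not modeled. At infinite depth the estimator recovers
  $\Delta\Delta G_i + \log_2 \sum_j q_j 2^{-\Delta\Delta G_j}$ — truth up to
  the expected additive constant.
* **Energies**: either a planted core motif — core-containing sequences get
  `strong` (default −2) plus a graded offset by the base following the core,
  default C = 0, T = 0.4, G = 1.3, A = 1.7, so the preference order is
  C < T < G < A and only the C/T-followed core drops below the −1 cutoff,
  with end-anchored cores weak (offset `max(grading)`); or, for depth
  studies, energies drawn uniformly over 0.5–5 kcal/mol (≈1.2–12.2 log2
  units), the range a protein–DNA interaction plausibly spans from
  nonspecific to specific binding.
* **Reads**: mate 1 is flank + core + flank, mate 2 its exact reverse
  complement; iid substitution errors at `error_rate`; a `corrupt_pair_rate`
  fraction of pairs (exactly `round(rate * N)` of them, so planted rates are
  recovered exactly on clean reads) get one substituted mate-2 core base to
  exercise the pair filter. Output is byte-identical under a fixed seed.
* **Downsampling** is multivariate hypergeometric (without replacement), so a
  downsampled table is exactly a lower-depth sequencing of the same reads.

What passing these simulations does *not* show: robustness to PCR duplicates
and amplification bias, to position-dependent error profiles, or to partial
protein occupancy effects — none of which the generator emulates. The
simulations validate the estimator under the stated generative model, not the
wet-lab protocol.

## Sequencing-depth requirements

`depth_curve()` samples assays at increasing depth and scores the estimated
landscape against the truth with an offset-invariant metric (Pearson by
default; Spearman and a top-set rank accuracy are selectable, since
"accuracy" admits several reasonable definitions). For an $n = 4$ library
with energies spanning 0.5–5 kcal/mol, recovery is essentially perfect
(Pearson r > 0.99) at $10^6$ read pairs per pool and already high at $10^5$;
accuracy is non-decreasing in depth within replicate spread. As throughput
arithmetic, $10^5$ pairs on a PE150 platform occupy
$10^5 \times 300 = 30$ Mb. The package reports its own curve under its own
generative model; thresholds quoted for other depth-calculation procedures
are not reproduction targets. Default problem sizes in the test suite and
acceptance script (depths $10^3$–$10^6$, 5 replicates, $2\times10^5$
read pairs for end-to-end runs) were chosen as the smallest sizes at which
these statements are stable across seeds.

## Marginalizing (K+1)-mer landscapes to K-mers

To compare experiments across random-region lengths, a (K+1)-mer table pair
can be reduced to K-mers. The default scheme sums each (K+1)-mer's count into
its two length-K windows (prefix and suffix) in both pools and recomputes the
energy on the marginal tables — summing counts before taking ratios
propagates sampling weight correctly. Averaging (K+1)-mer energies over
windows is available as `scheme = "average"`.

One property deserves care. For a landscape whose (K+1)-mer energies depend
only on the first K bases (bound counts $C_B(xb) = r\,w(x)$ at uniform
input), *prefix-window* marginalization is exactly energy-preserving: the
marginal bound count is $4r\,w(u)$, so the K-mer energy equals the planted
energy up to one additive constant. Both-window marginalization is **not**
exact in this construction: the suffix windows contribute
$r\sum_a w(a\,u_{1..K-1})$, a term that varies with $u$, so recovery holds
only approximately. The package therefore exposes `windows =
c("both", "prefix", "suffix")`; "both" remains the default for real data
(where no window is privileged), and the exactness tests use
`windows = "prefix"`, the construction under which the property is provable.

## Numerical and degenerate-case choices

* Lexicographic ordering A < C < G < T fixes sequence indices and all TSV
  row orders; identical inputs give byte-identical outputs.
* Proportions must sum to 1 within 1e−9 (asserted in tests); energies are
  computed in double precision directly from the ratio, with no intermediate
  logs of counts.
* An all-zero table with pseudocount 0 is an error for `proportions()`; the
  pipeline instead reports it through the QC table and skips the landscape.
* An empty read stream yields a valid all-zero table with a warning;
  mismatched mate-stream lengths are a hard error.
* Degenerate truths (zero energy variance) make accuracy metrics undefined;
  `depth_curve()` warns and reports NA rather than a number.
* Correlation requires at least 3 shared defined sequences; fewer is an
  error, not an NA.
* PWM consensus ties resolve to the alphabetically first base; `trim_logo()`
  keeps the leftmost maximal run on ties.
* Seeds: every sampling operation takes an explicit `seed` and restores the
  caller's RNG state; derived child seeds stay below $2^{31}$.

## Known limitations

* Relative energies only; no absolute affinities.
* Flank matching assumes the designed construct; heavily degraded or
  adapter-contaminated reads should be cleaned upstream.
* The PWM is position-independent by construction and cannot represent
  dinucleotide dependencies; the landscape itself should be consulted for
  those.
* Simulated depth requirements transfer to real experiments only to the
  extent that the Boltzmann-reweighting model holds.
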