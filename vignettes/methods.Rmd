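---
title: "Methods: two-condition DMR calling with RdDM and expression integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-condition DMR calling with RdDM and expression integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rddmr)
```

# The problem

Plant genomes are methylated in three cytosine contexts — symmetric CG and
CHG, and asymmetric CHH (H = A, C or T) — maintained by distinct pathways;
de novo methylation in all contexts is guided by 24-nt siRNAs through
RNA-directed DNA methylation (RdDM). During processes such as fruit
ripening the methylome is remodelled: comparing two developmental states
with replicated WGBS, one wants the regions that change (DMRs), how
reproducible each change is, whether the changes concentrate near
transcription start sites, whether they coincide with 24-nt siRNA clusters
(the RdDM fingerprint), and which differentially expressed genes carry a
promoter methylation loss. `rddmr` implements that full chain plus a
synthetic-study generator with planted ground truth.

# The DMR caller

All counts are per-cytosine methylated reads `c` out of informative reads
`ct`; methylation levels are always *weighted*: `sum(c) / sum(ct)` over a
selection, never a mean of per-site ratios.

**Depth filter.** A cytosine enters the analysis only with `ct >= 4` in
every library (`min_depth`, default 4). We read "depth" as the per-row
informative read count; per-strand cytosines are never collapsed, since
coverage is reported per strand.

**DMCs.** Replicates are pooled per condition (counts added) and each
cytosine is tested with a two-sided Fisher exact test on
`[[c_A, ct_A - c_A], [c_B, ct_B - c_B]]`. The test is implemented in the
package as the sum of hypergeometric point probabilities not exceeding the
observed one (relative tolerance 1 + 1e-7 for ties), and is verified in the
test suite against exhaustive log-choose enumeration for *all* tables with
row margins up to 30. `p < 0.05` (`dmc_alpha`) defines a DMC.

**Window scan.** Windows of 200 bp advanced by 50 bp (`window`, `step`)
pool the depth-passing counts per context. Untested (empty) windows do not
enter the multiple-testing family. Benjamini–Hochberg adjustment is applied
genome-wide *within each context*: the procedure produces per-context
candidate lists, so per-context families are the natural reading; a global
family would only make the caller more conservative. `bh_adjust()` is the
explicit step-up implementation, checked against a sequential oracle and
`stats::p.adjust`. Windows with FDR < 0.05 (`fdr`) are candidates.

**Merge and shrink.** Candidates from all three contexts are unioned into
maximal regions. Book-ended windows (zero gap) merge; a gap of one base
separates. Each region is trimmed to `[first DMC, last DMC]` (1-based,
inclusive; the interval columns `start0`/`end` remain 0-based half-open)
and regions without DMCs are dropped. By construction no two DMRs overlap
and every DMR boundary is a DMC position — both are asserted as invariants
in the tests.

**Filters.** A region survives with `n_dmc > 3` and `|mean_diff| > 0.15`,
where `mean_diff` is the pooled weighted level difference (condition B −
condition A) over all depth-passing cytosines of all contexts in the
region. "Mean methylation difference" admits two readings (pooled counts
vs mean of per-cytosine differences); we pool counts, consistent with how
levels are computed everywhere else, and expose both gates as parameters.
`direction` is `hypo` when condition B (ripe) is lower.

**Robust index.** With two replicates, per-replicate fold changes over the
DMR are `FC_i = (level_B_i + eps) / (level_A_i + eps)` with `eps = 0.01`
(the substrate of the published fold change is not specified; a
pseudocount on weighted levels keeps logs finite at fully unmethylated
regions while perturbing typical levels by ≤ 1 %). Then

$$\mathrm{robust\ index} = \frac{|\log_2 FC_1 - \log_2 FC_2|}{|\log_2 FC_1 + \log_2 FC_2|}$$

0 means identical replicate responses; opposite-sign fold changes make the
denominator 0 and the index `NA`. DMRs where any library's mean depth over
the region is below 4 (echoing the DMC depth rule) are also `NA` — the
"low depth" threshold is not published, so it is a parameter
(`depth_floor`). Ranking is ascending, `NA` last, ties broken by the
smallest candidate-window FDR and then genomic order, so reports are
deterministic byte-for-byte.

# Genomic context

Gene association uses the strand-aware window `[TSS - 2 kb, TES + 2 kb]`
with ≥ 1 bp half-open overlap. Element classification assigns each DMR by
its midpoint with priority gene body > TSS-up-2 kb > TES-down-2 kb >
intergenic (a DMR can straddle classes; midpoint assignment keeps the
classes a partition), and the genome background applies the same priority
to every base. Random-region controls match the DMR length multiset
exactly, draw contigs proportionally to the number of valid start
positions, and are reproducible by seed. Metagene profiles bin 2-kb flanks
into fixed 100-bp bins and length-normalise bodies into 20 bins;
minus-strand features are reversed so profiles read 5'→3'. A feature
shorter than the bin count simply spreads its bases over the bins
(per-base scaling; no crash).

# siRNA and expression integration

Small-RNA records outside 18–30 nt are discarded before size histograms
and 5'-nucleotide composition (count-weighted; T and U are synonyms).
Abundances are reads-per-million of total cleaned reads. Clusters fully
contained in a TE body ≥ 4 kb (`min_te_len`, configurable; "long" is not
defined in the source procedure) are excluded from the canonical RdDM set;
partial overlaps are retained. DMR–cluster overlap is ≥ 1 bp, half-open,
and feeds the same Fisher enrichment machinery as the random-region
controls. Both all-cluster and canonical-only overlap modes are available
because the published 67 %/17 % figure does not say which set it used.

DEGs are classified at adjusted p < 0.01 with sign of log2 fold change;
a DEG is *hypomethylated* when a hypo-DMR overlaps its regulatory window.
GO enrichment uses the observed/expected ratio
`(k/n) / (K/N)` against the full annotated background (the background is
not specified in the source; all supplied genes is the least surprising
choice) and flags terms passing `|log2 fold| > 1` and `p < 0.05`. No
multiple-testing correction is applied by default, matching the stated
criteria; `adjust = TRUE` switches the gate to BH values.

# The synthetic world

`simulate_study()` generates, from one integer seed: an i.i.d. reference at
GC 0.4 with an unmethylated control contig playing the chloroplast's role
in conversion QC; a non-overlapping gene/TE annotation (gene density
1/6 kb, TE density 1/12 kb, TE widths up to 8 kb so "long TE" exclusion has
substrate); planted DMRs; four methylomes (2 conditions × 2 replicates);
siRNA clusters with per-sample RPM; a DEG table and a GO map; and truth
tables for all planted signal.

Sampling model per cytosine: depth ~ Poisson(10) per strand (zero-truncated
inside planted DMRs so planted signal is always observable); the replicate
methylation probability is Beta-distributed around its mean with
overdispersion ρ = 0.02 (replicates in the emulated study are highly
concordant; no replicate-noise model is published, so this is a package
choice); observed methylated counts are Binomial, with bisulfite
conversion failure 0.004 adding false methylation on unmethylated
cytosines. Context baselines are CG/CHG/CHH = 0.40/0.11/0.02 — the
emulated immature-fruit averages.

**Planted DMR model.** Hypomethylated DMRs are RdDM-target-like islands:
in the immature condition they are methylated at CG/CHG/CHH =
0.90/0.65/0.35 (`dmr_baseline_levels`, typical plant RdDM-target levels),
and the ripe condition subtracts `delta` (default 0.3) in every context.
This choice is deliberate: a region whose CHH baseline is 2 % cannot lose
30 percentage points, and planting a subtraction on genome-average
baselines caps the *pooled all-context* mean difference near 0.09 — below
the 0.15 DMR gate — because ~64 % of cytosines are CHH. Biologically, the
regions that lose methylation during ripening are exactly the highly
methylated RdDM targets, so elevated in-DMR baselines are the realistic
stated world, and they make the pooled difference equal `delta` by
construction. Hypermethylated DMRs start at the genome baselines and gain
`delta` (de novo methylation of previously unmethylated sequence). Planted
DMRs are 300–1500 bp (widths are not published), mutually ≥ 1 kb apart,
placed 60/20/20 % in promoters/gene bodies/intergenic space, and kept out
of TE bodies ≥ 4 kb so their siRNA clusters stay canonical.

**siRNA and DEG planting.** Exactly `round(frac_colocated × n_hypo)`
hypo-DMRs receive an overlapping cluster (centre strictly inside the DMR);
background clusters (density 1/7 kb) keep a 500 bp margin from all planted
DMRs, so the co-location fraction is exactly recoverable and random
regions hit clusters at the emergent ~17 % background rate. Co-located
clusters lose `fold_decrease` (default 4×) abundance in the ripe
condition, with 10 % lognormal per-sample noise. The DEG table contains
exactly `n_up + n_down` genes with adjusted p < 0.01; an exact
`frac_hypo_linked` of them are genes carrying a planted hypo-DMR, and
"unlinked" DEGs are drawn only from genes whose windows touch no planted
hypo-DMR, keeping truth labels clean. The GO map plants one term
(GO:0009718, anthocyanin-biosynthesis-like) in an exact 25 % of
hypo-linked up-DEGs over an exact 5 % background — 5× enrichment by
construction, so recovery is a property of the world rather than of a
lucky draw.

**What the generator does not emulate** — and hence what a green test does
not establish: read-level artefacts (mapping bias, PCR duplicates,
M-bias), non-uniform genome composition (real TE/gene clustering,
pericentromeres), correlated methylation along the chromosome outside
planted DMRs, partial-methylation mosaicism, and any coupling between
expression and methylation beyond the planted promoter links. Recovery
numbers on this world are upper bounds on real-data performance.

One stated-world tension is kept deliberately: with conversion failure
0.004 the expected conversion rate sits exactly at the 0.996 QC threshold,
so simulated libraries occasionally flag QC failure by sampling noise. Both
numbers are the emulated study's stated values; the flag is informational.

# Numerical choices and degenerate inputs

* Fisher ties use the conventional `(1 + 1e-7)` relative tolerance; the
  enumeration oracle in the tests applies the same rule, so agreement is
  exact to 1e-10.
* Degenerate 2×2 tables (an all-zero row or column margin) return p = 1;
  an all-zero table is an error.
* `weighted_methylation_level()` on an empty selection is an error, not 0.
* Windows shorter than the window size (contig end) are clipped; a contig
  shorter than one window forms a single clipped window.
* Robust index: denominator 0 with numerator 0 (identical fold changes of
  1) returns 0; denominator 0 otherwise returns `NA`.
* All interval logic is 0-based half-open internally (`start0`, `end`),
  per-cytosine positions 1-based; the converters live in one file and BED
  output is emitted directly from internal coordinates.

# Performance and scale

The caller is vectorised data.table work plus a deduplicated Fisher kernel
(identical count tables are tested once); a 2-Mb, 4-library study (~0.8 M
cytosines) simulates in ~4 s and calls in ~15 s on one core. The test
suite, including the 2-Mb recovery and null-calibration acceptance runs,
completes in about two minutes.

# Known limitations

* Only two replicates enter the robust index, as in the published formula;
  more replicates would need a generalised consistency score.
* The caller pools replicates for testing (as published); no
  beta-binomial/shrinkage test is provided, so replicate overdispersion
  beyond the depth floor is handled only by the robust-index ranking.
* siRNA cluster discovery is out of scope: clusters are consumed as
  intervals. `call_sirna_clusters_naive()` is a labelled convenience for
  synthetic pipelines, not a substitute for a dedicated cluster caller.
* GO enrichment does no term-graph propagation and, by default, no
  multiple-testing correction across terms (matching the stated criteria).
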