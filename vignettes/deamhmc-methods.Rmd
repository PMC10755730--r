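---
title: "Methods: base-resolution 5hmC calling from deaminase conversion sequencing"
author: "deamhmc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: base-resolution 5hmC calling from deaminase conversion sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deamhmc)
```

## The readout model

Single-step deaminase conversion sequencing maps 5-hydroxymethylcytosine
(5hmC) at base resolution using an engineered APOBEC3A (A3A) cytosine
deaminase. The enzyme deaminates cytosine (C, to uracil) and
5-methylcytosine (5mC, to thymine) on single-stranded DNA; after
amplification and sequencing both are read as T. 5hmC resists deamination
and is still read as C. Residual C in a read therefore marks a 5hmC site,
and the per-site C fraction `N_C / (N_C + N_T)` estimates the 5hmC
stoichiometry directly — no bisulfite, no glucosylation, no comparison of
paired libraries.

Everything in this package hangs off that readout model:

* the **simulator** applies the deamination probabilities once per
  molecule, per cytosine, on the molecule's own strand;
* the **aligner** works in the three-letter (C collapsed onto T) alphabet,
  because conversion destroys C/T identity;
* the **caller** tests whether the C readouts at a site exceed what
  residual non-conversion alone would produce.

A `DeaminationModel` stores P(deaminate | state, 5′ neighbor) as a 3 × 4
matrix. The two shipped enzymes are context-uniform — the engineered
variant shows no sequence-context bias — but the 5′-neighbor axis is kept
so partially biased variants (e.g. enzymes with residual TC/CC preference)
can be expressed. Default cells are the colony-sequencing conversion
rates: eA3A-v10 converts C at 99.92%, 5mC at 99.52% and 5hmC at only
0.16%; wild-type A3A converts C at 100.00%, 5mC at 99.68% and 5hmC at
80.71%, which is exactly why the wild type cannot support a direct 5hmC
readout.

## The synthetic world

The generators state a fixed world chosen once to match the statistical
structure the analysis assumes; none of these values is tuned against test
outcomes.

* **Genome**: GC fraction 0.42 and CpG enrichment 0.25 (mammalian genomes
  are CpG-depleted, observed/expected ≈ 0.2–0.25). Sequences come from a
  first-order model in which only the C→G transition deviates from
  independence; the binary "previous base is C" chain has geometric run
  lengths, which is what the vectorized sampler simulates.
* **Modifications**: each CpG cytosine (both strands) is independently
  5mC with probability 0.70 (typical somatic CpG methylation), 5hmC with
  probability 0.05, and unmodified otherwise; non-CpG cytosines carry
  5hmC at 10⁻⁴. The non-CpG rate places the CpG share of planted 5hmC
  near the ~96% observed in tissue. Planted sites are molecule-fraction
  1.0 — the map is binary; partial stoichiometry arises only in the
  amplicon mixture simulator.
* **Spike-ins**: a 5 kb fully unmodified lambda-like contig (true lambda
  is 48.5 kb; the stand-in is shortened for desk scale and is synthetic,
  not the lambda sequence) plus 367 bp all-5mC and all-5hmC amplicons
  matching the colony-sequencing substrate length. The real protocol adds
  spike-ins at ~0.1% mass; the simulator instead applies the same
  per-strand depth to every contig and controls spike-in mass through
  contig length — conversion-rate estimates depend only on observation
  counts, not on mass fraction.
* **Coverage**: reads are fixed-length single-end, placed uniformly, with
  the per-contig, per-strand read count Poisson(`mean_depth · L /
  read_len`); default 10× per strand, 100 bp reads. PCR duplication is
  not simulated (deamination acts once per molecule), sequencing error
  defaults to 0 to isolate the method's statistics (a uniform
  substitution rate is available), and qualities are constant Phred 40
  because the pipeline ignores them. 5fC/5caC are not simulated; their
  abundance is 2–3 orders of magnitude below 5hmC and their effect on the
  readout is negligible.

What a green simulation-based test does *not* establish: robustness to
real base-quality structure, PCR duplicates, mappability/repeat content of
a real genome, or strand-asymmetric library artifacts. The import path
(`readSiteCounts()`) exists so count tables from a production
trim/Bismark-style pipeline can feed the caller directly.

## Alignment and counting

The aligner is deliberately minimal: reads and reference are collapsed
C→T; the plus strand is indexed as converted forward sequence and the
minus strand as converted reverse complement; a 20 bp exact seed
(`Biostrings::PDict`) anchors each read and the full read is verified with
a bounded mismatch count (default 2). Reads with more than one equally
good locus are flagged non-unique and excluded from counting, mirroring
standard uniqueness hygiene. These defaults are this package's
documented choice, not inferred from any production aligner's settings.

Counting is strand-aware: a site row exists for each reference C (plus
strand) or G (minus strand), and only reads from the site's own strand
contribute — a minus-strand read over a plus-strand C shows the
complementary G and carries no conversion information (displayed in plus
orientation it would read C regardless of modification state, so
cross-strand counting would fabricate 5hmC signal). `N_other` counts
non-C/T readouts (sequencing error only) and is excluded from the
binomial; depth is `N_C + N_T`. Rows with zero depth are omitted.
Coordinates are 0-based half-open internally and in BED/bedGraph output.

## Spike-in calibration and the binomial null

Pooled conversion rates per spike-in class are read-level proportions
`ΣN_T / Σ(N_C + N_T)` (per-site medians are reported only as a
diagnostic). The caller's null parameter is

```
epsilon = max(1 − rate_unmodified, 1 − rate_all-5mC)
```

Both calibrations exist precisely because residual *unconverted 5mC* is
read as C exactly like 5hmC; taking the maximum is the conservative
choice when the two differ, and both single-class options remain
available by passing `epsilon` explicitly.

Each covered site is tested with the upper tail of the binomial,
`p = P(X ≥ N_C)` for `X ~ Binomial(N_C + N_T, epsilon)`, including the
observed count. Multiple-testing control is Benjamini–Hochberg step-up —
"q-value" without a named procedure is read as BH, which is standard and
directly testable; a Storey-style variant (π₀ estimated at λ = 0.5) is
available via `method = "storey"`. The BH family contains only sites
passing the depth filter (depth ≥ 5 by default); shallower sites keep
their p-value but carry `q = NA` and can never be high-confidence.
High-confidence means depth ≥ 5 and q < 0.01. Calling is per strand
(strand resolution is part of the assay); `mergeCpGStrands()` offers the
symmetric-CpG pooling as an explicit post-step.

## Genome summaries

`binSignal()` tiles contigs with fixed-width half-open bins (10 kb
default) and averages per-site fractions. With `high_conf_only = TRUE`
(default) non-high-confidence sites contribute a fraction of 0 but remain
in the denominator. This is a deliberate design decision: on a genome
whose true sites are molecule-fraction 1.0, averaging only the
significant sites would make every bin ≈ 1 and carry no information;
zero-filling the non-significant sites makes the bin value track the
density and level of confident 5hmC, which is what a binned comparison
between runs measures. Empty bins are excluded pairwise from the Pearson
correlation rather than zero-filled, because shared emptiness would
manufacture correlation.

Sequence context (CpG/CHG/CHH) is read 5′→3′ on the site's strand, with
NA at contig edges where the needed 3′ bases do not exist. Feature
assignment uses half-open intervals with an explicit, configurable
priority order (promoter > utr5 > exon > intron > utr3 by default; the
order is configuration, not an inference from any annotation tool);
unassigned sites are "intergenic" and proportions sum to 1. TSS
metaprofiles orient offsets by TSS strand (upstream negative) and average
fractions in fixed offset bins over all (TSS, site) pairs in the window.

## Kinetics

The deamination rate at substrate concentration [S] follows
Michaelis–Menten kinetics, `rate = k_cat [S] / (K_M + [S])`, and the
measured observable is the deaminated-product fraction
`I_D / (I_U + I_D) = rate · [E] · t`. `deaminationRate()` implements the
identity exactly as printed, and units are reported as printed (the
efficiency `k_cat/K_M` is in μM⁻¹ min⁻¹).

"Linear regression analysis of the Michaelis–Menten equation" is
implemented as the Lineweaver–Burk double-reciprocal fit (1/rate against
1/[S]; `K_M = slope/intercept`, `k_cat = 1/intercept`), with Hanes–Woolf
([S]/rate against [S]) behind a flag; the two agree exactly on noise-free
data, and the tests verify round-trip recovery to machine precision. A
non-positive linearization intercept marks the fit invalid rather than
returning negative constants. Constant rates across [S] are handled as
the saturation limit (K_M → 0, k_cat = rate, efficiency infinite).

Only the catalytic efficiencies are externally fixed constants (6.27 and
3.90 μM⁻¹ min⁻¹ for the engineered enzyme on C and 5mC; 90.82, 22.45 and
0.32 μM⁻¹ min⁻¹ for the wild type on C, 5mC and 5hmC). The shipped
(k_cat, K_M) split in `kineticDefaults()` is this package's choice: K_M
is placed inside each assay's substrate range (0.1–2.5 μM for C/5mC,
0.025–1.25 μM for 5hmC) so the linearization is well conditioned and the
noise-free observable stays strictly inside (0, 1) at the assay's enzyme
concentration and 5 min reaction time, and k_cat is the efficiency times
that K_M. The fitted efficiency is invariant to the split. The engineered
enzyme's activity on 5hmC is too low for kinetic constants, so that row
is deliberately absent.

The mixture experiment (amplicons mixed at theoretical 5hmC fractions
0–100%) has expected measured slope `conv_C + retention_5hmC − 1 =
0.9992 + 0.9984 − 1 = 0.9976` under the engineered-enzyme defaults; the
regression of measured `C/(C+T)` on the theoretical fraction is ordinary
least squares.

## Numerical and degenerate-input choices

* Contig-edge cytosines with no 5′ neighbor on their strand use the
  model row mean across contexts (identical to the cell value for the
  context-uniform defaults).
* All generators derive a 32-bit sub-seed per stage from the user seed,
  so stages are independently reproducible and FASTQ output is
  byte-identical for a fixed seed.
* `sitePValue` is vectorized `pbinom` upper tail; the test suite pins it
  to an independent `choose()`-sum enumeration to 10⁻¹² for all depths
  ≤ 12.
* Ties in p receive identical q (BH on sorted order is stable under
  ties); q is clipped to [0, 1].
* Zero-coverage amplicon sites are omitted with a warning; a zero-depth
  spike-in class is an error naming the class; correlation on fewer than
  3 shared non-empty bins or zero variance is an error rather than NaN.

## Known limitations

* The aligner assumes clean, indel-free, fixed-length reads; it is a
  stand-in for a production converted-genome aligner, not a replacement.
* No paired-end modeling, no adapter or insert-size simulation, no
  PCR-duplicate or overlapping-mate handling.
* No differential 5hmC between samples, and no 5mC calling — 5mC and C
  are indistinguishable by design in this assay.
* The synthetic genome has homogeneous composition; repeat-driven
  multi-mapping is essentially absent, so the non-unique-read path is
  exercised by construction in tests rather than at realistic rates.
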