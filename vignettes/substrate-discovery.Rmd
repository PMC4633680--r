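---
title: "Dual-branch label-free quantification for E3 ligase substrate discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-branch label-free quantification for E3 ligase substrate discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(e3lfq)
```

## The screening problem

An E3 ubiquitin ligase confers substrate specificity on the
ubiquitin–proteasome system: its substrates are ubiquitylated and degraded in
cells where the ligase is active, and accumulate when the ligase is knocked
out. Comparing the knockout (KO) and wild-type (WT) proteomes by shotgun
label-free quantification therefore turns substrate discovery into a
differential-abundance screen — with the twist that label-free quantitation
is noisy enough that any single software stack produces false positives. The
design implemented here reduces that risk by running **two independent
protein-quantitation branches** on the same peptide-ion evidence and
nominating only proteins that accumulate in the knockout according to
**both**.

The package operates downstream of identification and XIC extraction: its
input is a table of peptide ions (protein accession, peptide sequence,
charge, m/z, retention time) with one integrated XIC area per LC-MS run,
plus a run-to-genotype design. Raw-file processing, database search and FDR
control are out of scope.

## Pipeline model

Write $I_{pjr}$ for the XIC area of peptide ion $j$ of protein $p$ in run
$r$. The pipeline is:

1. **Median-of-ratios normalization.** For each run $r$ and a reference run
   $\rho$ (by default the run with the most quantified ions, ties broken by
   run id), the scale factor is
   $f_r = 1 / \operatorname{median}_j\, (I_{jr} / I_{j\rho})$
   over ions observed in both runs, and every cell of run $r$ is multiplied
   by $f_r$. Ratios are taken on raw intensities; the median is the standard
   midpoint convention for even counts. The median is taken over
   shared-observed ions (present in both runs), the defensible reading when
   identities are carried in the table. After normalization the median
   shared-ion ratio of every run to the reference is exactly 1, and an
   injected per-run loading bias is removed exactly in the noise-free limit.
   Missing cells are never imputed.

2. **Branch A — Top-3 protein abundance index (PAI).** Per protein, the at
   most three peptide ions with the highest mean intensity across runs
   (observed cells only) are fixed as reference peptides — the same set for
   every run, ties broken deterministically by the smaller
   (protein, peptide, charge) key — and the per-run PAI is the arithmetic
   mean of their observed areas in that run. One- and two-peptide proteins
   use whatever is available. "Highest across samples" is operationalized as
   the highest *mean over observed runs* rather than the sum, so a peptide
   missed in one run is not penalized for its missingness. PAI is computed
   on the normalized matrix (normalization precedes roll-up).

3. **Branch B — pairwise-ratio least-squares LFQ profiles.** For every run
   pair $(a,b)$ sharing at least one peptide of protein $p$, the
   protein-level ratio is
   $r_{ab} = \operatorname{median}_j \log_2 (I_{ja} / I_{jb})$;
   the per-run log2 abundances $x$ solve
   $\min_x \sum_{(a,b)} (x_a - x_b - r_{ab})^2$
   (each supported pair weighted equally), with the free additive constant
   fixed so the summed linear abundance equals the protein's summed observed
   intensity. The normal equations are the graph Laplacian of the supported
   run pairs; a disconnected run graph is profiled only on its largest
   connected component, with the other runs left missing and a warning. This
   branch runs on the raw matrix; its protein table is then normalized by
   equalizing per-run medians against the grand median of run medians. The
   branch is restricted to unique peptides — the simulator assigns every
   peptide to one protein, so razor-peptide bookkeeping is unnecessary — and
   a single shared peptide suffices to support a run pair; both are artifact
   choices, since the screen needs an independent second estimator rather
   than a re-implementation of any particular software.

4. **Quantifiability filters.** Per branch, only proteins quantified by at
   least 2 peptides and with an abundance in every run are tested. The
   completeness rule is why missingness is modelled but never imputed:
   incomplete proteins simply leave the differential analysis (and the
   missingness default is MCAR for the same reason — the filter discards
   intensity-dependent dropout before it can bias the tested set; a
   left-censored mode is available for sensitivity analysis).

5. **Per-protein test.** Log2 fold change is
   $\overline{\log_2 \mathrm{KO}} - \overline{\log_2 \mathrm{WT}}$, tested
   with Welch's unequal-variance two-sided t-test on log2 abundances
   (volcano axes are log2 ratios, so testing on the log scale is the
   coherent choice; a pooled-variance option exists behind
   `var_equal = TRUE`). Zero-variance degenerate groups follow a fixed
   convention: p = 1 when the group means are equal, p = the smallest
   positive double when they differ. A protein is flagged when
   $|\log_2 \mathrm{FC}| > 0.85$ — since $2^{0.85} \approx 1.80$, this is
   the "over 1.8-fold" rule — and p < 0.05 (raw; a Benjamini–Hochberg column
   is emitted for information only and never used in calling, matching the
   screening convention). The down-regulated threshold is the symmetric
   $-0.85$.

6. **Candidate call.** A substrate candidate must pass filters, fold-change
   and p-value cutoffs in *both* branches with a *positive* log2 fold change
   in both — accumulation in the knockout is the substrate signature;
   proteins depleted in the KO are reported in an informational section but
   never called. QC accompanies the call: Venn counts of quantifiable
   proteins per branch, within-genotype Pearson correlations of log2
   abundances per run pair (computed over proteins complete in the pair;
   pairs sharing fewer than 3 proteins are left missing with a warning), and
   detection of condition-absent markers — proteins with at least one
   quantified peptide in every run of one condition and none in any run of
   the other (the knocked-out gene product itself is the canonical case;
   the rule is strict on purpose, so a protein missing in only some runs of
   a condition is not mistaken for a knockout marker).

## What the simulator emulates

`generator_config()` describes a 3-vs-3 bottom-up LFQ experiment through the
standard abstraction: log-normal protein abundances (defaults: natural-log
mean `log(1e7)`, sd 1.5 — XIC areas spanning roughly four orders of
magnitude), a fixed per-peptide response factor (log-sd 1.0) capturing
ionization differences between peptides, per-run loading biases drawn
log-uniformly from [0.5, 2], and unit-mean log-normal technical noise.
Defaults: 2,000 background proteins with 2–12 peptides each, two spiked
substrates at linear fold changes 7.10 and 5.90 (filamin-sized effects,
assigned 12 peptides each — filamins are very large proteins with high
peptide yields), and one KO-absent marker protein (5 peptides, encoded as
missing cells in every KO run; zero is reserved for display, absence is
always `NA` in the ion table). Missingness is MCAR at 5% by default.

The technical CV default of 0.20 is a tuning constant — a typical label-free
technical variability — not a measured value; under it, within-genotype
replicate correlations of normalized protein abundances come out around
0.99, comfortably at or above the 0.95 floor expected of a reproducible
label-free experiment. Because the generator has no separate
biological-variance component, replicate scatter is purely technical; real
biological triplicates would be noisier, so recovery rates measured on the
simulator are an upper bound on real-data sensitivity, not an estimate of
it. Other real-data features deliberately not emulated: shared/razor
peptides, retention-time drift, charge-state envelopes, interference and
co-elution, and intensity-dependent detection limits (unless the censored
missingness mode is switched on).

Determinism: the full dataset is bit-identical for a fixed config and seed,
and the RNG is consumed identically whatever the scale factors, so
equivariance properties (doubling one run's loading doubles exactly that
column) hold draw-for-draw.

## Worked example

```{r example}
cfg <- generator_config(seed = 1)
report <- run_pipeline(config = cfg)
report
```

The two candidates are the spiked substrates, recovered with per-branch
log2 fold changes near the ground truth (log2 7.10 = 2.83, log2 5.90 =
2.56), and the KO-absent marker is surfaced by QC with zero attributed
peptides in the knockout.

```{r truth}
subset(report$truth, true_log2_fc != 0 | is_absent_marker)
```

## Numerical and design notes

- **Problem sizes.** Package tests exercise the default 2,000-protein,
  3-vs-3 configuration for calibration checks and 100-seed sweeps for
  recovery rates; module-level tests use 150-protein configurations, which
  are ample for the properties they probe.
- **Welch at n = 3.** With three replicates per group the Welch test is
  conservative: its true type-I error at nominal 0.05 is about 0.035 under
  equal variances (the Welch–Satterthwaite degrees of freedom drop below the
  pooled 4). The pooled t-test is exact there and available via
  `var_equal = TRUE`; Welch remains the default because it is robust to the
  unequal group variances that knockout comparisons can produce, and a
  conservative screen errs in the safe direction.
- **Ties and determinism.** Reference-peptide ties break on the ion key;
  the auto reference run breaks ties lexicographically; candidate lists are
  sorted by the weaker branch's fold change. Re-running a seeded pipeline
  writes byte-identical reports.
- **Degenerate inputs.** Zero intensities are rejected on input (absence is
  missing, not zero); proteins observed in a single run yield missing LFQ
  profiles rather than invented values; empty tables filter to empty tables.
- **Limitations.** No protein inference from shared peptides, no
  moderated-variance testing, no permutation FDR, no spectrum-level
  processing. The candidate call is designed for a two-branch intersection
  at raw p < 0.05; with thousands of tested proteins it controls false
  candidates through the intersection and the fold-change cutoff, not
  through multiplicity correction.
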