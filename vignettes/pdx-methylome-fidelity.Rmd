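---
title: "Assessing methylome fidelity in patient-derived xenografts"
author: "pdxmeth authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing methylome fidelity in patient-derived xenografts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdxmeth)
```

## The problem

Patient-derived tumour xenografts (PDXs) — human tumour fragments grown
subcutaneously in immunodeficient mice — are a mainstay of preclinical
oncology, but they are only useful as patient surrogates to the extent that
they preserve the molecular state of the original tumour. For DNA
methylation measured on Infinium 450K-style arrays, two confounders
complicate that question: contaminating host (mouse) DNA can
cross-hybridise to a subset of probes, and a tumour-specific minority of
CpG sites genuinely changes methylation state during engraftment. pdxmeth
implements the analysis framework for this setting: probe-level quality
control with host-genome masking, a calibrated "reversed methylation"
statistic on per-probe beta-value differences, resampling tests for where
in the (epi)genome the changing probes fall and how strongly they recur
across samples, a keep/discard rule for sequencing reads aligned against
both genomes, and a perturb-and-test simulation that converts the observed
per-sample change rate into a sample-size recommendation for two-group PDX
studies.

Everything operates on plain beta-value matrices (methylated signal
fraction per probe and sample, in [0, 1]); array preprocessing and
normalisation (IDAT handling, BMIQ and similar) are upstream of this
package, and enrichment-based sequencing analyses (DMR calling) enter only
as externally produced region sets.

## The reversed-methylation statistic

For a patient tumour P and its xenograft X the per-probe difference is

> delta-beta = beta(P) − beta(X),  in [−1, 1],

computed on the QC-retained probe set only (`delta_beta()`; the sign
convention is fixed as patient minus xenograft and swapping the samples
negates the vector). A probe is counted as *reversing* its methylation
state when |delta-beta| meets or exceeds a threshold interpretable as a
switch between the fully unmethylated and fully methylated states. The
threshold comes from reference bounds on the two states: 95% of fully
unmethylated probes sit at beta ≤ 0.31 while fully methylated probes sit
at beta ≥ 0.82, so the smallest difference compatible with a full state
change is

> 0.82 − 0.31 = 0.51.

`reversal_threshold()` encodes these fixed bounds; `calibrate_threshold()`
recomputes them from user-supplied reference distributions using
nearest-rank (type-1) quantiles — chosen because they are unambiguous on
small vectors and directly checkable by sorting. The boundary is inclusive
(a change of exactly 0.51 counts), and all percentages use the QC-retained
probe count as denominator, never the raw array size. Degenerate
calibrations (methylated bound not above the unmethylated bound) are
errors rather than silently producing a non-positive threshold.

`threshold_sensitivity()` reports the mean changing-probe percentage over
a grid of thresholds (default 0.51, 0.41, 0.31, 0.21) with the standard
error of the mean across pairs, since the changing fraction necessarily
grows as the threshold drops. `substitute_concordance()` supports the
substitute-tumour question — can a xenograft stand in for its patient in
an *inter*-tumour comparison? — via the per-probe difference of absolute
differences, ddb = |delta-beta(ref)| − |delta-beta(test)|, summarised as
the fraction of probes with |ddb| below a tolerance. No field-standard
tolerance exists for "close to zero", so the default (0.1) is an explicit,
configurable package choice.

## Probe quality control

`apply_qc()` applies four removal rules in a fixed order and attributes
each removed probe to the first rule that claims it, so the per-rule sets
plus the retained set always partition the input universe, while the
retained set itself is order-invariant:

1. **Detection**: a probe fails when any sample has detection p ≥ 0.01.
   "Detected" means p strictly below the cutoff; the tie (p = 0.01) counts
   as failing, the common array-QC convention. The boundary behaviour is
   documented because the opposite choice silently changes retained
   counts.
2. **Beads**: fewer than 3 beads in at least 5% of samples (inclusive at
   the 5% boundary). The bead rule is stated in the literature simply as a
   "bead cutoff of 0.05"; this package adopts the ChAMP reading of that
   number as a sample-fraction tolerance.
3. **Sex chromosomes**: chrX/chrY probes from the manifest.
4. **Mouse mask**: probes with detection p < 0.01 in a single host-tissue
   (mouse) sample hybridise to host DNA and are removed from all
   xenograft analyses. Here the tie counts as *not* detected, i.e. the
   probe is kept — the mask removes only probes positively detected in
   mouse.

Tightening the detection cutoff or the bead sample fraction can only
shrink the retained set, and re-applying QC to its own output removes
nothing; both properties are asserted in the test suite.

## Resampling enrichment and overlap tests

Each probe's genomic feature (TSS1500, TSS200, 5'UTR, 1st exon, body,
3'UTR, intergenic) and CpG-island relation (island, shore, shelf, open
sea) combine into a single category, so the retained universe is
partitioned. `resampling_enrichment()` compares a target set's category
composition against draws of the same size taken uniformly without
replacement from the universe (default 1,000 repetitions). The empirical
p-value uses the add-one estimator (r + 1)/(n_reps + 1) per tail, doubled
and capped at 1 — it can never be zero, and its floor 1/(n_reps + 1)
matches how resampling p-values below the resolution of the repetition
count are conventionally reported as "< 1/n_reps". Enrichment p-values
are two-sided (depletion at promoters/islands is as informative as
enrichment in intergenic regions); whether one- or two-sided testing was
used in prior analyses of this kind is not documented, so the choice is
stated here rather than inferred. Probes without manifest annotation are
excluded from both target and universe with a logged count.

`overlap_significance()` tests whether several samples' changing-probe
sets share more probes than chance: the null redraws each set at its own
size uniformly from the universe and records the intersection size. The
alternative null — conditioning on the observed sets and permuting only
one — was rejected as less symmetric; with sets that are themselves
random draws the redrawn null matches an exhaustive hypergeometric
enumeration on toy universes, which the test suite checks.
`overlap_percentages()` reports pairwise and full intersections using one
denominator, the smallest set, so 100% means "everything called by the
most conservative sample recurs elsewhere".

## Xenograft read filtering

For sequencing assays, reads are aligned separately against the graft
(human) and host (mouse) genomes and classified per name-matched pair:
human-only, mouse-only, both, neither. The keep rule retains human-only
and both; mouse-only pairs are host contamination. Pairs aligning to
neither genome are discarded — they carry no usable signal — a decision
this package documents as its own, since published keep rules enumerate
only the kept classes. "Aligned" requires, by default, both mates mapped
as primary alignments and flagged properly paired (`mate_mode = "strict"`;
`"any"` accepts a single mapped mate). Duplicate-flagged and mate-less
pairs are removed before classification; duplicate marking is trusted
from the SAM flags because deduplication belongs to the alignment
pipeline. No mapping-quality threshold is applied by default.
`keepset_concordance()` quantifies agreement with an alternative
classifier (e.g. a k-mer-based xenograft tool) as Jaccard overlap plus
both containment fractions.

## The sample-size simulation

The question: if every tumour acquires major methylation changes at a
tumour-specific ~2.7% of probes during engraftment, how many samples per
group does a two-group PDX comparison need before those idiosyncratic
changes stop contaminating group-level differences? The model
(`run_simulation()`):

- draw n methylomes from a pool;
- independently in each sample, shift 11,110 probe beta-values by 0.51 —
  5,555 up and 5,555 down, emulating the observed per-sample rate of
  major changes with a direction split that keeps the genome-wide mean
  unchanged;
- test every probe between the original n samples and their modified
  counterparts with a two-sided Wilcoxon rank-sum test;
- count probes with non-adjusted p ≤ 0.05 (inclusive; no multiple-testing
  correction, so the result applies to studies using any probe subset);
- repeat 5 times per group size over n = 5…50 and report mean ± SEM.

Two design points deserve emphasis. First, perturbed probe sets are drawn
independently per sample: the changes are tumour-specific, so no shared
target set exists to predict. A shared set would make every perturbed
probe trivially significant at moderate n and contradict the observed
small counts — the per-sample reading is the only one consistent with the
phenomenon being modelled. Second, shifts are applied only where the full
±0.51 fits inside [0, 1] (up-shifts where beta ≤ 0.49, down-shifts where
beta ≥ 0.51). Post-hoc clipping would silently shrink shifts exactly
where most beta-values live, at the bimodal extremes, breaking the
"5,555 of each" magnitude contract; a `clip` mode exists for sensitivity
analysis. How boundary values were handled in the original formulation is
undocumented, so the feasibility rule is this package's explicit choice.

Per-probe testing uses a compiled row-wise rank-sum kernel (tie-corrected
normal approximation with continuity correction, identical to
`wilcox.test(exact = FALSE, correct = TRUE)` and unit-tested against it),
because hundreds of thousands of probes are tested per repetition and no
vectorised per-row implementation was available; the scalar
`rank_sum_pvalue()` switches to the exact enumeration distribution when
the combined group size is at most 20 with no ties. Probes perturbed in
zero samples are skipped without testing — their groups are identical and
their p-value is exactly 1 — which is an exact shortcut, not an
approximation. With zero perturbations the significant count is therefore
exactly 0 at every n.

### Problem sizes

`power_study()` evaluates the grid in two tiers chosen by computational
cost: group sizes 5–15 run at the full 463,558-probe universe (the
region where significant counts peak and repetitions are cheapest), and
16–50 on a 50,000-probe universe with the perturbation count scaled by
the probe ratio and counts rescaled back (`scale_sim_config()`); because
probes are tested independently, expected counts scale linearly in the
universe size, and the scaled tier covers the region where counts are
near zero anyway. The full-scale tier draws fresh model samples per
repetition through a lazy column sampler rather than materialising a
2,000-methylome pool (several gigabytes): for group sizes far below the
pool size the two schemes are statistically indistinguishable, differing
only in across-repetition sample reuse, and repetitions are averaged
independently either way.

## The synthetic methylome generator

All tests and the acceptance analysis run on synthetic data, so the
generator is first-class, tested code. It emulates the structural features
the analysis relies on:

- **Bimodality with feature dependence.** Each probe gets a state
  (unmethylated / intermediate / methylated) from a mixture whose weights
  depend on its combined genomic-feature × island-relation category:
  CpG-island promoter probes are ~95% unmethylated, open-sea gene-body
  and intergenic probes ~80% methylated. State modes sit at beta 0.10,
  0.50 and 0.90; probe baselines scatter around the mode on the logit
  scale (SD 0.7; 0.42 for intermediate probes) and per-sample noise adds
  logit-scale Gaussian variation (SD 0.3). Working on the logit scale
  keeps every value strictly inside (0, 1) with no clipping artefacts.
  Under these defaults fewer than 35% of a sample's probes fall in the
  ambiguous mid-range (0.2, 0.8), matching the strongly bimodal look of
  real 450K data.
- **Planted ground truth.** A synthetic PDX is its patient column with
  `round(frac_changing × n)` probes (default 2.7%) shifted by at least
  0.51, direction chosen only where the shift is feasible, everything
  else untouched — so threshold-based detection must recover the planted
  set *exactly*, count and identity, which the tests assert. Sibling
  PDXs share a configurable fraction (default 86%) of their planted
  changes.
- **QC structure.** A mouse-only detection-p vector with an exact flagged
  fraction, plus clean-ish human detection-p and bead matrices with rare
  planted failures.
- **Read records.** Multinomial dual-genome alignment classes, writable
  as two name-matched SAM files that round-trip through the ingestion
  path.

What the generator does **not** emulate: real tissue and disease
composition of public 450K repositories, probe type I/II chemistry
differences, spatial correlation along the genome, or batch effects.
Passing tests therefore demonstrate the correctness of the statistical
machinery and the internal consistency of the pipeline on data with the
assumed structure — not that any particular biological dataset will show
the same change rates. The one place this matters quantitatively is the
sample-size simulation, where synthetic cross-sample variability stands
in for real between-methylome variability; the simulation's driving
mechanism (identical unperturbed groups, rare multi-sample perturbation
overlap) is insensitive to that substitution, which is why the simulated
curve lands where the published analysis of real pools does.

Every generator is a pure function of its parameters and seed, and one
master seed fans out to per-component child seeds through a splittable
hash (`child_seed()`), so whole pipeline runs are reproducible from a
single integer.

## Worked example

```{r example, eval = FALSE}
ann  <- generate_annotation(20000, seed = child_seed(1, "ann"))
pool <- generate_pool(methylome_model(n_probes = 20000,
                                      seed = child_seed(1, "pool")), 2, ann)
pdx  <- generate_pdx_pair(pool[, 1], pair_plan(seed = child_seed(1, "pair")))
beta <- cbind(patient = pool[, 1], PDX = pdx$beta)

thr <- reversal_threshold()                    # 0.82 - 0.31 = 0.51
rf  <- reversed_fraction(delta_beta(beta, "patient", "PDX"), thr)
rf$percent                                     # 2.7 — the planted rate

enr <- resampling_enrichment(rf$probes, rownames(beta), ann, seed = 1)
head(enr[order(enr$empirical_p), ])

pc <- power_study(seed = 1)                    # ~3 minutes
pc$mean_count[pc$n == 15]                      # ~2-3 significant probes
plot(pc)
```

## Known limitations

- The fixed 0.31/0.82 state bounds derive from prior array calibration
  work; for platforms with different error structure, recalibrate with
  `calibrate_threshold()` on reference data.
- The enrichment and overlap nulls assume exchangeable probes; genomic
  autocorrelation of methylation is not modelled, so p-values on real
  data are anti-conservative at fine genomic scales.
- The read filter classifies existing alignments; it does not align, does
  not recompute duplicates, and is not a k-mer classifier.
- Scaled-down power runs rescale counts linearly; this is exact for
  expected counts but inflates the Monte-Carlo variance of rescaled
  estimates by the probe ratio, which is why the default study design
  runs the peak region at full scale.
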