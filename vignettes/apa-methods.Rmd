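---
title: "Methods: quantifying 3'-UTR APA dynamics with apadyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying 3'-UTR APA dynamics with apadyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions, parameters and numerical
choices behind `apadyn`, in the order the pipeline runs. It is the place
where design decisions that were genuinely open are recorded, together
with the reasoning.

## Data model and coordinate conventions

All on-disk interval formats (BED6, BED6+family, bedGraph) are 0-based
half-open, as the BED standard prescribes; readers validate rather than
repair, and reject malformed lines naming the line number. Nothing is ever
"corrected" to 1-based. In memory, plain data.frames keep the 0-based
convention, and all interval arithmetic (overlap, intersection, merging)
is delegated to `GenomicRanges`/`IRanges`, converting at the boundary. A
pAS is a point feature (`end = start + 1`); the single base is the
cleavage site, and the +1 position is the next base on the transcript
strand. On the minus strand every window is reverse-complemented so that
"upstream" always means transcript 5'.

Two consequences worth knowing:

* UTR segment boundaries sit at the cleavage base's 5' edge, so the
  cleavage base itself belongs to the downstream segment. The positional
  regions (proximal/middle/distal) therefore partition stop-to-distal
  exactly, which the tests assert.
* Missing conservation scores are excluded from averages, never imputed as
  zero: phyloP-style tracks have gaps, and zero-filling would bias means
  toward neutrality.

## Usage quantification

`compute_pau()` computes `PAU_i = 100 * TPM_i / sum(TPM)` per gene and
sample, on the 0-100 percent scale throughout the package. PAU is defined
only where the gene's total TPM reaches the expression gate, `min_tpm`
(default 0.1 TPM); below it every PAU of the gene is missing in that
sample — including the single-pAS case, which reports missing rather than
a vacuous 100. "Expressed pAS" means TPM > 0 in at least one sample; no
per-pAS minimum PAU is imposed. PPAU is the PAU of the rank-1 (most 5')
site. Entropy of a gene-sample is missing whenever any of its PAUs is
missing; we deliberately do not renormalise over observed pASs, because a
partially observed distribution has no meaningful entropy.

Positional classification is purely ordinal: rank 1 is the smallest
coordinate on `+`, largest on `-`; single-pAS genes are SPA, rank 1 of a
multi-pAS gene is APA-proximal, the last rank APA-distal, everything
between APA-middle. Two pASs of one gene at the same coordinate are an
error (ambiguous rank), not a tie to break silently.

Long/short gene calls compare PAU-weighted 3'-UTR lengths across tissues
with a margin of `margin_nt` (default 100 nt) against **every** other
tissue; a `majority` mode is available but not the default, since the
strict reading is the conservative one. Genes defined in fewer than two
tissues are "neither", flagged via `defined_in`.

Sample clustering uses distance `1 - Pearson` on pairwise-complete genes
with average linkage. The linkage/distance pair is a choice — nothing in
the quantities themselves forces it — made because correlation distance is
standard for expression-profile dendrograms and average linkage is robust
to the chain-building artefacts of single linkage. Samples are sorted by
id before clustering so leaf order is deterministic under ties.

`delta_ppau()` works on replicate-mean PPAU per (tissue, stage) with the
significance gate |dPPAU| >= 20 on the percent scale. Whether to pool
replicates or average them first was open; replicate means keep the two
stages' noise symmetric and are what the trajectory layer uses anyway.

## Sequence determinants

The polyA-signal catalog ships as data
(`inst/extdata/polya_signals.txt`): 18 DNA hexamers in priority order,
AATAAA first, ATTAAA second, seeded from the commonly cited signal
compendia. It is marked "verify against PolyASite" in the file header —
the exact membership and order of the published 18-mer set should be
confirmed before use on real data, and any list can be substituted via the
`catalog` arguments.

`assign_polya_signal()` scans the upstream 50 nt and reports **one**
signal per pAS: the hexamer earliest in catalog priority, ties between
occurrences resolved toward the pAS. The alternative — counting every
occurrence — is supported indirectly (scan the windows yourself), but
unique-best matches how per-signal percentages are usually quoted.
Windows with more than 10% N are dropped from composition and logo
statistics (`max_n_frac`, configurable); position-wise, N is excluded from
the denominator. Information content is `2 - H(column)` bits with
`0 log 0 = 0`.

The signal/+1A association uses the Pearson chi-squared statistic on the
per-class 2x2 table without continuity correction by default (`correct =
FALSE`), since class counts are in the thousands at the intended scale;
the correction is exposed for small tables.

## Trajectories

Trajectories are replicate-mean PPAU per stage, z-scored per gene (sd
denominator n-1). Genes with any undefined stage or zero variance are
excluded with reason codes — an incomplete trajectory cannot be compared
shape-wise against complete ones, and a constant one has no shape.

Clustering is k-means on the z-rows with `n_start = 20` restarts under a
seed-derived RNG state per candidate k; k is chosen by mean silhouette
width over `k_range` (default 2..6), with k = 1 accepted when silhouette
is undefined. Rows are sorted by gene id first, so permuting the input
does not change memberships. This is intentionally *not* a
re-implementation of any published time-series clustering tool: the
scientific output is the decreasing-pattern gene set, and the documented
core (normalisation, k-means, non-exhaustive assignment) reproduces that
in kind with explicit parameters.

Non-exhaustive assignment releases members farther from their centroid
than a per-cluster radius: mean member-to-centroid distance plus
`tightness_mult` (default 1) within-cluster sds. A single pooled radius
was tried first and rejected: the planted-recovery tests showed it
releases a third of the genuinely decreasing genes, because tight and
diffuse clusters need different radii.

`select_ppau_decreased()` selects clusters whose centroid trend (Spearman
rho against stage index, ties mid-ranked) is negative, keeps members whose
own rho is negative, and — when the raw PPAU matrix is supplied — requires
the member's first-to-last-stage decline to reach `min_delta` (default 20,
the same gate as `delta_ppau()`). The delta gate exists because z-scoring
discards amplitude: a stable gene whose noise happens to drift downward
can imitate the *shape* of a decreasing trajectory but not a 20-point
decline. On synthetic data this one magnitude check moves precision from
roughly 0.9 to ~1.0 at a 2-4 point sensitivity cost (the tests compute
these numbers; see `test-acceptance.R`).

## Regulatory context

PWM scanning is plain log-odds against a background (uniform by default)
with pseudocount 1e-3, hit threshold `score_fraction` (default 0.8) of the
maximum attainable score. Gene-level enrichment of aUTR over cUTR uses the
one-sided Fisher exact test on presence/absence indicators, Bonferroni
corrected over the number of motifs, significant at 1e-3. This replaces a
black-box motif-enrichment tool with a transparent equivalent whose
statistic of record — the Bonferroni-corrected enrichment p — is the same
kind of quantity. Gene-level indicators (not occurrence counts) are the
default because aUTRs are systematically longer than cUTRs and occurrence
counts would conflate density with length.

The Fisher kernel itself is the exact hypergeometric tail
(`stats::phyper`/`dhyper`); the two-sided p sums all tables with density
at most the observed one (with the customary 1 + 1e-7 tolerance). Tests
compare it against full enumeration for every table with total at most 50
and against `stats::fisher.test`.

miRNA sites are assigned to segments by midpoint (sites are ~7 nt;
midpoint assignment avoids double counting at boundaries); density is
sites per kb. TEs are handled by bp overlap after merging per family
(coverage must not double-count overlapping copies); the TE-status
stratification splits segments at any-overlap >= 1 bp. Wilcoxon rank-sum
comparisons use the normal approximation with tie correction
(`exact = FALSE`) throughout, since group sizes in the intended use are
tens to thousands.

For genes with more than three pASs the "middle region" is
proximal-to-last-middle and the "distal region" last-middle-to-distal —
the boundary choice for multi-middle genes was open; this reading keeps
the three regions a partition for every n.

## The synthetic generator

`simulate_apa_dataset()` is first-class, tested code. Its defaults *are*
the study conditions the pipeline is exercised under:

| parameter | default | meaning |
|---|---|---|
| `pas_count_probs` | .536/.22/.13/.08/.034 | P(1..5 pASs); P(>1) = 46.4% of genes are APA genes. The split over 2..5 is a one-time realistic choice (decreasing, most APA genes have 2 sites). |
| `signal_probs` | .512/.289/.309/.435 | AATAAA planting probability for SPA/proximal/middle/distal |
| `attaaa_prob` | .133 | ATTAAA planting probability, all classes |
| `plus_one_a` | .80/.85/.83/.78 | +1 adenine probability (SPA/prox/mid/distal); the SPA value is only qualitatively constrained ("high"), .80 chosen once |
| `delta_ppau_total` | 30 | linear PPAU decline (percent points) across stages for planted decreasing genes |
| `ppau_noise_sd` / `replicate_noise_sd` | 3 / 3 | per-tissue stage noise and per-sample replicate noise on PPAU |
| `tissue_effect_sd` | 9 | per-gene tissue offsets; 3x the stage noise so samples cluster tissue-first |
| `te_coverage` | .26/.456/.512 | TE bp-coverage targets for proximal/middle/distal regions |
| `mirna_density` | 3/2/1.5 per kb | planted miRNA-site density, highest in the proximal region |
| `utr_len_range` | 200-3000 nt | total 3'-UTR length; pAS spacing >= 100 nt |

Structure worth knowing:

* The decline is linear in stage (configurable in principle to other
  monotone shapes); after noise, PPAU is truncated to [1, 99] for
  multi-pAS genes and the remaining pASs are renormalised proportionally
  so PAU sums are exactly 100.
* Gene TPM is log-normal with meanlog increasing 0.4 per extra pAS,
  encoding the positive pAS-count-expression association.
* TE placement draws element lengths until they sum to the per-segment
  coverage target and scatters them with exponential gaps scaled to the
  free space, so realized coverage matches the target essentially exactly;
  a renewal-process placement was tried first and undershot targets by
  2-3 points on short segments through edge effects.
* Conservation is piecewise-constant: N(0, .3) inside TEs, N(1, .3)
  outside, N(1.5, .3) over coding sequence (which the coding mask then
  excludes from pAS-window averages).
* One planted RBP motif (sharp PWM, consensus `TGCATGC`) is embedded
  verbatim in decreasing-gene aUTRs at rate .8 (cUTRs .1); decoy PWMs are
  never embedded, so any decoy enrichment is a false positive by
  construction.
* Everything is driven by per-step RNG streams derived from the single
  seed; (config, seed) determines the emitted files byte for byte.

What the generator does **not** emulate: realistic genome composition and
isochores, overlapping genes and shared UTRs, read-level noise (TPMs are
drawn, not estimated from reads), pAS micro-heterogeneity (cleavage-site
wobble), correlated miRNA/TE placement beyond the planted densities, and
orthology structure between "species" (a second species is just a second
generator run). Passing the recovery tests therefore shows the pipeline's
statistics are correct and well-calibrated under the planted model — not
that the biological effect sizes in real data will match.

## Problem sizes and runtime envelope

The test suite exercises: exactness kernels at 1000 genes; overlap oracles
on 200 random instances within 10 kb; Fisher enumeration to n = 50;
planted-signal recovery at ~10,000 pASs (5400 genes); trajectory recovery
at 1000 genes with 200 planted decliners over 4 stages x 2 replicates;
enrichment calibration with 1000 decoy PWMs across 20 seeds on 150-gene
datasets (50 decliners — sized so the planted motif's expected enrichment
sits well inside the Bonferroni threshold rather than on it); and
tissue-structure recovery at 400 genes x 32 samples. These sizes keep the
full suite in single-digit minutes on one core while leaving each
stochastic bound a comfortable margin.

## Known limitations

* The pAS annotation-merging window for deciding that a GENCODE and a
  PolyASite record describe "the same pAS" is not a solved problem; this
  package takes pre-merged pAS tables as input and does not re-merge.
* `standardize_trajectories()` requires complete trajectories; partially
  observed genes are excluded rather than imputed.
* The enrichment module's occurrence-count mode is reserved but not
  implemented; gene-level indicators are the only tested path.
* Wilcoxon p-values are approximate for very small groups (< ~10); use
  the exact test externally if that matters.
* The silhouette criterion cannot distinguish k = 1 from k = 2 by itself;
  a degenerate single-shape input falls back to k = 1 only when the range
  is restricted or silhouette is undefined.
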