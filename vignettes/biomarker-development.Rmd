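---
title: "From methylation atlas to MSP assay: methods and design choices"
author: "methylmsp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From methylation atlas to MSP assay: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylmsp)
```

# The problem

Cell-free DNA (cfDNA) in plasma is mostly of haematopoietic origin, but
injured solid organs shed DNA whose methylation pattern still carries
tissue identity. A practical tissue-of-origin assay therefore needs CpG
sites that are (i) strongly methylated in the target tissue, (ii)
essentially unmethylated everywhere else — above all in blood, which
dominates the cfDNA background — and (iii) clustered tightly enough that a
single short PCR amplicon can interrogate several of them at once.
`methylmsp` implements that selection pipeline on DNA methylation
microarray beta-values, the in-silico design of methylation-specific PCR
(MSP) assays on the bisulphite-converted sequence, and the statistics used
to qualify such assays analytically and in a small clinical cohort.
Kidney is used as the running example throughout, with a transplant
setting (ischaemia–reperfusion injury) as the clinical read-out, but
nothing in the machinery is kidney-specific.

# Discovery model

A beta-value is the methylated fraction estimated from array intensities,
`beta = M / (M + U + 100)`; the offset stabilises low-intensity probes and
keeps the value strictly below 1. All statistics run on beta fractions;
percentages (`beta * 100`) are display-only.

For a target tissue against the pooled remaining tissues,
`differential_methylation()` computes per-probe group means, their
difference, and a two-sided Wilcoxon rank-sum p-value, with
Benjamini–Hochberg adjustment applied jointly across every probe tested in
the run (the adjustment universe is one discovery run; nothing smaller
would control the intended FDR). Probes pass `dmc_filter()` when

* FDR-adjusted p `< 1e-10`,
* methylation difference `> 0.3`,
* mean beta in the other tissues `< 0.1`.

Every inequality is strict, exactly as the thresholds are stated; values
sitting on a boundary fail. The extremely stringent FDR bound reflects the
purpose: the output is a shortlist for assay development, not a
genome-wide inventory, so false positives are far more costly than false
negatives.

**Regional density.** Isolated CpGs cannot support an MSP amplicon, so a
probe is kept only if at least 2 passing probes (itself included) lie
within a 5 kb window centred on it — operationalised as pairwise distance
`<= 2500` bp, boundary inclusive. `assemble_dmrs()` then joins passing
probes by single linkage at the same 2.5 kb distance; each cluster is a
differentially methylated region (DMR) spanning the member probes'
positions exactly (no flanking padding, since the region's purpose is to
delimit where probes sit, not where an amplicon must be).

**Blood background.** Candidate probes are screened against a blood
reference matrix both quantitatively and qualitatively: a probe is
excluded when its blood median beta exceeds 0.1 **or** more than 2% of
blood samples exceed beta 0.2. Again both rules are strict inequalities;
a probe at exactly 2% positivity survives. DMRs that drop below 2 members
after the blood filter are discarded (`restrict_dmrs()` re-checks member
counts and recomputes spans; member-to-member density is not re-tested, as
the surviving probes already passed it).

**Missing values** are excluded pairwise: a probe is tested on whichever
samples have data, and blood positivity uses the non-missing denominator.
Probes with no data at all in one group are dropped with a warning. This
is a policy choice — array data show missingness without an agreed
handling convention — and it is flagged in the output so users can audit
affected probes.

## Rank-sum details

When the combined sample size is at most 12 and the data are tie-free the
p-value is exact (null distribution of the Mann–Whitney statistic);
otherwise a normal approximation with mid-ranks, tie-corrected variance
and a continuity correction is used. The continuity correction matters:
without it the approximate p deviates from the exact one by up to ~0.07
at 6 + 6 observations, with it the two agree within 0.02. Completely tied
data return p = 1. At the default discovery scale (45 vs 489 samples) the
approximation is effectively indistinguishable from exact.

# Bisulphite conversion and MSP design

Bisulphite treatment converts unmethylated cytosine to uracil (read as T)
and leaves methylated CpG cytosine intact, turning a methylation
difference into a sequence difference. `bisulfite_convert()` implements
the idealised chemistry: on the methylated template every CpG C is
retained and every CH C becomes T; on the unmethylated template every C
converts. Bottom-strand conversion is reverse-complement-then-convert. A
terminal C whose successor is unknown (sequence end or N) cannot be
classified and is conservatively converted, with a flag. Conversion is
validated exhaustively against an independent rule (all 4^8 octamers) and
by the strand-symmetry and idempotence properties.

Design runs on the methylated converted top strand by default (bottom via
`strand = "bottom"`); MSP primers must only ever amplify the methylated,
converted template. Amplicons of 58–72 bp are enumerated
(`enumerate_amplicons()`), deliberately shorter than the conventional
<=120 bp recommendation because cfDNA is fragmented (and urinary cfDNA more
so); each window needs at least 6 retained CpGs so that two can sit on
each oligo. For each window `design_oligos()` anchors the forward primer
at the window start, the reverse primer (reverse complement of the
converted sense strand) at the window end, and places an internal probe,
under hard constraints: >= 2 CpGs per oligo; the forward primer's 3'
terminal base is a CpG C and the reverse primer's 3' base pairs with a
CpG C (a 3'-terminal mismatch against unmethylated template is what
enforces methylation specificity); no oligo overlaps a masked variant
position or an N; primer sites do not overlap; the probe does not cover
either primer's 3' terminus. Primer/probe lengths default to 18–30 nt —
standard PCR practice, configurable, since no tighter convention is
implied by the design rules themselves. When a window yields nothing, the
per-constraint rejection counts are reported so the user can see which
rule was binding.

**Traffic-light scoring.** Soft criteria are rated green (optimal),
yellow (acceptable) or red (risk), and a design's overall rating is its
worst:

| criterion | green | yellow | red |
|---|---|---|---|
| amplicon length (bp) | 58–72 | 73–120 (and < 58) | > 120 |
| oligo GC fraction | 0.40–0.60 | within 0.05 outside | further out |
| non-CpG cytosines (CH) per oligo | >= 3 | 1–2 | 0 |
| longest poly-G run | <= 3 | 4 | >= 5 |

The CH count is computed against the *source* sequence (those positions
read T in the converted oligo and are what discriminates converted from
unconverted DNA — conversion specificity). The green bands for length, GC
and CH restate the stated design rules; the *numeric* yellow/red
boundaries (GC ±0.05, poly-G 4 vs 5, sub-58 amplicons rated yellow) are
this package's calibration of a qualitative three-colour scheme and live
in one place (`score_design()`) should a user want different bands.
Melting temperatures (Wallace rule) are reported for information only —
no Tm acceptance rule is part of the criteria, and imposing one would be
a stronger claim than the design rules support. Ranking of candidates is
fully deterministic: rating, then total CpGs, then shorter amplicon, then
leftmost, then lexicographic.

# Assay evaluation statistics

**Dilution series.** `dilution_series_points(500, 2.5, 7)` gives the
7-point series 500 … 2.048 copies/reaction used for dynamic-range
checks.

**Single-molecule positivity.** At mean input `lambda` copies/reaction,
Poisson occupancy predicts a positive fraction `1 - exp(-lambda)` — at
the screening input of 0.17 copies/reaction, 15.6%. Observed positivity
is summarised with a Clopper–Pearson (exact binomial) interval. The exact
interval was chosen because reported screen intervals in this field are
consistent with it and because its conservative coverage suits
limit-of-detection claims; the method tag is always recorded, and the
empirical-coverage property (>= 95% across binomial settings) is tested.

**Comparing assays.** Positivity rates are compared with a two-sided
Fisher exact test (probability-mass convention). Where only printed
summaries of a screen are available, `reconstruct_screen_counts()`
recovers the underlying counts: it searches replicate totals in the
published range for count pairs that reproduce the printed rate at its
precision and whose exact-binomial interval agrees with the printed one
within 0.1 percentage points (a consistency band rather than exact
rounding, because the published interval method is typically unstated),
then keeps the candidate whose exact rate is closest to the printed
value.

**Digital PCR.** With `k` of `n` partitions positive, mean occupancy is
`lambda = -ln(1 - k/n)`; copies/reaction is `lambda * n` and a
reaction-to-plasma factor scales to copies/mL plasma, the primary
reported unit. Saturation (`k = n`) is an error, not an estimate. The
binomial interval on `k/n` propagates through the log transform.
Undetected markers are recorded as 0 copies — "undetectable" is a
measured value, not missing data.

**Clinical comparison.** `clinical_summary()` pairs each sample's marker
and total-reference (conversion-specific *ACTB*-style) quantifications,
reports absolute (copies/mL) and relative (% of total cfDNA) marker
levels with group medians/IQRs, and tests both measures across groups
with Kruskal–Wallis (tie-corrected H, chi-square p). An exact
enumeration branch exists for very small studies (total n <= ~10); the
default cohort sizes here (9/5/7/2, total 23) are safely in chi-square
territory and the null rejection rate at alpha = 0.05 is verified by
simulation.

# Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline consumes, with recorded
truth, under a single integer seed; each generator draws from a named
stream derived from that seed, so adding one call never perturbs another.

* `simulate_beta_matrix()` — background beta from a Beta distribution
  with mean 0.03 and concentration 20 (unimodal near 0, respecting the
  [0, 1] support; a Gaussian would not), planted probes shifted up by
  `delta` (default 0.5) in the target tissue only. Default cohort: 45
  target vs 489 samples over 16 other tissues, matching a realistic
  atlas discovery setting; 600 background probes laid out 10 kb apart
  (so background probes never form spurious 5 kb clusters with planted
  ones), 3 planted two-probe DMRs, 1% missingness.
* `simulate_blood_reference()` — the same background noise over (by
  default) 662 blood samples, with designated probes made positive
  (beta in 0.25–0.8) in a configured fraction of samples to exercise the
  2% positivity rule.
* `simulate_genomic_region()` — sequences with controlled CpG placement
  probability (optionally centre-clustered like a CpG-island core) over
  a 40% GC background, avoiding accidental CG at density 0.
* `simulate_replicate_screen()` / `simulate_partitions()` — binomial
  draws at `1 - exp(-efficiency * lambda)`, the same Poisson occupancy
  model the estimators invert.
* `simulate_clinical_cohort()` — group sizes 9/5/7/2 (HC, Pre-Tx, D1,
  D7) with marker occupancy 0 in HC/Pre-Tx, elevated at day 1
  (0.005/partition, ~130 copies/reaction at 26,000 partitions) and
  partially resolved at day 7 (0.001), against total-cfDNA occupancy of
  0.03–0.05; these defaults reproduce the qualitative clinical pattern
  (marker undetectable before transplant, strongly elevated after) at
  plausible cfDNA concentrations.

What the generators deliberately do **not** model: probe-affinity and
batch artefacts, cross-reactive probes, beta-value heteroscedasticity
across the intensity range, correlated methylation within real CpG
islands, incomplete bisulphite conversion, or PCR inhibition. Passing
recovery tests on synthetic data therefore demonstrates that the
*algorithms* do what they claim under their own model — planted regions
are recovered, null data yield nothing, estimators are unbiased — not
that any particular biological marker will validate in the laboratory.

# Problem sizes used in the shipped checks

The package's own validation runs at desk scale: discovery recovery and
null behaviour over 20 seeds at the full 45-vs-489 sample layout with 606
probes; clinical null calibration over a few hundred simulated cohorts;
dPCR recovery over 200 seeds at 26,000 partitions; interval coverage over
10,000 binomial draws; and a design audit over 100 seeded regions. These
sizes were chosen so the whole suite completes in a few minutes while
keeping Monte-Carlo error well below the margins being asserted.

# Known limitations

* Discovery treats tissues as exchangeable groups; no covariates, no
  paired designs, no probe-level quality weights.
* DMR boundaries are probe spans; they are not extended to biological
  region boundaries, and probe-sparse regions can split.
* Design does not screen thermodynamics (dimers, hairpins) or multiplex
  compatibility; it emits rule-compliant candidates for experimental
  screening, not guaranteed assays.
* The dPCR model assumes perfect partition detection and equal partition
  volumes; the reaction-to-plasma factor is the user's responsibility.
* The exact Kruskal–Wallis branch enumerates all group assignments and
  is only practical for very small totals.
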