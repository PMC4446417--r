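---
title: "Methods: junction-based cassette-exon splicing analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: junction-based cassette-exon splicing analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cassex` detects cassette-exon splicing changes between matched tumor and
normal RNA-seq samples from splice-junction read counts alone, without any
gene annotation. This vignette explains the model behind every stage, the
parameters that matter, the design choices made where the design was
genuinely open, and what the synthetic-cohort validation does and does not
demonstrate.

## Event model and discovery

A cassette (skipping) event is fully described by three exon–exon
junctions: an upstream inclusion junction UJ and a downstream inclusion
junction DJ, which flank the alternative exon, and a skipping junction SJ
that shares UJ's outer boundary (`SJ.start == UJ.start`) and DJ's
(`SJ.end == DJ.end`). Coordinates are stored 1-based inclusive on intronic
bases — the convention of the STAR `SJ.out.tab` dialect the package reads —
and the exon is derived as `[UJ.end + 1, DJ.start − 1]`, which must contain
at least one base. An exon with several alternative partners legitimately
produces several events, one per triplet.

Discovery applies two evidence filters, both defined on uniquely-mapping
read counts (multi-mapping counts are parsed but never used):

* **Support.** Each junction needs at least `min_reads = 5` reads in at
  least one sample of the dataset. Pooling is a per-junction maximum over
  samples.
* **Balance.** In *every* sample of the dataset the two inclusion junctions
  must have similar counts: `|UJC − DJC| < 10` **or**
  `|UJC − DJC| < 2·min(UJC, DJC)`, both inequalities strict, with an absent
  junction counting 0 reads. We read "every sample" literally: a single
  sample with `UJC = 0, DJC ≥ 10` removes the event. The alternative
  reading (only samples expressing the event) would keep more events at low
  expression but admits exactly the asymmetric-evidence artifacts the rule
  exists to remove. Note `min(UJC, DJC) = 0` in a sample forces reliance on
  the absolute bound there.

Junctions of unknown strand are retained; a triplet mixing `+` and `−` is
rejected, and an event inherits the defined strand when one exists. Events
built solely from unknown-strand junctions carry strand `*` and are
excluded from motif analysis only, because motif windows are
direction-specific. Canonical splice-site dinucleotides are *not* enforced:
in typical aligner output nearly all surviving junctions are canonical, so
we treat that as an observation, not a filter. Discovery runs per
cancer-type dataset (every filter above references "the dataset") and the
per-type event sets are unified by event id — a deterministic string built
from the five junction coordinates — for all cross-cancer analyses.

## PSI and the high-expression filter

Percent spliced-in is estimated per event and sample as

$$\mathrm{PSI} = \frac{\tfrac12(\mathrm{UJC} + \mathrm{DJC})}
{\tfrac12(\mathrm{UJC} + \mathrm{DJC}) + \mathrm{SJC}},$$

the average inclusion evidence over total evidence. PSI is undefined
(missing, never 0) when the denominator — the event's *coverage*
`0.5(UJC + DJC) + SJC` — is zero. The estimator is invariant to scaling all
three counts, and consistent as depth grows (verified by Monte-Carlo
against the generator's truth).

Only *highly expressed* events enter testing: coverage ≥ `min_cov = 10` in
**both** members of at least `min_pairs = 15` matched pairs of the cancer
type. The pairwise reading (both members, not any 15 samples) is chosen
because every downstream statistic is paired; it keeps the tested pairs and
the estimated effect on the same support.

## Differential calling

For each highly expressed event of a cancer type, the *usable pairs* are
those where both samples reach `min_cov`. Over usable pairs we compute the
mean paired difference `mean ΔPSI = mean(PSI_tumor − PSI_normal)` — the
mean of paired differences, not a difference of group means — and a
two-sided Wilcoxon signed-rank p-value. Zero differences are dropped before
ranking (the classic signed-rank treatment; PSI ties at 0 or 1 are common).
The exact null distribution is used when at most 25 nonzero differences
with untied magnitudes remain; otherwise the normal approximation with tie
and continuity correction. Fewer than two usable pairs makes an event
untestable (missing p). P-values are adjusted by Benjamini–Hochberg within
each cancer type (tests are grouped per dataset); the procedure behind the
published FDR threshold is not named in the literature the package follows,
and BH is the standard step-up choice. An event is significant iff
`q ≤ fdr = 0.05` **and** `|mean ΔPSI| ≥ min_delta = 0.10`. The joint rule
is deliberately conservative: on null cohorts the tests verify well under
1% of events are called.

## Recurrence, coherence, markers

Events significant in ≥ 2 cancer types are *coherent* when every
significant type shows the same ΔPSI sign, *non-coherent* otherwise;
single-type events are labeled `single`. The minority-sign types are
reported (`discordant_types`) so a summary can single out one outlier
cancer type; when exactly one type disagrees with one other, the
exclusion-direction type is reported — with only two types there is no
majority, and reporting labels is left to the caller.

A *splicing marker* is an event whose PSI changes by at least
`marker_delta = 0.10` in the **same direction** in at least
`marker_frac = 90%` of the usable pairs of one cancer type. The fraction is
`max(n_up, n_down) / n_pairs`, so five pairs up and five down is 50%, not
100%: consistency requires one direction. The threshold is inclusive
(≥ 90%), following the operational definition used in the source material's
marker table.

Support utilities follow the same conventions: frame preservation is total
exonic length divisible by 3 (multi-exon events sum their lengths);
two-proportion comparisons use the 2×2 chi-square without continuity
correction (erroring toward an exact test when an expected cell is zero);
set overlaps use the upper-tail hypergeometric
`P[X ≥ |A∩B|], X ~ HG(|U|, |B|, |A|)`; interval overlap requires ≥ 1
shared base (1-based inclusive arithmetic) plus an optional minimum overlap
fraction of the exon; all correlations are Pearson.

## Motif enrichment and conservation

For each stranded event three windows are extracted in transcription
orientation: the exon body and the `flank = 250` nt of each flanking intron
adjacent to the exon (shorter introns contribute entirely; windows never
cross into a neighboring exon). On the `−` strand the genomic roles of the
two introns swap and all sequences are reverse-complemented, so "upstream"
always means upstream of transcription — the analysis is invariant to
reverse-complementing the genome, which the acceptance suite asserts
end-to-end.

The scan tests every k-mer (k = 4, 5, 6) present in at least one foreground
region. The sampling unit is the **exon**, not the occurrence: a region
either contains the k-mer or not, which makes the test robust to window
length variation. With foreground = altered exons and background = highly
expressed exons *not* altered in that cancer type (excluded per cancer
type, not globally), the p-value is the upper hypergeometric tail over the
combined population. Flanking-intron scans are stratified by change
direction (included vs excluded in tumor), since splicing factors act
position-dependently; the exon-body scan pools directions and exists
largely to reproduce a negative result on null data. BH runs across all
k-mers (all k pooled) within each (region, direction, cancer type) stratum
at `motif_fdr = 0.01`.

K-mers map to splicing factors by exact membership in a consensus table or
by containing a shorter consensus as a substring. Only RBFOX
(TGCATG/GCATG) and QKI (ACTAAC/CTAAC/ACTAA) ship as defaults: their literal
consensus is unambiguous, while PTB/CELF/MBNL consensus sets vary across
studies and are supplied by the user as a two-column TSV.

Conservation profiles average per-base track scores at each offset in
`[−half_window, +half_window]` from the motif midpoint, defined as
`start + floor((len − 1)/2)` on the genomic strand — even-length motifs
take the left-of-center base, fixed so profiles are reproducible.
Track positions without data are excluded from means, never treated as 0.

## The synthetic-cohort generator

The generator exists to make every contract above testable with known
truth. Its defaults are the package's reference study conditions: 3 cancer
types × 20 matched pairs, 1000 cassette loci, 100 altered at
|ΔPSI| = 0.25, mean junction depth 50, TGCATG planted in downstream introns
of tumor-included altered exons at 60% foreground vs 10% background rate,
and a conservation track at 0.9 over planted motif bases vs 0.4 baseline
(Gaussian noise, sd 0.05).

Values the reference conditions leave open were fixed once, on biological
plausibility, and are not tuned:

* Baseline PSI is uniform on [0.05, 0.95]; altered events draw from
  [0.05 + Δ, 0.95 − Δ] so the planted shift is exact (no clamping) and the
  invariant |PSI_tumor − PSI_normal| = Δ holds by construction.
* 80% of altered events are *coherent* (one sign in all types); the rest
  flip sign in one random type, emulating the observed pattern of a
  minority of discordant events driven by one outlier cancer type.
* Junction counts are Poisson: `UJC, DJC ~ Pois(d·π)` independently and
  `SJC ~ Pois(d·(1−π))`, with depth `d ~ Gamma(shape 10)` around
  `depth_mean` per event-sample. Poisson (rather than negative binomial)
  is sufficient because the generator's job is to exercise the estimator's
  contract, not to model library preparation; biological spread enters
  separately as a per-sample Beta(5,5) jitter of scale 0.1 (sd ≈ 0.015) on
  π, which gives the paired test realistic non-degenerate nulls.
* Gene models: exons 30–150 nt with 70% frame-preserving, introns
  300–800 nt (never shorter than the 250-nt flank), random strands,
  non-overlapping loci on one synthetic chromosome. Everything is
  deterministic given the design seed.

What the generator does **not** emulate: overdispersed or correlated
counts, alignment and mapping artifacts, annotation complexity
(overlapping genes, alternative 5′/3′ sites, intron retention), batch
effects, tumor purity gradients, or realistic sequence composition. Passing
tests therefore demonstrate that the *algorithms implement their
definitions* and recover planted signals under the stated noise model —
not that the thresholds are optimal for any particular real cohort.

## Validation problem sizes

The acceptance suite validates: PSI on the exhaustive count grid 0–50;
discovery against a cubic brute-force oracle on 100 random junction sets of
up to 200 junctions; the exact Wilcoxon p against full 2^n sign enumeration
up to n = 8; BH against a step-up oracle on 1000 random vectors; null
calibration on ten 500-event, 20-pair cohorts; planted-effect recovery
(sensitivity ≥ 0.9, empirical FDR ≤ 0.10) on the reference design; the
marker rule at exactly 90% vs 80% consistent pairs; motif recovery and a
rate-matched motif null over 20 seeded runs each; conservation profile
levels; and full reverse-complement invariance. These sizes were chosen as
the smallest at which each property is statistically unambiguous.

## Known limitations

* Only cassette exons are modeled — no alternative 5′/3′ splice sites,
  intron retention, or mutually exclusive exons.
* The literal all-samples balance filter can remove genuinely expressed
  events in large cohorts when one sample has pathological coverage; the
  behavior is intentional and documented, but worth remembering when a
  known event is missing.
* The marker rule and differential caller share the coverage filter, so an
  event can be a marker only where it is testable.
* Degenerate (IUPAC) motifs and position-weight matrices are out of scope;
  the scan is literal k-mers by design.
* Survival analysis and differential gene expression are out of scope;
  normalized expression enters only through the PSI–expression correlation
  check.
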