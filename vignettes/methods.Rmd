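---
title: "Methods: mixed-response classification and progenitor-referenced copy-number analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed-response classification and progenitor-referenced copy-number analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnamix)
```

This vignette documents the models, conventions and numerical choices
behind `scnamix`, in the spirit of a methods section: what each component
assumes, which parameters matter, and where design decisions were
genuinely open.

# Lesion-level response classification

## Model

The unit of observation is a lesion's longest axial diameter at baseline
and at one follow-up assessment. Percent change is
$100\,(d_{\mathrm{fu}} - d_{\mathrm{base}})/d_{\mathrm{base}}$; a lesion
*responds* at $\le -30\%$, *progresses* at $\ge +10\%$, and is *stable* in
between. The prose definitions of per-lesion response circulating in the
clinical literature assign the $+10\%$ boundary ambiguously (stable is
"not more than 10% growth" while progression is "at least a 10%
increase"); `scnamix` resolves the boundary into the extreme categories —
$\le -30$ is a response, $\ge +10$ a progression — so stable is an open
interval and the partition is exhaustive and mutually exclusive. A lesion
that disappears entirely ($-100\%$) is a response; no separate "complete
response" state is tracked.

At the patient level, only patients with at least two baseline-measurable
lesions are evaluable (with a single lesion, within-patient heterogeneity
cannot exist by construction). Among evaluable patients with at least one
responding lesion, the response is **mixed** when any lesion progresses or
any new lesion appears — a new lesion counts as mixed even when every
other lesion responds, since it represents disease escaping therapy —
and **homogeneous** otherwise. Evaluable patients with no responding
lesion are non-responders; the mixed/homogeneous distinction is only made
within responders.

Per-patient response variability is the **unscaled MAD** of lesion percent
changes (median of absolute deviations from the median, no 1.4826
normal-consistency factor): the quantity is a descriptive spread on an
already-relative scale, and the unscaled form is what the clinical
comparisons it feeds report. New lesions have no defined percent change
(baseline 0) and are excluded from the MAD but recorded in
`has_new_lesion`.

Classification operates on one assessment at a time; choosing the
assessment (first follow-up versus maximum response) is the caller's
responsibility, keeping the time-point policy out of the classifier.

## Statistics

Group comparisons use three conventions that matter for reproducing
printed values:

- **Fisher's exact test** is two-sided by the
  sum-of-small-point-probabilities rule (all margin-preserving tables with
  hypergeometric probability at most that of the observed table), not by
  doubling the one-sided tail.
- **Chi-squared** exposes the Yates continuity correction as a flag,
  default off. Published 2×2 comparisons are not consistent about the
  correction, and both conventions are legitimate; the flag makes the
  choice explicit rather than silent.
- **Mann–Whitney U** uses exact enumeration for small tie-free samples
  (both $n \le 20$) and the tie-corrected normal approximation otherwise;
  the continuity correction is exposed and off by default, as its use in
  the comparisons this package mirrors is unstated.

# Progenitor-referenced copy-number calling

## The problem

Conventional somatic CNA callers require a matched normal. For
laboratory-evolved clone pairs (a single-cell-derived progenitor and a
drug-resistant daughter expanded from it) no normal exists — but the
progenitor itself is the natural reference, and only alterations
*acquired by the daughter* are of interest, since only those can carry
resistance mechanisms. The caller therefore measures the daughter
relative to the progenitor in four steps.

## Step 1: depth ratios

Reads are counted in fixed 1 Mb bins and the per-bin ratio
$r_b = (d_b/p_b)\,(P/D)$ is formed, where $P, D$ are library totals.
The normalization direction is chosen so that a copy-number-unchanged bin
has expected ratio 1 (a literal reading of some verbal descriptions of
this step would invert the correction and scale unchanged bins away
from 1). Bins with zero coverage in either sample are masked throughout.
The generator's shared log-normal per-bin bias cancels exactly in the
ratio, which is the property that makes progenitor normalization superior
to comparing either sample to a flat expectation.

## Step 2: allelic balance

Heterozygous SNPs genotyped in the daughter (depth $\ge 40$, alternate
count $\ge 10$) are tested against BAF 0.5 with an exact two-sided
binomial test ($\alpha = 0.05$). A bin is *allelic-balanced* when more
than 20% of its retained SNPs are individually consistent with balance —
a deliberately low threshold that tolerates somatic variants and
miscalled homozygous sites among the putative heterozygous SNPs — and the
bin holds at least `min_snps = 5` retained SNPs, so that absence of SNP
evidence is never read as balance. The denominator is retained SNPs
(post-filter), the only population for which the balance test is defined.
Balanced bins are pooled genome-wide into the reference fit; whether a
balanced bin happens to sit inside a segment later called altered does not
retroactively remove it.

## Step 3: segmentation

Ratios are segmented per chromosome by recursive interval splitting: at
each step the interval whose mean best separates from its complement
(both changepoints tested jointly, the complement treated as a single
arc, as in circular binary segmentation) is split off when the Gaussian
log-likelihood gain exceeds a penalty, default $5\log n$. The joint
two-changepoint test is essential, not cosmetic: a single-split rule
cannot justify either boundary of a short event in the middle of a long
chromosome on its own (on a 150-bin chromosome, a 7-bin spike at twice
the baseline scores a single-split gain of ~9, below any penalty that
keeps the null clean), whereas the interval test isolates it in one move.
The penalty was calibrated on the procedure's specified null and signal
behavior: pure noise (sd 0.05–0.1) yields a single segment in $\ge 99\%$
of replicates, a 0.8-unit step is located within $\pm 2$ bins, and short
spikes down to one third of a copy on ploidy 3 are isolated reliably.
Minimum segment length is 3 bins.

## Step 4: reference model and calls

The ratios of balanced bins are modelled as a Gaussian mixture — one
component per copy-number state present among balanced regions (e.g.
(1,1) and (2,2) regions of the same genome sit at different ratio levels
when the two clones' ploidies differ). The component count is chosen by
BIC over 1–5 components. Two numerical choices matter:

- **Log-scale fitting.** A ratio of Poisson counts is right-skewed; fitted
  on the raw scale, BIC reliably splits a single state into two spurious
  components, biasing the reference mean by a substantial fraction of its
  sd (observed in development: a +0.07 bias that inflated the null
  false-call rate to 95%). On the log scale the per-state distribution is
  near-Gaussian at the bin counts this caller targets, and one state is
  fitted as one component. The selected reference is converted back to
  the ratio scale via lognormal moments so `mu`/`sigma` compare directly
  with segment means.
- **Reference selection and degeneracy.** The largest-weight component is
  the reference (the modal, unaltered state). A sd floor of $10^{-4}$
  guards constant input; at least 50 balanced bins are required.

Each bin is then tested through its segment: $z = (\bar r_{\mathrm{seg}} -
\mu)/\mathrm{se}$, two-sided, $\alpha = 0.001$. The significance level is
fixed rather than FDR-adjusted: with ~3,000 bins per genome it bounds the
expected false-positive bins at ~3 per genome before segmentation
smoothing, and in practice segmentation leaves far fewer independent
tests than bins. The default standard error is that of a segment mean,
$\sigma/\sqrt{L}$ (`se = "segment"`). The more conservative bin-level
variant ($\mathrm{se} = \sigma$, `se = "bin"`) is retained as an option;
it is the natural choice when bins are tested in isolation, but against a
segment mean it leaves the test with essentially no power for one-copy
changes on triploid backgrounds at 100–300 reads per bin (shift 1/3
against $\sigma \approx 0.10\!-\!0.14$ never reaches $|z| > 3.29$), which
would defeat the caller's purpose at realistic simulated depths. Calls
are *gain*/*loss* by the sign of the rejected deviation; genes are
annotated by any-overlap between gene intervals and called bins.

# Recurrent SCNAs

Per-tumor rates $R_{g,t}$, $R_{l,t}$ are the fractions of (unmasked)
genome gained/lost. The null model asks: if each tumor scattered its
alterations independently and uniformly, how many tumors would hit the
same bin by chance? Each of 1,000 simulations draws one
Bernoulli($R_{g,t}$) contribution per tumor and sums; the threshold is
the 97.5th empirical percentile of the simulated totals — the upper bound
of the stated central 95% interval (a one-sided 95th-percentile reading
is exposed via `prob`). The null yields a single genome-wide count
threshold, not per-bin nulls: totals are exchangeable across bins under
the model. Observed counts must *strictly* exceed the threshold (the
non-strict reading is the natural alternative; strict is chosen as the
conservative one). Adjacent flagged bins merge into regions; a one-bin
gap is not bridged. Integer-CN cohorts are converted to states per tumor
against `round(ploidy)`, the pragmatic choice for genome-doubled tumors
whose "neutral" state is 4.

Because the threshold is a discrete count percentile, the realized
null flag rate sits at or below the nominal 2.5% per direction —
typically 1.5–2% in the calibration runs — and a bin altered at three
times the threshold frequency is essentially always flagged.

Synteny projection transfers per-bin frequency tracks between genomes by
linear coordinate mapping within homology blocks and length-weighted
averaging into target bins; orientation is ignored (frequencies are
strandless), blocks may overlap (overlaps average), and uncovered target
bins are masked rather than zero-filled.

# Single-cell copy-number QC and diversity

## Filters

Filtering runs in the order: flat-state exclusion first, then the
noisy-profile filter among the survivors; both are idempotent.

- A cell with $\ge 95\%$ of bins at CN 2 is a normal diploid contaminant
  (infiltrating lymphocyte, normal epithelium); $\ge 95\%$ at CN 4 is a
  cell caught in G2 or a doublet. The rule is read as "fewer than 5% of
  the genome deviates from the flat state", the only reading that
  excludes normal cells rather than keeping them.
- A cell's profile features are its SCNA breakpoints (within-chromosome
  positions where CN changes) and its whole-chromosome aberrations
  (chromosomes uniformly away from the cell's modal CN, which produce no
  internal breakpoint). A feature is *shared* when at least one other
  cell of the same tumor has a breakpoint on the same chromosome within
  ±1 bin **with the same direction of copy-number step**, or the same
  whole-chromosome aberration. Cells sharing $< 33\%$ of their features
  are excluded; feature-free cells are retained (no evidence of noise).
  Direction-aware matching is part of the definition of sharing *an
  SCNA's* breakpoint — an SCNA is a gain or a loss, and two cells whose
  profiles step in opposite directions at the same position do not share
  an event. It also matters quantitatively: position-only matching lets
  dense random artifact breakpoints collide with each other by chance,
  degrading the filter exactly when several noisy cells co-occur in one
  tumor.

## Metrics

- **Pairwise diversity**: fraction of co-unmasked bins with unequal CN,
  for every cell pair (optionally within FACS ploidy groups, so that
  comparisons are not dominated by ploidy offsets). It is a pseudometric:
  symmetric, zero on identical profiles, bin-wise triangle inequality.
  The same operation serves clone-to-clone diversity of subclone call
  tracks.
- **Shannon evenness**: cells are grouped into clones by exact profile
  identity after a 3-bin median smoothing (absorbing isolated single-bin
  call wobble; a clustering alternative can be substituted by disabling
  `smooth` and pre-grouping); with clone proportions $p_i$ over $k$
  clones, $E = -\sum p_i \ln p_i / \ln k$ for $k \ge 2$ and $E = 0$ for a
  single clone. Defining the single-clone case as 0 (rather than
  undefined, the Pielou convention) encodes "no heterogeneity" and keeps
  per-tumor averages well-defined.
- **wGII**: mean over chromosomes of the fraction of that chromosome's
  unmasked bins deviating from `round(ploidy)` — each chromosome weighs
  equally regardless of length, the standard weighting that prevents
  large chromosomes from dominating. Fully masked chromosomes drop out.
- **Ploidy and WGD**: ploidy is the mean CN over unmasked bins; WGD is
  flagged at ploidy $\ge 3.0$ — a doubled genome that has since lost
  material still sits above 3, an unduplicated near-diploid below.

# The synthetic-data generators

The generators define the study conditions under which the pipeline is
validated; they emulate the statistical structure the analyses assume,
not the full complexity of real data.

- **Clone pairs**: Poisson counts at `mean_depth` per bin with a shared
  log-normal per-bin bias (sd 0.1) — real coverage bias (GC,
  mappability) is locus-specific and largely shared between clones of the
  same line, which is what makes the ratio informative. SNPs are uniform
  over bins (default 20 per bin); alt counts are Binomial(depth, 0.5) in
  balanced regions and Binomial(depth, 0.8) inside planted events.
  Planted events are non-overlapping integer copy deltas on a configurable
  background ploidy. Validation runs use 3,000 bins over 20 chromosomes,
  depths 100–300, events of 7–41 bins with deltas ±1 to +3 on ploidy 3.
- **Single-cell tumors**: tumor cells diverge from an aneuploid founder
  (default ~10–15% of genome altered) by whole-chromosome missegregation
  events — the dominant mode of ongoing chromosomal instability in these
  tumors — at an expected altered genome fraction `divergence_rate`; a
  configurable fraction of cells carries a doubled founder; contaminants
  are flat CN 2; noisy cells carry long random segmental artifacts
  (expected 50% of genome, mean length 60 bins) with breakpoints
  independent of the founder. What the generator does *not* model:
  replication-timing structure of true S-phase cells (their breakpoints
  would correlate with each other), segmental tumor-cell divergence, and
  coverage-driven CN uncertainty — so passing filter tests show the rules
  behave as documented, not that real S-phase cells are always caught.
- **Cohort profiles**: per-bin independent gain/loss states at requested
  per-tumor rates with optional boosted-rate recurrent bins. Real SCNAs
  are segmental, which the recurrence *null* deliberately ignores (it
  models per-bin counts); the generator matches the null's granularity.
- **Lesion cohorts**: per-patient categories (homogeneous / mixed by
  existing lesion / mixed by new lesion / non-responder) with planted
  percent changes kept $\ge 5$ points away from the −30/+10 boundaries,
  so zero-noise cohorts round-trip exactly; Gaussian noise in percentage
  points is added on top. New lesions are encoded as baseline 0 with
  `is_new = TRUE`, avoiding division by zero.

All generators set the seed from their configuration on entry: a fixed
`sim_config` yields byte-identical outputs.

# Problem sizes and known limitations

The shipped validation uses 20 clone pairs of 3,000 bins for caller
recovery, 5 null pairs for the false-call rate, 20 cohorts of 40 tumors ×
1,000 bins with 1,000 simulations each for recurrence calibration and
power, 150-patient lesion cohorts, and 80-cell tumors for the QC filters
— sizes at which the binomial/Monte-Carlo error bands quoted in the tests
are meaningful.

Known limitations: the caller reports gain/neutral/loss relative to the
progenitor, not allele-specific integer copy numbers; the Z-test treats
segment means as independent of the reference fit (both come from the
same genome, a second-order effect at these bin counts); the
noisy-cell filter's shared-fraction statistic degrades when many noisy
cells with correlated artifacts co-occur in a small tumor; and the
recurrence null assumes independent per-bin placement, so long real
segments make it conservative per-bin but anti-conservative for
region-level claims.
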