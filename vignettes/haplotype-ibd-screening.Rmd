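---
title: "Screening for founder disease variants by local IBD: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for founder disease variants by local IBD: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haploScreen)
```

# The screening problem

Many rare disease-causing variants (DCVs) arose once in a founder and were
inherited by present-day carriers together with a surrounding ancestral
haplotype.  Such variants are usually absent from SNP arrays and — at minor
allele frequencies of 0.01% and below — effectively un-imputable, because no
reference panel carries the variant haplotype.  But the *haplotype* around
the DCV is observable.  If a pedigree-phased disease haplotype is available
from a known carrier family, any individual whose phased array data share an
identical-by-descent (IBD) segment with it around the DCV locus is a
candidate carrier.  `haploScreen` scores that local sharing and calibrates
it against a control cohort, turning dense SNP-array data into a screening
test for specific known variants.

This is a screen, not a diagnostic: an individual carrying the DCV on a
haplotype *not* represented in the available disease-haplotype set is
invisible to the method, and a high scorer may share the background
haplotype without the variant.

# The scoring model

For one disease haplotype $d$ and one test individual with phased haplotypes
$(A, B)$, the IBD score is the log-likelihood ratio of *IBD around the DCV*
versus *no IBD*, accumulated by two Markov chains that start at the marker
nearest the DCV ("marker 0") and extend outward in opposite directions —
the IBD segment boundaries are unknown, but the segment, if present,
contains the DCV.

**Hidden states.**  Each chain has three states: IBD on haplotype A, IBD on
haplotype B, and non-IBD.  Two IBD states are needed because statistical
phasing produces block-level switch errors: true sharing can hop between the
individual's two reported haplotypes.  The chain starts with probability
$1/2$ on each IBD state.

**Transitions.**  Over an inter-marker interval of $\delta$ Morgans and $b$
bp, the IBD state survives with probability $e^{-k\delta}$, where $k$
(`decayMeioses`, default 20) is the expected number of meioses separating
the two haplotypes from their common founder — the genetic map distance
plays the role of the waiting time to the next recombination.  Conditional
on survival, the state hops to the other haplotype with the phase-switch
probability $s = \min(1, rb)$, where $r$ is one switch per 20.05 Mbp, the
rate at which block phasing errors are injected in the simulation study.
Non-IBD is absorbing: the IBD segment containing the DCV is contiguous, so
once sharing has ended within a chain it does not resume; background sharing
elsewhere in the window is deliberately not modelled.

**Emissions.**  In an IBD state the tracked haplotype copies the disease
allele up to a uniform error rate $g$ (default 1%): probability $1-g$ on a
match, $g$ on a mismatch.  Genotyping and imputation errors are
indistinguishable here and share the single rate.  In the non-IBD state, and
under the null hypothesis, alleles are independent population draws: a
marker with alternate-allele frequency $f$ emits an observed alternate
allele with probability $f$ and a reference allele with probability $1-f$.
Linkage disequilibrium is not modelled in the likelihood — IBD segments of
interest are longer than LD blocks — which is exactly why calibration must
be empirical (below).

**The null, precisely.**  Both observed alleles enter the likelihood at
every marker.  The non-IBD state emits the *mean* of the two alleles'
population probabilities, and the null likelihood is the product over
markers of that same mean.  This choice makes the cumulative log-likelihood
ratio exactly flat once the IBD mass has been absorbed, so the chain value
measures sharing around the DCV and nothing else.  The obvious alternative
— a mean over haplotypes of whole-window frequency products — was rejected:
combined with a per-marker-mean non-IBD emission it makes the alternative
strictly dominate the null on heterozygous data (a product of means exceeds
a mean of products), and in desk experiments null individuals accumulated
on the order of 100 ln-units over a 20-cM window, destroying calibration.

**Missing data.**  A marker missing on the disease haplotype, or on both
test haplotypes, contributes no emission and no transition; its map distance
accrues to the next informative marker, so skipping a marker is *exactly*
equivalent to deleting it from the panel (this is a tested invariant).  A
marker missing on only one test haplotype marginalises that haplotype's
emission to 1 and is otherwise used.

**Termination and the score.**  The cumulative ln LLR is tracked along each
chain; the chain stops at the window edge or as soon as the LLR falls more
than `dropThreshold` (default 10 ln-units) below its running maximum —
sharing around the DCV has demonstrably stopped.  The chain's value is its
running maximum, which is robust to isolated errors near the boundary.  The
pair score is the sum of the left and right chain values, with the DCV
marker itself assigned to the right chain only, so it is counted once.
When several disease haplotypes tag the same variant, an individual's score
is the maximum over the set (ties broken toward the lowest haplotype id).

The forward pass is validated against exhaustive enumeration of all $3^T$
hidden-state paths on small panels (agreement to $10^{-9}$ ln-units), and
the production implementation is vectorised across individuals with an
active-set shrink as chains terminate.

# Empirical calibration

Although an LLR is asymptotically $\chi^2$ under the null, LD invalidates
that asymptotic here: background haplotype sharing inflates scores in a
locus-specific way.  Calls are therefore calibrated against the empirical
distribution of per-control maximum scores in a control cohort of the same
ancestry, scored against the identical disease-haplotype set and panel (the
package refuses to mix panels, via a panel fingerprint).  The critical value
is the conservative order-statistic quantile — the
$\lceil p/100 \cdot n\rceil$-th order statistic, no interpolation — which
guarantees that at most $1-p/100$ of controls lie strictly above it;
interpolated quantiles can be anti-conservative on heavy-tailed nulls.
Calls use strict exceedance, p-values are the add-one permutation form
$(1 + \#\{\text{controls} \ge s\})/(n+1)$, and for large cohorts a top-$N$
ranking (e.g. the top 100) replaces the threshold when the positive set
would be too large to follow up.  At least 100 controls are recommended for
a stable 99th percentile; fewer triggers a warning.

# What the simulator emulates

The simulation framework reproduces a founder-effect power study at desk
scale:

* **Cohort.**  `synthCohort()` builds a panel of biallelic markers with
  frequencies from a Beta(0.8, 0.8) spectrum truncated to [0.01, 0.99]
  (U-shaped, array-like), and each haplotype as a mosaic of founder
  haplotypes with switch points Poisson on the genetic map.  The mosaic
  induces LD between nearby markers.  Defaults: 503 individuals (a
  1000-Genomes-EUR-sized reference cohort), a 20-cM panel at about 100
  markers/cM, a linear 1 cM/Mb map with the DCV at the centre.
* **Backbone realism.**  The founder count (150) and mean founder-segment
  length (0.15 cM) were fixed so that *background* co-founder runs between
  random individuals are of LD-block scale (a few hundredths to tenths of a
  cM, cohort extremes a few tenths) — far shorter than the implanted
  disease segments, as in outbred human cohorts where background IBD
  between unrelated individuals is well below 1 cM.  An early
  parameterisation with cM-scale founder segments made background sharing
  as long as the smallest disease segments, which would contradict the
  premise that 0.5-cM sharing is detectable above a control null.
* **Disease haplotypes.**  Single-founder mode: one ancestral haplotype,
  copied over windows of length uniform between the guaranteed core (5 cM,
  the largest simulated sharing) and the panel span, spliced onto distinct
  background haplotypes — all versions share an error-free ancestral core.
  Multiple-founder mode: haplotypes from distinct individuals, no enforced
  core.  Donors leave the test cohort.
* **Cases and errors.**  Each scenario implants 10 haplotypes × 5 cases by
  replacing one haplotype of a random individual over a symmetric cM
  interval around the DCV (0.5, 1, 2 or 5 cM — proxies for time to the
  common ancestor), then flips 1% of alleles (genotype/imputation error)
  and applies phase-switch errors at one per 20.05 Mbp.  Implant first,
  then errors: cases carry errors like everyone else, while disease
  haplotypes stay error-free (they are pedigree-phased, not
  statistically phased).  Everything derives from one scenario seed;
  repeated runs are bitwise identical.

What the mosaic backbone does *not* reproduce: the deep, locus-specific LD
and relatedness structure of real reference cohorts.  On real haplotypes a
fraction of controls reach scores equivalent to 1–2 cM of sharing, which
depresses sensitivity at short sharing lengths; the mosaic null is cleaner,
so absolute sensitivities here run higher than on real cohorts, while the
*trends* (sensitivity increasing with sharing length and with the number of
disease haplotypes; single-founder above multiple-founder) and the
by-construction 1% false-positive calibration are backbone-independent.
Passing tests therefore validate the machinery and the qualitative claims,
not real-cohort operating characteristics.

# Numerical and design choices

* Nearest-marker snapping of the DCV (ties to the lower index): the DCV is
  typically untyped; the chain origin only needs a coordinate.
* The forward pass is rescaled at every marker (log accumulated), so
  windows of thousands of markers are numerically safe.
* The left chain excludes the origin marker; both chains measure distances
  from the DCV marker's coordinates.
* Genotype-error injection derives its RNG stream from the seed *and* the
  cohort content: reproducible for a given input, but re-applying it never
  cancels the first pass.
* Average precision (step interpolation) for AUPRC; trapezoidal
  interpolation over PR points is known-optimistic.  A random classifier's
  AUPRC is the baseline rate (cases / cohort), e.g. 50/492 ≈ 0.1 in the
  default scenario design.
* Two sensitivity definitions are reported and labelled: against all
  simulated cases, and against only cases descending from the haplotypes in
  use (the per-founder view).
* Scoring is batch-parallel over disease–test pairs by construction:
  results are independent of chunking, which is asserted in the tests.

## Problem sizes used in the shipped tests

The test suite runs the grid at 503 individuals, ~2300 retained markers
over 20 cM, two scenario replicates per cell of
{single, multiple} × {0.5, 1, 2, 5} cM, and calibration checks with 10,000
independently drawn non-carriers; the exhaustive-path oracle runs on more
than 100 random instances of up to 12 markers.  These sizes were chosen to
exercise the full design at interactive turnaround.

# Limitations

* A carrier whose DCV sits on an unrepresented haplotype cannot be found;
  accumulating unique disease haplotypes is the only remedy.
* The error rate $g$ is uniform across markers; a frequency-dependent rate
  would be more faithful for rare alleles.
* Copy number is not resolved: for recessive variants the screen flags
  carriers of at least one copy.
* Multiallelic sites, sex-specific maps and multi-chromosome panels are out
  of scope; input must be phased.
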