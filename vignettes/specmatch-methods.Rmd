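---
title: "Matching mass spectra with a variance-scaled metametric"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching mass spectra with a variance-scaled metametric}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specmatch)
```

## The problem

Electron-ionization mass spectrometry (EI-MS) fingerprints a compound by the
m/z histogram of its charged fragments. In forensic or environmental samples
the spectrum of interest is rarely clean: chromatographic separation may be
incomplete, ubiquitous small molecules (air gases, solvents, sesquiterpenes)
contaminate the signal, and the noise floor can be high. `specmatch` ranks
the entries of a reference library against such a query spectrum and returns
the most plausible identifications. It is deliberately simple: plain-text
inputs, no instrument-specific processing, and a single scalar score per
library entry.

## Library model and normalization

A reference spectrum is a peak list $\{(x_i, y_i)\}_{i=1}^{N}$ with strictly
positive intensities normalized to percent, $\sum_i y_i = 100\%$. On disk the
library is a two-level tree `root/<class>/<Formula>_<Name>/ref.ms`, where
`ref.ms` is a two-column text file; intensities are treated as unnormalized
and rescaled at load time. This makes the library extensible with any text
editor, which is the point: the intended users are small laboratories and
investigators without MS tooling.

## Window-based reduction

Rather than peak-picking the query, the query's intensity is *reduced* onto
each reference's peak positions. For a profile (grid) query $I(x)$ sampled at
spacing $\Delta x$,

$$Y_i = \Delta x \sum_k I_k\, w(x_k \mid x_i),$$

a rectangle-rule quadrature of the window integral
$\int I(x)\,w(x \mid x_i)\,dx$; for a discrete (peak-list) query the sum runs
over the query peaks without the $\Delta x$ factor. Two windows are
available: rectangular (weight 1 within $\pm\sigma/2$, boundary inclusive)
and Gaussian $\exp(-(x - x_i)^2 / 2\sigma^2)$, the default with
$\sigma = 1/2$ m/z. Overlapping windows deliberately double-count shared
intensity — the reduction is defined per reference position, not as a
partition of the query. Captured intensities are normalized to percent,
$\tilde y_i = 100\, Y_i / \sum_j Y_j$, giving the query's distribution on the
reference's support. Reference positions are not assumed to be integers.

Numerical notes:

* $\Delta x$ cancels in $\tilde y$ and only rescales every entry's total
  capture $\sum_j Y_j$ by the same factor, so the final ranking is invariant
  to the quadrature convention.
* The normalization is computed as $100\,(Y_i / \sum_j Y_j)$, dividing
  before scaling; for nearly disjoint query/reference pairs the total can be
  denormal ($\sim 10^{-307}$) and the reciprocal would overflow.
* Gaussian windows are evaluated over the whole query by default. The
  `cutoff` argument restricts evaluation to $\pm\,\mathrm{cutoff}\times\sigma$
  of each centre; at the value 8 used by the benchmark the discarded weight
  is below $e^{-32} \approx 10^{-14}$, and the captured values agree with
  full evaluation to better than $10^{-8}$ relative to the captured scale.

## Metrics

With the reference $y$ and reduced query $\tilde y$ both on the percent
scale, five quantities are computed per entry:

* matched lines $N = \#\{i : \tilde y_i > c\}$ with the strict threshold
  $c = 10^{-15}$ (a numerical floor, not a physical cut), and the fraction
  $P = N/N_{\mathrm{ref}}$;
* Kullback–Leibler divergence
  $D_{KL} = \sum_i \tilde y_i \ln(\tilde y_i / y_i)$ with $0\ln 0 = 0$;
* Bhattacharyya coefficient
  $BC = \tfrac{1}{100}\sum_i \sqrt{\tilde y_i\, y_i}$, clamped to $[0,1]$
  against floating-point overshoot, and the distances $D_B = -\ln BC$ and
  $D_H = \sqrt{1 - BC}$;
* cosine distance $D_C = 1 - \langle y, \tilde y\rangle / (\|y\|\,\|\tilde y\|)$.

$D_B$ and $D_H$ are both strictly decreasing transforms of $BC$, so they
always induce the same ranking; both are kept because their sensitivities
differ across the $BC$ range. When no intensity is captured, or no line
clears the threshold, the distances are undefined — interpreted as "species
not present" — and the entry is flagged rather than dropped, so output
length is stable.

## The metametric

The four distances live on incomparable scales. For the query at hand, each
is divided by its spread across the library — the population standard
deviation $\varsigma_X = \sqrt{\langle D_X^2\rangle - \langle D_X\rangle^2}$
over the entries with defined metrics — and the scaled distances are summed
and penalized by the matched fraction and the captured intensity:

$$D_{\mathrm{meta}} = \frac{1}{P \cdot \sum_j Y_j}
  \left( \frac{D_{KL}}{\varsigma_{KL}} + \frac{D_B}{\varsigma_B}
       + \frac{D_H}{\varsigma_H} + \frac{D_C}{\varsigma_C} \right).$$

Lower is better; entries with undefined metrics score $+\infty$ and rank
last, with ties broken byte-wise by entry id for reproducibility. Spreads
are recomputed per query over the defined entries. A zero spread (possible
only in degenerate libraries where a metric is constant) would divide by
zero; that term is skipped with a warning. Because scaling the query by
$s > 0$ leaves all four distances and $P$ unchanged and multiplies every
entry's $\sum_j Y_j$ by $s$, the ranking is invariant under intensity
rescaling — only relative scores matter, and no absolute accept/reject
threshold is defined (deliberately: the best match is always reported and
must be confirmed by an expert).

## Background removal

Profile spectra carry a noise floor that would otherwise leak into every
window. Under the assumptions that true peaks occupy a minor part of the m/z
range and the baseline is zero, an iterative sigma clip is applied: start
from the RMS of all intensities about zero, repeatedly keep only values
strictly below $q \times \mathrm{RMS}$ and recompute the RMS over the
survivors, and stop when the set stops shrinking, empties, reaches zero RMS,
or after $p$ iterations (defaults $q = 1.5$, $p = 3$). Values of the
original spectrum strictly below the final threshold are zeroed; everything
else is returned bit-identical. The RMS of an empty survivor set is defined
as 0 and stops the iteration, which resolves the otherwise-undefined corner
where everything is signal. Thresholds are non-increasing across iterations
because each clip removes the largest survivors. Discrete peak lists bypass
cleaning: they are already centroided.

## Synthetic benchmark

The validation harness generates mixtures that emulate an unseparated
environmental sample:

* the target's peaks are rendered as Gaussians on a 0–500 m/z grid of 2000
  points, each peak with a width drawn uniformly from 0.05–0.1 m/z;
* renderings of five ubiquitous background species (benzene, oxygen,
  nitrogen, carbon dioxide, farnesene) are added, each rescaled so its base
  peak is a uniform 0.1–0.2 fraction of the target's base peak;
* uniform noise $U(0, \max(\mathrm{signal})/\mathrm{SN})$ is added per grid
  point. S/N is defined against the noise amplitude's upper bound; the
  choice is monotone-equivalent to any other uniform-noise convention and
  only relabels the difficulty axis.

Two condition sets are standard: *basic* (S/N 100–1000, no jitter) and
*extended* (S/N 5–100, peak intensities jittered by ±50%, positions by
±0.2 m/z). Each benchmark trial draws a target uniformly from the library,
synthesizes a mixture, background-cleans it, ranks the library with the
metametric and with each single distance independently, and records the true
entry's rank; repeats are scored by top-K accuracy, mean reciprocal rank,
and mean rank. Repeat $r$ seeds the random stream with
$\mathrm{seed} + r - 1$, so a benchmark is fully determined by (seed,
configuration, library).

The fixture library generator produces synthetic entries (5–40 peaks at
integer m/z in 20–450, log-uniform intensities over three decades) plus
named stand-ins for the five background species, and can lay 400 entries out
across the 17 classes of a realistic chemical-threat library. Everything
about these spectra is random except names, formulas, and mass ranges.

### What the synthetic data does and does not show

The generator reproduces the *geometry* of the problem — peak widths,
overlap, contamination, noise — but not the intensity structure of real EI
fragmentation: log-uniform intensities have no fragment-series correlations,
no isotope patterns, and no shared base-peak conventions between related
compounds. Consequently the *fused* metametric's dominance over every single
distance is robust across library realizations (we observe top-1 margins
above 50 percentage points under extended noise), but the relative ordering
*among* the single distances varies with the library draw: on some synthetic
libraries cosine beats KL, on others the reverse, whereas curated real
libraries show a stable ordering. Tests therefore assert the robust
properties (metametric dominance, exact Bhattacharyya–Hellinger rank
equality, scale invariance, self-identification) and not the single-metric
ordering. Passing them demonstrates the pipeline's correctness and the value
of the fusion, not field performance on real spectra.

A related subtlety: because each captured intensity is proportional to the
(random) rendered peak width, the reduced distribution of even a noiseless
rendering is a width-distorted copy of the reference. A uniform width
cancels in the percent normalization, so the noiseless self-identification
checks fix the width at 0.08 m/z; with random widths the distortion is part
of the intended difficulty.

## Problem sizes and defaults

| Parameter | Default | Meaning |
|---|---|---|
| window / sigma | Gaussian, 0.5 m/z | reduction kernel |
| `c` | 1e-15 | strict presence threshold on percent intensities |
| `q`, `p` | 1.5, 3 | background clip selectivity and iteration cap |
| cutoff | Inf (API), 8 (benchmark) | Gaussian evaluation range in sigmas |
| grid | 0–500 m/z, 2000 pts | rendering grid |
| basic / extended S/N | 100–1000 / 5–100 | noise conditions |

The shipped test-suite benchmarks use 8 repeats × 100 trials on a 50-entry
library and 8 repeats × 50 trials on the 400-entry layout; the acceptance
script uses the same 400-entry sizes. These are the package's chosen
problem sizes for routine verification; larger runs (e.g. 48 × 500) only
tighten the standard errors and can be requested through
`simulation_config()`.

## Known limitations

* No peak-picking, isotope handling, or retention-time dimension; the
  reduction is the only bridge between profile data and the library.
* The background model assumes a zero baseline and sparse peaks; sloping
  baselines need external correction first.
* Identification is always biased toward the library: the best match is
  reported even when the true compound is absent. Reports carry an explicit
  expert-confirmation caveat for this reason.
* Biological matrices (metabolites, degradation products) are out of scope;
  the benchmark emulates environmental mixtures only.
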