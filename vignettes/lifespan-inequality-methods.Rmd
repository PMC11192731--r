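---
title: "Measuring lifespan inequality and polarization from abridged life tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring lifespan inequality and polarization from abridged life tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifespanineq)
```

## The grouped lifespan distribution

Everything in this package is a functional of one object: the discrete
distribution of age at death implied by an abridged period life table.
For a synthetic cohort of radix $\ell_0$ (100,000 by convention), interval
$k$ starting at age $x_k$ with width $n_k$ contributes a mass point

$$c_k = x_k + a_k, \qquad f_k = d_k / \ell_0,$$

where $d_k$ are the deaths in the interval and $a_k$ the average years
lived in it by those who die there. `to_distribution()` performs exactly
this construction; its mean $\mu = \sum_k f_k c_k$ is life expectancy at
birth, and under the person-years chain used here it coincides *exactly*
(not approximately) with the $e_0$ obtained from
`remaining_life_expectancy()` — both reduce to
$\sum_k d_k (x_k + a_k)/\ell_0$. The test suite asserts this identity to
$10^{-8}$ relative error.

A period life table is a statistical construct: it reflects one calendar
year's death rates applied to a hypothetical cohort, not the history of a
real birth cohort. All indicators here are therefore snapshots of current
mortality conditions.

### Conditioning on survival to 15

The over-15 variants restrict the support to intervals starting at or
above 15 and renormalize the masses by the deaths above that boundary.
Two conventions were genuinely open:

- **Ages stay absolute.** The conditional distribution keeps $c_k$ as ages
  at death (a death at 70 is the value 70, not "55 years after 15"). This
  matches how the over-15 indicator files are defined on ages at death,
  and makes conditioning with `min_age = 0` the exact identity.
- **Relative measures normalize by the conditional mean age at death**,
  not by remaining expectancy $e_{15}$. Nothing in the indicator
  definitions suggests switching numeraire after conditioning, and the
  absolute-age convention keeps every cross-column identity
  (e.g. $GE(2) = \sigma^2/2\mu^2$) valid within the over-15 panel too.

Conditioning requires an interval boundary at 15, which every standard
abridged layout has; the validator enforces it so the error surfaces at
read time, not deep in a batch run.

## The indicator battery

Absolute measures (variance, standard deviation, IQR, absolute Gini
$AG = \mu G$, life disparity $e^\dagger$) respond to differences in years;
relative measures (Gini, the GE family, Keyfitz's $H$) respond to
proportional differences and are invariant under a common rescaling of all
ages at death. The property suite checks both invariance classes
explicitly, including the two-person example (deaths at 6 and 60 versus 7
and 70) where every relative index agrees across the two populations and
every absolute index ranks the second higher.

Numerical choices worth recording:

- **Gini** is computed as the full $O(K^2)$ pairwise double sum. With
  $K \approx 22$ age groups this is microseconds, mirrors the defining
  formula term for term, and leaves the sorted $O(K \log K)$ form free to
  serve as an independent oracle in the tests.
- **Quantiles** interpolate the CDF linearly within intervals (deaths
  uniform within an interval). A quartile falling in the open-ended
  terminal interval is returned as that interval's mean age at death
  $x_K + a_K$; with realistic mortality less than 5 % of mass lies there,
  and the generator refuses parameter sets that would violate that.
- **GE family**: $GE(\theta)$ accepts any real $\theta$; $\theta \le 1$
  requires all $c_k > 0$ for masses $f_k > 0$, i.e. the 0–1 interval must
  have $a_0 > 0$ — the error message says so. $\theta$ values within
  $10^{-12}$ of 0 or 1 dispatch to the exact MLD/Theil limits, and the
  tests verify continuity of the general form into both limits at
  $\theta = 10^{-6}$ and $1 \pm 10^{-6}$.
- **Life disparity**: the defining sum
  $e^\dagger = \sum_x f_x [e_x + (a_x/n)(e_{x+1} - e_x)]$ leaves the
  terminal interval's successor $e_{K+1}$ undefined. The closure adopted
  here sets $e_{K+1} := 0$ with $n$ := the modal closed-interval width
  (5 for abridged layouts), i.e. a terminal contribution
  $f_K e_K (1 - a_K/5)$ floored at zero. It is deterministic, continuous
  in the inputs, and affects only the small open-interval mass; an
  alternative (dropping the interpolation term entirely in the last
  interval) differs by well under the 2 % tolerance at which the
  continuous-model oracle validates $e^\dagger$.

## Polarization

$DER(\alpha) = \sum_k \sum_j |c_k - c_j| f_k^{1+\alpha} f_j$ combines
alienation (the $|c_k - c_j|$ distances) with identification (the
$f_k^{1+\alpha}$ concentration weight). Two deliberate fidelity decisions:

- The masses entering the formula are the probability masses
  $f_k = d_k/\ell_0$ exactly as the grouped construction defines them,
  not per-year densities. A consequence worth knowing: for $\alpha > 0$
  the relative index $DER \cdot \mu^{\alpha-1}$ is then not strictly
  scale-invariant under the discrete convention. The formulas are applied
  verbatim rather than silently re-deriving a continuous version.
- Under these formulas $DER(0)$ equals $2 AG$, twice the absolute Gini
  (each unordered pair is counted in both orders). The factor-2 relation
  is asserted as an identity test at $10^{-12}$; no hidden $\tfrac12$
  normalization is applied anywhere.

## Group aggregation

For a weighted set of countries, `pool_distributions()` builds the exact
mixture distribution (population shares $s_g$ on each group's own mass
points), and `ge_decompose()` splits GE inequality into

$$\text{within} = \sum_g s_g \left(\frac{\mu_g}{\bar\mu}\right)^\theta
GE_g(\theta), \qquad
\text{between} = GE(\theta) \text{ of the shares-at-means distribution},$$

with the $\theta \in \{0, 1\}$ limits using their log forms. With
population shares as weights the two components sum to the pooled GE
*exactly*; the suite asserts additivity to $10^{-9}$ on random mixtures.
Weights follow what the panel schema carries: total population for the
total scope, adult (over-15) population for the over-15 scope. Gini and
DER are not additively decomposable, so no pseudo-decomposition is
offered for them — group values come from the pooled distribution only.
Whether group rows should be produced by pooling tables or by decomposing
indices is therefore moot for the GE columns (the two routes agree by the
additivity property); both routes are exposed.

## The synthetic generator

Real abridged tables come from vital-registration systems; for testing,
the package simulates them from a five-parameter Siler force of mortality

$$h(t) = a_1 e^{-b_1 t} + a_2 + a_3 e^{b_3 t},$$

chosen over Gompertz–Makeham because the declining infant term is what
produces the characteristic bimodal age-at-death density: an
infant-mortality spike falling steeply to adolescence, then an adult
bell-shaped mode. Survival is closed-form, deaths are exact survival
differences, and each interval's $a_k$ is the exact person-years integral
evaluated by adaptive quadrature (relative tolerance $10^{-10}$) — table
construction involves no randomness at all. The optional Gaussian
excess-hazard bump (analytic cumulative hazard via the normal CDF) yields
the `hiv_like` preset's mid-adult mortality hump.

Preset parameter values were fixed once, on demographic plausibility:

- `modern`: $a_1 = 0.03$, $b_1 = 1.2$, $a_2 = 4\times10^{-4}$,
  $a_3 = 5\times10^{-5}$, $b_3 = 0.095$ — about 1.8 % infant mortality,
  $e_0 \approx 70.6$, adult mode near 80;
- `historical`: $a_1 = 0.25$, $b_1 = 1.0$, $a_2 = 8\times10^{-3}$,
  $a_3 = 3\times10^{-4}$, $b_3 = 0.075$ — high infant mortality
  ($\approx 20\,\%$ under 5), $e_0 \approx 40$, wide adult spread;
- `hiv_like`: the modern schedule plus a bump of height 0.012 at age 35
  (s.d. 8 years).

Random parameter draws for property tests sample the infant and
background components uniformly and solve the senescent level from a
sampled adult modal age $M \in [68, 85]$ via $a_3 = b_3 e^{-b_3 M}$;
these ranges guarantee survival past 100 stays below the 5 % open-interval
cap, so every draw yields a valid table. The generator refuses parameter
sets breaching that cap rather than silently truncating mass.

`micro_sample()` draws exact ages at death by inverse-transform sampling
(vectorized bisection on the monotone cumulative hazard, 64 iterations,
resolution far below any tolerance used). It is the individual-level
oracle: binning a large sample with `bin_sample_to_table()` and computing
grouped indicators converges to the deterministic table's indicators at
the Monte-Carlo rate $\sim 1/\sqrt{n}$, which the tests check across
three sample sizes.

### What the scenarios emulate — and what they do not

`make_scenario_pair()` builds deterministic before/after pairs
reproducing two qualitative mechanisms: concentrating old-age deaths
toward the modal interval (inequality falls, polarization rises — the
identification effect) and adult progress under stagnant infant
mortality (both rise — the alienation effect). The pairs reproduce the
*directions* of these mechanisms; the underlying continuous distributions
behind any particular published illustration are not recoverable from
summary numbers, so no attempt is made to match index levels, only signs
of change. The transfer fraction in the concentration scenario (half the
mass of each 65+ interval moved to the modal interval) was fixed once as
a visible, mid-range choice.

Synthetic tables emulate the *shape* of real mortality but not its
messiness: no age heaping, no vital-registration undercount, no
cohort-period interaction, no country-specific quality codes beyond
pass-through strings. Passing tests therefore demonstrate correctness of
the computations on well-formed tables, not robustness to dirty source
data — the validator is the guard at that boundary, and corrupted tables
are logged and skipped by the batch pipeline rather than repaired.

## Degenerate inputs and tie-breaks

- Zero radix, zero deaths above a conditioning boundary, or a
  non-positive mean raise immediate degenerate-input errors.
- A supplied survivorship column inconsistent with cumulative deaths
  (beyond $10^{-4}\ell_0$) is recomputed from deaths with a warning —
  $d_k$ and $a_k$ are the primitives of every formula here.
- A death interval with zero survivors is an inconsistency error, not a
  silent `NaN`.
- Interval layouts are data-driven: any contiguous abridged layout with
  one open-ended terminal interval and a boundary at 15 is accepted, and
  the interval count is whatever the data says (layout conventions vary
  across life-table vintages; 22 groups for 0–1, 1–4, 5–9, …, 100+ is
  typical). Boundary ages are half-open: age 15 belongs to 15–19.

## Problem sizes

The shipped test-and-analysis configuration uses tables of ~22 intervals;
property suites run on 100 random hazards, identity suites on the same;
the Monte-Carlo convergence checks use samples up to 128,000 draws and
the expanded-cohort oracles up to 5,000 individuals. These sizes were
chosen so every statistical check is comfortably beyond its own noise
floor (binomial error at $n = 64{,}000$ is an order of magnitude below
the 0.01 tolerance on the Gini comparison) while the whole suite remains
interactive.
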