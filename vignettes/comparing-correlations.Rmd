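---
title: "Comparing two Pearson correlations: models, procedures and design choices"
author: "corcmp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing two Pearson correlations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corcmp)
```

## The statistical problem

Two sample Pearson correlations differ by chance alone far more often than
intuition suggests, and whether an observed difference is significant
depends on how the two coefficients are related. corcmp distinguishes the
three canonical designs:

* **independent groups**: $r_1$ and $r_2$ estimated in disjoint samples of
  sizes $n_1$ and $n_2$;
* **dependent overlapping**: $r_{jk}$ and $r_{jh}$ estimated in one sample
  of size $n$, sharing variable $j$, with the *related correlation*
  $r_{kh}$ describing the leftover dependence;
* **dependent nonoverlapping**: $r_{jk}$ and $r_{hm}$ from one sample with
  no shared variable, with four related correlations $r_{jh}, r_{jm},
  r_{kh}, r_{km}$.

All procedures assume jointly (approximately) normal variables, simple
random sampling, and large-ish $n$; the $t$-based procedures additionally
use $df = n - 3$ exactly, which is the convention every implemented
variant shares.

## Common building blocks

The Fisher transform $Z = \operatorname{atanh}(r)$ stabilises the variance
of a sample correlation at approximately $1/(n-3)$; `fisher_r_to_z()` and
`fisher_z_to_r()` expose it, and `single_corr_ci()` gives the standard
back-transformed interval
$\tanh\{\operatorname{atanh}(r) \pm q_{(1+\gamma)/2}/\sqrt{n-3}\}$ used
inside Zou's intervals.

For dependent comparisons the key quantity is $c$, the estimated
correlation between the two *sample* correlations. In the overlapping case

$$c = \frac{r_{kh}\,(1 - r_{jk}^2 - r_{jh}^2) - \tfrac12\, r_{jk} r_{jh}\,
      (1 - r_{jk}^2 - r_{jh}^2 - r_{kh}^2)}
      {(1 - r_{jk}^2)(1 - r_{jh}^2)},$$

and in the nonoverlapping case the numerator is the four-variable
Pearson–Filon covariance term. Three families of procedures then differ in
how they use $c$:

* raw-scale asymptotic $z$ (Pearson–Filon, Olkin): difference of raw
  correlations scaled by $\sqrt{n}$ and the asymptotic variance. The two
  published denominator forms are algebraically identical, which the test
  suite verifies on random inputs — their agreement is exact, not a
  numerical coincidence.
* $t$ with $df = n-3$ (Hotelling, Williams, Hendrickson): based on the
  determinant of the $3\times3$ correlation matrix. Williams' and
  Hendrickson's corrections add a term in $(\bar r)^2 (1-r_{kh})^3$ to the
  variance, differing in the $n$-scaling of that term.
* Fisher-$z$ based $z$ (Dunn & Clark and its Steiger / Hittner / Silver
  modifications, Meng, Raghunathan):
  $z = (Z_1 - Z_2)\sqrt{(n-3)/(2-2c)}$. Steiger evaluates $c$ at the plain
  mean $\bar r = (r_1 + r_2)/2$, Hittner/Silver at the back-transformed
  mean Fisher $Z$, which slightly stabilises the estimate under unequal
  correlations. Raghunathan et al.'s form
  $\sqrt{(n-3)/2}\,(Z_1 - Z_2)/\sqrt{1-c}$ is algebraically the Dunn &
  Clark statistic; the suite records their 4-decimal agreement as a
  regression check.

Meng's variance uses $\bar r^2 = (r_{jk}^2 + r_{jh}^2)/2$ and a factor
$f = (1-r_{kh})/\{2(1-\bar r^2)\}$ capped at 1; the cap is applied
silently. Its companion interval is reported on the **Fisher-z difference
scale** (its midpoint is exactly $Z_{jk} - Z_{jh}$) and the rendered
report labels the scale explicitly so it is not misread as an interval for
$r_{jk} - r_{jh}$.

Zou's intervals combine the two single-correlation limits
$(l_i, u_i)$ via the MOVER construction,
$$L = r_1 - r_2 - \sqrt{(r_1-l_1)^2 + (u_2-r_2)^2 - 2c\,(r_1-l_1)(u_2-r_2)},$$
with the analogous upper bound; $c = 0$ recovers the independent-groups
interval, a reduction the tests verify.

## Tunable parameters

| argument | meaning | default |
|---|---|---|
| `alternative` | direction of the alternative; `"greater"` means $\rho_1 > \rho_2$ (first minus second) | `"two.sided"` |
| `alpha` | significance level for p-value decisions | 0.05 |
| `conf.level` | level of all interval procedures | 0.95 |
| `null.value` | hypothesised lower bound for $|\rho_1 - \rho_2|$ | 0 |
| `test` | labels of the procedures to run | `"all"` |

A nonzero `null.value` states a *magnitude* hypothesis: the null
"$|\rho_1-\rho_2| \le$ `null.value`" is rejected exactly when Zou's
interval lies entirely outside $[-\texttt{null.value}, +\texttt{null.value}]$.
Only the interval procedure can test this claim, so the comparison then
runs `zou2007` alone. One-sided alternatives affect the p-values only; the
intervals are always central two-sided intervals at `conf.level`.

## Numerical and degenerate-input choices

* Inputs with $|r| = 1$ are rejected everywhere, uniformly: every
  procedure either Fisher-transforms $r$ or divides by $1-r^2$, and a
  uniform rule is easier to reason about than per-test exceptions.
* Group sizes must exceed 3 so that the Fisher variance $1/(n-3)$ and
  $df = n-3$ are positive.
* Related correlations that make the implied correlation matrix
  non-positive-semi-definite trigger a **warning**, not an error
  (`check_psd()`, eigenvalue tolerance $10^{-9}$): the statistics remain
  computable and a hard error would block exploratory use, but such inputs
  cannot arise from real data.
* If a pathological input drives $2 - 2c \le 0$ (Dunn/Steiger/Hittner/
  Silver) or the $3\times3$ determinant non-positive (Hotelling,
  Williams), the affected procedure raises an error naming the offending
  quantity; selecting a subset of tests never evaluates the others, so a
  degenerate unselected procedure cannot abort a comparison.
* Statistics, p-values and interval bounds are rendered at 4 decimal
  places; raw differences are rendered at up to 4 decimals with trailing
  zeros trimmed. All internal computation is in double precision.

Reported statistics are exact functions of the input coefficients. Note
that coefficients rounded to 4 decimals carry an input uncertainty of up
to $5\times10^{-5}$ each, which propagates to roughly
$\sqrt{n-3}\,\delta r/(1-r^2) \approx 10^{-3}$ in a $z$ statistic at
$n \approx 300$ — so the fourth printed decimal of a statistic computed
from rounded coefficients can differ from the value computed from the
underlying raw data.

## The synthetic-data generator

`sample_mvn()` draws i.i.d. rows from a multivariate normal via the upper
Cholesky factor of the population correlation matrix. It emulates exactly
the sampling model the tests assume — jointly normal variables with a
specified correlation structure — and none of the features of real
psychometric data (bounded discrete scores, skewness, heteroscedastic
measurement error, outliers). Calibration results below therefore speak to
the procedures' behaviour *under their own assumptions*; robustness to
non-normality is a separate question outside the package's scope.

`make_aptitude_fixture()` generates a two-sample aptitude-style data set
(n = 291 and 334) over `knowledge`, `logic`, `intelligence.a`,
`intelligence.b`, with sample 1's population correlations set to the
coefficient values used in the worked examples and sample 2's single
specified correlation at 0.2024. Correlations of sample 2 for which no
target exists are left at 0 and documented as such. Because the fixture is
a fresh multivariate normal draw, its sample correlations differ from the
targets by ordinary $1/\sqrt{n-3}$ Fisher-scale sampling error — it
exercises the raw-data path end to end, while exact coefficient-level
checks are carried by the worked-example inputs themselves.

`estimate_rejection_rate()` is the Monte Carlo harness: it simulates
replicates under a given population structure, runs the requested tests on
each replicate's sample correlations, and reports per-test rejection
rates with binomial Monte Carlo standard errors. One seeded generator
drives each run, so results are exactly reproducible from the spec and
seed.

## Calibration results computed by the test suite

The acceptance tests run three null scenarios at $n = 100$ with 10,000
replicates each — overlapping ($\rho_{jk} = \rho_{jh} = 0.3$,
$\rho_{kh} = 0.2$), nonoverlapping ($\rho_{jk} = \rho_{hm} = 0.2$, related
correlations 0.1) and independent ($\rho_1 = \rho_2 = 0.3$) — and require
every procedure's empirical type-I error to fall in $[0.035, 0.065]$
around the nominal 0.05 (Fisher's independent-groups z is additionally
held within 3 Monte Carlo standard errors of 0.05). A smaller power
scenario ($\rho_{jk} = 0.1$ vs $\rho_{jh} = 0.5$ at $n = 300$) checks that
all procedures reject a clearly false null most of the time. These problem
sizes keep each scenario to a few seconds while leaving the Monte Carlo
standard error at $\approx 0.002$, small against the width of the
acceptance band.

## Interfaces

`compare_corr()` accepts raw data with a variable-pair specification
`~a + b | c + d` (formula or string): two data sets (or a `by` grouping
column) dispatch to the independent case; one data set dispatches on how
many variables the two pairs share (one → overlapping, with the shared
variable as $j$; none → nonoverlapping; two → error). Missing data are
handled by listwise deletion over the union of the involved variables so
that every coefficient in a dependent comparison is computed on the same
rows — the dependent-test derivations assume a single $n$. The
coefficient-level functions take the correlations by the fixed argument
names (`r.jk`, `r.jh`, `r.kh`, ...) to prevent silent mis-assignment of
related correlations, and the command-line interface requires them as
named flags for the same reason.

## Known limitations

* Only two correlations are compared; simultaneous comparisons of more
  than two, structural-equation approaches, rank/partial/robust
  correlations and bootstrap procedures are out of scope.
* All inference is asymptotic (or $t$-approximate); no exact small-sample
  distributions are provided.
* The threshold (`null.value`) convention — a magnitude claim tested via
  interval exclusion of the band — is one defensible reading of a
  "difference exceeds a threshold" hypothesis; a one-sided variant is not
  offered.
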