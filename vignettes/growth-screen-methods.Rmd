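---
title: "Methods: growth phenomics for deletion-library screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth phenomics for deletion-library screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growthscreen)
```

# The measurement model

An arrayed fitness screen grows each deletion strain of a library in
96-well plates on a robotic platform, reading OD600 every 30 minutes.
Each strain is summarised by two parameters with distinct physiology:

* **growth rate** `r` (1/h) — the maximal specific growth rate during
  exponential phase, i.e. the steepest slope of `log OD` against time;
* **growth yield** `K` (OD units) — the population density on entry into
  stationary phase.

The two parameters are nearly uncorrelated across strains, so they are
scored separately throughout.

`growthscreen`'s generating model (and the oracle for its extractors) is a
three-parameter logistic with an explicit lag,

$$
\mathrm{OD}(t) \;=\; b \;+\;
\begin{cases}
x_0 & t < \lambda\\[2pt]
\dfrac{K}{1 + \frac{K - x_0}{x_0}\, e^{-r (t - \lambda)}} & t \ge \lambda
\end{cases}
\;+\; \varepsilon_t ,
\qquad \varepsilon_t \sim \mathcal N(0, \sigma^2)\ \text{clipped at } 0,
$$

with blank `b` (medium absorbance), inoculum `x_0`, lag `λ`, and additive
reader noise. This is the simplest model in which rate and yield are
separate degrees of freedom; richer likelihood-based fits (Gompertz,
Baranyi) are deliberately out of scope.

# From wells to phenotypes

## Parameter extraction

`extract_growth_params()` works on blank-subtracted, running-median
smoothed curves (`preprocess_curve()`, window 3):

1. **Plateau / yield.** The OD derivative is estimated by a 7-point
   sliding least-squares slope, median-filtered. The stationary plateau is
   the maximal suffix where the derivative stays at or below 5% of its
   maximum, with violation gaps shorter than 3 points closed (isolated
   noisy readings must not break the suffix). The yield is the mean OD
   over the plateau. Curves that never reach a plateau (still exponential
   at the final read) fall back to `max(OD)` and are flagged `truncated`.
2. **Rate.** Sliding 5-point windows of the least-squares slope of
   `log(OD + 10^{-4})` are fitted over readings above a 0.01 OD detection
   floor. Windows must reach `R^2 >= 0.97` — this excludes lag-phase
   windows whose log-slope is dominated by reader noise. When a plateau
   exists, each window slope is divided by `1 - mean(OD)/K_hat`, the exact
   saturation factor of a logistic (for which the instantaneous log-slope
   is `r (1 - OD/K)`), windows with `mean(OD) > 0.8 K_hat` are dropped,
   and the rate is the **median** of the corrected slopes. Under the
   logistic model every growth-phase window then estimates the same `r`,
   so the median is unbiased and robust; taking the maximum of noisy
   window slopes instead is upward-biased by roughly 10% at the default
   noise level. Without a plateau the maximum raw window slope is used,
   which keeps a pure exponential exact.
3. **Lethality.** A well whose maximum blank-subtracted OD stays below
   0.05 is lethal: rate and yield are reported as 0 with the flag set, and
   such wells never enter sigma scoring.

A note on the uncorrected alternative: the raw maximal 5-point log-slope
underestimates a logistic's `r` by ~2.5% already at `x_0/K = 0.02/1.2`,
because the instantaneous log-slope is below `r` from the very first
reading. The saturation correction removes this bias (noiseless recovery
is within 0.5%), which is why the package does not use the plain
max-window-slope definition.

## Plate normalisation and sigma scoring

Every plate carries wild-type reference wells. Each well's rate and yield
are divided by the mean of the non-lethal wild-type wells on the same
plate; technical replicates are averaged per (strain, biological
replicate, plate) and then across plates. The per-well wild-type relative
values, pooled across the plates of a condition, form the empirical
wild-type distribution with mean $\mu_{WT}$ and standard deviation
$sd_{WT}$, and a strain's score is

$$\sigma = \frac{x - \mu_{WT}}{sd_{WT}},$$

the number of wild-type standard deviations its mean relative parameter
lies from the wild-type mean. Phenotypes: $|\sigma| > 2$ is non-normal,
$|\sigma| > 3$ strong, signed into `highly_impaired` / `impaired` /
`normal` / `improved` / `highly_improved`. Boundary values (exactly
$\pm 2$, $\pm 3$) go to the more extreme class — a measure-zero event that
just needs a deterministic rule. $\sigma$ is computed on the mean over
biological replicates; the replicate SEM is carried alongside but does not
enter the score. Condition summaries report percentages over scored
strains only, with lethal and unmeasured strains excluded from the
denominator but reported as counts, so either convention can be
reconstituted.

## Epistasis

For a double deletion with single-mutant relative fitness $W_A$, $W_B$
and double fitness $W_{AB}$, the interaction score is the deviation from
the multiplicative null,

$$\varepsilon = W_{AB} - W_A \cdot W_B,$$

negative aggravating, positive alleviating; a lethal double gives
$\varepsilon = -W_A W_B$. `epistasis_with_error()` computes $\varepsilon$
per biological replicate triple (paired by replicate label), then reports
the replicate mean, SEM and a **t-based 95% confidence interval**
(mean $\pm t_{0.975,\,n-1}\,\mathrm{SEM}$). The t interval matters: with
the standard three biological replicates, a naive mean $\pm 2\,$SEM band
covers the truth only ~82% of the time ($P(|T_2| \le 2) = 0.816$), so all
calibration statements in this package are made about the proper 95% CI.
Epsilon is computed separately for rate and yield.

## Upstream element enrichment and the windowed scan

Upstream flanks use half-open coordinates anchored at the first base of
the mature gene (position 0); a flank of length $L$ covers $-L..-1$, and
sequences shorter than the nominal length simply lack their distal
positions (no padding). Four conserved pol III promoter-proximal elements
are provided as defaults — T-rich stretches anchored at −53 and −30, a
TATA-like element at −42 and a transcription-start element at −13, each
searched within ±4 bp. The consensus strings (`TTTT`, `TATAWA`, `YYCAA`)
are pragmatic IUPAC stand-ins for published profile matrices and are fully
configurable; they are not calibrated against any external matrix.

Enrichment of an element in a phenotype class is the hypergeometric upper
tail $P(X \ge k)$ with universe $N$ (classified genes whose flank covers
the search window), $K$ carriers, class size $n$, $k$ carriers in the
class; p-values are reported raw as $-\log_{10} p$, one test per
element × class cell, matching how such matrices are usually displayed.

The windowed k-mer scan emulates a positionally constrained motif search:
a 9-bp window slides across the upstream region; within each window every
exact k-mer (4–8 bp) present in at least two foreground sequences is
tested for over-representation against the background set by a one-sided
Fisher exact test (computed as the hypergeometric tail), and the window's
E-value is the best p times the number of k-mers tested in that window.
This deliberately replaces EM-based motif discovery with exhaustive
enumeration: it is deterministic, exact, and sufficient for anchored
elements; it cannot learn degenerate position-weight motifs, so its
output is compared to profile-based searches qualitatively (which windows
light up), never numerically.

Because ~92 heavily overlapping windows are scanned, the per-window
E-value does not control the familywise error of the whole scan: under
the null, *some* window reaches `E < 0.05` in roughly half of runs. The
scan therefore also reports `e_value_scan` (per-window E × number of
windows tested). Calls of the form "did the scan find anything" should
threshold `e_value_scan`; measured on seeded null simulations this keeps
the scan-level false-positive rate at zero out of 40 runs while a strongly
planted 6-mer still scores $\log_{10} E \approx -15$.

# The synthetic screen

`simulate_library()` generates the full study: a truth table of planted
effect classes (deterministic largest-remainder assignment), plates for
every condition × biological replicate with wild-type and blank wells,
and optional double mutants constructed exactly on the multiplicative
null, $W_{AB} = W_A W_B + \varepsilon_{\text{planted}}$, so the epistasis
estimator has a true zero to recover.

Default conditions, chosen once as typical for a yeast plate screen:

| parameter | default | meaning |
|---|---|---|
| `dt` | 0.5 h | read every 30 min |
| `t_max` | 30 h | long enough for the wild type to hold a ≥3-point plateau at the 5% derivative threshold (a 24 h read is not) |
| `od0`, `K_wt`, `r_wt`, `lag_wt` | 0.02, 1.2, 0.4/h, 2 h | wild-type logistic |
| `blank_od` | 0.08 | medium absorbance |
| `noise_sd` | 0.005 OD | additive reader noise |
| `cv_bio` | 2% | lognormal culture-to-culture variation on rate and capacity |
| replicates | 3 biological × 12 technical | 36 wells per strain per condition |
| plate layout | 4 WT + 2 blank wells per 96 | ≥4 wild-type references per plate |

Two modelling choices deserve emphasis:

* **Wild-type wells are independent isolates.** Each wild-type well draws
  its own biological multiplier. If all wild-type wells on a plate shared
  one culture, the wild-type reference distribution would collapse to
  technical noise and every strain with normal biology would score
  $|\sigma| \gg 2$. Independent isolates give the reference the same
  biological variance the strains have.
* **Planted effect sizes.** The default truth specification plants strong
  effects as 0.90 multipliers: at `cv_bio = 2%` these sit about five
  wild-type standard deviations below 1, i.e. they are unambiguous
  phenotypes that a correct pipeline must classify as impaired, while
  0.95 multipliers probe the boundary region.

What the generator does **not** emulate: diauxic shifts, evaporation and
edge effects, condition-specific growth mechanisms, position effects on
the plate, or correlated reader drift. Passing recovery tests on this
generator therefore demonstrates the correctness of the estimators under
the stated noise model, not robustness to every artefact of real plate
data.

Seeding: one master seed; per-plate noise streams derive from it by a
stable string hash of (condition, plate index), and per-condition culture
draws by a hash of (condition). Regenerating any subset of plates in any
order reproduces identical data.

# Numerical choices and degenerate inputs

* Log floor `1e-4` inside the rate fit avoids `log(0)` after clipping;
  detection floor 0.01 OD keeps sub-noise readings out of windows.
* A blank at or above the curve maximum flags `no_growth`; it is not an
  error. Fewer detectable points than a window gives a no-growth result,
  never an exception.
* A wild-type reference requires ≥3 values and positive spread; ties at
  class boundaries go to the extreme class; duplicate conflicting scores
  for one matrix cell are an error rather than silently resolved.
* `epistasis_value(0 fitness)` is valid (lethal double); SEM with a
  single replicate is undefined and rejected.
* Fisher's one-sided p is computed as `phyper` on the 2×2 margins, which
  is exact and fast; `fisher.test` is used as an independent oracle in the
  test-suite only.

# Validation scale

The shipped validation (test-suite acceptance blocks and
`scripts/acceptance.R`) runs, per seed: 2,000 null strains for tail
calibration; one full 200-strain screen (3×12 replicates, ~8,000 wells)
for parameter recovery and phenotype classification; 100 seeded pairs for
epistasis CI coverage; all 1,635 hypergeometric configurations with
N ≤ 12 against draw enumeration; and 1 planted + 20 null motif scans over
141 genes. These sizes make every check rerun in a few minutes on one
core while leaving the statistical margins wide (e.g. measured RMSE
~1.3% against the 3% requirement).

# Known limitations

* Rate extraction assumes a single exponential phase; diauxic curves
  would be summarised by whichever phase wins the window search.
* The saturation correction uses the plateau estimate `K_hat`; curves
  truncated before stationary phase fall back to the uncorrected maximal
  slope, which is noisier and slightly right-skewed for nearly saturated
  curves.
* Lag time is not reported as a phenotype.
* Element consensus defaults are stand-ins; users with profile matrices
  should supply their own consensus strings or tolerances.
* The scan tests exact k-mers only; a motif more degenerate than its most
  frequent exact word is detected only through that word.
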