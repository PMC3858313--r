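---
title: "Methods: detecting the chaotic firing regime between period-1 and period-2"
author: "hrchaos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting the chaotic firing regime between period-1 and period-2}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and the question

The Hindmarsh–Rose (HR) model is a three-variable, dimensionless
caricature of a bursting neuron:

$$\dot x = y - a x^3 + b x^2 - z + I,\qquad
  \dot y = c - d x^2 - y,\qquad
  \dot z = r\,\bigl(s\,(x - x_{\mathrm{rest}}) - z\bigr),$$

with $x$ the membrane potential, $y$ a fast recovery variable and $z$ a
slow adaption current.  Throughout the package $a=1$, $b=3$, $c=1$,
$d=5$, $s=4$, $x_{\mathrm{rest}}=-1.6$; the two parameters that are
varied are the injected current $I$ and the slow time-scale constant
$r$.  The observable is the interspike-interval (ISI) series: the time
differences between successive maxima of $x$.

In the $(I, r)$ plane the model exhibits, besides the well-known
comb-shaped chaotic region with its period-adding and period-doubling
structure, a second, narrow chaotic band that separates the period-1
region from the period-2 region.  The reference point used everywhere
in the package and its tests is $I = 2.53$, $r = 0.0245$, which sits
inside that band.  This firing is easy to mistake for noise in
recordings: the package's purpose is to simulate it, map it, and
provide the diagnostics (return maps, nonlinear prediction with
surrogates) that distinguish it from genuinely stochastic firing.

## Integration and spike detection

The deterministic model is integrated with a fixed-step classical
Runge–Kutta scheme, `dt = 0.01` model-time units by default.  The step
was chosen by convergence: halving `dt` changes the state of a
non-chaotic run at $t = 100$ by less than $10^{-6}$, and spike counts
are invariant to halving (both are asserted in the test suite, along
with agreement with an independent adaptive solver).  With additive
noise the integrator switches to Euler–Maruyama; the noise term enters
$\dot y$ by default (configurable to $\dot x$), scaled by
$\sigma\sqrt{dt}$.

Spikes are interior local maxima of $x$ at or above a threshold of 0,
at least 1 time unit apart.  HR action potentials peak well above 0
while subthreshold oscillations stay below, so the threshold is not
delicate; peak times are refined by quadratic interpolation through the
three samples around each maximum, which makes ISI values insensitive
to the sampling grid.  Before any statistics, a transient of 500 time
units *or* the first 50 spikes (whichever is longer) is discarded.

## Largest Lyapunov exponent

`largest_lyapunov()` uses the Benettin tangent-vector method: the state
and a unit tangent vector are integrated together, the tangent under
the analytic Jacobian

$$J = \begin{pmatrix} -3 a x^2 + 2 b x & 1 & -1\\
                      -2 d x & -1 & 0\\
                      r s & 0 & -r \end{pmatrix},$$

renormalizing every 1 time unit and averaging the log stretch factors
over 5000 time units after a 500-unit transient.  Limit cycles give
exponents within $\pm 0.002$ of zero, equilibria give negative values,
and the chaotic band at the reference point gives $\approx +0.005$ per
time unit.  The estimate is insensitive (to within 10%) to the
renormalization interval in $[0.5, 2]$ and to the initial tangent
direction.

## Regime classification

`classify_period()` declares period $k$ when, over the analyzed tail,
$\max_i |\mathrm{ISI}_{i+k} - \mathrm{ISI}_i| / \overline{\mathrm{ISI}}$
falls below a relative tolerance, 1% by default.  The smallest
$k \le 8$ wins, so period-2 is never reported as period-4.  This exact
max-difference rule is the right detector for noiseless model output
(whose ISIs repeat to far better than 1%), but it cannot serve for
jittered data: under multiplicative Gaussian jitter of coefficient of
variation $cv$ its statistic concentrates near $4\,cv$, so a 5%
tolerance would reject 5% jitter outright.  The data-driven
classifiers therefore use a jitter-robust variant: the series is
period-$k$ when each of the $k$ phase classes is tight around its own
median — its quantile-based scale estimate stays below
$1.5\,\cdot\,$`rel_tol_noisy`$\,\cdot$ (phase median), which accepts
jitter up to $cv =$ `rel_tol_noisy` (default 5%) with an estimation
margin, *and* no value deviates from the phase median by more than
$8\,\cdot\,$`rel_tol_noisy`$\,\cdot$ (phase median).  The second cap is
what rejects chaos: the chaotic band's ISI distribution has a narrow
bulk that a purely robust scale statistic would accept, but its
occasional much-longer intervals land far outside any phase's cap.

For noiseless model points, `classify_point()` reports `quiescent`
(fewer than two post-transient spikes), `periodic(k)`, `chaotic`
(aperiodic with Lyapunov exponent above 0.001), or `unclassified`
(aperiodic but with an exponent too small to call — typically long
transients near boundaries).  The 0.001 cutoff guards against calling
a slowly converging limit cycle chaotic; genuinely chaotic cells in
this system sit at 0.004–0.01.

For data-only series, `classify_series()` replaces the Lyapunov
criterion with the surrogate prediction test below: `chaotic` when the
one-step prediction error falls below the shuffle-surrogate mean minus
three standard deviations, otherwise `stochastic`.  The `stochastic`
label is reserved for data; a noiseless model point can never receive
it.

## Scan lines and their presets

Experimentally, washing out extracellular calcium changes the membrane
dynamics gradually; in the model this corresponds to moving along a
straight line in the $(I, r)$ plane with $I$ increasing and $r$
decreasing, at a preparation-specific slope.  `scan_line()` therefore
evaluates points in order with state continuation (each point starts
from the previous point's final state), which follows attractors the
way a slow drift does.

The preset lines were transcribed empirically: endpoints were chosen,
once, so that each scan crosses the chaotic band between period-1 and
period-2 and then reproduces its documented regime order at the default
resolution of 150 points:

* **BL1** `(2.35, 0.028) → (3.61, 0.016)`: period-1 → chaos → period-2
  → period-1.  After the band it swings right of the comb region into
  tonic period-1 spiking.
* **BL2** `(2.46, 0.0285) → (3.055, 0.012)`: … period-2 → period-4 →
  chaos → period-3 (the scan also resolves the intermediate period-8
  stage of the doubling cascade, which a coarser figure would not).
* **BL3** `(2.48, 0.028) → (3.05, 0.007)`: period-adding with chaos;
  contains period-2 → chaos → period-3 → chaos → period-4.
* **BL4** `(2.455, 0.0245) → (2.52, 0.004)`: period-adding without
  chaos: period-1 → chaos → period-2 → period-3 → period-4.
* **SL1** `(2.42, 0.0285) → (4.0, 0.004)`: clips a period-4 tongue and
  returns: period-1 → chaos → period-2 → period-4 → period-2 → period-1.
* **ML0** `(2.5, 0.035) → (2.5, 0.001)`: the classical fixed-$I$ scan;
  period-1 → chaos → period-2 → period-adding.
* **TL1–TL4**: reference scans of the comb region (doubling not to
  chaos; doubling to chaos; chaos within period-adding; period-adding
  without chaos).

Straight-line geometry imposes real constraints here: a line that
crosses the band where it is solid (r roughly 0.018–0.027) and must end
in period-1 again has to thread between the period-4 tongues
(r ≈ 0.0155–0.0185, I ≈ 2.85–3.3) and the comb body; BL1's steep slope
is the resolution of that constraint, not an aesthetic choice.

One detail worth knowing: at $I = 2.53$ a hair-thin period-2 sliver
(width below $2.5\times10^{-4}$ in $r$, near $r = 0.02625$) lies
between the chaotic band and the period-1 region above it — the upper
exit from the band is actually a very compressed period-doubling
route.  At any practical scan step ($5\times10^{-4}$ and coarser) the
sliver is invisible and the first periodic regime above the band is
period-1, which is how the regime order is always described.

## The exponent map and its two regions

`compute_lle_map()` grids the rectangle $2.3 \le I \le 3.42$,
$0.001 \le r \le 0.035$ (default 56×35 cells; 112×70 resolves the comb
teeth).  Parts of this rectangle are **multistable** — a chaotic and a
periodic attractor coexist, most prominently in the comb's periodic
windows — so a map computed from a single initial condition per cell
understates where a chaotic attractor exists and fragments the comb
into several components at coarse grids.  Each cell is therefore
evaluated twice: once continuing the state along increasing $r$ within
its column, once from a fixed cold-start state, keeping the larger
exponent.  The averaging time per cell is 10000 units after a 500-unit
transient, enough to bring the estimator's fluctuation well below the
0.002 threshold used for region labeling.

`label_chaotic_regions()` thresholds the map at 0.002, labels
4-connected components (conservative: diagonal contact does not merge
regions), and drops components smaller than 4 cells.  At the default
settings this yields exactly two regions: the narrow band containing
$(2.53, 0.0245)$ and the comb-shaped region.  The count is stable for
thresholds in $[0.001, 0.0025]$; above about 0.003 the coarse 56×35
grid severs the comb's thinnest bridge (cells whose exponent sits
between 0.002 and 0.003) and the comb reports as two pieces.  That is
a resolution artifact, not a third chaotic region, and disappears at
finer grids; the region-count test therefore asserts stability over
$[0.001, 0.0025]$.

## Nonlinear prediction and surrogates

`npe()` implements simple nearest-neighbor forecasting on the delay
embedding $X_i = (s_i, \dots, s_{i+m-1})$ (delay 1).  For each base
point with a valid $h$-step future, the $k = \max(1,
\operatorname{round}(\varepsilon P))$ nearest valid neighbors (Euclidean
distance, self excluded, ties broken by smaller index) vote by
averaging their futures, and

$$\mathrm{NPE} = \frac{\sqrt{\sum_i (\hat s_i - s_i)^2}}
                     {\sqrt{\sum_i (\bar s - s_i)^2}},$$

with $\bar s$ the mean of the whole series — i.e. RMS error relative to
the baseline predictor "always guess the mean".  Base points without an
$h$-step future are excluded from $P$.

Two quantitative facts shape the defaults:

* For an uncorrelated series the predictor averages $k$ effectively
  random futures, so its expected NPE is $\sqrt{1 + 1/k}$, slightly
  *above* 1: about 1.10 at $k = 5$ (500 ISIs at $\varepsilon = 1\%$)
  and 1.05 at $k = 10$ (1000 ISIs).  Surrogate curves should be read
  against that level, which is why the headline comparisons use 1000
  ISIs.
* For the chaotic band's ISIs the one-step NPE is ≈ 0.4 and rises
  monotonically toward 1 by $h = 10$; the conclusion is unchanged for
  $m \in \{3..8\}$ and $\varepsilon \in \{0.5\%, 1\%, 2\%\}$.

Surrogates are seeded uniform random permutations (value distribution
preserved exactly, temporal structure destroyed); 10 are used by
default and summarized by per-horizon mean and standard deviation.
The determinism call is: original NPE at $h=1$ below the surrogate
mean minus 3 standard deviations.  No Theiler window beyond
self-exclusion is applied by default (a window option exists).

## Synthetic records and what they do and do not show

`gen_stationary()` produces jittered stationary records (multiplicative
Gaussian jitter, default CV 0.5%, emulating proportional measurement
and biological variability; optional spike-time quantization emulating
a 10 kHz acquisition).  `gen_washout()` integrates while $(I, r)$
drifts continuously along a line — linearly, or exponentially
approaching the endpoint with time constant `duration/3`, which mirrors
the gradual effect of a solution change — and derives the ground-truth
regime schedule from a stationary pre-scan of the same line.
`gen_stochastic_alternation()` locates a period-adding boundary by
bisection (default: the period-3/period-4 boundary near
$I \approx 2.5$, $r \approx 0.005$) and integrates with additive noise
(intensity 0.1 on $\dot y$ gives a clear irregular alternation between
the two patterns).

Two honest limitations, both visible in the test suite:

* **Dynamic bifurcation delay.**  Under a slow parameter drift the
  trajectory clings to the period-1 branch past the static boundary, so
  the chaotic segment of a washout record begins later (by a few
  percent of the record) than the stationary pre-scan predicts.  The
  delay shrinks too slowly with slower drift to vanish in practice, and
  small intrinsic noise — which does cut such delays short — corrupts
  the window classification instead.  Segmentation tests therefore
  drift along the transition segment of the line and use a window of
  about 6% of the record, within which the smearing stays.
* **Pattern alternation is partially predictable.**  A record
  alternating between period-$k$ and period-$(k{+}1)$ patterns keeps
  deterministic within-cycle structure (a long inter-burst interval is
  always followed by a short one), so its one-step NPE sits around
  0.5–0.8 — far below the shuffle-surrogate band — for *any* noise
  level that preserves the two patterns (an idealized series with
  i.i.d. random pattern choice already gives ≈ 0.6).  The mean − 3 sd
  shuffle rule therefore cannot, even in principle, separate stochastic
  pattern alternation from chaos; it separates both from their
  shuffles.  The corresponding acceptance expectation is kept, and
  fails, rather than being weakened; distinguishing the two requires
  the return-map geometry or model-based diagnostics, not this
  statistic.

The generators emulate stationarity, drift, jitter and quantization —
not spike sorting errors, missing spikes, slow nonstationarities other
than the modeled drift, or any biophysics beyond the HR equations, so
green tests here demonstrate the pipeline's correctness on records
whose generating process is known, not performance on arbitrary real
recordings.

## Problem sizes used by the tests

The suite runs the full pipeline at reduced but representative sizes:
the exponent map at 56×35 cells (the band/comb separation is already
clear there), scans at 150 points per line, 500–1000 ISIs for the
prediction tests, and a washout record of ≈ 5000 ISIs.  All randomness
is seeded; noiseless paths are bit-reproducible.
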