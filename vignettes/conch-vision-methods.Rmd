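---
title: "Methods: looming psychophysics and eye optics in conchvision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: looming psychophysics and eye optics in conchvision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conchvision)
```

`conchvision` reimplements, as a tested pipeline, the computational content
of a behavioural-plus-anatomical study of spatial vision in a strombid
gastropod: calibrated expanding stimuli, behavioural threshold inference,
and eye-optics estimation, with a synthetic observer in place of the animal
data. This vignette documents the models, the parameter choices that matter,
and what the package's passing tests do and do not establish.

## Viewing geometry and expansion profiles

A flat screen at distance $D$ maps an on-screen width $w$ to visual angle
$\alpha = 2\arctan(w/2D)$; `angular_size()` and `physical_width()` are exact
inverses (round-trip checked to $10^{-9}$ relative). The default geometry is
the experimental setup: $D = 50$ mm, and a cylindrical vessel of 60 mm
radius recorded but not modelled — its curvature only blurs and shrinks the
image in the curved plane, so behavioural acuity measured through it is a
limiting (conservative) value.

Two expansion paradigms drive the looms, both growing from ~0° to 83°:

- **exponential** (contrast experiment): $\alpha(t) = \alpha_0 e^{\gamma t}$
  with $\gamma = \ln(\alpha_{max}/\alpha_0)/T$, $T = 10$ s. This is constant
  $\dot\alpha/\alpha$, the profile of an object approaching at constant
  speed-to-size ratio. The seed size $\alpha_0$ defaults to the angular size
  of one pixel (~0.29° at the default geometry): an exponential cannot start
  at exactly 0°, and one pixel is the smallest renderable object.
- **linear** (resolution experiment): $\alpha(t) = \alpha_{max}\, t/T$,
  $T = 5$ s.

The study's prose describes the *area* of the circle as growing
exponentially / at a constantly increasing rate, while its figures plot
*angular size* as exponential / linear in time; the package follows the
figures, because reported event angles are read off those curves. Both
trajectories are strictly increasing and hit $\alpha_{max}$ exactly at $T$;
`time_to_reach()` inverts them so behavioural event times can be expressed
as stimulus angular sizes. A degenerate exponential profile with
$\alpha_0 = \alpha_{max}$ collapses to the constant $\alpha_{max}$.

The frame rate defaults to 60 fps, a common LCD refresh; the study does not
report one.

## Photometry: contrast labels and isoluminance

The display model maps byte $b$ to relative luminance $L = (b/255)^\gamma$.
The default is $\gamma = 1$ (bytes linear in luminance): it is the only
choice that reproduces the stimulus labels the study prints (byte 220 on
255 → Michelson contrast 0.07; 210 → 0.10). The checkerboard grey the study
used (153 rather than ~127) implies the physical monitor was non-linear,
$\gamma \approx 1.357$; since the monitor calibration is unreported, the
package exposes $\gamma$ as configuration and documents the caveat:

```{r}
contrast_label(220, 255)
isoluminant_grey(0, 255)                         # linear display
isoluminant_grey(0, 255, display_model(1.357))   # the study's grey
```

Contrast labels round to two decimals only at the reporting step; internal
arithmetic is unrounded. `isoluminant_grey()` minimises
$|L(g) - \tfrac12(L(\mathrm{black}) + L(\mathrm{white}))|$ over bytes, ties
broken toward the lower byte (so a 0/255 board on a linear display gives
127, not 128).

Rendering conventions the study leaves unstated and the package fixes: the
checkerboard is anchored at the frame's top-left corner with a white check
first; the disc is centred on the frame; check pixel width is the rounded
physical width over the pixel pitch, and a check below one pixel is a
configuration error rather than a silently aliased stimulus. A disc that
outgrows the frame clips with a warning. Frames are written as 8-bit
greyscale PNG, which round-trips byte-exactly.

## Eye optics

With rhabdom-centre separation $s$ and focal length $f$, the
inter-receptor angle is the small-angle form $\Delta\varphi = s/f$
(the arctangent differs by under $10^{-4}$ degrees at these magnitudes),
and the anatomical resolution limit is one grating period sampled by two
receptors, $2\Delta\varphi$. Focal length may be supplied directly or as
$f = 2r$ from the lens radius, the ratio measured in strombid lenses.
Reported values follow the study's printing convention: angles to two
decimals, and the resolution as *twice the rounded* inter-receptor angle —
`eye_anatomy()`'s defaults give $\Delta\varphi = 0.517° \to 0.52°$ and a
reported resolution of $1.04°$ (doubling before rounding would print
1.03°; the package keeps the unrounded value available in
`optical_estimates()`).

Optical sensitivity uses Land's equation for an extended source,
$$ S = \left(\frac{\pi}{4}\right)^2 A^2 \left(\frac{d}{f}\right)^2
   \left(1 - e^{-kx}\right) \quad [\mu m^2\,sr], $$
with aperture $A$, rhabdom diameter $d$ and length $x$, and absorption
coefficient $k = 0.0067\,\mu m^{-1}$. The exponential absorption factor was
chosen (over the $kx/(2.3+kx)$ alternative) because it reproduces the
study's printed value with its printed inputs. $S$ is strictly increasing
in $A$, $d$, $x$ and decreasing in $f$ (property-tested).

The retinal census extrapolates counts in a sectioned patch to the whole
eye: `count × total_area / sampled_area`, rounded to the nearest 100 cells.
The package stores areas in µm² and takes the default sampled area as
2048 µm² — a 204.8 µm block-face width × 10 µm of sectioning depth. (The
study prints the sampled area with a positive exponent, $2.048\times10^3$
mm², which is dimensionally inconsistent with its own extrapolation; only
$2.048\times10^{-3}$ mm² reproduces the printed per-eye total.) Densities
are reported to three significant figures.

`acuity_blur()` renders a scene as seen at a given acuity by Fourier-domain
filtering with the Gaussian modulation transfer function
$\mathrm{MTF}(\nu) = \exp(-3.56\,(\alpha_{min}\nu)^2)$, $\nu$ in
cycles/degree — the convention of the acuity-visualisation literature, under
which a grating at the resolution limit $\nu = 1/\alpha_{min}$ retains
$e^{-3.56} \approx 2.8\%$ of its amplitude. Boundaries are periodic;
mean luminance is preserved exactly and variance never increases.

## Trial model and threshold inference

Behaviour is recorded under a five-category ethogram in severity order:
stop feeding, partial/full proboscis withdrawal, partial/full eyestalk
withdrawal. A trial counts as a **response** only if it contains a
transition beyond stop-feeding: feeding pauses occur spontaneously, and the
exclusion reduces false positives. The response unit is the trial
(individual × repeat; 20 × 2 = 40 for contrast, 19 × 2 = 38 for
resolution), matching the per-level n the study reports; a per-individual
collapse (responded in ≥ 1 repeat) is available but not the default.

Per-level responder counts get Wilson score intervals, which keep good
coverage at these n and at extreme proportions. Each level is compared with
the control by Fisher's exact test, two-sided under the usual
probability-mass rule (the study does not state sidedness; its printed
p-values are unrecoverable anyway because the control's responder count is
unreported, so the implementation is validated against exhaustive
hypergeometric enumeration rather than against printed values). Bonferroni
correction uses $m$ = number of non-control levels (9 contrast, 8
resolution), configurable. The threshold is the *smallest* level whose
adjusted p-value is ≤ α = 0.05 — significance against control, not merely
any response, reconciling the looser "lowest contrast that elicited a
response" phrasing with the exact-test reporting. For the resolution
experiment the minimum resolvable angle is twice the threshold check width
(a check is half a grating period). If no level is significant the outcome
is explicitly "no threshold".

Spearman correlations use average ranks; p-values come from exact
permutation enumeration for $n \le 9$ without ties (at most $9!$ orderings,
evaluated in closed form over an insertion-generated permutation matrix)
and the t-approximation otherwise. The paired Wilcoxon repeat check drops
zero differences and is exact up to 15 untied pairs. Degenerate inputs are
defined, not errors: identical repeats give $V = 0, p = 1$; a constant
vector leaves $\rho$ undefined with a warning; empty margins give $p = 1$.

## The synthetic observer

The generator replaces the unreleased animal data with the statistical
structure the analysis assumes. Responses are Bernoulli draws from a
high-threshold psychometric function on log level,
$$ P(x) = \gamma_g + (1 - \gamma_g - \lambda)\,
   \Phi\!\left(\frac{\ln x - \ln\theta}{\sigma}\right), $$
with the control at the guess rate $\gamma_g$. The log-normal core was
chosen because both level series span about a decade; a logistic core would
behave equivalently behind the same interface. Individuals draw
$\ln\theta_i \sim N(\ln\theta, \sigma_{ind})$; all randomness runs through
per-individual substreams derived deterministically from one global seed,
so tables are byte-for-byte reproducible.

Defaults were fixed once from the study's printed summaries and not
revisited:

| parameter | contrast | resolution | rationale |
|---|---|---|---|
| θ | 0.09 | 0.45° | contrast: back-solved from the printed 20% response at C = 0.07 and 62.5% at C = 0.10; resolution: between the 0.4° and 0.53° levels, making 0.53° the identifiable target |
| σ (log units) | 0.29 | 0.08 | same back-solution; resolution responding is near-step around threshold |
| guess, lapse | 0.02 | 0.02 | no spontaneous control rate is reported; 2% is a synthetic convention |
| σ_ind | 0.05 | 0.05 | mild individual spread |
| re-emergence base/gain/noise | 90 s / 25 s / 15 s | same | the study plots re-emergence rising with level but prints no values; conventions only |

The check-width series `{0.3, 0.4, 0.53, 0.8, 1.1, 1.6, 2.2, 3.2}`° fills
the study's stated 0.3–3.2° range (8 stimuli) in near-geometric steps with
the 0.53° level present; the study prints only the endpoints and the
threshold level.

Responding trials receive 2–5 events in strict severity order placed at
increasing angular sizes via `time_to_reach()` (so severe transitions occur
late in the expansion, stop-feeding early, and full withdrawals only in
responding trials); 30% of non-responding trials show a stop-feeding-only
pause, exercising the exclusion rule. Exact event-timing distributions are
unconstrained by the study and are synthetic conventions.

**What the generator does not emulate:** habituation or sensitisation
across repeats (the study found no repeat effect), attention lapses
correlated in time, the two-threshold structure of early alerting vs late
escape, response-latency distributions tied to the physical loom kinetics,
and any monitor non-idealities. Passing recovery tests therefore show that
*the inference pipeline recovers the thresholds of data satisfying its own
assumptions at the study's sample sizes* — not that the study's animal
thresholds are correct.

## Problem sizes and numerical choices

The test suite runs the full design (19–20 individuals × 2 repeats),
a 5,000-trial-per-level convergence check of the simulator against its
psychometric function, a 200-replicate threshold-recovery study (modal
recovery at the designed 0.53° level), and exhaustive-enumeration oracles
for Fisher (all 2×2 tables at small margins), Wilcoxon ($2^6$ sign
assignments) and Spearman ($5!$ permutations) — sizes chosen so the whole
suite completes in a couple of minutes on one core. Geometry inverses are
tested to $10^{-9}$ relative; the isoluminance contract to 0.5% on a
balanced board; MTF attenuation to $10^{-6}$.

## Limitations

- The monitor's gamma and pixel pitch are unreported, so absolute pixel
  sizes and the grey-153 calibration can be rationalised but not
  reproduced; all photometric defaults assume the linear display that
  matches the printed contrast labels.
- Printed Fisher p-values and correlation coefficients of the study depend
  on the unreleased trial data (including the control responder count) and
  are not targets; the package validates its statistics against
  enumeration oracles instead.
- The anatomical estimates derive from a single sectioned eye; the package
  propagates no between-eye variance.
- Cylindrical-vessel optics are recorded, not modelled; behavioural acuity
  through the curved wall is a limiting value.
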