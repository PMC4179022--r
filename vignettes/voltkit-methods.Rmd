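---
title: "Voltammetric post-processing with voltkit: models, conventions and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voltammetric post-processing with voltkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
library(voltkit)
```

voltkit post-processes controlled-potential electrochemical records: it
parses the heterogeneous ASCII files that potentiostats export, pretreats
voltammograms (smoothing, background subtraction, IR-drop and double-layer
correction, conversion to dimensionless form), applies derivative, integral
and half-order ("semi") transforms, performs generalized elimination
voltammetry, and evaluates peaks and waves against cursor-defined baselines.
This vignette explains the models behind each step, the conventions the
package commits to where the field leaves a choice open, and the numerical
decisions that matter for interpreting results.

## The voltammogram container

Everything flows through one tabular object: a `voltammogram` is a tibble
with columns `potential` (V), `current` (A) and `time` (s), plus attributes
for the scan rate, the plotting orientation (IUPAC: anodic currents
positive) and a label. Instrument files record potential and current but not
time, so when no time column is supplied it is reconstructed as

$$t_j = \frac{1}{v}\sum_{i \le j} |\Delta E_i|,$$

the cumulative swept potential divided by the scan rate. This supports
direction reversals in cyclic experiments; it assumes the instrument swept
at the nominal rate throughout, which is true of the applied (staircase)
ramp but only approximately true of a severely IR-distorted potential axis.
When a record's true clock is known — as for the synthetic generators — it
is attached explicitly and all operators use it.

## Parsing potentiostat ASCII exports

Instrument exports differ in delimiters (space, tab, semicolon, sometimes
comma), decimal marks, line endings, header text and column layout. The
parser makes the informal "skip the headers" behaviour precise: a line is
*numeric* under a dialect iff it splits into two or more items that all
parse as reals under that dialect's decimal mark, and a *block* is a maximal
run of numeric lines with a constant column count. Any text line — before,
between or after blocks — is retained as header text and separates traces.

The decimal comma requires a commitment: `12,5 17,3` is one ambiguous
soup of digits unless the roles of comma and delimiter are fixed. The
package mirrors the convention of instrument software: with a decimal
point, the comma is an extra item delimiter; with a decimal comma, it
cannot be. Sniffing tries the decimal point first, because almost every
decimal-comma file is *also* consistent with the point reading; reading a
decimal-comma file therefore requires `decimal_mark = ","`, exactly as the
corresponding checkbox must be ticked in instrument software. Scientific
notation is accepted; thousands separators are not (irresolvably ambiguous
with the decimal comma). Files are assumed UTF-8 with a Latin-1 fallback;
binary files are rejected with a clear error rather than mis-parsed.

Two layouts cover the observed multi-curve exports: `paired_xy`
(`X1 Y1 X2 Y2 ...`, the default, with a curve selector) and `shared_x`
(`X Y1 Y2 ...`). A block with an odd column count cannot be paired and
raises an error naming the problem.

## Pretreatment

**Savitzky–Golay smoothing** (`smooth_current()`) fits a local polynomial of
order $k$ over a window of $2m+1$ points by least squares and keeps the
centre value; only the current axis is touched. At the record ends the
window *shrinks symmetrically* (capping the order at the number of offsets)
instead of padding or filtering asymmetrically: a sweep turn is a physical
event, and fabricating data across it would smear the switching transient.
The cost is slightly less smoothing over the outermost $m$ points. Exact
polynomial reproduction up to order $k$ holds everywhere, including the
shrunk edges.

**Background subtraction** (`subtract_background()`) subtracts a blank
point-for-point and deliberately refuses mismatched potential axes (beyond
$10^{-9}$ V) instead of silently interpolating: a blank recorded on a
different grid is usually a sign the experiments differed in more than the
analyte.

**IR-drop and double-layer correction** (`correct_ru_cdl()`) implements the
classical two-step correction for records where hardware compensation was
unavailable. The potential axis is corrected by the ohmic drop across the
uncompensated resistance $R_u$,

$$E'_t = E_t + I_t R_u,$$

and the current by the charging contribution of a potential-independent
double-layer capacitance $C_{DL}$,

$$I_{F,t} = I_t + C_{DL}\frac{dE'_t}{dt} + R_u C_{DL}\frac{dI_t}{dt},$$

with central-difference time derivatives (one-sided at the ends; second
order, no phase shift). Because the corrected potential axis is no longer
uniformly spaced, the result is linearly re-interpolated onto a uniform
grid per sweep direction, with the input's point count. Setting both
parameters to zero is the identity (up to that re-grid); $C_{DL}=0$ with
$R_u>0$ gives the separate IR-only correction.

The sign of the ohmic term is convention-dependent: $+I R_u$ is correct for
one current-sign convention and wrong for the other, and instrument files
do not announce theirs. The package implements the form above and exposes
`ir_sign = -1` to flip it, rather than guessing from the data. For the same
reason the helper `estimate_cdl()` — a least-squares fit of current against
the local sweep rate over a user-chosen non-Faradaic window — reports the
capacitance magnitude only.

**Dimensionless form** (`to_dimensionless()`) divides the current by
$F A C \sqrt{D F v / (R T)}$, the normalization under which reversible
voltammograms of different conditions superimpose. The package
simultaneously rescales the time axis to the dimensionless time
$\tau = (F v / R T)\, t$. This second step is essential and easy to
overlook: the semiintegral of the dimensionless current plateaus at the
apparent number of transferred electrons only when the half-order operator
runs over $\tau$, because half-order integration carries units of
$\mathrm{time}^{1/2}$. With both rescalings, `semiintegrate()` applied to a
dimensionless reversible record reads out $n$ directly at the plateau.

## Transforms

`vg_derivative()` and `vg_integral()` are plain central differences and
cumulative trapezoids over the time axis. The half-order pair is the
scientific core:

`semiintegrate()` applies the Riemann–Liouville operator of order $-1/2$
using the Grünwald–Letnikov (G1) discretization on a uniform step
$\Delta t$:

$$m_j = \sqrt{\Delta t}\,\sum_{k=0}^{j-1} w_k\, I_{j-k},
\qquad w_0 = 1,\; w_k = w_{k-1}\,\frac{k - 1/2}{k}.$$

The weight recursion is exact rational arithmetic on floats and makes runs
bit-reproducible; the convolution itself is evaluated by FFT, which changes
nothing but the cost ($O(N \log N)$ instead of $O(N^2)$). G1 was chosen
over Riemann-sum and higher-order schemes because it is the standard of the
electrochemical literature, parameter-free, and exactly linear.
`semidifferentiate()` is semiintegration followed by ordinary
differentiation, in that order; transforms all return records of the input
length, so they compose freely.

Two numerical properties of G1 matter when reading results:

* For a signal that starts at a nonzero value (a potential step), the
  pointwise relative error at the $j$-th sample decays like $1/(8j)$
  regardless of the step size — about 11 % at the first point, 0.1 % by the
  hundredth. Accuracy statements in the tests are therefore made in the
  natural norm for this operator: maximum absolute error relative to the
  signal scale (under which the constant-current closed form
  $\frac{d^{-1/2}}{dt^{-1/2}} 1 = 2\sqrt{t/\pi}$ is reproduced to 0.9 % at
  $N = 10^4$), supplemented by a pointwise bound after the initial 5 % of
  the record.
* In that signal-scale norm the scheme converges at order $1/2$ for
  stepped inputs and at order $\approx 1$ for smooth inputs vanishing at
  $t=0$ — both checked empirically in the test suite.

The neopolarogram (semiintegral of a cyclic voltammogram) doubles as a
diagnostic: for a reversible couple with no uncompensated resistance the
forward and backward branches superimpose, and a growing branch gap is a
sensitive indicator of $R_u$. The test suite verifies both the congruence
and its monotone breakdown under injected $R_u$.

Semiintegration is performed over time, not over potential index; at fixed
scan rate the two differ only by the constant $\sqrt{v}$, but the time-axis
choice keeps multi-cycle records and the dimensionless convention coherent.
For multi-cycle records the operator runs over the whole record's
cumulative time, which is what the congruence diagnostic requires.

## Elimination voltammetry

The elimination procedure assumes the measured current is a sum of
components with known scan-rate power laws — kinetic $\propto v^0$,
diffusion-controlled $\propto v^{1/2}$, capacitive $\propto v^1$ — with
shapes independent of $v$ on the potential axis, planar diffusion, and
negligible (or corrected) $R_u$. Recording the same system at relative
rates $\rho_i = v_i / v_{\mathrm{ref}}$ and combining
$f(I) = \sum_i a_i I_i$ lets one choose the $a_i$ so that one component is
conserved (amplitude 1 at the reference rate) and others are cancelled:

$$\sum_i a_i\, \rho_i^{\,p} = \begin{cases} 1 & p = p_{\text{conserved}} \\
0 & p \in p_{\text{eliminated}} \end{cases}$$

— a square linear system over the selected powers $p \in \{0, 1/2, 1\}$,
solved exactly (`solve_elimination()`). Eliminating one component takes two
scan rates; eliminating two takes three. For the classical rate trio
$\rho = (0.5, 1, 2)$, conserving diffusion and eliminating the other two
gives the familiar coefficients $(-11.657,\ 17.485,\ -5.8284)$.

`standard_eliminations()` enumerates the six textbook selections E1–E6
(three two-rate single eliminations, three three-rate double eliminations).
The labels are cosmetic and vary across the literature; the
conserve/eliminate sets are the interface, and the two-rate functions are
built from the reference rate and the smallest companion rate.
`apply_elimination()` interpolates all inputs onto the reference record's
potential grid (monotone records only — split cycles first), drops points
outside any input's range rather than extrapolating, and refuses scan-rate
sets that do not match the spec.

Applied to a surface-confined (adsorption-controlled) signal, whose
Faradaic current scales as $v^1$ and whose peak drifts with $\log v$, the
conserve-diffusion function annihilates the common amplitude and leaves a
characteristic peak–counter-peak residue crossing zero near the peak — a
rapid qualitative test for adsorption that the test suite reproduces on
synthetic trios.

## Peaks and waves

Peaked responses (differential-pulse, square-wave) are evaluated against a
**chord** baseline through the curve points nearest two user cursors;
cyclic voltammograms use a **tangent** baseline, the least-squares line over
a window centred at the cursor on the pre-peak foot. The peak is the global
extremum of the baseline-subtracted curve between the cursors — optionally
restricted to within a distance of a cursor, which is how shoulders are
isolated — and is refined off-grid by a three-point parabola (disable with
`refine = FALSE` for exact-grid work). "The point nearest the cursor" is a
sample, not an interpolate, with ties to the lower index. Records in the
classical polarographic orientation are handled by `iupac = FALSE`, which
negates the curve before evaluation; heights are always reported
non-negative, and negating the data while toggling the flag changes
nothing.

Wave-shaped responses (polarography, rotating-disk, neopolarograms,
amperometric standard additions) are measured between a lower and an upper
baseline anchored at cursors on the two plateaus, in three modes: `flat`
(both horizontal), `skewed` (lower baseline from the local tangent, upper
parallel to it — the usual choice for normal-pulse records), and
`separate` (each from its own tangent). The half-wave potential is where
the curve crosses the mid-gap line, located by linear interpolation between
the bracketing samples; if the curve wanders across mid-gap more than once,
the crossing nearest the steepest slope is taken. The wave height is the
baseline gap at that abscissa. Baselines that cross between the cursors, or
a curve that never reaches mid-gap, raise `NoWave` rather than returning a
number.

`split_cycles()` separates multi-cycle records at strict sign changes of
the potential step (flat steps inherit the running direction), sharing the
vertex sample between neighbours. Staircase amperograms are evaluated as
repeated flat-mode wave measurements over user-chosen step windows; no
automatic step detection is attempted.

## The synthetic generators

The package tests itself against signals whose ground truth is known by
construction; the generators are first-class exported code.

`synth_cv()` builds a reversible (Nernstian) cyclic voltammogram *through
its semiintegral*: the neopolarogram of a reversible couple under planar
semi-infinite diffusion is exactly the Nernst sigmoid
$M(E) = n / (1 + e^{-nF(E - E^0)/RT})$ on the potential program, and the
dimensionless current is its half-order derivative over $\tau$. This is
mathematically equivalent to solving the diffusion problem, avoids a PDE
solver, and makes the electron-count plateau true by construction — so
recovering the plateau with `semiintegrate()` is a genuine round-trip test
of the transform code, not a fit. The default conditions are desk-typical:
$A = 0.1\,\mathrm{cm^2}$, $C = 1\,\mathrm{mM}$,
$D = 10^{-5}\,\mathrm{cm^2\,s^{-1}}$, $v = 0.1\,\mathrm{V\,s^{-1}}$,
$T = 298.15\,\mathrm{K}$, a $\pm 0.25$ V sweep about $E^0$ (wide enough
that the wave is fully developed at both ends). The generated record
describes an oxidation and carries its ground truth (plateau, $E^0$, the
noise-free $\psi$ and $M$) as attributes. The forward-peak value of the
construction, $\psi_{\max} \approx 0.446$ for $n = 1$, agrees with the
classical reversible constant and is asserted as a cross-check.

`synth_mixture()` is the forward model of the elimination decomposition
(component shapes fixed, amplitudes following the three power laws);
`distort_ru_cdl()` runs the $R_u$/$C_{DL}$ correction backwards, using the
same discrete derivative operators as the corrector so that
distort-then-correct is an honest numerical inverse; the Gaussian-peak,
sigmoid-wave and staircase generators are direct closed forms. Noise, when
requested, is additive Gaussian on the current only and requires an
explicit seed; generators never touch the session RNG stream.

What the generators deliberately do **not** emulate: quasi-reversible and
irreversible kinetics, radial (microelectrode) diffusion, heteroscedastic
or correlated noise, potential-dependent capacitance, and instrument
artefacts such as current ranging steps. Passing tests therefore show the
algorithms are implemented correctly under their stated assumptions, not
that those assumptions hold for any particular bench record.

## Numerical choices and degenerate inputs

* Linear interpolation everywhere a re-grid is needed (corrections,
  elimination common grids): voltammetric data are densely sampled and
  smooth at the sample scale, and linear interpolation cannot overshoot.
* Uniform-step checks use a relative tolerance of $10^{-6}$
  (semiintegration) and $10^{-9}$ (stored-grid comparisons).
* The fixed-point iteration in `distort_ru_cdl()` converges because its
  contraction factor is $R_u C_{DL} / \Delta t$, far below 1 for realistic
  cell time constants at desk sampling rates; it stops at $10^{-14}$
  relative change.
* Degenerate inputs raise classed conditions (`voltkit_error_*`) naming
  the problem — `NoPeak` for a monotone residual, `NoWave` for crossing
  baselines, singular elimination systems for repeated rates, ragged rows
  for malformed files — rather than returning plausible numbers.
* Problem sizes in the test suite (records of $2^8$–$10^4$ points,
  Monte-Carlo loops of 20–100 replicates) were chosen as the smallest sizes
  at which the asserted tolerances are comfortably resolved.

## Known limitations

The time reconstruction assumes a constant nominal sweep rate, so severely
IR-distorted files without an explicit clock are corrected approximately.
Binary instrument formats are out of scope, as are instrument control,
hardware compensation, report generation, arbitrary fractional orders
other than $\pm 1/2$, deconvolution, and elimination under radial
diffusion. Eq-style parameter persistence stores the last-used parameter
set only, not a history.

## A worked end-to-end example

```{r example}
# a reversible one-electron CV under the default desk conditions
cv <- synth_cv(n_points = 2049, noise_sigma = 2e-8, seed = 7)
params <- attr(cv, "params")

smoothed <- smooth_current(cv, poly_order = 3, side_points = 7)
psi <- to_dimensionless(smoothed, params)
neo <- semiintegrate(psi)
half <- (nrow(neo) + 1) %/% 2
max(neo$current[1:half])  # reads out ~1 electron

fit <- solve_elimination(
  elimination_spec("diffusion", c("kinetic", "capacitive"), c(0.5, 1, 2)))
tidy(fit)
```
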