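---
title: "Thermodynamic modeling of the Scl-Gata2-Fli1 stem cell switch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamic modeling of the Scl-Gata2-Fli1 stem cell switch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadswitch)
```

## The model

Scl (Tal1), Gata2 and Fli1 form a densely connected triad of
transcriptional regulators (TRs) at the core of the hematopoietic
stem-cell gene regulatory network. Each gene is controlled by a distal
enhancer — *Scl+19*, *Gata2-3*, *Fli1+12* — carrying binding sites for
the triad TRs, so the module is wired almost entirely out of positive
feedback. `triadswitch` implements a statistical-thermodynamic model of
these enhancers, an exact recursive estimator of the TR-DNA binding free
energies from enhancer-reporter fold-change data, and the resulting
dimensionless ODE model of the triad's dynamics.

### Chromatin-ratchet enhancer thermodynamics

Enhancer action is modeled as a shift of the closed/open chromatin
equilibrium: TRs can only bind when the chromatin has spontaneously
unwrapped, and their binding traps ("ratchets") the open state in which
RNA polymerase can reach the promoter. With the open, empty enhancer as
the energy reference, the closed state carries weight $K - 1$ and each
TR-bound configuration $c$ a Boltzmann weight
$w_c = e^{-\Delta G_c}$ (free energies in units of $1/\beta$),
concentration-adjusted so that dimensionless TR concentrations
$(x_s, x_g, x_f)$ enter as $w_c\, x_s^{a_c} x_g^{g_c} x_f^{d_c}$. Fli1
binds as a dimer, so its copy number is always even and its
concentration enters quadratically. Writing
$Z_b = \sum_c w_c \prod_T x_T^{\,\nu_{c,T}}$, weak polymerase binding at
the promoter gives the reporter fold enhancement over the enhancerless
construct

$$F = \frac{K\,(1 + Z_b)}{K + Z_b},$$

which runs from $F = 1$ (no binding) to the saturating value $K$: the
chromatin equilibrium constant *is* the maximum possible fold
enhancement. Only the configurations that measurably affect reporter
expression are included: `G`, `FF`, `G.FF` for *Scl+19*; those plus the
`S.G.FF` complex for *Gata2-3*; and `G`, `FF`, `G.FF`, `G.S.FF.G`
(primary and secondary GATA sites) for *Fli1+12*. TR-TR interaction
energies are absorbed into the composite configuration weights.

Notch and Bmp4 act at the promoters (Gata2: both; Fli1: Bmp4 only),
cooperatively with polymerase. The dimensionless transcription factor of
a gene is

$$f = \eta_{\mathrm{eff}}\,
\frac{(1 + Z_b)\,(1 + \omega_N n + \omega_B b)}
     {K - 1 + (1 + Z_b)(1 + n + b)},$$

with $n, b$ the cofactor concentrations normalized by their promoter
dissociation constants and $\omega > 1$ the polymerase-interaction
factors. Because $n$ and $b$ appear in numerator and denominator the
cofactor effect saturates. We treat Notch and Bmp4 promoter binding as
mutually exclusive (the additive $n + b$ term): it is the simplest form
consistent with the observed saturability, and the calibration property
below holds under the independent-binding alternative too. Gata1
repression of Gata2 is phenomenological: a factor
$\eta \in (0, 1]$ multiplying the Gata2 transcription factor only, with
no binding model of its own.

### Free energies from reporter tables

Each reporter construct measures one fold enhancement, and
$Z_b = K(F-1)/(K-F)$ inverts the fold formula in closed form. Because
every construct in the library introduces exactly one new configuration
beyond the constructs below it, the weights follow recursively:
single-site constructs give the single-TR weights, the pair construct
gives the pair weight after subtracting the singles, and the wild type
pins the full complex. The fit is exact — re-simulating every construct
reproduces its measured fold to machine precision — and it is feasible
only when $K$ exceeds the largest measured fold (820.51 for *Scl+19*,
the binding constraint that anchors the whole parameterization). A
negative composite weight is unphysical and aborts the fit with a
structured infeasibility error instead of being clamped, since clamping
would silently change the model. A least-squares `relaxed` mode
(squared log-fold residuals, weights optimized on the log scale) is
available for inconsistent tables; log-fold weighting was chosen because
reporter intensities are ratio-scale.

The packaged table (`hsc_reporter_library()`) pins the anchors printed
with the original experiments — 820.51 for wild-type *Scl+19*, roughly
20- and 60-fold for the *Fli1+12* constructs — and fills the remaining
cells with clearly labeled placeholder values (`source = "placeholder"`,
chosen once as round numbers of a plausible magnitude: strong pair
synergy, weak singles). Every quantity that depends on a placeholder
cell — mutant phenotype boundaries, pulse-duration plateaus, matched
clamp values — is only qualitative; quantities pinned by the anchors
(the fit round trip, the feasibility bound, the omega calibration) are
exact.

### The dimensionless ODE system

With protein production proportional to transcription (mRNA at
quasi-steady state) and first-order degradation, normalizing each
concentration by its wild-type HSC steady-state value and time by the
Scl degradation timescale gives

$$\frac{dx_i}{d\tau} = \gamma_i\left(\frac{f_i(x, \text{signal})}{f_i^{wt}} - x_i\right),$$

where $f_i^{wt}$ is the zero-signal transcription factor at the
wild-type state $(1,1,1)$ — so the wild-type state is a zero-signal
steady state by construction — and
$\gamma_i = t_{1/2}(\mathrm{Scl})/t_{1/2}(i)$. The measured half-lives
(Scl 8 h, Gata2 about 10 min, Fli1 2 h) give $\gamma = (1, 48, 4)$: the
10-minute Methods value is used for Gata2 rather than the looser
"under 30 minutes" bound. Time is measured in Scl *mean lifetimes*
(half-life / ln 2, about 11.54 h), the convention that makes Scl's
dimensionless decay rate exactly 1; `time_unit = "half_life"` switches
the hour conversion to the 8 h half-life for sensitivity checks, since
the phrase "normalized by the Scl half-life" is ambiguous between the
two. Only reported hours depend on this choice.

The omegas are calibrated so that saturating Notch raises wild-type
Gata2 output 3.5-fold and saturating Bmp4 4-fold, the fold changes
measured in wild-type HSCs: from the saturating limit of $f$,
$\omega = \text{fold} \cdot (1 + Z_b)/(K + Z_b)$ evaluated at
$(1,1,1)$. A requested fold of 1 yields $\omega < 1$ under the
mutual-exclusion form (flagged with a warning as repression-like) but
still leaves the saturating output unchanged, which is the calibrated
contract.

## Numerical methods

**Steady states.** The system is three-dimensional and cheap, so no
continuation package is used: steady states come from damped Newton
refinement (finite-difference Jacobians, projection onto the
nonnegative orthant) multi-started from a log-spaced grid spanning
$10^{-4}$ to $10$ per axis plus the endpoints of long forward
integrations; results are deduplicated at a relative log-space merge
radius of $10^{-4}$ and must satisfy a residual norm below $10^{-10}$.
If two attractors are found without a separating saddle, extra Newton
starts are seeded along log-space chords between them. Stability is
read off Jacobian eigenvalue real parts with margin $10^{-8}$;
marginal cases fall back to perturbed simulation.

**Response curves.** `trace_response()` recomputes the full
steady-state set independently at every grid point of one signal axis
(the others held neutral: $n = b = 0$, $\eta = 1$, since concurrent
activation and Gata1 signals are physiologically unlikely), classifies
the curve as irreversibly bistable (two stable states coexist at the
neutral signal), reversibly bistable, or monostable, and brackets
saddle-node thresholds by bisection on the stable-state count.
`static_threshold()` instead follows one branch (OFF under rising
activation, ON under falling $\eta$) with warm-started Newton steps and
an adaptive log-scale step size, halving the step on nonconvergence,
loss of stability or a branch jump; this locates the fold itself and is
what the reduced-module matching equates.

**Dynamics.** Integration uses `deSolve::lsoda` with relative
tolerance $10^{-8}$ and absolute tolerance $10^{-10}$; piecewise
signal schedules are integrated segment by segment so discontinuities
never straddle a step. Minimum pulse durations are bisected to
0.01 $\tau$, with basin membership decided by integrating 200 $\tau$
after pulse release (much longer than the slowest relaxation time,
$1/\gamma_s = 1\,\tau$) and assigning the endpoint to the nearest
stable state in log space. A pulse amplitude below the static threshold
returns `Inf`: no duration can switch. Gata1 deactivation pulses map an
amplitude $a \ge 0$ to $\eta = 1/(1+a)$ so that "plateau amplitude"
means $\eta \to 0$. Filter-curve plateaus are evaluated at $10^3$ times
the static threshold. The accumulation time `t_acc` is the first
crossing of 50% of the ON-state Scl level (configurable; no sharper
definition is implied by the data).

**Chromatin constants.** Exact fitting leaves $(K_s, K_g, K_f)$ as the
only free parameters, each bounded below by its enhancer's largest
measured fold. The `auto_K()` rule takes 1.05 times each bound and
verifies that both Notch and Bmp4 at physiological amplitude
($\le 10^3$) can switch the triad ON, scanning multipliers in
$[1.01, 2]$ if not: switchability requires the wild-type enhancement to
sit near saturation, so the admissible band hugs the bounds. With the
packaged table the 1.05 margin is immediately switchable, giving
$K \approx (862, 525, 63)$. Once the free energies are fixed, the
switchable irreversible bistability is robust to several-fold changes
of $K$ without refitting (tested at 3x).

## Module designs

`make_design()` derives mutants from the wild-type parameter set by
string keys: site deletions (`"fli1p12:dEBOX"`) remove every
configuration requiring the deleted site (deleting the primary GATA
site of *Fli1+12* removes `G`, `G.FF` and `G.S.FF.G`, leaving Fli1
decoupled from Scl and Gata2); knockouts (`"ko:Scl"`) zero one gene's
production; heterozygotes (`"het:Gata2"`) halve it; `"reduced:<x>"`
clamps Scl at a constant, removing its feedback. Mutants keep the
wild-type normalization constants $f_i^{wt}$, so they need not have
$(1,1,1)$ as a steady state. The ten studied site-deletion designs are
both *Scl+19* sites, the three *Gata2-3* sites, one representative
*Scl+19*/*Gata2-3* double deletion, and the four *Fli1+12* sites — the
6/4 split between designs touching *Scl+19*/*Gata2-3* and designs
touching only *Fli1+12* is the stable contract; the choice of
representative double is not.

## What the synthetic generator does and does not emulate

`generate_truth()` samples configuration weights log-uniformly in
$[0.1, 10^4]$ and $K$ log-uniformly in $[10, 10^4]$ (the reported range
for nucleosomal equilibrium constants), rejecting draws whose wild-type
enhancement comes within 1% of $K$ so the inversion stays
well-conditioned. `generate_library()` then emits exactly the construct
set each fit needs, with optional multiplicative lognormal noise
$e^{\sigma z}$ on the fold values — reporter intensities are
ratio-scale, so multiplicative noise is the natural error model; none
is specified by the data. This exercises the full
fit-to-dynamics pipeline without real supplementary data, but it does
not emulate replicate structure, construct-position effects, or
flow-cytometry measurement distributions: passing recovery tests shows
the estimator is exact and stable, not that real reporter data meet its
assumptions.

## Problem sizes and limitations

The shipped tests trace response curves on 11-21 point signal grids,
scan switchability on small $K$ grids, and evaluate pulse plateaus at
four amplitudes per axis — sizes chosen to characterize each curve with
the 3-variable model, where a full steady-state search costs well under
a second.

Known limitations:

* All quantities downstream of the placeholder reporter cells are
  qualitative. In particular, with the placeholder table the
  activation-threshold-matched reduced module loses zero-signal
  bistability (its irreversible minimum pulse is infinite), several
  *Scl+19*/*Gata2-3* deletion designs retain reversible bistability at
  very high Notch rather than being strictly monostable, the
  *Fli1+12* primary-GATA deletion loses its high state entirely, and
  the deactivation/activation clamp ratio lands near 13 rather than 4,
  and the upper boundary of the switchable region (chromatin constants
  large enough that neither Notch nor Bmp4 can switch the triad) lies
  beyond the scanned `K` range, so the switchable band does not appear
  narrow.
  These are properties of the placeholder cells, not of the method; the
  anchor-pinned quantities are reproduced exactly.
* No stochastic dynamics: the model is deterministic by design, and
  separatrix distances only gesture at fluctuation susceptibility.
* No sequence-level affinity prediction or nucleosome positioning; the
  configuration inventory is taken from the measured site deletions.
* Scl positive autoregulation is omitted (no bona fide Scl site in
  *Scl+19*).
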