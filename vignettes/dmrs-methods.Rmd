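---
title: "Quantitative deuterium MRS of metabolizing mixtures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative deuterium MRS of metabolizing mixtures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmrskit)
```

## The measurement problem

Deuterium magnetic resonance spectroscopy (DMRS) follows a ²H-labelled tracer
through a metabolizing system in real time: a deuterated substrate (glucose,
pyruvate, fumarate, acetone, nicotinamide, ...) is added to a cell suspension
inside the NMR tube, and a ²H spectrum is recorded every one to three minutes
for hours. Each resonance integral is proportional to the deuterium
concentration on that chemical site, so the series of spectra is a set of
concentration-versus-time curves for the substrate and its products.

Three ingredients turn raw integrals into chemistry:

1. **An internal concentration standard.** Water at natural isotopic
   abundance contains a known amount of semi-heavy water (HDO). With a
   deuterium abundance $f_D = 1.56\times10^{-4}$ and $[\mathrm{H_2O}] =
   55.56$ mol/L, the deuterium concentration of neat water is
   $$[D_\mathrm{ref}] = [\mathrm{H_2O}]\,\bigl(2 f_D (1-f_D) + f_D^2\bigr)
   \approx 17.3\ \mathrm{mM},$$
   and any other signal converts by the ratio rule
   $$D_x = D_\mathrm{ref}\cdot\frac{S_x}{S_\mathrm{ref}}\cdot
   \frac{NS_\mathrm{ref}}{NS_x},$$
   where $S$ is the line integral and $NS$ the number of summed transients.
   When cells and glass beads displace part of the water in the coil's
   sensitive volume, the reference signal shrinks by a reduction factor
   $FR = S_\mathrm{cells}/S_\mathrm{buffer} \approx 0.866$, so the effective
   water reference becomes $17.3 \times 0.866 \approx 15$ mM. Substituting
   $S_\mathrm{cells} = FR\,S_\mathrm{buffer}$ and $D_\mathrm{cells} =
   FR\,D_\mathrm{buffer}$ shows the buffer- and cell-referenced conversions
   are algebraically identical; `concentration_from_integral()` implements
   both through one `dmrs_cal` object and the identity is enforced by test.

2. **A kinetic model.** Enzymatic conversion of an abundant substrate by a
   fixed cell population is well described by first-order kinetics. Every
   quantified trace is fitted with the mono-exponential
   $$I(t) = A\,e^{-t k} + y_0,$$
   where $A > 0$ for a decaying substrate, $A < 0$ for a rising product,
   $A + y_0$ is the initial level, and $y_0$ the asymptote (residual
   substrate or final product). When a substrate feeds a single observed
   product, the two traces are fitted jointly with one shared $k$
   (`fit_shared_rate()`, five parameters), which is both physically demanded
   by the one-step mechanism and statistically stronger than two separate
   fits.

3. **A deuterium budget.** Deuterons leaving a substrate either arrive on an
   observed product, exchange into water (raising the HDO line), or vanish
   into pools below the detection limit. The *added-D* value — the sum of
   all observed pools minus the natural-abundance water baseline — is a
   conservation diagnostic: flat when the label stays visible, decaying when
   it leaks into unobservables.

The package implements this entire chain, together with a synthetic-data
module that generates ²H spectra with the statistical structure the analysis
assumes, so every stage is testable without the original spectrometer data.

## The synthetic world

### Reaction networks

`reaction_network()` describes pools of deuterium concentration (mM of
deuterons, *not* molecules) connected by first-order edges. Each edge routes
the deuterium leaving its substrate between the product, HDO, and an
`UNOBSERVED` pool, with fractions summing to one. The resulting linear system
$\dot c = M c$ has a generator matrix with zero column sums, so total
deuterium is conserved exactly; `simulate_concentrations()` evaluates
$c(t) = e^{Mt} c(0)$ with a matrix exponential (Padé, via the Matrix
package), which is exact for any network topology — including cycles, which
therefore need no special rejection; only malformed routing or negative
rates are refused. A property test checks agreement with brute-force
Runge–Kutta integration to $10^{-6}$ relative.

Observed substrate asymptotes are often nonzero (fumarate levels off at
6.5 mM [D] out of 44; acetone at 4.8 mM of 16 mM) while a pure first-order
decay always empties its pool. Whether this reflects an approach to
equilibrium or arrest of the cells is not resolved by the data, so the
network type carries a per-species `residual_d`: an unreactive fraction that
rides along as a constant offset. This is a fixture device that reproduces
the published asymptotes without committing to a mechanism.

### From concentrations to spectra

`synth_fid()` builds the time-domain signal as a sum of damped complex
exponentials, one per resonance site:
$$s(t) = \sum_j A_j\, e^{2\pi i f_j t}\, e^{-t/T_{2,j}}, \qquad
A_j \propto [D]_j \cdot NS \cdot \bigl(1 - e^{-TR/T_{1,j}}\bigr).$$

Choices behind this forward model, none of which the source data constrain
further:

* **Lineshape.** Pure Lorentzian with $T_2^* = T_2$: the synthetic magnet is
  perfectly shimmed. An optional extra broadening could be layered on via
  the apodization parameter; the default adds none.
* **Saturation.** 90° excitation throughout, so the spoiled steady-state
  factor reduces to $1 - e^{-TR/T_1}$. The general
  $\sin\theta\,(1-E_1)/(1-\cos\theta\,E_1)$ form is implemented
  (`steady_state_factor()`) but only $\theta = 90°$ is exercised. The
  acquisition schemes pair each tracer with the repetition time used for it
  (6.3 s for glucose, 11.5 s fumarate, 15.5 s pyruvate, 17.5 s acetone,
  2.1 s nicotinamide), which is what makes saturation nearly — but not
  exactly — negligible.
* **Decoupling and NOE.** ¹H decoupling is assumed to collapse multiplets
  with no intensity side-effects; amplitudes depend only on concentration,
  NS and saturation.
* **The HDO line** at 4.70 ppm is always present: it is the internal
  standard, at 17.3 mM in buffer and 15 mM with cells, with $T_1 = 0.63$ s,
  $T_2 = 0.61$ s.
* **Noise** is injected in the time domain as iid complex Gaussian samples.
  Its scale is calibrated analytically (the region integral is a linear
  functional of the noise, so its variance follows in closed form through
  the DFT) so that the HDO reference integral fluctuates with SD equal to
  `sigma_frac_of_ref` of its mean — 3.67% by default, the observed
  stability of the reference acquisition. A property test confirms the
  realized coefficient of variation falls in [2.5%, 5%] over 100+ spectra.
* **Timing.** A spectrum averaging $NS$ transients over $NS \times TR$
  seconds is stamped with the *midpoint* of its scan block — the symmetric
  choice for a linearly varying concentration.
* **Volatile losses** (acetone, propan-2-ol evaporation) are represented
  only as routing to `UNOBSERVED`; no explicit evaporation term.

### Relaxometry series

`synth_ir_series()` and `synth_cpmg_series()` generate the classic
inversion-recovery and CPMG observables
$$I(\tau) = I_0\bigl(1 - (1+e)\,e^{-\tau/T_1}\bigr), \qquad
I(n) = I_0\, e^{-n\,t_e/T_2},$$
on the instrument's schedules: 27 pseudo-logarithmic recovery delays from
0.01 to 25 s, and 28 echo-train lengths from 4 to 9000 echoes at a 1 ms echo
time. (The acquisition protocol's prose says "32" delays but prints 27
values; the printed list is authoritative here and is what
`ir_delay_schedule()` returns.) The fits (`fit_t1_ir()`, `fit_t2_cpmg()`)
use signed intensities — no magnitude fitting — with the inversion
efficiency bounded to $[0.8, 1]$ (hard pulses at 9.4 T are near-ideal, and
an unbounded efficiency makes the three-parameter model poorly identified on
noisy data). CPMG is fitted in intensity space so noise is weighted
uniformly; the log-linear regression is retained only as an independent test
oracle. Recovery across the studied dynamic range ($T_1 \in [0.058, 5.32]$ s,
$T_2 \in [0.055, 5.43]$ s) is verified noiseless to $10^{-6}$ and to 2% in
the mean at SNR 100.

## Spectral processing

The processing chain mirrors standard practice: exponential apodization
(3 Hz), zero filling (16 k acquired points to 32 k), Fourier transform,
zero-order phase correction, and referencing of the chemical-shift axis to
the HDO resonance at 4.70 ppm.

Numerical choices:

* The first time-domain point is halved before the transform (the trapezoid
  end-correction for a one-sided signal), which removes the constant
  baseline offset a truncated decay otherwise produces.
* The ppm axis is stored ascending internally and rendered descending (NMR
  convention) by display methods.
* Only zero-order phase is implemented: synthetic FIDs have no dead time, so
  a first-order term has nothing to correct. Auto-phasing maximizes the real
  integral over the declared regions via a coarse grid plus golden-section
  refinement, and recovers injected phases within 0.5°. Equivalence with
  any particular vendor's phasing algorithm is not claimed — only
  inject-and-recover correctness.
* Referencing finds the tallest peak in the 4.2–5.2 ppm water window and
  shifts the axis so its parabolic-interpolated apex sits at 4.70 ppm;
  sub-digit accuracy (~$10^{-4}$ ppm) on noiseless lines. A window with no
  peak above the noise floor leaves the axis untouched with a warning.
* `integrate_region()` integrates the piecewise-linear interpolant of the
  real part exactly between the region bounds. Interpolating the boundary
  segments (rather than snapping to grid points) makes integration exactly
  additive over adjacent sub-regions and invariant to zero filling to 0.1%.

## Quantification of a spectral series

For a synthetic series, `quantify_series()` relates the vector of region
integrals $S$ to pool concentrations $c$ through a coefficient matrix
$$K_{rp} = NS \cdot \tfrac12 \sum_{j \in p} w_j \bigl(1-e^{-TR/T_{1,j}}\bigr)
\,\mathrm{cov}_r(f_j, W_j),$$
where $w_j$ is the site's share of the pool's deuterons and
$\mathrm{cov}_r$ the closed-form fraction of a Lorentzian of width
$W_j = 1/(\pi T_{2,j}) + \mathrm{lb}$ centred at $f_j$ that falls inside
region $r$ (a difference of arctangents). Solving the small least-squares
system $S \approx K c$ simultaneously corrects for T1 saturation, the tails
a finite window truncates, and the leakage of neighbouring lines into each
other's windows. Nothing is fitted: every entry of $K$ follows from declared
constants. This is deliberately *not* lineshape deconvolution — positions,
widths and amplitudes are never estimated from the data, and genuinely
unresolved species (the nicotinamide/nicotinic-acid aromatic lines, a few Hz
apart at ~5–8 Hz width) are *not* separated: they are declared as one merged
pool via `pool_map`, exactly as joint integration of overlapping lines
treats them.

Fixed ppm windows with plain integration were considered and rejected: with
a 3 Hz broadened Lorentzian, a window wide enough to capture 99.5% of a line
overlaps the neighbours in every realistic region layout (malate C2 sits
0.33 ppm — 20 Hz — from water), and the resulting few-percent biases exceed
the 1% round-trip accuracy the test suite demands. `integrate_region()`
itself remains a plain trapezoid for users who want the uncorrected numbers,
and `quantify_series(overlap_correction = FALSE)` provides the
diagonal-only (own-line) correction.

**Scale anchoring.** Three conventions are offered. `scale = "model"`
(default) trusts the forward model's absolute units, which are exact in the
synthetic world. `scale = "initial_hdo"` reproduces the experimental
convention of assigning the first spectrum's water estimate the baseline
value (15 mM with cells): correct when water is stable, but biased by
however much water has already risen during the first scan block — for the
glucose-d7 scenario, whose water signal climbs from 15 to 62 mM, that bias
is about −3.4%, which is why it is not the default for synthetic round
trips. `scale = "external"` applies the reference-integral conversion
against a recorded buffer acquisition. Negative noise-driven estimates are
reported as-is and flagged; they are clipped only inside budget summaries,
with the clip count attached to the result.

## Kinetics fitting

`fit_monoexp()` and `fit_shared_rate()` are nonlinear least squares
(Gauss–Newton with the `port` trust region). Standard errors are the square
roots of the diagonal of $(J^\top J)^{-1} s^2$ at the optimum — the
covariance matrix of the converged fit — and the full covariance is kept on
the object. Choices:

* **Initialisation** (the fitted model class offers no canonical start):
  $y_0$ from the last observed value, $A$ from first minus last, and $k =
  \ln 2 / t_{1/2}$ with $t_{1/2}$ the first time the trace crosses half its
  range, falling back to $1/\mathrm{median}(t)$. Robust for monotone traces.
* **Restarts.** Up to five deterministic seeded log-normal perturbations of
  the start on non-convergence; a fit that still fails is returned with
  `converged = FALSE` rather than an error.
* **Degenerate traces.** A trace whose sample SD sits below the noise floor
  is reported with amplitude 0, $y_0$ at the mean, and `k = NA` flagged
  `"k_unidentifiable"` — a flat line carries no rate information and
  force-fitting it would only manufacture one.
* **Sign convention.** Substrate fits should have $A > 0$ and product fits
  $A < 0$; violations are flagged (`"sign_mismatch"`), never silently
  corrected, and a negative fitted $k$ is likewise flagged and reported.

`replicate_stats()` summarizes repeated runs (sample SD, $n-1$ denominator;
CV = SD/mean). `compare_rates()` performs the unpaired two-sample
comparison; the unequal-variance (Welch) variant is the default since
nothing guarantees equal variances between preparations, and the degenerate
zero-variance/equal-means case returns $p = 1$ by convention. No
multiple-testing correction is applied — single planned comparisons are the
use case. Its type-I error is verified by simulation to sit in [3.5%, 6.5%]
at $\alpha = 0.05$.

## The bundled study fixtures

`paper_scenarios()` packages six ready-made configurations whose rates,
initial deuterium loads, asymptotes and acquisition timings follow the
published yeast experiments:

| scenario | conversion | k (1/min) | spectra every | notes |
|---|---|---|---|---|
| `glc_d2` | glucose-d2 → ethanol-d2 | 0.0282 | 50.4 s | ethanol asymptote 20.86 mM; water 15→18 mM |
| `glc_d7` | glucose-d7 → ethanol-d3 | 0.0271 | 50.4 s | heavy exchange: water 15→62 mM |
| `pyr_d3` | pyruvate-d3 → ethanol-d3 + acetate-d3 | 0.0274 total | 124 s | branch ratio from 26 vs 3.1 mM [D] products |
| `fum_d2` | fumarate-d2 → malate-d2 | 0.0561 shared | 92 s | 44→6.5 mM [D], malate → 31 mM [D] |
| `ace_d6` | acetone-d6 → propan-2-ol-d6 | 0.0123 shared | 140 s | volatile losses → unobserved |
| `nam_d4` | nicotinamide-d4 → nicotinic-acid-d4 | 0.0669 shared | 168 s | reported as one merged pool |

Where a quantity is not printed anywhere (the ethanol asymptote of the
glucose-d7 run, the routing split behind nicotinamide's budget decay), a
representative value was fixed once and documented in the fixture source;
these numbers shape only the synthetic world, not any acceptance claim. The
glucose-d7 species is modelled with three effective lines (the α-anomer C1
plus two lines for the unresolved 3.3–3.9 ppm band); the β-anomer resonance
that overlaps water in the real molecule is left out of the synthetic model.
The reported 3.5-fold higher water yield per glucose for the d7 tracer is
not derivable from printed concentrations alone, so routing stays
user-configurable rather than a fixture claim.

`run_study()` executes a configuration end to end in one of two fidelity
modes: `"spectra"` synthesizes and processes every FID (the mode for
round-trip validation of the processing/quantification chain), while
`"trajectory"` works on exactly simulated concentrations with
reference-calibrated Gaussian noise (SD = 3.67% of the 15 mM water
reference per point) — the appropriate and much faster level for
rate-recovery studies. A single study seed fans out to per-stage child
seeds (`derive_seed()`), so identical (config, seed) pairs give identical
reports, byte for byte.

## What a green test establishes — and what it does not

The synthetic generator reproduces the *statistical structure the analysis
assumes*: Lorentzian lines at catalogued shifts, first-order kinetics,
stationary Gaussian noise at the reference-calibrated level, exact deuterium
conservation. Real spectra add baseline roll, field drift, lineshape
asymmetry, radiation damping of the water line, chemical-exchange
broadening, pH-dependent shift drift and cell settling — none of which are
modelled. A passing round trip therefore validates the *pipeline's
arithmetic and statistics*, not the spectrometer physics; the published
biological rate constants serve as fixture parameters, and re-deriving them
from the archived raw spectra is outside this package's scope (as is any
Bruker raw-format parsing).

## Known limitations

* No baseline correction, solvent suppression, or first-order phase: the
  synthetic data never need them, so these stages are untested against
  their real-world failure modes.
* The coverage-matrix solve assumes the declared $T_2$ and shifts are the
  truth; on real data, mis-declared widths would propagate directly into
  concentrations.
* Unresolved species can only be merged, not separated — by design;
  spectral fitting approaches (lineshape libraries, learned models) are
  future work and out of scope here.
* The first-order network cannot represent saturable (Michaelis–Menten)
  kinetics; no model selection is attempted.
* Multi-site "total" relaxation values are pooled by deuteron-weighted
  averaging in `relaxometry_table()` — one documented choice where the
  original tabulation's pooling rule is unstated.
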