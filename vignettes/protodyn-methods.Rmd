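---
title: "Models and methods behind protodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind protodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`protodyn` models the physics, photochemistry and biology of proton-dynamic
therapy experiments: a photosensitiser (PS) in solution, gel or cells is
excited by a clinical-energy proton beam, and the package reproduces the
chain from beam transport to differential cytotoxicity.  This vignette
records the models, their assumptions, the defaults and why they were
chosen, and what the tests do and do not establish.

## Proton transport

**Stopping power.** The mass stopping power is the relativistic Bethe
formula without shell or Barkas corrections,

$$\frac{S}{\rho} = K \frac{Z}{A} \frac{1}{\beta^2}
  \left[\ln\frac{2 m_e c^2 \beta^2 \gamma^2}{I} - \beta^2\right],$$

with $K = 0.307075$ MeV cm² mol⁻¹, evaluated per element and combined by
Bragg additivity over mass fractions (equivalently: effective $Z/A$ with
$\ln I$ averaged by electron fraction — the two forms are algebraically
identical, and the tests verify the additivity post-condition to machine
precision).  At 10 MeV in water this sits 0.6% above the standard
tabulation (shell corrections are missing); at 100 MeV the agreement is
0.03%.  The validity window is 0.05–250 MeV; below the 0.05 MeV floor the
stopping power is extrapolated as a constant, which costs well under 0.3%
in range at the energies of interest and keeps the engine dependency-free.

**Mean excitation energies.** Elements use the standard dosimetry
tabulation (H 19.2 eV, C 78, N 82, O 95, S 180, ...).  Compounds derive
$I$ by Bragg additivity on $\ln I$ unless a condensed-phase value is
supplied: liquid water is pinned at 75 eV and polystyrene at 68.7 eV.
DMSO has no commonly printed condensed value, so the additivity estimate
(~93 eV) is used; its density is set to 1.10 g/cm³.  These choices put the
computed 12.5 MeV Bragg peak in DMSO at 1.76 mm against the reported
"around 1.8 mm" — comfortably inside the ±0.1 mm the I-value and density
freedom is worth.

**Ranges and depth-energy.** CSDA ranges come from trapezoidal integration
of $1/(S/\rho)$ on a 3000-node log grid (agreeing with adaptive quadrature
to < 0.2%), inverted with monotone Hyman splines.  The residual-range
method gives the energy at depth, $R(E_0) - z\rho = R(E(z))$, saturating at
zero at the end of range: protons stop, there is no exit dose.

**Depth-dose.** Dose per unit fluence is
$D(z) = (S/\rho)(E(z)) \times 1.602\,176\,634\times10^{-10}$ Gy per
proton cm⁻².  The Gaussian entrance-energy spread (default 0.1% FWHM, the
value used in the original beam simulations) is averaged with 21
deterministic equi-spaced nodes over ±4σ with Gaussian weights — no RNG
anywhere in the physics.  Energy conservation
($\rho\int D\,\mathrm{d}z = E_0$) holds within 0.03% on a 2 µm grid and is
asserted at 1% in the acceptance suite.

**Dose-rate arithmetic.** $\dot D = \dot\Phi \cdot (S/\rho) \cdot
1.602\times10^{-10}$.  The printed experimental pair
(8×10⁸ cm⁻² s⁻¹, 5.3 Gy/s) implies $S/\rho \approx 41$ MeV cm²/g, above any
pure-Bethe value for DMSO near 12.5 MeV (35.9).  The package reports its
computed 4.6 Gy/s and does not force agreement; the acceptance check runs
at the stated ~15% slack.  The discrepancy plausibly hides an unstated
medium, energy or calibration step in the original dosimetry.

## Fluorescence versus depth and the enhancement term

The measured fluorescence maxima (1.6–1.7 mm) sit *before* the simulated
Bragg peak (1.8 mm), with elevated fluorescence proximal to the peak —
interpreted as the PS increasing the interaction cross sections of
high-energy protons.  The package models this as an enhanced effective
stopping power

$$S_\mathrm{eff}(E) = S(E)\,\bigl(1 + A\,w(E)\bigr), \qquad
  A = \mathrm{enhancement} \times c,$$

with the weight $w(E) = E/E_0$ largest for fast (proximal) protons, and
emission $F(z) \propto \phi_f\, D_\mathrm{eff}(z)\,(1 + A\,w(E(z)))$.
Because each proton samples PS encounters stochastically, the enhanced
curve carries extra range straggling, implemented as Gaussian depth
smearing with σ equal to `heterogeneity` (default 0.3) times the
enhancement-induced range shift, computed by discrete convolution on a
1 µm internal grid.  Consequences, all verified by tests: at zero
enhancement the profile is exactly proportional to the dose curve; with
enhancement the maximum shifts monotonically shallower and never passes
the Bragg peak; the FWHM is at least the dose FWHM.  An enhancement of
800 M⁻¹ at 110 µM places the maximum at 1.64 mm, bracketing the measured
values.

A note on the weight's direction: a weight that *grows as energy falls*
(e.g. $1/E$) boosts the distal side and can only move the maximum deeper —
incompatible with both the proximal-enhancement observation and the
shallow measured maxima.  The high-energy weight is therefore the
package's default; `weight` is an argument for users who want other forms.
The enhancement strength itself is a free phenomenological parameter — no
quantitative theory for it is claimed anywhere — and is fitted or chosen,
never derived.

## Type-II photokinetics

The steady-state singlet-oxygen level is
$\propto \dot X \,\phi_\mathrm{isc}\, \tau_\mathrm{eff}$ with
$1/\tau_\mathrm{eff} = 1/\tau + k_q[\mathrm{DABCO}]$.  Defaults:
τ = 3.45 µs (water, 25 °C; acetone-d6 is 1046 µs, a 303× level ratio),
$k_q = 5\times10^8$ M⁻¹s⁻¹ (literature order of magnitude — the
experiments only state [DABCO] = 200 mM, which is saturating for any
plausible $k_q$).

Bleaching follows a minimal two-pathway linear system on an exposure axis
$t$ (time, fluence or photon count, per condition):

$$\frac{\mathrm{d}P}{\mathrm{d}t} = -(k_\mathrm{so} + k_\mathrm{ion})P,
\qquad
\frac{\mathrm{d}Q}{\mathrm{d}t} = \eta\,k_\mathrm{so}P -
  r\,(k_\mathrm{so} + k_\mathrm{ion})Q,$$

where $k_\mathrm{so} = \sigma_\mathrm{so}\,x\,q$ (excitation rate $x$,
DABCO quench fraction $q = \tau_\mathrm{eff}/\tau$) is the
singlet-oxygen channel and $k_\mathrm{ion} = \sigma_\mathrm{ion}\,x$ the
ionisation channel, active only under protons.  $r$ is the
photoproduct-to-parent degradation ratio, default 1 — the assumption that
the photoproduct degrades like its parent.  Oxygen is treated as
unlimited; triplet-state kinetics, diffusion and type-I radical chemistry
are deliberately lumped into the two σ's.  This is the *minimal* model
consistent with the observed contrasts (light-mode bleaching fully
DABCO-protectable, proton-mode only partially, no photoproduct under
DABCO); whether the ~25-point DABCO protection maps linearly onto pathway
shares is not established by the data and not claimed.

The solver is an in-package adaptive Cash-Karp RK45 (rtol 10⁻⁸; no ODE
package is available in the offline stack), validated against the exact
two-exponential solution to 10⁻⁶.  Deconvolution uses
$G(t) = Q(t) + k_\mathrm{deg}\int_0^t Q$, with the parent decay rate
fitted by log-linear least squares through the origin; the round trip on
solver-generated data is exact to < 2% sup-norm.

`fit_kinetics` exploits the model's structure instead of nesting the
solver in an optimiser: log-parent is exactly linear in exposure, so
per-trace decay rates come from least squares through the origin, the
channel coefficients from a linear solve across conditions (the design row
is $(xq, x\cdot[\mathrm{proton}])$), and η from a final linear projection
of the photoproduct channel.  Confidence intervals are normal-theory
intervals from a seeded residual bootstrap on the log-parent residuals
(default seed 20190904, restored RNG state).  Noise-free recovery is exact
to 10⁻⁴; at 3% multiplicative noise the 95% intervals cover the truth in
≥ 90% of 50 seeded runs (measured: 94–96%).

One regime caveat, encoded in the tests: pointwise DABCO monotonicity of
the photoproduct ($Q$ larger with less DABCO) holds while formation
dominates; at exposures far beyond the observed bleaching range, a heavily
bleached parent lets the slower channel catch up and the curves can cross.
The property is asserted within the regime the experiments cover.

## Spectra

CCD spikes from ionising radiation are single-channel artefacts present in
every acquisition.  The despiker flags deviations from a running median
(window 7) beyond 6 robust SDs (1.4826 × MAD of the residuals) and
replaces them with the local median.  The robust SD is floored at 1% of
the maximum intensity so that a noiseless smooth band — whose only
residuals are curvature at the top — is never flagged; the operation is
idempotent.  Background handling is the exact linear rule
sample − dark − (solvent − dark).

Band decomposition fits a sum of Gaussians plus an optional constant
baseline by variable projection: amplitudes and baseline are linear and
solved exactly per evaluation, so the optimiser only works on centres and
log-widths inside physical box constraints (widths between two channels
and half the span).  Initialisation seeds bands sequentially at the
maximum of the smoothed residual *in Poisson-noise units*
(residual/√intensity), so a weak band in a quiet spectral region beats
noise blips on a strong band; two initialisation strategies are run and
the better SSE wins.  Exact Gaussians are recovered to 10⁻⁶, two bands
separated by one width to well under 5% of the width, and the
dry-gel preset with a 40× phosphorescence contrast is recovered within
~10% (the band-area estimate of a weak band over Poisson background
carries a few percent of irreducible noise; the fixed-seed test sits
within 5%).

Spectral matching reports the Pearson correlation of despiked,
area-normalised intensities on the common grid; area (not peak)
normalisation is robust to single-channel artefacts.

## Image profiling

Camera frames are RGB arrays; conversion to grayscale uses the standard
luminance weights (0.299, 0.587, 0.114).  Registration is translation-only
(the acquisition superimposes two frames from a fixed camera) by
exhaustive normalised cross-correlation over ±10 px, which keeps the
oracle exact: synthetic shifts are recovered with zero error.  The depth
profile averages over the lateral FWHM band around the lateral maximum —
the original description does not state the averaging region, so the band
is also a user argument — and the maximum is located by the same 3-point
parabolic interpolation as the Bragg peak.  Since no binary image codecs
exist in the offline stack, file I/O uses ASCII PPM (P3); in-memory arrays
are the primary interface.  Pixel scale and entrance line are explicit
user inputs (not recoverable from the published material).

## Cell response

Viability is mean blank-corrected absorbance over ≥ 3 wells divided by the
matched unirradiated control of the same PS status — irradiated no-PS
cells against media controls, PS-incubated cells against PS dark controls
— with delta-method SEM.  Values above 1.2 are flagged, not clipped.  The
differential gain is viability(no PS) − viability(PS) in percentage
points; per (experiment, dose) a two-sided Welch test on per-well
viabilities is reported (the original work reports P values without naming
a test; Welch is the defensible default and is documented as
configurable).  No multiple-testing correction is applied, matching the
reported raw per-dose P values.  Doses tested once only yield `NA`
p-values.  The survival simulator is linear-quadratic at RBE 1.1 with a
multiplicative proton-dynamic term $e^{-k_\mathrm{pd} D c}$ — the minimal
formalisation of an additive ~20-point differential effect; it reduces to
pure LQ at zero PS.

## Synthetic generators: the stated world

Each generator is deterministic under its seed (RNG state is saved and
restored), embeds its complete ground truth, and produces data satisfying
the consuming module's invariants by construction.

* **Beam images** — 12.5 MeV in DMSO, ErB-like PS at 110 µM, enhancement
  800 M⁻¹ (true fluorescence maximum ≈ 1.65 mm, inside the measured
  1.6–1.7 mm window), 10 mm lateral FWHM, 25 µm/px, red-dominant signal,
  a static bench background shared by lit and dark frames, Poisson photon
  noise, 8-bit quantisation, optional integer dark-frame shift.  Not
  emulated: demosaicing, gamma, optics blur, beam-current drift.
* **Spectra** — Gaussian bands on a flat dark level, Poisson counting
  noise, sparse high spikes on proton acquisitions; a 1270 nm ¹O₂ band
  preset with configurable SNR (the low-SNR preset, 0.5–2, exercises
  background subtraction; quantitative 2% area recovery is only meaningful
  at high SNR and is tested there); a dry-gel preset with a 40×
  phosphorescence contrast.
* **Kinetic traces** — forward solutions across (mode × DABCO) with 3%
  multiplicative Gaussian noise.  The truth is fixed by the observed
  contrasts: 20% maximum light-mode loss fixes σ_so = −ln 0.8; 80%
  proton-mode loss and 25-point DABCO protection fix the proton excitation
  ratio (3.63) and σ_ion.  η = 0.3 and r = 1 complete the record.
* **Plates** — LQ parameters α = 0.08 Gy⁻¹, β = 0.006 Gy⁻² (glioblastoma
  scale), doses 0/2/5/10 Gy, cercosporin-like 6 µM, 5 experiments × 3
  wells, 5% well noise, per-experiment beam scale factor (0.9–1.1), blank
  offset 0.08 OD.  The proton-dynamic coefficient is *solved* so the
  programmed mean gain is 19 points; recovery across the pipeline lands
  within 3 points.

A green test therefore establishes that the pipeline recovers the
parameters of data generated by its own forward models under realistic
noise — not that those models capture every feature of real detectors,
beams or cells.

## Numerical choices

RK45 rtol 10⁻⁸; range tables on 3000 log nodes with Hyman monotone
splines; peak localisation by exact 3-point parabola with a degenerate
(flat) input error; linearity flag at r² < 0.95; despike window 7 /
threshold 6 robust SDs with a 1% intensity floor; registration correlation
floor 0.2; bootstrap seed 20190904.  Tie-breaks: a curvature-free
3-point neighbourhood returns the grid argmax; band tables are sorted by
centre; the quenched phosphorescence band must match the unquenched band's
centre within 3 widths, otherwise the ratio is reported as a lower bound
with a flag.

## Known limitations

No shell/Barkas corrections, nuclear interactions, secondary particles or
lateral scattering beyond a fixed Gaussian width; no Monte-Carlo
transport.  The enhancement term is phenomenological with an unknown
functional form.  The kinetics lump all non-¹O₂ loss into one
DABCO-insensitive channel and ignore oxygen depletion.  P values from the
original cell experiments cannot be recomputed without per-well raw data
and are not targets.  Absolute radiometric calibration, instrument
response and wavelength calibration are out of scope throughout.
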