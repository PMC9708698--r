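---
title: "Inferring base-pair opening kinetics from imino-proton exchange"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring base-pair opening kinetics from imino-proton exchange}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iminoex)
```

## The physical model

A Watson–Crick or Hoogsteen base pair shields its imino proton (guanine H1,
uracil/thymine H3) from solvent. Exchange with water protons happens only in
the transiently open state, catalyzed by a base `B:` that abstracts the
proton. With opening rate $k_\mathrm{open}$, closing rate $k_\mathrm{close}$
and open-state exchange rate $k_\mathrm{ex,open}$, the observed exchange
rate is

$$k_\mathrm{ex} = \frac{k_\mathrm{open}\, k_\mathrm{ex,open}}
                        {k_\mathrm{close} + k_\mathrm{ex,open}} .$$

Two consequences drive the whole analysis:

* $k_\mathrm{ex} \le k_\mathrm{open}$ always (`overall_exchange_rate()`
  enforces and tests this), so a measured exchange rate is a *lower bound*
  on the opening rate — the basis of the in-cell classification, where the
  intracellular catalyst concentration is unknowable.
* When $k_\mathrm{ex,open} \gg k_\mathrm{close}$ (EX1 regime, reached at
  high base-catalyst concentration), $k_\mathrm{ex} \to k_\mathrm{open}$:
  titrating the catalyst until $k_\mathrm{ex}$ plateaus measures
  $k_\mathrm{open}$ directly.

## Measuring the exchange rate

In a water magnetization transfer experiment the water resonance is
selectively inverted and the imino signal is recorded after a delay $t$.
Exchange carries inverted magnetization into the imino pool, attenuating it:

$$\frac{I(t)}{I_0} = 1 - \frac{2 k_\mathrm{ex}}{R_{1w}-R_{1a}}
  \left(e^{-R_{1a} t} - e^{-R_{1w} t}\right),$$

where $R_{1a}$ is the *apparent* longitudinal relaxation rate of the imino
proton and $R_{1w}$ that of water. `intensity_ratio()` implements this,
switching to the analytic limit $1 - 2k_\mathrm{ex}t\,e^{-R_{1a}t}$ when
$|R_{1w}-R_{1a}| < 10^{-9}\,\mathrm{s^{-1}}$; the general branch uses an
`expm1` formulation so both branches agree to better than $10^{-8}$ at the
switch point.

**The apparent-rate reading.** The package interprets the $R_{1a}$ of the
transfer equation as the rate measured by selective inversion recovery,
which already contains the exchange contribution
($R_{1a} = R_{1a}^\mathrm{intrinsic} + k_\mathrm{ex}$). This is the only
reading under which the closed form solves the two-pool exchange system
exactly, and it matches what the recovery experiment actually measures.
`mcconnell_two_pool()` integrates the coupled two-pool longitudinal
equations (with detailed-balance back-exchange scaled by the water-to-imino
population ratio) as an independent numerical oracle; the test suite checks
agreement with the closed form to $10^{-4}$ relative across a parameter
grid at a population ratio of $10^6$. A full Bloch treatment (transverse
components, shaped-pulse profiles, radiation damping) is out of scope.

Perfect water inversion (the factor 2) is assumed; an
`inversion_efficiency` scalar (default 1) is available where the inversion
is imperfect.

## Fitting

`fit_exchange_rate()` performs bounded nonlinear least squares with two
free parameters: $k_\mathrm{ex} \in [0, 10^4]\,\mathrm{s^{-1}}$ and the
amplitude $I_0 \ge 0$. How the experimental $I_0$ was normalized is
unknowable from intensity tables alone, so the amplitude is always floated;
the fit is consequently invariant to intensity rescaling (tested to
$10^{-8}$ relative). Since the model is linear in $I_0$, the amplitude is
profiled out in closed form and the one-dimensional profiled objective is
minimized globally: a 61-point logarithmic grid over the $k_\mathrm{ex}$
bounds followed by golden-section refinement of the best bracket. A joint
two-parameter descent was found to possess a spurious second minimum on
noisy series (very large $k_\mathrm{ex}$ compensated by a near-zero or
negative amplitude); profiling with the non-negativity constraint removes
it, and the grid stage makes the fit start-point-free and deterministic.

$R_{1a}$ and $R_{1w}$ come from `fit_inversion_recovery()` /
`fit_saturation_recovery()` — Levenberg–Marquardt fits (via minpack.lm,
which is robust on zero-residual data) of
$I_\infty(1-2e^{-R_1 t})$ and $I_\infty(1-e^{-R_1 t})$ with asymptotic
standard errors. Flat series are rejected as unidentifiable.

**Error propagation.** `monte_carlo_kex()` perturbs the *observed*
intensities with independent Gaussian noise at the spectral noise sd
(estimated from a signal-free region by `estimate_noise_sigma()`), refits
each of 50 replicates (the default), and reports the replicate mean and sd.
Perturbing around observed rather than fitted intensities is a choice:
it makes the replicate distribution reflect the data actually in hand.
Uncertainty in $R_{1a}$/$R_{1w}$ is deliberately not propagated — the
error model attributes the error bars to spectral noise alone — and
replicate failures above 20% flag the result. With a fixed seed results are
bit-identical; the global RNG state is saved and restored.

**Slow sample decay.** When intensities decay linearly across acquisition
(e.g. slight leakage of oligonucleotide during an in-cell run),
`correct_leakage()` divides the spectrum recorded $k$-th of $n$ by
$1 - L\,(k-1)/(n-1)$, where $L$ is the total fraction lost. Because delays
are acquired in scrambled order (the default order is 100, 1, 10, 60,
30 ms), the correction follows acquisition rank, not delay order. For a 16%
loss over five spectra the multipliers are 1, 1/0.96, 1/0.92, 1/0.88,
1/0.84.

Two averaging modes handle overlapped or noisy peaks:
`average_intensity_fit()` (normalize each residue's series by its
shortest-delay intensity, average the ratios per delay, fit once) and
`average_kex_over_residues()` (unweighted mean of per-residue rates, sd
across residues).

## From titration to the opening rate

`base_form_concentration()` converts total Tris to its catalytically active
base form by Henderson–Hasselbalch speciation; the default pKa 8.26 is the
Tris value at 18 °C obtained from 8.06 at 25 °C with the −0.028 K⁻¹
temperature coefficient, quoted to two decimals. This default reproduces
the standard correspondence that ~300 mM total Tris at pH 8.0 delivers
100 mM base form. The exact pH of each titration point is an input field —
buffer pH within a titration is typically only known to a ~0.3-unit window,
so no single value is hard-coded. The two-sample swap protocol
(`titration_mixing_schedule()`) models how concentrations evolve when equal
volumes are exchanged between a low- and a high-concentration sample,
conserving mass and keeping pH and crowders fixed.

`kopen_from_plateau()` implements the plateau rule: the maximum
$k_\mathrm{ex}$ over the titration is taken as $k_\mathrm{open}$, carrying
that point's Monte-Carlo sd and flagging the estimate when the two highest
points still differ by more than 2 combined sd. `fit_saturation_model()` is
a clearly-labelled extension: assuming $k_\mathrm{ex,open} = k_B [B]$
(standard base catalysis) it fits
$k_\mathrm{ex}([B]) = k_\mathrm{open}[B]/(K_{1/2}+[B])$ with
$K_{1/2} = k_\mathrm{close}/k_B$, using the whole curve instead of its
endpoint. Neither $k_\mathrm{close}$ nor the open-state lifetime is
estimated in absolute terms — they are not identifiable from plateau data.

`classify_in_cell_opening()` compares the in-cell exchange rate (a lower
bound on the in-cell opening rate) with the in vitro opening rate. The
verdict is `increased_in_cell` only when the ±1 sd intervals separate:
$k_\mathrm{ex}^\mathrm{cell} - \sigma_\mathrm{cell} >
 k_\mathrm{open}^\mathrm{vitro} + \sigma_\mathrm{vitro}$.
The published analysis makes these calls visually from error bars; the
±1 sd rule is this package's explicit formalization, and the multiplier is
configurable. The bound is one-sided, so `decreased` is never a possible
verdict, and raising the in-cell rate can never flip a verdict back to
indeterminate (tested).

## The synthetic-data generator

No raw spectra are publicly available, so the generator *is* the study's
data source, and its defaults are fixed at the study conditions rather than
being tuning knobs:

* Five residues (G4, U14, G15, U18, G19) with two-state kinetics solved
  exactly through the published exchange rates at 10 and 300 mM total Tris
  (`hprna20_truth_kinetics()`); the published in-cell rates serve as the
  in-cell truth. The catalysis constant $k_B = 2\times10^5$ mM⁻¹s⁻¹ is a
  typical near-diffusion-limited proton-transfer value; only
  $K_{1/2}=k_\mathrm{close}/k_B$ affects the generated data.
* Delays 1, 10, 30, 60, 100 ms acquired in the scrambled order 100, 1, 10,
  60, 30 ms.
* $R_{1a}^\mathrm{intrinsic} = 2.0$, $R_{1w} = 0.4\,\mathrm{s^{-1}}$ —
  representative of imino protons in mid-size nucleic acids and of cellular
  water at 600 MHz.
* Additive homoscedastic Gaussian noise at 1% of the reference amplitude in
  vitro (signal-to-noise ~100, typical of a 1024-scan 1D); the in-cell
  noise sd is 6× the in vitro value, inside the plausible 4–8× window for
  the broader, noisier in-cell spectra. Where a published error bar must be
  matched without knowing the underlying noise, `noise_sd_for_kex_sd()`
  inverts the delta-method covariance of the two-parameter fit to find the
  intensity noise producing a requested $k_\mathrm{ex}$ sd.
* An 8-point titration from the swap schedule (10→300 mM, swap fraction
  0.25, 3 steps), plus a single in-cell condition; recovery series for
  every (residue, condition) and water series per condition.

What the generator does **not** emulate: frequency-domain lineshapes, peak
overlap, baseline distortions, $B_1$ inhomogeneity, NOE-mediated transfer
pathways, or heteroscedastic noise. Passing tests therefore demonstrate the
correctness of the estimators under the stated error model, not robustness
to spectral artifacts.

`generate_study()` writes the whole bundle as TSV plus a YAML manifest
(seed, truth, buffers); all randomness flows from the one seed in the
manifest, so bundles are byte-reproducible. Numbers are written with 17
significant digits so read/write round trips are lossless.

## The ensemble contact screen

Protons resonating within the water-inversion bandwidth (sugar H3′, about
half of the H4′) can relay magnetization to imino protons by NOE, mimicking
exchange. `imino_sugar_contacts()` screens a multi-model NMR ensemble
(loaded through bio3d, hydrogens required, `H4*`/prime-mark dialects
normalized) for sugar protons near imino protons. The conservative reading
of "in more than six of twelve structures" is at least 7 models
(`min_models = 7`; the parameter is exposed so 6 can be probed), with a
strict `<` comparison at the 5 Å cutoff (a `strict = FALSE` switch gives
`<=` for sensitivity checks). Both inter- and intra-residue pairs are
counted, and the default donor list covers guanine H1 and thymine/uracil
H3. The screen is validated against a brute-force all-pairs oracle and on a
synthetic 12-model ensemble (`synthetic_gq_ensemble()`, labelled synthetic)
whose geometry places exactly two H4′ protons inside the cutoff across all
models, one borderline pair inside it in only 5 of 12 models, and every H3′
outside — the configuration the screen must resolve. The deposited
telomeric ensemble itself is not redistributed with the package; the screen
accepts any multi-model PDB path.

## Numerical choices and problem sizes

* Exchange-fit bounds $[0, 10^4]\,\mathrm{s^{-1}}$; optimizer tolerance
  `factr = 1e4`; degenerate-rate tolerance $10^{-9}\,\mathrm{s^{-1}}$.
* ODE oracle: `lsoda` at `rtol = 1e-11`, `atol = 1e-12`; population ratio
  $10^6$ in oracle tests.
* Duplicate titration concentrations collapse to their mean with a warning;
  empty series, flat recoveries, and sub-minimal point counts raise errors
  rather than returning silently degenerate fits.
* The test suite sizes its simulations for depth rather than bulk: 200
  series for the bias/coverage study (median absolute relative bias < 5%,
  ~68% nominal 1-sd coverage), 1000 series for the opening-rate-bound
  property, 50 Monte-Carlo replicates as the working default.

## Known limitations

* The apparent-$R_{1a}$ interpretation, while the only self-consistent one,
  is an interpretation; data fitted with an exchange-free $R_{1a}$ would
  need the oracle's intrinsic-rate convention instead.
* The ±1 sd separation rule is a formalization of a visual judgement; with
  n = 1 spectra per point there is no distributional basis for a sharper
  test.
* In-cell noise magnitude and the in-cell opening rate itself are not
  observable; the generator emulates plausible conditions, and the in-cell
  truth enters only through the one-sided bound.
* The saturation model assumes a single monoprotic catalyst and
  activity-ideal speciation; ionic-strength corrections are out of scope.
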