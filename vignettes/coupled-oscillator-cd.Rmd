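---
title: "Coupled-oscillator CD of dimeric chromophores: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled-oscillator CD of dimeric chromophores: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devoecd)
```

## The model and its assumptions

`devoecd` treats a multichromophoric molecule as a set of classical
point-dipole oscillators, one per electrically allowed electronic
transition, fixed in a rigid molecular frame. The assumptions this buys
and their limits:

- **Point dipoles.** Each transition is collapsed to a point at its
  chromophore center. This is adequate when inter-chromophore distances
  are large compared to the chromophore (here ~10–15 Å vs ~5 Å aromatic
  cores); it degrades for close contacts, and no monopole expansion is
  offered.
- **Electronic independence.** The coupled-oscillator picture requires the
  transitions on the two moieties to be independent; conjugation across
  the biaryl linkage mixes them and invalidates quantitative predictions.
  That is exactly the regime the low-energy (> 300 nm) bands of
  tropolone-containing dimers live in, which is why every published-value
  check in this package is sign-, shape- or ratio-based and the engine is
  positioned as a *rationalization* tool, not a spectrum predictor.
- **Rigid geometry.** One conformer per calculation. Conformer ensembles
  are handled downstream by `ensemble_spectrum()` with Boltzmann weights.

At each wavenumber ν the engine builds B = diag(1/α) + G, inverts it, and
contracts Im A = Im B⁻¹ with the pseudoscalar weights R·(e×e) (CD) or the
scalar weights e·e (absorption). Inversion at every grid point is the cost
of the all-order treatment; for n ≤ ~20 oscillators on a ~10³-point grid
this is well under a second.

## Units and convention constants

Internally everything is in wavenumbers (cm⁻¹); interfaces speak nm with
λ = 10⁷/ν. Geometry is Å, converted to cm inside the coupling, so that
with cgs polarizability volumes (cm³ per molecule) 1/α and G share the
unit cm⁻³ and B is dimensionally clean.

The prefactors of the working equations are *convention constants*,
exposed in `devoe_constants()` and overridable per call:

- `alpha_conversion` = 1000·ln10/(8π²N_A) ≈ 4.84×10⁻²³: from the
  absorption cross-section σ = 4πkα″ with k = 2πν, giving
  α″(ν) = C·ε(ν)/ν.
- `abs_constant` is its inverse, chosen so an *uncoupled* oscillator
  reproduces its input band exactly — the decoupled limit is the anchor
  of the absorption normalization (tested to 1%).
- `cd_constant` = 4π·`abs_constant`. With this choice couplets come out
  at ~1 M⁻¹cm⁻¹ for ε_max = 10⁴ and R = 14.5 Å, the observed order of
  magnitude for such dimers.
- `coupling_constant` = 1 (bare cgs dipole–dipole tensor).

Because the source equations for this family of models circulate with
several normalizations, no test in the package asserts an absolute CD
magnitude; amplitude checks are always ratios (ε²-scaling, 1/R²-scaling,
mirror antisymmetry, full/first-order agreement), which the constants
cancel out of.

## Kramers–Kronig: causal vs resonance transform

`kk_real_from_imag()` offers two conventions, and the choice is a real
design decision, not numerics:

- **`"causal"` (default).** The full response-function relation
  α′(ν) = (2/π) P∫₀^∞ ν′α″(ν′)/(ν′²−ν²) dν′, i.e. the Hilbert transform
  of the *odd extension* of α″. The resulting α = α′ + iα″ is analytic in
  the upper half plane, and a contour argument then makes
  ∫₀^∞ ν·Im(αᵏ) dν vanish for every power k — which is precisely why the
  all-order coupled CD is *exactly* conservative (net rotational strength
  zero) in this mode, at any band width. The price: the non-resonant term
  shifts the zero of α′ off the band center by O(width²/center), a few
  cm⁻¹ for typical electronic bands — within one grid step at the 15–40
  cm⁻¹ resolutions used here.
- **`"resonance"`.** The one-sided (rotating-wave) Hilbert transform.
  For a symmetric α″ it is exactly antisymmetric, so α′(ν₀) = 0
  identically — the cleaner *local* statement — but the conservative-
  couplet integral then only vanishes to O(width/center), a few percent
  for broad bands.

Both satisfy the sign rule (α′ > 0 on the long-wavelength side, < 0 on the
short-wavelength side). Tests that assert exact antisymmetry use
`"resonance"`; everything flowing into the engine uses `"causal"`.

The principal value is computed by singularity subtraction:
[α″(ν′)−α″(ν)]/(ν′−ν) is smooth and trapezoid-integrable, and the
subtracted constant integrates to the analytic log term. Accuracy against
the closed-form Lorentzian dispersion (the oracle) is ~0.1% at 20 cm⁻¹
steps; grids must cover every band with a 3×FWHM margin, and tails that
fail to decay below 1% (10%) of the maximum at the grid ends draw a
warning (error).

## Numerical guards in the engine

- Frequency points where any |α_i| falls below 10⁻¹² of that band's
  maximum are skipped and linearly interpolated over (1/α diverges
  off-resonance for narrow bands). Zero-intensity bands are removed
  before inversion: they are spectroscopically inert but would make
  1/α singular.
- B with a 1-norm condition estimate above 10¹² is an error.
- Complex symmetric inversion uses LAPACK via `solve()`; a 2×2 hand
  inversion is kept in the test suite as the machine-precision oracle.

## What the synthetic generators emulate

The generators state a world once; their defaults are not tuned to tests.

- **`make_twisted_pair()`**: two identical oscillators perpendicular to
  their separation axis, twisted by a dihedral. Default separation 14.5 Å,
  the inter-moiety distance of the dimeric alkaloid's stable conformer.
  Dihedral 0 is the CD-silent coplanar arrangement; ±θ are enantiomers.
- **`make_multiband_molecule()`**: seven bands at 377, 342, 305, 270,
  252, 235, 222 nm — the extrema wavelengths of the biisocolchicide
  solvent series — with the strong/weak and sign pattern of its two band
  families. Geometrically, all in-window oscillators are parallel (their
  mutual cross terms vanish identically) and chirality is injected by a
  single intense far-UV anchor transition at 190 nm, emulating the strong
  sub-200 nm bands such chromophores carry. Each visible band then shows
  one monosignate cross term ∝ ε_i(λ)·α′_anchor(λ), peaked at its own
  center because the anchor's dispersion is flat across the window; the
  sign is set by which side of the anchor the pair sits on. Widths
  default to 600 cm⁻¹ (vibronic-component scale): the recovery target —
  extrema *at* the listed wavelengths — is only achievable when in-pair
  exciton shifts (|Gα| ≲ 0.1, pair spacing 5 Å) and neighbouring-band
  dispersion slopes are small, and broad strongly-coupled bands genuinely
  displace extrema by several nm. That displacement is physics, not
  error; the generator is *designed* to sit in the regime its contract
  names.
- **`make_solvent_series()`**: members are two-basis mixtures with the
  hidden weight following a logistic switch in water mole fraction,
  centered at X_w = 0.9, steepness such that 90% of the change happens
  within ΔX_w = 0.05 — the "swift change at vanishing co-solvent"
  behaviour. The two bases cross at exactly the designed isodichroic
  wavelengths (280 and 320 nm by default; the difference spectrum is a
  quadratic with those roots under a wide spectral envelope, so it
  vanishes nowhere else on the grid). `three_state` mode adds a hidden
  mid-switch component at 20% relative amplitude, which removes the
  common crossings and defeats any two-basis reconstruction — the
  negative control. Compositions are denser near the switch, as a real
  titration would be run.
- **`make_mutarotation_trace()`**: exact first-order relaxation of the
  minor-atropisomer fraction, default 17% → 5% (the chloroform-to-ethanol
  solvent jump) with k_obs = 0.1 min⁻¹, so equilibration is essentially
  complete within the ~45 min the real jump takes.
- **Noise** is additive i.i.d. Gaussian on the ordinate — chart-recorder
  noise — at 1% of signal amplitude by default; no wavelength
  correlation, no baseline drift, no concentration error. A green
  round-trip therefore establishes correctness of the estimators under
  the stated noise model, not robustness to structured artefacts.
  Every stochastic output requires a seed; ground truth is returned
  separately from the observable and never depends on the seed.

## Analysis defaults that the data do not fix

- Isodichroic agreement tolerance: 2% of the maximal across-member
  spread. Published series analyses locate these points visually; 2% is
  tight enough to reject three-component series and loose enough to merge
  the contiguous grid hits around a true crossing.
- Two-basis rejection factor: residual RMS > 3× the stated noise level in
  any member rejects the two-state hypothesis (with a machine-level floor
  so noiseless round trips pass). 3σ is the conventional decision line.
- Non-overlap for the non-degenerate cross term: band separation ≥ 3× the
  summed half-widths. The underlying expansion only requires "not
  overlapping"; 3× keeps α″ leakage below ~1%.
- Extrema: 5-point moving-average smoothing, parabolic sub-grid vertex
  placement, 2%-of-maximum prominence threshold.
- Relaxation fits: unweighted least squares (`nls`) with log-linearized
  starting values and `scaleOffset = 1` so exact, zero-residual traces
  converge; traces are short and near-uniform in noise, so weighting
  would add nothing.
- Gas constant 1.987×10⁻³ kcal mol⁻¹ K⁻¹, default temperature 300 K. A
  caution inherited from the data this models: population ratios printed
  as small rounded integers (5/95, 3/97) carry up to ~0.2 kcal/mol of
  rounding uncertainty in the recomputed ΔG, and some tabulated values
  disagree with exact recomputation by more than 10%. The package always
  reports recomputed values and leaves the reconciliation to the user.

## Known limitations

- No vibronic structure, no solvent shift of band positions, nothing
  quantum-chemical: band parameters are inputs, not predictions.
- One point dipole per transition; extended or strongly conjugated
  chromophores are outside the model's quantitative reach (see above).
- JCAMP-DX support is the minimal `XYDATA=(XY..XY)` form only.
- The CLI writes CSV and JSON only; plotting is limited to base-graphics
  quick looks via `plot()` methods.
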