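---
title: "Methods: drought-recovery photosynthesis limitation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drought-recovery photosynthesis limitation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photolim)
library(dplyr)
```

photolim implements the quantitative analysis chain used in field studies of
photosynthesis under drought and rewatering: fluorescence-based electron
transport, mesophyll conductance by the variable-J method, partitioning of
the assimilation deficit into stomatal, mesophyll and biochemical
limitations, soil and leaf water-status indices, relative-standard-curve
qPCR quantification of gene expression, and d-separation testing of causal
path models linking aquaporin and carbonic anhydrase expression to
conductances and assimilation. A forward leaf simulator and a synthetic
study generator provide ground truth for every stage.

## Electron transport from modulated fluorescence

The actual PSII photochemical efficiency is
$\Phi_{PSII} = (F_m' - F_s)/F_m'$, and the linear electron transport rate

$$J = \Phi_{PSII} \cdot PPFD \cdot \alpha \cdot \beta,$$

with $\beta = 0.5$ the fraction of absorbed quanta reaching PSII (equal
partitioning between photosystems) and $\alpha = 0.93$ the leaf absorptance.
Both constants are held in `fluor_constants()` and can be overridden, e.g.
with a measured absorptance. `calibrate_phi_relationship()` regresses
$\Phi_{PSII}$ on $\Phi_{CO_2} = (A_N + R_d)/PPFD$ from low-oxygen
light-response records; it is a validity check on the fluorescence signal,
not a correction, so a curvilinear relationship (quadratic term with
$|t| > 2$) only raises a warning.

## Mesophyll conductance by the variable-J method

Combining gas exchange with fluorescence-derived $J$ gives the chloroplastic
CO$_2$ mole fraction and the mesophyll conductance:

$$C_c = \frac{\Gamma^* \left[J + 8(A_N + R_d)\right]}{J - 4(A_N + R_d)},
\qquad g_m = \frac{A_N}{C_i - C_c}.$$

$\Gamma^*$ follows the standard Arrhenius parameterization (42.75 µmol
mol⁻¹ at 25 °C, $\Delta H_a$ = 37 830 J mol⁻¹). $R_d$ is the dark
respiration measured per campaign and attached to each record rather than a
global constant. Estimates are accepted when the sensitivity

$$\frac{dC_c}{dA_N} = \frac{12\,\Gamma^* J}{\left[J - 4(A_N+R_d)\right]^2}$$

lies in the inclusive window [10, 50]: below it the fluorescence signal
barely constrains $C_c$; above it small errors in $A_N$ dominate the
estimate. Records with $J \le 4(A_N+R_d)$ (electron transport below the
carboxylation demand floor) or with $C_i \le C_c$ at positive assimilation
are flagged and excluded from group summaries rather than clipped —
clipping would fabricate conductances. `derive_gasex()` applies the whole
chain to a table of records and reports how many were excluded.

A caution that the synthetic experiments make quantitative: the estimator
is heavy-tailed. Because $g_m = A_N/(C_i - C_c)$ with a difference in the
denominator, a few percent of noise on $A_N$ and $J$ occasionally produces
individual estimates several-fold too high, especially when the drawdown
$C_i - C_c$ is small. Group means of six replicates still fluctuate
visibly; medians are more robust if only the central tendency is needed.

## Limitation partitioning

`limitation_analysis()` partitions the assimilation deficit of each stressed
group against the *same-day* well-watered control mean (control assimilation
drifts over a season, so a fixed pre-drought baseline would conflate drift
with stress; days without a usable control are skipped, with no cross-day
interpolation). With the total diffusive conductance
$g_{tot} = (1/g_{sc} + 1/g_m)^{-1}$ and the assimilation sensitivity
$x = \partial A/\partial C_c$ evaluated analytically on the
RuBP-regeneration-limited branch at the reference $C_c$,

$$l_s = \frac{g_{tot}}{g_{sc}}\cdot\frac{x}{g_{tot}+x},\quad
  l_m = \frac{g_{tot}}{g_{m}}\cdot\frac{x}{g_{tot}+x},\quad
  l_b = \frac{g_{tot}}{g_{tot}+x},$$

which sum to one identically. The components are the first-order,
finite-change decomposition

$$S_L = l_s\,\frac{\Delta g_{sc}}{g_{sc}},\quad
  MC_L = l_m\,\frac{\Delta g_m}{g_m},\quad
  B_L = l_b\,\frac{\Delta ETR}{ETR},\quad T_L = S_L + MC_L + B_L.$$

ETR substitutes for carboxylation capacity in $x$ and $B_L$: the two are
tightly coupled, and ETR is measurable on every field date whereas
$V_{cmax}$ from A–C$_i$ curves is not (and is unreliable at low $g_s$).
Components are computed on group means by default (`per_leaf = TRUE`
averages per-leaf partitions instead). A stressed value above its reference
yields a negative component, reported as such. When components are
expressed as percentages of $T_L$, the divisor is floored at $10^{-9}$ so
that fully recovered days (all limitations vanished) do not divide by zero.

Accuracy of the first-order form, measured against the forward model: for
simultaneous 5% declines in all three drivers the error on $T_L$ is about
5%; across random ≤10% perturbations it stays near or below 10%. The one
systematic weak point is a pure ETR perturbation: the true response to a
change in ETR scales with *gross* assimilation while $T_L$ is expressed
relative to *net* assimilation, so $B_L$ is underestimated by roughly the
factor $1 + R_d/A_N$ (≈ 9% at the default study conditions), which can push
the pure-ETR case slightly past 10% relative error. This is a property of
the formulation, not of the implementation.

## Water status

`rew()` computes soil relative extractable water
$(\theta - \theta_{min})/(\theta_{max} - \theta_{min})$ with defaults
$\theta_{min} = 0.04$ (wilting point) and $\theta_{max} = 0.25$ m³ m⁻³
(field capacity); values above 1 occur transiently after irrigation and are
not clipped. $\theta$ is expected pre-averaged over measurement depths.
`rwc()` is the percent-of-full-turgor leaf water content
$(fresh - dry)/(turgid - dry) \times 100$.

## qPCR relative quantification

`fit_standard_curve()` regresses Ct on $\log_{10}$(template quantity) over
a dilution series (the 1, 10, 50, 100 ng design); a perfectly doubling
reaction has slope $-1/\log_{10} 2 = -3.3219$ cycles per decade.
Amplification efficiency $10^{-1/slope} - 1$ is reported for quality
control (warning outside 0.9–1.1) but not used to correct quantities — the
relative standard curve method interpolates every unknown on the same
curve, which subsumes efficiency. `relative_expression()` averages
technical replicates on the Ct scale (manufacturer convention; a
quantity-scale option exists), interpolates quantities, normalizes by the
same sample's housekeeping quantity and scales by the calibrator sample so
the calibrator's relative expression is exactly 1. Cts above 40 are treated
as missing and flagged; interpolations outside the dilution range are
flagged as extrapolations. `normalize_to_first_date()` is the shared
utility that scales any series (expression, $g_s$, $g_m$) by its
treatment-wise first-date mean for cross-variable comparison.

## d-separation path analysis

A causal hypothesis is a DAG over named variables (`causal_model()`,
readable from JSON/YAML). Cyclic graphs are refused with the offending
cycle printed. Notably, the physiologically attractive wiring in which
carbonic anhydrase expression both responds to assimilation and feeds back
on mesophyll conductance ($g_m \to A_N \to CA \to g_m$) is cyclic and
cannot be tested by d-separation; the shipped fixture `model3_acyclic()`
is that model with the feedback edge removed.

Testing uses the union basis set: one independence claim per non-adjacent
pair $(x, y)$, conditioned on the union of both vertices' parents. The set
has exactly $\binom{v}{2} - |E|$ claims, in deterministic lexicographic
order. Each claim is tested by Fisher-z partial correlation (computed from
the inverse covariance submatrix, which equals the residual-regression
estimator; complete cases only), the claim p-values are combined with
Fisher's $C = -2\sum \ln p_i$, and $C$ is referred to $\chi^2_{2k}$. The
fixture model has 8 claims, hence 16 degrees of freedom. A saturated model
has no claims and reports $P = 1$ with an `untestable` flag.
`compare_causal_models()` ranks models by $P$ (ties to fewer edges).

On linear-Gaussian data simulated from the fixture model ($n = 200$, 1000
replicates) the test rejects at close to the nominal 5%; a single violating
path of standardized strength 0.6 is detected essentially always. The
Gaussian partial-correlation test is the default to match the Pearson
correlations used in this literature; a rank-based variant can be obtained
by rank-transforming the data first.

## The synthetic study generator

`simulate_study()` emulates a three-treatment field experiment — C
(well-watered control), S (drought), SP (drought, pruned), six trees each —
measured on a schedule spanning water withholding at day 0 and rewatering
at day 13, under saturating light (1800 µmol m⁻² s⁻¹) and 400 µmol mol⁻¹
CO₂. Its purpose is ground truth for the pipeline, not inference about any
real site.

Leaf steady states come from the forward Farquhar–von Caemmerer–Berry
model: $A = \min(A_c, A_j)$ with the standard Rubisco kinetics
($K_c$ = 404.9 µmol mol⁻¹, $K_o$ = 278.4 mmol mol⁻¹ at 25 °C with their
Arrhenius scalings, O = 210 mmol mol⁻¹) coupled to the diffusion path
$C_c = C_a - A(1/g_{sc} + 1/g_m)$, solved by bisection on
$C_c \in (\Gamma^*, C_a]$ to $10^{-10}$ µmol mol⁻¹. Fluorescence pairs are
back-computed from $J$ at a fixed $F_m' = 2000$ (only the ratio carries
information). RuBP-limited records invert exactly through the variable-J
chain; Rubisco-limited records are labelled as such in the truth table and
invert with a known downward bias — the regression tests pin both
behaviours.

The drought dynamics are deliberately simple stand-ins for unobserved field
processes, tuned once to the qualitative ordering reported for such
experiments (gas exchange responds before leaf water status; recovery of
$g_s$ is slowest; SP responds faster than S): exponential REW depletion to
a floor of 0.08 (below 0.3 within two days), a power-saturating stomatal
response $f = \min(1, (REW/0.6)^{0.9})$ with first-order recovery
($\tau_S$ = 6 d, $\tau_{SP}$ = 3.5 d), and an electron-transport factor
tracking the stomatal one through a 2-day first-order lag with a floor of
0.65 of the well-watered rate. Mesophyll conductance deserves its own
response: a strictly proportional $g_m = 2.1\,g_{sc}$ coupling would pin
the ratio $MC_L/S_L$ at $g_{sc}/g_m$ on every day, making a rising
mesophyll share of the total limitation impossible by construction. The
generator therefore keeps the well-watered ratio at 2.1 but gives $g_m$ a
threshold-like target $\min(1, (REW/0.28)^2)$ approached with a 4-day
first-order lag — mesophyll conductance tracks leaf rather than soil water
status, holds up under mild deficit and collapses under severe deficit,
then recovers faster than $g_s$. Under these defaults the derived
mesophyll share of $T_L$ rises from early to late drought and diffusional
limitations dominate biochemical ones, the pattern this kind of experiment
reports.

Default scales are olive-like: $g_{sw,max}$ = 0.20 mol m⁻² s⁻¹, $J_{max}$
= 120 µmol e⁻ m⁻² s⁻¹, $R_d$ = 1.2 µmol m⁻² s⁻¹, $T_{leaf}$ = 30 °C; these
keep well-watered $dC_c/dA_N$ near 20–25, inside the Harley window.
$V_{cmax} = 2 J$ keeps leaves RuBP-limited down to $C_c \approx 31$ µmol
mol⁻¹, consistent with the inversion's assumption. Noise has two layers:
fixed lognormal leaf-to-leaf variation (sd 0.08) in conductance and
electron transport, and multiplicative Gaussian measurement noise (CV 2%,
the precision class of a field gas-exchange system) on $A_N$, $J$ and
$g_{sw}$, with $C_i$ recomputed from the noisy $A_N$ and $g_{sw}$ as an
instrument would.

Expression data come from a linear-Gaussian SEM over the fixture DAG with
standardized path coefficients (residual variances solved from the implied
parent covariances so every vertex has unit variance). Drought enters
through the exogenous aquaporin transcript, which receives a standardized
REW-derived drive (loading −0.6), so the whole expression table is
generated *by* the causal model it is later tested against. The SEM's
$g_s$/$g_m$/$A_N$ columns are standardized analogues of the physiological
variables, not the gas-exchange table's values. qPCR plates are built so
that the quantification chain recovers the requested relative expression
exactly at zero Ct noise (default Ct sd 0.15 cycles, three technical
replicates).

What the generator does *not* emulate: diurnal courses (one measurement
time per day), leaf energy balance, ABA or hydraulic signalling, cuvette
leaks, amplification-curve artefacts, and any coupling of expression noise
across genes. Passing tests therefore demonstrate that the analysis chain
is correct and calibrated on data satisfying its assumptions — not that
those assumptions hold in any particular field data set.

## Numerical and design choices

- Bisection tolerance $10^{-10}$ µmol mol⁻¹ on $C_c$; round-trip error in
  $g_m$ is then below $10^{-11}$ relative.
- Harley window [10, 50], inclusive on both ends, configurable.
- Fisher-z p-values use $n - |S| - 3$ effective observations; claims with
  $p = 0$ are floored at $10^{-300}$ with a warning before taking logs.
- Percent-of-total rendering floors $T_L$ at $10^{-9}$.
- Day indexing: day 0 is the last irrigation before withholding; rewatering
  begins day 13; recovery days are day − 13.
- CSVs are written with 6 significant digits by default (configurable).
- Complete-case analysis throughout; no imputation.
- Reproducibility: every stochastic function takes a `seed`; equal seeds
  give byte-identical tables.

Problem sizes used by the validation suite — 500-leaf conductance grids,
1000-replicate calibration runs at $n = 200$, 1000 random reference states
— were chosen to estimate rates to about ±1 percentage point while keeping
a full run in minutes on a laptop.

## Known limitations

- The $B_L$ gross-vs-net mismatch discussed above (~$R_d/A_N$ relative
  underestimate of the pure biochemical component).
- The variable-J estimator's heavy right tail propagates into group means;
  the Harley filter bounds sensitivity but is not an outlier rule.
- The d-separation machinery assumes linear-Gaussian dependencies; strong
  nonlinearity (e.g. the hyperbolic $g_m$–expression relationships seen in
  field data) reduces power and can distort calibration.
- Cyclic causal structures — including the biologically plausible CA
  feedback on $g_m$ — are outside what d-separation can test; the package
  refuses them rather than silently reinterpreting them.
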