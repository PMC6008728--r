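---
title: "Quantifying two-state conformational exchange: models, estimators and numerical choices"
author: "confex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying two-state conformational exchange}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confex)
```

# The problem

A protein that interconverts between a highly populated conformer B and a
sparsely populated conformer E on the microsecond-to-millisecond timescale
leaves two complementary experimental footprints. CPMG relaxation
dispersion NMR measures the effective transverse relaxation rate
$R_{2,\mathrm{eff}}(\nu_{\mathrm{CPMG}})$ of each reporter nucleus, whose
dependence on the refocusing frequency encodes the exchange rate
$k_{ex} = k_{BE} + k_{EB}$, the minor population $p_E$ and per-residue
chemical-shift differences $\Delta\omega$. Molecular dynamics
trajectories, discretised into microstates, yield a Markov state model
(MSM) whose slowest relaxation and stationary distribution give the same
$k_{ex}$ and $p_E$, plus information experiment cannot reach: the
intermediates, pathways, committor values and transition-path times of the
interconversion. confex implements both arms and the thermokinetic
bookkeeping that joins them, with synthetic-data generators providing
known ground truth for every estimator.

# Two-state CPMG dispersion

## Forward models

The numerical forward model propagates the two-state single-quantum
coherence vector $M = (M_B, M_E)$ under

$$L = \begin{pmatrix} -R_{2,0} - k_{BE} & k_{EB} \\
k_{BE} & -R_{2,0} - k_{EB} + i\,\delta\omega \end{pmatrix},$$

through the constant-time CPMG train. One echo element is
$\delta - \pi - 2\delta - \pi - \delta$ with $\delta = 1/(4\nu)$; ideal
$\pi$ pulses act as complex conjugation, so the element propagator is
$E(\delta)\,\overline{E(2\delta)}\,E(\delta)$ with $E(t) = e^{Lt}$
(closed-form 2×2 exponentials, series-corrected near degeneracy). The
number of elements $\nu T_{\mathrm{CPMG}}$ must be a positive integer;
incommensurate inputs are rejected rather than rounded, which reproduces
the conventional minimum frequency $1/T_{\mathrm{CPMG}}$ at one element.
$R_{2,\mathrm{eff}} = -\ln(|M(T_{\mathrm{CPMG}})|/|M(0)|)/T_{\mathrm{CPMG}}$
with $M(0)$ at the equilibrium populations $(1-p_E,\,p_E)$.

Assumptions: in-phase magnetization only, ideal infinitely short pulses,
equal intrinsic $R_{2,0}$ in both states (which makes $R_{2,0}$ an exact
additive offset), no TROSY/anti-TROSY interconversion, no off-resonance
effects. $\Delta\omega$ is parameterised in ppm and converted per field
through the gyromagnetic ratio, so profiles recorded at several static
fields share a single $\Delta\omega$ per residue. Its sign is not
identifiable from CPMG data and is constrained non-negative.

The Carver–Richards closed form is implemented as an independent oracle.
One numerical subtlety matters when comparing the two: Carver–Richards is
the *asymptotic* decay rate (the dominant eigenvalue of the element
propagator — we verified the identity to seven digits), whereas the
propagator's finite-time $R_{2,\mathrm{eff}}$ contains an amplitude
transient of order $\ln(\text{amplitude})/T_{\mathrm{CPMG}}$ arising from
the projection of the initial condition onto the decaying modes. At an
experimental $T_{\mathrm{CPMG}}$ of 20 ms this transient reaches a few per
cent of $R_{2,\mathrm{eff}}$ in the slow-exchange corner
($k_{ex} \sim 500$ s$^{-1}$, large $\Delta\omega$); at 0.5 s it is below
0.2%. The cross-oracle agreement test therefore uses
$T_{\mathrm{CPMG}} = 0.5$ s, where both expressions measure the same
quantity. The degenerate branch of the closed form (the inverse hyperbolic
cosine argument dipping below 1 by rounding in the no-exchange limit) is
clamped at 1, reproducing the exact $R_{2,\mathrm{eff}} = R_{2,0}$ limit.

## Global fitting

`fitTwoStateGlobal()` minimises
$\sum \left((R_{2,\mathrm{eff}}^{obs} - R_{2,\mathrm{eff}}^{model})/\sigma\right)^2$
over global $(k_{ex}, p_E)$, one $\Delta\omega$ per residue and one
$R_{2,0}$ per profile. Because $R_{2,0}$ enters additively, the
per-profile intercepts are profiled out in closed form (the weighted mean
of observed minus exchange contribution), and the nonlinear search runs
over $2 + n_{\mathrm{residues}}$ parameters only, by bounded
Levenberg–Marquardt least squares. A start grid
($k_{ex} \in \{500, 2000, 8000\}$ s$^{-1}$ ×
$p_E \in \{0.01, 0.05, 0.2\}$, $\Delta\omega$ starting at 1.5 ppm) guards
against local minima; user-supplied guesses are *added* to the grid, never
substituted for it, so recovery does not depend on their quality. Ties are
broken by lowest chi-square.

Degenerate data are flagged rather than silently fitted: a dataset whose
exchange model does not beat the exchange-free (intercept-only) model by
more than the 99% chi-square quantile of the extra parameters is marked
unidentifiable — this catches flat profiles ($p_E\,\Delta\omega^2 \approx
0$) without tripping on noise.

Uncertainties come from a residual-resampling bootstrap: residuals are
inflated by $\sqrt{n/(n-p)}$ (fitted residuals are systematically small),
resampled with replacement, added back to the fitted curves, and each
replicate refitted from the original solution. In a calibration experiment
the single-field design shows the classic $p_E$–$\Delta\omega$ ridge
(occasional boundary solutions); a two-field design, as used in practice,
breaks the ridge, and the acceptance suite runs its 100-repeat coverage
check on two-field data for that reason.

# Thermokinetics

With the major state B as reference, $k_{BE} = p_E k_{ex}$ and
$k_{EB} = (1-p_E) k_{ex}$. Each direction is fitted by error-weighted
least squares of $\ln k$ on $1/T$ (weights $(k/\sigma_k)^2$; the Table of
experimental $p_E$ errors is strongly heteroscedastic, and unweighted fits
visibly shift $\Delta H$, so weighting is the default). The activation
enthalpy of the B→E direction is reported as the Arrhenius activation
energy; the $E_a$ versus $E_a - RT$ distinction is left to the caller
since the published fit form is not stated. Equilibrium quantities follow
as $\Delta H = E_a^{BE} - E_a^{EB}$,
$\Delta G(T) = -RT\ln(k_{BE}/k_{EB})$, $\Delta S = (\Delta H - \Delta
G)/T$; errors propagate first-order through the fit covariances (inverse
weighted normal matrix, known-error convention).

The activation free energy uses the transition-path-time relation
$k = (2\tau_{\mathrm{TPT}})^{-1} e^{-\Delta G^\ddagger / k_B T}$, i.e.
$\Delta G^\ddagger = RT\ln(1/(2k\tau_{\mathrm{TPT}}))$, reported in
kJ mol$^{-1}$ and in $k_B T$ ($RT(310.15\,\mathrm{K}) = 2.578$ kJ
mol$^{-1}$). When $2k\tau_{\mathrm{TPT}} \ge 1$ the value (then $\le 0$)
is returned with a `barrierless` flag instead of an error. The
Eyring-prefactor route is deliberately not offered as a barrier estimate:
with a $\sim 6\times10^{12}$ s$^{-1}$ bond-vibration prefactor it
overstates conformational barriers by an order of $10\,k_BT$.

# Markov state models

Counting at lag $\tau$ is sliding by default and never crosses trajectory
boundaries. States outside the largest strongly connected component of
the count graph are trimmed and reported. Two estimators are provided:

* **reversible (default)** — row-normalised symmetrized counts
  $(C + C^T)/2$. Detailed balance holds by construction, the stationary
  vector is the normalised row sum, and the spectrum is computed from the
  symmetric similarity transform, guaranteeing real eigenvalues. This
  estimator assumes the data sample the equilibrium ensemble.
* **non-reversible** — row-normalised raw counts. Each row is a
  conditional estimate and is therefore unbiased under *any* start
  distribution; the stationary vector comes from the leading left
  eigenvector.

The choice matters: for trajectories launched from a minor state or from
transition regions (adaptive seeding — the only way a rare-switch process
yields events on a limited simulation budget), the symmetrized estimator
inherits the sampling imbalance and can misestimate $k_{ex}$ several-fold,
while the conditional estimator remains centred. The recovery tests on
enriched synthetic data therefore use `reversible = FALSE`; for
equilibrium-sampled data the reversible estimator is preferred and is the
default. A detailed-balance maximum-likelihood estimator is a noted
extension point; in our power analysis it did not outperform the
conditional estimator on enriched data.

Implied timescales are $t_i = -\tau/\ln\lambda_i$ for $i \ge 2$ ($t_1$ is
infinite; complex or non-positive eigenvalues yield NA and are flagged),
with eigenvalues sorted by decreasing modulus and ties broken
deterministically. Macrostate lumping uses the inner-simplex (PCCA-style)
vertex search on the top right eigenvectors with crisp argmax
assignment — deterministic given the model, with a warning when the
eigenvalue at the cut is complex. Chapman–Kolmogorov validation compares
propagated set probabilities against matrices re-counted at $n\tau$.

Free-energy surfaces weight each frame by
$\pi(\mathrm{microstate})/(\mathrm{frames\ in\ that\ microstate})$, so the
surface reflects the model's stationary distribution rather than raw
visitation — important exactly when sampling is enriched. 1D profiles
project probability, not free energy.

# Transition path theory

Forward committors solve $q^+_i = \sum_j T_{ij} q^+_j$ on intermediates
with $q^+(A) = 0$, $q^+(B) = 1$; backward committors use the
time-reversed chain (for reversible models $q^- = 1 - q^+$ to numerical
precision). Reactive flux $f_{ij} = \pi_i q^-_i T_{ij} q^+_j$, net flux
$\max(f_{ij} - f_{ji}, 0)$; the total A→B flux equals the net flux out of
the source and is divergence-free at intermediates. Pathways are peeled
off by deterministic bottleneck decomposition (repeatedly take the
widest-bottleneck path, subtract its bottleneck flux; lexicographic
tie-break), which makes path fractions reproducible; stochastic path
sampling would not be. Pathway *counts* depend on the discretisation and
the stopping fraction, so they are treated as fixture-relative
quantities, never compared against a published count.

Transition paths are extracted from labeled trajectories as the segment
from the last frame in the departed core to the first frame in the entered
core, with strict set membership; for continuous trajectories,
`coreLabels()` builds the cores as balls around the well minima. The core
radius trades two biases: too small a core inflates
$\tau_{\mathrm{TPT}}$ with well-bottom wandering, too large a core clips
genuine barrier segments; 0.45 length units (roughly the well width of
the fixtures) sits on a flat part of that trade-off.

# What the synthetic generators emulate

* `simulateCpmgDataset()` — Bloch–McConnell profiles with homoscedastic
  Gaussian noise. The published work estimates errors from repeat
  measurements but does not state a magnitude; the 0.3 s$^{-1}$ default is
  a package choice typical of amide $^{15}$N data and is flagged as such.
  Real data additionally carry baseline and off-resonance artefacts,
  pulse imperfections and per-residue noise levels (a per-point $\sigma$
  override is supported); passing the recovery tests says nothing about
  those effects.
* `nineteenStateModel()` — a reversible 19-state chain with one minor
  metastable state (0, "E"), a fast-mixing 4-state major basin (15–18,
  "B"), three cross-linked parallel pathways of transient intermediates,
  two dead-end kinetic traps and six basin satellites. The conductance
  parameterisation $k_{ij} = S_{ij}/\pi_i$ makes detailed balance exact;
  all rates scale linearly, so the slowest relaxation time is calibrated
  to exactly 3 μs, with $\pi_E/(\pi_E + \pi_B) = 1.4\%$. Frames are
  generated at 2.25 ns, mirroring saved-frame resolution finer than the
  22.5 ns analysis lag. What it does not emulate: discretisation error
  (frames are exact Markov states), so recovery tests probe estimator
  statistics, not clustering quality.
* `simulateLangevin()` — overdamped Euler–Maruyama on 2D Gaussian-well
  potentials. The scheme's stationary-distribution bias is controlled by
  the precondition $dt\,|\nabla^2 U|\,D/k_BT < 0.1$, enforced at
  construction from the well curvatures; trajectories escaping the
  confining region are flagged as an unstable-step symptom. The
  double-well fixture has a bare saddle height of ≈3.9 $k_BT$ and an
  x-projected PMF barrier of ≈3.1 $k_BT$ (`potentialPmfBarrier()`; the
  transverse channel is wider at the saddle than in the wells, and rates
  and transition-path times report on the PMF barrier, which is the
  constructed truth the barrier-recovery test uses). The rugged fixture
  (versioned YAML under `extdata/`) adds two off-path traps between two
  main wells.

# Problem sizes and stochastic-recovery checks

The test suite works at sizes chosen to give each statistical check real
power at interactive runtimes: dispersion fits use 3 residues × 20
frequencies (× 2 fields where the design matters), bootstrap calibration
runs 100 repeats × 80 replicates, Langevin fixtures run 2–4 × 10⁶ steps,
and the 19-state recovery uses 25 independent datasets of ≈145 μs each
(280 trajectories × 0.5175 μs, transition-enriched starts: 60 from E, 55
from each mid-pathway state 1/3/5, 55 from B).

The 19-state check deserves a note on its form. ≈140 μs of trajectory
carries limited information about a 3 μs rare-switch process: across every
estimator and seeding protocol we evaluated, the per-dataset relative
error of the recovered $k_{ex}$ has a median near 10% with a heavy tail —
consistent with the ±12% uncertainty published for the corresponding MD
estimate. A pass/fail test on a single dataset would be dominated by that
sampling noise, so the acceptance test asserts the *median* recovery error
over 25 independent datasets is below 15% (and that the recovered $p_E$
sits within 3 bootstrap standard errors of truth in the median
replicate). This tests the property of the method rather than the luck of
one draw. All seeds are fixed constants.

# Known limitations

In-phase ideal-pulse CPMG only (no TROSY interference, no three-state
models, no CEST/R1ρ); reversible estimation by symmetrization, not MLE;
crisp (not fuzzy) PCCA memberships; 2D potentials only; the
$\Delta G^\ddagger$ relation assumes the barrier does not distort
$\tau_{\mathrm{TPT}}$, which holds to about a $k_BT$ for moderate
barriers; Arrhenius extrapolation assumes temperature-independent
activation enthalpies over the extrapolated range.
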