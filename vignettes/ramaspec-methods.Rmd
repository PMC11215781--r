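---
title: "Models and methods behind ramaspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ramaspec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

ramaspec assesses backbone conformational ensembles of short peptides — the
kind produced by MD simulations of host–guest tripeptides such as GGG or
GAG — against the spectroscopic observables that constrain them
experimentally: backbone scalar couplings from NMR and amide I′ band
profiles from IR, Raman and vibrational circular dichroism (VCD)
spectroscopy. This vignette explains the models the package implements,
the parameters that matter, and the numerical and design choices made
along the way.

```{r setup}
library(ramaspec)
```

## Ramachandran ensembles

The central object is the distribution of the backbone dihedrals
$(\phi, \psi)$ of a single residue. Two representations are supported and
interconvertible:

* **Dihedral series** (`dihedral_series()`): the frame-by-frame trace, one
  $(\phi, \psi)$ pair per trajectory frame, angles in degrees wrapped to
  $[-180, 180)$, with the frame spacing (default 2 ps, a typical trajectory
  output stride) as metadata.
* **Ramachandran histogram** (`build_histogram()`): per-bin probabilities
  on the fixed $180 \times 180$ grid of $2^\circ \times 2^\circ$ cells
  (32,400 bins), with half-open $[\text{edge}, \text{edge}+2^\circ)$ bins.
  This resolution is the standard compromise between angular detail and
  per-bin counting noise for $10^5$–$10^6$ frame ensembles.

### The Gaussian mixture model

Model Ramachandran distributions are represented as superpositions of
two-dimensional Gaussians, one component per local secondary-structure
state (pPII, antiparallel β, the β-transition region, right- and
left-handed helices, ...). Each component has a weight, a center
$(\phi_0, \psi_0)$, widths $(\sigma_\phi, \sigma_\psi)$ in degrees, and
optionally a $\phi$–$\psi$ correlation $\rho$; the published descriptions
of such models mention only widths, but allowing a full $2\times2$
covariance costs nothing and defaults to $\rho = 0$.

Because the Ramachandran space is a torus, the density is evaluated as a
**wrapped Gaussian**: the plane density summed over the $3 \times 3$
nearest periodic images ($\pm 360^\circ$ per axis). The truncation error
of dropping farther images is bounded by the Gaussian mass beyond
$540^\circ/\sigma$ standard deviations of the nearest image; for the
widest plausible secondary-structure component ($\sigma = 45^\circ$) that
is below $10^{-12}$, and fitted widths are far narrower (typically
$8$–$25^\circ$). The torus integral of the density is 1 to better than
$10^{-6}$, which the test suite verifies by quadrature.

Sampling (`sample_mixture()`) picks a component per frame with probability
equal to its weight, draws a correlated bivariate normal displacement, and
wraps. A seed is mandatory: simulated ensembles are first-class inputs to
a reproducible pipeline, not throwaway noise.

**What the generator emulates and what it does not.** Sampled mixtures
reproduce the stationary distribution of a trajectory — the only property
the spectroscopic averages in this package depend on. They are i.i.d.
draws, so they carry no kinetics: no autocorrelation, no slow
interconversion between basins, no drift. Tests that pass on sampled
ensembles therefore validate the estimators, not the convergence of any
real simulation; windowed-population diagnostics on real trajectories can
reveal sampling pathologies that no i.i.d. synthetic ensemble exhibits.
The bundled mixture files (`mixture_gly_synthetic.yaml`,
`mixture_ala_synthetic.yaml`) are *illustrative reconstructions* — their
centers sit in the canonical mesostate regions and their weights are
plausible for glycine-like and alanine-like residues in water, but they
are not fitted to any experimental data set, and nothing in the package
hard-codes them.

### Mesostates

Mesostate boxes coarse-grain the distribution into named states. The four
defaults are the standard boxes for host-guest peptides: pPII
($-90 < \phi < -42$, $100 < \psi < 180$), antiparallel β
($-180 < \phi < -130$, $130 < \psi < 180$), the β-transition region
($-130 < \phi < -90$, $130 < \psi < 180$) and the right-handed helix
($-90 < \phi < -32$, $-60 < \psi < -14$), all in degrees.

Three conventions worth stating explicitly:

* **Strict boundaries.** The definitions are open intervals; a frame
  exactly on an edge belongs to no box. For continuous angles this is a
  measure-zero choice with no practical effect, but it makes histogram and
  frame-wise populations agree exactly, because every default box boundary
  is an even degree and therefore a bin edge.
* **Chirality symmetrization.** For achiral residues (glycine),
  $(-\phi, -\psi)$ is physically identical to $(\phi, \psi)$; symmetrized
  populations add the box and its point reflection. `symmetrize()` applies
  the same idea to mixtures (reflected twin components at half weight),
  series (appended reflected frames) and histograms (averaging with the
  reflected bins — the $2^\circ$ grid maps onto itself under reflection, so
  the pairing is exact).
* **Analysis windows.** Published mesostate tables are sometimes computed
  on a shorter time window than other observables (e.g. 50–300 ns vs
  50–500 ns of a 500 ns trajectory). The window is an argument, never an
  assumption; both conventions are equally accessible by slicing the
  series before analysis.

`windowed_populations()` reports non-overlapping block averages (the
convention of per-point time-average figures) of left-handed
($\phi > 0$), right-handed ($\phi < 0$) or total box populations — the
diagnostic used to detect asymmetric sampling of achiral residues.

### Quadrature

Box integrals of mixtures use a fixed $0.5^\circ$ midpoint grid, accurate
to about $10^{-6}$ for these smooth densities; mixture-weighted ensemble
averages (J-couplings, spectra) use the $2^\circ$ bin-center
discretization, putting model and MD ensembles on exactly the same
footing.

## J-couplings

Five scalar couplings constrain the ensemble per residue:
$^3J(H^N\!,H^\alpha)$, $^3J(H^N\!,C')$, $^3J(H^\alpha\!,C')$, either
$^3J(C,C')$ (glycine) or $^3J(H^N\!,C^\beta)$ (other residues) — all
driven by $\phi$ — and the $\psi$-dependent one-bond $^1J(N,C^\alpha)$.

The vicinal couplings follow the classic Karplus form
$J(\theta) = A\cos^2(\theta + \Delta) + B\cos(\theta + \Delta) + C$.
$^1J(N,C^\alpha)$ is implemented as a truncated Fourier series
($C_0 + A_1\cos\psi + B_1\sin\psi + A_2\cos 2\psi + \dots$), which
accommodates the published low-order empirical fits without committing to
any single one. All coefficients are configuration data
(`extdata/karplus_default.yaml`), defaulting to the widely used
Hu & Bax-style parameterizations for the $\phi$-couplings; the bundled
$^1J(N,C^\alpha)$ coefficients and some coefficient uncertainties are
illustrative, and users comparing to a specific experimental data set
should substitute the parameterization that data set was analyzed with.

Ensemble averages are linear: $\langle J \rangle = \sum_\theta p(\theta)
J(\theta)$ — the frame mean for a series, the weighted bin average for a
histogram or mixture.

**Uncertainty propagation.** The combined uncertainty per observable is
first-order (delta-method) Gaussian propagation,
$s^2 = s_\mathrm{exp}^2 + \sum_k (\partial \langle J\rangle / \partial
p_k)^2 s_{p_k}^2$, where the derivative with respect to each Karplus
coefficient is the ensemble average of its basis function (e.g.
$\langle\cos^2(\theta+\Delta)\rangle$ for $A$). The derivative terms are
averaged over the ensemble rather than evaluated at a mean angle — for a
linear-in-parameters form the two are identical, and averaging is
well-defined for multimodal ensembles where a "mean angle" is not.
Higher-order propagation terms are ignored. Where no coefficient
uncertainties exist (notably $^1J(N,C^\alpha)$ and $^3J(C,C')$), the
experimental uncertainty is used alone; the resulting $\chi^2_J$ is then
an overestimate, which the fit-quality flag records.

## The amide I′ exciton model

A tripeptide has two amide I′ oscillators (the two peptide groups
flanking the central residue). Their delocalized vibrational states are
obtained from the $2 \times 2$ symmetric Hamiltonian with the local
wavenumbers $\tilde\nu_1, \tilde\nu_2$ on the diagonal and a
conformation-dependent coupling $V(\phi, \psi)$ off-diagonal. The
eigenvalues and mixing angle come from the closed-form solution, checked
in the tests against an independent eigendecomposition.

The geometry behind $V$ is an idealized peptide frame built from standard
internal coordinates (bond lengths 1.33/1.46/1.52/1.23 Å for C–N, N–Cα,
Cα–C and C=O; sp² angles; ω fixed at 180°), placed by natural-extension
reference-frame construction so the two amide groups adopt exactly the
requested $(\phi, \psi)$. A point transition dipole (default 0.30 D,
tilted 20° from the C=O axis toward the amide N, origin 0.868 Å from the
carbonyl carbon along C=O) sits on each group, and the default coupling is
transition-dipole coupling between them. Typical computed couplings are a
few cm⁻¹, the right order for nearest-neighbor amide I coupling. A
user-supplied coupling function (e.g. an interpolator over a calibrated
coupling map) can replace TDC, because published calibrations are maps,
not TDC.

Per conformation and exciton state the package computes IR dipole
strengths $|{\sum_i c_{ik} \vec\mu_i}|^2$, isotropic/anisotropic Raman
invariants of the mixed polarizability tensor (local tensors axially
symmetric about the dipole, principal values 1 and 0.2 by default), and
exciton rotational strengths
$$R_k = \pi \tilde\nu_0\, c_{1k} c_{2k}\, (\vec r_2 - \vec r_1) \cdot
(\vec\mu_1 \times \vec\mu_2),$$
with $\tilde\nu_0$ the mean local wavenumber. Using a common
$\tilde\nu_0$ prefactor for both branches (rather than each branch's own
eigenwavenumber) makes the conservation law $R_+ + R_- = 0$ hold at
machine precision for every conformation, because the mixing coefficients
satisfy $c_{1+}c_{2+} = -c_{1-}c_{2-}$ exactly; with per-branch
prefactors the sum rule would be violated by $O((\tilde\nu_+ -
\tilde\nu_-)/\tilde\nu_0)$, a few parts in $10^3$, for no physical gain at
this level of theory. Ensemble spectra place area-normalized Gaussians
(default $\sigma = 6$ cm⁻¹) at the exciton wavenumbers, scaled by the
state intensities, and average with ensemble weights over a 1600–1720
cm⁻¹ grid at 1 cm⁻¹ spacing (121 points).

**Exact mirror antisymmetry.** Reflecting a conformation through
$(\phi,\psi) \to (-\phi,-\psi)$ mirrors the idealized geometry through the
construction plane. The implementation is arranged so this holds to the
last floating-point bit (torsion trigonometry is passed as
cosine/sine pairs; angle wrapping is the identity on in-range values), so
IR and Raman profiles of mirror ensembles are bit-identical and VCD is
bit-negated. Consequently a chirality-symmetrized histogram — where mirror
bins carry exactly equal weights — yields a VCD profile that vanishes to
rounding error ($\sim 10^{-13}$ of the IR peak), the correct achiral
limit.

**Calibration caveat.** Local wavenumbers (defaults 1648/1672 cm⁻¹
mimicking the N- vs C-terminal amide split in D₂O), dipole parameters and
bandwidth are calibration choices, not measured constants; C-terminal
capping variants are represented only as shifts of the local wavenumbers.
Computed intensities are in model units unless `ir_scale`/`vcd_scale` are
calibrated against a measured spectrum, so quantitative intensity
comparisons across differently calibrated configurations are meaningless,
while peak positions, band shapes, symmetry properties and
dimensionless ratios are meaningful.

## Reduced χ² scores

$$\chi^2_J = \frac{1}{N}\sum_{i=1}^{N}
\frac{(J_{i,\mathrm{calc}} - J_{i,\mathrm{exp}})^2}{s_i^2}, \qquad
\chi^2_\mathrm{VCD} = \frac{1}{N'}\sum_{k}
\frac{(\Delta\varepsilon_{\mathrm{calc},k} -
\Delta\varepsilon_{\mathrm{exp},k})^2}{s_k^2},$$

with $N$ the number of couplings (five here) and $N'$ the number of
wavenumbers from 1600 to 1720 cm⁻¹. The divisor is $N$, not $N - p$:
these are goodness-of-description scores for fixed ensembles, not fit
residuals. Fits with $\chi^2_J < 2$ (strictly) are flagged acceptable,
with a recorded caveat when any uncertainty lacked parameter-error
propagation. Experimental profiles are linearly interpolated onto the
calculation grid — adequate for smooth band profiles at 1 cm⁻¹ spacing —
and must cover the full window.

For achiral residues the experimental VCD vanishes and the glycine
convention applies: $\Delta\varepsilon_{\mathrm{exp},k} = 0$, $s_k = 1$,
making $\chi^2_\mathrm{VCD}$ the mean squared calculated VCD — a direct
penalty on spurious chirality in the sampled ensemble. Reports carry raw
values; any display scaling (plots of such statistics are often shown
$\times 10^7$) is left to the user, since it presumes an intensity
normalization the package does not impose.

## Hydrogen bonds

Detection is the standard geometric criterion: donor–acceptor (heavy
atom) distance ≤ 3 Å and donor–hydrogen–acceptor angle within 20° of
linear (≥ 160°), the common convention of trajectory-analysis libraries.
"Deviation from linear" is deliberately implemented on the D–H–A angle,
and the distance on the heavy atoms, not H···A. No periodic-image search
is performed; supply whole molecules or pre-imaged coordinates. Counts are
partitioned into intrapeptide, peptide–water and water–water categories
from per-atom group labels; means are per frame, and the SEM comes from
non-overlapping block averages (default 1 ns) to respect the serial
correlation of simulation data — at least two complete blocks are
required, otherwise the SEM is refused rather than silently misreported.

## Numerical choices, sizes and limitations

* Histograms: half-open bins, $[-180, 180)$ axes; $\pm 180^\circ$ wraps to
  $-180^\circ$. Angle wrapping is exact (identity) for in-range values.
* Quadrature: $0.5^\circ$ midpoint rule for box integrals (tolerance
  $10^{-6}$); $2^\circ$ bin centers for ensemble averages.
* Eigenproblems: closed-form $2\times2$ diagonalization via
  `atan2`, stable for degenerate local wavenumbers and zero coupling.
* Degenerate inputs: empty mesostate boxes integrate to 0 with a warning;
  zero uncertainties, empty ensembles, non-normalized mixtures and
  hydrogens without donor parents are errors, not silent results.
* Test and demonstration ensembles use $10^4$–$10^6$ frames: $10^6$ for
  population comparisons (binomial error $\sim 0.05\%$), $10^5$ for
  spectroscopic averages, sizes chosen so sampling error is far below the
  effects being checked while the full suite runs in seconds.
* Out of scope: running MD, fitting mixture parameters to experiment,
  force-field parameterization, kinetics/free-energy analysis, vibrational
  Hamiltonians beyond two coupled oscillators, and trajectory file parsing
  (ensembles enter as $\phi/\psi$ tables or in-memory series; extract
  dihedrals with your trajectory toolkit of choice).

## Reproducibility

Every stochastic step takes an explicit seed. `run_pipeline()` writes a
provenance log with input hashes and the seed next to its numeric
artifacts, and rerunning a configuration reproduces those artifacts
byte-for-byte.
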