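# ramaspec

Spectroscopic assessment of Ramachandran ensembles for short peptides.

MD force fields are routinely judged by how well the backbone conformational
ensemble of a guest residue — glycine or alanine in a GxG host–guest
tripeptide, say — reproduces the experimental observables that actually
constrain that ensemble: five backbone J-coupling constants from NMR, and
the amide I′ band profiles measured by IR, Raman and vibrational circular
dichroism (VCD) spectroscopy in D₂O. ramaspec implements that assessment
pipeline end to end for anyone comparing simulated (or model) peptide
ensembles against spectroscopy:

* **Ramachandran analysis** — 2°×2° histograms (32,400 bins) from (ϕ, ψ)
  time series; populations of the standard mesostate boxes (pPII,
  antiparallel β, β-transition, α-helix) with chirality symmetrization for
  achiral residues; windowed left/right-handed population diagnostics.
* **Synthetic ensembles** — periodic 2D Gaussian mixtures on the
  Ramachandran torus (weights, centers, widths, optional correlation),
  with exact wrapped-Gaussian evaluation, quadrature, seeded sampling and
  chirality symmetrization. These double as the model distributions used
  as spectroscopic benchmarks and as reproducible stand-ins for MD frames.
* **J-couplings** — Karplus-type relations
  `J(θ) = A·cos²(θ+Δ) + B·cos(θ+Δ) + C` (and a Fourier form for the
  ψ-dependent ¹J(N,Cα)), ensemble averaging, and first-order Gaussian
  propagation of experimental plus Karplus-parameter uncertainties.
* **Amide I′ exciton model** — two coupled local oscillators with
  conformation-dependent transition-dipole coupling on an idealized
  peptide frame; per-conformation IR dipole strengths, Raman tensor
  invariants and rotational strengths `R± = ±π·ν̃₀·c₁c₂·T₁₂·(μ₁×μ₂)`;
  Gaussian-broadened, ensemble-averaged IR / isotropic Raman / anisotropic
  Raman / VCD profiles on a 1600–1720 cm⁻¹ grid.
* **Reduced χ² scores** — `χ²_J = (1/N)Σ(J_calc−J_exp)²/s²` over the five
  couplings and `χ²_VCD = (1/N′)Σ(Δε_calc−Δε_exp)²/s²` over the 121
  wavenumbers, including the achiral-null convention (Δε_exp = 0, s = 1)
  for glycine, with an "acceptable below 2" fit flag.
* **Hydrogen bonds** — geometric detection (donor–acceptor ≤ 3 Å, D–H–A
  within 20° of linear), intrapeptide vs peptide–water partitioning, and
  block-averaged standard errors.

Everything is tidyverse-native: ensembles, histograms, spectra and reports
are tibbles (or carry `tidy()`/`glance()` methods), and each result type
has an `autoplot()`.

## Worked example

Score a model alanine-like ensemble against a bundled synthetic
experimental data set (both shipped as editable fixtures under
`inst/extdata/`; the `*_synthetic.*` files are illustrative
reconstructions, not measured data):

```r
library(ramaspec)

mix <- read_mixture(system.file("extdata", "mixture_ala_synthetic.yaml",
                                package = "ramaspec"))
ens <- sample_mixture(mix, n = 1e5, seed = 7)

mesostate_populations(ens)
#> # A tibble: 4 × 2
#>   mesostate population
#>   <chr>          <dbl>
#> 1 pPII          0.584
#> 2 abeta         0.117
#> 3 betat         0.0995
#> 4 alphaR        0.117

jexp <- readr::read_csv(system.file("extdata", "jexp_ala_synthetic.csv",
                                    package = "ramaspec"))
jtab <- jcoupling_table(build_histogram(ens), jexp)
jtab
#> # A tibble: 5 × 5
#>   observable J_exp J_calc     s propagated
#>   <chr>      <dbl>  <dbl> <dbl> <lgl>
#> 1 3J_HN_HA    5.91   5.77 0.233 TRUE
#> 2 3J_HN_Cp    1.39   1.32 0.161 TRUE
#> 3 3J_HA_Cp    1.82   1.84 0.249 TRUE
#> 4 3J_HN_CB    1.85   1.88 0.281 TRUE
#> 5 1J_N_CA    11.0   10.9  0.2   FALSE

spec <- ensemble_spectra(read_exciton_config(), build_histogram(ens))
vcd_exp <- readr::read_csv(system.file("extdata", "vcd_ala_synthetic.csv",
                                       package = "ramaspec"))
chi2_report(jtab, spec, exp_profile = vcd_exp, s = 0.15,
            ensemble_name = "ala-like demo")
#> <chi2_report: ala-like demo>
#>   chi2_J   = 0.2736  [acceptable (uncertainties exclude unavailable
#>                       Karplus-parameter errors; chi-square overestimated)]
#>   chi2_VCD = 1.012
```

The ensemble is dominated by pPII (58%), its averaged couplings sit within
combined uncertainties of the (synthetic) experimental values, and
χ²_VCD ≈ 1 — exactly what a correct model scored against data carrying
its own noise level should produce. `s` for ¹J(N,Cα) is the experimental
uncertainty alone (no published Karplus-parameter errors exist for it),
which the fit flag records as a caveat.

For achiral residues, symmetrize before simulating spectra — the VCD
profile of a chirality-symmetric ensemble vanishes identically:

```r
gly <- read_mixture(system.file("extdata", "mixture_gly_synthetic.yaml",
                                package = "ramaspec"))
h <- symmetrize(build_histogram(sample_mixture(gly, 1e5, seed = 1)))
sp <- ensemble_spectra(read_exciton_config(), h)
max(abs(sp$vcd)) / max(sp$ir)  # ~1e-13: numerically zero
```

`run_pipeline()` (or the thin `inst/scripts/ramaspec` CLI with
`simulate` / `analyze` / `compare` / `hbond` subcommands) drives the whole
chain from a YAML configuration and writes histogram, mesostate,
J-coupling, spectra and χ² tables plus a provenance log (input hashes,
seed) to an output directory.

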