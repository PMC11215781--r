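test_that("idealized geometry reproduces the requested dihedrals", {
  cfg <- exciton_config()
  phi <- c(-66, 120, -150)
  psi <- c(145, -40, 80)
  g <- ramaspec:::PEP_GEOM
  n <- length(phi)
  # rebuild the backbone exactly as the model does and measure the torsions
  # with an independent textbook dihedral formula
  rep_row <- function(v) matrix(v, nrow = n, ncol = 3, byrow = TRUE)
  C1 <- rep_row(c(0, 0, 0))
  N2 <- rep_row(c(g$b_CN, 0, 0))
  a <- pi / 180 * (180 - g$ang_C_N_CA)
  CA2 <- rep_row(c(g$b_CN + g$b_NCA * cos(a), g$b_NCA * sin(a), 0))
  C2 <- ramaspec:::place_atom(
    C1, N2, CA2, g$b_CAC, g$ang_N_CA_C,
    cos(pi / 180 * phi), sin(pi / 180 * phi)
  )
  N3 <- ramaspec:::place_atom(
    N2, CA2, C2, g$b_CN, g$ang_CA_C_N,
    cos(pi / 180 * psi), sin(pi / 180 * psi)
  )
  for (i in seq_len(n)) {
    expect_equal(oracle_dihedral(C1[i, ], N2[i, ], CA2[i, ], C2[i, ]), phi[i],
                 tolerance = 1e-9)
    expect_equal(oracle_dihedral(N2[i, ], CA2[i, ], C2[i, ], N3[i, ]), psi[i],
                 tolerance = 1e-9)
    expect_equal(sqrt(sum((C2[i, ] - CA2[i, ])^2)), g$b_CAC, tolerance = 1e-9)
  }
})

test_that("decoupled oscillators keep their local wavenumbers and dipoles", {
  cfg <- exciton_config(coupling = function(phi, psi) rep(0, length(phi)))
  st <- exciton_states(cfg, c(-66, 30), c(145, -60))
  expect_equal(st$nu_minus, rep(min(cfg$nu_local), 2))
  expect_equal(st$nu_plus, rep(max(cfg$nu_local), 2))
  # mixing is the identity up to state ordering and sign
  expect_equal(abs(st$c1_minus * st$c2_minus), rep(0, 2), tolerance = 1e-12)
  expect_equal(st$c1_minus^2 + st$c2_minus^2, rep(1, 2))
  ci <- conformer_intensities(cfg, -66, 145)
  expect_equal(ci$ir_minus + ci$ir_plus, 2 * cfg$dipole_moment^2, tolerance = 1e-12)
  expect_equal(ci$rot_minus, 0, tolerance = 1e-12)
  expect_equal(ci$rot_plus, 0, tolerance = 1e-12)
})

test_that("degenerate coupled oscillators split by +/- V at 45-degree mixing", {
  V <- 7.3
  cfg <- exciton_config(
    nu_local = c(1660, 1660),
    coupling = function(phi, psi) rep(V, length(phi))
  )
  st <- exciton_states(cfg, -66, 145)
  expect_equal(st$nu_minus, 1660 - V)
  expect_equal(st$nu_plus, 1660 + V)
  expect_equal(abs(st$c1_plus), cos(pi / 4), tolerance = 1e-12)
  expect_equal(abs(st$c2_plus), sin(pi / 4), tolerance = 1e-12)
})

test_that("exciton states match an independent eigen decomposition", {
  cfg <- exciton_config()
  set.seed(19)
  phi <- runif(20, -180, 180)
  psi <- runif(20, -180, 180)
  st <- exciton_states(cfg, phi, psi)
  for (i in seq_len(20)) {
    H <- matrix(c(cfg$nu_local[1], st$coupling[i],
                  st$coupling[i], cfg$nu_local[2]), 2, 2)
    ev <- eigen(H, symmetric = TRUE)
    expect_equal(st$nu_minus[i], min(ev$values), tolerance = 1e-10)
    expect_equal(st$nu_plus[i], max(ev$values), tolerance = 1e-10)
    # mixing columns are orthonormal eigenvectors (up to sign)
    v_plus <- ev$vectors[, which.max(ev$values)]
    got <- c(st$c1_plus[i], st$c2_plus[i])
    expect_equal(abs(sum(v_plus * got)), 1, tolerance = 1e-10)
  }
})

test_that("rotational strengths obey the exciton sum rule and oracle", {
  cfg <- exciton_config()
  set.seed(29)
  phi <- runif(50, -180, 180)
  psi <- runif(50, -180, 180)
  ci <- conformer_intensities(cfg, phi, psi)
  expect_equal(ci$rot_minus + ci$rot_plus, rep(0, 50), tolerance = 1e-12)
  # independent evaluation of the coupled-oscillator rotational strength
  geom <- ramaspec:::oscillator_geometry(cfg, phi, psi)
  st <- exciton_states(cfg, phi, psi)
  nu0 <- mean(cfg$nu_local)
  for (i in c(1, 17, 42)) {
    mu1 <- geom$mu1[i, ]; mu2 <- geom$mu2[i, ]
    tv <- geom$r2[i, ] - geom$r1[i, ]
    cross12 <- c(
      mu1[2] * mu2[3] - mu1[3] * mu2[2],
      mu1[3] * mu2[1] - mu1[1] * mu2[3],
      mu1[1] * mu2[2] - mu1[2] * mu2[1]
    )
    r_oracle <- pi * nu0 * st$c1_plus[i] * st$c2_plus[i] * sum(tv * cross12)
    expect_equal(ci$rot_plus[i], r_oracle, tolerance = 1e-10)
  }
})

test_that("total IR dipole strength is invariant to the coupling", {
  phi <- c(-66, 40); psi <- c(145, -100)
  base <- conformer_intensities(
    exciton_config(coupling = function(p, q) rep(0, length(p))), phi, psi
  )
  for (V in c(-12, 3, 25)) {
    ci <- conformer_intensities(
      exciton_config(coupling = function(p, q) rep(V, length(p))), phi, psi
    )
    expect_equal(ci$ir_minus + ci$ir_plus, base$ir_minus + base$ir_plus,
                 tolerance = 1e-12)
  }
})

test_that("a single conformation yields the analytic two-Gaussian IR profile", {
  cfg <- exciton_config()
  s <- dihedral_series(-66, 145)
  sp <- ensemble_spectra(cfg, s)
  ci <- conformer_intensities(cfg, -66, 145)
  amp <- 1 / (cfg$bandwidth * sqrt(2 * pi))
  expected <- amp * (
    ci$ir_minus * exp(-(sp$wavenumber - ci$nu_minus)^2 / (2 * cfg$bandwidth^2)) +
      ci$ir_plus * exp(-(sp$wavenumber - ci$nu_plus)^2 / (2 * cfg$bandwidth^2))
  )
  expect_equal(sp$ir, expected, tolerance = 1e-12)
  expect_equal(nrow(sp), 121)
})

test_that("histogram-weighted and frame-by-frame spectra coincide at bin centers", {
  cfg <- exciton_config()
  set.seed(37)
  centers <- seq(-179, 179, by = 2)
  s <- dihedral_series(sample(centers, 500, TRUE), sample(centers, 500, TRUE))
  sp_frames <- ensemble_spectra(cfg, s)
  sp_hist <- ensemble_spectra(cfg, build_histogram(s))
  expect_equal(sp_hist$ir, sp_frames$ir, tolerance = 1e-10)
  expect_equal(sp_hist$vcd, sp_frames$vcd, tolerance = 1e-10)
})

test_that("mirror ensembles keep IR/Raman and exactly negate VCD", {
  cfg <- exciton_config()
  m <- read_mixture(ext_fixture("mixture_ala_synthetic.yaml"))
  s <- sample_mixture(m, 3000, seed = 41)
  s_mirror <- dihedral_series(wrap_angle(-s$phi), wrap_angle(-s$psi))
  sp <- ensemble_spectra(cfg, s)
  spm <- ensemble_spectra(cfg, s_mirror)
  expect_identical(sp$ir, spm$ir)
  expect_identical(sp$raman_iso, spm$raman_iso)
  expect_identical(sp$raman_aniso, spm$raman_aniso)
  expect_identical(sp$vcd, -spm$vcd)
})

test_that("configuration validation catches physical nonsense", {
  expect_error(exciton_config(nu_local = c(1000, 1650)), "1500-1800")
  expect_error(exciton_config(bandwidth = 0), "bandwidth")
  expect_error(exciton_config(coupling = 3), "tdc")
  cfg <- read_exciton_config()
  expect_equal(cfg$nu_local, c(1648, 1672))
  expect_equal(range(cfg$grid), c(1600, 1720))
})
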