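#' Two-oscillator amide I' exciton model configuration
#'
#' Parameters of the coupled-oscillator model used to simulate amide I' band
#' profiles of a tripeptide: the two local amide I' wavenumbers (N- and
#' C-terminal peptide groups, which differ in D2O), a conformation-dependent
#' inter-oscillator coupling, transition-dipole geometry on an idealized
#' peptide frame, Raman tensor anisotropy, and Gaussian band broadening.
#'
#' The coupling is either computed by transition-dipole coupling (`"tdc"`)
#' from the idealized geometry, or supplied as a function of (phi, psi)
#' returning cm^-1 (e.g. an interpolator over a tabulated nearest-neighbor
#' coupling map). All intensity parameters are calibration choices, not
#' measured constants; profiles are in model units unless you calibrate
#' `ir_scale` / `vcd_scale` against experiment.
#'
#' @param nu_local Length-2 numeric, local wavenumbers in cm^-1 (within
#'   1500-1800). Defaults 1648 and 1672 mimic the N- vs C-terminal amide I'
#'   split of short peptides in D2O.
#' @param coupling `"tdc"` or a function `f(phi, psi)` in cm^-1.
#' @param dipole_moment Transition dipole magnitude in D.
#' @param dipole_tilt_deg Tilt of the transition dipole away from the C=O
#'   axis, toward the amide N, in degrees.
#' @param dipole_offset Position of the point dipole along the C=O bond,
#'   in Angstrom from the carbonyl carbon.
#' @param bandwidth Gaussian band standard deviation in cm^-1 (> 0).
#' @param raman_par,raman_perp Principal values of the local Raman tensor
#'   (component along the transition dipole vs perpendicular, relative
#'   units).
#' @param grid Wavenumber grid for ensemble spectra (cm^-1); the default
#'   1600-1720 at 1 cm^-1 gives 121 points.
#' @param ir_scale,vcd_scale Multiplicative output scales (model units).
#' @return An `exciton_config` list.
#' @export
exciton_config <- function(nu_local = c(1648, 1672),
                           coupling = "tdc",
                           dipole_moment = 0.30,
                           dipole_tilt_deg = 20,
                           dipole_offset = 0.868,
                           bandwidth = 6,
                           raman_par = 1,
                           raman_perp = 0.2,
                           grid = seq(1600, 1720, by = 1),
                           ir_scale = 1,
                           vcd_scale = 1) {
  stopifnot(length(nu_local) == 2)
  if (any(nu_local < 1500) || any(nu_local > 1800)) {
    abort("local wavenumbers must lie within 1500-1800 cm^-1")
  }
  if (bandwidth <= 0) abort("bandwidth must be positive")
  if (any(diff(grid) <= 0)) abort("wavenumber grid must be strictly increasing")
  if (!identical(coupling, "tdc") && !is.function(coupling)) {
    abort("coupling must be \"tdc\" or a function of (phi, psi)")
  }
  structure(
    list(
      nu_local = as.numeric(nu_local), coupling = coupling,
      dipole_moment = dipole_moment, dipole_tilt_deg = dipole_tilt_deg,
      dipole_offset = dipole_offset, bandwidth = bandwidth,
      raman_par = raman_par, raman_perp = raman_perp,
      grid = as.numeric(grid), ir_scale = ir_scale, vcd_scale = vcd_scale
    ),
    class = "exciton_config"
  )
}

#' Read an exciton configuration from YAML
#' @param path YAML file; keys as in [exciton_config()] (a `grid` key may be
#'   given as `list(from, to, by)`). Defaults to the bundled configuration.
#' @return An `exciton_config`.
#' @export
read_exciton_config <- function(path = NULL) {
  path <- path %||% system.file("extdata", "exciton_default.yaml",
                                package = "ramaspec", mustWork = TRUE)
  spec <- yaml::read_yaml(path)
  if (!is.null(spec$grid) && is.list(spec$grid)) {
    spec$grid <- seq(spec$grid$from, spec$grid$to, by = spec$grid$by %||% 1)
  }
  if (!is.null(spec$nu_local)) spec$nu_local <- unlist(spec$nu_local)
  do.call(exciton_config, spec)
}

# TDC prefactor: 1 D^2 / Angstrom^3 expressed in cm^-1.
TDC_CM1 <- 5034.12

# Idealized backbone internal coordinates (Angstrom, degrees); standard
# trans-peptide values, omega fixed at 180.
PEP_GEOM <- list(
  b_CN = 1.33, b_NCA = 1.46, b_CAC = 1.52, b_CO = 1.23,
  ang_C_N_CA = 121.7, ang_N_CA_C = 111.0, ang_CA_C_N = 116.2,
  ang_CA_C_O = 120.8, ang_O_C_N = 122.7
)

# Vectorized placement of atom D given predecessors A-B-C, bond length r,
# bond angle theta (degrees, at C between B and D) and the torsion
# A-B-C-D supplied as (cos_t, sin_t). A, B, C are n x 3 matrices.
place_atom <- function(A, B, C, r, theta, cos_t, sin_t) {
  b1 <- vec_unit(B - A)
  b2 <- vec_unit(C - B)
  nrm <- vec_unit(vec_cross(b1, b2))
  m <- vec_cross(nrm, b2)
  th <- deg2rad(theta)
  C + r * (-b2 * cos(th) + m * (sin(th) * cos_t) - nrm * (sin(th) * sin_t))
}

# Build the two amide oscillators of an idealized blocked central residue for
# vectors of (phi, psi): point transition dipoles mu1/mu2 (D) at origins
# r1/r2 (Angstrom). Oscillator 1 (C1=O1, preceding peptide bond) is rigid;
# oscillator 2 (C2=O2) moves with (phi, psi). Torsion trig is fed as
# cos/sin pairs so that the geometry of (-phi, -psi) is the exact mirror
# image (z -> -z) of that of (phi, psi).
oscillator_geometry <- function(config, phi, psi) {
  n <- length(phi)
  g <- PEP_GEOM
  rep_row <- function(v) matrix(v, nrow = n, ncol = 3, byrow = TRUE)
  C1 <- rep_row(c(0, 0, 0))
  N2 <- rep_row(c(g$b_CN, 0, 0))
  a <- deg2rad(180 - g$ang_C_N_CA)
  CA2 <- rep_row(c(g$b_CN + g$b_NCA * cos(a), g$b_NCA * sin(a), 0))
  O1 <- place_atom(CA2, N2, C1, g$b_CO, g$ang_O_C_N,
                   cos_t = rep(1, n), sin_t = rep(0, n))
  cphi <- cos(deg2rad(phi)); sphi <- sin(deg2rad(phi))
  cpsi <- cos(deg2rad(psi)); spsi <- sin(deg2rad(psi))
  C2 <- place_atom(C1, N2, CA2, g$b_CAC, g$ang_N_CA_C, cphi, sphi)
  N3 <- place_atom(N2, CA2, C2, g$b_CN, g$ang_CA_C_N, cpsi, spsi)
  O2 <- place_atom(N2, CA2, C2, g$b_CO, g$ang_CA_C_O, -cpsi, -spsi) # psi + 180
  dip <- function(C, O, N) {
    u_co <- vec_unit(O - C)
    u_cn <- vec_unit(N - C)
    axis <- vec_unit(vec_cross(u_co, u_cn))
    al <- deg2rad(config$dipole_tilt_deg)
    u <- u_co * cos(al) + vec_cross(axis, u_co) * sin(al) # rotate toward N
    list(mu = config$dipole_moment * u, origin = C + config$dipole_offset * u_co)
  }
  d1 <- dip(C1, O1, N2)
  d2 <- dip(C2, O2, N3)
  list(mu1 = d1$mu, r1 = d1$origin, mu2 = d2$mu, r2 = d2$origin)
}

# Inter-oscillator coupling (cm^-1) for vectors of angles.
coupling_value <- function(config, phi, psi, geom = NULL) {
  if (is.function(config$coupling)) {
    return(config$coupling(phi, psi))
  }
  geom <- geom %||% oscillator_geometry(config, phi, psi)
  tv <- geom$r2 - geom$r1
  r <- vec_norm(tv)
  if (any(r < 1e-6)) abort("coincident dipole origins: coupling undefined")
  nh <- tv / r
  TDC_CM1 * (rowSums(geom$mu1 * geom$mu2) -
               3 * rowSums(geom$mu1 * nh) * rowSums(geom$mu2 * nh)) / r^3
}

#' Exciton states of the two-oscillator amide I' Hamiltonian
#'
#' Diagonalizes, per conformation, the 2 x 2 symmetric Hamiltonian with the
#' local wavenumbers on the diagonal and the conformation-dependent coupling
#' off-diagonal. The mixing matrix columns (`c1_*`, `c2_*`) give the local
#' mode composition of each delocalized state and are orthonormal.
#'
#' @param config An [exciton_config()].
#' @param phi,psi Numeric vectors of dihedrals in degrees (recycled).
#' @return A tibble with columns `phi`, `psi`, `coupling` (cm^-1), the two
#'   eigen-wavenumbers `nu_minus` <= `nu_plus` (cm^-1) and mixing
#'   coefficients `c1_minus`, `c2_minus`, `c1_plus`, `c2_plus`.
#' @export
exciton_states <- function(config, phi, psi) {
  stopifnot(inherits(config, "exciton_config"))
  n <- max(length(phi), length(psi))
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  V <- coupling_value(config, phi, psi)
  nu1 <- config$nu_local[1]; nu2 <- config$nu_local[2]
  m <- (nu1 + nu2) / 2
  s <- sqrt(((nu1 - nu2) / 2)^2 + V^2)
  theta <- 0.5 * atan2(2 * V, nu1 - nu2)
  tibble(
    phi = phi, psi = psi, coupling = V,
    nu_minus = m - s, nu_plus = m + s,
    c1_minus = -sin(theta), c2_minus = cos(theta),
    c1_plus = cos(theta), c2_plus = sin(theta)
  )
}

#' Per-conformation exciton intensities
#'
#' For each (phi, psi) conformation, computes for both exciton states the IR
#' dipole strength (|sum of mixed transition dipoles|^2, D^2), the isotropic
#' and anisotropic Raman invariants of the mixed polarizability tensor, and
#' the coupled-oscillator (exciton) rotational strength
#' `R_k = pi * nu0 * c1k * c2k * (r2 - r1) . (mu1 x mu2)`
#' with `nu0` the mean local wavenumber; the two branches carry equal and
#' opposite rotational strengths, so every conformation (and hence any
#' ensemble) has zero integrated VCD.
#'
#' @inheritParams exciton_states
#' @return A tibble, one row per conformation: `nu_minus`, `nu_plus`,
#'   `ir_minus`, `ir_plus`, `iso_minus`, `iso_plus`, `aniso_minus`,
#'   `aniso_plus`, `rot_minus`, `rot_plus`.
#' @export
conformer_intensities <- function(config, phi, psi) {
  stopifnot(inherits(config, "exciton_config"))
  n <- max(length(phi), length(psi))
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  geom <- oscillator_geometry(config, phi, psi)
  tv <- geom$r2 - geom$r1
  if (any(vec_norm(tv) < 1e-6)) {
    abort("coincident dipole origins: rotational strength undefined")
  }
  st <- exciton_states_from_geom(config, phi, psi, geom)
  mu1 <- geom$mu1; mu2 <- geom$mu2
  strengths <- function(c1, c2) {
    M <- mu1 * c1 + mu2 * c2
    rowSums(M^2)
  }
  # local Raman tensors: axially symmetric about the transition dipole
  ap <- config$raman_par; aq <- config$raman_perp
  tensor_cols <- function(u) {
    # unique components of aq*I + (ap-aq) u u^T for unit rows u
    list(
      xx = aq + (ap - aq) * u[, 1]^2, yy = aq + (ap - aq) * u[, 2]^2,
      zz = aq + (ap - aq) * u[, 3]^2, xy = (ap - aq) * u[, 1] * u[, 2],
      yz = (ap - aq) * u[, 2] * u[, 3], zx = (ap - aq) * u[, 3] * u[, 1]
    )
  }
  t1 <- tensor_cols(vec_unit(mu1))
  t2 <- tensor_cols(vec_unit(mu2))
  raman <- function(c1, c2) {
    A <- purrr::map2(t1, t2, function(a, b) c1 * a + c2 * b)
    abar <- (A$xx + A$yy + A$zz) / 3
    gam2 <- 0.5 * ((A$xx - A$yy)^2 + (A$yy - A$zz)^2 + (A$zz - A$xx)^2) +
      3 * (A$xy^2 + A$yz^2 + A$zx^2)
    list(iso = abar^2, aniso = gam2)
  }
  nu0 <- mean(config$nu_local)
  triple <- rowSums(tv * vec_cross(mu1, mu2))
  rot_plus <- pi * nu0 * st$c1_plus * st$c2_plus * triple
  rot_minus <- -rot_plus # orthonormal mixing: c1m*c2m = -c1p*c2p exactly
  rm_m <- raman(st$c1_minus, st$c2_minus)
  rm_p <- raman(st$c1_plus, st$c2_plus)
  tibble(
    phi = phi, psi = psi,
    nu_minus = st$nu_minus, nu_plus = st$nu_plus,
    ir_minus = strengths(st$c1_minus, st$c2_minus),
    ir_plus = strengths(st$c1_plus, st$c2_plus),
    iso_minus = rm_m$iso, iso_plus = rm_p$iso,
    aniso_minus = rm_m$aniso, aniso_plus = rm_p$aniso,
    rot_minus = rot_minus, rot_plus = rot_plus
  )
}

# exciton_states with a precomputed geometry (avoids rebuilding it)
exciton_states_from_geom <- function(config, phi, psi, geom) {
  V <- coupling_value(config, phi, psi, geom)
  nu1 <- config$nu_local[1]; nu2 <- config$nu_local[2]
  m <- (nu1 + nu2) / 2
  s <- sqrt(((nu1 - nu2) / 2)^2 + V^2)
  theta <- 0.5 * atan2(2 * V, nu1 - nu2)
  list(
    nu_minus = m - s, nu_plus = m + s,
    c1_minus = -sin(theta), c2_minus = cos(theta),
    c1_plus = cos(theta), c2_plus = sin(theta)
  )
}

#' Conformationally averaged amide I' band profiles
#'
#' Computes IR, isotropic Raman, anisotropic Raman and VCD amide I' profiles
#' of an ensemble: per conformation (or probability-weighted histogram bin)
#' the two exciton bands are broadened with area-normalized Gaussians of the
#' configured width, scaled by the state intensities, and averaged with the
#' ensemble weights over the configured wavenumber grid.
#'
#' A chirality-symmetric ensemble (see [symmetrize()]) yields an identically
#' vanishing VCD profile: mirror conformations carry exactly opposite
#' rotational strengths at identical wavenumbers.
#'
#' @param config An [exciton_config()].
#' @param ensemble A [dihedral_series()], `rama_histogram` or
#'   [gaussian_mixture()].
#' @return An `amide_spectra` tibble with columns `wavenumber`, `ir`,
#'   `raman_iso`, `raman_aniso`, `vcd` (model units).
#' @export
ensemble_spectra <- function(config, ensemble) {
  stopifnot(inherits(config, "exciton_config"))
  ew <- as_ensemble_weights(ensemble)
  ci <- conformer_intensities(config, ew$phi, ew$psi)
  grid <- config$grid
  sigma <- config$bandwidth
  amp <- 1 / (sigma * sqrt(2 * pi))
  G_minus <- exp(-(outer(grid, ci$nu_minus, "-")^2) / (2 * sigma^2))
  G_plus <- exp(-(outer(grid, ci$nu_plus, "-")^2) / (2 * sigma^2))
  profile <- function(int_minus, int_plus, scale = 1) {
    scale * amp * drop(G_minus %*% (ew$w * int_minus) +
                         G_plus %*% (ew$w * int_plus))
  }
  structure(
    tibble(
      wavenumber = grid,
      ir = profile(ci$ir_minus, ci$ir_plus, config$ir_scale),
      raman_iso = profile(ci$iso_minus, ci$iso_plus),
      raman_aniso = profile(ci$aniso_minus, ci$aniso_plus),
      vcd = profile(ci$rot_minus, ci$rot_plus, config$vcd_scale)
    ),
    class = c("amide_spectra", class(tibble()))
  )
}

#' Write or read amide spectra as CSV
#' @param spectra An `amide_spectra` tibble.
#' @param path File path.
#' @export
write_spectra <- function(spectra, path) {
  readr::write_csv(as_tibble(spectra), path)
  invisible(path)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path) {
  sp <- readr::read_csv(path, show_col_types = FALSE)
  structure(as_tibble(sp), class = c("amide_spectra", class(tibble())))
}
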