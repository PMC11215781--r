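#' Karplus-type relation between a scalar coupling and a backbone dihedral
#'
#' Defines one empirical coupling relation J(theta). Two functional forms are
#' supported:
#' \describe{
#'   \item{`"cos2"`}{the classic three-term Karplus equation for vicinal
#'     (3J) couplings, `A*cos^2(theta + offset) + B*cos(theta + offset) + C`,
#'     coefficients in Hz, offset in degrees.}
#'   \item{`"trig"`}{a truncated trigonometric series
#'     `C0 + A1*cos(t) + B1*sin(t) + A2*cos(2t) + B2*sin(2t)` with
#'     `t = theta + offset`, used for the psi-dependent one-bond 1J(N,Ca)
#'     coupling, for which published parameterizations are low-order Fourier
#'     fits.}
#' }
#' Coefficient uncertainties (`sigmas`, Hz) are optional; when present they
#' feed Gaussian error propagation in [combined_uncertainty()]. For some
#' observables no parameter uncertainties have been published and the
#' experimental uncertainty is then used alone.
#'
#' @param observable Name of the coupling, e.g. `"3J_HN_HA"`.
#' @param angle Driving backbone dihedral, `"phi"` or `"psi"`.
#' @param coefficients Named numeric vector: `A`, `B`, `C` for `"cos2"`;
#'   any of `C0`, `A1`, `B1`, `A2`, `B2` for `"trig"`.
#' @param offset_deg Phase offset in degrees.
#' @param sigmas Optional named numeric vector of coefficient standard
#'   errors (names a subset of the coefficient names).
#' @param form `"cos2"` or `"trig"`.
#' @return A `karplus_set` object.
#' @examples
#' k <- karplus_set("3J_HN_HA", "phi", c(A = 7.09, B = -1.42, C = 1.55), -60)
#' karplus_eval(k, -60)
#' @export
karplus_set <- function(observable, angle = c("phi", "psi"), coefficients,
                        offset_deg = 0, sigmas = NULL,
                        form = c("cos2", "trig")) {
  angle <- match.arg(angle)
  form <- match.arg(form)
  coefficients <- unlist(coefficients)
  if (any(!is.finite(coefficients))) abort("Karplus coefficients must be finite")
  allowed <- if (form == "cos2") c("A", "B", "C") else c("C0", "A1", "B1", "A2", "B2")
  if (form == "cos2" && !all(c("A", "B", "C") %in% names(coefficients))) {
    abort("cos2 form needs coefficients A, B and C")
  }
  if (!all(names(coefficients) %in% allowed)) {
    abort(paste0("unknown coefficient names; allowed: ", paste(allowed, collapse = ", ")))
  }
  if (!is.null(sigmas)) {
    sigmas <- unlist(sigmas)
    if (!all(names(sigmas) %in% names(coefficients))) {
      abort("sigma names must match coefficient names")
    }
    if (any(sigmas < 0)) abort("coefficient uncertainties must be non-negative")
  }
  structure(
    list(
      observable = observable, angle = angle, form = form,
      coefficients = coefficients, offset_deg = offset_deg, sigmas = sigmas
    ),
    class = "karplus_set"
  )
}

#' @export
print.karplus_set <- function(x, ...) {
  cat(sprintf(
    "<karplus_set %s: %s(%s), coefficients %s>\n", x$observable, x$form,
    x$angle, paste(sprintf("%s=%.3g", names(x$coefficients), x$coefficients),
                   collapse = " ")
  ))
  invisible(x)
}

# Basis functions of the coupling relation evaluated at angles (degrees);
# columns named like the coefficients. J(theta) = basis %*% coefficients and
# dJ/dcoef_k = basis[, k], which is what error propagation needs.
karplus_basis <- function(params, angle) {
  t <- deg2rad(angle + params$offset_deg)
  if (params$form == "cos2") {
    cbind(A = cos(t)^2, B = cos(t), C = rep(1, length(t)))
  } else {
    full <- cbind(
      C0 = rep(1, length(t)), A1 = cos(t), B1 = sin(t),
      A2 = cos(2 * t), B2 = sin(2 * t)
    )
    full[, names(params$coefficients), drop = FALSE]
  }
}

#' Evaluate a Karplus relation at given dihedral angles
#'
#' @param params A [karplus_set()].
#' @param angle Numeric vector of dihedral angles in degrees.
#' @return Coupling constants in Hz, periodic in the angle with period 360.
#' @export
karplus_eval <- function(params, angle) {
  stopifnot(inherits(params, "karplus_set"))
  drop(karplus_basis(params, angle) %*% params$coefficients)
}

#' Ensemble-averaged J-coupling constant
#'
#' The conformational average `<J> = sum_theta p(theta) J(theta)` over the
#' driving dihedral of the coupling: the arithmetic frame mean for a dihedral
#' series, the probability-weighted bin average for a histogram, and grid
#' quadrature for a Gaussian mixture.
#'
#' @param params A [karplus_set()].
#' @param ensemble A [dihedral_series()], `rama_histogram` or
#'   [gaussian_mixture()].
#' @return The averaged coupling in Hz.
#' @export
ensemble_average_J <- function(params, ensemble) {
  stopifnot(inherits(params, "karplus_set"))
  ew <- as_ensemble_weights(ensemble)
  theta <- if (params$angle == "phi") ew$phi else ew$psi
  sum(ew$w * karplus_eval(params, theta))
}

#' Combined experimental + Karplus-parameter uncertainty
#'
#' First-order (delta-method) Gaussian error propagation for an
#' ensemble-averaged coupling:
#' `s^2 = s_exp^2 + sum_k (d<J>/dp_k)^2 * s_pk^2`,
#' where the derivatives with respect to the Karplus coefficients are the
#' ensemble averages of the corresponding basis functions. When a parameter
#' set carries no coefficient uncertainties the experimental uncertainty is
#' returned unchanged (the convention for observables whose parameterization
#' errors are unavailable; the resulting chi-square is then an
#' overestimate).
#'
#' @param s_exp Experimental standard uncertainty in Hz (>= 0).
#' @param params A [karplus_set()].
#' @param ensemble Ensemble over which the average is taken.
#' @return Combined standard uncertainty in Hz.
#' @export
combined_uncertainty <- function(s_exp, params, ensemble) {
  stopifnot(inherits(params, "karplus_set"))
  if (!is.finite(s_exp) || s_exp < 0) abort("s_exp must be a non-negative Hz value")
  if (is.null(params$sigmas) || length(params$sigmas) == 0) {
    if (s_exp == 0) abort("all uncertainties are zero; chi-square is undefined")
    return(s_exp)
  }
  ew <- as_ensemble_weights(ensemble)
  theta <- if (params$angle == "phi") ew$phi else ew$psi
  basis <- karplus_basis(params, theta)
  derivs <- drop(crossprod(basis, ew$w)) # ensemble-averaged dJ/dp_k
  s2 <- s_exp^2 + sum((derivs[names(params$sigmas)] * params$sigmas)^2)
  if (s2 <= 0) abort("all uncertainties are zero; chi-square is undefined")
  sqrt(s2)
}

#' Default Karplus parameter sets
#'
#' Reads the parameter library shipped with the package
#' (`extdata/karplus_default.yaml`): one set per observable used for
#' host-guest peptides, following the widely used Hu & Bax-style
#' parameterizations for the phi-dependent vicinal couplings and a low-order
#' Fourier form for 1J(N,Ca). These are ordinary configuration data — edit
#' the YAML or supply your own file to change them; coefficient
#' uncertainties are illustrative where the literature gives none.
#'
#' @param path Optional path to a YAML parameter library; defaults to the
#'   bundled file.
#' @return Named list of [karplus_set()] objects.
#' @export
read_karplus <- function(path = NULL) {
  path <- path %||% system.file("extdata", "karplus_default.yaml",
                                package = "ramaspec", mustWork = TRUE)
  spec <- yaml::read_yaml(path)
  sets <- purrr::map(spec$observables, function(s) {
    karplus_set(
      observable = s$observable,
      angle = s$angle,
      coefficients = unlist(s$coefficients),
      offset_deg = as.numeric(s$offset_deg %||% 0),
      sigmas = if (!is.null(s$coefficient_sigmas)) unlist(s$coefficient_sigmas),
      form = s$form %||% "cos2"
    )
  })
  setNames(sets, purrr::map_chr(sets, "observable"))
}

#' J-coupling comparison table for an ensemble
#'
#' Computes ensemble-averaged couplings for every observable in an
#' experimental table, with combined uncertainties, ready for [chi2_J()].
#'
#' @param ensemble A [dihedral_series()], `rama_histogram` or
#'   [gaussian_mixture()].
#' @param experimental A data frame with columns `observable`, `J_exp` (Hz)
#'   and `s_exp` (Hz), typically five rows per residue.
#' @param karplus Named list of [karplus_set()]s covering every observable
#'   (default: the bundled library).
#' @return A tibble with columns `observable`, `J_exp`, `J_calc`, `s`, and
#'   `propagated` (whether Karplus-parameter errors entered `s`).
#' @export
jcoupling_table <- function(ensemble, experimental, karplus = read_karplus()) {
  experimental <- as_tibble(experimental)
  stopifnot(all(c("observable", "J_exp", "s_exp") %in% names(experimental)))
  missing_obs <- setdiff(experimental$observable, names(karplus))
  if (length(missing_obs) > 0) {
    abort(paste0("no Karplus set for observable(s): ",
                 paste(missing_obs, collapse = ", ")))
  }
  ew <- as_ensemble_weights(ensemble) # reduce once, reuse per observable
  rows <- purrr::pmap_dfr(experimental, function(observable, J_exp, s_exp, ...) {
    ks <- karplus[[observable]]
    tibble(
      observable = observable,
      J_exp = J_exp,
      J_calc = ensemble_average_J(ks, ew),
      s = combined_uncertainty(s_exp, ks, ew),
      propagated = !is.null(ks$sigmas) && length(ks$sigmas) > 0
    )
  })
  rows
}
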