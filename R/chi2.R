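#' Reduced chi-square over J-coupling constants
#'
#' `chi2_J = (1/N) * sum_i (J_calc_i - J_exp_i)^2 / s_i^2` over the N
#' observables of a residue (five for the host-guest peptides this package
#' targets). Uncertainties `s` combine experimental and, where available,
#' propagated Karplus-parameter errors (see [combined_uncertainty()]).
#'
#' @param jset A data frame with columns `J_exp`, `J_calc`, `s` (Hz), e.g.
#'   from [jcoupling_table()].
#' @return Dimensionless reduced chi-square (>= 0).
#' @examples
#' chi2_J(data.frame(J_exp = c(5, 7), J_calc = c(5, 8), s = c(1, 1)))
#' @export
chi2_J <- function(jset) {
  jset <- as_tibble(jset)
  stopifnot(all(c("J_exp", "J_calc", "s") %in% names(jset)))
  if (nrow(jset) == 0) abort("empty J-coupling set")
  if (any(jset$s <= 0)) abort("all uncertainties s must be strictly positive")
  mean(((jset$J_calc - jset$J_exp) / jset$s)^2)
}

#' Reduced chi-square over an amide I' VCD profile
#'
#' `chi2_VCD = (1/N') * sum_k (de_calc_k - de_exp_k)^2 / s_k^2` over the N'
#' wavenumbers of the calculated grid between 1600 and 1720 cm^-1 (121
#' points at the default 1 cm^-1 spacing). The experimental profile is
#' linearly interpolated onto the calculation grid and must cover it.
#'
#' For achiral residues (glycine), whose experimental VCD vanishes, use the
#' null convention `exp_profile = 0`, `s = 1`: the statistic is then simply
#' the mean squared calculated VCD, a direct measure of how strongly an
#' ensemble breaks chirality symmetry.
#'
#' @param calc An `amide_spectra` tibble (needs `wavenumber` and `vcd`).
#' @param exp_profile Either a single number (constant profile, e.g. 0 for
#'   the achiral null) or a data frame with columns `wavenumber` and `vcd`.
#' @param s Either a single number or a data frame with `wavenumber` and `s`
#'   (noise-derived standard deviations); default 1.
#' @param range Wavenumber window over which the statistic is taken.
#' @return Dimensionless reduced chi-square.
#' @export
chi2_VCD <- function(calc, exp_profile = 0, s = 1, range = c(1600, 1720)) {
  calc <- as_tibble(calc)
  stopifnot(all(c("wavenumber", "vcd") %in% names(calc)))
  keep <- calc$wavenumber >= range[1] & calc$wavenumber <= range[2]
  if (min(calc$wavenumber) > range[1] || max(calc$wavenumber) < range[2]) {
    abort("calculated grid does not cover the 1600-1720 cm^-1 window")
  }
  grid <- calc$wavenumber[keep]
  de_calc <- calc$vcd[keep]
  de_exp <- resample_profile(exp_profile, "vcd", grid)
  s_k <- resample_profile(s, "s", grid)
  if (any(s_k <= 0)) abort("all profile uncertainties must be strictly positive")
  mean(((de_calc - de_exp) / s_k)^2)
}

resample_profile <- function(x, value_col, grid) {
  if (is.numeric(x) && length(x) == 1) return(rep(x, length(grid)))
  x <- as_tibble(x)
  stopifnot(all(c("wavenumber", value_col) %in% names(x)))
  if (min(x$wavenumber) > min(grid) || max(x$wavenumber) < max(grid)) {
    abort("profile does not cover the requested wavenumber range")
  }
  approx(x$wavenumber, x[[value_col]], xout = grid)$y
}

#' Qualify a reduced chi-square value
#'
#' Labels a fit `"acceptable"` when the reduced chi-square is strictly below
#' 2, the conventional threshold when all uncertainties are fully known.
#' When any observable lacked Karplus-parameter error propagation the label
#' carries a caveat: the statistic is then an overestimate and the threshold
#' is conservative.
#'
#' @param chi2 Reduced chi-square value (>= 0).
#' @param all_errors_known Whether every uncertainty included parameter
#'   error propagation.
#' @return A character label.
#' @export
fit_quality_flag <- function(chi2, all_errors_known = TRUE) {
  stopifnot(chi2 >= 0)
  label <- if (chi2 < 2) "acceptable" else "not acceptable"
  if (!all_errors_known) {
    label <- paste0(
      label,
      " (uncertainties exclude unavailable Karplus-parameter errors; chi-square overestimated)"
    )
  }
  label
}

#' Full chi-square comparison report for one ensemble
#'
#' Bundles the J-coupling and VCD reduced chi-square statistics with their
#' per-observable / per-wavenumber deviations. A pure function of its
#' inputs: identical inputs give an identical report.
#'
#' @param jset J-coupling table (see [chi2_J()]).
#' @param calc Calculated `amide_spectra`, or NULL to skip the VCD score.
#' @param exp_profile,s VCD experimental profile and uncertainty, as in
#'   [chi2_VCD()]. Defaults give the achiral null convention.
#' @param ensemble_name,source Metadata strings recorded in the report.
#' @return A `chi2_report` object with [tidy()] and [glance()] methods.
#' @export
chi2_report <- function(jset, calc = NULL, exp_profile = 0, s = 1,
                        ensemble_name = "ensemble", source = "unspecified") {
  jset <- as_tibble(jset)
  report <- list(
    ensemble = ensemble_name,
    source = source,
    chi2_J = chi2_J(jset),
    chi2_VCD = if (!is.null(calc)) chi2_VCD(calc, exp_profile, s) else NA_real_,
    j_deviations = mutate(jset, deviation = (.data$J_calc - .data$J_exp) / .data$s),
    vcd_deviations = if (!is.null(calc)) {
      calc <- as_tibble(calc)
      keep <- calc$wavenumber >= 1600 & calc$wavenumber <= 1720
      grid <- calc$wavenumber[keep]
      tibble(
        wavenumber = grid,
        deviation = (calc$vcd[keep] - resample_profile(exp_profile, "vcd", grid)) /
          resample_profile(s, "s", grid)
      )
    },
    all_errors_known = all(jset$propagated %||% TRUE)
  )
  report$flag <- fit_quality_flag(report$chi2_J, report$all_errors_known)
  structure(report, class = "chi2_report")
}

#' @export
print.chi2_report <- function(x, ...) {
  cat(sprintf("<chi2_report: %s>\n", x$ensemble))
  cat(sprintf("  chi2_J   = %.4g  [%s]\n", x$chi2_J, x$flag))
  if (!is.na(x$chi2_VCD)) cat(sprintf("  chi2_VCD = %.4g\n", x$chi2_VCD))
  invisible(x)
}

#' @rdname chi2_report
#' @param x A `chi2_report`.
#' @param ... Unused.
#' @method tidy chi2_report
#' @export
tidy.chi2_report <- function(x, ...) {
  jd <- x$j_deviations |>
    mutate(term = .data$observable, kind = "jcoupling") |>
    select("term", "kind", "deviation")
  if (is.null(x$vcd_deviations)) return(jd)
  bind_rows(
    jd,
    x$vcd_deviations |>
      mutate(term = paste0("vcd_", .data$wavenumber), kind = "vcd") |>
      select("term", "kind", "deviation")
  )
}

#' @rdname chi2_report
#' @method glance chi2_report
#' @export
glance.chi2_report <- function(x, ...) {
  tibble(
    ensemble = x$ensemble,
    chi2_J = x$chi2_J,
    chi2_VCD = x$chi2_VCD,
    n_J = nrow(x$j_deviations),
    n_wavenumbers = if (is.null(x$vcd_deviations)) NA_integer_ else nrow(x$vcd_deviations),
    flag = x$flag
  )
}
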