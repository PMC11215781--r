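#' Plot a Ramachandran histogram
#'
#' Filled-tile Ramachandran plot of the per-bin probabilities, with the
#' default mesostate boxes overlaid.
#'
#' @param object A `rama_histogram`.
#' @param boxes Named list of [mesostate_box()]es to outline (NULL for none).
#' @param trans Transformation for the fill scale (`"sqrt"` flattens the
#'   dynamic range; use `"identity"` for raw probabilities).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rama_histogram
#' @export
autoplot.rama_histogram <- function(object, boxes = mesostate_boxes(),
                                    trans = "sqrt", ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$phi, y = .data$psi)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$prob)) +
    ggplot2::scale_fill_viridis_c(trans = trans, name = "probability") +
    ggplot2::coord_fixed(xlim = c(-180, 180), ylim = c(-180, 180), expand = FALSE) +
    ggplot2::labs(x = expression(phi ~ "(deg)"), y = expression(psi ~ "(deg)")) +
    ggplot2::theme_minimal()
  if (!is.null(boxes)) {
    rects <- purrr::map_dfr(boxes, function(b) {
      b <- as_mesostate_box(b)
      tibble(xmin = b$phi_min, xmax = b$phi_max, ymin = b$psi_min,
             ymax = b$psi_max, name = b$name)
    })
    p <- p + ggplot2::geom_rect(
      data = rects,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$ymin, ymax = .data$ymax),
      inherit.aes = FALSE, fill = NA, colour = "white", linewidth = 0.3
    )
  }
  p
}

#' Plot amide I' band profiles
#'
#' One panel per profile (IR, isotropic/anisotropic Raman, VCD) over the
#' wavenumber grid.
#'
#' @param object An `amide_spectra` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot amide_spectra
#' @export
autoplot.amide_spectra <- function(object, ...) {
  long <- as_tibble(object) |>
    tidyr::pivot_longer(-"wavenumber", names_to = "profile", values_to = "intensity") |>
    mutate(profile = factor(.data$profile,
                            levels = c("ir", "raman_iso", "raman_aniso", "vcd")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$wavenumber, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~profile, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = expression("wavenumber (cm"^-1 * ")"),
                  y = "intensity (model units)") +
    ggplot2::theme_minimal()
}

#' Plot windowed left/right-handed mesostate populations
#'
#' Reproduces the standard sampling-balance diagnostic: block-averaged
#' right-handed, left-handed and total populations of one mesostate along
#' the trajectory.
#'
#' @param series A [dihedral_series()].
#' @param box A [mesostate_box()].
#' @param window Window length in ps.
#' @return A ggplot object.
#' @export
plot_windowed_populations <- function(series, box, window) {
  dat <- bind_rows(
    windowed_populations(series, box, window, "right"),
    windowed_populations(series, box, window, "left"),
    windowed_populations(series, box, window, "total")
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time / 1000, y = .data$population,
                                    colour = .data$handedness)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_manual(values = c(right = "black", left = "red",
                                            total = "blue")) +
    ggplot2::labs(x = "time (ns)", y = "population") +
    ggplot2::theme_minimal()
}
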