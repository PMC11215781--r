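#' Mesostate definitions on the Ramachandran plot
#'
#' A mesostate is a rectangular open region of the Ramachandran plot used to
#' coarse-grain a conformational distribution into named states. The default
#' set holds the four standard right-handed boxes for short host-guest
#' peptides:
#' \itemize{
#'   \item pPII: -90 < phi < -42, 100 < psi < 180
#'   \item a-beta (antiparallel beta strand): -180 < phi < -130, 130 < psi < 180
#'   \item beta-t (transition region between a-beta and pPII):
#'     -130 < phi < -90, 130 < psi < 180
#'   \item alpha-R (right-handed helix): -90 < phi < -32, -60 < psi < -14
#' }
#' Boundaries are strict inequalities: a frame exactly on an edge belongs to
#' no box (a measure-zero convention for continuous angles).
#'
#' @param name Mesostate label.
#' @param phi_range,psi_range Length-2 numeric vectors, open interval bounds
#'   in degrees.
#' @return `mesostate_box()` returns a single `mesostate_box`;
#'   `mesostate_boxes()` a named list of the four defaults.
#' @examples
#' mesostate_boxes()$pPII
#' @export
mesostate_box <- function(name, phi_range, psi_range) {
  stopifnot(length(phi_range) == 2, length(psi_range) == 2)
  if (phi_range[1] >= phi_range[2] || psi_range[1] >= psi_range[2]) {
    abort("mesostate ranges must be nonempty (min < max)")
  }
  structure(
    list(
      name = name,
      phi_min = phi_range[1], phi_max = phi_range[2],
      psi_min = psi_range[1], psi_max = psi_range[2]
    ),
    class = "mesostate_box"
  )
}

#' @rdname mesostate_box
#' @export
mesostate_boxes <- function() {
  list(
    pPII = mesostate_box("pPII", c(-90, -42), c(100, 180)),
    abeta = mesostate_box("abeta", c(-180, -130), c(130, 180)),
    betat = mesostate_box("betat", c(-130, -90), c(130, 180)),
    alphaR = mesostate_box("alphaR", c(-90, -32), c(-60, -14))
  )
}

as_mesostate_box <- function(box) {
  if (inherits(box, "mesostate_box")) return(box)
  stopifnot(all(c("phi_min", "phi_max", "psi_min", "psi_max") %in% names(box)))
  structure(box, class = "mesostate_box")
}

#' Point-reflect a mesostate box through the origin
#'
#' The left-handed partner of a right-handed box: (phi, psi) -> (-phi, -psi).
#'
#' @param box A [mesostate_box()].
#' @return A `mesostate_box` covering the reflected region.
#' @export
reflect_box <- function(box) {
  box <- as_mesostate_box(box)
  mesostate_box(
    paste0(box$name, "_reflected"),
    c(-box$phi_max, -box$phi_min),
    c(-box$psi_max, -box$psi_min)
  )
}

in_box <- function(phi, psi, box) {
  phi > box$phi_min & phi < box$phi_max & psi > box$psi_min & psi < box$psi_max
}

boxes_overlap <- function(a, b) {
  a$phi_min < b$phi_max & b$phi_min < a$phi_max &
    a$psi_min < b$psi_max & b$psi_min < a$psi_max
}

validate_disjoint <- function(boxes) {
  nm <- names(boxes) %||% purrr::map_chr(boxes, "name")
  if (length(boxes) < 2) return(invisible(boxes))
  for (i in seq_len(length(boxes) - 1)) {
    for (j in seq((i + 1), length(boxes))) {
      if (boxes_overlap(as_mesostate_box(boxes[[i]]), as_mesostate_box(boxes[[j]]))) {
        abort(sprintf("mesostate boxes overlap: %s and %s", nm[i], nm[j]))
      }
    }
  }
  invisible(boxes)
}

#' Mesostate populations of an ensemble
#'
#' Fraction of the ensemble inside each mesostate box: the number of frames
#' (or the probability mass) within the region divided by the total. For
#' achiral residues set `symmetrize = TRUE`: the population of each box is
#' then the sum of its right-handed (as given) and left-handed
#' (point-reflected) populations, matching how populations of
#' chirality-symmetric ensembles are reported.
#'
#' @param x A [dihedral_series()], `rama_histogram` or [gaussian_mixture()].
#' @param boxes Named list of [mesostate_box()]es; must be pairwise disjoint.
#' @param symmetrize Add the population of each box's point reflection.
#' @param resolution Quadrature grid spacing (degrees), mixture input only.
#' @return A tibble with columns `mesostate` and `population`.
#' @examples
#' s <- dihedral_series(rep(-66, 4), rep(145, 4))
#' mesostate_populations(s)
#' @export
mesostate_populations <- function(x, boxes = mesostate_boxes(),
                                  symmetrize = FALSE, resolution = 0.5) {
  validate_disjoint(boxes)
  nm <- names(boxes) %||% purrr::map_chr(boxes, "name")
  pop_one <- function(box) {
    box <- as_mesostate_box(box)
    raw <- box_mass(x, box, resolution)
    if (symmetrize) raw <- raw + box_mass(x, reflect_box(box), resolution)
    raw
  }
  tibble(mesostate = nm, population = unname(purrr::map_dbl(boxes, pop_one)))
}

box_mass <- function(x, box, resolution = 0.5) {
  if (inherits(x, "rama_mixture")) {
    mesostate_integral(x, box, resolution = resolution)
  } else if (inherits(x, "rama_histogram")) {
    sum(x$prob[in_box(x$phi, x$psi, box)])
  } else {
    s <- as_dihedral_series(x)
    mean(in_box(s$phi, s$psi, box))
  }
}

#' Windowed left/right-handed mesostate populations
#'
#' Splits a dihedral series into consecutive non-overlapping time windows and
#' reports, per window, the fraction of frames in a mesostate box: the
#' right-handed population (frames inside the box as given, phi < 0 for the
#' standard boxes), the left-handed population (frames inside the
#' point-reflected box, phi > 0), or their total. Used to monitor sampling
#' balance of achiral residues along a trajectory, where left and right
#' populations should agree on average.
#'
#' @param series A [dihedral_series()].
#' @param box A [mesostate_box()].
#' @param window Window length in ps; must be at least one frame interval
#'   and no longer than the series.
#' @param handedness `"right"`, `"left"` or `"total"`.
#' @return A tibble with columns `time` (window midpoint, ps), `population`,
#'   and `handedness`.
#' @export
windowed_populations <- function(series, box, window,
                                 handedness = c("total", "right", "left")) {
  series <- as_dihedral_series(series)
  handedness <- match.arg(handedness)
  box <- as_mesostate_box(box)
  dt <- frame_interval(series)
  if (window < dt) abort("window must be at least one frame interval")
  duration <- nrow(series) * dt
  if (window > duration) abort("window exceeds the series duration")
  per_window <- max(1L, floor(window / dt))
  wid <- (seq_len(nrow(series)) - 1L) %/% per_window
  keep <- wid < (nrow(series) %/% per_window) # drop trailing partial window
  inside <- switch(handedness,
    right = in_box(series$phi, series$psi, box),
    left = in_box(series$phi, series$psi, reflect_box(box)),
    total = in_box(series$phi, series$psi, box) |
      in_box(series$phi, series$psi, reflect_box(box))
  )
  tibble(window = wid[keep], inside = inside[keep]) |>
    group_by(.data$window) |>
    summarise(population = mean(.data$inside), .groups = "drop") |>
    mutate(
      time = time_origin(series) + (.data$window + 0.5) * per_window * dt,
      handedness = handedness
    ) |>
    select("time", "population", "handedness")
}
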