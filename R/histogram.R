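#' Ramachandran histogram on the standard 2-degree grid
#'
#' Bins a dihedral series onto the fixed 180 x 180 grid of 2 x 2 degree cells
#' (32,400 bins) covering \[-180, 180) in both angles, with half-open
#' \[edge, edge + 2) bins, and converts counts to per-bin probabilities.
#'
#' @param series A [dihedral_series()] or data frame with `phi`, `psi`.
#' @return A `rama_histogram`: a tibble with one row per bin, columns `phi`
#'   and `psi` (bin centers, odd degrees) and `prob`; attribute `n_frames`.
#' @examples
#' h <- build_histogram(dihedral_series(c(0.5, 0.5, -66), c(0.5, 1.2, 145)))
#' sum(h$prob)
#' @export
build_histogram <- function(series) {
  series <- as_dihedral_series(series)
  ix <- bin_index(series$phi)
  iy <- bin_index(series$psi)
  counts <- tabulate(ix + 180L * (iy - 1L), nbins = 32400L)
  rama_histogram(counts / nrow(series), n_frames = nrow(series))
}

# 1-based bin index along one axis for 2-degree bins on [-180, 180)
bin_index <- function(angle) {
  i <- as.integer(floor((wrap_angle(angle) + 180) / 2)) + 1L
  pmin(pmax(i, 1L), 180L)
}

rama_bin_centers <- function() seq(-179, 179, by = 2)

rama_histogram <- function(prob, n_frames = NA_integer_) {
  stopifnot(length(prob) == 32400L, all(prob >= 0))
  centers <- rama_bin_centers()
  structure(
    tibble(
      phi = rep(centers, times = 180L),
      psi = rep(centers, each = 180L),
      prob = as.numeric(prob)
    ),
    class = c("rama_histogram", class(tibble())),
    n_frames = n_frames
  )
}

#' @export
print.rama_histogram <- function(x, ...) {
  cat(sprintf(
    "<rama_histogram: 32,400 bins (2 x 2 degrees), %s frames>\n",
    format(attr(x, "n_frames"))
  ))
  invisible(x)
}

#' Discretize a Gaussian mixture onto the 2-degree Ramachandran grid
#'
#' Evaluates the mixture density at the 32,400 bin centers and normalizes,
#' i.e. midpoint-rule bin probabilities. This is how a model Ramachandran
#' distribution is placed on the same footing as an MD-derived histogram.
#'
#' @param mixture A [gaussian_mixture()].
#' @return A `rama_histogram`.
#' @export
mixture_histogram <- function(mixture) {
  stopifnot(inherits(mixture, "rama_mixture"))
  centers <- rama_bin_centers()
  grid_phi <- rep(centers, times = 180L)
  grid_psi <- rep(centers, each = 180L)
  d <- mixture_density(mixture, grid_phi, grid_psi)
  rama_histogram(d / sum(d))
}

#' @rdname symmetrize
#' @export
symmetrize.rama_histogram <- function(x, ...) {
  # reflection maps bin center (phi, psi) -> (-phi, -psi); both are grid
  # centers, so the pairing is exact
  m <- matrix(x$prob, nrow = 180L)
  msym <- (m + m[180L:1L, 180L:1L]) / 2
  rama_histogram(as.numeric(msym), n_frames = attr(x, "n_frames"))
}

#' Write a histogram as a dense CSV grid
#'
#' Rows are phi bins, columns psi bins (centers in the header / first
#' column), cells are probabilities.
#'
#' @param histogram A `rama_histogram`.
#' @param path Output file.
#' @export
write_histogram_grid <- function(histogram, path) {
  stopifnot(inherits(histogram, "rama_histogram"))
  m <- matrix(histogram$prob, nrow = 180L)
  centers <- rama_bin_centers()
  out <- as_tibble(as.data.frame(m), .name_repair = ~ paste0("psi_", centers))
  out <- dplyr::bind_cols(tibble(phi = centers), out)
  readr::write_csv(out, path)
  invisible(path)
}
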