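#' Time series of backbone dihedrals for one residue
#'
#' A tidy container for the (phi, psi) trace of a single (usually central)
#' residue: one row per trajectory frame, angles in degrees wrapped to
#' \[-180, 180), with the frame spacing carried as metadata.
#'
#' @param phi,psi Numeric vectors of equal length, angles in degrees.
#' @param frame_interval Time between consecutive frames in ps (> 0).
#' @param time_origin Time of the first frame in ps.
#' @return A `dihedral_series` tibble with columns `phi` and `psi`.
#' @examples
#' s <- dihedral_series(c(-66, -70, 185), c(145, 150, -30))
#' frame_interval(s)
#' @export
dihedral_series <- function(phi, psi, frame_interval = 2, time_origin = 0) {
  if (length(phi) != length(psi)) abort("phi and psi must have equal length")
  if (length(phi) == 0) abort("a dihedral series must contain at least one frame")
  if (!is.finite(frame_interval) || frame_interval <= 0) {
    abort("frame_interval must be a positive time in ps")
  }
  if (any(!is.finite(phi)) || any(!is.finite(psi))) abort("angles must be finite")
  structure(
    tibble(phi = wrap_angle(as.numeric(phi)), psi = wrap_angle(as.numeric(psi))),
    class = c("dihedral_series", class(tibble())),
    frame_interval = frame_interval,
    time_origin = time_origin
  )
}

#' @rdname dihedral_series
#' @param series A `dihedral_series`.
#' @export
frame_interval <- function(series) attr(series, "frame_interval") %||% 2

#' @rdname dihedral_series
#' @export
time_origin <- function(series) attr(series, "time_origin") %||% 0

#' @rdname dihedral_series
#' @export
n_frames <- function(series) nrow(series)

#' Frame times of a dihedral series
#' @param series A [dihedral_series()].
#' @return Numeric vector of times in ps, one per frame.
#' @export
frame_times <- function(series) {
  time_origin(series) + (seq_len(nrow(series)) - 1) * frame_interval(series)
}

#' Read or write a dihedral table (CSV)
#'
#' The interchange format is a two-column CSV with header `phi,psi`, angles
#' in degrees. Values outside \[-180, 180) are wrapped on reading. Extra
#' columns are ignored; non-numeric rows raise an error naming the line.
#'
#' @param path File path.
#' @param frame_interval,time_origin Frame spacing metadata in ps (not stored
#'   in the file).
#' @return `read_dihedral_table()` returns a [dihedral_series()].
#' @export
read_dihedral_table <- function(path, frame_interval = 2, time_origin = 0) {
  tab <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("phi", "psi") %in% names(tab))) {
    abort("dihedral table must have `phi` and `psi` columns")
  }
  phi <- suppressWarnings(as.numeric(tab$phi))
  psi <- suppressWarnings(as.numeric(tab$psi))
  bad <- which(is.na(phi) | is.na(psi))
  if (length(bad) > 0) {
    abort(sprintf("non-numeric dihedral value at data line %d of %s", bad[1], path))
  }
  dihedral_series(phi, psi, frame_interval = frame_interval, time_origin = time_origin)
}

#' @rdname read_dihedral_table
#' @param series A [dihedral_series()] to write.
#' @export
write_dihedral_table <- function(series, path) {
  readr::write_csv(tibble(phi = series$phi, psi = series$psi), path)
  invisible(path)
}

#' Coerce plain phi/psi data to a dihedral series
#' @param x A data frame with `phi` and `psi` columns, or a `dihedral_series`.
#' @param ... Passed to [dihedral_series()].
#' @export
as_dihedral_series <- function(x, ...) {
  if (inherits(x, "dihedral_series")) return(x)
  stopifnot(is.data.frame(x), all(c("phi", "psi") %in% names(x)))
  dihedral_series(x$phi, x$psi, ...)
}
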