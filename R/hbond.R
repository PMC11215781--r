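#' Geometric hydrogen-bond criteria
#'
#' The standard distance-plus-angle definition: a donor-hydrogen-acceptor
#' triple is a hydrogen bond when the donor-to-acceptor (heavy atom) distance
#' is at most `cutoff` and the D-H-A angle deviates from linear (180
#' degrees) by at most `max_angle_dev`.
#'
#' @param cutoff Donor-acceptor distance cutoff in Angstrom (default 3).
#' @param max_angle_dev Maximum deviation of the D-H-A angle from 180
#'   degrees (default 20, i.e. angle >= 160 degrees).
#' @return An `hbond_criteria` list.
#' @export
hbond_criteria <- function(cutoff = 3, max_angle_dev = 20) {
  if (cutoff <= 0) abort("distance cutoff must be positive")
  if (max_angle_dev <= 0 || max_angle_dev >= 90) {
    abort("angular tolerance must lie in (0, 90) degrees")
  }
  structure(list(cutoff = cutoff, max_angle_dev = max_angle_dev),
            class = "hbond_criteria")
}

validate_frame <- function(atoms) {
  atoms <- as_tibble(atoms)
  required <- c("atom", "x", "y", "z", "group", "donor", "acceptor", "parent")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("frame is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  hydrogens <- atoms[!is.na(atoms$parent), ]
  if (nrow(hydrogens) > 0) {
    bad <- !(hydrogens$parent %in% atoms$atom[atoms$donor %in% TRUE])
    if (any(bad)) {
      abort(sprintf("hydrogen %s is not bonded to a donor atom in the frame",
                    hydrogens$atom[which(bad)[1]]))
    }
  }
  atoms
}

#' Detect hydrogen bonds in a coordinate frame
#'
#' Scans all (donor, hydrogen, acceptor) combinations of an annotated frame
#' and returns those satisfying the geometric criteria. A frame is a tidy
#' atom table with one row per atom:
#' \describe{
#'   \item{`atom`}{unique atom identifier.}
#'   \item{`x`, `y`, `z`}{coordinates in Angstrom.}
#'   \item{`group`}{molecule class, e.g. `"peptide"` or `"water"`, used by
#'     [summarize_hbonds()] to partition bonds.}
#'   \item{`donor`, `acceptor`}{logical flags on heavy atoms.}
#'   \item{`parent`}{for hydrogens, the `atom` id of the covalently bonded
#'     donor heavy atom; `NA` for heavy atoms.}
#' }
#'
#' @param atoms Frame table as described above.
#' @param criteria An [hbond_criteria()].
#' @return A tibble with columns `donor`, `hydrogen`, `acceptor`, `distance`
#'   (Angstrom, donor-acceptor), `angle` (degrees, D-H-A), and the groups of
#'   donor and acceptor.
#' @export
detect_hbonds <- function(atoms, criteria = hbond_criteria()) {
  atoms <- validate_frame(atoms)
  hyd <- atoms[!is.na(atoms$parent), ]
  acc <- atoms[atoms$acceptor %in% TRUE, ]
  if (nrow(hyd) == 0 || nrow(acc) == 0) return(empty_hbond_table())
  coord <- as.matrix(atoms[, c("x", "y", "z")])
  rownames(coord) <- atoms$atom
  pairs <- tidyr::expand_grid(h = hyd$atom, a = acc$atom)
  pairs$d <- hyd$parent[match(pairs$h, hyd$atom)]
  pairs <- pairs[pairs$a != pairs$d, , drop = FALSE]
  if (nrow(pairs) == 0) return(empty_hbond_table())
  D <- coord[pairs$d, , drop = FALSE]
  H <- coord[pairs$h, , drop = FALSE]
  A <- coord[pairs$a, , drop = FALSE]
  dist_da <- vec_norm(A - D)
  v1 <- D - H
  v2 <- A - H
  cosang <- rowSums(v1 * v2) / (vec_norm(v1) * vec_norm(v2))
  angle <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  keep <- dist_da <= criteria$cutoff & angle >= 180 - criteria$max_angle_dev
  grp <- setNames(atoms$group, atoms$atom)
  tibble(
    donor = pairs$d[keep], hydrogen = pairs$h[keep], acceptor = pairs$a[keep],
    distance = unname(dist_da[keep]), angle = unname(angle[keep]),
    donor_group = unname(grp[pairs$d[keep]]),
    acceptor_group = unname(grp[pairs$a[keep]])
  )
}

empty_hbond_table <- function() {
  tibble(
    donor = character(), hydrogen = character(), acceptor = character(),
    distance = numeric(), angle = numeric(),
    donor_group = character(), acceptor_group = character()
  )
}

hbond_category <- function(donor_group, acceptor_group) {
  dplyr::case_when(
    donor_group == "peptide" & acceptor_group == "peptide" ~ "intrapeptide",
    donor_group == "water" & acceptor_group == "water" ~ "water-water",
    TRUE ~ "peptide-water"
  )
}

#' Per-frame hydrogen-bond statistics with block-averaged SEM
#'
#' Counts hydrogen bonds in every frame of a trajectory, splits them into
#' intrapeptide, peptide-water and water-water categories from the `group`
#' annotations, and reports the mean count per frame per category together
#' with a standard error of the mean estimated from block averages
#' (consecutive non-overlapping time blocks, 1 ns by default), the standard
#' remedy for the serial correlation of simulation time series.
#'
#' @param frames List of frame tables (see [detect_hbonds()]), time-ordered.
#' @param criteria An [hbond_criteria()].
#' @param frame_interval Time between frames in ps (default 2).
#' @param block_length Block length for the SEM in ps (default 1000 = 1 ns).
#' @return An `hbond_summary` tibble: one row per category with `mean_bonds`,
#'   `sem`, `n_blocks`; attributes carry `n_frames` and the settings.
#' @export
summarize_hbonds <- function(frames, criteria = hbond_criteria(),
                             frame_interval = 2, block_length = 1000) {
  stopifnot(is.list(frames), length(frames) > 0)
  per_block <- max(1L, floor(block_length / frame_interval))
  n_blocks <- length(frames) %/% per_block
  if (n_blocks < 2) {
    abort("fewer than 2 complete blocks: SEM undefined; shorten block_length")
  }
  categories <- c("intrapeptide", "peptide-water", "water-water")
  counts <- purrr::map_dfr(seq_along(frames), function(i) {
    hb <- detect_hbonds(frames[[i]], criteria)
    tab <- table(factor(hbond_category(hb$donor_group, hb$acceptor_group),
                        levels = categories))
    tibble(frame = i, category = categories, n = as.integer(tab))
  })
  counts$block <- (counts$frame - 1L) %/% per_block
  counts <- counts[counts$block < n_blocks, , drop = FALSE]
  out <- counts |>
    group_by(.data$category) |>
    summarise(mean_bonds = mean(.data$n), .groups = "drop")
  block_stats <- counts |>
    group_by(.data$category, .data$block) |>
    summarise(block_mean = mean(.data$n), .groups = "drop") |>
    group_by(.data$category) |>
    summarise(sem = sd(.data$block_mean) / sqrt(n_blocks), .groups = "drop")
  out <- left_join(out, block_stats, by = "category") |>
    mutate(category = as.character(.data$category), n_blocks = n_blocks)
  structure(out,
    class = c("hbond_summary", class(tibble())),
    n_frames = length(frames), frame_interval = frame_interval,
    block_length = block_length, criteria = criteria
  )
}
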