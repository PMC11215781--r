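# Independent oracles and fixture builders used across the suite. These are
# deliberately written as plain scalar loops / direct formulas, sharing no
# code with the package internals they check.

# Direct-summation wrapped-Gaussian density: explicit loop over components
# and the 3 x 3 periodic images.
oracle_density <- function(components, phi, psi) {
  total <- 0
  for (i in seq_len(nrow(components))) {
    w <- components$weight[i]
    sx <- components$sigma_phi[i]
    sy <- components$sigma_psi[i]
    rho <- if ("rho" %in% names(components)) components$rho[i] else 0
    for (ix in c(-1, 0, 1)) {
      for (iy in c(-1, 0, 1)) {
        dx <- phi + 360 * ix - components$phi0[i]
        dy <- psi + 360 * iy - components$psi0[i]
        z <- (dx / sx)^2 - 2 * rho * (dx / sx) * (dy / sy) + (dy / sy)^2
        total <- total + w * exp(-z / (2 * (1 - rho^2))) /
          (2 * pi * sx * sy * sqrt(1 - rho^2))
      }
    }
  }
  total
}

random_mixture_components <- function(k, seed) {
  set.seed(seed)
  tibble::tibble(
    label = paste0("c", seq_len(k)),
    weight = runif(k, 0.1, 1),
    phi0 = runif(k, -180, 180),
    psi0 = runif(k, -180, 180),
    sigma_phi = runif(k, 8, 25),
    sigma_psi = runif(k, 8, 25),
    rho = runif(k, -0.4, 0.4)
  )
}

# Signed dihedral angle (degrees) for single points, textbook formula.
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(
    b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
    b1[1] * b2[2] - b1[2] * b2[1]
  )
  n2 <- c(
    b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
    b2[1] * b3[2] - b2[2] * b3[1]
  )
  m1 <- c(
    n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
    n1[1] * b2[2] - n1[2] * b2[1]
  ) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# Exhaustive O(N^2) hydrogen-bond detection: loop over every hydrogen and
# every acceptor, test both criteria with scalar arithmetic.
oracle_hbonds <- function(atoms, cutoff = 3, max_dev = 20) {
  found <- list()
  for (ih in seq_len(nrow(atoms))) {
    if (is.na(atoms$parent[ih])) next
    h <- c(atoms$x[ih], atoms$y[ih], atoms$z[ih])
    id <- atoms$parent[ih]
    idx_d <- which(atoms$atom == id)
    d <- c(atoms$x[idx_d], atoms$y[idx_d], atoms$z[idx_d])
    for (ia in seq_len(nrow(atoms))) {
      if (!isTRUE(atoms$acceptor[ia]) || atoms$atom[ia] == id) next
      a <- c(atoms$x[ia], atoms$y[ia], atoms$z[ia])
      if (sqrt(sum((a - d)^2)) > cutoff) next
      v1 <- d - h
      v2 <- a - h
      ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
      if (ang >= 180 - max_dev) {
        found[[length(found) + 1]] <-
          c(id, atoms$atom[ih], atoms$atom[ia])
      }
    }
  }
  if (length(found) == 0) {
    return(data.frame(donor = character(), hydrogen = character(),
                      acceptor = character()))
  }
  out <- as.data.frame(do.call(rbind, found), stringsAsFactors = FALSE)
  names(out) <- c("donor", "hydrogen", "acceptor")
  out[order(out$donor, out$hydrogen, out$acceptor), , drop = FALSE]
}

# Random annotated frame: a few peptide-like donor/acceptor groups plus
# waters, coordinates in a 10 A box so some contacts fall near the cutoffs.
random_hbond_frame <- function(seed, n_water = 6, n_pep = 3) {
  set.seed(seed)
  rows <- list()
  add <- function(...) rows[[length(rows) + 1]] <<- list(...)
  for (i in seq_len(n_pep)) {
    d <- runif(3, 0, 10)
    hdir <- rnorm(3)
    hdir <- hdir / sqrt(sum(hdir^2))
    h <- d + hdir * 1.0
    add(atom = paste0("pN", i), x = d[1], y = d[2], z = d[3],
        group = "peptide", donor = TRUE, acceptor = FALSE, parent = NA_character_)
    add(atom = paste0("pH", i), x = h[1], y = h[2], z = h[3],
        group = "peptide", donor = FALSE, acceptor = FALSE, parent = paste0("pN", i))
    o <- runif(3, 0, 10)
    add(atom = paste0("pO", i), x = o[1], y = o[2], z = o[3],
        group = "peptide", donor = FALSE, acceptor = TRUE, parent = NA_character_)
  }
  for (i in seq_len(n_water)) {
    o <- runif(3, 0, 10)
    add(atom = paste0("wO", i), x = o[1], y = o[2], z = o[3],
        group = "water", donor = TRUE, acceptor = TRUE, parent = NA_character_)
    for (j in 1:2) {
      hdir <- rnorm(3)
      hdir <- hdir / sqrt(sum(hdir^2))
      h <- o + hdir * 0.96
      add(atom = paste0("wH", i, "_", j), x = h[1], y = h[2], z = h[3],
          group = "water", donor = FALSE, acceptor = FALSE,
          parent = paste0("wO", i))
    }
  }
  dplyr::bind_rows(rows)
}

# A frame holding exactly `k` ideal collinear peptide-water hydrogen bonds,
# spatially separated so no accidental extras appear.
constant_hbond_frame <- function(k) {
  rows <- list()
  for (i in seq_len(k)) {
    x0 <- 20 * i
    rows[[length(rows) + 1]] <- list(
      atom = paste0("N", i), x = x0, y = 0, z = 0, group = "peptide",
      donor = TRUE, acceptor = FALSE, parent = NA_character_
    )
    rows[[length(rows) + 1]] <- list(
      atom = paste0("H", i), x = x0 + 1, y = 0, z = 0, group = "peptide",
      donor = FALSE, acceptor = FALSE, parent = paste0("N", i)
    )
    rows[[length(rows) + 1]] <- list(
      atom = paste0("W", i), x = x0 + 2.8, y = 0, z = 0, group = "water",
      donor = FALSE, acceptor = TRUE, parent = NA_character_
    )
  }
  dplyr::bind_rows(rows)
}

ext_fixture <- function(name) {
  system.file("extdata", name, package = "ramaspec", mustWork = TRUE)
}
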