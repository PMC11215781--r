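test_that("histograms place single frames in the right half-open bin", {
  h <- build_histogram(dihedral_series(0.5, 0.5))
  hit <- h[h$prob > 0, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$phi, 1) # center of [0, 2)
  expect_equal(hit$psi, 1)
  expect_equal(hit$prob, 1)
  expect_equal(nrow(h), 32400)
})

test_that("boundary angles wrap into the grid and mass is conserved", {
  h <- build_histogram(dihedral_series(c(-180, 180, 179.99), c(-180, 0, -180)))
  expect_equal(sum(h$prob), 1, tolerance = 1e-12)
  # -180 and +180 both wrap into the first phi bin, center -179
  expect_equal(sum(h$prob[h$phi == -179]), 2 / 3)
  expect_equal(h$prob[h$phi == -179 & h$psi == -179], 1 / 3)
})

test_that("histogram mass is conserved for arbitrary input", {
  set.seed(4)
  s <- dihedral_series(runif(5000, -720, 720), runif(5000, -720, 720))
  h <- build_histogram(s)
  expect_equal(sum(h$prob), 1, tolerance = 1e-12)
  expect_true(all(h$prob >= 0))
})

test_that("sampled bin probabilities match analytic bin integrals", {
  m <- gaussian_mixture(tibble::tibble(
    label = c("pPII", "aR"), weight = c(0.7, 0.3),
    phi0 = c(-66, -65), psi0 = c(145, -35),
    sigma_phi = c(11, 10), sigma_psi = c(13, 9)
  ))
  n <- 1e5
  h <- build_histogram(sample_mixture(m, n, seed = 23))
  top <- order(h$prob, decreasing = TRUE)[1:10]
  z2 <- purrr::map_dbl(top, function(i) {
    # analytic bin mass by fine midpoint quadrature over the 2x2 deg cell
    sub <- expand.grid(
      phi = h$phi[i] + seq(-0.875, 0.875, by = 0.25),
      psi = h$psi[i] + seq(-0.875, 0.875, by = 0.25)
    )
    p <- sum(mixture_density(m, sub$phi, sub$psi)) * 0.25^2
    (h$prob[i] - p)^2 / (p * (1 - p) / n)
  })
  # simultaneous goodness-of-fit over the 10 bins: the summed squared
  # z-scores are chi-square(10) under multinomial sampling
  expect_lt(sum(z2), qchisq(0.9999, df = 10))
})

test_that("mesostate classification follows the printed strict boxes", {
  s <- dihedral_series(rep(-66, 5), rep(145, 5))
  pops <- mesostate_populations(s)
  expect_equal(pops$population[pops$mesostate == "pPII"], 1)
  expect_equal(sum(pops$population), 1)
  # left-handed frames count only under symmetrization
  sL <- dihedral_series(rep(66, 5), rep(-145, 5))
  expect_equal(
    mesostate_populations(sL)$population,
    rep(0, 4)
  )
  popsL <- mesostate_populations(sL, symmetrize = TRUE)
  expect_equal(popsL$population[popsL$mesostate == "pPII"], 1)
  # boundary frames are excluded (strict inequalities)
  sb <- dihedral_series(c(-90, -42), c(150, 100))
  expect_equal(mesostate_populations(sb)$population, rep(0, 4))
})

test_that("uniform ensembles give area-proportional populations", {
  h <- ramaspec:::rama_histogram(rep(1 / 32400, 32400))
  pops <- mesostate_populations(h)
  areas <- purrr::map_dbl(mesostate_boxes(), function(b) {
    (b$phi_max - b$phi_min) * (b$psi_max - b$psi_min) / 360^2
  })
  expect_equal(pops$population, unname(areas), tolerance = 1e-12)
  pops2 <- mesostate_populations(h, symmetrize = TRUE)
  expect_equal(pops2$population, unname(2 * areas), tolerance = 1e-12)
})

test_that("overlapping mesostate boxes are rejected by name", {
  boxes <- list(
    a = mesostate_box("a", c(-90, -40), c(100, 180)),
    b = mesostate_box("b", c(-60, -30), c(150, 180))
  )
  expect_error(mesostate_populations(dihedral_series(0, 0), boxes), "a and b")
})

test_that("histogram and frame-wise populations agree on bin-edge boxes", {
  m <- read_mixture(ext_fixture("mixture_gly_synthetic.yaml"))
  s <- sample_mixture(m, 2e4, seed = 31)
  h <- build_histogram(s)
  # the printed boxes have even-degree boundaries, aligned with the 2-deg
  # bin edges, so both routes count exactly the same frames
  expect_equal(
    mesostate_populations(h)$population,
    mesostate_populations(s)$population,
    tolerance = 1e-12
  )
})

test_that("windowed populations reduce correctly on forced inputs", {
  box <- mesostate_boxes()$pPII
  s_in <- dihedral_series(rep(-66, 100), rep(145, 100), frame_interval = 2)
  wp <- windowed_populations(s_in, box, window = 40, handedness = "total")
  expect_equal(nrow(wp), 5)
  expect_equal(wp$population, rep(1, 5))
  # alternating in/out with windows spanning even frame counts
  s_alt <- dihedral_series(
    rep(c(-66, 0), 50), rep(c(145, 0), 50),
    frame_interval = 2
  )
  wp2 <- windowed_populations(s_alt, box, window = 40, handedness = "right")
  expect_equal(wp2$population, rep(0.5, 5))
  expect_error(windowed_populations(s_in, box, window = 1), "frame interval")
  expect_error(windowed_populations(s_in, box, window = 1e6), "duration")
})

test_that("left and right populations balance for a symmetric ensemble", {
  m <- read_mixture(ext_fixture("mixture_gly_synthetic.yaml"))
  s <- sample_mixture(m, 1e5, seed = 57)
  box <- mesostate_boxes()$pPII
  left <- windowed_populations(s, box, window = 2000, handedness = "left")
  right <- windowed_populations(s, box, window = 2000, handedness = "right")
  total <- windowed_populations(s, box, window = 2000, handedness = "total")
  expect_equal(total$population, left$population + right$population)
  p <- mean(total$population) / 2
  expect_lt(
    abs(mean(left$population) - mean(right$population)),
    3 * sqrt(2 * p * (1 - p) / nrow(s))
  )
})
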