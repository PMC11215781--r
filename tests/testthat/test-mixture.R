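test_that("density is maximal at the center of a single component", {
  m <- gaussian_mixture(tibble::tibble(
    label = "pPII", weight = 1, phi0 = -66, psi0 = 145,
    sigma_phi = 11, sigma_psi = 13
  ))
  d0 <- mixture_density(m, -66, 145)
  set.seed(1)
  elsewhere <- mixture_density(m, runif(200, -180, 180), runif(200, -180, 180))
  expect_true(all(elsewhere <= d0))
  expect_gt(d0, 0)
})

test_that("an imposed mirror pair gives a chirality-symmetric density", {
  m <- gaussian_mixture(tibble::tibble(
    label = c("a", "a'"), weight = c(0.5, 0.5),
    phi0 = c(-60, 60), psi0 = c(150, -150),
    sigma_phi = c(12, 12), sigma_psi = c(12, 12)
  ))
  expect_equal(mixture_density(m, -60, 150), mixture_density(m, 60, -150))
  expect_equal(mixture_density(m, -10, 40), mixture_density(m, 10, -40))
})

test_that("density matches the direct periodic-image summation oracle", {
  comp <- random_mixture_components(3, seed = 11)
  m <- gaussian_mixture(comp)
  comp$weight <- comp$weight / sum(comp$weight)
  pts <- data.frame(
    phi = c(-170, -66, 0, 95, 179), psi = c(160, 145, -5, -120, -179)
  )
  for (i in seq_len(nrow(pts))) {
    expect_equal(
      mixture_density(m, pts$phi[i], pts$psi[i]),
      oracle_density(comp, pts$phi[i], pts$psi[i]),
      tolerance = 1e-12
    )
  }
})

test_that("density is periodic and normalized on the torus", {
  m <- gaussian_mixture(random_mixture_components(4, seed = 3))
  expect_equal(mixture_density(m, -66, 145), mixture_density(m, -66 + 360, 145 - 720))
  g <- expand.grid(
    phi = seq(-179.75, 179.75, by = 0.5),
    psi = seq(-179.75, 179.75, by = 0.5)
  )
  expect_equal(sum(mixture_density(m, g$phi, g$psi)) * 0.25, 1, tolerance = 1e-6)
})

test_that("invalid mixture parameters are rejected", {
  base <- tibble::tibble(
    label = "x", weight = 1, phi0 = 0, psi0 = 0,
    sigma_phi = 10, sigma_psi = 10
  )
  expect_error(gaussian_mixture(dplyr::mutate(base, sigma_phi = -1)), "positive")
  expect_error(gaussian_mixture(dplyr::mutate(base, weight = -0.2)), "non-negative")
  expect_error(gaussian_mixture(dplyr::mutate(base, rho = 1)), "correlation")
  expect_error(gaussian_mixture(base[0, ]), "at least one component")
})

test_that("sampling is seeded, weight-proportional and wrapped", {
  m <- gaussian_mixture(tibble::tibble(
    label = c("main", "off"), weight = c(1, 0),
    phi0 = c(-66, 100), psi0 = c(145, -100),
    sigma_phi = c(4, 4), sigma_psi = c(5, 5)
  ))
  s1 <- sample_mixture(m, 1e5, seed = 42)
  s2 <- sample_mixture(m, 1e5, seed = 42)
  expect_identical(s1$phi, s2$phi)
  expect_identical(s1$psi, s2$psi)
  expect_true(all(s1$phi >= -180 & s1$phi < 180))
  # degenerate weights: everything from component 1, so circular means must
  # land within 3 standard errors of its center
  expect_lt(abs(mean(s1$phi) - (-66)), 3 * 4 / sqrt(1e5))
  expect_lt(abs(mean(s1$psi) - 145), 3 * 5 / sqrt(1e5))
})

test_that("mesostate_integral recovers full and contained masses", {
  m <- gaussian_mixture(tibble::tibble(
    label = "pPII", weight = 1, phi0 = -66, psi0 = 145,
    sigma_phi = 8, sigma_psi = 8
  ))
  torus <- mesostate_box("all", c(-180, 180), c(-180, 180))
  expect_equal(mesostate_integral(m, torus), 1, tolerance = 1e-6)
  wide <- mesostate_box("wide", c(-66 - 48, -66 + 48), c(145 - 48, 145 + 48))
  expect_equal(mesostate_integral(m, wide), 1, tolerance = 1e-4)
  expect_warning(
    out <- mesostate_integral(m, list(
      phi_min = 10, phi_max = 10, psi_min = 0, psi_max = 5
    )),
    "empty"
  )
  expect_identical(out, 0)
})

test_that("mesostate_integral agrees with a Monte-Carlo fraction", {
  m <- gaussian_mixture(random_mixture_components(3, seed = 5))
  box <- mesostate_boxes()$pPII
  n <- 2e5
  s <- sample_mixture(m, n, seed = 99)
  p_mc <- mean(s$phi > box$phi_min & s$phi < box$phi_max &
                 s$psi > box$psi_min & s$psi < box$psi_max)
  p_quad <- mesostate_integral(m, box)
  expect_lt(abs(p_mc - p_quad), 3 * sqrt(p_quad * (1 - p_quad) / n))
})

test_that("symmetrize builds the reflected twin construction", {
  m <- gaussian_mixture(tibble::tibble(
    label = "pPII", weight = 1, phi0 = -66, psi0 = 145,
    sigma_phi = 11, sigma_psi = 13
  ))
  ms <- symmetrize(m)
  expect_true(is_symmetric(ms))
  expect_equal(nrow(ms), 2)
  expect_equal(ms$weight, c(0.5, 0.5))
  expect_equal(ms$phi0, c(-66, 66))
  expect_equal(ms$psi0, c(145, -145))
})

test_that("symmetrized densities have the point symmetry; idempotence", {
  m <- symmetrize(gaussian_mixture(random_mixture_components(3, seed = 7)))
  set.seed(8)
  phi <- runif(100, -180, 180)
  psi <- runif(100, -180, 180)
  expect_equal(mixture_density(m, phi, psi), mixture_density(m, -phi, -psi))
  # symmetrizing an already-symmetric mixture leaves the density unchanged
  m2 <- symmetrize(m)
  g <- expand.grid(phi = seq(-179, 179, by = 2), psi = seq(-179, 179, by = 2))
  expect_equal(
    mixture_density(m2, g$phi, g$psi),
    mixture_density(m, g$phi, g$psi),
    tolerance = 1e-12
  )
})

test_that("symmetrized box mass equals the halved box + reflection identity", {
  m <- gaussian_mixture(random_mixture_components(3, seed = 13))
  ms <- symmetrize(m)
  box <- mesostate_boxes()$pPII
  lhs <- mesostate_integral(ms, box)
  rhs <- (mesostate_integral(m, box) + mesostate_integral(m, reflect_box(box))) / 2
  expect_equal(lhs, rhs, tolerance = 1e-8)
})

test_that("sampled histograms converge to the analytic density", {
  m <- gaussian_mixture(random_mixture_components(3, seed = 21))
  target <- mixture_histogram(m)
  tv <- function(n) {
    h <- build_histogram(sample_mixture(m, n, seed = 17))
    sum(abs(h$prob - target$prob)) / 2
  }
  expect_lt(tv(1e6), tv(1e3))
})

test_that("mixture YAML definitions round-trip", {
  m <- gaussian_mixture(random_mixture_components(3, seed = 31))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_mixture(m, path)
  m2 <- read_mixture(path)
  expect_equal(as.data.frame(m2), as.data.frame(m), tolerance = 1e-9)
  gly <- read_mixture(ext_fixture("mixture_gly_synthetic.yaml"))
  expect_true(is_symmetric(gly))
  expect_equal(sum(gly$weight), 1)
})
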