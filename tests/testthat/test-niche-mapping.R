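piecewise_profiles <- function() {
  # NO3 linear 25 -> 0 uM over 0 -> 2 m; NH4 zero until 2.2 m then linear to
  # 50 uM at 4 m
  zs <- sort(c(seq(0, 4, by = 0.25), 2.2))  # include the NH4 kink as a sample
  no3 <- pmax(25 * (1 - zs / 2), 0)
  nh4 <- pmax(50 * (zs - 2.2) / 1.8, 0)
  dplyr::bind_rows(
    tibble::tibble(depth_m = zs, species = "NO3", concentration_uM = no3),
    tibble::tibble(depth_m = zs, species = "NH4", concentration_uM = nh4)
  )
}

test_that("transition-zone boundaries interpolate the threshold crossings", {
  zone <- detect_nat_zone(piecewise_profiles(), eps_no3 = 1, eps_nh4 = 1)
  expect_equal(zone$z_no3, 2 * 24 / 25, tolerance = 1e-12)       # 1.92 m
  expect_equal(zone$z_nh4, 2.2 + 1.8 / 50, tolerance = 1e-12)    # 2.236 m
  expect_equal(zone$z_top, 1.92)
  expect_equal(zone$mode, "gap")
})

test_that("profiles without a transition are rejected", {
  zs <- seq(0, 4, by = 0.5)
  flat <- dplyr::bind_rows(
    tibble::tibble(depth_m = zs, species = "NO3", concentration_uM = 25),
    tibble::tibble(depth_m = zs, species = "NH4", concentration_uM = 50 * zs / 4)
  )
  expect_error(detect_nat_zone(flat), class = "natzone_no_transition_error")

  # NO3 below threshold already at the surface
  dead <- dplyr::bind_rows(
    tibble::tibble(depth_m = zs, species = "NO3", concentration_uM = 0.1),
    tibble::tibble(depth_m = zs, species = "NH4", concentration_uM = 50 * zs / 4)
  )
  expect_error(detect_nat_zone(dead), class = "natzone_no_transition_error")
})

test_that("coincident crossings give a zero-width zone", {
  prof <- dplyr::bind_rows(
    tibble::tibble(depth_m = c(0, 2.3, 4), species = "NO3",
                   concentration_uM = c(25, 1, 0)),
    tibble::tibble(depth_m = c(0, 2.3, 4), species = "NH4",
                   concentration_uM = c(0, 1, 50))
  )
  zone <- detect_nat_zone(prof)
  expect_equal(zone$z_top, 2.3)
  expect_equal(zone$z_bottom, 2.3)
})

test_that("zone detection is invariant to profile super-sampling", {
  base <- piecewise_profiles()
  z0 <- detect_nat_zone(base)
  dense <- base |>
    dplyr::group_by(.data$species) |>
    dplyr::reframe(as.data.frame(stats::approx(.data$depth_m,
                                               .data$concentration_uM,
                                               xout = seq(0, 4, by = 0.03125)))) |>
    dplyr::rename(depth_m = "x", concentration_uM = "y")
  z1 <- detect_nat_zone(dense)
  expect_equal(z1$z_top, z0$z_top, tolerance = 1e-9)
  expect_equal(z1$z_bottom, z0$z_bottom, tolerance = 1e-9)
})

test_that("rate maxima report the shallowest maximal cell", {
  df <- tibble::tibble(z_mid = c(0.5, 1.5, 2.5, 3.5), R_amx = c(0, 0, 5, 1))
  expect_equal(rate_maximum_depth(df), 2.5)

  tie <- tibble::tibble(z_mid = c(0.5, 1.5, 2.5), R_amx = c(3, 3, 0))
  expect_equal(rate_maximum_depth(tie), 0.5)

  zero <- tibble::tibble(z_mid = c(0.5, 1.5), R_amx = c(0, 0))
  expect_error(rate_maximum_depth(zero), class = "natzone_no_active_zone_error")

  z <- seq(0, 4, by = 0.01)
  gauss <- tibble::tibble(z_mid = z, R_amx = exp(-(z - 2.37)^2 / 0.08))
  expect_equal(rate_maximum_depth(gauss), z[which.min(abs(z - 2.37))])
})

test_that("confinement index is the in-zone fraction of summed abundance", {
  zone <- tibble::tibble(z_top = 1, z_bottom = 3)
  ab <- tibble::tibble(taxon = "t", depth_m = c(0.5, 1.5, 2, 2.5, 3.5),
                       abundance = c(0, 0.2, 0.5, 0.3, 0))
  expect_equal(confinement_index(ab, zone)$index, 1)

  zone1 <- tibble::tibble(z_top = 1.9, z_bottom = 2.1)
  expect_equal(confinement_index(ab, zone1)$index, 0.5)

  outside <- tibble::tibble(z_top = 5, z_bottom = 6)
  expect_equal(confinement_index(ab, outside)$index, 0)

  zero <- tibble::tibble(taxon = "t", depth_m = 1:3, abundance = 0)
  expect_error(confinement_index(zero, zone),
               class = "natzone_undefined_index_error")
})

test_that("exhaustive permutation p-values match full enumeration", {
  zone <- tibble::tibble(z_top = 2.9, z_bottom = 3.1)
  ab <- tibble::tibble(taxon = "t", depth_m = 1:5, abundance = c(0, 0, 1, 0, 0))
  res <- confinement_test(ab, zone, seed = 1)
  expect_equal(res$method, "exhaustive")
  expect_equal(res$n_permutations, 120L)
  # 24 of 120 permutations keep the mass at the single in-zone depth
  expect_equal(res$p_value, 25 / 121, tolerance = 1e-12)
  expect_equal(res$index, 1)
})

test_that("constant abundance gives p = 1 in both modes", {
  zone <- tibble::tibble(z_top = 1.5, z_bottom = 3.5)
  ab <- tibble::tibble(taxon = "t", depth_m = 1:6, abundance = 0.1)
  expect_equal(confinement_test(ab, zone, seed = 3)$p_value, 1)
  mc <- confinement_test(ab, zone, seed = 3, n_perm = 999, exhaustive = FALSE)
  expect_equal(mc$p_value, 1)
})

test_that("Monte-Carlo p agrees with enumeration within 3 binomial SEs", {
  zone <- tibble::tibble(z_top = 2.5, z_bottom = 5.5)
  cases <- list(
    c(0.1, 0, 0.4, 0.3, 0.05, 0, 0.15),
    c(0, 0.2, 0.5, 0.3, 0, 0),
    c(0.3, 0.3, 0.1, 0.1, 0.2)
  )
  for (a in cases) {
    ab <- tibble::tibble(taxon = "t", depth_m = seq_along(a), abundance = a)
    ex <- confinement_test(ab, zone, seed = 5)
    mc <- confinement_test(ab, zone, seed = 5, n_perm = 999, exhaustive = FALSE)
    se <- sqrt(ex$p_value * (1 - ex$p_value) / 999)
    expect_lt(abs(mc$p_value - ex$p_value), 3 * se + 1e-3)
    expect_gte(mc$p_value, 1 / 1000)
    expect_gte(ex$p_value, 1 / (ex$n_permutations + 1))
  }
})

test_that("permutation tests are reproducible by seed", {
  zone <- tibble::tibble(z_top = 2, z_bottom = 6)
  set.seed(99)
  ab <- tibble::tibble(taxon = rep(c("a", "b"), each = 12),
                       depth_m = rep(1:12, 2), abundance = runif(24))
  r1 <- confinement_test(ab, zone, seed = 7)
  r2 <- confinement_test(ab, zone, seed = 7)
  expect_identical(r1, r2)
  r3 <- confinement_test(ab, zone, seed = 8)
  expect_false(identical(r1$p_value, r3$p_value))
})
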