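test_that("monod and inhibition factors match their closed forms", {
  expect_equal(monod(5, 5), 0.5)
  expect_equal(monod(0, 5), 0)
  expect_equal(monod(15, 5), 0.75)
  expect_error(monod(-1, 5), class = "natzone_input_error")

  expect_equal(inhibition(0, 1), 1)
  expect_equal(inhibition(1, 1), 0.5)
  expect_lt(inhibition(1e9, 1), 1e-8)
  expect_error(inhibition(-1, 1), class = "natzone_input_error")
})

test_that("volumetric rates compose the stated rate laws", {
  g <- nat_grid(2, 1)  # single cell, center z = 1
  kp <- kinetic_params(R0 = 100, z_att = 1e9, K_O2 = 10, K_NO3 = 8, Ki_O2 = 10)
  # z_att >> z so R_C = R0 at the cell center

  zero <- volumetric_rates(data.frame(O2 = 0, NO3 = 0, NH4 = 0), g, kp)
  expect_equal(unlist(zero[c("R_O2C", "R_denC", "R_nit", "R_amx")]),
               c(R_O2C = 0, R_denC = 0, R_nit = 0, R_amx = 0))

  # saturating O2, no nitrate: everything aerobic
  sat <- volumetric_rates(data.frame(O2 = 1e9, NO3 = 0, NH4 = 0), g, kp)
  expect_equal(sat$R_O2C, 100, tolerance = 1e-6)
  expect_equal(sat$R_denC, 0)
  expect_equal(sat$R_amx, 0)

  # half-saturation everywhere: O2 = K_O2 = Ki_O2, NO3 = K_NO3
  half <- volumetric_rates(data.frame(O2 = 10, NO3 = 8, NH4 = 0), g, kp)
  expect_equal(half$R_O2C, 50)
  expect_equal(half$R_denC, 100 * 0.5 * 0.5 * 0.5)

  expect_error(volumetric_rates(data.frame(O2 = -1, NO3 = 0, NH4 = 0), g, kp),
               class = "natzone_input_error")
})

test_that("species sources implement the network stoichiometry", {
  kp <- kinetic_params(r_NC = 0.151)
  base <- tibble::tibble(cell = 1L, z_mid = 1, R_O2C = 0, R_denC = 0,
                         R_nit = 0, R_amx = 0)

  s0 <- species_sources(base, kp)
  expect_equal(unlist(s0[c("S_O2", "S_NO3", "S_NH4", "S_N2N")]),
               c(S_O2 = 0, S_NO3 = 0, S_NH4 = 0, S_N2N = 0))

  # anammox alone: 5 NH4 : 3 NO3 -> 4 N2
  amx <- species_sources(dplyr::mutate(base, R_amx = 10), kp)
  expect_equal(amx$S_NH4, -10)
  expect_equal(amx$S_NO3, -6)
  expect_equal(amx$S_N2N, 16)
  expect_equal(amx$S_O2, 0)

  # denitrification alone
  den <- species_sources(dplyr::mutate(base, R_denC = 5), kp)
  expect_equal(den$S_NO3, -4)
  expect_equal(den$S_NH4, 0.755)
  expect_equal(den$S_N2N, 4)
})

test_that("fixed nitrogen consumed equals N2-N produced for any rate vector", {
  kp <- kinetic_params()
  set.seed(101)
  for (i in 1:20) {
    rates <- tibble::tibble(cell = 1:5, z_mid = seq(0.1, 0.5, 0.1),
                            R_O2C = runif(5, 0, 100), R_denC = runif(5, 0, 50),
                            R_nit = runif(5, 0, 30), R_amx = runif(5, 0, 20))
    s <- species_sources(rates, kp)
    lhs <- -s$S_NO3 - s$S_NH4 + kp$r_NC * (rates$R_O2C + rates$R_denC)
    expect_equal(lhs, s$S_N2N, tolerance = 1e-14)
  }
})

test_that("anammox rate is monotone in its substrates and inhibitor", {
  g <- nat_grid(1, 1)
  kp <- kinetic_params()
  r_amx <- function(o2, no3, nh4) {
    volumetric_rates(data.frame(O2 = o2, NO3 = no3, NH4 = nh4), g, kp)$R_amx
  }
  nh4 <- seq(0, 50, length.out = 11)
  expect_true(all(diff(sapply(nh4, function(v) r_amx(0, 10, v))) >= 0))
  no3 <- seq(0, 40, length.out = 11)
  expect_true(all(diff(sapply(no3, function(v) r_amx(0, v, 5))) >= 0))
  o2 <- seq(0, 100, length.out = 11)
  expect_true(all(diff(sapply(o2, function(v) r_amx(v, 10, 5))) <= 0))
})

test_that("mineralization pathways scale linearly in R0", {
  g <- nat_grid(2, 8)
  concs <- data.frame(O2 = seq(100, 0, length.out = 8),
                      NO3 = seq(20, 1, length.out = 8),
                      NH4 = seq(0, 30, length.out = 8))
  r1 <- volumetric_rates(concs, g, kinetic_params(R0 = 300))
  r3 <- volumetric_rates(concs, g, kinetic_params(R0 = 900))
  expect_equal(r3$R_O2C, 3 * r1$R_O2C, tolerance = 1e-12)
  expect_equal(r3$R_denC, 3 * r1$R_denC, tolerance = 1e-12)
  expect_equal(r3$R_nit, r1$R_nit)   # independent of R0
  expect_equal(r3$R_amx, r1$R_amx)
})
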