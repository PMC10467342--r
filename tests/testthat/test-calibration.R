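coarse_setup <- function(n = 120) ref_setup(n)

test_that("the objective is zero for self-consistent observations", {
  setup <- coarse_setup()
  obs <- generate_observed(setup, depths = seq(0.1, 3.9, by = 0.2),
                           noise_sd = 0, seed = 1)
  val <- profile_objective(obs, setup)
  expect_lt(as.numeric(val), 1e-12)
})

test_that("the objective is the weighted sum of squared residuals", {
  setup <- coarse_setup()
  sol <- solve_setup(setup)
  m <- approx(sol$profile$z_mid, sol$profile$NO3, xout = 1.7, rule = 2)$y
  obs1 <- tibble::tibble(species = "NO3", depth_m = 1.7,
                         concentration_uM = m + 2 * 3, sigma_uM = 3)
  expect_equal(as.numeric(profile_objective(obs1, setup)), 4, tolerance = 1e-9)

  # two species, hand-summed
  m2 <- approx(sol$profile$z_mid, sol$profile$NH4, xout = 3.1, rule = 2)$y
  obs2 <- tibble::tibble(
    species = c("NO3", "NH4"), depth_m = c(1.7, 3.1),
    concentration_uM = c(m + 1.5, m2 - 2), sigma_uM = c(0.5, 4)
  )
  expect_equal(as.numeric(profile_objective(obs2, setup)),
               (1.5 / 0.5)^2 + (2 / 4)^2, tolerance = 1e-9)

  expect_error(
    profile_objective(tibble::tibble(species = "NO3", depth_m = 99,
                                     concentration_uM = 1), setup),
    class = "natzone_input_error")
})

test_that("the objective is invariant to observation order", {
  setup <- coarse_setup()
  obs <- generate_observed(setup, depths = seq(0.2, 3.8, by = 0.4),
                           noise_sd = 2, seed = 4)
  perm <- obs[sample(nrow(obs)), ]
  expect_equal(as.numeric(profile_objective(obs, setup, params = c(k_amx = 0.2))),
               as.numeric(profile_objective(perm, setup, params = c(k_amx = 0.2))),
               tolerance = 1e-12)
})

test_that("a single free rate constant is recovered from noiseless data", {
  setup <- coarse_setup()
  obs <- generate_observed(setup, depths = seq(0.1, 3.9, by = 0.2),
                           noise_sd = 0, seed = 2)
  fit <- fit_profiles(obs, setup, free = "k_amx", lower = 0.005, upper = 2,
                      start = 0.3, seed = 11)
  expect_true(fit$converged)
  expect_lt(abs(fit$par[["k_amx"]] - 0.1) / 0.1, 0.01)
  expect_lt(fit$objective, 1e-6)
})

test_that("starting at the truth leaves the parameters unchanged", {
  setup <- coarse_setup()
  obs <- generate_observed(setup, depths = seq(0.3, 3.7, by = 0.4),
                           noise_sd = 0, seed = 3)
  fit <- fit_profiles(obs, setup, free = "k_amx", lower = 0.005, upper = 2,
                      start = 0.1, seed = 12)
  expect_lt(abs(fit$par[["k_amx"]] - 0.1) / 0.1, 1e-3)
  expect_lt(fit$objective, 1e-8)
})

test_that("calibration rejects invalid specifications", {
  setup <- coarse_setup()
  obs <- tibble::tibble(species = "NO3", depth_m = 1, concentration_uM = 10)
  expect_error(
    fit_profiles(obs, setup, free = "k_amx", lower = 0.5, upper = 2,
                 start = 0.1, seed = 1),
    class = "natzone_input_error")  # start outside bounds
  expect_error(
    fit_profiles(obs, setup, free = letters[1:7], lower = 0, upper = 1, seed = 1),
    class = "natzone_input_error")  # too many free parameters
  expect_error(
    fit_profiles(obs, setup, free = "not_a_param", lower = 0.1, upper = 1,
                 start = 0.5, seed = 1),
    class = "natzone_input_error")
  expect_error(
    fit_profiles(obs, setup, free = "k_amx", lower = 0.005, upper = Inf,
                 start = 0.1, seed = 1),
    class = "natzone_input_error")  # bounds must be finite
})
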