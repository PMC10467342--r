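test_that("pure diffusion reproduces the linear profile exactly", {
  o <- oracle_parts(n = 50)
  sol <- solve_steady_state(o$grid, o$por, o$tp, NULL, o$bc)
  expect_true(sol$converged)
  exact <- 10 + (2 - 10) * o$grid$z_mid
  expect_equal(sol$profile$A, exact, tolerance = 1e-12)
})

test_that("advection-diffusion matches the exponential closed form", {
  for (Pe in c(1, 5)) {
    Ds <- effective_diffusivity(0.02, 0.8)
    o <- oracle_parts(n = 200, w = Pe * Ds)
    sol <- solve_steady_state(o$grid, o$por, o$tp, NULL, o$bc)
    expect_true(sol$converged)
    exact <- 10 + (2 - 10) * (exp(Pe * o$grid$z_mid) - 1) / (exp(Pe) - 1)
    relerr <- max(abs(sol$profile$A - exact)) / max(abs(exact))
    expect_lt(relerr, 0.005)
  }
})

test_that("first-order decay matches the cosh profile at second order", {
  k <- 5
  Ds <- effective_diffusivity(0.02, 0.8)
  decay <- function(cm, grid) {
    m <- -k * as.matrix(cm)
    colnames(m) <- "A"
    m
  }
  bc <- boundary_conditions(top = c(A = 10), bottom = list(A = "zero_gradient"))
  al <- sqrt(k / Ds)
  errs <- sapply(c(50, 100, 200), function(n) {
    g <- nat_grid(1, n)
    sol <- solve_steady_state(g, porosity_profile(g, 0.8),
                              transport_params(D0 = c(A = 0.02), w = 0),
                              NULL, bc, reactions = decay)
    expect_true(sol$converged)
    exact <- 10 * cosh(al * (1 - g$z_mid)) / cosh(al)
    max(abs(sol$profile$A - exact)) / max(abs(exact))
  })
  expect_lt(errs[3], 0.005)
  orders <- diff(-log2(errs))
  expect_true(all(orders > 1.7 & orders < 2.3))
})

test_that("a single decaying cell solves the hand-derived balance", {
  # one cell, fixed top C0, zero-gradient bottom, first-order decay k, w = 0:
  # (a / (z1 dz)) (C0 - C1) = phi k C1  =>  C1 = C0 g / (g + phi k)
  g <- nat_grid(1, 1)
  phi <- 0.7; D0 <- 0.02; k <- 3; C0 <- 12
  a <- phi * effective_diffusivity(D0, phi)
  gcoef <- a / (0.5 * 1)
  expected <- C0 * gcoef / (gcoef + phi * k)
  decay <- function(cm, grid) {
    m <- -k * as.matrix(cm); colnames(m) <- "A"; m
  }
  sol <- solve_steady_state(
    g, porosity_profile(g, phi), transport_params(D0 = c(A = D0), w = 0), NULL,
    boundary_conditions(top = c(A = C0), bottom = list(A = "zero_gradient")),
    reactions = decay)
  expect_true(sol$converged)
  expect_equal(sol$profile$A, expected, tolerance = 1e-10)
})

test_that("assemble_residual vanishes on exact discrete solutions", {
  o <- oracle_parts(n = 40)
  lin <- 10 + (2 - 10) * o$grid$z_mid
  r <- assemble_residual(data.frame(A = lin), o$grid, o$por, o$tp, NULL, o$bc)
  expect_lt(max(abs(r$A)), 1e-10)

  # constant field equal to both Dirichlet values, zero sources
  o2 <- oracle_parts(n = 40, top = 7, bottom = 7)
  r2 <- assemble_residual(data.frame(A = rep(7, 40)), o2$grid, o2$por, o2$tp,
                          NULL, o2$bc)
  expect_lt(max(abs(r2$A)), 1e-10)

  expect_error(
    assemble_residual(data.frame(A = rep(7, 39)), o2$grid, o2$por, o2$tp,
                      NULL, o2$bc),
    class = "natzone_structure_error")
})

test_that("the reference nitrogen-network scenario converges and closes its budgets", {
  sol <- solve_setup(ref_setup(200))
  expect_true(sol$converged)
  expect_true(all(sol$profile$O2 >= 0 & sol$profile$NO3 >= 0 &
                    sol$profile$NH4 >= 0))
  mb <- mass_balance_report(sol)
  expect_true(all(mb$closure_rel <= 1e-6))
  expect_lte(mb$closure_rel[mb$species == "fixed_N"], 1e-6)
})

test_that("a no-reaction linear solution balances boundary fluxes", {
  o <- oracle_parts(n = 60)
  sol <- solve_steady_state(o$grid, o$por, o$tp, NULL, o$bc)
  mb <- mass_balance_report(sol)
  expect_equal(mb$flux_top, mb$flux_bottom, tolerance = 1e-10)
  expect_lte(mb$closure_rel, 1e-10)
})

test_that("depth-integrated rates reduce to porosity-weighted quadrature", {
  fake <- structure(list(profile = tibble::tibble(
    cell = 1:4, z_mid = c(0.5, 1.5, 2.5, 3.5), dz = rep(1, 4), phi = 0.8,
    R_amx = c(0, 2, 0, 0), R_nit = rep(3, 4), R_O2C = 0, R_denC = 0
  )), class = "nat_solution")
  expect_equal(depth_integrated_rate(fake, "R_amx"), 2 * 0.8 * 1)
  expect_equal(depth_integrated_rate(fake, "R_nit"), 3 * 0.8 * 4)
  expect_error(depth_integrated_rate(fake, "R_bogus"), class = "natzone_input_error")

  # exponential rate profile on a fine grid against the analytic integral
  g <- nat_grid(4, 800)
  z_att <- 0.5
  fine <- structure(list(profile = tibble::tibble(
    cell = g$cell, z_mid = g$z_mid, dz = g$dz, phi = 0.75,
    R_amx = exp(-g$z_mid / z_att)
  )), class = "nat_solution")
  analytic <- z_att * (1 - exp(-4 / z_att)) * 0.75
  expect_equal(depth_integrated_rate(fine, "R_amx"), analytic, tolerance = 5e-3)
})

test_that("exhausted iteration budgets return diagnostics, not an error", {
  setup <- ref_setup(100)
  sol <- solve_steady_state(setup$grid, setup$porosity, setup$transport,
                            setup$kinetics, setup$bc,
                            solver_control(max_newton = 1, max_ptc = 1))
  expect_false(sol$converged)
  expect_true(is.finite(sol$residual_norm))
})

test_that("anammox activity is confined to substrate co-occurrence", {
  sol <- solve_setup(ref_setup(200))
  p <- sol$profile
  both <- p$NH4 > 1e-9 & p$NO3 > 1e-9
  expect_true(all(p$R_amx[!both] <= 1e-9 * max(p$R_amx)))
  peak <- rate_maximum_depth(sol)
  co <- range(p$z_mid[both])
  expect_gte(peak, co[1])
  expect_lte(peak, co[2])
})
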