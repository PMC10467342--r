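#' Build a one-dimensional sediment grid
#'
#' Cell-centered finite-volume discretization of the sediment column. Depth is
#' measured in meters below the sediment-water interface, positive downward,
#' with 0 at the interface.
#'
#' @param L Total depth extent in meters (> 0).
#' @param n_cells Number of cells (>= 1).
#' @param spacing Either `"uniform"` (all cells `L / n_cells` wide) or
#'   `"geometric"`, where cell widths grow by a constant `ratio` downward,
#'   refining near the interface when `ratio > 1`.
#' @param ratio Width ratio between successive cells for geometric spacing.
#'
#' @return A tibble of class `nat_grid` with columns `cell`, `z_mid` (cell
#'   center depth, m) and `dz` (cell width, m), and attributes `L` and
#'   `interfaces` (the `n_cells + 1` interface depths, from 0 to `L`).
#' @examples
#' nat_grid(2, 4)
#' nat_grid(7, 3, spacing = "geometric", ratio = 2)
#' @export
nat_grid <- function(L, n_cells, spacing = c("uniform", "geometric"), ratio = 1) {
  check_number(L, "L", lower = 0, strict_lower = TRUE)
  check_number(n_cells, "n_cells", lower = 1)
  if (n_cells != round(n_cells)) abort_input("`n_cells` must be a whole number")
  n_cells <- as.integer(n_cells)
  spacing <- match.arg(spacing)

  if (spacing == "uniform" || isTRUE(all.equal(ratio, 1))) {
    dz <- rep(L / n_cells, n_cells)
  } else {
    check_number(ratio, "ratio", lower = 0, strict_lower = TRUE)
    w1 <- L * (1 - ratio) / (1 - ratio^n_cells)
    dz <- w1 * ratio^(seq_len(n_cells) - 1)
  }
  interfaces <- c(0, cumsum(dz))
  interfaces[n_cells + 1] <- L  # absorb rounding in the cumulative sum
  z_mid <- (interfaces[-1] + interfaces[-(n_cells + 1)]) / 2

  out <- tibble::tibble(cell = seq_len(n_cells), z_mid = z_mid, dz = dz)
  attr(out, "L") <- L
  attr(out, "interfaces") <- interfaces
  class(out) <- c("nat_grid", class(out))
  out
}

grid_extent <- function(grid) attr(grid, "L")

#' Porosity model and evaluation on a grid
#'
#' Porosity follows the standard exponential compaction law
#' \eqn{\phi(z) = \phi_\infty + (\phi_0 - \phi_\infty) e^{-z/\lambda}}.
#' With `lambda = Inf` (default) or `phi0 == phi_inf` the profile is constant
#' at `phi0`.
#'
#' @param grid A `nat_grid`.
#' @param phi0 Porosity at the sediment-water interface, in (0, 1].
#' @param phi_inf Asymptotic porosity at depth, in (0, 1]; defaults to `phi0`.
#' @param lambda Attenuation length in meters (> 0), or `Inf` for constant
#'   porosity.
#'
#' @return The grid tibble with a `phi` column appended (values in (0, 1]).
#' @examples
#' g <- nat_grid(2, 10)
#' porosity_profile(g, phi0 = 0.8)
#' porosity_profile(g, phi0 = 0.9, phi_inf = 0.7, lambda = 0.5)
#' @export
porosity_profile <- function(grid, phi0 = 0.75, phi_inf = phi0, lambda = Inf) {
  check_number(phi0, "phi0", lower = 0, upper = 1, strict_lower = TRUE)
  check_number(phi_inf, "phi_inf", lower = 0, upper = 1, strict_lower = TRUE)
  check_number(lambda, "lambda", lower = 0, strict_lower = TRUE, allow_inf = TRUE)
  phi <- porosity_at(grid$z_mid, phi0, phi_inf, lambda)
  if (any(phi <= 0) || any(phi > 1)) {
    abort_input("porosity model yields values outside (0, 1] on the grid",
                class = "natzone_parameter_error")
  }
  dplyr::mutate(tibble::as_tibble(grid), phi = phi)
}

porosity_at <- function(z, phi0, phi_inf, lambda) {
  if (is.infinite(lambda) || phi0 == phi_inf) {
    rep(phi0, length(z))
  } else {
    phi_inf + (phi0 - phi_inf) * exp(-z / lambda)
  }
}

#' Tortuosity-corrected effective diffusivity
#'
#' Boudreau's relation \eqn{D_s = D_0 / (1 - \ln \phi^2)}: the free-solution
#' diffusivity is reduced for the convoluted diffusion path in the sediment
#' matrix. At \eqn{\phi = 1} there is no correction.
#'
#' @param D0 Free-solution diffusivity, m^2 yr^-1 (> 0). Vectorized.
#' @param phi Porosity in (0, 1]. Vectorized.
#' @return Effective diffusivity `Ds <= D0`, m^2 yr^-1.
#' @examples
#' effective_diffusivity(0.03, 1)            # no correction
#' effective_diffusivity(1, exp(-1 / 2))     # exactly D0 / 2
#' @export
effective_diffusivity <- function(D0, phi) {
  if (any(!is.finite(D0)) || any(D0 <= 0)) {
    abort_input("`D0` must be positive and finite", class = "natzone_parameter_error")
  }
  if (any(!is.finite(phi)) || any(phi <= 0) || any(phi > 1)) {
    abort_input("`phi` must lie in (0, 1]", class = "natzone_parameter_error")
  }
  D0 / (1 - 2 * log(phi))
}

#' Transport parameters
#'
#' @param D0 Named numeric vector of free-solution diffusivities, m^2 yr^-1,
#'   one per modeled species (names define the species set, e.g. `O2`, `NO3`,
#'   `NH4`). Defaults are representative of cold (~2 degC) bottom water.
#' @param w Burial (pore-water advection) velocity, m yr^-1, >= 0, positive
#'   downward; constant with depth.
#' @return A list of class `nat_transport`.
#' @examples
#' transport_params()
#' @export
transport_params <- function(D0 = c(O2 = 0.037, NO3 = 0.031, NH4 = 0.031),
                             w = 1e-5) {
  if (is.null(names(D0)) || any(names(D0) == "")) {
    abort_input("`D0` must be a fully named vector (species names)")
  }
  if (any(!is.finite(D0)) || any(D0 <= 0)) abort_input("all `D0` must be > 0")
  check_number(w, "w", lower = 0)
  structure(list(D0 = D0, w = w), class = "nat_transport")
}
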