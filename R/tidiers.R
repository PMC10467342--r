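# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a steady-state solution into long format
#'
#' @param x A `nat_solution`.
#' @param ... Unused.
#' @return Tibble with columns `depth_m`, `quantity`, `value`, `type`
#'   (`"concentration"` in uM, `"rate"` or `"source"` in uM yr^-1).
#' @export
tidy.nat_solution <- function(x, ...) {
  p <- x$profile
  long <- tidyr::pivot_longer(p, -c("cell", "z_mid", "dz", "phi"),
                              names_to = "quantity", values_to = "value")
  dplyr::transmute(
    long,
    depth_m = .data$z_mid, quantity = .data$quantity, value = .data$value,
    type = dplyr::case_when(
      startsWith(.data$quantity, "R_") ~ "rate",
      startsWith(.data$quantity, "S_") ~ "source",
      TRUE ~ "concentration"
    )
  )
}

#' One-row summary of a steady-state solution
#'
#' @param x A `nat_solution`.
#' @param ... Unused.
#' @return Tibble with convergence diagnostics and, when the nitrogen network
#'   is present, the depth-integrated anammox rate (mmol m^-2 yr^-1).
#' @export
glance.nat_solution <- function(x, ...) {
  out <- tibble::tibble(
    converged = x$converged, residual_norm = x$residual_norm,
    iterations = x$iterations, n_cells = nrow(x$profile),
    extent_m = grid_extent(x$grid)
  )
  if ("R_amx" %in% names(x$profile)) {
    out$anammox_integrated <- depth_integrated_rate(x, "R_amx")
  }
  out
}

#' Tidy fitted calibration parameters
#'
#' @param x A `nat_fit`.
#' @param ... Unused.
#' @return Tibble with `parameter`, `estimate`, `start`, `lower`, `upper`.
#' @export
tidy.nat_fit <- function(x, ...) {
  dplyr::mutate(x$bounds, estimate = unname(x$par[.data$parameter]),
                .after = "parameter")
}

#' One-row summary of a calibration
#'
#' @param x A `nat_fit`.
#' @param ... Unused.
#' @return Tibble with the objective, convergence flag, forward-run count and
#'   observation count.
#' @export
glance.nat_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective, converged = x$converged,
                 n_forward_evaluations = x$n_forward_evaluations,
                 n_obs = nrow(x$residuals), n_free = length(x$free))
}

#' @export
tidy.nat_zone <- function(x, ...) tibble::as_tibble(x)

#' @export
tidy.nat_confinement <- function(x, ...) tibble::as_tibble(x)
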