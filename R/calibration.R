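# Weighted least-squares calibration of kinetic/transport parameters against
# observed porewater profiles, by bounded derivative-free search over forward
# model runs.

#' Bundle a full forward-model setup
#'
#' @param grid A [nat_grid()].
#' @param porosity A [porosity_profile()] tibble.
#' @param transport A [transport_params()] object.
#' @param kinetics A [kinetic_params()] object (or `NULL`).
#' @param bc A [boundary_conditions()] object.
#' @param control A [solver_control()] object.
#' @return A list of class `nat_setup`.
#' @export
model_setup <- function(grid, porosity, transport, kinetics, bc,
                        control = solver_control()) {
  structure(list(grid = grid, porosity = porosity, transport = transport,
                 kinetics = kinetics, bc = bc, control = control),
            class = "nat_setup")
}

#' Solve the forward model of a bundled setup
#'
#' Convenience wrapper around [solve_steady_state()] for a [model_setup()].
#'
#' @param setup A [model_setup()].
#' @param init Optional warm-start concentrations.
#' @return A `nat_solution`.
#' @export
solve_setup <- function(setup, init = NULL) {
  solve_steady_state(setup$grid, setup$porosity, setup$transport,
                     setup$kinetics, setup$bc, setup$control, init = init)
}

# Free-parameter vocabulary: kinetic names, "w", "D0_<species>",
# "top_<species>", "bottom_<species>" (fixed-concentration bottoms only).
apply_params <- function(setup, values) {
  kin_names <- c("R0", "z_att", "r_NC", "k_nit", "k_amx",
                 "K_O2", "K_O2nit", "K_NO3", "Ki_O2")
  for (nm in names(values)) {
    v <- values[[nm]]
    if (nm %in% kin_names) {
      setup$kinetics[[nm]] <- v
    } else if (nm == "w") {
      setup$transport$w <- v
    } else if (startsWith(nm, "D0_")) {
      sp <- sub("^D0_", "", nm)
      if (!sp %in% names(setup$transport$D0)) abort_input(sprintf("unknown species in `%s`", nm))
      setup$transport$D0[[sp]] <- v
    } else if (startsWith(nm, "top_")) {
      sp <- sub("^top_", "", nm)
      if (!sp %in% names(setup$bc$top)) abort_input(sprintf("unknown species in `%s`", nm))
      setup$bc$top[[sp]] <- v
    } else if (startsWith(nm, "bottom_")) {
      sp <- sub("^bottom_", "", nm)
      if (!sp %in% names(setup$bc$bottom) || is.character(setup$bc$bottom[[sp]])) {
        abort_input(sprintf("`%s` is not a fixed-concentration boundary", nm))
      }
      setup$bc$bottom[[sp]] <- v
    } else {
      abort_input(sprintf("unknown free parameter `%s`", nm))
    }
  }
  # re-validate kinetics
  if (!is.null(setup$kinetics)) setup$kinetics <- do.call(kinetic_params, unclass(setup$kinetics))
  setup
}

current_param_values <- function(setup, free) {
  vapply(free, function(nm) {
    if (nm %in% names(setup$kinetics)) setup$kinetics[[nm]]
    else if (nm == "w") setup$transport$w
    else if (startsWith(nm, "D0_")) setup$transport$D0[[sub("^D0_", "", nm)]]
    else if (startsWith(nm, "top_")) setup$bc$top[[sub("^top_", "", nm)]]
    else if (startsWith(nm, "bottom_")) setup$bc$bottom[[sub("^bottom_", "", nm)]]
    else abort_input(sprintf("unknown free parameter `%s`", nm))
  }, numeric(1))
}

# interpolate a converged solution to observation depths (linear between cell
# centers, clamped at the ends)
interp_solution <- function(solution, species, depths) {
  p <- solution$profile
  if (is.null(p[[species]])) abort_input(sprintf("species `%s` not in solution", species))
  stats::approx(p$z_mid, p[[species]], xout = depths, rule = 2)$y
}

#' Weighted sum-of-squares objective against observed profiles
#'
#' \eqn{\sum_{s}\sum_i ((C_{model}(z_i) - C_{obs,i})/\sigma_i)^2}, with the
#' model linearly interpolated from cell centers to observation depths. A
#' forward run that fails to converge contributes a large finite penalty
#' (1e12) so the optimizer steps away from it.
#'
#' @param observed Long tibble with columns `species`, `depth_m`,
#'   `concentration_uM` and optional `sigma_uM` (default 1).
#' @param setup A [model_setup()].
#' @param params Optional named vector of parameter overrides (see
#'   [fit_profiles()] for the vocabulary).
#' @param init Optional warm-start concentrations for the forward solve.
#' @return The objective value, with the forward solution attached as
#'   attribute `"solution"`.
#' @export
profile_objective <- function(observed, setup, params = NULL, init = NULL) {
  validate_observed(observed, grid_extent(setup$grid))
  if (!is.null(params) && length(params)) setup <- apply_params(setup, as.list(params))
  sol <- solve_setup(setup, init = init)
  if (!sol$converged) {
    out <- 1e12
    attr(out, "solution") <- sol
    return(out)
  }
  sigma <- observed[["sigma_uM"]] %||% rep(1, nrow(observed))
  resid <- vapply(seq_len(nrow(observed)), function(i) {
    m <- interp_solution(sol, observed$species[i], observed$depth_m[i])
    (m - observed$concentration_uM[i]) / sigma[i]
  }, numeric(1))
  out <- sum(resid^2)
  attr(out, "solution") <- sol
  out
}

validate_observed <- function(observed, L) {
  for (nm in c("species", "depth_m", "concentration_uM")) {
    if (is.null(observed[[nm]])) {
      abort_input(sprintf("observed profiles must contain column `%s`", nm))
    }
  }
  if (any(observed$depth_m < 0 | observed$depth_m > L)) {
    abort_input("observation depths fall outside the model extent")
  }
  if (!is.null(observed[["sigma_uM"]]) && any(observed[["sigma_uM"]] <= 0)) {
    abort_input("`sigma_uM` must be > 0")
  }
  invisible(observed)
}

#' Fit model parameters to observed profiles
#'
#' Bounded derivative-free minimization of [profile_objective()] by
#' Nelder-Mead simplex search on transformed coordinates (log scale for
#' strictly positive bounds), with deterministic seeded restarts from
#' perturbed starting points. Forward runs are warm-started from the best
#' solution found so far.
#'
#' @inheritParams profile_objective
#' @param free Character vector of free parameter names: any kinetic
#'   parameter, `"w"`, `"D0_<species>"`, `"top_<species>"` or
#'   `"bottom_<species>"`. At most 6; more than 3 triggers an
#'   identifiability warning.
#' @param lower,upper Named (or positionally matched) finite bounds.
#' @param start Optional named starting values (default: the setup's current
#'   values). Must lie inside the bounds.
#' @param seed Integer seed for the restart perturbations.
#' @param n_restarts Total number of starts (the given start plus perturbed
#'   copies), default 3.
#' @param optim_control Passed to [stats::optim()] (`maxit`, `reltol`).
#' @return An object of class `nat_fit`: list with `par` (fitted values),
#'   `objective`, `converged`, `n_forward_evaluations`, `residuals` (tibble of
#'   per-observation model values and weighted residuals), `free`, `bounds`,
#'   `seed`.
#' @export
fit_profiles <- function(observed, setup, free, lower, upper, start = NULL,
                         seed = 1, n_restarts = 3,
                         optim_control = list(maxit = 500, reltol = 1e-12)) {
  if (length(free) > 6) abort_input("at most 6 free parameters are supported")
  if (length(free) > 3) {
    rlang::warn("more than 3 free parameters: check identifiability")
  }
  lower <- stats::setNames(rep_len(lower, length(free)), free)
  upper <- stats::setNames(rep_len(upper, length(free)), free)
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower >= upper)) {
    abort_input("bounds must be finite with lower < upper")
  }
  start <- if (is.null(start)) current_param_values(setup, free) else
    stats::setNames(rep_len(start, length(free)), free)[free]
  if (any(start < lower | start > upper)) {
    bad <- free[start < lower | start > upper]
    abort_input(paste0("starting value outside bounds for: ",
                       paste(bad, collapse = ", ")))
  }
  validate_observed(observed, grid_extent(setup$grid))

  # coordinate transform: sin^2 mapping onto [lo, hi], on the log scale where
  # the bounds allow it
  use_log <- lower > 0
  to_internal <- function(p) {
    lo <- ifelse(use_log, log(lower), lower)
    hi <- ifelse(use_log, log(upper), upper)
    v <- ifelse(use_log, log(p), p)
    asin(sqrt(pmin(pmax((v - lo) / (hi - lo), 0), 1)))
  }
  from_internal <- function(y) {
    lo <- ifelse(use_log, log(lower), lower)
    hi <- ifelse(use_log, log(upper), upper)
    v <- lo + (hi - lo) * sin(y)^2
    stats::setNames(ifelse(use_log, exp(v), v), free)
  }

  n_eval <- 0L
  warm <- new.env(parent = emptyenv())
  warm$cm <- NULL
  fn <- function(y) {
    p <- from_internal(y)
    n_eval <<- n_eval + 1L
    val <- profile_objective(observed, setup, params = p, init = warm$cm)
    sol <- attr(val, "solution")
    if (sol$converged) {
      warm$cm <- as.matrix(as.data.frame(sol$profile)[, sol$species, drop = FALSE])
    }
    as.numeric(val)
  }

  starts <- list(start)
  if (n_restarts > 1) {
    perturb <- with_seed(seed, lapply(seq_len(n_restarts - 1), function(i) {
      f <- exp(stats::runif(length(free), -0.4, 0.4))
      pmin(pmax(start * f, lower * 1.0001), upper * 0.9999)
    }))
    starts <- c(starts, perturb)
  }

  best <- NULL
  if (length(free) == 1L) {
    # one dimension: Brent's method on the bounded internal coordinate
    best <- stats::optim(to_internal(start), fn, method = "Brent",
                         lower = 0, upper = pi / 2,
                         control = list(maxit = optim_control$maxit %||% 500))
  } else {
    for (s in starts) {
      opt <- stats::optim(to_internal(s), fn, method = "Nelder-Mead",
                          control = optim_control)
      if (is.null(best) || opt$value < best$value) best <- opt
    }
  }

  par <- from_internal(best$par)
  final <- profile_objective(observed, setup, params = par, init = warm$cm)
  sol <- attr(final, "solution")
  sigma <- observed[["sigma_uM"]] %||% rep(1, nrow(observed))
  model_vals <- vapply(seq_len(nrow(observed)), function(i) {
    interp_solution(sol, observed$species[i], observed$depth_m[i])
  }, numeric(1))
  wres <- (model_vals - observed$concentration_uM) / sigma
  residuals <- tibble::tibble(
    species = observed$species, depth_m = observed$depth_m,
    observed = observed$concentration_uM, model = model_vals,
    sigma = sigma, weighted_residual = wres
  )

  structure(list(
    par = par, objective = as.numeric(final),
    converged = (best$convergence == 0) && sol$converged,
    n_forward_evaluations = n_eval + 1L,
    residuals = residuals, free = free,
    bounds = tibble::tibble(parameter = free, lower = lower, upper = upper,
                            start = start),
    seed = as.integer(seed), solution = sol
  ), class = "nat_fit")
}

#' @export
print.nat_fit <- function(x, ...) {
  cat("<nat_fit> ", length(x$free), " free parameter(s), objective ",
      format(x$objective, digits = 6), if (x$converged) " (converged)" else
        " (NOT converged)", "\n", sep = "")
  print(tibble::tibble(parameter = names(x$par), estimate = unname(x$par)))
  invisible(x)
}
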