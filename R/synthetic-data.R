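# Seeded generators for synthetic porewater profiles and depth-resolved
# community tables: the test bed standing in for field data.

#' Generate noisy synthetic porewater observations
#'
#' Solves the forward model, interpolates the steady-state profiles to the
#' sampling depths, and adds seeded Gaussian measurement noise truncated at 0
#' (a slight downward bias at near-zero concentrations, documented rather than
#' resampled away).
#'
#' @param setup A [model_setup()] describing the scenario.
#' @param depths Sampling depths, m, within the model extent.
#' @param noise_sd Named numeric vector of noise levels per species (uM for
#'   `noise_type = "absolute"`, a fraction for `"relative"`). Species missing
#'   from the vector get 0.
#' @param seed Integer seed (required).
#' @param noise_type `"absolute"` (uM) or `"relative"` (fraction of the model
#'   value).
#' @param sigma_floor_uM Lower floor for the reported uncertainty column when
#'   relative noise would give a vanishing sigma, uM.
#' @return Long tibble with columns `species`, `depth_m`, `concentration_uM`,
#'   `sigma_uM`, deterministic given `seed`. The noiseless model values are
#'   attached as attribute `"model"` and the forward solution as `"solution"`.
#' @export
generate_observed <- function(setup, depths, noise_sd = 0, seed,
                              noise_type = c("absolute", "relative"),
                              sigma_floor_uM = 0.1) {
  if (missing(seed)) abort_input("`seed` must be given explicitly")
  noise_type <- match.arg(noise_type)
  L <- grid_extent(setup$grid)
  check_nonneg_vector(depths, "depths")
  if (any(depths > L)) abort_input("sampling depths fall outside the model extent")
  sol <- solve_setup(setup)
  if (!sol$converged) {
    rlang::abort(paste0("scenario forward model did not converge (relative residual ",
                        format(sol$residual_norm, digits = 3), ")"),
                 class = c("natzone_numerical_error", "natzone_error"))
  }
  species <- sol$species
  if (length(noise_sd) == 1L && is.null(names(noise_sd))) {
    noise_sd <- stats::setNames(rep(noise_sd, length(species)), species)
  }
  check_nonneg_vector(unname(noise_sd), "noise_sd")

  model <- purrr::map_dfr(species, function(sp) {
    tibble::tibble(species = sp, depth_m = sort(depths),
                   model_uM = interp_solution(sol, sp, sort(depths)))
  })
  sd_vec <- unname(ifelse(is.na(noise_sd[model$species]), 0,
                          noise_sd[model$species]))
  sigma <- if (noise_type == "absolute") {
    rep_len(sd_vec, nrow(model))
  } else {
    pmax(sd_vec * model$model_uM, ifelse(sd_vec > 0, sigma_floor_uM, 0))
  }
  noise <- with_seed(seed, stats::rnorm(nrow(model), 0, ifelse(sigma > 0, sigma, 0)))
  out <- tibble::tibble(
    species = model$species, depth_m = model$depth_m,
    concentration_uM = pmax(model$model_uM + noise, 0),
    sigma_uM = ifelse(sigma > 0, sigma, 1)
  )
  attr(out, "model") <- model
  attr(out, "solution") <- sol
  out
}

#' Specify Gaussian depth niches for synthetic taxa
#'
#' Each taxon's expected relative abundance along depth is a Gaussian bump on
#' a flat background: \eqn{\pi_t(z) = A_t e^{-(z-\mu_t)^2/(2\sigma_t^2)} + b_t},
#' in relative-abundance units.
#'
#' @param taxon Character labels.
#' @param A Peak amplitudes (> 0), relative-abundance units.
#' @param mu Niche center depths, m.
#' @param sigma Niche widths (> 0), m.
#' @param b Flat backgrounds (>= 0), relative-abundance units.
#' @return A tibble with one row per taxon.
#' @export
taxon_niches <- function(taxon, A, mu, sigma, b = 0) {
  out <- tibble::tibble(taxon = as.character(taxon), A = A, mu = mu,
                        sigma = sigma, b = rep_len(b, length(taxon)))
  if (anyDuplicated(out$taxon)) abort_input("duplicate taxon labels")
  if (any(out$A <= 0) || any(out$sigma <= 0) || any(out$b < 0)) {
    abort_input("need A > 0, sigma > 0, b >= 0")
  }
  out
}

#' Generate a synthetic depth-resolved community table
#'
#' Expected proportions per depth follow the Gaussian niches, with a residual
#' `"other"` taxon absorbing the remaining probability; the observed table is
#' a multinomial draw of `n_reads` reads per depth divided by `n_reads`
#' (compositional amplicon-style noise). Per-depth abundances sum to 1
#' exactly.
#'
#' @param depths Sampled depths, m.
#' @param niches A [taxon_niches()] tibble.
#' @param n_reads Reads per sample (>= 1).
#' @param seed Integer seed (required).
#' @return Long tibble with columns `taxon` (including `"other"`), `depth_m`,
#'   `abundance`. Expected proportions are attached as attribute
#'   `"expected"`.
#' @export
generate_community <- function(depths, niches, n_reads, seed) {
  if (missing(seed)) abort_input("`seed` must be given explicitly")
  check_number(n_reads, "n_reads", lower = 1)
  check_nonneg_vector(depths, "depths")
  if (nrow(niches) < 1) abort_input("need at least one taxon")
  depths <- sort(depths)

  expected <- purrr::map_dfr(seq_along(depths), function(i) {
    z <- depths[i]
    pi_t <- niches$A * exp(-(z - niches$mu)^2 / (2 * niches$sigma^2)) + niches$b
    tot <- sum(pi_t)
    if (tot > 1) {
      abort_input(sprintf(
        "expected taxon abundances sum to %.3f > 1 at depth %.3g m; shrink A or b",
        tot, z), class = "natzone_degenerate_composition_error")
    }
    tibble::tibble(taxon = c(niches$taxon, "other"), depth_m = z,
                   expected = c(pi_t, 1 - tot))
  })

  counts <- with_seed(seed, {
    purrr::map_dfr(seq_along(depths), function(i) {
      e <- expected[expected$depth_m == depths[i], ]
      k <- as.integer(stats::rmultinom(1, size = n_reads, prob = e$expected))
      tibble::tibble(taxon = e$taxon, depth_m = depths[i],
                     abundance = k / n_reads)
    })
  })
  attr(counts, "expected") <- expected
  counts
}
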