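# Shared scenario builders. The reference scenario is the packaged
# GS13-CC2-like configuration; coarse variants keep unit tests fast.

ref_setup <- function(n_cells = 400) {
  cfg <- nat_config()
  cfg$grid$n_cells <- n_cells
  setup_from_config(cfg)
}

# single-species transport-only pieces for the closed-form oracles
oracle_parts <- function(L = 1, n = 100, phi0 = 0.8, D0 = 0.02, w = 0,
                         top = 10, bottom = 2) {
  g <- nat_grid(L, n)
  list(grid = g, por = porosity_profile(g, phi0),
       tp = transport_params(D0 = c(A = D0), w = w),
       bc = boundary_conditions(top = c(A = top), bottom = list(A = bottom)))
}

# long profile tibble from a solved network state (for zone detection)
solution_profiles <- function(sol) {
  p <- sol$profile
  dplyr::bind_rows(
    tibble::tibble(depth_m = p$z_mid, species = "NO3", concentration_uM = p$NO3),
    tibble::tibble(depth_m = p$z_mid, species = "NH4", concentration_uM = p$NH4)
  )
}

# observation depths for calibration experiments: dense over the upper
# decimeters (resolving the oxic nitrification layer) and 0.1 m below
calib_depths <- function() {
  c(seq(0.025, 0.575, by = 0.025), seq(0.65, 3.95, by = 0.1))
}

# number of local maxima of a rate profile, ignoring ripples below
# min_frac of the global maximum
n_rate_maxima <- function(r, min_frac = 0.1) {
  idx <- which(diff(sign(diff(r))) == -2) + 1L
  if (r[1] > r[2]) idx <- c(1L, idx)
  n <- length(r)
  if (r[n] > r[n - 1]) idx <- c(idx, n)
  sum(r[idx] >= min_frac * max(r))
}

expect_tbl <- function(x) testthat::expect_s3_class(x, "tbl_df")
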