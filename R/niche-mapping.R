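# Nitrate-ammonium transition zone (NAT) detection and niche-confinement
# statistics for depth-resolved taxon abundances.

#' Detect the nitrate-ammonium transition zone
#'
#' The NAT zone is the depth interval where downward-diffusing nitrate meets
#' upward-diffusing ammonium. It is bracketed by the nitrate penetration depth
#' (deepest depth with NO3 >= `eps_no3`, linearly interpolated at the final
#' down-crossing) and the ammonium appearance depth (shallowest depth with
#' NH4 >= `eps_nh4`, linearly interpolated at the first up-crossing). The
#' thresholds default to 1 uM, a typical porewater detection limit.
#'
#' @param profiles Long tibble of porewater profiles with columns `depth_m`,
#'   `species`, `concentration_uM` (as returned by [read_profiles()] or
#'   [generate_observed()]), containing the two species of interest.
#' @param eps_no3,eps_nh4 Concentration thresholds, uM.
#' @param no3,nh4 Species labels in `profiles` (default `"NO3"`, `"NH4"`).
#' @return A one-row tibble of class `nat_zone` with columns `z_top`,
#'   `z_bottom` (m), `z_no3`, `z_nh4` (the two crossing depths), `eps_no3`,
#'   `eps_nh4`, and `mode` (`"gap"` if the nitrate front lies above the
#'   ammonium front, `"overlap"` otherwise).
#' @details Errors with class `natzone_no_transition_error` when no transition
#'   is resolvable: nitrate below threshold at the surface, ammonium below
#'   threshold at depth, nitrate never dropping below threshold, or ammonium
#'   already present at the surface.
#' @export
detect_nat_zone <- function(profiles, eps_no3 = 1, eps_nh4 = 1,
                            no3 = "NO3", nh4 = "NH4") {
  check_number(eps_no3, "eps_no3", lower = 0, strict_lower = TRUE)
  check_number(eps_nh4, "eps_nh4", lower = 0, strict_lower = TRUE)
  get_prof <- function(sp) {
    p <- profiles[profiles$species == sp, , drop = FALSE]
    if (nrow(p) < 2) {
      abort_input(sprintf("profile `%s` needs at least 2 points", sp))
    }
    p <- p[order(p$depth_m), ]
    if (anyDuplicated(p$depth_m)) {
      abort_input(sprintf("profile `%s` has duplicated depths", sp))
    }
    check_nonneg_vector(p$concentration_uM, sp)
    p
  }
  no_transition <- function(msg) {
    rlang::abort(paste0("no resolvable transition zone: ", msg),
                 class = c("natzone_no_transition_error", "natzone_error"))
  }
  pn <- get_prof(no3)
  pa <- get_prof(nh4)

  if (pn$concentration_uM[1] < eps_no3) {
    no_transition("NO3 below threshold at the shallowest sample")
  }
  if (pa$concentration_uM[nrow(pa)] < eps_nh4) {
    no_transition("NH4 below threshold at the deepest sample")
  }

  # final down-crossing of NO3 through eps_no3
  above <- pn$concentration_uM >= eps_no3
  if (all(above)) no_transition("NO3 never drops below threshold")
  i <- max(which(above))          # deepest point still at/above threshold
  if (i == nrow(pn)) no_transition("NO3 re-crosses threshold at the bottom")
  z_no3 <- interp_crossing(pn$depth_m[i], pn$concentration_uM[i],
                           pn$depth_m[i + 1], pn$concentration_uM[i + 1],
                           eps_no3)

  # first up-crossing of NH4 through eps_nh4
  above_a <- pa$concentration_uM >= eps_nh4
  j <- min(which(above_a))        # shallowest point at/above threshold
  if (j == 1) {
    if (pa$concentration_uM[1] > eps_nh4) {
      no_transition("NH4 already above threshold at the shallowest sample")
    }
    z_nh4 <- pa$depth_m[1]
  } else {
    z_nh4 <- interp_crossing(pa$depth_m[j - 1], pa$concentration_uM[j - 1],
                             pa$depth_m[j], pa$concentration_uM[j],
                             eps_nh4)
  }

  out <- tibble::tibble(
    z_top = min(z_no3, z_nh4), z_bottom = max(z_no3, z_nh4),
    z_no3 = z_no3, z_nh4 = z_nh4,
    eps_no3 = eps_no3, eps_nh4 = eps_nh4,
    mode = if (z_nh4 < z_no3) "overlap" else "gap"
  )
  class(out) <- c("nat_zone", class(out))
  out
}

# depth where the linear segment (z1,c1)-(z2,c2) crosses eps
interp_crossing <- function(z1, c1, z2, c2, eps) {
  if (c1 == c2) return(z1)
  z1 + (eps - c1) * (z2 - z1) / (c2 - c1)
}

#' Depth of the maximal reaction rate
#'
#' @param solution A `nat_solution`, or a data frame with columns `z_mid` (or
#'   `depth_m`) and the rate column named by `which`.
#' @param which Rate column, default `"R_amx"` (the anammox rate).
#' @return Center depth (m) of the cell with the maximal rate; ties broken to
#'   the shallowest. Errors with class `natzone_no_active_zone_error` if no
#'   rate is positive.
#' @export
rate_maximum_depth <- function(solution, which = "R_amx") {
  df <- if (inherits(solution, "nat_solution")) solution$profile else solution
  z <- df$z_mid %||% df$depth_m
  r <- df[[which]]
  if (is.null(z) || is.null(r)) {
    abort_input(sprintf("need a depth column and a `%s` column", which))
  }
  if (all(r <= 0)) {
    rlang::abort("no active zone: all rates are zero",
                 class = c("natzone_no_active_zone_error", "natzone_error"))
  }
  ord <- order(z)
  z <- z[ord]; r <- r[ord]
  z[which.max(r)]  # which.max returns the first (shallowest) maximum
}

#' Confinement index of taxon depth distributions to a zone
#'
#' Fraction of a taxon's summed relative abundance that falls at sampled
#' depths inside the zone: \eqn{\sum_{z_i \in zone} a(z_i) / \sum_i a(z_i)}.
#' 1 means the taxon occurs only inside the zone; 0 means never inside.
#'
#' @param abundance Long tibble with columns `taxon`, `depth_m`, `abundance`
#'   (relative abundances in \[0, 1\]), e.g. from [read_abundance_table()] or
#'   [generate_community()].
#' @param zone A `nat_zone` from [detect_nat_zone()] (or any one-row data
#'   frame with `z_top`, `z_bottom`).
#' @param taxa Optional character vector restricting which taxa to score
#'   (default: all).
#' @return Tibble with columns `taxon`, `index`, `total_abundance`,
#'   `n_depths`, `n_in_zone`. Errors if a requested taxon has zero total
#'   abundance.
#' @export
confinement_index <- function(abundance, zone, taxa = NULL) {
  validate_abundance(abundance)
  if (!is.null(taxa)) {
    missing <- setdiff(taxa, unique(abundance$taxon))
    if (length(missing)) {
      abort_input(paste0("taxa not in table: ", paste(missing, collapse = ", ")))
    }
    abundance <- abundance[abundance$taxon %in% taxa, ]
  }
  dplyr::group_by(abundance, .data$taxon) |>
    dplyr::summarise(
      index = confine_frac(.data$abundance, .data$depth_m,
                           zone$z_top, zone$z_bottom, .data$taxon[1]),
      total_abundance = sum(.data$abundance),
      n_depths = dplyr::n(),
      n_in_zone = sum(.data$depth_m >= zone$z_top & .data$depth_m <= zone$z_bottom),
      .groups = "drop"
    )
}

confine_frac <- function(a, z, z_top, z_bottom, label = "taxon") {
  tot <- sum(a)
  if (tot <= 0) {
    rlang::abort(sprintf("confinement index undefined: `%s` has zero total abundance",
                         label),
                 class = c("natzone_undefined_index_error", "natzone_error"))
  }
  sum(a[z >= z_top & z <= z_bottom]) / tot
}

#' Permutation test for niche confinement
#'
#' Tests whether a taxon's depth distribution is more confined to the zone
#' than expected if abundances were exchangeable across sampled depths. The
#' null is generated by permuting the abundance vector over depth labels; the
#' p-value is \eqn{(1 + \#\{index_{perm} \ge index_{obs}\})/(n_{perm} + 1)}.
#' With at most 7 sampled depths all permutations are enumerated exactly
#' (the denominator is then the number of permutations); otherwise `n_perm`
#' seeded Monte-Carlo permutations are drawn.
#'
#' @inheritParams confinement_index
#' @param n_perm Number of Monte-Carlo permutations (default 999).
#' @param seed Integer seed; required, so results are reproducible.
#' @param exhaustive `NULL` (auto: exhaustive when <= 7 depths) or logical.
#' @return Tibble of class `nat_confinement` with columns `taxon`, `index`,
#'   `p_value`, `n_permutations`, `method` (`"exhaustive"` or
#'   `"monte_carlo"`), `seed`. `p_value >= 1/(n_permutations + 1)` always.
#' @export
confinement_test <- function(abundance, zone, taxa = NULL, n_perm = 999,
                             seed, exhaustive = NULL) {
  if (missing(seed)) abort_input("`seed` must be given explicitly")
  check_number(n_perm, "n_perm", lower = 1)
  validate_abundance(abundance)
  idx <- confinement_index(abundance, zone, taxa)

  res <- purrr::map_dfr(idx$taxon, function(tx) {
    sub <- abundance[abundance$taxon == tx, ]
    sub <- sub[order(sub$depth_m), ]
    a <- sub$abundance
    in_zone <- sub$depth_m >= zone$z_top & sub$depth_m <= zone$z_bottom
    n <- length(a)
    if (n < 2) abort_input("need at least 2 sampled depths for a permutation test")
    obs <- sum(a[in_zone]) / sum(a)
    use_exhaustive <- exhaustive %||% (n <= 7)
    if (use_exhaustive) {
      perms <- all_permutations(n)
      # index under permutation p: sum over in-zone positions of permuted a
      stat <- (matrix(a[perms], nrow(perms), n)[, in_zone, drop = FALSE] |>
                 rowSums()) / sum(a)
      n_eff <- nrow(perms)
      p <- (1 + sum(stat >= obs - 1e-12)) / (n_eff + 1)
      method <- "exhaustive"
    } else {
      stat <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
        ap <- sample(a)
        sum(ap[in_zone]) / sum(ap)
      }, numeric(1)))
      n_eff <- n_perm
      p <- (1 + sum(stat >= obs - 1e-12)) / (n_perm + 1)
      method <- "monte_carlo"
    }
    tibble::tibble(taxon = tx, index = obs, p_value = p,
                   n_permutations = as.integer(n_eff), method = method,
                   seed = as.integer(seed))
  })
  class(res) <- c("nat_confinement", class(res))
  res
}

# all permutations of 1..n as a (n! x n) integer matrix; n <= 7 in practice
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out[row:(row + nrow(sub) - 1L), ] <- cbind(k, matrix(rest[sub], nrow(sub)))
    row <- row + nrow(sub)
  }
  out
}

validate_abundance <- function(abundance) {
  for (nm in c("taxon", "depth_m", "abundance")) {
    if (is.null(abundance[[nm]])) {
      abort_input(sprintf("abundance table must contain column `%s`", nm))
    }
  }
  check_nonneg_vector(abundance$abundance, "abundance")
  invisible(abundance)
}
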