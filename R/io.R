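# Readers/writers for profile, abundance and config files, and the packaged
# reference scenario. All tabular output is plain delimited text with numbers
# serialized at 15 significant digits, so writer/reader pairs round-trip
# bit-identically for values representable at that precision.

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read porewater profiles from delimited text
#'
#' Expects a comma- or tab-delimited file (auto-detected) with header columns
#' `depth_m`, `species`, `concentration_uM` and optional `sigma_uM`.
#'
#' @param path File path.
#' @return Long tibble ordered by species then depth.
#' @export
read_profiles <- function(path) {
  delim <- detect_delim(path)
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  required <- c("depth_m", "species", "concentration_uM")
  for (nm in required) {
    if (!nm %in% names(df)) {
      abort_input(sprintf("profile file is missing required column `%s`", nm),
                  class = "natzone_format_error")
    }
  }
  if (!is.numeric(df$depth_m) || anyNA(df$depth_m)) {
    abort_input("`depth_m` must be numeric", class = "natzone_format_error")
  }
  bad <- which(!is.finite(df$concentration_uM) | df$concentration_uM < 0)
  if (length(bad)) {
    abort_input(sprintf("negative or non-numeric concentration at row %d", bad[1]))
  }
  keep <- c("species", "depth_m", "concentration_uM",
            intersect("sigma_uM", names(df)))
  df <- df[keep]
  df[order(df$species, df$depth_m), ]
}

#' Write porewater profiles to delimited text
#'
#' @param profiles Long tibble with columns `depth_m`, `species`,
#'   `concentration_uM` and optional `sigma_uM`.
#' @param path Output path; extension `.tsv` selects tab delimiting,
#'   otherwise comma.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  cols <- c("depth_m", "species", "concentration_uM",
            intersect("sigma_uM", names(profiles)))
  out <- profiles[cols]
  for (nm in setdiff(cols, "species")) out[[nm]] <- format_num(out[[nm]])
  readr::write_delim(out, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Read a taxa-by-depth relative abundance table
#'
#' Wide format: first column holds taxon labels, remaining column headers are
#' sample depths in meters.
#'
#' @param path File path (comma- or tab-delimited, auto-detected).
#' @return Long tibble with columns `taxon`, `depth_m`, `abundance`.
#' @export
read_abundance_table <- function(path) {
  delim <- detect_delim(path)
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  if (ncol(df) < 2) abort_input("abundance table needs a taxon column plus depth columns",
                                class = "natzone_format_error")
  taxa <- as.character(df[[1]])
  if (anyDuplicated(taxa)) {
    abort_input(paste0("duplicate taxon labels: ",
                       paste(unique(taxa[duplicated(taxa)]), collapse = ", ")))
  }
  depths <- suppressWarnings(as.numeric(names(df)[-1]))
  if (anyNA(depths)) {
    abort_input("abundance column headers must be depths in meters",
                class = "natzone_format_error")
  }
  for (j in 2:ncol(df)) {
    v <- df[[j]]
    if (!is.numeric(v)) {
      abort_input(sprintf("non-numeric abundance in column `%s`", names(df)[j]))
    }
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad)) {
      abort_input(sprintf("invalid abundance at row %d, column `%s`",
                          bad[1], names(df)[j]))
    }
  }
  tidyr::pivot_longer(
    dplyr::rename(df, taxon = 1), -"taxon",
    names_to = "depth_m", values_to = "abundance",
    names_transform = list(depth_m = as.numeric)
  )
}

#' Write a taxa-by-depth relative abundance table
#'
#' @param abundance Long tibble with columns `taxon`, `depth_m`, `abundance`.
#' @param path Output path; `.tsv` selects tab delimiting, otherwise comma.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(abundance, path) {
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  wide <- tidyr::pivot_wider(
    abundance[c("taxon", "depth_m", "abundance")],
    names_from = "depth_m", values_from = "abundance"
  )
  names(wide)[-1] <- format_num(as.numeric(names(wide)[-1]))
  for (j in 2:ncol(wide)) wide[[j]] <- format_num(wide[[j]])
  readr::write_delim(wide, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Default configuration document
#'
#' Returns the fully-defaulted nested configuration: the packaged
#' "GS13-CC2-like" reference scenario, a 4 m column on 400 uniform cells whose
#' steady state reproduces the qualitative pattern of the target core (oxygen
#' depleted within decimeters, nitrate penetrating to about 2 m, ammonium
#' rising below, with the nitrate-ammonium transition around 2.3 m). Every
#' parameter has a default, so a config file needs to list only overrides.
#'
#' @return Nested named list of class `nat_config`.
#' @export
nat_config <- function() {
  kp <- unclass(kinetic_params())
  tp <- transport_params()
  structure(list(
    grid = list(L = 4, n_cells = 400, spacing = "uniform", ratio = 1),
    porosity = list(phi0 = 0.75, phi_inf = 0.75, lambda = Inf),
    transport = list(D0 = as.list(tp$D0), w = tp$w),
    kinetics = kp,
    boundary = list(
      top = list(O2 = 250, NO3 = 15, NH4 = 0),
      bottom = list(O2 = "zero_gradient", NO3 = "zero_gradient", NH4 = 50)
    ),
    solver = unclass(solver_control()),
    nat = list(eps_no3 = 1, eps_nh4 = 1),
    fit = list(free = character(0), lower = numeric(0), upper = numeric(0),
               start = numeric(0), seed = 1, n_restarts = 3, maxit = 500),
    synthetic = list(
      depths = seq(0.05, 3.95, by = 0.1),
      noise_type = "relative",
      noise_sd = list(O2 = 0.05, NO3 = 0.05, NH4 = 0.05),
      seed = 42,
      community = list(
        n_reads = 50000,
        seed = 43,
        niches = list(
          list(taxon = "Ca_Bathyanammoxibiaceae_like", A = 0.074, mu = 2.2,
               sigma = 0.12, b = 0),
          list(taxon = "Ca_Subterrananammoxibiaceae_like", A = 0.006, mu = 2.2,
               sigma = 0.08, b = 0),
          list(taxon = "Ca_Scalinduaceae_like", A = 0.003, mu = 2.2,
               sigma = 0.15, b = 0),
          list(taxon = "background_like", A = 1e-4, mu = 2, sigma = 1, b = 0.01)
        )
      )
    )
  ), class = "nat_config")
}

merge_config <- function(defaults, user, path = character(0)) {
  for (nm in names(user)) {
    here <- paste(c(path, nm), collapse = "$")
    if (!nm %in% names(defaults)) {
      abort_input(sprintf("unknown configuration key `%s`", here))
    }
    d <- defaults[[nm]]
    u <- user[[nm]]
    if (is.list(d) && !is.null(names(d)) && is.list(u) && nm != "niches") {
      defaults[[nm]] <- merge_config(d, u, c(path, nm))
    } else {
      defaults[[nm]] <- u
    }
  }
  defaults
}

#' Read a configuration file
#'
#' YAML document of overrides merged over [nat_config()] defaults; unknown
#' keys are rejected with the offending key path.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A `nat_config` list.
#' @export
read_config <- function(path = NULL) {
  cfg <- nat_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (length(user)) cfg <- structure(merge_config(unclass(cfg), user),
                                       class = "nat_config")
  }
  cfg
}

#' Write a configuration document as YAML
#'
#' @param cfg A `nat_config` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' Build a forward-model setup from a configuration
#'
#' @param cfg A `nat_config` list (see [nat_config()], [read_config()]).
#' @return A [model_setup()] object.
#' @export
setup_from_config <- function(cfg) {
  g <- nat_grid(cfg$grid$L, cfg$grid$n_cells, cfg$grid$spacing, cfg$grid$ratio)
  lam <- cfg$porosity$lambda
  if (is.null(lam) || (is.character(lam) && lam %in% c("Inf", ".inf"))) lam <- Inf
  por <- porosity_profile(g, cfg$porosity$phi0, cfg$porosity$phi_inf, lam)
  tp <- transport_params(D0 = unlist(cfg$transport$D0), w = cfg$transport$w)
  kp <- do.call(kinetic_params, cfg$kinetics)
  bc <- boundary_conditions(top = unlist(cfg$boundary$top),
                            bottom = cfg$boundary$bottom)
  ctl <- do.call(solver_control, cfg$solver)
  model_setup(g, por, tp, kp, bc, ctl)
}

#' Write / read a detected zone record
#'
#' One-row delimited file with the `nat_zone` fields; the writer/reader pair
#' round-trips exactly at 15 significant digits.
#'
#' @param zone A `nat_zone` tibble from [detect_nat_zone()].
#' @param path File path (`.tsv` for tab delimiting, otherwise comma).
#' @return `path` (writer) or a `nat_zone` tibble (reader).
#' @export
write_zone <- function(zone, path) {
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  out <- tibble::as_tibble(zone)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], format_num)
  readr::write_delim(out, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' @rdname write_zone
#' @export
read_zone <- function(path) {
  df <- readr::read_delim(path, delim = detect_delim(path),
                          show_col_types = FALSE, progress = FALSE)
  for (nm in c("z_top", "z_bottom")) {
    if (!nm %in% names(df)) {
      abort_input(sprintf("zone file is missing column `%s`", nm),
                  class = "natzone_format_error")
    }
  }
  class(df) <- c("nat_zone", class(df))
  df
}

#' Path of the packaged reference scenario config
#'
#' @return Path to the `gs13cc2_like.yaml` fixture inside the installed
#'   package.
#' @export
reference_config_path <- function() {
  system.file("extdata", "gs13cc2_like.yaml", package = "natzone",
              mustWork = TRUE)
}
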