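## Conversion parameter registry. Parameters ship as packaged CSV files
## (one source of truth, auditable by diffing a single file) and are loaded
## into a typed registry used by every estimator.

#' Load the packaged conversion parameter registry
#'
#' The registry bundles (i) per-species, per-stratum biomass expansion
#' factors `BEF`, root-to-shoot ratios `R`, basic wood density `D` (t/m3)
#' and carbon fraction `CF` for the seven arbor species groups, including a
#' pooled `total` stratum used by the age-independent method; (ii) the
#' per-species linear biomass-volume coefficients `(a, b)` of `B = aV + b`;
#' (iii) the fixed volume conversion constants (biomass expansion
#' coefficient 1.90, volumetric density 0.5, carbon content factor 0.5);
#' and (iv) mean per-hectare biomass and carbon fraction for economic
#' forests (23.7 t/hm2, 0.47) and shrubland (19.76 t/hm2, 0.47).
#'
#' @return An object of class `forcarb_registry`: a list with elements
#'   `species_params`, `biomass_equations`, `volume_constants`,
#'   `area_params`.
#' @export
default_registry <- function() {
  reg <- list(
    species_params = readr::read_csv(forcarb_file("species_parameters.csv"),
                                     show_col_types = FALSE, progress = FALSE),
    biomass_equations = readr::read_csv(forcarb_file("biomass_equations.csv"),
                                        show_col_types = FALSE, progress = FALSE),
    volume_constants = local({
      k <- readr::read_csv(forcarb_file("volume_conversion_constants.csv"),
                           show_col_types = FALSE, progress = FALSE)
      as.list(setNames(k$value, k$constant))
    }),
    area_params = readr::read_csv(forcarb_file("area_based_parameters.csv"),
                                  show_col_types = FALSE, progress = FALSE)
  )
  class(reg) <- "forcarb_registry"
  validate_registry(reg)
}

validate_registry <- function(reg) {
  sp <- reg$species_params
  if (any(sp$BEF <= 0) || any(sp$R <= 0) || any(sp$D <= 0)) {
    abort("Species parameters BEF, R and D must be strictly positive.")
  }
  if (any(sp$CF <= 0 | sp$CF >= 1)) {
    abort("Carbon fractions CF must lie strictly between 0 and 1.")
  }
  const_dcf <- dplyr::summarise(
    dplyr::group_by(sp, .data$species),
    d_ok = dplyr::n_distinct(.data$D) == 1,
    cf_ok = dplyr::n_distinct(.data$CF) == 1, .groups = "drop")
  if (!all(const_dcf$d_ok & const_dcf$cf_ok)) {
    abort("D and CF must be constant across strata within a species.")
  }
  if (any(reg$biomass_equations$a <= 0)) {
    abort("Biomass equation slopes `a` must be strictly positive.")
  }
  if (any(unlist(reg$volume_constants) <= 0)) {
    abort("Volume conversion constants must be strictly positive.")
  }
  ap <- reg$area_params
  if (any(ap$mean_biomass_t_per_hm2 <= 0) || any(ap$CF <= 0 | ap$CF >= 1)) {
    abort("Area-based parameters out of range.")
  }
  reg
}

#' Look up conversion parameters for a species and stratum
#'
#' @param species One of the seven arbor species tokens.
#' @param stratum An age group (`young`, `middle_aged`, `near_mature`,
#'   `mature`) or `total` for the pooled row used by the age-independent
#'   biomass expansion factor method.
#' @param registry A `forcarb_registry`.
#' @return A one-row tibble with `species`, `stratum`, `BEF`, `R`, `D`, `CF`.
#' @export
#' @examples
#' get_species_params("P_yunnanensis", "total")
get_species_params <- function(species, stratum, registry = default_registry()) {
  sp <- registry$species_params
  row <- sp[sp$species == species & sp$stratum == stratum, ]
  if (nrow(row) != 1) {
    have <- sp$stratum[sp$species == species]
    if (length(have) == 0) {
      abort(sprintf("Unknown species `%s`; known: %s.", species,
                    paste(unique(sp$species), collapse = ", ")))
    }
    abort(sprintf("No stratum `%s` for species `%s`; available: %s.",
                  stratum, species, paste(have, collapse = ", ")))
  }
  row
}

#' Look up the linear biomass-volume equation for an arbor species
#'
#' @param species One of the seven arbor species tokens.
#' @param registry A `forcarb_registry`.
#' @return A one-row tibble with `species`, `a` (t/m3), `b` (t) of
#'   `B = aV + b`.
#' @export
#' @examples
#' get_biomass_equation("P_yunnanensis")
get_biomass_equation <- function(species, registry = default_registry()) {
  eq <- registry$biomass_equations
  row <- eq[eq$species == species, ]
  if (nrow(row) != 1) {
    abort(sprintf("No biomass equation for species `%s`; supported: %s.",
                  species, paste(eq$species, collapse = ", ")))
  }
  row
}

#' Apply overrides to a parameter registry
#'
#' Replaces selected registry cells and re-validates every invariant, so an
#' override that would make a carbon fraction leave (0, 1) or a slope go
#' non-positive is rejected.
#'
#' @param registry A `forcarb_registry` to start from.
#' @param species_params Optional data frame with columns
#'   `species`, `stratum` and any of `BEF`, `R`, `D`, `CF`; matching rows
#'   are replaced cell-wise.
#' @param biomass_equations Optional data frame with `species` and `a`/`b`.
#' @param volume_constants Optional named list with any of `delta`, `rho`,
#'   `gamma`.
#' @param area_params Optional data frame with `vegetation_type` and any of
#'   `mean_biomass_t_per_hm2`, `CF`.
#' @return The amended, validated `forcarb_registry`.
#' @export
load_registry_overrides <- function(registry = default_registry(),
                                    species_params = NULL,
                                    biomass_equations = NULL,
                                    volume_constants = NULL,
                                    area_params = NULL) {
  patch_rows <- function(base, patch, keys) {
    if (is.null(patch)) return(base)
    patch <- tibble::as_tibble(patch)
    bad <- setdiff(names(patch), names(base))
    if (length(bad) > 0) {
      abort(sprintf("Unknown override column(s): %s.", paste(bad, collapse = ", ")))
    }
    idx <- match(do.call(paste, base[keys]), do.call(paste, patch[keys]))
    for (col in setdiff(names(patch), keys)) {
      hit <- !is.na(idx) & !is.na(patch[[col]][idx])
      base[[col]][hit] <- patch[[col]][idx][hit]
    }
    base
  }
  registry$species_params <- patch_rows(registry$species_params,
                                        species_params, c("species", "stratum"))
  registry$biomass_equations <- patch_rows(registry$biomass_equations,
                                           biomass_equations, "species")
  registry$area_params <- patch_rows(registry$area_params,
                                     area_params, "vegetation_type")
  if (!is.null(volume_constants)) {
    bad <- setdiff(names(volume_constants), c("delta", "rho", "gamma"))
    if (length(bad) > 0) {
      abort(sprintf("Unknown volume constant(s): %s.", paste(bad, collapse = ", ")))
    }
    registry$volume_constants[names(volume_constants)] <- volume_constants
  }
  validate_registry(registry)
}

#' 2019 average transaction prices of China's eight carbon trading pilots
#'
#' @return A tibble with columns `market` and `price_cny_per_tco2e`.
#' @export
pilot_prices <- function() {
  readr::read_csv(forcarb_file("pilot_prices_2019.csv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' @export
print.forcarb_registry <- function(x, ...) {
  cat("<forcarb_registry>\n")
  cat(sprintf("  species_params: %d rows (%d species x strata)\n",
              nrow(x$species_params), dplyr::n_distinct(x$species_params$species)))
  cat(sprintf("  biomass_equations: %d species\n", nrow(x$biomass_equations)))
  cat(sprintf("  volume_constants: delta=%.2f rho=%.2f gamma=%.2f\n",
              x$volume_constants$delta, x$volume_constants$rho,
              x$volume_constants$gamma))
  cat(sprintf("  area_params: %s\n",
              paste(sprintf("%s %.2f t/hm2 (CF %.2f)", x$area_params$vegetation_type,
                            x$area_params$mean_biomass_t_per_hm2, x$area_params$CF),
                    collapse = "; ")))
  invisible(x)
}
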