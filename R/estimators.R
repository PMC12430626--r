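## Volume-to-carbon estimators. Four methods for the arbor layer plus the
## mean-biomass area method for economic forests and shrubland. All methods
## share the same inventory and return the same stock-table shape so they
## can be compared like for like.

ARBOR_METHODS <- c("variable_bef", "bef", "volume_conversion", "continuous_bcf")

# assemble the grouped stock table from per-record contributions
aggregate_stock <- function(tab, by, method) {
  out <- tab |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by %||% character()))) |>
    dplyr::summarise(area_hm2 = sum(.data$area_hm2),
                     carbon_tC = sum(.data$carbon_tC),
                     .groups = "drop") |>
    dplyr::mutate(method = method,
                  density_tC_per_hm2 = ifelse(.data$area_hm2 > 0,
                                              .data$carbon_tC / .data$area_hm2,
                                              NA_real_))
  dplyr::relocate(out, "method")
}

arbor_only <- function(inventory) {
  stopifnot(inherits(inventory, "forcarb_inventory"))
  tab <- tibble::as_tibble(inventory)
  tab[tab$vegetation_type == "arbor", , drop = FALSE]
}

#' Arbor carbon by the age-stratified biomass expansion factor method
#'
#' Per-record carbon is `V x D x BEF(species, age) x (1 + R(species, age))
#' x CF`, with the expansion factor and root-to-shoot ratio specific to the
#' record's species and age group. Economic and shrub records are ignored.
#'
#' @param inventory A `forcarb_inventory`.
#' @param registry A `forcarb_registry`.
#' @param by Grouping columns for the result (subset of `species`,
#'   `age_group`, `zone`, `vegetation_type`); `NULL` for the overall total.
#' @return A stock table: tibble with `method`, grouping columns,
#'   `area_hm2`, `carbon_tC`, `density_tC_per_hm2`.
#' @export
carbon_variable_bef <- function(inventory, registry = default_registry(),
                                by = "species") {
  tab <- arbor_only(inventory)
  if (any(tab$age_group == "not_applicable")) {
    bad <- tab$record_id[tab$age_group == "not_applicable"]
    abort(sprintf("Arbor record(s) without age group: %s.",
                  paste(head(bad, 5), collapse = ", ")))
  }
  sp <- registry$species_params
  idx <- match(paste(tab$species, tab$age_group),
               paste(sp$species, sp$stratum))
  if (anyNA(idx)) {
    bad <- tab$record_id[is.na(idx)]
    abort(sprintf("No (species, age_group) parameters for record(s): %s.",
                  paste(head(bad, 5), collapse = ", ")))
  }
  tab$carbon_tC <- tab$volume_m3 * sp$D[idx] * sp$BEF[idx] *
    (1 + sp$R[idx]) * sp$CF[idx]
  aggregate_stock(tab, by, "variable_bef")
}

#' Arbor carbon by the pooled biomass expansion factor method
#'
#' As [carbon_variable_bef()] but without age stratification: every record
#' of a species uses the pooled `total` parameter row.
#'
#' @inheritParams carbon_variable_bef
#' @return A stock table (see [carbon_variable_bef()]).
#' @export
carbon_bef <- function(inventory, registry = default_registry(),
                       by = "species") {
  tab <- arbor_only(inventory)
  sp <- registry$species_params[registry$species_params$stratum == "total", ]
  idx <- match(tab$species, sp$species)
  if (anyNA(idx)) {
    bad <- tab$record_id[is.na(idx)]
    abort(sprintf("No pooled parameters for record(s): %s.",
                  paste(head(bad, 5), collapse = ", ")))
  }
  tab$carbon_tC <- tab$volume_m3 * sp$D[idx] * sp$BEF[idx] *
    (1 + sp$R[idx]) * sp$CF[idx]
  aggregate_stock(tab, by, "bef")
}

#' Arbor carbon by the fixed volume conversion method
#'
#' Species-independent conversion `C = V x delta x rho x gamma` with the
#' biomass expansion coefficient `delta` (default 1.90), volumetric density
#' `rho` (default 0.5) and carbon content factor `gamma` (default 0.5), so
#' under defaults every cubic metre of standing volume carries 0.475 tC.
#'
#' @inheritParams carbon_variable_bef
#' @param constants Named list with `delta`, `rho`, `gamma`; defaults to the
#'   registry's packaged constants.
#' @return A stock table (see [carbon_variable_bef()]).
#' @export
carbon_volume_conversion <- function(inventory, registry = default_registry(),
                                     constants = registry$volume_constants,
                                     by = "species") {
  for (k in c("delta", "rho", "gamma")) {
    stopifnot_scalar_number(constants[[k]], k, positive = TRUE)
  }
  tab <- arbor_only(inventory)
  tab$carbon_tC <- tab$volume_m3 * constants$delta * constants$rho *
    constants$gamma
  aggregate_stock(tab, by, "volume_conversion")
}

#' Arbor carbon by linear biomass-volume functions
#'
#' Biomass per species follows `B = aV + b` with species-specific
#' coefficients; carbon is `B x CF` with the species carbon fraction. The
#' intercept `b` makes the application level matter, so it must be chosen
#' explicitly:
#'
#' * `"species_aggregate"` - `V` is the species-group total volume and the
#'   intercept enters once per species. This matches treating the species
#'   group as the modelled stand. Grouping is restricted to `species` (or
#'   the overall total) because the intercept is not attributable to
#'   individual records.
#' * `"per_record"` - the equation is applied to every sub-compartment, so
#'   the intercept enters once per record; any grouping is available.
#'
#' A species group with zero total volume still contributes `b x CF`; such
#' rows are flagged in the `intercept_only` column.
#'
#' @inheritParams carbon_variable_bef
#' @param application_level `"species_aggregate"` or `"per_record"`
#'   (required; no default).
#' @return A stock table with an extra logical column `intercept_only`.
#' @export
carbon_continuous_bcf <- function(inventory, registry = default_registry(),
                                  application_level, by = "species") {
  if (missing(application_level)) {
    abort(paste("`application_level` must be given explicitly:",
                '"species_aggregate" or "per_record".'))
  }
  application_level <- match.arg(application_level,
                                 c("species_aggregate", "per_record"))
  tab <- arbor_only(inventory)
  eq <- registry$biomass_equations
  sp <- registry$species_params[registry$species_params$stratum == "total", ]
  idx <- match(tab$species, eq$species)
  if (anyNA(idx)) {
    bad <- tab$record_id[is.na(idx)]
    abort(sprintf("No biomass equation for record(s): %s.",
                  paste(head(bad, 5), collapse = ", ")))
  }
  cf <- sp$CF[match(tab$species, sp$species)]
  if (application_level == "per_record") {
    tab$carbon_tC <- (eq$a[idx] * tab$volume_m3 + eq$b[idx]) * cf
    out <- aggregate_stock(tab, by, "continuous_bcf")
    out$intercept_only <- FALSE
    return(out)
  }
  if (!all(by %in% "species")) {
    abort(paste("With application_level = \"species_aggregate\" the intercept",
                "belongs to the species group; group by \"species\" (or NULL)",
                "or use \"per_record\"."))
  }
  per_species <- tab |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(area_hm2 = sum(.data$area_hm2),
                     volume_m3 = sum(.data$volume_m3), .groups = "drop")
  j <- match(per_species$species, eq$species)
  cfs <- sp$CF[match(per_species$species, sp$species)]
  per_species$carbon_tC <- (eq$a[j] * per_species$volume_m3 + eq$b[j]) * cfs
  per_species$intercept_only <- per_species$volume_m3 == 0
  out <- aggregate_stock(per_species, by, "continuous_bcf")
  flags <- per_species |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by %||% character()))) |>
    dplyr::summarise(intercept_only = all(.data$intercept_only), .groups = "drop")
  if (is.null(by)) out$intercept_only <- flags$intercept_only else
    out <- dplyr::left_join(out, flags, by = by)
  out
}

#' Carbon of economic forests and shrubland by mean per-hectare biomass
#'
#' These vegetation types carry area but no standing volume, so carbon is
#' `area x mean biomass x CF` with type-specific mean biomass (23.7 t/hm2
#' economic, 19.76 t/hm2 shrub) and carbon fraction 0.47.
#'
#' @inheritParams carbon_variable_bef
#' @param by Grouping columns (subset of `vegetation_type`, `zone`);
#'   default by vegetation type.
#' @return A stock table (see [carbon_variable_bef()]).
#' @export
carbon_area_based <- function(inventory, registry = default_registry(),
                              by = "vegetation_type") {
  stopifnot(inherits(inventory, "forcarb_inventory"))
  tab <- tibble::as_tibble(inventory)
  tab <- tab[tab$vegetation_type %in% c("economic", "shrub"), , drop = FALSE]
  ap <- registry$area_params
  idx <- match(tab$vegetation_type, ap$vegetation_type)
  tab$carbon_tC <- tab$area_hm2 * ap$mean_biomass_t_per_hm2[idx] * ap$CF[idx]
  aggregate_stock(tab, by, "area_based")
}

#' Carbon density of stock-table groups
#'
#' Recomputes `density_tC_per_hm2 = carbon_tC / area_hm2` for each row and
#' checks consistency: a group with zero area but positive carbon is an
#' inconsistency and raises an error.
#'
#' @param stock A stock table (output of a `carbon_*` estimator or a sum of
#'   such tables).
#' @return The stock table with a fresh `density_tC_per_hm2` column.
#' @export
carbon_density <- function(stock) {
  bad <- stock$area_hm2 <= 0 & stock$carbon_tC > 0
  if (any(bad)) {
    abort(sprintf("%d group(s) have positive carbon over zero area.", sum(bad)))
  }
  stock$density_tC_per_hm2 <- ifelse(stock$area_hm2 > 0,
                                     stock$carbon_tC / stock$area_hm2, NA_real_)
  stock
}

#' Total row of a stock table
#'
#' @param stock A stock table.
#' @return A one-row tibble with `method` (collapsed), `area_hm2`,
#'   `carbon_tC`, `density_tC_per_hm2`.
#' @export
stock_total <- function(stock) {
  tibble::tibble(
    method = paste(unique(stock$method), collapse = "+"),
    area_hm2 = sum(stock$area_hm2),
    carbon_tC = sum(stock$carbon_tC),
    density_tC_per_hm2 = sum(stock$carbon_tC) / sum(stock$area_hm2)
  )
}

#' Whole-vegetation stock table (arbor method + area-based types)
#'
#' Combines one arbor-layer method with the mean-biomass estimates for
#' economic forests and shrubland into a single stock table grouped by
#' vegetation type (arbor optionally split further by species).
#'
#' @inheritParams carbon_variable_bef
#' @param arbor_method One of `"variable_bef"`, `"bef"`,
#'   `"volume_conversion"`, `"continuous_bcf"`.
#' @param split_arbor_by Extra arbor grouping column (e.g. `"species"`,
#'   `"age_group"`, `"zone"`) or `NULL` for one arbor row.
#' @param application_level Passed to [carbon_continuous_bcf()] when that
#'   method is selected.
#' @return A stock table with a `vegetation_type` column (plus the arbor
#'   split column when requested).
#' @export
vegetation_stocks <- function(inventory, registry = default_registry(),
                              arbor_method = "bef", split_arbor_by = NULL,
                              application_level = "species_aggregate") {
  arbor_method <- match.arg(arbor_method, ARBOR_METHODS)
  by <- unique(c("vegetation_type", split_arbor_by))
  arbor <- switch(arbor_method,
    variable_bef = carbon_variable_bef(inventory, registry, by = by),
    bef = carbon_bef(inventory, registry, by = by),
    volume_conversion = carbon_volume_conversion(inventory, registry, by = by),
    continuous_bcf = {
      st <- carbon_continuous_bcf(inventory, registry,
                                  application_level = application_level,
                                  by = setdiff(by, "vegetation_type"))
      st$vegetation_type <- "arbor"
      dplyr::select(st, -dplyr::any_of("intercept_only"))
    })
  areal <- carbon_area_based(inventory, registry,
                             by = intersect(by, c("vegetation_type", "species",
                                                  "age_group", "zone")))
  dplyr::bind_rows(arbor, areal) |>
    dplyr::relocate("method", "vegetation_type")
}
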