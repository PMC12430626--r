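## Inventory data model: one row per sub-compartment, the smallest
## forest-inventory mapping unit with homogeneous stand attributes.

#' Controlled vocabularies of the inventory schema
#'
#' Accepted tokens for the categorical inventory fields. The seven arbor
#' species groups are the dominant species of the study system; economic
#' forests and shrubland are carried as mixed pseudo-species because their
#' inventories record area only.
#'
#' @return A named list of character vectors: `species`, `arbor_species`,
#'   `vegetation_type`, `age_group`, `zone`.
#' @export
inventory_levels <- function() {
  arbor <- c("K_fortunei", "P_armandii", "P_yunnanensis", "C_funebris",
             "Quercus_sp", "E_robusta", "A_cremastogyne")
  list(
    arbor_species = arbor,
    species = c(arbor, "economic_mixed", "shrub_mixed", "none"),
    vegetation_type = c("arbor", "economic", "shrub", "non_stocked"),
    age_group = c("young", "middle_aged", "near_mature", "mature",
                  "not_applicable"),
    zone = c("core", "buffer", "experimental")
  )
}

#' Token synonym table for categorical inventory fields
#'
#' Loads the packaged synonym table mapping free-text source tokens
#' (e.g. `"Pinus yunnanensis"`, `"middle-aged"`) to canonical schema tokens.
#' Matching is case-insensitive after collapsing separators and stripping
#' abbreviation dots.
#'
#' @param path Optional path to a replacement synonym CSV with columns
#'   `field`, `token`, `canonical`.
#' @return A tibble with columns `field`, `token`, `canonical`.
#' @export
inventory_synonyms <- function(path = NULL) {
  path <- path %||% forcarb_file("species_synonyms.csv")
  syn <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("field", "token", "canonical") %in% names(syn))) {
    abort("Synonym table needs columns `field`, `token`, `canonical`.")
  }
  syn$token <- normalize_token(syn$token)
  syn
}

# resolve one categorical column against canonical levels + synonyms;
# returns canonical tokens with NA where unresolvable
resolve_tokens <- function(x, field, synonyms) {
  levels <- inventory_levels()[[field]]
  norm <- normalize_token(x)
  canon_norm <- normalize_token(levels)
  out <- levels[match(norm, canon_norm)]
  syn <- synonyms[synonyms$field == field, ]
  hit <- match(norm, syn$token)
  out[is.na(out) & !is.na(hit)] <- syn$canonical[hit[is.na(out) & !is.na(hit)]]
  out
}

#' Construct an inventory table
#'
#' Builds a validated inventory from per-record vectors. Records violating a
#' schema invariant are dropped and reported in the `problems` attribute
#' (see [inventory_problems()]).
#'
#' Invariants enforced per record: non-negative area and volume; economic
#' and shrub records have `age_group = "not_applicable"`; arbor records have
#' one of the seven arbor species and a real age group; non-stocked records
#' carry zero volume; `record_id` unique.
#'
#' @param records A data frame with columns `record_id`, `compartment_id`,
#'   `vegetation_type`, `species`, `age_group`, `area_hm2`, `volume_m3`,
#'   `zone` (canonical tokens; see [inventory_levels()]).
#' @param provenance Free-text source tag stored with the table.
#' @return A tibble of class `forcarb_inventory` with one row per valid
#'   record, attributes `provenance` and `problems`.
#' @export
as_inventory <- function(records, provenance = "unspecified") {
  required <- c("record_id", "compartment_id", "vegetation_type", "species",
                "age_group", "area_hm2", "volume_m3", "zone")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    abort(sprintf("Missing inventory column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  tab <- tibble::as_tibble(records)[required]
  tab$record_id <- as.character(tab$record_id)
  tab$compartment_id <- as.character(tab$compartment_id)
  tab$area_hm2 <- as.numeric(tab$area_hm2)
  tab$volume_m3 <- as.numeric(tab$volume_m3)

  problems <- check_inventory_rows(tab)
  if (nrow(problems) > 0) {
    tab <- tab[-unique(problems$row), , drop = FALSE]
  }
  structure(tab,
            class = c("forcarb_inventory", class(tibble::tibble())),
            provenance = provenance,
            problems = problems)
}

# row-level invariant checks; returns tibble(row, record_id, field, message)
check_inventory_rows <- function(tab) {
  lv <- inventory_levels()
  out <- list()
  note <- function(rows, field, message) {
    if (any(rows)) {
      out[[length(out) + 1L]] <<- tibble::tibble(
        row = which(rows),
        record_id = tab$record_id[rows],
        field = field, message = message)
    }
  }
  note(is.na(tab$area_hm2) | tab$area_hm2 < 0, "area_hm2",
       "area must be a non-negative number")
  note(is.na(tab$volume_m3) | tab$volume_m3 < 0, "volume_m3",
       "volume must be a non-negative number")
  note(!tab$vegetation_type %in% lv$vegetation_type | is.na(tab$vegetation_type),
       "vegetation_type",
       paste("accepted:", paste(lv$vegetation_type, collapse = ", ")))
  note(!tab$species %in% lv$species | is.na(tab$species), "species",
       paste("accepted:", paste(lv$species, collapse = ", ")))
  note(!tab$age_group %in% lv$age_group | is.na(tab$age_group), "age_group",
       paste("accepted:", paste(lv$age_group, collapse = ", ")))
  note(!tab$zone %in% lv$zone | is.na(tab$zone), "zone",
       paste("accepted:", paste(lv$zone, collapse = ", ")))
  arbor <- !is.na(tab$vegetation_type) & tab$vegetation_type == "arbor"
  note(arbor & !tab$species %in% lv$arbor_species, "species",
       "arbor records need one of the seven arbor species")
  note(arbor & tab$age_group %in% "not_applicable", "age_group",
       "arbor records need a real age group")
  areal <- !is.na(tab$vegetation_type) & tab$vegetation_type %in% c("economic", "shrub")
  note(areal & !tab$age_group %in% "not_applicable", "age_group",
       "economic/shrub records must use age_group not_applicable")
  nonstocked <- !is.na(tab$vegetation_type) & tab$vegetation_type == "non_stocked"
  note(nonstocked & !is.na(tab$volume_m3) & tab$volume_m3 != 0, "volume_m3",
       "non-stocked land must have zero volume")
  note(duplicated(tab$record_id), "record_id", "duplicate record_id")
  if (length(out) == 0) {
    return(tibble::tibble(row = integer(), record_id = character(),
                          field = character(), message = character()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$row)
}

#' Row-level problems recorded while building or reading an inventory
#'
#' @param inventory A `forcarb_inventory`.
#' @return A tibble with columns `row`, `record_id`, `field`, `message`;
#'   zero rows when every source row validated.
#' @export
inventory_problems <- function(inventory) {
  attr(inventory, "problems") %||%
    tibble::tibble(row = integer(), record_id = character(),
                   field = character(), message = character())
}

#' Read a sub-compartment inventory from delimited text
#'
#' Reads a CSV (UTF-8, header row) into a validated inventory. Source
#' headers may differ from the canonical schema: supply `col_map` as a named
#' character vector `c(canonical = "source header", ...)`. Categorical
#' tokens are matched case-insensitively against the canonical levels and
#' the synonym table. Rows that fail a schema invariant are dropped,
#' reported via [inventory_problems()] and a warning.
#'
#' @param source Path to (or connection of) a delimited text file.
#' @param col_map Optional named character vector mapping canonical column
#'   names to source header names.
#' @param synonyms Synonym table, by default [inventory_synonyms()].
#' @param provenance Source tag; defaults to the file path.
#' @return A `forcarb_inventory`.
#' @export
read_inventory <- function(source, col_map = NULL,
                           synonyms = inventory_synonyms(),
                           provenance = NULL) {
  raw <- readr::read_csv(source, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  required <- c("record_id", "compartment_id", "vegetation_type", "species",
                "age_group", "area_hm2", "volume_m3", "zone")
  col_map <- col_map %||% setNames(required, required)
  if (is.null(names(col_map))) names(col_map) <- col_map
  full_map <- setNames(required, required)
  full_map[names(col_map)] <- col_map
  absent <- full_map[!full_map %in% names(raw)]
  if (length(absent) > 0) {
    abort(sprintf("Required column(s) not found in source: %s.",
                  paste(sprintf("%s (mapped from `%s`)", names(absent), absent),
                        collapse = ", ")))
  }
  tab <- setNames(raw[unname(full_map)], names(full_map))
  for (field in c("vegetation_type", "species", "age_group", "zone")) {
    resolved <- resolve_tokens(tab[[field]], field, synonyms)
    keep_raw <- is.na(resolved)  # leave raw token so the validator names it
    resolved[keep_raw] <- tab[[field]][keep_raw]
    tab[[field]] <- resolved
  }
  suppressWarnings({
    tab$area_hm2 <- as.numeric(tab$area_hm2)
    tab$volume_m3 <- as.numeric(tab$volume_m3)
  })
  inv <- as_inventory(tab, provenance = provenance %||%
                        if (is.character(source)) source else "connection")
  problems <- inventory_problems(inv)
  if (nrow(problems) > 0) {
    warn(sprintf("%d inventory row(s) failed validation and were dropped; see inventory_problems().",
                 length(unique(problems$row))))
  }
  inv
}

#' Write an inventory to delimited text
#'
#' Writes the canonical CSV schema so that
#' `read_inventory(write_inventory(x, f))` reproduces `x` field for field.
#'
#' @param inventory A `forcarb_inventory`.
#' @param sink File path to write to.
#' @return `sink`, invisibly.
#' @export
write_inventory <- function(inventory, sink) {
  stopifnot(inherits(inventory, "forcarb_inventory"))
  readr::write_csv(tibble::as_tibble(inventory), sink, progress = FALSE)
  invisible(sink)
}

#' Summarize inventory areas and volumes
#'
#' Sums area and standing volume, optionally grouped. With `by = NULL` the
#' grand totals are returned; group sums are additive (they re-sum to the
#' grand totals).
#'
#' @param inventory A `forcarb_inventory`.
#' @param by Character vector of grouping columns among `vegetation_type`,
#'   `species`, `age_group`, `zone`; `NULL` for grand totals.
#' @return A tibble with the grouping columns plus `n_records`, `area_hm2`,
#'   `volume_m3`.
#' @export
summarize_inventory <- function(inventory, by = NULL) {
  stopifnot(inherits(inventory, "forcarb_inventory"))
  allowed <- c("vegetation_type", "species", "age_group", "zone")
  if (!all(by %in% allowed)) {
    abort(sprintf("`by` must be among: %s.", paste(allowed, collapse = ", ")))
  }
  tibble::as_tibble(inventory) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by %||% character()))) |>
    dplyr::summarise(n_records = dplyr::n(),
                     area_hm2 = sum(.data$area_hm2),
                     volume_m3 = sum(.data$volume_m3),
                     .groups = "drop")
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.forcarb_inventory <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "forcarb_inventory")
  attr(out, "provenance") <- NULL
  attr(out, "problems") <- NULL
  out
}

#' @export
print.forcarb_inventory <- function(x, ...) {
  cat(sprintf("<forcarb_inventory> %d records (source: %s)\n",
              nrow(x), attr(x, "provenance") %||% "unspecified"))
  np <- nrow(inventory_problems(x))
  if (np > 0) cat(sprintf("  %d row problem(s); see inventory_problems()\n", np))
  NextMethod()
}
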