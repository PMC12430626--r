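## Report assembly: stocks, proportions, densities and values per grouping
## dimension, with a grand-total row, rankings and CSV/Markdown emitters.

#' Assemble a stock-and-value report
#'
#' Joins a stock table with its valuations under the market-mean and
#' optimal price schemes into the standard report shape: per group area,
#' carbon, proportion of total carbon, density, the two scheme values,
#' their mean, and mean value per hectare, plus a grand-total row. Rows are
#' sorted by descending carbon.
#'
#' @param stock A stock table whose grouping columns identify the report
#'   rows (e.g. from [vegetation_stocks()] or a `carbon_*` estimator).
#' @param market,optimal `price_scheme` objects; defaults are the packaged
#'   market mean (27.76 CNY/tCO2e) and the optimal-price lower bound
#'   (19.02 CNY/tCO2e).
#' @param group_dimension Columns defining the report rows; defaults to all
#'   grouping columns present in `stock`.
#' @return An object of class `carbon_report`: a tibble with `group`
#'   columns, `area_hm2`, `carbon_tC`, `proportion_pct`,
#'   `density_tC_per_hm2`, `value_market_wan`, `value_optimal_wan`,
#'   `value_mean_wan`, `value_mean_cny_per_hm2`, with the total row in
#'   attribute `total` (also accessible via [report_total()]).
#' @export
build_report <- function(stock,
                         market = market_mean_price(),
                         optimal = optimal_price(10.11),
                         group_dimension = NULL) {
  meta <- c("method", "area_hm2", "carbon_tC", "density_tC_per_hm2",
            "intercept_only")
  group_dimension <- group_dimension %||% setdiff(names(stock), meta)
  missing <- setdiff(group_dimension, names(stock))
  if (length(missing) > 0) {
    abort(sprintf("Grouping dimension(s) absent from stock table: %s.",
                  paste(missing, collapse = ", ")))
  }
  grouped <- stock |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_dimension))) |>
    dplyr::summarise(area_hm2 = sum(.data$area_hm2),
                     carbon_tC = sum(.data$carbon_tC), .groups = "drop") |>
    dplyr::mutate(method = paste(unique(stock$method), collapse = "+"))
  vm <- monetize(grouped, market)
  vo <- monetize(grouped, optimal)
  va <- average_valuation(vm, vo)
  total_c <- sum(grouped$carbon_tC)
  rep <- grouped |>
    dplyr::mutate(
      proportion_pct = 100 * .data$carbon_tC / total_c,
      density_tC_per_hm2 = ifelse(.data$area_hm2 > 0,
                                  .data$carbon_tC / .data$area_hm2, NA_real_),
      value_market_wan = vm$value_wan_cny,
      value_optimal_wan = vo$value_wan_cny,
      value_mean_wan = va$value_wan_cny,
      value_mean_cny_per_hm2 = va$value_cny_per_hm2
    ) |>
    dplyr::select(-"method") |>
    dplyr::arrange(dplyr::desc(.data$carbon_tC))
  total <- tibble::tibble(
    area_hm2 = sum(rep$area_hm2),
    carbon_tC = total_c,
    proportion_pct = 100,
    density_tC_per_hm2 = total_c / sum(rep$area_hm2),
    value_market_wan = sum(rep$value_market_wan),
    value_optimal_wan = sum(rep$value_optimal_wan),
    value_mean_wan = sum(rep$value_mean_wan),
    value_mean_cny_per_hm2 = 1e4 * sum(rep$value_mean_wan) / sum(rep$area_hm2)
  )
  structure(rep, class = c("carbon_report", class(tibble::tibble())),
            total = total, group_dimension = group_dimension,
            schemes = list(market = market, optimal = optimal))
}

#' Grand-total row of a report
#'
#' @param report A `carbon_report`.
#' @return A one-row tibble of column totals.
#' @export
report_total <- function(report) {
  attr(report, "total")
}

#' Rank report groups by a column
#'
#' Strict descending order; ties are broken lexicographically on the group
#' label and flagged.
#'
#' @param report A `carbon_report`.
#' @param by Column to rank on, default `"carbon_tC"`.
#' @return A tibble with `rank`, the group columns, the ranked column and a
#'   logical `tied` flag.
#' @export
ranking <- function(report, by = "carbon_tC") {
  if (nrow(report) == 0) abort("Cannot rank an empty report.")
  if (!by %in% names(report)) {
    abort(sprintf("No column `%s` in report.", by))
  }
  keys <- attr(report, "group_dimension")
  label <- do.call(paste, c(unclass(report)[keys], sep = "/"))
  ord <- order(-report[[by]], label)
  out <- tibble::as_tibble(report)[ord, c(keys, by)]
  out$tied <- duplicated(out[[by]]) | duplicated(out[[by]], fromLast = TRUE)
  dplyr::bind_cols(tibble::tibble(rank = seq_len(nrow(out))), out)
}

#' Write a report as CSV or a Markdown table
#'
#' Numeric presentation is rounded half-up to 2 decimals; the grand-total
#' row is appended with group label `"total"`.
#'
#' @param report A `carbon_report`.
#' @param path Output file path.
#' @param format `"csv"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "markdown")) {
  format <- match.arg(format)
  keys <- attr(report, "group_dimension")
  total <- report_total(report)
  for (k in keys) total[[k]] <- if (k == keys[1]) "total" else ""
  flat <- dplyr::bind_rows(tibble::as_tibble(report), total[c(keys, setdiff(names(total), keys))])
  num <- vapply(flat, is.numeric, logical(1))
  flat[num] <- lapply(flat[num], round_half_up, digits = 2)
  if (format == "csv") {
    readr::write_csv(flat, path, progress = FALSE)
  } else {
    header <- paste0("| ", paste(names(flat), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(flat)), collapse = "|"), "|")
    body <- apply(flat, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    writeLines(c(header, sep, body), path)
  }
  invisible(path)
}

#' @export
print.carbon_report <- function(x, ...) {
  cat(sprintf("<carbon_report> by %s (%d groups)\n",
              paste(attr(x, "group_dimension"), collapse = ", "), nrow(x)))
  NextMethod()
  t <- report_total(x)
  cat(sprintf("total: %.2f hm2, %.2f tC, density %.2f tC/hm2, mean value %.2f wan CNY\n",
              t$area_hm2, t$carbon_tC, t$density_tC_per_hm2, t$value_mean_wan))
  invisible(x)
}
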