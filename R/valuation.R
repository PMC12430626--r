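## Monetization of carbon stocks. Value = 44/12 x C x P, with 44/12 the
## mass conversion from elemental carbon to CO2 and P a price in CNY per
## tonne of CO2 equivalent.

C_TO_CO2 <- 44 / 12

#' Build a price scheme
#'
#' @param price_cny_per_tco2e Unit price in CNY per tonne CO2 equivalent.
#' @param name Scheme label (`"market_mean"`, `"optimal_low"`,
#'   `"optimal_high"`, `"custom"`, or a composite label).
#' @param provenance Free-text description of the components the price was
#'   derived from.
#' @return An object of class `price_scheme`.
#' @export
price_scheme <- function(price_cny_per_tco2e, name = "custom",
                         provenance = "user-supplied") {
  stopifnot_scalar_number(price_cny_per_tco2e, "price_cny_per_tco2e",
                          positive = TRUE)
  structure(list(name = name, price_cny_per_tco2e = price_cny_per_tco2e,
                 provenance = provenance),
            class = "price_scheme")
}

#' Market-mean carbon price from pilot-market prices
#'
#' Arithmetic mean of regional pilot carbon-market transaction prices. With
#' the packaged 2019 prices of China's eight pilot markets the mean is
#' 27.76 CNY/tCO2e.
#'
#' @param prices Numeric vector of positive prices (CNY/tCO2e); defaults to
#'   the packaged eight 2019 pilot prices.
#' @return A `price_scheme` named `"market_mean"`. The stored price is the
#'   2-decimal reported value; the unrounded mean is kept in `provenance`.
#' @export
market_mean_price <- function(prices = pilot_prices()$price_cny_per_tco2e) {
  if (length(prices) == 0) abort("Need at least one pilot price.")
  if (any(!is.finite(prices) | prices <= 0)) {
    abort("All pilot prices must be positive numbers.")
  }
  mean_raw <- mean(prices)
  price_scheme(round_half_up(mean_raw, 2), name = "market_mean",
               provenance = sprintf("mean of %d pilot prices (unrounded %.6f)",
                                    length(prices), mean_raw))
}

#' Carbon price from an optimal (shadow) price in USD per tonne carbon
#'
#' Converts a per-tonne-carbon USD price to CNY per tonne CO2 equivalent:
#' `P = usd_per_tC x 12/44 x exchange`. The 2019 lower bound 10.11 USD/tC
#' at 6.8985 CNY/USD gives 19.02 CNY/tCO2e.
#'
#' @param usd_per_tC Price in USD per tonne of elemental carbon.
#' @param exchange_cny_per_usd Exchange rate, CNY per USD.
#' @param name Scheme label, default `"optimal_low"`.
#' @return A `price_scheme` storing the 2-decimal reported price.
#' @export
optimal_price <- function(usd_per_tC, exchange_cny_per_usd = 6.8985,
                          name = "optimal_low") {
  stopifnot_scalar_number(usd_per_tC, "usd_per_tC", positive = TRUE)
  stopifnot_scalar_number(exchange_cny_per_usd, "exchange_cny_per_usd",
                          positive = TRUE)
  raw <- usd_per_tC / C_TO_CO2 * exchange_cny_per_usd
  price_scheme(round_half_up(raw, 2), name = name,
               provenance = sprintf("%.4f USD/tC x 12/44 x %.4f CNY/USD (unrounded %.6f)",
                                    usd_per_tC, exchange_cny_per_usd, raw))
}

#' Monetize a carbon stock table under a price scheme
#'
#' Per group, value (CNY) is `44/12 x carbon_tC x price`; also reported in
#' units of 10,000 CNY (wan) and per hectare. Full floating precision is
#' kept; round only at presentation.
#'
#' @param stock A stock table (see [carbon_variable_bef()]).
#' @param scheme A `price_scheme`.
#' @return The stock table with columns `scheme`, `price_cny_per_tco2e`,
#'   `value_cny`, `value_wan_cny`, `value_cny_per_hm2`.
#' @export
monetize <- function(stock, scheme) {
  stopifnot(inherits(scheme, "price_scheme"))
  stock$scheme <- scheme$name
  stock$price_cny_per_tco2e <- scheme$price_cny_per_tco2e
  stock$value_cny <- C_TO_CO2 * stock$carbon_tC * scheme$price_cny_per_tco2e
  stock$value_wan_cny <- stock$value_cny / 1e4
  stock$value_cny_per_hm2 <- ifelse(stock$area_hm2 > 0,
                                    stock$value_cny / stock$area_hm2, NA_real_)
  stock
}

#' Average two valuations of the same stocks
#'
#' The final value under the two-scheme convention is the arithmetic mean
#' of the market-mean and optimal-price valuations, which (by linearity)
#' equals monetization at the average price.
#'
#' @param v1,v2 Monetized stock tables (outputs of [monetize()]) over the
#'   same groups and carbon.
#' @return A monetized table with `scheme = "mean(<a>,<b>)"` and averaged
#'   value columns.
#' @export
average_valuation <- function(v1, v2) {
  keys <- setdiff(names(v1), c("method", "scheme", "price_cny_per_tco2e",
                               "value_cny", "value_wan_cny",
                               "value_cny_per_hm2", "area_hm2", "carbon_tC",
                               "density_tC_per_hm2", "intercept_only"))
  a <- dplyr::arrange(v1, dplyr::across(dplyr::all_of(keys)))
  b <- dplyr::arrange(v2, dplyr::across(dplyr::all_of(keys)))
  same_groups <- nrow(a) == nrow(b) &&
    (length(keys) == 0 || identical(a[keys], b[keys]))
  if (!same_groups || max(abs(a$carbon_tC - b$carbon_tC)) > 1e-6 * max(1, max(abs(a$carbon_tC)))) {
    abort("Valuations must cover the same groups and carbon stocks.")
  }
  out <- a
  out$scheme <- sprintf("mean(%s,%s)", a$scheme[1], b$scheme[1])
  out$price_cny_per_tco2e <- (a$price_cny_per_tco2e + b$price_cny_per_tco2e) / 2
  out$value_cny <- (a$value_cny + b$value_cny) / 2
  out$value_wan_cny <- (a$value_wan_cny + b$value_wan_cny) / 2
  out$value_cny_per_hm2 <- (a$value_cny_per_hm2 + b$value_cny_per_hm2) / 2
  out
}

#' @export
print.price_scheme <- function(x, ...) {
  cat(sprintf("<price_scheme> %s: %.2f CNY/tCO2e (%s)\n",
              x$name, x$price_cny_per_tco2e, x$provenance))
  invisible(x)
}
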