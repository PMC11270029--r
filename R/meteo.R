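# Meteorological feature derivation: saturation vapor pressure, relative
# humidity, wind speed, temperature-bin exposures with lags/leads, and
# binary threshold covariates (e.g. a PM10 > 50 ug/m3 pollution flag).

#' Saturation vapor pressure (Magnus-type formula)
#'
#' `E(T) = 6.11 * 10^(7.5 T / (237.7 + T))`, with T in degrees Celsius
#' and the result in hPa (the leading constant 6.11 fixes the unit).
#'
#' @param t Temperature in degrees Celsius; must exceed -237.7.
#' @return Saturation vapor pressure in hPa.
#' @examples
#' saturation_vapor_pressure(0)   # 6.11
#' @export
saturation_vapor_pressure <- function(t) {
  if (any(!is.na(t) & t <= -237.7)) {
    stop("temperature out of formula domain (must exceed -237.7 degrees C)")
  }
  6.11 * 10^((7.5 * t) / (237.7 + t))
}

#' Relative humidity from air and dew-point temperature
#'
#' Ratio of the saturation vapor pressure at the dew point to that at the
#' air temperature, times 100. Bounded by 100 whenever the dew point does
#' not exceed the air temperature.
#'
#' @param t_mean Air temperature, degrees Celsius.
#' @param t_dew Dew-point temperature, degrees Celsius.
#' @return Relative humidity in percent.
#' @examples
#' relative_humidity(15, 15)  # 100
#' @export
relative_humidity <- function(t_mean, t_dew) {
  100 * saturation_vapor_pressure(t_dew) / saturation_vapor_pressure(t_mean)
}

#' Wind speed from u and v components
#'
#' @param u,v Horizontal and vertical wind components, m/s.
#' @return Wind speed in m/s, `sqrt(u^2 + v^2)`.
#' @examples
#' wind_speed(3, 4)  # 5
#' @export
wind_speed <- function(u, v) {
  sqrt(u^2 + v^2)
}

new_bin_scheme <- function(breaks, labels, reference) {
  stopifnot(length(labels) == length(breaks) + 1L,
            !is.unsorted(breaks, strictly = TRUE),
            reference %in% labels, !anyDuplicated(labels))
  structure(list(breaks = as.numeric(breaks),
                 labels = as.character(labels),
                 reference = reference,
                 lower = c(-Inf, breaks),
                 upper = c(breaks, Inf)),
            class = "bin_scheme")
}

#' Temperature bin schemes
#'
#' The main scheme has 10 daily-mean-temperature bins with the 12-18 C
#' comfort zone as reference: `<0; 0-3; 3-6; 6-9; 9-12; 12-18; 18-21;
#' 21-24; 24-27; >27`. The Germany variant, reflecting its milder
#' climate, has 9 bins, identical below 24 C with a single `>24` top
#' bin. Bins are lower-closed/upper-open `[lower, upper)`; the bottom
#' bin is `(-Inf, 0)` and the top bin `[27, Inf)` (or `[24, Inf)`).
#'
#' @param scheme `"full"` (10 bins) or `"germany"` (9 bins).
#' @return A `bin_scheme` object: ordered bins partitioning the real
#'   line, with the comfort-zone reference label.
#' @examples
#' bin_scheme("full")$labels
#' @export
bin_scheme <- function(scheme = c("full", "germany")) {
  scheme <- match.arg(scheme)
  if (scheme == "full") {
    new_bin_scheme(breaks = c(0, 3, 6, 9, 12, 18, 21, 24, 27),
                   labels = c("<0", "0-3", "3-6", "6-9", "9-12", "12-18",
                              "18-21", "21-24", "24-27", ">27"),
                   reference = "12-18")
  } else {
    new_bin_scheme(breaks = c(0, 3, 6, 9, 12, 18, 21, 24),
                   labels = c("<0", "0-3", "3-6", "6-9", "9-12", "12-18",
                              "18-21", "21-24", ">24"),
                   reference = "12-18")
  }
}

#' @export
print.bin_scheme <- function(x, ...) {
  cat(sprintf("<bin_scheme> %d bins, reference \"%s\": %s\n",
              length(x$labels), x$reference, paste(x$labels, collapse = " | ")))
  invisible(x)
}

#' Assign daily mean temperatures to bins
#'
#' Every finite temperature maps to exactly one bin under the
#' lower-closed/upper-open convention, so shared endpoints (e.g. 3 C)
#' fall in the upper bin.
#'
#' @param t Numeric vector of daily mean temperatures, degrees Celsius.
#' @param scheme A [bin_scheme()].
#' @return Factor of bin labels with levels in scheme order.
#' @examples
#' assign_temp_bin(c(15, -5, 27), bin_scheme("full"))
#' @export
assign_temp_bin <- function(t, scheme = bin_scheme("full")) {
  stopifnot(inherits(scheme, "bin_scheme"))
  idx <- findInterval(t, scheme$breaks) + 1L
  factor(scheme$labels[idx], levels = scheme$labels)
}

#' Derive weather features for a city-day table
#'
#' Adds relative humidity, wind speed and the temperature-bin label to a
#' raw weather table. Precipitation is a pass-through control and is not
#' transformed.
#'
#' @param weather data.frame with columns `city`, `date`, `t_mean`,
#'   `t_dew`, `precip`, `u_wind`, `v_wind`.
#' @param scheme A [bin_scheme()].
#' @return The input with `rh`, `wind_speed` and `temp_bin` columns added.
#' @export
derive_weather <- function(weather, scheme = bin_scheme("full")) {
  req <- c("city", "date", "t_mean", "t_dew", "precip", "u_wind", "v_wind")
  missing <- setdiff(req, names(weather))
  if (length(missing)) {
    stop("weather table lacks columns: ", paste(missing, collapse = ", "))
  }
  weather$rh <- relative_humidity(weather$t_mean, weather$t_dew)
  weather$wind_speed <- wind_speed(weather$u_wind, weather$v_wind)
  weather$temp_bin <- assign_temp_bin(weather$t_mean, scheme)
  weather
}

# Column name for an offset: -k -> lag, +k -> lead, 0 -> lag0.
.lag_col_name <- function(k) {
  if (k < 0) paste0("temp_bin_lag", -k)
  else if (k > 0) paste0("temp_bin_lead", k)
  else "temp_bin_lag0"
}

#' Add lagged/lead temperature-bin columns
#'
#' For each offset k, adds a column holding the bin label of `date + k`
#' within the same city (offset -1 = the day before, stored as
#' `temp_bin_lag1`; +1 = the day after, `temp_bin_lead1`). A missing
#' neighbour day yields `NA`, never a silently dropped row.
#'
#' @param weather data.frame with `city`, `date` (Date) and `temp_bin`.
#' @param offsets Integer vector of day offsets.
#' @return The input with one extra factor column per offset.
#' @export
add_exposure_lags <- function(weather, offsets) {
  stopifnot(all(c("city", "date", "temp_bin") %in% names(weather)))
  dates <- as.Date(weather$date)
  key <- paste(weather$city, dates)
  for (k in as.integer(offsets)) {
    idx <- match(paste(weather$city, dates + k), key)
    weather[[.lag_col_name(k)]] <- weather$temp_bin[idx]
  }
  weather
}

#' Binarise a covariate at a threshold
#'
#' Strict exceedance: 1 iff `value > threshold` (used e.g. for a PM10
#' pollution flag at the 50 ug/m3 WHO guideline). Missing values stay
#' missing.
#'
#' @param value Numeric vector.
#' @param threshold Single numeric threshold.
#' @return Integer 0/1 vector with `NA` preserved.
#' @examples
#' binarize_covariate(c(51, 50, 0, NA), 50)
#' @export
binarize_covariate <- function(value, threshold) {
  stopifnot(length(threshold) == 1L, is.finite(threshold))
  out <- as.integer(value > threshold)
  out[is.na(value)] <- NA_integer_
  out
}
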