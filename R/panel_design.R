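# Assembly of the estimation table: outcome, temperature-bin exposure
# dummies against the comfort-zone reference, meteorological controls,
# fixed-effect group labels and cluster labels.

#' Build the fixed-effects estimation design
#'
#' Joins scored speeches to city-day weather features and assembles the
#' regression table for the panel model: the outcome, one 0/1 exposure
#' column per non-reference temperature bin, control columns, the three
#' fixed-effect dimensions (politician, month-by-city, day-of-week) and
#' the cluster labels. Rows that fail to join or lack a required field
#' are dropped with a logged reason, never silently.
#'
#' The month-by-city fixed effect uses calendar month-of-year by default
#' (capturing location-specific seasonality); `month_fe = "year_month"`
#' switches to one effect per calendar month of the sample. The
#' month-by-city *cluster* uses year-month by default (errors correlated
#' within the same city during the same month); `cluster_month`
#' switches that convention independently.
#'
#' @param speeches data.frame with `speech_id`, `speaker_id`, `city`,
#'   `date`, and the outcome column.
#' @param weather data.frame from [derive_weather()] (needs `city`,
#'   `date`, `temp_bin` and the control columns).
#' @param outcome Name of the outcome column in `speeches`
#'   (e.g. `"flesch_kincaid"`).
#' @param controls Character vector of control column names looked up in
#'   the weather table first, then in `speeches`.
#' @param scheme The [bin_scheme()] used to build `weather`.
#' @param month_fe `"month_of_year"` or `"year_month"`.
#' @param cluster `"month_by_city"` or `"politician"`.
#' @param cluster_month Month convention for the month-by-city cluster.
#' @param demographic Optional name of a column in `speeches` holding a
#'   categorical demographic (for [fit_interaction()]).
#' @return A `panel_design` object.
#' @export
build_design <- function(speeches, weather,
                         outcome = "flesch_kincaid",
                         controls = c("precip", "rh", "wind_speed"),
                         scheme = bin_scheme("full"),
                         month_fe = c("month_of_year", "year_month"),
                         cluster = c("month_by_city", "politician"),
                         cluster_month = c("year_month", "month_of_year"),
                         demographic = NULL) {
  month_fe <- match.arg(month_fe)
  cluster <- match.arg(cluster)
  cluster_month <- match.arg(cluster_month)
  stopifnot(is.data.frame(speeches), is.data.frame(weather),
            inherits(scheme, "bin_scheme"))
  req_sp <- c("speech_id", "speaker_id", "city", "date", outcome)
  missing_sp <- setdiff(req_sp, names(speeches))
  if (length(missing_sp)) {
    stop("speeches lack columns: ", paste(missing_sp, collapse = ", "))
  }
  if (!all(c("city", "date", "temp_bin") %in% names(weather))) {
    stop("weather lacks city/date/temp_bin; run derive_weather() first")
  }
  sp_date <- as.Date(speeches$date)
  w_date <- as.Date(weather$date)

  dropped <- data.frame(speech_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  log_drop <- function(ids, reason) {
    if (length(ids)) {
      dropped <<- rbind(dropped, data.frame(speech_id = as.character(ids),
                                            reason = reason,
                                            stringsAsFactors = FALSE))
    }
  }

  j <- match(paste(speeches$city, sp_date), paste(weather$city, w_date))
  unjoined <- is.na(j)
  log_drop(speeches$speech_id[unjoined], "no_weather")

  ctrl_src <- function(nm, rows_sp, rows_w) {
    if (nm %in% names(weather)) weather[[nm]][rows_w]
    else if (nm %in% names(speeches)) speeches[[nm]][rows_sp]
    else stop("control column not found in weather or speeches: ", nm)
  }

  keep <- which(!unjoined)
  jj <- j[keep]
  y <- as.numeric(speeches[[outcome]][keep])
  bins <- weather$temp_bin[jj]
  ctrl <- if (length(controls)) {
    m <- vapply(controls, function(nm) as.numeric(ctrl_src(nm, keep, jj)),
                numeric(length(keep)))
    matrix(m, nrow = length(keep), dimnames = list(NULL, controls))
  } else {
    matrix(numeric(0), nrow = length(keep), ncol = 0)
  }
  demo <- if (!is.null(demographic)) {
    if (!demographic %in% names(speeches)) {
      stop("demographic column not found: ", demographic)
    }
    speeches[[demographic]][keep]
  }

  bad <- is.na(y) | is.na(bins)
  if (ncol(ctrl)) bad <- bad | apply(ctrl, 1L, anyNA)
  log_drop(speeches$speech_id[keep][bad], "missing_field")
  ok <- !bad
  if (!any(ok)) stop("all rows dropped while building the design")
  keep <- keep[ok]
  jj <- jj[ok]
  y <- y[ok]
  bins <- droplevels(bins[ok])
  bins <- factor(as.character(bins), levels = scheme$labels)
  ctrl <- ctrl[ok, , drop = FALSE]
  if (!is.null(demo)) demo <- factor(demo[ok])

  nonref <- setdiff(scheme$labels, scheme$reference)
  present <- nonref[nonref %in% levels(droplevels(bins))]
  expo <- vapply(present, function(lb) as.numeric(bins == lb),
                 numeric(length(y)))
  expo <- matrix(expo, nrow = length(y),
                 dimnames = list(NULL, paste0("bin_", present)))

  date_k <- as.Date(speeches$date[keep])
  city_k <- as.character(speeches$city[keep])
  moy <- format(date_k, "%m")
  ym <- format(date_k, "%Y-%m")
  fe <- list(
    politician = factor(as.character(speeches$speaker_id[keep])),
    month_city = factor(paste(city_k,
                              if (month_fe == "month_of_year") moy else ym,
                              sep = ":")),
    day_of_week = factor(format(date_k, "%u")))
  cl <- if (cluster == "politician") {
    fe$politician
  } else {
    factor(paste(city_k,
                 if (cluster_month == "year_month") ym else moy,
                 sep = ":"))
  }

  structure(list(outcome = y,
                 exposure = expo,
                 controls = ctrl,
                 fe = fe,
                 cluster = cl,
                 row_ids = as.character(speeches$speech_id[keep]),
                 demographic = demo,
                 reference = scheme$reference,
                 bin_levels = nonref,
                 dropped = dropped,
                 meta = list(outcome = outcome, controls = controls,
                             month_fe = month_fe, cluster = cluster,
                             cluster_month = cluster_month,
                             absent_bins = setdiff(nonref, present))),
            class = "panel_design")
}

#' @export
print.panel_design <- function(x, ...) {
  cat(sprintf(
    "<panel_design> N=%d, %d exposure dummies (ref \"%s\"), %d controls\n",
    length(x$outcome), ncol(x$exposure), x$reference, ncol(x$controls)))
  cat(sprintf("  FE levels: %s; clusters: %d (%s); dropped rows: %d\n",
              paste(sprintf("%s=%d", names(x$fe),
                            vapply(x$fe, nlevels, integer(1))),
                    collapse = ", "),
              nlevels(droplevels(x$cluster)), x$meta$cluster,
              nrow(x$dropped)))
  invisible(x)
}
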