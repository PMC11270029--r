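# End-to-end pipeline: filter -> score -> join weather -> design ->
# estimate -> report, as a configured, logged run with per-stage counts
# that telescope exactly.

#' Standardised time-trend control columns
#'
#' Week index = whole weeks since the earliest date in the run; powers
#' 1..order, each standardised to mean 0 / sd 1 for conditioning.
#'
#' @param dates Vector of dates.
#' @param order 1 (linear) or 3 (cubic).
#' @return Numeric matrix with `order` columns `trend_week`,
#'   `trend_week2`, `trend_week3`.
#' @export
make_trend <- function(dates, order = 1L) {
  stopifnot(order %in% c(1L, 3L))
  dates <- as.Date(dates)
  week <- floor(as.numeric(dates - min(dates)) / 7)
  cols <- vapply(seq_len(order), function(p) {
    v <- week^p
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }, numeric(length(week)))
  cols <- matrix(cols, nrow = length(week))
  colnames(cols) <- c("trend_week", "trend_week2", "trend_week3")[seq_len(order)]
  cols
}

#' Pipeline run configuration
#'
#' Validates inputs up front: every referenced column must exist before
#' any computation starts. Tables may be passed as data.frames or as
#' paths to UTF-8 delimited files with ISO-8601 dates.
#'
#' @param speeches Speech table (or CSV path): `speech_id`,
#'   `speaker_id`, `city`, `date`, `is_chair`, plus `text` or count
#'   columns.
#' @param weather Raw weather table (or CSV path): `city`, `date`,
#'   `t_mean`, `t_dew`, `precip`, `u_wind`, `v_wind`.
#' @param demographics Optional table (or path): `speaker_id`,
#'   `birth_year`, `gender`.
#' @param scheme `"full"` or `"germany"` bin scheme.
#' @param outcome One of `flesch_kincaid`, `flesch`, `rix`,
#'   `avg_sentence_length`, `avg_word_syllables`.
#' @param interaction `"none"`, `"age_quartile"`, `"gender"`, or
#'   `"period"` (requires demographics for the first two).
#' @param month_fe,cluster,cluster_month Conventions passed to
#'   [build_design()].
#' @param lags Integer day offsets for lagged exposure columns.
#' @param trend `"none"`, `"linear"`, or `"cubic"` weekly time trend.
#' @param extra_controls Names of additional numeric covariate columns
#'   (e.g. a topic label expanded upstream, or a pollution flag).
#' @param min_words Word-count filter threshold.
#' @param seed Integer seed echoed into the report.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @return A validated `run_config`.
#' @export
run_config <- function(speeches, weather, demographics = NULL,
                       scheme = c("full", "germany"),
                       outcome = c("flesch_kincaid", "flesch", "rix",
                                   "avg_sentence_length",
                                   "avg_word_syllables"),
                       interaction = c("none", "age_quartile", "gender",
                                       "period"),
                       month_fe = c("month_of_year", "year_month"),
                       cluster = c("month_by_city", "politician"),
                       cluster_month = c("year_month", "month_of_year"),
                       lags = integer(0),
                       trend = c("none", "linear", "cubic"),
                       extra_controls = character(0),
                       min_words = 25L,
                       seed = 1L,
                       out_dir = NULL) {
  read_tab <- function(x) {
    if (is.character(x) && length(x) == 1L) {
      utils::read.csv(x, stringsAsFactors = FALSE, encoding = "UTF-8")
    } else {
      x
    }
  }
  speeches <- read_tab(speeches)
  weather <- read_tab(weather)
  demographics <- if (!is.null(demographics)) read_tab(demographics)
  scheme <- match.arg(scheme)
  outcome <- match.arg(outcome)
  interaction <- match.arg(interaction)
  month_fe <- match.arg(month_fe)
  cluster <- match.arg(cluster)
  cluster_month <- match.arg(cluster_month)
  trend <- match.arg(trend)

  req_sp <- c("speech_id", "speaker_id", "city", "date", "is_chair")
  miss <- setdiff(req_sp, names(speeches))
  if (length(miss)) stop("speeches lack columns: ", paste(miss, collapse = ", "))
  count_cols <- c("total_words", "total_sentences", "total_syllables",
                  "long_words")
  if (!("text" %in% names(speeches)) && !all(count_cols %in% names(speeches))) {
    stop("speeches need `text` or the four count columns")
  }
  req_w <- c("city", "date", "t_mean", "t_dew", "precip", "u_wind", "v_wind")
  miss <- setdiff(req_w, names(weather))
  if (length(miss)) stop("weather lacks columns: ", paste(miss, collapse = ", "))
  if (interaction %in% c("age_quartile", "gender")) {
    if (is.null(demographics)) {
      stop("interaction '", interaction, "' needs a demographics table")
    }
    need <- c("speaker_id", if (interaction == "age_quartile") "birth_year"
              else "gender")
    miss <- setdiff(need, names(demographics))
    if (length(miss)) {
      stop("demographics lack columns: ", paste(miss, collapse = ", "))
    }
  }
  miss <- setdiff(extra_controls, names(speeches))
  if (length(miss)) {
    stop("extra control columns not in speeches: ", paste(miss, collapse = ", "))
  }
  structure(list(speeches = speeches, weather = weather,
                 demographics = demographics, scheme = scheme,
                 outcome = outcome, interaction = interaction,
                 month_fe = month_fe, cluster = cluster,
                 cluster_month = cluster_month, lags = as.integer(lags),
                 trend = trend, extra_controls = extra_controls,
                 min_words = as.integer(min_words), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

# Fixed-format CSV writer so repeated runs are byte-identical.
.write_table <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) format(v, digits = 15, trim = TRUE,
                                                scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
}

#' Run the full pipeline
#'
#' Stages: read -> filter (chair, short) -> score (unscorable) -> derive
#' weather -> build design (unjoined / missing fields) -> estimate ->
#' report. Stage counts telescope: rows read equal the estimated N plus
#' the sum of all logged drop reasons. Deterministic given inputs and
#' config; intermediates, the coefficient table (CSV and JSON) and the
#' report (JSON and text) are written to `out_dir` when set.
#'
#' @param config A [run_config()].
#' @return A `run_report` list: stage `counts`, `coefficients`,
#'   optional `marginal_effects`, `fit`, `config_echo`, `version`,
#'   `timings` (seconds per stage).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  timings <- list()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }
  speeches <- config$speeches
  n_read <- nrow(speeches)

  filt <- tick("filter", filter_speeches(speeches, config$min_words))
  n_chair <- sum(filt$exclusions$reason == "chair")
  n_short <- sum(filt$exclusions$reason == "short")

  sc <- tick("score", score_speeches(filt$retained))
  n_unscorable <- nrow(sc$exclusions)
  scored <- sc$scored

  scheme <- bin_scheme(config$scheme)
  weather <- tick("weather", derive_weather(config$weather, scheme))
  if (length(config$lags)) {
    weather <- add_exposure_lags(weather, config$lags)
  }

  if (config$trend != "none") {
    ord <- if (config$trend == "linear") 1L else 3L
    scored <- cbind(scored, make_trend(scored$date, ord))
  }
  if (config$interaction %in% c("age_quartile", "gender")) {
    dem <- config$demographics
    j <- match(scored$speaker_id, dem$speaker_id)
    if (config$interaction == "age_quartile") {
      age <- as.integer(format(as.Date(scored$date), "%Y")) - dem$birth_year[j]
      scored$demographic <- as.character(assign_age_quartile(age))
    } else {
      scored$demographic <- dem$gender[j]
    }
  } else if (config$interaction == "period") {
    scored$demographic <- as.character(
      assign_period(as.integer(format(as.Date(scored$date), "%Y"))))
  }

  controls <- c("precip", "rh", "wind_speed", config$extra_controls)
  if (config$trend != "none") {
    ord <- if (config$trend == "linear") 1L else 3L
    controls <- c(controls,
                  c("trend_week", "trend_week2", "trend_week3")[seq_len(ord)])
  }
  design <- tick("design", build_design(
    scored, weather, outcome = config$outcome, controls = controls,
    scheme = scheme, month_fe = config$month_fe, cluster = config$cluster,
    cluster_month = config$cluster_month,
    demographic = if (config$interaction != "none") "demographic"))
  n_unjoined <- sum(design$dropped$reason == "no_weather")
  n_missing <- sum(design$dropped$reason == "missing_field")

  fit <- tick("estimate", fit_fe_ols(design))
  inter <- if (config$interaction != "none") {
    tick("interaction", fit_interaction(design))
  }

  counts <- c(read = n_read, chair_dropped = n_chair, short_dropped = n_short,
              unscorable = n_unscorable, unjoined = n_unjoined,
              missing_field = n_missing, estimated_n = fit$n_obs)
  stopifnot(counts[["read"]] ==
              counts[["estimated_n"]] + n_chair + n_short + n_unscorable +
              n_unjoined + n_missing)

  coefs <- coef_table(fit)
  report <- structure(list(
    counts = counts,
    coefficients = coefs,
    marginal_effects = if (!is.null(inter)) inter$marginal_effects,
    fit = fit,
    interaction_fit = inter,
    exclusions = rbind(filt$exclusions, sc$exclusions, design$dropped),
    config_echo = config[setdiff(names(config),
                                 c("speeches", "weather", "demographics"))],
    version = as.character(utils::packageVersion("parlheat")),
    timings = unlist(timings)),
    class = "run_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_table(scored, file.path(config$out_dir, "scored_speeches.csv"))
    .write_table(coefs, file.path(config$out_dir, "coefficients.csv"))
    .write_table(report$exclusions, file.path(config$out_dir, "exclusions.csv"))
    jsonlite::write_json(
      list(terms = coefs,
           cluster_scheme = config$cluster,
           n_obs = fit$n_obs, n_clusters = fit$n_clusters),
      file.path(config$out_dir, "coefficients.json"),
      auto_unbox = TRUE, digits = NA)
    if (!is.null(inter)) {
      .write_table(inter$marginal_effects,
                   file.path(config$out_dir, "marginal_effects.csv"))
    }
    jsonlite::write_json(
      list(counts = as.list(counts),
           config = report$config_echo[c("scheme", "outcome", "interaction",
                                         "month_fe", "cluster", "trend",
                                         "seed")],
           version = report$version,
           timings = as.list(report$timings)),
      file.path(config$out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    writeLines(utils::capture.output(print(report)),
               file.path(config$out_dir, "report.txt"))
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("parlheat pipeline run\n")
  cat(sprintf("  version %s\n", x$version))
  cat("  stage counts:\n")
  for (nm in names(x$counts)) {
    cat(sprintf("    %-14s %d\n", nm, x$counts[[nm]]))
  }
  cat("  coefficients:\n")
  print(x$coefficients, digits = 4, row.names = FALSE)
  if (!is.null(x$marginal_effects)) {
    cat("  marginal effects:\n")
    print(x$marginal_effects, digits = 4, row.names = FALSE)
  }
  invisible(x)
}
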