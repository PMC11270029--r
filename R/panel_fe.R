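# Multi-way fixed-effects OLS: alternating-projections demeaning, least
# squares on the within-transformed data, and CR1 cluster-robust
# inference. Written from scratch; verified in the test suite against a
# dense dummy-variable regression oracle.

#' Iterative multi-way demeaning (within transformation)
#'
#' Alternating projections: group means are subtracted for each
#' fixed-effect dimension in declared order, sweeping until the largest
#' absolute column-wise group mean across all dimensions falls below
#' `tol`. For a single dimension one pass is exact. Singleton groups are
#' retained (they demean to zero).
#'
#' @param m Numeric matrix or vector (rows = observations).
#' @param groups List of factors (or vectors coercible to factor), one
#'   per fixed-effect dimension, each of length `nrow(m)`.
#' @param tol Convergence tolerance on the max absolute group mean.
#' @param max_iter Maximum number of full sweeps.
#' @return The demeaned matrix, with attributes `iterations` and
#'   `converged`.
#' @examples
#' demean_multiway(c(1, 2, 3, 5), list(c("A", "A", "B", "B")))
#' @export
demean_multiway <- function(m, groups, tol = 1e-10, max_iter = 10000L) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (!length(groups)) stop("need at least one fixed-effect dimension")
  gs <- lapply(groups, function(g) as.integer(droplevels(as.factor(g))))
  if (any(vapply(gs, length, integer(1)) != nrow(m))) {
    stop("group label lengths must match nrow(m)")
  }
  sizes <- lapply(gs, tabulate)
  worst_mean <- function(mm) {
    max(vapply(seq_along(gs), function(d) {
      gm <- rowsum(mm, gs[[d]], reorder = TRUE) / sizes[[d]]
      max(abs(gm))
    }, numeric(1)))
  }
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    for (d in seq_along(gs)) {
      gm <- rowsum(m, gs[[d]], reorder = TRUE) / sizes[[d]]
      m <- m - gm[gs[[d]], , drop = FALSE]
    }
    w <- worst_mean(m)
    if (w < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) {
      stop(sprintf(
        "demeaning did not converge in %d sweeps (residual group mean %.3e)",
        max_iter, w))
    }
  }
  attr(m, "iterations") <- iter
  attr(m, "converged") <- converged
  m
}

# Degrees of freedom absorbed by the FE dimensions, mirroring a dense
# dummy regression with intercept: L1 + sum(L_d - 1) over the remaining
# dimensions (exact for connected, non-redundant groupings).
.absorbed_df <- function(fe) {
  L <- vapply(fe, function(g) nlevels(droplevels(as.factor(g))), integer(1))
  sum(L) - (length(L) - 1L)
}

#' CR1 cluster-robust covariance matrix
#'
#' Sandwich estimator summing score outer products within clusters:
#' `(X'X)^{-1} [sum_g X_g' e_g e_g' X_g] (X'X)^{-1}`, scaled by the
#' small-sample factor `G/(G-1) * (N-1)/(N-K)`. With every observation
#' its own cluster this reduces to the HC1 heteroskedasticity-robust
#' form. Single-observation clusters are allowed; a single cluster is an
#' error.
#'
#' @param x Demeaned regressor matrix (full column rank).
#' @param residuals Residual vector.
#' @param cluster Cluster labels, length `nrow(x)`.
#' @param k Model degrees of freedom: slope columns plus absorbed
#'   fixed-effect levels (see [fit_fe_ols()]).
#' @return Symmetric covariance matrix for the slope coefficients.
#' @export
cluster_robust_vcov <- function(x, residuals, cluster, k = ncol(x)) {
  x <- as.matrix(x)
  cl <- droplevels(as.factor(cluster))
  g <- nlevels(cl)
  n <- nrow(x)
  if (g < 2L) stop("cluster-robust variance needs at least 2 clusters")
  if (length(residuals) != n || length(cl) != n) {
    stop("residuals and cluster labels must match nrow(x)")
  }
  bread <- chol2inv(chol(crossprod(x)))
  s <- rowsum(x * as.numeric(residuals), cl)
  meat <- crossprod(s)
  adj <- (g / (g - 1)) * ((n - 1) / (n - k))
  v <- adj * bread %*% meat %*% bread
  v <- (v + t(v)) / 2
  dimnames(v) <- list(colnames(x), colnames(x))
  v
}

# Shared fitting core: demean, prune collinear columns, OLS, CR1 vcov.
.fit_core <- function(y, x, fe, cluster, tol = 1e-10, max_iter = 10000L,
                      conf_level = 0.95) {
  stopifnot(nrow(x) == length(y))
  dm <- demean_multiway(cbind(y, x), fe, tol = tol, max_iter = max_iter)
  yd <- dm[, 1L]
  xd <- dm[, -1L, drop = FALSE]
  qx <- qr(xd)
  r <- qx$rank
  if (r == 0L) stop("no identifiable regressors after demeaning")
  keep <- sort(qx$pivot[seq_len(r)])
  dropped_terms <- colnames(xd)[setdiff(seq_len(ncol(xd)), keep)]
  if (length(dropped_terms)) {
    xd <- xd[, keep, drop = FALSE]
    qx <- qr(xd)
    if (qx$rank < ncol(xd)) {
      stop("rank deficiency persists after pruning columns: ",
           paste(colnames(xd), collapse = ", "))
    }
  }
  beta <- qr.coef(qx, yd)
  resid <- yd - as.numeric(xd %*% beta)
  k <- ncol(xd) + .absorbed_df(fe)
  vc <- cluster_robust_vcov(xd, resid, cluster, k = k)
  se <- sqrt(pmax(diag(vc), 0))
  crit <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(beta = stats::setNames(as.numeric(beta), colnames(xd)),
                 vcov = vc,
                 se = stats::setNames(se, colnames(xd)),
                 ci_low = stats::setNames(as.numeric(beta) - crit * se,
                                          colnames(xd)),
                 ci_high = stats::setNames(as.numeric(beta) + crit * se,
                                           colnames(xd)),
                 residuals = resid,
                 n_obs = length(y),
                 n_clusters = nlevels(droplevels(as.factor(cluster))),
                 fe_levels = vapply(fe, function(g)
                   nlevels(droplevels(as.factor(g))), integer(1)),
                 n_singletons = vapply(fe, function(g)
                   sum(table(g) == 1L), integer(1)),
                 df_k = k,
                 conf_level = conf_level,
                 dropped_terms = dropped_terms,
                 demeaning_iterations = attr(dm, "iterations"),
                 converged = attr(dm, "converged")),
            class = "fe_estimate")
}

#' Fit the multi-way fixed-effects panel model
#'
#' Estimates the exposure-response model: outcome regressed on the
#' non-reference temperature-bin dummies and controls, absorbing the
#' politician, month-by-city and day-of-week fixed effects by iterative
#' demeaning. Coefficients equal those of a dense regression with
#' explicit dummy columns for every fixed-effect level. Inference is
#' CR1 cluster-robust with normal (1.96) critical values: at the sample
#' sizes and cluster counts this model is built for, the t/normal
#' distinction is immaterial. Collinear columns are pruned and reported
#' in `dropped_terms`. The model degrees of freedom `df_k` count slope
#' columns plus absorbed fixed-effect levels (minus redundancies) so
#' that standard errors mirror the dense dummy regression.
#'
#' @param design A `panel_design` from [build_design()].
#' @param tol,max_iter Demeaning convergence controls.
#' @param conf_level Confidence level for the reported intervals.
#' @return An `fe_estimate`: named `beta`, cluster-robust `vcov`, `se`,
#'   `ci_low`/`ci_high`, sample and cluster counts, fixed-effect level
#'   counts, demeaning iterations and convergence flag.
#' @export
fit_fe_ols <- function(design, tol = 1e-10, max_iter = 10000L,
                       conf_level = 0.95) {
  stopifnot(inherits(design, "panel_design"))
  x <- cbind(design$exposure, design$controls)
  .fit_core(design$outcome, x, design$fe, design$cluster,
            tol = tol, max_iter = max_iter, conf_level = conf_level)
}

#' @export
print.fe_estimate <- function(x, ...) {
  cat(sprintf("<fe_estimate> N=%d, clusters=%d, df K=%d, demeaning sweeps=%d\n",
              x$n_obs, x$n_clusters, x$df_k, x$demeaning_iterations))
  print(coef_table(x), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Coefficient table of a fitted model
#'
#' @param est An `fe_estimate`.
#' @return data.frame with `term`, `estimate`, `se`, `ci_low`, `ci_high`.
#' @export
coef_table <- function(est) {
  stopifnot(inherits(est, "fe_estimate"))
  data.frame(term = names(est$beta),
             estimate = as.numeric(est$beta),
             se = as.numeric(est$se),
             ci_low = as.numeric(est$ci_low),
             ci_high = as.numeric(est$ci_high),
             stringsAsFactors = FALSE)
}

#' Fit the demographic-interaction model and extract marginal effects
#'
#' Interacts every exposure dummy with every level of a demographic
#' (age quartile, gender, or period group), so each coefficient is
#' directly the marginal effect of that temperature bin, relative to the
#' comfort zone, for that demographic level, with its clustered standard
#' error. For speaker-constant demographics the level main effect is
#' absorbed by the politician fixed effect; for time-varying ones
#' (e.g. age quartile) level main-effect dummies are added
#' automatically. Exposure-level cells with no observations are reported
#' as missing rows, never silently dropped.
#'
#' @param design A `panel_design` built with a `demographic` column (or
#'   pass `demographic` explicitly).
#' @param demographic Optional factor of demographic labels (one per
#'   design row), overriding `design$demographic`.
#' @param conf_level Confidence level for intervals.
#' @return List of class `fe_interaction`: `fit` (the underlying
#'   `fe_estimate`) and `marginal_effects` (data.frame keyed by
#'   `bin` and `level`).
#' @export
fit_interaction <- function(design, demographic = NULL, conf_level = 0.95) {
  stopifnot(inherits(design, "panel_design"))
  demo <- if (is.null(demographic)) design$demographic else demographic
  if (is.null(demo)) stop("no demographic supplied")
  demo <- droplevels(factor(demo))
  n <- length(design$outcome)
  if (length(demo) != n) stop("demographic length must match design rows")
  if (anyNA(demo)) stop("demographic labels contain NA; drop those rows first")
  lev <- levels(demo)
  if (length(lev) == 1L) {
    fit <- fit_fe_ols(design, conf_level = conf_level)
    me <- coef_table(fit)
    me <- me[grepl("^bin_", me$term), , drop = FALSE]
    me <- data.frame(bin = sub("^bin_", "", me$term), level = lev,
                     me[c("estimate", "se", "ci_low", "ci_high")],
                     stringsAsFactors = FALSE)
    return(structure(list(fit = fit, marginal_effects = me),
                     class = "fe_interaction"))
  }
  # speaker-constant demographic? (one level per politician)
  by_pol <- tapply(as.character(demo), design$fe$politician,
                   function(v) length(unique(v)))
  speaker_constant <- all(by_pol == 1L)

  bins <- design$bin_levels
  expo <- design$exposure
  cols <- list()
  cell_n <- matrix(0L, nrow = length(bins), ncol = length(lev),
                   dimnames = list(bins, lev))
  for (l in lev) {
    dl <- as.numeric(demo == l)
    for (b in colnames(expo)) {
      bl <- sub("^bin_", "", b)
      col <- expo[, b] * dl
      cell_n[bl, l] <- sum(col > 0)
      cols[[paste0(b, ":", l)]] <- col
    }
  }
  keep_cols <- names(cols)[vapply(cols, function(v) any(v != 0), logical(1))]
  xint <- do.call(cbind, cols[keep_cols])
  colnames(xint) <- keep_cols
  if (!speaker_constant) {
    base <- lev[1L]
    mains <- vapply(lev[-1L], function(l) as.numeric(demo == l), numeric(n))
    mains <- matrix(mains, nrow = n,
                    dimnames = list(NULL, paste0("demo_", lev[-1L])))
    xint <- cbind(xint, mains)
  }
  x <- cbind(xint, design$controls)
  fit <- .fit_core(design$outcome, x, design$fe, design$cluster,
                   conf_level = conf_level)
  grid <- expand.grid(bin = bins, level = lev, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  term <- paste0("bin_", grid$bin, ":", grid$level)
  idx <- match(term, names(fit$beta))
  me <- data.frame(bin = grid$bin, level = grid$level,
                   estimate = as.numeric(fit$beta)[idx],
                   se = as.numeric(fit$se)[idx],
                   ci_low = as.numeric(fit$ci_low)[idx],
                   ci_high = as.numeric(fit$ci_high)[idx],
                   n_cell = cell_n[cbind(grid$bin, grid$level)],
                   stringsAsFactors = FALSE)
  structure(list(fit = fit, marginal_effects = me,
                 speaker_constant = speaker_constant),
            class = "fe_interaction")
}

#' @export
print.fe_interaction <- function(x, ...) {
  cat(sprintf("<fe_interaction> N=%d, clusters=%d\n",
              x$fit$n_obs, x$fit$n_clusters))
  print(x$marginal_effects, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Assign ages to the study's age quartiles
#'
#' Q1 = 19-44, Q2 = 45-50, Q3 = 51-56, Q4 = 57 and above (integer ages;
#' for fractional ages strictly between 56 and 57 the top quartile is
#' used). Missing ages yield missing labels; ages below 18 are an error.
#'
#' @param age Numeric vector of ages at the time of the speech, years.
#' @return Factor with levels `19-44`, `45-50`, `51-56`, `57+`.
#' @examples
#' assign_age_quartile(c(44, 45, 56, 57))
#' @export
assign_age_quartile <- function(age) {
  age <- as.numeric(age)
  if (any(!is.na(age) & age < 18)) stop("ages below 18 are out of range")
  cut(age, breaks = c(-Inf, 44, 50, 56, Inf),
      labels = c("19-44", "45-50", "51-56", "57+"), right = TRUE)
}

#' Assign calendar years to study periods
#'
#' Closed ranges 1950-1967, 1968-1985, 1986-2003, 2004-2019. Years
#' outside the study span are an error.
#'
#' @param year Integer vector of calendar years.
#' @return Factor of period labels.
#' @examples
#' assign_period(c(1967, 1968, 2019))
#' @export
assign_period <- function(year) {
  year <- as.numeric(year)
  if (any(!is.na(year) & (year < 1950 | year > 2019))) {
    stop("year outside the 1950-2019 study span")
  }
  cut(year, breaks = c(1949, 1967, 1985, 2003, 2019),
      labels = c("1950-1967", "1968-1985", "1986-2003", "2004-2019"),
      right = TRUE)
}
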