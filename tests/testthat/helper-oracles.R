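# Independent oracles and shared Monte-Carlo studies.

# Literal transcription of the printed Magnus-type formula, kept
# independent of the package implementation.
svp_ref <- function(t) 6.11 * 10^((7.5 * t) / (237.7 + t))

# Random small panel with 3 FE dimensions for estimator-oracle checks.
random_panel <- function(n = 400, n_f1 = 25, n_f2 = 10, n_f3 = 6,
                         n_x = 3, n_cl = 25) {
  f1 <- factor(sample(seq_len(n_f1), n, replace = TRUE))
  f2 <- factor(sample(seq_len(n_f2), n, replace = TRUE))
  f3 <- factor(sample(seq_len(n_f3), n, replace = TRUE))
  x <- matrix(rnorm(n * n_x), n, dimnames = list(NULL, paste0("x", 1:n_x)))
  beta <- rnorm(n_x)
  y <- as.numeric(x %*% beta) +
    rnorm(n_f1)[f1] + rnorm(n_f2)[f2] + rnorm(n_f3)[f3] + rnorm(n)
  list(y = y, x = x, fe = list(f1 = f1, f2 = f2, f3 = f3),
       cluster = factor(sample(seq_len(n_cl), n, replace = TRUE)),
       beta = beta)
}

# Fit y on x with FE absorbed, via the package internals used by
# fit_fe_ols, exposed through demean_multiway + lm.fit for tests that
# need raw matrices rather than a panel_design.
fit_raw <- function(y, x, fe, cluster) {
  dm <- demean_multiway(cbind(y, x), fe)
  xd <- dm[, -1, drop = FALSE]
  b <- qr.coef(qr(xd), dm[, 1])
  e <- dm[, 1] - as.numeric(xd %*% b)
  L <- vapply(fe, function(g) nlevels(droplevels(as.factor(g))), integer(1))
  k <- ncol(xd) + sum(L) - (length(L) - 1L)
  list(beta = b, resid = e, xd = xd, k = k,
       vcov = cluster_robust_vcov(xd, e, cluster, k = k))
}

.study_cache <- new.env(parent = emptyenv())

# Parameter-recovery study at the generator's default scale: simulate,
# estimate, collect bin coefficients and clustered SEs. Cached so the
# acceptance criterion and the module property tests share one run.
recovery_study <- function(reps = 250L) {
  key <- paste0("recovery_", reps)
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  bins <- paste0("bin_", setdiff(bin_scheme("full")$labels, "12-18"))
  est <- se <- matrix(NA_real_, reps, length(bins),
                      dimnames = list(NULL, bins))
  for (r in seq_len(reps)) {
    p <- simulate_panel(sim_config(seed = 20000L + r))
    f <- fit_fe_ols(build_design(p$speeches, p$weather))
    est[r, ] <- f$beta[bins]
    se[r, ] <- f$se[bins]
  }
  truth <- sim_config()$true_bin_effects
  out <- list(est = est, se = se,
              truth = setNames(truth[sub("^bin_", "", bins)], bins))
  .study_cache[[key]] <- out
  out
}

# Type-I error study: the generator's default conditions with all true
# effects set to zero.
null_study <- function(reps = 1000L) {
  key <- paste0("null_", reps)
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  labels <- bin_scheme("full")$labels
  cfg0 <- sim_config(true_bin_effects = setNames(rep(0, length(labels)),
                                                 labels))
  bins <- paste0("bin_", setdiff(labels, "12-18"))
  z <- matrix(NA_real_, reps, length(bins), dimnames = list(NULL, bins))
  for (r in seq_len(reps)) {
    cfg <- cfg0
    cfg$seed <- 40000L + r
    p <- simulate_panel(cfg)
    f <- fit_fe_ols(build_design(p$speeches, p$weather))
    z[r, ] <- f$beta[bins] / f$se[bins]
  }
  .study_cache[[key]] <- z
  z
}
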