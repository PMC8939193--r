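## Null-simulation audit of smooth-term p-values: fit a confounder-only
## model, simulate responses from its fitted means (so the tested ordinal
## effect is zero by construction), refit with the smooth ordinal term
## added, and collect the Wald-type p-values.

#' Configuration for a null-calibration experiment
#'
#' @param base_spec A [model_spec()] *without* the tested ordinal term
#'   (the confounder model).
#' @param test_term The [ordinal_term()] whose p-value calibration is
#'   audited; its effect is zero by construction under the resampling.
#' @param n_rep Number of simulation replicates.
#' @param seed Master seed; each replicate draws from its own child
#'   stream, so individual replicates are reproducible.
#' @param method Smoothing-selection criterion for the refits.
#' @param alpha_grid Significance levels at which empirical rejection
#'   rates are reported.
#' @return An object of class `"calibration_config"`.
#' @export
calibration_config <- function(base_spec, test_term, n_rep = 1000,
                               seed = 1, method = c("REML", "ML"),
                               alpha_grid = c(0.01, 0.05, 0.1)) {
  stopifnot(inherits(base_spec, "model_spec"),
            inherits(test_term, "ordinal_term"))
  method <- match.arg(method)
  if (n_rep < 1) stop("n_rep must be >= 1", call. = FALSE)
  if (any(alpha_grid <= 0 | alpha_grid >= 1))
    stop("alpha_grid values must lie in (0, 1)", call. = FALSE)
  base_names <- c(base_spec$parametric,
                  vapply(base_spec$ordinal, `[[`, character(1), "name"))
  if (test_term$name %in% base_names)
    stop("test term '", test_term$name,
         "' must not appear in the base spec", call. = FALSE)
  structure(list(base_spec = base_spec, test_term = test_term,
                 n_rep = as.integer(n_rep), seed = as.integer(seed),
                 method = method, alpha_grid = sort(alpha_grid)),
            class = "calibration_config")
}

#' Fit the confounder (null) model
#'
#' Fits `base_spec` to the data; the fitted means do not depend on the
#' tested ordinal column and are the resampling distribution for the
#' null-calibration experiment.
#'
#' @param base_spec A [model_spec()] excluding the tested term.
#' @param data Subject-level data.
#' @param method Smoothing-selection criterion.
#' @return An `ordsmooth_fit`.
#' @export
fit_null_model <- function(base_spec, data, method = "REML") {
  fit_gam(base_spec, data, method = method)
}

#' Run the null-calibration experiment
#'
#' Per replicate: draw a new response from the null model's fitted means
#' (at the original covariate values; covariates are never resampled),
#' refit the model with the smooth ordinal test term added (smoothing
#' parameter re-estimated each time), and store the Wald-type smooth-term
#' p-value. Non-converged replicates are excluded and counted; more than
#' 20% failures aborts with an error.
#'
#' @param config A [calibration_config()].
#' @param data Subject-level data containing the confounders and the test
#'   term's column.
#' @return An object of class `"calibration_result"`: `p_values`,
#'   `rejection_rate` (per alpha), `ks_distance`, `n_failed`, `alpha_grid`.
#' @export
run_calibration <- function(config, data) {
  stopifnot(inherits(config, "calibration_config"))
  spec0 <- config$base_spec
  null_fit <- fit_null_model(spec0, data, config$method)
  mu0 <- fitted(null_fit)
  family <- spec0$family

  spec1 <- model_spec(spec0$response, family,
                      parametric = spec0$parametric,
                      ordinal = c(spec0$ordinal, list(config$test_term)))
  ## design built once: only the response changes across replicates
  design <- suppressWarnings(build_design(spec1, data))
  n <- design$nobs
  if (length(mu0) != n)
    stop("null-model rows and augmented-design rows differ ",
         "(missingness pattern?)", call. = FALSE)
  phi0 <- if (family == "gaussian") null_fit$scale else 1

  set.seed(config$seed)
  rep_seeds <- sample.int(2147483646L, config$n_rep)

  draw_y <- switch(family,
    binomial = function() stats::rbinom(n, 1, mu0),
    poisson  = function() stats::rpois(n, mu0),
    gaussian = function() stats::rnorm(n, mu0, sqrt(phi0)))

  p_values <- rep(NA_real_, config$n_rep)
  for (r in seq_len(config$n_rep)) {
    set.seed(rep_seeds[r])
    ystar <- draw_y()
    fit <- tryCatch(
      suppressWarnings(suppressMessages(
        fit_from_design(design, y = ystar, method = config$method))),
      error = function(e) NULL)
    if (!is.null(fit) && fit$converged) {
      st <- suppressMessages(smooth_test(fit, config$test_term$name))
      p_values[r] <- st[["p-value"]]
    }
  }
  n_failed <- sum(is.na(p_values))
  if (n_failed > 0.2 * config$n_rep)
    stop("more than 20% of calibration replicates failed (",
         n_failed, "/", config$n_rep,
         "); the configuration is unstable", call. = FALSE)
  p_values <- p_values[!is.na(p_values)]

  rejection_rate <- vapply(config$alpha_grid,
                           function(a) mean(p_values <= a), numeric(1))
  names(rejection_rate) <- format(config$alpha_grid)

  m <- length(p_values)
  ps <- sort(p_values)
  ks_distance <- max(pmax(abs(seq_len(m) / m - ps),
                          abs((seq_len(m) - 1) / m - ps)))

  structure(list(p_values = p_values, rejection_rate = rejection_rate,
                 ks_distance = ks_distance, n_failed = n_failed,
                 alpha_grid = config$alpha_grid, config = config),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Null-calibration result: ", length(x$p_values),
      " replicates (", x$n_failed, " failed)\n", sep = "")
  cat("Empirical rejection rates:\n")
  print(signif(x$rejection_rate, 3))
  cat("KS distance from uniform:", signif(x$ks_distance, 3), "\n")
  invisible(x)
}

#' Uniform QQ table for simulated p-values
#'
#' Pairs the sorted empirical p-values with uniform theoretical quantiles
#' `(i - 0.5)/n` and truncates to the region below `upper`, the part of the
#' distribution that matters when testing at conventional significance
#' levels. Points below the diagonal flag anti-conservative p-values.
#'
#' @param p_values Vector of p-values.
#' @param upper Truncation point, default 0.1.
#' @return Data frame with columns `theoretical`, `empirical`.
#' @export
qq_uniform <- function(p_values, upper = 0.1) {
  if (!length(p_values)) stop("no p-values supplied", call. = FALSE)
  ps <- sort(p_values)
  m <- length(ps)
  theo <- (seq_len(m) - 0.5) / m
  keep <- theo <= upper & ps <= upper
  data.frame(theoretical = theo[keep], empirical = ps[keep])
}
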