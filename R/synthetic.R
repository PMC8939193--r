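## Synthetic cohorts with known ground truth. The BPD-like generator
## emulates the structure of a neonatal retrospective cohort: ~100 very-low
## birth weight preterm infants, a dichotomized binary lung-disease outcome,
## six clinical confounders, and three ordinal 7-level predictors coding the
## week (1..6, top-coded ">6" as level 7) a bacterial group was first
## detected in the upper airway, with sparse extreme levels (few infants at
## week 1).

ordinal_shape <- function(shape, k, size) {
  if (is.numeric(shape)) {
    if (length(shape) != k)
      stop("custom effect vector must have length k = ", k, call. = FALSE)
    v <- shape
  } else {
    v <- switch(match.arg(shape, c("null", "linear", "decreasing-step")),
      "null" = rep(0, k),
      ## later detection -> lower risk: linear drop of 2*size over 1..k
      "linear" = size * ((k + 1) / 2 - seq_len(k)) / ((k - 1) / 2),
      ## elevated risk for detection in the first two weeks only
      "decreasing-step" = size * (c(rep(1, 2), rep(0, k - 2)) - 2 / k))
  }
  v - mean(v)
}

#' Configuration for a BPD-like synthetic cohort
#'
#' Defaults state a plausible very-low-birth-weight cohort: n = 100
#' subjects, birth weight below 1000 g, a binary
#' bronchopulmonary-dysplasia-style outcome with ~40% prevalence, and three
#' correlated ordinal 7-level predictors whose lowest level (detection in
#' week 1) is sparse (expected ~3 subjects at n = 100).
#'
#' @param n Number of subjects (>= 30).
#' @param seed Integer seed; generation is bit-reproducible given the
#'   configuration.
#' @param k Levels per ordinal predictor (default 7: weeks 1..6 plus ">6").
#' @param intercept Logit-scale intercept.
#' @param effects Named list of confounder effects on the logit scale:
#'   `weight` (per gram), `sga`, `sex`, `multiples`, `steroids` (per day),
#'   `antibiotics` (per day).
#' @param shapes Named list of ordinal effect shapes for `gram_neg`,
#'   `gram_pos`, `pathogenic`: `"null"`, `"linear"`, `"decreasing-step"`,
#'   or a custom length-`k` numeric vector (centred internally).
#' @param effect_size Scale of the named ordinal shapes (logit units).
#' @param occupancy Level-occupancy probabilities (length `k`), sparse at
#'   level 1 by default.
#' @param ordinal_cor Latent (Gaussian-copula) correlation among the three
#'   ordinal predictors.
#' @return An object of class `"bpd_config"`.
#' @export
bpd_config <- function(n = 100, seed = 1, k = 7,
                       intercept = 6.6,
                       effects = list(weight = -0.010, sga = 0.8,
                                      sex = 1.0, multiples = 0.7,
                                      steroids = -0.15, antibiotics = 0.05),
                       shapes = list(gram_neg = "null", gram_pos = "null",
                                     pathogenic = "null"),
                       effect_size = 1.5,
                       occupancy = c(0.03, 0.10, 0.17, 0.20,
                                     0.18, 0.12, 0.20),
                       ordinal_cor = 0.3) {
  if (n < 30) stop("n must be at least 30", call. = FALSE)
  k <- as.integer(k)
  if (length(occupancy) != k || any(occupancy <= 0))
    stop("occupancy must be ", k, " positive probabilities", call. = FALSE)
  occupancy <- occupancy / sum(occupancy)
  need <- c("weight", "sga", "sex", "multiples", "steroids", "antibiotics")
  if (!all(need %in% names(effects)))
    stop("effects must name: ", paste(need, collapse = ", "), call. = FALSE)
  need_o <- c("gram_neg", "gram_pos", "pathogenic")
  if (!all(need_o %in% names(shapes)))
    stop("shapes must name: ", paste(need_o, collapse = ", "), call. = FALSE)
  if (abs(ordinal_cor) >= 1)
    stop("ordinal_cor must be in (-1, 1)", call. = FALSE)
  if (n * min(occupancy) < 0.5)
    warning("a level has expected count < 0.5 across all terms; ",
            "fits may be unstable", call. = FALSE)
  structure(list(n = as.integer(n), seed = as.integer(seed), k = k,
                 intercept = intercept, effects = effects, shapes = shapes,
                 effect_size = effect_size, occupancy = occupancy,
                 ordinal_cor = ordinal_cor),
            class = "bpd_config")
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate a BPD-like synthetic cohort
#'
#' Draws confounders (birth weight as a normal truncated below 1000 g per
#' the inclusion criterion, Poisson medication-day counts, Bernoulli
#' binaries), three correlated ordinal predictors via a Gaussian copula
#' over the configured level occupancy, and a Bernoulli response from the
#' logistic model defined by the configuration. The exact generating truth
#' is returned alongside the data.
#'
#' @param config A [bpd_config()].
#' @return List with elements `data` (data frame with columns `bpd`,
#'   `weight_g`, `sga`, `sex_male`, `multiples`, `steroid_days`,
#'   `antibiotic_days`, `gram_neg`, `gram_pos`, `pathogenic`) and `truth`
#'   (centred per-term coefficient vectors, linear predictor `eta`, mean
#'   `mu`).
#' @export
generate_bpd_like <- function(config = bpd_config()) {
  stopifnot(inherits(config, "bpd_config"))
  n <- config$n; k <- config$k
  set.seed(config$seed)

  weight_g <- rtrunc_norm(n, 750, 150, 400, 995)
  sga <- stats::rbinom(n, 1, 0.2)
  sex_male <- stats::rbinom(n, 1, 0.5)
  multiples <- stats::rbinom(n, 1, 0.3)
  steroid_days <- stats::rpois(n, 5)
  antibiotic_days <- stats::rpois(n, 7)

  ## Gaussian copula over the three ordinal predictors
  R <- matrix(config$ordinal_cor, 3, 3); diag(R) <- 1
  L <- chol(R)
  Zl <- matrix(stats::rnorm(n * 3), n, 3) %*% L
  cuts <- stats::qnorm(cumsum(config$occupancy)[-k])
  to_level <- function(z) findInterval(z, cuts) + 1L
  gram_neg <- to_level(Zl[, 1])
  gram_pos <- to_level(Zl[, 2])
  pathogenic <- to_level(Zl[, 3])

  fo <- lapply(config$shapes, ordinal_shape, k = k,
               size = config$effect_size)
  ef <- config$effects
  eta <- config$intercept +
    ef$weight * weight_g + ef$sga * sga + ef$sex * sex_male +
    ef$multiples * multiples + ef$steroids * steroid_days +
    ef$antibiotics * antibiotic_days +
    fo$gram_neg[gram_neg] + fo$gram_pos[gram_pos] +
    fo$pathogenic[pathogenic]
  mu <- stats::plogis(eta)
  bpd <- stats::rbinom(n, 1, mu)

  data <- data.frame(bpd, weight_g, sga, sex_male, multiples,
                     steroid_days, antibiotic_days,
                     gram_neg, gram_pos, pathogenic)
  list(data = data,
       truth = list(coefs = fo, eta = eta, mu = mu, config = config))
}

#' Generate a single-ordinal-predictor GLM test bed
#'
#' One ordinal predictor with configurable level occupancy, a known
#' (centred) effect vector, and a response from the requested family; the
#' exact generating truth is returned for parameter-recovery and coverage
#' experiments.
#'
#' @param n Number of observations.
#' @param k Number of ordinal levels.
#' @param family `"gaussian"`, `"binomial"`, or `"poisson"`.
#' @param effect Length-`k` effect vector (centred internally).
#' @param seed Integer seed.
#' @param intercept Intercept on the link scale.
#' @param sigma Gaussian error standard deviation.
#' @param occupancy Level probabilities (default uniform).
#' @return List with `data` (columns `y`, `x`) and `truth`.
#' @export
generate_ordinal_glm <- function(n, k, family = "gaussian", effect,
                                 seed = 1, intercept = 0, sigma = 1,
                                 occupancy = rep(1 / k, k)) {
  stopifnot(length(effect) == k, length(occupancy) == k)
  family <- match.arg(family, c("gaussian", "binomial", "poisson"))
  occupancy <- occupancy / sum(occupancy)
  f <- effect - mean(effect)
  set.seed(seed)
  x <- sample.int(k, n, replace = TRUE, prob = occupancy)
  eta <- intercept + f[x]
  fam <- family_object(family)
  mu <- fam$linkinv(eta)
  y <- switch(family,
              gaussian = stats::rnorm(n, mu, sigma),
              binomial = stats::rbinom(n, 1, mu),
              poisson  = stats::rpois(n, mu))
  list(data = data.frame(y = y, x = x),
       truth = list(coefs = f, eta = eta, mu = mu,
                    intercept = intercept, family = family, sigma = sigma))
}
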