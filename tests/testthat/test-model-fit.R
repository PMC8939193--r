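test_that("design assembly: layout, column counts, and input validation", {
  sim <- generate_bpd_like(bpd_config(n = 120, seed = 3))
  des <- suppressWarnings(build_design(bpd_full_spec(), sim$data))
  expect_identical(ncol(des$X), 25L)            # 1 + 6 + 3 * (7 - 1)
  expect_identical(colnames(des$X)[1], "(Intercept)")
  expect_identical(colnames(des$X)[2:7], bpd_parametric)
  cols <- unlist(des$term_cols)
  expect_identical(sort(unname(cols)), 8:25)    # disjoint cover of smooth cols
  for (nm in names(des$blocks))
    expect_identical(length(des$term_cols[[nm]]),
                     ncol(des$blocks[[nm]]$S))

  ## reduces to the ordinary GLM design with no ordinal terms
  des0 <- build_design(bpd_base_spec(), sim$data)
  expect_identical(ncol(des0$X), 7L)
  expect_length(des0$blocks, 0L)

  expect_error(build_design(bpd_full_spec(),
                            sim$data[setdiff(names(sim$data), "sga")]),
               "not found")
  expect_error(model_spec("y", "binomial", parametric = c("a", "a")),
               "duplicate")
  d2 <- sim$data; d2$flat <- 1
  spec2 <- model_spec("bpd", "binomial", parametric = "flat")
  expect_warning(build_design(spec2, d2), "constant")
  d3 <- sim$data; d3$weight_g[c(2, 9)] <- NA
  expect_message(build_design(bpd_base_spec(), d3), "dropping 2")
})

test_that("gaussian PIRLS reproduces the closed-form ridge solution in one step", {
  sim <- generate_ordinal_glm(n = 150, k = 5, family = "gaussian",
                              effect = c(0, 1, 1.5, 1.2, 2), seed = 5)
  spec <- model_spec("y", "gaussian",
                     ordinal = list(ordinal_term("x", 5, 2)))
  des <- build_design(spec, sim$data)
  lam <- 2.5
  ft <- pirls(des, lambda = lam)
  Sl <- matrix(0, ncol(des$X), ncol(des$X))
  cols <- des$term_cols[[1]]
  Sl[cols, cols] <- lam * des$blocks[[1]]$S
  beta_ridge <- solve(crossprod(des$X) + Sl, crossprod(des$X, des$y))
  expect_lt(max(abs(ft$beta - drop(beta_ridge))), 1e-10)
  expect_true(ft$converged)
})

test_that("vanishing penalty recovers the unpenalized GLM", {
  sim <- generate_ordinal_glm(n = 400, k = 5, family = "binomial",
                              effect = c(-1, 0, 0.5, 1, 1.5), seed = 9,
                              intercept = -0.3)
  spec <- model_spec("y", "binomial",
                     ordinal = list(ordinal_term("x", 5, 1)))
  fit <- quiet_fit(spec, sim$data, lambda = 1e-8)
  gl <- stats::glm(sim$data$y ~ 0 + fit$design$X, family = binomial)
  expect_lt(max(abs(fit$beta - unname(coef(gl)))), 1e-6)
})

test_that("the penalty keeps separated levels finite", {
  ## all subjects at level 4 are events: the unpenalized dummy MLE diverges
  set.seed(21)
  x <- rep(1:4, each = 25)
  eta <- c(-0.5, 0, 0.5, 0)[x]
  y <- rbinom(100, 1, plogis(eta))
  y[x == 4] <- 1
  spec <- model_spec("y", "binomial",
                     ordinal = list(ordinal_term("x", 4, 2)))
  fit <- quiet_fit(spec, data.frame(y = y, x = x), lambda = 1)
  expect_true(fit$converged)
  expect_true(all(is.finite(fit$beta)))
  expect_true(is.finite(fit$penalized_deviance))
})

test_that("REML criterion equals the mixed-model restricted likelihood (gaussian)", {
  sim <- generate_ordinal_glm(n = 180, k = 6, family = "gaussian",
                              effect = c(0, .4, 1.2, 1.3, 1.4, 2), seed = 3)
  spec2 <- model_spec("y", "gaussian",
                      ordinal = list(ordinal_term("x", 6, 2)))
  des <- build_design(spec2, sim$data)
  phi <- 1.21
  for (ll in c(-8, -3, 0, 2, 5, 9)) {
    expect_lt(abs(as.numeric(reml_criterion(des, log_lambda = ll,
                                            scale = phi)) -
                  reml_mixed_oracle(des, des$y, ll, phi)), 1e-6)
  }
  ## order-1 penalty (no null-space direction) as well
  spec1 <- model_spec("y", "gaussian",
                      ordinal = list(ordinal_term("x", 6, 1)))
  des1 <- build_design(spec1, sim$data)
  for (ll in c(-4, 1, 6))
    expect_lt(abs(as.numeric(reml_criterion(des1, log_lambda = ll,
                                            scale = phi)) -
                  reml_mixed_oracle(des1, des1$y, ll, phi)), 1e-6)
})

test_that("ML criterion equals the profiled mixed-model marginal likelihood", {
  sim <- generate_ordinal_glm(n = 160, k = 5, family = "gaussian",
                              effect = c(0, 1, 2.2, 2.0, 3), seed = 13)
  spec <- model_spec("y", "gaussian",
                     ordinal = list(ordinal_term("x", 5, 2)))
  des <- build_design(spec, sim$data)
  for (ll in c(-4, 0, 3, 6))
    expect_lt(abs(as.numeric(reml_criterion(des, log_lambda = ll,
                                            method = "ML", scale = 0.8)) -
                  ml_mixed_oracle(des, des$y, ll, 0.8)), 1e-6)
})

test_that("smoothing selection finds an interior REML minimum on smooth-effect data", {
  sim <- generate_ordinal_glm(n = 2000, k = 8, family = "gaussian",
                              effect = sin(seq(0, pi, length.out = 8)) * 1.5,
                              seed = 17)
  spec <- model_spec("y", "gaussian",
                     ordinal = list(ordinal_term("x", 8, 2)))
  des <- build_design(spec, sim$data)
  grid <- seq(-12, 12, length.out = 41)
  crit <- vapply(grid, function(ll)
    as.numeric(reml_criterion(des, log_lambda = ll)), numeric(1))
  expect_true(all(is.finite(crit)))
  expect_gt(which.min(crit), 1)                   # interior minimum
  expect_lt(which.min(crit), 41)

  lam <- optimize_smoothing(des)
  ll_hat <- attr(lam, "log_lambda")
  c_hat <- as.numeric(reml_criterion(des, log_lambda = ll_hat))
  expect_lte(c_hat, min(crit) + 1e-6)             # beats the grid
  ## local-minimum certificate: a decade away in either direction is worse
  expect_gt(as.numeric(reml_criterion(des, log_lambda = ll_hat - log(10))),
            c_hat)
  expect_gt(as.numeric(reml_criterion(des, log_lambda = ll_hat + log(10))),
            c_hat)
})

test_that("null terms are driven to the boundary, active terms stay interior", {
  set.seed(31)
  n <- 900
  x1 <- sample.int(6, n, replace = TRUE)          # null term
  x2 <- sample.int(6, n, replace = TRUE)          # active, wiggly
  f2 <- c(0, 1.4, 0.2, 1.6, 0.1, 1.2)
  y <- rnorm(n, (f2 - mean(f2))[x2], 1)
  spec <- model_spec("y", "gaussian",
                     ordinal = list(ordinal_term("x1", 6, 1),
                                    ordinal_term("x2", 6, 1)))
  des <- build_design(spec, data.frame(y = y, x1 = x1, x2 = x2))
  lam <- suppressWarnings(optimize_smoothing(des))
  ll <- attr(lam, "log_lambda")
  expect_gte(ll[1], 11.5)                         # null: upper boundary
  expect_lt(abs(ll[2]), 11.5)                     # active: interior
})

test_that("fitted-model bookkeeping: intercept-only, GLM reduction, edf behaviour", {
  set.seed(41)
  y <- rbinom(200, 1, 0.35)
  fit0 <- quiet_fit(model_spec("y", "binomial"), data.frame(y = y))
  expect_equal(unname(fit0$beta), qlogis(mean(y)), tolerance = 1e-8)
  expect_equal(fit0$edf_total, 1, tolerance = 1e-8)

  ## with no ordinal terms the fit is the unpenalized GLM, SEs included
  sim <- generate_bpd_like(bpd_config(n = 200, seed = 6))
  fit <- quiet_fit(bpd_base_spec(), sim$data)
  gl <- stats::glm(bpd ~ weight_g + sga + sex_male + multiples +
                     steroid_days + antibiotic_days,
                   family = binomial, data = sim$data,
                   control = list(epsilon = 1e-12))
  expect_lt(max(abs(fit$beta - unname(coef(gl)))), 1e-6)
  expect_lt(max(abs(sqrt(diag(fit$Vb)) -
                    unname(summary(gl)$coefficients[, 2]))), 1e-6)

  ## term edf is non-increasing in that term's smoothing parameter
  simg <- generate_ordinal_glm(n = 300, k = 6, family = "gaussian",
                               effect = c(0, .5, 2, 1.8, 2.4, 3), seed = 19)
  specg <- model_spec("y", "gaussian",
                      ordinal = list(ordinal_term("x", 6, 1)))
  edfs <- vapply(c(1e-4, 1e-2, 1, 1e2, 1e4), function(l)
    quiet_fit(specg, simg$data, lambda = l)$edf[[1]], numeric(1))
  expect_true(all(diff(edfs) < 1e-10))
})

test_that("REML machinery agrees with mgcv on a penalized binomial fit", {
  skip_if_not_installed("mgcv")
  sim <- generate_ordinal_glm(n = 400, k = 7, family = "binomial",
                              effect = c(1.5, 1.2, .5, .2, 0, -.3, -.2),
                              seed = 5)
  spec <- model_spec("y", "binomial",
                     ordinal = list(ordinal_term("x", 7, 2)))
  des <- build_design(spec, sim$data)
  Z <- des$X[, des$term_cols[[1]]]
  gm <- mgcv::gam(des$y ~ Z, paraPen = list(Z = list(des$blocks[[1]]$S)),
                  family = binomial, method = "REML")
  ## same criterion value at mgcv's optimum, and same coefficients there
  expect_lt(abs(as.numeric(reml_criterion(des, log_lambda = log(gm$sp))) -
                gm$gcv.ubre), 1e-3)
  fit_at <- quiet_fit(spec, sim$data, lambda = gm$sp)
  expect_lt(max(abs(fit_at$beta - unname(coef(gm)))), 1e-5)
  expect_lt(abs(fit_at$edf_total - sum(gm$edf)), 1e-4)
})
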