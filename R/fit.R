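## Core penalized-likelihood machinery: penalized IRLS for fixed smoothing
## parameters, a Laplace-approximate REML/ML criterion, and grid-seeded
## derivative-free optimization of the log smoothing parameters.

## sum_j lambda_j S_j embedded in the full p x p coefficient space
total_penalty <- function(design, lambda) {
  p <- ncol(design$X)
  S <- matrix(0, p, p)
  J <- length(design$blocks)
  if (J == 0L) return(S)
  if (length(lambda) != J)
    stop("lambda must have one entry per ordinal term (", J, ")",
         call. = FALSE)
  for (j in seq_len(J)) {
    cols <- design$term_cols[[j]]
    S[cols, cols] <- S[cols, cols] + lambda[j] * design$blocks[[j]]$S
  }
  S
}

## exact log-likelihood at mu (phi enters only for gaussian)
family_loglik <- function(family, y, mu, phi = 1) {
  switch(family,
    binomial = sum(y * log(mu) + (1 - y) * log1p(-mu)),
    poisson  = sum(stats::dpois(y, mu, log = TRUE)),
    gaussian = {
      n <- length(y)
      -n / 2 * log(2 * pi * phi) - sum((y - mu)^2) / (2 * phi)
    })
}

init_mu <- function(family, y) {
  switch(family,
         binomial = (y + 0.5) / 2,
         poisson  = y + 0.1,
         gaussian = y)
}

#' Penalized iteratively reweighted least squares
#'
#' Minimizes `deviance(beta) + sum_j lambda_j t(beta_j) S_j beta_j` for fixed
#' smoothing parameters by Fisher scoring on the working model, with
#' step-halving on any increase of the penalized deviance. For the gaussian
#' identity model a single step gives the closed-form ridge-type solution.
#'
#' @param design A [build_design()] bundle.
#' @param y Response vector (defaults to the one stored in the design).
#' @param family Family name (defaults to the design's).
#' @param lambda Positive smoothing parameter per ordinal term.
#' @param beta0 Optional starting coefficients.
#' @param max_iter,tol_dev,tol_beta Convergence controls: stop when the
#'   relative penalized-deviance change is below `tol_dev` and the maximum
#'   coefficient change below `tol_beta`.
#' @return List with `beta`, working weights `w`, `eta`, `mu`, `deviance`,
#'   `penalized_deviance`, `converged`, `iter`.
#' @export
pirls <- function(design, y = design$y, family = design$family, lambda,
                  beta0 = NULL, max_iter = 200L, tol_dev = 1e-9,
                  tol_beta = 1e-8) {
  X <- design$X
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) != nrow(X)", call. = FALSE)
  check_response(y, family)
  if (length(design$blocks) && any(lambda <= 0))
    stop("all smoothing parameters must be positive", call. = FALSE)
  Sl <- total_penalty(design, lambda)
  fam <- family_object(family)

  dev_of <- function(mu) sum(fam$dev.resids(y, mu, rep(1, n)))
  pen_of <- function(beta) drop(crossprod(beta, Sl %*% beta))

  if (is.null(beta0)) {
    mu <- init_mu(family, y)
    eta <- fam$linkfun(mu)
    beta <- NULL
    pdev <- Inf
  } else {
    beta <- beta0
    eta <- drop(X %*% beta)
    mu <- fam$linkinv(eta)
    pdev <- dev_of(mu) + pen_of(beta)
  }

  converged <- FALSE
  iter <- 0L
  w <- rep(1, n)
  for (iter in seq_len(max_iter)) {
    mu_eta <- fam$mu.eta(eta)
    w <- mu_eta^2 / fam$variance(mu)
    z <- eta + (y - mu) / mu_eta
    sw <- sqrt(w)
    H <- crossprod(X * sw) + Sl
    R <- tryCatch(chol(H), error = function(e)
      stop("penalized Hessian is not positive definite; ",
           "check for collinear parametric columns", call. = FALSE))
    beta_new <- backsolve(R, forwardsolve(t(R), crossprod(X, w * z)))
    beta_new <- drop(beta_new)

    ## step-halving on penalized-deviance increase
    step <- 1
    halvings <- 0L
    repeat {
      beta_try <- if (is.null(beta)) beta_new else
        beta + step * (beta_new - beta)
      eta_try <- drop(X %*% beta_try)
      mu_try <- fam$linkinv(eta_try)
      pdev_try <- dev_of(mu_try) + pen_of(beta_try)
      if (is.finite(pdev_try) &&
          (pdev_try <= pdev + 1e-12 * (1 + abs(pdev)) || is.null(beta)))
        break
      halvings <- halvings + 1L
      if (halvings > 30L) break
      step <- step / 2
    }

    dbeta <- if (is.null(beta)) Inf else max(abs(beta_try - beta))
    ddev <- abs(pdev - pdev_try) / (1 + abs(pdev_try))
    beta <- beta_try; eta <- eta_try; mu <- mu_try; pdev <- pdev_try
    if (ddev < tol_dev && dbeta < tol_beta) {
      converged <- TRUE
      break
    }
  }
  names(beta) <- colnames(X)
  mu_eta <- fam$mu.eta(eta)
  w <- mu_eta^2 / fam$variance(mu)
  list(beta = beta, w = w, eta = eta, mu = mu,
       deviance = dev_of(mu), penalized_deviance = pdev,
       converged = converged, iter = iter)
}

## orthonormal basis of the total-penalty null space restricted to smooth
## columns, embedded in R^p, together with the always-unpenalized
## parametric columns; used by the ML criterion.
unpenalized_basis <- function(design) {
  p <- ncol(design$X)
  cols <- design$para_cols
  N <- matrix(0, p, length(cols))
  N[cbind(cols, seq_along(cols))] <- 1
  for (j in seq_along(design$blocks)) {
    bb <- design$blocks[[j]]
    if (bb$nullspace_dim > 0L) {
      ev <- eigen(bb$S, symmetric = TRUE)
      null_vec <- ev$vectors[, ncol(bb$S) - seq_len(bb$nullspace_dim) + 1L,
                             drop = FALSE]
      Nj <- matrix(0, p, bb$nullspace_dim)
      Nj[design$term_cols[[j]], ] <- null_vec
      N <- cbind(N, Nj)
    }
  }
  N
}

#' Laplace-approximate REML / ML criterion
#'
#' Negative restricted (or marginal) log-likelihood of the smoothing
#' parameters, using the Laplace approximation at the penalized MLE. For the
#' gaussian identity model the approximation is exact and the criterion
#' equals the restricted log-likelihood of the equivalent linear mixed
#' model. For binomial/poisson the scale is fixed at 1; for gaussian an
#' unknown scale is profiled out REML-style.
#'
#' @inheritParams pirls
#' @param log_lambda Vector of log smoothing parameters.
#' @param method `"REML"` (default) or `"ML"`.
#' @param scale Known dispersion; `NULL` profiles it (gaussian only).
#' @param fit Optional pre-computed [pirls()] result at these smoothing
#'   parameters (avoids refitting).
#' @return The criterion value (smaller is better), with the inner fit
#'   attached as attribute `"fit"`.
#' @export
reml_criterion <- function(design, y = design$y, family = design$family,
                           log_lambda, method = c("REML", "ML"),
                           scale = NULL, fit = NULL) {
  method <- match.arg(method)
  lambda <- exp(log_lambda)
  if (is.null(fit)) fit <- pirls(design, y, family, lambda)
  if (!fit$converged)
    warning("inner PIRLS did not converge at log(lambda) = ",
            paste(signif(log_lambda, 3), collapse = ", "), call. = FALSE)
  X <- design$X
  n <- nrow(X); p <- ncol(X)
  Sl <- total_penalty(design, lambda)
  P <- drop(crossprod(fit$beta, Sl %*% fit$beta))
  H <- crossprod(X * sqrt(fit$w)) + Sl
  R <- tryCatch(chol(H), error = function(e)
    stop("penalized Hessian indefinite at log(lambda) = ",
         paste(signif(log_lambda, 3), collapse = ", "),
         "; consider a stronger smoothing-parameter floor", call. = FALSE))
  ldetH <- 2 * sum(log(diag(R)))

  ranks <- vapply(design$blocks, `[[`, numeric(1), "rank")
  ldS <- vapply(design$blocks, `[[`, numeric(1), "logdet_plus")
  r_tot <- sum(ranks)
  Mp <- p - r_tot
  ldetS <- sum(ranks * log_lambda) + sum(ldS)

  phi <- scale
  if (is.null(phi)) {
    if (family == "gaussian") {
      dof <- if (method == "REML") n - Mp else n
      phi <- (fit$deviance + P) / dof
    } else phi <- 1
  }

  ll <- family_loglik(family, y, fit$mu, phi)

  if (method == "REML") {
    crit <- -(ll - P / (2 * phi)
              + 0.5 * (ldetS - r_tot * log(phi))
              - 0.5 * (ldetH - p * log(phi))
              + 0.5 * Mp * log(2 * pi))
  } else {
    ## ML: fixed (unpenalized) directions profiled, not integrated out, so
    ## the Laplace determinant is over the penalized block of H only
    N <- unpenalized_basis(design)
    Q <- qr.Q(qr(N), complete = TRUE)[, -seq_len(ncol(N)), drop = FALSE]
    HQ <- crossprod(Q, H %*% Q)
    ldetHQ <- 2 * sum(log(diag(chol(HQ))))
    crit <- -(ll - P / (2 * phi)
              + 0.5 * (ldetS - r_tot * log(phi))
              - 0.5 * (ldetHQ - r_tot * log(phi)))
  }
  attr(crit, "fit") <- fit
  attr(crit, "scale") <- phi
  crit
}

#' Select smoothing parameters by REML or ML
#'
#' Minimizes [reml_criterion()] over `log(lambda) in [-12, 12]^J`: a coarse
#' grid (5 points per dimension) seeds a derivative-free local search
#' (Brent for one term, Nelder-Mead otherwise). A solution within 0.5 of
#' the box boundary triggers a warning: the term is then effectively
#' unpenalized (lower boundary) or shrunk to its penalty null space (upper
#' boundary).
#'
#' @inheritParams reml_criterion
#' @param method `"REML"` or `"ML"`.
#' @return Named vector of selected smoothing parameters, with attributes
#'   `"log_lambda"`, `"criterion"`, and `"boundary"`.
#' @export
optimize_smoothing <- function(design, y = design$y, family = design$family,
                               method = c("REML", "ML"), scale = NULL) {
  method <- match.arg(method)
  J <- length(design$blocks)
  if (J == 0L)
    return(structure(numeric(0), log_lambda = numeric(0),
                     criterion = NA_real_, boundary = logical(0)))
  box <- c(-12, 12)
  obj <- function(ll) {
    ll <- pmin(pmax(ll, box[1]), box[2])
    tryCatch(
      as.numeric(suppressWarnings(
        reml_criterion(design, y, family, ll, method, scale))),
      error = function(e) Inf)
  }

  grid1 <- seq(box[1], box[2], length.out = 5)
  grid <- as.matrix(expand.grid(rep(list(grid1), J)))
  vals <- apply(grid, 1L, obj)
  if (!any(is.finite(vals)))
    stop("smoothing criterion not finite anywhere on the seeding grid",
         call. = FALSE)
  start <- grid[which.min(vals), ]

  if (J == 1L) {
    lo <- max(box[1], start - 6); hi <- min(box[2], start + 6)
    opt <- stats::optimize(obj, c(lo, hi), tol = 1e-6)
    ll_hat <- opt$minimum
    crit <- opt$objective
    ## accept a grid boundary point if the interior search did not beat it
    if (min(vals) < crit) { ll_hat <- start; crit <- min(vals) }
  } else {
    opt <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-9, maxit = 1000L))
    ll_hat <- pmin(pmax(opt$par, box[1]), box[2])
    crit <- opt$value
  }
  boundary <- abs(ll_hat) >= 11.5
  if (any(boundary))
    warning("smoothing parameter(s) at the search boundary for term(s): ",
            paste(names(design$blocks)[boundary], collapse = ", "),
            " (effect effectively unpenalized or shrunk to its null space)",
            call. = FALSE)
  lambda <- exp(ll_hat)
  names(lambda) <- names(design$blocks)
  structure(lambda, log_lambda = ll_hat, criterion = crit,
            boundary = boundary)
}

## shared by fit_gam and the calibration loop: fit at given / selected
## lambda on a pre-built design, fill posterior quantities
fit_from_design <- function(design, y = design$y, method = "REML",
                            lambda = NULL, scale = NULL) {
  J <- length(design$blocks)
  family <- design$family
  boundary <- logical(J)
  criterion_value <- NA_real_
  if (J > 0L && is.null(lambda)) {
    lam <- optimize_smoothing(design, y, family, method, scale)
    boundary <- attr(lam, "boundary")
    criterion_value <- attr(lam, "criterion")
    lambda <- as.numeric(lam)
  } else if (J > 0L) {
    lambda <- rep_len(as.numeric(lambda), J)
  } else lambda <- numeric(0)
  names(lambda) <- names(design$blocks)

  fit <- pirls(design, y, family, lambda)
  X <- design$X
  n <- nrow(X); p <- ncol(X)
  Sl <- total_penalty(design, lambda)
  XtWX <- crossprod(X * sqrt(fit$w))
  H <- XtWX + Sl
  Hinv <- chol2inv(chol(H))
  Fmat <- Hinv %*% XtWX
  edf_all <- diag(Fmat)
  ## upper-bound edf accounting for smoothing bias, tr(2F - FF); its
  ## per-term share is the reference rank of the smooth-term Wald test
  edf1_all <- 2 * edf_all - rowSums(Fmat * t(Fmat))
  edf_term <- vapply(seq_len(J), function(j)
    sum(edf_all[design$term_cols[[j]]]), numeric(1))
  edf1_term <- vapply(seq_len(J), function(j)
    sum(edf1_all[design$term_cols[[j]]]), numeric(1))
  names(edf_term) <- names(edf1_term) <- names(design$blocks)
  edf_total <- sum(edf_all)

  phi <- scale
  if (is.null(phi)) {
    phi <- if (family == "gaussian")
      fit$deviance / (n - edf_total) else 1
  }
  Vb <- phi * Hinv
  dimnames(Vb) <- list(colnames(X), colnames(X))

  ## intercept-only (unpenalized) deviance for reference
  null_dev <- {
    fam <- family_object(family)
    mu0 <- rep(mean(y), n)
    sum(fam$dev.resids(y, mu0, rep(1, n)))
  }

  structure(list(
    beta = fit$beta, lambda = lambda,
    log_lambda = if (J) log(lambda) else numeric(0),
    Vb = Vb, edf = edf_term, edf1 = edf1_term, edf_total = edf_total,
    deviance = fit$deviance, null_deviance = null_dev,
    penalized_deviance = fit$penalized_deviance,
    criterion = method, criterion_value = criterion_value,
    scale = phi, converged = fit$converged, boundary = boundary,
    iterations = c(inner = fit$iter),
    w = fit$w, mu = fit$mu, eta = fit$eta,
    design = design, spec = design$spec, nobs = n
  ), class = "ordsmooth_fit")
}

#' Fit a penalized GLM with ordinal smooth terms
#'
#' Entry point composing [build_design()], [optimize_smoothing()] and
#' [pirls()]: assembles the design, selects the smoothing parameters by
#' Laplace-approximate REML (or ML), refits at the selected values, and
#' fills the Bayesian posterior covariance
#' \eqn{V_\beta = \phi (X^T W X + \sum_j \lambda_j S_j)^{-1}}, per-term
#' effective degrees of freedom, deviances and convergence diagnostics.
#'
#' @inheritParams build_design
#' @param method Smoothing-selection criterion, `"REML"` (default) or
#'   `"ML"`.
#' @param lambda Optional fixed smoothing parameters (skips selection);
#'   mainly for limit checks.
#' @param scale Known dispersion, or `NULL` to fix it at 1
#'   (binomial/poisson) or estimate it (gaussian).
#' @return An object of class `"ordsmooth_fit"`.
#' @seealso [summary.ordsmooth_fit()], [smooth_test()], [coef_curve()],
#'   [predict.ordsmooth_fit()]
#' @examples
#' sim <- generate_ordinal_glm(n = 300, k = 5, family = "gaussian",
#'                             effect = c(0, 0.5, 1.5, 1.6, 1.7), seed = 1)
#' spec <- model_spec("y", "gaussian",
#'                    ordinal = list(ordinal_term("x", k = 5, order = 2)))
#' fit <- fit_gam(spec, sim$data)
#' summary(fit)
#' @export
fit_gam <- function(spec, data, method = c("REML", "ML"), lambda = NULL,
                    scale = NULL, constraint = "sumzero") {
  method <- match.arg(method)
  design <- build_design(spec, data, constraint)
  fit_from_design(design, method = method, lambda = lambda, scale = scale)
}

#' @export
print.ordsmooth_fit <- function(x, ...) {
  cat("Penalized GLM with ordinal smooth terms (", x$spec$family,
      ", ", x$criterion, ")\n", sep = "")
  cat("n =", x$nobs, " coefficients =", length(x$beta),
      " total edf =", signif(x$edf_total, 4), "\n")
  if (length(x$lambda)) {
    cat("Smoothing parameters (log scale):\n")
    print(signif(x$log_lambda, 4))
  }
  cat("Deviance:", signif(x$deviance, 6),
      " Null deviance:", signif(x$null_deviance, 6), "\n")
  if (!x$converged) cat("WARNING: fit did not converge\n")
  invisible(x)
}

#' @export
coef.ordsmooth_fit <- function(object, ...) object$beta

#' @export
fitted.ordsmooth_fit <- function(object, ...) object$mu
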