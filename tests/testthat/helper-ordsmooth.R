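## shared fixtures and independent oracles for the test suite

## fit with warnings/messages silenced (boundary smoothing parameters and
## unobserved sparse levels are routine in simulation loops)
quiet_fit <- function(...) suppressWarnings(suppressMessages(fit_gam(...)))

bpd_parametric <- c("weight_g", "sga", "sex_male", "multiples",
                    "steroid_days", "antibiotic_days")

bpd_base_spec <- function() {
  model_spec("bpd", "binomial", parametric = bpd_parametric)
}

bpd_full_spec <- function(order = 2) {
  model_spec("bpd", "binomial", parametric = bpd_parametric,
             ordinal = list(ordinal_term("gram_neg", 7, order),
                            ordinal_term("gram_pos", 7, order),
                            ordinal_term("pathogenic", 7, order)))
}

## independent closed-form restricted log-likelihood of the equivalent
## linear mixed model (V-matrix route), for a gaussian fit with a single
## ordinal smooth term and known scale phi; negated so that it is directly
## comparable with reml_criterion()
reml_mixed_oracle <- function(design, y, log_lambda, phi) {
  X <- design$X
  n <- nrow(X)
  bb <- design$blocks[[1]]
  cols <- design$term_cols[[1]]
  eg <- eigen(bb$S, symmetric = TRUE)
  r <- bb$rank
  Ur <- eg$vectors[, seq_len(r), drop = FALSE]
  dr <- eg$values[seq_len(r)]
  Zr <- X[, cols, drop = FALSE] %*% Ur %*% diag(1 / sqrt(dr), r)
  Xf <- X[, setdiff(seq_len(ncol(X)), cols), drop = FALSE]
  if (bb$nullspace_dim > 0) {
    nv <- eg$vectors[, (r + 1):(r + bb$nullspace_dim), drop = FALSE]
    Xf <- cbind(Xf, X[, cols, drop = FALSE] %*% nv)
  }
  lambda <- exp(log_lambda)
  V <- phi * diag(n) + (phi / lambda) * tcrossprod(Zr)
  Vi <- solve(V)
  XtVX <- crossprod(Xf, Vi %*% Xf)
  P <- Vi - Vi %*% Xf %*% solve(XtVX, t(Xf) %*% Vi)
  Mf <- ncol(Xf)
  0.5 * (as.numeric(determinant(V)$modulus) +
         as.numeric(determinant(XtVX)$modulus) +
         drop(t(y) %*% P %*% y) + (n - Mf) * log(2 * pi))
}

## profiled (fixed effects maximized, random integrated) gaussian marginal
## likelihood oracle for the ML criterion, same setting as above
ml_mixed_oracle <- function(design, y, log_lambda, phi) {
  X <- design$X
  n <- nrow(X)
  bb <- design$blocks[[1]]
  cols <- design$term_cols[[1]]
  eg <- eigen(bb$S, symmetric = TRUE)
  r <- bb$rank
  Ur <- eg$vectors[, seq_len(r), drop = FALSE]
  dr <- eg$values[seq_len(r)]
  Zr <- X[, cols, drop = FALSE] %*% Ur %*% diag(1 / sqrt(dr), r)
  Xf <- X[, setdiff(seq_len(ncol(X)), cols), drop = FALSE]
  if (bb$nullspace_dim > 0) {
    nv <- eg$vectors[, (r + 1):(r + bb$nullspace_dim), drop = FALSE]
    Xf <- cbind(Xf, X[, cols, drop = FALSE] %*% nv)
  }
  lambda <- exp(log_lambda)
  V <- phi * diag(n) + (phi / lambda) * tcrossprod(Zr)
  Vi <- solve(V)
  bh <- solve(crossprod(Xf, Vi %*% Xf), crossprod(Xf, Vi %*% y))
  resid <- y - Xf %*% bh
  0.5 * (as.numeric(determinant(V)$modulus) +
         drop(t(resid) %*% Vi %*% resid) + n * log(2 * pi))
}

## moore-penrose pseudoinverse through svd (independent of the eigen route
## used inside smooth_test)
svd_pinv <- function(A, tol = 1e-8) {
  sv <- svd(A)
  pos <- sv$d > tol * max(sv$d)
  sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}
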