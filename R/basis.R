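#' Declare an ordinal smooth term
#'
#' An ordinal predictor with levels coded `1..k` enters the model through a
#' dummy (one-hot) basis, one indicator function per level, with a quadratic
#' difference penalty on adjacent level coefficients. The penalty order
#' controls what the term shrinks towards as the smoothing parameter grows:
#' order 1 shrinks the level coefficients towards a common constant, order 2
#' towards a straight line in the level index.
#'
#' @param name Column name of the ordinal predictor (integer levels `1..k`).
#' @param k Number of levels, at least 3. A 2-level ordinal factor has no
#'   interior structure to smooth; include it as a parametric binary term
#'   instead.
#' @param order Difference-penalty order, 1 or 2. After the sum-to-zero
#'   identifiability constraint the penalty null space has dimension
#'   `order - 1`: zero for order 1, one (the centred linear trend) for
#'   order 2.
#' @return An object of class `"ordinal_term"`.
#' @examples
#' ordinal_term("week_first_detection", k = 7, order = 2)
#' @export
ordinal_term <- function(name, k, order = 2) {
  if (!is.character(name) || length(name) != 1L || is.na(name) || !nzchar(name))
    stop("'name' must be a single non-empty string", call. = FALSE)
  k <- as.integer(k)
  order <- as.integer(order)
  if (is.na(k) || k < 3L)
    stop("ordinal term '", name, "': k must be an integer >= 3; ",
         "a 2-level ordinal factor has no interior structure -- ",
         "use a parametric binary term instead", call. = FALSE)
  if (is.na(order) || !order %in% c(1L, 2L))
    stop("ordinal term '", name, "': penalty order must be 1 or 2",
         call. = FALSE)
  structure(list(name = name, k = k, order = order), class = "ordinal_term")
}

#' @export
print.ordinal_term <- function(x, ...) {
  cat("Ordinal smooth term '", x$name, "': ", x$k, " levels, order-",
      x$order, " difference penalty\n", sep = "")
  invisible(x)
}

#' Dummy (one-hot) indicator matrix for an ordinal predictor
#'
#' Row i carries a single 1 in the column of the observed level `x[i]`.
#' Unobserved levels are permitted (all-zero column) but flagged with a
#' warning, because the corresponding coefficient is then identified only
#' through the smoothing penalty.
#'
#' @param x Integer vector of observed levels, each in `1..k`.
#' @param k Number of levels.
#' @return An `n x k` binary matrix.
#' @export
indicator_matrix <- function(x, k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer", call. = FALSE)
  if (length(x) == 0L) stop("empty level vector", call. = FALSE)
  xn <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(xn) | !is.finite(xn) | xn != round(xn) | xn < 1 | xn > k)
  if (length(bad))
    stop("ordinal levels must be integers in 1..", k,
         "; offending row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) ", ..." else "", call. = FALSE)
  xi <- as.integer(xn)
  B <- matrix(0, length(xi), k)
  B[cbind(seq_along(xi), xi)] <- 1
  unobs <- setdiff(seq_len(k), unique(xi))
  if (length(unobs))
    warning("unobserved ordinal level(s) ",
            paste(unobs, collapse = ", "),
            ": coefficient(s) identified only through the penalty",
            call. = FALSE)
  B
}

#' Difference matrix of order 1 or 2
#'
#' Returns the `(k - order) x k` matrix `D` such that `D %*% beta` is the
#' vector of adjacent first differences (order 1) or second differences
#' (order 2) of the level coefficients, so that the penalty is `||D beta||^2`.
#'
#' @param k Number of levels.
#' @param order Difference order, 1 or 2.
#' @export
difference_matrix <- function(k, order) {
  k <- as.integer(k); order <- as.integer(order)
  if (!order %in% c(1L, 2L)) stop("order must be 1 or 2", call. = FALSE)
  if (k <= order)
    stop("k must exceed the penalty order (k = ", k, ", order = ", order, ")",
         call. = FALSE)
  diff(diag(k), differences = order)
}

#' Difference-penalty matrix S = t(D) D
#'
#' Symmetric positive semidefinite `k x k` matrix representing the quadratic
#' difference penalty: `t(beta) %*% S %*% beta` equals the sum of squared
#' order-`order` adjacent differences of `beta`. Its rank is `k - order`;
#' constant vectors (and, for order 2, vectors linear in the level index)
#' span the null space.
#'
#' @inheritParams difference_matrix
#' @export
penalty_matrix <- function(k, order) {
  D <- difference_matrix(k, order)
  S <- crossprod(D)
  (S + t(S)) / 2
}

#' Evaluate the difference penalty for a coefficient vector
#'
#' Direct evaluation of the sum of squared adjacent differences,
#' `sum(diff(beta, differences = order)^2)`; equals the quadratic form
#' `t(beta) %*% penalty_matrix(k, order) %*% beta`.
#'
#' @param beta Numeric vector of level coefficients (length `k`).
#' @param order Difference order, 1 or 2.
#' @export
penalty_value <- function(beta, order) {
  order <- as.integer(order)
  if (!order %in% c(1L, 2L)) stop("order must be 1 or 2", call. = FALSE)
  if (length(beta) <= order)
    stop("beta must have length greater than the penalty order", call. = FALSE)
  sum(diff(beta, differences = order)^2)
}

## identifiability reparameterizations: beta_full = C %*% theta,
## with C a k x (k-1) map whose column space excludes (sumzero) or
## complements (droplevel) the constrained direction.
constraint_map <- function(k, type = c("sumzero", "droplevel")) {
  type <- match.arg(type)
  if (type == "sumzero") {
    ## orthonormal complement of the ones vector; guarantees t(1) C = 0
    qr.Q(qr(matrix(1, k, 1)), complete = TRUE)[, -1L, drop = FALSE]
  } else {
    rbind(0, diag(k - 1L))
  }
}

#' Build the constrained basis block for an ordinal term
#'
#' Expands the observed levels into the dummy basis, applies the
#' identifiability constraint (by default: level coefficients sum to zero,
#' absorbed by reparameterizing onto the orthogonal complement of the ones
#' vector), and transforms the difference penalty accordingly. The returned
#' block carries the constrained design `Z`, the constrained penalty `S`
#' (symmetric PSD, rank `k - order`), the back-transform `C` from constrained
#' coefficients to the full `k` level coefficients, and the dimension of the
#' penalty null space after constraint (`order - 1`).
#'
#' @param term An [ordinal_term()].
#' @param x Integer vector of observed levels in `1..k`.
#' @param type Identifiability constraint: `"sumzero"` (default) or
#'   `"droplevel"` (level-1 coefficient pinned to zero; mainly for
#'   invariance checks -- fitted values and smooth tests do not depend on
#'   the choice).
#' @return An object of class `"basis_block"`.
#' @export
constrain <- function(term, x, type = c("sumzero", "droplevel")) {
  stopifnot(inherits(term, "ordinal_term"))
  type <- match.arg(type)
  k <- term$k
  B <- indicator_matrix(x, k)
  C <- constraint_map(k, type)
  Z <- B %*% C
  S_full <- penalty_matrix(k, term$order)
  S <- crossprod(C, S_full %*% C)
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev)))
    stop("constrained penalty not positive semidefinite", call. = FALSE)
  ev <- pmax(ev, 0)
  r <- k - term$order                    # penalized rank after constraint
  structure(list(
    term = term,
    Z = Z,
    S = S,
    C = C,
    nullspace_dim = term$order - 1L,
    rank = r,
    logdet_plus = sum(log(ev[seq_len(r)]))
  ), class = "basis_block")
}
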