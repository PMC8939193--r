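#' Specify a penalized GLM with ordinal smooth terms
#'
#' Describes the model \eqn{\eta = \alpha + x^T\gamma + \sum_j f_j(o_j)},
#' \eqn{\mu = h(\eta)}: a binary, count, or continuous response with its
#' canonical link, parametric (linear) covariates, and ordinal predictors
#' entering through the penalized dummy basis.
#'
#' @param response Name of the response column (0/1 for binomial,
#'   nonnegative counts for poisson, numeric for gaussian).
#' @param family One of `"binomial"`, `"gaussian"`, `"poisson"`; the
#'   canonical link (logit / identity / log) is used.
#' @param parametric Character vector of column names entering linearly
#'   (may be empty for an intercept-only or smooth-only model).
#' @param ordinal List of [ordinal_term()] objects (may be empty, in which
#'   case the model is an ordinary GLM).
#' @return An object of class `"model_spec"`.
#' @examples
#' model_spec("bpd", "binomial",
#'   parametric = c("weight_g", "sex_male"),
#'   ordinal = list(ordinal_term("pathogenic", k = 7, order = 2)))
#' @export
model_spec <- function(response,
                       family = c("binomial", "gaussian", "poisson"),
                       parametric = character(),
                       ordinal = list()) {
  family <- match.arg(family)
  if (!is.character(response) || length(response) != 1L || !nzchar(response))
    stop("'response' must be a single column name", call. = FALSE)
  if (length(parametric) && !is.character(parametric))
    stop("'parametric' must be a character vector of column names",
         call. = FALSE)
  if (inherits(ordinal, "ordinal_term")) ordinal <- list(ordinal)
  if (!all(vapply(ordinal, inherits, logical(1), "ordinal_term")))
    stop("'ordinal' must be a list of ordinal_term objects", call. = FALSE)
  ord_names <- vapply(ordinal, `[[`, character(1), "name")
  all_pred <- c(parametric, ord_names)
  if (anyDuplicated(all_pred))
    stop("duplicate predictor name(s): ",
         paste(unique(all_pred[duplicated(all_pred)]), collapse = ", "),
         call. = FALSE)
  if (response %in% all_pred)
    stop("response column '", response, "' also appears as a predictor",
         call. = FALSE)
  structure(list(response = response, family = family,
                 parametric = parametric, ordinal = ordinal),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Model spec: ", x$response, " ~ ", sep = "")
  rhs <- c(x$parametric,
           vapply(x$ordinal, function(t)
             sprintf("s(%s, k = %d, m = %d)", t$name, t$k, t$order),
             character(1)))
  cat(if (length(rhs)) paste(rhs, collapse = " + ") else "1", "\n")
  cat("Family:", x$family, "(canonical link)\n")
  invisible(x)
}

family_object <- function(family) {
  switch(family,
         binomial = stats::binomial(),
         gaussian = stats::gaussian(),
         poisson  = stats::poisson(),
         stop("unsupported family: ", family, call. = FALSE))
}

check_response <- function(y, family) {
  if (!is.numeric(y) || anyNA(y) || any(!is.finite(y)))
    stop("response must be numeric with no missing/non-finite values",
         call. = FALSE)
  if (family == "binomial" && !all(y %in% c(0, 1)))
    stop("binomial response must be coded 0/1", call. = FALSE)
  if (family == "poisson" && (any(y < 0) || any(y != round(y))))
    stop("poisson response must be nonnegative integer counts", call. = FALSE)
  invisible(y)
}

#' Assemble the model matrix and penalty blocks
#'
#' Builds the full design: intercept column first, then parametric columns
#' as supplied (no standardization), then one constrained dummy block per
#' ordinal term. Rows with missing values in any used column are dropped
#' with a message. The per-term penalty matrices are returned aligned with
#' the column ranges they act on.
#'
#' @param spec A [model_spec()].
#' @param data Data frame with one row per subject.
#' @param constraint Identifiability constraint passed to [constrain()].
#' @return An object of class `"design_bundle"` with elements `X`, `y`,
#'   `blocks`, `term_cols` (name -> column indices), `para_cols`,
#'   `family`, `nobs`.
#' @export
build_design <- function(spec, data, constraint = "sumzero") {
  stopifnot(inherits(spec, "model_spec"))
  data <- as.data.frame(data)
  ord_names <- vapply(spec$ordinal, `[[`, character(1), "name")
  used <- c(spec$response, spec$parametric, ord_names)
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols))
    stop("column(s) not found in data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  keep <- stats::complete.cases(data[used])
  if (!all(keep)) {
    message("dropping ", sum(!keep), " row(s) with missing values")
    data <- data[keep, , drop = FALSE]
  }
  n <- nrow(data)
  if (n == 0L) stop("no complete rows left in data", call. = FALSE)

  y <- check_response(data[[spec$response]], spec$family)

  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  para_cols <- integer(0)
  for (v in spec$parametric) {
    col <- data[[v]]
    if (!is.numeric(col))
      stop("parametric column '", v, "' must be numeric", call. = FALSE)
    if (any(!is.finite(col)))
      stop("non-finite values in parametric column '", v, "'", call. = FALSE)
    if (stats::var(col) == 0)
      warning("parametric column '", v, "' is constant; kept as supplied",
              call. = FALSE)
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- v
    para_cols <- c(para_cols, ncol(X))
  }

  blocks <- list()
  term_cols <- list()
  for (term in spec$ordinal) {
    bb <- constrain(term, data[[term$name]], type = constraint)
    cols <- ncol(X) + seq_len(ncol(bb$Z))
    colnames(bb$Z) <- paste0(term$name, ".", seq_len(ncol(bb$Z)))
    X <- cbind(X, bb$Z)
    blocks[[term$name]] <- bb
    term_cols[[term$name]] <- cols
  }

  structure(list(X = X, y = y, blocks = blocks, term_cols = term_cols,
                 para_cols = c(1L, para_cols), family = spec$family,
                 spec = spec, constraint = constraint, nobs = n,
                 data = data[used]),
            class = "design_bundle")
}
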