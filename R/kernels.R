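#' Specify an additive signal kernel
#'
#' Builds the kernel used to regress one variable on a set of candidate
#' ancestors. Three nested families are available on variables
#' \eqn{x = (x_1, \dots, x_m)}:
#' \describe{
#'   \item{linear}{\eqn{K(x,x') = 1 + \beta_1 \sum_i x_i x_i'}}
#'   \item{quadratic}{adds \eqn{\beta_2 \sum_{i \le j} x_i x_j x_i' x_j'}
#'     (squares and cross products, each unordered pair counted once)}
#'   \item{nonlinear}{adds \eqn{\beta_3 \prod_i (1 + k(x_i, x_i'))} with a
#'     universal base kernel \eqn{k} (Gaussian or Matérn 5/2, unit scale)}
#' }
#' All kernels contain the constant 1, so the constant function is always in
#' the hypothesis space. Defaults are \eqn{\beta_i = 0.1} and unit base-kernel
#' parameters; the data are assumed standardized, so no bandwidths are learned.
#'
#' @param family One of `"linear"`, `"quadratic"`, `"nonlinear"`.
#' @param variables Character vector of the active variable names, in the
#'   column order the kernel expects.
#' @param beta1,beta2,beta3 Nonnegative weights of the linear, quadratic and
#'   nonlinear blocks. Blocks absent from `family` are ignored.
#' @param base Base kernel for the nonlinear block: `"gaussian"`
#'   (\eqn{k(u,v) = \exp(-(u-v)^2/2)}) or `"matern"` (Matérn 5/2, unit scale).
#' @return An object of class `"kernel_spec"`.
#' @seealso [kernel_matrix()], [kernel_split()], [feature_map()]
#' @export
kernel_spec <- function(family = c("linear", "quadratic", "nonlinear"),
                        variables = character(),
                        beta1 = 0.1, beta2 = 0.1, beta3 = 0.1,
                        base = c("gaussian", "matern")) {
  family <- match.arg(family)
  base <- match.arg(base)
  variables <- as.character(variables)
  if (anyDuplicated(variables))
    stop("duplicate variable names in kernel spec", call. = FALSE)
  for (b in c(beta1, beta2, beta3))
    if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b < 0)
      stop("beta weights must be single nonnegative numbers", call. = FALSE)
  structure(
    list(family = family, variables = variables,
         beta1 = beta1, beta2 = beta2, beta3 = beta3, base = base),
    class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("<kernel_spec> %s kernel on %d variable(s)\n",
              x$family, length(x$variables)))
  betas <- switch(x$family,
    linear = sprintf("beta1=%g", x$beta1),
    quadratic = sprintf("beta1=%g beta2=%g", x$beta1, x$beta2),
    nonlinear = sprintf("beta1=%g beta2=%g beta3=%g base=%s",
                        x$beta1, x$beta2, x$beta3, x$base))
  cat(" ", betas, "\n")
  invisible(x)
}

# base kernel gram between two numeric vectors (unit parameters)
.base_gram <- function(u, v, base) {
  d <- outer(u, v, "-")
  if (base == "gaussian") {
    exp(-d^2 / 2)
  } else { # matern 5/2, unit length-scale
    r <- abs(d)
    (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r)
  }
}

.check_rows <- function(x, spec, what) {
  x <- as.matrix(x)
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop(what, ": rows must be finite numeric", call. = FALSE)
  m <- length(spec$variables)
  if (ncol(x) != m)
    stop(sprintf("%s: %d column(s) but kernel spec has %d variable(s)",
                 what, ncol(x), m), call. = FALSE)
  if (!is.null(colnames(x)) && m > 0 && !identical(colnames(x), spec$variables))
    stop(what, ": column names do not match kernel spec variable order",
         call. = FALSE)
  x
}

#' Evaluate the Gram matrix of an additive kernel
#'
#' @param spec A [kernel_spec()].
#' @param x Numeric matrix (rows = samples, columns = `spec$variables`, in
#'   order). Column names, when present, must match the spec.
#' @param y Optional second sample matrix on the same variables; defaults to
#'   `x`, giving a symmetric positive semidefinite Gram matrix.
#' @return A `nrow(x)` by `nrow(y)` matrix.
#' @export
kernel_matrix <- function(spec, x, y = x) {
  stopifnot(inherits(spec, "kernel_spec"))
  x <- .check_rows(x, spec, "x")
  y <- .check_rows(y, spec, "y")
  K <- matrix(1, nrow(x), nrow(y))
  if (length(spec$variables) == 0L) return(K)
  S <- tcrossprod(x, y)
  K <- K + spec$beta1 * S
  if (spec$family %in% c("quadratic", "nonlinear")) {
    # sum_{i<=j} x_i x_j x_i' x_j' = (S^2 + sum_i x_i^2 x_i'^2) / 2
    K <- K + spec$beta2 * (S^2 + tcrossprod(x^2, y^2)) / 2
  }
  if (spec$family == "nonlinear") {
    P <- matrix(1, nrow(x), nrow(y))
    for (i in seq_along(spec$variables))
      P <- P * (1 + .base_gram(x[, i], y[, i], spec$base))
    K <- K + spec$beta3 * P
  }
  K
}

#' Split a kernel along one variable
#'
#' Decomposes the additive kernel as \eqn{K_s = K_1 + K_2}, where \eqn{K_1}
#' collects every term not involving the excluded variable (it is the same
#' kernel family on the remaining variables) and \eqn{K_2 = K_s - K_1}
#' collects every term that does. Both parts are positive semidefinite, so
#' the fitted function decomposes as \eqn{f = f_1 + f_2} with
#' \eqn{\|f\|^2_{K_s} = \|f_1\|^2_{K_1} + \|f_2\|^2_{K_2}}; the second norm
#' measures the excluded variable's contribution to the signal.
#'
#' @param spec A [kernel_spec()].
#' @param variable Name of the variable to split out; must belong to
#'   `spec$variables`.
#' @return An object of class `"kernel_split"` with elements `spec` (the full
#'   kernel), `excluded` (the variable), and `k1_spec` (the kernel on the
#'   remaining variables).
#' @export
kernel_split <- function(spec, variable) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (!is.character(variable) || length(variable) != 1L ||
      !variable %in% spec$variables)
    stop("unknown variable: ", variable, call. = FALSE)
  k1 <- spec
  k1$variables <- setdiff(spec$variables, variable)
  structure(list(spec = spec, excluded = variable, k1_spec = k1),
            class = "kernel_split")
}

#' Gram matrices of a kernel split
#'
#' Evaluates \eqn{K_s}, \eqn{K_1} and \eqn{K_2 = K_s - K_1} of a
#' [kernel_split()] on sample rows. `x` and `y` carry the columns of the
#' *full* spec; the excluded variable's column is dropped internally for
#' \eqn{K_1}.
#'
#' @param split A `"kernel_split"` object.
#' @param x,y Sample matrices on the full variable set (see [kernel_matrix()]).
#' @return A list with matrices `ks`, `k1`, `k2`.
#' @export
split_matrices <- function(split, x, y = x) {
  stopifnot(inherits(split, "kernel_split"))
  x <- .check_rows(x, split$spec, "x")
  y <- .check_rows(y, split$spec, "y")
  keep <- match(split$k1_spec$variables, split$spec$variables)
  ks <- kernel_matrix(split$spec, x, y)
  k1 <- kernel_matrix(split$k1_spec,
                      x[, keep, drop = FALSE], y[, keep, drop = FALSE])
  list(ks = ks, k1 = k1, k2 = ks - k1)
}

#' Explicit feature map of the linear and quadratic kernels
#'
#' The linear and quadratic kernels have finite rank, so their Gram matrix
#' factors exactly as \eqn{\Phi \Phi^\top}. Regression through the feature
#' matrix replaces an \eqn{N \times N} solve by a \eqn{p \times p} solve
#' (see [gp_fit_features()]), with
#' \eqn{p = 1 + m} (linear) or \eqn{p = 1 + m + m(m+1)/2} (quadratic).
#' Columns are ordered: constant, linear terms in variable order, squares in
#' variable order, then cross products in lexicographic pair order, so
#' coefficient vectors are comparable across runs.
#'
#' @param spec A linear or quadratic [kernel_spec()]; the fully nonlinear
#'   family has no finite exact feature map and is rejected.
#' @param x Sample matrix on `spec$variables`.
#' @return An `nrow(x)` by `p` feature matrix with descriptive column names.
#' @export
feature_map <- function(spec, x) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (spec$family == "nonlinear")
    stop("the nonlinear kernel has no finite exact feature map; ",
         "use kernel_matrix() and gp_fit() instead", call. = FALSE)
  x <- .check_rows(x, spec, "x")
  m <- length(spec$variables)
  vars <- if (m > 0) spec$variables else character()
  phi <- matrix(1, nrow(x), 1L, dimnames = list(NULL, "(const)"))
  if (m > 0) {
    lin <- sqrt(spec$beta1) * x
    colnames(lin) <- vars
    phi <- cbind(phi, lin)
  }
  if (spec$family == "quadratic" && m > 0) {
    sq <- sqrt(spec$beta2) * x^2
    colnames(sq) <- paste0(vars, "^2")
    phi <- cbind(phi, sq)
    if (m > 1) {
      idx <- utils::combn(m, 2)
      cross <- sqrt(spec$beta2) * x[, idx[1, ], drop = FALSE] *
        x[, idx[2, ], drop = FALSE]
      colnames(cross) <- paste0(vars[idx[1, ]], ":", vars[idx[2, ]])
      phi <- cbind(phi, cross)
    }
  }
  phi
}
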