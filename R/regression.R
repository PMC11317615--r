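#' Kernel ridge regression with signal/noise variance decomposition
#'
#' Solves the regularized regression
#' \deqn{\min_{f \in H_{K_s}} \|f\|_{K_s}^2 + \frac{1}{\gamma}\|f(X) - Y\|^2}
#' in closed form through the representer coefficients
#' \eqn{z = (K + \gamma I)^{-1} Y}, where \eqn{K} is the Gram matrix of the
#' signal kernel on the training rows. At the minimum the explained data
#' variance splits into a smooth signal part
#' \eqn{V^{(s)} = \|f\|^2_{K_s} = z^\top K z} and a white-noise part
#' \eqn{V^{(n)} = \frac{1}{\gamma}\|f(X) - Y\|^2 = \gamma \|z\|^2}
#' (the residual is exactly \eqn{\gamma z}), so that
#' \eqn{V^{(s)} + V^{(n)} = Y^\top z}. The signal fraction
#' \eqn{V^{(s)} / (V^{(s)} + V^{(n)}) \in [0,1]} is the evidence that the
#' target is a function of the kernel's variables.
#'
#' A relative jitter of `1e-10 * mean(diag(gram))` is added before the
#' symmetric factorization to guard against semidefinite Grams.
#'
#' @param gram Symmetric positive semidefinite `N` by `N` Gram matrix.
#' @param y Numeric target vector of length `N` (finite).
#' @param gamma Positive noise regularization.
#' @return An object of class `"gp_fit"`: a list with `z` (representer
#'   coefficients), `gamma`, `V_signal`, `V_noise`, `ratio` (signal fraction),
#'   and `fitted` (in-sample predictions, equal to `y - gamma * z`).
#' @export
gp_fit <- function(gram, y, gamma) {
  gram <- as.matrix(gram)
  y <- as.numeric(y)
  n <- length(y)
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma <= 0)
    stop("gamma must be a single positive number", call. = FALSE)
  if (nrow(gram) != n || ncol(gram) != n)
    stop("gram must be square and match length(y)", call. = FALSE)
  if (anyNA(y) || any(!is.finite(y)))
    stop("targets must be finite", call. = FALSE)
  scale <- max(abs(gram), 1)
  if (max(abs(gram - t(gram))) > 1e-8 * scale)
    stop("gram matrix is not symmetric", call. = FALSE)
  gram <- (gram + t(gram)) / 2
  jitter <- 1e-10 * mean(diag(gram))
  ch <- tryCatch(chol(gram + diag(gamma + jitter, n)),
                 error = function(e) NULL)
  if (is.null(ch))
    stop("gram matrix is not positive semidefinite", call. = FALSE)
  z <- backsolve(ch, forwardsolve(t(ch), y))
  kz <- drop(gram %*% z)
  v_s <- max(0, sum(z * kz))
  v_n <- gamma * sum(z^2)
  structure(
    list(z = z, gamma = gamma, V_signal = v_s, V_noise = v_n,
         ratio = signal_to_noise(v_s, v_n), fitted = kz),
    class = "gp_fit")
}

#' Signal fraction of the explained variance
#'
#' Returns \eqn{V^{(s)} / (V^{(s)} + V^{(n)}) \in [0,1]}. The degenerate case
#' \eqn{V^{(s)} = V^{(n)} = 0} (for instance a zero target) is reported as 0,
#' i.e. "no signal", rather than an error.
#'
#' @param v_signal,v_noise Nonnegative variance components.
#' @return A number in `[0, 1]`.
#' @export
signal_to_noise <- function(v_signal, v_noise) {
  if (!is.numeric(v_signal) || !is.numeric(v_noise) ||
      length(v_signal) != 1L || length(v_noise) != 1L ||
      v_signal < 0 || v_noise < 0)
    stop("variance components must be single nonnegative numbers",
         call. = FALSE)
  tot <- v_signal + v_noise
  if (tot == 0) return(0)
  min(1, max(0, v_signal / tot))
}

#' @export
print.gp_fit <- function(x, ...) {
  cat(sprintf(
    "<gp_fit> N=%d  gamma=%g  V(s)=%.4g  V(n)=%.4g  signal ratio=%.4f\n",
    length(x$z), x$gamma, x$V_signal, x$V_noise, x$ratio))
  invisible(x)
}

#' Low-rank fit through an explicit feature map
#'
#' Identical decomposition to [gp_fit()] for finite-rank kernels, computed
#' through a `p` by `p` solve instead of an `N` by `N` one. With features
#' \eqn{\Phi} (from [feature_map()]) the Gram is \eqn{\Phi\Phi^\top} and, by
#' the Woodbury identity, \eqn{z = (Y - \Phi w)/\gamma} with
#' \eqn{w = (\Phi^\top\Phi + \gamma I_p)^{-1}\Phi^\top Y}; moreover
#' \eqn{\Phi^\top z = w}, so \eqn{V^{(s)} = \|w\|^2}.
#'
#' @param features `N` by `p` feature matrix.
#' @param y Target vector.
#' @param gamma Positive noise regularization.
#' @return A `"gp_fit"` object (with an extra element `w`, the primal feature
#'   weights). When `p >= N` the low-rank path offers no saving; it is still
#'   performed, with a message.
#' @export
gp_fit_features <- function(features, y, gamma) {
  phi <- as.matrix(features)
  y <- as.numeric(y)
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("gamma must be a single positive number", call. = FALSE)
  if (nrow(phi) != length(y))
    stop("features and targets disagree on N", call. = FALSE)
  if (anyNA(y) || any(!is.finite(y)) || anyNA(phi) || any(!is.finite(phi)))
    stop("features and targets must be finite", call. = FALSE)
  n <- length(y); p <- ncol(phi)
  if (p >= n)
    message(sprintf("feature rank p=%d >= N=%d: no saving over the full Gram",
                    p, n))
  a <- crossprod(phi)
  diag(a) <- diag(a) + gamma
  w <- drop(solve(a, crossprod(phi, y)))
  z <- drop(y - phi %*% w) / gamma
  v_s <- sum(w^2)
  v_n <- gamma * sum(z^2)
  structure(
    list(z = z, gamma = gamma, V_signal = v_s, V_noise = v_n,
         ratio = signal_to_noise(v_s, v_n), fitted = drop(phi %*% w), w = w),
    class = "gp_fit")
}

#' Regress one variable on a set of ancestors
#'
#' Convenience wrapper tying together [kernel_spec()], [kernel_matrix()] /
#' [feature_map()] and [gp_fit()]: fits `target ~ f(ancestors)` on a
#' (normalized) sample table and keeps the training rows and kernel so that
#' the fit can predict on new rows.
#'
#' @param data An [hg_data()] object or numeric matrix with column names.
#' @param target Name of the response variable.
#' @param ancestors Character vector of predictor variable names.
#' @param family Kernel family (see [kernel_spec()]).
#' @param gamma Noise regularization (default 0.02, see [hg_config()]).
#' @param low_rank Use the feature-map path when the family permits it and
#'   `p < N` (default `TRUE`).
#' @param ... Passed to [kernel_spec()] (`beta1`, `beta2`, `beta3`, `base`).
#' @return A `"gp_regression"` object: a `"gp_fit"` plus `spec`, `target`,
#'   `x_train` and `y_train`.
#' @export
gp_regress <- function(data, target, ancestors,
                       family = c("linear", "quadratic", "nonlinear"),
                       gamma = 0.02, low_rank = TRUE, ...) {
  vals <- hg_values(data)
  family <- match.arg(family)
  miss <- setdiff(c(target, ancestors), colnames(vals))
  if (length(miss))
    stop("unknown variable(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (target %in% ancestors)
    stop("target cannot be its own ancestor", call. = FALSE)
  spec <- kernel_spec(family, variables = ancestors, ...)
  x <- vals[, ancestors, drop = FALSE]
  y <- vals[, target]
  use_features <- low_rank && family != "nonlinear"
  if (use_features) {
    phi <- feature_map(spec, x)
    if (ncol(phi) < nrow(phi)) {
      fit <- gp_fit_features(phi, y, gamma)
    } else {
      fit <- gp_fit(kernel_matrix(spec, x), y, gamma)
    }
  } else {
    fit <- gp_fit(kernel_matrix(spec, x), y, gamma)
  }
  fit$spec <- spec
  fit$target <- target
  fit$x_train <- x
  fit$y_train <- y
  class(fit) <- c("gp_regression", "gp_fit")
  fit
}

#' Predict from a fitted kernel regression
#'
#' Evaluates the representer form \eqn{\hat f(\cdot) = K_s(\cdot, X) z} on new
#' rows. On the training rows this returns exactly `y - gamma * z` (the
#' residual identity of the closed-form minimizer).
#'
#' @param object A `"gp_regression"` from [gp_regress()].
#' @param newdata Matrix or [hg_data()] containing the fit's ancestor columns.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.gp_regression <- function(object, newdata, ...) {
  vals <- hg_values(newdata)
  vars <- object$spec$variables
  miss <- setdiff(vars, colnames(vals))
  if (length(miss))
    stop("newdata lacks variable(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  k_new <- kernel_matrix(object$spec, vals[, vars, drop = FALSE],
                         object$x_train)
  drop(k_new %*% object$z)
}

# objective of the regularized regression at coefficient vector z:
# z'Kz + (1/gamma) * ||Kz - y||^2  (used by tests as a minimality oracle)
.gp_objective <- function(gram, y, gamma, z) {
  kz <- drop(gram %*% z)
  sum(z * kz) + sum((kz - y)^2) / gamma
}
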