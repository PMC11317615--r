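#' Attribute signal variance to candidate ancestors
#'
#' For a fit with representer coefficients `z` on the full kernel
#' \eqn{K_s}, and for each candidate variable \eqn{j} the split
#' \eqn{K_s = K_1^{(j)} + K_2^{(j)}} of [kernel_split()], the share
#' \deqn{s_j = \frac{z^\top K_2^{(j)} z}{z^\top K_s z} \in [0, 1]}
#' measures variable \eqn{j}'s contribution to the signal data variance
#' (\eqn{\|f_2\|^2_{K_2} / \|f\|^2_{K_s}} in the mode decomposition
#' \eqn{f = f_1 + f_2}). Shares need not sum to one: interaction terms are
#' counted in every participating variable's component. Tiny negative values
#' from floating-point cancellation are clamped to zero. A zero coefficient
#' vector yields all-zero shares by convention.
#'
#' @param z Representer coefficient vector of the fit.
#' @param k2_grams Named list of \eqn{K_2} Gram matrices, one per candidate.
#' @param gram Gram matrix of the full kernel \eqn{K_s} on the same rows.
#' @return Named numeric vector of shares in `[0, 1]`.
#' @export
signal_contributions <- function(z, k2_grams, gram) {
  z <- as.numeric(z)
  denom <- sum(z * drop(gram %*% z))
  shares <- vapply(k2_grams, function(k2) sum(z * drop(k2 %*% z)),
                   numeric(1))
  if (denom <= 0 || all(z == 0))
    return(stats::setNames(numeric(length(k2_grams)), names(k2_grams)))
  shares <- shares / denom
  shares[shares < 0 & abs(shares) < 1e-10] <- 0
  pmin(pmax(shares, 0), 1)
}

# --- internal pruning engine ------------------------------------------------
#
# Incremental evaluation of fits and per-node contribution shares along the
# pruning path. Nodes may be clusters (several columns each). For the
# nonlinear family the per-column base-kernel Grams are cached once, and the
# product term is maintained by elementwise division when columns leave the
# active set (each factor is >= 1, so division is safe). Quadratic forms
# z' K1 z are evaluated in closed form without materializing K1:
#   z'K1z = (sum z)^2 + b1 * sum_{i not in J} (z'u_i)^2
#         + b2 * sum_{i<=l not in J} (u_i' diag(z) u_l)^2
#         + b3 * sum_{ab} z_a z_b P_ab / prod_{i in J} B_i[ab]
# where J is the excluded node's column set and B_i = 1 + k(x_i, x_i').

.prune_engine <- function(x_all, y, col_node, family, b1, b2, b3, base,
                          gamma) {
  n <- nrow(x_all)
  nonlin <- family == "nonlinear"
  quad <- family %in% c("quadratic", "nonlinear")
  b_list <- NULL
  p_mat <- NULL
  if (nonlin) {
    b_list <- lapply(seq_len(ncol(x_all)), function(i)
      1 + .base_gram(x_all[, i], x_all[, i], base))
    p_mat <- Reduce("*", b_list, matrix(1, n, n))
  }
  s_mat <- tcrossprod(x_all)
  s2_mat <- if (quad) tcrossprod(x_all^2) else NULL

  env <- new.env(parent = emptyenv())
  env$x <- x_all; env$y <- y; env$col_node <- col_node
  env$active_cols <- seq_len(ncol(x_all))
  env$S <- s_mat; env$S2 <- s2_mat; env$P <- p_mat; env$B <- b_list
  env$family <- family; env$b1 <- b1; env$b2 <- b2; env$b3 <- b3
  env$gamma <- gamma; env$n <- n
  env
}

.engine_fit <- function(env) {
  cols <- env$active_cols
  xa <- env$x[, cols, drop = FALSE]
  if (env$family == "nonlinear") {
    gram <- 1 + env$b1 * env$S + env$b2 * (env$S^2 + env$S2) / 2 +
      env$b3 * env$P
    return(gp_fit(gram, env$y, env$gamma))
  }
  p <- 1L + length(cols) +
    if (env$family == "quadratic")
      length(cols) * (length(cols) + 1L) / 2 else 0L
  if (p < env$n) {
    spec <- kernel_spec(env$family, variables = colnames(xa),
                        beta1 = env$b1, beta2 = env$b2)
    gp_fit_features(feature_map(spec, xa), env$y, env$gamma)
  } else {
    gram <- 1 + env$b1 * env$S
    if (env$family == "quadratic")
      gram <- gram + env$b2 * (env$S^2 + env$S2) / 2
    gp_fit(gram, env$y, env$gamma)
  }
}

# shares per active node given the current fit
.engine_shares <- function(env, fit) {
  cols <- env$active_cols
  nodes <- unique(env$col_node[cols])
  z <- fit$z
  v_s <- fit$V_signal
  if (v_s <= 0)
    return(stats::setNames(numeric(length(nodes)), nodes))
  xa <- env$x[, cols, drop = FALSE]
  sz2 <- sum(z)^2
  g <- drop(crossprod(xa, z))
  lin_tot <- sum(g^2)
  if (env$family != "linear") {
    gq <- crossprod(xa, z * xa)
    frob <- sum(gq^2)
    diag2 <- sum(diag(gq)^2)
  }
  if (env$family == "nonlinear")
    m_mat <- env$P * tcrossprod(z)
  shares <- vapply(nodes, function(nd) {
    j <- which(env$col_node[cols] == nd)    # positions within active cols
    k1 <- sz2 + env$b1 * (lin_tot - sum(g[j]^2))
    if (env$family != "linear") {
      frob_ex <- frob - 2 * sum(gq[j, , drop = FALSE]^2) +
        sum(gq[j, j, drop = FALSE]^2)
      diag2_ex <- diag2 - sum(diag(gq)[j]^2)
      k1 <- k1 + env$b2 * (frob_ex + diag2_ex) / 2
    }
    if (env$family == "nonlinear") {
      bj <- env$B[[cols[j[1]]]]
      if (length(j) > 1)
        for (jj in j[-1]) bj <- bj * env$B[[cols[jj]]]
      k1 <- k1 + env$b3 * sum(m_mat / bj)
    }
    share <- (v_s - k1) / v_s
    if (share < 0 && abs(share) < 1e-8) share <- 0
    min(1, max(0, share))
  }, numeric(1))
  stats::setNames(shares, nodes)
}

.engine_remove <- function(env, node) {
  drop_cols <- intersect(env$active_cols, which(env$col_node == node))
  for (j in drop_cols) {
    u <- env$x[, j]
    env$S <- env$S - tcrossprod(u)
    if (!is.null(env$S2)) env$S2 <- env$S2 - tcrossprod(u^2)
    if (!is.null(env$P)) env$P <- env$P / env$B[[j]]
  }
  env$active_cols <- setdiff(env$active_cols, drop_cols)
  invisible(env)
}

# noise ratio of the ancestor-free (constant-kernel) fit, in closed form:
# (J + g I)^{-1} y = (y - sum(y)/(n+g)) / g with J the all-ones matrix
.empty_set_ratio <- function(y, gamma) {
  n <- length(y)
  z <- (y - sum(y) / (n + gamma)) / gamma
  v_s <- sum(z)^2
  v_n <- gamma * sum(z^2)
  1 - signal_to_noise(v_s, v_n)
}

# resolve node names to column names, honoring cluster groups
.node_columns <- function(data, nodes) {
  groups <- if (inherits(data, "hg_data")) data$groups else NULL
  lapply(stats::setNames(nodes, nodes), function(nd) {
    if (!is.null(groups) && nd %in% names(groups)) groups[[nd]] else nd
  })
}

# universe of node names for a data object (cluster names replace members)
.node_universe <- function(data) {
  vals <- hg_values(data)
  groups <- if (inherits(data, "hg_data")) data$groups else NULL
  if (is.null(groups)) return(colnames(vals))
  grouped <- unlist(groups, use.names = FALSE)
  c(names(groups), setdiff(colnames(vals), grouped))
}

#' Iteratively prune a candidate ancestor set
#'
#' Starting from the full candidate set, repeatedly: fit the kernel
#' regression, attribute signal variance to each remaining candidate with the
#' mode decomposition (see [signal_contributions()]), remove the candidate
#' with the smallest share (ties broken by variable-name order), and refit.
#' The path continues down to a single candidate and records, at every step,
#' the active ancestor set, the variance components and the noise-to-signal
#' ratio \eqn{V^{(n)}/(V^{(s)}+V^{(n)})}. The ratio of the ancestor-free
#' (constant-kernel) fit is recorded as `terminal_ratio`, completing the
#' path's right end. Shares are recomputed after every removal.
#'
#' @param data A normalized [hg_data()] object (auto-normalized, with a
#'   warning, otherwise).
#' @param target Node whose ancestors are sought (not in `candidates`).
#' @param candidates Character vector of candidate ancestor nodes.
#' @param family Kernel family, see [kernel_spec()].
#' @param gamma Noise regularization (default 0.02, see [hg_config()]).
#' @param beta1,beta2,beta3,base Kernel parameters, see [kernel_spec()].
#' @return An object of class `"prune_trace"`: list with `target`, `family`,
#'   `steps` (list of per-step records), `increments` (consecutive
#'   noise-ratio differences), `terminal_ratio` and `gamma`.
#' @export
prune_path <- function(data, target, candidates,
                       family = c("linear", "quadratic", "nonlinear"),
                       gamma = 0.02, beta1 = 0.1, beta2 = 0.1, beta3 = 0.1,
                       base = "gaussian") {
  family <- match.arg(family)
  data <- .ensure_normalized(data)
  vals <- hg_values(data)
  if (length(candidates) == 0)
    stop("empty candidate set", call. = FALSE)
  if (target %in% candidates)
    stop("target cannot be its own candidate ancestor", call. = FALSE)
  cols_of <- .node_columns(data, candidates)
  tcols <- .node_columns(data, target)[[1]]
  miss <- setdiff(c(unlist(cols_of), tcols), colnames(vals))
  if (length(miss))
    stop("unknown variable(s): ", paste(miss, collapse = ", "), call. = FALSE)
  all_cols <- unlist(cols_of, use.names = FALSE)
  if (nrow(vals) <= length(all_cols))
    warning(sprintf(
      "N=%d samples for %d candidate columns: accuracy requires N > d",
      nrow(vals), length(all_cols)), call. = FALSE)
  y <- .target_vector(vals, tcols, family, gamma, beta1, beta2, beta3, base)
  col_node <- rep(names(cols_of), lengths(cols_of))
  x_all <- vals[, all_cols, drop = FALSE]
  env <- .prune_engine(x_all, y, col_node, family, beta1, beta2, beta3,
                       base, gamma)
  steps <- vector("list", length(candidates))
  removed <- NA_character_
  active <- candidates
  for (k in seq_along(candidates)) {
    fit <- .engine_fit(env)
    noise <- 1 - fit$ratio
    steps[[k]] <- list(ancestors = active, removed = removed,
                       V_signal = fit$V_signal, V_noise = fit$V_noise,
                       noise_ratio = noise)
    if (length(active) == 1L) break
    shares <- .engine_shares(env, fit)
    shares <- shares[order(shares, names(shares))]
    removed <- names(shares)[1]
    .engine_remove(env, removed)
    active <- setdiff(active, removed)
  }
  steps <- steps[!vapply(steps, is.null, logical(1))]
  ratios <- vapply(steps, `[[`, numeric(1), "noise_ratio")
  structure(
    list(target = target, family = family, steps = steps,
         increments = diff(ratios),
         terminal_ratio = .empty_set_ratio(y, gamma), gamma = gamma),
    class = "prune_trace")
}

# response vector for a (possibly multi-column cluster) target: for a
# single column it is that column; for a cluster the member with the
# strongest signal against the remaining universe is used
.target_vector <- function(vals, tcols, family, gamma, b1, b2, b3, base) {
  if (length(tcols) == 1L) return(vals[, tcols])
  ratios <- vapply(tcols, function(tc) {
    others <- setdiff(colnames(vals), tc)
    spec <- kernel_spec(family, variables = others, beta1 = b1, beta2 = b2,
                        beta3 = b3, base = base)
    f <- if (family == "nonlinear")
      gp_fit(kernel_matrix(spec, vals[, others, drop = FALSE]),
             vals[, tc], gamma)
    else gp_fit_features(feature_map(spec, vals[, others, drop = FALSE]),
                         vals[, tc], gamma)
    f$ratio
  }, numeric(1))
  vals[, tcols[which.max(ratios)]]
}

.ensure_normalized <- function(data) {
  if (!inherits(data, "hg_data")) data <- hg_data(data)
  if (!data$normalized) {
    x <- data$values
    mu <- colMeans(x)
    sd_pop <- sqrt(colMeans(sweep(x, 2, mu)^2))
    if (any(abs(mu) > 1e-10) || any(abs(sd_pop - 1) > 1e-10)) {
      warning("data are not normalized; standardizing columns",
              call. = FALSE)
      data <- hg_normalize(data)
    } else {
      data$normalized <- TRUE
      data$center <- mu; data$scale <- sd_pop
    }
  }
  data
}

#' @export
print.prune_trace <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("<prune_trace> target=%s family=%s (%d step(s))\n",
              x$target, x$family, nrow(df)))
  print(df, row.names = FALSE)
  cat(sprintf("  ancestor-free noise ratio: %.4f\n", x$terminal_ratio))
  invisible(x)
}

#' @export
as.data.frame.prune_trace <- function(x, ...) {
  data.frame(
    size = lengths(lapply(x$steps, `[[`, "ancestors")),
    removed = vapply(x$steps, `[[`, character(1), "removed"),
    V_signal = vapply(x$steps, `[[`, numeric(1), "V_signal"),
    V_noise = vapply(x$steps, `[[`, numeric(1), "V_noise"),
    noise_ratio = vapply(x$steps, `[[`, numeric(1), "noise_ratio"),
    stringsAsFactors = FALSE)
}

#' Threshold stopping rule
#'
#' Returns the smallest ancestor set along the pruning path whose
#' signal-to-noise ratio (1 - noise ratio) is still above 0.5, i.e. pruning
#' stops just before the ratio would drop below one half. If even the full
#' candidate set is below the threshold, the empty set is returned.
#'
#' @param trace A [prune_path()] result.
#' @param threshold Signal threshold (default 0.5).
#' @return Character vector of retained ancestors (possibly empty).
#' @export
select_threshold <- function(trace, threshold = 0.5) {
  stopifnot(inherits(trace, "prune_trace"))
  ratios <- vapply(trace$steps, `[[`, numeric(1), "noise_ratio")
  ok <- which(ratios < 1 - threshold)
  if (length(ok) == 0) return(character())
  trace$steps[[max(ok)]]$ancestors
}

#' Inflection (largest-surge) stopping rule
#'
#' Locates the pruning step with the largest increase in the noise-to-signal
#' ratio -- the removal that evidently eliminated a crucial ancestor -- and
#' returns the ancestor set immediately before that removal. The path is
#' completed on the right by the ancestor-free ratio (`terminal_ratio`), so
#' that removing the last, genuinely informative candidate registers as a
#' surge; if that final jump is the largest, the last (singleton) set is
#' returned. Ties are broken toward the earliest step. A single-step trace
#' without a terminal ratio returns that step's set.
#'
#' @param trace A [prune_path()] result.
#' @return Character vector of retained ancestors.
#' @export
select_inflection <- function(trace) {
  stopifnot(inherits(trace, "prune_trace"))
  ratios <- vapply(trace$steps, `[[`, numeric(1), "noise_ratio")
  inc <- diff(ratios)
  term <- trace$terminal_ratio
  if (!is.null(term) && is.finite(term))
    inc <- c(inc, term - ratios[length(ratios)])
  if (length(inc) == 0) return(trace$steps[[1]]$ancestors)
  k <- which.max(inc)   # surge k is the removal leading from step k to k+1
  trace$steps[[min(k, length(trace$steps))]]$ancestors
}

#' Select the signal kernel by climbing the kernel ladder
#'
#' Fits the target on the full candidate set with each kernel family in
#' ladder order (by default linear, then quadratic, then fully nonlinear)
#' and keeps the first family whose signal-to-noise ratio exceeds 0.5. If no
#' family reaches the threshold the node is declared ancestor-free.
#'
#' @inheritParams prune_path
#' @param ladder Character vector of families to try, in order.
#' @param threshold Signal threshold (default 0.5).
#' @return A list with `family` (chosen family name, or `NULL` if none
#'   passes), `fit` (the [gp_fit()] of the chosen -- or last tried --
#'   family) and `ratios` (named signal ratios of every family tried).
#' @export
choose_kernel <- function(data, target, candidates, gamma = 0.02,
                          ladder = c("linear", "quadratic", "nonlinear"),
                          threshold = 0.5, beta1 = 0.1, beta2 = 0.1,
                          beta3 = 0.1, base = "gaussian") {
  stopifnot(all(ladder %in% c("linear", "quadratic", "nonlinear")))
  data <- .ensure_normalized(data)
  vals <- hg_values(data)
  if (length(candidates) == 0) stop("empty candidate set", call. = FALSE)
  cols_of <- .node_columns(data, candidates)
  tcols <- .node_columns(data, target)[[1]]
  all_cols <- unlist(cols_of, use.names = FALSE)
  x <- vals[, all_cols, drop = FALSE]
  y <- .target_vector(vals, tcols, ladder[1], gamma, beta1, beta2, beta3,
                      base)
  ratios <- stats::setNames(rep(NA_real_, length(ladder)), ladder)
  fit <- NULL
  for (fam in ladder) {
    spec <- kernel_spec(fam, variables = all_cols, beta1 = beta1,
                        beta2 = beta2, beta3 = beta3, base = base)
    fit <- if (fam == "nonlinear") {
      gp_fit(kernel_matrix(spec, x), y, gamma)
    } else {
      phi <- feature_map(spec, x)
      if (ncol(phi) < nrow(phi)) gp_fit_features(phi, y, gamma)
      else gp_fit(kernel_matrix(spec, x), y, gamma)
    }
    ratios[fam] <- fit$ratio
    if (fit$ratio > threshold)
      return(list(family = fam, fit = fit, ratios = ratios[!is.na(ratios)]))
  }
  list(family = NULL, fit = fit, ratios = ratios)
}

#' Bootstrap null distribution of the noise-to-signal ratio
#'
#' Draws `n_boot` independent standard-normal target vectors (the natural
#' null for variables normalized to unit variance), computes each one's
#' noise-to-signal ratio against the same Gram matrix and regularization,
#' and summarizes the resulting null distribution. In the absence of signal
#' the observed ratio should fall between the 5% and 95% quantiles with
#' probability 0.9. Ratios are evaluated through the Gram eigenbasis
#' (\eqn{V^{(n)} = \sum_i c_i^2 \gamma/(\lambda_i+\gamma)^2},
#' \eqn{V^{(s)} = \sum_i c_i^2 \lambda_i/(\lambda_i+\gamma)^2} with
#' \eqn{c = Q^\top y}), which is exact and makes repeated draws cheap.
#'
#' @param gram Gram matrix of the kernel under test.
#' @param gamma Noise regularization.
#' @param n_boot Number of bootstrap draws (at least 2).
#' @param seed Optional integer seed for the draws.
#' @return An object of class `"hg_null"`: list with `mean`, `sd`, `q05`,
#'   `q95`, `ratios` (all draws) and `n_boot`.
#' @export
bootstrap_null <- function(gram, gamma, n_boot = 100, seed = NULL) {
  gram <- as.matrix(gram)
  if (n_boot < 2) stop("n_boot must be at least 2", call. = FALSE)
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  n <- nrow(gram)
  eg <- eigen((gram + t(gram)) / 2, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  cmat <- crossprod(eg$vectors, matrix(stats::rnorm(n * n_boot), n, n_boot))
  wn <- gamma / (lam + gamma)^2
  ws <- lam / (lam + gamma)^2
  v_n <- colSums(cmat^2 * wn)
  v_s <- colSums(cmat^2 * ws)
  ratios <- v_n / (v_s + v_n)
  qs <- stats::quantile(ratios, c(0.05, 0.95), names = FALSE)
  structure(list(mean = mean(ratios), sd = stats::sd(ratios),
                 q05 = qs[1], q95 = qs[2], ratios = ratios,
                 n_boot = n_boot),
            class = "hg_null")
}

#' Z-score of an observed noise ratio against the bootstrap null
#'
#' @param observed Observed noise-to-signal ratio.
#' @param null A [bootstrap_null()] result.
#' @return `(observed - mean) / sd`; signed infinity (with a warning) when
#'   the null standard deviation is zero.
#' @export
noise_z_score <- function(observed, null) {
  stopifnot(inherits(null, "hg_null"))
  if (null$sd == 0) {
    warning("null distribution has zero spread; Z-score is infinite",
            call. = FALSE)
    return(sign(observed - null$mean) * Inf)
  }
  (observed - null$mean) / null$sd
}

#' @export
print.hg_null <- function(x, ...) {
  cat(sprintf(
    "<hg_null> %d draws: mean=%.4f sd=%.4f, 90%% band [%.4f, %.4f]\n",
    x$n_boot, x$mean, x$sd, x$q05, x$q95))
  invisible(x)
}

# save/restore the RNG state so seeded helpers do not disturb the caller
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
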