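#' @name benchmarks
#' @title Seeded benchmark generators with ground-truth graphs
#' @description
#' Three self-contained generators emulate standard structure-recovery
#' benchmarks: a nonlinear mass-spring lattice chain
#' ([simulate_fput()]), four algebraic-equation systems
#' ([generate_algebraic()]), and a mass-action chemical reaction network
#' ([simulate_reactions()]). Each returns an `"hg_benchmark"`: raw
#' (pre-normalization) samples as [hg_data()], a ground-truth directed edge
#' list, and generator metadata. Regeneration under the same seed is
#' bit-identical; snapshots are pooled across trajectories and shuffled
#' with the dataset seed.
NULL

.new_benchmark <- function(values, truth, meta) {
  structure(list(data = hg_data(values), truth = truth, meta = meta),
            class = "hg_benchmark")
}

#' @export
print.hg_benchmark <- function(x, ...) {
  cat(sprintf("<hg_benchmark> %s: %d sample(s) x %d variable(s), %d truth edge(s)\n",
              x$meta$generator, nrow(x$data$values), ncol(x$data$values),
              nrow(x$truth)))
  invisible(x)
}

#' Simulate the nonlinear mass-spring lattice chain
#'
#' Integrates a chain of `M` masses at equilibrium spacing `h = 1/M`, each
#' tied to its neighbours by a nonlinear spring:
#' \deqn{\ddot x_j = \frac{c^2}{h^2}(x_{j+1} + x_{j-1} - 2 x_j)
#'       \,\bigl(1 + \alpha(x_{j+1} - x_{j-1})\bigr),}
#' with \eqn{\alpha(x) = x^2} by default and fixed boundaries
#' \eqn{x_{-1} = x_M = 0} (two additional pinned masses). This weakly
#' chaotic lattice is a classic system-identification benchmark: every
#' recorded acceleration is an exact nonlinear function of three
#' neighbouring positions, while velocities are functions of nothing else
#' observed.
#'
#' Trajectories start from random low-mode sine displacement profiles
#' (modes 1-3, random coefficients, peak amplitude drawn in `[0.5, 1.5]`)
#' with independent random low-mode velocity profiles (peak in `[0, 2]`),
#' so the pooled snapshots sample the chaotic attractor rather than the
#' neighbourhood of a single smooth mode. They are integrated with fixed-step
#' 4th-order Runge-Kutta (`dt = 0.01`), recording every 25th step after the
#' first. Accelerations are evaluated from the right-hand side at the
#' recorded positions (never finite-differenced), so the defining equation
#' holds exactly on the dataset. A trajectory whose displacement exceeds
#' 1e3 is rejected and resampled.
#'
#' @param M Number of moving masses (at least 3). Default 10.
#' @param c_wave Wave speed \eqn{c}. Default 1.
#' @param alpha Nonlinearity function of the strain; default `function(x) x^2`.
#' @param n_snapshots Total pooled snapshots (default 1000); must be
#'   divisible by `n_traj`.
#' @param n_traj Number of independent trajectories (default 20).
#' @param dt Integrator step.
#' @param subsample Steps between snapshots.
#' @param burn_in Time units integrated before the first snapshot
#'   (additional thermalization; default 0).
#' @param seed Integer seed.
#' @return An `"hg_benchmark"` with variables `x0..x{M-1}` (positions),
#'   `v0..v{M-1}` (velocities), `a0..a{M-1}` (accelerations); truth edges
#'   link each acceleration to its one to three neighbouring positions.
#' @export
simulate_fput <- function(M = 10, c_wave = 1, alpha = function(x) x^2,
                          n_snapshots = 1000, n_traj = 20, dt = 0.01,
                          subsample = 25, burn_in = 0, seed = 1) {
  if (M < 3) stop("M must be at least 3", call. = FALSE)
  if (n_snapshots %% n_traj != 0)
    stop("n_snapshots must be divisible by n_traj", call. = FALSE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  h <- 1 / M
  acc_of <- function(x) {
    xp <- c(0, x, 0)                     # pinned boundary masses
    jj <- 2:(M + 1)
    (c_wave^2 / h^2) * (xp[jj + 1] + xp[jj - 1] - 2 * xp[jj]) *
      (1 + alpha(xp[jj + 1] - xp[jj - 1]))
  }
  deriv <- function(t, state, parms) {
    x <- state[1:M]; v <- state[(M + 1):(2 * M)]
    list(c(v, acc_of(x)))
  }
  mode_profile <- function(peak) {
    co <- stats::rnorm(3)
    p <- sapply(1:M, function(j) sum(co * sin(pi * (1:3) * j / (M + 1))))
    if (max(abs(p)) == 0) p else p * peak / max(abs(p))
  }
  n_per <- n_snapshots / n_traj
  n_burn <- round(burn_in / dt)
  times <- seq(0, by = dt, length.out = n_burn + n_per * subsample + 1)
  keep <- 1 + n_burn + subsample * seq_len(n_per)
  snaps <- vector("list", n_traj)
  for (tr in seq_len(n_traj)) {
    for (try in 1:20) {
      x0 <- mode_profile(stats::runif(1, 0.5, 1.5))
      v0 <- mode_profile(stats::runif(1, 0, 2))
      sol <- deSolve::rk4(c(x0, v0), times, deriv, parms = NULL)
      xs <- sol[keep, 1 + (1:M), drop = FALSE]
      vs <- sol[keep, 1 + M + (1:M), drop = FALSE]
      if (all(is.finite(xs)) && all(is.finite(vs)) &&
          max(abs(xs)) <= 1e3) break
      if (try == 20) stop("lattice trajectory keeps blowing up",
                          call. = FALSE)
    }
    as_ <- t(apply(xs, 1, acc_of))
    snaps[[tr]] <- cbind(xs, vs, as_)
  }
  vals <- do.call(rbind, snaps)
  idx <- 0:(M - 1)
  colnames(vals) <- c(paste0("x", idx), paste0("v", idx), paste0("a", idx))
  traj_id <- rep(seq_len(n_traj), each = n_per)
  perm <- sample(nrow(vals))
  truth <- do.call(rbind, lapply(idx, function(j) {
    parents <- paste0("x", intersect(c(j - 1, j, j + 1), idx))
    data.frame(source = parents, target = paste0("a", j),
               stringsAsFactors = FALSE)
  }))
  .new_benchmark(vals[perm, , drop = FALSE], truth,
                 meta = list(generator = "fput", M = M, c = c_wave,
                             h = h, dt = dt, subsample = subsample,
                             n_traj = n_traj, seed = seed,
                             trajectory = traj_id[perm]))
}

#' Generate an algebraic-equation benchmark system
#'
#' Four small systems of hidden algebraic equations over independent
#' standard-normal sources `w1..w4` and dependent variables `x1..x3`, with
#' `N` samples each:
#' \describe{
#'   \item{1 (d=6, linear)}{`x1 = w1`, `x2 = w2`.}
#'   \item{2 (d=7, quadratic)}{`x1 = w1`, `x2 = x1^2 + 1 + 0.1 w2`,
#'     `x3 = w3`.}
#'   \item{3 (d=6, nonlinear)}{`x1 = w1 * w2`, `x2 = w2 * sin(w4)`.}
#'   \item{4 (d=7, quadratic)}{`x1 = w1`, `x2 = x1^3 + 1 + 0.1 w2`,
#'     `x3 = (x1 + 2)^3 + 0.1 w3`. The cubic dependencies admit an exact
#'     quadratic representation in terms of the observed variables
#'     (`x2 = x3 - 6 x1^2 - 12 x1 - 7 + 0.1 w2 - 0.1 w3`), so the quadratic
#'     family suffices.}
#' }
#' The truth edge list records the generating equations; `meta$family` is
#' the most complex kernel family the system requires.
#'
#' @param example Integer 1-4.
#' @param n Number of samples (default 1000, at least 10).
#' @param seed Integer seed.
#' @return An `"hg_benchmark"`.
#' @export
generate_algebraic <- function(example, n = 1000, seed = 1) {
  if (!example %in% 1:4) stop("unknown example id: ", example, call. = FALSE)
  if (n < 10) stop("need at least 10 samples", call. = FALSE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  w <- matrix(stats::rnorm(n * 4), n, 4,
              dimnames = list(NULL, paste0("w", 1:4)))
  edge <- function(s, t) data.frame(source = s, target = t,
                                    stringsAsFactors = FALSE)
  if (example == 1) {
    vals <- cbind(w, x1 = w[, "w1"], x2 = w[, "w2"])
    truth <- rbind(edge("w1", "x1"), edge("w2", "x2"))
    fam <- "linear"
  } else if (example == 2) {
    x1 <- w[, "w1"]
    vals <- cbind(w, x1 = x1, x2 = x1^2 + 1 + 0.1 * w[, "w2"],
                  x3 = w[, "w3"])
    truth <- rbind(edge("w1", "x1"), edge(c("x1", "w2"), "x2"),
                   edge("w3", "x3"))
    fam <- "quadratic"
  } else if (example == 3) {
    vals <- cbind(w, x1 = w[, "w1"] * w[, "w2"],
                  x2 = w[, "w2"] * sin(w[, "w4"]))
    truth <- rbind(edge(c("w1", "w2"), "x1"), edge(c("w2", "w4"), "x2"))
    fam <- "nonlinear"
  } else {
    x1 <- w[, "w1"]
    vals <- cbind(w, x1 = x1, x2 = x1^3 + 1 + 0.1 * w[, "w2"],
                  x3 = (x1 + 2)^3 + 0.1 * w[, "w3"])
    truth <- rbind(edge("w1", "x1"), edge(c("x1", "w2"), "x2"),
                   edge(c("x1", "w3"), "x3"))
    fam <- "quadratic"
  }
  .new_benchmark(vals, truth,
                 meta = list(generator = paste0("algebraic", example),
                             example = example, n = n, seed = seed,
                             family = fam))
}

# mass-action right-hand side for the ethylene hydrogenation network
#   H2 <-> 2H;  H + C2H4 <-> C2H5;  C2H5 + H -> C2H6
.reaction_rhs <- function(conc, rates) {
  r1 <- rates[["k1f"]] * conc[["H2"]] - rates[["k1r"]] * conc[["H"]]^2
  r2 <- rates[["k2f"]] * conc[["H"]] * conc[["C2H4"]] -
    rates[["k2r"]] * conc[["C2H5"]]
  r3 <- rates[["k3"]] * conc[["C2H5"]] * conc[["H"]]
  c(H2 = -r1, H = 2 * r1 - r2 - r3, C2H4 = -r2, C2H5 = r2 - r3, C2H6 = r3)
}

#' Simulate the ethylene hydrogenation reaction network
#'
#' Mass-action kinetics for the hydrogenation of ethylene into ethane
#' through the elementary reactions
#' \eqn{H_2 \rightleftharpoons 2H},
#' \eqn{H + C_2H_4 \rightleftharpoons C_2H_5} and
#' \eqn{C_2H_5 + H \to C_2H_6}. Observed variables are snapshots of the
#' concentrations `H2`, `H`, `C2H4`, `C2H5` and their time derivatives
#' `dH2`, `dH`, `dC2H4`, `dC2H5`; derivatives are evaluated from the
#' mass-action right-hand side at the recorded concentrations, so each one
#' is an exact quadratic polynomial in its rate-law parents (the
#' ground-truth edges). Ethane itself is a pure product and is tracked only
#' in the metadata (for conservation checks).
#'
#' @param rates Named rate constants `k1f`, `k1r`, `k2f`, `k2r`, `k3`
#'   (defaults `0.7, 0.2, 1.0, 0.3, 0.5`).
#' @param n_snapshots Total pooled snapshots (default 600); divisible by
#'   `n_traj`.
#' @param n_traj Number of trajectories (default 30), each started from
#'   independent initial concentrations drawn uniformly in `[0.5, 1.5]`
#'   (ethane starts at 0).
#' @param t_max Time horizon per trajectory; snapshots are taken at evenly
#'   spaced times in `(0, t_max]`. Default 4.
#' @param seed Integer seed.
#' @return An `"hg_benchmark"`; `meta$ethane` carries the ethane
#'   concentration and `meta$trajectory` the trajectory id of each row.
#' @export
simulate_reactions <- function(rates = c(k1f = 0.7, k1r = 0.2, k2f = 1.0,
                                         k2r = 0.3, k3 = 0.5),
                               n_snapshots = 600, n_traj = 30, t_max = 4,
                               seed = 1) {
  need <- c("k1f", "k1r", "k2f", "k2r", "k3")
  if (!all(need %in% names(rates)) || any(rates[need] <= 0))
    stop("rates must be positive and named ", paste(need, collapse = ", "),
         call. = FALSE)
  if (n_snapshots %% n_traj != 0)
    stop("n_snapshots must be divisible by n_traj", call. = FALSE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  species <- c("H2", "H", "C2H4", "C2H5", "C2H6")
  deriv <- function(t, state, parms)
    list(.reaction_rhs(as.list(state), parms))
  n_per <- n_snapshots / n_traj
  times <- c(0, seq(t_max / n_per, t_max, length.out = n_per))
  rows <- vector("list", n_traj)
  ethane <- numeric(0)
  for (tr in seq_len(n_traj)) {
    init <- stats::setNames(c(stats::runif(4, 0.5, 1.5), 0), species)
    sol <- deSolve::ode(init, times, deriv, parms = as.list(rates),
                        method = "lsoda", rtol = 1e-9, atol = 1e-10)
    conc <- sol[-1, species, drop = FALSE]
    if (min(conc) < -1e-8)
      stop("negative concentration encountered", call. = FALSE)
    conc[conc < 0] <- 0
    dcon <- t(apply(conc, 1, function(row)
      .reaction_rhs(as.list(row), as.list(rates))))
    rows[[tr]] <- cbind(conc[, 1:4, drop = FALSE],
                        dcon[, 1:4, drop = FALSE])
    ethane <- c(ethane, conc[, "C2H6"])
  }
  vals <- do.call(rbind, rows)
  colnames(vals) <- c("H2", "H", "C2H4", "C2H5",
                      "dH2", "dH", "dC2H4", "dC2H5")
  truth <- rbind(
    data.frame(source = c("H2", "H"), target = "dH2"),
    data.frame(source = c("H2", "H", "C2H4", "C2H5"), target = "dH"),
    data.frame(source = c("H", "C2H4", "C2H5"), target = "dC2H4"),
    data.frame(source = c("H", "C2H4", "C2H5"), target = "dC2H5"))
  traj_id <- rep(seq_len(n_traj), each = n_per)
  perm <- sample(nrow(vals))
  .new_benchmark(vals[perm, , drop = FALSE], truth,
                 meta = list(generator = "reactions", rates = rates,
                             t_max = t_max, n_traj = n_traj, seed = seed,
                             family = "quadratic",
                             trajectory = traj_id[perm],
                             ethane = ethane[perm],
                             times = rep(times[-1], n_traj)[perm]))
}
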