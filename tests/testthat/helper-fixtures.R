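# shared fixture builders; everything is generated in code under fixed seeds

random_rows <- function(n, vars, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * length(vars)), n, length(vars),
         dimnames = list(NULL, vars))
}

random_spd <- function(n, seed = 1) {
  set.seed(seed)
  a <- matrix(rnorm(n * n), n, n)
  crossprod(a) / n + diag(0.1, n)
}

# hand-built pruning trace for testing the stopping rules in isolation
fake_trace <- function(noise_ratios, sizes, terminal = NULL) {
  stopifnot(length(noise_ratios) == length(sizes))
  steps <- lapply(seq_along(sizes), function(i) {
    list(ancestors = paste0("v", seq_len(sizes[i])),
         removed = if (i == 1) NA_character_ else paste0("v", sizes[i] + 1),
         V_signal = 1 - noise_ratios[i], V_noise = noise_ratios[i],
         noise_ratio = noise_ratios[i])
  })
  structure(list(target = "y", family = "linear", steps = steps,
                 increments = diff(noise_ratios),
                 terminal_ratio = terminal, gamma = 0.02),
            class = "prune_trace")
}

# normalized data where the target equals one candidate plus independent noise
# columns; used by contribution and pruning tests
copy_plus_noise <- function(n = 500, seed = 4) {
  set.seed(seed)
  w1 <- rnorm(n)
  vals <- cbind(y = w1, w1 = w1, n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  hg_normalize(hg_data(vals))
}
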