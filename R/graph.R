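#' Discovery configuration
#'
#' Collects every tunable of the discovery pipeline in one object. Defaults
#' follow the method's standard settings on normalized data: kernel weights
#' \eqn{\beta_i = 0.1}, unit base-kernel parameters, regularization
#' \eqn{\gamma = 0.02} (calibrated so that exactly functional relations on
#' roughly a thousand standardized samples read as strong signal while pure
#' noise stays far above the 0.5 gate; see the methods vignette),
#' the linear-quadratic-nonlinear ladder with a 0.5 signal
#' threshold, the inflection (largest-surge) stopping rule, and 100
#' bootstrap draws for the Z-score.
#'
#' @param gamma Noise regularization.
#' @param ladder Kernel families tried, in order (see [choose_kernel()]).
#' @param stop Stopping rule for pruning: `"inflection"` (largest surge in
#'   the noise-to-signal ratio) or `"threshold"` (stop before the signal
#'   ratio drops below 0.5).
#' @param threshold Signal threshold of the kernel ladder (and of the
#'   threshold stopping rule).
#' @param n_boot Bootstrap draws per node (0 disables the Z-score).
#' @param seed Integer seed; every source of randomness (the bootstrap)
#'   derives its per-node seed from it, independently of processing order.
#' @param beta1,beta2,beta3,base Kernel parameters, see [kernel_spec()].
#' @param exclude Node names never proposed as ancestors.
#' @param node_overrides Named list of per-node partial configurations
#'   (e.g. `list(x1 = list(ladder = "nonlinear"))`).
#' @param verbose Log per-node progress (chosen family, ratio path,
#'   stopping decision) with [message()].
#' @return A list of class `"hg_config"`.
#' @export
hg_config <- function(gamma = 0.02,
                      ladder = c("linear", "quadratic", "nonlinear"),
                      stop = c("inflection", "threshold"),
                      threshold = 0.5, n_boot = 100, seed = 1,
                      beta1 = 0.1, beta2 = 0.1, beta3 = 0.1,
                      base = "gaussian", exclude = character(),
                      node_overrides = list(), verbose = FALSE) {
  stop <- match.arg(stop)
  structure(list(gamma = gamma, ladder = ladder, stop = stop,
                 threshold = threshold, n_boot = n_boot, seed = seed,
                 beta1 = beta1, beta2 = beta2, beta3 = beta3, base = base,
                 exclude = exclude, node_overrides = node_overrides,
                 verbose = verbose),
            class = "hg_config")
}

.empty_edges <- function() {
  data.frame(source = character(), target = character(),
             family = character(), ratio = numeric(), zscore = numeric(),
             stringsAsFactors = FALSE)
}

.new_graph <- function(nodes, edges, reports) {
  structure(list(nodes = nodes, edges = edges, reports = reports),
            class = "hg_graph")
}

# merge a per-node override into the shared config
.node_config <- function(config, node) {
  ov <- config$node_overrides[[node]]
  if (is.null(ov)) return(config)
  for (nm in names(ov)) config[[nm]] <- ov[[nm]]
  config
}

#' Discover the functional dependency hypergraph
#'
#' Runs per-node ancestor discovery for every node of the sample table:
#' every other node is initially a candidate ancestor; the kernel ladder
#' ([choose_kernel()]) decides whether the node has ancestors at all and
#' with which kernel family; if a family passes the 0.5 signal gate, the
#' candidate set is pruned along the contribution path ([prune_path()]) and
#' the configured stopping rule picks the final ancestor set, whose fit is
#' then scored against a bootstrap pure-noise null ([bootstrap_null()]).
#' Nodes are processed independently, so results do not depend on the
#' processing order; edges are *functional*, not causal, and cycles are
#' legal output.
#'
#' @param data An [hg_data()] object (normalized automatically, with a
#'   warning, if needed); may carry cluster nodes from [merge_clusters()].
#' @param config An [hg_config()].
#' @return An object of class `"hg_graph"`: `nodes` (character), `edges`
#'   (data frame with `source`, `target`, `family`, `ratio` -- the final
#'   signal-to-noise ratio of the target's fit -- and `zscore`), and
#'   `reports` (named list of per-node ancestor reports, each with
#'   `has_ancestors`, `family`, `ancestors`, `signal_ratio`, `noise_ratio`,
#'   `z_score`, `null_band`, `ladder_ratios` and the full `trace`).
#' @export
discover_graph <- function(data, config = hg_config()) {
  stopifnot(inherits(config, "hg_config"))
  data <- .ensure_normalized(data)
  nodes <- .node_universe(data)
  if (length(nodes) < 2 || nrow(hg_values(data)) < 2)
    stop("need at least 2 samples and 2 nodes", call. = FALSE)
  node_order <- sort(nodes)   # seeds keyed to sorted order, not input order
  reports <- stats::setNames(vector("list", length(nodes)), nodes)
  for (node in nodes) {
    cfg <- .node_config(config, node)
    cand <- setdiff(nodes, c(node, cfg$exclude))
    boot_seed <- if (is.null(cfg$seed)) NULL
      else cfg$seed + match(node, node_order)
    reports[[node]] <- .discover_node(data, node, cand, cfg, boot_seed)
    if (cfg$verbose) {
      rep <- reports[[node]]
      message(sprintf(
        "node %s: family=%s ancestors={%s} signal=%.3f z=%.2f",
        node, rep$family %||% "none",
        paste(rep$ancestors, collapse = ","),
        rep$signal_ratio %||% NA_real_, rep$z_score %||% NA_real_))
    }
  }
  edges <- do.call(rbind, c(list(.empty_edges()), lapply(nodes, function(nd) {
    rep <- reports[[nd]]
    if (!rep$has_ancestors || length(rep$ancestors) == 0)
      return(NULL)
    data.frame(source = rep$ancestors, target = nd, family = rep$family,
               ratio = rep$signal_ratio %||% NA_real_,
               zscore = rep$z_score %||% NA_real_,
               stringsAsFactors = FALSE)
  })))
  rownames(edges) <- NULL
  .new_graph(nodes = nodes, edges = edges, reports = reports)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.discover_node <- function(data, node, candidates, cfg, boot_seed) {
  sel <- choose_kernel(data, node, candidates, gamma = cfg$gamma,
                       ladder = cfg$ladder, threshold = cfg$threshold,
                       beta1 = cfg$beta1, beta2 = cfg$beta2,
                       beta3 = cfg$beta3, base = cfg$base)
  report <- list(target = node, has_ancestors = FALSE, family = NULL,
                 ancestors = character(), signal_ratio = NULL,
                 noise_ratio = NULL, z_score = NULL, null_band = NULL,
                 ladder_ratios = sel$ratios, trace = NULL)
  if (is.null(sel$family)) {
    # score the best (last tried) full-set fit against the pure-noise null
    if (cfg$n_boot >= 2 && !is.null(sel$fit)) {
      gram <- .node_gram(data, candidates, utils::tail(cfg$ladder, 1), cfg)
      null <- bootstrap_null(gram, cfg$gamma, cfg$n_boot, boot_seed)
      report$noise_ratio <- 1 - sel$fit$ratio
      report$z_score <- noise_z_score(report$noise_ratio, null)
      report$null_band <- c(null$q05, null$q95)
    }
    return(report)
  }
  trace <- prune_path(data, node, candidates, family = sel$family,
                      gamma = cfg$gamma, beta1 = cfg$beta1,
                      beta2 = cfg$beta2, beta3 = cfg$beta3, base = cfg$base)
  final <- if (cfg$stop == "inflection") select_inflection(trace)
    else select_threshold(trace, cfg$threshold)
  report$trace <- trace
  if (length(final) == 0) return(report)
  sizes <- lengths(lapply(trace$steps, `[[`, "ancestors"))
  step <- trace$steps[[match(length(final), sizes)]]
  report$has_ancestors <- TRUE
  report$family <- sel$family
  report$ancestors <- sort(final)
  report$noise_ratio <- step$noise_ratio
  report$signal_ratio <- 1 - step$noise_ratio
  if (cfg$n_boot >= 2) {
    gram <- .node_gram(data, final, sel$family, cfg)
    null <- bootstrap_null(gram, cfg$gamma, cfg$n_boot, boot_seed)
    report$z_score <- noise_z_score(report$noise_ratio, null)
    report$null_band <- c(null$q05, null$q95)
  }
  report
}

# Gram of the configured kernel on a node set's columns
.node_gram <- function(data, nodes, family, cfg) {
  vals <- hg_values(data)
  cols <- unlist(.node_columns(data, nodes), use.names = FALSE)
  spec <- kernel_spec(family, variables = cols, beta1 = cfg$beta1,
                      beta2 = cfg$beta2, beta3 = cfg$beta3, base = cfg$base)
  kernel_matrix(spec, vals[, cols, drop = FALSE])
}

#' @export
print.hg_graph <- function(x, ...) {
  cat(sprintf("<hg_graph> %d node(s), %d edge(s)\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges) > 0) print(x$edges, row.names = FALSE)
  invisible(x)
}

#' Merge variables into cluster nodes
#'
#' Declares named, disjoint groups of variables that subsequent discovery
#' treats as single nodes: a cluster's variables enter candidate kernels
#' jointly and are never separated during pruning. Merging highly
#' interdependent variables yields a sparser graph and avoids splitting one
#' cluster's activation across its members. When a cluster is itself the
#' target node, the member with the strongest signal against the remaining
#' variables represents it.
#'
#' @param data An [hg_data()] object.
#' @param groups Named list of character vectors; groups must be disjoint
#'   and reference existing variables. Singleton groups are allowed (and
#'   leave discovery results unchanged).
#' @return The data object with cluster metadata attached.
#' @export
merge_clusters <- function(data, groups) {
  if (!inherits(data, "hg_data")) data <- hg_data(data)
  if (length(groups) == 0) { data$groups <- NULL; return(data) }
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be named", call. = FALSE)
  members <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(members))
    stop("groups must be disjoint", call. = FALSE)
  miss <- setdiff(members, colnames(data$values))
  if (length(miss))
    stop("unknown variable(s) in groups: ", paste(miss, collapse = ", "),
         call. = FALSE)
  clash <- intersect(names(groups),
                     setdiff(colnames(data$values), members))
  if (length(clash))
    stop("group name(s) collide with ungrouped variables: ",
         paste(clash, collapse = ", "), call. = FALSE)
  data$groups <- lapply(groups, as.character)
  data
}

#' Score a recovered graph against a ground truth
#'
#' Counts true/false positives and negatives over all ordered (or, with
#' `direction_sensitive = FALSE`, unordered) non-self node pairs and reports
#' \eqn{TPR = TP/(TP+FN)}, \eqn{FPR = FP/(FP+TN)} and
#' \eqn{FDR = FP/(TP+FP)}. Ratios with a zero denominator are reported as
#' `NaN`, never as 0.
#'
#' @param graph An `"hg_graph"` or an edge data frame with columns `source`
#'   and `target` (in which case `nodes` must list the node universe).
#' @param truth Data frame of ground-truth edges (`source`, `target`), e.g.
#'   from [read_truth_edges()] or a benchmark's `$truth`.
#' @param direction_sensitive Compare ordered pairs (`TRUE`, default) or
#'   unordered pairs.
#' @param nodes Node universe when `graph` is a plain edge data frame.
#' @return A list of class `"recovery_metrics"` with counts `TP`, `FP`,
#'   `FN`, `TN` and rates `TPR`, `FPR`, `FDR`.
#' @export
compare_graphs <- function(graph, truth, direction_sensitive = TRUE,
                           nodes = NULL) {
  if (inherits(graph, "hg_graph")) {
    nodes <- graph$nodes
    edges <- graph$edges
  } else {
    edges <- graph
    if (is.null(nodes)) stop("supply the node universe via nodes=",
                             call. = FALSE)
  }
  truth <- as.data.frame(truth)
  bad <- setdiff(unique(c(truth$source, truth$target)), nodes)
  if (length(bad))
    stop("truth references unknown node(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  key <- function(s, t) {
    if (direction_sensitive) paste(s, t, sep = "\r")
    else paste(pmin(s, t), pmax(s, t), sep = "\r")
  }
  pred <- unique(key(edges$source, edges$target))
  true <- unique(key(truth$source, truth$target))
  d <- length(nodes)
  total <- as.integer(if (direction_sensitive) d * (d - 1)
                      else d * (d - 1) / 2)
  tp <- length(intersect(pred, true))
  fp <- length(setdiff(pred, true))
  fn <- length(setdiff(true, pred))
  tn <- total - tp - fp - fn
  rate <- function(num, den) if (den == 0) NaN else num / den
  structure(list(TP = tp, FP = fp, FN = fn, TN = tn,
                 TPR = rate(tp, tp + fn), FPR = rate(fp, fp + tn),
                 FDR = rate(fp, tp + fp)),
            class = "recovery_metrics")
}

#' @export
print.recovery_metrics <- function(x, ...) {
  cat(sprintf(
    "<recovery_metrics> TP=%d FP=%d FN=%d TN=%d | TPR=%.3f FPR=%.3f FDR=%.3f\n",
    x$TP, x$FP, x$FN, x$TN, x$TPR, x$FPR, x$FDR))
  invisible(x)
}
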