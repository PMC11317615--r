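#' Sample table container
#'
#' Wraps an `N` by `d` numeric matrix of samples (rows) on named variables
#' (columns): the universe of nodes for graph discovery. The object records
#' whether columns have been standardized and, after [hg_normalize()], the
#' per-column raw mean and standard deviation.
#'
#' @param x Numeric matrix or data frame; column names are the variable
#'   names (generated as `v1..vd` when absent).
#' @return An object of class `"hg_data"`.
#' @export
hg_data <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("samples must form a numeric matrix", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)))
    stop("samples must be finite (no missing values)", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("v", seq_len(ncol(x)))
  nm <- colnames(x)
  if (any(nm == "") || anyDuplicated(nm))
    stop("variable names must be unique and non-empty", call. = FALSE)
  structure(list(values = x, center = NULL, scale = NULL,
                 normalized = FALSE, groups = NULL, dropped = character()),
            class = "hg_data")
}

#' Extract the numeric sample matrix
#'
#' @param data An [hg_data()] object, matrix or data frame.
#' @return Numeric matrix with variable names as column names.
#' @export
hg_values <- function(data) {
  if (inherits(data, "hg_data")) return(data$values)
  hg_data(data)$values
}

#' @export
print.hg_data <- function(x, ...) {
  cat(sprintf("<hg_data> %d sample(s) x %d variable(s)%s\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) " (normalized)" else ""))
  if (length(x$dropped))
    cat("  dropped constant column(s):", paste(x$dropped, collapse = ", "),
        "\n")
  if (!is.null(x$groups))
    cat("  cluster nodes:", paste(names(x$groups), collapse = ", "), "\n")
  invisible(x)
}

#' Standardize each variable to zero mean and unit variance
#'
#' Centers and scales every column by its raw mean and *population* standard
#' deviation (`sqrt(mean((x - mean(x))^2))`), recording both for later
#' reporting. Constant columns cannot be standardized and would poison the
#' kernels, so they are dropped from the analysis universe with a warning
#' (a constant is trivially ancestor-free). The operation is idempotent.
#'
#' @param data An [hg_data()] object (or matrix coercible to one).
#' @return A normalized `"hg_data"` object.
#' @export
hg_normalize <- function(data) {
  if (!inherits(data, "hg_data")) data <- hg_data(data)
  if (data$normalized) return(data)
  x <- data$values
  if (nrow(x) < 2) stop("need at least 2 samples to normalize", call. = FALSE)
  mu <- colMeans(x)
  sd_pop <- sqrt(colMeans(sweep(x, 2, mu)^2))
  const <- sd_pop == 0
  if (any(const)) {
    warning("dropping constant column(s): ",
            paste(colnames(x)[const], collapse = ", "), call. = FALSE)
    data$dropped <- c(data$dropped, colnames(x)[const])
    x <- x[, !const, drop = FALSE]
    mu <- mu[!const]; sd_pop <- sd_pop[!const]
    if (!is.null(data$groups))
      data$groups <- lapply(data$groups, setdiff, y = data$dropped)
  }
  data$values <- sweep(sweep(x, 2, mu), 2, sd_pop, "/")
  data$center <- mu
  data$scale <- sd_pop
  data$normalized <- TRUE
  data
}

#' Read a sample table from CSV or TSV
#'
#' Strict numeric reader with cell-level diagnostics: ragged rows, missing or
#' non-numeric cells and duplicate column names are rejected with the row and
#' column of the first offending entry. Parsing is locale-independent
#' (`.` decimal separator).
#'
#' @param path File path.
#' @param format `"csv"` or `"tsv"`; guessed from the file extension by
#'   default.
#' @param header Does the first line carry variable names? If `FALSE`, names
#'   `v1..vd` are generated.
#' @return A raw (unnormalized) [hg_data()] object.
#' @export
read_samples <- function(path, format = c("auto", "csv", "tsv"),
                         header = TRUE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.tsv$|\\.tab$", path, ignore.case = TRUE))
      "tsv" else "csv"
  sep <- if (format == "tsv") "\t" else ","
  df <- tryCatch(
    utils::read.table(path, header = header, sep = sep, dec = ".",
                      colClasses = "character", check.names = FALSE,
                      comment.char = "", quote = "\"",
                      blank.lines.skip = TRUE, fill = FALSE,
                      encoding = "UTF-8"),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e),
                             call. = FALSE))
  if (nrow(df) == 0 || ncol(df) == 0)
    stop("empty table: ", path, call. = FALSE)
  if (!header) colnames(df) <- paste0("v", seq_len(ncol(df)))
  if (anyDuplicated(colnames(df)))
    stop("duplicate column name(s): ",
         paste(unique(colnames(df)[duplicated(colnames(df))]), collapse = ", "),
         call. = FALSE)
  num <- suppressWarnings(
    vapply(df, function(col) as.numeric(trimws(col)), numeric(nrow(df))))
  num <- matrix(num, nrow = nrow(df), dimnames = list(NULL, colnames(df)))
  bad <- which(is.na(num) | trimws(as.matrix(df)) == "", arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("missing or non-numeric cell at row %d, column '%s'",
                 bad[1, 1], colnames(df)[bad[1, 2]]), call. = FALSE)
  hg_data(num)
}

#' Write a sample table to CSV or TSV
#'
#' @param data [hg_data()] object or matrix.
#' @param path Output path.
#' @param format `"csv"` or `"tsv"` (guessed from the extension by default).
#' @return `path`, invisibly.
#' @export
write_samples <- function(data, path, format = c("auto", "csv", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.tsv$|\\.tab$", path, ignore.case = TRUE))
      "tsv" else "csv"
  vals <- hg_values(data)
  utils::write.table(vals, path, sep = if (format == "tsv") "\t" else ",",
                     row.names = FALSE, col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read a ground-truth edge list
#'
#' Expects a two-column TSV (optionally with a header line `source<TAB>target`)
#' of directed edges `ancestor -> node`.
#'
#' @param path File path.
#' @return A data frame with character columns `source` and `target`.
#' @export
read_truth_edges <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2) stop("edge list needs two columns", call. = FALSE)
  df <- df[, 1:2]
  names(df) <- c("source", "target")
  if (nrow(df) > 0 && identical(unname(tolower(unlist(df[1, ]))),
                                c("source", "target")))
    df <- df[-1, , drop = FALSE]
  rownames(df) <- NULL
  df
}

# canonical list form of a graph for JSON serialization; numbers are rounded
# to 12 significant digits so that write -> read -> write is byte-identical
.graph_to_list <- function(graph) {
  rnd <- function(v) ifelse(is.na(v), NA, signif(v, 12))
  edges <- graph$edges
  list(
    nodes = as.list(graph$nodes),
    edges = lapply(seq_len(nrow(edges)), function(i) {
      list(source = edges$source[i], target = edges$target[i],
           family = edges$family[i], ratio = rnd(edges$ratio[i]),
           zscore = rnd(edges$zscore[i]))
    }))
}

#' Write a discovered hypergraph to disk
#'
#' Three formats are supported. JSON is the canonical, lossless form
#' (`nodes` plus `edges` with `source`, `target`, `family`, `ratio`,
#' `zscore`); it round-trips through [read_graph_json()]. DOT maps each
#' edge's signal-to-noise ratio to pen width and gray intensity (stronger
#' edges are wider and darker). GraphML carries the same edge attributes and
#' is written through the igraph library.
#'
#' @param graph An `"hg_graph"` from [discover_graph()] (or
#'   [read_graph_json()]).
#' @param path Output file path.
#' @param format `"json"`, `"dot"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_graph <- function(graph, path, format = c("json", "dot", "graphml")) {
  stopifnot(inherits(graph, "hg_graph"))
  format <- match.arg(format)
  if (format == "json") {
    json <- jsonlite::toJSON(.graph_to_list(graph), auto_unbox = TRUE,
                             pretty = TRUE, digits = NA, na = "null")
    writeLines(json, path, useBytes = TRUE)
  } else if (format == "dot") {
    ratio <- graph$edges$ratio
    pw <- sprintf("%.2f", 0.5 + 3 * ifelse(is.na(ratio), 0.5, ratio))
    gray <- sprintf("gray%d",
                    round(80 * (1 - ifelse(is.na(ratio), 0.5, ratio))))
    lines <- c("digraph dependencies {",
               sprintf("  \"%s\";", graph$nodes),
               sprintf("  \"%s\" -> \"%s\" [penwidth=%s, color=%s, label=\"%s\"];",
                       graph$edges$source, graph$edges$target, pw, gray,
                       graph$edges$family),
               "}")
    writeLines(lines, path)
  } else {
    ig <- as_igraph(graph)
    igraph::write_graph(ig, path, format = "graphml")
  }
  invisible(path)
}

#' Read the canonical JSON form of a hypergraph
#'
#' @param path Path to a JSON file produced by [write_graph()].
#' @return An `"hg_graph"` object.
#' @export
read_graph_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  num_or_na <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  edges <- do.call(rbind, lapply(obj$edges, function(e) {
    data.frame(source = e$source, target = e$target, family = e$family,
               ratio = num_or_na(e$ratio), zscore = num_or_na(e$zscore),
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) edges <- .empty_edges()
  .new_graph(nodes = vapply(obj$nodes, identity, character(1)),
             edges = edges, reports = NULL)
}

#' Convert a hypergraph to an igraph object
#'
#' @param graph An `"hg_graph"`.
#' @return An igraph directed graph with `family`, `ratio` and `zscore`
#'   edge attributes.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "hg_graph"))
  edges <- graph$edges
  edges$ratio[is.na(edges$ratio)] <- NaN
  edges$zscore[is.na(edges$zscore)] <- NaN
  igraph::graph_from_data_frame(edges, directed = TRUE,
                                vertices = data.frame(name = graph$nodes))
}
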