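#' Construct a two-condition measurement table
#'
#' Holds, per node, either a single value per condition (\code{m_e1},
#' \code{m_e2}) or condition means plus replicate variances (\code{var_e1},
#' \code{var_e2}) with global replicate counts \code{n1}, \code{n2}. The
#' variance basis is all-or-nothing: mixing nodes with and without variances
#' would put raw and Welch-standardized differentials on incomparable scales,
#' so it is rejected.
#'
#' @param data data frame with columns \code{node}, \code{m_e1}, \code{m_e2}
#'   and optionally \code{var_e1}, \code{var_e2}.
#' @param n1,n2 replicate counts for the two conditions; required (each
#'   >= 2) when variances are present.
#' @return An object of class \code{"measurement_table"}: list with elements
#'   \code{data}, \code{n1}, \code{n2}, \code{has_variance}.
#' @examples
#' measurement_table(data.frame(node = c("A", "B"),
#'                              m_e1 = c(1, 3), m_e2 = c(2, 5)))
#' @export
measurement_table <- function(data, n1 = NULL, n2 = NULL) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  req <- c("node", "m_e1", "m_e2")
  if (!all(req %in% names(data)))
    stop("measurement data needs columns node, m_e1, m_e2", call. = FALSE)
  data$node <- as.character(data$node)
  dup <- unique(data$node[duplicated(data$node)])
  if (length(dup))
    stop("duplicate node identifier(s) in measurement table: ",
         paste(dQuote(utils::head(dup, 5L)), collapse = ", "), call. = FALSE)
  for (col in c("m_e1", "m_e2"))
    if (!is.numeric(data[[col]]))
      stop("column ", col, " must be numeric", call. = FALSE)
  has_var <- "var_e1" %in% names(data) || "var_e2" %in% names(data)
  if (has_var) {
    if (!all(c("var_e1", "var_e2") %in% names(data)))
      stop("variances must be given for both conditions or neither",
           call. = FALSE)
    if (anyNA(data$var_e1) || anyNA(data$var_e2))
      stop("variance columns must cover every node when present",
           call. = FALSE)
    if (any(data$var_e1 < 0) || any(data$var_e2 < 0))
      stop("variances must be nonnegative", call. = FALSE)
    if (is.null(n1) || is.null(n2))
      stop("replicate counts n1 and n2 are required with variance data",
           call. = FALSE)
    n1 <- as.integer(n1); n2 <- as.integer(n2)
    if (n1 < 2L || n2 < 2L)
      stop("replicate counts must be >= 2 when variances are used",
           call. = FALSE)
    data <- data[, c("node", "m_e1", "m_e2", "var_e1", "var_e2")]
  } else {
    data <- data[, req]
    n1 <- if (is.null(n1)) NA_integer_ else as.integer(n1)
    n2 <- if (is.null(n2)) NA_integer_ else as.integer(n2)
  }
  rownames(data) <- NULL
  structure(list(data = data, n1 = n1, n2 = n2, has_variance = has_var),
            class = "measurement_table")
}

#' @export
print.measurement_table <- function(x, ...) {
  cat(sprintf("Measurement table: %d nodes, %s\n", nrow(x$data),
              if (x$has_variance)
                sprintf("means + variances (n1 = %d, n2 = %d)", x$n1, x$n2)
              else "single value per condition"))
  print(utils::head(x$data, 6L))
  if (nrow(x$data) > 6L) cat("  ...\n")
  invisible(x)
}

#' Read a node measurement table from TSV
#'
#' @param path TSV file with a header row.
#' @param id_column name of the node identifier column.
#' @param columns_e1,columns_e2 for single measurements, the value column name
#'   for each condition; with replicate variances, a length-2 vector
#'   \code{c(mean, variance)} per condition.
#' @param n1,n2 replicate counts (required when variance columns are named).
#' @return A [measurement_table()].
#' @export
read_measurements <- function(path, id_column = "id",
                              columns_e1, columns_e2,
                              n1 = NULL, n2 = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  need <- c(id_column, columns_e1, columns_e2)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(dQuote(missing_cols), collapse = ", "), call. = FALSE)
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !(raw[[col]] %in% c("NA", "")))
    if (length(bad))
      stop(sprintf("non-numeric value %s in column %s, row %d",
                   dQuote(raw[[col]][bad[1L]]), dQuote(col), bad[1L]),
           call. = FALSE)
    v
  }
  d <- data.frame(node = raw[[id_column]], m_e1 = num(columns_e1[1L]),
                  m_e2 = num(columns_e2[1L]), stringsAsFactors = FALSE)
  if (length(columns_e1) > 1L || length(columns_e2) > 1L) {
    if (length(columns_e1) != 2L || length(columns_e2) != 2L)
      stop("give either one column (value) or two (mean, variance) per condition",
           call. = FALSE)
    d$var_e1 <- num(columns_e1[2L])
    d$var_e2 <- num(columns_e2[2L])
  }
  measurement_table(d, n1 = n1, n2 = n2)
}

#' Attach measurements to a network
#'
#' Reconciles node coverage between a network and a measurement table.
#' \code{keep_unscored} (the default) keeps uncovered nodes in the network;
#' their edges receive no score downstream and are removed by any positive
#' threshold. \code{drop_node} removes uncovered nodes and their edges;
#' \code{error} aborts on the first uncovered node.
#'
#' @param net a [typed_network()].
#' @param table a [measurement_table()].
#' @param on_missing policy for network nodes without measurements.
#' @return List with elements \code{network}, \code{table} (restricted to
#'   network nodes), and \code{report} (character vector of uncovered nodes).
#' @export
attach_measurements <- function(net, table,
                                on_missing = c("keep_unscored", "drop_node",
                                               "error")) {
  on_missing <- match.arg(on_missing)
  stopifnot(inherits(net, "typed_network"),
            inherits(table, "measurement_table"))
  uncovered <- setdiff(net$nodes, table$data$node)
  if (length(uncovered) && on_missing == "error")
    stop("node(s) without measurements: ",
         paste(dQuote(utils::head(uncovered, 10L)), collapse = ", "),
         call. = FALSE)
  if (length(uncovered) && on_missing == "drop_node") {
    keep_edge <- !(net$edges$source %in% uncovered |
                     net$edges$target %in% uncovered)
    net <- typed_network(net$edges[keep_edge, , drop = FALSE],
                         metadata = net$metadata)
  }
  tab_data <- table$data[table$data$node %in% net$nodes, , drop = FALSE]
  table <- measurement_table(tab_data,
                             n1 = if (is.na(table$n1)) NULL else table$n1,
                             n2 = if (is.na(table$n2)) NULL else table$n2)
  list(network = net, table = table,
       report = if (on_missing == "drop_node") uncovered
                else setdiff(net$nodes, table$data$node))
}
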