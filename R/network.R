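#' Canonical edge types and the default raw-value mapping
#'
#' Edges must be typed as one of \code{"interaction"}, \code{"stimulation"} or
#' \code{"inhibition"}. Files may carry these literal names (case-insensitive)
#' or the corresponding Systems Biology Ontology terms: SBO:0000231
#' (interaction), SBO:0000170 (stimulation), SBO:0000169 (inhibition).
#'
#' @return \code{edge_types()} returns the three canonical type names;
#'   \code{default_type_mapping()} returns the named character vector mapping
#'   the six canonical raw values to them.
#' @export
edge_types <- function() c("interaction", "stimulation", "inhibition")

#' @rdname edge_types
#' @export
default_type_mapping <- function() {
  c(interaction   = "interaction",
    stimulation   = "stimulation",
    inhibition    = "inhibition",
    "SBO:0000231" = "interaction",
    "SBO:0000170" = "stimulation",
    "SBO:0000169" = "inhibition")
}

# Resolve raw edge-type strings to canonical types. Literal-name keys match
# case-insensitively; SBO terms match exactly. Unmapped values are an error
# naming the value and the offending edge.
resolve_edge_types <- function(raw, source, target,
                               type_mapping = default_type_mapping()) {
  keys <- names(type_mapping)
  idx <- match(raw, keys)
  miss <- is.na(idx)
  if (any(miss)) {
    idx2 <- match(tolower(raw[miss]), tolower(keys))
    idx[miss][!is.na(idx2)] <- idx2[!is.na(idx2)]
  }
  bad <- which(is.na(idx))
  if (length(bad)) {
    b <- bad[1L]
    stop(sprintf(
      "unmapped interaction type %s on edge %s -> %s (%d offending edge%s); ",
      if (is.na(raw[b]) || !nzchar(raw[b])) "<missing>" else dQuote(raw[b]),
      source[b], target[b], length(bad), if (length(bad) > 1L) "s" else ""),
      "extend `type_mapping` to accept it", call. = FALSE)
  }
  out <- unname(type_mapping[idx])
  stopifnot(all(out %in% edge_types()))
  out
}

#' Construct a typed network
#'
#' The container used throughout the package: a node set plus a list of typed
#' edges. For \code{interaction} edges the pair is undirected; such edges are
#' stored with lexicographically ordered endpoints so that output is
#' reproducible. \code{stimulation}/\code{inhibition} edges are directed from
#' the regulator (source) to the regulated node (target). Self-loops and
#' duplicate edges are permitted; every edge gets a unique \code{edge_id}.
#'
#' @param edges data frame with columns \code{source}, \code{target},
#'   \code{interaction_type} and optionally \code{edge_id}.
#' @param nodes character vector of node identifiers; defaults to the edge
#'   endpoints. Extra entries define isolated nodes.
#' @param metadata named list of free-form provenance strings.
#' @return An object of class \code{"typed_network"}: a list with elements
#'   \code{nodes} (character), \code{edges} (data frame \code{edge_id},
#'   \code{source}, \code{target}, \code{interaction_type}) and
#'   \code{metadata}.
#' @examples
#' net <- typed_network(data.frame(source = "A", target = "B",
#'                                 interaction_type = "stimulation"))
#' net
#' @export
typed_network <- function(edges = NULL, nodes = NULL, metadata = list()) {
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- data.frame(edge_id = character(), source = character(),
                        target = character(),
                        interaction_type = character(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    req <- c("source", "target", "interaction_type")
    if (!all(req %in% names(edges)))
      stop("`edges` needs columns source, target, interaction_type",
           call. = FALSE)
    edges$source <- as.character(edges$source)
    edges$target <- as.character(edges$target)
    edges$interaction_type <- as.character(edges$interaction_type)
    bad <- setdiff(unique(edges$interaction_type), edge_types())
    if (length(bad))
      stop("invalid interaction_type value(s): ",
           paste(dQuote(bad), collapse = ", "), call. = FALSE)
    if (is.null(edges$edge_id))
      edges$edge_id <- sprintf("e%d", seq_len(nrow(edges)))
    edges$edge_id <- as.character(edges$edge_id)
    if (anyDuplicated(edges$edge_id))
      stop("edge_id values must be unique within a network", call. = FALSE)
    # canonical endpoint order for undirected interaction edges
    flip <- edges$interaction_type == "interaction" &
      edges$target < edges$source
    if (any(flip)) {
      tmp <- edges$source[flip]
      edges$source[flip] <- edges$target[flip]
      edges$target[flip] <- tmp
    }
    edges <- edges[, c("edge_id", "source", "target", "interaction_type")]
  }
  nodes <- sort(unique(c(as.character(nodes), edges$source, edges$target)))
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, metadata = metadata),
            class = "typed_network")
}

#' @export
print.typed_network <- function(x, ...) {
  cat(sprintf("Typed network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) {
    tab <- table(factor(x$edges$interaction_type, levels = edge_types()))
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
        "\n", sep = "")
  }
  if (length(x$metadata))
    cat("  metadata: ", paste(names(x$metadata), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

# order-insensitive equality on (nodes, source, target, type); edge ids and
# metadata are excluded, matching the round-trip contract of the file formats
networks_equal <- function(a, b) {
  if (!identical(sort(a$nodes), sort(b$nodes))) return(FALSE)
  key <- function(n) sort(with(n$edges,
                               paste(source, interaction_type, target)))
  identical(key(a), key(b))
}
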