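#' Read a typed network from SIF, GraphML or XGMML
#'
#' All three Cytoscape-era interchange formats are supported. The edge type is
#' taken from the SIF relationship column or from the edge attribute named by
#' \code{type_attribute} (default \code{"Interactiontype"}), and resolved
#' through \code{type_mapping}; the default mapping accepts the three literal
#' type names and the three SBO terms (see [default_type_mapping()]).
#' Edges whose raw type is absent or unmapped are rejected.
#'
#' @param path file to read.
#' @param format \code{"sif"}, \code{"graphml"}, \code{"xgmml"} or
#'   \code{"auto"} (dispatch on file extension).
#' @param type_attribute name of the edge attribute carrying the type.
#' @param type_mapping named character vector raw value -> canonical type.
#' @return A [typed_network()].
#' @examples
#' f <- tempfile(fileext = ".sif")
#' writeLines("A stimulation B", f)
#' read_network(f)
#' @export
read_network <- function(path, format = c("auto", "sif", "graphml", "xgmml"),
                         type_attribute = "Interactiontype",
                         type_mapping = default_type_mapping()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sif = "sif", graphml = "graphml",
                     xgmml = "xgmml", xml = "xgmml",
                     stop("cannot infer network format from extension ",
                          dQuote(ext), "; pass `format` explicitly",
                          call. = FALSE))
  }
  net <- switch(format,
                sif     = read_sif(path, type_mapping),
                graphml = read_graphml(path, type_attribute, type_mapping),
                xgmml   = read_xgmml(path, type_attribute, type_mapping))
  net$metadata$source_file <- basename(path)
  net$metadata$format <- format
  net
}

read_sif <- function(path, type_mapping) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  src <- tgt <- raw <- character()
  iso <- character()
  for (i in seq_along(lines)) {
    # tab-delimited if any tab present, otherwise whitespace-delimited
    tok <- if (grepl("\t", lines[i], fixed = TRUE))
      strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    else strsplit(trimws(lines[i]), "[[:space:]]+")[[1L]]
    tok <- tok[nzchar(tok)]
    if (length(tok) == 1L) { iso <- c(iso, tok); next }
    if (length(tok) == 2L)
      stop(sprintf("SIF format error at line %d: expected 1 or >= 3 columns",
                   i), call. = FALSE)
    # >= 3 columns fan out: source rel t1 t2 ... -> one edge per target
    k <- length(tok) - 2L
    src <- c(src, rep(tok[1L], k))
    raw <- c(raw, rep(tok[2L], k))
    tgt <- c(tgt, tok[-(1:2)])
  }
  if (!length(src))
    return(typed_network(nodes = iso))
  type <- resolve_edge_types(raw, src, tgt, type_mapping)
  typed_network(data.frame(source = src, target = tgt,
                           interaction_type = type,
                           stringsAsFactors = FALSE),
                nodes = iso)
}

read_xml_doc <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("XML format error in ", basename(path), ": ", conditionMessage(e),
         call. = FALSE))
  xml2::xml_ns_strip(doc)
  doc
}

read_graphml <- function(path, type_attribute, type_mapping) {
  doc <- read_xml_doc(path)
  if (xml2::xml_name(doc) != "graphml")
    stop("format error: ", basename(path), " has root element <",
         xml2::xml_name(doc), ">, expected <graphml>", call. = FALSE)
  # key id -> attr.name, so <data key="..."> can be resolved by name
  keys <- xml2::xml_find_all(doc, "./key")
  key_name <- stats::setNames(xml2::xml_attr(keys, "attr.name"),
                              xml2::xml_attr(keys, "id"))
  node_ids <- xml2::xml_attr(xml2::xml_find_all(doc, ".//graph/node"), "id")
  edges <- xml2::xml_find_all(doc, ".//graph/edge")
  get_data <- function(edge, name) {
    d <- xml2::xml_find_all(edge, "./data")
    nm <- key_name[xml2::xml_attr(d, "key")]
    v <- xml2::xml_text(d)[match(name, nm)]
    if (length(v)) v else NA_character_
  }
  src <- xml2::xml_attr(edges, "source")
  tgt <- xml2::xml_attr(edges, "target")
  raw <- vapply(edges, get_data, "", name = type_attribute)
  if (!length(edges)) return(typed_network(nodes = node_ids))
  type <- resolve_edge_types(raw, src, tgt, type_mapping)
  typed_network(data.frame(source = src, target = tgt,
                           interaction_type = type,
                           stringsAsFactors = FALSE),
                nodes = node_ids)
}

read_xgmml <- function(path, type_attribute, type_mapping) {
  doc <- read_xml_doc(path)
  if (xml2::xml_name(doc) != "graph")
    stop("format error: ", basename(path), " has root element <",
         xml2::xml_name(doc), ">, expected XGMML <graph>", call. = FALSE)
  nodes <- xml2::xml_find_all(doc, "./node")
  ids <- xml2::xml_attr(nodes, "id")
  labels <- xml2::xml_attr(nodes, "label")
  labels[is.na(labels)] <- ids[is.na(labels)]
  id2label <- stats::setNames(labels, ids)
  edges <- xml2::xml_find_all(doc, "./edge")
  if (!length(edges)) return(typed_network(nodes = labels))
  att_value <- function(edge, name) {
    a <- xml2::xml_find_all(edge, "./att")
    v <- xml2::xml_attr(a, "value")[match(name, xml2::xml_attr(a, "name"))]
    if (length(v)) v else NA_character_
  }
  ref <- function(x) ifelse(x %in% names(id2label), id2label[x], x)
  src <- ref(xml2::xml_attr(edges, "source"))
  tgt <- ref(xml2::xml_attr(edges, "target"))
  raw <- vapply(edges, att_value, "", name = type_attribute)
  type <- resolve_edge_types(raw, src, tgt, type_mapping)
  typed_network(data.frame(source = unname(src), target = unname(tgt),
                           interaction_type = type,
                           stringsAsFactors = FALSE),
                nodes = labels)
}

# Pull (network, edge attribute df, node attribute df) out of whatever object
# write_network is given.
as_writable <- function(x) {
  if (inherits(x, "typed_network"))
    return(list(net = x, edge_attrs = NULL, node_attrs = NULL))
  if (inherits(x, "linkscore")) {
    links <- x$links
    net <- typed_network(links[, c("edge_id", "source", "target",
                                   "interaction_type")],
                         nodes = x$network$nodes)
    ea <- links[, c("edge_id", "score", "consistency_class")]
    na <- x$measurements$data[, c("node", "m_e1", "m_e2")]
    return(list(net = net, edge_attrs = ea, node_attrs = na))
  }
  if (inherits(x, "condensation")) {
    links <- x$kept
    net <- typed_network(links[, c("edge_id", "source", "target",
                                   "interaction_type")])
    ea <- if (nrow(links)) links[, c("edge_id", "score", "consistency_class")]
    na <- x$measurements$data[x$measurements$data$node %in% net$nodes,
                              c("node", "m_e1", "m_e2"), drop = FALSE]
    return(list(net = net, edge_attrs = ea, node_attrs = na))
  }
  stop("cannot write object of class ", class(x)[1L], call. = FALSE)
}

#' Write a network (optionally with scores and measurements) to disk
#'
#' Round-trip safe: reading a written file reproduces the nodes, edges and
#' interaction types. With \code{include_attributes = TRUE}, per-edge
#' \code{link_score} / \code{consistency_class} and per-node \code{m_e1} /
#' \code{m_e2} are embedded as attributes (GraphML \code{<data>}, XGMML
#' \code{<att>}); for SIF, which has no attribute slots, they go to a sidecar
#' TSV next to the file (\code{<path>.edges.tsv}).
#'
#' @param x a [typed_network()], a [linkscore()] fit or a condensation result.
#' @param path output file.
#' @param format \code{"sif"}, \code{"graphml"} or \code{"xgmml"}.
#' @param include_attributes embed scores/measurements where available.
#' @return Invisibly, the path(s) written.
#' @export
write_network <- function(x, path, format = c("graphml", "sif", "xgmml"),
                          include_attributes = FALSE) {
  format <- match.arg(format)
  w <- as_writable(x)
  if (!include_attributes) w$edge_attrs <- w$node_attrs <- NULL
  paths <- switch(format,
                  sif     = write_sif(w, path),
                  graphml = write_graphml(w, path),
                  xgmml   = write_xgmml(w, path))
  invisible(paths)
}

write_sif <- function(w, path) {
  net <- w$net
  lines <- character()
  if (nrow(net$edges))
    lines <- with(net$edges, paste(source, interaction_type, target,
                                   sep = "\t"))
  iso <- setdiff(net$nodes, c(net$edges$source, net$edges$target))
  con <- file(path, "wb")  # binary mode: LF endings on every platform
  writeLines(c(lines, iso), con)
  close(con)
  paths <- path
  if (!is.null(w$edge_attrs)) {
    sidecar <- paste0(path, ".edges.tsv")
    tab <- cbind(net$edges, w$edge_attrs[match(net$edges$edge_id,
                                               w$edge_attrs$edge_id),
                                         -1L, drop = FALSE])
    utils::write.table(tab, sidecar, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, sidecar)
  }
  paths
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

num_attr <- function(v) formatC(v, format = "g", digits = 15)

write_graphml <- function(w, path) {
  net <- w$net
  lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
             "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
             paste0("  <key id=\"d0\" for=\"edge\" ",
                    "attr.name=\"Interactiontype\" attr.type=\"string\"/>"))
  has_ea <- !is.null(w$edge_attrs)
  has_na <- !is.null(w$node_attrs)
  if (has_ea)
    lines <- c(lines,
      "  <key id=\"d1\" for=\"edge\" attr.name=\"link_score\" attr.type=\"double\"/>",
      "  <key id=\"d2\" for=\"edge\" attr.name=\"consistency_class\" attr.type=\"string\"/>")
  if (has_na)
    lines <- c(lines,
      "  <key id=\"d3\" for=\"node\" attr.name=\"m_e1\" attr.type=\"double\"/>",
      "  <key id=\"d4\" for=\"node\" attr.name=\"m_e2\" attr.type=\"double\"/>")
  lines <- c(lines, "  <graph id=\"G\" edgedefault=\"directed\">")
  for (n in net$nodes) {
    if (has_na && n %in% w$node_attrs$node) {
      r <- w$node_attrs[w$node_attrs$node == n, ]
      lines <- c(lines, sprintf(
        "    <node id=\"%s\"><data key=\"d3\">%s</data><data key=\"d4\">%s</data></node>",
        xml_escape(n), num_attr(r$m_e1), num_attr(r$m_e2)))
    } else
      lines <- c(lines, sprintf("    <node id=\"%s\"/>", xml_escape(n)))
  }
  if (nrow(net$edges)) for (i in seq_len(nrow(net$edges))) {
    e <- net$edges[i, ]
    data <- sprintf("<data key=\"d0\">%s</data>", e$interaction_type)
    if (has_ea && e$edge_id %in% w$edge_attrs$edge_id) {
      a <- w$edge_attrs[w$edge_attrs$edge_id == e$edge_id, ]
      if (is.finite(a$score))
        data <- paste0(data,
                       sprintf("<data key=\"d1\">%s</data>", num_attr(a$score)),
                       sprintf("<data key=\"d2\">%s</data>",
                               a$consistency_class))
    }
    lines <- c(lines, sprintf(
      "    <edge id=\"%s\" source=\"%s\" target=\"%s\">%s</edge>",
      xml_escape(e$edge_id), xml_escape(e$source), xml_escape(e$target),
      data))
  }
  lines <- c(lines, "  </graph>", "</graphml>")
  con <- file(path, "wb"); writeLines(lines, con); close(con)
  path
}

write_xgmml <- function(w, path) {
  net <- w$net
  id_of <- stats::setNames(seq_along(net$nodes), net$nodes)
  lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
             paste0("<graph label=\"network\" directed=\"1\" ",
                    "xmlns=\"http://www.cs.rpi.edu/XGMML\">"))
  has_na <- !is.null(w$node_attrs)
  for (n in net$nodes) {
    atts <- ""
    if (has_na && n %in% w$node_attrs$node) {
      r <- w$node_attrs[w$node_attrs$node == n, ]
      atts <- sprintf(paste0(
        "<att name=\"m_e1\" type=\"real\" value=\"%s\"/>",
        "<att name=\"m_e2\" type=\"real\" value=\"%s\"/>"),
        num_attr(r$m_e1), num_attr(r$m_e2))
    }
    lines <- c(lines, sprintf("  <node label=\"%s\" id=\"%d\">%s</node>",
                              xml_escape(n), id_of[[n]], atts))
  }
  if (nrow(net$edges)) for (i in seq_len(nrow(net$edges))) {
    e <- net$edges[i, ]
    atts <- sprintf(
      "<att name=\"Interactiontype\" type=\"string\" value=\"%s\"/>",
      e$interaction_type)
    if (!is.null(w$edge_attrs) && e$edge_id %in% w$edge_attrs$edge_id) {
      a <- w$edge_attrs[w$edge_attrs$edge_id == e$edge_id, ]
      if (is.finite(a$score))
        atts <- paste0(atts, sprintf(paste0(
          "<att name=\"link_score\" type=\"real\" value=\"%s\"/>",
          "<att name=\"consistency_class\" type=\"string\" value=\"%s\"/>"),
          num_attr(a$score), a$consistency_class))
    }
    lines <- c(lines, sprintf(
      "  <edge label=\"%s (%s) %s\" source=\"%d\" target=\"%d\">%s</edge>",
      xml_escape(e$source), e$interaction_type, xml_escape(e$target),
      id_of[[e$source]], id_of[[e$target]], atts))
  }
  lines <- c(lines, "</graph>")
  con <- file(path, "wb"); writeLines(lines, con); close(con)
  path
}
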