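# Minimal deterministic ZIP writer (stored entries only, fixed timestamps).
# Used to build session archives; reading goes through utils::unzip.

crc32_table <- local({
  tab <- integer(256L)
  for (i in 0:255) {
    c <- i
    for (k in 1:8)
      c <- if (bitwAnd(c, 1L))
        bitwXor(bitwShiftR(c, 1L), -306674912L)  # reversed polynomial
      else bitwShiftR(c, 1L)
    tab[i + 1L] <- c
  }
  tab
})

crc32 <- function(bytes) {
  c <- -1L
  for (b in as.integer(bytes))
    c <- bitwXor(bitwShiftR(c, 8L),
                 crc32_table[bitwAnd(bitwXor(c, b), 255L) + 1L])
  bitwXor(c, -1L)
}

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                            endian = "little")
u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                            endian = "little")

# entries: named list of raw vectors (names = archive paths)
write_zip <- function(entries, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- integer(length(entries))
  crcs <- integer(length(entries))
  pos <- 0L
  for (i in seq_along(entries)) {
    name <- charToRaw(names(entries)[i])
    data <- entries[[i]]
    crcs[i] <- crc32(data)
    offsets[i] <- pos
    header <- c(u32(67324752L),            # local header signature
                u16(20L), u16(0L), u16(0L),  # version, flags, method = store
                u16(0L), u16(0x21L),         # fixed mod time/date
                u32(crcs[i]), u32(length(data)), u32(length(data)),
                u16(length(name)), u16(0L))
    writeBin(c(header, name, data), con)
    pos <- pos + length(header) + length(name) + length(data)
  }
  cd_start <- pos
  cd_size <- 0L
  for (i in seq_along(entries)) {
    name <- charToRaw(names(entries)[i])
    data <- entries[[i]]
    rec <- c(u32(33639248L),               # central directory signature
             u16(20L), u16(20L), u16(0L), u16(0L),
             u16(0L), u16(0x21L),
             u32(crcs[i]), u32(length(data)), u32(length(data)),
             u16(length(name)), u16(0L), u16(0L),
             u16(0L), u16(0L), u32(0L), u32(offsets[i]))
    writeBin(c(rec, name), con)
    cd_size <- cd_size + length(rec) + length(name)
  }
  writeBin(c(u32(101010256L), u16(0L), u16(0L),  # end of central directory
             u16(length(entries)), u16(length(entries)),
             u32(cd_size), u32(cd_start), u16(0L)), con)
  invisible(path)
}

#' Extract networks from a Cytoscape-style session archive
#'
#' A session file is a zip container holding XGMML network documents. Every
#' embedded network is returned together with its per-node attributes (the
#' \code{<att>} values attached to its \code{<node>} elements), so saved
#' analyses can be replayed without the original GUI. Only the zip/XGMML
#' layer is interpreted; visual properties are ignored.
#'
#' @param path session archive (zip).
#' @param type_attribute,type_mapping edge typing, as in [read_network()].
#' @return Named list (one element per embedded network) of lists with
#'   elements \code{name}, \code{network} (a [typed_network()]) and
#'   \code{node_attributes} (data frame, one row per node).
#' @export
extract_session_networks <- function(path,
                                     type_attribute = "Interactiontype",
                                     type_mapping = default_type_mapping()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  magic <- readBin(path, "raw", n = 2L)
  if (!identical(magic, charToRaw("PK")))
    stop("format error: ", basename(path), " is not a zip archive",
         call. = FALSE)
  exdir <- tempfile("session_")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE))
  files <- utils::unzip(path, exdir = exdir)
  xgmml <- files[grepl("\\.(xgmml|xml)$", files, ignore.case = TRUE)]
  # keep only files whose root element is an XGMML <graph>
  is_graph <- vapply(xgmml, function(f)
    tryCatch(xml2::xml_name(xml2::read_xml(f)) == "graph",
             error = function(e) FALSE), logical(1L))
  xgmml <- xgmml[is_graph]
  if (!length(xgmml))
    stop("format error: no embedded XGMML networks in ", basename(path),
         call. = FALSE)
  out <- lapply(xgmml, function(f) {
    net <- read_xgmml(f, type_attribute, type_mapping)
    list(name = sub("\\.(xgmml|xml)$", "", basename(f), ignore.case = TRUE),
         network = net,
         node_attributes = read_xgmml_node_attributes(f))
  })
  stats::setNames(out, vapply(out, `[[`, "", "name"))
}

read_xgmml_node_attributes <- function(path) {
  doc <- read_xml_doc(path)
  nodes <- xml2::xml_find_all(doc, "./node")
  labels <- xml2::xml_attr(nodes, "label")
  ids <- xml2::xml_attr(nodes, "id")
  labels[is.na(labels)] <- ids[is.na(labels)]
  rows <- lapply(seq_along(nodes), function(i) {
    a <- xml2::xml_find_all(nodes[[i]], "./att")
    vals <- as.list(xml2::xml_attr(a, "value"))
    names(vals) <- xml2::xml_attr(a, "name")
    types <- xml2::xml_attr(a, "type")
    vals[types %in% c("real", "integer")] <-
      lapply(vals[types %in% c("real", "integer")], as.numeric)
    vals
  })
  cols <- unique(unlist(lapply(rows, names)))
  df <- data.frame(node = labels, stringsAsFactors = FALSE)
  for (col in cols)
    df[[col]] <- unlist(lapply(rows, function(r)
      if (is.null(r[[col]])) NA else r[[col]]))
  df
}

#' Build a synthetic session archive from a network and measurements
#'
#' Test double for [extract_session_networks()]: wraps the network (with the
#' measurement values attached as node attributes) as a single XGMML
#' document inside a minimal zip archive. The archive is byte-deterministic
#' for identical inputs.
#'
#' @param net a [typed_network()].
#' @param table a [measurement_table()] (may be \code{NULL}).
#' @param path output archive path.
#' @param name network name inside the archive.
#' @return Invisibly, \code{path}.
#' @export
make_session_fixture <- function(net, table = NULL, path,
                                 name = "network") {
  stopifnot(inherits(net, "typed_network"))
  node_attrs <- if (!is.null(table))
    table$data[table$data$node %in% net$nodes, , drop = FALSE]
  w <- list(net = net, edge_attrs = NULL,
            node_attrs = if (!is.null(node_attrs) && nrow(node_attrs))
              node_attrs)
  tmp <- tempfile(fileext = ".xgmml")
  on.exit(unlink(tmp))
  write_xgmml(w, tmp)
  entries <- list()
  entries[[sprintf("networks/%s.xgmml", name)]] <-
    readBin(tmp, "raw", n = file.info(tmp)$size)
  write_zip(entries, path)
  invisible(path)
}
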