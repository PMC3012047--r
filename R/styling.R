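default_palette <- function() {
  rbind(low = c(0, 200, 0), mid = c(255, 255, 255), high = c(220, 0, 0))
}

#' Build a quantile-anchored color scale for node values
#'
#' Anchors the scale at the 10\%, 50\% and 90\% empirical quantiles of the
#' pooled measurement values (both conditions together). Values at or below
#' the low anchor map to the low color, values at or above the high anchor to
#' the high color ("same intensity" clamping); in between, colors are
#' linearly interpolated per RGB channel through the mid color at the median.
#'
#' @param values numeric vector to anchor on (typically all m_e1 and m_e2
#'   pooled).
#' @param q_low,q_mid,q_high anchor quantiles, \code{0 <= q_low < q_mid <
#'   q_high <= 1}.
#' @param palette 3 x 3 matrix of RGB rows (low, mid, high), 0-255. Default
#'   green / white / red.
#' @return An object of class \code{"color_scale"} with fields \code{q10},
#'   \code{q50}, \code{q90} and the palette.
#' @examples
#' sc <- build_color_scale(1:100)
#' unlist(sc[c("q10", "q50", "q90")])  # 10.9, 50.5, 90.1
#' @export
build_color_scale <- function(values, q_low = 0.10, q_mid = 0.50,
                              q_high = 0.90, palette = default_palette()) {
  values <- values[!is.na(values)]
  if (!length(values))
    stop("cannot build a color scale from an empty value list",
         call. = FALSE)
  if (!(q_low >= 0 && q_low < q_mid && q_mid < q_high && q_high <= 1))
    stop("need 0 <= q_low < q_mid < q_high <= 1", call. = FALSE)
  palette <- as.matrix(palette)
  stopifnot(identical(dim(palette), c(3L, 3L)),
            all(palette >= 0), all(palette <= 255))
  q <- stats::quantile(values, c(q_low, q_mid, q_high), names = FALSE,
                       type = 7)
  structure(list(q10 = q[1L], q50 = q[2L], q90 = q[3L], palette = palette),
            class = "color_scale")
}

#' @export
print.color_scale <- function(x, ...) {
  cat(sprintf("Color scale: anchors %.4g (low) / %.4g (mid) / %.4g (high)\n",
              x$q10, x$q50, x$q90))
  invisible(x)
}

#' Map measurement values to colors on a quantile scale
#'
#' @param v numeric vector of values.
#' @param scale a [build_color_scale()] result.
#' @return Character vector of hex colors (\code{"#RRGGBB"}).
#' @export
value_to_color <- function(v, scale) {
  stopifnot(inherits(scale, "color_scale"))
  p <- scale$palette
  interp <- function(v, a, b, ca, cb) {
    f <- if (b > a) pmin(pmax((v - a) / (b - a), 0), 1) else rep(1, length(v))
    sapply(seq_along(v),
           function(i) (1 - f[i]) * ca + f[i] * cb)  # 3 x n channel matrix
  }
  lo <- v <= scale$q10 | scale$q10 == scale$q90
  hi <- v >= scale$q90 & !lo
  mid_lo <- !lo & !hi & v <= scale$q50
  mid_hi <- !lo & !hi & v > scale$q50
  rgbm <- matrix(0, 3L, length(v))
  rgbm[, lo] <- p["low", ]
  if (scale$q10 == scale$q90) rgbm[, lo] <- p["mid", ]  # degenerate scale
  rgbm[, hi] <- p["high", ]
  if (any(mid_lo))
    rgbm[, mid_lo] <- interp(v[mid_lo], scale$q10, scale$q50,
                             p["low", ], p["mid", ])
  if (any(mid_hi))
    rgbm[, mid_hi] <- interp(v[mid_hi], scale$q50, scale$q90,
                             p["mid", ], p["high", ])
  rgbm <- round(rgbm)
  grDevices::rgb(rgbm[1L, ], rgbm[2L, ], rgbm[3L, ], maxColorValue = 255)
}

# white -> full color, fraction f of saturation; sign picks red/green side
score_to_color <- function(score, max_abs) {
  f <- if (max_abs > 0) pmin(abs(score) / max_abs, 1) else rep(1, length(score))
  full <- ifelse(score >= 0, "#DC0000", "#00C800")
  up <- grDevices::col2rgb(full)
  mixed <- round(255 * rep(1 - f, each = 3L) + up * rep(f, each = 3L))
  out <- grDevices::rgb(mixed[1L, ], mixed[2L, ], mixed[3L, ],
                        maxColorValue = 255)
  out[score == 0] <- "#FFFFFF"
  out
}

#' Compute the visual style of a scored (or condensed) network
#'
#' Nodes are drawn as two-half circles: left half colored by the E1 value,
#' right half by the E2 value, on the shared quantile [build_color_scale()].
#' Edges are red for startups (score > 0) and green for shutdowns (score <
#' 0); color saturation and line width grow linearly with |score| up to the
#' largest kept |score| (a single shared score maps to full width). Links in
#' a non-consistent class (source/target principle, inconsistent) are
#' flagged \code{wavy} and rendered dashed.
#'
#' @param x a [linkscore()] fit or condensation result.
#' @param scale optional [build_color_scale()]; defaults to the pooled
#'   measurement values of \code{x}.
#' @param width_range numeric (min, max) edge widths, min > 0.
#' @return An object of class \code{"style_map"}: list with data frames
#'   \code{node_styles} (node, left_color, right_color) and
#'   \code{edge_styles} (edge_id, color, width, wavy).
#' @export
style_network <- function(x, scale = NULL, width_range = c(1, 8)) {
  if (inherits(x, "linkscore")) {
    links <- x$links[!is.na(x$links$score), , drop = FALSE]
    tab <- x$measurements
    nodes <- x$network$nodes
  } else if (inherits(x, "condensation")) {
    links <- x$kept
    tab <- x$measurements
    nodes <- x$retained_nodes
  } else stop("cannot style object of class ", class(x)[1L], call. = FALSE)
  stopifnot(length(width_range) == 2L, width_range[1L] > 0,
            width_range[2L] >= width_range[1L])
  if (is.null(scale))
    scale <- build_color_scale(c(tab$data$m_e1, tab$data$m_e2))
  nd <- tab$data[tab$data$node %in% nodes, , drop = FALSE]
  node_styles <- data.frame(node = nd$node,
                            left_color = value_to_color(nd$m_e1, scale),
                            right_color = value_to_color(nd$m_e2, scale),
                            stringsAsFactors = FALSE)
  if (nrow(links)) {
    max_abs <- max(abs(links$score))
    frac <- if (max_abs > 0) abs(links$score) / max_abs
            else rep(1, nrow(links))
    edge_styles <- data.frame(
      edge_id = links$edge_id,
      color = score_to_color(links$score, max_abs),
      width = width_range[1L] + diff(width_range) * frac,
      wavy = links$consistency_class %in%
        c("source_principle", "target_principle", "inconsistent"),
      stringsAsFactors = FALSE)
  } else {
    edge_styles <- data.frame(edge_id = character(), color = character(),
                              width = numeric(), wavy = logical(),
                              stringsAsFactors = FALSE)
  }
  structure(list(node_styles = node_styles, edge_styles = edge_styles,
                 scale = scale),
            class = "style_map")
}

#' @export
print.style_map <- function(x, ...) {
  cat(sprintf("Style map: %d node styles, %d edge styles (%d wavy)\n",
              nrow(x$node_styles), nrow(x$edge_styles),
              sum(x$edge_styles$wavy)))
  invisible(x)
}

#' Write style attributes as TSV tables
#'
#' Pure, byte-stable export of the style map (node half-colors, edge
#' color/width/wavy) for downstream tools.
#'
#' @param style a [style_network()] result.
#' @param node_path,edge_path output TSV paths (\code{NULL} skips).
#' @return Invisibly, the paths written.
#' @export
write_style <- function(style, node_path = NULL, edge_path = NULL) {
  stopifnot(inherits(style, "style_map"))
  if (!is.null(node_path))
    utils::write.table(style$node_styles, node_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(edge_path))
    utils::write.table(style$edge_styles, edge_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(c(node_path, edge_path))
}

#' Render a condensed network to a static figure
#'
#' Static stand-in for an interactive network canvas: force-directed layout
#' (deterministic for a fixed \code{layout_seed}), two-half node circles
#' colored by condition, edges colored/width-scaled by score, wavy links
#' dashed, with a legend for the color scale.
#'
#' @param result a condensation result (or [linkscore()] fit).
#' @param style optional [style_network()] result; computed if missing.
#' @param path output image file (\code{.png} or \code{.svg}); \code{NULL}
#'   draws on the active device.
#' @param layout_seed integer seed for the layout.
#' @return Invisibly, \code{path}.
#' @export
render_figure <- function(result, style = NULL, path = NULL,
                          layout_seed = 1L) {
  if (is.null(style)) style <- style_network(result)
  links <- if (inherits(result, "condensation")) result$kept
           else result$links[!is.na(result$links$score), , drop = FALSE]
  nodes <- style$node_styles$node
  if (!is.null(path)) {
    ext <- tolower(tools::file_ext(path))
    switch(ext,
           png = grDevices::png(path, width = 1200, height = 1000,
                                res = 130),
           svg = grDevices::svg(path, width = 9, height = 7.5),
           stop("unsupported figure format: ", ext, call. = FALSE))
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  graphics::par(mar = c(1, 1, 2, 1))
  if (!length(nodes)) {
    graphics::plot.new()
    graphics::title("Condensed network (empty)")
    draw_scale_legend(style$scale)
    return(invisible(path))
  }
  g <- igraph::graph_from_data_frame(
    links[, c("source", "target"), drop = FALSE], directed = TRUE,
    vertices = data.frame(name = nodes))
  set.seed(layout_seed)
  lay <- igraph::layout_with_fr(g)
  lay <- igraph::norm_coords(lay)
  graphics::plot(NA, xlim = c(-1.15, 1.15), ylim = c(-1.3, 1.15),
                 axes = FALSE, xlab = "", ylab = "", asp = 1)
  graphics::title("Condensed network")
  pos <- stats::setNames(split(lay, row(lay)), igraph::V(g)$name)
  es <- style$edge_styles
  if (nrow(links)) for (i in seq_len(nrow(links))) {
    p1 <- pos[[links$source[i]]]; p2 <- pos[[links$target[i]]]
    j <- match(links$edge_id[i], es$edge_id)
    graphics::segments(p1[1L], p1[2L], p2[1L], p2[2L], col = es$color[j],
                       lwd = es$width[j], lty = if (es$wavy[j]) 2L else 1L)
  }
  r <- 0.045
  ns <- style$node_styles
  for (i in seq_len(nrow(ns))) {
    p <- pos[[ns$node[i]]]
    draw_half_circle(p[1L], p[2L], r, ns$left_color[i], left = TRUE)
    draw_half_circle(p[1L], p[2L], r, ns$right_color[i], left = FALSE)
    graphics::text(p[1L], p[2L] + 1.6 * r, ns$node[i], cex = 0.55)
  }
  draw_scale_legend(style$scale)
  invisible(path)
}

draw_half_circle <- function(x, y, r, col, left = TRUE) {
  th <- if (left) seq(pi / 2, 3 * pi / 2, length.out = 40L)
        else seq(-pi / 2, pi / 2, length.out = 40L)
  graphics::polygon(x + r * cos(th), y + r * sin(th), col = col,
                    border = "grey30")
}

draw_scale_legend <- function(scale) {
  vals <- seq(scale$q10, scale$q90, length.out = 50L)
  if (scale$q10 == scale$q90) vals <- rep(scale$q50, 50L)
  cols <- value_to_color(vals, scale)
  xs <- seq(-0.5, 0.5, length.out = 51L)
  usr <- graphics::par("usr")
  y0 <- usr[3L] + 0.06 * diff(usr[3:4])
  graphics::rect(xs[-51L], y0, xs[-1L], y0 + 0.04 * diff(usr[3:4]),
                 col = cols, border = NA)
  graphics::text(c(-0.5, 0, 0.5), y0 - 0.03 * diff(usr[3:4]),
                 signif(c(scale$q10, scale$q50, scale$q90), 3), cex = 0.6)
}

#' @rdname render_figure
#' @param x a condensation result (for the plot method).
#' @param ... passed on to [render_figure()].
#' @export
plot.condensation <- function(x, ...) {
  render_figure(x, ...)
  invisible(x)
}
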