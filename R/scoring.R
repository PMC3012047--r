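#' Per-node differentials between two conditions
#'
#' The differential of node A is the change of its measured value from
#' condition E1 to condition E2, \eqn{D_A = M_{A,E2} - M_{A,E1}}. When
#' replicate variances are available the differential is standardized by the
#' pooled standard error from Welch's formula,
#' \deqn{D_A = \frac{M_{A,E2} - M_{A,E1}}
#'                  {\sqrt{Var_{A,E1}/n_1 + Var_{A,E2}/n_2}},}
#' which is the Welch two-sample t statistic; no p-value is attached, the
#' statistic is used purely as a variance-aware effect size. Both functions
#' are vectorized.
#'
#' @param m_e1,m_e2 measured value (or replicate mean) in conditions E1, E2.
#' @param var_e1,var_e2 replicate variances (nonnegative).
#' @param n1,n2 replicate counts (>= 1; >= 2 for meaningful variances).
#' @param var_floor optional lower bound substituted for a zero pooled
#'   variance term. The default (\code{NULL}) treats a zero pooled variance
#'   as an error rather than fabricating an unbounded score.
#' @return Numeric vector of signed differentials (positive = up in E2).
#' @examples
#' differential(5.37, 7.15)                   # 1.78
#' differential_welch(0, 2, 1, 1, 4, 4)       # 2 / sqrt(0.5)
#' @export
differential <- function(m_e1, m_e2) {
  if (!all(is.finite(m_e1)) || !all(is.finite(m_e2)))
    stop("measurement values must be finite", call. = FALSE)
  m_e2 - m_e1
}

#' @rdname differential
#' @export
differential_welch <- function(m_e1, m_e2, var_e1, var_e2, n1, n2,
                               var_floor = NULL) {
  if (!all(is.finite(m_e1)) || !all(is.finite(m_e2)))
    stop("measurement values must be finite", call. = FALSE)
  if (any(var_e1 < 0) || any(var_e2 < 0))
    stop("variances must be nonnegative", call. = FALSE)
  if (any(n1 < 1) || any(n2 < 1))
    stop("replicate counts must be positive", call. = FALSE)
  pooled <- var_e1 / n1 + var_e2 / n2
  if (any(pooled <= 0)) {
    if (is.null(var_floor))
      stop("zero pooled variance: the Welch denominator is undefined; ",
           "set `var_floor` to substitute a floor", call. = FALSE)
    warning(sprintf("%d zero pooled variance(s) floored at %g",
                    sum(pooled <= 0), var_floor), call. = FALSE)
    pooled <- pmax(pooled, var_floor)
  }
  (m_e2 - m_e1) / sqrt(pooled)
}

#' Signed link score of a typed edge
#'
#' For an interaction or stimulation between A and B the score is the sum of
#' the node differentials, \eqn{D_A + D_B}; for an inhibition of B by A it is
#' the difference \eqn{D_A - D_B}, so that anticorrelated change of inhibitor
#' and target (the expected pattern) scores high. A positive score is a
#' startup of the link, a negative score a shutdown. On log-transformed
#' abundances the interaction score equals the log fold change of the
#' mass-action complex activity,
#' \eqn{\log\frac{[A]_{E2}[B]_{E2}}{[A]_{E1}[B]_{E1}}}.
#' Vectorized over all arguments.
#'
#' @param edge_type \code{"interaction"}, \code{"stimulation"} or
#'   \code{"inhibition"} (recycled as needed).
#' @param d_source,d_target differentials of the edge's source (regulator)
#'   and target node. For interactions the two roles are exchangeable.
#' @return Numeric vector of signed link scores.
#' @examples
#' link_score("stimulation", 1.78, 0.82)  #  2.60: startup
#' link_score("inhibition",   1,   -1)    #  2:    startup (anticorrelated)
#' @export
link_score <- function(edge_type, d_source, d_target) {
  bad <- setdiff(unique(edge_type), edge_types())
  if (length(bad))
    stop("unknown edge type(s): ", paste(dQuote(bad), collapse = ", "),
         call. = FALSE)
  n <- max(length(edge_type), length(d_source), length(d_target))
  edge_type <- rep_len(edge_type, n)
  d_source <- rep_len(d_source, n)
  d_target <- rep_len(d_target, n)
  ifelse(edge_type == "inhibition", d_source - d_target,
         d_source + d_target)
}

#' Consistency classification of a scored link
#'
#' Classifies the change pattern of an edge's two endpoints. With
#' \code{s}/\code{t} the signs of the source/target differentials after
#' dead-banding at \code{epsilon} (|d| <= epsilon counts as no change), and
#' "agreement" meaning equal signs for interaction/stimulation but opposite
#' signs for inhibition:
#' \itemize{
#'   \item both nonzero and agreeing: \code{consistent};
#'   \item both inside the dead-band: \code{no_change};
#'   \item source change dominates a zero or disagreeing target
#'     (|d_source| > |d_target|): \code{source_principle} — the regulator's
#'     change alone justifies the startup/shutdown call, the target being
#'     counteracted by effectors outside the network;
#'   \item target change dominates a zero or disagreeing source:
#'     \code{target_principle};
#'   \item otherwise (including equal-magnitude disagreement):
#'     \code{inconsistent}.
#' }
#' The two principles and the inconsistent class correspond to the "wavy
#' line" rendering of the condensed network. Vectorized.
#'
#' @param edge_type edge type (recycled).
#' @param d_source,d_target node differentials.
#' @param epsilon nonnegative dead-band; 0 is a strict sign test.
#' @return Character vector over \{consistent, source_principle,
#'   target_principle, inconsistent, no_change\}.
#' @export
classify_consistency <- function(edge_type, d_source, d_target,
                                 epsilon = 0) {
  if (length(epsilon) != 1L || is.na(epsilon) || epsilon < 0)
    stop("`epsilon` must be a single nonnegative number", call. = FALSE)
  n <- max(length(edge_type), length(d_source), length(d_target))
  edge_type <- rep_len(edge_type, n)
  d_source <- rep_len(d_source, n); d_target <- rep_len(d_target, n)
  s <- ifelse(abs(d_source) <= epsilon, 0, sign(d_source))
  t <- ifelse(abs(d_target) <= epsilon, 0, sign(d_target))
  agree <- ifelse(edge_type == "inhibition", s == -t, s == t)
  out <- rep("inconsistent", n)
  out[s != 0 & t != 0 & agree] <- "consistent"
  out[s == 0 & t == 0] <- "no_change"
  src_dom <- s != 0 & !(t != 0 & agree) & abs(d_source) > abs(d_target)
  tgt_dom <- t != 0 & !(s != 0 & agree) & abs(d_target) > abs(d_source)
  out[src_dom] <- "source_principle"
  out[tgt_dom] <- "target_principle"
  out
}

#' Score every link of a network between two conditions
#'
#' The fitting function of the package: computes one differential per node
#' (raw differences, or Welch-standardized when the table carries replicate
#' variances) and one signed link score per edge, together with the
#' consistency class of each link. Nodes without measurements are handled by
#' the \code{on_missing} policy of [attach_measurements()]; under the default
#' \code{keep_unscored} their edges get an \code{NA} score and are dropped by
#' any condensation threshold.
#'
#' @param network a [typed_network()].
#' @param measurements a [measurement_table()] covering (some of) its nodes.
#' @param epsilon dead-band for [classify_consistency()].
#' @param var_floor passed to [differential_welch()] for degenerate
#'   variances.
#' @param on_missing coverage policy, see [attach_measurements()].
#' @return An object of class \code{"linkscore"}: list with elements
#'   \code{links} (data frame: edge_id, source, target, interaction_type,
#'   d_source, d_target, score, direction, consistency_class),
#'   \code{differentials} (data frame: node, d, basis), \code{basis}
#'   (\code{"single"} or \code{"welch"}), \code{network},
#'   \code{measurements}, \code{unscored} (edge ids without measurements).
#' @examples
#' net <- typed_network(data.frame(source = "A", target = "B",
#'                                 interaction_type = "stimulation"))
#' tab <- measurement_table(data.frame(node = c("A", "B"),
#'                                     m_e1 = c(1, 3), m_e2 = c(2, 5)))
#' fit <- linkscore(net, tab)
#' coef(fit)   # named link scores; here A->B scores 1 + 2 = 3
#' @export
linkscore <- function(network, measurements, epsilon = 0, var_floor = NULL,
                      on_missing = c("keep_unscored", "drop_node", "error")) {
  att <- attach_measurements(network, measurements, match.arg(on_missing))
  net <- att$network; tab <- att$table
  basis <- if (tab$has_variance) "welch" else "single"
  d <- if (tab$has_variance)
    differential_welch(tab$data$m_e1, tab$data$m_e2,
                       tab$data$var_e1, tab$data$var_e2,
                       tab$n1, tab$n2, var_floor = var_floor)
  else differential(tab$data$m_e1, tab$data$m_e2)
  diffs <- data.frame(node = tab$data$node, d = d, basis = basis,
                      stringsAsFactors = FALSE)
  e <- net$edges
  d_of <- stats::setNames(diffs$d, diffs$node)
  ds <- unname(d_of[e$source]); dt <- unname(d_of[e$target])
  score <- rep(NA_real_, nrow(e))
  ok <- !is.na(ds) & !is.na(dt)
  score[ok] <- link_score(e$interaction_type[ok], ds[ok], dt[ok])
  consistency <- rep(NA_character_, nrow(e))
  if (any(ok))
    consistency[ok] <- classify_consistency(e$interaction_type[ok],
                                            ds[ok], dt[ok], epsilon)
  direction <- rep(NA_character_, nrow(e))
  direction[ok] <- c("shutdown", "neutral", "startup")[sign(score[ok]) + 2L]
  links <- data.frame(e, d_source = ds, d_target = dt, score = score,
                      direction = direction,
                      consistency_class = consistency,
                      stringsAsFactors = FALSE)
  rownames(links) <- NULL
  structure(list(links = links, differentials = diffs, basis = basis,
                 epsilon = epsilon, network = net, measurements = tab,
                 unscored = e$edge_id[!ok], coverage_report = att$report),
            class = "linkscore")
}

#' @export
print.linkscore <- function(x, ...) {
  cat(sprintf("Link scores (%s basis): %d edges, %d nodes\n", x$basis,
              nrow(x$links), length(x$network$nodes)))
  sc <- x$links$score
  if (any(!is.na(sc)))
    cat(sprintf("  score range [%.4g, %.4g]; %d startup, %d shutdown, %d neutral\n",
                min(sc, na.rm = TRUE), max(sc, na.rm = TRUE),
                sum(sc > 0, na.rm = TRUE), sum(sc < 0, na.rm = TRUE),
                sum(sc == 0, na.rm = TRUE)))
  if (length(x$unscored))
    cat(sprintf("  %d edge(s) unscored (nodes without measurements)\n",
                length(x$unscored)))
  invisible(x)
}

#' @export
summary.linkscore <- function(object, ...) {
  sc <- object$links$score
  out <- list(
    n_edges = nrow(object$links),
    n_nodes = length(object$network$nodes),
    basis = object$basis,
    n_unscored = length(object$unscored),
    score_quantiles = stats::quantile(sc, c(0, .03, .1, .5, .9, .97, 1),
                                      na.rm = TRUE),
    direction = table(factor(object$links$direction,
                             levels = c("startup", "shutdown", "neutral"))),
    consistency = table(factor(object$links$consistency_class,
                               levels = c("consistent", "source_principle",
                                          "target_principle", "inconsistent",
                                          "no_change"))))
  class(out) <- "summary.linkscore"
  out
}

#' @export
print.summary.linkscore <- function(x, ...) {
  cat(sprintf("Link-score fit (%s basis): %d edges on %d nodes (%d unscored)\n",
              x$basis, x$n_edges, x$n_nodes, x$n_unscored))
  cat("Score quantiles:\n"); print(round(x$score_quantiles, 4))
  cat("Direction:\n"); print(x$direction)
  cat("Consistency:\n"); print(x$consistency)
  invisible(x)
}

#' @export
coef.linkscore <- function(object, ...) {
  stats::setNames(object$links$score, object$links$edge_id)
}

#' Histogram of link scores with optional threshold markers
#'
#' @param x a [linkscore()] fit.
#' @param thresholds optional length-2 numeric: resolved (lower, upper)
#'   cutoffs to mark.
#' @param ... passed to [graphics::hist()].
#' @export
plot.linkscore <- function(x, thresholds = NULL, ...) {
  sc <- x$links$score[!is.na(x$links$score)]
  if (!length(sc)) stop("no scored links to plot", call. = FALSE)
  graphics::hist(sc, breaks = "FD", col = "grey85", border = "grey40",
                 main = "Link score distribution", xlab = "link score", ...)
  graphics::abline(v = 0, lty = 3)
  if (!is.null(thresholds))
    graphics::abline(v = thresholds, col = c("darkgreen", "red"), lwd = 2)
  invisible(x)
}
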