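#' Two-sided threshold specification for condensation
#'
#' \code{absolute} mode gives the score cutoffs directly (\code{lower <= 0 <=
#' upper}); a link survives when its score is \code{<= lower} or \code{>=
#' upper}. \code{quantile} mode gives tail masses in \code{[0, 0.5)}: the
#' lower fraction of the signed score distribution (shutdown side) and the
#' upper fraction (startup side) are kept. Quantiles act on the signed
#' scores, not |score|, so the two tails are controlled independently.
#'
#' @param mode \code{"quantile"} or \code{"absolute"}.
#' @param lower,upper shutdown-/startup-side threshold (quantile tail mass or
#'   absolute score).
#' @return An object of class \code{"threshold_spec"}.
#' @examples
#' threshold_spec("quantile", 0.03, 0.03)
#' threshold_spec("absolute", -2, 2)
#' @export
threshold_spec <- function(mode = c("quantile", "absolute"),
                           lower = 0.03, upper = lower) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(lower), is.numeric(upper),
            length(lower) == 1L, length(upper) == 1L)
  if (mode == "quantile") {
    if (lower < 0 || lower >= 0.5 || upper < 0 || upper >= 0.5)
      stop("quantile tails must lie in [0, 0.5)", call. = FALSE)
  } else if (lower > 0 || upper < 0)
    stop("absolute thresholds need lower <= 0 <= upper", call. = FALSE)
  structure(list(mode = mode, lower = lower, upper = upper),
            class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf("Threshold spec (%s): lower %g, upper %g\n",
              x$mode, x$lower, x$upper))
  invisible(x)
}

#' Resolve a threshold spec to absolute score cutoffs
#'
#' In quantile mode with tail mass q on n scores, the cutoffs are the
#' floor(q*n)-th smallest and floor(q*n)-th largest score (\code{-Inf} /
#' \code{+Inf} when floor(q*n) = 0), so that, ties aside, exactly floor(q*n)
#' links survive in each tail under the inclusive keep rule of
#' [condense()]. This order-statistic convention makes the removed fraction
#' converge to 1 - 2q at every network size (94\% at q = 0.03). Absolute
#' specs pass through unchanged.
#'
#' @param scores numeric vector of link scores (NAs, i.e. unscored links,
#'   are ignored).
#' @param spec a [threshold_spec()].
#' @return Numeric length-2 vector \code{c(lower, upper)} of absolute
#'   cutoffs.
#' @export
resolve_thresholds <- function(scores, spec) {
  stopifnot(inherits(spec, "threshold_spec"))
  if (spec$mode == "absolute") return(c(lower = spec$lower,
                                        upper = spec$upper))
  scores <- scores[!is.na(scores)]
  if (!length(scores))
    stop("cannot resolve quantile thresholds on an empty score list",
         call. = FALSE)
  s <- sort(scores)
  n <- length(s)
  k_lo <- floor(spec$lower * n)
  k_hi <- floor(spec$upper * n)
  c(lower = if (k_lo >= 1) s[k_lo] else -Inf,
    upper = if (k_hi >= 1) s[n - k_hi + 1L] else Inf)
}

#' Condense a scored network
#'
#' Removes every link whose score fails the two-sided threshold (kept iff
#' score <= lower cutoff or >= upper cutoff, boundaries inclusive), then
#' prunes nodes left without any kept link. Unscored links (nodes without
#' measurements under the \code{keep_unscored} policy) never survive.
#'
#' @param x a [linkscore()] fit.
#' @param spec a [threshold_spec()]; the default keeps the 3\% tails.
#' @param ... unused.
#' @return An object of class \code{"condensation"}: list with \code{kept}
#'   (scored-link data frame), \code{removed_count},
#'   \code{removed_fraction}, \code{retained_nodes}, \code{cutoffs} (the
#'   resolved absolute cutoffs), \code{spec}, \code{n_total}, plus the
#'   measurement table for styling.
#' @examples
#' fx <- generate_fixture(n_nodes = 30, n_edges = 60, seed = 1)
#' fit <- linkscore(fx$network, fx$measurements)
#' condense(fit, threshold_spec("quantile", 0.05))
#' @export
condense <- function(x, spec = threshold_spec("quantile", 0.03), ...) {
  UseMethod("condense")
}

#' @export
condense.linkscore <- function(x, spec = threshold_spec("quantile", 0.03),
                               ...) {
  condense_links(x$links, spec, measurements = x$measurements,
                 basis = x$basis)
}

#' @export
condense.condensation <- function(x, spec = threshold_spec("quantile", 0.03),
                                  ...) {
  condense_links(x$kept, spec, measurements = x$measurements,
                 basis = x$basis)
}

condense_links <- function(links, spec, measurements = NULL, basis = NULL) {
  stopifnot(inherits(spec, "threshold_spec"))
  n_total <- nrow(links)
  if (spec$mode == "quantile" && !any(!is.na(links$score)))
    stop("cannot resolve quantile thresholds: no scored links",
         call. = FALSE)
  cut <- if (n_total) resolve_thresholds(links$score, spec)
         else c(lower = -Inf, upper = Inf)
  keep <- !is.na(links$score) &
    (links$score <= cut[["lower"]] | links$score >= cut[["upper"]])
  kept <- links[keep, , drop = FALSE]
  rownames(kept) <- NULL
  structure(list(
    kept = kept,
    removed_count = n_total - nrow(kept),
    removed_fraction = if (n_total) (n_total - nrow(kept)) / n_total else 0,
    retained_nodes = sort(unique(c(kept$source, kept$target))),
    cutoffs = cut, spec = spec, n_total = n_total,
    measurements = measurements, basis = basis),
    class = "condensation")
}

#' @export
print.condensation <- function(x, ...) {
  cat(sprintf(
    "Condensation (%s %g/%g): kept %d of %d links (removed %.0f%%), %d nodes\n",
    x$spec$mode, x$spec$lower, x$spec$upper, nrow(x$kept), x$n_total,
    100 * round(x$removed_fraction, 2), length(x$retained_nodes)))
  cat(sprintf("  resolved cutoffs: [%.4g, %.4g]\n",
              x$cutoffs[["lower"]], x$cutoffs[["upper"]]))
  invisible(x)
}

#' @export
summary.condensation <- function(object, ...) {
  k <- object$kept
  cat(sprintf("Condensed network: %d links, %d nodes (removed %d links, %.2f)\n",
              nrow(k), length(object$retained_nodes),
              object$removed_count, object$removed_fraction))
  if (nrow(k)) {
    ord <- order(-abs(k$score))
    cat("Strongest links:\n")
    print(utils::head(k[ord, c("source", "interaction_type", "target",
                               "score", "direction", "consistency_class")],
                      10L), row.names = FALSE)
  }
  invisible(object)
}

#' Condense at a series of increasingly stringent thresholds
#'
#' Batch analogue of an interactive threshold slider: one condensation per
#' spec, all resolved against the full fit (not incrementally), so the kept
#' sets are comparable across specs and nested when the specs are ordered
#' from lenient to stringent.
#'
#' @param x a [linkscore()] fit.
#' @param specs list of [threshold_spec()]s, lenient to stringent.
#' @return List of condensation results, one per spec.
#' @export
condensation_series <- function(x, specs) {
  stopifnot(inherits(x, "linkscore"))
  lapply(specs, function(s) condense(x, s))
}

#' Log-transform and quantile-normalize a raw sample matrix
#'
#' Standard microarray-style preprocessing ahead of scoring: an elementwise
#' log transform first, then quantile normalization across the sample columns
#' (each value replaced by the mean of the values sharing its rank, ties
#' averaged), then per-condition means and — when a condition has >= 2
#' replicate columns — variances.
#'
#' @param x numeric matrix or data frame, rows = nodes (rownames =
#'   identifiers), columns = samples.
#' @param e1_cols,e2_cols column names or indices of the replicates of each
#'   condition.
#' @param log_base \code{"none"}, \code{"log2"}, \code{"ln"} or
#'   \code{"log10"}.
#' @param quantile_normalize apply quantile normalization after the log
#'   transform.
#' @return A [measurement_table()]; it carries variances iff both conditions
#'   have >= 2 replicate columns.
#' @examples
#' m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3,
#'             dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' preprocess_measurements(m, "s1", "s2", quantile_normalize = TRUE)
#' @export
preprocess_measurements <- function(x, e1_cols, e2_cols,
                                    log_base = c("none", "log2", "ln",
                                                 "log10"),
                                    quantile_normalize = FALSE) {
  log_base <- match.arg(log_base)
  m <- as.matrix(x)
  if (is.null(rownames(m)))
    stop("the value matrix needs rownames (node identifiers)", call. = FALSE)
  if (!is.numeric(m)) stop("values must be numeric", call. = FALSE)
  m <- m[, c(e1_cols, e2_cols), drop = FALSE]
  if (log_base != "none") {
    if (any(m <= 0)) {
      bad <- rownames(m)[which(rowSums(m <= 0) > 0)[1L]]
      stop("nonpositive value under log transform (node ", dQuote(bad), ")",
           call. = FALSE)
    }
    m <- switch(log_base, log2 = log2(m), ln = log(m), log10 = log10(m))
  }
  if (quantile_normalize)
    m <- limma::normalizeQuantiles(m, ties = TRUE)
  i1 <- seq_along(e1_cols)
  i2 <- length(e1_cols) + seq_along(e2_cols)
  d <- data.frame(node = rownames(m),
                  m_e1 = rowMeans(m[, i1, drop = FALSE]),
                  m_e2 = rowMeans(m[, i2, drop = FALSE]),
                  stringsAsFactors = FALSE)
  n1 <- length(e1_cols); n2 <- length(e2_cols)
  if (n1 >= 2L && n2 >= 2L) {
    d$var_e1 <- apply(m[, i1, drop = FALSE], 1L, stats::var)
    d$var_e2 <- apply(m[, i2, drop = FALSE], 1L, stats::var)
    measurement_table(d, n1 = n1, n2 = n2)
  } else measurement_table(d)
}

#' Write the per-edge condensation report and JSON summary
#'
#' @param fit the [linkscore()] fit the condensation came from.
#' @param result a condensation of that fit.
#' @param tsv_path,json_path output files (either may be \code{NULL} to
#'   skip).
#' @return Invisibly, the summary list.
#' @export
condensation_report <- function(fit, result, tsv_path = NULL,
                                json_path = NULL) {
  stopifnot(inherits(fit, "linkscore"), inherits(result, "condensation"))
  links <- fit$links
  links$kept <- links$edge_id %in% result$kept$edge_id
  if (!is.null(tsv_path)) {
    out <- links[, c("edge_id", "source", "interaction_type", "target",
                     "d_source", "d_target", "score", "consistency_class",
                     "kept")]
    utils::write.table(out, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  summary <- list(
    n_edges = result$n_total,
    n_kept = nrow(result$kept),
    removed_count = result$removed_count,
    removed_fraction = round(result$removed_fraction, 2),
    n_unscored = length(fit$unscored),
    retained_nodes = length(result$retained_nodes),
    basis = fit$basis,
    threshold_mode = result$spec$mode,
    threshold_lower = result$spec$lower,
    threshold_upper = result$spec$upper,
    cutoff_lower = unname(result$cutoffs[["lower"]]),
    cutoff_upper = unname(result$cutoffs[["upper"]]))
  if (!is.null(json_path))
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  invisible(summary)
}
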