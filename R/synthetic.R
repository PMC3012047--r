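#' Generate a typed network with planted startups and shutdowns
#'
#' Emulates the structure of a curated molecular network overlaid with
#' two-condition log-scale expression data: a random typed network, baseline
#' node values drawn on the log2 scale (normal around
#' \code{baseline_mean}), and a chosen set of planted edges whose endpoint
#' values are shifted between conditions in the pattern their type makes
#' consistent — correlated shifts for interactions/stimulations,
#' anticorrelated for inhibitions — so each planted edge carries a link score
#' of about \code{2 * effect_size} (positive for startups, negative for
#' shutdowns). All other variation is noise. The default sizes mirror a
#' medium curated network (124 nodes, 206 edges, 3 + 3 planted links of 2
#' log2 units effect each).
#'
#' Planted edges are chosen with pairwise-disjoint endpoints, and no other
#' edge may join two planted nodes, so that with \code{noise_sd = 0} the
#' planted links are exactly the top-|score| set (background scores are 0 and
#' leakage edges touching one planted node score at most
#' \code{effect_size}).
#'
#' @param n_nodes,n_edges network size.
#' @param type_mix named probabilities over the three edge types.
#' @param n_startups,n_shutdowns number of planted startup/shutdown edges.
#' @param effect_size planted shift (log2 units) per endpoint.
#' @param noise_sd condition noise (and, with replicates, the
#'   within-condition replicate standard deviation; must then be > 0).
#' @param replicates \code{NULL} for single measurements, or \code{c(n1,
#'   n2)} to draw replicates and emit means + variances.
#' @param baseline_mean,baseline_sd log2-scale baseline distribution.
#' @param seed integer seed; runs are reproducible.
#' @return List with elements \code{network} ([typed_network()]),
#'   \code{measurements} ([measurement_table()]) and \code{ground_truth}
#'   (named character vector edge_id -> \code{"startup"} /
#'   \code{"shutdown"}).
#' @examples
#' fx <- generate_fixture(n_nodes = 20, n_edges = 30, n_startups = 1,
#'                        n_shutdowns = 1, noise_sd = 0, seed = 7)
#' fx$ground_truth
#' @export
generate_fixture <- function(n_nodes = 124, n_edges = 206,
                             type_mix = c(interaction = 0.5,
                                          stimulation = 0.3,
                                          inhibition = 0.2),
                             n_startups = 3, n_shutdowns = 3,
                             effect_size = 2, noise_sd = 0.2,
                             replicates = NULL,
                             baseline_mean = 7, baseline_sd = 1.5,
                             seed = 1L) {
  n_planted <- n_startups + n_shutdowns
  if (n_planted > n_edges)
    stop("more planted edges than edges requested", call. = FALSE)
  if (!isTRUE(all.equal(sum(type_mix), 1)) ||
      !setequal(names(type_mix), edge_types()))
    stop("`type_mix` must be probabilities over the three edge types summing to 1",
         call. = FALSE)
  if (!is.null(replicates)) {
    stopifnot(length(replicates) == 2L, all(replicates >= 2L))
    if (noise_sd <= 0)
      stop("replicate draws need noise_sd > 0 (replicate variance)",
           call. = FALSE)
  }
  max_pairs <- n_nodes * (n_nodes - 1) / 2
  if (n_edges > max_pairs)
    stop("more edges requested than distinct node pairs", call. = FALSE)
  set.seed(seed)
  nodes <- sprintf("N%03d", seq_len(n_nodes))
  # unique unordered node pairs (no self-pairs, so scores stay generically
  # distinct: an inhibition self-loop always scores exactly 0), random
  # orientation
  pair_idx <- sample(max_pairs, n_edges)
  j <- ceiling((1 + sqrt(1 + 8 * pair_idx)) / 2)
  i <- pair_idx - (j - 1) * (j - 2) / 2
  flip <- stats::runif(n_edges) < 0.5
  src <- nodes[ifelse(flip, j, i)]
  tgt <- nodes[ifelse(flip, i, j)]
  type <- sample(edge_types(), n_edges, replace = TRUE,
                 prob = type_mix[edge_types()])
  edges <- data.frame(source = src, target = tgt, interaction_type = type,
                      stringsAsFactors = FALSE)
  planted_idx <- pick_planted(edges, n_planted)
  if (length(planted_idx) < n_planted)
    stop("could not place ", n_planted,
         " planted edges with disjoint endpoints; use a larger network",
         call. = FALSE)
  net <- typed_network(edges, nodes = nodes)
  # typed_network may reorder interaction endpoints; recover planted ids by row
  planted_ids <- net$edges$edge_id[planted_idx]
  label <- rep(c("startup", "shutdown"), c(n_startups, n_shutdowns))
  ground_truth <- stats::setNames(label, planted_ids)

  shift <- stats::setNames(rep(0, n_nodes), nodes)
  for (i in seq_len(n_planted)) {
    e <- net$edges[planted_idx[i], ]
    s <- if (label[i] == "startup") effect_size else -effect_size
    if (e$interaction_type == "inhibition") {
      shift[e$source] <- s
      shift[e$target] <- if (e$source == e$target) s else -s
    } else {
      shift[e$source] <- s
      shift[e$target] <- s
    }
  }
  baseline <- stats::rnorm(n_nodes, baseline_mean, baseline_sd)
  if (is.null(replicates)) {
    m_e1 <- baseline + if (noise_sd > 0) stats::rnorm(n_nodes, 0, noise_sd)
                       else 0
    m_e2 <- baseline + shift +
      if (noise_sd > 0) stats::rnorm(n_nodes, 0, noise_sd) else 0
    tab <- measurement_table(data.frame(node = nodes, m_e1 = m_e1,
                                        m_e2 = m_e2,
                                        stringsAsFactors = FALSE))
  } else {
    r1 <- matrix(stats::rnorm(n_nodes * replicates[1L], baseline, noise_sd),
                 nrow = n_nodes)
    r2 <- matrix(stats::rnorm(n_nodes * replicates[2L], baseline + shift,
                              noise_sd), nrow = n_nodes)
    tab <- measurement_table(
      data.frame(node = nodes,
                 m_e1 = rowMeans(r1), m_e2 = rowMeans(r2),
                 var_e1 = apply(r1, 1L, stats::var),
                 var_e2 = apply(r2, 1L, stats::var),
                 stringsAsFactors = FALSE),
      n1 = replicates[1L], n2 = replicates[2L])
  }
  list(network = net, measurements = tab, ground_truth = ground_truth)
}

# choose planted edge rows: no two planted edges share a node, no self-loop,
# and no other edge connects two planted nodes
pick_planted <- function(edges, n_planted) {
  if (n_planted == 0L) return(integer())
  idx <- which(edges$source != edges$target)
  cand <- idx[sample.int(length(idx))]
  chosen <- integer(); used <- character()
  for (i in cand) {
    if (edges$source[i] %in% used || edges$target[i] %in% used) next
    trial_used <- c(used, edges$source[i], edges$target[i])
    other <- setdiff(seq_len(nrow(edges)), c(chosen, i))
    clash <- edges$source[other] %in% trial_used &
      edges$target[other] %in% trial_used
    if (any(clash)) next
    chosen <- c(chosen, i); used <- trial_used
    if (length(chosen) == n_planted) break
  }
  chosen
}

#' Write fixture files to a directory
#'
#' Emits the generated network (GraphML), measurement table (TSV), ground
#' truth (TSV) and optionally a session archive, for use outside R.
#'
#' @param fixture a [generate_fixture()] result.
#' @param dir output directory (created if needed).
#' @param session also write a session zip archive.
#' @return Invisibly, the paths written.
#' @export
write_fixture <- function(fixture, dir, session = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    network = file.path(dir, "network.graphml"),
    measurements = file.path(dir, "measurements.tsv"),
    truth = file.path(dir, "ground_truth.tsv"))
  write_network(fixture$network, paths[["network"]], "graphml")
  tab <- fixture$measurements$data
  names(tab)[names(tab) == "node"] <- "id"
  utils::write.table(tab, paths[["measurements"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(edge_id = names(fixture$ground_truth),
               planted = unname(fixture$ground_truth)),
    paths[["truth"]], sep = "\t", quote = FALSE, row.names = FALSE)
  if (session) {
    paths <- c(paths, session = file.path(dir, "session.zip"))
    make_session_fixture(fixture$network, fixture$measurements,
                         paths[["session"]])
  }
  invisible(paths)
}
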