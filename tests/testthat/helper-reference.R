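# Independent brute-force reference used as the oracle for the scoring path.
# Looks nodes up one edge at a time, straight from the formulae; shares no
# code with linkscore().
reference_scores <- function(net, tab) {
  vapply(seq_len(nrow(net$edges)), function(i) {
    e <- net$edges[i, ]
    r_s <- tab$data[tab$data$node == e$source, ]
    r_t <- tab$data[tab$data$node == e$target, ]
    if (!nrow(r_s) || !nrow(r_t)) return(NA_real_)
    d <- function(r) {
      if (tab$has_variance)
        (r$m_e2 - r$m_e1) / sqrt(r$var_e1 / tab$n1 + r$var_e2 / tab$n2)
      else r$m_e2 - r$m_e1
    }
    if (e$interaction_type == "inhibition") d(r_s) - d(r_t)
    else d(r_s) + d(r_t)
  }, numeric(1L))
}

random_network <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  nodes <- sprintf("g%02d", seq_len(n_nodes))
  typed_network(data.frame(
    source = sample(nodes, n_edges, replace = TRUE),
    target = sample(nodes, n_edges, replace = TRUE),
    interaction_type = sample(edge_types(), n_edges, replace = TRUE)),
    nodes = nodes)
}

random_measurements <- function(nodes, seed, variance = FALSE) {
  set.seed(seed)
  d <- data.frame(node = nodes,
                  m_e1 = rnorm(length(nodes), 7, 2),
                  m_e2 = rnorm(length(nodes), 7, 2))
  if (variance) {
    d$var_e1 <- rchisq(length(nodes), 3)
    d$var_e2 <- rchisq(length(nodes), 3)
    measurement_table(d, n1 = 4, n2 = 6)
  } else measurement_table(d)
}

swap_conditions <- function(tab) {
  d <- tab$data
  names(d)[match(c("m_e1", "m_e2"), names(d))] <- c("m_e2", "m_e1")
  if (tab$has_variance) {
    names(d)[match(c("var_e1", "var_e2"), names(d))] <-
      c("var_e2", "var_e1")
    measurement_table(d, n1 = tab$n2, n2 = tab$n1)
  } else measurement_table(d)
}
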