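scored_fit <- function(n_edges, seed = 1, noise_sd = 0.6) {
  fx <- generate_fixture(n_nodes = max(20, ceiling(n_edges * 0.6)),
                         n_edges = n_edges, n_startups = 0,
                         n_shutdowns = 0, noise_sd = noise_sd, seed = seed)
  linkscore(fx$network, fx$measurements)
}

test_that("threshold specs validate their ranges", {
  expect_error(threshold_spec("quantile", 0.6), "0, 0.5")
  expect_error(threshold_spec("quantile", -0.1), "0, 0.5")
  expect_error(threshold_spec("absolute", 1, 2), "lower <= 0 <= upper")
  expect_s3_class(threshold_spec("absolute", -2, 2), "threshold_spec")
})

test_that("absolute specs pass through; quantile cutoffs are order statistics", {
  expect_equal(resolve_thresholds(rnorm(10),
                                  threshold_spec("absolute", -2, 2)),
               c(lower = -2, upper = 2))
  # brute-force ordering oracle on the integers 1..100
  cut <- resolve_thresholds(sample(1:100), threshold_spec("quantile", 0.03))
  expect_equal(unname(cut), c(3, 98))  # 3rd smallest, 3rd largest
  expect_equal(sum(1:100 <= cut[["lower"]]), 3L)
  expect_equal(sum(1:100 >= cut[["upper"]]), 3L)
  # q = 0 keeps nothing
  cut0 <- resolve_thresholds(1:100, threshold_spec("quantile", 0))
  expect_equal(unname(cut0), c(-Inf, Inf))
  expect_error(resolve_thresholds(numeric(),
                                  threshold_spec("quantile", 0.1)),
               "empty")
})

test_that("condensing 206 distinct scores at the 3% tails removes 94%", {
  fit <- scored_fit(206, seed = 21)
  expect_equal(length(unique(fit$links$score)), 206L)
  res <- condense(fit, threshold_spec("quantile", 0.03))
  expect_equal(nrow(res$kept), 12L)  # floor(0.03 * 206) per tail
  expect_lte(abs(res$removed_count - 0.94 * 206), 1)
  expect_equal(res$removed_fraction, 194 / 206)
})

test_that("degenerate and identity threshold cases behave", {
  fit <- scored_fit(30, seed = 3)
  all_kept <- condense(fit, threshold_spec("absolute", 0, 0))
  expect_equal(nrow(all_kept$kept), 30L)
  expect_equal(all_kept$removed_fraction, 0)
  links0 <- fit$links; links0$score <- 0
  links0$direction <- "neutral"
  res0 <- netcondense:::condense_links(links0,
                                       threshold_spec("absolute", -1, 1))
  expect_equal(nrow(res0$kept), 0L)
  expect_length(res0$retained_nodes, 0L)
  expect_equal(res0$removed_fraction, 1)
})

test_that("retained nodes are exactly the endpoints of kept links", {
  for (seed in 1:5) {
    fit <- scored_fit(80, seed = seed)
    res <- condense(fit, threshold_spec("quantile", 0.05))
    expect_setequal(res$retained_nodes,
                    c(res$kept$source, res$kept$target))
    # no orphan: every retained node has a kept incident edge
    deg <- table(c(res$kept$source, res$kept$target))
    expect_true(all(deg[res$retained_nodes] >= 1))
  }
})

test_that("kept sets are nested under increasingly stringent thresholds", {
  fit <- scored_fit(120, seed = 6)
  specs <- list(threshold_spec("absolute", -0.5, 0.5),
                threshold_spec("absolute", -1.5, 1.5),
                threshold_spec("absolute", -3, 3))
  series <- condensation_series(fit, specs)
  for (i in 2:3)
    expect_true(all(series[[i]]$kept$edge_id %in%
                      series[[i - 1L]]$kept$edge_id))
  qspecs <- list(threshold_spec("quantile", 0.2),
                 threshold_spec("quantile", 0.1),
                 threshold_spec("quantile", 0.02))
  qseries <- condensation_series(fit, qspecs)
  for (i in 2:3)
    expect_true(all(qseries[[i]]$kept$edge_id %in%
                      qseries[[i - 1L]]$kept$edge_id))
  single <- condensation_series(fit, specs[1])
  expect_length(single, 1L)
  expect_equal(single[[1]]$kept, condense(fit, specs[[1]])$kept)
  expect_length(condensation_series(fit, list()), 0L)
})

test_that("quantile retention keeps floor(q*n) per tail plus boundary ties", {
  for (seed in 1:4) {
    n <- sample(100:400, 1)
    q <- runif(1, 0.01, 0.2)
    fit <- scored_fit(n, seed = seed + 40)
    res <- condense(fit, threshold_spec("quantile", q))
    ties <- sum(fit$links$score %in% res$cutoffs) - 2L
    expect_equal(nrow(res$kept), 2L * floor(q * n) + max(ties, 0L))
  }
})

test_that("condensation is idempotent at the same resolved cutoffs", {
  fit <- scored_fit(90, seed = 7)
  res <- condense(fit, threshold_spec("quantile", 0.1))
  again <- condense(res, threshold_spec("absolute",
                                        res$cutoffs[["lower"]],
                                        res$cutoffs[["upper"]]))
  expect_equal(again$kept, res$kept)
  expect_equal(again$removed_count, 0L)
})

test_that("unscored edges are always removed and counted", {
  net <- typed_network(data.frame(source = c("A", "B"),
                                  target = c("B", "C"),
                                  interaction_type = "stimulation"))
  tab <- measurement_table(data.frame(node = c("A", "B"),
                                      m_e1 = c(0, 0), m_e2 = c(5, 5)))
  fit <- linkscore(net, tab)
  res <- condense(fit, threshold_spec("absolute", 0, 0))
  expect_equal(nrow(res$kept), 1L)
  expect_equal(res$removed_count, 1L)
  expect_false("C" %in% res$retained_nodes)
})

test_that("quantile normalization and log transform preprocess correctly", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3,
              dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  tab <- preprocess_measurements(m, "s1", "s2", quantile_normalize = TRUE)
  expect_equal(tab$data$m_e1, c(2.5, 3.5, 4.5))  # rank-mean by hand
  expect_equal(tab$data$m_e2, c(2.5, 3.5, 4.5))
  # identical columns are left unchanged
  m2 <- matrix(c(5, 1, 3, 5, 1, 3), nrow = 3,
               dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  tab2 <- preprocess_measurements(m2, "s1", "s2",
                                  quantile_normalize = TRUE)
  expect_equal(tab2$data$m_e1, c(5, 1, 3))
  # log2 first
  m3 <- matrix(c(4, 8), nrow = 1, dimnames = list("A", c("s1", "s2")))
  tab3 <- preprocess_measurements(m3, "s1", "s2", log_base = "log2")
  expect_equal(c(tab3$data$m_e1, tab3$data$m_e2), c(2, 3))
  expect_error(preprocess_measurements(m3 - 4, "s1", "s2",
                                       log_base = "log2"), "A")
})

test_that("replicate columns yield means, variances and counts", {
  set.seed(10)
  m <- matrix(rlnorm(5 * 7, 3, 1), nrow = 5,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:7)))
  tab <- preprocess_measurements(m, paste0("s", 1:3), paste0("s", 4:7),
                                 log_base = "log2",
                                 quantile_normalize = TRUE)
  expect_true(tab$has_variance)
  expect_equal(c(tab$n1, tab$n2), c(3L, 4L))
  lm2 <- limma::normalizeQuantiles(log2(m), ties = TRUE)
  expect_equal(tab$data$m_e1, unname(rowMeans(lm2[, 1:3])))
  expect_equal(tab$data$var_e1, unname(apply(lm2[, 1:3], 1, var)))
})

test_that("the condensation report counts match the result", {
  fx <- generate_fixture(seed = 13)
  fit <- linkscore(fx$network, fx$measurements)
  res <- condense(fit, threshold_spec("quantile", 0.03))
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  s <- condensation_report(fit, res, tsv, js)
  rep <- read.delim(tsv)
  expect_equal(nrow(rep), res$n_total)
  expect_equal(sum(rep$kept), nrow(res$kept))
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$n_kept, nrow(res$kept))
  expect_equal(parsed$removed_fraction, round(res$removed_fraction, 2))
})
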