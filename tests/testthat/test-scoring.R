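test_that("differentials are E2 minus E1, on printed expression pairs", {
  expect_equal(differential(5.37, 7.15), 1.78)
  expect_equal(differential(7041, 9124), 2083)
  expect_equal(differential(c(3, -2.5, 0), c(3, -2.5, 0)), c(0, 0, 0))
  expect_error(differential(Inf, 1), "finite")
})

test_that("Welch differential divides by the pooled standard error", {
  expect_equal(differential_welch(0, 2, 1, 1, 4, 4), 2 / sqrt(0.5))
  expect_equal(differential_welch(1, 3, 4, 9, 4, 9), 2 / sqrt(2))
  expect_equal(differential_welch(5, 5, 2, 7, 3, 8), 0)
})

test_that("Welch differential matches the Welch t statistic on samples", {
  set.seed(42)
  for (i in 1:20) {
    x1 <- rnorm(sample(3:12, 1), mean = runif(1, -2, 2))
    x2 <- rnorm(sample(3:12, 1), mean = runif(1, -2, 2), sd = 2)
    t_ref <- unname(t.test(x2, x1, var.equal = FALSE)$statistic)
    expect_equal(
      differential_welch(mean(x1), mean(x2), var(x1), var(x2),
                         length(x1), length(x2)),
      t_ref, tolerance = 1e-12)
  }
})

test_that("zero pooled variance errors unless a floor is supplied", {
  expect_error(differential_welch(1, 2, 0, 0, 4, 4), "pooled variance")
  expect_warning(
    d <- differential_welch(1, 2, 0, 0, 4, 4, var_floor = 1e-12),
    "floored")
  expect_equal(d, 1 / sqrt(1e-12))
})

test_that("link score sums differentials, with sign flip for inhibitions", {
  expect_equal(link_score("stimulation", 1.78, 0.82), 2.60)
  expect_equal(link_score("stimulation", 3, -3), 0)
  expect_equal(link_score("inhibition", 2, -2), 4)   # anticorrelated startup
  expect_equal(link_score("inhibition", -1, 2), -3)  # inhibitor down, target up
  expect_error(link_score("binds", 1, 1), "unknown edge type")
})

test_that("interaction score is symmetric in its endpoints", {
  set.seed(1)
  a <- rnorm(200); b <- rnorm(200)
  expect_equal(link_score("interaction", a, b),
               link_score("interaction", b, a))
})

test_that("interaction score equals the mass-action log activity ratio", {
  set.seed(2)
  for (i in 1:50) {
    ab <- runif(4, 0.1, 50)  # abundances A1, A2, B1, B2
    score <- link_score("interaction",
                        log(ab[2]) - log(ab[1]), log(ab[4]) - log(ab[3]))
    expect_equal(score, log((ab[2] * ab[4]) / (ab[1] * ab[3])),
                 tolerance = 1e-12)
  }
})

test_that("anticorrelated stimulation never outscores the correlated pair", {
  set.seed(3)
  for (i in 1:100) {
    a <- runif(1, 0, 5); b <- runif(1, 0, 5)
    expect_lte(abs(link_score("stimulation", a, -b)),
               abs(link_score("stimulation", a, b)))
  }
})

test_that("consistency classification follows the sign/dominance rules", {
  expect_equal(classify_consistency("stimulation", 2, 1), "consistent")
  expect_equal(classify_consistency("interaction", -2, -1), "consistent")
  expect_equal(classify_consistency("inhibition", 2, -1), "consistent")
  expect_equal(classify_consistency("stimulation", 2, -0.3),
               "source_principle")
  expect_equal(classify_consistency("stimulation", -0.2, 2),
               "target_principle")
  expect_equal(classify_consistency("inhibition", 0.3, 2),
               "target_principle")
  expect_equal(classify_consistency("stimulation", 1, -1), "inconsistent")
  expect_equal(classify_consistency("interaction", 0, 0, 0.1), "no_change")
  expect_equal(classify_consistency("stimulation", 0.05, -0.05, 0.1),
               "no_change")
  # dead-banded side counts as zero change, dominance still applies
  expect_equal(classify_consistency("stimulation", 2, 0.05, 0.1),
               "source_principle")
  expect_error(classify_consistency("stimulation", 1, 1, -1), "nonnegative")
})

test_that("score_network path agrees with the brute-force reference", {
  for (seed in 1:30) {
    net <- random_network(sample(5:50, 1), sample(5:80, 1), seed)
    tab <- random_measurements(net$nodes, seed + 1000,
                               variance = seed %% 2 == 0)
    fit <- linkscore(net, tab)
    expect_equal(fit$links$score, reference_scores(net, tab),
                 tolerance = 1e-12)
    expect_identical(fit$basis,
                     if (tab$has_variance) "welch" else "single")
  }
})

test_that("swapping conditions negates every differential and score", {
  for (variance in c(FALSE, TRUE)) {
    net <- random_network(20, 40, 11)
    tab <- random_measurements(net$nodes, 12, variance = variance)
    fit <- linkscore(net, tab)
    fit_sw <- linkscore(net, swap_conditions(tab))
    expect_equal(fit_sw$differentials$d, -fit$differentials$d)
    expect_equal(fit_sw$links$score, -fit$links$score)
    dir <- fit$links$direction
    expect_identical(fit_sw$links$direction,
                     ifelse(dir == "startup", "shutdown",
                            ifelse(dir == "shutdown", "startup", dir)))
  }
})

test_that("Welch differentials scale inversely with the noise scale", {
  tab <- random_measurements(sprintf("g%02d", 1:15), 7, variance = TRUE)
  fit <- linkscore(random_network(15, 25, 8), tab)
  for (c_scale in c(0.5, 2, 10)) {
    d <- tab$data
    d$var_e1 <- d$var_e1 * c_scale^2
    d$var_e2 <- d$var_e2 * c_scale^2
    fit2 <- linkscore(random_network(15, 25, 8),
                      measurement_table(d, n1 = tab$n1, n2 = tab$n2))
    expect_equal(fit2$links$score, fit$links$score / c_scale)
  }
})

test_that("self-loops score with both roles played by the same node", {
  net <- typed_network(data.frame(source = "A", target = "A",
                                  interaction_type = "stimulation"))
  tab <- measurement_table(data.frame(node = "A", m_e1 = 1, m_e2 = 2.5))
  fit <- linkscore(net, tab)
  expect_equal(fit$links$score, 3)  # D_A + D_A
})

test_that("uncovered nodes follow the attachment policy", {
  net <- typed_network(data.frame(source = c("A", "B"),
                                  target = c("B", "C"),
                                  interaction_type = "stimulation"))
  tab <- measurement_table(data.frame(node = c("A", "B"),
                                      m_e1 = c(1, 1), m_e2 = c(2, 3)))
  fit <- linkscore(net, tab)  # keep_unscored
  expect_equal(sum(is.na(fit$links$score)), 1L)
  expect_identical(fit$coverage_report, "C")
  dropped <- linkscore(net, tab, on_missing = "drop_node")
  expect_equal(nrow(dropped$links), 1L)
  expect_false("C" %in% dropped$network$nodes)
  expect_error(linkscore(net, tab, on_missing = "error"), "C")
})

test_that("mixed variance coverage is rejected", {
  d <- data.frame(node = c("A", "B"), m_e1 = c(1, 2), m_e2 = c(2, 3),
                  var_e1 = c(1, NA), var_e2 = c(1, 1))
  expect_error(measurement_table(d, n1 = 3, n2 = 3), "cover every node")
})

test_that("the linkscore fit prints, summarises and exposes coefficients", {
  fx <- generate_fixture(n_nodes = 20, n_edges = 30, n_startups = 1,
                         n_shutdowns = 1, seed = 4)
  fit <- linkscore(fx$network, fx$measurements)
  expect_output(print(fit), "30 edges")
  s <- summary(fit)
  expect_s3_class(s, "summary.linkscore")
  expect_equal(sum(s$direction), 30L)
  cf <- coef(fit)
  expect_named(cf, fit$links$edge_id)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit, thresholds = c(-1, 1)))
})
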