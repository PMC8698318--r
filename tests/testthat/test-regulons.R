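test_that("z-scoring standardizes rows and flags degenerate genes", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(2, 8, 5))
  z <- zscore_genes(m)
  expect_equal(unname(z["a", ]), c(-1, 0, 1))
  expect_equal(attr(z, "degenerate"), "b")
  expect_equal(unname(rowMeans(z)), rep(0, 2), tolerance = 1e-9)
  expect_equal(unname(apply(z, 1, sd)), rep(1, 2), tolerance = 1e-9)
  expect_error(zscore_genes(m[, 1, drop = FALSE]), "2 conditions")
})

test_that("cluster quality scores match hand evaluation on separated 1-D points", {
  x <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  q <- cluster_quality_scores(x, c(1, 1, 2, 2))
  expect_equal(unname(q["silhouette"]), 0.990, tolerance = 1e-3)
  expect_error(cluster_quality_scores(x, rep(1, 4)), "k >= 2")
})

test_that("true separated partition beats every alternative on Davies-Bouldin", {
  x <- matrix(c(0, 0.2, 0.4, 10, 10.2, 10.4), ncol = 1)
  true_db <- cluster_quality_scores(x, c(1, 1, 1, 2, 2, 2))["davies_bouldin"]
  for (size in 1:2) {
    for (members in utils::combn(6, size, simplify = FALSE)) {
      lab <- rep(1, 6); lab[members] <- 2
      if (identical(lab, c(1, 1, 1, 2, 2, 2))) next
      expect_gt(cluster_quality_scores(x, lab)["davies_bouldin"], true_db)
    }
  }
})

test_that("random labels on i.i.d. data give near-zero silhouette", {
  set.seed(12)
  sils <- replicate(20, {
    z <- matrix(rnorm(40 * 4), 40, 4)
    cluster_quality_scores(z, sample(1:4, 40, replace = TRUE))["silhouette"]
  })
  expect_lt(abs(mean(sils)), 0.1)
})

test_that("consensus selection recovers a planted k and is scale-invariant", {
  set.seed(5)
  centers <- matrix(c(0, 0, 0, 5, 5, 5, -5, 5, 0), 3, 3, byrow = TRUE)
  z <- centers[rep(1:3, each = 15), ] + matrix(rnorm(45 * 3, sd = 0.05), 45, 3)
  rownames(z) <- sprintf("g%02d", 1:45)
  part <- select_partition(z)
  expect_equal(part$k, 3)
  expect_equal(select_partition(z * 11)$k, part$k)
  expect_error(select_partition(z[1:3, ]), "fewer")
})

test_that("hypergeometric p-values equal enumeration", {
  expect_identical(hypergeom_pvalue(10, 5, 4, 0), 1)
  expect_equal(hypergeom_pvalue(10, 5, 4, 4), 5 / 210, tolerance = 1e-12)
  expect_identical(hypergeom_pvalue(7, 7, 7, 7), 1)
  expect_error(hypergeom_pvalue(10, 11, 4, 2), "inconsistent")
  expect_error(hypergeom_pvalue(10, 5, 4, 5), "inconsistent")
  # enumeration over actual draws for a small case
  draws <- utils::combn(8, 4, simplify = FALSE)
  succ <- 1:3  # K = 3 successes in population 1..8
  for (k in 0:3) {
    tail_prob <- mean(vapply(draws, function(d)
      length(intersect(d, succ)) >= k, TRUE))
    expect_equal(hypergeom_pvalue(8, 3, 4, k), tail_prob, tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the brute-force step-up definition", {
  got <- bh_adjust(c(0.01, 0.02, 0.03, 0.04), alpha = 0.1)
  expect_equal(got$adjusted, rep(0.04, 4), tolerance = 1e-12)
  expect_true(all(got$significant))
  expect_equal(bh_adjust(0.03)$adjusted, 0.03)
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(9)
  for (i in 1:50) {
    p <- runif(sample(1:8, 1))
    expect_equal(bh_adjust(p)$adjusted, bh_brute(p), tolerance = 1e-12)
  }
})

test_that("switch classification follows the endpoint and interior rules", {
  expect_identical(classify_switch(c(-1, 0, 1)), "up")
  expect_identical(classify_switch(c(1, 0, -1)), "down")
  expect_identical(classify_switch(c(0, 2, 0.2)), "transient")
  expect_identical(classify_switch(c(0, -2, -0.2)), "transient")
  expect_error(classify_switch(c(0, 1)), "3 time points")
})

test_that("regulon names concatenate regulator and target count", {
  expect_identical(name_regulon("E2F8", 123), "E2F8.123")
  expect_identical(name_regulon("ZNF521", 45), "ZNF521.45")
  expect_identical(name_regulon("X", 2), "X.2")
  expect_error(name_regulon("", 3), "empty")
  expect_error(name_regulon("A", 0), "n_targets")
})

test_that("noise-free planted regulons are recovered exactly with r = 1", {
  cfg <- expression_sim_config(noise_sd = 0, donor_sd = 0, seed = 2,
                               prior_extra_targets = 3,
                               planted_regulons = default_planted_regulons(cascade = FALSE))
  out <- run_regulon_pipeline(cfg)
  truth <- out$sim$truth$regulons
  rec <- vapply(out$regulons, `[[`, "", "regulator")
  expect_setequal(rec, names(truth))
  for (r in out$regulons) {
    expect_setequal(r$targets, truth[[r$regulator]]$targets)
    expect_equal(r$correlation, 1, tolerance = 1e-9)
    expect_identical(r$direction, truth[[r$regulator]]$direction)
    expect_identical(r$name, name_regulon(r$regulator, length(r$targets)))
  }
})

test_that("every retained regulon satisfies the correlation gate", {
  out <- run_regulon_pipeline(expression_sim_config(seed = 5))
  expect_gt(length(out$regulons), 0)
  for (r in out$regulons) expect_gt(r$correlation, 0.8)
  # decoy regulators with random targets never pass
  decoys <- out$sim$truth$decoy_regulators
  expect_false(any(vapply(out$regulons, `[[`, "", "regulator") %in% decoys))
})

test_that("regulon inference is invariant to gene order", {
  cfg <- expression_sim_config(seed = 8)
  out <- run_regulon_pipeline(cfg)
  set.seed(1)
  z2 <- out$z[sample(nrow(out$z)), ]
  regs2 <- infer_regulons(z2, out$parts$up, out$parts$down, out$sim$prior,
                          timepoints = out$sim$timepoints)
  name1 <- sort(vapply(out$regulons, `[[`, "", "name"))
  name2 <- sort(vapply(regs2, `[[`, "", "name"))
  expect_identical(name1, name2)
})

test_that("the TF-TF network links regulators to TF targets only", {
  regulons <- list(
    structure(list(regulator = "A", targets = c("B", "g1"), name = "A.2",
                   correlation = 0.95, activity = 1:4,
                   activity_timepoint = c(-1, 0, 0.5, 1),
                   direction = "up", deg_direction = "up", n_targets = 2L),
              class = "regulon"))
  g <- build_tf_network(regulons, tf_list = c("A", "B"))
  el <- igraph::as_edgelist(g)
  expect_equal(nrow(el), 1)
  expect_equal(el[1, ], c("A", "B"))
  expect_equal(igraph::V(g)$n_targets[igraph::V(g)$name == "A"], 2L)
  g2 <- build_tf_network(regulons, tf_list = "A")
  expect_equal(igraph::ecount(g2), 0)
})

test_that("the planted regulatory cascade appears as a directed path", {
  sim <- simulate_expression(expression_sim_config(seed = 3))
  truth <- sim$truth$regulons
  regulons <- lapply(names(truth), function(tf) structure(list(
    regulator = tf, targets = truth[[tf]]$targets,
    name = name_regulon(tf, length(truth[[tf]]$targets)),
    correlation = 1, activity = NULL, activity_timepoint = NULL,
    direction = truth[[tf]]$direction,
    deg_direction = truth[[tf]]$direction,
    n_targets = length(truth[[tf]]$targets)), class = "regulon"))
  g <- build_tf_network(regulons, sim$tf_list)
  expect_true(igraph::are_adjacent(g, "TF01", "TF03"))
  expect_true(igraph::are_adjacent(g, "TF03", "TF05"))
  d <- igraph::distances(g, "TF01", "TF05", mode = "out")
  expect_equal(as.numeric(d), 2)
})
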