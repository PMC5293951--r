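test_that("regimes are classified by the relative waiting times", {
  expect_equal(classify_regime(100, 500, 200), "isolation_completes_ri")
  expect_equal(classify_regime(300, 50, 5000), "fusion_latest_split_only")
  expect_equal(classify_regime(30, 50, 5000), "chained_isolation")
  expect_equal(classify_regime(100, 100, 500), "partial_ri_contact")
  # ties: t_s = t_r counts as RI completing, t_i = t_s as fusion
  expect_equal(classify_regime(100, 200, 200), "isolation_completes_ri")
  expect_equal(classify_regime(50, 50, 5000), "fusion_latest_split_only")
  expect_error(classify_regime(0, 1, 1), "> 0")
})

test_that("a lineage that never isolates leaves a single-tip history", {
  p <- regime_parameters(t_i = 1e9, t_s = 50, t_r = 10, total_time = 1000)
  h <- simulate_history(p, seed = 1)
  expect_equal(nrow(h$lineages), 1)
  expect_equal(nrow(h$events), 0)
  tr <- reconstruct_tree(h)
  expect_s3_class(tr, "phylo")
  expect_equal(length(tr$tip.label), 1)
  expect_equal(tr$edge.length, 1000)
})

test_that("every lineage is in exactly one state and the dead stay dead", {
  p <- regime_parameters(t_i = 200, t_s = 300, t_r = 800,
                         total_time = 3000, max_lineages = 128)
  for (seed in derive_seeds(606, 10)) {
    h <- simulate_history(p, seed = seed)
    ln <- h$lineages
    expect_true(all(ln$status %in% c("extant", "fused", "extinct")))
    # extant lineages have no death time; dead lineages have exactly one
    expect_true(all(is.na(ln$death[ln$status == "extant"])))
    expect_true(all(!is.na(ln$death[ln$status != "extant"])))
    # no event involves a lineage after its death
    ev <- h$events
    for (i in seq_len(nrow(ev))) {
      ids <- stats::na.omit(c(ev$lineage1[i], ev$lineage2[i]))
      expect_true(all(is.na(ln$death[ids]) | ln$death[ids] >= ev$time[i]))
    }
    # event log is time-ordered
    expect_true(!is.unsorted(ev$time))
  }
})

test_that("fixed timing with distant contact doubles lineages every t_i", {
  p <- regime_parameters(t_i = 100, t_s = 1e6, t_r = 50,
                         timing_mode = "fixed", total_time = 650,
                         max_lineages = 4096)
  h <- simulate_history(p, seed = 3)
  tr <- reconstruct_tree(h)
  expect_equal(length(tr$tip.label), 2^6)
  # every isolation completes RI; no fusions or extinctions occur
  expect_true("ri_complete" %in% h$events$type)
  expect_false(any(h$events$type %in% c("fuse", "extinction")))
  # internodal branch lengths are exactly t_i with zero variance
  s <- internode_summary(tr)
  expect_equal(s$mean, 100, tolerance = 1e-12)
  expect_equal(s$variance, 0, tolerance = 1e-12)
  # and the cap truncates gracefully
  p_cap <- regime_parameters(t_i = 100, t_s = 1e6, t_r = 50,
                             timing_mode = "fixed", total_time = 650,
                             max_lineages = 16)
  h_cap <- simulate_history(p_cap, seed = 3)
  expect_true(h_cap$truncated)
  expect_equal(sum(h_cap$lineages$status == "extant"), 16)
})

test_that("fast fusion erases all but the most recent split", {
  p <- regime_parameters(t_i = 100, t_s = 50, t_r = 1e6,
                         timing_mode = "fixed", contact_outcomes = fuse_only,
                         total_time = 1030)
  h <- simulate_history(p, seed = 2)
  # all splits but the last are followed by fuse events
  n_iso <- sum(h$events$type == "isolation")
  n_fuse <- sum(h$events$type == "fuse")
  expect_equal(n_fuse, n_iso - 1)
  tr <- reconstruct_tree(h)
  expect_equal(length(tr$tip.label), 2)
  # the visible split is the latest isolating event
  last_split <- max(h$events$time[h$events$type == "isolation"])
  expect_equal(tr$root.edge, last_split)
  expect_equal(max(ape::node.depth.edgelength(tr)), 1030 - last_split)
})

test_that("reconstructed trees are valid, ultrametric and round-trip Newick", {
  p <- regime_parameters(t_i = 150, t_s = 400, t_r = 600,
                         total_time = 2000, max_lineages = 128)
  for (seed in derive_seeds(1234, 8)) {
    h <- simulate_history(p, seed = seed)
    tr <- suppressMessages(reconstruct_tree(h))
    if (is.null(tr) || length(tr$tip.label) < 2) next
    expect_true(ape::is.binary(tr))
    expect_true(all(tr$edge.length > 0))
    expect_true(ape::is.ultrametric(tr, tol = 1e-8))
    stem <- if (is.null(tr$root.edge)) 0 else tr$root.edge
    expect_lte(max(ape::node.depth.edgelength(tr)) + stem, 2000 + 1e-6)
    expect_equal(length(tr$tip.label), extant_lineages(h))
    # Newick serialization round-trips topology and branch lengths
    tr2 <- ape::read.tree(text = ape::write.tree(tr))
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(tr2)), 0,
                 ignore_attr = TRUE)
    expect_equal(sort(tr2$edge.length), sort(tr$edge.length),
                 tolerance = 1e-9)
  }
})

test_that("histories and trees are reproducible under a fixed seed", {
  p <- regime_parameters(t_i = 150, t_s = 400, t_r = 600, total_time = 1500)
  h1 <- simulate_history(p, seed = 99)
  h2 <- simulate_history(p, seed = 99)
  expect_identical(h1$events, h2$events)
  expect_identical(ape::write.tree(reconstruct_tree(h1)),
                   ape::write.tree(reconstruct_tree(h2)))
})

test_that("internode waits in the random-timing Yule regime scale as t_i/k", {
  waits <- scaled_yule_waits(t_i = 100, n_target = 2000, master_seed = 42)
  expect_length(waits, 2000)
  ks <- stats::ks.test(waits, "pexp", 1)
  expect_gt(ks$p.value, 0.01)
})

test_that("the exponential-timing speciation rate is consistent with 1/t_i", {
  t_i <- 200
  lambdas <- c()
  for (seed in derive_seeds(5150, 500)) {
    h <- simulate_history(yule_params(t_i = t_i, total_time = 1000,
                                      max_lineages = 128), seed = seed)
    tr <- suppressMessages(reconstruct_tree(h))
    if (is.null(tr) || length(tr$tip.label) < 2) next
    lambdas <- c(lambdas, diversification_estimate(tr)$lambda)
  }
  se <- stats::sd(lambdas) / sqrt(length(lambdas))
  # ln(n)/crown_age is a noisy but roughly unbiased reader of the Yule rate
  expect_lt(abs(mean(lambdas) - 1 / t_i), max(6 * se, 0.1 / t_i))
})

test_that("coupled RI times inherit the 1/(epsilon u) mean and halve with u", {
  p1 <- regime_parameters(t_i = 100, t_s = 100, coupling =
                            list(epsilon = 0.05, u = 1e-3), total_time = 100)
  expect_equal(mutdiv:::expected_tr(p1), 1 / (0.05 * 1e-3))
  set.seed(8)
  draws1 <- replicate(20000, mutdiv:::draw_ri_time(p1))
  p2 <- p1; p2$coupling$u <- 2e-3
  set.seed(8)
  draws2 <- replicate(20000, mutdiv:::draw_ri_time(p2))
  expect_equal(mean(draws2) / mean(draws1), 0.5, tolerance = 1e-9)
  se <- stats::sd(draws1) / sqrt(length(draws1))
  expect_lt(abs(mean(draws1) - 20000), 3 * se)
})

test_that("fusion regimes diversify more slowly than the RI-first regime", {
  seeds <- derive_seeds(2718, 200)
  mean_lambda <- function(t_s, t_r) {
    vals <- c()
    for (seed in seeds) {
      p <- regime_parameters(t_i = 500, t_s = t_s, t_r = t_r,
                             contact_outcomes = fuse_only,
                             total_time = 4000, max_lineages = 128)
      h <- simulate_history(p, seed = seed)
      tr <- suppressMessages(reconstruct_tree(h))
      if (is.null(tr)) next
      vals <- c(vals, if (length(tr$tip.label) < 2) 0
                else diversification_estimate(tr, age = "stem")$lambda)
    }
    mean(vals)
  }
  ri_first <- mean_lambda(t_s = 1e6, t_r = 100)   # contact never interferes
  fusing <- mean_lambda(t_s = 300, t_r = 1e6)     # contact always fuses
  expect_gt(ri_first, fusing)
})
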