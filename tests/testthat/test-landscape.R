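test_that("incompatibility counts follow the linear and quadratic laws", {
  lin <- landscape_model(1000, 0.02, "pairwise_linear")
  quad <- landscape_model(1000, 0.02, "snowball_quadratic")
  expect_equal(incompatibility_count(0, lin), 0)
  expect_equal(incompatibility_count(0, quad), 0)
  expect_equal(incompatibility_count(50, lin), 1.0)
  expect_equal(incompatibility_count(100, quad), 0.02 * 100 * 99 / 2)
  # quadratic signature: doubling d approaches a 4x increase
  ratio <- incompatibility_count(2 * 1000, quad) /
    incompatibility_count(1000, quad)
  expect_equal(ratio, 4, tolerance = 2e-3)
  # snowball dominates the paired model from d = 4 on and without bound
  d <- 4:500
  expect_true(all(incompatibility_count(d, quad) >
                  incompatibility_count(d, lin)))
  expect_gt(incompatibility_count(500, quad) / incompatibility_count(500, lin),
            100)
  expect_error(incompatibility_count(-1, lin), ">= 0")
})

test_that("path counts and the snowball condition match the closed forms", {
  m <- landscape_model(10, 0.1)
  ep <- expected_paths(m)
  expect_equal(ep$expected_paths, 9)
  expect_true(ep$viable)
  expect_false(expected_paths(landscape_model(1, 0.999))$viable)
  # boundary of the strict inequality L(1 - eps) > 1
  expect_false(expected_paths(landscape_model(1, 1e-12))$viable)
  # ln(L)/L threshold: 0.04 < ln(100)/100 = 0.04605 < 0.05
  expect_true(snowball_condition(landscape_model(100, 0.04)))
  expect_false(snowball_condition(landscape_model(100, 0.05)))
  # more targets demand a smaller epsilon
  expect_lt(log(1000) / 1000, log(100) / 100)
  expect_error(snowball_condition(landscape_model(1, 0.5)), "big_l")
})

test_that("interbreeding probability is the geometric survival function", {
  expect_equal(interbreed_probability(0, 0.3), 1)
  expect_equal(interbreed_probability(10, 0.05), 0.95^10)
  for (eps in c(0.01, 0.05, 0.2, 0.7)) {
    dist <- ri_substitution_distribution(eps)
    for (d in c(0, 1, 5, 20, 100)) {
      # P(still interbreeding after d) = P(isolating substitution is beyond d);
      # absolute bound because the survival itself underflows 1 - cdf at
      # large d and eps
      expect_lt(abs(interbreed_probability(d, eps) - (1 - dist$cdf(d))),
                1e-12)
    }
    # monotone non-increasing in d
    expect_true(all(diff(interbreed_probability(0:200, eps)) <= 0))
  }
})

test_that("the RI waiting distribution is geometric with mean 1/epsilon", {
  dist <- ri_substitution_distribution(0.5)
  expect_equal(dist$pmf(1), 0.5)
  expect_equal(dist$pmf(2), 0.25)
  # exact finite normalization: sum up to K is 1 - (1-eps)^K
  for (K in c(1, 5, 30)) {
    expect_equal(sum(dist$pmf(1:K)), 1 - 0.5^K, tolerance = 1e-12)
  }
  # truncated mean series reproduces the 1/eps closed form
  dist02 <- ri_substitution_distribution(0.02)
  expect_equal(sum((1:5000) * dist02$pmf(1:5000)), 50, tolerance = 1e-6)
  # sampler mean, Monte Carlo
  set.seed(404)
  draws <- dist02$sample(10000)
  expect_true(all(draws >= 1))
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 50), 3 * se)
  expect_error(ri_substitution_distribution(0), "epsilon")
  expect_error(ri_substitution_distribution(1), "epsilon")
})

test_that("expected RI time scales as 1/(epsilon * substitution rate)", {
  expect_equal(expected_time_to_ri(0.01, 1e-3), 1e5)
  # almost-certain first-substitution isolation takes about one substitution
  expect_equal(expected_time_to_ri(1 - 1e-12, 1), 1, tolerance = 1e-9)
  # doubling the substitution rate (e.g. via doubled u) halves the time
  expect_equal(expected_time_to_ri(0.02, 2e-3),
               expected_time_to_ri(0.02, 1e-3) / 2)
  expect_error(expected_time_to_ri(0.02, 0), "positive")
})

test_that("epsilon and the growth exponent are recovered from clean tables", {
  lin <- landscape_model(1000, 0.02, "pairwise_linear")
  quad <- landscape_model(1000, 0.02, "snowball_quadratic")
  f_lin <- fit_epsilon_and_exponent(
    make_incompatibility_table(lin, 10:100, form = "power_law"),
    "pairwise_linear")
  expect_equal(f_lin$exponent_hat, 1, tolerance = 1e-3)
  expect_equal(f_lin$epsilon_hat, 0.02, tolerance = 1e-3)
  f_quad <- fit_epsilon_and_exponent(
    make_incompatibility_table(quad, 10:100, form = "power_law"),
    "snowball_quadratic")
  expect_equal(f_quad$exponent_hat, 2, tolerance = 1e-3)
  expect_equal(f_quad$epsilon_hat, 0.02, tolerance = 1e-3)
  # the exact pair count bends the small-d slope slightly above 2
  f_pairs <- fit_epsilon_and_exponent(
    make_incompatibility_table(quad, 10:100, form = "pairs"),
    "snowball_quadratic")
  expect_equal(f_pairs$exponent_hat, 2, tolerance = 0.05)
})

test_that("the exponent survives Poisson sampling noise", {
  quad <- landscape_model(1000, 0.02, "snowball_quadratic")
  tab <- make_incompatibility_table(quad, 1:200, noise = "poisson", seed = 5)
  f <- fit_epsilon_and_exponent(tab, "snowball_quadratic")
  expect_gt(f$exponent_hat, 1.8)
  expect_lt(f$exponent_hat, 2.2)
  # Poisson engine handles the zero counts that log least squares drops
  fp <- fit_epsilon_and_exponent(tab, "snowball_quadratic", engine = "poisson")
  expect_gt(fp$exponent_hat, 1.8)
  expect_lt(fp$exponent_hat, 2.2)
})

test_that("unfittable tables are rejected with clear errors", {
  expect_error(fit_epsilon_and_exponent(data.frame(d = 1:5, count = 0)),
               "zero")
  expect_error(
    fit_epsilon_and_exponent(data.frame(d = 1:5, count = c(1, 1, 0, 0, 0))),
    "positive counts")
  expect_error(fit_epsilon_and_exponent(data.frame(x = 1, y = 2)), "columns")
})
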