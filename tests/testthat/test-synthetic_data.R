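test_that("config validation and determinism", {
  expect_error(sim_config(n_genes = 1), "at least 2")
  expect_error(sim_config(sigma = -0.1), "sigma")
  expect_error(sim_config(treated_fraction = 1.5), "treated_fraction")
  expect_error(sim_config(perturbed = c(nope = 2)), "not in gene set")
  cfg <- sim_config(n_genes = 4, n_samples = 10, seed = 7)
  d1 <- simulate_qpcr(cfg)
  d2 <- simulate_qpcr(cfg)
  expect_identical(d1$cq$cq, d2$cq$cq)
  expect_identical(d1$quantities$q, d2$quantities$q)
})

test_that("noise-free limit gives all-zero stability statistics", {
  cfg <- sim_config(n_genes = 4, n_samples = 8, sigma = 0, sigma_content = 0,
                    treated_fraction = 0, seed = 1)
  ds <- simulate_qpcr(cfg)
  for (g in cfg$gene_ids) expect_equal(m_value(ds$quantities, g), 0)
  curve <- v_curve(ds$quantities, rank_stepwise(ds$quantities))
  expect_equal(unname(curve$v_values), rep(0, 2))
  expect_identical(curve$recommended_n, 2L)
})

test_that("the shared mRNA-content factor cancels in every M", {
  # same seed => identical eps draws; only sigma_content differs
  base <- sim_config(n_genes = 5, n_samples = 12, sigma = 0.3,
                     sigma_content = 0, treated_fraction = 0, seed = 3)
  loud <- base; loud$sigma_content <- 1
  q0 <- simulate_qpcr(base)$quantities
  q1 <- simulate_qpcr(loud)$quantities
  for (g in base$gene_ids) {
    expect_equal(m_value(q0, g), m_value(q1, g), tolerance = 1e-12)
  }
  # and with all sigma zero, M stays exactly zero despite content noise
  pure <- sim_config(n_genes = 4, n_samples = 8, sigma = 0, sigma_content = 1,
                     treated_fraction = 0, seed = 5)
  qp <- simulate_qpcr(pure)$quantities
  for (g in pure$gene_ids) expect_equal(m_value(qp, g), 0, tolerance = 1e-12)
})

test_that("Cq and quantity views are consistent", {
  ds <- simulate_qpcr(sim_config(n_genes = 4, n_samples = 6, seed = 11))
  expect_equal(cq_to_quantity(ds$cq)$q, ds$quantities$q, tolerance = 1e-12)
  expect_true(all(ds$cq$cq > 10) && all(ds$cq$cq < 40))
})

test_that("expected M follows the closed form", {
  cfg <- sim_config(n_genes = 3, n_samples = 10, sigma = 0.2, seed = 1)
  expect_equal(expected_m(cfg, "gene01"), sqrt(0.08), tolerance = 1e-12)
  cfg0 <- sim_config(n_genes = 3, n_samples = 10, sigma = c(0, 0, 0), seed = 1)
  expect_equal(expected_m(cfg0, "gene01"), 0)
  cfg2 <- sim_config(n_genes = 3, n_samples = 10, sigma = c(0.1, 0.2, 0.4),
                     seed = 1)
  expect_equal(expected_m(cfg2, "gene02"),
               mean(c(sqrt(0.04 + 0.01), sqrt(0.04 + 0.16))))
  pert <- sim_config(n_genes = 3, n_samples = 10, perturbed = c(gene01 = 2))
  expect_error(expected_m(pert, "gene01"), "unperturbed")
})

test_that("empirical M approaches the closed form at large n", {
  cfg <- sim_config(n_genes = 4, n_samples = 2000,
                    sigma = c(0.1, 0.2, 0.3, 0.4), sigma_content = 0.5,
                    treated_fraction = 0, seed = 17)
  q <- simulate_qpcr(cfg)$quantities
  for (g in cfg$gene_ids) {
    expect_equal(m_value(q, g), expected_m(cfg, g), tolerance = 0.08)
  }
})

test_that("true stability order ranks perturbed genes below unperturbed", {
  cfg <- sim_config(n_genes = 4, n_samples = 10,
                    sigma = c(0.4, 0.1, 0.2, 0.3),
                    perturbed = c(gene02 = 2), treated_fraction = 0.5)
  ds <- simulate_qpcr(cfg)
  expect_identical(ds$true_stability_order,
                   c("gene03", "gene04", "gene01", "gene02"))
  expect_length(ds$treated_samples, 5)
})

test_that("experiment suites jitter around the base configuration", {
  base <- sim_config(n_genes = 4, n_samples = 8, sigma = 0.2, seed = 1)
  suite <- simulate_experiment_suite(base, n_experiments = 3,
                                     heterogeneity = 0.3, seed = 9)
  expect_length(suite, 3)
  sigmas <- sapply(suite, function(d) d$config$sigma)
  expect_gt(stats::sd(sigmas), 0)  # jitter actually applied
  again <- simulate_experiment_suite(base, 3, heterogeneity = 0.3, seed = 9)
  expect_identical(suite[[2]]$cq$cq, again[[2]]$cq$cq)
  # zero jitter: same sigma everywhere, different draws
  flat <- simulate_experiment_suite(base, 2, heterogeneity = 0, seed = 9)
  expect_equal(flat[[1]]$config$sigma, flat[[2]]$config$sigma)
  expect_false(identical(flat[[1]]$cq$cq, flat[[2]]$cq$cq))
})

test_that("well-separated sigma is recovered at the ranking extremes", {
  # sigma ratios >= 2 between adjacent genes; the statistic cannot order
  # the final pair, so "most stable recovered" means reaching that pair
  least_first <- 0L
  most_in_pair <- 0L
  for (s in 1:100) {
    cfg <- sim_config(n_genes = 5, n_samples = 50,
                      sigma = c(0.05, 0.1, 0.2, 0.4, 0.8),
                      sigma_content = 0.5, treated_fraction = 0,
                      seed = 70000 + s)
    r <- rank_stepwise(simulate_qpcr(cfg)$quantities)
    if (r$ranking[1] == "gene05") least_first <- least_first + 1L
    if ("gene01" %in% utils::tail(r$ranking, 2)) most_in_pair <- most_in_pair + 1L
  }
  expect_gte(least_first, 95L)
  expect_gte(most_in_pair, 95L)
})
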