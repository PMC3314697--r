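test_that("gene flow M follows (1/FST - 1)/4 and is undefined at 0", {
  expect_equal(gene_flow_M(1), 0)
  expect_equal(gene_flow_M(0.5), 0.25)
  expect_equal(gene_flow_M(0.96), (1 / 0.96 - 1) / 4)
  expect_true(is.na(gene_flow_M(0)))
  expect_true(is.na(gene_flow_M(-0.02)))
  f <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(gene_flow_M(f)) < 0))
})

test_that("distance from the ancestral location matches the geographic
           matrix and is monotone along a simulated coastline", {
  sim <- simulate_fixation_cascade(
    sim_params(mode = "fixation-cascade", n_pops_per_front = 6,
               fronts = 1, fixation_prob = 1, sample_size = 6, seed = 13))
  st <- sim$table
  d <- distance_from_ancestor(st, sim$truth$origin)
  expect_equal(unname(d[sim$truth$origin]), 0)
  km <- geographic_distance(st)
  expect_equal(unname(d), unname(km[sim$truth$origin, ]))
  # single northward front: founding order increases with distance
  ord <- sim$truth$founding_order[names(d)]
  expect_equal(order(d), order(ord))
  expect_error(distance_from_ancestor(st, "nowhere"), "unknown")
})

test_that("clock dating reproduces the printed worked examples", {
  c4 <- clock_dating(4, 490)
  expect_equal(c4$percent_rounded, 0.82)
  expect_equal(c4$t_low_myr_rounded, 0.9)
  expect_equal(c4$t_high_myr_rounded, 1.3)

  c2 <- clock_dating(2, 490)
  expect_equal(c2$percent_rounded, 0.41)
  expect_equal(c2$t_low_yr_rounded, 460000)
  expect_equal(c2$t_high_yr_rounded, 630000)

  c0 <- clock_dating(0, 490)
  expect_equal(c0$percent_divergence, 0)
  expect_equal(c0$t_high_myr, 0)

  # linear in steps; halving L doubles the percent
  expect_equal(clock_dating(8, 490)$percent_divergence,
               2 * c4$percent_divergence)
  expect_equal(clock_dating(4, 245)$percent_divergence,
               2 * c4$percent_divergence)
  expect_lt(c4$t_low_myr, c4$t_high_myr)
})

test_that("the pair test flags constant divergence and the diversity test
           flags the monomorphic regime", {
  # f = 1 cascade: every population monomorphic and distinct -> DA == 1
  sim <- simulate_fixation_cascade(
    sim_params(mode = "fixation-cascade", n_pops_per_front = 4,
               fronts = 1, fixation_prob = 1, sample_size = 6, seed = 21))
  res <- good_model_pair_test(sim$table, sim$haps,
                              ancestor_location = sim$truth$origin,
                              nperm = 99, seed = 1)
  expect_true(is.na(res$r))
  dres <- good_model_diversity_test(sim$table,
                                    ancestor_location = sim$truth$origin)
  expect_true(is.na(dres$r))
  expect_match(dres$undefined_reason, "constant")
})

test_that("Good-model simulations show the predicted negative divergence
           gradient; cascades do not", {
  neg <- vapply(1:6, function(s) {
    sim <- simulate_good_model(
      sim_params(mode = "good-model", n_pops = 10, pop_size = 100,
                 mutation_rate = 0.2, generations_between_foundings = 80,
                 sample_size = 25, seed = 600 + s))
    good_model_pair_test(sim$table, sim$haps,
                         ancestor_location = sim$truth$origin,
                         nperm = 199, seed = s)$r
  }, numeric(1))
  expect_gt(mean(neg < 0), 0.5)

  ns <- vapply(1:6, function(s) {
    sim <- simulate_fixation_cascade(
      sim_params(mode = "fixation-cascade", n_pops_per_front = 10,
                 fronts = 2, fixation_prob = 0.65, sample_size = 8,
                 seed = 700 + s))
    good_model_pair_test(sim$table, sim$haps,
                         ancestor_location = sim$truth$origin,
                         nperm = 199, seed = s)$p_less
  }, numeric(1))
  expect_gt(mean(ns > 0.05), 0.5)
})

test_that("with a finite founding propagule, diversity declines with
           distance from the ancestor", {
  rs <- vapply(1:10, function(s) {
    sim <- simulate_good_model(
      sim_params(mode = "good-model", n_pops = 10, pop_size = 300,
                 mutation_rate = 0.5, generations_between_foundings = 60,
                 propagule_size = 2, sample_size = 25, seed = 800 + s))
    good_model_diversity_test(sim$table,
                              ancestor_location = sim$truth$origin)$r
  }, numeric(1))
  expect_lt(stats::median(rs), 0)
})
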