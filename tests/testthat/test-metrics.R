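test_that("metric values match hand-computed cases", {
  expect_equal(srmse(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(srmse(c(0.6, 0.4), c(0.5, 0.5)), sqrt(2 * 0.02))
  expect_equal(srmse(c(1, 0), c(0, 1)), 2)

  expect_equal(jsd(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(jsd(c(1, 0), c(0, 1)), 1)

  expect_equal(wasserstein_ordinal(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(wasserstein_ordinal(c(1, 0, 0), c(0, 0, 1)), 2)
  expect_equal(wasserstein_ordinal(c(0.5, 0.5), c(0, 1)), 0.5)

  expect_error(srmse(c(1, 0), c(1, 0, 0)), class = "hhsynth_metric_error")
})

test_that("metrics agree with brute-force oracles on random pairs", {
  set.seed(2024)
  for (i in 1:300) {
    n <- sample(2:12, 1)
    pq <- random_share_pair(n)
    expect_equal(srmse(pq$p, pq$q), oracle_srmse(pq$p, pq$q), tolerance = 1e-12)
    expect_equal(jsd(pq$p, pq$q), oracle_jsd(pq$p, pq$q), tolerance = 1e-12)
    expect_equal(wasserstein_ordinal(pq$p, pq$q), oracle_w1(pq$p, pq$q),
                 tolerance = 1e-12)
  }
})

test_that("metric symmetries and ordinal shift additivity hold", {
  set.seed(7)
  for (i in 1:50) {
    pq <- random_share_pair(8)
    expect_equal(jsd(pq$p, pq$q), jsd(pq$q, pq$p), tolerance = 1e-12)
    expect_equal(srmse(pq$p, pq$q), srmse(pq$q, pq$p), tolerance = 1e-12)
    expect_gte(jsd(pq$p, pq$q), 0)
    expect_lte(jsd(pq$p, pq$q), 1)
  }
  # one-hot shift distance equals the index gap
  n <- 9
  for (i in 1:n) for (j in 1:n) {
    p <- replace(rep(0, n), i, 1)
    q <- replace(rep(0, n), j, 1)
    expect_equal(wasserstein_ordinal(p, q), abs(i - j))
  }
})

test_that("SRMSE grows with category count at fixed per-category error", {
  vals <- vapply(c(2, 4, 8, 16), function(n) {
    p <- rep(1 / n, n)
    q <- p + rep(c(0.01, -0.01), n / 2)
    srmse(p, q)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("cross-tab R-squared behaves at the extremes and flags degeneracy", {
  # 2x2 with dependence: size-1 households are all male singletons
  pop <- population(c(
    lapply(1:4, function(i) hh(person(30, "male", "head"), id = paste0("m", i))),
    lapply(1:4, function(i) hh(person(30, "male", "head"),
                               person(29, "female", "partner"),
                               id = paste0("c", i)))))
  size_spec <- target_descriptor("household_size", c("1", "2"), c(1, 1),
                                 ordered = TRUE, level = "household")
  ref_exact <- expand.grid(household_size = c("1", "2"), gender = c("male", "female"),
                           stringsAsFactors = FALSE)
  ref_exact$share <- c(4 / 12, 4 / 12, 0, 4 / 12)
  ct <- crosstab_r2(pop, ref_exact, c("household_size", "gender"),
                    size_spec = size_spec)
  expect_equal(ct$r_squared, 1, tolerance = 1e-12)
  expect_equal(ct$n_cells, 4L)

  # independence product against the dependent reference scores below 1
  ref_indep <- ref_exact
  ref_indep$share <- c(1 / 3 * 2 / 3, 2 / 3 * 2 / 3, 1 / 3 * 1 / 3, 2 / 3 * 1 / 3)
  ct2 <- crosstab_r2(pop, ref_indep, c("household_size", "gender"),
                     size_spec = size_spec)
  expect_lt(ct2$r_squared, 1)

  ref_flat <- ref_exact
  ref_flat$share <- rep(0.25, 4)
  ct3 <- crosstab_r2(pop, ref_flat, c("household_size", "gender"),
                     size_spec = size_spec)
  expect_true(ct3$degenerate)
  expect_true(is.na(ct3$r_squared))

  ref_inc <- expand.grid(household_size = c("1", "2"), income = c("low", "high"),
                         stringsAsFactors = FALSE)
  ref_inc$share <- rep(0.25, 4)
  expect_error(crosstab_r2(pop, ref_inc, c("household_size", "income"),
                           size_spec = size_spec),
               "income", class = "hhsynth_metric_error")
})

test_that("bootstrap confidence intervals are seeded and bounded", {
  expect_equal(unname(bootstrap_ci(rep(0.7, 10), seed = 1)),
               c(0.7, 0.7, 0.7))
  ci <- bootstrap_ci(rep(c(0, 1), each = 10), n_boot = 4000, seed = 5)
  expect_equal(unname(ci["mean"]), 0.5)
  expect_gte(ci["lower"], 0)
  expect_lte(ci["upper"], 1)
  expect_lt(ci["lower"], ci["mean"])
  expect_gt(ci["upper"], ci["mean"])
  # determinism
  x <- c(0.61, 0.70, 0.66, 0.74, 0.58)
  expect_identical(bootstrap_ci(x, seed = 11), bootstrap_ci(x, seed = 11))
  expect_error(bootstrap_ci(0.5), class = "hhsynth_metric_error")
  expect_error(bootstrap_ci(c(0.5, 0.6), n_boot = 10), class = "hhsynth_metric_error")
})

test_that("convergence traces track the generation batches", {
  targets <- fixture_targets()
  backend <- reference_sampler_backend(targets, default_schema(), seed = 3)
  res <- generate_population(generation_config(60, batch_size = 10, seed = 3),
                             targets, default_schema(), default_rules(), backend)
  tr <- convergence_trace(res$trace, targets)
  expect_equal(length(unique(tr$batch)), 6L)
  # final trace point equals the fit-report SRMSE
  fr <- fit_report(res$population, targets)
  last <- tr[tr$batch == max(tr$batch), ]
  for (nm in fr$per_descriptor$descriptor) {
    expect_equal(last$srmse[last$descriptor == nm],
                 fr$per_descriptor$srmse[fr$per_descriptor$descriptor == nm],
                 tolerance = 1e-12)
  }
  expect_error(convergence_trace(list(batches = list()), targets),
               class = "hhsynth_metric_error")
})
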