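test_that("designs and datasets are reproducible from their seed", {
  d1 <- make_design(seed = 4)
  d2 <- make_design(seed = 4)
  expect_identical(d1$sites, d2$sites)
  expect_identical(d1$treat, d2$treat)

  s1 <- simulate_dataset(d1, truth_params(), seed = 10)
  s2 <- simulate_dataset(d2, truth_params(), seed = 10)
  expect_identical(s1$data$counts, s2$data$counts)
  expect_identical(s1$latent, s2$latent)
})

test_that("the default design matches the study layout", {
  d <- make_design(seed = 1)
  expect_equal(d$n_sites, 71)
  expect_equal(d$n_years, 4)
  expect_equal(d$n_periods, 4)
  expect_equal(unname(colSums(d$treat)), c(0, 0, 10, 8))
  # year-4 treated sites are a subset of year-3's; none treated in years 1-2
  expect_true(all(d$treat[d$treat[, 4] == 1, 3] == 1))
  expect_equal(anyDuplicated(d$sites[, c("x_m", "y_m")]), 0L)
  # elevation spans the design range along the grid
  expect_gt(diff(range(d$sites$elevation_m)), 400)
  expect_error(make_design(seed = 1, n_sites = 5, n_treat_y3 = 9),
               "more treated sites")
})

test_that("realized temperature-precipitation correlation is calibrated to -0.9", {
  rs <- vapply(1:20, function(s) {
    d <- make_design(seed = s)
    pearson_correlation(d$sites$tmean_c, d$sites$precip_mm)
  }, 0)
  expect_lt(abs(mean(rs) + 0.9), 0.05)
})

test_that("perfect detection with one period reveals the latent state", {
  truth <- truth_params(params = nmix_params(
    beta_psi = c(0.5, -1), beta_lambda = c(-0.1, 0, 0, -0.1),
    beta_p = c(40, 0, 0, 0, 0)))
  d <- make_design(seed = 2, n_sites = 30, n_periods = 1)
  sim <- simulate_dataset(d, truth, seed = 3)
  y <- sim$data$y[, , 1]
  expect_identical(as.integer(y), as.integer(sim$latent))
})

test_that("initial abundance draws match their Poisson intensity", {
  d <- make_design(seed = 6, n_sites = 2000)
  sim <- simulate_dataset(d, truth_params(), seed = 7)
  psi <- initial_intensity(reference_params(), sim$data$climate)
  mc_se <- sqrt(sum(psi)) / length(psi)
  expect_lt(abs(mean(sim$latent[, 1]) - mean(psi)), 4 * mc_se)
})

test_that("counts never exceed the latent state and extinction is absorbing", {
  sim <- simulate_reference(seed = 12)
  N <- sim$latent
  for (j in seq_len(sim$data$n_periods)) {
    expect_true(all(sim$data$y[, , j] <= N))
  }
  for (t in 2:ncol(N)) {
    gone <- N[, t - 1] == 0
    expect_true(all(N[gone, t] == 0))
    expect_true(all(sim$data$y[gone, t, ] == 0))
  }
  # sparse-count regime: yearly totals of detected individuals are tens
  yearly <- apply(sim$data$y, 2, function(m) sum(apply(m, 1, max)))
  expect_true(all(yearly < 500))
  expect_gt(sum(yearly), 0)
})

test_that("treatment acts as a seed-controlled counterfactual", {
  d_treated <- make_design(seed = 8)
  d_control <- d_treated
  d_control$treat[] <- 0
  s_treated <- simulate_dataset(d_treated, truth_params(), seed = 9)
  s_control <- simulate_dataset(d_control, truth_params(), seed = 9)
  ever_treated <- rowSums(d_treated$treat) > 0
  # untouched sites share identical trajectories and counts
  expect_identical(s_treated$latent[!ever_treated, ],
                   s_control$latent[!ever_treated, ])
  # all sites agree before the treatment years
  expect_identical(s_treated$latent[, 1:2], s_control$latent[, 1:2])
})

test_that("the generative model and the likelihood agree (self-consistency)", {
  # under the truth, the marginal likelihood of simulated data beats the
  # likelihood under perturbed parameters, on average over seeds
  spec <- truth_params()$spec
  truth <- reference_params()
  worse <- nmix_params(beta_psi = truth$beta_psi + c(1.2, 1),
                       beta_lambda = truth$beta_lambda + c(-1, 0.8, 0, 0.4),
                       beta_p = truth$beta_p + c(-1.5, 0, 0.8, 0, 0))
  diffs <- vapply(1:10, function(s) {
    sim <- simulate_reference(seed = 100 + s, n_sites = 40)
    dataset_loglik(sim$data, truth, spec) -
      dataset_loglik(sim$data, worse, spec)
  }, 0)
  expect_gt(mean(diffs), 0)
})
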