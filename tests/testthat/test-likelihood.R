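top_spec <- nmix_spec(lambda_terms = c("climate", "treatment", "density"))

test_that("link functions evaluate their linear predictors", {
  p0 <- nmix_params(beta_psi = c(0, 0), beta_lambda = rep(0, 4),
                    beta_p = rep(0, 5))
  expect_equal(initial_intensity(p0, 3.2), 1)
  expect_equal(growth_rate(p0, top_spec, 1, 1, 5), 1)
  expect_equal(detection_prob(p0, 1, 1, 1, 1), 0.5)

  expect_equal(initial_intensity(nmix_params(beta_psi = c(0, log(2))), 1), 2)
  t1 <- reference_params()
  expect_equal(initial_intensity(t1, 0), exp(-2.63))
  expect_equal(growth_rate(nmix_params(beta_lambda = -1.08),
                           nmix_spec(lambda_terms = character()), 0),
               exp(-1.08))
  dens_only <- nmix_spec(lambda_terms = "density")
  expect_equal(growth_rate(nmix_params(beta_lambda = c(0, -0.24)),
                           dens_only, 0, density = 1), exp(-0.24))
  expect_equal(detection_prob(nmix_params(beta_p = -10)), 1 / (1 + exp(10)))
  expect_equal(detection_prob(t1), plogis(0.37))

  expect_error(initial_intensity(nmix_params(beta_psi = c(800, 0)), 0),
               "overflow")
})

test_that("growth rate is strictly decreasing in density when beta3 < 0", {
  pars <- nmix_params(beta_lambda = c(-0.5, -0.24))
  spec <- nmix_spec(lambda_terms = "density")
  lam <- growth_rate(pars, spec, 0, density = 0:10)
  expect_true(all(diff(lam) < 0))
})

test_that("the latent transition is Poisson with absorbing extinction", {
  expect_equal(transition_logpmf(0, 0, 2), 0)
  expect_equal(transition_logpmf(0, 1, 2), -Inf)
  expect_equal(transition_logpmf(2, 1, 0.5), -1)  # Poisson(1) at k = 1
  # normalization over the destination state
  for (np in c(1, 3)) {
    for (lam in c(0.4, 1.7)) {
      s <- sum(exp(transition_logpmf(np, 0:200, lam)))
      expect_equal(s, 1, tolerance = 1e-12)
    }
  }
})

test_that("cumulative detection follows the complement rule", {
  expect_equal(cumulative_detection(0, 4), 0)
  expect_equal(cumulative_detection(1, 7), 1)
  expect_equal(cumulative_detection(plogis(0.37), 4), 0.972, tolerance = 5e-4)
  p <- seq(0.05, 0.95, by = 0.1)
  expect_true(all(diff(cumulative_detection(p, 4)) > 0))
  expect_true(all(cumulative_detection(0.3, 1:6) ==
                    cummax(cumulative_detection(0.3, 1:6))))
})

test_that("forward recursion reproduces the zero-count closed form", {
  # T = 1, J = 1, y = 0: sum_N Pois(N; psi) (1-p)^N = exp(-psi p)
  for (psi in c(0.5, 1, 2)) {
    for (p in c(0.3, 0.5, 0.9)) {
      ll <- forward_marginal_loglik(matrix(0L, 1, 1), log(psi),
                                    numeric(0), p, K = 60)
      expect_equal(ll, -psi * p, tolerance = 1e-10)
    }
  }
})

test_that("forward recursion equals exhaustive enumeration on small instances", {
  set.seed(101)
  for (rep in 1:25) {
    inst <- random_instance()
    ll_fwd <- forward_marginal_loglik(inst$y, inst$log_psi, inst$eta_lambda,
                                      inst$p, inst$K,
                                      c_density = inst$c_density)
    ll_enum <- enum_loglik(inst$y, inst$log_psi, inst$eta_lambda, inst$p,
                           inst$K, c_density = inst$c_density)
    expect_equal(ll_fwd, ll_enum, tolerance = 1e-10)
  }
})

test_that("likelihood is stable once K passes the Poisson tail", {
  y <- matrix(c(1L, 0L, 2L, 1L, 0L, 1L), 3, 2)
  ll1 <- forward_marginal_loglik(y, 0.5, c(-0.2, -0.2), 0.5, K = 30,
                                 c_density = -0.1)
  ll2 <- forward_marginal_loglik(y, 0.5, c(-0.2, -0.2), 0.5, K = 60,
                                 c_density = -0.1)
  expect_equal(ll1, ll2, tolerance = 1e-12)
})

test_that("counts above the truncation bound are rejected", {
  expect_error(forward_marginal_loglik(matrix(7L, 1, 1), 0, numeric(0),
                                       0.5, K = 5), "K")
})

test_that("total probability over all count arrays approaches one", {
  # 1 site, T = 1, J = 1: sum over y of exp(loglik) -> 1 as K grows
  psi <- 1.3; p <- 0.6
  tot <- sum(vapply(0:40, function(yv)
    exp(forward_marginal_loglik(matrix(as.integer(yv), 1, 1), log(psi),
                                numeric(0), p, K = 80)), 0))
  expect_equal(tot, 1, tolerance = 1e-8)
})

test_that("dataset likelihood is an independent sum over sites", {
  counts <- matrix(c(1L, 0L, 2L,
                     0L, 0L, 1L), 3, 2)
  dat <- toy_dataset(counts)
  pars <- nmix_params(beta_psi = c(0, -0.5),
                      beta_lambda = c(-0.3, 0.1, 0, -0.1),
                      beta_p = c(0.3, 0.1, -0.2, 0.1, 0))
  per_site <- site_logliks(dat, pars, top_spec, K = 25)
  expect_equal(dataset_loglik(dat, pars, top_spec, K = 25), sum(per_site))
  expect_equal(site_marginal_loglik(dat, "t02", pars, top_spec, K = 25),
               unname(per_site["t02"]))
  # per-site values are invariant to site order
  dat2 <- toy_dataset(counts[c(2, 3, 1), ])
  expect_error(site_marginal_loglik(dat, "nope", pars, top_spec), "unknown")
  expect_true(is.finite(dataset_loglik(dat2, pars, top_spec, K = 25)))
})

test_that("site likelihoods agree with the low-level forward entry", {
  counts <- matrix(c(2L, 0L, 1L, 1L, 0L, 0L), 3, 2)
  dat <- toy_dataset(counts, J = 2)
  pars <- nmix_params(beta_psi = c(-0.2, -0.5),
                      beta_lambda = c(-0.3, 0.2, -1, -0.15),
                      beta_p = c(0.3, 0.1, -0.2, 0.1, -0.05))
  ll <- site_logliks(dat, pars, top_spec, K = 20)
  for (i in 1:3) {
    Tn <- length(dat$years)
    psi <- log(initial_intensity(pars, dat$climate[i]))
    eta <- vapply(2:Tn, function(t)
      log(growth_rate(pars, top_spec, dat$climate[i],
                      treatment = dat$treat[i, t], density = 0)), 0)
    pmat <- t(vapply(seq_len(Tn), function(t) {
      rep(detection_prob(pars, dat$Wp[i, t, "wind"], dat$Wp[i, t, "noise"],
                         dat$Wp[i, t, "date"], dat$Wp[i, t, "time"]),
          dat$n_periods)
    }, numeric(dat$n_periods)))
    ll_i <- forward_marginal_loglik(dat$y[i, , ], psi, eta, pmat, 20,
                                    c_density = pars$beta_lambda[4])
    expect_equal(unname(ll[i]), ll_i, tolerance = 1e-12)
  }
})

test_that("direct marginal-likelihood maximization recovers strong signals", {
  set.seed(21)
  sim <- simulate_reference(seed = 31, n_sites = 120)
  spec <- nmix_spec(lambda_terms = character())
  ml <- fit_marginal_ml(sim$data, spec)
  expect_equal(ml$convergence, 0)
  # climate effect on initial abundance is strongly negative in truth (-1.56)
  expect_lt(ml$coef[["psi_climate"]], -0.5)
  null_pars <- nmix_params(beta_psi = c(0, 0), beta_lambda = 0,
                           beta_p = rep(0, 5))
  expect_gt(ml$loglik, dataset_loglik(sim$data, null_pars, spec))
})
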