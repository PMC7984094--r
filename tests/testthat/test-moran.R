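test_that("Moran's I matches the brute-force double sum on a toy", {
  coords <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1))
  vals <- c(2.0, -1.0, 0.5, 3.5)
  w <- opennmix:::spatial_weights(coords, "inverse_distance")
  expect_equal(morans_i(vals, coords), moran_bruteforce(vals, w))

  set.seed(13)
  coords <- cbind(runif(12), runif(12))
  vals <- rnorm(12)
  w <- opennmix:::spatial_weights(coords, "k_nearest", k = 3)
  expect_equal(morans_i(vals, coords, "k_nearest", k = 3),
               moran_bruteforce(vals, w))
})

test_that("Moran's I is invariant to affine transformation of values", {
  set.seed(21)
  coords <- cbind(runif(15), runif(15))
  vals <- rnorm(15)
  i1 <- morans_i(vals, coords)
  i2 <- morans_i(3.7 * vals - 12, coords)
  expect_equal(i1, i2, tolerance = 1e-12)
})

test_that("degenerate spatial inputs error", {
  coords <- cbind(c(0, 1, 2), c(0, 0, 0))
  expect_error(morans_i(rep(1, 3), coords), "constant")
  expect_error(morans_i(1:2, coords[1:2, ]), "at least 3")
  dup <- cbind(c(0, 0, 1), c(0, 0, 1))
  expect_error(morans_i(c(1, 2, 3), dup), "duplicate")
})

test_that("the permutation null of Moran's I has mean -1/(n-1)", {
  set.seed(31)
  n <- 25
  coords <- cbind(runif(n), runif(n))
  vals <- rnorm(n)
  w <- opennmix:::spatial_weights(coords, "inverse_distance")
  z0 <- vals - mean(vals)
  perms <- vapply(1:4000, function(b) {
    z <- z0[sample.int(n)]
    (n / sum(w)) * as.numeric(t(z) %*% w %*% z) / sum(z0^2)
  }, 0)
  expect_lt(abs(mean(perms) - (-1 / (n - 1))), 0.01)
})

test_that("the permutation test is reproducible and well-behaved", {
  set.seed(41)
  coords <- cbind(runif(20), runif(20))
  vals <- rnorm(20)
  r1 <- permutation_test(vals, coords, n_perm = 199, seed = 5)
  r2 <- permutation_test(vals, coords, n_perm = 199, seed = 5)
  expect_identical(r1, r2)
  expect_gt(r1$p_value, 0)
  expect_lte(r1$p_value, 1)
  expect_equal(r1$expected_I, -1 / 19)
  expect_error(permutation_test(vals, coords, n_perm = 50), "99")
})

test_that("a strong spatial gradient is detected with high power", {
  g <- expand.grid(x = 0:5, y = 0:5)
  vals <- g$x + 0.5 * g$y + rnorm(36, 0, 0.1)
  res <- permutation_test(vals, as.matrix(g), n_perm = 499, seed = 2)
  expect_lte(res$p_value, 0.01)
})

# a minimal hand-built fit object: enough structure for fitted_values()
fake_fit <- function(dat, draws, latent_list) {
  structure(list(draws = draws, latent = latent_list,
                 spec = nmix_spec(lambda_terms = character()),
                 data = dat,
                 config = mcmc_config(n_chains = length(latent_list),
                                      n_iter = 10, burn_in = 0, thin = 1)),
            class = "nmix_fit")
}

test_that("fitted values average N*p over draws (hand-checked)", {
  counts <- matrix(c(1L, 0L, 2L, 0L, 1L, 0L), 3, 2)
  dat <- toy_dataset(counts)
  spec0 <- nmix_spec(lambda_terms = character())
  nms <- c("psi_(Intercept)", "psi_climate", "lambda_(Intercept)",
           "p_(Intercept)", "p_wind", "p_noise", "p_date", "p_time")
  # two draws with p fixed at 0.5 (intercept 0) and known latents
  draws <- matrix(0, 2, 8, dimnames = list(NULL, nms))
  N1 <- matrix(2L, 3, 2); N2 <- matrix(4L, 3, 2)
  latent <- array(c(N1, N2), c(3, 2, 2))
  fit <- fake_fit(dat, draws, list(latent))
  rf <- fitted_values(fit)
  expect_s3_class(rf, "residual_field")
  expect_equal(nrow(rf), 6)
  expect_equal(rf$fitted, rep(0.5 * 3, 6))      # mean(2,4) * 0.5
  expect_equal(rf$residual, rf$observed - rf$fitted)

  # doubling the retained latent draws doubles the fitted values
  fit2 <- fake_fit(dat, draws, list(latent * 2L))
  expect_equal(fitted_values(fit2)$fitted, 2 * rf$fitted)
})

test_that("perfect-detection degenerate fits give zero residuals", {
  counts <- matrix(c(1L, 0L, 2L, 0L, 1L, 0L), 3, 2)
  dat <- toy_dataset(counts)
  nms <- c("psi_(Intercept)", "psi_climate", "lambda_(Intercept)",
           "p_(Intercept)", "p_wind", "p_noise", "p_date", "p_time")
  draws <- matrix(0, 2, 8, dimnames = list(NULL, nms))
  draws[, "p_(Intercept)"] <- 40    # p = 1
  N <- apply(dat$y, c(1, 2), max)   # N = y (all periods equal here)
  latent <- array(rep(N, 2), c(3, 2, 2))
  fit <- fake_fit(dat, draws, list(latent))
  rf <- fitted_values(fit)
  expect_equal(rf$residual, rep(0, 6), tolerance = 1e-12)
})

test_that("the per-year residual scan covers every year and flags bad years", {
  sim <- simulate_reference(seed = 19, n_sites = 40)
  fit <- run_mcmc(sim$data, truth_params()$spec, config = mcmc_config(
    n_chains = 2, n_iter = 1500, thin = 5, burn_in = 300, seed = 4),
    pointwise = FALSE)
  scan <- residual_scan(fit, n_perm = 199, seed = 6)
  expect_equal(nrow(scan), 4)
  expect_equal(scan$year, sim$data$years)
  expect_true(all(scan$status %in% c("ok", "untestable")))
  ok <- scan$status == "ok"
  expect_true(all(scan$p_value[ok] > 0 & scan$p_value[ok] <= 1))

  # a year slice with too few sites is untestable, not an error
  rf <- fitted_values(fit)[1:2, ]
  scan2 <- opennmix:::residual_scan_field(rf, n_perm = 199, seed = 1)
  expect_true(all(scan2$status == "untestable"))
})
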