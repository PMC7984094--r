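#' Fitted values and residuals of a fitted model
#'
#' For each site-year, the fitted value is the posterior mean of
#' `N_{i,t} * pbar_{i,t}` over the retained draws, where `pbar` is the mean
#' detection probability across the survey periods at that draw; the
#' residual is the observed mean count over periods minus the fitted value.
#' These site-level residuals are the input to the spatial autocorrelation
#' diagnostics.
#'
#' @param fit An [run_mcmc()] fit that retained latent abundance draws.
#' @param data The [pcount_data()] the model was fitted to (defaults to the
#'   data stored in the fit).
#' @return A tibble of class `residual_field` with columns `site_id`,
#'   `year`, `x`, `y`, `observed`, `fitted`, `residual`.
#' @export
fitted_values <- function(fit, data = fit$data) {
  stopifnot(inherits(fit, "nmix_fit"))
  if (is.null(fit$latent) || !length(fit$latent)) {
    stop("fit does not retain latent abundance draws")
  }
  n <- length(data$site_ids); Tn <- length(data$years)
  spec <- fit$spec

  # accumulate E[N * p] over chains and retained draws
  acc <- matrix(0, n, Tn)
  total <- 0L
  offset <- 0L
  for (c_ in seq_along(fit$latent)) {
    Ncube <- fit$latent[[c_]]
    n_keep <- dim(Ncube)[3]
    for (s in seq_len(n_keep)) {
      beta <- fit$draws[offset + s, ]
      pars <- param_unflatten(beta, spec)
      P <- detection_matrix(data, pars, spec)
      acc <- acc + Ncube[, , s] * P
    }
    offset <- offset + n_keep
    total <- total + n_keep
  }
  fitted <- acc / total
  obs <- apply(data$y, c(1, 2), mean)

  tidyr::expand_grid(site_id = data$site_ids, year = data$years) |>
    dplyr::mutate(
      x = data$coords[match(.data$site_id, data$site_ids), "x"],
      y = data$coords[match(.data$site_id, data$site_ids), "y"],
      observed = obs[cbind(match(.data$site_id, data$site_ids),
                           match(.data$year, data$years))],
      fitted = fitted[cbind(match(.data$site_id, data$site_ids),
                            match(.data$year, data$years))],
      residual = .data$observed - .data$fitted
    ) |>
    structure(class = c("residual_field", class(tibble::tibble())))
}

# row-standardized spatial weight matrix
spatial_weights <- function(coords, scheme = c("inverse_distance",
                                               "k_nearest"), k = 4) {
  scheme <- match.arg(scheme)
  d <- as.matrix(dist(coords))
  n <- nrow(d)
  if (scheme == "inverse_distance") {
    if (any(d[upper.tri(d)] == 0)) {
      stop("duplicate coordinates are incompatible with inverse-distance weights")
    }
    w <- 1 / d
    diag(w) <- 0
  } else {
    w <- matrix(0, n, n)
    for (i in seq_len(n)) {
      nb <- order(d[i, ])[2:(k + 1)]
      w[i, nb] <- 1
    }
  }
  rs <- rowSums(w)
  if (any(rs == 0)) stop("site with no neighbours under this weight scheme")
  w / rs
}

#' Moran's I spatial autocorrelation statistic
#'
#' `I = (n / S0) * (sum_ij w_ij z_i z_j) / (sum_i z_i^2)` with centred
#' values `z`, zero diagonal and row-standardized weights (`S0` is the total
#' weight). Under the permutation null its expectation is `-1/(n-1)`.
#'
#' @param values Numeric vector (length >= 3, non-constant).
#' @param coords Two-column matrix of site coordinates.
#' @param scheme Weight scheme: `"inverse_distance"` (default) or
#'   `"k_nearest"`.
#' @param k Neighbour count for `"k_nearest"`.
#' @return Moran's I (scalar).
#' @export
morans_i <- function(values, coords, scheme = "inverse_distance", k = 4) {
  values <- as.numeric(values)
  coords <- as.matrix(coords)
  n <- length(values)
  if (n < 3) stop("need at least 3 values")
  if (nrow(coords) != n) stop("coords must have one row per value")
  if (sd(values) == 0) stop("Moran's I is undefined for constant values")
  w <- spatial_weights(coords, scheme, k)
  z <- values - mean(values)
  (n / sum(w)) * as.numeric(t(z) %*% w %*% z) / sum(z^2)
}

#' Permutation test for Moran's I
#'
#' Two-sided test against the spatial-randomness null: values are randomly
#' reassigned to locations `n_perm` times and the p-value is
#' `(1 + #{|I_perm - E[I]| >= |I_obs - E[I]|}) / (n_perm + 1)` with
#' `E[I] = -1/(n-1)`.
#'
#' @inheritParams morans_i
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed.
#' @return A list with `I`, `expected_I`, `p_value`, `n_perm`, `seed`.
#' @export
permutation_test <- function(values, coords, scheme = "inverse_distance",
                             n_perm = 999, seed = 1, k = 4) {
  if (n_perm < 99) stop("use at least 99 permutations")
  I_obs <- morans_i(values, coords, scheme, k)
  n <- length(values)
  e_i <- -1 / (n - 1)
  set.seed(seed)
  w <- spatial_weights(as.matrix(coords), scheme, k)
  z0 <- values - mean(values)
  denom0 <- sum(z0^2)
  s0 <- sum(w)
  stat <- function(z) (n / s0) * as.numeric(t(z) %*% w %*% z) / denom0
  I_perm <- vapply(seq_len(n_perm),
                   function(b) stat(z0[sample.int(n)]), 0)
  p <- (1 + sum(abs(I_perm - e_i) >= abs(I_obs - e_i))) / (n_perm + 1)
  list(I = I_obs, expected_I = e_i, p_value = p, n_perm = n_perm, seed = seed)
}

#' Per-year spatial autocorrelation scan of model residuals
#'
#' Applies the Moran's I permutation test to each year's slice of the
#' residual field. A year with fewer than 3 sites or constant residuals is
#' flagged untestable rather than erroring.
#'
#' @param fit An [run_mcmc()] fit (with latent draws).
#' @param data The fitted [pcount_data()] (defaults to the fit's data).
#' @param n_perm,seed Permutation settings.
#' @param scheme,k Weight scheme, as [morans_i()].
#' @return A tibble of class `moran_scan`: one row per year with columns
#'   `year`, `I`, `expected_I`, `p_value`, `n_sites`, `scheme`, `n_perm`,
#'   `seed`, `status`.
#' @export
residual_scan <- function(fit, data = fit$data, n_perm = 999, seed = 1,
                          scheme = "inverse_distance", k = 4) {
  rf <- fitted_values(fit, data)
  residual_scan_field(rf, n_perm = n_perm, seed = seed, scheme = scheme,
                      k = k)
}

residual_scan_field <- function(rf, n_perm = 999, seed = 1,
                                scheme = "inverse_distance", k = 4) {
  years <- sort(unique(rf$year))
  rows <- purrr::map(years, function(yr) {
    sl <- dplyr::filter(rf, .data$year == yr)
    if (nrow(sl) < 3 || sd(sl$residual) == 0) {
      return(tibble::tibble(year = yr, I = NA_real_,
                            expected_I = NA_real_, p_value = NA_real_,
                            n_sites = nrow(sl), scheme = scheme,
                            n_perm = n_perm, seed = seed,
                            status = "untestable"))
    }
    res <- permutation_test(sl$residual, cbind(sl$x, sl$y), scheme,
                            n_perm = n_perm, seed = seed, k = k)
    tibble::tibble(year = yr, I = res$I, expected_I = res$expected_I,
                   p_value = res$p_value, n_sites = nrow(sl),
                   scheme = scheme, n_perm = n_perm, seed = seed,
                   status = "ok")
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("moran_scan", class(out)))
}
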