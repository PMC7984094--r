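#' Link-scale model components
#'
#' The three linear predictors of the model and the latent transition law.
#' `initial_intensity()` gives the expected initial abundance
#' `psi = exp(b0 + b1 * climate)`; `growth_rate()` gives the per-capita
#' annual growth rate `lambda = exp(...)` including any quadratic or
#' interaction terms the spec carries; `detection_prob()` gives the
#' per-period detection probability on the logit scale.
#'
#' Covariates other than density are assumed already standardized; density is
#' the (latent) abundance in raw count units, so a negative density
#' coefficient is a per-individual decrement of log growth rate — negative
#' density dependence, while a positive one indicates an Allee effect.
#'
#' @param params An [nmix_params()] object.
#' @param climate Scaled climate score (PC1).
#' @return A positive intensity, growth rate, or a probability in (0, 1).
#' @name link-functions
NULL

guard_exp <- function(eta, what) {
  if (any(!is.finite(eta))) stop("non-finite linear predictor for ", what)
  if (any(abs(eta) > 700)) stop("linear predictor overflow for ", what)
  exp(eta)
}

#' @rdname link-functions
#' @export
initial_intensity <- function(params, climate) {
  b <- params$beta_psi
  eta <- b[1] + if (length(b) > 1) b[2] * climate else 0
  guard_exp(eta, "initial abundance")
}

#' @rdname link-functions
#' @param spec An [nmix_spec()] naming the growth-rate terms `params` carries.
#' @param treatment 0/1 playback-treatment indicator.
#' @param density Abundance in the previous year (raw count units).
#' @export
growth_rate <- function(params, spec, climate, treatment = 0, density = 0) {
  b <- params$beta_lambda
  terms <- spec$lambda_terms
  if (length(b) != 1 + length(terms)) {
    stop("beta_lambda length does not match spec terms")
  }
  eta <- b[1]
  k <- 1
  for (tm in terms) {
    k <- k + 1
    eta <- eta + b[k] * switch(tm,
      climate = climate,
      treatment = treatment,
      density = density,
      density2 = density^2,
      climate2 = climate^2,
      `climate:density` = climate * density)
  }
  guard_exp(eta, "growth rate")
}

#' @rdname link-functions
#' @param wind,noise,date,time Scaled survey covariates.
#' @export
detection_prob <- function(params, wind = 0, noise = 0, date = 0, time = 0) {
  b <- params$beta_p
  x <- cbind(1, wind, noise, date, time)[, seq_along(b), drop = FALSE]
  eta <- drop(x %*% b)
  if (any(!is.finite(eta))) stop("non-finite linear predictor for detection")
  plogis(eta)
}

#' Latent abundance transition log-probability
#'
#' `log P(N_t = n_next | N_{t-1} = n_prev)` under the Poisson growth process
#' with mean `n_prev * lam`. A site at zero abundance stays at zero with
#' probability one: extinction is absorbing (the model has no immigration
#' term).
#'
#' @param n_prev,n_next Non-negative integer abundances.
#' @param lam Positive per-capita growth rate.
#' @return Log-probability (`-Inf` allowed).
#' @examples
#' transition_logpmf(0, 0, 2)   # 0: extinction is absorbing
#' transition_logpmf(2, 1, 0.5) # Poisson(1) at 1
#' @export
transition_logpmf <- function(n_prev, n_next, lam) {
  stopifnot(all(n_prev >= 0), all(n_next >= 0), all(lam > 0))
  k <- max(length(n_prev), length(n_next), length(lam))
  n_prev <- rep_len(n_prev, k)
  n_next <- rep_len(n_next, k)
  lam <- rep_len(lam, k)
  out <- dpois(n_next, n_prev * lam, log = TRUE)
  zero <- n_prev == 0
  out[zero] <- ifelse(n_next[zero] == 0, 0, -Inf)
  out
}

#' Cumulative detection probability over repeated periods
#'
#' Probability of detecting an individual at least once in `J` independent
#' survey periods with per-period detection probability `p`:
#' `1 - (1 - p)^J`. With the four 2.5-minute periods of a 10-minute point
#' count this converts the per-period probability into the whole-survey one.
#'
#' @param p Per-period detection probability in `[0, 1]`.
#' @param J Number of periods (positive integer).
#' @return Probability in `[0, 1]`.
#' @examples
#' cumulative_detection(plogis(0.37), 4)
#' @export
cumulative_detection <- function(p, J = 4) {
  stopifnot(all(p >= 0 & p <= 1), J >= 1, J == as.integer(J))
  1 - (1 - p)^J
}

#' Single-site forward marginal log-likelihood
#'
#' Low-level entry to the forward recursion for one site, taking the linear
#' predictors directly: `log_psi` for initial abundance, `eta_lambda` (length
#' `T - 1`) for the growth-rate predictor excluding density terms, and
#' `c_density`/`c_density2` for the coefficients multiplying the latent
#' abundance and its square inside `log(lambda)`. Mainly useful for testing
#' the recursion against direct enumeration on small instances.
#'
#' @param y Integer count matrix, years in rows, periods in columns.
#' @param log_psi Log initial-abundance intensity.
#' @param eta_lambda Numeric vector of length `nrow(y) - 1`.
#' @param p Detection probability matrix, same shape as `y` (or a scalar).
#' @param K Latent truncation bound (`>= max(y)`).
#' @param c_density,c_density2 Density-term coefficients in `log(lambda)`.
#' @return The marginal log-likelihood.
#' @export
forward_marginal_loglik <- function(y, log_psi, eta_lambda, p, K,
                                    c_density = 0, c_density2 = 0) {
  y <- as.matrix(y)
  storage.mode(y) <- "integer"
  if (length(p) == 1) p <- matrix(p, nrow(y), ncol(y))
  stopifnot(length(eta_lambda) == nrow(y) - 1,
            all(dim(p) == dim(y)), all(p >= 0 & p <= 1))
  if (K < max(y)) stop("K is smaller than the maximum observed count")
  forward_loglik_cpp(y, log_psi, as.numeric(eta_lambda), c_density,
                     c_density2, p, as.integer(K))
}

#' Marginal log-likelihood of the point-count data
#'
#' Integrates the latent abundance trajectories out of the hierarchical model
#' exactly (up to truncation at `K`) with a forward recursion over the states
#' `0..K`, at cost `O(T K^2)` per site instead of the `O(K^T)` of naive
#' enumeration. Because the density covariate in the growth rate is the
#' latent abundance itself, the transition kernel row for source state `n`
#' uses `lambda(n)`.
#'
#' `site_marginal_loglik()` returns one site's contribution;
#' `dataset_loglik()` sums over sites (sites are independent given the
#' parameters).
#'
#' @param data A [pcount_data()] object.
#' @param params An [nmix_params()] object.
#' @param spec An [nmix_spec()].
#' @param K Truncation bound for the latent abundance: integer (recycled per
#'   site) or `NULL` for the adaptive rule — max observed count per site plus
#'   a buffer grown until the Poisson tail mass above `K` at every node is
#'   below `1e-8`, capped at 50.
#' @return Log-likelihood (scalar; per-site vector from
#'   `site_logliks()`).
#' @export
dataset_loglik <- function(data, params, spec, K = NULL) {
  sum(site_logliks(data, params, spec, K))
}

#' @rdname dataset_loglik
#' @param site A `site_id` present in the data.
#' @export
site_marginal_loglik <- function(data, site, params, spec, K = NULL) {
  i <- match(site, data$site_ids)
  if (is.na(i)) stop("unknown site: ", site)
  unname(site_logliks(data, params, spec, K)[i])
}

#' @rdname dataset_loglik
#' @export
site_logliks <- function(data, params, spec, K = NULL) {
  stopifnot(inherits(data, "pcount_data"))
  beta <- param_vector(params, spec)
  Kvec <- resolve_K(data, params, spec, K)
  ll <- site_logliks_cpp(data$y, data$climate, data$treat,
                         wp_for_spec(data, spec), spec_flags(spec),
                         beta, Kvec)
  setNames(as.numeric(ll), data$site_ids)
}

# detection covariate cube restricted (in order) to the spec's p terms
wp_for_spec <- function(data, spec) {
  idx <- match(spec$p_terms, dimnames(data$Wp)[[3]])
  if (anyNA(idx)) stop("detection covariates missing from data: ",
                       paste(spec$p_terms[is.na(idx)], collapse = ", "))
  data$Wp[, , idx, drop = FALSE]
}

# per-site truncation bound
resolve_K <- function(data, params, spec, K) {
  max_y <- apply(data$y, 1, max)
  if (!is.null(K)) {
    Kvec <- as.integer(rep_len(K, length(max_y)))
    if (any(Kvec < max_y)) {
      stop("K is smaller than the maximum observed count at some site")
    }
    return(Kvec)
  }
  cap <- 50L
  n <- length(max_y)
  Kvec <- integer(n)
  for (i in seq_len(n)) {
    psi <- initial_intensity(params, data$climate[i])
    Ki <- max(max_y[i], 1L)
    repeat {
      # Poisson means reachable at this truncation: initial intensity and the
      # largest transition mean (source state Ki in any year)
      mus <- psi
      for (t in 2:dim(data$y)[2]) {
        lam <- growth_rate(params, spec, data$climate[i],
                           treatment = data$treat[i, t], density = Ki)
        mus <- c(mus, Ki * lam)
      }
      if (Ki >= cap || all(ppois(Ki, mus, lower.tail = FALSE) < 1e-8)) break
      Ki <- Ki + 1L
    }
    Kvec[i] <- Ki
  }
  Kvec
}

#' Maximum marginal-likelihood fit
#'
#' Direct maximization of the exact marginal likelihood over the coefficient
#' vector (quasi-Newton), independent of the MCMC machinery. Useful as a fast
#' point-estimate cross-check of the Bayesian fit.
#'
#' @inheritParams dataset_loglik
#' @param start Optional start value for the flat coefficient vector.
#' @return A list with `params` ([nmix_params()]), the named coefficient
#'   vector `coef`, the maximized `loglik` and the `optim` convergence code.
#' @export
fit_marginal_ml <- function(data, spec, K = NULL, start = NULL) {
  nms <- param_names(spec)
  start <- start %||% rep(0, length(nms))
  nll <- function(b) {
    p <- param_unflatten(b, spec)
    -tryCatch(dataset_loglik(data, p, spec, K), error = function(e) -Inf)
  }
  opt <- optim(start, nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-10))
  list(params = param_unflatten(opt$par, spec),
       coef = setNames(opt$par, nms),
       loglik = -opt$value, convergence = opt$convergence)
}
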