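# Independent oracles and tiny fixtures, built in code.

# Exhaustive-enumeration marginal likelihood for one site: sums the joint
# probability over every latent trajectory (N_1, ..., N_T) in {0..K}^T.
# Deliberately naive (O(K^T)); the forward recursion must match it.
enum_loglik <- function(y, log_psi, eta_lambda, p, K,
                        c_density = 0, c_density2 = 0) {
  y <- as.matrix(y)
  Tn <- nrow(y)
  if (length(p) == 1) p <- matrix(p, nrow(y), ncol(y))
  states <- 0:K
  grid <- do.call(expand.grid, rep(list(states), Tn))
  total <- -Inf
  for (r in seq_len(nrow(grid))) {
    Ns <- as.integer(grid[r, ])
    lp <- dpois(Ns[1], exp(log_psi), log = TRUE)
    if (Tn > 1) {
      for (t in 2:Tn) {
        np <- Ns[t - 1]
        if (np == 0) {
          lp <- lp + if (Ns[t] == 0) 0 else -Inf
        } else {
          lam <- exp(eta_lambda[t - 1] + c_density * np + c_density2 * np^2)
          lp <- lp + dpois(Ns[t], np * lam, log = TRUE)
        }
      }
    }
    for (t in seq_len(Tn)) {
      lp <- lp + sum(dbinom(y[t, ], Ns[t], p[t, ], log = TRUE))
    }
    if (is.finite(lp)) {
      m <- max(total, lp)
      total <- m + log(exp(total - m) + exp(lp - m))
    }
  }
  total
}

# Random small forward-vs-enumeration instance (T <= 3, K <= 15)
random_instance <- function() {
  Tn <- sample(1:3, 1)
  J <- sample(1:2, 1)
  K <- sample(6:15, 1)
  log_psi <- runif(1, -1.5, 1.5)
  eta_lambda <- runif(max(Tn - 1, 0), -1, 0.7)
  c_density <- runif(1, -0.4, 0.1)
  p <- matrix(runif(Tn * J, 0.2, 0.9), Tn, J)
  y <- matrix(rpois(Tn * J, 1.2), Tn, J)
  y <- pmin(y, K - 1)
  list(y = y, log_psi = log_psi, eta_lambda = eta_lambda,
       c_density = c_density, p = p, K = K)
}

# Direct double-sum Moran's I with an explicit weight matrix
moran_bruteforce <- function(values, w) {
  z <- values - mean(values)
  n <- length(z)
  num <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) num <- num + w[i, j] * z[i] * z[j]
  }
  (n / sum(w)) * num / sum(z^2)
}

# flat coefficient vector in sampler layout (internal helper re-exposed)
param_vector_ok <- function(params, spec) {
  opennmix:::param_vector(params, spec)
}

# Small hand-built dataset: n sites on a line, T years, J periods.
# Counts supplied as an n x T matrix, replicated across periods (or an
# n x T x J array). Covariates vary across surveys so standardization works.
toy_dataset <- function(counts, J = 2, treat_year = NULL) {
  if (length(dim(counts)) == 2) {
    counts <- array(rep(counts, J), c(dim(counts), J))
  }
  n <- dim(counts)[1]; Tn <- dim(counts)[2]
  stopifnot(n >= 3)
  sites <- tibble::tibble(
    site_id = sprintf("t%02d", seq_len(n)),
    x_m = (seq_len(n) - 1) * 500, y_m = 0,
    elevation_m = seq(800, 1400, length.out = n),
    tmean_c = seq(16, 11, length.out = n),
    precip_mm = seq(1900, 2450, length.out = n)
  )
  tab <- tidyr::expand_grid(site_id = sites$site_id,
                            year = seq_len(Tn) + 2013,
                            period = seq_len(J))
  ii <- match(tab$site_id, sites$site_id)
  tt <- tab$year - 2013
  tab$count <- counts[cbind(ii, tt, tab$period)]
  set.seed(42)
  tab$wind <- sample(0:3, nrow(tab), TRUE)
  tab$noise <- sample(0:3, nrow(tab), TRUE)
  tab$jdate <- sample(140:170, nrow(tab), TRUE)
  tab$time_hr <- round(runif(nrow(tab), 6, 11), 2)
  treatment <- NULL
  if (!is.null(treat_year)) {
    treatment <- tibble::tibble(site_id = sites$site_id[1],
                                year = treat_year + 2013, treated = 1L)
  }
  pcount_data(tab, sites, treatment)
}
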