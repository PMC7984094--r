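#' Prior specification for model coefficients
#'
#' Independent normal priors on every coefficient (link scales). The default
#' is diffuse — mean 0, sd 10 — vague relative to any plausible log/logit
#' scale effect while still preventing numerical overflow of the linear
#' predictors.
#'
#' @param mean,sd Scalars, or vectors recycled over coefficients; `sd > 0`.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(mean = 0, sd = 10) {
  stopifnot(is.numeric(mean), is.numeric(sd), all(sd > 0))
  structure(list(mean = mean, sd = sd), class = "prior_spec")
}

#' MCMC configuration
#'
#' `mcmc_config()` is the desk-scale default (3 chains x 20,000 iterations,
#' thin 5, burn-in 2,000 — about 10,800 retained draws).
#' `mcmc_config_long()` is the long-run preset (3 chains x 500,000, thin 20,
#' burn-in 1,000) matching the original analysis scale.
#'
#' @param n_chains,n_iter,thin,burn_in Chain layout; `burn_in < n_iter`,
#'   `thin >= 1`.
#' @param seed Integer seed; mandatory for reproducible fits.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3, n_iter = 20000, thin = 5,
                        burn_in = 2000, seed = 1) {
  stopifnot(n_chains >= 1, thin >= 1, burn_in >= 0, burn_in < n_iter)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 thin = as.integer(thin), burn_in = as.integer(burn_in),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

#' @rdname mcmc_config
#' @export
mcmc_config_long <- function(seed = 1) {
  mcmc_config(n_chains = 3, n_iter = 500000, thin = 20, burn_in = 1000,
              seed = seed)
}

#' Initial sampler state
#'
#' Coefficients start at zero; each latent abundance starts just above its
#' data floor, `N_{i,t} = max_j y_{i,j,t} + 1`, which is always consistent
#' with the observations. Deterministic given the data.
#'
#' @param data A [pcount_data()] object.
#' @param spec An [nmix_spec()].
#' @return A list with `params` ([nmix_params()]) and integer matrix `N`.
#' @export
init_state <- function(data, spec) {
  stopifnot(inherits(data, "pcount_data"), inherits(spec, "nmix_spec"))
  params <- param_unflatten(rep(0, length(param_names(spec))), spec)
  N <- apply(data$y, c(1, 2), max) + 1L
  dimnames(N) <- list(data$site_ids, data$years)
  list(params = params, N = N)
}

# full-conditional log density of N_{i,t} = m given everything else
# (observation terms for year t, transition in, transition out)
latent_conditional <- function(i, t, m, data, N, params, spec, P) {
  Tn <- dim(data$y)[2]
  ll <- sum(dbinom(data$y[i, t, ], m, P[i, t], log = TRUE))
  if (t == 1) {
    ll <- ll + dpois(m, initial_intensity(params, data$climate[i]), log = TRUE)
  } else {
    np <- N[i, t - 1]
    lam <- growth_rate(params, spec, data$climate[i],
                       treatment = data$treat[i, t], density = np)
    ll <- ll + transition_logpmf(np, m, lam)
  }
  if (t < Tn) {
    lam_out <- growth_rate(params, spec, data$climate[i],
                           treatment = data$treat[i, t + 1], density = m)
    ll <- ll + transition_logpmf(m, N[i, t + 1], lam_out)
  }
  ll
}

detection_matrix <- function(data, params, spec) {
  Wp <- wp_for_spec(data, spec)
  n <- dim(Wp)[1]; Tn <- dim(Wp)[2]
  eta <- matrix(params$beta_p[1], n, Tn)
  for (k in seq_along(spec$p_terms)) {
    eta <- eta + params$beta_p[1 + k] * Wp[, , k]
  }
  plogis(eta)
}

#' One Metropolis sweep over the latent abundances
#'
#' Reference (plain R) implementation of the discrete latent update used
#' inside [run_mcmc()]: for each site-year, propose `N' = N +/- 1` reflected
#' at the data floor `max_j y`, and accept by the full-conditional ratio
#' (observation terms plus both adjacent transitions; the transition out of
#' year `t` re-evaluates the growth rate because the density covariate is the
#' latent abundance itself).
#'
#' @param state List with elements `params` and `N` (see [init_state()]).
#' @param data,spec Data and model spec.
#' @return The updated state.
#' @export
update_latent <- function(state, data, spec) {
  N <- state$N
  params <- state$params
  P <- detection_matrix(data, params, spec)
  n <- dim(data$y)[1]; Tn <- dim(data$y)[2]
  floorN <- apply(data$y, c(1, 2), max)
  for (i in seq_len(n)) {
    for (t in seq_len(Tn)) {
      cur <- N[i, t]
      fl <- floorN[i, t]
      prop <- cur + sample(c(-1L, 1L), 1)
      if (prop < fl) prop <- 2L * fl - prop
      if (prop == cur) next
      # Hastings term: both +/-1 proposals from the floor reach floor+1
      lq <- if (cur == fl && prop == fl + 1L) -log(2) else
        if (cur == fl + 1L && prop == fl) log(2) else 0
      l0 <- latent_conditional(i, t, cur, data, N, params, spec, P)
      l1 <- latent_conditional(i, t, prop, data, N, params, spec, P)
      if (is.finite(l1) && log(runif(1)) < l1 - l0 + lq) N[i, t] <- prop
    }
  }
  state$N <- N
  state
}

# block log-likelihoods given the latent state (R reference versions)
block_loglik <- function(block, data, N, params, spec) {
  Tn <- dim(data$y)[2]
  if (block == "psi") {
    return(sum(dpois(N[, 1], initial_intensity(params, data$climate),
                     log = TRUE)))
  }
  if (block == "lambda") {
    s <- 0
    for (t in 2:Tn) {
      lam <- growth_rate(params, spec, data$climate,
                         treatment = data$treat[, t], density = N[, t - 1])
      s <- s + sum(transition_logpmf(N[, t - 1], N[, t], lam))
    }
    return(s)
  }
  P <- detection_matrix(data, params, spec)
  s <- 0
  for (t in seq_len(Tn)) {
    for (j in seq_len(dim(data$y)[3])) {
      s <- s + sum(dbinom(data$y[, t, j], N[, t], P[, t], log = TRUE))
    }
  }
  s
}

#' One random-walk Metropolis pass over the coefficients
#'
#' Reference (plain R) implementation of the per-coefficient update used
#' inside [run_mcmc()], conditioned on the current latent abundances. With
#' `data = NULL` the likelihood is dropped and the target is the prior — a
#' direct check that the sampler recovers its prior with no data.
#'
#' @param state List with `params` and `N`.
#' @param data A [pcount_data()] or `NULL` for a prior-only update.
#' @param spec,prior Model spec and [prior_spec()].
#' @param step Proposal sd, scalar or per-coefficient.
#' @return The updated state, with an `accept` attribute (0/1 per
#'   coefficient).
#' @export
update_betas <- function(state, data, spec, prior = prior_spec(),
                         step = 0.1) {
  nms <- param_names(spec)
  beta <- param_vector(state$params, spec)
  np <- length(beta)
  step <- rep_len(step, np)
  pm <- rep_len(prior$mean, np)
  psd <- rep_len(prior$sd, np)
  blocks <- c(rep("psi", 1 + length(spec$psi_terms)),
              rep("lambda", 1 + length(spec$lambda_terms)),
              rep("p", 1 + length(spec$p_terms)))
  accept <- integer(np)
  for (k in seq_len(np)) {
    ll0 <- if (is.null(data)) 0 else
      block_loglik(blocks[k], data, state$N, param_unflatten(beta, spec), spec)
    prop <- beta
    prop[k] <- beta[k] + step[k] * rnorm(1)
    ll1 <- if (is.null(data)) 0 else
      block_loglik(blocks[k], data, state$N, param_unflatten(prop, spec), spec)
    dprior <- dnorm(prop[k], pm[k], psd[k], log = TRUE) -
      dnorm(beta[k], pm[k], psd[k], log = TRUE)
    if (is.finite(ll1) && log(runif(1)) < ll1 - ll0 + dprior) {
      beta <- prop
      accept[k] <- 1L
    }
  }
  state$params <- param_unflatten(beta, spec)
  attr(state, "accept") <- setNames(accept, nms)
  state
}

#' Fit a dynamic N-mixture model by MCMC
#'
#' Metropolis-within-Gibbs over the latent abundance matrix and the
#' coefficients: each iteration sweeps every `N_{i,t}` with a +/-1 proposal
#' reflected at the data floor, then updates each coefficient by adaptive
#' random-walk Metropolis (step sizes tuned toward a 0.3-0.5 acceptance rate
#' during burn-in only, frozen thereafter). Chains run sequentially from one
#' seeded RNG stream, so a fit is reproducible from its config alone.
#'
#' For WAIC, the per-draw per-site marginal log-likelihoods (latent states
#' integrated out by the forward algorithm) are evaluated at every retained
#' draw unless `pointwise = FALSE`.
#'
#' @param data A [pcount_data()] object.
#' @param spec An [nmix_spec()] (or a formula string for [parse_model()]).
#' @param prior A [prior_spec()].
#' @param config An [mcmc_config()].
#' @param pointwise Compute the draws x sites marginal log-likelihood matrix?
#' @param K Latent truncation bound for the pointwise likelihoods (`NULL` =
#'   adaptive rule at the posterior mean).
#' @return An object of class `nmix_fit`.
#' @export
run_mcmc <- function(data, spec, prior = prior_spec(),
                     config = mcmc_config(), pointwise = TRUE, K = NULL) {
  stopifnot(inherits(data, "pcount_data"))
  if (is.character(spec)) spec <- parse_model(spec)
  stopifnot(inherits(spec, "nmix_spec"), inherits(prior, "prior_spec"),
            inherits(config, "mcmc_config"))
  nms <- param_names(spec)
  np <- length(nms)
  pm <- rep_len(prior$mean, np)
  psd <- rep_len(prior$sd, np)
  Wp <- wp_for_spec(data, spec)
  flags <- spec_flags(spec)

  set.seed(config$seed)
  chains <- vector("list", config$n_chains)
  for (c_ in seq_len(config$n_chains)) {
    chains[[c_]] <- mcmc_chain_cpp(
      data$y, data$climate, data$treat, Wp, flags, pm, psd,
      config$n_iter, config$burn_in, config$thin, TRUE)
    if (any(!is.finite(chains[[c_]]$beta))) {
      stop("divergent linear predictor during sampling; ",
           "check covariate scaling or tighten the prior")
    }
  }

  draws <- do.call(rbind, lapply(chains, `[[`, "beta"))
  colnames(draws) <- nms
  n_keep <- nrow(chains[[1]]$beta)
  fit <- structure(list(
    draws = draws,
    chain = rep(seq_len(config$n_chains), each = n_keep),
    latent = lapply(chains, `[[`, "N"),
    accept_beta = rowMeans(do.call(cbind,
                                   lapply(chains, `[[`, "accept_beta"))),
    accept_latent = mean(vapply(chains, `[[`, 0, "accept_latent")),
    step = lapply(chains, `[[`, "step"),
    spec = spec, prior = prior, config = config, data = data,
    param_names = nms
  ), class = "nmix_fit")

  if (pointwise) {
    post_mean <- param_unflatten(colMeans(draws), spec)
    Kvec <- resolve_K(data, post_mean, spec, K)
    fit$K <- Kvec
    fit$pointwise <- pointwise_loglik_cpp(
      data$y, data$climate, data$treat, Wp, flags, draws, Kvec)
    colnames(fit$pointwise) <- data$site_ids
  }
  fit
}

#' @export
print.nmix_fit <- function(x, ...) {
  cat(sprintf(
    "<nmix_fit> %s\n  %d draws (%d chains); latent acceptance %.2f\n",
    x$spec$label, nrow(x$draws), x$config$n_chains, x$accept_latent))
  print(posterior_summary(x))
  invisible(x)
}

#' Split-chain potential scale reduction factor
#'
#' Gelman-Rubin R-hat per coefficient, computed on chains split in half so
#' within-chain drift also inflates the statistic. Values near 1 indicate the
#' chains mix over the same distribution.
#'
#' @param fit An [run_mcmc()] fit with at least 2 chains, or a draws matrix
#'   plus a `chain` index vector.
#' @param chain Chain index per row, if `fit` is a plain matrix.
#' @return Named numeric vector of R-hat values.
#' @export
gelman_rubin <- function(fit, chain = NULL) {
  if (inherits(fit, "nmix_fit")) {
    draws <- fit$draws; chain <- fit$chain
  } else {
    draws <- as.matrix(fit)
    if (is.null(chain)) stop("chain index required for a plain draws matrix")
  }
  if (length(unique(chain)) < 2) stop("need at least 2 chains for R-hat")
  half <- function(v) {
    n <- length(v) %/% 2
    list(v[seq_len(n)], v[n + seq_len(n)])
  }
  apply(draws, 2, function(v) {
    pieces <- unlist(lapply(split(v, chain), half), recursive = FALSE)
    if (any(lengths(pieces) < 5)) stop("need at least 10 draws per chain")
    m <- length(pieces); n <- min(lengths(pieces))
    pieces <- lapply(pieces, function(p) p[seq_len(n)])
    means <- vapply(pieces, mean, 0)
    vars <- vapply(pieces, var, 0)
    W <- mean(vars)
    B <- n * var(means)
    if (W == 0) return(if (B == 0) 1 else Inf)
    sqrt(((n - 1) / n * W + B / n) / W)
  })
}

#' Posterior summary table
#'
#' Mean, posterior standard deviation and central 95% interval per
#' coefficient, in the conventional reporting layout (`Mean`, `SD`,
#' `Lower CI`, `Upper CI`).
#'
#' @param fit An `nmix_fit`, or any draws matrix with named columns.
#' @return A tibble with one row per coefficient.
#' @export
posterior_summary <- function(fit) {
  draws <- if (inherits(fit, "nmix_fit")) fit$draws else as.matrix(fit)
  if (nrow(draws) < 1) stop("no posterior draws to summarise")
  qs <- t(apply(draws, 2, quantile, probs = c(0.025, 0.975), names = FALSE))
  tibble::tibble(
    Parameter = colnames(draws) %||% paste0("par", seq_len(ncol(draws))),
    Mean = unname(colMeans(draws)),
    SD = unname(apply(draws, 2, sd)),
    `Lower CI` = unname(qs[, 1]),
    `Upper CI` = unname(qs[, 2])
  )
}

#' @export
tidy.nmix_fit <- function(x, ...) {
  s <- posterior_summary(x)
  tibble::tibble(term = s$Parameter, estimate = s$Mean, std.error = s$SD,
                 conf.low = s$`Lower CI`, conf.high = s$`Upper CI`)
}

#' @export
glance.nmix_fit <- function(x, ...) {
  rhat <- tryCatch(max(gelman_rubin(x)), error = function(e) NA_real_)
  w <- if (!is.null(x$pointwise)) waic(x$pointwise) else
    list(waic = NA_real_, lppd = NA_real_, p_waic = NA_real_)
  tibble::tibble(
    model = x$spec$label,
    n_draws = nrow(x$draws),
    n_chains = x$config$n_chains,
    max_rhat = rhat,
    accept_latent = x$accept_latent,
    waic = w$waic, lppd = w$lppd, p_waic = w$p_waic
  )
}
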