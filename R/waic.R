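#' Watanabe-Akaike information criterion
#'
#' Computed from a draws x sites matrix of pointwise posterior log
#' predictive densities (here: marginal site log-likelihoods, latent
#' trajectories integrated out). `lppd = sum_i log mean_s exp(ll_si)` with a
#' stable log-mean-exp; the effective number of parameters is the
#' variance-based form `p_waic = sum_i var_s(ll_si)` (sample variance);
#' `waic = -2 (lppd - p_waic)`, so smaller is better.
#'
#' @param pointwise_loglik Numeric matrix, draws in rows, sites in columns;
#'   at least 2 draws.
#' @return A list with `waic`, `lppd` and `p_waic`.
#' @examples
#' ll <- rbind(log(c(0.5)), log(c(0.25)))
#' waic(ll)
#' @export
waic <- function(pointwise_loglik) {
  ll <- as.matrix(pointwise_loglik)
  if (nrow(ll) < 2) stop("need at least 2 draws for WAIC")
  if (ncol(ll) < 1) stop("need at least 1 site")
  lppd <- sum(apply(ll, 2, log_mean_exp))
  p_waic <- sum(apply(ll, 2, var))
  list(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic)
}

log_mean_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

#' Information-criterion model weights
#'
#' `w_k = exp(-Delta_k / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_k = WAIC_k - min(WAIC)`; invariant to adding a constant to every
#' WAIC. Interpreted as the relative support for each candidate model.
#'
#' @param waic_values Numeric vector of WAIC values (at least one finite).
#' @return Weights summing to 1.
#' @examples
#' model_weights(c(1708.00, 1709.11, 1710.28))
#' @export
model_weights <- function(waic_values) {
  stopifnot(length(waic_values) >= 1)
  if (!any(is.finite(waic_values))) stop("need at least one finite WAIC")
  d <- waic_values - min(waic_values, na.rm = TRUE)
  w <- exp(-d / 2)
  w[!is.finite(w)] <- 0
  w / sum(w)
}

#' Fit and rank a set of candidate models by WAIC
#'
#' Fits every spec in the set with the same data, prior and MCMC
#' configuration (each fit reuses the config seed, so the comparison is
#' reproducible as a whole), computes WAIC from the per-draw marginal site
#' log-likelihoods, and assembles the ranked model table with Delta-WAIC and
#' weights. A fit that errors is kept as a flagged row with `NA` scores
#' rather than aborting the comparison.
#'
#' @param data A [pcount_data()] object.
#' @param model_set List of [nmix_spec()] objects (default:
#'   [build_model_set()]).
#' @param prior,config Shared [prior_spec()] and [mcmc_config()].
#' @return A tibble of class `nmix_model_table`, sorted by WAIC, with
#'   columns `Model`, `WAIC`, `dWAIC`, `Weight`, `p_waic`, `status`; the
#'   fitted objects are attached as attribute `fits`.
#' @export
select_models <- function(data, model_set = build_model_set(),
                          prior = prior_spec(), config = mcmc_config()) {
  stopifnot(length(model_set) >= 1)
  fits <- purrr::map(model_set, function(spec) {
    tryCatch(run_mcmc(data, spec, prior = prior, config = config,
                      pointwise = TRUE),
             error = function(e) structure(list(message = conditionMessage(e)),
                                           class = "nmix_fit_error"))
  })
  rows <- purrr::map2(model_set, fits, function(spec, fit) {
    if (inherits(fit, "nmix_fit_error")) {
      tibble::tibble(Model = spec$label, WAIC = NA_real_, p_waic = NA_real_,
                     status = paste("failed:", fit$message))
    } else {
      w <- waic(fit$pointwise)
      tibble::tibble(Model = spec$label, WAIC = w$waic, p_waic = w$p_waic,
                     status = "ok")
    }
  })
  tab <- dplyr::bind_rows(rows)
  ok <- is.finite(tab$WAIC)
  tab$dWAIC <- tab$WAIC - min(tab$WAIC[ok])
  tab$Weight <- NA_real_
  tab$Weight[ok] <- model_weights(tab$WAIC[ok])
  tab <- dplyr::arrange(tab, .data$WAIC) |>
    dplyr::select("Model", "WAIC", "dWAIC", "Weight", "p_waic", "status")
  structure(tab, class = c("nmix_model_table", class(tab)), fits = fits)
}

#' @export
print.nmix_model_table <- function(x, ...) {
  cat("<nmix_model_table> WAIC model comparison\n")
  NextMethod()
}

#' @export
tidy.nmix_model_table <- function(x, ...) {
  tibble::as_tibble(x)
}
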