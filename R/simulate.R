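#' Generative truth for synthetic datasets
#'
#' Bundles a parameter set, the model spec those parameters belong to, and
#' the covariate-generation settings the simulator draws from. The defaults
#' reproduce the study conditions the package's analyses assume: the
#' top-model posterior means as coefficients, a target temperature by
#' precipitation correlation of -0.9 along the elevation gradient,
#' calm-morning wind/noise scores concentrated at 0-2, and surveys spread
#' over a late-May/June date window between 06:00 and 11:00.
#'
#' @param params An [nmix_params()] object (defaults to the top-model
#'   posterior means).
#' @param spec The [nmix_spec()] the parameters refer to.
#' @param target_cor Target correlation between site temperature and
#'   precipitation normals.
#' @param wind_probs,noise_probs Probabilities over the 0-5 ordinal scores.
#' @param date_window Julian-date survey window (days).
#' @param time_window Start-time window (hours, 24 h clock).
#' @return An object of class `truth_params`.
#' @export
truth_params <- function(params = reference_params(),
                         spec = nmix_spec(
                           lambda_terms = c("climate", "treatment", "density")),
                         target_cor = -0.9,
                         wind_probs = c(0.35, 0.30, 0.20, 0.10, 0.04, 0.01),
                         noise_probs = c(0.35, 0.30, 0.20, 0.10, 0.04, 0.01),
                         date_window = c(135, 181),
                         time_window = c(6, 11)) {
  stopifnot(inherits(params, "nmix_params"), inherits(spec, "nmix_spec"),
            length(wind_probs) == 6, length(noise_probs) == 6,
            target_cor >= -1, target_cor <= 1)
  # make sure lengths agree up front
  param_vector(params, spec)
  structure(list(params = params, spec = spec, target_cor = target_cor,
                 wind_probs = wind_probs / sum(wind_probs),
                 noise_probs = noise_probs / sum(noise_probs),
                 date_window = date_window, time_window = time_window),
            class = "truth_params")
}

#' Top-model coefficient values
#'
#' The posterior-mean coefficients of the best-supported model (climate on
#' initial abundance; climate, treatment and density on growth rate; wind,
#' noise, date and time on detection), used as the default generative truth.
#'
#' @return An [nmix_params()] object.
#' @export
reference_params <- function() {
  nmix_params(
    beta_psi = c(-2.63, -1.56),
    beta_lambda = c(-1.08, -0.75, -1.46, -0.24),
    beta_p = c(0.37, 0.23, -0.57, 0.51, -0.13)
  )
}

#' Generate a study design: survey grid, climate gradient, treatment plan
#'
#' Lays sites on a regular grid whose elevation rises along one axis,
#' generates per-site 30-year temperature and precipitation normals that
#' decrease/increase with elevation with noise calibrated so the realized
#' temperature-precipitation correlation is close to `target_cor`, and
#' assigns the playback treatment plan: `n_treat_y3` previously
#' low-suitability sites treated in year 3 (half from the low-elevation half
#' of the grid, half from the high-elevation half) of which `n_treat_y4`
#' remain treated in year 4.
#'
#' @param seed Integer seed (required: designs are reproducible).
#' @param n_sites Number of survey sites.
#' @param grid_spacing Grid spacing in metres.
#' @param n_years Number of primary periods (years).
#' @param n_periods Count periods per survey.
#' @param elev_range Elevation range in metres.
#' @param n_treat_y3,n_treat_y4 Treated sites in years 3 and 4
#'   (`n_treat_y4 <= n_treat_y3`; treatment never occurs in years 1-2).
#' @param target_cor Target temperature-precipitation correlation.
#' @return An object of class `study_design`: a list with the design
#'   settings, a `sites` tibble (`site_id, x_m, y_m, elevation_m, tmean_c,
#'   precip_mm`) and the site x year 0/1 `treat` matrix.
#' @export
make_design <- function(seed, n_sites = 71, grid_spacing = 500,
                        n_years = 4, n_periods = 4,
                        elev_range = c(800, 1400),
                        n_treat_y3 = 10, n_treat_y4 = 8,
                        target_cor = -0.9) {
  stopifnot(n_sites >= 2, n_years >= 2, n_periods >= 1,
            n_treat_y4 <= n_treat_y3)
  if (n_treat_y3 > n_sites) stop("more treated sites than sites")
  if (n_years < 3 && n_treat_y3 > 0) stop("treatment starts in year 3")
  set.seed(seed)

  ncol_ <- ceiling(sqrt(n_sites))
  idx <- seq_len(n_sites) - 1L
  col <- idx %% ncol_
  row <- idx %/% ncol_
  x <- col * grid_spacing
  y <- row * grid_spacing

  # elevation climbs along the x axis with mild local relief
  frac <- if (max(x) > 0) x / max(x) else rep(0.5, n_sites)
  elev <- elev_range[1] + frac * diff(elev_range) + runif(n_sites, -30, 30)

  # linear climate-elevation trends; noise sd set so that each variable's
  # correlation with elevation is sqrt(|target_cor|), giving
  # cor(tmean, precip) = -|target_cor| in expectation
  slope_t <- -6.5 / 1000            # deg C per m (lapse rate)
  slope_p <- 630 / 930              # mm per m across the local relief
  rho <- sqrt(abs(target_cor))
  noise_fac <- sqrt(1 / rho^2 - 1)
  sd_e <- sd(elev)
  tmean <- 19 - 6.5 * elev / 1000 +
    rnorm(n_sites, 0, abs(slope_t) * sd_e * noise_fac)
  precip <- 1870 + slope_p * (elev - 660) +
    rnorm(n_sites, 0, slope_p * sd_e * noise_fac)
  precip <- pmax(precip, 0)

  sites <- tibble::tibble(
    site_id = sprintf("s%03d", seq_len(n_sites)),
    x_m = x, y_m = y, elevation_m = elev,
    tmean_c = tmean, precip_mm = precip
  )

  treat <- matrix(0, n_sites, n_years)
  if (n_treat_y3 > 0) {
    scores <- climate_pc1(sites)$pc1
    low_half <- elev <= stats::median(elev)
    pick_warmest <- function(group, k) {
      cand <- which(group)
      cand[order(scores[cand], decreasing = TRUE)][seq_len(min(k, length(cand)))]
    }
    n_low <- ceiling(n_treat_y3 / 2)
    chosen <- c(pick_warmest(low_half, n_low),
                pick_warmest(!low_half, n_treat_y3 - n_low))
    chosen <- unique(chosen)[seq_len(min(n_treat_y3, length(unique(chosen))))]
    treat[chosen, 3] <- 1
    if (n_years >= 4 && n_treat_y4 > 0) {
      keep <- sample(chosen, n_treat_y4)
      treat[keep, 4] <- 1
    }
  }

  structure(list(
    n_sites = n_sites, grid_spacing = grid_spacing, n_years = n_years,
    n_periods = n_periods, elev_range = elev_range, seed = seed,
    sites = sites, treat = treat,
    years = 2014:(2013 + n_years)
  ), class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf(
    "<study_design> %d sites on a %d m grid; %d years x %d periods; treated site-years by year: %s\n",
    x$n_sites, x$grid_spacing, x$n_years, x$n_periods,
    paste(colSums(x$treat), collapse = ", ")))
  invisible(x)
}

#' Simulate a point-count dataset from a design and a generative truth
#'
#' Draws the hierarchical model forward: initial abundance
#' `N_1 ~ Poisson(psi_i)` from the climate score, subsequent years
#' `N_t ~ Poisson(N_{t-1} lambda_{i,t-1})` with the truth's growth-rate
#' terms (extinction is absorbing), and counts
#' `y_{i,j,t} ~ Binomial(N_t, p_{i,t})` with detection driven by the drawn
#' survey covariates. The latent abundance matrix is returned alongside the
#' data so recovery studies can score the fit against the truth.
#'
#' @param design A [make_design()] object.
#' @param truth A [truth_params()] object.
#' @param seed Integer seed.
#' @return A list of class `nmix_sim` with elements `data` (a
#'   [pcount_data()]), `latent` (site x year integer matrix `N`), `design`,
#'   `truth` and `seed`.
#' @export
simulate_dataset <- function(design, truth = truth_params(), seed) {
  stopifnot(inherits(design, "study_design"), inherits(truth, "truth_params"))
  set.seed(seed)
  n <- design$n_sites; Tn <- design$n_years; J <- design$n_periods
  years <- design$years

  # survey covariates, one value per site-year, replicated over periods
  wind <- matrix(sample(0:5, n * Tn, TRUE, truth$wind_probs), n, Tn)
  noise <- matrix(sample(0:5, n * Tn, TRUE, truth$noise_probs), n, Tn)
  jdate <- matrix(round(runif(n * Tn, truth$date_window[1],
                              truth$date_window[2])), n, Tn)
  time_hr <- matrix(round(runif(n * Tn, truth$time_window[1],
                                truth$time_window[2]), 2), n, Tn)

  counts <- tidyr::expand_grid(
    site_id = design$sites$site_id, year = years, period = seq_len(J)
  )
  ii <- match(counts$site_id, design$sites$site_id)
  tt <- match(counts$year, years)
  counts$count <- 0L
  counts$wind <- wind[cbind(ii, tt)]
  counts$noise <- noise[cbind(ii, tt)]
  counts$jdate <- jdate[cbind(ii, tt)]
  counts$time_hr <- time_hr[cbind(ii, tt)]

  treatment <- tidyr::expand_grid(site_id = design$sites$site_id,
                                  year = years) |>
    dplyr::mutate(treated = as.integer(
      design$treat[cbind(match(.data$site_id, design$sites$site_id),
                         match(.data$year, years))]))

  shell <- pcount_data(counts, design$sites, treatment)

  # latent dynamics and observation draws on the standardized covariates.
  # Draws use one uniform per variate (inverse CDF), so a counterfactual copy
  # differing only in the treatment plan reuses identical randomness at every
  # unaffected site-year.
  u_N <- matrix(runif(n * Tn), n, Tn)
  u_y <- array(runif(n * Tn * J), c(n, Tn, J))
  pars <- truth$params; spec <- truth$spec
  psi <- initial_intensity(pars, shell$climate)
  N <- matrix(0L, n, Tn, dimnames = list(shell$site_ids, years))
  N[, 1] <- stats::qpois(u_N[, 1], psi)
  for (t in 2:Tn) {
    lam <- growth_rate(pars, spec, shell$climate,
                       treatment = shell$treat[, t], density = N[, t - 1])
    N[, t] <- ifelse(N[, t - 1] == 0L, 0L,
                     stats::qpois(u_N[, t], N[, t - 1] * lam))
  }
  P <- matrix(0, n, Tn)
  for (t in seq_len(Tn)) {
    P[, t] <- detection_prob(pars,
                             wind = shell$Wp[, t, "wind"],
                             noise = shell$Wp[, t, "noise"],
                             date = shell$Wp[, t, "date"],
                             time = shell$Wp[, t, "time"])
  }
  yobs <- array(0L, c(n, Tn, J))
  for (t in seq_len(Tn)) {
    for (j in seq_len(J)) {
      yobs[, t, j] <- stats::qbinom(u_y[, t, j], N[, t], P[, t])
    }
  }
  counts$count <- yobs[cbind(ii, tt, match(counts$period, seq_len(J)))]

  data <- pcount_data(counts, design$sites, treatment)
  structure(list(data = data, latent = N, design = design, truth = truth,
                 seed = seed),
            class = "nmix_sim")
}

#' @export
print.nmix_sim <- function(x, ...) {
  tot <- colSums(x$latent)
  cat(sprintf("<nmix_sim> seed %s; latent totals by year: %s\n",
              x$seed, paste(tot, collapse = ", ")))
  print(x$data)
  invisible(x)
}

#' Simulate the reference scenario
#'
#' Convenience wrapper: default 71-site design plus the top-model
#' posterior-mean truth ([reference_params()]). `n_sites` can be enlarged for
#' recovery studies while keeping everything else at the study conditions.
#'
#' @param seed Integer seed.
#' @param n_sites Number of sites (default 71).
#' @param ... Further overrides passed to [make_design()].
#' @return An `nmix_sim` list, as [simulate_dataset()].
#' @export
simulate_reference <- function(seed, n_sites = 71, ...) {
  design <- make_design(seed = seed, n_sites = n_sites, ...)
  simulate_dataset(design, truth_params(), seed = seed + 1L)
}
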