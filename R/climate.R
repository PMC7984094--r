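#' Centre and scale a numeric vector
#'
#' Centres to mean zero and scales to unit sample standard deviation, keeping
#' the constants used so new values can be placed on the same scale. All model
#' covariates are standardized this way before entering the linear predictors,
#' so coefficients are comparable across covariates.
#'
#' @param values Numeric vector with at least two distinct values.
#' @return Numeric vector with attributes `center` and `scale`.
#' @examples
#' standardize(c(1, 2, 3))
#' @export
standardize <- function(values) {
  stopifnot(is.numeric(values))
  if (length(values) < 2) stop("need at least 2 values to standardize")
  if (anyNA(values)) stop("missing values in input")
  s <- sd(values)
  if (s == 0) stop("cannot standardize a constant (zero-variance) input")
  m <- mean(values)
  structure((values - m) / s, center = m, scale = s)
}

#' Pearson product-moment correlation
#'
#' Thin validation wrapper around [stats::cor()] used when summarising the
#' association between site-level temperature and precipitation normals.
#'
#' @param x,y Numeric vectors of equal length (at least 3), neither constant.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired values")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance input")
  cor(x, y, method = "pearson")
}

#' Principal-component climate gradient
#'
#' Collapses per-site 30-year temperature and precipitation normals into a
#' single climate score: the first principal component of the 2x2 correlation
#' matrix of the standardized variables. Because mean temperature and annual
#' precipitation are strongly anti-correlated along an elevation gradient, one
#' component captures nearly all the variation; its share is
#' `(1 + |r|) / 2` for correlation `r` between the two variables.
#'
#' The sign is fixed so that cooler-and-wetter sites score negative (positive
#' loading on temperature, negative on precipitation), making the orientation
#' deterministic regardless of the eigen-solver.
#'
#' @param climate Data frame with columns `site_id`, `tmean_c` (deg C) and
#'   `precip_mm` (mm/year); one row per site, at least 3 sites.
#' @return An object of class `climate_scores`: a tibble with columns
#'   `site_id` and `pc1`, plus attributes `variance_explained`, `loadings`,
#'   `correlation`, and the `center`/`scale` constants of both inputs.
#' @examples
#' cl <- tibble::tibble(site_id = 1:5, tmean_c = c(16, 15, 14, 13, 12),
#'                      precip_mm = c(1900, 2050, 2150, 2300, 2450))
#' climate_pc1(cl)
#' @export
climate_pc1 <- function(climate) {
  stopifnot(is.data.frame(climate))
  need <- c("site_id", "tmean_c", "precip_mm")
  if (!all(need %in% names(climate))) {
    stop("climate table must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(climate) < 3) stop("need at least 3 sites for a climate gradient")
  if (anyDuplicated(climate$site_id)) stop("duplicate site_id in climate table")
  if (any(climate$precip_mm < 0)) stop("precip_mm must be non-negative")

  zt <- standardize(climate$tmean_c)
  zp <- standardize(climate$precip_mm)
  r <- pearson_correlation(climate$tmean_c, climate$precip_mm)

  R <- matrix(c(1, r, r, 1), 2)
  eig <- eigen(R, symmetric = TRUE)
  v <- eig$vectors[, 1]
  # orient: temperature loading positive, precipitation loading negative;
  # for r >= 0 the sign rule degenerates to temperature-positive
  if (v[1] < 0) v <- -v
  if (r < 0 && v[2] > 0) v <- -v

  scores <- as.numeric(v[1]) * as.numeric(zt) + as.numeric(v[2]) * as.numeric(zp)
  out <- tibble::tibble(site_id = climate$site_id, pc1 = scores)
  structure(out,
    class = c("climate_scores", class(out)),
    variance_explained = eig$values[1] / sum(eig$values),
    loadings = setNames(v, c("tmean_c", "precip_mm")),
    correlation = r,
    center = c(tmean_c = attr(zt, "center"), precip_mm = attr(zp, "center")),
    scale = c(tmean_c = attr(zt, "scale"), precip_mm = attr(zp, "scale"))
  )
}

#' @export
print.climate_scores <- function(x, ...) {
  cat(sprintf(
    "<climate_scores> %d sites; PC1 explains %.1f%% (r = %.3f)\n",
    nrow(x), 100 * attr(x, "variance_explained"), attr(x, "correlation")
  ))
  NextMethod()
}

#' @rdname climate_pc1
#' @param x A `climate_scores` object.
#' @param ... Unused.
#' @export
glance.climate_scores <- function(x, ...) {
  tibble::tibble(
    n_sites = nrow(x),
    variance_explained = attr(x, "variance_explained"),
    correlation = attr(x, "correlation"),
    loading_tmean = attr(x, "loadings")[["tmean_c"]],
    loading_precip = attr(x, "loadings")[["precip_mm"]]
  )
}
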