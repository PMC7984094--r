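#' Assemble a point-count dataset
#'
#' Validates and packs the three study tables into the container the
#' likelihood and sampler work from: a `site x year x period` count array,
#' standardized survey covariates, the per-site climate score (PC1 of the
#' temperature/precipitation normals, re-standardized like every other
#' covariate), the site x year treatment indicator and site coordinates.
#'
#' Survey covariates (wind, noise, date, time) are treated as recorded once
#' per survey: within a site-year they are averaged across periods and
#' broadcast back across the periods in the model.
#'
#' @param counts Data frame with columns `site_id`, `year`, `period`,
#'   `count`, `wind`, `noise`, `jdate`, `time_hr`; one row per site x year x
#'   period, complete design.
#' @param sites Data frame with columns `site_id`, `x_m`, `y_m`,
#'   `elevation_m`, `tmean_c`, `precip_mm`.
#' @param treatment Optional data frame with columns `site_id`, `year`,
#'   `treated` (0/1). Missing rows (or `NULL`) mean untreated.
#' @return An object of class `pcount_data`.
#' @export
pcount_data <- function(counts, sites, treatment = NULL) {
  stopifnot(is.data.frame(counts), is.data.frame(sites))
  need_counts <- c("site_id", "year", "period", "count", "wind", "noise",
                   "jdate", "time_hr")
  need_sites <- c("site_id", "x_m", "y_m", "elevation_m", "tmean_c",
                  "precip_mm")
  miss <- setdiff(need_counts, names(counts))
  if (length(miss)) stop("counts table missing column(s): ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(need_sites, names(sites))
  if (length(miss)) stop("sites table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(sites$site_id)) stop("duplicate site_id in sites table")
  unknown <- setdiff(counts$site_id, sites$site_id)
  if (length(unknown)) stop("counts reference unknown site_id(s): ",
                            paste(head(unknown, 5), collapse = ", "))
  if (any(counts$count < 0)) stop("negative counts are invalid")
  if (any(counts$count != floor(counts$count))) stop("counts must be integers")
  if (any(!counts$wind %in% 0:5) || any(!counts$noise %in% 0:5)) {
    stop("wind and noise must be integers on the 0-5 scale")
  }
  dup_xy <- anyDuplicated(sites[, c("x_m", "y_m")])
  if (dup_xy) stop("duplicate site coordinates")

  site_ids <- sites$site_id
  years <- sort(unique(counts$year))
  periods <- sort(unique(counts$period))
  Tn <- length(years); J <- length(periods)
  if (!identical(as.integer(periods), seq_len(J))) {
    stop("period must take values 1..J")
  }
  n <- length(site_ids)
  if (nrow(counts) != n * Tn * J) {
    stop("counts must contain one row per site x year x period (",
         n * Tn * J, " rows expected, ", nrow(counts), " found)")
  }

  ii <- match(counts$site_id, site_ids)
  tt <- match(counts$year, years)
  jj <- match(counts$period, periods)
  y <- array(NA_integer_, c(n, Tn, J))
  y[cbind(ii, tt, jj)] <- as.integer(counts$count)
  if (anyNA(y)) stop("duplicated or missing site x year x period rows")

  # survey covariates: mean over periods, then standardized across surveys
  raw <- list(wind = counts$wind, noise = counts$noise,
              date = counts$jdate, time = counts$time_hr)
  Wp <- array(NA_real_, c(n, Tn, 4), dimnames = list(NULL, NULL, names(raw)))
  scaling <- list()
  for (v in names(raw)) {
    m <- matrix(0, n, Tn)
    cnt <- matrix(0L, n, Tn)
    for (r in seq_len(nrow(counts))) {
      m[ii[r], tt[r]] <- m[ii[r], tt[r]] + raw[[v]][r]
      cnt[ii[r], tt[r]] <- cnt[ii[r], tt[r]] + 1L
    }
    m <- m / cnt
    z <- standardize(as.numeric(m))
    scaling[[v]] <- c(center = attr(z, "center"), scale = attr(z, "scale"))
    Wp[, , v] <- matrix(as.numeric(z), n, Tn)
  }

  treat <- matrix(0, n, Tn)
  if (!is.null(treatment) && nrow(treatment) > 0) {
    need_tr <- c("site_id", "year", "treated")
    miss <- setdiff(need_tr, names(treatment))
    if (length(miss)) stop("treatment table missing column(s): ",
                           paste(miss, collapse = ", "))
    if (any(!treatment$treated %in% 0:1)) stop("treated must be 0/1")
    ti <- match(treatment$site_id, site_ids)
    if (anyNA(ti)) stop("treatment references unknown site_id(s)")
    ty <- match(treatment$year, years)
    keep <- !is.na(ty)
    treat[cbind(ti[keep], ty[keep])] <- treatment$treated[keep]
  }

  scores <- climate_pc1(sites[, c("site_id", "tmean_c", "precip_mm")])
  zclim <- standardize(scores$pc1)
  scaling$climate <- c(center = attr(zclim, "center"),
                       scale = attr(zclim, "scale"))

  structure(list(
    counts = tibble::as_tibble(counts),
    sites = tibble::as_tibble(sites),
    treatment_table = if (is.null(treatment)) NULL else
      tibble::as_tibble(treatment),
    site_ids = site_ids, years = years, n_periods = J,
    y = y, Wp = Wp, treat = treat,
    climate = as.numeric(zclim),
    climate_scores = scores,
    coords = cbind(x = sites$x_m, y = sites$y_m),
    scaling = scaling
  ), class = "pcount_data")
}

#' @export
print.pcount_data <- function(x, ...) {
  cat(sprintf(
    "<pcount_data> %d sites x %d years x %d periods; %d birds detected; %d treated site-years\n",
    length(x$site_ids), length(x$years), x$n_periods, sum(x$y), sum(x$treat)))
  invisible(x)
}

#' Read a point-count dataset from CSV tables
#'
#' Reads the three comma-delimited tables (`counts.csv`: `site_id, year,
#' period, count, wind, noise, jdate, time_hr`; `sites.csv`: `site_id, x_m,
#' y_m, elevation_m, tmean_c, precip_mm`; optional `treatment.csv`:
#' `site_id, year, treated`) and assembles them with [pcount_data()].
#' An absent treatment table means no site was ever treated.
#'
#' @param counts_path,sites_path,treatment_path File paths; `treatment_path`
#'   may be `NULL` or point to a non-existent file.
#' @return A [pcount_data()] object.
#' @export
read_dataset <- function(counts_path, sites_path, treatment_path = NULL) {
  counts <- readr::read_csv(counts_path, show_col_types = FALSE)
  sites <- readr::read_csv(sites_path, show_col_types = FALSE)
  treatment <- NULL
  if (!is.null(treatment_path) && file.exists(treatment_path)) {
    treatment <- readr::read_csv(treatment_path, show_col_types = FALSE)
  }
  pcount_data(counts, sites, treatment)
}

#' Write a dataset back to the CSV dialects the readers accept
#'
#' @param data A [pcount_data()] object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(data, dir) {
  stopifnot(inherits(data, "pcount_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(dir, "counts.csv"),
             sites = file.path(dir, "sites.csv"),
             treatment = file.path(dir, "treatment.csv"))
  readr::write_csv(data$counts, paths["counts"])
  readr::write_csv(data$sites, paths["sites"])
  tr <- data$treatment_table
  if (is.null(tr)) {
    tr <- tidyr::expand_grid(site_id = data$site_ids, year = data$years) |>
      dplyr::mutate(treated = 0L)
  }
  readr::write_csv(tr, paths["treatment"])
  invisible(paths)
}
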