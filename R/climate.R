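#' Monthly Southern Oscillation Index table
#'
#' Validates a monthly SOI series (Troup-style standardised anomaly of the
#' Tahiti--Darwin pressure difference, stored on the scale whose 12-month
#' means match the covariate axis used throughout the model, not the x10
#' convention). Negative values indicate El Nino conditions, positive
#' La Nina.
#'
#' @param df A data frame with columns `year`, `month` (1--12) and `soi`.
#' @return A validated data frame of class `titi_soi`.
#' @export
monthly_soi <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("year", "month", "soi")
  if (!all(need %in% names(df)))
    stop("SOI table must have columns year, month, soi")
  df <- df[order(df$year, df$month), need]
  if (any(df$month < 1 | df$month > 12))
    stop("SOI months must be in 1..12")
  key <- paste(df$year, df$month)
  if (anyDuplicated(key))
    stop("duplicate year/month rows in SOI table")
  if (any(!is.finite(df$soi)))
    stop("non-finite SOI values")
  df$year <- as.integer(df$year)
  df$month <- as.integer(df$month)
  class(df) <- c("titi_soi", "data.frame")
  df
}

# fast lookup of one monthly value; errors naming the missing month
soi_value <- function(soi, year, month) {
  i <- which(soi$year == year & soi$month == month)
  if (length(i) != 1L)
    stop(sprintf("SOI value missing for %04d-%02d", year, month))
  soi$soi[i]
}

# mean of 12 monthly values starting at (year, month)
soi_window_mean <- function(soi, year, month) {
  months <- (month - 1L + 0:11) %% 12L + 1L
  years  <- year + ((month - 1L + 0:11) %/% 12L)
  vals <- numeric(12L)
  for (j in 1:12) vals[j] <- soi_value(soi, years[j], months[j])
  mean(vals)
}

#' Annual survival covariate
#'
#' The survival covariate for model year `t` is the arithmetic mean of the
#' 12 monthly SOI values from April of calendar year `1975 + t` (the year
#' whose census, on 31 March of `1976 + t`, closes the survival interval)
#' through the following March. This is the period over which annual
#' survival is measured.
#'
#' @param soi A [monthly_soi()] table.
#' @param t Model year (t = 1 is 1976); the index may run from 0 to 31 to
#'   support lagged models.
#' @return The 12-month mean (scalar).
#' @export
survival_covariate <- function(soi, t) {
  soi_window_mean(soi, 1975L + as.integer(t), 4L)
}

#' Annual fecundity covariate
#'
#' The fecundity covariate for model year `t` is the mean of the 12 monthly
#' SOI values from October of calendar year `1974 + t` (just before the
#' onset of egg-laying for the season whose chicks are censused on 31 March
#' of `1975 + t + 1`) through the following September.
#'
#' @inheritParams survival_covariate
#' @return The 12-month mean (scalar).
#' @export
fecundity_covariate <- function(soi, t) {
  soi_window_mean(soi, 1974L + as.integer(t), 10L)
}

#' Annual climate covariates for the assessment period
#'
#' Computes the survival covariate for model years `t_s` and the fecundity
#' covariate for model years `t_f`. The default index ranges cover every
#' value a lag between -2 and +1 can require for model years 1--30.
#'
#' @param soi A [monthly_soi()] table.
#' @param t_s Model-year indices for the survival covariate.
#' @param t_f Model-year indices for the fecundity covariate.
#' @return An object of class `titi_covariates` with fields `z_s`, `t_s`,
#'   `z_f`, `t_f` and the observed ranges over model years 1--30.
#' @export
annual_covariates <- function(soi, t_s = -1:32, t_f = -2:31) {
  z_s <- vapply(t_s, function(t) survival_covariate(soi, t), numeric(1))
  z_f <- vapply(t_f, function(t) fecundity_covariate(soi, t), numeric(1))
  obs_s <- z_s[t_s >= 1 & t_s <= 30]
  obs_f <- z_f[t_f >= 1 & t_f <= 30]
  structure(
    list(z_s = z_s, t_s = as.integer(t_s), z_f = z_f, t_f = as.integer(t_f),
         range_s = range(obs_s), range_f = range(obs_f)),
    class = "titi_covariates")
}

# covariate value at model year t (vectorised over t)
covariate_at <- function(z, t_index, t) {
  i <- match(t, t_index)
  if (anyNA(i))
    stop(sprintf("covariate not available for model year(s) %s",
                 paste(t[is.na(i)], collapse = ", ")))
  z[i]
}

#' Apply a model's climate lags to the annual covariates
#'
#' An `S-1` model drives survival in year `t - 1` with the survival
#' covariate of year `t`; equivalently, survival in year `t` is driven by
#' the covariate of year `t + 1`. An `S+1` model drives survival in year
#' `t + 1` with the covariate of year `t`, so year `t` is driven by the
#' covariate of year `t - 1`. Fecundity lags are defined analogously. A
#' missing lag (`NA`) means the corresponding rate is constant over time
#' and no driver is produced for that axis.
#'
#' @param cov A [annual_covariates()] object.
#' @param spec A [model_spec()].
#' @return A list with `zs_drive` and `zf_drive` (numeric vectors indexed
#'   by model year 1--30, or `NULL` for a constant-rate axis) plus the lags.
#' @export
apply_lags <- function(cov, spec) {
  t <- 1:30
  zs <- if (is.na(spec$lag_s)) NULL else
    covariate_at(cov$z_s, cov$t_s, t - spec$lag_s)
  zf <- if (is.na(spec$lag_f)) NULL else
    covariate_at(cov$z_f, cov$t_f, t - spec$lag_f)
  list(zs_drive = zs, zf_drive = zf, lag_s = spec$lag_s, lag_f = spec$lag_f)
}
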