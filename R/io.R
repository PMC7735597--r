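# CSV schemas shared by the analysis scripts. All floating-point output is
# written with 17 significant digits so reruns are bitwise comparable.

fmt17 <- function(x) {
  if (is.numeric(x)) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  else x
}

write_csv17 <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt17), stringsAsFactors = FALSE)
  names(out) <- names(df)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a monthly SOI table (`year,month,soi`)
#' @param path CSV path.
#' @return A [monthly_soi()] table.
#' @export
read_soi_csv <- function(path) monthly_soi(utils::read.csv(path))

#' Write a monthly SOI table
#' @param soi A [monthly_soi()] table.
#' @param path CSV path.
#' @export
write_soi_csv <- function(soi, path) write_csv17(as.data.frame(soi), path)

#' Read a forcing table (`year,harvest,bycatch`, calendar years 1976-2004)
#' @param path CSV path.
#' @return A [forcing_series()].
#' @export
read_forcing_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("year", "harvest", "bycatch")
  if (!all(need %in% names(df)))
    stop("forcing file must have columns year, harvest, bycatch")
  df <- df[order(df$year), ]
  if (!identical(as.integer(df$year), 1976:2004))
    stop("forcing file must cover calendar years 1976-2004, one row each")
  forcing_series(df$harvest, df$bycatch)
}

#' Write a forcing table
#' @param forcing A [forcing_series()].
#' @param path CSV path.
#' @export
write_forcing_csv <- function(forcing, path) {
  write_csv17(data.frame(year = 1976:2004, harvest = forcing$H,
                         bycatch = forcing$B), path)
}

#' Read a CPUE table (`year,cpue`)
#' @param path CSV path.
#' @return Data frame ready for [observation_data()].
#' @export
read_cpue_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("year", "cpue") %in% names(df)))
    stop("CPUE file must have columns year, cpue")
  df
}

#' Write a CPUE table
#' @param cpue Data frame with `year`, `cpue`.
#' @param path CSV path.
#' @export
write_cpue_csv <- function(cpue, path) {
  write_csv17(cpue[, c("year", "cpue")], path)
}

#' Write the annual covariates for audit (`year,z_s,z_f`)
#' @param cov A [annual_covariates()] object.
#' @param path CSV path.
#' @export
write_covariates_csv <- function(cov, path) {
  t <- 1:30
  write_csv17(data.frame(year = model_year_to_calendar(t),
                         z_s = covariate_at(cov$z_s, cov$t_s, t),
                         z_f = covariate_at(cov$z_f, cov$t_f, t)),
              path)
}

#' Write a trajectory in wide format
#' @param traj A `titi_trajectory`.
#' @param path CSV path.
#' @export
write_trajectory_csv <- function(traj, path) {
  nT <- length(traj$N)
  df <- data.frame(year = traj$years, t(traj$n))
  names(df) <- c("year", paste0("n", 0:14))
  df$N <- traj$N
  df$N_adult <- traj$N_a
  df$s_a <- c(traj$s_a, NA)[seq_len(nT)]
  df$s_j <- c(traj$s_j, NA)[seq_len(nT)]
  df$f <- traj$f
  df$b_rate <- c(traj$b, NA)[seq_len(nT)]
  df$h_rate <- c(traj$h, NA)[seq_len(nT)]
  write_csv17(df, path)
}

#' Write retained posterior draws (one row per draw)
#' @param fitobj A `titi_fit`.
#' @param path CSV path.
#' @export
write_draws_csv <- function(fitobj, path) {
  df <- as.data.frame(fitobj$draws)
  df$chain <- fitobj$chain
  df$lp <- fitobj$lp
  write_csv17(df, path)
}

#' Write a model-selection table (`model,W,delta_w,weight`)
#' @param wtab A [waic_table()].
#' @param path CSV path.
#' @export
write_waic_csv <- function(wtab, path) write_csv17(wtab, path)

#' Write a truth record as JSON
#' @param truth A [generate_truth()] record.
#' @param path JSON path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(params = as.list(truth$params), model = truth$spec$name,
         harvest_frac = truth$harvest_frac,
         bycatch_rate = truth$bycatch_rate,
         N = truth$trajectory$N, N_a = truth$trajectory$N_a,
         n0 = truth$trajectory$n[1, ],
         s_a = truth$trajectory$s_a, s_j = truth$trajectory$s_j,
         f = truth$trajectory$f, years = truth$trajectory$years),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Validate an input-file bundle
#'
#' Schema- and coverage-checks the raw files of a run before any compute:
#' column names, forcing span, the CPUE-year whitelist, and that the SOI
#' table covers every month the most extreme requested lag needs. Each
#' violation is reported with the file and rule.
#'
#' @param soi_file,forcing_file,cpue_file CSV paths.
#' @param specs List of [model_spec()]s the run will fit.
#' @param constants A [fixed_constants()] object.
#' @return A validated list (`soi`, `covariates`, `forcing`, `cpue`)
#'   ready for [observation_data()] / [assessment_inputs()].
#' @export
validate_inputs <- function(soi_file, forcing_file, cpue_file,
                            specs = list(model_spec()),
                            constants = fixed_constants()) {
  for (f in c(soi_file, forcing_file, cpue_file))
    if (!file.exists(f)) stop(sprintf("input file not found: %s", f))
  soi <- tryCatch(read_soi_csv(soi_file), error = function(e)
    stop(sprintf("%s: %s", soi_file, conditionMessage(e))))
  forcing <- tryCatch(read_forcing_csv(forcing_file), error = function(e)
    stop(sprintf("%s: %s", forcing_file, conditionMessage(e))))
  cpue <- tryCatch(read_cpue_csv(cpue_file), error = function(e)
    stop(sprintf("%s: %s", cpue_file, conditionMessage(e))))
  bad <- setdiff(cpue$year, CPUE_YEARS)
  if (length(bad) > 0)
    stop(sprintf("%s: CPUE year(s) %s violate the 1979-92/1994-98 whitelist",
                 cpue_file, paste(sort(bad), collapse = ", ")))
  lags_s <- vapply(specs, function(s) s$lag_s, integer(1))
  lags_f <- vapply(specs, function(s) s$lag_f, integer(1))
  t_s <- unique(unlist(lapply(lags_s[!is.na(lags_s)],
                              function(l) 1:30 - l)))
  t_f <- unique(unlist(lapply(lags_f[!is.na(lags_f)],
                              function(l) 1:30 - l)))
  cov <- tryCatch(
    annual_covariates(soi,
                      t_s = if (length(t_s)) sort(t_s) else 0:31,
                      t_f = if (length(t_f)) sort(t_f) else -1:30),
    error = function(e)
      stop(sprintf("%s: insufficient SOI span: %s", soi_file,
                   conditionMessage(e))))
  list(soi = soi, covariates = cov, forcing = forcing, cpue = cpue)
}
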