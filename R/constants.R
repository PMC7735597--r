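#' Fixed constants of the population model
#'
#' Bundles the quantities that are fixed inputs rather than estimated
#' parameters: the maximum potential adult survival and fecundity that cap
#' the logistic climate links, the regional weka depredation probability,
#' and the dimensions of the age-structured model.
#'
#' The model has 15 age classes (0--14): class 0 is fully grown chicks at a
#' post-breeding census on 31 March, class 14 is a recycling "plus group".
#' Model year `t = 1` is the 1976 breeding season and `t = 30` is 2005, so a
#' trajectory has 29 annual transitions.
#'
#' @param s_max_a Maximum potential adult survival (default 0.98, from
#'   allometric considerations for a conservative cap).
#' @param f_max Maximum fecundity, chicks per adult on 1 April (default 0.9,
#'   just above the product of the largest observed egg-laying probability
#'   and egg-to-chick survival in the congeneric short-tailed shearwater).
#' @param w Probability that a breeding attempt fails to weka depredation
#'   (default 0.11, the regional rate).
#' @param n_ages Number of age classes (15).
#' @param n_years Number of model years (30; 1976--2005).
#' @param run_in_years Length of the pre-model run-in used to equilibrate
#'   the age structure (5).
#' @return An object of class `titi_constants`.
#' @export
fixed_constants <- function(s_max_a = 0.98, f_max = 0.9, w = 0.11,
                            n_ages = 15L, n_years = 30L, run_in_years = 5L) {
  stopifnot(s_max_a > 0, s_max_a < 1, f_max > 0, f_max <= 1, w >= 0, w < 1,
            n_ages == 15L, n_years >= 2L, run_in_years >= 0L)
  structure(
    list(s_max_a = s_max_a, f_max = f_max, w = w,
         n_ages = as.integer(n_ages), n_years = as.integer(n_years),
         run_in_years = as.integer(run_in_years)),
    class = "titi_constants")
}

# calendar year of model year t (t = 1 is 1976)
model_year_to_calendar <- function(t) 1975L + as.integer(t)

# model year of a calendar year
calendar_to_model_year <- function(year) as.integer(year) - 1975L

# model-year windows over which the auxiliary vital-rate estimates apply
WINDOW_ADULT    <- 21:29          # calendar 1996-2004
WINDOW_FECUND   <- c(22:24, 28:30) # calendar 1997-99 and 2003-05
WINDOW_JUVENILE <- 21:28          # calendar 1996-2003

# calendar years with usable CPUE (Rama-period harvest diaries)
CPUE_YEARS <- c(1979:1992, 1994:1998)
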