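#' Model parameters for the tumor-immune dynamics
#'
#' Constructs and validates the rate constants of the discrete-time
#' tumor-immune model.  The state variable is the coronal cross-section area
#' of the tumor in mm^2 (the fitted observable), not cell number.
#'
#' The packaged defaults are the calibrated parameter set shipped with the
#' package: under the default five-arm design they place the untreated
#' control at 38.9 mm^2 on day 18 and give deterministic threshold-crossing
#' (100 mm^2) survival times of 27 days for controls and 60 days for the
#' combined 1-MT + two-fraction (7-day interval) arm.
#'
#' @param a Gompertz growth rate (per day, >= 0).
#' @param K Carrying capacity (mm^2 of coronal cross-section, > 0).
#' @param C0 Initial tumor size at day 0 (mm^2, > 0 and < K).
#' @param alpha Linear-quadratic linear radiosensitivity (per Gy, >= 0).
#' @param beta Linear-quadratic quadratic radiosensitivity (per Gy^2, >= 0).
#'   The default keeps the conventional beta/alpha ratio of 0.1 per Gy.
#' @param gamma Immune-stimulation retention per day, in [0, 1).  The
#'   stimulation level decays geometrically by this factor every day.
#' @param mu Immune kill efficiency (per unit stimulation per day, >= 0).
#' @param sigma 1-MT potentiation factor (dimensionless, >= 0).  On days the
#'   drug is active the immune kill rate is multiplied by (1 + sigma).
#' @return An object of class \code{"model_params"}: a named numeric vector
#'   with the eight parameters above.
#' @examples
#' p <- model_params()
#' p["K"]
#' @export
model_params <- function(a = 0.1, K = 200, C0 = 0.01,
                         alpha = 0.2, beta = 0.02,
                         gamma = 0.94, mu = 0.38, sigma = 0.3) {
  p <- c(a = a, K = K, C0 = C0, alpha = alpha, beta = beta,
         gamma = gamma, mu = mu, sigma = sigma)
  validate_model_params(p)
  class(p) <- "model_params"
  p
}

#' @keywords internal
validate_model_params <- function(p) {
  needed <- c("a", "K", "C0", "alpha", "beta", "gamma", "mu", "sigma")
  if (!all(needed %in% names(p)))
    stop("model parameters must contain: ", paste(needed, collapse = ", "))
  p <- p[needed]
  if (any(!is.finite(p)))
    stop("model parameters must be finite")
  if (p["a"] < 0)       stop("growth rate 'a' must be >= 0")
  if (p["K"] <= 0)      stop("carrying capacity 'K' must be > 0")
  if (p["C0"] <= 0)     stop("initial size 'C0' must be > 0")
  if (p["C0"] >= p["K"]) stop("initial size 'C0' must be below the carrying capacity 'K'")
  if (p["alpha"] < 0)   stop("radiosensitivity 'alpha' must be >= 0")
  if (p["beta"] < 0)    stop("radiosensitivity 'beta' must be >= 0")
  if (p["gamma"] < 0 || p["gamma"] >= 1)
    stop("immune retention 'gamma' must lie in [0, 1)")
  if (p["mu"] < 0)      stop("immune kill efficiency 'mu' must be >= 0")
  if (p["sigma"] < 0)   stop("potentiation factor 'sigma' must be >= 0")
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Tumor-immune model parameters:\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Treatment schedule for one experimental arm
#'
#' Radiotherapy is given as whole-day events (day, dose in Gy); the IDO1
#' inhibitor 1-methyl-tryptophan (1-MT) is active on a set of whole days.
#' Day 0 is the day of tumor inoculation, and an event on day d takes effect
#' within the update that produces the day-d state.
#'
#' @param rt_days Integer days (>= 0) of the radiotherapy fractions.
#' @param rt_dose Dose per fraction in Gy (> 0); either one value recycled
#'   over all fractions or one value per fraction.
#' @param mt_days Integer days on which 1-MT is active.
#' @return An object of class \code{"treatment_schedule"}: a list with
#'   \code{rt_events} (data frame with columns \code{day}, \code{dose}) and
#'   \code{mt_days} (integer vector).
#' @examples
#' # 8 Gy on days 7 and 14, 1-MT on days 7..16 (the combined long-interval arm)
#' treatment_schedule(rt_days = c(7, 14), rt_dose = 8, mt_days = 7:16)
#' @export
treatment_schedule <- function(rt_days = integer(0), rt_dose = 8,
                               mt_days = integer(0)) {
  rt_days <- as.integer(rt_days)
  mt_days <- sort(unique(as.integer(mt_days)))
  if (length(rt_days)) {
    if (any(rt_days < 0)) stop("radiotherapy days must be >= 0")
    if (anyDuplicated(rt_days)) stop("radiotherapy days must be unique")
    dose <- rep_len(as.numeric(rt_dose), length(rt_days))
    if (any(dose <= 0)) stop("dose per fraction must be > 0")
  } else {
    dose <- numeric(0)
  }
  if (length(mt_days) && any(mt_days < 0)) stop("1-MT days must be >= 0")
  structure(list(rt_events = data.frame(day = rt_days, dose = dose),
                 mt_days = mt_days),
            class = "treatment_schedule")
}

#' @export
print.treatment_schedule <- function(x, ...) {
  if (nrow(x$rt_events) == 0) {
    cat("RT: none\n")
  } else {
    cat("RT: ", paste(sprintf("%g Gy @ day %d", x$rt_events$dose,
                              x$rt_events$day), collapse = ", "), "\n", sep = "")
  }
  if (length(x$mt_days)) {
    cat("1-MT active days: ", paste(range(x$mt_days), collapse = "-"),
        " (", length(x$mt_days), " days)\n", sep = "")
  } else {
    cat("1-MT: none\n")
  }
  invisible(x)
}

#' The five treatment arms of the fractionation study
#'
#' Control; 1-MT only; 1-MT + one 8 Gy fraction on day 7; 1-MT + two 8 Gy
#' fractions on days 7 and 11 (short interval); 1-MT + two fractions on days
#' 7 and 14 (long interval).  1-MT runs for 10 days starting on day 7 in all
#' drug-containing arms.
#'
#' @param dose Dose per fraction in Gy (default 8).
#' @param mt_days Days on which 1-MT is active (default 7..16).
#' @return Named list of \code{\link{treatment_schedule}} objects with names
#'   \code{control}, \code{mt}, \code{mt_rt1}, \code{mt_rt2_short},
#'   \code{mt_rt2_long}.
#' @examples
#' names(default_arms())
#' @export
default_arms <- function(dose = 8, mt_days = 7:16) {
  list(
    control      = treatment_schedule(),
    mt           = treatment_schedule(mt_days = mt_days),
    mt_rt1       = treatment_schedule(rt_days = 7, rt_dose = dose,
                                      mt_days = mt_days),
    mt_rt2_short = treatment_schedule(rt_days = c(7, 11), rt_dose = dose,
                                      mt_days = mt_days),
    mt_rt2_long  = treatment_schedule(rt_days = c(7, 14), rt_dose = dose,
                                      mt_days = mt_days)
  )
}
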