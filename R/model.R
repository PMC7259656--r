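#' One Gompertz growth step
#'
#' Advances the tumor cross-section area by \code{dt} days under Gompertz
#' growth dC/dt = a C ln(K/C), using the exact one-step solution
#' C' = K (C/K)^exp(-a dt).
#'
#' @param C Current area (mm^2, > 0).
#' @param a Growth rate (per day, >= 0).
#' @param K Carrying capacity (mm^2, > 0).
#' @param dt Time step in days (>= 0, default 1).
#' @return The area after \code{dt} days (mm^2).
#' @examples
#' gompertz_step(1, a = 0.1, K = 100)    # 1.550
#' gompertz_step(50, a = 0.2, K = 50)    # fixed point at K
#' @export
gompertz_step <- function(C, a, K, dt = 1) {
  if (any(C <= 0)) stop("tumor area 'C' must be > 0")
  if (K <= 0) stop("carrying capacity 'K' must be > 0")
  if (a < 0) stop("growth rate 'a' must be >= 0")
  if (dt < 0) stop("time step 'dt' must be >= 0")
  K * (C / K)^exp(-a * dt)
}

#' Linear-quadratic cell survival
#'
#' Surviving fraction after a single radiation fraction of dose d Gy,
#' S(d) = exp(-alpha d - beta d^2).
#'
#' @param dose Dose in Gy (>= 0).
#' @param alpha Linear coefficient (per Gy).
#' @param beta Quadratic coefficient (per Gy^2).
#' @return Surviving fraction in (0, 1].
#' @examples
#' lq_survival(8, alpha = 0.2, beta = 0.02)  # 0.0561
#' @export
lq_survival <- function(dose, alpha, beta) {
  if (any(dose < 0)) stop("dose must be >= 0")
  exp(-alpha * dose - beta * dose^2)
}

#' One day of tumor-immune dynamics
#'
#' Applies, in order: (1) Gompertz growth over one day; (2) if a dose is
#' given, linear-quadratic kill, with the killed area recruited as immune
#' stimulation; (3) geometric decay of the immune stimulation level (decay
#' before adding the new recruitment); (4) immune-mediated kill
#' C <- C exp(-mu (1 + sigma u) I), where u = 1 on 1-MT-active days.
#'
#' @param state List with elements \code{day} (integer), \code{C} (area,
#'   mm^2) and \code{I} (immune stimulation, same units as C).
#' @param params A \code{\link{model_params}} object.
#' @param dose Radiation dose given this day in Gy (default 0 = none).
#' @param mt_active Logical: is 1-MT active this day?
#' @return The state one day later (list with \code{day}, \code{C}, \code{I}).
#' @examples
#' s <- list(day = 0, C = 10, I = 0)
#' daily_update(s, model_params(a = 0), dose = 8)
#' @export
daily_update <- function(state, params, dose = 0, mt_active = FALSE) {
  params <- validate_model_params(params)
  if (dose < 0) stop("dose must be >= 0")
  if (!is.list(state) || is.null(state$C) || is.null(state$I))
    stop("state must be a list with elements day, C and I")
  if (state$C < 0 || state$I < 0) stop("state C and I must be >= 0")

  C <- state$C
  I <- state$I
  # (1) growth (a size of exactly zero stays zero: extinct tumor)
  if (C > 0) C <- gompertz_step(C, params[["a"]], params[["K"]], 1)
  # (2) radiation kill and recruitment
  R <- 0
  if (dose > 0) {
    S <- lq_survival(dose, params[["alpha"]], params[["beta"]])
    R <- C * (1 - S)
    C <- C * S
  }
  # (3) immune stimulation: decay, then add today's recruitment
  I <- params[["gamma"]] * I + R
  # (4) immune-mediated kill, potentiated by 1-MT
  u <- as.numeric(isTRUE(as.logical(mt_active)))
  C <- C * exp(-params[["mu"]] * (1 + params[["sigma"]] * u) * I)

  list(day = state$day + 1L, C = C, I = I)
}

# Fast internal simulator: doses and 1-MT activity precomputed per day.
# doses[d], mt[d] refer to the update producing the day-d state.
sim_core <- function(p, doses, mt, horizon) {
  a <- p[["a"]]; K <- p[["K"]]
  alpha <- p[["alpha"]]; beta <- p[["beta"]]
  gamma <- p[["gamma"]]; mu <- p[["mu"]]; sigma <- p[["sigma"]]
  ea <- exp(-a)
  C <- p[["C0"]]; I <- 0
  Cs <- numeric(horizon + 1L); Is <- numeric(horizon + 1L)
  Cs[1L] <- C
  if (horizon > 0L) for (d in seq_len(horizon)) {
    C <- K * (C / K)^ea
    dose <- doses[d]
    if (dose > 0) {
      S <- exp(-alpha * dose - beta * dose * dose)
      R <- C * (1 - S)
      C <- C * S
    } else R <- 0
    I <- gamma * I + R
    C <- C * exp(-mu * (1 + sigma * mt[d]) * I)
    Cs[d + 1L] <- C
    Is[d + 1L] <- I
  }
  list(C = Cs, I = Is)
}

# Expand a treatment_schedule into per-day dose and 1-MT vectors.
schedule_vectors <- function(schedule, horizon) {
  if (!inherits(schedule, "treatment_schedule"))
    stop("'schedule' must be a treatment_schedule object")
  doses <- numeric(horizon)
  ev <- schedule$rt_events
  if (nrow(ev)) {
    if (any(ev$day > horizon))
      stop("radiotherapy day ", max(ev$day), " lies beyond the horizon ", horizon)
    # day-0 events act within the update producing day 1 would be wrong;
    # an event on day d acts in the update producing the day-d state, so a
    # day-0 event cannot act (there is no update producing day 0).
    if (any(ev$day == 0))
      stop("radiotherapy on day 0 is not representable (day 0 is the initial state)")
    doses[ev$day] <- doses[ev$day] + ev$dose
  }
  mt <- numeric(horizon)
  md <- schedule$mt_days[schedule$mt_days >= 1 & schedule$mt_days <= horizon]
  mt[md] <- 1
  list(doses = doses, mt = mt)
}

#' Simulate the tumor-immune dynamics for one treatment arm
#'
#' Deterministic daily simulation from day 0 (initial state C = C0, I = 0)
#' to the horizon, applying \code{\link{daily_update}} once per day with the
#' arm's radiotherapy doses and 1-MT activity.
#'
#' @param params A \code{\link{model_params}} object.
#' @param schedule A \code{\link{treatment_schedule}}; all radiotherapy days
#'   must lie within the horizon.
#' @param horizon Last simulated day (integer >= 0).
#' @return A data frame of class \code{"tumor_trajectory"} with columns
#'   \code{day} (0..horizon), \code{C} (tumor area, mm^2) and \code{I}
#'   (immune stimulation level).
#' @examples
#' tr <- simulate_tumor(model_params(), default_arms()$control, horizon = 18)
#' tr$C[tr$day == 18]  # 38.9 mm^2
#' @export
simulate_tumor <- function(params, schedule = treatment_schedule(),
                           horizon = 18) {
  params <- validate_model_params(params)
  horizon <- as.integer(horizon)
  if (horizon < 0) stop("horizon must be >= 0")
  sv <- schedule_vectors(schedule, horizon)
  out <- sim_core(params, sv$doses, sv$mt, horizon)
  traj <- data.frame(day = 0:horizon, C = out$C, I = out$I)
  class(traj) <- c("tumor_trajectory", "data.frame")
  traj
}

#' @export
plot.tumor_trajectory <- function(x, log = "", ...) {
  graphics::plot(x$day, x$C, type = "l", xlab = "day post inoculation",
                 ylab = expression(tumor ~ area ~ (mm^2)), log = log, ...)
  invisible(x)
}

#' Write a simulated trajectory to CSV
#'
#' @param traj A trajectory from \code{\link{simulate_tumor}}.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj)[, c("day", "C", "I")], path,
                   row.names = FALSE)
  invisible(path)
}
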