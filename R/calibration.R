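#' One treatment group's observations for calibration
#'
#' @param label Group label.
#' @param schedule The group's \code{\link{treatment_schedule}}.
#' @param areas Per-animal tumor cross-section areas (mm^2, >= 0) measured at
#'   \code{day}.
#' @param day Observation day (default 18).
#' @return An object of class \code{"group_observation"}.
#' @export
group_observation <- function(label, schedule, areas, day = 18) {
  if (!inherits(schedule, "treatment_schedule"))
    stop("'schedule' must be a treatment_schedule")
  areas <- as.numeric(areas)
  if (length(areas) < 1) stop("group '", label, "' needs at least one animal")
  if (any(!is.finite(areas)) || any(areas < 0))
    stop("areas must be finite and >= 0")
  structure(list(label = as.character(label), schedule = schedule,
                 areas = areas, day = as.integer(day)),
            class = "group_observation")
}

#' Build group observations from an animal-level size table
#'
#' @param sizes Data frame as returned by
#'   \code{\link{read_size_measurements}} (columns \code{animal_id},
#'   \code{group}, \code{day}, \code{area_mm2}).
#' @param arms Named list of \code{\link{treatment_schedule}}s; names must
#'   cover the group labels in \code{sizes}.
#' @param day Observation day to extract (default 18).
#' @return List of \code{\link{group_observation}} objects, in the order the
#'   groups appear in \code{arms}.
#' @export
group_observations <- function(sizes, arms = default_arms(), day = 18) {
  sizes <- sizes[sizes$day == day, , drop = FALSE]
  missing <- setdiff(unique(sizes$group), names(arms))
  if (length(missing))
    stop("no schedule defined for group(s): ", paste(missing, collapse = ", "))
  present <- intersect(names(arms), unique(sizes$group))
  lapply(present, function(g)
    group_observation(g, arms[[g]], sizes$area_mm2[sizes$group == g], day))
}

# Bounds used for the fit: generous physical ranges.
default_param_bounds <- function() {
  list(a     = c(1e-3, 2),
       K     = c(1, 1000),
       C0    = c(1e-6, 100),
       alpha = c(0, 2),
       beta  = c(0, 1),
       gamma = c(0, 0.999),
       mu    = c(0, 10),
       sigma = c(0, 100))
}

# Predicted group-mean area for each observation at its observation day.
predict_groups <- function(params, observations) {
  vapply(observations, function(ob) {
    sv <- schedule_vectors(ob$schedule, ob$day)
    sim_core(params, sv$doses, sv$mt, ob$day)$C[ob$day + 1L]
  }, numeric(1))
}

#' Least-squares objective of the calibration
#'
#' Sum over treatment groups of the squared difference between the simulated
#' area at the observation day and the observed group mean area.
#'
#' @param free_values Numeric vector of values for the free parameters, in
#'   the order of \code{free_names}.
#' @param free_names Names of the free parameters (subset of the
#'   \code{\link{model_params}} fields).
#' @param observations List of \code{\link{group_observation}} objects.
#' @param fixed A full \code{\link{model_params}} vector supplying the fixed
#'   parameters (entries named in \code{free_names} are overridden).
#' @return The residual sum of squares (mm^4).
#' @examples
#' obs <- list(group_observation("control", treatment_schedule(),
#'                               areas = c(38, 40), day = 18))
#' tumor_objective(c(0.1, 200), c("a", "K"), obs, model_params())
#' @export
tumor_objective <- function(free_values, free_names, observations, fixed) {
  p <- unclass(fixed)
  p[free_names] <- free_values
  validate_model_params(p)
  pred <- predict_groups(p, observations)
  obs <- vapply(observations, function(ob) mean(ob$areas), numeric(1))
  sum((pred - obs)^2)
}

#' Fit the tumor-immune model to group mean tumor sizes
#'
#' Bounded nonlinear least squares: minimizes the sum over treatment groups
#' of (simulated area at the observation day - observed group mean area)^2
#' over the chosen free parameters, with the remaining parameters held at
#' their values in \code{init}.  Optimization uses \code{\link[stats]{nlminb}}
#' with box bounds; candidate values are clipped to the bounds at evaluation.
#'
#' By default the free set is {a, K, gamma, mu, sigma}: five group means
#' cannot identify all eight parameters, so the initial size C0 and the
#' radiosensitivities alpha, beta are held at externally supplied values
#' (prior-report estimates), mirroring the study's use of earlier reports
#' for initial values.
#'
#' @param observations List of \code{\link{group_observation}} objects.
#' @param init A \code{\link{model_params}} object: initial values for the
#'   free parameters and fixed values for the rest.
#' @param free Character vector of free parameter names.
#' @param bounds Named list of c(lower, upper) per parameter; defaults to
#'   generous physical ranges.
#' @param control Passed to \code{\link[stats]{nlminb}} (defaults: at most
#'   500 iterations, absolute objective tolerance 1e-8).
#' @return An object of class \code{"tumor_fit"} with components
#'   \code{params} (full fitted parameter vector), \code{free},
#'   \code{rss}, \code{converged}, \code{n_iterations},
#'   \code{observations}, \code{fitted} (predicted group means) and
#'   \code{init}.
#' @examples
#' p <- model_params()
#' obs <- lapply(names(default_arms()), function(g)
#'   group_observation(g, default_arms()[[g]],
#'                     simulate_tumor(p, default_arms()[[g]], 18)$C[19]))
#' fit <- fit_tumor_model(obs, init = p)
#' coef(fit)
#' @export
fit_tumor_model <- function(observations,
                            init = model_params(),
                            free = c("a", "K", "gamma", "mu", "sigma"),
                            bounds = default_param_bounds(),
                            control = list()) {
  if (!length(observations)) stop("at least one group observation is required")
  if (!all(vapply(observations, inherits, logical(1), "group_observation")))
    stop("'observations' must be a list of group_observation objects")
  init <- validate_model_params(init)
  free <- match.arg(free, names(init), several.ok = TRUE)
  if (length(free) > length(observations))
    warning("under-determined fit: ", length(free), " free parameters but only ",
            length(observations), " groups")

  lo <- vapply(bounds[free], `[`, numeric(1), 1)
  hi <- vapply(bounds[free], `[`, numeric(1), 2)
  start <- pmin(pmax(unclass(init)[free], lo), hi)

  obj <- function(v) {
    v <- pmin(pmax(v, lo), hi)  # bound clipping at evaluation
    tumor_objective(v, free, observations, init)
  }
  f0 <- obj(start)
  if (!is.finite(f0)) stop("objective is not finite at the initial values")

  ctl <- utils::modifyList(list(iter.max = 500, eval.max = 2000,
                                rel.tol = 1e-8, abs.tol = 0),
                           control)
  opt <- stats::nlminb(start, obj, lower = lo, upper = hi, control = ctl)

  par <- pmin(pmax(opt$par, lo), hi)
  # never return a point worse than the initialization
  if (opt$objective > f0) {
    par <- start
    opt$objective <- f0
    opt$convergence <- 1L
    opt$message <- "no improvement over the initialization"
  }
  # nlminb reports "false convergence" when started at (or reaching) a point
  # it cannot improve; for a least-squares fit that is convergence.
  converged <- opt$convergence == 0 ||
    (grepl("false convergence", if (is.null(opt$message)) "" else opt$message) &&
       opt$objective <= f0 + 1e-12)
  params <- unclass(init)
  params[free] <- par
  class(params) <- "model_params"

  structure(list(params = params,
                 free = free,
                 rss = opt$objective,
                 converged = converged,
                 n_iterations = opt$iterations,
                 observations = observations,
                 fitted = predict_groups(params, observations),
                 init = init,
                 bounds = bounds,
                 control = ctl),
            class = "tumor_fit")
}

#' @export
print.tumor_fit <- function(x, digits = 4, ...) {
  cat("Tumor-immune model fit (least squares on group mean areas)\n")
  cat("Groups:", paste(vapply(x$observations, `[[`, character(1), "label"),
                       collapse = ", "), "\n")
  cat("Free parameters:\n")
  print(signif(unclass(x$params)[x$free], digits))
  cat("RSS:", format(x$rss, digits = digits),
      " converged:", x$converged, "\n")
  invisible(x)
}

#' @export
coef.tumor_fit <- function(object, all = FALSE, ...) {
  if (all) unclass(object$params) else unclass(object$params)[object$free]
}

#' @export
residuals.tumor_fit <- function(object, ...) {
  obs <- vapply(object$observations, function(ob) mean(ob$areas), numeric(1))
  r <- obs - object$fitted
  names(r) <- vapply(object$observations, `[[`, character(1), "label")
  r
}

#' @export
summary.tumor_fit <- function(object, ...) {
  obs <- vapply(object$observations, function(ob) mean(ob$areas), numeric(1))
  tab <- data.frame(
    group = vapply(object$observations, `[[`, character(1), "label"),
    n = vapply(object$observations, function(ob) length(ob$areas), integer(1)),
    observed_mean = obs,
    fitted = object$fitted,
    residual = obs - object$fitted)
  out <- list(fit = object, table = tab)
  class(out) <- "summary.tumor_fit"
  out
}

#' @export
print.summary.tumor_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nGroup means (mm^2):\n")
  print(x$table, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Predict tumor areas from a fitted model
#'
#' @param object A \code{"tumor_fit"}.
#' @param schedule Treatment schedule to simulate (default: control, no
#'   treatment).
#' @param days Days at which to report the predicted area.
#' @param ... Unused.
#' @return Data frame with columns \code{day} and \code{C}.
#' @export
predict.tumor_fit <- function(object, schedule = treatment_schedule(),
                              days = 18, ...) {
  horizon <- max(days)
  tr <- simulate_tumor(object$params, schedule, horizon)
  tr[tr$day %in% days, c("day", "C")]
}

#' @export
plot.tumor_fit <- function(x, ...) {
  obs <- vapply(x$observations, function(ob) mean(ob$areas), numeric(1))
  labs <- vapply(x$observations, `[[`, character(1), "label")
  m <- rbind(observed = obs, fitted = x$fitted)
  graphics::barplot(m, beside = TRUE, names.arg = labs,
                    legend.text = rownames(m),
                    ylab = expression(mean ~ tumor ~ area ~ (mm^2)), ...)
  invisible(x)
}

#' Simulate synthetic cohorts from a fitted model
#'
#' Draws animal-level day-18 areas from the fitted parameters using the
#' package's synthetic-cohort generator (lognormal growth-rate heterogeneity
#' and measurement noise).
#'
#' @param object A \code{"tumor_fit"}.
#' @param nsim Number of cohorts.
#' @param seed Master seed.
#' @param ... Passed to \code{\link{generator_config}} (e.g.
#'   \code{n_per_arm}, \code{size_noise_sd}).
#' @return A list of \code{nsim} cohort data frames (see
#'   \code{\link{synth_cohort}}).
#' @export
simulate.tumor_fit <- function(object, nsim = 1, seed = 1, ...) {
  arms <- lapply(object$observations, `[[`, "schedule")
  names(arms) <- vapply(object$observations, `[[`, character(1), "label")
  lapply(seq_len(nsim), function(i) {
    cfg <- generator_config(params = object$params, arms = arms,
                            seed = seed + i - 1, ...)
    synth_cohort(cfg)
  })
}
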