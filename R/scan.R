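#' Scan two-fraction schedules over inter-fraction intervals
#'
#' Simulates treatment with 1-MT plus two radiation fractions, the first at
#' \code{first_day} and the second at \code{first_day + interval}, for each
#' requested interval, and reports the predicted tumor area at each
#' evaluation day.  A second fraction falling after an evaluation day simply
#' does not affect that day's area.
#'
#' The defaults bracket the experimental arms: first fraction day 7, 8 Gy per
#' fraction, intervals 1..14 days (the short and long arms used 4 and 7),
#' evaluation days 18, 25 and 32, and the 1-MT window fixed at days 7-16
#' regardless of the interval, as in the experiments.
#'
#' @param params A \code{\link{model_params}} object (typically fitted).
#' @param first_day Day of the first fraction.
#' @param dose Dose per fraction in Gy.
#' @param intervals Integer inter-fraction intervals in days (>= 1).
#' @param mt_days Days on which 1-MT is active.
#' @param eval_days Days at which the predicted area is reported.
#' @return A data frame of class \code{"scan_table"} with columns
#'   \code{interval}, \code{eval_day}, \code{area_mm2}; one row per
#'   (interval, eval day) pair.
#' @examples
#' tab <- scan_intervals(model_params(), intervals = 1:14)
#' optimal_interval(tab, eval_day = 18)
#' @export
scan_intervals <- function(params, first_day = 7, dose = 8,
                           intervals = 1:14, mt_days = 7:16,
                           eval_days = c(18, 25, 32)) {
  params <- validate_model_params(params)
  intervals <- as.integer(intervals)
  if (!length(intervals)) stop("at least one interval is required")
  if (any(intervals < 1)) stop("intervals must be >= 1")
  eval_days <- as.integer(eval_days)
  if (!length(eval_days)) stop("at least one evaluation day is required")

  horizon <- max(eval_days, first_day + max(intervals))
  rows <- lapply(intervals, function(D) {
    sched <- treatment_schedule(rt_days = c(first_day, first_day + D),
                                rt_dose = dose, mt_days = mt_days)
    sv <- schedule_vectors(sched, horizon)
    C <- sim_core(params, sv$doses, sv$mt, horizon)$C
    data.frame(interval = D, eval_day = eval_days,
               area_mm2 = C[eval_days + 1L])
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  class(tab) <- c("scan_table", "data.frame")
  tab
}

#' Interval minimizing the predicted tumor area
#'
#' @param table A \code{"scan_table"} from \code{\link{scan_intervals}}.
#' @param eval_day Evaluation day to use (must be present in the table).
#' @return The interval (days) with the minimal predicted area at
#'   \code{eval_day}; ties are broken toward the smaller interval.
#' @export
optimal_interval <- function(table, eval_day) {
  sub <- table[table$eval_day == eval_day, , drop = FALSE]
  if (!nrow(sub)) stop("evaluation day ", eval_day, " is not in the scan table")
  sub <- sub[order(sub$interval), , drop = FALSE]
  sub$interval[which.min(sub$area_mm2)]
}

#' @export
plot.scan_table <- function(x, log = "y", ...) {
  days <- sort(unique(x$eval_day))
  ints <- sort(unique(x$interval))
  graphics::matplot(ints,
                    sapply(days, function(d)
                      x$area_mm2[x$eval_day == d][order(x$interval[x$eval_day == d])]),
                    type = "b", pch = 1, lty = 1, log = log,
                    xlab = "inter-fraction interval (days)",
                    ylab = expression(predicted ~ area ~ (mm^2)), ...)
  graphics::legend("bottomright", legend = paste("day", days),
                   col = seq_along(days), lty = 1, bty = "n")
  invisible(x)
}
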