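#' One-way fixed-effects analysis of variance
#'
#' Classic decomposition F = (SSB/dfB) / (SSW/dfW) across k groups, as used
#' to compare tumor sizes and cytokine levels between the treatment arms.
#'
#' @param groups Named list of numeric vectors (one per group, each n >= 2).
#' @return List with \code{F}, \code{df1}, \code{df2}, \code{p}.
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(4, 5, 6)))  # F = 13.5
#' @export
one_way_anova <- function(groups) {
  check_groups(groups, min_groups = 2, min_n = 2)
  n <- lengths(groups)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(n * means) / sum(n)
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- length(groups) - 1
  df2 <- sum(n) - length(groups)
  if (ssw <= 0) stop("zero within-group variance: F statistic undefined")
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, df1 = df1, df2 = df2,
       p = stats::pf(F, df1, df2, lower.tail = FALSE))
}

check_groups <- function(groups, min_groups, min_n) {
  if (!is.list(groups) || length(groups) < min_groups)
    stop("at least ", min_groups, " groups are required")
  bad <- lengths(groups) < min_n
  if (any(bad))
    stop("every group needs n >= ", min_n)
  if (any(!vapply(groups, function(g) all(is.finite(g)), logical(1))))
    stop("group values must be finite")
  invisible(groups)
}

#' Bonferroni-corrected pairwise comparisons
#'
#' All pairwise two-sample t tests between groups, with each raw p-value
#' multiplied by the number of pairs and capped at 1.  The default base test
#' is the pooled-variance two-sample t (matching common statistical-software
#' post-hoc behavior); set \code{welch = TRUE} for the unequal-variance
#' Welch t.
#'
#' @param groups Named list of numeric vectors (each n >= 2).
#' @param welch Use Welch's t instead of the pooled-variance t.
#' @return Symmetric matrix of Bonferroni-adjusted p-values (diagonal NA).
#' @export
bonferroni_pairwise <- function(groups, welch = FALSE) {
  check_groups(groups, min_groups = 2, min_n = 2)
  k <- length(groups)
  labs <- names(groups)
  if (is.null(labs)) labs <- paste0("group", seq_len(k))
  n_pairs <- k * (k - 1) / 2
  p <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    raw <- stats::t.test(groups[[i]], groups[[j]], var.equal = !welch)$p.value
    p[i, j] <- p[j, i] <- min(1, raw * n_pairs)
  }
  p
}

#' Welch two-sample t test
#'
#' Two-sided t test without assuming equal variances
#' (Welch-Satterthwaite degrees of freedom); the sign of t follows
#' mean(a) - mean(b).
#'
#' @param a,b Numeric vectors (each n >= 2).
#' @return List with \code{t}, \code{df}, \code{p}.
#' @examples
#' welch_t(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, df = 4
#' @export
welch_t <- function(a, b) {
  check_groups(list(a, b), min_groups = 2, min_n = 2)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    stop("both groups have zero variance but different means")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Survival sample
#'
#' @param time Positive survival/censoring times in days.
#' @param event Event indicators: 1 = death, 0 = censored at that day.
#' @return Object of class \code{"survival_sample"} (data frame with
#'   columns \code{time}, \code{event}).
#' @export
survival_sample <- function(time, event) {
  time <- as.numeric(time)
  event <- as.integer(event)
  if (!length(time)) stop("survival sample must be nonempty")
  if (length(time) != length(event)) stop("time and event lengths differ")
  if (any(time <= 0)) stop("survival times must be positive")
  if (!all(event %in% c(0L, 1L))) stop("event flags must be 0 or 1")
  structure(data.frame(time = time, event = event),
            class = c("survival_sample", "data.frame"))
}

as_survival_sample <- function(s) {
  if (inherits(s, "survival_sample")) return(s)
  if (is.data.frame(s) && all(c("time", "event") %in% names(s)))
    return(survival_sample(s$time, s$event))
  stop("expected a survival_sample or a data frame with columns time, event")
}

#' Kaplan-Meier median survival
#'
#' The Kaplan-Meier estimate is computed with
#' \code{\link[survival]{survfit}}; the median is the smallest observed time
#' t with S(t) <= 0.5 (no interpolation).  If the survival curve never
#' reaches 0.5 (e.g. heavy censoring) the median is undefined and \code{NA}
#' is returned.
#'
#' @param s A \code{\link{survival_sample}} (or data frame with columns
#'   \code{time}, \code{event}).
#' @return Median survival in days, or \code{NA} if undefined.
#' @examples
#' km_median(survival_sample(1:6, rep(1, 6)))      # 3
#' km_median(survival_sample(c(27, 27, 28), c(1, 1, 1)))  # 27
#' @export
km_median <- function(s) {
  s <- as_survival_sample(s)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = s)
  w <- which(sf$surv <= 0.5)
  if (!length(w)) return(NA_real_)
  sf$time[w[1]]
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison of two survival samples (1 degree of
#' freedom), computed with \code{\link[survival]{survdiff}}.  Event times at
#' which only one group is at risk contribute nothing to the statistic.
#'
#' @param a,b \code{\link{survival_sample}} objects (or data frames with
#'   columns \code{time}, \code{event}).
#' @return List with \code{chisq} and \code{p}.
#' @export
logrank_test <- function(a, b) {
  a <- as_survival_sample(a)
  b <- as_survival_sample(b)
  if (sum(a$event) + sum(b$event) < 1)
    stop("log-rank test needs at least one event")
  d <- rbind(cbind(a, group = "a"), cbind(b, group = "b"))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  chisq <- unname(sd$chisq)
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Read group/value measurements from CSV
#'
#' @param path CSV with columns \code{group}, \code{value}.
#' @return Named list of numeric vectors, one per group.
#' @export
read_group_values <- function(path) {
  if (!file.exists(path)) stop("measurement file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("group", "value") %in% names(d)))
    stop("CSV must contain columns 'group' and 'value'")
  split(as.numeric(d$value), d$group)
}

#' Read survival records from CSV
#'
#' @param path CSV with columns \code{group}, \code{time_days}, \code{event}.
#' @return Named list of \code{\link{survival_sample}} objects, one per group.
#' @export
read_survival_records <- function(path) {
  if (!file.exists(path)) stop("survival file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("group", "time_days", "event") %in% names(d)))
    stop("CSV must contain columns 'group', 'time_days' and 'event'")
  lapply(split(d, d$group), function(g) survival_sample(g$time_days, g$event))
}
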