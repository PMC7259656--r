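#' Bootstrap uncertainty for the model calibration
#'
#' Repeats the least-squares fit on datasets in which the animals of each
#' treatment group are resampled with replacement (group sizes preserved),
#' following the study's procedure of 10,000 bootstrap refits.  Group means
#' are recomputed on each replicate and the fit rerun from the same
#' initialization as the original fit.
#'
#' Replicates whose refit does not converge are kept in the sample matrix
#' but flagged, and excluded from the percentile intervals; the exclusion
#' count is reported.
#'
#' @param fit A \code{"tumor_fit"} from \code{\link{fit_tumor_model}}.
#' @param n_reps Number of bootstrap replicates (default 10000, as in the
#'   study; use a few hundred for quick uncertainty checks).
#' @param seed Integer seed; identical seeds give identical results.
#' @param level Confidence level for the percentile intervals (default 0.95).
#' @return An object of class \code{"tumor_boot"}: list with
#'   \code{samples} (n_reps x n_free matrix), \code{converged} (logical
#'   vector), \code{n_failed}, \code{ci} (2 x n_free matrix of percentile
#'   bounds), \code{n_reps}, \code{seed}, \code{level}.
#' @examples
#' p <- model_params()
#' arms <- default_arms()[c("control", "mt_rt2_long")]
#' obs <- lapply(names(arms), function(g)
#'   group_observation(g, arms[[g]],
#'                     simulate_tumor(p, arms[[g]], 18)$C[19] * c(0.9, 1.1)))
#' fit <- fit_tumor_model(obs, init = p, free = c("a", "mu"))
#' bootstrap_fit(fit, n_reps = 5, seed = 1)
#' @export
bootstrap_fit <- function(fit, n_reps = 10000, seed = 1, level = 0.95) {
  if (!inherits(fit, "tumor_fit")) stop("'fit' must be a tumor_fit object")
  n_reps <- as.integer(n_reps)
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (any(vapply(fit$observations, function(ob) length(ob$areas), integer(1)) < 1))
    stop("every group needs at least one animal")

  free <- fit$free
  samples <- matrix(NA_real_, n_reps, length(free),
                    dimnames = list(NULL, free))
  converged <- logical(n_reps)

  set.seed(as.integer(seed))
  for (r in seq_len(n_reps)) {
    obs_r <- lapply(fit$observations, function(ob) {
      ob$areas <- ob$areas[sample.int(length(ob$areas), length(ob$areas),
                                      replace = TRUE)]
      ob
    })
    fr <- fit_tumor_model(obs_r, init = fit$init, free = free,
                          bounds = fit$bounds, control = fit$control)
    samples[r, ] <- unclass(fr$params)[free]
    converged[r] <- fr$converged
  }

  ok <- samples[converged, , drop = FALSE]
  alpha <- (1 - level) / 2
  ci <- if (nrow(ok)) {
    apply(ok, 2, stats::quantile, probs = c(alpha, 1 - alpha), names = FALSE)
  } else {
    matrix(NA_real_, 2, length(free))
  }
  dimnames(ci) <- list(paste0(c(alpha, 1 - alpha) * 100, "%"), free)

  structure(list(samples = samples, converged = converged,
                 n_failed = sum(!converged), ci = ci,
                 n_reps = n_reps, seed = as.integer(seed), level = level),
            class = "tumor_boot")
}

#' @export
print.tumor_boot <- function(x, digits = 4, ...) {
  cat("Bootstrap of the tumor-immune model fit:", x$n_reps,
      "replicates (seed", paste0(x$seed, ")"), "\n")
  if (x$n_failed)
    cat(x$n_failed, "non-converged refits excluded from the intervals\n")
  cat("Percentile intervals (level ", x$level, "):\n", sep = "")
  print(signif(x$ci, digits))
  invisible(x)
}

#' @export
confint.tumor_boot <- function(object, parm, level, ...) {
  ci <- t(object$ci)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
summary.tumor_boot <- function(object, digits = 4, ...) {
  ok <- object$samples[object$converged, , drop = FALSE]
  tab <- data.frame(parameter = colnames(object$samples),
                    mean = colMeans(ok),
                    sd = apply(ok, 2, stats::sd),
                    lower = object$ci[1, ],
                    upper = object$ci[2, ])
  rownames(tab) <- NULL
  tab
}

#' Write bootstrap parameter samples to CSV
#'
#' @param boot A \code{"tumor_boot"}.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_bootstrap_csv <- function(boot, path) {
  d <- as.data.frame(boot$samples)
  d$converged <- boot$converged
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
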