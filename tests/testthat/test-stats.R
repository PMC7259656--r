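test_that("one-way ANOVA reproduces the hand-computed fixture", {
  # SSB = 13.5, SSW = 4, df = (1, 4) -> F = 13.5
  res <- one_way_anova(list(g1 = c(1, 2, 3), g2 = c(4, 5, 6)))
  expect_equal(res$F, 13.5)
  expect_equal(res$df1, 1)
  expect_equal(res$df2, 4)
  expect_equal(res$p, pf(13.5, 1, 4, lower.tail = FALSE))
  expect_equal(round(res$p, 3), 0.021)

  # identical means with nonzero spread: F = 0, p = 1
  res0 <- one_way_anova(list(a = c(1, 3), b = c(2, 2), c = c(0, 4)))
  expect_equal(res0$F, 0)
  expect_equal(res0$p, 1)

  expect_error(one_way_anova(list(a = c(1, 2))), "at least 2 groups")
  expect_error(one_way_anova(list(a = c(1, 2), b = 3)), "n >= 2")
  expect_error(one_way_anova(list(a = c(1, 1), b = c(2, 2))),
               "zero within-group variance")
})

test_that("one-way ANOVA agrees with stats::oneway.test on random data", {
  set.seed(11)
  g <- list(a = rnorm(5, 0), b = rnorm(7, 0.5), c = rnorm(6, 1))
  res <- one_way_anova(g)
  ref <- oneway.test(values ~ grp,
                     data = data.frame(values = unlist(g),
                                       grp = rep(names(g), lengths(g))),
                     var.equal = TRUE)
  expect_equal(res$F, unname(ref$statistic))
  expect_equal(res$p, ref$p.value)
})

test_that("Bonferroni pairwise correction multiplies and caps", {
  set.seed(2)
  g <- lapply(setNames(nm = paste0("g", 1:5)), function(i) rnorm(4))
  adj <- bonferroni_pairwise(g)
  expect_equal(dim(adj), c(5, 5))
  expect_true(isSymmetric(adj))
  # C(5,2) = 10 comparisons performed
  expect_equal(sum(!is.na(adj[upper.tri(adj)])), 10)
  # adjusted p = min(1, raw * 10), so always >= raw
  raw12 <- t.test(g[[1]], g[[2]], var.equal = TRUE)$p.value
  expect_equal(adj[1, 2], min(1, raw12 * 10))
  expect_true(all(adj[upper.tri(adj)] <= 1))
  # well-separated groups stay significant, equal groups cap at 1
  far <- list(a = c(1, 2, 3), b = c(41, 42, 43), c = c(1.5, 2.5, 2))
  adjf <- bonferroni_pairwise(far)
  expect_lt(adjf["a", "b"], 0.05)
  expect_equal(adjf["a", "c"], 1)
})

test_that("Welch t matches the hand fixture and links to ANOVA F", {
  res <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3 / sqrt(2 / 3))
  expect_equal(round(res$t, 3), -3.674)
  expect_equal(res$df, 4)
  expect_equal(round(res$p, 3), 0.021)
  # equal variances and sizes: t^2 equals the ANOVA F
  expect_equal(res$t^2, one_way_anova(list(c(1, 2, 3), c(4, 5, 6)))$F)

  # identical samples: t = 0, p = 1
  expect_equal(welch_t(c(2, 3, 4), c(2, 3, 4)),
               list(t = 0, df = 4, p = 1))
  # sign follows mean(a) - mean(b)
  expect_gt(welch_t(c(4, 5, 6), c(1, 2, 3))$t, 0)
  expect_error(welch_t(5, c(1, 2)), "n >= 2")
})

test_that("Kaplan-Meier median uses the first time S(t) <= 0.5", {
  expect_equal(km_median(survival_sample(1:6, rep(1, 6))), 3)
  expect_equal(km_median(survival_sample(c(27, 27, 28), c(1, 1, 1))), 27)
  # all censored: survival never drops, median undefined
  expect_true(is.na(km_median(survival_sample(c(100, 100), c(0, 0)))))
  expect_error(survival_sample(numeric(0), integer(0)), "nonempty")
  expect_error(survival_sample(c(0, 3), c(1, 1)), "positive")
})

test_that("KM survival curve is non-increasing, starts at 1, drops at events", {
  set.seed(4)
  s <- survival_sample(sample(1:40, 25, replace = TRUE),
                       rbinom(25, 1, 0.7))
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = s)
  expect_true(all(diff(sf$surv) <= 1e-12))
  expect_true(all(sf$surv <= 1))
  expect_true(all(sf$n.event[sf$surv < c(1, head(sf$surv, -1))] > 0))
})

test_that("log-rank matches the brute-force risk-table oracle", {
  # identical samples: chi-square 0, p = 1
  a <- survival_sample(c(5, 8, 12), c(1, 1, 1))
  res <- logrank_test(a, a)
  expect_equal(res$chisq, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-6)

  # toy samples vs explicit observed-minus-expected computation
  a <- survival_sample(c(1, 2), c(1, 1))
  b <- survival_sample(c(3, 4), c(1, 1))
  res <- logrank_test(a, b)
  expect_equal(res$chisq, logrank_oracle(c(1, 2), c(1, 1), c(3, 4), c(1, 1)),
               tolerance = 1e-10)

  set.seed(9)
  for (i in 1:5) {
    ta <- sample(1:30, 8, replace = TRUE); ea <- rbinom(8, 1, 0.8)
    tb <- sample(1:30, 10, replace = TRUE); eb <- rbinom(10, 1, 0.8)
    if (sum(ea) + sum(eb) == 0) next
    expect_equal(logrank_test(survival_sample(ta, ea),
                              survival_sample(tb, eb))$chisq,
                 logrank_oracle(ta, ea, tb, eb), tolerance = 1e-8)
  }

  # one group fully censored before any event in the other: finite statistic
  a <- survival_sample(c(2, 3), c(0, 0))
  b <- survival_sample(c(5, 8), c(1, 1))
  res <- logrank_test(a, b)
  expect_true(is.finite(res$chisq))
  expect_error(logrank_test(survival_sample(3, 0), survival_sample(4, 0)),
               "at least one event")
})

test_that("group and survival CSV readers round-trip", {
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(group = c("a", "a", "b"), value = c(1, 2, 9)),
            path, row.names = FALSE)
  g <- read_group_values(path)
  expect_equal(g, list(a = c(1, 2), b = 9))

  write.csv(data.frame(group = c("ctl", "ctl", "trt"),
                       time_days = c(20, 25, 80), event = c(1, 1, 0)),
            path, row.names = FALSE)
  s <- read_survival_records(path)
  expect_equal(names(s), c("ctl", "trt"))
  expect_equal(s$ctl$time, c(20, 25))
  expect_equal(s$trt$event, 0L)
})
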