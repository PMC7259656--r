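test_that("noiseless cohorts reproduce the model predictions exactly", {
  cfg <- generator_config(size_noise_sd = 0, growth_sd = 0, seed = 3)
  cohort <- synth_cohort(cfg)
  expect_equal(nrow(cohort), 20)           # 5 arms x 4 animals
  expect_equal(unique(cohort$day), 18)
  for (g in names(cfg$arms)) {
    pred <- simulate_tumor(cfg$params, cfg$arms[[g]], 18)$C[19]
    expect_equal(cohort$area_mm2[cohort$group == g], rep(pred, 4))
  }
})

test_that("cohort means respect the lognormal bias factor at large n", {
  sd <- 0.2
  cfg <- generator_config(n_per_arm = 1000, size_noise_sd = sd,
                          growth_sd = 0, seed = 8)
  cohort <- synth_cohort(cfg)
  for (g in c("control", "mt_rt2_long")) {
    pred <- simulate_tumor(cfg$params, cfg$arms[[g]], 18)$C[19]
    x <- cohort$area_mm2[cohort$group == g]
    expected_mean <- pred * exp(sd^2 / 2)   # lognormal mean correction
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - expected_mean), 2 * se)
  }
})

test_that("generators are bit-reproducible under the master seed", {
  cfg <- generator_config(seed = 21, n_genes = 30)
  expect_identical(synth_cohort(cfg), synth_cohort(cfg))
  expect_identical(synth_survival(cfg, "control", 12),
                   synth_survival(cfg, "control", 12))
  expect_identical(synth_cytokines(cfg), synth_cytokines(cfg))
  expect_identical(synth_expression(cfg)$values,
                   synth_expression(cfg)$values)
  # substreams differ across stages and arms
  expect_false(identical(synth_survival(cfg, "control", 12),
                         synth_survival(cfg, "mt", 12)))
  cfg2 <- generator_config(seed = 22, n_genes = 30)
  expect_false(identical(synth_cohort(cfg), synth_cohort(cfg2)))
})

test_that("survival times are threshold crossings censored at day 100", {
  # no heterogeneity: all animals share the deterministic crossing day
  cfg <- generator_config(growth_sd = 0, seed = 5)
  s <- synth_survival(cfg, "control", 10)
  expect_equal(length(unique(s$time)), 1)
  expect_true(all(s$event == 1))
  # the packaged control crossing is day 27
  expect_equal(unique(s$time), 27)

  # threshold below the initial size: immediate crossing at day 1
  cfg_low <- generator_config(death_threshold = 0.005, growth_sd = 0, seed = 5)
  s_low <- synth_survival(cfg_low, "control", 5)
  expect_equal(s_low$time, rep(1, 5))

  # a slow-growing arm never crosses: censored at the censor day
  cfg_slow <- generator_config(params = model_params(a = 0.01),
                               growth_sd = 0, seed = 5)
  s_slow <- synth_survival(cfg_slow, "control", 5)
  expect_true(all(s_slow$event == 0))
  expect_true(all(s_slow$time == 100))

  expect_error(synth_survival(cfg, "nope", 5), "unknown arm")
})

test_that("the cytokine panel has 12 analytes and a spiked IL-1A", {
  cfg <- generator_config(seed = 13)
  pan <- synth_cytokines(cfg)
  analytes <- setdiff(names(pan), c("animal_id", "group"))
  expect_length(analytes, 12)
  expect_true(all(c("IL-1A", "TNF-A", "GM-CSF", "Ifn-G") %in% analytes))
  expect_equal(nrow(pan), 20)
  # spike raises treated-arm means of IL-1A only
  treated <- pan$group != "control"
  expect_gt(mean(pan[["IL-1A"]][treated]) - mean(pan[["IL-1A"]][!treated]), 10)
  expect_lt(abs(mean(pan[["IL-6"]][treated]) - mean(pan[["IL-6"]][!treated])), 15)
})

test_that("null cytokine panels give uniform ANOVA p-values, spiked ones power", {
  # type-I calibration: ~5% of null ANOVA p-values below 0.05
  set.seed(1234)
  n_reps <- 1000
  p_null <- replicate(n_reps, {
    cfg <- generator_config(cytokine_spike_sds = 0,
                            seed = sample.int(1e6, 1))
    pan <- synth_cytokines(cfg)
    one_way_anova(split(pan[["IL-4"]], pan$group))$p
  })
  expect_gt(mean(p_null < 0.05), 0.02)
  expect_lt(mean(p_null < 0.05), 0.09)

  # power: 3-sd spike on IL-1A rejects in the majority of replicates
  rej <- replicate(500, {
    cfg <- generator_config(seed = sample.int(1e6, 1))
    pan <- synth_cytokines(cfg)
    one_way_anova(split(pan[["IL-1A"]], pan$group))$p < 0.05
  })
  expect_gt(mean(rej), 0.5)
})

test_that("synthetic expression carries the IDO1 spike on a 5 vs 9 design", {
  cfg <- generator_config(seed = 17, n_genes = 100)
  m <- synth_expression(cfg)
  expect_equal(sum(m$groups == "control"), 5)
  expect_equal(sum(m$groups == "case"), 9)
  expect_equal(length(m$genes), 100)

  # the estimate's own 95% CI contains the generating spike
  res <- gene_log2fc(m, "IDO1")
  x <- m$values["IDO1", ]
  ci_half <- qt(0.975, 12) * sqrt(var(x[m$groups == "case"]) / 9 +
                                  var(x[m$groups == "control"]) / 5)
  expect_lt(abs(res$log2fc - 2.73), ci_half + 1e-12)

  # null generator: mean estimate near zero over replicates
  fcs <- sapply(1:40, function(i) {
    cfg0 <- generator_config(seed = 1000 + i, n_genes = 2, ido1_spike = 0)
    gene_log2fc(synth_expression(cfg0), "IDO1")$log2fc
  })
  expect_lt(abs(mean(fcs)), 3 * sd(fcs) / sqrt(length(fcs)) + 0.1)
})

test_that("noiseless generator composed with the fit recovers the truth", {
  truth <- model_params()
  cfg <- generator_config(size_noise_sd = 0, growth_sd = 0, seed = 2)
  cohort <- synth_cohort(cfg)
  obs <- group_observations(cohort, cfg$arms)

  # initialized at truth: exact recovery, zero RSS
  fit0 <- fit_tumor_model(obs, init = truth)
  expect_lt(fit0$rss, 1e-10)
  expect_equal(coef(fit0), unclass(truth)[fit0$free], tolerance = 1e-4)

  # initialized at 1.5x truth: within 10%
  fit1 <- fit_tumor_model(obs, init = init_at_1p5(truth))
  relerr <- abs(coef(fit1) - unclass(truth)[fit1$free]) /
    unclass(truth)[fit1$free]
  expect_true(all(relerr < 0.10))
})

test_that("the fixture bundle round-trips through the readers", {
  cfg <- generator_config(seed = 31, n_genes = 20)
  dir <- tempfile("bundle_")
  paths <- write_synth_bundle(cfg, dir, n_survival = 4)
  expect_true(all(file.exists(unlist(paths))))

  sizes <- read_size_measurements(paths[["sizes"]])
  expect_equal(nrow(sizes), 20)
  surv <- read_survival_records(paths[["survival"]])
  expect_equal(sort(names(surv)), sort(names(cfg$arms)))
  expect_equal(nrow(surv$control), 4)
  m <- synth_expression(cfg)
  m2 <- read_expression(paths[["expression"]],
                        case = m$samples[m$groups == "case"],
                        control = m$samples[m$groups == "control"])
  expect_equal(m2$values, m$values, tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
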