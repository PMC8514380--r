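test_that("Kaplan-Meier matches the closed-form product limit", {
  # three subjects, events at 1, 2, 3: S = 2/3, 1/3, 0
  km <- kaplanMeier(tiny_cohort(1:3, c(1, 1, 1), rep("wild", 3)), "rfs")
  expect_equal(km$curves$survival[km$curves$n_event > 0], c(2/3, 1/3, 0))

  # all censored: the curve never drops
  km0 <- kaplanMeier(tiny_cohort(1:4, rep(0, 4), rep("wild", 4)), "rfs")
  expect_true(all(km0$curves$survival == 1))

  expect_error(kaplanMeier(tiny_cohort(c(-1, 2), c(1, 1), rep("wild", 2))),
               class = "tp53sig_invalid_record")
})

test_that("Kaplan-Meier equals the risk-set oracle on random inputs", {
  set.seed(21)
  for (i in 1:25) {
    d <- random_surv(sample(3:50, 1))
    km <- kaplanMeier(tiny_cohort(d$time, d$event, d$group), "rfs")
    oracle <- brute_km(d$time, d$event)
    got <- km$curves[km$curves$n_event > 0, ]
    expect_equal(got$time, oracle$time)
    expect_equal(got$survival, oracle$surv)
    # curve properties: starts from 1, non-increasing
    expect_true(all(diff(c(1, got$survival)) <= 1e-12))
  }
})

test_that("log-rank matches the hypergeometric oracle and is symmetric", {
  # identical groups: statistic 0, p = 1
  d <- tiny_cohort(rep(c(1, 2, 3), 2), rep(c(1, 0, 1), 2),
                   rep(c("mutant", "wild"), each = 3))
  lr <- logRank(d, "rfs")
  expect_equal(lr$statistic, 0)
  expect_equal(lr$p_value, 1)
  expect_equal(lr$df, 1)

  # six-subject worked example against the per-event-time oracle
  d6 <- tiny_cohort(c(1, 2, 3, 4, 5, 6), c(1, 1, 0, 1, 1, 1),
                    c("mutant", "mutant", "wild", "wild", "mutant", "wild"))
  lr6 <- logRank(d6, "rfs")
  expect_equal(lr6$statistic,
               brute_logrank(d6$rfs_time, d6$rfs_event, d6$tp53_status))

  # random inputs, including ties
  set.seed(22)
  for (i in 1:20) {
    d <- random_surv(sample(6:50, 1))
    if (length(unique(d$group)) < 2 || sum(d$event) == 0) next
    got <- logRank(tiny_cohort(d$time, d$event, d$group), "rfs")
    expect_equal(got$statistic, brute_logrank(d$time, d$event, d$group))
    # relabeling the groups leaves the statistic unchanged
    flipped <- ifelse(d$group == "mutant", "wild", "mutant")
    expect_equal(logRank(tiny_cohort(d$time, d$event, flipped),
                         "rfs")$statistic, got$statistic)
  }

  expect_error(logRank(tiny_cohort(1:3, c(1, 1, 1), rep("wild", 3))),
               class = "tp53sig_degenerate_grouping")
})

test_that("Cox fit matches the analytic partial likelihood", {
  # three subjects, all events, binary covariate: maximise the Efron/
  # Breslow-free (untied) partial likelihood by direct search
  d <- tiny_cohort(c(1, 2, 3), c(1, 1, 1), c("mutant", "wild", "mutant"))
  fit <- coxFit(d, "rfs", "tp53_status", "univariate")
  neg_logpl <- function(b)
    -(b - log(2 * exp(b) + 1) - log(exp(b) + 1))
  b_hat <- stats::optimize(neg_logpl, c(-5, 5))$minimum
  expect_equal(log(fit$hazard_ratio), b_hat, tolerance = 1e-4)
  expect_true(fit$ci_low <= fit$hazard_ratio &&
                fit$hazard_ratio <= fit$ci_high)

  expect_error(coxFit(tiny_cohort(1:3, c(1, 1, 1), rep("wild", 3)),
                      "rfs", "tp53_status"),
               class = "tp53sig_degenerate_variable")
  expect_error(coxFit(tiny_cohort(1:4, c(0, 0, 0, 0),
                                  rep(c("mutant", "wild"), 2)),
                      "rfs", "tp53_status"),
               class = "tp53sig_invalid_record")
})

test_that("null covariate CIs cover 1 at the nominal rate", {
  cfg <- simConfig(nPatients = 2000, covariateLogHR = c())
  set.seed(23)
  covered <- vapply(1:200, function(s) {
    cl <- simulateClinical(simulateExpression(cfg, seed = s)$labels, cfg,
                           seed = s + 300000)
    # adjuvant endocrine therapy has no direct effect in this config, but is
    # class-associated; fit it jointly with the true signature effect
    f <- coxFit(cl, "rfs", c("tp53_status", "adj_endocrine"), "multivariate")
    row <- f[f$variable == "adj_endocrine", ]
    row$ci_low <= 1 && 1 <= row$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.93)
})

test_that("two-stage prognostic table enforces its entry rule", {
  co <- simulateCohort(seed = 101)
  t3 <- suppressMessages(runTable3(co$clinical))
  expect_equal(nrow(t3$univariate), 11)
  expect_setequal(
    t3$selected,
    t3$univariate$variable[!is.na(t3$univariate$p_value) &
                             t3$univariate$p_value <= 0.05])
  if (!is.null(t3$multivariate))
    expect_setequal(t3$multivariate$variable, t3$selected)

  # nothing significant: multivariate step skipped with a notice
  null_cfg <- simConfig(trueLogHR = 0, covariateLogHR = c(),
                        baselineHazard = 0.02)
  cl <- simulateClinical(simulateExpression(null_cfg, seed = 5)$labels,
                         null_cfg, seed = 6)
  t3n <- suppressMessages(runTable3(cl, entryP = 1e-6))
  expect_null(t3n$multivariate)
  expect_length(t3n$selected, 0)

  # degenerate grouping is an error
  cl2 <- co$clinical; cl2$tp53_status <- "mutant"
  expect_error(runTable3(cl2), class = "tp53sig_degenerate_variable")
})

test_that("subtype assignment follows the receptor/Ki-67 definitions", {
  rec <- data.frame(
    er   = c("positive", "positive", "negative", "negative", "positive"),
    pgr  = c("negative", "positive", "negative", "negative", "positive"),
    her2 = c("negative", "negative", "negative", "positive", "negative"),
    ki67_pct = c(8, 10, 50, 20, NA))
  expect_identical(assignSubtype(rec),
                   c("LuminalA", "LuminalB", "TNBC", NA, NA))
})

test_that("subgroup RFS reports tests or explicit degeneracy notes", {
  co <- simulateCohort(simConfig(nPatients = 400), seed = 31)
  res <- suppressMessages(subgroupRFS(co$clinical))
  expect_setequal(res$summary$subgroup,
                  c("ER+", "ER-", "LuminalA", "LuminalB", "TNBC",
                    "Grade1", "Grade2", "Grade3"))
  tested <- !is.na(res$summary$p_value)
  expect_true(any(tested))
  expect_true(all(res$summary$note[!tested] != ""))
  # every tested subgroup has both classes and at least one event
  expect_true(all(res$summary$n_mutant[tested] > 0 &
                    res$summary$n_wild[tested] > 0 &
                    res$summary$events[tested] > 0))

  # zero events in a subgroup: note instead of p-value
  cl <- co$clinical
  cl$rfs_event <- 0L
  res0 <- suppressMessages(subgroupRFS(cl))
  expect_true(all(is.na(res0$summary$p_value)))
})

test_that("characteristics table applies the right test per variable", {
  # hand-computed 2x2: [[20,10],[10,20]] gives X^2 = 20/3
  rec <- data.frame(
    tp53_status = rep(c("mutant", "wild"), each = 30),
    er = c(rep(c("positive", "negative"), c(20, 10)),
           rep(c("positive", "negative"), c(10, 20))),
    age = rep(50, 60))
  ct <- suppressWarnings(characteristicsTable(rec))
  er_row <- ct$summary[ct$summary$variable == "er", ]
  expect_equal(er_row$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(er_row$df, 1)
  expect_identical(er_row$test, "chi-squared")

  # identical group distributions: statistic 0, p 1
  rec2 <- data.frame(
    tp53_status = rep(c("mutant", "wild"), each = 20),
    er = rep(rep(c("positive", "negative"), each = 10), 2),
    age = rep(c(40, 60), 20))
  ct2 <- characteristicsTable(rec2)
  expect_equal(ct2$summary[ct2$summary$variable == "er", "statistic"], 0)
  expect_equal(ct2$summary[ct2$summary$variable == "er", "p_value"], 1)
  # age identical across groups: Kruskal-Wallis statistic 0
  expect_equal(ct2$summary[ct2$summary$variable == "age", "statistic"], 0)

  # missing values: excluded from the test, reported as counts
  rec3 <- rec
  rec3$grade <- c(rep(NA, 6), sample(rep(1:3, 18)))
  ct3 <- suppressWarnings(characteristicsTable(rec3))
  expect_equal(ct3$summary[ct3$summary$variable == "grade", "n_missing"], 6)
  expect_equal(sum(ct3$tables$grade), 54)

  expect_error(characteristicsTable(data.frame(tp53_status = rep("wild", 5),
                                               age = 1:5)),
               class = "tp53sig_degenerate_grouping")
})
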