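test_that("config validation rejects impossible parameters", {
  expect_error(simConfig(nPatients = 1), class = "tp53sig_config_error")
  expect_error(simConfig(fracMutant = 1.2), class = "tp53sig_config_error")
  expect_error(simConfig(baselineHazard = 0), class = "tp53sig_config_error")
  expect_error(simConfig(scoreSdlog = c(wild = -1, mutant = 0.3)),
               class = "tp53sig_config_error")
  bad <- defaultCovariateProbs(); bad$er_pos["mutant"] <- 1.5
  expect_error(simConfig(covariateProbs = bad),
               class = "tp53sig_config_error")
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- simConfig(nPatients = 60)
  a <- simulateCohort(cfg, seed = 9)
  b <- simulateCohort(cfg, seed = 9)
  expect_identical(a$expression, b$expression)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$labels, b$labels)
  c_ <- simulateCohort(cfg, seed = 10)
  expect_false(identical(a$expression, c_$expression))
})

test_that("simulated expression carries the intended class separation", {
  cfg <- simConfig(nPatients = 10000)
  ex <- simulateExpression(cfg, seed = 1)
  sc <- signatureScore(ex$expression)
  expect_equal(unname(sc), unname(ex$trueScore), tolerance = 1e-12)
  a <- rocAuc(sc, ex$labels)
  expect_gte(a, 0.95)
  expect_lte(a, 1.0)
  # imperfect classification at the published cutoff, as in real data
  cross <- mean((sc > TP53_CUTOFF) != (ex$labels == "mutant"))
  expect_gt(cross, 0)
  expect_lt(cross, 0.06)

  # null configuration: no class difference, AUC near one half
  null_cfg <- simConfig(nPatients = 4000,
                        scoreMeanlog = c(wild = 0, mutant = 0),
                        scoreSdlog = c(wild = 0.3, mutant = 0.3))
  exn <- simulateExpression(null_cfg, seed = 2)
  expect_lt(abs(rocAuc(signatureScore(exn$expression), exn$labels) - 0.5),
            0.05)
})

test_that("clinical covariates hit their class-conditional targets", {
  cfg <- simConfig(nPatients = 10000)
  ex <- simulateExpression(cfg, seed = 3)
  cl <- simulateClinical(ex$labels, cfg, seed = 4)
  mut <- cl[cl$tp53_status == "mutant", ]
  wld <- cl[cl$tp53_status == "wild", ]
  expect_lt(abs(mean(mut$er == "positive") - 0.55), 0.03)
  expect_lt(abs(mean(wld$er == "positive") - 0.89), 0.03)
  expect_lt(abs(mean(mut$p_ln == "positive") - 0.35), 0.03)
  expect_lt(abs(mean(mut$grade == 3, na.rm = TRUE) - 0.58), 0.03)
})

test_that("endpoint construction keeps the survival invariants", {
  co <- simulateCohort(simConfig(nPatients = 2000), seed = 11)
  cl <- co$clinical
  expect_true(all(cl$rfs_time >= 0 & cl$os_time >= 0 & cl$bcss_time >= 0))
  expect_true(all(cl$rfs_time <= cl$os_time + 1e-12))
  expect_true(all(cl$rfs_event %in% 0:1 & cl$os_event %in% 0:1 &
                    cl$bcss_event %in% 0:1))
  # a breast-cancer death is a death
  expect_true(all(cl$os_event[cl$bcss_event == 1] == 1))
  expect_true(all(cl$bcss_time[cl$bcss_event == 1] ==
                    cl$os_time[cl$bcss_event == 1]))

  # vanishing follow-up: everyone censored
  tiny <- simConfig(censorTimeMax = 1e-9)
  cl0 <- simulateClinical(simulateExpression(tiny, seed = 1)$labels, tiny,
                          seed = 2)
  expect_equal(sum(cl0$rfs_event) + sum(cl0$os_event) + sum(cl0$bcss_event),
               0)

  expect_error(simulateClinical(factor(rep("wild", 10)), simConfig()),
               class = "tp53sig_alignment_error")
})

test_that("the packaged development-cohort fixture is intact", {
  fx <- table1Fixture()
  expect_equal(nrow(fx), 34)
  expect_equal(as.vector(table(fx$status_by_microarray)), c(18, 16))
  expect_equal(as.vector(table(fx$status_by_score)), c(17, 17))
  br13 <- fx[fx$sample_id == "BR013", ]
  expect_equal(br13$tp53_signature_score, 1.4350)
  expect_identical(as.character(br13$status_by_score), "mutant")
  expect_identical(as.character(br13$status_by_microarray), "wild")
  expect_equal(min(fx$tp53_signature_score), 0.1707)
  expect_identical(fx$sample_id[which.min(fx$tp53_signature_score)], "BR047")
  expect_equal(max(fx$tp53_signature_score), 4.0595)
})
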