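test_that("rank AUC equals the all-pairs concordance count", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(4:200, 1)
    status <- c("mutant", "wild",
                sample(c("mutant", "wild"), n - 2, replace = TRUE))
    score <- round(stats::rlnorm(n, 0, 0.8), sample(1:3, 1))  # forces ties
    expect_equal(rocAuc(score, status), brute_auc(score, status))
  }
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(12)
  score <- stats::rlnorm(60, 0, 0.7)
  status <- sample(c("mutant", "wild"), 60, replace = TRUE,
                   prob = c(0.4, 0.6))
  a <- rocAuc(score, status)
  expect_equal(rocAuc(log(score), status), a)
  expect_equal(rocAuc(score^3, status), a)
  expect_equal(rocAuc(rank(score), status), a)
})

test_that("AUC hits the degenerate and perfect extremes", {
  expect_equal(rocAuc(c(5, 6, 7, 1, 2), rep(c("mutant", "wild"), c(3, 2))), 1)
  expect_equal(rocAuc(c(1, 2, 5, 6), rep(c("mutant", "wild"), c(2, 2))), 0)
  expect_error(rocAuc(1:4, rep("mutant", 4)),
               class = "tp53sig_degenerate_labels")
})

test_that("label permutation centres the AUC at one half", {
  fx <- table1Fixture()
  set.seed(13)
  perm_auc <- replicate(10000,
    rocAuc(fx$tp53_signature_score, sample(fx$status_by_microarray)))
  expect_lt(abs(mean(perm_auc) - 0.5), 0.005)
})

test_that("AUC agrees with pROC on the fixture and random data", {
  fx <- table1Fixture()
  expect_equal(
    rocAuc(fx$tp53_signature_score, fx$status_by_microarray),
    as.numeric(pROC::auc(pROC::roc(
      fx$status_by_microarray, fx$tp53_signature_score,
      levels = c("wild", "mutant"), direction = "<", quiet = TRUE))))
  set.seed(14)
  score <- stats::rlnorm(80)
  status <- sample(c("mutant", "wild"), 80, replace = TRUE)
  expect_equal(
    rocAuc(score, status),
    as.numeric(pROC::auc(pROC::roc(status, score,
                                   levels = c("wild", "mutant"),
                                   direction = "<", quiet = TRUE))))
})

test_that("Youden cutoff selection scans midpoint thresholds", {
  # two-point case: midpoint 1.5 separates perfectly
  rc <- selectCutoff(c(1, 2), c("wild", "mutant"))
  expect_equal(selectedCutoff(rc), 1.5)
  expect_equal(youdenJ(rc), 1)

  # separable data: J = 1 and the training data classify perfectly
  set.seed(15)
  w <- stats::runif(20, 0, 1); m <- stats::runif(15, 2, 3)
  rc <- selectCutoff(c(w, m), rep(c("wild", "mutant"), c(20, 15)))
  expect_equal(youdenJ(rc), 1)
  calls <- classifyScore(c(w, m), selectedCutoff(rc))
  expect_identical(as.character(calls), rep(c("wild", "mutant"), c(20, 15)))

  # no separation: J = 0 at a sentinel, with a warning
  expect_warning(rc0 <- selectCutoff(rep(2, 6),
                                     rep(c("wild", "mutant"), 3)),
                 "separate")
  expect_equal(youdenJ(rc0), 0)
  expect_true(is.infinite(selectedCutoff(rc0)))

  expect_error(selectCutoff(1:3, rep("wild", 3)),
               class = "tp53sig_degenerate_labels")
})

test_that("fixture recalibration lands in the score gap", {
  fx <- table1Fixture()
  rc <- selectCutoff(fx$tp53_signature_score, fx$status_by_microarray)
  expect_gt(selectedCutoff(rc), 1.1003)
  expect_lt(selectedCutoff(rc), 1.2907)
  # at that cutoff only BR013 is misclassified: J = 1 + 17/18 - 1
  expect_equal(youdenJ(rc), 17 / 18)
  expect_true(validObject(rc))
})

test_that("agreement rate counts concordant calls", {
  x <- c("mutant", "wild", "mutant", "wild")
  expect_equal(agreementRate(x, x)$rate, 1)
  inv <- ifelse(x == "mutant", "wild", "mutant")
  expect_equal(agreementRate(x, inv)$rate, 0)

  calls <- data.frame(sample_id = c("a", "b"),
                      tp53_status = c("mutant", "wild"))
  ref <- data.frame(sample_id = c("b", "c"),
                    reference_status = c("wild", "wild"))
  expect_error(agreementRate(calls, ref), "a.*c|c.*a",
               class = "tp53sig_alignment_error")

  fx <- table1Fixture()
  ag <- agreementRate(fx$status_by_score, fx$status_by_microarray)
  expect_equal(ag$n, 34)
  expect_equal(ag$rate, 33 / 34)
  expect_equal(as.numeric(ag$table["mutant", "wild"]), 1)  # BR013
})
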