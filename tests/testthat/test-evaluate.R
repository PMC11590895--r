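test_that("confusion tallies grids and one-vs-rest counts correctly", {
  a <- rep(c("x", "y"), 5)
  cm <- confusion(a, a, c("x", "y"))
  expect_equal(unname(diag(cm$table)), c(5, 5))
  expect_true(all(cm$counts$fp == 0) && all(cm$counts$fn == 0))
  expect_true(all(cm$counts$tp + cm$counts$tn + cm$counts$fp +
                    cm$counts$fn == cm$n))

  # independent pair-tally oracle on random 3-class vectors
  set.seed(15)
  cls <- c("a", "b", "c")
  act <- sample(cls, 50, TRUE); prd <- sample(cls, 50, TRUE)
  cm <- confusion(act, prd, cls)
  for (i in cls) for (j in cls)
    expect_equal(cm$table[i, j], sum(act == i & prd == j))

  expect_error(confusion(character(), character()), "shape error")
  expect_error(confusion(c("a", "b"), c("a")), "shape error")
  expect_error(confusion(c("a", "q"), c("a", "a"), c("a", "b")),
               "vocabulary error")
})

test_that("class metrics follow the one-vs-rest definitions in percent", {
  cm <- confusion(c("p", "n"), c("p", "n"), c("p", "n"))
  m <- classMetrics(cm)
  expect_true(all(m[m$class == "p", -1] == 100))

  expect_equal(f1Score(93.70, 93.49), 93.59, tolerance = 1e-4)
  expect_true(is.na(f1Score(0, 0)))

  # zero-denominator metrics are NA and excluded from the macro average
  cm0 <- confusion(rep("a", 4), c("a", "a", "a", "a"), c("a", "b"))
  expect_message(m0 <- classMetrics(cm0), "undefined")
  expect_true(is.na(m0$tpr[m0$class == "b"]))
  expect_equal(m0$tpr[m0$class == "Overall"], 100)
})

test_that("binary metric sets show the TPR/TNR symmetry", {
  set.seed(16)
  act <- sample(c("lying", "standing"), 300, TRUE, prob = c(0.6, 0.4))
  prd <- ifelse(runif(300) < 0.85, act,
                ifelse(act == "lying", "standing", "lying"))
  m <- classMetrics(confusion(act, prd, c("lying", "standing")))
  expect_equal(m$tpr[m$class == "lying"], m$tnr[m$class == "standing"])
  expect_equal(m$tpr[m$class == "standing"], m$tnr[m$class == "lying"])
  expect_equal(m$accuracy[m$class == "lying"],
               m$accuracy[m$class == "standing"])
})

test_that("metrics are invariant to permuting the sample order", {
  set.seed(17)
  act <- sample(c("a", "b", "c"), 120, TRUE)
  prd <- sample(c("a", "b", "c"), 120, TRUE)
  perm <- sample(120)
  expect_equal(classMetrics(confusion(act, prd, c("a", "b", "c"))),
               classMetrics(confusion(act[perm], prd[perm], c("a", "b", "c"))))
})

test_that("rocAuc sweeps thresholds and equals the concordance oracle", {
  act <- rep(c("pos", "neg"), each = 5)
  sc <- c(6:10, 1:5) / 10
  r <- rocAuc(act, sc, "pos")
  expect_equal(r$auc, 1)
  expect_equal(r$tpr[1], 0); expect_equal(r$fpr[1], 0)
  expect_equal(r$tpr[length(r$tpr)], 1)
  expect_equal(r$fpr[length(r$fpr)], 1)
  expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))

  expect_equal(rocAuc(act, rep(0.5, 10), "pos")$auc, 0.5)

  set.seed(18)
  for (i in 1:5) {
    n <- sample(20:200, 1)
    act <- sample(c("pos", "neg"), n, TRUE)
    if (length(unique(act)) < 2) next
    sc <- round(rnorm(n, ifelse(act == "pos", 0.5, 0), 1), 1)  # with ties
    expect_equal(rocAuc(act, sc, "pos")$auc, oracle_auc(act, sc, "pos"),
                 tolerance = 1e-9)
  }
  expect_error(rocAuc(rep("pos", 5), rnorm(5), "pos"), "argument error")
})

test_that("rocAuc agrees with an established ROC implementation", {
  set.seed(19)
  act <- sample(c("pos", "neg"), 150, TRUE)
  sc <- rnorm(150, ifelse(act == "pos", 0.8, 0))
  got <- rocAuc(act, sc, "pos")$auc
  want <- as.numeric(pROC::auc(pROC::roc(act, sc, levels = c("neg", "pos"),
                                         direction = "<", quiet = TRUE)))
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("time budgets assign 10 s per non-overlapping window", {
  tracks <- list(annotationTrack("c1", rbind(
    data.frame(behavior = "lying", tier = "state", start_s = 0, end_s = 86400),
    data.frame(behavior = "feeding", tier = "action", start_s = 0,
               end_s = 3600))))
  p <- data.frame(calf_id = "c1", start_s = seq(0, 86390, by = 10),
                  label = "lying")
  tb <- timeBudget(p, tracks, tier = "state")
  expect_equal(tb$predicted_s[tb$behavior == "lying"], 86400)
  expect_equal(tb$observed_s[tb$behavior == "lying"], 86400)

  p3 <- data.frame(calf_id = "c1", start_s = c(0, 10, 20),
                   label = "rumination")
  tb3 <- timeBudget(p3, tracks, tier = "action")
  expect_equal(tb3$predicted_s[tb3$behavior == "rumination"], 30)
  expect_equal(tb3$observed_s[tb3$behavior == "feeding"], 3600)
  # untagged action time counts as observed "others"
  expect_equal(tb3$observed_s[tb3$behavior == "others"], 86400 - 3600)

  pov <- data.frame(calf_id = "c1", start_s = c(0, 5), label = "lying")
  expect_error(timeBudget(pov, tracks), "aggregation error")
})

test_that("cough frequency compares daily counts", {
  tracks <- list(annotationTrack("c1", rbind(
    data.frame(behavior = "standing", tier = "state", start_s = 0,
               end_s = 7200),
    data.frame(behavior = "coughing", tier = "event",
               start_s = c(10, 500, 900), end_s = c(10.5, 500.6, 900.4)))))
  pred <- data.frame(calf_id = "c1", t_s = c(10.1, 500.2, 3000),
                     label = c("coughing", "coughing", "non_coughing"))
  cf <- coughFrequency(pred, tracks)
  expect_equal(cf$predicted_n, 2)
  expect_equal(cf$observed_n, 3)
})

test_that("pearsonR matches hand-computed covariance over SDs", {
  expect_equal(pearsonR(1:10, 1:10), 1)
  expect_equal(pearsonR(1:10, -2 * (1:10) + 7), -1)
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  # cov(x,y)/ (sd x sd y) = (sum((x-2.5)(y-2.5))/3) / (sd^2) = 0.6
  expect_equal(pearsonR(x, y), 0.6)
  expect_error(pearsonR(1:2, 1:2), "argument error")
  expect_error(pearsonR(rep(1, 5), 1:5), "undefined-correlation")
})

test_that("Cohen's kappa follows (P0 - Pc)/(1 - Pc)", {
  expect_equal(cohensKappa(letters[1:8], letters[1:8])$kappa, 1)

  k <- cohensKappa(table = matrix(c(20, 10, 5, 15), 2))
  expect_equal(k$p0, 0.7)
  expect_equal(k$pc, 0.5)
  expect_equal(k$kappa, 0.4)

  expect_error(cohensKappa(rep("a", 5), rep("a", 5)), "undefined-kappa")
  expect_error(cohensKappa(c("a", "b"), c("a")), "shape error")
})

test_that("kappa agrees with an established implementation", {
  set.seed(20)
  x <- sample(c("a", "b", "c"), 500, TRUE)
  y <- ifelse(runif(500) < 0.7, x, sample(c("a", "b", "c"), 500, TRUE))
  got <- cohensKappa(x, y)$kappa
  want <- e1071::classAgreement(table(x, y))$kappa
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("evaluationReport bundles metrics with one-vs-rest AUCs", {
  set.seed(21)
  act <- sample(c("lying", "standing"), 100, TRUE)
  probs <- data.frame(prob_lying = runif(100))
  probs$prob_standing <- 1 - probs$prob_lying
  pred <- ifelse(probs$prob_lying > 0.5, "lying", "standing")
  rep <- evaluationReport(act, pred, c("lying", "standing"), probs)
  expect_named(rep, c("confusion", "metrics", "auc"))
  expect_length(rep$auc, 2)
  # symmetric binary scores: the two one-vs-rest AUCs coincide
  expect_equal(unname(rep$auc["lying"]), unname(rep$auc["standing"]),
               tolerance = 1e-9)
})
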