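test_that("MR grading maps size change and cellularity to grades 1-5", {
  g <- mr_grade(c(0, 25, 50, 95, 10, -5, 30, 100),
                low_cellularity = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE,
                                    FALSE, FALSE),
                evident_tumor = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                                  FALSE))
  expect_identical(g$score, c(1L, 2L, 3L, 4L, 3L, 1L, 3L, 5L))
  expect_identical(g$derived_class,
                   c("NR", "NR", "R", "R", "R", "NR", "R", "R"))
  expect_error(mr_grade(120), "<= 100")
})

test_that("classification metrics reproduce confusion-matrix arithmetic", {
  # 56 R / 16 NR with TP=49, FN=7, TN=12, FP=4
  pred <- data.frame(
    true_class = rep(c("R", "R", "NR", "NR"), c(49, 7, 12, 4)),
    predicted_class = rep(c("R", "NR", "NR", "R"), c(49, 7, 12, 4)),
    vote_fraction = rep(c(0.9, 0.2, 0.1, 0.8), c(49, 7, 12, 4)))
  m <- classification_metrics(pred)
  expect_identical(c(m$TP, m$FN, m$TN, m$FP), c(49L, 7L, 12L, 4L))
  expect_equal(m$accuracy, 61 / 72)
  expect_equal(m$sensitivity, 49 / 56)
  expect_equal(m$specificity, 12 / 16)
  expect_equal(m$precision, 49 / 53)
  expect_equal(m$f_score, 2 * (49 / 53) * (49 / 56) / (49 / 53 + 49 / 56))

  # perfect predictions
  mp <- classification_metrics(data.frame(
    true_class = c("R", "R", "NR"), predicted_class = c("R", "R", "NR"),
    vote_fraction = c(1, 0.9, 0)))
  expect_equal(unlist(mp[c("accuracy", "sensitivity", "specificity",
                           "precision", "f_score", "auc")]),
               setNames(rep(1, 6), c("accuracy", "sensitivity", "specificity",
                                     "precision", "f_score", "auc")))

  # uninformative constant score
  mc <- classification_metrics(data.frame(
    true_class = c("R", "R", "NR"), predicted_class = c("R", "R", "R"),
    vote_fraction = c(0.7, 0.7, 0.7)))
  expect_equal(mc$auc, 0.5)

  expect_warning(
    m1 <- classification_metrics(data.frame(
      true_class = c("R", "R"), predicted_class = c("R", "NR"),
      vote_fraction = c(0.9, 0.1))),
    "single-class")
  expect_true(is.na(m1$auc))
  expect_equal(m1$accuracy, 0.5)
})

test_that("in-package AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  truth <- rep(c("R", "NR"), c(30, 20))
  score <- rnorm(50) + (truth == "R")
  score[3] <- score[40]  # introduce a tie
  pred <- data.frame(true_class = truth, predicted_class = truth,
                     vote_fraction = score)
  m <- classification_metrics(pred)
  ref <- as.numeric(pROC::auc(pROC::roc(truth, score, levels = c("NR", "R"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(m$auc, ref, tolerance = 1e-12)
})

test_that("feature t-test behaves under no-difference, separation and label swap", {
  lab <- rep(c("R", "NR"), each = 10)
  same <- data.frame(patient_id = sprintf("P%02d", 1:20), label = lab,
                     A = rep(rnorm(10, 1, 0.5), 2))
  r <- feature_ttest(same, "A")
  expect_equal(r$t, 0, tolerance = 1e-12)
  expect_equal(r$p, 1, tolerance = 1e-12)

  set.seed(23)
  sep <- data.frame(patient_id = sprintf("P%02d", 1:20), label = lab,
                    A = c(rnorm(10, 0, 0.1), rnorm(10, 5, 0.1)))
  r2 <- feature_ttest(sep, "A")
  expect_lt(r2$p, 1e-6)

  swapped <- sep
  swapped$label <- ifelse(sep$label == "R", "NR", "R")
  r3 <- feature_ttest(swapped, "A")
  expect_equal(r3$t, -r2$t)
  expect_equal(r3$p, r2$p)

  const <- data.frame(patient_id = sprintf("P%02d", 1:20), label = lab, A = 1)
  expect_error(feature_ttest(const, "A"), "zero pooled variance")
})

test_that("KM curves match product-limit hand computations", {
  k <- km_curve(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(k$surv, c(2 / 3, 1 / 3, 0))

  k0 <- km_curve(c(1, 5, 9), c(FALSE, FALSE, FALSE))
  expect_true(all(k0$surv == 1))

  k1 <- km_curve(4, TRUE)
  expect_equal(k1$surv[k1$time == 4], 0)

  # random censored inputs vs a brute-force oracle
  set.seed(19)
  for (rep in 1:10) {
    n <- sample(5:25, 1)
    times <- round(rexp(n, 0.1), 1)
    events <- runif(n) < 0.7
    if (!any(events)) events[1] <- TRUE
    k <- km_curve(times, events)
    o <- oracle_km(times, events)
    got <- k[k$n_event > 0, c("time", "surv")]
    expect_equal(got$time, o$time)
    expect_equal(got$surv, o$surv, tolerance = 1e-12)
    expect_true(all(diff(k$surv) <= 1e-12))  # non-increasing
  }

  expect_error(km_curve(numeric(0), logical(0)), "empty")
})

test_that("log-rank test matches hand-computed risk-set arithmetic", {
  # identical groups: exchangeability
  t1 <- c(2, 4, 6, 8); e1 <- c(TRUE, FALSE, TRUE, FALSE)
  r <- logrank_test(t1, e1, t1, e1)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p, 1, tolerance = 1e-12)

  # A events at 1,2; B events at 3,4:
  # O-E for A = 2 - (1/2 + 1/3) = 7/6; V = 1/4 + 2/9 = 17/36
  # chi-square = (7/6)^2 / (17/36) = 49/17
  r2 <- logrank_test(c(1, 2), c(TRUE, TRUE), c(3, 4), c(TRUE, TRUE))
  expect_equal(r2$statistic, 49 / 17, tolerance = 1e-9)
  expect_equal(r2$p, pchisq(49 / 17, 1, lower.tail = FALSE), tolerance = 1e-12)

  expect_error(logrank_test(c(1, 2), c(FALSE, FALSE), c(3), c(FALSE)),
               "no events")
  expect_error(logrank_test(numeric(0), logical(0), c(1), c(TRUE)),
               "non-empty")
})

test_that("survival report stratifies by truth and by each prediction set", {
  cfg <- cohort_config(n_responders = 12L, n_nonresponders = 8L,
                       slice_grid = 16L, mean_slices = 3, seed = 77L)
  rec <- generate_cohort(cfg)$records

  perfect <- data.frame(patient_id = rec$patient_id,
                        predicted_class = rec$true_class)
  set.seed(3)
  noisy <- data.frame(patient_id = rec$patient_id,
                      predicted_class = sample(rec$true_class))
  rep_ <- survival_report(rec, list(model_a = perfect, model_b = noisy))
  expect_s3_class(rep_, "survival_report")
  expect_length(rep_, 3L)  # truth + 2 prediction sets
  expect_named(rep_, c("truth", "model_a", "model_b"))

  # predictions identical to truth reproduce the truth stratification
  expect_equal(rep_$model_a$curves$R$surv, rep_$truth$curves$R$surv)
  expect_equal(rep_$model_a$logrank$p, rep_$truth$logrank$p)

  bad <- data.frame(patient_id = paste0("X", rec$patient_id),
                    predicted_class = rec$true_class)
  expect_error(survival_report(rec, list(m = bad)), "mismatched")
})
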