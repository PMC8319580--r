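#' Modified-response (MR) grading
#'
#' Maps pathology fields to the 1-5 modified-response grade and the derived
#' response class. Grade 5: no evident tumor; grade 4: more than 90% size
#' reduction; grade 3: at least 30% reduction, or low residual cellularity;
#' grade 2: reduction in (0, 30); grade 1: no reduction. Grades 1-2 are
#' non-responders (NR), 3-5 responders (R). A reduction of exactly 30% is
#' grade 3 (R).
#'
#' @param size_reduction_pct tumor size reduction in percent (<= 100);
#'   vectorized.
#' @param low_cellularity very low residual tumor cellularity?
#' @param evident_tumor is tumor evident at all?
#' @return data.frame with columns `score` (integer 1-5) and
#'   `derived_class` ("R"/"NR").
#' @export
mr_grade <- function(size_reduction_pct, low_cellularity = FALSE,
                     evident_tumor = TRUE) {
  stopifnot(all(size_reduction_pct <= 100))
  n <- length(size_reduction_pct)
  low_cellularity <- rep_len(low_cellularity, n)
  evident_tumor <- rep_len(evident_tumor, n)
  score <- ifelse(!evident_tumor, 5L,
           ifelse(size_reduction_pct > 90, 4L,
           ifelse(size_reduction_pct >= 30 | low_cellularity, 3L,
           ifelse(size_reduction_pct > 0, 2L, 1L))))
  data.frame(score = as.integer(score),
             derived_class = ifelse(score >= 3L, "R", "NR"),
             stringsAsFactors = FALSE)
}

#' Classification metrics of LOPO predictions
#'
#' Confusion counts with R the positive class, the derived rates, and the
#' Mann-Whitney AUC of the vote fraction against the true class.
#'
#' @param predictions data.frame with `true_class`, `predicted_class` and
#'   `vote_fraction` (as from [lopo_evaluate()]).
#' @return a `metrics_report` list: TP, TN, FP, FN, accuracy, sensitivity,
#'   specificity, precision, f_score, auc. If only one true class is
#'   present the AUC is NA with a warning.
#' @export
classification_metrics <- function(predictions) {
  stopifnot(nrow(predictions) >= 1L,
            all(c("true_class", "predicted_class") %in% names(predictions)))
  truth <- predictions$true_class == "R"
  pred <- predictions$predicted_class == "R"
  TP <- sum(truth & pred); FN <- sum(truth & !pred)
  TN <- sum(!truth & !pred); FP <- sum(!truth & pred)
  auc <- if (length(unique(truth)) < 2L) {
    warning("AUC undefined: single-class truth")
    NA_real_
  } else {
    auc_mw(predictions$vote_fraction, truth)
  }
  sens <- TP / (TP + FN)
  prec <- TP / (TP + FP)
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN,
                 accuracy = (TP + TN) / (TP + TN + FP + FN),
                 sensitivity = sens,
                 specificity = TN / (TN + FP),
                 precision = prec,
                 f_score = 2 * prec * sens / (prec + sens),
                 auc = auc),
            class = "metrics_report")
}

#' Two-sample t-test of one feature between response classes
#'
#' Student's pooled-variance t-test of the feature between R and NR
#' patients (Welch's version behind `welch = TRUE`).
#'
#' @param table a feature table with >= 2 patients per class.
#' @param feature feature name.
#' @param welch use the Welch (unequal-variance) variant.
#' @return list(t, p).
#' @export
feature_ttest <- function(table, feature, welch = FALSE) {
  assert_feature_table(table)
  stopifnot(feature %in% feature_cols(table))
  xR <- table[[feature]][table$label == "R"]
  xN <- table[[feature]][table$label == "NR"]
  if (length(xR) < 2L || length(xN) < 2L) stop("need >= 2 patients per class")
  if (sd(xR) == 0 && sd(xN) == 0)
    stop("zero pooled variance for feature ", feature)
  tt <- t.test(xR, xN, var.equal = !welch)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Kaplan-Meier recurrence-free survival curve
#'
#' Product-limit estimator; censored subjects leave the risk set without a
#' step.
#'
#' @param times non-negative survival times (months).
#' @param events logical/0-1 event indicators (TRUE = recurrence observed).
#' @return a `km_curve` data.frame: time, n_risk, n_event, n_censor, surv.
#' @export
km_curve <- function(times, events) {
  if (length(times) == 0L) stop("empty input")
  stopifnot(length(times) == length(events), all(times >= 0))
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Log-rank test between two survival groups
#'
#' Standard log-rank chi-square with 1 degree of freedom.
#'
#' @param times_a,events_a group A survival times and event indicators.
#' @param times_b,events_b group B.
#' @return list(statistic, p).
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0L || length(times_b) == 0L)
    stop("both groups must be non-empty")
  if (sum(events_a) + sum(events_b) == 0)
    stop("no events in either group")
  time <- c(times_a, times_b)
  event <- as.integer(c(events_a, events_b))
  grp <- rep(c("A", "B"), c(length(times_a), length(times_b)))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ grp)
  list(statistic = unname(sd_$chisq),
       p = pchisq(sd_$chisq, df = 1L, lower.tail = FALSE))
}

#' Survival stratification report for true and predicted cohorts
#'
#' Kaplan-Meier curves and a log-rank p for the true R/NR split and for
#' each supplied prediction set (e.g. the textural, SDT and hybrid models).
#'
#' @param records patient records with `patient_id`, `true_class`,
#'   `survival_months`, `event`.
#' @param predictions named list of prediction data.frames (`patient_id`,
#'   `predicted_class`), each covering all records. May be empty.
#' @return a `survival_report`: named list (truth first) of
#'   list(curves = list(R, NR), logrank = list(statistic, p)).
#' @export
survival_report <- function(records, predictions = list()) {
  stopifnot(all(c("patient_id", "true_class", "survival_months", "event")
                %in% names(records)))
  strata <- c(list(truth = records$true_class),
              lapply(predictions, function(p) {
                m <- match(records$patient_id, p$patient_id)
                if (anyNA(m)) stop("mismatched patient ids in predictions")
                p$predicted_class[m]
              }))
  out <- lapply(strata, function(cls) {
    iR <- cls == "R"; iN <- cls == "NR"
    list(curves = list(
           R = km_curve(records$survival_months[iR], records$event[iR]),
           NR = km_curve(records$survival_months[iN], records$event[iN])),
         logrank = logrank_test(records$survival_months[iR],
                                records$event[iR],
                                records$survival_months[iN],
                                records$event[iN]))
  })
  structure(out, class = "survival_report")
}

#' Survival probability at a time point from a KM curve
#'
#' Step-function evaluation of the product-limit estimate.
#'
#' @param curve a [km_curve()].
#' @param t time (months).
#' @return estimated S(t).
#' @export
km_survival_at <- function(curve, t) {
  s <- curve$surv[curve$time <= t]
  if (length(s) == 0L) 1 else s[length(s)]
}
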