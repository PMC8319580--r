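#' Class-balancing configuration
#'
#' Defaults are the standard analysis configuration: plain SMOTE with
#' `k_neighbors = 3` and `random_state = 14`, minority oversampled to double
#' size, and `B = 300` bootstrap undersamples of the majority class.
#' `smote_m` (the borderline-SMOTE neighbor count, 5) is stored for
#' configuration fidelity but unused by plain SMOTE.
#'
#' @param smote_k neighbors used for SMOTE interpolation.
#' @param smote_m borderline-variant neighbor count (stored, unused).
#' @param smote_seed seed of the SMOTE/bootstrap randomness.
#' @param oversample_factor minority size multiplier (2 = double).
#' @param B number of bootstrap-balanced training sets.
#' @return a `balance_config` object.
#' @export
balance_config <- function(smote_k = 3L, smote_m = 5L, smote_seed = 14L,
                           oversample_factor = 2, B = 300L) {
  stopifnot(B >= 1L, smote_k >= 1L, oversample_factor >= 1)
  structure(list(smote_k = as.integer(smote_k), smote_m = as.integer(smote_m),
                 smote_seed = as.integer(smote_seed),
                 oversample_factor = oversample_factor, B = as.integer(B)),
            class = "balance_config")
}

#' Ensemble configuration
#'
#' Defaults are the standard analysis configuration: AdaBoost with depth-4
#' decision trees, 150 estimators, learning rate 0.1, responder (R) the
#' positive class, and a 50% majority-vote threshold (inclusive: a vote
#' fraction of exactly 0.5 predicts R).
#'
#' @param max_depth weak-learner tree depth.
#' @param n_estimators boosting rounds per classifier.
#' @param learning_rate AdaBoost shrinkage.
#' @param vote_threshold ensemble vote fraction at or above which R is
#'   predicted.
#' @param positive_class the predicted-positive label.
#' @return an `ensemble_config` object.
#' @export
ensemble_config <- function(max_depth = 4L, n_estimators = 150L,
                            learning_rate = 0.1, vote_threshold = 0.5,
                            positive_class = "R") {
  stopifnot(max_depth >= 1L, n_estimators >= 1L, learning_rate > 0,
            vote_threshold > 0, vote_threshold < 1)
  structure(list(max_depth = as.integer(max_depth),
                 n_estimators = as.integer(n_estimators),
                 learning_rate = learning_rate,
                 vote_threshold = vote_threshold,
                 positive_class = positive_class),
            class = "ensemble_config")
}

#' SMOTE oversampling of the minority class
#'
#' Returns the original rows plus synthetic rows up to
#' `factor x nrow(X)` total. Each synthetic row is a convex combination of a
#' minority row and one of its `k` nearest minority neighbors (Euclidean),
#' with interpolation coefficient uniform in [0, 1]. Deterministic given
#' `seed`.
#'
#' @param X numeric matrix (or data.frame of numerics) of minority rows.
#' @param factor oversampling factor (2 doubles the minority).
#' @param k number of nearest neighbors; must be < nrow(X).
#' @param seed integer seed.
#' @return matrix of `round(factor * nrow(X))` rows (originals first), with
#'   attribute `n_synthetic`.
#' @export
smote_oversample <- function(X, factor = 2, k = 3L, seed = 14L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n <= k) stop("minority count (", n, ") must exceed k (", k, ")")
  n_syn <- round((factor - 1) * n)
  if (n_syn == 0L) {
    out <- X
    attr(out, "n_synthetic") <- 0L
    return(out)
  }
  d <- as.matrix(dist(X))
  diag(d) <- Inf
  nn <- t(apply(d, 1L, function(r) order(r)[seq_len(k)]))

  syn <- with_seed(seed, {
    base <- rep_len(seq_len(n), n_syn)
    out <- matrix(0, n_syn, ncol(X))
    for (s in seq_len(n_syn)) {
      i <- base[s]
      j <- nn[i, sample.int(k, 1L)]
      gap <- runif(1)
      out[s, ] <- X[i, ] + gap * (X[j, ] - X[i, ])
    }
    out
  })
  colnames(syn) <- colnames(X)
  out <- rbind(X, syn)
  attr(out, "n_synthetic") <- n_syn
  attr(out, "parents") <- seq_len(n)
  out
}

#' Build B class-balanced training sets
#'
#' The minority class (determined from the training rows) is SMOTE-
#' oversampled once; each of the `B` sets pairs it with a bootstrap sample
#' (with replacement) of equal size from the majority rows, shuffled. Every
#' set is exactly class-balanced.
#'
#' @param train_table a feature table with both classes present.
#' @param balance a [balance_config()].
#' @param seed integer seed (defaults to `balance$smote_seed`).
#' @return list of `B` data.frames (`label` + feature columns). Each carries
#'   attribute `train_idx`: the `train_table` row indices that entered it
#'   (SMOTE parents and bootstrap draws); the list carries `minority_class`.
#' @export
make_balanced_sets <- function(train_table, balance = balance_config(),
                               seed = balance$smote_seed) {
  assert_feature_table(train_table)
  fc <- feature_cols(train_table)
  cls <- table(train_table$label)
  if (length(cls) < 2L) stop("both classes must be present")
  if (min(cls) == 0L) stop("empty class")
  minority <- names(cls)[which.min(cls)]   # ties resolve to first name
  min_idx <- which(train_table$label == minority)
  maj_idx <- which(train_table$label != minority)
  if (length(maj_idx) == 0L) stop("empty majority class")

  seeds <- derive_seeds(seed, balance$B + 1L)
  Xmin <- smote_oversample(as.matrix(train_table[min_idx, fc]),
                           balance$oversample_factor, balance$smote_k,
                           seeds[balance$B + 1L])
  n_over <- nrow(Xmin)
  min_df <- as.data.frame(Xmin)
  names(min_df) <- fc
  min_df <- cbind(label = minority, min_df, stringsAsFactors = FALSE)

  sets <- vector("list", balance$B)
  for (b in seq_len(balance$B)) {
    draw <- with_seed(seeds[b],
                      sample(maj_idx, n_over, replace = TRUE))
    maj_df <- cbind(label = train_table$label[draw],
                    train_table[draw, fc, drop = FALSE],
                    stringsAsFactors = FALSE)
    set <- rbind(min_df, maj_df)
    perm <- with_seed(seeds[b] + 1L, sample.int(nrow(set)))
    set <- set[perm, , drop = FALSE]
    rownames(set) <- NULL
    attr(set, "train_idx") <- sort(unique(c(min_idx, draw)))
    sets[[b]] <- set
  }
  attr(sets, "minority_class") <- minority
  sets
}

#' Train the AdaBoost-DT voting ensemble
#'
#' One AdaBoost decision-tree classifier per balanced training set, trained
#' on the named feature columns only.
#'
#' @param balanced_sets output of [make_balanced_sets()].
#' @param subset feature names the members may see.
#' @param ens an [ensemble_config()].
#' @return an `sdt_ensemble`: list(members, subset, config, B).
#' @export
train_ensemble <- function(balanced_sets, subset,
                           ens = ensemble_config()) {
  stopifnot(length(balanced_sets) >= 1L, length(subset) >= 1L)
  members <- lapply(balanced_sets, function(set) {
    if (!all(subset %in% names(set))) stop("subset not in training columns")
    y <- as.integer(set$label == ens$positive_class)
    if (length(unique(y)) < 2L) stop("single-class training set")
    .adaboost_fit_cpp(as.matrix(set[subset]), y, ens$max_depth,
                      ens$n_estimators, ens$learning_rate)
  })
  structure(list(members = members, subset = subset, config = ens,
                 B = length(members)),
            class = "sdt_ensemble")
}

#' Majority-vote prediction for one patient
#'
#' The vote fraction is the share of ensemble members predicting the
#' positive class; the label is positive when the fraction reaches the vote
#' threshold (inclusive).
#'
#' @param ensemble an [train_ensemble()] result.
#' @param row one-row data.frame (or named vector) with the subset features.
#' @return list(vote_fraction, predicted_class).
#' @export
predict_vote <- function(ensemble, row) {
  stopifnot(inherits(ensemble, "sdt_ensemble"))
  if (is.data.frame(row)) {
    if (!all(ensemble$subset %in% names(row)))
      stop("missing feature(s): ",
           paste(setdiff(ensemble$subset, names(row)), collapse = ", "))
    x <- as.matrix(row[1L, ensemble$subset, drop = FALSE])
  } else {
    if (!all(ensemble$subset %in% names(row)))
      stop("missing feature(s): ",
           paste(setdiff(ensemble$subset, names(row)), collapse = ", "))
    x <- matrix(row[ensemble$subset], nrow = 1L)
  }
  votes <- vapply(ensemble$members,
                  function(m) .adaboost_score_cpp(m, x) >= 0, logical(1))
  vf <- mean(votes)
  cfg <- ensemble$config
  list(vote_fraction = vf,
       predicted_class = if (vf >= cfg$vote_threshold) cfg$positive_class
                         else "NR")
}

#' Leak-free leave-one-patient-out evaluation
#'
#' For every patient: remove the patient, re-balance (SMOTE + bootstrap) and
#' re-train the full ensemble on the remainder, and predict the held-out
#' patient. The held-out row never enters SMOTE neighbor search, bootstrap
#' draws or training; the returned attribute `fold_train_idx` records, per
#' fold, every original row index that entered any training computation, so
#' the isolation can be audited.
#'
#' @param table a feature table with >= 2 patients per class.
#' @param subset feature names used by the classifiers.
#' @param balance a [balance_config()].
#' @param ens an [ensemble_config()].
#' @param seed integer seed; per-fold seeds are derived from it.
#' @return data.frame with one row per patient (`patient_id`, `true_class`,
#'   `vote_fraction`, `predicted_class`), attribute `fold_train_idx`.
#' @export
lopo_evaluate <- function(table, subset, balance = balance_config(),
                          ens = ensemble_config(), seed = 1L) {
  assert_feature_table(table)
  if (min(table(table$label)) < 2L) stop("need >= 2 patients per class")
  n <- nrow(table)
  fold_seeds <- derive_seeds(seed, n)
  preds <- vector("list", n)
  used <- vector("list", n)
  for (i in seq_len(n)) {
    train <- table[-i, , drop = FALSE]
    sets <- make_balanced_sets(train, balance, seed = fold_seeds[i])
    fit <- train_ensemble(sets, subset, ens)
    p <- predict_vote(fit, table[i, , drop = FALSE])
    preds[[i]] <- data.frame(patient_id = table$patient_id[i],
                             true_class = table$label[i],
                             vote_fraction = p$vote_fraction,
                             predicted_class = p$predicted_class,
                             stringsAsFactors = FALSE)
    # map train-table row indices back to original table rows
    orig <- seq_len(n)[-i]
    used[[i]] <- sort(unique(orig[unlist(lapply(sets, attr, "train_idx"))]))
  }
  out <- do.call(rbind, preds)
  rownames(out) <- NULL
  attr(out, "fold_train_idx") <- used
  out
}
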