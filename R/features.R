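#' Robust-scale a feature table
#'
#' Standardizes each feature independently to `(x - median) / IQR` so the
#' median moves to zero and the interquartile range to one. Quartiles use
#' linear interpolation between order statistics.
#'
#' @param table a feature table (`patient_id`, `label`, feature columns).
#' @return the scaled table, with attributes `center` (medians) and
#'   `scale` (IQRs) per feature.
#' @export
robust_scale <- function(table) {
  assert_feature_table(table)
  fc <- feature_cols(table)
  centers <- scales <- setNames(numeric(length(fc)), fc)
  for (f in fc) {
    q <- quantile(table[[f]], c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    if (iqr == 0) stop("zero IQR for feature ", f)
    centers[f] <- q[2]; scales[f] <- iqr
    table[[f]] <- (table[[f]] - q[2]) / iqr
  }
  attr(table, "center") <- centers
  attr(table, "scale") <- scales
  table
}

#' Inter-feature coefficient-of-determination matrix
#'
#' Squared Pearson correlation for every feature pair.
#'
#' @param table a feature table with at least 3 patients.
#' @return a symmetric features x features matrix of R^2 with unit diagonal.
#' @export
correlation_matrix <- function(table) {
  assert_feature_table(table)
  if (nrow(table) < 3L) stop("need at least 3 patients")
  X <- as.matrix(table[feature_cols(table)])
  if (any(apply(X, 2L, sd) == 0))
    stop("constant feature column: R^2 undefined")
  R2 <- cor(X)^2
  diag(R2) <- 1
  R2
}

# --- mutual information on 3-bin discretized features -----------------------

# Discretize columns of X at mean +/- sd into bins 1..3 (Peng's mRMR
# convention for continuous variables).
discretize3 <- function(X) {
  m <- colMeans(X)
  s <- apply(X, 2L, sd)
  lo <- sweep(X, 2L, m - s, ">")
  hi <- sweep(X, 2L, m + s, ">")
  matrix(1L + lo + hi, nrow(X), ncol(X), dimnames = dimnames(X))
}

# Mutual information (bits) between each discretized column of D and a
# discrete class vector.
mi_with_class <- function(D, y) {
  n <- nrow(D)
  yl <- sort(unique(y))
  Y <- vapply(yl, function(v) as.numeric(y == v), numeric(n))
  ny <- colSums(Y)
  out <- numeric(ncol(D))
  for (a in 1:3) {
    Ia <- D == a
    na <- colSums(Ia)                       # per-feature marginal of bin a
    Cab <- crossprod(Ia, Y)                 # features x classes joint counts
    for (k in seq_along(yl)) {
      c_ <- Cab[, k]
      pos <- c_ > 0
      out[pos] <- out[pos] +
        c_[pos] / n * log2(c_[pos] * n / (na[pos] * ny[k]))
    }
  }
  setNames(out, colnames(D))
}

# Pairwise mutual information (bits) between all discretized columns.
mi_pairwise <- function(D) {
  n <- nrow(D)
  F_ <- ncol(D)
  I <- lapply(1:3, function(a) D == a)
  marg <- vapply(I, colSums, numeric(F_))   # features x 3
  out <- matrix(0, F_, F_, dimnames = list(colnames(D), colnames(D)))
  for (a in 1:3) {
    for (b in 1:3) {
      C <- crossprod(I[[a]], I[[b]])
      denom <- outer(marg[, a], marg[, b])
      pos <- C > 0
      out[pos] <- out[pos] + C[pos] / n * log2(C[pos] * n / denom[pos])
    }
  }
  out
}

# Greedy mRMR ranking (difference form: relevance minus mean redundancy)
# over all columns; returns the full ordered feature list.
mrmr_rank_once <- function(X, y) {
  D <- discretize3(X)
  rel <- mi_with_class(D, y)
  red <- mi_pairwise(D)
  fn <- colnames(X)
  F_ <- length(fn)
  sel <- integer(0)
  remaining <- seq_len(F_)
  for (pos in seq_len(F_)) {
    score <- if (length(sel) == 0L) rel[remaining]
             else rel[remaining] -
                  rowMeans(red[remaining, sel, drop = FALSE])
    pick <- remaining[which.max(score)]
    sel <- c(sel, pick)
    remaining <- setdiff(remaining, pick)
  }
  fn[sel]
}

#' mRMR feature ranking under leave-one-patient-out cross-validation
#'
#' Ranks the features of each LOPO fold's training rows by greedy mRMR
#' (mutual-information difference form: relevance to the class minus mean
#' redundancy to already-ranked features; features discretized into 3 bins
#' at mean +/- sd). Fold rankings are consolidated position by position:
#' each rank is assigned the not-yet-placed feature appearing most often at
#' that position across folds (ties broken by mean fold rank, then name).
#'
#' @param table a feature table; both classes must be present in every fold.
#' @param keep number of top features to retain (default 8).
#' @return a `ranked_features` object: list(features = top `keep` names,
#'   occurrence = times each retained feature held its position across
#'   folds, consolidated = full consolidated ranking, tally = features x
#'   positions count matrix).
#' @export
mrmr_rank_lopo <- function(table, keep = 8L) {
  assert_feature_table(table)
  fc <- feature_cols(table)
  keep <- as.integer(keep)
  stopifnot(keep >= 1L, keep <= length(fc))
  n <- nrow(table)
  X <- as.matrix(table[fc])
  y <- table$label
  if (length(unique(y)) < 2L) stop("both classes must be present")

  F_ <- length(fc)
  tally <- matrix(0L, F_, F_, dimnames = list(fc, NULL))
  ranksum <- setNames(numeric(F_), fc)
  for (i in seq_len(n)) {
    yi <- y[-i]
    if (length(unique(yi)) < 2L)
      stop("degenerate single-class fold when leaving out patient ", i)
    r <- mrmr_rank_once(X[-i, , drop = FALSE], yi)
    for (pos in seq_len(F_)) tally[r[pos], pos] <- tally[r[pos], pos] + 1L
    ranksum[r] <- ranksum[r] + seq_len(F_)
  }
  meanrank <- ranksum / n

  consolidated <- character(F_)
  placed <- character(0)
  for (pos in seq_len(F_)) {
    rem <- setdiff(fc, placed)
    cnt <- tally[rem, pos]
    best <- rem[cnt == max(cnt)]
    if (length(best) > 1L) {
      mr <- meanrank[best]
      best <- best[mr == min(mr)]
      best <- sort(best)[1L]
    }
    consolidated[pos] <- best
    placed <- c(placed, best)
  }
  occurrence <- vapply(seq_len(keep),
                       function(p) tally[consolidated[p], p], integer(1))
  structure(list(features = consolidated[seq_len(keep)],
                 occurrence = setNames(occurrence, consolidated[seq_len(keep)]),
                 consolidated = consolidated, tally = tally),
            class = "ranked_features")
}

# --- 0.632+ bootstrap AUC ---------------------------------------------------

#' Combine apparent and bootstrap AUC with the 0.632+ rule
#'
#' Given the apparent (resubstitution) AUC and the mean out-of-bag bootstrap
#' AUC, with no-information rate `gamma` (0.5 for AUC): the bootstrap value
#' is floored at `gamma`; the relative overfitting rate is
#' `R = (auc_app - boot') / (auc_app - gamma)` clamped to `[0, 1]` (0 when
#' `auc_app <= gamma`); the weight is `w = 0.632 / (1 - 0.368 R)`; the
#' estimate is `(1 - w) auc_app + w boot'`.
#'
#' @param auc_app apparent AUC.
#' @param auc_boot mean out-of-bag bootstrap AUC.
#' @param gamma no-information AUC (default 0.5).
#' @return an `auc632` object: list(auc_app, auc_boot, R, w, auc632plus).
#' @export
auc632_combine <- function(auc_app, auc_boot, gamma = 0.5) {
  boot_p <- max(auc_boot, gamma)
  R <- if (auc_app <= gamma) 0
       else min(max((auc_app - boot_p) / (auc_app - gamma), 0), 1)
  w <- 0.632 / (1 - 0.368 * R)
  structure(list(auc_app = auc_app, auc_boot = auc_boot, R = R, w = w,
                 auc632plus = (1 - w) * auc_app + w * boot_p),
            class = "auc632")
}

# Fit the selection-time classifier (same AdaBoost-DT family as the final
# ensemble) and return its continuous decision score, R positive.
fit_score_model <- function(X, y01, cfg) {
  .adaboost_fit_cpp(X, as.integer(y01), cfg$max_depth, cfg$n_estimators,
                    cfg$learning_rate)
}

#' 0.632+ bootstrap AUC of a feature subset
#'
#' Trains the AdaBoost decision-tree classifier on all training rows to get
#' the apparent AUC, then on `B_sel` bootstrap replicates scored on their
#' out-of-bag rows (replicates whose bootstrap sample or out-of-bag set is
#' single-class are skipped), and combines the two with [auc632_combine()].
#'
#' @param train a feature table containing both classes.
#' @param subset non-empty character vector of feature names.
#' @param model_config an [ensemble_config()] (weak-learner settings reused).
#' @param B_sel number of bootstrap replicates (>= 1).
#' @param seed integer seed for the bootstrap draws.
#' @return an `auc632` object (see [auc632_combine()]).
#' @export
auc632plus <- function(train, subset, model_config = ensemble_config(),
                       B_sel = 50L, seed = 1L) {
  assert_feature_table(train)
  stopifnot(length(subset) >= 1L, all(subset %in% feature_cols(train)))
  if (B_sel < 1L) stop("B_sel must be >= 1")
  y <- as.integer(train$label == model_config$positive_class)
  if (length(unique(y)) < 2L) stop("both classes required")
  X <- as.matrix(train[subset])
  n <- nrow(X)

  fit <- fit_score_model(X, y, model_config)
  auc_app <- auc_mw(.adaboost_score_cpp(fit, X), y == 1L)

  boot_seeds <- derive_seeds(seed, B_sel)
  aucs <- rep(NA_real_, B_sel)
  for (b in seq_len(B_sel)) {
    idx <- with_seed(boot_seeds[b], sample.int(n, n, replace = TRUE))
    oob <- setdiff(seq_len(n), idx)
    if (length(unique(y[idx])) < 2L) next
    if (length(unique(y[oob])) < 2L) next
    fb <- fit_score_model(X[idx, , drop = FALSE], y[idx], model_config)
    aucs[b] <- auc_mw(.adaboost_score_cpp(fb, X[oob, , drop = FALSE]),
                      y[oob] == 1L)
  }
  if (all(is.na(aucs)))
    stop("all bootstrap out-of-bag sets were single-class")
  auc632_combine(auc_app, mean(aucs, na.rm = TRUE))
}

#' Sequential forward selection scored by LOPO-averaged 0.632+ AUC
#'
#' Starting from the top-ranked candidate, repeatedly adds the candidate
#' that maximizes the subset's score until the candidate list is exhausted,
#' then returns the prefix with the maximum score. The score of a subset is
#' the [auc632plus()] value computed on each LOPO fold's training rows and
#' averaged over folds (set `lopo = FALSE` to score once on the full table).
#'
#' @param table a feature table.
#' @param candidates a [mrmr_rank_lopo()] result or character vector; the
#'   first element seeds the subset.
#' @param model_config an [ensemble_config()].
#' @param B_sel bootstrap replicates inside the estimator.
#' @param seed integer seed.
#' @param lopo average the score over LOPO folds (default) or score once.
#' @return list(selected, trace) where `trace` is a data.frame with one row
#'   per subset size (feature added, score).
#' @export
sfs_select <- function(table, candidates, model_config = ensemble_config(),
                       B_sel = 50L, seed = 1L, lopo = TRUE) {
  assert_feature_table(table)
  if (inherits(candidates, "ranked_features")) candidates <- candidates$features
  if (length(candidates) == 0L) stop("empty candidate list")
  stopifnot(all(candidates %in% feature_cols(table)))
  n <- nrow(table)
  fold_seeds <- derive_seeds(seed, n + 1L)

  score_subset <- function(subset) {
    if (!lopo)
      return(auc632plus(table, subset, model_config, B_sel,
                        fold_seeds[n + 1L])$auc632plus)
    mean(vapply(seq_len(n), function(i) {
      auc632plus(table[-i, , drop = FALSE], subset, model_config, B_sel,
                 fold_seeds[i])$auc632plus
    }, numeric(1)))
  }

  subset <- candidates[1L]
  trace <- data.frame(size = 1L, added = candidates[1L],
                      score = score_subset(subset),
                      stringsAsFactors = FALSE)
  remaining <- setdiff(candidates, subset)
  while (length(remaining) > 0L) {
    scores <- vapply(remaining, function(f) score_subset(c(subset, f)),
                     numeric(1))
    best <- remaining[which.max(scores)]
    subset <- c(subset, best)
    trace <- rbind(trace, data.frame(size = length(subset), added = best,
                                     score = max(scores),
                                     stringsAsFactors = FALSE))
    remaining <- setdiff(remaining, best)
  }
  list(selected = subset[seq_len(which.max(trace$score))], trace = trace)
}
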