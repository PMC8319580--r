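# Independent oracles and small fixtures shared across the suite.

# -- GLCM oracle: offset-shift construction, independent of compute_glcm ----
oracle_glcm <- function(window, distance, angle, Ng) {
  off <- switch(as.character(angle),
                "0" = c(0L, distance), "45" = c(-distance, distance),
                "90" = c(-distance, 0L), "135" = c(-distance, -distance))
  nr <- nrow(window); nc <- ncol(window)
  rs <- seq_len(nr); cs <- seq_len(nc)
  r1 <- rs[rs + off[1] >= 1 & rs + off[1] <= nr]
  c1 <- cs[cs + off[2] >= 1 & cs + off[2] <= nc]
  p <- matrix(0, Ng, Ng)
  a <- window[r1, c1, drop = FALSE]
  b <- window[r1 + off[1], c1 + off[2], drop = FALSE]
  for (k in seq_along(a)) {
    p[a[k], b[k]] <- p[a[k], b[k]] + 1
    p[b[k], a[k]] <- p[b[k], a[k]] + 1
  }
  p / sum(p)
}

# -- parametric-map oracle: naive per-pixel loop over compute_glcm ----------
oracle_maps <- function(q, win = 3L, step = 1L, dist = 1L,
                        angles = c(0L, 45L, 90L, 135L)) {
  half <- win %/% 2L
  nr <- nrow(q$levels); nc <- ncol(q$levels)
  maps <- replicate(8, matrix(NA_real_, nr, nc), simplify = FALSE)
  names(maps) <- c("ENT", "CON", "COR", "MAX", "MEA", "HOM", "STD", "ENE")
  validity <- matrix(FALSE, nr, nc)
  for (r0 in seq(half + 1L, nr - half, by = step)) {
    for (c0 in seq(half + 1L, nc - half, by = step)) {
      rows <- (r0 - half):(r0 + half); cols <- (c0 - half):(c0 + half)
      if (!all(q$mask[rows, cols])) next
      w <- q$levels[rows, cols]
      f <- rowMeans(vapply(angles, function(a)
        texture_features(compute_glcm(w, dist, a, Ng = q$Ng)), numeric(8)))
      for (m in seq_along(maps)) maps[[m]][r0, c0] <- f[m]
      validity[r0, c0] <- TRUE
    }
  }
  list(maps = maps, validity = validity)
}

# -- mutual information / mRMR oracle: table()-based, loop-based ------------
oracle_mi <- function(a, b) {
  tb <- table(a, b)
  n <- sum(tb)
  s <- 0
  for (i in seq_len(nrow(tb))) for (j in seq_len(ncol(tb))) {
    if (tb[i, j] > 0)
      s <- s + tb[i, j] / n * log2(tb[i, j] * n /
                                   (sum(tb[i, ]) * sum(tb[, j])))
  }
  s
}

oracle_discretize <- function(x) {
  m <- mean(x); s <- sd(x)
  ifelse(x > m + s, 3L, ifelse(x > m - s, 2L, 1L))
}

oracle_mrmr_rank <- function(X, y) {
  D <- apply(X, 2L, oracle_discretize)
  fn <- colnames(X)
  rel <- vapply(fn, function(f) oracle_mi(D[, f], y), numeric(1))
  sel <- character(0)
  rem <- fn
  while (length(rem) > 0L) {
    sc <- vapply(rem, function(f) {
      if (length(sel) == 0L) rel[f]
      else rel[f] - mean(vapply(sel, function(s) oracle_mi(D[, f], D[, s]),
                                numeric(1)))
    }, numeric(1))
    pick <- rem[which.max(sc)]
    sel <- c(sel, pick)
    rem <- setdiff(rem, pick)
  }
  sel
}

# Consolidation oracle: most-frequent-at-position with mean-rank then name
# tie-breaks, skipping placed features.
oracle_consolidate <- function(rankings) {
  fn <- rankings[[1]]
  F_ <- length(fn)
  tally <- matrix(0L, F_, F_, dimnames = list(sort(fn), NULL))
  ranksum <- setNames(numeric(F_), sort(fn))
  for (r in rankings) {
    for (pos in seq_len(F_)) tally[r[pos], pos] <- tally[r[pos], pos] + 1L
    ranksum[r] <- ranksum[r] + seq_len(F_)
  }
  meanrank <- ranksum / length(rankings)
  placed <- character(0)
  out <- character(F_)
  for (pos in seq_len(F_)) {
    rem <- setdiff(rownames(tally), placed)
    cnt <- tally[rem, pos]
    best <- rem[cnt == max(cnt)]
    if (length(best) > 1L) {
      best <- best[meanrank[best] == min(meanrank[best])]
      best <- sort(best)[1L]
    }
    out[pos] <- best
    placed <- c(placed, best)
  }
  out
}

# -- product-limit oracle ----------------------------------------------------
oracle_km <- function(times, events) {
  ut <- sort(unique(times[events > 0]))
  s <- 1
  surv <- numeric(length(ut))
  for (k in seq_along(ut)) {
    at_risk <- sum(times >= ut[k])
    d <- sum(times == ut[k] & events > 0)
    s <- s * (1 - d / at_risk)
    surv[k] <- s
  }
  data.frame(time = ut, surv = surv)
}

# -- fixtures ----------------------------------------------------------------

# Random feature table; `signal` shifts feature means between classes.
random_table <- function(n_R = 8L, n_NR = 4L, n_feat = 5L, seed = 1L,
                         signal = 0) {
  set.seed(seed)
  n <- n_R + n_NR
  lab <- rep(c("R", "NR"), c(n_R, n_NR))
  X <- matrix(rnorm(n * n_feat), n, n_feat)
  X[lab == "R", ] <- X[lab == "R", ] + signal
  colnames(X) <- paste0("F", seq_len(n_feat))
  data.frame(patient_id = sprintf("P%03d", seq_len(n)), label = lab, X,
             stringsAsFactors = FALSE)
}

# Small synthetic cohort with class-separated texture, cached per session.
.fixture_env <- new.env(parent = emptyenv())
shared_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    cfg <- cohort_config(n_responders = 8L, n_nonresponders = 4L,
                         slice_grid = 32L, mean_slices = 4, seed = 42L)
    .fixture_env$cohort <- generate_cohort(cfg)
  }
  .fixture_env$cohort
}

shared_features <- function() {
  if (is.null(.fixture_env$features)) {
    co <- shared_cohort()
    .fixture_env$features <- build_feature_table(co$images, co$records)
  }
  .fixture_env$features
}

# Random quantized slice with a ragged mask.
random_quantized_slice <- function(n = 16L, Ng = 16L, seed = 1L,
                                   mask_frac = 0.85) {
  set.seed(seed)
  x <- matrix(rnorm(n * n), n, n)
  mask <- matrix(runif(n * n) < mask_frac, n, n)
  while (sum(mask) < 9L) mask[sample.int(n * n, 1L)] <- TRUE
  quantize(x, mask, Ng)
}
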