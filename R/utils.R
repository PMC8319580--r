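.TEX_NAMES <- c("ENT", "CON", "COR", "MAX", "MEA", "HOM", "STD", "ENE")

#' Canonical feature names
#'
#' The 72 tumor features in their fixed order: the 8 first-pass textural
#' features (ENT, CON, COR, MAX, MEA, HOM, STD, ENE) followed by the 64
#' second-derivative texture (SDT) features named `MAP_FEATURE`, map-major
#' (ENT_ENT, ENT_CON, ..., ENE_ENE). `ENT_CON` is the contrast of the
#' entropy parametric map.
#'
#' @param set one of `"hybrid"` (all 72), `"textural"` (8) or `"sdt"` (64).
#' @return character vector of feature names.
#' @export
feature_names <- function(set = c("hybrid", "textural", "sdt")) {
  set <- match.arg(set)
  sdt <- paste(rep(.TEX_NAMES, each = 8L), rep(.TEX_NAMES, times = 8L),
               sep = "_")
  switch(set,
    textural = .TEX_NAMES,
    sdt      = sdt,
    hybrid   = c(.TEX_NAMES, sdt))
}

# Columns of a feature table that are features (not id/label bookkeeping).
feature_cols <- function(table) {
  setdiff(names(table), c("patient_id", "label"))
}

# Validate the patients x features + label layout used throughout.
assert_feature_table <- function(table) {
  stopifnot(is.data.frame(table))
  if (!all(c("patient_id", "label") %in% names(table)))
    stop("feature table needs 'patient_id' and 'label' columns")
  fc <- feature_cols(table)
  if (anyDuplicated(fc)) stop("duplicate feature names")
  vals <- as.matrix(table[fc])
  if (anyNA(vals) || any(!is.finite(vals)))
    stop("feature table contains missing or non-finite values")
  if (anyNA(table$label)) stop("label missing for some patients")
  invisible(table)
}

# Mann-Whitney AUC of a continuous score against a binary truth
# (ties counted 1/2, identical to the rank-sum formulation).
auc_mw <- function(score, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: both classes must be present")
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Deterministic per-unit seeds derived from one global seed.
derive_seeds <- function(seed, n) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  expr
}
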