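#' Texture extraction configuration
#'
#' Defaults are the standard analysis configuration: 128 gray levels, a 3x3
#' sliding window moved one pixel at a time, co-occurrences at one-pixel
#' distance along 0, 45, 90 and 135 degrees.
#'
#' @param Ng number of gray levels for quantization.
#' @param window_size odd sliding-window side length, pixels.
#' @param step window step, pixels.
#' @param distance co-occurrence offset, pixels.
#' @param angles subset of c(0, 45, 90, 135) degrees.
#' @return an object of class `texture_config`.
#' @export
texture_config <- function(Ng = 128L, window_size = 3L, step = 1L,
                           distance = 1L, angles = c(0L, 45L, 90L, 135L)) {
  stopifnot(Ng >= 2L, window_size %% 2L == 1L, step >= 1L, distance >= 1L,
            all(angles %in% c(0L, 45L, 90L, 135L)), length(angles) >= 1L)
  structure(list(Ng = as.integer(Ng), window_size = as.integer(window_size),
                 step = as.integer(step), distance = as.integer(distance),
                 angles = as.integer(angles)),
            class = "texture_config")
}

#' Quantize a slice to discrete gray levels
#'
#' Linear (equal-width) binning of the mask-true intensity range into `Ng`
#' levels 1..Ng; the maximum maps to level Ng. A constant region maps to
#' level 1. Quantization is range-relative, making downstream features
#' invariant to additive intensity shifts.
#'
#' @param intensities numeric matrix.
#' @param mask logical matrix, same shape; at least one TRUE pixel.
#' @param Ng number of gray levels.
#' @return a `quantized_slice`: list(levels, mask, Ng) with `levels` an
#'   integer matrix (NA outside the mask).
#' @export
quantize <- function(intensities, mask = NULL, Ng = 128L) {
  stopifnot(is.matrix(intensities), Ng >= 2L)
  if (is.null(mask)) mask <- !is.na(intensities)
  stopifnot(is.logical(mask), all(dim(mask) == dim(intensities)))
  if (!any(mask)) stop("empty mask: nothing to quantize")
  vals <- intensities[mask]
  lo <- min(vals); hi <- max(vals)
  levels <- matrix(NA_integer_, nrow(intensities), ncol(intensities))
  if (hi == lo) {
    levels[mask] <- 1L
  } else {
    l <- floor((intensities[mask] - lo) / (hi - lo) * Ng) + 1L
    levels[mask] <- as.integer(pmin(l, Ng))
  }
  structure(list(levels = levels, mask = mask, Ng = as.integer(Ng)),
            class = "quantized_slice")
}

#' Compute a symmetric GLCM for one window
#'
#' Counts every ordered pixel pair at the given offset together with its
#' reverse (symmetric accumulation) over a fully populated window of gray
#' levels, normalized to sum 1.
#'
#' @param window integer matrix of gray levels (no NA), e.g. a sub-grid of a
#'   [quantize()]d slice.
#' @param distance offset in pixels.
#' @param angle one of 0, 45, 90, 135 degrees.
#' @param Ng number of gray levels (defaults to `max(window)`).
#' @return a `glcm`: list(p = Ng x Ng matrix, distance, angle).
#' @export
compute_glcm <- function(window, distance = 1L, angle = 0L, Ng = max(window)) {
  stopifnot(is.matrix(window), !anyNA(window), distance >= 1L,
            angle %in% c(0L, 45L, 90L, 135L))
  off <- switch(as.character(angle),
                "0" = c(0L, distance), "45" = c(-distance, distance),
                "90" = c(-distance, 0L), "135" = c(-distance, -distance))
  nr <- nrow(window); nc <- ncol(window)
  p <- matrix(0, Ng, Ng)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      r2 <- r + off[1L]; c2 <- c + off[2L]
      if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
      i <- window[r, c]; j <- window[r2, c2]
      p[i, j] <- p[i, j] + 1
      p[j, i] <- p[j, i] + 1
    }
  }
  tot <- sum(p)
  if (tot == 0) stop("no valid pixel pairs at this offset")
  structure(list(p = p / tot, distance = as.integer(distance),
                 angle = as.integer(angle)), class = "glcm")
}

#' Haralick-type features of one GLCM
#'
#' With `p(i,j)` the normalized symmetric GLCM, `mu = sum i p(i,j)` and
#' `sigma^2 = sum (i - mu)^2 p(i,j)`:
#' entropy `ENT = -sum p log2 p` (over p > 0), contrast
#' `CON = sum (i-j)^2 p`, correlation
#' `COR = sum (i-mu)(j-mu) p / sigma^2` (1 for a constant window),
#' maximum probability `MAX`, mean `MEA = mu`, homogeneity
#' `HOM = sum p / (1 + (i-j)^2)`, standard deviation `STD = sigma`, and
#' energy (angular second moment) `ENE = sum p^2`.
#'
#' @param g a [compute_glcm()] result (or a normalized symmetric matrix).
#' @return named numeric vector of the 8 features.
#' @export
texture_features <- function(g) {
  p <- if (inherits(g, "glcm")) g$p else g
  stopifnot(is.matrix(p), nrow(p) == ncol(p))
  if (abs(sum(p) - 1) > 1e-8) stop("GLCM is not normalized")
  Ng <- nrow(p)
  i <- matrix(seq_len(Ng), Ng, Ng)        # row index = first level
  j <- t(i)
  mu <- sum(i * p)
  sig2 <- sum((i - mu)^2 * p)
  pos <- p > 0
  ent <- -sum(p[pos] * log2(p[pos]))
  con <- sum((i - j)^2 * p)
  cor <- if (sig2 > 1e-12) sum((i - mu) * (j - mu) * p) / sig2 else 1
  hom <- sum(p / (1 + (i - j)^2))
  c(ENT = ent, CON = con, COR = cor, MAX = max(p), MEA = mu, HOM = hom,
    STD = sqrt(sig2), ENE = sum(p^2))
}

#' Sliding-window parametric maps of the 8 GLCM features
#'
#' Sweeps a square window over the slice; for every window lying fully
#' inside the ROI mask, computes one symmetric GLCM per angle, averages each
#' feature over the angles, and assigns the result to the window's center
#' pixel. Windows touching the ROI boundary or image edge are skipped (no
#' padding), so the validity mask is an eroded subset of the ROI.
#'
#' @param q a [quantize()]d slice.
#' @param window_size,step,distance,angles see [texture_config()].
#' @return a `parametric_maps` object: list(maps = named list of 8 matrices,
#'   validity = logical matrix, n_valid).
#' @export
parametric_maps <- function(q, window_size = 3L, step = 1L, distance = 1L,
                            angles = c(0L, 45L, 90L, 135L)) {
  stopifnot(inherits(q, "quantized_slice"), window_size %% 2L == 1L)
  levels <- q$levels
  levels[is.na(levels)] <- 0L
  res <- .glcm_maps_cpp(levels, q$mask, as.integer(window_size),
                        as.integer(step), as.integer(distance),
                        as.integer(angles))
  if (res$n_valid == 0L)
    stop("ROI too small: no window fits fully inside the mask")
  maps <- res$maps
  names(maps) <- .TEX_NAMES
  structure(list(maps = maps, validity = res$validity,
                 n_valid = res$n_valid), class = "parametric_maps")
}

#' Second-derivative texture (SDT) features of one slice
#'
#' Each first-pass parametric map is re-quantized (same equal-width policy,
#' over its own observed range on the validity mask) and run through the
#' sliding-window analysis a second time. The slice-level SDT value for
#' `MAP_FEATURE` is the mean of the second-pass FEATURE map of MAP; the
#' slice-level first-pass textural features are the plain means of the 8
#' parametric maps.
#'
#' @param pm a [parametric_maps()] result.
#' @param config a [texture_config()].
#' @return named vector of 72 values (8 textural + 64 SDT), or `NULL` if the
#'   validity region is too small for any second-pass window (slice flagged
#'   for exclusion).
#' @export
sdt_features <- function(pm, config = texture_config()) {
  stopifnot(inherits(pm, "parametric_maps"))
  first <- vapply(pm$maps, function(m) mean(m[pm$validity]), numeric(1))
  names(first) <- .TEX_NAMES

  out <- numeric(0)
  for (mn in .TEX_NAMES) {
    q2 <- quantize(pm$maps[[mn]], pm$validity, config$Ng)
    pm2 <- tryCatch(
      parametric_maps(q2, config$window_size, config$step, config$distance,
                      config$angles),
      error = function(e) NULL)
    if (is.null(pm2)) return(NULL)   # too-small validity region: exclude slice
    second <- vapply(pm2$maps, function(m) mean(m[pm2$validity]), numeric(1))
    names(second) <- paste(mn, .TEX_NAMES, sep = "_")
    out <- c(out, second)
  }
  c(first, out)
}

#' Area-weighted aggregation of slice features over a tumor
#'
#' Each tumor-level feature is the ROI-area-weighted mean of the slice-level
#' values: `sum(area_s * value_s) / sum(area_s)`.
#'
#' @param slice_values list of equal-length named numeric vectors.
#' @param areas positive slice ROI areas (pixels).
#' @return named numeric vector.
#' @export
aggregate_tumor <- function(slice_values, areas) {
  if (length(slice_values) == 0L) stop("all slices excluded: nothing to aggregate")
  stopifnot(length(slice_values) == length(areas), all(areas > 0))
  V <- do.call(rbind, slice_values)
  w <- areas / sum(areas)
  colSums(V * w)
}

#' Extract the 72-feature vector of one tumor
#'
#' Per slice: quantize the ROI, build first-pass parametric maps, derive the
#' 8 map means and 64 SDT features; then aggregate over slices by ROI-area
#' weighting. Slices whose ROI cannot host a first- or second-pass window
#' are excluded.
#'
#' @param image a `tumor_image` (see [generate_cohort()]).
#' @param config a [texture_config()].
#' @return named numeric vector of 72 finite values.
#' @export
extract_features <- function(image, config = texture_config()) {
  stopifnot(inherits(image, "tumor_image"))
  n_slices <- dim(image$volume)[1L]
  vals <- list(); areas <- numeric(0)
  for (s in seq_len(n_slices)) {
    msk <- image$mask[s, , ]
    if (sum(msk) < config$window_size^2) next
    q <- quantize(image$volume[s, , ], msk, config$Ng)
    pm <- tryCatch(
      parametric_maps(q, config$window_size, config$step, config$distance,
                      config$angles),
      error = function(e) NULL)
    if (is.null(pm)) next
    v <- sdt_features(pm, config)
    if (is.null(v)) next
    vals[[length(vals) + 1L]] <- v
    areas <- c(areas, sum(msk))
  }
  if (length(vals) == 0L)
    stop("no usable slice in patient ", image$patient_id)
  out <- aggregate_tumor(vals, areas)
  stopifnot(length(out) == 72L, all(is.finite(out)))
  out[feature_names("hybrid")]
}

#' Build a patients x features table for a cohort
#'
#' @param images list of `tumor_image`.
#' @param records patient records with `patient_id` and `true_class`.
#' @param config a [texture_config()].
#' @return data.frame with `patient_id`, `label` (R/NR) and 72 feature
#'   columns in canonical order.
#' @export
build_feature_table <- function(images, records, config = texture_config()) {
  feats <- t(vapply(images, extract_features, numeric(72L), config = config))
  ids <- vapply(images, `[[`, character(1), "patient_id")
  lab <- records$true_class[match(ids, records$patient_id)]
  if (anyNA(lab)) stop("mismatched patient ids between images and records")
  out <- data.frame(patient_id = ids, label = lab, feats,
                    stringsAsFactors = FALSE, check.names = FALSE)
  assert_feature_table(out)
}

#' Write / read a feature table as CSV
#'
#' @param table a feature table.
#' @param path CSV path.
#' @return `path` (write) or the table (read).
#' @export
write_feature_table <- function(table, path) {
  assert_feature_table(table)
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  out <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  assert_feature_table(out)
}
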