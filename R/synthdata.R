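#' Synthetic cohort configuration
#'
#' Parameters of the synthetic LABC cohort generator. Defaults emulate the
#' study conditions the pipeline targets: 56 responders (R) and 16
#' non-responders (NR), a median of about 10 tumor slices per patient, and
#' ten-year recurrence-free survival of roughly 75% (R) versus 40% (NR, the
#' lower edge of the reported 40-60% band, which gives the log-rank test
#' usable power at this sample size).
#'
#' Tumor texture is a stationary Gaussian random field: white noise smoothed
#' with an isotropic Gaussian kernel whose width (the correlation length, in
#' pixels) is class specific. GLCM features such as contrast and entropy
#' respond monotonically to the correlation length, so
#' `texture_scale_R != texture_scale_NR` induces a class-conditional texture
#' difference; setting them equal (and the hazards equal) yields a null
#' cohort with no signal.
#'
#' @param n_responders,n_nonresponders class sizes; their sum must be >= 4.
#' @param slice_grid pixels per side of each square slice.
#' @param mean_slices mean slice count per tumor; counts are drawn as
#'   3 + Poisson(mean_slices - 3) so every tumor has at least 3 slices.
#' @param texture_scale_R,texture_scale_NR Gaussian correlation length in
#'   pixels for each class.
#' @param field_sd standard deviation of the correlated field (intensity
#'   units, before noise).
#' @param noise_sd standard deviation of added white noise.
#' @param base_level constant intensity offset.
#' @param hazard_R,hazard_NR exponential recurrence hazards (events/month).
#' @param dropout_rate hazard of random loss to follow-up (events/month);
#'   follow-up is additionally cut administratively at `censor_horizon`.
#' @param censor_horizon administrative censoring time in months.
#' @param pixel_spacing pixel spacing in mm (metadata only).
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_responders = 56L, n_nonresponders = 16L,
                          slice_grid = 64L, mean_slices = 10,
                          texture_scale_R = 2.5, texture_scale_NR = 1.2,
                          field_sd = 40, noise_sd = 5, base_level = 100,
                          hazard_R = log(1 / 0.75) / 120,
                          hazard_NR = log(1 / 0.40) / 120,
                          dropout_rate = 0.1 / 120,
                          censor_horizon = 120, pixel_spacing = 0.8,
                          seed = 7L) {
  cfg <- list(n_responders = as.integer(n_responders),
              n_nonresponders = as.integer(n_nonresponders),
              slice_grid = as.integer(slice_grid),
              mean_slices = mean_slices,
              texture_scale_R = texture_scale_R,
              texture_scale_NR = texture_scale_NR,
              field_sd = field_sd, noise_sd = noise_sd,
              base_level = base_level,
              hazard_R = hazard_R, hazard_NR = hazard_NR,
              dropout_rate = dropout_rate,
              censor_horizon = censor_horizon,
              pixel_spacing = pixel_spacing,
              seed = as.integer(seed))
  if (cfg$n_responders < 0L || cfg$n_nonresponders < 0L ||
      cfg$n_responders + cfg$n_nonresponders < 4L)
    stop("configuration error: need n_responders + n_nonresponders >= 4")
  if (cfg$slice_grid < 8L)
    stop("configuration error: slice_grid too small")
  if (cfg$mean_slices < 3)
    stop("configuration error: mean_slices must be >= 3")
  if (cfg$texture_scale_R <= 0 || cfg$texture_scale_NR <= 0 ||
      cfg$field_sd <= 0 || cfg$noise_sd < 0)
    stop("configuration error: non-positive texture parameters")
  if (cfg$hazard_R <= 0 || cfg$hazard_NR <= 0 || cfg$censor_horizon <= 0)
    stop("configuration error: non-positive hazards or censor horizon")
  class(cfg) <- "cohort_config"
  cfg
}

# Row-smoothing matrix for a Gaussian kernel of width sigma (pixels);
# applied as K %*% Z %*% t(K) it yields an isotropic correlated field.
gauss_smoother <- function(n, sigma) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  K <- exp(-d^2 / (2 * sigma^2))
  K / rowSums(K)
}

# Elliptical ROI mask centered in an n x n grid.
ellipse_mask <- function(n, a, b) {
  cx <- (n + 1) / 2
  x <- seq_len(n) - cx
  outer(x, x, function(r, c) (r / a)^2 + (c / b)^2 <= 1)
}

#' Generate a synthetic patient cohort
#'
#' Draws, for every patient, a stack of 2D tumor slices (elliptical ROIs with
#' varying axes on a correlated Gaussian intensity field plus white noise)
#' and a clinical record: the response class, the tumor-size-change and
#' residual-cellularity fields that determine the modified-response grade
#' (responders map to grade >= 3, non-responders to grade <= 2), and
#' exponentially distributed recurrence-free survival with random dropout and
#' administrative censoring. Fully reproducible from `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return a list with elements `images` (list of `tumor_image`: `patient_id`,
#'   `volume` and `mask` arrays of shape slices x rows x cols,
#'   `pixel_spacing`) and `records` (data.frame with one row per patient:
#'   `patient_id`, `true_class`, `size_reduction_pct`, `low_cellularity`,
#'   `evident_tumor`, `survival_months`, `event`).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)

  n <- config$n_responders + config$n_nonresponders
  classes <- rep(c("R", "NR"), c(config$n_responders, config$n_nonresponders))
  g <- config$slice_grid
  K_R <- gauss_smoother(g, config$texture_scale_R)
  K_NR <- if (config$texture_scale_NR == config$texture_scale_R) K_R
          else gauss_smoother(g, config$texture_scale_NR)

  images <- vector("list", n)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    cls <- classes[i]
    pid <- sprintf("P%03d", i)
    K <- if (cls == "R") K_R else K_NR
    n_slices <- 3L + rpois(1L, config$mean_slices - 3)

    vol <- array(0, dim = c(n_slices, g, g))
    msk <- array(FALSE, dim = c(n_slices, g, g))
    for (s in seq_len(n_slices)) {
      # cross-sectional area varies across slices via the ellipse axes
      a <- runif(1, 0.13, 0.30) * g
      b <- runif(1, 0.13, 0.30) * g
      field <- K %*% matrix(rnorm(g * g), g, g) %*% t(K)
      field <- field / sd(field) * config$field_sd
      vol[s, , ] <- config$base_level + field +
        rnorm(g * g, sd = config$noise_sd)
      msk[s, , ] <- ellipse_mask(g, a, b)
    }
    images[[i]] <- structure(
      list(patient_id = pid, volume = vol, mask = msk,
           pixel_spacing = config$pixel_spacing),
      class = "tumor_image")

    records[[i]] <- make_record(pid, cls, config)
  }
  records <- do.call(rbind, records)
  rownames(records) <- NULL
  list(images = images, records = records)
}

# One clinical record consistent with the modified-response grading:
# R patients receive size reductions / cellularity fields mapping to grade
# >= 3, NR patients to grade <= 2.
make_record <- function(pid, cls, config) {
  if (cls == "R") {
    u <- runif(1)
    if (u < 0.10) {            # complete response, no evident tumor
      evident <- FALSE; lowcell <- FALSE; red <- 100
    } else if (u < 0.25) {     # low residual cellularity, modest shrinkage
      evident <- TRUE; lowcell <- TRUE; red <- runif(1, 5, 29)
    } else {                   # >= 30% size reduction
      evident <- TRUE; lowcell <- FALSE; red <- runif(1, 30, 95)
    }
    hazard <- config$hazard_R
  } else {
    evident <- TRUE; lowcell <- FALSE
    red <- if (runif(1) < 0.4) runif(1, -20, 0) else runif(1, 1e-3, 29)
    hazard <- config$hazard_NR
  }
  t_event <- rexp(1, hazard)
  t_drop <- if (config$dropout_rate > 0) rexp(1, config$dropout_rate) else Inf
  t_cens <- min(t_drop, config$censor_horizon)
  data.frame(patient_id = pid, true_class = cls,
             size_reduction_pct = red, low_cellularity = lowcell,
             evident_tumor = evident,
             survival_months = min(t_event, t_cens),
             event = t_event <= t_cens,
             stringsAsFactors = FALSE)
}

#' Write a cohort to disk (NIfTI volumes + CSV patient table)
#'
#' Writes one NIfTI volume and one NIfTI mask per patient, a CSV patient
#' table, and a JSON manifest listing all file paths. Volumes are written as
#' float64 so read-back reproduces the arrays exactly.
#'
#' @param images,records as returned by [generate_cohort()].
#' @param out_dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(images, records, out_dir) {
  if (length(images) == 0L) stop("empty patient list")
  if (length(images) != nrow(records))
    stop("images and records are inconsistent")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)

  entries <- lapply(images, function(img) {
    vfile <- file.path(out_dir, paste0(img$patient_id, "_volume.nii.gz"))
    mfile <- file.path(out_dir, paste0(img$patient_id, "_mask.nii.gz"))
    RNifti::writeNifti(img$volume, vfile, datatype = "double")
    RNifti::writeNifti(array(as.integer(img$mask), dim = dim(img$mask)),
                       mfile, datatype = "uint8")
    list(patient_id = img$patient_id, volume = basename(vfile),
         mask = basename(mfile), pixel_spacing = img$pixel_spacing)
  })
  table_file <- file.path(out_dir, "patients.csv")
  write.csv(records, table_file, row.names = FALSE)
  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(patients = entries, patient_table = basename(table_file)),
    manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `manifest.json`.
#' @return a list with `images` and `records`, as from [generate_cohort()].
#' @export
read_cohort <- function(dir) {
  manifest <- file.path(dir, "manifest.json")
  if (!file.exists(manifest)) stop("no manifest.json in ", dir)
  m <- jsonlite::read_json(manifest)
  records <- read.csv(file.path(dir, m$patient_table),
                      stringsAsFactors = FALSE)
  images <- lapply(m$patients, function(e) {
    vol <- RNifti::readNifti(file.path(dir, e$volume))
    msk <- RNifti::readNifti(file.path(dir, e$mask))
    structure(list(patient_id = e$patient_id,
                   volume = array(as.numeric(vol), dim = dim(vol)),
                   mask = array(msk > 0, dim = dim(msk)),
                   pixel_spacing = e$pixel_spacing),
              class = "tumor_image")
  })
  list(images = images, records = records)
}
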