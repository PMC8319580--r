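#' End-to-end run configuration
#'
#' Bundles every stage's parameters. Defaults equal the standard analysis
#' configuration (128 gray levels, 3x3 window, top-8 mRMR retention, SMOTE
#' k=3 / seed 14 / double oversampling, B=300 balanced sets, AdaBoost depth
#' 4 / 150 estimators / learning rate 0.1, 50% vote threshold). Overrides
#' are recorded in the run manifest.
#'
#' @param out_dir output directory for all stage artifacts.
#' @param cohort a [cohort_config()] (used when `cohort_dir` is NULL).
#' @param cohort_dir optional directory of an existing cohort
#'   (see [write_cohort()]); when given, no cohort is synthesized.
#' @param texture a [texture_config()].
#' @param feature_set one of "hybrid", "textural", "sdt".
#' @param n_keep features retained from the mRMR ranking.
#' @param B_sel bootstrap replicates inside the 0.632+ estimator.
#' @param balance a [balance_config()].
#' @param ensemble an [ensemble_config()].
#' @param seed global seed; all stage seeds derive from it.
#' @return a `run_config` object.
#' @export
run_config <- function(out_dir = tempfile("sdtexture_run_"),
                       cohort = cohort_config(), cohort_dir = NULL,
                       texture = texture_config(),
                       feature_set = c("hybrid", "textural", "sdt"),
                       n_keep = 8L, B_sel = 50L,
                       balance = balance_config(),
                       ensemble = ensemble_config(), seed = 1L) {
  feature_set <- match.arg(feature_set)
  structure(list(out_dir = out_dir, cohort = cohort, cohort_dir = cohort_dir,
                 texture = texture, feature_set = feature_set,
                 n_keep = as.integer(n_keep), B_sel = as.integer(B_sel),
                 balance = balance, ensemble = ensemble,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the whole pipeline
#'
#' Executes generate (or load) -> extract -> scale -> rank/select ->
#' LOPO-evaluate -> survival analysis, writing the feature CSV, selection
#' JSON, prediction CSV, metrics JSON, survival JSON and a run manifest to
#' `config$out_dir`. Reruns with an identical config reproduce identical
#' outputs.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the in-memory stage results
#'   (`features`, `ranking`, `selection`, `predictions`, `metrics`,
#'   `survival`, `manifest`).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  timings <- list()
  stage <- function(name, expr) {
    s <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    timings[[name]] <<- round(as.numeric(Sys.time() - s, units = "secs"), 3)
    out
  }

  cohort <- stage("cohort", {
    if (is.null(config$cohort_dir)) generate_cohort(config$cohort)
    else read_cohort(config$cohort_dir)
  })

  features <- stage("extract", {
    tab <- build_feature_table(cohort$images, cohort$records, config$texture)
    write_feature_table(tab, file.path(config$out_dir, "features.csv"))
    tab
  })

  scaled <- stage("scale", robust_scale(features))
  keep_cols <- c("patient_id", "label", feature_names(config$feature_set))
  scaled <- scaled[keep_cols]

  ranking <- stage("rank", mrmr_rank_lopo(scaled, config$n_keep))
  selection <- stage("select",
    sfs_select(scaled, ranking, config$ensemble, config$B_sel,
               seed = config$seed))
  jsonlite::write_json(
    list(feature_set = config$feature_set,
         ranking = ranking$features,
         occurrence = as.list(ranking$occurrence),
         sfs_trace = selection$trace,
         selected = selection$selected),
    file.path(config$out_dir, "selection.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)

  predictions <- stage("evaluate",
    lopo_evaluate(scaled, selection$selected, config$balance,
                  config$ensemble, seed = config$seed))
  write.csv(predictions, file.path(config$out_dir, "predictions.csv"),
            row.names = FALSE)

  metrics <- stage("metrics", classification_metrics(predictions))
  jsonlite::write_json(unclass(metrics),
                       file.path(config$out_dir, "metrics.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  surv <- stage("survive", {
    preds <- setNames(list(predictions), config$feature_set)
    survival_report(cohort$records, preds)
  })
  jsonlite::write_json(
    lapply(surv, function(s) list(
      logrank_statistic = s$logrank$statistic, logrank_p = s$logrank$p,
      curves = lapply(s$curves, as.data.frame))),
    file.path(config$out_dir, "survival.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)

  manifest <- list(
    package_version = as.character(utils::packageVersion("sdtexture")),
    seed = config$seed,
    config = serialize_config(config),
    stage_timings_s = timings,
    outputs = c("features.csv", "selection.json", "predictions.csv",
                "metrics.json", "survival.json"),
    total_s = round(as.numeric(Sys.time() - t0, units = "secs"), 3))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(features = features, ranking = ranking,
                 selection = selection, predictions = predictions,
                 metrics = metrics, survival = surv, manifest = manifest))
}

# Config <-> plain-list (JSON-ready) round trip for the run manifest.
serialize_config <- function(config) {
  lapply(unclass(config), function(x) if (is.list(x)) unclass(x) else x)
}

#' Rebuild a run config from a manifest
#'
#' @param manifest_path path to a `manifest.json` written by
#'   [run_pipeline()].
#' @return a `run_config` equal to the one the run used.
#' @export
config_from_manifest <- function(manifest_path) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cc <- m$config
  run_config(
    out_dir = cc$out_dir,
    cohort = do.call(cohort_config, cc$cohort),
    cohort_dir = if (length(cc$cohort_dir)) cc$cohort_dir else NULL,
    texture = do.call(texture_config, cc$texture),
    feature_set = cc$feature_set,
    n_keep = cc$n_keep, B_sel = cc$B_sel,
    balance = do.call(balance_config, cc$balance),
    ensemble = do.call(ensemble_config, cc$ensemble),
    seed = cc$seed)
}
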