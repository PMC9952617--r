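#' Pipeline configuration
#'
#' The full end-to-end configuration: cohort generation, preprocessing,
#' statistics, features, split and training, plus the master seed.
#' Unknown keys are rejected and a serialized YAML copy is stored beside
#' every run's outputs.
#'
#' @param cohort Named list of [cohort_config()] arguments (without
#'   `seed`).
#' @param preprocess Named list: `lambda` (baseline-correction stiffness).
#' @param stats Named list: `alpha`, `annotation_filter`.
#' @param features Named list: `wavenumbers`, `halfwidth`.
#' @param split Named list: `n_sets`, `eval_set`.
#' @param train Named list: `algorithms`, `k_folds`.
#' @param seed Master seed (required).
#' @param out_dir Output directory for [run_pipeline()].
#' @return A validated `sers_pipeline_config`.
#' @export
pipeline_config <- function(cohort = list(), preprocess = list(),
                            stats = list(), features = list(),
                            split = list(), train = list(), seed = NULL,
                            out_dir = NULL) {
  raw <- list(cohort = cohort, preprocess = preprocess, stats = stats,
              features = features, split = split, train = train,
              seed = seed, out_dir = out_dir)
  validate_pipeline_config(raw)
}

pipeline_defaults <- function() {
  list(
    preprocess = list(lambda = 5000),
    stats = list(alpha = 0.05,
                 annotation_filter = c("cancer_stroma", "dcis_stroma")),
    features = list(wavenumbers = default_marker_wavenumbers(),
                    halfwidth = 10),
    split = list(n_sets = 4, eval_set = 4),
    train = list(algorithms = model_families(), k_folds = 3)
  )
}

#' Validate a pipeline configuration
#'
#' @param config A named list (e.g. parsed from YAML).
#' @return The completed `sers_pipeline_config`; unknown or missing keys
#'   raise a config error naming the key.
#' @export
validate_pipeline_config <- function(config) {
  known <- c("cohort", "preprocess", "stats", "features", "split", "train",
             "seed", "out_dir")
  extra <- setdiff(names(config), known)
  if (length(extra)) {
    config_error("unknown config key '%s'", extra[1])
  }
  if (is.null(config$seed) || !is.finite(suppressWarnings(as.numeric(config$seed)))) {
    config_error("config field 'seed' is required and must be an integer")
  }
  defaults <- pipeline_defaults()
  section_keys <- list(
    cohort = setdiff(names(formals(cohort_config)), "seed"),
    preprocess = names(defaults$preprocess),
    stats = names(defaults$stats),
    features = names(defaults$features),
    split = names(defaults$split),
    train = names(defaults$train)
  )
  for (sec in names(section_keys)) {
    given <- config[[sec]] %||% list()
    bad <- setdiff(names(given), section_keys[[sec]])
    if (length(bad)) config_error("unknown config key '%s.%s'", sec, bad[1])
    if (sec != "cohort") {
      config[[sec]] <- modifyList(defaults[[sec]], given)
    }
  }
  cohort_args <- c(config$cohort %||% list(),
                   list(seed = as.integer(config$seed)))
  config$cohort_config <- do.call(cohort_config, cohort_args)
  config$seed <- as.integer(config$seed)
  structure(config, class = "sers_pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML path.
#' @param config A `sers_pipeline_config` (or plain list for writing).
#' @return `read_pipeline_config` returns a validated config.
#' @export
read_pipeline_config <- function(path) {
  validate_pipeline_config(yaml::read_yaml(path))
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  drop <- c("cohort_config", "out_dir")
  lst <- unclass(config)[setdiff(names(unclass(config)), drop)]
  # peak library and axis are reproducible from defaults; store overrides only
  lst$cohort <- lapply(lst$cohort, function(v) if (is.function(v)) NULL else v)
  yaml::write_yaml(lst, path)
  invisible(path)
}

stage_names <- function() {
  c("simulate", "preprocess", "annotate", "diffpeaks", "features", "split",
    "train", "evaluate", "aggregate")
}

#' Run the end-to-end pipeline
#'
#' simulate -> preprocess -> annotate -> diffpeaks -> features -> split ->
#' train -> evaluate -> aggregate, writing each stage's outputs under the
#' configured directory together with the serialized config and a run
#' manifest (per-file MD5 hashes, applied seeds, package version).
#' Rerunning with an identical config and seed reproduces the output
#' tree byte for byte; with `resume = TRUE` stages whose outputs already
#' exist are skipped.
#'
#' @param config A `sers_pipeline_config`.
#' @param out_dir Output directory (overrides the config's).
#' @param resume Skip stages whose outputs exist.
#' @param quiet Suppress stage messages.
#' @return The run manifest tibble (invisibly the full result list as
#'   attribute `results`).
#' @export
run_pipeline <- function(config, out_dir = NULL, resume = FALSE,
                         quiet = FALSE) {
  if (!inherits(config, "sers_pipeline_config")) {
    config <- validate_pipeline_config(config)
  }
  out_dir <- out_dir %||% config$out_dir %||%
    file.path(tempdir(), sprintf("sers-run-%d", config$seed))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  paths <- list()
  results <- list()
  cfg <- config$cohort_config

  run_stage <- function(stage, outfiles, fn, force = FALSE) {
    outs <- file.path(out_dir, outfiles)
    if (resume && !force && all(file.exists(outs))) {
      say("[%s] cached (%d file(s))", stage, length(outs))
    } else {
      fn(outs)
      say("[%s] wrote %d file(s)", stage, length(outs))
    }
    paths[[stage]] <<- outs
    outs
  }

  # 1 simulate
  cube_files <- sprintf("cube-%03d.rds", seq_len(cfg$n_dcis + cfg$n_ibc))
  mask_files <- sprintf("mask-%03d.png", seq_len(cfg$n_dcis + cfg$n_ibc))
  sim_out <- c(cube_files, mask_files, "manifest.tsv", "silicon.rds",
               "config.yaml")
  cohort <- NULL
  run_stage("simulate", sim_out, function(outs) {
    cohort <<- simulate_cohort(cfg)
    for (i in seq_len(nrow(cohort))) {
      write_cube(cohort$cube[[i]], file.path(out_dir, cube_files[i]))
      write_mask(cohort$mask[[i]], file.path(out_dir, mask_files[i]))
    }
    write_table_tsv(
      tibble(patient_id = cohort$patient_id, diagnosis = cohort$diagnosis,
             cube = cube_files, mask = mask_files),
      file.path(out_dir, "manifest.tsv"))
    saveRDS(attr(cohort, "silicon"), file.path(out_dir, "silicon.rds"))
    write_pipeline_config(config, file.path(out_dir, "config.yaml"))
  })
  if (is.null(cohort)) cohort <- simulate_cohort(cfg)
  silicon <- attr(cohort, "silicon")

  # 2 preprocess: calibrate -> bin -> baseline-correct
  processed <- vector("list", nrow(cohort))
  run_stage("preprocess", "processed.rds", function(outs) {
    processed <<- purrr::map(cohort$cube, function(cube) {
      cube |>
        calibrate(silicon, resample_to = cfg$axis) |>
        bin_pixels(cfg$bin_factor) |>
        subtract_baseline(lambda = config$preprocess$lambda)
    })
    saveRDS(processed, outs[1])
  })
  if (is.null(processed[[1]])) processed <- readRDS(paths$preprocess[1])

  # 3 annotate: tagged spectrum tables
  tagged <- NULL
  run_stage("annotate", "tagged.rds", function(outs) {
    tagged <<- purrr::map2(processed, cohort$mask, tag_spectra)
    saveRDS(tagged, outs[1])
  })
  if (is.null(tagged)) tagged <- readRDS(paths$annotate[1])

  # 4 two-pass differential-band discovery on raw stroma means
  report <- NULL
  run_stage("diffpeaks", "differential_peaks.tsv", function(outs) {
    raw_tagged <- purrr::map2(cohort$cube, cohort$mask, function(cube, mask) {
      cube |>
        calibrate(silicon, resample_to = cfg$axis) |>
        bin_pixels(cfg$bin_factor) |>
        tag_spectra(mask)
    })
    pm <- patient_means(raw_tagged,
                        annotation_filter = config$stats$annotation_filter)
    report <<- discover_differential_bands(
      pm, alpha = config$stats$alpha, lambda = config$preprocess$lambda)
    write_table_tsv(report$peaks, outs[1])
  })
  results$diff_report <- report

  # 5 mesh features
  feats <- NULL
  run_stage("features", "mesh_features.tsv", function(outs) {
    feats <<- purrr::pmap(
      list(processed, cohort$mask, cohort$patient_id, cohort$diagnosis),
      function(cube, mask, pid, dx) {
        mesh_features(cube, stroma_mesh(mask, dx, pid),
                      wavenumbers = config$features$wavenumbers,
                      halfwidth = config$features$halfwidth)
      }) |> dplyr::bind_rows()
    write_table_tsv(feats, outs[1])
  })
  if (is.null(feats)) feats <- read_table_tsv(paths$features[1])

  # 6 patient split
  plan <- NULL
  run_stage("split", "split_plan.tsv", function(outs) {
    plan <<- stratified_split(
      dplyr::distinct(cohort[, c("patient_id", "diagnosis")]),
      n_sets = config$split$n_sets, seed = child_seed(config$seed, 7),
      eval_set = config$split$eval_set)
    write_table_tsv(plan, outs[1])
  })
  if (is.null(plan)) plan <- read_table_tsv(paths$split[1])

  train_ids <- plan$patient_id[plan$role == "train"]
  eval_ids <- plan$patient_id[plan$role == "evaluation"]

  # 7 train six families with kappa-maximizing grid search
  # (training must rerun if downstream stages still need the fitted models)
  downstream_missing <- !all(file.exists(file.path(
    out_dir, c("eval_report.tsv", "patient_predictions.tsv"))))
  models <- NULL
  run_stage("train", "cv_report.tsv", force = downstream_missing,
            fn = function(outs) {
    models <<- train_models(
      feats[feats$patient_id %in% train_ids, ],
      algorithms = config$train$algorithms,
      k_folds = config$train$k_folds,
      seed = child_seed(config$seed, 8))
    write_table_tsv(models$cv, outs[1])
  })
  results$models <- models

  # 8 evaluate on the held-out set
  eval_report <- NULL
  run_stage("evaluate", "eval_report.tsv",
            force = !file.exists(file.path(out_dir, "patient_predictions.tsv")),
            fn = function(outs) {
    eval_report <<- evaluate(models, feats[feats$patient_id %in% eval_ids, ])
    write_table_tsv(eval_report$metrics, outs[1])
  })
  results$eval_report <- eval_report

  # 9 mesh-ratio patient aggregation of the best family
  run_stage("aggregate", "patient_predictions.tsv", function(outs) {
    best <- eval_report$metrics$model[1]
    mp <- eval_report$predictions
    mp$predicted <- as.character(mp[[best]])
    write_table_tsv(patient_aggregate(mp), outs[1])
  })
  results$patient_predictions <- read_table_tsv(paths$aggregate[1])

  manifest <- dplyr::bind_rows(lapply(stage_names(), function(st) {
    tibble(stage = st, file = basename(paths[[st]]),
           md5 = unname(tools::md5sum(paths[[st]])))
  }))
  manifest$seed <- config$seed
  manifest$package_version <- as.character(utils::packageVersion("sersstroma"))
  write_table_tsv(manifest, file.path(out_dir, "run_manifest.tsv"))
  attr(manifest, "results") <- results
  attr(manifest, "out_dir") <- out_dir
  invisible(manifest)
}
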