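#' Run configuration for the end-to-end pipeline
#'
#' Fully serializes a run: scene and design parameters, observer cohort,
#' per-stage seeds, stage toggles, gaze sampling rate and averaging-window
#' selection. The default is a desk-scale configuration (a reduced cohort
#' and block count and a 100 Hz synthetic gaze rate) so a complete run
#' stays interactive; `fast = FALSE` gives the full study-scale design
#' (15 observers, 3 blocks, 1000 Hz).
#'
#' @param n_participants cohort size.
#' @param n_blocks blocks per session.
#' @param gaze_sample_rate Hz for synthetic gaze.
#' @param seed master seed; stage seeds derive from it.
#' @param stages character vector of stages to run.
#' @param n_perm permutations for the classification stage.
#' @param window `"feature"` or `"full"` for classification features.
#' @param out_dir output directory.
#' @param fast convenience switch for the desk-scale defaults.
#' @return `run_config` object.
#' @export
run_config <- function(n_participants = if (fast) 6 else 15,
                       n_blocks = if (fast) 1 else 3,
                       gaze_sample_rate = if (fast) 100 else 1000,
                       seed = 1,
                       stages = c("simulate", "preprocess", "metrics",
                                  "psychofit", "dominance", "classify",
                                  "mixedmodel"),
                       n_perm = if (fast) 50 else 1000,
                       window = "feature",
                       out_dir = tempfile("crossgaze_run_"),
                       fast = TRUE) {
  structure(as.list(environment()), class = "run_config")
}

stage_seed <- function(config, k) (config$seed * 1009L + k * 9176L) %%
  .Machine$integer.max

#' Run the analysis pipeline end to end
#'
#' Executes simulate -> preprocess -> metrics -> psychometrics ->
#' dominance -> classification -> mixed model, writing per-stage outputs
#' under `config$out_dir` and a manifest with file hashes and the seeds
#' used. Rerunning with the same config reproduces identical outputs.
#' A stage failure is recorded in the manifest and downstream stages are
#' skipped.
#'
#' @param config a [run_config()].
#' @return List of stage results (class `crossgaze_results`), invisibly
#'   also written to disk.
#' @export
run_pipeline <- function(config = run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  scene <- scene_config()
  grid <- design_grid(n_blocks = config$n_blocks)
  manifest <- list(seed = config$seed, stages = list())
  results <- list(config = config)
  failed <- FALSE

  run_stage <- function(name, fun) {
    if (failed || !(name %in% config$stages)) {
      manifest$stages[[name]] <<- list(status = if (failed) "skipped"
                                       else "disabled")
      return(NULL)
    }
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) e)
    dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    if (inherits(res, "error")) {
      failed <<- TRUE
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res),
                                       seconds = dt)
      message(sprintf("[crossgaze] stage %s FAILED: %s", name,
                      conditionMessage(res)))
      return(NULL)
    }
    manifest$stages[[name]] <<- list(status = "ok", seconds = round(dt, 2))
    message(sprintf("[crossgaze] stage %-10s done in %6.1f s", name, dt))
    res
  }

  # -- simulate ------------------------------------------------------------
  dataset <- run_stage("simulate", function() {
    cohort <- default_observer_cohort(config$n_participants,
                                      seed = stage_seed(config, 1))
    ds <- generate_dataset(cohort, grid, scene,
                           seed = stage_seed(config, 2),
                           gaze = TRUE,
                           gaze_sample_rate = config$gaze_sample_rate,
                           gaze_intervals = "comparison")
    write_tsv_table(ds$trials, file.path(config$out_dir, "trials.tsv"))
    write_gaze_traces(ds, file.path(config$out_dir, "gaze"))
    ds
  })
  results$dataset <- dataset

  # -- preprocess + metrics ------------------------------------------------
  metrics <- run_stage("metrics", function() {
    m <- compute_gaze_metrics(dataset)
    write_tsv_table(m, file.path(config$out_dir, "metrics.tsv"))
    m
  })
  results$metrics <- metrics

  excl <- run_stage("preprocess", function() {
    fr <- metrics[metrics$window == "feature",
                  c("participant_id", "task", "trial_id", "interval",
                    "interpolated_fraction")]
    ex <- apply_exclusions(fr)
    jsonlite::write_json(
      list(excluded_trials = ex$report$excluded_trials,
           excluded_participants = ex$report$excluded_participants,
           n_trials = ex$report$n_trials,
           n_excluded = ex$report$n_excluded),
      file.path(config$out_dir, "cleaning_report.json"), auto_unbox = TRUE)
    ex
  })
  results$exclusions <- excl

  # -- psychometrics -------------------------------------------------------
  psych <- run_stage("psychofit", function() {
    out <- list()
    for (pid in unique(dataset$trials$participant_id)) {
      for (task in unique(dataset$trials$task)) {
        tr <- dataset$trials[dataset$trials$participant_id == pid, ]
        pd <- psychometric_data(tr, task)
        fit <- fit_psychometric(pd$levels, pd$k, pd$n, n_boot = 100,
                                seed = stage_seed(config, 3))
        std <- if (task == "speed") grid$standard_speed else grid$standard_tta
        out[[paste(pid, task, sep = "_")]] <- list(
          participant_id = pid, task = task,
          pse = fit$pse, sigma = fit$sigma, gamma = fit$gamma,
          lambda = fit$lambda, jnd = fit$jnd, se_jnd = fit$se_jnd,
          weber = weber(fit$jnd, std), deviance = fit$deviance,
          uninformative = fit$uninformative)
      }
    }
    jsonlite::write_json(out, file.path(config$out_dir, "psychfits.json"),
                         auto_unbox = TRUE, digits = NA)
    out
  })
  results$psychfits <- psych

  # -- dominance -----------------------------------------------------------
  dom <- run_stage("dominance", function() {
    out <- list()
    for (pid in unique(dataset$trials$participant_id)) {
      for (task in unique(dataset$trials$task)) {
        tr <- dataset$trials[dataset$trials$participant_id == pid &
                               dataset$trials$task == task, ]
        cues <- cue_table(tr, scene)
        gd <- general_dominance(tr$chose_comparison, cues)
        sig <- psych[[paste(pid, task, sep = "_")]]$sigma
        theo <- theoretical_observer_responses(
          tr, rule = task, noise_sd = sig,
          standard_speed = grid$standard_speed,
          standard_tta = grid$standard_tta,
          seed = stage_seed(config, 4))
        gd_theo <- general_dominance(theo, cues)
        out[[paste(pid, task, sep = "_")]] <- list(
          participant = as.list(gd$general_dominance),
          participant_r2m = gd$r2m_full,
          theoretical = as.list(gd_theo$general_dominance),
          theoretical_r2m = gd_theo$r2m_full)
      }
    }
    jsonlite::write_json(out, file.path(config$out_dir, "dominance.json"),
                         auto_unbox = TRUE, digits = NA)
    out
  })
  results$dominance <- dom

  # -- classification ------------------------------------------------------
  clf <- run_stage("classify", function() {
    feat <- metrics[metrics$window == config$window &
                      metrics$trial_id %in% excl$kept, ]
    means <- participant_task_means(metrics)
    pids <- unique(means$participant_id)
    A <- as.matrix(means[means$task == "speed",
                         gaze_feature_names()][match(pids,
                           means$participant_id[means$task == "speed"]), ])
    B <- as.matrix(means[means$task == "tta",
                         gaze_feature_names()][match(pids,
                           means$participant_id[means$task == "tta"]), ])
    keepcols <- which(apply(A - B, 2, sd) > 0)
    # the F transform needs n - p >= 1; drop trailing features if the
    # cohort is smaller than the feature set
    if (length(keepcols) > nrow(A) - 1)
      keepcols <- keepcols[seq_len(nrow(A) - 1)]
    man <- tryCatch(manova_compare(A[, keepcols, drop = FALSE],
                                   B[, keepcols, drop = FALSE]),
                    error = function(e) NULL)
    task_rep <- loso_cv(feat, label = "task")
    obs_rep <- kfold_cv(feat, label = "participant_id", k = 10,
                        seed = stage_seed(config, 5))
    perm_task <- permutation_test(feat, "task", cv_fun = loso_cv,
                                  n_perm = config$n_perm,
                                  seed = stage_seed(config, 6))
    res <- list(manova = man, task = task_rep, observer = obs_rep,
                permutation_task = perm_task)
    jsonlite::write_json(
      list(task_accuracy = task_rep$accuracy, task_nir = task_rep$nir,
           observer_accuracy = obs_rep$accuracy, observer_nir = obs_rep$nir,
           permutation_p_task = perm_task$p_string,
           wilks_lambda = if (!is.null(man)) man$wilks_lambda else NA,
           manova_f = if (!is.null(man)) man$f_stat else NA),
      file.path(config$out_dir, "classification.json"), auto_unbox = TRUE)
    if (!is.null(man))
      write_tsv_table(as.data.frame(task_rep$confusion_matrix),
                      file.path(config$out_dir, "confusion_task.tsv"))
    res
  })
  results$classification <- clf

  # -- mixed model ---------------------------------------------------------
  mm <- run_stage("mixedmodel", function() {
    feat <- metrics[metrics$window == "full" &
                      metrics$trial_id %in% excl$kept &
                      metrics$interval == "comparison", ]
    d <- merge(as.data.frame(feat),
               as.data.frame(dataset$trials[, c("trial_id", "correct",
                                                "comparison_speed",
                                                "comparison_tta")]),
               by = "trial_id")
    rep <- suppressWarnings(simplify_ladder(d))
    jsonlite::write_json(
      list(estimates = as.list(rep$estimates), se = as.list(rep$se),
           p = as.list(rep$p), vif = as.list(rep$vif),
           ladder = rep$ladder_record, aic = rep$aic),
      file.path(config$out_dir, "mixed_model.json"), auto_unbox = TRUE,
      digits = NA)
    rep
  })
  results$mixed_model <- mm

  # -- manifest ------------------------------------------------------------
  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest.json", files)]
  manifest$files <- lapply(files, function(f)
    list(path = sub(paste0(config$out_dir, "/?"), "", f),
         md5 = unname(tools::md5sum(f))))
  manifest$config <- config[setdiff(names(config), "out_dir")]
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  class(results) <- "crossgaze_results"
  invisible(results)
}

#' Write / read a run configuration as YAML
#'
#' Fully serializes a [run_config()] (scene and design parameters are
#' reconstructed from their defaults plus any overrides recorded here) so
#' a run can be reproduced from its config file alone.
#'
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @return `read_run_config()` returns a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- run_config()
  for (nm in intersect(names(raw), names(cfg))) cfg[[nm]] <- raw[[nm]]
  cfg$stages <- unlist(cfg$stages)
  cfg
}
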