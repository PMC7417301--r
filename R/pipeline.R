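# End-to-end orchestration: simulate -> preprocess -> transform -> select ->
# classify -> evaluate, with config echoing and artifact output so every
# reported number is recomputable from serialized intermediates.

#' Build OPT and/or sIMU feature matrices for one task
#'
#' Applies the full preprocessing chain to every trial of the task
#' (trim, filter, height-normalize, then trunk-align + time-normalize for
#' OPT) and assembles the feature matrix.
#'
#' @param cohort A list with `athletes` and `trials` ([generate_cohort()]
#'   or [read_cohort()]).
#' @param task Task name.
#' @param config A [preprocess_config()].
#' @param variant `"OPT"` or `"sIMU"`.
#' @return A [feature_matrix()].
#' @export
task_matrices <- function(cohort, task, config = preprocess_config(),
                          variant = c("OPT", "sIMU")) {
  variant <- match.arg(variant)
  sel <- Filter(function(tr) identical(tr$task, task), cohort$trials)
  if (length(sel) == 0L) stop("no trials found for task '", task, "'")
  if (variant == "sIMU") {
    # positions are not part of the sIMU feature set; dropping them before
    # filtering/resampling halves the preprocessing work
    sel <- lapply(sel, function(tr) { tr$positions <- NULL; tr })
  }
  heights <- setNames(cohort$athletes$height, cohort$athletes$athlete_id)
  pre <- lapply(sel, function(tr) {
    h <- heights[[tr$athlete_id]]
    if (is.null(h) || is.na(h))
      stop("no height on record for athlete ", tr$athlete_id)
    preprocess_trial(tr, h, config, variant)
  })
  if (variant == "OPT") build_opt_matrix(pre, cohort$athletes)
  else build_simu_matrix(pre, cohort$athletes, config)
}

#' Pipeline run configuration
#'
#' @param variant `"both"`, `"OPT"` or `"sIMU"`.
#' @param tasks Task names (`NULL` = every task present in the data).
#' @param classifiers Character vector of classifier kinds (see
#'   [classifier_spec()]); `"LDA"` by default.
#' @param preprocess A [preprocess_config()].
#' @param top_k,vote_threshold Ensemble-selection parameters.
#' @param scale_discipline `"per_fold"` or `"global"` robust-scaler fitting
#'   (sIMU only).
#' @param sweep If TRUE (default) sweep k from 1 to the retained count and
#'   report the optimum; if FALSE run a single pass with all retained PCs.
#' @param seed Integer seed for all stochastic components.
#' @param out_dir Output directory for artifacts (`NULL` = no files).
#' @return An object of class `run_config`.
#' @export
run_config <- function(variant = c("both", "OPT", "sIMU"), tasks = NULL,
                       classifiers = "LDA",
                       preprocess = preprocess_config(),
                       top_k = 25L, vote_threshold = 3L,
                       scale_discipline = c("per_fold", "global"),
                       sweep = TRUE, seed = 1L, out_dir = NULL) {
  variant <- match.arg(variant)
  scale_discipline <- match.arg(scale_discipline)
  classifiers <- toupper(classifiers)
  bad <- setdiff(classifiers, .CLASSIFIERS)
  if (length(bad))
    stop("unknown classifier kind(s): ", paste(bad, collapse = ", "))
  structure(list(variant = variant, tasks = tasks,
                 classifiers = classifiers, preprocess = preprocess,
                 top_k = as.integer(top_k),
                 vote_threshold = as.integer(vote_threshold),
                 scale_discipline = scale_discipline,
                 sweep = isTRUE(sweep), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unspecified fields take the [run_config()] defaults; every effective
#' value is echoed into the provenance log of the run.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  pp_args <- y$preprocess %||% list()
  pp <- do.call(preprocess_config, pp_args)
  args <- y[setdiff(names(y), "preprocess")]
  args$preprocess <- pp
  do.call(run_config, args)
}

#' Run the full pipeline on a cohort
#'
#' For each task x variant: build the feature matrix, run the leave-one-out
#' protocol for each configured classifier (sweeping k if configured),
#' compute signal-detection metrics for the optimum, and assemble per-
#' variant summary tables with `Average` and `STD` rows plus, when both
#' variants run, the per-task sIMU - OPT accuracy difference table. When
#' `config$out_dir` is set, all artifacts (accuracy-vs-k curves, per-task
#' results, summaries, a provenance log) are written there.
#'
#' @param config A [run_config()].
#' @param cohort A cohort list, or a directory path readable by
#'   [read_cohort()].
#' @return A list: `runs` (nested task/variant/classifier results),
#'   `summaries` (per variant, for the first configured classifier),
#'   `comparison` (sIMU - OPT differences, when both variants ran),
#'   `provenance`.
#' @export
run_pipeline <- function(config, cohort) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  tasks <- config$tasks
  if (is.null(tasks)) {
    tasks <- intersect(omat_tasks(),
                       unique(vapply(cohort$trials, `[[`, character(1),
                                     "task")))
  }
  if (length(tasks) == 0L) stop("no tasks to run")
  variants <- if (config$variant == "both") c("OPT", "sIMU") else
    config$variant
  labels_all <- setNames(cohort$athletes$skill, cohort$athletes$athlete_id)
  out_dir <- config$out_dir
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  runs <- list()
  summaries <- list()
  for (variant in variants) {
    per_task <- list()
    for (task in tasks) {
      fm <- tryCatch(
        task_matrices(cohort, task, config$preprocess, variant),
        error = function(e) stop("stage task_matrices failed for task '",
                                 task, "' (", variant, "): ",
                                 conditionMessage(e), call. = FALSE))
      y <- labels_all[rownames(fm$values)]
      opts <- cv_options(top_k = config$top_k,
                         vote_threshold = config$vote_threshold,
                         scale_discipline = config$scale_discipline,
                         seed = config$seed)
      for (cl in config$classifiers) {
        spec <- classifier_spec(cl, seed = config$seed)
        res <- if (config$sweep) {
          sw <- sweep_k(fm, y, spec, opts, task = task)
          sw
        } else {
          list(curve = NULL,
               optimal = loocv(fm, y, spec, k = NULL, opts, task = task),
               K = NA_integer_)
        }
        runs[[variant]][[task]][[cl]] <- res
        if (!is.null(out_dir)) {
          stem <- file.path(out_dir, paste(variant, task, cl, sep = "_"))
          if (!is.null(res$curve))
            utils::write.csv(res$curve, paste0(stem, "_curve.csv"),
                             row.names = FALSE)
          opt <- res$optimal
          jsonlite::write_json(
            list(task = task, variant = variant, classifier = cl,
                 k = opt$k, accuracy = opt$accuracy,
                 predictions = as.list(opt$predictions),
                 labels = as.list(opt$labels),
                 sdt = unclass(sdt_metrics(opt))),
            paste0(stem, "_cv.json"), auto_unbox = TRUE, digits = NA)
        }
      }
      per_task[[task]] <- runs[[variant]][[task]][[config$classifiers[1]]]$
        optimal
    }
    summaries[[variant]] <- summarize_tasks(per_task)
    if (!is.null(out_dir))
      utils::write.csv(.round_summary(summaries[[variant]]),
                       file.path(out_dir, paste0("summary_", variant,
                                                 ".csv")),
                       row.names = FALSE)
  }

  comparison <- NULL
  if (all(c("OPT", "sIMU") %in% names(summaries))) {
    comparison <- compare_variants(summaries$OPT, summaries$sIMU)
    if (!is.null(out_dir))
      utils::write.csv(comparison,
                       file.path(out_dir, "comparison_simu_minus_opt.csv"),
                       row.names = FALSE)
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("omat")),
    r_version = R.version.string,
    seed = config$seed,
    config = .echo_config(config),
    n_athletes = nrow(cohort$athletes),
    tasks = tasks, variants = variants)
  if (!is.null(out_dir))
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  list(runs = runs, summaries = summaries, comparison = comparison,
       provenance = provenance)
}

.echo_config <- function(config) {
  cfg <- unclass(config)
  cfg$preprocess <- unclass(cfg$preprocess)
  cfg
}

# accuracy reported as percentage with 2 decimals, rates to 2 d.p.
.round_summary <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[, num] <- lapply(df[, num, drop = FALSE], round, digits = 2)
  df
}

#' Compare variant accuracies per task
#'
#' @param opt_summary,simu_summary Data frames with `task` and `accuracy`
#'   columns (e.g. from [summarize_tasks()]; `Average`/`STD` rows are
#'   dropped).
#' @return A data frame with per-task `accuracy_opt`, `accuracy_simu` and
#'   `diff` (sIMU - OPT), followed by a `Mean` row of the per-task values.
#' @export
compare_variants <- function(opt_summary, simu_summary) {
  strip <- function(df) df[!df$task %in% c("Average", "STD"), , drop = FALSE]
  o <- strip(opt_summary); s <- strip(simu_summary)
  if (!setequal(o$task, s$task))
    stop("task mismatch between variants; unmatched: ",
         paste(union(setdiff(o$task, s$task), setdiff(s$task, o$task)),
               collapse = ", "))
  s <- s[match(o$task, s$task), , drop = FALSE]
  out <- data.frame(task = o$task, accuracy_opt = o$accuracy,
                    accuracy_simu = s$accuracy,
                    diff = s$accuracy - o$accuracy)
  rbind(out, data.frame(task = "Mean",
                        accuracy_opt = mean(out$accuracy_opt),
                        accuracy_simu = mean(out$accuracy_simu),
                        diff = mean(out$diff)))
}

#' Bundled reference results for the 13-task screen
#'
#' Per-task reference classification results (cohort composition, retained
#' PC counts, accuracy, SDT metrics) for the optical and simulated-IMU
#' variants, distributed with the package for summary arithmetic and
#' comparison examples.
#'
#' @param variant `"OPT"` or `"sIMU"`.
#' @return A data frame, one row per task.
#' @export
reference_results <- function(variant = c("OPT", "sIMU")) {
  variant <- match.arg(variant)
  f <- system.file("extdata",
                   paste0("reference_results_",
                          tolower(sub("sIMU", "simu", variant)), ".csv"),
                   package = "omat")
  utils::read.csv(f, stringsAsFactors = FALSE)
}
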