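#' Experiment configuration
#'
#' Declarative description of a full synthetic benchmark: how many subjects
#' to simulate, which algorithms / connectivity sources / tasks to run, and
#' the optimiser budget. Validation happens here, before any computation.
#'
#' @param simulation A [sim_config()]; per-subject seeds are derived from
#'   the experiment seed, so the `seed` field of `simulation` is ignored.
#' @param subjects Number of simulated subjects (>= 1).
#' @param algorithms Character vector from [list_algorithms()].
#' @param source_modes Connectivity sources (see [run_subject()]).
#' @param tasks Task labels; each task is an independently seeded recording
#'   per subject (the generator has no task-specific signal model — see the
#'   methods vignette).
#' @param budget,n_random Optimiser budget per free parameter.
#' @param directions Cross-fitting directions (see [run_subject()]).
#' @param seed Global experiment seed.
#' @return A validated list of class `cnp_experiment_config`.
#' @export
experiment_config <- function(simulation = sim_config(), subjects = 2,
                              algorithms = "spectral_knn_unweighted",
                              source_modes = "all", tasks = "movie",
                              budget = 100, n_random = 10,
                              directions = "both", seed = 1) {
  stopifnot(inherits(simulation, "cnp_sim_config"))
  if (length(algorithms) < 1) abort("`algorithms` must be non-empty")
  unknown <- setdiff(algorithms, list_algorithms())
  if (length(unknown)) {
    abort(sprintf("`algorithms` contains unknown name(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  valid_modes <- c("all", "cortex", "subcortex", "noise", "within_roi", "within_roi_pca")
  bad <- setdiff(source_modes, valid_modes)
  if (length(bad)) abort(sprintf("`source_modes` contains unknown mode(s): %s", paste(bad, collapse = ", ")))
  if (subjects < 1) abort("`subjects` must be >= 1")
  if (!directions %in% c("both", "single")) abort("`directions` must be 'both' or 'single'")
  structure(list(simulation = simulation, subjects = as.integer(subjects),
                 algorithms = algorithms, source_modes = source_modes,
                 tasks = tasks, budget = budget, n_random = n_random,
                 directions = directions, seed = as.integer(seed)),
            class = "cnp_experiment_config")
}

#' Run a full synthetic benchmark experiment
#'
#' Simulates every subject and task from the experiment seed, runs the
#' complete per-subject pipeline ([run_subject()]), computes split-half (and,
#' when several tasks are configured, cross-task) reliability of the
#' connectopic maps, and — when at least two algorithms and two subjects are
#' configured — the repeated-measures ANOVA comparing algorithms. All output
#' is regenerable from the config alone.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional directory; when given, tidy CSVs (`records.csv`,
#'   `reliability.csv`, `anova.csv`) and the config (`config.json`) are
#'   written there.
#' @return A list with `records`, `reliability`, `anova` (a
#'   [rm_anova()] object or `NULL`), and `config`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "cnp_experiment_config"))
  records <- list(); reliab <- list()
  for (s in seq_len(config$subjects)) {
    for (ti in seq_along(config$tasks)) {
      sim <- config$simulation
      sim$seed <- as.integer(child_seed(config$seed, s * 131 + ti))
      subj <- simulate_subject(sim)
      id <- sprintf("s%02d", s)
      rec <- run_subject(subj$roi, list(cortex = subj$cortex, subcortex = subj$subcortex),
                         subj$truth, algorithms = config$algorithms,
                         source_modes = config$source_modes,
                         task = config$tasks[ti], subject = id,
                         seed = sim$seed, budget = config$budget,
                         n_random = config$n_random,
                         directions = config$directions,
                         keep_embeddings = TRUE)
      emb <- attr(rec, "embeddings")
      attr(rec, "embeddings") <- NULL
      records[[paste(s, ti)]] <- rec
      if (config$directions == "both") {
        keys <- names(emb)
        stems <- unique(sub("\\.(odd|even)$", "", keys))
        reliab[[paste(s, ti)]] <- purrr::map_dfr(stems, function(st) {
          split_half_reliability(emb[[paste0(st, ".odd")]],
                                 emb[[paste0(st, ".even")]]) |>
            mutate(subject = id, task = config$tasks[ti], combo = st, .before = 1)
        })
      }
    }
  }
  records <- bind_rows(records)
  reliability <- bind_rows(reliab)
  anova <- NULL
  if (length(config$algorithms) >= 2 && config$subjects >= 2) {
    agg <- records |>
      group_by(.data$subject, .data$map_type, .data$algorithm) |>
      summarise(abs_r = mean(.data$abs_r), .groups = "drop")
    anova <- rm_anova(agg, dv = "abs_r", within = c("map_type", "algorithm"),
                      subject = "subject")
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(records, file.path(out_dir, "records.csv"), row.names = FALSE)
    if (nrow(reliability)) {
      utils::write.csv(reliability, file.path(out_dir, "reliability.csv"), row.names = FALSE)
    }
    if (!is.null(anova)) {
      utils::write.csv(tidy(anova), file.path(out_dir, "anova.csv"), row.names = FALSE)
    }
    jsonlite::write_json(config[setdiff(names(config), "simulation")],
                         file.path(out_dir, "config.json"), auto_unbox = TRUE)
  }
  list(records = records, reliability = reliability, anova = anova,
       config = config)
}

sidecar_path <- function(path) paste0(sub("\\.[^./]*$", "", path), ".json")

#' Write / read a timeseries as CSV plus JSON metadata
#'
#' The matrix is stored as a headerless CSV (rows = vertices/sources) and
#' the run boundaries in a JSON sidecar of the same basename, so a
#' round-trip reproduces the object exactly (up to numeric printing
#' precision of the CSV, 17 significant digits).
#'
#' @param ts A [cnp_timeseries()].
#' @param path CSV file path; the sidecar is written next to it.
#' @return `write_timeseries()` returns `path` invisibly;
#'   `read_timeseries()` returns a [cnp_timeseries()].
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "cnp_timeseries"))
  utils::write.table(format(ts$data, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(list(run_offsets = ts$run_offsets,
                            n_series = nrow(ts$data)),
                       sidecar_path(path), auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  meta_path <- sidecar_path(path)
  if (!file.exists(meta_path)) {
    abort(sprintf("metadata sidecar with run_offsets not found: %s", meta_path))
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$run_offsets)) abort("metadata is missing `run_offsets`")
  data <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(data) <- NULL
  if (!is.null(meta$n_series) && nrow(data) != meta$n_series) {
    abort(sprintf("shape mismatch: CSV has %d rows, metadata says %d",
                  nrow(data), meta$n_series))
  }
  cnp_timeseries(data, meta$run_offsets)
}

#' Plot benchmark accuracies
#'
#' Group-mean prediction accuracy per algorithm and map type, with
#' per-subject points overlaid.
#'
#' @param records Accuracy tibble from [run_subject()] / [run_experiment()].
#' @return A ggplot object.
#' @export
plot_accuracy <- function(records) {
  means <- records |>
    group_by(.data$algorithm, .data$map_type) |>
    summarise(abs_r = mean(.data$abs_r), .groups = "drop")
  ggplot2::ggplot(means, ggplot2::aes(x = .data$algorithm, y = .data$abs_r,
                                      fill = .data$map_type)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_point(data = records,
                        position = ggplot2::position_dodge(width = 0.8),
                        alpha = 0.6, show.legend = FALSE) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "|r| (map prediction accuracy)", fill = "map") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
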