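#' Read and write choice-trial event logs
#'
#' The event-log CSV dialect has header
#' `trial_id,zone,time_s,event,food,actor_stage,recipient_stage,share_fraction`,
#' one row per timestamped event; cells that do not apply (e.g. stages on
#' non-SHARE rows) are empty. Food and stage labels are matched
#' case-insensitively against the closed vocabularies. On reading, rows
#' are grouped by trial and stably sorted by time; all validation
#' failures are collected and reported with their line numbers.
#'
#' @param path File path.
#' @param events An event-log tibble (e.g. from [simulate_trials()]).
#' @param foods Food vocabulary.
#' @return `read_event_log()` returns a validated event-log tibble;
#'   `write_event_log()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' cfg <- sim_config(n_trials = 2, seed = 1)
#' write_event_log(simulate_trials(cfg), f)
#' read_event_log(f)
#' @export
read_event_log <- function(path, foods = food_names()) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  if (!identical(hdr, event_log_columns())) {
    bad <- setdiff(event_log_columns(), hdr)
    extra <- setdiff(hdr, event_log_columns())
    abort(paste0(
      "bad event-log header",
      if (length(bad)) paste0("; missing: ", paste(bad, collapse = ", ")),
      if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", "))
    ))
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      trial_id = readr::col_character(),
      zone = readr::col_character(),
      time_s = readr::col_character(),
      event = readr::col_character(),
      food = readr::col_character(),
      actor_stage = readr::col_character(),
      recipient_stage = readr::col_character(),
      share_fraction = readr::col_double()
    ),
    show_col_types = FALSE
  )
  line <- seq_len(nrow(raw)) + 1L  # header is line 1
  problems <- character()
  time_s <- suppressWarnings(as.numeric(raw$time_s))
  bad_time <- is.na(time_s) | time_s < 0
  if (any(bad_time)) {
    problems <- c(problems, paste0(
      "unparseable or negative time_s on line(s) ",
      paste(line[bad_time], collapse = ", ")
    ))
  }
  ev <- toupper(trimws(raw$event))
  bad_ev <- !(ev %in% event_kinds())
  if (any(bad_ev)) {
    problems <- c(problems, paste0(
      "unknown event on line(s) ", paste(line[bad_ev], collapse = ", ")
    ))
  }
  fd <- tolower(trimws(raw$food))
  bad_fd <- !is.na(fd) & !(fd %in% foods)
  if (any(bad_fd)) {
    problems <- c(problems, paste0(
      "unknown food on line(s) ", paste(line[bad_fd], collapse = ", ")
    ))
  }
  if (length(problems) > 0L) {
    abort(paste0("invalid event log:\n  ", paste(problems, collapse = "\n  ")))
  }
  out <- tibble(
    trial_id = raw$trial_id, zone = raw$zone, time_s = time_s,
    event = ev, food = fd,
    actor_stage = tolower(trimws(raw$actor_stage)),
    recipient_stage = tolower(trimws(raw$recipient_stage)),
    share_fraction = raw$share_fraction
  )
  validate_event_log(out, foods)
}

#' @rdname read_event_log
#' @export
write_event_log <- function(events, path) {
  events <- validate_event_log(events)
  readr::write_csv(events[, event_log_columns()], path, na = "")
  invisible(path)
}

#' Read and write score tables
#'
#' Score tables are written with header
#' `trial_id,food,fa,fc,rj,ag,delay_score,delay_s` (plus `zone` when
#' present in memory).
#'
#' @param scores A score table ([score_trials()]).
#' @param path File path.
#' @return The tibble (read) or `path`, invisibly (write).
#' @export
write_score_table <- function(scores, path) {
  cols <- c("trial_id", "food", "fa", "fc", "rj", "ag",
            "delay_score", "delay_s")
  if ("zone" %in% names(scores)) cols <- c(cols, "zone")
  readr::write_csv(scores[, cols], path, na = "")
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  out <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("trial_id", "food", "fa", "fc", "rj", "ag", "delay_score")
  miss <- setdiff(req, names(out))
  if (length(miss) > 0L) {
    abort(paste0("score table missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  out
}

significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p <= 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    p < 0.1 ~ ".",
    TRUE ~ ""
  )
}

#' Write a LOCO table as CSV and JSON
#'
#' Mirrors the published contrast-table layout: one block per reference
#' food with columns `block, coefficient, estimate, se, z, p,
#' odds_ratio` and significance stars (`***` p <= 0.001, `**` p < 0.01,
#' `*` p < 0.05, `.` p < 0.1).
#'
#' @param loco A LOCO table ([loco_report()]).
#' @param path Output path; `.csv` and `.json` siblings are written.
#' @return The two paths, invisibly.
#' @export
write_loco <- function(loco, path) {
  stopifnot(is.data.frame(loco))
  base <- sub("\\.(csv|json)$", "", path)
  verb <- if (all(loco$stage == "choice")) "chosen" else "attempted"
  title_case <- function(x) paste0(toupper(substring(x, 1, 1)), substring(x, 2))
  out <- tibble(
    block = paste(title_case(loco$reference), "is", verb, "first"),
    coefficient = paste0(
      title_case(ifelse(loco$stage == "choice", "choice", "attempt")),
      ": ", title_case(loco$alternative)
    ),
    estimate = loco$estimate,
    se = loco$std.error,
    z = loco$statistic,
    p = loco$p.value,
    odds_ratio = loco$odds_ratio,
    stars = significance_stars(loco$p.value)
  )
  readr::write_csv(out, paste0(base, ".csv"), na = "")
  jsonlite::write_json(out, paste0(base, ".json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(paste0(base, ".csv"), paste0(base, ".json")))
}

#' Pipeline run configuration
#'
#' Assembles and validates the configuration driving [run_pipeline()].
#' Unknown keys are rejected; the structure round-trips losslessly
#' through [write_run_config()] / [read_run_config()].
#'
#' @param out_dir Output directory for the result bundle.
#' @param seed Seed for the simulation stage.
#' @param simulate Arguments forwarded to [sim_config()] (list), or
#'   `NULL` to skip simulation.
#' @param input_log Path to an event-log CSV to analyse when not
#'   simulating.
#' @param input_scores Path to a score-table CSV for a stats-only run.
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "score", "fit", "loco", "stats", "network")`.
#' @param mlogit Options for the model stage: `reference`, `covariates`,
#'   `tol`, `max_iter`.
#' @param pca_mode `"correlation"` or `"covariance"`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir = "foodchoice-out",
                       seed = 1L,
                       simulate = list(),
                       input_log = NULL,
                       input_scores = NULL,
                       stages = c("simulate", "score", "fit", "loco",
                                  "stats", "network"),
                       mlogit = list(),
                       pca_mode = "correlation") {
  known_stages <- c("simulate", "score", "fit", "loco", "stats", "network")
  bad <- setdiff(stages, known_stages)
  if (length(bad) > 0L) {
    abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  }
  ml_defaults <- list(reference = "bread", covariates = character(),
                      tol = 1e-8, max_iter = 100L)
  bad_ml <- setdiff(names(mlogit), names(ml_defaults))
  if (length(bad_ml) > 0L) {
    abort(paste0("unknown mlogit option(s): ", paste(bad_ml, collapse = ", ")))
  }
  if (!pca_mode %in% c("correlation", "covariance")) {
    abort("pca_mode must be 'correlation' or 'covariance'")
  }
  ml <- modifyList(ml_defaults, mlogit)
  # YAML round-trips empty vectors as lists; keep canonical types
  ml$covariates <- as.character(unlist(ml$covariates))
  ml$tol <- as.numeric(ml$tol)
  ml$max_iter <- as.integer(ml$max_iter)
  structure(
    list(
      out_dir = out_dir,
      seed = as.integer(seed),
      simulate = simulate,
      input_log = input_log,
      input_scores = input_scores,
      stages = stages,
      mlogit = ml,
      pca_mode = pca_mode
    ),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0L) {
    abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")))
  }
  do.call(run_config, raw)
}

#' @rdname run_config
#' @param config A `run_config` object.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order — simulate (or load an event
#' log) -> score -> fit the attempt and choice model sets -> LOCO tables
#' -> supporting statistics (correlations, Poisson GLM, PCA) -> sharing
#' networks — writing per-stage CSV/JSON outputs plus a run manifest
#' (seed, package version, config hash, file list) into `out_dir`.
#' Identical config and seed produce a byte-identical bundle. Input
#' paths are checked before any stage runs; a stage failure aborts with
#' the stage name.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`events`,
#'   `scores`, `fits`, `loco`, `stats`, `networks`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (p in c(config$input_log, config$input_scores)) {
    if (!is.null(p) && !file.exists(p)) {
      abort(paste0("input path does not exist: ", p))
    }
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  outfile <- function(name) file.path(config$out_dir, name)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  if ("simulate" %in% config$stages) {
    res$events <- stage("simulate", {
      sc <- do.call(sim_config, modifyList(config$simulate,
                                           list(seed = config$seed)))
      ev <- simulate_trials(sc)
      write_event_log(ev, outfile("events.csv"))
      ev
    })
  } else if (!is.null(config$input_log)) {
    res$events <- stage("read", read_event_log(config$input_log))
  }

  if ("score" %in% config$stages) {
    res$scores <- stage("score", {
      if (is.null(res$events)) abort("no event log available to score")
      s <- score_trials(res$events)
      write_score_table(s, outfile("scores.csv"))
      s
    })
  } else if (!is.null(config$input_scores)) {
    res$scores <- stage("read", read_score_table(config$input_scores))
  }

  if ("fit" %in% config$stages) {
    res$fits <- stage("fit", {
      if (is.null(res$scores)) abort("no score table available to fit")
      ml <- config$mlogit
      lapply(
        setNames(c("attempt", "choice"), c("attempt", "choice")),
        function(st) {
          fit_mlogit(
            build_choice_data(res$scores, st),
            reference = ml$reference, covariates = ml$covariates,
            tol = ml$tol, max_iter = ml$max_iter
          )
        }
      )
    })
    for (st in names(res$fits)) {
      readr::write_csv(tidy(res$fits[[st]]),
                       outfile(paste0("mlogit_", st, ".csv")))
    }
  }

  if ("loco" %in% config$stages && !is.null(res$fits)) {
    res$loco <- stage("loco", lapply(res$fits, loco_report))
    for (st in names(res$loco)) {
      write_loco(res$loco[[st]], outfile(paste0("loco_", st, ".csv")))
    }
  }

  if ("stats" %in% config$stages) {
    res$stats <- stage("stats", {
      if (is.null(res$scores)) abort("no score table available for stats")
      corr <- corr_matrix(res$scores)
      glm_fit <- fit_poisson_glm(res$scores)
      pca <- pca_descriptors(res$scores, mode = config$pca_mode)
      readr::write_csv(corr, outfile("correlations.csv"))
      readr::write_csv(tidy(glm_fit), outfile("glm.csv"))
      readr::write_csv(tidy(pca), outfile("pca.csv"))
      list(correlations = corr, glm = glm_fit, pca = pca)
    })
  }

  if ("network" %in% config$stages && !is.null(res$events)) {
    res$networks <- stage("network", {
      sh <- sharing_events(res$events)
      if (nrow(sh) > 0L) {
        nets <- build_networks(sh)
        write_network_edges(nets, outfile("sharing_edges.csv"))
        readr::write_csv(degree_summary(nets), outfile("sharing_degrees.csv"))
        nets
      } else {
        NULL
      }
    })
  }

  manifest <- list(
    package = "foodchoice",
    version = as.character(utils::packageVersion("foodchoice")),
    seed = config$seed,
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    files = sort(setdiff(list.files(config$out_dir), "manifest.json"))
  )
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
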