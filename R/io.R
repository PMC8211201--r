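# File formats, run configuration, and the end-to-end pipeline driver.

#' Read roosting detection records from CSV
#'
#' Expects the header `individual_id,day,roost_id`.  Days are abstract
#' integer indices; with `dates_as_index = TRUE` an ISO date column is
#' mapped to day indices (1 = earliest date).  Duplicate
#' individual-day rows are an error listing the offending rows.
#'
#' @param path CSV path.
#' @param dates_as_index Convert an ISO-8601 `day` column to integer
#'   indices.
#' @return Validated roosting `data.frame`.
#' @export
read_roosting_csv <- function(path, dates_as_index = FALSE) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("individual_id", "day", "roost_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- df[need]
  if (dates_as_index) {
    d <- as.Date(df$day)
    if (anyNA(d)) stop("day column is not parseable as ISO dates", call. = FALSE)
    df$day <- as.integer(d - min(d)) + 1L
  } else {
    day <- suppressWarnings(as.integer(df$day))
    if (anyNA(day)) {
      stop("day column must be integer indices ",
           "(or ISO dates with dates_as_index = TRUE)", call. = FALSE)
    }
    df$day <- day
  }
  validate_roosting(df)
  df
}

#' Write roosting detection records to CSV
#' @param data Roosting `data.frame`.
#' @param path Output path.
#' @export
write_roosting_csv <- function(data, path) {
  validate_roosting(data)
  utils::write.csv(data[c("individual_id", "day", "roost_id")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an association matrix as square CSV
#' @param m Association matrix with ids as dimnames.
#' @param path Output path.
#' @export
write_association_csv <- function(m, path) {
  check_assoc(m)
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' Read a square association-matrix CSV
#' @param path CSV written by [write_association_csv()].
#' @return Association matrix.
#' @export
read_association_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  check_assoc(m)
  m
}

#' Export an association network as GraphML
#' @param m Association matrix.
#' @param path Output path.
#' @export
write_network_graphml <- function(m, path) {
  check_assoc(m)
  igraph::write_graph(assoc_graph(m), path, format = "graphml")
  invisible(path)
}

#' Configuration for a full pipeline run
#'
#' Bundles the generator (or an input data path), the balancing
#' thresholds, the regime grids and the randomization budgets.  The
#' `"fast"` profile (200 permutations, 200 bootstraps, 3 Rcom repeats
#' for the reference) is meant for desk-scale runs; `"full"` uses the
#' reference analysis budgets (1000/1000/10).
#'
#' @param generator A [roost_config()] (ignored when `data_path` is
#'   set).
#' @param data_path Optional CSV of detection records to analyse
#'   instead of generating.
#' @param min_days,obs_cap Balancing thresholds for the reference.
#' @param individuals_grid,obs_grid Regime grids.
#' @param n_reps Replicates per regime.
#' @param profile `"full"` or `"fast"`.
#' @param n_rand,n_boot,n_repeat_obs Override the profile budgets.
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return A list of class `run_config`.
#' @export
run_config <- function(generator = roost_config(),
                       data_path = NULL,
                       min_days = 40, obs_cap = 40,
                       individuals_grid = c(5, 10, 15, 20, 25, 35, 50, 75, 99),
                       obs_grid = c(1, 5, 10, 15, 20, 30, 40),
                       n_reps = 100,
                       profile = c("full", "fast"),
                       n_rand = NULL, n_boot = NULL, n_repeat_obs = NULL,
                       seed = 1,
                       out_dir = "netsubsample-results") {
  profile <- match.arg(profile)
  defaults <- if (profile == "fast") {
    list(n_rand = 200L, n_boot = 200L, n_repeat_obs = 3L)
  } else {
    list(n_rand = 1000L, n_boot = 1000L, n_repeat_obs = 10L)
  }
  if (!is_count(seed, min = 0L)) stop("seed must be an integer", call. = FALSE)
  if (!is.null(data_path) && !file.exists(data_path)) {
    stop("data_path does not exist: ", data_path, call. = FALSE)
  }
  structure(list(
    generator = generator, data_path = data_path,
    min_days = as.integer(min_days), obs_cap = as.integer(obs_cap),
    individuals_grid = as.integer(individuals_grid),
    obs_grid = as.integer(obs_grid),
    n_reps = as.integer(n_reps), profile = profile,
    n_rand = as.integer(n_rand %||% defaults$n_rand),
    n_boot = as.integer(n_boot %||% defaults$n_boot),
    n_repeat_obs = as.integer(n_repeat_obs %||% defaults$n_repeat_obs),
    seed = as.integer(seed), out_dir = out_dir
  ), class = "run_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys mirror the [run_config()] arguments,
#'   with generator parameters under `generator:`.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  gen <- if (!is.null(y$generator)) do.call(roost_config, y$generator) else roost_config()
  y$generator <- NULL
  do.call(run_config, c(list(generator = gen), y))
}

#' Write a pipeline configuration to YAML
#' @param config A `run_config` object.
#' @param path Output path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  y <- unclass(config)
  gen <- unclass(y$generator)
  gen$n_communities <- NULL
  y$generator <- gen
  yaml::write_yaml(y, path)
  invisible(path)
}

write_meta <- function(path, config_hash, seed) {
  meta <- list(file = basename(path), config_hash = config_hash,
               master_seed = seed,
               package = paste0("netsubsample ",
                                as.character(utils::packageVersion("netsubsample"))))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Run the whole pipeline
#'
#' Generate (or load) detection data, build the balanced reference
#' network, run the subsampling experiment, summarize the grid, and fit
#' the regression analyses.  All artifacts are written under
#' `config$out_dir`, each with a sidecar `.meta.json` declaring the
#' configuration hash and master seed; a rerun with the same
#' configuration and seed reproduces the result files byte for byte.
#' Any stage failure aborts with a stage-named error.
#'
#' @param config A [run_config()] object (or path to a YAML config).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the reference, results table, grid
#'   summary, regression fits and output file paths.
#' @export
run_all <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  say <- function(...) if (!quiet) message(...)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- rlang::hash(unclass(config))
  files <- character()
  emit <- function(name) {
    p <- file.path(config$out_dir, name)
    write_meta(p, hash, config$seed)
    files <<- c(files, p)
    p
  }

  say("stage data: ", if (is.null(config$data_path)) "generating" else "loading",
      " detection records")
  data <- stage("data", {
    if (is.null(config$data_path)) {
      pop <- generate_population(config$generator,
                                 seed = derive_seed(config$seed, 101))
      write_roosting_csv(pop$data, file.path(config$out_dir, "data.csv"))
      emit("data.csv")
      pop$data
    } else {
      read_roosting_csv(config$data_path)
    }
  })

  say("stage observed: building balanced reference network")
  ref <- stage("observed", build_observed(
    data, min_days = config$min_days, obs_cap = config$obs_cap,
    n_rand = config$n_rand, n_boot = config$n_boot,
    n_repeat = config$n_repeat_obs, seed = derive_seed(config$seed, 102)))
  stage("observed", {
    jsonlite::write_json(
      c(ref$metrics, list(p_q = ref$p_q, r_com = ref$r_com_obs,
                          n_individuals = length(ref$ids),
                          obs_cap = ref$obs_cap)),
      file.path(config$out_dir, "observed.json"), auto_unbox = TRUE,
      pretty = TRUE, digits = NA)
    emit("observed.json")
  })

  say("stage experiment: ", length(config$individuals_grid) *
        length(config$obs_grid), " regimes x ", config$n_reps, " replicates")
  results <- stage("experiment", run_experiment(
    ref, individuals_grid = config$individuals_grid,
    obs_grid = config$obs_grid, n_reps = config$n_reps,
    n_rand = config$n_rand, n_boot = config$n_boot,
    seed = derive_seed(config$seed, 103), progress = !quiet))
  stage("experiment", {
    utils::write.csv(results, file.path(config$out_dir, "results.csv"),
                     row.names = FALSE)
    emit("results.csv")
  })

  say("stage summary")
  grid_summary <- stage("summary", summarize_grid(results, ref))
  stage("summary", {
    utils::write.csv(grid_summary, file.path(config$out_dir, "summary.csv"),
                     row.names = FALSE)
    emit("summary.csv")
  })

  say("stage analyze: regression models")
  regressions <- stage("analyze", {
    specs <- list(
      delta_n_comm = function() fit_discrepancy_model(results, "delta_n_comm"),
      delta_density = function() fit_discrepancy_model(results, "delta_density"),
      delta_clustering = function() fit_discrepancy_model(
        results, "delta_clustering", log_transform = FALSE),
      evidence = function() fit_detection_model(results, "evidence"),
      acceptable_rcom = function() fit_detection_model(results, "acceptable_rcom"))
    lapply(specs, function(f) tryCatch(f(), error = function(e) conditionMessage(e)))
  })
  stage("analyze", {
    rows <- lapply(names(regressions), function(nm) {
      r <- regressions[[nm]]
      if (!inherits(r, "netss_regression")) return(NULL)
      cbind(model = nm, r$terms, r_squared = r$r_squared)
    })
    tab <- do.call(rbind, rows)
    if (!is.null(tab)) {
      utils::write.csv(tab, file.path(config$out_dir, "regressions.csv"),
                       row.names = FALSE)
      emit("regressions.csv")
    }
    report <- file.path(config$out_dir, "report.txt")
    con <- file(report, open = "wt")
    on.exit(close(con), add = TRUE)
    sink(con)
    cat("netsubsample pipeline report\n\n")
    print(ref)
    cat("\nGrid summary (counts per regime out of", config$n_reps, "replicates):\n")
    print(grid_summary, row.names = FALSE)
    cat("\nRegression models:\n\n")
    for (nm in names(regressions)) {
      cat("--", nm, "--\n")
      r <- regressions[[nm]]
      if (inherits(r, "netss_regression")) print(r) else cat("not fitted:", r, "\n")
      cat("\n")
    }
    sink()
    emit("report.txt")
  })

  say("done: ", length(files), " artifacts in ", config$out_dir)
  invisible(list(ref = ref, results = results, summary = grid_summary,
                 regressions = regressions, files = files))
}
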