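#' Build a pipeline configuration
#'
#' A pipeline configuration names either a simulation setup (arguments for
#' [sim_config()]) or a directory of input CSV tables plus a food
#' composition table, together with the requirement configuration. It can
#' be built in R or read from YAML with [read_pipeline_config()].
#'
#' @param simulation Named list of [sim_config()] arguments, or `NULL`
#'   when reading observed tables.
#' @param inputs `NULL`, or a list with `tables` (directory for
#'   [read_tables()]) and `fct` (CSV path).
#' @param requirements `"default"` for the built-in requirement
#'   distributions, or a CSV path with columns as
#'   [default_requirements()]. Must be supplied.
#' @param iron_table `"default"` or a CSV path as
#'   [default_iron_table()].
#' @param seed Integer seed for the run.
#' @param outcomes Log-ratio outcomes for the inference stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = list(), inputs = NULL,
                            requirements = "default",
                            iron_table = "default",
                            seed = 1L,
                            outcomes = c("log_rdear", "log_mpa_ratio")) {
  structure(list(simulation = simulation, inputs = inputs,
                 requirements = requirements, iron_table = iron_table,
                 seed = as.integer(seed), outcomes = outcomes),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with the same fields.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path), class = "hh_io_error")
  }
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config(
    simulation = raw$simulation %||% list(),
    inputs = raw$inputs,
    requirements = raw$requirements %||% NULL,
    iron_table = raw$iron_table %||% "default",
    seed = raw$seed %||% 1L,
    outcomes = raw$outcomes %||% c("log_rdear", "log_mpa_ratio")
  )
  cfg$requirements <- raw$requirements
  cfg
}

resolve_requirements <- function(config) {
  req <- config$requirements
  if (is.null(req)) {
    abort("pipeline config must name requirement tables ('default' or a CSV path)",
          class = "hh_config_error")
  }
  if (identical(req, "default")) return(default_requirements())
  if (!file.exists(req)) {
    abort(sprintf("requirement table not found: %s", req),
          class = "hh_config_error")
  }
  readr::read_csv(req, show_col_types = FALSE)
}

resolve_iron_table <- function(config) {
  it <- config$iron_table %||% "default"
  if (identical(it, "default")) return(default_iron_table())
  if (!file.exists(it)) {
    abort(sprintf("iron probability table not found: %s", it),
          class = "hh_config_error")
  }
  readr::read_csv(it, show_col_types = FALSE)
}

#' Run the full allocation-analysis pipeline
#'
#' Executes every stage in order — data (simulated or read), per-visit
#' nutrient intakes, intake profiles and MDD-W, usual-intake models,
#' probability of adequacy and MPA, allocation ratios, equity tests and
#' determinant models — writing each stage's table as CSV into `out_dir`
#' together with a run log. Runs are deterministic for a fixed seed.
#'
#' @param config A [pipeline_config()] (or YAML path).
#' @param out_dir Output directory.
#' @param seed Optional override of the config seed.
#' @return Invisibly, a list with every stage's tables.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
  }
  cat(sprintf("pipeline run, seed %d\n", config$seed), file = log_path)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      log_line("stage %s failed: %s", name, conditionMessage(e))
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "hh_pipeline_error", parent = e)
    })
  }

  requirements <- stage("config", resolve_requirements(config))
  iron_table <- stage("config", resolve_iron_table(config))

  study <- stage("data", {
    if (is.null(config$inputs)) {
      sim_args <- config$simulation
      sim_args$seed <- config$seed
      study <- simulate_study(do.call(sim_config, sim_args))
      log_line("simulated %d households in %d clusters",
               nrow(study$households),
               dplyr::n_distinct(study$households$cluster_id))
      study
    } else {
      tabs <- read_tables(config$inputs$tables)
      tabs$fct <- read_fct(config$inputs$fct)
      log_line("read %d households from %s", nrow(tabs$households),
               config$inputs$tables)
      tabs
    }
  })
  write_tables(study, out_dir)
  write_fct(study$fct, file.path(out_dir, "fct.csv"))
  if (!is.null(study$ground_truth)) {
    readr::write_csv(study$ground_truth$members,
                     file.path(out_dir, "ground_truth_members.csv"))
    readr::write_csv(study$ground_truth$households,
                     file.path(out_dir, "ground_truth_households.csv"))
    yaml::write_yaml(config_echo(study$ground_truth$config),
                     file.path(out_dir, "config_echo.yaml"))
  }

  per_visit <- stage("nutrients",
                     portions_to_intake(study$portions, study$fct))
  readr::write_csv(per_visit, file.path(out_dir, "per_visit_intakes.csv"))
  profiles <- stage("nutrients",
                    intake_profiles(study$portions, study$visits,
                                    study$fct))
  readr::write_csv(profiles, file.path(out_dir, "intake_profiles.csv"))
  log_line("nutrient stage: %d member profiles", nrow(profiles))

  ui <- stage("usual_intake",
              usual_intakes(per_visit, study$members, study$households,
                            nutrients = hh_micronutrients()))
  readr::write_csv(ui$usual, file.path(out_dir, "usual_intakes.csv"))
  readr::write_csv(usual_model_summary(ui$models),
                   file.path(out_dir, "usual_intake_models.csv"))
  log_line("usual-intake stage: %d models", length(ui$models))

  adequacy <- stage("adequacy",
                    compute_adequacy(ui$usual, study$members,
                                     requirements, iron_table))
  readr::write_csv(adequacy, file.path(out_dir, "adequacy.csv"))
  log_line("adequacy stage: mean MPA %.3f", mean(adequacy$mpa))

  ratios <- stage("allocation",
                  allocation_ratios(profiles, study$members, adequacy))
  readr::write_csv(ratios, file.path(out_dir, "allocation_ratios.csv"))

  equity <- stage("inference",
                  equity_tests(ratios, study$households))
  readr::write_csv(equity, file.path(out_dir, "equity_tests.csv"))

  determinants <- stage("inference", {
    out <- list()
    for (pr in c("pw_hh", "pw_mil")) {
      frame <- determinant_frame(ratios, study$households, profiles,
                                 study$members, pair = pr)
      for (oc in intersect(config$outcomes, names(frame))) {
        fit <- fit_determinants(frame, oc)
        td <- tidy(fit)
        td$pair <- pr
        out[[length(out) + 1]] <- td
      }
    }
    list_rbind(out) |> select("pair", dplyr::everything())
  })
  readr::write_csv(determinants, file.path(out_dir, "determinants.csv"))
  log_line("inference stage: %d equity tests, %d determinant terms",
           nrow(equity), nrow(determinants))

  invisible(list(study = study, per_visit = per_visit,
                 profiles = profiles, usual = ui, adequacy = adequacy,
                 ratios = ratios, equity = equity,
                 determinants = determinants))
}

# YAML-serialisable echo of a sim_config
config_echo <- function(config) {
  out <- unclass(config)
  out$true_log_rdear_mean <- as.list(out$true_log_rdear_mean)
  out$food_use_probs <- NULL
  out$portion_lognormal_params <- NULL
  out
}
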