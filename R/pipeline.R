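#' Pipeline configuration
#'
#' Assembles (or reads from YAML) the configuration for [run_pipeline()]:
#' cohort settings, preset overrides, whether the analysis goes through the
#' rendered-frame detection chain or reads the event tables directly, and the
#' output directory.
#'
#' @param path Optional YAML file; entries mirror the arguments below.
#' @param n_per_group,runs_per_animal,seed Cohort settings (see
#'   [cohort_params()]).
#' @param frames If `TRUE`, analyze through render -> detect -> label;
#'   otherwise profile the simulated event tables directly.
#' @param write_frames Also write each run's frame stack as multi-page TIFF
#'   (slow and bulky; off by default).
#' @param out Output directory.
#' @param control,mptp Named lists of overrides applied to the two presets.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, n_per_group = 8, runs_per_animal = 6,
                            seed = 1L, frames = FALSE, write_frames = FALSE,
                            out = "gait_out", control = list(),
                            mptp = list()) {
  cfg <- list(n_per_group = n_per_group, runs_per_animal = runs_per_animal,
              seed = seed, frames = frames, write_frames = write_frames,
              out = out, control = control, mptp = mptp)
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    bad <- setdiff(names(user), names(cfg))
    if (length(bad)) {
      stop("pipeline_config: unknown config key(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    cfg[names(user)] <- user
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full simulation-and-analysis pipeline
#'
#' simulate -> (render -> detect -> label | read events) -> gait parameters ->
#' open field -> group statistics and TH-correlation report, all driven by a
#' single seed. Outputs written to `config$out`: `events.csv` (all contact
#' events), `animals.csv`, `trajectories.csv`, `profiles.csv` (tidy gait
#' table), `group_summary.csv`, `anova.csv`, `correlations.csv`, `report.md`
#' and `manifest.json` (package version, seed, config hash). Identical
#' config + seed give byte-identical CSV outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`cohort`,
#'   `profiles`, `group_summary`, `anova`, `correlations`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage [%s] failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  ctrl <- stage("presets", do.call(control_params, config$control))
  mptp <- stage("presets", do.call(mptp_params, config$mptp))
  cohort <- stage("simulate", simulate_cohort(
    ctrl, mptp, cohort_params(n_per_group = config$n_per_group,
                              runs_per_animal = config$runs_per_animal,
                              seed = config$seed)))

  ev_all <- dplyr::bind_rows(lapply(seq_len(nrow(cohort$animals)), function(a) {
    dplyr::bind_rows(lapply(seq_along(cohort$runs[[a]]), function(r) {
      ev <- cohort$runs[[a]][[r]]$events
      ev$animal <- cohort$animals$animal[a]; ev$run <- r
      ev
    }))
  }))
  readr::write_csv(ev_all[c("animal", "run", "paw", "t_on", "t_off", "x", "y",
                            "max_area", "max_intensity")],
                   file.path(config$out, "events.csv"))

  if (isTRUE(config$write_frames)) {
    stage("render", for (a in seq_len(nrow(cohort$animals))) {
      for (r in seq_along(cohort$runs[[a]])) {
        fs <- render_frames(cohort$runs[[a]][[r]])
        write_frames_tiff(fs, file.path(config$out, sprintf(
          "frames_%s_run%d.tiff", cohort$animals$animal[a], r)))
      }
    })
  }

  profiles <- stage("analyze", cohort_gait_table(
    cohort, chain = if (isTRUE(config$frames)) "frames" else "events"))
  readr::write_csv(profiles, file.path(config$out, "profiles.csv"))

  traj_tab <- dplyr::bind_rows(lapply(names(cohort$trajectories), function(a) {
    dplyr::mutate(cohort$trajectories[[a]], animal = a, .before = 1L)
  }))
  readr::write_csv(traj_tab, file.path(config$out, "trajectories.csv"))

  of <- stage("openfield", tibble::tibble(
    animal = cohort$animals$animal,
    group = cohort$animals$group,
    distance = vapply(cohort$animals$animal, function(a) {
      path_length(cohort$trajectories[[a]])$total_distance
    }, numeric(1))))
  animals_out <- dplyr::left_join(cohort$animals,
                                  of[c("animal", "distance")], by = "animal")
  readr::write_csv(animals_out, file.path(config$out, "animals.csv"))

  per_animal <- dplyr::summarise(
    dplyr::group_by(profiles, animal, group, parameter, paw),
    value = mean(value, na.rm = TRUE), .groups = "drop")
  gs <- stage("stats", dplyr::bind_rows(lapply(
    split(per_animal, list(per_animal$parameter, per_animal$paw),
          drop = TRUE, sep = "|"),
    function(sub) {
      dplyr::mutate(group_summary(sub$value, sub$group),
                    parameter = sub$parameter[1L], paw = sub$paw[1L],
                    .before = 1L)
    })))
  gs <- dplyr::bind_rows(gs, dplyr::mutate(
    group_summary(of$distance, of$group),
    parameter = "openfield_distance", paw = NA_character_, .before = 1L))
  readr::write_csv(gs, file.path(config$out, "group_summary.csv"))

  aov_tab <- stage("stats", dplyr::bind_rows(lapply(
    split(per_animal, list(per_animal$parameter, per_animal$paw),
          drop = TRUE, sep = "|"),
    function(sub) {
      a <- one_way_anova(sub$value, sub$group)
      tibble::tibble(parameter = sub$parameter[1L], paw = sub$paw[1L],
                     F = a$F, df_between = a$df_between,
                     df_within = a$df_within, p = a$p)
    })))
  readr::write_csv(aov_tab, file.path(config$out, "anova.csv"))

  cors <- stage("report", correlation_table(
    profiles, cohort$animals, trajectories = cohort$trajectories))
  readr::write_csv(cors, file.path(config$out, "correlations.csv"))

  manifest <- list(
    package = "mousegait",
    version = as.character(utils::packageVersion("mousegait")),
    seed = config$seed,
    config = config_no_path(config),
    config_hash = config_hash(config),
    n_animals = nrow(cohort$animals),
    n_runs = sum(lengths(cohort$runs))
  )
  jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  writeLines(report_md(gs, cors, manifest), file.path(config$out, "report.md"))
  invisible(list(cohort = cohort, profiles = profiles, group_summary = gs,
                 anova = aov_tab, correlations = cors, manifest = manifest))
}

# the output path is not part of the scientific configuration: identical
# settings must give identical manifests wherever they are written
config_no_path <- function(config) {
  cfg <- unclass(config)
  cfg$out <- NULL
  cfg
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(config_no_path(config), f, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(f))
}

report_md <- function(gs, cors, manifest) {
  fmt <- function(x, d = 3) formatC(x, digits = d, format = "fg")
  lines <- c(
    "# Gait analysis report", "",
    sprintf("Package mousegait %s, seed %s, config hash `%s`.",
            manifest$version, manifest$seed, manifest$config_hash), "",
    "## Group summaries (mean +/- SEM)", "",
    "| parameter | paw | group | n | mean | SEM |",
    "|---|---|---|---|---|---|",
    sprintf("| %s | %s | %s | %d | %s | %s |",
            gs$parameter, ifelse(is.na(gs$paw), "-", gs$paw), gs$group,
            gs$n, fmt(gs$mean), fmt(gs$sem)),
    "", "## Correlation with SN TH level", "",
    "| parameter | paw | r | p | n |",
    "|---|---|---|---|---|",
    sprintf("| %s | %s | %s | %s | %d |",
            cors$parameter, ifelse(is.na(cors$paw), "-", cors$paw),
            fmt(cors$r), formatC(cors$p, digits = 3, format = "g"), cors$n)
  )
  lines
}
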