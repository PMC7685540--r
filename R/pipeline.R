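#' Default pipeline configuration
#'
#' Nested list of parameters for [run_pipeline()].  Top-level sections:
#' `table` ([table_profile()] arguments), `cohort` (n_subjects, MSI
#' mean/SD, drift, noise), `observer` (per-biomarker investigator error
#' and rater-bias SDs), `raters`, `pairings`, `analysis` (trim basis,
#' phases, ICC type, SEM method), `tracking` (`enabled` plus
#' [register_first_image()] / [track_search_config()] settings), `seed`.
#' Angles are degrees throughout; biomarkers are unitless.
#'
#' @return Named list with the default configuration.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    table = list(accel = 6, plateau_velocity = 6, max_angle = 40,
                 frame_rate = 15, include_return = TRUE),
    cohort = list(n_subjects = 30L, msi_mean = 0.24, msi_sd = 0.09,
                  drift_mean = 0.04, drift_sd = 0.015, noise_sd = 0.52),
    observer = list(msi = list(error_sd = 0.024, rater_bias_sd = 0),
                    msv = list(error_sd = 0.020, rater_bias_sd = 0)),
    raters = c("AxB", "DT1", "DT2"),
    pairings = list(intra = c("DT1", "DT2"), inter = c("AxB", "DT1"),
                    completeness = c("AxB", "DT2")),
    analysis = list(trim = "amplitude", phases = "both",
                    icc_type = "agreement", sem_method = "anova"),
    tracking = list(enabled = FALSE, n_repeats = 5L, perturbation_sd = 1,
                    noise_sd = 0, write_frames = FALSE),
    write_sequences = TRUE)
}

validate_config <- function(config) {
  ref <- default_config()
  unknown <- setdiff(names(config), names(ref))
  if (length(unknown))
    stop("invalid config key(s): ", paste(unknown, collapse = ", "))
  for (sec in c("table", "cohort", "analysis", "tracking")) {
    if (is.null(config[[sec]])) next
    bad <- setdiff(names(config[[sec]]), names(ref[[sec]]))
    if (length(bad))
      stop("invalid config key(s) in `", sec, "`: ", paste(bad, collapse = ", "))
  }
  out <- utils::modifyList(ref, config)
  ## pairings and raters are replaced wholesale, not merged element-wise
  if (!is.null(config$pairings)) out$pairings <- config$pairings
  if (!is.null(config$raters)) out$raters <- config$raters
  if (is.null(out$seed)) stop("config must carry a `seed` (stochastic stages enabled)")
  out
}

#' Read a pipeline configuration from a JSON file
#'
#' Unknown keys are rejected with an error naming them; missing keys fall
#' back to [default_config()].
#'
#' @param path JSON file.
#' @return Validated configuration list.
#' @export
read_config <- function(path) {
  config <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(config)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[spineshare] %-12s %s", stage, sprintf(...)))
}

#' Run the end-to-end simulation and repeatability pipeline
#'
#' Stages: (1) simulate a cohort of subjects under the table profile;
#' (2) optionally render each subject's image sequence and re-derive the
#' intervertebral angles by template tracking, once per rater with
#' rater-specific first-image registration; (3) compute MSI and MSV per
#' subject; (4) build subjects x raters reading matrices (when tracking is
#' disabled, investigator error is injected directly on the biomarkers via
#' the observer model); (5) repeatability analysis per biomarker and
#' pairing; (6) write the report.  All outputs are deterministic given the
#' config and seed, and every JSON artifact carries a provenance block
#' (package version, config hash, seed).
#'
#' @param config configuration list (see [default_config()]) or path to a
#'   JSON config file.
#' @param outdir output directory.
#' @param seed optional override of `config$seed`.
#' @return (Invisibly) a list with the reading matrices, the
#'   [repeatability_report()] and the output paths.
#' @export
run_pipeline <- function(config = default_config(), outdir, seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  config <- validate_config(config)
  if (!is.null(seed)) config$seed <- seed
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  provenance <- list(package = "spineshare",
                     version = as.character(utils::packageVersion("spineshare")),
                     config_hash = config_hash(config), seed = config$seed)

  ## stage 1: simulate
  profile <- do.call(table_profile, config$table)
  cohort <- do.call(generate_cohort,
                    c(list(profile = profile, seed = config$seed),
                      config$cohort))
  n <- length(cohort$sequences)
  pipeline_log("simulate", "%d subjects, %d frames each, config %s",
               n, length(cohort$sequences[[1]]$frame_times),
               provenance$config_hash)
  if (isTRUE(config$write_sequences)) {
    seq_dir <- file.path(outdir, "sequences")
    dir.create(seq_dir, showWarnings = FALSE)
    for (id in names(cohort$sequences))
      write_motion_sequence(cohort$sequences[[id]],
                            file.path(seq_dir, paste0(id, ".csv")))
  }

  ## stages 2-4: per-rater biomarker readings
  raters <- config$raters
  readings <- if (isTRUE(config$tracking$enabled)) {
    pipeline_log("track", "tracking enabled: render + track per rater")
    track_readings(cohort, config, outdir)
  } else {
    observed_readings(cohort, config)
  }
  pipeline_log("biomarkers", "reading matrices %d x %d (raters: %s)",
               n, length(raters), paste(raters, collapse = ", "))
  readings_df <- do.call(rbind, lapply(names(readings), function(bm) {
    m <- readings[[bm]]
    data.frame(subject = rep(rownames(m), ncol(m)),
               rater = rep(colnames(m), each = nrow(m)),
               biomarker = bm, value = as.vector(m))
  }))
  utils::write.csv(readings_df, file.path(outdir, "readings.csv"),
                   row.names = FALSE)

  ## stage 5: repeatability
  report <- repeatability_report(
    readings, pairings = config$pairings, outdir = outdir,
    type = config$analysis$icc_type, sem_method = config$analysis$sem_method)
  pipeline_log("repeat", "%d pairings x %d biomarkers analysed",
               length(config$pairings), length(readings))

  ## stage 6: report
  results_json <- file.path(outdir, "results.json")
  jsonlite::write_json(
    list(provenance = provenance,
         group_stats = report$group_stats,
         repeatability = report$table),
    results_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_report_md(report, file.path(outdir, "report.md"), provenance)
  pipeline_log("report", "written to %s", outdir)
  invisible(list(cohort = cohort, readings = readings, report = report,
                 paths = list(results = results_json, outdir = outdir)))
}

## Tracking-free route: investigator error injected on the biomarker scale.
observed_readings <- function(cohort, config) {
  truth <- vapply(cohort$sequences, function(s) {
    r <- motion_share(s, trim = config$analysis$trim,
                      phases = config$analysis$phases)
    c(msi = r$msi, msv = r$msv)
  }, numeric(2L))
  raters <- config$raters
  out <- lapply(c(msi = "msi", msv = "msv"), function(bm) {
    ob <- config$observer[[bm]]
    m <- with_seed(derive_seed(config$seed, match(bm, c("msi", "msv"))), {
      bias <- rnorm(length(raters), 0, ob$rater_bias_sd)
      err <- matrix(rnorm(ncol(truth) * length(raters), 0, ob$error_sd),
                    ncol(truth), length(raters))
      truth[bm, ] + matrix(bias, ncol(truth), length(raters), byrow = TRUE) + err
    })
    dimnames(m) <- list(colnames(truth), raters)
    m
  })
  out
}

## Tracking route: per rater, register (with investigator perturbation),
## track, extract angles, compute biomarkers.
track_readings <- function(cohort, config, outdir) {
  raters <- config$raters
  geometry <- vertebral_geometry()
  subjects <- names(cohort$sequences)
  msi <- msv <- matrix(NA_real_, length(subjects), length(raters),
                       dimnames = list(subjects, raters))
  for (i in seq_along(subjects)) {
    iseq <- render_frames(cohort$sequences[[i]], geometry,
                          noise_sd = config$tracking$noise_sd,
                          seed = derive_seed(config$seed, 500 + i))
    if (isTRUE(config$tracking$write_frames))
      write_image_sequence(iseq, file.path(outdir, "frames", subjects[i]))
    for (j in seq_along(raters)) {
      tmpl <- register_first_image(
        iseq$frames[[1]], geometry,
        n_repeats = config$tracking$n_repeats,
        perturbation_sd = config$tracking$perturbation_sd,
        seed = derive_seed(config$seed, 1000 * j + i))
      series <- track_sequence(iseq, tmpl)
      if (any(series$flag)) series <- retrack_failures(series, iseq, tmpl)
      seq_hat <- extract_intervertebral_angles(series)
      r <- motion_share(seq_hat, trim = config$analysis$trim,
                        phases = config$analysis$phases)
      msi[i, j] <- r$msi; msv[i, j] <- r$msv
    }
    pipeline_log("track", "subject %s done (%d raters)", subjects[i],
                 length(raters))
  }
  list(msi = msi, msv = msv)
}

write_report_md <- function(report, path, provenance) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# Motion sharing repeatability report")
  w("")
  w("Package spineshare %s | config %s | seed %s",
    provenance$version, provenance$config_hash, provenance$seed)
  w("")
  w("## Group descriptive statistics")
  w("")
  w("| biomarker | reading set | mean | SD | n |")
  w("|---|---|---|---|---|")
  gs <- report$group_stats
  for (i in seq_len(nrow(gs)))
    w("| %s | %s | %.2f | %.2f | %d |", toupper(gs$biomarker[i]), gs$rater[i],
      gs$mean[i], gs$sd[i], gs$n[i])
  w("")
  w("## Repeatability")
  w("")
  w("| biomarker | pairing | raters | ICC (95%% CI) | category | SEM | SEM %% | MD |")
  w("|---|---|---|---|---|---|---|---|")
  tb <- report$table
  for (i in seq_len(nrow(tb)))
    w("| %s | %s | %s | %.2f (%.2f, %.2f) | %s | %.3f | %d%% | %.3f |",
      toupper(tb$biomarker[i]), tb$pairing[i], tb$raters[i], tb$icc[i],
      tb$ci_lower[i], tb$ci_upper[i], tb$category[i], tb$sem[i],
      tb$sem_pct[i], tb$md[i])
  invisible(path)
}
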