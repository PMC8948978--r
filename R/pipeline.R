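#' Pipeline configuration
#'
#' Configures an end-to-end run: input (a directory of per-patient
#' subdirectories with `mesh.ply`/`mesh.stl`/`mesh.obj`, `cll.csv` or
#' `cll.json`, and `landmarks.json` or `landmarks.csv`, or a synthetic
#' [cohort_spec()]), parametrization settings, evaluation settings, and
#' the output directory.
#'
#' @param input_dir directory of per-patient inputs, or `NULL` when
#'   `synthetic` is given.
#' @param synthetic a [cohort_spec()], or `NULL` when `input_dir` is given.
#' @param config a [param_config()].
#' @param k_values component counts for the evaluation metrics.
#' @param specificity_samples random shapes per specificity evaluation.
#' @param seed integer seed for all stochastic steps (required).
#' @param out_dir output directory (created if absent).
#' @param mode_pcs component indices for which mode meshes are written.
#' @param mode_sds SD multipliers for the mode meshes.
#' @param skip_failures if `TRUE`, patients that fail any stage are skipped
#'   (and logged) instead of aborting the run.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, synthetic = NULL,
                            config = param_config(), k_values = c(5L, 9L),
                            specificity_samples = 1000L, seed,
                            out_dir, mode_pcs = 1:5, mode_sds = c(-3, 0, 3),
                            skip_failures = FALSE) {
  if (is.null(input_dir) == is.null(synthetic))
    ssm_stop("bad_config", "give exactly one of input_dir or synthetic")
  if (missing(seed)) ssm_stop("bad_config", "a seed is required")
  structure(list(input_dir = input_dir, synthetic = synthetic,
                 config = config, k_values = as.integer(k_values),
                 specificity_samples = as.integer(specificity_samples),
                 seed = as.integer(seed), out_dir = out_dir,
                 mode_pcs = as.integer(mode_pcs), mode_sds = mode_sds,
                 skip_failures = isTRUE(skip_failures)),
            class = "pipeline_config")
}

# Hash of the serialized configuration, stamped into every output file.
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(
    list(config = unclass(cfg$config),
         synthetic = if (!is.null(cfg$synthetic)) {
           s <- unclass(cfg$synthetic)
           s$mean_params <- as.list(unclass(s$mean_params))
           s
         },
         input_dir = cfg$input_dir, k_values = cfg$k_values,
         specificity_samples = cfg$specificity_samples, seed = cfg$seed,
         mode_pcs = cfg$mode_pcs, mode_sds = cfg$mode_sds),
    tmp, digits = NA, auto_unbox = TRUE)
  unname(tools::md5sum(tmp))
}

read_patient_dir <- function(dir) {
  pick <- function(names) {
    for (f in names) if (file.exists(file.path(dir, f))) return(file.path(dir, f))
    ssm_stop("missing_file", "none of %s found in %s",
             paste(names, collapse = "/"), dir)
  }
  list(mesh = read_mesh(pick(c("mesh.ply", "mesh.stl", "mesh.obj"))),
       cll = read_centerline(pick(c("cll.csv", "cll.json"))),
       landmarks = read_landmarks(pick(c("landmarks.json", "landmarks.csv"))))
}

#' Write a synthetic cohort to disk
#'
#' One subdirectory per synthetic patient containing `mesh.ply`, `cll.csv`,
#' `landmarks.json`, and `truth.json` (the generative mode draws).
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort_dir <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort$shapes)) {
    sub <- file.path(dir, sprintf("synthetic_%03d", i))
    dir.create(sub, showWarnings = FALSE)
    s <- cohort$shapes[[i]]
    write_mesh(s$mesh, file.path(sub, "mesh.ply"))
    write_centerline(s$cll, file.path(sub, "cll.csv"))
    write_landmarks(s$landmarks, file.path(sub, "landmarks.json"))
    jsonlite::write_json(c(as.list(cohort$truth[i, ]),
                           list(noise_sd = cohort$noise_sd)),
                         file.path(sub, "truth.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  invisible(dir)
}

#' Run the full SSM pipeline
#'
#' Generates or ingests the cohort, parametrizes every patient, aligns and
#' stacks the shape vectors, fits the SSM, writes mode meshes, and runs the
#' full quality evaluation. Artifacts written under `out_dir`: per-patient
#' `grids/<id>.csv`, `cohort.csv`, `model.json`, `modes/pc<i>_s<s>.ply`,
#' `report.json`, `report.csv`, `run.log.jsonl`, and `config.json`. Every
#' artifact carries the configuration hash. The run is deterministic for a
#' fixed seed.
#'
#' @param cfg a [pipeline_config()].
#' @return Invisibly, a list with the fitted `model`, `cohort`, `report`,
#'   `failures` (ids and messages of skipped patients), and `hash`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(cfg$out_dir, "grids"), showWarnings = FALSE)
  dir.create(file.path(cfg$out_dir, "modes"), showWarnings = FALSE)
  hash <- config_hash(cfg)
  logfile <- file.path(cfg$out_dir, "run.log.jsonl")
  unlink(logfile)
  log_event <- function(...) {
    entry <- list(...)
    entry$elapsed_s <- round(as.numeric(proc.time()[["elapsed"]]) - t0, 3)
    cat(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA), "\n",
        sep = "", file = logfile, append = TRUE)
  }
  t0 <- as.numeric(proc.time()[["elapsed"]])
  log_event(stage = "start", config_hash = hash, seed = cfg$seed,
            n_stations = cfg$config$n_stations, n_rays = cfg$config$n_rays,
            neck_end = cfg$config$neck_end)

  if (!is.null(cfg$synthetic)) {
    cohort_raw <- generate_cohort(cfg$synthetic, cfg$config)
    triples <- cohort_raw$shapes
    ids <- sprintf("synthetic_%03d", seq_along(triples))
    log_event(stage = "synthesize", n = length(triples),
              noise_sd = cohort_raw$noise_sd)
  } else {
    dirs <- list.dirs(cfg$input_dir, recursive = FALSE)
    if (length(dirs) == 0L)
      ssm_stop("missing_file", "no patient subdirectories in %s", cfg$input_dir)
    ids <- basename(dirs)
    triples <- vector("list", length(dirs))
    log_event(stage = "ingest", n = length(dirs))
  }

  vectors <- list(); kept <- character(); failures <- list()
  for (i in seq_along(ids)) {
    res <- tryCatch({
      tr <- if (!is.null(cfg$synthetic)) triples[[i]]
            else read_patient_dir(list.dirs(cfg$input_dir, recursive = FALSE)[i])
      grid <- parametrize_neck(tr$mesh, tr$cll, tr$landmarks, cfg$config,
                               id = ids[i])
      aligned <- align_to_baseline(rearrange_longitudinal(grid))
      write_grid_csv(aligned, file.path(cfg$out_dir, "grids",
                                        paste0(ids[i], ".csv")), hash)
      flatten_grid(aligned)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[ids[i]]] <- conditionMessage(res)
      log_event(stage = "parametrize", id = ids[i], status = "failed",
                message = conditionMessage(res))
      if (!cfg$skip_failures)
        ssm_stop("patient_failed", "patient %s failed: %s (use skip_failures to continue)",
                 ids[i], conditionMessage(res))
    } else {
      vectors[[ids[i]]] <- res
      kept <- c(kept, ids[i])
      log_event(stage = "parametrize", id = ids[i], status = "ok")
    }
  }

  cohort <- shape_cohort(vectors[kept], ids = kept,
                         rings = cfg$config$n_stations,
                         rays = cfg$config$n_rays)
  write_cohort_csv(cohort, file.path(cfg$out_dir, "cohort.csv"))
  model <- fit_ssm(cohort)
  write_model(model, file.path(cfg$out_dir, "model.json"))
  log_event(stage = "fit", n_shapes = nrow(cohort$matrix),
            n_components = length(model$eigenvalues))

  for (pc in cfg$mode_pcs[cfg$mode_pcs <= length(model$eigenvalues)]) {
    for (s in cfg$mode_sds) {
      mm <- mode_mesh(model, pc, s)
      write_mesh(mm, file.path(cfg$out_dir, "modes",
                               sprintf("pc%d_s%+g.ply", pc, s)),
                 comment = paste("config_hash", hash))
    }
  }

  report <- evaluate_all(cohort, k_values = cfg$k_values,
                         n_samples = cfg$specificity_samples, seed = cfg$seed)
  write_report(report, file.path(cfg$out_dir, "report.json"))
  write_report(report, file.path(cfg$out_dir, "report.csv"))
  jsonlite::write_json(list(config_hash = hash, seed = cfg$seed,
                            k_values = cfg$k_values,
                            specificity_samples = cfg$specificity_samples,
                            n_patients = length(kept),
                            failures = failures),
                       file.path(cfg$out_dir, "config.json"),
                       digits = NA, auto_unbox = TRUE)
  log_event(stage = "done", n_failures = length(failures))
  invisible(list(model = model, cohort = cohort, report = report,
                 failures = failures, hash = hash))
}

# Per-patient grid CSV: one row per contour point.
write_grid_csv <- function(grid, path, hash = NULL) {
  d <- dim(grid$points)
  df <- data.frame(
    ring = rep(seq_len(d[1L]), each = d[2L]),
    ray = rep(seq_len(d[2L]), times = d[1L]),
    angle_deg = rep((seq_len(d[2L]) - 1L) * 360 / d[2L], times = d[1L]),
    x = as.vector(t(grid$points[, , 1L])),
    y = as.vector(t(grid$points[, , 2L])),
    z = as.vector(t(grid$points[, , 3L])),
    arc_mm = if (is.null(grid$arc)) NA_real_ else rep(grid$arc, each = d[2L]))
  con <- file(path, "w")
  if (!is.null(hash)) writeLines(paste("# config_hash:", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(path)
}
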