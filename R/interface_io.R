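# On-disk formats, configuration and pipeline assembly.
#
# Traces are one CSV per molecule (frame, donor, acceptor; 0-based frames)
# plus a JSON manifest carrying the simulation config, the seed, and the
# file inventory. Ground truth travels as a CSV of state intervals plus a
# per-molecule truth table.

#' Write an ensemble of traces (and ground truth) to a directory
#'
#' @param ensemble a `fret_ensemble` from [simulate_ensemble()], or a bare
#'   list of `fluor_trace`.
#' @param dir output directory (created if needed).
#' @param ground_truth write the ground-truth CSVs when available.
#' @return Invisibly, the manifest list.
#' @export
write_traces <- function(ensemble, dir, ground_truth = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  traces <- if (inherits(ensemble, "fret_ensemble")) ensemble$traces
            else ensemble
  files <- character(length(traces))
  for (k in seq_along(traces)) {
    tr <- traces[[k]]
    files[k] <- paste0(tr$molecule_id, ".csv")
    write.csv(data.frame(frame = seq_along(tr$donor) - 1L,
                         donor = tr$donor, acceptor = tr$acceptor),
              file.path(dir, files[k]), row.names = FALSE)
  }
  manifest <- list(
    format = "aptakinetics-traces-v1",
    frame_interval = traces[[1]]$frame_interval,
    molecules = vapply(traces, `[[`, "", "molecule_id"),
    files = files)
  if (inherits(ensemble, "fret_ensemble")) {
    manifest$config <- unclass(ensemble$config)
    manifest$seed <- ensemble$config$seed
    if (ground_truth) {
      paths <- do.call(rbind, lapply(names(ensemble$truth$paths), function(id) {
        p <- ensemble$truth$paths[[id]]
        data.frame(molecule_id = id, state = p$state,
                   start_s = p$start, end_s = p$end)
      }))
      write.csv(paths, file.path(dir, "ground_truth_paths.csv"),
                row.names = FALSE)
      write.csv(ensemble$truth$table,
                file.path(dir, "ground_truth_molecules.csv"),
                row.names = FALSE)
    }
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read traces written by [write_traces()]
#'
#' Validates the schema: each CSV must have columns frame, donor, acceptor
#' with 0-based consecutive frames; the frame interval comes from the
#' manifest. Malformed files are reported with the file name and offending
#' line.
#'
#' @param dir directory containing trace CSVs and `manifest.json`.
#' @return A list of `fluor_trace` (possibly empty, with a warning).
#' @export
read_traces <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json in ", dir)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  if (length(mf$files) == 0) {
    warning("manifest lists no trace files in ", dir)
    return(list())
  }
  traces <- vector("list", length(mf$files))
  for (k in seq_along(mf$files)) {
    f <- file.path(dir, mf$files[k])
    d <- read.csv(f)
    miss <- setdiff(c("frame", "donor", "acceptor"), names(d))
    if (length(miss))
      stop(sprintf("%s: missing column(s) %s", mf$files[k],
                   paste(miss, collapse = ", ")))
    if (nrow(d) == 0) stop(sprintf("%s: empty trace", mf$files[k]))
    bad <- which(diff(d$frame) != 1)
    if (length(bad))
      stop(sprintf("%s: non-consecutive frame index at line %d",
                   mf$files[k], bad[1] + 2L))
    if (anyNA(d$donor) || anyNA(d$acceptor))
      stop(sprintf("%s: missing intensity value at line %d", mf$files[k],
                   which(!complete.cases(d))[1] + 1L))
    traces[[k]] <- structure(
      list(molecule_id = mf$molecules[k],
           frame_interval = mf$frame_interval,
           donor = d$donor, acceptor = d$acceptor),
      class = "fluor_trace")
  }
  names(traces) <- mf$molecules
  traces
}

default_pipeline_config <- function() {
  list(
    seed = 1L,
    simulate = list(enabled = TRUE, n_molecules = 50,
                    k_on = 0.7e8, c_nM = 5, k_off = 0.7,
                    frame_interval = 0.1, n_frames = 3000,
                    fret_mode = "fixed_2pca",
                    fret_mean = 0.38, fret_sd = 0.14),
    analyze = list(min_frames = 4, donor_only_cut = 0.15, min_events = 10),
    kinetics = list(enabled = TRUE, min_n = 50))
}

#' Run the simulate -> analyze -> kinetics pipeline from a config
#'
#' Config is a nested list (or a YAML/JSON file path) with sections
#' `simulate` (trace generation; set `enabled: false` and give `traces_dir`
#' to analyze pre-existing files), `analyze` (segmentation and QC) and
#' `kinetics`. All randomness flows from `config$seed`. Outputs (events
#' table, kinetics report, manifest) are written under `out_dir`.
#'
#' @param config nested list or path to a YAML/JSON config file.
#' @param out_dir output directory.
#' @return Invisibly, the run manifest (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir) {
  if (is.character(config)) {
    config <- if (grepl("[.]ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(default_pipeline_config(), config)
  for (f in c("k_on", "c_nM", "k_off", "frame_interval", "n_frames",
              "fret_mean", "fret_sd"))   # guard against YAML string scalars
    cfg$simulate[[f]] <- as.numeric(cfg$simulate[[f]])
  if (cfg$simulate$enabled &&
      (cfg$simulate$k_on < 0 || cfg$simulate$k_off < 0 ||
       cfg$simulate$c_nM < 0))
    stop("validation: rates and concentration must be non-negative")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- character(0)
  c_M <- cfg$simulate$c_nM * 1e-9

  if (cfg$simulate$enabled) {
    sim_cfg <- trace_sim_config(
      k_on = cfg$simulate$k_on, c = c_M, k_off = cfg$simulate$k_off,
      frame_interval = cfg$simulate$frame_interval,
      n_frames = cfg$simulate$n_frames, fret_mode = cfg$simulate$fret_mode,
      fret_mean = cfg$simulate$fret_mean, fret_sd = cfg$simulate$fret_sd,
      seed = cfg$seed)
    ens <- simulate_ensemble(sim_cfg, cfg$simulate$n_molecules)
    write_traces(ens, file.path(out_dir, "traces"))
    traces <- ens$traces
    stages <- c(stages, "simulate")
  } else {
    if (is.null(cfg$traces_dir)) stop("stage analyze: no traces_dir given")
    traces <- read_traces(cfg$traces_dir)
  }

  an <- analyze_traces(traces, min_frames = cfg$analyze$min_frames,
                       donor_only_cut = cfg$analyze$donor_only_cut)
  qc <- qc_filter(an$events, min_events = cfg$analyze$min_events)
  write.csv(an$events, file.path(out_dir, "events.csv"), row.names = FALSE)
  stages <- c(stages, "analyze")

  report <- NULL
  if (isTRUE(cfg$kinetics$enabled)) {
    est <- estimate_kinetics(traces, c = c_M,
                             min_frames = cfg$analyze$min_frames,
                             min_events = cfg$analyze$min_events,
                             min_n = cfg$kinetics$min_n)
    report <- list(k_off = est$k_off, k_on = est$k_on, K_d = est$K_d,
                   tau_b = est$tau_b, tau_ub = est$tau_ub,
                   n_bound = est$fits$bound$n_used,
                   n_unbound = est$fits$unbound$n_used,
                   censored_fraction = est$dwells$censored_fraction)
    jsonlite::write_json(report, file.path(out_dir, "kinetics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stages <- c(stages, "kinetics")
  }

  manifest <- list(
    format = "aptakinetics-run-v1",
    seed = cfg$seed,
    stages = stages,
    config = cfg,
    qc = list(molecules_kept = qc$n_kept, molecules_rejected = qc$n_rejected,
              n_events = nrow(an$events)),
    kinetics = report,
    outputs = list.files(out_dir, recursive = TRUE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Write a sensor response to CSV
#'
#' @param response a `sensor_response`.
#' @param path output CSV path (columns t_s, B_mol_m2, residual).
#' @return Invisibly, `path`.
#' @export
write_response <- function(response, path) {
  write.csv(data.frame(t_s = response$times, B_mol_m2 = response$B,
                       residual = c(NA, response$residual)),
            path, row.names = FALSE)
  invisible(path)
}
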