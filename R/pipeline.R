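## Config-driven orchestration: ingest a trajectory, run superposition
## metrics, orientation descriptors, bootstrap statistics and state
## segmentation, and emit a machine-readable report.

REPORT_SCHEMA_VERSION <- "1.0"

#' Build a run configuration
#'
#' @param trajectory path to the trajectory file.
#' @param format trajectory format (`"pdb"`, `"xyz"`, `"dcd"`).
#' @param reference optional path to a single-model PDB used as the RMSD
#'   reference; default is the first frame.
#' @param topology optional path to a PDB supplying the topology for
#'   xyz/dcd input.
#' @param lipid_selection list with any of `chain`, `atom_name` selecting
#'   the lipid reference atoms, or `NULL` to use the fallback membrane frame
#'   (normal +z, midplane at the origin).
#' @param membrane_mode `"per_frame"` (re-estimate the bilayer frame every
#'   frame), `"static"` (first frame only), or `"fallback"`.
#' @param dt_ps frame spacing when the file has no timestamps.
#' @param domain cytoplasmic-domain residue range (default `c(1, 16)`).
#' @param n_resamples,block_length_ns,confidence_level bootstrap settings.
#' @param theta_up,theta_down,min_dwell_ns state-classification settings.
#' @param seed integer seed recorded in every artifact.
#' @param out_dir optional output directory; when given, [run_pipeline()]
#'   writes TSV/JSON artifacts there.
#' @return object of class `RunConfig`.
#' @export
run_config <- function(trajectory,
                       format = "pdb",
                       reference = NULL,
                       topology = NULL,
                       lipid_selection = list(chain = "X", atom_name = "P"),
                       membrane_mode = c("per_frame", "static", "fallback"),
                       dt_ps = 1,
                       domain = c(1L, 16L),
                       n_resamples = 1000L,
                       block_length_ns = 1,
                       confidence_level = 0.95,
                       theta_up = 35,
                       theta_down = 28,
                       min_dwell_ns = 1,
                       seed = 1L,
                       out_dir = NULL) {
  membrane_mode <- match.arg(membrane_mode)
  cfg <- list(trajectory = trajectory, format = format, reference = reference,
              topology = topology, lipid_selection = lipid_selection,
              membrane_mode = membrane_mode, dt_ps = dt_ps, domain = domain,
              n_resamples = as.integer(n_resamples),
              block_length_ns = block_length_ns,
              confidence_level = confidence_level,
              theta_up = theta_up, theta_down = theta_down,
              min_dwell_ns = min_dwell_ns, seed = as.integer(seed),
              out_dir = out_dir)
  structure(cfg, class = "RunConfig")
}

#' Read a run configuration from a JSON or YAML file
#' @param path config file; `.json` is always supported, `.yml`/`.yaml`
#'   requires the yaml package.
#' @return a `RunConfig`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    pd_stop(sprintf("config file not found: %s", path), "validation_error")
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      pd_stop("YAML configs require the yaml package", "validation_error")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- raw[!vapply(raw, is.null, logical(1))]
  do.call(run_config, raw)
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$trajectory) || !file.exists(cfg$trajectory))
    pd_stop(sprintf("trajectory path does not exist: %s",
                    cfg$trajectory %||% "<missing>"), "validation_error")
  for (fld in c("reference", "topology"))
    if (!is.null(cfg[[fld]]) && !file.exists(cfg[[fld]]))
      pd_stop(sprintf("%s path does not exist: %s", fld, cfg[[fld]]),
              "validation_error")
  if (cfg$theta_down >= cfg$theta_up)
    pd_stop("theta_down must be below theta_up", "validation_error")
  invisible(cfg)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "validation_error")) stop(e)
    pd_stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            "stage_error")
  })
}

config_digest <- function(cfg) {
  fnv1a(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = 10,
                         null = "null"))
}

#' Run the full analysis pipeline
#'
#' Stages, in order: structure I/O; superposition metrics (RMSD series
#' against the reference, per-chain RMSF profiles); orientation descriptors
#' (per-chain theta/d series and their chain-mean); block-bootstrap
#' summaries of theta and d; two-state segmentation of the chain-mean theta
#' series. Stage failures abort with an error naming the stage. When
#' `out_dir` is set, TSV/JSON artifacts and the full report JSON are written
#' there (atomically: to a temporary name, then renamed).
#'
#' @param cfg a `RunConfig` (or path to a config file).
#' @return object of class `AnalysisReport`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  validate_run_config(cfg)

  traj <- stage("structure_io", {
    topo <- if (!is.null(cfg$topology)) read_pdb(cfg$topology)[[1]]
    read_trajectory(cfg$trajectory, format = cfg$format, topology = topo,
                    dt_ps = cfg$dt_ps)
  })
  reference <- if (!is.null(cfg$reference))
    stage("structure_io", read_pdb(cfg$reference)[[1]])

  lipid_idx <- if (!is.null(cfg$lipid_selection) &&
                   cfg$membrane_mode != "fallback")
    stage("structure_io",
          do.call(select_atoms,
                  c(list(traj), cfg$lipid_selection[c("chain", "atom_name")])))
  protein_chains <- setdiff(unique(traj$topology$chain_id),
                            if (is.null(cfg$lipid_selection)) character(0)
                            else cfg$lipid_selection$chain)

  prot_ca <- stage("structure_io",
                   select_atoms(traj, chain = protein_chains, atom_name = "CA"))

  sup <- stage("superposition_metrics", {
    list(rmsd = rmsd_series(traj, reference = reference,
                            fit_indices = prot_ca),
         rmsf = rmsf_profile(traj, ca_indices = prot_ca))
  })

  orient <- stage("membrane_geometry", {
    per_chain <- lapply(protein_chains, function(ch)
      orientation_series(traj, ch, lipid_ref = lipid_idx,
                         domain = cfg$domain,
                         per_frame_membrane =
                           cfg$membrane_mode == "per_frame"))
    names(per_chain) <- protein_chains
    list(per_chain = per_chain, mean = aggregate_orientation(per_chain))
  })

  dt <- if (length(traj$times) > 1L) diff(traj$times)[1] else cfg$dt_ps
  block_frames <- max(1L, round(cfg$block_length_ns * 1000 / dt))
  boot <- stage("resampling_stats", {
    list(theta = block_bootstrap(orient$mean$theta, cfg$n_resamples,
                                 block_frames, cfg$confidence_level,
                                 seed = cfg$seed),
         d = block_bootstrap(orient$mean$d, cfg$n_resamples, block_frames,
                             cfg$confidence_level, seed = cfg$seed + 1L))
  })

  seg <- stage("state_dynamics",
               segment_states(orient$mean$theta, orient$mean$times,
                              cfg$theta_up, cfg$theta_down,
                              cfg$min_dwell_ns * 1000))

  report <- structure(list(
    schema_version = REPORT_SCHEMA_VERSION,
    provenance = list(config = unclass(cfg),
                      config_hash = config_digest(cfg),
                      seed = cfg$seed,
                      package_version =
                        as.character(utils::packageVersion("pentadyn"))),
    rmsd = sup$rmsd,
    rmsd_summary = list(mean = mean(sup$rmsd$rmsd),
                        sd = stats::sd(sup$rmsd$rmsd)),
    rmsf = as.data.frame(sup$rmsf),
    orientation = orient,
    bootstrap = boot,
    segmentation = seg
  ), class = "AnalysisReport")

  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.AnalysisReport <- function(x, ...) {
  cat(sprintf(paste0(
    "<AnalysisReport> schema %s\n",
    "  RMSD %.2f +/- %.2f A over %d frames\n",
    "  theta %.2f deg (bootstrap SD %.2f), d %.2f A (bootstrap SD %.2f)\n",
    "  %d state transitions\n"),
    x$schema_version, x$rmsd_summary$mean, x$rmsd_summary$sd, nrow(x$rmsd),
    x$bootstrap$theta$mean, x$bootstrap$theta$sd,
    x$bootstrap$d$mean, x$bootstrap$d$sd, nrow(x$segmentation$transitions)))
  invisible(x)
}

report_to_list <- function(report) {
  list(
    schema_version = report$schema_version,
    provenance = report$provenance,
    rmsd_summary = report$rmsd_summary,
    rmsf = report$rmsf,
    bootstrap = list(theta = unclass(report$bootstrap$theta),
                     d = unclass(report$bootstrap$d)),
    occupancy = as.list(tryCatch(occupancy(report$segmentation),
                                 error = function(e) NULL)),
    transitions = report$segmentation$transitions
  )
}

#' Write an analysis report and its TSV side-files
#'
#' @param report an `AnalysisReport`.
#' @param dir output directory (created if needed).
#' @return named vector of paths written.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  atomically <- function(path, writer) {
    tmp <- paste0(path, ".tmp")
    writer(tmp)
    file.rename(tmp, path)
    path
  }
  paths <- c(
    report = atomically(file.path(dir, "report.json"), function(p)
      jsonlite::write_json(report_to_list(report), p, auto_unbox = TRUE,
                           digits = 10, pretty = TRUE, null = "null")),
    rmsd = atomically(file.path(dir, "rmsd.tsv"), function(p)
      write_metric_tsv(report$rmsd, p)),
    rmsf = atomically(file.path(dir, "rmsf.tsv"), function(p)
      write_metric_tsv(report$rmsf, p)),
    orientation = atomically(file.path(dir, "orientation.tsv"), function(p)
      write_orientation_tsv(c(report$orientation$per_chain,
                              list(report$orientation$mean)), p)),
    segmentation = {
      p <- file.path(dir, "segmentation.tsv")
      tmp <- paste0(p, ".tmp")
      write_segmentation(report$segmentation, report$orientation$mean$theta,
                         tmp)
      file.rename(tmp, p)
      file.rename(paste0(tmp, ".transitions.json"),
                  paste0(p, ".transitions.json"))
      p
    }
  )
  invisible(paths)
}

#' Read back a serialized report summary
#'
#' Reconstructs the subset of an `AnalysisReport` needed by
#' [compare_systems()] from a `report.json` written by [write_report()].
#'
#' @param path path to a `report.json`.
#' @return an `AnalysisReport` (summary fields only).
#' @export
read_report_json <- function(path) {
  if (!file.exists(path))
    pd_stop(sprintf("report file not found: %s", path), "validation_error")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$schema_version))
    pd_stop(sprintf("%s is not a pentadyn report", path), "comparison_error")
  structure(list(
    schema_version = raw$schema_version,
    provenance = raw$provenance,
    rmsd_summary = raw$rmsd_summary,
    rmsf = as.data.frame(raw$rmsf),
    bootstrap = list(theta = raw$bootstrap$theta, d = raw$bootstrap$d),
    segmentation = list(transitions = as.data.frame(raw$transitions))
  ), class = "AnalysisReport")
}

#' Compare analysis reports quantity by quantity
#'
#' For every pair of reports, differences of means for the headline
#' quantities (RMSD, theta, d) with bootstrap SDs propagated in quadrature
#' where available.
#'
#' @param reports list of `AnalysisReport` objects (>= 2) with the same
#'   schema version and matching RMSF residue sets.
#' @return data frame with columns `system_a`, `system_b`, `quantity`,
#'   `mean_a`, `mean_b`, `difference`, `sd_quadrature`.
#' @export
compare_systems <- function(reports) {
  if (!is.list(reports) || length(reports) < 2L)
    pd_stop("need at least two reports to compare", "comparison_error")
  sv <- vapply(reports, function(r) r$schema_version, character(1))
  if (length(unique(sv)) != 1L)
    pd_stop("reports have different schema versions", "comparison_error")
  keysets <- lapply(reports, function(r)
    paste(r$rmsf$chain_id, r$rmsf$residue_number))
  for (k in keysets[-1])
    if (!identical(k, keysets[[1]]))
      pd_stop("reports cover different residue sets", "comparison_error")
  qty <- function(r) data.frame(
    quantity = c("rmsd_mean", "theta_mean", "d_mean"),
    mean = c(r$rmsd_summary$mean, r$bootstrap$theta$mean, r$bootstrap$d$mean),
    sd = c(r$rmsd_summary$sd, r$bootstrap$theta$sd, r$bootstrap$d$sd))
  nm <- names(reports) %||% sprintf("system_%d", seq_along(reports))
  if (is.null(names(reports)) || any(!nzchar(nm)))
    nm <- sprintf("system_%d", seq_along(reports))
  out <- list()
  for (i in seq_along(reports)) for (j in seq_along(reports)) {
    if (j <= i) next
    qa <- qty(reports[[i]]); qb <- qty(reports[[j]])
    out[[length(out) + 1L]] <- data.frame(
      system_a = nm[i], system_b = nm[j], quantity = qa$quantity,
      mean_a = qa$mean, mean_b = qb$mean,
      difference = qa$mean - qb$mean,
      sd_quadrature = sqrt(qa$sd^2 + qb$sd^2))
  }
  do.call(rbind, out)
}
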