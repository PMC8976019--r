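#' Simulate a two-condition replicate design to disk
#'
#' Generates the replicate ensembles of a two-condition comparison (defaults:
#' 5 ligand-bound vs 3 ligand-free runs of 120 frames at 0.25 ns) through the
#' synthetic generator, writes each replicate as a multi-model PDB file and
#' records a manifest of seeds and files.
#'
#' @param config list with elements `ref` (a reference geometry or arguments
#'   for [reference_geometry()]), `config_with`, `config_without`
#'   ([synthetic_config()]), `n_with`, `n_without`, `base_seed`.
#' @param outdir output directory (created if needed).
#' @return The manifest (list of files, seeds, conditions), invisibly;
#'   written as `manifest.json` in `outdir`.
#' @export
run_simulate <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ref <- config$ref
  if (!inherits(ref, "trajectory_ensemble"))
    ref <- do.call(reference_geometry, as.list(ref))
  n_with <- config$n_with %||% 5
  n_without <- config$n_without %||% 3
  base_seed <- config$base_seed %||% 1
  ens <- generate_condition_ensembles(ref, config$config_with,
                                      config$config_without,
                                      n_with, n_without, base_seed)
  manifest <- list(base_seed = base_seed, package = pkg_version(),
                   replicates = list())
  for (cond in names(ens)) {
    for (i in seq_along(ens[[cond]])) {
      f <- file.path(outdir, sprintf("%s_rep%d.pdb", cond, i))
      write_multimodel_pdb(ens[[cond]][[i]], f)
      manifest$replicates[[length(manifest$replicates) + 1L]] <- list(
        file = basename(f), condition = cond, replicate = i,
        seed = base_seed + (if (cond == "without") n_with else 0L) + i)
    }
  }
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pkg_version <- function() {
  as.character(utils::packageVersion("kvcoupling"))
}

run_stage <- function(stage, replicate, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "', replicate ", replicate, ": ",
         conditionMessage(e), call. = FALSE))
}

#' End-to-end two-condition coupling comparison
#'
#' Runs the full coupling workflow over two sets of replicate trajectories:
#' read, superpose, optional analysis window, per-replicate RMSD/RMSF/DCCM,
#' condition-mean matrices, delta-DCCM, segment-pair block summaries and an
#' optional ligand contact table. Exactly two conditions are supported, the
#' with/without design of a drug-effect comparison.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{files_with, files_without}{character vectors of multi-model PDB
#'       paths (or lists of `trajectory_ensemble` objects).}
#'     \item{segments}{named list of [segment()] definitions used for block
#'       summaries.}
#'     \item{dt}{frame spacing ns (default 0.25).}
#'     \item{atom_names}{representative atoms (default `"CA"`).}
#'     \item{window}{optional `c(t_start, t_end)` ns analysis window.}
#'     \item{contact}{optional list(chain =, resname =, cutoff =, criterion =)
#'       defining the ligand for the persistence table.}
#'     \item{seed}{seed recorded in the provenance block.}
#'     \item{outdir}{optional directory; when set, all matrices and tables
#'       are written as delimited text plus a JSON summary.}
#'   }
#' @return A list of class `comparison_report` with elements `rmsd`, `rmsf`,
#'   `dccm` (per replicate), `mean_with`, `mean_without`, `delta`, `blocks`,
#'   `contacts`, `provenance`.
#' @export
run_compare <- function(config) {
  for (need in c("files_with", "files_without"))
    if (is.null(config[[need]]))
      stop("config lacks '", need, "' (exactly two conditions are required)")
  if (!is.null(config$conditions) && length(config$conditions) != 2)
    stop("exactly two conditions are supported")
  dt <- config$dt %||% 0.25
  atom_names <- config$atom_names %||% "CA"
  segs <- config$segments

  load_set <- function(files, label) {
    lapply(seq_along(files), function(i) {
      x <- files[[i]]
      if (inherits(x, "trajectory_ensemble")) return(x)
      if (!file.exists(x))
        stop("stage 'read', replicate ", i, " (", label, "): file not found: ",
             x, call. = FALSE)
      run_stage("read", i, read_multimodel_pdb(x, dt = dt, replicate_id = i,
                                               condition = label))
    })
  }
  with_trajs <- load_set(config$files_with, "with")
  without_trajs <- load_set(config$files_without, "without")

  analyse <- function(trajs) {
    lapply(seq_along(trajs), function(i) {
      tr <- trajs[[i]]
      tr <- run_stage("superpose", i, superpose_trajectory(tr))
      if (!is.null(config$window))
        tr <- run_stage("window", i,
                        analysis_window(tr, config$window[1],
                                        config$window[2]))
      list(
        rmsd = run_stage("rmsd", i,
                         rmsd_series(tr, atom_names = atom_names,
                                     superpose = FALSE)),
        rmsf = run_stage("rmsf", i,
                         rmsf_profile(tr, atom_names = atom_names,
                                      superpose = FALSE)),
        dccm = run_stage("dccm", i,
                         dccm_matrix(tr, atom_names = atom_names,
                                     superpose = FALSE)),
        traj = tr)
    })
  }
  res_with <- analyse(with_trajs)
  res_without <- analyse(without_trajs)

  mean_with <- average_dccm(lapply(res_with, `[[`, "dccm"))
  mean_without <- average_dccm(lapply(res_without, `[[`, "dccm"))
  delta <- delta_dccm(mean_with, mean_without)

  blocks <- list()
  if (!is.null(segs) && length(segs) >= 2) {
    nm <- names(segs)
    for (i in seq_along(segs)) for (j in seq_along(segs)) {
      if (i >= j) next
      key <- paste0(nm[i], "_x_", nm[j])
      blocks[[key]] <- segment_pair_submatrix(delta, segs[[i]], segs[[j]])
    }
  }

  contacts <- NULL
  if (!is.null(config$contact)) {
    cc <- config$contact
    tr1 <- res_with[[1]]$traj
    lig <- residue_group(tr1, chain = cc$chain %||% "X",
                         resname = cc$resname %||% "RL3")
    tabs <- lapply(seq_along(res_with), function(i)
      run_stage("contacts", i,
                persistence_table(res_with[[i]]$traj, lig, segs,
                                  cutoff = cc$cutoff %||% 4.0,
                                  criterion = cc$criterion %||% "min")))
    contacts <- tabs[[1]][, c("chain", "resno", "resname")]
    contacts$persistence <- rowMeans(
      do.call(cbind, lapply(tabs, `[[`, "persistence")))
    attr(contacts, "n_replicates") <- length(tabs)
  }

  report <- structure(list(
    rmsd = list(with = lapply(res_with, `[[`, "rmsd"),
                without = lapply(res_without, `[[`, "rmsd")),
    rmsf = list(with = lapply(res_with, `[[`, "rmsf"),
                without = lapply(res_without, `[[`, "rmsf")),
    dccm = list(with = lapply(res_with, `[[`, "dccm"),
                without = lapply(res_without, `[[`, "dccm")),
    mean_with = mean_with, mean_without = mean_without, delta = delta,
    blocks = blocks, contacts = contacts,
    provenance = list(
      seed = config$seed %||% NA,
      n_with = length(res_with), n_without = length(res_without),
      window = config$window, atom_names = atom_names,
      package = pkg_version())),
    class = "comparison_report")

  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Coupling comparison report\n")
  cat("  replicates:", x$provenance$n_with, "with vs",
      x$provenance$n_without, "without\n")
  cat("  residues:", nrow(x$delta), "\n")
  if (length(x$blocks)) {
    cat("  delta-DCCM segment blocks:\n")
    for (nm in names(x$blocks))
      cat(sprintf("    %-24s mean %+0.3f\n", nm, x$blocks[[nm]]$mean))
  }
  if (!is.null(x$contacts))
    cat("  contact persistence over", attr(x$contacts, "n_replicates"),
        "replicate(s):", nrow(x$contacts), "residues\n")
  invisible(x)
}

#' Write a comparison report to a directory
#'
#' Matrices become tab-delimited text with `chain:resno` labels; per-replicate
#' RMSD/RMSF tables and the contact table are TSV; block summaries and
#' provenance go into `summary.json`.
#'
#' @param report a `comparison_report`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_dccm(report$mean_with, file.path(outdir, "dccm_mean_with.tsv"))
  write_dccm(report$mean_without, file.path(outdir, "dccm_mean_without.tsv"))
  write_dccm(report$delta, file.path(outdir, "delta_dccm.tsv"))
  for (cond in c("with", "without")) {
    for (i in seq_along(report$rmsd[[cond]])) {
      utils::write.table(report$rmsd[[cond]][[i]],
                         file.path(outdir, sprintf("rmsd_%s_rep%d.tsv", cond, i)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(report$rmsf[[cond]][[i]],
                         file.path(outdir, sprintf("rmsf_%s_rep%d.tsv", cond, i)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_dccm(report$dccm[[cond]][[i]],
                 file.path(outdir, sprintf("dccm_%s_rep%d.tsv", cond, i)))
    }
  }
  if (!is.null(report$contacts))
    utils::write.table(report$contacts,
                       file.path(outdir, "contact_persistence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    provenance = report$provenance,
    blocks = lapply(report$blocks, function(b)
      list(mean = b$mean, min = b$min, max = b$max)))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}

#' Batch electrophysiology fitting over a trace directory
#'
#' Reads every trace file, fits activation kinetics on the test pulse and
#' deactivation kinetics on the tail, builds the G-V curve from the tail
#' peaks and fits it with a Boltzmann; per-file failures are collected
#' without aborting the run.
#'
#' @param config list with elements `trace_files` (character vector or a
#'   directory containing `*.tsv` traces written by [write_trace()]),
#'   `protocol` (a [voltage_protocol()]), optional `reference_potential`,
#'   `blank`, and `dose` (list(conc =, effect =) for an additional
#'   dose-response fit).
#' @return A list of class `ephys_report`: `kinetics` (per-trace data.frame),
#'   `gv`, `boltzmann`, `dose_response`, `failures` (named list of error
#'   messages), `exit_status` (0 if no failures).
#' @export
run_ephys <- function(config) {
  files <- config$trace_files
  if (length(files) == 1 && dir.exists(files))
    files <- list.files(files, pattern = "\\.tsv$", full.names = TRUE)
  if (!length(files)) stop("no trace files to fit")
  protocol <- config$protocol %||% voltage_protocol()
  traces <- list(); failures <- list()
  for (f in files) {
    tr <- tryCatch(read_trace(f), error = function(e) e)
    if (inherits(tr, "error")) {
      failures[[basename(f)]] <- conditionMessage(tr)
    } else traces[[length(traces) + 1L]] <- tr
  }
  kin <- list()
  for (tr in traces) {
    row <- tryCatch({
      act <- biexp_fit(tr, "activation", c(0, protocol$test_duration))
      deact <- biexp_fit(tr, "deactivation",
                         c(protocol$test_duration + 0.005,
                           protocol$test_duration + protocol$tail_duration))
      data.frame(test_potential = tr$test_potential,
                 tau_fast_act = act$tau_fast, tau_slow_act = act$tau_slow,
                 tau_fast_deact = deact$tau_fast,
                 tau_slow_deact = deact$tau_slow)
    }, error = function(e) e)
    if (inherits(row, "error")) {
      failures[[paste0("fit_", tr$test_potential, "mV")]] <-
        conditionMessage(row)
    } else kin[[length(kin) + 1L]] <- row
  }
  gv <- NULL; bfit <- NULL
  if (length(traces)) {
    gv <- tryCatch(gv_from_tails(traces, protocol,
                                 config$reference_potential %||% 40,
                                 config$blank %||% 0.005),
                   error = function(e) e)
    if (inherits(gv, "error")) {
      failures[["gv"]] <- conditionMessage(gv); gv <- NULL
    } else {
      bfit <- tryCatch(boltzmann_fit(gv$potential, gv$g_norm),
                       error = function(e) e)
      if (inherits(bfit, "error")) {
        failures[["boltzmann"]] <- conditionMessage(bfit); bfit <- NULL
      }
    }
  }
  dr <- NULL
  if (!is.null(config$dose))
    dr <- dose_response_fit(config$dose$conc, config$dose$effect)
  structure(list(kinetics = if (length(kin)) do.call(rbind, kin),
                 gv = gv, boltzmann = bfit, dose_response = dr,
                 failures = failures,
                 exit_status = if (length(failures)) 2L else 0L),
            class = "ephys_report")
}

#' @export
print.ephys_report <- function(x, ...) {
  cat("Ephys fit report\n")
  if (!is.null(x$kinetics))
    cat("  kinetics fitted for", nrow(x$kinetics), "trace(s)\n")
  if (!is.null(x$boltzmann))
    cat(sprintf("  G-V Boltzmann: V1/2 = %.2f mV, k = %.2f mV\n",
                x$boltzmann$v_half, x$boltzmann$slope_k))
  if (!is.null(x$dose_response) && !x$dose_response$degenerate)
    cat(sprintf("  dose-response: EC50 = %.3g uM, Emax = %.3g%%\n",
                x$dose_response$ec50, x$dose_response$e_max))
  if (length(x$failures))
    cat("  failures:", paste(names(x$failures), collapse = ", "), "\n")
  invisible(x)
}
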