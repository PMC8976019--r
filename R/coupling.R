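#' Per-frame RMSD from a reference frame
#'
#' Root-mean-square deviation of the selected atoms from the reference frame,
#' per frame, optionally after removing rigid-body motion by Kabsch
#' superposition on the fit selection. The RMSD series tracks total drift of
#' a selection from the start of a simulation; a series fluctuating about a
#' steady value indicates an equilibrated complex.
#'
#' @param traj a [trajectory_ensemble()].
#' @param segments selection segments (`NULL` = all residues).
#' @param atom_names atom names to measure over (default `"CA"`; `NULL` = all).
#' @param superpose remove rigid-body motion first (default `TRUE`).
#' @param fit_segments segments used for the superposition fit (default: the
#'   whole structure).
#' @param reference_frame reference frame index (default 1).
#' @return data.frame with columns `time` (ns) and `rmsd` (Angstrom);
#'   attribute `selection` names the selection.
#' @export
rmsd_series <- function(traj, segments = NULL, atom_names = "CA",
                        superpose = TRUE, fit_segments = NULL,
                        reference_frame = 1L) {
  if (!is.null(atom_names) && !any(traj$atoms$atom %in% atom_names))
    atom_names <- NULL
  if (superpose)
    traj <- superpose_trajectory(traj, fit_segments,
                                 reference_frame = reference_frame)
  idx <- resolve_selection(traj, segments, atom_names)
  ref <- frame_coords(traj, reference_frame)[idx, , drop = FALSE]
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    d <- frame_coords(traj, k)[idx, , drop = FALSE] - ref
    sqrt(mean(rowSums(d^2)))
  }, numeric(1))
  out <- data.frame(time = traj$timestamps, rmsd = vals)
  attr(out, "selection") <- selection_label(segments)
  out
}

selection_label <- function(segments) {
  if (is.null(segments)) return("all")
  paste(vapply(as_segment_list(segments), `[[`, "", "name"), collapse = "+")
}

#' Per-residue RMSF about the time-mean position
#'
#' Root-mean-square fluctuation of each selected atom about its mean position
#' over the trajectory, after optional superposition; residues contributing
#' several selected atoms report the RMS over those atoms. RMSF is a
#' stationary dispersion measure: unlike RMSD it is invariant to frame order.
#'
#' @inheritParams rmsd_series
#' @return data.frame with columns `chain`, `resno`, `rmsf` (Angstrom).
#' @export
rmsf_profile <- function(traj, segments = NULL, atom_names = "CA",
                         superpose = TRUE, fit_segments = NULL) {
  if (n_frames(traj) < 2)
    stop("fluctuation undefined: RMSF needs at least 2 frames")
  if (!is.null(atom_names) && !any(traj$atoms$atom %in% atom_names))
    atom_names <- NULL
  if (superpose)
    traj <- superpose_trajectory(traj, fit_segments)
  idx <- resolve_selection(traj, segments, atom_names)
  sub <- traj$coords[, idx, , drop = FALSE]
  mean_pos <- apply(sub, c(2, 3), mean)
  dev2 <- sweep(sub, c(2, 3), mean_pos)^2
  msf_atom <- apply(dev2, 2, mean) * 3   # mean over frames & axes, x3 = |d|^2
  a <- traj$atoms[idx, , drop = FALSE]
  res <- paste(a$chain, a$resno)
  msf_res <- tapply(msf_atom, res, mean)
  ord <- !duplicated(res)
  out <- data.frame(chain = a$chain[ord], resno = a$resno[ord])
  out$rmsf <- sqrt(as.numeric(msf_res[paste(out$chain, out$resno)]))
  out[order(out$chain, out$resno), , drop = FALSE]
}

#' Dynamic cross-correlation matrix (DCCM)
#'
#' For one representative atom per residue (Calpha by default), the DCCM entry
#' for residues i, j is
#' \deqn{C_{ij} = \frac{\langle \Delta r_i \cdot \Delta r_j \rangle}
#'   {\sqrt{\langle |\Delta r_i|^2\rangle \langle |\Delta r_j|^2\rangle}}}
#' where \eqn{\Delta r_i(t) = r_i(t) - \langle r_i \rangle} is the
#' displacement from the time-mean position after superposition. Values run
#' from -1 (fully anticorrelated motion) through 0 (uncorrelated) to +1
#' (fully correlated); the scalar (dot-product) form is used, not per-axis
#' correlation.
#'
#' Residues with zero displacement variance cannot be normalised; their rows
#' and columns are returned as `NaN` with a warning, never silently zeroed.
#'
#' @inheritParams rmsd_series
#' @param atom_names atom names, one match per residue required (default
#'   `"CA"`).
#' @return An `n x n` matrix of class `dccm_matrix`, with dimnames
#'   `chain:resno`, and attributes `n_frames`, `condition`, `replicate_id`.
#' @export
dccm_matrix <- function(traj, segments = NULL, atom_names = "CA",
                        superpose = TRUE, fit_segments = NULL) {
  if (n_frames(traj) < 2)
    stop("DCCM needs at least 2 frames")
  if (!is.null(atom_names) && !any(traj$atoms$atom %in% atom_names))
    atom_names <- NULL
  if (superpose)
    traj <- superpose_trajectory(traj, fit_segments)
  idx <- resolve_selection(traj, segments, atom_names)
  a <- traj$atoms[idx, , drop = FALSE]
  res <- paste0(a$chain, ":", a$resno)
  if (anyDuplicated(res))
    stop("selection yields several atoms for residue(s) ",
         paste(unique(res[duplicated(res)]), collapse = ", "),
         "; DCCM needs one representative atom per residue")
  nf <- n_frames(traj)
  # centered per-axis displacement matrices, frames x residues
  num <- 0
  sub <- traj$coords[, idx, , drop = FALSE]
  for (ax in 1:3) {
    m <- sub[, , ax, drop = FALSE]
    dim(m) <- dim(sub)[1:2]
    m <- sweep(m, 2, colMeans(m))
    num <- num + crossprod(m) / nf       # <dx_i dx_j> accumulated per axis
  }
  v <- diag(num)
  zero <- v <= 0 | !is.finite(v)
  denom <- sqrt(v)
  denom[zero] <- NA_real_
  C <- num / outer(denom, denom)
  C <- pmin(pmax(C, -1), 1)
  diag(C) <- 1
  if (any(zero)) {
    C[zero, ] <- NaN
    C[, zero] <- NaN
    warning("zero-variance residue(s) ", paste(res[zero], collapse = ", "),
            ": correlation undefined (NaN)")
  }
  dimnames(C) <- list(res, res)
  structure(C, class = c("dccm_matrix", "matrix", "array"),
            n_frames = nf, condition = traj$condition,
            replicate_id = traj$replicate_id)
}

#' @export
print.dccm_matrix <- function(x, ...) {
  cat("DCCM:", nrow(x), "residues,", attr(x, "n_frames"), "frames")
  if (!is.na(attr(x, "condition"))) cat(", condition", attr(x, "condition"))
  cat("\n  off-diagonal range: [",
      sprintf("%.3f", min(x[upper.tri(x)], na.rm = TRUE)), ", ",
      sprintf("%.3f", max(x[upper.tri(x)], na.rm = TRUE)), "]\n", sep = "")
  invisible(x)
}

#' Average DCCMs over replicate simulations
#'
#' Entrywise arithmetic mean of replicate matrices sharing one residue
#' ordering; this is the per-condition averaging step of the coupling
#' analysis. An optional Fisher z-transform average is available but the
#' plain mean is the default.
#'
#' @param matrices list of [dccm_matrix()] objects with identical residue ids.
#' @param fisher_z average on the Fisher z scale instead (default `FALSE`).
#' @return A `dccm_matrix` whose `n_frames` is the total over replicates and
#'   whose `replicate_id` is cleared; attribute `n_replicates` is set.
#' @export
average_dccm <- function(matrices, fisher_z = FALSE) {
  if (!length(matrices)) stop("need at least one matrix")
  ids <- rownames(matrices[[1]])
  for (m in matrices)
    if (!identical(rownames(m), ids))
      stop("residue orderings differ between matrices")
  if (fisher_z) {
    zs <- lapply(matrices, function(m) atanh(pmin(pmax(m, -1 + 1e-12),
                                                  1 - 1e-12)))
    avg <- tanh(Reduce(`+`, zs) / length(zs))
  } else {
    avg <- Reduce(`+`, matrices) / length(matrices)
  }
  diag(avg) <- 1
  dimnames(avg) <- list(ids, ids)
  structure(avg, class = c("dccm_matrix", "matrix", "array"),
            n_frames = sum(vapply(matrices, attr, 0, "n_frames")),
            condition = attr(matrices[[1]], "condition"),
            replicate_id = NA_integer_,
            n_replicates = length(matrices))
}

#' Condition-difference correlation matrix (delta-DCCM)
#'
#' Entrywise difference `mean_with - mean_without` between condition-mean
#' DCCMs. Positive entries mark residue pairs whose motion became more
#' correlated in the "with" condition, negative entries a loss of
#' correlation; a broad negative block between voltage-sensor and pore
#' segments is the signature of electro-mechanical uncoupling.
#'
#' @param mean_with,mean_without condition-mean [dccm_matrix()] objects with
#'   identical residue orderings.
#' @return An `n x n` matrix of class `delta_dccm` with zero diagonal and
#'   attributes `n_replicates_with`, `n_replicates_without`.
#' @export
delta_dccm <- function(mean_with, mean_without) {
  if (!identical(rownames(mean_with), rownames(mean_without)))
    stop("residue orderings differ between condition means")
  d <- unclass(mean_with) - unclass(mean_without)
  diag(d) <- 0
  attributes(d) <- list(dim = dim(d),
                        dimnames = dimnames(mean_with))
  structure(d, class = c("delta_dccm", "matrix", "array"),
            n_replicates_with = attr(mean_with, "n_replicates"),
            n_replicates_without = attr(mean_without, "n_replicates"))
}

#' @export
print.delta_dccm <- function(x, ...) {
  cat("Delta-DCCM:", nrow(x), "residues; range [",
      sprintf("%.3f", min(x, na.rm = TRUE)), ", ",
      sprintf("%.3f", max(x, na.rm = TRUE)), "]\n", sep = " ")
  invisible(x)
}

#' Extract a segment-pair block from a (delta-)DCCM
#'
#' Slices the rows belonging to one segment and the columns belonging to
#' another — e.g. S4 x selectivity filter — and summarises the block. These
#' blocks are the units in which voltage-sensor/pore coupling is read off the
#' matrices.
#'
#' @param m a [dccm_matrix()] or [delta_dccm()].
#' @param seg_a,seg_b [segment()] objects; both must be contained in the
#'   matrix residue ids.
#' @return A list of class `dccm_block`: `values` (the block, rows = seg_a),
#'   `mean`, `min`, `max`, and the two segment names.
#' @export
segment_pair_submatrix <- function(m, seg_a, seg_b) {
  ids <- rownames(m)
  ra <- segment_residues(seg_a); rb <- segment_residues(seg_b)
  miss <- c(setdiff(ra, ids), setdiff(rb, ids))
  if (length(miss))
    stop("segment residues not in matrix: ", paste(miss, collapse = ", "))
  block <- unclass(m)[ra, rb, drop = FALSE]
  structure(list(values = block,
                 mean = mean(block, na.rm = TRUE),
                 min = min(block, na.rm = TRUE),
                 max = max(block, na.rm = TRUE),
                 seg_a = seg_a$name, seg_b = seg_b$name),
            class = "dccm_block")
}

#' @export
print.dccm_block <- function(x, ...) {
  cat(sprintf("%s x %s block (%d x %d): mean %.3f, range [%.3f, %.3f]\n",
              x$seg_a, x$seg_b, nrow(x$values), ncol(x$values),
              x$mean, x$min, x$max))
  invisible(x)
}

#' Restrict a trajectory to a time window
#'
#' Keeps frames with `t_start <= t <= t_end` (both ends inclusive), the
#' windowing used for snapshot bookkeeping such as the post-equilibration
#' 10-30 ns window: 81 of 120 frames at 0.25 ns spacing.
#'
#' @param traj a [trajectory_ensemble()].
#' @param t_start,t_end window bounds in ns, `t_start < t_end`.
#' @return The windowed [trajectory_ensemble()].
#' @export
analysis_window <- function(traj, t_start, t_end) {
  if (t_start >= t_end) stop("need t_start < t_end")
  tol <- 1e-9
  keep <- traj$timestamps >= t_start - tol & traj$timestamps <= t_end + tol
  if (!any(keep))
    stop("window [", t_start, ", ", t_end, "] ns contains no frames")
  trajectory_ensemble(traj$atoms, traj$coords[keep, , , drop = FALSE],
                      traj$timestamps[keep], traj$replicate_id,
                      traj$condition)
}

#' Write a labelled correlation matrix as delimited text
#' @param m a [dccm_matrix()] or [delta_dccm()].
#' @param path output path (tab-separated, `chain:resno` row/column labels).
#' @return `path`, invisibly.
#' @export
write_dccm <- function(m, path) {
  utils::write.table(as.data.frame(unclass(m)), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}

#' Read a labelled correlation matrix written by [write_dccm()]
#' @param path input path.
#' @return A numeric matrix with `chain:resno` dimnames.
#' @export
read_dccm <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}
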