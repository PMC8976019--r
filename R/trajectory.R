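#' Construct a trajectory ensemble
#'
#' A trajectory ensemble holds a fixed atom table plus one coordinate set per
#' frame, the frame timestamps in nanoseconds, and optional replicate/condition
#' labels. It is the common container passed between the reader, the
#' superposition stage and the coupling statistics.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resname`, `atom`,
#'   `element`. The triple (chain, resno, atom) must be unique.
#' @param coords numeric array of dimension `n_frames x n_atoms x 3`, in
#'   Angstrom.
#' @param timestamps numeric vector of frame times in ns, strictly increasing.
#' @param replicate_id integer replicate label (optional).
#' @param condition character condition label, e.g. `"with_ligand"`.
#'
#' @return An object of class `trajectory_ensemble`: a list with elements
#'   `atoms`, `coords`, `timestamps`, `replicate_id`, `condition`.
#' @export
trajectory_ensemble <- function(atoms, coords, timestamps,
                                replicate_id = NA_integer_,
                                condition = NA_character_) {
  stopifnot(is.data.frame(atoms))
  required <- c("chain", "resno", "resname", "atom", "element")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (is.matrix(coords)) # single frame convenience
    coords <- array(coords, dim = c(1L, nrow(coords), 3L))
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("coords must be an n_frames x n_atoms x 3 array")
  if (dim(coords)[2] != nrow(atoms))
    stop("coords atom dimension (", dim(coords)[2],
         ") does not match atom table (", nrow(atoms), ")")
  if (dim(coords)[1] != length(timestamps))
    stop("number of frames (", dim(coords)[1],
         ") does not match timestamps (", length(timestamps), ")")
  if (!all(is.finite(coords)))
    stop("coords contain non-finite values")
  if (length(timestamps) > 1 && any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing")
  key <- paste(atoms$chain, atoms$resno, atoms$atom)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom) records: ",
         key[duplicated(key)][1])
  structure(
    list(atoms = atoms, coords = coords,
         timestamps = as.numeric(timestamps),
         replicate_id = replicate_id, condition = condition),
    class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat("Trajectory ensemble:", n_frames(x), "frames,",
      nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain)), "chain(s)\n")
  if (n_frames(x) > 0)
    cat(sprintf("  time %g .. %g ns\n", x$timestamps[1],
                x$timestamps[n_frames(x)]))
  if (!is.na(x$condition))
    cat("  condition:", x$condition,
        if (!is.na(x$replicate_id)) paste0("(replicate ", x$replicate_id, ")"),
        "\n")
  invisible(x)
}

#' Number of frames in a trajectory ensemble
#' @param traj a `trajectory_ensemble`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Coordinates of one frame
#' @param traj a `trajectory_ensemble`.
#' @param i frame index.
#' @return `n_atoms x 3` numeric matrix.
#' @export
frame_coords <- function(traj, i) {
  m <- traj$coords[i, , , drop = FALSE]
  dim(m) <- dim(traj$coords)[2:3]
  m
}

# ---- multi-model PDB I/O ----------------------------------------------------

parse_pdb_atoms <- function(lines) {
  rec <- substr(lines, 1, 6)
  keep <- rec == "ATOM  " | rec == "HETATM"
  lines <- lines[keep]
  data.frame(
    chain = substr(lines, 22, 22),
    resno = as.integer(substr(lines, 23, 26)),
    resname = trimws(substr(lines, 18, 20)),
    atom = trimws(substr(lines, 13, 16)),
    element = trimws(substr(lines, 77, 78)),
    x = as.numeric(substr(lines, 31, 38)),
    y = as.numeric(substr(lines, 39, 46)),
    z = as.numeric(substr(lines, 47, 54)),
    stringsAsFactors = FALSE)
}

#' Read a multi-model PDB file as a trajectory ensemble
#'
#' Each MODEL/ENDMDL block becomes one frame; all models must contain exactly
#' the same atoms in the same order. Frame timestamps are assigned as
#' `k * dt` for frames `k = 1..N`, i.e. the energy-minimised start structure
#' is not part of the file: a 120-model file at `dt = 0.25` ns spans
#' 0.25 to 30 ns.
#'
#' @param path path to a PDB file containing at least one MODEL block.
#' @param dt frame spacing in ns (default 0.25).
#' @param replicate_id,condition labels stored on the ensemble.
#' @return A [trajectory_ensemble()].
#' @export
read_multimodel_pdb <- function(path, dt = 0.25,
                                replicate_id = NA_integer_,
                                condition = NA_character_) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty PDB file: ", path)
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (!length(starts)) {
    # single implicit model
    atoms <- parse_pdb_atoms(lines)
    if (!nrow(atoms)) stop("no ATOM/HETATM records in ", path)
    starts <- 0L; ends <- length(lines) + 1L
    blocks <- list(atoms)
  } else {
    if (length(starts) != length(ends))
      stop("unbalanced MODEL/ENDMDL records in ", path)
    blocks <- lapply(seq_along(starts), function(k)
      parse_pdb_atoms(lines[(starts[k] + 1L):(ends[k] - 1L)]))
  }
  ref <- blocks[[1]]
  if (!nrow(ref)) stop("MODEL 1 contains no atoms in ", path)
  ref_key <- paste(ref$chain, ref$resno, ref$atom)
  for (k in seq_along(blocks)) {
    key <- paste(blocks[[k]]$chain, blocks[[k]]$resno, blocks[[k]]$atom)
    if (!identical(key, ref_key))
      stop("MODEL ", k, " atom set differs from MODEL 1 in ", path)
  }
  nf <- length(blocks); na <- nrow(ref)
  coords <- array(NA_real_, dim = c(nf, na, 3))
  for (k in seq_len(nf))
    coords[k, , ] <- as.matrix(blocks[[k]][, c("x", "y", "z")])
  atoms <- ref[, c("chain", "resno", "resname", "atom", "element")]
  rownames(atoms) <- NULL
  trajectory_ensemble(atoms, coords, timestamps = dt * seq_len(nf),
                      replicate_id = replicate_id, condition = condition)
}

fmt_atom_name <- function(name, element) {
  # standard PDB convention: 1-2 letter elements start in column 14
  ifelse(nchar(name) >= 4 | nchar(element) == 2,
         sprintf("%-4s", name), sprintf(" %-3s", name))
}

#' Write a trajectory ensemble as a multi-model PDB file
#'
#' Coordinates are written at the PDB format's 3-decimal precision, one MODEL
#' block per frame. Ligand (non amino-acid) residues are written as HETATM.
#'
#' @param traj a [trajectory_ensemble()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(traj, path) {
  a <- traj$atoms
  het <- !(a$resname %in% pdb_standard_residues)
  record <- ifelse(het, "HETATM", "ATOM  ")
  name4 <- fmt_atom_name(a$atom, a$element)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(n_frames(traj))) {
    xyz <- frame_coords(traj, k)
    writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(sprintf(
      "%s%5d %s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      record, seq_len(nrow(a)), name4, "", a$resname, a$chain, a$resno,
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, a$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

pdb_standard_residues <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

# ---- atom selection ---------------------------------------------------------

resolve_selection <- function(traj, segments = NULL, atom_names = NULL) {
  a <- traj$atoms
  idx <- rep(TRUE, nrow(a))
  if (!is.null(segments)) {
    segments <- as_segment_list(segments)
    in_seg <- rep(FALSE, nrow(a))
    for (s in segments) {
      hit <- a$chain == s$chain & a$resno >= s$first & a$resno <= s$last
      if (!any(hit))
        stop("segment '", s$name, "' (chain ", s$chain, ", residues ",
             s$first, "-", s$last, ") matches no atoms in the trajectory")
      in_seg <- in_seg | hit
    }
    idx <- idx & in_seg
  }
  if (!is.null(atom_names) && length(atom_names))
    idx <- idx & a$atom %in% atom_names
  if (!any(idx)) {
    want <- if (is.null(segments)) "whole trajectory" else
      paste(vapply(segments, function(s)
        paste0(s$chain, ":", s$first, "-", s$last), ""), collapse = ", ")
    stop("no atoms match selection (", want, "; atoms ",
         paste(atom_names, collapse = ","), ")")
  }
  which(idx)
}

#' Restrict a trajectory ensemble to a selection
#'
#' @param traj a [trajectory_ensemble()].
#' @param segments a [segment()], a list of segments, or `NULL` for all
#'   residues.
#' @param atom_names character vector of atom names to keep (e.g. `"CA"`);
#'   `NULL` or empty keeps all atom names.
#' @return A sub-ensemble with the same frame count.
#' @export
select_atoms <- function(traj, segments = NULL, atom_names = NULL) {
  idx <- resolve_selection(traj, segments, atom_names)
  atoms <- traj$atoms[idx, , drop = FALSE]
  rownames(atoms) <- NULL
  trajectory_ensemble(atoms, traj$coords[, idx, , drop = FALSE],
                      traj$timestamps, traj$replicate_id, traj$condition)
}

# ---- Kabsch superposition ---------------------------------------------------

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between a
#' mobile and a reference point set. The rotation always has determinant +1:
#' for mirror-degenerate inputs the sign of the smallest singular vector is
#' flipped, so no improper (reflecting) transform is ever returned.
#'
#' The fitted coordinates are `mobile %*% rotation + translation` (row
#' vectors).
#'
#' @param mobile,reference `n x 3` coordinate matrices, `n >= 3`, reference
#'   not collinear.
#' @return A list of class `superposition` with `rotation` (3x3),
#'   `translation` (length 3) and `post_fit_rmsd`.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference)))
    stop("mobile and reference differ in shape")
  if (nrow(mobile) < 3)
    stop("superposition needs at least 3 atoms, got ", nrow(mobile))
  cm <- colMeans(mobile); cr <- colMeans(reference)
  M <- sweep(mobile, 2, cm); R0 <- sweep(reference, 2, cr)
  sv_ref <- svd(R0)$d
  if (sv_ref[2] < 1e-8 * max(sv_ref[1], 1e-12))
    stop("reference coordinates are collinear; superposition is degenerate")
  H <- crossprod(M, R0)            # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  if (d == 0) d <- 1
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  trans <- cr - as.vector(cm %*% rot)
  fitted <- mobile %*% rot
  fitted <- sweep(fitted, 2, trans, "+")
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  structure(list(rotation = rot, translation = trans, post_fit_rmsd = rmsd),
            class = "superposition")
}

apply_transform <- function(xyz, fit) {
  sweep(xyz %*% fit$rotation, 2, fit$translation, "+")
}

#' Superpose every frame of a trajectory onto a reference frame
#'
#' Removes rigid-body motion before RMSD/RMSF/DCCM calculation. The fit uses
#' the Calpha atoms of `fit_segments` (all Calpha atoms by default; all atoms
#' if the trajectory has no atom named CA); the resulting transform is applied
#' to every atom of the frame.
#'
#' @param traj a [trajectory_ensemble()].
#' @param fit_segments segments whose atoms define the fit; `NULL` = all.
#' @param fit_atom_names atom names used for fitting (default `"CA"`).
#' @param reference_frame index of the frame used as reference (default 1).
#' @return A superposed [trajectory_ensemble()].
#' @export
superpose_trajectory <- function(traj, fit_segments = NULL,
                                 fit_atom_names = "CA",
                                 reference_frame = 1L) {
  if (!is.null(fit_atom_names) && !any(traj$atoms$atom %in% fit_atom_names))
    fit_atom_names <- NULL
  idx <- resolve_selection(traj, fit_segments, fit_atom_names)
  ref <- frame_coords(traj, reference_frame)[idx, , drop = FALSE]
  out <- traj$coords
  for (k in seq_len(n_frames(traj))) {
    xyz <- frame_coords(traj, k)
    fit <- kabsch_superpose(xyz[idx, , drop = FALSE], ref)
    out[k, , ] <- apply_transform(xyz, fit)
  }
  traj$coords <- out
  traj
}
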