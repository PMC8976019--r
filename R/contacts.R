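#' Define an atom group
#'
#' An atom group names a set of atoms — typically a bound ligand or one
#' residue's heavy atoms — used for contact detection.
#'
#' @param name group label, e.g. `"RL3"`.
#' @param atoms data.frame with columns `chain`, `resno`, `atom`.
#' @return A list of class `atom_group`.
#' @export
atom_group <- function(name, atoms) {
  stopifnot(is.data.frame(atoms),
            all(c("chain", "resno", "atom") %in% names(atoms)))
  if (!nrow(atoms)) stop("atom group '", name, "' is empty")
  structure(list(name = name, atoms = atoms), class = "atom_group")
}

#' Atom group from a whole residue
#'
#' Collects all atoms of one residue (optionally excluding hydrogens) into an
#' [atom_group()]. Use `resname` to pick up a ligand HETATM residue such as
#' `"RL3"` without knowing its residue number.
#'
#' @param traj a [trajectory_ensemble()].
#' @param chain chain id.
#' @param resno residue number (or `NULL` if selecting by `resname`).
#' @param resname residue name filter (optional).
#' @param heavy_only drop hydrogens (default `TRUE`).
#' @return An [atom_group()].
#' @export
residue_group <- function(traj, chain, resno = NULL, resname = NULL,
                          heavy_only = TRUE) {
  a <- traj$atoms
  keep <- a$chain == chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(resname)) keep <- keep & a$resname == resname
  if (heavy_only) keep <- keep & a$element != "H"
  if (!any(keep))
    stop("no atoms for chain ", chain,
         if (!is.null(resno)) paste0(" residue ", paste(resno, collapse = ",")),
         if (!is.null(resname)) paste0(" resname ", resname))
  label <- if (!is.null(resname)) resname else
    paste0(chain, ":", paste(unique(a$resno[keep]), collapse = ","))
  atom_group(label, a[keep, c("chain", "resno", "atom")])
}

group_indices <- function(traj, group) {
  key <- paste(traj$atoms$chain, traj$atoms$resno, traj$atoms$atom)
  want <- paste(group$atoms$chain, group$atoms$resno, group$atoms$atom)
  idx <- match(want, key)
  if (anyNA(idx))
    stop("atom group '", group$name, "' references atoms absent from the ",
         "trajectory: ", paste(want[is.na(idx)], collapse = "; "))
  idx
}

#' Minimum distance between two atom sets
#'
#' @param coords_a,coords_b `n x 3` coordinate matrices (Angstrom).
#' @return Minimum pairwise Euclidean distance in Angstrom.
#' @export
min_distance <- function(coords_a, coords_b) {
  coords_a <- rbind(coords_a); coords_b <- rbind(coords_b)
  if (!nrow(coords_a) || !nrow(coords_b))
    stop("empty atom group in distance calculation")
  d2 <- outer(rowSums(coords_a^2), rowSums(coords_b^2), "+") -
    2 * tcrossprod(coords_a, coords_b)
  sqrt(max(min(d2), 0))
}

centroid_distance <- function(coords_a, coords_b) {
  sqrt(sum((colMeans(rbind(coords_a)) - colMeans(rbind(coords_b)))^2))
}

#' Per-frame contact state between two atom groups
#'
#' A frame is in contact when the criterion distance is at or below the
#' cutoff. The default criterion is the minimum heavy-atom distance with a
#' 4.0 Angstrom cutoff (the usual hydrophobic-contact convention); the
#' `"centroid"` criterion compares geometric centroids and suits
#' aromatic-ring proxies (5.5 Angstrom is a common ring-ring cutoff).
#'
#' @param traj a [trajectory_ensemble()].
#' @param group_a,group_b [atom_group()] objects resolvable in `traj`.
#' @param cutoff contact cutoff in Angstrom (> 0, or 0 to require overlap).
#' @param criterion `"min"` (minimum pairwise distance) or `"centroid"`.
#' @return A list of class `contact_series`: `in_contact` (logical per
#'   frame), `distance` (criterion distance per frame), `persistence`
#'   (percent of frames in contact), plus `cutoff` and `criterion`.
#' @export
contact_series <- function(traj, group_a, group_b, cutoff = 4.0,
                           criterion = c("min", "centroid")) {
  criterion <- match.arg(criterion)
  if (cutoff < 0) stop("cutoff must be >= 0")
  ia <- group_indices(traj, group_a)
  ib <- group_indices(traj, group_b)
  dist_fun <- if (criterion == "min") min_distance else centroid_distance
  d <- vapply(seq_len(n_frames(traj)), function(k) {
    xyz <- frame_coords(traj, k)
    dist_fun(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE])
  }, numeric(1))
  state <- d <= cutoff
  structure(list(in_contact = state, distance = d,
                 persistence = 100 * mean(state),
                 cutoff = cutoff, criterion = criterion,
                 pair = c(group_a$name, group_b$name)),
            class = "contact_series")
}

#' @export
print.contact_series <- function(x, ...) {
  cat(sprintf("Contact %s -- %s: %.1f%% of %d frames (criterion %s <= %g A)\n",
              x$pair[1], x$pair[2], x$persistence, length(x$in_contact),
              x$criterion, x$cutoff))
  invisible(x)
}

#' Ligand-residue contact persistence table
#'
#' For every residue in the given segments, the percentage of frames in which
#' the ligand is in contact with that residue (heavy-atom criterion by
#' default) — the per-residue "duration of hydrophobic interaction" summary
#' of a binding site.
#'
#' @param traj a [trajectory_ensemble()].
#' @param ligand an [atom_group()] for the ligand.
#' @param segments residues to tabulate, as [segment()] or list of segments.
#' @param cutoff contact cutoff in Angstrom (default 4.0).
#' @param criterion see [contact_series()].
#' @return data.frame with columns `chain`, `resno`, `resname`,
#'   `n_contact_frames`, `persistence` (percent), sorted by chain and residue
#'   number; attributes `n_frames` and `cutoff`.
#' @export
persistence_table <- function(traj, ligand, segments, cutoff = 4.0,
                              criterion = "min") {
  segments <- as_segment_list(segments)
  a <- traj$atoms
  rows <- list()
  for (s in segments) {
    for (r in s$first:s$last) {
      hit <- a$chain == s$chain & a$resno == r & a$element != "H"
      if (!any(hit))
        stop("residue ", s$chain, ":", r, " (segment '", s$name,
             "') not present in the trajectory")
      grp <- atom_group(paste0(s$chain, ":", r),
                        a[hit, c("chain", "resno", "atom")])
      cs <- contact_series(traj, ligand, grp, cutoff, criterion)
      rows[[length(rows) + 1L]] <- data.frame(
        chain = s$chain, resno = r, resname = a$resname[hit][1],
        n_contact_frames = sum(cs$in_contact),
        persistence = cs$persistence)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chain, out$resno), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_frames") <- n_frames(traj)
  attr(out, "cutoff") <- cutoff
  out
}
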