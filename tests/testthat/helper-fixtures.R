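# Small builders shared across the suite. Everything is generated in code;
# no fixture files.

# trajectory from a list of n_atoms x 3 coordinate matrices
make_traj <- function(frames, chains = NULL, resnos = NULL,
                      atom = "CA", dt = 0.25) {
  n <- nrow(frames[[1]])
  if (is.null(chains)) chains <- rep("A", n)
  if (is.null(resnos)) resnos <- seq_len(n)
  atoms <- data.frame(chain = chains, resno = resnos, resname = "ALA",
                      atom = atom, element = "C", stringsAsFactors = FALSE)
  coords <- array(NA_real_, dim = c(length(frames), n, 3))
  for (k in seq_along(frames)) coords[k, , ] <- frames[[k]]
  trajectory_ensemble(atoms, coords, timestamps = dt * seq_along(frames))
}

rotation_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
}

# literal two-model PDB text, 3 atoms
two_model_pdb_lines <- function() {
  atom_line <- function(i, name, resno, x, y, z)
    sprintf("ATOM  %5d  %-3s ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, name, resno, x, y, z)
  c("MODEL        1",
    atom_line(1, "N", 1, 0, 0, 0),
    atom_line(2, "CA", 1, 1.5, 0, 0),
    atom_line(3, "C", 1, 2.5, 1, 0),
    "ENDMDL",
    "MODEL        2",
    atom_line(1, "N", 1, 0.1, 0, 0),
    atom_line(2, "CA", 1, 1.6, 0, 0),
    atom_line(3, "C", 1, 2.6, 1, 0),
    "ENDMDL", "END")
}

# independent double-loop DCCM oracle (literal formula)
dccm_oracle <- function(coords) {
  nf <- dim(coords)[1]; na <- dim(coords)[2]
  mean_pos <- apply(coords, c(2, 3), mean)
  C <- matrix(NA_real_, na, na)
  for (i in seq_len(na)) for (j in seq_len(na)) {
    num <- 0; vi <- 0; vj <- 0
    for (t in seq_len(nf)) {
      di <- coords[t, i, ] - mean_pos[i, ]
      dj <- coords[t, j, ] - mean_pos[j, ]
      num <- num + sum(di * dj)
      vi <- vi + sum(di * di); vj <- vj + sum(dj * dj)
    }
    C[i, j] <- num / sqrt(vi * vj)
  }
  C
}
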