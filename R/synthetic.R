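#' Idealised tetrameric reference geometry
#'
#' Builds a deterministic single-frame Calpha trace emulating a homotetrameric
#' channel: one alpha-helical backbone per subunit (1.5 Angstrom rise, 100
#' degrees per residue, 2.3 Angstrom radius), subunits placed on a circle and
#' labelled with chains A, B, C, ... as the subunits Mol A-D of a channel
#' model. The geometry carries no physics; it only provides well-separated,
#' non-degenerate coordinates for the statistical generators.
#'
#' @param n_subunits number of subunits / chains (default 4).
#' @param residues_per_subunit residues per chain (>= 3; superposition needs
#'   at least three atoms).
#' @param first_residue number of the first residue of every chain (use e.g.
#'   230 to emulate author numbering around an S4 segment 235-241).
#' @param ring_radius distance of each helix axis from the pore axis
#'   (Angstrom).
#' @return A single-frame [trajectory_ensemble()] of Calpha atoms.
#' @export
reference_geometry <- function(n_subunits = 4, residues_per_subunit = 20,
                               first_residue = 1, ring_radius = 20) {
  if (n_subunits < 1) stop("need at least one subunit")
  if (residues_per_subunit < 3)
    stop("need at least 3 residues per subunit (superposition minimum)")
  atoms <- NULL; xyz <- NULL
  for (s in seq_len(n_subunits)) {
    phi <- 2 * pi * (s - 1) / n_subunits
    axis <- ring_radius * c(cos(phi), sin(phi), 0)
    i <- seq_len(residues_per_subunit)
    theta <- (i - 1) * 100 * pi / 180
    local <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * (i - 1))
    xyz <- rbind(xyz, sweep(local, 2, axis, "+"))
    atoms <- rbind(atoms, data.frame(
      chain = LETTERS[s],
      resno = as.integer(first_residue) + i - 1L,
      resname = "ALA", atom = "CA", element = "C",
      stringsAsFactors = FALSE))
  }
  trajectory_ensemble(atoms, array(xyz, dim = c(1L, nrow(xyz), 3L)),
                      timestamps = 0)
}

#' Configuration for the correlated-motion trajectory generator
#'
#' Defines the statistical ground truth of a synthetic run. Defaults mirror a
#' 30 ns production run documented every 0.25 ns (120 frames). Displacements
#' are zero-mean Gaussian with per-atom standard deviation `sigma` per axis;
#' `correlation_blocks` plant exact inter-segment displacement correlations
#' via a shared latent factor, and `ar1_phi` adds stationary AR(1) temporal
#' smoothness that leaves the cross-residue correlation targets unchanged.
#'
#' @param n_frames frames per run (default 120).
#' @param dt frame spacing in ns (default 0.25).
#' @param seed RNG seed for the run.
#' @param sigma per-axis displacement standard deviation in Angstrom
#'   (default 0.5, a typical equilibrated-backbone fluctuation scale).
#' @param correlation_blocks list of `list(seg_a =, seg_b =, rho =)` entries;
#'   `rho` in \[-1, 1\]. A segment may appear in at most one block (this keeps
#'   the implied covariance positive semi-definite by construction).
#' @param ar1_phi AR(1) coefficient in \[0, 1) (default 0.5).
#' @param rigid_motion overlay a random rigid rotation+translation per frame
#'   (default `FALSE`); removed exactly by the superposition stage.
#' @param contact_schedule optional named list `"chain:resno" -> logical
#'   vector` of length `n_frames` planting ligand contacts for those frames.
#' @param condition,replicate_id labels stored on the generated ensemble.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_frames = 120, dt = 0.25, seed = 1,
                             sigma = 0.5, correlation_blocks = list(),
                             ar1_phi = 0.5, rigid_motion = FALSE,
                             contact_schedule = NULL,
                             condition = NA_character_,
                             replicate_id = NA_integer_) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (dt <= 0) stop("dt must be > 0")
  if (sigma < 0) stop("sigma must be >= 0")
  if (ar1_phi < 0 || ar1_phi >= 1) stop("ar1_phi must be in [0, 1)")
  seen <- character()
  for (b in correlation_blocks) {
    if (!all(c("seg_a", "seg_b", "rho") %in% names(b)))
      stop("each correlation block needs seg_a, seg_b, rho")
    if (abs(b$rho) > 1)
      stop("target correlation out of [-1, 1]: rho = ", b$rho,
           " implies a non positive semi-definite covariance")
    ids <- c(segment_residues(b$seg_a), segment_residues(b$seg_b))
    if (any(ids %in% seen))
      stop("segment residues shared between correlation blocks; the implied ",
           "covariance is not guaranteed positive semi-definite")
    seen <- c(seen, ids)
  }
  if (!is.null(contact_schedule)) {
    ok <- vapply(contact_schedule, function(s)
      is.logical(s) && length(s) == n_frames, TRUE)
    if (!all(ok))
      stop("contact_schedule entries must be logical vectors of length ",
           n_frames)
  }
  structure(list(n_frames = as.integer(n_frames), dt = dt, seed = seed,
                 sigma = sigma, correlation_blocks = correlation_blocks,
                 ar1_phi = ar1_phi, rigid_motion = rigid_motion,
                 contact_schedule = contact_schedule,
                 condition = condition, replicate_id = replicate_id),
            class = "synthetic_config")
}

# Stationary AR(1) filter on a frames x k matrix of iid N(0,1) draws;
# marginal variance (and hence cross-column correlation) is preserved.
ar1_filter <- function(m, phi) {
  if (phi == 0 || nrow(m) < 2) return(m)
  out <- m
  w <- sqrt(1 - phi^2)
  for (t in 2:nrow(m)) out[t, ] <- phi * out[t - 1, ] + w * m[t, ]
  out
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a correlated-motion synthetic trajectory
#'
#' Frames are the reference geometry plus zero-mean Gaussian displacements
#' whose inter-residue correlation structure realises the configured blocks
#' exactly: within a block with target `rho`, each axis displacement is
#' `sqrt(|rho|) * z_block + sqrt(1 - |rho|) * eps_atom` (the second segment's
#' loading carries `sign(rho)`), which gives correlation `rho` between the
#' two segments analytically. An optional AR(1) filter adds temporal
#' smoothness without changing the stationary targets, and an optional
#' per-frame rigid rotation+translation overlay exercises the superposition
#' stage. The run is fully reproducible from `config$seed`.
#'
#' @param ref single-frame reference [trajectory_ensemble()] (see
#'   [reference_geometry()]).
#' @param config a [synthetic_config()].
#' @return A [trajectory_ensemble()] with timestamps `dt * (1..n_frames)`.
#'   If a contact schedule is present, a one-atom-per-scheduled-residue
#'   ligand residue (chain `X`, resname `RL3`) is appended whose atoms track
#'   the scheduled residue at 2 Angstrom in contact frames and are displaced
#'   1000 Angstrom away otherwise.
#' @export
generate_trajectory <- function(ref, config) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  atoms <- ref$atoms
  base <- frame_coords(ref, 1)
  nf <- config$n_frames; na <- nrow(atoms)
  res_id <- paste0(atoms$chain, ":", atoms$resno)

  # block membership: loading on the shared factor per atom (0 if unblocked)
  n_blocks <- length(config$correlation_blocks)
  loading <- matrix(0, na, max(n_blocks, 1))
  resid_sd <- rep(1, na)
  for (bi in seq_len(n_blocks)) {
    b <- config$correlation_blocks[[bi]]
    rho <- b$rho
    in_a <- res_id %in% segment_residues(b$seg_a)
    in_b <- res_id %in% segment_residues(b$seg_b)
    loading[in_a, bi] <- sqrt(abs(rho))
    loading[in_b, bi] <- sign(rho) * sqrt(abs(rho))
    resid_sd[in_a | in_b] <- sqrt(1 - abs(rho))
  }

  coords <- array(NA_real_, dim = c(nf, na, 3))
  for (ax in 1:3) {
    z <- ar1_filter(matrix(stats::rnorm(nf * max(n_blocks, 1)), nf),
                    config$ar1_phi)
    eps <- ar1_filter(matrix(stats::rnorm(nf * na), nf), config$ar1_phi)
    disp <- z %*% t(loading) + sweep(eps, 2, resid_sd, "*")
    coords[, , ax] <- config$sigma * disp +
      matrix(base[, ax], nf, na, byrow = TRUE)
  }

  if (isTRUE(config$rigid_motion)) {
    for (k in seq_len(nf)) {
      rot <- random_rotation()
      trans <- stats::runif(3, -20, 20)
      coords[k, , ] <- sweep(coords[k, , ] %*% rot, 2, trans, "+")
    }
  }

  if (!is.null(config$contact_schedule)) {
    sched <- config$contact_schedule
    lig_atoms <- data.frame(
      chain = "X", resno = 1L, resname = "RL3",
      atom = paste0("C", seq_along(sched)), element = "C",
      stringsAsFactors = FALSE)
    lig <- array(NA_real_, dim = c(nf, length(sched), 3))
    for (j in seq_along(sched)) {
      target <- match(names(sched)[j], res_id)
      if (is.na(target))
        stop("contact_schedule residue ", names(sched)[j],
             " not in reference geometry")
      offset <- ifelse(sched[[j]], 2, 1000)  # in/out of any contact cutoff
      for (ax in 1:3)
        lig[, j, ax] <- coords[, target, ax] +
          if (ax == 1) offset else 0
    }
    atoms <- rbind(atoms, lig_atoms)
    full <- array(NA_real_, dim = c(nf, na + length(sched), 3))
    full[, seq_len(na), ] <- coords
    full[, na + seq_along(sched), ] <- lig
    coords <- full
  }

  trajectory_ensemble(atoms, coords, timestamps = config$dt * seq_len(nf),
                      replicate_id = config$replicate_id,
                      condition = config$condition)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate replicate ensembles for a two-condition design
#'
#' Emulates a replicate simulation design — e.g. 5 runs of the
#' ligand-bound open-state complex versus 3 ligand-free runs — with
#' deterministic per-replicate seeds: with-condition replicate `i` uses
#' `base_seed + i`, without-condition replicate `j` uses
#' `base_seed + n_with + j`, so the two conditions never share an RNG stream.
#'
#' @param ref reference geometry.
#' @param config_with,config_without [synthetic_config()] objects for the two
#'   conditions (their `seed`, `condition` and `replicate_id` fields are
#'   overwritten per replicate).
#' @param n_with,n_without replicate counts (defaults 5 and 3).
#' @param base_seed base RNG seed.
#' @return A list with elements `with` and `without`, each a list of
#'   [trajectory_ensemble()] objects labelled `"with_ligand"` /
#'   `"without_ligand"`.
#' @export
generate_condition_ensembles <- function(ref, config_with, config_without,
                                         n_with = 5, n_without = 3,
                                         base_seed = 1) {
  if (n_with < 1 || n_without < 1) stop("need at least 1 replicate per condition")
  gen <- function(cfg, n, offset, label) {
    lapply(seq_len(n), function(i) {
      cfg$seed <- base_seed + offset + i
      cfg$condition <- label
      cfg$replicate_id <- i
      generate_trajectory(ref, cfg)
    })
  }
  list(with = gen(config_with, n_with, 0L, "with_ligand"),
       without = gen(config_without, n_without, n_with, "without_ligand"))
}
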