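test_that("RMSD series matches closed forms", {
  set.seed(21)
  base <- matrix(rnorm(15), 5, 3)
  # static trajectory: all zeros
  tr <- make_traj(list(base, base, base))
  expect_equal(rmsd_series(tr, superpose = FALSE)$rmsd, rep(0, 3))
  # uniform +1 A shift in x without superposition: RMSD exactly 1
  tr2 <- make_traj(list(base, sweep(base, 2, c(1, 0, 0), "+")))
  expect_equal(rmsd_series(tr2, superpose = FALSE)$rmsd, c(0, 1))
  # rigid rotation with superposition: zero
  tr3 <- make_traj(list(base, base %*% rotation_z(40)))
  expect_lt(rmsd_series(tr3, superpose = TRUE)$rmsd[2], 1e-8)
  expect_error(rmsd_series(tr, atom_names = "CA",
                           segments = segment("x", "Q", 1, 2)),
               "matches no atoms")
})

test_that("RMSF is zero for static atoms and needs two frames", {
  base <- matrix(c(0, 0, 0, 10, 0, 0), 2, 3, byrow = TRUE)
  tr <- make_traj(list(base, base, base))
  expect_equal(rmsf_profile(tr, superpose = FALSE)$rmsf, c(0, 0))
  expect_error(rmsf_profile(make_traj(list(base))), "fluctuation undefined")
  # one jittered, one static residue
  set.seed(22)
  frames <- lapply(1:500, function(k)
    base + rbind(rnorm(3, sd = 0.3), c(0, 0, 0)))
  rf <- rmsf_profile(make_traj(frames), superpose = FALSE)
  expect_gt(rf$rmsf[1], 0.2)
  expect_equal(rf$rmsf[2], 0)
})

test_that("isotropic Gaussian jitter gives RMSF near sigma*sqrt(3)", {
  ref <- reference_geometry(1, 5)
  tj <- generate_trajectory(ref, synthetic_config(
    n_frames = 3000, seed = 23, sigma = 0.4, ar1_phi = 0))
  rf <- rmsf_profile(tj, superpose = FALSE)
  expect_equal(mean(rf$rmsf), 0.4 * sqrt(3), tolerance = 0.03)
})

test_that("DCCM equals the literal double-loop formula and hits exact limits", {
  set.seed(24)
  ref <- reference_geometry(1, 5)
  tj <- generate_trajectory(ref, synthetic_config(n_frames = 15, seed = 5,
                                                  ar1_phi = 0))
  C <- dccm_matrix(tj, superpose = FALSE)
  expect_lt(max(abs(unclass(C) - dccm_oracle(tj$coords))), 1e-12)

  # identical / negated displacements give +1 / -1
  d <- rnorm(20)
  base <- matrix(c(0, 0, 0, 5, 0, 0, 10, 0, 0), 3, 3, byrow = TRUE)
  frames <- lapply(1:20, function(k)
    base + cbind(c(d[k], d[k], -d[k]), 0, 0))
  C2 <- dccm_matrix(make_traj(frames), superpose = FALSE)
  expect_equal(C2[1, 2], 1)
  expect_equal(C2[1, 3], -1)
})

test_that("DCCM invariants hold on random inputs", {
  for (seed in 1:5) {
    ref <- reference_geometry(2, 6)
    tj <- generate_trajectory(ref, synthetic_config(
      n_frames = 40, seed = seed, ar1_phi = 0.3,
      correlation_blocks = list(list(seg_a = segment("a", "A", 1, 3),
                                     seg_b = segment("b", "B", 2, 5),
                                     rho = runif(1, -1, 1)))))
    C <- dccm_matrix(tj, superpose = FALSE)
    expect_equal(unclass(C), t(unclass(C)))
    expect_equal(unname(diag(C)), rep(1, nrow(C)))
    expect_true(all(C >= -1 & C <= 1))
  }
})

test_that("DCCM and RMSF are frame-permutation invariant; RMSD is equivariant", {
  ref <- reference_geometry(1, 6)
  tj <- generate_trajectory(ref, synthetic_config(n_frames = 30, seed = 26,
                                                  ar1_phi = 0))
  set.seed(27)
  perm <- sample(30)
  tj_perm <- tj
  tj_perm$coords <- tj$coords[perm, , , drop = FALSE]
  expect_equal(unclass(dccm_matrix(tj_perm, superpose = FALSE)),
               unclass(dccm_matrix(tj, superpose = FALSE)), tolerance = 1e-12)
  expect_equal(rmsf_profile(tj_perm, superpose = FALSE)$rmsf,
               rmsf_profile(tj, superpose = FALSE)$rmsf, tolerance = 1e-12)
  # RMSD follows the permutation (reference = original frame 1)
  r_orig <- rmsd_series(tj, superpose = FALSE)$rmsd
  idx1 <- which(perm == 1)
  tj_ref1 <- tj_perm
  r_perm <- rmsd_series(tj_ref1, superpose = FALSE,
                        reference_frame = idx1)$rmsd
  expect_equal(r_perm, r_orig[perm], tolerance = 1e-12)
})

test_that("our DCCM agrees with an established implementation", {
  ref <- reference_geometry(2, 8)
  tj <- generate_trajectory(ref, synthetic_config(
    n_frames = 200, seed = 28, ar1_phi = 0,
    correlation_blocks = list(list(seg_a = segment("a", "A", 1, 4),
                                   seg_b = segment("b", "B", 3, 8),
                                   rho = 0.7))))
  C <- dccm_matrix(tj, superpose = FALSE)
  xyz <- matrix(aperm(tj$coords, c(1, 3, 2)), nrow = n_frames(tj))
  # bio3d expects frames x (x1,y1,z1,x2,...) ordering
  xyz <- t(apply(tj$coords, 1, function(m) as.vector(t(m))))
  ref_dccm <- bio3d::dccm(xyz)
  expect_equal(unclass(C), unclass(ref_dccm), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("zero-variance residues are flagged NaN with a warning, not zeroed", {
  base <- matrix(c(0, 0, 0, 5, 0, 0, 10, 0, 0), 3, 3, byrow = TRUE)
  set.seed(29)
  frames <- lapply(1:10, function(k)
    base + rbind(rnorm(3, sd = 0.5), rnorm(3, sd = 0.5), 0))
  expect_warning(C <- dccm_matrix(make_traj(frames), superpose = FALSE),
                 "zero-variance")
  expect_true(all(is.nan(C[3, -3])))
  expect_true(all(is.nan(C[-3, 3])))
  expect_false(anyNA(C[1:2, 1:2]))
})

test_that("replicate averaging and delta matrices follow their algebra", {
  ref <- reference_geometry(1, 5)
  mk <- function(seed) dccm_matrix(generate_trajectory(
    ref, synthetic_config(n_frames = 25, seed = seed, ar1_phi = 0)),
    superpose = FALSE)
  A <- mk(1); B <- mk(2)
  expect_equal(unclass(average_dccm(list(A))), unclass(A),
               ignore_attr = "n_replicates")
  # average of M and its off-diagonal negation: zeros off-diagonal, unit diag
  negA <- -unclass(A); diag(negA) <- 1
  negA <- structure(negA, class = class(A), n_frames = attr(A, "n_frames"),
                    condition = NA_character_, replicate_id = NA_integer_)
  avg <- average_dccm(list(A, negA))
  expect_equal(unname(diag(avg)), rep(1, 5))
  expect_lt(max(abs(avg[upper.tri(avg)])), 1e-12)
  expect_equal(attr(avg, "n_frames"), 50)

  mw <- average_dccm(list(A)); mo <- average_dccm(list(B))
  d <- delta_dccm(mw, mo)
  expect_equal(unname(diag(d)), rep(0, 5))
  expect_equal(unclass(d), -unclass(delta_dccm(mo, mw)), ignore_attr = TRUE)
  expect_lt(max(abs(delta_dccm(mw, mw))), 1e-15)
  # ordering mismatch is an error
  B2 <- B[5:1, 5:1]
  B2 <- structure(B2, class = class(B), n_frames = attr(B, "n_frames"))
  expect_error(delta_dccm(mw, average_dccm(list(B2))), "ordering")
  expect_error(average_dccm(list(A, B2)), "ordering")
})

test_that("segment-pair blocks slice the expected ranges", {
  ref <- reference_geometry(2, 100, first_residue = 230)
  tj <- generate_trajectory(ref, synthetic_config(n_frames = 20, seed = 31,
                                                  ar1_phi = 0))
  C <- dccm_matrix(tj, superpose = FALSE)
  blk <- segment_pair_submatrix(C, segment("S4", "B", 235, 241),
                                segment("SF", "A", 310, 320))
  expect_equal(dim(blk$values), c(7, 11))
  one <- segment_pair_submatrix(C, segment("i", "A", 240, 240),
                                segment("j", "B", 300, 300))
  expect_equal(dim(one$values), c(1, 1))
  expect_equal(one$values[1, 1], C["A:240", "B:300"])
  expect_error(segment_pair_submatrix(C, segment("x", "A", 1, 5),
                                      segment("SF", "A", 310, 320)),
               "not in matrix")
})

test_that("analysis window keeps inclusive endpoints on the frame grid", {
  ref <- reference_geometry(1, 4)
  tj <- generate_trajectory(ref, synthetic_config(n_frames = 120, seed = 32))
  expect_equal(n_frames(analysis_window(tj, 10, 30)), 81)
  expect_equal(n_frames(analysis_window(tj, 0, 1e9)), 120)
  last <- analysis_window(tj, 29.9, 30.0)
  expect_equal(n_frames(last), 1)
  expect_equal(last$timestamps, 30.0)
  expect_error(analysis_window(tj, 40, 50), "no frames")
  expect_error(analysis_window(tj, 5, 5), "t_start < t_end")
})

test_that("labelled matrices round-trip through delimited text", {
  ref <- reference_geometry(1, 4)
  C <- dccm_matrix(generate_trajectory(
    ref, synthetic_config(n_frames = 10, seed = 33)), superpose = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_dccm(C, f)
  back <- read_dccm(f)
  expect_equal(back, unclass(C), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(rownames(back), rownames(C))
})
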