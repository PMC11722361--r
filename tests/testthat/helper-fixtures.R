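# Fixtures are built in code so tests exercise the real construction and
# I/O paths without stored binaries.

# Arginine residue (PDB author numbering 1335) plus a 3-nucleotide DNA
# strand whose 5' residue carries a 5'-OH (no phosphate group).
make_arg_dna_structure <- function() {
  atoms <- data.frame(
    atom_id = 1:20,
    atom_name = c("N", "CA", "C", "O", "CB", "CG", "CD", "NE", "CZ",
                  "NH1", "NH2",
                  "O5'", "C1'", "N9",                     # DG 1 (5', no P)
                  "P", "OP1", "OP2",                      # DG 2
                  "P", "OP1", "OP2"),                     # DG 3
    element = c("N", "C", "C", "O", "C", "C", "C", "N", "C", "N", "N",
                "O", "C", "N", "P", "O", "O", "P", "O", "O"),
    residue_number = c(rep(1335L, 11), rep(1L, 3), rep(2L, 3), rep(3L, 3)),
    residue_name = c(rep("ARG", 11), rep("DG", 9)),
    chain_id = c(rep("A", 11), rep("B", 9)),
    stringsAsFactors = FALSE
  )
  set.seed(1203)
  xyz <- matrix(stats::runif(60, 0, 3), ncol = 3)
  structure_model(atoms, xyz)
}

# A trajectory with the structure's coordinates jittered by iid Gaussian
# noise of sd `sigma` (nm) per coordinate.
make_jitter_trajectory <- function(struct, n, sigma, seed = 1,
                                   frame_interval = 1) {
  set.seed(seed)
  na <- nrow(struct$atoms)
  frames <- array(stats::rnorm(na * 3 * n, 0, sigma), dim = c(na, 3, n))
  frames <- frames + as.vector(struct$xyz)
  trajectory_ensemble(struct, frames, frame_interval)
}

# Single-frame trajectory wrapper around a structure.
as_one_frame_traj <- function(struct, frame_interval = 1) {
  trajectory_ensemble(struct, array(struct$xyz, dim = c(nrow(struct$atoms), 3, 1)),
                      frame_interval)
}

# Rotation matrix about z by `theta` radians.
rot_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}

# Brute-force minimal RMSD: coarse search over ZYZ Euler angles followed by
# Nelder-Mead refinement of the rotation; independent of the SVD route.
brute_force_rmsd <- function(mobile, reference, n_grid = 14) {
  cm <- colMeans(mobile); cr <- colMeans(reference)
  M <- sweep(mobile, 2, cm); Rf <- sweep(reference, 2, cr)
  rot_zyz <- function(a, b, c) {
    Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
    Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
    Rz(a) %*% Ry(b) %*% Rz(c)
  }
  obj <- function(p) {
    R <- rot_zyz(p[1], p[2], p[3])
    sqrt(mean(rowSums((M %*% t(R) - Rf)^2)))
  }
  best <- c(0, 0, 0); best_v <- obj(best)
  as_grid <- seq(0, 2 * pi, length.out = n_grid)
  bs_grid <- seq(0, pi, length.out = n_grid %/% 2 + 1)
  for (a in as_grid) for (b in bs_grid) for (cc in as_grid) {
    v <- obj(c(a, b, cc))
    if (v < best_v) { best <- c(a, b, cc); best_v <- v }
  }
  opt <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  opt$value
}

# Minimal PDB text for low-level parser tests.
minimal_pdb_text <- function() {
  c("ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "END")
}
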