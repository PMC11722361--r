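# Superposition, RMSD/RMSF, COM distance distributions and entropy.

test_that("identical point sets superpose with zero RMSD and identity rotation", {
  set.seed(10)
  x <- matrix(rnorm(15), 5, 3)
  tr <- kabsch_superpose(x, x)
  expect_equal(tr$rmsd, 0, tolerance = 1e-12)
  expect_equal(tr$rotation, diag(3), tolerance = 1e-10)
  expect_equal(det(tr$rotation), 1, tolerance = 1e-8)
})

test_that("a rigidly rotated point set superposes exactly", {
  set.seed(11)
  x <- matrix(rnorm(21), 7, 3)
  y <- x %*% t(rot_z(pi / 2)) + rep(1, 7) %o% c(0.3, -0.1, 2)
  tr <- kabsch_superpose(x, y)
  expect_equal(tr$rmsd, 0, tolerance = 1e-10)
  expect_equal(apply_transform(tr, x), y, tolerance = 1e-10)
})

test_that("the reflection case still yields a proper rotation", {
  set.seed(12)
  x <- matrix(rnorm(12), 4, 3)
  y <- x %*% diag(c(1, 1, -1))   # mirrored target
  tr <- kabsch_superpose(x, y)
  expect_equal(det(tr$rotation), 1, tolerance = 1e-8)
  expect_gt(tr$rmsd, 0)
})

test_that("a displaced point matches the brute-force rotation-search RMSD", {
  set.seed(13)
  x <- matrix(rnorm(12), 4, 3)
  y <- x
  y[2, ] <- y[2, ] + c(0.3, 0, 0)
  got <- kabsch_superpose(x, y)$rmsd
  expect_lt(abs(got - brute_force_rmsd(x, y)), 1e-3)
})

test_that("degenerate collinear configurations are rejected", {
  x <- cbind(1:4, 0, 0)
  expect_error(kabsch_superpose(x, x + 1), "collinear")
})

test_that("superposition RMSD is symmetric and rigid-motion invariant", {
  set.seed(14)
  x <- matrix(rnorm(18), 6, 3)
  y <- x + matrix(rnorm(18, 0, 0.05), 6, 3)
  r1 <- kabsch_superpose(x, y)$rmsd
  expect_equal(kabsch_superpose(y, x)$rmsd, r1, tolerance = 1e-10)
  ym <- y %*% t(rot_z(1.1)) + rep(1, 6) %o% c(4, 5, 6)
  expect_equal(kabsch_superpose(x, ym)$rmsd, r1, tolerance = 1e-10)
})

test_that("backbone RMSD of a translated copy is zero with full matching", {
  s <- make_arg_dna_structure()
  s2 <- s
  s2$xyz <- s$xyz + 0.7
  res <- backbone_rmsd(s, s2)
  expect_equal(res$rmsd, 0, tolerance = 1e-8)
  expect_equal(res$n_matched, 4)     # N, CA, C, O of the one protein residue
  expect_equal(res$n_dropped_a, 0)
})

test_that("backbone RMSD matches atoms by identity and drops the rest", {
  s <- make_arg_dna_structure()
  s2 <- s
  s2$atoms$residue_number[1] <- 9999L   # de-match the N atom
  res <- backbone_rmsd(s, s2)
  expect_equal(res$n_matched, 3)
  expect_equal(res$n_dropped_a, 1)
  expect_equal(res$n_dropped_b, 1)
})

test_that("a frozen trajectory has zero side-chain RMSF", {
  s <- make_arg_dna_structure()
  tr <- make_jitter_trajectory(s, n = 5, sigma = 0)
  r <- sidechain_rmsf(tr, select_atoms(s, "protein"), 1335)
  expect_equal(unname(r$per_residue), 0, tolerance = 1e-10)
})

test_that("isotropic jitter of sd sigma gives RMSF near sigma * sqrt(3)", {
  s <- make_arg_dna_structure()
  sig <- 0.03
  n <- 4000
  # jitter only the analysed side chain; the fit atoms stay frozen so the
  # superposition is exact and the Gaussian-moment oracle applies
  set.seed(21)
  frames <- array(as.vector(s$xyz), dim = c(nrow(s$atoms), 3, n))
  sc <- select_atoms(s, "resid 1335 and sidechain")$indices
  frames[sc, , ] <- frames[sc, , ] +
    rnorm(length(sc) * 3 * n, 0, sig)
  tr <- trajectory_ensemble(s, frames)
  r <- sidechain_rmsf(tr, select_atoms(s, "nucleic"), 1335)
  expect_equal(unname(r$per_residue), nm_to_ang(sig * sqrt(3)),
               tolerance = 0.05)
})

test_that("rigid rotation of every frame leaves RMSF at zero after fitting", {
  s <- make_arg_dna_structure()
  n <- 8
  frames <- array(0, dim = c(nrow(s$atoms), 3, n))
  for (t in seq_len(n))
    frames[, , t] <- s$xyz %*% t(rot_z(0.2 * t))
  tr <- trajectory_ensemble(s, frames)
  r <- sidechain_rmsf(tr, select_atoms(s, "all"), 1335)
  expect_equal(unname(r$per_residue), 0, tolerance = 1e-6)
})

test_that("a static structure gives a degenerate COM distance distribution", {
  s <- make_arg_dna_structure()
  tr <- make_jitter_trajectory(s, n = 4, sigma = 0)
  dd <- com_distance_series(tr, select_atoms(s, "protein"),
                            select_atoms(s, "nucleic"))
  expect_equal(dd$sd, 0)
  expect_null(dd$density)
})

test_that("the distance histogram integrates to one", {
  s <- make_arg_dna_structure()
  tr <- make_jitter_trajectory(s, n = 500, sigma = 0.05, seed = 31)
  dd <- com_distance_series(tr, select_atoms(s, "protein"),
                            select_atoms(s, "nucleic"))
  bw <- diff(dd$breaks)[1]
  expect_equal(sum(dd$density$density) * bw, 1, tolerance = 1e-10)
})

test_that("identical series compare with Z = 0 and p = 1", {
  x <- rnorm(50)
  z <- compare_distributions_z(x, x)
  expect_equal(z$z, 0)
  expect_equal(z$p, 1)
})

test_that("the Z statistic reproduces its closed form on planted Gaussians", {
  set.seed(41)
  a <- rnorm(100, 0, 1); b <- rnorm(100, 1, 1)
  z <- compare_distributions_z(a, b)
  zc <- (mean(a) - mean(b)) / sqrt(var(a) / 100 + var(b) / 100)
  expect_equal(z$z, zc)
  expect_equal(z$p, 2 * pnorm(-abs(zc)))
  expect_lt(abs(z$z + 7.07), 1.5)   # nominal value for a unit shift, n_eff 100
})

test_that("the Z comparison is antisymmetric in its arguments", {
  set.seed(42)
  a <- rnorm(80); b <- rnorm(80, 0.5)
  z1 <- compare_distributions_z(a, b)
  z2 <- compare_distributions_z(b, a)
  expect_equal(z1$z, -z2$z)
  expect_equal(z1$p, z2$p)
})

test_that("a large planted shift is detected at p below 1e-4", {
  set.seed(43)
  a <- rnorm(500, 30, 1); b <- rnorm(500, 40, 1)   # 10 Angstrom shift
  expect_lt(compare_distributions_z(a, b)$p, 1e-4)
})

test_that("autocorrelation widens the Z-test standard errors", {
  set.seed(44)
  a <- rnorm(200); b <- rnorm(200, 0.3)
  z_iid <- compare_distributions_z(a, b)
  z_cor <- compare_distributions_z(a, b, tauA = 10, tauB = 10)
  expect_gt(z_cor$se_a, z_iid$se_a)
  expect_lt(abs(z_cor$z), abs(z_iid$z))
})

test_that("a single mode at x = hbar*omega/kBT = 1 gives the closed-form entropy", {
  kt <- kT(300)
  lam <- pam_constants$hbar^2 / kt       # makes x exactly 1
  s <- entropy_from_eigenvalues(lam, 300)
  expect_equal(s, pam_constants$R * (1 / (exp(1) - 1) - log(1 - exp(-1))),
               tolerance = 1e-12)
  expect_equal(s, 8.6525, tolerance = 1e-4)
})

test_that("stiff modes contribute vanishing entropy", {
  s <- entropy_from_eigenvalues(c(1e-12, 0), 300)
  expect_lt(s, 1e-6)
  expect_equal(entropy_from_eigenvalues(numeric(0), 300), 0)
})

test_that("entropy grows when the covariance is uniformly scaled up", {
  lam <- c(1e-4, 5e-4, 2e-3)
  expect_gt(entropy_from_eigenvalues(2 * lam, 300),
            entropy_from_eigenvalues(lam, 300))
})

test_that("the Schlitter formula upper-bounds the quantum formula", {
  lam <- 10^seq(-6, -2, length.out = 9)
  expect_gt(entropy_from_eigenvalues(lam, 300, "schlitter"),
            entropy_from_eigenvalues(lam, 300, "quantum"))
})

test_that("a planted diagonal covariance is recovered within tolerance", {
  ens <- gen_gaussian_ensemble(covariance = rep(c(4e-4, 1e-3, 2e-3), each = 3),
                               masses = rep(12, 3), n = 20000, seed = 51)
  got <- quasiharmonic_entropy(ens, 1:3, 300, fit = FALSE)
  want <- planted_entropy(ens, 300)
  expect_equal(got$S, want, tolerance = 0.02)
})

test_that("entropy is additive over independent atom blocks", {
  # dimension-major layout: x of atoms 1-4, then y, then z
  ens <- gen_gaussian_ensemble(covariance = c(rep(6e-4, 2), rep(2e-3, 2),
                                              rep(6e-4, 2), rep(2e-3, 2),
                                              rep(6e-4, 2), rep(2e-3, 2)),
                               masses = rep(12, 4), n = 30000, seed = 52)
  s_all <- quasiharmonic_entropy(ens, 1:4, 300, fit = FALSE)$S
  s_a <- quasiharmonic_entropy(ens, 1:2, 300, fit = FALSE)$S
  s_b <- quasiharmonic_entropy(ens, 3:4, 300, fit = FALSE)$S
  expect_equal(s_all, s_a + s_b, tolerance = 0.02)
})

test_that("rigid-body removal drops exactly six modes for a fitted ensemble", {
  s <- make_arg_dna_structure()
  tr <- make_jitter_trajectory(s, n = 400, sigma = 0.02, seed = 53)
  res <- quasiharmonic_entropy(tr, select_atoms(s, "resid 1335"), 300,
                               fit = TRUE)
  expect_equal(res$n_dropped, 6)
  expect_gt(res$S, 0)
})

test_that("entropy requires an explicit positive temperature", {
  s <- make_arg_dna_structure()
  tr <- make_jitter_trajectory(s, n = 20, sigma = 0.01)
  expect_error(quasiharmonic_entropy(tr, 1:3, -1), "temperature")
})
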