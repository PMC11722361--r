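# Synthetic-data generators. Every generator is deterministic given its
# seed, echoes its parameters, and carries a ground truth computable without
# running the analysis pipeline, so each downstream stage is testable by
# plant-and-recover.

#' Correlated binary contact series (two-state Markov chain)
#'
#' Generates a stationary two-state Markov chain with prescribed occupancy
#' `p` and integrated autocorrelation time `tau`. With the chain's second
#' eigenvalue mu, the integrated time is tau = dt (1 + mu) / (2 (1 - mu)),
#' inverted here as mu = (2 tau/dt - 1) / (2 tau/dt + 1); the equivalent
#' exponential autocorrelation time is tau_exp = -dt / log(mu). `tau = 0`
#' (or tau <= dt/2) yields i.i.d. Bernoulli draws.
#'
#' @param p stationary occupancy, 0 < p < 1.
#' @param tau integrated autocorrelation time, ps (>= 0).
#' @param n number of frames.
#' @param frame_interval dt, ps.
#' @param seed RNG seed (mandatory).
#' @return a [contact_series()] with attribute `ground_truth`
#'   (list `p`, `tau`, `mu`).
#' @export
gen_markov_binary <- function(p, tau, n, frame_interval = 1, seed) {
  stopifnot(p > 0, p < 1, tau >= 0, n >= 1)
  set.seed(seed)
  dt <- frame_interval
  if (tau <= dt / 2) {
    vals <- stats::rbinom(n, 1, p)
    mu <- 0
  } else {
    r <- 2 * tau / dt
    mu <- (r - 1) / (r + 1)
    a <- p * (1 - mu)            # P(0 -> 1)
    b <- (1 - p) * (1 - mu)      # P(1 -> 0)
    if (a > 1 || b > 1) stop("infeasible (p, tau) combination")
    state <- stats::rbinom(1, 1, p)
    runs_s <- integer(0); runs_l <- integer(0)
    total <- 0L
    while (total < n) {
      # geometric sojourn in the current state (support >= 1)
      len <- 1L + stats::rgeom(1, if (state == 1) b else a)
      runs_s <- c(runs_s, state); runs_l <- c(runs_l, len)
      total <- total + len
      state <- 1L - state
    }
    vals <- inverse.rle(structure(list(lengths = runs_l, values = runs_s),
                                  class = "rle"))[seq_len(n)]
  }
  out <- contact_series(vals, frame_interval, pair_id = "synthetic-markov")
  attr(out, "ground_truth") <- list(p = p, tau = tau, mu = mu)
  out
}

#' Multivariate Gaussian atomic ensemble with planted covariance
#'
#' Draws i.i.d. frames around a mean geometry with a prescribed coordinate
#' covariance, so the quasi-harmonic entropy is known in closed form from
#' the planted mass-weighted eigenvalues (see [planted_entropy()]). The
#' covariance uses the coordinate layout (x of all atoms, then all y, then
#' all z), matching [quasiharmonic_entropy()].
#'
#' @param covariance either a length-3N vector (diagonal covariance, nm^2)
#'   or a 3N x 3N positive semi-definite matrix.
#' @param masses per-atom masses, amu (length N).
#' @param n number of frames.
#' @param seed RNG seed.
#' @param mean_coords optional N x 3 mean geometry (nm); defaults to atoms
#'   1 nm apart along x.
#' @param frame_interval ps.
#' @return a [trajectory_ensemble()] with attribute `ground_truth`
#'   (list `eigenvalues` of the mass-weighted covariance, `covariance`,
#'   `masses`).
#' @export
gen_gaussian_ensemble <- function(covariance, masses, n, seed,
                                  mean_coords = NULL, frame_interval = 1) {
  set.seed(seed)
  N <- length(masses)
  if (is.null(mean_coords))
    mean_coords <- cbind(seq_len(N) * 1.0, 0, 0)
  w <- rep(sqrt(masses), times = 3)
  if (is.matrix(covariance)) {
    stopifnot(nrow(covariance) == 3 * N, ncol(covariance) == 3 * N)
    ec <- eigen((covariance + t(covariance)) / 2, symmetric = TRUE)
    if (min(ec$values) < -1e-10) stop("covariance is not positive semi-definite")
    L <- ec$vectors %*% diag(sqrt(pmax(ec$values, 0)), 3 * N)
    samp <- matrix(stats::rnorm(n * 3 * N), n) %*% t(L)
    mw <- (w %o% w) * covariance
    lam <- eigen(mw, symmetric = TRUE, only.values = TRUE)$values
  } else {
    stopifnot(length(covariance) == 3 * N, all(covariance >= 0))
    samp <- matrix(stats::rnorm(n * 3 * N), n) *
      rep(sqrt(covariance), each = n)
    lam <- sort(w^2 * covariance, decreasing = TRUE)
  }
  frames <- array(0, dim = c(N, 3, n))
  for (d in 1:3)
    frames[, d, ] <- mean_coords[, d] + t(samp[, (d - 1) * N + seq_len(N)])
  atoms <- data.frame(atom_id = seq_len(N),
                      atom_name = rep("CA", N), element = rep("C", N),
                      residue_number = seq_len(N),
                      residue_name = rep("GLY", N),
                      chain_id = "A", mass = masses)
  ref <- structure_model(atoms, mean_coords)
  out <- trajectory_ensemble(ref, frames, frame_interval,
                             source_label = "synthetic-gaussian")
  attr(out, "ground_truth") <- list(eigenvalues = lam, covariance = covariance,
                                    masses = masses)
  out
}

#' Closed-form entropy of a planted Gaussian ensemble
#'
#' @param ensemble a [gen_gaussian_ensemble()] result.
#' @param temperature K.
#' @param method see [entropy_from_eigenvalues()].
#' @return entropy in J/mol/K.
#' @export
planted_entropy <- function(ensemble, temperature, method = "quantum") {
  gt <- attr(ensemble, "ground_truth")
  entropy_from_eigenvalues(gt$eigenvalues, temperature, method)
}

#' Probe trajectory with planted contact episodes
#'
#' Builds a minimal system (a single probe atom, a 3-atom nucleobase site
#' and a 3-atom phosphate site) plus per-frame interaction-energy series.
#' During a planted episode the probe satisfies *both* the distance and
#' energy criteria of its category; outside (and during `*_weak` episodes)
#' it violates at least one, so classification recall and precision are
#' 100% by construction.
#'
#' @param episodes data.frame with columns `start`, `end` (1-based frame
#'   ranges, inclusive) and `category` in `"base"`, `"phosphate"`, `"none"`,
#'   `"base_weak"` (distance met, energy too weak). Episodes must tile
#'   1..n without overlap.
#' @param n number of frames.
#' @param seed RNG seed.
#' @param criteria the [contact_criteria()] the episodes are planted
#'   against.
#' @param energy_levels list with `base`, `phosphate`, `weak`, `off`
#'   energies (kJ/mol).
#' @param noise positional jitter sd (nm), kept small against the cutoffs.
#' @param frame_interval ps.
#' @return list with `traj`, `energies` (data.frame `base`, `phosphate`),
#'   `selections` (probe/base/phosphate), `ground_truth` (planted occupancy
#'   per category), `criteria`.
#' @export
gen_probe_trajectory <- function(episodes, n, seed,
                                 criteria = contact_criteria(),
                                 energy_levels = list(base = -150,
                                                      phosphate = -400,
                                                      weak = -50, off = -5),
                                 noise = 0.01, frame_interval = 1) {
  set.seed(seed)
  cov <- integer(n)
  for (i in seq_len(nrow(episodes))) {
    idx <- episodes$start[i]:episodes$end[i]
    if (any(cov[idx] != 0)) stop("episode schedule overlaps")
    cov[idx] <- i
  }
  if (any(cov == 0)) stop("episodes must tile the full frame range")

  base_xyz <- rbind(c(0, 0, 0), c(0.12, 0, 0), c(0, 0.12, 0))
  phos_xyz <- rbind(c(3, 0, 0), c(3.12, 0, 0), c(3, 0.12, 0))
  atoms <- data.frame(
    atom_id = 1:7,
    atom_name = c("CZ", "N1", "C2", "O6", "P", "OP1", "OP2"),
    element = c("C", "N", "C", "O", "P", "O", "O"),
    residue_number = c(1L, rep(10L, 3), rep(11L, 3)),
    residue_name = c("ARG", rep("DG", 3), rep("DG", 3)),
    chain_id = c("A", rep("B", 6)))
  ref <- structure_model(atoms, rbind(c(10, 10, 10), base_xyz, phos_xyz))
  m <- ref$atoms$mass
  com_of <- function(rows, xyz) colSums(xyz * m[rows] / sum(m[rows]))
  base_com <- com_of(2:4, base_xyz)
  phos_com <- com_of(5:7, phos_xyz)

  frames <- array(0, dim = c(7, 3, n))
  for (t in seq_len(n)) {
    frames[2:4, , t] <- base_xyz
    frames[5:7, , t] <- phos_xyz
  }
  e_base <- numeric(n); e_phos <- numeric(n)
  near <- function(com, d) com + c(d, 0, 0) + stats::rnorm(3, 0, noise)
  for (t in seq_len(n)) {
    cat_t <- episodes$category[cov[t]]
    pos <- switch(cat_t,
      base      = near(base_com, 0.4),
      base_weak = near(base_com, 0.4),
      phosphate = near(phos_com, 0.35),
      none      = c(10, 10, 10) + stats::rnorm(3, 0, noise))
    frames[1, , t] <- pos
    e_base[t] <- switch(cat_t, base = energy_levels$base,
                        base_weak = energy_levels$weak,
                        energy_levels$off)
    e_phos[t] <- switch(cat_t, phosphate = energy_levels$phosphate,
                        energy_levels$off)
  }
  traj <- trajectory_ensemble(ref, frames, frame_interval,
                              source_label = "synthetic-probe")
  planted <- c(base = mean(episodes$category[cov] == "base"),
               phosphate = mean(episodes$category[cov] == "phosphate"))
  list(traj = traj,
       energies = data.frame(base = e_base, phosphate = e_phos),
       selections = list(
         probe = select_atoms(ref, "resid 1", label = "probe"),
         base = select_atoms(ref, "resid 10", label = "base site"),
         phosphate = select_atoms(ref, "resid 11", label = "phosphate site")),
       ground_truth = planted, criteria = criteria)
}

#' Analytic one-dimensional double-well toy system
#'
#' V(x) = a (x^2 - 1)^2 with minima at x = +/-1 nm and barrier height `a`
#' at x = 0. Because the collective variable is the coordinate itself, the
#' reference free-energy surface equals V up to a constant; basin free
#' energies follow by numerical Boltzmann integration.
#'
#' @param a barrier height, kJ/mol.
#' @param mass amu.
#' @param friction ps^-1.
#' @param temperature K.
#' @param x0 initial position, nm.
#' @return a [toy_system()] with extra fields `a` and `reference_fes`
#'   (function of a grid returning V shifted to min 0).
#' @export
analytic_double_well <- function(a = 2.5, mass = 1, friction = 5,
                                 temperature = 300, x0 = -1) {
  stopifnot(a > 0)
  sys <- toy_system(
    potential = function(x) a * (x[, 1]^2 - 1)^2,
    gradient = function(x) matrix(4 * a * x[, 1] * (x[, 1]^2 - 1), ncol = 1),
    mass = mass, friction = friction, temperature = temperature, x0 = x0)
  sys$a <- a
  sys$reference_fes <- function(grid) {
    v <- a * (grid^2 - 1)^2
    v - min(v)
  }
  sys
}

#' Basin free-energy difference from a free-energy profile
#'
#' dF = F_right - F_left with F_basin = -kBT ln sum_grid exp(-F/kBT),
#' splitting the grid at `split`.
#'
#' @param F free-energy values on `grid`, kJ/mol.
#' @param grid CV grid.
#' @param temperature K.
#' @param split dividing point between the basins.
#' @export
basin_delta_f <- function(F, grid, temperature, split = 0) {
  kt <- kT(temperature)
  lhs <- F[grid < split]; rhs <- F[grid >= split]
  fb <- function(f) -kt * .logsumexp(-f / kt)
  fb(rhs) - fb(lhs)
}

#' Harmonic lambda-state sample sets with analytic free energies
#'
#' State lambda is the harmonic oscillator U(x) = k(lambda)/2 (x -
#' x0(lambda))^2; exact Gaussian samples are drawn from each state and the
#' analytic reduced free-energy difference between states i and j is
#' (1/2) ln(k_j / k_i) (center shifts do not change the partition function).
#'
#' @param lambdas schedule of lambda values.
#' @param n_per_state samples per state.
#' @param temperature K.
#' @param seed RNG seed.
#' @param k_fn spring constant (kJ/mol/nm^2) as a function of lambda.
#' @param x0_fn center (nm) as a function of lambda.
#' @return list with `problem` (an `mbar_problem`), `analytic_f` (reduced
#'   free energies relative to state 1), `energy_fns`, `sampler`,
#'   `lambdas`.
#' @export
gen_harmonic_lambda_samples <- function(lambdas, n_per_state, temperature,
                                        seed,
                                        k_fn = function(l) 1 + l,
                                        x0_fn = function(l) 0 * l) {
  set.seed(seed)
  kt <- kT(temperature)
  ks <- vapply(lambdas, k_fn, numeric(1))
  x0s <- vapply(lambdas, x0_fn, numeric(1))
  stopifnot(all(ks > 0))
  energy_fns <- lapply(seq_along(lambdas), function(i) {
    force(i)
    function(x) 0.5 * ks[i] * (x - x0s[i])^2
  })
  samples <- lapply(seq_along(lambdas), function(i)
    stats::rnorm(n_per_state, x0s[i], sqrt(kt / ks[i])))
  sampler <- function(lambda, n)
    stats::rnorm(n, x0_fn(lambda), sqrt(kt / k_fn(lambda)))
  list(problem = reduced_potentials(samples, energy_fns, temperature),
       analytic_f = 0.5 * log(ks / ks[1]),
       energy_fns = energy_fns, sampler = sampler, lambdas = lambdas)
}
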