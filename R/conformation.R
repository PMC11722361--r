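# Superposition/RMSD, side-chain RMSF, domain COM distance distributions
# with two-tailed Z comparison, and quasi-harmonic conformational entropy.

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares optimal rotation and translation mapping `mobile` onto
#' `reference`, with optional weights (e.g. masses) and proper handling of
#' the reflection case (the rotation always has determinant +1).
#'
#' @param mobile,reference n x 3 coordinate matrices (same point count,
#'   n >= 3, not all collinear).
#' @param weights optional non-negative weights, length n.
#' @return list of class `rigid_transform`: `rotation` (3 x 3, det +1),
#'   `translation` (length 3), `rmsd` (weighted, same length unit as input).
#'   The fitted coordinates are `mobile %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3)
    stop("mobile and reference must be matching n x 3 matrices")
  n <- nrow(mobile)
  if (n < 3) stop("at least 3 points required")
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  M <- sweep(mobile, 2, cm)
  Rf <- sweep(reference, 2, cr)
  H <- t(M * w) %*% Rf
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300))
    stop("degenerate (collinear) point configuration")
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- cr - as.vector(rot %*% cm)
  fitted <- M %*% t(rot)
  rmsd <- sqrt(sum(w * rowSums((fitted - Rf)^2)))
  structure(list(rotation = rot, translation = trans, rmsd = rmsd),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: rmsd = %.6g, det(R) = %.4f\n",
              x$rmsd, det(x$rotation)))
  invisible(x)
}

#' Apply a rigid transform to coordinates
#' @param transform a `rigid_transform`.
#' @param coords n x 3 matrix.
#' @export
apply_transform <- function(transform, coords) {
  sweep(as.matrix(coords) %*% t(transform$rotation), 2,
        transform$translation, "+")
}

#' Backbone RMSD between two structures
#'
#' Atoms are matched by chain id + residue number + atom name over the given
#' backbone atom names; unmatched atoms are dropped and counted. The RMSD is
#' computed after optimal superposition and reported in Angstrom.
#'
#' @param structA,structB [structure_model()] objects.
#' @param selection selection expression restricting the comparison
#'   (default `"backbone"`).
#' @param atom_names backbone atom set; use `c("CA")` for CA-only RMSD.
#' @return list of class `rmsd_result`: `rmsd` (Angstrom), `n_matched`,
#'   `n_dropped_a`, `n_dropped_b`, `transform`.
#' @export
backbone_rmsd <- function(structA, structB, selection = "backbone",
                          atom_names = c("N", "CA", "C", "O")) {
  key <- function(s) {
    idx <- select_atoms(s, selection)$indices
    a <- s$atoms[idx, ]
    keep <- toupper(a$atom_name) %in% toupper(atom_names)
    idx <- idx[keep]; a <- a[keep, ]
    list(idx = idx, key = paste(a$chain_id, a$residue_number, toupper(a$atom_name)))
  }
  ka <- key(structA); kb <- key(structB)
  common <- intersect(ka$key, kb$key)
  if (length(common) < 3) stop("fewer than 3 matched backbone atoms")
  ia <- ka$idx[match(common, ka$key)]
  ib <- kb$idx[match(common, kb$key)]
  tr <- kabsch_superpose(structA$xyz[ia, ], structB$xyz[ib, ])
  structure(list(rmsd = nm_to_ang(tr$rmsd), n_matched = length(common),
                 n_dropped_a = length(ka$idx) - length(common),
                 n_dropped_b = length(kb$idx) - length(common),
                 transform = tr),
            class = "rmsd_result")
}

#' @export
print.rmsd_result <- function(x, ...) {
  cat(sprintf("backbone RMSD: %.3f Angstrom over %d matched atoms (dropped %d/%d)\n",
              x$rmsd, x$n_matched, x$n_dropped_a, x$n_dropped_b))
  invisible(x)
}

# Superpose every frame of a trajectory onto a reference frame using the
# fit selection (mass-weighted); returns a new frames array.
.fit_frames <- function(traj, fit_idx, ref_coords = NULL, weights = NULL) {
  nf <- n_frames(traj)
  if (is.null(ref_coords)) ref_coords <- traj$frames[fit_idx, , 1]
  if (is.null(weights)) weights <- traj$reference$atoms$mass[fit_idx]
  frames <- traj$frames
  for (t in seq_len(nf)) {
    tr <- kabsch_superpose(frames[fit_idx, , t], ref_coords, weights)
    frames[, , t] <- apply_transform(tr, frames[, , t])
  }
  frames
}

#' Side-chain root mean square fluctuations
#'
#' Frames are least-squares fitted (mass-weighted, on `fit_selection`) onto
#' their running mean structure; RMSF_i = sqrt(<|x_i - <x_i>|^2>) is then
#' reported per heavy side-chain atom of the target residue and aggregated
#' per residue, in Angstrom.
#'
#' @param traj a [trajectory_ensemble()] with at least 2 frames.
#' @param fit_selection selection used for the superposition.
#' @param target_residue residue number whose side chain is analysed.
#' @param chain optional chain id.
#' @return list with `per_atom` (named vector, Angstrom) and `per_residue`
#'   (mean over side-chain heavy atoms).
#' @export
sidechain_rmsf <- function(traj, fit_selection, target_residue, chain = NULL) {
  if (n_frames(traj) < 2) stop("RMSF needs at least 2 frames")
  fit_idx <- .sel_indices(fit_selection, traj$reference)
  frames <- .fit_frames(traj, fit_idx)
  mean1 <- apply(frames[fit_idx, , , drop = FALSE], c(1, 2), mean)
  frames <- .fit_frames(trajectory_ensemble(traj$reference, frames,
                                            traj$frame_interval),
                        fit_idx, ref_coords = mean1)
  expr <- paste("resid", target_residue, "and sidechain and heavy")
  if (!is.null(chain)) expr <- paste(expr, "and chain", chain)
  sc <- select_atoms(traj$reference, expr)$indices
  if (length(sc) == 0) stop("target residue has no side-chain heavy atoms")
  per_atom <- numeric(length(sc))
  for (i in seq_along(sc)) {
    x <- t(frames[sc[i], , ])                       # n_frames x 3
    mu <- colMeans(x)
    per_atom[i] <- sqrt(mean(rowSums(sweep(x, 2, mu)^2)))
  }
  per_atom <- nm_to_ang(per_atom)
  names(per_atom) <- traj$reference$atoms$atom_name[sc]
  list(per_atom = per_atom, per_residue = mean(per_atom))
}

#' Domain centre-of-mass distance distribution
#'
#' Per-frame mass-weighted COM distance between two domains, in Angstrom,
#' with a histogram density estimate (Scott-rule bin width by default).
#'
#' @param traj a [trajectory_ensemble()].
#' @param domainA,domainB selections (all heavy atoms of each domain by
#'   convention; pass CA-only selections to switch).
#' @param breaks optional histogram breaks (Angstrom).
#' @return list of class `distance_distribution`: `series` (Angstrom),
#'   `density` (data.frame mid/density or NULL for a degenerate series),
#'   `breaks`, `mean`, `sd`.
#' @export
com_distance_series <- function(traj, domainA, domainB, breaks = NULL) {
  r <- nm_to_ang(com_distance(traj, domainA, domainB))
  s <- stats::sd(r)
  dens <- NULL
  if (length(r) > 1 && s > 0) {
    if (is.null(breaks)) {
      bw <- 3.49 * s * length(r)^(-1/3)            # Scott's rule
      breaks <- seq(min(r) - bw, max(r) + bw, by = bw)
    }
    h <- graphics::hist(r, breaks = breaks, plot = FALSE)
    dens <- data.frame(mid = h$mids, density = h$density)
  }
  structure(list(series = r, density = dens, breaks = breaks,
                 mean = mean(r), sd = s),
            class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf("COM distance: mean %.2f Angstrom, sd %.2f, n = %d%s\n",
              x$mean, x$sd, length(x$series),
              if (is.null(x$density)) " (degenerate)" else ""))
  invisible(x)
}

#' @export
plot.distance_distribution <- function(x, ...) {
  if (is.null(x$density)) stop("degenerate distribution: nothing to plot")
  plot(x$density$mid, x$density$density, type = "h",
       xlab = "COM distance (Angstrom)", ylab = "probability density", ...)
  invisible(x)
}

#' Two-tailed Z comparison of two distance series
#'
#' Z = (mean_A - mean_B) / sqrt(SE_A^2 + SE_B^2) with autocorrelation-
#' corrected standard errors (n_eff = n dt / (2 tau), capped at n), and the
#' two-tailed normal p-value.
#'
#' @param seriesA,seriesB numeric series or `distance_distribution` objects.
#' @param tauA,tauB integrated autocorrelation times, ps.
#' @param frame_interval frame spacing, ps.
#' @return list with `z`, `p`, `mean_a`, `mean_b`, `se_a`, `se_b`.
#' @export
compare_distributions_z <- function(seriesA, seriesB, tauA = 0, tauB = 0,
                                    frame_interval = 1) {
  grab <- function(s) if (inherits(s, "distance_distribution")) s$series else as.numeric(s)
  a <- grab(seriesA); b <- grab(seriesB)
  if (length(a) == 0 || length(b) == 0) stop("empty series")
  se <- function(x, tau) {
    n <- length(x)
    n_eff <- if (tau <= frame_interval / 2) n else min(n, n * frame_interval / (2 * tau))
    sqrt(stats::var(x) / n_eff)
  }
  sa <- se(a, tauA); sb <- se(b, tauB)
  if (sa == 0 && sb == 0) stop("zero variance in both series")
  z <- (mean(a) - mean(b)) / sqrt(sa^2 + sb^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)), mean_a = mean(a),
       mean_b = mean(b), se_a = sa, se_b = sb)
}

#' Quasi-harmonic entropy from mode eigenvalues
#'
#' Per-mode entropy of a quantum harmonic oscillator with frequency
#' omega = sqrt(kB T / lambda), where lambda is an eigenvalue of the
#' mass-weighted covariance matrix (amu nm^2). With x = hbar omega / kB T,
#' the quantum formula gives S = R sum x/(e^x - 1) - ln(1 - e^-x); the
#' Schlitter variant gives the upper bound S = (R/2) sum ln(1 + e^2/x^2).
#'
#' @param eigenvalues mass-weighted covariance eigenvalues, amu nm^2.
#' @param temperature K.
#' @param method `"quantum"` (Andricioaei-Karplus) or `"schlitter"`.
#' @return entropy in J/mol/K.
#' @export
entropy_from_eigenvalues <- function(eigenvalues, temperature,
                                     method = c("quantum", "schlitter")) {
  method <- match.arg(method)
  stopifnot(temperature > 0, all(eigenvalues >= 0))
  lam <- eigenvalues[eigenvalues > 0]
  if (length(lam) == 0) return(0)
  kt <- kT(temperature)
  omega <- sqrt(kt / lam)
  x <- pam_constants$hbar * omega / kt
  s_mode <- if (method == "quantum")
    x / (exp(x) - 1) - log1p(-exp(-x))
  else
    0.5 * log1p(exp(2) / x^2)
  pam_constants$R * sum(s_mode)
}

#' Quasi-harmonic conformational entropy of a selection
#'
#' Builds the mass-weighted covariance of atomic fluctuations of the
#' selection (after optional least-squares removal of rigid-body motion),
#' eigen-decomposes it, and evaluates the per-mode oscillator entropy.
#' With rigid-body removal the six near-zero eigenvalues are excluded by a
#' magnitude floor rather than by count (a warning is raised when the count
#' differs from 6).
#'
#' @param traj a [trajectory_ensemble()].
#' @param selection atoms to analyse.
#' @param temperature K (required; no silent default).
#' @param fit remove rigid-body motion by mass-weighted fitting onto the
#'   ensemble mean of the selection (default TRUE). Use FALSE for ensembles
#'   whose covariance is defined in the lab frame (e.g. planted synthetic
#'   ensembles).
#' @param method `"quantum"` or `"schlitter"`.
#' @param eig_floor eigenvalue magnitude floor, amu nm^2.
#' @return list of class `entropy_result`: `S` (J/mol/K), `eigenvalues`,
#'   `omega` (ps^-1), `temperature`, `n_frames`, `n_modes`,
#'   `n_dropped`, `method`, `label`.
#' @export
quasiharmonic_entropy <- function(traj, selection, temperature, fit = TRUE,
                                  method = c("quantum", "schlitter"),
                                  eig_floor = 1e-8) {
  method <- match.arg(method)
  stopifnot(temperature > 0)
  idx <- .sel_indices(selection, traj$reference)
  nf <- n_frames(traj)
  if (nf < 3 * length(idx))
    warning("fewer frames (", nf, ") than 3N (", 3 * length(idx),
            "): entropy may be poorly converged")
  m <- traj$reference$atoms$mass[idx]
  frames <- traj$frames[idx, , , drop = FALSE]
  if (fit) {
    sub <- trajectory_ensemble(
      structure_model(traj$reference$atoms[idx, ], traj$reference$xyz[idx, , drop = FALSE]),
      frames, traj$frame_interval)
    f1 <- .fit_frames(sub, seq_along(idx))
    mean1 <- apply(f1, c(1, 2), mean)
    sub$frames <- f1
    frames <- .fit_frames(sub, seq_along(idx), ref_coords = mean1)
  }
  # n_frames x 3N matrix of mass-weighted fluctuations
  X <- t(matrix(frames, nrow = length(idx) * 3, ncol = nf))
  X <- sweep(X, 2, colMeans(X))
  X <- sweep(X, 2, rep(sqrt(m), times = 3), "*")  # columns are (x..., y..., z...)
  C <- crossprod(X) / nf
  lam <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  lam[lam < 0] <- 0
  keep <- lam > eig_floor
  if (fit && sum(!keep) != 6)
    warning("expected 6 rigid-body modes below the floor, found ", sum(!keep))
  lam_keep <- lam[keep]
  kt <- kT(temperature)
  structure(list(S = entropy_from_eigenvalues(lam_keep, temperature, method),
                 eigenvalues = lam_keep, omega = sqrt(kt / lam_keep),
                 temperature = temperature, n_frames = nf,
                 n_modes = length(lam_keep), n_dropped = sum(!keep),
                 method = method,
                 label = if (inherits(selection, "atom_selection"))
                           selection$label else "indices"),
            class = "entropy_result")
}

#' @export
print.entropy_result <- function(x, ...) {
  cat(sprintf("quasi-harmonic entropy [%s]: %.2f J/mol/K (%d modes, %d dropped, %s, T = %g K)\n",
              x$label, x$S, x$n_modes, x$n_dropped, x$method, x$temperature))
  invisible(x)
}
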