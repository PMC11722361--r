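# Dual-criterion contact classification between arginine guanidinium groups
# and DNA bases / backbone phosphates, with autocorrelation-corrected
# occupancy statistics.

#' Contact classification criteria
#'
#' A candidate guanidinium--base pair is prefiltered on the centre-of-mass
#' distance (default < 0.6 nm; phosphate pairs < 0.5 nm) being met in at
#' least `min_occupancy_prefilter` of the pooled frames, and a frame counts
#' as an effective contact only if the distance criterion holds *and* the
#' interaction energy is attractive with magnitude at least the category
#' threshold (100 kJ/mol for bases, 350 kJ/mol for phosphates).
#'
#' @param base_distance_cutoff nm, guanidinium--nucleobase COM cutoff.
#' @param phosphate_distance_cutoff nm, guanidinium--phosphate COM cutoff.
#' @param base_energy_threshold kJ/mol, magnitude of attractive energy.
#' @param phosphate_energy_threshold kJ/mol, magnitude of attractive energy.
#' @param min_occupancy_prefilter fraction of pooled frames (inclusive bound).
#' @return list of class `contact_criteria`.
#' @export
contact_criteria <- function(base_distance_cutoff = 0.6,
                             phosphate_distance_cutoff = 0.5,
                             base_energy_threshold = 100,
                             phosphate_energy_threshold = 350,
                             min_occupancy_prefilter = 0.05) {
  stopifnot(base_distance_cutoff > 0, phosphate_distance_cutoff > 0,
            base_energy_threshold > 0, phosphate_energy_threshold > 0,
            min_occupancy_prefilter >= 0, min_occupancy_prefilter <= 1)
  structure(list(base_distance_cutoff = base_distance_cutoff,
                 phosphate_distance_cutoff = phosphate_distance_cutoff,
                 base_energy_threshold = base_energy_threshold,
                 phosphate_energy_threshold = phosphate_energy_threshold,
                 min_occupancy_prefilter = min_occupancy_prefilter),
            class = "contact_criteria")
}

.criteria_for <- function(criteria, category) {
  category <- match.arg(category, c("base", "phosphate"))
  if (category == "base")
    list(cutoff = criteria$base_distance_cutoff,
         threshold = criteria$base_energy_threshold)
  else
    list(cutoff = criteria$phosphate_distance_cutoff,
         threshold = criteria$phosphate_energy_threshold)
}

# Per-frame mass-weighted centre of mass of a selection: n_frames x 3 (nm).
.com_series <- function(traj, selection) {
  idx <- .sel_indices(selection, traj$reference)
  m <- traj$reference$atoms$mass[idx]
  w <- m / sum(m)
  nf <- n_frames(traj)
  out <- matrix(0, nf, 3)
  for (d in 1:3) {
    sub <- matrix(traj$frames[idx, d, ], nrow = length(idx), ncol = nf)
    out[, d] <- as.vector(w %*% sub)
  }
  out
}

#' Centre-of-mass distance series between two atom groups
#'
#' @param traj a [trajectory_ensemble()].
#' @param groupA,groupB [select_atoms()] selections (or index vectors).
#' @return numeric vector of per-frame mass-weighted COM distances, nm.
#' @export
com_distance <- function(traj, groupA, groupB) {
  a <- .com_series(traj, groupA)
  b <- .com_series(traj, groupB)
  sqrt(rowSums((a - b)^2))
}

#' Per-frame group--group interaction energy
#'
#' Sums pairwise Coulomb energies (prefactor 138.935458 kJ mol^-1 nm e^-2)
#' and, when Lennard-Jones parameters are supplied, 12-6 LJ energies with
#' Lorentz--Berthelot combination, between two groups for every frame.
#' Alternatively a pre-computed per-frame energy table (e.g. exported from
#' an MD engine) is passed through unchanged with pair metadata attached.
#'
#' @param traj a [trajectory_ensemble()].
#' @param groupA,groupB selections.
#' @param charges per-atom charges (e) for the whole structure; defaults to
#'   the structure's `charge` column.
#' @param lj_params optional data.frame with per-atom `sigma` (nm) and
#'   `epsilon` (kJ/mol), row per structure atom.
#' @param table optional numeric vector (or single-column data.frame) of
#'   per-frame energies in kJ/mol; returned as-is.
#' @param pair_id label attached to the series.
#' @param category contact category, `"base"` or `"phosphate"`.
#' @return numeric vector (kJ/mol) of class `pair_energy_series` with
#'   attributes `pair_id` and `category`.
#' @export
pair_interaction_energy <- function(traj, groupA, groupB, charges = NULL,
                                    lj_params = NULL, table = NULL,
                                    pair_id = "pair", category = "base") {
  if (!is.null(table)) {
    e <- if (is.data.frame(table)) table[[ncol(table)]] else as.numeric(table)
    if (!is.null(traj) && length(e) != n_frames(traj))
      stop("energy table length does not match trajectory frame count")
    return(structure(as.numeric(e), class = "pair_energy_series",
                     pair_id = pair_id, category = category))
  }
  ref <- traj$reference
  ia <- .sel_indices(groupA, ref)
  ib <- .sel_indices(groupB, ref)
  if (is.null(charges)) charges <- ref$atoms$charge
  if (anyNA(charges[c(ia, ib)]))
    stop("missing charges; supply `charges` or an external energy `table`")
  qq <- pam_constants$f_coulomb * outer(charges[ia], charges[ib])
  if (!is.null(lj_params)) {
    sig <- outer(lj_params$sigma[ia], lj_params$sigma[ib], "+") / 2
    eps <- sqrt(outer(lj_params$epsilon[ia], lj_params$epsilon[ib]))
  }
  nf <- n_frames(traj)
  e <- numeric(nf)
  for (t in seq_len(nf)) {
    fa <- matrix(traj$frames[ia, , t], length(ia), 3)
    fb <- matrix(traj$frames[ib, , t], length(ib), 3)
    d2 <- outer(rowSums(fa^2), rowSums(fb^2), "+") - 2 * fa %*% t(fb)
    r <- sqrt(pmax(d2, 0))
    e[t] <- sum(qq / r)
    if (!is.null(lj_params)) {
      sr6 <- (sig / r)^6
      e[t] <- e[t] + sum(4 * eps * (sr6^2 - sr6))
    }
  }
  structure(e, class = "pair_energy_series", pair_id = pair_id,
            category = category)
}

#' Prefilter candidate contact pairs on pooled distance occupancy
#'
#' A pair survives iff its category-specific COM distance cutoff is met in
#' at least `min_occupancy_prefilter` (inclusive) of all frames pooled
#' across replicates.
#'
#' @param trajs a `trajectory_ensemble` or list of replicate ensembles
#'   sharing the reference topology.
#' @param arginine_groups named list of guanidinium-group selections.
#' @param dna_groups named list; each element is `list(selection =, category =)`
#'   with category `"base"` or `"phosphate"`.
#' @param criteria a [contact_criteria()].
#' @return data.frame with columns `arginine`, `dna_group`, `category`,
#'   `occupancy`, `retained`.
#' @export
prefilter_pairs <- function(trajs, arginine_groups, dna_groups,
                            criteria = contact_criteria()) {
  if (inherits(trajs, "trajectory_ensemble")) trajs <- list(trajs)
  out <- expand.grid(arginine = names(arginine_groups),
                     dna_group = names(dna_groups),
                     stringsAsFactors = FALSE)
  out$category <- vapply(out$dna_group,
                         function(g) dna_groups[[g]]$category, character(1))
  occ <- numeric(nrow(out))
  for (i in seq_len(nrow(out))) {
    cutoff <- .criteria_for(criteria, out$category[i])$cutoff
    hits <- 0; total <- 0
    for (traj in trajs) {
      d <- com_distance(traj, arginine_groups[[out$arginine[i]]],
                        dna_groups[[out$dna_group[i]]]$selection)
      hits <- hits + sum(d < cutoff)
      total <- total + length(d)
    }
    occ[i] <- hits / total
  }
  out$occupancy <- occ
  out$retained <- occ >= criteria$min_occupancy_prefilter
  out
}

#' Classify per-frame effective contacts from distance and energy series
#'
#' A frame is a contact iff the COM distance is strictly below the category
#' cutoff and the interaction energy is attractive with magnitude at least
#' the category threshold (E <= -threshold).
#'
#' @param distances per-frame COM distances, nm.
#' @param energies aligned per-frame interaction energies, kJ/mol.
#' @param criteria a [contact_criteria()].
#' @param category `"base"` or `"phosphate"`.
#' @param frame_interval frame spacing, ps.
#' @param pair_id label.
#' @return A `contact_series`: list with binary `values`, `frame_interval`,
#'   `pair_id`, `category`.
#' @export
classify_contacts <- function(distances, energies, criteria, category,
                              frame_interval = 1, pair_id = "pair") {
  if (length(distances) != length(energies))
    stop("distance and energy series must be frame-aligned")
  crit <- .criteria_for(criteria, category)
  vals <- as.integer(distances < crit$cutoff & energies <= -crit$threshold)
  contact_series(vals, frame_interval, pair_id = pair_id, category = category)
}

#' Construct a binary contact occupancy series
#'
#' @param values binary vector (0/1 or logical).
#' @param frame_interval ps.
#' @param pair_id,category labels.
#' @export
contact_series <- function(values, frame_interval = 1, pair_id = "pair",
                           category = "base") {
  values <- as.integer(values)
  if (!all(values %in% c(0L, 1L))) stop("contact series must be binary")
  stopifnot(frame_interval > 0)
  structure(list(values = values, frame_interval = frame_interval,
                 pair_id = pair_id, category = category),
            class = "contact_series")
}

#' Integrated autocorrelation time
#'
#' tau = dt * (1/2 + sum_k rho(k)) with Sokal-style automatic windowing:
#' the sum is truncated at the smallest lag M with M >= c * tau(M)/dt
#' (c = 6). A constant series has tau = 0 by definition; for an
#' uncorrelated series tau approaches dt/2.
#'
#' @param series numeric series (typically the pair interaction energy).
#' @param frame_interval dt, ps.
#' @param c_window Sokal window constant.
#' @return tau in ps (>= 0).
#' @export
integrated_autocorrelation_time <- function(series, frame_interval = 1,
                                            c_window = 6) {
  if (inherits(series, "contact_series")) {
    frame_interval <- series$frame_interval
    series <- series$values
  }
  n <- length(series)
  if (n < 10) stop("series too short for autocorrelation estimation")
  if (stats::var(series) == 0) return(0)
  lag_max <- min(n - 1, 10000L)
  rho <- as.vector(stats::acf(series, lag.max = lag_max, plot = FALSE,
                              demean = TRUE)$acf)[-1]
  tau_k <- 0.5 + cumsum(rho)            # in units of dt
  ks <- seq_along(tau_k)
  ok <- which(ks >= c_window * tau_k)
  M <- if (length(ok) > 0) ok[1] else lag_max
  max(frame_interval * tau_k[M], 0)
}

#' Occupancy frequency with autocorrelation-corrected standard error
#'
#' Treats the binary series as Bernoulli draws: p-hat = mean occupancy,
#' variance p(1-p), and the effective number of independent samples
#' n_eff = n * dt / (2 tau), capped at n. The tau should be the largest
#' integrated autocorrelation time of the matching pair's energy series
#' across replicates.
#'
#' @param contacts a [contact_series()].
#' @param tau integrated autocorrelation time, ps.
#' @return A `freq_estimate` list: `p`, `variance`, `tau`, `n_eff`, `se`,
#'   `n_frames`, `replicate_id`.
#' @export
frequency_with_error <- function(contacts, tau) {
  stopifnot(inherits(contacts, "contact_series"), tau >= 0)
  x <- contacts$values
  n <- length(x)
  dt <- contacts$frame_interval
  p <- mean(x)
  v <- p * (1 - p)
  n_eff <- if (tau <= dt / 2) n else min(n, n * dt / (2 * tau))
  structure(list(p = p, variance = v, tau = tau, n_eff = n_eff,
                 se = sqrt(v / n_eff), n_frames = n,
                 replicate_id = attr(contacts, "replicate_id")),
            class = "freq_estimate")
}

#' @export
print.freq_estimate <- function(x, ...) {
  cat(sprintf("occupancy %.4f +/- %.4f (n_eff %.1f of %d, tau %.2f ps)\n",
              x$p, x$se, x$n_eff, x$n_frames, x$tau))
  invisible(x)
}

#' Aggregate replicate frequency estimates
#'
#' Mean of the replicate means, with error given by the standard deviation
#' of the replicate means divided by sqrt(R).
#'
#' @param estimates list of `freq_estimate` objects (or numeric means).
#' @return list with `mean`, `error` (NA with a warning for < 2 replicates),
#'   and `n_replicates`.
#' @export
aggregate_replicates <- function(estimates) {
  means <- vapply(estimates,
                  function(e) if (inherits(e, "freq_estimate")) e$p else as.numeric(e),
                  numeric(1))
  r <- length(means)
  if (r < 2) {
    warning("fewer than 2 replicates: error undefined")
    return(list(mean = mean(means), error = NA_real_, n_replicates = r))
  }
  list(mean = mean(means), error = stats::sd(means) / sqrt(r), n_replicates = r)
}
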