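# Geometric hydrogen-bond detection, frequency normalization and the
# PAM-specificity index.

#' Hydrogen-bond criteria
#'
#' Standard geometric definition: donor--acceptor distance at most 3.5
#' Angstrom and hydrogen-donor-acceptor angle at most 30 degrees (small
#' angle = near-linear D-H...A arrangement).
#'
#' @param donor_acceptor_cutoff Angstrom.
#' @param angle_cutoff degrees, vertex at the donor.
#' @export
hbond_criteria <- function(donor_acceptor_cutoff = 3.5, angle_cutoff = 30) {
  stopifnot(donor_acceptor_cutoff > 0, angle_cutoff > 0, angle_cutoff < 180)
  structure(list(donor_acceptor_cutoff = donor_acceptor_cutoff,
                 angle_cutoff = angle_cutoff),
            class = "hbond_criteria")
}

# Pair each hydrogen with its covalently bound donor heavy atom: nearest
# donor in the same residue within 1.25 Angstrom in the reference frame.
.pair_hydrogens_to_donors <- function(structure, donors, hydrogens) {
  xyz <- structure$xyz
  at <- structure$atoms
  parent <- integer(length(hydrogens))
  for (i in seq_along(hydrogens)) {
    h <- hydrogens[i]
    same_res <- donors[at$residue_number[donors] == at$residue_number[h] &
                       at$chain_id[donors] == at$chain_id[h]]
    if (length(same_res) == 0)
      stop("hydrogen atom ", at$atom_id[h], " has no donor parent in its residue")
    d <- sqrt(colSums((t(xyz[same_res, , drop = FALSE]) - xyz[h, ])^2))
    j <- which.min(d)
    if (d[j] > 0.125)
      stop("hydrogen atom ", at$atom_id[h], " is not covalently bound to a donor")
    parent[i] <- same_res[j]
  }
  parent
}

#' Detect hydrogen bonds along a trajectory
#'
#' For every (donor, hydrogen, acceptor) triplet, a frame has the bond iff
#' the donor--acceptor distance is at most the cutoff and the
#' hydrogen-donor-acceptor angle is at most the angle cutoff.
#' Donor--hydrogen pairing is taken from `dh_pairs` when given, otherwise
#' inferred from covalent geometry in the reference frame.
#'
#' @param traj a [trajectory_ensemble()].
#' @param donors,hydrogens,acceptors selections (donor and acceptor heavy
#'   atoms, typically N/O).
#' @param criteria a [hbond_criteria()].
#' @param dh_pairs optional integer vector: for each hydrogen, the structure
#'   index of its donor.
#' @param category interaction category label (e.g. "PAM-NB", "PAM-BB",
#'   "non-PAM").
#' @return list of `hbond_series`, each a list with `values` (binary),
#'   `donor`, `hydrogen`, `acceptor` (atom indices), `category`,
#'   `frame_interval`.
#' @export
detect_hbonds <- function(traj, donors, hydrogens, acceptors,
                          criteria = hbond_criteria(), dh_pairs = NULL,
                          category = "non-PAM") {
  ref <- traj$reference
  d_idx <- .sel_indices(donors, ref)
  h_idx <- .sel_indices(hydrogens, ref)
  a_idx <- .sel_indices(acceptors, ref)
  parent <- if (is.null(dh_pairs)) .pair_hydrogens_to_donors(ref, d_idx, h_idx)
            else as.integer(dh_pairs)
  cut_nm <- ang_to_nm(criteria$donor_acceptor_cutoff)
  cos_cut <- cos(criteria$angle_cutoff * pi / 180)
  nf <- n_frames(traj)
  out <- list()
  for (i in seq_along(h_idx)) {
    h <- h_idx[i]; d <- parent[i]
    for (a in a_idx) {
      if (a == d || a == h) next
      vals <- integer(nf)
      for (t in seq_len(nf)) {
        f <- traj$frames[, , t]
        da <- f[a, ] - f[d, ]
        r <- sqrt(sum(da^2))
        if (r > cut_nm) next
        dh <- f[h, ] - f[d, ]
        ca <- sum(da * dh) / (r * sqrt(sum(dh^2)))
        if (ca >= cos_cut) vals[t] <- 1L
      }
      out[[length(out) + 1]] <- structure(
        list(values = vals, donor = d, hydrogen = h, acceptor = a,
             category = category, frame_interval = traj$frame_interval),
        class = "hbond_series")
    }
  }
  out
}

#' Hydrogen-bond frequency of a series
#'
#' Ratio of frames with the bond present to the total number of frames.
#'
#' @param series an `hbond_series` (or binary vector).
#' @return frequency in `[0, 1]`.
#' @export
hbond_frequency <- function(series) {
  v <- if (inherits(series, "hbond_series")) series$values else as.numeric(series)
  if (length(v) == 0) stop("empty hydrogen-bond series")
  mean(v)
}

#' Per-category hydrogen-bond frequencies
#'
#' Sums per-triplet frequencies within each category (one count per triplet
#' per frame).
#'
#' @param series_list list of `hbond_series`.
#' @param categories category levels to report (zero for empty categories).
#' @return named numeric vector of summed frequencies.
#' @export
hbond_category_frequencies <- function(series_list,
                                       categories = c("PAM-NB", "PAM-BB", "non-PAM")) {
  out <- stats::setNames(numeric(length(categories)), categories)
  for (s in series_list) {
    if (!s$category %in% names(out)) out[s$category] <- 0
    out[s$category] <- out[s$category] + hbond_frequency(s)
  }
  out
}

#' Normalize a set of frequencies to unit sum
#'
#' Divides each entry by the sum of all entries in the dataset (e.g. the
#' PAM-NB, PAM-BB and non-PAM frequencies of one arginine). An all-zero
#' dataset is returned unchanged with a warning.
#'
#' @param freqs non-negative numeric vector.
#' @return vector of the same shape summing to 1 (or all zeros).
#' @export
normalize_frequencies <- function(freqs) {
  stopifnot(all(freqs >= 0))
  s <- sum(freqs)
  if (s == 0) {
    warning("all-zero frequency dataset: returning zeros")
    return(freqs)
  }
  freqs / s
}

#' PAM specificity index
#'
#' Ratio of the hydrogen-bond frequency with the PAM nucleotides to the
#' frequency with non-PAM nucleotides, with a small epsilon guard in the
#' denominator and first-order error propagation. The alternative bounded
#' form f_PAM / (f_PAM + f_nonPAM) is available via `mode = "share"`.
#'
#' @param freq_pam frequency with PAM nucleotides (NB + BB).
#' @param freq_nonpam frequency with non-PAM nucleotides.
#' @param err_pam,err_nonpam input standard errors.
#' @param epsilon denominator guard.
#' @param mode `"ratio"` (default) or `"share"`.
#' @param residue residue label.
#' @return list of class `specificity_index` with `value`, `error`,
#'   `residue`, `mode`, and `flag` ("both-zero" when applicable).
#' @export
specificity_index <- function(freq_pam, freq_nonpam, err_pam = 0,
                              err_nonpam = 0, epsilon = 1e-6,
                              mode = c("ratio", "share"), residue = "") {
  mode <- match.arg(mode)
  stopifnot(freq_pam >= 0, freq_nonpam >= 0)
  flag <- NA_character_
  if (freq_pam == 0 && freq_nonpam == 0) {
    flag <- "both-zero"
    val <- 0; err <- 0
  } else if (mode == "ratio") {
    den <- freq_nonpam + epsilon
    val <- freq_pam / den
    err <- sqrt((err_pam / den)^2 + (freq_pam * err_nonpam / den^2)^2)
  } else {
    den <- freq_pam + freq_nonpam
    val <- freq_pam / den
    # d/df_P = f_N/den^2 ; d/df_N = -f_P/den^2
    err <- sqrt((freq_nonpam * err_pam)^2 + (freq_pam * err_nonpam)^2) / den^2
  }
  structure(list(value = val, error = err, residue = residue, mode = mode,
                 flag = flag),
            class = "specificity_index")
}

#' @export
print.specificity_index <- function(x, ...) {
  cat(sprintf("specificity index%s: %.4f +/- %.4f (%s)%s\n",
              if (nzchar(x$residue)) paste0(" [", x$residue, "]") else "",
              x$value, x$error, x$mode,
              if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}
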