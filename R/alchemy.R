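# Alchemical free-energy machinery: reduced-potential assembly, MBAR
# estimator with asymptotic uncertainties, Metropolis neighbor swaps,
# lambda-window optimization to a target exchange acceptance,
# thermodynamic-cycle ddG and block-averaged enthalpy decomposition.

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Assemble a reduced-potential matrix
#'
#' u[k, n] = U_k(x_n) / (kB T): every pooled sample evaluated in every
#' state's energy function.
#'
#' @param samples list of numeric vectors (or matrices with one row per
#'   sample), one element per state, samples drawn from that state.
#' @param energy_fns list of state energy functions (kJ/mol), same length.
#' @param temperature K.
#' @return list of class `mbar_problem`: `u` (K x N matrix), `N_k` (samples
#'   per state), `temperature`.
#' @export
reduced_potentials <- function(samples, energy_fns, temperature) {
  K <- length(energy_fns)
  stopifnot(length(samples) == K, K >= 1)
  N_k <- vapply(samples, function(s) if (is.matrix(s)) nrow(s) else length(s),
                integer(1))
  pooled <- do.call(c, lapply(samples, as.numeric))
  N <- sum(N_k)
  u <- matrix(0, K, N)
  for (k in seq_len(K)) u[k, ] <- energy_fns[[k]](pooled) / kT(temperature)
  if (!all(is.finite(u))) stop("non-finite reduced potentials")
  structure(list(u = u, N_k = N_k, temperature = temperature),
            class = "mbar_problem")
}

#' Solve the MBAR equations
#'
#' Finds the reduced free energies f_k of all states from samples of all
#' states, by self-consistent iteration with a Newton-Raphson switch once
#' close to the fixed point, anchored at f_1 = 0. Uncertainties come from
#' the asymptotic covariance of the estimator. Adjacent-state overlap below
#' 0.03 raises a warning.
#'
#' @param u K x N reduced-potential matrix, or an `mbar_problem`.
#' @param N_k samples per state (ignored when `u` is an `mbar_problem`).
#' @param tolerance convergence threshold on max |delta f|.
#' @param max_iter iteration cap.
#' @return object of class `mbar`: `f_k` (reduced free energies, f_1 = 0),
#'   `Theta` (covariance of f_k), `N_k`, `overlap` (adjacent-state overlap),
#'   `iterations`, `converged`, `temperature` (if known).
#' @export
mbar_solve <- function(u, N_k = NULL, tolerance = 1e-8, max_iter = 2000) {
  temperature <- NA_real_
  if (inherits(u, "mbar_problem")) {
    N_k <- u$N_k; temperature <- u$temperature; u <- u$u
  }
  K <- nrow(u); N <- ncol(u)
  stopifnot(length(N_k) == K, sum(N_k) == N)
  if (all(N_k == 0)) stop("at least one state needs samples")
  smp <- which(N_k > 0)               # unsampled states drop out of the mixture
  logN <- log(N_k[smp])
  f <- numeric(K)

  # log denominator per sample: log sum_{k sampled} N_k exp(f_k - u_kn)
  log_denom <- function(f) {
    a <- f[smp] + logN - u[smp, , drop = FALSE]   # |smp| x N
    m <- apply(a, 2, max)
    m + log(colSums(exp(sweep(a, 2, m))))
  }
  sc_update <- function(f) {
    ld <- log_denom(f)
    fn <- -apply(sweep(-u, 2, ld), 1, .logsumexp)
    fn - fn[1]
  }

  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    f_new <- sc_update(f)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < 1e-2 && length(smp) > 1) {   # Newton on the sampled states
      for (nr in seq_len(200)) {
        it <- it + 1
        ld <- log_denom(f)
        Wn <- exp(sweep(f[smp] + logN - u[smp, , drop = FALSE], 2, ld))
        g <- rowSums(Wn) - N_k[smp]
        H <- diag(rowSums(Wn), length(smp)) - Wn %*% t(Wn)
        step <- tryCatch(solve(H[-1, -1, drop = FALSE], g[-1]),
                         error = function(e) NULL)
        if (is.null(step)) break
        f[smp[-1]] <- f[smp[-1]] - step
        if (max(abs(step)) < tolerance) { converged <- TRUE; break }
      }
      if (converged) { f <- sc_update(f); break }
    }
    if (delta < tolerance) { converged <- TRUE; break }
  }
  if (!converged) stop("MBAR did not converge within ", max_iter, " iterations")
  f <- f - f[1]

  # asymptotic covariance: W is N x K with W_nk = exp(f_k - u_kn)/denom_n
  ld <- log_denom(f)
  Wm <- t(exp(sweep(f - u, 2, ld)))              # N x K, columns sum to 1
  sv <- svd(Wm)
  S <- diag(sv$d, length(sv$d))
  inner <- diag(K) - S %*% t(sv$v) %*% (N_k * sv$v) %*% S
  ei <- eigen((inner + t(inner)) / 2, symmetric = TRUE)
  pos <- ei$values > max(ei$values) * 1e-10
  inner_pinv <- ei$vectors[, pos, drop = FALSE] %*%
    (t(ei$vectors[, pos, drop = FALSE]) / ei$values[pos])
  Theta <- sv$v %*% S %*% inner_pinv %*% S %*% t(sv$v)

  # adjacent-state overlap: O_{k,k+1} from the overlap matrix N_k W^T W
  O <- (t(Wm) %*% Wm) * N_k
  overlap <- if (K > 1) vapply(seq_len(K - 1),
                               function(k) min(O[k, k + 1], O[k + 1, k]),
                               numeric(1)) else numeric(0)
  both_sampled <- if (K > 1) N_k[-K] > 0 & N_k[-1] > 0 else logical(0)
  if (any(overlap[both_sampled] < 0.03))
    warning("low overlap between adjacent states (min ",
            format(min(overlap), digits = 2), ")")
  structure(list(f_k = f, Theta = Theta, N_k = N_k, overlap = overlap,
                 iterations = it, converged = converged,
                 temperature = temperature),
            class = "mbar")
}

#' @export
print.mbar <- function(x, ...) {
  cat("MBAR solution over", length(x$f_k), "states (", x$iterations,
      "iterations )\n")
  se <- sqrt(pmax(diag(x$Theta) + x$Theta[1, 1] - 2 * x$Theta[1, ], 0))
  print(data.frame(state = seq_along(x$f_k), f_k = x$f_k, se_vs_state1 = se,
                   N_k = x$N_k))
  invisible(x)
}

#' @export
coef.mbar <- function(object, ...) object$f_k

#' @export
summary.mbar <- function(object, ...) {
  K <- length(object$f_k)
  dg <- delta_f(object, 1, K)
  structure(list(K = K, f_k = object$f_k, ddG_reduced = dg,
                 overlap = object$overlap, N_k = object$N_k,
                 temperature = object$temperature),
            class = "summary.mbar")
}

#' @export
print.summary.mbar <- function(x, ...) {
  cat(sprintf("MBAR: %d states, Delta f(1 -> %d) = %.4f +/- %.4f kT",
              x$K, x$K, x$ddG_reduced$df, x$ddG_reduced$se))
  if (!is.na(x$temperature))
    cat(sprintf("  (%.4f +/- %.4f kJ/mol at %g K)",
                x$ddG_reduced$df * kT(x$temperature),
                x$ddG_reduced$se * kT(x$temperature), x$temperature))
  cat("\n")
  if (length(x$overlap))
    cat("adjacent overlap:", paste(format(x$overlap, digits = 3),
                                   collapse = " "), "\n")
  invisible(x)
}

#' Free-energy difference between two states of an MBAR solution
#'
#' @param fit an [mbar_solve()] result.
#' @param i,j state indices; the difference is f_j - f_i.
#' @return list with `df` (reduced units) and `se`.
#' @export
delta_f <- function(fit, i, j) {
  stopifnot(inherits(fit, "mbar"))
  v <- fit$Theta[i, i] + fit$Theta[j, j] - 2 * fit$Theta[i, j]
  list(df = fit$f_k[j] - fit$f_k[i], se = sqrt(max(v, 0)))
}

#' Metropolis neighbor-swap decision
#'
#' Accepts a configuration exchange between neighboring states with
#' probability min(1, exp(-[U_i(x_j) + U_j(x_i) - U_i(x_i) - U_j(x_j)]/kBT)).
#'
#' @param x_i,x_j current configurations of the two states.
#' @param U_i,U_j state energy functions (kJ/mol).
#' @param temperature K.
#' @return logical: swap accepted.
#' @export
neighbor_swap <- function(x_i, x_j, U_i, U_j, temperature) {
  delta <- (U_i(x_j) + U_j(x_i) - U_i(x_i) - U_j(x_j)) / kT(temperature)
  delta <= 0 || stats::runif(1) < exp(-delta)
}

#' Estimate the swap acceptance rate between two states
#'
#' Mean Metropolis acceptance probability over paired pilot samples.
#'
#' @param sampler function(lambda, n) drawing n samples from the state.
#' @param energy_fn function(lambda) returning that state's energy function.
#' @param lambda_i,lambda_j the two states.
#' @param n_pilot pilot samples per state.
#' @param temperature K.
#' @export
swap_acceptance_rate <- function(sampler, energy_fn, lambda_i, lambda_j,
                                 n_pilot = 200, temperature = 300) {
  xi <- sampler(lambda_i, n_pilot)
  xj <- sampler(lambda_j, n_pilot)
  Ui <- energy_fn(lambda_i); Uj <- energy_fn(lambda_j)
  delta <- (Ui(xj) + Uj(xi) - Ui(xi) - Uj(xj)) / kT(temperature)
  mean(pmin(1, exp(-delta)))
}

#' Optimize a lambda schedule to a target exchange acceptance
#'
#' Moves interior lambda values by damped gradient descent on the squared
#' acceptance deficits of their adjacent gaps, inserting a midpoint window
#' into the worst gap when the interior adjustment stalls, until the minimum
#' neighbor acceptance reaches the target (default 10%) or the window budget
#' is exhausted.
#'
#' @param sampler function(lambda, n) drawing pilot samples.
#' @param energy_fn function(lambda) -> energy function (kJ/mol).
#' @param lambdas initial strictly increasing schedule including 0 and 1.
#' @param target_acceptance minimum acceptable neighbor acceptance.
#' @param temperature K.
#' @param n_pilot pilot samples per acceptance estimate.
#' @param max_iter gradient-descent iterations per window count.
#' @param max_windows window budget.
#' @param rate descent step scale.
#' @return list of class `lambda_schedule`: `lambdas`, `acceptance`
#'   (per gap), `achieved` (logical), `n_windows`.
#' @export
optimize_lambda_schedule <- function(sampler, energy_fn, lambdas,
                                     target_acceptance = 0.10,
                                     temperature = 300, n_pilot = 200,
                                     max_iter = 40, max_windows = 64,
                                     rate = 0.25) {
  stopifnot(all(diff(lambdas) > 0), lambdas[1] == 0,
            lambdas[length(lambdas)] == 1)
  acc_all <- function(ls) vapply(seq_len(length(ls) - 1), function(k)
    swap_acceptance_rate(sampler, energy_fn, ls[k], ls[k + 1], n_pilot,
                         temperature), numeric(1))
  repeat {
    acc <- acc_all(lambdas)
    for (iter in seq_len(max_iter)) {
      if (min(acc) >= target_acceptance) break
      K <- length(lambdas)
      if (K > 2) {
        # equalize neighbor acceptances: move each interior lambda toward
        # its weaker gap, step damped by the local gap widths
        new <- lambdas
        for (k in 2:(K - 1)) {
          d_lo <- target_acceptance - acc[k - 1]   # deficit of gap below
          d_hi <- target_acceptance - acc[k]       # deficit of gap above
          grad <- d_hi * max(d_hi, 0) - d_lo * max(d_lo, 0)
          width <- min(lambdas[k] - lambdas[k - 1],
                       lambdas[k + 1] - lambdas[k])
          new[k] <- lambdas[k] + rate * width * sign(grad) *
            min(abs(grad) / max(target_acceptance^2, 1e-12), 1)
        }
        new <- pmin(pmax(new, 0), 1)
        if (all(diff(new) > 1e-6)) lambdas <- new
      }
      acc <- acc_all(lambdas)
    }
    if (min(acc) >= target_acceptance || length(lambdas) >= max_windows) break
    worst <- which.min(acc)
    lambdas <- sort(c(lambdas, mean(lambdas[worst:(worst + 1)])))
  }
  achieved <- min(acc) >= target_acceptance
  if (!achieved)
    warning("target acceptance not reached within the window budget (min ",
            format(min(acc), digits = 3), ")")
  structure(list(lambdas = lambdas, acceptance = acc, achieved = achieved,
                 n_windows = length(lambdas)),
            class = "lambda_schedule")
}

#' @export
print.lambda_schedule <- function(x, ...) {
  cat("lambda schedule:", length(x$lambdas), "windows, min acceptance",
      format(min(x$acceptance), digits = 3),
      if (x$achieved) "(target met)\n" else "(target NOT met)\n")
  invisible(x)
}

#' Thermodynamic-cycle ddG
#'
#' ddG = dG_m2 (mutation with DNA bound) - dG_m1 (mutation without DNA),
#' uncertainties summed in quadrature. A negative ddG means the mutation
#' favours the DNA-bound state (stabilizes binding).
#'
#' @param dG_m1,dG_m2 free energies (any consistent unit) with standard
#'   errors given either as `se_m1`/`se_m2` or as length-2 vectors
#'   `c(value, se)`.
#' @param se_m1,se_m2 standard errors.
#' @param unit unit label carried through.
#' @return list of class `cycle_result`: `ddG`, `se`, `dG_m1`, `dG_m2`,
#'   `unit`.
#' @export
ddg_cycle <- function(dG_m1, dG_m2, se_m1 = 0, se_m2 = 0, unit = "kcal/mol") {
  if (length(dG_m1) == 2) { se_m1 <- dG_m1[2]; dG_m1 <- dG_m1[1] }
  if (length(dG_m2) == 2) { se_m2 <- dG_m2[2]; dG_m2 <- dG_m2[1] }
  structure(list(ddG = dG_m2 - dG_m1, se = sqrt(se_m1^2 + se_m2^2),
                 dG_m1 = dG_m1, dG_m2 = dG_m2, unit = unit),
            class = "cycle_result")
}

#' @export
print.cycle_result <- function(x, ...) {
  cat(sprintf("ddG = %.3f +/- %.3f %s (dG_m1 = %.3f, dG_m2 = %.3f)\n",
              x$ddG, x$se, x$unit, x$dG_m1, x$dG_m2))
  invisible(x)
}

#' Per-residue interaction-energy average with block errors
#'
#' Discards the initial equilibration fraction of the series, averages the
#' remainder, and estimates the error as the standard deviation of
#' `n_blocks` contiguous block means divided by sqrt(n_blocks).
#'
#' @param series per-frame residue--DNA interaction energies, kJ/mol.
#' @param equilibration_fraction fraction of initial frames discarded.
#' @param n_blocks number of blocks.
#' @return list of class `enthalpy_estimate`: `mean`, `error`,
#'   `block_means`, `n_used`, `n_discarded`.
#' @export
per_residue_deltaE <- function(series, equilibration_fraction = 0.10,
                               n_blocks = 5) {
  n0 <- floor(length(series) * equilibration_fraction)
  kept <- series[(n0 + 1):length(series)]
  if (length(kept) < n_blocks) stop("too few frames after equilibration discard")
  blocks <- split(kept, cut(seq_along(kept), n_blocks, labels = FALSE))
  bm <- vapply(blocks, mean, numeric(1))
  structure(list(mean = mean(kept), error = stats::sd(bm) / sqrt(n_blocks),
                 block_means = unname(bm), n_used = length(kept),
                 n_discarded = n0),
            class = "enthalpy_estimate")
}

#' @export
print.enthalpy_estimate <- function(x, ...) {
  cat(sprintf("deltaE = %.3f +/- %.3f kJ/mol (%d frames, %d discarded)\n",
              x$mean, x$error, x$n_used, x$n_discarded))
  invisible(x)
}
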