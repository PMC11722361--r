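# Well-tempered metadynamics engine: Gaussian bias deposition with tempered
# heights, one-sided harmonic walls, multiple walkers sharing one hill log,
# BAOAB Langevin propagation on analytic toy landscapes, and free-energy
# surface reconstruction with convergence diagnostics.

#' Well-tempered metadynamics configuration
#'
#' The bias is grown by Gaussians of width `sigma` deposited every
#' `deposition_stride` ps with pre-tempering height
#' `deposition_rate * deposition_stride`; the actual height of each hill is
#' scaled by exp(-V(s)/(kB (gamma - 1) T)) where V is the bias already
#' present at the deposition point and gamma = (T + dT)/T is the bias
#' factor. Defaults follow common practice for COM-distance collective
#' variables: deposition rate 1.0 kJ/mol/ps, stride 10 ps, bias factor 4 at
#' 300 K, and one-sided harmonic walls of 3500 kJ/mol/nm^2.
#'
#' @param deposition_rate omega, kJ/mol per ps.
#' @param deposition_stride t_G, ps.
#' @param bias_factor gamma > 1, dimensionless.
#' @param temperature K.
#' @param sigma Gaussian width per collective variable (CV units).
#' @param walls list of walls from [harmonic_wall()].
#' @return list of class `metad_config`.
#' @export
metad_config <- function(deposition_rate = 1.0, deposition_stride = 10,
                         bias_factor = 4, temperature = 300, sigma = 0.05,
                         walls = list()) {
  stopifnot(deposition_rate > 0, deposition_stride > 0, bias_factor > 1,
            temperature > 0, all(sigma > 0))
  structure(list(deposition_rate = deposition_rate,
                 deposition_stride = deposition_stride,
                 bias_factor = bias_factor, temperature = temperature,
                 sigma = sigma, walls = walls),
            class = "metad_config")
}

#' One-sided harmonic wall
#'
#' Lower wall at `at`: (k/2)(at - s)^2 for s < at, 0 otherwise; upper wall
#' symmetric. Energy and force are continuous at the wall position.
#'
#' @param side `"lower"` or `"upper"`.
#' @param at wall position (CV units).
#' @param k force constant, kJ/mol per CV unit squared.
#' @param dim which CV the wall acts on.
#' @export
harmonic_wall <- function(side = c("lower", "upper"), at, k = 3500, dim = 1L) {
  side <- match.arg(side)
  stopifnot(k > 0)
  list(side = side, at = at, k = k, dim = as.integer(dim))
}

#' Wall energy and force
#'
#' @param s CV points: numeric vector (one point) or matrix points x D.
#' @param walls list of [harmonic_wall()]s.
#' @return list with `energy` (per point) and `force` (points x D matrix,
#'   -dV/ds).
#' @export
wall_potential <- function(s, walls) {
  s <- if (is.matrix(s)) s else matrix(s, nrow = 1)
  e <- numeric(nrow(s))
  f <- matrix(0, nrow(s), ncol(s))
  for (w in walls) {
    x <- s[, w$dim]
    excess <- if (w$side == "lower") pmin(x - w$at, 0) else pmax(x - w$at, 0)
    e <- e + 0.5 * w$k * excess^2
    f[, w$dim] <- f[, w$dim] - w$k * excess
  }
  list(energy = e, force = f)
}

# Hills are stored as a data.frame: time, center.1..D, sigma.1..D, height,
# biasf, walker.
.hill_centers <- function(hills) {
  unname(as.matrix(hills[, grep("^center", names(hills)), drop = FALSE]))
}
.hill_sigmas <- function(hills) {
  unname(as.matrix(hills[, grep("^sigma", names(hills)), drop = FALSE]))
}

#' Metadynamics bias potential from a hill log
#'
#' V(s) = sum_h height_h * exp(-sum_i (s_i - c_{h,i})^2 / (2 sigma_{h,i}^2)).
#' With an empty log the bias is zero everywhere.
#'
#' @param hills hill log data.frame (see [run_wtmetad()]); may have 0 rows.
#' @param s CV points: numeric vector of length D for one point, or a
#'   points x D matrix.
#' @return numeric vector of bias values, kJ/mol.
#' @export
bias_potential <- function(hills, s) {
  if (is.null(hills) || nrow(hills) == 0) {
    return(numeric(if (is.matrix(s)) nrow(s) else length(s)))
  }
  cen <- .hill_centers(hills); sig <- .hill_sigmas(hills)
  # a bare vector is a set of points when the CV is one-dimensional,
  # otherwise a single multi-dimensional point
  if (!is.matrix(s)) {
    s <- if (ncol(cen) == 1L) matrix(s, ncol = 1) else matrix(s, nrow = 1)
  }
  if (ncol(s) != ncol(cen)) stop("CV dimension mismatch with hill log")
  v <- numeric(nrow(s))
  for (h in seq_len(nrow(hills))) {
    expo <- rep(0, nrow(s))
    for (d in seq_len(ncol(s)))
      expo <- expo + (s[, d] - cen[h, d])^2 / (2 * sig[h, d]^2)
    v <- v + hills$height[h] * exp(-expo)
  }
  v
}

#' Deposit one tempered hill
#'
#' Height = omega * t_G * exp(-V(s)/(kB (gamma - 1) T)), where V(s) is the
#' bias already accumulated at the deposition point. The temperature boost
#' dT of the well-tempered exponent is expressed in energy units as
#' kB (gamma - 1) T.
#'
#' @param s CV position of the walker (length D).
#' @param config a [metad_config()].
#' @param hills existing hill log (possibly empty).
#' @param time deposition time, ps.
#' @param walker walker id.
#' @return one-row data.frame to append to the hill log.
#' @export
deposit_hill <- function(s, config, hills = NULL, time = 0, walker = 1L) {
  if (config$bias_factor <= 1) stop("bias factor must exceed 1")
  v <- if (is.null(hills) || nrow(hills) == 0) 0 else bias_potential(hills, s)
  dT_energy <- pam_constants$kB * (config$bias_factor - 1) * config$temperature
  h0 <- config$deposition_rate * config$deposition_stride
  sigma <- rep(config$sigma, length.out = length(s))
  row <- data.frame(time = time, t(s), t(sigma),
                    height = h0 * exp(-v / dT_energy),
                    biasf = config$bias_factor, walker = as.integer(walker))
  names(row) <- c("time", paste0("center.", seq_along(s)),
                  paste0("sigma.", seq_along(s)), "height", "biasf", "walker")
  row
}

#' Toy dynamical system on an analytic potential
#'
#' @param potential function: matrix (points x D) -> vector of energies
#'   (kJ/mol).
#' @param gradient function: matrix (points x D) -> matrix of dV/ds.
#' @param mass amu.
#' @param friction Langevin friction, ps^-1.
#' @param temperature K.
#' @param x0 initial CV position (length D).
#' @return list of class `toy_system`.
#' @export
toy_system <- function(potential, gradient, mass = 1, friction = 5,
                       temperature = 300, x0 = 0) {
  stopifnot(mass > 0, friction > 0, temperature > 0)
  structure(list(potential = potential, gradient = gradient, mass = mass,
                 friction = friction, temperature = temperature,
                 x0 = as.numeric(x0), dim = length(x0)),
            class = "toy_system")
}

#' Run well-tempered metadynamics on a toy system
#'
#' Propagates `n_walkers` independent BAOAB Langevin walkers under
#' potential + shared metadynamics bias + walls. Every `deposition_stride`
#' each walker (in walker order) deposits a tempered hill into the shared
#' log, so the log ordering is lexicographic in (time, walker). For 1D
#' systems the bias and its force are cached on a fine grid (hill addition
#' updates the cache); correctness is defined by direct summation, which the
#' cache reproduces to interpolation accuracy.
#'
#' @param system a [toy_system()].
#' @param config a [metad_config()].
#' @param n_walkers number of walkers.
#' @param n_steps Langevin steps per walker.
#' @param seed RNG seed (required: runs are bit-reproducible given the seed).
#' @param dt integration timestep, ps.
#' @param grid_spacing bias-cache spacing for 1D systems (CV units).
#' @return list with `hills` (data.frame log), `cv_traj` (array
#'   n_steps x D x n_walkers of CV positions), `config`, `dt`.
#' @export
run_wtmetad <- function(system, config, n_walkers = 1, n_steps, seed,
                        dt = 0.005, grid_spacing = NULL) {
  stopifnot(inherits(system, "toy_system"), inherits(config, "metad_config"))
  set.seed(seed)
  D <- system$dim
  W <- n_walkers
  kt <- kT(system$temperature)
  m <- system$mass
  stride <- max(1L, round(config$deposition_stride / dt))
  dT_energy <- pam_constants$kB * (config$bias_factor - 1) * config$temperature
  h0 <- config$deposition_rate * config$deposition_stride
  sigma <- rep(config$sigma, length.out = D)

  use_grid <- (D == 1)
  if (use_grid) {
    lo <- min(vapply(config$walls, `[[`, numeric(1), "at"), system$x0) - 0.5
    hi <- max(vapply(config$walls, `[[`, numeric(1), "at"), system$x0) + 0.5
    if (is.null(grid_spacing)) grid_spacing <- sigma[1] / 10
    g <- seq(lo, hi, by = grid_spacing)
    Vg <- numeric(length(g))      # bias on grid
    Fg <- numeric(length(g))      # bias force on grid (-dV/ds)
    interp <- function(vals, x) {
      i <- pmin(pmax(floor((x - lo) / grid_spacing) + 1, 1), length(g) - 1L)
      fr <- (x - g[i]) / grid_spacing
      vals[i] * (1 - fr) + vals[i + 1L] * fr
    }
  }

  # hill log pre-allocation
  n_dep <- (n_steps %/% stride) * W
  hills <- data.frame(time = numeric(n_dep))
  for (d in 1:D) hills[[paste0("center.", d)]] <- numeric(n_dep)
  for (d in 1:D) hills[[paste0("sigma.", d)]] <- numeric(n_dep)
  hills$height <- numeric(n_dep)
  hills$biasf <- numeric(n_dep)
  hills$walker <- integer(n_dep)
  hill_i <- 0L
  hc <- matrix(0, n_dep, D)   # centers for direct-sum bias (D > 1)
  hh <- numeric(n_dep)

  x <- matrix(rep(system$x0, each = W), W, D)
  v <- matrix(stats::rnorm(W * D, 0, sqrt(kt / m)), W, D)
  c1 <- exp(-system$friction * dt)
  c2 <- sqrt((1 - c1^2) * kt / m)

  bias_force_at <- function(x) {
    if (use_grid) matrix(interp(Fg, x[, 1]), W, 1)
    else if (hill_i == 0L) matrix(0, W, D)
    else {
      f <- matrix(0, W, D)
      for (h in seq_len(hill_i)) {
        expo <- rep(0, W)
        for (d in 1:D) expo <- expo + (x[, d] - hc[h, d])^2 / (2 * sigma[d]^2)
        e <- hh[h] * exp(-expo)
        for (d in 1:D) f[, d] <- f[, d] + e * (x[, d] - hc[h, d]) / sigma[d]^2
      }
      f
    }
  }
  bias_value_at <- function(xrow) {
    if (use_grid) interp(Vg, xrow[1])
    else if (hill_i == 0L) 0
    else {
      expo <- 0
      for (d in 1:D) expo <- expo + (xrow[d] - hc[seq_len(hill_i), d])^2 / (2 * sigma[d]^2)
      sum(hh[seq_len(hill_i)] * exp(-expo))
    }
  }

  force_at <- function(x)
    -system$gradient(x) + wall_potential(x, config$walls)$force + bias_force_at(x)

  cv_traj <- array(0, dim = c(n_steps, D, W))
  f <- force_at(x)
  half <- 0.5 * dt
  for (step in seq_len(n_steps)) {
    v <- v + half * f / m
    x <- x + half * v
    v <- c1 * v + c2 * matrix(stats::rnorm(W * D), W, D)
    x <- x + half * v
    f <- force_at(x)
    v <- v + half * f / m
    if (!all(is.finite(x)) || max(abs(x)) > 1e6)
      stop("unstable trajectory: energy blowup detected (reduce dt)")
    cv_traj[step, , ] <- t(x)
    if (step %% stride == 0L) {
      t_now <- step * dt
      for (wk in seq_len(W)) {
        vb <- bias_value_at(x[wk, ])
        height <- h0 * exp(-vb / dT_energy)
        hill_i <- hill_i + 1L
        hills$time[hill_i] <- t_now
        for (d in 1:D) {
          hills[[paste0("center.", d)]][hill_i] <- x[wk, d]
          hills[[paste0("sigma.", d)]][hill_i] <- sigma[d]
        }
        hills$height[hill_i] <- height
        hills$biasf[hill_i] <- config$bias_factor
        hills$walker[hill_i] <- wk
        hc[hill_i, ] <- x[wk, ]
        hh[hill_i] <- height
        if (use_grid) {
          e <- height * exp(-(g - x[wk, 1])^2 / (2 * sigma[1]^2))
          Vg <- Vg + e
          Fg <- Fg + e * (g - x[wk, 1]) / sigma[1]^2
        }
      }
    }
  }
  list(hills = hills[seq_len(hill_i), , drop = FALSE], cv_traj = cv_traj,
       config = config, dt = dt)
}

#' Reconstruct the free-energy surface from a hill log
#'
#' F(s) = -gamma/(gamma - 1) * V(s), shifted so that min F = 0 on the grid
#' (the time-dependent offset C(T) is absorbed by the shift).
#'
#' @param hills hill log.
#' @param grid numeric vector (1D) or `list(x =, y =)` (2D).
#' @param bias_factor gamma; defaults to the `biasf` recorded in the log.
#' @return object of class `fes`: `grid`, `F` (vector or matrix, kJ/mol,
#'   min 0), `gamma`, `n_hills`.
#' @export
reconstruct_fes <- function(hills, grid, bias_factor = NULL) {
  if (is.null(hills) || nrow(hills) == 0) stop("empty hills log")
  gamma <- if (!is.null(bias_factor)) bias_factor else hills$biasf[1]
  pref <- gamma / (gamma - 1)
  if (is.list(grid)) {
    pts <- as.matrix(expand.grid(grid$x, grid$y))
    Fv <- -pref * bias_potential(hills, pts)
    Fm <- matrix(Fv, length(grid$x), length(grid$y))
    Fm <- Fm - min(Fm)
    out <- list(grid = grid, F = Fm, gamma = gamma, n_hills = nrow(hills))
  } else {
    Fv <- -pref * bias_potential(hills, matrix(grid, ncol = 1))
    out <- list(grid = grid, F = Fv - min(Fv), gamma = gamma,
                n_hills = nrow(hills))
  }
  structure(out, class = "fes")
}

#' @export
print.fes <- function(x, ...) {
  cat(sprintf("free-energy surface: %s grid, %d hills, gamma = %g, range %.3f kJ/mol\n",
              if (is.matrix(x$F)) paste(dim(x$F), collapse = " x ")
              else length(x$F),
              x$n_hills, x$gamma, max(x$F)))
  invisible(x)
}

#' @export
plot.fes <- function(x, ...) {
  if (is.matrix(x$F))
    graphics::contour(x$grid$x, x$grid$y, x$F, xlab = "CV1", ylab = "CV2", ...)
  else
    plot(x$grid, x$F, type = "l", xlab = "CV", ylab = "F (kJ/mol)", ...)
  invisible(x)
}

#' Time-averaged free-energy surface from a hill log
#'
#' The instantaneous estimate F(s, t) = -gamma/(gamma-1) V(s, t) fluctuates
#' around the converged surface once the bias has filled the landscape;
#' averaging the estimate over checkpoints in the tail of the run (each
#' aligned by mean shift) suppresses these fluctuations. This is the
#' recommended estimator for quantitative basin/barrier readings; the
#' instantaneous [reconstruct_fes()] is retained as the defining transform.
#'
#' @param hills hill log (time-ordered).
#' @param grid CV grid (1D numeric vector).
#' @param bias_factor gamma; defaults to the log's `biasf`.
#' @param from fraction of the log after which averaging starts.
#' @param checkpoints number of evenly spaced averaging checkpoints.
#' @return object of class `fes` (min shifted to 0) with `n_checkpoints`.
#' @export
average_fes <- function(hills, grid, bias_factor = NULL, from = 0.5,
                        checkpoints = 25) {
  stopifnot(nrow(hills) >= 2, from >= 0, from < 1, !is.list(grid))
  gamma <- if (!is.null(bias_factor)) bias_factor else hills$biasf[1]
  pref <- gamma / (gamma - 1)
  n <- nrow(hills)
  cks <- unique(round(seq(max(from * n, 1), n, length.out = checkpoints)))
  V <- numeric(length(grid))
  acc <- numeric(length(grid))
  ck_i <- 1L
  for (h in seq_len(n)) {
    V <- V + hills$height[h] *
      exp(-(grid - hills$center.1[h])^2 / (2 * hills$sigma.1[h]^2))
    if (ck_i <= length(cks) && h == cks[ck_i]) {
      Fh <- -pref * V
      acc <- acc + (Fh - mean(Fh))
      ck_i <- ck_i + 1L
    }
  }
  Fm <- acc / length(cks)
  structure(list(grid = grid, F = Fm - min(Fm), gamma = gamma,
                 n_hills = n, n_checkpoints = length(cks)),
            class = "fes")
}

#' Block-wise convergence diagnostic of the reconstructed FES
#'
#' Splits the hill log into `n_blocks` equal cumulative prefixes, rebuilds
#' the FES from each prefix, aligns it to the final FES by mean shift and
#' reports the RMS deviation per block. A converging run shows a decreasing
#' trend.
#'
#' @param hills hill log.
#' @param grid CV grid (1D vector or 2D list).
#' @param bias_factor gamma (defaults to the log's `biasf`).
#' @param n_blocks number of cumulative blocks (>= 2).
#' @return data.frame with `block`, `n_hills`, `rms_dev` (kJ/mol).
#' @export
fes_convergence <- function(hills, grid, bias_factor = NULL, n_blocks = 5) {
  stopifnot(n_blocks >= 2, nrow(hills) >= n_blocks)
  final <- reconstruct_fes(hills, grid, bias_factor)
  ends <- round(seq_len(n_blocks) / n_blocks * nrow(hills))
  rms <- numeric(n_blocks)
  for (b in seq_len(n_blocks)) {
    fb <- reconstruct_fes(hills[seq_len(ends[b]), , drop = FALSE], grid,
                          bias_factor)
    diff <- fb$F - final$F
    diff <- diff - mean(diff)
    rms[b] <- sqrt(mean(diff^2))
  }
  data.frame(block = seq_len(n_blocks), n_hills = ends, rms_dev = rms)
}

#' Write / read a hill log in PLUMED-compatible text layout
#'
#' Columns: time, one center and one sigma per CV, height, biasf.
#'
#' @param hills hill log data.frame.
#' @param path file path.
#' @return `path` (write) or the hill log data.frame (read).
#' @export
write_hills <- function(hills, path) {
  D <- length(grep("^center", names(hills)))
  cvs <- paste0("cv", seq_len(D))
  fields <- c("time", cvs, paste0("sigma_", cvs), "height", "biasf")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(fields, collapse = " ")), con)
  tab <- hills[, c("time", paste0("center.", seq_len(D)),
                   paste0("sigma.", seq_len(D)), "height", "biasf")]
  utils::write.table(format(tab, digits = 12, scientific = FALSE, trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_hills
#' @export
read_hills <- function(path) {
  header <- readLines(path, n = 1)
  fields <- strsplit(sub("^#!\\s*FIELDS\\s*", "", header), "\\s+")[[1]]
  tab <- utils::read.table(path, skip = 1, col.names = fields,
                           check.names = FALSE)
  D <- length(grep("^cv[0-9]+$", fields))
  out <- data.frame(time = tab$time)
  for (d in seq_len(D)) out[[paste0("center.", d)]] <- tab[[paste0("cv", d)]]
  for (d in seq_len(D)) out[[paste0("sigma.", d)]] <- tab[[paste0("sigma_cv", d)]]
  out$height <- tab$height
  out$biasf <- tab$biasf
  out$walker <- NA_integer_
  out
}
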