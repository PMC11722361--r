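# Well-tempered metadynamics: bias algebra, walls, engine, FES and I/O.

one_hill <- function(center = 0, sigma = 0.1, height = 1, biasf = 4) {
  data.frame(time = 1, center.1 = center, sigma.1 = sigma,
             height = height, biasf = biasf, walker = 1L)
}

test_that("the bias is zero without hills and peaks at a hill center", {
  expect_equal(bias_potential(NULL, 0.3), 0)
  expect_equal(bias_potential(one_hill(), 0), 1)
})

test_that("one sigma away the Gaussian bias is exp(-1/2)", {
  expect_equal(bias_potential(one_hill(center = 0.2, sigma = 0.1), 0.3),
               exp(-0.5), tolerance = 1e-12)
})

test_that("the bias is non-negative everywhere", {
  hills <- rbind(one_hill(0), one_hill(0.5), one_hill(-0.2, height = 0.3))
  expect_true(all(bias_potential(hills, seq(-2, 2, 0.05)) >= 0))
})

test_that("the first hill carries the untempered height omega * t_G", {
  cfg <- metad_config(deposition_rate = 1.2, deposition_stride = 10)
  h <- deposit_hill(0, cfg)
  expect_equal(h$height, 12)
})

test_that("a hill deposited where V = kB (gamma-1) T is tempered by e^-1", {
  cfg <- metad_config(deposition_rate = 1, deposition_stride = 1,
                      bias_factor = 4, temperature = 300)
  v_target <- pam_constants$kB * 3 * 300
  prior <- one_hill(center = 0, sigma = 0.1, height = v_target)
  h <- deposit_hill(0, cfg, hills = prior)
  expect_equal(h$height, exp(-1), tolerance = 1e-12)
})

test_that("hill heights are non-increasing at a repeatedly visited point", {
  cfg <- metad_config(deposition_rate = 1, deposition_stride = 1, sigma = 0.1)
  hills <- NULL
  heights <- numeric(5)
  for (i in 1:5) {
    h <- deposit_hill(0.4, cfg, hills, time = i)
    hills <- rbind(hills, h)
    heights[i] <- h$height
  }
  expect_true(all(diff(heights) < 0))
})

test_that("one-sided walls are zero inside and harmonic outside", {
  walls <- list(harmonic_wall("lower", 0.3), harmonic_wall("upper", 1.2))
  expect_equal(wall_potential(0.7, walls)$energy, 0)
  expect_equal(wall_potential(0.2, walls)$energy, 0.5 * 3500 * 0.1^2)
  expect_equal(wall_potential(1.3, walls)$energy, 17.5)
})

test_that("the wall force is continuous at the wall position", {
  walls <- list(harmonic_wall("lower", 0.3))
  eps <- 1e-9
  f_in <- wall_potential(0.3 + eps, walls)$force[1, 1]
  f_out <- wall_potential(0.3 - eps, walls)$force[1, 1]
  expect_lt(abs(f_in - f_out), 1e-4)
  # restoring direction: pushes back toward the allowed region
  expect_gt(wall_potential(0.1, walls)$force[1, 1], 0)
})

test_that("a near-zero-temperature walker relaxes into the harmonic minimum", {
  sys <- toy_system(potential = function(x) 0.5 * 50 * (x[, 1] - 0.4)^2,
                    gradient = function(x) matrix(50 * (x[, 1] - 0.4), ncol = 1),
                    temperature = 1e-6, x0 = 1.2)
  cfg <- metad_config(deposition_rate = 1e-12, deposition_stride = 10,
                      sigma = 0.1, temperature = 1e-6)
  run <- run_wtmetad(sys, cfg, n_steps = 5000, seed = 1)
  expect_equal(run$cv_traj[5000, 1, 1], 0.4, tolerance = 1e-3)
})

test_that("the same seed reproduces the hill log bit-identically", {
  sys <- analytic_double_well()
  cfg <- metad_config(deposition_rate = 1, deposition_stride = 0.5,
                      sigma = 0.1,
                      walls = list(harmonic_wall("lower", -1.5),
                                   harmonic_wall("upper", 1.5)))
  r1 <- run_wtmetad(sys, cfg, n_walkers = 2, n_steps = 2000, seed = 77)
  r2 <- run_wtmetad(sys, cfg, n_walkers = 2, n_steps = 2000, seed = 77)
  expect_identical(r1$hills, r2$hills)
  expect_identical(r1$cv_traj, r2$cv_traj)
})

test_that("the shared hill log is ordered lexicographically in (time, walker)", {
  sys <- analytic_double_well()
  cfg <- metad_config(deposition_rate = 1, deposition_stride = 0.5, sigma = 0.1,
                      walls = list(harmonic_wall("lower", -1.5),
                                   harmonic_wall("upper", 1.5)))
  run <- run_wtmetad(sys, cfg, n_walkers = 3, n_steps = 1000, seed = 5)
  h <- run$hills
  expect_false(is.unsorted(h$time))
  expect_true(all(tapply(h$walker, h$time, function(w) identical(as.integer(w), 1:3))))
})

test_that("walls confine the walkers to the allowed region", {
  sys <- analytic_double_well()
  cfg <- metad_config(deposition_rate = 1, deposition_stride = 0.5, sigma = 0.1,
                      walls = list(harmonic_wall("lower", -1.5),
                                   harmonic_wall("upper", 1.5)))
  run <- run_wtmetad(sys, cfg, n_steps = 20000, seed = 9)
  expect_lt(max(abs(run$cv_traj)), 1.7)
})

test_that("a single-hill FES is the scaled inverted Gaussian of the bias equation", {
  grid <- seq(-1, 1, by = 0.01)
  h <- one_hill(center = 0, sigma = 0.2, height = 1.5, biasf = 4)
  fes <- reconstruct_fes(h, grid)
  pref <- 4 / 3
  want <- pref * (1.5 - bias_potential(h, matrix(grid, ncol = 1)))
  expect_equal(fes$F, want - min(want), tolerance = 1e-12)
  expect_equal(min(fes$F), 0)
  expect_equal(max(fes$F) - min(fes$F), pref * 1.5, tolerance = 1e-3)
})

test_that("the FES prefactor approaches one in the standard-metadynamics limit", {
  grid <- seq(-2, 2, by = 0.05)
  h <- one_hill(center = 0, sigma = 0.2, height = 1)
  f_large <- reconstruct_fes(h, grid, bias_factor = 1e9)
  expect_equal(max(f_large$F), 1, tolerance = 1e-6)
})

test_that("identical disjoint halves of a hill log reconstruct identical surfaces", {
  set.seed(8)
  half <- data.frame(time = 1:30, center.1 = runif(30, -1, 1), sigma.1 = 0.1,
                     height = runif(30, 0.2, 1), biasf = 4, walker = 1L)
  full <- rbind(half, transform(half, time = time + 30))
  grid <- seq(-1.2, 1.2, by = 0.02)
  f1 <- reconstruct_fes(full[1:30, ], grid)
  f2 <- reconstruct_fes(full[31:60, ], grid)
  expect_equal(f1$F, f2$F, tolerance = 1e-12)
})

test_that("block deviations of a converging run trend downward", {
  sys <- analytic_double_well()
  cfg <- metad_config(deposition_rate = 0.5, deposition_stride = 0.5,
                      sigma = 0.08,
                      walls = list(harmonic_wall("lower", -1.5),
                                   harmonic_wall("upper", 1.5)))
  run <- run_wtmetad(sys, cfg, n_walkers = 2, n_steps = 60000, seed = 2)
  conv <- fes_convergence(run$hills, seq(-1.5, 1.5, 0.02), n_blocks = 5)
  expect_lt(cor(conv$block, conv$rms_dev, method = "spearman"), 0)
  expect_equal(conv$rms_dev[5], 0, tolerance = 1e-12)
})

test_that("an unconverged sliver of a run shows a large terminal deviation", {
  sys <- analytic_double_well()
  cfg <- metad_config(deposition_rate = 1, deposition_stride = 0.5, sigma = 0.08,
                      walls = list(harmonic_wall("lower", -1.5),
                                   harmonic_wall("upper", 1.5)))
  run <- run_wtmetad(sys, cfg, n_steps = 800, seed = 3)
  conv <- fes_convergence(run$hills, seq(-1.5, 1.5, 0.02), n_blocks = 4)
  expect_gt(conv$rms_dev[1], 0.2)
})

test_that("hill logs round-trip through the PLUMED text layout", {
  sys <- analytic_double_well()
  cfg <- metad_config(deposition_rate = 1, deposition_stride = 0.5, sigma = 0.1,
                      walls = list(harmonic_wall("lower", -1.5),
                                   harmonic_wall("upper", 1.5)))
  run <- run_wtmetad(sys, cfg, n_steps = 1000, seed = 4)
  f <- tempfile(fileext = ".dat")
  write_hills(run$hills, f)
  expect_match(readLines(f, n = 1), "^#! FIELDS time cv1 sigma_cv1 height biasf$")
  back <- read_hills(f)
  for (col in c("time", "center.1", "sigma.1", "height", "biasf"))
    expect_equal(back[[col]], run$hills[[col]], tolerance = 1e-9)
  grid <- seq(-1.5, 1.5, 0.05)
  expect_equal(reconstruct_fes(back, grid)$F,
               reconstruct_fes(run$hills, grid)$F, tolerance = 1e-6)
})

test_that("an unstable timestep triggers blowup detection", {
  sys <- toy_system(potential = function(x) 0.5 * 1e6 * x[, 1]^2,
                    gradient = function(x) matrix(1e6 * x[, 1], ncol = 1),
                    x0 = 1)
  cfg <- metad_config(deposition_rate = 1, deposition_stride = 10, sigma = 0.1)
  expect_error(run_wtmetad(sys, cfg, n_steps = 5000, seed = 1, dt = 0.05),
               "blowup")
})

test_that("tempering drives heights toward the well-tempered floor in visited basins", {
  sys <- analytic_double_well()
  cfg <- metad_config(deposition_rate = 0.5, deposition_stride = 0.5,
                      sigma = 0.08,
                      walls = list(harmonic_wall("lower", -1.5),
                                   harmonic_wall("upper", 1.5)))
  run <- run_wtmetad(sys, cfg, n_walkers = 2, n_steps = 60000, seed = 6)
  h <- run$hills
  early <- mean(h$height[seq_len(50)])
  late <- mean(h$height[(nrow(h) - 49):nrow(h)])
  expect_lt(late, 0.5 * early)
})
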