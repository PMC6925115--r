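test_that("the DFT stage is unitary, centered, and sane on a delta", {
  expect_equal(dft_matrix(1), matrix(1 + 0i, 1, 1))
  F <- dft_matrix(8)
  expect_lt(rel_err(F %*% Conj(t(F)), diag(8) + 0i), 1e-14)
  # centered delta -> flat magnitude 1/sqrt(n)
  d <- rep(0+0i, 8); d[5] <- 1   # index of coordinate 0
  expect_equal(Mod(as.vector(F %*% d)), rep(1 / sqrt(8), 8),
               tolerance = 1e-12)
  expect_lt(rel_err(idft_matrix(8) %*% F, diag(8) + 0i), 1e-14)
})

test_that("phase evolution maps follow exp(-i b0 l delta)", {
  b0 <- matrix(0, 4, 4)
  expect_equal(phase_evolution(b0, 3, 1e-3), matrix(1+0i, 4, 4))
  b0[2, 2] <- 2 * pi * 100            # 100 Hz off-resonance
  expect_equal(phase_evolution(b0, 0, 1e-3), matrix(1+0i, 4, 4))
  # l * delta = 2.5 ms -> phase -pi/2
  p <- phase_evolution(b0, 5, 5e-4)
  expect_equal(Arg(p[2, 2]), -pi / 2, tolerance = 1e-12)
  expect_equal(Mod(p), matrix(1, 4, 4), tolerance = 1e-12)
})

test_that("nuft_exact matches the fast DFT on Cartesian grids", {
  n <- 8
  set.seed(1)
  img <- matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)), n, n)
  x <- centered_coords(n)
  tr <- trajectory(cbind(rep(x, times = n), rep(x, each = n)),
                   rep(0, n^2), 0, n)
  s <- nuft_exact(img, tr)
  F <- dft_matrix(n)
  K <- F %*% img %*% F          # unitary 2D DFT (F symmetric)
  # documented scale: direct sum = n * unitary transform
  expect_lt(rel_err(s, n * as.vector(K)), 1e-10)
  # k = 0 sample is the plain image sum
  k0 <- which(tr$coords[, 1] == 0 & tr$coords[, 2] == 0)
  expect_equal(s[k0], sum(img), tolerance = 1e-10)
  # delta at the origin -> constant magnitude
  d <- matrix(0+0i, n, n); d[n / 2 + 1, n / 2 + 1] <- 1
  expect_equal(Mod(nuft_exact(d, tr)), rep(1, n^2), tolerance = 1e-12)
  # out-of-range coordinates rejected
  expect_error(nuft_exact(img, trajectory(cbind(3, 0), 0, 0, 8)), NA)
  bad <- trajectory(cbind(7, 0), 0, 0, 16)
  expect_error(nuft_exact(img, bad), "range")
})

test_that("segment interpolators have unit row sums and one-hot nodes", {
  traj <- make_spiral(16, 64, 0.01)
  for (scheme in c("linear", "hanning")) {
    seg <- segment_interp(traj, 4, scheme)
    expect_equal(seg$n_nodes, 5L)        # L segments -> L + 1 nodes
    expect_equal(rowSums(seg$G), rep(1, 64), tolerance = 1e-12)
  }
  # a sample exactly at node l gets a one-hot row (linear scheme)
  tr <- trajectory(cbind(c(0, 1, 2), 0), c(0, 0.005, 0.01), 0.01, 16)
  seg <- segment_interp(tr, 2, "linear")
  expect_equal(seg$G, rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
               tolerance = 1e-12)
})

test_that("segmented forward collapses exactly when b0 is zero", {
  n <- 16
  coils <- make_coil_maps(n, 3, seed = 2)
  traj <- make_spiral(n, 80, 0.01)
  img <- multi_ellipse_phantom(n, 6, 3) * exp(1i * random_phase(n, 4))
  for (L in c(0, 4)) {
    seg <- segment_interp(traj, L)
    got <- segmented_forward(img, coils, NULL, traj, seg)
    want <- exact_forward(img, coils, NULL, traj)
    expect_lt(rel_err(got, want), 1e-12)
  }
})

test_that("segmentation error decreases with more segments", {
  n <- 16
  coils <- make_coil_maps(n, 2, seed = 5)
  b0 <- make_b0_map(n, 100, seed = 6)
  traj <- make_spiral(n, 200, 0.0125)
  img <- multi_ellipse_phantom(n, 6, 7) * exp(1i * random_phase(n, 8))
  ex <- exact_forward(img, coils, b0, traj)
  errs <- sapply(c(1, 3, 7, 15), function(L)
    rel_err(segmented_forward(img, coils, b0, traj,
                              segment_interp(traj, L)), ex))
  expect_true(all(diff(errs) <= 1e-12))
  expect_lt(errs[4], 0.05 * errs[1])
})

test_that("single-pixel segmented signal approaches the analytic value", {
  n <- 16
  img <- matrix(0+0i, n, n); img[5, 9] <- 2 - 1i
  coils <- make_coil_maps(n, 1, seed = 9)
  b0 <- make_b0_map(n, 80, seed = 10)
  traj <- make_spiral(n, 100, 0.0125)
  # analytic continuous-phase signal for one source pixel
  r <- c(centered_coords(n)[5], centered_coords(n)[9])
  sens <- coils[5, 9, 1]
  want <- sens * img[5, 9] * exp(-1i * b0[5, 9] * traj$times) *
    exp(-2i * pi * (traj$coords[, 1] * r[1] + traj$coords[, 2] * r[2]) / n)
  expect_lt(rel_err(exact_forward(img, coils, b0, traj), want), 1e-12)
  got <- segmented_forward(img, coils, b0, traj, segment_interp(traj, 8))
  # linear interpolation of exp(i phi) between nodes: error < (dphi)^2 / 8
  dphi <- abs(b0[5, 9]) * traj$duration / 8
  expect_lt(max(Mod(got - want)), Mod(img[5, 9]) * Mod(sens) * dphi^2 / 8)
})

test_that("spiral design hits its contract", {
  n <- 32
  traj <- make_spiral(n, 400, 0.0125)
  expect_equal(traj$coords[1, ], c(0, 0))
  expect_equal(traj$times[1], 0)
  radii <- sqrt(rowSums(traj$coords^2))
  expect_lt(abs(max(radii) - n / 2), 1)
  expect_true(!is.unsorted(traj$times))
  su <- spiral_undersampling(traj)
  expect_equal(su$n_samples, 400)
  expect_gt(su$undersampling, 0)
  expect_lte(su$cells_touched, su$needed)
})

test_that("poisson masks track the target acceleration and sample DC", {
  n <- 64
  expect_equal(poisson_mask(n, 1), matrix(1L, n, n))
  fr <- sapply(1:6, function(s) mean(poisson_mask(n, 2, s)))
  expect_true(all(fr > 0.21 & fr < 0.29))
  for (acc in c(4, 8)) {
    f <- mean(sapply(1:3, function(s) mean(poisson_mask(n, acc, s))))
    expect_lt(abs(f * acc^2 - 1), 0.15)
  }
  m <- poisson_mask(n, 4, seed = 3)
  expect_equal(m[n / 2 + 1, n / 2 + 1], 1L)       # DC always sampled
  expect_identical(m, poisson_mask(n, 4, seed = 3))
  # masks are readable back from the plain-text export
  path <- withr::local_tempfile(fileext = ".txt")
  write_mask(m, path)
  expect_equal(read_mask(path), m, ignore_attr = TRUE)
})

test_that("synthetic coil and B0 maps satisfy their invariants", {
  n <- 24
  cm <- make_coil_maps(n, 8, seed = 4)
  sos <- apply(Mod(cm)^2, c(1, 2), sum)
  expect_true(all(sos > 0))
  expect_identical(cm, make_coil_maps(n, 8, seed = 4))
  # single channel degenerates to a near-uniform center profile
  c1 <- Mod(make_coil_maps(n, 1, seed = 4)[, , 1])
  expect_gt(min(c1) / max(c1), 0.5)
  b0 <- make_b0_map(n, 120, seed = 5)
  expect_lte(max(abs(b0)), 2 * pi * 120 + 1e-9)
  expect_equal(max(abs(b0)), 2 * pi * 120, tolerance = 1e-9)
  expect_equal(make_b0_map(n, 0), matrix(0, n, n))
})

test_that("simulated signals are linear in the image", {
  n <- 16
  fm <- forward_model(make_coil_maps(n, 3, seed = 1),
                      traj = make_spiral(n, 100, 0.0125),
                      b0 = make_b0_map(n, 60, seed = 2), n_seg = 3)
  set.seed(3)
  i1 <- matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)), n, n)
  i2 <- matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)), n, n)
  a <- 1.5 - 0.5i
  lhs <- simulate_signal(fm, i1 * a + i2)
  rhs <- a * simulate_signal(fm, i1) + simulate_signal(fm, i2)
  expect_lt(rel_err(lhs, rhs), 1e-12)
})

test_that("zero-filled adjoint inverts a fully sampled single-coil model", {
  n <- 16
  fm <- flat_coil_fm(n)
  img <- multi_ellipse_phantom(n, 5, 11) * exp(1i * random_phase(n, 12))
  rec <- zero_filled_adjoint(fm, simulate_signal(fm, img))
  expect_lt(rel_err(rec, img), 1e-6)
})
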