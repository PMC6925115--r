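test_that("neighbor gathering matches an exhaustive distance sort", {
  n <- 8
  set.seed(4)
  coords <- cbind(runif(16, -4, 4), runif(16, -4, 4))
  traj <- trajectory(coords, rep(0, 16), 0, n)
  nt <- gather_neighbors(traj, n, 5)
  x <- centered_coords(n)
  gx <- rep(x, times = n); gy <- rep(x, each = n)
  for (r in sample(n * n, 12)) {
    d <- sqrt((coords[, 1] - gx[r])^2 + (coords[, 2] - gy[r])^2)
    o <- order(d)[1:5]
    expect_equal(nt$idx[r, ], o)
    expect_equal(nt$dist[r, ], d[o], tolerance = 1e-12)
    expect_true(!is.unsorted(nt$dist[r, ]))
  }
  # offsets point from the grid location to the sample
  expect_equal(nt$offsets[3, 2, 1], coords[nt$idx[3, 2], 1] - gx[3],
               tolerance = 1e-12)
})

test_that("neighbor gathering handles degenerate trajectories", {
  n <- 4
  one <- trajectory(cbind(0.3, -0.2), 0, 0, n)
  nt <- gather_neighbors(one, n, 1)
  expect_true(all(nt$idx == 1L))
  # grid-on-grid: each location is its own nearest neighbor at distance 0
  x <- centered_coords(n)
  grid <- trajectory(cbind(rep(x, times = n), rep(x, each = n)),
                     rep(0, n^2), 0, n)
  ng <- gather_neighbors(grid, n, 1)
  expect_equal(ng$idx[, 1], seq_len(n^2))
  expect_equal(max(ng$dist), 0)
  expect_error(gather_neighbors(grid, n, n^2 + 1))
})

test_that("assemble_S is the pure gather it claims to be", {
  n <- 8
  traj <- make_spiral(n, 30, 0.01)
  nt <- gather_neighbors(traj, n, 3)
  # constant signal -> all-ones tensor
  S1 <- assemble_S(rep(1+0i, 30), nt)
  expect_true(all(unclass(S1) == 1+0i))
  # one-hot signal lights up exactly the table entries that reference it
  oh <- rep(0+0i, 30); oh[7] <- 1
  S2 <- unclass(assemble_S(oh, nt))
  dim(S2) <- c(n * n, 3)
  expect_identical(S2 != 0, nt$idx == 7L)
  # random multi-channel instance vs index-by-index loop
  set.seed(5)
  sig <- matrix(complex(real = rnorm(60), imaginary = rnorm(60)), 30, 2)
  S3 <- unclass(ct_perm(assemble_S(sig, nt), c("kRO", "kPE", "nb", "ch")))
  for (r in sample(n * n, 10)) for (nb in 1:3) for (c in 1:2) {
    i <- (r - 1) %% n + 1; j <- (r - 1) %/% n + 1
    expect_identical(S3[i, j, nb, c], sig[nt$idx[r, nb], c])
  }
})

test_that("k_plus_i_apply reduces to a plain inverse FT on exact gridding", {
  n <- 8
  x <- centered_coords(n)
  # fully sampled Cartesian single coil, trajectory = the grid itself
  traj <- trajectory(cbind(rep(x, times = n), rep(x, each = n)),
                     rep(0, n^2), 0, n)
  nt <- gather_neighbors(traj, n, 2)
  set.seed(6)
  k <- matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)), n, n)
  S <- assemble_S(as.vector(k), nt)
  # H one-hot on the exact on-grid (first) neighbor, M identically 1
  H <- array(0+0i, c(n, n, 2, 1, 1)); H[, , 1, 1, 1] <- 1
  M <- array(1+0i, c(n, n, 1))
  got <- k_plus_i_apply(S, H, M)
  iF <- idft_matrix(n)
  expect_lt(rel_err(got, iF %*% k %*% iF), 1e-12)
  # zero H -> zero image
  expect_equal(k_plus_i_apply(S, H * 0, M), matrix(0+0i, n, n))
})

test_that("k_plus_i_apply equals the column-assembled linear operator", {
  net <- toy_spiral_net(n = 8, n_ch = 2, n_ts = 2, n_n = 3, seed = 7)
  hm <- network_HM(net)
  nt <- net$nt
  m <- net$traj$n_samples
  # assemble the operator column by column from unit signals
  A <- matrix(0+0i, 64, m * 2)
  e <- matrix(0+0i, m, 2)
  for (k in seq_len(m * 2)) {
    e[k] <- 1
    A[, k] <- as.vector(k_plus_i_apply(assemble_S(e, nt), hm$H, hm$M))
    e[k] <- 0
  }
  set.seed(8)
  sig <- matrix(complex(real = rnorm(m * 2), imaginary = rnorm(m * 2)), m, 2)
  direct <- k_plus_i_apply(assemble_S(sig, nt), hm$H, hm$M)
  expect_lt(rel_err(direct, matrix(A %*% as.vector(sig), 8, 8)), 1e-12)
  # and the staged network computes the same map
  vianet <- network_forward(net, sig)
  expect_lt(rel_err(ct_perm(vianet, c("RO", "PE")), direct), 1e-12)
})

test_that("every topology equals its explicitly assembled matrix", {
  traj <- make_spiral(8, 40, 0.01)
  for (id in c("fc2d", "two_by_1d", "pi_kernel", "scc", "gcc",
               "knuft_mln", "k_plus_i_mln")) {
    ts <- topology_spec(id, n = 8, n_ch = 2, n_ts = 2, n_n = 3, acc = 2,
                        n_traj = 40, seed = 11)
    net <- if (id %in% c("k_plus_i_mln", "knuft_mln"))
      build_topology(ts, traj = traj) else build_topology(ts)
    A <- assemble_operator(net)
    din <- net$input$dims
    set.seed(12)
    v <- array(complex(real = rnorm(prod(din)),
                       imaginary = rnorm(prod(din))), din)
    out <- as.vector(unclass(network_forward(net, v)))
    expect_lt(rel_err(out, as.vector(A %*% as.vector(v))), 1e-10)
    expect_equal(network_params(net), count_topology_params(net$topology))
  }
  expect_error(build_topology(topology_spec("general", n = 8)),
               "unbuildable")
})

test_that("gcc applies its location-specific compression mid-pipeline", {
  ts <- topology_spec("gcc", n = 8, n_ch = 3, n_n = 2, acc = 2,
                      n_virt = 2, seed = 13)
  net <- build_topology(ts)
  names <- vapply(net$stages, function(s)
    if (is.null(s$name)) "" else s$name, character(1))
  i <- which(names == "gcc")
  expect_gt(i, 1)
  sp <- net$stages[[i]]$spec
  expect_equal(unname(sp$roles[c("RO", "ch")]),
               c("independent", "fully_connected"))
  expect_equal(dim(net$stages[[i]]$w), c(3L, 2L, 8L))  # ch_in, ch_out, RO
  # surrounded by the fixed Fourier stages
  expect_false(net$stages[[i - 1]]$trainable)
  expect_false(net$stages[[i + 1]]$trainable)
})

test_that("with one segment the two spiral topologies coincide", {
  traj <- make_spiral(8, 40, 0.01)
  t1 <- topology_spec("k_plus_i_mln", n = 8, n_ch = 2, n_ts = 1, n_n = 3,
                      seed = 3)
  t2 <- topology_spec("knuft_mln", n = 8, n_ch = 2, n_ts = 1, n_n = 3,
                      seed = 3)
  expect_equal(count_topology_params(t1), count_topology_params(t2))
  n1 <- build_topology(t1, traj = traj)
  n2 <- build_topology(t2, traj = traj)
  set.seed(14)
  sig <- array(complex(real = rnorm(80), imaginary = rnorm(80)), c(40, 2))
  expect_identical(unclass(network_forward(n1, sig)),
                   unclass(network_forward(n2, sig)))
})

test_that("parameter counts reproduce the published table rows", {
  dims <- list(n = 128, n_ch = 13, n_ts = 7, n_n = 12, acc = 4)
  expect_equal(count_topology_params(
    topology_spec("automap", n = dims$n, n_ch = dims$n_ch, acc = dims$acc)),
    1409286144)
  expect_equal(count_topology_params(
    topology_spec("general", n = dims$n, n_ch = dims$n_ch, acc = dims$acc)),
    1744830464)
  expect_equal(count_topology_params(
    topology_spec("k_plus_i_mln", n = dims$n, n_ch = dims$n_ch,
                  n_ts = dims$n_ts, n_n = dims$n_n)),
    36012032)
  expect_equal(count_topology_params(
    topology_spec("k_plus_i_mln", n = dims$n, n_ch = dims$n_ch,
                  n_ts = 1, n_n = dims$n_n)),
    5111808)
})

test_that("counts agree with built networks over randomized small dims", {
  set.seed(15)
  for (rep in 1:4) {
    n <- sample(c(4, 8), 1)
    ts <- topology_spec(sample(c("two_by_1d", "pi_kernel", "k_plus_i_mln",
                                 "knuft_mln"), 1),
                        n = n, n_ch = sample(1:3, 1),
                        n_ts = sample(1:3, 1), n_n = sample(1:3, 1),
                        seed = rep)
    net <- build_topology(ts, traj = make_spiral(n, 6 * n, 0.01))
    expect_equal(network_params(net), count_topology_params(net$topology))
  }
})

test_that("weight tensors round-trip through the JSON container", {
  w <- build_sfc(sfc_spec(c(a = 3, b = 2), c(a = "fully_connected",
                                             b = "independent"), seed = 5))
  path <- withr::local_tempfile(fileext = ".json")
  write_ctensor(w, path)
  w2 <- read_ctensor(path)
  expect_equal(unclass(w2), unclass(w), tolerance = 1e-15, ignore_attr = TRUE)
  expect_identical(ct_axes(w2), ct_axes(w))
})

test_that("trained networks round-trip through the JSON container", {
  net <- toy_spiral_net(n = 8, n_ch = 2, n_ts = 2, n_n = 2, seed = 17)
  path <- withr::local_tempfile(fileext = ".json")
  mln_save(net, path)
  net2 <- mln_load(path)
  # a network without a trajectory round-trips too
  p2 <- withr::local_tempfile(fileext = ".json")
  mln_save(build_topology(topology_spec("two_by_1d", n = 8, seed = 2)), p2)
  expect_s3_class(mln_load(p2), "mln_net")
  set.seed(18)
  m <- net$traj$n_samples
  sig <- array(complex(real = rnorm(m * 2), imaginary = rnorm(m * 2)),
               c(m, 2))
  expect_equal(unclass(network_forward(net2, sig)),
               unclass(network_forward(net, sig)), tolerance = 1e-12)
})
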