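test_that("weight shapes follow the per-axis role rule", {
  # single fully connected axis: plain matrix
  sp <- sfc_spec(c(x = 5), c(x = "fully_connected"))
  expect_equal(dim(build_sfc(sp)), c(5L, 5L))

  # shared axis absent, independent axis appended
  sp <- sfc_spec(c(RO = 4, PE = 4, ch = 2),
                 c(RO = "shared", PE = "fully_connected",
                   ch = "independent"))
  w <- build_sfc(sp)
  expect_equal(dim(w), c(4L, 4L, 2L))
  expect_equal(ct_axes(w), c("PE_in", "PE_out", "ch"))

  # joint contraction of several fully connected axes
  sp <- sfc_spec(c(a = 3, b = 2), c(a = "fully_connected",
                                    b = "fully_connected"),
                 out_lengths = c(a = 1, b = 4))
  expect_equal(dim(build_sfc(sp)), c(3L, 2L, 1L, 4L))
})

test_that("degenerate and inconsistent specs are rejected", {
  expect_error(sfc_spec(c(a = 3, b = 2), c(a = "shared", b = "independent")),
               "fully connected")
  expect_error(sfc_spec(c(a = 3), c(a = "fully_connected"),
                        out_lengths = c(b = 2)))
  expect_error(sfc_spec(c(a = 3, b = 2),
                        c(a = "fully_connected", b = "shared"),
                        out_lengths = c(b = 2)),
               "non-fully-connected")
  expect_error(sfc_spec(c(a = 3), c(b = "fully_connected")))
  # shape mismatch at apply time
  sp <- sfc_spec(c(a = 3), c(a = "fully_connected"))
  w <- build_sfc(sp)
  expect_error(sfc_apply(ctensor(1:4 + 0i, "a"), w, sp), "lengths")
  expect_error(sfc_apply(ctensor(matrix(1:6 + 0i, 2), c("p", "q")), w, sp),
               "missing")
})

test_that("identity weights reproduce the input", {
  sp <- sfc_spec(c(RO = 4, PE = 6), c(RO = "fully_connected",
                                      PE = "shared"))
  w <- ctensor(diag(4) + 0i, c("RO_in", "RO_out"))
  x <- rand_ct(c(4, 6), c("RO", "PE"), seed = 2)
  y <- sfc_apply(x, w, sp)
  expect_lt(rel_err(ct_perm(y, c("RO", "PE")), x), 1e-14)
})

test_that("two 1D-FC layers with DFT weights equal the 2D DFT", {
  n <- 4
  sp1 <- sfc_spec(c(kRO = n, kPE = n),
                  c(kRO = "fully_connected", kPE = "shared"),
                  out_names = c(kRO = "RO"))
  sp2 <- sfc_spec(c(RO = n, kPE = n),
                  c(kPE = "fully_connected", RO = "shared"),
                  out_names = c(kPE = "PE"))
  F <- dft_matrix(n)
  w1 <- ctensor(F, c("kRO_in", "kRO_out"))
  w2 <- ctensor(F, c("kPE_in", "kPE_out"))
  x <- rand_ct(c(n, n), c("kRO", "kPE"), seed = 3)
  y <- ct_perm(sfc_apply(sfc_apply(x, w1, sp1), w2, sp2), c("RO", "PE"))
  # brute-force centered 2D DFT sum
  k <- centered_coords(n)
  bf <- matrix(0+0i, n, n)
  for (a in 1:n) for (b in 1:n)
    bf[a, b] <- sum(unclass(x) *
                      exp(-2i * pi * (k[a] * outer(k, rep(1, n)) +
                                      k[b] * outer(rep(1, n), k)) / n)) / n
  expect_lt(rel_err(y, bf), 1e-12)
})

test_that("a 2x1D network needs 2 N^2 complex weights against N^4 for 2D-FC", {
  n <- 8
  t1 <- topology_spec("two_by_1d", n = n)
  t2 <- topology_spec("fc2d", n = n)
  expect_equal(count_topology_params(t1), 2 * 2 * n^2)
  expect_equal(count_topology_params(t2), 2 * n^4)
})

test_that("sfc_apply equals explicit loop summation on randomized specs", {
  cases <- list(
    list(axes = c(a = 4, b = 3), roles = c(a = "fully_connected",
                                           b = "shared"),
         out = c(a = 2)),
    list(axes = c(a = 3, b = 3, c = 2),
         roles = c(a = "independent", b = "fully_connected", c = "shared"),
         out = c(b = 3)),
    list(axes = c(a = 2, b = 2, c = 3, d = 2),
         roles = c(a = "fully_connected", b = "independent",
                   c = "fully_connected", d = "shared"),
         out = c(a = 2, c = 1)))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    sp <- sfc_spec(cs$axes, cs$roles, out_lengths = cs$out, seed = i)
    w <- build_sfc(sp)
    x <- rand_ct(unname(cs$axes), names(cs$axes), seed = 10 + i)
    got <- sfc_apply(x, w, sp)
    want <- sfc_apply_loop(x, w, sp)
    expect_lt(rel_err(ct_perm(got, ct_axes(want)), want), 1e-12)
    expect_equal(param_count(sp), 2 * length(w))
  }
})

test_that("sfc_apply is linear and equivariant along shared axes", {
  sp <- sfc_spec(c(RO = 5, PE = 4, ch = 2),
                 c(RO = "shared", PE = "fully_connected",
                   ch = "independent"), seed = 4)
  w <- build_sfc(sp)
  x <- rand_ct(c(5, 4, 2), c("RO", "PE", "ch"), seed = 5)
  y <- rand_ct(c(5, 4, 2), c("RO", "PE", "ch"), seed = 6)
  a <- 0.7 - 1.2i; b <- -0.3 + 0.4i
  lhs <- sfc_apply(ctensor(a * unclass(x) + b * unclass(y),
                           c("RO", "PE", "ch")), w, sp)
  rhs <- a * unclass(sfc_apply(x, w, sp)) + b * unclass(sfc_apply(y, w, sp))
  expect_lt(rel_err(lhs, rhs), 1e-13)

  perm <- c(3, 1, 5, 2, 4)
  xp <- ctensor(unclass(x)[perm, , ], c("RO", "PE", "ch"))
  yp <- sfc_apply(xp, w, sp)
  y0 <- sfc_apply(x, w, sp)
  expect_lt(rel_err(yp, unclass(y0)[perm, , ]), 1e-14)
})

test_that("initialization is deterministic per seed and scaled by fan-in", {
  sp1 <- sfc_spec(c(a = 64), c(a = "fully_connected"), seed = 9)
  expect_identical(unclass(build_sfc(sp1)), unclass(build_sfc(sp1)))
  sp2 <- sfc_spec(c(a = 64), c(a = "fully_connected"), seed = 10)
  expect_false(identical(unclass(build_sfc(sp1)), unclass(build_sfc(sp2))))
  w <- build_sfc(sp1)
  expect_lt(abs(stats::sd(Re(w)) - sqrt(1 / 64)), 0.2 * sqrt(1 / 64))
})

test_that("parameter counts follow the FC and convolution formulas", {
  # M x N x F1 -> M x N x F2, all axes fully connected
  M <- 3; N <- 4; F1 <- 2; F2 <- 5
  sp <- sfc_spec(c(m = M, n = N, f = F1),
                 c(m = "fully_connected", n = "fully_connected",
                   f = "fully_connected"),
                 out_lengths = c(f = F2))
  expect_equal(param_count(sp), 2 * M^2 * N^2 * F1 * F2)
  expect_equal(conv_param_count(3, 5, 2, 7), 2 * 3 * 5 * 2 * 7)
  # degenerate singleton
  sp1 <- sfc_spec(c(a = 1), c(a = "fully_connected"))
  expect_equal(param_count(sp1), 2)
})

test_that("split-real gradients match finite differences", {
  sp <- sfc_spec(c(RO = 3, PE = 4, ch = 2),
                 c(RO = "independent", PE = "fully_connected",
                   ch = "fully_connected"),
                 out_lengths = c(PE = 2, ch = 3), seed = 7)
  w <- build_sfc(sp)
  x <- rand_ct(c(3, 4, 2), c("RO", "PE", "ch"), seed = 8)
  tgt <- rand_ct(c(3, 2, 3), c("RO", "PE", "ch"), seed = 9)
  lossfun <- function(wv) {
    y <- sfc_apply(x, ctensor(wv, ct_axes(w)), sp)
    l1_loss(ct_perm(y, ct_axes(tgt)), tgt)
  }
  y0 <- sfc_apply(x, w, sp)
  r <- unclass(ct_perm(y0, ct_axes(tgt))) - unclass(tgt)
  g0 <- complex(real = sign(Re(r)), imaginary = sign(Im(r))) / length(r)
  dim(g0) <- dim(tgt)
  bk <- mlnrecon:::sfc_backward(x, w, sp, ctensor(g0, ct_axes(tgt)))
  eps <- 1e-6
  set.seed(11)
  for (k in sample(length(w), 6)) {
    for (part in list(1, 1i)) {
      wv <- unclass(w)
      wv[k] <- wv[k] + part * eps
      fd <- (lossfun(wv) - lossfun(unclass(w))) / eps
      an <- if (identical(part, 1)) Re(unclass(bk$gw)[k])
            else Im(unclass(bk$gw)[k])
      expect_lt(abs(fd - an), 1e-5 * max(1, abs(an)))
    }
  }
})

test_that("layer specs round-trip through the YAML config dialect", {
  sp <- sfc_spec(c(kRO = 8, kPE = 8, nb = 3, ch = 2),
                 c(kRO = "independent", kPE = "independent",
                   nb = "fully_connected", ch = "fully_connected"),
                 out_lengths = c(nb = 1, ch = 4),
                 out_names = c(ch = "ts"), seed = 42)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sfc_spec(sp, path)
  sp2 <- read_sfc_spec(path)
  expect_equal(sp2$axes, sp$axes)
  expect_equal(sp2$roles, sp$roles)
  expect_equal(sp2$out_lengths, sp$out_lengths)
  expect_equal(sp2$out_names, sp$out_names)
  expect_identical(unclass(build_sfc(sp2)), unclass(build_sfc(sp)))
})
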