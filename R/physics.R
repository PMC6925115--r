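#' Centered pixel / k-space coordinates
#'
#' The package uses one coordinate convention throughout: image pixel
#' indices and Cartesian k-space indices run over `{-n/2, ..., n/2 - 1}`
#' (DC-centered), and non-Cartesian k-space coordinates are continuous in
#' cycles per field-of-view within `[-n/2, n/2]`.
#'
#' @param n matrix size.
#' @return integer vector of length `n`.
#' @export
centered_coords <- function(n) seq.int(-floor(n / 2), length.out = n)

#' Unitary DC-centered DFT matrix
#'
#' `F[m, r] = exp(-2i*pi*k_m*x_r/n) / sqrt(n)` with `k`, `x` centered, so
#' `F %*% Conj(t(F))` is the identity. `idft_matrix` is its inverse
#' (`Conj(F)` for this symmetric convention); it is the fixed, non-trained
#' Fourier stage of every reconstruction network in the package.
#'
#' @param n transform length, `n >= 1`.
#' @return complex `n x n` matrix.
#' @export
dft_matrix <- function(n) {
  stopifnot(n >= 1)
  k <- centered_coords(n)
  exp(-2i * pi * outer(k, k) / n) / sqrt(n)
}

#' @rdname dft_matrix
#' @export
idft_matrix <- function(n) Conj(dft_matrix(n))

#' Non-Cartesian k-space trajectory
#'
#' @param coords numeric matrix `[n_samples, 2]` of (kx, ky) in cycles per
#'   field-of-view; `|k| <= n/2` for target matrix size `n`.
#' @param times per-sample acquisition time in seconds, non-decreasing
#'   within `[0, duration]`.
#' @param duration total acquisition duration T in seconds.
#' @param n target matrix size.
#' @return an object of class `mln_traj`.
#' @export
trajectory <- function(coords, times, duration, n) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2, length(times) == nrow(coords))
  if (any(abs(coords) > n / 2 + 1e-9))
    stop("trajectory coordinates exceed +-n/2 for matrix size ", n)
  if (is.unsorted(times) || any(times < 0) || any(times > duration + 1e-12))
    stop("times must be non-decreasing within [0, duration]")
  structure(list(coords = coords, times = as.numeric(times),
                 duration = as.numeric(duration), n = as.integer(n),
                 n_samples = nrow(coords)),
            class = "mln_traj")
}

#' @export
print.mln_traj <- function(x, ...) {
  cat(sprintf("<mln_traj> %d samples, T = %.3g ms, matrix %d\n",
              x$n_samples, 1000 * x$duration, x$n))
  invisible(x)
}

# dense NUFT matrix E[m, r] = exp(-2i pi k_m . x_r / n), image vectorized
# column-major over the centered n x n grid (first axis fastest)
nuft_matrix <- function(traj, n = traj$n) {
  x <- centered_coords(n)
  xr <- rep(x, times = n)
  yr <- rep(x, each = n)
  exp(-2i * pi * (outer(traj$coords[, 1], xr) +
                  outer(traj$coords[, 2], yr)) / n)
}

#' Exact (slow) non-uniform Fourier transform
#'
#' Direct-summation oracle: `signal[m] = sum_r img(r) exp(-2i*pi*k_m.r/n)`.
#' `O(n^2 * n_samples)` — this is the reference all fast paths and trained
#' operators are judged against, never a production transform. On Cartesian
#' integer trajectories it equals `n` times the unitary 2D DFT.
#'
#' @param img complex `n x n` matrix (or `ctensor`).
#' @param traj an [trajectory()].
#' @return complex vector of length `traj$n_samples`.
#' @export
nuft_exact <- function(img, traj) {
  img <- unclass(img)
  n <- nrow(img)
  stopifnot(ncol(img) == n)
  if (any(abs(traj$coords) > n / 2 + 1e-9))
    stop("trajectory coordinate out of range for this image size")
  as.vector(nuft_matrix(traj, n) %*% as.vector(img))
}

#' Phase-evolution map for one time segment
#'
#' `P_l(r) = exp(-1i * b0(r) * l * delta)`: the per-pixel off-resonance
#' phase accrued after `l` segment spacings. The segmented image is
#' `D_l = I * P_l` (Hadamard product), formed by the caller.
#'
#' @param b0 `n x n` off-resonance map in rad/s.
#' @param l segment index in `0:L`.
#' @param delta segment spacing in seconds (`T / L`).
#' @return complex `n x n` unit-modulus map.
#' @export
phase_evolution <- function(b0, l, delta) exp(-1i * unclass(b0) * l * delta)

#' Time-segment interpolator
#'
#' For `L` segments the acquisition window `[0, T]` is spanned by `L + 1`
#' equally spaced nodes `l * delta`, `delta = T/L`; `G` holds one row per
#' trajectory sample with interpolation coefficients over the nodes. Rows
#' sum to 1 and are one-hot at exact node times. `L = 0` (a single node) is
#' the degenerate no-segmentation case with `G` identically 1.
#'
#' @param traj an [trajectory()].
#' @param L segment count (`>= 0`); node count is `L + 1`.
#' @param scheme `"linear"` (default) or `"hanning"` (raised-cosine window,
#'   renormalized to unit row sum).
#' @return object of class `mln_seginterp` with fields `G`
#'   (`n_samples x (L+1)`), `L`, `n_nodes`, `delta`, `scheme`.
#' @export
segment_interp <- function(traj, L, scheme = c("linear", "hanning")) {
  scheme <- match.arg(scheme)
  stopifnot(L >= 0)
  m <- traj$n_samples
  if (L == 0) {
    G <- matrix(1, m, 1)
    delta <- traj$duration
  } else {
    delta <- traj$duration / L
    u <- traj$times / delta            # node units, in [0, L]
    G <- matrix(0, m, L + 1)
    if (scheme == "linear") {
      lo <- pmin(floor(u), L - 1)
      f <- u - lo
      G[cbind(seq_len(m), lo + 1)] <- 1 - f
      G[cbind(seq_len(m), lo + 2)] <- f
    } else {
      for (l in 0:L) {
        d <- abs(u - l)
        G[, l + 1] <- ifelse(d < 1, 0.5 * (1 + cos(pi * d)), 0)
      }
      G <- G / rowSums(G)
    }
  }
  structure(list(G = G, L = L, n_nodes = ncol(G), delta = delta,
                 scheme = scheme), class = "mln_seginterp")
}

#' Time-segmented forward signal model
#'
#' Approximates the continuous off-resonance signal by interpolating
#' between `L + 1` segment phase maps:
#' `s_hat = sum_j G[, j] * F_u(I * P_j)` per receive channel, with the
#' image weighted by that channel's sensitivity. With `b0 = 0` (rows of `G`
#' summing to 1) this reduces exactly to the coil-weighted [nuft_exact()].
#'
#' @param img complex `n x n` image.
#' @param coils complex `n x n x n_ch` sensitivity array.
#' @param b0 `n x n` off-resonance map in rad/s (or `NULL` for 0).
#' @param traj an [trajectory()].
#' @param seg an [segment_interp()] built for `traj`.
#' @return complex matrix `[n_samples, n_ch]`.
#' @export
segmented_forward <- function(img, coils, b0, traj, seg) {
  img <- unclass(img)
  n <- nrow(img)
  stopifnot(dim(coils)[1] == n, dim(coils)[2] == n)
  if (is.null(b0)) b0 <- matrix(0, n, n)
  stopifnot(all(dim(b0) == c(n, n)))
  E <- nuft_matrix(traj, n)
  n_ch <- dim(coils)[3]
  out <- matrix(0+0i, traj$n_samples, n_ch)
  for (j in seq_len(seg$n_nodes)) {
    P <- phase_evolution(b0, j - 1, seg$delta)
    D <- matrix(as.vector(img * P), n * n, 1)
    X <- matrix(0+0i, n * n, n_ch)
    for (c in seq_len(n_ch)) X[, c] <- D * as.vector(coils[, , c])
    out <- out + seg$G[, j] * (E %*% X)
  }
  out
}

#' Exact continuous-phase signal (oracle)
#'
#' `s_c(t_m) = sum_r coil_c(r) img(r) exp(-1i b0(r) t_m)
#' exp(-2i*pi*k_m.r/n)` by direct summation; the reference against which
#' the time-segmentation error of [segmented_forward()] is measured.
#'
#' @inheritParams segmented_forward
#' @return complex matrix `[n_samples, n_ch]`.
#' @export
exact_forward <- function(img, coils, b0, traj) {
  img <- unclass(img)
  n <- nrow(img)
  if (is.null(b0)) b0 <- matrix(0, n, n)
  E <- nuft_matrix(traj, n) * exp(-1i * outer(traj$times, as.vector(b0)))
  n_ch <- dim(coils)[3]
  out <- matrix(0+0i, traj$n_samples, n_ch)
  for (c in seq_len(n_ch))
    out[, c] <- E %*% (as.vector(img) * as.vector(coils[, , c]))
  out
}

#' Variable-density Archimedean spiral trajectory
#'
#' A single-shot Archimedean-type spiral from k = 0 out to `|k| = n/2`,
#' with radial sample density proportional to `radius^(-vd_exponent)`
#' (denser near the k-space center for `vd_exponent > 0`) and uniform
#' dwell time `duration / n_samples`. This is a generic stand-in design:
#' the defaults reach a regime of ~3.2-fold undersampling over a 12.5 ms
#' readout without reproducing any scanner-specific gradient design.
#'
#' @param n target matrix size.
#' @param n_samples number of acquired points (`>= n`).
#' @param duration readout duration in seconds.
#' @param vd_exponent density exponent in `[0, 1)`; 0 is uniform radial
#'   density.
#' @param n_turns number of revolutions; default `max(2, round(n / 6.4))`
#'   (about 3.2-fold radial undersampling relative to the `n/2` turns of a
#'   fully sampled spiral).
#' @return an [trajectory()].
#' @export
make_spiral <- function(n, n_samples, duration = 0.0125, vd_exponent = 0.5,
                        n_turns = max(2, round(n / 6.4))) {
  stopifnot(n_samples >= n, vd_exponent >= 0, vd_exponent < 1)
  tau <- seq(0, 1, length.out = n_samples)
  r <- (n / 2) * tau^(1 / (1 - vd_exponent))
  theta <- 2 * pi * n_turns * (r / (n / 2))
  coords <- cbind(r * cos(theta), r * sin(theta))
  # guard the corner cases of floating-point radius overshoot
  coords <- pmin(pmax(coords, -n / 2), n / 2)
  times <- (seq_len(n_samples) - 1) * duration / n_samples
  trajectory(coords, times, duration, n)
}

#' Effective undersampling of a trajectory
#'
#' Ratio of Nyquist samples needed (integer grid cells within the sampled
#' k-space disk of radius `n/2`) to the number of acquired samples; also
#' reports how many distinct Nyquist cells the trajectory touches.
#'
#' @param traj an [trajectory()]. @param n matrix size.
#' @return list with `needed`, `n_samples`, `undersampling`,
#'   `cells_touched`.
#' @export
spiral_undersampling <- function(traj, n = traj$n) {
  g <- expand.grid(kx = centered_coords(n), ky = centered_coords(n))
  needed <- sum(g$kx^2 + g$ky^2 <= (n / 2)^2)
  cells <- unique(paste(pmax(pmin(round(traj$coords[, 1]), n / 2 - 1), -n / 2),
                        pmax(pmin(round(traj$coords[, 2]), n / 2 - 1), -n / 2)))
  list(needed = needed, n_samples = traj$n_samples,
       undersampling = needed / traj$n_samples,
       cells_touched = length(cells))
}

# exclusion-radius calibration: continuous random sequential adsorption
# saturates near 0.70 accepted darts per r^2 of area, so r = 0.84 * acc
# puts the sampled fraction near 1/acc^2 (verified in the test suite).
.poisson_radius_coef <- 0.84

#' Poisson-disk undersampling mask
#'
#' Dart-throwing (random sequential adsorption) with continuous candidate
#' coordinates and exclusion radius proportional to `acc`; accepted darts
#' are rounded onto the k-space grid, giving a blue-noise mask whose
#' realized overall reduction tracks `acc^2` (equal acceleration on both
#' axes). The DC cell is always sampled. Deterministic per seed.
#'
#' @param n matrix size. @param acc per-axis acceleration (`>= 1`).
#' @param seed integer seed.
#' @return `n x n` binary (0/1) integer matrix.
#' @export
poisson_mask <- function(n, acc, seed = 1L) {
  stopifnot(acc >= 1)
  if (acc == 1) return(matrix(1L, n, n))
  r <- .poisson_radius_coef * acc
  r2 <- r * r
  M <- 30L * n * n
  pts <- with_seed(seed, cbind(stats::runif(M, -n / 2, n / 2 - 1e-9),
                               stats::runif(M, -n / 2, n / 2 - 1e-9)))
  pts[1, ] <- 0                       # DC first, always accepted
  # bucket grid of pitch r: any conflicting point lies in a 3x3 block
  nb <- max(1L, as.integer(ceiling(n / r)))
  bx <- pmin(pmax(floor((pts[, 1] + n / 2) / r), 0), nb - 1)
  by <- pmin(pmax(floor((pts[, 2] + n / 2) / r), 0), nb - 1)
  bid <- bx * nb + by + 1
  buck <- vector("list", nb * nb)
  ax <- numeric(M); ay <- numeric(M)
  k <- 0L
  for (i in seq_len(M)) {
    cand <- integer(0)
    bxi <- bx[i]; byi <- by[i]
    for (dx in -1:1) for (dy in -1:1) {
      ux <- bxi + dx; uy <- byi + dy
      if (ux >= 0 && ux < nb && uy >= 0 && uy < nb)
        cand <- c(cand, buck[[ux * nb + uy + 1]])
    }
    if (length(cand)) {
      d2 <- (ax[cand] - pts[i, 1])^2 + (ay[cand] - pts[i, 2])^2
      if (any(d2 < r2)) next
    }
    k <- k + 1L
    ax[k] <- pts[i, 1]; ay[k] <- pts[i, 2]
    buck[[bid[i]]] <- c(buck[[bid[i]]], k)
  }
  mask <- matrix(0L, n, n)
  ix <- pmin(pmax(round(ax[seq_len(k)]) + n %/% 2 + 1, 1), n)
  iy <- pmin(pmax(round(ay[seq_len(k)]) + n %/% 2 + 1, 1), n)
  mask[cbind(ix, iy)] <- 1L
  mask
}

#' Write / read a 0/1 mask as plain text
#'
#' @param mask binary matrix. @param path file path.
#' @export
write_mask <- function(mask, path) {
  utils::write.table(mask, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) as.matrix(utils::read.table(path))

#' Synthetic coil sensitivity maps
#'
#' Smooth complex Gaussian-lobe profiles centered on a ring around the
#' field of view (one lobe per channel, with seeded jitter on the lobe
#' angles), plus a small uniform baseline so the sum-of-squares magnitude
#' is positive at every pixel. Each channel carries a smooth random
#' low-order polynomial phase. With `n_ch = 1` the ring degenerates to a
#' single near-uniform center lobe. These are synthetic stand-ins for
#' measured sensitivity maps; deterministic per seed.
#'
#' @param n matrix size. @param n_ch number of channels (`>= 1`).
#' @param seed integer seed.
#' @return complex array `n x n x n_ch`.
#' @export
make_coil_maps <- function(n, n_ch, seed = 1L) {
  stopifnot(n_ch >= 1)
  u <- centered_coords(n) / n
  X <- matrix(rep(u, times = n), n, n)
  Y <- matrix(rep(u, each = n), n, n)
  with_seed(seed, {
    out <- array(0+0i, c(n, n, n_ch))
    for (j in seq_len(n_ch)) {
      if (n_ch == 1) {
        cx <- 0; cy <- 0; sigma <- 0.9
      } else {
        ang <- 2 * pi * (j - 1) / n_ch + stats::runif(1, -0.15, 0.15)
        cx <- 0.55 * cos(ang); cy <- 0.55 * sin(ang); sigma <- 0.35
      }
      mag <- 0.05 + exp(-((X - cx)^2 + (Y - cy)^2) / (2 * sigma^2))
      a <- stats::rnorm(5, 0, pi / 2)
      ph <- a[1] + a[2] * X + a[3] * Y + a[4] * (X^2 - Y^2) + a[5] * X * Y
      out[, , j] <- mag * exp(1i * ph)
    }
    out
  })
}

#' Synthetic B0 off-resonance map
#'
#' A smooth random field — low-order 2D polynomial plus two sinusoids —
#' scaled so the maximum absolute off-resonance equals
#' `2 * pi * max_hz` rad/s. Deterministic per seed; `max_hz = 0` gives the
#' zero map.
#'
#' @param n matrix size. @param max_hz peak off-resonance in Hz.
#' @param seed integer seed.
#' @return `n x n` numeric matrix in rad/s.
#' @export
make_b0_map <- function(n, max_hz, seed = 1L) {
  if (max_hz == 0) return(matrix(0, n, n))
  u <- centered_coords(n) / n
  X <- matrix(rep(u, times = n), n, n)
  Y <- matrix(rep(u, each = n), n, n)
  with_seed(seed, {
    a <- stats::rnorm(6)
    f <- a[1] * X + a[2] * Y + a[3] * X * Y + a[4] * X^2 + a[5] * Y^2 + a[6] * (X^2 + Y^2)
    for (k in 1:2) {
      fr <- stats::runif(2, 0.5, 2)
      ph <- stats::runif(1, 0, 2 * pi)
      f <- f + 0.5 * stats::rnorm(1) * sin(2 * pi * (fr[1] * X + fr[2] * Y) + ph)
    }
    f * (2 * pi * max_hz / max(abs(f)))
  })
}

#' MR forward model (image to signal)
#'
#' Bundles coil maps, an optional B0 map, a sampling scheme (non-Cartesian
#' trajectory or Cartesian mask) and a time-segment interpolator into one
#' image-to-signal simulator. Signals are produced in unitary-DFT units
#' (the raw non-uniform Fourier sum divided by `n`), so on a fully sampled
#' Cartesian scheme with flat coils the signal equals the unitary 2D DFT
#' of the image.
#'
#' @param coils complex `n x n x n_ch` array from [make_coil_maps()].
#' @param traj an [trajectory()], or `NULL` when `mask` is given.
#' @param mask `n x n` binary Cartesian sampling mask; converted to a
#'   zero-duration trajectory over the sampled cells (column-major order).
#' @param b0 `n x n` off-resonance map in rad/s or `NULL`.
#' @param n_seg number of time segments `L` for the forward interpolation
#'   (`L + 1` nodes); ignored when `b0` is `NULL`.
#' @param interp interpolation scheme, see [segment_interp()].
#' @return object of class `mln_forward`.
#' @export
forward_model <- function(coils, traj = NULL, mask = NULL, b0 = NULL,
                          n_seg = 1L, interp = "linear") {
  n <- dim(coils)[1]
  stopifnot(dim(coils)[2] == n)
  if (is.null(traj) && is.null(mask)) stop("need a trajectory or a mask")
  type <- if (is.null(traj)) "cartesian" else "noncartesian"
  if (is.null(traj)) {
    stopifnot(all(dim(mask) == c(n, n)))
    x <- centered_coords(n)
    idx <- which(mask != 0)
    coords <- cbind(x[(idx - 1) %% n + 1], x[(idx - 1) %/% n + 1])
    traj <- trajectory(coords, rep(0, length(idx)), 0, n)
  }
  seg <- if (is.null(b0)) segment_interp(traj, 0L)
         else segment_interp(traj, as.integer(n_seg), interp)
  structure(list(type = type, n = n, n_ch = dim(coils)[3], coils = coils,
                 b0 = b0, traj = traj, mask = mask, seg = seg,
                 E = nuft_matrix(traj, n)),
            class = "mln_forward")
}

#' @export
print.mln_forward <- function(x, ...) {
  cat(sprintf("<mln_forward> %s, matrix %d, %d channels, %d samples, %s\n",
              x$type, x$n, x$n_ch, x$traj$n_samples,
              if (is.null(x$b0)) "no B0" else
                sprintf("B0 with %d segments", x$seg$L)))
  invisible(x)
}

#' Simulate signals from images through a forward model
#'
#' @param fm an [forward_model()].
#' @param imgs complex `n x n` image, or `n^2 x n_img` matrix of vectorized
#'   images (column-major).
#' @return complex array `[n_samples, n_ch]` for one image, or
#'   `[n_samples, n_ch, n_img]`.
#' @export
simulate_signal <- function(fm, imgs) {
  n <- fm$n
  one <- FALSE
  if (is.matrix(imgs) && all(dim(imgs) == c(n, n))) {
    imgs <- matrix(as.vector(unclass(imgs)), n * n, 1)
    one <- TRUE
  }
  stopifnot(nrow(imgs) == n * n)
  n_img <- ncol(imgs)
  m <- fm$traj$n_samples
  out <- array(0+0i, c(m, fm$n_ch, n_img))
  for (j in seq_len(fm$seg$n_nodes)) {
    P <- if (is.null(fm$b0)) 1
         else as.vector(phase_evolution(fm$b0, j - 1, fm$seg$delta))
    gj <- fm$seg$G[, j]
    for (c in seq_len(fm$n_ch)) {
      W <- imgs * (P * as.vector(fm$coils[, , c]))
      out[, c, ] <- out[, c, ] + gj * (fm$E %*% W)
    }
  }
  out <- out / n
  if (one) {
    out <- out[, , 1, drop = FALSE]
    dim(out) <- c(m, fm$n_ch)
  }
  out
}

#' Zero-filled adjoint reconstruction (baseline)
#'
#' Grids the measured samples back onto k-space (adjoint of the unitary
#' sampling operator), inverse-Fourier-transforms per channel and combines
#' channels with conjugate coil weighting normalized by the coil
#' sum-of-squares. The standard non-iterative baseline a trained network is
#' compared against.
#'
#' @param fm an [forward_model()].
#' @param signal complex `[n_samples, n_ch]` matrix.
#' @return complex `n x n` image.
#' @export
zero_filled_adjoint <- function(fm, signal) {
  n <- fm$n
  acc <- matrix(0+0i, n, n)
  sos <- matrix(0, n, n)
  for (c in seq_len(fm$n_ch)) {
    xc <- matrix(Conj(t(fm$E)) %*% signal[, c], n, n) / n
    acc <- acc + Conj(fm$coils[, , c]) * xc
    sos <- sos + Mod(fm$coils[, , c])^2
  }
  acc / (sos + 1e-8)
}
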