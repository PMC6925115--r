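#' Normalized root-mean-square error
#'
#' `||recon - ref||_2 / ||ref||_2` on the complex values.
#'
#' @param recon,ref complex arrays of identical shape.
#' @return scalar `>= 0`.
#' @export
nrmse <- function(recon, ref) {
  if (!all(dim2(recon) == dim2(ref))) stop("shape mismatch")
  den <- sqrt(sum(Mod(ref)^2))
  if (den == 0) stop("zero-valued reference")
  sqrt(sum(Mod(unclass(recon) - unclass(ref))^2)) / den
}

# sliding-window box sums via integral image; "valid" region only
box_sums <- function(x, w) {
  cs <- apply(apply(x, 2, cumsum), 1, cumsum)  # transposed integral image
  cs <- t(cs)
  n1 <- nrow(x); n2 <- ncol(x)
  Z <- matrix(0, n1 + 1, n2 + 1)
  Z[-1, -1] <- cs
  i <- seq_len(n1 - w + 1); j <- seq_len(n2 - w + 1)
  Z[i + w, j + w] - Z[i, j + w] - Z[i + w, j] + Z[i, j]
}

#' Structural similarity index (SSIM)
#'
#' Computed on image magnitudes with the standard constants: uniform
#' `7 x 7` window, `K1 = 0.01`, `K2 = 0.03`, dynamic range equal to the
#' maximum magnitude of the reference, sample (n-1) covariance
#' normalization, mean taken over the valid window positions.
#'
#' @param recon,ref images (complex allowed; magnitudes are compared),
#'   identical shape, at least `7 x 7`.
#' @param win window size. @param K1,K2 stability constants.
#' @return scalar in `[-1, 1]`.
#' @export
ssim <- function(recon, ref, win = 7L, K1 = 0.01, K2 = 0.03) {
  x <- Mod(unclass(recon)); y <- Mod(unclass(ref))
  if (!all(dim(x) == dim(y))) stop("shape mismatch")
  if (all(y == 0)) stop("zero-valued reference")
  L <- max(y)
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  np <- win * win
  mx <- box_sums(x, win) / np
  my <- box_sums(y, win) / np
  cf <- np / (np - 1)                      # sample covariance
  vx <- cf * (box_sums(x * x, win) / np - mx^2)
  vy <- cf * (box_sums(y * y, win) / np - my^2)
  cxy <- cf * (box_sums(x * y, win) / np - mx * my)
  s <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
       ((mx^2 + my^2 + C1) * (vx + vy + C2))
  mean(s)
}

#' Pseudo-replica noise map
#'
#' Reconstructs `n_reps` noise-perturbed copies of one fixed signal and
#' returns the per-pixel standard deviation of the reconstructions over
#' the replicas, combining both quadratures
#' (`sqrt(Var(Re) + Var(Im))`) so the map is exactly proportional to the
#' injected noise level for a linear reconstruction. `on = "magnitude"`
#' gives the per-pixel sd of the magnitude images instead.
#'
#' @param object a fitted [mln()] model, an `mln_net`, or any function
#'   mapping a signal array to a complex image.
#' @param signal fixed complex `[n_samples, n_ch]` signal.
#' @param noise_sd complex Gaussian noise sd (per real component).
#' @param n_reps number of replicas (`>= 2`).
#' @param seed integer seed.
#' @param on `"complex"` (default) or `"magnitude"`.
#' @return numeric per-pixel sd map.
#' @export
noise_map <- function(object, signal, noise_sd, n_reps = 32L, seed = 1L,
                      on = c("complex", "magnitude")) {
  on <- match.arg(on)
  stopifnot(n_reps >= 2)
  rec <- if (is.function(object)) object
         else if (inherits(object, "mln")) function(s) predict(object, s)
         else function(s) {
           out <- network_forward(object, array(s, dim2(signal)))
           unclass(ct_perm(out, c("RO", "PE")))
         }
  reps <- with_seed(seed, lapply(seq_len(n_reps), function(r)
    rec(signal + array(rcnorm(length(signal), noise_sd), dim2(signal)))))
  d <- dim2(reps[[1]])
  A <- vapply(reps, as.vector, complex(prod(d)))
  if (on == "complex") {
    v <- apply(Re(A), 1, stats::var) + apply(Im(A), 1, stats::var)
    array(sqrt(v), d)
  } else {
    array(apply(Mod(A), 1, stats::sd), d)
  }
}

#' Per-location RMS of the regridding tensor
#'
#' For each k-space grid location the root-mean-square of the
#' corresponding H entries over (neighbor, channel, segment). Trained
#' networks show low RMS on grid locations close to acquired trajectory
#' points and high RMS in the gaps, where the reconstruction must lean
#' harder on neighboring samples and channels.
#'
#' @param H `[n, n, n_n, n_ch, n_ts]` tensor, or a fitted [mln()] model /
#'   `mln_net` with an H stage.
#' @return `n x n` numeric map.
#' @export
kernel_rms_map <- function(H) {
  if (inherits(H, "mln")) H <- network_HM(H$net)$H
  else if (inherits(H, "mln_net")) H <- network_HM(H)$H
  d <- dim(H)
  A <- Mod(H)^2
  dim(A) <- c(d[1] * d[2], prod(d[-(1:2)]))
  matrix(sqrt(rowMeans(A)), d[1], d[2])
}

#' Image-side segment maps of a trained k+I network
#'
#' The `n_ts` per-pixel combination maps `M[, , t]` of the last layer,
#' with magnitude and phase views. In trained networks these maps carry
#' structure reminiscent of the B0 field (segment phase evolution) and of
#' compressed coil sensitivities.
#'
#' @param M `[n, n, n_ts]` tensor, or a fitted [mln()] model / `mln_net`.
#' @return list with `maps` (list of complex matrices), `magnitude` and
#'   `phase` (lists of numeric matrices).
#' @export
segment_maps <- function(M) {
  if (inherits(M, "mln")) M <- network_HM(M$net)$M
  else if (inherits(M, "mln_net")) M <- network_HM(M)$M
  maps <- lapply(seq_len(dim(M)[3]), function(t) M[, , t])
  list(maps = maps, magnitude = lapply(maps, Mod),
       phase = lapply(maps, Arg))
}

#' Benchmark a topology against the zero-filled adjoint baseline
#'
#' For each acceleration and seed: draw a Poisson-disk mask, simulate a
#' training corpus through it, fit the (Cartesian) k+I network, and
#' evaluate SSIM and NRMSE on held-out images against the ground truth —
#' alongside the zero-filled adjoint baseline on the same signals.
#'
#' @param accelerations per-axis acceleration factors to test.
#' @param cfg an [corpus_config()] describing the training corpus.
#' @param coils coil sensitivity array for the simulated acquisition.
#' @param control an [mln_control()].
#' @param n_test held-out images per run.
#' @param seeds seeds (one fit per acceleration x seed).
#' @param n_ts,n_n k+I dimensions for the fitted networks. The benchmark
#'   default regrids from the single nearest acquired sample per grid
#'   location (`n_n = 1`): with blue-noise Cartesian masks the nearest
#'   sample dominates and the per-location combination across channels
#'   carries the parallel-imaging information, while larger neighborhoods
#'   add weights that remain near initialization in the extreme
#'   acceleration arms within desk-scale budgets and only inject noise.
#' @return object of class `mln_report`: list with `per_image` (long
#'   data.frame) and `summary` (medians and IQRs per acceleration and
#'   method).
#' @export
run_benchmark <- function(accelerations, cfg, coils,
                          control = mln_control(), n_test = 6L,
                          seeds = 1L, n_ts = 1L, n_n = 1L) {
  stopifnot(length(accelerations) >= 1)
  rows <- list()
  for (acc in accelerations) for (sd in seeds) {
    mask <- poisson_mask(cfg$n, acc, seed = sd * 1000L + round(acc))
    fm <- forward_model(coils, mask = mask)
    cfg_i <- cfg
    cfg_i$seed <- sample_seed(cfg$seed, sd, 7L)
    corp <- make_corpus(cfg_i, fm)
    ctrl <- control; ctrl$seed <- sd
    fit <- mln(topology_spec("k_plus_i_mln", n = cfg$n, n_ch = fm$n_ch,
                             n_ts = n_ts, n_n = n_n, acc = acc, seed = sd),
               corp, ctrl)
    cfg_t <- cfg_i
    cfg_t$seed <- sample_seed(cfg$seed, sd, 8L)
    cfg_t$n_images <- as.integer(n_test)
    test <- make_corpus(cfg_t, fm)
    n <- cfg$n
    for (j in seq_len(n_test)) {
      ref <- matrix(test$images[, j], n, n)
      sig <- test$signals[, , j]
      rec_mln <- predict(fit, sig)
      rec_zf <- zero_filled_adjoint(fm, sig)
      rows[[length(rows) + 1L]] <- data.frame(
        acceleration = acc, seed = sd, image = j,
        method = c("mln", "zero_filled"),
        ssim = c(ssim(rec_mln, ref), ssim(rec_zf, ref)),
        nrmse = c(nrmse(rec_mln, ref), nrmse(rec_zf, ref)))
    }
  }
  per_image <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(ssim, nrmse) ~ acceleration + method,
                          per_image, stats::median)
  names(agg)[3:4] <- c("ssim_median", "nrmse_median")
  iqr <- stats::aggregate(cbind(ssim, nrmse) ~ acceleration + method,
                          per_image, stats::IQR)
  agg$ssim_iqr <- iqr$ssim
  agg$nrmse_iqr <- iqr$nrmse
  structure(list(per_image = per_image, summary = agg,
                 topology = "k_plus_i_mln", seeds = seeds),
            class = "mln_report")
}

#' @export
print.mln_report <- function(x, ...) {
  cat("Benchmark report (median over held-out images and seeds):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
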