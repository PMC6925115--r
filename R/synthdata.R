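#' Multi-ellipse (modified Shepp-Logan style) phantom
#'
#' Sum of `n_ellipses` random ellipses — random center, semi-axes,
#' rotation, and intensity drawn uniformly from `[-0.5, 1]` — clipped to
#' `[0, 1]`. Deterministic per seed. `n_ellipses = 0` gives the zero
#' image.
#'
#' @param n matrix size (`>= 8`). @param n_ellipses ellipse count.
#' @param seed integer seed.
#' @return `n x n` numeric magnitude image in `[0, 1]`.
#' @export
multi_ellipse_phantom <- function(n, n_ellipses = 8L, seed = 1L) {
  stopifnot(n >= 8)
  u <- centered_coords(n) / n
  X <- matrix(rep(u, times = n), n, n)
  Y <- matrix(rep(u, each = n), n, n)
  with_seed(seed, {
    img <- matrix(0, n, n)
    for (e in seq_len(n_ellipses)) {
      cx <- stats::runif(1, -0.35, 0.35); cy <- stats::runif(1, -0.35, 0.35)
      a <- stats::runif(1, 0.05, 0.4); b <- stats::runif(1, 0.05, 0.4)
      th <- stats::runif(1, 0, pi)
      amp <- stats::runif(1, -0.5, 1)
      xr <- (X - cx) * cos(th) + (Y - cy) * sin(th)
      yr <- -(X - cx) * sin(th) + (Y - cy) * cos(th)
      img <- img + amp * ((xr / a)^2 + (yr / b)^2 <= 1)
    }
    pmin(pmax(img, 0), 1)
  })
}

# isotropic Gaussian smoothing by FFT (periodic boundary); internal
smooth2d <- function(img, sigma) {
  n <- nrow(img)
  k <- centered_coords(n)
  K <- exp(-2 * pi^2 * sigma^2 * (outer(k^2, k^2, "+")) / n^2)
  # DC-centered transfer function; shift to match R's fft layout
  K <- K[c((n / 2 + 1):n, 1:(n / 2)), c((n / 2 + 1):n, 1:(n / 2))]
  Re(stats::fft(stats::fft(img) * K, inverse = TRUE)) / (n * n)
}

#' Procedural brain-like magnitude image (synthetic)
#'
#' A stand-in for real anatomical training images: an elliptical head
#' support with a bright cortical-ribbon-like annulus, interior tissue
#' intensities produced by quantizing a smoothed random field to
#' piecewise levels (CSF/grey/white-like), dark ventricle-like blobs,
#' and fine-scale band-passed (difference-of-Gaussians) texture that
#' plays the role of cortical folds — the granular structure that
#' distinguishes anatomy from smooth geometric phantoms. Purely
#' procedural: it emulates the intensity statistics of brain MRI (edges,
#' piecewise compartments, fine folds), not anatomy. Deterministic per
#' seed.
#'
#' @inheritParams multi_ellipse_phantom
#' @return `n x n` numeric magnitude image in `[0, 1]`.
#' @export
brainlike_image <- function(n, seed = 1L) {
  stopifnot(n >= 8)
  u <- centered_coords(n) / n
  X <- matrix(rep(u, times = n), n, n)
  Y <- matrix(rep(u, each = n), n, n)
  with_seed(seed, {
    a <- stats::runif(1, 0.3, 0.38); b <- stats::runif(1, 0.36, 0.44)
    cx <- stats::runif(1, -0.03, 0.03); cy <- stats::runif(1, -0.03, 0.03)
    rr <- ((X - cx) / a)^2 + ((Y - cy) / b)^2
    head <- rr <= 1
    ribbon <- rr <= 1 & rr >= 0.72
    field <- smooth2d(matrix(stats::rnorm(n * n), n, n), sigma = n / 16)
    q <- stats::quantile(field[head], c(0.3, 0.7))
    tissue <- matrix(0.35, n, n)
    tissue[field > q[1]] <- 0.6
    tissue[field > q[2]] <- 0.85
    img <- ifelse(head, tissue, 0)
    img[ribbon] <- 0.9
    for (v in 1:2) {
      vx <- cx + stats::runif(1, -0.08, 0.08)
      vy <- cy + stats::runif(1, -0.1, 0.1)
      va <- stats::runif(1, 0.03, 0.07); vb <- stats::runif(1, 0.04, 0.1)
      vent <- ((X - vx) / va)^2 + ((Y - vy) / vb)^2 <= 1
      img[vent & head] <- 0.15
    }
    # cortical-fold-like fine texture: band-passed noise ribbons
    z <- matrix(stats::rnorm(n * n), n, n)
    tex <- smooth2d(z, n / 40) - smooth2d(z, n / 14)
    tex <- tex / max(1e-9, max(abs(tex)))
    img[head] <- img[head] + 0.3 * tanh(3 * tex[head])
    mod <- 1 + 0.15 * smooth2d(matrix(stats::rnorm(n * n), n, n), n / 8) /
      max(1e-9, max(abs(smooth2d(matrix(stats::rnorm(n * n), n, n), n / 8))))
    pmin(pmax(img * mod, 0), 1)
  })
}

#' Random smooth phase map
#'
#' `phase(r) = sum_j a_j sin(omega_j q(r) + phi_j)` with `q` a random
#' quadratic form of the pixel coordinates normalized to `[0, 1]` over the
#' image. Defaults: 3 sinusoids, amplitudes uniform in `[0, pi]`,
#' frequencies uniform in `[0.5, 3]` cycles over the range of `q` — smooth
#' multi-radian phase as produced by coils and shim in practice. Output in
#' radians; deterministic per seed.
#'
#' @param n matrix size (`>= 8`). @param seed integer seed.
#' @param n_sin number of sinusoids.
#' @param amp_range,freq_range ranges for the amplitudes (radians) and
#'   frequencies (cycles across the quadratic form's range).
#' @return `n x n` numeric phase map (radians).
#' @export
random_phase <- function(n, seed = 1L, n_sin = 3L,
                         amp_range = c(0, pi), freq_range = c(0.5, 3)) {
  stopifnot(n >= 8)
  u <- centered_coords(n) / n
  X <- matrix(rep(u, times = n), n, n)
  Y <- matrix(rep(u, each = n), n, n)
  with_seed(seed, {
    cf <- stats::rnorm(5)
    q <- cf[1] * X^2 + cf[2] * X * Y + cf[3] * Y^2 + cf[4] * X + cf[5] * Y
    q <- (q - min(q)) / max(1e-12, max(q) - min(q))
    ph <- matrix(0, n, n)
    for (j in seq_len(n_sin)) {
      aj <- stats::runif(1, amp_range[1], amp_range[2])
      fj <- stats::runif(1, freq_range[1], freq_range[2])
      pj <- stats::runif(1, 0, 2 * pi)
      ph <- ph + aj * sin(2 * pi * fj * q + pj)
    }
    ph
  })
}

#' Random crop / flip / rotate augmentation
#'
#' Random crop to `target x target`, independent random flips along each
#' axis, and a random 0/90 degree rotation — each stage individually
#' switchable. Deterministic per seed; with all stages disabled (and
#' matching sizes) this is the identity.
#'
#' @param img source magnitude image, at least `target` in each dimension.
#' @param target output size; default `nrow(img)` (no crop if equal).
#' @param seed integer seed.
#' @param crop,flip,rotate logical switches.
#' @return `target x target` image.
#' @export
augment <- function(img, target = nrow(img), seed = 1L,
                    crop = TRUE, flip = TRUE, rotate = TRUE) {
  if (nrow(img) < target || ncol(img) < target)
    stop("source image smaller than crop target")
  with_seed(seed, {
    if (crop) {
      ox <- sample.int(nrow(img) - target + 1L, 1L) - 1L
      oy <- sample.int(ncol(img) - target + 1L, 1L) - 1L
    } else {
      ox <- (nrow(img) - target) %/% 2L
      oy <- (ncol(img) - target) %/% 2L
    }
    out <- img[ox + seq_len(target), oy + seq_len(target)]
    if (flip) {
      if (stats::runif(1) < 0.5) out <- out[rev(seq_len(target)), ]
      if (stats::runif(1) < 0.5) out <- out[, rev(seq_len(target))]
    }
    if (rotate && stats::runif(1) < 0.5)
      out <- t(out)[rev(seq_len(target)), ]   # 90 degrees
    out
  })
}

#' Corpus configuration
#'
#' @param n_images number of samples (`>= 1`).
#' @param n matrix size of the ground-truth images.
#' @param source `"ellipse"` (multi-ellipse phantoms) or `"brainlike"`
#'   (procedural brain-like images).
#' @param source_size size at which source images are generated before
#'   augmentation cropping; default `2 * n`.
#' @param augment_flags logical switches, see [augment()].
#' @param phase_args list of arguments forwarded to [random_phase()].
#' @param noise_sd complex Gaussian noise sd added to signals (per real
#'   component, in signal units); default 0 (noiseless training, as is the
#'   default regime of the method).
#' @param seed master seed; per-sample seeds are derived by counter, so
#'   corpus generation is order-independent.
#' @return object of class `mln_corpus_config`.
#' @export
corpus_config <- function(n_images, n, source = c("ellipse", "brainlike"),
                          source_size = 2L * n,
                          augment_flags = list(crop = TRUE, flip = TRUE,
                                               rotate = TRUE),
                          phase_args = list(), noise_sd = 0, seed = 1L) {
  source <- match.arg(source)
  stopifnot(n_images >= 1, source_size >= n)
  structure(list(n_images = as.integer(n_images), n = as.integer(n),
                 source = source, source_size = as.integer(source_size),
                 augment_flags = augment_flags, phase_args = phase_args,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "mln_corpus_config")
}

# counter-derived per-sample seed; independent of generation order
sample_seed <- function(master, i, stream = 0L) {
  as.integer((as.double(master) * 7919 + i * 104729 + stream * 15485863) %%
               2147483647)
}

#' Generate one paired (signal, image) training sample
#'
#' Complex ground truth = augmented magnitude source times
#' `exp(1i * random_phase)`; signal = the forward model applied to it
#' (plus optional complex Gaussian noise). Fully regenerable from
#' `(cfg, fm, i)`.
#'
#' @param cfg an [corpus_config()]. @param fm an [forward_model()].
#' @param i sample index in `1:cfg$n_images`.
#' @return list with `image` (complex `n x n`), `signal`
#'   (`[n_samples, n_ch]`), `meta` (seeds and ids).
#' @export
corpus_sample <- function(cfg, fm, i) {
  img <- corpus_sample_image(cfg, i)
  sig <- simulate_signal(fm, img)
  if (cfg$noise_sd > 0) {
    nz <- with_seed(sample_seed(cfg$seed, i, 3L),
                    rcnorm(length(sig), cfg$noise_sd))
    sig <- sig + array(nz, dim(sig))
  }
  list(image = img, signal = sig,
       meta = list(index = i, seed = cfg$seed, source = cfg$source,
                   forward = fm$type))
}

#' Materialize a synthetic training corpus
#'
#' Generates `cfg$n_images` paired samples through the forward model.
#' Ground-truth images are returned as an `n^2 x n_images` complex matrix
#' (vectorized column-major) and signals as
#' `[n_samples, n_ch, n_images]`. Generation is deterministic per master
#' seed and per-sample (counter-derived seeds), so any subset can be
#' regenerated independently with [corpus_sample()].
#'
#' @param cfg an [corpus_config()]. @param fm an [forward_model()].
#' @param indices which samples to generate (default all).
#' @return object of class `mln_corpus` with fields `images`, `signals`,
#'   `cfg`, `fm`, `indices`.
#' @export
make_corpus <- function(cfg, fm, indices = seq_len(cfg$n_images)) {
  n <- cfg$n
  imgs <- matrix(0+0i, n * n, length(indices))
  for (j in seq_along(indices)) {
    s <- corpus_sample_image(cfg, indices[j])
    imgs[, j] <- as.vector(s)
  }
  sigs <- simulate_signal(fm, imgs)
  if (length(dim(sigs)) == 2) dim(sigs) <- c(dim(sigs), 1L)
  if (cfg$noise_sd > 0) {
    for (j in seq_along(indices)) {
      nz <- with_seed(sample_seed(cfg$seed, indices[j], 3L),
                      rcnorm(length(sigs[, , j]), cfg$noise_sd))
      sigs[, , j] <- sigs[, , j] + matrix(nz, dim(sigs)[1], dim(sigs)[2])
    }
  }
  structure(list(images = imgs, signals = sigs, cfg = cfg, fm = fm,
                 indices = indices),
            class = "mln_corpus")
}

# ground-truth complex image of sample i (no signal simulation); internal
corpus_sample_image <- function(cfg, i) {
  s <- sample_seed(cfg$seed, i)
  n <- cfg$n
  src <- switch(cfg$source,
                ellipse = multi_ellipse_phantom(cfg$source_size,
                                                n_ellipses = 8L, seed = s),
                brainlike = brainlike_image(cfg$source_size, seed = s))
  af <- cfg$augment_flags
  mag <- augment(src, target = n, seed = sample_seed(cfg$seed, i, 1L),
                 crop = isTRUE(af$crop), flip = isTRUE(af$flip),
                 rotate = isTRUE(af$rotate))
  ph <- do.call(random_phase,
                c(list(n = n, seed = sample_seed(cfg$seed, i, 2L)),
                  cfg$phase_args))
  mag * exp(1i * ph)
}

#' @export
print.mln_corpus <- function(x, ...) {
  cat(sprintf("<mln_corpus> %d %s samples, matrix %d, %d channels\n",
              length(x$indices), x$cfg$source, x$cfg$n, dim(x$signals)[2]))
  invisible(x)
}

#' Corpus manifest
#'
#' One record per sample (index, derived seeds, source type, forward-model
#' id) — enough to regenerate any sample bit-exactly.
#'
#' @param corpus an [make_corpus()] result.
#' @return data.frame.
#' @export
corpus_manifest <- function(corpus) {
  cfg <- corpus$cfg
  data.frame(index = corpus$indices,
             source = cfg$source,
             seed_image = sample_seed(cfg$seed, corpus$indices),
             seed_augment = sample_seed(cfg$seed, corpus$indices, 1L),
             seed_phase = sample_seed(cfg$seed, corpus$indices, 2L),
             forward = corpus$fm$type,
             n = cfg$n)
}
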