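#' Training configuration
#'
#' The training recipe is deliberately plain: Adam at a fixed learning
#' rate with L1 loss on the complex residual, complex weights optimized as
#' independent real and imaginary parts, no bias terms, no regularization,
#' no schedule.
#'
#' @param learning_rate fixed Adam step size (default 0.002).
#' @param beta1 Adam first-moment decay (default 0.9).
#' @param beta2,epsilon standard Adam defaults.
#' @param batch_size samples per step.
#' @param max_steps step budget.
#' @param loss `"l1_split"` (mean of `|Re| + |Im|` over the residual,
#'   the default) or `"l1_mod"` (mean complex modulus).
#' @param window,tol convergence rule: stop when the relative change of
#'   the `window`-step mean loss falls below `tol`.
#' @param seed seed controlling weight initialization when [mln()] builds
#'   the network itself.
#' @return object of class `mln_control`.
#' @export
mln_control <- function(learning_rate = 0.002, beta1 = 0.9, beta2 = 0.999,
                        epsilon = 1e-8, batch_size = 8L, max_steps = 5000L,
                        loss = c("l1_split", "l1_mod"),
                        window = 200L, tol = 1e-4, seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_steps >= 1)
  structure(list(learning_rate = learning_rate, beta1 = beta1,
                 beta2 = beta2, epsilon = epsilon,
                 batch_size = as.integer(batch_size),
                 max_steps = as.integer(max_steps),
                 loss = match.arg(loss), window = as.integer(window),
                 tol = tol, seed = as.integer(seed)),
            class = "mln_control")
}

#' L1 loss on complex images
#'
#' Component-wise by default: mean over entries of
#' `|Re(pred - target)| + |Im(pred - target)|`. The `"l1_mod"` variant
#' takes the mean complex modulus instead.
#'
#' @param pred,target complex arrays of identical shape.
#' @param type loss variant.
#' @return scalar loss.
#' @export
l1_loss <- function(pred, target, type = c("l1_split", "l1_mod")) {
  type <- match.arg(type)
  if (!all(dim2(pred) == dim2(target))) stop("shape mismatch")
  r <- unclass(pred) - unclass(target)
  if (type == "l1_split") mean(abs(Re(r)) + abs(Im(r))) else mean(Mod(r))
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

# loss and its gradient w.r.t. pred under the split-real convention
loss_grad <- function(pred, target, type) {
  r <- pred - target
  nt <- length(r)
  if (type == "l1_split") {
    g <- complex(real = sign(Re(r)), imaginary = sign(Im(r))) / nt
  } else {
    m <- Mod(r)
    g <- ifelse(m > 0, r / m, 0+0i) / nt
  }
  dim(g) <- dim(r)
  list(loss = if (type == "l1_split") mean(abs(Re(r)) + abs(Im(r)))
       else mean(Mod(r)), g = g)
}

# Adam on the split-real parameters of all trainable stages.
# signals: [n_samples, n_ch, n_img]; targets: [n^2, n_img].
train_network <- function(net, signals, targets, control,
                          eval_every = 0L, eval_fun = NULL) {
  din <- net$input$dims
  n_img <- dim(signals)[3]
  stopifnot(prod(din) == prod(dim(signals)[1:2]))
  n <- net$topology$n
  bs <- min(control$batch_size, n_img)
  tr <- which(vapply(net$stages, function(s)
    identical(s$type, "sfc") && isTRUE(s$trainable), logical(1)))
  opt <- lapply(tr, function(i) {
    e <- new.env(parent = emptyenv())
    e$m <- complex(length(net$stages[[i]]$w))
    e$v <- complex(length(net$stages[[i]]$w))
    e
  })
  losses <- numeric(0)
  evals <- list()
  b1 <- control$beta1; b2 <- control$beta2
  lr <- control$learning_rate; eps <- control$epsilon
  w <- control$window
  converged <- FALSE
  for (t in seq_len(control$max_steps)) {
    idx <- ((t - 1L) * bs + seq_len(bs) - 1L) %% n_img + 1L
    xb <- array(signals[, , idx], c(din, bs))
    x <- ctensor(xb, c(net$input$axes, "smp"))
    fw <- network_forward(net, x, keep_cache = TRUE)
    out <- ct_perm(fw$out, c("RO", "PE", "smp"))
    tgt <- array(targets[, idx], c(n, n, bs))
    lg <- loss_grad(unclass(out), tgt, control$loss)
    if (!is.finite(lg$loss))
      stop("training aborted: non-finite loss at step ", t,
           " (learning rate too high or degenerate inputs)")
    losses[t] <- lg$loss
    g <- ctensor(lg$g, c("RO", "PE", "smp"))
    gw <- network_backward(net, fw$cache, g)
    c1 <- 1 - b1^t
    s2 <- sqrt(1 - b2^t)
    for (j in seq_along(tr)) {
      i <- tr[j]
      e <- opt[[j]]
      wst <- net$stages[[i]]$w
      wnew <- adam_update(as.vector(unclass(wst)), e$m, e$v,
                          as.vector(unclass(gw[[i]])),
                          lr, b1, b2, eps, c1, s2)
      dim(wnew) <- dim(wst)
      net$stages[[i]]$w <- new_ct(wnew, ct_axes(wst))
    }
    if (eval_every > 0L && !is.null(eval_fun) && t %% eval_every == 0L)
      evals[[length(evals) + 1L]] <- list(step = t, value = eval_fun(net))
    if (t >= 2L * w) {
      m1 <- mean(losses[(t - w + 1L):t])
      m0 <- mean(losses[(t - 2L * w + 1L):(t - w)])
      if (abs(m1 - m0) / max(abs(m0), 1e-12) < control$tol) {
        converged <- TRUE
        break
      }
    }
  }
  list(net = net,
       log = list(loss = losses, steps = length(losses),
                  converged = converged, evals = evals))
}

#' Fit a minimal linear reconstruction network
#'
#' The central model-fitting function: builds the requested topology for
#' the corpus's sampling scheme, then optimizes its trainable complex
#' tensors by Adam with L1 loss so that the network maps simulated
#' signals to their ground-truth complex images. The result is a trained
#' linear signal-to-image operator — a data-driven (regularized by
#' minimality, not by penalties) left-inverse of the forward model on the
#' span of the training images.
#'
#' @param topology an [topology_spec()], or a topology id string (then
#'   `n`, `n_ch` are taken from the corpus and remaining dimensions from
#'   `...`).
#' @param corpus an [make_corpus()] training corpus (its forward model
#'   supplies the sampling scheme).
#' @param control an [mln_control()].
#' @param net optionally a pre-built (e.g. planted) `mln_net` to start
#'   from, bypassing topology construction.
#' @param ... forwarded to [topology_spec()] when `topology` is a string.
#' @return an object of class `mln` with methods `print`, `summary`,
#'   `coef`, `predict`, `fitted`, `residuals`, `plot`.
#' @examples
#' \donttest{
#' fm <- forward_model(make_coil_maps(16, 1), mask = matrix(1L, 16, 16))
#' corp <- make_corpus(corpus_config(64, 16, "ellipse"), fm)
#' fit <- mln("two_by_1d", corp, mln_control(max_steps = 400))
#' print(fit)
#' }
#' @export
mln <- function(topology, corpus, control = mln_control(), net = NULL, ...) {
  stopifnot(inherits(corpus, "mln_corpus"))
  fm <- corpus$fm
  if (is.character(topology))
    topology <- topology_spec(topology, n = corpus$cfg$n, n_ch = fm$n_ch,
                              seed = control$seed, ...)
  if (is.null(net)) {
    net <- if (topology$id %in% c("fc2d", "two_by_1d"))
      build_topology(topology)
    else build_topology(topology, traj = fm$traj)
  }
  res <- train_network(net, corpus$signals, corpus$images, control)
  structure(list(net = res$net, topology = res$net$topology,
                 control = control, log = res$log,
                 forward = fm, corpus_cfg = corpus$cfg,
                 final_loss = utils::tail(res$log$loss, 1),
                 call = match.call()),
            class = "mln")
}

#' @export
print.mln <- function(x, ...) {
  cat(sprintf("Minimal linear network: topology '%s'\n", x$topology$id))
  cat(sprintf("  matrix %d, %d channels, %d segments, %d neighbors\n",
              x$topology$n, x$topology$n_ch, x$topology$n_ts,
              x$topology$n_n))
  cat(sprintf("  %s trainable real parameters\n",
              format(network_params(x$net), big.mark = ",")))
  cat(sprintf("  trained %d steps (%s), final L1 loss %.4g\n",
              x$log$steps,
              if (isTRUE(x$log$converged)) "converged" else "step budget",
              x$final_loss))
  invisible(x)
}

#' @export
summary.mln <- function(object, ...) {
  w <- coef(object)
  cat("Trained tensors:\n")
  for (nm in names(w))
    cat(sprintf("  %-8s [%s]  rms %.4g\n", nm,
                paste(dim(w[[nm]]), collapse = "x"),
                sqrt(mean(Mod(w[[nm]])^2))))
  print(object)
  invisible(object)
}

#' @export
coef.mln <- function(object, ...) {
  w <- list()
  for (st in object$net$stages)
    if (identical(st$type, "sfc") && isTRUE(st$trainable))
      w[[st$name]] <- st$w
  w
}

#' Reconstruct images from signals with a trained network
#'
#' @param object a fitted [mln()] model.
#' @param signal complex `[n_samples, n_ch]` signal, or
#'   `[n_samples, n_ch, k]` batch (the fitted model does not keep its
#'   training corpus, so a signal must always be given).
#' @param ... unused.
#' @return complex `n x n` image or `n x n x k` array.
#' @export
predict.mln <- function(object, signal, ...) {
  net <- object$net
  din <- net$input$dims
  d <- dim2(signal)
  batched <- length(d) == 3L || prod(d) != prod(din)
  if (!batched) {
    out <- network_forward(net, array(signal, din))
    matrix(unclass(ct_perm(out, c("RO", "PE"))), net$topology$n)
  } else {
    k <- d[length(d)]
    x <- ctensor(array(signal, c(din, k)), c(net$input$axes, "smp"))
    out <- ct_perm(network_forward(net, x), c("RO", "PE", "smp"))
    array(unclass(out), c(net$topology$n, net$topology$n, k))
  }
}

#' @export
fitted.mln <- function(object, corpus, ...) {
  if (missing(corpus)) stop("supply the training corpus to refit from")
  predict(object, corpus$signals)
}

#' @export
residuals.mln <- function(object, corpus, ...) {
  if (missing(corpus)) stop("supply the corpus to compute residuals on")
  f <- fitted(object, corpus)
  n <- object$topology$n
  f - array(corpus$images, c(n, n, ncol(corpus$images)))
}

#' Plot a trained network's interpretability maps
#'
#' For k+I style fits, an image of the per-location RMS of the regridding
#' tensor H with the trajectory overlaid (low RMS on sampled locations,
#' high in the gaps); otherwise the magnitude of the first trained tensor.
#'
#' @param x a fitted [mln()] model. @param ... passed to [graphics::image()].
#' @export
plot.mln <- function(x, ...) {
  hm <- try(network_HM(x$net), silent = TRUE)
  if (!inherits(hm, "try-error")) {
    rms <- kernel_rms_map(hm$H)
    graphics::image(centered_coords(x$topology$n),
                    centered_coords(x$topology$n), rms,
                    xlab = "kRO", ylab = "kPE",
                    main = "regridding kernel RMS", ...)
    if (!is.null(x$net$traj))
      graphics::points(x$net$traj$coords, pch = ".", col = "blue")
  } else {
    w <- coef(x)[[1]]
    graphics::image(Mod(matrix(unclass(w), dim(w)[1])),
                    main = names(coef(x))[1], ...)
  }
  invisible(x)
}
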