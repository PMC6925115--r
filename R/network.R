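# Linear network machinery: a network is an ordered list of stages, each a
# linear map with an exact hand-derived split-real backward pass. Stage
# types: "sfc" (trainable or frozen subspace-connected layer), "gather"
# (trajectory samples -> Cartesian neighbor tensor), "flatten" (merge two
# axes), "add_axis" (append a singleton axis), "squeeze" (drop singleton
# axes). Everything tolerates an extra batch axis ("smp") riding through.

stage_forward <- function(st, x) {
  switch(st$type,
    sfc = sfc_apply(x, st$w, st$spec),
    gather = gather_forward(st, x),
    flatten = flatten_forward(st, x),
    add_axis = {
      d <- ct_dim(x)
      v <- unclass(x); dim(v) <- c(unname(d), 1L)
      ctensor(v, c(names(d), st$axis))
    },
    squeeze = ct_squeeze(x, st$axes),
    stop("unknown stage type: ", st$type))
}

stage_backward <- function(st, cc, g, need_gx = TRUE) {
  x_in <- cc$x
  switch(st$type,
    sfc = {
      r <- sfc_backward(x_in, st$w, st$spec, g,
                        need_gx = need_gx, need_gw = isTRUE(st$trainable),
                        lo = cc$lo, xp = cc$xp)
      list(gx = r$gx, gw = r$gw)
    },
    gather = list(gx = if (need_gx) gather_backward(st, x_in, g), gw = NULL),
    flatten = list(gx = if (need_gx) flatten_backward(st, x_in, g), gw = NULL),
    add_axis = {
      gx <- NULL
      if (need_gx) {
        d <- ct_dim(x_in)
        gp <- unclass(ct_perm(g, c(names(d), st$axis)))
        dim(gp) <- unname(d)
        gx <- ctensor(gp, names(d))
      }
      list(gx = gx, gw = NULL)
    },
    squeeze = {
      gx <- NULL
      if (need_gx) {
        d <- ct_dim(x_in)
        kept <- names(d)[!(names(d) %in% st$axes)]
        gp <- unclass(ct_perm(g, kept))
        dim(gp) <- unname(d)
        gx <- ctensor(gp, names(d))
      }
      list(gx = gx, gw = NULL)
    },
    stop("unknown stage type: ", st$type))
}

gather_forward <- function(st, x) {
  xa <- ct_axes(x)
  rest <- setdiff(xa, "samp")
  xp <- ct_perm(x, c("samp", rest))
  d <- ct_dim(xp)
  m <- d[["samp"]]
  X <- unclass(xp); dim(X) <- c(m, prod(d) / m)
  S <- X[as.vector(st$idx), , drop = FALSE]
  nn <- ncol(st$idx)
  dim(S) <- c(st$n, st$n, nn, unname(d[rest]))
  new_ct(S, c("kRO", "kPE", "nb", rest))
}

gather_backward <- function(st, x_in, g) {
  xa <- ct_axes(x_in)
  rest <- setdiff(xa, "samp")
  d_in <- ct_dim(ct_perm(x_in, c("samp", rest)))
  gp <- ct_perm(g, c("kRO", "kPE", "nb", rest))
  G <- unclass(gp); dim(G) <- c(st$n * st$n * ncol(st$idx),
                                prod(ct_dim(gp)) / (st$n * st$n * ncol(st$idx)))
  grp <- as.vector(st$idx)
  zr <- rowsum(Re(G), grp)
  zi <- rowsum(Im(G), grp)
  gx <- matrix(0+0i, d_in[["samp"]], ncol(G))
  gx[as.integer(rownames(zr)), ] <- zr + 1i * zi
  dim(gx) <- unname(d_in)
  ct_perm(new_ct(gx, c("samp", rest)), xa)
}

flatten_forward <- function(st, x) {
  xa <- ct_axes(x)
  rest <- setdiff(xa, st$from)
  xp <- ct_perm(x, c(st$from, rest))
  d <- ct_dim(xp)
  v <- unclass(xp)
  dim(v) <- c(prod(d[st$from]), unname(d[rest]))
  new_ct(v, c(st$to, rest))
}

flatten_backward <- function(st, x_in, g) {
  xa <- ct_axes(x_in)
  rest <- setdiff(xa, st$from)
  d <- ct_dim(ct_perm(x_in, c(st$from, rest)))
  gp <- unclass(ct_perm(g, c(st$to, rest)))
  dim(gp) <- unname(d)
  ct_perm(new_ct(gp, c(st$from, rest)), xa)
}

#' Run a linear network forward
#'
#' @param net an `mln_net` from [build_topology()].
#' @param x input array matching `net$input` (axes attached automatically),
#'   optionally with a trailing batch dimension (axis `"smp"`).
#' @param keep_cache keep per-stage inputs for a backward pass.
#' @return the output `ctensor`, or (with `keep_cache`) a list
#'   `(out, cache)`.
#' @export
network_forward <- function(net, x, keep_cache = FALSE) {
  if (is.null(attr(x, "axes"))) {
    din <- net$input$dims
    xd <- dim(x)
    if (is.null(xd)) xd <- length(x)
    if (prod(xd) == prod(din)) {
      x <- ctensor(array(x, din), net$input$axes)
    } else if (length(xd) == length(din) + 1L &&
               all(xd[seq_along(din)] == din)) {
      x <- ctensor(x, c(net$input$axes, "smp"))
    } else if (prod(xd) %% prod(din) == 0) {
      x <- ctensor(array(x, c(din, prod(xd) / prod(din))),
                   c(net$input$axes, "smp"))
    } else stop("input does not match the network's input contract")
  }
  cache <- if (keep_cache) vector("list", length(net$stages))
  for (i in seq_along(net$stages)) {
    st <- net$stages[[i]]
    if (keep_cache && identical(st$type, "sfc")) {
      r <- sfc_apply(x, st$w, st$spec, cache = TRUE)
      cache[[i]] <- list(x = x, lo = r$lo, xp = r$xp)
      x <- r$y
    } else {
      if (keep_cache) cache[[i]] <- list(x = x)
      x <- stage_forward(st, x)
    }
  }
  if (keep_cache) list(out = x, cache = cache) else x
}

# backward pass: returns list(gw = per-stage weight gradients (NULL for
# fixed stages)); gradient w.r.t. the network input is not needed anywhere
network_backward <- function(net, cache, g) {
  ns <- length(net$stages)
  tr <- which(vapply(net$stages, function(s)
    identical(s$type, "sfc") && isTRUE(s$trainable), logical(1)))
  first_tr <- if (length(tr)) min(tr) else 1L
  gw <- vector("list", ns)
  for (i in rev(seq_len(ns))) {
    if (i < first_tr) break   # nothing upstream left to update
    r <- stage_backward(net$stages[[i]], cache[[i]], g,
                        need_gx = i > first_tr)
    gw[i] <- list(r$gw)
    g <- r$gx
  }
  gw
}

#' Trainable real-parameter count of a built network
#'
#' @param net an `mln_net`.
#' @return numeric count (complex weights count as two reals).
#' @export
network_params <- function(net) {
  s <- 0
  for (st in net$stages)
    if (identical(st$type, "sfc") && isTRUE(st$trainable))
      s <- s + 2 * prod(as.double(dim(st$w)))
  s
}

#' Assemble the explicit reconstruction matrix of a network
#'
#' Feeds every unit input through the network and collects the vectorized
#' outputs as columns — the brute-force representation of the network's
#' linear action, used as the oracle that any built topology must equal.
#'
#' @param net an `mln_net`.
#' @return complex matrix `[prod(output dims), prod(input dims)]`.
#' @export
assemble_operator <- function(net) {
  din <- net$input$dims
  ni <- prod(din)
  e <- array(0+0i, din)
  out1 <- network_forward(net, e)
  no <- length(out1)
  A <- matrix(0+0i, no, ni)
  for (k in seq_len(ni)) {
    e[k] <- 1
    A[, k] <- as.vector(unclass(network_forward(net, e)))
    e[k] <- 0
  }
  A
}
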