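#' Subspace-connected complex linear layer specification
#'
#' The subspace-connected (SFC) layer generalizes the fully-connected layer
#' to multi-axis tensors by assigning each input axis one of three roles:
#' \describe{
#'   \item{`fully_connected`}{the axis is contracted against a weight matrix
#'     and replaced by a new axis of length `out_lengths[axis]`; several
#'     fully connected axes are contracted jointly (the weight tensor spans
#'     their full cross product).}
#'   \item{`shared`}{the operation is applied identically at every index of
#'     the axis (one set of weights, as the FT stage of a reconstruction
#'     applied to every line).}
#'   \item{`independent`}{a separate set of weights is used at every index
#'     of the axis (as per-location regridding kernels).}
#' }
#' The layer is purely linear on the complex field: no bias terms and no
#' activation functions anywhere.
#'
#' The weight tensor has one `in_len` dimension per fully connected axis
#' (in declaration order) followed by their `out_len` dimensions, then one
#' dimension of `in_len` per independent axis; shared axes do not appear.
#' Complex weights count as two real parameters each.
#'
#' @param axes named integer vector: input axis lengths, in declaration
#'   order.
#' @param roles named character vector over the same axes; each one of
#'   `"fully_connected"`, `"shared"`, `"independent"` (unambiguous
#'   abbreviations such as `"fc"` are accepted).
#' @param out_lengths named integer vector giving the output length of each
#'   fully connected axis; defaults to the input lengths. Naming a
#'   non-fully-connected axis is an error.
#' @param out_names optional named character vector renaming the output axis
#'   of a fully connected axis (e.g. `c(kRO = "RO")` for a domain change).
#' @param init weight initialization scheme; only `"gaussian"` (complex
#'   Gaussian, each real component N(0, 1/fan_in) with fan_in the product of
#'   contracted input lengths) is defined.
#' @param seed integer seed making initialization deterministic.
#' @return an object of class `sfc_spec`.
#' @examples
#' # GRAPPA-like kernel: contract neighbors and channels jointly,
#' # shared over k-space locations
#' sp <- sfc_spec(c(kRO = 8, kPE = 8, n = 3, ch = 2),
#'                c(kRO = "shared", kPE = "shared",
#'                  n = "fully_connected", ch = "fully_connected"),
#'                out_lengths = c(n = 1, ch = 1))
#' param_count(sp)
#' @export
sfc_spec <- function(axes, roles, out_lengths = NULL, out_names = NULL,
                     init = "gaussian", seed = 1L) {
  if (is.null(names(axes)) || anyDuplicated(names(axes)))
    stop("axes must be uniquely named")
  axes <- vapply(axes, as.integer, integer(1))
  if (any(axes < 1L)) stop("axis lengths must be positive")
  if (!setequal(names(roles), names(axes)))
    stop("every axis must be assigned exactly one role")
  roles <- vapply(roles[names(axes)], function(r)
    match.arg(r, c("fully_connected", "shared", "independent")),
    character(1))
  fc <- names(axes)[roles == "fully_connected"]
  if (length(fc) == 0L)
    stop("at least one axis must be fully connected (pure broadcast layers are rejected)")
  if (is.null(out_lengths)) out_lengths <- axes[fc]
  if (!all(names(out_lengths) %in% fc))
    stop("out_lengths given for a non-fully-connected axis")
  ol <- axes[fc]
  ol[names(out_lengths)] <- as.integer(out_lengths)
  if (any(ol < 1L)) stop("output lengths must be positive")
  on <- fc
  names(on) <- fc
  if (!is.null(out_names)) {
    if (!all(names(out_names) %in% fc))
      stop("out_names given for a non-fully-connected axis")
    on[names(out_names)] <- out_names
  }
  structure(list(axes = axes, roles = roles, fc_axes = fc,
                 ind_axes = names(axes)[roles == "independent"],
                 shared_axes = names(axes)[roles == "shared"],
                 out_lengths = ol, out_names = on,
                 init = init, seed = as.integer(seed)),
            class = "sfc_spec")
}

#' @export
print.sfc_spec <- function(x, ...) {
  cat("<sfc_spec> [",
      paste(sprintf("%s(%d)%s", names(x$axes), x$axes,
                    c(fully_connected = "*", shared = "", independent = "!")[x$roles]),
            collapse = ", "),
      "] ", param_count(x), " real parameters\n", sep = "")
  invisible(x)
}

# weight tensor dimensions and axis names implied by a spec: the input
# dims of the fully connected axes (declaration order), then their output
# dims, then the independent axes
sfc_weight_dims <- function(spec) {
  fc <- spec$fc_axes
  list(dims = c(unname(spec$axes[fc]), unname(spec$out_lengths[fc]),
                unname(spec$axes[spec$ind_axes])),
       axes = c(paste0(fc, "_in"), paste0(fc, "_out"), spec$ind_axes))
}

#' Build (initialize) the weights of an SFC layer
#'
#' @param spec an [sfc_spec()].
#' @return a `ctensor` of complex weights with the shape mandated by the
#'   spec: `(in x out)` per fully connected axis, `in` per independent axis,
#'   shared axes absent. Deterministic given `spec$seed`.
#' @export
build_sfc <- function(spec) {
  stopifnot(inherits(spec, "sfc_spec"))
  wd <- sfc_weight_dims(spec)
  fan_in <- prod(spec$axes[spec$fc_axes])
  if (!identical(spec$init, "gaussian"))
    stop("unknown weight_init scheme: ", spec$init)
  vals <- with_seed(spec$seed,
                    rcnorm(prod(wd$dims), sd = sqrt(1 / fan_in)))
  ctensor(array(vals, wd$dims), wd$axes)
}

#' Real parameter count of an SFC layer
#'
#' Complex weights count as two real parameters; there are never bias
#' terms. For a layer taking an `M x N x F1` tensor to `M x N x F2` with all
#' axes fully connected this is `2 * M^2 * N^2 * F1 * F2`.
#'
#' @param spec an [sfc_spec()].
#' @return integer (stored as double to avoid 32-bit overflow).
#' @export
param_count <- function(spec) {
  stopifnot(inherits(spec, "sfc_spec"))
  2 * prod(as.double(sfc_weight_dims(spec)$dims))
}

#' Real parameter count of a complex 2D convolution layer
#'
#' Listed for taxonomy/bookkeeping only (the package trains no
#' convolutional layers): a `K1 x K2` kernel mapping `F1` to `F2` feature
#' maps has `2 * K1 * K2 * F1 * F2` real parameters (bias terms discarded).
#'
#' @param k1,k2 kernel size. @param f1,f2 input/output feature counts.
#' @return numeric count.
#' @export
conv_param_count <- function(k1, k2, f1, f2) 2 * k1 * k2 * f1 * f2

# Permutation bookkeeping shared by forward and backward passes.
# Axes of x not declared in the spec are treated as extra shared axes
# (this is how a batch axis rides through every layer).
sfc_layout <- function(x, spec) {
  xa <- ct_axes(x)
  need <- names(spec$axes)
  if (!all(need %in% xa)) stop("input is missing declared axes: ",
                               paste(setdiff(need, xa), collapse = ", "))
  d <- ct_dim(x)
  if (!all(d[need] == spec$axes))
    stop("input axis lengths do not match the layer spec")
  fc <- spec$fc_axes
  ind_in_x <- xa[xa %in% spec$ind_axes]
  sh_in_x <- xa[!(xa %in% c(fc, spec$ind_axes))]
  S <- prod(d[sh_in_x]); P <- prod(d[ind_in_x])
  Fin <- prod(spec$axes[fc]); Fout <- prod(spec$out_lengths[fc])
  nonc_in_x <- xa[!(xa %in% fc)]
  list(xa = xa, d = d, fc = fc, ind_in_x = ind_in_x, sh_in_x = sh_in_x,
       nonc_in_x = nonc_in_x, S = as.integer(S), P = as.integer(P),
       Fin = as.integer(Fin), Fout = as.integer(Fout))
}

# weight permuted to [P, Fin, Fout] matching the layout's independent order
sfc_weight_3d <- function(w, spec, lo) {
  wa <- ct_axes(w)
  want <- c(lo$ind_in_x,
            paste0(lo$fc, "_in"), paste0(lo$fc, "_out"))
  wp <- aperm(unclass(w), match(want, wa))
  dim(wp) <- c(lo$P, lo$Fin, lo$Fout)
  wp
}

# x permuted/reshaped to [P, S, Fin]; independent axes fastest so that
# per-location weight vectors recycle down the columns without copies
sfc_x_3d <- function(x, lo) {
  xp <- unclass(ct_perm(x, c(lo$ind_in_x, lo$sh_in_x, lo$fc)))
  dim(xp) <- c(lo$P, lo$S, lo$Fin)
  xp
}

#' Apply an SFC layer
#'
#' Contracts the fully connected axes of `x` against the weights, applying
#' one weight set per index combination of the independent axes and the
#' same set at every index of the shared axes. Axes of `x` that the spec
#' does not declare are carried through unchanged (shared), so a batch axis
#' needs no special handling. The operation is linear in `x`.
#'
#' Output layout: non-contracted axes in input order, then the output axis
#' of each fully connected axis in spec declaration order.
#'
#' @param x a `ctensor` containing all axes declared by `spec`.
#' @param w weights from [build_sfc()] (or any tensor of that shape).
#' @param spec the [sfc_spec()].
#' @param cache also return the permuted layout/input (reused by the
#'   training backward pass to avoid re-permuting).
#' @return the output `ctensor`, or (with `cache`) a list
#'   `(y, lo, xp)`.
#' @export
sfc_apply <- function(x, w, spec, cache = FALSE) {
  lo <- sfc_layout(x, spec)
  S <- lo$S; P <- lo$P; Fin <- lo$Fin; Fout <- lo$Fout
  out_ax0 <- unname(spec$out_names[lo$fc])
  # fast path: no independent axes and contracted axes already leading --
  # one BLAS call, no array permutes
  if (P == 1L && identical(lo$xa, c(lo$fc, lo$sh_in_x))) {
    X <- unclass(x); dim(X) <- c(Fin, S)
    W <- unclass(ct_perm(w, c(paste0(lo$fc, "_in"), paste0(lo$fc, "_out"))))
    dim(W) <- c(Fin, Fout)
    out <- crossprod(X, W)               # t(X) %*% W, (S, Fout)
    dim(out) <- c(unname(lo$d[lo$sh_in_x]), unname(spec$out_lengths[lo$fc]))
    y <- new_ct(out, c(lo$sh_in_x, out_ax0))
    return(if (cache) list(y = y, lo = lo, xp = NULL) else y)
  }
  xp <- sfc_x_3d(x, lo)
  wp <- sfc_weight_3d(w, spec, lo)
  if (P == 1L) {
    out <- matrix(xp, S, Fin) %*% matrix(wp, Fin, Fout)
    dim(out) <- c(1L, S, Fout)
  } else {
    out <- sfc_contract_fwd(xp, wp, P, S, Fin, Fout)
  }
  out_ax <- unname(spec$out_names[lo$fc])
  dims <- c(unname(lo$d[lo$ind_in_x]), unname(lo$d[lo$sh_in_x]),
            unname(spec$out_lengths[lo$fc]))
  dim(out) <- dims
  y <- new_ct(out, c(lo$ind_in_x, lo$sh_in_x, out_ax))
  y <- ct_perm(y, c(lo$nonc_in_x, out_ax))
  if (cache) list(y = y, lo = lo, xp = xp) else y
}

# Exact split-real gradients of sfc_apply.
# With y = W x on the complex field and g = dL/dRe(y) + i dL/dIm(y):
#   dL/dx = t(Conj(W)) g   and   dL/dW = g Conj(x)'
# summed over shared axes for the weight gradient.
sfc_backward <- function(x, w, spec, g, need_gx = TRUE, need_gw = TRUE,
                         lo = NULL, xp = NULL) {
  if (is.null(lo)) lo <- sfc_layout(x, spec)
  out_ax <- unname(spec$out_names[lo$fc])
  wd <- sfc_weight_dims(spec)
  # fast path mirroring sfc_apply: contracted axes leading on both sides
  if (lo$P == 1L && identical(lo$xa, c(lo$fc, lo$sh_in_x)) &&
      identical(ct_axes(g), c(out_ax, lo$sh_in_x))) {
    X <- unclass(x); dim(X) <- c(lo$Fin, lo$S)
    G <- unclass(g); dim(G) <- c(lo$Fout, lo$S)
    res <- list()
    if (need_gx) {
      W <- unclass(ct_perm(w, c(paste0(lo$fc, "_in"),
                                paste0(lo$fc, "_out"))))
      dim(W) <- c(lo$Fin, lo$Fout)
      gx <- Conj(W) %*% G                 # (Fin, S)
      dim(gx) <- unname(lo$d[c(lo$fc, lo$sh_in_x)])
      res$gx <- new_ct(gx, c(lo$fc, lo$sh_in_x))
    }
    if (need_gw) {
      gwm <- tcrossprod(Conj(X), G)       # (Fin, Fout)
      dim(gwm) <- c(unname(spec$axes[lo$fc]),
                    unname(spec$out_lengths[lo$fc]))
      gwt <- new_ct(gwm, c(paste0(lo$fc, "_in"), paste0(lo$fc, "_out")))
      res$gw <- ct_perm(gwt, wd$axes)
    }
    return(res)
  }
  gp <- unclass(ct_perm(g, c(lo$ind_in_x, lo$sh_in_x, out_ax)))
  dim(gp) <- c(lo$P, lo$S, lo$Fout)
  if (is.null(xp) && need_gw) xp <- sfc_x_3d(x, lo)
  wp <- sfc_weight_3d(w, spec, lo)
  S <- lo$S; P <- lo$P; Fin <- lo$Fin; Fout <- lo$Fout
  gx <- NULL; gw <- NULL
  if (P == 1L) {
    gm <- matrix(gp, S, Fout)
    if (need_gx) {
      gx <- gm %*% t(Conj(matrix(wp, Fin, Fout)))
      dim(gx) <- c(P, S, Fin)
    }
    if (need_gw) {
      gw <- t(Conj(matrix(xp, S, Fin))) %*% gm
      dim(gw) <- c(P, Fin, Fout)
    }
  } else {
    if (need_gx) {
      gx <- sfc_contract_gx(gp, wp, P, S, Fin, Fout)
      dim(gx) <- c(P, S, Fin)
    }
    if (need_gw) {
      gw <- sfc_contract_gw(xp, gp, P, S, Fin, Fout)
      dim(gw) <- c(P, Fin, Fout)
    }
  }
  res <- list()
  if (need_gx) {
    dim(gx) <- c(unname(lo$d[lo$ind_in_x]), unname(lo$d[lo$sh_in_x]),
                 unname(spec$axes[lo$fc]))
    gxt <- new_ct(gx, c(lo$ind_in_x, lo$sh_in_x, lo$fc))
    res$gx <- ct_perm(gxt, lo$xa)
  }
  if (need_gw) {
    # reshape [P, Fin, Fout] back to the stored weight layout
    wd <- sfc_weight_dims(spec)
    dim(gw) <- c(unname(lo$d[lo$ind_in_x]),
                 unname(spec$axes[lo$fc]), unname(spec$out_lengths[lo$fc]))
    gwt <- new_ct(gw, c(lo$ind_in_x,
                         paste0(lo$fc, "_in"), paste0(lo$fc, "_out")))
    res$gw <- ct_perm(gwt, wd$axes)
  }
  res
}

#' Serialize / restore an SFC layer spec
#'
#' Specs round-trip through a small YAML dialect with keys `axes`, `roles`,
#' `out_lengths`, `out_names`, `init`, `seed`.
#'
#' @param spec an [sfc_spec()]. @param path file path.
#' @return `write_sfc_spec` returns `path` invisibly; `read_sfc_spec`
#'   returns the restored `sfc_spec`.
#' @export
write_sfc_spec <- function(spec, path) {
  yaml::write_yaml(list(axes = as.list(spec$axes),
                        roles = as.list(spec$roles),
                        out_lengths = as.list(spec$out_lengths),
                        out_names = as.list(spec$out_names),
                        init = spec$init, seed = spec$seed), path)
  invisible(path)
}

#' @rdname write_sfc_spec
#' @export
read_sfc_spec <- function(path) {
  l <- yaml::read_yaml(path)
  sfc_spec(unlist(l$axes), unlist(l$roles),
           out_lengths = unlist(l$out_lengths),
           out_names = unlist(l$out_names),
           init = l$init, seed = l$seed)
}
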