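#' Save / load a complex tensor with axis metadata
#'
#' Writes a `ctensor` (e.g. a single layer's weights) to JSON with its
#' shape and axis names; complex values are stored as paired real and
#' imaginary vectors.
#'
#' @param x a `ctensor`. @param path file path.
#' @return `write_ctensor` returns `path` invisibly; `read_ctensor` the
#'   restored `ctensor`.
#' @export
write_ctensor <- function(x, path) {
  jsonlite::write_json(list(dims = dim(x), axes = ct_axes(x),
                            re = as.vector(Re(x)), im = as.vector(Im(x))),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ctensor
#' @export
read_ctensor <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  ctensor(array(complex(real = j$re, imaginary = j$im), j$dims), j$axes)
}

#' Save / load a trained network
#'
#' Serializes an `mln_net` (topology id and dimensions, sampling
#' coordinates, and all stage weight tensors with shape and axis-name
#' metadata) to a single JSON file; complex values are stored as paired
#' real/imaginary vectors.
#'
#' @param net an `mln_net` (or a fitted [mln()] model, whose network is
#'   saved).
#' @param path file path.
#' @return `mln_save` returns `path` invisibly; `mln_load` the restored
#'   `mln_net`.
#' @export
mln_save <- function(net, path) {
  if (inherits(net, "mln")) net <- net$net
  ts <- net$topology
  ws <- list()
  for (i in seq_along(net$stages)) {
    st <- net$stages[[i]]
    if (identical(st$type, "sfc") && isTRUE(st$trainable))
      ws[[as.character(i)]] <- list(
        name = st$name, dims = dim(st$w), axes = ct_axes(st$w),
        re = as.vector(Re(st$w)), im = as.vector(Im(st$w)))
  }
  traj <- net$traj
  jsonlite::write_json(list(
    topology = ts[c("id", "n", "n_ch", "n_ts", "n_n", "acc", "n_virt",
                    "ts_shared", "seed")],
    traj = if (!is.null(traj)) list(coords = traj$coords,
                                    times = traj$times,
                                    duration = traj$duration, n = traj$n),
    weights = ws), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname mln_save
#' @export
mln_load <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  tp <- j$topology
  ts <- topology_spec(tp$id, n = tp$n, n_ch = tp$n_ch, n_ts = tp$n_ts,
                      n_n = tp$n_n, acc = tp$acc, n_virt = tp$n_virt,
                      ts_shared = tp$ts_shared, seed = tp$seed)
  traj <- NULL
  if (length(j$traj$coords))
    traj <- trajectory(j$traj$coords, j$traj$times, j$traj$duration,
                       j$traj$n)
  net <- if (ts$id %in% c("fc2d", "two_by_1d")) build_topology(ts)
         else build_topology(ts, traj = traj)
  for (k in names(j$weights)) {
    i <- as.integer(k)
    wrec <- j$weights[[k]]
    w <- array(complex(real = wrec$re, imaginary = wrec$im),
               unlist(wrec$dims))
    net$stages[[i]]$w <- ctensor(w, unlist(wrec$axes))
  }
  net
}
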