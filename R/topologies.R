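#' Network topology specification
#'
#' Declares one of the reconstruction network topologies and its
#' dimensions:
#' \describe{
#'   \item{`fc2d`}{single all-axes fully connected layer, k-space to image
#'     (`2 N^4` real parameters).}
#'   \item{`two_by_1d`}{two 1D fully connected layers, each shared along
#'     the other axis (`2 * 2 N^2` real parameters).}
#'   \item{`pi_kernel`}{parallel-imaging kernel network: neighbor+channel
#'     kernel shared over k-space (GRAPPA-like, single combined output
#'     channel), then fixed 2 x 1D inverse FT.}
#'   \item{`scc`}{software coil compression (channel-axis FC shared over
#'     k-space) feeding the `pi_kernel` network.}
#'   \item{`gcc`}{geometric coil compression: FT along readout, then a
#'     location-specific channel compression (independent along RO, FC
#'     along channels, shared along kPE), FT back, feeding `pi_kernel`.}
#'   \item{`knuft_mln`}{transposed time-segmented NUFT pipeline:
#'     trajectory-side expansion into time segments (location-specific,
#'     shared along channels), neighbor gathering onto the grid, a
#'     location-specific collapse shared along segments, fixed FT, and
#'     image-side segment combination.}
#'   \item{`k_plus_i_mln`}{the k+I network: location-specific regridding
#'     tensor H over (neighbor, channel) into `n_ts` segments, fixed 2D
#'     FT, and the image-side per-pixel segment combination tensor M.}
#' }
#' Ids `"automap"` and `"general"` are accepted by
#' [count_topology_params()] only (their printed parameter-count formulas
#' are evaluated for comparison; those networks are not built).
#'
#' @param id topology id.
#' @param n matrix size. @param n_ch receive channels.
#' @param n_ts time segments (segment maps). @param n_n neighbors gathered
#'   per grid location. @param acc acceleration factor.
#' @param n_traj number of trajectory samples (needed to count the
#'   trajectory-side expansion of `knuft_mln`; filled in automatically
#'   when building with a trajectory).
#' @param n_virt target channels of the coil-compression topologies.
#' @param ts_shared share the k-side kernel over grid locations and add an
#'   independent per-location segment map (the TS-shared k+I variant).
#' @param seed seed for weight initialization.
#' @return object of class `mln_topology`.
#' @export
topology_spec <- function(id = c("fc2d", "two_by_1d", "scc", "gcc",
                                 "pi_kernel", "knuft_mln", "k_plus_i_mln",
                                 "automap", "general"),
                          n, n_ch = 1L, n_ts = 1L, n_n = 1L, acc = 1L,
                          n_traj = NULL, n_virt = 2L, ts_shared = FALSE,
                          seed = 1L) {
  id <- match.arg(id)
  stopifnot(n >= 2, n_ch >= 1, n_ts >= 1, n_n >= 1, acc >= 1)
  structure(list(id = id, n = as.integer(n), n_ch = as.integer(n_ch),
                 n_ts = as.integer(n_ts), n_n = as.integer(n_n),
                 acc = acc, n_traj = n_traj,
                 n_virt = as.integer(n_virt), ts_shared = isTRUE(ts_shared),
                 seed = as.integer(seed)),
            class = "mln_topology")
}

#' @export
print.mln_topology <- function(x, ...) {
  cat(sprintf("<mln_topology> %s: n=%d n_ch=%d n_ts=%d n_n=%d acc=%g\n",
              x$id, x$n, x$n_ch, x$n_ts, x$n_n, x$acc))
  invisible(x)
}

# frozen unitary Fourier stage along one axis (shared over all others)
ft_stage <- function(n, from, to, inverse = TRUE, name = from) {
  spec <- sfc_spec(stats::setNames(n, from),
                   stats::setNames("fully_connected", from),
                   out_names = stats::setNames(to, from), seed = 0L)
  Fm <- if (inverse) idft_matrix(n) else dft_matrix(n)
  list(type = "sfc", name = paste0("ft_", name), spec = spec,
       w = ctensor(Fm, c(paste0(from, "_in"), paste0(from, "_out"))),
       trainable = FALSE)
}

tr_stage <- function(name, spec) {
  list(type = "sfc", name = name, spec = spec, trainable = TRUE)
}

# ordered stage descriptors for a topology; m = number of trajectory
# samples (only needed by the knuft expansion stage)
topology_stage_specs <- function(ts, m = ts$n_traj) {
  n <- ts$n; n_ch <- ts$n_ch; n_ts <- ts$n_ts; n_n <- ts$n_n
  kernel_axes <- function(ch, loc_roles) {
    sfc_spec(c(kRO = n, kPE = n, nb = n_n, ch = ch),
             c(kRO = loc_roles, kPE = loc_roles,
               nb = "fully_connected", ch = "fully_connected"),
             out_lengths = c(nb = 1L, ch = 1L),
             out_names = c(nb = "u1", ch = "u2"))
  }
  M_spec <- sfc_spec(c(RO = n, PE = n, ts = n_ts),
                     c(RO = "independent", PE = "independent",
                       ts = "fully_connected"),
                     out_lengths = c(ts = 1L), out_names = c(ts = "u3"))
  # with a single segment the image-side combination is fixed at 1 (the
  # no-B0 variant trains only the regridding kernel)
  M_stage <- if (n_ts > 1L) tr_stage("M", M_spec) else
    list(type = "sfc", name = "M", spec = M_spec,
         w = ctensor(array(1+0i, c(1, 1, n, n)),
                     c("ts_in", "ts_out", "RO", "PE")),
         trainable = FALSE)
  ift2 <- list(ft_stage(n, "kRO", "RO"), ft_stage(n, "kPE", "PE"))
  switch(ts$id,
    fc2d = list(
      tr_stage("fc2d", sfc_spec(c(kRO = n, kPE = n),
                                c(kRO = "fully_connected",
                                  kPE = "fully_connected"),
                                out_names = c(kRO = "RO", kPE = "PE")))),
    two_by_1d = list(
      tr_stage("fc_ro", sfc_spec(c(kRO = n, kPE = n),
                                 c(kRO = "fully_connected", kPE = "shared"),
                                 out_names = c(kRO = "RO"))),
      tr_stage("fc_pe", sfc_spec(c(RO = n, kPE = n),
                                 c(kPE = "fully_connected", RO = "shared"),
                                 out_names = c(kPE = "PE")))),
    pi_kernel = c(
      list(list(type = "gather", name = "gather"),
           tr_stage("kernel", kernel_axes(n_ch, "shared")),
           list(type = "squeeze", name = "squeeze1", axes = c("u1", "u2"))),
      ift2),
    scc = c(
      list(tr_stage("scc", sfc_spec(c(ch = n_ch), c(ch = "fully_connected"),
                                    out_lengths = c(ch = ts$n_virt),
                                    out_names = c(ch = "ch"))),
           list(type = "gather", name = "gather"),
           tr_stage("kernel", kernel_axes(ts$n_virt, "shared")),
           list(type = "squeeze", name = "squeeze1", axes = c("u1", "u2"))),
      ift2),
    gcc = c(
      list(ft_stage(n, "kRO", "RO", inverse = TRUE, name = "hybrid"),
           tr_stage("gcc", sfc_spec(c(RO = n, ch = n_ch),
                                    c(RO = "independent",
                                      ch = "fully_connected"),
                                    out_lengths = c(ch = ts$n_virt),
                                    out_names = c(ch = "ch"))),
           ft_stage(n, "RO", "kRO", inverse = FALSE, name = "back"),
           list(type = "flatten", name = "flatten",
                from = c("kRO", "kPE_s"), to = "samp"),
           list(type = "gather", name = "gather"),
           tr_stage("kernel", kernel_axes(ts$n_virt, "shared")),
           list(type = "squeeze", name = "squeeze1", axes = c("u1", "u2"))),
      ift2),
    knuft_mln = {
      if (n_ts == 1L) {
        ts2 <- ts; ts2$id <- "k_plus_i_mln"
        topology_stage_specs(ts2, m)
      } else {
        if (is.null(m)) stop("knuft_mln needs n_traj (or a trajectory)")
        c(list(list(type = "add_axis", name = "add_u", axis = "u"),
               tr_stage("expand",
                        sfc_spec(c(u = 1L, samp = as.integer(m)),
                                 c(u = "fully_connected",
                                   samp = "independent"),
                                 out_lengths = c(u = n_ts),
                                 out_names = c(u = "ts"))),
               list(type = "gather", name = "gather"),
               tr_stage("H", kernel_axes(n_ch, "independent")),
               list(type = "squeeze", name = "squeeze1", axes = c("u1", "u2"))),
          ift2,
          list(M_stage,
               list(type = "squeeze", name = "squeeze2", axes = "u3")))
      }
    },
    k_plus_i_mln = {
      loc <- if (ts$ts_shared) "shared" else "independent"
      H_spec <- sfc_spec(c(kRO = n, kPE = n, nb = n_n, ch = n_ch),
                         c(kRO = loc, kPE = loc,
                           nb = "fully_connected", ch = "fully_connected"),
                         out_lengths = c(nb = 1L, ch = n_ts),
                         out_names = c(nb = "u1", ch = "ts"))
      segmap <- if (ts$ts_shared) list(
        list(type = "add_axis", name = "add_u", axis = "u"),
        tr_stage("segmap",
                 sfc_spec(c(u = 1L, kRO = n, kPE = n, ts = n_ts),
                          c(u = "fully_connected", kRO = "independent",
                            kPE = "independent", ts = "independent"),
                          out_lengths = c(u = 1L),
                          out_names = c(u = "u2"))),
        list(type = "squeeze", name = "squeeze_seg", axes = "u2"))
      c(list(list(type = "gather", name = "gather"),
             tr_stage("H", H_spec),
             list(type = "squeeze", name = "squeeze1", axes = "u1")),
        segmap,
        ift2,
        list(M_stage,
             list(type = "squeeze", name = "squeeze2", axes = "u3")))
    },
    stop("topology '", ts$id, "' cannot be built"))
}

#' Real-parameter counts of the network topologies
#'
#' Sums two times the complex tensor sizes of all trainable stages of the
#' built topology. For the two reference architectures that the package
#' does not build, the published count formulas are evaluated instead:
#' `automap` is `n_ch n^4 / acc + 2 n^4 + C` with the convolutional
#' constant `C = 0`, and `general` (the full general-purpose signal-to-
#' image transform) is `2 n_ch n^4 / acc`.
#'
#' @param ts an [topology_spec()].
#' @return numeric real-parameter count.
#' @examples
#' count_topology_params(topology_spec("k_plus_i_mln", n = 128, n_ch = 13,
#'                                     n_ts = 7, n_n = 12, acc = 4))
#' @export
count_topology_params <- function(ts) {
  n <- as.double(ts$n)
  if (ts$id == "automap")
    return(ts$n_ch * n^4 / ts$acc + 2 * n^4)
  if (ts$id == "general")
    return(2 * ts$n_ch * n^4 / ts$acc)
  stages <- topology_stage_specs(ts)
  s <- 0
  for (st in stages)
    if (identical(st$type, "sfc") && isTRUE(st$trainable))
      s <- s + param_count(st$spec)
  s
}

#' Nearest-trajectory-sample table for Cartesian grid locations
#'
#' For every location of the centered `n x n` k-space grid, the indices of
#' the `n_neighbors` nearest trajectory samples (Euclidean distance in
#' k-space units; ties broken by lower sample index) with their distances
#' and k-space offsets.
#'
#' @param traj an [trajectory()]. @param n grid size.
#' @param n_neighbors neighbors per grid location
#'   (`<= traj$n_samples`).
#' @return object of class `mln_neighbors`: `idx` and `dist`
#'   (`[n^2, n_neighbors]`, grid locations vectorized column-major),
#'   `offsets` (`[n^2, n_neighbors, 2]`), `n`, `n_neighbors`.
#' @export
gather_neighbors <- function(traj, n, n_neighbors) {
  if (traj$n_samples < 1L) stop("empty trajectory")
  stopifnot(n_neighbors <= traj$n_samples)
  x <- centered_coords(n)
  gx <- rep(x, times = n); gy <- rep(x, each = n)
  D <- outer(gx, traj$coords[, 1], "-")^2 + outer(gy, traj$coords[, 2], "-")^2
  ng <- n * n
  idx <- matrix(0L, ng, n_neighbors)
  dst <- matrix(0, ng, n_neighbors)
  for (r in seq_len(ng)) {
    o <- order(D[r, ])[seq_len(n_neighbors)]   # radix sort: stable, so
    idx[r, ] <- o                              # ties go to lower index
    dst[r, ] <- sqrt(D[r, o])
  }
  off <- array(0, c(ng, n_neighbors, 2))
  off[, , 1] <- matrix(traj$coords[idx, 1], ng) - gx
  off[, , 2] <- matrix(traj$coords[idx, 2], ng) - gy
  structure(list(idx = idx, dist = dst, offsets = off, n = as.integer(n),
                 n_neighbors = as.integer(n_neighbors), traj = traj),
            class = "mln_neighbors")
}

#' Gather signal samples into the neighbor tensor S
#'
#' `S[i, j, nb, ch] = signal[idx(i, j, nb), ch]` — the pure (linear)
#' gather that arranges trajectory data onto the Cartesian grid for the
#' regridding kernel.
#'
#' @param signal complex vector (single channel) or `[n_samples, n_ch]`
#'   matrix.
#' @param nt an [gather_neighbors()] table.
#' @return `ctensor` with axes `(kRO, kPE, nb, ch)`.
#' @export
assemble_S <- function(signal, nt) {
  if (is.null(dim(signal))) signal <- matrix(signal, ncol = 1)
  x <- ctensor(signal, c("samp", "ch"))
  gather_forward(list(idx = nt$idx, n = nt$n), x)
}

#' Apply the k+I reconstruction given its two tensors
#'
#' `K[i,j,t] = sum_{nb,ch} S[i,j,nb,ch] H[i,j,nb,ch,t]`, then the fixed
#' unitary inverse 2D FT per segment, then
#' `Ihat[i,j] = sum_t M[i,j,t] * FT2D(K)[i,j,t]`. Linear in `S`.
#'
#' @param S neighbor tensor from [assemble_S()] (axes kRO, kPE, nb, ch).
#' @param H complex `[n, n, n_n, n_ch, n_ts]` regridding tensor.
#' @param M complex `[n, n, n_ts]` image-side combination tensor.
#' @return complex `n x n` image.
#' @export
k_plus_i_apply <- function(S, H, M) {
  S <- unclass(ct_perm(S, c("kRO", "kPE", "nb", "ch")))
  n <- dim(H)[1]; n_ts <- dim(H)[5]
  stopifnot(all(dim(S) == dim(H)[1:4]), all(dim(M) == c(n, n, n_ts)))
  iF <- idft_matrix(n)
  out <- matrix(0+0i, n, n)
  for (t in seq_len(n_ts)) {
    SH <- as.vector(S) * as.vector(H[, , , , t])
    dim(SH) <- c(n * n, length(SH) / (n * n))
    Kt <- matrix(rowSums(SH), n, n)
    out <- out + M[, , t] * (iF %*% Kt %*% iF)
  }
  out
}

#' Build a reconstruction network topology
#'
#' Materializes the stage list of a topology (see [topology_spec()]) with
#' initialized weights and, for gather-based topologies, the neighbor
#' table of the given sampling scheme. Cartesian sampling may be given as
#' a mask (arbitrary point sets, e.g. Poisson disk) which is converted to
#' a zero-duration trajectory; `gcc`/`scc`/`pi_kernel` default to regular
#' line undersampling of the phase-encoding axis by `acc`.
#'
#' @param ts an [topology_spec()].
#' @param traj an [trajectory()] (non-Cartesian sampling).
#' @param mask binary `n x n` Cartesian sampling mask.
#' @return object of class `mln_net` with fields `stages`, `input`
#'   (axes and dims contract), `topology`, `nt` (neighbor table or NULL).
#' @export
build_topology <- function(ts, traj = NULL, mask = NULL) {
  n <- ts$n
  if (ts$id %in% c("automap", "general"))
    stop("unknown/unbuildable topology id: ", ts$id)
  needs_gather <- !(ts$id %in% c("fc2d", "two_by_1d"))
  pe_lines <- NULL
  if (needs_gather && is.null(traj)) {
    if (is.null(mask)) {
      if (ts$id %in% c("pi_kernel", "scc", "gcc")) {
        pe_lines <- seq(1, n, by = max(1L, as.integer(round(ts$acc))))
        mask <- matrix(0L, n, n)
        mask[, pe_lines] <- 1L
      } else stop("topology '", ts$id, "' needs a trajectory or mask")
    }
    x <- centered_coords(n)
    idx <- which(mask != 0)
    coords <- cbind(x[(idx - 1) %% n + 1], x[(idx - 1) %/% n + 1])
    traj <- trajectory(coords, rep(0, length(idx)), 0, n)
  }
  if (ts$id == "gcc") {
    if (is.null(pe_lines))
      pe_lines <- sort(unique((which(mask != 0) - 1) %/% n + 1))
    # gcc operates on [kRO, sampled kPE lines, ch]; rebuild the sample
    # coordinate list in the flatten stage's storage order (kRO fastest)
    x <- centered_coords(n)
    coords <- cbind(rep(x, times = length(pe_lines)),
                    rep(x[pe_lines], each = n))
    traj <- trajectory(coords, rep(0, nrow(coords)), 0, n)
  }
  m <- if (needs_gather) traj$n_samples else NULL
  ts$n_traj <- m
  stages <- topology_stage_specs(ts, m)
  nt <- NULL
  for (i in seq_along(stages)) {
    st <- stages[[i]]
    if (identical(st$type, "gather")) {
      if (is.null(nt)) nt <- gather_neighbors(traj, n, ts$n_n)
      st$idx <- nt$idx
      st$n <- n
    } else if (identical(st$type, "sfc") && isTRUE(st$trainable)) {
      st$spec$seed <- ts$seed * 131L + i
      st$w <- build_sfc(st$spec)
    }
    stages[[i]] <- st
  }
  input <- switch(ts$id,
    fc2d = ,
    two_by_1d = list(axes = c("kRO", "kPE"), dims = c(n, n)),
    gcc = list(axes = c("kRO", "kPE_s", "ch"),
               dims = c(n, length(pe_lines), ts$n_ch)),
    list(axes = c("samp", "ch"), dims = c(m, ts$n_ch)))
  structure(list(stages = stages, input = input, topology = ts,
                 nt = nt, traj = if (needs_gather) traj else NULL,
                 pe_lines = pe_lines),
            class = "mln_net")
}

#' @export
print.mln_net <- function(x, ...) {
  cat(sprintf("<mln_net> %s: %d stages, %s trainable real parameters\n",
              x$topology$id, length(x$stages),
              format(network_params(x), big.mark = ",")))
  for (st in x$stages)
    cat(sprintf("  %-10s %s%s\n", st$type,
                if (!is.null(st$name)) st$name else "",
                if (identical(st$type, "sfc"))
                  sprintf(" [%s]%s", paste(dim(st$w), collapse = "x"),
                          if (isTRUE(st$trainable)) "*" else " (fixed)")
                else ""))
  invisible(x)
}

#' Extract the k+I tensors from a built network
#'
#' Rearranges the trained weights of the `H` and `M` stages into the
#' shapes used by [k_plus_i_apply()], [kernel_rms_map()] and
#' [segment_maps()].
#'
#' @param net an `mln_net` with k+I structure.
#' @return list with `H` (`[n, n, n_n, n_ch, n_ts]`) and `M`
#'   (`[n, n, n_ts]`).
#' @export
network_HM <- function(net) {
  ts <- net$topology
  n <- ts$n
  Hst <- Mst <- NULL
  for (st in net$stages) {
    if (identical(st$name, "H")) Hst <- st
    if (identical(st$name, "M")) Mst <- st
  }
  if (is.null(Hst) || is.null(Mst))
    stop("network has no H/M stages (not a k+I style topology)")
  Hw <- Hst$w   # axes: nb_in, nb_out(1), ch_in, ts(out), [kRO, kPE]
  wa <- ct_axes(Hw)
  if (all(c("kRO", "kPE") %in% wa)) {
    Hp <- unclass(ct_perm(Hw, c("kRO", "kPE", "nb_in", "nb_out",
                                "ch_in", "ch_out")))
  } else {
    # location-shared kernel: broadcast over the grid
    Hp0 <- unclass(ct_perm(Hw, c("nb_in", "nb_out", "ch_in", "ch_out")))
    Hp <- aperm(array(Hp0, c(dim(Hp0), n, n)), c(5, 6, 1, 2, 3, 4))
  }
  dim(Hp) <- c(n, n, ts$n_n, ts$n_ch, ts$n_ts)
  Mw <- Mst$w   # axes: ts_in, ts_out(1), RO, PE
  Mp <- unclass(ct_perm(Mw, c("RO", "PE", "ts_in", "ts_out")))
  dim(Mp) <- c(n, n, ts$n_ts)
  list(H = Hp, M = Mp)
}
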