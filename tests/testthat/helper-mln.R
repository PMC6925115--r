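# shared fixtures and oracles for the test suite (all generated in code)

rel_err <- function(a, b) {
  den <- sqrt(sum(Mod(unclass(b))^2))
  sqrt(sum(Mod(unclass(a) - unclass(b))^2)) / max(den, .Machine$double.eps)
}

rand_ct <- function(dims, axes, seed = 1) {
  set.seed(seed)
  ctensor(array(complex(real = stats::rnorm(prod(dims)),
                        imaginary = stats::rnorm(prod(dims))), dims), axes)
}

# brute-force SFC contraction: explicit loop over every index tuple
sfc_apply_loop <- function(x, w, spec) {
  xa <- ct_axes(x)
  d <- ct_dim(x)
  fc <- spec$fc_axes
  out_ax <- unname(spec$out_names[fc])
  nonc <- xa[!(xa %in% fc)]
  od <- c(unname(d[nonc]), unname(spec$out_lengths[fc]))
  out <- array(0+0i, od)
  oaxes <- c(nonc, out_ax)
  wa <- ct_axes(w)
  # iterate over all (output index, contracted index) combinations
  oidx <- as.matrix(expand.grid(lapply(od, seq_len)))
  cidx <- as.matrix(expand.grid(lapply(unname(spec$axes[fc]), seq_len)))
  for (r in seq_len(nrow(oidx))) {
    oi <- oidx[r, ]
    names(oi) <- oaxes
    acc <- 0+0i
    for (s in seq_len(nrow(cidx))) {
      ci <- cidx[s, ]
      names(ci) <- fc
      xi <- integer(length(xa)); names(xi) <- xa
      xi[nonc] <- oi[nonc]; xi[fc] <- ci
      wi <- integer(length(wa)); names(wi) <- wa
      wi[paste0(fc, "_in")] <- ci
      wi[paste0(fc, "_out")] <- oi[out_ax]
      ind <- spec$ind_axes
      if (length(ind)) wi[ind] <- oi[ind]
      acc <- acc + unclass(x)[matrix(xi[xa], 1)] *
        unclass(w)[matrix(wi[wa], 1)]
    }
    out[matrix(unname(oi), 1)] <- acc
  }
  ctensor(out, oaxes)
}

# small spiral instance shared by several tests
toy_spiral_net <- function(id = "k_plus_i_mln", n = 8, n_ch = 2, n_ts = 2,
                           n_n = 3, seed = 5) {
  traj <- make_spiral(n, 5 * n, 0.01)
  ts <- topology_spec(id, n = n, n_ch = n_ch, n_ts = n_ts, n_n = n_n,
                      seed = seed)
  build_topology(ts, traj = traj)
}

flat_coil_fm <- function(n, mask = matrix(1L, n, n)) {
  forward_model(array(1+0i, c(n, n, 1)), mask = mask)
}
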