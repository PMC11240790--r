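# Shared fixtures: tiny phantoms and geometry used across test files.

phantom_geom_small <- function() phantom_geometry()

small_tumor_case <- function(seed = 11) {
  generate_case(phantom_params(shape = c(48, 48, 48), has_tumor = TRUE,
                               seed = seed))
}

small_control_case <- function(seed = 12) {
  generate_case(phantom_params(shape = c(48, 48, 48), seed = seed))
}

# independent pure-R flood-fill labelling, used as the oracle against the
# package's compiled component labelling
flood_fill_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  m <- rowSums(abs(offs))
  offs <- offs[m > 0 & m <= switch(as.character(connectivity),
                                   "6" = 1, "18" = 2, "26" = 3), , drop = FALSE]
  lab <- array(0L, dim = d)
  nxt <- 0L
  for (v in which(mask != 0)) {
    if (lab[v] != 0L) next
    nxt <- nxt + 1L
    queue <- integer(sum(mask != 0)); queue[1] <- v; head <- 1L; tail <- 1L
    lab[v] <- nxt
    while (head <= tail) {
      cur <- queue[head]; head <- head + 1L
      p <- arrayInd(cur, d)
      for (r in seq_len(nrow(offs))) {
        q <- p + offs[r, ]
        if (any(q < 1) || any(q > d)) next
        li <- q[1] + d[1] * ((q[2] - 1) + d[2] * (q[3] - 1))
        if (mask[li] != 0 && lab[li] == 0L) {
          lab[li] <- nxt
          tail <- tail + 1L; queue[tail] <- li
        }
      }
    }
  }
  lab
}

# brute-force per-voxel sliding-window accumulation oracle
brute_force_sliding <- function(model, input, spec) {
  d <- dim(input)[1:3]
  pos <- tile_positions(d, spec)
  acc <- NULL; cnt <- array(0, dim = d)
  for (r in seq_len(nrow(pos))) {
    s <- pos[r, ]
    ix <- (s[1] + 1):(s[1] + spec$patch_size[1])
    iy <- (s[2] + 1):(s[2] + spec$patch_size[2])
    iz <- (s[3] + 1):(s[3] + spec$patch_size[3])
    p <- predict_proba(model, input[ix, iy, iz, , drop = FALSE])
    if (is.null(acc)) acc <- array(0, dim = c(d, dim(p)[4]))
    for (c in seq_len(dim(p)[4]))
      acc[ix, iy, iz, c] <- acc[ix, iy, iz, c] + p[, , , c]
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1
  }
  for (c in seq_len(dim(acc)[4])) acc[, , , c] <- acc[, , , c] / cnt
  acc
}
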