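#' Sliding-window tiling specification
#'
#' Fixed patch size and stride for patch-based inference (full-scale
#' defaults: 128x128x64 patches at stride 32x32x32 for the pancreas stages,
#' 128x128x128 for the duct stages).
#'
#' @param patch_size integer length-3.
#' @param stride integer length-3, `1 <= stride <= patch_size` per axis.
#' @return A `pd_tiling_spec`.
#' @export
tiling_spec <- function(patch_size, stride) {
  patch_size <- as.integer(patch_size); stride <- as.integer(stride)
  if (length(patch_size) != 3L || length(stride) != 3L)
    stop("patch_size and stride must each have 3 components")
  if (any(stride < 1L) || any(stride > patch_size))
    stop("stride must satisfy 1 <= stride <= patch_size per axis")
  structure(list(patch_size = patch_size, stride = stride),
            class = "pd_tiling_spec")
}

#' Patch start positions covering a volume
#'
#' Per axis the starts are `0, stride, 2*stride, ...` plus a final start
#' clamped to `shape - patch` so the last patch is flush with the boundary;
#' the full grid is the cartesian product, and every voxel is covered by at
#' least one patch.
#'
#' @param volume_shape integer length-3, must be >= patch_size per axis.
#' @param spec a [tiling_spec()].
#' @return integer matrix, one 0-based (i, j, k) start per row.
#' @export
tile_positions <- function(volume_shape, spec) {
  stopifnot(inherits(spec, "pd_tiling_spec"))
  volume_shape <- as.integer(volume_shape)
  ax <- c("x", "y", "z")
  starts <- lapply(1:3, function(a) {
    if (volume_shape[a] < spec$patch_size[a])
      stop(sprintf("volume extent %d < patch size %d along axis %s",
                   volume_shape[a], spec$patch_size[a], ax[a]))
    last <- volume_shape[a] - spec$patch_size[a]
    unique(c(seq(0L, last, by = spec$stride[a]), last))
  })
  g <- expand.grid(i = starts[[1]], j = starts[[2]], k = starts[[3]])
  as.matrix(g)
}

# symmetric padding so a volume smaller than a patch can be processed;
# returns the padded array and the offset of the original volume inside it
pad_to_patch <- function(x, patch_size, fill) {
  d <- dim(x)[1:3]
  need <- pmax(patch_size - d, 0L)
  lo <- need %/% 2L
  if (all(need == 0L)) return(list(x = x, offset = c(0L, 0L, 0L)))
  nd <- c(pmax(d, patch_size), dim(x)[4])
  out <- array(fill, dim = nd)
  out[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]), lo[3] + seq_len(d[3]), ] <- x
  list(x = out, offset = lo)
}

#' Sliding-window prediction over a large volume
#'
#' Tiles the volume per [tile_positions()], predicts each patch, and averages
#' the per-patch probabilities voxel-wise over all patches covering a voxel
#' (unweighted arithmetic mean). Volumes smaller than a patch are padded
#' symmetrically with `pad_value` and un-padded after prediction.
#'
#' @param model a model accepted by [predict_proba()].
#' @param input 3D or 4D (x, y, z, channel) array.
#' @param spec a [tiling_spec()].
#' @param pad_value fill for padding (0 = window minimum on normalized CT).
#' @return 4D probability array with the input's spatial shape.
#' @export
sliding_window_predict <- function(model, input, spec, pad_value = 0) {
  x <- as_input4d(input)
  orig <- dim(x)[1:3]
  padded <- pad_to_patch(x, spec$patch_size, pad_value)
  x <- padded$x
  d <- dim(x)[1:3]
  pos <- tile_positions(d, spec)
  out_ch <- NULL
  acc <- NULL; cnt <- array(0, dim = d)
  ps <- spec$patch_size
  for (r in seq_len(nrow(pos))) {
    s <- pos[r, ]
    ix <- (s[1] + 1):(s[1] + ps[1]); iy <- (s[2] + 1):(s[2] + ps[2])
    iz <- (s[3] + 1):(s[3] + ps[3])
    patch <- x[ix, iy, iz, , drop = FALSE]
    p <- predict_proba(model, patch)
    if (is.null(acc)) {
      out_ch <- dim(p)[4]
      acc <- array(0, dim = c(d, out_ch))
    }
    acc[ix, iy, iz, ] <- acc[ix, iy, iz, , drop = FALSE] + p
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1
  }
  for (c in seq_len(out_ch)) acc[, , , c] <- acc[, , , c] / cnt
  off <- padded$offset
  acc[off[1] + seq_len(orig[1]), off[2] + seq_len(orig[2]),
      off[3] + seq_len(orig[3]), , drop = FALSE]
}

#' Threshold a probability grid
#' @param prob array with values in `[0, 1]`.
#' @param threshold inclusive: voxels with `prob >= threshold` become 1.
#' @return 0/1 array of the same shape.
#' @export
binarize <- function(prob, threshold) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  array(as.numeric(prob >= threshold), dim = dim(prob))
}

#' Label connected components of a binary mask
#' @param mask 3D 0/1 array.
#' @param connectivity 6, 18 or 26.
#' @return integer array of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 26) {
  mask <- as.array(mask)
  d <- dim(mask)
  cc_label3d(as.logical(mask), d[1], d[2], d[3], as.integer(connectivity))
}

#' Keep only the largest connected component
#'
#' Stabilizes the coarse pancreas segmentation against speckle before taking
#' its centroid. Ties are broken in favour of the component whose smallest
#' (i, j, k) voxel is lexicographically first; an empty mask stays empty.
#'
#' @param mask 3D 0/1 array.
#' @param connectivity 6, 18 or 26.
#' @return 0/1 array retaining exactly one component.
#' @export
largest_component <- function(mask, connectivity = 26) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(array(0, dim = dim(lab)))
  counts <- tabulate(lab)
  best <- which(counts == max(counts))
  if (length(best) > 1L) {
    # lexicographic (i, j, k) seed voxel per tied component
    dl <- dim(lab)
    keys <- vapply(best, function(b) {
      w <- which(lab == b, arr.ind = TRUE)
      w <- w[order(w[, 1], w[, 2], w[, 3]), , drop = FALSE]
      ((w[1, 1] - 1) * dl[2] + (w[1, 2] - 1)) * dl[3] + (w[1, 3] - 1)
    }, numeric(1))
    best <- best[which.min(keys)]
  }
  array(as.numeric(lab == best), dim = dim(lab))
}

#' Binary dilation/erosion with a Euclidean ball
#' @param mask 3D 0/1 array.
#' @param radius integer radius in voxels.
#' @param op `"dilate"` or `"erode"`.
#' @return 0/1 array.
#' @export
morph_ball <- function(mask, radius, op = c("dilate", "erode")) {
  op <- match.arg(op)
  d <- dim(mask)
  out <- morph3d(as.logical(mask), d[1], d[2], d[3], as.integer(radius),
                 op == "dilate")
  array(as.numeric(out), dim = d)
}
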