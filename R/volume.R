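#' 3D volume and label-map containers
#'
#' A `pd_volume` carries a 3D scalar grid (Hounsfield units or normalized
#' intensity) plus its voxel spacing in mm and the world position of voxel
#' (0,0,0). A `pd_labelmap` carries one binary channel per anatomical
#' structure on the same grid, so overlapping structures (a duct running
#' inside the pancreas) are representable. All voxel indices in this API are
#' 0-based and boxes are half-open `[start, start + size)`.
#'
#' @param data 3D numeric array (volume) or 4D array, x-y-z-channel (labelmap).
#' @param spacing numeric length-3, mm per voxel, all > 0.
#' @param origin numeric length-3, world position (mm) of voxel (0,0,0).
#' @return A `pd_volume` object.
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("volume data must have exactly 3 axes")
  if (any(dim(data) < 1L)) stop("every axis must have extent >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive numbers (mm)")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "pd_volume")
}

#' @param label_names character vector naming the channels of `data`
#'   (e.g. pancreas, pancreatic_duct, common_bile_duct, tumor).
#' @rdname volume
#' @export
labelmap <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     label_names) {
  data <- as.array(data)
  if (length(dim(data)) != 4L) stop("labelmap data must be 4D (x, y, z, channel)")
  if (length(label_names) != dim(data)[4])
    stop("label_names must name every channel")
  storage.mode(data) <- "double"
  if (any(!data %in% c(0, 1))) stop("labelmap channels must be binary")
  spacing <- as.numeric(spacing)
  if (any(spacing <= 0)) stop("spacing must be positive")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin),
                 label_names = as.character(label_names)),
            class = "pd_labelmap")
}

#' @export
print.pd_volume <- function(x, ...) {
  cat(sprintf("<pd_volume> %s voxels @ (%s) mm, range [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, digits = 4), collapse = ", "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.pd_labelmap <- function(x, ...) {
  counts <- apply(x$data, 4, sum)
  cat(sprintf("<pd_labelmap> %s voxels @ (%s) mm\n",
              paste(dim(x$data)[1:3], collapse = "x"),
              paste(format(x$spacing, digits = 4), collapse = ", ")))
  for (i in seq_along(x$label_names))
    cat(sprintf("  %-18s %d voxels\n", x$label_names[i], as.integer(counts[i])))
  invisible(x)
}

#' Extract one structure's binary mask from a labelmap
#' @param lm a `pd_labelmap`.
#' @param name structure name, one of `lm$label_names`.
#' @return 3D 0/1 array.
#' @export
label_mask <- function(lm, name) {
  stopifnot(inherits(lm, "pd_labelmap"))
  i <- match(name, lm$label_names)
  if (is.na(i)) stop("unknown structure: ", name)
  lm$data[, , , i, drop = TRUE]
}

#' Voxel crop bookkeeping
#'
#' Records where a crop came from: the (possibly negative, 0-based) start
#' index into the source grid, the crop size, and the source shape, so crops
#' can be pasted back. The half-open box must intersect the source grid.
#'
#' @param start integer length-3, 0-based; may be negative when padding occurred.
#' @param size integer length-3, all > 0.
#' @param source_shape integer length-3 shape of the source grid.
#' @return A `pd_crop_region`.
#' @export
crop_region <- function(start, size, source_shape) {
  start <- as.integer(start); size <- as.integer(size)
  source_shape <- as.integer(source_shape)
  if (any(size <= 0L)) stop("crop size components must be > 0")
  if (any(start >= source_shape) || any(start + size <= 0L))
    stop("crop box does not intersect the source grid")
  structure(list(start = start, size = size, source_shape = source_shape),
            class = "pd_crop_region")
}

# ---- NIfTI I/O -------------------------------------------------------------

#' Read a CT volume from a NIfTI file
#'
#' Spacing and origin are taken from the file geometry; intensities are left
#' untouched. Only 3D images are accepted.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [volume()].
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("expected a 3D image, got ", length(d), " axes: ", path)
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3L || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0))
    stop("non-invertible geometry (bad pixdim) in ", path)
  aff <- RNifti::xform(img)
  volume(array(as.numeric(img), dim = d), spacing = sp[1:3], origin = aff[1:3, 4])
}

#' Write a volume to NIfTI
#' @param v a [volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "pd_volume"))
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  aff <- diag(4); diag(aff)[1:3] <- v$spacing; aff[1:3, 4] <- v$origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read/write a multi-channel labelmap (4D uint8 NIfTI + JSON sidecar)
#'
#' Channels are stored along the 4th NIfTI dimension as unsigned 8-bit; a
#' sidecar `<path>.json` names the channels.
#'
#' @param lm a [labelmap()].
#' @param path output path.
#' @export
write_labelmap <- function(lm, path) {
  stopifnot(inherits(lm, "pd_labelmap"))
  img <- RNifti::asNifti(lm$data)
  RNifti::pixdim(img) <- c(lm$spacing, 1)
  RNifti::writeNifti(img, path, datatype = "uint8")
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(labels = lm$label_names, origin = lm$origin),
                       side, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_labelmap
#' @export
load_labelmap <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) stop("expected a 4D labelmap: ", path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (!file.exists(side)) stop("missing label sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  sp <- RNifti::pixdim(img)[1:3]
  labelmap(array(as.numeric(img), dim = d), spacing = sp,
           origin = if (!is.null(meta$origin)) meta$origin else c(0, 0, 0),
           label_names = meta$labels)
}

# ---- resampling and intensity normalization --------------------------------

round_half_up <- function(x) floor(x + 0.5)

# gather with trilinear or nearest interpolation at continuous 0-based
# source indices (vectors cx, cy, cz of equal length)
interp_gather <- function(arr, cx, cy, cz, mode) {
  d <- dim(arr)
  clamp <- function(v, hi) pmin(pmax(v, 0), hi)
  if (mode == "nearest") {
    ix <- clamp(round_half_up(cx), d[1] - 1)
    iy <- clamp(round_half_up(cy), d[2] - 1)
    iz <- clamp(round_half_up(cz), d[3] - 1)
    return(arr[cbind(ix + 1, iy + 1, iz + 1)])
  }
  cx <- clamp(cx, d[1] - 1); cy <- clamp(cy, d[2] - 1); cz <- clamp(cz, d[3] - 1)
  x0 <- pmin(floor(cx), d[1] - 2 + (d[1] == 1)); fx <- cx - x0
  y0 <- pmin(floor(cy), d[2] - 2 + (d[2] == 1)); fy <- cy - y0
  z0 <- pmin(floor(cz), d[3] - 2 + (d[3] == 1)); fz <- cz - z0
  x1 <- pmin(x0 + 1, d[1] - 1); y1 <- pmin(y0 + 1, d[2] - 1); z1 <- pmin(z0 + 1, d[3] - 1)
  g <- function(ix, iy, iz) arr[cbind(ix + 1, iy + 1, iz + 1)]
  (1 - fz) * ((1 - fy) * ((1 - fx) * g(x0, y0, z0) + fx * g(x1, y0, z0)) +
              fy       * ((1 - fx) * g(x0, y1, z0) + fx * g(x1, y1, z0))) +
  fz       * ((1 - fy) * ((1 - fx) * g(x0, y0, z1) + fx * g(x1, y0, z1)) +
              fy       * ((1 - fx) * g(x0, y1, z1) + fx * g(x1, y1, z1)))
}

resample_grid <- function(arr, in_spacing, target_spacing, mode) {
  in_shape <- dim(arr)
  out_shape <- pmax(1, round_half_up(in_shape * in_spacing / target_spacing))
  # voxel i center sits at world origin + i * spacing; sample the source there
  cx <- (seq_len(out_shape[1]) - 1) * target_spacing[1] / in_spacing[1]
  cy <- (seq_len(out_shape[2]) - 1) * target_spacing[2] / in_spacing[2]
  cz <- (seq_len(out_shape[3]) - 1) * target_spacing[3] / in_spacing[3]
  grid <- expand.grid(cx = cx, cy = cy, cz = cz)
  vals <- interp_gather(arr, grid$cx, grid$cy, grid$cz, mode)
  array(vals, dim = out_shape)
}

#' Resample a volume or labelmap to a new voxel spacing
#'
#' The cascade runs at two working resolutions: a low-resolution grid at
#' twice the target spacing for pancreas localization and a high-resolution
#' grid for everything downstream. Output shape is
#' `round(shape * spacing / target_spacing)` (half-up, min 1 per axis);
#' intensities are interpolated linearly, labels with nearest neighbour.
#'
#' @param v a [volume()] or [labelmap()].
#' @param target_spacing numeric length-3, mm, all > 0.
#' @param mode `"linear"` or `"nearest"`; labelmaps always use nearest.
#' @return resampled object of the same class.
#' @export
resample <- function(v, target_spacing, mode = c("linear", "nearest")) {
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(target_spacing <= 0))
    stop("target_spacing must be three positive numbers")
  if (isTRUE(all.equal(v$spacing, target_spacing, tolerance = 1e-12)))
    return(v)
  if (inherits(v, "pd_labelmap")) {
    chans <- lapply(seq_len(dim(v$data)[4]), function(i)
      resample_grid(v$data[, , , i, drop = TRUE], v$spacing, target_spacing, "nearest"))
    return(labelmap(array(unlist(chans, use.names = FALSE), dim = c(dim(chans[[1]]), length(chans))),
                    spacing = target_spacing, origin = v$origin,
                    label_names = v$label_names))
  }
  stopifnot(inherits(v, "pd_volume"))
  mode <- match.arg(mode)
  volume(resample_grid(v$data, v$spacing, target_spacing, mode),
         spacing = target_spacing, origin = v$origin)
}

#' Window and normalize CT intensities
#'
#' Clips Hounsfield units to the soft-tissue window `[-87, 199]` and rescales
#' affinely to `[0, 1]`, the network input range.
#'
#' @param v a [volume()] in HU.
#' @param window numeric length-2 `(lo, hi)`, `lo < hi`.
#' @return A [volume()] with intensities in `[0, 1]`.
#' @export
normalize_hu <- function(v, window = c(-87, 199)) {
  stopifnot(inherits(v, "pd_volume"))
  if (length(window) != 2L || window[1] >= window[2])
    stop("window must be (lo, hi) with lo < hi")
  d <- pmin(pmax(v$data, window[1]), window[2])
  volume((d - window[1]) / (window[2] - window[1]),
         spacing = v$spacing, origin = v$origin)
}

# ---- crop / paste ----------------------------------------------------------

# gather a half-open box [start, start+size) from a 3D array, filling
# out-of-bounds voxels
gather_box <- function(arr, start, size, fill) {
  d <- dim(arr)
  out <- array(fill, dim = size)
  lo <- pmax(start, 0L); hi <- pmin(start + size, d)      # source range
  if (any(lo >= hi)) return(out)
  out[(lo[1] - start[1] + 1):(hi[1] - start[1]),
      (lo[2] - start[2] + 1):(hi[2] - start[2]),
      (lo[3] - start[3] + 1):(hi[3] - start[3])] <-
    arr[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2], (lo[3] + 1):hi[3]]
  out
}

#' Extract a fixed-size crop around a voxel
#'
#' Crops a `size` box centred on `center` (start = center - size %/% 2);
#' voxels falling outside the source grid are set to `fill`. Used to cut the
#' high-resolution region around the pancreas centre for the fine, duct and
#' tumor stages.
#'
#' @param v a [volume()] or [labelmap()].
#' @param center integer length-3, 0-based voxel index, inside the grid.
#' @param size integer length-3 crop shape.
#' @param fill scalar for out-of-bounds voxels (0 for labels and for
#'   normalized CT, where 0 is the window minimum).
#' @return `list(volume = cropped object, region = `[crop_region()]`)`.
#' @export
extract_crop <- function(v, center, size, fill = 0) {
  center <- as.integer(center); size <- as.integer(size)
  shp <- if (inherits(v, "pd_labelmap")) dim(v$data)[1:3] else dim(v$data)
  if (any(center < 0L) || any(center >= shp))
    stop("crop center outside the source grid")
  start <- center - size %/% 2L
  region <- crop_region(start, size, shp)
  if (inherits(v, "pd_labelmap")) {
    chans <- lapply(seq_len(dim(v$data)[4]), function(i)
      gather_box(v$data[, , , i, drop = TRUE], start, size, 0))
    out <- labelmap(array(unlist(chans, use.names = FALSE), dim = c(size, length(chans))),
                    spacing = v$spacing, origin = v$origin,
                    label_names = v$label_names)
  } else {
    out <- volume(gather_box(v$data, start, size, fill),
                  spacing = v$spacing,
                  origin = v$origin + start * v$spacing)
  }
  list(volume = out, region = region)
}

#' Paste a crop back into source geometry
#'
#' Inverse of [extract_crop()]: copies in-bounds crop voxels to their source
#' positions (out-of-bounds crop voxels are dropped) on a `background`-valued
#' grid. Used to lift crop-space tumor probability maps back to scan space.
#'
#' @param target_shape integer length-3, must equal `region$source_shape`.
#' @param crop 3D array or [volume()] of shape `region$size`.
#' @param region the [crop_region()] returned by [extract_crop()].
#' @param background scalar fill for voxels not covered by the crop.
#' @return 3D array of shape `target_shape`.
#' @export
paste_crop <- function(target_shape, crop, region, background = 0) {
  stopifnot(inherits(region, "pd_crop_region"))
  target_shape <- as.integer(target_shape)
  if (!all(target_shape == region$source_shape))
    stop("target_shape does not match the crop's source_shape")
  arr <- if (inherits(crop, "pd_volume")) crop$data else as.array(crop)
  if (!all(dim(arr) == region$size)) stop("crop shape does not match region size")
  out <- array(background, dim = target_shape)
  start <- region$start
  lo <- pmax(start, 0L); hi <- pmin(start + region$size, target_shape)
  if (any(lo >= hi)) return(out)
  out[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2], (lo[3] + 1):hi[3]] <-
    arr[(lo[1] - start[1] + 1):(hi[1] - start[1]),
        (lo[2] - start[2] + 1):(hi[2] - start[2]),
        (lo[3] - start[3] + 1):(hi[3] - start[3])]
  out
}

#' Carry a voxel index between two grids
#'
#' Maps a 0-based voxel index from one spacing/origin to the nearest voxel of
#' another, via world coordinates. Used to carry the coarse-grid pancreas
#' centre onto the high-resolution grid.
#'
#' @param index integer length-3, 0-based.
#' @param from_spacing,to_spacing mm per voxel on each grid.
#' @param from_origin,to_origin world position of each grid's voxel (0,0,0).
#' @return integer length-3 index on the target grid.
#' @export
map_index_between_spacings <- function(index, from_spacing, to_spacing,
                                       from_origin = c(0, 0, 0),
                                       to_origin = c(0, 0, 0)) {
  if (any(from_spacing <= 0) || any(to_spacing <= 0))
    stop("spacings must be positive")
  world <- from_origin + as.numeric(index) * from_spacing
  as.integer(round_half_up((world - to_origin) / to_spacing))
}
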