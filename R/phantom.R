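#' Phantom generation parameters
#'
#' Parameters of the synthetic abdominal CT phantom: a curved ellipsoidal
#' pancreas-like organ spanning the volume laterally, a thin pancreatic duct
#' along its axis, a common bile duct entering the head region from above,
#' and optionally a spherical head tumor. A tumor obstructs both ducts: the
#' visible duct terminates at the tumor surface (ductal interruption) and the
#' remaining upstream (tail-ward / liver-ward) duct is dilated by
#' `duct_dilation_factor`. Tumor attenuation classes shift the tumor mean by
#' `tumor_hu_offset` relative to the pancreas: hypo -30 HU, iso 0 HU,
#' hyper +30 HU, mirroring hypo-/iso-/hyper-attenuating lesions (iso tumors
#' are invisible by intensity alone, which is exactly why the duct channels
#' carry signal). Additive Gaussian acquisition noise is applied to the CT
#' only, never to the labels.
#'
#' @param shape integer length-3 grid shape in voxels.
#' @param spacing mm per voxel.
#' @param has_tumor logical.
#' @param tumor_radius_mm tumor sphere radius; must fit inside the head.
#' @param tumor_attenuation_class `"hypo"`, `"iso"` or `"hyper"`.
#' @param tumor_hu_offset HU added to pancreas mean inside the tumor;
#'   defaults to -30/0/+30 by class and must be 0 iff the class is `"iso"`.
#' @param duct_dilation_factor multiplier (>= 1) on duct radii upstream of
#'   the tumor; forced to 1 when `has_tumor` is `FALSE`.
#' @param duct_radius_mm baseline pancreatic-duct radius (mm); the common
#'   bile duct is drawn 25% wider.
#' @param noise_sd_hu Gaussian noise standard deviation (HU).
#' @param background_hu,pancreas_hu,duct_hu mean tissue intensities (HU).
#' @param seed integer RNG seed; generation is bit-reproducible.
#' @return A `pd_phantom_params` list.
#' @export
phantom_params <- function(shape = c(64, 64, 64), spacing = c(1, 1, 1),
                           has_tumor = FALSE, tumor_radius_mm = 6,
                           tumor_attenuation_class = c("hypo", "iso", "hyper"),
                           tumor_hu_offset = NULL,
                           duct_dilation_factor = if (has_tumor) 1.8 else 1,
                           duct_radius_mm = 1.6,
                           noise_sd_hu = 10,
                           background_hu = 40, pancreas_hu = 80, duct_hu = 10,
                           seed = 1L) {
  tumor_attenuation_class <- match.arg(tumor_attenuation_class)
  if (is.null(tumor_hu_offset))
    tumor_hu_offset <- c(hypo = -30, iso = 0, hyper = 30)[[tumor_attenuation_class]]
  if ((tumor_hu_offset == 0) != (tumor_attenuation_class == "iso"))
    stop("tumor_hu_offset must be 0 exactly for the iso class")
  if (!has_tumor) duct_dilation_factor <- 1
  if (duct_dilation_factor < 1) stop("duct_dilation_factor must be >= 1")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 has_tumor = isTRUE(has_tumor),
                 tumor_radius_mm = tumor_radius_mm,
                 tumor_attenuation_class = tumor_attenuation_class,
                 tumor_hu_offset = tumor_hu_offset,
                 duct_dilation_factor = duct_dilation_factor,
                 duct_radius_mm = duct_radius_mm,
                 noise_sd_hu = noise_sd_hu,
                 background_hu = background_hu, pancreas_hu = pancreas_hu,
                 duct_hu = duct_hu, seed = as.integer(seed)),
            class = "pd_phantom_params")
}

# union of spheres along a polyline: marks voxels within radii[i] mm of
# point P[i,]; only the local bounding box of each sphere is touched
.tube_mask <- function(shape, spacing, P, radii) {
  mask <- array(FALSE, dim = shape)
  for (i in seq_len(nrow(P))) {
    r <- radii[i]
    lo <- pmax(1L, as.integer(floor((P[i, ] - r) / spacing)) + 1L)
    hi <- pmin(shape, as.integer(ceiling((P[i, ] + r) / spacing)) + 1L)
    if (any(lo > hi)) next
    xs <- (lo[1]:hi[1] - 1) * spacing[1] - P[i, 1]
    ys <- (lo[2]:hi[2] - 1) * spacing[2] - P[i, 2]
    zs <- (lo[3]:hi[3] - 1) * spacing[3] - P[i, 3]
    d2 <- outer(outer(xs^2, ys^2, `+`), zs^2, `+`)
    mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
      mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] | (d2 <= r^2)
  }
  mask
}

.structure_names <- c("pancreas", "pancreatic_duct", "common_bile_duct", "tumor")

#' Generate one synthetic CT case
#'
#' Deterministic for a fixed seed (bit-exact). Geometry, in mm: the pancreas
#' axis is a sine-curved polyline spanning 10--90% of the x extent with the
#' head at the low-x end; the organ is the union of spheres along the axis
#' with the radius profile widest at the head. The pancreatic duct follows
#' the same axis; the common bile duct descends from the top of the volume
#' into the head, meeting the axis there. With a tumor, a sphere of
#' `tumor_radius_mm` is planted on the axis in the head, both ducts stop at
#' its surface, and the remaining upstream duct radii are multiplied by
#' `duct_dilation_factor`.
#'
#' @param params a [phantom_params()].
#' @param case_id identifier stored in the result.
#' @return A `pd_phantom_case`: `ct` ([volume()], HU), `labels`
#'   ([labelmap()]), `params`, `case_id`.
#' @export
generate_case <- function(params, case_id = sprintf("case_%06d", params$seed)) {
  stopifnot(inherits(params, "pd_phantom_params"))
  p <- params
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(p$seed)

  ext <- p$shape * p$spacing                      # physical extent, mm

  # pancreas axis: head at low x
  nseg <- 64L
  tt <- seq(0, 1, length.out = nseg)
  axis_pts <- cbind(x = (0.10 + 0.80 * tt) * ext[1],
                    y = 0.5 * ext[2] + 0.10 * ext[2] * sin(pi * tt),
                    z = 0.5 * ext[3] + 0.04 * ext[3] * (tt - 0.5))
  r_min <- 0.12 * min(ext[2], ext[3])
  organ_r <- r_min * (1.6 - 0.8 * tt)             # widest at the head (t = 0)

  head_t_max <- 0.25                               # head = first quarter of the axis
  t_tumor <- 0.12                                  # tumor centre parameter
  i_tumor <- which.min(abs(tt - t_tumor))
  tumor_c <- axis_pts[i_tumor, ]
  r_head <- organ_r[i_tumor]
  if (p$has_tumor && p$tumor_radius_mm > r_head * 1.25)
    stop(sprintf("tumor radius %.1f mm exceeds the head region (max %.1f mm)",
                 p$tumor_radius_mm, r_head * 1.25))

  organ <- .tube_mask(p$shape, p$spacing, axis_pts, organ_r)

  tumor <- array(FALSE, dim = p$shape)
  if (p$has_tumor)
    tumor <- .tube_mask(p$shape, p$spacing, matrix(tumor_c, 1),
                        p$tumor_radius_mm)

  # pancreatic duct along the axis; with a tumor the visible duct is the
  # upstream (tail-ward) segment, dilated, terminating at the tumor surface
  pd_r <- rep(p$duct_radius_mm, nseg)
  keep <- rep(TRUE, nseg)
  if (p$has_tumor) {
    up <- tt >= t_tumor
    pd_r[up] <- pd_r[up] * p$duct_dilation_factor
    dist_tc <- sqrt(rowSums(sweep(axis_pts, 2, tumor_c)^2))
    keep <- up & dist_tc >= p$tumor_radius_mm
  }
  pduct <- .tube_mask(p$shape, p$spacing, axis_pts[keep, , drop = FALSE],
                      pd_r[keep])
  if (p$has_tumor) pduct <- pduct & !tumor

  # common bile duct: from the top of the volume down into the head
  cbd_entry <- c(tumor_c[1] + 0.08 * ext[1], 0.40 * ext[2], 0.92 * ext[3])
  cbd_end <- tumor_c
  ss <- seq(0, 1, length.out = 48L)
  cbd_pts <- cbind(cbd_entry[1] + ss * (cbd_end[1] - cbd_entry[1]),
                   cbd_entry[2] + ss * (cbd_end[2] - cbd_entry[2]),
                   cbd_entry[3] + ss * (cbd_end[3] - cbd_entry[3]))
  cbd_r <- rep(1.25 * p$duct_radius_mm, length(ss))
  keep_c <- rep(TRUE, length(ss))
  if (p$has_tumor) {
    cbd_r <- cbd_r * p$duct_dilation_factor
    dist_tc <- sqrt(rowSums(sweep(cbd_pts, 2, tumor_c)^2))
    keep_c <- dist_tc >= p$tumor_radius_mm
  }
  cbd <- .tube_mask(p$shape, p$spacing, cbd_pts[keep_c, , drop = FALSE],
                    cbd_r[keep_c])
  if (p$has_tumor) cbd <- cbd & !tumor

  pancreas <- organ | tumor

  ct <- array(p$background_hu, dim = p$shape)
  ct[pancreas] <- p$pancreas_hu
  ct[pduct] <- p$duct_hu
  ct[cbd] <- p$duct_hu
  ct[tumor] <- p$pancreas_hu + p$tumor_hu_offset
  ct <- ct + rnorm(length(ct), 0, p$noise_sd_hu)

  lab <- array(0, dim = c(p$shape, 4L))
  lab[, , , 1] <- as.numeric(pancreas)
  lab[, , , 2] <- as.numeric(pduct)
  lab[, , , 3] <- as.numeric(cbd)
  lab[, , , 4] <- as.numeric(tumor)

  structure(list(
    ct = volume(ct, spacing = p$spacing),
    labels = labelmap(lab, spacing = p$spacing, label_names = .structure_names),
    params = p, case_id = case_id), class = "pd_phantom_case")
}

# largest-remainder apportionment of n into parts proportional to weights
largest_remainder <- function(n, weights) {
  q <- n * weights / sum(weights)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(q - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Generate a phantom cohort with a manifest
#'
#' Tumor cases are apportioned across the hypo/iso/hyper attenuation classes
#' by largest remainder from `class_mix` (default 77/14/8, the attenuation
#' mix of the modelled clinical cohort). Per-case seeds are drawn
#' deterministically from the cohort seed, and tumor radii are drawn
#' uniformly from `tumor_radius_range_mm` so the manifest records a diameter
#' for size-subgroup analyses.
#'
#' @param n_tumor,n_control case counts (>= 0).
#' @param class_mix numeric length-3 weights for (hypo, iso, hyper).
#' @param base a [phantom_params()] supplying everything not set per case.
#' @param seed cohort seed.
#' @param tumor_radius_range_mm uniform sampling range for tumor radii.
#' @return `list(cases = list of pd_phantom_case, manifest = tibble)` with
#'   manifest columns case_id, patient_id, has_tumor, class, diameter_mm, seed.
#' @export
generate_cohort <- function(n_tumor, n_control,
                            class_mix = c(hypo = 77, iso = 14, hyper = 8),
                            base = phantom_params(), seed = 1L,
                            tumor_radius_range_mm = c(4.5, 7.5)) {
  if (n_tumor < 0 || n_control < 0) stop("counts must be >= 0")
  if (n_tumor + n_control == 0) stop("empty cohort")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  classes <- rep(c("hypo", "iso", "hyper"), largest_remainder(n_tumor, class_mix))
  n <- n_tumor + n_control
  case_seeds <- sample.int(2^31 - 1, n)
  radii <- runif(n, tumor_radius_range_mm[1], tumor_radius_range_mm[2])
  has_tumor <- rep(c(TRUE, FALSE), c(n_tumor, n_control))
  dil <- if (base$duct_dilation_factor > 1) base$duct_dilation_factor else 1.8
  cases <- vector("list", n)
  man <- vector("list", n)
  for (i in seq_len(n)) {
    cls <- if (has_tumor[i]) classes[i] else "hypo"
    prm <- phantom_params(shape = base$shape, spacing = base$spacing,
                          has_tumor = has_tumor[i],
                          tumor_radius_mm = radii[i],
                          tumor_attenuation_class = cls,
                          duct_dilation_factor = if (has_tumor[i]) dil else 1,
                          duct_radius_mm = base$duct_radius_mm,
                          noise_sd_hu = base$noise_sd_hu,
                          background_hu = base$background_hu,
                          pancreas_hu = base$pancreas_hu, duct_hu = base$duct_hu,
                          seed = case_seeds[i])
    id <- sprintf("case_%03d", i)
    cases[[i]] <- generate_case(prm, case_id = id)
    tum_i <- has_tumor[i]
    man[[i]] <- tibble::tibble(
      case_id = id, patient_id = sprintf("pt_%03d", i),
      has_tumor = tum_i,
      class = if (tum_i) cls else NA_character_,
      diameter_mm = if (tum_i) 2 * radii[i] else NA_real_,
      seed = case_seeds[i])
  }
  list(cases = cases, manifest = do.call(rbind, man))
}
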