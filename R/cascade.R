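# The four-stage detection workflow: coarse pancreas localization, fine
# pancreas segmentation, duct segmentation with the anatomical plausibility
# filter, secondary-feature tumor detection, fold ensembling and case
# classification.

#' Bundle of trained stage models
#'
#' Holds the per-fold models of every cascade stage together with the
#' geometry, the duct-segmentation mode, and the decision threshold. All
#' stages must have the same number of folds.
#'
#' @param coarse_pancreas,fine_pancreas,tumor lists of fold models.
#' @param ducts either a list of fold models (multi-label softmax over
#'   CBD/PD/background) or `list(cbd = ..., pd = ...)` of two single-label
#'   fold-model lists.
#' @param duct_mode `"multi"` or `"single"`.
#' @param geom a [cascade_geometry()].
#' @param threshold case-score decision threshold (default 0.61, the
#'   operating point established on the validation set at full scale).
#' @param seg_threshold intermediate binarization threshold for pancreas
#'   and duct masks (0.5).
#' @param attach_radius pancreas dilation radius (voxels) for the duct
#'   plausibility filter.
#' @param filter_which apply the plausibility filter to `"both"` ducts,
#'   `"cbd"` only, or `"none"`.
#' @param tumor_channels input channels of the tumor stage, in order.
#' @param window HU normalization window.
#' @return A `pd_stage_bundle`.
#' @export
stage_bundle <- function(coarse_pancreas, fine_pancreas, ducts, tumor,
                         duct_mode = c("multi", "single"),
                         geom = cascade_geometry(4), threshold = 0.61,
                         seg_threshold = 0.5, attach_radius = 2,
                         filter_which = c("both", "cbd", "none"),
                         tumor_channels = c("ct", "pancreas", "cbd", "pd"),
                         window = c(-87, 199)) {
  duct_mode <- match.arg(duct_mode)
  filter_which <- match.arg(filter_which)
  nf <- length(coarse_pancreas)
  duct_nf <- if (duct_mode == "multi") length(ducts) else length(ducts$cbd)
  if (duct_mode == "single" && length(ducts$cbd) != length(ducts$pd))
    stop("single mode needs matching cbd/pd fold counts")
  if (length(fine_pancreas) != nf || length(tumor) != nf || duct_nf != nf)
    stop("all stages must have the same fold count")
  structure(list(coarse_pancreas = coarse_pancreas,
                 fine_pancreas = fine_pancreas, ducts = ducts, tumor = tumor,
                 duct_mode = duct_mode, geom = geom, threshold = threshold,
                 seg_threshold = seg_threshold, attach_radius = attach_radius,
                 filter_which = filter_which, tumor_channels = tumor_channels,
                 window = window, n_folds = nf),
            class = "pd_stage_bundle")
}

#' All-oracle bundle (ground truth substituted at every stage)
#'
#' Used to verify that the cascade plumbing is exact: with oracles
#' everywhere, per-structure Dice must be 1 and calls must match the truth.
#'
#' @param geom a [cascade_geometry()].
#' @param n_folds fold multiplicity to emulate.
#' @param ... passed to [stage_bundle()].
#' @export
oracle_bundle <- function(geom = cascade_geometry(4), n_folds = 3, ...) {
  om <- function(st) lapply(seq_len(n_folds), function(f) oracle_model(st))
  stage_bundle(coarse_pancreas = om("pancreas"), fine_pancreas = om("pancreas"),
               ducts = om(c("common_bile_duct", "pancreatic_duct")),
               tumor = om("tumor"), duct_mode = "multi", geom = geom, ...)
}

condition_pancreas_not_located <- function(case_id) {
  structure(class = c("pd_pancreas_not_located", "error", "condition"),
            list(message = paste0("pancreas not located in case ", case_id),
                 call = NULL))
}

# fold-mean probability for one stage over a (possibly tiled) input.
# oracle models resolve to the ground-truth mask of their structure.
stage_fold_probs <- function(models, input, spec, gt = NULL, full = FALSE) {
  lapply(models, function(m) {
    if (is_oracle(m)) {
      if (is.null(gt)) stop("oracle models require ground truth")
      chans <- lapply(m$structures, function(s) label_mask(gt, s))
      array(unlist(chans, use.names = FALSE), dim = c(dim(chans[[1]]), length(chans)))
    } else if (full) {
      predict_proba(m, input)
    } else {
      sliding_window_predict(m, input, spec)
    }
  })
}

fold_mean <- function(grids) {
  acc <- grids[[1]]
  if (length(grids) > 1) for (i in 2:length(grids)) acc <- acc + grids[[i]]
  acc / length(grids)
}

#' Locate the pancreas on the low-resolution volume
#'
#' Resamples the CT to the low working resolution, normalizes, runs the
#' coarse fold models by sliding window, averages folds, binarizes at the
#' intermediate threshold, keeps the largest connected component and maps
#' its centroid to the high-resolution grid.
#'
#' @param ct a [volume()] in HU.
#' @param bundle a [stage_bundle()].
#' @param gt optional ground-truth [labelmap()] (native grid), required for
#'   oracle models.
#' @param case_id identifier used in error messages.
#' @return 0-based voxel index on the high-resolution grid.
#' @export
locate_pancreas <- function(ct, bundle, gt = NULL, case_id = "case") {
  geom <- bundle$geom
  low <- normalize_hu(resample(ct, geom$low_spacing, "linear"), bundle$window)
  gt_l <- if (!is.null(gt)) resample(gt, geom$low_spacing) else NULL
  spec <- tiling_spec(geom$pancreas_patch, geom$stride)
  probs <- stage_fold_probs(bundle$coarse_pancreas, low$data, spec, gt_l)
  mn <- fold_mean(probs)[, , , 1]
  mask <- largest_component(binarize(mn, bundle$seg_threshold), 26)
  if (sum(mask) == 0) stop(condition_pancreas_not_located(case_id))
  map_index_between_spacings(mask_centroid(mask), geom$low_spacing,
                             geom$high_spacing)
}

#' Fine pancreas segmentation on the high-resolution crop
#'
#' @param ct_high normalized high-resolution [volume()].
#' @param center 0-based crop centre from [locate_pancreas()].
#' @param bundle a [stage_bundle()].
#' @param gt_crop optional cropped ground truth for oracle folds.
#' @return `list(prob = fold-mean crop-shaped grid, region = crop region,
#'   crop = normalized CT crop volume)`.
#' @export
segment_pancreas_fine <- function(ct_high, center, bundle, gt_crop = NULL) {
  geom <- bundle$geom
  center <- pmin(pmax(as.integer(center), 0L), dim(ct_high$data) - 1L)
  cr <- extract_crop(ct_high, center, geom$crop_size, 0)
  spec <- tiling_spec(geom$pancreas_patch, geom$stride)
  probs <- stage_fold_probs(bundle$fine_pancreas, cr$volume$data, spec, gt_crop)
  list(prob = fold_mean(probs)[, , , 1], region = cr$region, crop = cr$volume)
}

#' Duct segmentation on the pancreas crop
#'
#' Multi mode: one softmax model with channels (CBD, PD, background); the
#' per-duct grids are the first two channels. Single mode: two independent
#' sigmoid models. Duct models tile with the (larger) duct patch size.
#'
#' @param crop normalized CT crop [volume()] (or 3D array).
#' @param bundle a [stage_bundle()].
#' @param gt_crop optional cropped ground truth for oracle folds.
#' @return `list(cbd = prob grid, pd = prob grid)` in crop shape.
#' @export
segment_ducts <- function(crop, bundle, gt_crop = NULL) {
  geom <- bundle$geom
  x <- if (inherits(crop, "pd_volume")) crop$data else as.array(crop)
  spec <- tiling_spec(pmin(geom$duct_patch, dim(x)[1:3]), geom$stride)
  if (bundle$duct_mode == "multi") {
    probs <- stage_fold_probs(bundle$ducts, x, spec, gt_crop)
    mn <- fold_mean(probs)
    if (dim(mn)[4] < 2) stop("multi-label duct model must emit >= 2 channels")
    return(list(cbd = mn[, , , 1], pd = mn[, , , 2]))
  }
  cbd <- fold_mean(stage_fold_probs(
    bundle$ducts$cbd, x, spec,
    if (!is.null(gt_crop)) gt_crop else NULL))[, , , 1]
  pd <- fold_mean(stage_fold_probs(bundle$ducts$pd, x, spec, gt_crop))[, , , 1]
  list(cbd = cbd, pd = pd)
}

#' Anatomical plausibility filter for duct segmentations
#'
#' Keeps exactly the connected components of the duct mask that originate
#' from the pancreas segmentation, operationalized as intersecting the
#' pancreas mask dilated by `attach_radius` voxels; everything else is
#' background. Output is a subset of the input and the operation is
#' idempotent.
#'
#' @param duct_mask,pancreas_mask binary arrays of identical shape.
#' @param connectivity component connectivity (26).
#' @param attach_radius dilation radius in voxels.
#' @return filtered binary duct mask.
#' @export
filter_ducts_by_pancreas <- function(duct_mask, pancreas_mask,
                                     connectivity = 26, attach_radius = 2) {
  if (!all(dim(duct_mask) == dim(pancreas_mask)))
    stop("duct and pancreas masks must share a shape")
  if (sum(duct_mask) == 0) return(array(0, dim = dim(duct_mask)))
  pan <- if (attach_radius > 0) morph_ball(pancreas_mask, attach_radius, "dilate")
         else pancreas_mask
  lab <- label_components(duct_mask, connectivity)
  keep <- sort(unique(lab[lab > 0 & pan > 0]))
  array(as.numeric(lab %in% keep & lab > 0), dim = dim(duct_mask))
}

#' Secondary-feature tumor detection on the full crop
#'
#' Stacks the CT crop with the binarized anatomy masks in the fixed,
#' documented channel order given by `bundle$tumor_channels` (default CT,
#' pancreas, CBD, PD) and runs each tumor fold model in a single full-crop
#' forward pass (the model's receptive field covers the crop; no tiling).
#'
#' @param crop normalized CT crop.
#' @param pancreas_mask,cbd_mask,pd_mask binary crop-shaped masks.
#' @param bundle a [stage_bundle()].
#' @param gt_crop optional cropped ground truth for oracle folds.
#' @return list of per-fold tumor probability grids (crop shape).
#' @export
detect_tumor <- function(crop, pancreas_mask, cbd_mask, pd_mask, bundle,
                         gt_crop = NULL) {
  x <- if (inherits(crop, "pd_volume")) crop$data else as.array(crop)
  chans <- list(ct = x, pancreas = pancreas_mask, cbd = cbd_mask, pd = pd_mask)
  sel <- chans[bundle$tumor_channels]
  if (any(!vapply(sel, function(a) all(dim(a)[1:3] == dim(x)[1:3]), logical(1))))
    stop("tumor input channels must share the crop shape")
  input <- array(unlist(sel, use.names = FALSE), dim = c(dim(x)[1:3], length(sel)))
  probs <- stage_fold_probs(bundle$tumor, input, spec = NULL, gt_crop,
                            full = TRUE)
  lapply(probs, function(p) p[, , , 1])
}

#' Fold ensemble and case classification
#'
#' Averages the per-fold tumor probability grids voxel-wise (mean before
#' max), takes the maximum voxel of the ensemble map as the case score, and
#' calls the case positive when the score reaches the threshold (inclusive).
#'
#' @param fold_grids nonempty list of per-fold tumor probability grids.
#' @param threshold decision threshold.
#' @return list: `tumor_prob` (ensemble grid), `case_score`,
#'   `per_fold_scores`, `call`.
#' @export
ensemble_and_classify <- function(fold_grids, threshold = 0.61) {
  if (!length(fold_grids)) stop("no fold predictions to ensemble")
  mn <- fold_mean(fold_grids)
  list(tumor_prob = mn, case_score = max(mn),
       per_fold_scores = vapply(fold_grids, max, numeric(1)),
       call = max(mn) >= threshold)
}

#' Patient-level score over multiple scans
#' @param scan_scores nonempty numeric vector of per-scan case scores.
#' @param rule `"max"` (default) or `"mean"`.
#' @export
patient_score <- function(scan_scores, rule = c("max", "mean")) {
  rule <- match.arg(rule)
  if (!length(scan_scores)) stop("no scan scores")
  if (rule == "max") max(scan_scores) else mean(scan_scores)
}

#' Run the full detection cascade on one CT volume
#'
#' Executes localization, fine pancreas segmentation, duct segmentation with
#' the plausibility filter, secondary-feature tumor detection, and fold
#' ensembling. When ground truth is supplied, per-structure Dice scores and
#' the localization criterion are computed in crop space. A "pancreas not
#' located" failure yields a negative call with a diagnostic flag instead of
#' an error.
#'
#' @param ct a [volume()] in HU (native grid).
#' @param bundle a [stage_bundle()].
#' @param gt optional ground-truth [labelmap()] on the CT grid.
#' @param case_id case identifier attached to results and errors.
#' @param gt_input use ground-truth pancreas/duct masks as tumor-stage
#'   inputs (the "GT input" condition) instead of predicted ones.
#' @return A `pd_detection_result`.
#' @export
run_pipeline <- function(ct, bundle, gt = NULL, case_id = "case",
                         gt_input = FALSE) {
  stopifnot(inherits(bundle, "pd_stage_bundle"))
  geom <- bundle$geom
  ct_h <- normalize_hu(resample(ct, geom$high_spacing, "linear"), bundle$window)
  gt_h <- if (!is.null(gt)) resample(gt, geom$high_spacing) else NULL

  center <- tryCatch(
    locate_pancreas(ct, bundle, gt, case_id),
    pd_pancreas_not_located = function(e) NULL)
  if (is.null(center)) {
    return(structure(list(case_id = case_id, case_score = 0, call = FALSE,
                          flags = "pancreas_not_located",
                          per_fold_scores = rep(0, bundle$n_folds),
                          tumor_prob = NULL, masks = NULL, crop_region = NULL,
                          dscs = NULL, localization_hit = NA),
                     class = "pd_detection_result"))
  }

  center <- pmin(pmax(center, 0L), dim(ct_h$data) - 1L)
  gt_crop <- if (!is.null(gt_h))
    extract_crop(gt_h, center, geom$crop_size)$volume else NULL

  fine <- segment_pancreas_fine(ct_h, center, bundle, gt_crop)
  pan_mask <- binarize(fine$prob, bundle$seg_threshold)
  ducts <- segment_ducts(fine$crop, bundle, gt_crop)
  cbd_mask <- binarize(ducts$cbd, bundle$seg_threshold)
  pd_mask <- binarize(ducts$pd, bundle$seg_threshold)
  if (bundle$filter_which %in% c("both", "cbd"))
    cbd_mask <- filter_ducts_by_pancreas(cbd_mask, pan_mask,
                                         attach_radius = bundle$attach_radius)
  if (bundle$filter_which == "both")
    pd_mask <- filter_ducts_by_pancreas(pd_mask, pan_mask,
                                        attach_radius = bundle$attach_radius)

  if (gt_input) {
    if (is.null(gt_crop)) stop("gt_input = TRUE requires ground truth")
    pan_in <- label_mask(gt_crop, "pancreas")
    cbd_in <- label_mask(gt_crop, "common_bile_duct")
    pd_in <- label_mask(gt_crop, "pancreatic_duct")
  } else {
    pan_in <- pan_mask; cbd_in <- cbd_mask; pd_in <- pd_mask
  }
  folds <- detect_tumor(fine$crop, pan_in, cbd_in, pd_in, bundle, gt_crop)
  ens <- ensemble_and_classify(folds, bundle$threshold)
  tumor_mask <- binarize(ens$tumor_prob, bundle$seg_threshold)

  dscs <- NULL; loc <- NA
  if (!is.null(gt_crop)) {
    dscs <- c(pancreas = dice(pan_mask, label_mask(gt_crop, "pancreas")),
              common_bile_duct = dice(cbd_mask, label_mask(gt_crop, "common_bile_duct")),
              pancreatic_duct = dice(pd_mask, label_mask(gt_crop, "pancreatic_duct")),
              tumor = dice(tumor_mask, label_mask(gt_crop, "tumor")))
    gt_tum <- label_mask(gt_crop, "tumor")
    loc <- if (sum(gt_tum) > 0) localization_hit(tumor_mask, gt_tum) else NA
  }
  structure(list(case_id = case_id, case_score = ens$case_score,
                 call = ens$call, per_fold_scores = ens$per_fold_scores,
                 tumor_prob = ens$tumor_prob,
                 masks = list(pancreas = pan_mask, common_bile_duct = cbd_mask,
                              pancreatic_duct = pd_mask, tumor = tumor_mask),
                 crop_region = fine$region, dscs = dscs,
                 localization_hit = loc, flags = character(0)),
            class = "pd_detection_result")
}

#' @export
print.pd_detection_result <- function(x, ...) {
  cat(sprintf("<detection> %s  score %.3f  call %s%s\n", x$case_id,
              x$case_score, if (x$call) "POSITIVE" else "negative",
              if (length(x$flags)) paste0("  [", paste(x$flags, collapse = ","), "]")
              else ""))
  if (!is.null(x$dscs))
    cat("  DSC:", paste(sprintf("%s %.3f", names(x$dscs), x$dscs),
                        collapse = ", "), "\n")
  invisible(x)
}
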