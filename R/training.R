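# Patient-level splits, the augmentation suite, patch sampling, and the
# per-stage training loop (Adam on soft-Dice + cross-entropy).

#' Patient-level train/validation/test splits
#'
#' One shared held-out test set (last fraction) plus `n_folds` independently
#' re-drawn train/validation splits of the remaining patients — the
#' "threefold bootstrapping" scheme: each fold re-samples its own 70/15
#' split, yielding three models per stage that act as separate opinions.
#' Assignment is per patient, never per scan.
#'
#' @param patient_ids character vector (duplicates collapse to one patient).
#' @param fractions train/val/test fractions of the whole cohort, summing
#'   to 1 (default 0.70/0.15/0.15).
#' @param n_folds number of re-drawn splits.
#' @param seed RNG seed; the plan is deterministic.
#' @return A `pd_split_plan`: `test` (ids), `folds` (list of
#'   `list(train=, val=)`), plus the seed and fractions.
#' @export
make_splits <- function(patient_ids, fractions = c(0.70, 0.15, 0.15),
                        n_folds = 3, seed = 1L) {
  ids <- unique(as.character(patient_ids))
  n <- length(ids)
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  n_test <- round_half_up(n * fractions[3])
  n_train <- round_half_up(n * fractions[1])
  n_val <- n - n_test - n_train
  if (n_test < 1 || n_train < 1 || n_val < 1)
    stop(sprintf("too few patients (%d) for fractions %s", n,
                 paste(fractions, collapse = "/")))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  test <- sort(sample(ids, n_test))
  pool <- setdiff(ids, test)
  folds <- lapply(seq_len(n_folds), function(f) {
    tr <- sort(sample(pool, n_train))
    list(train = tr, val = sort(setdiff(pool, tr)))
  })
  structure(list(test = test, folds = folds, seed = seed,
                 fractions = fractions), class = "pd_split_plan")
}

#' Augmentation configuration
#'
#' The spatial transforms (flip, in-plane rotation, elastic deformation) are
#' applied identically to every channel and the target, with linear
#' interpolation for intensity channels and nearest for masks. Noise touches
#' intensity channels only; erosion/dilation touches duct mask channels
#' only (simulating imperfect upstream duct segmentations fed to the tumor
#' model). All probabilities 0 gives the identity.
#'
#' @param p_flip,p_rotate,p_elastic,p_duct_morph,p_gaussian,p_poisson
#'   per-transform probabilities.
#' @param flip_axes axes (subset of 1:3) eligible for flipping.
#' @param rotation_range_deg in-plane rotation drawn uniformly in +/- range.
#' @param elastic_grid,elastic_sd displacement-grid spacing (voxels) and
#'   displacement sd (voxels).
#' @param duct_morph_radius integer radii sampled for duct erode/dilate.
#' @param gaussian_sd additive Gaussian sd in normalized intensity units.
#' @param poisson_peak photon-count scale for Poisson noise (smaller =
#'   noisier).
#' @return A `pd_augment_config`.
#' @export
augment_config <- function(p_flip = 0.5, p_rotate = 0.2, p_elastic = 0.2,
                           p_duct_morph = 0.3, p_gaussian = 0.3,
                           p_poisson = 0.15, flip_axes = 1:2,
                           rotation_range_deg = 15,
                           elastic_grid = 32, elastic_sd = 4,
                           duct_morph_radius = 1:2,
                           gaussian_sd = 0.02, poisson_peak = 60) {
  structure(as.list(environment()), class = "pd_augment_config")
}

# warp every channel of a 4D array (and a target) to new sampling coords
.warp_all <- function(channels, target, channel_types, cx, cy, cz) {
  d <- dim(channels)
  for (c in seq_len(d[4])) {
    mode <- if (channel_types[c] == "intensity") "linear" else "nearest"
    channels[, , , c] <- array(
      interp_gather(channels[, , , c, drop = TRUE], cx, cy, cz, mode), d[1:3])
  }
  dt <- dim(target)
  for (c in seq_len(dt[4]))
    target[, , , c] <- array(
      interp_gather(target[, , , c, drop = TRUE], cx, cy, cz, "nearest"), dt[1:3])
  list(channels = channels, target = target)
}

#' Apply the training augmentation suite to one sample
#'
#' @param sample `list(channels = 4D array, target = 4D mask array,
#'   channel_types = character)` with types `"intensity"`, `"mask"` or
#'   `"duct"` per channel.
#' @param cfg an [augment_config()].
#' @return augmented sample of the same structure.
#' @export
augment <- function(sample, cfg) {
  stopifnot(inherits(cfg, "pd_augment_config"))
  ch <- sample$channels; tg <- sample$target
  if (length(dim(tg)) == 3L) dim(tg) <- c(dim(tg), 1L)
  types <- sample$channel_types
  if (is.null(types) || length(types) != dim(ch)[4])
    stop("every channel must be tagged intensity/mask/duct")
  if (!all(types %in% c("intensity", "mask", "duct")))
    stop("unknown channel type; use intensity, mask or duct")
  d <- dim(ch)[1:3]

  for (ax in cfg$flip_axes) if (runif(1) < cfg$p_flip) {
    idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idx[[ax]] <- rev(idx[[ax]])
    ch <- ch[idx[[1]], idx[[2]], idx[[3]], , drop = FALSE]
    tg <- tg[idx[[1]], idx[[2]], idx[[3]], , drop = FALSE]
  }

  need_warp <- FALSE
  g <- expand.grid(x = seq_len(d[1]) - 1, y = seq_len(d[2]) - 1,
                   z = seq_len(d[3]) - 1)
  cx <- g$x; cy <- g$y; cz <- g$z
  if (runif(1) < cfg$p_rotate) {
    th <- runif(1, -cfg$rotation_range_deg, cfg$rotation_range_deg) * pi / 180
    c1 <- (d[1] - 1) / 2; c2 <- (d[2] - 1) / 2
    nx <- cos(th) * (cx - c1) - sin(th) * (cy - c2) + c1
    ny <- sin(th) * (cx - c1) + cos(th) * (cy - c2) + c2
    cx <- nx; cy <- ny
    need_warp <- TRUE
  }
  if (runif(1) < cfg$p_elastic) {
    gs <- cfg$elastic_grid
    cd <- pmax(2L, as.integer(ceiling(d / gs)) + 1L)
    for (axis in 1:3) {
      disp <- array(rnorm(prod(cd), 0, cfg$elastic_sd), dim = cd)
      up <- interp_gather(disp, g$x / gs, g$y / gs, g$z / gs, "linear")
      if (axis == 1) cx <- cx + up else if (axis == 2) cy <- cy + up
      else cz <- cz + up
    }
    need_warp <- TRUE
  }
  if (need_warp) {
    w <- .warp_all(ch, tg, types, cx, cy, cz)
    ch <- w$channels; tg <- w$target
  }

  for (c in which(types == "duct")) if (runif(1) < cfg$p_duct_morph) {
    r <- sample(cfg$duct_morph_radius, 1)
    op <- sample(c("dilate", "erode"), 1)
    ch[, , , c] <- morph_ball(ch[, , , c, drop = TRUE], r, op)
  }
  for (c in which(types == "intensity")) {
    if (runif(1) < cfg$p_gaussian)
      ch[, , , c] <- ch[, , , c] + rnorm(prod(d), 0, cfg$gaussian_sd)
    if (runif(1) < cfg$p_poisson) {
      v <- pmax(ch[, , , c, drop = TRUE], 0)
      ch[, , , c] <- array(rpois(prod(d), v * cfg$poisson_peak) /
                             cfg$poisson_peak, d)
    }
  }
  list(channels = ch, target = tg, channel_types = types)
}

#' Sample a training patch, optionally biased to foreground
#'
#' With probability `fg_fraction` the patch centre is a uniformly drawn
#' foreground voxel of the target (falling back to uniform when the target
#' is empty); otherwise uniform over the volume. The patch is clamped
#' in-bounds; volumes smaller than the patch are centred and zero-padded.
#'
#' @param channels 4D input array.
#' @param target 4D target mask array.
#' @param patch_size integer length-3.
#' @param fg_fraction probability of centring on foreground.
#' @return `list(channels, target)` cropped to `patch_size`.
#' @export
sample_patch <- function(channels, target, patch_size, fg_fraction = 0.5) {
  d <- dim(channels)[1:3]
  patch_size <- as.integer(patch_size)
  fg <- NULL
  if (runif(1) < fg_fraction) {
    nc <- dim(target)[4]
    fgsum <- target[, , , 1]
    if (nc > 1) for (c in 2:(nc - 1)) fgsum <- pmax(fgsum, target[, , , c])
    idx <- which(fgsum > 0)
    if (length(idx)) {
      v <- idx[sample.int(length(idx), 1)] - 1
      fg <- c(v %% d[1], (v %/% d[1]) %% d[2], v %/% (d[1] * d[2]))
    }
  }
  center <- if (!is.null(fg)) fg else
    c(sample.int(d[1], 1), sample.int(d[2], 1), sample.int(d[3], 1)) - 1
  start <- center - patch_size %/% 2L
  start <- pmin(pmax(start, pmin(0L, d - patch_size)), pmax(d - patch_size, 0L))
  start <- ifelse(d < patch_size, -((patch_size - d) %/% 2L), start)
  gather4 <- function(a) {
    out <- array(0, dim = c(patch_size, dim(a)[4]))
    for (c in seq_len(dim(a)[4]))
      out[, , , c] <- gather_box(a[, , , c, drop = TRUE], as.integer(start),
                                 patch_size, 0)
    out
  }
  list(channels = gather4(channels), target = gather4(target), start = start)
}

# ---- stage sample construction --------------------------------------------

# geometry shared by training and inference at one scale
#' Cascade geometry (working resolutions, crop and patch sizes)
#'
#' Full scale matches the clinical settings: low resolution (1.37, 1.37, 2)
#' mm, high resolution (0.68, 0.68, 1) mm, pancreas crop 256x256x192,
#' pancreas patches 128x128x64 and duct patches 128x128x128 at stride 32^3.
#' A `scale` divisor shrinks every size geometry-similarly for phantom-scale
#' runs; spacings can be overridden for isotropic phantoms.
#'
#' @param scale integer divisor applied to crop/patch/stride sizes.
#' @param low_spacing,high_spacing working resolutions (mm).
#' @param crop_size,pancreas_patch,duct_patch,stride explicit overrides.
#' @return A `pd_geometry` list.
#' @export
cascade_geometry <- function(scale = 1,
                             low_spacing = c(1.37, 1.37, 2),
                             high_spacing = c(0.68, 0.68, 1),
                             crop_size = c(256, 256, 192) %/% scale,
                             pancreas_patch = c(128, 128, 64) %/% scale,
                             duct_patch = c(128, 128, 128) %/% scale,
                             stride = pmax(1L, c(32, 32, 32) %/% scale)) {
  structure(list(low_spacing = low_spacing, high_spacing = high_spacing,
                 crop_size = as.integer(crop_size),
                 pancreas_patch = as.integer(pancreas_patch),
                 duct_patch = as.integer(duct_patch),
                 stride = as.integer(stride), scale = scale),
            class = "pd_geometry")
}

# centroid (0-based, rounded) of a binary mask
mask_centroid <- function(mask) {
  w <- which(mask != 0, arr.ind = TRUE)
  if (nrow(w) == 0) stop("empty mask has no centroid")
  as.integer(round_half_up(colMeans(w) - 1))
}

# resample/normalize a case once at both working resolutions so repeated
# patch draws during training do not pay the interpolation cost again
prepare_case <- function(case, geom, window = c(-87, 199)) {
  if (inherits(case, "pd_case_ctx")) return(case)
  ct_h <- resample(case$ct, geom$high_spacing, "linear")
  structure(list(
    case_id = case$case_id,
    ct_h = normalize_hu(ct_h, window),
    gt_h = resample(case$labels, geom$high_spacing),
    ct_l = normalize_hu(resample(case$ct, geom$low_spacing, "linear"), window),
    gt_l = resample(case$labels, geom$low_spacing)), class = "pd_case_ctx")
}

# build (channels, target, channel_types) for one case and stage;
# crops are centred on the ground-truth pancreas centroid plus jitter
build_stage_sample <- function(case, stage, geom,
                               tumor_channels = c("ct", "pancreas", "cbd", "pd"),
                               jitter = 2, window = c(-87, 199)) {
  ctx <- prepare_case(case, geom, window)
  if (stage == "coarse_pancreas") {
    ch <- ctx$ct_l$data; dim(ch) <- c(dim(ch), 1L)
    tg <- label_mask(ctx$gt_l, "pancreas"); dim(tg) <- c(dim(tg), 1L)
    return(list(channels = ch, target = tg, channel_types = "intensity"))
  }
  center <- mask_centroid(label_mask(ctx$gt_h, "pancreas"))
  if (jitter > 0)
    center <- center + sample(-jitter:jitter, 3, replace = TRUE)
  center <- pmin(pmax(center, 0L), dim(ctx$ct_h$data) - 1L)
  crop <- extract_crop(ctx$ct_h, center, geom$crop_size, 0)
  gt_c <- extract_crop(ctx$gt_h, center, geom$crop_size)$volume
  ctd <- crop$volume$data; dim(ctd) <- c(dim(ctd), 1L)
  msk <- function(nm) label_mask(gt_c, nm)
  if (stage == "fine_pancreas") {
    tg <- msk("pancreas"); dim(tg) <- c(dim(tg), 1L)
    return(list(channels = ctd, target = tg, channel_types = "intensity"))
  }
  if (stage == "ducts_multi") {
    cbd <- msk("common_bile_duct"); pd <- msk("pancreatic_duct")
    bg <- 1 - pmax(cbd, pd)
    tg <- array(c(cbd, pd, bg), dim = c(geom$crop_size, 3L))
    return(list(channels = ctd, target = tg, channel_types = "intensity"))
  }
  if (stage %in% c("ducts_cbd", "ducts_pd")) {
    nm <- if (stage == "ducts_cbd") "common_bile_duct" else "pancreatic_duct"
    tg <- msk(nm); dim(tg) <- c(dim(tg), 1L)
    return(list(channels = ctd, target = tg, channel_types = "intensity"))
  }
  if (stage == "tumor") {
    chans <- list(ct = ctd[, , , 1])
    if (!is.null(ctx$pred)) {
      # predicted-input condition: anatomy channels come from the fold's
      # own upstream models (precomputed full-volume masks), so training
      # sees the same imperfect masks the cascade produces at test time
      pmsk <- function(nm) extract_crop(volume(ctx$pred[[nm]]),
                                        center, geom$crop_size, 0)$volume$data
      chans$pancreas <- pmsk("pancreas")
      chans$cbd <- pmsk("cbd")
      chans$pd <- pmsk("pd")
    } else {
      chans$pancreas <- msk("pancreas")
      chans$cbd <- msk("common_bile_duct")
      chans$pd <- msk("pancreatic_duct")
    }
    sel <- chans[tumor_channels]
    ch <- array(unlist(sel, use.names = FALSE), dim = c(geom$crop_size, length(sel)))
    types <- ifelse(tumor_channels == "ct", "intensity",
                    ifelse(tumor_channels %in% c("cbd", "pd"), "duct", "mask"))
    tg <- msk("tumor"); dim(tg) <- c(dim(tg), 1L)
    return(list(channels = ch, target = tg, channel_types = types))
  }
  stop("unknown stage: ", stage)
}

# run one fold's upstream models (locate -> fine pancreas -> ducts ->
# plausibility filter) on a prepared case and paste the binarized masks
# back to the full high-resolution grid; used to train the tumor stage on
# predicted inputs
predict_anatomy_ctx <- function(ctx, bundle) {
  geom <- bundle$geom
  spec <- tiling_spec(geom$pancreas_patch, geom$stride)
  probs <- stage_fold_probs(bundle$coarse_pancreas, ctx$ct_l$data, spec,
                            ctx$gt_l)
  mask <- largest_component(binarize(fold_mean(probs)[, , , 1],
                                     bundle$seg_threshold), 26)
  center <- if (sum(mask) == 0) dim(ctx$ct_h$data) %/% 2L
            else map_index_between_spacings(mask_centroid(mask),
                                            geom$low_spacing,
                                            geom$high_spacing)
  center <- pmin(pmax(as.integer(center), 0L), dim(ctx$ct_h$data) - 1L)
  fine <- segment_pancreas_fine(ctx$ct_h, center, bundle)
  pan <- binarize(fine$prob, bundle$seg_threshold)
  ducts <- segment_ducts(fine$crop, bundle)
  cbd <- binarize(ducts$cbd, bundle$seg_threshold)
  pd <- binarize(ducts$pd, bundle$seg_threshold)
  if (bundle$filter_which %in% c("both", "cbd"))
    cbd <- filter_ducts_by_pancreas(cbd, pan, attach_radius = bundle$attach_radius)
  if (bundle$filter_which == "both")
    pd <- filter_ducts_by_pancreas(pd, pan, attach_radius = bundle$attach_radius)
  full <- function(m) paste_crop(dim(ctx$ct_h$data), m, fine$region, 0)
  list(pancreas = full(pan), cbd = full(cbd), pd = full(pd))
}

# ---- optimizer and training loop ------------------------------------------

adam_init <- function(params) {
  flat <- unlist(params, recursive = FALSE)
  list(m = lapply(flat, function(p) p * 0), v = lapply(flat, function(p) p * 0),
       t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  flatp <- unlist(params, recursive = FALSE)
  flatg <- unlist(grads, recursive = FALSE)
  for (i in seq_along(flatp)) {
    g <- flatg[[names(flatp)[i]]]
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g^2
    mhat <- state$m[[i]] / (1 - beta1^state$t)
    vhat <- state$v[[i]] / (1 - beta2^state$t)
    flatp[[i]] <- flatp[[i]] - lr * mhat / (sqrt(vhat) + eps)
  }
  for (bl in names(params))
    for (pn in names(params[[bl]]))
      params[[bl]][[pn]] <- flatp[[paste(bl, pn, sep = ".")]]
  list(params = params, state = state)
}

#' Stage training configuration
#'
#' Phantom-scale defaults: narrow depth-2 residual nets, Adam at 2e-3,
#' 150 steps of batch 2 on foreground-biased 32-voxel patches. All of it is
#' overridable per stage; the full-scale counterpart would raise depth to 4
#' and filters to 32-256.
#'
#' @param steps optimizer steps.
#' @param batch_size patches per step.
#' @param lr Adam learning rate.
#' @param patch_size training patch size (NULL = stage default).
#' @param fg_fraction foreground-biased sampling probability.
#' @param filters,depth network width/depth.
#' @param eval_every validation cadence (steps).
#' @param augment_cfg an [augment_config()]; NULL disables augmentation.
#' @param balance_classes sample training cases inversely to the frequency
#'   of their (tumor, attenuation-class) group, so rare iso/hyper tumors
#'   are seen as often as the hypo majority.
#' @param decay_after,decay_factor step-decay learning-rate schedule: after
#'   `decay_after` fraction of the steps, multiply the rate by
#'   `decay_factor` (defaults disable decay).
#' @param seed base RNG seed.
#' @return A `pd_train_config`.
#' @export
train_config <- function(steps = 150, batch_size = 2, lr = 2e-3,
                         patch_size = NULL, fg_fraction = 0.7,
                         filters = c(4, 8), depth = 2, eval_every = 25,
                         augment_cfg = augment_config(),
                         balance_classes = FALSE,
                         decay_after = 1, decay_factor = 1, seed = 1L) {
  structure(as.list(environment()), class = "pd_train_config")
}

stage_net_config <- function(stage, cfg, tumor_channels) {
  if (stage == "ducts_multi")
    network_config(1, 3, depth = cfg$depth, filters = cfg$filters, head = "softmax")
  else if (stage == "tumor")
    network_config(length(tumor_channels), 1, depth = cfg$depth,
                   filters = cfg$filters)
  else network_config(1, 1, depth = cfg$depth, filters = cfg$filters)
}

stage_patch_size <- function(stage, cfg, geom) {
  if (!is.null(cfg$patch_size)) return(as.integer(cfg$patch_size))
  if (stage %in% c("ducts_multi", "ducts_cbd", "ducts_pd")) geom$duct_patch
  else if (stage == "coarse_pancreas") geom$pancreas_patch
  else if (stage == "tumor") pmin(geom$crop_size, geom$duct_patch)
  else geom$pancreas_patch
}

#' Train one cascade stage on one fold
#'
#' Optimizes soft-Dice + cross-entropy with Adam on sampled, augmented
#' patches from the fold's training patients; tracks soft Dice on held-out
#' validation samples and returns the checkpoint with the best validation
#' Dice. Deterministic for fixed seeds.
#'
#' @param cases list of `pd_phantom_case` (or compatible) objects.
#' @param manifest cohort manifest mapping case_id to patient_id.
#' @param stage one of coarse_pancreas, fine_pancreas, ducts_multi,
#'   ducts_cbd, ducts_pd, tumor.
#' @param fold fold index into `split_plan$folds`.
#' @param split_plan a [make_splits()] plan.
#' @param config a [train_config()].
#' @param geom a [cascade_geometry()].
#' @param tumor_channels input channel names for the tumor stage (drop the
#'   duct channels to train the CT-only ablation).
#' @return A `pd_segmodel` with a training log in `training_meta$log`.
#' @export
train_stage <- function(cases, manifest, stage, fold, split_plan,
                        config = train_config(), geom = cascade_geometry(4),
                        tumor_channels = c("ct", "pancreas", "cbd", "pd")) {
  stopifnot(inherits(split_plan, "pd_split_plan"))
  pid <- setNames(manifest$patient_id, manifest$case_id)
  ids <- vapply(cases, function(cs) cs$case_id, character(1))
  fold_def <- split_plan$folds[[fold]]
  train_cases <- lapply(cases[pid[ids] %in% fold_def$train], prepare_case, geom)
  val_cases <- lapply(cases[pid[ids] %in% fold_def$val], prepare_case, geom)
  if (!length(train_cases)) stop("empty train split for fold ", fold)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed + 1000L * fold + 17L * nchar(stage))

  netc <- stage_net_config(stage, config, tumor_channels)
  model <- build_model(netc, seed = config$seed + fold, stage = stage, fold = fold)
  psz <- stage_patch_size(stage, config, geom)
  head <- netc$head

  # fixed validation samples (no jitter, no augmentation)
  val_samples <- lapply(head(val_cases, 3), function(cs) {
    s <- build_stage_sample(cs, stage, geom, tumor_channels, jitter = 0)
    sample_patch(s$channels, s$target, psz, fg_fraction = 1)
  })
  val_dice <- function(m) {
    if (!length(val_samples)) return(NA_real_)
    mean(vapply(val_samples, function(s) {
      p <- predict_proba(m, s$channels)
      if (head == "softmax") {
        nfg <- dim(p)[4] - 1
        mean(vapply(seq_len(nfg), function(c)
          dice(p[, , , c] >= 0.5, s$target[, , , c]), numeric(1)))
      } else dice(p[, , , 1] >= 0.5, s$target[, , , 1])
    }, numeric(1)))
  }

  case_w <- NULL
  if (isTRUE(config$balance_classes) && !is.null(manifest$class)) {
    # two-level balance: keep tumor/control exposure 50/50, and within the
    # tumor half give each attenuation class equal weight
    tr_ids <- vapply(train_cases, function(cs) cs$case_id, character(1))
    mrow <- match(tr_ids, manifest$case_id)
    is_t <- manifest$has_tumor[mrow]
    grp <- ifelse(is_t, paste0("t_", manifest$class[mrow]), "control")
    tgroups <- setdiff(unique(grp), "control")
    w <- numeric(length(grp))
    if (any(!is_t)) w[!is_t] <- 0.5 / sum(!is_t)
    for (g in tgroups) w[grp == g] <- 0.5 / length(tgroups) / sum(grp == g)
    case_w <- w / sum(w)
  }
  state <- adam_init(model$params)
  best <- list(params = model$params, dice = -Inf)
  log <- list()
  for (step in seq_len(config$steps)) {
    gacc <- NULL; lacc <- 0
    for (b in seq_len(config$batch_size)) {
      cs <- train_cases[[sample.int(length(train_cases), 1, prob = case_w)]]
      s0 <- build_stage_sample(cs, stage, geom, tumor_channels)
      s <- sample_patch(s0$channels, s0$target, psz, config$fg_fraction)
      if (!is.null(config$augment_cfg))
        s <- augment(list(channels = s$channels, target = s$target,
                          channel_types = s0$channel_types),
                     config$augment_cfg)
      fw <- unet_forward(model, s$channels, keep_cache = TRUE)
      lg <- nn_loss_grad(fw$logits, s$target, head)
      gr <- unet_backward(model, fw, lg$dlogits)
      lacc <- lacc + lg$loss
      gacc <- if (is.null(gacc)) gr else mapply(function(a, b)
        mapply(`+`, a, b, SIMPLIFY = FALSE), gacc, gr, SIMPLIFY = FALSE)
    }
    gacc <- lapply(gacc, function(bl) lapply(bl, function(g) g / config$batch_size))
    lr_now <- config$lr *
      if (step > config$steps * config$decay_after) config$decay_factor else 1
    up <- adam_step(model$params, gacc, state, lr_now)
    model$params <- up$params; state <- up$state
    if (step %% config$eval_every == 0 || step == config$steps) {
      vd <- val_dice(model)
      log[[length(log) + 1]] <- tibble::tibble(
        step = step, loss = lacc / config$batch_size, val_dice = vd)
      if (is.na(vd) || vd >= best$dice) {
        best$params <- model$params
        best$dice <- if (is.na(vd)) best$dice else vd
      }
    }
  }
  model$params <- best$params
  model$training_meta$log <- do.call(rbind, log)
  model$training_meta$best_val_dice <- best$dice
  model$training_meta$train_cases <- vapply(train_cases, function(cs) cs$case_id,
                                            character(1))
  model
}

#' Train the full stage bundle (all stages, all folds)
#'
#' @inheritParams train_stage
#' @param stages stages to train.
#' @param n_folds folds per stage.
#' @param configs optional named list of per-stage [train_config()]s.
#' @param threshold case-score threshold stored on the bundle.
#' @param duct_mode `"multi"` (one softmax model) or `"single"` (two
#'   single-label models).
#' @param tumor_inputs `"predicted"` (default): each fold's tumor model
#'   trains on the anatomy masks produced by that fold's own upstream
#'   models, matching the test-time input distribution; `"gt"` trains on
#'   ground-truth masks (the "GT input" condition).
#' @return A `pd_stage_bundle` ready for [run_pipeline()].
#' @export
train_bundle <- function(cases, manifest, split_plan,
                         geom = cascade_geometry(4),
                         configs = list(), n_folds = length(split_plan$folds),
                         duct_mode = c("multi", "single"),
                         tumor_channels = c("ct", "pancreas", "cbd", "pd"),
                         tumor_inputs = c("predicted", "gt"),
                         threshold = 0.61) {
  duct_mode <- match.arg(duct_mode)
  tumor_inputs <- match.arg(tumor_inputs)
  cases <- lapply(cases, prepare_case, geom)   # resample/normalize once
  duct_stages <- if (duct_mode == "multi") "ducts_multi" else c("ducts_cbd", "ducts_pd")
  stages <- c("coarse_pancreas", "fine_pancreas", duct_stages)
  models <- list()
  for (st in stages) {
    cfg <- if (!is.null(configs[[st]])) configs[[st]] else train_config()
    models[[st]] <- lapply(seq_len(n_folds), function(f)
      train_stage(cases, manifest, st, f, split_plan, cfg, geom, tumor_channels))
  }
  duct_models <- if (duct_mode == "multi") models$ducts_multi
                 else list(cbd = models$ducts_cbd, pd = models$ducts_pd)
  tcfg <- if (!is.null(configs$tumor)) configs$tumor else train_config()
  dummy_tumor <- list(const_model(0, in_channels = length(tumor_channels)))
  models$tumor <- lapply(seq_len(n_folds), function(f) {
    fold_cases <- cases
    if (tumor_inputs == "predicted") {
      partial <- stage_bundle(
        coarse_pancreas = models$coarse_pancreas[f],
        fine_pancreas = models$fine_pancreas[f],
        ducts = if (duct_mode == "multi") duct_models[f]
                else list(cbd = duct_models$cbd[f], pd = duct_models$pd[f]),
        tumor = dummy_tumor, duct_mode = duct_mode, geom = geom,
        threshold = threshold)
      pid <- setNames(manifest$patient_id, manifest$case_id)
      # training patients plus the few validation cases the checkpoint
      # selection actually evaluates
      ids <- vapply(cases, function(ctx) ctx$case_id, character(1))
      val_used <- head(ids[pid[ids] %in% split_plan$folds[[f]]$val], 3)
      fold_pat <- split_plan$folds[[f]]$train
      fold_cases <- lapply(cases, function(ctx) {
        if (pid[[ctx$case_id]] %in% fold_pat || ctx$case_id %in% val_used)
          ctx$pred <- predict_anatomy_ctx(ctx, partial)
        ctx
      })
    }
    train_stage(fold_cases, manifest, "tumor", f, split_plan, tcfg, geom,
                tumor_channels)
  })
  stage_bundle(coarse_pancreas = models$coarse_pancreas,
               fine_pancreas = models$fine_pancreas,
               ducts = duct_models, tumor = models$tumor,
               duct_mode = duct_mode, geom = geom,
               tumor_channels = tumor_channels, threshold = threshold)
}
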