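geom_t <- phantom_geometry()

test_that("oracle cascade reproduces ground truth exactly end-to-end", {
  ob <- oracle_bundle(geom_t, n_folds = 3)
  tum <- small_tumor_case(101)
  r <- run_pipeline(tum$ct, ob, gt = tum$labels, case_id = "t1")
  expect_true(r$call)
  expect_equal(unname(r$dscs), rep(1, 4))
  expect_true(r$localization_hit)
  expect_equal(r$case_score, 1)

  ctl <- small_control_case(102)
  r2 <- run_pipeline(ctl$ct, ob, gt = ctl$labels, case_id = "c1")
  expect_false(r2$call)
  expect_equal(unname(r2$dscs), rep(1, 4))
})

test_that("pancreas localization: oracle centroid, degenerate and two-blob cases", {
  tum <- small_tumor_case(103)
  ob <- oracle_bundle(geom_t, n_folds = 1)
  center <- locate_pancreas(tum$ct, ob, gt = tum$labels)
  gt_low <- resample(tum$labels, geom_t$low_spacing)
  true_c <- map_index_between_spacings(
    pdacascade:::mask_centroid(label_mask(gt_low, "pancreas")),
    geom_t$low_spacing, geom_t$high_spacing)
  expect_true(all(abs(center - true_c) <= 2))

  # an all-zero model cannot locate the pancreas; the pipeline flags it
  zb <- stage_bundle(list(const_model(0)), list(const_model(0)),
                     list(const_model(0, out_channels = 3)),
                     list(const_model(0, in_channels = 4)),
                     duct_mode = "multi", geom = geom_t)
  expect_error(locate_pancreas(tum$ct, zb, case_id = "zz"), "not located")
  r <- run_pipeline(tum$ct, zb, gt = tum$labels, case_id = "zz")
  expect_false(r$call)
  expect_equal(r$flags, "pancreas_not_located")
  expect_equal(r$case_score, 0)

  # two blobs: the centroid must come from the dominant component
  low_dim <- dim(resample(tum$ct, geom_t$low_spacing)$data)
  blob <- array(0, dim = c(low_dim, 1))
  blob[3:10, 3:10, 3:10, 1] <- 1          # 512 voxels
  blob[20:21, 20:21, 20:21, 1] <- 1       # 8 voxels
  geom1 <- geom_t                          # single whole-volume tile
  geom1$pancreas_patch <- low_dim
  geom1$stride <- low_dim
  fb <- stage_bundle(list(fn_model(function(x) blob)), list(const_model(0)),
                     list(const_model(0, out_channels = 3)),
                     list(const_model(0, in_channels = 4)),
                     duct_mode = "multi", geom = geom1)
  ctr <- locate_pancreas(tum$ct, fb)
  expect_true(all(abs(ctr - map_index_between_spacings(
    c(mean(2:9), mean(2:9), mean(2:9)), geom_t$low_spacing,
    geom_t$high_spacing)) <= 1))
})

test_that("duct plausibility filter keeps pancreas-attached components only", {
  pan <- array(0, dim = c(20, 20, 20)); pan[5:15, 5:15, 5:15] <- 1
  duct <- array(0, dim = c(20, 20, 20))
  duct[10:18, 10, 10] <- 1                 # crosses the pancreas boundary
  kept <- filter_ducts_by_pancreas(duct, pan, attach_radius = 2)
  expect_equal(kept, duct)

  iso <- array(0, dim = c(20, 20, 20)); iso[19:20, 19, 19] <- 1
  both <- duct + iso
  f <- filter_ducts_by_pancreas(both, pan, attach_radius = 2)
  expect_equal(f, duct)

  expect_equal(sum(filter_ducts_by_pancreas(duct, pan * 0,
                                            attach_radius = 2)), 0)
  expect_error(filter_ducts_by_pancreas(duct, array(0, c(5, 5, 5))), "shape")

  # subset, idempotence, monotonicity in radius, and the flood-fill oracle
  set.seed(17)
  for (i in 1:25) {
    dm <- array(rbinom(10^3, 1, 0.15), dim = c(10, 10, 10))
    pm <- array(rbinom(10^3, 1, 0.05), dim = c(10, 10, 10))
    f1 <- filter_ducts_by_pancreas(dm, pm, attach_radius = 1)
    expect_true(all(f1 <= dm))
    expect_equal(filter_ducts_by_pancreas(f1, pm, attach_radius = 1), f1)
    f2 <- filter_ducts_by_pancreas(dm, pm, attach_radius = 2)
    expect_true(all(f2 >= f1))
    # oracle: flood-fill components intersecting the dilated pancreas
    lab <- flood_fill_components(dm, 26)
    pan_d <- morph_ball(pm, 1, "dilate")
    keep <- unique(lab[lab > 0 & pan_d > 0])
    expect_equal(f1, array(as.numeric(lab %in% keep & lab > 0), dim(dm)))
  }
})

test_that("tumor stage input stacking preserves the documented channel order", {
  tum <- small_tumor_case(104)
  gt_h <- resample(tum$labels, geom_t$high_spacing)
  ctr <- pdacascade:::mask_centroid(label_mask(gt_h, "pancreas"))
  crop <- extract_crop(normalize_hu(resample(tum$ct, geom_t$high_spacing)),
                       ctr, geom_t$crop_size, 0)$volume
  gt_c <- extract_crop(gt_h, ctr, geom_t$crop_size)$volume
  pan <- label_mask(gt_c, "pancreas"); cbd <- label_mask(gt_c, "common_bile_duct")
  pd <- label_mask(gt_c, "pancreatic_duct")
  net <- build_model(network_config(4, 1, depth = 2, filters = c(4, 8)),
                     seed = 8)
  b <- stage_bundle(list(const_model(0)), list(const_model(0)),
                    list(const_model(0, out_channels = 3)), list(net),
                    duct_mode = "multi", geom = geom_t)
  a <- detect_tumor(crop, pan, cbd, pd, b)
  swapped <- detect_tumor(crop, pan, pd, cbd, b)   # duct channels permuted
  expect_false(identical(a[[1]], swapped[[1]]))
  expect_error(detect_tumor(crop, pan[1:10, , ], cbd, pd, b), "shape")
})

test_that("multi-label duct segmentation yields per-voxel probabilities summing to 1", {
  net <- build_model(network_config(1, 3, depth = 2, filters = c(4, 8),
                                    head = "softmax"), seed = 4)
  b <- stage_bundle(list(const_model(0)), list(const_model(0)), list(net),
                    list(const_model(0, in_channels = 4)),
                    duct_mode = "multi", geom = geom_t)
  crop <- array(runif(prod(geom_t$crop_size)), dim = geom_t$crop_size)
  ducts <- segment_ducts(crop, b)
  expect_equal(dim(ducts$cbd), geom_t$crop_size)
  expect_true(all(ducts$cbd >= 0 & ducts$cbd <= 1))
  expect_true(all(ducts$cbd + ducts$pd <= 1 + 1e-6))
})

test_that("ensembling averages before the max and thresholds inclusively", {
  g <- function(v) { a <- array(0.05, dim = c(4, 4, 4)); a[2, 2, 2] <- v; a }
  ens <- ensemble_and_classify(list(g(1), g(1), g(0.1)), threshold = 0.61)
  expect_equal(ens$case_score, 0.7)
  expect_true(ens$call)
  expect_equal(ens$per_fold_scores, c(1, 1, 0.1))

  exact <- ensemble_and_classify(list(g(0.61)), threshold = 0.61)
  expect_true(exact$call)                   # inclusive boundary
  expect_equal(ensemble_and_classify(list(g(0.4)))$case_score, 0.4)

  # ensemble mean lies within the fold envelope voxel-wise
  set.seed(3)
  grids <- lapply(1:3, function(i) array(runif(64), dim = c(4, 4, 4)))
  mn <- ensemble_and_classify(grids)$tumor_prob
  lo <- pmin(grids[[1]], grids[[2]], grids[[3]])
  hi <- pmax(grids[[1]], grids[[2]], grids[[3]])
  expect_true(all(mn >= lo - 1e-12 & mn <= hi + 1e-12))
  expect_error(ensemble_and_classify(list()), "no fold")
})

test_that("patient-level aggregation follows the configured rule", {
  expect_equal(patient_score(0.42), 0.42)
  expect_equal(patient_score(c(0.2, 0.8)), 0.8)
  expect_equal(patient_score(c(0.2, 0.8), rule = "mean"), 0.5)
  expect_error(patient_score(numeric(0)), "no scan scores")
})

test_that("oracle pipeline runs are bit-identical across invocations", {
  ob <- oracle_bundle(geom_t, n_folds = 2)
  cs <- small_tumor_case(105)
  r1 <- run_pipeline(cs$ct, ob, gt = cs$labels, case_id = "d")
  r2 <- run_pipeline(cs$ct, ob, gt = cs$labels, case_id = "d")
  expect_identical(r1, r2)
})
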