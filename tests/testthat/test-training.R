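test_that("splits are patient-level, exhaustive and reproducible", {
  ids <- sprintf("p%03d", 1:100)
  plan <- make_splits(ids, seed = 3)
  expect_length(plan$test, 15)
  for (f in plan$folds) {
    expect_length(f$train, 70)
    expect_length(f$val, 15)
    expect_length(intersect(f$train, f$val), 0)
    expect_length(intersect(f$train, plan$test), 0)
    expect_length(intersect(f$val, plan$test), 0)
    expect_setequal(c(f$train, f$val, plan$test), ids)
  }
  expect_identical(plan, make_splits(ids, seed = 3))
  # bootstrapped folds re-draw the train/val partition independently
  expect_false(identical(plan$folds[[1]]$train, plan$folds[[2]]$train))
  expect_error(make_splits(sprintf("p%d", 1:3)), "too few")
})

test_that("a patient's scans always share a bucket", {
  man <- tibble::tibble(case_id = sprintf("scan%02d", 1:12),
                        patient_id = rep(sprintf("p%02d", 1:6), each = 2))
  plan <- make_splits(man$patient_id, fractions = c(0.5, 0.25, 0.25),
                      n_folds = 2, seed = 1)
  bucket_of <- function(pid, f)
    c("train", "val", "test")[c(pid %in% plan$folds[[f]]$train,
                                pid %in% plan$folds[[f]]$val,
                                pid %in% plan$test)]
  for (f in 1:2) {
    buckets <- vapply(man$patient_id, bucket_of, character(1), f = f)
    per_scan <- split(buckets, man$patient_id)
    expect_true(all(vapply(per_scan, function(b) length(unique(b)) == 1,
                           logical(1))))
  }
})

test_that("augmentation: identity at zero probability, involutive flips, tagged channels", {
  set.seed(5)
  ch <- array(rnorm(16^3 * 2), dim = c(16, 16, 16, 2))
  tg <- array(rbinom(16^3, 1, 0.1), dim = c(16, 16, 16, 1))
  s <- list(channels = ch, target = tg, channel_types = c("intensity", "duct"))

  off <- augment_config(p_flip = 0, p_rotate = 0, p_elastic = 0,
                        p_duct_morph = 0, p_gaussian = 0, p_poisson = 0)
  same <- augment(s, off)
  expect_identical(same$channels, ch)
  expect_identical(same$target, tg)

  flips <- augment_config(p_flip = 1, p_rotate = 0, p_elastic = 0,
                          p_duct_morph = 0, p_gaussian = 0, p_poisson = 0,
                          flip_axes = 1)
  twice <- augment(augment(s, flips), flips)
  expect_identical(twice$channels, ch)
  expect_identical(twice$target, tg)

  expect_error(augment(list(channels = ch, target = tg,
                            channel_types = c("intensity", "bogus")), off),
               "unknown channel type")
  expect_error(augment(list(channels = ch, target = tg), off), "tagged")
})

test_that("duct morphology touches only duct channels; masks stay binary", {
  tube <- array(0, dim = c(16, 16, 16))
  tube[4:12, 8:9, 8:9] <- 1
  ch <- array(0, dim = c(16, 16, 16, 2))
  ch[, , , 1] <- rnorm(16^3)
  ch[, , , 2] <- tube
  tg <- array(rbinom(16^3, 1, 0.2), dim = c(16, 16, 16, 1))
  s <- list(channels = ch, target = tg, channel_types = c("intensity", "duct"))
  cfg <- augment_config(p_flip = 0, p_rotate = 0.5, p_elastic = 0.5,
                        p_duct_morph = 1, p_gaussian = 0, p_poisson = 0)
  set.seed(9)
  for (i in 1:5) {
    a <- augment(s, cfg)
    expect_true(all(a$channels[, , , 2] %in% c(0, 1)))
    expect_true(all(a$target %in% c(0, 1)))
  }
  # with spatial transforms disabled, a dilate strictly grows the duct and
  # leaves CT untouched (draw until the coin picks dilate)
  cfg2 <- augment_config(p_flip = 0, p_rotate = 0, p_elastic = 0,
                         p_duct_morph = 1, p_gaussian = 0, p_poisson = 0,
                         duct_morph_radius = 1)
  set.seed(2)
  repeat {
    a <- augment(s, cfg2)
    expect_identical(a$channels[, , , 1], ch[, , , 1])
    if (sum(a$channels[, , , 2]) > sum(tube)) break   # dilate branch taken
    expect_lt(sum(a$channels[, , , 2]), sum(tube))    # else it eroded
  }
})

test_that("patch sampling respects foreground bias, bounds and seeding", {
  ch <- array(rnorm(20^3), dim = c(20, 20, 20, 1))
  tg <- array(0, dim = c(20, 20, 20, 1)); tg[15:17, 15:17, 15:17, 1] <- 1
  set.seed(1)
  for (i in 1:20) {
    p <- sample_patch(ch, tg, c(8, 8, 8), fg_fraction = 1)
    expect_gte(sum(p$target), 1)
    expect_equal(dim(p$channels), c(8, 8, 8, 1))
  }
  set.seed(2)
  hits <- replicate(40, sum(sample_patch(ch, tg, c(6, 6, 6), 0)$target) > 0)
  expect_lt(mean(hits), 0.5)
  set.seed(3); a <- sample_patch(ch, tg, c(8, 8, 8), 0.5)
  set.seed(3); b <- sample_patch(ch, tg, c(8, 8, 8), 0.5)
  expect_identical(a, b)
  # empty foreground falls back to uniform sampling without error
  p0 <- sample_patch(ch, tg * 0, c(8, 8, 8), fg_fraction = 1)
  expect_equal(sum(p0$target), 0)
})

test_that("the overfit smoke test reaches high Dice with a decreasing loss", {
  co <- generate_cohort(2, 2, base = phantom_params(shape = c(48, 48, 48)),
                        seed = 31)
  man <- co$manifest
  plan <- make_splits(man$patient_id, fractions = c(0.5, 0.25, 0.25),
                      n_folds = 1, seed = 1)
  geom <- phantom_geometry()
  cfg <- train_config(steps = 200, batch_size = 1, lr = 3e-3,
                      filters = c(4, 8), patch_size = c(32, 32, 16),
                      eval_every = 25, seed = 5, augment_cfg = NULL)
  m <- train_stage(co$cases, man, "fine_pancreas", 1, plan, cfg, geom)
  log <- m$training_meta$log
  # loss trend decreases (median of late evals below median of early evals)
  expect_lt(median(tail(log$loss, 3)), median(head(log$loss, 3)))
  # training-set Dice after overfitting, at the patch granularity the
  # stage trains and validates on
  tr_case <- co$cases[[match(TRUE, man$patient_id %in% plan$folds[[1]]$train)]]
  s <- pdacascade:::build_stage_sample(tr_case, "fine_pancreas", geom,
                                       jitter = 0)
  set.seed(1)
  sp <- pdacascade:::sample_patch(s$channels, s$target, c(32, 32, 16),
                                  fg_fraction = 1)
  p <- predict_proba(m, sp$channels)
  expect_gte(dice(p[, , , 1] >= 0.5, sp$target[, , , 1]), 0.9)
  # leakage audit: recorded training cases never include val/test patients
  pid <- setNames(man$patient_id, man$case_id)
  expect_true(all(pid[m$training_meta$train_cases] %in%
                    plan$folds[[1]]$train))
})
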