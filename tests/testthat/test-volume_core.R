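test_that("NIfTI round-trip preserves grid, spacing and errors on non-3D", {
  tmp <- tempfile(fileext = ".nii.gz")
  v <- volume(array(42, dim = c(4, 4, 4)), spacing = c(1, 1, 1))
  write_volume(v, tmp)
  v2 <- load_volume(tmp)
  expect_equal(v2$data, v$data)
  expect_equal(v2$spacing, c(1, 1, 1), tolerance = 1e-6)

  v3 <- volume(array(rnorm(64), dim = c(4, 4, 4)), spacing = c(0.68, 0.68, 1))
  write_volume(v3, tmp)
  expect_lt(max(abs(load_volume(tmp)$spacing - c(0.68, 0.68, 1))), 1e-6)
  expect_equal(load_volume(tmp)$data, v3$data, tolerance = 1e-6)

  img2d <- RNifti::asNifti(matrix(0, 4, 4))
  RNifti::writeNifti(img2d, tmp)
  expect_error(load_volume(tmp), "3D")
  expect_error(load_volume("/nonexistent/file.nii"), "no such file")
})

test_that("resample geometry: factor-2 shapes, constants, labels, ramp oracle", {
  v <- volume(array(rnorm(16^3), dim = c(16, 16, 16)), spacing = c(1, 1, 1))
  out <- resample(v, c(0.5, 0.5, 0.5))
  expect_equal(dim(out$data), c(32, 32, 32))

  cv <- volume(array(7, dim = c(9, 10, 11)), spacing = c(1, 1.3, 0.7))
  rc <- resample(cv, c(0.9, 0.6, 1.4))
  expect_equal(unique(as.vector(rc$data)), 7)

  mask <- labelmap(array(rbinom(8^3, 1, 0.4), dim = c(8, 8, 8, 1)),
                   spacing = c(1, 1, 1), label_names = "m")
  rm_ <- resample(mask, c(2, 2, 2))
  expect_true(all(rm_$data %in% c(0, 1)))

  # closed-form oracle: linear interpolation of the ramp f(i) = i is exact,
  # so downsampling by 2 must read value 2*i at output voxel i
  ramp <- volume(array(rep(0:15, 16 * 16), dim = c(16, 16, 16)),
                 spacing = c(1, 1, 1))
  rr <- resample(ramp, c(2, 2, 2))
  expected <- 2 * (seq_len(dim(rr$data)[1]) - 1)
  interior <- expected <= 15
  expect_lt(max(abs(rr$data[interior, 4, 4] - expected[interior])), 1e-6)

  expect_error(resample(v, c(0, 1, 1)), "positive")
})

test_that("normalize_hu maps the window affinely onto [0, 1]", {
  v <- volume(array(c(-87, 199, 56, -500, 3000, 0), dim = c(6, 1, 1)))
  n <- normalize_hu(v)
  expect_equal(n$data[1:5, 1, 1],
               c(0, 1, 0.5, 0, 1), tolerance = 1e-12)
  expect_true(all(n$data >= 0 & n$data <= 1))
  # idempotent when re-windowed on (0, 1)
  expect_equal(normalize_hu(n, c(0, 1))$data, n$data)
  # monotone
  x <- sort(rnorm(50, 50, 120))
  nx <- normalize_hu(volume(array(x, dim = c(50, 1, 1))))$data
  expect_true(all(diff(as.vector(nx)) >= 0))
  expect_error(normalize_hu(v, c(5, 5)), "lo < hi")
})

test_that("extract_crop arithmetic, padding, and the brute-force gather oracle", {
  arr <- array(seq_len(10^3), dim = c(10, 10, 10))
  v <- volume(arr)
  cr <- extract_crop(v, c(5, 5, 5), c(6, 6, 6), fill = -1)
  expect_equal(cr$region$start, c(2L, 2L, 2L))
  expect_equal(dim(cr$volume$data), c(6, 6, 6))
  expect_false(any(cr$volume$data == -1))

  # out-of-bounds crop: leading planes must be fill
  cr2 <- extract_crop(v, c(1, 5, 5), c(8, 8, 8), fill = -1)
  expect_equal(cr2$region$start, c(-3L, 1L, 1L))
  expect_true(all(cr2$volume$data[1:3, , ] == -1))
  # brute-force per-voxel gather
  brute <- array(-1, dim = c(8, 8, 8))
  for (i in 1:8) for (j in 1:8) for (k in 1:8) {
    src <- c(i, j, k) - 1 + cr2$region$start    # 0-based source voxel
    if (all(src >= 0) && all(src < 10))
      brute[i, j, k] <- arr[src[1] + 1, src[2] + 1, src[3] + 1]
  }
  expect_equal(cr2$volume$data, brute)

  expect_error(extract_crop(v, c(10, 5, 5), c(4, 4, 4)), "outside")
})

test_that("paste_crop inverts extract_crop and drops out-of-bounds voxels", {
  set.seed(7)
  # full coverage: paste returns the crop itself
  v <- volume(array(rnorm(6^3), dim = c(6, 6, 6)))
  cr <- extract_crop(v, c(3, 3, 3), c(6, 6, 6))
  expect_equal(paste_crop(c(6, 6, 6), cr$volume, cr$region), v$data,
               tolerance = 1e-14)

  # conservation for a fully interior region
  v2 <- volume(array(rnorm(10^3), dim = c(10, 10, 10)))
  cr2 <- extract_crop(v2, c(5, 5, 5), c(4, 4, 4))
  pasted <- paste_crop(c(10, 10, 10), cr2$volume, cr2$region, background = 2)
  expect_equal(sum(pasted) - 2 * (1000 - 64), sum(cr2$volume$data),
               tolerance = 1e-9)

  # 200 randomized geometries: round-trip is the identity in-bounds
  for (i in 1:200) {
    d <- sample(4:12, 3, replace = TRUE)
    src <- array(rnorm(prod(d)), dim = d)
    center <- sapply(d, function(n) sample(0:(n - 1), 1))
    size <- sample(2:10, 3, replace = TRUE)
    cr <- extract_crop(volume(src), center, size, fill = NA)
    back <- paste_crop(d, cr$volume, cr$region, background = Inf)
    inb <- !is.infinite(back)
    expect_identical(back[inb], src[inb])
  }
  expect_error(paste_crop(c(5, 5, 5), array(0, c(2, 2, 2)),
                          crop_region(c(0, 0, 0), c(2, 2, 2), c(6, 6, 6))),
               "source_shape")
})

test_that("map_index_between_spacings works via world coordinates", {
  expect_equal(map_index_between_spacings(c(3, 4, 5), c(1, 1, 1), c(1, 1, 1)),
               c(3L, 4L, 5L))
  expect_equal(map_index_between_spacings(c(10, 10, 10), c(1.37, 1.37, 2),
                                          c(0.685, 0.685, 1)),
               c(20L, 20L, 20L))
  # spacing ratios up to ~3 (the working resolutions differ by 2x); beyond
  # that the half-voxel rounding error alone can exceed one target voxel
  set.seed(42)
  for (i in 1:50) {
    fs <- runif(3, 0.68, 2); ts <- runif(3, 0.68, 2)
    idx <- sample(0:40, 3, replace = TRUE)
    there <- map_index_between_spacings(idx, fs, ts)
    back <- map_index_between_spacings(there, ts, fs)
    expect_true(all(abs(back - idx) <= 1))
  }
  expect_error(map_index_between_spacings(c(1, 1, 1), c(-1, 1, 1), c(1, 1, 1)),
               "positive")
})

test_that("labelmap I/O round-trips with its sidecar", {
  lm <- labelmap(array(rbinom(4^3 * 2, 1, 0.3), dim = c(4, 4, 4, 2)),
                 spacing = c(1, 1, 2), label_names = c("a", "b"))
  tmp <- tempfile(fileext = ".nii.gz")
  write_labelmap(lm, tmp)
  lm2 <- load_labelmap(tmp)
  expect_equal(lm2$data, lm$data)
  expect_equal(lm2$label_names, c("a", "b"))
  expect_equal(lm2$spacing, c(1, 1, 2), tolerance = 1e-6)
})
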