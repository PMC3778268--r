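test_that("binarization keeps only large-enough clusters above threshold", {
  # all-zero image: nothing to keep
  empty <- binarize_lesion(abnormality_image(array(0, c(10, 10, 10))))
  expect_equal(empty$n_voxels, 0)
  expect_false(any(empty$mask))

  # one 5x5x5 cuboid at 0.5 survives when min_cluster allows it
  img <- cuboid_image()
  m <- binarize_lesion(img, min_cluster = 100)
  expect_equal(m$n_voxels, 125)
  expect_equal(lesion_volume(m), 125)
  expect_equal(unname(which(m$mask)), which(img$grid > 0.3))

  # two disjoint 4x4x4 blocks of 64 voxels each: both below min_cluster
  g <- array(0, c(20, 20, 20))
  g[2:5, 2:5, 2:5] <- 0.9
  g[12:15, 12:15, 12:15] <- 0.9
  m2 <- binarize_lesion(abnormality_image(g), min_cluster = 100)
  expect_equal(m2$n_voxels, 0)
  # ... but both survive with min_cluster <= 64, total 128
  m3 <- binarize_lesion(abnormality_image(g), min_cluster = 64)
  expect_equal(m3$n_voxels, 128)
})

test_that("the abnormality threshold is strict", {
  g <- array(0, c(5, 5, 5))
  g[3, 3, 3] <- 0.3
  m <- binarize_lesion(abnormality_image(g), threshold = 0.3, min_cluster = 1)
  expect_equal(m$n_voxels, 0)
  g[3, 3, 3] <- 0.3 + 1e-9
  m2 <- binarize_lesion(abnormality_image(g), threshold = 0.3, min_cluster = 1)
  expect_equal(m2$n_voxels, 1)
})

test_that("invalid images are rejected with a diagnostic", {
  g <- array(0.5, c(4, 4, 4))
  g[1] <- NA
  expect_error(abnormality_image(g), "non-finite")
  g[1] <- 1.5
  expect_error(abnormality_image(g), "0, 1")
  expect_error(abnormality_image(array(0.1, c(4, 4, 4)),
                                 affine = matrix(0, 4, 4)),
               "invertible")
})

test_that("binarization matches the flood-fill oracle on random volumes", {
  for (conn in c(6, 18, 26)) {
    for (s in 1:6) {
      set.seed(1000 + s)
      g <- array(runif(16^3)^3, c(16, 16, 16))
      mc <- sample(c(1, 5, 20, 60), 1)
      m <- binarize_lesion(abnormality_image(g), threshold = 0.3,
                           min_cluster = mc, connectivity = conn)
      expect_equal(m$mask, oracle_binarize(g, 0.3, mc, conn),
                   info = sprintf("conn=%d seed=%d", conn, s))
    }
  }
})

test_that("binarization is idempotent on an already-valid mask", {
  img <- cuboid_image(value = 1)
  m <- binarize_lesion(img, min_cluster = 100)
  again <- binarize_lesion(
    abnormality_image(array(as.numeric(m$mask), dim(m$mask)), img$affine),
    min_cluster = 100)
  expect_identical(again$mask, m$mask)
})

test_that("lateralised volumes split voxels by world-x of the center", {
  # 5x5x5 block, affine x = 2*i0 - 4: i0 < 2 left, i0 = 2 midline, i0 > 2 right
  aff <- diag(c(2, 2, 2, 1)); aff[1, 4] <- -4
  g <- array(0.9, c(5, 5, 5))
  b <- binarize_lesion(abnormality_image(g, aff), min_cluster = 1)
  lat <- lateralised_volumes(b)
  expect_equal(lat, c(left = 50L, right = 50L))
  expect_lt(lat["left"] + lat["right"], b$n_voxels)  # 25 midline voxels

  # block entirely at x < 0
  aff2 <- diag(c(2, 2, 2, 1)); aff2[1, 4] <- -40
  b2 <- binarize_lesion(cuboid_image(affine = aff2), min_cluster = 1)
  expect_equal(lateralised_volumes(b2), c(left = 125L, right = 0L))

  # brute-force coordinate check on a random mask
  set.seed(7)
  g3 <- array(runif(10 * 8 * 6), c(10, 8, 6))
  aff3 <- diag(c(2, 2, 2, 1)); aff3[1, 4] <- -9
  b3 <- binarize_lesion(abnormality_image(g3, aff3), threshold = 0.5,
                        min_cluster = 1)
  idx <- which(b3$mask, arr.ind = TRUE)
  wx <- aff3[1, 1] * (idx[, 1] - 1) + aff3[1, 4]
  expect_equal(lateralised_volumes(b3),
               c(left = sum(wx < 0), right = sum(wx > 0)))
  # left + right = total when nothing sits exactly on the midline
  expect_true(all(wx != 0))
  expect_equal(sum(lateralised_volumes(b3)), b3$n_voxels)
})

test_that("overlap maps count patients per voxel", {
  masks <- lapply(list(c(3, 3, 3), c(3, 3, 3), c(5, 5, 5)), function(from)
    binarize_lesion(cuboid_image(from = from, to = from + 2, value = 0.9),
                    min_cluster = 1))
  om <- overlap_map(masks)
  expect_equal(om$n_patients, 3)
  expect_equal(max(om$counts), 3)           # the shared core voxel(s)
  expect_equal(om$counts[5, 5, 5], 3)
  expect_true(all(om$counts >= 0 & om$counts <= 3))

  # single mask: counts equal the 0/1 mask
  om1 <- overlap_map(masks[1])
  expect_equal(om1$counts, array(as.integer(masks[[1]]$mask),
                                 dim(masks[[1]]$mask)))

  # incremental == batch
  inc <- array(0L, dim(masks[[1]]$mask))
  for (m in masks) inc <- inc + m$mask
  expect_equal(om$counts, inc)

  # mismatched spaces rejected
  bad <- binarize_lesion(cuboid_image(dims = c(10, 10, 10)), min_cluster = 1)
  expect_error(overlap_map(c(masks, list(bad))), "shape")
})

test_that("lesion masks and overlap maps survive a NIfTI round trip", {
  m <- binarize_lesion(cuboid_image(), min_cluster = 1)
  f <- tempfile(fileext = ".nii.gz")
  write_lesion_nifti(m, f)
  back <- RNifti::readNifti(f)
  expect_equal(array(as.logical(back), dim(m$mask)), m$mask)
  expect_equal(unclass(RNifti::xform(back))[1:3, 4], m$affine[1:3, 4],
               ignore_attr = TRUE)
})
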