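test_that("distance transform handles degenerate and collinear cases", {
  allsolid <- volumeFromArray(array(1, c(4, 4, 4)))
  expect_true(all(asArray(distanceTransform3D(allsolid)) == 0))

  v <- volumeFromArray(array(c(1, 0, 0), c(3, 1, 1)))
  expect_equal(as.vector(asArray(distanceTransform3D(v))), c(0, 1, 2))

  expect_error(distanceTransform3D(rand_volume(c(3, 3, 3), 1, channels = 3L)),
               "single-channel")

  # no solid voxel at all: the finite sentinel everywhere, no infinities
  empty <- volumeFromArray(array(0, c(4, 4, 4)))
  d <- asArray(distanceTransform3D(empty))
  expect_true(all(is.finite(d)))
  expect_true(all(d > sqrt(3 * 3^2)))  # beyond the volume diagonal
})

test_that("distance transform equals the brute-force oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    solid <- array(runif(8^3) < 0.1, dim = c(8, 8, 8))
    if (!any(solid)) next
    v <- volumeFromArray(array(as.double(solid), c(8, 8, 8)))
    got <- asArray(distanceTransform3D(v, threshold = 0.5))
    expect_equal(got, brute_edt(solid), tolerance = 1e-6)
  }
})

test_that("distance transform is axis-order independent and mirror-symmetric", {
  set.seed(42)
  solid <- array(runif(7 * 6 * 5) < 0.15, dim = c(7, 6, 5))
  v <- volumeFromArray(array(as.double(solid), dim = dim(solid)))
  a <- asArray(distanceTransform3D(v, axisOrder = c(1, 2, 3)))
  b <- asArray(distanceTransform3D(v, axisOrder = c(3, 2, 1)))
  expect_identical(a, b)
  # mirroring the input mirrors the field
  vm <- volumeFromArray(array(as.double(solid[7:1, , ]), dim = dim(solid)))
  am <- asArray(distanceTransform3D(vm))
  expect_equal(am, a[7:1, , ], tolerance = 1e-12)
})

test_that("median filter matches the full-sort oracle", {
  cst <- volumeFromArray(array(0.4, c(5, 5, 5)))
  expect_equal(asArray(medianFilter3D(cst)), asArray(cst))

  v <- volumeFromArray(array(0:26 / 26, c(3, 3, 3)))
  expect_equal(asArray(medianFilter3D(v))[2, 2, 2], 13 / 26,
               tolerance = 1e-6)

  for (seed in 1:5) {
    v <- rand_volume(c(6, 6, 6), seed)
    expect_equal(asArray(medianFilter3D(v)), median_oracle(asArray(v)))
  }
  # element format is preserved and outputs are input elements
  vu <- rand_volume(c(5, 5, 5), 3, dtype = "u8")
  mu <- medianFilter3D(vu)
  expect_identical(voxelType(mu), "u8")
  expect_true(all(asArray(mu) %in% asArray(vu)))
})

test_that("rescaleIntensity spans [0,1] exactly and is idempotent", {
  v <- volumeFromArray(c(2, 4, 6) / 10)
  expect_equal(as.vector(asArray(rescaleIntensity(v))), c(0, 0.5, 1),
               tolerance = 1e-6)
  cst <- makeVolume(c(3, 3), fill = 0.7)
  expect_true(all(asArray(rescaleIntensity(cst)) == 0))

  r <- rand_volume(c(6, 5, 4), 9)
  out <- asArray(rescaleIntensity(r))
  expect_identical(min(out), 0)
  expect_identical(max(out), 1)
  # increasing affine map: order is preserved
  expect_identical(order(as.vector(out)), order(as.vector(asArray(r))))
  # idempotent
  expect_equal(asArray(rescaleIntensity(rescaleIntensity(r))), out,
               tolerance = 1e-7)
})

test_that("threshold uses the >= solidity convention", {
  v <- volumeFromArray(c(0.4999, 0.5, 0.501))
  expect_equal(as.vector(asArray(thresholdVolume(v, 0.5))), c(0, 1, 1))
  low <- makeVolume(c(4, 4), fill = 0.1)
  expect_true(all(asArray(thresholdVolume(low, 0.5)) == 0))
  r <- rand_volume(c(5, 5, 5), 2)
  expect_equal(asArray(thresholdVolume(r, 0.3)),
               array(as.double(asArray(r) >= 0.3), dim = c(5, 5, 5)))
})

test_that("separable convolution matches the dense oracle", {
  k <- c(0.25, 0.5, 0.25)
  cst <- makeVolume(c(5, 5, 5), fill = 0.6)
  expect_equal(asArray(convolveSeparable(cst, k)), asArray(cst),
               tolerance = 1e-6)

  # impulse response is the outer product of the 1D kernels
  imp <- makeVolume(c(9, 9, 9), fill = 0)
  imp@data[5, 5, 5, 1] <- 1
  out <- asArray(convolveSeparable(imp, k))
  expect_equal(out[4:6, 4:6, 4:6], outer(outer(k, k), k), tolerance = 1e-6)

  v <- rand_volume(c(8, 8, 8), 5)
  expect_equal(asArray(convolveSeparable(v, k)),
               dense_conv_oracle(asArray(v), k, k, k), tolerance = 1e-6)
  expect_error(convolveSeparable(v, c(0.5, 0.5)), "odd length")

  # Gaussian kernel: odd length 2*ceil(3 sigma)+1, sums to 1
  gk <- gaussianKernel1D(1.2)
  expect_identical(length(gk), as.integer(2 * ceiling(3 * 1.2) + 1))
  expect_equal(sum(gk), 1)
})

test_that("derivative and normals follow central differences", {
  cst <- makeVolume(c(5, 5, 5), fill = 0.3)
  expect_true(all(asArray(derivativeMagnitude(cst)) == 0))
  nrm <- asArray(surfaceNormals(cst), drop = FALSE)
  expect_true(all(nrm == 0))

  # ramp f = x/10: interior gradient magnitude 0.1, normal (-1, 0, 0)
  d <- c(7, 5, 5)
  ramp <- volumeFromArray(array(rep(seq_len(d[1]) / 10, prod(d[2:3])), d))
  mag <- asArray(derivativeMagnitude(ramp))
  expect_equal(mag[2:6, , ], array(0.1, c(5, 5, 5)), tolerance = 1e-6)
  n <- asArray(surfaceNormals(ramp), drop = FALSE)
  expect_equal(n[3, 3, 3, ], c(-1, 0, 0), tolerance = 1e-6)

  # random volume vs a hand-rolled central-difference oracle along x
  v <- rand_volume(c(6, 6, 6), 8)
  a <- asArray(v)
  gx <- (a[clamp_idx(6, 1), , ] - a[clamp_idx(6, -1), , ]) / 2
  gy <- (a[, clamp_idx(6, 1), ] - a[, clamp_idx(6, -1), ]) / 2
  gz <- (a[, , clamp_idx(6, 1)] - a[, , clamp_idx(6, -1)]) / 2
  expect_equal(asArray(derivativeMagnitude(v)), sqrt(gx^2 + gy^2 + gz^2),
               tolerance = 1e-6)
})

test_that("mean curvature is 0 on planes, 1/r on spheres, odd under negation", {
  d <- c(9, 9, 9)
  ramp <- volumeFromArray(array(rep(seq_len(d[1]) / 10, prod(d[2:3])), d))
  expect_equal(max(abs(asArray(meanCurvature(ramp)))), 0, tolerance = 1e-9)

  # radial distance field: level sets are spheres, H = 1/r
  n <- 33
  ctr <- (n + 1) / 2
  ax <- (seq_len(n) - ctr)^2
  r <- sqrt(outer(outer(ax, ax, "+"), ax, "+"))
  v <- volumeFromArray(r / n)  # scaling does not change H
  H <- asArray(meanCurvature(v))
  sel <- which(abs(r - 10) < 0.5 & !is.na(H), arr.ind = TRUE)
  expect_gt(nrow(sel), 50)
  expect_equal(mean(H[sel]), 1 / 10, tolerance = 0.02)

  Hneg <- asArray(meanCurvature(elementwiseOp(v, -1, "mul")))
  expect_equal(Hneg, -H, tolerance = 1e-6)
})

test_that("region filter matches the direct reduce oracle", {
  cst <- makeVolume(c(4, 4, 4), fill = 0.8)
  for (op in c("min", "max", "avg"))
    expect_equal(asArray(regionFilter(cst, op, 1)), asArray(cst),
                 tolerance = 1e-6)

  spike <- makeVolume(c(7, 7, 7), fill = 0)
  spike@data[4, 4, 4, 1] <- 1
  dil <- asArray(regionFilter(spike, "max", 1))
  expect_true(all(dil[3:5, 3:5, 3:5] == 1))
  expect_equal(sum(dil), 27)

  v <- rand_volume(c(6, 6, 6), 7)
  for (op in c("min", "max", "avg"))
    expect_equal(asArray(regionFilter(v, op, 2)),
                 region_oracle(asArray(v), op, 2), tolerance = 1e-6)
})

test_that("elementwise arithmetic follows IEEE semantics", {
  a <- rand_volume(c(4, 4), 1)
  expect_equal(asArray(elementwiseOp(a, 0, "add")), asArray(a))
  expect_equal(asArray(elementwiseOp(a, 1, "pow")), asArray(a))
  one <- makeVolume(c(2, 2), fill = 1)
  zero <- makeVolume(c(2, 2), fill = 0)
  expect_true(all(asArray(elementwiseOp(one, zero, "div")) == Inf))
  expect_true(all(is.nan(asArray(elementwiseOp(zero, zero, "div")))))
  b <- rand_volume(c(4, 4), 2)
  expect_equal(asArray(elementwiseOp(a, b, "sub")),
               asArray(a) - asArray(b), tolerance = 1e-7)
  expect_error(elementwiseOp(a, rand_volume(c(3, 3), 1), "add"),
               "shape mismatch.*4, 4.*3, 3")
})

test_that("slice extraction cuts cross-sections and round-trips", {
  v <- volumeFromArray(array(seq_len(8) / 10, c(2, 2, 2)))
  s <- extractSlice(v, "z", 1)
  expect_identical(voxelDims(s), c(2L, 2L))
  expect_equal(as.vector(asArray(s)), c(1, 2, 3, 4) / 10, tolerance = 1e-6)
  expect_error(extractSlice(v, 3, 3), "valid range is 1..2")

  # stacking all slices along an axis reconstructs the volume
  vol <- rand_volume(c(4, 5, 3), 6)
  for (ax in 1:3) {
    slices <- lapply(seq_len(voxelDims(vol)[ax]), function(i)
      asArray(extractSlice(vol, ax, i)))
    stacked <- array(unlist(slices), dim = c(dim(slices[[1]]),
                                             length(slices)))
    stacked <- aperm(stacked, order(c(setdiff(1:3, ax), ax)))
    expect_equal(stacked, asArray(vol))
  }
})

test_that("kernels preserve dims and documented channel counts", {
  v <- rand_volume(c(5, 6, 7), 4)
  for (f in list(medianFilter3D, rescaleIntensity,
                 function(x) thresholdVolume(x, 0.5),
                 function(x) gaussianBlur(x, 0.8),
                 derivativeMagnitude, meanCurvature,
                 function(x) regionFilter(x, "avg", 1),
                 function(x) distanceTransform3D(x, 0.5))) {
    out <- f(v)
    expect_identical(voxelDims(out), voxelDims(v))
    expect_identical(nChannels(out), 1L)
  }
  expect_identical(nChannels(surfaceNormals(v)), 3L)
})
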