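test_that("TIFF stacks read through with supplied voxel size", {
  set.seed(11)
  arr <- array(runif(4 * 4 * 4), dim = c(4, 4, 4))
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(lapply(seq_len(4), function(k) arr[, , k]), path,
                  bits.per.sample = 32L)
  vol <- readVolume(path, voxelSizeMm = 0.125)
  expect_equal(dim(intensities(vol)), c(4L, 4L, 4L))
  expect_equal(voxelSize(vol), 0.125)
  expect_equal(intensities(vol), arr, tolerance = 1e-6)
  expect_error(readVolume(path), "voxelSizeMm")
})

test_that("NIfTI carries its own isotropic spacing; anisotropy is rejected", {
  set.seed(12)
  vol0 <- SpineVolume(array(runif(60), dim = c(5, 4, 3)), 0.125)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  writeVolumeNifti(vol0, path)
  vol <- readVolume(path)
  expect_equal(voxelSize(vol), 0.125)
  expect_equal(intensities(vol), intensities(vol0), tolerance = 1e-9)

  aniso <- RNifti::asNifti(array(0, dim = c(3, 3, 3)))
  RNifti::pixdim(aniso) <- c(0.1, 0.2, 0.1)
  path2 <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(aniso, path2)
  expect_error(readVolume(path2), "isotropic")

  expect_error(readVolume("/no/such/volume.nii"), "/no/such/volume.nii")
})

test_that("MIP collapses each ray to its maximum", {
  zeros <- SpineVolume(array(0, dim = c(3, 4, 5)), 0.125)
  expect_true(all(pixels(mip(zeros, "horizontal")) == 0))

  arr <- array(0, dim = c(3, 4, 5))
  arr[2, 3, 4] <- 7
  vol <- SpineVolume(arr, 0.125)
  hz <- pixels(mip(vol, "horizontal"))
  expect_equal(hz[2, 3], 7)
  expect_equal(sum(hz), 7)

  set.seed(42)
  noise <- array(runif(8^3), dim = c(8, 8, 8))
  vol <- SpineVolume(noise, 0.125)
  expect_equal(pixels(mip(vol, "horizontal")), apply(noise, c(1, 2), max))
  expect_equal(pixels(mip(vol, "coronal")), apply(noise, c(2, 3), max))
  expect_equal(pixels(mip(vol, "sagittal")), apply(noise, c(1, 3), max))
})

test_that("MIP commutes with axis relabeling", {
  set.seed(43)
  arr <- array(runif(5 * 6 * 7), dim = c(5, 6, 7))
  canonical <- SpineVolume(arr, 0.2)
  # same data stored with dims in (z, x, y) order
  permuted <- SpineVolume(aperm(arr, c(3, 1, 2)), 0.2,
                          axisMap = c("z", "x", "y"))
  for (pl in c("horizontal", "coronal", "sagittal"))
    expect_equal(pixels(mip(permuted, pl)), pixels(mip(canonical, pl)))
})

test_that("stripe MIP degenerates, excludes, and matches the masked oracle", {
  set.seed(44)
  arr <- array(runif(16 * 12 * 10), dim = c(16, 12, 10))
  h <- 0.25
  vol <- SpineVolume(arr, h)
  midY <- 12 * h / 2
  flat <- fitMidline(cbind(c(0, 4), c(midY, midY)))

  # stripe covering all of y reduces to the full sagittal MIP
  expect_equal(pixels(stripeLateralMip(vol, flat, widthMm = 100)),
               pixels(mip(vol, "sagittal")))

  # a bright voxel farther than width/2 from the midline is excluded
  arr2 <- array(0, dim = c(16, 12, 10))
  arr2[5, 12, 3] <- 99   # y-center 2.875 mm, midline 1.5 mm
  vol2 <- SpineVolume(arr2, h)
  expect_equal(max(pixels(stripeLateralMip(vol2, flat, widthMm = 1))), 0)
  expect_equal(max(pixels(mip(vol2, "sagittal"))), 99)

  # sinusoidal midline vs explicit mask-then-max oracle
  xk <- seq(0, 4, by = 0.5)
  sine <- fitMidline(cbind(xk, midY + 0.8 * sin(xk)))
  got <- pixels(stripeLateralMip(vol, sine, widthMm = 1))
  xc <- (seq_len(16) - 0.5) * h
  expect_equal(got, stripeOracle(arr, h, evalMidline(sine, xc), 1))
})

test_that("stripe MIP is monotone in width and clamps beyond the spline domain", {
  set.seed(45)
  arr <- array(runif(20 * 10 * 8), dim = c(20, 10, 8))
  h <- 0.25
  vol <- SpineVolume(arr, h)
  # spline domain covers only the middle of the volume
  sp <- fitMidline(cbind(c(1.5, 2.5, 3.5), c(1.1, 1.4, 1.2)))
  w <- c(0.5, 1, 2, 5)
  imgs <- lapply(w, function(wi) pixels(stripeLateralMip(vol, sp, wi)))
  for (i in seq_len(length(w) - 1))
    expect_true(all(imgs[[i + 1]] >= imgs[[i]]))
  # out-of-domain columns use the endpoint value
  xc <- (seq_len(20) - 0.5) * h
  expect_equal(pixels(stripeLateralMip(vol, sp, 1)),
               stripeOracle(arr, h, evalMidline(sp, xc), 1))
})

test_that("projection writer emits a TIFF plus JSON sidecar", {
  set.seed(46)
  vol <- SpineVolume(array(runif(4^3, max = 10), dim = c(4, 4, 4)), 0.125)
  img <- mip(vol, "horizontal")
  path <- withr::local_tempfile(fileext = ".tif")
  writeProjection(img, path)
  expect_true(file.exists(path) && file.exists(paste0(path, ".json")))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$plane, "horizontal")
  expect_equal(side$pixel_size_mm, 0.125)
})
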