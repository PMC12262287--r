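make_image <- function(nr = 40, nc = 40, channels = c("dapi", "target"),
                       value = 100) {
  mc_image(array(value, c(nr, nc, length(channels))), channels)
}

test_that("patch cropping yields one patch per small nucleus and tiles large boxes", {
  # three small nuclei -> three patches with distinct bboxes
  mask <- matrix(0L, 80, 80)
  mask[5:20, 5:20] <- 1L
  mask[30:45, 30:45] <- 2L
  mask[60:75, 10:25] <- 3L
  img <- make_image(80, 80)
  patches <- crop_patches(img, nucleus_mask(mask), patch_size = 32L)
  expect_length(patches, 3L)
  expect_equal(length(unique(vapply(patches, function(p)
    paste(p$bbox, collapse = ","), character(1)))), 3L)
  expect_true(all(vapply(patches, function(p)
    all(dim(p$pixels)[1:2] == c(32L, 32L)), logical(1))))

  # a 300x300 bbox tiled at stride 256 with edge-anchored final windows
  mask2 <- matrix(0L, 320, 320)
  mask2[11:310, 11:310] <- 1L
  img2 <- make_image(320, 320)
  patches2 <- crop_patches(img2, nucleus_mask(mask2))
  expect_length(patches2, 4L)
  expect_equal(vapply(patches2, function(p) p$window_index, integer(1)), 0:3)

  # a 100x100 nucleus upscales into a single window
  mask3 <- matrix(0L, 300, 300)
  mask3[101:200, 101:200] <- 1L
  patches3 <- crop_patches(make_image(300, 300), nucleus_mask(mask3))
  expect_length(patches3, 1L)
  expect_equal(dim(patches3[[1]]$pixels)[1:2], c(256L, 256L))
  expect_false(patches3[[1]]$boundary)
})

test_that("border-touching nuclei are flagged, empty masks warn", {
  mask <- matrix(0L, 50, 50)
  mask[1:12, 20:30] <- 1L   # touches row 1
  patches <- crop_patches(make_image(50, 50), nucleus_mask(mask),
                          patch_size = 32L)
  expect_true(patches[[1]]$boundary)
  expect_warning(out <- crop_patches(make_image(50, 50),
                                     nucleus_mask(matrix(0L, 50, 50))),
                 "no nuclei")
  expect_length(out, 0L)
})

test_that("channel rescaling divides dapi by its max and target/centromere jointly", {
  arr <- array(0, c(16, 16, 3),
               dimnames = list(NULL, NULL, c("dapi", "target", "centromere")))
  arr[, , 1] <- 64; arr[1, 1, 1] <- 128      # dapi max 128
  arr[, , 2] <- 50; arr[2, 2, 2] <- 100      # target max 100
  arr[, , 3] <- 100; arr[3, 3, 3] <- 200     # centromere max 200
  p <- structure(list(pixels = arr, nucleus = matrix(TRUE, 16, 16),
                      label = 1L, bbox = c(0L, 0L, 16L, 16L),
                      window_index = 0L, boundary = FALSE,
                      source_image_id = "t",
                      channels = c("dapi", "target", "centromere"),
                      rescaled = FALSE, flags = character(0)),
                 class = "nucleus_patch")
  r <- rescale_channels(p)
  expect_equal(unname(r$pixels[1, 1, "dapi"]), 1.0)
  expect_equal(unname(r$pixels[5, 5, "dapi"]), 0.5)
  expect_equal(unname(r$pixels[2, 2, "target"]), 0.5)  # joint divisor is 200
  expect_equal(unname(r$pixels[3, 3, "centromere"]), 1.0)
  expect_true(all(r$pixels >= 0 & r$pixels <= 1))

  # joint rescaling is invariant to a common positive factor within headroom
  arr2 <- arr; arr2[, , 2:3] <- arr[, , 2:3] * 1.2
  p2 <- p; p2$pixels <- arr2
  r2 <- rescale_channels(p2)
  expect_equal(r2$pixels[, , 2:3], r$pixels[, , 2:3], tolerance = 1e-12)

  # all-zero target is left at zero and flagged
  arr3 <- arr; arr3[, , 2] <- 0
  p3 <- p; p3$pixels <- arr3
  r3 <- rescale_channels(p3)
  expect_true(all(r3$pixels[, , "target"] == 0))
  expect_true("empty_target" %in% r3$flags)
})

test_that("rfp channel is never rescaled", {
  arr <- array(0, c(8, 8, 3),
               dimnames = list(NULL, NULL, c("dapi", "target", "rfp")))
  arr[, , 1] <- 100; arr[, , 2] <- 100; arr[, , 3] <- 37
  p <- structure(list(pixels = arr, nucleus = matrix(TRUE, 8, 8), label = 1L,
                      bbox = c(0L, 0L, 8L, 8L), window_index = 0L,
                      boundary = FALSE, source_image_id = "t",
                      channels = c("dapi", "target", "rfp"),
                      rescaled = FALSE, flags = character(0)),
                 class = "nucleus_patch")
  r <- rescale_channels(p)
  expect_equal(unique(as.vector(r$pixels[, , "rfp"])), 37)
})

test_that("contrast distortion scales about the 8-bit midpoint and clips", {
  img <- make_image(10, 10, value = 200)
  up <- distort_image(img, "contrast_up")
  expect_equal(unique(as.vector(up$pixels)), round(127.5 + 1.4 * (200 - 127.5)))
  down <- distort_image(img, "contrast_down")
  expect_equal(unique(as.vector(down$pixels)), round(127.5 + 0.6 * (200 - 127.5)))
  # magnitude 0 is the identity
  same <- distort_image(img, "contrast_up", magnitude = 0)
  expect_equal(same$pixels, img$pixels)
  # clipping
  bright <- distort_image(make_image(5, 5, value = 250), "contrast_up")
  expect_equal(unique(as.vector(bright$pixels)), 255)
})

test_that("geometric distortions resize by the stated factor and rotation preserves constants centrally", {
  img <- make_image(50, 40, value = 90)
  small <- distort_image(img, "shrink")
  expect_equal(dim(small$pixels)[1:2], c(round(0.8 * 50), round(0.8 * 40)))
  big <- distort_image(img, "enlarge")
  expect_equal(dim(big$pixels)[1:2], c(60, 48))
  expect_equal(unique(as.vector(small$pixels)), 90)

  sq <- make_image(64, 64, value = 120)
  back <- distort_image(distort_image(sq, "rotate", 45), "rotate", -45)
  # pixels in the central disk survive both rotations unchanged
  ctr <- ellipse_mask(64, 64, 32.5, 32.5, 20, 20)
  expect_equal(unique(back$pixels[, , 1][ctr]), 120)
})

test_that("image and mask round-trip through tiff and png readers", {
  tmp <- withr::local_tempdir()
  img <- mc_image(array(sample(0:255, 2 * 24 * 24, replace = TRUE),
                        c(24, 24, 2)), c("dapi", "target"))
  tiff::writeTIFF(list(img$pixels[, , 1] / 255, img$pixels[, , 2] / 255),
                  file.path(tmp, "img.tif"))
  rt <- read_mc_image(file.path(tmp, "img.tif"),
                      list(dapi = 1, target = 2))
  expect_equal(rt$pixels, img$pixels, ignore_attr = TRUE)

  png::writePNG(img$pixels[, , 2] / 255, file.path(tmp, "t.png"))
  jsonlite::write_json(list(target = "t.png"),
                       file.path(tmp, "map.json"), auto_unbox = TRUE)
  rt2 <- read_mc_image(tmp, file.path(tmp, "map.json"))
  expect_equal(rt2$pixels[, , 1], img$pixels[, , 2], ignore_attr = TRUE)

  mask <- nucleus_mask(matrix(sample(0:3, 100, replace = TRUE), 10, 10))
  write_mask_tiff(mask, file.path(tmp, "m.tif"))
  expect_equal(unclass(read_mask_tiff(file.path(tmp, "m.tif"))),
               unclass(mask), ignore_attr = TRUE)
})

test_that("patch manifests record provenance", {
  tmp <- withr::local_tempdir()
  mask <- matrix(0L, 40, 40); mask[5:18, 5:18] <- 1L; mask[25:38, 25:38] <- 2L
  patches <- crop_patches(make_image(40, 40), nucleus_mask(mask),
                          patch_size = 32L, source_image_id = "fieldA")
  man <- write_patches(patches, tmp)
  expect_equal(nrow(man), 2L)
  expect_true(all(file.exists(file.path(tmp, man$patch_id))))
  expect_equal(man$source_image, rep("fieldA", 2))
})
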