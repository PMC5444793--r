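test_that("binarization uses a strict '<' and partitions the lung", {
  img <- matrix(-800L, 20, 20)
  mask <- matrix(TRUE, 20, 20)
  expect_equal(sum(binarize(img, mask, -900)$laa), 0)
  expect_equal(sum(binarize(matrix(-1000L, 20, 20), mask, -900)$laa), 400)
  # a pixel exactly at the threshold is NOT low-attenuation
  img[5, 5] <- -900L
  bin <- binarize(img, mask, -900)
  expect_false(bin$laa[5, 5])
  expect_true(all(xor(bin$laa, bin$normal_lung) == mask))
  expect_error(binarize(img, mask, 800), "plausible")
  expect_error(binarize(img, mask, -2000), "plausible")
})

test_that("betti_numbers matches hand-worked examples", {
  expect_identical(unname(betti_numbers(matrix(FALSE, 6, 6))), c(0L, 0L))
  solid <- matrix(FALSE, 5, 5); solid[2:4, 2:4] <- TRUE
  expect_identical(unname(betti_numbers(solid)), c(1L, 0L))
  annulus <- solid; annulus[3, 3] <- FALSE
  expect_identical(unname(betti_numbers(annulus)), c(1L, 1L))
  # annulus with a centre hole plus three isolated pixels
  g <- matrix(as.logical(c(1,1,1,0,0,
                           1,0,1,0,1,
                           1,1,1,0,0,
                           0,0,0,0,0,
                           1,0,0,0,1)), 5, 5, byrow = TRUE)
  expect_identical(unname(betti_numbers(g)), c(4L, 1L))
  # diagonal contact: 8-connected foreground joins, no hole is created
  diag2 <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2)
  expect_identical(unname(betti_numbers(diag2)), c(1L, 0L))
})

test_that("betti_numbers agrees with the flood-fill oracle on random grids", {
  set.seed(101)
  for (i in 1:200) {
    g <- random_grid(sample(2:7, 1), sample(2:7, 1), p = stats::runif(1, 0.2, 0.8))
    expect_identical(unname(betti_numbers(g)), unname(r_betti(g)))
  }
})

test_that("euler characteristic of cubical sets matches known values", {
  solid <- matrix(FALSE, 5, 5); solid[2:4, 2:4] <- TRUE
  expect_identical(euler_characteristic(solid), 1L)
  annulus <- solid; annulus[3, 3] <- FALSE
  expect_identical(euler_characteristic(annulus), 0L)
  expect_identical(euler_characteristic(matrix(FALSE, 3, 3)), 0L)
})

test_that("b0 - b1 equals the Euler characteristic on random grids", {
  set.seed(202)
  for (i in 1:200) {
    g <- random_grid(16, 16, p = stats::runif(1, 0.2, 0.8))
    b <- betti_numbers(g)
    expect_identical(as.integer(b["b0"] - b["b1"]), euler_characteristic(g))
  }
})

test_that("quantify_slice reproduces phantom ground truth between lesion and lung HU", {
  ph <- tiny_phantom()  # 3 disks + 1 ring, lesions at -980, lung at -780
  curves <- quantify_slice(ph$image, ph$mask, threshold_grid(-1000, -700))
  span <- dplyr::filter(curves, threshold_hu > -980, threshold_hu <= -780)
  expect_true(all(span$b0 == ph$truth$b0))
  expect_true(all(span$b1 == ph$truth$b1))
  expect_equal(span$laa_pct,
               rep(100 * ph$truth$laa_pixels / ph$truth$lung_pixels,
                   nrow(span)))
  below <- dplyr::filter(curves, threshold_hu <= -980)
  expect_true(all(below$laa_pct == 0 & below$b0 == 0 & below$b1 == 0))
})

test_that("LAA% follows its formula and is monotone along the filtration", {
  img <- matrix(-800L, 10, 10)
  img[1:5, 1:5] <- -1000L  # 25 of 100 lung pixels below -900
  mask <- matrix(TRUE, 10, 10)
  curves <- quantify_slice(img, mask, threshold_grid(-1000, -700))
  expect_equal(dplyr::filter(curves, threshold_hu == -900)$laa_pct, 25)

  ph <- make_phantom(phantom_spec(image_size = 96, lesion_count = 3,
                                  ring_count = 1, noise_sd = 18, seed = 4))
  mask2 <- segment_lungs(ph$image)
  noisy <- quantify_slice(ph$image, mask2, threshold_grid(-1000, -700))
  expect_false(is.unsorted(noisy$laa_pct))
})

test_that("normalized Betti numbers are invariant to padding with non-lung", {
  ph <- tiny_phantom()
  base <- quantify_slice(ph$image, ph$mask, threshold_grid(-1000, -800))
  pad <- 12
  big_img <- matrix(40L, nrow(ph$image) + 2 * pad, ncol(ph$image) + 2 * pad)
  big_mask <- matrix(FALSE, nrow(big_img), ncol(big_img))
  idx_r <- pad + seq_len(nrow(ph$image)); idx_c <- pad + seq_len(ncol(ph$image))
  big_img[idx_r, idx_c] <- ph$image
  big_mask[idx_r, idx_c] <- ph$mask
  padded <- quantify_slice(big_img, big_mask, threshold_grid(-1000, -800))
  expect_equal(padded$nb0, base$nb0)
  expect_equal(padded$nb1, base$nb1)
  expect_equal(padded$laa_pct, base$laa_pct)
})
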