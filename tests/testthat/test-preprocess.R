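test_that("Otsu threshold separates a two-level raster exactly", {
  r <- matrix(c(rep(10L, 50), rep(200L, 50)), 10, 10)
  t <- otsu_threshold(r)
  expect_false(attr(t, "degenerate"))
  expect_gt(as.numeric(t), 10)
  expect_lte(as.numeric(t), 200)
  fg <- r > as.numeric(t)
  expect_identical(unname(table(fg)[["TRUE"]]), 50L)  # exact class split
  expect_true(all(r[fg] == 200L))
})

test_that("constant rasters are flagged degenerate", {
  t <- otsu_threshold(matrix(7L, 5, 5))
  expect_true(attr(t, "degenerate"))
  expect_identical(as.numeric(t), 7)
})

test_that("Otsu equals the exhaustive within-class-variance minimizer", {
  # crafted 3-level raster with known counts
  r3 <- matrix(c(rep(0L, 30), rep(100L, 50), rep(255L, 20)), 10, 10)
  expect_identical(as.numeric(otsu_threshold(r3)), otsu_bruteforce(r3))
  # random 8-bit rasters
  set.seed(42)
  for (i in 1:25) {
    r <- matrix(sample(0:255, 400, TRUE), 20, 20)
    expect_identical(as.numeric(otsu_threshold(r)), otsu_bruteforce(r))
  }
  # bimodal rasters, closer to real channel histograms
  set.seed(43)
  for (i in 1:10) {
    r <- matrix(as.integer(pmin(pmax(round(c(
      rnorm(300, 30, 12), rnorm(100, 180, 25))), 0), 255)), 20, 20)
    expect_identical(as.numeric(otsu_threshold(r)), otsu_bruteforce(r))
  }
})

test_that("median filter matches the naive replicate-padded oracle", {
  set.seed(8)
  for (i in 1:5) {
    m <- matrix(sample(0:255, 15 * 18, TRUE), 15, 18)
    expect_identical(imgtsne:::median_filter_byte(m, 3L),
                     matrix(as.integer(median_naive(m, 3)), 15, 18))
  }
})

test_that("cleaning a blank channel yields a blank channel", {
  out <- clean_channel(matrix(0L, 32, 32))
  expect_true(all(out == 0L))
  expect_identical(dim(out), c(32L, 32L))
})

test_that("cleaning keeps a centered bright square and zeroes the field", {
  r <- square_raster(c(64, 64), value = 200, at = c(29, 36))
  p <- clean_params(median_kernel = 3, closing_radius = 1,
                    upweight_factor = 1.5)
  out <- clean_channel(r, p)
  # step-by-step reference: median keeps the square block (corners erode),
  # Otsu splits 0 vs 200, closing restores the block, nothing touches the
  # border, upweighting scales the plateau to min(200 * 1.5, 255)
  expect_true(all(out[31:34, 31:34] == 255L))      # interior plateau clipped
  field <- out
  field[29:36, 29:36] <- 0L
  expect_true(all(field == 0L))                    # everything else is 0
})

test_that("border-touching components are cleared, interior ones kept", {
  r <- matrix(0L, 64, 64)
  r[1:10, 1:10] <- 200L         # touches the border
  r[30:40, 30:40] <- 200L       # interior
  out <- clean_channel(r)
  expect_true(all(out[1:10, 1:10] == 0L))
  expect_true(any(out[30:40, 30:40] > 0L))
})

test_that("the foreground mask is stable under re-cleaning", {
  r <- square_raster(c(64, 64), value = 180, at = c(20, 40))
  out1 <- clean_channel(r)
  out2 <- clean_channel(out1)
  expect_identical(out2 > 0L, out1 > 0L)
})

test_that("cleaned output is always unsigned-byte and upweighting is monotone", {
  set.seed(21)
  rec <- cohort_recipe(n_images = 1, n_channels = 1, image_dims = c(48, 64),
                       blob_count = 3, blob_sigma = 4, seed = 21)
  r <- generate_image(rec, 1, seed = 3)$channels[, , 1]
  for (f in c(1, 1.5, 2)) {
    out <- clean_channel(r, clean_params(upweight_factor = f))
    expect_true(all(out >= 0L & out <= 255L))
  }
  lo <- clean_channel(r, clean_params(upweight_factor = 1.2))
  hi <- clean_channel(r, clean_params(upweight_factor = 2))
  expect_true(all(hi >= lo))
})

test_that("wide-dtype channels are rescaled into byte range before cleaning", {
  r <- square_raster(c(48, 48), value = 40000L, background = 100L,
                     at = c(20, 28))
  out <- clean_channel(r)
  expect_true(all(out >= 0L & out <= 255L))
  expect_true(any(out[22:26, 22:26] > 0L))
})

test_that("compositing respects palette, selection and disjoint supports", {
  # single channel in red: green and blue planes stay zero
  arr <- array(0L, c(48, 48, 2))
  arr[20:28, 20:28, 1] <- 200L
  arr[20:28, 36:44, 2] <- 200L
  im <- multiplex_image(arr, marker_names = c("CD3", "CD8"), image_id = "c")
  comp1 <- composite_channels(im, "CD3", palette = c(CD3 = "#FF0000"))
  expect_true(all(comp1$rgb[, , 2] == 0L))
  expect_true(all(comp1$rgb[, , 3] == 0L))
  expect_true(any(comp1$rgb[, , 1] > 0L))
  # disjoint red/green blobs never mix
  comp2 <- composite_channels(im, c("CD3", "CD8"),
                              palette = c(CD3 = "#FF0000", CD8 = "#00FF00"))
  both <- comp2$rgb[, , 1] > 0L & comp2$rgb[, , 2] > 0L
  expect_false(any(both))
})

test_that("a 6-of-44 selection equals the oracle recomposition", {
  rec <- cohort_recipe(n_images = 1, n_channels = 44, image_dims = c(48, 64),
                       blob_count = 3, blob_sigma = 4,
                       diff_channels = integer(0), seed = 9)
  im <- generate_image(rec, 1, seed = 9, image_id = "tcycif")
  sel <- im$marker_names[c(2, 7, 11, 20, 33, 44)]
  comp <- composite_channels(im, sel)
  expect_identical(comp$selected_markers, sel)
  expect_identical(dim(comp$cleaned_channels)[3], 6L)
  expect_identical(comp$rgb, recompose_rgb(comp$cleaned_channels,
                                           unname(comp$palette[sel])))
  expect_true(all(comp$rgb >= 0L & comp$rgb <= 255L))
})

test_that("unknown markers in the selection are reported with valid names", {
  im <- constant_image(c(1, 2), marker_names = c("CD3", "CD8"))
  expect_error(composite_channels(im, c("CD3", "CD99")), "CD99")
  expect_error(composite_channels(im, c("CD3", "CD99")), "CD8")
})

test_that("clean_params validates its fields", {
  expect_error(clean_params(median_kernel = 2), "odd")
  expect_error(clean_params(closing_radius = -1), ">= 0")
  expect_error(clean_params(upweight_factor = 0.5), ">= 1")
})
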