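test_that("coordinate scaling maps the embedding onto the drawable span", {
  co <- tibble::tibble(image_id = c("a", "b"), x = c(0, 1), y = c(0, 1))
  pos <- scale_coords_to_canvas(co, canvas_dims = c(1000, 1000),
                                tile_dims = c(100, 100), margin_px = 50)
  # drawable span per axis: 1000 - 2*50 - 100 = 800, offsets 50 and 850;
  # the y axis is flipped so embedding-up is canvas-up
  expect_identical(pos$x, c(50, 850))
  expect_identical(pos$y, c(850, 50))
})

test_that("coincident embedding coordinates center all tiles", {
  co <- tibble::tibble(image_id = c("a", "b", "c"), x = rep(2, 3), y = rep(-1, 3))
  pos <- scale_coords_to_canvas(co, c(1000, 800), c(100, 50), 50)
  expect_true(all(pos$x == 50 + (1000 - 100 - 100) / 2))
  expect_true(all(pos$y == 50 + (800 - 100 - 50) / 2))
})

test_that("coordinate mode preserves per-axis order for random tables", {
  set.seed(31)
  for (i in 1:5) {
    n <- sample(5:40, 1)
    co <- tibble::tibble(image_id = paste0("i", 1:n),
                         x = rnorm(n), y = runif(n, -5, 5))
    pos <- scale_coords_to_canvas(co, c(4000, 3000), c(222, 167), 50)
    expect_identical(order(pos$x), order(co$x))
    expect_identical(order(pos$y), order(-co$y))   # flipped axis
    expect_true(all(pos$x >= 50 & pos$x + 222 <= 3950))
    expect_true(all(pos$y >= 50 & pos$y + 167 <= 2950))
  }
})

test_that("grid placement is row-major with the stated row capacity", {
  pos <- grid_layout(paste0("i", 1:6), canvas_width = 3 * 110 + 10,
                     tile_dims = c(100, 80), gap_px = 10)
  # per_row = floor((340 - 10) / 110) = 3 -> two rows
  expect_identical(pos$x[4], 10)                  # tile 4 starts row 2
  expect_identical(pos$y[4], 10 + 80 + 10)
  expect_identical(pos$y[1:3], rep(10, 3))
  empty <- grid_layout(character(0), 1000, c(100, 100), 10)
  expect_identical(nrow(empty), 0L)
  expect_error(grid_layout("a", 50, c(100, 100), 10), "wider than")
})

test_that("grid tiles never overlap at cohort scales", {
  for (n in c(1, 6, 92, 210)) {
    pos <- grid_layout(paste0("i", seq_len(n)), 4000, c(222, 167), 10)
    expect_no_overlap(pos, c(222, 167))
  }
})

test_that("Poisson-disc samples respect the minimum distance", {
  for (s in 1:5) {
    pts <- poisson_disc_sample(c(1000, 800), r = 80, n_points = 40, seed = s)
    expect_true(all(pts$x >= 0 & pts$x < 1000))
    expect_true(all(pts$y >= 0 & pts$y < 800))
    expect_gte(min_pairwise_dist(pts$x, pts$y), 80)
  }
})

test_that("Poisson-disc sampling is deterministic and caps at n_points", {
  a <- poisson_disc_sample(c(2000, 1500), r = 100, n_points = 30, seed = 9)
  b <- poisson_disc_sample(c(2000, 1500), r = 100, n_points = 30, seed = 9)
  expect_identical(a, b)
  expect_identical(nrow(a), 30L)
  c2 <- poisson_disc_sample(c(2000, 1500), r = 100, n_points = 30, seed = 10)
  expect_false(identical(a, c2))
})

test_that("an oversized radius yields a single point with a warning", {
  expect_warning(
    pts <- poisson_disc_sample(c(100, 100), r = 500, n_points = 5, seed = 1),
    "placed 1 of 5")
  expect_identical(nrow(pts), 1L)
  # zero requested points: empty, no warning
  expect_silent(p0 <- poisson_disc_sample(c(100, 100), r = 10, n_points = 0))
  expect_identical(nrow(p0), 0L)
})

test_that("shuffling permutes ids deterministically per seed", {
  expect_identical(shuffle_order("solo", seed = 1), "solo")
  ids <- paste0("i", 1:10)
  s1 <- shuffle_order(ids, seed = 4)
  expect_setequal(s1, ids)
  expect_identical(s1, shuffle_order(ids, seed = 4))
  expect_false(identical(s1, shuffle_order(ids, seed = 5)))
  expect_error(shuffle_order(character(0)), "nonempty")
})

test_that("all three layout modes keep tiles inside the canvas", {
  ids <- paste0("i", 1:15)
  co <- tibble::tibble(image_id = ids, x = rnorm(15), y = rnorm(15))
  for (mode in c("coords", "grid", "random")) {
    lay <- compute_layout(ids, mode = mode, coords = co,
                          canvas_dims = c(2000, 1500), tile_dims = c(150, 120),
                          seed = 2, shuffle = TRUE)
    expect_s3_class(lay, "layout_result")
    expect_identical(sort(lay$render_order), sort(ids))
    expect_true(all(lay$positions$x >= 0 &
                    lay$positions$x + 150 <= lay$canvas_dims[1]))
    expect_true(all(lay$positions$y >= 0 &
                    lay$positions$y + 120 <= lay$canvas_dims[2]))
  }
})

test_that("layout_result rejects inconsistent inputs", {
  pos <- tibble::tibble(image_id = c("a", "a"), x = c(0, 10), y = c(0, 10))
  expect_error(layout_result("grid", pos, c("a", "a"), c(100, 100), c(10, 10)),
               "exactly one position")
  pos2 <- tibble::tibble(image_id = c("a", "b"), x = c(0, 95), y = c(0, 0))
  expect_error(layout_result("grid", pos2, c("a", "b"), c(100, 100), c(10, 10)),
               "inside the canvas")
  expect_error(layout_result("grid", pos2[1, ], c("a", "b"), c(100, 100),
                             c(5, 5)), "permutation")
})
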