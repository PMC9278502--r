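mk_thumb <- function(id, value, dims = c(20, 20)) {
  rgb <- array(as.integer(value), c(dims, 3L))
  structure(list(rgb_tile = rgb, tile_dims = dims,
                 border_color = NA_character_, border_px = 0L,
                 out_name = paste0(id, ".png"), source_id = id),
            class = "thumbnail")
}

empty_layout <- function(canvas = c(200, 150)) {
  layout_result("grid",
                tibble::tibble(image_id = character(0), x = numeric(0),
                               y = numeric(0)),
                character(0), canvas, c(20, 20))
}

test_that("an empty cohort renders a pure background canvas per theme", {
  for (th in c("black", "gray", "dark_blue")) {
    cv <- render_static_canvas(empty_layout(), list(), theme = th)
    bg <- grDevices::col2rgb(theme_color(th))
    for (p in 1:3) expect_true(all(cv[, , p] == bg[p]))
  }
})

test_that("a single tile occupies exactly its footprint", {
  lay <- layout_result("grid",
                       tibble::tibble(image_id = "a", x = 50, y = 50),
                       "a", c(300, 200), c(20, 20))
  cv <- render_static_canvas(lay, list(a = mk_thumb("a", 200)), theme = "black")
  nonbg <- cv[, , 1] != 0L
  expect_identical(sum(nonbg), 400L)
  expect_true(all(cv[51:70, 51:70, 1] == 200L))
})

test_that("overlapping tiles resolve to the later one in render order", {
  pos <- tibble::tibble(image_id = c("a", "b"), x = c(50, 50), y = c(40, 40))
  la <- layout_result("coords", pos, c("a", "b"), c(300, 200), c(20, 20))
  cva <- render_static_canvas(la, list(a = mk_thumb("a", 100),
                                       b = mk_thumb("b", 230)), "black")
  # direct paste oracle: b drawn after a, so the window is all 230
  expect_true(all(cva[41:60, 51:70, 1] == 230L))
  lb <- layout_result("coords", pos, c("b", "a"), c(300, 200), c(20, 20))
  cvb <- render_static_canvas(lb, list(a = mk_thumb("a", 100),
                                       b = mk_thumb("b", 230)), "black")
  expect_true(all(cvb[41:60, 51:70, 1] == 100L))
})

test_that("non-overlapping renders conserve tile pixel mass", {
  ids <- paste0("i", 1:6)
  pos <- grid_layout(ids, 200, c(20, 20), 10)
  lay <- layout_result("grid", pos, ids, c(200, 150), c(20, 20))
  thumbs <- lapply(seq_along(ids), function(i) mk_thumb(ids[i], 10 * i))
  names(thumbs) <- ids
  cv <- render_static_canvas(lay, thumbs, theme = "black")
  expect_identical(sum(as.numeric(cv)),
                   sum(vapply(thumbs, function(t) sum(as.numeric(t$rgb_tile)), 0)))
})

test_that("a tile outside the canvas is rejected", {
  lay <- layout_result("grid", tibble::tibble(image_id = "a", x = 280, y = 0),
                       "a", c(300, 200), c(20, 20))
  big <- mk_thumb("a", 1, dims = c(40, 40))
  expect_error(render_static_canvas(lay, list(a = big)), "exceeds")
})

test_that("the stack montage renders one labelled tile per channel", {
  rec <- cohort_recipe(n_images = 1, n_channels = 44, image_dims = c(48, 64),
                       blob_count = 2, blob_sigma = 3, seed = 23)
  im <- generate_image(rec, 1, seed = 23, image_id = "lung")
  mon <- stack_montage(im, tile_edge = 32)
  expect_length(mon$tiles, 44)
  expect_identical(mon$labels, im$marker_names)
  expect_identical(vapply(mon$tiles, function(t) t$source_id, ""),
                   im$marker_names)
  expect_identical(prod(mon$grid) >= 44, TRUE)
  # single-channel degenerate case
  im1 <- constant_image(5, dims = c(32, 32), image_id = "solo")
  mon1 <- stack_montage(im1, tile_edge = 32)
  expect_length(mon1$tiles, 1)
})

test_that("montage output is a writable in-range canvas", {
  im <- constant_image(c(3, 200, 90), dims = c(40, 40), image_id = "m3")
  path <- file.path(withr::local_tempdir(), "mont.png")
  mon <- stack_montage(im, tile_edge = 32, path = path)
  expect_true(file.exists(path))
  expect_true(all(mon$canvas >= 0L & mon$canvas <= 255L))
})

test_that("the live canvas embeds the full hover record of each image", {
  dir <- withr::local_tempdir()
  writeLines(c("image_id,value", "img_a,Response 1", "img_b,Response 2"),
             file.path(dir, "response.csv"))
  md <- read_metadata_dir(dir)
  co <- tibble::tibble(image_id = c("img_a", "img_b"), x = c(1.25, -3.5),
                       y = c(0.5, 2.75))
  html_path <- file.path(withr::local_tempdir(), "live.html")
  build_live_scatter(co, md, path = html_path)
  html <- paste(readLines(html_path), collapse = "\n")
  expect_match(html, "img_a", fixed = TRUE)
  expect_match(html, "img_a.png", fixed = TRUE)
  expect_match(html, "1.25", fixed = TRUE)
  expect_match(html, "-3.5", fixed = TRUE)
  expect_match(html, "Response 1", fixed = TRUE)
  expect_match(html, "Response 2", fixed = TRUE)
  expect_match(html, "response", fixed = TRUE)
  # two metadata values -> two distinct point colors in the payload
  payload <- jsonlite::fromJSON(sub(".*var DATA = (\\{.*?\\});.*", "\\1", html))
  cols <- unlist(payload$colors$response)
  expect_length(unique(cols), 2)
  # interaction toolbox present
  expect_match(html, "wheel", fixed = TRUE)
  expect_match(html, "reset", fixed = TRUE)
  expect_match(html, "save", fixed = TRUE)
})

test_that("missing metadata renders an uncolored scatter", {
  co <- tibble::tibble(image_id = c("a", "b"), x = 1:2, y = 1:2)
  path <- file.path(withr::local_tempdir(), "plain.html")
  build_live_scatter(co, metadata = NULL, path = path)
  html <- paste(readLines(path), collapse = "\n")
  payload <- jsonlite::fromJSON(sub(".*var DATA = (\\{.*?\\});.*", "\\1", html))
  expect_length(payload$categories, 0)
  expect_identical(payload$initial, "")
  # absent category requested -> warning, uncolored
  expect_warning(
    build_live_scatter(co, metadata = NULL, path = path, category = "ghost"),
    "absent")
})
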