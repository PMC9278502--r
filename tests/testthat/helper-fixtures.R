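# Small fixture builders shared across tests.

# image with one constant plane per channel (plane c has value vals[c])
constant_image <- function(vals, dims = c(16, 16), ...) {
  arr <- array(0L, c(dims, length(vals)))
  for (c in seq_along(vals)) arr[, , c] <- as.integer(vals[c])
  multiplex_image(arr, ...)
}

# single-channel raster with a bright square block on a dark field
square_raster <- function(dims = c(64, 64), value = 200, background = 0,
                          at = c(29, 36)) {
  m <- matrix(as.integer(background), dims[1], dims[2])
  m[at[1]:at[2], at[1]:at[2]] <- as.integer(value)
  m
}

# fast cohort recipe used by recovery-style tests: 96 x 128 px images keep a
# full 92-image cohort cheap while leaving room for 8 well-spaced blobs
recovery_recipe <- function(n_images = 92, seed = 1) {
  cohort_recipe(n_images = n_images, image_dims = c(96, 128), blob_count = 8,
                effect_size = 5, seed = seed)
}

# in-memory cohort (balanced 2 groups) from a recipe, no disk i/o
make_cohort_images <- function(recipe, seed) {
  g <- ((seq_len(recipe$n_images) - 1L) %% recipe$n_groups) + 1L
  imgs <- lapply(seq_len(recipe$n_images), function(i)
    generate_image(recipe, group = g[i], seed = seed * 1000L + i,
                   image_id = sprintf("img%03d", i)))
  names(imgs) <- vapply(imgs, function(im) im$image_id, "")
  list(images = imgs, groups = g)
}

expect_no_overlap <- function(pos, tile_dims) {
  expect_identical(
    count_tile_overlaps(pos$x, pos$y, tile_dims[1], tile_dims[2]), 0L)
}
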