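#' Layout result
#'
#' Canvas positions for every thumbnail of a cohort, plus the order in which
#' they are drawn (later ids draw on top of earlier ones). Canvas
#' coordinates are pixels with the origin at the top-left, x to the right
#' and y down; positions are the top-left corner of each tile.
#'
#' @param mode `"coords"`, `"grid"` or `"random"`.
#' @param positions tibble with `image_id`, `x`, `y` (top-left px).
#' @param render_order permutation of `positions$image_id`.
#' @param canvas_dims `c(width_px, height_px)`.
#' @param tile_dims `c(tile_w, tile_h)` used for the in-bounds check.
#' @return an object of class `layout_result`.
#' @export
layout_result <- function(mode, positions, render_order, canvas_dims,
                          tile_dims) {
  mode <- match.arg(mode, c("coords", "grid", "random"))
  stopifnot(all(c("image_id", "x", "y") %in% names(positions)))
  if (anyDuplicated(positions$image_id))
    stop("each image must have exactly one position", call. = FALSE)
  if (!setequal(render_order, positions$image_id) ||
      length(render_order) != nrow(positions))
    stop("`render_order` must be a permutation of the image ids", call. = FALSE)
  if (nrow(positions)) {
    if (any(positions$x < 0 | positions$y < 0 |
            positions$x + tile_dims[1] > canvas_dims[1] |
            positions$y + tile_dims[2] > canvas_dims[2]))
      stop("tiles must lie fully inside the canvas", call. = FALSE)
  }
  structure(list(mode = mode,
                 positions = tibble::as_tibble(positions),
                 render_order = as.character(render_order),
                 canvas_dims = as.numeric(canvas_dims),
                 tile_dims = as.numeric(tile_dims)),
            class = "layout_result")
}

#' @export
print.layout_result <- function(x, ...) {
  cat(sprintf("<layout_result> mode '%s': %d tile(s) of %d x %d px on a %d x %d canvas\n",
              x$mode, nrow(x$positions), x$tile_dims[1], x$tile_dims[2],
              x$canvas_dims[1], x$canvas_dims[2]))
  invisible(x)
}

#' Map embedding coordinates onto the canvas
#'
#' Affine per-axis map sending the \[min, max\] range of the embedding onto
#' the drawable span (canvas minus margins minus one tile), so the relative
#' order along each axis is preserved. The embedding y axis is flipped so
#' that the static canvas and the scatterplot agree visually. Degenerate
#' axes (a single distinct value, e.g. one image) center the tiles.
#' Overlapping tiles are allowed; stacking is governed by the render order.
#'
#' @param coords tibble with `image_id`, `x`, `y` in embedding space.
#' @param canvas_dims `c(width_px, height_px)`.
#' @param tile_dims `c(tile_w, tile_h)` px.
#' @param margin_px canvas margin on every side (>= 0).
#' @return tibble with `image_id`, `x`, `y` top-left pixel positions.
#' @export
scale_coords_to_canvas <- function(coords, canvas_dims = c(4000, 3000),
                                   tile_dims, margin_px = 50) {
  stopifnot(nrow(coords) >= 1, margin_px >= 0)
  span <- c(canvas_dims[1] - 2 * margin_px - tile_dims[1],
            canvas_dims[2] - 2 * margin_px - tile_dims[2])
  if (any(span < 0)) stop("tile plus margins exceed the canvas", call. = FALSE)
  map_axis <- function(v, span, flip = FALSE) {
    r <- range(v)
    if (r[1] == r[2]) return(rep(span / 2, length(v)))
    u <- (v - r[1]) / (r[2] - r[1])
    if (flip) u <- 1 - u
    u * span
  }
  tibble::tibble(
    image_id = coords$image_id,
    x = margin_px + map_axis(coords$x, span[1]),
    y = margin_px + map_axis(coords$y, span[2], flip = TRUE))
}

#' Vertical-grid positions
#'
#' Row-major placement: tiles per row is
#' `floor((canvas_width - gap) / (tile_w + gap))`, rows are added as needed,
#' and no two tiles overlap.
#'
#' @param image_ids character vector (may be empty).
#' @param canvas_width canvas width in px.
#' @param tile_dims `c(tile_w, tile_h)` px.
#' @param gap_px gap between tiles and at the canvas edge (px).
#' @return tibble with `image_id`, `x`, `y` top-left positions, plus
#'   attribute `canvas_height` (px needed to hold all rows).
#' @export
grid_layout <- function(image_ids, canvas_width = 4000, tile_dims,
                        gap_px = 10) {
  per_row <- floor((canvas_width - gap_px) / (tile_dims[1] + gap_px))
  if (per_row < 1) stop("tile wider than the canvas", call. = FALSE)
  n <- length(image_ids)
  idx <- seq_len(n) - 1L
  pos <- tibble::tibble(
    image_id = as.character(image_ids),
    x = gap_px + (idx %% per_row) * (tile_dims[1] + gap_px),
    y = gap_px + (idx %/% per_row) * (tile_dims[2] + gap_px))
  n_rows <- if (n) ceiling(n / per_row) else 0
  attr(pos, "canvas_height") <- gap_px + n_rows * (tile_dims[2] + gap_px)
  pos
}

#' Poisson-disc (blue-noise) sampling
#'
#' Grid-accelerated dart throwing: a background grid of cell size
#' `r / sqrt(2)` holds at most one point per cell; while an active list is
#' nonempty, up to `k` candidates are drawn uniformly from the annulus
#' \[r, 2r\] around a random active point and accepted when at least `r`
#' away from every neighbor. The variant used here stops at `n_points`
#' accepted points and tolerates under-filling: when `r` is too large to
#' place `n_points`, the available points are returned with a warning
#' rather than an error, since the caller needs one point per image at
#' most.
#'
#' @param canvas_dims `c(width, height)` of the sampling domain.
#' @param r minimum pairwise distance (> 0).
#' @param k candidates tried per active point (>= 1).
#' @param n_points number of points requested (>= 0).
#' @param seed integer seed; the same seed yields the identical point list.
#' @return tibble with `x`, `y`; all points in bounds, pairwise distances
#'   >= `r`.
#' @export
poisson_disc_sample <- function(canvas_dims, r, k = 30, n_points, seed = 42) {
  stopifnot(r > 0, k >= 1, n_points >= 0)
  if (n_points == 0) return(tibble::tibble(x = numeric(0), y = numeric(0)))
  w <- canvas_dims[1]; h <- canvas_dims[2]
  cell <- r / sqrt(2)
  nx <- max(1L, ceiling(w / cell)); ny <- max(1L, ceiling(h / cell))
  grid <- matrix(NA_integer_, ny, nx)    # index of the point in each cell
  px <- numeric(0); py <- numeric(0)
  cell_of <- function(x, y)
    c(min(ny, 1L + floor(y / cell)), min(nx, 1L + floor(x / cell)))
  valid <- function(x, y) {
    if (x < 0 || x >= w || y < 0 || y >= h) return(FALSE)
    cc <- cell_of(x, y)
    ri <- max(1L, cc[1] - 2L):min(ny, cc[1] + 2L)
    ci <- max(1L, cc[2] - 2L):min(nx, cc[2] + 2L)
    nb <- grid[ri, ci]; nb <- nb[!is.na(nb)]
    !length(nb) || all((px[nb] - x)^2 + (py[nb] - y)^2 >= r^2)
  }
  withr::with_seed(as.integer(seed), {
    x0 <- stats::runif(1, 0, w); y0 <- stats::runif(1, 0, h)
    px <- x0; py <- y0
    cc <- cell_of(x0, y0); grid[cc[1], cc[2]] <- 1L
    active <- 1L
    while (length(active) && length(px) < n_points) {
      ai <- active[sample.int(length(active), 1L)]
      placed <- FALSE
      for (t in seq_len(k)) {
        rho <- stats::runif(1, r, 2 * r)
        theta <- stats::runif(1, 0, 2 * pi)
        cx <- px[ai] + rho * cos(theta); cy <- py[ai] + rho * sin(theta)
        if (valid(cx, cy)) {
          px <- c(px, cx); py <- c(py, cy)
          cc <- cell_of(cx, cy); grid[cc[1], cc[2]] <- length(px)
          active <- c(active, length(px))
          placed <- TRUE
          break
        }
      }
      if (!placed) active <- setdiff(active, ai)
    }
  })
  if (length(px) < n_points)
    warning(sprintf(
      "poisson_disc_sample: placed %d of %d points (r = %g too large for the canvas)",
      length(px), n_points, r), call. = FALSE)
  tibble::tibble(x = px, y = py)
}

#' Shuffle the render order
#'
#' Uniform random permutation of the image ids, deterministic given the
#' seed. Later ids are drawn on top of earlier ones on the static canvas,
#' so shuffling reveals images hidden under overlaps.
#'
#' @param image_ids nonempty character vector.
#' @param seed integer seed.
#' @return permuted character vector.
#' @export
shuffle_order <- function(image_ids, seed = 42) {
  if (!length(image_ids)) stop("`image_ids` must be nonempty", call. = FALSE)
  withr::with_seed(as.integer(seed),
                   image_ids[sample.int(length(image_ids))])
}

#' Compute a full layout for a cohort
#'
#' Dispatches to the three layout modes and wraps the result with a render
#' order (shuffled when requested).
#'
#' @param image_ids cohort image ids.
#' @param mode `"coords"`, `"grid"` or `"random"`.
#' @param coords tibble `image_id`, `x`, `y`; required for `"coords"`.
#' @param canvas_dims `c(width, height)` px.
#' @param tile_dims `c(tile_w, tile_h)` px.
#' @param margin_px canvas margin for `"coords"`/`"random"`.
#' @param gap_px tile gap for `"grid"`.
#' @param r minimum tile-center distance for `"random"`; default one tile
#'   diagonal.
#' @param shuffle shuffle the render order?
#' @param seed seed governing sampling and shuffling.
#' @return a [layout_result()].
#' @export
compute_layout <- function(image_ids, mode = c("coords", "grid", "random"),
                           coords = NULL, canvas_dims = c(4000, 3000),
                           tile_dims, margin_px = 50, gap_px = 10, r = NULL,
                           shuffle = FALSE, seed = 42) {
  mode <- match.arg(mode)
  image_ids <- as.character(image_ids)
  if (mode == "coords") {
    if (is.null(coords)) stop("`coords` required for coordinate layout", call. = FALSE)
    missing_ids <- setdiff(image_ids, coords$image_id)
    if (length(missing_ids))
      stop(sprintf("no coordinates for: %s",
                   paste(missing_ids, collapse = ", ")), call. = FALSE)
    coords <- coords[match(image_ids, coords$image_id), ]
    pos <- scale_coords_to_canvas(coords, canvas_dims, tile_dims, margin_px)
  } else if (mode == "grid") {
    pos <- grid_layout(image_ids, canvas_dims[1], tile_dims, gap_px)
    need_h <- attr(pos, "canvas_height")
    if (need_h > canvas_dims[2]) canvas_dims[2] <- need_h
  } else {
    if (is.null(r)) r <- sqrt(sum(tile_dims^2))
    span <- c(canvas_dims[1] - 2 * margin_px - tile_dims[1],
              canvas_dims[2] - 2 * margin_px - tile_dims[2])
    pts <- poisson_disc_sample(span, r, n_points = length(image_ids), seed = seed)
    if (nrow(pts) < length(image_ids))
      stop("canvas too small to place all images at the requested spacing",
           call. = FALSE)
    pos <- tibble::tibble(image_id = image_ids,
                          x = margin_px + pts$x, y = margin_px + pts$y)
  }
  order_ids <- if (shuffle && length(image_ids)) shuffle_order(image_ids, seed)
               else image_ids
  layout_result(mode, pos, order_ids, canvas_dims, tile_dims)
}
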