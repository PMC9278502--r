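#' Thumbnail of a cleaned composite
#'
#' Downscales the RGB composite so its longer edge equals `max_edge`
#' (images already smaller are left unchanged), preserving aspect ratio with
#' half-up rounding of the shorter edge. Downscaling is by area averaging:
#' every source pixel contributes to exactly one destination pixel and each
#' destination pixel is the mean of its source block, so a constant image
#' downscales to the same constant.
#'
#' @param composite a [composite_channels()] result.
#' @param max_edge maximum tile edge in pixels (>= 16).
#' @param out_dir optional directory; when given the tile is written there as
#'   `<image_id>.png`.
#' @return an object of class `thumbnail` with fields `rgb_tile`
#'   (rows x cols x 3 integers in \[0, 255\]), `tile_dims`, `border_color`
#'   (`NA` until [add_border()]), `border_px`, `out_name` and `source_id`.
#' @export
make_thumbnail <- function(composite, max_edge = 222, out_dir = NULL) {
  stopifnot(inherits(composite, "cleaned_composite"))
  if (max_edge < 16) stop("`max_edge` must be >= 16", call. = FALSE)
  tile <- downscale_rgb(composite$rgb, max_edge)
  th <- structure(
    list(rgb_tile = tile,
         tile_dims = dim(tile)[1:2],
         border_color = NA_character_,
         border_px = 0L,
         out_name = paste0(composite$image_id, ".png"),
         source_id = composite$image_id),
    class = "thumbnail")
  if (!is.null(out_dir)) write_thumbnail(th, out_dir)
  th
}

#' Channel-weighted thumbnail
#'
#' Identical to [make_thumbnail()] except each cleaned channel is scaled by
#' its per-marker weight before the color blend, e.g. to emphasise tumor
#' over immune markers.
#'
#' @inheritParams composite_channels
#' @inheritParams make_thumbnail
#' @param weights named nonnegative multipliers keyed by the selected
#'   markers.
#' @return a `thumbnail`.
#' @export
make_weighted_thumbnail <- function(image, selection, weights,
                                    params = clean_params(), palette = NULL,
                                    max_edge = 222, out_dir = NULL) {
  if (any(weights < 0))
    stop("weights must be nonnegative", call. = FALSE)
  comp <- composite_channels(image, selection, params = params,
                             palette = palette, weights = weights)
  make_thumbnail(comp, max_edge = max_edge, out_dir = out_dir)
}

#' Paint a metadata-colored border around a thumbnail
#'
#' Pastes the tile onto a rectangle `2 * border_px` larger in each axis,
#' filled with `color`; the interior is the unbordered tile, pixel for
#' pixel.
#'
#' @param thumb a `thumbnail`.
#' @param color hex (or named) display color for the frame.
#' @param border_px frame thickness in pixels (>= 1).
#' @return the bordered `thumbnail`.
#' @export
add_border <- function(thumb, color, border_px = 4L) {
  stopifnot(inherits(thumb, "thumbnail"))
  border_px <- as.integer(border_px)
  if (border_px < 1L) stop("`border_px` must be >= 1", call. = FALSE)
  d <- dim(thumb$rgb_tile)
  out <- array(0L, c(d[1] + 2L * border_px, d[2] + 2L * border_px, 3L))
  col <- as.integer(round(hex_to_rgb(color)))
  for (p in 1:3) out[, , p] <- col[p]
  out[border_px + seq_len(d[1]), border_px + seq_len(d[2]), ] <- thumb$rgb_tile
  thumb$rgb_tile <- out
  thumb$tile_dims <- dim(out)[1:2]
  thumb$border_color <- color
  thumb$border_px <- border_px
  thumb
}

#' Write a thumbnail as PNG
#'
#' All thumbnails of a cohort land in one output-tiles directory under names
#' derived from their source image id, so the interactive canvas can report
#' the tile filename for any point.
#'
#' @param thumb a `thumbnail`.
#' @param dir output directory (created if missing).
#' @return the written path, invisibly.
#' @export
write_thumbnail <- function(thumb, dir) {
  stopifnot(inherits(thumb, "thumbnail"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, thumb$out_name)
  png::writePNG(thumb$rgb_tile / 255, path)
  invisible(path)
}

#' @export
print.thumbnail <- function(x, ...) {
  cat(sprintf("<thumbnail> %s: %d x %d px%s -> %s\n", x$source_id,
              x$tile_dims[1], x$tile_dims[2],
              if (!is.na(x$border_color))
                sprintf(" (border %s, %d px)", x$border_color, x$border_px)
              else "", x$out_name))
  invisible(x)
}

# area-average downscale of an rgb array; no-op if already within max_edge
downscale_rgb <- function(rgb, max_edge) {
  d <- dim(rgb)
  long <- max(d[1:2])
  if (long <= max_edge) return(array(as.integer(round(rgb)), d))
  scale <- max_edge / long
  out_h <- max(1L, as.integer(floor(d[1] * scale + 0.5)))
  out_w <- max(1L, as.integer(floor(d[2] * scale + 0.5)))
  gi <- floor((seq_len(d[1]) - 1) * out_h / d[1])
  gj <- floor((seq_len(d[2]) - 1) * out_w / d[2])
  cnt <- outer(tabulate(gi + 1L, out_h), tabulate(gj + 1L, out_w))
  out <- array(0L, c(out_h, out_w, 3L))
  for (p in 1:3) {
    s <- rowsum(rgb[, , p], gi)          # collapse rows
    s <- t(rowsum(t(s), gj))             # collapse cols
    out[, , p] <- as.integer(pmin(pmax(round(s / cnt), 0), 255))
  }
  out
}
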