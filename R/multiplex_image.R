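#' Multiplex image container
#'
#' A `multiplex_image` holds one multichannel tissue image as a numeric array
#' of dimension `rows x cols x channels`, together with ordered marker names,
#' the container dialect it came from and an identifier derived from the file
#' name. Intensities are kept exactly as stored on disk; conversion to
#' unsigned-byte range happens only during channel cleaning.
#'
#' @param channels numeric array, `rows x cols x channels` (a matrix is
#'   accepted and treated as a single channel).
#' @param marker_names character vector of channel labels, one per plane.
#'   `NULL` autogenerates `"ch00".."chNN"`.
#' @param source_format one of `"tiff"`, `"ome-tiff"`, `"qptiff"`.
#' @param image_id identifier, unique within a cohort; usually the file
#'   basename without extension.
#'
#' @return an object of class `multiplex_image` with fields `channels`,
#'   `marker_names`, `source_format`, `pixel_dims` (rows, cols) and
#'   `image_id`.
#' @export
multiplex_image <- function(channels, marker_names = NULL,
                            source_format = c("tiff", "ome-tiff", "qptiff"),
                            image_id = "image") {
  source_format <- match.arg(source_format)
  if (is.matrix(channels)) channels <- array(channels, c(dim(channels), 1L))
  if (!is.array(channels) || length(dim(channels)) != 3L)
    stop("`channels` must be a rows x cols x channels array", call. = FALSE)
  n_ch <- dim(channels)[3]
  if (is.null(marker_names))
    marker_names <- sprintf("ch%02d", seq_len(n_ch) - 1L)
  if (length(marker_names) != n_ch)
    stop(sprintf("dimension mismatch: %d marker names for %d channel planes",
                 length(marker_names), n_ch), call. = FALSE)
  structure(
    list(channels = channels,
         marker_names = as.character(marker_names),
         source_format = source_format,
         pixel_dims = dim(channels)[1:2],
         image_id = as.character(image_id)),
    class = "multiplex_image")
}

#' @export
print.multiplex_image <- function(x, ...) {
  cat(sprintf("<multiplex_image> %s [%s]\n", x$image_id, x$source_format))
  cat(sprintf("  %d channel(s), %d x %d px\n",
              length(x$marker_names), x$pixel_dims[1], x$pixel_dims[2]))
  cat("  markers:", paste(utils::head(x$marker_names, 8), collapse = ", "),
      if (length(x$marker_names) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.multiplex_image <- function(x) dim(x$channels)

#' Extract one channel plane
#'
#' @param image a [multiplex_image()].
#' @param marker channel index or marker name.
#' @return a numeric matrix (rows x cols).
#' @export
get_channel <- function(image, marker) {
  stopifnot(inherits(image, "multiplex_image"))
  if (is.character(marker)) {
    idx <- match(marker, image$marker_names)
    if (is.na(idx))
      stop(sprintf("unknown marker '%s'; valid markers: %s", marker,
                   paste(image$marker_names, collapse = ", ")), call. = FALSE)
  } else idx <- as.integer(marker)
  image$channels[, , idx]
}
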