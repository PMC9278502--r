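#' Channel-cleaning parameters
#'
#' Parameters of the per-channel denoising pipeline. Defaults follow common
#' practice for immunofluorescence rasters: a 3x3 median window, a disc of
#' radius 1 for morphological closing, and a 1.5x foreground upweight.
#' Cleaned output is always unsigned-byte, i.e. integers in \[0, 255\].
#'
#' @param median_kernel odd integer window edge (px) of the median filter;
#'   1 disables filtering.
#' @param closing_radius radius (px) of the disc structuring element used to
#'   close gaps in the foreground mask; 0 disables closing.
#' @param upweight_factor multiplier (>= 1) applied to surviving foreground
#'   intensities, clipped at 255.
#' @return an object of class `clean_params`.
#' @export
clean_params <- function(median_kernel = 3L, closing_radius = 1L,
                         upweight_factor = 1.5) {
  median_kernel <- as.integer(median_kernel)
  closing_radius <- as.integer(closing_radius)
  if (median_kernel < 1L || median_kernel %% 2L == 0L)
    stop("`median_kernel` must be an odd integer >= 1", call. = FALSE)
  if (closing_radius < 0L) stop("`closing_radius` must be >= 0", call. = FALSE)
  if (upweight_factor < 1) stop("`upweight_factor` must be >= 1", call. = FALSE)
  structure(list(median_kernel = median_kernel,
                 closing_radius = closing_radius,
                 upweight_factor = upweight_factor,
                 output_range = c(0L, 255L)),
            class = "clean_params")
}

# Bring a raster of arbitrary stored dtype to integer [0,255].
# Unit-range floats are rescaled by 255; wider ranges are min-max scaled per
# channel; byte-range data pass through (rounded).
to_byte <- function(raster) {
  v <- raster
  rng <- range(v)
  if (!all(is.finite(rng))) stop("raster contains non-finite values", call. = FALSE)
  if (rng[2] <= 1 && rng[1] >= 0 && any(v != round(v))) {
    v <- v * 255
  } else if (rng[2] > 255 || rng[1] < 0) {
    v <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) * 255 else v * 0
  }
  matrix(as.integer(pmin(pmax(round(v), 0L), 255L)), nrow(raster), ncol(raster))
}

#' Otsu intensity threshold
#'
#' Finds the histogram threshold that minimizes the total within-class
#' intensity variance of the foreground/background split it induces
#' (equivalently, maximizes the between-class variance). Pixels strictly
#' above the returned threshold are foreground. The raster is rounded and
#' clipped to integer levels 0..255 before the histogram is built. When the
#' minimizing threshold is a plateau (exactly tied splits), the plateau
#' midpoint is returned.
#'
#' @param raster numeric matrix with values in \[0, 255\] (values outside are
#'   clipped).
#' @return the threshold (double), with attribute `degenerate = TRUE` when
#'   the raster is constant (the constant is returned and the whole image is
#'   background, since no pixel exceeds it).
#' @export
otsu_threshold <- function(raster) {
  v <- as.numeric(raster)
  if (!length(v)) stop("raster must have at least one pixel", call. = FALSE)
  v <- pmin(pmax(round(v), 0), 255)
  if (min(v) == max(v))
    return(structure(min(v), degenerate = TRUE))
  h <- as.numeric(tabulate(as.integer(v) + 1L, nbins = 256L))
  lev <- 0:255
  n <- sum(h)
  csum <- cumsum(h)
  cmom <- cumsum(h * lev)
  wA <- csum[1:255]; wB <- n - wA
  valid <- wA > 0 & wB > 0
  muA <- ifelse(valid, cmom[1:255] / wA, 0)
  muB <- ifelse(valid, (cmom[256] - cmom[1:255]) / wB, 0)
  between <- wA * wB * (muA - muB)^2
  between[!valid] <- -Inf
  cand <- lev[1:255][between == max(between)]
  structure(mean(cand), degenerate = FALSE)
}

# median filter with replicate border padding; window edge k (odd), k = 1 is
# identity. The common 3x3 case uses a vectorized median-of-9 sorting
# network; larger windows go through EBImage's constant-time filter.
median_filter_byte <- function(byte, k) {
  if (k <= 1L) return(byte)
  if (k == 3L) return(median3x3(byte))
  half <- (k - 1L) %/% 2L
  f <- EBImage::medianFilter(byte / 255, size = half)
  matrix(as.integer(pmin(pmax(round(f * 255), 0L), 255L)), nrow(byte), ncol(byte))
}

# median of the 3x3 neighborhood via the classic 19-exchange sorting network,
# evaluated on nine shifted copies of the (replicate-padded) raster
median3x3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- m[c(1L, seq_len(nr), nr), c(1L, seq_len(nc), nc)]
  v <- vector("list", 9L)
  i <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    i <- i + 1L
    v[[i]] <- pad[seq_len(nr) + 1L + dr, seq_len(nc) + 1L + dc]
  }
  s2 <- function(a, b) {
    lo <- pmin(v[[a]], v[[b]]); v[[b]] <<- pmax(v[[a]], v[[b]]); v[[a]] <<- lo
  }
  # exchange sequence (0-indexed in the classic listing, +1 here)
  s2(2,3); s2(5,6); s2(8,9); s2(1,2); s2(4,5); s2(7,8); s2(2,3); s2(5,6)
  s2(8,9); s2(1,4); s2(6,9); s2(5,8); s2(4,7); s2(2,5); s2(3,6); s2(5,8)
  s2(5,3); s2(7,5); s2(5,3)
  matrix(as.integer(v[[5]]), nr, nc)
}

# drop mask components touching the raster border
clear_border_mask <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  edge <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  edge <- edge[edge > 0]
  if (length(edge)) mask[lab %in% edge] <- 0L
  mask
}

#' Clean one marker channel
#'
#' The per-channel denoising pipeline: (1) median filtering to remove noise
#' while preserving edges; (2) Otsu thresholding to split foreground from
#' background; (3) morphological closing of the foreground mask to refine
#' morphological boundaries; (4) clearing of mask components that touch the
#' image border; (5) upweighting of the surviving foreground intensities,
#' clipped to \[0, 255\]. The mask is applied multiplicatively to the
#' median-filtered intensities, so foreground morphology is preserved;
#' background pixels are 0.
#'
#' @param raster numeric matrix (any stored dtype; converted to byte range).
#' @param params a [clean_params()].
#' @return integer matrix in \[0, 255\], same dimensions as `raster`.
#' @export
clean_channel <- function(raster, params = clean_params()) {
  stopifnot(inherits(params, "clean_params"))
  if (!is.matrix(raster) || !length(raster))
    stop("`raster` must be a nonempty matrix", call. = FALSE)
  byte <- to_byte(raster)
  filt <- median_filter_byte(byte, params$median_kernel)
  thr <- otsu_threshold(filt)
  if (isTRUE(attr(thr, "degenerate")))
    return(matrix(0L, nrow(raster), ncol(raster)))
  mask <- matrix(as.integer(filt > as.numeric(thr)), nrow(filt), ncol(filt))
  if (params$closing_radius > 0L) {
    brush <- EBImage::makeBrush(2L * params$closing_radius + 1L, shape = "disc")
    mask <- matrix(as.integer(EBImage::closing(mask, brush) > 0),
                   nrow(mask), ncol(mask))
  }
  mask <- clear_border_mask(mask)
  out <- pmin(round(filt * params$upweight_factor), 255) * mask
  matrix(as.integer(out), nrow(raster), ncol(raster))
}

#' Clean selected marker channels and composite them into an RGB image
#'
#' Each selected channel is cleaned independently with [clean_channel()]
#' (optionally scaled by a per-marker weight afterwards), colored with its
#' display color and additively blended; the blend is clipped to \[0, 255\].
#' Unselected channels contribute nothing.
#'
#' @param image a [multiplex_image()].
#' @param selection character vector of marker names to composite (subset of
#'   `image$marker_names`).
#' @param params a [clean_params()].
#' @param palette optional named vector of hex colors keyed by marker;
#'   markers without an entry get the default categorical cycle in selection
#'   order.
#' @param weights optional named nonnegative multipliers keyed by marker
#'   (default 1 for all).
#' @return an object of class `cleaned_composite` with fields
#'   `cleaned_channels` (rows x cols x n_selected integer array),
#'   `selected_markers`, `rgb` (rows x cols x 3, \[0, 255\]), `palette` and
#'   `image_id`.
#' @export
composite_channels <- function(image, selection, params = clean_params(),
                               palette = NULL, weights = NULL) {
  stopifnot(inherits(image, "multiplex_image"))
  selection <- as.character(selection)
  if (!length(selection)) stop("`selection` must be nonempty", call. = FALSE)
  bad <- setdiff(selection, image$marker_names)
  if (length(bad))
    stop(sprintf("unknown marker(s) %s; valid names: %s",
                 paste(sQuote(bad), collapse = ", "),
                 paste(image$marker_names, collapse = ", ")), call. = FALSE)
  pal <- stats::setNames(default_palette(length(selection)), selection)
  if (!is.null(palette)) {
    known <- intersect(names(palette), selection)
    pal[known] <- palette[known]
  }
  w <- stats::setNames(rep(1, length(selection)), selection)
  if (!is.null(weights)) {
    if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
    known <- intersect(names(weights), selection)
    w[known] <- weights[known]
  }
  d <- image$pixel_dims
  cleaned <- array(0L, c(d, length(selection)))
  rgb <- array(0, c(d, 3L))
  for (i in seq_along(selection)) {
    ch <- clean_channel(get_channel(image, selection[i]), params)
    ch <- pmin(round(ch * w[[i]]), 255)
    cleaned[, , i] <- as.integer(ch)
    col <- hex_to_rgb(pal[[i]]) / 255
    for (p in 1:3) rgb[, , p] <- rgb[, , p] + ch * col[p]
  }
  rgb <- array(as.integer(pmin(round(rgb), 255)), dim(rgb))
  structure(list(cleaned_channels = cleaned,
                 selected_markers = selection,
                 rgb = rgb, palette = pal, image_id = image$image_id),
            class = "cleaned_composite")
}

#' @export
print.cleaned_composite <- function(x, ...) {
  cat(sprintf("<cleaned_composite> %s: %d marker(s) [%s], %d x %d px\n",
              x$image_id, length(x$selected_markers),
              paste(x$selected_markers, collapse = ", "),
              dim(x$rgb)[1], dim(x$rgb)[2]))
  invisible(x)
}
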