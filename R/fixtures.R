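#' Recipe for a synthetic multiplexed cohort
#'
#' Describes a cohort of synthetic multichannel immunofluorescence images:
#' each channel is a dark background plus compact Gaussian-profile bright
#' blobs (cells appear as compact bright regions in IF imagery) plus
#' additive pixel noise, clipped to the 8-bit range. Blob centers are kept
#' at least three blob sigmas away from the border, so a channel's spatial
#' mean is (up to noise) independent of where the blobs land; within-group
#' variation of the channel means is then governed by the relative
#' amplitude jitter, which makes group effect sizes well-posed in
#' pooled-standard-deviation units: on the differing channels the two group
#' amplitudes are `effect_size` within-group standard deviations apart.
#'
#' The default recipe mirrors a 7-channel Vectra field of view at quarter
#' linear scale (336 x 252 of 1,344 x 1,008) so the full pipeline runs in
#' seconds; pass `image_dims = c(1008, 1344)` for a full-scale image.
#'
#' @param n_images number of images in the cohort.
#' @param n_channels channels per image.
#' @param image_dims `c(rows, cols)` in px.
#' @param n_groups number of groups (balanced assignment).
#' @param blob_count blobs per channel.
#' @param blob_sigma blob Gaussian sigma (px).
#' @param background background intensity (8-bit units).
#' @param base_amp baseline blob amplitude (8-bit units).
#' @param noise_sd additive pixel-noise standard deviation.
#' @param rel_jitter relative (CV) per-image amplitude jitter within group.
#' @param effect_size between-group separation of differing channel means,
#'   in pooled-SD units.
#' @param diff_channels channels whose abundance differs by group (within
#'   the first six, so the inbuilt feature vector sees the difference).
#' @param group_means optional `n_groups x n_channels` amplitude matrix
#'   overriding the constructed one.
#' @param seed integer seed for the whole cohort.
#' @return an object of class `cohort_recipe`.
#' @export
cohort_recipe <- function(n_images = 12, n_channels = 7,
                          image_dims = c(252, 336), n_groups = 2,
                          blob_count = 12, blob_sigma = 6, background = 8,
                          base_amp = 100, noise_sd = 4, rel_jitter = 0.03,
                          effect_size = 5, diff_channels = c(2, 5),
                          group_means = NULL, seed = 42) {
  stopifnot(n_images >= 1, n_channels >= 1, all(image_dims >= 16),
            n_groups >= 1, effect_size >= 0, rel_jitter > 0)
  diff_channels <- diff_channels[diff_channels <= n_channels]
  if (is.null(group_means)) {
    group_means <- matrix(base_amp, n_groups, n_channels)
    # each group after the first is raised on the differing channels by
    # effect_size within-group SDs (SD of the channel mean ~ rel_jitter * amp)
    if (n_groups > 1 && length(diff_channels))
      for (g in 2:n_groups)
        group_means[g, diff_channels] <-
          base_amp * (1 + (g - 1) * effect_size * rel_jitter)
  }
  stopifnot(nrow(group_means) == n_groups, ncol(group_means) == n_channels)
  structure(list(n_images = n_images, n_channels = n_channels,
                 image_dims = as.integer(image_dims), n_groups = n_groups,
                 blob_count = blob_count, blob_sigma = blob_sigma,
                 background = background, noise_sd = noise_sd,
                 rel_jitter = rel_jitter, effect_size = effect_size,
                 group_means = group_means, seed = as.integer(seed)),
            class = "cohort_recipe")
}

#' Generate one synthetic multichannel image
#'
#' @param recipe a [cohort_recipe()].
#' @param group group index (1-based).
#' @param seed integer seed for this image.
#' @param image_id identifier for the result.
#' @return a [multiplex_image()] with integer intensities in \[0, 255\].
#' @export
generate_image <- function(recipe, group = 1, seed = recipe$seed,
                           image_id = "synthetic") {
  stopifnot(inherits(recipe, "cohort_recipe"), group >= 1,
            group <= recipe$n_groups)
  d <- recipe$image_dims
  s <- recipe$blob_sigma
  arr <- withr::with_seed(as.integer(seed), {
    a <- array(0, c(d, recipe$n_channels))
    for (ch in seq_len(recipe$n_channels)) {
      plane <- matrix(recipe$background, d[1], d[2])
      amp <- recipe$group_means[group, ch] *
        (1 + stats::rnorm(1, 0, recipe$rel_jitter))
      if (recipe$blob_count > 0 && amp > 0) {
        lo <- 3 * s
        # blue-noise blob placement (centers >= 2.5 sigma apart) keeps blob
        # peaks from stacking above the 8-bit ceiling, so the channel's
        # spatial mean stays independent of where the blobs land
        sub_seed <- sample.int(2147483646L, 1L)
        pts <- suppressWarnings(poisson_disc_sample(
          c(d[2] - 2 * lo, d[1] - 2 * lo), r = 2.5 * s,
          n_points = recipe$blob_count, seed = sub_seed))
        if (nrow(pts) < recipe$blob_count)
          warning(sprintf(
            "placed %d of %d blobs; image too small for the blob spacing",
            nrow(pts), recipe$blob_count), call. = FALSE)
        cy <- lo + pts$y; cx <- lo + pts$x
        for (b in seq_len(nrow(pts))) {
          # each blob only touches a +/- 4 sigma window
          ri <- max(1L, floor(cy[b] - 4 * s)):min(d[1], ceiling(cy[b] + 4 * s))
          ci <- max(1L, floor(cx[b] - 4 * s)):min(d[2], ceiling(cx[b] + 4 * s))
          plane[ri, ci] <- plane[ri, ci] +
            amp * exp(-(outer((ri - cy[b])^2, (ci - cx[b])^2, "+")) / (2 * s^2))
        }
      }
      if (recipe$noise_sd > 0)
        plane <- plane + stats::rnorm(length(plane), 0, recipe$noise_sd)
      a[, , ch] <- pmin(pmax(round(plane), 0), 255)
    }
    a
  })
  multiplex_image(array(as.integer(arr), dim(arr)),
                  marker_names = sprintf("marker%02d", seq_len(recipe$n_channels)),
                  source_format = "tiff", image_id = image_id)
}

#' Generate a cohort on disk
#'
#' Writes `n_images` images (balanced across groups) in the requested
#' container dialect, plus the metadata tables the reader expects (one file
#' per category: `group`, `patient`) and optionally a coordinate file, laid
#' out as
#' \preformatted{
#'   dir/images/img001.<ext> ...
#'   dir/metadata/group.csv, dir/metadata/patient.csv
#'   dir/coords.csv            (when write_coords = TRUE)
#' }
#'
#' @param recipe a [cohort_recipe()].
#' @param dir output directory (created).
#' @param format `"tiff"`, `"ome-tiff"` or `"qptiff"`.
#' @param write_coords also write a Poisson-disc coordinate file?
#' @return invisibly, a list with `images` (named list of
#'   [multiplex_image()]), `image_dir`, `metadata_dir`, `coord_file`
#'   (`NULL` unless written) and `groups` (named group index per id).
#' @export
generate_cohort <- function(recipe, dir,
                            format = c("tiff", "ome-tiff", "qptiff"),
                            write_coords = FALSE) {
  format <- match.arg(format)
  image_dir <- file.path(dir, "images")
  meta_dir <- file.path(dir, "metadata")
  dir.create(image_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(meta_dir, recursive = TRUE, showWarnings = FALSE)
  ext <- switch(format, "tiff" = ".tif", "ome-tiff" = ".ome.tif",
                "qptiff" = ".qptiff")
  ids <- sprintf("img%03d", seq_len(recipe$n_images))
  groups <- ((seq_len(recipe$n_images) - 1L) %% recipe$n_groups) + 1L
  names(groups) <- ids
  images <- list()
  for (i in seq_len(recipe$n_images)) {
    seed_i <- (recipe$seed %% 100000L) * 10007L + i * 7919L
    im <- generate_image(recipe, group = groups[i], seed = seed_i,
                         image_id = ids[i])
    write_multiplex_tiff(im, file.path(image_dir, paste0(ids[i], ext)),
                         format = format)
    images[[ids[i]]] <- im
  }
  utils::write.table(
    data.frame(image_id = ids, value = sprintf("group%d", groups)),
    file.path(meta_dir, "group.csv"), sep = ",", row.names = FALSE,
    quote = FALSE)
  utils::write.table(
    data.frame(image_id = ids,
               value = sprintf("P%d", ((seq_along(ids) - 1L) %/% 2L) + 1L)),
    file.path(meta_dir, "patient.csv"), sep = ",", row.names = FALSE,
    quote = FALSE)
  coord_file <- NULL
  if (write_coords) {
    pts <- poisson_disc_sample(c(100, 100), r = 100 / (recipe$n_images + 2),
                               n_points = recipe$n_images, seed = recipe$seed)
    coord_file <- file.path(dir, "coords.csv")
    write_coordinates(
      tibble::tibble(image_id = ids, x = pts$x, y = pts$y), coord_file)
  }
  invisible(list(images = images, image_dir = image_dir,
                 metadata_dir = meta_dir, coord_file = coord_file,
                 groups = groups))
}

#' Write a multiplex image as plain TIFF, OME-TIFF or QPTIFF
#'
#' Test-image writer: a minimal little-endian uncompressed multi-page TIFF
#' encoder (grayscale 8/16-bit, one strip per plane) that can place an
#' OME-XML channel description on the first page — which the installed TIFF
#' bindings cannot — so OME-TIFF and pyramidal QPTIFF fixtures can be
#' fabricated offline. `"qptiff"` writes a two-level pyramid (full
#' resolution plus a half-resolution level per channel) with the channel
#' names embedded the same way.
#'
#' @param image a [multiplex_image()] with integer intensities.
#' @param path output path.
#' @param format container dialect.
#' @param bits 8 or 16 bits per sample.
#' @return `path`, invisibly.
#' @export
write_multiplex_tiff <- function(image, path,
                                 format = c("tiff", "ome-tiff", "qptiff"),
                                 bits = 8L) {
  format <- match.arg(format)
  stopifnot(inherits(image, "multiplex_image"))
  planes <- lapply(seq_along(image$marker_names),
                   function(c) image$channels[, , c])
  desc <- NULL
  if (format %in% c("ome-tiff", "qptiff"))
    desc <- build_ome_xml(image$marker_names, image$pixel_dims, bits)
  if (format == "qptiff") {
    half <- lapply(planes, halve_plane)
    planes <- c(planes, half)
  }
  write_tiff_pages(planes, path, bits = bits, description = desc)
  invisible(path)
}

halve_plane <- function(p) {
  h <- nrow(p) %/% 2L; w <- ncol(p) %/% 2L
  q <- p[seq_len(2L * h), seq_len(2L * w)]
  round((q[seq(1, 2 * h, 2), seq(1, 2 * w, 2)] +
         q[seq(2, 2 * h, 2), seq(1, 2 * w, 2)] +
         q[seq(1, 2 * h, 2), seq(2, 2 * w, 2)] +
         q[seq(2, 2 * h, 2), seq(2, 2 * w, 2)]) / 4)
}

build_ome_xml <- function(marker_names, dims, bits = 8L) {
  ch <- paste0(sprintf(
    '<Channel ID="Channel:0:%d" Name="%s" SamplesPerPixel="1"/>',
    seq_along(marker_names) - 1L, marker_names), collapse = "")
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<OME xmlns="http://www.openmicroscopy.org/Schemas/OME/2016-06">',
    '<Image ID="Image:0" Name="image">',
    sprintf(paste0('<Pixels ID="Pixels:0" DimensionOrder="XYCZT" Type="uint%d" ',
                   'SizeX="%d" SizeY="%d" SizeC="%d" SizeZ="1" SizeT="1">'),
            bits, dims[2], dims[1], length(marker_names)),
    ch, '<TiffData/></Pixels></Image></OME>')
}

# minimal little-endian multi-page TIFF writer: grayscale 8/16-bit,
# uncompressed, one strip per plane, optional ImageDescription on page 1
write_tiff_pages <- function(planes, path, bits = 8L, description = NULL) {
  stopifnot(bits %in% c(8L, 16L))
  con <- file(path, "wb"); on.exit(close(con))
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); u16(42L)
  u32(0L)                                   # IFD0 offset, patched below
  pos <- 8L
  n <- length(planes)
  offsets <- integer(n)
  desc_raw <- if (!is.null(description)) c(charToRaw(description), as.raw(0))
              else raw(0)
  for (i in seq_len(n)) {
    p <- planes[[i]]
    h <- nrow(p); w <- ncol(p)
    vals <- as.integer(round(t(p)))         # TIFF strips are row-major
    dat <- if (bits == 8L) as.raw(pmin(pmax(vals, 0L), 255L))
           else writeBin(pmin(pmax(vals, 0L), 65535L), raw(), size = 2,
                         endian = "little")
    data_off <- pos
    writeBin(dat, con); pos <- pos + length(dat)
    if (pos %% 2L == 1L) { writeBin(as.raw(0), con); pos <- pos + 1L }
    desc_off <- 0L
    if (i == 1L && length(desc_raw)) {
      desc_off <- pos; writeBin(desc_raw, con); pos <- pos + length(desc_raw)
      if (pos %% 2L == 1L) { writeBin(as.raw(0), con); pos <- pos + 1L }
    }
    tags <- list(
      c(256L, 4L, 1L, w),                   # ImageWidth
      c(257L, 4L, 1L, h),                   # ImageLength
      c(258L, 3L, 1L, bits),                # BitsPerSample
      c(259L, 3L, 1L, 1L),                  # Compression: none
      c(262L, 3L, 1L, 1L),                  # Photometric: BlackIsZero
      c(273L, 4L, 1L, data_off),            # StripOffsets
      c(277L, 3L, 1L, 1L),                  # SamplesPerPixel
      c(278L, 4L, 1L, h),                   # RowsPerStrip
      c(279L, 4L, 1L, length(dat)))         # StripByteCounts
    if (i == 1L && length(desc_raw))
      tags <- c(tags, list(c(270L, 2L, length(desc_raw), desc_off)))
    tags <- tags[order(vapply(tags, function(t) as.integer(t[1]), 0L))]
    offsets[i] <- pos
    u16(length(tags))
    for (tg in tags) {
      u16(tg[1]); u16(tg[2]); u32(tg[3])
      if (tg[2] == 3L && tg[3] == 1L) { u16(tg[4]); u16(0L) } else u32(tg[4])
    }
    u32(0L)                                 # next-IFD pointer, patched below
    pos <- pos + 2L + 12L * length(tags) + 4L
  }
  seek(con, 4L, rw = "write"); u32(offsets[1])
  for (i in seq_len(n)) {
    nt <- if (i == 1L && length(desc_raw)) 10L else 9L
    seek(con, offsets[i] + 2L + 12L * nt, rw = "write")
    u32(if (i < n) offsets[i + 1] else 0L)
  }
  invisible(path)
}
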