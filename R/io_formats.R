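#' Read a multichannel image from a TIFF-family container
#'
#' Supports the three container dialects in common use for multiplexed tissue
#' imaging: plain multi-page TIFF (one page per marker), OME-TIFF (channel
#' names embedded as OME-XML in the ImageDescription tag) and pyramidal
#' QPTIFF (Vectra-compatible; several resolution levels per channel).
#'
#' Marker names are resolved with the precedence: embedded channel metadata,
#' then the supplied `marker_names`, then autogenerated `"ch00".."chNN"`.
#' For pyramidal files `pyramid_policy` picks the resolution level:
#' `"max_edge"` loads the highest-resolution level whose longer edge does not
#' exceed `max_edge` pixels (falling back to the smallest level if all exceed
#' it); `"full"` always loads the full-resolution level.
#'
#' @param path path to a `.tif`, `.tiff`, `.ome.tif(f)` or `.qptiff` file.
#' @param marker_names optional character vector of channel labels, used when
#'   the file embeds none; length must equal the number of channel planes.
#' @param pyramid_policy `"max_edge"` or `"full"`.
#' @param max_edge pixel bound used by the `"max_edge"` policy.
#' @return a [multiplex_image()].
#' @export
read_multiplex <- function(path, marker_names = NULL,
                           pyramid_policy = c("max_edge", "full"),
                           max_edge = 4096) {
  pyramid_policy <- match.arg(pyramid_policy)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  dialect <- guess_dialect(path)
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE),
    error = function(e)
      stop(sprintf("cannot read %s container '%s': %s",
                   dialect, path, conditionMessage(e)), call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  # a page may be rows x cols or rows x cols x samples; keep first sample
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)

  desc <- attr(pages[[1]], "description")
  embedded <- if (!is.null(desc)) parse_channel_names(desc) else NULL
  is_ome <- !is.null(desc) && grepl("<OME", desc, fixed = TRUE)

  # group pages into pyramid levels by their pixel dimensions, encounter order
  dims_key <- vapply(pages, function(p) paste(dim(p), collapse = "x"), "")
  levels <- split(seq_along(pages), factor(dims_key, levels = unique(dims_key)))
  if (length(levels) > 1L || dialect == "qptiff") {
    edge <- vapply(levels, function(ix) max(dim(pages[[ix[1]]])), 0)
    keep <- if (pyramid_policy == "full") which.max(edge) else {
      ok <- which(edge <= max_edge)
      if (length(ok)) ok[which.max(edge[ok])] else which.min(edge)
    }
    pages <- pages[levels[[keep]]]
    if (length(levels) > 1L && dialect != "qptiff") dialect <- "qptiff"
  } else if (is_ome) dialect <- "ome-tiff"

  n_ch <- length(pages)
  nm <- embedded
  if (!is.null(nm) && length(nm) != n_ch) nm <- NULL
  if (is.null(nm) && !is.null(marker_names)) {
    if (length(marker_names) != n_ch)
      stop(sprintf("dimension mismatch: %d marker names supplied for %d planes",
                   length(marker_names), n_ch), call. = FALSE)
    nm <- marker_names
  }
  d <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), d), TRUE)))
    stop(sprintf("planes of '%s' disagree in size within one pyramid level", path),
         call. = FALSE)
  arr <- array(unlist(pages, use.names = FALSE), c(d, n_ch))
  multiplex_image(arr, marker_names = nm, source_format = dialect,
                  image_id = strip_image_ext(path))
}

guess_dialect <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.qptiff$", lp)) "qptiff"
  else if (grepl("\\.ome\\.tiff?$", lp)) "ome-tiff"
  else "tiff"
}

strip_image_ext <- function(path) {
  sub("\\.(ome\\.tiff?|qptiff|tiff?)$", "", basename(path), ignore.case = TRUE)
}

# Channel names from an embedded OME-XML (or OME-style) description.
parse_channel_names <- function(desc) {
  if (!nzchar(trimws(desc)) || !grepl("<", desc, fixed = TRUE)) return(NULL)
  doc <- tryCatch(xml2::read_xml(desc), error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  ch <- xml2::xml_find_all(doc, "//*[local-name()='Channel']")
  if (!length(ch)) return(NULL)
  nm <- xml2::xml_attr(ch, "Name")
  if (all(is.na(nm))) return(NULL)
  nm
}

#' Read a cohort of multichannel images from a directory
#'
#' @param dir directory containing TIFF-family images.
#' @param ... forwarded to [read_multiplex()].
#' @return a named list of [multiplex_image()] objects, keyed and ordered by
#'   `image_id` (file basename without extension). Unreadable files are
#'   skipped with a warning; an error is raised only if nothing loads.
#' @export
read_cohort <- function(dir, ...) {
  files <- sort(list.files(dir, pattern = "\\.(tiff?|qptiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  imgs <- list()
  for (f in files) {
    im <- tryCatch(read_multiplex(f, ...), error = function(e) {
      warning(sprintf("skipping '%s': %s", f, conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (!is.null(im)) imgs[[im$image_id]] <- im
  }
  if (!length(imgs)) stop(sprintf("no readable images in '%s'", dir), call. = FALSE)
  if (anyDuplicated(names(imgs)))
    stop("image_id values are not unique within the cohort", call. = FALSE)
  imgs
}

#' Read per-image categorical metadata from a directory of tables
#'
#' Each delimited file (comma or tab, sniffed; header row) in `dir` defines
#' one annotation category named after the file: its first column is the
#' `image_id`, its second the category value. A file named `colors.*` is
#' instead read as a value-to-display-color map (columns `value`, `color`).
#' Duplicate `image_id` rows within a category keep the last occurrence with
#' a warning; rows referencing ids absent from `image_ids` (when given) are
#' skipped with a warning.
#'
#' @param dir directory of annotation tables; may be empty or missing.
#' @param image_ids optional character vector of known cohort ids.
#' @return an object of class `cohort_metadata`: a list with `annotations`
#'   (tibble `image_id`, `category`, `value`) and `colors` (named character
#'   vector, possibly empty).
#' @export
read_metadata_dir <- function(dir, image_ids = NULL) {
  colors <- character(0)
  ann <- tibble::tibble(image_id = character(0), category = character(0),
                        value = character(0))
  if (!is.null(dir) && dir.exists(dir)) {
    files <- sort(list.files(dir, pattern = "\\.(csv|tsv|txt)$",
                             ignore.case = TRUE, full.names = TRUE))
    for (f in files) {
      tab <- read_delim_sniffed(f)
      if (is.null(tab) || !ncol(tab)) next
      cat_name <- tools::file_path_sans_ext(basename(f))
      if (tolower(cat_name) == "colors") {
        if (ncol(tab) >= 2) colors[as.character(tab[[1]])] <- as.character(tab[[2]])
        next
      }
      ids <- as.character(tab[[1]]); vals <- as.character(tab[[2]])
      if (!is.null(image_ids)) {
        bad <- !ids %in% image_ids
        if (any(bad)) {
          warning(sprintf("%s: skipping %d row(s) with unknown image_id (%s)",
                          basename(f), sum(bad),
                          paste(utils::head(ids[bad], 3), collapse = ", ")),
                  call. = FALSE)
          ids <- ids[!bad]; vals <- vals[!bad]
        }
      }
      if (anyDuplicated(ids)) {
        warning(sprintf("%s: duplicate image_id rows; keeping the last", basename(f)),
                call. = FALSE)
        keep <- !duplicated(ids, fromLast = TRUE)
        ids <- ids[keep]; vals <- vals[keep]
      }
      ann <- dplyr::bind_rows(ann, tibble::tibble(
        image_id = ids, category = cat_name, value = vals))
    }
  }
  structure(list(annotations = ann, colors = colors), class = "cohort_metadata")
}

#' @export
print.cohort_metadata <- function(x, ...) {
  cats <- unique(x$annotations$category)
  cat(sprintf("<cohort_metadata> %d annotation(s) in %d categor%s\n",
              nrow(x$annotations), length(cats),
              if (length(cats) == 1) "y" else "ies"))
  if (length(cats)) cat("  categories:", paste(cats, collapse = ", "), "\n")
  if (length(x$colors))
    cat("  color map:", paste(names(x$colors), collapse = ", "), "\n")
  invisible(x)
}

#' Categories present in a metadata object
#' @param metadata a `cohort_metadata`.
#' @return character vector of category names (possibly empty).
#' @export
metadata_categories <- function(metadata) {
  unique(metadata$annotations$category)
}

#' Per-image display colors for one annotation category
#'
#' Uses the metadata's own color map when it covers the category's values,
#' otherwise assigns the default categorical palette over the sorted unique
#' values.
#'
#' @param metadata a `cohort_metadata`.
#' @param category category name.
#' @param image_ids ids to resolve (default: all annotated ids).
#' @return named character vector of hex colors, one per resolved id;
#'   ids lacking the annotation get `NA`.
#' @export
annotation_colors <- function(metadata, category, image_ids = NULL) {
  ann <- dplyr::filter(metadata$annotations, .data$category == !!category)
  if (is.null(image_ids)) image_ids <- unique(ann$image_id)
  vals <- ann$value[match(image_ids, ann$image_id)]
  lv <- sort(unique(ann$value))
  pal <- if (all(lv %in% names(metadata$colors))) metadata$colors[lv]
         else stats::setNames(default_palette(length(lv)), lv)
  stats::setNames(unname(pal[vals]), image_ids)
}

read_delim_sniffed <- function(file) {
  first <- readLines(file, n = 1L, warn = FALSE)
  if (!length(first)) return(NULL)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(file, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "")
  tibble::as_tibble(tab)
}

#' Read per-image 2D embedding coordinates
#'
#' @param file delimited file (comma or tab, sniffed) with columns
#'   `image_id`, `x`, `y` (matched by name when the header provides them,
#'   else taken positionally).
#' @return a tibble with columns `image_id` (character), `x`, `y` (double).
#' @export
read_coordinates <- function(file) {
  tab <- read_delim_sniffed(file)
  if (is.null(tab) || ncol(tab) < 3)
    stop(sprintf("coordinate file '%s' needs image_id, x, y columns", file),
         call. = FALSE)
  nm <- tolower(names(tab))
  pick <- function(col, pos) if (col %in% nm) which(nm == col)[1] else pos
  out <- tibble::tibble(
    image_id = as.character(tab[[pick("image_id", 1L)]]),
    x = as.numeric(tab[[pick("x", 2L)]]),
    y = as.numeric(tab[[pick("y", 3L)]]))
  bad <- !is.finite(out$x) | !is.finite(out$y)
  if (any(bad))
    stop(sprintf("non-finite coordinate for image_id '%s' (row %d) in '%s'",
                 out$image_id[which(bad)[1]], which(bad)[1], file), call. = FALSE)
  if (anyDuplicated(out$image_id))
    stop(sprintf("duplicate image_id in coordinate file '%s'", file), call. = FALSE)
  out
}

#' Write embedding coordinates in the dialect [read_coordinates()] reads
#'
#' @param coords tibble with `image_id`, `x`, `y`.
#' @param file output path (CSV).
#' @return `file`, invisibly.
#' @export
write_coordinates <- function(coords, file) {
  stopifnot(all(c("image_id", "x", "y") %in% names(coords)))
  df <- data.frame(image_id = coords$image_id,
                   x = formatC(coords$x, format = "g", digits = 15),
                   y = formatC(coords$y, format = "g", digits = 15))
  utils::write.table(df, file, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(file)
}
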