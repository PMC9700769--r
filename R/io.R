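# Frame and ground-truth I/O. Internal intensity convention: numeric
# matrices on the 8-bit scale [0, 255]; PNG/TIFF pixel fractions are
# rescaled on read and write.

#' Read time-lapse frames
#'
#' Accepts a single PNG, a single (possibly multi-page) TIFF treated as the
#' time axis, a directory (PNG/TIFF files ordered lexicographically), or a
#' character vector of file paths in frame order. RGB input is averaged to
#' grayscale.
#'
#' @param path File path(s) or a directory.
#' @return List of numeric matrices with intensities in `[0, 255]`.
#' @export
read_frames <- function(path) {
  if (length(path) == 1L && dir.exists(path)) {
    path <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                            ignore.case = TRUE, full.names = TRUE))
    if (!length(path)) rlang::abort("no PNG/TIFF frames found in directory.")
  }
  frames <- list()
  for (p in path) {
    if (!file.exists(p)) rlang::abort(sprintf("frame not found: %s", p))
    ext <- tolower(tools::file_ext(p))
    imgs <- if (ext %in% c("tif", "tiff")) {
      tiff::readTIFF(p, all = TRUE)
    } else if (ext == "png") {
      list(png::readPNG(p))
    } else {
      rlang::abort(sprintf("unsupported frame format: %s", p))
    }
    for (im in imgs) {
      if (length(dim(im)) == 3L) im <- apply(im, c(1, 2), mean)
      frames[[length(frames) + 1L]] <- im * 255
    }
  }
  frames
}

#' Write a grayscale frame
#'
#' @param img Numeric matrix, intensities in `[0, 255]`.
#' @param path Output path; `.png` or `.tif`/`.tiff` selects the format.
#' @param bits 8 or 16 (PNG/TIFF bit depth).
#' @return `path`, invisibly.
#' @export
write_frame <- function(img, path, bits = 8) {
  assert_image(img)
  ext <- tolower(tools::file_ext(path))
  x <- img / 255
  if (ext == "png") {
    png::writePNG(x, path, dpi = NULL)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(x, path, bits.per.sample = bits)
  } else {
    rlang::abort("unsupported output format; use .png or .tif(f).")
  }
  invisible(path)
}

#' Write ground truth as JSON
#'
#' Serializes a `cord_truth` (vertices, edges with polylines, faces with
#' areas and vertex cycles, component count) to JSON.
#'
#' @param truth A `cord_truth` from [generate_network()].
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  obj <- list(
    vertices = truth$vertices,
    edges = list(
      from = truth$edges$from, to = truth$edges$to,
      path = lapply(truth$edges$path, function(m) unname(as.matrix(m)))
    ),
    faces = list(
      area = truth$faces$area,
      cycle = truth$faces$cycle
    ),
    n_components = truth$n_components
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read ground truth written by [write_ground_truth()]
#'
#' @param path `.json` path.
#' @return A `cord_truth` object.
#' @export
read_ground_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyMatrix = FALSE)
  ne <- length(obj$edges$from)
  nf <- length(obj$faces$area)
  structure(list(
    vertices = tibble::as_tibble(obj$vertices),
    edges = tibble::tibble(
      edge = seq_len(ne),
      from = as.integer(obj$edges$from),
      to = as.integer(obj$edges$to),
      path = lapply(seq_len(ne), function(i) {
        m <- do.call(rbind, lapply(obj$edges$path[[i]], as.numeric))
        colnames(m) <- c("row", "col")
        m
      })
    ),
    faces = tibble::tibble(
      face = seq_len(nf),
      area = as.numeric(obj$faces$area),
      cycle = lapply(seq_len(nf), function(i) as.integer(obj$faces$cycle[[i]]))
    ),
    n_components = as.integer(obj$n_components)
  ), class = "cord_truth")
}
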