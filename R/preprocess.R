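#' Preprocessing parameters for cord-network frames
#'
#' Parameters of the fixed per-frame chain: contrast-limited adaptive
#' histogram equalization (CLAHE), cropping of the growth boundary,
#' gaussian blurring, and conversion to binary.
#'
#' @param clahe_tile Side of the equalization tile, pixels (>= 2). A tile
#'   covering the whole image gives plain global histogram equalization.
#' @param clahe_clip Unitless histogram clip limit (multiples of the uniform
#'   bin count); `Inf` disables clipping.
#' @param blur_sigma Gaussian blur standard deviation, pixels; 0 = identity.
#' @param threshold_method `"otsu"` (between-class variance maximization) or
#'   `"fixed"`.
#' @param fixed_threshold Intensity in `[0, 255]`, used iff
#'   `threshold_method = "fixed"`; foreground is strictly above threshold.
#' @param min_object_px Connected foreground components smaller than this
#'   (px^2) are removed as speckle after thresholding.
#' @param crop_mode `"auto"` (tight bounding box of the dominant bright
#'   region, padded by `3 * blur_sigma`) or `"manual"`.
#' @param manual_roi Length-4 integer vector `(row0, col0, row1, col1)`,
#'   0-based half-open, used iff `crop_mode = "manual"`.
#'
#' @return An object of class `preprocess_params`.
#' @export
preprocess_params <- function(clahe_tile = 64, clahe_clip = 2,
                              blur_sigma = 2,
                              threshold_method = c("otsu", "fixed"),
                              fixed_threshold = 128,
                              min_object_px = 16,
                              crop_mode = c("auto", "manual"),
                              manual_roi = NULL) {
  threshold_method <- match.arg(threshold_method)
  crop_mode <- match.arg(crop_mode)
  if (!is_scalar_number(clahe_tile) || clahe_tile < 2) {
    rlang::abort("`clahe_tile` must be >= 2 pixels.")
  }
  if (!is_scalar_number(clahe_clip) && !identical(clahe_clip, Inf)) {
    rlang::abort("`clahe_clip` must be a positive number or Inf.")
  }
  if (clahe_clip <= 0) rlang::abort("`clahe_clip` must be positive.")
  if (!is_scalar_number(blur_sigma) || blur_sigma < 0) {
    rlang::abort("`blur_sigma` must be >= 0.")
  }
  if (!is_scalar_number(fixed_threshold) ||
      fixed_threshold < 0 || fixed_threshold > 255) {
    rlang::abort("`fixed_threshold` must lie in [0, 255].")
  }
  if (!is_scalar_number(min_object_px) || min_object_px < 0) {
    rlang::abort("`min_object_px` must be >= 0.")
  }
  if (crop_mode == "manual") {
    if (is.null(manual_roi) || length(manual_roi) != 4L || anyNA(manual_roi)) {
      rlang::abort("`manual_roi` must be (row0, col0, row1, col1), 0-based half-open.")
    }
  }
  structure(list(
    clahe_tile = clahe_tile, clahe_clip = clahe_clip,
    blur_sigma = blur_sigma, threshold_method = threshold_method,
    fixed_threshold = fixed_threshold, min_object_px = min_object_px,
    crop_mode = crop_mode, manual_roi = manual_roi
  ), class = "preprocess_params")
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-local histogram equalization with clipping. Each tile's 256-bin
#' histogram is clipped at `clahe_clip` times the uniform bin count (the
#' excess redistributed evenly), turned into the standard CDF transfer
#' `round((cdf(v) - cdf_min) / (n - cdf_min) * 255)`, and pixel values are
#' bilinearly interpolated between the mappings of the four surrounding
#' tile centres. A tile with a single occupied bin maps identically (no
#' contrast to redistribute). With one tile covering the image this is
#' plain (global) histogram equalization.
#'
#' @param img Numeric matrix of intensities in `[0, 255]`.
#' @param params A [preprocess_params()].
#' @return Matrix of the same dimensions, integer-valued in `[0, 255]`.
#' @export
equalize_contrast <- function(img, params = preprocess_params()) {
  assert_image(img)
  H <- nrow(img); W <- ncol(img)
  tile <- params$clahe_tile
  if (tile > min(H, W)) {
    rlang::abort("`clahe_tile` must not exceed the smaller image dimension.")
  }
  v <- round(img)
  ny <- as.integer(ceiling(H / tile)); nx <- as.integer(ceiling(W / tile))
  y_start <- (seq_len(ny) - 1L) * tile + 1L
  y_end <- pmin(seq_len(ny) * tile, H)
  x_start <- (seq_len(nx) - 1L) * tile + 1L
  x_end <- pmin(seq_len(nx) * tile, W)
  # 256 x (ny * nx) transfer functions, tile id = (tx - 1) * ny + ty
  M <- matrix(0, 256L, ny * nx)
  for (tx in seq_len(nx)) {
    for (ty in seq_len(ny)) {
      vals <- v[y_start[ty]:y_end[ty], x_start[tx]:x_end[tx]]
      n <- length(vals)
      h <- tabulate(vals + 1L, 256L)
      tid <- (tx - 1L) * ny + ty
      if (sum(h > 0) <= 1L) {       # constant tile: identity mapping
        M[, tid] <- 0:255
        next
      }
      if (is.finite(params$clahe_clip)) {
        limit <- params$clahe_clip * n / 256
        excess <- sum(pmax(h - limit, 0))
        h <- pmin(h, limit) + excess / 256
      }
      cdf <- cumsum(h)
      cdf_min <- cdf[which(cdf > 0)[1]]
      M[, tid] <- round((cdf - cdf_min) / (n - cdf_min) * 255)
    }
  }
  idx <- as.integer(v) + 1L
  if (ny == 1L && nx == 1L) {
    out <- matrix(M[idx, 1L], H, W)
    return(out)
  }
  cy <- (y_start + y_end) / 2
  cx <- (x_start + x_end) / 2
  ry <- seq_len(H); rx <- seq_len(W)
  jy <- findInterval(ry, cy); y1 <- pmax(jy, 1L); y2 <- pmin(jy + 1L, ny)
  wy <- ifelse(y1 == y2, 0, (ry - cy[y1]) / (cy[y2] - cy[y1]))
  jx <- findInterval(rx, cx); x1 <- pmax(jx, 1L); x2 <- pmin(jx + 1L, nx)
  wx <- ifelse(x1 == x2, 0, (rx - cx[x1]) / (cx[x2] - cx[x1]))
  Y1 <- rep(y1, times = W); Y2 <- rep(y2, times = W)
  WY <- rep(wy, times = W)
  X1 <- rep(x1, each = H); X2 <- rep(x2, each = H)
  WX <- rep(wx, each = H)
  t11 <- (X1 - 1L) * ny + Y1; t21 <- (X1 - 1L) * ny + Y2
  t12 <- (X2 - 1L) * ny + Y1; t22 <- (X2 - 1L) * ny + Y2
  out <- (1 - WY) * (1 - WX) * M[cbind(idx, t11)] +
         WY * (1 - WX) * M[cbind(idx, t21)] +
         (1 - WY) * WX * M[cbind(idx, t12)] +
         WY * WX * M[cbind(idx, t22)]
  matrix(round(pmin(255, pmax(0, out))), H, W)
}

#' Crop the growth boundary of a frame
#'
#' In `auto` mode, returns the tight bounding box (padded by
#' `3 * blur_sigma`, clamped to the frame) of the largest 8-connected
#' bright region under a coarse Otsu threshold — the intent is to exclude
#' empty margins beyond the growth boundary. In `manual` mode, returns the
#' stated 0-based half-open ROI. The attribute `crop_offset` (row, col,
#' 0-based) maps cropped coordinates back to frame coordinates.
#'
#' @inheritParams equalize_contrast
#' @return Cropped image matrix with attribute `crop_offset`.
#' @export
crop_growth_boundary <- function(img, params = preprocess_params()) {
  assert_image(img)
  H <- nrow(img); W <- ncol(img)
  if (params$crop_mode == "manual") {
    roi <- as.integer(params$manual_roi)
    if (roi[1] < 0L || roi[2] < 0L || roi[3] > H || roi[4] > W ||
        roi[3] <= roi[1] || roi[4] <= roi[2]) {
      rlang::abort("`manual_roi` out of image bounds or empty.")
    }
    out <- img[(roi[1] + 1L):roi[3], (roi[2] + 1L):roi[4], drop = FALSE]
    attr(out, "crop_offset") <- c(row = roi[1], col = roi[2])
    return(out)
  }
  if (diff(range(img)) < 1e-6) {
    rlang::abort("no growth region found (frame is constant).",
                 class = "cordnet_no_growth_region")
  }
  th <- EBImage::otsu(img / 255, range = c(0, 1), levels = 256L) * 255
  fg <- img > th
  if (!any(fg)) {
    rlang::abort("no growth region found (empty foreground).",
                 class = "cordnet_no_growth_region")
  }
  lab <- label_foreground(fg)
  sizes <- tabulate(lab[lab > 0L])
  big <- which.max(sizes)
  hit <- which(lab == big, arr.ind = TRUE)
  pad <- as.integer(ceiling(3 * params$blur_sigma))
  r0 <- max(1L, min(hit[, 1]) - pad); r1 <- min(H, max(hit[, 1]) + pad)
  c0 <- max(1L, min(hit[, 2]) - pad); c1 <- min(W, max(hit[, 2]) + pad)
  out <- img[r0:r1, c0:c1, drop = FALSE]
  attr(out, "crop_offset") <- c(row = r0 - 1L, col = c0 - 1L)
  out
}

#' Gaussian blur
#'
#' Gaussian convolution with edge-replicated boundary handling;
#' `blur_sigma = 0` is the identity.
#'
#' @inheritParams equalize_contrast
#' @return Blurred image matrix, same dimensions.
#' @export
blur_image <- function(img, params = preprocess_params()) {
  assert_image(img)
  off <- attr(img, "crop_offset")
  if (params$blur_sigma == 0) return(img)
  out <- EBImage::gblur(img / 255, sigma = params$blur_sigma,
                        boundary = "replicate") * 255
  out <- pmin(pmax(out, 0), 255)
  attr(out, "crop_offset") <- off
  out
}

#' Convert a grayscale frame to a binary cord mask
#'
#' Otsu mode selects the threshold maximizing between-class variance over
#' the 256-bin intensity histogram; foreground is strictly above threshold.
#' Connected foreground components smaller than `min_object_px` are then
#' removed as speckle. The returned mask carries a `provenance` attribute
#' recording the parameters and threshold used.
#'
#' @inheritParams equalize_contrast
#' @return Logical matrix (TRUE = cord foreground) with attributes
#'   `threshold`, `provenance`, and any inherited `crop_offset`.
#' @export
binarize <- function(img, params = preprocess_params()) {
  assert_image(img)
  if (params$threshold_method == "otsu") {
    if (diff(range(img)) < 1e-6) {  # constant up to convolution round-off
      rlang::abort("degenerate histogram: constant image has no Otsu threshold.",
                   class = "cordnet_degenerate_histogram")
    }
    th <- EBImage::otsu(img / 255, range = c(0, 1), levels = 256L) * 255
  } else {
    th <- params$fixed_threshold
  }
  fg <- img > th
  if (params$min_object_px > 0 && any(fg)) {
    lab <- label_foreground(fg)
    sizes <- tabulate(lab[lab > 0L])
    drop <- which(sizes < params$min_object_px)
    if (length(drop)) fg[lab %in% drop] <- FALSE
  }
  attr(fg, "crop_offset") <- attr(img, "crop_offset")
  attr(fg, "threshold") <- th
  attr(fg, "provenance") <- list(params = unclass(params), threshold = th)
  fg
}

#' Run the full preprocessing chain on one frame
#'
#' Applies, in the fixed order of the analysis: contrast equalization,
#' growth-boundary cropping, gaussian blurring, binarization. If no growth
#' region is found in `auto` crop mode the full frame is used with a
#' warning; a degenerate (constant) frame yields an empty mask with a
#' warning rather than an error.
#'
#' @inheritParams equalize_contrast
#' @return Logical cord mask with `crop_offset` and `provenance` attributes.
#' @export
preprocess_frame <- function(img, params = preprocess_params()) {
  eq <- equalize_contrast(img, params)
  cropped <- tryCatch(
    crop_growth_boundary(eq, params),
    cordnet_no_growth_region = function(cnd) {
      rlang::warn("no growth region found; using the full frame.")
      out <- eq
      attr(out, "crop_offset") <- c(row = 0L, col = 0L)
      out
    }
  )
  blurred <- blur_image(cropped, params)
  tryCatch(
    binarize(blurred, params),
    cordnet_degenerate_histogram = function(cnd) {
      rlang::warn("degenerate frame (constant intensity); returning empty mask.")
      out <- matrix(FALSE, nrow(blurred), ncol(blurred))
      attr(out, "crop_offset") <- attr(blurred, "crop_offset")
      attr(out, "provenance") <- list(params = unclass(params), threshold = NA_real_)
      out
    }
  )
}
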