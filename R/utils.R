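# Internal helpers shared across modules.

# Validate a 2-D grayscale image: numeric matrix, finite, within [0, 255].
assert_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img)) {
    rlang::abort(sprintf("`%s` must be a numeric matrix.", arg))
  }
  if (nrow(img) < 1L || ncol(img) < 1L) {
    rlang::abort(sprintf("`%s` must have at least one row and column.", arg))
  }
  if (anyNA(img) || any(!is.finite(img))) {
    rlang::abort(sprintf("`%s` contains non-finite values.", arg))
  }
  if (min(img) < 0 || max(img) > 255) {
    rlang::abort(sprintf(
      "`%s` must hold intensities in [0, 255] (got range [%g, %g]).",
      arg, min(img), max(img)
    ))
  }
  invisible(img)
}

assert_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !is.logical(mask)) {
    rlang::abort(sprintf("`%s` must be a logical matrix.", arg))
  }
  if (anyNA(mask)) rlang::abort(sprintf("`%s` contains NA.", arg))
  invisible(mask)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Label 8-connected foreground components; returns integer matrix with
# attribute n_labels.
label_foreground <- function(mask) cpp_label(mask, TRUE)

# Label 4-connected background components of `mask` (i.e. components of
# !mask); returns integer matrix with attribute n_labels.
label_background <- function(mask) cpp_label(!mask, FALSE)

# Labels present on the raster border.
border_labels <- function(lab) {
  H <- nrow(lab); W <- ncol(lab)
  b <- c(lab[1, ], lab[H, ], lab[, 1], lab[, W])
  sort(unique(b[b > 0L]))
}
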