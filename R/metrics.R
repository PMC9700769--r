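#' Areas enclosed by fully connected network cycles
#'
#' The contour-area metric: 4-connected background components that do not
#' touch the frame border are exactly the regions fully bounded by network
#' foreground (loops of connectivity). Each is reported with its area
#' (pixel count times `pixel_area`), centroid, and bounding contour. Areas
#' are in arbitrary units (px^2) unless a physical `pixel_area` is given.
#'
#' @param skel Logical skeleton (or mask) matrix.
#' @param pixel_area Factor converting px^2 to physical units; default 1
#'   (arbitrary units).
#' @param frame_id Optional frame index recorded on the result.
#' @return A tibble of class `enclosed_regions` with columns `region`,
#'   `n_pixels`, `area`, `centroid_row`, `centroid_col` and a list-column
#'   `contour` (boundary pixel coordinates of the region), plus attributes
#'   `summary` (count, mean, median and total area), `pixel_area` and
#'   `frame_id`. Zero rows is a valid result.
#' @export
enclosed_regions <- function(skel, pixel_area = 1, frame_id = NULL) {
  assert_mask(skel)
  if (!is_scalar_number(pixel_area) || pixel_area <= 0) {
    rlang::abort("`pixel_area` must be a positive number.")
  }
  lab <- label_background(skel)
  inner <- setdiff(seq_len(attr(lab, "n_labels")), border_labels(lab))
  rows <- lapply(inner, function(l) {
    px <- which(lab == l, arr.ind = TRUE)
    reg <- lab == l
    H <- nrow(reg); W <- ncol(reg)
    pad <- matrix(FALSE, H + 2L, W + 2L)
    pad[2:(H + 1L), 2:(W + 1L)] <- reg
    interior <- pad[1:H, 2:(W + 1L)] & pad[3:(H + 2L), 2:(W + 1L)] &
      pad[2:(H + 1L), 1:W] & pad[2:(H + 1L), 3:(W + 2L)]
    bd <- which(reg & !interior, arr.ind = TRUE)
    tibble::tibble(
      n_pixels = nrow(px),
      area = nrow(px) * pixel_area,
      centroid_row = mean(px[, 1]),
      centroid_col = mean(px[, 2]),
      contour = list(cbind(row = bd[, 1], col = bd[, 2]))
    )
  })
  out <- if (length(rows)) {
    dplyr::bind_rows(rows)
  } else {
    tibble::tibble(n_pixels = integer(0), area = numeric(0),
                   centroid_row = numeric(0), centroid_col = numeric(0),
                   contour = list())
  }
  out <- dplyr::mutate(out, region = dplyr::row_number(), .before = 1)
  attr(out, "summary") <- list(
    count = nrow(out),
    mean_area = if (nrow(out)) mean(out$area) else 0,
    median_area = if (nrow(out)) median(out$area) else 0,
    total_area = sum(out$area)
  )
  attr(out, "pixel_area") <- pixel_area
  attr(out, "frame_id") <- frame_id %||% attr(skel, "frame_id")
  class(out) <- c("enclosed_regions", class(out))
  out
}

#' Per-frame connectivity record
#'
#' Collapses one frame's skeleton, graph and enclosed-region set into one
#' tidy row: the loop count, the mean/median/total enclosed area (the
#' contour-area metric; total is the headline series), skeleton length,
#' junction/endpoint/component counts and the cyclomatic number. An empty
#' skeleton yields an all-zero record.
#'
#' @param skel Logical skeleton matrix.
#' @param graph Optional [skeleton_to_graph()] result (computed if omitted).
#' @param regions Optional [enclosed_regions()] result (computed if omitted).
#' @param frame_id Frame index; if `graph` or `regions` carry a different
#'   non-NULL `frame_id`, the mismatch is an error.
#' @param pixel_area Passed to [enclosed_regions()] when computed here.
#' @return One-row tibble.
#' @export
frame_metrics <- function(skel, graph = NULL, regions = NULL,
                          frame_id = NA_integer_, pixel_area = 1) {
  assert_mask(skel)
  ids <- c(attr(graph, "frame_id"), attr(regions, "frame_id"),
           if (!is.na(frame_id)) frame_id)
  if (length(unique(ids)) > 1L) {
    rlang::abort("frame provenance mismatch: skeleton, graph and regions disagree on frame_id.")
  }
  if (is.null(graph)) graph <- skeleton_to_graph(skel)
  if (is.null(regions)) regions <- enclosed_regions(skel, pixel_area, frame_id)
  s <- attr(regions, "summary")
  tibble::tibble(
    frame_id = frame_id,
    loop_count = s$count,
    mean_area = s$mean_area,
    median_area = s$median_area,
    total_area = s$total_area,
    skeleton_length = sum(graph$edges$length),
    junctions = sum(graph$nodes$kind == "junction"),
    endpoints = sum(graph$nodes$kind == "endpoint"),
    components = graph$n_components,
    cyclomatic = cyclomatic_number(graph)
  )
}

#' Compare two replicate series of frame records
#'
#' For each time point, the mean and standard error of a chosen frame
#' metric across replicate runs of each condition, the difference curve
#' a - b, and a seeded bootstrap percentile confidence interval for the
#' terminal-frame difference. This is the comparison behind
#' passage-degradation curves: a condition with degraded networks shows a
#' smaller enclosed-area series and a terminal difference excluding zero.
#'
#' @param series_a,series_b Lists of per-replicate tibbles as returned by
#'   [frame_metrics()] row-bound over frames; within each series all
#'   replicates must have the same number of time-ordered frames.
#' @param metric Column to compare; default `"total_area"`, the headline
#'   contour-area series. (The mean area per loop is also emitted but is
#'   not monotone under degradation: merging two loops by losing a shared
#'   cord preserves the total while raising the mean.)
#' @param n_boot Bootstrap resamples (default 2000).
#' @param conf Confidence level (default 0.95).
#' @param rng_seed Seed for the bootstrap (default 1); results are
#'   invariant to the order of replicates within a series.
#' @return Object of class `cord_comparison` with elements `by_time`
#'   (tibble: time, means, SEMs, diff), `terminal` (tibble: estimate,
#'   ci_lower, ci_upper, conf, n_boot) and `metric`. See [tidy()] /
#'   [glance()] methods.
#' @export
compare_series <- function(series_a, series_b, metric = "total_area",
                           n_boot = 2000, conf = 0.95, rng_seed = 1) {
  get_mat <- function(series, arg) {
    if (!is.list(series) || !length(series)) {
      rlang::abort(sprintf("`%s` must be a non-empty list of frame-record tibbles.", arg))
    }
    lens <- vapply(series, nrow, integer(1))
    if (length(unique(lens)) != 1L || lens[1] == 0L) {
      rlang::abort(sprintf("replicates in `%s` must all have the same (positive) number of frames.", arg))
    }
    vapply(series, function(d) as.numeric(d[[metric]]), numeric(lens[1]))
  }
  A <- get_mat(series_a, "series_a")  # T x R_a
  B <- get_mat(series_b, "series_b")
  A <- matrix(A, nrow = if (is.matrix(A)) nrow(A) else 1)
  B <- matrix(B, nrow = if (is.matrix(B)) nrow(B) else 1)
  if (nrow(A) != nrow(B)) {
    rlang::abort("both series must cover the same number of time points.")
  }
  sem <- function(x) if (length(x) > 1L) sd(x) / sqrt(length(x)) else 0
  by_time <- tibble::tibble(
    time = seq_len(nrow(A)),
    mean_a = rowMeans(A),
    sem_a = apply(A, 1, sem),
    mean_b = rowMeans(B),
    sem_b = apply(B, 1, sem),
    diff = rowMeans(A) - rowMeans(B)
  )
  # terminal-frame bootstrap; sorted values make the CI order-invariant
  ta <- sort(A[nrow(A), ]); tb <- sort(B[nrow(B), ])
  boots <- withr::with_seed(rng_seed, {
    vapply(seq_len(n_boot), function(i) {
      mean(ta[sample.int(length(ta), replace = TRUE)]) -
        mean(tb[sample.int(length(tb), replace = TRUE)])
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(boots, c(alpha, 1 - alpha), type = 7))
  structure(list(
    by_time = by_time,
    terminal = tibble::tibble(
      estimate = mean(ta) - mean(tb),
      ci_lower = ci[1], ci_upper = ci[2],
      conf = conf, n_boot = n_boot,
      n_a = length(ta), n_b = length(tb)
    ),
    metric = metric
  ), class = "cord_comparison")
}

#' @export
print.cord_comparison <- function(x, ...) {
  cat(sprintf("<cord_comparison> metric: %s, %d time point(s)\n",
              x$metric, nrow(x$by_time)))
  cat(sprintf("terminal difference %.3f, %g%% CI [%.3f, %.3f]\n",
              x$terminal$estimate, 100 * x$terminal$conf,
              x$terminal$ci_lower, x$terminal$ci_upper))
  invisible(x)
}

#' Tidy a series comparison
#'
#' @param x A `cord_comparison`.
#' @param ... Unused.
#' @return The per-time-point tibble (time, mean_a, sem_a, mean_b, sem_b,
#'   diff).
#' @export
tidy.cord_comparison <- function(x, ...) x$by_time

#' One-row summary of a series comparison
#'
#' @param x A `cord_comparison`.
#' @param ... Unused.
#' @return One-row tibble with the terminal-frame difference estimate and
#'   its bootstrap confidence interval.
#' @export
glance.cord_comparison <- function(x, ...) {
  dplyr::mutate(x$terminal, metric = x$metric, .before = 1)
}

#' @export
print.cord_truth <- function(x, ...) {
  cat(sprintf(
    "<cord_truth> %d vertices, %d edges, %d bounded face(s), %d component(s)\n",
    nrow(x$vertices), nrow(x$edges), nrow(x$faces), x$n_components
  ))
  invisible(x)
}
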