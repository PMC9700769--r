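#' Topology summary of a binary raster
#'
#' Counts connected components of the foreground (8-connectivity) and holes
#' (4-connected background components not touching the frame border). This
#' pair is the conserved quantity of topology-preserving skeletonization:
#' eroding "until prior to disconnection" means neither number may change.
#'
#' @param raster Logical matrix (TRUE = foreground).
#' @return Named integer vector `c(n_components, n_holes)`.
#' @export
#' @examples
#' ring <- outer(1:32, 1:32, function(r, c) {
#'   d <- sqrt((r - 16)^2 + (c - 16)^2); d >= 8 & d <= 12
#' })
#' euler_summary(ring)
euler_summary <- function(raster) {
  assert_mask(raster)
  labf <- label_foreground(raster)
  labb <- label_background(raster)
  holes <- attr(labb, "n_labels") - length(border_labels(labb))
  c(n_components = as.integer(attr(labf, "n_labels")),
    n_holes = as.integer(holes))
}

#' Skeletonize a binary cord mask by repeated topology-preserving erosion
#'
#' Iterated boundary erosion in which a border pixel is removed only if its
#' removal preserves local connectivity and creates no hole (a simple-point
#' test on the 3x3 neighbourhood), iterating until no pixel is removable —
#' the formalization of eroding "until prior to disconnection". Two
#' directional sub-passes per pass (north/west then south/east borders) in
#' raster order keep the result deterministic and limit drift. Arc
#' endpoints are preserved. Spurs shorter than `prune_length` that end at a
#' junction are then pruned; pruning cannot change the component or hole
#' count.
#'
#' @param mask Logical matrix (TRUE = cord foreground).
#' @param prune_length Prune terminal branches shorter than this many
#'   pixels (default 5); `0` disables pruning.
#' @return Logical skeleton matrix (1 px wide) with the same dimensions;
#'   `euler_summary()` of the input is preserved exactly. Carries over a
#'   `crop_offset` attribute if present.
#' @export
skeletonize <- function(mask, prune_length = 5) {
  assert_mask(mask)
  off <- attr(mask, "crop_offset")
  if (!any(mask)) {
    rlang::warn("empty mask; returning empty skeleton.")
    out <- matrix(FALSE, nrow(mask), ncol(mask))
    attr(out, "crop_offset") <- off
    return(out)
  }
  sk <- cpp_thin(mask)
  if (prune_length > 0) sk <- prune_spurs(sk, prune_length)
  attr(sk, "crop_offset") <- off
  sk
}

# Reduced pixel adjacency of a thin skeleton: orthogonal neighbours always,
# diagonal neighbours only when neither shared orthogonal cell is
# foreground (otherwise the diagonal shortcut would create a spurious
# 3-cycle that is not a hole). Returns pixel coords, neighbour lists and
# degrees; pixel ids are column-major over foreground pixels.
pixel_adjacency <- function(skel) {
  H <- nrow(skel); W <- ncol(skel)
  fg <- which(skel)
  n <- length(fg)
  idx <- matrix(0L, H, W)
  idx[fg] <- seq_len(n)
  coords <- arrayInd(fg, dim(skel))
  from <- integer(0); to <- integer(0)
  offs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
               c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  for (o in offs) {
    dr <- o[1]; dc <- o[2]
    r_rng <- max(1L, 1L - dr):min(H, H - dr)
    c_rng <- max(1L, 1L - dc):min(W, W - dc)
    ok <- skel[r_rng, c_rng, drop = FALSE] &
      skel[r_rng + dr, c_rng + dc, drop = FALSE]
    if (dr != 0L && dc != 0L) {
      ok <- ok & !skel[r_rng + dr, c_rng, drop = FALSE] &
        !skel[r_rng, c_rng + dc, drop = FALSE]
    }
    w <- which(ok)
    if (length(w)) {
      from <- c(from, idx[r_rng, c_rng, drop = FALSE][w])
      to <- c(to, idx[r_rng + dr, c_rng + dc, drop = FALSE][w])
    }
  }
  nbr <- split(to, factor(from, levels = seq_len(n)))
  list(n = n, coords = coords, nbr = nbr, degree = lengths(nbr), ids = fg)
}

# Remove terminal branches shorter than prune_length that end at a junction
# (degree >= 3). Isolated arcs (endpoint to endpoint) are never pruned, so
# the component and hole counts are invariant. Iterates until stable.
prune_spurs <- function(skel, prune_length) {
  for (iter in seq_len(100L)) {
    adj <- pixel_adjacency(skel)
    if (adj$n == 0L) return(skel)
    endpoints <- which(adj$degree == 1L)
    if (!length(endpoints)) return(skel)
    kill <- integer(0)
    for (e in endpoints) {
      path <- e
      prev <- 0L
      cur <- e
      repeat {
        nxt <- setdiff(adj$nbr[[cur]], prev)
        if (length(nxt) != 1L) { path <- NULL; break }  # junction pixel or dead end
        if (adj$degree[nxt] >= 3L) break                # reached a junction
        if (adj$degree[nxt] == 1L) { path <- NULL; break }  # isolated arc
        path <- c(path, nxt)
        if (length(path) >= prune_length) { path <- NULL; break }
        prev <- cur; cur <- nxt
      }
      if (!is.null(path) && length(path) < prune_length) kill <- c(kill, path)
    }
    if (!length(kill)) return(skel)
    skel[adj$ids[unique(kill)]] <- FALSE
  }
  skel
}

# TRUE if the raster contains a 2x2 all-foreground block (thinness check).
has_2x2_block <- function(skel) {
  H <- nrow(skel); W <- ncol(skel)
  if (H < 2L || W < 2L) return(FALSE)
  a <- skel[-H, -W] & skel[-1, -W] & skel[-H, -1] & skel[-1, -1]
  any(a)
}
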