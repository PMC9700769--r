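#' Specification for a synthetic cord-network image
#'
#' Parameters of the synthetic generator that emulates endothelial
#' cord-networks on Matrigel: a bright reticular network of cords over a
#' darker background, with uneven illumination, additive noise, and a
#' degradation axis (edge dropout) mimicking passage-dependent loss of
#' network complexity.
#'
#' The network geometry is a Voronoi tessellation of `n_seeds` points
#' placed uniformly with a hard-core minimum separation (0.65 * sqrt(H*W /
#' n_seeds)), so the mesh has a characteristic cell size as real cord
#' networks do. Ridges are clipped to the frame and drawn as bright strokes
#' of `cord_width` pixels.
#'
#' @param image_height,image_width Frame size in pixels (>= 64).
#' @param n_seeds Number of Voronoi generator points (>= 4).
#' @param cord_width Stroke thickness of drawn cords, pixels (>= 1).
#' @param edge_dropout Probability in `[0, 1]` that an edge is removed; the
#'   passage-degradation axis.
#' @param noise_sd Standard deviation of additive Gaussian noise, intensity
#'   units on the 8-bit scale.
#' @param illumination_amplitude Peak deviation of the smooth multiplicative
#'   illumination gradient, intensity units on the 8-bit scale (the
#'   multiplier ranges over `1 +/- illumination_amplitude/255`).
#' @param foreground_level,background_level Cord and background intensities
#'   in `[0, 255]`.
#' @param rng_seed Integer seed; identical specs give bit-identical output.
#' @param pixel_size Optional physical pixel edge length; purely metadata
#'   used to convert areas out of arbitrary units. Default `NULL` keeps
#'   areas in px^2 ("arbitrary units").
#'
#' @return An object of class `network_spec` (a validated list).
#' @export
#' @examples
#' spec <- network_spec(n_seeds = 16, rng_seed = 7)
#' net <- generate_network(spec)
#' nrow(net$truth$faces)
network_spec <- function(image_height = 256, image_width = 256,
                         n_seeds = 25, cord_width = 3,
                         edge_dropout = 0, noise_sd = 5,
                         illumination_amplitude = 10,
                         foreground_level = 200, background_level = 40,
                         rng_seed = 1, pixel_size = NULL) {
  spec <- list(
    image_height = image_height, image_width = image_width,
    n_seeds = n_seeds, cord_width = cord_width,
    edge_dropout = edge_dropout, noise_sd = noise_sd,
    illumination_amplitude = illumination_amplitude,
    foreground_level = foreground_level,
    background_level = background_level,
    rng_seed = rng_seed, pixel_size = pixel_size
  )
  validate_network_spec(spec)
  structure(spec, class = "network_spec")
}

validate_network_spec <- function(spec) {
  with(spec, {
    if (!is_scalar_number(image_height) || !is_scalar_number(image_width) ||
        image_height < 64 || image_width < 64) {
      rlang::abort("image dimensions must be numbers >= 64 pixels.")
    }
    if (!is_scalar_number(n_seeds) || n_seeds < 4) {
      rlang::abort("`n_seeds` must be >= 4.")
    }
    if (!is_scalar_number(cord_width) || cord_width < 1) {
      rlang::abort("`cord_width` must be >= 1 pixel.")
    }
    if (!is_scalar_number(edge_dropout) || edge_dropout < 0 || edge_dropout > 1) {
      rlang::abort("`edge_dropout` must lie in [0, 1].")
    }
    if (!is_scalar_number(noise_sd) || noise_sd < 0) {
      rlang::abort("`noise_sd` must be >= 0.")
    }
    if (!is_scalar_number(illumination_amplitude) || illumination_amplitude < 0) {
      rlang::abort("`illumination_amplitude` must be >= 0.")
    }
    if (!is_scalar_number(foreground_level) || !is_scalar_number(background_level) ||
        foreground_level < 0 || foreground_level > 255 ||
        background_level < 0 || background_level > 255 ||
        foreground_level <= background_level) {
      rlang::abort("levels must lie in [0, 255] with foreground > background.")
    }
    if (!is_scalar_number(rng_seed) || rng_seed != round(rng_seed)) {
      rlang::abort("`rng_seed` must be an integer.")
    }
  })
  invisible(spec)
}

# --- geometry -------------------------------------------------------------

# Uniform seeds with hard-core minimum separation (sequential rejection).
# Coordinates are continuous (x in [0, W], y in [0, H]).
hardcore_seeds <- function(n, H, W) {
  rmin <- 0.65 * sqrt(H * W / n)
  xs <- numeric(n); ys <- numeric(n)
  got <- 0L; tries <- 0L; max_tries <- 2000L * n
  while (got < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      rlang::abort("could not place seeds with the hard-core separation; reduce `n_seeds`.")
    }
    x <- runif(1) * W; y <- runif(1) * H
    if (got == 0L || min((xs[seq_len(got)] - x)^2 + (ys[seq_len(got)] - y)^2) >= rmin^2) {
      got <- got + 1L
      xs[got] <- x; ys[got] <- y
    }
  }
  cbind(x = xs, y = ys)
}

# Sutherland-Hodgman clip of polygon `pts` (k x 2, x/y) against half-plane
# a*x + b*y <= cc. `src` labels the clip plane that created each edge
# (edge i runs from vertex i to vertex i+1, cyclically); newly created
# edges along the clip line get source `newsrc`.
clip_halfplane <- function(pts, src, a, b, cc, newsrc) {
  n <- nrow(pts)
  if (n == 0L) return(list(pts = pts, src = src))
  f <- pts[, 1] * a + pts[, 2] * b - cc
  inside <- f <= 1e-9
  op <- matrix(0, 0, 2); os <- integer(0)
  for (i in seq_len(n)) {
    k <- if (i == n) 1L else i + 1L
    if (inside[i]) {
      if (inside[k]) {
        op <- rbind(op, pts[i, ]); os <- c(os, src[i])
      } else {
        t <- f[i] / (f[i] - f[k])
        op <- rbind(op, pts[i, ], pts[i, ] + t * (pts[k, ] - pts[i, ]))
        os <- c(os, src[i], newsrc)
      }
    } else if (inside[k]) {
      t <- f[i] / (f[i] - f[k])
      op <- rbind(op, pts[i, ] + t * (pts[k, ] - pts[i, ]))
      os <- c(os, src[i])
    }
  }
  list(pts = op, src = os)
}

# Voronoi ridge segments of `seeds` within the [0,W] x [0,H] frame.
# Returns vertices (m x 2, x/y) and an edge table (from, to) in
# deterministic construction order. Ridges that cross the frame are dropped
# entirely rather than clipped to stubs: a clip point is a degree-1 vertex,
# so it can never lie on a cycle and the bounded-face set is unchanged,
# while stub pairs meeting the border closer than the optical resolution
# (cord radius + blur support) would seal regions the planar-graph truth
# counts as open. Border cells therefore stay open in the image exactly as
# they are in the graph.
voronoi_ridges <- function(seeds, H, W) {
  n <- nrow(seeds)
  seg_p1 <- list(); seg_p2 <- list(); seg_pair <- character(0)
  seg_i <- integer(0); seg_j <- integer(0)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n)) {
    pts <- matrix(c(0, 0, W, 0, W, H, 0, H), ncol = 2, byrow = TRUE)
    src <- rep(0L, 4L)
    for (j in seq_len(n)) {
      if (j == i) next
      d <- seeds[j, ] - seeds[i, ]
      m <- (seeds[j, ] + seeds[i, ]) / 2
      res <- clip_halfplane(pts, src, d[1], d[2], sum(d * m), j)
      pts <- res$pts; src <- res$src
      if (nrow(pts) == 0L) break
    }
    k <- nrow(pts)
    if (k == 0L) next
    for (e in seq_len(k)) {
      j <- src[e]
      if (j == 0L) next
      key <- paste(min(i, j), max(i, j))
      if (!is.null(seen[[key]])) next
      p1 <- pts[e, ]; p2 <- pts[if (e == k) 1L else e + 1L, ]
      if (sum((p1 - p2)^2) < 1e-14) next
      tol <- 1e-7
      if (min(p1[1], p2[1]) < tol || max(p1[1], p2[1]) > W - tol ||
          min(p1[2], p2[2]) < tol || max(p1[2], p2[2]) > H - tol) {
        seen[[key]] <- TRUE  # frame-crossing ridge: dropped, not clipped
        next
      }
      seen[[key]] <- TRUE
      seg_p1[[length(seg_p1) + 1L]] <- p1
      seg_p2[[length(seg_p2) + 1L]] <- p2
      seg_i <- c(seg_i, i); seg_j <- c(seg_j, j)
    }
  }
  if (length(seg_p1) == 0L) {
    return(list(vertices = matrix(0, 0, 2), edges = matrix(0L, 0, 2)))
  }
  P <- rbind(do.call(rbind, seg_p1), do.call(rbind, seg_p2))
  vid <- snap_vertices(P, tol = 1e-5)
  ne <- length(seg_p1)
  from <- vid[seq_len(ne)]; to <- vid[ne + seq_len(ne)]
  keep <- from != to
  V <- attr(vid, "vertices")
  colnames(V) <- c("x", "y")
  list(vertices = V, edges = cbind(from = from[keep], to = to[keep]))
}

# Merge near-identical 2-D points; returns an id per row with the merged
# coordinate table in attribute "vertices". Grid-hash single linkage at
# tolerance `tol` (coordinates are O(1)-separated, so this is safe).
snap_vertices <- function(P, tol = 1e-5) {
  m <- nrow(P)
  ids <- integer(m)
  vx <- numeric(0); vy <- numeric(0)
  cells <- new.env(hash = TRUE, parent = emptyenv())
  for (r in seq_len(m)) {
    gx <- floor(P[r, 1] / tol); gy <- floor(P[r, 2] / tol)
    hit <- 0L
    for (dx in -1:1) {
      for (dy in -1:1) {
        key <- paste(gx + dx, gy + dy)
        cand <- cells[[key]]
        if (!is.null(cand)) {
          for (id in cand) {
            if (abs(vx[id] - P[r, 1]) <= tol && abs(vy[id] - P[r, 2]) <= tol) {
              hit <- id; break
            }
          }
        }
        if (hit > 0L) break
      }
      if (hit > 0L) break
    }
    if (hit == 0L) {
      vx <- c(vx, P[r, 1]); vy <- c(vy, P[r, 2])
      hit <- length(vx)
      key <- paste(gx, gy)
      cells[[key]] <- c(cells[[key]], hit)
    }
    ids[r] <- hit
  }
  attr(ids, "vertices") <- cbind(vx, vy)
  ids
}

# --- planar faces ---------------------------------------------------------

# Bounded faces of a planar straight-line graph by rotation-system
# traversal. `vertices`: m x 2 (x, y) with y measured downward (image row);
# `edges`: k x 2 vertex indices, no self-loops, no crossings. Returns a
# list of faces, each list(cycle = vertex ids in walk order, area = px^2).
planar_faces <- function(vertices, edges) {
  k <- nrow(edges)
  if (k == 0L) return(list())
  x <- vertices[, 1]; y <- -vertices[, 2]  # flip to y-up maths convention
  # half-edges 2e-1 (from->to) and 2e (to->from)
  he_from <- integer(2 * k); he_to <- integer(2 * k)
  he_from[seq(1, 2 * k, 2)] <- edges[, 1]; he_to[seq(1, 2 * k, 2)] <- edges[, 2]
  he_from[seq(2, 2 * k, 2)] <- edges[, 2]; he_to[seq(2, 2 * k, 2)] <- edges[, 1]
  ang <- atan2(y[he_to] - y[he_from], x[he_to] - x[he_from])
  out_by_v <- split(seq_len(2 * k), he_from[seq_len(2 * k)])
  nxt_in_rot <- integer(2 * k)  # CCW successor among outgoing half-edges
  pos_in_rot <- integer(2 * k)
  for (v in names(out_by_v)) {
    hs <- out_by_v[[v]]
    hs <- hs[order(ang[hs], hs)]
    L <- length(hs)
    nxt_in_rot[hs] <- hs[c(seq_len(L)[-1], 1L)]
  }
  twin <- function(h) h + ifelse(h %% 2L == 1L, 1L, -1L)
  faces <- list()
  visited <- logical(2 * k)
  for (h0 in seq_len(2 * k)) {
    if (visited[h0]) next
    h <- h0
    cyc <- integer(0)
    area2 <- 0
    repeat {
      visited[h] <- TRUE
      u <- he_from[h]; v <- he_to[h]
      cyc <- c(cyc, u)
      area2 <- area2 + (x[u] * y[v] - x[v] * y[u])
      h <- nxt_in_rot[twin(h)]
      if (h == h0) break
    }
    # with this rotation convention bounded faces come out with negative
    # signed area (one positive outer orbit per component with cycles)
    area <- -area2 / 2
    if (area > 1e-7) {
      faces[[length(faces) + 1L]] <- list(cycle = cyc, area = area)
    }
  }
  faces
}

# --- realization and rendering --------------------------------------------

# All random draws for one spec, in a fixed order so that nested dropout
# levels, time-lapse prefixes and generate_network() share one realization.
network_realization <- function(spec, seed_points = NULL) {
  H <- spec$image_height; W <- spec$image_width
  withr::with_seed(spec$rng_seed, {
    seeds <- if (is.null(seed_points)) {
      hardcore_seeds(spec$n_seeds, H, W)
    } else {
      cbind(x = seed_points[, 2], y = seed_points[, 1])
    }
    vor <- voronoi_ridges(seeds, H, W)
    ne <- nrow(vor$edges)
    perm <- if (ne > 0L) sample.int(ne) else integer(0)
    edges <- vor$edges[perm, , drop = FALSE]
    u <- runif(ne)
    theta <- runif(1, 0, 2 * pi)
    noise <- matrix(rnorm(H * W, 0, max(spec$noise_sd, 0)), H, W)
    list(vertices = vor$vertices, edges = edges, u = u,
         theta = theta, noise = noise)
  })
}

# Ground truth of the retained edge subset: reindexed vertices, edges with
# polyline geometry, bounded faces with areas, component count.
build_truth <- function(vertices, edges) {
  if (nrow(edges) == 0L) {
    return(structure(list(
      vertices = tibble::tibble(vertex = integer(0), row = numeric(0), col = numeric(0)),
      edges = tibble::tibble(edge = integer(0), from = integer(0), to = integer(0),
                             path = list()),
      faces = tibble::tibble(face = integer(0), area = numeric(0), cycle = list()),
      n_components = 0L
    ), class = "cord_truth"))
  }
  used <- sort(unique(c(edges[, 1], edges[, 2])))
  remap <- setNames(seq_along(used), used)
  V <- vertices[used, , drop = FALSE]
  E <- cbind(remap[as.character(edges[, 1])], remap[as.character(edges[, 2])])
  dimnames(E) <- NULL
  fc <- planar_faces(V, E)
  g <- igraph::graph_from_edgelist(E, directed = FALSE)
  ncomp <- igraph::components(g)$no
  path_of <- function(i) {
    cbind(row = V[E[i, ], 2], col = V[E[i, ], 1])
  }
  structure(list(
    vertices = tibble::tibble(vertex = seq_along(used),
                              row = V[, 2], col = V[, 1]),
    edges = tibble::tibble(edge = seq_len(nrow(E)),
                           from = E[, 1], to = E[, 2],
                           path = lapply(seq_len(nrow(E)), path_of)),
    faces = tibble::tibble(face = seq_along(fc),
                           area = vapply(fc, `[[`, numeric(1), "area"),
                           cycle = lapply(fc, `[[`, "cycle")),
    n_components = ncomp
  ), class = "cord_truth")
}

# Draw edges as strokes of `cord_width` px on an H x W logical raster.
# Pixel (r, c) has centre (x = c - 0.5, y = r - 0.5).
rasterize_edges <- function(H, W, vertices, edges, cord_width) {
  mask <- matrix(FALSE, H, W)
  half <- cord_width / 2
  for (i in seq_len(nrow(edges))) {
    p1 <- vertices[edges[i, 1], ]; p2 <- vertices[edges[i, 2], ]
    r0 <- max(1L, floor(min(p1[2], p2[2]) - half + 0.5))
    r1 <- min(H, ceiling(max(p1[2], p2[2]) + half + 0.5))
    c0 <- max(1L, floor(min(p1[1], p2[1]) - half + 0.5))
    c1 <- min(W, ceiling(max(p1[1], p2[1]) + half + 0.5))
    if (r1 < r0 || c1 < c0) next
    rs <- r0:r1; cs <- c0:c1
    py <- rep(rs - 0.5, times = length(cs))
    px <- rep(cs - 0.5, each = length(rs))
    dx <- p2[1] - p1[1]; dy <- p2[2] - p1[2]
    L2 <- dx * dx + dy * dy
    t <- pmin(1, pmax(0, ((px - p1[1]) * dx + (py - p1[2]) * dy) / L2))
    d2 <- (px - (p1[1] + t * dx))^2 + (py - (p1[2] + t * dy))^2
    hit <- d2 <= half^2
    if (any(hit)) {
      sub <- mask[rs, cs, drop = FALSE]
      sub[hit] <- TRUE
      mask[rs, cs] <- sub
    }
  }
  mask
}

# Apply illumination gradient and pre-drawn noise field; quantize to 8-bit.
render_image <- function(raster, spec, theta, noise) {
  H <- nrow(raster); W <- ncol(raster)
  img <- matrix(spec$background_level, H, W)
  img[raster] <- spec$foreground_level
  if (spec$illumination_amplitude > 0) {
    gx <- matrix(rep(2 * ((seq_len(W) - 0.5) / W) - 1, each = H), H, W)
    gy <- matrix(rep(2 * ((seq_len(H) - 0.5) / H) - 1, times = W), H, W)
    g <- (cos(theta) * gx + sin(theta) * gy) /
      (abs(cos(theta)) + abs(sin(theta)))
    img <- img * (1 + spec$illumination_amplitude / 255 * g)
  }
  img <- img + noise
  round(pmin(pmax(img, 0), 255))
}

#' Generate a synthetic cord-network image with exact ground truth
#'
#' Draws the Voronoi ridge network of the spec's seed points as bright
#' cords, removes each edge independently with probability
#' `spec$edge_dropout`, and corrupts the rendering with a smooth
#' multiplicative illumination gradient and additive Gaussian noise. The
#' returned ground truth describes the retained, pre-noise geometry:
#' vertices, edges and the bounded faces of the planar graph, i.e. the
#' areas contained in loops of connectivity.
#'
#' @param spec A [network_spec()].
#' @param seed_points Optional n x 2 matrix of (row, col) seed coordinates
#'   overriding the random hard-core placement (useful for regular layouts).
#' @return A list with elements `image` (H x W numeric matrix of 8-bit
#'   intensities) and `truth` (class `cord_truth`: tibbles `vertices`,
#'   `edges`, `faces` and the count `n_components`).
#' @export
generate_network <- function(spec, seed_points = NULL) {
  validate_network_spec(spec)
  real <- network_realization(spec, seed_points)
  assemble_level(real, spec, spec$edge_dropout)
}

assemble_level <- function(real, spec, dropout, prefix = NULL) {
  keep <- real$u >= dropout
  edges <- real$edges[keep, , drop = FALSE]
  if (!is.null(prefix)) edges <- edges[seq_len(prefix), , drop = FALSE]
  truth <- build_truth(real$vertices, edges)
  raster <- rasterize_edges(spec$image_height, spec$image_width,
                            real$vertices, edges, spec$cord_width)
  img <- render_image(raster, spec, real$theta, real$noise)
  list(image = img, truth = truth)
}

#' Generate a nested degradation series of cord-network images
#'
#' Emulates passage-dependent loss of network complexity: the same
#' realization is rendered at increasing edge-dropout levels, with dropout
#' sets nested (an edge removed at one level stays removed at all higher
#' levels), so the ground-truth bounded-face count and total enclosed area
#' are non-increasing along the series.
#'
#' @inheritParams generate_network
#' @param dropout_levels Strictly increasing probabilities in `[0, 1]`.
#' @return A list with one `list(image, truth)` element per level.
#' @export
degrade_series <- function(spec, dropout_levels, seed_points = NULL) {
  validate_network_spec(spec)
  if (length(dropout_levels) < 1L || anyNA(dropout_levels) ||
      any(dropout_levels < 0) || any(dropout_levels > 1) ||
      is.unsorted(dropout_levels, strictly = TRUE)) {
    rlang::abort("`dropout_levels` must be strictly increasing values in [0, 1].")
  }
  real <- network_realization(spec, seed_points)
  lapply(dropout_levels, function(p) assemble_level(real, spec, p))
}

#' Assemble a synthetic time-lapse of progressive network formation
#'
#' Frame `k` of `n_frames` draws the first `ceiling(k / n_frames * E)`
#' edges of the (post-dropout) edge list, so cords appear progressively and
#' the final frame is pixel-identical to [generate_network()]'s image.
#'
#' @inheritParams generate_network
#' @param n_frames Number of frames (>= 2).
#' @return A list with `frames` (list of images) and `truths` (list of
#'   per-frame `cord_truth` objects for the drawn edge prefix).
#' @export
timelapse_assembly <- function(spec, n_frames, seed_points = NULL) {
  validate_network_spec(spec)
  if (!is_scalar_number(n_frames) || n_frames < 2 || n_frames != round(n_frames)) {
    rlang::abort("`n_frames` must be an integer >= 2.")
  }
  real <- network_realization(spec, seed_points)
  keepn <- sum(real$u >= spec$edge_dropout)
  out <- lapply(seq_len(n_frames), function(k) {
    assemble_level(real, spec, spec$edge_dropout,
                   prefix = ceiling(k / n_frames * keepn))
  })
  list(frames = lapply(out, `[[`, "image"),
       truths = lapply(out, `[[`, "truth"))
}
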