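#' Convert a skeleton to its planar node/edge graph
#'
#' Skeleton pixels with a number of neighbours different from 2 become
#' nodes (endpoints at degree 1, junctions at degree >= 3, isolated pixels
#' at degree 0); maximal chains of 2-neighbour pixels become edges with
#' their pixel-path geometry and length. A pure cycle with no junction gets
#' one anchor node (its first pixel in column-major order) and a self-loop
#' edge. Pixel adjacency is 8-connected, with diagonal links suppressed
#' when an orthogonal 2-step path exists, so that independent cycles of the
#' graph correspond one-to-one to holes of the raster.
#'
#' @param skel Logical skeleton matrix, e.g. from [skeletonize()].
#' @return An object of class `skeleton_graph`: a list with tibbles `nodes`
#'   (node, row, col, degree, kind) and `edges` (edge, from, to, length,
#'   path), and `n_components`. Edge `length` is the summed step length of
#'   the pixel path (1 per orthogonal, sqrt(2) per diagonal step).
#' @export
skeleton_to_graph <- function(skel) {
  assert_mask(skel)
  adj <- pixel_adjacency(skel)
  empty <- list(
    nodes = tibble::tibble(node = integer(0), row = integer(0),
                           col = integer(0), degree = integer(0),
                           kind = character(0)),
    edges = tibble::tibble(edge = integer(0), from = integer(0),
                           to = integer(0), length = numeric(0),
                           path = list()),
    n_components = 0L
  )
  if (adj$n == 0L) {
    return(structure(empty, class = "skeleton_graph",
                     frame_id = attr(skel, "frame_id")))
  }
  deg <- adj$degree
  # connected components of the pixel graph
  comp <- integer(adj$n)
  nc <- 0L
  for (s in seq_len(adj$n)) {
    if (comp[s] > 0L) next
    nc <- nc + 1L
    queue <- s; comp[s] <- nc
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      nb <- adj$nbr[[cur]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- nc
      queue <- c(queue, new)
    }
  }
  is_node <- deg != 2L
  # pure cycles: components with no natural node get an anchor
  for (k in seq_len(nc)) {
    members <- which(comp == k)
    if (!any(is_node[members])) is_node[min(members)] <- TRUE
  }
  node_px <- which(is_node)
  node_id <- integer(adj$n)
  node_id[node_px] <- seq_along(node_px)

  seen <- new.env(hash = TRUE, parent = emptyenv())
  e_from <- integer(0); e_to <- integer(0)
  e_len <- numeric(0); e_path <- list()
  step_len <- function(a, b) {
    sqrt(sum((adj$coords[a, ] - adj$coords[b, ])^2))
  }
  for (p in node_px) {
    for (q in adj$nbr[[p]]) {
      path <- c(p, q)
      prev <- p; cur <- q
      while (!is_node[cur]) {
        nxt <- setdiff(adj$nbr[[cur]], prev)
        prev <- cur; cur <- nxt[[1]]
        path <- c(path, cur)
      }
      interior <- path[-c(1L, length(path))]
      key <- paste(
        paste(sort(c(p, cur)), collapse = "-"),
        paste(sort(interior), collapse = ","),
        sep = "|"
      )
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      len <- sum(vapply(seq_len(length(path) - 1L),
                        function(i) step_len(path[i], path[i + 1L]),
                        numeric(1)))
      e_from <- c(e_from, node_id[p])
      e_to <- c(e_to, node_id[cur])
      e_len <- c(e_len, len)
      e_path[[length(e_path) + 1L]] <-
        cbind(row = adj$coords[path, 1], col = adj$coords[path, 2])
    }
  }
  kind <- dplyr::case_when(
    deg[node_px] == 0L ~ "isolated",
    deg[node_px] == 1L ~ "endpoint",
    deg[node_px] == 2L ~ "cycle_anchor",
    TRUE ~ "junction"
  )
  structure(list(
    nodes = tibble::tibble(
      node = seq_along(node_px),
      row = adj$coords[node_px, 1],
      col = adj$coords[node_px, 2],
      degree = as.integer(deg[node_px]),
      kind = kind
    ),
    edges = tibble::tibble(
      edge = seq_along(e_from),
      from = e_from, to = e_to, length = e_len, path = e_path
    ),
    n_components = nc
  ), class = "skeleton_graph", frame_id = attr(skel, "frame_id"))
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf(
    "<skeleton_graph> %d nodes, %d edges, %d component(s), cyclomatic %d\n",
    nrow(x$nodes), nrow(x$edges), x$n_components,
    cyclomatic_number(x)
  ))
  invisible(x)
}

#' Cyclomatic number of a skeleton graph
#'
#' `E - V + C`: the number of independent cycles; for a connected skeleton
#' with no border-touching cycle this equals the number of enclosed regions.
#'
#' @param graph A `skeleton_graph`.
#' @return Integer.
#' @export
cyclomatic_number <- function(graph) {
  as.integer(nrow(graph$edges) - nrow(graph$nodes) + graph$n_components)
}
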