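# Independent oracles and fixture builders. These deliberately avoid the
# package's own implementation paths (cpp_label, planar face traversal),
# using plain flood fills, Euler's formula and brute-force scans instead.

# Flood-fill connected-component labelling in plain R.
flood_label <- function(mask, eight) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  offs <- if (eight) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  nextl <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] > 0L) next
    nextl <- nextl + 1L
    queue <- start
    lab[start] <- nextl
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      r <- (cur - 1L) %% H + 1L; c <- (cur - 1L) %/% H + 1L
      for (k in seq_len(nrow(offs))) {
        rr <- r + offs[k, 1]; cc <- c + offs[k, 2]
        if (rr < 1 || rr > H || cc < 1 || cc > W) next
        i <- (cc - 1L) * H + rr
        if (mask[i] && lab[i] == 0L) {
          lab[i] <- nextl
          queue <- c(queue, i)
        }
      }
    }
  }
  lab
}

# (components, holes) by flood fill: 8-connected foreground, 4-connected
# background excluding border-touching components.
euler_oracle <- function(mask) {
  labf <- flood_label(mask, eight = TRUE)
  labb <- flood_label(!mask, eight = FALSE)
  H <- nrow(mask); W <- ncol(mask)
  border <- unique(c(labb[1, ], labb[H, ], labb[, 1], labb[, W]))
  border <- border[border > 0L]
  c(n_components = max(labf), n_holes = length(setdiff(unique(labb[labb > 0L]), border)))
}

# Euler's formula oracle for ground truth: bounded faces per connected
# component = Ec - Vc + 1, summed over components with at least one cycle.
euler_faces_oracle <- function(truth) {
  if (nrow(truth$edges) == 0L) return(0L)
  g <- igraph::graph_from_edgelist(cbind(truth$edges$from, truth$edges$to),
                                   directed = FALSE)
  co <- igraph::components(g)
  sum(vapply(seq_len(co$no), function(k) {
    vs <- which(co$membership == k)
    ec <- sum(truth$edges$from %in% vs & truth$edges$to %in% vs)
    ec - length(vs) + 1L
  }, numeric(1)))
}

# Brute-force Otsu: scan all 256 candidate thresholds for the one that
# maximizes between-class variance of the binned histogram.
otsu_oracle <- function(img) {
  v <- pmin(255L, pmax(0L, as.integer(round(img))))
  h <- tabulate(v + 1L, 256L)
  n <- sum(h)
  best <- -Inf; best_t <- 0L
  for (t in 0:254) {
    w0 <- sum(h[seq_len(t + 1L)])
    w1 <- n - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum((0:t) * h[seq_len(t + 1L)]) / w0
    mu1 <- sum(((t + 1L):255L) * h[(t + 2L):256L]) / w1
    bc <- w0 * w1 * (mu0 - mu1)^2
    if (bc > best) { best <- bc; best_t <- t }
  }
  best_t
}

# Even-odd point-in-polygon test used to match measured regions to ground
# truth faces.
point_in_polygon <- function(py, px, yy, xx) {
  n <- length(yy); j <- n; inside <- FALSE
  for (i in seq_len(n)) {
    if ((yy[i] > py) != (yy[j] > py) &&
        px < (xx[j] - xx[i]) * (py - yy[i]) / (yy[j] - yy[i]) + xx[i]) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

# Random morphologically closed Bernoulli field, the mask family used for
# topology properties.
random_closed_mask <- function(H = 96, W = 96, p = 0.45) {
  m <- matrix(runif(H * W) < p, H, W)
  EBImage::closing(m, EBImage::makeBrush(3, "box")) > 0
}

# 1-px ring of radius r (pixels at distance [r, r + 1)).
make_ring <- function(H = 64, ctr = NULL, r = 15) {
  if (is.null(ctr)) ctr <- (H + 1) / 2
  m0 <- matrix(0, H, H)
  d <- sqrt((row(m0) - ctr)^2 + (col(m0) - ctr)^2)
  d >= r & d < r + 1
}

# Theta-shaped skeleton: rectangle ring plus a vertical chord.
make_theta <- function() {
  sk <- matrix(FALSE, 40, 40)
  sk[10, 10:30] <- TRUE; sk[30, 10:30] <- TRUE
  sk[10:30, 10] <- TRUE; sk[10:30, 30] <- TRUE
  sk[10:30, 20] <- TRUE
  sk
}

# Validation-scale noise-free synthetic network spec; n_seeds varies
# deterministically with the seed over [9, 60].
validation_spec <- function(seed, size = 512, noise_sd = 0,
                            illumination_amplitude = 0) {
  network_spec(size, size, n_seeds = 9 + (seed * 7) %% 52,
               noise_sd = noise_sd,
               illumination_amplitude = illumination_amplitude,
               rng_seed = seed)
}
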