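test_that("network_spec rejects invalid parameters", {
  expect_error(network_spec(n_seeds = 3), "n_seeds")
  expect_error(network_spec(image_height = 32), "image dimensions")
  expect_error(network_spec(edge_dropout = 1.5), "edge_dropout")
  expect_error(network_spec(cord_width = 0), "cord_width")
  expect_error(network_spec(foreground_level = 30, background_level = 40),
               "foreground")
  expect_error(network_spec(rng_seed = 1.5), "rng_seed")
})

test_that("identical specs give bit-identical images and ground truth", {
  spec <- network_spec(n_seeds = 16, rng_seed = 99)
  a <- generate_network(spec)
  b <- generate_network(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$truth$faces$area, b$truth$faces$area)
  expect_identical(a$truth$vertices, b$truth$vertices)
})

test_that("full dropout yields background-only image and empty truth", {
  net <- generate_network(network_spec(edge_dropout = 1, noise_sd = 0,
                                       illumination_amplitude = 0,
                                       rng_seed = 2))
  expect_identical(nrow(net$truth$edges), 0L)
  expect_identical(nrow(net$truth$faces), 0L)
  expect_true(all(net$image == net$image[1, 1]))
})

test_that("bounded-face count matches the Euler-formula oracle", {
  for (s in c(1, 5, 12, 31)) {
    net <- generate_network(network_spec(320, 320, n_seeds = 10 + 3 * s,
                                         rng_seed = s))
    expect_identical(nrow(net$truth$faces),
                     as.integer(euler_faces_oracle(net$truth)))
    expect_true(all(net$truth$faces$area > 0))
  }
  # and under partial dropout, where the retained graph has several
  # components and dangling edges
  for (p in c(0.2, 0.5)) {
    net <- generate_network(network_spec(320, 320, n_seeds = 30,
                                         edge_dropout = p, rng_seed = 7))
    expect_identical(nrow(net$truth$faces),
                     as.integer(euler_faces_oracle(net$truth)))
  }
})

test_that("a regular 3x3 interior seed grid gives the Euler-predicted face", {
  spec <- network_spec(120, 120, n_seeds = 9, noise_sd = 0,
                       illumination_amplitude = 0, rng_seed = 1)
  pts <- as.matrix(expand.grid(row = c(30, 60, 90), col = c(30, 60, 90)))
  net <- generate_network(spec, seed_points = pts)
  # ridges crossing the frame are dropped: the retained graph is the
  # central square, V = 4, E = 4, one bounded face by Euler's formula
  expect_identical(nrow(net$truth$faces),
                   as.integer(euler_faces_oracle(net$truth)))
  expect_identical(nrow(net$truth$faces), 1L)
  expect_equal(net$truth$faces$area[[1]], 30 * 30, tolerance = 1e-6)
})

test_that("degrade_series is nested and its face counts are non-increasing", {
  spec <- network_spec(n_seeds = 25, rng_seed = 5)
  lv <- c(0, 0.2, 0.4, 0.6)
  ds <- degrade_series(spec, lv)
  counts <- vapply(ds, function(x) nrow(x$truth$faces), integer(1))
  totals <- vapply(ds, function(x) sum(x$truth$faces$area), numeric(1))
  expect_false(is.unsorted(rev(counts)))
  expect_false(is.unsorted(rev(totals)))
  for (x in ds) {
    expect_identical(nrow(x$truth$faces), as.integer(euler_faces_oracle(x$truth)))
  }
  # nesting: every edge retained at a higher level is present at all lower
  # levels (compare edge endpoint coordinate sets)
  keys <- lapply(ds, function(x) {
    if (nrow(x$truth$edges) == 0) character(0) else {
      tr <- x$truth
      vapply(seq_len(nrow(tr$edges)), function(i) {
        f <- tr$edges$from[i]; t <- tr$edges$to[i]
        paste(sort(c(paste(round(tr$vertices$row[f], 6), round(tr$vertices$col[f], 6)),
                     paste(round(tr$vertices$row[t], 6), round(tr$vertices$col[t], 6)))),
              collapse = "|")
      }, character(1))
    }
  })
  for (j in 2:4) expect_true(all(keys[[j]] %in% keys[[j - 1]]))
})

test_that("degrade_series endpoints: single level 0 equals generate_network", {
  spec <- network_spec(n_seeds = 12, edge_dropout = 0, rng_seed = 21)
  ds <- degrade_series(spec, 0)
  net <- generate_network(spec)
  expect_identical(ds[[1]]$image, net$image)
  expect_identical(ds[[1]]$truth$faces$area, net$truth$faces$area)
})

test_that("degrade_series covers the full range and rejects bad levels", {
  spec <- network_spec(n_seeds = 16, rng_seed = 3)
  ds <- degrade_series(spec, c(0, 1))
  expect_gte(nrow(ds[[1]]$truth$faces), 1)
  expect_identical(nrow(ds[[2]]$truth$faces), 0L)
  expect_error(degrade_series(spec, c(0.4, 0.2)), "strictly increasing")
  expect_error(degrade_series(spec, c(0, 1.2)), "strictly increasing")
})

test_that("timelapse_assembly draws edge prefixes ending at the full image", {
  spec <- network_spec(n_seeds = 20, rng_seed = 13)
  n <- 5
  tl <- timelapse_assembly(spec, n)
  net <- generate_network(spec)
  expect_identical(tl$frames[[n]], net$image)
  E <- nrow(net$truth$edges)
  for (k in seq_len(n)) {
    expect_identical(nrow(tl$truths[[k]]$edges), as.integer(ceiling(k / n * E)))
  }
  counts <- vapply(tl$truths, function(t) nrow(t$faces), integer(1))
  expect_false(is.unsorted(counts))
  expect_error(timelapse_assembly(spec, 1), "n_frames")
})

test_that("hard-core seeds keep the minimum separation", {
  spec <- network_spec(rng_seed = 17)
  pts <- withr::with_seed(17, cordnet:::hardcore_seeds(25, 256, 256))
  dmin <- min(dist(pts))
  expect_gte(dmin, 0.65 * sqrt(256 * 256 / 25))
})
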