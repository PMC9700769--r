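test_that("skeleton_to_graph handles lines, pure cycles and theta shapes", {
  # straight 30-px line: two endpoints, one edge of length 29
  line <- matrix(FALSE, 40, 40); line[20, 5:34] <- TRUE
  g <- skeleton_to_graph(line)
  expect_identical(nrow(g$nodes), 2L)
  expect_identical(sort(g$nodes$kind), c("endpoint", "endpoint"))
  expect_identical(nrow(g$edges), 1L)
  expect_equal(g$edges$length, 29)
  # single closed ring: one anchor, one self-loop
  ring <- make_ring(64, r = 15)
  gr <- skeleton_to_graph(ring)
  expect_identical(nrow(gr$nodes), 1L)
  expect_identical(gr$nodes$kind, "cycle_anchor")
  expect_identical(nrow(gr$edges), 1L)
  expect_identical(gr$edges$from, gr$edges$to)
  expect_identical(cyclomatic_number(gr), 1L)
  # theta: 2 junctions, 3 edges, cyclomatic 2
  th <- skeleton_to_graph(make_theta())
  expect_identical(nrow(th$nodes), 2L)
  expect_true(all(th$nodes$kind == "junction"))
  expect_identical(nrow(th$edges), 3L)
  expect_identical(cyclomatic_number(th), 2L)
  # isolated pixel
  iso <- matrix(FALSE, 8, 8); iso[4, 4] <- TRUE
  gi <- skeleton_to_graph(iso)
  expect_identical(gi$nodes$kind, "isolated")
  expect_identical(nrow(gi$edges), 0L)
})

test_that("node degrees sum to twice the edge count", {
  shapes <- list(make_theta(), make_ring(64, r = 12))
  withr::with_seed(11, {
    for (i in 1:10) {
      shapes[[length(shapes) + 1L]] <-
        skeletonize(random_closed_mask(), prune_length = 5)
    }
  })
  for (sk in shapes) {
    g <- skeleton_to_graph(sk)
    nself <- sum(g$edges$from == g$edges$to)
    expect_identical(sum(g$nodes$degree),
                     2L * (nrow(g$edges) - nself) + 2L * nself)
  }
})

test_that("enclosed regions match analytic and exhaustive-count references", {
  # ring of radius 15: one region with area within 5% of pi r^2
  ring <- make_ring(64, r = 15)
  rg <- enclosed_regions(ring)
  expect_identical(nrow(rg), 1L)
  expect_lt(abs(rg$area - pi * 15^2) / (pi * 15^2), 0.05)
  # border-touching U encloses nothing
  u <- matrix(FALSE, 20, 20)
  u[1:15, 5] <- TRUE; u[1:15, 15] <- TRUE; u[15, 5:15] <- TRUE
  expect_identical(nrow(enclosed_regions(u)), 0L)
  # 2x2 grid of touching 10-px squares: four 9x9 interiors
  sq <- matrix(FALSE, 40, 40)
  for (r in c(5, 15, 25)) sq[r, 5:25] <- TRUE
  for (cc in c(5, 15, 25)) sq[5:25, cc] <- TRUE
  rgs <- enclosed_regions(sq)
  expect_identical(nrow(rgs), 4L)
  expect_identical(rgs$area, rep(81, 4))
  # pixel_area scaling
  rgs2 <- enclosed_regions(sq, pixel_area = 0.25)
  expect_identical(rgs2$area, rep(81 * 0.25, 4))
  expect_error(enclosed_regions(sq, pixel_area = -1), "pixel_area")
})

test_that("region areas, border background and skeleton pixels tile the frame", {
  withr::with_seed(21, {
    for (i in 1:8) {
      sk <- skeletonize(random_closed_mask(), prune_length = 5)
      rg <- enclosed_regions(sk)
      lab <- cordnet:::label_background(sk)
      border <- cordnet:::border_labels(lab)
      border_bg <- sum(lab %in% border)
      expect_identical(sum(rg$n_pixels) + border_bg + sum(sk),
                       length(sk))
    }
  })
})

test_that("enclosed-region count equals the cyclomatic number on synthetic skeletons", {
  for (s in c(2, 9, 23)) {
    net <- generate_network(network_spec(320, 320, n_seeds = 10 + 5 * s,
                                         noise_sd = 0,
                                         illumination_amplitude = 0,
                                         rng_seed = s))
    mask <- preprocess_frame(net$image, preprocess_params())
    sk <- skeletonize(mask)
    g <- skeleton_to_graph(sk)
    expect_identical(nrow(enclosed_regions(sk)), cyclomatic_number(g))
  }
})

test_that("frame_metrics summarizes a frame and checks provenance", {
  # empty skeleton: all-zero record
  empty <- matrix(FALSE, 16, 16)
  rec <- frame_metrics(empty)
  expect_identical(rec$loop_count, 0L)
  expect_identical(rec$total_area, 0)
  expect_identical(rec$components, 0L)
  # theta: cyclomatic number 2 and loop count 2 agree
  th <- make_theta()
  rec2 <- frame_metrics(th)
  expect_identical(rec2$loop_count, 2L)
  expect_identical(rec2$cyclomatic, 2L)
  expect_identical(rec2$junctions, 2L)
  # mismatched provenance rejected
  g <- skeleton_to_graph(th)
  attr(g, "frame_id") <- 1L
  r <- enclosed_regions(th, frame_id = 2L)
  expect_error(frame_metrics(th, g, r), "provenance")
})

test_that("noise-free synthetic loop count equals the ground truth", {
  net <- generate_network(network_spec(384, 384, n_seeds = 25, noise_sd = 0,
                                       illumination_amplitude = 0,
                                       rng_seed = 42))
  res <- analyze_frames(list(net$image))
  expect_identical(as.integer(res$metrics$loop_count),
                   nrow(net$truth$faces))
})

test_that("compare_series contracts: identity, invariance, errors", {
  rec <- function(v) tibble::tibble(total_area = v, mean_area = v)
  sa <- lapply(c(10, 12, 14), function(v) rec(c(v, v + 1)))
  cmp <- compare_series(sa, sa, n_boot = 200)
  expect_true(all(tidy(cmp)$diff == 0))
  expect_lte(glance(cmp)$ci_lower, 0)
  expect_gte(glance(cmp)$ci_upper, 0)
  # replicate order is irrelevant
  sb <- lapply(c(20, 5, 11), function(v) rec(v))
  c1 <- compare_series(lapply(c(1, 2, 3), function(v) rec(v)), sb, n_boot = 500)
  c2 <- compare_series(lapply(c(3, 2, 1), function(v) rec(v)), rev(sb), n_boot = 500)
  expect_identical(glance(c1), glance(c2))
  expect_identical(tidy(c1)$diff, tidy(c2)$diff)
  # mismatched replicate lengths rejected
  bad <- list(rec(1:3), rec(1:2))
  expect_error(compare_series(bad, sa), "same")
  expect_error(compare_series(list(), sa), "non-empty")
})
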