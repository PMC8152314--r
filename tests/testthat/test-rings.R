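test_that("a straight constant-calibre segment yields the forced ring layout", {
  net <- coronary_network(list(
    straight_segment(1, NA, c(0, 0), c(500, 0), n = 11)))
  rings <- decompose(net)
  expect_identical(nrow(rings), 10L)
  expect_equal(rings$x_um, seq(25, 475, by = 50))
  expect_equal(rings$wall_um, rep(30, 10))          # (300 - 240) / 2
  expect_equal(rings$outer_r_um, rep(150, 10))
  expect_equal(rings$axis_deg, rep(0, 10))
  expect_equal(rings$flow_um, rings$direct_um)      # straight through origin
  expect_equal(rings$flow_um, seq(25, 475, by = 50))
})

test_that("trailing remainders shorter than the ring length are discarded", {
  net <- coronary_network(list(
    straight_segment(1, NA, c(0, 0), c(480, 0), n = 11)))
  expect_identical(nrow(decompose(net)), 9L)
  # segment shorter than one ring contributes nothing, with a message
  short <- coronary_network(list(
    straight_segment(1, NA, c(0, 0), c(2000, 0), n = 5),
    straight_segment(2, 1, c(2000, 0), c(2000, 40), n = 2,
                     outer = 200, inner = 150)))
  expect_message(r <- decompose(short), "no rings")
  expect_true(all(r$segment_id == 1))
})

test_that("flow distance accumulates along the tree path", {
  root <- straight_segment(1, NA, c(0, 0), c(600, 0), n = 13)
  child <- straight_segment(2, 1, c(400, 0), c(400, 300), n = 7,
                            outer = 200, inner = 150)
  net <- coronary_network(list(root, child))
  rings <- decompose(net)
  child_rings <- rings[rings$segment_id == 2, ]
  expect_equal(child_rings$flow_um[1], 400 + 25)
  expect_equal(diff(child_rings$flow_um), rep(50, 5))
  # flow >= direct everywhere; child centres sit at direct sqrt(400^2 + y^2)
  expect_true(all(rings$flow_um >= rings$direct_um - 1e-9))
  expect_equal(child_rings$direct_um,
               sqrt(400^2 + seq(25, 275, by = 50)^2))
})

test_that("linear taper is interpolated exactly at ring centres", {
  net <- coronary_network(list(
    straight_segment(1, NA, c(0, 0), c(1000, 0), n = 21,
                     outer = c(400, 300), inner = c(320, 240))))
  rings <- decompose(net)
  centres <- seq(25, 975, by = 50)
  expect_equal(2 * rings$outer_r_um, 400 - 100 * centres / 1000,
               tolerance = 1e-12)
  expect_equal(2 * rings$inner_r_um, 320 - 80 * centres / 1000,
               tolerance = 1e-12)
})

test_that("ring counts are conserved and flow dominates direct distance", {
  for (s in c(2, 13, 29)) {
    net <- generate_network(generator_config(seed = s))
    rings <- suppressMessages(decompose(net))
    expected <- sum(vapply(net$segments,
                           function(seg) floor(arc_length(seg) / 50),
                           numeric(1)))
    expect_identical(nrow(rings), as.integer(expected))
    expect_true(all(rings$flow_um >= rings$direct_um - 1e-9))
    # per segment, flow strictly increases with ring index
    for (d in split(rings, rings$segment_id))
      expect_true(all(diff(d$flow_um) > 0))
    # total ringed length deficit below one ring length per segment
    deficit <- sum(vapply(net$segments, arc_length, numeric(1))) -
      nrow(rings) * 50
    expect_lt(deficit, length(net$segments) * 50)
    expect_gte(deficit, 0)
  }
})

test_that("ring tables serialise with the fixed column layout", {
  net <- two_segment_fixture()
  rings <- decompose(net)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ring_table(rings, path)
  tab <- utils::read.csv(path)
  expect_identical(names(tab),
                   c("segment_id", "ring_index", "outer_r_um", "inner_r_um",
                     "wall_um", "x_um", "y_um", "axis_deg", "direct_um",
                     "flow_um"))
  expect_identical(nrow(tab), nrow(rings))

  write_ring_table(rings[0, ], path)
  empty <- utils::read.csv(path)
  expect_identical(nrow(empty), 0L)
  expect_identical(ncol(empty), 10L)
})
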