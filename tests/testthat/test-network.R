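test_that("native segment table round-trips a network exactly", {
  net <- two_segment_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  write_network(net, path)
  back <- read_network(path, format = "segment_table")
  expect_equal(length(back$segments), length(net$segments))
  for (id in names(net$segments)) {
    expect_equal(back$segments[[id]]$parent_id, net$segments[[id]]$parent_id)
    expect_equal(back$segments[[id]]$points, net$segments[[id]]$points,
                 tolerance = 1e-12)
  }
})

test_that("segment-table row count equals the sum of per-segment points", {
  net <- generate_network(generator_config(seed = 7))
  path <- withr::local_tempfile(fileext = ".csv")
  write_network(net, path)
  n_rows <- nrow(utils::read.csv(path))
  expect_identical(n_rows,
                   sum(vapply(net$segments, function(s) nrow(s$points),
                              integer(1))))
})

test_that("structural and validation errors name the offending segment", {
  root <- straight_segment(1, NA, c(0, 0), c(1000, 0))
  orphan <- straight_segment(2, 99, c(1000, 0), c(1000, 500))
  expect_error(coronary_network(list(root, orphan)), "parent 99 does not exist")

  a <- straight_segment(1, 2, c(0, 0), c(500, 0))
  b <- straight_segment(2, 1, c(500, 0), c(500, 500))
  expect_error(coronary_network(list(a, b)), "exactly one root")

  expect_error(
    vessel_segment(1, NA, data.frame(x = c(0, 100), y = c(0, 0),
                                     outer_d = c(300, -5), inner_d = c(240, 200))),
    "nonpositive outer")
  expect_error(
    vessel_segment(1, NA, data.frame(x = c(0, 100), y = c(0, 0),
                                     outer_d = c(300, 300), inner_d = c(240, 320))),
    "inner diameter must be smaller")

  far_child <- straight_segment(2, 1, c(1000, 40), c(1000, 500))
  expect_error(coronary_network(list(root, far_child)), "tolerance")

  expect_error(write_network(structure(list(segments = list()),
                                       class = "coronary_network"),
                             tempfile()), "empty network")
})

test_that("loading translates the orifice to the origin and preserves distances", {
  seg1 <- straight_segment(1, NA, c(200, -300), c(1200, -300))
  seg2 <- straight_segment(2, 1, c(1200, -300), c(1200, 200),
                           outer = 200, inner = 150)
  net <- coronary_network(list(seg1, seg2))
  expect_equal(as.numeric(net$segments[["1"]]$points[1, c("x", "y")]), c(0, 0))
  # pairwise distance between the two segment tips is translation-invariant
  tip1 <- as.numeric(net$segments[["1"]]$points[11, c("x", "y")])
  tip2 <- as.numeric(net$segments[["2"]]$points[11, c("x", "y")])
  expect_equal(sqrt(sum((tip1 - tip2)^2)), 500)
})

test_that("networks are trees: segments = parent links + 1, all reachable", {
  for (s in c(3, 11)) {
    net <- generate_network(generator_config(seed = s))
    parents <- vapply(net$segments, function(x) x$parent_id, integer(1))
    expect_identical(length(net$segments), sum(!is.na(parents)) + 1L)
    expect_silent(validate_network(net))  # reachability checked on build
  }
})

test_that("SWC import derives the lumen from the wall model and stays planar", {
  swc <- c("# synthetic morphology",
           "1 2 0 0 0 200 -1",
           "2 2 500 0 0 200 1",
           "3 2 1000 0 3 190 2")
  path <- withr::local_tempfile(fileext = ".swc")
  writeLines(swc, path)
  expect_warning(
    net <- read_network(path, format = "swc", wall_model = c(a = 10, b = 0.05)),
    "planar")
  pts <- net$segments[[1]]$points
  expect_equal(pts$outer_d[1], 400)
  expect_equal(pts$inner_d[1], 400 - 2 * (10 + 0.05 * 400))  # 340 um
  expect_error(read_network(path, format = "swc"), "wall_model")
})

test_that("arc_length matches hand values and a brute-force oracle", {
  expect_equal(arc_length(straight_segment(1, NA, c(0, 0), c(500, 0), n = 2)),
               500)
  bent <- vessel_segment(1, NA, data.frame(
    x = c(0, 300, 300), y = c(0, 0, 400),
    outer_d = 300, inner_d = 240))
  expect_equal(arc_length(bent), 700)

  set.seed(5)
  pts <- data.frame(x = cumsum(runif(100, 1, 50)),
                    y = cumsum(rnorm(100, 0, 20)),
                    outer_d = 300, inner_d = 240)
  seg <- vessel_segment(1, NA, pts)
  brute <- 0
  for (i in 2:100) brute <- brute +
      sqrt((pts$x[i] - pts$x[i - 1])^2 + (pts$y[i] - pts$y[i - 1])^2)
  expect_equal(arc_length(seg), brute, tolerance = 1e-12)
})

test_that("direction_at returns distal-pointing unit tangents", {
  segx <- straight_segment(1, NA, c(0, 0), c(500, 0), n = 6)
  expect_equal(direction_at(segx, 250, 50), c(1, 0))
  segy <- straight_segment(1, NA, c(0, 0), c(0, 500), n = 6)
  expect_equal(direction_at(segy, 250, 50), c(0, 1))

  # quarter circle of radius 1000: tangent at the arc midpoint (45 deg)
  th <- seq(0, pi / 2, length.out = 200)
  arc <- vessel_segment(1, NA, data.frame(
    x = 1000 * sin(th), y = 1000 * (1 - cos(th)),
    outer_d = 300, inner_d = 240))
  L <- arc_length(arc)
  v <- direction_at(arc, L / 2, 20)
  analytic <- c(cos(pi / 4), sin(pi / 4))
  angle_err <- acos(min(1, sum(v * analytic))) * 180 / pi
  expect_lt(angle_err, 1)

  expect_error(direction_at(segx, 600, 50), "outside segment")
})
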