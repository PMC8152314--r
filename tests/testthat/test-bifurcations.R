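test_that("branching angles follow the 90/180-degree convention", {
  # one daughter continues the mother's course, the other is perpendicular
  mother <- straight_segment(1, NA, c(0, 0), c(400, 0), n = 9)
  cont <- straight_segment(2, 1, c(400, 0), c(800, 0), n = 9,
                           outer = 250, inner = 200)
  perp <- straight_segment(3, 1, c(400, 0), c(400, 400), n = 9,
                           outer = 150, inner = 110)
  net <- coronary_network(list(mother, cont, perp))
  b <- extract_bifurcations(net)
  expect_identical(nrow(b), 1L)
  expect_equal(b$angle1_deg, 180, tolerance = 1e-9)   # larger daughter
  expect_equal(b$angle2_deg, 90, tolerance = 1e-9)

  # symmetric Y at +/- 45 degrees: both daughters score 135
  yb <- extract_bifurcations(y_fixture(45))
  expect_equal(c(yb$angle1_deg, yb$angle2_deg), c(135, 135), tolerance = 0.5)
})

test_that("angles are label-symmetric and rotation-invariant", {
  net <- y_fixture(30)
  b <- extract_bifurcations(net)
  th <- 72 * pi / 180
  rot <- lapply(net$segments, function(s) {
    p <- s$points
    vessel_segment(s$segment_id, s$parent_id, data.frame(
      x = p$x * cos(th) - p$y * sin(th),
      y = p$x * sin(th) + p$y * cos(th),
      outer_d = p$outer_d, inner_d = p$inner_d))
  })
  b_rot <- extract_bifurcations(coronary_network(unname(rot)))
  expect_equal(sort(c(b$angle1_deg, b$angle2_deg)),
               sort(c(b_rot$angle1_deg, b_rot$angle2_deg)), tolerance = 1e-6)
})

test_that("a single child at a segment tip is a continuation, not a bifurcation", {
  net <- two_segment_fixture()
  expect_message(b <- extract_bifurcations(net), "continuation")
  expect_identical(nrow(b), 0L)
})

test_that("murray_residual reproduces hand values and scale invariance", {
  expect_equal(murray_residual(100, 100 / 2^(1/3), 100 / 2^(1/3)), 0,
               tolerance = 1e-12)
  expect_equal(murray_residual(100, 100, 100), log10(2), tolerance = 1e-12)
  # continuation limit: tiny second daughter
  expect_equal(murray_residual(100, 100, 1e-6), 0, tolerance = 1e-9)
  # invariant under uniform rescaling of all radii
  set.seed(1)
  r <- runif(3, 50, 200)
  expect_equal(murray_residual(r[1], r[2], r[3]),
               murray_residual(10 * r[1], 10 * r[2], 10 * r[3]),
               tolerance = 1e-12)
})

test_that("the branching exponent is recovered from generated bifurcations", {
  set.seed(101)
  for (g_true in c(2, 3, 4)) {
    bifs <- simulate_bifurcations(200, gamma = g_true, sigma_log = 0)
    fit <- fit_murray_exponent(bifs)
    expect_equal(fit$gamma_hat, g_true, tolerance = 1e-3)
  }
  bifs <- simulate_bifurcations(200, gamma = 2, sigma_log = 0.05)
  expect_equal(fit_murray_exponent(bifs)$gamma_hat, 2, tolerance = 0.15)
})

test_that("identical radius ratios trigger the low-identifiability warning", {
  bifs <- data.frame(r_m_um = c(100, 80, 60),
                     r_d1_um = c(100, 80, 60) * 0.9,
                     r_d2_um = c(100, 80, 60) * 0.6)
  expect_warning(fit_murray_exponent(bifs), "weakly identified")
})

test_that("angle-ratio correlation behaves at the analytic extremes", {
  ratio <- seq(1, 3, length.out = 10)
  bifs <- data.frame(r_m_um = 100, r_d1_um = 100 / ratio, r_d2_um = 100 / ratio,
                     angle1_deg = 180 - 30 * (ratio - 1),
                     angle2_deg = 180 - 30 * (ratio - 1))
  res <- angle_ratio_correlation(bifs)
  expect_equal(res$pearson_r, -1, tolerance = 1e-12)

  const <- transform(bifs, angle1_deg = 120, angle2_deg = 120)
  expect_error(angle_ratio_correlation(const), "zero variance")
})

test_that("generated networks show the negative angle-ratio relation", {
  bifs <- do.call(rbind, lapply(1:8, function(s) {
    suppressMessages(extract_bifurcations(
      generate_network(generator_config(seed = 300 + s))))
  }))
  expect_gte(nrow(bifs), 50)
  res <- angle_ratio_correlation(bifs)
  expect_lt(res$pearson_r, 0)
  expect_lt(res$p_value, 0.05)
})
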