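test_that("spectrum counts rings into half-open diameter classes", {
  sp <- spectrum(ring_table_of(rep(300, 10)))
  expect_equal(unname(sp$counts[as.character(300)]), 10)
  expect_equal(sp$n_rings, 10)
  expect_equal(sum(sp$counts), 10)

  # boundary 325 falls upward into the 350 class
  sp2 <- spectrum(ring_table_of(325))
  expect_equal(unname(sp2$counts[as.character(350)]), 1)
  expect_equal(unname(sp2$counts[as.character(300)]), 0)

  # sub-floor rings dropped with a message, overshoot pooled on top
  expect_message(sp3 <- spectrum(ring_table_of(c(60, 300, 900))), "dropped")
  expect_equal(sp3$n_dropped, 1)
  expect_equal(unname(sp3$counts[as.character(700)]), 1)
})

test_that("spectrum matches a brute-force loop classifier on 1000 rings", {
  set.seed(42)
  d <- runif(1000, 100, 600)
  sp <- spectrum(ring_table_of(d))
  centers <- seq(100, 700, by = 50)
  brute <- integer(13)
  for (x in d) {
    for (k in seq_along(centers)) {
      if (x >= centers[k] - 25 && x < centers[k] + 25) {
        brute[k] <- brute[k] + 1L
        break
      }
    }
  }
  expect_identical(unname(sp$counts), brute)
})

test_that("pooling spectra over animals equals the spectrum of pooled rings", {
  set.seed(7)
  d1 <- runif(400, 90, 650); d2 <- runif(300, 90, 650)
  pooled <- pool_spectra(spectrum(ring_table_of(d1)),
                         spectrum(ring_table_of(d2)))
  direct <- spectrum(ring_table_of(c(d1, d2)))
  expect_identical(pooled$counts, direct$counts)
  # permutation invariance
  shuffled <- spectrum(ring_table_of(sample(c(d1, d2))))
  expect_identical(shuffled$counts, direct$counts)
})

test_that("chi-square comparison matches hand contingency arithmetic", {
  b13 <- diameter_binning()
  mk <- function(counts) {
    structure(list(counts = stats::setNames(counts, b13$centers),
                   n_rings = sum(counts), n_dropped = 0,
                   group = NA, binning = b13), class = "ring_spectrum")
  }
  a <- mk(c(10, 20, rep(0, 11)))
  b <- mk(c(20, 10, rep(0, 11)))
  res <- chi2_compare(a, b)
  expect_equal(res$chi2, 20 / 3, tolerance = 1e-9)  # hand: sum (O-E)^2/E
  expect_equal(res$df, 1)
  expect_identical(res$dropped_classes, b13$centers[3:13])

  set.seed(11)
  ca <- rpois(13, 40) + 1; cb <- rpois(13, 40) + 1
  res2 <- chi2_compare(mk(ca), mk(cb))
  expect_equal(res2$chi2, chisq_by_hand(rbind(ca, cb)), tolerance = 1e-9)
  expect_equal(res2$df, 12)

  # symmetry and the identical-spectra degenerate case
  res3 <- chi2_compare(mk(cb), mk(ca))
  expect_equal(res2$chi2, res3$chi2)
  same <- chi2_compare(mk(ca), mk(ca))
  expect_equal(same$chi2, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)
})

test_that("chi-square grows about linearly with proportional total counts", {
  b13 <- diameter_binning()
  mk <- function(counts) {
    structure(list(counts = stats::setNames(counts, b13$centers),
                   n_rings = sum(counts), n_dropped = 0,
                   group = NA, binning = b13), class = "ring_spectrum")
  }
  ca <- c(30, 50, 70, 90, 80, 60, 50, 40, 30, 20, 15, 10, 5)
  cb <- rev(ca)
  x1 <- chi2_compare(mk(ca), mk(cb))
  x3 <- chi2_compare(mk(3 * ca), mk(3 * cb))
  expect_equal(x3$df, x1$df)
  expect_equal(x3$chi2 / x1$chi2, 3, tolerance = 1e-9)
})

test_that("the 2-D histogram bins flow distance and marginalises to the spectrum", {
  rings <- ring_table_of(rep(300, 7), flow_um = rep(5500, 7))
  h <- histogram2d(rings)
  expect_equal(h$counts["300", "5"], 7)
  expect_equal(sum(h$counts), 7)

  net <- generate_network(generator_config(seed = 17))
  rr <- suppressMessages(decompose(net))
  h2 <- suppressMessages(histogram2d(rr))
  sp <- suppressMessages(
    spectrum(rr[rr$flow_um < 25000, , drop = FALSE]))
  expect_equal(unname(rowSums(h2$counts)), unname(sp$counts))
})

test_that("an imposed joint density is recovered within total variation 0.05", {
  b13 <- diameter_binning()
  dens <- matrix(0, nrow = 13, ncol = 25)
  dens[2, 8:13] <- 3; dens[4, 5:10] <- 2; dens[7, 1:6] <- 4; dens[11, 1:3] <- 5
  dens <- dens / sum(dens)
  set.seed(99)
  rings <- sample_rings_from_density(dens, n = 10000)
  h <- histogram2d(rings)
  expect_equal(sum(h$counts), 10000)
  tv <- 0.5 * sum(abs(h$counts / sum(h$counts) - dens))
  expect_lt(tv, 0.05)
})
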