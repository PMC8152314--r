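#' Configuration for the synthetic coronary-tree generator
#'
#' The generator grows planar, orifice-rooted trees that mimic a perfused
#' left-coronary resistance-artery network traced down to ~80 um: lumen
#' radii split at bifurcations according to a tunable branching exponent,
#' walls follow a linear thickness-versus-diameter law with Gaussian
#' scatter, daughters take off at angles that shrink with the
#' mother/daughter radius ratio, and centerlines meander with a small
#' direction random walk. All randomness flows from one seed.
#'
#' @param seed Integer seed; identical seeds give identical networks.
#' @param root_outer_d Outer diameter of the root stem at the orifice, um.
#' @param murray_gamma Branching exponent; 3 is Murray's law.
#' @param asymmetry Range of the daughter radius ratio `r_d2 / r_d1`
#'   (sampled uniformly).
#' @param segment_length_median,segment_length_sdlog Log-normal segment
#'   length distribution (um).
#' @param terminal_cutoff Branches stop below this outer diameter, um
#'   (the preparation limit).
#' @param wall_a,wall_b,wall_sigma Wall model
#'   `w = wall_a + wall_b * outer_d + N(0, wall_sigma)`, um. `wall_sigma`
#'   is the contour-reading error of the tracing and is applied to the
#'   outer and the inner contour independently, so recorded lumina scatter
#'   around the exact Murray-compliant construction; at `wall_sigma = 0`
#'   the recorded network is noise-free.
#' @param angle_c,angle_sigma Branching-angle law
#'   `angle = 180 - angle_c * (r_m / r_d - 1) + N(0, angle_sigma)`,
#'   degrees, clamped to (60, 180].
#' @param taper Per-segment linear fractional diameter loss.
#' @param tortuosity_sd Direction random-walk SD per 50-um step, degrees.
#' @param max_flow_mm Branches stop beyond this flow distance, mm.
#' @param side_loss Probability that the smaller daughter of a bifurcation
#'   leaves the traced plane (a penetrating branch) and is omitted from
#'   the network. In situ planar video microscopy of an intramural network
#'   captures only branches running near the surface plane; this single
#'   loss rate is calibrated so that networks carry on the order of
#'   500-1000 ring units, bracketing realistic per-heart counts.
#' @param wall_b_shift Optional list `(range = c(lo, hi), delta)`: adds
#'   `delta` to `wall_b` for vessels whose outer diameter falls in
#'   `range` (used by the training presets to remodel the wall).
#' @param extra_branches Optional list of side-branch enrichment rules,
#'   each `list(outer_d = c(lo, hi), flow_mm = c(lo, hi), rate_per_mm)`:
#'   extra terminal twigs of the given calibre sprouted at the given flow
#'   distances (used by the presets to reshape the diameter spectra).
#' @param preset Name of the group preset the config came from.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             root_outer_d = 550,
                             murray_gamma = 3,
                             asymmetry = c(0.4, 1.0),
                             segment_length_median = 900,
                             segment_length_sdlog = 0.4,
                             terminal_cutoff = 80,
                             wall_a = 8, wall_b = 0.06, wall_sigma = 3,
                             angle_c = 25, angle_sigma = 10,
                             taper = 0.05,
                             tortuosity_sd = 3,
                             max_flow_mm = 20,
                             side_loss = 0.62,
                             wall_b_shift = NULL,
                             extra_branches = list(),
                             preset = "none") {
  cfg <- list(seed = as.integer(seed), root_outer_d = root_outer_d,
              murray_gamma = murray_gamma, asymmetry = asymmetry,
              segment_length_median = segment_length_median,
              segment_length_sdlog = segment_length_sdlog,
              terminal_cutoff = terminal_cutoff,
              wall_a = wall_a, wall_b = wall_b, wall_sigma = wall_sigma,
              angle_c = angle_c, angle_sigma = angle_sigma,
              taper = taper, tortuosity_sd = tortuosity_sd,
              max_flow_mm = max_flow_mm, side_loss = side_loss,
              wall_b_shift = wall_b_shift,
              extra_branches = extra_branches,
              preset = preset)
  stopifnot(root_outer_d > 0, terminal_cutoff > 0,
            terminal_cutoff < root_outer_d, murray_gamma > 0,
            length(asymmetry) == 2, asymmetry[1] > 0,
            asymmetry[2] <= 1, asymmetry[1] <= asymmetry[2],
            segment_length_median > 0, wall_sigma >= 0, angle_sigma >= 0,
            taper >= 0, taper < 1, wall_b < 0.5,
            side_loss >= 0, side_loss < 1)
  structure(cfg, class = "generator_config")
}

#' Group presets for the synthetic generator
#'
#' Four presets emulate the qualitative sex and swim-training contrasts of
#' the study design: `MSed` (male sedentary) is the male baseline; `MEx`
#' thickens the wall of mid-calibre (200-500 um) vessels and enriches
#' 400-um-class branches within 5 mm of the orifice and 200-um-class
#' branches at 8-13 mm; `FSed` is a lighter-calibre female baseline with a
#' small-vessel cluster far from the orifice; `FEx` thins the largest
#' walls and inserts a new 200-250-um population at 5-8 mm flow distance.
#' `none` returns the plain default configuration.
#'
#' @param name One of `"MSed"`, `"MEx"`, `"FSed"`, `"FEx"`, `"none"`.
#' @param seed Seed stored in the returned config.
#' @return A [generator_config()].
#' @export
group_preset <- function(name = c("none", "MSed", "MEx", "FSed", "FEx"),
                         seed = 1L) {
  name <- match.arg(name)
  switch(name,
    none = generator_config(seed = seed),
    MSed = generator_config(seed = seed, preset = "MSed"),
    MEx = generator_config(
      seed = seed, preset = "MEx",
      wall_b_shift = list(range = c(200, 500), delta = 0.02),
      extra_branches = list(
        list(outer_d = c(375, 425), flow_mm = c(0, 5), rate_per_mm = 0.8),
        list(outer_d = c(175, 225), flow_mm = c(8, 13), rate_per_mm = 1.2))),
    FSed = generator_config(
      seed = seed, preset = "FSed", root_outer_d = 500,
      extra_branches = list(
        list(outer_d = c(150, 350), flow_mm = c(10, 15), rate_per_mm = 0.8))),
    FEx = generator_config(
      seed = seed, preset = "FEx", root_outer_d = 500,
      wall_b_shift = list(range = c(400, Inf), delta = -0.015),
      extra_branches = list(
        list(outer_d = c(140, 175), flow_mm = c(8, 15), rate_per_mm = 0.9),
        list(outer_d = c(200, 250), flow_mm = c(5, 8), rate_per_mm = 1.2))))
}

# noise-free wall thickness and outer diameter for a given lumen diameter,
# honouring any preset wall_b shift (resolved on the unshifted outer)
wall_for_lumen <- function(lumen_d, cfg) {
  b <- cfg$wall_b
  outer0 <- (lumen_d + 2 * cfg$wall_a) / (1 - 2 * b)
  if (!is.null(cfg$wall_b_shift)) {
    rng <- cfg$wall_b_shift$range
    shift <- outer0 >= rng[1] & outer0 <= rng[2]
    b <- ifelse(shift, b + cfg$wall_b_shift$delta, b)
  }
  (cfg$wall_a + b * lumen_d) / (1 - 2 * b)
}

#' Grow a synthetic coronary network
#'
#' Recursive planar growth from the orifice along +X. Segment lengths are
#' log-normal; centerlines advance in 50-um steps with a direction random
#' walk; lumen diameter tapers linearly within a segment; at each segment
#' end two daughters are spawned whose lumen radii satisfy
#' `r_d1^g + r_d2^g = r_m^g` exactly for the configured exponent and a
#' uniformly sampled asymmetry ratio. Walls are drawn from the linear wall
#' model; daughter take-off angles follow the angle law. Branches die when
#' their outer diameter falls under the terminal cutoff or their flow
#' distance passes the cap, and trailing traced points below the cutoff
#' are pruned so the result always passes [validate_network()].
#'
#' @param cfg A [generator_config()] (or preset).
#' @param seed Optional seed overriding `cfg$seed`.
#' @return A validated `coronary_network`; `metadata$preset` and
#'   `metadata$seed` record the provenance.
#' @export
generate_network <- function(cfg = generator_config(), seed = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  if (is.null(seed)) seed <- cfg$seed
  set.seed(seed)
  step <- 50
  segments <- list()
  next_id <- 0L

  root_lumen <- cfg$root_outer_d - 2 * (cfg$wall_a + cfg$wall_b * cfg$root_outer_d)
  stopifnot(root_lumen > 0)
  queue <- list(list(x = 0, y = 0, dir = 0, lumen = root_lumen,
                     flow = 0, parent = NA_integer_))

  while (length(queue) > 0L && length(segments) < 4000L) {
    job <- queue[[1]]; queue <- queue[-1]
    if (job$flow > cfg$max_flow_mm * 1000) next
    w0 <- wall_for_lumen(job$lumen, cfg)
    if (job$lumen + 2 * w0 < cfg$terminal_cutoff) next

    len <- stats::rlnorm(1, log(cfg$segment_length_median),
                         cfg$segment_length_sdlog)
    n_steps <- max(2L, as.integer(round(len / step)))

    dirs <- job$dir + cumsum(c(0, stats::rnorm(n_steps, 0,
                                               cfg$tortuosity_sd * pi / 180)))
    x <- job$x + c(0, cumsum(step * cos(dirs[-1])))
    y <- job$y + c(0, cumsum(step * sin(dirs[-1])))
    lumen <- job$lumen * seq(1, 1 - cfg$taper, length.out = n_steps + 1L)

    # side-twig enrichment (presets): terminal twigs sprouting mid-segment.
    # Each twig junction is treated as a genuine bifurcation: the host
    # lumen is stepped down distally so that the branching-exponent
    # relation holds there too.
    g <- cfg$murray_gamma
    twig_specs <- list()
    for (rule in cfg$extra_branches) {
      pt_flow_mm <- (job$flow + step * (seq_len(n_steps + 1L) - 1L)) / 1000
      at <- which(pt_flow_mm >= rule$flow_mm[1] & pt_flow_mm < rule$flow_mm[2])
      at <- at[at > 1L & at < n_steps + 1L]
      if (length(at) == 0) next
      p_hit <- rule$rate_per_mm * step / 1000
      hits <- at[stats::runif(length(at)) < p_hit]
      for (i in hits) {
        twig_outer <- stats::runif(1, rule$outer_d[1], rule$outer_d[2])
        twig_lumen <- twig_outer - 2 * (cfg$wall_a + cfg$wall_b * twig_outer)
        if (twig_lumen <= 0 || twig_lumen > 0.85 * lumen[i]) next
        shrink <- (1 - (twig_lumen / lumen[i])^g)^(1 / g)
        lumen[(i + 1L):(n_steps + 1L)] <-
          lumen[(i + 1L):(n_steps + 1L)] * shrink
        twig_specs[[length(twig_specs) + 1L]] <- list(
          i = i, lumen = twig_lumen,
          dir = dirs[i] + sample(c(-1, 1), 1) *
            stats::runif(1, 50, 80) * pi / 180)
      }
    }

    w <- wall_for_lumen(lumen, cfg) + stats::rnorm(n_steps + 1L, 0, cfg$wall_sigma)
    w <- pmax(w, 0.5)
    outer <- lumen + 2 * w
    inner <- lumen - 2 * stats::rnorm(n_steps + 1L, 0, cfg$wall_sigma)
    inner <- pmin(pmax(inner, 0.3 * outer), outer - 1)

    # prune trailing points under the preparation cutoff
    below <- which(outer < cfg$terminal_cutoff)
    keep_n <- if (length(below) > 0) below[1] - 1L else n_steps + 1L
    if (keep_n < 2L) next
    idx <- seq_len(keep_n)
    pts <- data.frame(x = x[idx], y = y[idx],
                      outer_d = outer[idx], inner_d = inner[idx])
    next_id <- next_id + 1L
    this_id <- next_id
    segments[[this_id]] <- vessel_segment(this_id, job$parent, pts)

    for (tw in twig_specs) {
      if (tw$i > keep_n) next
      twig <- grow_twig(cfg, x0 = x[tw$i], y0 = y[tw$i], dir0 = tw$dir,
                        lumen_d = tw$lumen)
      if (!is.null(twig)) {
        next_id <- next_id + 1L
        segments[[next_id]] <- vessel_segment(next_id, this_id, twig$points)
      }
    }
    if (keep_n < n_steps + 1L) next  # branch died inside the segment

    seg_arc <- step * n_steps
    end_flow <- job$flow + seg_arc
    end_dir <- dirs[n_steps + 1L]

    # Murray-exact bifurcation at the segment end
    r_m <- lumen[n_steps + 1L] / 2
    a <- stats::runif(1, cfg$asymmetry[1], cfg$asymmetry[2])
    r_d1 <- r_m / (1 + a^g)^(1 / g)
    r_d2 <- a * r_d1
    side <- sample(c(-1, 1), 1)
    daughters <- list(list(r = r_d1, s = side), list(r = r_d2, s = -side))
    # smaller daughter may dive out of the traced plane and be lost
    if (stats::runif(1) < cfg$side_loss) daughters <- daughters[1]
    for (d in daughters) {
      ang <- 180 - cfg$angle_c * (r_m / d$r - 1) +
        stats::rnorm(1, 0, cfg$angle_sigma)
      ang <- min(180, max(60 + 1e-6, ang))
      dev <- (180 - ang) * pi / 180
      queue <- c(queue, list(list(
        x = x[n_steps + 1L], y = y[n_steps + 1L],
        dir = end_dir + d$s * dev,
        lumen = 2 * d$r, flow = end_flow, parent = this_id)))
    }
  }
  if (length(segments) == 0L)
    stop("configuration produced no segments", call. = FALSE)
  coronary_network(segments,
                   metadata = list(preset = cfg$preset, seed = seed),
                   diameter_cutoff = cfg$terminal_cutoff, attach_tol = 5)
}

# terminal side twig: short, unbranched, slightly tapering
grow_twig <- function(cfg, x0, y0, dir0, lumen_d) {
  len <- stats::runif(1, 250, 650)
  n_steps <- max(2L, as.integer(round(len / 50)))
  dirs <- dir0 + cumsum(c(0, stats::rnorm(n_steps, 0,
                                          cfg$tortuosity_sd * pi / 180)))
  x <- x0 + c(0, cumsum(50 * cos(dirs[-1])))
  y <- y0 + c(0, cumsum(50 * sin(dirs[-1])))
  lumen <- lumen_d * seq(1, 1 - cfg$taper, length.out = n_steps + 1L)
  w <- wall_for_lumen(lumen, cfg) + stats::rnorm(n_steps + 1L, 0, cfg$wall_sigma)
  w <- pmax(w, 0.5)
  outer <- lumen + 2 * w
  inner <- lumen - 2 * stats::rnorm(n_steps + 1L, 0, cfg$wall_sigma)
  inner <- pmin(pmax(inner, 0.3 * outer), outer - 1)
  below <- which(outer < cfg$terminal_cutoff)
  keep_n <- if (length(below) > 0) below[1] - 1L else n_steps + 1L
  if (keep_n < 2L) return(NULL)
  idx <- seq_len(keep_n)
  list(points = data.frame(x = x[idx], y = y[idx],
                           outer_d = outer[idx], inner_d = inner[idx]))
}

#' Generate a group of synthetic networks
#'
#' Per-network seeds are derived deterministically from the base seed, so
#' the whole cohort reproduces from one integer.
#'
#' @param preset Preset name, see [group_preset()].
#' @param n Number of animals (networks).
#' @param seed Base seed.
#' @return List of `coronary_network` objects.
#' @export
generate_group <- function(preset, n = 10, seed = 1L) {
  cfg <- group_preset(preset, seed = seed)
  lapply(seq_len(n), function(i) {
    derived <- (as.numeric(seed) * 1009 + i * 9973) %% 2147483647
    generate_network(cfg, seed = as.integer(derived))
  })
}

#' Simulate bifurcation radii with a known branching exponent
#'
#' Draws mother lumen radii log-uniformly, splits each exactly according
#' to `r_d1^g + r_d2^g = r_m^g` with a uniformly sampled asymmetry, then
#' perturbs every radius with independent log-normal noise. Used to
#' exercise exponent recovery: at `sigma_log = 0` the fitted exponent
#' equals the generating one.
#'
#' @param n Number of bifurcations.
#' @param gamma Generating exponent.
#' @param sigma_log SD of the log-normal multiplicative radius noise.
#' @param r_m_range Range of mother lumen radii, um.
#' @param asymmetry Range of the daughter ratio `r_d2 / r_d1`.
#' @return `data.frame` with `r_m_um`, `r_d1_um`, `r_d2_um`.
#' @export
simulate_bifurcations <- function(n, gamma = 3, sigma_log = 0,
                                  r_m_range = c(40, 250),
                                  asymmetry = c(0.4, 1.0)) {
  r_m <- exp(stats::runif(n, log(r_m_range[1]), log(r_m_range[2])))
  a <- stats::runif(n, asymmetry[1], asymmetry[2])
  r_d1 <- r_m / (1 + a^gamma)^(1 / gamma)
  r_d2 <- a * r_d1
  noise <- function(k) exp(stats::rnorm(k, 0, sigma_log))
  data.frame(r_m_um = r_m * noise(n),
             r_d1_um = r_d1 * noise(n),
             r_d2_um = r_d2 * noise(n))
}

#' Sample ring units from an imposed diameter-by-distance density
#'
#' Draws ring units directly from a known joint density on the diameter
#' class by flow-distance bin grid (uniform within each cell), giving a
#' ground truth against which [histogram2d()] recovery can be measured.
#'
#' @param density Matrix of cell probabilities, rows = diameter classes of
#'   `binning`, columns = consecutive `flow_bin_mm`-wide distance bins
#'   starting at 0; normalised internally.
#' @param n Number of rings to draw.
#' @param binning A [diameter_binning()].
#' @param flow_bin_mm Distance bin width, mm.
#' @return Ring table with `outer_d_um`, `flow_um`, `wall_um` (from the
#'   default wall law, for convenience).
#' @export
sample_rings_from_density <- function(density, n,
                                      binning = diameter_binning(),
                                      flow_bin_mm = 1) {
  stopifnot(nrow(density) == length(binning$centers), all(density >= 0),
            sum(density) > 0)
  p <- density / sum(density)
  cells <- sample.int(length(p), n, replace = TRUE, prob = as.vector(p))
  ki <- (cells - 1L) %% nrow(p) + 1L
  kj <- (cells - 1L) %/% nrow(p) + 1L
  outer_d <- stats::runif(n, binning$centers[ki] - binning$width / 2,
                          binning$centers[ki] + binning$width / 2)
  flow_mm <- stats::runif(n, (kj - 1) * flow_bin_mm, kj * flow_bin_mm)
  data.frame(outer_d_um = outer_d,
             flow_um = flow_mm * 1000,
             wall_um = 8 + 0.06 * outer_d)
}
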