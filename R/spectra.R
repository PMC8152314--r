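#' Outer-diameter class binning
#'
#' The default binning has 13 classes centred at 100, 150, ..., 700 um of
#' outer diameter; class k spans the half-open interval
#' `[centre - 25, centre + 25)`. Thirteen fully occupied classes give a
#' two-group homogeneity test 12 degrees of freedom.
#'
#' @param centers Class centres in micrometres, equally spaced.
#' @return An object of class `diameter_binning` with elements `centers`,
#'   `breaks` and `width`.
#' @export
diameter_binning <- function(centers = seq(100, 700, by = 50)) {
  stopifnot(length(centers) >= 2, all(diff(centers) > 0))
  w <- diff(centers)
  stopifnot(max(w) - min(w) < 1e-9)
  structure(list(centers = centers,
                 breaks = c(centers - w[1] / 2, centers[length(centers)] + w[1] / 2),
                 width = w[1]),
            class = "diameter_binning")
}

# class index per outer diameter; NA below floor, top class for overshoot
classify_diameter <- function(outer_d, binning) {
  k <- findInterval(outer_d, binning$breaks, rightmost.closed = FALSE)
  k[k == 0] <- NA_integer_                         # below the floor: dropped
  k[k > length(binning$centers)] <- length(binning$centers)  # pooled on top
  k
}

#' Ring-frequency spectrum by outer-diameter class
#'
#' Counts ring units per outer-diameter class. Rings thinner than the
#' lowest class edge (75 um by default, just under the ~80 um preparation
#' cutoff) are dropped with a message; rings above the top edge are pooled
#' into the top class.
#'
#' @param rings Ring table from [decompose()] (needs `outer_d_um`), or a
#'   pooled table for several animals.
#' @param binning A [diameter_binning()].
#' @param group Optional group label carried on the result.
#' @return Object of class `ring_spectrum`: list with `counts` (named by
#'   class centre), `n_rings`, `n_dropped`, `group`, `binning`.
#' @export
spectrum <- function(rings, binning = diameter_binning(), group = NA_character_) {
  stopifnot(nrow(rings) > 0)
  k <- classify_diameter(rings$outer_d_um, binning)
  dropped <- sum(is.na(k))
  if (dropped > 0)
    message(dropped, " ring(s) below ", binning$breaks[1],
            " um dropped from the spectrum")
  counts <- tabulate(k[!is.na(k)], nbins = length(binning$centers))
  names(counts) <- binning$centers
  structure(list(counts = counts, n_rings = sum(counts),
                 n_dropped = dropped, group = group, binning = binning),
            class = "ring_spectrum")
}

#' @export
print.ring_spectrum <- function(x, ...) {
  cat("<ring_spectrum>", if (!is.na(x$group)) paste0(" group ", x$group),
      " n = ", x$n_rings, " rings in ", length(x$counts), " classes\n",
      sep = "")
  print(x$counts)
  invisible(x)
}

#' Pool spectra across animals
#'
#' Pooling is class-wise summation of counts, so the pooled spectrum of a
#' group equals the spectrum of the concatenated ring tables.
#'
#' @param ... `ring_spectrum` objects sharing a binning.
#' @return A pooled `ring_spectrum`.
#' @export
pool_spectra <- function(...) {
  sp <- list(...)
  if (length(sp) == 1L && is.list(sp[[1]]) && !inherits(sp[[1]], "ring_spectrum"))
    sp <- sp[[1]]
  stopifnot(length(sp) >= 1, all(vapply(sp, inherits, logical(1), "ring_spectrum")))
  ctr <- sp[[1]]$binning$centers
  for (s in sp) stopifnot(identical(s$binning$centers, ctr))
  counts <- Reduce(`+`, lapply(sp, `[[`, "counts"))
  structure(list(counts = counts,
                 n_rings = sum(counts),
                 n_dropped = sum(vapply(sp, `[[`, numeric(1), "n_dropped")),
                 group = sp[[1]]$group, binning = sp[[1]]$binning),
            class = "ring_spectrum")
}

#' Bidimensional diameter-by-flow-distance histogram
#'
#' Joint ring-unit counts on the grid of outer-diameter classes by 1-mm
#' half-open flow-distance bins `[0,1), ..., [max-1, max)` mm. Marginalising
#' over distance reproduces the diameter spectrum of the in-range rings.
#' Rings at or beyond the distance ceiling are dropped with a message.
#'
#' @param rings Ring table (needs `outer_d_um`, `flow_um`).
#' @param binning A [diameter_binning()].
#' @param flow_bin_mm Flow-distance bin width, mm.
#' @param max_flow_mm Distance ceiling, mm.
#' @param group Optional group label.
#' @return Object of class `ring_hist2d`: list with `counts` (matrix,
#'   diameter classes x distance bins), `flow_breaks_mm`, `binning`,
#'   `n_dropped`, `group`.
#' @export
histogram2d <- function(rings, binning = diameter_binning(),
                        flow_bin_mm = 1, max_flow_mm = 25,
                        group = NA_character_) {
  stopifnot(nrow(rings) > 0, flow_bin_mm > 0, max_flow_mm > flow_bin_mm)
  flow_breaks <- seq(0, max_flow_mm, by = flow_bin_mm)
  kd <- classify_diameter(rings$outer_d_um, binning)
  flow_mm <- rings$flow_um / 1000
  kf <- findInterval(flow_mm, flow_breaks, rightmost.closed = FALSE)
  kf[kf > length(flow_breaks) - 1L] <- NA_integer_  # beyond ceiling
  keep <- !is.na(kd) & !is.na(kf)
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(n_drop, " ring(s) outside the diameter floor or ", max_flow_mm,
            " mm flow ceiling dropped from the 2-D histogram")
  counts <- matrix(0L, nrow = length(binning$centers),
                   ncol = length(flow_breaks) - 1L,
                   dimnames = list(binning$centers, flow_breaks[-length(flow_breaks)]))
  tab <- table(factor(kd[keep], levels = seq_along(binning$centers)),
               factor(kf[keep], levels = seq_len(ncol(counts))))
  counts[] <- as.integer(tab)
  structure(list(counts = counts, flow_breaks_mm = flow_breaks,
                 binning = binning, n_dropped = n_drop, group = group),
            class = "ring_hist2d")
}

#' Chi-squared comparison of two ring spectra
#'
#' Two-sample homogeneity chi-squared test on the 2 x K contingency table
#' of class counts, without continuity correction. Classes empty in both
#' groups are dropped first; the degrees of freedom are then K' - 1. With
#' the default 13-class binning fully occupied this gives 12 degrees of
#' freedom. Counts are pooled over animals before testing, so the test
#' treats rings, not animals, as the sampling unit.
#'
#' @param a,b `ring_spectrum` objects on the same binning, both non-empty.
#' @return List with `chi2`, `df`, `p`, `dropped_classes` (class centres
#'   empty in both groups).
#' @export
chi2_compare <- function(a, b) {
  stopifnot(inherits(a, "ring_spectrum"), inherits(b, "ring_spectrum"),
            identical(a$binning$centers, b$binning$centers),
            a$n_rings > 0, b$n_rings > 0)
  tab <- rbind(a$counts, b$counts)
  empty <- colSums(tab) == 0
  dropped <- a$binning$centers[empty]
  tab <- tab[, !empty, drop = FALSE]
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(ht$expected < 1))
    warning(sum(ht$expected < 1),
            " cell(s) with expected count < 1; statistic may be unstable",
            call. = FALSE)
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, dropped_classes = dropped)
}

#' Write a spectrum or 2-D histogram to CSV
#'
#' Spectrum CSV columns: `class_center_um, count`. 2-D histogram in long
#' form: `class_center_um, flow_bin_mm, count`.
#'
#' @param x A `ring_spectrum` or `ring_hist2d`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(x, path) {
  if (inherits(x, "ring_spectrum")) {
    tab <- data.frame(class_center_um = x$binning$centers,
                      count = unname(x$counts))
  } else if (inherits(x, "ring_hist2d")) {
    tab <- expand.grid(class_center_um = x$binning$centers,
                       flow_bin_mm = x$flow_breaks_mm[-length(x$flow_breaks_mm)])
    tab$count <- as.vector(x$counts)
  } else stop("unsupported object")
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
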