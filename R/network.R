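#' Construct a vessel segment
#'
#' A segment is one numbered, unbranched run of a traced arterial tree: an
#' ordered polyline of centerline points (proximal to distal), each carrying
#' the outer and inner (lumen) diameter read off the preparation at that
#' point. Coordinates and diameters are in micrometres, in the plane of the
#' network collage.
#'
#' @param segment_id Integer identifier, unique within a network.
#' @param parent_id Integer identifier of the parent segment, or `NA` for
#'   the root stem arising at the orifice.
#' @param points `data.frame` with numeric columns `x`, `y`, `outer_d`,
#'   `inner_d` (micrometres), at least two rows, ordered proximal to distal.
#' @return An object of class `vessel_segment`.
#' @export
vessel_segment <- function(segment_id, parent_id, points) {
  stopifnot(is.data.frame(points))
  required <- c("x", "y", "outer_d", "inner_d")
  missing_cols <- setdiff(required, names(points))
  if (length(missing_cols) > 0L) {
    stop("segment ", segment_id, ": missing point columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  points <- as.data.frame(points)[required]
  for (col in required) points[[col]] <- as.numeric(points[[col]])
  seg <- structure(
    list(segment_id = as.integer(segment_id),
         parent_id = if (is.na(parent_id)) NA_integer_ else as.integer(parent_id),
         points = points),
    class = "vessel_segment")
  validate_segment(seg)
  seg
}

validate_segment <- function(seg) {
  p <- seg$points
  id <- seg$segment_id
  if (nrow(p) < 2L)
    stop("segment ", id, ": needs at least 2 centerline points", call. = FALSE)
  if (!all(is.finite(as.matrix(p))))
    stop("segment ", id, ": non-finite point values", call. = FALSE)
  step <- sqrt(diff(p$x)^2 + diff(p$y)^2)
  if (any(step == 0))
    stop("segment ", id, ": consecutive centerline points coincide", call. = FALSE)
  if (any(p$outer_d <= 0))
    stop("segment ", id, ": nonpositive outer diameter", call. = FALSE)
  if (any(p$inner_d <= 0))
    stop("segment ", id, ": nonpositive inner diameter", call. = FALSE)
  if (any(p$inner_d >= p$outer_d))
    stop("segment ", id, ": inner diameter must be smaller than outer diameter",
         call. = FALSE)
  invisible(seg)
}

#' Assemble a coronary network from segments
#'
#' Builds and validates a rooted planar arterial tree. The network is
#' translated so that the orifice -- the first point of the single root
#' segment -- sits at the coordinate origin, matching the convention that
#' the orifice is the zero point of the measurement plane with the X axis
#' running toward the apex.
#'
#' @param segments List of [vessel_segment()] objects.
#' @param metadata Named list of free-form labels (animal id, group, ...).
#' @param diameter_cutoff Minimum outer diameter (micrometres) any traced
#'   point may have; traced preparations stop near 80 um.
#' @param attach_tol Maximum distance (micrometres) between a child's first
#'   point and the nearest point of its parent; tracing noise allowance.
#' @return An object of class `coronary_network`: a list with elements
#'   `segments` (named by id), `root_id`, and `metadata`.
#' @export
coronary_network <- function(segments, metadata = list(),
                             diameter_cutoff = 80, attach_tol = 5) {
  stopifnot(is.list(segments), length(segments) > 0L)
  ids <- vapply(segments, function(s) s$segment_id, integer(1))
  if (anyDuplicated(ids))
    stop("duplicate segment ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(segments) <- as.character(ids)
  parents <- vapply(segments, function(s) s$parent_id, integer(1))

  roots <- ids[is.na(parents)]
  if (length(roots) != 1L)
    stop("network must have exactly one root segment, found ",
         length(roots), call. = FALSE)
  orphan <- setdiff(parents[!is.na(parents)], ids)
  if (length(orphan) > 0L) {
    bad <- ids[!is.na(parents) & parents %in% orphan]
    stop("segment ", bad[1], ": parent ", parents[as.character(bad[1])],
         " does not exist", call. = FALSE)
  }

  net <- structure(
    list(segments = segments, root_id = roots, metadata = metadata),
    class = "coronary_network")

  # cycle / connectivity check: walk from root, every segment reached once
  children <- split(ids, factor(parents, levels = ids))
  reached <- integer(0)
  stack <- roots
  while (length(stack) > 0L) {
    cur <- stack[[1]]; stack <- stack[-1]
    reached <- c(reached, cur)
    stack <- c(stack, children[[as.character(cur)]])
    if (length(reached) > length(ids))
      stop("parent links contain a cycle", call. = FALSE)
  }
  if (length(reached) != length(ids)) {
    bad <- setdiff(ids, reached)
    stop("segment ", bad[1],
         ": unreachable from root (cycle or broken parent chain)",
         call. = FALSE)
  }

  # translate orifice to (0, 0)
  origin <- as.numeric(segments[[as.character(roots)]]$points[1L, c("x", "y")])
  if (any(origin != 0)) {
    net$segments <- lapply(net$segments, function(s) {
      s$points$x <- s$points$x - origin[1]
      s$points$y <- s$points$y - origin[2]
      s
    })
  }

  validate_network(net, diameter_cutoff = diameter_cutoff,
                   attach_tol = attach_tol)
  net
}

#' Validate a coronary network's structural invariants
#'
#' @param net A `coronary_network`.
#' @param diameter_cutoff,attach_tol See [coronary_network()].
#' @return The network, invisibly; errors describe the offending segment.
#' @export
validate_network <- function(net, diameter_cutoff = 80, attach_tol = 5) {
  stopifnot(inherits(net, "coronary_network"))
  for (seg in net$segments) {
    validate_segment(seg)
    if (min(seg$points$outer_d) < diameter_cutoff)
      stop("segment ", seg$segment_id, ": outer diameter below the ",
           diameter_cutoff, " um preparation cutoff", call. = FALSE)
  }
  att <- attachment_map(net)
  bad <- att$attach_dist > attach_tol
  if (any(bad))
    stop("segment ", att$segment_id[bad][1],
         ": first point is ", round(att$attach_dist[bad][1], 2),
         " um from its parent centerline (tolerance ", attach_tol, " um)",
         call. = FALSE)
  invisible(net)
}

#' @export
print.coronary_network <- function(x, ...) {
  n_pts <- sum(vapply(x$segments, function(s) nrow(s$points), integer(1)))
  total <- sum(vapply(x$segments, arc_length, numeric(1)))
  cat("<coronary_network> ", length(x$segments), " segments, ",
      n_pts, " traced points, total length ",
      format(round(total / 1000, 2)), " mm\n", sep = "")
  if (length(x$metadata) > 0)
    cat("  metadata: ",
        paste(names(x$metadata), unlist(x$metadata), sep = "=",
              collapse = ", "), "\n", sep = "")
  invisible(x)
}

# ---- geometry helpers -------------------------------------------------------

cum_arc <- function(seg) {
  p <- seg$points
  c(0, cumsum(sqrt(diff(p$x)^2 + diff(p$y)^2)))
}

#' Arc length of a segment's centerline
#'
#' Sum of Euclidean distances between consecutive traced points, in
#' micrometres.
#'
#' @param seg A `vessel_segment`.
#' @return Length in micrometres.
#' @export
arc_length <- function(seg) {
  p <- seg$points
  sum(sqrt(diff(p$x)^2 + diff(p$y)^2))
}

# Linear interpolation of all point fields at arc positions s (vectorised).
interp_at <- function(seg, s) {
  ca <- cum_arc(seg)
  p <- seg$points
  data.frame(
    x = stats::approx(ca, p$x, s, rule = 2)$y,
    y = stats::approx(ca, p$y, s, rule = 2)$y,
    outer_d = stats::approx(ca, p$outer_d, s, rule = 2)$y,
    inner_d = stats::approx(ca, p$inner_d, s, rule = 2)$y)
}

#' Local axis direction of a segment
#'
#' Unit secant vector of the centerline over the arc window
#' `[s - window/2, s + window/2]`, clipped to the segment, pointing
#' distally. Used for ring axis angles and for mother/daughter axes at
#' bifurcations; the window smooths manual-tracing jitter.
#'
#' @param seg A `vessel_segment`.
#' @param s Arc position in micrometres, `0 <= s <= arc_length(seg)`.
#' @param window Secant window in micrometres.
#' @return Numeric length-2 unit vector `(dx, dy)`.
#' @export
direction_at <- function(seg, s, window) {
  stopifnot(window > 0)
  L <- arc_length(seg)
  if (s < -1e-9 || s > L + 1e-9)
    stop("arc position ", s, " outside segment [0, ", L, "]", call. = FALSE)
  a <- max(0, s - window / 2)
  b <- min(L, s + window / 2)
  if (b - a <= 1e-12)
    stop("degenerate direction window at arc ", s, call. = FALSE)
  pa <- interp_at(seg, a)
  pb <- interp_at(seg, b)
  v <- c(pb$x - pa$x, pb$y - pa$y)
  nv <- sqrt(sum(v^2))
  if (nv == 0)
    stop("degenerate direction window at arc ", s,
         " (centerline doubles back)", call. = FALSE)
  v / nv
}

#' Child attachment positions on parent segments
#'
#' For every non-root segment, finds the parent centerline point nearest to
#' the child's first point; that point defines the attachment arc position
#' used for flow distances and bifurcation extraction.
#'
#' @param net A `coronary_network`.
#' @return `data.frame` with columns `segment_id`, `parent_id`,
#'   `attach_index` (point index on the parent), `attach_arc`
#'   (arc position, um), `attach_dist` (distance child-start to that point).
#' @export
attachment_map <- function(net) {
  rows <- lapply(net$segments, function(seg) {
    if (is.na(seg$parent_id)) return(NULL)
    par <- net$segments[[as.character(seg$parent_id)]]
    p0 <- seg$points[1L, ]
    d2 <- (par$points$x - p0$x)^2 + (par$points$y - p0$y)^2
    i <- which.min(d2)
    data.frame(segment_id = seg$segment_id, parent_id = seg$parent_id,
               attach_index = i, attach_arc = cum_arc(par)[i],
               attach_dist = sqrt(d2[i]))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(segment_id = integer(0), parent_id = integer(0),
                      attach_index = integer(0), attach_arc = numeric(0),
                      attach_dist = numeric(0))
  rownames(out) <- NULL
  out
}

# Flow distance (path length from the orifice) at each segment's first point.
# Returns a named numeric vector keyed by segment id.
flow_at_start <- function(net) {
  att <- attachment_map(net)
  flow <- stats::setNames(rep(NA_real_, length(net$segments)),
                          names(net$segments))
  flow[as.character(net$root_id)] <- 0
  pending <- att
  while (nrow(pending) > 0L) {
    ready <- !is.na(flow[as.character(pending$parent_id)])
    if (!any(ready)) stop("broken parent chain in flow computation")
    for (k in which(ready)) {
      row <- pending[k, ]
      flow[as.character(row$segment_id)] <-
        flow[[as.character(row$parent_id)]] + row$attach_arc
    }
    pending <- pending[!ready, , drop = FALSE]
  }
  flow
}

# ---- i/o --------------------------------------------------------------------

#' Read a traced network from disk
#'
#' Two dialects are supported. The native segment table is a CSV with
#' columns `segment_id, parent_id, point_index, x_um, y_um, outer_d_um,
#' inner_d_um` (header mandatory, decimal point, UTF-8). SWC morphology
#' files (7 columns: id, type, x, y, z, radius, parent) are imported with
#' the radius read as the outer radius; the lumen is then derived from a
#' linear wall model `inner_d = outer_d - 2 (a + b outer_d)` clamped to
#' stay positive. SWC `z` is ignored with a warning: the analysis plane is
#' the 2-D collage plane.
#'
#' @param path File path.
#' @param format `"segment_table"` or `"swc"`.
#' @param wall_model For SWC input, named numeric vector or list with
#'   elements `a` (um) and `b` (dimensionless).
#' @param ... Passed to [coronary_network()] (`diameter_cutoff`,
#'   `attach_tol`).
#' @return A validated `coronary_network`, orifice at (0, 0).
#' @export
read_network <- function(path, format = c("segment_table", "swc"),
                         wall_model = NULL, ...) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "segment_table") {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    required <- c("segment_id", "parent_id", "point_index",
                  "x_um", "y_um", "outer_d_um", "inner_d_um")
    missing_cols <- setdiff(required, names(tab))
    if (length(missing_cols) > 0L)
      stop("segment table missing columns: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    segs <- lapply(split(tab, tab$segment_id), function(d) {
      d <- d[order(d$point_index), ]
      vessel_segment(d$segment_id[1], d$parent_id[1],
                     data.frame(x = d$x_um, y = d$y_um,
                                outer_d = d$outer_d_um, inner_d = d$inner_d_um))
    })
    coronary_network(unname(segs), ...)
  } else {
    if (is.null(wall_model) || !all(c("a", "b") %in% names(wall_model)))
      stop("SWC import needs wall_model = c(a = <um>, b = <dimensionless>)",
           call. = FALSE)
    read_swc(path, a = wall_model[["a"]], b = wall_model[["b"]], ...)
  }
}

read_swc <- function(path, a, b, ...) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  fields <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  if (ncol(fields) != 7L)
    stop("SWC file must have 7 columns (id type x y z radius parent)",
         call. = FALSE)
  colnames(fields) <- c("id", "type", "x", "y", "z", "radius", "parent")
  swc <- as.data.frame(fields)
  if (any(swc$z != 0))
    warning("SWC z coordinates ignored: analysis is planar", call. = FALSE)
  outer_d <- 2 * swc$radius
  inner_d <- pmax(outer_d - 2 * (a + b * outer_d), 0.05 * outer_d)

  # split the SWC point chain into unbranched segments at branch points
  kids <- table(swc$parent[swc$parent != -1])
  is_branch <- stats::setNames(rep(FALSE, nrow(swc)), swc$id)
  is_branch[names(kids)[kids > 1]] <- TRUE
  idx <- stats::setNames(seq_len(nrow(swc)), swc$id)

  seg_of <- rep(NA_integer_, nrow(swc))
  seg_parent <- integer(0)
  next_seg <- 0L
  roots <- which(swc$parent == -1)
  if (length(roots) != 1L)
    stop("SWC must contain exactly one root (parent = -1)", call. = FALSE)
  # walk chains; start a new segment at the root and after every branch point
  children_of <- split(seq_len(nrow(swc)), factor(swc$parent, levels = swc$id))
  queue <- list(list(start = roots, parent_seg = NA_integer_))
  segs <- list()
  while (length(queue) > 0L) {
    job <- queue[[1]]; queue <- queue[-1]
    chain <- job$start
    repeat {
      kid <- children_of[[as.character(swc$id[chain[length(chain)]])]]
      if (is.null(kid) || length(kid) != 1L) break
      chain <- c(chain, kid)
    }
    next_seg <- next_seg + 1L
    this_id <- next_seg
    pts <- data.frame(x = swc$x[chain], y = swc$y[chain],
                      outer_d = outer_d[chain], inner_d = inner_d[chain])
    segs[[this_id]] <- vessel_segment(this_id, job$parent_seg, pts)
    tips <- children_of[[as.character(swc$id[chain[length(chain)]])]]
    for (k in tips) {
      # child chain starts at the branch point so it attaches exactly
      queue <- c(queue, list(list(start = c(chain[length(chain)], k),
                                  parent_seg = this_id)))
    }
  }
  coronary_network(segs, ...)
}

#' Write a network as a native segment table
#'
#' The native dialect round-trips exactly: `read_network(write_network(net))`
#' reproduces the network field by field.
#'
#' @param net A valid `coronary_network`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "coronary_network"))
  if (length(net$segments) == 0L) stop("nothing to write: empty network")
  rows <- lapply(net$segments, function(seg) {
    data.frame(segment_id = seg$segment_id,
               parent_id = seg$parent_id,
               point_index = seq_len(nrow(seg$points)),
               x_um = seg$points$x, y_um = seg$points$y,
               outer_d_um = seg$points$outer_d,
               inner_d_um = seg$points$inner_d)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$segment_id, tab$point_index), ]
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
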