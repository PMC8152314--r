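# Fixture builders shared across the suite. All geometry in micrometres.

# straight polyline segment between two points with n points and constant
# or linearly tapering diameters
straight_segment <- function(id, parent, from, to, n = 11,
                             outer = 300, inner = 240) {
  tt <- seq(0, 1, length.out = n)
  vessel_segment(id, parent, data.frame(
    x = from[1] + tt * (to[1] - from[1]),
    y = from[2] + tt * (to[2] - from[2]),
    outer_d = if (length(outer) == 2) outer[1] + tt * diff(outer) else outer,
    inner_d = if (length(inner) == 2) inner[1] + tt * diff(inner) else inner))
}

# root 1000 um along +X plus one child leaving its tip at +Y
two_segment_fixture <- function() {
  root <- straight_segment(1, NA, c(0, 0), c(1000, 0))
  child <- straight_segment(2, 1, c(1000, 0), c(1000, 500),
                            outer = 200, inner = 150)
  coronary_network(list(root, child))
}

# symmetric Y: mother along +X, daughters at +/- 45 degrees, Murray-exact
y_fixture <- function(theta_deg = 45) {
  th <- theta_deg * pi / 180
  r_m <- 100
  r_d <- r_m / 2^(1/3)            # symmetric Murray daughters
  mother <- straight_segment(1, NA, c(0, 0), c(400, 0), n = 9,
                             outer = 2 * r_m + 60, inner = 2 * r_m)
  d1 <- straight_segment(2, 1, c(400, 0),
                         c(400 + 400 * cos(th), 400 * sin(th)), n = 9,
                         outer = 2 * r_d + 50, inner = 2 * r_d)
  d2 <- straight_segment(3, 1, c(400, 0),
                         c(400 + 400 * cos(th), -400 * sin(th)), n = 9,
                         outer = 2 * r_d + 50, inner = 2 * r_d)
  coronary_network(list(mother, d1, d2))
}

# minimal ring table for spectrum/wall tests
ring_table_of <- function(outer_d, flow_um = rep(5000, length(outer_d)),
                          wall_um = 8 + 0.06 * outer_d) {
  data.frame(outer_d_um = outer_d, flow_um = flow_um, wall_um = wall_um)
}

# independent two-way balanced ANOVA oracle: from-scratch sums of squares
anova_by_hand <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  n <- length(y)
  cell_n <- table(a, b)
  stopifnot(length(unique(cell_n)) == 1)  # balanced only
  grand <- mean(y)
  ma <- tapply(y, a, mean); mb <- tapply(y, b, mean)
  mab <- tapply(y, interaction(a, b), mean)
  r <- cell_n[1, 1]
  ss_a <- sum(table(a) * (ma - grand)^2)
  ss_b <- sum(table(b) * (mb - grand)^2)
  ss_cells <- r * sum((mab - grand)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_e <- sum((y - ave(y, a, b))^2)
  df_a <- nlevels(a) - 1; df_b <- nlevels(b) - 1
  df_ab <- df_a * df_b
  df_e <- n - nlevels(a) * nlevels(b)
  list(F_a = (ss_a / df_a) / (ss_e / df_e),
       F_b = (ss_b / df_b) / (ss_e / df_e),
       F_ab = (ss_ab / df_ab) / (ss_e / df_e),
       df = c(df_a, df_b, df_ab, df_e))
}

# independent chi-square homogeneity oracle on a 2 x K count matrix
chisq_by_hand <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}
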