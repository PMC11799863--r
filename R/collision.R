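#' Minimum distance between two 3D segments
#'
#' Exact clamped closed-form minimum distance between the closed segments
#' `[p1, p1 + L1 d1]` and `[p2, p2 + L2 d2]`, with the arc-length
#' parameters of the closest points.  This is the geometric kernel of the
#' tunnel-convergence check (tunnels are capped cylinders around these
#' axes).
#'
#' @param p1,p2 Segment start points (3-vectors, mm).
#' @param d1,d2 Unit direction vectors.
#' @param L1,L2 Segment lengths, mm (> 0).
#' @return Named list `distance_mm`, `s1`, `s2` (closest-point parameters
#'   in mm along each segment).
#' @export
segment_distance <- function(p1, d1, L1, p2, d2, L2) {
  stopifnot(L1 > 0, L2 > 0)
  d1 <- unitize(as.numeric(d1))
  d2 <- unitize(as.numeric(d2))
  r <- as.numeric(p1) - as.numeric(p2)
  a <- L1^2
  b <- L1 * L2 * sum(d1 * d2)
  c_ <- L2^2
  d <- L1 * sum(d1 * r)
  e <- L2 * sum(d2 * r)
  denom <- a * c_ - b^2

  # closest points in normalized parameters (s, t) in [0,1]^2 of
  # f(s,t) = |r + s L1 d1 - t L2 d2|^2; standard clamped solution
  if (denom > 1e-12 * a * c_) {
    s <- (b * e - c_ * d) / denom
  } else {
    s <- 0 # parallel: pick an endpoint, then clamp t
  }
  s <- min(1, max(0, s))
  t <- if (c_ > 0) (b * s + e) / c_ else 0
  if (t < 0) {
    t <- 0
    s <- min(1, max(0, -d / a))
  } else if (t > 1) {
    t <- 1
    s <- min(1, max(0, (b - d) / a))
  }
  diff <- r + s * L1 * d1 - t * L2 * d2
  list(distance_mm = vnorm(diff), s1 = s * L1, s2 = t * L2)
}

#' Check pairwise tunnel convergence
#'
#' For every unordered pair of tunnels, computes the minimum axis distance
#' over the drilled depth and the residual bone wall thickness
#' `distance - r1 - r2`.  A pair collides when the wall is thinner than
#' `min_wall_mm` (default 0: touching counts as collision).  Pairs on
#' opposite sides of the femur are checked too -- cross-femur convergence
#' is the clinically relevant failure.
#'
#' @param tunnels List of at least two [tunnel()]s.
#' @param min_wall_mm Minimum acceptable wall thickness, mm.
#' @return Data frame with one row per pair: `ligament_a`, `ligament_b`,
#'   `min_axis_distance_mm`, `wall_thickness_mm`, `collides`, `s_a_mm`,
#'   `s_b_mm` (depth along each tunnel at closest approach).
#' @export
check_convergence <- function(tunnels, min_wall_mm = 0) {
  stopifnot(length(tunnels) >= 2)
  pairs <- combn(length(tunnels), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]
    j <- pairs[2, k]
    a <- tunnels[[i]]
    b <- tunnels[[j]]
    sd <- segment_distance(a$entry, a$direction, a$depth_mm,
                           b$entry, b$direction, b$depth_mm)
    wall <- sd$distance_mm - a$diameter_mm / 2 - b$diameter_mm / 2
    data.frame(ligament_a = a$ligament, ligament_b = b$ligament,
               min_axis_distance_mm = sd$distance_mm,
               wall_thickness_mm = wall,
               collides = wall < min_wall_mm,
               s_a_mm = sd$s1, s_b_mm = sd$s2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
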