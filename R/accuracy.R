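#' Angular deviation between planned and achieved tunnels
#'
#' The full 3D angle between the two direction vectors,
#' `acos(clamp(dot))` in degrees.  This equals the maximal angle over all
#' projection planes (attained in the plane spanned by the two vectors;
#' any other projection can only shrink it), which is the reading
#' convention used clinically.  Directions are compared signed: a drill
#' reversed 180 degrees is maximal error, not zero.
#'
#' @param planned,achieved [tunnel()]s, or unit 3-vectors.
#' @return Angle in degrees, in \[0, 180\].
#' @export
angular_deviation <- function(planned, achieved) {
  d1 <- if (inherits(planned, "tunnel")) planned$direction else
    unitize(as.numeric(planned))
  d2 <- if (inherits(achieved, "tunnel")) achieved$direction else
    unitize(as.numeric(achieved))
  rad2deg(acos(min(1, max(-1, sum(d1 * d2)))))
}

#' Entry-point distance between planned and achieved tunnels
#'
#' Euclidean distance in mm between the two entry points; the achieved
#' tunnel is expected to have been mapped into the pre-operative frame
#' first (see [evaluate_knee()]).
#'
#' @param planned,achieved [tunnel()]s, or 3-points.
#' @return Distance in mm.
#' @export
entry_distance <- function(planned, achieved) {
  e1 <- if (inherits(planned, "tunnel")) planned$entry else
    as.numeric(planned)
  e2 <- if (inherits(achieved, "tunnel")) achieved$entry else
    as.numeric(achieved)
  stopifnot(all(is.finite(e1)), all(is.finite(e2)))
  vnorm(e1 - e2)
}

#' Per-tunnel accuracy records for one knee
#'
#' Maps the achieved tunnels into the pre-operative frame through the
#' registration transform, then computes both accuracy endpoints against
#' the plan, ligament by ligament.
#'
#' @param planned,achieved Lists of [tunnel()]s aligned by ligament
#'   (achieved in post-operative coordinates).
#' @param reg A `registration_result` (post-op -> pre-op), or a
#'   [rigid_transform()]; identity if `NULL`.
#' @param group `"freehand"` or `"psi"`.
#' @param knee_id Identifier carried into the records.
#' @return Data frame with columns `knee_id`, `group`, `ligament`,
#'   `angular_deviation_deg`, `entry_distance_mm`.
#' @export
evaluate_knee <- function(planned, achieved, reg = NULL,
                          group = c("freehand", "psi"), knee_id = "knee") {
  group <- match.arg(group)
  stopifnot(length(planned) == length(achieved))
  transform <- if (is.null(reg)) rigid_identity()
  else if (inherits(reg, "registration_result")) reg$transform
  else reg
  rows <- lapply(seq_along(planned), function(i) {
    p <- planned[[i]]
    a <- achieved[[i]]
    if (!identical(p$ligament, a$ligament))
      stop("ligament mismatch at position ", i, ": planned ", p$ligament,
           " vs achieved ", a$ligament)
    a_pre <- apply_transform(transform, a)
    data.frame(knee_id = knee_id, group = group, ligament = p$ligament,
               angular_deviation_deg = angular_deviation(p, a_pre),
               entry_distance_mm = entry_distance(p, a_pre),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
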