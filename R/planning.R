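#' Tunnel angle prescription for one ligament
#'
#' Angles follow the clinical reading convention: `axial_angle_deg` is the
#' anterior deviation from the mediolateral axis seen in the axial plane,
#' `coronal_angle_deg` the proximal deviation seen in the coronal plane
#' (both positive anterior/proximal).
#'
#' @param ligament One of `"LCL"`, `"PT"`, `"MCL"`, `"POL"`.
#' @param axial_angle_deg,coronal_angle_deg Degrees, in (-90, 90).
#' @param diameter_mm,depth_mm Tunnel diameter and depth, mm (> 0).
#' @return An object of class `tunnel_spec`.
#' @export
tunnel_spec <- function(ligament, axial_angle_deg, coronal_angle_deg,
                        diameter_mm, depth_mm) {
  ligament <- match.arg(ligament, LIGAMENTS)
  stopifnot(abs(axial_angle_deg) < 90, abs(coronal_angle_deg) < 90,
            diameter_mm > 0, depth_mm > 0)
  structure(
    list(ligament = ligament, axial_angle_deg = axial_angle_deg,
         coronal_angle_deg = coronal_angle_deg, diameter_mm = diameter_mm,
         depth_mm = depth_mm),
    class = "tunnel_spec"
  )
}

#' Default and alternative tunnel prescriptions
#'
#' The default preset is the study protocol: LCL 30 degrees anterior / 0
#' coronal, PT 30/30, MCL 30/30, POL 30/30; lateral tunnels 8 mm diameter,
#' medial 7 mm, all 25 mm deep.  Two literature alternatives are shipped as
#' named presets: `"moatshe"` (LCL/PT 35 degrees anterior, MCL 40/40, POL
#' 20/20) and `"kim"` (LCL/PT 20 anterior / 10 proximal).
#'
#' @param preset `"protocol"` (the study protocol angles), `"moatshe"` or `"kim"`.
#' @return List of four [tunnel_spec()]s.
#' @export
default_tunnel_specs <- function(preset = c("protocol", "moatshe",
                                            "kim")) {
  preset <- match.arg(preset)
  ang <- switch(preset,
    "protocol" = list(LCL = c(30, 0), PT = c(30, 30), MCL = c(30, 30),
                           POL = c(30, 30)),
    "moatshe" = list(LCL = c(35, 0), PT = c(35, 0), MCL = c(40, 40),
                     POL = c(20, 20)),
    "kim" = list(LCL = c(20, 10), PT = c(20, 10), MCL = c(30, 30),
                 POL = c(30, 30))
  )
  lapply(LIGAMENTS, function(lig) {
    tunnel_spec(lig, ang[[lig]][1], ang[[lig]][2],
                diameter_mm = if (lig %in% LATERAL_LIGAMENTS) 8 else 7,
                depth_mm = 25)
  })
}

#' Dimensional parameters of the drill guides
#'
#' Descriptive constants of the patient-specific instrumentation: Kirschner
#' wire diameter, cannula clearance (cannula inner diameter = wire +
#' clearance), bone-to-guide tolerance, and mean guide thickness.
#'
#' @param kwire_diameter_mm,cannula_clearance_mm,bone_offset_mm,mean_thickness_mm
#'   Dimensions in mm.
#' @return An object of class `psi_guide_params` with derived field
#'   `cannula_inner_diameter_mm`.
#' @export
psi_guide_params <- function(kwire_diameter_mm = 2.5,
                             cannula_clearance_mm = 0.6,
                             bone_offset_mm = 0.4,
                             mean_thickness_mm = 3.3) {
  structure(
    list(kwire_diameter_mm = kwire_diameter_mm,
         cannula_clearance_mm = cannula_clearance_mm,
         bone_offset_mm = bone_offset_mm,
         mean_thickness_mm = mean_thickness_mm,
         cannula_inner_diameter_mm = kwire_diameter_mm + cannula_clearance_mm),
    class = "psi_guide_params"
  )
}

#' A planned or achieved bone tunnel
#'
#' A capped cylinder: entry point on the bone surface, unit direction into
#' the bone, diameter and depth.  The exit (bottom) point is
#' `entry + depth * direction`.
#'
#' @param entry 3-point, mm.
#' @param direction 3-vector (normalized internally; must be nonzero).
#' @param diameter_mm,depth_mm Positive dimensions, mm.
#' @param ligament Ligament label.
#' @return An object of class `tunnel`.
#' @export
tunnel <- function(entry, direction, diameter_mm, depth_mm, ligament) {
  stopifnot(diameter_mm > 0, depth_mm > 0)
  structure(
    list(entry = as.numeric(entry), direction = unitize(as.numeric(direction)),
         diameter_mm = diameter_mm, depth_mm = depth_mm,
         ligament = match.arg(ligament, LIGAMENTS)),
    class = "tunnel"
  )
}

#' @export
print.tunnel <- function(x, ...) {
  cat(sprintf(
    "%s tunnel: entry [%.1f %.1f %.1f] mm, direction [%.3f %.3f %.3f], %g mm x %g mm\n",
    x$ligament, x$entry[1], x$entry[2], x$entry[3], x$direction[1],
    x$direction[2], x$direction[3], x$diameter_mm, x$depth_mm))
  invisible(x)
}

#' Tunnel direction from axial and coronal angles
#'
#' Under the default `"projection"` convention the returned direction is
#' `normalize(ml + tan(axial) ap + tan(coronal) si)`: the unique direction
#' whose projection onto the axial plane makes `axial_deg` with ML and
#' whose projection onto the coronal plane makes `coronal_deg` with ML --
#' i.e. both angles as they would be read off axial and coronal CT slices
#' simultaneously.  The `"sequential"` convention instead rotates ML by the
#' axial angle about SI and then elevates by the coronal angle (the two
#' conventions differ by about 3 degrees at 30/30).
#'
#' @param frame An [build_frame()] anatomical frame.
#' @param axial_deg,coronal_deg Angles in degrees, each in (-90, 90).
#' @param convention `"projection"` (default) or `"sequential"`.
#' @return Unit 3-vector.
#' @export
direction_from_angles <- function(frame, axial_deg, coronal_deg,
                                  convention = c("projection", "sequential")) {
  stopifnot(inherits(frame, "anatomical_frame"),
            abs(axial_deg) < 90, abs(coronal_deg) < 90)
  convention <- match.arg(convention)
  if (convention == "projection") {
    unitize(frame$ml + tan(deg2rad(axial_deg)) * frame$ap +
              tan(deg2rad(coronal_deg)) * frame$si)
  } else {
    ax <- deg2rad(axial_deg)
    co <- deg2rad(coronal_deg)
    unitize(cos(co) * (cos(ax) * frame$ml + sin(ax) * frame$ap) +
              sin(co) * frame$si)
  }
}

#' Axial and coronal angles of a tunnel direction
#'
#' Exact inverse of [direction_from_angles()] under the projection
#' convention: `axial = atan(ap component / ml component)`, `coronal =
#' atan(si component / ml component)`.
#'
#' @param frame An anatomical frame.
#' @param direction 3-vector with positive ML component (into the bone).
#' @return Named numeric vector `c(axial_deg, coronal_deg)`.
#' @export
angles_from_direction <- function(frame, direction) {
  stopifnot(inherits(frame, "anatomical_frame"))
  d <- unitize(as.numeric(direction))
  ml_c <- sum(d * frame$ml)
  if (ml_c <= 0)
    stop("direction is not into the bone (non-positive ML component)")
  c(axial_deg = rad2deg(atan(sum(d * frame$ap) / ml_c)),
    coronal_deg = rad2deg(atan(sum(d * frame$si) / ml_c)))
}

#' Plan all tunnels of one knee
#'
#' One tunnel per prescription, entered at the ligament's footprint and
#' directed by the side-appropriate anatomical frame.
#'
#' @param model A `femur_model` (supplies footprints).
#' @param specs List of [tunnel_spec()]s; defaults to the study protocol.
#' @param frames Named list with elements `lateral` and `medial`, each an
#'   anatomical frame.
#' @param convention Angle composition convention, see
#'   [direction_from_angles()].
#' @return List of [tunnel()]s, one per spec.
#' @export
plan_knee <- function(model, specs = default_tunnel_specs(), frames,
                      convention = c("projection", "sequential")) {
  convention <- match.arg(convention)
  stopifnot(inherits(model, "femur_model"),
            all(c("lateral", "medial") %in% names(frames)))
  lapply(specs, function(sp) {
    fp <- model$footprints[[sp$ligament]]
    if (is.null(fp))
      stop("no footprint for ligament '", sp$ligament, "'")
    frame <- frames[[if (sp$ligament %in% LATERAL_LIGAMENTS) "lateral"
                     else "medial"]]
    tunnel(entry = fp,
           direction = direction_from_angles(frame, sp$axial_angle_deg,
                                             sp$coronal_angle_deg,
                                             convention = convention),
           diameter_mm = sp$diameter_mm, depth_mm = sp$depth_mm,
           ligament = sp$ligament)
  })
}

#' Build both per-side frames for a femur model
#'
#' @param model A `femur_model`.
#' @param knee_side `"right"` or `"left"`.
#' @return Named list `list(lateral = , medial = )` of anatomical frames.
#' @export
knee_frames <- function(model, knee_side = "right") {
  list(lateral = build_frame(model$landmarks, "lateral", knee_side),
       medial = build_frame(model$landmarks, "medial", knee_side))
}

#' Serialize a tunnel plan to JSON
#'
#' @param tunnels List of [tunnel()]s.
#' @param path Output path.
#' @export
write_plan <- function(tunnels, path) {
  jsonlite::write_json(
    lapply(tunnels, function(tn)
      list(ligament = tn$ligament, entry = tn$entry,
           direction = tn$direction, diameter_mm = tn$diameter_mm,
           depth_mm = tn$depth_mm)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a tunnel plan from JSON
#'
#' @param path Path written by [write_plan()].
#' @return List of [tunnel()]s.
#' @export
read_plan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(obj)), function(i)
    tunnel(unlist(obj$entry[i]), unlist(obj$direction[i]),
           obj$diameter_mm[i], obj$depth_mm[i], obj$ligament[i]))
}
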