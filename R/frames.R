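#' Landmark set for anatomical frame construction
#'
#' Bundles the five bony landmarks from which a per-knee anatomical
#' coordinate system is built: both epicondyles, two points on the femoral
#' shaft axis, and the most anterior point of the trochlea.  All coordinates
#' are in millimetres, in the same frame as the bone mesh they annotate.
#'
#' @param medial_epicondyle,lateral_epicondyle 3-vectors, mm.
#' @param shaft_axis_point_distal,shaft_axis_point_proximal 3-vectors on the
#'   diaphyseal axis; proximal minus distal defines the superior direction.
#' @param most_anterior_trochlea 3-vector; disambiguates the anterior sense.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(medial_epicondyle, lateral_epicondyle,
                         shaft_axis_point_distal, shaft_axis_point_proximal,
                         most_anterior_trochlea) {
  lm <- list(
    medial_epicondyle = as.numeric(medial_epicondyle),
    lateral_epicondyle = as.numeric(lateral_epicondyle),
    shaft_axis_point_distal = as.numeric(shaft_axis_point_distal),
    shaft_axis_point_proximal = as.numeric(shaft_axis_point_proximal),
    most_anterior_trochlea = as.numeric(most_anterior_trochlea)
  )
  for (nm in names(lm)) {
    if (length(lm[[nm]]) != 3L || any(!is.finite(lm[[nm]])))
      stop("landmark '", nm, "' must be a finite 3-vector")
  }
  if (vnorm(lm$medial_epicondyle - lm$lateral_epicondyle) <= 0)
    stop("epicondyles must be distinct")
  if (vnorm(lm$shaft_axis_point_proximal - lm$shaft_axis_point_distal) <= 0)
    stop("shaft axis points must be distinct")
  structure(lm, class = "landmark_set")
}

#' Build a per-knee anatomical coordinate frame
#'
#' Constructs the orthonormal mediolateral (ML) / anteroposterior (AP) /
#' superoinferior (SI) triad that defines the axial plane (ML-AP) and
#' coronal plane (ML-SI) in which tunnel angulations are prescribed.
#'
#' The SI axis is the normalized shaft direction (proximal minus distal);
#' the ML axis is the inter-epicondylar direction orthogonalized against SI
#' (Gram-Schmidt) and sign-flipped so it points *across the femur away from
#' the entry side* (medially for a lateral-side frame, laterally for a
#' medial-side frame); the AP axis completes the triad with its sign chosen
#' so the anterior trochlea landmark has a positive AP coordinate.  The
#' origin is the entry-side epicondyle.  One angle convention ("anterior",
#' "proximal" positive) thereby serves both sides.
#'
#' @param landmarks A [landmark_set()].
#' @param side `"lateral"` or `"medial"`: the tunnel entry side the frame
#'   serves.
#' @param knee_side `"right"` or `"left"` (metadata; left knees are handled
#'   by mirroring landmarks, see [mirror_landmarks()]).
#' @return An object of class `anatomical_frame` with fields `origin`,
#'   `ml`, `ap`, `si`, `side`, `knee_side`.
#' @export
build_frame <- function(landmarks, side = c("lateral", "medial"),
                        knee_side = c("right", "left")) {
  stopifnot(inherits(landmarks, "landmark_set"))
  side <- match.arg(side)
  knee_side <- match.arg(knee_side)

  si <- unitize(landmarks$shaft_axis_point_proximal -
                  landmarks$shaft_axis_point_distal)
  inter_epi <- landmarks$medial_epicondyle - landmarks$lateral_epicondyle
  ml_raw <- inter_epi - sum(inter_epi * si) * si
  if (vnorm(ml_raw) < 1e-6 * vnorm(inter_epi))
    stop("degenerate geometry: epicondylar axis is parallel to the shaft axis")
  ml <- unitize(ml_raw)
  # ml must point away from the entry side, i.e. towards the medial
  # epicondyle for a lateral frame and vice versa
  if (side == "medial") ml <- -ml
  origin <- if (side == "lateral") landmarks$lateral_epicondyle else
    landmarks$medial_epicondyle

  ap <- cross3(si, ml)
  if (sum(ap * (landmarks$most_anterior_trochlea - origin)) < 0) ap <- -ap

  structure(
    list(origin = origin, ml = ml, ap = ap, si = si,
         side = side, knee_side = knee_side),
    class = "anatomical_frame"
  )
}

#' Mirror a landmark set across the sagittal plane
#'
#' Reflects all landmarks across the plane through the inter-epicondylar
#' midpoint whose normal is the shaft-orthogonalized inter-epicondylar
#' direction.  Used to map a right-knee configuration to the equivalent
#' left knee (and back); planned tunnel angles are invariant under this
#' operation.
#'
#' @param landmarks A [landmark_set()].
#' @return A mirrored `landmark_set`.
#' @export
mirror_landmarks <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  si <- unitize(landmarks$shaft_axis_point_proximal -
                  landmarks$shaft_axis_point_distal)
  inter_epi <- landmarks$medial_epicondyle - landmarks$lateral_epicondyle
  n <- unitize(inter_epi - sum(inter_epi * si) * si)
  mid <- (landmarks$medial_epicondyle + landmarks$lateral_epicondyle) / 2
  refl <- function(p) p - 2 * sum((p - mid) * n) * n
  landmark_set(
    medial_epicondyle = refl(landmarks$medial_epicondyle),
    lateral_epicondyle = refl(landmarks$lateral_epicondyle),
    shaft_axis_point_distal = refl(landmarks$shaft_axis_point_distal),
    shaft_axis_point_proximal = refl(landmarks$shaft_axis_point_proximal),
    most_anterior_trochlea = refl(landmarks$most_anterior_trochlea)
  )
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat("Anatomical frame (", x$side, " side, ", x$knee_side, " knee)\n",
      sep = "")
  cat(sprintf("  origin: [%7.2f %7.2f %7.2f] mm\n", x$origin[1], x$origin[2],
              x$origin[3]))
  for (ax in c("ml", "ap", "si"))
    cat(sprintf("  %s axis: [%7.4f %7.4f %7.4f]\n", ax, x[[ax]][1],
                x[[ax]][2], x[[ax]][3]))
  invisible(x)
}

frame_axis_matrix <- function(frame) cbind(frame$ml, frame$ap, frame$si)

#' Read landmarks and footprints from a JSON sidecar
#'
#' The sidecar convention stores, next to each STL, a JSON object with one
#' 3-vector (mm, mesh coordinates) per landmark and per ligament footprint.
#'
#' @param path Path to the JSON file.
#' @return A list with elements `landmarks` ([landmark_set()]) and
#'   `footprints` (named list of 3-vectors).
#' @export
read_sidecar <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lm_names <- c("medial_epicondyle", "lateral_epicondyle",
                "shaft_axis_point_distal", "shaft_axis_point_proximal",
                "most_anterior_trochlea")
  landmarks <- do.call(landmark_set, lapply(lm_names, function(n) obj[[n]]))
  fp <- obj$footprints
  footprints <- lapply(fp, as.numeric)
  list(landmarks = landmarks, footprints = footprints)
}

#' Write landmarks and footprints to a JSON sidecar
#'
#' @param landmarks A [landmark_set()].
#' @param footprints Named list of 3-vectors (mm).
#' @param path Output path.
#' @export
write_sidecar <- function(landmarks, footprints, path) {
  obj <- c(unclass(landmarks), list(footprints = footprints))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
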