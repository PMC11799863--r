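# Synthetic distal femur: a smooth union of two condylar ellipsoids and a
# capped shaft cylinder, polygonized from its implicit field.  Canonical
# pose is a right knee: +x lateral, +y anterior, +z proximal, origin near
# the inter-condylar center, units mm.

#' Default shape parameters of the synthetic distal femur
#'
#' All values are mm in the canonical right-knee pose.  The defaults give an
#' epicondylar width of about 82 mm (adult range) with the popliteal tendon
#' footprint about 14 mm antero-distal to the LCL footprint and the POL
#' footprint postero-proximal to the MCL footprint, consistent with
#' published attachment anatomy.
#'
#' @return Named list of shape parameters.
#' @export
femur_shape_defaults <- function() {
  list(
    lat_condyle_center = c(20, -4, 6),
    lat_condyle_semi   = c(20, 26, 20),
    med_condyle_center = c(-21, -4, 6),
    med_condyle_semi   = c(21, 27, 21),
    shaft_center_xy    = c(0, 3),
    shaft_radius       = 15,
    shaft_z            = c(18, 85),
    blend_mm           = 4,
    jitter_frac        = 0.03,
    # seed points (projected onto the surface) for footprints and landmarks
    footprint_seeds = list(
      LCL = c(41, -7, 8),
      PT  = c(41, 8, -12),
      MCL = c(-43, -4, 6),
      POL = c(-43, -12, 14)
    ),
    landmark_seeds = list(
      lateral_epicondyle = c(42, -4, 6),
      medial_epicondyle = c(-44, -4, 6),
      most_anterior_trochlea = c(0, 26, 2)
    ),
    shaft_axis_z = c(30, 80)
  )
}

# quasi-signed-distance of an axis-aligned ellipsoid (scaled implicit)
ellipsoid_field <- function(P, center, semi) {
  q <- sweep(sweep(P, 2, center, "-"), 2, semi, "/")
  (sqrt(rowSums(q^2)) - 1) * min(semi)
}

# exact SDF of a z-aligned capped cylinder
capped_cylinder_field <- function(P, center_xy, radius, z_range) {
  dr <- sqrt((P[, 1] - center_xy[1])^2 + (P[, 2] - center_xy[2])^2) - radius
  dz <- pmax(z_range[1] - P[, 3], P[, 3] - z_range[2])
  inside <- pmin(pmax(dr, dz), 0)
  outside <- sqrt(pmax(dr, 0)^2 + pmax(dz, 0)^2)
  inside + outside
}

femur_field <- function(P, shape) {
  f1 <- ellipsoid_field(P, shape$lat_condyle_center, shape$lat_condyle_semi)
  f2 <- ellipsoid_field(P, shape$med_condyle_center, shape$med_condyle_semi)
  f3 <- capped_cylinder_field(P, shape$shaft_center_xy, shape$shaft_radius,
                              shape$shaft_z)
  k <- shape$blend_mm
  # smooth union (log-sum-exp); clamp exponents for numerical safety
  m <- pmin(f1, pmin(f2, f3))
  -k * log(exp(-(f1 - m) / k) + exp(-(f2 - m) / k) + exp(-(f3 - m) / k)) + m
}

#' Generate a synthetic distal femur with ligament footprints
#'
#' Polygonizes the implicit femur field on a regular grid (marching
#' tetrahedra), yielding a watertight triangle mesh, then projects ligament
#' footprints (LCL, PT, MCL, POL) and frame landmarks onto the surface.
#' Per-specimen shape variability is a small seeded jitter (default +/-3%)
#' of the condyle/shaft dimensions, applied before the global size scale so
#' that `size_scale` rescales a given specimen exactly.
#'
#' @param size_scale Global similarity scale (1 = average adult knee).
#' @param seed Integer seed controlling the shape jitter (deterministic).
#' @param resolution_mm Polygonization grid spacing; smaller is finer.
#' @param shape Shape parameter list, see [femur_shape_defaults()].
#' @return An object of class `femur_model`: fields `mesh` ([trimesh()]),
#'   `footprints` (named list of on-surface 3-points), `landmarks`
#'   ([landmark_set()]), `size_scale`.
#' @export
generate_femur <- function(size_scale = 1.0, seed = 1L, resolution_mm = 3,
                           shape = femur_shape_defaults()) {
  stopifnot(size_scale > 0, resolution_mm > 0)
  set.seed(as.integer(seed))
  jf <- shape$jitter_frac
  jit <- function(x) x * (1 + runif(length(x), -jf, jf))
  shape$lat_condyle_semi <- jit(shape$lat_condyle_semi)
  shape$med_condyle_semi <- jit(shape$med_condyle_semi)
  shape$shaft_radius <- jit(shape$shaft_radius)

  lo <- c(-(abs(shape$med_condyle_center[1]) + max(shape$med_condyle_semi)),
          min(shape$lat_condyle_center[2] - shape$lat_condyle_semi[2],
              shape$med_condyle_center[2] - shape$med_condyle_semi[2]),
          min(shape$lat_condyle_center[3] - shape$lat_condyle_semi[3],
              shape$med_condyle_center[3] - shape$med_condyle_semi[3]))
  hi <- c(shape$lat_condyle_center[1] + max(shape$lat_condyle_semi),
          max(shape$lat_condyle_center[2] + shape$lat_condyle_semi[2],
              shape$shaft_center_xy[2] + shape$shaft_radius),
          shape$shaft_z[2])
  lo <- lo - 3 * resolution_mm
  hi <- hi + 3 * resolution_mm
  xs <- seq(lo[1], hi[1], by = resolution_mm)
  ys <- seq(lo[2], hi[2], by = resolution_mm)
  zs <- seq(lo[3], hi[3], by = resolution_mm)
  grid <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  f <- femur_field(grid, shape)
  f[abs(f) < 1e-9] <- 1e-9  # avoid exact-zero grid values (degenerate tets)

  poly <- marching_tetrahedra_cpp(f, xs, ys, zs)
  mesh <- trimesh(poly$vertices, poly$faces)
  if (!mesh_is_closed(mesh))
    stop("polygonization produced a non-watertight mesh (",
         nrow(mesh$vertices), " vertices); the isosurface may intersect ",
         "the grid boundary")

  proj <- function(p) as.numeric(mesh_closest_points(p, mesh)$points)
  footprints <- lapply(shape$footprint_seeds, proj)
  lmk <- shape$landmark_seeds
  landmarks <- landmark_set(
    medial_epicondyle = proj(lmk$medial_epicondyle),
    lateral_epicondyle = proj(lmk$lateral_epicondyle),
    shaft_axis_point_distal = c(shape$shaft_center_xy, shape$shaft_axis_z[1]),
    shaft_axis_point_proximal = c(shape$shaft_center_xy, shape$shaft_axis_z[2]),
    most_anterior_trochlea = proj(lmk$most_anterior_trochlea)
  )

  if (size_scale != 1) {
    mesh$vertices <- mesh$vertices * size_scale
    footprints <- lapply(footprints, function(p) p * size_scale)
    landmarks <- landmark_set(
      medial_epicondyle = landmarks$medial_epicondyle * size_scale,
      lateral_epicondyle = landmarks$lateral_epicondyle * size_scale,
      shaft_axis_point_distal = landmarks$shaft_axis_point_distal * size_scale,
      shaft_axis_point_proximal =
        landmarks$shaft_axis_point_proximal * size_scale,
      most_anterior_trochlea = landmarks$most_anterior_trochlea * size_scale
    )
  }

  structure(
    list(mesh = mesh, footprints = footprints, landmarks = landmarks,
         size_scale = size_scale, resolution_mm = resolution_mm),
    class = "femur_model"
  )
}

#' @export
print.femur_model <- function(x, ...) {
  w <- vnorm(x$landmarks$lateral_epicondyle - x$landmarks$medial_epicondyle)
  cat("Synthetic distal femur: ", nrow(x$mesh$vertices), " vertices, ",
      nrow(x$mesh$faces), " faces; epicondylar width ",
      sprintf("%.1f", w), " mm\n", sep = "")
  invisible(x)
}

#' Epicondylar width of a femur model
#'
#' @param model A `femur_model`.
#' @return Distance in mm between the epicondyle landmarks.
#' @export
epicondylar_width <- function(model) {
  vnorm(model$landmarks$lateral_epicondyle - model$landmarks$medial_epicondyle)
}

#' Manufacture the "post-operative" counterpart of a femur
#'
#' Applies a rigid transform to the mesh (emulating the repositioned
#' post-operative CT), optionally perturbs vertices with isotropic Gaussian
#' noise (segmentation/surface error), and carries the achieved tunnels
#' through the same rigid transform (tunnels are not noised: they are
#' geometric annotations, not surface estimates).  Footprints and landmarks
#' are rigidly transformed and not noised, so their distance to the
#' noiseless surface is invariant.
#'
#' @param model A `femur_model` (pre-operative).
#' @param tunnels List of achieved [tunnel()]s in pre-operative coordinates
#'   (may be empty).
#' @param transform A [rigid_transform()].
#' @param noise_sd Isotropic per-coordinate Gaussian vertex noise, mm
#'   (>= 0).
#' @param seed Integer seed for the noise.
#' @return List with `model` (displaced `femur_model`) and `tunnels`
#'   (achieved tunnels in displaced coordinates).
#' @export
make_postop <- function(model, tunnels = list(), transform = rigid_identity(),
                        noise_sd = 0, seed = 1L) {
  stopifnot(inherits(model, "femur_model"), noise_sd >= 0)
  mesh2 <- apply_transform(transform, model$mesh)
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    mesh2$vertices <- mesh2$vertices +
      matrix(rnorm(length(mesh2$vertices), sd = noise_sd),
             ncol = 3)
  }
  out <- model
  out$mesh <- mesh2
  out$footprints <- lapply(model$footprints,
                           function(p) apply_transform(transform, p))
  lm <- lapply(unclass(model$landmarks),
               function(p) apply_transform(transform, p))
  out$landmarks <- do.call(landmark_set, lm)
  list(model = out,
       tunnels = lapply(tunnels, function(tn) apply_transform(transform, tn)))
}

#' Write a femur model as STL plus JSON sidecar
#'
#' @param model A `femur_model`.
#' @param stl_path Path for the STL file; the sidecar is written next to it
#'   with extension `.json`.
#' @param binary Binary STL (default) or ASCII.
#' @export
write_femur <- function(model, stl_path, binary = TRUE) {
  write_stl(model$mesh, stl_path, binary = binary)
  write_sidecar(model$landmarks, model$footprints,
                sub("\\.stl$", ".json", stl_path, ignore.case = TRUE))
  invisible(stl_path)
}

#' Read a femur model from STL plus JSON sidecar
#'
#' @param stl_path Path to the STL file (sidecar expected next to it).
#' @return A `femur_model`.
#' @export
read_femur <- function(stl_path) {
  mesh <- read_stl(stl_path)
  sc <- read_sidecar(sub("\\.stl$", ".json", stl_path, ignore.case = TRUE))
  structure(
    list(mesh = mesh, footprints = sc$footprints, landmarks = sc$landmarks,
         size_scale = NA_real_, resolution_mm = NA_real_),
    class = "femur_model"
  )
}
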