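#' Rigid transform (rotation + translation)
#'
#' @param rotation 3x3 rotation matrix (orthonormal, det +1).
#' @param translation 3-vector, mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6)
    stop("rotation must be orthonormal with determinant +1")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
rigid_identity <- function() rigid_transform()

#' Rotation about an axis
#'
#' @param axis 3-vector (normalized internally).
#' @param angle_deg Rotation angle, degrees (right-hand rule).
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- unitize(axis)
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Compose two rigid transforms
#'
#' `compose_transform(t2, t1)` is the transform that first applies `t1`,
#' then `t2`.
#'
#' @param t2,t1 [rigid_transform()]s.
#' @return A [rigid_transform()].
#' @export
compose_transform <- function(t2, t1) {
  rigid_transform(t2$rotation %*% t1$rotation,
                  as.numeric(t2$rotation %*% t1$translation) + t2$translation)
}

#' Invert a rigid transform
#'
#' @param transform A [rigid_transform()].
#' @return A [rigid_transform()].
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

#' Rotation angle of a rigid transform
#'
#' @param transform A [rigid_transform()].
#' @return Angle in degrees of the rotation component.
#' @export
rotation_angle_deg <- function(transform) {
  tr <- sum(diag(transform$rotation))
  rad2deg(acos(min(1, max(-1, (tr - 1) / 2))))
}

#' Apply a rigid transform
#'
#' Generic rigid action: points are rotated and translated; tunnels have
#' their entry transformed and direction rotated (diameter and depth are
#' invariant); meshes and femur models transform all their geometry.
#'
#' @param transform A [rigid_transform()].
#' @param x A 3-vector, n x 3 matrix, [tunnel()], or [trimesh()].
#' @return The transformed object, same type as `x`.
#' @export
apply_transform <- function(transform, x) UseMethod("apply_transform", x)

#' @export
apply_transform.default <- function(transform, x) {
  if (is.matrix(x)) {
    sweep(x %*% t(transform$rotation), 2, transform$translation, "+")
  } else {
    as.numeric(transform$rotation %*% as.numeric(x)) + transform$translation
  }
}

#' @export
apply_transform.tunnel <- function(transform, x) {
  x$entry <- apply_transform.default(transform, x$entry)
  x$direction <- as.numeric(transform$rotation %*% x$direction)
  x
}

#' @export
apply_transform.trimesh <- function(transform, x) {
  x$vertices <- apply_transform.default(transform, x$vertices)
  x
}

#' Least-squares rigid fit of paired point sets (Kabsch/SVD)
#'
#' Finds the rigid transform minimizing `sum ||R a_i + t - b_i||^2`, with
#' reflection correction so the result is a proper rotation.
#'
#' @param points_a,points_b n x 3 matrices of paired points (n >= 3,
#'   non-collinear).
#' @return A [rigid_transform()] mapping `points_a` onto `points_b`.
#' @export
best_rigid <- function(points_a, points_b) {
  A <- as.matrix(points_a)
  B <- as.matrix(points_b)
  stopifnot(nrow(A) == nrow(B), ncol(A) == 3, nrow(A) >= 3)
  ca <- colMeans(A)
  cb <- colMeans(B)
  Ac <- sweep(A, 2, ca)
  Bc <- sweep(B, 2, cb)
  H <- crossprod(Ac, Bc)
  s <- svd(H)
  if (s$d[2] < 1e-9 * max(s$d[1], 1e-300))
    stop("degenerate (collinear) point configuration")
  D <- diag(c(1, 1, sign(det(s$v %*% t(s$u)))))
  R <- s$v %*% D %*% t(s$u)
  rigid_transform(R, cb - as.numeric(R %*% ca))
}

# principal-axes + centroid initialization: among the four proper-rotation
# sign assignments of the PCA axes, keep the one with the smallest sampled
# closest-point distance
icp_init <- function(src_pts, target_mesh, n_probe = 200L) {
  pa <- prcomp(src_pts, center = TRUE)$rotation
  tv <- target_mesh$vertices
  pb <- prcomp(tv, center = TRUE)$rotation
  if (det(pa) < 0) pa[, 3] <- -pa[, 3]
  if (det(pb) < 0) pb[, 3] <- -pb[, 3]
  ca <- colMeans(src_pts)
  cb <- colMeans(tv)
  probe <- src_pts[seq(1, nrow(src_pts),
                       length.out = min(n_probe, nrow(src_pts))), ,
                   drop = FALSE]
  best <- NULL
  best_d <- Inf
  for (sgn in list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) {
    S <- diag(c(sgn, prod(sgn)))
    R <- pb %*% S %*% t(pa)
    cand <- rigid_transform(R, cb - as.numeric(R %*% ca))
    d <- mean(mesh_closest_points(apply_transform(cand, probe),
                                  target_mesh)$distance)
    if (d < best_d) {
      best_d <- d
      best <- cand
    }
  }
  best
}

#' Iterative closest point registration of two meshes
#'
#' Rigidly registers `source_mesh` onto `target_mesh` by alternating
#' vertex-to-surface nearest-point correspondence with the least-squares
#' rigid fit ([best_rigid()]).  Source vertices are subsampled for
#' desk-scale runtime.  Iteration stops when the mean closest-point
#' distance improves by less than `tol_mm` or after `max_iter` iterations.
#'
#' @param source_mesh,target_mesh [trimesh()] objects.
#' @param init Initial [rigid_transform()], or `NULL` for principal-axes +
#'   centroid initialization.
#' @param max_iter Iteration cap.
#' @param tol_mm Convergence threshold on the mean-distance improvement.
#' @param n_sample Maximum number of source vertices used (<= 5000).
#' @return An object of class `registration_result`: `transform`
#'   (source -> target), `mean_distance_mm`, `iterations`, `converged`,
#'   `trace` (mean distance per iteration).
#' @export
icp <- function(source_mesh, target_mesh, init = NULL, max_iter = 100L,
                tol_mm = 1e-4, n_sample = 2000L) {
  stopifnot(inherits(source_mesh, "trimesh"), inherits(target_mesh, "trimesh"),
            nrow(source_mesh$vertices) > 0, nrow(target_mesh$vertices) > 0)
  n_sample <- min(n_sample, 5000L, nrow(source_mesh$vertices))
  pick <- unique(round(seq(1, nrow(source_mesh$vertices),
                           length.out = n_sample)))
  src <- source_mesh$vertices[pick, , drop = FALSE]

  transform <- if (is.null(init)) icp_init(src, target_mesh) else init
  trace <- numeric(0)
  prev <- Inf
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    moved <- apply_transform(transform, src)
    cp <- mesh_closest_points(moved, target_mesh)
    mean_d <- mean(cp$distance)
    trace <- c(trace, mean_d)
    if (mean_d < .Machine$double.eps^0.5 || prev - mean_d < tol_mm) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
    prev <- mean_d
    step <- best_rigid(moved, cp$points)
    transform <- compose_transform(step, transform)
  }
  if (!converged)
    warning("ICP did not converge within ", max_iter, " iterations ",
            "(last mean distance ", signif(trace[length(trace)], 4), " mm)")
  structure(
    list(transform = transform, mean_distance_mm = trace[length(trace)],
         iterations = it, converged = converged, trace = trace),
    class = "registration_result"
  )
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(
    "ICP registration: mean closest-point distance %.4g mm after %d iteration%s (%s)\n",
    x$mean_distance_mm, x$iterations, if (x$iterations == 1) "" else "s",
    if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Serialize a rigid transform as a 4x4 homogeneous matrix
#'
#' @param transform A [rigid_transform()].
#' @return 4x4 numeric matrix.
#' @export
as_homogeneous <- function(transform) {
  rbind(cbind(transform$rotation, transform$translation), c(0, 0, 0, 1))
}
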