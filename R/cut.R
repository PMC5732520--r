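# Plane clipping of a closed triangle surface with cap triangulation, and
# the stance-configuration specimen cut.

#' Rotation matrix about an arbitrary axis
#' @param axis Length-3 axis (normalised internally).
#' @param angle_deg Rotation angle in degrees (right-hand rule).
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- as.numeric(axis)
  u <- u / sqrt(sum(u^2))
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  ct * diag(3) + st * ux + (1 - ct) * (u %o% u)
}

# rotation taking unit vector a onto unit vector b
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2)); cc <- sum(a * b)
  if (s < 1e-12) {
    if (cc > 0) return(diag(3))
    # opposite: rotate pi about any perpendicular axis
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- c(a[2] * p[3] - a[3] * p[2], a[3] * p[1] - a[1] * p[3],
           a[1] * p[2] - a[2] * p[1])
    return(rotation_about_axis(v, 180))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - cc) / s^2)
}

#' Clip a closed surface by a plane
#'
#' Keeps the half-space `dot(x - point, normal) <= 0`, splits crossing
#' triangles, and closes the cut cross-section with a triangle fan about its
#' centroid (exact for star-shaped sections, which all pipeline geometries
#' produce).
#'
#' @param s A closed [surface()].
#' @param point Point on the plane (mm).
#' @param normal Plane normal; the positive side is removed.
#' @param cap Close the cut face (default `TRUE`).
#' @return A [surface()].
#' @export
clip_surface <- function(s, point, normal, cap = TRUE) {
  point <- as.numeric(point)
  normal <- as.numeric(normal)
  normal <- normal / sqrt(sum(normal^2))
  g <- as.vector(sweep(s$vertices, 2, point, "-") %*% normal)
  scale <- max(abs(g), 1)
  tol <- 1e-9 * scale
  g[abs(g) < tol] <- 0
  tg <- matrix(g[s$triangles], ncol = 3)
  keep_all <- rowSums(tg <= 0) == 3L
  drop_all <- rowSums(tg >= 0) == 3L & !keep_all
  mixed <- which(!keep_all & !drop_all)
  if (!any(g < 0)) stop("plane removes the entire surface", call. = FALSE)
  if (!any(g > 0) || (length(mixed) == 0L && all(keep_all))) {
    return(s) # plane misses the surface on the kept side
  }
  if (length(mixed) == 0L && !any(keep_all)) {
    stop("plane does not intersect the surface", call. = FALSE)
  }

  verts <- s$vertices
  new_tris <- list(s$triangles[keep_all, , drop = FALSE])
  edge_cache <- new.env(hash = TRUE)
  n_orig <- nrow(verts)
  extra <- list()

  edge_point <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    idx <- edge_cache[[key]]
    if (is.null(idx)) {
      t <- g[i] / (g[i] - g[j])
      extra[[length(extra) + 1L]] <<- verts[i, ] + t * (verts[j, ] - verts[i, ])
      idx <- n_orig + length(extra)
      edge_cache[[key]] <- idx
    }
    idx
  }

  for (t in mixed) {
    tri <- s$triangles[t, ]
    gv <- g[tri]
    # Sutherland-Hodgman against the half-space g <= 0
    poly <- integer(0)
    for (e in 1:3) {
      i <- tri[e]; j <- tri[if (e == 3) 1 else e + 1]
      gi <- gv[e]; gj <- gv[if (e == 3) 1 else e + 1]
      if (gi <= 0) poly <- c(poly, i)
      if ((gi < 0 && gj > 0) || (gi > 0 && gj < 0)) {
        poly <- c(poly, edge_point(i, j))
      }
    }
    np <- length(poly)
    if (np < 3L) next
    for (k in 2:(np - 1L)) {
      new_tris[[length(new_tris) + 1L]] <- matrix(
        c(poly[1], poly[k], poly[k + 1L]), 1, 3
      )
    }
  }
  if (length(extra)) verts <- rbind(verts, do.call(rbind, extra))
  tris <- do.call(rbind, new_tris)

  if (cap) {
    # open boundary of the kept set = the cut loop, directed per surface
    # orientation; fan the reversed edges from the loop centroid
    from <- c(tris[, 1], tris[, 2], tris[, 3])
    to <- c(tris[, 2], tris[, 3], tris[, 1])
    dk <- from * 2^26 + to
    rk <- to * 2^26 + from
    open <- is.na(match(rk, dk))
    if (any(open)) {
      ce <- cbind(from[open], to[open])
      centroid <- colMeans(verts[unique(as.vector(ce)), , drop = FALSE])
      verts <- rbind(verts, centroid)
      cidx <- nrow(verts)
      tris <- rbind(tris, cbind(cidx, ce[, 2], ce[, 1]))
    }
  }
  compact_surface(verts, matrix(as.integer(tris), ncol = 3))
}

#' Cut the specimen and orient it for stance loading
#'
#' Applies the specimen cut: a plane `cut_distance` mm from the
#' greater-trochanter-tip landmark along the shaft axis, tilted
#' `coronal_slope_deg` in the coronal (x-z) plane, with the cut face closed.
#' The result is then rigidly moved so the cut-face normal points along
#' global -z and the cut plane sits at z = 0: the applied load acts along
#' -z (vertical) and the shaft axis makes `coronal_slope_deg` with the
#' vertical, the stance configuration.
#'
#' @param s A closed [surface()] in world mm.
#' @param landmark_gt_tip Greater-trochanter-tip analog landmark (mm).
#' @param shaft_axis Unit vector along the shaft, pointing distally.
#' @param cut_distance Distance from landmark to cut plane (mm, default
#'   120).
#' @param coronal_slope_deg Cut-plane tilt in the coronal plane (degrees,
#'   default 20). The coronal plane is the plane orthogonal to
#'   `anterior_axis`.
#' @param anterior_axis The specimen's anterior direction (default world
#'   `c(0, 1, 0)`); tilting happens about this axis so the slope stays in
#'   the specimen's coronal plane whatever its pose in the scanner.
#' @return A closed [surface()] with attributes `landmark` (transformed
#'   landmark) and `shaft_axis` (transformed axis).
#' @export
cut_and_orient <- function(s, landmark_gt_tip, shaft_axis,
                           cut_distance = 120, coronal_slope_deg = 20,
                           anterior_axis = c(0, 1, 0)) {
  landmark <- as.numeric(landmark_gt_tip)
  ax <- as.numeric(shaft_axis)
  ax <- ax / sqrt(sum(ax^2))
  anterior <- as.numeric(anterior_axis)
  anterior <- anterior / sqrt(sum(anterior^2))
  p <- landmark + cut_distance * ax
  # tilt the cut normal in the coronal plane (about the anterior axis)
  n_cut <- as.vector(rotation_about_axis(anterior, coronal_slope_deg) %*% ax)
  span <- range(sweep(s$vertices, 2, p, "-") %*% n_cut)
  if (span[1] >= 0 || span[2] <= 0) {
    stop("cut plane does not intersect the surface", call. = FALSE)
  }
  clipped <- clip_surface(s, p, n_cut, cap = TRUE)
  # orient: cut normal -> -z, cut plane -> z = 0; then pin the remaining
  # spin about z so the shaft axis lies in the coronal (x-z) plane with
  # positive x - the orientation is then canonical for any input frame
  rot <- rotation_between(n_cut, c(0, 0, -1))
  ant_r <- as.vector(rot %*% anterior)
  if (sqrt(ant_r[1]^2 + ant_r[2]^2) > 1e-9) {
    spin <- rotation_about_axis(
      c(0, 0, 1), 90 - atan2(ant_r[2], ant_r[1]) * 180 / pi
    )
    rot <- spin %*% rot
  }
  v <- clipped$vertices %*% t(rot)
  p_rot <- as.vector(rot %*% p)
  v <- sweep(v, 2, c(p_rot[1], p_rot[2], p_rot[3]), "-")
  out <- surface(v, clipped$triangles)
  attr(out, "landmark") <- as.vector(rot %*% landmark) - p_rot
  attr(out, "shaft_axis") <- as.vector(rot %*% ax)
  attr(out, "cut_normal") <- c(0, 0, -1)
  # rigid map between oriented model coordinates and the CT frame:
  # x_model = rotation %*% x_ct - offset
  attr(out, "ct_transform") <- list(rotation = rot, offset = p_rot)
  out
}
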