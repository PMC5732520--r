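# Tetrahedral meshing: signed distance to a closed triangle surface sampled
# on a snapped lattice, Kuhn 6-tet subdivision of the lattice cells, and a
# marching-tetrahedra clip of boundary cells against the zero level set.

#' Construct a tetrahedral mesh object
#'
#' @param nodes Numeric `n x 3` node coordinates (mm).
#' @param tets Integer `m x 4`, 1-based, positively oriented.
#' @param boundary_tris Integer `b x 3` outward-oriented boundary faces.
#' @param shell Data frame of shell elements: columns `n1,n2,n3`
#'   (node ids) and `thickness` (mm); may have zero rows.
#' @param node_sets Named list of integer node-id vectors.
#' @param cut_plane Optional `list(point, normal)` marking the specimen cut
#'   face.
#' @param ct_transform Optional rigid map `list(rotation, offset)` from the
#'   CT frame to model coordinates (`x_model = rotation x_ct - offset`),
#'   used when sampling element HU.
#' @return Object of class `tet_mesh`.
#' @export
tet_mesh <- function(nodes, tets, boundary_tris, shell = NULL,
                     node_sets = list(), cut_plane = NULL,
                     ct_transform = NULL) {
  nodes <- as.matrix(nodes)
  tets <- matrix(as.integer(as.matrix(tets)), ncol = 4)
  boundary_tris <- matrix(as.integer(as.matrix(boundary_tris)), ncol = 3)
  if (max(tets) > nrow(nodes) || min(tets) < 1L) {
    stop("tet node indices out of range", call. = FALSE)
  }
  if (is.null(shell)) {
    shell <- tibble::tibble(n1 = integer(), n2 = integer(), n3 = integer(),
                            thickness = numeric())
  }
  structure(
    list(nodes = nodes, tets = tets, boundary_tris = boundary_tris,
         shell = tibble::as_tibble(shell), node_sets = node_sets,
         cut_plane = cut_plane, ct_transform = ct_transform),
    class = "tet_mesh"
  )
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf(
    "<tet_mesh> %d nodes, %d tets, %d boundary tris, %d shells, volume %.6g mm^3\n",
    nrow(x$nodes), nrow(x$tets), nrow(x$boundary_tris), nrow(x$shell),
    mesh_volume(x)
  ))
  if (length(x$node_sets)) {
    cat("  node sets:",
        paste(sprintf("%s (%d)", names(x$node_sets),
                      lengths(x$node_sets)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Signed tet volumes (mm^3)
#' @param mesh A [tet_mesh()].
#' @return Numeric vector, one entry per tet; positive for valid meshes.
#' @export
tet_volumes <- function(mesh) {
  signed_tet_volume(mesh$nodes, mesh$tets)
}

signed_tet_volume <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 2], , drop = FALSE] - a
  c_ <- nodes[tets[, 3], , drop = FALSE] - a
  d <- nodes[tets[, 4], , drop = FALSE] - a
  (b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
     b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
     b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}

#' Total mesh volume (mm^3)
#' @param mesh A [tet_mesh()].
#' @return Numeric scalar.
#' @export
mesh_volume <- function(mesh) sum(tet_volumes(mesh))

#' Tet edge lengths (mm)
#' @param mesh A [tet_mesh()].
#' @return Numeric vector over unique edges.
#' @export
mesh_edge_lengths <- function(mesh) {
  tt <- mesh$tets
  pairs <- rbind(tt[, c(1, 2)], tt[, c(1, 3)], tt[, c(1, 4)],
                 tt[, c(2, 3)], tt[, c(2, 4)], tt[, c(3, 4)])
  key <- pmin(pairs[, 1], pairs[, 2]) * 2^26 + pmax(pairs[, 1], pairs[, 2])
  pairs <- pairs[!duplicated(key), , drop = FALSE]
  sqrt(rowSums((mesh$nodes[pairs[, 1], , drop = FALSE] -
                  mesh$nodes[pairs[, 2], , drop = FALSE])^2))
}

## ---- signed distance ------------------------------------------------------

# Signed distance of lattice grid points to a closed surface. Magnitudes are
# exact only within `margin` of the surface (all that marching tets needs);
# far points carry the correct sign with a large magnitude.
signed_distance_grid <- function(s, xs, ys, zs, margin) {
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  big <- 1e6
  dmin <- array(big, c(nx, ny, nz))
  v <- s$vertices
  tr <- s$triangles

  ## unsigned distance, pruned to triangle bbox + margin
  for (t in seq_len(nrow(tr))) {
    a <- v[tr[t, 1], ]; b <- v[tr[t, 2], ]; cc <- v[tr[t, 3], ]
    lo <- pmin(a, b, cc) - margin
    hi <- pmax(a, b, cc) + margin
    ix <- which(xs >= lo[1] & xs <= hi[1])
    iy <- which(ys >= lo[2] & ys <= hi[2])
    iz <- which(zs >= lo[3] & zs <= hi[3])
    if (!length(ix) || !length(iy) || !length(iz)) next
    g <- expand.grid(x = xs[ix], y = ys[iy], z = zs[iz],
                     KEEP.OUT.ATTRS = FALSE)
    p <- as.matrix(g)
    d <- point_triangle_distance(p, a, b, cc)
    gi <- expand.grid(i = ix, j = iy, k = iz, KEEP.OUT.ATTRS = FALSE)
    lin <- gi$i + (gi$j - 1L) * nx + (gi$k - 1L) * nx * ny
    upd <- d < dmin[lin]
    dmin[lin[upd]] <- d[upd]
  }

  ## parity along +x grid lines (tiny deterministic jitter avoids
  ## edge-grazing double counts on symmetric geometry)
  jy <- 1.234567e-4 * (if (ny > 1) ys[2] - ys[1] else 1)
  jz <- 1.987654e-4 * (if (nz > 1) zs[2] - zs[1] else 1)
  crossings <- vector("list", ny * nz)
  for (t in seq_len(nrow(tr))) {
    a <- v[tr[t, 1], ]; b <- v[tr[t, 2], ]; cc <- v[tr[t, 3], ]
    e1 <- b - a; e2 <- cc - a
    # ray dir +x: h = d x e2 = (0, -e2[3], e2[2])
    h <- c(0, -e2[3], e2[2])
    det <- e1[2] * h[2] + e1[3] * h[3]
    if (abs(det) < 1e-14) next
    iy <- which(ys + jy >= min(a[2], b[2], cc[2]) &
                  ys + jy <= max(a[2], b[2], cc[2]))
    iz <- which(zs + jz >= min(a[3], b[3], cc[3]) &
                  zs + jz <= max(a[3], b[3], cc[3]))
    if (!length(iy) || !length(iz)) next
    gi <- expand.grid(j = iy, k = iz, KEEP.OUT.ATTRS = FALSE)
    oy <- ys[gi$j] + jy; oz <- zs[gi$k] + jz
    sx <- -a[1] # ray origin at x = 0; crossing x is then the ray parameter
    sy <- oy - a[2]; sz <- oz - a[3]
    u <- (sy * h[2] + sz * h[3]) / det
    # q = s x e1 with s = (sx, sy, sz); only dir-dot (x comp) and e2-dot needed
    qx <- sy * e1[3] - sz * e1[2]
    vv <- qx / det
    ok <- u >= 0 & vv >= 0 & (u + vv) <= 1
    if (!any(ok)) next
    # crossing x: from t = e2 . q / det with full q
    qy <- sz * e1[1] - sx * e1[3]
    qz <- sx * e1[2] - sy * e1[1]
    tt <- (e2[1] * qx + e2[2] * qy + e2[3] * qz) / det
    xc <- tt[ok]
    lines_ <- gi$j[ok] + (gi$k[ok] - 1L) * ny
    for (m in seq_along(lines_)) {
      l <- lines_[m]
      crossings[[l]] <- c(crossings[[l]], xc[m])
    }
  }
  inside <- array(FALSE, c(nx, ny, nz))
  for (l in seq_len(ny * nz)) {
    xc <- crossings[[l]]
    if (is.null(xc)) next
    j <- ((l - 1L) %% ny) + 1L
    k <- ((l - 1L) %/% ny) + 1L
    n_right <- length(xc) - findInterval(xs, sort(xc))
    inside[, j, k] <- (n_right %% 2L) == 1L
  }
  ifelse(inside, -dmin, dmin)
}

# distance from points p (n x 3) to triangle (a, b, c), vectorised over p
point_triangle_distance <- function(p, a, b, c) {
  e0 <- b - a; e1 <- c - a
  n <- c(e0[2] * e1[3] - e0[3] * e1[2],
         e0[3] * e1[1] - e0[1] * e1[3],
         e0[1] * e1[2] - e0[2] * e1[1])
  nn <- sum(n^2)
  d <- sweep(p, 2, a, "-")
  # barycentric coordinates of the in-plane projection
  d00 <- sum(e0 * e0); d01 <- sum(e0 * e1); d11 <- sum(e1 * e1)
  dp0 <- d %*% e0; dp1 <- d %*% e1
  denom <- max(d00 * d11 - d01^2, 1e-300)
  u <- as.vector(d11 * dp0 - d01 * dp1) / denom
  vvv <- as.vector(d00 * dp1 - d01 * dp0) / denom
  inside <- u >= 0 & vvv >= 0 & (u + vvv) <= 1
  dist2 <- rep(Inf, nrow(p))
  if (nn > 0 && any(inside)) {
    plane_d <- as.vector(d %*% n) / sqrt(nn)
    dist2[inside] <- plane_d[inside]^2
  }
  seg2 <- function(p0, p1) {
    e <- p1 - p0
    le <- sum(e^2)
    w <- sweep(p, 2, p0, "-")
    t <- pmin(pmax(as.vector(w %*% e) / max(le, 1e-300), 0), 1)
    rowSums((w - outer(t, e))^2)
  }
  dist2 <- pmin(dist2, seg2(a, b), seg2(b, c), seg2(c, a))
  sqrt(dist2)
}

## ---- marching tetrahedra --------------------------------------------------

# Kuhn subdivision of the unit cube: 6 tets sharing the main diagonal.
KUHN_PATHS <- rbind(
  c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
  c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)
)

#' Tetrahedralize a closed surface
#'
#' Fills the surface with tetrahedra from a snapped lattice (pitch
#' `target_edge/sqrt(2)` so the median tet edge lands on the target):
#' lattice cells are split into 6 tets, cells crossing the boundary are
#' clipped to the zero level set of the surface's signed distance by
#' marching tetrahedra. Box-like surfaces whose bounding box equals the
#' surface are reproduced exactly.
#'
#' @param s A closed [surface()].
#' @param target_edge Target global edge length in mm (default 1.5).
#' @return A [tet_mesh()]; all tets positively oriented, boundary faces
#'   outward. Carries over any cut-plane attribute from [cut_and_orient()].
#' @export
tetrahedralize <- function(s, target_edge = 1.5) {
  stopifnot(inherits(s, "surface"), target_edge > 0)
  h <- target_edge / sqrt(2)
  lo <- apply(s$vertices, 2, min)
  hi <- apply(s$vertices, 2, max)
  ext <- hi - lo
  ndiv <- pmax(1L, as.integer(round(ext / h)))
  xs <- seq(lo[1], hi[1], length.out = ndiv[1] + 1L)
  ys <- seq(lo[2], hi[2], length.out = ndiv[2] + 1L)
  zs <- seq(lo[3], hi[3], length.out = ndiv[3] + 1L)
  phi <- signed_distance_grid(s, xs, ys, zs, margin = 2.5 * max(ext / ndiv))
  snap <- 1e-9 * max(ext)
  phi[abs(phi) < snap] <- 0

  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  vid <- function(i, j, k) i + (j - 1L) * nx + (k - 1L) * nx * ny
  cells <- expand.grid(i = seq_len(nx - 1L), j = seq_len(ny - 1L),
                       k = seq_len(nz - 1L), KEEP.OUT.ATTRS = FALSE)
  corner <- function(di, dj, dk) vid(cells$i + di, cells$j + dj, cells$k + dk)
  corners <- cbind(
    corner(0L, 0L, 0L), corner(1L, 0L, 0L), corner(0L, 1L, 0L),
    corner(1L, 1L, 0L), corner(0L, 0L, 1L), corner(1L, 0L, 1L),
    corner(0L, 1L, 1L), corner(1L, 1L, 1L)
  )
  step_bit <- c(1L, 2L, 4L) # corner index bit per axis
  tet_list <- vector("list", 6L)
  for (p in seq_len(6L)) {
    path <- KUHN_PATHS[p, ]
    c0 <- 0L
    c1 <- c0 + step_bit[path[1]]
    c2 <- c1 + step_bit[path[2]]
    tet_list[[p]] <- cbind(corners[, 1L], corners[, 1L + c1],
                           corners[, 1L + c2], corners[, 8L])
  }
  lat_tets <- do.call(rbind, tet_list)

  phiv <- as.vector(phi)
  ins <- phiv <= 0
  n_in <- matrix(ins[lat_tets], ncol = 4)
  n_in <- rowSums(n_in)
  full <- lat_tets[n_in == 4L, , drop = FALSE]
  mixed <- lat_tets[n_in >= 1L & n_in <= 3L, , drop = FALSE]

  # cut-point ids keyed by lattice edge; appended after lattice vids
  edge_env <- new.env(hash = TRUE)
  cutpts <- list()
  lat_coord <- function(v) {
    v0 <- v - 1L
    i <- v0 %% nx
    j <- (v0 %/% nx) %% ny
    k <- v0 %/% (nx * ny)
    cbind(xs[i + 1L], ys[j + 1L], zs[k + 1L])
  }
  n_lat <- nx * ny * nz
  cut_id <- function(vi, vo) {
    key <- paste(min(vi, vo), max(vi, vo))
    idx <- edge_env[[key]]
    if (is.null(idx)) {
      t <- phiv[vi] / (phiv[vi] - phiv[vo])
      pi_ <- lat_coord(vi); po <- lat_coord(vo)
      cutpts[[length(cutpts) + 1L]] <<- pi_ + t * (po - pi_)
      idx <- n_lat + length(cutpts)
      edge_env[[key]] <- idx
    }
    idx
  }

  sub_tets <- list(full)
  if (nrow(mixed) > 0L) {
    for (r in seq_len(nrow(mixed))) {
      vv <- mixed[r, ]
      iin <- vv[ins[vv]]
      iout <- vv[!ins[vv]]
      ni <- length(iin)
      if (ni == 1L) {
        a <- iin[1]
        p1 <- cut_id(a, iout[1]); p2 <- cut_id(a, iout[2])
        p3 <- cut_id(a, iout[3])
        sub_tets[[length(sub_tets) + 1L]] <- matrix(c(a, p1, p2, p3), 1, 4)
      } else if (ni == 2L) {
        a <- iin[1]; b <- iin[2]
        pac <- cut_id(a, iout[1]); pad <- cut_id(a, iout[2])
        pbc <- cut_id(b, iout[1]); pbd <- cut_id(b, iout[2])
        sub_tets[[length(sub_tets) + 1L]] <- rbind(
          c(a, pac, pad, b),
          c(pac, pad, b, pbc),
          c(pad, b, pbc, pbd)
        )
      } else {
        a <- iin[1]; b <- iin[2]; cc <- iin[3]
        pad <- cut_id(a, iout[1]); pbd <- cut_id(b, iout[1])
        pcd <- cut_id(cc, iout[1])
        sub_tets[[length(sub_tets) + 1L]] <- rbind(
          c(a, b, cc, pad),
          c(b, cc, pad, pbd),
          c(cc, pad, pbd, pcd)
        )
      }
    }
  }
  all_tets <- do.call(rbind, sub_tets)
  if (nrow(all_tets) == 0L) {
    stop("meshing failed: no interior lattice cells; reduce target_edge",
         call. = FALSE)
  }

  # node table: kept lattice vertices + cut points
  used <- sort(unique(as.vector(all_tets)))
  lat_used <- used[used <= n_lat]
  cut_used <- used[used > n_lat]
  nodes <- rbind(lat_coord(lat_used),
                 if (length(cut_used)) {
                   do.call(rbind, cutpts)[cut_used - n_lat, , drop = FALSE]
                 })
  remap <- integer(max(used))
  remap[used] <- seq_along(used)
  tets <- matrix(remap[as.vector(all_tets)], ncol = 4)

  # enforce positive orientation, drop degenerate slivers
  vol <- signed_tet_volume(nodes, tets)
  neg <- vol < 0
  tets[neg, 3:4] <- tets[neg, c(4, 3)]
  vol <- abs(vol)
  keep <- vol > 1e-10 * max(vol)
  tets <- tets[keep, , drop = FALSE]

  boundary <- boundary_faces(tets)
  cut_plane <- if (!is.null(attr(s, "cut_normal"))) {
    list(point = c(0, 0, 0), normal = attr(s, "cut_normal"))
  }
  m <- tet_mesh(nodes, tets, boundary, cut_plane = cut_plane,
                ct_transform = attr(s, "ct_transform"))
  # drop nodes orphaned by sliver removal
  compact_mesh(m)
}

# outward-oriented boundary faces (faces used by exactly one tet)
boundary_faces <- function(tets) {
  f <- rbind(tets[, c(2, 3, 4)], tets[, c(1, 4, 3)],
             tets[, c(1, 2, 4)], tets[, c(1, 3, 2)])
  key <- apply_face_key(f)
  tab <- table(key)
  single <- names(tab)[tab == 1L]
  f[key %in% single, , drop = FALSE]
}

apply_face_key <- function(f) {
  a <- pmin(f[, 1], f[, 2], f[, 3])
  c_ <- pmax(f[, 1], f[, 2], f[, 3])
  b <- f[, 1] + f[, 2] + f[, 3] - a - c_
  paste(a, b, c_)
}

compact_mesh <- function(m) {
  used <- sort(unique(c(as.vector(m$tets), as.vector(m$boundary_tris))))
  remap <- integer(nrow(m$nodes))
  remap[used] <- seq_along(used)
  tet_mesh(
    m$nodes[used, , drop = FALSE],
    matrix(remap[as.vector(m$tets)], ncol = 4),
    matrix(remap[as.vector(m$boundary_tris)], ncol = 3),
    shell = m$shell,
    node_sets = lapply(m$node_sets, function(sset) remap[sset]),
    cut_plane = m$cut_plane,
    ct_transform = m$ct_transform
  )
}

## ---- shell overlay and boundary sets -------------------------------------

#' Overlay cortical shell elements on the mesh boundary
#'
#' Every boundary triangle receives a membrane shell of the given
#' thickness, except triangles lying on the specimen cut face and triangles
#' entirely inside the resin-fixed node set (if tagged).
#'
#' @param mesh A [tet_mesh()].
#' @param thickness Shell thickness in mm (default 0.2).
#' @return The mesh with its `shell` table populated (idempotent).
#' @export
overlay_shell <- function(mesh, thickness = 0.2) {
  stopifnot(inherits(mesh, "tet_mesh"))
  if (nrow(mesh$boundary_tris) == 0L) {
    stop("mesh has no boundary triangles", call. = FALSE)
  }
  bt <- mesh$boundary_tris
  keep <- rep(TRUE, nrow(bt))
  if (!is.null(mesh$cut_plane)) {
    gn <- sweep(mesh$nodes, 2, mesh$cut_plane$point, "-") %*%
      mesh$cut_plane$normal
    on_cut <- abs(gn) < 1e-6
    keep <- keep & !(on_cut[bt[, 1]] & on_cut[bt[, 2]] & on_cut[bt[, 3]])
  }
  fixed <- mesh$node_sets[["fixed_distal"]]
  if (!is.null(fixed)) {
    inset <- seq_len(nrow(mesh$nodes)) %in% fixed
    keep <- keep & !(inset[bt[, 1]] & inset[bt[, 2]] & inset[bt[, 3]])
  }
  mesh$shell <- tibble::tibble(
    n1 = bt[keep, 1], n2 = bt[keep, 2], n3 = bt[keep, 3],
    thickness = thickness
  )
  mesh
}

# algebraic sphere fit: |x|^2 = 2 c.x + r^2 - |c|^2
fit_sphere <- function(pts) {
  A <- cbind(2 * pts, 1)
  b <- rowSums(pts^2)
  sol <- qr.solve(A, b)
  list(center = sol[1:3], radius = sqrt(max(sol[4] + sum(sol[1:3]^2), 0)))
}

#' Tag the resin-box and resin-cap boundary node sets
#'
#' `fixed_distal`: all nodes within `distal_depth` mm of the cut plane
#' (the resin-box band). `cap_contact`: boundary nodes on the femoral-head
#' analog within `cap_angle_deg` of the load axis (+z from the head
#' centre); the head centre is fit as a sphere through the topmost boundary
#' nodes unless supplied.
#'
#' @param mesh A [tet_mesh()] with a cut plane (see [cut_and_orient()]).
#' @param distal_depth Resin-box depth from the cut plane (mm, default 30).
#' @param cap_angle_deg Half-angle of the loaded spherical cap (degrees).
#' @param head_center,head_radius Optional known head sphere (mm); fitted
#'   from the top 15% of boundary nodes when `NULL`.
#' @return The mesh with `node_sets$fixed_distal` and
#'   `node_sets$cap_contact` populated (disjoint; cap nodes inside the
#'   fixed band are never tagged).
#' @export
tag_boundary_sets <- function(mesh, distal_depth = 30, cap_angle_deg,
                              head_center = NULL, head_radius = NULL) {
  stopifnot(inherits(mesh, "tet_mesh"))
  if (is.null(mesh$cut_plane)) {
    stop("mesh has no identified cut face; run cut_and_orient first",
         call. = FALSE)
  }
  if (cap_angle_deg <= 0) {
    stop("node set 'cap_contact' is empty (cap_angle_deg must be > 0)",
         call. = FALSE)
  }
  n <- mesh$cut_plane$normal
  p <- mesh$cut_plane$point
  height <- as.vector(sweep(mesh$nodes, 2, p, "-") %*% (-n))
  fixed <- which(height <= distal_depth + 1e-9)
  if (length(fixed) == 0L) {
    stop("node set 'fixed_distal' is empty", call. = FALSE)
  }
  bnodes <- unique(as.vector(mesh$boundary_tris))
  if (is.null(head_center)) {
    zb <- height[bnodes]
    topband <- bnodes[zb >= max(zb) - 0.15 * diff(range(zb))]
    sp <- fit_sphere(mesh$nodes[topband, , drop = FALSE])
    head_center <- sp$center
    head_radius <- sp$radius
  }
  rel <- sweep(mesh$nodes[bnodes, , drop = FALSE], 2, head_center, "-")
  rr <- sqrt(rowSums(rel^2))
  cosang <- rel[, 3] / pmax(rr, 1e-12)
  on_sphere <- abs(rr - head_radius) < 0.25 * head_radius
  cap <- bnodes[on_sphere & cosang >= cos(cap_angle_deg * pi / 180) &
                  rel[, 3] > 0]
  cap <- setdiff(cap, fixed)
  if (length(cap) == 0L) {
    stop("node set 'cap_contact' is empty (cap_angle too small?)",
         call. = FALSE)
  }
  mesh$node_sets$fixed_distal <- fixed
  mesh$node_sets$cap_contact <- cap
  mesh
}

## ---- export ---------------------------------------------------------------

#' Export a mesh as ASCII VTU
#' @param mesh A [tet_mesh()].
#' @param path Output `.vtu` path.
#' @param cell_data Optional named list of per-tet numeric vectors.
#' @return `path`, invisibly.
#' @export
write_mesh_vtu <- function(mesh, path, cell_data = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  np <- nrow(mesh$nodes); nc <- nrow(mesh$tets)
  w <- function(...) writeLines(paste0(...), con)
  w(sprintf('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">'))
  w("<UnstructuredGrid>")
  w(sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', np, nc))
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(sprintf("%.10g %.10g %.10g", mesh$nodes[, 1], mesh$nodes[, 2],
                     mesh$nodes[, 3]), con)
  w("</DataArray></Points>")
  w("<Cells>")
  w('<DataArray type="Int64" Name="connectivity" format="ascii">')
  writeLines(sprintf("%d %d %d %d", mesh$tets[, 1] - 1L, mesh$tets[, 2] - 1L,
                     mesh$tets[, 3] - 1L, mesh$tets[, 4] - 1L), con)
  w("</DataArray>")
  w('<DataArray type="Int64" Name="offsets" format="ascii">')
  writeLines(as.character(seq_len(nc) * 4L), con)
  w("</DataArray>")
  w('<DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(rep("10", nc), con)
  w("</DataArray>")
  w("</Cells>")
  if (!is.null(cell_data)) {
    w("<CellData>")
    for (nm in names(cell_data)) {
      w(sprintf('<DataArray type="Float64" Name="%s" format="ascii">', nm))
      writeLines(sprintf("%.10g", cell_data[[nm]]), con)
      w("</DataArray>")
    }
    w("</CellData>")
  }
  w("</Piece></UnstructuredGrid></VTKFile>")
  invisible(path)
}

#' Export a solver deck in Abaqus-style INP format
#'
#' Nodes, C3D4 tets, S3 shells with a shell-section thickness, and the
#' tagged node sets. 1-based ids.
#'
#' @param mesh A [tet_mesh()].
#' @param path Output `.inp` path.
#' @return `path`, invisibly.
#' @export
write_mesh_inp <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("*NODE")
  writeLines(sprintf("%d, %.10g, %.10g, %.10g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  w("*ELEMENT, TYPE=C3D4, ELSET=BONE")
  writeLines(sprintf("%d, %d, %d, %d, %d", seq_len(nrow(mesh$tets)),
                     mesh$tets[, 1], mesh$tets[, 2], mesh$tets[, 3],
                     mesh$tets[, 4]), con)
  if (nrow(mesh$shell) > 0L) {
    off <- nrow(mesh$tets)
    w("*ELEMENT, TYPE=S3, ELSET=CORTEX")
    writeLines(sprintf("%d, %d, %d, %d", off + seq_len(nrow(mesh$shell)),
                       mesh$shell$n1, mesh$shell$n2, mesh$shell$n3), con)
    w("*SHELL SECTION, ELSET=CORTEX")
    w(sprintf("%.6g", mesh$shell$thickness[1]))
  }
  for (nm in names(mesh$node_sets)) {
    w(sprintf("*NSET, NSET=%s", toupper(nm)))
    ids <- mesh$node_sets[[nm]]
    for (i in seq(1, length(ids), by = 12)) {
      w(paste(ids[i:min(i + 11, length(ids))], collapse = ", "))
    }
  }
  invisible(path)
}
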