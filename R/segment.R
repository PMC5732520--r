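# Iso-surface extraction from the thresholded voxel mask: the boundary of
# the voxelised region, triangulated. Vertices sit on voxel corners so the
# surface deviates from the true interface by at most half a voxel
# diagonal.

largest_component_mask <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0L) return(mask)
  lin <- array(0L, d)
  lin[idx] <- seq_along(idx)
  edge_pairs <- function(axis) {
    shift <- c(1L, d[1], d[1] * d[2])[axis]
    coord <- arrayInd(idx, d)[, axis]
    ok <- coord < d[axis] & mask[idx + shift]
    cbind(lin[idx[ok]], lin[idx[ok] + shift])
  }
  edges <- rbind(edge_pairs(1L), edge_pairs(2L), edge_pairs(3L))
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(edges) > 0L) {
    g <- igraph::add_edges(g, as.vector(t(edges)))
  }
  comp <- igraph::components(g)
  keep <- idx[comp$membership == which.max(comp$csize)]
  out <- array(FALSE, d)
  out[keep] <- TRUE
  out
}

#' Triangulated boundary surface of a voxel mask
#'
#' @param mask Logical 3-D array (voxel inside/outside).
#' @param spacing,origin Volume geometry as in [ct_volume()].
#' @return A closed [surface()] in world mm.
#' @export
mask_to_surface <- function(mask, spacing, origin = c(0, 0, 0)) {
  d <- dim(mask)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  nc1 <- d[1] + 1L; nc2 <- d[2] + 1L
  cid <- function(i, j, k) i + (j - 1L) * nc1 + (k - 1L) * nc1 * nc2

  pad <- function(m, axis, dir) {
    # neighbour occupancy shifted along `axis` by `dir`
    out <- array(FALSE, d)
    if (axis == 1L) {
      if (dir > 0) out[seq_len(d[1] - 1L), , ] <- m[2:d[1], , ]
      else out[2:d[1], , ] <- m[seq_len(d[1] - 1L), , ]
    } else if (axis == 2L) {
      if (dir > 0) out[, seq_len(d[2] - 1L), ] <- m[, 2:d[2], ]
      else out[, 2:d[2], ] <- m[, seq_len(d[2] - 1L), ]
    } else {
      if (dir > 0) out[, , seq_len(d[3] - 1L)] <- m[, , 2:d[3]]
      else out[, , 2:d[3]] <- m[, , seq_len(d[3] - 1L)]
    }
    out
  }

  quads <- vector("list", 6L)
  qi <- 0L
  for (axis in 1:3) {
    for (dir in c(1L, -1L)) {
      face_vox <- which(mask & !pad(mask, axis, dir))
      if (length(face_vox) == 0L) next
      ijk <- arrayInd(face_vox, d)
      i <- ijk[, 1]; j <- ijk[, 2]; k <- ijk[, 3]
      # corner indices of the exposed face, ordered for outward normal
      q <- switch(paste0(axis, if (dir > 0) "+" else "-"),
        "1+" = cbind(cid(i + 1L, j, k), cid(i + 1L, j + 1L, k),
                     cid(i + 1L, j + 1L, k + 1L), cid(i + 1L, j, k + 1L)),
        "1-" = cbind(cid(i, j, k), cid(i, j, k + 1L),
                     cid(i, j + 1L, k + 1L), cid(i, j + 1L, k)),
        "2+" = cbind(cid(i, j + 1L, k), cid(i, j + 1L, k + 1L),
                     cid(i + 1L, j + 1L, k + 1L), cid(i + 1L, j + 1L, k)),
        "2-" = cbind(cid(i, j, k), cid(i + 1L, j, k),
                     cid(i + 1L, j, k + 1L), cid(i, j, k + 1L)),
        "3+" = cbind(cid(i, j, k + 1L), cid(i + 1L, j, k + 1L),
                     cid(i + 1L, j + 1L, k + 1L), cid(i, j + 1L, k + 1L)),
        "3-" = cbind(cid(i, j, k), cid(i, j + 1L, k),
                     cid(i + 1L, j + 1L, k), cid(i + 1L, j, k))
      )
      qi <- qi + 1L
      quads[[qi]] <- q
    }
  }
  q <- do.call(rbind, quads[seq_len(qi)])
  if (is.null(q) || nrow(q) == 0L) stop("mask has no boundary", call. = FALSE)
  tris <- rbind(q[, c(1, 2, 3), drop = FALSE], q[, c(1, 3, 4), drop = FALSE])
  used <- sort(unique(as.vector(tris)))
  remap <- integer(max(used))
  remap[used] <- seq_along(used)
  # corner (ci,cj,ck) world position: origin + (c - 1.5) * spacing
  ck <- (used - 1L) %/% (nc1 * nc2)
  rem <- (used - 1L) %% (nc1 * nc2)
  cj <- rem %/% nc1
  ci <- rem %% nc1
  verts <- cbind(origin[1] + (ci - 0.5) * spacing[1],
                 origin[2] + (cj - 0.5) * spacing[2],
                 origin[3] + (ck - 0.5) * spacing[3])
  surface(verts, matrix(remap[as.vector(tris)], ncol = 3))
}

#' Segment bone from a CT volume
#'
#' Thresholds the volume, keeps the largest 6-connected component, and
#' returns its triangulated boundary surface in world mm.
#'
#' @param volume A [ct_volume()].
#' @param threshold HU threshold; voxels strictly above it are bone.
#' @return A closed [surface()].
#' @export
segment_bone <- function(volume, threshold) {
  stopifnot(inherits(volume, "ct_volume"))
  mask <- volume$values > threshold
  if (!any(mask)) {
    stop(sprintf(
      "empty segmentation: threshold %g outside HU range [%g, %g]",
      threshold, min(volume$values), max(volume$values)
    ), call. = FALSE)
  }
  mask <- largest_component_mask(mask)
  mask_to_surface(mask, volume$spacing, volume$origin)
}
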