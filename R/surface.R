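#' Construct a triangulated surface
#'
#' Closed, outward-oriented triangle surfaces in world millimetres are the
#' geometry currency between segmentation, the specimen cut and the mesher.
#'
#' @param vertices Numeric `n x 3` matrix of vertex coordinates (mm).
#' @param triangles Integer `m x 3` matrix of 1-based vertex indices,
#'   counter-clockwise seen from outside.
#' @return Object of class `surface`.
#' @export
surface <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  stopifnot(ncol(vertices) == 3, nrow(triangles) >= 1)
  if (min(triangles) < 1L || max(triangles) > nrow(vertices)) {
    stop("triangle indices out of range", call. = FALSE)
  }
  structure(list(vertices = vertices, triangles = triangles),
            class = "surface")
}

#' @export
print.surface <- function(x, ...) {
  cat(sprintf("<surface> %d vertices, %d triangles, area %.4g mm^2",
              nrow(x$vertices), nrow(x$triangles), surface_area(x)))
  if (surface_is_closed(x)) {
    cat(sprintf(", enclosed volume %.6g mm^3\n", surface_volume(x)))
  } else {
    cat(" (open)\n")
  }
  invisible(x)
}

tri_verts <- function(s) {
  list(a = s$vertices[s$triangles[, 1], , drop = FALSE],
       b = s$vertices[s$triangles[, 2], , drop = FALSE],
       c = s$vertices[s$triangles[, 3], , drop = FALSE])
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Total surface area (mm^2)
#' @param s A [surface()].
#' @return Numeric scalar.
#' @export
surface_area <- function(s) {
  tv <- tri_verts(s)
  n <- cross3(tv$b - tv$a, tv$c - tv$a)
  sum(sqrt(rowSums(n^2))) / 2
}

#' Volume enclosed by a closed surface (mm^3)
#'
#' Signed volume by the divergence theorem; positive for outward
#' orientation.
#' @param s A [surface()].
#' @return Numeric scalar.
#' @export
surface_volume <- function(s) {
  tv <- tri_verts(s)
  sum(rowSums(tv$a * cross3(tv$b - tv$a, tv$c - tv$a))) / 6
}

surface_edge_key <- function(i, j) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  lo * (2^26) + hi
}

#' Is a surface closed and edge-manifold?
#'
#' Every undirected edge must be used by exactly two triangles and, with
#' consistent orientation, once in each direction.
#' @param s A [surface()].
#' @return Logical scalar.
#' @export
surface_is_closed <- function(s) {
  tr <- s$triangles
  keys <- c(surface_edge_key(tr[, 1], tr[, 2]),
            surface_edge_key(tr[, 2], tr[, 3]),
            surface_edge_key(tr[, 3], tr[, 1]))
  all(table(keys) == 2L)
}

#' Apply a rigid transform to a surface
#' @param s A [surface()].
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 numeric (mm).
#' @return Transformed [surface()].
#' @export
transform_surface <- function(s, rotation = diag(3), translation = c(0, 0, 0)) {
  surface(sweep(s$vertices %*% t(rotation), 2, translation, "+"), s$triangles)
}

# drop unreferenced vertices, remap indices
compact_surface <- function(vertices, triangles) {
  used <- sort(unique(as.vector(triangles)))
  remap <- integer(max(used))
  remap[used] <- seq_along(used)
  surface(vertices[used, , drop = FALSE],
          matrix(remap[as.vector(triangles)], ncol = 3))
}

## ---- primitives -----------------------------------------------------------

#' Axis-aligned box surface
#' @param lower,upper Length-3 corners (mm).
#' @return A closed [surface()] of 12 triangles.
#' @export
surface_box <- function(lower = c(0, 0, 0), upper = c(20, 20, 20)) {
  l <- as.numeric(lower); u <- as.numeric(upper)
  v <- rbind(
    c(l[1], l[2], l[3]), c(u[1], l[2], l[3]), c(u[1], u[2], l[3]),
    c(l[1], u[2], l[3]), c(l[1], l[2], u[3]), c(u[1], l[2], u[3]),
    c(u[1], u[2], u[3]), c(l[1], u[2], u[3])
  )
  tr <- rbind(
    c(1, 3, 2), c(1, 4, 3),         # bottom (z = lo), outward -z
    c(5, 6, 7), c(5, 7, 8),         # top
    c(1, 2, 6), c(1, 6, 5),         # y = lo
    c(2, 3, 7), c(2, 7, 6),         # x = hi
    c(3, 4, 8), c(3, 8, 7),         # y = hi
    c(4, 1, 5), c(4, 5, 8)          # x = lo
  )
  surface(v, tr)
}

#' Icosphere surface
#' @param center Length-3 centre (mm).
#' @param radius Radius (mm).
#' @param subdivisions Number of 4-to-1 subdivision passes (default 3;
#'   1280 triangles).
#' @return A closed [surface()].
#' @export
surface_sphere <- function(center = c(0, 0, 0), radius = 10, subdivisions = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  tr <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (pass in seq_len(subdivisions)) {
    edges <- new.env(hash = TRUE)
    newv <- list()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      idx <- edges[[key]]
      if (is.null(idx)) {
        m <- v[i, ] + v[j, ]
        m <- m / sqrt(sum(m^2))
        newv[[length(newv) + 1L]] <<- m
        idx <- nrow(v) + length(newv)
        edges[[key]] <- idx
      }
      idx
    }
    newtr <- matrix(0L, nrow(tr) * 4L, 3L)
    for (t in seq_len(nrow(tr))) {
      a <- tr[t, 1]; b <- tr[t, 2]; cc <- tr[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newtr[4 * t - 3, ] <- c(a, ab, ca)
      newtr[4 * t - 2, ] <- c(b, bc, ab)
      newtr[4 * t - 1, ] <- c(cc, ca, bc)
      newtr[4 * t, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, newv))
    tr <- newtr
  }
  surface(sweep(v * radius, 2, as.numeric(center), "+"), tr)
}

#' Capped cylinder surface along +z
#'
#' Cylinder of given radius from `base` extending `length` mm along +z,
#' closed with a flat disk at the bottom and either a flat disk or a
#' hemisphere of the same radius at the top.
#'
#' @param base Length-3 centre of the bottom disk (mm).
#' @param radius Radius (mm).
#' @param length Shaft length (mm), base to top-cap equator.
#' @param n_seg Circumferential segments (default 32).
#' @param top One of `"flat"`, `"hemisphere"`.
#' @return A closed [surface()].
#' @export
surface_cylinder <- function(base = c(0, 0, 0), radius = 10, length = 100,
                             n_seg = 32, top = c("flat", "hemisphere")) {
  top <- match.arg(top)
  base <- as.numeric(base)
  th <- seq(0, 2 * pi, length.out = n_seg + 1L)[-(n_seg + 1L)]
  ring <- cbind(radius * cos(th), radius * sin(th))
  lo <- cbind(ring, 0)
  hi <- cbind(ring, length)
  v <- rbind(lo, hi, c(0, 0, 0))
  n <- n_seg
  nxt <- c(2:n, 1)
  side <- rbind(
    cbind(seq_len(n), nxt, n + nxt),
    cbind(seq_len(n), n + nxt, n + seq_len(n))
  )
  bottom <- cbind(nxt, seq_len(n), 2L * n + 1L)
  tr <- rbind(side, bottom)
  if (top == "flat") {
    v <- rbind(v, c(0, 0, length))
    tr <- rbind(tr, cbind(n + seq_len(n), n + nxt, 2L * n + 2L))
  } else {
    # hemisphere: stacked rings up to the pole
    n_lat <- max(4L, ceiling(n / 4))
    prev_ring <- n + seq_len(n)
    for (i in seq_len(n_lat - 1L)) {
      a <- i / n_lat * pi / 2
      rr <- radius * cos(a)
      zz <- length + radius * sin(a)
      v <- rbind(v, cbind(rr * cos(th), rr * sin(th), zz))
      cur <- nrow(v) - n + seq_len(n)
      tr <- rbind(tr,
                  cbind(prev_ring, prev_ring[nxt], cur[nxt]),
                  cbind(prev_ring, cur[nxt], cur))
      prev_ring <- cur
    }
    v <- rbind(v, c(0, 0, length + radius))
    pole <- nrow(v)
    tr <- rbind(tr, cbind(prev_ring, prev_ring[nxt], pole))
  }
  surface(sweep(v, 2, base, "+"), matrix(as.integer(tr), ncol = 3))
}

## ---- STL / PLY ------------------------------------------------------------

#' Write a surface as ASCII STL or PLY
#' @param s A [surface()].
#' @param path Output path ending in `.stl` or `.ply`.
#' @return `path`, invisibly.
#' @export
write_surface <- function(s, path) {
  stopifnot(inherits(s, "surface"))
  if (grepl("\\.stl$", path, ignore.case = TRUE)) {
    tv <- tri_verts(s)
    nrm <- cross3(tv$b - tv$a, tv$c - tv$a)
    nrm <- nrm / pmax(sqrt(rowSums(nrm^2)), 1e-300)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid femstrength", con)
    fmt <- function(p) sprintf("%.9g %.9g %.9g", p[, 1], p[, 2], p[, 3])
    lines <- paste0(
      "facet normal ", fmt(nrm), "\n outer loop\n  vertex ", fmt(tv$a),
      "\n  vertex ", fmt(tv$b), "\n  vertex ", fmt(tv$c),
      "\n endloop\nendfacet"
    )
    writeLines(lines, con)
    writeLines("endsolid femstrength", con)
  } else if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      "ply", "format ascii 1.0",
      paste("element vertex", nrow(s$vertices)),
      "property float x", "property float y", "property float z",
      paste("element face", nrow(s$triangles)),
      "property list uchar int vertex_indices", "end_header"
    ), con)
    writeLines(sprintf("%.9g %.9g %.9g", s$vertices[, 1], s$vertices[, 2],
                       s$vertices[, 3]), con)
    writeLines(sprintf("3 %d %d %d", s$triangles[, 1] - 1L,
                       s$triangles[, 2] - 1L, s$triangles[, 3] - 1L), con)
  } else {
    stop("unsupported surface format: ", path, call. = FALSE)
  }
  invisible(path)
}

#' Read an ASCII STL or PLY surface
#' @param path Input path ending in `.stl` or `.ply`.
#' @return A [surface()]; STL vertices are merged exactly by coordinates.
#' @export
read_surface <- function(path) {
  if (!file.exists(path)) stop("surface file not found: ", path, call. = FALSE)
  if (grepl("\\.stl$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
    xyz <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p) {
      as.numeric(p[2:4])
    }))
    key <- paste(xyz[, 1], xyz[, 2], xyz[, 3])
    uidx <- !duplicated(key)
    verts <- xyz[uidx, , drop = FALSE]
    idx <- match(key, key[uidx])
    surface(verts, matrix(idx, ncol = 3, byrow = TRUE))
  } else if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    hd_end <- match("end_header", trimws(lines))
    nv <- as.integer(sub("element vertex ", "",
                         grep("^element vertex", lines, value = TRUE)))
    nf <- as.integer(sub("element face ", "",
                         grep("^element face", lines, value = TRUE)))
    vlines <- lines[hd_end + seq_len(nv)]
    flines <- lines[hd_end + nv + seq_len(nf)]
    verts <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"),
                                   function(p) as.numeric(p[1:3])))
    tris <- do.call(rbind, lapply(strsplit(trimws(flines), "\\s+"),
                                  function(p) as.integer(p[2:4]) + 1L))
    surface(verts, tris)
  } else {
    stop("unsupported surface format: ", path, call. = FALSE)
  }
}
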