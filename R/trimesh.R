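# Closed triangulated-mesh representation.
#
# A `trimesh` is a list with
#   vertices : N x 3 numeric matrix, positions in units of the target edge
#              length l0
#   faces    : F x 3 integer matrix, 1-based vertex indices, consistently
#              oriented so that all normals point outward (signed volume > 0)
# Adjacency, edges, degrees and all geometric quantities are derived.

#' Construct a triangulated closed-surface mesh
#'
#' @param vertices numeric matrix with one row per vertex and columns x, y, z.
#' @param faces integer matrix with one row per oriented triangle (1-based
#'   vertex indices); all triangles must wind consistently so that face
#'   normals point away from the enclosed volume.
#' @param validate if `TRUE` (default) the mesh is checked to be a closed,
#'   consistently oriented 2-manifold of sphere topology.
#' @return an object of class `trimesh`.
#' @export
trimesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  m <- structure(list(vertices = vertices, faces = faces), class = "trimesh")
  if (validate) validate_trimesh(m)
  m
}

#' Validate the manifold invariants of a trimesh
#'
#' Checks that the mesh is a closed orientable 2-manifold of sphere topology:
#' every edge borders exactly two faces with opposite directed orientations,
#' the Euler characteristic V - E + F equals 2, every vertex has degree at
#' least 3, and the signed volume is positive (outward orientation).
#'
#' @param mesh a `trimesh`.
#' @return invisibly `TRUE`; errors otherwise.
#' @export
validate_trimesh <- function(mesh) {
  cpp_check_mesh(mesh$vertices, mesh$faces)
  if (min(mesh_degrees(mesh)) < 3L) stop("vertex with degree < 3")
  if (enclosed_volume(mesh) <= 0) stop("signed volume not positive (inward orientation?)")
  invisible(TRUE)
}

#' @export
print.trimesh <- function(x, ...) {
  e <- mesh_edges(x)
  cat(sprintf(
    "trimesh: %d vertices, %d edges, %d faces (chi = %d)\n",
    nrow(x$vertices), nrow(e), nrow(x$faces),
    nrow(x$vertices) - nrow(e) + nrow(x$faces)))
  cat(sprintf("  mean edge length %.4f, mean radius %.4f, area %.4f, volume %.4f\n",
              mean(edge_lengths(x)), mesh_mean_radius(x),
              mesh_area(x), enclosed_volume(x)))
  invisible(x)
}

#' Edge list of a trimesh
#'
#' @param mesh a `trimesh`.
#' @return two-column integer matrix of undirected edges, each once, with
#'   the smaller vertex index first.
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  e <- unique(e)
  e[order(e[, 1L], e[, 2L]), , drop = FALSE]
}

#' Vertex degrees (number of incident edges)
#' @param mesh a `trimesh`.
#' @return integer vector of length N.
#' @export
mesh_degrees <- function(mesh) {
  e <- mesh_edges(mesh)
  tabulate(c(e[, 1L], e[, 2L]), nbins = nrow(mesh$vertices))
}

#' Edge lengths of a trimesh
#' @param mesh a `trimesh`.
#' @param edges optional edge matrix as returned by [mesh_edges()].
#' @return numeric vector of Euclidean edge lengths.
#' @export
edge_lengths <- function(mesh, edges = mesh_edges(mesh)) {
  d <- mesh$vertices[edges[, 1L], , drop = FALSE] -
       mesh$vertices[edges[, 2L], , drop = FALSE]
  sqrt(rowSums(d * d))
}

#' Per-face areas
#' @param mesh a `trimesh`.
#' @return numeric vector with one area per face.
#' @export
face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  u <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  w <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cx <- cbind(u[, 2L] * w[, 3L] - u[, 3L] * w[, 2L],
              u[, 3L] * w[, 1L] - u[, 1L] * w[, 3L],
              u[, 1L] * w[, 2L] - u[, 2L] * w[, 1L])
  0.5 * sqrt(rowSums(cx * cx))
}

#' Total surface area
#' @param mesh a `trimesh`.
#' @return total area (l0^2 units).
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

#' Enclosed volume of a closed oriented mesh
#'
#' The signed sum of tetrahedron volumes spanned by each oriented face and
#' the origin. For a closed surface this is translation invariant and equals
#' the enclosed volume, positive when faces are outward oriented.
#'
#' @param mesh a `trimesh`.
#' @return signed volume (l0^3 units).
#' @export
enclosed_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  cc <- v[f[, 3L], , drop = FALSE]
  cx <- cbind(b[, 2L] * cc[, 3L] - b[, 3L] * cc[, 2L],
              b[, 3L] * cc[, 1L] - b[, 1L] * cc[, 3L],
              b[, 1L] * cc[, 2L] - b[, 2L] * cc[, 1L])
  sum(rowSums(a * cx)) / 6
}

#' Mean radius about the vertex centroid
#' @param mesh a `trimesh`.
#' @return mean distance of vertices from their centroid.
#' @export
mesh_mean_radius <- function(mesh) {
  ctr <- colMeans(mesh$vertices)
  d <- sweep(mesh$vertices, 2L, ctr)
  mean(sqrt(rowSums(d * d)))
}

#' Euler characteristic V - E + F
#' @param mesh a `trimesh`.
#' @return integer; 2 for sphere topology.
#' @export
euler_characteristic <- function(mesh) {
  nrow(mesh$vertices) - nrow(mesh_edges(mesh)) + nrow(mesh$faces)
}

# vertices and faces of a regular icosahedron, outward oriented
icosahedron_mesh <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  # enforce outward orientation (convex, centred at the origin)
  det3 <- v[f[, 1L], ] * 0
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1L], ]; b <- v[f[i, 2L], ]; cc <- v[f[i, 3L], ]
    if (sum(a * c(b[2] * cc[3] - b[3] * cc[2],
                  b[3] * cc[1] - b[1] * cc[3],
                  b[1] * cc[2] - b[2] * cc[1])) < 0)
      f[i, ] <- f[i, c(1L, 3L, 2L)]
  }
  list(vertices = v, faces = f)
}

#' Build a subdivided icosahedral sphere mesh
#'
#' Starts from a regular icosahedron and applies `subdivisions` rounds of
#' 4-to-1 edge-midpoint subdivision, projecting every vertex onto the sphere
#' of radius `target_radius`. Vertex count is 10 * 4^s + 2.
#'
#' @param subdivisions non-negative integer subdivision level s.
#' @param target_radius sphere radius; every vertex ends up at exactly this
#'   distance from the centre, so the mean radius matches it. Use
#'   `unit_edge = TRUE` to choose the radius so that the mean edge length is
#'   1 (the simulation length unit l0).
#' @param unit_edge if `TRUE`, `target_radius` is ignored and the mesh is
#'   scaled so the mean edge length equals 1.
#' @return a `trimesh`; the attribute `mean_edge` records the mean edge
#'   length so callers can rescale to l0 units.
#' @export
build_icosphere <- function(subdivisions, target_radius = 1, unit_edge = FALSE) {
  stopifnot(subdivisions >= 0)
  ico <- icosahedron_mesh()
  v <- ico$vertices
  f <- ico$faces
  s <- 0L
  while (s < subdivisions) {
    nv <- nrow(v)
    key <- function(a, b) pmin(a, b) * (nv + 1) + pmax(a, b)
    mid_env <- new.env(hash = TRUE)
    newv <- list()
    idx <- nv
    midpoint <- function(a, b) {
      k <- as.character(key(a, b))
      got <- mid_env[[k]]
      if (!is.null(got)) return(got)
      idx <<- idx + 1L
      newv[[length(newv) + 1L]] <<- (v[a, ] + v[b, ]) / 2
      mid_env[[k]] <- idx
      idx
    }
    nf <- matrix(0L, nrow(f) * 4L, 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1L]; b <- f[i, 2L]; cc <- f[i, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[4L * i - 3L, ] <- c(a, ab, ca)
      nf[4L * i - 2L, ] <- c(b, bc, ab)
      nf[4L * i - 1L, ] <- c(cc, ca, bc)
      nf[4L * i, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- nf
    s <- s + 1L
  }
  r <- sqrt(rowSums(v * v))
  v <- v / r  # project to unit sphere
  m <- trimesh(v, f, validate = FALSE)
  if (unit_edge) {
    scale <- 1 / mean(edge_lengths(m))
  } else {
    scale <- target_radius
  }
  m$vertices <- m$vertices * scale
  attr(m, "mean_edge") <- mean(edge_lengths(m))
  validate_trimesh(m)
  m
}
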