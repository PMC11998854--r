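# Topological Monte Carlo moves on a trimesh: edge flip, vertex insertion
# (edge split), vertex removal (degree-4 collapse), with the generation
# probabilities needed by the Metropolis rule.
#
# Generation probabilities are recorded as rates per unit Monte Carlo time
# with the kind-attempt factor included (and the exchange attempt-rate
# prefactor pexchange divided out, since it cancels in the ratio):
#   flip       forward = reverse = 1/E
#   insertion  forward = 1/(W * v_c)          [density in the placement cube]
#              reverse = E' / (2 * W' * n'_rem)
#   removal    forward = E / (2 * W * n_rem)
#              reverse = 1/(W' * v_c)
# where W = N + E * (pflip + 2 * pexchange) is the per-sweep move-slot
# weight, primes denote the post-move mesh, v_c the placement-cube volume
# and n_rem the number of removable (degree-4) vertices. The 1/2 is the
# random choice of re-triangulating diagonal. With these rates,
# gen_ratio = reverse/forward makes the Metropolis rule satisfy detailed
# balance exactly at mu = mu_eq even though N and E fluctuate.

slot_weight_r <- function(n_vertices, n_edges, params) {
  n_vertices + n_edges * (params$pflip + 2 * params$pexchange)
}

# rows of mesh$faces containing both i and j, first the one with directed i->j
edge_face_rows <- function(mesh, i, j) {
  f <- mesh$faces
  has <- which(rowSums(f == i) + rowSums(f == j) == 2L)
  if (length(has) != 2L) stop("edge does not border exactly 2 faces")
  dir_ij <- vapply(has, function(r) {
    t <- f[r, ]
    any(t == i & t[c(2L, 3L, 1L)] == j)
  }, logical(1))
  c(has[dir_ij], has[!dir_ij])
}

third_vertex <- function(face_row, i, j) face_row[face_row != i & face_row != j]

new_proposal <- function(kind, valid, reason = NULL, ...) {
  structure(c(list(kind = kind, valid = valid, reason = reason), list(...)),
            class = "topology_proposal")
}

#' @export
print.topology_proposal <- function(x, ...) {
  cat(sprintf("topology proposal: %s (%s)\n", x$kind,
              if (x$valid) "valid" else paste0("rejected: ", x$reason)))
  if (x$valid)
    cat(sprintf("  Pgen forward %.3g, reverse %.3g, ratio %.3g\n",
                x$p_gen_forward, x$p_gen_reverse, x$gen_ratio))
  invisible(x)
}

#' Propose an edge flip
#'
#' Selects an edge uniformly at random and proposes replacing it by the
#' opposite diagonal of the two adjacent triangles. The proposal is invalid
#' if the diagonal already exists or if either endpoint would drop below
#' degree 3. Forward and reverse generation probabilities are both 1/E, so
#' the generation ratio is 1.
#'
#' @param mesh a `trimesh`.
#' @param params a [sim_params()] list (attempt-rate factors).
#' @return a `topology_proposal`.
#' @export
propose_edge_flip <- function(mesh, params = sim_params()) {
  e <- mesh_edges(mesh)
  E <- nrow(e)
  pick <- e[sample.int(E, 1L), ]
  i <- pick[1L]; j <- pick[2L]
  fr <- edge_face_rows(mesh, i, j)
  k <- third_vertex(mesh$faces[fr[1L], ], i, j)
  l <- third_vertex(mesh$faces[fr[2L], ], i, j)
  deg <- mesh_degrees(mesh)
  if (k == l)
    return(new_proposal("flip", FALSE, "degenerate opposite vertices"))
  if (any(rowSums(e == k) + rowSums(e == l) == 2L))
    return(new_proposal("flip", FALSE, "opposite edge already exists",
                        edge = c(i, j), opposite = c(k, l)))
  if (deg[i] <= 3L || deg[j] <= 3L)
    return(new_proposal("flip", FALSE, "endpoint degree would drop below 3",
                        edge = c(i, j), opposite = c(k, l)))
  new_proposal("flip", TRUE, edge = c(i, j), opposite = c(k, l),
               face_rows = fr, p_gen_forward = 1 / E, p_gen_reverse = 1 / E,
               gen_ratio = 1)
}

#' Propose a vertex insertion (edge split)
#'
#' Selects an edge uniformly at random and proposes splitting it: a new
#' vertex, placed uniformly inside a cube of half-width
#' `params$insert_halfwidth` centred on the edge midpoint, is connected to
#' the edge endpoints and the two opposite vertices (N -> N+1, E -> E+3,
#' F -> F+2). The reverse generation probability is the rate with which
#' [propose_vertex_removal()] would regenerate the pre-move mesh.
#'
#' @inheritParams propose_edge_flip
#' @return a `topology_proposal`.
#' @export
propose_vertex_insertion <- function(mesh, params = sim_params()) {
  e <- mesh_edges(mesh)
  E <- nrow(e)
  N <- nrow(mesh$vertices)
  if (params$max_vertices > 0 && N >= params$max_vertices)
    return(new_proposal("insert", FALSE, "at max_vertices"))
  pick <- e[sample.int(E, 1L), ]
  i <- pick[1L]; j <- pick[2L]
  fr <- edge_face_rows(mesh, i, j)
  k <- third_vertex(mesh$faces[fr[1L], ], i, j)
  l <- third_vertex(mesh$faces[fr[2L], ], i, j)
  delta <- params$insert_halfwidth
  vc <- (2 * delta)^3
  pos <- (mesh$vertices[i, ] + mesh$vertices[j, ]) / 2 +
    runif(3L, -delta, delta)
  W <- slot_weight_r(N, E, params)
  Ep <- E + 3L
  deg <- mesh_degrees(mesh)
  # removable count on the post-move mesh: the new vertex has degree 4;
  # k and l gain one edge (degree-4 k/l leave the class; degree-3 enter)
  n_rem_after <- sum(deg[-c(k, l)] == 4L) + sum(deg[c(k, l)] == 3L) + 1L
  Wp <- slot_weight_r(N + 1L, Ep, params)
  new_proposal("insert", TRUE, edge = c(i, j), opposite = c(k, l),
               face_rows = fr, position = pos,
               p_gen_forward = 1 / (W * vc),
               p_gen_reverse = Ep / (2 * Wp * n_rem_after),
               gen_ratio = Ep * W * vc / (2 * Wp * n_rem_after))
}

# oriented link cycle (c1, c2, c3, c4) of a degree-4 vertex, with the face
# rows fv[q] = face (v, c[q], c[q+1])
link_cycle_r <- function(mesh, v) {
  f <- mesh$faces
  rows <- which(rowSums(f == v) == 1L)
  if (length(rows) != 4L) return(NULL)
  cyc <- integer(4L)
  fvr <- integer(4L)
  # successor of neighbour a in face (v, a, b): directed edge a -> b
  succ <- function(a) {
    for (r in rows) {
      t <- f[r, ]
      p <- which(t == v)
      nxt <- t[c(2L, 3L, 1L)[p]]
      if (nxt == a) return(c(t[c(3L, 1L, 2L)[p]], r))  # wrong direction helper
    }
    NULL
  }
  # face with directed edge v -> a contains (v, a, succ)
  step <- function(a) {
    for (r in rows) {
      t <- f[r, ]
      p <- which(t == v)
      if (t[c(2L, 3L, 1L)[p]] == a) return(c(t[c(3L, 1L, 2L)[p]], r))
    }
    NULL
  }
  a <- f[rows[1L], ][f[rows[1L], ] != v][1L]
  for (q in 1:4) {
    sr <- step(a)
    if (is.null(sr)) return(NULL)
    cyc[q] <- a
    fvr[q] <- sr[2L]
    a <- sr[1L]
  }
  if (a != cyc[1L]) return(NULL)
  list(cycle = cyc, face_rows = fvr)
}

#' Propose a vertex removal (degree-4 collapse)
#'
#' Selects uniformly among removable vertices (degree exactly 4, the exact
#' inverse class of insertion), picks one of the two re-triangulating
#' diagonals of the quadrilateral hole at random, and proposes removing the
#' vertex. The proposal is invalid if no removable vertex exists, N is at
#' the configured minimum, the diagonal already exists, an opposite vertex
#' would drop below degree 3, or the vertex lies outside the insertion cube
#' of the chosen diagonal (in which case the reverse insertion could never
#' regenerate it and reversibility would be broken).
#'
#' @inheritParams propose_edge_flip
#' @return a `topology_proposal`.
#' @export
propose_vertex_removal <- function(mesh, params = sim_params()) {
  deg <- mesh_degrees(mesh)
  removable <- which(deg == 4L)
  n_rem <- length(removable)
  N <- nrow(mesh$vertices)
  if (n_rem == 0L)
    return(new_proposal("remove", FALSE, "no removable (degree-4) vertex"))
  if (N <= params$min_vertices)
    return(new_proposal("remove", FALSE, "at min_vertices"))
  v <- removable[sample.int(n_rem, 1L)]
  lc <- link_cycle_r(mesh, v)
  if (is.null(lc))
    return(new_proposal("remove", FALSE, "link of vertex is not a 4-cycle"))
  cyc <- lc$cycle
  if (runif(1L) < 0.5) cyc <- cyc[c(2L, 3L, 4L, 1L)]
  d1 <- cyc[1L]; o1 <- cyc[2L]; d2 <- cyc[3L]; o2 <- cyc[4L]
  e <- mesh_edges(mesh)
  if (any(e[, 1L] == min(d1, d2) & e[, 2L] == max(d1, d2)))
    return(new_proposal("remove", FALSE, "diagonal already exists",
                        vertex = v, diagonal = c(d1, d2)))
  if (deg[o1] <= 3L || deg[o2] <= 3L)
    return(new_proposal("remove", FALSE, "opposite vertex degree would drop below 3",
                        vertex = v, diagonal = c(d1, d2)))
  delta <- params$insert_halfwidth
  mid <- (mesh$vertices[d1, ] + mesh$vertices[d2, ]) / 2
  if (any(abs(mesh$vertices[v, ] - mid) >= delta))
    return(new_proposal("remove", FALSE, "vertex outside insertion cube of diagonal",
                        vertex = v, diagonal = c(d1, d2)))
  E <- nrow(e)
  W <- slot_weight_r(N, E, params)
  Wp <- slot_weight_r(N - 1L, E - 3L, params)
  vc <- (2 * delta)^3
  new_proposal("remove", TRUE, vertex = v, diagonal = c(d1, d2),
               opposite = c(o1, o2), cycle = cyc,
               p_gen_forward = E / (2 * W * n_rem),
               p_gen_reverse = 1 / (Wp * vc),
               gen_ratio = 2 * W * n_rem / (Wp * vc * E))
}

#' Apply a valid topology proposal to a mesh
#'
#' @param mesh a `trimesh`.
#' @param proposal a valid `topology_proposal` from one of the `propose_*`
#'   functions.
#' @return the modified `trimesh` (a new object; meshes are immutable).
#' @export
apply_proposal <- function(mesh, proposal) {
  if (!isTRUE(proposal$valid)) stop("cannot apply an invalid proposal")
  f <- mesh$faces
  v <- mesh$vertices
  if (proposal$kind == "flip") {
    i <- proposal$edge[1L]; j <- proposal$edge[2L]
    k <- proposal$opposite[1L]; l <- proposal$opposite[2L]
    fr <- proposal$face_rows
    f[fr[1L], ] <- c(k, i, l)
    f[fr[2L], ] <- c(l, j, k)
  } else if (proposal$kind == "insert") {
    i <- proposal$edge[1L]; j <- proposal$edge[2L]
    k <- proposal$opposite[1L]; l <- proposal$opposite[2L]
    fr <- proposal$face_rows
    nv <- nrow(v) + 1L
    v <- rbind(v, proposal$position)
    f[fr[1L], ] <- c(i, nv, k)
    f[fr[2L], ] <- c(nv, j, k)
    f <- rbind(f, c(j, nv, l), c(nv, i, l))
  } else if (proposal$kind == "remove") {
    vid <- proposal$vertex
    cyc <- proposal$cycle
    d1 <- cyc[1L]; o1 <- cyc[2L]; d2 <- cyc[3L]; o2 <- cyc[4L]
    rows <- which(rowSums(f == vid) == 1L)
    f <- f[-rows, , drop = FALSE]
    f <- rbind(f, c(d1, o1, d2), c(d1, d2, o2))
    v <- v[-vid, , drop = FALSE]
    f[f > vid] <- f[f > vid] - 1L
  } else stop("unknown proposal kind")
  rownames(v) <- NULL
  trimesh(v, f, validate = FALSE)
}
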