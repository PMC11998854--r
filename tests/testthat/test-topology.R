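# Topological move proposals: validity screens, generation-probability
# bookkeeping, and exact reversibility.

test_that("every edge flip on a tetrahedron is invalid", {
  tet <- tetrahedron_mesh()
  set.seed(1)
  for (i in 1:20) {
    pr <- propose_edge_flip(tet)
    expect_false(pr$valid)
  }
})

test_that("a flip applied twice restores the original adjacency", {
  m <- build_icosphere(1, unit_edge = TRUE)
  set.seed(7)
  pr <- NULL
  for (i in 1:100) {
    pr <- propose_edge_flip(m)
    if (pr$valid) break
  }
  expect_true(pr$valid)
  expect_equal(pr$gen_ratio, 1)
  m2 <- apply_proposal(m, pr)
  expect_equal(euler_characteristic(m2), 2L)
  # reverse flip: the new edge is the former opposite pair
  rev <- list(kind = "flip", valid = TRUE,
              edge = sort(pr$opposite), opposite = pr$edge,
              face_rows = vesiclegrowth:::edge_face_rows(m2, pr$opposite[1],
                                                         pr$opposite[2]))
  m3 <- apply_proposal(m2, rev)
  expect_equal(mesh_edges(m3), mesh_edges(m))
})

test_that("edge selection is uniform over the edge list", {
  m <- build_icosphere(1, unit_edge = TRUE)
  e <- mesh_edges(m)
  E <- nrow(e)
  set.seed(42)
  counts <- integer(E)
  n <- 4000L
  for (i in seq_len(n)) {
    pr <- propose_vertex_insertion(m)
    idx <- which(e[, 1] == pr$edge[1] & e[, 2] == pr$edge[2])
    counts[idx] <- counts[idx] + 1L
  }
  # chi-squared against uniform; generous threshold (far beyond 4 SE)
  chi <- sum((counts - n / E)^2 / (n / E))
  expect_lt(chi, qchisq(1 - 1e-6, df = E - 1))
})

test_that("insertion bookkeeping: counts, degree, and exact inverse", {
  m <- build_icosphere(0, unit_edge = TRUE)  # icosahedron
  set.seed(3)
  pr <- propose_vertex_insertion(m)
  expect_true(pr$valid)
  m2 <- apply_proposal(m, pr)
  expect_equal(nrow(m2$vertices), 13L)
  expect_equal(nrow(mesh_edges(m2)), 33L)
  expect_equal(nrow(m2$faces), 22L)
  expect_equal(euler_characteristic(m2), 2L)
  expect_equal(mesh_degrees(m2)[13L], 4L)
  validate_trimesh(m2)
  # removal of the inserted vertex along the original edge restores adjacency
  lc <- vesiclegrowth:::link_cycle_r(m2, 13L)
  cyc <- lc$cycle
  # rotate the cycle so the diagonal is the original split edge
  if (!all(sort(cyc[c(1, 3)]) == sort(pr$edge))) cyc <- cyc[c(2, 3, 4, 1)]
  expect_equal(sort(cyc[c(1, 3)]), sort(pr$edge))
  rem <- list(kind = "remove", valid = TRUE, vertex = 13L, cycle = cyc)
  m3 <- apply_proposal(m2, rem)
  expect_equal(mesh_edges(m3), mesh_edges(m))
  expect_equal(m3$vertices, m$vertices, ignore_attr = TRUE)
})

test_that("removal is rejected when no degree-4 vertex exists", {
  m <- build_icosphere(1, unit_edge = TRUE)  # all degrees 5 or 6
  set.seed(2)
  pr <- propose_vertex_removal(m)
  expect_false(pr$valid)
  expect_match(pr$reason, "removable")
})

test_that("recorded reverse-generation rate matches the removal rate on the new mesh", {
  m <- build_icosphere(1, unit_edge = TRUE)
  p <- sim_params()
  set.seed(11)
  for (rep in 1:10) {
    pr <- propose_vertex_insertion(m, p)
    m2 <- apply_proposal(m, pr)
    # enumerate the post-move mesh directly
    E2 <- nrow(mesh_edges(m2))
    n_rem2 <- sum(mesh_degrees(m2) == 4L)
    W2 <- vesiclegrowth:::slot_weight_r(nrow(m2$vertices), E2, p)
    expect_equal(pr$p_gen_reverse, E2 / (2 * W2 * n_rem2), tolerance = 1e-12)
  }
})

test_that("random insert/flip/remove sequences preserve the manifold invariants", {
  m <- build_icosphere(1, unit_edge = TRUE)
  p <- sim_params()
  set.seed(19)
  nacc <- 0L
  for (i in 1:400) {
    kind <- sample(c("flip", "insert", "remove"), 1L)
    pr <- switch(kind,
                 flip = propose_edge_flip(m, p),
                 insert = propose_vertex_insertion(m, p),
                 remove = propose_vertex_removal(m, p))
    if (!pr$valid) next
    m <- apply_proposal(m, pr)
    nacc <- nacc + 1L
    expect_equal(euler_characteristic(m), 2L)
  }
  expect_gt(nacc, 100L)
  validate_trimesh(m)
  expect_true(min(mesh_degrees(m)) >= 3L)
})
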