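test_that("icosphere construction has the right combinatorics", {
  ico <- build_icosphere(0, target_radius = 1)
  expect_equal(nrow(ico$vertices), 12L)
  expect_equal(nrow(mesh_edges(ico)), 30L)
  expect_equal(nrow(ico$faces), 20L)
  expect_equal(euler_characteristic(ico), 2L)
  for (s in 0:3) {
    m <- build_icosphere(s, target_radius = 2)
    expect_equal(nrow(m$vertices), 10L * 4L^s + 2L)
    expect_equal(euler_characteristic(m), 2L)
    # all vertices exactly on the target sphere, so mean radius matches
    expect_lt(abs(mesh_mean_radius(m) - 2) / 2, 0.01)
  }
})

test_that("unit-edge icosphere at s=4 approximates the standard vesicle size", {
  m <- cached("ico4", build_icosphere(4, unit_edge = TRUE))
  expect_equal(mean(edge_lengths(m)), 1, tolerance = 1e-9)
  r <- mesh_mean_radius(m)
  # radius over mean edge length ~ 15; the pristine (unthermalised)
  # icosphere sits a little above because edge lengths vary across the mesh
  expect_lt(abs(r - 15) / 15, 0.15)
})

test_that("enclosed volume matches known solids and is translation invariant", {
  cm <- cube_mesh()
  expect_equal(enclosed_volume(cm), 1.0, tolerance = 1e-12)
  cm2 <- cm
  cm2$vertices <- sweep(cm2$vertices, 2L, c(17.3, -4.2, 0.9), "+")
  expect_equal(enclosed_volume(cm2), 1.0, tolerance = 1e-9)
  # icosphere volume below the circumscribed sphere, converging with level
  R <- 3
  vols <- vapply(1:4, function(s)
    enclosed_volume(build_icosphere(s, target_radius = R)), numeric(1))
  vsph <- 4 / 3 * pi * R^3
  expect_true(all(vols < vsph))
  expect_true(all(diff(vols) > 0))
  expect_lt((vsph - vols[4]) / vsph, 0.01)
})

test_that("mesh validation catches broken meshes", {
  m <- build_icosphere(1)
  expect_true(validate_trimesh(m))
  # open surface: drop one face
  bad <- trimesh(m$vertices, m$faces[-1, , drop = FALSE], validate = FALSE)
  expect_error(validate_trimesh(bad), "manifold")
  # inconsistent orientation: flip one face's winding
  bad2 <- m
  bad2$faces[3, ] <- bad2$faces[3, c(1, 3, 2)]
  expect_error(validate_trimesh(bad2), "orientation")
})

test_that("OFF and PLY snapshots round-trip", {
  m <- build_icosphere(1, target_radius = 4.2)
  for (writer in list(write_off, write_ply)) {
    path <- tempfile()
    writer(m, path)
    m2 <- read_mesh(path)
    expect_equal(m2$vertices, m$vertices, tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(m2$faces, m$faces, ignore_attr = TRUE)
    unlink(path)
  }
})
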