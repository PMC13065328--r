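# small flat mesh in the z = 0 plane: a grid of triangles
flat_mesh <- function(nx = 5, ny = 5, h = 0.01) {
  g <- expand.grid(x = 0:(nx - 1), y = 0:(ny - 1))
  verts <- cbind(g$x * h, g$y * h, 0)
  faces <- NULL
  id <- function(i, j) (j - 1) * nx + i
  for (j in 1:(ny - 1)) for (i in 1:(nx - 1)) {
    faces <- rbind(faces,
                   c(id(i, j), id(i + 1, j), id(i, j + 1)),
                   c(id(i + 1, j), id(i + 1, j + 1), id(i, j + 1)))
  }
  cortical_mesh(verts, faces, rep("left", nrow(verts)))
}

test_that("projection lands on vertices, feet of perpendiculars, and breaks ties low", {
  mesh <- flat_mesh()
  v7 <- mesh$vertices[7, ]
  contacts <- data.frame(
    x = c(v7[1], 0.013, 0.02),
    y = c(v7[2], 0.012, 0.02),
    z = c(0, 0.005, 0.004),   # on-vertex; above interior; above a vertex
    hemisphere = "left")
  pr <- project_to_surface(contacts, mesh)
  expect_equal(pr$points[1, ], v7)
  expect_equal(pr$points[2, ], c(0.013, 0.012, 0), tolerance = 1e-12)
  expect_equal(pr$dist[2], 0.005)
  # directly above a shared vertex: equidistant faces, lowest index wins
  expect_equal(pr$points[3, ], c(0.02, 0.02, 0), tolerance = 1e-12)
  expect_equal(pr$face[3],
               min(which(apply(mesh$faces, 1, function(f)
                 any(apply(mesh$vertices[f, ], 1, function(p)
                   all(p == c(0.02, 0.02, 0))))))))
})

test_that("far-away contacts are excluded with a warning", {
  mesh <- flat_mesh()
  contacts <- data.frame(x = 0.01, y = 0.01, z = 0.5, hemisphere = "left")
  expect_warning(pr <- project_to_surface(contacts, mesh), "excluded")
  expect_true(pr$excluded[1])
})

test_that("geodesics on a flat mesh are Euclidean and zero on the diagonal", {
  mesh <- flat_mesh(7, 7)
  contacts <- data.frame(x = c(0.004, 0.051, 0.004),
                         y = c(0.003, 0.044, 0.003),
                         z = 0, hemisphere = "left")
  pr <- project_to_surface(contacts, mesh)
  D <- geodesic_distances(mesh, pr, n_steiner = 8L)
  expect_equal(D[1, 3], 0)
  expect_equal(D[1, 1], 0)
  eu <- sqrt((0.051 - 0.004)^2 + (0.044 - 0.003)^2)
  expect_lt(abs(D[1, 2] - eu) / eu, 0.01)
})

test_that("icosphere geodesics match the great-circle arc within 1%", {
  mesh <- make_spheroid_mesh(radius = 1, distortion = 0,
                             subdivisions = 4L, gap = 0.5)
  ctr <- c(-(1 + 0.25), 0, 0)
  th <- c(0.3, 2.2); ph <- c(0.5, 1.8)
  pts <- cbind(ctr[1] + sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  contacts <- data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                         hemisphere = "left")
  pr <- suppressWarnings(project_to_surface(contacts, mesh, max_dist = Inf))
  D <- geodesic_distances(mesh, pr)
  u1 <- pts[1, ] - ctr; u2 <- pts[2, ] - ctr
  arc <- acos(sum(u1 * u2) / sqrt(sum(u1^2) * sum(u2^2)))
  expect_lt(abs(D[1, 2] - arc) / arc, 0.01)
})

test_that("cross-hemisphere distances are undefined", {
  mesh <- make_spheroid_mesh(radius = 0.05, subdivisions = 2L)
  contacts <- data.frame(x = c(-0.1, 0.1), y = 0, z = 0,
                         hemisphere = c("left", "right"))
  pr <- suppressWarnings(project_to_surface(contacts, mesh, max_dist = Inf))
  D <- geodesic_distances(mesh, pr)
  expect_identical(D[1, 2], Inf)
})

test_that("planar embedding reproduces the edge lengths exactly", {
  e <- planar_embed(3, 4, 5)
  expect_equal(sqrt(sum((e$B - e$A)^2)), 3, tolerance = 1e-12)
  expect_equal(sqrt(sum((e$C - e$B)^2)), 4, tolerance = 1e-12)
  expect_equal(sqrt(sum((e$C - e$A)^2)), 5, tolerance = 1e-12)
  expect_gt(e$C[2], 0)
  eq <- planar_embed(2, 2, 2)
  expect_equal(eq$C, c(1, sqrt(3)), tolerance = 1e-12)
  expect_error(planar_embed(1, 1, 2.5), "triangle inequality")
})

test_that("triangle acceptance follows the minimum-angle rule", {
  D <- matrix(0, 3, 3)
  set_d <- function(d12, d23, d13) {
    D <<- matrix(0, 3, 3)
    D[1, 2] <<- D[2, 1] <<- d12
    D[2, 3] <<- D[3, 2] <<- d23
    D[1, 3] <<- D[3, 1] <<- d13
  }
  set_d(0.02, 0.02, 0.02)
  expect_equal(nrow(enumerate_triangles(D, rep("left", 3))$triangles), 1)
  set_d(0.01, 0.01, 0.02)  # collinear
  expect_equal(nrow(enumerate_triangles(D, rep("left", 3))$triangles), 0)
  set_d(1, 1, 1.8)  # most acute angle acos(0.9) ~ 25.8 degrees
  expect_equal(nrow(enumerate_triangles(D, rep("left", 3))$triangles), 0)
  set_d(0.01, 0.01, 0.025)  # violates the triangle inequality
  out <- enumerate_triangles(D, rep("left", 3))
  expect_equal(nrow(out$triangles), 0)
  expect_equal(out$n_rejected_inequality, 1)
})

test_that("enumeration matches a brute-force oracle and is monotone in angle_min", {
  set.seed(11)
  n <- 25
  pts <- cbind(runif(n, 0, 0.1), runif(n, 0, 0.1))
  D <- as.matrix(dist(pts))
  out <- enumerate_triangles(D, rep("left", n))
  # independent oracle: direct loop over triples with planar angles
  cnt <- 0
  for (a in 1:(n - 2)) for (b in (a + 1):(n - 1)) for (c in (b + 1):n) {
    e <- sort(c(D[a, b], D[b, c], D[c, a]))
    ang <- acos(min(1, max(-1, (e[2]^2 + e[3]^2 - e[1]^2) / (2 * e[2] * e[3]))))
    if (ang > pi / 4) cnt <- cnt + 1
  }
  expect_equal(nrow(out$triangles), cnt)
  n60 <- nrow(enumerate_triangles(D, rep("left", n), pi / 3)$triangles)
  expect_lte(n60, nrow(out$triangles))
  # embedded edges reproduce the geodesic lengths
  tr <- out$triangles
  expect_equal(sqrt((tr$cx - tr$bx)^2 + tr$cy^2), tr$bc, tolerance = 1e-12)
  expect_equal(sqrt(tr$cx^2 + tr$cy^2), tr$ca, tolerance = 1e-12)
})

test_that("size bins spread the triangles into an effective uniform distribution", {
  set.seed(12)
  n <- 20
  pts <- cbind(runif(n, 0, 0.08), runif(n, 0, 0.08))
  D <- as.matrix(dist(pts))
  tri <- bin_triangles(enumerate_triangles(D, rep("left", n)))
  tr <- tri$triangles
  nt_sum <- tapply(tr$n_t, tr$size_bin, sum)
  expect_true(all(abs(nt_sum - 1) < 1e-12))
  # all triangles forced into one bin -> every weight 1/m
  tri1 <- tri
  m <- nrow(tr)
  one <- enumerate_triangles(D, rep("left", n))
  one$triangles$xi <- 50  # all identical sizes
  b1 <- bin_triangles(one)
  expect_equal(b1$triangles$n_t, rep(1 / m, m))
  # a 0.5 cm triangle lands in the undersized bin
  tiny <- enumerate_triangles(as.matrix(dist(rbind(c(0, 0), c(0.005, 0),
                                                   c(0.0025, 0.00433)))),
                              rep("left", 3))
  bt <- bin_triangles(tiny)
  expect_equal(bt$triangles$size_bin, 33L)
})
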