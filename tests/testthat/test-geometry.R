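test_that("generated closed surfaces satisfy closedness, orientation and volume", {
  for (s in list(unit_sphere(1), unit_sphere(2),
                 ellipsoid_surface(c(38, 35, 55), c(10, -5, 2), subdiv = 2))) {
    expect_true(validate_surface(s))
    expect_identical(euler_characteristic(s), 2L)
    expect_gt(enclosed_volume(s), 0)
  }
})

test_that("mesh refinement converges monotonically to analytic ellipsoid area and volume", {
  a <- c(1.3, 1.0, 1.9)
  area_true <- oracle_ellipsoid_area(a[1], a[2], a[3])
  vol_true <- 4 / 3 * pi * prod(a)
  areas <- vols <- numeric(4)
  for (k in 1:4) {
    s <- ellipsoid_surface(a, subdiv = k)
    areas[k] <- surface_area(s)
    vols[k] <- enclosed_volume(s)
  }
  # inscribed polyhedra underestimate; errors must shrink monotonically
  expect_true(all(diff(abs(areas - area_true)) < 0))
  expect_true(all(diff(abs(vols - vol_true)) < 0))
  # doubling the resolution at study scale changes the area by < 1%
  expect_lt(abs(areas[4] - areas[3]) / areas[3], 0.01)
  expect_lt(abs(areas[4] - area_true) / area_true, 0.005)
})

test_that("ventricle construction yields valid classified components", {
  vent <- coarse_setup()$ventricle
  expect_gte(nrow(vent$surface$vertices), 200)
  # each component closed, genus 0; cavity shells flipped in the combined mesh
  for (cmp in vent$components) {
    expect_true(validate_surface(cmp))
    expect_identical(euler_characteristic(cmp), 2L)
  }
  expect_setequal(levels(vent$node_class),
                  c("epicardial", "endocardial", "septal"))
  expect_false(any(is.na(vent$node_class)))
  # fiber directions are unit vectors
  expect_lt(max(abs(sqrt(rowSums(vent$fibers$directions^2)) - 1)), 1e-9)
  # wall-depth coordinate inside [0, 1]
  expect_true(all(vent$sampling$depth >= 0 & vent$sampling$depth <= 1))
})

test_that("degenerate fiber rotation gives depth-independent directions", {
  # identical positions evaluated at endocardial and epicardial depth:
  # with rotation 0 the helix angle vanishes and the direction is purely
  # circumferential, so depth cannot matter
  set.seed(21)
  th <- runif(6, 0, 2 * pi); zz <- runif(6, -30, 30)
  pts <- cbind(20 * cos(th), 20 * sin(th), zz)
  f_endo <- rule_based_fibers(pts, rep(0, 6), c(30, 30, 45), c(0, 0, 0),
                              rotation = 0)
  f_epi <- rule_based_fibers(pts, rep(1, 6), c(30, 30, 45), c(0, 0, 0),
                             rotation = 0)
  expect_equal(f_endo$directions, f_epi$directions, tolerance = 1e-12)
  # with rotation, the same points at different depth disagree
  g_endo <- rule_based_fibers(pts, rep(0, 6), c(30, 30, 45), c(0, 0, 0),
                              rotation = 120)
  expect_gt(max(abs(g_endo$directions - f_epi$directions)), 0.1)
})

test_that("extreme wall parameters are rejected with a diagnostic", {
  expect_error(build_ventricle(wall_thickness = 40), "short axis")
  expect_error(build_ventricle(axes = c(38, 35, 55), wall_thickness = 26,
                               subdiv = c(epi = 1, lv = 1, rv = 1),
                               grid_spacing = 6),
               "cavity|vanish")
})

test_that("surface Laplacian is symmetric, zero-row-sum and annihilates linear fields on flat patches", {
  vent <- coarse_setup()$ventricle
  L <- surface_laplacian(vent$surface)
  expect_lt(max(abs(L - Matrix::t(L))), 1e-12)
  expect_lt(max(abs(Matrix::rowSums(L))), 1e-12)
  tau_const <- rep(3.7, nrow(vent$surface$vertices))
  expect_lt(max(abs(L %*% tau_const)), 1e-10)
  # flat regular patch: linear field annihilated in the interior
  p <- flat_patch(12, 12)
  Lp <- surface_laplacian(list(vertices = p$vertices, faces = p$faces))
  lin <- 2.5 * p$vertices[, 1] - 1.2 * p$vertices[, 2]
  expect_lt(max(abs((Lp %*% lin)[p$interior])), 1e-8)
})

test_that("geodesic graph distances behave like a metric dominated by Euclidean distance", {
  su <- coarse_setup()
  gg <- su$graph
  expect_equal(igraph::components(gg$graph)$no, 1)
  set.seed(11)
  pairs <- cbind(sample(gg$n_nodes, 20), sample(gg$n_nodes, 20))
  v <- su$ventricle$surface$vertices
  d <- geodesic_distances(gg, from = pairs[, 1])
  for (i in seq_len(20)) {
    eu <- sqrt(sum((v[pairs[i, 1], ] - v[pairs[i, 2], ])^2))
    expect_gte(d[i, pairs[i, 2]] + 1e-9, eu)
  }
})

test_that("line-graph shortest paths equal cumulative edge lengths", {
  gg <- structure(list(
    graph = igraph::graph_from_edgelist(cbind(1:2, 2:3), directed = FALSE),
    edges = data.frame(from = 1:2, to = 2:3, length_mm = c(1, 1),
                       transmural = c(FALSE, FALSE)),
    n_nodes = 3L), class = "geodesic_graph")
  expect_equal(as.numeric(geodesic_distances(gg, from = 1)), c(0, 1, 2))
  tau <- fra_candidates(gg, v_surface = 1, v_transmural = 1, candidates = 1L)
  expect_equal(as.numeric(tau), c(0, 1, 2))
})

test_that("transmural pairs link endocardial nodes to nearest epicardial nodes", {
  vent <- coarse_setup()$ventricle
  tp <- transmural_pairs(vent)
  expect_true(all(vent$node_class[tp[, 1]] != "epicardial"))
  expect_true(all(vent$node_class[tp[, 2]] == "epicardial"))
  d <- sqrt(rowSums((vent$surface$vertices[tp[, 1], ] -
                     vent$surface$vertices[tp[, 2], ])^2))
  expect_lt(max(d), 40)   # links cross the wall, not the whole chamber
})
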