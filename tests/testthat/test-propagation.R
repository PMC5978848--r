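# a minimal stand-in wall: a cubic grid block with a uniform fiber field,
# enough for the low-level propagation and source machinery
block_ventricle <- function(n = 9, h = 1, fiber = c(1, 0, 0)) {
  g <- as.matrix(expand.grid(i = seq_len(n), j = seq_len(n), k = seq_len(n)))
  pos <- (g - 1) * h
  smp <- list(positions = pos, grid_index = g, spacing = h, dV = h^3,
              depth = rep(0.5, nrow(pos)),
              nearest_surface_node = rep(1L, nrow(pos)),
              surface_to_sample = 1L, n = nrow(pos),
              fiber = matrix(fiber / sqrt(sum(fiber^2)), nrow(pos), 3,
                             byrow = TRUE))
  list(sampling = smp,
       surface = list(vertices = pos[1, , drop = FALSE]),
       params = list(center = colMeans(pos)))
}

test_that("isotropic propagation reproduces Euclidean travel times on a convex block", {
  bv <- block_ventricle(n = 9, h = 1)
  ctr <- bv$sampling$positions[365, ]   # center of the 9^3 block
  st <- stimulus_set(rbind(ctr), radius = 0.1)
  act <- anisotropic_activation(bv, st, v_t = 1, k = 1)
  d <- sqrt(rowSums(sweep(bv$sampling$positions, 2, ctr, `-`)^2))
  # 26-neighborhood graph metric error is bounded (~8% worst case off-lattice)
  expect_true(all(act$tau_vol + 1e-9 >= d))
  expect_lt(max(act$tau_vol - d), 0.09 * max(d) + 1e-9)
  expect_identical(act$tau_vol[365], 0)
})

test_that("along-fiber speed is k*v_t: 6 mm along the fiber at k=3 takes 2 ms", {
  bv <- block_ventricle(n = 9, h = 1, fiber = c(1, 0, 0))
  start <- which(apply(bv$sampling$positions, 1,
                       function(p) all(p == c(1, 4, 4))))
  target <- which(apply(bv$sampling$positions, 1,
                        function(p) all(p == c(7, 4, 4))))
  st <- stimulus_set(rbind(bv$sampling$positions[start, ]), radius = 0.1)
  act <- anisotropic_activation(bv, st, v_t = 1, k = 3)
  expect_equal(act$tau_vol[target], 2, tolerance = 1e-12)
  # purely transverse target: on the 26-neighborhood lattice the optimal
  # route zig-zags at 45 degrees to exploit the fast fiber axis, so the
  # travel time is 4 * sqrt(2)/sqrt(1 + (k^2-1)/2) rather than 4/v_t
  across <- which(apply(bv$sampling$positions, 1,
                        function(p) all(p == c(1, 8, 4))))
  expect_equal(act$tau_vol[across], 4 * sqrt(2) / sqrt(5), tolerance = 1e-12)
})

test_that("propagation equals an exhaustive Dijkstra oracle on the same graph", {
  vent <- single_ventricle()
  st <- stimulus_set(rbind(vent$sampling$positions[17, ]), radius = 0.1)
  act <- anisotropic_activation(vent, st, v_t = 0.6, k = 2)
  g <- edlact:::sampling_graph(vent$sampling, v_t = 0.6, k = 2)
  el <- igraph::as_edgelist(g)
  seeds <- edlact:::stimulus_seed_points(vent$sampling, st)
  d <- oracle_dijkstra(vent$sampling$n, el[, 1], el[, 2],
                       igraph::E(g)$cost, seeds$idx[1])
  expect_equal(act$tau_vol, d, tolerance = 1e-12)
})

test_that("activation is edge-Lipschitz and monotone under added seeds", {
  vent <- single_ventricle()
  p1 <- vent$sampling$positions[11, ]
  p2 <- vent$sampling$positions[vent$sampling$n - 5, ]
  a1 <- anisotropic_activation(vent, stimulus_set(rbind(p1)), v_t = 0.5, k = 2)
  a12 <- anisotropic_activation(vent, stimulus_set(rbind(p1, p2)),
                                v_t = 0.5, k = 2)
  expect_true(all(a12$tau_vol <= a1$tau_vol + 1e-9))
  # |tau_i - tau_j| <= edge cost for every graph edge
  g <- edlact:::sampling_graph(vent$sampling, v_t = 0.5, k = 2)
  el <- igraph::as_edgelist(g)
  dtau <- abs(a1$tau_vol[el[, 1]] - a1$tau_vol[el[, 2]])
  expect_true(all(dtau <= igraph::E(g)$cost + 1e-9))
})

test_that("stimulus sets validate onsets and radii", {
  expect_error(stimulus_set(c(0, 0, 0), radius = 0), "radius")
  expect_error(stimulus_set(c(0, 0, 0), onset = -1), "onset")
})

test_that("ectopic pairs sit on opposite wall sides at the same location", {
  vent <- coarse_setup()$ventricle
  ctr <- vent$params$center; a <- vent$params$axes
  pr <- ectopic_pair(vent, c(ctr[1] - 0.88 * a[1], ctr[2], ctr[3]),
                     label = "x")
  smp <- vent$sampling
  d_endo <- smp$depth[which.min(rowSums(sweep(smp$positions, 2,
    as.numeric(pr$endo[1, 1:3]), `-`)^2))]
  d_epi <- smp$depth[which.min(rowSums(sweep(smp$positions, 2,
    as.numeric(pr$epi[1, 1:3]), `-`)^2))]
  expect_lt(d_endo, 0.35)
  expect_gt(d_epi - d_endo, 0.3)
  expect_lt(sqrt(sum((as.numeric(pr$endo[1, 1:3]) -
                      as.numeric(pr$epi[1, 1:3]))^2)), 20)
  expect_error(ectopic_pair(vent, ctr + c(0, 0, 200)), "outside")
})

test_that("septal pair lands on opposite septal faces", {
  vent <- coarse_setup()$ventricle
  ctr <- vent$params$center
  pr <- ectopic_pair(vent, ctr + c(-2, 0, -5), mode = "septal")
  cls <- vent$node_class[vent$sampling$nearest_surface_node]
  il <- which.min(rowSums(sweep(vent$sampling$positions, 2,
                                as.numeric(pr$left[1, 1:3]), `-`)^2))
  ir <- which.min(rowSums(sweep(vent$sampling$positions, 2,
                                as.numeric(pr$right[1, 1:3]), `-`)^2))
  expect_identical(as.character(cls[il]), "septal")
  expect_identical(as.character(cls[ir]), "septal")
  expect_lt(vent$sampling$positions[il, 1], ctr[1])
  expect_gt(vent$sampling$positions[ir, 1], ctr[1])
})

test_that("the ectopic catalogue has the eight study scenarios", {
  cat8 <- ectopic_catalogue(coarse_setup()$ventricle)
  expect_length(cat8, 8)
  expect_true(all(vapply(cat8, nrow, 0L) == 1L))  # single-seed scenarios
})

test_that("sinus profile: 4 endocardial/septal seeds, geodesically well separated", {
  su <- coarse_setup()
  sin4 <- sinus_stimuli(su$ventricle)
  expect_identical(nrow(sin4), 4L)
  cls <- su$ventricle$node_class[su$ventricle$sampling$nearest_surface_node]
  idx <- apply(as.matrix(sin4[, 1:3]), 1, function(p)
    which.min(rowSums(sweep(su$ventricle$sampling$positions, 2, p, `-`)^2)))
  expect_true(all(cls[idx] %in% c("endocardial", "septal")))
  sn <- apply(as.matrix(sin4[, 1:3]), 1, function(p)
    which.min(rowSums(sweep(su$ventricle$surface$vertices, 2, p, `-`)^2)))
  gd <- geodesic_distances(su$graph, from = sn)[, sn]
  expect_gt(min(gd[upper.tri(gd)]), 20)
  # n_sites = 1 degenerates to a single ectopic-like stimulus
  s1 <- sinus_stimuli(su$ventricle, n_sites = 1)
  expect_identical(nrow(s1), 1L)
})
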