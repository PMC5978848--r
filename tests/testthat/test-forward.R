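test_that("TMP template is a smooth non-decreasing step with the right limits", {
  tpl <- tmp_template(width = 2)
  x <- seq(-30, 30, by = 0.1)
  expect_true(all(diff(tpl$s(x)) >= 0))
  expect_lt(tpl$s(-30), 1e-9)
  expect_gt(tpl$s(30), 1 - 1e-9)
  # 10-90% rise time equals the nominal width
  sc <- x[min(which(tpl$s(x) >= 0.9))] - x[max(which(tpl$s(x) <= 0.1))]
  expect_equal(sc, 2, tolerance = 0.1)
  # derivative integrates to the unit step
  expect_equal(sum(tpl$ds(x)) * 0.1, 1, tolerance = 1e-6)
  # width 0 is the Heaviside convention, preserving matrix shape
  h <- tmp_template(width = 0)
  m <- h$s(matrix(c(-1, 1, 2, -2), 2))
  expect_identical(dim(m), c(2L, 2L))
  expect_identical(as.vector(m), c(0, 1, 1, 0))
})

test_that("isotropic wavefront dipoles are anti-parallel to the TMP gradient", {
  vent <- single_ventricle()
  st <- stimulus_set(rbind(vent$sampling$positions[31, ]))
  act <- anisotropic_activation(vent, st, v_t = 0.5, k = 1)
  go <- sampling_gradient_operator(vent)
  tpl <- tmp_template(width = 2)
  t0 <- stats::median(act$tau_vol)
  ds <- wavefront_dipoles(act, vent, conductivity_setup("isotropic"), tpl,
                          t = t0, grad_op = go)
  gtau <- cbind(as.numeric(go$Gx %*% act$tau_vol),
                as.numeric(go$Gy %*% act$tau_vol),
                as.numeric(go$Gz %*% act$tau_vol))
  grad_phi <- -tpl$amplitude * tpl$ds(t0 - act$tau_vol) * gtau
  nm <- sqrt(rowSums(ds$moments^2)) * sqrt(rowSums(grad_phi^2))
  act_pts <- which(nm > 1e-6 * max(nm))
  cosines <- rowSums(ds$moments * grad_phi)[act_pts] / nm[act_pts]
  expect_lt(max(cosines), -1 + 1e-9)
})

test_that("fibers orthogonal to the gradient leave the moment at its transversal value", {
  vent <- single_ventricle()
  st <- stimulus_set(rbind(vent$sampling$positions[31, ]))
  act <- anisotropic_activation(vent, st, v_t = 0.5, k = 1)
  go <- sampling_gradient_operator(vent)
  tpl <- tmp_template(width = 2)
  t0 <- stats::median(act$tau_vol)
  iso <- wavefront_dipoles(act, vent, conductivity_setup("isotropic"), tpl,
                           t = t0, grad_op = go)
  # replace each fiber by a unit vector orthogonal to the local moment
  gtau <- iso$moments
  ref <- matrix(c(0, 0, 1), nrow(gtau), 3, byrow = TRUE)
  swap <- abs(gtau[, 3]) > 0.9 * sqrt(rowSums(gtau^2))
  ref[swap, ] <- matrix(c(1, 0, 0), sum(swap), 3, byrow = TRUE)
  perp <- cbind(gtau[, 2] * ref[, 3] - gtau[, 3] * ref[, 2],
                gtau[, 3] * ref[, 1] - gtau[, 1] * ref[, 3],
                gtau[, 1] * ref[, 2] - gtau[, 2] * ref[, 1])
  nrm <- sqrt(rowSums(perp^2))
  ok <- nrm > 1e-12
  perp[ok, ] <- perp[ok, ] / nrm[ok]
  perp[!ok, ] <- matrix(c(1, 0, 0), sum(!ok), 3, byrow = TRUE)
  vent2 <- vent
  vent2$sampling$fiber <- perp
  un <- wavefront_dipoles(act, vent2, conductivity_setup("unequal"), tpl,
                          t = t0, grad_op = go)
  # unequal tensor with sigma_i_t = isotropic sigma: same moments
  expect_equal(un$moments, iso$moments, tolerance = 1e-9)
})

test_that("a fully depolarized spherical region has vanishing net dipole moment", {
  # brute-force summation over a cube-grid ball: the gradient is supported on
  # a closed shell whose vector area is zero
  n <- 13; h <- 1
  g <- as.matrix(expand.grid(i = seq_len(n), j = seq_len(n), k = seq_len(n)))
  pos <- (g - 1) * h
  ctr <- colMeans(pos)
  keep <- sqrt(rowSums(sweep(pos, 2, ctr, `-`)^2)) < 5.5
  smp <- list(positions = pos[keep, ], grid_index = g[keep, ], spacing = h,
              dV = h^3, n = sum(keep),
              fiber = matrix(c(1, 0, 0), sum(keep), 3, byrow = TRUE))
  fake <- list(sampling = smp)
  go <- sampling_gradient_operator(fake)
  tau <- sqrt(rowSums(sweep(smp$positions, 2, ctr, `-`)^2))  # radial front
  act <- structure(list(tau_vol = tau), class = "volume_activation")
  tpl <- tmp_template(width = 1)
  ds <- wavefront_dipoles(act, fake, conductivity_setup("isotropic"), tpl,
                          t = 3, grad_op = go)
  net <- sqrt(sum(colSums(ds$moments)^2))
  total <- sum(sqrt(rowSums(ds$moments^2)))
  expect_lt(net, 1e-6 * total)
})

test_that("measured BSPMs are quiet before activation and linear in the TMP amplitude", {
  su <- coarse_setup()
  vent <- su$ventricle
  st0 <- ectopic_catalogue(vent)$lv_free_wall_endo
  st <- stimulus_set(as.matrix(st0[, 1:3]), onset = 15,
                     radius = st0$radius[1], scenario = "delayed")
  act <- anisotropic_activation(vent, st, v_t = 0.4, k = 1)
  b1 <- simulate_measured_bspm(su$solver, vent, act,
                               conductivity_setup("isotropic"),
                               template = tmp_template(width = 2),
                               dt = 2, noise_sd = 0, grad_op = su$grad_op)
  pre <- b1$times < min(act$tau_vol) - 6
  expect_gt(sum(pre), 0)
  expect_lt(max(abs(b1$phi[, pre])), 1e-3 * max(abs(b1$phi)))
  b2 <- simulate_measured_bspm(su$solver, vent, act,
                               conductivity_setup("isotropic"),
                               template = tmp_template(amplitude = 200,
                                                       width = 2),
                               dt = 2, noise_sd = 0, grad_op = su$grad_op)
  expect_equal(b2$phi, 2 * b1$phi, tolerance = 1e-12)
})

test_that("the three conductivity cases generate mutually distinct BSPMs", {
  su <- coarse_setup()
  vent <- su$ventricle
  st <- ectopic_catalogue(vent)$lv_free_wall_endo
  act <- anisotropic_activation(vent, st, v_t = 0.4, k = 1)
  maps <- lapply(c("isotropic", "equal", "unequal"), function(cs)
    simulate_measured_bspm(su$solver, vent, act, conductivity_setup(cs),
                           template = tmp_template(width = 2), dt = 2,
                           noise_sd = 0, grad_op = su$grad_op))
  expect_gt(rd(maps[[1]]$phi, maps[[2]]$phi), 0.01)
  expect_gt(rd(maps[[1]]$phi, maps[[3]]$phi), 0.01)
  expect_gt(rd(maps[[2]]$phi, maps[[3]]$phi), 0.01)
  # the unequal tensor departs farther from the isotropic map
  expect_gt(rd(maps[[1]]$phi, maps[[3]]$phi), rd(maps[[1]]$phi, maps[[2]]$phi))
})

test_that("the EDL forward obeys step limits and layer closure", {
  su <- coarse_setup()
  n <- su$transfer$n_nodes
  set.seed(2)
  tau <- runif(n, 10, 60)
  tpl <- tmp_template(width = 0)
  b <- edl_forward(su$transfer, tau, tpl, times = c(0, 5, 35, 80))
  expect_identical(max(abs(b$phi[, 1])), 0)      # before the earliest node
  colnorm <- max(sqrt(colSums(su$transfer$A^2)))
  expect_lt(max(abs(b$phi[, 4])), 1e-6 * colnorm)  # closed uniform layer
  expect_gt(max(abs(b$phi[, 3])), 1e-3)
  expect_error(edl_forward(su$transfer, tau[-1], tpl, times = 0:3), "nodes")
})

test_that("a single-column transfer toy reproduces the scaled step", {
  toy <- structure(list(A = matrix(c(1, -1), 2, 1), jump_factor = 0.25,
                        amplitude = 100, n_electrodes = 2L, n_nodes = 1L,
                        heart_label = "toy"),
                   class = "edl_transfer")
  tpl <- tmp_template(width = 2)
  b <- edl_forward(toy, tau = 10, tpl, times = c(0, 10, 20))
  expect_equal(b$phi, matrix(c(1, -1), 2, 1) %*% rbind(tpl$s(c(-10, 0, 10))),
               tolerance = 1e-12)
})

test_that("noise injection is calibrated, seed-reproducible and optional", {
  phi <- matrix(0, 120, 100)
  b <- bspm(phi, seq_len(100), rereference = FALSE)
  expect_identical(add_noise(b, sd = 0)$phi, phi)
  n1 <- add_noise(b, sd = 0.02, seed = 42)
  n2 <- add_noise(b, sd = 0.02, seed = 42)
  expect_identical(n1$phi, n2$phi)
  # sample SD of the injected noise within 5% of 20 uV (1.2e4 entries);
  # re-referencing only removes the per-sample electrode mean
  expect_equal(stats::sd(n1$phi), 0.02, tolerance = 0.05)
})
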