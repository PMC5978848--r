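test_that("fastest-route maps satisfy shortest-path axioms", {
  su <- coarse_setup()
  tc <- su$tau_cand
  cand <- attr(tc, "candidates")
  # tau_f(f) = 0
  expect_identical(max(abs(tc[cbind(seq_along(cand), cand)])), 0)
  # triangle inequality under the weighted metric (spot check)
  set.seed(5)
  f <- sample(nrow(tc), 5)
  for (i in f) {
    m <- sample(ncol(tc), 10)
    for (j in sample(ncol(tc), 10))
      expect_true(all(tc[i, j] <= tc[i, m] + tc[cbind(m, j)] + 1e-9))
  }
})

test_that("fastest-route maps equal an exhaustive Dijkstra oracle on random meshes", {
  for (seed in 1:10) {
    s <- random_mesh(seed)
    # a couple of random extra links play the role of transmural edges
    set.seed(seed + 1000)
    tp <- cbind(sample(nrow(s$vertices), 2), sample(nrow(s$vertices), 2))
    tp <- tp[tp[, 1] != tp[, 2], , drop = FALSE]
    gg <- geodesic_graph(s, if (nrow(tp)) tp else NULL)
    src <- sample(nrow(s$vertices), 2)
    got <- fra_candidates(gg, v_surface = 0.8, v_transmural = 0.4,
                          candidates = src)
    want <- oracle_graph_distances(gg, src, 0.8, 0.4)
    expect_equal(unclass(got)[seq_along(src), ], want, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("ranking is exactly self-consistent for EDL-generated candidates", {
  su <- coarse_setup()
  k <- 386L
  tau_k <- su$tau_cand[k, ]
  times <- seq(0, max(tau_k) + 4, by = 2)
  meas <- edl_forward(su$transfer, tau_k, tmp_template(width = 0), times)
  ie <- rank_candidates(su$tau_cand, su$transfer, meas)
  expect_identical(ie$node, k)
  expect_equal(ie$cor, 1, tolerance = 1e-12)
  expect_identical(ie$rd, 0)
  expect_error(rank_candidates(su$tau_cand, su$transfer,
                               bspm(matrix(0, 120, 3), 1:3)),
               "zero variance")
})

test_that("the top-2% subset of 1500 candidates has 30 members", {
  su <- coarse_setup()
  n <- su$transfer$n_nodes
  set.seed(8)
  big <- su$tau_cand[sample(nrow(su$tau_cand), 1500, replace = TRUE), ]
  attr(big, "candidates") <- seq_len(1500)
  meas <- edl_forward(su$transfer, big[77, ], tmp_template(width = 0),
                      seq(0, max(big[77, ]) + 4, by = 4))
  ie <- rank_candidates(big, su$transfer, meas)
  expect_identical(ie$n_top, 30L)
})

test_that("20 uV noise moves the selected focus by at most 10 mm of geodesic distance", {
  su <- coarse_setup()
  k <- 213
  tau_k <- su$tau_cand[k, ]
  times <- seq(0, max(tau_k) + 4, by = 2)
  meas <- add_noise(edl_forward(su$transfer, tau_k, tmp_template(width = 0),
                                times), sd = 0.02, seed = 31)
  ie <- rank_candidates(su$tau_cand, su$transfer, meas)
  gd <- geodesic_distances(su$graph, from = ie$node)[1, k]
  expect_lte(gd, 10)
})

test_that("second_best returns the spatially distinct runner-up, or nothing", {
  su <- coarse_setup()
  pos <- su$ventricle$surface$vertices
  k <- 386L
  meas <- edl_forward(su$transfer, su$tau_cand[k, ], tmp_template(width = 0),
                      seq(0, max(su$tau_cand[k, ]) + 4, by = 2))
  ie <- rank_candidates(su$tau_cand, su$transfer, meas)
  sb <- second_best(ie, su$tau_cand, pos, min_separation = 30)
  expect_gte(sqrt(sum((pos[sb$node, ] - pos[ie$node, ])^2)), 30)
  expect_gte(ie$table$rank[ie$table$node == sb$node], 2)
  # impossible separation: nothing qualifies
  expect_null(second_best(ie, su$tau_cand, pos, min_separation = 1e6))
  # two artificial near-tied clusters 50 mm apart: the runner-up cluster head
  tab <- ie$table
  d <- sqrt(rowSums((pos[tab$node, ] - matrix(pos[ie$node, ], nrow(tab), 3,
                                              byrow = TRUE))^2))
  far <- tab$node[d > 50][1]
  tab2 <- tab
  tab2$cor[tab2$node == far] <- tab2$cor[1] - 0.01  # near-tied by construction
  tab2 <- tab2[order(-tab2$cor, tab2$rd), ]
  tab2$rank <- seq_len(nrow(tab2))
  ie2 <- ie; ie2$table <- tab2
  sb2 <- second_best(ie2, su$tau_cand, pos, min_separation = 30)
  expect_identical(sb2$node, far)
})

test_that("multifocal estimation recovers the number and location of foci", {
  su <- coarse_setup()
  tc <- su$tau_cand
  pos <- su$ventricle$surface$vertices
  tpl0 <- tmp_template(width = 0)
  # one focus: the gain rule must not add more
  k1 <- 119L
  m1 <- edl_forward(su$transfer, tc[k1, ], tpl0,
                    seq(0, max(tc[k1, ]) + 4, by = 2))
  mf1 <- multifocal_sinus_estimate(tc, su$transfer, m1)
  expect_identical(nrow(mf1$foci), 1L)
  expect_identical(mf1$foci$node[1], k1)
  # two well-separated foci, noise-free
  k2 <- which.max(geodesic_distances(su$graph, from = k1)[1, ])
  tau2 <- pmin(tc[k1, ], 10 + tc[k2, ])
  m2 <- edl_forward(su$transfer, tau2, tpl0, seq(0, max(tau2) + 4, by = 2))
  mf2 <- multifocal_sinus_estimate(tc, su$transfer, m2,
                                   onsets = seq(0, 30, by = 5))
  expect_gte(nrow(mf2$foci), 2L)
  derr <- vapply(c(k1, k2), function(k)
    min(sqrt(rowSums((pos[mf2$foci$node, , drop = FALSE] -
                      matrix(pos[k, ], nrow(mf2$foci), 3, byrow = TRUE))^2))),
    0)
  expect_lt(max(derr), 10)
  # combined map never exceeds the single-focus map anywhere
  expect_true(all(mf2$tau <= tc[k1, ] * mf2$scales[k1] + 1e-9))
})

test_that("the optimizer is exactly stationary at the truth for lambda 0, noise-free", {
  su <- coarse_setup()
  tpl <- tmp_template(width = 2)
  tau_true <- su$tau_cand[123, ]
  meas <- edl_forward(su$transfer, tau_true, tpl,
                      seq(0, max(tau_true) + 6, by = 2))
  fit <- optimize_activation(list(tau = tau_true), su$transfer, meas,
                             lambda = 0, su$laplacian, template = tpl,
                             polish = FALSE)
  expect_identical(fit$tau, tau_true)
  expect_identical(fit$residual_norm, 0)
  expect_true(fit$converged)
})

test_that("accepted optimizer steps monotonically decrease the objective", {
  su <- coarse_setup()
  tpl <- tmp_template(width = 2)
  tau_true <- su$tau_cand[77, ]
  meas <- add_noise(edl_forward(su$transfer, tau_true, tpl,
                                seq(0, max(tau_true) + 6, by = 2)),
                    sd = 0.02, seed = 9)
  ie <- rank_candidates(su$tau_cand, su$transfer, meas)
  f10 <- optimize_activation(ie, su$transfer, meas, lambda = 1e-4,
                             su$laplacian, template = tpl, max_iter = 10,
                             polish = FALSE)
  f25 <- optimize_activation(ie, su$transfer, meas, lambda = 1e-4,
                             su$laplacian, template = tpl, max_iter = 25,
                             polish = FALSE)
  obj0 <- sum((bspm_pred_test(su$transfer, ie$tau, tpl, meas) - meas$phi)^2) +
    1e-4 * as.numeric(Matrix::crossprod(su$laplacian %*% ie$tau))
  expect_lte(f10$objective, obj0)
  expect_lte(f25$objective, f10$objective)
})

test_that("the fitted model object exposes the standard accessor methods", {
  su <- coarse_setup()
  tpl <- tmp_template(width = 2)
  tau_true <- su$tau_cand[50, ]
  meas <- add_noise(edl_forward(su$transfer, tau_true, tpl,
                                seq(0, max(tau_true) + 6, by = 2)),
                    sd = 0.02, seed = 2)
  fit <- edl_inverse(meas, su$transfer, su$graph, su$laplacian, lambda = 1e-4,
                     tau_cand = su$tau_cand, template = tpl, max_iter = 15,
                     polish = FALSE)
  expect_s3_class(fit, "edl_inverse")
  expect_length(coef(fit), su$transfer$n_nodes)
  expect_identical(dim(fitted(fit)$phi), dim(meas$phi))
  expect_identical(dim(residuals(fit)), dim(meas$phi))
  expect_equal(fitted(fit)$phi - meas$phi, residuals(fit))
  s <- summary(fit)
  expect_s3_class(s, "summary.edl_inverse")
  expect_gt(s$cor_bspm, 0.8)
  expect_output(print(fit), "EDL activation-time inverse fit")
  expect_output(print(s), "BSPM fit")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})
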