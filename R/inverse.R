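#' Fastest-route candidate activation maps
#'
#' Every ventricular surface node is considered as a candidate focus; its
#' activation map is the exact single-source shortest-path travel time on the
#' geodesic graph, with surface edges traversed at `v_surface` and transmural
#' edges at `v_transmural` (mm/ms).
#'
#' @param gg a `geodesic_graph` over the ventricular surface.
#' @param v_surface surface propagation velocity, mm/ms (default 0.8).
#' @param v_transmural transmural velocity, mm/ms (default 0.4).
#' @param candidates node subset (default all nodes).
#' @return matrix (candidates x nodes) of activation times, ms; candidate node
#'   ids in `rownames`-free attribute `candidates`.
#' @export
fra_candidates <- function(gg, v_surface = 0.8, v_transmural = 0.4,
                           candidates = NULL) {
  stopifnot(v_surface > 0, v_transmural > 0)
  if (is.null(candidates)) candidates <- seq_len(gg$n_nodes)
  tau <- geodesic_distances(gg, from = candidates,
                            surface_velocity = v_surface,
                            transmural_velocity = v_transmural)
  attr(tau, "candidates") <- candidates
  attr(tau, "velocities") <- c(surface = v_surface, transmural = v_transmural)
  tau
}

#' Rank fastest-route candidates against a measured BSPM
#'
#' Each candidate map is pushed through the EDL forward on the measured time
#' grid; the Pearson correlation (COR) and relative difference (RD, Frobenius)
#' between the flattened predicted and measured matrices are tabulated. The
#' top `top_frac` (default 2%) of candidates by COR are selected, and among
#' them the one with the smallest RD is the initial estimate. Ties are broken
#' by lower RD, then lower node index.
#'
#' @param tau_cand candidate matrix from [fra_candidates()].
#' @param transfer an `edl_transfer`.
#' @param measured a `bspm`.
#' @param template a `tmp_template` (default sharp step).
#' @param top_frac fraction of candidates forming the COR-best subset; with
#'   fewer than 50 candidates the subset is the single best.
#' @param scale_duration rescale each candidate map so its span matches the
#'   measured depolarization duration when they disagree by more than 10%
#'   (the fastest-route velocities fix the activation pattern, not its time
#'   scale); exact self-consistent candidates are left untouched by the gate.
#' @param chunk candidates per matrix-product block.
#' @return object of class `initial_estimate`: `node` (focus), `tau`
#'   (activation map, ms), `cor`, `rd`, `table` (full ordered candidate
#'   table), `scale` (duration rescaling applied to the selected map).
#' @export
rank_candidates <- function(tau_cand, transfer, measured,
                            template = tmp_template(width = 0),
                            top_frac = 0.02, scale_duration = TRUE,
                            chunk = 128L) {
  M <- measured$phi
  if (stats::sd(M) == 0) stop("measured BSPM has zero variance")
  times <- measured$times
  A <- transfer$A
  nc <- nrow(tau_cand)
  n <- ncol(tau_cand)
  stopifnot(n == ncol(A))
  eval_rows <- function(tau_mat) {
    m_vec <- as.vector(M)
    m_cent <- m_vec - mean(m_vec)
    m_ss <- sum(m_cent^2)
    m_norm <- sqrt(sum(m_vec^2))
    nr <- nrow(tau_mat)
    cor_v <- numeric(nr); rd_v <- numeric(nr)
    for (s in seq(1, nr, by = chunk)) {
      e <- min(s + chunk - 1L, nr)
      blk <- s:e
      S <- template$s(outer(-t(tau_mat[blk, , drop = FALSE]), times, `+`))
      # stacked step matrices: rows = nodes, cols = blk x times
      S <- array(S, dim = c(n, length(blk), length(times)))
      P <- A %*% matrix(S, n, length(blk) * length(times))
      P <- array(P, dim = c(nrow(A), length(blk), length(times)))
      for (i in seq_along(blk)) {
        p <- P[, i, ]
        p <- sweep(p, 2, colMeans(p))      # zero-mean reference per sample
        pv <- as.vector(p)
        pc <- pv - mean(pv)
        denom <- sqrt(sum(pc^2) * m_ss)
        cor_v[blk[i]] <- if (denom > 0) sum(pc * m_cent) / denom else 0
        rd_v[blk[i]] <- sqrt(sum((pv - m_vec)^2)) / m_norm
      }
    }
    list(cor = cor_v, rd = rd_v)
  }
  base <- eval_rows(tau_cand)
  cor_v <- base$cor; rd_v <- base$rd
  scl <- rep(1, nc)
  if (scale_duration) {
    # rescale candidates whose span disagrees with the observed
    # depolarization duration, and keep whichever variant correlates better
    dur <- depolarization_duration(measured)
    span <- apply(tau_cand, 1, max) - apply(tau_cand, 1, min)
    s_all <- dur / pmax(span, 1e-9)
    need <- which(abs(s_all - 1) > 0.1)
    if (length(need)) {
      alt <- eval_rows(tau_cand[need, , drop = FALSE] * s_all[need])
      take <- alt$cor > cor_v[need]
      idx <- need[take]
      cor_v[idx] <- alt$cor[take]
      rd_v[idx] <- alt$rd[take]
      scl[idx] <- s_all[idx]
    }
  }
  tau_cand_s <- tau_cand * scl
  cand_id <- attr(tau_cand, "candidates")
  ord <- order(-cor_v, rd_v, cand_id)
  tab <- data.frame(node = cand_id[ord], cor = cor_v[ord], rd = rd_v[ord],
                    rank = seq_len(nc))
  n_top <- if (nc >= 50) max(1L, as.integer(ceiling(top_frac * nc))) else 1L
  top <- tab[seq_len(n_top), ]
  sel <- top[order(top$rd, top$node), ][1, ]
  sel_row <- which(cand_id == sel$node)
  structure(list(node = sel$node, tau = tau_cand_s[sel_row, ],
                 cor = sel$cor, rd = sel$rd, table = tab,
                 scale = scl[sel_row], scales = scl, n_top = n_top),
            class = "initial_estimate")
}

# supra-threshold span of the measured map (5% of the absolute maximum)
depolarization_duration <- function(measured) {
  thr <- 0.05 * max(abs(measured$phi))
  on <- which(apply(abs(measured$phi), 2, max) > thr)
  if (!length(on)) return(diff(range(measured$times)))
  measured$times[on[length(on)]] - measured$times[on[1]]
}

#' @export
print.initial_estimate <- function(x, ...) {
  cat(sprintf("<initial_estimate: focus node %d, COR %.3f, RD %.3f (top subset %d of %d)>\n",
              x$node, x$cor, x$rd, x$n_top, nrow(x$table)))
  invisible(x)
}

#' Second-best, spatially distinct initial estimate
#'
#' The best-ranked candidate whose focus lies at least `min_separation` mm
#' (default 30) from the primary focus; `NULL` when no candidate qualifies.
#' Used to detect and rescue near-tied ambiguous initial estimates.
#'
#' @param estimate an `initial_estimate`.
#' @param tau_cand the candidate matrix used to build it.
#' @param positions node positions (n x 3, mm).
#' @param min_separation mm.
#' @return an `initial_estimate` (with the same candidate table) or `NULL`.
#' @export
second_best <- function(estimate, tau_cand, positions, min_separation = 30) {
  tab <- estimate$table
  d <- sqrt(rowSums((positions[tab$node, , drop = FALSE] -
                     matrix(positions[estimate$node, ], nrow(tab), 3,
                            byrow = TRUE))^2))
  ok <- which(d >= min_separation)
  if (!length(ok)) return(NULL)
  sel <- tab[ok[1], ]
  cand_id <- attr(tau_cand, "candidates")
  row <- which(cand_id == sel$node)
  scl <- if (!is.null(estimate$scales)) estimate$scales[row] else 1
  structure(list(node = sel$node,
                 tau = tau_cand[row, ] * scl,
                 cor = sel$cor, rd = sel$rd, table = tab,
                 scale = scl, scales = estimate$scales,
                 n_top = estimate$n_top,
                 separation_mm = d[ok[1]]),
            class = "initial_estimate")
}

#' Multi-focal initial estimate for sinus-like rhythms
#'
#' Greedy "first come, first served" construction: starting from the best
#' single-focus candidate, repeatedly add the (focus, onset) pair whose
#' combined map `tau(j) = min_f (onset_f + tau_f(j))` maximally increases the
#' COR with the measured BSPM; stop when the gain falls below `gain_tol`
#' (default 0.005) or `max_foci` (default 6) is reached.
#'
#' @param tau_cand candidate matrix from [fra_candidates()].
#' @param transfer an `edl_transfer`.
#' @param measured a `bspm`.
#' @param template step template for the candidate BSPMs.
#' @param onsets candidate onset grid, ms.
#' @param gain_tol minimal COR improvement to accept a focus.
#' @param max_foci cap on the number of foci.
#' @return an `initial_estimate` whose `foci` element lists (node, onset).
#' @export
multifocal_sinus_estimate <- function(tau_cand, transfer, measured,
                                      template = tmp_template(width = 0),
                                      onsets = seq(0, 40, by = 5),
                                      gain_tol = 0.005, max_foci = 6) {
  first <- rank_candidates(tau_cand, transfer, measured, template,
                           top_frac = 0.02)
  cand_id <- attr(tau_cand, "candidates")
  tau_scaled <- tau_cand * first$scales
  cur_tau <- tau_scaled[which(cand_id == first$node), ]
  foci <- data.frame(node = first$node, onset = 0)
  cur_cor <- bspm_cor(transfer, cur_tau, template, measured)
  repeat {
    if (nrow(foci) >= max_foci) break
    best <- list(gain = -Inf)
    for (on in onsets) {
      # combined "first come, first served" maps for every candidate focus
      comb <- pmin(tau_scaled + on,
                   matrix(cur_tau, nrow(tau_scaled), ncol(tau_scaled),
                          byrow = TRUE))
      cors <- bspm_cor_rows(transfer, comb, template, measured)
      i <- which.max(cors)
      if (cors[i] - cur_cor > best$gain) {
        best <- list(gain = cors[i] - cur_cor, node = cand_id[i],
                     onset = on, tau = comb[i, ], cor = cors[i])
      }
    }
    if (best$gain < gain_tol) break
    cur_tau <- best$tau
    cur_cor <- best$cor
    foci <- rbind(foci, data.frame(node = best$node, onset = best$onset))
  }
  structure(list(node = foci$node[1], tau = cur_tau,
                 cor = cur_cor,
                 rd = bspm_rd(transfer, cur_tau, template, measured),
                 table = first$table, scale = first$scale,
                 scales = first$scales,
                 n_top = first$n_top, foci = foci),
            class = "initial_estimate")
}

bspm_pred <- function(transfer, tau, template, measured) {
  S <- template$s(outer(-tau, measured$times, `+`))
  p <- transfer$A %*% S
  sweep(p, 2, colMeans(p))
}

bspm_cor <- function(transfer, tau, template, measured) {
  stats::cor(as.vector(bspm_pred(transfer, tau, template, measured)),
             as.vector(measured$phi))
}

bspm_rd <- function(transfer, tau, template, measured) {
  p <- bspm_pred(transfer, tau, template, measured)
  sqrt(sum((p - measured$phi)^2)) / sqrt(sum(measured$phi^2))
}

# vectorized COR of many candidate maps (rows of tau_mat)
bspm_cor_rows <- function(transfer, tau_mat, template, measured,
                          chunk = 128L) {
  nc <- nrow(tau_mat)
  out <- numeric(nc)
  n <- ncol(tau_mat)
  times <- measured$times
  m_vec <- as.vector(measured$phi)
  m_cent <- m_vec - mean(m_vec)
  m_ss <- sum(m_cent^2)
  for (s in seq(1, nc, by = chunk)) {
    e <- min(s + chunk - 1L, nc)
    blk <- s:e
    S <- template$s(outer(-t(tau_mat[blk, , drop = FALSE]), times, `+`))
    S <- array(S, dim = c(n, length(blk), length(times)))
    P <- transfer$A %*% matrix(S, n, length(blk) * length(times))
    P <- array(P, dim = c(nrow(transfer$A), length(blk), length(times)))
    for (i in seq_along(blk)) {
      p <- P[, i, ]
      p <- sweep(p, 2, colMeans(p))
      pc <- as.vector(p); pc <- pc - mean(pc)
      denom <- sqrt(sum(pc^2) * m_ss)
      out[blk[i]] <- if (denom > 0) sum(pc * m_cent) / denom else 0
    }
  }
  out
}

#' Levenberg-Marquardt refinement of activation times
#'
#' Minimizes `||Phi_EDL(tau) - Phi_meas||_F^2 + lambda ||L tau||^2` with an
#' analytic Jacobian from the smoothed TMP template. The Gauss-Newton normal
#' matrix factorizes as `(A'A) o (D D')` (Hadamard product) where
#' `D[j, t] = s'(t - tau_j)`, which keeps each iteration at a dense
#' n x n Cholesky. Damping is adapted multiplicatively; accepted steps
#' monotonically decrease the objective. A final polish pass with a sharper
#' template (width `polish_width`) is run when `polish = TRUE`.
#'
#' @param init an `initial_estimate` (or list with `tau`).
#' @param transfer an `edl_transfer`.
#' @param measured a `bspm`.
#' @param lambda regularization weight (>= 0).
#' @param L surface Laplacian (sparse, n x n).
#' @param template optimizer template (default logistic width 2 ms).
#' @param max_iter iteration cap (default 200).
#' @param tol relative objective tolerance (default 1e-6).
#' @param polish run the sharper polish pass.
#' @param polish_width template width for the polish pass, ms.
#' @return object of class `inverse_result`: `tau` (refined map), `lambda`,
#'   `iterations`, `residual_norm`, `penalty`, `objective`, `converged`,
#'   `initial`.
#' @export
optimize_activation <- function(init, transfer, measured, lambda, L,
                                template = tmp_template(width = 2),
                                max_iter = 200, tol = 1e-6,
                                polish = TRUE, polish_width = 1) {
  stopifnot(lambda >= 0)
  tau0 <- init$tau
  if (any(!is.finite(tau0))) stop("initial activation map must be finite")
  r1 <- lm_activation(tau0, transfer, measured, lambda, L, template,
                      max_iter = max_iter, tol = tol)
  if (polish && template$width > polish_width) {
    r2 <- lm_activation(r1$tau, transfer, measured, lambda, L,
                        tmp_template(amplitude = template$amplitude,
                                     width = polish_width),
                        max_iter = max(20L, max_iter %/% 4), tol = tol)
    r2$iterations <- r1$iterations + r2$iterations
    r2$converged <- r1$converged && r2$converged
    r1 <- r2
  }
  structure(c(r1, list(lambda = lambda, initial = init)),
            class = "inverse_result")
}

#' @export
print.inverse_result <- function(x, ...) {
  cat(sprintf("<inverse_result: %d iterations%s, residual %.4g, penalty %.4g, lambda %.3g>\n",
              x$iterations, if (x$converged) "" else " (not converged)",
              x$residual_norm, x$penalty, x$lambda))
  invisible(x)
}

lm_activation <- function(tau, transfer, measured, lambda, L, template,
                          max_iter = 200, tol = 1e-6) {
  A <- transfer$A
  M <- measured$phi
  times <- measured$times
  n <- length(tau)
  AtA <- crossprod(A)
  LtL <- Matrix::crossprod(L)
  # keep activation times inside the observed window: outside it the forward
  # map is flat and the Gauss-Newton curvature vanishes
  lo <- min(times) - 2 * max(template$width, 1)
  hi <- max(times) + 2 * max(template$width, 1)
  clamp <- function(x) pmin(pmax(x, lo), hi)
  tau <- clamp(tau)
  obj_parts <- function(tau) {
    S <- template$s(outer(-tau, times, `+`))
    P <- A %*% S
    P <- sweep(P, 2, colMeans(P))
    R <- P - M
    pen <- as.numeric(Matrix::crossprod(L %*% tau))
    list(R = R, res2 = sum(R^2), pen = pen, f = sum(R^2) + lambda * pen)
  }
  cur <- obj_parts(tau)
  if (!is.finite(cur$f)) stop("non-finite objective at the initial estimate")
  mu <- 1e-3
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    D <- template$ds(outer(-tau, times, `+`))           # n x T
    G <- crossprod(A, cur$R)                            # n x T
    grad <- -2 * rowSums(G * D) +
      2 * lambda * as.numeric(LtL %*% tau)
    H <- AtA * tcrossprod(D) + lambda * as.matrix(LtL)
    accepted <- FALSE
    dH <- pmax(diag(H), 1e-6 * max(diag(H)))
    for (try in 1:8) {
      Hd <- H + mu * diag(dH, n)
      step <- tryCatch(solve(Hd, -grad / 2), error = function(e) NULL)
      if (!is.null(step)) {
        cand <- clamp(tau + step)
        nxt <- obj_parts(cand)
        if (is.finite(nxt$f) && nxt$f < cur$f) {
          rel <- (cur$f - nxt$f) / max(cur$f, .Machine$double.eps)
          tau <- cand
          cur <- nxt
          mu <- max(mu / 3, 1e-12)
          accepted <- TRUE
          if (rel < tol) converged <- TRUE
          break
        }
      }
      mu <- mu * 10
    }
    if (!accepted) { converged <- TRUE; break }  # stalled at a minimum
    if (converged) break
  }
  list(tau = tau, iterations = it, residual_norm = sqrt(cur$res2),
       penalty = cur$pen, objective = cur$f, converged = converged)
}

#' L-curve choice of the regularization weight
#'
#' Runs the optimizer on a logarithmic lambda grid and picks the corner of
#' the (log residual norm, log penalty) curve by the maximum-distance-to-chord
#' rule.
#'
#' @inheritParams optimize_activation
#' @param grid lambda grid (default `10^seq(-6, -2)`).
#' @param max_iter iteration cap per grid point.
#' @return list: `lambda` (selected), `path` (data.frame lambda, residual,
#'   penalty).
#' @export
choose_lambda <- function(init, transfer, measured, L,
                          grid = 10^seq(-6, -2), template = tmp_template(width = 2),
                          max_iter = 40) {
  res <- lapply(grid, function(lam)
    lm_activation(init$tau, transfer, measured, lam, L, template,
                  max_iter = max_iter))
  path <- data.frame(lambda = grid,
                     residual = vapply(res, `[[`, 0, "residual_norm"),
                     penalty = sqrt(vapply(res, `[[`, 0, "penalty")))
  x <- log10(pmax(path$residual, 1e-300))
  y <- log10(pmax(path$penalty, 1e-300))
  # distance from chord between first and last grid points
  dx <- x[length(x)] - x[1]; dy <- y[length(y)] - y[1]
  nrm <- sqrt(dx^2 + dy^2)
  d <- abs(dx * (y - y[1]) - dy * (x - x[1])) / max(nrm, 1e-12)
  list(lambda = grid[which.max(d)], path = path)
}

# ---- the user-facing model fit ---------------------------------------------

#' Fit ventricular activation times from a BSPM (EDL inverse)
#'
#' The full two-step inverse procedure: a fastest-route initial estimate
#' (every surface node as candidate focus, COR/RD ranking; optionally the
#' multi-focal sinus variant), followed by Laplacian-regularized
#' Levenberg-Marquardt refinement of the activation map. When
#' `second_best = TRUE` the optimizer is additionally started from the best
#' candidate at least 30 mm away, and the lower-residual result is kept.
#'
#' @param measured a `bspm`.
#' @param transfer an `edl_transfer`.
#' @param graph a `geodesic_graph` over the ventricular surface.
#' @param laplacian surface Laplacian of the ventricular surface.
#' @param lambda numeric regularization weight, or `"auto"` for the L-curve
#'   choice.
#' @param velocities `c(surface =, transmural =)` fastest-route velocities,
#'   mm/ms.
#' @param multifocal use the multi-focal (sinus) initial estimate.
#' @param second_best try the spatially distinct runner-up initial estimate
#'   and keep the lower-residual fit.
#' @param positions node positions (needed for `second_best`; taken from
#'   `attr(graph, "positions")` or supplied explicitly).
#' @param template optimizer template.
#' @param ranking_template step template used when ranking fastest-route
#'   candidates (default: sharp Heaviside).
#' @param tau_cand optional precomputed [fra_candidates()] matrix.
#' @param max_iter,tol,polish passed to [optimize_activation()].
#' @return object of class `edl_inverse`; see [coef.edl_inverse()],
#'   [fitted.edl_inverse()], [residuals.edl_inverse()], `summary`, `plot`.
#' @export
edl_inverse <- function(measured, transfer, graph, laplacian,
                        lambda = "auto",
                        velocities = c(surface = 0.8, transmural = 0.4),
                        multifocal = FALSE, second_best = FALSE,
                        positions = NULL,
                        template = tmp_template(width = 2),
                        ranking_template = tmp_template(width = 0),
                        tau_cand = NULL,
                        max_iter = 200, tol = 1e-6, polish = TRUE) {
  cl <- match.call()
  if (is.null(tau_cand))
    tau_cand <- fra_candidates(graph, velocities[["surface"]],
                               velocities[["transmural"]])
  init <- if (multifocal) {
    multifocal_sinus_estimate(tau_cand, transfer, measured,
                              template = ranking_template)
  } else {
    rank_candidates(tau_cand, transfer, measured,
                    template = ranking_template)
  }
  lam_path <- NULL
  if (identical(lambda, "auto")) {
    sel <- choose_lambda(init, transfer, measured, laplacian,
                         template = template)
    lambda <- sel$lambda
    lam_path <- sel$path
  }
  fit <- optimize_activation(init, transfer, measured, lambda, laplacian,
                             template = template, max_iter = max_iter,
                             tol = tol, polish = polish)
  alt <- NULL
  if (second_best) {
    if (is.null(positions)) stop("second_best = TRUE needs node positions")
    sb <- second_best(init, tau_cand, positions)
    if (!is.null(sb)) {
      alt <- optimize_activation(sb, transfer, measured, lambda, laplacian,
                                 template = template, max_iter = max_iter,
                                 tol = tol, polish = polish)
      if (alt$residual_norm < fit$residual_norm) {
        tmp <- fit; fit <- alt; alt <- tmp
      }
    }
  }
  structure(list(tau = fit$tau, fit = fit, alternative = alt,
                 initial = init, lambda = fit$lambda,
                 lambda_path = lam_path,
                 transfer = transfer, measured = measured,
                 template = template, velocities = velocities,
                 call = cl),
            class = "edl_inverse")
}

#' @export
print.edl_inverse <- function(x, ...) {
  cat("EDL activation-time inverse fit\n")
  cat(sprintf("  %d heart nodes, %d electrodes, %d time samples\n",
              length(x$tau), nrow(x$measured$phi), ncol(x$measured$phi)))
  cat(sprintf("  initial focus node %d (COR %.3f, RD %.3f)\n",
              x$initial$node, x$initial$cor, x$initial$rd))
  cat(sprintf("  lambda %.3g, %d iterations, residual %.4g mV\n",
              x$lambda, x$fit$iterations, x$fit$residual_norm))
  invisible(x)
}

#' @export
summary.edl_inverse <- function(object, ...) {
  pred <- fitted(object)
  out <- list(
    n_nodes = length(object$tau),
    focus_node = which.min(object$tau),
    tau_range = range(object$tau),
    lambda = object$lambda,
    iterations = object$fit$iterations,
    converged = object$fit$converged,
    residual_norm = object$fit$residual_norm,
    cor_bspm = stats::cor(as.vector(pred$phi), as.vector(object$measured$phi)),
    rd_bspm = rd(object$measured$phi, pred$phi),
    used_second_best = !is.null(object$alternative) &&
      object$fit$initial$node != object$initial$node)
  class(out) <- "summary.edl_inverse"
  out
}

#' @export
print.summary.edl_inverse <- function(x, ...) {
  cat("EDL inverse fit summary\n")
  cat(sprintf("  nodes: %d   earliest node: %d   tau: %.1f..%.1f ms\n",
              x$n_nodes, x$focus_node, x$tau_range[1], x$tau_range[2]))
  cat(sprintf("  lambda %.3g, %d iterations (%s)\n", x$lambda, x$iterations,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  BSPM fit: COR %.3f, RD %.3f, residual %.4g mV\n",
              x$cor_bspm, x$rd_bspm, x$residual_norm))
  if (x$used_second_best) cat("  (second-best initial estimate selected)\n")
  invisible(x)
}

#' @describeIn edl_inverse the estimated activation times (ms).
#' @param object,x an `edl_inverse` fit.
#' @param ... unused.
#' @export
coef.edl_inverse <- function(object, ...) object$tau

#' @describeIn edl_inverse predicted BSPM of the fitted activation map.
#' @export
fitted.edl_inverse <- function(object, ...) {
  predict(object)
}

#' @describeIn edl_inverse predicted BSPM at (optionally new) sample times.
#' @param times new sample times, ms (default: the measured grid).
#' @export
predict.edl_inverse <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$measured$times
  edl_forward(object$transfer, object$tau, object$template, times)
}

#' @describeIn edl_inverse electrode-by-time residual matrix (mV).
#' @export
residuals.edl_inverse <- function(object, ...) {
  fitted(object)$phi - object$measured$phi
}

#' @describeIn edl_inverse diagnostic plot: sorted activation map and
#'   measured vs fitted traces of the electrode with the largest signal.
#' @export
plot.edl_inverse <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(sort(x$tau), type = "l", xlab = "node (sorted)",
                 ylab = "activation time [ms]", main = "activation map", ...)
  e <- which.max(apply(abs(x$measured$phi), 1, max))
  graphics::plot(x$measured$times, x$measured$phi[e, ], type = "l",
                 xlab = "time [ms]", ylab = "potential [mV]",
                 main = sprintf("electrode %d", e))
  graphics::lines(x$measured$times, fitted(x)$phi[e, ], lty = 2)
  graphics::legend("topleft", c("measured", "fitted"), lty = 1:2, bty = "n")
  invisible(x)
}
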