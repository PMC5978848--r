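#' Transmembrane potential template
#'
#' Parameterizes the TMP upstroke: during depolarization each point is either
#' at rest or activated, so the TMP is `rest + amplitude * s(t - tau)` with a
#' non-decreasing step function `s`. The logistic template (`width` = 10-90%
#' rise time, ms) is differentiable and is what the optimizer needs; width 0
#' gives the sharp Heaviside convention.
#'
#' @param amplitude upstroke amplitude, mV (default 100).
#' @param rest resting value, mV.
#' @param width upstroke width, ms (0 = Heaviside).
#' @return object of class `tmp_template` with elements `s(x)` (activation
#'   fraction), `ds(x)` (its time derivative, 1/ms), `amplitude`, `rest`,
#'   `width`.
#' @export
tmp_template <- function(amplitude = 100, rest = -85, width = 2) {
  stopifnot(width >= 0)
  if (width == 0) {
    s <- function(x) (x > 0) * 1      # preserves dim attributes
    ds <- function(x) x * 0
  } else {
    sc <- width / (2 * log(9))        # 10-90% rise over `width` ms
    s <- function(x) stats::plogis(x / sc)
    ds <- function(x) stats::dlogis(x / sc) / sc
  }
  structure(list(s = s, ds = ds, amplitude = amplitude, rest = rest,
                 width = width),
            class = "tmp_template")
}

#' Body surface potential map container
#'
#' @param phi electrodes x time matrix, mV.
#' @param times sample times, ms.
#' @param meta list of provenance fields (case, scenario, seed, noise sd).
#' @param rereference subtract the electrode mean per sample.
#' @return object of class `bspm`.
#' @export
bspm <- function(phi, times, meta = list(), rereference = TRUE) {
  phi <- as.matrix(phi)
  stopifnot(ncol(phi) == length(times))
  if (rereference) phi <- sweep(phi, 2, colMeans(phi))
  structure(list(phi = phi, times = as.numeric(times), meta = meta,
                 zero_mean = rereference),
            class = "bspm")
}

#' @export
print.bspm <- function(x, ...) {
  cat(sprintf("<bspm: %d electrodes x %d samples, t = %g..%g ms, max |phi| = %.3g mV%s>\n",
              nrow(x$phi), ncol(x$phi), min(x$times), max(x$times),
              max(abs(x$phi)),
              if (length(x$meta)) paste0(", ",
                paste(names(x$meta), unlist(x$meta), sep = "=", collapse = " ")) else ""))
  invisible(x)
}

#' Moving-least-squares gradient operator on the wall sampling
#'
#' For each sampling point, a linear fit over its `k` nearest grid neighbors
#' yields the spatial gradient as a sparse linear operator; built once per
#' geometry and reused for every activation map. Neighbor selection keeps
#' whole distance tie groups (so interior grid stencils stay symmetric) and
#' widens the reach where thin walls leave too few neighbors. Errors if a
#' point has fewer than 4 non-coplanar neighbors.
#'
#' @param ventricle a `ventricle`.
#' @param k nominal number of neighbors (default 12; ties included).
#' @return list of three sparse matrices `Gx`, `Gy`, `Gz` (n x n) with
#'   `grad(f) = cbind(Gx f, Gy f, Gz f)`.
#' @export
sampling_gradient_operator <- function(ventricle, k = 12) {
  smp <- ventricle$sampling
  gi <- smp$grid_index
  n <- smp$n
  key <- paste(gi[, 1], gi[, 2], gi[, 3])
  lut <- stats::setNames(seq_len(n), key)
  neighbor_table <- function(reach) {
    offs <- as.matrix(expand.grid(di = -reach:reach, dj = -reach:reach,
                                  dk = -reach:reach))
    offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
    nb <- matrix(NA_integer_, n, nrow(offs))
    for (r in seq_len(nrow(offs))) {
      j <- lut[paste(gi[, 1] + offs[r, 1], gi[, 2] + offs[r, 2],
                     gi[, 3] + offs[r, 3])]
      nb[, r] <- unname(j)
    }
    list(nb = nb, odist = sqrt(rowSums(offs^2)))
  }
  nb1 <- neighbor_table(1L)
  nb2 <- NULL
  trip_i <- vector("list", n); trip_j <- vector("list", n)
  wx <- vector("list", n); wy <- vector("list", n); wz <- vector("list", n)
  for (p in seq_len(n)) {
    pick <- function(tb, kk) {
      js <- tb$nb[p, ]
      ok <- which(!is.na(js))
      ok <- ok[order(tb$odist[ok])]
      if (length(ok) > kk) {
        # include the whole distance tie group at the cutoff: partial tie
        # groups give directionally biased stencils on regular grids
        cut <- tb$odist[ok[kk]] + 1e-9
        ok <- ok[tb$odist[ok] <= cut]
      }
      js[ok]
    }
    js <- pick(nb1, k)
    X <- smp$positions[js, , drop = FALSE] -
      matrix(smp$positions[p, ], length(js), 3, byrow = TRUE)
    # thin-wall stencils can be coplanar: widen the reach before giving up
    if (length(js) < 4 || rcond(crossprod(X)) < 1e-10) {
      if (is.null(nb2)) nb2 <- neighbor_table(2L)
      js <- pick(nb2, max(k, 18L))
      X <- smp$positions[js, , drop = FALSE] -
        matrix(smp$positions[p, ], length(js), 3, byrow = TRUE)
    }
    if (length(js) < 4)
      stop("sampling point ", p, " has fewer than 4 neighbors for gradient estimation")
    XtX <- crossprod(X)
    if (rcond(XtX) < 1e-10)
      stop("sampling point ", p, " has coplanar neighbors; cannot estimate gradient")
    P <- solve(XtX, t(X))      # 3 x k: gradient = P %*% (f_nb - f_p)
    trip_i[[p]] <- rep(p, length(js) + 1L)
    trip_j[[p]] <- c(js, p)
    wx[[p]] <- c(P[1, ], -sum(P[1, ]))
    wy[[p]] <- c(P[2, ], -sum(P[2, ]))
    wz[[p]] <- c(P[3, ], -sum(P[3, ]))
  }
  ii <- unlist(trip_i); jj <- unlist(trip_j)
  list(Gx = Matrix::sparseMatrix(i = ii, j = jj, x = unlist(wx), dims = c(n, n)),
       Gy = Matrix::sparseMatrix(i = ii, j = jj, x = unlist(wy), dims = c(n, n)),
       Gz = Matrix::sparseMatrix(i = ii, j = jj, x = unlist(wz), dims = c(n, n)))
}

#' Volumetric wavefront dipoles at a time instant
#'
#' The primary cardiac source is the distributed dipole density
#' `J = -Sigma_i grad(phi_h)`, with `Sigma_i` the intracellular conductivity
#' tensor (eigenvalue `sigma_i_l` along the local fiber, `sigma_i_t`
#' across). Composing the TMP template with the activation map,
#' `grad(phi_h)(p, t) = -amplitude * s'(t - tau(p)) * grad(tau)(p)`, so the
#' dipole moment per sample point is
#' `m(p, t) = amplitude * s'(t - tau_p) * Sigma_i(p) grad(tau)(p) dV`.
#'
#' @param activation a `volume_activation`.
#' @param ventricle the generating `ventricle`.
#' @param setup a `conductivity_setup`.
#' @param template a `tmp_template`.
#' @param t time, ms.
#' @param grad_op optional precomputed [sampling_gradient_operator()].
#' @return list of class `dipole_set`: `positions` (n x 3 mm), `moments`
#'   (n x 3), `t`.
#' @export
wavefront_dipoles <- function(activation, ventricle, setup, template, t,
                              grad_op = NULL) {
  q <- intracellular_moment_pattern(activation, ventricle, setup, grad_op)
  w <- template$amplitude * template$ds(t - activation$tau_vol)
  structure(list(positions = ventricle$sampling$positions,
                 moments = q * w, t = t),
            class = "dipole_set")
}

# time-independent part: q_p = Sigma_i(p) grad(tau)(p) dV  (n x 3)
intracellular_moment_pattern <- function(activation, ventricle, setup,
                                         grad_op = NULL) {
  if (is.null(grad_op)) grad_op <- sampling_gradient_operator(ventricle)
  tau <- activation$tau_vol
  g <- cbind(as.numeric(grad_op$Gx %*% tau),
             as.numeric(grad_op$Gy %*% tau),
             as.numeric(grad_op$Gz %*% tau))
  f <- ventricle$sampling$fiber
  along <- rowSums(g * f)
  sig_t <- setup$sigma_i_t
  sig_l <- setup$sigma_i_l
  (sig_t * g + (sig_l - sig_t) * along * f) * ventricle$sampling$dV
}

#' Simulate the "measured" BSPM of a scenario
#'
#' Forward stage of the synthetic study: ground-truth activation is turned
#' into volumetric wavefront dipoles, propagated to the electrodes through
#' the BEM volume conductor, sampled every `dt` ms over the depolarization
#' phase, and contaminated with Gaussian noise. This generator is
#' deliberately distinct from the EDL forward used inside the inverse: the
#' anisotropic intracellular tensor acts on the sources directly.
#'
#' @param solver a `bem_solver` of the torso model.
#' @param ventricle the `ventricle` inside it.
#' @param activation a `volume_activation` for the scenario.
#' @param setup a `conductivity_setup`.
#' @param template a `tmp_template` (logistic width > 0 recommended).
#' @param dt sample step, ms (default 1).
#' @param noise_sd additive Gaussian noise SD in mV (default 0.02 = 20 uV);
#'   0 for noise-free.
#' @param seed RNG seed for the noise.
#' @param grad_op optional precomputed gradient operator.
#' @return a `bspm` (zero-mean referenced).
#' @export
simulate_measured_bspm <- function(solver, ventricle, activation, setup,
                                   template = tmp_template(), dt = 1,
                                   noise_sd = 0.02, seed = 1,
                                   grad_op = NULL) {
  q <- intracellular_moment_pattern(activation, ventricle, setup, grad_op)
  pos <- ventricle$sampling$positions
  W <- solver$Minv[solver$electrode_rows, , drop = FALSE]
  gq <- dipole_pattern_source(solver$nodes, pos, q)
  Bq <- W %*% gq                       # electrodes x sampling points
  times <- seq(0, max(activation$tau_vol) + 3 * max(template$width, 1), by = dt)
  D <- template$amplitude *
    template$ds(outer(-activation$tau_vol, times, `+`))   # n x T
  phi <- Bq %*% D
  out <- bspm(phi, times,
              meta = list(case = setup$case,
                          scenario = attr(activation$stimuli, "scenario"),
                          noise_sd = noise_sd, seed = seed))
  if (noise_sd > 0) out <- add_noise(out, sd = noise_sd, seed = seed)
  out
}

# source-term matrix for per-point unit patterns q (n x 3):
# gq[i, p] = (1/4pi) q_p . (r_i - pos_p)/|r_i - pos_p|^3
dipole_pattern_source <- function(nodes, positions, q, chunk = 2000L) {
  n <- nrow(positions)
  gq <- matrix(0, nrow(nodes), n)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    for (d in 1:3) {
      Dd <- outer(nodes[, d], positions[s:e, d], `-`)
      if (d == 1) { R2 <- Dd^2; acc <- Dd * rep(q[s:e, 1], each = nrow(nodes)) }
      else {
        R2 <- R2 + Dd^2
        acc <- acc + Dd * rep(q[s:e, d], each = nrow(nodes))
      }
    }
    gq[, s:e] <- acc / (4 * pi * R2^1.5)
  }
  gq
}

#' EDL forward map
#'
#' Predicted BSPM of an activation-time map on the ventricular surface:
#' `Phi[e, t] = sum_j A[e, j] * s(t - tau_j)` with the transfer matrix's
#' zero-mean reference. Linear in the layer strength.
#'
#' @param transfer an `edl_transfer`.
#' @param tau activation times at the transfer's heart nodes, ms.
#' @param template a `tmp_template` (only the step shape is used; the
#'   amplitude is already folded into the transfer matrix).
#' @param times sample times, ms.
#' @return a `bspm`.
#' @export
edl_forward <- function(transfer, tau, template = tmp_template(width = 0),
                        times) {
  if (length(tau) != transfer$n_nodes)
    stop("tau has length ", length(tau), " but the transfer matrix has ",
         transfer$n_nodes, " heart nodes")
  S <- template$s(outer(-tau, times, `+`))
  bspm(transfer$A %*% S, times, meta = list(source = "edl_forward"))
}

#' Add calibrated Gaussian noise to a BSPM
#'
#' Independent Gaussian noise per entry (in mV; 0.02 mV = 20 uV), added
#' before zero-mean re-referencing; reproducible through `seed`.
#'
#' @param x a `bspm`.
#' @param sd noise SD, mV.
#' @param seed RNG seed.
#' @return a `bspm`.
#' @export
add_noise <- function(x, sd = 0.02, seed = 1) {
  stopifnot(sd >= 0)
  if (sd == 0) return(x)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  noise <- matrix(stats::rnorm(length(x$phi), sd = sd), nrow(x$phi))
  meta <- x$meta
  meta$noise_sd <- sd
  meta$seed <- seed
  bspm(x$phi + noise, x$times, meta = meta)
}
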