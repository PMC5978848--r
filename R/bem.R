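#' Signed solid angles of mesh triangles at observation points
#'
#' Van Oosterom-Strackee formula per triangle. With outward-oriented faces the
#' row sums over a closed surface equal 4*pi for interior points and 0 for
#' exterior points. With `lump = TRUE` each triangle's solid angle is split
#' equally over its three vertices, giving the (observation x vertex) kernel
#' used by linear-collocation BEM and by the dipole-layer source term.
#'
#' @param obs observation points (n_obs x 3, mm).
#' @param vertices,faces mesh arrays.
#' @param lump return vertex-lumped matrix (n_obs x n_vertices) instead of
#'   per-face (n_obs x n_faces).
#' @return dense matrix of solid angles (steradian).
#' @export
solid_angle_matrix <- function(obs, vertices, faces, lump = TRUE) {
  n_obs <- nrow(obs)
  nf <- nrow(faces)
  v1 <- vertices[faces[, 1], , drop = FALSE]
  v2 <- vertices[faces[, 2], , drop = FALSE]
  v3 <- vertices[faces[, 3], , drop = FALSE]
  out <- matrix(0, n_obs, nf)
  for (i in seq_len(n_obs)) {
    p <- obs[i, ]
    r1 <- cbind(v1[, 1] - p[1], v1[, 2] - p[2], v1[, 3] - p[3])
    r2 <- cbind(v2[, 1] - p[1], v2[, 2] - p[2], v2[, 3] - p[3])
    r3 <- cbind(v3[, 1] - p[1], v3[, 2] - p[2], v3[, 3] - p[3])
    n1 <- sqrt(rowSums(r1^2)); n2 <- sqrt(rowSums(r2^2)); n3 <- sqrt(rowSums(r3^2))
    num <- r1[, 1] * (r2[, 2] * r3[, 3] - r2[, 3] * r3[, 2]) +
           r1[, 2] * (r2[, 3] * r3[, 1] - r2[, 1] * r3[, 3]) +
           r1[, 3] * (r2[, 1] * r3[, 2] - r2[, 2] * r3[, 1])
    den <- n1 * n2 * n3 + rowSums(r1 * r2) * n3 +
           rowSums(r2 * r3) * n1 + rowSums(r3 * r1) * n2
    om <- 2 * atan2(num, den)
    om[n1 < 1e-12 | n2 < 1e-12 | n3 < 1e-12] <- 0  # observation at a vertex
    out[i, ] <- om
  }
  if (!lump) return(out)
  nv <- nrow(vertices)
  res <- matrix(0, n_obs, nv)
  third <- out / 3
  for (k in 1:3) {
    idx <- faces[, k]
    # accumulate columns by vertex id
    for (grp in split(seq_len(nf), idx)) {
      j <- idx[grp[1]]
      res[, j] <- res[, j] + if (length(grp) == 1) third[, grp] else
        rowSums(third[, grp, drop = FALSE])
    }
  }
  res
}

#' Assemble the boundary-element solver for a volume conductor
#'
#' Linear collocation BEM for the inhomogeneous isotropic conductor: vertex
#' potentials on every compartment surface carrying a conductivity jump, with
#' analytically integrated per-triangle solid angles lumped one third per
#' vertex. Self-surface diagonal entries are set by the auto-solid-angle rule
#' (principal-value row total 2*pi), and the singular potential reference is
#' fixed by deflation. The factorized system is reusable for many
#' right-hand sides.
#'
#' @param vcm a `volume_conductor`.
#' @return object of class `bem_solver`: `Minv` (deflated inverse), collocation
#'   bookkeeping (`nodes`, `surface_of_node`), `electrode_rows`,
#'   `sigma_source` (bulk conductivity at the cardiac sources), `vcm`.
#' @export
assemble_bem <- function(vcm) {
  comps <- vcm$compartments
  jumps <- vapply(comps, function(cm) cm$sigma_in - cm$sigma_out, 0)
  active <- names(comps)[abs(jumps) > 1e-12]
  if (!length(active)) stop("no conductivity jumps: BEM system empty")
  nodes <- do.call(rbind, lapply(active, function(nm) comps[[nm]]$surface$vertices))
  surf_of <- rep(active, vapply(active, function(nm) nrow(comps[[nm]]$surface$vertices), 0L))
  n <- nrow(nodes)
  sigma_bar <- (vapply(comps[active], function(cm) cm$sigma_in + cm$sigma_out, 0) / 2)[
    match(surf_of, active)]

  M <- diag(sigma_bar, n, n)
  off <- 0L
  for (nm in active) {
    s <- comps[[nm]]$surface
    nv <- nrow(s$vertices)
    D <- solid_angle_matrix(nodes, s$vertices, s$faces, lump = TRUE)
    self <- which(surf_of == nm)
    # auto solid angle: principal-value row total over the own surface = 2*pi
    for (ii in seq_along(self)) {
      i <- self[ii]
      D[i, ii] <- 0
      D[i, ii] <- 2 * pi - sum(D[i, ])
    }
    coef <- (comps[[nm]]$sigma_in - comps[[nm]]$sigma_out) / (4 * pi)
    M[, off + seq_len(nv)] <- M[, off + seq_len(nv)] - coef * D
    off <- off + nv
  }
  # deflation: remove the constant-mode singularity
  M <- M + mean(sigma_bar) / n
  Minv <- tryCatch(solve(M), error = function(e)
    stop("BEM system singular after deflation: ", conditionMessage(e)))
  kappa <- NA_real_
  el_rows <- which(surf_of == names(comps)[1])[vcm$electrodes]
  structure(list(Minv = Minv, nodes = nodes, surface_of_node = surf_of,
                 active_surfaces = active, sigma_bar = sigma_bar,
                 electrode_rows = el_rows,
                 sigma_source = attr(vcm, "sigma_heart") %||%
                   comps[[1]]$sigma_in,
                 vcm = vcm, condition = kappa),
            class = "bem_solver")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bem_solver <- function(x, ...) {
  cat(sprintf("<bem_solver: %d collocation nodes on %d surfaces, %d electrodes>\n",
              nrow(x$nodes), length(x$active_surfaces), length(x$electrode_rows)))
  invisible(x)
}

#' Body-surface potentials of interior current dipoles
#'
#' Computes the electrode potentials (zero-mean referenced across electrodes)
#' generated by a set of current dipoles inside the conductor. Linear in the
#' dipole moments.
#'
#' @param solver a `bem_solver`.
#' @param positions n x 3 dipole positions (mm).
#' @param moments n x 3 dipole moments.
#' @param all_nodes return potentials at all collocation nodes instead of the
#'   zero-mean electrode subset.
#' @param min_distance reject dipoles closer than this (mm) to any BEM
#'   surface node.
#' @return numeric vector of potentials.
#' @export
dipole_potential <- function(solver, positions, moments, all_nodes = FALSE,
                             min_distance = 1e-2) {
  positions <- rbind(positions)
  moments <- rbind(moments)
  stopifnot(nrow(positions) == nrow(moments))
  nd <- nearest_dist(positions, solver$nodes)
  if (any(nd$dist < min_distance))
    stop("dipole(s) on or too close to a BEM surface: min distance ",
         format(min(nd$dist)), " mm")
  g <- dipole_source_term(solver$nodes, positions, moments)
  phi <- drop(solver$Minv %*% g)
  if (all_nodes) return(phi)
  e <- phi[solver$electrode_rows]
  e - mean(e)
}

# infinite-medium source term g = sigma_s * phi_inf at collocation points:
# g(r) = (1/4pi) sum_d p_d . (r - r_d) / |r - r_d|^3
dipole_source_term <- function(nodes, positions, moments) {
  g <- numeric(nrow(nodes))
  for (d in seq_len(nrow(positions))) {
    dx <- nodes[, 1] - positions[d, 1]
    dy <- nodes[, 2] - positions[d, 2]
    dz <- nodes[, 3] - positions[d, 3]
    r3 <- (dx^2 + dy^2 + dz^2)^1.5
    g <- g + (moments[d, 1] * dx + moments[d, 2] * dy + moments[d, 3] * dz) / r3
  }
  g / (4 * pi)
}

#' EDL transfer matrix
#'
#' Column j is the zero-mean electrode potential pattern of a unit-strength
#' equivalent-dipole-layer patch on the barycentric area of ventricular
#' surface node j, scaled by the potential-jump factor
#' `sigma_i / (sigma_i + sigma_e)` times the TMP amplitude. Units: mV per
#' unit (dimensionless) activation step.
#'
#' @param solver a `bem_solver`.
#' @param ventricle a `ventricle` (its combined surface defines the layer).
#' @param jump_factor potential-jump factor (default from the isotropic
#'   conductivities, 0.25).
#' @param amplitude TMP upstroke amplitude in mV (default 100).
#' @return object of class `edl_transfer`: `A` (electrodes x heart nodes, each
#'   column zero-mean), plus metadata.
#' @export
edl_transfer <- function(solver, ventricle,
                         jump_factor = edl_jump_factor(),
                         amplitude = 100) {
  hs <- ventricle$surface
  G <- solid_angle_matrix(solver$nodes, hs$vertices, hs$faces, lump = TRUE)
  sigma_h <- solver$sigma_source
  rhs <- (sigma_h * jump_factor * amplitude / (4 * pi)) * G
  phi <- solver$Minv %*% rhs
  A <- phi[solver$electrode_rows, , drop = FALSE]
  A <- sweep(A, 2, colMeans(A))
  structure(list(A = A, jump_factor = jump_factor, amplitude = amplitude,
                 n_electrodes = nrow(A), n_nodes = ncol(A),
                 heart_label = hs$label),
            class = "edl_transfer")
}

#' @export
print.edl_transfer <- function(x, ...) {
  cat(sprintf("<edl_transfer: %d electrodes x %d heart nodes, jump %.3g, amplitude %g mV>\n",
              x$n_electrodes, x$n_nodes, x$jump_factor, x$amplitude))
  invisible(x)
}

# ---- analytic sphere oracles ------------------------------------------------

#' Analytic surface potential of a dipole in a homogeneous sphere
#'
#' Closed-form Legendre series for a current dipole inside a homogeneous
#' conducting sphere with insulating exterior. For a dipole on the z-axis at
#' radius `b`, the surface potential at colatitude theta and azimuth phi is
#' a sum over radial (z) and tangential (x) moment components:
#' radial: `p_z/(4 pi sigma R^2) * sum (2n+1) (b/R)^(n-1) P_n(cos theta)`;
#' tangential: `p_x/(4 pi sigma R^2) * sum (2n+1)/n (b/R)^(n-1)
#' P_n^1(cos theta) cos phi` (with the sign fixed so the central-dipole limit
#' equals `3 p.r / (4 pi sigma R^2)`). Serves as the independent oracle for
#' the boundary-element solver.
#'
#' @param surface_points n x 3 points on the sphere surface.
#' @param dipole_pos dipole position `c(0, 0, b)` with `b < R` (any position
#'   is accepted; the frame is rotated internally so the dipole lies on +z).
#' @param moment dipole moment vector.
#' @param radius sphere radius R.
#' @param sigma conductivity.
#' @param n_terms series truncation.
#' @return potentials at `surface_points` (same reference as the series, i.e.
#'   zero monopole term).
#' @export
sphere_dipole_potential <- function(surface_points, dipole_pos, moment,
                                    radius = 1, sigma = 1, n_terms = 60) {
  b <- sqrt(sum(dipole_pos^2))
  if (b >= radius) stop("dipole must be strictly inside the sphere")
  # rotate so the dipole sits on +z
  if (b > 1e-12) {
    ez <- dipole_pos / b
  } else {
    ez <- c(0, 0, 1)
  }
  ref <- if (abs(ez[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  ex <- ref - sum(ref * ez) * ez
  ex <- ex / sqrt(sum(ex^2))
  ey <- c(ez[2] * ex[3] - ez[3] * ex[2],
          ez[3] * ex[1] - ez[1] * ex[3],
          ez[1] * ex[2] - ez[2] * ex[1])
  Rm <- rbind(ex, ey, ez)
  sp <- surface_points %*% t(Rm)
  pm <- drop(Rm %*% moment)
  r <- sqrt(rowSums(sp^2))
  ct <- pmin(pmax(sp[, 3] / r, -1), 1)
  phi_az <- atan2(sp[, 2], sp[, 1])
  st <- sqrt(pmax(1 - ct^2, 0))

  # Legendre P_n and associated P_n^1 (Condon-Shortley: P_1^1 = -sin(theta))
  # by upward recurrence; the tangential sign is fixed so the central-dipole
  # limit reduces to 3 p.r / (4 pi sigma R^2).
  Pnm1 <- rep(1, length(ct)); Pn <- ct              # P_0, P_1
  Qnm1 <- rep(0, length(ct)); Qn <- -st             # P_0^1 (=0), P_1^1
  tang <- pm[1] * cos(phi_az) + pm[2] * sin(phi_az)
  out <- numeric(length(ct))
  brR <- 1                                          # (b/R)^(n-1)
  for (n in 1:n_terms) {
    if (n > 1) {
      Pnew <- ((2 * n - 1) * ct * Pn - (n - 1) * Pnm1) / n
      Qnew <- ((2 * n - 1) * ct * Qn - n * Qnm1) / (n - 1)
      Pnm1 <- Pn; Pn <- Pnew
      Qnm1 <- Qn; Qn <- Qnew
      brR <- brR * (b / radius)
    }
    out <- out + pm[3] * (2 * n + 1) * brR * Pn -
                 tang * ((2 * n + 1) / n) * brR * Qn
  }
  out / (4 * pi * sigma * radius^2)
}

#' Analytic central-dipole potential in two concentric spheres
#'
#' A central dipole `p = c(0, 0, p)` inside concentric spheres of radii
#' `R1 < R2` with conductivities `sigma1` (inner) and `sigma2` (shell),
#' insulating exterior. Only the n = 1 harmonic is excited; the three series
#' coefficients follow from continuity of potential and normal current at R1
#' and zero normal current at R2.
#'
#' @param points n x 3 observation points with radius in (0, R2].
#' @param p dipole strength along z.
#' @param R1,R2 radii; `sigma1,sigma2` conductivities.
#' @return potential at the points.
#' @export
concentric_sphere_central_dipole <- function(points, p = 1, R1 = 0.5, R2 = 1,
                                             sigma1 = 1, sigma2 = 1) {
  # phi1 = p cos(th)/(4 pi sigma1 r^2) + A r cos(th)   (r < R1)
  # phi2 = B r cos(th) + C cos(th) / r^2               (R1 < r < R2)
  k <- p / (4 * pi * sigma1)
  # (k/R1^2 + A R1) = (B R1 + C/R1^2)            potential continuity at R1
  # sigma1 (-2k/R1^3 + A) = sigma2 (B - 2 C/R1^3) normal current at R1
  # B - 2 C/R2^3 = 0                              insulation at R2
  M <- rbind(c(R1, -R1, -1 / R1^2),
             c(sigma1, -sigma2, 2 * sigma2 / R1^3),
             c(0, 1, -2 / R2^3))
  rhs <- c(-k / R1^2, 2 * sigma1 * k / R1^3, 0)
  abc <- solve(M, rhs)
  r <- sqrt(rowSums(points^2))
  ct <- points[, 3] / r
  inner <- r <= R1
  out <- numeric(length(r))
  out[inner] <- (k / r[inner]^2 + abc[1] * r[inner]) * ct[inner]
  out[!inner] <- (abc[2] * r[!inner] + abc[3] / r[!inner]^2) * ct[!inner]
  out
}
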