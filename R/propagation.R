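#' Anisotropic wavefront propagation on the myocardial wall sampling
#'
#' Graph-eikonal surrogate for a monodomain propagation solver: activation
#' times are shortest-path travel times on a dense neighborhood graph over the
#' volumetric wall sampling. An edge with unit vector e costs
#' `|e| / v(e)` with `v(e) = v_t * sqrt(1 + (k^2 - 1) * cos(theta)^2)`,
#' where theta is the angle between the edge and the local fiber direction:
#' speed `v_t` across fibers, `k * v_t` along them. `k = 1` reduces to
#' isotropic geodesic propagation.
#'
#' @param ventricle a `ventricle` (supplies sampling and fiber field).
#' @param stimuli a `stimulus_set`.
#' @param v_t transversal conduction velocity, mm/ms (default 0.4).
#' @param k velocity anisotropy ratio (>= 1); typically
#'   `conductivity_setup(case)$velocity_ratio`.
#' @return object of class `volume_activation`: `tau_vol` (ms per sampling
#'   point), `tau_surf` (ms per ventricular surface node, the gold-standard
#'   restriction), `stimuli`, `v_t`, `k`.
#' @export
anisotropic_activation <- function(ventricle, stimuli, v_t = 0.4, k = 1) {
  stopifnot(k >= 1, v_t > 0)
  smp <- ventricle$sampling
  g <- sampling_graph(smp, v_t = v_t, k = k)
  seeds <- stimulus_seed_points(smp, stimuli)
  if (!length(seeds$idx)) stop("no sampling points inside any stimulus sphere")
  dmat <- igraph::distances(g, v = seeds$idx, weights = igraph::E(g)$cost,
                            algorithm = "dijkstra")
  tau <- do.call(pmin, c(lapply(seq_along(seeds$idx), function(i)
    seeds$onset[i] + dmat[i, ]), list(na.rm = FALSE)))
  if (any(!is.finite(tau))) {
    bad <- which(!is.finite(tau))
    stop("unreachable sampling points (disconnected sampling): ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "")
  }
  tau_surf <- tau[smp$surface_to_sample]
  structure(list(tau_vol = unname(tau), tau_surf = unname(tau_surf),
                 stimuli = stimuli, v_t = v_t, k = k),
            class = "volume_activation")
}

#' @export
print.volume_activation <- function(x, ...) {
  cat(sprintf("<volume_activation '%s': tau 0..%.1f ms on %d wall points, %d surface nodes>\n",
              attr(x$stimuli, "scenario") %||% "?", max(x$tau_vol),
              length(x$tau_vol), length(x$tau_surf)))
  invisible(x)
}

# neighborhood graph over the regular-grid sampling (26-neighborhood)
sampling_graph <- function(smp, v_t = 1, k = 1) {
  gi <- smp$grid_index
  key <- paste(gi[, 1], gi[, 2], gi[, 3])
  lut <- stats::setNames(seq_len(nrow(gi)), key)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  # each undirected edge once: keep lexicographically positive offsets
  keep <- offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
          (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0)
  offs <- offs[keep, , drop = FALSE]
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nb_key <- paste(gi[, 1] + offs[r, 1], gi[, 2] + offs[r, 2], gi[, 3] + offs[r, 3])
    j <- lut[nb_key]
    ok <- !is.na(j)
    from <- c(from, which(ok))
    to <- c(to, unname(j[ok]))
  }
  e <- smp$positions[to, , drop = FALSE] - smp$positions[from, , drop = FALSE]
  len <- sqrt(rowSums(e^2))
  fmid <- smp$fiber[from, , drop = FALSE] + smp$fiber[to, , drop = FALSE]
  fmid <- fmid / pmax(sqrt(rowSums(fmid^2)), .Machine$double.eps)
  cth <- abs(rowSums(e * fmid)) / len
  v <- v_t * sqrt(1 + (k^2 - 1) * cth^2)
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  if (igraph::vcount(g) < nrow(gi))
    g <- igraph::add_vertices(g, nrow(gi) - igraph::vcount(g))
  igraph::E(g)$cost <- len / v
  g
}

stimulus_seed_points <- function(smp, stimuli) {
  idx <- integer(0); onset <- numeric(0)
  for (s in seq_len(nrow(stimuli))) {
    d <- sqrt(rowSums(sweep(smp$positions, 2,
                            as.numeric(stimuli[s, c("x", "y", "z")]), `-`)^2))
    inside <- which(d <= stimuli$radius[s])
    if (!length(inside)) inside <- which.min(d)
    idx <- c(idx, inside)
    onset <- c(onset, rep(stimuli$onset[s], length(inside)))
  }
  list(idx = idx, onset = onset)
}

#' Stimulus sets
#'
#' A `stimulus_set` is a data frame with columns `x`, `y`, `z` (seed position,
#' mm), `onset` (ms), `radius` (mm), and a `scenario` attribute. Ectopic
#' scenarios carry exactly one seed.
#'
#' @param positions n x 3 seed positions.
#' @param onset onset times, ms (recycled).
#' @param radius stimulation radius, mm (recycled; default 0.8, a sphere of
#'   two 0.4-mm voxels).
#' @param scenario label.
#' @return a `stimulus_set`.
#' @export
stimulus_set <- function(positions, onset = 0, radius = 0.8,
                         scenario = "ectopic") {
  positions <- rbind(positions)
  stopifnot(all(radius > 0), all(onset >= 0))
  d <- data.frame(x = positions[, 1], y = positions[, 2], z = positions[, 3],
                  onset = rep_len(onset, nrow(positions)),
                  radius = rep_len(radius, nrow(positions)))
  attr(d, "scenario") <- scenario
  class(d) <- c("stimulus_set", "data.frame")
  d
}

#' Rule-based sinus-rhythm stimulation profile
#'
#' A simplified Purkinje-like endocardial profile: by default 4 seeds — a
#' septal site near the apex (LV face), a high LV endocardial free-wall
#' site, a mid RV endocardial free-wall site and a basal RV endocardial site
#' near the septum — with staggered onsets (0, 5, 10, 15 ms) yielding four
#' distinct, geodesically well separated early-activation sites.
#'
#' @param ventricle a `ventricle` (biventricular).
#' @param n_sites number of seeds (>= 1; seeds are taken in the order above).
#' @param onsets onset times, ms.
#' @return a `stimulus_set` with scenario `"sinus"`.
#' @export
sinus_stimuli <- function(ventricle, n_sites = 4,
                          onsets = c(0, 5, 10, 15)) {
  stopifnot(n_sites >= 1)
  smp <- ventricle$sampling
  cls <- ventricle$node_class[smp$nearest_surface_node]
  pos <- smp$positions
  ctr <- ventricle$params$center
  a <- ventricle$params$axes[1]
  apex_z <- ctr[3] - 0.55 * ventricle$params$axes[3]
  base_z <- ctr[3] + 0.35 * ventricle$params$axes[3]
  pick <- function(mask, target) {
    cand <- which(mask)
    if (!length(cand)) stop("no sampling points available for a sinus seed")
    cand[which.min(rowSums(sweep(pos[cand, , drop = FALSE], 2, target, `-`)^2))]
  }
  endo <- cls == "endocardial" & smp$depth < 0.35
  seeds <- c(
    pick(cls == "septal" & smp$depth < 0.5 & pos[, 1] < ctr[1],
         c(ctr[1] - 5, ctr[2], apex_z)),
    pick(endo & pos[, 1] < ctr[1],
         c(ctr[1] - a, ctr[2], base_z)),
    pick(endo & pos[, 1] > ctr[1],
         c(ctr[1] + a, ctr[2], ctr[3] - 10)),
    pick(endo & pos[, 1] > ctr[1],
         c(ctr[1] + 0.45 * a, ctr[2], base_z)))
  seeds <- seeds[seq_len(min(n_sites, length(seeds)))]
  stimulus_set(smp$positions[seeds, , drop = FALSE],
               onset = rep_len(onsets, length(seeds)),
               radius = 2, scenario = "sinus")
}

#' Paired endocardial/epicardial ectopic foci
#'
#' Given a wall position, returns two single-seed stimulus sets on opposite
#' sides of the wall at the same circumferential/apicobasal location: the
#' sampling point of minimal wall depth (endocardial) and of maximal wall
#' depth (epicardial) within `search_radius` of the position. In septal mode
#' the two seeds are the points nearest the LV and RV septal faces instead.
#'
#' @param ventricle a `ventricle`.
#' @param position length-3 point inside the wall (mm).
#' @param mode `"free_wall"` or `"septal"`.
#' @param search_radius mm.
#' @param label scenario stem.
#' @return list of two `stimulus_set`s (`endo`/`epi`, or `left`/`right` for
#'   septal mode).
#' @export
ectopic_pair <- function(ventricle, position, mode = c("free_wall", "septal"),
                         search_radius = 14, label = "ectopic") {
  mode <- match.arg(mode)
  smp <- ventricle$sampling
  d <- sqrt(rowSums(sweep(smp$positions, 2, position, `-`)^2))
  loc <- which(d <= search_radius)
  if (length(loc) < 2) stop("position outside the myocardial wall")
  if (mode == "free_wall") {
    endo <- loc[which.min(smp$depth[loc])]
    epi <- loc[which.max(smp$depth[loc])]
    list(endo = stimulus_set(smp$positions[endo, , drop = FALSE],
                             scenario = paste0(label, "_endo")),
         epi = stimulus_set(smp$positions[epi, , drop = FALSE],
                            scenario = paste0(label, "_epi")))
  } else {
    cls <- ventricle$node_class[smp$nearest_surface_node]
    sep <- loc[cls[loc] == "septal"]
    if (length(sep) < 2) stop("no septal sampling points near position")
    ctr <- ventricle$params$center[1]
    lv_side <- sep[smp$positions[sep, 1] < ctr]
    rv_side <- sep[smp$positions[sep, 1] >= ctr]
    if (!length(lv_side) || !length(rv_side))
      stop("septal pair needs points on both septal faces")
    l <- lv_side[which.min(smp$depth[lv_side])]
    r <- rv_side[which.min(smp$depth[rv_side])]
    list(left = stimulus_set(smp$positions[l, , drop = FALSE],
                             scenario = paste0(label, "_left")),
         right = stimulus_set(smp$positions[r, , drop = FALSE],
                              scenario = paste0(label, "_right")))
  }
}

#' The eight-scenario ectopic catalogue
#'
#' Mirrors the study design: paired foci on both sides of the septum, on the
#' LV free wall (endo/epi), on the RV free wall (endo/epi), and basal LV/RV
#' near the septum.
#'
#' @param ventricle a biventricular `ventricle`.
#' @return named list of 8 single-seed `stimulus_set`s.
#' @export
ectopic_catalogue <- function(ventricle) {
  p <- ventricle$params
  ctr <- p$center; a <- p$axes
  cav <- p$cavities
  septum_x <- ctr[1] + (cav$lv$center[1] + cav$lv$axes[1] +
                        cav$rv$center[1] - cav$rv$axes[1]) / 2
  sept <- ectopic_pair(ventricle, c(septum_x, ctr[2], ctr[3] - 0.1 * a[3]),
                       mode = "septal", label = "septal")
  lv_mid <- c(ctr[1] - 0.88 * a[1], ctr[2], ctr[3] - 0.15 * a[3])
  lv <- ectopic_pair(ventricle, lv_mid, label = "lv_free_wall")
  rv_mid <- c(ctr[1] + 0.88 * a[1], ctr[2], ctr[3])
  rv <- ectopic_pair(ventricle, rv_mid, label = "rv_free_wall")
  basal_l <- ectopic_pair(ventricle,
                          c(septum_x - 0.25 * a[1], ctr[2], ctr[3] + 0.45 * a[3]),
                          label = "base_lv")
  basal_r <- ectopic_pair(ventricle,
                          c(septum_x + 0.28 * a[1], ctr[2], ctr[3] + 0.45 * a[3]),
                          label = "base_rv")
  list(septal_left = sept$left, septal_right = sept$right,
       base_lv = basal_l$endo, base_rv = basal_r$endo,
       lv_free_wall_epi = lv$epi, lv_free_wall_endo = lv$endo,
       rv_free_wall_endo = rv$endo, rv_free_wall_epi = rv$epi)
}
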