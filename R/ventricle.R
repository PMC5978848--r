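#' Synthetic ventricular geometry, fiber field and wall sampling
#'
#' Builds the closed ventricular surface used by the equivalent dipole layer
#' (EDL): an epicardial ellipsoid shell plus one or two endocardial cavity
#' shells (LV and RV). The endocardial components are oriented so that the
#' outward direction points away from the myocardium (into the cavity), which
#' is the orientation the EDL source layer requires; as stand-alone meshes the
#' cavity shells are ordinary closed ellipsoids. The septum is the muscle
#' between the two cavities.
#'
#' A rule-based fiber field is attached to a volumetric sampling of the wall:
#' the helix angle rotates linearly with wall depth from `+fiber_rotation/2`
#' at the endocardium to `-fiber_rotation/2` at the epicardium, about the
#' local circumferential direction.
#'
#' @param axes epicardial semi-axes (mm), default `c(38, 35, 55)` (x = LV->RV,
#'   z = base->apex axis).
#' @param wall_thickness LV free wall thickness in mm (must be smaller than
#'   the short axis); RV cavity is scaled along, giving a thinner RV wall.
#' @param subdiv icosphere subdivision levels, named `c(epi=, lv=, rv=)`.
#' @param fiber_rotation total endo-to-epi helix rotation in degrees
#'   (default 120: +60 endo to -60 epi).
#' @param grid_spacing volumetric sampling spacing h in mm (volume element
#'   dV = h^3).
#' @param chambers `"biventricular"` (default) or `"single"` (one concentric
#'   cavity; the cheap unit-test variant).
#' @param center heart center (mm) in the torso frame.
#'
#' @return list of class `ventricle` with elements
#'   `surface` (combined `triangle_surface`, endocardial faces flipped),
#'   `components` (list of the positively oriented component surfaces),
#'   `node_class` (factor: epicardial / endocardial / septal per surface node),
#'   `node_component` (epi/lv/rv per surface node),
#'   `fibers` (fiber field on the sampling: positions, directions, depth),
#'   `sampling` (myocardial sampling: positions, dV, grid index, neighbor
#'   structure, nearest surface node maps), and the generating parameters.
#' @export
build_ventricle <- function(axes = c(38, 35, 55),
                            wall_thickness = 11,
                            subdiv = c(epi = 3, lv = 3, rv = 2),
                            fiber_rotation = 120,
                            grid_spacing = 3,
                            chambers = c("biventricular", "single"),
                            center = c(0, 0, 0)) {
  chambers <- match.arg(chambers)
  a <- axes[1]; b <- axes[2]; c3 <- axes[3]
  if (!(wall_thickness < min(axes)))
    stop("wall thickness must be smaller than the short axis")

  if (chambers == "biventricular") {
    # cavity geometry in units of the epicardial axes
    lv_center0 <- c(-0.368 * a, 0, -0.091 * c3)
    lv_axes0   <- c(0.342 * a, 0.457 * b, 0.582 * c3)
    rv_center0 <- c(0.526 * a, 0, 0.036 * c3)
    rv_axes0   <- c(0.316 * a, 0.429 * b, 0.545 * c3)
    # scale the LV cavity so the LV free wall equals wall_thickness
    s_lv <- (a - abs(lv_center0[1]) - wall_thickness) / lv_axes0[1]
    if (s_lv <= 0.05) stop("wall thickness too large: LV cavity would vanish")
    lv_axes <- lv_axes0 * s_lv
    rv_axes <- rv_axes0 * s_lv
    cav <- list(lv = list(center = lv_center0, axes = lv_axes),
                rv = list(center = rv_center0, axes = rv_axes))
  } else {
    f <- (axes - wall_thickness) / axes
    if (any(f <= 0.05)) stop("wall thickness too large for a single-chamber cavity")
    cav <- list(lv = list(center = c(0, 0, 0), axes = axes - wall_thickness))
  }

  sd <- function(nm, def) if (nm %in% names(subdiv)) subdiv[[nm]] else def
  epi <- ellipsoid_surface(axes, center, subdiv = sd("epi", 3), label = "epicardium")
  comps <- list(epi = epi)
  for (nm in names(cav)) {
    comps[[nm]] <- ellipsoid_surface(cav[[nm]]$axes, center + cav[[nm]]$center,
                                     subdiv = sd(nm, 2),
                                     label = paste0("endocardium_", nm))
  }

  # geometric sanity: cavities strictly inside the epicardium, disjoint
  for (nm in names(cav)) {
    if (any(ellipsoid_inside(comps[[nm]]$vertices, axes, center) >= 0.999))
      stop("self-intersecting ventricular surface: cavity '", nm,
           "' touches the epicardium; reduce wall_thickness or cavity size")
  }
  if (length(cav) == 2) {
    for (pair in list(c("lv", "rv"), c("rv", "lv"))) {
      if (any(ellipsoid_inside(comps[[pair[1]]]$vertices,
                               cav[[pair[2]]]$axes,
                               center + cav[[pair[2]]]$center) <= 1.001))
        stop("self-intersecting ventricular surface: LV and RV cavities overlap")
    }
  }

  # combined EDL surface: cavity components flipped (outward = away from muscle)
  verts <- comps$epi$vertices
  faces <- comps$epi$faces
  comp_id <- rep("epi", nrow(verts))
  for (nm in names(cav)) {
    sc <- reverse_orientation(comps[[nm]])
    faces <- rbind(faces, sc$faces + nrow(verts))
    verts <- rbind(verts, sc$vertices)
    comp_id <- c(comp_id, rep(nm, nrow(sc$vertices)))
  }
  surface <- structure(list(vertices = verts, faces = faces, label = "ventricular_surface"),
                       class = "triangle_surface")

  # node classification: epicardial / endocardial / septal
  node_class <- ifelse(comp_id == "epi", "epicardial", "endocardial")
  if (length(cav) == 2) {
    lv_face <- center[1] + cav$lv$center[1] + 0.55 * cav$lv$axes[1]
    rv_face <- center[1] + cav$rv$center[1] - 0.55 * cav$rv$axes[1]
    node_class[comp_id == "lv" & verts[, 1] > lv_face] <- "septal"
    node_class[comp_id == "rv" & verts[, 1] < rv_face] <- "septal"
  }
  node_class <- factor(node_class, levels = c("epicardial", "endocardial", "septal"))

  sampling <- build_myocardial_sampling(axes, center, cav, surface, comp_id,
                                        grid_spacing)
  fibers <- rule_based_fibers(sampling$positions, sampling$depth, axes, center,
                              fiber_rotation)
  sampling$fiber <- fibers$directions

  structure(list(surface = surface, components = comps,
                 node_class = node_class, node_component = comp_id,
                 fibers = fibers, sampling = sampling,
                 params = list(axes = axes, wall_thickness = wall_thickness,
                               cavities = cav, subdiv = subdiv,
                               fiber_rotation = fiber_rotation,
                               grid_spacing = grid_spacing,
                               chambers = chambers, center = center)),
            class = "ventricle")
}

#' @export
print.ventricle <- function(x, ...) {
  cat(sprintf("<ventricle: %s, %d surface nodes (%s), %d wall sample points, h = %g mm>\n",
              x$params$chambers, nrow(x$surface$vertices),
              paste(sprintf("%s %d", names(table(x$node_class)), table(x$node_class)),
                    collapse = ", "),
              nrow(x$sampling$positions), x$params$grid_spacing))
  invisible(x)
}

# volumetric point sampling of the myocardial wall on a regular grid
build_myocardial_sampling <- function(axes, center, cav, surface, comp_id, h) {
  gx <- seq(center[1] - axes[1], center[1] + axes[1], by = h)
  gy <- seq(center[2] - axes[2], center[2] + axes[2], by = h)
  gz <- seq(center[3] - axes[3], center[3] + axes[3], by = h)
  grid <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  gidx <- as.matrix(expand.grid(i = seq_along(gx), j = seq_along(gy),
                                k = seq_along(gz)))
  inside <- ellipsoid_inside(grid, axes, center) < 0.985
  for (nm in names(cav))
    inside <- inside & ellipsoid_inside(grid, cav[[nm]]$axes,
                                        center + cav[[nm]]$center) > 1.02
  pos <- grid[inside, , drop = FALSE]
  gidx <- gidx[inside, , drop = FALSE]
  if (nrow(pos) < 50) stop("myocardial sampling too sparse; reduce grid_spacing")

  # distances to endo and epi component vertices -> wall depth in [0, 1]
  epi_v <- surface$vertices[comp_id == "epi", , drop = FALSE]
  endo_v <- surface$vertices[comp_id != "epi", , drop = FALSE]
  d_epi <- nearest_dist(pos, epi_v)
  d_endo <- nearest_dist(pos, endo_v)
  depth <- d_endo$dist / (d_endo$dist + d_epi$dist)

  d_all <- nearest_dist(pos, surface$vertices)
  # map each surface node to its nearest sampling point (for tau restriction)
  s2v <- nearest_dist(surface$vertices, pos)

  list(positions = pos, grid_index = gidx, spacing = h, dV = h^3,
       depth = depth, nearest_surface_node = d_all$idx,
       surface_to_sample = s2v$idx,
       n = nrow(pos))
}

# chunked nearest-neighbour search (exact, brute force)
nearest_dist <- function(p, q, chunk = 2000L) {
  n <- nrow(p)
  idx <- integer(n); dist <- numeric(n)
  q2 <- rowSums(q^2)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    pp <- p[s:e, , drop = FALSE]
    d2 <- outer(rowSums(pp^2), q2, `+`) - 2 * pp %*% t(q)
    j <- max.col(-d2, ties.method = "first")
    idx[s:e] <- j
    dist[s:e] <- sqrt(pmax(d2[cbind(seq_len(e - s + 1L), j)], 0))
  }
  list(idx = idx, dist = dist)
}

#' Rule-based myocardial fiber field
#'
#' Local frame from the epicardial ellipsoid: radial direction from the
#' implicit-function gradient, circumferential = z x radial, longitudinal
#' completes the frame. The fiber helix angle varies linearly with wall depth
#' `d` as `alpha(d) = rotation/2 - rotation * d` degrees (endo +rotation/2,
#' epi -rotation/2). Near the apex, where the circumferential direction
#' degenerates, a fixed fallback axis is used.
#'
#' @param positions n x 3 sample positions (mm).
#' @param depth wall-depth coordinate in `[0, 1]` (0 endo, 1 epi).
#' @param axes,center epicardial ellipsoid parameters.
#' @param rotation total rotation in degrees.
#' @return list of class `fiber_field`: `positions`, `directions` (unit rows),
#'   `depth`.
#' @export
rule_based_fibers <- function(positions, depth, axes, center, rotation = 120) {
  p <- sweep(positions, 2, center, `-`)
  grad <- sweep(p, 2, axes^2, `/`)        # gradient of sum((x/a)^2)
  rhat <- grad / pmax(sqrt(rowSums(grad^2)), .Machine$double.eps)
  zhat <- c(0, 0, 1)
  circ <- cbind(-rhat[, 2], rhat[, 1], 0)  # z x rhat
  cn <- sqrt(rowSums(circ^2))
  bad <- cn < 1e-6
  if (any(bad)) circ[bad, ] <- matrix(c(0, 1, 0), sum(bad), 3, byrow = TRUE)
  circ <- circ / pmax(sqrt(rowSums(circ^2)), .Machine$double.eps)
  long <- cbind(rhat[, 2] * circ[, 3] - rhat[, 3] * circ[, 2],
                rhat[, 3] * circ[, 1] - rhat[, 1] * circ[, 3],
                rhat[, 1] * circ[, 2] - rhat[, 2] * circ[, 1])
  long <- long / pmax(sqrt(rowSums(long^2)), .Machine$double.eps)
  alpha <- (rotation / 2 - rotation * depth) * pi / 180
  dirs <- circ * cos(alpha) + long * sin(alpha)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  structure(list(positions = positions, directions = dirs, depth = depth,
                 rotation = rotation),
            class = "fiber_field")
}

#' Transmural node pairs for the fastest route graph
#'
#' Links each endocardial (or septal) surface node to its nearest epicardial
#' node, so shortest paths can cross the wall with a distinct transmural
#' velocity.
#'
#' @param ventricle a `ventricle`.
#' @return 2-column integer matrix (endo node, epi node).
#' @export
transmural_pairs <- function(ventricle) {
  cls <- ventricle$node_class
  endo <- which(cls != "epicardial")
  epi <- which(cls == "epicardial")
  nn <- nearest_dist(ventricle$surface$vertices[endo, , drop = FALSE],
                     ventricle$surface$vertices[epi, , drop = FALSE])
  cbind(endo, epi[nn$idx])
}
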