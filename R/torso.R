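#' Volume conductor model
#'
#' Nested closed compartments with piecewise-constant isotropic conductivity.
#' Each compartment is a closed `triangle_surface` with the conductivity just
#' inside and just outside of it; outside the outermost (torso) surface the
#' conductivity is zero. Electrodes are torso-surface vertices.
#'
#' @param compartments named list; each element a list with `surface`
#'   (`triangle_surface`), `sigma_in`, `sigma_out` (S/m). The first element
#'   must be the outermost (torso) surface with `sigma_out = 0`.
#' @param electrodes integer vector of torso vertex indices used as
#'   electrodes.
#' @param check verify nesting and electrode placement.
#' @return object of class `volume_conductor`.
#' @export
volume_conductor <- function(compartments, electrodes, check = TRUE) {
  stopifnot(length(compartments) >= 1)
  if (compartments[[1]]$sigma_out != 0)
    stop("outermost compartment must have sigma_out = 0")
  for (cm in compartments) {
    if (cm$sigma_in <= 0) stop("conductivities must be strictly positive")
  }
  vcm <- structure(list(compartments = compartments, electrodes = electrodes),
                   class = "volume_conductor")
  if (check) validate_volume_conductor(vcm)
  vcm
}

#' @export
print.volume_conductor <- function(x, ...) {
  cat("<volume_conductor>\n")
  for (nm in names(x$compartments)) {
    cm <- x$compartments[[nm]]
    cat(sprintf("  %-12s %5d nodes  sigma_in %.3g  sigma_out %.3g S/m\n",
                nm, nrow(cm$surface$vertices), cm$sigma_in, cm$sigma_out))
  }
  cat(sprintf("  electrodes: %d on '%s'\n", length(x$electrodes),
              names(x$compartments)[1]))
  invisible(x)
}

#' Validate compartment nesting and electrode placement
#'
#' Inner surfaces must be strictly inside the torso surface and pairwise
#' disjoint; every electrode must lie on the torso surface (it is stored as a
#' torso vertex index, so this reduces to an index check plus uniqueness).
#'
#' @param vcm a `volume_conductor`.
#' @param tol containment tolerance on the winding number test.
#' @return invisibly `TRUE`, or an error.
#' @export
validate_volume_conductor <- function(vcm, tol = 1e-3) {
  outer <- vcm$compartments[[1]]$surface
  inner <- vcm$compartments[-1]
  for (nm in names(inner)) {
    s <- inner[[nm]]$surface
    w <- winding_fraction(s$vertices, outer)
    if (any(abs(w - 1) > tol))
      stop("compartment '", nm, "' not strictly inside the torso surface")
  }
  if (length(inner) > 1) {
    nms <- names(inner)
    for (i in seq_along(inner)) for (j in seq_along(inner)) {
      if (i == j) next
      w <- winding_fraction(inner[[i]]$surface$vertices, inner[[j]]$surface)
      if (any(w > 0.5 - tol) && !all(abs(w - 1) < tol))
        stop("compartments '", nms[i], "' and '", nms[j], "' intersect")
    }
  }
  el <- vcm$electrodes
  if (anyDuplicated(el) || any(el < 1) || any(el > nrow(outer$vertices)))
    stop("electrodes must be distinct torso vertex indices")
  invisible(TRUE)
}

# winding number (solid angle / 4pi) of a closed surface at query points:
# ~1 inside, ~0 outside
winding_fraction <- function(points, surface) {
  om <- solid_angle_matrix(points, surface$vertices, surface$faces,
                           lump = FALSE)
  rowSums(om) / (4 * pi)
}

#' Build the synthetic torso volume conductor
#'
#' Ellipsoidal torso containing two lungs, a ventricular heart (built with
#' [build_ventricle()]) and two blood compartments. Default conductivities
#' (S/m): thorax 0.2, lungs 0.04, blood 0.6; the heart bulk is 0.2, the sum of
#' the isotropic intra- (0.05) and extracellular (0.15) values, and equals the
#' thorax value, so the ventricular surface itself carries no conductivity
#' jump. The blood compartments are slightly shrunk copies of the endocardial
#' cavity shells so that the EDL source surface does not coincide with a
#' conductivity interface.
#'
#' @param ventricle a `ventricle`, positioned inside the torso (see
#'   `heart_center`).
#' @param torso_axes torso ellipsoid semi-axes (mm).
#' @param torso_subdiv,lung_subdiv icosphere subdivision levels.
#' @param n_electrodes number of electrodes, quasi-uniform over the torso
#'   surface (default 120).
#' @param conductivities named list: `thorax`, `lungs`, `blood`, `heart`
#'   (S/m). Set `lungs = NULL` to omit the lung compartments.
#' @param blood_shrink scale factor applied to cavity shells to form the
#'   blood compartments.
#' @return a `volume_conductor`; the heart bulk conductivity is carried in
#'   `attr(, "sigma_heart")`.
#' @export
build_torso <- function(ventricle,
                        torso_axes = c(140, 100, 240),
                        torso_subdiv = 3, lung_subdiv = 2,
                        n_electrodes = 120,
                        conductivities = list(thorax = 0.2, lungs = 0.04,
                                              blood = 0.6, heart = 0.2),
                        blood_shrink = 0.9) {
  torso <- ellipsoid_surface(torso_axes, c(0, 0, 0), subdiv = torso_subdiv,
                             label = "torso")
  comps <- list(torso = list(surface = torso,
                             sigma_in = conductivities$thorax, sigma_out = 0))
  if (!is.null(conductivities$lungs)) {
    lungc <- list(c(-85, -5, 60), c(85, -5, 60))
    lunga <- c(35, 45, 110)
    for (i in 1:2) {
      lg <- ellipsoid_surface(lunga, lungc[[i]], subdiv = lung_subdiv,
                              label = paste0("lung_", c("l", "r")[i]))
      comps[[paste0("lung_", c("l", "r")[i])]] <-
        list(surface = lg, sigma_in = conductivities$lungs,
             sigma_out = conductivities$thorax)
    }
  }
  # heart bulk: no conductivity jump when heart == thorax; recorded for BEM
  cavs <- ventricle$params$cavities
  hc <- ventricle$params$center
  for (nm in names(cavs)) {
    bl <- ellipsoid_surface(cavs[[nm]]$axes * blood_shrink,
                            hc + cavs[[nm]]$center,
                            subdiv = max(lung_subdiv, 2),
                            label = paste0("blood_", nm))
    comps[[paste0("blood_", nm)]] <-
      list(surface = bl, sigma_in = conductivities$blood,
           sigma_out = conductivities$heart)
  }
  el <- quasi_uniform_electrodes(torso, n_electrodes)
  vcm <- volume_conductor(comps, el)
  attr(vcm, "sigma_heart") <- conductivities$heart
  vcm
}

# quasi-uniform electrode selection: Fibonacci directions mapped to the
# ellipsoid, snapped to distinct torso vertices
quasi_uniform_electrodes <- function(torso, n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  dirs <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  v <- torso$vertices
  vn <- v / sqrt(rowSums(v^2))
  used <- integer(0)
  for (k in seq_len(n)) {
    d2 <- rowSums(sweep(vn, 2, dirs[k, ], `-`)^2)
    ord <- order(d2)
    j <- ord[!(ord %in% used)][1]
    used <- c(used, j)
  }
  used
}

#' Electrode coordinates of a volume conductor
#' @param vcm a `volume_conductor`.
#' @return matrix (n_electrodes x 3) of positions in mm.
#' @export
electrode_positions <- function(vcm) {
  vcm$compartments[[1]]$surface$vertices[vcm$electrodes, , drop = FALSE]
}

#' Conductivity setups of the anisotropy study
#'
#' The three myocardial conductivity cases: `isotropic`
#' (sigma_i = 0.05, sigma_e = 0.15 in both directions), `equal` (both spaces
#' have longitudinal/transversal ratio 3), and `unequal` (ratio 3
#' extracellular, 9 intracellular). The transversal values are shared by all
#' cases.
#'
#' @param case one of `"isotropic"`, `"equal"`, `"unequal"`.
#' @return list of class `conductivity_setup` with `sigma_i_l`, `sigma_i_t`,
#'   `sigma_e_l`, `sigma_e_t` (S/m), `case`, and `velocity_ratio`, the
#'   wavefront-speed anisotropy sqrt(sigma_i_l / sigma_i_t) used by the
#'   propagation surrogate.
#' @export
conductivity_setup <- function(case = c("isotropic", "equal", "unequal")) {
  case <- match.arg(case)
  s <- switch(case,
    isotropic = list(sigma_i_l = 0.05, sigma_i_t = 0.05,
                     sigma_e_l = 0.15, sigma_e_t = 0.15),
    equal     = list(sigma_i_l = 0.15, sigma_i_t = 0.05,
                     sigma_e_l = 0.45, sigma_e_t = 0.15),
    unequal   = list(sigma_i_l = 0.45, sigma_i_t = 0.05,
                     sigma_e_l = 0.45, sigma_e_t = 0.15))
  s$case <- case
  s$velocity_ratio <- sqrt(s$sigma_i_l / s$sigma_i_t)
  class(s) <- "conductivity_setup"
  s
}

#' EDL strength (potential-jump) factor
#'
#' The activation wavefront generates a potential jump of
#' `sigma_i / (sigma_i + sigma_e)` times the TMP amplitude; computed from the
#' isotropic (transversal) conductivities of a setup.
#'
#' @param setup a `conductivity_setup`.
#' @return dimensionless scalar (0.25 for the default values).
#' @export
edl_jump_factor <- function(setup = conductivity_setup("isotropic")) {
  setup$sigma_i_t / (setup$sigma_i_t + setup$sigma_e_t)
}
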