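#' Triangulated closed surfaces
#'
#' A `triangle_surface` is the basic geometric container of the package: a
#' closed, consistently oriented triangle mesh with vertex coordinates in mm.
#' All compartment boundaries of the volume conductor (thorax, lungs, blood
#' pools) and the components of the ventricular surface are stored this way.
#'
#' @param vertices numeric matrix (n x 3), coordinates in mm.
#' @param faces integer matrix (m x 3), 1-based vertex indices per triangle.
#' @param label compartment name.
#' @param check validate closedness/orientation/volume (default `TRUE`).
#'
#' @return An object of class `triangle_surface` with elements `vertices`,
#'   `faces`, `label`.
#' @export
triangle_surface <- function(vertices, faces, label = "surface", check = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  stopifnot(ncol(vertices) == 3L, ncol(faces) == 3L)
  s <- structure(list(vertices = vertices, faces = faces, label = label),
                 class = "triangle_surface")
  if (check) validate_surface(s)
  s
}

#' @export
print.triangle_surface <- function(x, ...) {
  cat(sprintf("<triangle_surface '%s': %d vertices, %d faces, area %.1f mm^2, volume %.1f mm^3>\n",
              x$label, nrow(x$vertices), nrow(x$faces),
              surface_area(x), enclosed_volume(x)))
  invisible(x)
}

#' Validate a closed oriented triangle surface
#'
#' Checks that every edge is shared by exactly two faces with opposite
#' traversal direction (closed, orientable, consistently oriented), that no
#' face is degenerate, and that the signed enclosed volume is positive.
#'
#' @param s a `triangle_surface`.
#' @param require_positive_volume set `FALSE` for surfaces deliberately
#'   oriented with inward normals (endocardial components seen from the
#'   myocardium).
#' @return invisibly `TRUE`; stops with a diagnostic otherwise.
#' @export
validate_surface <- function(s, require_positive_volume = TRUE) {
  f <- s$faces
  nv <- nrow(s$vertices)
  if (any(f < 1L | f > nv)) stop("face indices out of range")
  # directed edges: each undirected edge must appear exactly once per direction
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key_dir <- paste(he[, 1], he[, 2])
  if (anyDuplicated(key_dir))
    stop("surface not consistently oriented: repeated directed edge")
  key_und <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  cnt <- table(key_und)
  if (any(cnt != 2L))
    stop("surface not closed: ", sum(cnt != 2L), " edges not shared by exactly 2 faces")
  a <- face_areas(s)
  if (any(a <= 0) || any(!is.finite(a))) stop("degenerate face (area <= 0)")
  v <- enclosed_volume(s)
  if (require_positive_volume && v <= 0)
    stop(sprintf("signed enclosed volume %.3g not positive; orientation inverted?", v))
  invisible(TRUE)
}

#' Per-face areas, total area, enclosed volume, Euler characteristic
#'
#' @param s a `triangle_surface`.
#' @return `face_areas`: numeric vector (mm^2); `surface_area`: scalar (mm^2);
#'   `enclosed_volume`: signed scalar (mm^3, positive for outward
#'   orientation); `euler_characteristic`: integer V - E + F.
#' @export
face_areas <- function(s) {
  v <- s$vertices; f <- s$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' @rdname face_areas
#' @export
surface_area <- function(s) sum(face_areas(s))

#' @rdname face_areas
#' @export
enclosed_volume <- function(s) {
  v <- s$vertices; f <- s$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  d <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) +
      a[, 2] * (b[, 3] * d[, 1] - b[, 1] * d[, 3]) +
      a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])) / 6
}

#' @rdname face_areas
#' @export
euler_characteristic <- function(s) {
  f <- s$faces
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  ne <- length(unique(paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))))
  nv <- length(unique(as.vector(f)))
  nv - ne + nrow(f)
}

#' Outward unit vertex normals (area-weighted face normal average)
#' @param s a `triangle_surface`.
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(s) {
  v <- s$vertices; f <- s$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    for (d in 1:3) {
      n[, d] <- n[, d] + unname(tapply(fn[, d], factor(f[, k], levels = seq_len(nrow(v))),
                                       sum, default = 0))
    }
  }
  n[is.na(n)] <- 0
  n / pmax(sqrt(rowSums(n^2)), .Machine$double.eps)
}

# ---- icosphere / ellipsoid construction -------------------------------------

icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t, 0), c(1,  t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1,  t), c(0, 1,  t), c(0, -1, -t), c(0, 1, -t),
    c( t, 0, -1), c(t, 0,  1), c(-t, 0, -1), c(-t, 0,  1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

subdivide_mesh <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  nv <- nrow(v)
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  ekey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  uk <- unique(ekey)
  mid_id <- match(ekey, uk) + nv
  ue <- edges[!duplicated(ekey), , drop = FALSE]
  mids <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
  nf <- nrow(f)
  m12 <- mid_id[seq_len(nf)]
  m23 <- mid_id[nf + seq_len(nf)]
  m31 <- mid_id[2 * nf + seq_len(nf)]
  faces <- rbind(cbind(f[, 1], m12, m31),
                 cbind(f[, 2], m23, m12),
                 cbind(f[, 3], m31, m23),
                 cbind(m12, m23, m31))
  list(vertices = rbind(v, mids), faces = faces)
}

#' Triangulated sphere / ellipsoid by icosahedron subdivision
#'
#' Subdivides an icosahedron `subdiv` times, projects onto the unit sphere,
#' then scales/offsets onto an ellipsoid. Levels 2/3/4 give 162/642/2562
#' vertices. The result is closed, genus 0 and outward oriented by
#' construction.
#'
#' @param semiaxes length-3 semi-axes in mm.
#' @param center length-3 center in mm.
#' @param subdiv number of subdivision levels (>= 0).
#' @param label surface label.
#' @return a `triangle_surface`.
#' @export
ellipsoid_surface <- function(semiaxes = c(1, 1, 1), center = c(0, 0, 0),
                              subdiv = 3, label = "ellipsoid") {
  m <- icosahedron()
  for (i in seq_len(subdiv)) {
    m <- subdivide_mesh(m)
    m$vertices <- m$vertices / sqrt(rowSums(m$vertices^2))
  }
  v <- sweep(sweep(m$vertices, 2, semiaxes, `*`), 2, center, `+`)
  triangle_surface(v, m$faces, label = label)
}

# inside test for a point cloud against an axis-aligned ellipsoid
ellipsoid_inside <- function(p, semiaxes, center) {
  q <- sweep(sweep(p, 2, center, `-`), 2, semiaxes, `/`)
  rowSums(q^2)
}

reverse_orientation <- function(s) {
  s$faces <- s$faces[, c(1, 3, 2)]
  s
}

# ---- surface Laplacian ------------------------------------------------------

#' Surface Laplacian operator
#'
#' Symmetric graph (umbrella) Laplacian `L = D - W` over the mesh edge
#' structure, with unit edge weights. Rows sum to zero, so constants are
#' annihilated; on regular flat patches linear fields are annihilated in the
#' interior. Used as the second-order Tikhonov penalty on activation times.
#'
#' @param surface a `triangle_surface` (possibly multiple components).
#' @return sparse symmetric `dgCMatrix` (nodes x nodes).
#' @export
surface_laplacian <- function(surface) {
  f <- surface$faces
  nv <- nrow(surface$vertices)
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  und <- cbind(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  und <- und[!duplicated(paste(und[, 1], und[, 2])), , drop = FALSE]
  cnt_check <- table(table(paste(he[, 1], he[, 2])))
  # manifoldness: directed edges must be unique (checked cheaply here)
  if (any(as.integer(names(cnt_check)) > 1))
    stop("non-manifold edges: directed edge repeated")
  W <- Matrix::sparseMatrix(i = c(und[, 1], und[, 2]),
                            j = c(und[, 2], und[, 1]),
                            x = 1, dims = c(nv, nv))
  D <- Matrix::Diagonal(nv, Matrix::rowSums(W))
  methods::as(D - W, "CsparseMatrix")
}

# ---- geodesic graph ---------------------------------------------------------

#' Geodesic edge graph over a ventricular surface
#'
#' Builds the weighted graph used by the fastest route algorithm: mesh edges
#' carry their Euclidean length (mm); additional transmural edges link each
#' endocardial node to its nearest epicardial node so that the two wall sides
#' communicate with a distinct (slower) velocity.
#'
#' @param surface a `triangle_surface` (all ventricular components combined).
#' @param transmural_pairs 2-column integer matrix (endo node, epi node);
#'   `NULL` for none.
#' @return a list of class `geodesic_graph` with `graph` (igraph), `edges`
#'   (data.frame: from, to, length_mm, transmural), `n_nodes`.
#' @export
geodesic_graph <- function(surface, transmural_pairs = NULL) {
  f <- surface$faces
  v <- surface$vertices
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  und <- cbind(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  und <- und[!duplicated(paste(und[, 1], und[, 2])), , drop = FALSE]
  len <- sqrt(rowSums((v[und[, 1], , drop = FALSE] - v[und[, 2], , drop = FALSE])^2))
  tm <- rep(FALSE, nrow(und))
  if (!is.null(transmural_pairs) && nrow(transmural_pairs) > 0) {
    tp <- as.matrix(transmural_pairs)
    tlen <- sqrt(rowSums((v[tp[, 1], , drop = FALSE] - v[tp[, 2], , drop = FALSE])^2))
    und <- rbind(und, tp)
    len <- c(len, tlen)
    tm <- c(tm, rep(TRUE, nrow(tp)))
  }
  g <- igraph::graph_from_edgelist(und, directed = FALSE)
  if (igraph::vcount(g) < nrow(v))
    g <- igraph::add_vertices(g, nrow(v) - igraph::vcount(g))
  igraph::E(g)$length <- len
  igraph::E(g)$transmural <- tm
  comp <- igraph::components(g)
  if (comp$no != 1L)
    stop("geodesic graph disconnected (", comp$no, " components); add transmural pairs")
  structure(list(graph = g,
                 edges = data.frame(from = und[, 1], to = und[, 2],
                                    length_mm = len, transmural = tm),
                 n_nodes = nrow(v)),
            class = "geodesic_graph")
}

#' Shortest-path (geodesic) distances on a `geodesic_graph`
#'
#' @param gg a `geodesic_graph`.
#' @param from source node indices (default all).
#' @param surface_velocity,transmural_velocity mm/ms; when given, edge costs
#'   become travel times (ms) instead of lengths (mm).
#' @return matrix of distances (mm) or travel times (ms), `length(from)` x nodes.
#' @export
geodesic_distances <- function(gg, from = NULL, surface_velocity = NULL,
                               transmural_velocity = NULL) {
  w <- gg$edges$length_mm
  if (!is.null(surface_velocity)) {
    stopifnot(surface_velocity > 0, transmural_velocity > 0)
    w <- ifelse(gg$edges$transmural, w / transmural_velocity, w / surface_velocity)
  }
  if (is.null(from)) from <- seq_len(gg$n_nodes)
  igraph::distances(gg$graph, v = from, weights = w, algorithm = "dijkstra")
}
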