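#' Quality measures: relative difference, correlation, RMS
#'
#' `rd` is the Frobenius norm of the difference between simulated and
#' reconstructed signals relative to that of the simulated data;
#' `cor_flat` the Pearson correlation of the flattened values; `rms_diff`
#' the root-mean-square difference (ms for activation maps). Both COR and RD
#' are invariant to the zero-mean electrode reference when both inputs are
#' re-referenced.
#'
#' @param sim,rec equally shaped numeric vectors/matrices (simulated =
#'   reference first).
#' @return scalar.
#' @export
rd <- function(sim, rec) {
  sim <- as.matrix(sim); rec <- as.matrix(rec)
  stopifnot(all(dim(sim) == dim(rec)))
  ns <- sqrt(sum(sim^2))
  if (ns == 0) stop("reference signal has zero norm")
  sqrt(sum((sim - rec)^2)) / ns
}

#' @rdname rd
#' @export
cor_flat <- function(sim, rec) {
  sim <- as.vector(sim); rec <- as.vector(rec)
  stopifnot(length(sim) == length(rec))
  if (stats::sd(sim) == 0 || stats::sd(rec) == 0)
    stop("zero variance input to correlation")
  stats::cor(sim, rec)
}

#' @rdname rd
#' @export
rms_diff <- function(sim, rec) {
  sim <- as.vector(sim); rec <- as.vector(rec)
  stopifnot(length(sim) == length(rec))
  sqrt(mean((sim - rec)^2))
}

#' Focus localization error
#'
#' The recovered focus is the node with minimal reconstructed activation
#' time; reported are the Euclidean distance (mm) to the true seed position,
#' the geodesic (graph) distance when a graph is given, and the difference
#' between the reconstructed earliest activation time and the true onset
#' (ms). Exact ties on the minimum are broken by lowest node index and
#' flagged.
#'
#' @param tau_hat reconstructed activation map (ms, per surface node).
#' @param true_position true seed position (mm).
#' @param surface the ventricular `triangle_surface`.
#' @param true_onset true stimulus onset (ms).
#' @param graph optional `geodesic_graph` for the geodesic distance.
#' @return list: `node`, `distance_mm`, `geodesic_mm` (NA without graph),
#'   `diff_first_at_ms`, `tie`.
#' @export
focus_distance <- function(tau_hat, true_position, surface, true_onset = 0,
                           graph = NULL) {
  stopifnot(all(is.finite(tau_hat)))
  m <- min(tau_hat)
  ties <- which(tau_hat == m)
  node <- ties[1]
  d <- sqrt(sum((surface$vertices[node, ] - true_position)^2))
  gd <- NA_real_
  if (!is.null(graph)) {
    true_node <- which.min(rowSums(sweep(surface$vertices, 2, true_position, `-`)^2))
    gd <- as.numeric(geodesic_distances(graph, from = node)[1, true_node])
  }
  list(node = node, distance_mm = d, geodesic_mm = gd,
       diff_first_at_ms = tau_hat[node] - true_onset,
       tie = length(ties) > 1)
}

#' Early activation sites of an activation map
#'
#' Local minima of the activation map (with respect to the mesh neighbor
#' structure) whose value lies within `window` ms of the global minimum,
#' greedily thinned so that no two sites lie within `suppression_radius` mm
#' of each other (geodesic distance). The default window of 20 ms covers the
#' onset staggering of a Purkinje-like stimulation profile plus the
#' transmural breakthrough delay, so all rule-based sinus breakthrough sites
#' qualify as "early".
#'
#' @param tau activation map (ms per node).
#' @param graph a `geodesic_graph` of the surface.
#' @param suppression_radius mm (default 10).
#' @param window ms (default 20).
#' @return data.frame (node, tau); attribute `degenerate` flags an all-tied
#'   map.
#' @export
early_sites <- function(tau, graph, suppression_radius = 10, window = 20) {
  stopifnot(all(is.finite(tau)))
  el <- graph$edges
  n <- graph$n_nodes
  # local minimum: tau[i] <= tau[j] for all mesh neighbors j
  worse <- rep(FALSE, n)
  worse[el$from[tau[el$from] > tau[el$to]]] <- TRUE
  worse[el$to[tau[el$to] > tau[el$from]]] <- TRUE
  cand <- which(!worse & tau <= min(tau) + window)
  degenerate <- length(unique(tau)) == 1L
  cand <- cand[order(tau[cand], cand)]
  sites <- integer(0)
  if (length(cand)) {
    dmat <- geodesic_distances(graph, from = cand)
    for (i in seq_along(cand)) {
      if (!length(sites) ||
          all(dmat[i, sites] >= suppression_radius))
        sites <- c(sites, cand[i])
    }
  }
  out <- data.frame(node = sites, tau = tau[sites])
  attr(out, "degenerate") <- degenerate
  out
}

#' Endocardial/epicardial/septal class of a focus node
#'
#' @param node surface node index.
#' @param ventricle a `ventricle`.
#' @return character class label.
#' @export
focus_class <- function(node, ventricle) {
  as.character(ventricle$node_class[node])
}
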