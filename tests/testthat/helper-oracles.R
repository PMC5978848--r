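# Independent oracles, deliberately implemented apart from the package code
# paths they check.

# plain O(n^2) Dijkstra over an edge list (from, to, weight), undirected
oracle_dijkstra <- function(n, from, to, w, source) {
  dist <- rep(Inf, n)
  dist[source] <- 0
  visited <- rep(FALSE, n)
  adj <- vector("list", n)
  for (i in seq_along(from)) {
    adj[[from[i]]] <- rbind(adj[[from[i]]], c(to[i], w[i]))
    adj[[to[i]]] <- rbind(adj[[to[i]]], c(from[i], w[i]))
  }
  for (iter in seq_len(n)) {
    u <- which(!visited)[which.min(dist[!visited])]
    if (!length(u) || !is.finite(dist[u])) break
    visited[u] <- TRUE
    nb <- adj[[u]]
    if (is.null(nb)) next
    for (r in seq_len(nrow(nb))) {   # parallel edges: the minimum must win
      cand <- dist[u] + nb[r, 2]
      if (cand < dist[nb[r, 1]]) dist[nb[r, 1]] <- cand
    }
  }
  dist
}

oracle_graph_distances <- function(gg, sources, surface_velocity = NULL,
                                   transmural_velocity = NULL) {
  w <- gg$edges$length_mm
  if (!is.null(surface_velocity))
    w <- ifelse(gg$edges$transmural, w / transmural_velocity,
                w / surface_velocity)
  t(vapply(sources, function(s)
    oracle_dijkstra(gg$n_nodes, gg$edges$from, gg$edges$to, w, s),
    numeric(gg$n_nodes)))
}

# numeric ellipsoid surface area via 2D quadrature of the parametric element
oracle_ellipsoid_area <- function(a, b, c3, n = 400) {
  th <- seq(0, pi, length.out = n + 1)     # colatitude
  ph <- seq(0, 2 * pi, length.out = 2 * n + 1)
  dth <- th[2] - th[1]; dph <- ph[2] - ph[1]
  thm <- (th[-1] + th[-length(th)]) / 2
  phm <- (ph[-1] + ph[-length(ph)]) / 2
  acc <- 0
  for (t in thm) {
    st <- sin(t); ct <- cos(t)
    # |r_theta x r_phi| for r = (a st cos, b st sin, c ct)
    ex <- b * c3 * st^2 * cos(phm)
    ey <- a * c3 * st^2 * sin(phm)
    ez <- a * b * st * ct
    acc <- acc + sum(sqrt(ex^2 + ey^2 + ez^2)) * dth * dph
  }
  acc
}

# flat, regularly triangulated rectangular patch (for Laplacian checks)
flat_patch <- function(nx = 10, ny = 10, h = 1) {
  g <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  v <- cbind((g$x - 1) * h, (g$y - 1) * h, 0)
  id <- function(i, j) (j - 1) * nx + i
  f <- NULL
  for (j in seq_len(ny - 1)) for (i in seq_len(nx - 1)) {
    f <- rbind(f, c(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
               c(id(i, j), id(i + 1, j + 1), id(i, j + 1)))
  }
  interior <- which(g$x > 1 & g$x < nx & g$y > 1 & g$y < ny)
  list(vertices = v, faces = f, interior = interior)
}

# random jittered closed mesh (a deformed icosphere) for property tests
random_mesh <- function(seed, subdiv = 1, jitter = 0.15) {
  set.seed(seed)
  s <- ellipsoid_surface(c(1, 1, 1) * (1 + runif(3)), subdiv = subdiv)
  s$vertices <- s$vertices * (1 + jitter * matrix(runif(length(s$vertices), -1, 1),
                                                  ncol = 3))
  s
}

# local re-implementation of the predicted BSPM, to keep the objective
# check independent of the optimizer internals
bspm_pred_test <- function(transfer, tau, template, measured) {
  S <- template$s(outer(-tau, measured$times, `+`))
  P <- transfer$A %*% S
  sweep(P, 2, colMeans(P))
}
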