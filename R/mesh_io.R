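#' Mesh and table I/O
#'
#' Minimal readers/writers for the standard exchange formats used around the
#' pipeline: ASCII PLY and legacy ASCII VTK polydata for surfaces (0-based
#' vertex indices on disk, per the formats), CSV for electrode coordinates
#' (x,y,z in mm, one row per electrode) and activation maps (node, tau_ms),
#' and CSV+JSON for transfer matrices.
#'
#' @param surface a `triangle_surface`.
#' @param path file path.
#' @name mesh_io
NULL

#' @rdname mesh_io
#' @export
write_ply <- function(surface, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("comment %s", surface$label),
               sprintf("element vertex %d", nrow(surface$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(surface$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(format(surface$vertices, trim = TRUE, digits = 10),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  utils::write.table(cbind(3L, surface$faces - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname mesh_io
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply" || !grepl("ascii", lines[2]))
    stop("not an ASCII PLY file")
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)[1]))
  hdr <- which(lines == "end_header")
  lab <- sub("^comment ", "", grep("^comment", lines, value = TRUE)[1])
  if (is.na(lab)) lab <- "surface"
  v <- matrix(scan(text = lines[hdr + seq_len(nv)], quiet = TRUE),
              nv, 3, byrow = TRUE)
  f <- matrix(scan(text = lines[hdr + nv + seq_len(nf)], quiet = TRUE),
              nf, 4, byrow = TRUE)
  if (any(f[, 1] != 3)) stop("non-triangular faces in PLY")
  triangle_surface(v, f[, 2:4] + 1L, label = lab)
}

#' @rdname mesh_io
#' @param point_data optional named list of per-vertex scalar vectors to
#'   embed as `POINT_DATA` (e.g. an activation map).
#' @export
write_vtk <- function(surface, path, point_data = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", surface$label, "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(surface$vertices))), con)
  utils::write.table(format(surface$vertices, trim = TRUE, digits = 10),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  nf <- nrow(surface$faces)
  writeLines(sprintf("POLYGONS %d %d", nf, 4 * nf), con)
  utils::write.table(cbind(3L, surface$faces - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  if (!is.null(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nrow(surface$vertices)), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(format(point_data[[nm]], trim = TRUE, digits = 10), con)
    }
  }
  invisible(path)
}

#' @rdname mesh_io
#' @export
read_vtk <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)[1]
  nv <- as.integer(strsplit(lines[ip], " +")[[1]][2])
  vals <- scan(text = lines[(ip + 1):length(lines)], quiet = TRUE,
               n = 3 * nv)
  v <- matrix(vals, nv, 3, byrow = TRUE)
  ifc <- grep("^POLYGONS", lines)[1]
  nf <- as.integer(strsplit(lines[ifc], " +")[[1]][2])
  fv <- scan(text = lines[(ifc + 1):length(lines)], quiet = TRUE, n = 4 * nf)
  f <- matrix(fv, nf, 4, byrow = TRUE)
  if (any(f[, 1] != 3)) stop("non-triangular polygons in VTK")
  triangle_surface(v, f[, 2:4] + 1L, label = lines[2])
}

#' @rdname mesh_io
#' @param positions electrode coordinate matrix (n x 3, mm).
#' @export
write_electrodes_csv <- function(positions, path) {
  utils::write.csv(data.frame(x = positions[, 1], y = positions[, 2],
                              z = positions[, 3]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname mesh_io
#' @export
read_electrodes_csv <- function(path) {
  as.matrix(utils::read.csv(path))[, c("x", "y", "z"), drop = FALSE]
}

#' @rdname mesh_io
#' @param tau activation map (ms).
#' @export
write_activation_csv <- function(tau, path) {
  utils::write.csv(data.frame(node = seq_along(tau), tau_ms = tau),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname mesh_io
#' @export
read_activation_csv <- function(path) {
  d <- utils::read.csv(path)
  d$tau_ms[order(d$node)]
}

#' @rdname mesh_io
#' @param transfer an `edl_transfer`.
#' @param stem output path stem; writes `<stem>.csv` (matrix) and
#'   `<stem>.json` (metadata).
#' @export
write_transfer <- function(transfer, stem) {
  utils::write.table(transfer$A, paste0(stem, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(jump_factor = transfer$jump_factor,
                            amplitude = transfer$amplitude,
                            n_electrodes = transfer$n_electrodes,
                            n_nodes = transfer$n_nodes,
                            heart_label = transfer$heart_label),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname mesh_io
#' @export
read_transfer <- function(stem) {
  A <- as.matrix(utils::read.table(paste0(stem, ".csv"), sep = ","))
  dimnames(A) <- NULL
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  structure(list(A = A, jump_factor = meta$jump_factor,
                 amplitude = meta$amplitude,
                 n_electrodes = nrow(A), n_nodes = ncol(A),
                 heart_label = meta$heart_label),
            class = "edl_transfer")
}

#' @rdname mesh_io
#' @param x a `bspm`.
#' @export
write_bspm_csv <- function(x, path) {
  m <- as.data.frame(x$phi)
  names(m) <- sprintf("t%g", x$times)
  utils::write.csv(m, path, row.names = FALSE)
  invisible(path)
}

#' @rdname mesh_io
#' @export
read_bspm_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  times <- as.numeric(sub("^t", "", names(d)))
  bspm(as.matrix(d), times, rereference = FALSE)
}
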