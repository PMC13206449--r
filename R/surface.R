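#' Icosphere surface mesh
#'
#' Subdivides an icosahedron \code{subdivisions} times (each triangle into
#' four, midpoints projected to the unit sphere), giving a watertight
#' triangulation with \eqn{10 \cdot 4^n + 2} vertices.
#'
#' @param subdivisions non-negative subdivision count.
#' @return a \code{surface_mesh}: list with \code{vertices} (n x 3, unit
#'   norm), \code{faces} (m x 3 vertex indices), \code{edges} (e x 2).
#' @export
build_icosphere <- function(subdivisions = 0L) {
  if (subdivisions < 0) stop("subdivisions must be >= 0", call. = FALSE)
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
  for (s in seq_len(subdivisions)) {
    midpoint_cache <- new.env(hash = TRUE)
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- midpoint_cache[[key]]
      if (!is.null(hit)) return(hit)
      p <- v[a, ] + v[b, ]
      p <- p / sqrt(sum(p^2))
      newv[[length(newv) + 1L]] <<- p
      idx <- nv + length(newv)
      midpoint_cache[[key]] <- idx
      idx
    }
    newf <- matrix(0L, 4L * nrow(f), 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c3 <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      newf[(4 * i - 3):(4 * i), ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(c3, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- newf
  }
  e <- unique(t(apply(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)]), 1L, sort)))
  structure(list(vertices = v, faces = f, edges = e),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces, %d edges\n",
              nrow(x$vertices), nrow(x$faces), nrow(x$edges)))
  invisible(x)
}

# graph-geodesic distances (mm) between all vertex pairs: shortest paths
# along mesh edges weighted by chord length times mesh_scale
mesh_geodesics <- function(mesh, mesh_scale = 100) {
  v <- mesh$vertices
  e <- mesh$edges
  w <- sqrt(rowSums((v[e[, 1], ] - v[e[, 2], ])^2)) * mesh_scale
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  igraph::distances(g, weights = w)
}

#' Geodesic Gaussian smoothing of vertexwise data
#'
#' Per participant, replaces each vertex value with a Gaussian-weighted
#' average of its neighborhood:
#' \deqn{v_i \leftarrow \sum_j w_{ij} v_j / \sum_j w_{ij}, \quad
#'   w_{ij} = e^{-d_{ij}^2 / 2\sigma^2},}
#' with \eqn{\sigma = FWHM / (2\sqrt{2\ln 2})} and \eqn{d_{ij}} the
#' graph-geodesic distance in mm (mesh edge lengths scaled by
#' \code{mesh_scale}, a sphere radius of the order of a hemisphere).
#' Weights are truncated at \eqn{3\sigma} and renormalized.  Missing values
#' are excluded from both sums; \code{fwhm = 0} is the identity.
#'
#' @param m measure matrix whose columns are the mesh vertices.
#' @param mesh a \code{surface_mesh}.
#' @param fwhm smoothing level in mm (>= 0).
#' @param mesh_scale mm per unit-sphere distance (default 100).
#' @return the smoothed matrix (attributes preserved,
#'   \code{smoothing_fwhm} updated).
#' @export
smooth_vertex_data <- function(m, mesh, fwhm, mesh_scale = 100) {
  stopifnot(inherits(mesh, "surface_mesh"), fwhm >= 0)
  if (ncol(m) != nrow(mesh$vertices))
    stop(sprintf("matrix has %d columns but mesh has %d vertices",
                 ncol(m), nrow(mesh$vertices)), call. = FALSE)
  if (fwhm == 0) return(m)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  D <- mesh_geodesics(mesh, mesh_scale)
  W <- exp(-D^2 / (2 * sigma^2))
  W[D > 3 * sigma] <- 0
  W <- Matrix::Matrix(W, sparse = TRUE)
  vals <- m
  miss <- is.na(vals)
  vals[miss] <- 0
  num <- as.matrix(vals %*% W)
  den <- as.matrix((!miss) %*% W)
  out <- num / den
  out[den == 0] <- NA_real_
  dimnames(out) <- dimnames(m)
  for (a in c("metric", "truth")) attr(out, a) <- attr(m, a)
  attr(out, "smoothing_fwhm") <- fwhm
  out
}

#' Write / read a mesh as ASCII PLY
#'
#' @param mesh a \code{surface_mesh}.
#' @param path output file.
#' @return \code{write_mesh_ply}: the path, invisibly.
#'   \code{read_mesh_ply}: a \code{surface_mesh}.
#' @export
write_mesh_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(format(mesh$vertices, digits = 10), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, mesh$faces - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mesh_ply
#' @export
read_mesh_ply <- function(path) {
  lines <- readLines(path)
  hdr_end <- which(lines == "end_header")
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)))
  v <- do.call(rbind, lapply(strsplit(trimws(
    lines[(hdr_end + 1):(hdr_end + nv)]), "\\s+"), as.numeric))
  f <- do.call(rbind, lapply(strsplit(trimws(
    lines[(hdr_end + nv + 1):(hdr_end + nv + nf)]), "\\s+"),
    function(x) as.integer(x[-1]) + 1L))
  e <- unique(t(apply(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)]), 1L, sort)))
  structure(list(vertices = v, faces = f, edges = e),
            class = "surface_mesh")
}
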