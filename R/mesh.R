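#' Build a toy cortical mesh
#'
#' Constructs a triangulated surface used as the spatial support for the
#' synthetic source-space simulations: either a geodesic icosphere (a closed
#' surface obtained by repeated subdivision of an icosahedron, projected onto
#' a sphere) or a regular planar grid. An icosphere at subdivision level
#' \eqn{n} has \eqn{10 \cdot 4^n + 2} vertices and \eqn{20 \cdot 4^n}
#' triangles.
#'
#' @param spec A list describing the mesh. For an icosphere:
#'   `list(type = "icosphere", subdiv = 2, radius_mm = 50)`. For a planar
#'   grid: `list(type = "grid", nx = 20, ny = 15, spacing_mm = 5)`.
#' @return An object of class `cortical_mesh` with elements
#'   `vertex_coords` (n x 3 matrix, mm), `triangles` (m x 3 integer matrix of
#'   1-based vertex indices) and `n_vertices`.
#' @examples
#' mesh <- build_mesh(list(type = "icosphere", subdiv = 1))
#' mesh$n_vertices  # 42
#' @export
build_mesh <- function(spec) {
  stopifnot(is.list(spec), !is.null(spec$type))
  mesh <- switch(spec$type,
    icosphere = .icosphere(
      subdiv = if (is.null(spec$subdiv)) 2L else as.integer(spec$subdiv),
      radius = if (is.null(spec$radius_mm)) 50 else spec$radius_mm
    ),
    grid = .grid_mesh(
      nx = as.integer(spec$nx), ny = as.integer(spec$ny),
      spacing = if (is.null(spec$spacing_mm)) 5 else spec$spacing_mm
    ),
    stop("unknown mesh type: ", spec$type)
  )
  validate_mesh(mesh)
  mesh
}

new_cortical_mesh <- function(vertex_coords, triangles) {
  vertex_coords <- unname(as.matrix(vertex_coords))
  triangles <- unname(as.matrix(triangles))
  storage.mode(triangles) <- "integer"
  structure(
    list(
      vertex_coords = vertex_coords,
      triangles = triangles,
      n_vertices = nrow(vertex_coords)
    ),
    class = "cortical_mesh"
  )
}

#' @export
print.cortical_mesh <- function(x, ...) {
  cat(sprintf(
    "cortical_mesh: %d vertices, %d triangles\n",
    x$n_vertices, nrow(x$triangles)
  ))
  invisible(x)
}

#' Validate a cortical mesh
#'
#' Checks that the mesh has at least 4 vertices, finite coordinates,
#' in-range triangle indices, and forms a single connected component.
#'
#' @param mesh A `cortical_mesh`.
#' @return The mesh, invisibly; errors otherwise.
#' @export
validate_mesh <- function(mesh) {
  v <- mesh$vertex_coords
  tr <- mesh$triangles
  if (nrow(v) < 4L) stop("degenerate mesh: fewer than 4 vertices")
  if (!all(is.finite(v))) stop("mesh coordinates must be finite")
  if (any(tr < 1L) || any(tr > nrow(v))) {
    stop("triangle indices out of range")
  }
  if (!.mesh_connected(mesh)) stop("mesh is not a single connected component")
  invisible(mesh)
}

.mesh_connected <- function(mesh) {
  n <- mesh$n_vertices
  adj <- vector("list", n)
  tr <- mesh$triangles
  for (j in 1:3) {
    a <- tr[, j]
    b <- tr[, (j %% 3) + 1L]
    for (i in seq_along(a)) {
      adj[[a[i]]] <- c(adj[[a[i]]], b[i])
      adj[[b[i]]] <- c(adj[[b[i]]], a[i])
    }
  }
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    cur <- queue[1L]
    queue <- queue[-1L]
    nb <- adj[[cur]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, unique(new))
  }
  all(seen)
}

.icosphere <- function(subdiv, radius) {
  stopifnot(subdiv >= 0L, radius > 0)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  normalize <- function(m) m / sqrt(rowSums(m^2))
  v <- normalize(v)
  if (subdiv > 0L) {
    for (lev in seq_len(subdiv)) {
      midpoint <- new.env(hash = TRUE)
      verts <- v
      get_mid <- function(a, b) {
        key <- paste(min(a, b), max(a, b))
        hit <- midpoint[[key]]
        if (!is.null(hit)) return(hit)
        m <- (verts[a, ] + verts[b, ]) / 2
        verts <<- rbind(verts, m / sqrt(sum(m^2)))
        idx <- nrow(verts)
        midpoint[[key]] <- idx
        idx
      }
      newf <- matrix(0L, nrow(f) * 4L, 3L)
      for (i in seq_len(nrow(f))) {
        a <- f[i, 1L]; b <- f[i, 2L]; c <- f[i, 3L]
        ab <- get_mid(a, b); bc <- get_mid(b, c); ca <- get_mid(c, a)
        newf[(i - 1L) * 4L + 1:4, ] <- rbind(
          c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca)
        )
      }
      v <- verts
      f <- newf
    }
  }
  new_cortical_mesh(v * radius, f)
}

.grid_mesh <- function(nx, ny, spacing) {
  stopifnot(nx >= 2L, ny >= 2L, spacing > 0)
  xy <- expand.grid(x = seq_len(nx) - 1L, y = seq_len(ny) - 1L)
  v <- cbind(xy$x * spacing, xy$y * spacing, 0)
  idx <- function(ix, iy) (iy - 1L) * nx + ix
  tris <- vector("list", (nx - 1L) * (ny - 1L))
  k <- 0L
  for (iy in seq_len(ny - 1L)) {
    for (ix in seq_len(nx - 1L)) {
      k <- k + 1L
      a <- idx(ix, iy); b <- idx(ix + 1L, iy)
      c2 <- idx(ix, iy + 1L); d <- idx(ix + 1L, iy + 1L)
      tris[[k]] <- rbind(c(a, b, d), c(a, d, c2))
    }
  }
  new_cortical_mesh(v, do.call(rbind, tris))
}

#' Pairwise Euclidean vertex distances (mm)
#'
#' @param mesh A `cortical_mesh`.
#' @return A dense n x n distance matrix.
#' @export
mesh_distances <- function(mesh) {
  as.matrix(stats::dist(mesh$vertex_coords))
}

# Edge -> triangle incidence counts; 2 everywhere for a closed surface.
mesh_edge_counts <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  table(key)
}

#' Write / read a mesh as a two-section text file
#'
#' The format is plain text: a header, a vertex table (`x y z` in mm, one per
#' line) and a triangle table of 0-based vertex indices. Vertex indices are
#' 0-based in all files written by this package.
#'
#' @param mesh A `cortical_mesh`.
#' @param path Output file path.
#' @return `write_mesh` returns `path` invisibly; `read_mesh` returns a
#'   `cortical_mesh`.
#' @export
write_mesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# megpacr mesh v1 (vertex indices are 0-based)",
    sprintf("n_vertices %d", mesh$n_vertices),
    sprintf("n_triangles %d", nrow(mesh$triangles)),
    "vertices"
  ), con)
  utils::write.table(format(mesh$vertex_coords, digits = 17, trim = TRUE),
    con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines("triangles", con)
  utils::write.table(mesh$triangles - 1L, con,
    row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  lines <- readLines(path)
  nv <- as.integer(sub("n_vertices ", "", grep("^n_vertices ", lines, value = TRUE)[1]))
  nt <- as.integer(sub("n_triangles ", "", grep("^n_triangles ", lines, value = TRUE)[1]))
  iv <- which(lines == "vertices")[1]
  it <- which(lines == "triangles")[1]
  v <- do.call(rbind, lapply(strsplit(trimws(lines[(iv + 1):(iv + nv)]), "\\s+"), as.numeric))
  tr <- do.call(rbind, lapply(strsplit(trimws(lines[(it + 1):(it + nt)]), "\\s+"), as.integer)) + 1L
  mesh <- new_cortical_mesh(v, tr)
  validate_mesh(mesh)
  mesh
}

#' Import a FreeSurfer binary triangle surface
#'
#' Reads the classic big-endian FreeSurfer surface format (magic number
#' 16777214) as produced by e.g. `mris_convert`, returning coordinates in mm.
#'
#' @param path Path to a FreeSurfer surface file.
#' @return A `cortical_mesh`.
#' @export
read_fs_surface <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic_bytes <- readBin(con, "raw", 3L)
  magic <- sum(as.integer(magic_bytes) * c(65536, 256, 1))
  if (magic != 16777214L) stop("not a FreeSurfer triangle surface (bad magic)")
  # two newline-terminated comment lines
  nl <- 0L
  prev <- as.raw(0)
  while (nl < 2L) {
    b <- readBin(con, "raw", 1L)
    if (b == as.raw(10)) {
      nl <- nl + 1L
      prev <- b
      next
    }
    if (nl == 1L) nl <- 0L  # single newline inside comment resets
    prev <- b
  }
  nv <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  nf <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  v <- matrix(readBin(con, "numeric", nv * 3L, size = 4L, endian = "big"),
    ncol = 3L, byrow = TRUE)
  f <- matrix(readBin(con, "integer", nf * 3L, size = 4L, endian = "big"),
    ncol = 3L, byrow = TRUE) + 1L
  mesh <- new_cortical_mesh(v, f)
  validate_mesh(mesh)
  mesh
}
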