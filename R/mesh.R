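# Triangulated isosurfaces by marching tetrahedra on a regular grid. Each
# grid cell is split into six tetrahedra sharing the main diagonal; the
# decomposition is identical in every cell and face diagonals of neighboring
# cells coincide, so extracted surfaces are watertight wherever the level set
# does not touch the grid boundary. Vertices are deduplicated by the grid
# edge they lie on.

CUBE_CORNERS <- rbind(
  c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
  c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1)
)
CUBE_TETS <- rbind(
  c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
  c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7)
)

#' Extract an isosurface from a scalar grid (marching tetrahedra)
#'
#' @param values 3D array of node values.
#' @param level isovalue.
#' @param origin grid origin (position of node [1,1,1]).
#' @param spacing grid spacing (A).
#' @return a `surface_mesh`: list with `vertices` (n x 3), `faces` (m x 3
#'   vertex indices) and `edge_key` (internal). Empty mesh if the level is
#'   outside the value range.
#' @export
marching_tetrahedra <- function(values, level, origin = c(0, 0, 0), spacing = 1) {
  dm <- dim(values)
  nx <- dm[1]; ny <- dm[2]; nz <- dm[3]
  empty <- list(vertices = matrix(numeric(0), 0, 3),
                faces = matrix(integer(0), 0, 3))
  if (level <= min(values) || level >= max(values)) {
    return(structure(c(empty, list(level = level)), class = "surface_mesh"))
  }
  v <- values
  v[v == level] <- level + (max(abs(values)) + 1) * 1e-12
  # locate crossing cells
  sub <- function(dx, dy, dz) v[(1:(nx - 1)) + dx, (1:(ny - 1)) + dy, (1:(nz - 1)) + dz]
  lo <- hi <- sub(0, 0, 0)
  for (k in 2:8) {
    s <- sub(CUBE_CORNERS[k, 1], CUBE_CORNERS[k, 2], CUBE_CORNERS[k, 3])
    lo <- pmin(lo, s); hi <- pmax(hi, s)
  }
  cross <- which(lo < level & hi > level, arr.ind = TRUE)
  if (nrow(cross) == 0) {
    return(structure(c(empty, list(level = level)), class = "surface_mesh"))
  }
  node_id <- function(i, j, k) (k - 1) * nx * ny + (j - 1) * nx + i
  tri_edges <- list()   # each element: 3 rows of (nodeA, nodeB)
  for (ci in seq_len(nrow(cross))) {
    i0 <- cross[ci, 1]; j0 <- cross[ci, 2]; k0 <- cross[ci, 3]
    cid <- node_id(i0 + CUBE_CORNERS[, 1], j0 + CUBE_CORNERS[, 2],
                   k0 + CUBE_CORNERS[, 3])
    cv <- v[cid]
    for (t in 1:6) {
      tet <- CUBE_TETS[t, ]
      tv <- cv[tet]; tid <- cid[tet]
      ins <- tv < level
      ni <- sum(ins)
      if (ni == 0 || ni == 4) next
      a <- which(ins); b <- which(!ins)
      if (ni == 1 || ni == 3) {
        lone <- if (ni == 1) a else b
        rest <- if (ni == 1) b else a
        e <- rbind(c(tid[lone], tid[rest[1]]),
                   c(tid[lone], tid[rest[2]]),
                   c(tid[lone], tid[rest[3]]))
        tri_edges[[length(tri_edges) + 1]] <- e
      } else {
        e1 <- c(tid[a[1]], tid[b[1]]); e2 <- c(tid[a[1]], tid[b[2]])
        e3 <- c(tid[a[2]], tid[b[2]]); e4 <- c(tid[a[2]], tid[b[1]])
        tri_edges[[length(tri_edges) + 1]] <- rbind(e1, e2, e3)
        tri_edges[[length(tri_edges) + 1]] <- rbind(e1, e3, e4)
      }
    }
  }
  E <- do.call(rbind, tri_edges)
  key <- paste(pmin(E[, 1], E[, 2]), pmax(E[, 1], E[, 2]))
  uk <- unique(key)
  vid <- match(key, uk)
  faces <- matrix(vid, ncol = 3, byrow = TRUE)
  # interpolated vertex positions for the unique edges
  first <- match(uk, key)
  n1 <- E[first, 1]; n2 <- E[first, 2]
  pos_of <- function(id) {
    k <- (id - 1) %/% (nx * ny)
    r <- (id - 1) %% (nx * ny)
    j <- r %/% nx
    i <- r %% nx
    cbind(i, j, k)
  }
  p1 <- pos_of(n1); p2 <- pos_of(n2)
  v1 <- v[n1]; v2 <- v[n2]
  tt <- (level - v1) / (v2 - v1)
  verts <- sweep((p1 + tt * (p2 - p1)) * spacing, 2, origin, "+")
  # drop degenerate faces (two corners on the same edge)
  ok <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] & faces[, 1] != faces[, 3]
  structure(list(vertices = verts, faces = faces[ok, , drop = FALSE],
                 level = level),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Total area of a triangle mesh
#' @param mesh a `surface_mesh`.
#' @return area in Angstrom^2.
#' @export
mesh_area <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(0)
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  c0 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  u <- b - a; w <- c0 - a
  cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Is every mesh edge shared by exactly two faces?
#' @param mesh a `surface_mesh`.
#' @return TRUE for a closed (watertight) mesh.
#' @export
mesh_is_closed <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(FALSE)
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2)
}

#' Write a mesh as ASCII PLY
#' @param mesh a `surface_mesh`.
#' @param path output file.
#' @param values optional per-vertex scalar written as a `quality` property.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path, values = NULL) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nv),
           "property float x", "property float y", "property float z")
  if (!is.null(values)) hdr <- c(hdr, "property float quality")
  hdr <- c(hdr, sprintf("element face %d", nf),
           "property list uchar int vertex_indices", "end_header")
  vl <- if (is.null(values)) {
    sprintf("%.4f %.4f %.4f", mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3])
  } else {
    sprintf("%.4f %.4f %.4f %.4f", mesh$vertices[, 1], mesh$vertices[, 2],
            mesh$vertices[, 3], values)
  }
  fl <- sprintf("3 %d %d %d", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                mesh$faces[, 3] - 1L)
  writeLines(c(hdr, vl, fl), path)
  invisible(path)
}
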