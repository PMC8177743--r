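## Discretization of SO(3) via the 600-cell tessellation of the unit
## quaternion sphere. Cell-center quaternions give a near-uniform covering of
## rotation space used for global rotation scans; antipodal degeneracy
## (q ~ -q) means only the upper w-hemisphere is needed.

#' Construct the 600-cell
#'
#' Vertices are the 120 unit quaternions of the binary icosahedral group:
#' the 8 permutations of (+-1, 0, 0, 0), the 16 sign choices of
#' (+-1/2, +-1/2, +-1/2, +-1/2), and the 96 even permutations of
#' (+-phi, +-1, +-1/phi, 0) / 2 with phi the golden ratio. Tetrahedral cells
#' are the 4-cliques of the edge graph at the minimal vertex distance 1/phi;
#' the 600-cell has exactly 600 of them.
#'
#' @return A list with \code{vertices} (120 x 4 matrix of unit quaternions)
#'   and \code{cells} (600 x 4 integer matrix of vertex indices).
#' @export
build_600cell <- function() {
  phi <- (1 + sqrt(5)) / 2
  verts <- matrix(0, 0, 4)
  for (i in 1:4) for (s in c(1, -1)) {
    v <- numeric(4); v[i] <- s
    verts <- rbind(verts, v)
  }
  sgn <- as.matrix(expand.grid(c(.5, -.5), c(.5, -.5), c(.5, -.5), c(.5, -.5)))
  verts <- rbind(verts, unname(sgn))
  base <- c(phi, 1, 1 / phi, 0) / 2
  evenperms <- list(
    c(1, 2, 3, 4), c(1, 3, 4, 2), c(1, 4, 2, 3), c(2, 1, 4, 3),
    c(2, 3, 1, 4), c(2, 4, 3, 1), c(3, 1, 2, 4), c(3, 2, 4, 1),
    c(3, 4, 1, 2), c(4, 1, 3, 2), c(4, 2, 1, 3), c(4, 3, 2, 1))
  for (p in evenperms)
    for (s1 in c(1, -1)) for (s2 in c(1, -1)) for (s3 in c(1, -1)) {
      v <- base * c(s1, s2, s3, 1)
      verts <- rbind(verts, v[order(p)])
    }
  rownames(verts) <- NULL
  stopifnot(nrow(verts) == 120)

  ## edge graph at the minimal distance 1/phi; cells are its 4-cliques
  D <- as.matrix(stats::dist(verts))
  adj <- abs(D - 1 / phi) < 1e-9
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cl <- igraph::cliques(g, min = 4, max = 4)
  cells <- t(vapply(cl, as.integer, integer(4)))
  cells <- cells[order(cells[, 1], cells[, 2], cells[, 3], cells[, 4]), ]
  list(vertices = verts, cells = cells)
}

## internal: rotation_grid constructor from a (ncell x 4corner x 4coord)
## array of cell vertices
new_rotation_grid <- function(cell_verts, level) {
  n <- dim(cell_verts)[1]
  centers <- apply(cell_verts, c(1, 3), mean)
  centers <- centers / sqrt(rowSums(centers^2))
  structure(list(level = level, cells = cell_verts, quaternions = centers),
            class = "rotation_grid")
}

#' Level-0 rotation grid on the upper quaternion hemisphere
#'
#' Restricts the 600-cell to the cells covering the upper (w >= 0) hemisphere
#' of the 3-sphere: every cell whose centroid has w >= 0 is retained, which
#' keeps the 270 cells strictly above the equator plus all 60 equatorial
#' cells, 330 in total. Cell centroids projected onto the sphere are the grid
#' quaternions.
#'
#' @param cell600 Output of \code{\link{build_600cell}} (built if missing).
#' @return An object of class \code{rotation_grid} with fields \code{level}
#'   (0), \code{cells} (ncell x 4 x 4 array of cell-corner quaternions) and
#'   \code{quaternions} (ncell x 4 matrix of unit cell centers).
#' @export
hemisphere_grid <- function(cell600 = build_600cell()) {
  V <- cell600$vertices
  cells <- cell600$cells
  ## scalar (w) part is the first quaternion component
  cent_w <- vapply(seq_len(nrow(cells)),
                   function(i) mean(V[cells[i, ], 1]), numeric(1))
  keep <- which(cent_w >= -1e-9)
  arr <- array(0, c(length(keep), 4, 4))
  for (i in seq_along(keep)) arr[i, , ] <- V[cells[keep[i], ], ]
  new_rotation_grid(arr, level = 0L)
}

#' Refine a rotation grid by tetrahedral octasection
#'
#' Each tetrahedron is split into eight: four corner tetrahedra plus four
#' from the inner octahedron, split along its shortest diagonal. Edge
#' midpoints are renormalized onto the unit sphere, so all corners of all
#' children remain unit quaternions.
#'
#' @param grid A \code{rotation_grid}.
#' @param levels Number of successive subdivisions (each multiplies the cell
#'   count by 8).
#' @return A finer \code{rotation_grid}.
#' @export
subdivide <- function(grid, levels = 1) {
  stopifnot(inherits(grid, "rotation_grid"), levels >= 1)
  for (l in seq_len(levels)) {
    n <- dim(grid$cells)[1]
    out <- array(0, c(8 * n, 4, 4))
    for (i in seq_len(n))
      out[(8 * i - 7):(8 * i), , ] <- split_tetrahedron(grid$cells[i, , ])
    grid <- new_rotation_grid(out, level = grid$level + 1L)
  }
  grid
}

## internal: octasection of one spherical tetrahedron (4 x 4 matrix of
## corners) into an 8 x 4 x 4 array of children
split_tetrahedron <- function(tet) {
  mid <- function(i, j) {
    m <- (tet[i, ] + tet[j, ]) / 2
    m / sqrt(sum(m^2))
  }
  m12 <- mid(1, 2); m13 <- mid(1, 3); m14 <- mid(1, 4)
  m23 <- mid(2, 3); m24 <- mid(2, 4); m34 <- mid(3, 4)
  kids <- array(0, c(8, 4, 4))
  kids[1, , ] <- rbind(tet[1, ], m12, m13, m14)
  kids[2, , ] <- rbind(tet[2, ], m12, m23, m24)
  kids[3, , ] <- rbind(tet[3, ], m13, m23, m34)
  kids[4, , ] <- rbind(tet[4, ], m14, m24, m34)
  ## inner octahedron: opposite pairs (m12,m34), (m13,m24), (m14,m23);
  ## split along the shortest diagonal
  d <- c(sum((m12 - m34)^2), sum((m13 - m24)^2), sum((m14 - m23)^2))
  if (which.min(d) == 1) {
    p <- m12; q <- m34; ring <- list(m13, m14, m24, m23)
  } else if (which.min(d) == 2) {
    p <- m13; q <- m24; ring <- list(m12, m14, m34, m23)
  } else {
    p <- m14; q <- m23; ring <- list(m12, m13, m34, m24)
  }
  for (k in 1:4)
    kids[4 + k, , ] <- rbind(p, q, ring[[k]], ring[[k %% 4 + 1]])
  kids
}

#' Locate the grid cell whose cone contains a quaternion
#'
#' A quaternion lies in the cone of a tetrahedral cell if it is a nonnegative
#' combination of the cell's four corner quaternions.
#'
#' @param grid A \code{rotation_grid}.
#' @param q Unit quaternion.
#' @param tol Tolerance on the nonnegativity of the barycentric weights.
#' @return The index of a containing cell, or \code{NA_integer_} if none.
#' @export
find_cell <- function(grid, q, tol = 1e-9) {
  n <- dim(grid$cells)[1]
  for (i in seq_len(n)) {
    lam <- tryCatch(solve(t(grid$cells[i, , ]), q), error = function(e) NULL)
    if (!is.null(lam) && all(lam >= -tol)) return(i)
  }
  NA_integer_
}

#' Rotation angle between two quaternions
#'
#' The geodesic rotation angle \code{2 * acos(|<qa, qb>|)} in radians,
#' accounting for the antipodal degeneracy.
#'
#' @param qa,qb Unit quaternions.
#' @return Angle in radians, in \code{[0, pi]}.
#' @export
quaternion_angle <- function(qa, qb) {
  2 * acos(min(1, abs(sum(qa * qb))))
}

#' @export
print.rotation_grid <- function(x, ...) {
  cat("rotation_grid: level", x$level, "with", nrow(x$quaternions),
      "cells on the upper quaternion hemisphere\n")
  invisible(x)
}

#' Write / read a rotation grid's quaternions as CSV
#'
#' Columns \code{w,x,y,z,level}; intended for reproducible external scans.
#' Only the center quaternions are exported, not the cell geometry.
#'
#' @param grid A \code{rotation_grid}.
#' @param path Output CSV path.
#' @return \code{write_grid_csv} returns \code{path} invisibly;
#'   \code{read_grid_csv} returns a matrix of quaternions with a
#'   \code{"level"} attribute.
#' @export
write_grid_csv <- function(grid, path) {
  df <- data.frame(w = grid$quaternions[, 1], x = grid$quaternions[, 2],
                   y = grid$quaternions[, 3], z = grid$quaternions[, 4],
                   level = grid$level)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path) {
  df <- utils::read.csv(path)
  q <- as.matrix(df[, c("w", "x", "y", "z")])
  attr(q, "level") <- df$level[1]
  q
}
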