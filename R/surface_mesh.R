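#' Triangulated cortical surface mesh
#'
#' Construct and validate a `surface_mesh`: vertex coordinates in mm, triangle
#' faces (1-based vertex indices), and a per-vertex cortex mask marking which
#' vertices carry signal (medial-wall vertices are typically masked out after
#' surface projection).
#'
#' @param vertices numeric V x 3 matrix of vertex positions (mm).
#' @param faces integer F x 3 matrix of 1-based vertex indices, one row per
#'   triangle. All three indices of a face must be distinct.
#' @param mask optional logical vector of length V; `TRUE` marks vertices that
#'   enter the analysis. Defaults to all `TRUE`.
#' @param hemisphere optional character tag (e.g. `"lh"`, `"rh"`) carried as
#'   metadata; filled per-vertex by [merge_hemispheres()].
#'
#' @return An object of class `surface_mesh`: a list with elements
#'   `vertices`, `faces`, `mask`, `hemisphere`.
#' @seealso [read_surface()], [vertex_areas()], [build_neighborhoods()]
#' @export
#' @examples
#' mesh <- make_icosphere(0)
#' mesh
surface_mesh <- function(vertices, faces, mask = NULL, hemisphere = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  if (ncol(vertices) != 3L)
    stop("'vertices' must be a V x 3 matrix of coordinates")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(faces) != 3L)
    stop("'faces' must be an F x 3 matrix of vertex indices")
  v <- nrow(vertices)
  if (nrow(faces) > 0L) {
    if (anyNA(faces) || min(faces) < 1L || max(faces) > v)
      stop("face indices must lie in [1, ", v, "]; found out-of-range index ",
           if (anyNA(faces)) "NA" else faces[which(faces < 1L | faces > v)[1L]])
    degen <- faces[, 1L] == faces[, 2L] | faces[, 1L] == faces[, 3L] |
      faces[, 2L] == faces[, 3L]
    if (any(degen))
      stop("degenerate face (repeated vertex index) at row ", which(degen)[1L])
  }
  if (is.null(mask)) mask <- rep(TRUE, v)
  mask <- as.logical(mask)
  if (length(mask) != v || anyNA(mask))
    stop("'mask' must be a complete logical vector of length ", v)
  structure(
    list(vertices = vertices, faces = faces, mask = mask,
         hemisphere = hemisphere),
    class = "surface_mesh"
  )
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces),
      "faces;", sum(x$mask), "in cortex mask\n")
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)

#' Per-vertex surface area
#'
#' Distributes each triangle's area equally over its three corners:
#' `area(i) = (1/3) * sum of areas of triangles incident to i`. Total vertex
#' area equals total triangle area exactly, so cluster sizes reported in mm^2
#' partition the surface.
#'
#' @param mesh a [surface_mesh()].
#' @return numeric vector of length V, in mm^2. Vertices referenced by no face
#'   get area 0. Zero-area (collinear) triangles contribute 0 and raise a
#'   warning.
#' @export
vertex_areas <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  f <- mesh$faces
  v <- mesh$vertices
  if (nrow(f) == 0L) return(numeric(n_vertices(mesh)))
  a <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  b <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cx <- a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L]
  cy <- a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L]
  cz <- a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
  tri_area <- 0.5 * sqrt(cx^2 + cy^2 + cz^2)
  if (any(tri_area == 0))
    warning(sum(tri_area == 0), " zero-area triangle(s); they contribute no area")
  share <- tri_area / 3
  out <- numeric(n_vertices(mesh))
  for (k in 1:3) {
    acc <- tapply(share, f[, k], sum)
    idx <- as.integer(names(acc))
    out[idx] <- out[idx] + as.numeric(acc)
  }
  out
}

#' Unique undirected edges of a mesh
#'
#' @param mesh a [surface_mesh()].
#' @return integer E x 2 matrix, each row an edge with `[,1] < [,2]`.
#' @export
mesh_edges <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(1L, 3L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  e[!duplicated(e[, 1L] * (n_vertices(mesh) + 1) + e[, 2L]), , drop = FALSE]
}

# Sparse symmetric 0/1 adjacency over masked vertices only (edges incident to
# a masked-out vertex are dropped, so paths cannot traverse the medial wall).
mesh_adjacency <- function(mesh, masked_only = TRUE) {
  v <- n_vertices(mesh)
  e <- mesh_edges(mesh)
  if (masked_only) {
    keep <- mesh$mask[e[, 1L]] & mesh$mask[e[, 2L]]
    e <- e[keep, , drop = FALSE]
  }
  Matrix::sparseMatrix(i = c(e[, 1L], e[, 2L]), j = c(e[, 2L], e[, 1L]),
                       x = 1, dims = c(v, v))
}

#' Order-k neighborhood index
#'
#' For every masked vertex, the set of masked vertices at edge-graph distance
#' 1..`order` (self excluded). Order 2 is the neighborhood cluster I that the
#' vIFC statistic correlates each vertex against; vertices beyond it form the
#' "outside" set. Masked-out vertices are removed from the graph before the
#' breadth-first expansion, so they neither appear in neighbor sets nor relay
#' adjacency.
#'
#' @param mesh a [surface_mesh()].
#' @param order integer >= 1, maximum graph distance included.
#' @return An object of class `nbhd_index`: list with `neighbors` (length-V
#'   list of sorted integer vectors; `NULL` entries for masked-out vertices),
#'   `order`, `mask`, and `n_isolated`, the count of masked vertices left with
#'   an empty neighbor set (a diagnostic, not an error).
#' @export
#' @examples
#' nb <- build_neighborhoods(make_icosphere(0), order = 2)
#' lengths(nb$neighbors)  # every icosahedron vertex reaches all but its antipode
build_neighborhoods <- function(mesh, order = 2L) {
  stopifnot(inherits(mesh, "surface_mesh"))
  order <- as.integer(order)
  if (is.na(order) || order < 1L) stop("'order' must be an integer >= 1")
  a <- mesh_adjacency(mesh)
  reach <- a
  if (order > 1L) {
    step <- a
    for (k in 2:order) {
      step <- step %*% a
      reach <- reach + step
    }
  }
  reach <- methods::as(Matrix::drop0(reach), "generalMatrix")
  reach <- methods::as(reach, "CsparseMatrix")
  v <- n_vertices(mesh)
  neighbors <- vector("list", v)
  # column j of reach holds everything reachable from j within `order` steps
  p <- reach@p
  ri <- reach@i + 1L
  for (j in seq_len(v)) {
    if (!mesh$mask[j]) next
    idx <- if (p[j + 1L] > p[j]) ri[(p[j] + 1L):p[j + 1L]] else integer(0)
    neighbors[[j]] <- idx[idx != j]
  }
  n_isolated <- sum(vapply(seq_len(v), function(j)
    mesh$mask[j] && length(neighbors[[j]]) == 0L, logical(1)))
  structure(list(neighbors = neighbors, order = order, mask = mesh$mask,
                 n_isolated = n_isolated),
            class = "nbhd_index")
}

#' @export
print.nbhd_index <- function(x, ...) {
  deg <- lengths(x$neighbors[x$mask])
  cat("nbhd_index: order", x$order, "|", sum(x$mask), "masked vertices |",
      "neighbor count", min(deg), "-", max(deg), "|", x$n_isolated,
      "isolated\n")
  invisible(x)
}

#' Combine left and right hemisphere meshes into one analysis domain
#'
#' Concatenates two meshes into a single `surface_mesh` whose face graph keeps
#' the hemispheres disconnected (no cross-hemisphere edges), but whose vertex
#' set is shared by all downstream maps. With the combined mesh, the "outside"
#' set of the vIFC denominator spans both hemispheres, matching whole-cortex
#' analyses; passing a single mesh restricts it to that hemisphere.
#'
#' @param lh,rh [surface_mesh()] objects.
#' @return A `surface_mesh` with `hemisphere` a per-vertex character vector.
#' @export
merge_hemispheres <- function(lh, rh) {
  stopifnot(inherits(lh, "surface_mesh"), inherits(rh, "surface_mesh"))
  nl <- n_vertices(lh)
  surface_mesh(
    vertices = rbind(lh$vertices, rh$vertices),
    faces = rbind(lh$faces, rh$faces + nl),
    mask = c(lh$mask, rh$mask),
    hemisphere = c(rep("lh", nl), rep("rh", n_vertices(rh)))
  )
}
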