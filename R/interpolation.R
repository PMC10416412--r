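#' Fill missing plane values by linear interpolation
#'
#' Imputes the missing cells of one Z-plane by piecewise-linear
#' interpolation over the Delaunay triangulation of the observed cell
#' centers (via the interp package). Only cells inside the convex hull of
#' the observed cells can be filled; exterior missing cells stay `NA` and
#' flagged, and observed cells are never altered. Missing cells contribute
#' nothing to the interpolant — they are absent, not zero.
#'
#' @param pm A [plane_matrix()].
#' @return The plane with filled `values` and an extra logical matrix
#'   `imputed` marking the cells that were filled.
#' @export
fill_plane <- function(pm) {
  stopifnot(inherits(pm, "plane_matrix"))
  obs <- which(pm$observed & !is.na(pm$values), arr.ind = TRUE)
  if (nrow(obs) < 3) {
    stop("fill_plane needs at least 3 observed cells", call. = FALSE)
  }
  ox <- pm$x[obs[, 2]]
  oy <- pm$y[obs[, 1]]
  ov <- pm$values[obs]
  if (qr(cbind(ox - mean(ox), oy - mean(oy)))$rank < 2) {
    stop("observed cells are collinear; cannot interpolate a plane",
         call. = FALSE)
  }
  mis <- which(pm$missing, arr.ind = TRUE)
  pm$imputed <- matrix(FALSE, nrow(pm$values), ncol(pm$values))
  if (nrow(mis)) {
    qx <- pm$x[mis[, 2]]
    qy <- pm$y[mis[, 1]]
    r <- interp::interp(ox, oy, ov, xo = qx, yo = qy,
                        output = "points", method = "linear")
    filled <- !is.na(r$z)
    pm$values[mis[filled, , drop = FALSE]] <- r$z[filled]
    pm$imputed[mis[filled, , drop = FALSE]] <- TRUE
  }
  pm
}

#' Interpolate a 3D mutant-fraction volume from a map
#'
#' Builds a continuous scalar field from the quantified samples of a
#' [assemble_map()] by scattered-data interpolation over their Delaunay
#' tetrahedralization and evaluates it on a regular grid spanning the
#' sample bounding box. Natural-neighbor (Laplace weights) is the default;
#' `"linear"` is barycentric interpolation within each tetrahedron. Both
#' reproduce sample values at sample points, stay within the observed data
#' range, and refuse to extrapolate: grid nodes outside the convex hull of
#' the samples are flagged `FALSE` in `hull_mask` and carry `NA` —
#' extrapolated mutant fractions would not be meaningful.
#'
#' @param map A `mutation_map` (or a data.frame with `x_um`, `y_um`,
#'   `z_um`, `p_hat`, `status`).
#' @param resolution Integer length-3 grid size, default `c(50, 50, 25)`.
#' @param method `"natural_neighbor"` or `"linear"`.
#' @return An object of class `ctce_volume`: coordinate vectors `x`, `y`,
#'   `z` (micrometres), `values` (nx x ny x nz array in \[0, 1\], `NA`
#'   outside the hull), `hull_mask`, `method`, `sites`, and the fitted
#'   `interpolant`.
#' @export
interpolate_volume <- function(map, resolution = c(50, 50, 25),
                               method = c("natural_neighbor", "linear")) {
  method <- match.arg(method)
  stopifnot(length(resolution) == 3, all(resolution >= 2))
  d <- if (inherits(map, "mutation_map")) map$data else map
  d <- d[!is.na(d$p_hat) & d$status == "ok", , drop = FALSE]
  if (nrow(d) < 4) {
    stop("3D interpolation needs >= 4 quantified samples", call. = FALSE)
  }
  pts <- as.matrix(d[, c("x_um", "y_um", "z_um")])
  itp <- scattered_interpolant(pts, d$p_hat, method = method)
  gx <- seq(min(pts[, 1]), max(pts[, 1]), length.out = resolution[1])
  gy <- seq(min(pts[, 2]), max(pts[, 2]), length.out = resolution[2])
  gz <- seq(min(pts[, 3]), max(pts[, 3]), length.out = resolution[3])
  q <- as.matrix(expand.grid(x = gx, y = gy, z = gz,
                             KEEP.OUT.ATTRS = FALSE))
  v <- predict(itp, q)
  vol <- array(pmin(pmax(v, 0), 1), dim = resolution)
  structure(
    list(x = gx, y = gy, z = gz, values = vol, hull_mask = !is.na(vol),
         method = method, sites = d, interpolant = itp),
    class = "ctce_volume"
  )
}

#' @export
print.ctce_volume <- function(x, ...) {
  cat(sprintf(
    "<ctce_volume> %d x %d x %d grid (%s), %d/%d nodes inside hull\n",
    length(x$x), length(x$y), length(x$z), x$method,
    sum(x$hull_mask), length(x$hull_mask)))
  if (any(x$hull_mask)) {
    cat(sprintf("  fraction range %.4g .. %.4g from %d samples\n",
                min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE),
                nrow(x$sites)))
  }
  invisible(x)
}

#' Serialize a volume as a voxel CSV
#'
#' Long-format table with columns `x`, `y`, `z`, `value`, `in_hull`.
#' @param volume A `ctce_volume`.
#' @param path Output file.
#' @export
write_volume_csv <- function(volume, path) {
  stopifnot(inherits(volume, "ctce_volume"))
  g <- expand.grid(x = volume$x, y = volume$y, z = volume$z,
                   KEEP.OUT.ATTRS = FALSE)
  g$value <- as.vector(volume$values)
  g$in_hull <- as.vector(volume$hull_mask)
  utils::write.csv(g, path, row.names = FALSE)
  invisible(path)
}

# Corner offsets of the unit cube, index = 1 + dx + 2*dy + 4*dz.
.cube_corners <- rbind(
  c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0),
  c(0, 0, 1), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))

# Six-tetrahedron decomposition of a cube around the main diagonal v0-v7
# (one tet per axis-order path); face diagonals match between neighboring
# cubes, so the extracted surface is crack-free.
.cube_tets <- rbind(
  c(1, 2, 4, 8), c(1, 2, 6, 8), c(1, 3, 4, 8),
  c(1, 3, 7, 8), c(1, 5, 6, 8), c(1, 5, 7, 8))

#' Extract an isosurface mesh from a volume
#'
#' Marching-tetrahedra triangulation of the level set `values == level`,
#' restricted to grid cells whose eight corners all lie inside the convex
#' hull of the samples. Each cube is split into six tetrahedra; surface
#' vertices are placed on tetrahedron edges by inverse linear
#' interpolation of the corner values. Levels outside the value range
#' give an empty mesh.
#'
#' @param volume A [interpolate_volume()] result.
#' @param level Mutant-fraction level in (0, 1).
#' @return An object of class `iso_mesh`: `vertices` (n x 3, micrometres),
#'   `faces` (m x 3 vertex indices), `level`.
#' @export
extract_isosurface <- function(volume, level) {
  stopifnot(inherits(volume, "ctce_volume"))
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    stop("`level` must be a single value in (0, 1)", call. = FALSE)
  }
  V <- volume$values
  H <- volume$hull_mask
  nx <- length(volume$x)
  ny <- length(volume$y)
  nz <- length(volume$z)
  verts <- list()
  vkey <- new.env(hash = TRUE, parent = emptyenv())
  nvert <- 0L
  faces <- list()
  add_vertex <- function(pnt) {
    key <- paste(sprintf("%.10g", pnt), collapse = ",")
    id <- vkey[[key]]
    if (is.null(id)) {
      nvert <<- nvert + 1L
      id <- nvert
      vkey[[key]] <- id
      verts[[id]] <<- pnt
    }
    id
  }
  edge_cross <- function(tv, tp, i, j) {
    t <- (level - tv[i]) / (tv[j] - tv[i])
    t <- min(max(t, 0), 1)
    tp[i, ] + t * (tp[j, ] - tp[i, ])
  }
  for (iz in seq_len(nz - 1)) {
    for (iy in seq_len(ny - 1)) {
      for (ix in seq_len(nx - 1)) {
        ci <- ix + .cube_corners[, 1]
        cj <- iy + .cube_corners[, 2]
        ck <- iz + .cube_corners[, 3]
        lin <- cbind(ci, cj, ck)
        if (!all(H[lin])) next
        cv <- V[lin]
        if (min(cv) > level || max(cv) <= level) next
        cp <- cbind(volume$x[ci], volume$y[cj], volume$z[ck])
        for (ti in seq_len(nrow(.cube_tets))) {
          sel <- .cube_tets[ti, ]
          tv <- cv[sel]
          tp <- cp[sel, , drop = FALSE]
          above <- tv > level
          na <- sum(above)
          if (na == 0L || na == 4L) next
          if (na == 1L || na == 3L) {
            a <- if (na == 1L) which(above) else which(!above)
            oth <- setdiff(1:4, a)
            ids <- vapply(oth, function(o) {
              add_vertex(edge_cross(tv, tp, a, o))
            }, integer(1))
            faces[[length(faces) + 1L]] <- ids
          } else {
            ab <- which(above)
            cd <- which(!above)
            pac <- add_vertex(edge_cross(tv, tp, ab[1], cd[1]))
            pad <- add_vertex(edge_cross(tv, tp, ab[1], cd[2]))
            pbd <- add_vertex(edge_cross(tv, tp, ab[2], cd[2]))
            pbc <- add_vertex(edge_cross(tv, tp, ab[2], cd[1]))
            faces[[length(faces) + 1L]] <- c(pac, pad, pbd)
            faces[[length(faces) + 1L]] <- c(pac, pbd, pbc)
          }
        }
      }
    }
  }
  vmat <- if (nvert) do.call(rbind, verts) else matrix(numeric(0), 0, 3)
  fmat <- if (length(faces)) do.call(rbind, faces) else
    matrix(integer(0), 0, 3)
  # drop degenerate faces whose deduplicated vertices coincide
  if (nrow(fmat)) {
    ok <- fmat[, 1] != fmat[, 2] & fmat[, 1] != fmat[, 3] &
          fmat[, 2] != fmat[, 3]
    fmat <- fmat[ok, , drop = FALSE]
  }
  colnames(vmat) <- c("x", "y", "z")
  structure(list(vertices = vmat, faces = fmat, level = level),
            class = "iso_mesh")
}

#' @export
print.iso_mesh <- function(x, ...) {
  cat(sprintf("<iso_mesh> level %.3g: %d vertices, %d triangles\n",
              x$level, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Export a triangle mesh
#'
#' ASCII PLY or Wavefront OBJ.
#'
#' @param mesh An [extract_isosurface()] result.
#' @param path Output file.
#' @export
write_mesh_ply <- function(mesh, path) {
  stopifnot(inherits(mesh, "iso_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"),
             con)
  if (nrow(mesh$vertices)) {
    writeLines(sprintf("%.6f %.6f %.6f", mesh$vertices[, 1],
                       mesh$vertices[, 2], mesh$vertices[, 3]), con)
  }
  if (nrow(mesh$faces)) {
    writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                       mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  }
  invisible(path)
}

#' @rdname write_mesh_ply
#' @export
write_mesh_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "iso_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(mesh$vertices)) {
    writeLines(sprintf("v %.6f %.6f %.6f", mesh$vertices[, 1],
                       mesh$vertices[, 2], mesh$vertices[, 3]), con)
  }
  if (nrow(mesh$faces)) {
    writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                       mesh$faces[, 3]), con)
  }
  invisible(path)
}
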