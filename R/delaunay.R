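# Incremental (Bowyer-Watson) Delaunay tetrahedralization and the two
# scattered-data interpolants built on it: linear barycentric within the
# containing tetrahedron, and natural-neighbor with Laplace weights
# (Voronoi facet area over site distance, computed from the circumcenters
# of the insertion cavity).
#
# All geometry runs in normalized coordinates (the data bounding box scaled
# into the unit cube) with a tiny deterministic site jitter, which keeps
# the floating-point in-sphere test well conditioned on regular-grid
# sampling designs where many sites are exactly cospherical.

#' Delaunay tetrahedralization of scattered 3D points
#'
#' @param points Numeric n x 3 matrix, n >= 4, not all coplanar.
#' @param jitter Relative magnitude of the deterministic symmetry-breaking
#'   perturbation applied in normalized coordinates.
#' @return An object of class `delaunay3d`: `points` (original), `tets`
#'   (m x 4 vertex indices), plus internal normalized geometry.
#' @export
delaunay3d <- function(points, jitter = 1e-8) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  stopifnot(ncol(points) == 3, nrow(points) >= 4, all(is.finite(points)))
  n <- nrow(points)
  ctr <- colMeans(points)
  if (qr(sweep(points, 2, ctr))$rank < 3) {
    stop("degenerate geometry: sample points are coplanar or collinear; ",
         "3D interpolation needs >= 4 non-coplanar samples", call. = FALSE)
  }
  lo <- apply(points, 2, min)
  span <- max(apply(points, 2, max) - lo)
  p <- sweep(points, 2, lo) / span
  p <- p + with_seed(derive_seed(20260101L, "delaunay", n), {
    matrix(stats::runif(3 * n, -jitter, jitter), ncol = 3)
  })
  sup <- rbind(c(-50, -50, -50), c(150, -50, -50),
               c(-50, 150, -50), c(-50, -50, 150))
  verts <- rbind(p, sup)
  tets <- matrix(n + 1:4, nrow = 1)
  geo <- circumsphere(verts, tets)
  cc <- geo$center
  r2 <- geo$r2
  ord <- with_seed(derive_seed(20260101L, "insertion", n), sample.int(n))
  for (q_i in ord) {
    q <- p[q_i, ]
    d2 <- (cc[, 1] - q[1])^2 + (cc[, 2] - q[2])^2 + (cc[, 3] - q[3])^2
    bad <- which(d2 <= r2 * (1 + 1e-12) + 1e-300)
    if (!length(bad)) next # numerically outside everything; cannot happen
    bad <- cavity_component(verts, tets, bad, q)
    faces <- tet_faces(tets[bad, , drop = FALSE])
    key <- face_key(faces)
    boundary <- faces[!(key %in% key[duplicated(key)]), , drop = FALSE]
    newt <- cbind(boundary, q_i)
    keep <- setdiff(seq_len(nrow(tets)), bad)
    tets <- rbind(tets[keep, , drop = FALSE], newt)
    geo_new <- circumsphere(verts, newt)
    cc <- rbind(cc[keep, , drop = FALSE], geo_new$center)
    r2 <- c(r2[keep], geo_new$r2)
  }
  real <- rowSums(tets > n) == 0
  tets <- tets[real, , drop = FALSE]
  structure(
    list(points = points, tets = unname(tets), norm_points = p,
         norm_origin = lo, norm_scale = span,
         cc = cc[real, , drop = FALSE], r2 = r2[real]),
    class = "delaunay3d"
  )
}

# Faces of each tet as sorted vertex triples (4 per tet).
tet_faces <- function(tets) {
  f <- rbind(tets[, c(1, 2, 3), drop = FALSE],
             tets[, c(1, 2, 4), drop = FALSE],
             tets[, c(1, 3, 4), drop = FALSE],
             tets[, c(2, 3, 4), drop = FALSE])
  lo <- pmin(f[, 1], f[, 2], f[, 3])
  hi <- pmax(f[, 1], f[, 2], f[, 3])
  cbind(lo, f[, 1] + f[, 2] + f[, 3] - lo - hi, hi, deparse.level = 0)
}

# Collision-free integer key for sorted vertex triples (vertex ids stay
# far below 2^17, so the packed key fits exactly in a double).
face_key <- function(faces) {
  (faces[, 1] * 131072 + faces[, 2]) * 131072 + faces[, 3]
}

# Circumcenters and squared radii for a block of tets; degenerate (flat)
# tets get r2 = -Inf so they never capture an insertion point.
circumsphere <- function(verts, tets) {
  m <- nrow(tets)
  center <- matrix(NA_real_, m, 3)
  r2 <- numeric(m)
  for (i in seq_len(m)) {
    a <- verts[tets[i, 1], ]
    mat <- rbind(verts[tets[i, 2], ] - a,
                 verts[tets[i, 3], ] - a,
                 verts[tets[i, 4], ] - a)
    # offset o = center - a satisfies mat %*% o = rowSums(mat^2) / 2
    sol <- tryCatch(solve(mat, 0.5 * rowSums(mat^2)),
                    error = function(e) NULL)
    if (is.null(sol)) {
      center[i, ] <- a
      r2[i] <- -Inf
    } else {
      center[i, ] <- a + as.numeric(sol)
      r2[i] <- sum(sol^2)
    }
  }
  list(center = center, r2 = r2)
}

# Restrict a candidate cavity to the face-connected component containing
# the tetrahedron that holds q (floating-point safety net: a spurious
# in-sphere hit elsewhere must not punch a disconnected hole).
cavity_component <- function(verts, tets, bad, q) {
  if (length(bad) <= 1) return(bad)
  host <- NA_integer_
  for (b in bad) {
    w <- barycentric_one(verts, tets[b, ], q)
    if (!is.null(w) && all(w >= -1e-9)) {
      host <- b
      break
    }
  }
  if (is.na(host)) return(bad)
  keys <- matrix(face_key(tet_faces(tets[bad, , drop = FALSE])),
                 nrow = length(bad)) # one row per bad tet, 4 face keys
  comp_i <- match(host, bad)
  frontier <- comp_i
  rest <- setdiff(seq_along(bad), comp_i)
  while (length(frontier) && length(rest)) {
    fkeys <- as.vector(keys[frontier, , drop = FALSE])
    hit <- rest[rowSums(matrix(keys[rest, , drop = FALSE] %in% fkeys,
                               nrow = length(rest))) > 0]
    comp_i <- c(comp_i, hit)
    frontier <- hit
    rest <- setdiff(rest, hit)
  }
  bad[comp_i]
}

barycentric_one <- function(verts, tet, q) {
  a <- verts[tet[1], ]
  mat <- cbind(verts[tet[2], ] - a, verts[tet[3], ] - a, verts[tet[4], ] - a)
  w <- tryCatch(solve(mat, q - a), error = function(e) NULL)
  if (is.null(w)) return(NULL)
  c(1 - sum(w), w)
}

#' Locate query points in a tetrahedralization
#'
#' @param tri A [delaunay3d()].
#' @param queries k x 3 matrix (original coordinates).
#' @return A list: `tet` (tet index per query, `NA` outside the convex
#'   hull) and `bary` (k x 4 barycentric weights w.r.t. that tet's
#'   vertices).
#' @export
locate_points <- function(tri, queries) {
  stopifnot(inherits(tri, "delaunay3d"))
  q <- normalize_queries(tri, queries)
  k <- nrow(q)
  tet_id <- rep(NA_integer_, k)
  bary <- matrix(NA_real_, k, 4)
  open <- rep(TRUE, k)
  tol <- 1e-9
  p <- tri$norm_points
  for (ti in seq_len(nrow(tri$tets))) {
    if (!any(open)) break
    v <- tri$tets[ti, ]
    a <- p[v[1], ]
    mat <- cbind(p[v[2], ] - a, p[v[3], ] - a, p[v[4], ] - a)
    inv <- tryCatch(solve(mat), error = function(e) NULL)
    if (is.null(inv)) next
    box_lo <- pmin(p[v[1], ], p[v[2], ], p[v[3], ], p[v[4], ]) - tol
    box_hi <- pmax(p[v[1], ], p[v[2], ], p[v[3], ], p[v[4], ]) + tol
    cand <- which(open &
                  q[, 1] >= box_lo[1] & q[, 1] <= box_hi[1] &
                  q[, 2] >= box_lo[2] & q[, 2] <= box_hi[2] &
                  q[, 3] >= box_lo[3] & q[, 3] <= box_hi[3])
    if (!length(cand)) next
    w <- t(inv %*% (t(q[cand, , drop = FALSE]) - a))
    w1 <- 1 - rowSums(w)
    inside <- w[, 1] >= -tol & w[, 2] >= -tol & w[, 3] >= -tol & w1 >= -tol
    hit <- cand[inside]
    if (length(hit)) {
      tet_id[hit] <- ti
      bary[hit, ] <- cbind(w1[inside], w[inside, , drop = FALSE])
      open[hit] <- FALSE
    }
  }
  list(tet = tet_id, bary = bary)
}

normalize_queries <- function(tri, queries) {
  q <- as.matrix(queries)
  storage.mode(q) <- "double"
  if (ncol(q) != 3) stop("queries must have 3 columns", call. = FALSE)
  sweep(q, 2, tri$norm_origin) / tri$norm_scale
}

#' Scattered-data interpolant over a Delaunay tetrahedralization
#'
#' `method = "linear"` interpolates barycentrically within the containing
#' tetrahedron (C0, exact at sites, convex weights). `method =
#' "natural_neighbor"` uses Laplace natural-neighbor weights — for each
#' query, the Voronoi facet area between the query and each natural
#' neighbor divided by their distance — computed from the circumcenters of
#' the tetrahedra whose circumspheres contain the query. Both are exact at
#' sample sites (queries within snapping distance of a site return the
#' site value) and never overshoot the observed data range; both return
#' `NA` outside the convex hull of the sites rather than extrapolate.
#'
#' @param points n x 3 site coordinates.
#' @param values Numeric values at the sites.
#' @param method `"natural_neighbor"` (default) or `"linear"`.
#' @return An object of class `scattered_interpolant`; evaluate with
#'   [predict.scattered_interpolant()].
#' @export
scattered_interpolant <- function(points, values,
                                  method = c("natural_neighbor", "linear")) {
  method <- match.arg(method)
  points <- as.matrix(points)
  stopifnot(length(values) == nrow(points), all(is.finite(values)))
  tri <- delaunay3d(points)
  structure(list(tri = tri, values = as.numeric(values), method = method),
            class = "scattered_interpolant")
}

#' Evaluate a scattered-data interpolant
#'
#' @param object A [scattered_interpolant()].
#' @param queries k x 3 matrix of coordinates.
#' @param ... Unused.
#' @return Numeric vector; `NA` outside the convex hull of the sites.
#' @export
predict.scattered_interpolant <- function(object, queries, ...) {
  tri <- object$tri
  q <- as.matrix(queries)
  if (length(q) == 3 && is.null(dim(queries))) q <- matrix(q, 1)
  vals <- object$values
  out <- rep(NA_real_, nrow(q))
  qn <- normalize_queries(tri, q)
  snap <- snap_to_sites(tri, qn)
  loc <- locate_points(tri, q)
  for (j in seq_len(nrow(q))) {
    if (!is.na(snap[j])) {
      out[j] <- vals[snap[j]]
    } else if (!is.na(loc$tet[j])) {
      if (object$method == "linear") {
        v <- tri$tets[loc$tet[j], ]
        out[j] <- sum(loc$bary[j, ] * vals[v])
      } else {
        out[j] <- laplace_nn_value(tri, vals, qn[j, ], loc$tet[j])
      }
    }
  }
  out
}

# Queries within snapping distance of a (pre-jitter true) site index; the
# interpolation contract returns the site value exactly there. Chunked
# vectorized distance computation; coordinates are normalized.
snap_to_sites <- function(tri, qn, radius = 1e-6) {
  p0 <- sweep(tri$points, 2, tri$norm_origin) / tri$norm_scale
  k <- nrow(qn)
  snap <- rep(NA_integer_, k)
  pp <- rowSums(p0^2)
  step <- 4000L
  for (s in seq(1L, k, by = step)) {
    e <- min(s + step - 1L, k)
    qc <- qn[s:e, , drop = FALSE]
    d2 <- outer(rowSums(qc^2), pp, "+") - 2 * qc %*% t(p0)
    i <- max.col(-d2, ties.method = "first")
    dmin <- d2[cbind(seq_len(nrow(d2)), i)]
    hit <- dmin < radius^2
    snap[(s:e)[hit]] <- i[hit]
  }
  snap
}

# Laplace natural-neighbor value at one normalized query point.
laplace_nn_value <- function(tri, vals, q, host) {
  p <- tri$norm_points
  tets <- tri$tets
  d2 <- (tri$cc[, 1] - q[1])^2 + (tri$cc[, 2] - q[2])^2 +
        (tri$cc[, 3] - q[3])^2
  inside <- which(d2 <= tri$r2 * (1 + 1e-12) + 1e-300)
  if (!length(inside)) inside <- host
  if (!(host %in% inside)) inside <- c(host, inside)
  inside <- cavity_component(p, tets, inside, q)
  faces <- tet_faces(tets[inside, , drop = FALSE])
  key <- face_key(faces)
  boundary <- faces[!(key %in% key[duplicated(key)]), , drop = FALSE]
  # circumcenters of the would-be new tets (q + boundary face)
  m <- nrow(boundary)
  ccs <- matrix(NA_real_, m, 3)
  for (i in seq_len(m)) {
    vv <- rbind(q, p[boundary[i, 1], ], p[boundary[i, 2], ],
                p[boundary[i, 3], ])
    g <- circumsphere(vv, matrix(1:4, 1))
    ccs[i, ] <- g$center
  }
  nbrs <- sort(unique(as.integer(boundary)))
  w <- numeric(length(nbrs))
  for (k in seq_along(nbrs)) {
    v <- nbrs[k]
    rows <- which(boundary[, 1] == v | boundary[, 2] == v |
                  boundary[, 3] == v)
    if (length(rows) < 3) next
    poly <- ccs[rows, , drop = FALSE]
    if (any(!is.finite(poly))) next
    u <- p[v, ] - q
    du <- sqrt(sum(u^2))
    if (du < 1e-14) return(vals[v])
    u <- u / du
    e1 <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- e1 - sum(e1 * u) * u
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(u[2] * e1[3] - u[3] * e1[2],
            u[3] * e1[1] - u[1] * e1[3],
            u[1] * e1[2] - u[2] * e1[1])
    ctr <- colMeans(poly)
    s1 <- as.numeric((poly - rep(ctr, each = nrow(poly))) %*% e1)
    s2 <- as.numeric((poly - rep(ctr, each = nrow(poly))) %*% e2)
    ord <- order(atan2(s2, s1))
    s1 <- s1[ord]
    s2 <- s2[ord]
    area <- abs(sum(s1 * c(s2[-1], s2[1]) - c(s1[-1], s1[1]) * s2)) / 2
    w[k] <- area / du
  }
  if (sum(w) <= 0) {
    # degenerate facet geometry: fall back to barycentric in the host tet
    v <- tets[host, ]
    bw <- barycentric_one(p, v, q)
    return(sum(pmax(bw, 0) * vals[v]) / sum(pmax(bw, 0)))
  }
  sum(w * vals[nbrs]) / sum(w)
}
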