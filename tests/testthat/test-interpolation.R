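make_plane <- function(values, missing = NULL) {
  nr <- nrow(values)
  nc <- ncol(values)
  miss <- matrix(FALSE, nr, nc)
  if (!is.null(missing)) miss[missing] <- TRUE
  vals <- values
  vals[miss] <- NA_real_
  structure(list(values = vals, missing = miss,
                 observed = !miss, x = seq_len(nc) * 100,
                 y = seq_len(nr) * 100, z_index = 0, z_um = 0,
                 wells = matrix("w", nr, nc), disc_radius = 40),
            class = "plane_matrix")
}

test_that("plane fill is linear, hull-limited and leaves data untouched", {
  v <- matrix(runif(20), 4, 5)
  # no missing cells: identity
  expect_equal(fill_plane(make_plane(v))$values, v)
  # one interior missing cell in a constant field is filled with it
  c5 <- matrix(0.5, 4, 5)
  pm <- make_plane(c5, missing = cbind(2, 3))
  filled <- fill_plane(pm)
  expect_equal(filled$values[2, 3], 0.5)
  expect_true(filled$imputed[2, 3])
  # linearity: midpoint of a linear ramp
  ramp <- outer(rep(1, 4), seq(0, 1, length.out = 5))
  pm2 <- make_plane(ramp, missing = cbind(2, 3))
  expect_equal(fill_plane(pm2)$values[2, 3], 0.5, tolerance = 1e-9)
  # a corner cell outside the observed hull stays flagged
  pm3 <- make_plane(ramp, missing = rbind(c(1, 1), c(1, 2), c(2, 1)))
  f3 <- fill_plane(pm3)
  expect_true(is.na(f3$values[1, 1]))
  expect_false(f3$imputed[1, 1])
  # observed cells unchanged
  expect_equal(f3$values[3:4, ], ramp[3:4, ])
  expect_error(fill_plane(make_plane(matrix(1, 1, 2))), "at least 3")
})

test_that("linear interpolation agrees with the brute-force oracle", {
  worst <- 0
  for (cfgi in 1:20) {
    cfg <- random_config(n = 12 + cfgi, seed = 100 + cfgi)
    it <- scattered_interpolant(cfg$points, cfg$values, "linear")
    set.seed(500 + cfgi)
    q <- cbind(runif(100, 0, 100), runif(100, 0, 80), runif(100, 0, 40))
    mine <- predict(it, q)
    ref <- oracle_linear(it$tri, cfg$values, q)
    expect_identical(is.na(mine), is.na(ref))
    if (any(!is.na(mine))) {
      worst <- max(worst, max(abs(mine - ref), na.rm = TRUE))
    }
  }
  expect_lt(worst, 1e-9)
})

test_that("interpolants are exact at sites and bounded by the data range", {
  for (method in c("linear", "natural_neighbor")) {
    cfg <- random_config(n = 30, seed = 77)
    it <- scattered_interpolant(cfg$points, cfg$values, method)
    expect_equal(predict(it, cfg$points), cfg$values, tolerance = 1e-9)
    set.seed(78)
    q <- cbind(runif(150, 0, 100), runif(150, 0, 80), runif(150, 0, 40))
    v <- predict(it, q)
    v <- v[!is.na(v)]
    expect_gte(min(v), min(cfg$values) - 1e-9)
    expect_lte(max(v), max(cfg$values) + 1e-9)
  }
})

test_that("interpolants are continuous along interior segments", {
  cfg <- random_config(n = 40, seed = 13)
  ctr <- colMeans(cfg$points)
  for (method in c("linear", "natural_neighbor")) {
    it <- scattered_interpolant(cfg$points, cfg$values, method)
    set.seed(14)
    jumps <- c()
    for (s in 1:5) {
      # segment between interior points (shrunk toward the centroid)
      a <- ctr + 0.5 * (cfg$points[sample(40, 1), ] - ctr)
      b <- ctr + 0.5 * (cfg$points[sample(40, 1), ] - ctr)
      tt <- seq(0, 1, length.out = 120)
      seg <- outer(tt, b - a) + rep(a, each = 120)
      v <- predict(it, seg)
      dv <- abs(diff(v))
      jumps <- c(jumps, dv[!is.na(dv)])
    }
    # steps of h ~ 1% of the domain must not produce O(1) jumps
    expect_lt(max(jumps), 0.15 * diff(range(cfg$values)))
  }
})

test_that("4-point barycentric interpolation averages at the centroid", {
  pts <- rbind(c(0, 0, 0), c(100, 0, 0), c(0, 100, 0), c(0, 0, 100))
  vals <- c(0.1, 0.3, 0.5, 0.9)
  it <- scattered_interpolant(pts, vals, "linear")
  # tolerance reflects the triangulation's 1e-8 symmetry-breaking jitter
  expect_lt(abs(predict(it, matrix(colMeans(pts), 1)) - mean(vals)), 1e-8)
})

test_that("volume interpolation covers the hull and rejects degeneracy", {
  # constant map: volume identically 0.3 inside the hull
  cfg <- random_config(n = 25, seed = 5)
  d <- data.frame(x_um = cfg$points[, 1], y_um = cfg$points[, 2],
                  z_um = cfg$points[, 3], p_hat = 0.3, status = "ok")
  vol <- interpolate_volume(d, resolution = c(10, 10, 6), method = "linear")
  expect_true(all(abs(vol$values[vol$hull_mask] - 0.3) < 1e-9))
  expect_true(all(is.na(vol$values[!vol$hull_mask])))
  expect_identical(vol$hull_mask, !is.na(vol$values))
  # coplanar samples are refused with a named deficiency
  flat <- data.frame(x_um = runif(10), y_um = runif(10), z_um = 5,
                     p_hat = 0.5, status = "ok")
  expect_error(interpolate_volume(flat, resolution = c(5, 5, 5)),
               "coplanar")
})

test_that("interpolation recovers a smooth field better with more samples", {
  f <- make_clone_field(c(1000, 800, 400),
                        list(list(center = c(500, 400, 200),
                                  scale = c(250, 200, 120), peak = 0.9)),
                        0.05)
  set.seed(31)
  qx <- cbind(runif(150, 200, 800), runif(150, 150, 650),
              runif(150, 80, 320))
  truth <- eval_field(f, qx)
  rmse <- vapply(c(50, 100, 200), function(n) {
    set.seed(1000 + n)
    pts <- cbind(runif(n, 0, 1000), runif(n, 0, 800), runif(n, 0, 400))
    it <- scattered_interpolant(pts, eval_field(f, pts), "linear")
    v <- predict(it, qx)
    sqrt(mean((v - truth)^2, na.rm = TRUE))
  }, numeric(1))
  expect_lt(rmse[3], rmse[1])
})

test_that("isosurface recovers the analytic level set of a Gaussian bump", {
  sigma <- 30
  vol <- gaussian_volume(sigma = sigma, peak = 0.9, half = 60, n = 25)
  mesh <- extract_isosurface(vol, 0.45)
  expect_gt(nrow(mesh$faces), 0)
  r <- sqrt(rowSums(mesh$vertices^2))
  r_true <- sigma * sqrt(2 * log(2))
  cell <- max(diff(vol$x))
  expect_lt(max(abs(r - r_true)), cell)
  # per-vertex trilinear residual stays below the cell variation bound
  res <- apply(mesh$vertices, 1, function(p) trilinear_at(vol, p) - 0.45)
  grad_scale <- 0.9 * exp(-0.5) / sigma # max |df/dr| of the Gaussian
  expect_lt(max(abs(res)), grad_scale * cell)
  # level above the maximum: empty mesh
  empty <- extract_isosurface(vol, 0.95)
  expect_equal(nrow(empty$vertices), 0)
  expect_equal(nrow(empty$faces), 0)
  expect_error(extract_isosurface(vol, 1.2), "level")
})

test_that("meshes have valid topology and export to PLY and OBJ", {
  vol <- gaussian_volume(n = 15)
  mesh <- extract_isosurface(vol, 0.45)
  expect_true(all(mesh$faces >= 1 & mesh$faces <= nrow(mesh$vertices)))
  dir <- withr::local_tempdir()
  write_mesh_ply(mesh, ply <- file.path(dir, "m.ply"))
  write_mesh_obj(mesh, obj <- file.path(dir, "m.obj"))
  hdr <- readLines(ply, n = 12)
  expect_equal(hdr[1], "ply")
  expect_true(sprintf("element vertex %d", nrow(mesh$vertices)) %in% hdr)
  obj_lines <- readLines(obj)
  expect_equal(sum(startsWith(obj_lines, "v ")), nrow(mesh$vertices))
  expect_equal(sum(startsWith(obj_lines, "f ")), nrow(mesh$faces))
})
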