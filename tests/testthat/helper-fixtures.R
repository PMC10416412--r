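# Shared fixtures: quiet noise-free generator settings, a small random
# scattered-data generator, and the independent brute-force barycentric
# oracle used to cross-check the linear interpolant.

quiet_params <- function(...) trace_params(noise_sd = 0, ...)

# Random non-degenerate scattered configuration for interpolation tests.
random_config <- function(n = 20, seed = 1) {
  set.seed(seed)
  list(points = cbind(runif(n, 0, 100), runif(n, 0, 80), runif(n, 0, 40)),
       values = runif(n))
}

# Brute-force linear interpolation oracle: for each query, scan every
# tetrahedron, solve the barycentric system directly, and accept the first
# tetrahedron whose weights are all non-negative (sign test). Independent
# of the bounding-box walk used by locate_points().
oracle_linear <- function(tri, vals, queries) {
  p <- tri$norm_points
  qn <- ctce3d:::normalize_queries(tri, queries)
  vapply(seq_len(nrow(qn)), function(j) {
    for (ti in seq_len(nrow(tri$tets))) {
      tet <- tri$tets[ti, ]
      a <- p[tet[1], ]
      mat <- cbind(p[tet[2], ] - a, p[tet[3], ] - a, p[tet[4], ] - a)
      w <- tryCatch(solve(mat, qn[j, ] - a), error = function(e) NULL)
      if (is.null(w)) next
      w <- c(1 - sum(w), w)
      if (all(w >= -1e-9)) return(sum(w * vals[tet]))
    }
    NA_real_
  }, numeric(1))
}

# Trilinear interpolation inside a ctce_volume, for mesh residual checks.
trilinear_at <- function(vol, pnt) {
  ix <- findInterval(pnt[1], vol$x, all.inside = TRUE)
  iy <- findInterval(pnt[2], vol$y, all.inside = TRUE)
  iz <- findInterval(pnt[3], vol$z, all.inside = TRUE)
  fx <- (pnt[1] - vol$x[ix]) / (vol$x[ix + 1] - vol$x[ix])
  fy <- (pnt[2] - vol$y[iy]) / (vol$y[iy + 1] - vol$y[iy])
  fz <- (pnt[3] - vol$z[iz]) / (vol$z[iz + 1] - vol$z[iz])
  v <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
         (if (dz) fz else 1 - fz)
    v <- v + w * vol$values[ix + dx, iy + dy, iz + dz]
  }
  v
}

# Analytic single-Gaussian volume on a full (all-in-hull) grid.
gaussian_volume <- function(sigma = 30, peak = 0.9, half = 60, n = 25) {
  g <- seq(-half, half, length.out = n)
  vals <- array(0, dim = c(n, n, n))
  for (k in seq_len(n)) {
    r2 <- outer(g^2, g^2, "+") + g[k]^2
    vals[, , k] <- peak * exp(-r2 / (2 * sigma^2))
  }
  structure(list(x = g, y = g, z = g, values = vals,
                 hull_mask = array(TRUE, dim = c(n, n, n)),
                 method = "analytic", sites = NULL, interpolant = NULL),
            class = "ctce_volume")
}

# Minimal fraction table for a fully observed single-plane layout.
full_fraction_table <- function(lay, values) {
  pos <- enumerate_positions(lay)
  data.frame(well = pos$well, p_hat = values, n_eff = 15000,
             ci_low = pmax(values - 0.01, 0),
             ci_high = pmin(values + 0.01, 1),
             normality_ok = TRUE, status = "ok",
             stringsAsFactors = FALSE)
}
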