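demo_plane <- function(values, missing_wells = character(0)) {
  lay <- grid_layout(n_blocks = 1, rows = 3, cols = 4, z_planes = 0)
  ft <- full_fraction_table(lay, values)
  ft$status[ft$well %in% missing_wells] <- "no signal"
  plane_matrix(assemble_map(ft, lay), 0)
}

test_that("color mapping is monotone over the fixed range", {
  spec <- figure_spec()
  v <- sort(runif(30))
  pal <- grDevices::hcl.colors(256, spec$colormap)
  idx <- match(fraction_colors(v, spec), pal)
  expect_true(all(diff(idx) >= 0))
  expect_equal(fraction_colors(NA, spec), spec$missing_col)
  # the top of the range maps to the palette's top color
  expect_equal(fraction_colors(1, spec), pal[256])
  expect_equal(fraction_colors(0, spec), pal[1])
})

test_that("circle maps encode fractions as rim arcs and missing as grey", {
  vals <- c(0, 0.25, 1, seq(0.1, 0.9, length.out = 9))
  pm <- demo_plane(vals)
  dir <- withr::local_tempdir()
  objs <- render_circle_map(pm, figure_spec(), f <- file.path(dir, "c.png"))
  expect_true(file.exists(f))
  expect_equal(nrow(objs), 12)
  # proportional encoding with the documented endpoints
  expect_equal(objs$arc_deg[objs$fraction == 0], 0)
  expect_equal(objs$arc_deg[objs$fraction == 1], 360)
  expect_equal(objs$arc_deg[abs(objs$fraction - 0.25) < 1e-12], 90)
  # grey circle count equals the plane's missing count
  lay <- grid_layout(n_blocks = 1, rows = 3, cols = 4, z_planes = 0)
  wells <- enumerate_positions(lay)$well
  pm2 <- demo_plane(vals, missing_wells = wells[c(2, 7)])
  objs2 <- render_circle_map(pm2, figure_spec(), file.path(dir, "c2.png"))
  expect_equal(sum(objs2$missing), sum(pm2$missing))
  expect_equal(sum(objs2$missing), 2)
  # an all-missing plane still renders
  pm3 <- demo_plane(vals, missing_wells = wells)
  objs3 <- render_circle_map(pm3, figure_spec(), f3 <- file.path(dir, "c3.png"))
  expect_true(file.exists(f3))
  expect_true(all(objs3$missing))
})

test_that("heatmaps render deterministically with monotone colors", {
  vals <- (1:12) / 13
  pm <- demo_plane(vals)
  dir <- withr::local_tempdir()
  out <- render_heatmap_2d(pm, figure_spec(), f1 <- file.path(dir, "h1.png"))
  # constant plane: a single color
  pmc <- demo_plane(rep(0.4, 12))
  outc <- render_heatmap_2d(pmc, figure_spec(), file.path(dir, "hc.png"))
  expect_equal(length(unique(as.vector(outc$colors))), 1)
  # maximum cell carries the highest palette position
  pal <- grDevices::hcl.colors(256, "Viridis")
  idx <- matrix(match(out$colors, pal), nrow(out$colors))
  expect_equal(which.max(idx), which.max(pm$values))
  # byte-identical re-render for identical inputs and spec
  render_heatmap_2d(pm, figure_spec(), f2 <- file.path(dir, "h2.png"))
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("3D export embeds the scene and snapshots every plane", {
  cfg <- random_config(n = 40, seed = 3)
  d <- data.frame(x_um = cfg$points[, 1], y_um = cfg$points[, 2],
                  z_um = cfg$points[, 3],
                  p_hat = cfg$values, status = "ok")
  vol <- interpolate_volume(d, resolution = c(8, 8, 5), method = "linear")
  mesh <- extract_isosurface(vol, 0.5)
  dir <- withr::local_tempdir()
  ex <- export_3d(vol, list(mesh), figure_spec(), f <- file.path(dir, "v.html"))
  expect_true(file.exists(f))
  expect_length(ex$snapshots, 5)
  expect_true(all(file.exists(ex$snapshots)))
  # parse the embedded scene graph back out of the HTML
  html <- paste(readLines(f, warn = FALSE), collapse = "\n")
  json <- sub('.*<script type="application/json" id="scene-data">', "", html)
  json <- sub("</script>.*", "", json)
  scene <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  expect_equal(scene$kind, "ctce3d-scene")
  expect_length(scene$surfaces, 1)
  expect_equal(scene$surfaces[[1]]$level, 0.5)
  expect_length(scene$slices, 5)
  # no meshes: a valid slices-only scene
  ex0 <- export_3d(vol, list(), figure_spec(), f0 <- file.path(dir, "v0.html"))
  expect_length(ex0$payload$surfaces, 0)
  expect_true(file.exists(f0))
  # identical embedded payload on re-export
  ex2 <- export_3d(vol, list(mesh), figure_spec(),
                   file.path(dir, "v2.html"))
  expect_identical(ex$payload, ex2$payload)
})
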