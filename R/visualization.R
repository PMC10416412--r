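#' Figure specification
#'
#' Shared styling for all figure families. The default colormap is the
#' perceptually uniform viridis over the fixed range \[0, 1\], so panels
#' across Z-planes and genes are directly comparable; missing positions
#' are drawn grey.
#'
#' @param colormap Palette name understood by [grDevices::hcl.colors()].
#' @param range Value range mapped onto the palette (low < high).
#' @param missing_col Color for missing positions.
#' @param format `"png"` or `"svg"`.
#' @param title Optional title.
#' @param width,height Device size in pixels (png) or inches (svg).
#' @return An object of class `figure_spec`.
#' @export
figure_spec <- function(colormap = "Viridis", range = c(0, 1),
                        missing_col = "grey60",
                        format = c("png", "svg"), title = NULL,
                        width = 800, height = 600) {
  format <- match.arg(format)
  stopifnot(length(range) == 2, range[1] < range[2])
  structure(list(colormap = colormap, range = range,
                 missing_col = missing_col, format = format, title = title,
                 width = width, height = height),
            class = "figure_spec")
}

spec_palette <- function(spec, n = 256L) {
  grDevices::hcl.colors(n, spec$colormap)
}

#' Map fractions to colors, monotonically along the palette
#' @param values Numeric values.
#' @param spec A [figure_spec()].
#' @export
fraction_colors <- function(values, spec = figure_spec()) {
  pal <- spec_palette(spec)
  s <- (values - spec$range[1]) / diff(spec$range)
  idx <- 1L + as.integer(floor(pmin(pmax(s, 0), 1) * (length(pal) - 1L)))
  out <- pal[idx]
  out[is.na(values)] <- spec$missing_col
  out
}

open_device <- function(spec, path) {
  if (spec$format == "png") {
    grDevices::png(path, width = spec$width, height = spec$height,
                   res = 96)
  } else {
    grDevices::svg(path, width = spec$width / 96, height = spec$height / 96)
  }
}

#' Render a circle (rim) map of one plane
#'
#' One circle per grid position at its physical XY location. The extent to
#' which the circle rim is filled encodes the mutant allele fraction — an
#' empty rim is 0, a full rim 1.0, a quarter rim 0.25 (90 degrees) — with
#' the arc starting at 12 o'clock and running clockwise. Positions that
#' produced no data are drawn as filled grey circles.
#'
#' @param pm A [plane_matrix()].
#' @param spec A [figure_spec()].
#' @param path Output image file.
#' @return Invisibly, a data.frame describing every drawn circle (`well`,
#'   `x`, `y`, `fraction`, `missing`, `arc_deg`, `color`) — the renderer's
#'   object list, used by tests instead of pixel inspection.
#' @export
render_circle_map <- function(pm, spec = figure_spec(), path) {
  stopifnot(inherits(pm, "plane_matrix"))
  cells <- which(!is.na(pm$wells), arr.ind = TRUE)
  r <- pm$disc_radius %||% (0.35 * min(diff(pm$x), diff(pm$y)))
  objs <- data.frame(
    well = pm$wells[cells],
    x = pm$x[cells[, 2]], y = pm$y[cells[, 1]],
    fraction = pm$values[cells], missing = pm$missing[cells],
    stringsAsFactors = FALSE)
  objs$arc_deg <- ifelse(objs$missing, NA_real_, 360 * objs$fraction)
  objs$color <- ifelse(objs$missing, spec$missing_col,
                       fraction_colors(objs$fraction, spec))
  open_device(spec, path)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4, 4, 3, 1))
  graphics::plot(NA, xlim = range(pm$x) + c(-2 * r, 2 * r),
                 ylim = range(pm$y) + c(-2 * r, 2 * r), asp = 1,
                 xlab = "x (um)", ylab = "y (um)",
                 main = spec$title %||%
                   sprintf("z = %.4g um", pm$z_um))
  tt <- seq(0, 2 * pi, length.out = 90)
  for (i in seq_len(nrow(objs))) {
    cx <- objs$x[i]
    cy <- objs$y[i]
    if (objs$missing[i]) {
      graphics::polygon(cx + r * cos(tt), cy + r * sin(tt),
                        col = spec$missing_col, border = NA)
      next
    }
    graphics::lines(cx + r * cos(tt), cy + r * sin(tt), col = "grey80")
    f <- objs$fraction[i]
    if (!is.na(f) && f > 0) {
      # from 12 o'clock, clockwise
      a <- seq(pi / 2, pi / 2 - 2 * pi * f, length.out = max(8, 90 * f))
      graphics::lines(cx + r * cos(a), cy + r * sin(a),
                      col = objs$color[i], lwd = 3)
    }
  }
  invisible(objs)
}

#' Render a 2D heatmap of one (filled) plane
#'
#' Raster heatmap of the plane values with a colorbar; the color mapping
#' is monotone in the fraction over the spec's fixed range. Cells that
#' remain unfilled (outside the observed convex hull) are rendered in the
#' missing color.
#'
#' @param pm A [plane_matrix()], normally after [fill_plane()].
#' @param spec A [figure_spec()].
#' @param path Output image file.
#' @return Invisibly, a list with the plotted `values` matrix and the
#'   `colors` matrix actually used.
#' @export
render_heatmap_2d <- function(pm, spec = figure_spec(), path) {
  stopifnot(inherits(pm, "plane_matrix"))
  vals <- pm$values
  cols <- matrix(fraction_colors(vals, spec), nrow(vals), ncol(vals))
  open_device(spec, path)
  on.exit(grDevices::dev.off())
  graphics::layout(matrix(1:2, 1, 2), widths = c(5, 1))
  graphics::par(mar = c(4, 4, 3, 1))
  z <- t(vals) # image() wants x along rows
  zcol <- pmin(pmax((z - spec$range[1]) / diff(spec$range), 0), 1)
  graphics::image(pm$x, pm$y, matrix(NA_real_, length(pm$x), length(pm$y)),
                  zlim = c(0, 1),
                  xlab = "x (um)", ylab = "y (um)",
                  main = spec$title %||% sprintf("z = %.4g um", pm$z_um))
  graphics::rect(graphics::par("usr")[1], graphics::par("usr")[3],
                 graphics::par("usr")[2], graphics::par("usr")[4],
                 col = spec$missing_col, border = NA)
  graphics::image(pm$x, pm$y, zcol, zlim = c(0, 1),
                  col = spec_palette(spec), add = TRUE)
  graphics::par(mar = c(4, 1, 3, 3))
  ramp <- seq(spec$range[1], spec$range[2], length.out = 256)
  graphics::image(1, ramp, matrix(ramp, 1), col = spec_palette(spec),
                  axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4)
  graphics::mtext("mutant fraction", side = 4, line = 2, cex = 0.8)
  invisible(list(values = vals, colors = cols))
}

#' Export an interactive 3D view as standalone HTML
#'
#' Writes a single self-contained HTML file showing the volume as per-Z
#' slice planes plus translucent isosurfaces, rendered by a small embedded
#' canvas viewer (drag to rotate, wheel to zoom); all data are embedded as
#' JSON, with no network dependency. Also writes one static PNG heatmap
#' snapshot per Z-plane next to the HTML file.
#'
#' @param volume A [interpolate_volume()] result with at least one node
#'   inside the hull.
#' @param meshes List of [extract_isosurface()] meshes (may be empty:
#'   slices-only view).
#' @param spec A [figure_spec()].
#' @param path Output HTML file; snapshots are written as
#'   `<path-sans-ext>_z<k>.png`.
#' @return Invisibly, a list with the embedded `payload` and the snapshot
#'   file paths.
#' @export
export_3d <- function(volume, meshes = list(), spec = figure_spec(),
                      path) {
  stopifnot(inherits(volume, "ctce_volume"))
  if (!any(volume$hull_mask)) {
    stop("empty volume: no grid nodes inside the sample hull",
         call. = FALSE)
  }
  if (inherits(meshes, "iso_mesh")) meshes <- list(meshes)
  payload <- list(
    kind = "ctce3d-scene",
    method = volume$method,
    x = round(volume$x, 6), y = round(volume$y, 6), z = round(volume$z, 6),
    value_range = spec$range,
    palette = spec_palette(spec, 64L),
    missing_col = spec$missing_col,
    slices = lapply(seq_along(volume$z), function(k) {
      m <- volume$values[, , k]
      m[is.na(m)] <- -1 # sentinel the viewer paints as missing
      unname(apply(m, 2, function(col) round(col, 5), simplify = FALSE))
    }),
    surfaces = lapply(meshes, function(m) {
      list(level = m$level,
           vertices = round(unname(m$vertices), 3),
           faces = m$faces - 1L)
    })
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  html <- paste0(
    "<!DOCTYPE html>\n<html>\n<head>\n<meta charset=\"utf-8\">\n",
    "<title>", spec$title %||% "3D mutant-fraction heatmap", "</title>\n",
    "<style>body{margin:0;background:#111;color:#eee;font:13px sans-serif}",
    "#hud{position:fixed;top:8px;left:10px}</style>\n</head>\n<body>\n",
    "<div id=\"hud\"></div>\n<canvas id=\"view\"></canvas>\n",
    "<script type=\"application/json\" id=\"scene-data\">", json,
    "</script>\n<script>", viewer_js(), "</script>\n</body>\n</html>\n")
  writeLines(html, path, sep = "")
  base <- sub("\\.html?$", "", path)
  snaps <- character(0)
  for (k in seq_along(volume$z)) {
    pm <- structure(list(
      values = volume$values[, , k],
      missing = !volume$hull_mask[, , k],
      observed = volume$hull_mask[, , k],
      x = volume$y, y = volume$x, # transposed below
      z_index = k - 1L, z_um = volume$z[k], wells = NULL,
      disc_radius = NULL), class = "plane_matrix")
    # plane_matrix stores values as [row=y, col=x]; the volume is [x, y, z]
    pm$values <- t(volume$values[, , k])
    pm$missing <- t(!volume$hull_mask[, , k])
    pm$observed <- t(volume$hull_mask[, , k])
    pm$x <- volume$x
    pm$y <- volume$y
    snap <- sprintf("%s_z%d.png", base, k)
    sp <- spec
    sp$format <- "png"
    sp$title <- sprintf("z = %.4g um", volume$z[k])
    render_heatmap_2d(pm, sp, snap)
    snaps <- c(snaps, snap)
  }
  invisible(list(payload = payload, snapshots = snaps, html = path))
}

# Minimal orthographic canvas viewer embedded in exported HTML.
viewer_js <- function() {
  paste0(
"var S=JSON.parse(document.getElementById('scene-data').textContent);",
"var cv=document.getElementById('view'),cx=cv.getContext('2d');",
"var yaw=0.6,pitch=-1.0,zoom=1;",
"function fit(){cv.width=innerWidth;cv.height=innerHeight;}fit();",
"addEventListener('resize',function(){fit();draw();});",
"var ctrx=(S.x[0]+S.x[S.x.length-1])/2,ctry=(S.y[0]+S.y[S.y.length-1])/2,",
"ctrz=(S.z[0]+S.z[S.z.length-1])/2;",
"var ext=Math.max(S.x[S.x.length-1]-S.x[0],S.y[S.y.length-1]-S.y[0],",
"S.z[S.z.length-1]-S.z[0]);",
"function proj(p){var x=p[0]-ctrx,y=p[1]-ctry,z=p[2]-ctrz;",
"var cy=Math.cos(yaw),sy=Math.sin(yaw),cp=Math.cos(pitch),",
"sp=Math.sin(pitch);var x1=cy*x+sy*y,y1=-sy*x+cy*y;",
"var y2=cp*y1-sp*z,z2=sp*y1+cp*z;",
"var s=zoom*Math.min(cv.width,cv.height)/(1.6*ext);",
"return [cv.width/2+x1*s,cv.height/2-z2*s,y2];}",
"function colr(v){if(v<0)return S.missing_col;",
"var t=(v-S.value_range[0])/(S.value_range[1]-S.value_range[0]);",
"t=Math.max(0,Math.min(1,t));",
"return S.palette[Math.round(t*(S.palette.length-1))];}",
"function draw(){cx.setTransform(1,0,0,1,0,0);",
"cx.fillStyle='#111';cx.fillRect(0,0,cv.width,cv.height);",
"var items=[];",
"for(var k=0;k<S.z.length;k++){var sl=S.slices[k];",
"for(var i=0;i<S.x.length-1;i++)for(var j=0;j<S.y.length-1;j++){",
"var v=sl[j][i];if(v<0)continue;",
"var q=[[S.x[i],S.y[j],S.z[k]],[S.x[i+1],S.y[j],S.z[k]],",
"[S.x[i+1],S.y[j+1],S.z[k]],[S.x[i],S.y[j+1],S.z[k]]].map(proj);",
"items.push({d:(q[0][2]+q[2][2])/2,q:q,c:colr(v),a:0.85});}}",
"for(var s=0;s<S.surfaces.length;s++){var m=S.surfaces[s];",
"for(var f=0;f<m.faces.length;f++){var fc=m.faces[f];",
"var q=[m.vertices[fc[0]],m.vertices[fc[1]],m.vertices[fc[2]]].map(proj);",
"items.push({d:(q[0][2]+q[1][2]+q[2][2])/3,q:q,c:'#ff4444',a:0.35});}}",
"items.sort(function(a,b){return a.d-b.d;});",
"for(var n=0;n<items.length;n++){var it=items[n];cx.beginPath();",
"cx.moveTo(it.q[0][0],it.q[0][1]);",
"for(var v=1;v<it.q.length;v++)cx.lineTo(it.q[v][0],it.q[v][1]);",
"cx.closePath();cx.globalAlpha=it.a;cx.fillStyle=it.c;cx.fill();}",
"cx.globalAlpha=1;",
"document.getElementById('hud').textContent='mutant-fraction volume ('+",
"S.method+'); drag to rotate, wheel to zoom; '+S.surfaces.length+",
"' isosurface(s)';}",
"var drag=null;cv.addEventListener('mousedown',function(e){",
"drag=[e.clientX,e.clientY];});",
"addEventListener('mouseup',function(){drag=null;});",
"addEventListener('mousemove',function(e){if(!drag)return;",
"yaw+=(e.clientX-drag[0])*0.01;pitch+=(e.clientY-drag[1])*0.01;",
"drag=[e.clientX,e.clientY];draw();});",
"cv.addEventListener('wheel',function(e){",
"zoom*=Math.pow(1.1,-Math.sign(e.deltaY));draw();e.preventDefault();});",
"draw();")
}
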