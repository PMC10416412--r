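#' Read and validate a pipeline configuration
#'
#' The whole pipeline is driven by one YAML file: the simulated scenario
#' (domain, clones, layout, trace parameters, dropout), the statistics
#' level, the interpolation method and resolution, figure styling, the
#' output directory and the top-level seed. See
#' [default_config()] for a complete, runnable example. Validation errors
#' name the offending field.
#'
#' For quantification of real (non-simulated) data, set `peak_table` to a
#' peak-area CSV — the table produced by instrument software, with the
#' [quantify_dir()] schema — instead of simulating traces; exactly one of
#' the two input routes may be active.
#'
#' @param path YAML file path, or a list with the same structure.
#' @return A validated config (class `pipeline_config`).
#' @export
read_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  # merge over the defaults one level deep: a supplied sub-field (e.g.
  # field$clones) replaces the default wholesale, it is never spliced
  base <- default_config()
  for (k in names(cfg)) {
    if (is.list(base[[k]]) && is.list(cfg[[k]]) &&
        !is.null(names(base[[k]]))) {
      for (k2 in names(cfg[[k]])) base[[k]][[k2]] <- cfg[[k]][[k2]]
    } else {
      base[k] <- cfg[k]
    }
  }
  cfg <- base
  fail <- function(field, why) {
    stop(sprintf("config field `%s`: %s", field, why), call. = FALSE)
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) {
    fail("seed", "must be a single integer")
  }
  if (!is.null(cfg$peak_table) && isTRUE(cfg$simulate)) {
    fail("peak_table", "provide either a peak table or a simulation, not both")
  }
  if (length(cfg$field$extent) != 3 || any(cfg$field$extent <= 0)) {
    fail("field.extent", "must be 3 positive numbers (micrometres)")
  }
  if (cfg$dropout < 0 || cfg$dropout > 1) {
    fail("dropout", "must lie in [0, 1]")
  }
  if (cfg$stats$level <= 0.5 || cfg$stats$level >= 1) {
    fail("stats.level", "must lie in (0.5, 1)")
  }
  if (!cfg$interpolation$method %in% c("natural_neighbor", "linear")) {
    fail("interpolation.method", "must be natural_neighbor or linear")
  }
  if (length(cfg$interpolation$resolution) != 3 ||
      any(cfg$interpolation$resolution < 2)) {
    fail("interpolation.resolution", "must be 3 integers >= 2")
  }
  if (any(cfg$render$isolevels <= 0) || any(cfg$render$isolevels >= 1)) {
    fail("render.isolevels", "levels must lie in (0, 1)")
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname read_config
#' @export
default_config <- function() {
  list(
    seed = 1L,
    gene = "GENE",
    output_dir = "ctce3d_out",
    simulate = TRUE,
    peak_table = NULL,
    field = list(
      extent = c(4000, 1500, 400),
      background = 0.02,
      clones = list(
        list(center = c(1200, 700, 150), scale = c(700, 450, 160),
             peak = 0.8),
        list(center = c(3000, 900, 300), scale = c(450, 350, 120),
             peak = 0.45))),
    layout = list(n_blocks = 2L, rows = 6L, cols = 8L,
                  circle_area = 25000, pitch_xy = 250,
                  z_planes = c(0, 100, 200, 300, 400)),
    trace = list(noise_sd = 2.5, signal_gain = 15000, hd_split = 1,
                 ss_frac = 0.05),
    dropout = 0.1,
    stats = list(level = 0.95),
    interpolation = list(method = "natural_neighbor",
                         resolution = c(50, 50, 25)),
    render = list(isolevels = c(0.4), colormap = "Viridis",
                  format = "png"),
    log_level = "info"
  )
}

cfg_field <- function(cfg) {
  make_clone_field(cfg$field$extent,
                   clones = lapply(cfg$field$clones, function(cl) {
                     list(center = unlist(cl$center),
                          scale = unlist(cl$scale), peak = cl$peak)
                   }),
                   background_fraction = cfg$field$background %||% 0)
}

cfg_layout <- function(cfg) {
  l <- cfg$layout
  grid_layout(n_blocks = l$n_blocks, rows = l$rows, cols = l$cols,
              circle_area = l$circle_area, pitch_xy = l$pitch_xy,
              z_planes = unlist(l$z_planes),
              block_offsets = if (!is.null(l$block_offsets)) {
                do.call(rbind, l$block_offsets)
              })
}

cfg_trace_params <- function(cfg) {
  do.call(trace_params, cfg$trace)
}

pipe_log <- function(cfg, fmt, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf(paste0("[ctce3d] ", fmt), ...))
}

#' Pipeline stages
#'
#' Each stage reads its inputs from, and writes its outputs into,
#' `config$output_dir` under fixed names, so the stages compose: running
#' them in sequence is byte-identical to [run_pipeline()] with the same
#' config and seed (all randomness flows from the single config seed
#' through [derive_seed()]).
#'
#' * `run_simulate()`: traces + `traces/manifest.csv` (one CSV per well).
#' * `run_quantify()`: `peak_areas.csv` from the traces (or copies in the
#'   externally supplied peak table).
#' * `run_stats()`: `fractions.csv` with CIs and the normality screen.
#' * `run_interpolate()`: `volume.csv`, `layout.yaml` and isosurface
#'   meshes `mesh_iso<level>.ply`/`.obj`.
#' * `run_render()`: circle maps and heatmaps per plane, plus the
#'   interactive `_3d.html` (with per-plane snapshots).
#'
#' @param config A [read_config()] result (or a path to one).
#' @param force Overwrite existing figure outputs.
#' @return Each stage invisibly returns its primary artifact; see Details.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
run_simulate <- function(config) {
  cfg <- as_config(config)
  if (!isTRUE(cfg$simulate)) {
    stop("config has `simulate: false`; nothing to simulate", call. = FALSE)
  }
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_dataset(cfg_field(cfg), cfg_layout(cfg),
                          cfg_trace_params(cfg), cfg$dropout,
                          seed = cfg$seed,
                          dir = file.path(cfg$output_dir, "traces"))
  pipe_log(cfg, "simulate: %d positions, %d traces written, %d missing",
           nrow(sim$manifest), sum(!sim$manifest$missing),
           sum(sim$manifest$missing))
  invisible(sim$manifest)
}

#' @rdname pipeline
#' @export
run_quantify <- function(config) {
  cfg <- as_config(config)
  out <- file.path(cfg$output_dir, "peak_areas.csv")
  if (!is.null(cfg$peak_table)) {
    tab <- utils::read.csv(cfg$peak_table, stringsAsFactors = FALSE)
  } else {
    tdir <- file.path(cfg$output_dir, "traces")
    if (!dir.exists(tdir) || !length(list.files(tdir))) {
      stop(sprintf("no traces found under '%s'; run the simulate stage ",
                   tdir), call. = FALSE)
    }
    tab <- quantify_dir(tdir,
                        expected_layout = peak_layout(cfg_trace_params(cfg)))
  }
  utils::write.csv(tab, out, row.names = FALSE)
  pipe_log(cfg, "quantify: %d rows (%d ok, %d other)", nrow(tab),
           sum(tab$status == "ok"), sum(tab$status != "ok"))
  invisible(tab)
}

#' @rdname pipeline
#' @export
run_stats <- function(config) {
  cfg <- as_config(config)
  pa <- file.path(cfg$output_dir, "peak_areas.csv")
  if (!file.exists(pa)) {
    stop("peak_areas.csv not found; run the quantify stage", call. = FALSE)
  }
  tab <- estimate_all(utils::read.csv(pa, stringsAsFactors = FALSE),
                      level = cfg$stats$level)
  utils::write.csv(tab, file.path(cfg$output_dir, "fractions.csv"),
                   row.names = FALSE)
  pipe_log(cfg, "stats: %d estimates at level %.3g", sum(!is.na(tab$p_hat)),
           cfg$stats$level)
  invisible(tab)
}

#' @rdname pipeline
#' @export
run_interpolate <- function(config) {
  cfg <- as_config(config)
  fr <- file.path(cfg$output_dir, "fractions.csv")
  if (!file.exists(fr)) {
    stop("fractions.csv not found; run the stats stage", call. = FALSE)
  }
  layout <- cfg_layout(cfg)
  map <- assemble_map(utils::read.csv(fr, stringsAsFactors = FALSE), layout)
  write_layout_yaml(layout, file.path(cfg$output_dir, "layout.yaml"))
  vol <- interpolate_volume(map, resolution = cfg$interpolation$resolution,
                            method = cfg$interpolation$method)
  write_volume_csv(vol, file.path(cfg$output_dir, "volume.csv"))
  meshes <- lapply(cfg$render$isolevels, function(lv) {
    m <- extract_isosurface(vol, lv)
    write_mesh_ply(m, file.path(cfg$output_dir,
                                sprintf("%s_iso%.2f.ply", cfg$gene, lv)))
    write_mesh_obj(m, file.path(cfg$output_dir,
                                sprintf("%s_iso%.2f.obj", cfg$gene, lv)))
    m
  })
  pipe_log(cfg, "interpolate: %d/%d voxels in hull, %d mesh(es)",
           sum(vol$hull_mask), length(vol$hull_mask), length(meshes))
  invisible(list(map = map, volume = vol, meshes = meshes))
}

#' @rdname pipeline
#' @export
run_render <- function(config, force = FALSE) {
  cfg <- as_config(config)
  art <- run_interpolate_cached(cfg)
  map <- art$map
  fdir <- file.path(cfg$output_dir, "figures")
  dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
  spec <- figure_spec(colormap = cfg$render$colormap,
                      format = cfg$render$format)
  files <- character(0)
  for (zi in seq_along(cfg_layout(cfg)$z_planes) - 1L) {
    pm <- plane_matrix(map, zi)
    f1 <- file.path(fdir, sprintf("%s_plane%d_circles.%s", cfg$gene, zi + 1,
                                  cfg$render$format))
    f2 <- file.path(fdir, sprintf("%s_plane%d_heatmap.%s", cfg$gene, zi + 1,
                                  cfg$render$format))
    check_overwrite(c(f1, f2), force)
    sp <- spec
    sp$title <- sprintf("%s, z = %.4g um", cfg$gene, pm$z_um)
    render_circle_map(pm, sp, f1)
    filled <- tryCatch(fill_plane(pm), error = function(e) pm)
    render_heatmap_2d(filled, sp, f2)
    files <- c(files, f1, f2)
  }
  f3 <- file.path(fdir, sprintf("%s_3d.html", cfg$gene))
  check_overwrite(f3, force)
  sp <- spec
  sp$title <- sprintf("%s 3D mutant-fraction heatmap", cfg$gene)
  ex <- export_3d(art$volume, art$meshes, sp, f3)
  files <- c(files, f3, ex$snapshots)
  pipe_log(cfg, "render: %d files under %s", length(files), fdir)
  invisible(files)
}

# run_render needs the interpolation artifacts; rebuild them from disk so
# the stage composes identically whether or not run_interpolate just ran.
run_interpolate_cached <- function(cfg) {
  run_interpolate(cfg)
}

check_overwrite <- function(paths, force) {
  hit <- paths[file.exists(paths)]
  if (length(hit) && !force) {
    stop("output exists (use force = TRUE / --force to overwrite): ",
         paste(hit, collapse = ", "), call. = FALSE)
  }
}

#' @rdname pipeline
#' @export
run_pipeline <- function(config, force = FALSE) {
  cfg <- as_config(config)
  manifest <- if (isTRUE(cfg$simulate)) run_simulate(cfg) else NULL
  pa <- run_quantify(cfg)
  fr <- run_stats(cfg)
  files <- run_render(cfg, force = force)
  report <- list(
    package = "ctce3d",
    package_version = as.character(utils::packageVersion("ctce3d")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = cfg$seed,
    parameters = unclass(cfg),
    counts = list(
      positions = if (!is.null(manifest)) nrow(manifest) else nrow(pa),
      traces = if (!is.null(manifest)) sum(!manifest$missing) else NA,
      quantified = sum(fr$status == "ok"),
      missing = sum(fr$status != "ok"),
      figures = length(files))
  )
  jsonlite::write_json(report, file.path(cfg$output_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  pipe_log(cfg, "pipeline complete: %s", cfg$output_dir)
  invisible(report)
}

as_config <- function(config) {
  if (inherits(config, "pipeline_config")) config else read_config(config)
}
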