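#' Bind fraction estimates to grid coordinates
#'
#' Joins a fraction table (see [estimate_all()]) onto the full position
#' census of a layout. Every layout position appears exactly once in the
#' result: positions absent from the table, and rows whose status is not
#' `"ok"`, become explicit missing entries with a reason — they are carried,
#' never dropped, so downstream maps can draw them grey.
#'
#' @param fraction_table Data.frame with at least `well`, `p_hat`,
#'   `n_eff`, `ci_low`, `ci_high`, `normality_ok`, `status`.
#' @param layout A [grid_layout()].
#' @return An object of class `mutation_map`: a list with `data` (one row
#'   per layout position: position columns plus `p_hat`, `n_eff`, `ci_low`,
#'   `ci_high`, `normality_ok`, `status`) and `layout`.
#' @export
assemble_map <- function(fraction_table, layout) {
  stopifnot(inherits(layout, "grid_layout"))
  pos <- enumerate_positions(layout)
  if (anyDuplicated(fraction_table$well)) {
    dup <- unique(fraction_table$well[duplicated(fraction_table$well)])
    stop("duplicate well(s) in fraction table: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(fraction_table$well, pos$well)
  if (length(unknown)) {
    stop("well(s) not in layout: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  i <- match(pos$well, fraction_table$well)
  pick <- function(col, default) {
    if (col %in% names(fraction_table)) fraction_table[[col]][i] else default
  }
  d <- pos
  d$p_hat <- pick("p_hat", NA_real_)
  d$n_eff <- pick("n_eff", NA_real_)
  d$ci_low <- pick("ci_low", NA_real_)
  d$ci_high <- pick("ci_high", NA_real_)
  d$normality_ok <- pick("normality_ok", NA)
  d$status <- pick("status", NA_character_)
  d$status[is.na(i)] <- "not sampled"
  d$p_hat[d$status != "ok"] <- NA_real_
  if (any(d$p_hat < 0 | d$p_hat > 1, na.rm = TRUE)) {
    stop("fraction values must lie in [0, 1]", call. = FALSE)
  }
  rownames(d) <- NULL
  structure(list(data = d, layout = layout), class = "mutation_map")
}

#' @export
print.mutation_map <- function(x, ...) {
  d <- x$data
  cat(sprintf("<mutation_map> %d positions (%d quantified, %d missing), %d z-plane(s)\n",
              nrow(d), sum(d$status == "ok"), sum(d$status != "ok"),
              length(x$layout$z_planes)))
  if (any(d$status == "ok")) {
    cat(sprintf("  fraction range %.4g .. %.4g\n",
                min(d$p_hat, na.rm = TRUE), max(d$p_hat, na.rm = TRUE)))
  }
  invisible(x)
}

#' Per-plane value matrix and missing mask
#'
#' Lays the positions of one Z-plane out as a matrix in (row, column)
#' order spanning all blocks, with the accompanying logical missing mask.
#' Matrix rows index unique Y coordinates (increasing), columns unique X;
#' lattice cells not backed by any layout position (possible under custom
#' block offsets) are `NA` in the values and `FALSE` in `observed`.
#'
#' @param map A [assemble_map()] result.
#' @param z_index 0-based plane index.
#' @return A list of class `plane_matrix`: `values` (fractions, `NA` where
#'   missing), `missing` (TRUE where a position exists but gave no data),
#'   `observed` (TRUE where a quantified value sits), `x`, `y` (cell-center
#'   coordinates, micrometres), `z_index`, `z_um`, `wells` (well-id matrix).
#' @export
plane_matrix <- function(map, z_index) {
  stopifnot(inherits(map, "mutation_map"))
  d <- map$data[map$data$z_index == z_index, , drop = FALSE]
  if (!nrow(d)) {
    stop(sprintf("no plane with z_index %s", z_index), call. = FALSE)
  }
  xs <- sort(unique(round(d$x_um, 6)))
  ys <- sort(unique(round(d$y_um, 6)))
  val <- matrix(NA_real_, nrow = length(ys), ncol = length(xs))
  wells <- matrix(NA_character_, nrow = length(ys), ncol = length(xs))
  miss <- matrix(FALSE, nrow = length(ys), ncol = length(xs))
  ri <- match(round(d$y_um, 6), ys)
  ci <- match(round(d$x_um, 6), xs)
  idx <- cbind(ri, ci)
  val[idx] <- d$p_hat
  wells[idx] <- d$well
  miss[idx] <- d$status != "ok"
  structure(
    list(values = val, missing = miss, observed = !miss & !is.na(wells),
         x = xs, y = ys, z_index = z_index, z_um = d$z_um[1], wells = wells,
         disc_radius = disc_radius(map$layout)),
    class = "plane_matrix"
  )
}

#' Write plane values back into a map
#'
#' Inverse of [plane_matrix()] for the value fields: cells flagged missing
#' or outside the lattice are left untouched, so
#' `plane_matrix(set_plane(map, z, plane_matrix(map, z)), z)` is the
#' identity.
#'
#' @param map A `mutation_map`.
#' @param z_index 0-based plane index.
#' @param pm A `plane_matrix` for that plane.
#' @export
set_plane <- function(map, z_index, pm) {
  stopifnot(inherits(map, "mutation_map"), inherits(pm, "plane_matrix"))
  sel <- which(map$data$z_index == z_index)
  d <- map$data[sel, , drop = FALSE]
  ri <- match(round(d$y_um, 6), pm$y)
  ci <- match(round(d$x_um, 6), pm$x)
  ok <- d$status == "ok"
  map$data$p_hat[sel[ok]] <- pm$values[cbind(ri[ok], ci[ok])]
  map
}

#' Serialize a mutation map / layout
#'
#' The map goes to a long-format CSV (one row per position, all estimate
#' columns); the layout to YAML. Both round-trip losslessly through
#' [read_map_csv()] / [read_layout_yaml()].
#'
#' @param map A `mutation_map`.
#' @param path Output file.
#' @export
write_map_csv <- function(map, path) {
  stopifnot(inherits(map, "mutation_map"))
  utils::write.csv(map$data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_map_csv
#' @param layout A [grid_layout()].
#' @export
read_map_csv <- function(path, layout) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  assemble_map(d[d$status != "not sampled", , drop = FALSE], layout)
}

#' @rdname write_map_csv
#' @export
write_layout_yaml <- function(layout, path) {
  stopifnot(inherits(layout, "grid_layout"))
  yaml::write_yaml(list(
    n_blocks = layout$n_blocks, rows = layout$rows, cols = layout$cols,
    circle_area = layout$circle_area, pitch_xy = layout$pitch_xy,
    z_planes = as.numeric(layout$z_planes),
    block_offsets = apply(layout$block_offsets, 1, as.numeric,
                          simplify = FALSE),
    plane_shifts = apply(layout$plane_shifts, 1, as.numeric,
                         simplify = FALSE)), path)
  invisible(path)
}

#' @rdname write_map_csv
#' @export
read_layout_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  grid_layout(n_blocks = y$n_blocks, rows = y$rows, cols = y$cols,
              circle_area = y$circle_area, pitch_xy = y$pitch_xy,
              z_planes = unlist(y$z_planes),
              block_offsets = do.call(rbind, y$block_offsets),
              plane_shifts = do.call(rbind, y$plane_shifts))
}
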