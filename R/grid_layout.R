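#' LCM sampling-grid layout
#'
#' Describes the laser-capture-microdissection sampling lattice: `n_blocks`
#' adjacent blocks, each a `rows x cols` pattern of microdissected discs of
#' `circle_area` square micrometres, repeated on each Z-plane (one cryosection
#' per plane). The canonical design is 8 columns by 6 rows of 25,000 um^2
#' discs per block; eight adjacent blocks on a single section give 384
#' candidate positions, two blocks give the 96 positions per plane used for
#' multi-plane sampling.
#'
#' Disc centers must not overlap, so `pitch_xy >= 2 * sqrt(circle_area / pi)`
#' (twice the disc radius, about 178.4 um for 25,000 um^2 discs). The disc
#' spacing within a grid is an instrument-placement choice; the default pitch
#' is 250 um center-to-center. By default blocks are laid side by side along
#' the X axis; `block_offsets` overrides placement (one XY origin per block,
#' in micrometres). `plane_shifts` is an optional per-plane rigid XY offset
#' hook for users with fiducial registration; the default assumes perfect
#' inter-plane registration.
#'
#' @param n_blocks Number of adjacent blocks.
#' @param rows,cols Rows and columns per block.
#' @param circle_area Disc area in square micrometres.
#' @param pitch_xy Center-to-center disc spacing in micrometres.
#' @param z_planes Strictly increasing Z coordinates (micrometres), one per
#'   tissue section.
#' @param block_offsets Optional `n_blocks x 2` matrix of block XY origins
#'   (micrometres). Default: blocks abutted along X at the pitch spacing.
#' @param plane_shifts Optional `length(z_planes) x 2` matrix of rigid XY
#'   shifts per plane (micrometres); default zero.
#' @return An object of class `grid_layout`.
#' @examples
#' lay <- grid_layout(n_blocks = 8, z_planes = 0)
#' nrow(enumerate_positions(lay)) # 384
#' @export
grid_layout <- function(n_blocks = 1L, rows = 6L, cols = 8L,
                        circle_area = 25000, pitch_xy = 250,
                        z_planes = 0, block_offsets = NULL,
                        plane_shifts = NULL) {
  stopifnot(n_blocks >= 1, rows >= 1, cols >= 1, circle_area > 0,
            pitch_xy > 0, length(z_planes) >= 1)
  radius <- sqrt(circle_area / pi)
  if (pitch_xy < 2 * radius) {
    stop(sprintf(
      "pitch_xy = %.4g um lets %.5g um^2 discs overlap (need >= %.4g um)",
      pitch_xy, circle_area, 2 * radius), call. = FALSE)
  }
  if (is.unsorted(z_planes, strictly = TRUE)) {
    stop("`z_planes` must be strictly increasing", call. = FALSE)
  }
  if (is.null(block_offsets)) {
    block_offsets <- cbind(x = (seq_len(n_blocks) - 1) * cols * pitch_xy,
                           y = 0)
  }
  block_offsets <- matrix(as.numeric(as.matrix(block_offsets)),
                          ncol = 2, dimnames = list(NULL, c("x", "y")))
  if (nrow(block_offsets) != n_blocks) {
    stop("`block_offsets` must have one XY row per block", call. = FALSE)
  }
  if (is.null(plane_shifts)) {
    plane_shifts <- matrix(0, nrow = length(z_planes), ncol = 2)
  }
  plane_shifts <- matrix(as.numeric(as.matrix(plane_shifts)), ncol = 2)
  if (nrow(plane_shifts) != length(z_planes)) {
    stop("`plane_shifts` must have one XY row per z-plane", call. = FALSE)
  }
  lay <- structure(
    list(n_blocks = as.integer(n_blocks), rows = as.integer(rows),
         cols = as.integer(cols), circle_area = circle_area,
         pitch_xy = pitch_xy, z_planes = as.numeric(z_planes),
         block_offsets = block_offsets, plane_shifts = plane_shifts),
    class = "grid_layout"
  )
  pos0 <- enumerate_positions(lay, check_overlap = FALSE)
  pos0 <- pos0[pos0$z_index == 0L, ]
  if (nrow(pos0) > 1) {
    d <- stats::dist(pos0[, c("x_um", "y_um")])
    if (min(d) < 2 * radius - 1e-9) {
      stop(sprintf(
        "block placement overlaps: disc centers %.4g um apart (need >= %.4g)",
        min(d), 2 * radius), call. = FALSE)
    }
  }
  lay
}

#' Enumerate all candidate sampling positions of a layout
#'
#' One row per (block, row, col, z-plane) with 0-based indices, disc-center
#' coordinates in micrometres (origin at the first block's first disc), and a
#' well identifier usable as a PCR-plate key, e.g. `"B1-A01-Z1"` (block 1,
#' plate row A = grid row 0, column 01, plane 1).
#'
#' @param layout A [grid_layout()].
#' @param check_overlap Internal; skip the overlap validation.
#' @return A data.frame with columns `well`, `block`, `row`, `col`,
#'   `z_index`, `x_um`, `y_um`, `z_um`. Total rows are always
#'   `n_blocks * rows * cols * length(z_planes)`.
#' @export
enumerate_positions <- function(layout, check_overlap = TRUE) {
  stopifnot(inherits(layout, "grid_layout"))
  g <- expand.grid(col = seq_len(layout$cols) - 1L,
                   row = seq_len(layout$rows) - 1L,
                   block = seq_len(layout$n_blocks) - 1L,
                   z_index = seq_along(layout$z_planes) - 1L,
                   KEEP.OUT.ATTRS = FALSE)
  ox <- layout$block_offsets[g$block + 1L, 1]
  oy <- layout$block_offsets[g$block + 1L, 2]
  sx <- layout$plane_shifts[g$z_index + 1L, 1]
  sy <- layout$plane_shifts[g$z_index + 1L, 2]
  out <- data.frame(
    well = sprintf("B%d-%s%02d-Z%d", g$block + 1L, LETTERS[g$row + 1L],
                   g$col + 1L, g$z_index + 1L),
    block = g$block, row = g$row, col = g$col, z_index = g$z_index,
    x_um = ox + sx + g$col * layout$pitch_xy,
    y_um = oy + sy + g$row * layout$pitch_xy,
    z_um = layout$z_planes[g$z_index + 1L],
    stringsAsFactors = FALSE
  )
  out[order(out$z_index, out$block, out$row, out$col), , drop = FALSE]
}

#' Disc radius of a layout, in micrometres
#' @param layout A [grid_layout()].
#' @export
disc_radius <- function(layout) sqrt(layout$circle_area / pi)

#' @export
print.grid_layout <- function(x, ...) {
  cat(sprintf(
    "<grid_layout> %d block(s) of %d x %d discs (%.5g um^2, pitch %.4g um), %d z-plane(s)\n",
    x$n_blocks, x$rows, x$cols, x$circle_area, x$pitch_xy,
    length(x$z_planes)))
  cat(sprintf("  %d candidate positions; z = %s um\n",
              x$n_blocks * x$rows * x$cols * length(x$z_planes),
              paste(x$z_planes, collapse = ", ")))
  invisible(x)
}

#' Default multi-plane demonstration layout
#'
#' Two adjacent 8 x 6 blocks (96 positions per plane) across five Z-planes
#' spanning `z_span` micrometres, mirroring a five-section tumor sampling
#' design: a 400 um span gives 100 um plane spacing, a 200 um span 50 um.
#'
#' @param z_span Total Z extent in micrometres.
#' @param n_planes Number of sections.
#' @export
default_layout <- function(z_span = 400, n_planes = 5) {
  grid_layout(n_blocks = 2L,
              z_planes = seq(0, z_span, length.out = n_planes))
}
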