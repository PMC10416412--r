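#' Ground-truth 3D clonal mutant-fraction fields
#'
#' A `clone_field` is a deterministic scalar field f(x, y, z) in \[0, 1\]
#' standing in for the spatial distribution of a mutant allele fraction in a
#' tumor: smooth anisotropic Gaussian "clones" over a uniform background.
#' Clones combine with the background by *saturating maximum*, not by
#' summation — a mutant fraction is a proportion, so two overlapping clones
#' with peak 0.6 give 0.6 at the shared center, never 1.2 — which guarantees
#' the field stays in \[0, 1\] everywhere.
#'
#' @param extent_xyz Numeric length-3: physical domain size in micrometres;
#'   the domain is `[0, extent_xyz[1]] x [0, extent_xyz[2]] x [0, extent_xyz[3]]`.
#' @param clones List of clones, each a list with elements `center` (length-3,
#'   micrometres), `scale` (length-3 Gaussian sd in micrometres, all > 0) and
#'   `peak` (peak mutant fraction in \[0, 1\]).
#' @param background_fraction Baseline mutant fraction in \[0, 1\] outside
#'   all clones.
#' @return An object of class `clone_field`.
#' @examples
#' f <- make_clone_field(c(4000, 3000, 400),
#'   clones = list(list(center = c(2000, 1500, 200),
#'                      scale = c(600, 500, 150), peak = 0.8)),
#'   background_fraction = 0.02)
#' eval_field(f, cbind(2000, 1500, 200)) # 0.8 at the clone center
#' @export
make_clone_field <- function(extent_xyz, clones = list(),
                             background_fraction = 0) {
  stopifnot(is.numeric(extent_xyz), length(extent_xyz) == 3L,
            all(is.finite(extent_xyz)), all(extent_xyz > 0))
  check_unit_scalar(background_fraction, "background_fraction")
  if (length(clones) && !is.null(names(clones))) clones <- unname(clones)
  for (i in seq_along(clones)) {
    cl <- clones[[i]]
    if (!is.list(cl) || !all(c("center", "scale", "peak") %in% names(cl))) {
      stop(sprintf("clone %d must have `center`, `scale` and `peak`", i),
           call. = FALSE)
    }
    stopifnot(length(cl$center) == 3L, length(cl$scale) == 3L,
              all(cl$scale > 0))
    check_unit_scalar(cl$peak, sprintf("clones[[%d]]$peak", i))
    if (any(cl$center < 0) || any(cl$center > extent_xyz)) {
      stop(sprintf("clone %d center (%s) lies outside the domain extent", i,
                   paste(signif(cl$center, 6), collapse = ", ")),
           call. = FALSE)
    }
  }
  structure(
    list(extent_xyz = as.numeric(extent_xyz), clones = clones,
         background_fraction = background_fraction),
    class = "clone_field"
  )
}

#' Evaluate a clone field at points
#'
#' Pure function of the coordinates: repeated evaluation at the same point
#' returns identical values.
#'
#' @param field A [make_clone_field()] object.
#' @param xyz Numeric matrix (n x 3) of coordinates in micrometres.
#' @return Numeric vector of mutant fractions in \[0, 1\], one per row.
#' @export
eval_field <- function(field, xyz) {
  stopifnot(inherits(field, "clone_field"))
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stop("`xyz` must have 3 columns", call. = FALSE)
  storage.mode(xyz) <- "double"
  v <- rep(field$background_fraction, nrow(xyz))
  for (cl in field$clones) {
    d2 <- ((xyz[, 1] - cl$center[1]) / cl$scale[1])^2 +
          ((xyz[, 2] - cl$center[2]) / cl$scale[2])^2 +
          ((xyz[, 3] - cl$center[3]) / cl$scale[3])^2
    v <- pmax(v, cl$peak * exp(-0.5 * d2))
  }
  pmin(pmax(v, 0), 1)
}

#' @export
print.clone_field <- function(x, ...) {
  cat(sprintf("<clone_field> extent %s um, %d clone(s), background %.3g\n",
              paste(x$extent_xyz, collapse = " x "),
              length(x$clones), x$background_fraction))
  for (i in seq_along(x$clones)) {
    cl <- x$clones[[i]]
    cat(sprintf("  clone %d: center (%s), scale (%s), peak %.3g\n", i,
                paste(signif(cl$center, 5), collapse = ", "),
                paste(signif(cl$scale, 5), collapse = ", "), cl$peak))
  }
  invisible(x)
}
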