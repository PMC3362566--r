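#' Vertical column grid
#'
#' Depth coordinate positive down, surface at 0 m. Cells are defined by their
#' interface depths; a single-cell grid recovers the 0-D box configuration.
#'
#' @param depth total column depth (m); ignored if \code{z_edges} is given
#' @param dz uniform cell thickness (m); ignored if \code{z_edges} is given
#' @param z_edges optional strictly increasing vector of interface depths (m)
#'   starting at 0
#' @return an object of class \code{column_grid} with fields \code{z_edges},
#'   \code{z_centers}, \code{dz}, \code{n}
#' @export
#' @examples
#' g <- column_grid(depth = 200, dz = 2)
#' g$n
column_grid <- function(depth = 200, dz = 2, z_edges = NULL) {
  if (is.null(z_edges)) {
    if (depth <= 0 || dz <= 0) stop("depth and dz must be > 0", call. = FALSE)
    z_edges <- seq(0, depth, by = dz)
    if (z_edges[length(z_edges)] < depth) z_edges <- c(z_edges, depth)
  }
  if (length(z_edges) < 2 || z_edges[1] != 0 || any(diff(z_edges) <= 0))
    stop("z_edges must start at 0 and be strictly increasing", call. = FALSE)
  thick <- diff(z_edges)
  structure(list(z_edges = z_edges,
                 z_centers = z_edges[-length(z_edges)] + thick / 2,
                 dz = thick,
                 n = length(thick)),
            class = "column_grid")
}

#' @export
print.column_grid <- function(x, ...) {
  cat(sprintf("column grid: %d cells, 0-%g m, dz %g-%g m\n",
              x$n, x$z_edges[length(x$z_edges)], min(x$dz), max(x$dz)))
  invisible(x)
}
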