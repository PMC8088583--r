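#' Free-energy surface from the top two projections
#'
#' Boltzmann inversion of a two-dimensional kernel density estimate of the
#' top two PC (or DVP) projections: the density `rho` is estimated on a
#' regular grid by a Gaussian product kernel with per-axis bandwidth
#' `smoothing x` the Silverman/normal-reference default
#' ([MASS::bandwidth.nrd()]), and the free energy is
#' `dG = -ln(rho / rho_max)` in units of kT, so the minimum is exactly 0 at
#' the density mode.
#'
#' @param proj a `projection_table` (its first two columns are used) or an
#'   `n x 2` matrix.
#' @param grid_size grid points per axis (default 100).
#' @param smoothing bandwidth multiplier (default 1); larger values smooth
#'   the landscape, smaller ones sharpen basins.
#' @return an object of class `energy_surface`: list with `pc1`, `pc2` (cell
#'   centers), `G` (`grid_size x grid_size` matrix of dG values, kT),
#'   `smoothing`.
#' @export
free_energy_surface <- function(proj, grid_size = 100L, smoothing = 1) {
  P <- if (inherits(proj, "projection_table")) proj$proj else as.matrix(proj)
  if (ncol(P) < 2L) stop("need two projection columns")
  x <- P[, 1L]; y <- P[, 2L]
  if (nrow(unique(cbind(x, y))) < 2L) {
    stop("degenerate input: all points identical")
  }
  if (smoothing <= 0) stop("smoothing must be positive")
  hx <- MASS::bandwidth.nrd(x)
  hy <- MASS::bandwidth.nrd(y)
  if (hx <= 0) hx <- diff(range(x)) / 10 + 1e-8
  if (hy <= 0) hy <- diff(range(y)) / 10 + 1e-8
  kd <- MASS::kde2d(x, y, h = smoothing * c(hx, hy), n = grid_size,
                    lims = c(extend_range(x, hx), extend_range(y, hy)))
  G <- -log(kd$z / max(kd$z))
  structure(list(pc1 = kd$x, pc2 = kd$y, G = G, smoothing = smoothing),
            class = "energy_surface")
}

extend_range <- function(v, h) range(v) + c(-1, 1) * 2 * h

#' @export
print.energy_surface <- function(x, ...) {
  cat("<energy_surface> ", length(x$pc1), "x", length(x$pc2),
      " grid; dG range 0 - ", round(max(x$G[is.finite(x$G)]), 2),
      " kT (smoothing ", x$smoothing, ")\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.energy_surface <- function(x, ...) {
  data.frame(pc1 = rep(x$pc1, times = length(x$pc2)),
             pc2 = rep(x$pc2, each = length(x$pc1)),
             dG = as.vector(x$G))
}

#' Write an energy surface as a TSV grid (pc1, pc2, dG)
#' @param surface an `energy_surface`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_energy_surface <- function(surface, path) {
  utils::write.table(as.data.frame(surface), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
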