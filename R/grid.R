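# Staggered latitude-depth channel grid.
#
# Convention: y increases northward from 0 to Ly (m); z is negative downward,
# z = 0 at the surface and z = -H at the bottom.  Cell centers live at
# (y_centers, z_centers); scalar fields are ny x nz matrices; y-face fields
# are (ny+1) x nz; z-face fields are ny x (nz+1); streamfunctions live on
# cell corners, (ny+1) x (nz+1).

#' Build a staggered latitude--depth channel grid
#'
#' Constructs the finite-volume grid used by all transport operators: a
#' re-entrant-channel stand-in with solid walls at `y = 0` and `y = Ly`, a
#' rigid lid at `z = 0` and a flat bottom at `z = -H`.  Meridional spacing is
#' uniform; vertical spacing is either uniform or geometrically stretched so
#' that surface cells are thin (resolving the seasonal boundary layer) and
#' deep cells are thick.
#'
#' @param ny Number of meridional cells (>= 3).
#' @param nz Number of vertical cells (>= 5).
#' @param Ly Channel width (m). Default 2000 km.
#' @param H Depth (m, positive). Default 3000 m.
#' @param stretching `"geometric"` (default) for a surface-refined grid or
#'   `"uniform"` for equal spacing.
#' @param dz_surface Thickness of the top cell (m) when `stretching =
#'   "geometric"`. Default 5 m.
#' @return An object of class `channel_grid`: a list with `y_centers`,
#'   `z_centers`, `y_faces`, `z_faces` (z non-positive, decreasing), `dy`,
#'   `dz` (cell thicknesses), `dz_faces` (center-to-center spacing used for
#'   vertical gradients), and `cell_volume` (ny x nz, m^3 per m of zonal
#'   extent).
#' @examples
#' g <- build_grid(20, 40)
#' sum(g$dz)  # equals H
#' @export
build_grid <- function(ny, nz, Ly = 2e6, H = 3000,
                       stretching = c("geometric", "uniform"),
                       dz_surface = 5) {
  stretching <- match.arg(stretching)
  if (!is.numeric(ny) || !is.numeric(nz) || ny < 3 || nz < 5) {
    stop("invalid configuration: need ny >= 3 and nz >= 5", call. = FALSE)
  }
  if (Ly <= 0 || H <= 0 || dz_surface <= 0) {
    stop("invalid configuration: Ly, H and dz_surface must be positive",
         call. = FALSE)
  }
  ny <- as.integer(ny); nz <- as.integer(nz)

  dy <- Ly / ny
  y_faces <- seq(0, Ly, length.out = ny + 1)
  y_centers <- 0.5 * (y_faces[-1] + y_faces[-(ny + 1)])

  if (stretching == "uniform" || dz_surface * nz >= H) {
    dz <- rep(H / nz, nz)
  } else {
    # geometric spacing dz_k = dz_surface * r^(k-1) summing exactly to H
    f <- function(r) dz_surface * (r^nz - 1) / (r - 1) - H
    r <- stats::uniroot(f, c(1 + 1e-12, 10), tol = 1e-14)$root
    dz <- dz_surface * r^(seq_len(nz) - 1)
    dz <- dz * (H / sum(dz))  # absorb root tolerance
  }
  z_faces <- c(0, -cumsum(dz))
  z_centers <- 0.5 * (z_faces[-1] + z_faces[-(nz + 1)])
  # spacing between adjacent cell centers, across interior z-faces
  dz_faces <- c(dz[1] / 2, -diff(z_centers), dz[nz] / 2)

  grid <- structure(list(
    ny = ny, nz = nz, Ly = Ly, H = H,
    dy = dy, dz = dz, dz_faces = dz_faces,
    y_centers = y_centers, y_faces = y_faces,
    z_centers = z_centers, z_faces = z_faces,
    cell_volume = outer(rep(dy, ny), dz)
  ), class = "channel_grid")
  grid
}

#' @export
print.channel_grid <- function(x, ...) {
  cat(sprintf("<channel_grid> %d x %d cells, Ly = %.0f km, H = %.0f m\n",
              x$ny, x$nz, x$Ly / 1e3, x$H))
  cat(sprintf("  dy = %.1f km; dz = %.2f m (top) .. %.1f m (bottom)\n",
              x$dy / 1e3, x$dz[1], x$dz[x$nz]))
  invisible(x)
}

# internal: indices of y cells whose centers fall inside [band[1], band[2]]
band_index <- function(grid, band) {
  idx <- which(grid$y_centers >= band[1] & grid$y_centers <= band[2])
  if (!length(idx)) {
    stop("band [", band[1], ", ", band[2], "] m contains no grid cells",
         call. = FALSE)
  }
  idx
}

# internal: indices of z cells with centers shallower than `depth` m
top_index <- function(grid, depth = 100) {
  which(grid$z_centers > -depth)
}
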