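#' Parametric vesicle / tubule geometry
#'
#' Defines a single membrane structure to be rasterized as a surface-labeled
#' shell: a sphere (vesicle) of the given outer diameter, or a tubule modeled
#' as a capsule (spherocylinder) — a cylinder of the given diameter with
#' hemispherical end caps, whose `length` is the full end-to-end extent
#' including the caps. The label is confined to a shell within
#' `shell_halfwidth` nm of the ideal surface, emulating antibody decoration of
#' a membrane. A vesicle with `diameter = 0` and `shell_halfwidth = 0` is a
#' point source.
#'
#' @param shape `"vesicle"` or `"tubule"`.
#' @param diameter outer diameter in nm (>= 0; 0 only for a point source).
#' @param length tubules only: end-to-end length in nm, including the
#'   hemispherical caps; must satisfy `length >= diameter`.
#' @param shell_halfwidth half-thickness of the labeled shell in nm
#'   (default 5, i.e. surface +/- 5 nm).
#' @return object of class `structure_spec`.
#' @examples
#' structure_spec("vesicle", diameter = 110)
#' structure_spec("tubule", diameter = 30, length = 300)
#' @export
structure_spec <- function(shape = c("vesicle", "tubule"), diameter,
                           length = NULL, shell_halfwidth = 5) {
  shape <- match.arg(shape)
  stopifnot_scalar_num(diameter, "diameter", 0)
  stopifnot_scalar_num(shell_halfwidth, "shell_halfwidth", 0)
  if (shape == "tubule") {
    if (is.null(length))
      stop("tubules require `length`", call. = FALSE)
    stopifnot_scalar_num(length, "length", 0, strict = TRUE)
    if (length < diameter)
      stop("tubule `length` must be >= `diameter` (length includes end caps)",
           call. = FALSE)
  } else {
    length <- NULL  # ignored for vesicles
  }
  structure(list(shape = shape, diameter = diameter, length = length,
                 shell_halfwidth = shell_halfwidth),
            class = "structure_spec")
}

#' @export
print.structure_spec <- function(x, ...) {
  if (x$shape == "vesicle")
    cat(sprintf("<structure_spec> vesicle, diameter %g nm, shell +/-%g nm\n",
                x$diameter, x$shell_halfwidth))
  else
    cat(sprintf("<structure_spec> tubule, %g x %g nm, shell +/-%g nm\n",
                x$diameter, x$length, x$shell_halfwidth))
  invisible(x)
}

# maximum linear extent of the structure (nm), without the shell
structure_extent <- function(spec) {
  if (spec$shape == "vesicle") spec$diameter else spec$length
}

#' Voxel grid parameters
#'
#' Cubic rasterization grid: `n` voxels per axis of edge `voxel_size` nm.
#' Defaults (200 voxels of 5 nm) give a 1 um field.
#'
#' @param n voxels per axis (>= 1).
#' @param voxel_size voxel edge in nm (> 0).
#' @return object of class `grid_params`.
#' @export
grid_params <- function(n = 200, voxel_size = 5) {
  stopifnot_scalar_num(n, "n", 1)
  stopifnot_scalar_num(voxel_size, "voxel_size", 0, strict = TRUE)
  structure(list(n = as.integer(n), voxel_size = voxel_size),
            class = "grid_params")
}

#' 3D label-density grid
#'
#' @param values nonnegative finite 3D array (label density, arbitrary units).
#' @param voxel_size voxel edge in nm.
#' @return object of class `voxel_grid`.
#' @export
voxel_grid <- function(values, voxel_size) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop("voxel values must be finite and nonnegative", call. = FALSE)
  stopifnot_scalar_num(voxel_size, "voxel_size", 0, strict = TRUE)
  structure(list(values = values, voxel_size = voxel_size),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_grid> %d x %d x %d @ %g nm, %d nonzero voxels\n",
              d[1], d[2], d[3], x$voxel_size, sum(x$values > 0)))
  invisible(x)
}

#' Sample a uniformly random 3D rotation
#'
#' Draws a rotation uniformly from SO(3) via a uniform unit quaternion
#' (four iid standard normals, normalized), so sampled orientations are
#' exactly isotropic. Deterministic given `seed`.
#'
#' @param seed integer seed, or NULL to use the current RNG stream.
#' @return 3x3 rotation matrix (orthonormal, determinant +1).
#' @examples
#' R <- sample_orientation(seed = 1)
#' crossprod(R)  # identity
#' @export
sample_orientation <- function(seed = NULL) {
  q <- with_seed(seed, stats::rnorm(4))
  q <- q / sqrt(sum(q^2))
  quat_to_rot(q)
}

# unit quaternion (w, x, y, z) -> rotation matrix
quat_to_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

check_rotation <- function(rot) {
  if (!is.matrix(rot) || !all(dim(rot) == c(3, 3)))
    stop("`rot` must be a 3x3 matrix", call. = FALSE)
  if (max(abs(crossprod(rot) - diag(3))) > 1e-8 || abs(det(rot) - 1) > 1e-8)
    stop("`rot` must be a proper rotation (orthonormal, det +1)", call. = FALSE)
  invisible(rot)
}

#' Rasterize a surface-labeled structure on a voxel grid
#'
#' Places the structure at the grid center in the given orientation and marks
#' every voxel whose center lies within `shell_halfwidth` of the ideal surface
#' with value 1 (0 elsewhere): a binary surface-label shell. For a vesicle the
#' surface is the sphere of radius `diameter/2`; for a tubule it is the capsule
#' surface at distance `diameter/2` from the axial segment of half-length
#' `(length - diameter)/2`, the axis being the rotated z-axis. Membership is
#' tested at voxel centers, with coordinates in nm from the grid center.
#'
#' @param spec a [structure_spec()].
#' @param grid a [grid_params()]; the structure plus shell must fit inside.
#' @param rot 3x3 rotation matrix (e.g. from [sample_orientation()]);
#'   identity by default.
#' @return a [voxel_grid()] of 0/1 label density.
#' @examples
#' vg <- render_structure(structure_spec("vesicle", 110), grid_params(64, 5))
#' sum(vg$values > 0)
#' @export
render_structure <- function(spec, grid, rot = diag(3)) {
  core <- render_shell_core(spec, grid, rot)
  vals <- array(0, c(grid$n, grid$n, grid$n))
  vals[core$ix, core$iy, core$iz] <- core$shell
  structure(list(values = vals, voxel_size = grid$voxel_size),
            class = "voxel_grid")
}

# shared rasterization core: computes the 0/1 shell only inside the
# structure's axis-aligned bounding box (plus one voxel of slack)
render_shell_core <- function(spec, grid, rot) {
  stopifnot(inherits(spec, "structure_spec"), inherits(grid, "grid_params"))
  check_rotation(rot)
  if (structure_extent(spec) + 2 * spec$shell_halfwidth >=
        grid$n * grid$voxel_size)
    stop("structure (plus shell) does not fit inside the grid", call. = FALSE)

  r2 <- spec$diameter / 2
  if (spec$shape == "tubule") {
    h <- (spec$length - spec$diameter) / 2
    axis <- as.vector(rot %*% c(0, 0, 1))
    reach <- h * abs(axis) + r2 + spec$shell_halfwidth
  } else {
    reach <- rep(r2 + spec$shell_halfwidth, 3)
  }

  coords <- axis_coords(grid$n, grid$voxel_size)
  ix <- which(abs(coords) <= reach[1] + grid$voxel_size)
  iy <- which(abs(coords) <= reach[2] + grid$voxel_size)
  iz <- which(abs(coords) <= reach[3] + grid$voxel_size)
  cx <- coords[ix]; cy <- coords[iy]; cz <- coords[iz]
  nx <- length(cx); ny <- length(cy); nz <- length(cz)
  X <- array(rep(cx, times = ny * nz), c(nx, ny, nz))
  Y <- array(rep(cy, each = nx, times = nz), c(nx, ny, nz))
  Z <- array(rep(cz, each = nx * ny), c(nx, ny, nz))

  if (spec$shape == "vesicle") {
    d_surface <- abs(sqrt(X^2 + Y^2 + Z^2) - r2)
  } else {
    # distance to the axial segment of half-length h along the rotated z-axis
    t <- X * axis[1] + Y * axis[2] + Z * axis[3]
    t <- pmin(pmax(t, -h), h)
    d_axis <- sqrt((X - t * axis[1])^2 + (Y - t * axis[2])^2 +
                     (Z - t * axis[3])^2)
    d_surface <- abs(d_axis - r2)
  }
  shell <- array(0, dim(X))
  shell[d_surface <= spec$shell_halfwidth] <- 1
  if (spec$diameter == 0 && sum(shell) == 0) {
    # point source on an even grid: no voxel center coincides with the grid
    # center, so light up the single nearest voxel
    shell[which.min(d_surface)] <- 1
  }
  list(ix = ix, iy = iy, iz = iz, shell = shell)
}

# render + orthographic z-projection without materializing the 3D grid;
# identical to project_grid(render_structure(...)) since everything outside
# the bounding box is zero
render_projection <- function(spec, grid, rot = diag(3)) {
  core <- render_shell_core(spec, grid, rot)
  img <- matrix(0, grid$n, grid$n)
  img[core$ix, core$iy] <- rowSums(core$shell, dims = 2)
  image2d(img, grid$voxel_size)
}

#' Project a voxel grid into the focal plane
#'
#' Orthographic sum along the optical (z) axis. Valid when the object is much
#' smaller than the axial resolution, so the whole structure lies within one
#' focal slice. Total intensity is conserved exactly and the pixel size equals
#' the voxel size.
#'
#' @param vg a [voxel_grid()].
#' @return an [image2d()].
#' @export
project_grid <- function(vg) {
  stopifnot(inherits(vg, "voxel_grid"))
  image2d(rowSums(vg$values, dims = 2), vg$voxel_size)
}
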