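#' 2D image with physical pixel size
#'
#' A minimal container for single-channel 2D images: a numeric matrix of
#' nonnegative finite intensities plus the pixel size in nanometres. All
#' simulated and measured images in the package are carried in this form.
#' Pixel centers sit at `(i - 0.5) * pixel_size` from the image corner
#' (0-based index `i - 1`), so spatial coordinates refer to pixel centers.
#'
#' @param values numeric matrix of intensities (nonnegative unless
#'   `allow_negative = TRUE`, e.g. for residual images).
#' @param pixel_size pixel edge length in nm (> 0).
#' @param allow_negative permit negative values (residuals).
#' @return An object of class `image2d`: a list with `values` and `pixel_size`.
#' @examples
#' img <- image2d(matrix(0, 10, 10), pixel_size = 5)
#' dim(img$values)
#' @export
image2d <- function(values, pixel_size, allow_negative = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(values)))
    stop("image values must be finite", call. = FALSE)
  if (!allow_negative && any(values < 0))
    stop("image values must be nonnegative", call. = FALSE)
  stopifnot_scalar_num(pixel_size, "pixel_size", 0, strict = TRUE)
  structure(list(values = values, pixel_size = pixel_size), class = "image2d")
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d> %d x %d px @ %g nm/px, total intensity %.6g\n",
              nrow(x$values), ncol(x$values), x$pixel_size, sum(x$values)))
  invisible(x)
}

#' Physical coordinates of pixel centers
#'
#' Coordinates in nm of each pixel center along one axis, measured from the
#' image center (so a centered structure sits at 0).
#'
#' @param n number of pixels along the axis.
#' @param size pixel size in nm.
#' @return numeric vector of length `n`.
#' @keywords internal
axis_coords <- function(n, size) ((seq_len(n) - 0.5) - n / 2) * size

#' Write an image (or voxel grid) to TIFF with a JSON sidecar
#'
#' Images are written as 32-bit float TIFF, one page for an `image2d`, one page
#' per z-slice for a `voxel_grid`. A `<path>.json` sidecar records the pixel or
#' voxel size in nm plus any extra metadata supplied.
#'
#' @param x an `image2d` or `voxel_grid`.
#' @param path output TIFF path.
#' @param metadata named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(x, path, metadata = list()) {
  if (inherits(x, "image2d")) {
    v <- x$values
    scale <- max(v, 1e-12)
    tiff::writeTIFF(v / scale, path, bits.per.sample = 32L)
    meta <- c(list(kind = "image2d", pixel_size_nm = x$pixel_size,
                   intensity_scale = scale), metadata)
  } else if (inherits(x, "voxel_grid")) {
    scale <- max(x$values, 1e-12)
    pages <- lapply(seq_len(dim(x$values)[3]),
                    function(k) x$values[, , k] / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    meta <- c(list(kind = "voxel_grid", voxel_size_nm = x$voxel_size,
                   intensity_scale = scale), metadata)
  } else stop("`x` must be an image2d or voxel_grid", call. = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image written by [write_image_tiff()]
#'
#' @param path TIFF path; the `<path>.json` sidecar must exist.
#' @return an `image2d` or `voxel_grid` matching what was written.
#' @export
read_image_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  scale <- if (is.null(meta$intensity_scale)) 1 else meta$intensity_scale
  if (identical(meta$kind, "voxel_grid")) {
    arr <- array(0, c(dim(pages[[1]]), length(pages)))
    for (k in seq_along(pages)) arr[, , k] <- pages[[k]] * scale
    voxel_grid(arr, meta$voxel_size_nm)
  } else {
    image2d(pages[[1]] * scale, meta$pixel_size_nm)
  }
}
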