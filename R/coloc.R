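#' Estimate a per-channel intensity cutoff from background regions
#'
#' Reproduces the background-thresholding procedure used for colocalization
#' scoring: `n_rois` square regions of interest are placed uniformly at random
#' on the image (avoiding an optional exclusion mask), the brightest pixel of
#' each ROI is recorded, and the cutoff is the mean of those maxima plus one
#' standard deviation.
#'
#' @param img an [image2d()].
#' @param n_rois number of background ROIs (default 100).
#' @param roi_size ROI side length in pixels (default 10).
#' @param exclusion_mask optional logical matrix (same shape as the image);
#'   TRUE pixels may not intersect any ROI.
#' @param seed RNG seed or NULL.
#' @return object of class `threshold_estimate` with `roi_maxima_mean`,
#'   `roi_maxima_sd`, `cutoff = mean + sd`, `n_rois`, `roi_size`, `seed`.
#' @export
estimate_threshold <- function(img, n_rois = 100, roi_size = 10,
                               exclusion_mask = NULL, seed = NULL) {
  stopifnot(inherits(img, "image2d"))
  stopifnot_scalar_num(n_rois, "n_rois", 1)
  stopifnot_scalar_num(roi_size, "roi_size", 1)
  v <- img$values
  nr <- nrow(v) - roi_size + 1L
  nc <- ncol(v) - roi_size + 1L
  if (nr < 1 || nc < 1)
    stop("image smaller than the ROI size", call. = FALSE)

  if (!is.null(exclusion_mask)) {
    if (!is.logical(exclusion_mask) || !all(dim(exclusion_mask) == dim(v)))
      stop("`exclusion_mask` must be a logical matrix matching the image",
           call. = FALSE)
    # summed-area table: a top-left position is valid iff its window contains
    # no masked pixel
    S <- apply(apply(exclusion_mask, 2, cumsum), 1, cumsum)  # S[j, i]
    S <- t(S)
    pad <- matrix(0, nrow(v) + 1L, ncol(v) + 1L)
    pad[-1, -1] <- S
    i <- rep(seq_len(nr), nc); j <- rep(seq_len(nc), each = nr)
    cnt <- pad[cbind(i + roi_size, j + roi_size)] -
      pad[cbind(i, j + roi_size)] - pad[cbind(i + roi_size, j)] +
      pad[cbind(i, j)]
    valid <- which(cnt == 0)
  } else {
    valid <- seq_len(nr * nc)
  }
  if (length(valid) < 1)
    stop("insufficient background: no ROI position avoids the mask",
         call. = FALSE)

  picks <- with_seed(seed, valid[sample.int(length(valid), n_rois,
                                            replace = TRUE)])
  pi0 <- (picks - 1L) %% nr + 1L
  pj0 <- (picks - 1L) %/% nr + 1L
  maxima <- vapply(seq_len(n_rois), function(k) {
    max(v[pi0[k]:(pi0[k] + roi_size - 1L), pj0[k]:(pj0[k] + roi_size - 1L)])
  }, numeric(1))
  m <- mean(maxima)
  s <- if (n_rois > 1) stats::sd(maxima) else 0
  structure(list(roi_maxima_mean = m, roi_maxima_sd = s, cutoff = m + s,
                 n_rois = as.integer(n_rois), roi_size = as.integer(roi_size),
                 seed = seed),
            class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf(
    "<threshold_estimate> cutoff %.3f (ROI maxima %.3f +/- %.3f, %d ROIs of %d px)\n",
    x$cutoff, x$roi_maxima_mean, x$roi_maxima_sd, x$n_rois, x$roi_size))
  invisible(x)
}

#' Detect candidate spots by local maxima with non-maximum suppression
#'
#' Candidate centers are pixels strictly above `cutoff` that are maxima of
#' their 3 x 3 neighborhood, scanned in order of decreasing intensity; a
#' candidate is kept only if no already-kept candidate lies within
#' `min_separation` (nm). A simple, analyzable stand-in for commercial object
#' finders.
#'
#' @param img an [image2d()].
#' @param cutoff intensity threshold (counts).
#' @param min_separation suppression radius in nm.
#' @return data.frame with columns `i`, `j` (pixel indices), `x`, `y`
#'   (nm from image center), `intensity`, ordered by decreasing intensity.
#'   Zero rows when nothing exceeds the cutoff.
#' @export
detect_spots <- function(img, cutoff, min_separation) {
  stopifnot(inherits(img, "image2d"))
  stopifnot_scalar_num(cutoff, "cutoff", -Inf)
  stopifnot_scalar_num(min_separation, "min_separation", 0)
  v <- img$values
  empty <- data.frame(i = integer(), j = integer(), x = numeric(),
                      y = numeric(), intensity = numeric())
  nr <- nrow(v); nc <- ncol(v)
  if (nr < 3 || nc < 3) {
    cand <- which(v > cutoff)
  } else {
    # 3x3 local maxima (ties allowed; suppression resolves plateaus)
    core <- v[2:(nr - 1), 2:(nc - 1)]
    ismax <- core > cutoff
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ismax <- ismax & core >= v[2:(nr - 1) + di, 2:(nc - 1) + dj]
    }
    sub <- which(ismax)
    si <- (sub - 1L) %% (nr - 2L) + 2L
    sj <- (sub - 1L) %/% (nr - 2L) + 2L
    cand <- (sj - 1L) * nr + si
    # border pixels are never candidates: their neighborhood is incomplete
    # and a border spot cannot be fitted anyway
  }
  if (length(cand) == 0) return(empty)
  ord <- cand[order(v[cand], decreasing = TRUE)]
  ij <- arrayInd(ord, dim(v))
  xs <- axis_coords(nrow(v), img$pixel_size)
  ys <- axis_coords(ncol(v), img$pixel_size)
  px <- xs[ij[, 1]]; py <- ys[ij[, 2]]
  keep <- logical(length(ord))
  kx <- numeric(0); ky <- numeric(0)
  for (k in seq_along(ord)) {
    if (length(kx) == 0 ||
        all((kx - px[k])^2 + (ky - py[k])^2 >= min_separation^2)) {
      keep[k] <- TRUE
      kx <- c(kx, px[k]); ky <- c(ky, py[k])
    }
  }
  data.frame(i = ij[keep, 1], j = ij[keep, 2], x = px[keep], y = py[keep],
             intensity = v[ord][keep])
}

# channel peak within `radius` nm of (x0, y0); nm coordinates from image center
peak_near <- function(img, x0, y0, radius) {
  xs <- axis_coords(nrow(img$values), img$pixel_size)
  ys <- axis_coords(ncol(img$values), img$pixel_size)
  ii <- which(abs(xs - x0) <= radius)
  jj <- which(abs(ys - y0) <= radius)
  if (length(ii) == 0 || length(jj) == 0) return(-Inf)
  sub <- img$values[ii, jj, drop = FALSE]
  D2 <- outer((xs[ii] - x0)^2, (ys[jj] - y0)^2, "+")
  m <- sub[D2 <= radius^2]
  if (length(m) == 0) -Inf else max(m)
}

#' Classify size-gated spots by cargo channel content
#'
#' The full colocalization procedure: spots are detected on the reference
#' channel (e.g. the coat-protein stain), each is fitted with the elliptical
#' 2D profile, spots whose fitted size is `>= size_max` or whose fit fails are
#' excluded, and each retained spot is scored for signal in channels A and B
#' by comparing the channel's peak intensity within `peak_radius` of the
#' fitted center against that channel's cutoff. The default radius of two
#' pixels covers sub-pixel registration error while keeping the peak window
#' small enough that a background maximum rarely beats a cutoff calibrated on
#' 10 x 10 ROI maxima. Categories are `A_only`, `B_only`,
#' `both`, or `none`; summary fractions are computed over the spots positive
#' in at least one channel.
#'
#' @param reference_img,channelA,channelB [image2d()] objects of identical
#'   shape and pixel size.
#' @param cutoffs named list with numeric elements `reference`, `A`, `B`
#'   (counts), typically the `cutoff` of [estimate_threshold()] per channel.
#' @param size_max spot-size gate in nm (default 150): spots at or above it
#'   are excluded.
#' @param psf a [psf_spec()] (defines the search radius and fit
#'   initialization).
#' @param min_separation detector suppression radius in nm (default
#'   2 * psf fwhm).
#' @param peak_radius search radius in nm for the per-channel peak around the
#'   fitted center (default 2 pixels).
#' @param model fit profile, `"lorentzian"` or `"gaussian"`.
#' @return object of class `classification_summary`: counts and fractions for
#'   the three positive categories, `n_spots_total`, `n_excluded_by_size`,
#'   `n_not_converged`, `n_none`, the cutoffs, and a per-spot data.frame
#'   `spots`.
#' @export
classify_spots <- function(reference_img, channelA, channelB, cutoffs,
                           size_max = 150, psf = psf_spec("lorentzian", 80),
                           min_separation = 2 * psf$fwhm,
                           peak_radius = 2 * reference_img$pixel_size,
                           model = "lorentzian") {
  for (im in list(reference_img, channelA, channelB))
    stopifnot(inherits(im, "image2d"))
  if (!all(dim(channelA$values) == dim(reference_img$values)) ||
      !all(dim(channelB$values) == dim(reference_img$values)))
    stop("channel images must match the reference image shape", call. = FALSE)
  for (nm in c("reference", "A", "B"))
    if (is.null(cutoffs[[nm]]) || !is.finite(cutoffs[[nm]]))
      stop(sprintf("missing cutoff for channel '%s'", nm), call. = FALSE)

  det <- detect_spots(reference_img, cutoffs$reference, min_separation)
  rows <- list()
  n_size <- 0L; n_fail <- 0L
  for (k in seq_len(nrow(det))) {
    fit <- tryCatch(
      fit_spot(reference_img, model, center = c(det$x[k], det$y[k]),
               init_fwhm = psf$fwhm),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) { n_fail <- n_fail + 1L; next }
    size <- spot_size(fit)
    if (size >= size_max) { n_size <- n_size + 1L; next }
    pa <- peak_near(channelA, fit$center[1], fit$center[2], peak_radius)
    pb <- peak_near(channelB, fit$center[1], fit$center[2], peak_radius)
    a_pos <- pa > cutoffs$A
    b_pos <- pb > cutoffs$B
    category <- if (a_pos && b_pos) "both" else if (a_pos) "A_only"
    else if (b_pos) "B_only" else "none"
    rows[[length(rows) + 1L]] <- data.frame(
      x = unname(fit$center[1]), y = unname(fit$center[2]), size = size,
      axis_ratio = axis_ratio(fit), peak_A = pa, peak_B = pb,
      category = category)
  }
  spots <- if (length(rows)) do.call(rbind, rows)
  else data.frame(x = numeric(), y = numeric(), size = numeric(),
                  axis_ratio = numeric(), peak_A = numeric(),
                  peak_B = numeric(), category = character())

  counts <- c(A_only = sum(spots$category == "A_only"),
              B_only = sum(spots$category == "B_only"),
              both = sum(spots$category == "both"))
  n_pos <- sum(counts)
  fractions <- if (n_pos > 0) counts / n_pos else counts * NA_real_
  structure(list(counts = counts, fractions = fractions,
                 n_positive = n_pos,
                 n_none = sum(spots$category == "none"),
                 n_spots_total = nrow(det),
                 n_excluded_by_size = n_size,
                 n_not_converged = n_fail,
                 cutoffs = cutoffs, size_max = size_max, spots = spots),
            class = "classification_summary")
}

#' @export
print.classification_summary <- function(x, ...) {
  cat(sprintf("<classification_summary> %d detected, %d excluded by size, %d fit failures\n",
              x$n_spots_total, x$n_excluded_by_size, x$n_not_converged))
  if (x$n_positive > 0) {
    f <- x$fractions
    cat(sprintf("  A_only %d (%.1f%%), B_only %d (%.1f%%), both %d (%.1f%%); none %d\n",
                x$counts[1], 100 * f[1], x$counts[2], 100 * f[2],
                x$counts[3], 100 * f[3], x$n_none))
  } else cat("  no channel-positive spots\n")
  invisible(x)
}

#' Pearson's colocalization coefficient
#'
#' Pixel-wise Pearson correlation between two channels over an optional mask.
#' Near +1 for colocalized signal, near 0 for unrelated signal, negative for
#' mutually exclusive staining.
#'
#' @param imgA,imgB [image2d()] objects of identical shape.
#' @param mask optional logical matrix selecting the pixels to correlate.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_coloc <- function(imgA, imgB, mask = NULL) {
  stopifnot(inherits(imgA, "image2d"), inherits(imgB, "image2d"))
  if (!all(dim(imgA$values) == dim(imgB$values)))
    stop("images must have the same shape", call. = FALSE)
  a <- imgA$values; b <- imgB$values
  if (!is.null(mask)) {
    if (!is.logical(mask) || !all(dim(mask) == dim(a)))
      stop("`mask` must be a logical matrix matching the images", call. = FALSE)
    a <- a[mask]; b <- b[mask]
  }
  if (length(a) < 2) stop("need at least 2 pixels", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance in at least one channel", call. = FALSE)
  stats::cor(as.vector(a), as.vector(b))
}
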