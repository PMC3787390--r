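#' Run the vesicle-versus-tubule shape discrimination experiment
#'
#' End-to-end: generate the simulated frames ([generate_shape_dataset()]),
#' fit every frame with the elliptical 2D Lorentzian, summarize the size and
#' axis-ratio distribution per structure class, and compare the first
#' (reference, normally the vesicle) class against every other class on both
#' statistics.
#'
#' A pair of classes is flagged *distinguishable* on a statistic when the
#' absolute difference of class means is at least the pooled within-class SD
#' (a large effect) **and** a Wilcoxon rank-sum test, Holm-corrected across
#' the compared pairs, rejects at `alpha`; otherwise the pair is flagged
#' *indistinguishable* on that statistic. Effect size leads because with
#' hundreds of frames per class a rank test alone would flag differences far
#' below the within-class spread. A pair is distinguishable overall if it is
#' distinguishable on either statistic.
#'
#' @param cfg a [shape_experiment_config()].
#' @param alpha significance level for the rank test (default 0.01).
#' @param fit_crop crop side in pixels passed to [fit_spot()]; default `Inf`
#'   (fit the whole frame): each simulated frame holds a single object, and a
#'   full-frame fit uses the Lorentzian tails that a tight crop would discard.
#' @param out_dir optional directory: writes `shape_report.json`,
#'   `per_frame.csv` and `size_distributions.png` /
#'   `axis_ratio_distributions.png`.
#' @return object of class `shape_report`: per-class summaries
#'   (`size_distribution` objects, axis-ratio mean/sd), a `comparisons`
#'   data.frame (one row per pair and statistic with difference of means,
#'   pooled SD, test statistic, raw and Holm-adjusted p, flag), per-frame
#'   results, fit-failure count, the config and seed.
#' @export
run_shape_experiment <- function(cfg, alpha = 0.01, fit_crop = Inf,
                                 out_dir = NULL) {
  stopifnot(inherits(cfg, "shape_experiment_config"))
  ds <- generate_shape_dataset(cfg)
  res <- list()
  for (k in seq_along(ds$frames)) {
    fit <- tryCatch(
      fit_spot(ds$frames[[k]], "lorentzian", init_fwhm = cfg$psf$fwhm,
               crop = fit_crop),
      error = function(e) NULL)
    ok <- !is.null(fit) && fit$converged
    res[[k]] <- data.frame(
      class = ds$truth$class[k], frame = k, converged = ok,
      size = if (ok) spot_size(fit) else NA_real_,
      axis_ratio = if (ok) axis_ratio(fit) else NA_real_,
      fwhm_major = if (ok) fit$fwhm_major else NA_real_,
      fwhm_minor = if (ok) fit$fwhm_minor else NA_real_,
      theta = if (ok) fit$theta else NA_real_,
      residual_norm = if (ok) fit$residual_norm else NA_real_)
  }
  per_frame <- do.call(rbind, res)
  classes <- names(cfg$structures)
  by_class <- split(per_frame[per_frame$converged, ],
                    factor(per_frame$class[per_frame$converged],
                           levels = classes))

  summaries <- lapply(by_class, function(d) {
    list(size = structure(list(sizes = d$size, mean = mean(d$size),
                               sd = if (nrow(d) > 1) stats::sd(d$size)
                               else NA_real_, n = nrow(d)),
                          class = "size_distribution"),
         axis_ratio = list(values = d$axis_ratio, mean = mean(d$axis_ratio),
                           sd = if (nrow(d) > 1) stats::sd(d$axis_ratio)
                           else NA_real_, n = nrow(d)))
  })

  ref <- classes[1]
  others <- classes[-1]
  comp <- list()
  for (stat in c("size", "axis_ratio")) {
    pvals <- numeric(length(others))
    rows <- list()
    for (i in seq_along(others)) {
      a <- by_class[[ref]][[stat]]
      b <- by_class[[others[i]]][[stat]]
      wt <- stats::wilcox.test(a, b, exact = FALSE)
      pooled_sd <- sqrt((stats::var(a) * (length(a) - 1) +
                           stats::var(b) * (length(b) - 1)) /
                          (length(a) + length(b) - 2))
      pvals[i] <- wt$p.value
      rows[[i]] <- data.frame(
        reference = ref, class = others[i], statistic = stat,
        mean_ref = mean(a), mean_other = mean(b),
        diff_means = mean(b) - mean(a), pooled_sd = pooled_sd,
        W = unname(wt$statistic), p_value = wt$p.value)
    }
    p_adj <- stats::p.adjust(pvals, method = "holm")
    for (i in seq_along(rows)) {
      rows[[i]]$p_holm <- p_adj[i]
      rows[[i]]$distinguishable <-
        abs(rows[[i]]$diff_means) >= rows[[i]]$pooled_sd && p_adj[i] < alpha
    }
    comp[[stat]] <- do.call(rbind, rows)
  }
  comparisons <- do.call(rbind, comp)
  rownames(comparisons) <- NULL

  report <- structure(list(
    classes = classes, summaries = summaries, comparisons = comparisons,
    per_frame = per_frame, n_fit_failures = sum(!per_frame$converged),
    alpha = alpha, seed = cfg$seed, config = cfg),
    class = "shape_report")

  if (!is.null(out_dir)) write_shape_report(report, out_dir)
  report
}

#' Overall distinguishability flag for one class pair
#'
#' @param report a `shape_report`.
#' @param class name of the class compared against the reference.
#' @param statistic `"size"`, `"axis_ratio"`, or `"any"` (default): on `"any"`
#'   the pair is distinguishable if it is on either statistic.
#' @return logical.
#' @export
distinguishable <- function(report, class, statistic = "any") {
  stopifnot(inherits(report, "shape_report"))
  cmp <- report$comparisons
  sel <- cmp$class == class
  if (!any(sel)) stop("unknown class: ", class, call. = FALSE)
  if (statistic == "any") any(cmp$distinguishable[sel])
  else {
    sel <- sel & cmp$statistic == statistic
    if (!any(sel)) stop("unknown statistic: ", statistic, call. = FALSE)
    any(cmp$distinguishable[sel])
  }
}

#' @export
print.shape_report <- function(x, ...) {
  cat(sprintf("<shape_report> %d classes, seed %s, %d fit failures\n",
              length(x$classes), format(x$seed), x$n_fit_failures))
  for (cls in x$classes) {
    s <- x$summaries[[cls]]
    cat(sprintf("  %-15s n=%3d  size %6.1f +/- %5.1f nm   axis ratio %.3f +/- %.3f\n",
                cls, s$size$n, s$size$mean, s$size$sd,
                s$axis_ratio$mean, s$axis_ratio$sd))
  }
  cat("comparisons vs", x$classes[1], ":\n")
  cmp <- x$comparisons
  for (i in seq_len(nrow(cmp)))
    cat(sprintf("  %-15s %-10s diff %7.2f (pooled sd %6.2f), p_holm %.3g -> %s\n",
                cmp$class[i], cmp$statistic[i], cmp$diff_means[i],
                cmp$pooled_sd[i], cmp$p_holm[i],
                if (cmp$distinguishable[i]) "distinguishable"
                else "indistinguishable"))
  invisible(x)
}

write_shape_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$per_frame,
                   file.path(out_dir, "per_frame.csv"), row.names = FALSE)
  json <- list(
    seed = report$seed, alpha = report$alpha, classes = report$classes,
    n_fit_failures = report$n_fit_failures,
    summaries = lapply(report$summaries, function(s) list(
      size_mean = round(s$size$mean, 6), size_sd = round(s$size$sd, 6),
      n = s$size$n, axis_ratio_mean = round(s$axis_ratio$mean, 6),
      axis_ratio_sd = round(s$axis_ratio$sd, 6))),
    comparisons = lapply(seq_len(nrow(report$comparisons)), function(i) {
      r <- report$comparisons[i, ]
      list(class = r$class, statistic = r$statistic,
           diff_means = round(r$diff_means, 6),
           pooled_sd = round(r$pooled_sd, 6),
           p_holm = signif(r$p_holm, 6),
           distinguishable = r$distinguishable)
    }))
  jsonlite::write_json(json, file.path(out_dir, "shape_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  pf <- report$per_frame[report$per_frame$converged, ]
  for (stat in c("size", "axis_ratio")) {
    grDevices::png(file.path(out_dir, paste0(stat, "_distributions.png")),
                   width = 900, height = 600)
    vals <- split(pf[[stat]], factor(pf$class, levels = report$classes))
    graphics::boxplot(vals, main = paste(stat, "by structure class"),
                      ylab = if (stat == "size") "size (nm)"
                      else "major/minor FWHM ratio", las = 2)
    grDevices::dev.off()
  }
  invisible(out_dir)
}

# exclusion mask for background ROI placement: pixels well above the robust
# background level (median + 10 MAD, i.e. objects, not noise), dilated by
# `radius` nm via a box-kernel convolution
background_mask <- function(img, psf, radius = 2 * psf$fwhm) {
  v <- img$values
  cut0 <- stats::median(v) + 10 * stats::mad(v)
  bright <- v > cut0
  if (!any(bright)) return(matrix(FALSE, nrow(v), ncol(v)))
  rad_px <- ceiling(radius / img$pixel_size)
  box <- matrix(1, 2 * rad_px + 1, 2 * rad_px + 1)
  conv2_zero(bright + 0, box) > 0.5
}

#' Run the end-to-end colocalization classification experiment
#'
#' Generates a synthetic two-cargo field ([generate_spot_field()]), estimates
#' per-channel background cutoffs with spot-excluding masks, detects, fits and
#' classifies the spots ([classify_spots()]), and scores the result against
#' the generator's ground truth by nearest-center matching within one PSF
#' FWHM.
#'
#' The mean+1SD background cutoff is deliberately permissive — it scores cargo
#' *presence* at an already-identified object. Using it directly as the
#' detection threshold would also detect the bright reference spots' own
#' Lorentzian tails, so the detector uses `detect_cutoff_factor` times the
#' reference cutoff and a suppression radius scaled to the field's packing
#' distance.
#'
#' @param cfg a [spot_field_config()].
#' @param size_max spot-size gate in nm (default 150).
#' @param psf a [psf_spec()] used by detection/fitting.
#' @param n_rois,roi_size background thresholding parameters.
#' @param detect_cutoff_factor multiple of the reference-channel background
#'   cutoff used as the detection threshold (default 2).
#' @param detect_min_separation non-maximum-suppression radius in nm; default
#'   0.6 times the generator's minimum spot separation.
#' @return list with `summary` (a `classification_summary`), `thresholds`,
#'   `truth_fractions`, `recovered_fractions`, `confusion` (truth x assigned
#'   table over matched spots), `n_matched`, and the generated `field`.
#' @export
run_classification_experiment <- function(cfg, size_max = 150,
                                          psf = psf_spec("lorentzian", 80),
                                          n_rois = 100, roi_size = 10,
                                          detect_cutoff_factor = 2,
                                          detect_min_separation = NULL) {
  stopifnot(inherits(cfg, "spot_field_config"))
  field <- generate_spot_field(cfg)
  seeds <- cfg$seed + c(101, 202, 303)
  imgs <- list(reference = field$reference, A = field$channelA,
               B = field$channelB)
  thr <- list()
  for (k in seq_along(imgs)) {
    nm <- names(imgs)[k]
    thr[[nm]] <- estimate_threshold(
      imgs[[nm]], n_rois = n_rois, roi_size = roi_size,
      exclusion_mask = background_mask(imgs[[nm]], psf), seed = seeds[k])
  }
  cutoffs <- lapply(thr, function(t) t$cutoff)
  cutoffs$reference <- cutoffs$reference * detect_cutoff_factor
  if (is.null(detect_min_separation))
    detect_min_separation <- 0.6 * cfg$min_separation
  summary <- classify_spots(field$reference, field$channelA, field$channelB,
                            cutoffs, size_max = size_max, psf = psf,
                            min_separation = detect_min_separation)

  truth <- field$truth
  truth_fracs <- if (nrow(truth) > 0)
    prop.table(table(factor(truth$category,
                            levels = c("A_only", "B_only", "both"))))
  else table(factor(character(), levels = c("A_only", "B_only", "both")))

  # nearest-center matching of classified spots to ground truth
  spots <- summary$spots
  matched <- integer(0)
  pairs <- list()
  if (nrow(spots) > 0 && nrow(truth) > 0) {
    for (k in seq_len(nrow(spots))) {
      d2 <- (truth$x - spots$x[k])^2 + (truth$y - spots$y[k])^2
      j <- which.min(d2)
      if (d2[j] <= psf$fwhm^2 && !(j %in% matched)) {
        matched <- c(matched, j)
        pairs[[length(pairs) + 1L]] <- data.frame(
          truth = truth$category[j], assigned = spots$category[k])
      }
    }
  }
  confusion <- if (length(pairs)) {
    p <- do.call(rbind, pairs)
    table(truth = factor(p$truth, c("A_only", "B_only", "both")),
          assigned = factor(p$assigned, c("A_only", "B_only", "both", "none")))
  } else NULL

  list(summary = summary, thresholds = thr,
       truth_fractions = truth_fracs,
       recovered_fractions = summary$fractions,
       confusion = confusion, n_matched = length(matched), field = field)
}
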