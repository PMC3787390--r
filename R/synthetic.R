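#' Configuration for the vesicle/tubule shape-simulation experiment
#'
#' Defaults reproduce the reference simulation design: one 110 nm vesicle
#' class and four 30 nm tubule classes of length 80, 110, 150 and 300 nm,
#' 150 structures per class in isotropic random orientations, rasterized on a
#' 200^3 grid of 5 nm voxels and imaged with the 80 nm FWHM Lorentzian STED
#' PSF under Poisson noise.
#'
#' @param structures list of [structure_spec()] objects, one per class.
#' @param n_per_class frames per class (default 150).
#' @param psf a [psf_spec()].
#' @param grid a [grid_params()].
#' @param noise a [noise_params()] or NULL for noise-free frames.
#' @param seed master RNG seed (default 1).
#' @return object of class `shape_experiment_config`.
#' @export
shape_experiment_config <- function(
    structures = list(
      vesicle_110 = structure_spec("vesicle", 110),
      tubule_30x80 = structure_spec("tubule", 30, 80),
      tubule_30x110 = structure_spec("tubule", 30, 110),
      tubule_30x150 = structure_spec("tubule", 30, 150),
      tubule_30x300 = structure_spec("tubule", 30, 300)),
    n_per_class = 150, psf = psf_spec("lorentzian", 80),
    grid = grid_params(200, 5), noise = noise_params(), seed = 1) {
  stopifnot(length(structures) >= 1,
            all(vapply(structures, inherits, TRUE, "structure_spec")))
  stopifnot_scalar_num(n_per_class, "n_per_class", 1)
  if (is.null(names(structures)) || any(names(structures) == ""))
    names(structures) <- vapply(structures, function(s) {
      if (s$shape == "vesicle") sprintf("vesicle_%g", s$diameter)
      else sprintf("tubule_%gx%g", s$diameter, s$length)
    }, character(1))
  structure(list(structures = structures,
                 n_per_class = as.integer(n_per_class),
                 psf = psf, grid = grid, noise = noise, seed = seed),
            class = "shape_experiment_config")
}

#' Generate simulated single-structure frames with ground truth
#'
#' For every structure class, draws `n_per_class` isotropic orientations,
#' rasterizes the surface-labeled structure, projects it into the focal plane,
#' convolves with the PSF and (optionally) applies Poisson noise. Fully
#' reproducible from the config seed.
#'
#' @param cfg a [shape_experiment_config()].
#' @return list with `frames` (list of [image2d()]) and `truth` (data.frame
#'   with class, frame index, and orientation quaternion columns qw/qx/qy/qz).
#' @export
generate_shape_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "shape_experiment_config"))
  frames <- list()
  truth <- list()
  with_seed(cfg$seed, {
    for (cls in names(cfg$structures)) {
      spec <- cfg$structures[[cls]]
      for (k in seq_len(cfg$n_per_class)) {
        q <- stats::rnorm(4)
        q <- q / sqrt(sum(q^2))
        rot <- quat_to_rot(q)
        img <- image_structure(render_projection(spec, cfg$grid, rot),
                               cfg$psf, cfg$noise)
        frames[[length(frames) + 1L]] <- img
        truth[[length(truth) + 1L]] <- data.frame(
          class = cls, frame = length(frames), replicate = k,
          qw = q[1], qx = q[2], qy = q[3], qz = q[4])
      }
    }
  })
  list(frames = frames, truth = do.call(rbind, truth))
}

#' Configuration for a synthetic multi-channel spot field
#'
#' Defines a two-cargo colocalization field: `n_spots` carriers placed
#' uniformly with a minimum pairwise separation. Every spot appears in the
#' reference channel (the coat stain); its category — drawn from
#' `fractions = c(A_only, B_only, both)` — decides which cargo channels
#' receive its signal. Spot apparent sizes (FWHM) are drawn from a truncated
#' normal; per-channel peak amplitudes are log-normal around the configured
#' means; each channel gets independent Poisson noise over a constant
#' background.
#'
#' @param field_px field side in pixels (default 3000).
#' @param pixel_size nm per pixel (default 5).
#' @param n_spots number of spots (default 200).
#' @param fractions length-3 numeric `(A_only, B_only, both)` summing to 1.
#' @param size_mean,size_sd spot FWHM distribution in nm (default 125 / 12),
#'   truncated to `[90, 200]`.
#' @param amp_reference,amp_A,amp_B mean peak amplitudes in counts.
#' @param amp_sdlog log-normal spread of amplitudes.
#' @param background per-channel Poisson background rate (counts/pixel).
#' @param min_separation minimum center-to-center distance in nm
#'   (default 600; beyond the tail truncation radius of the rendered spots,
#'   so channels are independent at neighboring spot centers).
#' @param margin minimum distance of centers from the field edge in nm
#'   (default 300).
#' @param seed master RNG seed.
#' @return object of class `spot_field_config`.
#' @export
spot_field_config <- function(field_px = 3000, pixel_size = 5, n_spots = 200,
                              fractions = c(A_only = 0.66, B_only = 0.20,
                                            both = 0.15),
                              size_mean = 125, size_sd = 12,
                              amp_reference = 150, amp_A = 120, amp_B = 120,
                              amp_sdlog = 0.25, background = 5,
                              min_separation = 600, margin = 300, seed = 1) {
  stopifnot_scalar_num(n_spots, "n_spots", 0)
  if (length(fractions) != 3 || any(fractions < 0))
    stop("`fractions` must be 3 nonnegative numbers (A_only, B_only, both)",
         call. = FALSE)
  if (abs(sum(fractions) - 1) > 0.02)
    stop("`fractions` must sum to 1", call. = FALSE)
  # tolerate rounded percentage triples (e.g. 66/20/15 sums to 101)
  fractions <- fractions / sum(fractions)
  names(fractions) <- c("A_only", "B_only", "both")
  structure(list(field_px = as.integer(field_px), pixel_size = pixel_size,
                 n_spots = as.integer(n_spots), fractions = fractions,
                 size_mean = size_mean, size_sd = size_sd,
                 amp_reference = amp_reference, amp_A = amp_A, amp_B = amp_B,
                 amp_sdlog = amp_sdlog, background = background,
                 min_separation = min_separation, margin = margin,
                 seed = seed),
            class = "spot_field_config")
}

# add a circular Lorentzian spot of peak `amp` and width `fwhm` at (x0, y0)
# nm (from image center) into matrix `m`; evaluated on a local window only
add_lorentz_spot <- function(m, px, x0, y0, fwhm, amp, reach = 4 * fwhm) {
  xs <- axis_coords(nrow(m), px)
  ys <- axis_coords(ncol(m), px)
  ii <- which(abs(xs - x0) <= reach)
  jj <- which(abs(ys - y0) <= reach)
  if (length(ii) == 0 || length(jj) == 0) return(m)
  r2 <- outer((xs[ii] - x0)^2, (ys[jj] - y0)^2, "+")
  m[ii, jj] <- m[ii, jj] + amp / (1 + 4 * r2 / fwhm^2)
  m
}

#' Generate a synthetic two-cargo spot field with ground truth
#'
#' @param cfg a [spot_field_config()].
#' @return list with `reference`, `channelA`, `channelB` ([image2d()] count
#'   images) and `truth`, a data.frame with per-spot position (nm from image
#'   center), true FWHM, category and channel amplitudes.
#' @export
generate_spot_field <- function(cfg) {
  stopifnot(inherits(cfg, "spot_field_config"))
  n <- cfg$field_px
  px <- cfg$pixel_size
  half <- n * px / 2 - cfg$margin
  if (half <= 0) stop("margin leaves no room for spots", call. = FALSE)
  with_seed(cfg$seed, {
    # uniform placement with minimum pairwise separation (rejection sampling)
    xs <- numeric(0); ys <- numeric(0)
    tries <- 0L
    while (length(xs) < cfg$n_spots) {
      if (tries > 200 * max(cfg$n_spots, 1))
        stop("packing failure: cannot place spots at this min_separation",
             call. = FALSE)
      tries <- tries + 1L
      cx <- stats::runif(1, -half, half)
      cy <- stats::runif(1, -half, half)
      if (length(xs) == 0 ||
          all((xs - cx)^2 + (ys - cy)^2 >= cfg$min_separation^2)) {
        xs <- c(xs, cx); ys <- c(ys, cy)
      }
    }
    cats <- if (cfg$n_spots > 0)
      sample(c("A_only", "B_only", "both"), cfg$n_spots, replace = TRUE,
             prob = cfg$fractions) else character(0)
    sizes <- pmin(pmax(stats::rnorm(cfg$n_spots, cfg$size_mean, cfg$size_sd),
                       90), 200)
    amp_r <- stats::rlnorm(cfg$n_spots, log(cfg$amp_reference), cfg$amp_sdlog)
    amp_a <- stats::rlnorm(cfg$n_spots, log(cfg$amp_A), cfg$amp_sdlog)
    amp_b <- stats::rlnorm(cfg$n_spots, log(cfg$amp_B), cfg$amp_sdlog)

    ref <- matrix(0, n, n); cha <- matrix(0, n, n); chb <- matrix(0, n, n)
    for (k in seq_len(cfg$n_spots)) {
      ref <- add_lorentz_spot(ref, px, xs[k], ys[k], sizes[k], amp_r[k])
      if (cats[k] %in% c("A_only", "both"))
        cha <- add_lorentz_spot(cha, px, xs[k], ys[k], sizes[k], amp_a[k])
      if (cats[k] %in% c("B_only", "both"))
        chb <- add_lorentz_spot(chb, px, xs[k], ys[k], sizes[k], amp_b[k])
    }
    noisy <- function(m) {
      matrix(stats::rpois(length(m), m + cfg$background), n, n)
    }
    list(reference = image2d(noisy(ref), px),
         channelA = image2d(noisy(cha), px),
         channelB = image2d(noisy(chb), px),
         truth = data.frame(x = xs, y = ys, size = sizes, category = cats,
                            amp_reference = amp_r,
                            amp_A = ifelse(cats %in% c("A_only", "both"),
                                           amp_a, 0),
                            amp_B = ifelse(cats %in% c("B_only", "both"),
                                           amp_b, 0)))
  })
}

#' Configuration for a synthetic exchange / FRAP timecourse
#'
#' Single-exponential saturation toward a plateau, with optional bleach
#' events. A test harness for the scalar kinetic quantifications, not a
#' mechanistic transport model.
#'
#' @param plateau_fold asymptotic fold increase over the baseline (default
#'   10.2).
#' @param rate rate constant per minute (default 0.15).
#' @param baseline starting intensity of the acceptor ROI (default 10).
#' @param noise_sd Gaussian intensity noise SD (default 0).
#' @param frame_interval minutes between frames (default 1).
#' @param duration total minutes (default 30).
#' @param bleach_events data.frame with columns `time` (min) and
#'   `surviving_fraction`, or NULL.
#' @param seed RNG seed.
#' @return object of class `timecourse_config`.
#' @export
timecourse_config <- function(plateau_fold = 10.2, rate = 0.15, baseline = 10,
                              noise_sd = 0, frame_interval = 1, duration = 30,
                              bleach_events = NULL, seed = 1) {
  stopifnot_scalar_num(plateau_fold, "plateau_fold", 0)
  stopifnot_scalar_num(rate, "rate", 0)
  stopifnot_scalar_num(duration, "duration", 0, strict = TRUE)
  structure(list(plateau_fold = plateau_fold, rate = rate,
                 baseline = baseline, noise_sd = noise_sd,
                 frame_interval = frame_interval, duration = duration,
                 bleach_events = bleach_events, seed = seed),
            class = "timecourse_config")
}

#' Generate a donor/acceptor exchange timecourse
#'
#' The acceptor ROI relaxes exponentially toward `baseline * plateau_fold`
#' with the configured rate; a bleach event at time `t` multiplies the current
#' acceptor intensity by its surviving fraction, after which relaxation toward
#' the plateau resumes (fluorescence recovery). The donor mirrors the
#' acceptor so that donor + acceptor is constant (before noise). Gaussian
#' noise is added independently to both.
#'
#' @param cfg a [timecourse_config()].
#' @return list of two [time_series()]: `acceptor` and `donor`.
#' @export
generate_timecourse <- function(cfg) {
  stopifnot(inherits(cfg, "timecourse_config"))
  times <- seq(0, cfg$duration, by = cfg$frame_interval)
  plateau <- cfg$baseline * cfg$plateau_fold
  events <- cfg$bleach_events
  if (!is.null(events)) events <- events[order(events$time), , drop = FALSE]

  acceptor <- numeric(length(times))
  cur <- cfg$baseline   # state at time t_last
  t_last <- 0
  ev_idx <- 1L
  relax <- function(i0, dt) plateau + (i0 - plateau) * exp(-cfg$rate * dt)
  for (k in seq_along(times)) {
    t <- times[k]
    # apply any bleach events between t_last and t (inclusive)
    while (!is.null(events) && ev_idx <= nrow(events) &&
           events$time[ev_idx] <= t) {
      te <- events$time[ev_idx]
      cur <- relax(cur, te - t_last)
      cur <- cur * events$surviving_fraction[ev_idx]
      t_last <- te
      ev_idx <- ev_idx + 1L
    }
    cur <- relax(cur, t - t_last)
    t_last <- t
    acceptor[k] <- cur
  }
  total <- cfg$baseline + plateau
  donor <- pmax(total - acceptor, 0)
  if (cfg$noise_sd > 0) {
    noise <- with_seed(cfg$seed, stats::rnorm(2 * length(times), 0,
                                              cfg$noise_sd))
    acceptor <- pmax(acceptor + noise[seq_along(times)], 0)
    donor <- pmax(donor + noise[length(times) + seq_along(times)], 0)
  }
  list(acceptor = time_series(times, acceptor, "acceptor"),
       donor = time_series(times, donor, "donor"))
}
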