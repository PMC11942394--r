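#' Imaging noise model for synthetic time-lapse frames
#'
#' Captures the nuisance structure of a phase-contrast acquisition well
#' enough to exercise the front tracker: additive Gaussian pixel noise, a
#' quadratic vignetting falloff toward the frame corners, and a uniform
#' background level. A fixed seed makes the generated stack reproducible
#' bit for bit.
#'
#' @param sigma additive Gaussian noise sd, in units of the normalised
#'   frame intensity (ring peak ~ 1).
#' @param vignetting relative intensity loss at the frame corner (0 = none).
#' @param background constant background level.
#' @param seed RNG seed for the noise.
#' @return List of class `imaging_noise_model`.
#' @export
imaging_noise_model <- function(sigma = 0.05, vignetting = 0.1,
                                background = 0.1, seed = 1) {
  if (sigma < 0) stop("sigma must be nonnegative")
  if (vignetting < 0 || vignetting >= 1) stop("vignetting must be in [0, 1)")
  structure(list(sigma = sigma, vignetting = vignetting,
                 background = background, seed = as.integer(seed)),
            class = "imaging_noise_model")
}

#' Render one synthetic phase-contrast-like frame
#'
#' Projects the radially symmetric cross-linking production profile of a
#' field state onto a pixel grid: the brightest ring sits at the front
#' radius. Intensity is the production profile divided by `intensity_scale`
#' (per-frame peak if `NULL`; a series renderer passes the run-wide peak so
#' the ring fades as the reaction dies out), then shaded by vignetting,
#' offset by the background and corrupted by Gaussian noise. Rendering is
#' deterministic under a fixed noise seed; the caller's RNG state is left
#' untouched.
#'
#' @param state a `field_state` (see [sim_state()]); must carry the domain
#'   radius `R0`.
#' @param p model parameters.
#' @param pixel_size_um pixel size, um/px (default 10).
#' @param noise an [imaging_noise_model()].
#' @param intensity_scale production value mapping to intensity 1.
#' @param pad_px margin of bath pixels around the disc.
#' @param seed_offset added to the noise seed (frame index in a series).
#' @return Numeric matrix (square, odd side), attributes `pixel_size_um`,
#'   `center` (row, col of the disc centre).
#' @export
render_frame <- function(state, p, pixel_size_um = 10,
                         noise = imaging_noise_model(),
                         intensity_scale = NULL, pad_px = 8,
                         seed_offset = 0) {
  stopifnot(inherits(state, "field_state"))
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  if (is.null(state$R0) || !is.finite(state$R0)) {
    stop("state has no domain radius; cannot size the frame")
  }
  px_mm <- pixel_size_um / 1000
  W <- ceiling(state$R0 / px_mm) + pad_px
  side <- 2L * as.integer(W) + 1L
  ctr <- W + 1L
  prod <- production_profile(state, p)
  scale <- intensity_scale %||% max(prod, 1e-300)
  if (scale <= 0) scale <- 1
  ax <- seq_len(side) - ctr
  rr_px <- sqrt(outer(ax^2, ax^2, "+"))          # radius of each pixel, px
  rr_mm <- rr_px * px_mm
  # piecewise-linear radial interpolation of the production profile;
  # pixels outside the disc are bath (zero signal)
  intens <- stats::approx(state$r, prod / scale, xout = pmin(rr_mm, state$R0),
                          rule = 2)$y
  intens[rr_mm > state$R0] <- 0
  dim(intens) <- c(side, side)
  vig <- 1 - noise$vignetting * (rr_px / (sqrt(2) * W))^2
  frame <- noise$background + intens * vig
  if (noise$sigma > 0) {
    frame <- frame + .with_seed(noise$seed + seed_offset,
                                matrix(stats::rnorm(side * side, 0, noise$sigma),
                                       side, side))
  }
  attr(frame, "pixel_size_um") <- pixel_size_um
  attr(frame, "center") <- c(ctr, ctr)
  frame
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Render a whole simulation as a synthetic image series
#'
#' @param sim a `gel_sim`.
#' @param p model parameters (default: the run's).
#' @param pixel_size_um pixel size, um/px.
#' @param noise an [imaging_noise_model()].
#' @param every keep every `every`-th stored state (thins long runs).
#' @param idx explicit state indices to render (overrides `every`).
#' @param scale `"frame"`: normalise each frame to its own production peak,
#'   mimicking an autoscaled acquisition (the experimental preprocessing
#'   autoscales too) — the ring keeps its contrast while it exists and
#'   vanishes into the noise floor only when production truly flattens.
#'   `"series"`: one run-wide scale, so the ring fades as the reaction dies.
#' @return Object of class `image_series`: list of `frames`, `timestamps`
#'   (s), `pixel_size_um`, `center`.
#' @export
render_series <- function(sim, p = NULL, pixel_size_um = 10,
                          noise = imaging_noise_model(), every = 1,
                          idx = NULL, scale = c("frame", "series")) {
  stopifnot(inherits(sim, "gel_sim"))
  scale <- match.arg(scale)
  p <- p %||% sim$params
  idx <- idx %||% seq(1, length(sim$times), by = every)
  series_peak <- NULL
  if (scale == "series") {
    pk <- 0
    for (i in idx) pk <- max(pk, max(production_profile(sim_state(sim, i), p)))
    series_peak <- if (pk > 0) pk else 1
  }
  frames <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    frames[[k]] <- render_frame(sim_state(sim, idx[k]), p, pixel_size_um,
                                noise, intensity_scale = series_peak,
                                seed_offset = k)
  }
  image_series(frames, sim$times[idx], pixel_size_um)
}

#' Image series container
#'
#' @param frames list of equal-sized numeric matrices.
#' @param timestamps strictly increasing times, s.
#' @param pixel_size_um pixel size, um/px.
#' @param center optional (row, col) centre estimate; defaults to the frame
#'   centre.
#' @return Object of class `image_series`.
#' @export
image_series <- function(frames, timestamps, pixel_size_um, center = NULL) {
  if (!length(frames)) stop("empty image series")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims != dims[, 1])) stop("all frames must have the same shape")
  if (length(timestamps) != length(frames) ||
      (length(timestamps) > 1 && any(diff(timestamps) <= 0))) {
    stop("timestamps must be strictly increasing, one per frame")
  }
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  center <- center %||% ((dims[, 1] + 1) / 2)
  structure(list(frames = frames, timestamps = timestamps,
                 pixel_size_um = pixel_size_um, center = center),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("image_series: %d frames %dx%d px, %g um/px, t = %g..%g s\n",
              length(x$frames), d[1], d[2], x$pixel_size_um,
              min(x$timestamps), max(x$timestamps)))
  invisible(x)
}

#' Difference-of-Gaussians bandpass filter
#'
#' Approximates the FFT bandpass used to enhance the low-contrast gelation
#' interface in the experimental time-lapses ("filter large structures down
#' to 50 px, small structures up to 3 px"): a difference of Gaussian
#' low-passes with `sigma_small = small_px / 2` and
#' `sigma_large = large_px / 2`, applied in the Fourier domain with
#' periodic boundaries. Output has exactly zero mean.
#'
#' @param frame numeric matrix, at least 64 x 64.
#' @param large_px structures larger than this are removed (default 50).
#' @param small_px structures smaller than this are removed (default 3).
#' @return Filtered matrix, same shape, zero mean; attributes preserved.
#' @export
bandpass_filter <- function(frame, large_px = 50, small_px = 3) {
  if (!is.matrix(frame) || nrow(frame) < 64 || ncol(frame) < 64) {
    stop("frame must be a matrix of at least 64 x 64 pixels")
  }
  if (large_px <= small_px) stop("large_px must exceed small_px")
  nr <- nrow(frame); nc <- ncol(frame)
  fx <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)) / nr
  fy <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)) / nc
  f2 <- outer(fx^2, fy^2, "+")
  gauss_tf <- function(sig) exp(-2 * pi^2 * sig^2 * f2)
  H <- gauss_tf(small_px / 2) - gauss_tf(large_px / 2)
  out <- Re(stats::fft(stats::fft(frame) * H, inverse = TRUE)) / (nr * nc)
  out <- out - mean(out)
  attributes(out) <- attributes(frame)
  dim(out) <- c(nr, nc)
  out
}

#' Azimuthally averaged radial intensity profile
#'
#' @param frame numeric matrix.
#' @param center (row, col) of the symmetry centre, px.
#' @return Data frame with `radius_px` (1 px bins) and `intensity`.
#' @export
radial_profile <- function(frame, center = attr(frame, "center")) {
  if (is.null(center)) center <- (dim(frame) + 1) / 2
  if (center[1] < 1 || center[1] > nrow(frame) ||
      center[2] < 1 || center[2] > ncol(frame)) {
    stop("center lies outside the frame")
  }
  rr <- sqrt(outer((seq_len(nrow(frame)) - center[1])^2,
                   (seq_len(ncol(frame)) - center[2])^2, "+"))
  bin <- as.integer(round(rr))
  means <- tapply(as.vector(frame), bin, mean)
  data.frame(radius_px = as.integer(names(means)),
             intensity = as.numeric(means))
}

#' Detect the front diameter in a single frame
#'
#' Measures the ring radius as the peak of the azimuthally averaged radial
#' intensity profile, refined to sub-pixel precision by parabolic
#' interpolation through the peak bin and its neighbours. The detection is
#' rejected (not found) when the peak's prominence over the profile median
#' is below `prominence` times the profile's robust spread (MAD), so flat
#' or noise-only frames yield `NA`.
#'
#' @param frame numeric matrix (raw or bandpassed).
#' @param center (row, col) centre, px; defaults to the frame's `center`
#'   attribute or geometric centre.
#' @param pixel_size_um pixel size; defaults to the frame attribute.
#' @param prominence detection threshold in robust-sd units (default 6).
#' @param min_radius_px ignore bins closer to the centre than this.
#' @return List with `diameter_um` (`NA_real_` if not found), `radius_px`,
#'   `prominence`.
#' @export
detect_front_diameter <- function(frame, center = NULL, pixel_size_um = NULL,
                                  prominence = 6, min_radius_px = 3) {
  center <- center %||% attr(frame, "center") %||% ((dim(frame) + 1) / 2)
  pixel_size_um <- pixel_size_um %||% attr(frame, "pixel_size_um")
  if (is.null(pixel_size_um)) stop("pixel_size_um not given and not an attribute")
  prof <- radial_profile(frame, center)
  # the corner bins average very few pixels; restrict to radii fully inside
  rmax <- floor(min(center[1] - 1, nrow(frame) - center[1],
                    center[2] - 1, ncol(frame) - center[2]))
  prof <- prof[prof$radius_px >= min_radius_px & prof$radius_px <= rmax, ]
  if (nrow(prof) < 5) stop("usable radial profile too short")
  v <- prof$intensity
  med <- stats::median(v)
  spread <- stats::mad(v)
  i <- max(which(v == max(v)))             # outermost tie
  prom <- if (spread > 0) (v[i] - med) / spread else Inf
  if (max(v) <= med || prom < prominence) {
    return(list(diameter_um = NA_real_, radius_px = NA_real_,
                prominence = if (is.finite(prom)) prom else 0))
  }
  r_pk <- prof$radius_px[i]
  if (i > 1 && i < length(v)) {           # parabolic sub-pixel refinement
    denom <- v[i - 1] - 2 * v[i] + v[i + 1]
    if (denom < 0) r_pk <- r_pk + 0.5 * (v[i - 1] - v[i + 1]) / denom
  }
  list(diameter_um = 2 * r_pk * pixel_size_um, radius_px = r_pk,
       prominence = prom)
}

#' Track the gelation front through an image series
#'
#' Bandpass-filters each frame (optional), detects the ring diameter, and
#' enforces inward motion: a detection jumping outward by more than
#' `max_outward_px` relative to the last accepted one is dropped as spurious.
#' Results are returned as a [front_trajectory()] in physical units, from
#' which gelation time and the two-phase velocities follow exactly as for
#' simulated fields.
#'
#' @param series an [image_series()] with at least 5 frames.
#' @param bandpass apply [bandpass_filter()] first (default TRUE).
#' @param large_px,small_px bandpass scales.
#' @param prominence detection threshold, see [detect_front_diameter()].
#' @param max_outward_px outward-jump rejection threshold (default 5).
#' @return A [front_trajectory()] (radii in mm).
#' @export
track_image_series <- function(series, bandpass = TRUE,
                               large_px = 50, small_px = 3,
                               prominence = 6, max_outward_px = 5) {
  stopifnot(inherits(series, "image_series"))
  nf <- length(series$frames)
  if (nf < 5) stop("need at least 5 frames")
  radius_px <- rep(NA_real_, nf)
  last <- NA_real_
  for (k in seq_len(nf)) {
    fr <- series$frames[[k]]
    if (bandpass) fr <- bandpass_filter(fr, large_px, small_px)
    det <- detect_front_diameter(fr, center = series$center,
                                 pixel_size_um = series$pixel_size_um,
                                 prominence = prominence)
    r <- det$radius_px
    if (is.finite(r) && is.finite(last) && r > last + max_outward_px) {
      r <- NA_real_                         # outward jump: spurious detection
    }
    if (is.finite(r)) last <- r
    radius_px[k] <- r
  }
  if (!any(is.finite(radius_px))) stop("front detection failed on every frame")
  radius_mm <- radius_px * series$pixel_size_um / 1000
  front_trajectory(series$timestamps, radius_mm, source = "image_tracking")
}

#' Write / read an image series as plain-text PGM frames
#'
#' Frames are stored as ASCII PGM (P2, 16-bit) files `<prefix>_0001.pgm`,
#' ..., quantised over the series-wide intensity range, with a sidecar
#' `<prefix>_meta.csv` holding timestamps, pixel size and the quantisation
#' range so that reading inverts writing up to quantisation (relative error
#' <= 1/65535 of the intensity range).
#'
#' @param series an [image_series()].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return `write_image_series`: the metadata path, invisibly;
#'   `read_image_series`: an [image_series()].
#' @export
write_image_series <- function(series, dir, prefix = "frame") {
  stopifnot(inherits(series, "image_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lo <- min(vapply(series$frames, min, 0)); hi <- max(vapply(series$frames, max, 0))
  if (hi <= lo) hi <- lo + 1
  files <- character(length(series$frames))
  for (k in seq_along(series$frames)) {
    f <- series$frames[[k]]
    q <- round((f - lo) / (hi - lo) * 65535)
    path <- file.path(dir, sprintf("%s_%04d.pgm", prefix, k))
    con <- file(path, "w")
    writeLines(c("P2", paste(ncol(f), nrow(f)), "65535"), con)
    write(t(q), con, ncolumns = ncol(f))
    close(con)
    files[k] <- basename(path)
  }
  meta <- data.frame(file = files, timestamp_s = series$timestamps,
                     pixel_size_um = series$pixel_size_um,
                     center_row = series$center[1],
                     center_col = series$center[2],
                     intensity_lo = lo, intensity_hi = hi)
  meta_path <- file.path(dir, paste0(prefix, "_meta.csv"))
  utils::write.csv(meta, meta_path, row.names = FALSE)
  invisible(meta_path)
}

#' @rdname write_image_series
#' @param meta_path path to the `<prefix>_meta.csv` written alongside frames.
#' @export
read_image_series <- function(meta_path) {
  meta <- utils::read.csv(meta_path)
  dir <- dirname(meta_path)
  frames <- lapply(meta$file, function(fn) {
    toks <- scan(file.path(dir, fn), what = character(), quiet = TRUE,
                 comment.char = "#")
    if (toks[1] != "P2") stop("not an ASCII PGM (P2) file: ", fn)
    w <- as.integer(toks[2]); h <- as.integer(toks[3])
    vals <- as.numeric(toks[-(1:4)])
    lo <- meta$intensity_lo[1]; hi <- meta$intensity_hi[1]
    matrix(vals, nrow = h, ncol = w, byrow = TRUE) / 65535 * (hi - lo) + lo
  })
  image_series(frames, meta$timestamp_s, meta$pixel_size_um[1],
               center = c(meta$center_row[1], meta$center_col[1]))
}

#' Estimate the disc centre from the first frame
#'
#' Intensity-weighted centroid of the positive part of the bandpassed first
#' frame — adequate for real stacks where the centre is not known a priori.
#'
#' @param series an [image_series()].
#' @return Numeric (row, col).
#' @export
estimate_center <- function(series) {
  stopifnot(inherits(series, "image_series"))
  f <- bandpass_filter(series$frames[[1]])
  w <- pmax(f, 0)
  sw <- sum(w)
  if (sw <= 0) return((dim(f) + 1) / 2)
  c(sum(row(f) * w), sum(col(f) * w)) / sw
}
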