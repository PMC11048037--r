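#' Retina-like detector configuration
#'
#' Describes a foveated concentric-ring pixel mosaic: a central fovea of
#' fine rings with constant radial pitch surrounded by peripheral rings
#' whose radial extents grow geometrically out to the edge of the
#' photosensitive disc, mimicking the fall-off of photoreceptor density
#' away from the fovea.
#'
#' The default fovea schedule assigns ring `k` (1-based) a pixel count
#' proportional to its circumference, `6306 * (2k - 1) / 50^2`, corrected by
#' largest remainder so the counts sum to exactly 6306.
#'
#' @param n_fovea_rings Number of fovea rings (default 50).
#' @param n_periph_rings Number of peripheral rings (default 88).
#' @param min_pixel_size_um Radial pitch of fovea rings, micrometres
#'   (default 14).
#' @param photosensitive_radius_um Radius of the photosensitive disc,
#'   micrometres (default 5113).
#' @param periph_pixels_per_ring Pixels in each peripheral ring
#'   (default 520).
#' @param fovea_ring_schedule Optional integer vector of per-ring fovea
#'   pixel counts (length `n_fovea_rings`).
#' @return An object of class `ring_detector_config`.
#' @examples
#' cfg <- ring_detector_config()
#' sum(cfg$fovea_ring_schedule)    # 6306
#' @export
ring_detector_config <- function(n_fovea_rings = 50, n_periph_rings = 88,
                                 min_pixel_size_um = 14,
                                 photosensitive_radius_um = 5113,
                                 periph_pixels_per_ring = 520,
                                 fovea_ring_schedule = NULL) {
  if (n_fovea_rings < 1) abort("`n_fovea_rings` must be >= 1.")
  if (n_periph_rings < 0) abort("`n_periph_rings` must be >= 0.")
  if (min_pixel_size_um <= 0) abort("`min_pixel_size_um` must be > 0.")
  if (photosensitive_radius_um <= n_fovea_rings * min_pixel_size_um &&
      n_periph_rings > 0) {
    abort("photosensitive radius must exceed the fovea extent.")
  }
  if (is.null(fovea_ring_schedule)) {
    fovea_ring_schedule <- largest_remainder_schedule(
      6306 * (2 * seq_len(n_fovea_rings) - 1) / n_fovea_rings^2, 6306)
  }
  if (length(fovea_ring_schedule) != n_fovea_rings ||
      any(fovea_ring_schedule < 1)) {
    abort("`fovea_ring_schedule` must give a positive count per fovea ring.")
  }
  structure(list(
    n_fovea_rings = as.integer(n_fovea_rings),
    n_periph_rings = as.integer(n_periph_rings),
    min_pixel_size_um = min_pixel_size_um,
    photosensitive_radius_um = photosensitive_radius_um,
    periph_pixels_per_ring = as.integer(periph_pixels_per_ring),
    fovea_ring_schedule = as.integer(fovea_ring_schedule),
    reference_counts = list(fovea_pixels = 6306L, periph_pixels = 45760L,
                            total_pixels = 52066L, R = 7.07, Q = 731)),
    class = "ring_detector_config")
}

# Round a positive real vector to integers preserving the target sum.
largest_remainder_schedule <- function(x, total) {
  fl <- floor(x)
  short <- total - sum(fl)
  if (short > 0) {
    bump <- order(x - fl, decreasing = TRUE)[seq_len(short)]
    fl[bump] <- fl[bump] + 1
  } else if (short < 0) {
    drop <- order(x - fl)[seq_len(-short)]
    fl[drop] <- fl[drop] - 1
  }
  pmax(as.integer(fl), 1L)
}

#' Build the concentric-ring pixel layout
#'
#' Constructs the full per-pixel geometry of the mosaic as a tibble: one row
#' per pixel with ring index, angular index, centre radius and angle, radial
#' extent and arc extent. Fovea rings use the constant minimum pitch;
#' peripheral radial extents grow geometrically from that pitch so the
#' outermost ring ends exactly at the photosensitive radius.
#'
#' @param config A [ring_detector_config()].
#' @return A tibble of class `ring_layout` with columns `ring`, `index`,
#'   `r_inner_um`, `r_outer_um`, `r_center_um`, `theta_center_rad`, `dr_um`,
#'   `arc_um`; the configuration and per-ring boundaries are attached as
#'   attributes. Use [glance()] for the summary metrics (pixel counts, ring
#'   count, R, Q).
#' @examples
#' layout <- build_ring_layout(ring_detector_config())
#' glance(layout)
#' @export
build_ring_layout <- function(config = ring_detector_config()) {
  nf <- config$n_fovea_rings
  np <- config$n_periph_rings
  pitch <- config$min_pixel_size_um
  fovea_edge <- nf * pitch
  if (np > 0) {
    span <- config$photosensitive_radius_um - fovea_edge
    if (span <= 0) abort("schedule/radius inconsistency: no peripheral span.")
    # growth factor g solves pitch * sum_{j=1..np} g^j = span
    f <- function(g) pitch * sum(g^seq_len(np)) - span
    if (f(1 + 1e-12) > 0) {
      abort(paste("schedule/radius inconsistency: peripheral span too small",
                  "for rings growing from the fovea pitch."))
    }
    g <- uniroot(f, c(1 + 1e-12, 4), tol = 1e-14)$root
    periph_dr <- pitch * g^seq_len(np)
    boundaries <- c(seq(0, fovea_edge, by = pitch),
                    fovea_edge + cumsum(periph_dr))
    boundaries[length(boundaries)] <- config$photosensitive_radius_um
  } else {
    boundaries <- seq(0, fovea_edge, by = pitch)
  }
  counts <- c(config$fovea_ring_schedule,
              rep(config$periph_pixels_per_ring, np))
  rings <- purrr::map(seq_len(nf + np), function(k) {
    n <- counts[[k]]
    idx <- seq_len(n) - 1L
    tibble::tibble(
      ring = k, index = idx,
      r_inner_um = boundaries[k], r_outer_um = boundaries[k + 1],
      r_center_um = (boundaries[k] + boundaries[k + 1]) / 2,
      theta_center_rad = (idx + 0.5) * 2 * pi / n,
      dr_um = boundaries[k + 1] - boundaries[k],
      arc_um = (boundaries[k] + boundaries[k + 1]) / 2 * 2 * pi / n)
  })
  layout <- dplyr::bind_rows(rings)
  structure(layout, config = config, boundaries = boundaries,
            ring_counts = counts,
            class = c("ring_layout", class(layout)))
}

#' @export
glance.ring_layout <- function(x, ...) {
  cfg <- attr(x, "config")
  counts <- attr(x, "ring_counts")
  nf <- cfg$n_fovea_rings
  fovea_px <- sum(counts[seq_len(nf)])
  periph_px <- sum(counts[-seq_len(nf)])
  tibble::tibble(
    n_rings = length(counts),
    fovea_pixels = fovea_px,
    periph_pixels = periph_px,
    total_pixels = fovea_px + periph_px,
    R = max(x$dr_um) / min(x$dr_um),
    Q = 2 * cfg$photosensitive_radius_um / cfg$min_pixel_size_um)
}

#' Logarithmic pixel response model
#'
#' Emulates a logarithmic photoresponse (as produced by a 7T logarithmic
#' pixel circuit): `response = dark_offset + gain * log(1 + v)` for input
#' luminance `v`, with the input clamped at `saturation_input`. Monotone
#' non-decreasing; `log_pixel_decode()` inverts the encoding exactly below
#' saturation.
#'
#' @param dark_offset Output at zero input.
#' @param gain Output units per e-fold of input.
#' @param saturation_input Input level at which the response saturates.
#' @return An object of class `log_pixel_model`.
#' @export
log_pixel_model <- function(dark_offset = 0, gain = 1,
                            saturation_input = Inf) {
  if (gain <= 0) abort("`gain` must be > 0.")
  structure(list(dark_offset = dark_offset, gain = gain,
                 saturation_input = saturation_input),
            class = "log_pixel_model")
}

#' @rdname log_pixel_model
#' @param model A `log_pixel_model`.
#' @param v Input luminance values (>= 0).
#' @export
log_pixel_encode <- function(model, v) {
  if (any(v < 0)) abort("input luminance must be >= 0.")
  model$dark_offset + model$gain * log1p(pmin(v, model$saturation_input))
}

#' @rdname log_pixel_model
#' @param r Encoded response values.
#' @export
log_pixel_decode <- function(model, r) {
  expm1((r - model$dark_offset) / model$gain)
}

# Map cartesian coordinates (um, detector-centred) to 1-based pixel ids;
# NA outside the photosensitive disc.
locate_pixels <- function(x_um, y_um, layout) {
  boundaries <- attr(layout, "boundaries")
  counts <- attr(layout, "ring_counts")
  offsets <- c(0L, cumsum(counts))
  r <- sqrt(x_um^2 + y_um^2)
  ring <- findInterval(r, boundaries, rightmost.closed = TRUE)
  ring[ring < 1 | ring > length(counts)] <- NA_integer_
  ang <- atan2(y_um, x_um) %% (2 * pi)
  idx <- floor(ang / (2 * pi) * counts[ring])
  idx <- pmin(idx, counts[ring] - 1L)    # guard the 2*pi wrap
  offsets[ring] + idx + 1L
}

#' Sample a Cartesian image onto the ring mosaic
#'
#' Averages the scene luminance over each pixel footprint (supersampled on
#' the Cartesian grid) and applies the logarithmic pixel response. The image
#' centre is taken as the detector centre; the image must cover the whole
#' photosensitive disc at the stated scale.
#'
#' @param image Numeric matrix of scene luminance (rows = y, cols = x).
#' @param layout A [build_ring_layout()] result.
#' @param pixel_model A [log_pixel_model()].
#' @param scale_um Micrometres per image grid cell.
#' @param oversample Subsamples per cell edge for footprint averaging.
#' @return A tibble with one row per mosaic pixel: `pixel`, `ring`, `index`,
#'   `response` (and `mean_input`, the footprint-average luminance).
#' @export
retina_sample <- function(image, layout, pixel_model = log_pixel_model(),
                          scale_um = attr(layout, "config")$min_pixel_size_um,
                          oversample = 4) {
  cfg <- attr(layout, "config")
  half_x <- ncol(image) * scale_um / 2
  half_y <- nrow(image) * scale_um / 2
  if (half_x < cfg$photosensitive_radius_um ||
      half_y < cfg$photosensitive_radius_um) {
    abort("image smaller than the detector footprint at this scale.")
  }
  sub <- (seq_len(oversample) - 0.5) / oversample
  xs <- as.vector(outer(seq_len(ncol(image)) - 1, sub, `+`)) * scale_um - half_x
  ys <- as.vector(outer(seq_len(nrow(image)) - 1, sub, `+`)) * scale_um - half_y
  grid <- expand.grid(y = ys, x = xs)
  pid <- locate_pixels(grid$x, grid$y, layout)
  # value at each subsample point = value of the parent cell
  ci <- findInterval((grid$x + half_x) / scale_um, seq_len(ncol(image)) - 1,
                     rightmost.closed = TRUE)
  ri <- findInterval((grid$y + half_y) / scale_um, seq_len(nrow(image)) - 1,
                     rightmost.closed = TRUE)
  vals <- image[cbind(ri, ci)]
  keep <- !is.na(pid)
  means <- rep(0, nrow(layout))
  sums <- tapply(vals[keep], pid[keep], mean)
  means[as.integer(names(sums))] <- as.numeric(sums)
  tibble::tibble(
    pixel = seq_len(nrow(layout)),
    ring = layout$ring, index = layout$index,
    mean_input = means,
    response = log_pixel_encode(pixel_model, means))
}

#' Reconstruct a Cartesian image from mosaic responses
#'
#' Inverse of [retina_sample()]: each output cell takes the decoded value of
#' the mosaic pixel whose footprint contains it; cells outside the
#' photosensitive disc get `background`.
#'
#' @param responses Tibble from [retina_sample()] (or a numeric vector of
#'   per-pixel responses in layout order).
#' @param layout A [build_ring_layout()] result.
#' @param output_shape `c(nrow, ncol)` of the output image.
#' @param pixel_model The [log_pixel_model()] used at sampling time.
#' @param scale_um Micrometres per output grid cell.
#' @param background Fill value outside the photosensitive disc.
#' @return Numeric matrix of decoded scene luminance.
#' @export
retina_reconstruct <- function(responses, layout, output_shape,
                               pixel_model = log_pixel_model(),
                               scale_um = attr(layout, "config")$min_pixel_size_um,
                               background = 0) {
  resp <- if (is.data.frame(responses)) responses$response else responses
  if (length(resp) != nrow(layout)) {
    abort("responses length must match the layout pixel count.")
  }
  decoded <- log_pixel_decode(pixel_model, resp)
  nr <- output_shape[1]; nc <- output_shape[2]
  xs <- ((seq_len(nc) - 0.5) - nc / 2) * scale_um
  ys <- ((seq_len(nr) - 0.5) - nr / 2) * scale_um
  grid <- expand.grid(y = ys, x = xs)
  pid <- locate_pixels(grid$x, grid$y, layout)
  out <- ifelse(is.na(pid), background, decoded[pid])
  matrix(out, nrow = nr, ncol = nc)
}

#' Export / import a ring layout as CSV
#'
#' One row per pixel: `ring`, `index`, `r_center_um`, `theta_center_rad`,
#' `dr_um`, `arc_um`.
#'
#' @param layout A `ring_layout`.
#' @param path Output CSV path.
#' @return `write_ring_layout()` returns `path` invisibly;
#'   `read_ring_layout()` returns a tibble.
#' @export
write_ring_layout <- function(layout, path) {
  write.csv(layout[, c("ring", "index", "r_center_um", "theta_center_rad",
                       "dr_um", "arc_um")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ring_layout
#' @export
read_ring_layout <- function(path) {
  tibble::as_tibble(read.csv(path))
}
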