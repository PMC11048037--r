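#' Synthetic laser-spot generator
#'
#' Generates test images with known ground truth: an elliptical Gaussian
#' spot `amplitude * exp(-((x-x0)^2/(2 sx^2) + (y-y0)^2/(2 sy^2))) + offset`
#' optionally damaged by a notch (a circular bite removed from the spot,
#' emulating occlusions and dropouts in real spot images) and corrupted by
#' additive Gaussian noise. Deterministic for a fixed seed.
#'
#' Coordinates are 0-based cell-centre units: `x` rightward along columns,
#' `y` downward along rows.
#'
#' @param shape `c(nrow, ncol)` of the image.
#' @param amplitude,x0,y0,sx,sy,offset Gaussian truth parameters.
#' @param notch Optional list `list(x, y, radius)`: cells within `radius` of
#'   `(x, y)` are zeroed (minus the offset floor).
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param seed Integer seed for the noise.
#' @return A list with `image` (matrix) and `truth` (one-row tibble of the
#'   generator parameters).
#' @examples
#' spot <- generate_synthetic_spot(c(64, 64), x0 = 30, y0 = 34)
#' @export
generate_synthetic_spot <- function(shape = c(64, 64), amplitude = 1,
                                    x0 = (shape[2] - 1) / 2,
                                    y0 = (shape[1] - 1) / 2,
                                    sx = 6, sy = 6, offset = 0,
                                    notch = NULL, noise_sd = 0, seed = 42) {
  if (amplitude <= 0 || sx <= 0 || sy <= 0) {
    abort("amplitude and sigmas must be > 0.")
  }
  xs <- matrix(rep(seq_len(shape[2]) - 1, each = shape[1]), nrow = shape[1])
  ys <- matrix(rep(seq_len(shape[1]) - 1, times = shape[2]), nrow = shape[1])
  img <- amplitude * exp(-((xs - x0)^2 / (2 * sx^2) +
                           (ys - y0)^2 / (2 * sy^2))) + offset
  if (!is.null(notch)) {
    bite <- (xs - notch$x)^2 + (ys - notch$y)^2 <= notch$radius^2
    img[bite] <- offset
  }
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    img <- img + matrix(rnorm(length(img), 0, noise_sd), nrow = shape[1])
  }
  truth <- tibble::tibble(amplitude = amplitude, x0 = x0, y0 = y0,
                          sx = sx, sy = sy, offset = offset,
                          noise_sd = noise_sd, seed = seed,
                          notched = !is.null(notch))
  list(image = img, truth = truth)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Binarize a spot image
#'
#' Global thresholding of a grayscale image into a foreground (spot
#' candidate) mask. The default threshold is Otsu's, computed on the image
#' rescaled to `[0, 1]`; a fixed threshold on the same scale may be given
#' instead.
#'
#' @param image Numeric matrix.
#' @param threshold `"otsu"` or a number in `[0, 1]` on the rescaled range.
#' @return Logical matrix; all-`FALSE` (with a warning) for a constant image.
#' @export
binarize <- function(image, threshold = "otsu") {
  rng <- range(image)
  if (diff(rng) == 0) {
    warn("constant image: empty mask.")
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  norm <- (image - rng[1]) / diff(rng)
  thr <- if (identical(threshold, "otsu")) {
    EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  } else threshold
  norm > thr
}

gaussian_kernel_1d <- function(sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable convolution with replicate padding.
convolve_sep <- function(image, kx, ky = kx) {
  pad_apply <- function(m, k, along_rows) {
    half <- (length(k) - 1L) / 2L
    if (along_rows) m <- t(m)
    n <- ncol(m)
    idx <- pmin(pmax(seq_len(n + 2 * half) - half, 1L), n)
    padded <- m[, idx, drop = FALSE]
    out <- matrix(0, nrow(m), n)
    for (j in seq_along(k)) {
      out <- out + k[j] * padded[, j:(j + n - 1), drop = FALSE]
    }
    if (along_rows) t(out) else out
  }
  pad_apply(pad_apply(image, kx, along_rows = FALSE), ky, along_rows = TRUE)
}

#' Canny edge detection
#'
#' Classic four-stage Canny operator: Gaussian smoothing, Sobel gradients,
#' non-maximum suppression along the quantized gradient direction, and
#' double-threshold hysteresis (weak edge pixels are kept only when
#' 8-connected, directly or transitively, to a strong pixel). Thresholds are
#' fractions of the maximum gradient magnitude. Edges come out 1 pixel wide
#' along the gradient direction.
#'
#' @param image Numeric matrix.
#' @param sigma Gaussian smoothing sigma in cells.
#' @param low,high Hysteresis thresholds as fractions of the maximum
#'   gradient magnitude; `0 <= low < high <= 1`.
#' @return Logical edge map of the same shape.
#' @export
canny_edges <- function(image, sigma = 1.4, low = 0.1, high = 0.3) {
  if (!(low < high) || low < 0 || high > 1) {
    abort("need 0 <= low < high <= 1.")
  }
  if (diff(range(image)) == 0) {
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  k <- gaussian_kernel_1d(sigma)
  sm <- convolve_sep(image, k)
  shift <- function(m, dy, dx) {
    nr <- nrow(m); nc <- ncol(m)
    ri <- pmin(pmax(seq_len(nr) + dy, 1L), nr)
    ci <- pmin(pmax(seq_len(nc) + dx, 1L), nc)
    m[ri, ci, drop = FALSE]
  }
  # Sobel
  gx <- (shift(sm, -1, 1) + 2 * shift(sm, 0, 1) + shift(sm, 1, 1)) -
        (shift(sm, -1, -1) + 2 * shift(sm, 0, -1) + shift(sm, 1, -1))
  gy <- (shift(sm, 1, -1) + 2 * shift(sm, 1, 0) + shift(sm, 1, 1)) -
        (shift(sm, -1, -1) + 2 * shift(sm, -1, 0) + shift(sm, -1, 1))
  mag <- sqrt(gx^2 + gy^2)
  mmax <- max(mag)
  if (mmax == 0) return(matrix(FALSE, nrow(image), ncol(image)))
  # non-maximum suppression: keep pixels that dominate both neighbours
  # along the gradient direction, quantized to the 8 compass offsets
  ang <- atan2(gy, gx)
  dx <- round(cos(ang)); dy <- round(sin(ang))
  nr <- nrow(mag); nc <- ncol(mag)
  ri <- matrix(rep(seq_len(nr), nc), nr); ci <- matrix(rep(seq_len(nc), each = nr), nr)
  gather <- function(sgn) {
    r2 <- pmin(pmax(ri + sgn * dy, 1), nr)
    c2 <- pmin(pmax(ci + sgn * dx, 1), nc)
    matrix(mag[cbind(as.vector(r2), as.vector(c2))], nr, nc)
  }
  nms <- mag >= gather(1) & mag >= gather(-1)
  strong <- nms & mag >= high * mmax
  weak <- nms & mag >= low * mmax
  # hysteresis: grow the strong set through weak pixels (8-connectivity)
  dilate8 <- function(m) {
    out <- m
    for (dy in -1:1) for (dx in -1:1) {
      if (dy || dx) out <- out | shift(m, dy, dx)
    }
    out
  }
  repeat {
    grown <- strong | (dilate8(strong) & weak)
    if (identical(grown, strong)) break
    strong <- grown
  }
  strong
}

#' Spot centroid and equivalent-area radius
#'
#' Centroid (first moment of the mask, or intensity-weighted when an image
#' is supplied) and the radius of the circle with the same area as the
#' foreground; the boundary cells (foreground cells with a background
#' 4-neighbour) are returned ordered by angle around the centroid.
#'
#' @param mask Logical foreground matrix.
#' @param image Optional intensity matrix for weighted moments.
#' @return A list of class `spot_geometry`: `centroid` (`c(x, y)`, 0-based
#'   cell units), `radius` (cells), `area` (cells), `boundary` (tibble of
#'   `x`, `y`).
#' @export
spot_geometry <- function(mask, image = NULL) {
  if (!any(mask)) abort("empty foreground: no spot to measure.")
  w <- if (is.null(image)) mask * 1 else ifelse(mask, image, 0)
  xs <- matrix(rep(seq_len(ncol(mask)) - 1, each = nrow(mask)), nrow(mask))
  ys <- matrix(rep(seq_len(nrow(mask)) - 1, times = ncol(mask)), nrow(mask))
  total <- sum(w)
  cx <- sum(w * xs) / total
  cy <- sum(w * ys) / total
  area <- sum(mask)
  inner <- mask &
    rbind(mask[-1, , drop = FALSE], FALSE) &
    rbind(FALSE, mask[-nrow(mask), , drop = FALSE]) &
    cbind(mask[, -1, drop = FALSE], FALSE) &
    cbind(FALSE, mask[, -ncol(mask), drop = FALSE])
  bnd <- which(mask & !inner, arr.ind = TRUE)
  boundary <- tibble::tibble(x = bnd[, 2] - 1, y = bnd[, 1] - 1)
  boundary <- boundary[order(atan2(boundary$y - cy, boundary$x - cx)), ]
  structure(list(centroid = c(x = cx, y = cy), radius = sqrt(area / pi),
                 area = area, boundary = boundary),
            class = "spot_geometry")
}

#' @export
print.spot_geometry <- function(x, ...) {
  cat(sprintf("<spot_geometry> centroid (%.2f, %.2f), radius %.2f cells\n",
              x$centroid[1], x$centroid[2], x$radius))
  invisible(x)
}

ellipse_inside <- function(mask, cx, cy, a, b, phi, n_check = 90) {
  th <- seq(0, 2 * pi, length.out = n_check + 1)[-1]
  for (f in c(1, 0.5)) {
    ex <- cx + f * a * cos(th) * cos(phi) - f * b * sin(th) * sin(phi)
    ey <- cy + f * a * cos(th) * sin(phi) + f * b * sin(th) * cos(phi)
    ci <- round(ex) + 1; ri <- round(ey) + 1
    if (any(ci < 1 | ci > ncol(mask) | ri < 1 | ri > nrow(mask))) return(FALSE)
    if (!all(mask[cbind(ri, ci)])) return(FALSE)
  }
  TRUE
}

#' Convex-hull raster of a foreground mask
#'
#' The spot "domain": all cells inside the convex hull of the foreground,
#' closing over notches and dropouts in the observed spot.
#'
#' @param mask Logical foreground matrix.
#' @return Logical matrix of the filled convex hull.
#' @export
convex_mask <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) < 3) return(mask)
  h <- grDevices::chull(pts[, 2], pts[, 1])
  hx <- pts[h, 2]; hy <- pts[h, 1]
  nr <- nrow(mask); nc <- ncol(mask)
  cx <- matrix(rep(seq_len(nc), each = nr), nr)
  cy <- matrix(rep(seq_len(nr), nc), nr)
  inside <- matrix(TRUE, nr, nc)
  n <- length(h)
  gx <- mean(hx); gy <- mean(hy)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    # half-plane test, oriented by the hull centroid
    cr <- (hx[j] - hx[i]) * (cy - hy[i]) - (hy[j] - hy[i]) * (cx - hx[i])
    s <- sign((hx[j] - hx[i]) * (gy - hy[i]) - (hy[j] - hy[i]) * (gx - hx[i]))
    if (s == 0) next
    inside <- inside & (s * cr >= -1e-9)
  }
  inside | mask
}

#' Largest inscribed ellipse of a spot domain
#'
#' Finds a large (rotated) ellipse inscribed in the spot domain -- the
#' convex hull of the foreground, so the ellipse spans defects (notches,
#' dropouts) bitten out of the observed spot. The centre is seeded at the
#' maximum of the domain's distance transform and the axes and rotation are
#' refined by coordinate ascent on a discrete grid. The result is a local
#' area maximum of this search, not a certified global optimum.
#'
#' @param mask Logical foreground matrix (connected region).
#' @return A list of class `spot_ellipse`: `center` (`c(x, y)`), `axes`
#'   (`c(a, b)` semi-axes in cells), `rotation_rad`, `area`.
#' @export
inscribe_ellipse <- function(mask) {
  if (sum(mask) < 4) abort("region too thin for an inscribed ellipse.")
  mask <- convex_mask(mask)
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  d <- EBImage::imageData(dm)
  seed <- which(d == max(d), arr.ind = TRUE)[1, ]
  cy <- seed[1] - 1; cx <- seed[2] - 1
  r0 <- max(d) - 0.5
  if (r0 < 1) abort("region thinner than 2 cells: degenerate ellipse.")
  a <- b <- r0
  phi <- 0
  step_geom <- max(1, r0 / 8)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    cand <- list()
    for (da in c(step_geom, 0)) for (db in c(step_geom, 0)) {
      if (da == 0 && db == 0) next
      for (dphi in c(-pi / 12, 0, pi / 12)) {
        for (dc in list(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
          cand <- c(cand, list(c(a + da, b + db, phi + dphi,
                                 cx + dc[1], cy + dc[2])))
        }
      }
    }
    for (cc in cand) {
      if (cc[1] * cc[2] > a * b &&
          ellipse_inside(mask, cc[4], cc[5], cc[1], cc[2], cc[3])) {
        a <- cc[1]; b <- cc[2]; phi <- cc[3]; cx <- cc[4]; cy <- cc[5]
        improved <- TRUE
        break
      }
    }
    if (!improved && step_geom > 0.5) {
      step_geom <- step_geom / 2
      improved <- TRUE
    }
  }
  structure(list(center = c(x = cx, y = cy), axes = c(a = a, b = b),
                 rotation_rad = phi %% pi, area = pi * a * b),
            class = "spot_ellipse")
}

#' Ellipse membership mask
#'
#' @param ellipse A [inscribe_ellipse()] result.
#' @param shape `c(nrow, ncol)`.
#' @return Logical matrix, `TRUE` inside the ellipse.
#' @export
ellipse_mask <- function(ellipse, shape) {
  xs <- matrix(rep(seq_len(shape[2]) - 1, each = shape[1]), nrow = shape[1])
  ys <- matrix(rep(seq_len(shape[1]) - 1, times = shape[2]), nrow = shape[1])
  phi <- ellipse$rotation_rad
  u <- (xs - ellipse$center[1]) * cos(phi) + (ys - ellipse$center[2]) * sin(phi)
  v <- -(xs - ellipse$center[1]) * sin(phi) + (ys - ellipse$center[2]) * cos(phi)
  (u / ellipse$axes[1])^2 + (v / ellipse$axes[2])^2 <= 1
}

#' Defect compensation by inscribed-ellipse infill
#'
#' Repairs notches and dropouts before Gaussian fitting: cells of the
#' inscribed ellipse that fell outside the foreground are replenished with
#' the intensity at the point reflected through the ellipse centre (spots
#' are centro-symmetric to good approximation), falling back to the mean
#' foreground intensity where the mirrored point is also defective.
#'
#' @param image Numeric matrix.
#' @param mask Foreground mask (default: [binarize()] of `image`).
#' @param ellipse Optional precomputed [inscribe_ellipse()].
#' @return List with `image` (compensated), `mask` (mask union ellipse) and
#'   `ellipse`.
#' @export
compensate_spot <- function(image, mask = binarize(image), ellipse = NULL) {
  ellipse <- ellipse %||% inscribe_ellipse(mask)
  em <- ellipse_mask(ellipse, dim(image))
  fill <- which(em & !mask, arr.ind = TRUE)
  out <- image
  if (nrow(fill)) {
    # reflect through the ellipse centre (0-based x = col - 1, y = row - 1)
    mr <- round(2 * ellipse$center[2] + 1 - fill[, 1])
    mc <- round(2 * ellipse$center[1] + 1 - fill[, 2])
    ok <- mr >= 1 & mr <= nrow(image) & mc >= 1 & mc <= ncol(image)
    ok[ok] <- mask[cbind(mr[ok], mc[ok])]
    out[fill[ok, , drop = FALSE]] <- image[cbind(mr[ok], mc[ok])]
    out[fill[!ok, , drop = FALSE]] <- mean(image[mask])
  }
  list(image = out, mask = mask | em, ellipse = ellipse)
}

#' Power-law (gamma) intensity transform
#'
#' `s = gain * r^gamma`, clipped to `[0, 1]`; monotone for any `gamma > 0`,
#' preserving 0 and (for `gain = 1`) 1.
#'
#' @param image Numeric matrix with values in `[0, 1]`.
#' @param gamma Exponent (> 0).
#' @param gain Multiplicative gain.
#' @return Transformed matrix in `[0, 1]`.
#' @export
gamma_transform <- function(image, gamma, gain = 1) {
  if (gamma <= 0) abort("`gamma` must be > 0.")
  if (any(image < 0)) abort("negative intensities: normalize to [0, 1] first.")
  pmin(pmax(gain * image^gamma, 0), 1)
}

#' Least-squares 2-D Gaussian fit
#'
#' Fits `amplitude * exp(-((x - x0)^2 / (2 sx^2) + (y - y0)^2 / (2 sy^2)))
#' + offset` to a spot image by Levenberg--Marquardt nonlinear least
#' squares, initialized from image moments unless `init` is given.
#'
#' @param image Numeric matrix with a dominant unimodal blob.
#' @param init Optional named list of starting values
#'   (`amplitude, x0, y0, sx, sy, offset`).
#' @param mask Optional logical matrix restricting the fit to valid cells
#'   (e.g. the compensated foreground, excluding unrepaired defects).
#' @param max_iter Maximum solver iterations.
#' @return An object of class `gaussian_spot_fit`; use [tidy()] for the
#'   parameter table and [glance()] for fit diagnostics.
#' @export
fit_gaussian <- function(image, init = NULL, mask = NULL, max_iter = 100) {
  keep <- if (is.null(mask)) rep(TRUE, length(image)) else as.vector(mask)
  df <- tibble::tibble(
    x = as.vector(matrix(rep(seq_len(ncol(image)) - 1, each = nrow(image)),
                         nrow(image)))[keep],
    y = as.vector(matrix(rep(seq_len(nrow(image)) - 1, times = ncol(image)),
                         nrow(image)))[keep],
    z = as.vector(image)[keep])
  if (is.null(init)) {
    off0 <- min(df$z)
    w <- pmax(df$z - off0, 0)
    tw <- sum(w)
    if (tw == 0) abort("flat image: nothing to fit.")
    x0 <- sum(w * df$x) / tw
    y0 <- sum(w * df$y) / tw
    sx0 <- sqrt(max(sum(w * (df$x - x0)^2) / tw, 0.25))
    sy0 <- sqrt(max(sum(w * (df$y - y0)^2) / tw, 0.25))
    init <- list(amplitude = max(df$z) - off0, x0 = x0, y0 = y0,
                 sx = sx0, sy = sy0, offset = off0)
  }
  par0 <- unlist(init[c("amplitude", "x0", "y0", "sx", "sy", "offset")])
  resfun <- function(p) {
    df$z - (p[1] * exp(-((df$x - p[2])^2 / (2 * p[4]^2) +
                         (df$y - p[3])^2 / (2 * p[5]^2))) + p[6])
  }
  fit <- minpack.lm::nls.lm(
    par = par0, fn = resfun,
    lower = c(1e-12, -Inf, -Inf, 1e-6, 1e-6, -Inf),
    control = minpack.lm::nls.lm.control(maxiter = max_iter))
  if (fit$info %in% c(0, 5, 9)) {
    abort(paste0("Gaussian fit did not converge: ", fit$message,
                 " (moment init: x0=", round(init$x0, 2),
                 ", y0=", round(init$y0, 2), ")"))
  }
  est <- setNames(as.list(fit$par),
                  c("amplitude", "x0", "y0", "sx", "sy", "offset"))
  structure(list(amplitude = est$amplitude, x0 = est$x0, y0 = est$y0,
                 sx = est$sx, sy = est$sy, offset = est$offset,
                 rss = sum(fit$fvec^2), n = nrow(df),
                 iterations = fit$niter, model = fit),
            class = "gaussian_spot_fit")
}

#' @export
print.gaussian_spot_fit <- function(x, ...) {
  cat(sprintf(
    "<gaussian_spot_fit> A=%.4g center=(%.3f, %.3f) sigma=(%.3f, %.3f) offset=%.4g rss=%.3g\n",
    x$amplitude, x$x0, x$y0, x$sx, x$sy, x$offset, x$rss))
  invisible(x)
}

#' @export
tidy.gaussian_spot_fit <- function(x, ...) {
  terms <- c("amplitude", "x0", "y0", "sx", "sy", "offset")
  se <- tryCatch({
    s2 <- x$rss / max(x$n - length(terms), 1)
    sqrt(diag(s2 * solve(x$model$hessian / 2)))
  }, error = function(e) rep(NA_real_, length(terms)))
  tibble::tibble(term = terms,
                 estimate = unlist(x[terms], use.names = FALSE),
                 std.error = as.numeric(se))
}

#' @export
glance.gaussian_spot_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n = x$n, rmse = sqrt(x$rss / x$n),
                 iterations = x$iterations)
}

#' Radial veiling-glare halo profile
#'
#' Samples the veiling luminance of the glare model over image radii: cell
#' radius `r` maps to glare angle `r * deg_per_cell` and the profile value
#' is `L_v` at that angle. Non-negative and non-increasing with radius.
#'
#' @inheritParams veiling_luminance
#' @param max_radius_cells Largest radius to tabulate.
#' @param deg_per_cell Angular scale of the image, degrees per cell.
#' @return A tibble of class `halo_profile` with `radius_cells`,
#'   `theta_deg`, `luminance`.
#' @export
halo_profile <- function(observer, scene, exposure,
                         calib = glare_calibration(),
                         max_radius_cells = 64, deg_per_cell = 0.05) {
  radius <- seq_len(max_radius_cells)
  theta <- radius * deg_per_cell
  lum <- veiling_luminance(theta, observer, scene, exposure, calib)
  out <- tibble::tibble(radius_cells = radius, theta_deg = theta,
                        luminance = lum)
  class(out) <- c("halo_profile", class(out))
  out
}

#' Biomimetic halo overlay
#'
#' Composites the veiling-glare halo onto the compensated spot, centred on
#' the fitted spot centre. Compositing is done in linear intensity
#' (`additive` adds the normalized halo; `screen` uses
#' `1 - (1-a)(1-b)`), then the result is min--max tone-mapped back to
#' `[0, 1]`.
#'
#' @param compensated Numeric spot matrix.
#' @param fit A [fit_gaussian()] result giving the halo centre.
#' @param halo A [halo_profile()].
#' @param mode `"additive"` or `"screen"`.
#' @return List with `image` (tone-mapped, `[0, 1]`), `linear` (pre
#'   tone-map composite) and `halo_image` (the rendered halo field).
#' @export
overlay_halo <- function(compensated, fit, halo, mode = c("additive", "screen")) {
  mode <- match.arg(mode)
  if (any(halo$luminance < 0)) abort("halo profile must be non-negative.")
  if (fit$x0 < 0 || fit$x0 > ncol(compensated) - 1 ||
      fit$y0 < 0 || fit$y0 > nrow(compensated) - 1) {
    abort("fitted centre lies outside the image.")
  }
  xs <- matrix(rep(seq_len(ncol(compensated)) - 1, each = nrow(compensated)),
               nrow(compensated))
  ys <- matrix(rep(seq_len(nrow(compensated)) - 1, times = ncol(compensated)),
               nrow(compensated))
  r <- sqrt((xs - fit$x0)^2 + (ys - fit$y0)^2)
  prof <- approx(c(0, halo$radius_cells), c(halo$luminance[1], halo$luminance),
                 xout = pmin(r, max(halo$radius_cells)), rule = 2)$y
  halo_img <- if (max(prof) > 0) prof / max(prof) else prof
  spot_lin <- compensated
  linear <- switch(mode,
                   additive = spot_lin + halo_img,
                   screen = 1 - (1 - pmin(spot_lin, 1)) * (1 - halo_img))
  rng <- range(linear)
  mapped <- if (diff(rng) > 0) (linear - rng[1]) / diff(rng) else linear * 0
  list(image = mapped, linear = linear, halo_image = halo_img)
}

#' Full laser-spot bionic pipeline
#'
#' Runs extraction (binarize, Canny, geometry), compensation (inscribed
#' ellipse infill, gamma enhancement, Gaussian fit) and, when a halo
#' profile is supplied, the biomimetic halo overlay.
#'
#' @param image Spot image matrix.
#' @param gamma Gamma-transform exponent applied after compensation.
#' @param halo Optional [halo_profile()].
#' @param canny_sigma,canny_low,canny_high Canny parameters.
#' @return A list of class `spot_pipeline`: `mask`, `edges`, `geometry`,
#'   `ellipse`, `compensated`, `fit`, `bionic` (or `NULL`), plus a one-row
#'   `summary` tibble (centroid, radius, fitted centre and sigmas).
#' @export
process_spot <- function(image, gamma = 0.8, halo = NULL,
                         canny_sigma = 1.4, canny_low = 0.1,
                         canny_high = 0.3) {
  mask <- binarize(image)
  edges <- canny_edges(image, canny_sigma, canny_low, canny_high)
  geom <- spot_geometry(mask, image)
  comp <- compensate_spot(image, mask)
  rng <- range(comp$image)
  normed <- if (diff(rng) > 0) (comp$image - rng[1]) / diff(rng) else comp$image
  enhanced <- gamma_transform(normed, gamma)
  # fit on the observed foreground only, then let the fitted model complete
  # the compensation over the replenished (ellipse) cells
  fit <- fit_gaussian(enhanced, mask = mask)
  fill <- comp$mask & !mask
  if (any(fill)) {
    xs <- matrix(rep(seq_len(ncol(image)) - 1, each = nrow(image)), nrow(image))
    ys <- matrix(rep(seq_len(nrow(image)) - 1, times = ncol(image)), nrow(image))
    pred <- fit$amplitude * exp(-((xs - fit$x0)^2 / (2 * fit$sx^2) +
                                  (ys - fit$y0)^2 / (2 * fit$sy^2))) + fit$offset
    enhanced[fill] <- pred[fill]
  }
  bionic <- if (!is.null(halo)) overlay_halo(enhanced, fit, halo) else NULL
  geom_comp <- spot_geometry(comp$mask, comp$image)
  summary <- tibble::tibble(
    centroid_x = unname(geom$centroid[1]),
    centroid_y = unname(geom$centroid[2]),
    radius_cells = geom_comp$radius, raw_radius_cells = geom$radius,
    fit_x0 = fit$x0, fit_y0 = fit$y0, fit_sx = fit$sx, fit_sy = fit$sy)
  structure(list(mask = mask, edges = edges, geometry = geom,
                 compensated_geometry = geom_comp,
                 ellipse = comp$ellipse, compensated = comp$image,
                 enhanced = enhanced,
                 fit = fit, bionic = bionic, summary = summary),
            class = "spot_pipeline")
}
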